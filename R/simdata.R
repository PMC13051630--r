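#' Configuration for the synthetic cross-prediction panel
#'
#' Defaults emulate the study system the package is built for: a panel of
#' 132 highly homozygous inbred accessions genotyped at ~3,000 genome-wide
#' SNPs (MAF > 0.05), 20 of them crossed into 156 F1 hybrids, with traits
#' measured over 3 consecutive years at broad-sense heritabilities around
#' 0.9.
#'
#' @param n_inbred number of inbred founder accessions.
#' @param n_loci number of biallelic SNP loci.
#' @param maf_range length-2 numeric, bounds of the uniform distribution
#'   population alternate-allele frequencies are drawn from.
#' @param residual_het_rate probability that an inbred carries a residual
#'   heterozygous call at a locus (inbreds are highly but not perfectly
#'   homozygous); must be in `[0, 0.2]`. The default 0.10 puts F1
#'   heterozygosity (~0.3 at these allele frequencies) at roughly 2.5-3x
#'   the inbred level, the relation reported for this kind of panel.
#' @param n_parents number of inbreds used as cross parents.
#' @param n_f1 number of F1 hybrids (distinct unordered parent pairs).
#' @param n_years number of replicate years.
#' @param h2_target broad-sense heritability the phenotype noise is
#'   calibrated to, in `(0, 1]`.
#' @param dominance_ratio target ratio of dominance-deviation variance to
#'   additive variance in the founder panel (>= 0).
#' @param year_effects optional numeric vector of per-year fixed offsets
#'   (trait units); `NULL` means offsets of +/- 0.25 genetic SD are used.
#' @param seed integer seed; every simulation operation is a pure function
#'   of its inputs and this seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_inbred = 132, n_loci = 3000, maf_range = c(0.05, 0.5),
                       residual_het_rate = 0.10, n_parents = 20, n_f1 = 156,
                       n_years = 3, h2_target = 0.9, dominance_ratio = 0.5,
                       year_effects = NULL, seed = 1L) {
  cfg <- list(n_inbred = as.integer(n_inbred), n_loci = as.integer(n_loci),
              maf_range = as.numeric(maf_range),
              residual_het_rate = residual_het_rate,
              n_parents = as.integer(n_parents), n_f1 = as.integer(n_f1),
              n_years = as.integer(n_years), h2_target = h2_target,
              dominance_ratio = dominance_ratio, year_effects = year_effects,
              seed = as.integer(seed))
  if (cfg$n_inbred < 1L || cfg$n_loci < 1L)
    stop("n_inbred and n_loci must be positive", call. = FALSE)
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[1] > cfg$maf_range[2] || cfg$maf_range[2] > 0.5)
    stop("maf_range must satisfy 0 < low <= high <= 0.5", call. = FALSE)
  if (cfg$residual_het_rate < 0 || cfg$residual_het_rate > 0.2)
    stop("residual_het_rate must be in [0, 0.2]", call. = FALSE)
  if (cfg$n_parents > cfg$n_inbred)
    stop("n_parents cannot exceed n_inbred", call. = FALSE)
  if (cfg$n_f1 > cfg$n_parents * (cfg$n_parents - 1) / 2)
    stop("n_f1 exceeds the number of unordered parent pairs", call. = FALSE)
  if (cfg$h2_target <= 0 || cfg$h2_target > 1)
    stop("h2_target must be in (0, 1]", call. = FALSE)
  if (cfg$dominance_ratio < 0)
    stop("dominance_ratio must be >= 0", call. = FALSE)
  if (!is.null(year_effects) && length(year_effects) != cfg$n_years)
    stop("year_effects must have length n_years", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder (inbred) genotypes
#'
#' Each locus gets a population alternate-allele frequency drawn uniformly
#' from `config$maf_range`; each inbred is homozygous (`1` with that
#' frequency, else `-1`) except at calls flipped to heterozygous (`0`)
#' with probability `residual_het_rate`. Loci that come out monomorphic
#' are redrawn for a bounded number of rounds so every retained locus is
#' polymorphic; the MAF > 0.05 panel rule is applied downstream by
#' [filter_maf()].
#'
#' @param config a [sim_config()].
#' @param max_rounds maximum regeneration rounds for monomorphic loci.
#' @return accessions x loci genotype matrix coded in \{-1, 0, 1\}.
#' @export
simulate_founder_genotypes <- function(config, max_rounds = 50L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_inbred; m <- config$n_loci
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  draw_locus <- function(pj) {
    x <- ifelse(runif(n) < pj, 1, -1)
    if (config$residual_het_rate > 0)
      x[runif(n) < config$residual_het_rate] <- 0
    x
  }
  g <- vapply(p, draw_locus, numeric(n))
  mono <- function(g) apply(g, 2, function(x) length(unique(x)) == 1L)
  bad <- mono(g)
  round <- 0L
  while (any(bad) && round < max_rounds) {
    round <- round + 1L
    p[bad] <- runif(sum(bad), config$maf_range[1], config$maf_range[2])
    g[, bad] <- vapply(p[bad], draw_locus, numeric(n))
    bad <- mono(g)
  }
  if (any(bad))
    stop("monomorphic-locus regeneration did not converge in ", max_rounds,
         " rounds", call. = FALSE)
  dimnames(g) <- list(sprintf("INB%03d", seq_len(n)),
                      sprintf("M%04d", seq_len(m)))
  g
}

#' Simulate F1 crosses and their true genotypes
#'
#' Samples `n_f1` distinct unordered pairs of parents, orients each pair
#' as mother/father reproducibly, and simulates each F1's true genotype by
#' Mendelian gamete sampling: a homozygous parent transmits its allele, a
#' heterozygous parent transmits either allele with probability 1/2.
#'
#' @param genotypes founder genotype matrix.
#' @param parent_ids accession ids (rownames of `genotypes`) used as parents.
#' @param n_f1 number of crosses to generate.
#' @param seed integer seed.
#' @return list with `crosses` (data.frame `f1_id`, `mother_id`,
#'   `father_id`) and `f1_genotypes` (true F1 genotype matrix).
#' @export
make_crosses <- function(genotypes, parent_ids, n_f1, seed = 1L) {
  check_geno(genotypes)
  if (anyDuplicated(parent_ids))
    stop("duplicate parent ids", call. = FALSE)
  missing <- setdiff(parent_ids, rownames(genotypes))
  if (length(missing))
    stop("parents not in genotype matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(parent_ids) < 2)
    stop("need at least two parents", call. = FALSE)
  pairs <- t(combn(parent_ids, 2))
  if (n_f1 > nrow(pairs))
    stop("n_f1 exceeds the number of unordered parent pairs", call. = FALSE)
  set.seed(seed)
  sel <- pairs[sample(nrow(pairs), n_f1), , drop = FALSE]
  flip <- runif(n_f1) < 0.5
  mother <- ifelse(flip, sel[, 2], sel[, 1])
  father <- ifelse(flip, sel[, 1], sel[, 2])
  crosses <- data.frame(f1_id = sprintf("F1_%03d", seq_len(n_f1)),
                        mother_id = mother, father_id = father,
                        stringsAsFactors = FALSE)
  m <- ncol(genotypes)
  gamete <- function(x) {
    # alternate-allele count (0/1) transmitted by a parent with codes x
    a <- (x + 1) / 2                     # -1 -> 0, 0 -> 0.5, 1 -> 1
    het <- x == 0
    a[het] <- rbinom(sum(het), 1, 0.5)
    a
  }
  f1 <- matrix(0, n_f1, m,
               dimnames = list(crosses$f1_id, colnames(genotypes)))
  for (i in seq_len(n_f1)) {
    f1[i, ] <- gamete(genotypes[mother[i], ]) +
      gamete(genotypes[father[i], ]) - 1
  }
  list(crosses = crosses, f1_genotypes = f1)
}

#' Simulate a trait architecture with additive and dominance effects
#'
#' QTL positions are sampled without replacement; additive effects are
#' standard normal draws rescaled so the additive genetic variance in the
#' founder panel is 1. Dominance effects (applied when a genotype is
#' heterozygous) are concentrated on a small subset of `n_dom` QTL,
#' preferring low-frequency loci when a panel is supplied — the
#' complementation picture in which hybrids of two low-value parents
#' carrying recessive alleles at different loci exceed both parents —
#' default to directional positive draws, and are rescaled so the
#' founder-panel ratio of dominance-deviation variance to additive
#' variance equals `dominance_ratio`. With `dominance_ratio = 0` all
#' dominance effects are exactly zero.
#'
#' @param n_loci number of genotyped loci.
#' @param n_qtl number of causal loci.
#' @param dominance_ratio target Var(dominance)/Var(additive) in founders.
#' @param seed integer seed.
#' @param genotypes optional founder genotype matrix used to compute
#'   realized variances for effect scaling (recommended); when absent the
#'   scaling uses expected-heterozygosity algebra with `het_rate`.
#' @param dominance_sign `"positive"` (directional, default) or `"random"`.
#' @param n_dom number of QTL carrying a dominance effect (default:
#'   `min(8, n_qtl)`, "a few specific loci").
#' @param het_rate expected heterozygous-call rate used only when
#'   `genotypes` is `NULL`.
#' @param intercept trait intercept (trait units).
#' @return list of class `trait_architecture` with `qtl_indices`,
#'   `additive_effects`, `dominance_effects` (same length as the QTL set,
#'   zero outside the dominance subset), `intercept`.
#' @export
simulate_architecture <- function(n_loci, n_qtl, dominance_ratio, seed = 1L,
                                  genotypes = NULL,
                                  dominance_sign = c("positive", "random"),
                                  n_dom = NULL, het_rate = 0.1,
                                  intercept = 0) {
  dominance_sign <- match.arg(dominance_sign)
  if (n_qtl < 1) stop("n_qtl must be positive", call. = FALSE)
  if (n_qtl > n_loci) stop("n_qtl cannot exceed n_loci", call. = FALSE)
  if (dominance_ratio < 0) stop("dominance_ratio must be >= 0", call. = FALSE)
  if (is.null(n_dom)) n_dom <- min(8L, n_qtl)
  n_dom <- max(1L, min(n_dom, n_qtl))
  set.seed(seed)
  qtl <- sort(sample.int(n_loci, n_qtl))
  a <- rnorm(n_qtl)
  # dominance on a sparse subset, preferring low-MAF loci when known
  if (!is.null(genotypes)) {
    maf_q <- pmin(allele_freqs(genotypes), 1 - allele_freqs(genotypes))[qtl]
    w <- pmax(0.55 - maf_q, 0.05)
  } else w <- rep(1, n_qtl)
  dom_idx <- sample.int(n_qtl, n_dom, prob = w)
  d <- numeric(n_qtl)
  d[dom_idx] <- if (dominance_sign == "positive") abs(rnorm(n_dom))
                else rnorm(n_dom)

  if (!is.null(genotypes)) {
    check_geno(genotypes)
    if (n_loci != ncol(genotypes))
      stop("n_loci does not match ncol(genotypes)", call. = FALSE)
    X <- genotypes[, qtl, drop = FALSE]
    add_val <- drop(X %*% a)
    if (var(add_val) <= 0)
      stop("additive value has zero variance in the supplied panel",
           call. = FALSE)
    a <- a / sqrt(var(add_val))          # founder additive variance = 1
    if (dominance_ratio > 0) {
      H <- (X == 0) * 1
      dom_val <- drop(H %*% d)
      vd <- var(dom_val)
      if (vd <= 0)
        stop("no heterozygous calls at QTL in the supplied panel; cannot ",
             "scale dominance effects (increase residual_het_rate)",
             call. = FALSE)
      d <- d * sqrt(dominance_ratio / vd)
    } else d <- rep(0, n_qtl)
  } else {
    # expectation-based scaling: Var(x_k) ~= 4p(1-p)(1-h) + h - (h... )
    # use unit-variance additive standardization and Bernoulli(het_rate)
    # heterozygosity for the dominance deviation
    a <- a / sqrt(sum(a^2))
    if (dominance_ratio > 0) {
      vd <- sum(d^2) * het_rate * (1 - het_rate)
      if (vd <= 0) stop("het_rate must be positive when dominance_ratio > 0",
                        call. = FALSE)
      d <- d * sqrt(dominance_ratio / vd)
    } else d <- rep(0, n_qtl)
  }
  structure(list(qtl_indices = qtl, additive_effects = a,
                 dominance_effects = d, intercept = intercept),
            class = "trait_architecture")
}

#' Genetic values under a trait architecture
#'
#' `g_i = intercept + sum_k a_k x_ik + sum_k d_k 1[x_ik == 0]`.
#'
#' @param genotypes genotype matrix covering the architecture's loci.
#' @param arch a `trait_architecture`.
#' @return named numeric vector of genetic values.
#' @export
genetic_values <- function(genotypes, arch) {
  stopifnot(inherits(arch, "trait_architecture"))
  X <- genotypes[, arch$qtl_indices, drop = FALSE]
  drop(arch$intercept + X %*% arch$additive_effects +
         ((X == 0) * 1) %*% arch$dominance_effects)
}

#' Simulate multi-year phenotype records
#'
#' Observed values are `y_iy = g_i + year_effect_y + e_iy` with i.i.d.
#' Gaussian noise whose variance is calibrated from the target broad-sense
#' heritability on the realized genetic variance of the panel:
#' `sigma_e^2 = sigma_g^2 * n_years * (1 - h2) / h2`, so that
#' `h_b^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2 / n_years)` equals
#' `h2_target` in expectation.
#'
#' @param genotypes genotype matrix of all accessions to phenotype.
#' @param arch a `trait_architecture`.
#' @param config a [sim_config()] (uses `n_years`, `h2_target`,
#'   `year_effects`, `seed`).
#' @param trait trait label for the output records.
#' @return long-format data.frame `accession`, `year`, `trait`, `value`.
#' @export
simulate_phenotypes <- function(genotypes, arch, config, trait = "trait1") {
  stopifnot(inherits(config, "sim_config"))
  if (config$h2_target <= 0 || config$h2_target > 1)
    stop("h2_target must be in (0, 1]", call. = FALSE)
  g <- genetic_values(genotypes, arch)
  sg2 <- var(g)
  se2 <- sg2 * config$n_years * (1 - config$h2_target) / config$h2_target
  yeff <- config$year_effects
  if (is.null(yeff)) {
    # deterministic small year offsets, +/- a quarter genetic SD
    yeff <- 0.25 * sqrt(sg2) *
      scale(seq_len(config$n_years), scale = FALSE)[, 1]
  }
  set.seed(config$seed)
  n <- length(g)
  recs <- do.call(rbind, lapply(seq_len(config$n_years), function(y) {
    data.frame(accession = names(g), year = sprintf("Y%d", y), trait = trait,
               value = g + yeff[y] + rnorm(n, 0, sqrt(se2)),
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(is.finite(recs$value)))
  rownames(recs) <- NULL
  recs
}

#' Simulate a complete cross-prediction study
#'
#' Generates the full synthetic analogue of the study system: an inbred
#' founder panel, parent selection, F1 crosses with true genotypes, and
#' multi-year phenotypes for three correlated base traits — two
#' capsaicinoid-content-like traits (`CAPgDW`, `DCAPgDW`, strongly
#' positively correlated, shared QTL) and a placenta-dry-weight-like trait
#' (`DWP`, negatively correlated with the contents and with negative
#' directional dominance, matching the observed opposite heterosis
#' pattern). Derived traits (`TCAPgDW`, `CAPFL`, `DCAPFL`, `TCAPFL`) can
#' be appended with [derive_traits()].
#'
#' @param config a [sim_config()].
#' @param n_qtl number of causal loci shared by the traits.
#' @param traits character subset of `c("CAPgDW", "DCAPgDW", "DWP")`.
#' @return list with `genotypes` (founders), `f1_genotypes` (true),
#'   `crosses`, `parent_ids`, `phenotypes` (long data.frame over all
#'   accessions and traits), `architectures`, `config`.
#' @export
simulate_study <- function(config = sim_config(), n_qtl = 60,
                           traits = c("CAPgDW", "DCAPgDW", "DWP")) {
  stopifnot(inherits(config, "sim_config"))
  founders <- simulate_founder_genotypes(config)
  set.seed(config$seed + 1L)
  parents <- sort(sample(rownames(founders), config$n_parents))
  cr <- make_crosses(founders, parents, config$n_f1, seed = config$seed + 2L)
  all_geno <- rbind(founders, cr$f1_genotypes)

  # shared QTL set; trait-specific rescaling of one base effect vector
  # gives the observed correlation structure (contents ~ r 0.9, DWP
  # negative) without hard-coding correlations
  base <- simulate_architecture(ncol(founders), n_qtl, config$dominance_ratio,
                                seed = config$seed + 3L, genotypes = founders,
                                dominance_sign = "positive")
  archs <- list()
  intercepts <- c(CAPgDW = 9000, DCAPgDW = 4900, DWP = 0.45)
  scales    <- c(CAPgDW = 2800, DCAPgDW = 1500, DWP = 0.08)
  set.seed(config$seed + 4L)
  for (tr in intersect(c("CAPgDW", "DCAPgDW", "DWP"), traits)) {
    ar <- base
    s <- scales[[tr]]
    if (tr == "DWP") {
      # negative genetic correlation with the contents plus independent
      # variation; dominance directional negative (hybrids below mid-parent)
      jitter_a <- rnorm(length(base$additive_effects), 0, 0.8)
      ar$additive_effects <- s * (-0.5 * base$additive_effects + jitter_a /
                                    sqrt(sum(jitter_a^2)) * 0.9)
      ar$dominance_effects <- -0.5 * s * base$dominance_effects
    } else {
      jitter_a <- rnorm(length(base$additive_effects), 0, 0.3)
      ar$additive_effects <- s * (base$additive_effects + jitter_a /
                                    sqrt(sum(jitter_a^2)) * 0.3)
      ar$dominance_effects <- s * base$dominance_effects
    }
    ar$intercept <- intercepts[[tr]]
    archs[[tr]] <- ar
  }
  pheno <- do.call(rbind, lapply(names(archs), function(tr) {
    cfg_tr <- config
    cfg_tr$seed <- config$seed + 10L + match(tr, names(archs))
    cfg_tr$year_effects <- NULL
    simulate_phenotypes(all_geno, archs[[tr]], cfg_tr, trait = tr)
  }))
  rownames(pheno) <- NULL
  list(genotypes = founders, f1_genotypes = cr$f1_genotypes,
       crosses = cr$crosses, parent_ids = parents, phenotypes = pheno,
       architectures = archs, config = config)
}
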