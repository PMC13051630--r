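#' Root square error per prediction
#'
#' `RSE = sqrt((observed - predicted)^2) = |observed - predicted|`, the
#' per-individual prediction-error measure.
#'
#' @param observed,predicted numeric vectors.
#' @return nonnegative numeric vector.
#' @export
rse <- function(observed, predicted) {
  sqrt((observed - predicted)^2)
}

#' Prediction accuracy per trait and model
#'
#' Pearson correlation (t-based two-sided p, sample size) between observed
#' and predicted values per (trait, model); degenerate constant
#' predictions are reported as not-available with a reason code instead of
#' a correlation.
#'
#' @param results prediction-result data.frame (`f1_id`, `trait`, `model`,
#'   `observed`, `predicted`, `rse`).
#' @return data.frame `trait`, `model`, `r`, `p`, `n`, `reason`.
#' @export
gp_accuracy <- function(results) {
  grid <- unique(results[c("trait", "model")])
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    d <- results[results$trait == grid$trait[i] &
                   results$model == grid$model[i], ]
    ct <- cor_with_p(d$observed, d$predicted)
    if (is.na(ct$r) && !is.na(ct$reason) && ct$reason == "zero variance" &&
        sd(d$predicted) == 0)
      ct$reason <- "constant predictions"
    data.frame(trait = grid$trait[i], model = grid$model[i], r = ct$r,
               p = ct$p, n = ct$n, reason = ct$reason,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlate per-F1 prediction error with inheritance characteristics
#'
#' Per trait, Pearson correlation of the root square error with the
#' additive effect, the absolute MP heterosis, the absolute HP heterosis,
#' and the parental genetic distance (the heterosis columns enter as
#' absolute values; the additive effect is already nonnegative).
#'
#' @param results prediction-result data.frame, filtered to one model
#'   (defaults to `model`).
#' @param heterosis heterosis table from [heterosis_table()].
#' @param distances table from [parental_distance()].
#' @param model model whose predictions are analyzed (default
#'   `"gblup_gauss"`).
#' @return data.frame `trait`, `factor`, `r`, `p`, `n`, `stars`.
#' @export
error_factor_analysis <- function(results, heterosis, distances,
                                  model = "gblup_gauss") {
  res <- results[results$model == model, ]
  if (nrow(res) == 0)
    stop("no prediction results for model ", model, call. = FALSE)
  d <- merge(res, heterosis, by = c("f1_id", "trait"))
  d <- merge(d, distances[c("f1_id", "distance")], by = "f1_id")
  d$abs_mp <- abs(d$mp_heterosis)
  d$abs_hp <- abs(d$hp_heterosis)
  factors <- c(additive_effect = "additive_effect", abs_mp = "abs_mp",
               abs_hp = "abs_hp", distance = "distance")
  out <- do.call(rbind, lapply(unique(d$trait), function(tr) {
    dd <- d[d$trait == tr, ]
    do.call(rbind, lapply(names(factors), function(f) {
      ct <- cor_with_p(dd$rse, dd[[factors[[f]]]])
      data.frame(trait = tr, factor = f, r = ct$r, p = ct$p, n = ct$n,
                 stars = sig_stars(ct$p), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Run the parent-to-F1 genomic prediction workflow end to end
#'
#' Orchestrates the full analysis: (A) BLUP summarization and broad-sense
#' heritability over all accessions, heterosis tables for the F1s;
#' (B) F1 genotype estimation from the parents; (C) training every
#' requested model on the inbred accessions only (a leakage guard refuses
#' training sets containing F1 ids, and training BLUPs are refit from
#' inbred phenotype records alone so F1 phenotypes cannot reach model
#' fitting even through variance-component estimates), prediction of the
#' F1s, the accuracy table and the error-factor correlation table. Fully reproducible from
#' inputs + seed; a manifest records versions, seed and row counts.
#'
#' @param genotypes inbred (training) genotype matrix.
#' @param phenotypes long-format phenotype records covering inbreds and
#'   F1s.
#' @param crosses cross table.
#' @param traits traits to analyze (default: all in `phenotypes`).
#' @param models models to train (default [gp_model_names()]).
#' @param maf MAF filter threshold applied to the training panel.
#' @param seed integer seed for the stochastic trainers.
#' @param error_model model used for the error-factor analysis.
#' @param outdir optional directory; when given, all tables are written
#'   as CSV plus a JSON manifest.
#' @param ... extra arguments passed to [fit_gp_model()].
#' @return list with `blups`, `h2`, `heterosis`, `heterosis_summary`,
#'   `heterosis_correlates`, `distances`, `f1_genotypes`, `predictions`,
#'   `accuracy`, `error_factors`, `manifest`.
#' @export
run_pipeline <- function(genotypes, phenotypes, crosses, traits = NULL,
                         models = gp_model_names(), maf = 0.05, seed = 1L,
                         error_model = "gblup_gauss", outdir = NULL, ...) {
  check_geno(genotypes)
  check_crosses(crosses)
  models <- match.arg(models, gp_model_names(), several.ok = TRUE)
  if (is.null(traits)) traits <- unique(phenotypes$trait)
  # leakage guard: the training panel must not contain any F1
  leaked <- intersect(rownames(genotypes), crosses$f1_id)
  if (length(leaked))
    stop("leakage guard: F1 accession(s) present in the training genotype ",
         "panel: ", paste(utils::head(leaked, 5), collapse = ", "),
         call. = FALSE)
  g <- filter_maf(genotypes, maf)

  # (A) BLUPs, heritability, heterosis (joint fit over all accessions)
  blups <- fit_blup_all(phenotypes[phenotypes$trait %in% traits, ])
  h2 <- unique(blups[c("trait", "sigma2_g", "sigma2_e", "n_reps", "h2_b")])
  rownames(h2) <- NULL
  # training BLUPs are refit from inbred records only, so no F1 phenotype
  # can influence model fitting even through variance components
  ph_inbred <- phenotypes[phenotypes$trait %in% traits &
                            phenotypes$accession %in% rownames(genotypes), ]
  blups_train <- fit_blup_all(ph_inbred)
  het <- heterosis_table(blups, crosses)
  het_sum <- heterosis_summary(het)
  dists <- parental_distance(g, crosses)
  het_cor <- heterosis_correlates(het, dists)

  # (B) estimated F1 genotypes on the filtered panel
  gf1 <- estimate_f1_genotypes(g, crosses)

  # (C) train on inbreds only, predict the F1s
  inbred_ids <- rownames(g)
  preds <- list()
  for (tr in traits) {
    b <- blups[blups$trait == tr, ]
    y <- setNames(b$blup, b$accession)
    bt <- blups_train[blups_train$trait == tr, ]
    y_train <- setNames(bt$blup, bt$accession)[inbred_ids]
    if (anyNA(y_train))
      stop("inbred accessions lack BLUPs for trait ", tr, call. = FALSE)
    obs_f1 <- y[crosses$f1_id]
    for (mod in models) {
      fit <- fit_gp_model(y_train, g, mod, seed = seed, ...)
      pr <- predict(fit, gf1)
      preds[[paste(tr, mod)]] <- data.frame(
        f1_id = crosses$f1_id, trait = tr, model = mod,
        observed = unname(obs_f1), predicted = unname(pr[crosses$f1_id]),
        rse = unname(rse(obs_f1, pr[crosses$f1_id])),
        stringsAsFactors = FALSE)
    }
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  acc <- gp_accuracy(predictions)
  err <- if (error_model %in% models)
    error_factor_analysis(predictions, het, dists, model = error_model)
  else NULL

  manifest <- list(
    package = "crossgp",
    version = as.character(utils::packageVersion("crossgp")),
    r_version = as.character(getRversion()),
    seed = seed, maf = maf, models = models, traits = traits,
    n_inbred = length(inbred_ids), n_f1 = nrow(crosses),
    n_loci = ncol(g), n_phenotype_records = nrow(phenotypes),
    n_predictions = nrow(predictions))

  out <- list(blups = blups, blups_train = blups_train, h2 = h2,
              heterosis = het,
              heterosis_summary = het_sum, heterosis_correlates = het_cor,
              distances = dists, f1_genotypes = gf1,
              predictions = predictions, accuracy = acc,
              error_factors = err, manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

#' Dominance-ratio sweep: heterosis vs prediction accuracy
#'
#' Simulates the panel at each requested dominance ratio (same seeds, so
#' the founder panel, crosses and effect draws are shared and only the
#' dominance magnitude changes), runs the single-trait workflow with the
#' requested model, and reports per ratio: the strong-heterosis group
#' proportion, the mean MP heterosis, the F1 prediction accuracy, and the
#' correlation of the root square error with absolute MP heterosis. This
#' is the in-silico version of the heterosis-error mechanism: directional
#' dominance raises the strong-heterosis fraction and degrades prediction
#' from homozygous training data, leaving errors correlated with
#' heterosis.
#'
#' @param ratios dominance ratios to sweep (default `c(0, 0.5, 1)`).
#' @param config base [sim_config()]; its `dominance_ratio` is replaced.
#' @param seeds integer vector of replicate seeds to average over.
#' @param model prediction model (default `"gblup_gauss"`).
#' @param n_qtl causal loci for the simulated trait.
#' @return data.frame with one row per (ratio, seed) and the averaged
#'   summary in attribute `"summary"` (one row per ratio).
#' @export
sweep_dominance <- function(ratios = c(0, 0.5, 1), config = sim_config(),
                            seeds = 1:3, model = "gblup_gauss",
                            n_qtl = 60) {
  rows <- list()
  for (seed in seeds) {
    for (r in ratios) {
      cfg <- config
      cfg$dominance_ratio <- r
      cfg$seed <- as.integer(seed)
      st <- simulate_study(cfg, n_qtl = n_qtl, traits = "CAPgDW")
      res <- run_pipeline(st$genotypes, st$phenotypes, st$crosses,
                          models = model, seed = seed,
                          error_model = model)
      grp <- res$heterosis_summary$groups
      ef <- res$error_factors
      rows[[length(rows) + 1L]] <- data.frame(
        ratio = r, seed = seed,
        strong_prop = grp$strong[1],
        mean_mp = res$heterosis_summary$stats$mean[
          res$heterosis_summary$stats$heterosis == "mp"][1],
        accuracy = res$accuracy$r[1],
        rse_mp_r = ef$r[ef$factor == "abs_mp"][1],
        rse_mp_p = ef$p[ef$factor == "abs_mp"][1])
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$ratio), function(d)
    data.frame(ratio = d$ratio[1], strong_prop = mean(d$strong_prop),
               mean_mp = mean(d$mean_mp), accuracy = mean(d$accuracy),
               rse_mp_r = mean(d$rse_mp_r))))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, name)
    write.csv(d, file.path(outdir, paste0(name, ".csv")), row.names = FALSE)
  wr(out$blups, "blups")
  wr(out$h2, "heritability")
  wr(out$heterosis, "heterosis")
  wr(out$heterosis_summary$stats, "heterosis_stats")
  wr(out$heterosis_summary$groups, "heterosis_groups")
  wr(out$heterosis_correlates, "heterosis_correlates")
  wr(out$distances, "parental_distances")
  wr(out$predictions, "predictions")
  wr(out$accuracy, "accuracy")
  if (!is.null(out$error_factors)) wr(out$error_factors, "error_factors")
  jsonlite::write_json(out$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
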