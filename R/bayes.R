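#' Bayesian whole-genome regression by Gibbs sampling
#'
#' Samplers with standard conjugate updates: BRR puts a common
#' scaled-inverse-chi-squared marker-effect variance on all effects;
#' Bayes A gives every marker its own variance; Bayes B and Bayes C are
#' spike-and-slab models with sampled prior inclusion probability `pi`
#' (B: per-marker slab variances, C: common slab variance). Markers are
#' centered by training-panel means; hyperprior scales follow the usual
#' variance-partition heuristic (half the phenotypic variance to markers,
#' degrees of freedom `nu = 4`), and `pi ~ Beta(1, 9)` started at 0.1.
#' Chains are deterministic under a fixed seed.
#'
#' @param y named numeric vector of training phenotypes.
#' @param x training genotype matrix (accessions x loci).
#' @param model `"brr"`, `"bayes_a"`, `"bayes_b"` or `"bayes_c"`.
#' @param n_iter total Gibbs iterations (default 6000).
#' @param burn_in burn-in iterations discarded (default 1000).
#' @param seed integer seed.
#' @param pi_init initial inclusion probability (B/C).
#' @param pi_fixed if non-`NULL`, fixes `pi` at this value instead of
#'   sampling it (B/C only; `pi_fixed = 1` nests Bayes C into BRR).
#' @param nu hyperprior degrees of freedom.
#' @param r2_markers share of phenotypic variance attributed to markers by
#'   the hyperprior scale heuristic.
#' @return object of class `bayes_fit` (also `gp_fit`) with posterior-mean
#'   effects, intercept and chain diagnostics.
#' @export
fit_bayes <- function(y, x, model = c("brr", "bayes_a", "bayes_b", "bayes_c"),
                      n_iter = 6000L, burn_in = 1000L, seed = 1L,
                      pi_init = 0.1, pi_fixed = NULL, nu = 4,
                      r2_markers = 0.5) {
  model <- match.arg(model)
  check_geno(x)
  y <- y[rownames(x)]
  if (anyNA(y)) stop("y must cover all rows of x", call. = FALSE)
  if (n_iter <= burn_in || burn_in < 0)
    stop("need n_iter > burn_in >= 0", call. = FALSE)
  if (sd(y) == 0) stop("constant y: sampler undefined", call. = FALSE)
  centers <- colMeans(x)
  Xc <- sweep(x, 2, centers)
  vy <- var(y)
  msx <- sum(apply(Xc, 2, var))
  if (msx <= 0) stop("monomorphic marker matrix", call. = FALSE)
  # scaled-inv-chi^2 scale with mode at the heuristic variance target
  Sb <- vy * r2_markers / msx * (nu + 2) / nu
  Se <- vy * (1 - r2_markers) * (nu + 2) / nu
  code <- c(brr = 0L, bayes_a = 1L, bayes_b = 2L, bayes_c = 3L)[[model]]
  sample_pi <- is.null(pi_fixed)
  pi0 <- if (sample_pi) pi_init else pi_fixed
  if (model %in% c("bayes_b", "bayes_c")) {
    # slab variance heuristic spreads the marker variance over the
    # expected included fraction
    Sb <- Sb / max(pi0, 1e-3)
  }
  if (!sample_pi && (pi0 <= 0 || pi0 > 1))
    stop("pi_fixed must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  res <- .gibbs_wgr(as.numeric(y), Xc, code, as.integer(n_iter),
                    as.integer(burn_in), nu, Sb, Se, pi0, sample_pi,
                    1, 9)
  structure(list(model = model, effects = drop(res$b), mu = res$mu,
                 centers = centers, loci = colnames(x),
                 training_ids = rownames(x), n = length(y),
                 diagnostics = list(sigma2_e = res$sigma2_e,
                                    sigma2_b = res$sigma2_b, pi = res$pi,
                                    n_kept = res$n_kept, n_iter = n_iter,
                                    burn_in = burn_in, seed = seed)),
            class = c("bayes_fit", "gp_fit"))
}

#' @export
predict.bayes_fit <- function(object, newdata, ...) {
  if (!identical(colnames(newdata), object$loci))
    stop("locus sets differ between training and prediction", call. = FALSE)
  Xc <- sweep(newdata, 2, object$centers)
  pred <- object$mu + drop(Xc %*% object$effects)
  names(pred) <- rownames(newdata)
  pred
}
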