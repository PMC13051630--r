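#' Kernel GBLUP by REML
#'
#' Fits the mixed model `y = 1 mu + u + e`, `u ~ N(0, sigma_u^2 K)` (one
#' kernel) or `u = u_a + u_d` with `u_a ~ N(0, sigma_a^2 K_A)`,
#' `u_d ~ N(0, sigma_d^2 K_D)` (two kernels), `e ~ N(0, sigma_e^2 I)`.
#'
#' Single kernel: the restricted likelihood is profiled in the variance
#' ratio `lambda = sigma_u^2 / sigma_e^2` through the spectral
#' decomposition of `K` (one eigendecomposition, then a bounded 1-D search
#' over `log lambda` in `[-12, 12]`). Two kernels: direct numerical
#' maximization of the restricted likelihood over the two ratios with
#' residual variance profiled out, L-BFGS-B with random restarts and
#' components clamped nonnegative.
#'
#' @param y named numeric vector of training phenotypes (BLUPs), names
#'   matching the kernel accession ids.
#' @param kernels a single [build_kernel()] object or a list of one
#'   (additive or gaussian GBLUP) or two (additive + dominance) of them.
#' @param g_train optional training genotype matrix stored in the fit so
#'   `predict()` can build cross-kernels from new genotypes.
#' @param n_restarts random restarts for the two-kernel optimizer.
#' @return object of class `gblup_fit` (also `gp_fit`): `mu`, variance
#'   components, prediction weights `alpha`, the training kernels and
#'   optimizer diagnostics.
#' @export
fit_gblup <- function(y, kernels, g_train = NULL, n_restarts = 3L) {
  if (inherits(kernels, "kernel_matrix")) kernels <- list(kernels)
  stopifnot(length(kernels) %in% c(1L, 2L),
            all(vapply(kernels, inherits, TRUE, "kernel_matrix")))
  ids <- kernels[[1]]$accession_ids
  if (length(kernels) == 2 &&
      !identical(ids, kernels[[2]]$accession_ids))
    stop("kernels built on different accession sets", call. = FALSE)
  if (is.null(names(y)) || !all(ids %in% names(y)))
    stop("y must be named by the kernel accession ids", call. = FALSE)
  y <- y[ids]
  n <- length(y)
  if (length(kernels) == 1L) {
    fit <- gblup_reml_1k(y, kernels[[1]]$K)
  } else {
    fit <- gblup_reml_2k(y, kernels[[1]]$K, kernels[[2]]$K, n_restarts)
  }
  structure(c(fit, list(model = if (length(kernels) == 2) "gblup_ad"
                        else paste0("gblup_",
                                    substr(kernels[[1]]$kind, 1, 1),
                                    if (kernels[[1]]$kind == "gaussian")
                                      "auss" else ""),
                        kernels = kernels, training_ids = ids,
                        g_train = list(g_train), n = n)),
            class = c("gblup_fit", "gp_fit"))
}

# single-kernel spectral REML (EMMA-style profile likelihood)
gblup_reml_1k <- function(y, K) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  profile <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    sxx <- sum(w * xt^2)
    mu <- sum(w * xt * yt) / sxx
    rss <- sum(w * (yt - xt * mu)^2)
    s2e <- rss / (n - 1)
    ll <- -0.5 * ((n - 1) * (log(2 * pi * s2e) + 1) +
                    sum(log(lam * d + 1)) + log(sxx))
    list(ll = ll, mu = mu, s2e = s2e)
  }
  opt <- optimize(function(l) profile(l)$ll, c(-12, 12), maximum = TRUE,
                  tol = 1e-8)
  lam <- exp(opt$maximum)
  pr <- profile(opt$maximum)
  s2e <- pr$s2e
  s2u <- lam * s2e
  delta <- 1 / lam                      # sigma_e^2 / sigma_u^2
  # prediction weights: u_new = K_x (K + delta I)^{-1} (y - 1 mu)
  alpha <- drop(U %*% ((crossprod(U, y - pr$mu)) / (d + delta)))
  list(mu = pr$mu, sigma2 = c(u = s2u, e = s2e), lambda = lam,
       alpha = alpha, reml_loglik = opt$objective,
       eigen = list(values = d))
}

# two-kernel REML: profile likelihood in the two variance ratios
gblup_reml_2k <- function(y, Ka, Kd, n_restarts = 3L) {
  n <- length(y)
  ones <- rep(1, n)
  nll <- function(par) {
    la <- exp(par[1]); ld <- exp(par[2])
    V <- la * Ka + ld * Kd + diag(n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi1 <- backsolve(ch, forwardsolve(t(ch), ones))
    Viy <- backsolve(ch, forwardsolve(t(ch), y))
    sxx <- sum(ones * Vi1)
    mu <- sum(y * Vi1) / sxx
    r <- y - mu
    rss <- sum(r * (Viy - mu * Vi1))
    if (rss <= 0) return(1e10)
    s2e <- rss / (n - 1)
    0.5 * ((n - 1) * (log(2 * pi * s2e) + 1) +
             2 * sum(log(diag(ch))) + log(sxx))
  }
  set.seed(11L)
  starts <- rbind(c(0, 0),
                  matrix(runif(2 * n_restarts, -4, 4), ncol = 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      optim(starts[i, ], nll, method = "L-BFGS-B", lower = c(-12, -12),
            upper = c(12, 12)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("two-kernel REML did not converge", call. = FALSE)
  la <- exp(best$par[1]); ld <- exp(best$par[2])
  V <- la * Ka + ld * Kd + diag(n)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi %*% ones)
  r <- y - mu
  s2e <- drop(crossprod(r, Vi %*% r)) / (n - 1)
  alpha <- drop(Vi %*% r)               # pred = mu + (la Ka_x + ld Kd_x) alpha
  list(mu = mu, sigma2 = c(a = la * s2e, d = ld * s2e, e = s2e),
       lambda = c(a = la, d = ld), alpha = alpha,
       reml_loglik = -best$value)
}

#' Predict from a kernel GBLUP fit
#'
#' `prediction = mu + k_cross %*% alpha`, the standard kernel-BLUP
#' extension to unphenotyped individuals; cross-kernels are built with the
#' allele frequencies and bandwidth frozen from training.
#'
#' @param object a `gblup_fit`.
#' @param newdata genotype matrix of prediction candidates (same loci as
#'   training), or `NULL` for training fitted values.
#' @param k_cross optional precomputed cross-kernel matrix (single-kernel
#'   fits) or list of two (additive, dominance), bypassing `newdata`.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.gblup_fit <- function(object, newdata = NULL, k_cross = NULL, ...) {
  kerns <- object$kernels
  two <- length(kerns) == 2L
  if (is.null(k_cross)) {
    if (is.null(newdata)) {
      k_cross <- lapply(kerns, function(k) k$K)
    } else {
      if (is.null(object$g_train[[1]]))
        stop("fit stores no training genotypes; supply k_cross",
             call. = FALSE)
      k_cross <- lapply(kerns, function(k)
        cross_kernel(newdata, object$g_train[[1]], k))
    }
  } else if (!is.list(k_cross)) k_cross <- list(k_cross)
  if (two) {
    pred <- object$mu +
      drop((object$lambda["a"] * k_cross[[1]] +
              object$lambda["d"] * k_cross[[2]]) %*% object$alpha)
  } else {
    pred <- object$mu + drop(k_cross[[1]] %*% object$alpha)
  }
  if (!all(is.finite(pred))) stop("non-finite predictions", call. = FALSE)
  pred
}
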