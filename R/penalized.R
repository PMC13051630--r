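#' Penalized whole-genome regression (ridge / lasso / elastic net)
#'
#' Coordinate-descent elastic net on standardized markers via glmnet,
#' with mixing parameter 0 (ridge), 1 (lasso) or 0.5 (elastic net) and the
#' penalty strength chosen by seeded k-fold cross-validation minimizing
#' mean squared error over the automatic log-spaced path. Coefficients are
#' returned by glmnet on the original code scale.
#'
#' @param y named numeric vector of training phenotypes.
#' @param x training genotype matrix (accessions x loci).
#' @param penalty `"ridge"`, `"lasso"` or `"en"`.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param lambda optional fixed penalty strength; skips cross-validation.
#' @param standardize standardize markers inside the solver (default TRUE).
#' @return object of class `penalized_fit` (also `gp_fit`).
#' @export
fit_penalized <- function(y, x, penalty = c("ridge", "lasso", "en"),
                          folds = 5L, seed = 1L, lambda = NULL,
                          standardize = TRUE) {
  penalty <- match.arg(penalty)
  check_geno(x)
  y <- y[rownames(x)]
  if (anyNA(y)) stop("y must cover all rows of x", call. = FALSE)
  if (sd(y) == 0) stop("constant y: penalized fit undefined", call. = FALSE)
  alpha <- c(ridge = 0, lasso = 1, en = 0.5)[[penalty]]
  if (is.null(lambda)) {
    if (length(y) < folds)
      stop("fewer observations than folds", call. = FALSE)
    set.seed(seed)
    fit <- glmnet::cv.glmnet(x, y, alpha = alpha, nfolds = folds,
                             standardize = standardize)
    lambda <- fit$lambda.min
  } else {
    fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = lambda,
                          standardize = standardize, thresh = 1e-12)
  }
  structure(list(model = penalty, fit = fit, lambda = lambda,
                 training_ids = rownames(x), loci = colnames(x),
                 n = length(y)),
            class = c("penalized_fit", "gp_fit"))
}

#' @export
predict.penalized_fit <- function(object, newdata, ...) {
  if (!identical(colnames(newdata), object$loci))
    stop("locus sets differ between training and prediction", call. = FALSE)
  pred <- drop(predict(object$fit, newx = newdata, s = object$lambda))
  names(pred) <- rownames(newdata)
  pred
}

#' Bagged regression-tree ensemble for genomic prediction
#'
#' Random forest on numeric genotype codes (ranger backend, single
#' threaded and seeded for determinism) with the regression defaults
#' n_trees = 500, mtry = p/3.
#'
#' @param y named numeric vector of training phenotypes.
#' @param x training genotype matrix.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return object of class `forest_fit` (also `gp_fit`).
#' @export
fit_forest <- function(y, x, n_trees = 500L, seed = 1L) {
  check_geno(x)
  y <- y[rownames(x)]
  if (anyNA(y)) stop("y must cover all rows of x", call. = FALSE)
  if (nrow(x) < 10) stop("need at least 10 training accessions", call. = FALSE)
  rf <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                       mtry = max(1L, floor(ncol(x) / 3)),
                       seed = seed, num.threads = 1L)
  structure(list(model = "rf", rf = rf, training_ids = rownames(x),
                 loci = colnames(x), n = length(y)),
            class = c("forest_fit", "gp_fit"))
}

#' @export
predict.forest_fit <- function(object, newdata, ...) {
  if (!identical(colnames(newdata), object$loci))
    stop("locus sets differ between training and prediction", call. = FALSE)
  pred <- predict(object$rf, data = newdata, num.threads = 1L)$predictions
  names(pred) <- rownames(newdata)
  pred
}
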