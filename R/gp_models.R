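#' The eleven supported genomic prediction models
#'
#' @return character vector of model names.
#' @export
gp_model_names <- function() {
  c("ridge", "lasso", "en", "brr", "bayes_a", "bayes_b", "bayes_c",
    "gblup_a", "gblup_ad", "gblup_gauss", "rf")
}

#' Fit one genomic prediction model
#'
#' Uniform front end over the model menu: penalized regressions
#' ([fit_penalized()]), Bayesian whole-genome regressions ([fit_bayes()]),
#' kernel GBLUP with additive, additive + dominance, or Gaussian
#' relationship matrices ([fit_gblup()]), and random forest
#' ([fit_forest()]). All fits predict through `predict(fit, g_new)`.
#'
#' @param y named numeric vector of training phenotypes (BLUPs).
#' @param x training genotype matrix (inbred accessions x loci).
#' @param model one of [gp_model_names()].
#' @param seed integer seed for the stochastic trainers.
#' @param ... passed to the backend fitter (e.g. `n_iter`, `folds`).
#' @return a `gp_fit` object.
#' @export
fit_gp_model <- function(y, x, model, seed = 1L, ...) {
  model <- match.arg(model, gp_model_names())
  dots <- list(...)
  fitter <- switch(model,
    ridge = , lasso = , en = fit_penalized,
    brr = , bayes_a = , bayes_b = , bayes_c = fit_bayes,
    rf = fit_forest,
    gblup_a = , gblup_ad = , gblup_gauss = fit_gblup)
  args <- dots[intersect(names(dots), names(formals(fitter)))]
  if (model %in% c("ridge", "lasso", "en"))
    return(do.call(fitter, c(list(y, x, penalty = model, seed = seed), args)))
  if (model %in% c("brr", "bayes_a", "bayes_b", "bayes_c"))
    return(do.call(fitter, c(list(y, x, model = model, seed = seed), args)))
  if (model == "rf")
    return(do.call(fitter, c(list(y, x, seed = seed), args)))
  kernels <- switch(model,
    gblup_a = build_kernel(x, "additive"),
    gblup_gauss = build_kernel(x, "gaussian"),
    gblup_ad = list(build_kernel(x, "additive"),
                    build_kernel(x, "dominance")))
  do.call(fitter, c(list(y, kernels, g_train = x), args))
}
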