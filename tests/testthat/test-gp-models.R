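make_training <- function(n = 30, m = 80, seed = 201, h2 = 0.9,
                          n_qtl = 15, noise_sd = 0.4) {
  pan <- small_panel(n_inbred = n, n_loci = m, n_parents = 6, n_f1 = 10,
                     seed = seed, n_qtl = n_qtl, h2 = h2)
  g <- pan$genotypes
  set.seed(seed + 5)
  y <- genetic_values(g, pan$arch) + rnorm(n, 0, noise_sd)
  names(y) <- rownames(g)
  list(g = g, y = y, pan = pan)
}

test_that("single-kernel GBLUP equals closed-form ridge at the REML penalty", {
  tr <- make_training(n = 20, m = 50)
  k <- build_kernel(tr$g, "additive")
  fit <- fit_gblup(tr$y, k, g_train = tr$g)
  p <- allele_freqs(tr$g)
  W <- sweep(tr$g, 2, 2 * (p - 0.5))
  lam <- 2 * sum(p * (1 - p)) * fit$sigma2[["e"]] / fit$sigma2[["u"]]
  b <- solve(crossprod(W) + lam * diag(ncol(W)),
             crossprod(W, tr$y - fit$mu))
  ridge_pred <- fit$mu + drop(W %*% b)
  gb_pred <- predict(fit)
  expect_gt(cor(ridge_pred, gb_pred), 0.999)
  expect_lt(max(abs(ridge_pred - gb_pred)), 1e-6)
})

test_that("GBLUP collapses to the mean without signal and extends sensibly", {
  g <- small_panel(n_inbred = 15, n_loci = 40, n_f1 = 5)$genotypes
  y <- setNames(rep(3, 15), rownames(g))
  fit <- fit_gblup(y, build_kernel(g, "gaussian"), g_train = g)
  expect_lt(max(abs(predict(fit) - 3)), 1e-4)
  # an infinitely distant candidate (zero kernel row) gets the prior mean
  tr <- make_training(n = 15, m = 40)
  fit2 <- fit_gblup(tr$y, build_kernel(tr$g, "gaussian"), g_train = tr$g)
  far <- predict(fit2, k_cross = matrix(0, 1, 15))
  expect_equal(unname(far), unname(fit2$mu))
  # reproducing property: a training-identical candidate gets its fitted value
  dup <- tr$g[4, , drop = FALSE]
  rownames(dup) <- "DUP"
  expect_equal(unname(predict(fit2, dup)), unname(predict(fit2)[4]),
               tolerance = 1e-10)
})

test_that("GBLUP recovers the genetic-variance share on an additive trait", {
  tr <- make_training(n = 150, m = 500, seed = 205, n_qtl = 40,
                      noise_sd = sqrt(1 / 0.9 - 1))
  fit <- fit_gblup(tr$y, build_kernel(tr$g, "additive"), g_train = tr$g)
  share <- fit$sigma2[["u"]] / (fit$sigma2[["u"]] + fit$sigma2[["e"]])
  expect_gt(share, 0.8)
  expect_lt(share, 0.97)
})

test_that("F1 kernel predictions match a joint mixed-model solve", {
  # joint-vs-conditional BLUP identity on a small panel
  tr <- make_training(n = 10, m = 30, seed = 208)
  k <- build_kernel(tr$g, "additive")
  fit <- fit_gblup(tr$y, k, g_train = tr$g)
  ids <- rownames(tr$g)
  gnew <- estimate_f1_genotypes(tr$g, data.frame(
    f1_id = c("F1", "F2"), mother_id = ids[c(1, 3)],
    father_id = ids[c(2, 5)]))
  pred <- predict(fit, gnew)
  # brute force: joint covariance of (train, new) under the fitted
  # components; conditional mean of u_new given y
  K_joint <- build_kernel(rbind(tr$g, gnew), "additive",
                          freqs = k$freqs)$K
  idx_t <- 1:10; idx_n <- 11:12
  Vt <- fit$sigma2[["u"]] * K_joint[idx_t, idx_t] +
    fit$sigma2[["e"]] * diag(10)
  joint <- fit$mu + fit$sigma2[["u"]] * K_joint[idx_n, idx_t] %*%
    solve(Vt, tr$y - fit$mu)
  expect_equal(unname(pred), unname(drop(joint)), tolerance = 1e-8)
})

test_that("two-kernel GBLUP fits additive plus dominance components", {
  tr <- make_training(n = 60, m = 150, seed = 210)
  fit <- fit_gp_model(tr$y, tr$g, "gblup_ad")
  expect_s3_class(fit, "gblup_fit")
  expect_true(all(fit$sigma2 >= 0))
  pred <- predict(fit, tr$g)
  expect_true(all(is.finite(pred)))
  expect_gt(cor(pred, tr$y), 0.5)
})

test_that("ridge at a fixed penalty matches the normal equations", {
  set.seed(33)
  g <- toy_geno(matrix(sample(c(-1, 0, 1), 15, TRUE), 5, 3))
  y <- setNames(c(1.2, -0.5, 0.3, 2.0, -1.1), rownames(g))
  lam <- 0.7
  fit <- fit_penalized(y, g, "ridge", lambda = lam, standardize = FALSE)
  # glmnet standardizes y internally, so its ridge solution corresponds to
  # the normal equations at penalty n * lambda / sd_n(y)
  n <- 5
  syn <- sqrt(mean((y - mean(y))^2))
  Xc <- sweep(g, 2, colMeans(g))
  b_oracle <- solve(crossprod(Xc) + n * lam / syn * diag(3),
                    crossprod(Xc, y - mean(y)))
  b_fit <- as.numeric(coef(fit$fit, s = lam))[-1]
  expect_equal(b_fit, unname(drop(b_oracle)), tolerance = 1e-4)
})

test_that("lasso on an orthogonal design soft-thresholds least squares", {
  # orthogonal +/-1 design (Hadamard-like), centered columns
  H <- cbind(c(1, 1, 1, 1), c(1, -1, 1, -1), c(1, 1, -1, -1),
             c(1, -1, -1, 1))
  g <- toy_geno(H[, 2:4])
  y <- setNames(c(3, 1, -1, 0.5), rownames(g))
  lam <- 0.4
  fit <- fit_penalized(y, g, "lasso", lambda = lam, standardize = FALSE)
  b_fit <- as.numeric(coef(fit$fit, s = lam))[-1]
  n <- 4
  ols <- drop(crossprod(g, y - mean(y))) / diag(crossprod(g))
  soft <- sign(ols) * pmax(abs(ols) - n * lam / diag(crossprod(g)), 0)
  expect_equal(b_fit, unname(soft), tolerance = 1e-6)
})

test_that("penalized fits respect their preconditions", {
  tr <- make_training(n = 12, m = 30)
  expect_error(fit_penalized(setNames(rep(1, 12), rownames(tr$g)), tr$g,
                             "ridge"), "constant")
  expect_error(fit_penalized(tr$y[1:4], tr$g[1:4, ], "ridge", folds = 5),
               "folds")
})

test_that("Gibbs samplers shrink null data and are seed-deterministic", {
  tr <- make_training(n = 25, m = 50)
  set.seed(44)
  y0 <- setNames(rnorm(25), rownames(tr$g))   # pure noise
  fit <- fit_bayes(y0, tr$g, "brr", n_iter = 1500, burn_in = 300, seed = 9)
  pred <- predict(fit, tr$g)
  expect_lt(sd(pred), sd(y0))
  expect_lt(max(abs(pred - mean(y0))), 2 * sd(y0))
  fit2 <- fit_bayes(y0, tr$g, "brr", n_iter = 1500, burn_in = 300, seed = 9)
  expect_identical(fit$effects, fit2$effects)
  expect_error(fit_bayes(y0, tr$g, "brr", n_iter = 100, burn_in = 200),
               "n_iter")
})

test_that("BRR tracks ridge at the prior-matched penalty", {
  tr <- make_training(n = 50, m = 100, seed = 215, n_qtl = 20)
  fit <- fit_bayes(tr$y, tr$g, "brr", n_iter = 4000, burn_in = 800,
                   seed = 13)
  lam <- fit$diagnostics$sigma2_e / fit$diagnostics$sigma2_b
  Xc <- sweep(tr$g, 2, colMeans(tr$g))
  b <- solve(crossprod(Xc) + lam * diag(ncol(Xc)),
             crossprod(Xc, tr$y - mean(tr$y)))
  ridge_pred <- mean(tr$y) + drop(Xc %*% b)
  expect_gt(cor(ridge_pred, predict(fit, tr$g)), 0.98)
})

test_that("Bayes C with certain inclusion converges to BRR", {
  tr <- make_training(n = 40, m = 60, seed = 220, n_qtl = 15)
  fb <- fit_bayes(tr$y, tr$g, "brr", n_iter = 4000, burn_in = 800, seed = 3)
  fc <- fit_bayes(tr$y, tr$g, "bayes_c", n_iter = 4000, burn_in = 800,
                  seed = 3, pi_fixed = 1)
  pb <- predict(fb, tr$g); pc <- predict(fc, tr$g)
  expect_gt(cor(pb, pc), 0.99)
  expect_lt(max(abs(pb - pc)) / sd(tr$y), 0.1)
})

test_that("sparse-prior samplers detect signal on held-out lines", {
  tr <- make_training(n = 60, m = 100, seed = 225, n_qtl = 5)
  hold <- 1:12
  for (mod in c("bayes_a", "bayes_b")) {
    fit <- fit_bayes(tr$y[-hold], tr$g[-hold, ], mod, n_iter = 2000,
                     burn_in = 400, seed = 17)
    pred <- predict(fit, tr$g[hold, ])
    expect_gt(cor(pred, tr$y[hold]), 0.3)
  }
})

test_that("random forest respects constant targets and averaging bounds", {
  tr <- make_training(n = 20, m = 40)
  yc <- setNames(rep(2.5, 20), rownames(tr$g))
  fit <- fit_forest(yc, tr$g, n_trees = 100, seed = 2)
  expect_equal(unname(predict(fit, tr$g)), rep(2.5, 20))
  fit2 <- fit_forest(tr$y, tr$g, n_trees = 200, seed = 2)
  pred <- predict(fit2, tr$g)
  expect_true(all(pred >= min(tr$y) & pred <= max(tr$y)))
  # seeded determinism
  fit3 <- fit_forest(tr$y, tr$g, n_trees = 200, seed = 2)
  expect_identical(predict(fit3, tr$g), pred)
  # out-of-sample signal on a sparse-QTL trait
  tr2 <- make_training(n = 60, m = 60, seed = 230, n_qtl = 1,
                       noise_sd = 0.2)
  hold <- 1:12
  f <- fit_forest(tr2$y[-hold], tr2$g[-hold, ], seed = 4)
  expect_gt(cor(predict(f, tr2$g[hold, ]), tr2$y[hold]), 0)
})

test_that("every model in the menu returns finite F1 predictions", {
  pan <- small_panel(n_inbred = 35, n_loci = 80, n_parents = 8, n_f1 = 12,
                     dominance_ratio = 0.5, seed = 240)
  bl <- fit_blup(pan$phenotypes)
  y <- setNames(bl$blup, bl$accession)[rownames(pan$genotypes)]
  gf1 <- estimate_f1_genotypes(pan$genotypes, pan$crosses)
  for (mod in gp_model_names()) {
    fit <- fit_gp_model(y, pan$genotypes, mod, seed = 7,
                        n_iter = 600, burn_in = 150, n_trees = 100)
    pred <- predict(fit, gf1)
    expect_true(all(is.finite(pred)), label = paste("finite:", mod))
    expect_length(pred, 12)
  }
})
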