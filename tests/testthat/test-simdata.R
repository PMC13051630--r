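test_that("config validation rejects impossible panels", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.3, 0.2)), "maf_range")
  expect_error(sim_config(residual_het_rate = 0.5), "residual_het_rate")
  expect_error(sim_config(n_parents = 200), "n_parents")
  expect_error(sim_config(n_parents = 5, n_f1 = 11), "unordered")
  expect_error(sim_config(h2_target = 0), "h2_target")
})

test_that("founder simulation respects homozygosity and the seed contract", {
  cfg <- sim_config(n_inbred = 30, n_loci = 80, residual_het_rate = 0,
                    n_parents = 5, n_f1 = 5, seed = 3)
  g <- simulate_founder_genotypes(cfg)
  expect_true(all(g %in% c(-1, 1)))
  expect_identical(g, simulate_founder_genotypes(cfg))
  # no monomorphic loci survive regeneration
  expect_true(all(apply(g, 2, function(x) length(unique(x)) > 1)))

  cfg2 <- sim_config(n_inbred = 30, n_loci = 80, residual_het_rate = 0.15,
                     n_parents = 5, n_f1 = 5, seed = 3)
  g2 <- simulate_founder_genotypes(cfg2)
  expect_gt(mean(g2 == 0), 0.08)
  expect_lt(mean(g2 == 0), 0.22)
})

test_that("realized allele frequencies track the configured distribution", {
  cfg <- sim_config(n_inbred = 500, n_loci = 200, maf_range = c(0.3, 0.3),
                    residual_het_rate = 0, n_parents = 5, n_f1 = 5, seed = 11)
  g <- simulate_founder_genotypes(cfg)
  expect_lt(abs(mean(allele_freqs(g)) - 0.3), 0.05)
})

test_that("crosses are Mendelian and reproducible", {
  # deterministic parents: P1 all -1, P2 all 1, P3 mixed
  g <- toy_geno(rbind(c(-1, -1, -1, -1), c(1, 1, 1, 1), c(-1, 1, 0, 0)),
                acc = c("P1", "P2", "P3"))
  cr <- make_crosses(g, c("P1", "P2"), 1, seed = 5)
  expect_equal(unname(cr$f1_genotypes[1, ]), c(0, 0, 0, 0))
  cr13 <- make_crosses(g, c("P1", "P3"), 1, seed = 5)
  # homozygous-same loci are certain
  expect_equal(unname(cr13$f1_genotypes[1, 1]), -1)
  expect_true(cr13$f1_genotypes[1, 2] %in% c(0))
  expect_identical(make_crosses(g, c("P1", "P3"), 1, seed = 5)$f1_genotypes,
                   cr13$f1_genotypes)
  expect_error(make_crosses(g, c("P1", "P1"), 1), "duplicate")
  expect_error(make_crosses(g, c("P1", "PX"), 1), "not in genotype")
})

test_that("het x het crosses segregate 1:2:1", {
  g <- toy_geno(matrix(0, 2, 1), acc = c("H1", "H2"))
  n <- 10000
  set.seed(77)
  draws <- replicate(n, {
    cr <- make_crosses(g, c("H1", "H2"), 1, seed = sample.int(1e7, 1))
    cr$f1_genotypes[1, 1]
  })
  freq <- table(factor(draws, levels = c(-1, 0, 1))) / n
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("opposite-homozygote loci give obligate heterozygotes", {
  pan <- small_panel(n_inbred = 30, n_loci = 100, n_f1 = 15)
  g <- pan$genotypes
  for (i in seq_len(nrow(pan$crosses))) {
    m <- g[pan$crosses$mother_id[i], ]
    f <- g[pan$crosses$father_id[i], ]
    opp <- which(m * f == -1 & m != 0)   # -1 x 1 or 1 x -1
    if (length(opp))
      expect_true(all(pan$f1_genotypes[i, opp] == 0))
  }
})

test_that("architecture scaling hits the requested dominance ratio", {
  cfg <- sim_config(n_inbred = 500, n_loci = 300, residual_het_rate = 0.1,
                    n_parents = 5, n_f1 = 5, seed = 21)
  g <- simulate_founder_genotypes(cfg)
  ar0 <- simulate_architecture(300, 40, 0, seed = 4, genotypes = g)
  expect_true(all(ar0$dominance_effects == 0))
  ar_all <- simulate_architecture(300, 300, 0.5, seed = 4, genotypes = g)
  expect_length(ar_all$qtl_indices, 300)
  expect_error(simulate_architecture(300, 0, 0.5), "n_qtl")

  ar1 <- simulate_architecture(300, 40, 1, seed = 4, genotypes = g)
  X <- g[, ar1$qtl_indices]
  va <- var(drop(X %*% ar1$additive_effects))
  vd <- var(drop(((X == 0) * 1) %*% ar1$dominance_effects))
  expect_gt(vd / va, 0.7)
  expect_lt(vd / va, 1.3)
})

test_that("phenotype noise obeys the heritability calibration", {
  pan <- small_panel(n_inbred = 30, n_loci = 60, n_f1 = 10, seed = 31)
  # noise-free limit: h2 = 1 and explicit zero year effects
  cfg <- pan$config
  cfg$h2_target <- 1
  cfg$year_effects <- rep(0, 3)
  ph <- simulate_phenotypes(pan$genotypes, pan$arch, cfg)
  gv <- genetic_values(pan$genotypes, pan$arch)
  for (yr in unique(ph$year)) {
    v <- ph$value[ph$year == yr]
    names(v) <- ph$accession[ph$year == yr]
    expect_equal(v[names(gv)], gv, tolerance = 1e-12)
  }
  # null architecture: value is exactly intercept + year effect
  ar0 <- pan$arch
  ar0$additive_effects[] <- 0
  ar0$dominance_effects[] <- 0
  cfg0 <- pan$config
  cfg0$year_effects <- c(-1, 0, 1)
  ph0 <- simulate_phenotypes(pan$genotypes, ar0, cfg0)
  expect_equal(ph0$value[ph0$year == "Y1"],
               rep(10 - 1, nrow(pan$genotypes)), tolerance = 1e-12)
})

test_that("target heritability is recovered by the downstream mixed model", {
  cfg <- sim_config(n_inbred = 300, n_loci = 200, n_parents = 5, n_f1 = 5,
                    h2_target = 0.9, seed = 41)
  g <- simulate_founder_genotypes(cfg)
  ar <- simulate_architecture(200, 30, 0, seed = 42, genotypes = g,
                              intercept = 10)
  ph <- simulate_phenotypes(g, ar, cfg)
  bl <- fit_blup(ph)
  expect_gt(bl$h2_b[1], 85)
  expect_lt(bl$h2_b[1], 95)
})

test_that("a purely additive panel shows no mean mid-parent heterosis", {
  pan <- small_panel(n_inbred = 80, n_loci = 300, n_parents = 12,
                     n_f1 = 50, dominance_ratio = 0, seed = 51)
  ph <- pan$phenotypes
  bl <- fit_blup(ph)
  het <- heterosis_table(bl, pan$crosses)
  expect_lt(abs(mean(het$mp_heterosis, na.rm = TRUE)), 5)
})
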