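test_that("parental genotypes follow Binomial(2, maf) moments", {
  set.seed(101)
  par <- simulate_parents(100000, 2, 0.3)
  g <- par$mother$genotype
  expect_true(all(g %in% 0:2))
  expect_equal(g, par$mother$a1 + par$mother$a2)
  # allele-frequency and variance against binomial theory, 3-SE bands
  af <- colMeans(g) / 2
  expect_true(all(abs(af - 0.3) < 3 * sqrt(0.3 * 0.7 / (2 * 100000))))
  v <- apply(g, 2, var)
  expect_true(all(abs(v - 0.42) < 0.01))

  expect_true(all(simulate_parents(50, 3, 0)$father$genotype == 0))
  expect_error(simulate_parents(10, 1, 1.5), "maf")
})

test_that("transmission gives MZ correlation 1 and DZ correlation 0.5", {
  set.seed(102)
  n <- 20000
  par <- simulate_parents(n, 4, 0.5)
  mz <- transmit_genotypes(par, "MZ")
  expect_identical(mz$twin1, mz$twin2)
  dz <- transmit_genotypes(par, "DZ")
  r <- sapply(1:4, function(j) cor(dz$twin1[, j], dz$twin2[, j]))
  expect_true(all(abs(r - 0.5) < 3 / sqrt(n)))

  # homozygous-absent parents transmit nothing
  zero <- matrix(0L, 5, 2)
  par0 <- list(mother = list(a1 = zero, a2 = zero),
               father = list(a1 = zero, a2 = zero))
  expect_true(all(transmit_genotypes(par0, "DZ")$twin1 == 0))
})

test_that("effect-size regimes hit their variance targets", {
  cfg <- sim_config(n_mz = 10, n_dz = 10, n_snps = 1000)
  e <- draw_effects(cfg)
  expect_true(all(e$beta1 == sqrt(1 / 1000)))
  expect_equal(sum(e$beta1^2), 1, tolerance = 1e-12)
  expect_equal(e$beta1[1], 0.0316, tolerance = 1e-3)

  e1 <- draw_effects(sim_config(n_mz = 10, n_dz = 10, n_snps = 1,
                                total_int_variance = 0))
  expect_equal(e1$beta1, 1)
  expect_equal(e1$beta3, 0)

  set.seed(103)
  en <- draw_effects(sim_config(n_mz = 10, n_dz = 10, n_snps = 1000,
                                effect_regime = "normal"))
  expect_lt(abs(sd(en$beta1) - 0.0316), 0.003)
  expect_lt(abs(mean(en$beta1)), 3 * 0.0316 / sqrt(1000))
  expect_false(any(en$beta1 == en$beta3))

  expect_error(sim_config(total_main_variance = -1), "non-negative")
})

test_that("phenotypes equal the moderated-regression construction exactly", {
  cfg <- sim_config(n_mz = 400, n_dz = 400, n_snps = 20, seed = 104)
  d <- simulate_twin_data(cfg)
  for (z in c("mz", "dz")) {
    g <- d[[z]]$genotype$twin1
    det <- d$effects$beta0 + drop(g %*% d$effects$beta1) +
      d$effects$beta2 * d[[z]]$moderator$twin1 +
      d[[z]]$moderator$twin1 * drop(g %*% d$effects$beta3)
    expect_equal(d[[z]]$phenotype$twin1, det + d[[z]]$residual$twin1,
                 tolerance = 1e-12)
    # parents are moderator-free
    detp <- d$effects$beta0 + drop(d[[z]]$genotype$mother %*% d$effects$beta1)
    expect_equal(d[[z]]$phenotype$mother, detp + d[[z]]$residual$mother,
                 tolerance = 1e-12)
  }
  expect_error(
    simulate_phenotype(matrix(0:2, 3, 1), moderator = c(0, 1),
                       effects = d$effects[1:4]),
    "length")
})

test_that("residual variance is recovered at scale", {
  d <- simulate_twin_data(sim_config(n_mz = 100, n_dz = 20000, seed = 105))
  expect_equal(var(d$dz$residual$twin1), 0.5, tolerance = 0.05 * 0.5)
})

test_that("the single-SNP interaction preset has the expected strata", {
  d <- simulate_study(2, n_mz = 100, n_dz = 50000, seed = 106)
  y <- d$dz$phenotype$twin1
  g <- d$dz$genotype$twin1[, 1]
  m <- d$dz$moderator$twin1
  expect_equal(var(y[m == 0]), 1.0, tolerance = 0.05)
  expect_equal(var(y[m == 1]), 2.5, tolerance = 0.1)
  expect_equal(unname(coef(lm(y[m == 1] ~ g[m == 1]))[2]), 2, tolerance = 0.05)
})

test_that("datasets are bit-reproducible from the seed, whatever is kept", {
  cfg <- sim_config(n_mz = 150, n_dz = 150, n_snps = 30, seed = 107)
  d1 <- simulate_twin_data(cfg)
  d2 <- simulate_twin_data(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_twin_data(cfg, keep = "dz_twin1")
  expect_identical(d1$dz$genotype$twin1, d3$dz$genotype$twin1)
  expect_identical(d1$mz$phenotype$twin2, d3$mz$phenotype$twin2)
  expect_null(d3$mz$genotype$twin1)
})

test_that("study presets and pair extraction behave", {
  expect_error(simulate_study(9), "unknown study")
  d <- simulate_study(3, n_mz = 60, n_dz = 80, seed = 108)
  expect_equal(d$config$n_snps, 1000L)
  expect_equal(sum(d$effects$beta1^2), 1, tolerance = 1e-12)
  p <- twin_pairs(d, n_pairs = 50)
  expect_equal(nrow(p), 100)
  expect_equal(sum(p$zygosity == "MZ"), 50)
  expect_equal(sum(p$zygosity == "DZ"), 50)
  expect_error(twin_pairs(d, n_pairs = 500), "available")
})
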