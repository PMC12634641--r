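test_that("scan estimates match the normal-equations oracle exactly", {
  set.seed(201)
  # hand-sized dataset plus a larger random instance
  for (n in c(8, 500)) {
    if (n == 8) {
      g <- cbind(c(0, 1, 2, 0, 1, 2, 0, 2),
                 c(2, 0, 1, 1, 2, 0, 1, 0),
                 c(1, 2, 0, 2, 0, 1, 2, 1))
      m <- c(0, 0, 0, 0, 1, 1, 1, 1)
      y <- c(0.3, 1.1, 2.2, -0.4, 2.6, 4.1, 0.2, 3.5)
    } else {
      g <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
      m <- rbinom(n, 1, 0.5)
      y <- rnorm(n) + g[, 1] * 0.5 + m * g[, 2]
    }
    for (model in c("moderated", "standard")) {
      s <- gwas_scan(y, g, m, model = model)
      for (j in 1:3) {
        X <- if (model == "moderated") cbind(1, g[, j], m, g[, j] * m)
             else cbind(1, g[, j], m)
        o <- oracle_ols(X, y)
        expect_equal(s$beta_main[j], o$coef[2], tolerance = 1e-10)
        expect_equal(s$se_main[j], o$se[2], tolerance = 1e-10)
        expect_equal(s$beta_mod[j], o$coef[3], tolerance = 1e-10)
        if (model == "moderated") {
          expect_equal(s$beta_int[j], o$coef[4], tolerance = 1e-10)
          expect_equal(s$se_int[j], o$se[4], tolerance = 1e-10)
        }
      }
      expect_equal(s$z_main, s$beta_main / s$se_main, tolerance = 1e-12)
    }
  }
})

test_that("type-I error is calibrated under the null", {
  set.seed(202)
  n <- 400; k <- 2500
  g <- matrix(rbinom(n * k, 2, 0.5), n, k)
  m <- rbinom(n, 1, 0.5)
  y <- rnorm(n)
  s <- gwas_scan(y, g, m)
  for (a in c(0.05, 0.005)) {
    tol <- 3 * sqrt(a * (1 - a) / k)
    expect_lt(abs(mean(s$p_main < a) - a), tol)
    expect_lt(abs(mean(s$p_int < a) - a), tol)
  }
})

test_that("degenerate SNPs are flagged, not fatal", {
  set.seed(203)
  n <- 100
  g <- cbind(rbinom(n, 2, 0.5), rep(1L, n))   # second SNP monomorphic
  m <- rbinom(n, 1, 0.5)
  s <- gwas_scan(rnorm(n), g, m)
  expect_false(s$degenerate[1])
  expect_true(s$degenerate[2])
  expect_true(is.na(s$beta_main[2]))
})

test_that("the unmoderated scan absorbs the interaction times the moderator mean", {
  d <- simulate_study(2, n_mz = 100, n_dz = 40000, seed = 204)
  y <- d$dz$phenotype$twin1
  g <- d$dz$genotype$twin1
  m <- d$dz$moderator$twin1
  smod <- gwas_scan(y, g, m, model = "moderated")
  sstd <- gwas_scan(y, g, m, model = "standard")
  # omitted-interaction projection: beta1_std ~= beta1_mod + beta3 * E[m]
  pred <- smod$beta_main + smod$beta_int * mean(m)
  expect_lt(abs(sstd$beta_main - pred), 3 * sstd$se_main)
  # and the moderated beta1 is the unexposed-stratum slope
  slope0 <- unname(coef(lm(y[m == 0] ~ g[m == 0, 1]))[2])
  expect_equal(smod$beta_main, slope0, tolerance = 1e-8)
})

test_that("significance counting respects both thresholds", {
  s <- fake_sumstats(beta_main = c(0, 0, 0), beta_int = c(0, 0, 0))
  s$p_main <- c(1, 1, 1); s$p_int <- c(1, 1, 1)
  cs <- count_significant(s, n_snps = 3)
  expect_equal(cs$n_main_genomewide + cs$n_int_genomewide +
                 cs$n_main_bonferroni + cs$n_int_bonferroni, 0)

  s$p_main <- c(1e-9, 1, 1); s$p_int <- c(1, 1e-3, 1)
  cs <- count_significant(s, n_snps = 3)
  expect_equal(cs$n_main_genomewide, 1)
  expect_equal(cs$n_int_genomewide, 0)
  expect_equal(cs$n_main_bonferroni, 1)
  expect_equal(cs$n_int_bonferroni, 1)   # 1e-3 < 0.05/3
  expect_equal(cs$additional_int, 1)
})

test_that("stratified r-squared separates moderator levels", {
  d <- simulate_study(2, n_mz = 100, n_dz = 50000, seed = 205)
  s <- stratified_r2(d$dz$phenotype$twin1, d$dz$genotype$twin1[, 1],
                     d$dz$moderator$twin1)
  expect_equal(s$overall, 0.75, tolerance = 0.01)
  expect_equal(unname(s$strata["mod=0"]), 0.50, tolerance = 0.01)
  expect_equal(unname(s$strata["mod=1"]), 0.80, tolerance = 0.01)

  # no genetic signal: everything near zero
  set.seed(205)
  n <- 5000
  g <- rbinom(n, 2, 0.5); m <- rbinom(n, 1, 0.5); y <- rnorm(n)
  s0 <- stratified_r2(y, g, m)
  expect_lt(s0$overall, 0.01)
  expect_true(all(s0$strata < 0.01))
  expect_error(stratified_r2(y, g, rnorm(n)), "binary")
})

test_that("main and interaction estimates trade off negatively across SNPs", {
  d <- simulate_twin_data(
    sim_config(n_mz = 10, n_dz = 3000, n_snps = 300, seed = 206),
    keep = "dz_twin1")
  s <- gwas_scan(d$dz$phenotype$twin1, d$dz$genotype$twin1,
                 d$dz$moderator$twin1)
  expect_lt(cor(s$beta_main, s$beta_int), 0)
})
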