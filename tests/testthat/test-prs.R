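test_that("a score built from the true weights is the genetic value", {
  d <- simulate_twin_data(
    sim_config(n_mz = 4000, n_dz = 10, n_snps = 100, seed = 401),
    keep = "mz_twin1")
  truth <- fake_sumstats(d$effects$beta1, d$effects$beta3)
  g <- d$mz$genotype$twin1
  m <- d$mz$moderator$twin1
  y <- d$mz$phenotype$twin1
  sc <- list(main = build_prs(truth, g, kind = "main"),
             int = build_prs(truth, g, m, kind = "int"),
             stand = build_prs(truth, g, kind = "stand"))
  expect_equal(attr(sc$main, "n_snps_used"), 100)
  # noiseless weights: both models recover (0, 1, 0, 1) within 3 SEs
  for (mod in c("gxe", "standard")) {
    f <- prsxe(y, sc, m, model = mod)
    est <- f$coefficients
    target <- c(0, 1, 0, 1)
    expect_true(all(abs(est$estimate - target) < 3 * est$se),
                info = mod)
  }
})

test_that("score construction validates alignment and flags degeneracy", {
  d <- simulate_twin_data(
    sim_config(n_mz = 50, n_dz = 10, n_snps = 5, seed = 402),
    keep = "mz_twin1")
  ss <- fake_sumstats(rep(0.1, 5), rep(0.1, 5))
  g <- d$mz$genotype$twin1

  g_bad <- g[, c(2, 1, 3, 4, 5)]
  expect_error(build_prs(ss, g_bad, kind = "main"), "not aligned")
  expect_error(build_prs(ss, g[, 1:4], kind = "main"), "not aligned")
  expect_error(build_prs(ss, g, kind = "int"), "moderator")

  zero <- build_prs(fake_sumstats(rep(0, 5), rep(0, 5)), g, kind = "main")
  expect_true(attr(zero, "degenerate"))
  # constant score makes the design collinear: flagged fit, not an error
  f <- prsxe(d$mz$phenotype$twin1,
             list(main = zero, int = zero), d$mz$moderator$twin1, "gxe")
  expect_true(f$degenerate)
  expect_true(all(is.na(f$coefficients$estimate)))
})

test_that("p-value thresholding filters discovery weights", {
  ss <- fake_sumstats(c(5, 0.1, 0.1), c(5, 0.1, 0.1))
  g <- matrix(rbinom(60, 2, 0.5), 20, 3,
              dimnames = list(NULL, ss$snp_id))
  s_all <- build_prs(ss, g, kind = "main")
  s_top <- build_prs(ss, g, kind = "main", p_threshold = 1e-6)
  expect_equal(attr(s_all, "n_snps_used"), 3)
  expect_equal(attr(s_top, "n_snps_used"), 1)
  expect_equal(as.numeric(s_top), 5 * g[, 1])
})

test_that("sign-mixed interactions cancel in the product-term model only", {
  # normal-regime architecture: the interaction-weighted score keeps its
  # signal, while the single-score product term collapses toward zero
  d <- simulate_twin_data(
    sim_config(n_mz = 3000, n_dz = 20000, n_snps = 400,
               effect_regime = "normal", seed = 403),
    keep = c("dz_twin1", "mz_twin1"))
  scan <- gwas_scan(d$dz$phenotype$twin1, d$dz$genotype$twin1,
                    d$dz$moderator$twin1)
  g <- d$mz$genotype$twin1
  m <- d$mz$moderator$twin1
  y <- d$mz$phenotype$twin1
  sc <- list(main = build_prs(scan, g, kind = "main"),
             int = build_prs(scan, g, m, kind = "int"),
             stand = build_prs(scan, g, kind = "stand"))
  fg <- prsxe(y, sc, m, "gxe")
  fs <- prsxe(y, sc, m, "standard")
  int_g <- fg$coefficients[fg$coefficients$term == "prs_int", ]
  int_s <- fs$coefficients[fs$coefficients$term == "prs_stand:moderator", ]
  expect_gt(int_g$estimate, 3 * int_g$se)     # bounded away from zero
  expect_lt(abs(int_s$estimate), 0.35)        # cancelled
  expect_lt(abs(int_s$estimate), int_g$estimate)
})

test_that("discovery noise attenuates the interaction score monotonically", {
  set.seed(404)
  n_disc <- c(6000, 1500, 400)
  reps <- 12
  means <- sapply(n_disc, function(nd) {
    est <- numeric(reps)
    for (r in seq_len(reps)) {
      d <- simulate_twin_data(
        sim_config(n_mz = 1500, n_dz = nd, n_snps = 150,
                   seed = 404000 + nd + r),
        keep = c("dz_twin1", "mz_twin1"))
      scan <- gwas_scan(d$dz$phenotype$twin1, d$dz$genotype$twin1,
                        d$dz$moderator$twin1)
      g <- d$mz$genotype$twin1
      m <- d$mz$moderator$twin1
      sc <- list(main = build_prs(scan, g, kind = "main"),
                 int = build_prs(scan, g, m, kind = "int"))
      f <- prsxe(d$mz$phenotype$twin1, sc, m, "gxe")
      est[r] <- coef(f)["prs_int"]
    }
    mean(est)
  })
  expect_true(all(diff(means) < 0))
  expect_true(all(means > 0 & means < 1))
})
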