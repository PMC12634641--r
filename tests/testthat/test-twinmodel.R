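test_that("expected moments follow the moderated path algebra", {
  p <- c(a = 1, c = 1, e = 1)
  mm <- expected_moments(p, 0.3, -0.2, "MZ")
  expect_equal(diag(mm$cov), c(3, 3))
  expect_equal(mm$cov[1, 2], 2)
  expect_equal(expected_moments(p, 0, 0, "DZ")$cov[1, 2], 1.5)

  # A-path moderation doubles the exposed additive variance contribution
  p2 <- c(a = 0.707, beta_a = 0.707, e = 0.5)
  mm2 <- expected_moments(p2, 1, 1, "MZ")
  expect_equal(mm2$cov[1, 1] - 0.25, (0.707 + 0.707)^2, tolerance = 1e-12)

  # asymmetric moderators
  p3 <- c(a = 0.8, beta_a = 0.3, c = 0.4, beta_c = 0.1, e = 0.5)
  mm3 <- expected_moments(p3, 0, 1, "MZ")
  expect_equal(mm3$cov[1, 2], 0.8 * (0.8 + 0.3) + 0.4 * (0.4 + 0.1))

  # means model uses own and co-twin moderators
  p4 <- c(a = 1, e = 1, mu = 0.5, beta_m_own = 2, beta_m_cotwin = -1)
  expect_equal(expected_moments(p4, 1, 0, "DZ")$mean, c(2.5, -0.5))
})

test_that("the FIML deviance matches direct density evaluation", {
  set.seed(301)
  for (i in 1:20) {
    p <- c(a = runif(1, 0.3, 1.5), c = runif(1, 0, 0.8),
           e = runif(1, 0.3, 1.2), beta_a = rnorm(1, 0, 0.4),
           beta_c = rnorm(1, 0, 0.2), beta_e = rnorm(1, 0, 0.2),
           mu = rnorm(1), beta_m_own = rnorm(1, 0, 0.5),
           beta_m_cotwin = rnorm(1, 0, 0.5))
    pairs <- simulate_twin_pairs(4, 4, p)
    expect_equal(ace_neg2ll(p, pairs), oracle_neg2ll(p, pairs),
                 tolerance = 1e-8)
  }
})

test_that("deviance is additive and sign-flip invariant, with a PD penalty", {
  set.seed(302)
  p <- c(a = 0.7, e = 0.7, beta_a = 0.5, mu = 0.2)
  pairs <- simulate_twin_pairs(30, 30, p)
  expect_equal(ace_neg2ll(p, rbind(pairs, pairs)), 2 * ace_neg2ll(p, pairs))

  pf <- p; pf["a"] <- -pf["a"]; pf["beta_a"] <- -0.5
  expect_equal(ace_neg2ll(pf, pairs), ace_neg2ll(p, pairs))

  expect_equal(ace_neg2ll(c(a = 0, c = 0, e = 0), pairs), 1e10)
  expect_error(ace_neg2ll(p, pairs[0, ]), "no twin pairs")
})

test_that("nested submodels never beat the full model", {
  set.seed(303)
  pairs <- simulate_twin_pairs(800, 800,
                               c(a = 0.7, e = 0.7, beta_a = 0.6, mu = 1,
                                 beta_m_own = 0.8))
  full <- ace_gxe(pairs)
  nomod <- ace_gxe(pairs, moderated = FALSE)
  bare <- ace_gxe(pairs, moderated = FALSE, means_moderators = FALSE)
  expect_lte(full$minus2lnL, nomod$minus2lnL + 1e-6)
  expect_lte(nomod$minus2lnL, bare$minus2lnL + 1e-6)
  # the full fit's deviance equals its own profile evaluated at the optimum
  expect_equal(ace_neg2ll(full$params, pairs), full$minus2lnL,
               tolerance = 1e-8)
})

test_that("moderated parameters are recovered across replicates", {
  set.seed(304)
  truth <- c(a = 0.707, e = 0.707, beta_a = 0.707)
  a_hat <- ba_hat <- numeric(30)
  for (r in 1:30) {
    pairs <- simulate_twin_pairs(2000, 2000, truth)
    f <- ace_gxe(pairs, restarts = 1)
    a_hat[r] <- f$params["a"]; ba_hat[r] <- f$params["beta_a"]
  }
  expect_lt(abs(mean(a_hat) - 0.707), 0.05)
  expect_lt(abs(mean(ba_hat) - 0.707), 0.07)
})

test_that("a pure-environment model yields a near-zero additive estimate", {
  set.seed(305)
  pairs <- simulate_twin_pairs(1500, 1500, c(a = 0, c = 0, e = 1))
  f <- ace_gxe(pairs, moderated = FALSE, means_moderators = FALSE)
  v <- sum(f$params[c("a", "c", "e")]^2)
  expect_lt(f$params["a"]^2 / v, 0.05)
  expect_true(all(f$params[c("a", "c", "e")] >= 0))   # canonical signs
  expect_true(all(is.finite(f$se[f$free])))
})

test_that("variance curves decompose the total exactly", {
  set.seed(306)
  pairs <- simulate_twin_pairs(400, 400, c(a = 0.7, e = 0.7, beta_a = 0.5))
  f <- ace_gxe(pairs)
  cur <- variance_decomposition(f, mod_grid = seq(-1, 2, 0.5))
  expect_equal(cur$Vt, cur$Va + cur$Vc + cur$Ve, tolerance = 1e-12)
  expect_true(all(cur[, c("Va", "Vc", "Ve")] >= 0))

  flat <- ace_gxe(pairs, moderated = FALSE)
  curf <- variance_decomposition(flat, mod_grid = c(0, 1))
  expect_equal(curf$Va[1], curf$Va[2])
})

test_that("fit objects expose the standard modelling interface", {
  set.seed(307)
  pairs <- simulate_twin_pairs(300, 300, c(a = 0.7, e = 0.7, mu = 0.3))
  f <- ace_gxe(pairs, moderated = FALSE)
  expect_s3_class(f, "ace_gxe")
  expect_named(coef(f))
  expect_equal(as.numeric(logLik(f)), -f$minus2lnL / 2)
  expect_equal(dim(vcov(f)), c(sum(f$free), sum(f$free)))
  sim <- simulate(f, seed = 1)
  expect_equal(nrow(sim), 600)
  expect_identical(simulate(f, seed = 1), sim)
  expect_output(print(f), "Moderated ACE")
})
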