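# Monte Carlo power machinery for the moderated-regression Wald tests.
#
# The single-SNP fit of Y ~ 1 + G + m + G:m with a binary moderator is
# exactly the pair of stratum-wise simple regressions (the interaction
# model is saturated in the moderator), which makes the per-replicate OLS
# closed-form and lets whole batches of replicates be fit with colSums.
# Under the fixed-effect polygenic regimes, the n_snps - 1 non-focal SNPs
# all carry the same weight, so their summed phenotypic contribution is
# effect * (1 + m) * S with S ~ Binomial(2 * (n_snps - 1), maf) -- an exact
# one-draw representation of the genetic background.

.mc_batch <- function(n, reps, effect, n_snps, alpha, maf, prevalence,
                      resid_var) {
  zcrit <- qnorm(1 - alpha / 2)
  gen <- function(r) {
    G <- matrix(rbinom(n * r, 2L, maf), n, r)
    M <- matrix(rbinom(n * r, 1L, prevalence), n, r)
    Y <- effect * G + effect * G * M +
      matrix(rnorm(n * r, 0, sqrt(resid_var)), n, r)
    if (n_snps > 1) {
      S <- matrix(rbinom(n * r, 2L * (n_snps - 1L), maf), n, r)
      Y <- Y + effect * S + effect * S * M
    }
    list(G = G, M = M, Y = Y)
  }
  z1 <- z3 <- rep(NA_real_, reps)
  todo <- seq_len(reps)
  discarded <- 0L
  tries <- 0L
  while (length(todo) > 0 && tries < 6L) {
    b <- gen(length(todo))
    n1 <- colSums(b$M); n0 <- n - n1
    W1 <- b$M; W0 <- 1 - b$M
    stat <- function(W, ns) {
      sx <- colSums(b$G * W); sy <- colSums(b$Y * W)
      cxx <- colSums(b$G^2 * W) - sx^2 / ns
      cxy <- colSums(b$G * b$Y * W) - sx * sy / ns
      cyy <- colSums(b$Y^2 * W) - sy^2 / ns
      list(cxx = cxx, cxy = cxy, cyy = cyy)
    }
    s0 <- stat(W0, n0); s1 <- stat(W1, n1)
    ok <- n0 >= 3 & n1 >= 3 & s0$cxx > 1e-10 & s1$cxx > 1e-10
    if (any(ok)) {
      b0 <- s0$cxy[ok] / s0$cxx[ok]
      b1 <- s1$cxy[ok] / s1$cxx[ok]
      sse <- (s0$cyy[ok] - b0 * s0$cxy[ok]) + (s1$cyy[ok] - b1 * s1$cxy[ok])
      sig2 <- sse / (n - 4)
      z1[todo[ok]] <- b0 / sqrt(sig2 / s0$cxx[ok])
      z3[todo[ok]] <- (b1 - b0) /
        sqrt(sig2 * (1 / s0$cxx[ok] + 1 / s1$cxx[ok]))
    }
    discarded <- discarded + sum(!ok)
    todo <- todo[!ok]
    tries <- tries + 1L
  }
  done <- !is.na(z1)
  list(power_main = mean(abs(z1[done]) > zcrit),
       power_int = mean(abs(z3[done]) > zcrit),
       reps = sum(done), discarded = discarded)
}

#' Monte Carlo power of the moderated-regression Wald tests
#'
#' Generates `reps` independent single-focal-SNP datasets at sample size
#' `n` under the moderated model (main and interaction coefficients both
#' equal to `effect`), fits `Y ~ 1 + G + m + G:m` by OLS and reports the
#' fraction of replicates whose main-effect and interaction Wald
#' statistics exceed the two-sided `alpha` threshold. In polygenic
#' conditions (`n_snps > 1`) the remaining SNPs contribute phenotypic
#' variance with the same fixed weight but only the focal SNP is fitted,
#' which inflates the residual exactly as a genome scan of one SNP at a
#' time would experience. Degenerate replicates (a stratum with no
#' genotype variance) are regenerated and counted.
#'
#' @param n sample size (>= 10).
#' @param effect main and interaction coefficient of the focal SNP
#'   (`1/sqrt(n_snps)` matches the study presets).
#' @param n_snps total SNPs in the generative model.
#' @param alpha two-sided significance threshold (genome-wide 5e-8 by
#'   default).
#' @param reps Monte Carlo replicates.
#' @param maf,prevalence,resid_var generative nuisance parameters.
#' @return An object of class `power_estimate`: `power_main`, `power_int`,
#'   binomial standard errors, replicate count and settings.
#' @export
#' @examples
#' set.seed(1)
#' power_moderated(n = 159, effect = 1, reps = 300)
power_moderated <- function(n, effect, n_snps = 1, alpha = 5e-8,
                            reps = 2000, maf = 0.5, prevalence = 0.5,
                            resid_var = 0.5) {
  if (n < 10) stop("n must be at least 10")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (reps < 1) stop("reps must be positive")
  if (alpha == 1) {
    out <- list(power_main = 1, power_int = 1, reps = reps, discarded = 0L)
  } else {
    # chunk replicates so n * reps matrices stay modest at large n
    block <- max(1L, min(reps, floor(2e7 / n)))
    agg <- c(main = 0, int = 0, reps = 0, discarded = 0)
    left <- reps
    while (left > 0) {
      r <- min(block, left)
      b <- .mc_batch(n, r, effect, n_snps, alpha, maf, prevalence, resid_var)
      agg <- agg + c(b$power_main * b$reps, b$power_int * b$reps,
                     b$reps, b$discarded)
      left <- left - r
    }
    out <- list(power_main = agg[["main"]] / agg[["reps"]],
                power_int = agg[["int"]] / agg[["reps"]],
                reps = agg[["reps"]], discarded = agg[["discarded"]])
  }
  out$se_main <- sqrt(out$power_main * (1 - out$power_main) / out$reps)
  out$se_int <- sqrt(out$power_int * (1 - out$power_int) / out$reps)
  out$n <- n; out$effect <- effect; out$n_snps <- n_snps; out$alpha <- alpha
  class(out) <- "power_estimate"
  out
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Monte Carlo power at n = %d (effect %.4g, %d SNP(s), alpha %.3g)\n",
              x$n, x$effect, x$n_snps, x$alpha))
  cat(sprintf("  main:        %.3f (SE %.3f)\n", x$power_main, x$se_main))
  cat(sprintf("  interaction: %.3f (SE %.3f)   [%d replicates]\n",
              x$power_int, x$se_int, x$reps))
  invisible(x)
}

#' Analytic noncentrality-based power
#'
#' Closed-form cross-check for the Monte Carlo engine. With a binary
#' moderator, the main-effect estimate is the unexposed-stratum slope with
#' sampling variance `sigma0^2 / (n P0 2pq)` and the interaction estimate
#' is the difference of stratum slopes, so its variance adds the exposed
#' stratum's term; the noncentrality is `lambda = effect / SE`. The
#' `"normal"` method reports `Phi(lambda - z) + Phi(-lambda - z)` at the
#' expected design. The default `"exact"` method additionally accounts for
#' the three design-level sources of spread that matter at the small
#' sample sizes where single-SNP power crosses 80%: the Wald statistic is
#' noncentral-t (the residual variance is estimated on `n - 4` degrees of
#' freedom), the stratum split is Binomial(`n`, prevalence), and each
#' stratum's genotype sum of squares fluctuates around `(n_s - 1) 2pq`
#' (integrated by Gauss-Hermite quadrature on its normal approximation).
#' Above `n = 2000` the two methods agree to well under Monte Carlo
#' resolution and the fast normal form is used either way. In polygenic
#' conditions the stratum residual variances are inflated by the
#' unmodelled background, `(n_snps - 1) effect^2 (1 + s)^2 2pq` at
#' stratum `s`.
#'
#' @inheritParams power_moderated
#' @param method `"exact"` (noncentral-t, design-averaged) or `"normal"`
#'   (plain normal approximation at the expected design).
#' @return named vector `c(main = , int = )` of approximate powers.
#' @export
power_analytic <- function(n, effect, n_snps = 1, alpha = 5e-8, maf = 0.5,
                           prevalence = 0.5, resid_var = 0.5,
                           method = c("exact", "normal")) {
  method <- match.arg(method)
  if (alpha >= 1) return(c(main = 1, int = 1))
  zcrit <- qnorm(1 - alpha / 2)
  vg <- 2 * maf * (1 - maf)
  bg <- (n_snps - 1) * effect^2 * vg
  sig2 <- c(resid_var + bg, resid_var + 4 * bg)     # strata m = 0, 1
  if (method == "normal" || n > 2000) {
    p <- c(1 - prevalence, prevalence)
    v_slope <- sig2 / (n * p * vg)          # true sampling variances
    sig2_pool <- sum(p * sig2)              # what the fitted model estimates
    se2 <- sig2_pool / (n * p * vg)         # expected squared Wald SEs
    lam <- c(main = effect / sqrt(se2[1]),
             int = effect / sqrt(se2[1] + se2[2]))
    # with an unmodelled heteroskedastic background the Wald z is not
    # unit-variance: scale by the ratio of true to pooled-SE variance
    s <- c(main = sqrt(v_slope[1] / se2[1]),
           int = sqrt((v_slope[1] + v_slope[2]) / (se2[1] + se2[2])))
    return(pnorm((lam - zcrit) / s) + pnorm((-lam - zcrit) / s))
  }
  df <- n - 4
  # central 4th moment of Binomial(2, maf) drives the spread of the
  # stratum genotype sum of squares
  g <- 0:2
  pr <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  w4 <- sum(pr * (g - 2 * maf)^4) - vg^2
  # probabilists' Gauss-Hermite nodes via the Golub-Welsch Jacobi matrix
  k <- 12L
  J <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) J[i, i + 1L] <- J[i + 1L, i] <- sqrt(i)
  ev <- eigen(J, symmetric = TRUE)
  x <- ev$values
  wq <- ev$vectors[1, ]^2
  pw <- function(lam) pt(zcrit, df, ncp = lam, lower.tail = FALSE) +
    pt(-zcrit, df, ncp = lam)
  n1s <- max(4L, qbinom(1e-10, n, prevalence)):
    min(n - 4L, qbinom(1e-10, n, prevalence, lower.tail = FALSE))
  wb <- dbinom(n1s, n, prevalence)
  tot <- c(main = 0, int = 0)
  for (ii in seq_along(n1s)) {
    n1 <- n1s[ii]; n0 <- n - n1
    s0 <- pmax((n0 - 1) * vg + x * sqrt((n0 - 1) * w4), 1e-3)
    s1 <- pmax((n1 - 1) * vg + x * sqrt((n1 - 1) * w4), 1e-3)
    tot["main"] <- tot["main"] +
      wb[ii] * sum(wq * pw(effect / sqrt(sig2[1] / s0)))
    V <- outer(sig2[1] / s0, sig2[2] / s1, "+")
    tot["int"] <- tot["int"] +
      wb[ii] * sum(outer(wq, wq) * pw(effect / sqrt(V)))
  }
  tot / sum(wb)
}

#' Search for the sample size reaching a target power
#'
#' Integer bisection on `n`, seeded by an analytic bracket from
#' [power_analytic()] and driven by [power_moderated()] at each candidate.
#' Near the decision boundary (estimated power within two binomial
#' standard errors of the target) the replicate count is escalated
#' fourfold to resolve the Monte Carlo noise. The search returns the
#' smallest `n` whose estimated power reaches the target.
#'
#' @inheritParams power_moderated
#' @param which `"main"` or `"int"` -- which Wald test to power.
#' @param target_power target (0.8 by default).
#' @param reps base Monte Carlo replicates per candidate `n`.
#' @param max_reps escalation ceiling.
#' @return An object of class `samplesize_search`: `n`, achieved `power`
#'   with `se`, and the search `trace` (a data.frame of candidates).
#' @export
find_n_for_power <- function(which = c("main", "int"), target_power = 0.8,
                             effect = 1, n_snps = 1, alpha = 5e-8,
                             reps = 2000, max_reps = 8 * reps, maf = 0.5,
                             prevalence = 0.5, resid_var = 0.5) {
  which <- match.arg(which)
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must lie strictly in (0, 1)")
  pw_an <- function(n) power_analytic(n, effect, n_snps, alpha, maf,
                                      prevalence, resid_var)[[which]]
  trace <- list()
  pw_mc <- function(n) {
    r <- reps
    repeat {
      est <- power_moderated(n, effect, n_snps, alpha, r, maf, prevalence,
                             resid_var)
      p <- if (which == "main") est$power_main else est$power_int
      se <- if (which == "main") est$se_main else est$se_int
      if (abs(p - target_power) >= 2 * se || r >= max_reps) {
        trace[[length(trace) + 1]] <<- data.frame(n = n, power = p, se = se,
                                                  reps = r)
        return(list(p = p, se = se))
      }
      r <- min(max_reps, r * 4L)
    }
  }

  # analytic seed and bracket
  n_seed <- 10
  for (cand in unique(round(exp(seq(log(10), log(5e6), length.out = 400))))) {
    if (pw_an(cand) >= target_power) { n_seed <- cand; break }
  }
  lo <- max(10L, as.integer(floor(n_seed * 0.5)))
  hi <- max(lo + 1L, as.integer(ceiling(n_seed * 1.6)))
  p_lo <- pw_mc(lo)
  while (p_lo$p >= target_power && lo > 10L) {
    lo <- max(10L, lo %/% 2L); p_lo <- pw_mc(lo)
  }
  p_hi <- pw_mc(hi)
  while (p_hi$p < target_power) {
    lo <- hi; p_lo <- p_hi
    hi <- as.integer(ceiling(hi * 1.6)); p_hi <- pw_mc(hi)
  }
  if (p_lo$p >= target_power) {       # power saturated at the floor
    lo_final <- lo
    res <- p_lo
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      p_mid <- pw_mc(mid)
      if (p_mid$p >= target_power) { hi <- mid; p_hi <- p_mid }
      else { lo <- mid; p_lo <- p_mid }
    }
    lo_final <- hi
    res <- p_hi
  }
  structure(list(which = which, target_power = target_power,
                 n = lo_final, power = res$p, se = res$se,
                 effect = effect, n_snps = n_snps, alpha = alpha,
                 trace = do.call(rbind, trace)),
            class = "samplesize_search")
}

#' @export
print.samplesize_search <- function(x, ...) {
  cat(sprintf("Sample size for %.0f%% power (%s effect, alpha %.3g): n = %d\n",
              100 * x$target_power, x$which, x$alpha, x$n))
  cat(sprintf("  achieved power %.3f (SE %.3f); %d candidates examined\n",
              x$power, x$se, nrow(x$trace)))
  invisible(x)
}

#' Power-analysis table across polygenicity conditions
#'
#' For each condition (`n_snps`, effect `1/sqrt(n_snps)`), finds the
#' sample size giving the target power for the main effect and for the
#' interaction, and evaluates the companion power at each (interaction
#' power at the main-effect n, and main-effect power at the interaction
#' n). The 100- and 1000-SNP conditions need sample sizes in the tens to
#' hundreds of thousands and are gated behind `heavy = TRUE`.
#'
#' @param n_snps_grid polygenicity conditions.
#' @param heavy include conditions whose searches run at n > 1e4.
#' @inheritParams find_n_for_power
#' @return data.frame with one row per condition: `n_snps`, `effect`,
#'   `n_80_main`, `power_int_at_main_n`, `n_80_int`, `power_main_at_int_n`.
#' @export
power_table <- function(n_snps_grid = c(1, 10, 100, 1000), heavy = FALSE,
                        target_power = 0.8, alpha = 5e-8, reps = 2000) {
  if (!heavy) {
    keep <- vapply(n_snps_grid, function(k)
      power_analytic(10000, 1 / sqrt(k), k, alpha)[["int"]] >= target_power,
      logical(1))
    n_snps_grid <- n_snps_grid[keep]
  }
  rows <- lapply(n_snps_grid, function(k) {
    eff <- 1 / sqrt(k)
    sm <- find_n_for_power("main", target_power, eff, k, alpha, reps)
    si <- find_n_for_power("int", target_power, eff, k, alpha, reps)
    at_m <- power_moderated(sm$n, eff, k, alpha, reps)
    at_i <- power_moderated(si$n, eff, k, alpha, reps)
    data.frame(n_snps = k, effect = eff,
               n_80_main = sm$n, power_int_at_main_n = at_m$power_int,
               n_80_int = si$n, power_main_at_int_n = at_i$power_main)
  })
  do.call(rbind, rows)
}
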