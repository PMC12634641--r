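# Moderated ACE twin model (van der Sluis specification), fit by
# full-information maximum likelihood with each twin's moderator entering
# the expected moments as a definition variable.

.ace_par_names <- c("a", "c", "e", "beta_a", "beta_c", "beta_e",
                    "mu", "beta_m_own", "beta_m_cotwin")

#' Expected moments of a twin pair under the moderated ACE model
#'
#' Each path coefficient is a linear function of the observed moderator:
#' the additive-genetic, shared-environment and unique-environment standard
#' deviations for twin i are `a + beta_a * m_i`, `c + beta_c * m_i` and
#' `e + beta_e * m_i`. Variances are their squares; the cross-twin
#' covariance is `R * (a + beta_a m1)(a + beta_a m2) + (c + beta_c m1)(c +
#' beta_c m2)` with genetic relatedness `R = 1` (MZ) or `0.5` (DZ). The
#' means model regresses each twin's phenotype on their own and their
#' co-twin's moderator, which buffers the moderation parameters against
#' gene-environment correlation.
#'
#' @param params named vector or list with elements `a`, `c`, `e`,
#'   `beta_a`, `beta_c`, `beta_e`, `mu`, `beta_m_own`, `beta_m_cotwin`
#'   (missing elements default to 0).
#' @param m1,m2 the two twins' moderator values.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return list with `mean` (length 2) and `cov` (2 x 2 matrix).
#' @export
expected_moments <- function(params, m1, m2, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  p <- .ace_fill(params)
  R <- if (zygosity == "MZ") 1 else 0.5
  pa <- p["a"] + p["beta_a"] * c(m1, m2)
  pc <- p["c"] + p["beta_c"] * c(m1, m2)
  pe <- p["e"] + p["beta_e"] * c(m1, m2)
  v <- pa^2 + pc^2 + pe^2
  cv <- R * pa[1] * pa[2] + pc[1] * pc[2]
  mu <- c(p["mu"] + p["beta_m_own"] * m1 + p["beta_m_cotwin"] * m2,
          p["mu"] + p["beta_m_own"] * m2 + p["beta_m_cotwin"] * m1)
  list(mean = unname(mu),
       cov = matrix(c(v[1], cv, cv, v[2]), 2, 2))
}

.ace_fill <- function(params) {
  p <- setNames(rep(0, length(.ace_par_names)), .ace_par_names)
  params <- unlist(params)
  p[intersect(names(params), .ace_par_names)] <-
    params[intersect(names(params), .ace_par_names)]
  p
}

#' Minus twice the log-likelihood of twin-pair data
#'
#' Sums the bivariate-normal -2 log density over pairs, with pair-specific
#' expected moments from [expected_moments()] (the moderators act as
#' definition variables). Parameter values yielding a non-positive-definite
#' pair covariance contribute a large finite penalty instead of an error,
#' so optimizers can recover.
#'
#' @param params named parameter vector (see [expected_moments()]).
#' @param pairs data.frame with columns `zygosity` ("MZ"/"DZ"), `m1`, `m2`,
#'   `y1`, `y2` (as produced by [twin_pairs()]).
#' @return scalar -2 log-likelihood.
#' @export
ace_neg2ll <- function(params, pairs) {
  if (nrow(pairs) == 0) stop("no twin pairs supplied")
  p <- .ace_fill(params)
  R <- ifelse(pairs$zygosity == "MZ", 1, 0.5)
  pa1 <- p["a"] + p["beta_a"] * pairs$m1
  pa2 <- p["a"] + p["beta_a"] * pairs$m2
  pc1 <- p["c"] + p["beta_c"] * pairs$m1
  pc2 <- p["c"] + p["beta_c"] * pairs$m2
  pe1 <- p["e"] + p["beta_e"] * pairs$m1
  pe2 <- p["e"] + p["beta_e"] * pairs$m2
  v1 <- pa1^2 + pc1^2 + pe1^2
  v2 <- pa2^2 + pc2^2 + pe2^2
  cv <- R * pa1 * pa2 + pc1 * pc2
  det <- v1 * v2 - cv^2
  if (any(!is.finite(det)) || any(det <= 1e-12) ||
      any(v1 <= 1e-12) || any(v2 <= 1e-12)) return(1e10)
  d1 <- pairs$y1 - (p["mu"] + p["beta_m_own"] * pairs$m1 +
                      p["beta_m_cotwin"] * pairs$m2)
  d2 <- pairs$y2 - (p["mu"] + p["beta_m_own"] * pairs$m2 +
                      p["beta_m_cotwin"] * pairs$m1)
  sum(2 * log(2 * pi) + log(det) +
        (v2 * d1^2 - 2 * cv * d1 * d2 + v1 * d2^2) / det)
}

#' Fit the moderated ACE twin model by maximum likelihood
#'
#' Quasi-Newton (BFGS) minimisation of [ace_neg2ll()] from data-informed
#' start values (`a = c = e = sqrt(var(y)/3)`, moderation at 0, means from
#' a moderator regression), with jittered restarts keeping the best
#' solution. Standard errors come from the numerical Hessian at the
#' optimum. Path signs are indeterminate (`(x, beta_x)` and
#' `(-x, -beta_x)` give the same likelihood), so fits are canonicalised to
#' a non-negative path at moderator 0; when a path is essentially 0, the
#' sign of its moderation coefficient is set by the value at moderator 1.
#'
#' @param pairs per-pair data.frame from [twin_pairs()] (columns
#'   `zygosity`, `m1`, `m2`, `y1`, `y2`).
#' @param moderated moderate the A, C, E paths? `FALSE` fixes `beta_a`,
#'   `beta_c`, `beta_e` at 0 (the classical ACE model).
#' @param means_moderators regress the phenotype means on own and co-twin
#'   moderators? `FALSE` fixes both means coefficients at 0.
#' @param components `"ace"` (default) or `"ae"` (drop the shared
#'   environment and its moderation).
#' @param restarts number of jittered restarts beyond the data-informed
#'   start.
#' @param control passed to [stats::optim()] (defaults: `maxit = 2000`,
#'   `reltol = 1e-10`).
#' @return An object of class `ace_gxe` with the estimated parameters,
#'   standard errors, `-2lnL`, convergence flag and pair counts. Methods:
#'   `print`, `summary`, `coef`, `logLik`, `vcov`, `plot`, `simulate`.
#'
#' The specification is the van der Sluis form of twin GxE modelling:
#' moderation on all three variance paths plus both twins' moderators in
#' the means model.
#' @export
#' @examples
#' d <- simulate_study(2, n_mz = 1500, n_dz = 1500, seed = 3)
#' fit <- ace_gxe(twin_pairs(d, n_pairs = 1500))
#' fit
#' variance_decomposition(fit, mod_grid = c(0, 1))
ace_gxe <- function(pairs, moderated = TRUE, means_moderators = TRUE,
                    components = c("ace", "ae"), restarts = 3,
                    control = list()) {
  components <- match.arg(components)
  need <- c("zygosity", "m1", "m2", "y1", "y2")
  if (!all(need %in% names(pairs))) stop("pairs must have columns ",
                                         paste(need, collapse = ", "))
  pairs <- pairs[complete.cases(pairs[, need]), ]
  n_mz <- sum(pairs$zygosity == "MZ")
  n_dz <- sum(pairs$zygosity == "DZ")
  if (n_mz < 2 || n_dz < 2) stop("need at least 2 MZ and 2 DZ pairs")

  free <- c(a = TRUE, c = components == "ace", e = TRUE,
            beta_a = moderated, beta_c = moderated && components == "ace",
            beta_e = moderated,
            mu = TRUE, beta_m_own = means_moderators,
            beta_m_cotwin = means_moderators)
  free <- free[.ace_par_names]

  y <- c(pairs$y1, pairs$y2)
  mown <- c(pairs$m1, pairs$m2)
  mco <- c(pairs$m2, pairs$m1)
  mfit <- stats::lm.fit(cbind(1, mown, mco), y)
  sd3 <- sqrt(max(var(mfit$residuals), 1e-4) / 3)
  base <- setNames(rep(0, 9), .ace_par_names)
  base[c("a", "c", "e")] <- sd3
  base["mu"] <- mfit$coefficients[1]
  if (means_moderators) {
    base["beta_m_own"] <- mfit$coefficients[2]
    base["beta_m_cotwin"] <- mfit$coefficients[3]
  }
  if (components == "ae") base["c"] <- 0

  obj <- function(theta) {
    p <- base
    p[free] <- theta
    ace_neg2ll(p, pairs)
  }
  ctrl <- utils::modifyList(list(maxit = 2000, reltol = 1e-10), control)

  starts <- list(base[free])
  if (restarts > 0) {
    for (r in seq_len(restarts)) {
      jit <- base
      jit[c("a", "c", "e")] <- jit[c("a", "c", "e")] *
        runif(3, 0.5, 1.5)
      if (moderated)
        jit[c("beta_a", "beta_c", "beta_e")] <- rnorm(3, 0, 0.3 * sd3)
      starts[[r + 1]] <- jit[free]
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(optim(s, obj, method = "BFGS", control = ctrl),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("twin-model optimisation failed from all starts")

  params <- base
  params[free] <- best$par
  se <- setNames(rep(NA_real_, 9), .ace_par_names)
  H <- tryCatch(optimHess(best$par, obj), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se[free] <- ifelse(dv > 0, sqrt(dv), NA_real_)
    }
  }

  # canonicalise path signs
  for (comp in c("a", "c", "e")) {
    b <- paste0("beta_", comp)
    flip <- if (abs(params[comp]) > 1e-6) params[comp] < 0
            else (params[comp] + params[b]) < 0
    if (isTRUE(flip)) {
      params[comp] <- -params[comp]
      params[b] <- -params[b]
    }
  }

  structure(list(
    params = params, se = se, free = free,
    minus2lnL = best$value,
    converged = best$convergence == 0,
    n_mz = n_mz, n_dz = n_dz,
    moderated = moderated, means_moderators = means_moderators,
    components = components,
    data = pairs, call = match.call()
  ), class = "ace_gxe")
}

#' @export
print.ace_gxe <- function(x, digits = 4, ...) {
  cat("Moderated ACE twin model (FIML)\n")
  cat(sprintf("  %d MZ + %d DZ pairs; -2lnL = %.4f%s\n", x$n_mz, x$n_dz,
              x$minus2lnL, if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- x$params[x$free]
  cat("  free parameters:\n")
  print(round(est, digits))
  v0 <- unname(x$params["a"]^2 + x$params["c"]^2 + x$params["e"]^2)
  cat(sprintf("  standardized at moderator 0: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$params["a"]^2 / v0, x$params["c"]^2 / v0, x$params["e"]^2 / v0))
  invisible(x)
}

#' @export
coef.ace_gxe <- function(object, ...) object$params[object$free]

#' @export
logLik.ace_gxe <- function(object, ...) {
  structure(-object$minus2lnL / 2, df = sum(object$free),
            nobs = object$n_mz + object$n_dz, class = "logLik")
}

#' @export
vcov.ace_gxe <- function(object, ...) {
  nm <- names(object$params)[object$free]
  se <- object$se[object$free]
  V <- diag(se^2, nrow = length(se))
  dimnames(V) <- list(nm, nm)
  V
}

#' @export
summary.ace_gxe <- function(object, ...) {
  est <- object$params[object$free]
  se <- object$se[object$free]
  z <- est / se
  tab <- data.frame(estimate = est, se = se, z = z,
                    p = 2 * pnorm(-abs(z)))
  out <- list(table = tab, minus2lnL = object$minus2lnL,
              converged = object$converged,
              n_mz = object$n_mz, n_dz = object$n_dz,
              curves = variance_decomposition(object, mod_grid = c(0, 1)))
  class(out) <- "summary.ace_gxe"
  out
}

#' @export
print.summary.ace_gxe <- function(x, digits = 4, ...) {
  cat("Moderated ACE twin model (FIML)\n")
  cat(sprintf("  %d MZ + %d DZ pairs; -2lnL = %.4f%s\n", x$n_mz, x$n_dz,
              x$minus2lnL, if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$table, digits))
  cat("  variance components at moderator levels:\n")
  print(round(x$curves, digits), row.names = FALSE)
  invisible(x)
}

#' Variance-decomposition curves over a moderator grid
#'
#' Evaluates `Va(m) = (a + beta_a m)^2`, `Vc(m)`, `Ve(m)` and their sum
#' `Vt(m)` on a grid of moderator values — the moderation plot's backing
#' table.
#'
#' @param fit an [ace_gxe()] fit.
#' @param mod_grid moderator values at which to evaluate the components.
#' @return data.frame with columns `m`, `Va`, `Vc`, `Ve`, `Vt`.
#' @export
variance_decomposition <- function(fit, mod_grid = seq(0, 1, by = 0.1)) {
  p <- fit$params
  Va <- (p["a"] + p["beta_a"] * mod_grid)^2
  Vc <- (p["c"] + p["beta_c"] * mod_grid)^2
  Ve <- (p["e"] + p["beta_e"] * mod_grid)^2
  data.frame(m = mod_grid, Va = unname(Va), Vc = unname(Vc),
             Ve = unname(Ve), Vt = unname(Va + Vc + Ve))
}

#' @export
plot.ace_gxe <- function(x, mod_grid = seq(0, 1, length.out = 51), ...) {
  cur <- variance_decomposition(x, mod_grid)
  matplot(cur$m, cur[, c("Va", "Vc", "Ve", "Vt")], type = "l", lty = c(2, 2, 2, 1),
          lwd = 2, col = c("blue", "darkgreen", "red", "black"),
          xlab = "moderator", ylab = "variance", ...)
  legend("topleft", c("Va", "Vc", "Ve", "Vt"), lty = c(2, 2, 2, 1), lwd = 2,
         col = c("blue", "darkgreen", "red", "black"), bty = "n")
  invisible(cur)
}

#' Simulate twin pairs directly from moderated ACE parameters
#'
#' Draws phenotypes from the model's own generative form: shared and
#' unique standard-normal components scaled by the (moderated) path
#' coefficients, with additive-genetic components correlated 1 (MZ) or 0.5
#' (DZ) across co-twins. Useful as a fast generator for parameter-recovery
#' checks and as the engine behind [simulate.ace_gxe()].
#'
#' @param n_mz,n_dz pair counts.
#' @param params named parameter vector (see [expected_moments()]).
#' @param moderator_prevalence Bernoulli prevalence for the binary
#'   moderators drawn independently per twin.
#' @return pair data.frame in the [twin_pairs()] layout.
#' @export
simulate_twin_pairs <- function(n_mz, n_dz, params,
                                moderator_prevalence = 0.5) {
  p <- .ace_fill(params)
  gen <- function(n, zyg) {
    m1 <- rbinom(n, 1L, moderator_prevalence)
    m2 <- rbinom(n, 1L, moderator_prevalence)
    if (zyg == "MZ") {
      A1 <- A2 <- rnorm(n)
    } else {
      A0 <- rnorm(n)
      A1 <- (A0 + rnorm(n)) / sqrt(2)
      A2 <- (A0 + rnorm(n)) / sqrt(2)
    }
    C <- rnorm(n)
    y <- function(m, mo, A) {
      p["mu"] + p["beta_m_own"] * m + p["beta_m_cotwin"] * mo +
        (p["a"] + p["beta_a"] * m) * A +
        (p["c"] + p["beta_c"] * m) * C +
        (p["e"] + p["beta_e"] * m) * rnorm(n)
    }
    data.frame(pair_id = paste0(tolower(zyg), seq_len(n)), zygosity = zyg,
               m1 = m1, m2 = m2,
               y1 = y(m1, m2, A1), y2 = y(m2, m1, A2),
               stringsAsFactors = FALSE)
  }
  rbind(gen(n_mz, "MZ"), gen(n_dz, "DZ"))
}

#' @export
simulate.ace_gxe <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_twin_pairs(object$n_mz, object$n_dz, object$params))
  if (nsim == 1) out[[1]] else out
}

#' @importFrom stats simulate
NULL
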