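# End-to-end runners: simulate -> GWAS -> PRS -> twin model, plus the
# polygenicity/attenuation follow-up experiment.

.role_regressions <- function(data, study) {
  zyg_roles <- expand.grid(zyg = c("dz", "mz"),
                           role = c("twin1", "twin2", "mother", "father"),
                           stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(zyg_roles))) {
    z <- zyg_roles$zyg[i]; r <- zyg_roles$role[i]
    g <- data[[z]]$genotype[[r]]
    if (is.null(g)) next
    y <- data[[z]]$phenotype[[r]]
    is_twin <- r %in% c("twin1", "twin2")
    if (study == 1 || !is_twin) {
      f <- ols_wald(cbind(1, as.numeric(g[, 1])), y)
      rows[[paste(z, r)]] <- data.frame(
        zygosity = toupper(z), role = r,
        intercept = f$coef[1], beta_snp = f$coef[2], se_snp = f$se[2],
        beta_mod = NA_real_, beta_int = NA_real_,
        r2_full = f$r2, r2_mod0 = NA_real_, r2_mod1 = NA_real_)
    } else {
      m <- data[[z]]$moderator[[r]]
      f <- ols_wald(cbind(1, as.numeric(g[, 1]), m, as.numeric(g[, 1]) * m), y)
      s <- stratified_r2(y, g[, 1], m)
      rows[[paste(z, r)]] <- data.frame(
        zygosity = toupper(z), role = r,
        intercept = f$coef[1], beta_snp = f$coef[2], se_snp = f$se[2],
        beta_mod = f$coef[3], beta_int = f$coef[4],
        r2_full = s$overall, r2_mod0 = s$strata[1], r2_mod1 = s$strata[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Conventional single-score PRSxE uses the discovery main-effect weights:
# a moderator-naive scan's per-SNP estimate absorbs E[m] * beta3, which
# would leak interaction signal into the main-effect score and defeat the
# product-term test of aggregate moderation.
.prs_stage <- function(data, scan_mod, n_target) {
  if (data$mz$n < n_target)
    stop("not enough MZ families for the PRS target sample")
  i <- seq_len(n_target)
  g <- data$mz$genotype$twin1[i, , drop = FALSE]
  m <- data$mz$moderator$twin1[i]
  y <- data$mz$phenotype$twin1[i]
  scores <- list(main = build_prs(scan_mod, g, kind = "main"),
                 int = build_prs(scan_mod, g, m, kind = "int"),
                 stand = build_prs(scan_mod, g, kind = "stand"))
  list(scores = scores,
       fit_gxe = prsxe(y, scores, m, model = "gxe"),
       fit_standard = prsxe(y, scores, m, model = "standard"))
}

#' Run one simulation study end to end
#'
#' Executes the full pipeline for a study preset: data generation
#' ([simulate_study()]); moderated and standard scans of DZ twin 1 (the
#' discovery sample); PRSxE fits under both discovery models for the first
#' `n_target` MZ twin-1 individuals; and a twin-model fit on the first
#' `n_twin_pairs` pairs of each zygosity (classical ACE for the
#' no-interaction Study 1, moderated ACE otherwise). Single-SNP studies
#' additionally report the per-role regression tables.
#'
#' @param study integer 1-4.
#' @param seed master seed; every reported number is regenerable from it.
#' @param n_mz,n_dz family counts (see [simulate_study()] for defaults).
#' @param n_twin_pairs pairs per zygosity entering the twin model.
#' @param n_target MZ twin-1 individuals in the PRS target sample.
#' @param ... configuration overrides forwarded to [simulate_study()].
#' @return An object of class `study_report` holding the scan summaries,
#'   significance counts, per-role tables (single-SNP studies), both PRSxE
#'   fits, the twin fit with its variance curves, and the configuration.
#' @export
run_study <- function(study, seed = 1, n_mz = NULL, n_dz = NULL,
                      n_twin_pairs = 2000, n_target = 5000, ...) {
  data <- simulate_study(study, n_mz = n_mz, n_dz = n_dz, seed = seed, ...)
  y <- data$dz$phenotype$twin1
  g <- data$dz$genotype$twin1
  m <- data$dz$moderator$twin1
  scan_mod <- gwas_scan(y, g, m, model = "moderated")
  scan_std <- gwas_scan(y, g, m, model = "standard")
  counts <- count_significant(scan_mod)

  roles <- if (data$config$n_snps == 1L) .role_regressions(data, study) else NULL

  prs <- .prs_stage(data, scan_mod, n_target)

  pairs <- twin_pairs(data, n_pairs = n_twin_pairs)
  twin_fit <- if (study == 1)
    ace_gxe(pairs, moderated = FALSE, means_moderators = FALSE)
  else ace_gxe(pairs)
  curves <- variance_decomposition(twin_fit, mod_grid = seq(0, 1, 0.25))

  structure(list(
    study = study, seed = seed, config = data$config,
    effects = data$effects,
    scan_moderated = scan_mod, scan_standard = scan_std,
    counts = counts, role_regressions = roles,
    prs_gxe = prs$fit_gxe, prs_standard = prs$fit_standard,
    twin_fit = twin_fit, variance_curves = curves
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 3, ...) {
  cat(sprintf("Simulation study %d (seed %d): %d SNP(s), %s effects\n",
              x$study, x$seed, x$config$n_snps, x$config$effect_regime))
  if (!is.null(x$role_regressions)) {
    cat("\nPer-role phenotype-on-genotype regressions:\n")
    print(x$role_regressions, digits = digits, row.names = FALSE)
  } else {
    cat("\n"); print(x$counts)
  }
  cat("\nPRSxE, GxE-GWAS discovery:\n"); print(x$prs_gxe, digits = digits)
  cat("\nPRSxE, standard-GWAS discovery:\n"); print(x$prs_standard, digits = digits)
  cat("\nTwin model:\n"); print(x$twin_fit, digits = digits)
  cat("\nVariance decomposition:\n")
  print(round(x$variance_curves, digits), row.names = FALSE)
  invisible(x)
}

#' Polygenicity and discovery-power follow-up experiment
#'
#' Repeats the full pipeline across polygenicity conditions to trace how
#' discovery-sample noise attenuates PRSxE coefficients while the twin
#' model stays calibrated. Per replicate: a fresh fixed-regime simulation
#' (total main and interaction variance 1) with `n_discovery` DZ families,
#' moderated and standard scans of DZ twin 1, PRSxE fits on a fresh
#' `n_target` MZ target, and a moderated ACE fit on `n_twin_pairs` pairs
#' per zygosity. Replicates whose twin fit fails to converge are retained
#' and flagged.
#'
#' @param reps replicates per condition.
#' @param snp_grid polygenicity conditions.
#' @param n_discovery DZ families (discovery GWAS sample size).
#' @param n_mz MZ families (target + twin pairs are drawn from these).
#' @param n_twin_pairs,n_target analysis slice sizes.
#' @param seed master seed; each replicate derives its own stream.
#' @return An object of class `adhoc_result`: `estimates` (one row per
#'   replicate: twin `a` and `beta_a`, PRS coefficients from both models,
#'   convergence flag) and `summary` (condition-level means and SDs).
#' @export
run_adhoc <- function(reps = 100, snp_grid = c(1, 10, 100, 1000),
                      n_discovery = 20000, n_mz = 5000,
                      n_twin_pairs = 2000, n_target = 5000, seed = 1) {
  rows <- list()
  for (ci in seq_along(snp_grid)) {
    k <- snp_grid[ci]
    for (r in seq_len(reps)) {
      cfg <- sim_config(n_mz = n_mz, n_dz = n_discovery, n_snps = k,
                        effect_regime = "fixed",
                        seed = derive_seed(seed, ci * 100000L + r))
      data <- simulate_twin_data(cfg, keep = c("dz_twin1", "mz_twin1"))
      y <- data$dz$phenotype$twin1
      g <- data$dz$genotype$twin1
      m <- data$dz$moderator$twin1
      scan_mod <- gwas_scan(y, g, m, model = "moderated")
      prs <- .prs_stage(data, scan_mod, n_target)
      fitg <- coef(prs$fit_gxe); fits <- coef(prs$fit_standard)
      twin <- ace_gxe(twin_pairs(data, n_pairs = n_twin_pairs))
      rows[[length(rows) + 1]] <- data.frame(
        n_snps = k, rep = r,
        twin_a = unname(twin$params["a"]),
        twin_beta_a = unname(twin$params["beta_a"]),
        prs_main = unname(fitg["prs_main"]),
        prs_int = unname(fitg["prs_int"]),
        prs_stand = unname(fits["prs_stand"]),
        prs_stand_int = unname(fits["prs_stand:moderator"]),
        twin_converged = twin$converged)
    }
  }
  est <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(est, est$n_snps), function(d) {
    num <- d[, c("twin_a", "twin_beta_a", "prs_main", "prs_int",
                 "prs_stand", "prs_stand_int")]
    data.frame(n_snps = d$n_snps[1], reps = nrow(d),
               t(colMeans(num)),
               sd_prs_int = sd(num$prs_int),
               n_nonconverged = sum(!d$twin_converged))
  }))
  rownames(agg) <- NULL
  structure(list(estimates = est, summary = agg,
                 reps = reps, snp_grid = snp_grid,
                 n_discovery = n_discovery, seed = seed),
            class = "adhoc_result")
}

#' @export
print.adhoc_result <- function(x, digits = 3, ...) {
  cat(sprintf("Polygenicity experiment: %d replicate(s) per condition, discovery n = %d\n",
              x$reps, x$n_discovery))
  s <- x$summary
  s[-1] <- round(s[-1], digits)
  print(s, row.names = FALSE)
  invisible(x)
}
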