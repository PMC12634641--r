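#' Per-SNP association scan with and without moderation
#'
#' Fits an independent ordinary-least-squares regression per SNP. The
#' moderated scan uses `Y ~ 1 + G + m + G:m` and the standard scan drops the
#' interaction, `Y ~ 1 + G + m`. Significance comes from Wald z statistics
#' (`z = beta / se`) against the standard-normal reference. SNPs whose
#' design is rank deficient (monomorphic genotypes, or a constant moderator
#' stratum) are flagged with missing estimates rather than raising an
#' error, so genome-scale loops never abort.
#'
#' @param phenotype numeric outcome vector.
#' @param genotypes matrix of allele counts (individuals x SNPs); column
#'   names become SNP ids (generated when absent).
#' @param moderator environmental moderator vector.
#' @param model `"moderated"` (default) or `"standard"`.
#' @return An object of classes `gwas_scan` and `data.frame`, one row per
#'   SNP with estimate/SE/z/p columns for the intercept, SNP main effect,
#'   moderator and (moderated scan only) interaction, plus a logical
#'   `degenerate` flag. Attributes: `scan` (model kind) and `n`.
#' @seealso [count_significant()], [stratified_r2()], [build_prs()]
#' @export
#' @examples
#' d <- simulate_study(2, n_mz = 200, n_dz = 2000, seed = 1)
#' s <- gwas_scan(d$dz$phenotype$twin1, d$dz$genotype$twin1,
#'                d$dz$moderator$twin1)
#' s
gwas_scan <- function(phenotype, genotypes, moderator,
                      model = c("moderated", "standard")) {
  model <- match.arg(model)
  genotypes <- as.matrix(genotypes)
  n <- length(phenotype)
  if (nrow(genotypes) != n || length(moderator) != n)
    stop("phenotype, genotypes and moderator must have matching lengths")
  k <- ncol(genotypes)
  snp_id <- colnames(genotypes)
  if (is.null(snp_id)) snp_id <- sprintf("snp%04d", seq_len(k))

  p_design <- if (model == "moderated") 4L else 3L
  est <- matrix(NA_real_, k, 4 * p_design)
  y <- as.numeric(phenotype)
  m <- as.numeric(moderator)
  ones <- rep(1, n)
  for (j in seq_len(k)) {
    g <- as.numeric(genotypes[, j])
    X <- if (model == "moderated") cbind(ones, g, m, g * m)
         else cbind(ones, g, m)
    fit <- ols_wald(X, y)
    if (!is.null(fit))
      est[j, ] <- c(fit$coef, fit$se, fit$z, fit$p)
  }
  idx <- function(block, i) (block - 1L) * p_design + i
  out <- data.frame(
    snp_id = snp_id,
    beta0 = est[, idx(1, 1)], se0 = est[, idx(2, 1)],
    beta_main = est[, idx(1, 2)], se_main = est[, idx(2, 2)],
    z_main = est[, idx(3, 2)], p_main = est[, idx(4, 2)],
    beta_mod = est[, idx(1, 3)], se_mod = est[, idx(2, 3)],
    z_mod = est[, idx(3, 3)], p_mod = est[, idx(4, 3)],
    stringsAsFactors = FALSE)
  if (model == "moderated") {
    out$beta_int <- est[, idx(1, 4)]; out$se_int <- est[, idx(2, 4)]
    out$z_int <- est[, idx(3, 4)]; out$p_int <- est[, idx(4, 4)]
  } else {
    out$beta_int <- out$se_int <- out$z_int <- out$p_int <- NA_real_
  }
  out$n <- n
  out$degenerate <- is.na(out$beta_main)
  structure(out, scan = model, n = n,
            class = c("gwas_scan", "data.frame"))
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("GxE GWAS scan (%s model): %d SNP(s), n = %d\n",
              attr(x, "scan"), nrow(x), attr(x, "n")))
  if (any(x$degenerate))
    cat(sprintf("  %d degenerate SNP row(s) flagged\n", sum(x$degenerate)))
  print.data.frame(head(as.data.frame(x), 10), digits = 4, row.names = FALSE)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' @export
summary.gwas_scan <- function(object, alpha_gw = 5e-8, ...) {
  cs <- count_significant(object, alpha_gw = alpha_gw)
  cat(sprintf("Scan (%s) of %d SNP(s) at n = %d\n", attr(object, "scan"),
              nrow(object), attr(object, "n")))
  print(cs)
  invisible(cs)
}

#' Count significant SNPs at genome-wide and Bonferroni thresholds
#'
#' Tallies main-effect and interaction p-values below the conventional
#' genome-wide threshold (5e-8) and below a Bonferroni correction
#' (`0.05 / n_snps`). Bonferroni counts are reported both cumulatively and
#' as the "additional" hits lying between the two thresholds.
#'
#' @param scan a [gwas_scan()] result.
#' @param alpha_gw genome-wide significance threshold.
#' @param n_snps number of tests for the Bonferroni correction; defaults to
#'   the number of scan rows.
#' @return An object of class `significance_counts`.
#' @export
count_significant <- function(scan, alpha_gw = 5e-8, n_snps = nrow(scan)) {
  alpha_bonf <- 0.05 / n_snps
  cnt <- function(p, a) sum(p < a, na.rm = TRUE)
  structure(list(
    n_main_genomewide = cnt(scan$p_main, alpha_gw),
    n_int_genomewide = cnt(scan$p_int, alpha_gw),
    n_main_bonferroni = cnt(scan$p_main, alpha_bonf),
    n_int_bonferroni = cnt(scan$p_int, alpha_bonf),
    additional_main = cnt(scan$p_main, alpha_bonf) - cnt(scan$p_main, alpha_gw),
    additional_int = cnt(scan$p_int, alpha_bonf) - cnt(scan$p_int, alpha_gw),
    alpha_gw = alpha_gw, alpha_bonf = alpha_bonf, n_snps = n_snps
  ), class = "significance_counts")
}

#' @export
print.significance_counts <- function(x, ...) {
  cat(sprintf("Significant SNPs at p < %.3g (genome-wide): %d main, %d interaction\n",
              x$alpha_gw, x$n_main_genomewide, x$n_int_genomewide))
  cat(sprintf("Significant SNPs at p < %.3g (Bonferroni):  %d main (+%d), %d interaction (+%d)\n",
              x$alpha_bonf, x$n_main_bonferroni, x$additional_main,
              x$n_int_bonferroni, x$additional_int))
  invisible(x)
}

#' Overall and moderator-stratified variance explained
#'
#' For a binary moderator, reports the r-squared of the full moderated model
#' alongside the r-squared of a phenotype-on-genotype regression fitted
#' separately within each moderator stratum. In a moderated system these
#' three numbers need not agree: the full-model value is a mixture that
#' matches neither stratum.
#'
#' @param phenotype outcome vector.
#' @param genotype a single SNP's allele counts (or any genetic score).
#' @param moderator binary moderator vector.
#' @return list with `overall` (full moderated model r2) and `strata`, a
#'   named vector of per-stratum r2 (NA for strata with < 3 observations).
#' @export
stratified_r2 <- function(phenotype, genotype, moderator) {
  lev <- sort(unique(moderator))
  if (length(lev) != 2)
    stop("stratified_r2 expects a binary moderator")
  g <- as.numeric(genotype)
  full <- ols_wald(cbind(1, g, moderator, g * moderator), phenotype)
  strata <- vapply(lev, function(l) {
    i <- moderator == l
    if (sum(i) < 3) return(NA_real_)
    f <- ols_wald(cbind(1, g[i]), phenotype[i])
    if (is.null(f)) NA_real_ else f$r2
  }, numeric(1))
  names(strata) <- paste0("mod=", lev)
  list(overall = if (is.null(full)) NA_real_ else full$r2, strata = strata)
}
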