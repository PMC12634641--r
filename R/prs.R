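#' Build polygenic scores from discovery summary statistics
#'
#' Three score kinds mirror the three sets of discovery weights:
#' * `"main"` — weighted allele-count sum using the moderated scan's
#'   main-effect estimates, `PRS_main[i] = sum_j b1_j G[i, j]`;
#' * `"int"` — the moderated scan's interaction estimates, with the target
#'   individual's moderator multiplying the weighted sum,
#'   `PRS_int[i] = m[i] * sum_j b3_j G[i, j]`, so the score itself is the
#'   interaction variable;
#' * `"stand"` — a conventional single score from main-effect estimates,
#'   used together with an explicit product term at fit time.
#'
#' All SNPs enter with their raw OLS weights; the simulated SNPs are
#' independent, so no clumping or shrinkage is applied. An optional
#' p-value threshold is available but defaults to 1 (keep everything).
#'
#' `"main"` and `"stand"` both read the `beta_main` column and differ only
#' in intent; `"stand"` accepts either scan kind. Beware that a truly
#' moderator-naive discovery scan estimates `beta1 + E[m] * beta3` per SNP
#' (the omitted interaction projects onto the genotype), so scores built
#' from such weights carry a share of the interaction signal into the
#' main-effect term; the study runners therefore use the moderated scan's
#' main-effect weights for the conventional score, which keeps the product
#' term a clean test of aggregate moderation.
#'
#' @param sumstats a [gwas_scan()] result (or data.frame with its columns)
#'   from the discovery sample.
#' @param genotypes target-sample allele-count matrix; column names must
#'   match `sumstats$snp_id` exactly and in order.
#' @param moderator target-sample moderator (required for `kind = "int"`).
#' @param kind which score to build.
#' @param p_threshold keep SNPs with discovery p below this value (applied
#'   to the p-value of the weight's own coefficient).
#' @return An object of class `prs_vector`: numeric score per target
#'   individual with attributes `kind`, `n_snps_used` and `degenerate`
#'   (constant-score flag).
#' @export
build_prs <- function(sumstats, genotypes, moderator = NULL,
                      kind = c("main", "int", "stand"), p_threshold = 1) {
  kind <- match.arg(kind)
  genotypes <- as.matrix(genotypes)
  ids_g <- colnames(genotypes)
  if (!is.null(ids_g) && !identical(as.character(sumstats$snp_id), ids_g)) {
    bad <- union(setdiff(sumstats$snp_id, ids_g), setdiff(ids_g, sumstats$snp_id))
    if (length(bad) == 0) bad <- "(same ids, different order)"
    stop("discovery and target SNP sets are not aligned: ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (nrow(sumstats) != ncol(genotypes))
    stop("summary statistics rows do not match target genotype columns")
  scan_kind <- attr(sumstats, "scan")
  if (kind == "int") {
    if (is.null(moderator)) stop("kind = 'int' requires the target moderator")
    if (!is.null(scan_kind) && scan_kind != "moderated")
      stop("interaction scores need moderated-scan summary statistics")
  }
  w <- if (kind == "int") sumstats$beta_int else sumstats$beta_main
  pv <- if (kind == "int") sumstats$p_int else sumstats$p_main
  use <- !is.na(w) & (is.na(pv) | pv <= p_threshold)
  w[!use] <- 0
  score <- drop(genotypes %*% w)
  if (kind == "int") score <- as.numeric(moderator) * score
  structure(score,
            kind = kind, n_snps_used = sum(use),
            degenerate = sd(score) < .Machine$double.eps^0.5,
            class = "prs_vector")
}

#' @export
print.prs_vector <- function(x, ...) {
  cat(sprintf("Polygenic score (%s) for %d individuals, %d SNP(s) used\n",
              attr(x, "kind"), length(x), attr(x, "n_snps_used")))
  if (isTRUE(attr(x, "degenerate")))
    cat("  flagged degenerate: score is constant\n")
  print(summary(as.numeric(x)))
  invisible(x)
}

#' Fit a polygenic-score-by-environment regression in the target sample
#'
#' Two model kinds, matching the two discovery routes:
#' * `"gxe"` — `Y ~ 1 + PRS_main + m + PRS_int`, where `PRS_int` already
#'   carries the moderator (built by [build_prs()] with `kind = "int"`), so
#'   its coefficient is the aggregate interaction effect;
#' * `"standard"` — `Y ~ 1 + PRS_stand + m + PRS_stand:m`, the conventional
#'   PRSxE product-term model using standard-scan weights.
#'
#' @param phenotype target outcome vector.
#' @param scores for `"gxe"`, a list with components `main` and `int`; for
#'   `"standard"`, a list with component `stand` (or a bare numeric score).
#' @param moderator target moderator vector.
#' @param model model kind.
#' @return An object of class `prsxe`: coefficient table (estimate, se,
#'   Wald z, p), `r2`, `n`, `model` and a `degenerate` flag for collinear
#'   designs.
#' @export
#' @examples
#' d <- simulate_study(2, n_mz = 3000, n_dz = 20000, seed = 2)
#' sums <- gwas_scan(d$dz$phenotype$twin1, d$dz$genotype$twin1,
#'                   d$dz$moderator$twin1)
#' tg <- d$mz$genotype$twin1[1:2000, , drop = FALSE]
#' tm <- d$mz$moderator$twin1[1:2000]
#' sc <- list(main = build_prs(sums, tg, kind = "main"),
#'            int  = build_prs(sums, tg, tm, kind = "int"))
#' prsxe(d$mz$phenotype$twin1[1:2000], sc, tm, model = "gxe")
prsxe <- function(phenotype, scores, moderator,
                  model = c("gxe", "standard")) {
  model <- match.arg(model)
  m <- as.numeric(moderator)
  if (model == "gxe") {
    if (!all(c("main", "int") %in% names(scores)))
      stop("model = 'gxe' needs scores$main and scores$int")
    X <- cbind(1, as.numeric(scores$main), m, as.numeric(scores$int))
    terms <- c("(Intercept)", "prs_main", "moderator", "prs_int")
  } else {
    s <- if (is.list(scores)) scores$stand else scores
    if (is.null(s)) stop("model = 'standard' needs scores$stand")
    s <- as.numeric(s)
    X <- cbind(1, s, m, s * m)
    terms <- c("(Intercept)", "prs_stand", "moderator", "prs_stand:moderator")
  }
  fit <- ols_wald(X, as.numeric(phenotype))
  if (is.null(fit)) {
    tab <- data.frame(term = terms, estimate = NA_real_, se = NA_real_,
                      z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    out <- list(coefficients = tab, r2 = NA_real_, n = length(phenotype),
                model = model, degenerate = TRUE)
  } else {
    tab <- data.frame(term = terms, estimate = fit$coef, se = fit$se,
                      z = fit$z, p = fit$p, stringsAsFactors = FALSE)
    out <- list(coefficients = tab, r2 = fit$r2, n = length(phenotype),
                model = model, degenerate = FALSE)
  }
  class(out) <- "prsxe"
  out
}

#' @export
print.prsxe <- function(x, digits = 4, ...) {
  cat(sprintf("PRSxE regression (%s discovery model), n = %d\n",
              if (x$model == "gxe") "GxE GWAS" else "standard GWAS", x$n))
  if (x$degenerate) {
    cat("  flagged degenerate: collinear design, no estimates\n")
    return(invisible(x))
  }
  print(x$coefficients, digits = digits, row.names = FALSE)
  cat(sprintf("r-squared: %.4f\n", x$r2))
  invisible(x)
}

#' @export
coef.prsxe <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.prsxe <- function(object, ...) {
  print(object)
  invisible(object$coefficients)
}
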