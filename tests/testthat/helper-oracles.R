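# Independent oracles, deliberately written with different machinery than
# the package internals (explicit normal equations via solve(); explicit
# bivariate-normal density via matrix inversion per pair).

oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- drop(solve(XtX, t(X) %*% y))
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(sigma2 * solve(XtX)))
  list(coef = unname(beta), se = unname(se))
}

# -2 log-likelihood of twin pairs by direct per-pair density evaluation
oracle_neg2ll <- function(params, pairs) {
  tot <- 0
  for (i in seq_len(nrow(pairs))) {
    mom <- expected_moments(params, pairs$m1[i], pairs$m2[i],
                            zygosity = pairs$zygosity[i])
    d <- c(pairs$y1[i], pairs$y2[i]) - mom$mean
    q <- drop(t(d) %*% solve(mom$cov) %*% d)
    tot <- tot + 2 * log(2 * pi) + log(det(mom$cov)) + q
  }
  tot
}

# fake summary-statistics table with chosen weights, in gwas_scan layout
fake_sumstats <- function(beta_main, beta_int = rep(NA_real_, length(beta_main)),
                          scan = "moderated") {
  k <- length(beta_main)
  d <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(k)),
    beta0 = 0, se0 = 1,
    beta_main = beta_main, se_main = 1, z_main = beta_main,
    p_main = 2 * pnorm(-abs(beta_main)),
    beta_mod = 0, se_mod = 1, z_mod = 0, p_mod = 1,
    beta_int = beta_int, se_int = 1, z_int = beta_int,
    p_int = ifelse(is.na(beta_int), NA, 2 * pnorm(-abs(beta_int))),
    n = 1000L, degenerate = FALSE,
    stringsAsFactors = FALSE)
  structure(d, scan = scan, n = 1000L, class = c("gwas_scan", "data.frame"))
}
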