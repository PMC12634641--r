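# Shared ordinary-least-squares workhorse for the scan and PRS modules.
#
# Returns NULL for rank-deficient designs (e.g. a monomorphic SNP crossed
# with a binary moderator) so genome-scale loops can flag the row and move
# on instead of aborting. Wald z uses the standard-normal reference: at the
# sample sizes this package targets (n >= 1e4) the difference from t is
# negligible, and it matches the field convention z = beta / se.
ols_wald <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  d <- diag(R)
  if (min(d) < 1e-7 * max(d)) return(NULL)
  Xty <- crossprod(X, y)
  beta <- drop(backsolve(R, forwardsolve(t(R), Xty)))
  res <- y - drop(X %*% beta)
  sse <- sum(res * res)
  sigma2 <- sse / (n - p)
  XtXinv <- chol2inv(R)
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  z <- beta / se
  list(
    coef = beta, se = se, z = z,
    p = 2 * pnorm(-abs(z)),
    sigma2 = sigma2, sse = sse, df = n - p,
    r2 = {
      tss <- sum((y - mean(y))^2)
      if (tss > 0) 1 - sse / tss else NA_real_
    }
  )
}
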