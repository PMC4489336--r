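# Null phenotype model shared by all tests: y = X beta + e with X an
# intercept (optionally plus covariates), e ~ N(0, sigma^2 I).  Everything
# downstream needs only the projection P = I - H onto the residual space,
# the residuals, and sigma^2.

#' Fit the null model for association testing
#'
#' @param y numeric phenotype vector.
#' @param covariates optional numeric matrix of covariates (an intercept is
#'   always included; do not add a constant column).
#' @return object of class `null_model`: list with `residuals`, `sigma2`
#'   (residual variance on `n - d` degrees of freedom), `df_resid`,
#'   `project` (function applying `P = I - H` to a vector or matrix), and
#'   `design_rank`.
#' @export
fit_null_model <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop_winsig("need at least 3 observations", "winsig_bad_argument")
  X <- cbind(intercept = rep(1, n), covariates)
  qrX <- qr(X)
  d <- qrX$rank
  project <- function(v) {
    v <- as.matrix(v)
    v - qr.fitted(qrX, v)
  }
  e <- drop(project(y))
  structure(list(residuals = e,
                 sigma2 = sum(e^2) / (n - d),
                 df_resid = n - d,
                 project = project,
                 design_rank = d,
                 n = n),
            class = "null_model")
}
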