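#' Linear regression with heteroscedasticity-consistent standard errors
#'
#' Ordinary least squares coefficients with sandwich (White-type) standard
#' errors.  Affective-rating regressions on form variables routinely show
#' skewness, outliers and heteroscedasticity, so Wald inference uses an HC
#' covariance estimator rather than the classical one.  Flavors: HC0 (raw
#' squared residuals), HC1 (df-scaled), HC2 (leverage-corrected, default),
#' HC3 (jackknife-like).
#'
#' @param X Numeric predictor matrix (no intercept column; one is prepended).
#' @param y Numeric response.
#' @param hc_flavor One of `"HC0"`, `"HC1"`, `"HC2"`, `"HC3"`.
#' @return Object of class `robust_fit` with elements `terms`, `beta`,
#'   `robust_se`, `t`, `p` (two-sided, `n - p - 1` df), `r2`, `adjusted_r2`,
#'   `vcov`, `fitted`, `residuals`, `hc_flavor`, `n`, `df`.
#' @examples
#' set.seed(1)
#' x <- rnorm(100); y <- 1 + 2 * x + rnorm(100, sd = abs(x))
#' fit_robust(cbind(x = x), y, "HC2")
#' @export
fit_robust <- function(X, y, hc_flavor = c("HC2", "HC0", "HC1", "HC3")) {
  hc_flavor <- match.arg(hc_flavor)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  Xa <- cbind(`(Intercept)` = 1, X)
  k <- ncol(Xa)
  if (n <= k) stop("n must exceed the number of coefficients")
  qx <- qr(Xa)
  if (qx$rank < k) stop("rank-deficient design matrix")
  beta <- qr.coef(qx, y)
  fitted <- drop(Xa %*% beta)
  e <- y - fitted
  XtXinv <- chol2inv(qr.R(qx))
  h <- rowSums((Xa %*% XtXinv) * Xa)
  h <- pmin(h, 1 - 1e-12)
  omega <- switch(hc_flavor,
                  HC0 = e^2,
                  HC1 = e^2 * n / (n - k),
                  HC2 = e^2 / (1 - h),
                  HC3 = e^2 / (1 - h)^2)
  meat <- crossprod(Xa, Xa * omega)
  vc <- XtXinv %*% meat %*% XtXinv
  dimnames(vc) <- list(colnames(Xa), colnames(Xa))
  se <- sqrt(pmax(diag(vc), 0))
  tval <- ifelse(se > 0, beta / se, NA_real_)
  df <- n - k
  pval <- 2 * pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  rss <- sum(e^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj <- 1 - (1 - r2) * (n - 1) / (n - k)
  structure(list(terms = colnames(Xa), beta = beta, robust_se = se, t = tval,
                 p = pval, r2 = r2, adjusted_r2 = adj, vcov = vc,
                 fitted = fitted, residuals = e, hc_flavor = hc_flavor,
                 n = n, df = df),
            class = "robust_fit")
}

#' Coefficient table of a robust fit
#'
#' @param fit A [robust_fit][fit_robust].
#' @return Data frame with columns `term`, `estimate`, `std_error`, `t`, `p`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "robust_fit"))
  data.frame(term = fit$terms, estimate = unname(fit$beta),
             std_error = unname(fit$robust_se), t = unname(fit$t),
             p = unname(fit$p), row.names = NULL)
}

#' Predict from a robust fit
#' @param object A [robust_fit][fit_robust].
#' @param newdata Matrix (or data frame) containing the fit's predictor
#'   columns by name.
#' @param ... Unused.
#' @export
predict.robust_fit <- function(object, newdata, ...) {
  terms <- setdiff(object$terms, "(Intercept)")
  newdata <- as.matrix(as.data.frame(newdata)[, terms, drop = FALSE])
  drop(object$beta[1L] + newdata %*% object$beta[terms])
}

#' @export
print.robust_fit <- function(x, ...) {
  tab <- coef_table(x)
  stars <- cut(tab$p, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  cat("Linear regression with ", x$hc_flavor, " robust standard errors (n = ",
      x$n, ")\n", sep = "")
  out <- data.frame(term = tab$term,
                    estimate = sprintf("%.3f", tab$estimate),
                    std_error = sprintf("%.3f", tab$std_error),
                    t = paste0(sprintf("%.3f", tab$t), stars))
  print(out, row.names = FALSE, right = FALSE)
  cat(sprintf("Adjusted R^2 = %.4f\n", x$adjusted_r2))
  invisible(x)
}
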