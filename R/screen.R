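#' Screen predictors for zero variance and linear dependencies
#'
#' Drops constant columns, then walks the remaining columns in order and
#' removes any column that is (numerically) a linear combination of the
#' intercept and the columns already kept, so the retained design matrix has
#' full column rank with an intercept.  Earlier columns are preferred for
#' retention, which makes the screen deterministic for a fixed column order.
#' Indicator sets that sum to a constant (e.g. the three stress-position
#' indicators) lose exactly one member here.
#'
#' @param X Numeric matrix with named columns; no missing values.
#' @param tol Relative tolerance for declaring a residual norm zero.
#' @return List of class `screen_report`: `kept_columns`,
#'   `dropped_zero_variance`, `dropped_linear_combo` (all column names).
#' @export
screen_predictors <- function(X, tol = 1e-7) {
  if (anyNA(X)) stop("missing values in predictor matrix")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  rng <- apply(X, 2, function(c) diff(range(c)))
  zero_var <- colnames(X)[rng == 0]
  keep_idx <- which(rng > 0)

  Xc <- scale(X[, keep_idx, drop = FALSE], center = TRUE, scale = FALSE)
  kept <- integer(0)
  combo <- integer(0)
  Q <- NULL  # orthonormal basis of the kept, centred columns
  for (j in seq_along(keep_idx)) {
    v <- Xc[, j]
    nv <- sqrt(sum(v^2))
    r <- if (is.null(Q)) v else v - Q %*% crossprod(Q, v)
    if (sqrt(sum(r^2)) > tol * nv) {
      Q <- cbind(Q, r / sqrt(sum(r^2)))
      kept <- c(kept, keep_idx[j])
    } else {
      combo <- c(combo, keep_idx[j])
    }
  }
  if (!length(kept)) stop("all columns constant or collinear")
  structure(list(kept_columns = colnames(X)[kept],
                 dropped_zero_variance = zero_var,
                 dropped_linear_combo = colnames(X)[combo],
                 tol = tol),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Predictor screen: kept", length(x$kept_columns), "columns; dropped",
      length(x$dropped_zero_variance), "zero-variance,",
      length(x$dropped_linear_combo), "collinear\n")
  if (length(x$dropped_zero_variance))
    cat("  zero variance:", paste(x$dropped_zero_variance, collapse = ", "), "\n")
  if (length(x$dropped_linear_combo))
    cat("  linear combos:", paste(x$dropped_linear_combo, collapse = ", "), "\n")
  invisible(x)
}
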