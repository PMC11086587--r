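#' Best subset of predictors at each size
#'
#' For each subset size `k = 1..kmax`, finds the set of `k` predictor columns
#' minimising the residual sum of squares of the OLS fit (with intercept).
#' For `p <= exact_limit` the search is exact (full enumeration on the
#' sufficient statistics, in compiled code); beyond that a forward-selection /
#' sequential-replacement hybrid is used and the result is flagged as not
#' guaranteed exact.
#'
#' @param X Screened numeric predictor matrix (named columns, full rank).
#' @param y Numeric response.
#' @param kmax Largest subset size to search; default `min(ncol(X), 40)`.
#' @param exact_limit Largest `p` for which exhaustive enumeration is used.
#' @param mode `"auto"` (default: by `exact_limit`), `"exact"` or `"hybrid"`.
#' @return Object of class `subset_candidates`: a list with one element per
#'   size, each `list(size, cols, rss, exact)`; `cols` are column names.
#' @export
best_subsets <- function(X, y, kmax = min(ncol(X), 40L),
                         exact_limit = 16L, mode = c("auto", "exact", "hybrid")) {
  mode <- match.arg(mode)
  p <- ncol(X)
  n <- nrow(X)
  if (kmax < 1L) stop("kmax must be >= 1")
  if (kmax > p) stop("kmax exceeds the number of predictors")
  if (n <= kmax + 1L) stop("n too small for the requested kmax")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values")
  exact <- switch(mode, exact = TRUE, hybrid = FALSE, auto = p <= exact_limit)

  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  XtX <- crossprod(Xc)
  Xty <- drop(crossprod(Xc, yc))
  yty <- sum(yc^2)
  raw <- if (exact) best_subsets_exact_cpp(XtX, Xty, yty, kmax)
         else best_subsets_hybrid_cpp(XtX, Xty, yty, kmax)
  out <- lapply(seq_len(kmax), function(k) {
    list(size = k, cols = colnames(X)[raw[[k]]$cols],
         rss = raw[[k]]$rss, exact = exact)
  })
  structure(out, class = "subset_candidates")
}

#' @export
print.subset_candidates <- function(x, ...) {
  cat("Best subsets per size (", if (x[[1]]$exact) "exact" else "hybrid",
      " search):\n", sep = "")
  for (m in x)
    cat(sprintf("  k=%2d  rss=%.6g  [%s]\n", m$size, m$rss,
                paste(m$cols, collapse = ", ")))
  invisible(x)
}
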