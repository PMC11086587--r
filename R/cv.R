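#' Select the subset size by repeated k-fold cross-validation
#'
#' Scores candidate models by mean held-out root-mean-square error over
#' `folds x repeats` random fold assignments and returns the candidate with
#' the smallest mean RMSE; ties within `1e-12` go to the smaller model.
#' Folds are simple random partitions, re-randomised each repeat, without
#' stratification.
#'
#' Two evaluation modes are available.  The default, `reselect = TRUE`,
#' re-runs the best-subset search *inside every training fold* (at each
#' candidate size) and evaluates that fold-specific model on the held-out
#' fold, so the cross-validation honestly prices the whole selection
#' procedure and the tuned quantity is the subset *size*; the returned
#' `chosen` model is the full-data candidate of the winning size.  With
#' `reselect = FALSE` the candidate supports are held fixed and only their
#' coefficients are refit per training fold.  The fixed-support mode leaks
#' the full-data subset search into the held-out folds: under weak or null
#' signal its mean RMSE *decreases* with model size and large models win, so
#' it is kept only for comparison and diagnosis.
#'
#' @param X Numeric predictor matrix containing every candidate's columns.
#' @param y Numeric response.
#' @param candidates A [subset_candidates][best_subsets] object (or list of
#'   `list(size, cols)`), typically one best model per size.
#' @param folds Number of folds; default 10.
#' @param repeats Number of repeats with fresh random folds; default 200.
#' @param seed Integer seed making the fold stream reproducible.
#' @param reselect Re-run the subset search within each training fold
#'   (default `TRUE`); see Details.
#' @return Object of class `cv_selection`: `chosen` (the winning candidate),
#'   `cv_rmse_by_size` (data frame: size, mean, sd over the
#'   `folds * repeats` resamples), `folds`, `repeats`, `seed`, `reselect`.
#' @export
cv_select <- function(X, y, candidates, folds = 10L, repeats = 200L,
                      seed = NULL, reselect = TRUE) {
  if (!length(candidates)) stop("no candidate models")
  n <- nrow(X)
  if (n < 2L * folds) stop("need n >= 2*folds")
  if (!is.null(seed)) set.seed(as.integer(seed))

  cand_cols <- lapply(candidates, function(m) match(m$cols, colnames(X)))
  if (anyNA(unlist(cand_cols))) stop("candidate column missing from X")
  sizes <- vapply(candidates, function(m) as.integer(m$size), 1L)
  maxk <- max(sizes)
  if (floor(n - n / folds) <= maxk + 1L)
    stop("a training fold would have fewer rows than the largest candidate")

  if (reselect) {
    # the inner search needs every column; fixed supports only need theirs
    used <- seq_len(ncol(X))
  } else {
    used <- sort(unique(unlist(cand_cols)))
  }
  pos <- lapply(cand_cols, function(j) match(j, used))
  Xa <- cbind(`(Intercept)` = 1, X[, used, drop = FALSE])
  XtX_all <- crossprod(Xa)
  Xty_all <- drop(crossprod(Xa, y))
  yty_all <- sum(y^2)
  nc <- length(candidates)
  rmse <- matrix(NA_real_, nc, folds * repeats)

  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      test <- fold_id == f
      Xf <- Xa[test, , drop = FALSE]
      yf <- y[test]
      XtX_tr <- XtX_all - crossprod(Xf)
      Xty_tr <- Xty_all - drop(crossprod(Xf, yf))
      if (reselect) {
        # centred training-fold sufficient statistics for the inner search
        n_tr <- XtX_tr[1L, 1L]
        cs <- XtX_tr[1L, -1L]
        Sc <- XtX_tr[-1L, -1L] - tcrossprod(cs) / n_tr
        bc <- Xty_tr[-1L] - cs * (Xty_tr[1L] / n_tr)
        yc <- (yty_all - sum(yf^2)) - Xty_tr[1L]^2 / n_tr
        inner <- best_subsets_hybrid_cpp(Sc, bc, yc, maxk)
      }
      for (ci in seq_len(nc)) {
        jj <- if (reselect) c(1L, inner[[sizes[ci]]]$cols + 1L)
              else c(1L, pos[[ci]] + 1L)
        b <- tryCatch(solve(XtX_tr[jj, jj], Xty_tr[jj]),
                      error = function(e) NULL)
        if (is.null(b)) next
        pred <- drop(Xf[, jj, drop = FALSE] %*% b)
        rmse[ci, (r - 1L) * folds + f] <- sqrt(mean((yf - pred)^2))
      }
    }
  }

  means <- rowMeans(rmse, na.rm = TRUE)
  sds <- apply(rmse, 1, sd, na.rm = TRUE)
  # parsimony tie-break: smallest size within 1e-12 of the minimum mean RMSE
  ok <- which(means <= min(means, na.rm = TRUE) + 1e-12)
  chosen_idx <- ok[which.min(sizes[ok])]
  structure(list(chosen = candidates[[chosen_idx]],
                 cv_rmse_by_size = data.frame(size = sizes, mean_rmse = means,
                                              sd_rmse = sds),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = seed, reselect = reselect),
            class = "cv_selection")
}

#' @export
print.cv_selection <- function(x, ...) {
  cat("Repeated ", x$folds, "-fold CV (x", x$repeats, ", ",
      if (isTRUE(x$reselect)) "search re-run per fold"
      else "fixed candidate supports", "): chose size ",
      x$chosen$size, "\n", sep = "")
  cat("  terms:", paste(x$chosen$cols, collapse = ", "), "\n")
  best <- which.min(x$cv_rmse_by_size$mean_rmse)
  cat(sprintf("  mean RMSE %.5f (sd %.5f)\n",
              x$cv_rmse_by_size$mean_rmse[best], x$cv_rmse_by_size$sd_rmse[best]))
  invisible(x)
}
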