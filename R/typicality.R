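#' Per-word form-typicality scores
#'
#' Extracts the model's fitted (predicted) value for every word in the form
#' matrix and z-transforms the fitted values across words (sample SD, n - 1
#' denominator).  A positive score means the word's sound structure is typical
#' of words rated high on the modelled affective dimension; a negative score
#' means it is typical of the low end.  Scores depend on the fitted values
#' only, so they are invariant to any invertible rescaling of the predictors
#' (with refit).
#'
#' @param fit A [robust_fit][fit_robust] of an affective rating on form
#'   variables.
#' @param X Form matrix for the words to score; must contain the fit's
#'   predictor columns.
#' @return Data frame of class `typicality_scores` with columns `word`,
#'   `fitted` (raw predicted rating) and `typicality` (z-scored).
#' @export
typicality_scores <- function(fit, X) {
  pred <- predict(fit, X)
  s <- sd(pred)
  if (!is.finite(s) || s == 0) stop("zero variance in fitted values")
  structure(data.frame(word = if (!is.null(rownames(X))) rownames(X)
                              else as.character(seq_along(pred)),
                       fitted = unname(pred),
                       typicality = unname((pred - mean(pred)) / s),
                       row.names = NULL),
            class = c("typicality_scores", "data.frame"))
}

#' Fit the full form-typicality pipeline for one affective dimension
#'
#' Chains the three-step modelling procedure on an (already filtered)
#' lexicon: encode the words into form variables, screen out zero-variance
#' and collinear columns, find the best predictor subset at each size, pick
#' the size by repeated k-fold cross-validation (minimum mean held-out RMSE),
#' refit the chosen model on all words with HC-robust standard errors, and
#' z-score the fitted values into per-word typicality scores.
#'
#' @param lexicon Filtered lexicon data frame (see [read_lexicon()]); must
#'   contain `valence_mean`/`arousal_mean`, from which `emotionality` is
#'   derived when absent.
#' @param inv Phoneme inventory; default [load_inventory()].
#' @param dv Affective dimension: `"valence"`, `"emotionality"`, `"arousal"`.
#' @param folds,repeats Cross-validation plan; defaults 10 and 200.
#' @param kmax Largest subset size searched; default `min(p, 40)`.
#' @param exact_limit,voicing_vowels,hc_flavor See [best_subsets()],
#'   [form_variable_names()], [fit_robust()].
#' @param seed Seed for the CV fold stream.
#' @return Object of class `typicality_run`: `screen`, `candidates`,
#'   `selection`, `fit`, `scores`, `form_matrix`, `dv`, `manifest`.
#' @export
run_typicality <- function(lexicon, inv = load_inventory(),
                           dv = c("valence", "emotionality", "arousal"),
                           folds = 10L, repeats = 200L, kmax = NULL,
                           exact_limit = 16L, voicing_vowels = FALSE,
                           hc_flavor = "HC2", seed = 1L) {
  dv <- match.arg(dv)
  y <- switch(dv,
              valence = lexicon$valence_mean,
              arousal = lexicon$arousal_mean,
              emotionality = if (!is.null(lexicon$emotionality))
                lexicon$emotionality else derive_emotionality(lexicon$valence_mean))
  if (is.null(y)) stop("lexicon lacks the ratings needed for dv = ", dv)

  X <- encode_lexicon(lexicon, inv, voicing_vowels)
  screen <- screen_predictors(X)
  Xs <- X[, screen$kept_columns, drop = FALSE]
  if (is.null(kmax)) kmax <- min(ncol(Xs), 40L)
  candidates <- best_subsets(Xs, y, kmax = kmax, exact_limit = exact_limit)
  selection <- cv_select(Xs, y, candidates, folds = folds, repeats = repeats,
                         seed = seed)
  fit <- fit_robust(Xs[, selection$chosen$cols, drop = FALSE], y, hc_flavor)
  scores <- typicality_scores(fit, Xs)

  manifest <- list(
    dv = dv, seed = as.integer(seed),
    inventory = attr(inv, "id"),
    n_words = nrow(lexicon),
    n_form_variables = ncol(X),
    n_screened = ncol(Xs),
    kmax = kmax, folds = as.integer(folds), repeats = as.integer(repeats),
    exact_search = candidates[[1L]]$exact,
    chosen_size = selection$chosen$size,
    hc_flavor = hc_flavor,
    config_hash = config_hash(list(attr(inv, "id"), voicing_vowels, kmax,
                                   folds, repeats, hc_flavor, seed)),
    package_version = as.character(packageVersion("formtypic")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))

  structure(list(screen = screen, candidates = candidates,
                 selection = selection, fit = fit, scores = scores,
                 form_matrix = Xs, dv = dv, manifest = manifest),
            class = "typicality_run")
}

#' @export
print.typicality_run <- function(x, ...) {
  cat("Form-typicality model for", x$dv, "\n")
  cat("  ", x$manifest$n_words, " words, ", x$manifest$n_form_variables,
      " form variables (", x$manifest$n_screened, " after screening)\n",
      sep = "")
  print(x$selection)
  print(x$fit)
  invisible(x)
}

# Stable hash of a configuration list (no digest dependency: serialize to a
# temp file and md5sum it).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Most and least typical word forms
#'
#' @param scores A [typicality_scores] data frame.
#' @param n Number of words at each extreme; default 10.
#' @param value Which column to rank and report: z-scored `"typicality"`
#'   (default) or raw `"fitted"` values.
#' @return Data frame with columns `rank`, `most_word`, `most_value`,
#'   `least_word`, `least_value`.
#' @export
typicality_extremes <- function(scores, n = 10L,
                                value = c("typicality", "fitted")) {
  value <- match.arg(value)
  o <- order(scores[[value]], decreasing = TRUE)
  top <- scores[head(o, n), ]
  bot <- scores[tail(o, n), ]
  bot <- bot[order(bot[[value]]), ]
  data.frame(rank = seq_len(n),
             most_word = top$word, most_value = top[[value]],
             least_word = bot$word, least_value = bot[[value]])
}
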