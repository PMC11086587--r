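#' Derive emotionality from valence
#'
#' Emotionality is the absolute distance of a word's mean valence rating from
#' the 9-point scale midpoint: `|valence - 5|`, on \[0, 4\].  It measures
#' emotional load regardless of polarity.
#'
#' @param valence_mean Numeric vector of mean valence ratings on \[1, 9\].
#' @return Numeric vector of emotionality values.
#' @examples
#' derive_emotionality(c(1, 3, 5, 7, 9))  # 4 2 0 2 4
#' @export
derive_emotionality <- function(valence_mean) {
  if (any(is.na(valence_mean)))
    stop("missing valence values")
  if (any(valence_mean < 1 | valence_mean > 9))
    stop("valence out of the [1, 9] scale: ",
         paste(valence_mean[valence_mean < 1 | valence_mean > 9][1]))
  abs(valence_mean - 5)
}

#' Rating-agreement filter
#'
#' Keeps words whose raters showed reasonable agreement on both valence and
#' arousal: a word is kept iff `valence_sd < cutoff` and `arousal_sd < cutoff`
#' (strict inequality).  A between-rater SD at or above 1.5 on a 9-point scale
#' indicates that raters split between strong and negligible affective
#' responses, so such words add noise to affect analyses.
#'
#' @param lexicon Data frame with `valence_sd` and `arousal_sd` columns.
#' @param cutoff Agreement cutoff in rating-scale SD units; default 1.5.
#' @return List with `kept` and `removed` data frames; `removed` gains a
#'   `reason` column.
#' @export
agreement_filter <- function(lexicon, cutoff = 1.5) {
  for (col in c("valence_sd", "arousal_sd")) {
    if (is.null(lexicon[[col]])) stop("missing column: ", col)
    if (any(is.na(lexicon[[col]]))) stop("missing values in ", col)
    if (any(lexicon[[col]] < 0)) stop("negative values in ", col)
  }
  keep <- lexicon$valence_sd < cutoff & lexicon$arousal_sd < cutoff
  removed <- lexicon[!keep, , drop = FALSE]
  if (nrow(removed))
    removed$reason <- ifelse(removed$valence_sd >= cutoff,
                             "valence_sd >= cutoff", "arousal_sd >= cutoff")
  else removed$reason <- character(0)
  list(kept = lexicon[keep, , drop = FALSE], removed = removed)
}

#' Part-of-speech filter
#'
#' Removes closed-class and non-lexical items.  The default exclusion set
#' mirrors common practice in affective-norm studies: numbers, proper names,
#' adpositions, dates, determiners, interjections and pronouns.
#'
#' @param lexicon Data frame with a `pos` column.
#' @param excluded Character vector of POS labels to drop.
#' @param unknown How to treat POS labels outside both the excluded set and
#'   the open classes `noun`/`adjective`/`verb`/`adverb`: `"warn"` (keep with
#'   a warning, default) or `"error"`.
#' @return List with `kept` and `removed` data frames.
#' @export
pos_filter <- function(lexicon, excluded = .pos_default_excluded,
                       unknown = c("warn", "error")) {
  unknown <- match.arg(unknown)
  if (is.null(lexicon$pos)) stop("missing column: pos")
  known <- unique(c(excluded, .pos_default_excluded,
                    c("noun", "adjective", "verb", "adverb")))
  odd <- setdiff(unique(lexicon$pos), known)
  if (length(odd)) {
    msg <- paste("unknown POS label(s):", paste(odd, collapse = ", "))
    if (unknown == "error") stop(msg) else warning(msg)
  }
  keep <- !(lexicon$pos %in% excluded)
  removed <- lexicon[!keep, , drop = FALSE]
  removed$reason <- if (nrow(removed)) paste0("pos:", removed$pos) else character(0)
  list(kept = lexicon[keep, , drop = FALSE], removed = removed)
}

#' Remove prefixed words
#'
#' Drops words whose orthographic form begins with any listed prefix
#' (case-insensitive; the longest matching prefix is reported).  Derivational
#' prefixes, negating ones in particular, can flip a word's affective meaning
#' without changing most of its form, which dilutes form-affect associations.
#' The match is purely orthographic: pseudo-prefixed words (e.g. a word that
#' merely starts with "in") are false positives of this rule.
#'
#' @param lexicon Data frame with a `word` column.
#' @param prefixes Non-empty character vector of prefixes; a default Spanish
#'   list is used when omitted.
#' @return List with `kept` and `removed` data frames.
#' @export
strip_prefixed <- function(lexicon, prefixes = .prefixes_default) {
  if (!length(prefixes)) stop("empty prefix list")
  if (any(!nzchar(prefixes))) stop("empty prefix string")
  w <- tolower(as.character(lexicon$word))
  pfx <- tolower(prefixes)[order(-nchar(prefixes))]  # longest-match first
  hit <- rep(NA_character_, length(w))
  for (p in pfx) {
    m <- is.na(hit) & startsWith(w, p)
    hit[m] <- p
  }
  removed <- lexicon[!is.na(hit), , drop = FALSE]
  removed$reason <- if (nrow(removed))
    paste0("prefix:", hit[!is.na(hit)]) else character(0)
  list(kept = lexicon[is.na(hit), , drop = FALSE], removed = removed)
}

#' Run the full word-inclusion pipeline
#'
#' Chains the three inclusion stages in their canonical order — rating
#' agreement, POS exclusion, prefix removal — and records per-stage counts.
#' Also derives the `emotionality` column from `valence_mean` on the kept set.
#'
#' @inheritParams agreement_filter
#' @inheritParams pos_filter
#' @inheritParams strip_prefixed
#' @return List of class `filter_report`: `kept` (final data frame, with
#'   `emotionality`), `removed` (word + reason for every excluded row), and
#'   the counts `n_input`, `n_after_agreement`, `n_after_pos`,
#'   `n_after_prefix`.
#' @export
filter_lexicon <- function(lexicon, cutoff = 1.5,
                           excluded = .pos_default_excluded,
                           prefixes = .prefixes_default) {
  s1 <- agreement_filter(lexicon, cutoff)
  s2 <- pos_filter(s1$kept, excluded)
  s3 <- strip_prefixed(s2$kept, prefixes)
  removed <- rbind(s1$removed[, c("word", "reason")],
                   s2$removed[, c("word", "reason")],
                   s3$removed[, c("word", "reason")])
  kept <- s3$kept
  kept$emotionality <- derive_emotionality(kept$valence_mean)
  structure(list(kept = kept, removed = removed,
                 n_input = nrow(lexicon),
                 n_after_agreement = nrow(s1$kept),
                 n_after_pos = nrow(s2$kept),
                 n_after_prefix = nrow(s3$kept)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Word-inclusion pipeline:\n",
      "  input            ", x$n_input, "\n",
      "  after agreement  ", x$n_after_agreement, "\n",
      "  after POS        ", x$n_after_pos, "\n",
      "  after prefix     ", x$n_after_prefix, "\n", sep = "")
  invisible(x)
}

#' Serialize a filter report to JSON
#' @param report A `filter_report`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(n_input = report$n_input,
         n_after_agreement = report$n_after_agreement,
         n_after_pos = report$n_after_pos,
         n_after_prefix = report$n_after_prefix,
         removed = report$removed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
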