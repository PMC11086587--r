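#' Read a lexicon table
#'
#' Reads a UTF-8 CSV with the documented columns (`word`, `transcription`,
#' `stress_syllable`, `pos`, `valence_mean`, `valence_sd`, `arousal_mean`,
#' `arousal_sd`, plus optional covariate columns), validates every row, and
#' aggregates all row errors into one message.  Transcriptions are
#' whitespace-separated phoneme symbols with `.` between syllables; stress is
#' a 1-based syllable index.
#'
#' @param path CSV path.
#' @param inv Inventory used to validate transcriptions; `NULL` skips
#'   phoneme-level validation.
#' @param require_ratings If `FALSE`, rating columns may be absent.
#' @return Validated data frame.
#' @export
read_lexicon <- function(path, inv = load_inventory(), require_ratings = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("word", "transcription", "stress_syllable", "pos")
  if (require_ratings)
    required <- c(required, "valence_mean", "valence_sd",
                  "arousal_mean", "arousal_sd")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  errs <- character(0)
  for (i in seq_len(nrow(df))) {
    e <- tryCatch({
      tr <- parse_transcription(df$transcription[i])
      if (!is.null(inv) && !all(tr$phonemes %in% inv$symbol))
        stop("phoneme(s) not in inventory: ",
             paste(setdiff(tr$phonemes, inv$symbol), collapse = ", "))
      st <- df$stress_syllable[i]
      if (is.na(st) || st < 1 || st > tr$n_syllables)
        stop("stress_syllable out of range 1..", tr$n_syllables)
      NULL
    }, error = function(err) conditionMessage(err))
    if (!is.null(e)) errs <- c(errs, paste0("row ", i, " ('", df$word[i],
                                            "'): ", e))
  }
  if (require_ratings) {
    for (col in c("valence_mean", "arousal_mean")) {
      bad <- which(is.na(df[[col]]) | df[[col]] < 1 | df[[col]] > 9)
      if (length(bad))
        errs <- c(errs, paste0("row ", bad, ": ", col,
                               " out of the [1, 9] scale"))
    }
    for (col in c("valence_sd", "arousal_sd")) {
      bad <- which(is.na(df[[col]]) | df[[col]] < 0)
      if (length(bad))
        errs <- c(errs, paste0("row ", bad, ": ", col, " missing or negative"))
    }
  }
  if (length(errs))
    stop("invalid lexicon (", length(errs), " problem(s)):\n  ",
         paste(errs, collapse = "\n  "))
  df
}

#' Write a lexicon table
#' @param lexicon Data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  write.csv(lexicon, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a run manifest as JSON
#' @param manifest Named list (e.g. from a [run_typicality()] result).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
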