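#' Load a phoneme inventory
#'
#' Reads a phoneme inventory from a JSON configuration file and validates it.
#' Each entry carries a symbol plus an articulatory feature bundle: place,
#' manner and voicing for consonants; place, height and rounding for vowels
#' (vowels are uniformly voiced).  Numeric phoneme ids are assigned by listed
#' order (1-based), so id-based predictors such as the initial/final-phoneme
#' slopes are only comparable between runs that share a configuration.
#'
#' The packaged default, `es_castilian_31.json`, is a 31-phoneme Castilian
#' Spanish inventory (5 vowels, 26 consonants) in ASCII-safe symbols.
#'
#' @param config_path Path to a JSON inventory file, or `NULL` for the
#'   packaged Castilian default.
#' @return An object of class `phoneme_inventory`: a data frame with columns
#'   `symbol`, `class`, `place`, `manner`, `voicing`, `height`, `rounding`,
#'   `numeric_id`, plus an `id` attribute naming the configuration.
#' @examples
#' inv <- load_inventory()
#' nrow(inv)              # 31
#' inv[inv$symbol == "a", ]
#' @export
load_inventory <- function(config_path = NULL) {
  if (is.null(config_path)) {
    config_path <- system.file("extdata", "es_castilian_31.json",
                               package = "formtypic", mustWork = TRUE)
  }
  cfg <- jsonlite::fromJSON(config_path, simplifyDataFrame = TRUE)
  entries <- cfg$entries
  if (is.null(entries) || NROW(entries) == 0L)
    stop("inventory config has no entries: ", config_path)
  for (col in c("manner", "voicing", "height", "rounding"))
    if (is.null(entries[[col]])) entries[[col]] <- NA_character_
  entries <- entries[, c("symbol", "class", "place", "manner", "voicing",
                         "height", "rounding")]
  if (anyDuplicated(entries$symbol))
    stop("duplicate phoneme symbol(s): ",
         paste(unique(entries$symbol[duplicated(entries$symbol)]),
               collapse = ", "))
  if (!all(entries$class %in% c("vowel", "consonant")))
    stop("phoneme class must be 'vowel' or 'consonant'")

  is_v <- entries$class == "vowel"
  # vowels: place/height/rounding complete, no manner; voicing defaults voiced
  entries$voicing[is_v & is.na(entries$voicing)] <- "voiced"
  bad_v <- is_v & (is.na(entries$height) | is.na(entries$rounding) |
                     !is.na(entries$manner) |
                     !(entries$place %in% .places_v) |
                     entries$voicing != "voiced")
  if (any(bad_v))
    stop("invalid vowel entries (need place in front/central/back, height, ",
         "rounding, no manner, voiced): ",
         paste(entries$symbol[bad_v], collapse = ", "))
  bad_c <- !is_v & (is.na(entries$manner) | is.na(entries$voicing) |
                      !is.na(entries$height) | !is.na(entries$rounding) |
                      !(entries$place %in% .places_c))
  if (any(bad_c))
    stop("invalid consonant entries (need consonant place, manner, voicing, ",
         "no height/rounding): ", paste(entries$symbol[bad_c], collapse = ", "))
  if (!all(entries$manner[!is_v] %in% .manners))
    stop("unknown manner label(s): ",
         paste(setdiff(entries$manner[!is_v], .manners), collapse = ", "))
  if (!all(entries$voicing %in% .voicings))
    stop("unknown voicing label(s)")
  if (!all(entries$height[is_v] %in% .heights) ||
      !all(entries$rounding[is_v] %in% .roundings))
    stop("unknown vowel height/rounding label(s)")

  entries$numeric_id <- seq_len(nrow(entries))
  structure(entries,
            id = if (!is.null(cfg$id)) cfg$id else basename(config_path),
            class = c("phoneme_inventory", "data.frame"))
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat("Phoneme inventory '", attr(x, "id"), "': ", nrow(x), " phonemes (",
      sum(x$class == "vowel"), " vowels, ",
      sum(x$class == "consonant"), " consonants)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

# Parse a transcription string ("b a . l a") into phoneme symbols and the
# 1-based syllable index of each phoneme.  "." separates syllables.
parse_transcription <- function(transcription) {
  toks <- strsplit(trimws(transcription), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty transcription")
  syl <- cumsum(toks == ".") + 1L
  keep <- toks != "."
  if (!any(keep)) stop("transcription has no phonemes: ", transcription)
  list(phonemes = toks[keep], syllable = syl[keep],
       n_syllables = max(syl[keep]))
}
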