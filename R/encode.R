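#' Form-variable names
#'
#' The fixed roster of form variables produced by [encode_word()]: word-level
#' lengths, initial/final phoneme ids, overall counts of every articulatory
#' feature category, binary indicators of those categories at the initial and
#' final phoneme position, and the stress-position indicators.  The enumerated
#' roster has 83 named variables; its order is stable across calls.
#'
#' @param voicing_vowels If `TRUE`, vowels contribute to the voiced count and
#'   positional voicing indicators.  Defaults to `FALSE`: vowels are uniformly
#'   voiced, so counting them only adds a constant offset per vowel count.
#' @return Character vector of variable names, in matrix column order.
#' @export
form_variable_names <- function(voicing_vowels = FALSE) {
  cats <- c(.places_c, .manners, .voicings, .places_v, .heights, .roundings)
  c("length_letters", "n_phonemes", "n_syllables",
    "initial_phoneme_id", "final_phoneme_id",
    paste0("n_", cats), paste0("ini_", cats), paste0("fin_", cats),
    "stress_initial", "stress_medial", "stress_final")
}

# 0/1 feature indicator matrix, one row per inventory phoneme, one column per
# feature category (25 columns).  Row order = inventory order.
.feature_matrix <- function(inv, voicing_vowels = FALSE) {
  cats <- c(.places_c, .manners, .voicings, .places_v, .heights, .roundings)
  m <- matrix(0, nrow(inv), length(cats), dimnames = list(inv$symbol, cats))
  is_v <- inv$class == "vowel"
  m[cbind(which(!is_v), match(inv$place[!is_v], cats))] <- 1
  m[cbind(which(!is_v), match(inv$manner[!is_v], cats))] <- 1
  m[cbind(which(!is_v), match(inv$voicing[!is_v], cats))] <- 1
  m[cbind(which(is_v), match(inv$place[is_v], cats))] <- 1
  m[cbind(which(is_v), match(inv$height[is_v], cats))] <- 1
  m[cbind(which(is_v), match(inv$rounding[is_v], cats))] <- 1
  if (voicing_vowels)
    m[cbind(which(is_v), match(inv$voicing[is_v], cats))] <- 1
  m
}

#' Encode one word as a form-variable vector
#'
#' Turns a word's phonemic transcription, stress position and orthography into
#' the named numeric vector of form variables: number of letters, phonemes and
#' syllables; numeric ids of the initial and final phoneme; counts of each
#' place/manner/voicing category over consonants and each place/height/rounding
#' category over vowels; indicators of those categories at the initial and
#' final phoneme; and indicators of initial/medial/final primary stress.
#'
#' Letters are counted as given (accented characters count as one letter).
#' Monosyllables are coded as finally stressed, so the three stress indicators
#' always partition words.
#'
#' @param entry A list or one-row data frame with fields `word`,
#'   `transcription` (phonemes whitespace-separated, `.` between syllables)
#'   and `stress_syllable` (1-based syllable index).
#' @param inv A [phoneme inventory][load_inventory].
#' @param voicing_vowels See [form_variable_names()].
#' @return Named numeric vector of length 83.
#' @examples
#' inv <- load_inventory()
#' encode_word(list(word = "bala", transcription = "b a . l a",
#'                  stress_syllable = 1), inv)
#' @export
encode_word <- function(entry, inv, voicing_vowels = FALSE) {
  tr <- parse_transcription(entry$transcription)
  idx <- match(tr$phonemes, inv$symbol)
  if (anyNA(idx))
    stop("phoneme(s) not in inventory: ",
         paste(unique(tr$phonemes[is.na(idx)]), collapse = ", "),
         " (word '", entry$word, "')")
  stress <- as.integer(entry$stress_syllable)
  if (is.na(stress) || stress < 1L || stress > tr$n_syllables)
    stop("stress syllable ", entry$stress_syllable, " out of range 1..",
         tr$n_syllables, " (word '", entry$word, "')")
  fm <- .feature_matrix(inv, voicing_vowels)
  counts <- colSums(fm[idx, , drop = FALSE])
  v <- c(
    length_letters = nchar(as.character(entry$word)),
    n_phonemes = length(idx),
    n_syllables = tr$n_syllables,
    initial_phoneme_id = inv$numeric_id[idx[1L]],
    final_phoneme_id = inv$numeric_id[idx[length(idx)]],
    setNames(counts, paste0("n_", names(counts))),
    setNames(fm[idx[1L], ], paste0("ini_", colnames(fm))),
    setNames(fm[idx[length(idx)], ], paste0("fin_", colnames(fm))),
    stress_initial = 0, stress_medial = 0, stress_final = 0
  )
  # monosyllables count as final stress; the three indicators partition words
  pos <- if (stress == tr$n_syllables) "final"
         else if (stress == 1L) "initial" else "medial"
  v[paste0("stress_", pos)] <- 1
  v
}

#' Encode a lexicon into a form matrix
#'
#' Applies [encode_word()] to every row of a lexicon table.  Column order is
#' identical across calls with the same inventory and options.  Any invalid
#' entry aborts the whole encoding (no partial output).
#'
#' @param lexicon Data frame with columns `word`, `transcription`,
#'   `stress_syllable` (see [read_lexicon()]).
#' @param inv A [phoneme inventory][load_inventory].
#' @inheritParams encode_word
#' @return Numeric matrix, one row per word (rownames = words), columns named
#'   per [form_variable_names()].
#' @export
encode_lexicon <- function(lexicon, inv, voicing_vowels = FALSE) {
  if (NROW(lexicon) == 0L) stop("empty lexicon")
  fm <- .feature_matrix(inv, voicing_vowels)
  nms <- form_variable_names(voicing_vowels)
  out <- matrix(0, NROW(lexicon), length(nms),
                dimnames = list(as.character(lexicon$word), nms))
  for (i in seq_len(NROW(lexicon))) {
    tr <- parse_transcription(lexicon$transcription[i])
    idx <- match(tr$phonemes, inv$symbol)
    if (anyNA(idx))
      stop("row ", i, " (word '", lexicon$word[i], "'): phoneme(s) not in ",
           "inventory: ", paste(unique(tr$phonemes[is.na(idx)]), collapse = ", "))
    stress <- as.integer(lexicon$stress_syllable[i])
    if (is.na(stress) || stress < 1L || stress > tr$n_syllables)
      stop("row ", i, " (word '", lexicon$word[i], "'): stress syllable out ",
           "of range 1..", tr$n_syllables)
    last <- idx[length(idx)]
    out[i, 1:5] <- c(nchar(as.character(lexicon$word[i])), length(idx),
                     tr$n_syllables, inv$numeric_id[idx[1L]],
                     inv$numeric_id[last])
    out[i, 6:30] <- colSums(fm[idx, , drop = FALSE])
    out[i, 31:55] <- fm[idx[1L], ]
    out[i, 56:80] <- fm[last, ]
    pos <- if (stress == tr$n_syllables) "stress_final"
           else if (stress == 1L) "stress_initial" else "stress_medial"
    out[i, pos] <- 1
  }
  out
}
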