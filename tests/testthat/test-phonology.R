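inv <- load_inventory()

test_that("default inventory is valid and complete", {
  expect_s3_class(inv, "phoneme_inventory")
  expect_equal(nrow(inv), 31L)
  expect_equal(inv$numeric_id, seq_len(31L))
  expect_false(anyDuplicated(inv$symbol) > 0)
  a <- inv[inv$symbol == "a", ]
  expect_equal(a$class, "vowel")
  expect_equal(a$height, "open")
  expect_equal(a$rounding, "unrounded")
  expect_equal(a$place, "central")
  # consonants carry place+manner+voicing and nothing vowel-specific
  cons <- inv[inv$class == "consonant", ]
  expect_true(all(!is.na(cons$place) & !is.na(cons$manner) &
                    !is.na(cons$voicing)))
  expect_true(all(is.na(cons$height) & is.na(cons$rounding)))
  vows <- inv[inv$class == "vowel", ]
  expect_true(all(vows$voicing == "voiced" & is.na(vows$manner)))
})

test_that("malformed inventory configs are rejected", {
  tmp <- tempfile(fileext = ".json")
  cfg <- jsonlite::fromJSON(fixture_path("es_castilian_31.json"),
                            simplifyDataFrame = FALSE)
  dup <- cfg
  dup$entries[[32]] <- dup$entries[[6]]  # /p/ twice
  jsonlite::write_json(dup, tmp, auto_unbox = TRUE)
  expect_error(load_inventory(tmp), "duplicate")

  bad <- cfg
  bad$entries[[6]]$height <- "open"  # consonant with a vowel-only feature
  jsonlite::write_json(bad, tmp, auto_unbox = TRUE)
  expect_error(load_inventory(tmp), "consonant")

  empty <- list(id = "x", entries = list())
  jsonlite::write_json(empty, tmp, auto_unbox = TRUE)
  expect_error(load_inventory(tmp), "no entries")
})

test_that("encode_word handles the degenerate single-vowel word", {
  v <- encode_word(list(word = "a", transcription = "a",
                        stress_syllable = 1), inv)
  expect_equal(length(v), 83L)
  expect_equal(unname(v[c("length_letters", "n_phonemes", "n_syllables")]),
               c(1, 1, 1))
  expect_equal(unname(v["n_open"]), 1)
  expect_equal(unname(v["n_unrounded"]), 1)
  cons_counts <- v[paste0("n_", c("bilabial", "labiodental", "dental",
                                  "alveolar", "palatal", "velar",
                                  "labiovelar", "plosive", "nasal",
                                  "fricative", "affricate", "lateral",
                                  "trill", "tap", "approximant"))]
  expect_true(all(cons_counts == 0))
  expect_equal(unname(v["initial_phoneme_id"]), unname(v["final_phoneme_id"]))
  expect_equal(unname(v["stress_final"]), 1)  # monosyllable convention
})

test_that("encode_word matches the hand-computed 'bala' vector", {
  v <- encode_word(list(word = "bala", transcription = "b a . l a",
                        stress_syllable = 1), inv)
  expect_equal(unname(v[c("n_phonemes", "n_syllables")]), c(4, 2))
  expect_equal(unname(v[c("n_bilabial", "n_lateral", "n_plosive",
                          "n_open", "n_unrounded", "n_central")]),
               c(1, 1, 1, 2, 2, 2))
  expect_equal(unname(v[c("ini_bilabial", "ini_plosive", "ini_voiced",
                          "fin_open", "fin_central", "fin_unrounded")]),
               c(1, 1, 1, 1, 1, 1))
  expect_equal(unname(v[c("stress_initial", "stress_medial", "stress_final")]),
               c(1, 0, 0))
})

test_that("encode_word rejects bad input", {
  expect_error(encode_word(list(word = "q", transcription = "q a",
                                stress_syllable = 1), inv), "not in inventory")
  expect_error(encode_word(list(word = "bala", transcription = "b a . l a",
                                stress_syllable = 3), inv), "out of range")
})

test_that("encoder equals the committed independent oracle on the fixture", {
  lex <- read_lexicon(fixture_path("mini_lexicon.csv"))
  X <- encode_lexicon(lex, inv)
  exp <- read.csv(fixture_path("mini_lexicon_formvectors.csv"))
  M <- as.matrix(exp[, -1])
  rownames(M) <- exp$word
  expect_identical(colnames(X), colnames(M))
  expect_equal(unname(X), unname(M), tolerance = 0)
  expect_identical(rownames(X), rownames(M))
})

test_that("encode_lexicon is deterministic, row-per-entry, all-or-nothing", {
  lex <- read_lexicon(fixture_path("mini_lexicon.csv"))[1:3, ]
  X <- encode_lexicon(lex, inv)
  expect_equal(dim(X), c(3L, 83L))
  expect_identical(X, encode_lexicon(lex, inv))  # pure function
  twice <- rbind(lex[1, ], lex[1, ])
  X2 <- encode_lexicon(twice, inv)
  expect_equal(X2[1, ], X2[2, ])
  bad <- lex
  bad$transcription[2] <- "b a . q a"
  expect_error(encode_lexicon(bad, inv), "row 2")
  expect_error(encode_lexicon(lex[0, ], inv), "empty")
})

test_that("feature-count conservation holds on generated lexicons", {
  lex <- generate_lexicon(200, seed = 7)
  X <- encode_lexicon(lex, inv)
  manner <- rowSums(X[, paste0("n_", c("plosive", "nasal", "fricative",
                                       "affricate", "lateral", "trill",
                                       "tap", "approximant"))])
  height <- rowSums(X[, paste0("n_", c("open", "mid", "close"))])
  voicing <- rowSums(X[, c("n_voiced", "n_voiceless")])
  n_vowel <- height
  n_cons <- X[, "n_phonemes"] - n_vowel
  expect_equal(unname(manner), unname(n_cons))
  expect_equal(unname(voicing), unname(n_cons))  # consonant-only voicing
  # positional indicators of exclusive categories sum to <= 1
  for (pos in c("ini_", "fin_")) {
    m <- rowSums(X[, paste0(pos, c("plosive", "nasal", "fricative",
                                   "affricate", "lateral", "trill", "tap",
                                   "approximant"))])
    expect_true(all(m <= 1))
  }
  expect_true(all(rowSums(X[, c("stress_initial", "stress_medial",
                                "stress_final")]) == 1))
  # with vowels included in voicing, the conservation extends to all tokens
  Xv <- encode_lexicon(lex, inv, voicing_vowels = TRUE)
  expect_equal(unname(rowSums(Xv[, c("n_voiced", "n_voiceless")])),
               unname(Xv[, "n_phonemes"]))
})
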