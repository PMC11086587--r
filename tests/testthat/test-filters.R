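mklex <- function(n, vsd, asd, pos = "noun", word = NULL) {
  data.frame(word = if (is.null(word)) sprintf("w%03d", seq_len(n)) else word,
             transcription = "b a . l a", stress_syllable = 1L, pos = pos,
             valence_mean = 5, valence_sd = vsd, arousal_mean = 5,
             arousal_sd = asd, stringsAsFactors = FALSE)
}

test_that("agreement filter applies a strict SD cutoff on both dimensions", {
  lex <- mklex(3, vsd = c(1.49, 1.50, 0.3), asd = c(1.49, 0.4, 1.50))
  r <- agreement_filter(lex)
  expect_equal(r$kept$word, "w001")          # 1.49/1.49 kept (strict <)
  expect_equal(nrow(r$removed), 2L)
  expect_match(r$removed$reason[1], "valence_sd")
  expect_match(r$removed$reason[2], "arousal_sd")
  expect_error(agreement_filter(lex[, -6]), "valence_sd")
  lex$valence_sd[1] <- -0.1
  expect_error(agreement_filter(lex), "negative")
})

test_that("a constructed 100-word set keeps exactly the 60 agreeing words", {
  set.seed(11)
  vsd <- runif(100, 0.2, 1.4)
  asd <- runif(100, 0.2, 1.4)
  viol <- sample(100, 40)
  flip <- runif(40) < 0.5
  vsd[viol[flip]] <- runif(sum(flip), 1.5, 2.5)
  asd[viol[!flip]] <- runif(sum(!flip), 1.5, 2.5)
  r <- agreement_filter(mklex(100, vsd, asd))
  expect_equal(nrow(r$kept), 60L)
  expect_equal(nrow(r$removed), 40L)
})

test_that("raising the cutoff never shrinks the kept set", {
  set.seed(12)
  lex <- mklex(200, runif(200, 0, 3), runif(200, 0, 3))
  kept <- vapply(c(0.5, 1, 1.5, 2, 3),
                 function(ct) nrow(agreement_filter(lex, ct)$kept), 1L)
  expect_true(all(diff(kept) >= 0))
})

test_that("POS filter drops the default closed classes and only those", {
  lex <- mklex(4, 0.5, 0.5, pos = c("pronoun", "noun", "interjection",
                                    "adjective"))
  r <- pos_filter(lex)
  expect_equal(r$kept$pos, c("noun", "adjective"))
  expect_equal(sort(r$removed$reason), c("pos:interjection", "pos:pronoun"))
  # empty exclusion set is the identity
  r0 <- pos_filter(lex, excluded = character(0))
  expect_equal(nrow(r0$kept), 4L)
  expect_warning(pos_filter(mklex(1, 0.5, 0.5, pos = "gerund")), "unknown")
  expect_error(pos_filter(mklex(1, 0.5, 0.5, pos = "gerund"),
                          unknown = "error"), "unknown")
})

test_that("prefix stripping is orthographic, case-insensitive, longest-match", {
  lex <- mklex(4, 0.5, 0.5,
               word = c("indeciso", "mesa", "Interminable", "destino"))
  r <- strip_prefixed(lex, c("in", "des", "inter"))
  expect_equal(r$kept$word, "mesa")
  expect_equal(r$removed$reason,
               c("prefix:in", "prefix:inter", "prefix:des"))
  expect_error(strip_prefixed(lex, character(0)), "empty")
  expect_error(strip_prefixed(lex, c("in", "")), "empty")
})

test_that("emotionality is |valence - 5| with symmetry over the scale", {
  expect_equal(derive_emotionality(5), 0)
  expect_equal(derive_emotionality(3), 2)
  expect_equal(derive_emotionality(7), 2)
  expect_equal(derive_emotionality(1), 4)
  expect_equal(derive_emotionality(9), 4)
  x <- seq(0, 4, by = 0.25)
  expect_equal(derive_emotionality(5 + x), derive_emotionality(5 - x))
  expect_error(derive_emotionality(9.5), "scale")
  expect_error(derive_emotionality(0.5), "scale")
})

test_that("the chained pipeline partitions its input and counts decrease", {
  set.seed(13)
  lex <- generate_lexicon(300, seed = 13)
  lex <- plant_affect(lex, seed = 14)
  rep <- filter_lexicon(lex)
  expect_s3_class(rep, "filter_report")
  expect_true(rep$n_input >= rep$n_after_agreement)
  expect_true(rep$n_after_agreement >= rep$n_after_pos)
  expect_true(rep$n_after_pos >= rep$n_after_prefix)
  expect_equal(rep$n_input, rep$n_after_prefix + nrow(rep$removed))
  expect_true(all(rep$kept$emotionality == abs(rep$kept$valence_mean - 5)))
  # serializes to JSON
  f <- tempfile(fileext = ".json")
  write_filter_report(rep, f)
  js <- jsonlite::fromJSON(f)
  expect_equal(js$n_input, rep$n_input)
  expect_equal(nrow(js$removed), nrow(rep$removed))
})
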