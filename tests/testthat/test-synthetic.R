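inv_s <- load_inventory()

test_that("generate_lexicon is seed-deterministic and respects config", {
  a <- generate_lexicon(100, seed = 91)
  b <- generate_lexicon(100, seed = 91)
  expect_identical(a, b)
  c2 <- generate_lexicon(100, seed = 92, syllable_range = c(2, 2),
                         prefix_rate = 0)
  X <- encode_lexicon(c2, inv_s)
  expect_true(all(X[, "n_syllables"] == 2))
  # every generated transcription uses only inventory phonemes
  toks <- unlist(strsplit(a$transcription, "[[:space:]]+"))
  expect_true(all(setdiff(toks, ".") %in% inv_s$symbol))
})

test_that("prefixed fraction stays within binomial 99% bounds", {
  lex <- generate_lexicon(1000, seed = 93, prefix_rate = 0.1)
  stripped <- strip_prefixed(lex, c("in", "des", "re", "sub", "pre"))
  frac <- nrow(stripped$removed) / 1000
  # planted 0.1 plus a small background of organically prefix-like words;
  # 99% binomial band around 0.1 is roughly [0.076, 0.125]
  expect_gte(frac, qbinom(0.005, 1000, 0.1) / 1000)
  # allow background false positives on top of the planted rate
  expect_lte(frac, qbinom(0.995, 1000, 0.1) / 1000 + 0.05)
})

test_that("stored means and SDs equal recomputation from rater samples", {
  lex <- plant_affect(generate_lexicon(80, seed = 94), inv_s, seed = 95)
  R <- attr(lex, "raters")
  expect_equal(lex$valence_mean, rowMeans(R$valence), tolerance = 1e-12)
  expect_equal(lex$valence_sd, apply(R$valence, 1, sd), tolerance = 1e-12)
  expect_equal(lex$arousal_mean, rowMeans(R$arousal), tolerance = 1e-12)
  expect_equal(lex$arousal_sd, apply(R$arousal, 1, sd), tolerance = 1e-12)
  expect_true(all(R$valence >= 1 & R$valence <= 9))
  expect_true(all(R$valence == round(R$valence)))
})

test_that("degenerate rater model gives SD 0 and rounded latent means", {
  lex <- plant_affect(generate_lexicon(60, seed = 96), inv_s, seed = 97,
                      rater_sd = c(valence = 0, arousal = 0),
                      disagreement_rate = 0)
  expect_true(all(lex$valence_sd == 0))
  expect_true(all(lex$arousal_sd == 0))
  lat <- attr(lex, "latent")
  expect_equal(lex$valence_mean,
               round(pmin(pmax(lat$valence_latent, 1), 9)), tolerance = 1e-12)
})

test_that("disagreement words mostly exceed the 1.5-SD cutoff", {
  lex <- plant_affect(generate_lexicon(400, seed = 98), inv_s, seed = 99,
                      raters_per_word = 50L,
                      rater_sd = c(valence = 0.8, arousal = 0.8),
                      disagreement_rate = 0.3, disagreement_separation = 4)
  lat <- attr(lex, "latent")
  dis <- lat$valence_disagree
  expect_gt(sum(dis), 50)
  expect_gte(mean(lex$valence_sd[dis] >= 1.5), 0.9)
  # agreeing words rarely hit the cutoff at this rater sd
  expect_lt(mean(lex$valence_sd[!dis] >= 1.5), 0.1)
})

test_that("planted variance share is recovered by regression on form variables", {
  lex <- generate_lexicon(4000, seed = 100, prefix_rate = 0,
                          excluded_pos_rate = 0)
  lex <- plant_affect(lex, inv_s, seed = 101,
                      target_r2 = c(valence = 0.05, arousal = 0.05),
                      disagreement_rate = 0)
  X <- encode_lexicon(lex, inv_s)
  beta <- default_planted_beta()$valence
  f <- lm(lex$valence_mean ~ X[, names(beta)])
  expect_lt(abs(summary(f)$r.squared - 0.05), 0.02)
  # infeasible target errors
  expect_error(plant_affect(lex, inv_s, seed = 1,
                            planted_beta = list(valence = NULL, arousal = NULL),
                            target_r2 = c(valence = 0.1, arousal = 0)),
               "planted_beta")
})

test_that("make_fixture output equals the committed fixture and passes filters", {
  dir <- tempfile(); dir.create(dir)
  make_fixture(dir)
  new <- readLines(file.path(dir, "mini_lexicon.csv"))
  old <- readLines(fixture_path("mini_lexicon.csv"))
  expect_identical(new, old)
  lex <- read_lexicon(fixture_path("mini_lexicon.csv"))
  expect_equal(nrow(lex), 30L)
  expect_equal(nrow(agreement_filter(lex)$kept), 30L)  # all pass by design
})
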