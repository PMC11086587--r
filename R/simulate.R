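#' Generate a Spanish-like synthetic lexicon
#'
#' Samples phonotactically plausible words as concatenations of (C)V(C)
#' syllables over the packaged inventory, assigns a stress syllable with the
#' penultimate/final weighting typical of Spanish, derives orthography from a
#' fixed phoneme-to-letter map, gives each word a part of speech, and
#' prepends a derivational prefix to a configured fraction of words (so the
#' prefix-removal stage has something to remove).  The default POS mix
#' follows the composition of a filtered Spanish affective-norm lexicon
#' (roughly 65% nouns, 19% verbs, 15% adjectives, 1% adverbs), with a small
#' share of closed-class items to exercise the POS filter.
#'
#' @param n_words Number of words.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param syllable_range Integer c(min, max) syllables per word, within 1..8.
#' @param pos_probs Named probabilities over open POS classes.
#' @param excluded_pos_rate Fraction of words given a closed-class POS label
#'   (sampled from the default exclusion set).
#' @param prefix_rate Fraction of words receiving a prefix; the default 0.063
#'   mirrors the share of prefixed words a Spanish norm lexicon loses at the
#'   prefix-removal stage.
#' @param onset_prob,coda_prob Probabilities that a syllable has an onset /
#'   a coda.
#' @return Data frame with columns `word`, `transcription`,
#'   `stress_syllable`, `pos` (no ratings; see [plant_affect()]).
#' @export
generate_lexicon <- function(n_words, seed = NULL,
                             syllable_range = c(1L, 4L),
                             pos_probs = c(noun = 0.646, adjective = 0.153,
                                           verb = 0.189, adverb = 0.012),
                             excluded_pos_rate = 0.05,
                             prefix_rate = 0.063,
                             onset_prob = 0.9, coda_prob = 0.35) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(n_words >= 1, syllable_range[1] >= 1, syllable_range[2] <= 8,
            abs(sum(pos_probs) - 1) < 1e-8)

  onsets <- c("p", "b", "t", "d", "k", "g", "tS", "f", "T", "s", "x", "jj",
              "m", "n", "J", "l", "L", "rr", "r", "w")
  onset_w <- c(8, 6, 9, 7, 9, 5, 2, 4, 3, 9, 3, 2, 9, 7, 1, 7, 2, 2, 6, 2)
  codas <- c("s", "n", "r", "l", "d", "T")
  coda_w <- c(10, 8, 6, 4, 2, 1)
  vowels <- c("a", "e", "i", "o", "u")
  vowel_w <- c(10, 9, 6, 8, 4)
  orth <- c(a = "a", e = "e", i = "i", o = "o", u = "u", p = "p", b = "b",
            t = "t", d = "d", k = "c", g = "g", tS = "ch", f = "f", T = "z",
            s = "s", z = "s", S = "x", x = "j", jj = "y", B = "b", D = "d",
            G = "g", m = "m", n = "n", J = "n", l = "l", L = "ll", rr = "rr",
            r = "r", j = "i", w = "u")
  prefixes <- list(c("in", "i n"), c("des", "d e s"), c("re", "rr e"),
                   c("sub", "s u b"), c("pre", "p r e"))

  # sample.int avoids the sample(x) scalar pitfall when min == max
  n_syll <- syllable_range[1] - 1L +
    sample.int(syllable_range[2] - syllable_range[1] + 1L, n_words,
               replace = TRUE)
  words <- character(n_words)
  trans <- character(n_words)
  stress <- integer(n_words)
  for (i in seq_len(n_words)) {
    syls <- replicate(n_syll[i], {
      s <- character(0)
      if (runif(1) < onset_prob)
        s <- sample(onsets, 1, prob = onset_w)
      s <- c(s, sample(vowels, 1, prob = vowel_w))
      if (runif(1) < coda_prob)
        s <- c(s, sample(codas, 1, prob = coda_w))
      paste(s, collapse = " ")
    })
    tr <- paste(syls, collapse = " . ")
    ns <- n_syll[i]
    # Spanish-like stress: mostly penultimate, often final, rarely earlier
    stress[i] <- if (ns == 1L) 1L else {
      cand <- c(ns - 1L, ns, max(1L, ns - 2L))
      sample(cand, 1, prob = c(0.65, 0.3, 0.05))
    }
    toks <- strsplit(tr, " ")[[1]]
    words[i] <- paste(orth[toks[toks != "."]], collapse = "")
    trans[i] <- tr
  }

  pre <- runif(n_words) < prefix_rate
  for (i in which(pre)) {
    p <- prefixes[[sample.int(length(prefixes), 1)]]
    words[i] <- paste0(p[1], words[i])
    trans[i] <- paste(p[2], ".", trans[i])
    stress[i] <- stress[i] + 1L
  }

  pos <- sample(names(pos_probs), n_words, replace = TRUE, prob = pos_probs)
  drop_pos <- runif(n_words) < excluded_pos_rate
  pos[drop_pos] <- sample(.pos_default_excluded, sum(drop_pos), replace = TRUE)

  data.frame(word = words, transcription = trans, stress_syllable = stress,
             pos = pos, stringsAsFactors = FALSE)
}

#' Plant form-affect structure and simulate raters
#'
#' Gives every word a latent valence and arousal mean composed of the scale
#' midpoint, a linear effect of its form variables, and Gaussian residual
#' noise, with the coefficient vector rescaled so the form effect accounts
#' for exactly `target_r2` of the latent population variance.  Each word is
#' then rated by `raters_per_word` simulated raters: normal draws around the
#' latent mean (a `disagreement_rate` fraction of words instead uses a
#' symmetric two-component mixture separated by `disagreement_separation`,
#' emulating rater populations that split between strong and negligible
#' affective responses), clipped to the 9-point scale and rounded to
#' integers.  Stored means and SDs are recomputed from the integer samples.
#'
#' @param lexicon A lexicon from [generate_lexicon()] (or any table with
#'   `word`, `transcription`, `stress_syllable`).
#' @param inv Phoneme inventory.
#' @param seed Integer seed.
#' @param planted_beta Named list with elements `valence` and `arousal`, each
#'   a named coefficient vector over form variables (directions only; the
#'   magnitude is rescaled to `target_r2`).  Zero effects allowed via `NULL`
#'   only when the matching `target_r2` is 0.
#' @param target_r2 Named vector: population variance share of the form
#'   effect in the latent means.  Defaults 0.03 (valence) and 0.058
#'   (arousal), the magnitudes reported for Spanish affective norms.
#' @param latent_sd Named vector of latent population SDs; defaults 1.3 and
#'   1.0 rating points, matching descriptive norms.
#' @param raters_per_word Number of simulated raters; default 20.
#' @param rater_sd Within-rater SD around the latent mean, per dimension.
#' @param disagreement_rate Fraction of words with split rater populations.
#' @param disagreement_separation Distance between the two mixture modes.
#' @return The lexicon with columns `valence_mean`, `valence_sd`,
#'   `arousal_mean`, `arousal_sd` appended, plus attributes `latent` (data
#'   frame of latent means and disagreement flags) and `raters` (list of two
#'   integer matrices, words x raters).
#' @export
plant_affect <- function(lexicon, inv = load_inventory(), seed = NULL,
                         planted_beta = default_planted_beta(),
                         target_r2 = c(valence = 0.03, arousal = 0.058),
                         latent_sd = c(valence = 1.3, arousal = 1.0),
                         raters_per_word = 20L,
                         rater_sd = c(valence = 1.1, arousal = 1.3),
                         disagreement_rate = 0.10,
                         disagreement_separation = 4) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  X <- encode_lexicon(lexicon, inv)
  n <- nrow(X)
  out <- lexicon
  latent <- data.frame(row.names = seq_len(n))
  raters <- list()
  for (dim in c("valence", "arousal")) {
    beta <- planted_beta[[dim]]
    r2 <- target_r2[[dim]]
    sdt <- latent_sd[[dim]]
    if (r2 > 0) {
      if (is.null(beta) || !any(beta != 0))
        stop("target_r2[", dim, "] > 0 but planted_beta[[", dim, "]] is zero")
      bad <- setdiff(names(beta), colnames(X))
      if (length(bad)) stop("planted_beta names not form variables: ",
                            paste(bad, collapse = ", "))
      s <- drop(X[, names(beta), drop = FALSE] %*% beta)
      s <- s - mean(s)
      if (sd(s) == 0) stop("planted effect has zero variance in this lexicon")
      s <- s * sqrt(r2) * sdt / sd(s)
    } else {
      s <- numeric(n)
    }
    mu <- 5 + s + rnorm(n, 0, sqrt(1 - r2) * sdt)
    disagree <- runif(n) < disagreement_rate
    m <- raters_per_word
    shift <- matrix(0, n, m)
    if (any(disagree))
      shift[disagree, ] <- sample(c(-0.5, 0.5), sum(disagree) * m,
                                  replace = TRUE) * disagreement_separation
    R <- matrix(rnorm(n * m, mu, rater_sd[[dim]]), n, m) + shift
    R <- round(pmin(pmax(R, 1), 9))
    out[[paste0(dim, "_mean")]] <- rowMeans(R)
    out[[paste0(dim, "_sd")]] <- apply(R, 1, sd)
    latent[[paste0(dim, "_latent")]] <- mu
    latent[[paste0(dim, "_disagree")]] <- disagree
    raters[[dim]] <- R
  }
  attr(out, "latent") <- latent
  attr(out, "raters") <- raters
  out
}

#' Default planted coefficient directions
#'
#' Coefficient patterns used by [plant_affect()]: directions loosely follow
#' effects reported for Spanish (longer words and fricatives lean negative in
#' valence, final laterals and final stress positive; more phonemes and
#' initial fricatives lean high-arousal).  Magnitudes are relative only —
#' [plant_affect()] rescales them to the target variance share.
#'
#' @return Named list with `valence` and `arousal` coefficient vectors.
#' @export
default_planted_beta <- function() {
  list(
    valence = c(length_letters = -0.20, n_fricative = -0.08,
                fin_lateral = 0.35, ini_nasal = -0.20, stress_final = 0.45,
                n_mid = 0.07),
    arousal = c(n_phonemes = 0.15, ini_fricative = 0.30, fin_alveolar = -0.30,
                n_close = 0.20, stress_initial = -0.15))
}

#' Write the packaged mini-lexicon fixture
#'
#' Writes the ~30-word fixture shipped in `inst/extdata`: real Spanish words
#' (several drawn from published most/least-typical listings, e.g.
#' "general", "panel", "huir", "canal") with hand-checked transcriptions and
#' plausible synthetic ratings, all passing the agreement filter.  The
#' companion expected-form-vector file in `inst/extdata` is produced by an
#' independent Python encoder (`tools/encode_oracle.py`), not by this
#' package.
#'
#' @param dir Output directory.
#' @return Path of the written CSV, invisibly.
#' @export
make_fixture <- function(dir = ".") {
  w <- function(word, tr, st, pos, vm, vs, am, as_)
    data.frame(word = word, transcription = tr, stress_syllable = st,
               pos = pos, valence_mean = vm, valence_sd = vs,
               arousal_mean = am, arousal_sd = as_)
  fx <- rbind(
    w("general",  "x e . n e . r a l",     3L, "adjective", 5.4, 1.1, 4.2, 1.2),
    w("panel",    "p a . n e l",           2L, "noun",      5.1, 0.9, 3.8, 1.1),
    w("huir",     "u . i r",               2L, "verb",      3.1, 1.3, 6.4, 1.2),
    w("canal",    "k a . n a l",           2L, "noun",      5.3, 1.0, 4.1, 1.0),
    w("cruel",    "k r w e l",             1L, "adjective", 2.2, 1.2, 6.1, 1.3),
    w("local",    "l o . k a l",           2L, "adjective", 5.2, 0.8, 3.9, 1.0),
    w("laurel",   "l a w . r e l",         2L, "noun",      6.0, 1.1, 3.6, 1.1),
    w("mesa",     "m e . s a",             1L, "noun",      5.5, 0.9, 3.2, 0.9),
    w("bala",     "b a . l a",             1L, "noun",      2.8, 1.4, 6.8, 1.2),
    w("perro",    "p e . rr o",            1L, "noun",      6.8, 1.2, 5.2, 1.3),
    w("chico",    "tS i . k o",            1L, "noun",      6.1, 1.0, 4.6, 1.1),
    w("zapato",   "T a . p a . t o",       2L, "noun",      5.4, 0.8, 3.3, 0.9),
    w("yate",     "jj a . t e",            1L, "noun",      6.5, 1.2, 4.9, 1.3),
    w("agua",     "a . g w a",             1L, "noun",      7.2, 1.0, 3.9, 1.2),
    w("fuego",    "f w e . g o",           1L, "noun",      5.0, 1.4, 6.9, 1.1),
    w("dedo",     "d e . d o",             1L, "noun",      5.2, 0.7, 3.1, 0.8),
    w("sol",      "s o l",                 1L, "noun",      7.5, 0.9, 5.0, 1.2),
    w("mar",      "m a r",                 1L, "noun",      7.1, 1.1, 4.8, 1.3),
    w("flor",     "f l o r",               1L, "noun",      7.4, 0.8, 4.0, 1.1),
    w("casa",     "k a . s a",             1L, "noun",      7.0, 0.9, 3.5, 1.0),
    w("vida",     "b i . d a",             1L, "noun",      7.8, 1.0, 5.3, 1.3),
    w("tiempo",   "t j e m . p o",         1L, "noun",      5.6, 1.2, 4.4, 1.2),
    w("mujer",    "m u . x e r",           2L, "noun",      6.6, 1.1, 4.7, 1.2),
    w("corazon",  "k o . r a . T o n",     3L, "noun",      7.3, 1.0, 5.6, 1.3),
    w("arbol",    "a r . b o l",           1L, "noun",      6.9, 0.8, 3.4, 0.9),
    w("lluvia",   "L u . b j a",           1L, "noun",      5.8, 1.3, 4.3, 1.2),
    w("libro",    "l i . b r o",           1L, "noun",      6.7, 0.9, 3.7, 1.0),
    w("nino",     "n i . J o",             1L, "noun",      7.2, 1.1, 5.1, 1.3),
    w("cantar",   "k a n . t a r",         2L, "verb",      6.8, 1.0, 5.5, 1.2),
    w("lejos",    "l e . x o s",           1L, "adverb",    4.4, 1.2, 4.1, 1.1))
  path <- file.path(dir, "mini_lexicon.csv")
  write.csv(fx, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
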