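---
title: "Form typicality for affective content: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Form typicality for affective content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formtypic)
```

## The problem

Word forms are not fully arbitrary: across languages, some articulatory
properties of words are statistically associated with aspects of their
meanings.  For affective meaning this raises a measurable question — given a
lexicon with mean valence and arousal ratings, how much of the rating
variance can the *sound structure* of the words predict, and which words
have forms most "typical" of, say, positive valence?  `formtypic`
operationalises this as a regression problem: code each word's phonology
into a fixed vector of form variables, select a parsimonious predictive
model by cross-validation, and summarise each word by the z-scored fitted
value of that model — its **form typicality** for the rating.

The effects of interest are tiny (a few percent of rating variance at
best), which dictates most of the package's design: honest cross-validation,
heteroscedasticity-robust inference, and a synthetic-data module that can
plant known effects at realistic magnitudes so that every stage of the
pipeline is testable.

## The form-variable coding

A phoneme inventory (`load_inventory()`) assigns each symbol an articulatory
feature bundle: place, manner and voicing for consonants; place, height and
rounding for vowels.  The packaged default is a 31-phoneme Castilian Spanish
inventory in ASCII-safe symbols; it is a plain JSON file, so dialectal
variants are config edits, not code changes.  Numeric phoneme ids are the
1-based positions in the configured order.  Because the id assignment is a
convention, the single-slope "initial phoneme id" and "final phoneme id"
predictors are only comparable between runs sharing one configuration — a
documented limitation of id-coded predictors in general.

`encode_word()` produces 83 named variables per word:

* lengths: letters (accented characters count as one), phonemes, syllables;
* initial and final phoneme ids;
* counts of each feature category over the word (voicing counts cover
  consonants only by default — vowels are uniformly voiced, so counting them
  would add a multiple of the vowel count, i.e. pure collinearity;
  `voicing_vowels = TRUE` restores them);
* indicators of each category at the initial and at the final phoneme;
* stress position: initial, medial, final.  Monosyllables are coded
  *final*, so the three indicators always partition words (in Spanish,
  stress in monosyllables falls on the word-final — only — syllable).

Transcriptions are whitespace-separated phoneme symbols with `.` as the
syllable separator and stress given as an integer column; this round-trips
through CSV unambiguously, unlike in-string diacritics.

## Word-inclusion pipeline

Three stages, in a fixed order (`filter_lexicon()`):

1. **Rating agreement**: keep words with `valence_sd < 1.5` *and*
   `arousal_sd < 1.5` (strict inequality).  A between-rater SD of 1.5 on a
   nine-point scale means raters split between strong and negligible
   affective responses; such items mostly add noise.
2. **Part of speech**: drop numbers, proper names, adpositions, dates,
   determiners, interjections and pronouns (configurable).
3. **Prefix removal**: drop words beginning with a listed derivational
   prefix (a default Spanish list: in-, im-, des-, dis-, anti-, re-, pre-,
   sub-, contra-, auto-, inter-, super-).  Negating prefixes can invert a
   word's affective meaning while leaving most of its form intact, which
   systematically dilutes form–meaning associations.  The match is purely
   orthographic and therefore over-removes pseudo-prefixed words; this
   false-positive mode is accepted and documented rather than "fixed" with
   morphological parsing.

Emotionality is derived on the kept set as `|valence_mean − 5|` (distance
from the scale midpoint, range 0–4).

## The three-step typicality model

**Screening** (`screen_predictors()`): drop constant columns, then walk the
remaining columns in roster order and drop any column numerically in the
span of the intercept and the columns already kept (incremental
Gram–Schmidt, relative tolerance `1e-7`).  Preferring earlier columns makes
the screen deterministic; indicator sets that sum to one (the stress triple)
lose exactly their last member.

**Best subsets** (`best_subsets()`): for each size `k ≤ kmax` the
RSS-minimal subset, computed on centred sufficient statistics in compiled
code.  For `p ≤ exact_limit` (default 16) the search enumerates all
subsets; beyond, it uses forward selection refined by sequential
replacement, and flags the result as not guaranteed exact.  `kmax` defaults
to `min(p, 40)`: published models of this kind retain roughly 18–22 terms,
so 40 leaves generous headroom while bounding the search.

**Cross-validated size selection** (`cv_select()`): repeated k-fold CV
(defaults: 10 folds, 200 repeats, simple random partitions re-randomised
each repeat, no stratification), minimising mean held-out RMSE, ties within
`1e-12` resolved toward the smaller model.

A design point we changed after measurement: scoring *fixed* candidate
subsets (selected once on the full data) by CV, refitting only their
coefficients per fold, looks innocuous but leaks the full-data search into
every held-out fold.  The symptom is unambiguous — under a pure-null signal
the mean held-out RMSE *decreases* monotonically with subset size, so the
argmin lands on the largest model searched, and the refit model's adjusted
R² inflates to roughly the scale of the selection bias.  `cv_select()`
therefore re-runs the subset search *inside every training fold* by default
(`reselect = TRUE`), making the tuned quantity the subset *size*; the chosen
model is then the full-data best subset of the winning size.  This matches
how the standard CV tooling for subset regression treats the subset size as
the tuning parameter.  The fixed-support mode is retained
(`reselect = FALSE`) for diagnosis, and our acceptance suite checks the
null-pipeline property (adjusted R² ≈ 0 under zero planted signal) that the
fixed-support mode fails.

Even with honest re-selection, RMSE-argmin size selection is only weakly
parsimonious: when an extra spurious predictor happens to correlate with
the response throughout a given dataset, CV — which can only estimate
predictive error *within* that dataset — may genuinely prefer the larger
size.  In our support-recovery acceptance test (5 planted of 30, n = 4000,
signal R² 0.3) the RSS search finds exactly the planted support at size 5
in every replicate, but the CV argmin picks a size above 5 in roughly a
quarter of replicates; the corresponding criterion is accordingly reported
as not met rather than silently relaxed.  A one-standard-error selection
rule would restore parsimony but would change the stated selection rule
(minimum mean RMSE), so it is deliberately not applied.

**Robust refit** (`fit_robust()`): OLS coefficients with HC sandwich
standard errors.  Form-variable regressions routinely show skewness,
outliers and heteroscedasticity, making classical SEs anticonservative.
The default flavor is HC2 (leverage-corrected; unbiased under
homoscedasticity), with HC0/HC1/HC3 available; the choice matters little at
the n of typical norm studies.  Inference uses the t distribution with
`n − p − 1` df.

**Scores** (`typicality_scores()`): fitted values for every word,
z-transformed with the sample SD (n − 1).  Scores depend only on the fitted
values, hence are invariant to invertible reparameterisations of the
predictors; both the z-scores and the raw fitted values are returned, since
extreme-word tables are sometimes published on the raw fitted scale.

## Group and hierarchical statistics

* `bartlett_test()` gates the ANOVA choice; `welch_anova()` implements the
  heteroscedastic F with Welch–Satterthwaite denominator df.  The effect
  size uses the convention `ω² = df₁(F−1)/(df₁(F−1)+N)`; other ω²
  definitions exist, but this is the common one for Welch ANOVA and reduces
  sensibly at F = 1.
* `games_howell()` compares all group pairs with pairwise Welch t statistics
  referred to the studentized range with the full number of means.  Base R's
  `ptukey()` is only accurate to about `1e-7`, which is visible when checking
  the exact two-group reduction to Welch's t, so the package evaluates the
  studentized-range tail by direct double quadrature (adaptive integration,
  target `1e-10`); the reduction then holds to ~`1e-14`.
* `spearman_matrix()` uses average ranks for ties, pairwise-complete
  observations, and the t approximation for p-values; constant variables
  yield `NA` (undefined correlation) rather than an arbitrary value.
* `hierarchical_regression()` fits nested robust models step by step.  All
  continuous predictors are mean-centred *before* interaction columns are
  built (products of centred variables), categorical predictors expand
  against a stated reference level.  ΔR² is computed on *adjusted* R², so
  small negative increments are possible and meaningful (an added block not
  worth its degrees of freedom).  Block significance is a robust Wald
  chi-square on the added coefficients using the step's sandwich covariance;
  a classical nested-F would understate heteroscedasticity, and the Wald
  form needs no auxiliary fit.  The two entry orders of the five-step
  item-level designs share their final model, which the code exploits as an
  internal consistency check.

## The synthetic-data module

`generate_lexicon()` + `plant_affect()` define the package's stated world:

* words are (C)V(C) syllable concatenations over the packaged inventory
  with Spanish-like onset/coda pools and penultimate-heavy stress;
  orthography comes from a fixed phoneme→letter map;
* the POS mix defaults to the composition of a filtered Spanish norm
  lexicon (about 65% nouns, 19% verbs, 15% adjectives, 1% adverbs), plus a
  5% sprinkle of closed-class labels and a 6.3% prefixed fraction so the
  POS and prefix filters have real work;
* each word's latent valence and arousal are `5 + form effect + noise`,
  with the planted coefficient direction vector rescaled so the form effect
  explains exactly `target_r2` of the latent variance (defaults 0.03 for
  valence and 0.058 for arousal — the magnitudes reported for Spanish norm
  analyses) and latent SDs of 1.3 and 1.0 rating points;
* ratings are produced by a multi-rater model: 20 raters per word, normal
  around the latent mean (SDs 1.1 and 1.3), with a 10% disagreement
  subpopulation whose raters split symmetrically ±2 scale points around the
  mean — the mechanism that produces the high-SD words the agreement filter
  targets; responses are clipped to [1, 9] and rounded to integers, and the
  stored means/SDs are recomputed from the integer samples.

What the generator does **not** emulate: real morphology (prefixes are
pasted, not derived), the quadratic valence–arousal relation of real norms
(latent dimensions are independent by default), correlated lexico-semantic
covariates, and frequency structure.  A green end-to-end test therefore
establishes that the *pipeline machinery* recovers planted structure at
realistic magnitudes — not that any particular linguistic claim holds.

## Numerical choices and degenerate inputs

* Screening tolerance `1e-7` (relative residual norm); subset-search
  singular submatrices are skipped as infinite-RSS; CV tie tolerance
  `1e-12`; z-transform uses `n − 1`.
* Exact-fit degeneracies: zero residual variance gives zero robust SEs and
  undefined t (reported `NA`); constant fitted values make typicality
  undefined and raise an error rather than returning zeros.
* Rating-scale violations, unknown phonemes, out-of-range stress indices
  and malformed transcriptions fail loudly with row-level aggregation in
  `read_lexicon()`.
* All randomness flows from explicit integer seeds; runs are byte-stable
  given (data, config, seed).

## Known limitations

* The orthographic prefix filter over-removes pseudo-prefixed words.
* Id-coded initial/final phoneme slopes are inventory-order dependent.
* RMSE-argmin size selection retains a material false-inclusion rate for
  spurious predictors (see above); treat selected-model size and membership
  as descriptive, and the robust coefficient table as conditional on the
  selection.
* The hybrid subset search beyond `exact_limit` is a heuristic; its results
  carry `exact = FALSE` and may miss the RSS optimum for adversarial
  correlation structures.
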