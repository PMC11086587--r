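#' Study-1 driver: typicality models and POS comparisons
#'
#' Runs the full first-study pipeline on a raw lexicon: word-inclusion
#' filters, one form-typicality model per affective dimension (valence,
#' emotionality, arousal), variance-homogeneity checks and heteroscedastic
#' group comparisons of typicality across parts of speech (Bartlett, Welch
#' ANOVA with omega-squared, Games-Howell post hoc), and the 10 most / 10
#' least typical word forms per dimension.
#'
#' @param lexicon Raw lexicon data frame (see [read_lexicon()]).
#' @param inv Phoneme inventory.
#' @param folds,repeats,kmax,hc_flavor,seed Passed to [run_typicality()].
#' @param cutoff,excluded,prefixes Passed to [filter_lexicon()].
#' @param out_dir Optional directory; when given, all artifacts are written
#'   there as CSV/JSON.
#' @return List of class `study1_result`: `filter` (report), `runs` (one
#'   [run_typicality()] result per dimension), `anova` (per dimension:
#'   `bartlett`, `welch`, `games_howell`), `extremes` (per dimension).
#' @export
run_study1 <- function(lexicon, inv = load_inventory(), folds = 10L,
                       repeats = 200L, kmax = NULL, hc_flavor = "HC2",
                       seed = 1L, cutoff = 1.5,
                       excluded = .pos_default_excluded,
                       prefixes = .prefixes_default, out_dir = NULL) {
  filt <- filter_lexicon(lexicon, cutoff, excluded, prefixes)
  kept <- filt$kept
  dims <- c("valence", "emotionality", "arousal")
  runs <- anovas <- extremes <- setNames(vector("list", 3L), dims)
  for (d in dims) {
    runs[[d]] <- run_typicality(kept, inv, dv = d, folds = folds,
                                repeats = repeats, kmax = kmax,
                                hc_flavor = hc_flavor, seed = seed)
    sc <- runs[[d]]$scores$typicality
    anovas[[d]] <- list(bartlett = bartlett_test(sc, kept$pos),
                        welch = welch_anova(sc, kept$pos),
                        games_howell = games_howell(sc, kept$pos))
    extremes[[d]] <- typicality_extremes(runs[[d]]$scores, 10L)
  }
  res <- structure(list(filter = filt, runs = runs, anova = anovas,
                        extremes = extremes),
                   class = "study1_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_filter_report(filt, file.path(out_dir, "filter_report.json"))
    for (d in dims) {
      write.csv(coef_table(runs[[d]]$fit),
                file.path(out_dir, paste0("model_", d, ".csv")),
                row.names = FALSE)
      write.csv(runs[[d]]$scores,
                file.path(out_dir, paste0("scores_", d, ".csv")),
                row.names = FALSE)
      write.csv(extremes[[d]],
                file.path(out_dir, paste0("extremes_", d, ".csv")),
                row.names = FALSE)
      a <- anovas[[d]]
      jsonlite::write_json(
        list(bartlett = a$bartlett,
             welch = unclass(a$welch),
             games_howell = a$games_howell),
        file.path(out_dir, paste0("anova_", d, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      write_manifest(runs[[d]]$manifest,
                     file.path(out_dir, paste0("manifest_", d, ".json")))
    }
  }
  res
}

#' Study-2 driver: lexico-semantic correlations and 3-step hierarchies
#'
#' On a merged item table (affective ratings, typicality scores and
#' lexico-semantic covariates), computes the Spearman correlation matrix over
#' all numeric variables, then fits one 3-step hierarchical robust regression
#' per affective rating: lexico-semantic controls first, the other two
#' affective ratings second, the three typicality measures third.
#'
#' @param data Merged data frame.  Expected columns: the three rating
#'   variables, `typ_valence`/`typ_emotionality`/`typ_arousal`, the control
#'   variables, and optionally a categorical `pos`.
#' @param controls Character vector of control (step-1) terms.
#' @param ratings Named character vector mapping `valence`, `emotionality`,
#'   `arousal` to their column names.
#' @param hc_flavor HC flavor for the robust fits.
#' @param reference_levels Reference levels for categorical controls;
#'   default `c(pos = "noun")`.
#' @return List of class `study2_result`: `correlations` (a
#'   [spearman_matrix()]), `hier` (one [hierarchical_regression()] result per
#'   rating).
#' @export
run_study2 <- function(data, controls,
                       ratings = c(valence = "valence_mean",
                                   emotionality = "emotionality",
                                   arousal = "arousal_mean"),
                       hc_flavor = "HC2",
                       reference_levels = c(pos = "noun")) {
  typ <- c("typ_valence", "typ_emotionality", "typ_arousal")
  need <- c(unname(ratings), typ, setdiff(controls, "pos"))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  num_cols <- intersect(c(unname(ratings), typ, controls), names(data))
  num_cols <- num_cols[vapply(data[num_cols], is.numeric, TRUE)]
  corr <- spearman_matrix(data[num_cols])
  hier <- lapply(names(ratings), function(r) {
    others <- unname(ratings[setdiff(names(ratings), r)])
    hierarchical_regression(
      data, dv = ratings[[r]],
      step_terms = list(`Step 1 (Controls)` = controls,
                        `Step 2 (Other ratings)` = others,
                        `Step 3 (Form typicality)` = typ),
      hc_flavor = hc_flavor, reference_levels = reference_levels)
  })
  names(hier) <- names(ratings)
  structure(list(correlations = corr, hier = hier), class = "study2_result")
}

#' Study-3 driver: 5-step hierarchies on item-level behavioural data
#'
#' For a megastudy-style item table with a behavioural dependent variable
#' (mean lexical-decision RT or error rate), fits the two 5-step hierarchical
#' robust regressions: controls; affective ratings; their interactions with
#' arousal; typicality measures; typicality interactions (order "a") — and
#' the same with the rating and typicality blocks swapped (order "b").  The
#' final-step model is identical across orders; the orders differ in which
#' block gets credit for shared variance.
#'
#' @param data Merged item table (must contain `dv`, the controls, the three
#'   ratings and the three typicality columns).
#' @param dv Dependent-variable column name (e.g. `"rt"` or `"error_rate"`).
#' @inheritParams run_study2
#' @return List of class `study3_result` with elements `a` and `b`
#'   ([hierarchical_regression()] results).
#' @export
run_study3 <- function(data, dv, controls,
                       ratings = c(valence = "valence_mean",
                                   emotionality = "emotionality",
                                   arousal = "arousal_mean"),
                       hc_flavor = "HC2",
                       reference_levels = c(pos = "noun")) {
  if (is.null(data[[dv]])) stop("missing dependent-variable column: ", dv)
  v <- ratings[["valence"]]; e <- ratings[["emotionality"]]
  a <- ratings[["arousal"]]
  rate_block <- unname(ratings)
  rate_inter <- c(paste(v, a, sep = ":"), paste(e, a, sep = ":"))
  typ_block <- c("typ_valence", "typ_emotionality", "typ_arousal")
  typ_inter <- c("typ_valence:typ_arousal", "typ_emotionality:typ_arousal")
  steps_a <- list(`Step 1 (Controls)` = controls,
                  `Step 2a (Affective ratings)` = rate_block,
                  `Step 3a (Rating interactions)` = rate_inter,
                  `Step 4a (Form typicality)` = typ_block,
                  `Step 5a (Typicality interactions)` = typ_inter)
  steps_b <- list(`Step 1 (Controls)` = controls,
                  `Step 2b (Form typicality)` = typ_block,
                  `Step 3b (Typicality interactions)` = typ_inter,
                  `Step 4b (Affective ratings)` = rate_block,
                  `Step 5b (Rating interactions)` = rate_inter)
  structure(list(
    a = hierarchical_regression(data, dv, steps_a, hc_flavor,
                                reference_levels),
    b = hierarchical_regression(data, dv, steps_b, hc_flavor,
                                reference_levels)),
    class = "study3_result")
}
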