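# Shared brute-force oracles and small generators.  These are written from
# first principles (base R only) and deliberately do not reuse package
# internals, so they can check the implementation independently.

# RSS of an OLS fit with intercept on the given columns, via .lm.fit.
rss_oracle <- function(X, y, cols) {
  f <- .lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  sum(f$residuals^2)
}

# Exhaustive best subset per size by enumerating every column combination.
enum_best_oracle <- function(X, y, kmax) {
  p <- ncol(X)
  lapply(seq_len(kmax), function(k) {
    combs <- combn(p, k)
    rss <- apply(combs, 2, function(cc) rss_oracle(X, y, cc))
    best <- which.min(rss)
    list(size = k, cols = sort(combs[, best]), rss = rss[best])
  })
}

# Textbook Welch one-way ANOVA (independent re-derivation).
welch_oracle <- function(values, groups) {
  g <- factor(groups)
  ni <- tabulate(g); mi <- tapply(values, g, mean); vi <- tapply(values, g, var)
  k <- nlevels(g); wi <- ni / vi; W <- sum(wi)
  mw <- sum(wi * mi) / W
  num <- sum(wi * (mi - mw)^2) / (k - 1)
  lam <- sum((1 - wi / W)^2 / (ni - 1))
  den <- 1 + 2 * (k - 2) * lam / (k^2 - 1)
  df2 <- (k^2 - 1) / (3 * lam)
  list(F = num / den, df1 = k - 1, df2 = df2,
       p = pf(num / den, k - 1, df2, lower.tail = FALSE))
}

# A small ready-to-model lexicon with planted affect.
toy_lexicon <- function(n = 300, seed = 42, target_r2 = c(valence = 0.2,
                                                          arousal = 0.2)) {
  lex <- generate_lexicon(n, seed = seed, excluded_pos_rate = 0,
                          prefix_rate = 0)
  plant_affect(lex, seed = seed + 1, target_r2 = target_r2,
               disagreement_rate = 0)
}

fixture_path <- function(name)
  system.file("extdata", name, package = "formtypic", mustWork = TRUE)
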