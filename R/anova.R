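#' Bartlett's test of homogeneity of variance
#'
#' Classical Bartlett chi-squared test that the groups share a common
#' variance; used as the gate for switching from classical to Welch ANOVA.
#'
#' @param values Numeric vector.
#' @param groups Group labels (coerced to factor), same length as `values`.
#' @return List with `chi_sq`, `df` (= groups - 1) and `p`.
#' @export
bartlett_test <- function(values, groups) {
  g <- factor(groups)
  ni <- tabulate(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(ni < 2L))
    stop("group(s) with fewer than 2 observations: ",
         paste(levels(g)[ni < 2L], collapse = ", "))
  vi <- tapply(values, g, var)
  n <- length(values)
  k <- nlevels(g)
  sp2 <- sum((ni - 1) * vi) / (n - k)
  stat <- ((n - k) * log(sp2) - sum((ni - 1) * log(vi))) /
    (1 + (sum(1 / (ni - 1)) - 1 / (n - k)) / (3 * (k - 1)))
  list(chi_sq = stat, df = k - 1L, p = pchisq(stat, k - 1L, lower.tail = FALSE))
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F test for equality of group means under unequal variances, with
#' Welch-Satterthwaite denominator degrees of freedom (generally
#' non-integer), plus the omega-squared effect size
#' `df1 * (F - 1) / (df1 * (F - 1) + N)`.
#'
#' @inheritParams bartlett_test
#' @return List of class `welch_anova`: `F`, `df1`, `df2`, `p`, `omega_sq`,
#'   `n`.
#' @export
welch_anova <- function(values, groups) {
  g <- factor(groups)
  ni <- tabulate(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(ni < 2L)) stop("group(s) with fewer than 2 observations")
  mi <- tapply(values, g, mean)
  vi <- tapply(values, g, var)
  if (any(vi == 0)) stop("zero-variance group(s): ",
                         paste(levels(g)[vi == 0], collapse = ", "))
  k <- nlevels(g)
  wi <- ni / vi
  W <- sum(wi)
  mw <- sum(wi * mi) / W
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  lambda <- sum((1 - wi / W)^2 / (ni - 1))
  B <- 1 + 2 * (k - 2) * lambda / (k^2 - 1)
  Fstat <- A / B
  df2 <- (k^2 - 1) / (3 * lambda)
  n <- length(values)
  omega <- (k - 1) * (Fstat - 1) / ((k - 1) * (Fstat - 1) + n)
  structure(list(F = Fstat, df1 = k - 1, df2 = df2,
                 p = pf(Fstat, k - 1, df2, lower.tail = FALSE),
                 omega_sq = omega, n = n),
            class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch's F(%d, %.2f) = %.3f, p = %.4g, omega^2 = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$omega_sq))
  invisible(x)
}

#' Games-Howell post hoc pairwise comparisons
#'
#' All pairwise mean comparisons under unequal variances and sizes: each pair
#' gets a Welch t statistic with Welch-Satterthwaite df, referred to the
#' studentized-range distribution with the full number of group means (which
#' is what controls the familywise error rate across the pairs).
#'
#' @inheritParams bartlett_test
#' @return Data frame with one row per unordered pair: `group_a`, `group_b`,
#'   `mean_diff` (a minus b), `se`, `t`, `df`, `p_adj`.
#' @export
games_howell <- function(values, groups) {
  g <- factor(groups)
  ni <- tabulate(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(ni < 2L)) stop("group(s) with fewer than 2 observations")
  mi <- as.vector(tapply(values, g, mean))
  vi <- as.vector(tapply(values, g, var))
  if (any(vi == 0)) stop("zero-variance group(s)")
  k <- nlevels(g)
  pairs <- combn(k, 2)
  out <- data.frame(group_a = levels(g)[pairs[1, ]],
                    group_b = levels(g)[pairs[2, ]])
  a <- pairs[1, ]; b <- pairs[2, ]
  se2 <- vi[a] / ni[a] + vi[b] / ni[b]
  out$mean_diff <- mi[a] - mi[b]
  out$se <- sqrt(se2)
  out$t <- out$mean_diff / out$se
  out$df <- se2^2 / ((vi[a] / ni[a])^2 / (ni[a] - 1) +
                       (vi[b] / ni[b])^2 / (ni[b] - 1))
  out$p_adj <- vapply(seq_len(ncol(pairs)),
                      function(i) ptukey_upper(abs(out$t[i]) * sqrt(2),
                                               nmeans = k, df = out$df[i]),
                      1)
  out
}

# Upper-tail probability of the studentized range (nmeans means, df error
# degrees of freedom) by direct double quadrature.  Base R's ptukey() is only
# accurate to ~1e-7; the adaptive quadrature here targets ~1e-10 so the
# two-group reduction to Welch's t holds to 1e-8.
ptukey_upper <- function(q, nmeans, df) {
  if (!is.finite(q)) return(if (q > 0) 0 else 1)
  if (q <= 0) return(1)
  k <- nmeans
  prange <- function(r)  # P(range of k iid std normals <= r), vectorized
    vapply(r, function(ri) {
      if (ri <= 0) return(0)
      k * integrate(function(z) dnorm(z) * (pnorm(z) - pnorm(z - ri))^(k - 1),
                    -Inf, Inf, rel.tol = 1e-11, abs.tol = 1e-13,
                    subdivisions = 500L)$value
    }, 1)
  if (!is.finite(df)) return(max(0, min(1, 1 - prange(q))))
  # density of s = sqrt(chi^2_df / df)
  lc <- log(2) + (df / 2) * log(df / 2) - lgamma(df / 2)
  fs <- function(s) exp(lc + (df - 1) * log(s) - df * s^2 / 2)
  cdf <- integrate(function(s) fs(s) * prange(q * s), 0, Inf,
                   rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
  max(0, min(1, 1 - cdf))
}

#' Spearman correlation matrix with p-values
#'
#' Rank correlations (average ranks for ties) between every pair of columns,
#' using pairwise-complete observations.  Two-sided p-values come from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.  Pairs where either
#' variable is constant (correlation undefined) are flagged `NA`.
#'
#' @param data Data frame or matrix of numeric variables.
#' @return List of class `spearman_matrix`: `rho` and `p` (symmetric
#'   matrices), `n` (pairwise complete counts).
#' @export
spearman_matrix <- function(data) {
  data <- as.data.frame(data)
  p <- ncol(data)
  nm <- colnames(data)
  rho <- pv <- nn <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  diag(rho) <- 1
  diag(pv) <- 0
  for (i in seq_len(p)) nn[i, i] <- sum(!is.na(data[[i]]))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    ok <- complete.cases(data[[i]], data[[j]])
    n <- sum(ok)
    nn[i, j] <- nn[j, i] <- n
    if (n < 3L) next
    x <- rank(data[[i]][ok]); y <- rank(data[[j]][ok])
    if (sd(x) == 0 || sd(y) == 0) next  # constant: undefined, stays NA
    r <- cor(x, y)
    rho[i, j] <- rho[j, i] <- r
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    pv[i, j] <- pv[j, i] <- 2 * pt(-abs(tt), n - 2)
  }
  structure(list(rho = rho, p = pv, n = nn), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("Spearman correlations (pairwise complete):\n")
  print(round(x$rho, digits))
  invisible(x)
}
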