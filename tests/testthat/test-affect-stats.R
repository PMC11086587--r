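set.seed(71)
vals3 <- c(rnorm(5, 0, 1), rnorm(5, 0.5, 2), rnorm(5, -0.3, 0.5))
grp3 <- rep(c("a", "b", "c"), each = 5)

test_that("bartlett_test matches the base-R oracle and its df structure", {
  got <- bartlett_test(vals3, grp3)
  want <- bartlett.test(vals3, factor(grp3))
  expect_equal(got$chi_sq, unname(want$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(want$parameter))
  expect_equal(got$p, want$p.value, tolerance = 1e-10)
  # four groups -> df 3
  v4 <- rnorm(40); g4 <- rep(letters[1:4], each = 10)
  expect_equal(bartlett_test(v4, g4)$df, 3L)
  # duplicated identical groups: statistic ~ 0
  v <- rep(rnorm(10), 2); g <- rep(c("x", "y"), each = 10)
  expect_lt(bartlett_test(v, g)$chi_sq, 1e-10)
  expect_error(bartlett_test(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("welch_anova equals oneway.test and the textbook oracle", {
  got <- welch_anova(vals3, grp3)
  base <- oneway.test(vals3 ~ factor(grp3), var.equal = FALSE)
  expect_equal(got$F, unname(base$statistic), tolerance = 1e-10)
  expect_equal(got$df1, unname(base$parameter[1]))
  expect_equal(got$df2, unname(base$parameter[2]), tolerance = 1e-10)
  expect_equal(got$p, base$p.value, tolerance = 1e-10)
  ora <- welch_oracle(vals3, grp3)
  expect_equal(got$F, ora$F, tolerance = 1e-10)
  expect_equal(got$df2, ora$df2, tolerance = 1e-10)
  # omega^2 follows the stated convention
  expect_equal(got$omega_sq,
               got$df1 * (got$F - 1) / (got$df1 * (got$F - 1) + got$n),
               tolerance = 1e-12)
  expect_error(welch_anova(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3)),
               "zero-variance")
})

test_that("two-group Welch F is the square of Welch's t", {
  set.seed(72)
  for (i in 1:10) {
    v <- c(rnorm(8, 0, 1), rnorm(12, 0.4, 2))
    g <- rep(c("a", "b"), c(8, 12))
    got <- welch_anova(v, g)
    tt <- t.test(v ~ g)
    expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(got$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("welch_anova reduces to classical ANOVA when balanced and equal-variance", {
  set.seed(73)
  v <- rnorm(1500, rep(c(0, 0.1, 0.2), each = 500))
  g <- rep(c("a", "b", "c"), each = 500)
  # enforce exactly equal group variances so the reduction is exact up to
  # the O(1/n) Welch denominator correction
  for (l in unique(g)) {
    i <- g == l
    v[i] <- mean(v[i]) + (v[i] - mean(v[i])) / sd(v[i])
  }
  w <- welch_anova(v, g)
  f <- summary(aov(v ~ factor(g)))[[1]]$`F value`[1]
  expect_lt(abs(w$F / f - 1), 0.01)
})

test_that("games_howell enumerates pairs and reduces to Welch's t for 2 groups", {
  v4 <- rnorm(60); g4 <- rep(letters[1:4], each = 15)
  gh <- games_howell(v4, g4)
  expect_equal(nrow(gh), 6L)  # C(4,2)
  expect_true(all(gh$p_adj >= 0 & gh$p_adj <= 1))
  # antisymmetry of mean differences: recompute with relabelled groups
  gh2 <- games_howell(v4, factor(g4, levels = rev(letters[1:4])))
  m1 <- gh$mean_diff[gh$group_a == "a" & gh$group_b == "b"]
  m2 <- gh2$mean_diff[gh2$group_a == "b" & gh2$group_b == "a"]
  expect_equal(m1, -m2, tolerance = 1e-12)
  # two-group reduction: studentized range with 2 means == Welch t
  set.seed(74)
  for (i in 1:5) {
    v <- c(rnorm(10, 0, 1), rnorm(14, 0.8, 2.5))
    g <- rep(c("a", "b"), c(10, 14))
    gh <- games_howell(v, g)
    tt <- t.test(v ~ g)
    expect_equal(gh$p_adj, tt$p.value, tolerance = 1e-8)
    expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-10)
  }
})

test_that("studentized-range quadrature agrees with base ptukey", {
  for (k in c(2, 3, 4, 6)) for (df in c(5, 17.3, 120)) for (q in c(0.5, 2, 4))
    expect_equal(formtypic:::ptukey_upper(q, k, df),
                 ptukey(q, k, df, lower.tail = FALSE), tolerance = 1e-5)
})

test_that("group statistics are invariant to relabeling", {
  w1 <- welch_anova(vals3, grp3)
  w2 <- welch_anova(vals3, setNames(c("zz", "mm", "qq"), NULL)[
    match(grp3, c("a", "b", "c"))])
  expect_equal(w1$F, w2$F, tolerance = 1e-12)
  expect_equal(w1$p, w2$p, tolerance = 1e-12)
})

test_that("spearman_matrix matches a rank-then-Pearson oracle with ties", {
  set.seed(75)
  d <- data.frame(x = sample(1:5, 40, TRUE),       # heavy ties
                  y = sample(1:8, 40, TRUE),
                  z = rnorm(40))
  d$mono <- exp(d$z)                               # monotone transform
  sm <- spearman_matrix(d)
  expect_equal(diag(sm$rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(sm$rho["z", "mono"], 1, tolerance = 1e-12)
  ora <- cor(rank(d$x), rank(d$y))
  expect_equal(sm$rho["x", "y"], ora, tolerance = 1e-12)
  expect_equal(sm$rho["x", "y"],
               cor(d$x, d$y, method = "spearman"), tolerance = 1e-12)
  # symmetric, p in [0,1]
  expect_equal(sm$rho, t(sm$rho))
  expect_true(all(sm$p >= 0 & sm$p <= 1, na.rm = TRUE))
  # constant column flagged missing
  d$const <- 3
  smc <- spearman_matrix(d)
  expect_true(is.na(smc$rho["const", "x"]))
  # pairwise-complete handling
  d2 <- d
  d2$x[1:5] <- NA
  smm <- spearman_matrix(d2[, c("x", "y")])
  expect_equal(smm$n["x", "y"], 35)
})
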