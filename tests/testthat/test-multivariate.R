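test_that("winsorization clips at interpolated percentiles and is idempotent", {
  expect_equal(winsorize(rep(3, 8)), rep(3, 8))
  x <- rnorm(40)
  expect_equal(winsorize(x, 0, 100), x)
  # independent percentile oracle (linear interpolation between order stats)
  v <- 1:10
  lo <- 1 + 0.9 * (10 - 1) * 0.1   # manual type-7 interpolation, 10th pctl
  hi <- 1 + 0.9 * (10 - 1) + 0.1 * 0  # 90th pctl of 1..10 = 9.1
  hi <- 9.1
  w <- winsorize(v, 10, 90)
  expect_equal(w, pmin(pmax(v, 1.9), 9.1))
  expect_equal(min(w), 1.9); expect_equal(max(w), 9.1)
  # interior order statistics untouched
  expect_equal(w[3:8], as.numeric(v[3:8]))
  # idempotence
  set.seed(2)
  y <- rcauchy(101)
  expect_equal(winsorize(winsorize(y)), winsorize(y))
  expect_error(winsorize(numeric(0)), "empty")
  expect_error(winsorize(1:5, 90, 10), "lo_pct < hi_pct")
})

test_that("Mardia statistics match the definitional double-sum oracle", {
  set.seed(7)
  X <- matrix(rnorm(10), 5, 2)
  got <- mardia_tests(X)
  want <- brute_mardia(X)
  expect_equal(got$b1p, want$b1p)
  expect_equal(got$b2p, want$b2p)
  expect_equal(got$skew_df, 2 * 3 * 4 / 6)
})

test_that("Mardia behaves at the multinormal null and on symmetric data", {
  set.seed(11)
  p <- 3
  X <- matrix(rnorm(4000 * p), ncol = p)
  m <- mardia_tests(X)
  expect_lt(abs(m$b2p - p * (p + 2)), 0.5)   # E[b2p] = p(p+2)
  # univariate symmetric sample: skewness near zero, not significant
  xs <- c(-(1:50), 1:50) / 10
  m1 <- mardia_tests(matrix(xs, ncol = 1))
  expect_lt(m1$b1p, 1e-10)
  expect_error(mardia_tests(matrix(rnorm(4), 2, 2)), "n > p")
})

test_that("Henze-Zirkler holds its nominal size and flags singular input", {
  set.seed(21)
  rej <- mean(replicate(200, {
    X <- matrix(rnorm(500 * 3), ncol = 3)
    henze_zirkler(X)$p_value < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)

  X <- matrix(rnorm(60), 30, 2)
  dup <- cbind(X, X[, 1])
  expect_true(henze_zirkler(dup)$unstable)

  # p = 1 agrees with a scalar re-derivation of the same statistic
  set.seed(3)
  x <- rnorm(40)
  hz <- henze_zirkler(matrix(x, ncol = 1))
  n <- 40; p <- 1
  b <- ((2 * p + 1) * n / 4)^(1 / (p + 4)) / sqrt(2)
  s2 <- mean((x - mean(x))^2)
  di <- (x - mean(x))^2 / s2
  Dij <- outer(x, x, "-")^2 / s2
  stat <- n * (mean(exp(-b^2 / 2 * Dij)) -
                 2 * (1 + b^2)^(-1 / 2) * mean(exp(-b^2 / (2 * (1 + b^2)) * di)) +
                 (1 + 2 * b^2)^(-1 / 2))
  expect_equal(hz$hz_stat, stat)
})

test_that("robust Mahalanobis distance is zero iff group centers coincide", {
  tb <- make_subjects(12, 12, p = 3, seed = 13)
  # duplicate the IBS block as HC: identical groups
  df <- as.data.frame(tb)
  ibs <- df[df$group == "IBS", ]
  hc <- ibs
  hc$group <- "HC"; hc$subject_id <- paste0("c", seq_len(nrow(hc)))
  same <- subject_table(rbind(hc, ibs), regions = attr(tb, "regions"),
                        normalized = TRUE)
  res <- robust_mahalanobis(same, c("f1", "f2", "f3"))
  expect_equal(res$distance, 0, tolerance = 1e-10)
  expect_gt(res$p_value, 0.99)
})

test_that("with no winsorization and mean centers the classical distance is recovered", {
  tb <- make_subjects(15, 18, p = 3, effect = 0.8, seed = 17)
  res <- robust_mahalanobis(tb, c("f1", "f2", "f3"),
                            winsor_limits = c(0, 100), center = "mean",
                            ridge = FALSE)
  # direct linear-solve oracle
  fm <- feature_matrix(tb, c("f1", "f2", "f3"))
  X1 <- fm$x[fm$y == 0, ]; X2 <- fm$x[fm$y == 1, ]
  S <- ((nrow(X1) - 1) * cov(X1) + (nrow(X2) - 1) * cov(X2)) /
    (nrow(X1) + nrow(X2) - 2)
  diff <- colMeans(X1) - colMeans(X2)
  D_oracle <- sqrt(drop(t(diff) %*% solve(S, diff)))
  expect_equal(res$distance, D_oracle, tolerance = 1e-10)
  # Hotelling framing
  expect_equal(res$t2, 15 * 18 / 33 * D_oracle^2, tolerance = 1e-10)
  expect_equal(res$df1, 3); expect_equal(res$df2, 29)
})

test_that("robust distance approximates |mean difference|/SD for one clean feature", {
  # On large symmetric outlier-free samples the median centers coincide with
  # the means, so the robust distance without clipping matches the classical
  # standardized mean difference. (Clipping at the 10th/90th percentiles is
  # exercised separately: it shrinks the pooled SD of clean normal data by a
  # known ~16%, inflating D by the reciprocal factor.)
  set.seed(23)
  n <- 4000
  df <- data.frame(subject_id = as.character(seq_len(2 * n)),
                   group = rep(c("HC", "IBS"), each = n),
                   sex = "F", age = 30,
                   v = c(rnorm(n, 1, 1), rnorm(n, 0, 1)))
  tb <- subject_table(df, regions = "v", normalized = TRUE)
  res <- robust_mahalanobis(tb, "v", winsor_limits = c(0, 100))
  classical <- abs(mean(df$v[1:n]) - mean(df$v[-(1:n)])) /
    sqrt(((n - 1) * var(df$v[1:n]) + (n - 1) * var(df$v[-(1:n)])) / (2 * n - 2))
  expect_lt(abs(res$distance - classical) / classical, 0.05)
  # default clipping inflates D by roughly 1/0.84, never deflates it
  res_w <- robust_mahalanobis(tb, "v")
  expect_gt(res_w$distance, res$distance)
  expect_lt(res_w$distance / res$distance, 1.4)
})

test_that("robust distance is invariant to subject order, feature order and affine maps", {
  tb <- make_subjects(14, 16, p = 3, effect = 0.5, seed = 29)
  base <- robust_mahalanobis(tb, c("f1", "f2", "f3"))
  perm <- tb[sample(nrow(tb)), ]
  expect_equal(robust_mahalanobis(perm, c("f1", "f2", "f3"))$distance,
               base$distance)
  expect_equal(robust_mahalanobis(tb, c("f3", "f1", "f2"))$distance,
               base$distance)
  aff <- tb
  aff$f1 <- 100 + 3 * aff$f1; aff$f2 <- -2 + 0.5 * aff$f2; aff$f3 <- 7 * aff$f3
  expect_equal(robust_mahalanobis(aff, c("f1", "f2", "f3"))$distance,
               base$distance, tolerance = 1e-8)
})

test_that("robust Mahalanobis demands enough subjects per feature", {
  tb <- make_subjects(3, 3, p = 6, seed = 31)
  expect_error(robust_mahalanobis(tb, paste0("f", 1:6)), "p \\+ 1")
})

test_that("the permutation test handles degenerate, separated and tiny cohorts", {
  # identical subjects: every permuted statistic ties the observed one
  df <- data.frame(subject_id = as.character(1:10),
                   group = rep(c("HC", "IBS"), 5), sex = "F", age = 30,
                   v1 = 1, v2 = 2)
  tb <- subject_table(df, regions = c("v1", "v2"), normalized = TRUE)
  expect_equal(permutation_test(tb, c("v1", "v2"), n_perm = 50, seed = 1)$p_empirical, 1)

  # two groups of 5 split by ten pooled SDs on three features
  tb <- make_subjects(5, 5, p = 3, effect = 10, seed = 37)
  pt <- permutation_test(tb, c("f1", "f2", "f3"), n_perm = 1000, seed = 2)
  expect_lte(pt$p_empirical, 0.01)

  # determinism by seed
  pt2 <- permutation_test(tb, c("f1", "f2", "f3"), n_perm = 1000, seed = 2)
  expect_identical(pt$p_empirical, pt2$p_empirical)
  expect_error(permutation_test(tb, "f1", n_perm = 0), "n_perm")

  # add-one smoothing never reports zero
  pt3 <- permutation_test(tb, c("f1", "f2", "f3"), n_perm = 99, seed = 3,
                          add_one = TRUE)
  expect_gte(pt3$p_empirical, 1 / 100)
})
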