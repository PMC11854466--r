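# Run code under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards so package functions never clobber user RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

#' Winsorize a sample at percentile limits
#'
#' Values below the `lo_pct` percentile are set to it and values above the
#' `hi_pct` percentile are set to it; order statistics between the limits are
#' unchanged. Percentiles use linear interpolation between order statistics
#' (quantile type 7), stated explicitly because percentile conventions differ
#' across ecosystems.
#'
#' @param x Nonempty numeric sample (`NA`s preserved in place).
#' @param lo_pct,hi_pct Percentile limits, `0 <= lo_pct < hi_pct <= 100`.
#' @return The clipped sample, same length and order as `x`.
#' @export
winsorize <- function(x, lo_pct = 10, hi_pct = 90) {
  if (!length(x) || all(is.na(x))) stop("cannot winsorize an empty sample")
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100)) {
    stop("need 0 <= lo_pct < hi_pct <= 100")
  }
  q <- stats::quantile(x, c(lo_pct, hi_pct) / 100, na.rm = TRUE,
                       names = FALSE, type = 7)
  pmin(pmax(x, q[1]), q[2])
}

# Mahalanobis-type cross products G = Xc S^{-1} Xc' used by both normality
# tests; returns NULL on singular covariance.
scaled_gram <- function(X, ml = TRUE) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / if (ml) n else (n - 1)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) return(NULL)
  Xc %*% Sinv %*% t(Xc)
}

#' Mardia's multivariate skewness and kurtosis tests
#'
#' Multivariate skewness `b1p = mean_{i,j} (g_ij)^3` and kurtosis
#' `b2p = mean_i (g_ii)^2`, where `g` is the Mahalanobis cross-product matrix
#' computed with the maximum-likelihood covariance. Asymptotic reference
#' distributions: `n b1p / 6 ~ chi^2` with `p(p+1)(p+2)/6` df, and
#' `(b2p - p(p+2)) / sqrt(8 p (p+2) / n) ~ N(0, 1)`.
#'
#' @param X Numeric matrix (n observations x p variables, n > p).
#' @param group_scope Label recorded in the result (`"all"`, `"HC"`,
#'   `"IBS"`, ...).
#' @return List of class `normality_result` with `skew_stat`, `skew_df`,
#'   `skew_p`, `kurt_stat` (the z-score), `kurt_p`, `b1p`, `b2p`,
#'   `unstable` flag.
#' @export
mardia_tests <- function(X, group_scope = "all") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("Mardia's test requires n > p")
  if (!all(is.finite(X))) stop("non-finite entries in X")
  G <- scaled_gram(X, ml = TRUE)
  if (is.null(G)) {
    return(structure(list(test = "mardia", group_scope = group_scope,
                          unstable = TRUE,
                          message = "singular sample covariance"),
                     class = "normality_result"))
  }
  b1p <- mean(G^3)
  b2p <- mean(diag(G)^2)
  skew_stat <- n * b1p / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  kurt_z <- (b2p - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  structure(list(
    test = "mardia", group_scope = group_scope, n = n, p = p,
    b1p = b1p, b2p = b2p,
    skew_stat = skew_stat, skew_df = skew_df,
    skew_p = stats::pchisq(skew_stat, skew_df, lower.tail = FALSE),
    kurt_stat = kurt_z,
    kurt_p = 2 * stats::pnorm(-abs(kurt_z)),
    unstable = !is.finite(b1p) || !is.finite(b2p)
  ), class = "normality_result")
}

#' Henze-Zirkler multivariate normality test
#'
#' The HZ statistic with its lognormal approximation for the p-value. The
#' smoothing parameter is the standard
#' `b = ((2p+1) n / 4)^(1/(p+4)) / sqrt(2)`. Singular covariance or
#' non-finite intermediates are reported through an `unstable` flag rather
#' than raised, matching the numerical-instability behaviour this statistic
#' is known for on near-collinear morphometry panels.
#'
#' @inheritParams mardia_tests
#' @return List of class `normality_result` with `hz_stat`, `p_value`,
#'   `unstable`.
#' @export
henze_zirkler <- function(X, group_scope = "all") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("Henze-Zirkler test requires n > p")
  G <- scaled_gram(X, ml = TRUE)
  if (is.null(G)) {
    return(structure(list(test = "henze-zirkler", group_scope = group_scope,
                          unstable = TRUE,
                          message = "singular sample covariance"),
                     class = "normality_result"))
  }
  d_i <- diag(G)                               # squared distances to the mean
  Dij <- outer(d_i, d_i, "+") - 2 * G          # pairwise squared distances
  b <- ((2 * p + 1) * n / 4)^(1 / (p + 4)) / sqrt(2)
  b2 <- b^2
  t1 <- mean(exp(-b2 / 2 * Dij))
  t2 <- 2 * (1 + b2)^(-p / 2) * mean(exp(-b2 / (2 * (1 + b2)) * d_i))
  hz <- n * (t1 - t2 + (1 + 2 * b2)^(-p / 2))

  a <- 1 + 2 * b2
  wb <- (1 + b2) * (1 + 3 * b2)
  mu <- 1 - a^(-p / 2) * (1 + p * b2 / a + p * (p + 2) * b2^2 / (2 * a^2))
  s2 <- 2 * (1 + 4 * b2)^(-p / 2) +
    2 * a^(-p) * (1 + 2 * p * b2^2 / a^2 + 3 * p * (p + 2) * b2^4 / (4 * a^4)) -
    4 * wb^(-p / 2) * (1 + 3 * p * b2^2 / (2 * wb) + p * (p + 2) * b2^4 / (2 * wb^2))
  unstable <- !is.finite(hz) || !is.finite(mu) || !is.finite(s2) ||
    s2 <= 0 || mu <= 0 || hz <= 0
  pv <- if (unstable) NA_real_ else {
    lmu <- log(sqrt(mu^4 / (s2 + mu^2)))
    lsd <- sqrt(log((s2 + mu^2) / mu^2))
    stats::plnorm(hz, lmu, lsd, lower.tail = FALSE)
  }
  structure(list(test = "henze-zirkler", group_scope = group_scope,
                 n = n, p = p, b = b, hz_stat = hz, p_value = pv,
                 unstable = unstable),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("%s multivariate normality (scope: %s)\n", x$test, x$group_scope))
  if (isTRUE(x$unstable)) {
    cat("  unstable:", if (!is.null(x$message)) x$message else "non-finite intermediates", "\n")
  } else if (x$test == "mardia") {
    cat(sprintf("  skewness b1p = %.4g, chi2(%d) = %.4g, p = %.3g\n",
                x$b1p, x$skew_df, x$skew_stat, x$skew_p))
    cat(sprintf("  kurtosis b2p = %.4g, z = %.3f, p = %.3g\n",
                x$b2p, x$kurt_stat, x$kurt_p))
  } else {
    cat(sprintf("  HZ = %.4g, p = %.3g\n", x$hz_stat, x$p_value))
  }
  invisible(x)
}

#' Robust Mahalanobis distance between the HC and IBS group centers
#'
#' Outlier-resistant multivariate separation: each feature is winsorized
#' (default 10th/90th percentiles, on the pooled sample), group centers are
#' per-group medians of the winsorized data, and the covariance is the pooled
#' within-group covariance of the winsorized group-centered data. The
#' distance `D = sqrt((m_HC - m_IBS)' Sigma^{-1} (m_HC - m_IBS))` is framed
#' as a two-sample Hotelling statistic `T2 = (n1 n2 / (n1 + n2)) D^2` with
#' `F = (n1+n2-p-1) / (p (n1+n2-2)) * T2` on `(p, n1+n2-p-1)` df.
#'
#' A small ridge (`1e-6 * trace(Sigma)/p`) is added when the covariance
#' condition number exceeds `1e8`, as near-singular pooled covariances are
#' the norm when p approaches the sample size.
#'
#' @param table A [subject_table()] with both groups present.
#' @param features Feature columns (complete cases are used).
#' @param winsor_limits Percentile pair, default `c(10, 90)`; use
#'   `c(0, 100)` to disable clipping.
#' @param center `"median"` (default, robust) or `"mean"` (classical).
#' @param winsor_scope `"pooled"` (default) or `"group"`.
#' @param ridge Logical; apply conditional ridge regularization.
#' @return List of class `mahalanobis_result`: `distance`, `t2`, `f_stat`,
#'   `df1`, `df2`, `p_value`, plus the configuration used.
#' @export
robust_mahalanobis <- function(table, features,
                               winsor_limits = c(10, 90),
                               center = c("median", "mean"),
                               winsor_scope = c("pooled", "group"),
                               ridge = TRUE) {
  center <- match.arg(center)
  winsor_scope <- match.arg(winsor_scope)
  stopifnot(inherits(table, "subject_table"))
  fm <- feature_matrix(table, features)
  keep <- stats::complete.cases(fm$x)
  X <- fm$x[keep, , drop = FALSE]
  y <- fm$y[keep]
  n1 <- sum(y == 0); n2 <- sum(y == 1)
  if (n1 < 2 || n2 < 2) stop("need >= 2 subjects in each group")
  p <- ncol(X); n <- n1 + n2
  if (n <= p + 1) {
    stop("n1 + n2 <= p + 1: reduce the feature panel or regularize ",
         "(", n, " subjects for ", p, " features)")
  }

  W <- X
  for (j in seq_len(p)) {
    if (winsor_scope == "pooled") {
      W[, j] <- winsorize(X[, j], winsor_limits[1], winsor_limits[2])
    } else {
      W[y == 0, j] <- winsorize(X[y == 0, j], winsor_limits[1], winsor_limits[2])
      W[y == 1, j] <- winsorize(X[y == 1, j], winsor_limits[1], winsor_limits[2])
    }
  }

  loc <- if (center == "median") {
    function(M) apply(M, 2, stats::median)
  } else {
    colMeans
  }
  m1 <- loc(W[y == 0, , drop = FALSE])
  m2 <- loc(W[y == 1, , drop = FALSE])

  C1 <- sweep(W[y == 0, , drop = FALSE], 2, m1)
  C2 <- sweep(W[y == 1, , drop = FALSE], 2, m2)
  Sigma <- (crossprod(C1) + crossprod(C2)) / (n - 2)

  ridged <- FALSE
  if (ridge) {
    kap <- tryCatch(kappa(Sigma, exact = TRUE), error = function(e) Inf)
    if (!is.finite(kap) || kap > 1e8) {
      Sigma <- Sigma + diag(1e-6 * sum(diag(Sigma)) / p, p)
      ridged <- TRUE
    }
  }

  diff <- m1 - m2
  sol <- tryCatch(solve(Sigma, diff), error = function(e) {
    stop("covariance is singular even after regularization")
  })
  d2 <- drop(crossprod(diff, sol))
  D <- sqrt(max(d2, 0))
  t2 <- n1 * n2 / n * d2
  df1 <- p; df2 <- n - p - 1
  f_stat <- df2 / (p * (n - 2)) * t2
  structure(list(distance = D, t2 = t2, f_stat = f_stat,
                 df1 = df1, df2 = df2,
                 p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 n1 = n1, n2 = n2, p = p,
                 winsor_limits = winsor_limits, center = center,
                 winsor_scope = winsor_scope, ridged = ridged),
            class = "mahalanobis_result")
}

#' @export
print.mahalanobis_result <- function(x, ...) {
  cat(sprintf("Robust Mahalanobis separation (HC n=%d vs IBS n=%d, p=%d features)\n",
              x$n1, x$n2, x$p))
  cat(sprintf("  winsorized at (%g, %g) pctl [%s], centers: %s%s\n",
              x$winsor_limits[1], x$winsor_limits[2], x$winsor_scope,
              x$center, if (x$ridged) ", ridge-regularized" else ""))
  cat(sprintf("  D = %.4f, T2 = %.4f, F(%d, %d) = %.4f, p = %.4g\n",
              x$distance, x$t2, x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}

#' Permutation test for a multivariate group difference
#'
#' Observed statistic `T = sum over features of (mean_HC - mean_IBS)^2`; the
#' null distribution is built by reshuffling group labels (preserving group
#' sizes). The empirical p-value counts permuted statistics greater than or
#' equal to the observed one (`p = #\{T_perm >= T_obs\} / n_perm`); the
#' strict "greater than" rule would report p = 0 on degenerate data.
#' `add_one = TRUE` applies the `(1 + #) / (1 + n_perm)` smoothing.
#'
#' @param table A [subject_table()] with both groups, or a numeric matrix if
#'   `labels` is given.
#' @param features Feature columns (ignored when `table` is a matrix).
#' @param n_perm Number of permutations (>= 1), default 1000.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param labels Optional 0/1 vector when `table` is a matrix.
#' @param add_one Apply add-one smoothing to the empirical p.
#' @return List of class `permutation_result`: `observed_stat`, `n_perm`,
#'   `p_empirical`, `seed`.
#' @export
permutation_test <- function(table, features = NULL, n_perm = 1000,
                             seed = NULL, labels = NULL, add_one = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(table, "subject_table")) {
    fm <- feature_matrix(table, features)
    X <- fm$x; y <- fm$y
  } else {
    X <- as.matrix(table); y <- labels
    if (is.null(y)) stop("labels required when passing a matrix")
  }
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n1 <- sum(y == 0); n2 <- sum(y == 1)
  if (n1 < 1 || n2 < 1) stop("both groups must be present")
  n <- n1 + n2

  stat <- function(idx0) {
    # idx0: indices of the group coded 0
    s0 <- colSums(X[idx0, , drop = FALSE])
    stot <- .colSums(X, n, ncol(X))
    m0 <- s0 / n1
    m1 <- (stot - s0) / n2
    sum((m0 - m1)^2)
  }
  obs <- stat(which(y == 0))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample.int(n, n1)), numeric(1))
  })
  p <- if (add_one) (1 + sum(perm >= obs)) / (1 + n_perm) else mean(perm >= obs)
  structure(list(observed_stat = obs, n_perm = n_perm, p_empirical = p,
                 seed = seed, n1 = n1, n2 = n2),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%d vs %d, %d permutations%s)\n",
              x$n1, x$n2, x$n_perm,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  cat(sprintf("  T_obs = %.6g, empirical p = %.4g\n",
              x$observed_stat, x$p_empirical))
  invisible(x)
}
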