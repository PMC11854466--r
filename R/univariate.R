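#' Pooled standard deviation of two groups
#'
#' `sp = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param n1,n2 Group sizes (n1 + n2 > 2).
#' @param s1,s2 Group standard deviations (>= 0).
#' @return The pooled SD (vectorized over its arguments).
#' @export
pooled_sd <- function(n1, s1, n2, s2) {
  if (any(n1 + n2 <= 2)) stop("pooled SD requires n1 + n2 > 2")
  if (any(s1 < 0) || any(s2 < 0)) stop("SDs must be >= 0")
  sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
}

#' Cohen's d with 95% confidence interval from group summaries
#'
#' Standardized mean difference `d = (mean_HC - mean_IBS) / sp` using the
#' pooled SD; positive values indicate larger volumes/scores in healthy
#' controls. The 95% interval is
#' `d +/- 1.96 * sqrt((n1+n2)/(n1*n2) + d^2 / (2 (n1+n2)))`.
#'
#' When applied to a `cohort_summary`, one record per region is returned.
#'
#' @param n1,mean1,s1 HC group size, mean, SD (or vectors thereof).
#' @param n2,mean2,s2 IBS group size, mean, SD.
#' @param feature Optional feature label(s).
#' @return Data frame with columns `feature`, `d`, `sp`, `ci_lo`, `ci_hi`,
#'   `n1`, `n2`.
#' @export
cohens_d <- function(n1, mean1, s1, n2, mean2, s2, feature = NA_character_) {
  sp <- pooled_sd(n1, s1, n2, s2)
  diff <- mean1 - mean2
  if (any(sp == 0 & diff != 0)) {
    stop("zero pooled SD with unequal means: effect size is infinite")
  }
  d <- ifelse(sp == 0, 0, diff / sp)
  n <- n1 + n2
  se <- sqrt(n / (n1 * n2) + d^2 / (2 * n))
  data.frame(feature = feature, d = d, sp = sp,
             ci_lo = d - 1.96 * se, ci_hi = d + 1.96 * se,
             n1 = n1, n2 = n2, stringsAsFactors = FALSE)
}

#' @rdname cohens_d
#' @param summary A `cohort_summary` (see [cohort_summary()]).
#' @export
cohens_d_summary <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  cohens_d(summary$n_hc, summary$mean_hc, summary$sd_hc,
           summary$n_ibs, summary$mean_ibs, summary$sd_ibs,
           feature = summary$region)
}

# Mann-Whitney U with ties counted 0.5, via midranks.
mann_whitney_u <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
}

#' Cliff's delta with Mann-Whitney test
#'
#' Nonparametric effect size `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) /
#' (nx * ny)`, equivalently `2U/(nx*ny) - 1` with ties counted 0.5 in U.
#' `delta = +1` iff every value of `x` strictly exceeds every value of `y`.
#' The two-sided p-value uses exact enumeration for small tie-free samples
#' and the tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric samples (nonempty); by convention `x` = HC, `y` = IBS,
#'   so positive delta means higher values in healthy controls.
#' @param exact_max Largest group size for which the exact distribution is
#'   used when there are no ties.
#' @return List of class `cliff_result`: `delta`, `u_stat`, `p_raw`, `nx`,
#'   `ny`.
#' @export
cliffs_delta <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  u <- mann_whitney_u(x, y)
  delta <- 2 * u / (nx * ny) - 1
  ties <- anyDuplicated(c(x, y)) > 0
  p <- if (!ties && max(nx, ny) <= exact_max) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  structure(list(delta = delta, u_stat = u, p_raw = p, nx = nx, ny = ny),
            class = "cliff_result")
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, preserving order. `m` defaults to the number of
#' p-values but may be set larger (e.g. when only a subset of a family is
#' passed).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p)
}

#' Strength-band label for an effect size or correlation
#'
#' Assigns the conventional interpretive band from the absolute value.
#' Cliff's delta bands: negligible (0.00--0.14), small (0.15--0.33), medium
#' (0.34--0.47), large (0.48--1.00). Spearman bands: negligible (< 0.20),
#' weak (0.20--0.39), moderate (0.40--0.59), strong (0.60--0.79), very
#' strong (0.80--1.00). Band endpoints are closed; values falling in the
#' unprinted gaps between bands are assigned to the nearer band.
#'
#' @param value Numeric in `[-1, 1]` (vectorized).
#' @param scheme `"cliff"` or `"spearman"`.
#' @return Character vector of band labels.
#' @export
band_label <- function(value, scheme = c("cliff", "spearman")) {
  scheme <- match.arg(scheme)
  if (any(abs(value) > 1, na.rm = TRUE)) stop("|value| must be <= 1")
  a <- abs(value)
  if (scheme == "cliff") {
    # gap midpoints: 0.145, 0.335, 0.475
    cut(a, breaks = c(-Inf, 0.145, 0.335, 0.475, Inf),
        labels = c("negligible", "small", "medium", "large"),
        right = FALSE) |> as.character()
  } else {
    cut(a, breaks = c(-Inf, 0.20, 0.395, 0.595, 0.795, Inf),
        labels = c("negligible", "weak", "moderate", "strong", "very strong"),
        right = FALSE) |> as.character()
  }
}

#' Spearman rank-correlation matrix
#'
#' Pairwise-complete Spearman correlations between the requested features,
#' with unit diagonal. Pairs with fewer than `min_obs` complete observations
#' and constant features yield `NA` entries (with a warning) rather than
#' silent zeros.
#'
#' @param table A [subject_table()] (or data frame).
#' @param features Character vector of >= 2 feature columns.
#' @param min_obs Minimum complete observations per pair (default 3).
#' @return Symmetric correlation matrix.
#' @export
spearman_matrix <- function(table, features, min_obs = 3) {
  df <- as.data.frame(table)[, features, drop = FALSE]
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  const <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && all(v == v[1])
  })
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  # enforce the minimum-observations rule pair by pair
  obs <- crossprod(!is.na(x))
  rho[obs < min_obs] <- NA_real_
  if (any(const)) {
    warning("constant feature(s): ", paste(features[const], collapse = ", "),
            "; correlations set to NA")
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- ifelse(const, NA_real_, 1)
  rho
}

#' Per-feature univariate group comparison report
#'
#' For each feature: group medians and IQRs, Mann-Whitney U, raw and
#' Bonferroni-adjusted p-values, Cliff's delta and its strength band.
#' Positive delta indicates higher values in healthy controls.
#'
#' @param table A [subject_table()].
#' @param features Feature columns to compare.
#' @param m Number of comparisons for the Bonferroni correction (defaults to
#'   the number of features).
#' @return Data frame with one row per feature.
#' @export
univariate_report <- function(table, features, m = length(features)) {
  stopifnot(inherits(table, "subject_table"))
  hc <- table$group == "HC"
  rows <- lapply(features, function(f) {
    v <- table[[f]]
    cr <- cliffs_delta(v[hc], v[!hc])
    data.frame(
      feature = f,
      median_hc = stats::median(v[hc], na.rm = TRUE),
      iqr_hc = stats::IQR(v[hc], na.rm = TRUE),
      median_ibs = stats::median(v[!hc], na.rm = TRUE),
      iqr_ibs = stats::IQR(v[!hc], na.rm = TRUE),
      u_stat = cr$u_stat, p_raw = cr$p_raw,
      delta = cr$delta,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, m = m)
  out$band <- band_label(out$delta, "cliff")
  out
}
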