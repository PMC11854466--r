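#' Per-feature reproducibility record across two analyses
#'
#' Combines the effect-size estimates of one feature from two analyses
#' (cohorts, software versions, or processing streams) into the composite
#' reproducibility score `S = sigma + omega + epsilon`, where `sigma` is 1
#' when the effect directions agree, `omega` is 1 when the 95% confidence
#' intervals overlap (closed intervals: touching endpoints count), and
#' `epsilon = min(|d_A|, |d_B|)` is the minimum absolute effect magnitude.
#'
#' Exact-zero effects (a real possibility when d is computed from rounded
#' summary tables) need a convention. Under the default `"positive"` rule
#' the direction is the boolean `d > 0`, so zeros group with negative
#' effects; two zeros, or a zero paired with a negative effect, count as
#' consistent. `"conservative"` sets `sigma = 0` whenever exactly one of
#' `d_A`, `d_B` is 0 (direction not confirmed; two zeros still agree), and
#' `"lenient"` counts any zero as compatible with either direction.
#'
#' @param rec_A,rec_B Single rows (or aligned data frames) as returned by
#'   [cohens_d()], with columns `feature`, `d`, `ci_lo`, `ci_hi`.
#' @param zero_sign `"positive"` (default), `"conservative"` or
#'   `"lenient"`.
#' @return Data frame with columns `feature`, `d_A`, `d_B`, `sigma`,
#'   `omega`, `epsilon`, `score`.
#' @export
repro_record <- function(rec_A, rec_B,
                         zero_sign = c("positive", "conservative", "lenient")) {
  zero_sign <- match.arg(zero_sign)
  if (!identical(as.character(rec_A$feature), as.character(rec_B$feature))) {
    stop("feature labels differ between the two analyses")
  }
  sA <- sign(rec_A$d); sB <- sign(rec_B$d)
  sigma <- switch(zero_sign,
    positive = as.numeric((rec_A$d > 0) == (rec_B$d > 0)),
    conservative = as.numeric(sA == sB),  # sign(0)==sign(0) -> 1; one zero -> 0
    lenient = as.numeric(sA == sB | sA == 0 | sB == 0))
  omega <- as.numeric(pmax(rec_A$ci_lo, rec_B$ci_lo) <=
                      pmin(rec_A$ci_hi, rec_B$ci_hi))
  epsilon <- pmin(abs(rec_A$d), abs(rec_B$d))
  data.frame(feature = as.character(rec_A$feature),
             d_A = rec_A$d, d_B = rec_B$d,
             sigma = sigma, omega = omega, epsilon = epsilon,
             score = sigma + omega + epsilon,
             stringsAsFactors = FALSE)
}

#' Cross-analysis concordance of per-region effect sizes
#'
#' Computes Cohen's d (with 95% CI) per region in each of two cohort summary
#' tables, then summarizes their agreement: the correlation between the two
#' effect-size vectors, the fraction of regions with directionally consistent
#' effects, the fraction with overlapping confidence intervals, and the full
#' reproducibility-score ranking (score descending, ties broken by feature
#' label).
#'
#' @param table_A,table_B `cohort_summary` tables sharing >= 3 regions.
#' @param method Correlation between effect-size vectors: `"pearson"`
#'   (default) or `"spearman"`.
#' @param zero_sign Passed to [repro_record()].
#' @return List of class `concordance_summary`: `records` (ranked data
#'   frame with CIs and score components), `r`, `r_p_value`,
#'   `fraction_directionally_consistent`, `fraction_ci_overlap`,
#'   `cohorts`.
#' @export
concordance <- function(table_A, table_B, method = c("pearson", "spearman"),
                        zero_sign = c("positive", "conservative", "lenient")) {
  method <- match.arg(method)
  zero_sign <- match.arg(zero_sign)
  shared <- intersect(table_A$region, table_B$region)
  if (length(shared) < 3) stop("need >= 3 shared regions, got ", length(shared))
  A <- cohens_d_summary(table_A[match(shared, table_A$region), ])
  B <- cohens_d_summary(table_B[match(shared, table_B$region), ])
  rec <- repro_record(A, B, zero_sign = zero_sign)
  rec$lo_A <- A$ci_lo; rec$hi_A <- A$ci_hi
  rec$lo_B <- B$ci_lo; rec$hi_B <- B$ci_hi
  rec <- rec[order(-rec$score, rec$feature), ]
  rownames(rec) <- NULL
  ct <- stats::cor.test(A$d, B$d, method = method, exact = FALSE)
  structure(list(
    records = rec,
    r = unname(ct$estimate),
    r_p_value = ct$p.value,
    fraction_directionally_consistent = mean(rec$sigma),
    fraction_ci_overlap = mean(rec$omega),
    cohorts = c(attr(table_A, "cohort_id"), attr(table_B, "cohort_id"))
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, n = 5, ...) {
  cat(sprintf("Effect-size concordance (%s vs %s), %d shared regions\n",
              x$cohorts[1], x$cohorts[2], nrow(x$records)))
  cat(sprintf("  r = %.3f (p = %.3f)\n", x$r, x$r_p_value))
  cat(sprintf("  directionally consistent: %.1f%%   CI overlap: %.1f%%\n",
              100 * x$fraction_directionally_consistent,
              100 * x$fraction_ci_overlap))
  cat(sprintf("  top %d by reproducibility score S = sigma + omega + epsilon:\n", n))
  top <- utils::head(x$records[, c("feature", "d_A", "d_B", "sigma", "omega",
                                   "epsilon", "score")], n)
  print(format(top, digits = 3), row.names = FALSE)
  invisible(x)
}
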