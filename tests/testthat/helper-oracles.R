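# Independent oracles and fixture builders used across the suite.

# Exhaustive pairwise Cliff's delta: sign counting over all (i, j) pairs.
brute_cliff <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

# Mann-Whitney U by explicit pair counting, ties as 0.5.
brute_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Mardia's b1p / b2p by the definitional double sums (ML covariance).
brute_mardia <- function(X) {
  n <- nrow(X); p <- ncol(X)
  xbar <- colMeans(X)
  S <- matrix(0, p, p)
  for (i in seq_len(n)) S <- S + tcrossprod(X[i, ] - xbar)
  S <- S / n
  Sinv <- solve(S)
  b1 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    g <- drop(t(X[i, ] - xbar) %*% Sinv %*% (X[j, ] - xbar))
    b1 <- b1 + g^3
  }
  b2 <- 0
  for (i in seq_len(n)) {
    g <- drop(t(X[i, ] - xbar) %*% Sinv %*% (X[i, ] - xbar))
    b2 <- b2 + g^2
  }
  list(b1p = b1 / n^2, b2p = b2 / n)
}

# Minimal two-group subject table with p uncorrelated normal features;
# `effect` shifts the HC mean upward in SD units on every feature.
make_subjects <- function(n_hc = 10, n_ibs = 12, p = 3, effect = 0, seed = 1,
                          sd = 1) {
  set.seed(seed)
  n <- n_hc + n_ibs
  feats <- paste0("f", seq_len(p))
  X <- matrix(rnorm(n * p, sd = sd), n, p, dimnames = list(NULL, feats))
  X[seq_len(n_hc), ] <- X[seq_len(n_hc), ] + effect * sd
  df <- data.frame(subject_id = sprintf("P%03d", seq_len(n)),
                   group = rep(c("HC", "IBS"), c(n_hc, n_ibs)),
                   sex = rep_len(c("F", "M"), n),
                   age = 30 + seq_len(n) %% 20,
                   ibs_sss = c(rep(20, n_hc), rep(250, n_ibs)),
                   etiv = 1.5e6,
                   stringsAsFactors = FALSE)
  subject_table(cbind(df, as.data.frame(X)), regions = feats,
                normalized = TRUE)
}

# A small synthetic aseg.stats text in the FreeSurfer layout.
aseg_fixture_lines <- function(etiv = 1498456.2, drop_etiv = FALSE) {
  meas <- c(
    "# Measure BrainSeg, BrainSegVol, Brain Segmentation Volume, 1209113.0, mm^3",
    "# Measure Cortex, CortexVol, Total cortical gray matter volume, 501234.5, mm^3",
    if (!drop_etiv)
      sprintf("# Measure EstimatedTotalIntraCranialVol, EstimatedTotalIntraCranialVol, Estimated Total Intracranial Volume, %.1f, mm^3", etiv))
  c("# Title Segmentation Statistics",
    "# generating_program mri_segstats",
    meas,
    "# NTableCols 10",
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean normStdDev normMin normMax normRange",
    "  1   4   1234   7553.1  Left-Thalamus-Proper  85.1  7.2  40.0  105.0  65.0",
    "  2  17   2345   4145.8  Left-Hippocampus      71.5  8.1  30.0  100.0  70.0",
    "  3  99    111    222.2  Some-Novel-Structure  10.0  1.0   5.0   15.0  10.0")
}
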