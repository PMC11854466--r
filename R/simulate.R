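#' Simulation configuration for a two-group morphometry cohort
#'
#' Defaults emulate the study conditions: 29 healthy controls and 49 IBS
#' patients; per-group means and SDs of the 35 eTIV-normalized regional
#' volumes taken from the Bergen cohort summary table; strong bilateral
#' correlations (hippocampus 0.8, amygdala 0.7, putamen 0.9) over a mild
#' background inter-region correlation of 0.3; six RBANS cognitive indices
#' with normative mean 100 and SD 15, moderately inter-correlated and
#' essentially uncorrelated with the volumes; IBS symptom severity drawn in
#' the clinical bands (HC below 75, median about 21; IBS at or above 175,
#' median about 264); sex assigned at the cohort's female proportions; and
#' three missing severity scores per group.
#'
#' @param n_hc,n_ibs Group sizes.
#' @param region_panel Data frame with `region`, `mean_hc`, `sd_hc`,
#'   `mean_ibs`, `sd_ibs` (normalized-volume scale). Defaults to the
#'   shipped Bergen summary.
#' @param bilateral_rho Named correlations for left/right structure pairs.
#' @param background_rho Inter-region correlation outside bilateral pairs.
#' @param effect_vector Optional named vector of true Cohen's d (HC minus
#'   IBS) per region; when supplied it overrides the per-group means: the
#'   IBS mean becomes `mean_hc - d * sd`, so the injected effect is exactly
#'   recoverable.
#' @param cognitive_mean,cognitive_sd Normative scale of the cognitive
#'   indices.
#' @param cognitive_rho Inter-index correlation.
#' @param cognitive_shift Named vector of group deficits per index in SD
#'   units (positive = lower in IBS).
#' @param sss_hc,sss_ibs `c(mean, sd, lower, upper)` of the truncated-normal
#'   severity distribution per group.
#' @param missing_sss Number of severity scores blanked at random per group.
#' @param etiv_mean,etiv_sd Per-subject eTIV distribution (mm^3), clipped to
#'   the plausible adult range `[1.2e6, 1.8e6]`.
#' @param prop_female Named vector of female proportions per group.
#' @param seed Integer seed; generation is bit-reproducible given the
#'   config and seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_hc = 29, n_ibs = 49,
                       region_panel = NULL,
                       bilateral_rho = c(Hippocampus = 0.8, Amygdala = 0.7,
                                         Putamen = 0.9),
                       background_rho = 0.3,
                       effect_vector = NULL,
                       cognitive_mean = 100, cognitive_sd = 15,
                       cognitive_rho = 0.5,
                       cognitive_shift = c("Full-scale RBANS" = 0.45,
                                           "Memory Index" = 0.25,
                                           "Visuospatial Index" = 0,
                                           "Verbal Skills Index" = 0.25,
                                           "Attention Index" = 0.25,
                                           "Recall Index" = 0.45),
                       sss_hc = c(mean = 25, sd = 15, lower = 0, upper = 74),
                       sss_ibs = c(mean = 264, sd = 71, lower = 175, upper = 500),
                       missing_sss = 3,
                       etiv_mean = 1.5e6, etiv_sd = 1.2e5,
                       prop_female = c(HC = 0.690, IBS = 0.776),
                       seed = 1L) {
  if (is.null(region_panel)) {
    b <- shipped_cohort_summary("bergen")
    region_panel <- data.frame(region = b$region,
                               mean_hc = b$mean_hc, sd_hc = b$sd_hc,
                               mean_ibs = b$mean_ibs, sd_ibs = b$sd_ibs,
                               stringsAsFactors = FALSE)
  }
  stopifnot(all(c("region", "mean_hc", "sd_hc", "mean_ibs", "sd_ibs") %in%
                  names(region_panel)))
  if (any(region_panel$sd_hc <= 0) || any(region_panel$sd_ibs <= 0)) {
    stop("region SDs must be > 0")
  }
  if (!is.null(effect_vector)) {
    if (is.null(names(effect_vector)) ||
        !all(names(effect_vector) %in% region_panel$region)) {
      stop("effect_vector must be named by regions in the panel")
    }
    if (any(!is.finite(effect_vector))) stop("effect sizes must be finite")
  }
  structure(list(n_hc = n_hc, n_ibs = n_ibs, region_panel = region_panel,
                 bilateral_rho = bilateral_rho, background_rho = background_rho,
                 effect_vector = effect_vector,
                 cognitive_mean = cognitive_mean, cognitive_sd = cognitive_sd,
                 cognitive_rho = cognitive_rho, cognitive_shift = cognitive_shift,
                 sss_hc = sss_hc, sss_ibs = sss_ibs, missing_sss = missing_sss,
                 etiv_mean = etiv_mean, etiv_sd = etiv_sd,
                 prop_female = prop_female, seed = as.integer(seed)),
            class = "sim_config")
}

# Region-region correlation matrix: background rho everywhere, boosted on
# configured Left/Right pairs, repaired to the nearest positive definite
# matrix when needed.
region_correlation <- function(regions, bilateral_rho, background_rho) {
  p <- length(regions)
  R <- matrix(background_rho, p, p)
  diag(R) <- 1
  for (s in names(bilateral_rho)) {
    i <- grep(paste0("^Left .*", s), regions)
    j <- grep(paste0("^Right .*", s), regions)
    if (length(i) == 0) i <- match(paste("Left", s), regions)
    if (length(j) == 0) j <- match(paste("Right", s), regions)
    if (!is.na(i[1]) && !is.na(j[1])) {
      R[i[1], j[1]] <- R[j[1], i[1]] <- bilateral_rho[[s]]
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("correlation matrix not positive definite after repair")
  }
  R
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  # inverse-CDF truncated normal
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic two-group cohort
#'
#' Draws a subject-level table with the statistical structure the analyses
#' assume: correlated eTIV-normalized regional volumes per group (multiplied
#' back by a per-subject eTIV so that [etiv_normalize()] recovers the target
#' scale), correlated cognitive index scores with group deficits, severity
#' scores confined to the clinical bands, sex at the configured proportions,
#' and a few severity scores blanked. Identical config + seed regenerate the
#' table bit-identically.
#'
#' @param config A [sim_config()].
#' @return List of class `generated_cohort` with `table` (a
#'   [subject_table()] carrying raw mm^3 volumes plus `etiv`) and `truth`
#'   (the config echo).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  rp <- config$region_panel
  regions <- rp$region
  p <- length(regions)
  n1 <- config$n_hc; n2 <- config$n_ibs; n <- n1 + n2
  R <- region_correlation(regions, config$bilateral_rho, config$background_rho)

  mean_hc <- rp$mean_hc
  sd_hc <- rp$sd_hc
  if (is.null(config$effect_vector)) {
    mean_ibs <- rp$mean_ibs
    sd_ibs <- rp$sd_ibs
  } else {
    d <- rep(0, p); names(d) <- regions
    d[names(config$effect_vector)] <- config$effect_vector
    mean_ibs <- mean_hc - d * sd_hc
    sd_ibs <- sd_hc
  }

  cidx <- cognitive_panel()
  q <- length(cidx)
  Rc <- matrix(config$cognitive_rho, q, q); diag(Rc) <- 1
  shift <- rep(0, q); names(shift) <- cidx
  shift[names(config$cognitive_shift)] <- config$cognitive_shift

  tbl <- with_seed(config$seed, {
    Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
    norm_vol <- matrix(NA_real_, n, p, dimnames = list(NULL, regions))
    grp <- rep(c(0L, 1L), c(n1, n2))
    norm_vol[grp == 0L, ] <- sweep(sweep(Z[grp == 0L, , drop = FALSE], 2, sd_hc, "*"),
                                   2, mean_hc, "+")
    norm_vol[grp == 1L, ] <- sweep(sweep(Z[grp == 1L, , drop = FALSE], 2, sd_ibs, "*"),
                                   2, mean_ibs, "+")
    etiv <- pmin(pmax(stats::rnorm(n, config$etiv_mean, config$etiv_sd),
                      1.2e6), 1.8e6)
    raw_vol <- norm_vol * etiv

    Zc <- MASS::mvrnorm(n, mu = rep(0, q), Sigma = Rc)
    cog <- sweep(Zc, 2, rep(config$cognitive_sd, q), "*") + config$cognitive_mean
    cog[grp == 1L, ] <- sweep(cog[grp == 1L, , drop = FALSE], 2,
                              shift * config$cognitive_sd)
    colnames(cog) <- cidx

    sss <- numeric(n)
    sss[grp == 0L] <- rtruncnorm1(n1, config$sss_hc["mean"], config$sss_hc["sd"],
                                  config$sss_hc["lower"], config$sss_hc["upper"])
    sss[grp == 1L] <- rtruncnorm1(n2, config$sss_ibs["mean"], config$sss_ibs["sd"],
                                  config$sss_ibs["lower"], config$sss_ibs["upper"])
    sss <- round(sss)
    if (config$missing_sss > 0) {
      sss[sample(which(grp == 0L), min(config$missing_sss, n1))] <- NA
      sss[sample(which(grp == 1L), min(config$missing_sss, n2))] <- NA
    }

    sex <- character(n)
    sex[grp == 0L] <- ifelse(stats::runif(n1) < config$prop_female[["HC"]], "F", "M")
    sex[grp == 1L] <- ifelse(stats::runif(n2) < config$prop_female[["IBS"]], "F", "M")

    age <- round(pmax(18, stats::rnorm(n, 34, 10)))

    df <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = ifelse(grp == 0L, "HC", "IBS"),
      sex = sex, age = age, ibs_sss = sss, etiv = etiv,
      check.names = FALSE, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(raw_vol, check.names = FALSE),
                as.data.frame(cog, check.names = FALSE))
    subject_table(df, regions = regions, cognitive = cidx, normalized = FALSE)
  })
  structure(list(table = tbl, truth = config), class = "generated_cohort")
}

#' @export
print.generated_cohort <- function(x, ...) {
  cat("generated_cohort (seed", x$truth$seed, ")\n")
  print(x$table)
  invisible(x)
}

#' Stratified multiple imputation of missing severity scores
#'
#' Each missing `ibs_sss` cell is drawn from the empirical distribution of
#' the observed severity scores within the same (group, sex) stratum,
#' producing `m` completed copies. Because strata never mix groups, imputed
#' HC values stay below 75 and imputed IBS values stay at or above 175
#' whenever the observed data respect the clinical bands. An empty (group,
#' sex) stratum falls back to the group-only stratum with a warning.
#'
#' @param table A [subject_table()] whose only missing values are in
#'   `ibs_sss`.
#' @param m Number of completed copies, default 5.
#' @param seed Integer seed.
#' @return List of `m` completed subject tables (identity list when nothing
#'   is missing).
#' @export
impute_sss <- function(table, m = 5, seed = NULL) {
  stopifnot(inherits(table, "subject_table"))
  miss <- which(is.na(table$ibs_sss))
  if (!length(miss)) return(replicate(m, table, simplify = FALSE))
  with_seed(seed, {
    lapply(seq_len(m), function(i) {
      out <- table
      for (j in miss) {
        g <- table$group[j]; s <- table$sex[j]
        pool <- table$ibs_sss[table$group == g & table$sex == s &
                                !is.na(table$ibs_sss)]
        if (!length(pool)) {
          warning("empty (", g, ", ", s, ") stratum; falling back to group-only")
          pool <- table$ibs_sss[table$group == g & !is.na(table$ibs_sss)]
          if (!length(pool)) stop("no observed severity scores in group ", g)
        }
        out$ibs_sss[j] <- sample(pool, 1)
      }
      out
    })
  })
}
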