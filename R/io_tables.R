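#' Canonical regional volume panel
#'
#' The 35 eTIV-normalized regional and global volume labels used throughout
#' the package, in their canonical order: subcortical and cerebellar
#' structures, CSF, white-matter hypointensities, corpus callosum segments,
#' and global segmentation volumes.
#'
#' @return Character vector of 35 region labels.
#' @export
region_panel <- function() {
  c(
    "Left Cerebellum WM", "Left Cerebellum Cortex", "Left Thalamus",
    "Left Caudate", "Left Putamen", "Left Pallidum", "Left Hippocampus",
    "Left Amygdala", "Left Accumbens Area", "CSF",
    "Right Cerebellum WM", "Right Cerebellum Cortex", "Right Thalamus",
    "Right Caudate", "Right Putamen", "Right Pallidum", "Right Hippocampus",
    "Right Amygdala", "Right Accumbens Area", "WM Hypointensities",
    "CC Posterior", "CC Mid Posterior", "CC Central", "CC Mid Anterior",
    "CC Anterior", "BrainSegVol", "BrainSegVolNotVent", "lhCortexVol",
    "rhCortexVol", "CortexVol", "lhCerebralWhiteMatterVol",
    "rhCerebralWhiteMatterVol", "CerebralWhiteMatterVol",
    "SubCortGrayVol", "TotalGrayVol"
  )
}

#' RBANS cognitive index labels
#'
#' The six age-corrected cognitive index scores (mean 100, SD 15 in the
#' normative population) used by the cognition-aware analyses.
#'
#' @return Character vector of 6 index labels.
#' @export
cognitive_panel <- function() {
  c("Full-scale RBANS", "Memory Index", "Visuospatial Index",
    "Verbal Skills Index", "Attention Index", "Recall Index")
}

# FreeSurfer aseg StructName / Measure-name -> canonical label alias table.
aseg_aliases <- function() {
  c(
    "Left-Cerebellum-White-Matter"  = "Left Cerebellum WM",
    "Left-Cerebellum-Cortex"        = "Left Cerebellum Cortex",
    "Left-Thalamus"                 = "Left Thalamus",
    "Left-Thalamus-Proper"          = "Left Thalamus",
    "Left-Caudate"                  = "Left Caudate",
    "Left-Putamen"                  = "Left Putamen",
    "Left-Pallidum"                 = "Left Pallidum",
    "Left-Hippocampus"              = "Left Hippocampus",
    "Left-Amygdala"                 = "Left Amygdala",
    "Left-Accumbens-area"           = "Left Accumbens Area",
    "CSF"                           = "CSF",
    "Right-Cerebellum-White-Matter" = "Right Cerebellum WM",
    "Right-Cerebellum-Cortex"       = "Right Cerebellum Cortex",
    "Right-Thalamus"                = "Right Thalamus",
    "Right-Thalamus-Proper"         = "Right Thalamus",
    "Right-Caudate"                 = "Right Caudate",
    "Right-Putamen"                 = "Right Putamen",
    "Right-Pallidum"                = "Right Pallidum",
    "Right-Hippocampus"             = "Right Hippocampus",
    "Right-Amygdala"                = "Right Amygdala",
    "Right-Accumbens-area"          = "Right Accumbens Area",
    "WM-hypointensities"            = "WM Hypointensities",
    "CC_Posterior"                  = "CC Posterior",
    "CC_Mid_Posterior"              = "CC Mid Posterior",
    "CC_Central"                    = "CC Central",
    "CC_Mid_Anterior"               = "CC Mid Anterior",
    "CC_Anterior"                   = "CC Anterior",
    "BrainSegVol"                   = "BrainSegVol",
    "BrainSegVolNotVent"            = "BrainSegVolNotVent",
    "lhCortexVol"                   = "lhCortexVol",
    "rhCortexVol"                   = "rhCortexVol",
    "CortexVol"                     = "CortexVol",
    "lhCerebralWhiteMatterVol"      = "lhCerebralWhiteMatterVol",
    "rhCerebralWhiteMatterVol"      = "rhCerebralWhiteMatterVol",
    "CerebralWhiteMatterVol"        = "CerebralWhiteMatterVol",
    "SubCortGrayVol"                = "SubCortGrayVol",
    "TotalGrayVol"                  = "TotalGrayVol"
  )
}

canonical_region <- function(x) {
  al <- aseg_aliases()
  out <- unname(al[x])
  ifelse(is.na(out), x, out)
}

#' Parse a FreeSurfer aseg.stats file
#'
#' Reads the comment header (`# Measure` lines) and the whitespace-delimited
#' structure table of an `aseg.stats` file, returning absolute volumes in
#' mm^3. Structure names are mapped to the canonical labels of
#' [region_panel()] where an alias is known; unknown structures are preserved
#' under their original names.
#'
#' @param file Path to an `aseg.stats` file, or a character vector of its
#'   lines (useful for testing).
#' @return A list with components `volumes` (named numeric, structure rows),
#'   `measures` (named numeric, header `# Measure` values, e.g.
#'   `BrainSegVol`, `CortexVol`) and `etiv` (the
#'   `EstimatedTotalIntraCranialVol` measure, mm^3).
#' @export
parse_aseg_stats <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE))
  }

  measure_lines <- grep("^# Measure ", lines, value = TRUE)
  measures <- numeric(0)
  for (ml in measure_lines) {
    parts <- strsplit(sub("^# Measure ", "", ml), ",")[[1]]
    if (length(parts) < 4) {
      stop("malformed aseg.stats '# Measure' header line: ", ml)
    }
    key <- trimws(parts[2])
    val <- suppressWarnings(as.numeric(trimws(parts[length(parts) - 1L])))
    if (is.na(val)) {
      stop("non-numeric value in aseg.stats '# Measure' line: ", ml)
    }
    measures[key] <- val
  }
  if (!"EstimatedTotalIntraCranialVol" %in% names(measures)) {
    stop("aseg.stats header lacks the 'EstimatedTotalIntraCranialVol' measure")
  }

  # ColHeaders line declares the table layout
  hdr <- grep("^# ColHeaders", lines, value = TRUE)
  if (length(hdr) != 1L) {
    stop("aseg.stats file lacks a single '# ColHeaders' line")
  }
  cols <- strsplit(trimws(sub("^# ColHeaders", "", hdr)), "\\s+")[[1]]
  i_vol <- match("Volume_mm3", cols)
  i_name <- match("StructName", cols)
  if (is.na(i_vol) || is.na(i_name)) {
    stop("aseg.stats ColHeaders lack Volume_mm3 or StructName")
  }

  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  volumes <- numeric(0)
  for (bl in body) {
    f <- strsplit(trimws(bl), "\\s+")[[1]]
    if (length(f) < max(i_vol, i_name)) {
      stop("malformed aseg.stats table row: ", bl)
    }
    v <- suppressWarnings(as.numeric(f[i_vol]))
    if (is.na(v)) stop("non-numeric Volume_mm3 in row: ", bl)
    volumes[canonical_region(f[i_name])] <- v
  }

  list(volumes = volumes, measures = measures,
       etiv = unname(measures[["EstimatedTotalIntraCranialVol"]]))
}

#' Construct a subject-level feature table
#'
#' A `subject_table` is a data frame with one row per participant holding the
#' group label (`HC`/`IBS`), sex (`F`/`M`), age in years, the IBS symptom
#' severity score (`ibs_sss`, 0--500 or `NA`), the estimated total
#' intracranial volume (`etiv`, mm^3), regional volumes and cognitive index
#' scores. Which columns are regions and which are cognitive indices is
#' recorded in attributes so downstream analyses can select feature panels.
#'
#' @param df Data frame with at least `subject_id`, `group`, `sex`, `age`
#'   columns.
#' @param regions Character vector of region-volume column names.
#' @param cognitive Character vector of cognitive-index column names.
#' @param normalized Logical; `TRUE` when region columns hold dimensionless
#'   eTIV-normalized ratios rather than mm^3.
#' @return The validated data frame with class `subject_table`.
#' @export
subject_table <- function(df, regions = character(0), cognitive = character(0),
                          normalized = FALSE) {
  stopifnot(is.data.frame(df))
  need <- c("subject_id", "group", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("subject table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id values")
  bad <- setdiff(unique(as.character(df$group)), c("HC", "IBS"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df$group <- factor(as.character(df$group), levels = c("HC", "IBS"))
  df$sex <- factor(as.character(df$sex), levels = c("F", "M"))
  if ("ibs_sss" %in% names(df)) {
    ok <- is.na(df$ibs_sss) | (df$ibs_sss >= 0 & df$ibs_sss <= 500)
    if (!all(ok)) stop("ibs_sss outside [0, 500]")
  }
  if ("etiv" %in% names(df) && any(!is.na(df$etiv) & df$etiv <= 0)) {
    stop("etiv must be > 0")
  }
  miss <- setdiff(c(regions, cognitive), names(df))
  if (length(miss)) stop("declared feature columns absent: ", paste(miss, collapse = ", "))
  structure(df,
            class = c("subject_table", "data.frame"),
            regions = regions, cognitive = cognitive,
            normalized = isTRUE(normalized))
}

#' @export
print.subject_table <- function(x, ...) {
  cat(sprintf("subject_table: %d subjects (%d HC, %d IBS), %d region + %d cognitive features%s\n",
              nrow(x), sum(x$group == "HC"), sum(x$group == "IBS"),
              length(attr(x, "regions")), length(attr(x, "cognitive")),
              if (isTRUE(attr(x, "normalized"))) ", eTIV-normalized" else ""))
  NextMethod()
}

#' Normalize regional volumes by eTIV
#'
#' Divides every region column by the per-subject estimated total intracranial
#' volume, turning absolute mm^3 volumes into the dimensionless ratios used in
#' cross-cohort comparisons. The `etiv` column itself is retained
#' unnormalized.
#'
#' @param table A [subject_table()] with an `etiv` column (mm^3 > 0).
#' @return The table with normalized region columns and `normalized = TRUE`.
#' @export
etiv_normalize <- function(table) {
  stopifnot(inherits(table, "subject_table"))
  if (isTRUE(attr(table, "normalized"))) return(table)
  if (!"etiv" %in% names(table)) stop("no etiv column to normalize by")
  if (any(is.na(table$etiv)) || any(table$etiv <= 0)) stop("etiv must be > 0 for all subjects")
  regs <- attr(table, "regions")
  for (r in regs) table[[r]] <- table[[r]] / table$etiv
  attr(table, "normalized") <- TRUE
  table
}

#' Read / write subject-level tables as CSV
#'
#' Comma-separated, UTF-8, "." decimal; missing values are empty cells. The
#' region and cognitive feature panels can be declared directly or through a
#' YAML config file with `regions:` and `cognitive:` keys; columns from the
#' canonical panels are recognized automatically otherwise.
#'
#' @param path CSV file path.
#' @param regions,cognitive Optional character vectors naming feature columns.
#' @param config Optional path to a YAML file declaring `regions` and
#'   `cognitive`.
#' @param normalized Logical; whether region columns are already
#'   eTIV-normalized.
#' @return `read_subject_table`: a [subject_table()].
#' @export
read_subject_table <- function(path, regions = NULL, cognitive = NULL,
                               config = NULL, normalized = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    if (is.null(regions)) regions <- cfg$regions
    if (is.null(cognitive)) cognitive <- cfg$cognitive
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = "")
  if (nrow(df) == 0L) stop("empty subject table: ", path)
  if (is.null(regions)) regions <- intersect(region_panel(), names(df))
  if (is.null(cognitive)) cognitive <- intersect(cognitive_panel(), names(df))
  subject_table(df, regions = regions, cognitive = cognitive,
                normalized = normalized)
}

#' @rdname read_subject_table
#' @param table A [subject_table()] to serialize.
#' @export
write_subject_table <- function(table, path) {
  stopifnot(inherits(table, "subject_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write per-region cohort summary tables
#'
#' A `cohort_summary` holds per-region group summary statistics (sample size,
#' mean, SD of the eTIV-normalized volume for the HC and IBS groups) -- the
#' unit of the replication analysis when only printed summary tables of a
#' reference study are available. Columns: `region`, `n_hc`, `mean_hc`,
#' `sd_hc`, `n_ibs`, `mean_ibs`, `sd_ibs`.
#'
#' @param path CSV file path.
#' @param cohort_id Label identifying the cohort/pipeline.
#' @return A data frame of class `cohort_summary`.
#' @export
read_cohort_summary <- function(path, cohort_id = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cohort_summary(df, cohort_id = cohort_id)
}

#' @rdname read_cohort_summary
#' @param df Data frame with the summary columns.
#' @export
cohort_summary <- function(df, cohort_id = "cohort") {
  need <- c("region", "n_hc", "mean_hc", "sd_hc", "n_ibs", "mean_ibs", "sd_ibs")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort summary lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$region)) stop("duplicate region labels")
  if (any(df$n_hc < 2) || any(df$n_ibs < 2)) stop("group sizes must be >= 2")
  if (any(df$n_hc != round(df$n_hc)) || any(df$n_ibs != round(df$n_ibs))) {
    stop("group sizes must be integers")
  }
  if (any(df$sd_hc < 0) || any(df$sd_ibs < 0)) stop("SDs must be >= 0")
  structure(df, class = c("cohort_summary", "data.frame"), cohort_id = cohort_id)
}

#' @rdname read_cohort_summary
#' @param table A `cohort_summary` to serialize.
#' @export
write_cohort_summary <- function(table, path) {
  stopifnot(inherits(table, "cohort_summary"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Shipped Table-style cohort summary fixtures
#'
#' Convenience loaders for the two cohort summary tables shipped with the
#' package: the reference study's printed per-region summary statistics and
#' the Bergen cohort processed with the same segmentation pipeline.
#'
#' @param which `"skrobisz"` or `"bergen"`.
#' @return A `cohort_summary` with 35 regions.
#' @export
shipped_cohort_summary <- function(which = c("skrobisz", "bergen")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_table3.csv"),
                      package = "morphorep", mustWork = TRUE)
  read_cohort_summary(path, cohort_id = which)
}

#' Feature matrix and labels from a subject table
#'
#' @param table A [subject_table()].
#' @param features Character vector of feature column names.
#' @return List with `x` (numeric matrix, subjects x features) and `y`
#'   (integer labels, HC = 0, IBS = 1).
#' @export
feature_matrix <- function(table, features) {
  stopifnot(inherits(table, "subject_table"))
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("unknown feature column(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- table$subject_id
  list(x = x, y = as.integer(table$group == "IBS"))
}
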