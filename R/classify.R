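#' Confusion counts for a binary IBS-vs-HC prediction
#'
#' Positive class is IBS (coded 1).
#'
#' @param truth Integer/logical vector of true labels (1 = IBS).
#' @param pred Integer/logical vector of predicted labels.
#' @return List of class `confusion_counts`: `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  structure(list(tp = sum(truth == 1 & pred == 1),
                 fn = sum(truth == 1 & pred == 0),
                 tn = sum(truth == 0 & pred == 0),
                 fp = sum(truth == 0 & pred == 1)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined: zero denominator")
    return(NaN)
  }
  num / den
}

#' Classification metric suite from confusion counts
#'
#' The eleven standard confusion-matrix summaries (sensitivity TPR,
#' specificity TNR, precision PPV, NPV, FPR, FNR, FDR, accuracy, balanced
#' accuracy, F1, Matthews correlation coefficient) plus Cohen's kappa.
#' Ratios with zero denominators are reported as `NaN` with a warning,
#' never silently zero.
#'
#' @param counts A [confusion_counts()] (or list with `tp`, `fn`, `tn`,
#'   `fp`).
#' @return List of class `metric_report`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  if (any(c(tp, fn, tn, fp) < 0)) stop("negative confusion counts")
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty confusion matrix")
  tpr <- safe_ratio(tp, tp + fn, "TPR")
  tnr <- safe_ratio(tn, tn + fp, "TNR")
  ppv <- safe_ratio(tp, tp + fp, "PPV")
  npv <- safe_ratio(tn, tn + fn, "NPV")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined: zero denominator")
    NaN
  } else (tp * tn - fp * fn) / mcc_den
  p_obs <- (tp + tn) / total
  p_chance <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / total^2
  kappa <- if (p_chance == 1) {
    warning("kappa undefined: chance agreement is 1")
    NaN
  } else (p_obs - p_chance) / (1 - p_chance)
  structure(list(
    tpr = tpr, tnr = tnr, ppv = ppv, npv = npv,
    fpr = 1 - tnr, fnr = 1 - tpr, fdr = 1 - ppv,
    acc = p_obs, bacc = (tpr + tnr) / 2,
    f1 = if (is.nan(ppv) || is.nan(tpr) || ppv + tpr == 0) NaN
         else 2 * ppv * tpr / (ppv + tpr),
    mcc = mcc, kappa = kappa,
    counts = list(tp = tp, fn = fn, tn = tn, fp = fp)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cts <- x$counts
  cat(sprintf("confusion: TP=%d FN=%d TN=%d FP=%d\n", cts$tp, cts$fn, cts$tn, cts$fp))
  keys <- c("tpr", "tnr", "ppv", "npv", "fpr", "fnr", "fdr", "acc", "bacc",
            "f1", "mcc", "kappa")
  vals <- vapply(keys, function(k) x[[k]], numeric(1))
  if (!is.null(x$auc)) { keys <- c(keys, "auc"); vals <- c(vals, x$auc) }
  cat(paste(sprintf("%s=%.3f", toupper(keys), vals), collapse = " "), "\n")
  invisible(x)
}

#' ROC area under the curve by the rank statistic
#'
#' Computed via the Mann-Whitney identity `AUC = U / (n1 * n0)` with ties
#' counted 0.5, tying the classification harness to the same U statistic
#' underlying Cliff's delta (`AUC = (delta + 1) / 2` when positives are the
#' "x" sample).
#'
#' @param prob Predicted probabilities of the positive class.
#' @param truth 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(prob, truth) {
  truth <- as.integer(truth)
  pos <- prob[truth == 1]; neg <- prob[truth == 0]
  if (!length(pos) || !length(neg)) stop("need both classes for AUC")
  mann_whitney_u(pos, neg) / (length(pos) * length(neg))
}

#' Stratified train/test split
#'
#' Splits subjects into train and test partitions preserving the HC/IBS
#' proportions within one subject of the global proportion; deterministic
#' given the seed. At the study's 29/49 composition with a 0.30 test
#' fraction this yields a test set of 9 HC and 15 IBS.
#'
#' @param table A [subject_table()].
#' @param test_fraction Fraction held out, in (0, 1); default 0.30.
#' @param seed Integer seed.
#' @return List with `train` and `test` subject tables.
#' @export
stratified_split <- function(table, test_fraction = 0.30, seed = NULL) {
  stopifnot(inherits(table, "subject_table"))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  counts <- table(table$group)
  if (any(counts < 2)) stop("each class needs >= 2 members")
  idx_test <- with_seed(seed, {
    unlist(lapply(levels(table$group), function(g) {
      idx <- which(table$group == g)
      k <- max(1L, min(length(idx) - 1L, round(test_fraction * length(idx))))
      sample(idx, k)
    }))
  })
  idx_test <- sort(idx_test)
  list(train = table[-idx_test, ], test = table[idx_test, ])
}

#' @export
`[.subject_table` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "regions") <- attr(x, "regions")
    attr(out, "cognitive") <- attr(x, "cognitive")
    attr(out, "normalized") <- attr(x, "normalized")
    class(out) <- c("subject_table", "data.frame")
  }
  out
}

#' Leakage-free preprocessing: mean imputation + standardization
#'
#' Imputation means and scaling parameters are fitted on the training
#' partition only and applied unchanged to both partitions. Constant
#' training features are passed through unscaled (centered only) with a
#' warning; all-missing features are an error.
#'
#' @param train,test Numeric matrices (subjects x features) with identical
#'   columns.
#' @return List with transformed `train`, `test`, and the fitted `params`
#'   (`impute_mean`, `center`, `scale`).
#' @export
preprocess <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (!nrow(train)) stop("empty training matrix")
  imp <- colMeans(train, na.rm = TRUE)
  if (any(!is.finite(imp))) {
    stop("all-missing feature(s): ",
         paste(colnames(train)[!is.finite(imp)], collapse = ", "))
  }
  fill <- function(M) {
    for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- imp[j]
    M
  }
  train <- fill(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  const <- scl == 0
  if (any(const)) {
    warning("constant feature(s) passed through unscaled: ",
            paste(colnames(train)[const], collapse = ", "))
    scl[const] <- 1
  }
  tf <- function(M) sweep(sweep(fill(M), 2, ctr), 2, scl, "/")
  out <- list(train = tf(as.matrix(train)),
              test = if (!is.null(test)) tf(as.matrix(test)),
              params = list(impute_mean = imp, center = ctr, scale = scl))
  out
}

#' Reference classifier: ridge-regularized logistic regression
#'
#' A pluggable classifier honouring the harness contract: a list with
#' `name`, `fit(x, y)` returning a model object, and
#' `predict_prob(model, x)` returning positive-class probabilities in
#' `[0, 1]`.
#'
#' @param lambda Ridge penalty (glmnet `lambda`).
#' @param alpha Elastic-net mixing (0 = ridge).
#' @return Classifier contract list.
#' @export
logistic_classifier <- function(lambda = 0.1, alpha = 0) {
  list(
    name = "ridge-logistic",
    fit = function(x, y) {
      glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = alpha, lambda = lambda, standardize = FALSE)
    },
    predict_prob = function(model, x) {
      drop(stats::predict(model, newx = as.matrix(x), type = "response"))
    }
  )
}

#' Gradient-boosted-trees plug-in classifier
#'
#' Optional plug-in requiring the `xgboost` package.
#'
#' @param nrounds,max_depth,eta Boosting parameters.
#' @return Classifier contract list.
#' @export
xgboost_classifier <- function(nrounds = 50, max_depth = 3, eta = 0.3) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("the xgboost package is not installed")
  }
  list(
    name = "xgboost",
    fit = function(x, y) {
      xgboost::xgboost(data = as.matrix(x), label = y, nrounds = nrounds,
                       max_depth = max_depth, eta = eta,
                       objective = "binary:logistic", verbose = 0,
                       nthread = 1)
    },
    predict_prob = function(model, x) {
      stats::predict(model, as.matrix(x))
    }
  )
}

check_probs <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("classifier contract violation: probabilities outside [0, 1]")
  }
  p
}

#' Train/test evaluation of a classifier on a subject table
#'
#' Stratified split, leakage-free preprocessing, training on the train
#' partition, and evaluation on the held-out test partition. Predictions
#' with probability >= `threshold` are classified as IBS (the positive
#' class). Per-subject predictions retain sex, age and symptom severity for
#' subgroup summaries.
#'
#' @param classifier Classifier contract (see [logistic_classifier()]).
#' @param table A [subject_table()].
#' @param features Feature columns.
#' @param test_fraction,seed Passed to [stratified_split()].
#' @param threshold Probability cut for the IBS call, default 0.5.
#' @return List of class `evaluation`: `counts`, `metrics` (with AUC),
#'   `predictions` (data frame), `model`, `test_x`, `test_y`, `classifier`.
#' @export
evaluate <- function(classifier, table, features, test_fraction = 0.30,
                     seed = NULL, threshold = 0.5) {
  sp <- stratified_split(table, test_fraction, seed = seed)
  ftr <- feature_matrix(sp$train, features)
  fte <- feature_matrix(sp$test, features)
  pp <- preprocess(ftr$x, fte$x)
  model <- with_seed(seed, classifier$fit(pp$train, ftr$y))
  prob <- check_probs(classifier$predict_prob(model, pp$test))
  pred <- as.integer(prob >= threshold)
  cts <- confusion_counts(fte$y, pred)
  met <- metrics_from_counts(cts)
  met$auc <- auc_rank(prob, fte$y)
  preds <- data.frame(subject_id = sp$test$subject_id,
                      group = as.character(sp$test$group),
                      sex = as.character(sp$test$sex),
                      age = sp$test$age,
                      ibs_sss = sp$test$ibs_sss,
                      prob = prob, pred = pred,
                      truth = fte$y, stringsAsFactors = FALSE)
  structure(list(counts = cts, metrics = met, predictions = preds,
                 model = model, test_x = pp$test, test_y = fte$y,
                 classifier = classifier, threshold = threshold,
                 preprocess_params = pp$params),
            class = "evaluation")
}

stratified_folds <- function(y, folds, seed = NULL) {
  with_seed(seed, {
    f <- integer(length(y))
    for (g in unique(y)) {
      idx <- sample(which(y == g))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
}

#' Stratified k-fold cross-validation
#'
#' Stratified folds with class proportions within one subject of the global
#' proportions; preprocessing is fitted inside each fold (no leakage). The
#' aggregate row macro-averages the per-fold metrics.
#'
#' @inheritParams evaluate
#' @param folds Number of folds, default 10; must not exceed the
#'   minority-class count.
#' @return List of class `cv_result`: `per_fold` (data frame of metrics per
#'   fold) and `aggregate` (named numeric, macro average).
#' @export
cross_validate <- function(classifier, table, features, folds = 10,
                           seed = NULL, threshold = 0.5) {
  stopifnot(inherits(table, "subject_table"))
  fm <- feature_matrix(table, features)
  counts <- table(fm$y)
  if (length(counts) < 2) stop("labels are constant; nothing to cross-validate")
  if (folds > min(counts)) {
    stop("folds (", folds, ") exceed the minority class size (", min(counts),
         "); use fewer folds")
  }
  fold_id <- stratified_folds(fm$y, folds, seed = seed)
  keys <- c("tpr", "tnr", "ppv", "npv", "fpr", "fnr", "fdr", "acc", "bacc",
            "f1", "mcc", "kappa", "auc")
  rows <- lapply(seq_len(folds), function(k) {
    tr <- fold_id != k; te <- !tr
    pp <- preprocess(fm$x[tr, , drop = FALSE], fm$x[te, , drop = FALSE])
    model <- with_seed(if (is.null(seed)) NULL else seed + k,
                       classifier$fit(pp$train, fm$y[tr]))
    prob <- check_probs(classifier$predict_prob(model, pp$test))
    met <- suppressWarnings(
      metrics_from_counts(confusion_counts(fm$y[te], as.integer(prob >= threshold))))
    met$auc <- if (length(unique(fm$y[te])) == 2) auc_rank(prob, fm$y[te]) else NA_real_
    c(fold = k, vapply(keys, function(x) met[[x]], numeric(1)))
  })
  per_fold <- as.data.frame(do.call(rbind, rows))
  agg <- colMeans(per_fold[, keys, drop = FALSE], na.rm = TRUE)
  structure(list(per_fold = per_fold, aggregate = agg, folds = folds),
            class = "cv_result")
}

metric_from_probs <- function(metric, prob, truth, threshold) {
  if (metric == "auc") return(auc_rank(prob, truth))
  met <- suppressWarnings(
    metrics_from_counts(confusion_counts(truth, as.integer(prob >= threshold))))
  if (is.null(met[[metric]])) stop("unknown metric name: ", metric)
  met[[metric]]
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the mean decrease in a test-set metric when a
#' single feature column is shuffled, averaged over `n_repeats` independent
#' within-column permutations; deterministic given the seed. Features are
#' ranked by mean drop, descending.
#'
#' @param fitted An [evaluate()] result (trained model plus preprocessed
#'   held-out data), or a list with `model`, `test_x`, `test_y`,
#'   `classifier`.
#' @param metric Metric name from the report (`"acc"`, `"f1"`, `"mcc"`,
#'   `"auc"`, ...).
#' @param n_repeats Shuffles per feature (>= 1), default 10.
#' @param seed Integer seed.
#' @param threshold Probability cut used for count-based metrics.
#' @return Data frame of class `importance_ranking` with `feature`,
#'   `mean_drop`, `sd_drop`, `n_repeats`, ordered by `mean_drop`
#'   descending.
#' @export
permutation_importance <- function(fitted, metric = "acc", n_repeats = 10,
                                   seed = NULL, threshold = 0.5) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  X <- fitted$test_x; y <- fitted$test_y
  cls <- fitted$classifier; model <- fitted$model
  base_prob <- check_probs(cls$predict_prob(model, X))
  base <- metric_from_probs(metric, base_prob, y, threshold)
  drops <- with_seed(seed, {
    sapply(seq_len(ncol(X)), function(j) {
      vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        base - metric_from_probs(metric, check_probs(cls$predict_prob(model, Xp)),
                                 y, threshold)
      }, numeric(1))
    })
  })
  drops <- matrix(drops, nrow = n_repeats)
  out <- data.frame(feature = colnames(X),
                    mean_drop = colMeans(drops),
                    sd_drop = apply(drops, 2, stats::sd),
                    n_repeats = n_repeats,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_drop, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("importance_ranking", "data.frame")
  out
}
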