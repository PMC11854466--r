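test_that("metric identities hold on random confusion counts", {
  set.seed(5)
  for (i in 1:50) {
    cts <- list(tp = sample(1:30, 1), fn = sample(1:30, 1),
                tn = sample(1:30, 1), fp = sample(1:30, 1))
    m <- metrics_from_counts(cts)
    total <- with(cts, tp + fn + tn + fp)
    expect_equal(m$tpr + m$fnr, 1)
    expect_equal(m$tnr + m$fpr, 1)
    expect_equal(m$ppv + m$fdr, 1)
    expect_equal(m$bacc, (m$tpr + m$tnr) / 2)
    expect_equal(m$acc, (cts$tp + cts$tn) / total)
    expect_equal(m$f1, 2 * m$ppv * m$tpr / (m$ppv + m$tpr))
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    # class-swap symmetry of |MCC|
    sw <- metrics_from_counts(list(tp = cts$tn, fn = cts$fp,
                                   tn = cts$tp, fp = cts$fn))
    expect_equal(sw$mcc, m$mcc)
  }
  # perfect classifier
  m <- metrics_from_counts(list(tp = 10, fn = 0, tn = 8, fp = 0))
  expect_equal(m$tpr, 1); expect_equal(m$tnr, 1); expect_equal(m$mcc, 1)
  expect_equal(m$kappa, 1)
  # undefined ratios surface as NaN with a warning, never silent zeros
  expect_warning(m0 <- metrics_from_counts(list(tp = 0, fn = 0, tn = 5, fp = 3)),
                 "TPR")
  expect_true(is.nan(m0$tpr))
  expect_error(metrics_from_counts(list(tp = -1, fn = 0, tn = 1, fp = 0)),
               "negative")
})

test_that("AUC by ranks obeys the U/Cliff identity", {
  set.seed(6)
  prob <- runif(30)
  truth <- rbinom(30, 1, 0.5)
  truth[1] <- 1; truth[2] <- 0
  auc <- auc_rank(prob, truth)
  delta <- cliffs_delta(prob[truth == 1], prob[truth == 0])$delta
  expect_equal(auc, (delta + 1) / 2)
  expect_equal(auc_rank(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
})

test_that("stratified splitting reproduces the 9 HC / 15 IBS holdout", {
  gen <- generate_cohort(sim_config(seed = 2))
  sp <- stratified_split(gen$table, 0.30, seed = 99)
  expect_equal(nrow(sp$test), 24)
  expect_equal(sum(sp$test$group == "HC"), 9)
  expect_equal(sum(sp$test$group == "IBS"), 15)
  expect_equal(nrow(sp$train), 54)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  sp2 <- stratified_split(gen$table, 0.30, seed = 99)
  expect_identical(sp$test$subject_id, sp2$test$subject_id)
  expect_error(stratified_split(gen$table, 0), "test_fraction")
  tiny <- gen$table[c(1, 30, 31, 32), ]
  expect_error(stratified_split(tiny, 0.3), ">= 2")
})

test_that("preprocessing fits on train only and transforms both partitions", {
  set.seed(7)
  tr <- matrix(rnorm(40, mean = 10, sd = 2), 20, 2,
               dimnames = list(NULL, c("a", "b")))
  te <- matrix(rnorm(10, mean = 10, sd = 2), 5, 2,
               dimnames = list(NULL, c("a", "b")))
  tr[3, 1] <- NA
  pp <- preprocess(tr, te)
  expect_equal(colMeans(pp$train), c(a = 0, b = 0))
  expect_equal(apply(pp$train, 2, sd), c(a = 1, b = 1))
  # a test value equal to the train mean maps to zero
  te2 <- te; te2[1, "a"] <- pp$params$center[["a"]] * pp$params$scale[["a"]] +
    0  # train mean on the raw scale is center (imputed mean)
  te2[1, "a"] <- pp$params$center[["a"]]
  expect_equal(preprocess(tr, te2)$test[1, "a"], c(a = 0))
  # missing cells take the train mean (-> 0 after standardization)
  teNA <- te; teNA[2, "b"] <- NA
  expect_equal(unname(preprocess(tr, teNA)$test[2, "b"]),
               (pp$params$impute_mean[["b"]] - pp$params$center[["b"]]) /
                 pp$params$scale[["b"]])
  # changing the test partition never changes fitted parameters
  expect_identical(pp$params, preprocess(tr, te * 100)$params)
  # constant and all-missing features
  trc <- tr; trc[, 2] <- 3
  expect_warning(preprocess(trc, te), "constant")
  trm <- tr; trm[, 2] <- NA
  expect_error(preprocess(trm, te), "all-missing")
})

test_that("evaluation applies the threshold contract and degenerate classifiers", {
  gen <- generate_cohort(sim_config(seed = 3))
  tbl <- etiv_normalize(gen$table)
  always_ibs <- list(name = "always-1",
                     fit = function(x, y) NULL,
                     predict_prob = function(m, x) rep(1, nrow(x)))
  ev <- evaluate(always_ibs, tbl, region_panel(), seed = 11)
  expect_equal(ev$metrics$tpr, 1)
  expect_equal(ev$metrics$tnr, 0)
  expect_equal(ev$metrics$acc, 15 / 24)
  # probability exactly 0.5 is called IBS
  half <- list(name = "half", fit = function(x, y) NULL,
               predict_prob = function(m, x) rep(0.5, nrow(x)))
  ev2 <- evaluate(half, tbl, region_panel(), seed = 11)
  expect_equal(ev2$counts$tp + ev2$counts$fp, 24)
  # contract violation
  bad <- list(name = "bad", fit = function(x, y) NULL,
              predict_prob = function(m, x) rep(1.5, nrow(x)))
  expect_error(evaluate(bad, tbl, region_panel(), seed = 11),
               "contract violation")
})

test_that("label-permuted training yields chance-level test MCC", {
  set.seed(13)
  mccs <- replicate(50, {
    tb <- make_subjects(20, 20, p = 4, effect = 1, seed = sample.int(1e6, 1))
    df <- as.data.frame(tb)
    df$group <- sample(df$group)          # break the label-feature link
    tb2 <- subject_table(df, regions = attr(tb, "regions"), normalized = TRUE)
    ev <- evaluate(logistic_classifier(), tb2, paste0("f", 1:4),
                   seed = sample.int(1e6, 1))
    m <- ev$metrics$mcc
    if (is.nan(m)) 0 else m
  })
  se <- sd(mccs) / sqrt(length(mccs))
  expect_lt(abs(mean(mccs)), 3 * se + 1e-8)
})

test_that("cross-validation is stratified, leakage-safe and near-perfect on separable data", {
  tb <- make_subjects(25, 30, p = 3, effect = 6, seed = 41)
  cv <- cross_validate(logistic_classifier(), tb, c("f1", "f2", "f3"),
                       folds = 5, seed = 17)
  expect_equal(nrow(cv$per_fold), 5)
  expect_gte(cv$aggregate[["acc"]], 0.95)
  # fold class proportions within one subject of the global proportion
  fm <- feature_matrix(tb, "f1")
  fold_id <- morphorep:::stratified_folds(fm$y, 5, seed = 17)
  for (k in 1:5) {
    expect_lte(abs(sum(fm$y[fold_id == k] == 0) - 25 / 5), 1)
    expect_lte(abs(sum(fm$y[fold_id == k] == 1) - 30 / 5), 1)
  }
  expect_error(cross_validate(logistic_classifier(), tb, "f1", folds = 26),
               "fewer folds")
  const <- as.data.frame(tb); const$group <- "IBS"
  expect_error(
    cross_validate(logistic_classifier(),
                   subject_table(const, regions = attr(tb, "regions"),
                                 normalized = TRUE),
                   "f1"),
    "constant")
})

test_that("permutation importance isolates the informative feature", {
  # one feature carries all the signal, three are pure noise
  tb <- make_subjects(30, 30, p = 4, seed = 43)
  df <- as.data.frame(tb)
  df$f1 <- df$f1 + ifelse(df$group == "HC", 2.5, 0)
  tb <- subject_table(df, regions = attr(tb, "regions"), normalized = TRUE)
  ev <- evaluate(logistic_classifier(), tb, paste0("f", 1:4), seed = 47)
  imp <- permutation_importance(ev, metric = "acc", n_repeats = 20, seed = 47)
  expect_equal(imp$feature[1], "f1")
  expect_gt(imp$mean_drop[1], 0)
  # noise features: drop within 2 SD of zero (accuracy moves in 1/18 steps on
  # the 18-subject test set, so allow two such steps when the SD degenerates)
  noise <- imp[imp$feature != "f1", ]
  expect_true(all(abs(noise$mean_drop) <= 2 * noise$sd_drop + 2 / 18))
  expect_true(all(noise$mean_drop < imp$mean_drop[1]))
  # determinism
  i1 <- permutation_importance(ev, metric = "mcc", n_repeats = 1, seed = 5)
  i2 <- permutation_importance(ev, metric = "mcc", n_repeats = 1, seed = 5)
  expect_identical(i1, i2)
  expect_error(permutation_importance(ev, metric = "nope"), "unknown metric")
})
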