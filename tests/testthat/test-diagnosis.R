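test_that("metric identities hold, with undefined rates flagged", {
  m <- compute_metrics(73, 7, 53, 13)
  expect_equal(unname(m), c(100 * 126 / 146, 100 * 73 / 86, 100 * 53 / 60))
  expect_equal(unname(compute_metrics(1, 1, 1, 1)), c(50, 50, 50))
  expect_equal(unname(compute_metrics(5, 0, 7, 0)), c(100, 100, 100))
  expect_true(is.na(compute_metrics(0, 3, 2, 0)["sensitivity"]))
  expect_error(compute_metrics(-1, 0, 0, 1), "non-negative")
  expect_error(compute_metrics(0, 0, 0, 0), "no observations")
})

test_that("stratified folds partition subjects with every class in each fold", {
  y <- factor(rep(c("NC", "MCI"), c(20, 26)), levels = c("NC", "MCI"))
  folds <- stratified_folds(y, 4L, seed = 9L)
  expect_identical(sort(unique(folds)), 1:4)
  expect_identical(length(folds), length(y))
  for (f in 1:4) expect_true(all(table(y[folds == f]) >= 1L))
  expect_identical(folds, stratified_folds(y, 4L, seed = 9L))
  expect_false(identical(folds, stratified_folds(y, 4L, seed = 10L)))
  expect_error(stratified_folds(y, 25L, seed = 1L), "class count")
})

test_that("a separable cohort is learned perfectly on its training set", {
  co <- small_cohort()
  model <- train_diagnosis(co$table, co$labels, seed = 2L)
  pred <- predict_diagnosis(model, co$table)
  expect_identical(as.character(pred$label), as.character(co$labels))
  expect_true(all(pred$regional >= 0 & pred$regional <= 1))
  expect_identical(ncol(pred$regional), length(model$regions))
  # determinism: same data + seed -> identical fingerprint
  model2 <- train_diagnosis(co$table, co$labels, seed = 2L)
  expect_identical(model_fingerprint(model), model_fingerprint(model2))
})

test_that("duplicating every subject leaves the margin classifier unchanged", {
  # weighting equivalence holds when no slack is active, i.e. on a cohort
  # separated by a wide margin
  x <- withr::with_seed(61L,
    rbind(matrix(rnorm(40, 0, 0.5), ncol = 2),
          matrix(rnorm(40, 10, 0.5), ncol = 2)))
  y <- factor(rep(c("NC", "MCI"), each = 20), levels = c("NC", "MCI"))
  m1 <- cortexcad:::svm_fit(x, y, "linear", cost = 1)
  m2 <- cortexcad:::svm_fit(rbind(x, x), factor(rep(y, 2),
                                                levels = c("NC", "MCI")),
                            "linear", cost = 1)
  d1 <- cortexcad:::svm_decision(m1, x)
  d2 <- cortexcad:::svm_decision(m2, x)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("regional probabilities localize the planted effect", {
  co <- small_cohort()
  model <- train_diagnosis(co$table, co$labels, seed = 3L)
  pred <- predict_diagnosis(model, co$table)
  planted <- as.character(co$ground_truth$affected_regions)
  null_r <- setdiff(colnames(pred$regional), planted)
  mci <- co$labels == "MCI"
  expect_gt(median(pred$regional[mci, planted]),
            median(pred$regional[mci, null_r]))
  # calibration sanity: null regions stay non-extreme on average
  null_med <- median(pred$regional[, null_r])
  expect_gt(null_med, 0.2)
  expect_lt(null_med, 0.8)
})

test_that("cross-validation is deterministic, partition-exact and accurate", {
  co <- small_cohort()
  rep1 <- kfold_evaluate(co$table, co$labels, k = 4L, seed = 7L)
  rep2 <- kfold_evaluate(co$table, co$labels, k = 4L, seed = 7L)
  expect_identical(rep1$fold_assignment, rep2$fold_assignment)
  expect_identical(rep1$counts, rep2$counts)
  expect_identical(sum(rep1$counts), length(co$labels))
  expect_identical(unname(rep1$counts["TP"] + rep1$counts["FN"]),
                   sum(co$labels == "MCI"))
  expect_identical(unname(rep1$counts["TN"] + rep1$counts["FP"]),
                   sum(co$labels == "NC"))
  expect_gte(rep1$metrics["accuracy"], 90)
  # pooled metrics recomputed independently from the confusion counts
  expect_equal(unname(rep1$metrics["accuracy"]),
               100 * (rep1$counts[["TP"]] + rep1$counts[["TN"]]) /
                 sum(rep1$counts))
})

test_that("permuted labels drive cross-validated accuracy to chance", {
  co <- small_cohort()
  accs <- sapply(1:3, function(i) {
    perm <- withr::with_seed(40L + i, sample(co$labels))
    r <- kfold_evaluate(co$table, perm, k = 4L, seed = 7L)
    r$metrics[["accuracy"]] / 100
  })
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("comparison classifiers share folds and learn the separable cohort", {
  co <- small_cohort()
  reps <- compare_classifiers(co$table, co$labels, k = 3L, seed = 8L)
  expect_setequal(names(reps), c("svm_linear", "svm_polynomial", "svm_rbf",
                                 "decision_tree", "ensemble", "knn"))
  hashes <- vapply(reps, function(r) r$fold_hash, character(1))
  expect_identical(length(unique(hashes)), 1L)
  for (r in reps) expect_gte(r$metrics[["accuracy"]], 80)
})

test_that("no training state leaks from held-out subjects", {
  co <- small_cohort()
  audit <- suppressWarnings(
    audit_leakage(co$table, co$labels, k = 4L, seed = 13L))
  expect_true(audit$identical)
})

test_that("behavioural correlations recover exact and null relationships", {
  co <- small_cohort()
  model <- train_diagnosis(co$table, co$labels, seed = 4L)
  P <- predict_diagnosis(model, co$table)$regional
  scores <- data.frame(task_pos = P[, 1], task_neg = -P[, 1])
  out <- behavioral_correlation(P, scores)
  r1 <- out[out$region == colnames(P)[1] & out$score == "task_pos", ]
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-10)
  r2 <- out[out$region == colnames(P)[1] & out$score == "task_neg", ]
  expect_equal(r2$r, -1, tolerance = 1e-12)
  # independent Gaussian scores: small correlations, mostly
  null_scores <- withr::with_seed(50L,
    data.frame(noise = rnorm(nrow(P))))
  out_null <- behavioral_correlation(P, null_scores)
  expect_gt(mean(abs(out_null$r) < 0.3, na.rm = TRUE), 0.9)
  # constant column flagged undefined
  out_const <- behavioral_correlation(P, data.frame(const = rep(1, nrow(P))))
  expect_true(all(is.na(out_const$r)))
})

test_that("severity export paints regions and round-trips through CSV", {
  cube <- unit_cube_mesh()
  vlabs <- c(rep(1L, 4), rep(2L, 4))
  probs <- c(`1` = 0, `2` = 1)
  ply <- withr::local_tempfile(fileext = ".ply")
  csv <- withr::local_tempfile(fileext = ".csv")
  sev <- export_severity(probs, cube, vlabs, ply, csv)
  expect_equal(sev, c(rep(0, 4), rep(1, 4)))
  back <- attr(read_ply(ply), "scalars")$severity
  expect_equal(back, sev)
  expect_equal(read_severity_csv(csv), probs)
  # all-zero probabilities give a uniform minimal scalar
  expect_true(all(export_severity(c(`1` = 0, `2` = 0), cube, vlabs) == 0))
})
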