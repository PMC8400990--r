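# canonical label factor; MCI is the positive class throughout
as_diagnosis_factor <- function(labels) {
  f <- factor(as.character(labels), levels = c("NC", "MCI"))
  if (anyNA(f)) stop("labels must be 'NC' or 'MCI'")
  f
}

# md5 fingerprint of an arbitrary R object (bitwise on serialized doubles)
hash_object <- function(x) {
  raw <- serialize(x, NULL, version = 2L)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(raw, tmp)
  unname(tools::md5sum(tmp))
}

# decision values oriented so positive favours `positive`
svm_decision <- function(model, x, positive = "MCI") {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- sub("/.*", "", colnames(dv)[1])
  dv <- dv[, 1]
  if (first != positive) dv <- -dv
  unname(dv)
}

# Platt sigmoid calibration with smoothed targets:
# P(MCI | f) = 1 / (1 + exp(A f + B)), fit by minimizing the regularized
# negative log-likelihood on (decision value, label) pairs.
fit_platt <- function(dec, y, positive = "MCI") {
  yb <- y == positive
  np <- sum(yb); nn <- sum(!yb)
  tpos <- (np + 1) / (np + 2)
  tneg <- 1 / (nn + 2)
  tgt <- ifelse(yb, tpos, tneg)
  nll <- function(par) {
    z <- par[1] * dec + par[2]
    # stable -sum(t log p + (1-t) log(1-p)) with p = 1/(1+exp(z))
    sum(ifelse(z >= 0, tgt * z + log1p(exp(-z)),
               (tgt - 1) * z + log1p(exp(z))))
  }
  fit <- stats::optim(c(0, log((nn + 1) / (np + 1))), nll,
                      method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  list(A = fit$par[1], B = fit$par[2])
}

platt_prob <- function(platt, dec) {
  z <- platt$A * dec + platt$B
  1 / (1 + exp(pmin(500, pmax(-500, z))))
}

svm_fit <- function(x, y, kernel, cost) {
  gamma <- 1 / (ncol(x) * max(stats::var(as.vector(x)), 1e-8))
  e1071::svm(x, y, type = "C-classification", kernel = kernel,
             cost = cost, degree = 3, gamma = gamma, scale = FALSE,
             probability = FALSE)
}

# one region's calibrated probabilistic classifier: margin classifier plus
# Platt scaling fit on out-of-fold decision values from an inner stratified
# 3-fold CV on the training portion
train_regional_psvm <- function(x, y, kernel, cost, seed) {
  inner_k <- min(3L, min(table(y)))
  folds <- stratified_folds(y, inner_k, seed)
  oof_dec <- numeric(length(y))
  for (f in seq_len(inner_k)) {
    tr <- folds != f
    m <- svm_fit(x[tr, , drop = FALSE], droplevels(y[tr]), kernel, cost)
    oof_dec[!tr] <- svm_decision(m, x[!tr, , drop = FALSE])
  }
  final <- svm_fit(x, y, kernel, cost)
  list(svm = final, platt = fit_platt(oof_dec, y))
}

#' Stratified fold assignment
#'
#' @param labels Class labels.
#' @param k Number of folds; every fold receives at least one subject of
#'   each class.
#' @param seed Integer seed; the assignment is reproducible and leaves the
#'   global random state untouched.
#' @return Integer fold id (1..k) per subject.
#' @export
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  if (k > min(table(labels)))
    stop("k exceeds the smallest class count")
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

subset_subjects <- function(table, idx) {
  region_feature_table(table$features[idx, , , drop = FALSE],
                       table$subjects[idx], table$regions,
                       normalized = table$normalized,
                       norm_stats = table$norm_stats)
}

#' Train the two-layer regional diagnosis model
#'
#' Layer one fits, for every cortical region, a calibrated probabilistic
#' margin classifier on that region's fused features (min-max normalization
#' -> sequential CCA fusion -> SVM with Platt calibration by inner 3-fold
#' CV). Layer two fits a global margin classifier on the vector of regional
#' MCI probabilities. All statistics (normalization, fusion chains,
#' calibration) are estimated on the supplied subjects only, so the fitted
#' model can be replayed on held-out subjects without leakage.
#'
#' @param table A raw [region_feature_table()].
#' @param labels `"NC"` / `"MCI"` per subject; at least 3 of each.
#' @param kernel SVM kernel: `"linear"` (default), `"polynomial"` or
#'   `"radial"`.
#' @param cost SVM cost parameter (default 1).
#' @param seed Integer seed controlling inner-CV fold assignment.
#' @param min_region_frac Regions whose features are missing in more than
#'   this fraction of subjects are dropped with a warning (default 0.5).
#' @return Object of class `diagnosis_model`.
#' @export
train_diagnosis <- function(table, labels, kernel = "linear", cost = 1,
                            seed = 1L, min_region_frac = 0.5) {
  stopifnot(inherits(table, "region_feature_table"), !table$normalized)
  y <- as_diagnosis_factor(labels)
  if (min(table(y)) < 3L) stop("need at least 3 subjects per class")
  n <- length(y)

  norm <- normalize_features(table)
  miss_frac <- apply(norm$features, 2L, function(m) mean(apply(
    m, 1L, anyNA)))
  keep <- miss_frac <= min_region_frac
  if (any(!keep))
    warning(sum(!keep), " region(s) missing in > ",
            round(100 * min_region_frac), "% of subjects dropped: ",
            paste(utils::head(norm$regions[!keep], 10L), collapse = ", "))
  regions <- norm$regions[keep]
  imp <- suppressMessages(impute_missing(norm))

  chains <- vector("list", length(regions))
  regional <- vector("list", length(regions))
  probs <- matrix(NA_real_, n, length(regions),
                  dimnames = list(norm$subjects, as.character(regions)))
  for (i in seq_along(regions)) {
    ri <- match(regions[i], norm$regions)
    cols <- lapply(1:5, function(k) imp$features[, ri, k])
    chains[[i]] <- sequential_fuse(cols)
    x <- t(chains[[i]]$Z)
    regional[[i]] <- train_regional_psvm(x, y, kernel, cost,
                                         seed = as.integer(seed) + i)
    probs[, i] <- platt_prob(regional[[i]]$platt,
                             svm_decision(regional[[i]]$svm, x))
  }
  global <- svm_fit(probs, y, kernel, cost)
  structure(list(kernel = kernel, cost = cost, seed = as.integer(seed),
                 regions = regions, norm_stats = norm$norm_stats,
                 all_regions = norm$regions, chains = chains,
                 regional = regional, global = global,
                 train_probs = probs, positive = "MCI",
                 feature_order = region_feature_names()),
            class = "diagnosis_model")
}

#' @export
print.diagnosis_model <- function(x, ...) {
  cat("<diagnosis_model> ", length(x$regions), " regional classifiers (",
      x$kernel, " kernel), global layer over regional probabilities\n",
      sep = "")
  invisible(x)
}

#' Predict regional probabilities and the global diagnosis
#'
#' Held-out subjects pass through the stored normalization statistics, the
#' fitted fusion chains, the calibrated regional classifiers and the global
#' classifier; nothing is refit. The regional probability vector is the
#' subject's personalized severity map. A global decision value of exactly
#' zero is classified MCI (favouring sensitivity).
#'
#' @param model A [train_diagnosis()] model.
#' @param table A raw [region_feature_table()] with the same regions.
#' @return List: `regional` (subjects x regions matrix of MCI probabilities
#'   in [0, 1]), `label` (factor NC/MCI), `score` (global decision value,
#'   positive = MCI).
#' @export
predict_diagnosis <- function(model, table) {
  stopifnot(inherits(model, "diagnosis_model"),
            inherits(table, "region_feature_table"), !table$normalized)
  if (!identical(as.integer(table$regions), as.integer(model$all_regions)))
    stop("table regions do not match the fitted model")
  norm <- apply_normalization(table, model$norm_stats)
  imp <- suppressMessages(impute_missing(norm,
                                         model$norm_stats$col_means))
  n <- length(table$subjects)
  probs <- matrix(NA_real_, n, length(model$regions),
                  dimnames = list(table$subjects,
                                  as.character(model$regions)))
  for (i in seq_along(model$regions)) {
    ri <- match(model$regions[i], model$all_regions)
    cols <- lapply(1:5, function(k) imp$features[, ri, k])
    z <- sequential_transform(model$chains[[i]], cols)
    dec <- svm_decision(model$regional[[i]]$svm, t(z))
    probs[, i] <- platt_prob(model$regional[[i]]$platt, dec)
  }
  score <- svm_decision(model$global, probs)
  label <- factor(ifelse(score >= 0, "MCI", "NC"), levels = c("NC", "MCI"))
  list(regional = probs, label = label, score = score)
}

#' Diagnostic metrics from confusion counts
#'
#' MCI is the positive class: accuracy = (TP+TN)/total, sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), all reported in percent. A zero
#' denominator yields NA (flagged undefined), never 0.
#'
#' @param TP,FP,TN,FN Non-negative confusion counts, total > 0.
#' @return Named numeric vector `(accuracy, sensitivity, specificity)` in
#'   percent.
#' @export
compute_metrics <- function(TP, FP, TN, FN) {
  TP <- unname(TP); FP <- unname(FP); TN <- unname(TN); FN <- unname(FN)
  counts <- c(TP, FP, TN, FN)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("no observations")
  c(accuracy = 100 * (TP + TN) / total,
    sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_)
}

#' Stratified k-fold evaluation of the diagnosis pipeline
#'
#' For every fold the normalization statistics, the per-region fusion
#' chains and both classifier layers are fit on the training portion only
#' and replayed on the held-out portion. Confusion counts are pooled over
#' folds (per-fold metrics are also reported).
#'
#' @param table A raw [region_feature_table()].
#' @param labels NC/MCI per subject.
#' @param k Number of folds (the study uses 4 and 10).
#' @param kernel,cost Passed to [train_diagnosis()].
#' @param seed Integer seed for the fold assignment and inner CV.
#' @param folds Optional externally supplied fold assignment (overrides
#'   `k`/`seed` for the split).
#' @return Object of class `eval_report`: pooled `counts`
#'   (TP, FP, TN, FN), `metrics` (percent), `per_fold` data.frame, `k`,
#'   `seed`, `fold_assignment`, `fold_hash`.
#' @export
kfold_evaluate <- function(table, labels, k = 10L, kernel = "linear",
                           cost = 1, seed = 1L, folds = NULL) {
  y <- as_diagnosis_factor(labels)
  n <- length(y)
  if (k > n) stop("k exceeds the number of subjects")
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  counts <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- train_diagnosis(subset_subjects(table, which(tr)), y[tr],
                             kernel = kernel, cost = cost,
                             seed = as.integer(seed) * 1000L + f)
    pred <- predict_diagnosis(model, subset_subjects(table, which(!tr)))
    truth <- y[!tr]
    tp <- sum(pred$label == "MCI" & truth == "MCI")
    fp <- sum(pred$label == "MCI" & truth == "NC")
    tn <- sum(pred$label == "NC" & truth == "NC")
    fn <- sum(pred$label == "NC" & truth == "MCI")
    counts <- counts + c(TP = tp, FP = fp, TN = tn, FN = fn)
    m <- compute_metrics(tp, fp, tn, fn)
    per_fold[[f]] <- data.frame(fold = f, TP = tp, FP = fp, TN = tn,
                                FN = fn, accuracy = m["accuracy"],
                                sensitivity = m["sensitivity"],
                                specificity = m["specificity"],
                                row.names = NULL)
  }
  structure(list(counts = counts,
                 metrics = compute_metrics(counts["TP"], counts["FP"],
                                           counts["TN"], counts["FN"]),
                 per_fold = do.call(rbind, per_fold),
                 k = k, seed = as.integer(seed), n = n,
                 fold_assignment = folds,
                 fold_hash = hash_object(folds)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat("<eval_report> k=", x$k, " n=", x$n,
      sprintf(" | accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              m["accuracy"], m["sensitivity"], m["specificity"]), sep = "")
  cat("  pooled confusion: TP=", x$counts["TP"], " FP=", x$counts["FP"],
      " TN=", x$counts["TN"], " FN=", x$counts["FN"], "\n", sep = "")
  invisible(x)
}

# fused per-region design matrices for one train/test split (chains fit on
# the training portion only); used by the comparison classifiers
fused_design <- function(table, tr_idx, te_idx) {
  norm <- normalize_features(subset_subjects(table, tr_idx))
  imp_tr <- suppressMessages(impute_missing(norm))
  norm_te <- apply_normalization(subset_subjects(table, te_idx),
                                 norm$norm_stats)
  imp_te <- suppressMessages(impute_missing(norm_te,
                                            norm$norm_stats$col_means))
  R <- length(table$regions)
  xtr <- matrix(0, length(tr_idx), 2L * R)
  xte <- matrix(0, length(te_idx), 2L * R)
  for (ri in seq_len(R)) {
    cols_tr <- lapply(1:5, function(k) imp_tr$features[, ri, k])
    chain <- sequential_fuse(cols_tr)
    xtr[, (2 * ri - 1):(2 * ri)] <- t(chain$Z)
    cols_te <- lapply(1:5, function(k) imp_te$features[, ri, k])
    xte[, (2 * ri - 1):(2 * ri)] <- t(sequential_transform(chain, cols_te))
  }
  list(xtr = xtr, xte = xte)
}

#' Compare the pipeline against standard classifiers under identical folds
#'
#' Runs the two-layer pipeline with the linear, polynomial and RBF kernels,
#' and three standard comparison classifiers (decision tree, random-forest
#' ensemble, k-nearest-neighbours) on the concatenated per-region fused
#' features, all under the same stratified fold assignment (verified by a
#' shared fold hash in every report).
#'
#' @param table A raw [region_feature_table()].
#' @param labels NC/MCI per subject.
#' @param k Number of folds (default 10).
#' @param seed Fold seed.
#' @param cost SVM cost.
#' @param knn_k Neighbours for KNN (default 5).
#' @return Named list of `eval_report`s: `svm_linear`, `svm_polynomial`,
#'   `svm_rbf`, `decision_tree`, `ensemble`, `knn`.
#' @export
compare_classifiers <- function(table, labels, k = 10L, seed = 1L,
                                cost = 1, knn_k = 5L) {
  for (pkg in c("rpart", "randomForest", "class"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("package ", pkg, " is required for compare_classifiers()")
  y <- as_diagnosis_factor(labels)
  folds <- stratified_folds(y, k, seed)
  reports <- list()
  kernels <- c(svm_linear = "linear", svm_polynomial = "polynomial",
               svm_rbf = "radial")
  for (nm in names(kernels))
    reports[[nm]] <- kfold_evaluate(table, y, k = k, kernel = kernels[[nm]],
                                    cost = cost, seed = seed, folds = folds)
  flat <- list(decision_tree = NULL, ensemble = NULL, knn = NULL)
  counts <- lapply(flat, function(.) c(TP = 0L, FP = 0L, TN = 0L, FN = 0L))
  per_fold <- lapply(flat, function(.) vector("list", k))
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    d <- fused_design(table, tr, te)
    dtr <- data.frame(y = y[tr], d$xtr)
    dte <- data.frame(d$xte)
    names(dte) <- names(dtr)[-1]
    preds <- list(
      decision_tree = {
        fit <- rpart::rpart(y ~ ., data = dtr, method = "class")
        factor(as.character(stats::predict(fit, dte, type = "class")),
               levels = c("NC", "MCI"))
      },
      ensemble = withr::with_seed(as.integer(seed) + f, {
        fit <- randomForest::randomForest(d$xtr, y[tr])
        factor(as.character(stats::predict(fit, d$xte)),
               levels = c("NC", "MCI"))
      }),
      knn = factor(as.character(
        class::knn(d$xtr, d$xte, y[tr], k = knn_k)),
        levels = c("NC", "MCI")))
    for (nm in names(preds)) {
      p <- preds[[nm]]; truth <- y[te]
      add <- c(TP = sum(p == "MCI" & truth == "MCI"),
               FP = sum(p == "MCI" & truth == "NC"),
               TN = sum(p == "NC" & truth == "NC"),
               FN = sum(p == "NC" & truth == "MCI"))
      counts[[nm]] <- counts[[nm]] + add
      m <- compute_metrics(add["TP"], add["FP"], add["TN"], add["FN"])
      per_fold[[nm]][[f]] <- data.frame(fold = f, t(add), t(m),
                                        row.names = NULL)
    }
  }
  for (nm in names(flat)) {
    cn <- counts[[nm]]
    reports[[nm]] <- structure(
      list(counts = cn,
           metrics = compute_metrics(cn["TP"], cn["FP"], cn["TN"], cn["FN"]),
           per_fold = do.call(rbind, per_fold[[nm]]),
           k = k, seed = as.integer(seed), n = length(y),
           fold_assignment = folds, fold_hash = hash_object(folds)),
      class = "eval_report")
  }
  reports
}

#' Pearson correlation of regional probabilities with behavioural scores
#'
#' For every (region, score) pair: standard Pearson r with a two-sided
#' t-based p-value, pairwise deletion of missing scores. Raw p-values are
#' reported alongside Benjamini-Hochberg q-values. Pairs with fewer than 4
#' complete observations or a constant column are flagged undefined (NA).
#'
#' @param regional Subjects x regions matrix of regional MCI probabilities
#'   (column names = region ids).
#' @param scores Subjects x tasks data.frame or matrix of behavioural
#'   scores.
#' @return data.frame: `region`, `score`, `n`, `r`, `p`, `q`.
#' @export
behavioral_correlation <- function(regional, scores) {
  scores <- as.data.frame(scores)
  out <- expand.grid(region = colnames(regional), score = names(scores),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$r <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- regional[, out$region[i]]
    yv <- scores[[out$score[i]]]
    ok <- stats::complete.cases(x, yv)
    out$n[i] <- sum(ok)
    if (sum(ok) < 4L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(yv[ok]) == 0) next
    ct <- stats::cor.test(x[ok], yv[ok], method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Export a personalized regional severity map
#'
#' Paints each mesh vertex with its region's MCI probability (background
#' vertices get 0) and writes the coloured mesh as ASCII PLY plus a
#' per-region CSV. The severity scale is fixed to [0, 1].
#'
#' @param probs Named numeric vector of regional probabilities (names =
#'   region ids).
#' @param mesh A [trimesh()].
#' @param vertex_labels Region ids per vertex (from [label_vertices()]).
#' @param ply_path,csv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the per-vertex severity vector.
#' @export
export_severity <- function(probs, mesh, vertex_labels, ply_path = NULL,
                            csv_path = NULL) {
  sev <- rep(0, length(vertex_labels))
  hit <- match(as.character(vertex_labels), names(probs))
  sev[!is.na(hit)] <- probs[hit[!is.na(hit)]]
  if (!is.null(ply_path))
    write_ply(mesh, ply_path, scalars = list(severity = sev))
  if (!is.null(csv_path))
    utils::write.csv(data.frame(region = names(probs),
                                probability = unname(probs)),
                     csv_path, row.names = FALSE)
  invisible(sev)
}

#' Read a severity CSV written by [export_severity()]
#'
#' @param path CSV path.
#' @return Named numeric vector of regional probabilities.
#' @export
read_severity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$probability, df$region)
}

#' Audit a fold for test-set leakage
#'
#' Refits one fold's training-only state twice — once from the full cohort
#' and once after deleting a held-out subject of that fold — and compares
#' the [model_fingerprint()]s. Any dependence of the fitted normalization,
#' fusion chains or classifiers on held-out subjects would change the
#' fingerprint.
#'
#' @param table A raw [region_feature_table()].
#' @param labels NC/MCI per subject.
#' @param k,seed Fold configuration, as in [kfold_evaluate()].
#' @param fold Which fold to audit (default 1).
#' @param drop Which of the fold's test subjects to delete (default 1).
#' @return List: `identical` (logical), `hash_full`, `hash_dropped`.
#' @export
audit_leakage <- function(table, labels, k = 10L, seed = 1L, fold = 1L,
                          drop = 1L) {
  y <- as_diagnosis_factor(labels)
  folds <- stratified_folds(y, k, seed)
  tr <- which(folds != fold)
  te <- which(folds == fold)
  fit_seed <- as.integer(seed) * 1000L + as.integer(fold)
  fit_once <- function(subjects_present) {
    keep <- intersect(subjects_present, tr)
    train_diagnosis(subset_subjects(table, keep), y[keep], seed = fit_seed)
  }
  m_full <- fit_once(seq_along(y))
  m_drop <- fit_once(setdiff(seq_along(y), te[drop]))
  h1 <- model_fingerprint(m_full)
  h2 <- model_fingerprint(m_drop)
  list(identical = identical(h1, h2), hash_full = h1, hash_dropped = h2)
}

#' Fingerprint the training-derived state of a fitted model
#'
#' An md5 digest of everything estimated from the training subjects:
#' normalization statistics, fusion-chain transforms and correlations,
#' regional support vectors, coefficients and calibration parameters, and
#' the global classifier. Two fits on identical training data yield
#' identical fingerprints, so removing a *test* subject must not change a
#' fold's fingerprint — the no-leakage audit.
#'
#' @param model A [train_diagnosis()] model.
#' @return Character md5 string.
#' @export
model_fingerprint <- function(model) {
  svm_core <- function(m) list(coefs = m$coefs, rho = m$rho, SV = m$SV)
  hash_object(list(
    norm = model$norm_stats,
    chains = lapply(model$chains, function(ch)
      lapply(ch$models, function(m)
        list(m$Wx, m$Wy, m$correlations, m$x_mean, m$y_mean))),
    regional = lapply(model$regional, function(r)
      list(svm_core(r$svm), r$platt)),
    global = svm_core(model$global)))
}
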