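#' Split / replication configuration for the classification protocol
#'
#' Defaults mirror the clinical protocol: 59 subjects split into a training
#' set of 39 (11 malignant + 28 benign) and a testing set of 20 (10 + 10),
#' re-drawn at random 20 times, with five-fold cross-validation inside the
#' training set.
#'
#' @param n_train_malignant,n_train_benign Training class counts.
#' @param n_test_malignant,n_test_benign Testing class counts.
#' @param replications Number of random splits.
#' @param cv_folds Cross-validation folds for hyperparameter search.
#' @param seed Base seed; replication `r` uses `seed + r`.
#' @return An object of class `split_config`.
#' @export
split_config <- function(n_train_malignant = 11L, n_train_benign = 28L,
                         n_test_malignant = 10L, n_test_benign = 10L,
                         replications = 20L, cv_folds = 5L, seed = 1L) {
  stopifnot(replications >= 1, cv_folds >= 2)
  structure(list(n_train_malignant = n_train_malignant,
                 n_train_benign = n_train_benign,
                 n_test_malignant = n_test_malignant,
                 n_test_benign = n_test_benign,
                 replications = as.integer(replications),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "split_config")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Platt-style probability scaling: fit P(malignant | f) = sigmoid(a f + c)
# on decision values by minimizing cross-entropy against smoothed targets.
fit_platt <- function(dv, y_pos) {
  np <- sum(y_pos); nn <- sum(!y_pos)
  t <- ifelse(y_pos, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    p <- sigmoid(par[1] * dv + par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  fit <- stats::optim(c(1, 0), nll, method = "BFGS")
  fit$par
}

# Decision values oriented so larger = more malignant.
svm_decision <- function(model, X) {
  pr <- stats::predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (grepl("^malignant", colnames(dv)[1])) 1 else -1
  sgn * as.numeric(dv[, 1])
}

#' Train the image-feature SVM classifier (ImgSVM)
#'
#' Features are z-scored by training statistics; an RBF-kernel SVM is
#' tuned over the log2 grid `C in 2^(-5), 2^(-3), ..., 2^15` and
#' `gamma in 2^(-15), ..., 2^3` by mean accuracy under seeded stratified
#' five-fold cross-validation (ties broken toward smaller C, then smaller
#' gamma), then refit on the full training set. Predicted probabilities of
#' malignancy come from Platt-style scaling fitted on out-of-fold decision
#' values.
#'
#' @param features Numeric matrix / data.frame (rows = subjects).
#' @param labels Factor with levels `benign`, `malignant` (malignant =
#'   positive class); both classes must be present.
#' @param cv_folds Cross-validation folds.
#' @param seed Integer seed (fold assignment).
#' @param cost_grid,gamma_grid Hyperparameter grids.
#' @return An object of class `imgsvm` with `predict()` support.
#' @export
train_imgsvm <- function(features, labels, cv_folds = 5L, seed = 1L,
                         cost_grid = 2^seq(-5, 15, by = 2),
                         gamma_grid = 2^seq(-15, 3, by = 2)) {
  X <- as.matrix(features)
  y <- factor(labels, levels = c("benign", "malignant"))
  if (nlevels(droplevels(y)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  set.seed(seed)
  fold <- stratified_folds(y, cv_folds)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$cost, grid$gamma), ]
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2) next
      m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = grid$cost[g], gamma = grid$gamma[g],
                      scale = FALSE)
      correct <- correct +
        sum(stats::predict(m, Xs[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(acc)      # first max: smallest C, then smallest gamma
  model <- e1071::svm(Xs, y, kernel = "radial", cost = grid$cost[best],
                      gamma = grid$gamma[best], scale = FALSE)
  # out-of-fold decision values for probability calibration
  dv_oof <- numeric(length(y))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2) { dv_oof[!tr] <- 0; next }
    m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    scale = FALSE)
    dv_oof[!tr] <- svm_decision(m, Xs[!tr, , drop = FALSE])
  }
  platt <- fit_platt(dv_oof, y == "malignant")
  structure(list(model = model, center = ctr, scale = scl, platt = platt,
                 cost = grid$cost[best], gamma = grid$gamma[best],
                 cv_accuracy = acc[best]),
            class = "imgsvm")
}

#' @export
print.imgsvm <- function(x, ...) {
  cat(sprintf("<imgsvm> RBF SVM, C = 2^%g, gamma = 2^%g, CV accuracy %.3f\n",
              log2(x$cost), log2(x$gamma), x$cv_accuracy))
  invisible(x)
}

#' Predict malignancy probabilities with a trained ImgSVM
#' @param object An `imgsvm` model.
#' @param newdata Feature matrix / data.frame.
#' @param ... Unused.
#' @return Data.frame with `probability` (of malignancy) and `class`.
#' @export
predict.imgsvm <- function(object, newdata, ...) {
  Xs <- scale(as.matrix(newdata), object$center, object$scale)
  dv <- svm_decision(object$model, Xs)
  p <- sigmoid(object$platt[1] * dv + object$platt[2])
  data.frame(probability = p,
             class = factor(ifelse(p > 0.5, "malignant", "benign"),
                            levels = c("benign", "malignant")))
}

#' Area under the ROC curve (rank method)
#'
#' Mann-Whitney formulation with midranks, equivalent to the trapezoidal
#' area and to exhaustive pairwise concordance with ties counted 1/2.
#'
#' @param prob Predicted probabilities (or scores) of the positive class.
#' @param labels Logical / factor; positive = malignant.
#' @return AUC in `[0, 1]`, or `NA` for single-class labels.
#' @export
auc_roc <- function(prob, labels) {
  pos <- as.logical(labels == "malignant" | labels == TRUE)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated area: thresholds sweep the distinct predicted scores
#' in descending order and each recall increment is weighted by the
#' precision attained there.
#'
#' @inheritParams auc_roc
#' @return AUC-PR in `[0, 1]`, or `NA` for single-class labels.
#' @export
auc_pr <- function(prob, labels) {
  pos <- as.logical(labels == "malignant" | labels == TRUE)
  n1 <- sum(pos)
  if (n1 == 0 || n1 == length(pos)) return(NA_real_)
  ord <- order(prob, decreasing = TRUE)
  p <- prob[ord]; y <- pos[ord]
  # group ties: cumulative counts at each distinct threshold
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Hosmer-Lemeshow calibration test
#'
#' Chi-square goodness of fit comparing observed and expected event counts
#' across groups formed by deciles of the predicted probability. A p-value
#' above 0.05 indicates acceptable calibration.
#'
#' With `fitted = FALSE` (default) the statistic is referred to a
#' chi-square with `g` degrees of freedom, the correct null when the
#' probabilities were not estimated on the evaluated data (our use case:
#' held-out test sets). `fitted = TRUE` applies the classical `g - 2`
#' reduction for in-sample logistic fits.
#'
#' @param prob Predicted probabilities of the positive class.
#' @param labels Positive-class indicator (factor level `malignant` or
#'   logical).
#' @param groups Number of probability groups (default 10).
#' @param fitted Were the probabilities fitted on these same data?
#' @return List with `statistic`, `df`, `p_value`, `groups_used`.
#' @export
hosmer_lemeshow <- function(prob, labels, groups = 10L, fitted = FALSE) {
  pos <- as.numeric(labels == "malignant" | labels == TRUE)
  br <- unique(stats::quantile(prob, seq(0, 1, length.out = groups + 1),
                               type = 7))
  if (length(br) < 3) return(list(statistic = NA_real_, df = NA_real_,
                                  p_value = NA_real_, groups_used = 1L))
  g <- cut(prob, br, include.lowest = TRUE)
  O1 <- tapply(pos, g, sum)
  E1 <- tapply(prob, g, sum)
  ng <- tapply(pos, g, length)
  keep <- !is.na(ng)
  O1 <- O1[keep]; E1 <- E1[keep]; ng <- ng[keep]
  E1 <- pmin(pmax(E1, 1e-10), ng - 1e-10)
  stat <- sum((O1 - E1)^2 / E1 + ((ng - O1) - (ng - E1))^2 / (ng - E1))
  df <- length(ng) - if (fitted) 2 else 0
  if (df < 1) return(list(statistic = stat, df = df, p_value = NA_real_,
                          groups_used = length(ng)))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       groups_used = length(ng))
}

#' Evaluate binary predictions with the six-metric protocol
#'
#' Accuracy, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` (malignant
#' = positive class), AUC-ROC by the rank/trapezoidal method, AUC-PR by
#' precision-recall step interpolation, and the Hosmer-Lemeshow
#' calibration p-value over 10 probability-decile groups.
#'
#' @param prob Predicted malignancy probabilities.
#' @param labels True labels (`benign` / `malignant`).
#' @param classes Optional predicted classes; defaults to `prob > 0.5`.
#' @return Named list of the six metrics.
#' @export
evaluate_predictions <- function(prob, labels, classes = NULL) {
  y <- factor(labels, levels = c("benign", "malignant"))
  stopifnot(length(prob) == length(y))
  if (is.null(classes))
    classes <- factor(ifelse(prob > 0.5, "malignant", "benign"),
                      levels = levels(y))
  tp <- sum(classes == "malignant" & y == "malignant")
  fn <- sum(classes == "benign" & y == "malignant")
  tn <- sum(classes == "benign" & y == "benign")
  fp <- sum(classes == "malignant" & y == "benign")
  list(accuracy = (tp + tn) / length(y),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       auc_roc = auc_roc(prob, y),
       auc_pr = auc_pr(prob, y),
       calibration_p = hosmer_lemeshow(prob, y)$p_value)
}

#' Aggregate rank score across models
#'
#' For each metric column (all six treated as higher-is-better, the
#' calibration p-value included), models are sorted in descending order;
#' the highest value scores 10 and each next distinct value scores one
#' less, models sharing a value sharing the score. A model's aggregate is
#' the sum over the metric columns, so a model strictly best on all six
#' metrics scores 60.
#'
#' @param metric_table Data.frame / matrix, rows = models, 6 metric
#'   columns; row names identify models.
#' @param top_score Score of the best value per metric (default 10).
#' @return Named integer-valued vector of aggregate scores. Models with a
#'   missing metric are excluded with a warning.
#' @export
aggregate_score <- function(metric_table, top_score = 10) {
  M <- as.matrix(metric_table)
  stopifnot(nrow(M) >= 2)
  bad <- apply(M, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    warning("excluding model(s) with missing metrics: ",
            paste(rownames(M)[bad], collapse = ", "), call. = FALSE)
    M <- M[!bad, , drop = FALSE]
  }
  scores <- apply(M, 2, function(v) {
    r <- match(v, sort(unique(v), decreasing = TRUE))  # dense rank
    top_score - (r - 1)
  })
  out <- rowSums(scores)
  stats::setNames(out, rownames(M))
}

#' Run the repeated-split classification experiment
#'
#' Draws `replications` seeded stratified random splits with the
#' configured class counts, trains the image-feature SVM on each training
#' set, evaluates the six metrics on each held-out test set, and reports
#' their mean and standard deviation (plus normal-approximation 95%
#' confidence intervals for the AUCs) across replications.
#'
#' @param features Numeric matrix / data.frame of subject features.
#' @param labels Factor (`benign` / `malignant`).
#' @param config A [split_config()].
#' @return An object of class `eval_report`: `per_replication`
#'   (data.frame), `mean`, `sd`, `ci95`, and `config`.
#' @export
replicate_experiment <- function(features, labels, config = split_config()) {
  X <- as.matrix(features)
  y <- factor(labels, levels = c("benign", "malignant"))
  need_m <- config$n_train_malignant + config$n_test_malignant
  need_b <- config$n_train_benign + config$n_test_benign
  if (sum(y == "malignant") < need_m)
    stop("cohort has ", sum(y == "malignant"), " malignant subjects; ",
         need_m, " required", call. = FALSE)
  if (sum(y == "benign") < need_b)
    stop("cohort has ", sum(y == "benign"), " benign subjects; ",
         need_b, " required", call. = FALSE)
  reps <- vector("list", config$replications)
  for (r in seq_len(config$replications)) {
    set.seed(config$seed + r)
    im <- sample(which(y == "malignant"))
    ib <- sample(which(y == "benign"))
    tr <- c(im[seq_len(config$n_train_malignant)],
            ib[seq_len(config$n_train_benign)])
    te <- c(im[config$n_train_malignant + seq_len(config$n_test_malignant)],
            ib[config$n_train_benign + seq_len(config$n_test_benign)])
    fit <- train_imgsvm(X[tr, , drop = FALSE], y[tr],
                        cv_folds = config$cv_folds, seed = config$seed + r)
    pred <- predict(fit, X[te, , drop = FALSE])
    met <- evaluate_predictions(pred$probability, y[te], pred$class)
    reps[[r]] <- data.frame(replication = r, n_train = length(tr),
                            n_test = length(te), as.data.frame(met))
  }
  per <- do.call(rbind, reps)
  mcols <- c("accuracy", "sensitivity", "specificity", "auc_roc", "auc_pr",
             "calibration_p")
  mean_ <- colMeans(per[mcols], na.rm = TRUE)
  sd_ <- apply(per[mcols], 2, stats::sd, na.rm = TRUE)
  ci <- rbind(lower = mean_ - 1.96 * sd_ / sqrt(config$replications),
              upper = mean_ + 1.96 * sd_ / sqrt(config$replications))
  structure(list(per_replication = per, mean = mean_, sd = sd_, ci95 = ci,
                 config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d replications (train %d / test %d)\n",
              x$config$replications,
              x$per_replication$n_train[1], x$per_replication$n_test[1]))
  for (m in names(x$mean))
    cat(sprintf("  %-14s %.3f +/- %.3f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Random-forest feature importance
#'
#' Impurity-gain (Gini) importances from a seeded forest, normalized to
#' sum exactly 1. A constant feature column receives importance 0.
#'
#' @param features Numeric matrix / data.frame.
#' @param labels Class factor.
#' @param seed Integer seed.
#' @param n_trees Trees in the forest (default 500).
#' @return Named numeric vector summing to 1.
#' @export
rf_importance <- function(features, labels, seed = 1L, n_trees = 500L) {
  X <- as.matrix(features)
  y <- droplevels(factor(labels))
  stopifnot(nlevels(y) >= 2)
  set.seed(seed)
  fit <- randomForest::randomForest(X, y, ntree = n_trees)
  imp <- randomForest::importance(fit, type = 2)[, 1]
  imp / sum(imp)
}
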