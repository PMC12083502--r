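blob_data <- function(n_per = 20, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2, mean = sep), ncol = 2))
  y <- factor(rep(c("benign", "malignant"), each = n_per),
              levels = c("benign", "malignant"))
  list(X = X, y = y)
}

test_that("SVM separates well-separated blobs and is seed-deterministic", {
  d <- blob_data()
  fit <- train_imgsvm(d$X, d$y, seed = 3)
  ho <- blob_data(seed = 99)
  pred <- predict(fit, ho$X)
  expect_equal(mean(pred$class == ho$y), 1.0)
  expect_true(all(pred$probability[ho$y == "malignant"] > 0.5))

  fit2 <- train_imgsvm(d$X, d$y, seed = 3)
  expect_identical(c(fit$cost, fit$gamma), c(fit2$cost, fit2$gamma))
  expect_identical(fit$platt, fit2$platt)

  # uninformative features: CV accuracy near the majority-class rate
  set.seed(5)
  Xnull <- matrix(rnorm(60 * 3), 60, 3)
  ynull <- factor(rep(c("benign", "malignant"), c(40, 20)),
                  levels = c("benign", "malignant"))
  fitn <- train_imgsvm(Xnull, ynull, seed = 4)
  expect_lt(abs(fitn$cv_accuracy - 2 / 3), 0.15)

  expect_error(train_imgsvm(d$X, factor(rep("benign", 40),
                                        levels = c("benign", "malignant"))),
               "both classes")
})

test_that("metric identities hold on canonical prediction patterns", {
  y <- factor(rep(c("malignant", "benign"), each = 10),
              levels = c("benign", "malignant"))
  perfect <- c(rep(0.9, 10), rep(0.1, 10))
  m <- evaluate_predictions(perfect, y)
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "auc_roc", "auc_pr")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 auc_roc = 1, auc_pr = 1))

  allpos <- rep(0.9, 20)
  m <- evaluate_predictions(allpos, y)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_equal(m$accuracy, 0.5)

  # acc = (sens*P + spec*N) / (P + N) on random predictions
  set.seed(12)
  for (i in 1:5) {
    p <- runif(20)
    m <- evaluate_predictions(p, y)
    expect_equal(m$accuracy, (m$sensitivity * 10 + m$specificity * 10) / 20)
  }
})

test_that("AUC-ROC equals exhaustive pairwise concordance (ties = 1/2)", {
  set.seed(13)
  for (i in 1:6) {
    n <- sample(10:50, 1)
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    prob <- round(runif(n), 2)   # rounding forces ties
    expect_equal(auc_roc(prob, pos), auc_concordance(prob, pos),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(14)
  pos <- rep(c(TRUE, FALSE), each = 15)
  prob <- c(rnorm(15, 1), rnorm(15))
  expect_equal(auc_roc(prob, pos),
               as.numeric(pROC::auc(pROC::roc(pos, prob, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC-PR is exact on simple rankings", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_pr(c(0.9, 0.8, 0.2, 0.1), y), 1)
  # ranking with one inversion: precision steps 1, then 2/3 at recall 1/2 -> 1
  expect_equal(auc_pr(c(0.9, 0.3, 0.5, 0.1), y), 0.5 * 1 + 0.5 * 2 / 3)
})

test_that("Hosmer-Lemeshow is calibrated under the null", {
  set.seed(15)
  n_runs <- 500
  pvals <- replicate(n_runs, {
    p <- runif(200, 0.05, 0.95)
    yy <- runif(200) < p
    hosmer_lemeshow(p, yy)$p_value
  })
  rej <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
  # systematic miscalibration is detected
  set.seed(16)
  p <- runif(500, 0.05, 0.95)
  yy <- runif(500) < pmin(p + 0.25, 1)
  expect_lt(hosmer_lemeshow(p, yy)$p_value, 0.01)
})

test_that("aggregate scoring implements dense descending ranks", {
  metrics <- paste0("met", 1:6)
  tab <- matrix(0.5, 7, 6, dimnames = list(paste0("model", 1:7), metrics))
  tab["model1", ] <- 0.9
  sc <- aggregate_score(tab)
  expect_equal(unname(sc["model1"]), 60)
  expect_true(all(sc[-1] == 9 * 6))

  # identical rows share identical scores
  tab2 <- tab; tab2["model2", ] <- 0.9
  sc2 <- aggregate_score(tab2)
  expect_equal(unname(sc2["model1"]), unname(sc2["model2"]))

  # 7 distinct values per metric enumerate scores exactly {10, 9, ..., 4}
  set.seed(17)
  tab3 <- matrix(sample(42) / 42, 7, 6,
                 dimnames = list(paste0("m", 1:7), metrics))
  # enumeration oracle: score of model i on metric j = 10 - (number of
  # models with a strictly larger value)
  oracle <- matrix(0, 7, 6)
  for (i in 1:7) for (j in 1:6)
    oracle[i, j] <- 10 - sum(tab3[, j] > tab3[i, j])
  expect_true(all(apply(oracle, 2, function(cl) setequal(cl, 4:10))))
  expect_equal(unname(aggregate_score(tab3)), unname(rowSums(oracle)))

  tab4 <- tab; tab4["model3", 2] <- NA
  expect_warning(sc4 <- aggregate_score(tab4), "model3")
  expect_false("model3" %in% names(sc4))
})

test_that("repeated splits use the protocol counts and recover separability", {
  set.seed(18)
  n_b <- 38; n_m <- 21
  X <- rbind(matrix(rnorm(n_b * 3), ncol = 3),
             matrix(rnorm(n_m * 3, mean = 8), ncol = 3))
  y <- factor(rep(c("benign", "malignant"), c(n_b, n_m)),
              levels = c("benign", "malignant"))
  rep5 <- replicate_experiment(X, y, split_config(replications = 5, seed = 2))
  expect_equal(unique(rep5$per_replication$n_train), 39)
  expect_equal(unique(rep5$per_replication$n_test), 20)
  expect_equal(unname(rep5$mean["accuracy"]), 1)
  expect_equal(unname(rep5$sd["accuracy"]), 0)

  expect_error(replicate_experiment(X[1:30, ], y[1:30], split_config()),
               "malignant")
})

test_that("label-permuted features give chance-level AUC", {
  set.seed(19)
  X <- matrix(rnorm(59 * 4), 59, 4)
  y <- factor(rep(c("benign", "malignant"), c(38, 21)),
              levels = c("benign", "malignant"))
  repn <- replicate_experiment(X, y, split_config(replications = 20, seed = 7))
  expect_lt(abs(unname(repn$mean["auc_roc"]) - 0.5), 0.15)
})

test_that("random-forest importances are normalized and find planted signal", {
  set.seed(20)
  n <- 80
  X <- matrix(rnorm(n * 12), n, 12)
  y <- factor(ifelse(X[, 5] > 0, "malignant", "benign"))
  colnames(X) <- paste0("f", 1:12)
  imp <- rf_importance(X, y, seed = 9)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_equal(names(which.max(imp)), "f5")
  expect_identical(imp, rf_importance(X, y, seed = 9))

  Xc <- cbind(X, constant = 1)
  impc <- rf_importance(Xc, y, seed = 9)
  expect_equal(unname(impc["constant"]), 0)
})
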