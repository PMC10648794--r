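test_that("confusion counts partition the sample", {
  truth <- c(rep("OKC", 5), rep("NONKC", 5))
  cm <- confusion(truth, truth)
  expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(5L, 0L, 5L, 0L))
  all_pos <- confusion(truth, rep("OKC", 10))
  expect_identical(c(all_pos$tp, all_pos$fp, all_pos$tn, all_pos$fn), c(5L, 5L, 0L, 0L))

  set.seed(9)
  for (rep in 1:10) {
    yt <- sample(0:1, 30, replace = TRUE)
    yp <- sample(0:1, 30, replace = TRUE)
    cm <- confusion(yt, yp)
    # naive pairwise tally
    tally <- table(factor(yt, 0:1), factor(yp, 0:1))
    expect_identical(cm$tp, as.integer(tally["1", "1"]))
    expect_identical(cm$fp, as.integer(tally["0", "1"]))
    expect_identical(cm$tn, as.integer(tally["0", "0"]))
    expect_identical(cm$fn, as.integer(tally["1", "0"]))
    expect_identical(cm$tp + cm$fp + cm$tn + cm$fn, 30L)
  }
  expect_error(confusion(1:3, 1:2), "equal-length")
})

test_that("composite indices satisfy their defining identities", {
  # published sensitivity/specificity pair and its derived triple
  sens <- 0.969
  spec <- 0.979
  expect_equal(round(sens + spec - 1, 3), 0.948)
  expect_equal(round(sqrt(sens * spec), 3), 0.974)
  expect_equal(round((sens + spec) / 2, 3), 0.974)

  set.seed(21)
  for (rep in 1:15) {
    cm <- confusion_counts(
      sample(0:40, 1), sample(0:40, 1),
      sample(1:40, 1), sample(1:40, 1)
    )
    r <- metric_report(cm)
    if (!is.na(r$sensitivity) && !is.na(r$specificity)) {
      expect_equal(r$youden_j, r$sensitivity + r$specificity - 1)
      expect_equal(r$g_mean, sqrt(r$sensitivity * r$specificity))
      expect_equal(r$balanced_accuracy, (r$sensitivity + r$specificity) / 2)
    }
    expect_true(is.na(r$mcc) || (r$mcc >= -1 && r$mcc <= 1))
    expect_true(is.na(r$kappa) || (r$kappa >= -1 && r$kappa <= 1))
  }
})

test_that("hand-computed MCC and accuracy match", {
  r <- metric_report(confusion_counts(tp = 2, fp = 1, tn = 2, fn = 1))
  expect_equal(r$accuracy, 2 / 3, tolerance = 1e-12)
  expect_equal(r$mcc, 1 / 3, tolerance = 1e-12)
  expect_equal(r$kappa, 1 / 3, tolerance = 1e-12)
  expect_equal(r$jaccard, 2 / 4)
})

test_that("log loss uses the natural log with clipping", {
  y <- rep(c(0, 1), 10)
  expect_equal(log_loss(rep(0.5, 20), y), log(2), tolerance = 1e-12)
  # clipped probabilities keep the loss finite
  expect_true(is.finite(log_loss(c(0, 1), c(1, 0))))
  expect_gt(log_loss(c(0, 1), c(1, 0)), 30)
})

test_that("ROC starts at (0,0), ends at (1,1) and AUC matches the pair-count oracle", {
  y <- c(0, 0, 1, 1)
  perfect <- c(0.1, 0.2, 0.8, 0.9)
  pts <- roc_points(perfect, y)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(dplyr::last(pts$fpr), 1)
  expect_equal(dplyr::last(pts$tpr), 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))
  expect_equal(auc_score(perfect, y), 1)
  # indistinguishable scores force AUC 1/2
  expect_equal(auc_score(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:100, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    p <- round(runif(n), 2) # duplicated scores exercise tie handling
    expect_equal(auc_score(p, y), pair_count_auc(p, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  y <- sample(0:1, 60, replace = TRUE)
  y[1:2] <- 0:1
  p <- runif(60)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<")))
  expect_equal(auc_score(p, y), ref, tolerance = 1e-10)
})

test_that("label swap exchanges sensitivity and specificity", {
  set.seed(51)
  yt <- sample(0:1, 40, replace = TRUE)
  yp <- sample(0:1, 40, replace = TRUE)
  a <- metric_report(confusion(yt, yp))
  b <- metric_report(confusion(1 - yt, 1 - yp))
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$balanced_accuracy, b$balanced_accuracy)
  expect_equal(a$g_mean, b$g_mean)
})

test_that("undefined metrics are NA, never silently zero", {
  # no predicted positives: precision undefined
  r <- metric_report(confusion_counts(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_true(is.na(r$precision))
  expect_false(is.na(r$accuracy))
  # single-class truth: AUC undefined, reported as such
  r2 <- metric_report(confusion_counts(2, 1, 0, 0),
    probabilities = runif(3), truth = rep(1, 3)
  )
  expect_true(is.na(r2$auc))
  expect_match(r2$auc_note, "single class")
  expect_error(roc_points(runif(3), rep(1, 3)), "both classes")
})

test_that("metric reports tidy to a long table and Brier is the mean square", {
  p <- c(0.2, 0.7, 0.9)
  y <- c(0, 1, 1)
  r <- metric_report(confusion(y, as.integer(p >= 0.5)), probabilities = p, truth = y)
  expect_equal(r$brier, mean((p - y)^2))
  td <- tidy(r)
  expect_true(all(c("accuracy", "mcc", "auc", "g_mean") %in% td$metric))
  expect_identical(nrow(td), 15L)
  rep <- classification_report(c("OKC", "OKC", "NONKC"), c("OKC", "NONKC", "NONKC"))
  expect_equal(rep$support, c(2, 1))
})
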