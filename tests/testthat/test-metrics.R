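# Confusion counts, derived indices, ROC/AUC and cutoff selection.

test_that("confusion counts match direct tabulation", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 2, TN = 2, FP = 0, FN = 0))
  cc <- confusion(c(1, 0), c(0, 1))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 0, TN = 0, FP = 1, FN = 1))
  cc <- confusion(c(1, 1, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc[c("TP", "FN", "TN", "FP")]),
               c(TP = 2, FN = 1, TN = 1, FP = 0))
  expect_error(confusion(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("metric formulas agree with hand arithmetic on the 90/86 table", {
  m <- compute_metrics(list(TP = 90, FN = 10, TN = 86, FP = 14))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.86)
  expect_equal(m$dor, (90 * 86) / (14 * 10), tolerance = 1e-12)
  expect_equal(m$mcc, (90 * 86 - 14 * 10) / sqrt(104 * 100 * 100 * 96),
               tolerance = 1e-12)
  expect_equal(m$dp, (sqrt(3) / pi) * (log(0.9 / 0.1) + log(0.86 / 0.14)),
               tolerance = 1e-12)
})

test_that("degenerate confusion tables are flagged, not raised", {
  perfect <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$mcc, 1)
  expect_true(is.na(perfect$dor))
  expect_true(all(c("DOR", "DP") %in% attr(perfect, "undefined")))

  chance <- compute_metrics(list(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(chance$sensitivity, 0.5)
  expect_equal(chance$accuracy, 0.5)
  expect_equal(chance$mcc, 0)

  # all-negative predictions: sensitivity defined (0), precision undefined
  m <- compute_metrics(list(TP = 0, FN = 10, TN = 90, FP = 0))
  expect_equal(m$precision, 0)
  expect_true("precision" %in% attr(m, "undefined"))
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  set.seed(42)
  for (i in 1:1000) {
    counts <- as.list(setNames(rpois(4, 8) + (i %% 3 == 0),
                               c("TP", "FP", "TN", "FN")))
    truth <- c(rep(1, counts$TP + counts$FN), rep(0, counts$TN + counts$FP))
    pred <- c(rep(1, counts$TP), rep(0, counts$FN),
              rep(0, counts$TN), rep(1, counts$FP))
    expected <- suppressWarnings(cor(truth, pred))
    got <- mcc(counts)
    if (is.na(expected)) {
      expect_equal(got, 0)
    } else {
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant to scaling all four counts", {
  m1 <- compute_metrics(list(TP = 9, FP = 3, TN = 20, FN = 4))
  m2 <- compute_metrics(list(TP = 90, FP = 30, TN = 200, FN = 40))
  for (col in c("sensitivity", "specificity", "precision", "accuracy",
                "mcc", "dor", "dp")) {
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-12)
  }
})

test_that("AUC equals the normalized Mann-Whitney U, including ties", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- if (i %% 2 == 0) {
      sample(seq(0, 1, 0.25), n, replace = TRUE)  # heavy ties
    } else {
      runif(n)
    }
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    r <- rank(scores)  # midranks handle ties exactly as the U statistic
    u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
    expect_equal(roc_auc(scores, labels)$auc, u / (n1 * n0),
                 tolerance = 1e-12)
  }
})

test_that("ROC curve is anchored and monotone; worked AUC example holds", {
  ra <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
  expect_equal(ra$auc, 0.75)
  expect_equal(ra$curve$fpr[1], 0)
  expect_equal(ra$curve$tpr[1], 0)
  expect_equal(ra$curve$fpr[nrow(ra$curve)], 1)
  expect_equal(ra$curve$tpr[nrow(ra$curve)], 1)
  expect_true(all(diff(ra$curve$fpr) >= 0))
  expect_true(all(diff(ra$curve$tpr) >= 0))

  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("DP equals (sqrt(3)/pi) * log(DOR) wherever both are defined", {
  set.seed(11)
  for (i in 1:50) {
    counts <- list(TP = sample(1:50, 1), FP = sample(1:50, 1),
                   TN = sample(1:50, 1), FN = sample(1:50, 1))
    m <- compute_metrics(counts)
    if (!is.na(m$dor) && m$dor > 0) {
      expect_equal(m$dp, (sqrt(3) / pi) * log(m$dor), tolerance = 1e-10)
    }
  }
})

test_that("Youden cutoff follows the exhaustive-threshold oracle", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c(1, 0, 1, 0)
  # oracle: enumerate all thresholds, maximise TPR - FPR, smallest on ties
  js <- vapply(sort(unique(scores)), function(t) {
    pred <- as.numeric(scores >= t)
    mean(pred[labels == 1]) - mean(pred[labels == 0])
  }, numeric(1))
  best <- min(sort(unique(scores))[js == max(js)])
  expect_equal(optimal_cutoff(scores, labels), best)
  expect_equal(best, 0.3)

  # perfectly separated plateau: smallest optimal threshold in the score set
  s2 <- c(0.75, 0.8, 0.9, 0.1, 0.2, 0.25)
  y2 <- c(1, 1, 1, 0, 0, 0)
  expect_equal(optimal_cutoff(s2, y2), 0.75)

  # constant scores: J = 0 everywhere, returns the score (clipped)
  expect_equal(optimal_cutoff(rep(0.4, 4), c(1, 0, 1, 0)), 0.4)
  expect_lt(optimal_cutoff(rep(1, 4), c(1, 0, 1, 0)), 1)
})

test_that("haldane option gives finite DOR for degenerate tables", {
  m <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0), haldane = TRUE)
  expect_false(is.na(m$dor))
  expect_equal(m$dor, (5.5 * 5.5) / (0.5 * 0.5), tolerance = 1e-12)
})
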