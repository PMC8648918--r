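# Hold-out / k-fold drivers, permutation test, Cochran's Q, McNemar,
# Bonferroni.

test_that("hold-out driver confines fitting to the training partition", {
  fx <- make_separable(n = 200, seed = 3, sep = 6)
  ms <- evaluate_holdout(oracle_trainer(), fx$data, fx$labels, seed = 1)
  # the oracle rule is exact up to the Gaussian overlap at 0; near-perfect
  expect_gt(ms$accuracy, 0.9)
  ms2 <- evaluate_holdout(oracle_trainer(), fx$data, fx$labels, seed = 1)
  expect_identical(as.data.frame(ms), as.data.frame(ms2))

  # constant-majority trainer on 1:9 imbalance
  set.seed(5)
  y <- c(rep(1, 20), rep(0, 180))
  d <- tibble::tibble(f1 = rnorm(200))
  mm <- evaluate_holdout(majority_trainer(), d, y, seed = 2)
  expect_equal(mm$sensitivity, 0)
  expect_equal(mm$specificity, 1)
  expect_equal(mm$accuracy, 0.9)
})

test_that("k-fold pooling equals the sum of per-fold confusion counts", {
  fx <- make_separable(n = 160, seed = 9, sep = 6)
  res <- evaluate_kfold(oracle_trainer(), fx$data, fx$labels, k = 4, seed = 1)
  expect_equal(nrow(res$folds), 4)
  for (col in c("tp", "fp", "tn", "fn")) {
    expect_equal(sum(res$folds[[col]]), res$pooled[[col]])
  }
  expect_gt(res$pooled$accuracy, 0.9)
})

test_that("permutation test: shape, add-one p, and oracle separation", {
  fx <- make_separable(n = 120, seed = 4, sep = 6)
  rep10 <- permutation_test(oracle_trainer(), fx$data, fx$labels,
                            n_permutations = 10, seed = 1)
  expect_equal(nrow(rep10$permuted), 10)
  expect_true(all(rep10$p_values > 0, na.rm = TRUE))
  expect_true(all(rep10$p_values <= 1, na.rm = TRUE))
  # an (essentially) perfect rule beats every class-ratio-preserving shuffle
  expect_equal(unname(rep10$p_values[["mcc"]]), 1 / 11)
  # permutations preserve the class ratio exactly: permuted rows carry
  # metric sets computed against reshuffled labels of identical prevalence
  expect_true(all(rep10$permuted$tp + rep10$permuted$fn ==
                    rep10$real$tp + rep10$real$fn))
})

test_that("permutation null keeps a coin-flip trainer inside the distribution", {
  set.seed(8)
  y <- rbinom(80, 1, 0.5)
  d <- tibble::tibble(f1 = rnorm(80))
  coin <- trainer("coin",
                  fit = function(data, labels, seed) seed,
                  predict_class = function(model, data) {
                    set.seed(model)
                    rbinom(nrow(data), 1, 0.5)
                  })
  rep5 <- permutation_test(coin, d, y, n_permutations = 10, seed = 2)
  expect_gt(unname(rep5$p_values[["mcc"]]), 0.2)
})

test_that("Cochran's Q matches the closed form and handles degeneracy", {
  # identical columns: no heterogeneity
  m <- cbind(a = c(1, 0, 1, 1), b = c(1, 0, 1, 1))
  q <- cochran_q(m)
  expect_equal(q$q, 0)
  expect_equal(q$p_value, 1)

  # all rows constant: undefined flag
  m2 <- cbind(a = rep(1, 5), b = rep(1, 5))
  q2 <- cochran_q(m2)
  expect_true(q2$undefined)
  expect_equal(q2$p_value, 1)

  # k = 2 reduces to the uncorrected McNemar statistic (b - c)^2 / (b + c)
  set.seed(13)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    m3 <- cbind(rbinom(n, 1, 0.6), rbinom(n, 1, 0.5))
    b <- sum(m3[, 1] == 1 & m3[, 2] == 0)
    cc <- sum(m3[, 1] == 0 & m3[, 2] == 1)
    q3 <- cochran_q(m3)
    if (b + cc == 0) {
      expect_true(q3$undefined || q3$q == 0)
    } else {
      expect_equal(q3$q, (b - cc)^2 / (b + cc), tolerance = 1e-10)
    }
  }
})

test_that("Cochran's Q is invariant to row and column permutations", {
  set.seed(21)
  m <- cbind(rbinom(30, 1, 0.7), rbinom(30, 1, 0.5), rbinom(30, 1, 0.6))
  q0 <- cochran_q(m)$q
  expect_equal(cochran_q(m[sample(30), ])$q, q0, tolerance = 1e-12)
  expect_equal(cochran_q(m[, c(3, 1, 2)])$q, q0, tolerance = 1e-12)
})

test_that("McNemar exact p matches the binomial tail sum", {
  a <- c(rep(1, 15), rep(0, 5), rep(1, 10))
  b <- c(rep(0, 15), rep(1, 5), rep(1, 10))
  res <- mcnemar_test(a, b)
  expect_true(res$exact)
  # independent oracle: explicit binomial tail, not pbinom
  tail_sum <- sum(choose(20, 0:5)) / 2^20
  expect_equal(res$p_value, 2 * tail_sum, tolerance = 1e-6)
  expect_equal(res$p_value, 0.04138947, tolerance = 1e-6)

  sym <- mcnemar_test(c(rep(1, 10), rep(0, 10)), c(rep(0, 10), rep(1, 10)))
  expect_equal(sym$p_value, 1)

  none <- mcnemar_test(c(1, 1, 0), c(1, 1, 0))
  expect_equal(none$p_value, 1)
  expect_equal(none$statistic, 0)
})

test_that("McNemar large-sample branch uses the continuity correction", {
  a <- c(rep(1, 100), rep(0, 60), rep(1, 40))
  b <- c(rep(0, 100), rep(1, 60), rep(1, 40))
  res <- mcnemar_test(a, b)
  expect_false(res$exact)
  expect_equal(res$statistic, 39^2 / 160, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(39^2 / 160, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # chi-square(1) survival oracle via the normal tail
  expect_equal(res$p_value, 2 * pnorm(-sqrt(39^2 / 160)), tolerance = 1e-10)
})

test_that("exact and approximate McNemar agree for large discordance", {
  for (b in c(110, 130)) {
    for (cc in c(90, 100)) {
      n <- b + cc
      exact <- min(1, 2 * pbinom(min(b, cc), n, 0.5))
      approx <- pchisq((abs(b - cc) - 1)^2 / n, 1, lower.tail = FALSE)
      expect_lt(abs(exact - approx), 0.01)
    }
  }
})

test_that("McNemar type-I error stays near nominal under the null", {
  set.seed(31)
  rejections <- 0
  n_sim <- 1000
  for (i in seq_len(n_sim)) {
    # two equally accurate classifiers: correctness flips are symmetric
    a <- rbinom(60, 1, 0.7)
    b <- rbinom(60, 1, 0.7)
    if (mcnemar_test(a, b)$p_value <= 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / n_sim, 0.07)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.4, m = 5), 1)
  expect_equal(bonferroni(c(0.02, 0.03, 0.04)), c(0.06, 0.09, 0.12))
  expect_error(bonferroni(c(0.5, 1.2)), "0, 1")
})
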