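# The four reference classifiers and sequential forward selection.

test_that("intercept-only logistic predicts the prevalence", {
  d <- data.frame(row.names = 1:10)
  y <- c(rep(1, 3), rep(0, 7))
  fit <- fit_logistic(tibble::as_tibble(d), y)
  expect_equal(unname(predict(fit, tibble::as_tibble(d), type = "prob")),
               rep(0.3, 10), tolerance = 1e-6)
})

test_that("separable data is fit exactly with finite coefficients", {
  set.seed(3)
  d <- tibble::tibble(x = c(rnorm(20, -3), rnorm(20, 3)))
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(d, y)
  expect_true(all(is.finite(fit$coefficients)))
  expect_equal(predict(fit, d, type = "class"), y)
})

test_that("logistic cannot fit XOR (no linear separator exists)", {
  # An exhaustive check over linear rules on two binary inputs shows no
  # halfplane separates XOR; the best any linear rule can do is cut a
  # single corner. The logistic fit accordingly learns no real
  # discrimination: every fitted probability stays near 0.5 and the score
  # AUC is at chance, while a flexible fit on the interaction is perfect.
  set.seed(5)
  a <- rbinom(400, 1, 0.5); b <- rbinom(400, 1, 0.5)
  y <- as.numeric(xor(a, b))
  d <- tibble::tibble(a = a, b = b)
  fit <- fit_logistic(d, y)
  p <- predict(fit, d, type = "prob")
  expect_lt(max(abs(p - 0.5)), 0.1)
  auc <- roc_auc(p, y)$auc
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
  with_inter <- fit_logistic(dplyr::mutate(d, ab = a * b), y)
  expect_gt(mean(predict(with_inter, dplyr::mutate(d, ab = a * b),
                         type = "class") == y), 0.99)
})

test_that("logistic matches glm on a well-behaved problem", {
  set.seed(11)
  d <- tibble::tibble(x1 = rnorm(200), x2 = rnorm(200))
  y <- rbinom(200, 1, plogis(0.5 * d$x1 - 0.8 * d$x2))
  ours <- fit_logistic(d, y)
  ref <- glm(y ~ scale(d$x1) + scale(d$x2), family = binomial())
  expect_equal(unname(ours$coefficients),
               unname(coef(ref)), tolerance = 1e-4)
})

test_that("mean fitted probability equals prevalence (score equation)", {
  set.seed(13)
  d <- tibble::tibble(x = rnorm(150))
  y <- rbinom(150, 1, plogis(d$x))
  fit <- fit_logistic(d, y)
  expect_equal(mean(predict(fit, d, type = "prob")), mean(y),
               tolerance = 1e-6)
})

test_that("coefficient thresholding drops weak features and refits", {
  set.seed(17)
  d <- tibble::tibble(strong = rnorm(300), weak = rnorm(300))
  y <- rbinom(300, 1, plogis(2 * d$strong))
  fit <- fit_logistic(d, y, weight_threshold = 0.5)
  expect_equal(fit$features, "strong")
  expect_length(fit$coefficients, 2)  # intercept + kept feature
})

test_that("Poisson GLM: intercept-only rate is the label mean", {
  d <- data.frame(row.names = 1:20)
  y <- c(rep(1, 6), rep(0, 14))
  fit <- fit_glm_poisson(tibble::as_tibble(d), y)
  expect_equal(unname(predict(fit, tibble::as_tibble(d), type = "rate")),
               rep(0.3, 20), tolerance = 1e-8)
  # 0.3 < 0.5 so every prediction is negative
  expect_equal(unname(predict(fit, tibble::as_tibble(d), type = "class")),
               rep(0, 20))
})

test_that("Poisson GLM rates are monotone in a monotone signal", {
  set.seed(19)
  d <- tibble::tibble(x = sort(rnorm(100)))
  y <- rbinom(100, 1, plogis(2 * d$x))
  fit <- fit_glm_poisson(d, y)
  r <- predict(fit, d, type = "rate")
  expect_true(all(diff(r) >= -1e-12))
})

test_that("RBF-SVM solves XOR and wide-margin problems", {
  set.seed(23)
  n <- 200
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  d <- tibble::tibble(x1 = a + rnorm(n, sd = 0.15),
                      x2 = b + rnorm(n, sd = 0.15))
  y <- as.numeric(xor(a, b))
  fit <- fit_rbf_svm(d, y, seed = 1)
  acc <- mean(predict(fit, d, type = "class") == y)
  expect_gte(acc, 0.95)

  d2 <- tibble::tibble(x = c(rnorm(60, -4), rnorm(60, 4)))
  y2 <- rep(c(0, 1), each = 60)
  sp <- stratified_holdout_split(y2, 0.7, seed = 2)
  fit2 <- fit_rbf_svm(d2[sp$partitions$train, ], y2[sp$partitions$train],
                      seed = 2)
  expect_equal(predict(fit2, d2[sp$partitions$test, ], type = "class"),
               y2[sp$partitions$test])
  expect_error(fit_rbf_svm(d2, y2, tuning_grid = data.frame()), "empty")
})

test_that("SVM decision values orient toward the positive class", {
  set.seed(29)
  d <- tibble::tibble(x = c(rnorm(50, -2), rnorm(50, 2)))
  y <- rep(c(0, 1), each = 50)
  fit <- fit_rbf_svm(d, y, tuning_grid = data.frame(C = 1, gamma = 0.5),
                     seed = 1)
  dv <- predict(fit, d, type = "decision")
  expect_gt(mean(dv[y == 1]), mean(dv[y == 0]))
  expect_gt(roc_auc(dv, y)$auc, 0.95)
})

test_that("RBFN separates Gaussian blobs and degrades gracefully at K=1", {
  set.seed(31)
  d <- tibble::tibble(x1 = c(rnorm(80, -3), rnorm(80, 3)),
                      x2 = c(rnorm(80, -3), rnorm(80, 3)))
  y <- rep(c(0, 1), each = 80)
  sp <- stratified_holdout_split(y, 0.7, seed = 1)
  fit <- fit_rbfn(d[sp$partitions$train, ], y[sp$partitions$train],
                  K = 2, seed = 1)
  acc <- mean(predict(fit, d[sp$partitions$test, ], type = "class") ==
                y[sp$partitions$test])
  expect_gte(acc, 0.95)

  fit1 <- fit_rbfn(d, y, K = 1, seed = 1)
  m1 <- metric_set(y, predict(fit1, d, type = "class"))
  expect_lte(abs(m1$mcc), 0.3)  # single prototype has no discriminative geometry

  f_a <- fit_rbfn(d, y, K = 3, seed = 7)
  f_b <- fit_rbfn(d, y, K = 3, seed = 7)
  expect_identical(f_a$centers, f_b$centers)
  expect_error(fit_rbfn(d[1:5, ], y[1:5], K = 10), "exceeds")
})

test_that("SFS picks the informative feature first and respects caps", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 90
    y <- rep(c(0, 1), length.out = n)
    d <- tibble::tibble(signal = y * 2.5 + rnorm(n),
                        n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                        n4 = rnorm(n), n5 = rnorm(n))
    sel <- sequential_forward_selection(fast_lr_trainer(), d, y, seed = s)
    if (sel[1] == "signal") hits <- hits + 1
  }
  expect_gte(hits, 9)

  # identical features: exactly one survives the improvement rule
  set.seed(3)
  y <- rep(c(0, 1), 30)
  d2 <- tibble::tibble(a = y + rnorm(60, sd = 0.6))
  d2$b <- d2$a
  d2$c <- d2$a
  sel2 <- sequential_forward_selection(fast_lr_trainer(), d2, y, seed = 1)
  expect_length(sel2, 1)

  sel3 <- sequential_forward_selection(fast_lr_trainer(), d2, y,
                                       max_features = 2, seed = 1)
  expect_lte(length(sel3), 2)
})
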