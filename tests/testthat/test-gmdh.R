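# GMDH neurons, PSO fitting, layer-wise training and prediction.

test_that("neuron response is the clamped logistic of the basis expansion", {
  n0 <- structure(list(basis = gmdh_basis(c("const")),
                       coefficients = c(0)), class = "gmdh_neuron")
  expect_equal(neuron_response(n0, u = 1.3, v = -2), 0.5)

  n1 <- structure(list(basis = gmdh_basis(c("const")),
                       coefficients = c(20)), class = "gmdh_neuron")
  expect_gt(neuron_response(n1, 0, 0), 0.999)

  n2 <- structure(list(basis = gmdh_basis(c("const", "u")),
                       coefficients = c(0, 1)), class = "gmdh_neuron")
  expect_equal(neuron_response(n2, u = 1, v = 99), plogis(1),
               tolerance = 1e-12)

  # responses stay strictly inside (0, 1) even for extreme inputs
  n3 <- structure(list(basis = gmdh_basis(),
                       coefficients = rep(10, length(gmdh_basis()))),
                  class = "gmdh_neuron")
  r <- neuron_response(n3, u = c(-50, 0, 50), v = c(50, 0, -50))
  expect_true(all(r > 0 & r < 1))
  expect_true(all(is.finite(r)))
})

test_that("PSO fits a separable neuron to MCC 1 and is deterministic", {
  set.seed(1)
  y <- rep(c(0, 1), each = 20)
  u <- y * 2 - 1 + rnorm(40, sd = 0.1)  # margin around +-1
  v <- rnorm(40)
  # exhaustive 1-D threshold oracle: some threshold separates u perfectly
  thr_acc <- max(vapply(sort(u), function(t) mean((u >= t) == y), numeric(1)))
  expect_equal(thr_acc, 1)
  nr <- fit_neuron_pso(u, v, y, basis = gmdh_basis(c("const", "u")),
                       pso = pso_config(seed = 4))
  expect_equal(nr$estimation_mcc, 1)

  nr2 <- fit_neuron_pso(u, v, y, basis = gmdh_basis(c("const", "u")),
                        pso = pso_config(seed = 4))
  expect_identical(nr$coefficients, nr2$coefficients)
})

test_that("PSO cannot learn permuted labels", {
  mccs <- vapply(1:20, function(s) {
    set.seed(s)
    u <- rnorm(200); v <- rnorm(200)
    y <- sample(rep(c(0, 1), each = 100))
    fit_neuron_pso(u, v, y, pso = pso_config(seed = s))$estimation_mcc
  }, numeric(1))
  # null bound from simulating this permutation distribution: the swarm
  # can overfit 200 random labels with a 12-term basis to MCC ~ 0.33 at
  # most; anything materially above that would signal leakage
  expect_lte(max(mccs), 0.35)
  expect_lte(median(mccs), 0.3)
})

test_that("degenerate constant inputs yield a flagged zero-MCC neuron", {
  y <- rep(c(0, 1), 10)
  nr <- fit_neuron_pso(rep(1, 20), rep(2, 20), y)
  expect_true(nr$degenerate)
  expect_equal(nr$estimation_mcc, 0)
})

test_that("training learns a separable problem and respects top_k", {
  fx <- make_separable(n = 300, seed = 1, sep = 3, p_pos = 1 / 6)
  cfg <- gmdh_config(seed = 1)
  ms <- evaluate_holdout(gmdh_trainer(cfg), fx$data, fx$labels, seed = 1)
  expect_gte(ms$mcc, 0.8)

  m <- train_gmdh(fx$data, fx$labels, cfg)
  for (l in m$layers) expect_lte(length(l), cfg$top_k)
  # validation MCC of accepted layers is strictly increasing
  expect_true(all(diff(m$validation_trace) > 0) ||
                length(m$validation_trace) == 1)
  expect_gt(m$cutoff, 0)
  expect_lt(m$cutoff, 1)
})

test_that("pure-noise data stops early and scores near chance", {
  mccs <- vapply(1:6, function(s) {
    set.seed(s)
    d <- tibble::tibble(a = rnorm(160), b = rnorm(160), c = rnorm(160))
    y <- sample(rep(c(0, 1), each = 80))
    # pure-noise relief weights can degenerate to uniform, with a warning
    m <- suppressWarnings(
      evaluate_holdout(gmdh_trainer(gmdh_config(seed = s)), d, y, seed = s))
    m$mcc
  }, numeric(1))
  expect_lte(median(abs(mccs)), 0.15)
})

test_that("prediction is pure and range-bounded; errors name missing columns", {
  fx <- make_separable(n = 150, seed = 2)
  m <- train_gmdh(fx$data, fx$labels, gmdh_config(seed = 2))
  s <- predict_scores(m, fx$data)
  expect_true(all(s >= 0 & s <= 1))
  dup <- fx$data[c(1, 1, 5, 5), ]
  sd2 <- predict_scores(m, dup)
  expect_equal(sd2[1], sd2[2])
  expect_equal(sd2[3], sd2[4])
  expect_error(predict_scores(m, fx$data[, 1, drop = FALSE]), "missing feature")
  hard <- predict(m, fx$data, type = "class")
  expect_true(all(hard %in% c(0, 1)))
})

test_that("a perfectly fitted separable model reproduces training labels", {
  set.seed(7)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  d <- tibble::tibble(f1 = y * 6 - 3 + rnorm(n, sd = 0.2),
                      f2 = y * 6 - 3 + rnorm(n, sd = 0.2))
  m <- train_gmdh(d, y, gmdh_config(seed = 3))
  expect_equal(predict(m, d, type = "class"), y)
})

test_that("training is a pure function of data and seeds", {
  fx <- make_separable(n = 150, seed = 6)
  m1 <- train_gmdh(fx$data, fx$labels, gmdh_config(seed = 9))
  m2 <- train_gmdh(fx$data, fx$labels, gmdh_config(seed = 9))
  expect_identical(predict_scores(m1, fx$data), predict_scores(m2, fx$data))
  expect_identical(m1$cutoff, m2$cutoff)
})

test_that("model JSON round trip preserves scores bit-exactly", {
  fx <- make_separable(n = 150, seed = 8)
  m <- train_gmdh(fx$data, fx$labels, gmdh_config(seed = 5))
  m2 <- gmdh_from_json(gmdh_to_json(m))
  expect_identical(predict_scores(m2, fx$data), predict_scores(m, fx$data))
  expect_identical(m2$cutoff, m$cutoff)
})

test_that("degenerate feature tables are rejected", {
  y <- rep(c(0, 1), 10)
  expect_error(train_gmdh(tibble::tibble(a = rep(1, 20), b = rep(2, 20)),
                          y, gmdh_config(seed = 1)), "constant")
  expect_error(train_gmdh(tibble::tibble(a = rnorm(20), b = rep(1, 20)),
                          y, gmdh_config(seed = 1)), "2 non-constant")
})

test_that("generic PSO maximises a smooth objective", {
  vals <- vapply(1:10, function(s) {
    pso_optimize(function(x) -sum(x^2), dim = 5,
                 config = pso_config(seed = s))$value
  }, numeric(1))
  expect_true(all(vals > -1e-2))
  r1 <- pso_optimize(function(x) -sum((x - 3)^2), dim = 2,
                     config = pso_config(seed = 2))
  expect_equal(r1$par, c(3, 3), tolerance = 0.05)
  r2 <- pso_optimize(function(x) -sum((x - 3)^2), dim = 2,
                     config = pso_config(seed = 2))
  expect_identical(r1$par, r2$par)
})
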