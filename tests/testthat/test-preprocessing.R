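# Categorical logistic encoding and I-RELIEF feature weighting.

test_that("encoder maps categories to their positive-class probability", {
  # category A: 3 positives / 7 negatives; B: 2 / 2; C: only positives
  codes <- c(rep(0, 10), rep(1, 4), rep(2, 3))
  y <- c(rep(1, 3), rep(0, 7), 1, 1, 0, 0, 1, 1, 1)
  ft <- feature_table(data.frame(f = codes), kinds = c(f = "categorical"))
  enc <- fit_categorical_encoder(ft, y)
  m <- enc$maps$f
  expect_equal(unname(m["0"]), 0.3, tolerance = 1e-4)
  expect_equal(unname(m["1"]), 0.5, tolerance = 1e-4)
  # pure-positive category clips to the upper boundary
  expect_equal(unname(m["2"]), 1 - 1e-6, tolerance = 1e-7)
  # fallback for unseen categories is the fitting prevalence
  expect_equal(enc$fallback, mean(y), tolerance = 1e-9)
})

test_that("encoder ranks categories like their empirical proportions", {
  set.seed(2)
  codes <- sample(0:4, 300, replace = TRUE)
  y <- rbinom(300, 1, plogis(codes - 2))
  ft <- feature_table(data.frame(f = codes), kinds = c(f = "categorical"))
  enc <- fit_categorical_encoder(ft, y)
  emp <- vapply(0:4, function(l) mean(y[codes == l]), numeric(1))
  expect_equal(order(enc$maps$f), order(emp))
  # saturated logistic MLE equals the per-category empirical proportion
  expect_equal(unname(enc$maps$f), emp, tolerance = 1e-4)
})

test_that("apply_encoder replaces categorical columns and handles unseen codes", {
  ft <- feature_table(data.frame(f = c(0, 0, 1, 1), g = c(0.3, 1, 2, 0)),
                      kinds = c(f = "categorical"))
  y <- c(1, 0, 1, 1)
  enc <- fit_categorical_encoder(ft, y)
  out <- apply_encoder(enc, ft)
  expect_equal(unname(feature_kinds(out)["f"]), "continuous")
  expect_equal(out$g, ft$g)  # continuous passes through
  expect_equal(out$f[1], unname(enc$maps$f["0"]))

  ft2 <- feature_table(data.frame(f = c(0, 9), g = c(1, 2)),
                       kinds = c(f = "categorical"))
  out2 <- apply_encoder(enc, ft2)
  expect_equal(out2$f[2], enc$fallback)
  expect_equal(attr(out2, "n_fallback"), 1L)

  only_cont <- feature_table(data.frame(g = c(1, 2)))
  enc0 <- fit_categorical_encoder(only_cont, c(1, 0))
  passed <- apply_encoder(enc0, only_cont)
  expect_identical(passed$g, only_cont$g)
  expect_identical(feature_kinds(passed), feature_kinds(only_cont))
})

test_that("encoder survives a JSON round trip", {
  ft <- feature_table(data.frame(f = c(0, 0, 1, 1, 2, 2)),
                      kinds = c(f = "categorical"))
  enc <- fit_categorical_encoder(ft, c(1, 0, 1, 1, 0, 0))
  enc2 <- encoder_from_json(encoder_to_json(enc))
  expect_equal(enc2$maps$f, enc$maps$f, tolerance = 1e-12)
  expect_equal(enc2$fallback, enc$fallback)
})

test_that("I-RELIEF upweights the separating feature", {
  fx <- make_relief_fixture(n = 100, seed = 5)
  w <- irelief_weights(fx$data, fx$labels)
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
  expect_true(all(w$weights >= 0))
  expect_equal(names(which.max(w$weights)), "signal")
  expect_gt(w$weights[["signal"]], 0.5)
})

test_that("I-RELIEF weight matches a brute-force single-pass Relief oracle", {
  fx <- make_relief_fixture(n = 60, seed = 11)
  X <- scale(as.matrix(fx$data))
  y <- fx$labels
  # oracle: classic Relief-F with hard nearest hit/miss under L1 distance
  n <- nrow(X)
  margins <- matrix(0, n, ncol(X))
  for (i in seq_len(n)) {
    d <- colSums(abs(t(X) - X[i, ]))
    d[i] <- Inf
    hit <- which.min(ifelse(y == y[i], d, Inf))
    miss <- which.min(ifelse(y != y[i], d, Inf))
    margins[i, ] <- abs(X[i, ] - X[miss, ]) - abs(X[i, ] - X[hit, ])
  }
  oracle <- pmax(colMeans(margins), 0)
  oracle <- oracle / sum(oracle)
  w <- irelief_weights(fx$data, y)
  # same winner, and agreement on which features are (near) zero
  expect_equal(unname(which.max(w$weights)), which.max(oracle))
  expect_equal(unname(which(w$weights > 0.1)), which(oracle > 0.1))
})

test_that("I-RELIEF degenerate and symmetry behaviour", {
  d <- data.frame(a = rep(1, 20), b = rep(0, 20))
  y <- rep(c(0, 1), 10)
  expect_warning(w <- irelief_weights(d, y), "constant|uniform")
  expect_equal(unname(w$weights), c(0.5, 0.5))

  fx <- make_relief_fixture(n = 80, seed = 3)
  dup <- fx$data
  dup$signal2 <- dup$signal
  w2 <- irelief_weights(dup, fx$labels)
  expect_equal(w2$weights[["signal"]], w2$weights[["signal2"]],
               tolerance = 1e-6)
})

test_that("weights stay on the simplex and noise decays with n", {
  set.seed(6)
  noise_w_small <- noise_w_big <- numeric(0)
  for (s in 1:5) {
    fx1 <- make_relief_fixture(n = 40, seed = s)
    fx2 <- make_relief_fixture(n = 200, seed = s)
    w1 <- irelief_weights(fx1$data, fx1$labels)
    w2 <- irelief_weights(fx2$data, fx2$labels)
    expect_equal(sum(w1$weights), 1, tolerance = 1e-9)
    expect_equal(sum(w2$weights), 1, tolerance = 1e-9)
    noise_w_small <- c(noise_w_small, max(w1$weights[-1]))
    noise_w_big <- c(noise_w_big, max(w2$weights[-1]))
  }
  expect_lt(median(noise_w_big), median(noise_w_small) + 0.02)
  expect_lt(median(noise_w_big), 0.1)
})

test_that("permuting labels flattens the informative weight", {
  fx <- make_relief_fixture(n = 80, seed = 13)
  real_w <- irelief_weights(fx$data, fx$labels)$weights[["signal"]]
  perm_w <- vapply(1:20, function(i) {
    set.seed(100 + i)
    irelief_weights(fx$data, sample(fx$labels))$weights[["signal"]]
  }, numeric(1))
  # real weight exceeds every permuted weight (rank test at p = 1/21)
  expect_true(all(real_w > perm_w))
})

test_that("select_features implements top-m, threshold and fallbacks", {
  w <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(unname(select_features(w, top_m = 2)), c(1, 2))
  w2 <- c(a = 0.4, b = 0.4, c = 0.2)
  expect_equal(unname(select_features(w2, top_m = 1)), 1)  # tie -> lower index
  w3 <- c(a = 0.25, b = 0.2, c = 0.2, d = 0.2, e = 0.15)
  expect_equal(unname(select_features(w3, min_weight = 0.9)), 1)  # fallback
  expect_warning(sel <- select_features(w, top_m = 5), "exceeds")
  expect_length(sel, 3)
  expect_error(select_features(w, top_m = 1, min_weight = 0.1), "exactly one")
})
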