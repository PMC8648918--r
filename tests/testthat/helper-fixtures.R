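# Shared fixtures, built in code at test time.

# Two well-separated Gaussian features plus noise, mild imbalance.
make_separable <- function(n = 120, seed = 1, sep = 3, p_pos = 1 / 4) {
  set.seed(seed)
  y <- rbinom(n, 1, p_pos)
  while (length(unique(y)) < 2 || min(table(y)) < 4) y <- rbinom(n, 1, p_pos)
  mu <- sep * (y - 0.5)  # class means +-sep/2, so f1 > 0 is the Bayes rule
  d <- tibble::tibble(f1 = rnorm(n, mu),
                      f2 = rnorm(n, mu),
                      f3 = rnorm(n))
  list(data = d, labels = y)
}

# One perfectly separating feature + iid noise features.
make_relief_fixture <- function(n = 100, n_noise = 9, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  d <- as.data.frame(matrix(rnorm(n * n_noise), n))
  names(d) <- paste0("noise_", seq_len(n_noise))
  d <- cbind(signal = y * 2 + rnorm(n, sd = 0.1), d)
  list(data = tibble::as_tibble(d), labels = y)
}

# Trainer that memorises the rule y = 1[f1 > 0]; deterministic oracle.
oracle_trainer <- function() {
  trainer(name = "oracle",
          fit = function(data, labels, seed) NULL,
          predict_class = function(model, data) {
            as.numeric(tibble::as_tibble(data)$f1 > 0)
          },
          predict_score = function(model, data) {
            tibble::as_tibble(data)$f1
          })
}

# Trainer that always predicts the majority class of its training labels.
majority_trainer <- function() {
  trainer(name = "majority",
          fit = function(data, labels, seed) {
            as.numeric(mean(labels) >= 0.5)
          },
          predict_class = function(model, data) rep(model, nrow(data)),
          predict_score = NULL)
}

# Fast logistic trainer for wrapper tests.
fast_lr_trainer <- function() {
  trainer(name = "fast_lr",
          fit = function(data, labels, seed) fit_logistic(data, labels),
          predict_class = function(model, data) {
            predict(model, data, type = "class")
          },
          predict_score = function(model, data) {
            predict(model, data, type = "prob")
          })
}

# Deterministic label permutation that leaves the global RNG untouched.
with_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(x)
}

write_csv_fixture <- function(text, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}
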