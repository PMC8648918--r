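# Model assessment protocol: hold-out and k-fold drivers, the
# label-permutation test, and Cochran's Q + McNemar post-hoc comparisons
# with Bonferroni correction.

#' Hold-out evaluation of a trainer
#'
#' Splits the data with [stratified_holdout_split()], fits the trainer on
#' the training partition only (encoding, oversampling and every other
#' fitted component happen inside `trainer$fit` on those rows), and
#' reports test-partition metrics. Deterministic per seed.
#'
#' @param trainer A [trainer()].
#' @param data,labels The full dataset.
#' @param train_fraction Training fraction of the split (default 0.7).
#' @param seed Split and trainer seed.
#' @param stratify Stratify the split by class.
#' @return A [metric_set()] row with the test predictions in attributes
#'   `predictions` (tibble: index, truth, estimate, score) and `split`.
#' @export
evaluate_holdout <- function(trainer, data, labels, train_fraction = 0.7,
                             seed = 1L, stratify = TRUE) {
  labels <- check_labels(labels, n = nrow(data))
  sp <- stratified_holdout_split(labels, train_fraction, seed = seed,
                                 stratify = stratify)
  tr <- sp$partitions$train; te <- sp$partitions$test
  d <- as_tibble(data)
  kinds <- feature_kinds(data)
  d_tr <- feature_table(d[tr, , drop = FALSE], kinds = kinds,
                        sample_ids = sample_ids(data)[tr])
  d_te <- feature_table(d[te, , drop = FALSE], kinds = kinds,
                        sample_ids = sample_ids(data)[te])
  model <- trainer$fit(d_tr, labels[tr], seed = seed)
  est <- trainer$predict_class(model, d_te)
  sc <- if (!is.null(trainer$predict_score)) {
    trainer$predict_score(model, d_te)
  } else NULL
  ms <- metric_set(labels[te], est, scores = sc)
  attr(ms, "predictions") <- tibble(index = te, truth = labels[te],
                                    estimate = est,
                                    score = if (is.null(sc)) NA_real_ else sc)
  attr(ms, "split") <- sp
  ms
}

#' Stratified k-fold evaluation of a trainer
#'
#' Folds from [kfold_indices()]; each fold is predicted by a model fitted
#' on the remaining folds. Pooled metrics come from the concatenated
#' out-of-fold predictions, so pooled confusion counts are the sums of the
#' per-fold counts.
#'
#' @inheritParams evaluate_holdout
#' @param k Number of folds (default 4).
#' @return List with `folds` (tibble of per-fold metrics) and `pooled`
#'   (a [metric_set()] row over all out-of-fold predictions).
#' @export
evaluate_kfold <- function(trainer, data, labels, k = 4L, seed = 1L) {
  labels <- check_labels(labels, n = nrow(data))
  sp <- kfold_indices(labels, k = k, seed = seed)
  d <- as_tibble(data)
  kinds <- feature_kinds(data)
  ids <- sample_ids(data)
  est_all <- rep(NA_real_, length(labels))
  sc_all <- rep(NA_real_, length(labels))
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    te <- sp$partitions[[f]]
    tr <- setdiff(seq_along(labels), te)
    d_tr <- feature_table(d[tr, , drop = FALSE], kinds = kinds,
                          sample_ids = ids[tr])
    d_te <- feature_table(d[te, , drop = FALSE], kinds = kinds,
                          sample_ids = ids[te])
    model <- trainer$fit(d_tr, labels[tr], seed = seed + f)
    est_all[te] <- trainer$predict_class(model, d_te)
    if (!is.null(trainer$predict_score)) {
      sc_all[te] <- trainer$predict_score(model, d_te)
    }
    fold_metrics[[f]] <- mutate(as_tibble(metric_set(labels[te], est_all[te])),
                                fold = f, .before = 1L)
  }
  pooled <- metric_set(labels, est_all,
                       scores = if (all(is.na(sc_all))) NULL else sc_all)
  list(folds = bind_rows(fold_metrics), pooled = pooled)
}

#' Label-permutation test of a trainer
#'
#' Compares real-label performance with the performance on permuted-label
#' copies of the data. Each permutation shuffles the label vector
#' uniformly, exactly preserving the class ratio; the full training
#' pipeline is re-run per permutation with the same hold-out protocol.
#' The empirical p-value per metric uses the add-one rule
#' `(1 + #{permuted >= real}) / (n_permutations + 1)`, so it is never 0.
#'
#' @inheritParams evaluate_holdout
#' @param n_permutations Number of permuted label sets (default 10).
#' @return Object of class `permutation_report`: `real` (metric row),
#'   `permuted` (tibble of metric rows), `p_values` (named vector).
#' @export
permutation_test <- function(trainer, data, labels, n_permutations = 10L,
                             train_fraction = 0.7, seed = 1L) {
  labels <- check_labels(labels, n = nrow(data))
  if (n_permutations < 1L) abort("n_permutations must be >= 1")
  real <- evaluate_holdout(trainer, data, labels,
                           train_fraction = train_fraction, seed = seed)
  permuted <- map(seq_len(n_permutations), function(i) {
    y_perm <- with_local_seed(seed + 1000L + i, sample(labels))
    m <- evaluate_holdout(trainer, data, y_perm,
                          train_fraction = train_fraction, seed = seed)
    mutate(as_tibble(m), permutation = i, .before = 1L)
  })
  permuted <- bind_rows(permuted)
  metrics <- c("sensitivity", "specificity", "precision", "accuracy",
               "mcc", "auc")
  p_values <- vapply(metrics, function(mn) {
    r <- real[[mn]]
    if (is.na(r)) return(NA_real_)
    (1 + sum(permuted[[mn]] >= r, na.rm = TRUE)) / (n_permutations + 1)
  }, numeric(1))
  structure(list(real = real, permuted = permuted, p_values = p_values,
                 n_permutations = n_permutations, seed = seed),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("<permutation_report> ", x$n_permutations, " permutations\n", sep = "")
  cat("  real MCC ", signif(x$real$mcc, 4), ", permuted MCC range [",
      signif(min(x$permuted$mcc), 3), ", ", signif(max(x$permuted$mcc), 3),
      "]\n", sep = "")
  cat("  empirical p (MCC): ", signif(x$p_values[["mcc"]], 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.permutation_report <- function(x, ...) {
  tibble(metric = names(x$p_values),
         real = vapply(names(x$p_values), function(m) x$real[[m]], numeric(1)),
         p_value = unname(x$p_values))
}

#' Cochran's Q test over a correctness matrix
#'
#' Tests whether several classifiers have equal marginal accuracy on the
#' same test samples. `matrix` is binary with rows = samples, columns =
#' classifiers, entry 1 when the classifier got the sample right.
#' `Q = k(k-1) * sum_j (C_j - Cbar)^2 / (k * sum_i R_i - sum_i R_i^2)`
#' is referred to chi-square with `k - 1` degrees of freedom. If every row
#' is constant (all correct or all wrong) the statistic is undefined and
#' p = 1 is returned with a flag.
#'
#' @param matrix Binary correctness matrix (>= 2 columns).
#' @return Tibble with `q`, `df`, `p_value`, `undefined`.
#' @export
cochran_q <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2L) abort("need >= 2 classifiers")
  if (nrow(m) < 2L) abort("need >= 2 samples")
  if (!all(m %in% c(0, 1))) abort("correctness matrix must be binary")
  k <- ncol(m)
  Cj <- colSums(m)
  Ri <- rowSums(m)
  denom <- k * sum(Ri) - sum(Ri^2)
  if (denom == 0) {
    # every row constant (e.g. identical classifiers, or all-correct):
    # no heterogeneity to test; Q conventionally 0 with an undefined flag
    return(tibble(q = 0, df = k - 1L, p_value = 1, undefined = TRUE))
  }
  q <- k * (k - 1) * sum((Cj - mean(Cj))^2) / denom
  tibble(q = q, df = k - 1L, p_value = pchisq(q, df = k - 1L, lower.tail = FALSE),
         undefined = FALSE)
}

#' McNemar's test between two classifiers
#'
#' Paired comparison on shared test samples via the discordant counts
#' `b` (A correct, B wrong) and `c` (A wrong, B correct). For
#' `b + c < 25` the exact two-sided binomial p-value
#' `min(1, 2 * P(X <= min(b, c)))` with `X ~ Bin(b + c, 1/2)` is used;
#' otherwise the continuity-corrected chi-square statistic
#' `(|b - c| - 1)^2 / (b + c)`.
#'
#' @param correct_a,correct_b Binary correctness vectors of equal length.
#' @return Tibble with `b`, `c`, `statistic`, `p_value`, `exact`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) abort("length mismatch")
  if (!all(c(correct_a, correct_b) %in% c(0, 1))) {
    abort("correctness vectors must be binary")
  }
  b <- sum(correct_a == 1 & correct_b == 0)
  cc <- sum(correct_a == 0 & correct_b == 1)
  if (b + cc == 0) {
    return(tibble(b = b, c = cc, statistic = 0, p_value = 1, exact = TRUE))
  }
  if (b + cc < 25) {
    p <- min(1, 2 * pbinom(min(b, cc), size = b + cc, prob = 0.5))
    tibble(b = b, c = cc, statistic = NA_real_, p_value = p, exact = TRUE)
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    tibble(b = b, c = cc, statistic = stat,
           p_value = pchisq(stat, df = 1L, lower.tail = FALSE), exact = FALSE)
  }
}

#' Bonferroni correction
#'
#' `adjusted = min(1, p * m)`, with `m` defaulting to the number of
#' p-values.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Number of comparisons.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  pmin(1, p_values * m)
}
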