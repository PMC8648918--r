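# The full comparison workflow: train all five classifiers on a shared
# stratified split, compare them with Cochran's Q and pairwise McNemar
# tests (Bonferroni-adjusted), and rank candidate proteins by score.

#' Run the five-classifier benchmark
#'
#' Trains mGMDH-AFS and the four reference classifiers on the same
#' stratified 70/30 split, computes every performance index on the shared
#' test partition, then Cochran's Q across all methods and pairwise
#' McNemar tests of mGMDH-AFS against each baseline with Bonferroni
#' adjustment (m = number of pairwise tests). The whole run is a pure
#' function of (data, seed).
#'
#' @param data,labels The dataset; defaults to [generate_dt_benchmark()]
#'   drawn with `seed` when `data` is `NULL`.
#' @param seed Global seed driving the split, every trainer and (if
#'   requested) the permutation test.
#' @param trainers Named list of [trainer()]s; default: mGMDH-AFS,
#'   plain logistic regression, Poisson-link GLM, RBF-SVM, RBFN.
#' @param reference Name of the method compared against the others in the
#'   post-hoc tests.
#' @param train_fraction Training fraction of the shared split.
#' @param include_permutation Also run [permutation_test()] on the
#'   reference method (10 permutations).
#' @param feature_blocks Optional named list of feature-name subsets; the
#'   reference method is retrained on each block (e.g. biochemical-only
#'   vs biochemical+topology ablation).
#' @return Object of class `benchmark_report`.
#' @export
run_full_benchmark <- function(data = NULL, labels = NULL, seed = 1L,
                               trainers = default_trainers(),
                               reference = "mgmdh_afs",
                               train_fraction = 0.7,
                               include_permutation = FALSE,
                               feature_blocks = NULL) {
  if (is.null(data)) {
    bench <- generate_dt_benchmark(seed = seed)
    data <- bench$data; labels <- bench$labels
  }
  labels <- check_labels(labels, n = nrow(data))
  if (!reference %in% names(trainers)) {
    abort(paste0("reference method '", reference, "' not among trainers"))
  }
  results <- imap(trainers, function(tr, nm) {
    ms <- evaluate_holdout(tr, data, labels, train_fraction = train_fraction,
                           seed = seed)
    list(metrics = ms, predictions = attr(ms, "predictions"))
  })
  metrics <- bind_rows(imap(results, function(r, nm) {
    mutate(as_tibble(r$metrics), method = nm, .before = 1L)
  }))
  correctness <- vapply(results, function(r) {
    as.numeric(r$predictions$truth == r$predictions$estimate)
  }, numeric(nrow(results[[1L]]$predictions)))
  q <- cochran_q(correctness)
  others <- setdiff(names(trainers), reference)
  pairwise <- bind_rows(map(others, function(nm) {
    mutate(mcnemar_test(correctness[, reference], correctness[, nm]),
           comparison = paste0(reference, " vs ", nm), .before = 1L)
  }))
  pairwise$p_adjusted <- bonferroni(pairwise$p_value, m = length(others))
  permutation <- NULL
  if (include_permutation) {
    permutation <- permutation_test(trainers[[reference]], data, labels,
                                    n_permutations = 10L,
                                    train_fraction = train_fraction,
                                    seed = seed)
  }
  ablation <- NULL
  if (!is.null(feature_blocks)) {
    ablation <- bind_rows(imap(feature_blocks, function(cols, nm) {
      d <- as_tibble(data)[cols]
      d <- feature_table(d, kinds = feature_kinds(data)[cols],
                         sample_ids = sample_ids(data))
      ms <- evaluate_holdout(trainers[[reference]], d, labels,
                             train_fraction = train_fraction, seed = seed)
      mutate(as_tibble(ms), block = nm, .before = 1L)
    }))
  }
  structure(list(metrics = metrics, cochran = q, mcnemar = pairwise,
                 permutation = permutation, ablation = ablation,
                 reference = reference, seed = seed,
                 train_fraction = train_fraction,
                 n = length(labels), prevalence = mean(labels)),
            class = "benchmark_report")
}

#' @rdname run_full_benchmark
#' @param gmdh_config_ A [gmdh_config()] for the reference method.
#' @export
default_trainers <- function(gmdh_config_ = gmdh_config()) {
  list(mgmdh_afs = gmdh_trainer(gmdh_config_),
       logistic = logistic_trainer(oversample = FALSE),
       glm_poisson = glm_poisson_trainer(),
       rbf_svm = rbf_svm_trainer(),
       rbfn = rbfn_trainer())
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> n = ", x$n, ", prevalence = ",
      signif(x$prevalence, 3), ", seed = ", x$seed, "\n\n", sep = "")
  cols <- c("method", "sensitivity", "specificity", "precision", "accuracy",
            "mcc", "auc")
  print(as.data.frame(x$metrics[cols]), digits = 3, row.names = FALSE)
  cat("\nCochran's Q = ", signif(x$cochran$q, 4), " (df ", x$cochran$df,
      "), p = ", signif(x$cochran$p_value, 3), "\n", sep = "")
  print(as.data.frame(x$mcnemar[c("comparison", "b", "c", "p_value",
                                  "p_adjusted")]),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.benchmark_report <- function(x, ...) x$metrics

#' @export
glance.benchmark_report <- function(x, ...) {
  tibble(n = x$n, prevalence = x$prevalence, seed = x$seed,
         cochran_q = x$cochran$q, cochran_p = x$cochran$p_value,
         min_adjusted_mcnemar_p = min(x$mcnemar$p_adjusted))
}

#' @export
autoplot.benchmark_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$metrics[c("method", "sensitivity", "specificity", "precision",
                     "accuracy", "mcc")],
    -"method", names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize a benchmark report to JSON
#'
#' Deterministic, timestamp-free JSON; two runs with the same data and
#' seed produce byte-identical output.
#'
#' @param report A `benchmark_report`.
#' @export
report_to_json <- function(report) {
  obj <- list(
    seed = report$seed, n = report$n, prevalence = report$prevalence,
    train_fraction = report$train_fraction, reference = report$reference,
    metrics = report$metrics, cochran = report$cochran,
    mcnemar = report$mcnemar)
  if (!is.null(report$permutation)) {
    obj$permutation <- list(
      real = as_tibble(report$permutation$real),
      permuted = report$permutation$permuted,
      p_values = as.list(report$permutation$p_values))
  }
  if (!is.null(report$ablation)) obj$ablation <- report$ablation
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), na = "null",
                   dataframe = "rows")
}

#' Rank candidates by model score
#'
#' Scores every row of `data` with a trained model and returns the
#' descending-score ranking (ties keep sample-id order). When a set of
#' known positives is supplied, the ranking is additionally evaluated as a
#' retrieval task via ROC/AUC against that label set.
#'
#' @param model A trained `gmdh_model` (or any object with scores through
#'   `score_fun`).
#' @param data Feature table of candidates.
#' @param known_positive_ids Optional character vector of ids regarded as
#'   true positives.
#' @param score_fun Function `(model, data) -> scores`; defaults to
#'   [predict_scores()].
#' @return Tibble (id, score, rank), with attributes `auc` and `roc` when
#'   known positives were given.
#' @export
rank_candidates <- function(model, data, known_positive_ids = NULL,
                            score_fun = predict_scores) {
  if (nrow(data) == 0L) abort("empty candidate table")
  ids <- sample_ids(data)
  scores <- score_fun(model, data)
  ord <- order(-scores, seq_along(ids))
  out <- tibble(id = ids[ord], score = scores[ord],
                rank = seq_along(ids))
  if (!is.null(known_positive_ids) && length(known_positive_ids) > 0L) {
    truth <- as.numeric(ids %in% known_positive_ids)
    if (length(unique(truth)) == 2L) {
      ra <- roc_auc(scores, truth)
      attr(out, "auc") <- ra$auc
      attr(out, "roc") <- ra$curve
    }
  }
  out
}
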