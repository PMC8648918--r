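# I-RELIEF feature weighting: iterated Relief with kernel-smoothed
# (soft) nearest-hit / nearest-miss assignment under the weighted L1
# distance. Features are scored by how well they discriminate each sample
# from its neighbouring patterns of the opposite class versus its own.

#' I-RELIEF feature weights
#'
#' Iteratively estimates a nonnegative weight per feature. Each iteration
#' computes, for every sample, kernel-weighted expected margins against
#' same-class (hit) and opposite-class (miss) neighbours under the current
#' weighted L1 distance; the weight vector is updated to the normalised
#' positive part of the mean margin vector, so it always lies on the
#' probability simplex. Iteration stops when the L2 change drops below
#' `tolerance` or after `max_iterations`.
#'
#' Continuous features are z-scored internally (binary features enter as
#' 0/1) so distances are comparable across feature kinds; the returned
#' weights refer to the original columns.
#'
#' @param data Fully numeric feature table (categoricals already encoded).
#' @param labels 0/1 labels; at least two samples per class.
#' @param kernel_width Width sigma of the exp(-d/sigma) neighbour kernel,
#'   on the z-scored distance scale.
#' @param max_iterations,tolerance Fixed-point iteration controls.
#' @return Object of class `relief_weights`: nonnegative weights summing
#'   to 1, plus iteration diagnostics.
#' @export
#' @examples
#' d <- data.frame(signal = c(rnorm(20), rnorm(20, 3)), noise = rnorm(40))
#' w <- irelief_weights(d, labels = rep(c(0, 1), each = 20))
#' tidy(w)
irelief_weights <- function(data, labels, kernel_width = 1,
                            max_iterations = 50L, tolerance = 1e-4) {
  labels <- check_labels(labels, n = nrow(data))
  if (min(table(labels)) < 2L) abort("each class needs >= 2 samples")
  if (kernel_width <= 0) abort("kernel_width must be positive")
  kind <- feature_kinds(data)
  X <- as.matrix(as_tibble(data))
  if (!is.numeric(X)) abort("table must be fully numeric (encode categoricals first)")
  # z-score continuous columns; leave 0/1 features on their natural scale
  for (j in seq_len(ncol(X))) {
    if (kind[[j]] == "continuous") {
      s <- sd(X[, j])
      if (s > 0) X[, j] <- (X[, j] - mean(X[, j])) / s
    }
  }
  constant <- apply(X, 2L, function(col) max(col) == min(col))
  p <- ncol(X)
  if (all(constant)) {
    warn("all features constant; returning uniform weights")
    w <- rep(1 / p, p)
    res <- list(iterations = 0L, converged = TRUE, degenerate = TRUE)
  } else {
    res <- irelief_cpp(X, as.integer(labels), kernel_width,
                       as.integer(max_iterations), tolerance)
    if (isTRUE(res$degenerate)) {
      warn("zero total margin; returning uniform weights")
    }
    w <- res$weights
  }
  structure(list(weights = setNames(as.numeric(w), colnames(data)),
                 iterations = res$iterations, converged = res$converged,
                 degenerate = isTRUE(res$degenerate),
                 kernel_width = kernel_width),
            class = "relief_weights")
}

#' @export
print.relief_weights <- function(x, ...) {
  cat("<relief_weights> ", length(x$weights), " features, ",
      x$iterations, " iterations (",
      if (isTRUE(x$converged)) "converged" else "not converged", ")\n", sep = "")
  print(head(sort(x$weights, decreasing = TRUE), 10L))
  invisible(x)
}

#' @export
tidy.relief_weights <- function(x, ...) {
  tibble(feature = names(x$weights), weight = unname(x$weights)) |>
    arrange(desc(.data$weight))
}

#' @export
autoplot.relief_weights <- function(object, top = 30L, ...) {
  d <- head(tidy(object), top)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature, .data$weight),
                                  y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "I-RELIEF weight") +
    ggplot2::theme_minimal()
}

#' Select features from Relief weights
#'
#' Either the `top_m` heaviest features (ties resolve to the lower column
#' index) or every feature whose weight reaches `min_weight`. The result
#' is never empty: an over-strict threshold falls back to the single best
#' feature.
#'
#' @param weights A [irelief_weights()] object (or bare named numeric).
#' @param top_m Keep this many features.
#' @param min_weight Keep features with weight >= this value.
#' @return Sorted integer vector of selected feature indices (with feature
#'   names).
#' @export
select_features <- function(weights, top_m = NULL, min_weight = NULL) {
  w <- if (inherits(weights, "relief_weights")) weights$weights else weights
  p <- length(w)
  if (is.null(top_m) == is.null(min_weight)) {
    abort("give exactly one of `top_m` or `min_weight`")
  }
  if (!is.null(top_m)) {
    if (top_m < 1L) abort("top_m must be >= 1")
    if (top_m > p) {
      warn("top_m exceeds the number of features; returning all")
      top_m <- p
    }
    ord <- order(-w, seq_len(p))  # ties -> lower index
    idx <- sort(ord[seq_len(top_m)])
  } else {
    idx <- which(w >= min_weight)
    if (length(idx) == 0L) {
      idx <- order(-w, seq_len(p))[1L]  # never-empty guarantee
    }
    idx <- sort(idx)
  }
  setNames(idx, names(w)[idx])
}
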