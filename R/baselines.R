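# The four reference classifiers the GMDH network is compared against,
# plus sequential forward selection. All share the trainer interface in
# trainers.R so the validation harness runs unmodified on each.

scale_train <- function(X) {
  center <- colMeans(X)
  s <- apply(X, 2L, sd)
  s[s == 0] <- 1
  list(center = center, scale = s,
       X = sweep(sweep(X, 2L, center), 2L, s, `/`))
}

scale_apply <- function(X, sc) sweep(sweep(X, 2L, sc$center), 2L, sc$scale, `/`)

numeric_matrix <- function(data) {
  X <- as.matrix(as_tibble(data))
  if (ncol(X) > 0L && !is.numeric(X)) abort("features must be numeric")
  if (ncol(X) == 0L) storage.mode(X) <- "double"
  X
}

#' Logistic regression classifier
#'
#' The classical linear model `log(p / (1 - p)) = b0 + sum_j b_j x_j`,
#' fitted by iteratively reweighted least squares with a tiny ridge term
#' (`lambda = 1e-6`) on z-scored features, so coefficients stay finite
#' even under complete separation. Cases with fitted `p >= 0.5` are
#' classified positive. If `weight_threshold` is given, features whose
#' standardized coefficient is smaller in magnitude are dropped and the
#' model refitted once.
#'
#' @param data Feature table or data frame.
#' @param labels 0/1 labels.
#' @param fitting_indices Rows to fit on (default all).
#' @param weight_threshold Optional exclusion threshold on |standardized
#'   coefficient|.
#' @return Object of class `logistic_fit`.
#' @export
fit_logistic <- function(data, labels, fitting_indices = NULL,
                         weight_threshold = NULL) {
  labels <- check_labels(labels, n = nrow(data))
  if (is.null(fitting_indices)) fitting_indices <- seq_len(nrow(data))
  X <- numeric_matrix(data)[fitting_indices, , drop = FALSE]
  y <- labels[fitting_indices]
  if (length(unique(y)) < 2L) abort("both classes must be present in the fitting set")
  sc <- scale_train(X)
  fit <- irls_logistic(sc$X, y)
  if (!fit$converged && ncol(X) > 0L) {
    abort(paste0("IRLS did not converge after ", fit$iterations, " iterations"))
  }
  kept <- colnames(X)
  if (!is.null(weight_threshold) && ncol(X) > 0L) {
    coefs <- fit$coefficients[-1L]
    kept <- colnames(X)[abs(coefs) >= weight_threshold]
    if (length(kept) == 0L) kept <- colnames(X)[which.max(abs(coefs))]
    fit <- irls_logistic(sc$X[, kept, drop = FALSE], y)
  }
  structure(list(coefficients = fit$coefficients, features = kept,
                 scaling = sc[c("center", "scale")],
                 iterations = fit$iterations, converged = fit$converged),
            class = "logistic_fit")
}

#' @export
#' @rdname fit_logistic
#' @param object A `logistic_fit`.
#' @param type `"prob"`, `"class"` or `"link"`.
#' @param ... Unused.
predict.logistic_fit <- function(object, data, type = c("prob", "class", "link"),
                                 ...) {
  type <- arg_match(type)
  X <- numeric_matrix(data)
  Xs <- scale_apply(X, object$scaling)[, object$features, drop = FALSE]
  eta <- drop(cbind(1, Xs) %*% object$coefficients)
  switch(type,
         link = eta,
         prob = plogis(eta),
         class = as.numeric(plogis(eta) >= 0.5))
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(n_features = length(x$features), iterations = x$iterations,
         converged = x$converged)
}

#' Poisson-link GLM classifier
#'
#' A generalized linear model with the Poisson (log) link applied to the
#' 0/1 labels treated as counts; predictions are rates, thresholded at
#' 0.5 for classification. Fitted with [stats::glm()].
#'
#' @inheritParams fit_logistic
#' @return Object of class `glm_poisson_fit`.
#' @export
fit_glm_poisson <- function(data, labels, fitting_indices = NULL) {
  labels <- check_labels(labels, n = nrow(data), both_classes = FALSE)
  if (is.null(fitting_indices)) fitting_indices <- seq_len(nrow(data))
  X <- numeric_matrix(data)[fitting_indices, , drop = FALSE]
  y <- labels[fitting_indices]
  sc <- scale_train(X)
  df <- as.data.frame(sc$X)
  df$.y <- y
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = poisson()))
  if (!fit$converged) abort("Poisson GLM did not converge")
  structure(list(glm = fit, scaling = sc[c("center", "scale")],
                 features = colnames(X)),
            class = "glm_poisson_fit")
}

#' @export
#' @rdname fit_glm_poisson
#' @param object A `glm_poisson_fit`.
#' @param type `"rate"` or `"class"`.
#' @param ... Unused.
predict.glm_poisson_fit <- function(object, data, type = c("rate", "class"),
                                    ...) {
  type <- arg_match(type)
  X <- numeric_matrix(data)
  df <- as.data.frame(scale_apply(X, object$scaling)[, object$features,
                                                     drop = FALSE])
  rate <- predict(object$glm, newdata = df, type = "response")
  if (type == "rate") unname(rate) else as.numeric(rate >= 0.5)
}

#' RBF-kernel support vector machine
#'
#' Soft-margin SVM with a Gaussian kernel, trained by the SMO solver in
#' libsvm ([e1071::svm()]). The kernel width `gamma` and the cost `C` are
#' tuned by internal stratified 3-fold cross-validation maximising MCC
#' over a grid.
#'
#' @inheritParams fit_logistic
#' @param tuning_grid Data frame with columns `C` and `gamma`.
#' @param seed Seed for the internal CV folds.
#' @return Object of class `rbf_svm_fit`.
#' @export
fit_rbf_svm <- function(data, labels, fitting_indices = NULL,
                        tuning_grid = expand.grid(C = c(0.1, 1, 10, 100),
                                                  gamma = c(0.01, 0.1, 1, 10)),
                        seed = 1L) {
  labels <- check_labels(labels, n = nrow(data))
  if (is.null(fitting_indices)) fitting_indices <- seq_len(nrow(data))
  if (nrow(tuning_grid) == 0L) abort("tuning_grid is empty")
  X <- numeric_matrix(data)[fitting_indices, , drop = FALSE]
  y <- labels[fitting_indices]
  sc <- scale_train(X)
  yf <- factor(y, levels = c(0, 1))
  best <- NULL
  if (nrow(tuning_grid) > 1L) {
    folds <- kfold_indices(y, k = 3L, seed = seed)$partitions
    cv_mcc <- map_dbl(seq_len(nrow(tuning_grid)), function(g) {
      preds <- rep(NA_real_, length(y))
      for (f in folds) {
        fit <- e1071::svm(sc$X[-f, , drop = FALSE], yf[-f],
                          kernel = "radial", cost = tuning_grid$C[g],
                          gamma = tuning_grid$gamma[g], scale = FALSE)
        preds[f] <- as.numeric(as.character(predict(fit, sc$X[f, , drop = FALSE])))
      }
      mcc(confusion(y, preds))
    })
    best <- tuning_grid[which.max(cv_mcc), ]
  } else {
    best <- tuning_grid[1L, ]
  }
  fit <- e1071::svm(sc$X, yf, kernel = "radial", cost = best$C,
                    gamma = best$gamma, scale = FALSE, probability = FALSE)
  structure(list(svm = fit, C = best$C, gamma = best$gamma,
                 scaling = sc[c("center", "scale")], features = colnames(X)),
            class = "rbf_svm_fit")
}

#' @export
#' @rdname fit_rbf_svm
#' @param object An `rbf_svm_fit`.
#' @param type `"class"` or `"decision"` (signed distance to the margin,
#'   oriented so larger means more positive).
#' @param ... Unused.
predict.rbf_svm_fit <- function(object, data, type = c("class", "decision"),
                                ...) {
  type <- arg_match(type)
  X <- scale_apply(numeric_matrix(data), object$scaling)
  X <- X[, object$features, drop = FALSE]
  pr <- predict(object$svm, X, decision.values = TRUE)
  if (type == "class") return(as.numeric(as.character(pr)))
  dv <- drop(attr(pr, "decision.values"))
  # libsvm orients the decision value toward the first training class
  if (grepl("^0", colnames(attr(pr, "decision.values"))[1L])) dv <- -dv
  unname(dv)
}

#' Radial basis function network
#'
#' A hidden layer of `K` Gaussian prototypes (centers from seeded k-means,
#' common width = median inter-center distance) and a linear output layer
#' with one node per class fitted by least squares on the hidden
#' activations; each sample is assigned the class with the highest output
#' score.
#'
#' @inheritParams fit_logistic
#' @param K Number of prototypes (<= number of fitting samples).
#' @param seed Seed for k-means initialisation.
#' @return Object of class `rbfn_fit`.
#' @export
fit_rbfn <- function(data, labels, fitting_indices = NULL, K = 10L, seed = 1L) {
  labels <- check_labels(labels, n = nrow(data), both_classes = FALSE)
  if (is.null(fitting_indices)) fitting_indices <- seq_len(nrow(data))
  X <- numeric_matrix(data)[fitting_indices, , drop = FALSE]
  y <- labels[fitting_indices]
  if (K > nrow(X)) abort("K exceeds the number of fitting samples")
  sc <- scale_train(X)
  centers <- with_local_seed(seed, {
    if (K == 1L) {
      matrix(colMeans(sc$X), nrow = 1L)
    } else {
      km <- suppressWarnings(kmeans(sc$X, centers = K, nstart = 3L,
                                    iter.max = 50L))
      km$centers
    }
  })
  width <- if (K > 1L) median(dist(centers)) else 1
  if (!is.finite(width) || width <= 0) width <- 1
  H <- rbf_activations(sc$X, centers, width)
  Y <- cbind(`0` = as.numeric(y == 0), `1` = as.numeric(y == 1))
  W <- qr.coef(qr(cbind(1, H)), Y)
  W[is.na(W)] <- 0
  structure(list(centers = centers, width = width, weights = W,
                 scaling = sc[c("center", "scale")], features = colnames(X),
                 K = K), class = "rbfn_fit")
}

rbf_activations <- function(X, centers, width) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) - 2 * X %*% t(centers)
  exp(-pmax(d2, 0) / (2 * width^2))
}

#' @export
#' @rdname fit_rbfn
#' @param object An `rbfn_fit`.
#' @param type `"class"` or `"score"` (positive-class output minus
#'   negative-class output).
#' @param ... Unused.
predict.rbfn_fit <- function(object, data, type = c("class", "score"), ...) {
  type <- arg_match(type)
  X <- scale_apply(numeric_matrix(data), object$scaling)
  X <- X[, object$features, drop = FALSE]
  H <- rbf_activations(X, object$centers, object$width)
  S <- cbind(1, H) %*% object$weights
  if (type == "score") return(drop(S[, "1"] - S[, "0"]))
  as.numeric(S[, "1"] >= S[, "0"])
}

#' Sequential forward selection
#'
#' Greedy wrapper selection: starting from the empty set, at each step the
#' feature whose addition maximises an internal stratified 3-fold
#' cross-validated criterion (default MCC) is added; selection stops when
#' no candidate improves the criterion or `max_features` is reached. Ties
#' resolve to the lower feature index.
#'
#' @param trainer A [trainer()] (e.g. [rbf_svm_trainer()]).
#' @param data,labels Training data.
#' @param criterion Metric column to maximise (a [metric_set()] name).
#' @param max_features Cap on the number of selected features.
#' @param seed Seed for the internal folds.
#' @return Character vector of selected feature names, in selection order,
#'   with the criterion trace as attribute `criterion_trace`.
#' @export
sequential_forward_selection <- function(trainer, data, labels,
                                         criterion = "mcc",
                                         max_features = NULL, seed = 1L) {
  labels <- check_labels(labels, n = nrow(data))
  feats <- names(as_tibble(data))
  if (is.null(max_features)) max_features <- length(feats)
  if (max_features > length(feats)) abort("max_features exceeds n_features")
  folds <- kfold_indices(labels, k = 3L, seed = seed)$partitions
  cv_score <- function(cols) {
    preds <- rep(NA_real_, length(labels))
    d <- as_tibble(data)[cols]
    for (f in folds) {
      m <- trainer$fit(d[-f, , drop = FALSE], labels[-f], seed = seed)
      preds[f] <- trainer$predict_class(m, d[f, , drop = FALSE])
    }
    metric_set(labels, preds)[[criterion]]
  }
  selected <- character(0)
  best <- -Inf
  trace <- numeric(0)
  while (length(selected) < max_features) {
    candidates <- setdiff(feats, selected)
    scores <- map_dbl(candidates, function(fc) cv_score(c(selected, fc)))
    top <- which.max(scores)  # which.max takes the first (lower index) on ties
    if (scores[top] <= best) break
    best <- scores[top]
    selected <- c(selected, candidates[top])
    trace <- c(trace, best)
  }
  structure(selected, criterion_trace = trace)
}
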