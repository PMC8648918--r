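# The shared trainer interface: any classifier exposing fit / predict
# through this contract can be run by evaluate_holdout, evaluate_kfold,
# permutation_test and run_full_benchmark without modification.

#' Define a trainer
#'
#' @param name Short method name used in reports.
#' @param fit `function(data, labels, seed)` returning a fitted model.
#' @param predict_class `function(model, data)` returning 0/1 labels.
#' @param predict_score Optional `function(model, data)` returning
#'   continuous scores (enables AUC); `NULL` when the method has none.
#' @return Object of class `dt_trainer`.
#' @export
trainer <- function(name, fit, predict_class, predict_score = NULL) {
  structure(list(name = name, fit = fit, predict_class = predict_class,
                 predict_score = predict_score),
            class = "dt_trainer")
}

#' @export
print.dt_trainer <- function(x, ...) {
  cat("<dt_trainer> ", x$name,
      if (is.null(x$predict_score)) " (no scores)" else "", "\n", sep = "")
  invisible(x)
}

encode_if_needed <- function(data, labels) {
  kind <- feature_kinds(data)
  if (!any(kind == "categorical")) return(list(data = data, encoder = NULL))
  enc <- fit_categorical_encoder(data, labels)
  list(data = apply_encoder(enc, data), encoder = enc)
}

#' Built-in trainers
#'
#' Wrappers giving every classifier in the package the [trainer()]
#' interface. Categorical features are handled inside each trainer's `fit`
#' (fitted on the training rows only): the GMDH trainer uses the logistic
#' categorical encoder; the baselines do too, so all methods see interval
#' features.
#'
#' @param config A [gmdh_config()] for the GMDH trainer.
#' @param oversample For the logistic trainer: balance classes before
#'   fitting (`FALSE` reproduces the plain, imbalance-naive baseline).
#' @param weight_threshold,tuning_grid,K Passed to the underlying fits.
#' @name builtin_trainers
NULL

#' @rdname builtin_trainers
#' @export
gmdh_trainer <- function(config = gmdh_config()) {
  trainer(
    name = "mgmdh_afs",
    fit = function(data, labels, seed) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      cfg$pso$seed <- as.integer(seed)
      prep <- encode_if_needed(data, labels)
      model <- train_gmdh(prep$data, labels, cfg)
      list(model = model, encoder = prep$encoder)
    },
    predict_class = function(m, data) {
      if (!is.null(m$encoder)) data <- apply_encoder(m$encoder, data)
      predict(m$model, data, type = "class")
    },
    predict_score = function(m, data) {
      if (!is.null(m$encoder)) data <- apply_encoder(m$encoder, data)
      predict_scores(m$model, data)
    })
}

#' @rdname builtin_trainers
#' @export
logistic_trainer <- function(oversample = FALSE, weight_threshold = NULL) {
  trainer(
    name = if (oversample) "logistic_oversampled" else "logistic",
    fit = function(data, labels, seed) {
      prep <- encode_if_needed(data, labels)
      d <- prep$data; y <- labels
      if (oversample) {
        os <- oversample_minority(d, y, seed = seed)
        d <- os$data; y <- os$labels
      }
      list(model = fit_logistic(d, y, weight_threshold = weight_threshold),
           encoder = prep$encoder)
    },
    predict_class = function(m, data) {
      if (!is.null(m$encoder)) data <- apply_encoder(m$encoder, data)
      predict(m$model, data, type = "class")
    },
    predict_score = function(m, data) {
      if (!is.null(m$encoder)) data <- apply_encoder(m$encoder, data)
      predict(m$model, data, type = "prob")
    })
}

#' @rdname builtin_trainers
#' @export
glm_poisson_trainer <- function() {
  trainer(
    name = "glm_poisson",
    fit = function(data, labels, seed) {
      prep <- encode_if_needed(data, labels)
      list(model = fit_glm_poisson(prep$data, labels), encoder = prep$encoder)
    },
    predict_class = function(m, data) {
      if (!is.null(m$encoder)) data <- apply_encoder(m$encoder, data)
      predict(m$model, data, type = "class")
    },
    predict_score = function(m, data) {
      if (!is.null(m$encoder)) data <- apply_encoder(m$encoder, data)
      predict(m$model, data, type = "rate")
    })
}

#' @rdname builtin_trainers
#' @export
rbf_svm_trainer <- function(tuning_grid = expand.grid(C = c(0.1, 1, 10, 100),
                                                      gamma = c(0.01, 0.1, 1, 10))) {
  trainer(
    name = "rbf_svm",
    fit = function(data, labels, seed) {
      prep <- encode_if_needed(data, labels)
      list(model = fit_rbf_svm(prep$data, labels, tuning_grid = tuning_grid,
                               seed = seed),
           encoder = prep$encoder)
    },
    predict_class = function(m, data) {
      if (!is.null(m$encoder)) data <- apply_encoder(m$encoder, data)
      predict(m$model, data, type = "class")
    },
    predict_score = function(m, data) {
      if (!is.null(m$encoder)) data <- apply_encoder(m$encoder, data)
      predict(m$model, data, type = "decision")
    })
}

#' @rdname builtin_trainers
#' @export
rbfn_trainer <- function(K = 10L) {
  trainer(
    name = "rbfn",
    fit = function(data, labels, seed) {
      prep <- encode_if_needed(data, labels)
      list(model = fit_rbfn(prep$data, labels, K = K, seed = seed),
           encoder = prep$encoder)
    },
    predict_class = function(m, data) {
      if (!is.null(m$encoder)) data <- apply_encoder(m$encoder, data)
      predict(m$model, data, type = "class")
    },
    predict_score = function(m, data) {
      if (!is.null(m$encoder)) data <- apply_encoder(m$encoder, data)
      predict(m$model, data, type = "score")
    })
}
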