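# The mGMDH-AFS classifier core: a self-organising GMDH network of
# pairwise-input nonlinear neurons. Each neuron maps its two inputs (u, v)
# through a configurable basis of nonlinear non-convex terms (quadratic,
# sinusoid, exponential, logarithmic) and a logistic link, so its output is
# a score in (0, 1). Neuron coefficients are fitted by PSO maximising the
# Matthews correlation coefficient on an estimation set; layers are grown
# with the top-k neurons (ranked by validation MCC) until validation
# performance stops improving; the decision cutoff comes from the training
# ROC curve.

GMDH_BASIS_TAGS <- c("const", "u", "v", "uv", "u2", "v2",
                     "sin_u", "sin_v", "exp_u", "exp_v", "log_u", "log_v")

#' Neuron basis definition
#'
#' An ordered set of basis-function tags over a neuron's two inputs
#' `(u, v)`. Available terms: `const`, `u`, `v`, `uv` (product), `u2`,
#' `v2`, `sin_u`, `sin_v`, `exp_u`, `exp_v` (arguments clamped to
#' \[-20, 20\]), `log_u`, `log_v` (as `log(1 + |.|)`). `const` is always
#' included.
#'
#' @param tags Character vector of unique basis tags.
#' @return Character vector of class `gmdh_basis`.
#' @export
gmdh_basis <- function(tags = GMDH_BASIS_TAGS) {
  bad <- setdiff(tags, GMDH_BASIS_TAGS)
  if (length(bad) > 0L) abort(paste0("unknown basis tag(s): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(tags)) abort("basis tags must be unique")
  tags <- union("const", tags)
  structure(tags, class = "gmdh_basis")
}

basis_matrix <- function(u, v, tags) {
  cl <- function(x) pmin(pmax(x, -20), 20)
  cols <- map(tags, function(tg) switch(tg,
    const = rep(1, length(u)),
    u = u, v = v, uv = u * v, u2 = u^2, v2 = v^2,
    sin_u = sin(u), sin_v = sin(v),
    exp_u = exp(cl(u)), exp_v = exp(cl(v)),
    log_u = log1p(abs(u)), log_v = log1p(abs(v))))
  m <- do.call(cbind, cols)
  colnames(m) <- tags
  m
}

#' Evaluate a neuron's response
#'
#' `logistic(sum(coef * basis(u, v)))` with the linear predictor clamped to
#' \[-30, 30\], so the response is always strictly inside (0, 1).
#'
#' @param neuron A `gmdh_neuron` (from [fit_neuron_pso()] or inside a
#'   trained model).
#' @param u,v Numeric input vectors (recycled to common length).
#' @return Scores in (0, 1).
#' @export
#' @examples
#' n <- list(basis = gmdh_basis(c("const", "u")), coefficients = c(0, 1))
#' class(n) <- "gmdh_neuron"
#' neuron_response(n, u = 1, v = 0)  # logistic(1) ~ 0.7311
neuron_response <- function(neuron, u, v) {
  B <- basis_matrix(u, v, neuron$basis)
  eta <- pmin(pmax(drop(B %*% neuron$coefficients), -30), 30)
  plogis(eta)
}

#' Fit one GMDH neuron by particle swarm
#'
#' Runs canonical PSO over the neuron's coefficient vector, maximising the
#' MCC of the hard classification `response >= 0.5` against the estimation
#' labels. Fully deterministic given `pso$seed`. If both inputs are
#' constant the neuron is returned untrained with fitness 0 and a
#' `degenerate` flag.
#'
#' @param u,v Estimation-set values of the neuron's two inputs.
#' @param labels 0/1 estimation labels (both classes present).
#' @param basis A [gmdh_basis()].
#' @param pso A [pso_config()].
#' @param inputs Optional length-2 input reference (feature / neuron
#'   indices) stored on the neuron.
#' @return Object of class `gmdh_neuron` with coefficients and
#'   `estimation_mcc`.
#' @export
fit_neuron_pso <- function(u, v, labels, basis = gmdh_basis(),
                           pso = pso_config(), inputs = c(1L, 2L)) {
  labels <- check_labels(labels, n = length(u))
  if (length(v) != length(u)) abort("u and v must have equal length")
  degenerate <- (max(u) == min(u)) && (max(v) == min(v))
  if (degenerate) {
    neuron <- list(inputs = as.integer(inputs), basis = basis,
                   coefficients = rep(0, length(basis)),
                   estimation_mcc = 0, validation_mcc = NA_real_,
                   degenerate = TRUE)
    class(neuron) <- "gmdh_neuron"
    return(neuron)
  }
  B <- basis_matrix(u, v, basis)
  fit <- pso_fit_neuron_cpp(B, as.integer(labels), pso$swarm, pso$iterations,
                            pso$inertia, pso$c1, pso$c2,
                            pso$range[1], pso$range[2], pso$seed)
  neuron <- list(inputs = as.integer(inputs), basis = basis,
                 coefficients = setNames(as.numeric(fit$coefficients),
                                         as.character(basis)),
                 estimation_mcc = fit$fitness, validation_mcc = NA_real_,
                 degenerate = FALSE)
  class(neuron) <- "gmdh_neuron"
  neuron
}

#' GMDH training configuration
#'
#' @param top_k Neurons retained per layer (default 10).
#' @param max_layers Hard cap on network depth; early stopping normally
#'   triggers first.
#' @param basis A [gmdh_basis()].
#' @param pso A [pso_config()] template; each neuron gets a seed derived
#'   from `seed`, the layer and the pair index.
#' @param estimation_fraction Fraction of the (oversampled) training set
#'   used for coefficient estimation; the rest is the validation set that
#'   drives neuron ranking and early stopping.
#' @param relief List of [irelief_weights()] settings.
#' @param top_m,min_weight Feature-selection rule passed to
#'   [select_features()]; default `min_weight = 1/(2 * n_features)`.
#' @param oversample Balance the training classes by minority duplication
#'   before the estimation/validation split.
#' @param max_inputs_for_all_pairs,max_pairs With more than
#'   `max_inputs_for_all_pairs` selected features, layer 1 only fits the
#'   `max_pairs` pairs with the largest Relief weight sums.
#' @param cutoff_method Criterion for [optimal_cutoff()].
#' @param ranking MCC used to rank neurons within a layer (and pick the
#'   output neuron): `"combined"` (default; estimation and validation
#'   parts pooled, the most stable choice when the validation part holds
#'   few minority samples), `"validation"`, or `"estimation"`. Early
#'   stopping always watches the validation MCC.
#' @param cutoff_data Training rows the ROC cutoff is estimated on:
#'   `"train"` (default; all training rows) or `"validation"` (only the
#'   internal validation rows, whose scores are not inflated by
#'   coefficient fitting).
#' @param cutoff_boot Optional: number of bootstrap resamples whose median
#'   Youden threshold becomes the cutoff (default 0 = plug-in estimate;
#'   the smoothed variant can help when minority samples are very scarce
#'   but blurs clean separation plateaus).
#' @param layer_features Let layers after the first pair previous-layer
#'   neurons with the original selected features as well as with each
#'   other, so signal missed by the first layer's survivors can still
#'   enter the network.
#' @param seed Master seed; every stochastic step derives from it.
#' @return Object of class `gmdh_config`.
#' @export
gmdh_config <- function(top_k = 10L, max_layers = 10L, basis = gmdh_basis(),
                        pso = pso_config(), estimation_fraction = 0.7,
                        relief = list(kernel_width = 1, max_iterations = 50L,
                                      tolerance = 1e-4),
                        top_m = NULL, min_weight = NULL, oversample = TRUE,
                        max_inputs_for_all_pairs = 25L, max_pairs = 300L,
                        cutoff_method = "youden",
                        cutoff_data = c("train", "validation"),
                        cutoff_boot = 0L,
                        ranking = c("combined", "validation", "estimation"),
                        layer_features = FALSE, seed = 1L) {
  cutoff_data <- arg_match(cutoff_data)
  ranking <- arg_match(ranking)
  if (top_k < 1L) abort("top_k must be >= 1")
  if (estimation_fraction <= 0 || estimation_fraction >= 1) {
    abort("estimation_fraction must be in (0, 1)")
  }
  structure(list(top_k = as.integer(top_k), max_layers = as.integer(max_layers),
                 basis = basis, pso = pso,
                 estimation_fraction = estimation_fraction, relief = relief,
                 top_m = top_m, min_weight = min_weight,
                 oversample = isTRUE(oversample),
                 max_inputs_for_all_pairs = as.integer(max_inputs_for_all_pairs),
                 max_pairs = as.integer(max_pairs),
                 cutoff_method = cutoff_method,
                 cutoff_data = cutoff_data,
                 cutoff_boot = as.integer(cutoff_boot), ranking = ranking,
                 layer_features = isTRUE(layer_features),
                 seed = as.integer(seed)),
            class = "gmdh_config")
}

neuron_seed <- function(seed, layer, index) {
  as.integer((as.double(seed) * 7919 + layer * 104729 + index * 131) %% 2147483647)
}

#' Train the mGMDH-AFS network
#'
#' Full training pipeline on an already-encoded (fully numeric) feature
#' table: (1) I-RELIEF feature weighting and selection; (2) minority
#' oversampling of the training rows; (3) stratified split of the
#' oversampled set into estimation and validation parts; (4) layer-wise
#' growth — every unordered input pair is fitted with [fit_neuron_pso()],
#' neurons are ranked by validation MCC and the top `top_k` kept; outputs
#' of kept neurons feed the next layer; (5) early stopping as soon as a new
#' layer fails to beat the best validation MCC so far; (6) the output
#' neuron is the best-validation neuron of the last accepted layer and the
#' decision cutoff is the ROC-optimal threshold of the training-set scores.
#'
#' Continuous features are z-scored with training statistics before
#' entering the network.
#'
#' @param data Fully numeric feature table (apply [apply_encoder()] first
#'   if categorical features are present); see [gmdh_trainer()] for a
#'   wrapper that handles encoding.
#' @param labels 0/1 training labels.
#' @param config A [gmdh_config()].
#' @return Object of class `gmdh_model`.
#' @export
train_gmdh <- function(data, labels, config = gmdh_config()) {
  labels <- check_labels(labels, n = nrow(data))
  kind <- feature_kinds(data)
  if (any(kind == "categorical")) {
    abort("categorical features present; apply a fitted encoder first")
  }
  X <- as.matrix(as_tibble(data))
  constant <- apply(X, 2L, function(col) max(col) == min(col))
  if (all(constant)) abort("all features are constant")
  if (sum(!constant) < 2L) abort("need at least 2 non-constant features")
  usable <- which(!constant)

  # training-set scaling for continuous features
  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  for (j in usable) {
    if (kind[[j]] == "continuous") {
      center[j] <- mean(X[, j]); s <- sd(X[, j])
      scale[j] <- if (s > 0) s else 1
    }
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, `/`)

  # (1) feature weighting + selection
  rw <- irelief_weights(as_tibble(as.data.frame(Xs[, usable, drop = FALSE])),
                        labels,
                        kernel_width = config$relief$kernel_width,
                        max_iterations = config$relief$max_iterations,
                        tolerance = config$relief$tolerance)
  sel_rule <- if (!is.null(config$top_m)) {
    list(top_m = min(config$top_m, length(usable)))
  } else {
    list(min_weight = config$min_weight %||% (1 / (2 * length(usable))))
  }
  sel_local <- do.call(select_features, c(list(weights = rw), sel_rule))
  selected <- usable[sel_local]
  if (length(selected) < 2L) {
    # a pairwise network needs two inputs; take the two heaviest features
    sel_local <- select_features(rw, top_m = 2L)
    selected <- usable[sel_local]
  }
  sel_weights <- rw$weights[sel_local]

  # (2) estimation/validation split, (3) oversample each part separately.
  # Balancing the parts after the split keeps duplicated minority rows on
  # one side only, so validation MCC stays an honest selection signal.
  Xsel <- Xs[, selected, drop = FALSE]
  sp <- stratified_holdout_split(labels, config$estimation_fraction,
                                 seed = neuron_seed(config$seed, 0L, 2L))
  est <- sp$partitions$train; val <- sp$partitions$test
  balance <- function(idx, seed) {
    if (!config$oversample) {
      return(list(X = Xsel[idx, , drop = FALSE], y = labels[idx]))
    }
    os <- oversample_minority(as.data.frame(Xsel[idx, , drop = FALSE]),
                              labels[idx], seed = seed)
    list(X = as.matrix(os$data), y = os$labels)
  }
  est_part <- balance(est, neuron_seed(config$seed, 0L, 1L))
  val_part <- balance(val, neuron_seed(config$seed, 0L, 3L))
  y_est <- est_part$y; y_val <- val_part$y
  F_est <- est_part$X  # selected original features (z-scored)
  F_val <- val_part$X
  Z_est <- F_est       # current layer inputs
  Z_val <- F_val
  n_prev <- 0L         # neurons carried over from the previous layer
  layers <- list()
  best_val <- -Inf
  val_trace <- numeric(0)

  for (layer in seq_len(config$max_layers)) {
    m <- ncol(Z_est)
    if (m < 2L) break
    if (layer == 1L) {
      pairs <- t(combn(m, 2L))
      if (m > config$max_inputs_for_all_pairs) {
        psum <- sel_weights[pairs[, 1L]] + sel_weights[pairs[, 2L]]
        ord <- order(-psum, pairs[, 1L], pairs[, 2L])
        pairs <- pairs[head(ord, config$max_pairs), , drop = FALSE]
      }
    } else if (config$layer_features) {
      # previous-layer neurons pair with each other and, pass-through,
      # with the original selected features (feature-feature pairs were
      # layer 1's job); neuron-feature pairs ranked by feature weight
      nn <- if (n_prev >= 2L) t(combn(n_prev, 2L)) else
        matrix(integer(0), ncol = 2L)
      nf <- as.matrix(expand.grid(seq_len(n_prev),
                                  n_prev + seq_len(ncol(F_est))))
      w_ord <- order(-sel_weights[nf[, 2L] - n_prev], nf[, 1L], nf[, 2L])
      nf <- nf[w_ord, , drop = FALSE]
      room <- max(config$max_pairs - nrow(nn), 0L)
      pairs <- rbind(nn, head(nf, room))
      dimnames(pairs) <- NULL
    } else {
      if (n_prev < 2L) break
      pairs <- t(combn(n_prev, 2L))
    }
    if (nrow(pairs) == 0L) break
    neurons <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1L]; b <- pairs[i, 2L]
      ps <- config$pso
      ps$seed <- neuron_seed(config$seed, layer, i)
      nr <- fit_neuron_pso(Z_est[, a], Z_est[, b], y_est,
                           basis = config$basis, pso = ps,
                           inputs = c(a, b))
      if (nr$degenerate) {
        nr$validation_mcc <- 0
        nr$combined_mcc <- 0
      } else {
        val_pred <- as.numeric(neuron_response(nr, Z_val[, a], Z_val[, b]) >= 0.5)
        est_pred <- as.numeric(neuron_response(nr, Z_est[, a], Z_est[, b]) >= 0.5)
        nr$validation_mcc <- mcc(confusion(y_val, val_pred))
        nr$combined_mcc <- mcc(confusion(c(y_est, y_val), c(est_pred, val_pred)))
      }
      neurons[[i]] <- nr
    }
    vmcc <- map_dbl(neurons, "validation_mcc")
    emcc <- map_dbl(neurons, "estimation_mcc")
    rank_key <- switch(config$ranking,
                       combined = map_dbl(neurons, "combined_mcc"),
                       validation = vmcc,
                       estimation = emcc)
    ord <- order(-rank_key, -emcc, pairs[, 1L], pairs[, 2L])
    keep <- head(ord, config$top_k)
    layer_best <- max(vmcc[keep])  # early stopping watches validation MCC
    if (layer > 1L && layer_best <= best_val) break
    kept <- neurons[keep]
    layers[[layer]] <- kept
    best_val <- layer_best
    val_trace <- c(val_trace, layer_best)
    # kept neuron outputs, alongside the original features, feed the next
    # layer
    N_est <- vapply(kept, function(nr) {
      neuron_response(nr, Z_est[, nr$inputs[1L]], Z_est[, nr$inputs[2L]])
    }, numeric(nrow(Z_est)))
    N_val <- vapply(kept, function(nr) {
      neuron_response(nr, Z_val[, nr$inputs[1L]], Z_val[, nr$inputs[2L]])
    }, numeric(nrow(Z_val)))
    n_prev <- length(kept)
    if (config$layer_features) {
      Z_est <- cbind(N_est, F_est)
      Z_val <- cbind(N_val, F_val)
    } else {
      Z_est <- N_est
      Z_val <- N_val
    }
  }
  if (length(layers) == 0L) abort("no layer could be fitted")

  model <- structure(list(
    layers = layers,
    output_neuron = 1L,  # layers are stored ranked; best validation first
    feature_names = colnames(X)[selected],
    feature_index = selected,
    center = center[selected], scale = scale[selected],
    relief = rw, selected_weights = sel_weights,
    layer_features = config$layer_features,
    cutoff = 0.5, config = config,
    validation_trace = val_trace), class = "gmdh_model")

  cutoff_rows <- if (config$cutoff_data == "validation") val else seq_along(labels)
  cut_scores <- predict_scores(model, as_tibble(data)[cutoff_rows, , drop = FALSE])
  y_cut <- labels[cutoff_rows]
  model$cutoff <- if (config$cutoff_boot > 0L) {
    # median of resampled Youden thresholds: tames the variance of a
    # single threshold estimate when few minority samples are available
    boots <- with_local_seed(neuron_seed(config$seed, 0L, 4L), {
      vapply(seq_len(config$cutoff_boot), function(i) {
        idx <- sample.int(length(y_cut), replace = TRUE)
        if (length(unique(y_cut[idx])) < 2L) return(NA_real_)
        optimal_cutoff(cut_scores[idx], y_cut[idx],
                       method = config$cutoff_method)
      }, numeric(1))
    })
    median(boots, na.rm = TRUE)
  } else {
    optimal_cutoff(cut_scores, y_cut, method = config$cutoff_method)
  }
  model
}

#' Feed-forward scores of a trained GMDH model
#'
#' Evaluates the network on new samples and returns the output neuron's
#' score in (0, 1). Hard labels use `score >= model$cutoff` (see
#' [predict.gmdh_model()]).
#'
#' @param model A [train_gmdh()] fit.
#' @param data Feature table containing the model's input features.
#' @return Numeric scores in (0, 1).
#' @export
predict_scores <- function(model, data) {
  missing_cols <- setdiff(model$feature_names, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(as_tibble(data)[model$feature_names])
  F_mat <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  n <- nrow(F_mat)
  Z <- F_mat  # layer 1 sees the features; later layers neurons + features
  n_layers <- length(model$layers)
  for (l in seq_len(n_layers)) {
    kept <- model$layers[[l]]
    last <- l == n_layers
    upto <- if (last) model$output_neuron else length(kept)
    N <- matrix(vapply(kept[seq_len(upto)], function(nr) {
      neuron_response(nr, Z[, nr$inputs[1L]], Z[, nr$inputs[2L]])
    }, numeric(n)), nrow = n)
    if (last) return(N[, model$output_neuron])
    Z <- if (isTRUE(model$layer_features)) cbind(N, F_mat) else N
  }
}

#' @export
#' @rdname predict_scores
#' @param object A `gmdh_model`.
#' @param type `"score"` for the continuous output, `"class"` for hard 0/1
#'   labels at the model's cutoff.
#' @param ... Unused.
predict.gmdh_model <- function(object, data, type = c("score", "class"), ...) {
  type <- arg_match(type)
  s <- predict_scores(object, data)
  if (type == "score") s else as.numeric(s >= object$cutoff)
}

#' @export
print.gmdh_model <- function(x, ...) {
  cat("<gmdh_model> ", length(x$layers), " layer(s), ",
      length(x$feature_names), " selected features, cutoff ",
      signif(x$cutoff, 4), "\n", sep = "")
  cat("  validation MCC per layer: ",
      paste(signif(x$validation_trace, 3), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gmdh_model <- function(x, ...) {
  bind_rows(imap(x$layers, function(neurons, l) {
    bind_rows(imap(neurons, function(nr, i) {
      tibble(layer = as.integer(l), neuron = as.integer(i),
             input_1 = nr$inputs[1L], input_2 = nr$inputs[2L],
             estimation_mcc = nr$estimation_mcc,
             validation_mcc = nr$validation_mcc)
    }))
  }))
}

#' @export
glance.gmdh_model <- function(x, ...) {
  tibble(n_layers = length(x$layers),
         n_features = length(x$feature_names),
         cutoff = x$cutoff,
         best_validation_mcc = max(x$validation_trace))
}

#' @export
autoplot.gmdh_model <- function(object, ...) {
  d <- tibble(layer = seq_along(object$validation_trace),
              validation_mcc = object$validation_trace)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$layer, y = .data$validation_mcc)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$layer) +
    ggplot2::labs(x = "Layer", y = "Best validation MCC") +
    ggplot2::theme_minimal()
}

# JSON serialization ---------------------------------------------------------

#' Serialize a GMDH model to/from JSON
#'
#' The round trip is exact: scores from a deserialised model are
#' bit-identical to the original's.
#'
#' @param model A `gmdh_model`.
#' @export
gmdh_to_json <- function(model) {
  obj <- list(
    layers = map(model$layers, function(neurons) map(neurons, function(nr) {
      list(inputs = nr$inputs, basis = as.character(nr$basis),
           coefficients = unname(nr$coefficients),
           estimation_mcc = nr$estimation_mcc,
           validation_mcc = nr$validation_mcc,
           degenerate = isTRUE(nr$degenerate))
    })),
    output_neuron = model$output_neuron,
    feature_names = model$feature_names,
    feature_index = model$feature_index,
    center = model$center, scale = model$scale,
    cutoff = model$cutoff,
    layer_features = isTRUE(model$layer_features),
    validation_trace = model$validation_trace,
    config = list(top_k = model$config$top_k,
                  max_layers = model$config$max_layers,
                  basis = as.character(model$config$basis),
                  estimation_fraction = model$config$estimation_fraction,
                  seed = model$config$seed,
                  pso = unclass(model$config$pso)))
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
}

#' @rdname gmdh_to_json
#' @param json JSON string produced by [gmdh_to_json()].
#' @export
gmdh_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  layers <- map(obj$layers, function(neurons) map(neurons, function(nr) {
    structure(list(inputs = as.integer(unlist(nr$inputs)),
                   basis = gmdh_basis(unlist(nr$basis)),
                   coefficients = as.numeric(unlist(nr$coefficients)),
                   estimation_mcc = nr$estimation_mcc,
                   validation_mcc = nr$validation_mcc,
                   degenerate = isTRUE(nr$degenerate)),
              class = "gmdh_neuron")
  }))
  structure(list(layers = layers,
                 output_neuron = as.integer(obj$output_neuron),
                 feature_names = unlist(obj$feature_names),
                 feature_index = as.integer(unlist(obj$feature_index)),
                 center = as.numeric(unlist(obj$center)),
                 scale = as.numeric(unlist(obj$scale)),
                 cutoff = obj$cutoff,
                 layer_features = isTRUE(obj$layer_features),
                 validation_trace = as.numeric(unlist(obj$validation_trace)),
                 config = obj$config),
            class = "gmdh_model")
}
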