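# Categorical-to-interval logistic encoding: each category code of a
# categorical feature is mapped to the fitted probability of the positive
# class, estimated by a univariate logistic regression of the label on the
# one-hot (binary) encoding of that feature. A form of nonlinear data
# normalisation that turns unordered codes into comparable interval values.

#' Fit the categorical logistic encoder
#'
#' For every categorical feature a one-hot design over its observed
#' category codes is built and a per-feature logistic regression of the
#' class label on that design is fitted by iteratively reweighted least
#' squares on the fitting rows. Each category then maps to its fitted
#' positive-class probability; for a saturated fit this is the empirical
#' positive proportion within the category. Encoded values are clipped to
#' `[1e-6, 1 - 1e-6]`. Categories unseen at fitting time map to the
#' positive-class prevalence of the fitting set. If IRLS fails to converge
#' for a feature the encoder falls back to empirical category proportions
#' and flags the feature with a warning.
#'
#' @param data Feature table (or data frame) containing the features.
#' @param labels 0/1 labels aligned with `data`.
#' @param fitting_indices Rows used to fit the encoder (default: all).
#' @param max_iter,lambda IRLS iteration cap and ridge stabiliser.
#' @return Object of class `categorical_encoder`.
#' @export
#' @examples
#' d <- data.frame(grp = c(0, 0, 0, 1, 1))
#' enc <- fit_categorical_encoder(feature_table(d, kinds = c(grp = "categorical")),
#'                                labels = c(1, 0, 0, 1, 1))
#' tidy(enc)
fit_categorical_encoder <- function(data, labels, fitting_indices = NULL,
                                    max_iter = 50L, lambda = 1e-6) {
  labels <- check_labels(labels, n = nrow(data))
  if (is.null(fitting_indices)) fitting_indices <- seq_len(nrow(data))
  if (length(fitting_indices) == 0L) abort("fitting_indices must be non-empty")
  kind <- feature_kinds(data)
  cats <- names(kind)[kind == "categorical"]
  y <- labels[fitting_indices]
  prevalence <- mean(y)
  eps <- 1e-6
  clip <- function(p) pmin(pmax(p, eps), 1 - eps)
  maps <- list()
  diagnostics <- list()
  for (nm in cats) {
    codes <- as_tibble(data)[[nm]][fitting_indices]
    lev <- sort(unique(codes))
    X <- outer(codes, lev, `==`) * 1
    colnames(X) <- paste0("c", lev)
    fit <- irls_logistic(X, y, lambda = lambda, max_iter = max_iter,
                         intercept = FALSE)
    if (fit$converged) {
      vals <- plogis(pmin(pmax(fit$coefficients, -30), 30))
      # complete separation within a category: the saturated MLE sits at
      # the boundary, which IRLS only approaches; clip there directly
      emp <- vapply(lev, function(l) mean(y[codes == l]), numeric(1))
      vals[emp == 0] <- 0
      vals[emp == 1] <- 1
    } else {
      warn(paste0("encoder IRLS did not converge for '", nm,
                  "'; using empirical category proportions"))
      vals <- vapply(lev, function(l) mean(y[codes == l]), numeric(1))
    }
    maps[[nm]] <- setNames(clip(vals), as.character(lev))
    diagnostics[[nm]] <- list(iterations = fit$iterations,
                              converged = fit$converged)
  }
  structure(list(maps = maps, fallback = clip(prevalence),
                 feature_names = names(kind), diagnostics = diagnostics),
            class = "categorical_encoder")
}

#' Apply a fitted categorical encoder
#'
#' Categorical columns are replaced by their encoded interval values and
#' retagged continuous; binary and continuous columns pass through. Codes
#' not seen at fitting time receive the fallback value (the fitting-set
#' prevalence); the number of such fallbacks is recorded in the
#' `n_fallback` attribute.
#'
#' @param encoder A [fit_categorical_encoder()] object.
#' @param data A feature table with the same feature names it was fitted on.
#' @return An encoded [feature_table()].
#' @export
apply_encoder <- function(encoder, data) {
  unknown <- setdiff(names(encoder$maps), names(data))
  if (length(unknown) > 0L) {
    abort(paste0("encoder feature(s) missing from table: ",
                 paste(unknown, collapse = ", ")))
  }
  out <- as_tibble(data)
  kind <- feature_kinds(data)
  n_fallback <- 0L
  for (nm in names(encoder$maps)) {
    codes <- as.character(out[[nm]])
    enc <- unname(encoder$maps[[nm]][codes])
    miss <- is.na(enc)
    n_fallback <- n_fallback + sum(miss)
    enc[miss] <- encoder$fallback
    out[[nm]] <- enc
    kind[[nm]] <- "continuous"
  }
  ft <- feature_table(out, kinds = kind, sample_ids = sample_ids(data))
  attr(ft, "labels") <- attr(data, "labels")
  attr(ft, "n_fallback") <- n_fallback
  ft
}

#' @export
tidy.categorical_encoder <- function(x, ...) {
  if (length(x$maps) == 0L) {
    return(tibble(feature = character(), category = character(),
                  encoded = numeric()))
  }
  bind_rows(imap(x$maps, function(m, nm) {
    tibble(feature = nm, category = names(m), encoded = unname(m))
  }))
}

#' Serialize an encoder to/from JSON
#' @param encoder A fitted encoder.
#' @export
encoder_to_json <- function(encoder) {
  jsonlite::toJSON(list(maps = map(encoder$maps, as.list),
                        fallback = encoder$fallback,
                        feature_names = encoder$feature_names),
                   auto_unbox = TRUE, digits = I(17))
}

#' @rdname encoder_to_json
#' @param json JSON string from [encoder_to_json()].
#' @export
encoder_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  structure(list(maps = map(obj$maps, unlist),
                 fallback = obj$fallback,
                 feature_names = obj$feature_names,
                 diagnostics = list()),
            class = "categorical_encoder")
}
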