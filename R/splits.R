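# Class-preserving data splitting and minority oversampling.

#' Split index container
#'
#' Named, pairwise-disjoint integer index sets whose union covers the full
#' sample range (e.g. `train`/`test`, `fold_1..fold_k`,
#' `estimation`/`validation`), plus the seed that produced them.
#'
#' @param partitions Named list of integer vectors.
#' @param seed Integer seed recorded for reproducibility.
#' @param n Total number of samples the partitions must cover.
#' @return Object of class `split_indices`.
#' @export
split_indices <- function(partitions, seed, n) {
  if (is.null(names(partitions)) || any(!nzchar(names(partitions)))) {
    abort("partitions must be named")
  }
  idx <- sort(unlist(partitions, use.names = FALSE))
  if (any(lengths(partitions) == 0L)) abort("every partition must be non-empty")
  if (anyDuplicated(idx)) abort("partitions must be pairwise disjoint")
  if (!identical(idx, seq_len(n))) abort("partitions must cover all samples exactly")
  structure(list(partitions = map(partitions, as.integer),
                 seed = as.integer(seed), n = as.integer(n)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat("<split_indices> ", x$n, " samples, seed ", x$seed, "\n", sep = "")
  for (nm in names(x$partitions)) {
    cat("  ", nm, ": ", length(x$partitions[[nm]]), " samples\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.split_indices <- function(x, ...) {
  tibble(partition = rep(names(x$partitions), lengths(x$partitions)),
         index = unlist(x$partitions, use.names = FALSE))
}

#' Serialize split indices to/from JSON
#'
#' The JSON maps each partition name to a list of sample ids (or 1-based
#' indices when no ids are supplied).
#'
#' @param split A [split_indices()] object.
#' @param sample_ids Optional ids; indices are translated through them.
#' @export
split_to_json <- function(split, sample_ids = NULL) {
  parts <- split$partitions
  if (!is.null(sample_ids)) parts <- map(parts, ~ sample_ids[.x])
  jsonlite::toJSON(list(seed = split$seed, n = split$n, partitions = parts),
                   auto_unbox = TRUE, digits = I(17))
}

#' @rdname split_to_json
#' @param json JSON string produced by [split_to_json()].
#' @export
split_from_json <- function(json, sample_ids = NULL) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  parts <- obj$partitions
  if (!is.null(sample_ids)) parts <- map(parts, ~ match(.x, sample_ids))
  split_indices(map(parts, as.integer), seed = obj$seed, n = obj$n)
}

#' Stratified hold-out split
#'
#' Randomly partitions samples into `train`/`test` sets. With
#' `stratify = TRUE` (default) the split is drawn per class: each class
#' contributes `floor(train_fraction * class size)` training samples, and
#' leftover samples (to reach a total training size of
#' `round(train_fraction * n)`) are topped up on the training side, largest
#' fractional remainder first.
#'
#' @param labels 0/1 class labels (1 = positive / drug target).
#' @param train_fraction Fraction of samples assigned to training, in (0,1).
#' @param seed Integer seed; the same seed always yields the same split.
#' @param stratify Draw the split within each class (default) or globally.
#' @return A [split_indices()] with partitions `train` and `test`.
#' @export
#' @examples
#' y <- c(rep(1, 10), rep(0, 90))
#' sp <- stratified_holdout_split(y, 0.7, seed = 1)
#' table(y[sp$partitions$train])
stratified_holdout_split <- function(labels, train_fraction = 0.7, seed = 1L,
                                     stratify = TRUE) {
  labels <- check_labels(labels)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  n <- length(labels)
  with_local_seed(seed, {
    if (!stratify) {
      n_train <- round(train_fraction * n)
      if (n_train < 1L || n_train >= n) abort("split leaves an empty partition")
      train <- sort(sample.int(n, n_train))
    } else {
      classes <- sort(unique(labels))
      sizes <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
      if (any(sizes < 2L)) abort("cannot stratify: a class has fewer than 2 members")
      raw <- train_fraction * sizes
      take <- floor(raw)
      total_target <- round(train_fraction * n)
      deficit <- total_target - sum(take)
      if (deficit > 0L) {
        ord <- order(raw - take, -sizes, classes, decreasing = c(TRUE, FALSE, FALSE),
                     method = "radix")
        for (j in head(ord, deficit)) take[j] <- take[j] + 1L
      }
      if (any(take < 1L) || any(sizes - take < 1L)) {
        abort("train_fraction leaves a class empty on one side; adjust it")
      }
      train <- sort(unlist(map2(classes, take, function(cl, m) {
        idx <- which(labels == cl)
        idx[sample.int(length(idx), m)]
      })))
    }
    split_indices(list(train = train, test = setdiff(seq_len(n), train)),
                  seed = seed, n = n)
  })
}

#' Stratified k-fold indices
#'
#' Shuffles each class independently and deals samples round-robin into `k`
#' folds, so per-class fold sizes differ by at most one.
#'
#' @inheritParams stratified_holdout_split
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   members.
#' @return A [split_indices()] with partitions `fold_1 ... fold_k`.
#' @export
kfold_indices <- function(labels, k = 4L, seed = 1L) {
  labels <- check_labels(labels)
  k <- as.integer(k)
  if (k < 2L) abort("k must be >= 2")
  n <- length(labels)
  with_local_seed(seed, {
    folds <- vector("list", k)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        abort(paste0("class ", cl, " has ", length(idx),
                     " members; needs >= k = ", k))
      }
      idx <- idx[sample.int(length(idx))]
      assign_to <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    folds <- map(folds, sort)
    names(folds) <- paste0("fold_", seq_len(k))
    split_indices(folds, seed = seed, n = n)
  })
}

#' Oversample the minority class to balance
#'
#' Equalises class counts in a training set before fitting. The default
#' method duplicates minority rows drawn uniformly with replacement until
#' both classes are the same size; every original row is retained and no
#' unseen feature vector is ever synthesised, which keeps binary and
#' categorical features valid. `method = "smote"` instead interpolates new
#' continuous rows between a minority sample and one of its nearest
#' minority neighbours (binary/categorical columns are copied from the base
#' row).
#'
#' @param data Feature table or data frame (rows = samples).
#' @param labels 0/1 labels aligned with `data` rows.
#' @param seed Integer seed (resampling is deterministic per seed).
#' @param method `"duplicate"` (default) or `"smote"`.
#' @param smote_k Neighbours used by the SMOTE variant.
#' @return List with elements `data`, `labels` and `source_row` (the
#'   original row index each output row derives from).
#' @export
oversample_minority <- function(data, labels, seed = 1L,
                                method = c("duplicate", "smote"), smote_k = 5L) {
  method <- arg_match(method)
  labels <- check_labels(labels, n = nrow(data))
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0L)) abort("both classes must be non-empty")
  minority <- as.numeric(names(counts)[which.min(counts)])
  deficit <- abs(diff(as.integer(counts)))
  if (deficit == 0L) {
    return(list(data = as_tibble(data), labels = labels,
                source_row = seq_along(labels)))
  }
  min_idx <- which(labels == minority)
  with_local_seed(seed, {
    extra_src <- min_idx[sample.int(length(min_idx), deficit, replace = TRUE)]
    if (method == "duplicate") {
      new_rows <- as_tibble(data)[extra_src, , drop = FALSE]
    } else {
      base <- as_tibble(data)
      kind <- feature_kinds(data)
      cont <- names(kind)[kind == "continuous"]
      dmat <- as.matrix(dist(base[min_idx, , drop = FALSE]))
      diag(dmat) <- Inf
      new_rows <- map(extra_src, function(i) {
        pos_in_min <- match(i, min_idx)
        nb_local <- order(dmat[pos_in_min, ])[seq_len(min(smote_k, length(min_idx) - 1L))]
        nb <- min_idx[sample(nb_local, 1L)]
        row <- base[i, , drop = FALSE]
        gap <- runif(1)
        row[cont] <- row[cont] + gap * (base[nb, cont] - row[cont])
        row
      })
      new_rows <- bind_rows(new_rows)
    }
    list(data = bind_rows(as_tibble(data), new_rows),
         labels = c(labels, rep(minority, deficit)),
         source_row = c(seq_along(labels), extra_src))
  })
}
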