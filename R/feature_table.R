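# Feature tables: samples x features with per-feature kind metadata.
# Kinds: "binary" (values in {0,1}), "categorical" (integer codes >= 0,
# must be declared), "continuous" (anything numeric).

#' Construct a feature table
#'
#' A feature table is a tibble of numeric feature columns carrying two
#' attributes: `sample_ids` (one opaque identifier per row) and
#' `feature_kind` (a named character vector tagging every column as
#' `"binary"`, `"categorical"` or `"continuous"`). It is the learning
#' substrate for every classifier in the package: rows are proteins (or any
#' samples), columns are features such as biochemical annotations or graph
#' centralities.
#'
#' Kinds are inferred when not declared: a column whose values are all in
#' \{0, 1\} is tagged binary, everything else continuous. Categorical
#' columns (integer category codes) are never guessed; declare them through
#' `kinds`.
#'
#' @param data A data frame of numeric columns (features only).
#' @param kinds Optional named character vector of kind overrides, e.g.
#'   `c(ptm_class = "categorical")`. Names must match columns.
#' @param sample_ids Optional character vector of unique row identifiers;
#'   defaults to `"s1"..."sn"`.
#' @return A tibble of class `feature_table`.
#' @export
#' @examples
#' ft <- feature_table(data.frame(a = c(0, 1, 1), b = c(0.2, 3.1, -1)))
#' feature_kinds(ft)
feature_table <- function(data, kinds = NULL, sample_ids = NULL) {
  data <- as_tibble(as.data.frame(data))
  if (ncol(data) == 0L) abort("feature table needs at least one feature column")
  not_num <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(not_num) > 0L) {
    abort(paste0("non-numeric feature column(s): ", paste(not_num, collapse = ", ")))
  }
  if (anyNA(data)) {
    bad <- names(data)[vapply(data, anyNA, logical(1))]
    abort(paste0("missing values in column(s): ", paste(bad, collapse = ", "),
                 " (load with impute = TRUE to fill them)"))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(data)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(data)) abort("sample_ids length != row count")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate sample id(s): ", paste(dup, collapse = ", ")))
  }
  kind <- infer_feature_kinds(data, kinds)
  validate_kinds(data, kind)
  structure(data,
            sample_ids = sample_ids,
            feature_kind = kind,
            class = c("feature_table", class(data)))
}

#' @rdname feature_table
#' @param x A feature table (or plain data frame, for which kinds are
#'   inferred on the fly).
#' @export
feature_kinds <- function(x) {
  k <- attr(x, "feature_kind")
  if (is.null(k) || !all(names(x) %in% names(k))) {
    k <- infer_feature_kinds(as_tibble(x), NULL)
  }
  k[names(x)]
}

#' @rdname feature_table
#' @export
sample_ids <- function(x) {
  ids <- attr(x, "sample_ids")
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(x)))
  ids
}

infer_feature_kinds <- function(data, kinds = NULL) {
  inferred <- vapply(data, function(col) {
    if (all(col %in% c(0, 1))) "binary" else "continuous"
  }, character(1))
  if (!is.null(kinds)) {
    if (is.null(names(kinds)) || any(!nzchar(names(kinds)))) {
      abort("`kinds` must be a named character vector")
    }
    unknown <- setdiff(names(kinds), names(data))
    if (length(unknown) > 0L) {
      abort(paste0("kind override for unknown feature(s): ",
                   paste(unknown, collapse = ", ")))
    }
    bad <- setdiff(unique(kinds), c("binary", "categorical", "continuous"))
    if (length(bad) > 0L) abort(paste0("unknown feature kind: ", paste(bad, collapse = ", ")))
    inferred[names(kinds)] <- kinds
  }
  inferred
}

validate_kinds <- function(data, kind) {
  for (nm in names(data)) {
    col <- data[[nm]]
    if (kind[[nm]] == "binary" && !all(col %in% c(0, 1))) {
      abort(paste0("binary feature '", nm, "' has values outside {0,1}"))
    }
    if (kind[[nm]] == "categorical" &&
        (any(col < 0) || any(col != floor(col)))) {
      abort(paste0("categorical feature '", nm,
                   "' must hold integer category codes >= 0"))
    }
  }
  invisible(TRUE)
}

#' Read a feature table from CSV/TSV
#'
#' Expects a header row and a first column of unique sample identifiers;
#' every other column is a numeric feature. The delimiter is taken from the
#' file extension (`.tsv`/`.txt` means tab) unless given.
#'
#' @param path Path to the delimited file.
#' @param kind_map Optional named kind overrides (see [feature_table()]).
#' @param label_col Optional name of a column holding 0/1 class labels
#'   (1 = drug target). It is split off the table and attached as the
#'   `labels` attribute, retrievable with [class_labels()].
#' @param impute If `TRUE`, missing binary/categorical cells are filled with
#'   the column mode and continuous cells with the column median; the
#'   default is to fail on any missing value.
#' @param sep Field separator; `NULL` to infer from the extension.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, kind_map = NULL, label_col = NULL,
                               impute = FALSE, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  colClasses = "character", fill = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) abort("file must have an id column plus >= 1 feature column")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate sample id(s): ", paste(dup, collapse = ", ")))
  }
  feats <- raw[-1L]
  for (nm in names(feats)) {
    col <- feats[[nm]]
    col[col == "" | col == "NA"] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0L) {
      abort(paste0("non-numeric value '", col[bad[1L]], "' in column '", nm,
                   "', row ", bad[1L], " (id ", ids[bad[1L]], ")"))
    }
    feats[[nm]] <- num
  }
  labels <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% names(feats)) {
      abort(paste0("label column '", label_col, "' not found"))
    }
    labels <- feats[[label_col]]
    feats[[label_col]] <- NULL
    if (anyNA(labels) || !all(labels %in% c(0, 1))) {
      abort("labels must be 0/1 with no missing values")
    }
  }
  if (impute) feats <- impute_columns(feats, infer_feature_kinds(feats, kind_map))
  ft <- feature_table(feats, kinds = kind_map, sample_ids = ids)
  attr(ft, "labels") <- labels
  ft
}

#' Read a two-column (id, label) file
#'
#' @param path CSV/TSV with a header row, column 1 = sample id,
#'   column 2 = 0/1 label.
#' @param sep Field separator; `NULL` to infer from the extension.
#' @return Named numeric 0/1 vector (names = sample ids).
#' @export
read_labels <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, check.names = FALSE, fill = FALSE)
  if (ncol(raw) < 2L) abort("label file must have (id, label) columns")
  y <- as.numeric(raw[[2L]])
  if (anyNA(y) || !all(y %in% c(0, 1))) abort("labels must be 0/1")
  setNames(y, as.character(raw[[1L]]))
}

#' @rdname read_feature_table
#' @param x A feature table read with a `label_col`.
#' @export
class_labels <- function(x) attr(x, "labels")

impute_columns <- function(feats, kind) {
  for (nm in names(feats)) {
    col <- feats[[nm]]
    if (!anyNA(col)) next
    fill <- if (kind[[nm]] == "continuous") {
      median(col, na.rm = TRUE)
    } else {
      tab <- table(col)
      as.numeric(names(tab)[which.max(tab)])
    }
    col[is.na(col)] <- fill
    feats[[nm]] <- col
  }
  feats
}

# Shared label checks --------------------------------------------------------

check_labels <- function(labels, n = NULL, both_classes = TRUE) {
  if (!is.numeric(labels) || anyNA(labels) || !all(labels %in% c(0, 1))) {
    abort("labels must be a 0/1 numeric vector without missing values")
  }
  if (!is.null(n) && length(labels) != n) {
    abort("labels length does not match number of samples")
  }
  if (both_classes && length(unique(labels)) < 2L) {
    abort("both classes (0 and 1) must be present")
  }
  invisible(as.numeric(labels))
}

# Evaluate expr under a temporary RNG seed, restoring global state after.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}
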