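# Readers and writers.  The primary interchange format is CSV with a header
# row, an optional leading "id" column and a mandatory "label" column; a
# label-indexed sparse text format ("label index:value ...", 1-based
# feature indices) is supported for very sparse matrices.  All writes are
# atomic (temp file then rename).

#' Feature matrix with binary labels
#'
#' @param x nonnegative numeric matrix (samples x features), no missing
#'   values.
#' @param y binary labels (0/1), one per row.
#' @param feature_names unique feature names (defaults to the column names
#'   or `f1..fM`).
#' @param sample_ids sample identifiers (defaults to `s1..sn`).
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, y, feature_names = NULL, sample_ids = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values in the feature matrix")
  if (any(x < 0)) stop("feature values must be nonnegative")
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("label length mismatch")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  feature_names <- feature_names %||% colnames(x) %||%
    paste0("f", seq_len(ncol(x)))
  if (anyDuplicated(feature_names)) stop("duplicate feature names")
  if (length(feature_names) != ncol(x)) stop("feature name count mismatch")
  sample_ids <- sample_ids %||% rownames(x) %||% paste0("s", seq_len(nrow(x)))
  dimnames(x) <- NULL
  structure(
    list(x = x, y = y, feature_names = as.character(feature_names),
         sample_ids = as.character(sample_ids)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' Read a feature matrix
#'
#' CSV dialect: header row, optional `id` column, mandatory `label` column
#' (0/1), remaining columns numeric features.  Sparse dialect: one sample
#' per line, `label index:value ...`, feature indices 1-based; the feature
#' count is the largest index seen.
#'
#' @param path input file.
#' @param format `"csv"`, `"sparse"`, or `"auto"` (by file extension:
#'   `.csv` is CSV, anything else sparse).
#' @return a `feature_matrix`.
#' @export
read_matrix <- function(path, format = c("auto", "csv", "sparse")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "sparse"
  }
  if (format == "csv") read_matrix_csv(path) else read_matrix_sparse(path)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("CSV is missing the 'label' column")
  ids <- if ("id" %in% names(df)) as.character(df$id) else NULL
  feats <- setdiff(names(df), c("id", "label"))
  if (length(feats) == 0) stop("no feature columns")
  x <- as.matrix(df[, feats, drop = FALSE])
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0)[1]
    stop("missing/non-numeric value in data row ", bad)
  }
  labs <- df$label
  if (!all(labs %in% c(0, 1))) {
    bad <- which(!(labs %in% c(0, 1)))[1]
    stop("non-binary label in data row ", bad)
  }
  feature_matrix(x, labs, feature_names = feats, sample_ids = ids)
}

read_matrix_sparse <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty sparse file")
  parsed <- lapply(seq_along(lines), function(r) {
    toks <- strsplit(trimws(lines[r]), "\\s+")[[1]]
    lab <- suppressWarnings(as.numeric(toks[1]))
    if (is.na(lab) || !(lab %in% c(0, 1))) {
      stop("non-binary label in data row ", r)
    }
    if (length(toks) == 1) {
      return(list(label = lab, idx = integer(0), val = numeric(0)))
    }
    parts <- strsplit(toks[-1], ":", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("malformed entry in data row ", r)
    idx <- as.integer(vapply(parts, `[`, character(1), 1))
    val <- as.numeric(vapply(parts, `[`, character(1), 2))
    if (anyNA(idx) || anyNA(val) || any(idx < 1)) {
      stop("malformed entry in data row ", r)
    }
    list(label = lab, idx = idx, val = val)
  })
  M <- max(1L, max(unlist(lapply(parsed, `[[`, "idx")), 0L))
  x <- matrix(0, length(parsed), M)
  for (r in seq_along(parsed)) {
    x[r, parsed[[r]]$idx] <- parsed[[r]]$val
  }
  feature_matrix(x, vapply(parsed, `[[`, numeric(1), "label"))
}

#' Write a feature matrix
#'
#' @param data a `feature_matrix`.
#' @param path output file (written atomically).
#' @param format `"csv"` or `"sparse"` (see [read_matrix()]).
#' @return the path, invisibly.
#' @export
write_matrix <- function(data, path, format = c("csv", "sparse")) {
  stopifnot(inherits(data, "feature_matrix"))
  format <- match.arg(format)
  atomic_write(function(tmp) {
    if (format == "csv") {
      df <- data.frame(id = data$sample_ids, check.names = FALSE)
      xdf <- as.data.frame(data$x)
      names(xdf) <- data$feature_names
      df <- cbind(df, xdf)
      df$label <- data$y
      utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
    } else {
      lines <- vapply(seq_len(nrow(data$x)), function(r) {
        nz <- which(data$x[r, ] != 0)
        paste(c(data$y[r], sprintf("%d:%g", nz, data$x[r, nz])),
              collapse = " ")
      }, character(1))
      writeLines(lines, tmp)
    }
  }, path)
}

#' Write selection/benchmark results as JSON
#'
#' @param obj a list (e.g. `selection_result`s or metric rows).
#' @param path output file (written atomically).
#' @return the path, invisibly.
#' @export
write_results_json <- function(obj, path) {
  atomic_write(function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }, path)
}
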