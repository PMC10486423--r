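# Domain containers and readers/writers for feature blocks, label vectors,
# selection masks, and assembled datasets.

#' Create a feature block
#'
#' A feature block is one named matrix of per-sample feature values, typically
#' the activations of one fully-connected or average-pooling layer of a
#' pretrained convolutional network (e.g. DarkNet53, InceptionV3,
#' InceptionResNetV2, DenseNet201), one row per image sample.
#'
#' @param values numeric matrix, `n_samples x n_features`; all values must be
#'   finite.
#' @param name short block identifier, e.g. `"FV2"`; must be unique within a
#'   dataset.
#' @param source_tag free text naming the extractor/layer the block came from.
#' @return An object of class `feature_block` with elements `name`, `values`
#'   and `source_tag`.
#' @examples
#' fb <- feature_block(matrix(rnorm(20), 4, 5), "FV2", "InceptionV3/avg_pool")
#' dim(fb$values)
#' @export
feature_block <- function(values, name, source_tag = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop_ecgwo("feature block values must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_ecgwo("feature block '%s' must have at least 1 sample and 1 feature",
               name)
  if (!all(is.finite(values)))
    stop_ecgwo("feature block '%s' contains non-finite values", name)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_ecgwo("block name must be a non-empty string")
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- paste0(name, "_", seq_len(ncol(values)))
  structure(list(name = name, values = values,
                 source_tag = as.character(source_tag)),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("Feature block '%s': %d samples x %d features%s\n",
              x$name, nrow(x$values), ncol(x$values),
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]")
              else ""))
  invisible(x)
}

#' @export
dim.feature_block <- function(x) dim(x$values)

#' Create a label vector
#'
#' @param labels vector of class identifiers, one per sample (coerced to
#'   character).
#' @param classes ordered distinct class set; defaults to the sorted unique
#'   labels.
#' @param positive_class the class treated as "positive" (malignant) in
#'   confusion-matrix accounting; defaults to the last class.
#' @return An object of class `label_vector`.
#' @export
label_vector <- function(labels, classes = NULL, positive_class = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop_ecgwo("labels must be non-empty")
  if (is.null(classes)) classes <- sort(unique(labels))
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop_ecgwo("classes must be distinct")
  if (!all(labels %in% classes))
    stop_ecgwo("labels contain values outside the declared class set: %s",
               paste(setdiff(labels, classes), collapse = ", "))
  if (is.null(positive_class)) positive_class <- classes[length(classes)]
  if (!positive_class %in% classes)
    stop_ecgwo("positive_class '%s' is not one of the classes", positive_class)
  structure(list(labels = labels, classes = classes,
                 positive_class = positive_class),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$classes))
  cat(sprintf("Label vector: %d samples, %d classes (positive: '%s')\n",
              length(x$labels), length(x$classes), x$positive_class))
  print(tab)
  invisible(x)
}

#' @export
length.label_vector <- function(x) length(x$labels)

#' Create a selection mask
#'
#' A binary inclusion vector over the columns of a fused feature matrix.
#' A mask may never be empty: at least one feature must stay selected.
#'
#' @param bits vector of 0/1 values (logical accepted).
#' @return An object of class `selection_mask` with `bits` and
#'   `selected_count`.
#' @export
selection_mask <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) < 1L || !all(bits %in% c(0L, 1L)))
    stop_ecgwo("mask bits must be a non-empty 0/1 vector")
  k <- sum(bits)
  if (k < 1L) stop_ecgwo("selection mask must select at least one feature")
  structure(list(bits = bits, selected_count = k), class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("Selection mask: %d of %d features selected (%d%% reduction)\n",
              x$selected_count, length(x$bits),
              reduction_percentage(length(x$bits), x$selected_count)))
  invisible(x)
}

#' Assemble a dataset from feature blocks and labels
#'
#' Validates that every block shares the same number of samples as the label
#' vector, that block names are unique, and that at least two classes are
#' actually present.  Any mismatch raises; nothing is silently truncated.
#'
#' @param blocks list of [feature_block()] objects (order is preserved and
#'   defines fusion order).
#' @param labels a [label_vector()] (or plain vector, coerced).
#' @return An object of class `feature_dataset` with `blocks` (named list)
#'   and `labels`.
#' @examples
#' b1 <- feature_block(matrix(rnorm(8), 4, 2), "FV1")
#' b2 <- feature_block(matrix(rnorm(12), 4, 3), "FV2")
#' ds <- assemble_dataset(list(b1, b2), c("a", "a", "b", "b"))
#' @export
assemble_dataset <- function(blocks, labels) {
  if (!is.list(blocks) || length(blocks) < 1L)
    stop_ecgwo("blocks must be a non-empty list of feature blocks")
  if (!all(vapply(blocks, inherits, logical(1), "feature_block")))
    stop_ecgwo("every element of blocks must be a feature_block")
  if (!inherits(labels, "label_vector")) labels <- label_vector(labels)
  nm <- vapply(blocks, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop_ecgwo("duplicate block name(s): %s",
               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  ns <- vapply(blocks, function(b) nrow(b$values), integer(1))
  if (any(ns != length(labels$labels)))
    stop_ecgwo(
      "sample-count mismatch: blocks have %s rows but there are %d labels",
      paste(unique(ns), collapse = "/"), length(labels$labels))
  if (length(unique(labels$labels)) < 2L)
    stop_ecgwo("dataset must contain at least 2 classes, found %d",
               length(unique(labels$labels)))
  names(blocks) <- nm
  structure(list(blocks = blocks, labels = labels),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  widths <- vapply(x$blocks, function(b) ncol(b$values), integer(1))
  cat(sprintf("Feature dataset: %d samples, %d block(s) [%s], widths (%s)\n",
              length(x$labels$labels), length(x$blocks),
              paste(names(x$blocks), collapse = ", "),
              paste(widths, collapse = ", ")))
  invisible(x)
}

## ---- readers / writers -----------------------------------------------------

#' Read a feature block from disk
#'
#' Delimited files are comma-separated UTF-8 with a mandatory header row of
#' column names; the columnar-binary format is Feather (requires the `arrow`
#' package).  Row order is preserved; every cell must parse to a finite
#' number.
#'
#' @param path file to read.
#' @param format `"delimited"` (CSV, default) or `"columnar-binary"`
#'   (Feather).
#' @param name block name; defaults to the file name without extension.
#' @param source_tag optional provenance annotation.
#' @return A [feature_block()].
#' @export
read_feature_block <- function(path, format = c("delimited",
                                                "columnar-binary"),
                               name = NULL, source_tag = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ecgwo("file not found: %s", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "delimited") {
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character")
    if (ncol(df) < 1L || nrow(df) < 1L)
      stop_ecgwo("file %s holds no data rows", path)
    m <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, colnames(df)))
    for (j in seq_len(ncol(df))) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(!is.finite(v))
      if (length(bad))
        stop_ecgwo("non-numeric or non-finite cell at row %d, column '%s' of %s",
                   bad[1], colnames(df)[j], path)
      m[, j] <- v
    }
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop_ecgwo("the 'arrow' package is required for columnar-binary I/O")
    df <- as.data.frame(arrow::read_feather(path))
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    if (!all(is.finite(m)))
      stop_ecgwo("non-finite cell at row %d of %s",
                 which(!apply(is.finite(m), 1, all))[1], path)
  }
  feature_block(m, name = name, source_tag = source_tag)
}

#' Write a feature block to disk
#'
#' The written file reads back to an equal block: full double precision is
#' preserved (CSV uses 17 significant digits; Feather is bit-exact).
#'
#' @param block a [feature_block()].
#' @param path destination file.
#' @param format `"delimited"` or `"columnar-binary"`.
#' @return Invisibly, `path`.
#' @export
write_feature_block <- function(block, path,
                                format = c("delimited", "columnar-binary")) {
  format <- match.arg(format)
  if (!inherits(block, "feature_block"))
    stop_ecgwo("block must be a feature_block")
  if (format == "delimited") {
    df <- as.data.frame(block$values, check.names = FALSE)
    # 17 significant digits: round-trips IEEE doubles exactly
    df[] <- lapply(df, function(col) sprintf("%.17g", col))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop_ecgwo("the 'arrow' package is required for columnar-binary I/O")
    arrow::write_feather(as.data.frame(block$values, check.names = FALSE),
                         path)
  }
  invisible(path)
}

#' Read or write a label vector
#'
#' The on-disk form is either one label per line (no header) or a two-column
#' `sample,label` CSV with a header row; `write_labels` emits the one-per-line
#' form.
#'
#' @param path file to read or write.
#' @param positive_class optional positive class passed to [label_vector()].
#' @return `read_labels` returns a [label_vector()]; `write_labels` invisibly
#'   returns `path`.
#' @export
read_labels <- function(path, positive_class = NULL) {
  if (!file.exists(path)) stop_ecgwo("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_ecgwo("label file %s is empty", path)
  if (grepl(",", lines[1])) {
    df <- utils::read.csv(path, colClasses = "character")
    if (ncol(df) != 2L)
      stop_ecgwo("two-column sample,label table expected in %s", path)
    labels <- df[[2]]
  } else {
    labels <- trimws(lines)
  }
  label_vector(labels, positive_class = positive_class)
}

#' @rdname read_labels
#' @param labels a [label_vector()] or plain vector.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "label_vector")) labels <- labels$labels
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Read or write a selection mask
#'
#' Masks are serialized as a single line of `0`/`1` characters; a JSON
#' sidecar (`<path>.json`) records the selected count and, when available,
#' the column-origin map, so the artifact is both bit-exact and
#' human-checkable.
#'
#' @param path mask file.
#' @return `read_mask` returns a [selection_mask()]; `write_mask` invisibly
#'   returns `path`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_ecgwo("file not found: %s", path)
  line <- trimws(readLines(path, warn = FALSE)[1])
  bits <- as.integer(strsplit(line, "")[[1]])
  selection_mask(bits)
}

#' @rdname read_mask
#' @param mask a [selection_mask()].
#' @param origin optional column-origin data frame recorded in the sidecar.
#' @export
write_mask <- function(mask, path, origin = NULL) {
  if (!inherits(mask, "selection_mask"))
    stop_ecgwo("mask must be a selection_mask")
  writeLines(paste(mask$bits, collapse = ""), path)
  side <- list(selected_count = mask$selected_count,
               n_features = length(mask$bits))
  if (!is.null(origin)) side$column_origin <- origin
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
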