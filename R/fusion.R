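# Serial feature fusion: ordered concatenation of feature blocks with a
# column-origin map, plus the reduction-percentage bookkeeping used when
# reporting selector output.

#' Fuse feature blocks by serial concatenation
#'
#' Concatenates the blocks column-wise in the given order: blocks of widths
#' p and q fuse to width p + q (R^p (+) R^q -> R^(p+q)).  No rescaling or
#' normalization is applied; values are carried over unchanged and row order
#' is untouched.  A per-column origin map records which block and
#' within-block column each fused column came from, so the concatenation is
#' invertible.
#'
#' @param blocks ordered list of [feature_block()] objects sharing
#'   `n_samples`.
#' @return An object of class `fused_features` with elements `values`
#'   (matrix `n_samples x d_fused`), `column_origin` (data frame with
#'   columns `block`, `index`), and `combination_id` (e.g. `"FV2-FV3"`).
#' @examples
#' b2 <- feature_block(matrix(rnorm(30), 5, 6), "FV2")
#' b3 <- feature_block(matrix(rnorm(20), 5, 4), "FV3")
#' f <- fuse(list(b2, b3))
#' f$combination_id   # "FV2-FV3"
#' ncol(f$values)     # 10
#' @export
fuse <- function(blocks) {
  if (!is.list(blocks) || length(blocks) < 1L)
    stop_ecgwo("fuse() needs a non-empty list of feature blocks")
  if (!all(vapply(blocks, inherits, logical(1), "feature_block")))
    stop_ecgwo("every element must be a feature_block")
  ns <- vapply(blocks, function(b) nrow(b$values), integer(1))
  if (length(unique(ns)) != 1L)
    stop_ecgwo("blocks disagree on sample count: %s",
               paste(ns, collapse = ", "))
  values <- do.call(cbind, lapply(blocks, `[[`, "values"))
  origin <- do.call(rbind, lapply(blocks, function(b)
    data.frame(block = b$name, index = seq_len(ncol(b$values)),
               stringsAsFactors = FALSE)))
  rownames(origin) <- NULL
  structure(list(values = values,
                 column_origin = origin,
                 combination_id = paste(
                   vapply(blocks, `[[`, character(1), "name"),
                   collapse = "-")),
            class = "fused_features")
}

#' @export
print.fused_features <- function(x, ...) {
  cat(sprintf("Fused features '%s': %d samples x %d columns\n",
              x$combination_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.fused_features <- function(x) dim(x$values)

#' Project fused columns back onto a source block
#'
#' Inverse of [fuse()]: extracts the sub-matrix of fused columns whose
#' origin is `block_name`, reconstructing that block's values exactly.
#'
#' @param fused a `fused_features` object.
#' @param block_name name of the source block to reconstruct.
#' @return Numeric matrix equal to the original block's values.
#' @export
unfuse_block <- function(fused, block_name) {
  idx <- which(fused$column_origin$block == block_name)
  if (!length(idx))
    stop_ecgwo("no fused columns originate from block '%s'", block_name)
  fused$values[, idx, drop = FALSE]
}

#' The five standard fusion combinations
#'
#' Given exactly the four named blocks FV1..FV4, returns the five fused
#' combinations studied in the framework, in order: FV2-FV3, FV3-FV4,
#' FV2-FV4, FV2-FV3-FV4, FV1-FV2-FV3-FV4.
#'
#' @param blocks list of the four [feature_block()]s named `"FV1"`..`"FV4"`
#'   (any order; looked up by name).
#' @return Named list of five `fused_features` objects.
#' @export
standard_combinations <- function(blocks) {
  nm <- vapply(blocks, `[[`, character(1), "name")
  names(blocks) <- nm
  need <- paste0("FV", 1:4)
  missing <- setdiff(need, nm)
  if (length(missing))
    stop_ecgwo("missing named block(s): %s", paste(missing, collapse = ", "))
  combos <- list(c("FV2", "FV3"),
                 c("FV3", "FV4"),
                 c("FV2", "FV4"),
                 c("FV2", "FV3", "FV4"),
                 c("FV1", "FV2", "FV3", "FV4"))
  out <- lapply(combos, function(cc) fuse(blocks[cc]))
  names(out) <- vapply(out, `[[`, character(1), "combination_id")
  out
}

#' Reduction percentage
#'
#' The selector's headline summary: `100 * (1 - d_out / d_in)`, rounded to
#' the nearest integer with ties going away from zero.
#'
#' @param d_in fused column count before selection.
#' @param d_out selected column count.
#' @return Integer percent in `[0, 99]`.
#' @examples
#' reduction_percentage(2562, 948)  # 63
#' reduction_percentage(3456, 380)  # 89
#' @export
reduction_percentage <- function(d_in, d_out) {
  check_scalar(d_in, "d_in", lower = 1, integer = TRUE)
  check_scalar(d_out, "d_out", lower = 1, integer = TRUE)
  if (d_out > d_in)
    stop_ecgwo("d_out (%d) exceeds d_in (%d)", d_out, d_in)
  as.integer(round_half_away(100 * (1 - d_out / d_in)))
}
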