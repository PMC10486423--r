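# Published reference values the package's reporting format mirrors.

#' Reference reduction table for dermoscopy deep-feature selection
#'
#' The reported input/output dimensions and reduction percentages of the
#' five standard fusion combinations on the three dermoscopy benchmark
#' datasets (PH2, ISIC-MSK, ISIC-UDA), as published for the
#' entropy-controlled grey wolf selection framework this package
#' implements.  Useful as a fixture for verifying the package's
#' reduction-percentage arithmetic and reporting layout.
#'
#' Note one internal inconsistency of the published table: for the PH2
#' FV1-FV2-FV3-FV4 row the printed dimensions (4484 -> 628) imply an 86%
#' reduction while the printed percentage is 88; the row is flagged by
#' `consistent = FALSE`.
#'
#' @return Data frame with columns `dataset`, `combination`, `n_samples`,
#'   `d_in`, `d_out`, `reduction_printed`, `consistent` (whether
#'   [reduction_percentage()] of `d_in`, `d_out` equals the printed
#'   value).
#' @export
reference_reduction_table <- function() {
  df <- data.frame(
    dataset = rep(c("PH2", "ISIC-MSK", "ISIC-UDA"), each = 5),
    combination = rep(c("FV2-FV3", "FV3-FV4", "FV2-FV4",
                        "FV2-FV3-FV4", "FV1-FV2-FV3-FV4"), 3),
    n_samples = rep(c(140L, 201L, 271L), each = 5),
    d_in = rep(c(2562L, 2946L, 3456L, 4482L, 4484L), 3),
    d_out = c(948L, 884L, 380L, 583L, 628L,
              589L, 295L, 242L, 403L, 179L,
              436L, 383L, 346L, 538L, 448L),
    reduction_printed = c(63L, 70L, 89L, 87L, 88L,
                          77L, 90L, 93L, 91L, 96L,
                          83L, 87L, 90L, 88L, 90L),
    stringsAsFactors = FALSE)
  df$consistent <- mapply(reduction_percentage, df$d_in, df$d_out) ==
    df$reduction_printed
  df
}

#' Full-scale deep-feature block widths
#'
#' The widths of the four deep-feature blocks at full scale: FV1 (2,
#' classification-head output), FV2 (1536), FV3 (1026), FV4 (1920), as
#' extracted from the fully-connected and average-pooling layers of the
#' four pretrained networks.
#'
#' @return Named integer vector.
#' @export
reference_block_widths <- function() {
  c(FV1 = 2L, FV2 = 1536L, FV3 = 1026L, FV4 = 1920L)
}
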