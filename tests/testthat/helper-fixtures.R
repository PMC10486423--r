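# Fixtures built in code: small random blocks and datasets.

rand_block <- function(n, p, name, seed = 1, source_tag = "test") {
  set.seed(seed)
  feature_block(matrix(rnorm(n * p), n, p), name, source_tag)
}

# four named blocks FV1..FV4 at reduced widths, shared sample count
four_blocks <- function(n = 6, widths = c(2, 16, 10, 20), seed = 1) {
  set.seed(seed)
  lapply(seq_along(widths), function(b)
    feature_block(matrix(rnorm(n * widths[b]), n, widths[b]),
                  paste0("FV", b)))
}

# small, well-separated two-class dataset for classifier checks
separable_data <- function(n_per_class = 15, p = 6, delta = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, -delta / 2), n_per_class, p),
             matrix(rnorm(n_per_class * p, delta / 2), n_per_class, p))
  colnames(x) <- paste0("f", seq_len(p))
  y <- rep(c("benign", "malignant"), each = n_per_class)
  list(x = x, y = y)
}
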