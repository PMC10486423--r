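# Seeded generator of synthetic multi-block feature datasets with known
# informative / redundant / noise column structure.  The defaults emulate
# the study conditions at one tenth of the deep-feature widths: 200
# samples split 160/40 benign/malignant and block widths (2, 154, 102,
# 190), so every pipeline stage is exercisable in seconds without images
# or pretrained weights.

#' Synthetic dataset specification
#'
#' @param n_samples number of samples, default 200.
#' @param class_proportions named or unnamed proportions per class (must
#'   sum to 1); default `c(benign = 0.8, malignant = 0.2)`.
#' @param block_widths widths of the feature blocks, default
#'   `c(2, 154, 102, 190)` (blocks are named FV1..FVk).
#' @param n_informative per-block counts of class-informative columns;
#'   default `c(0, 7, 5, 8)`.
#' @param n_redundant per-block counts of redundant columns (noisy linear
#'   combinations of informative columns); default `c(0, 14, 10, 16)`.
#' @param effect_size class-mean separation delta of informative columns,
#'   in units of the unit within-class SD; default 2.
#' @param redundancy_noise_sd SD of the additive noise on redundant
#'   columns; default 0.1.
#' @param seed generator seed; the dataset is a pure function of the spec
#'   including the seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 200,
                           class_proportions = c(benign = 0.8,
                                                 malignant = 0.2),
                           block_widths = c(2, 154, 102, 190),
                           n_informative = c(0, 7, 5, 8),
                           n_redundant = c(0, 14, 10, 16),
                           effect_size = 2,
                           redundancy_noise_sd = 0.1,
                           seed = 0) {
  check_scalar(n_samples, "n_samples", lower = 4, integer = TRUE)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop_ecgwo("class_proportions must sum to 1")
  if (length(class_proportions) < 2L)
    stop_ecgwo("need at least 2 classes")
  if (is.null(names(class_proportions)))
    names(class_proportions) <- paste0("class", seq_along(class_proportions))
  nb <- length(block_widths)
  if (length(n_informative) != nb || length(n_redundant) != nb)
    stop_ecgwo("n_informative and n_redundant must match block_widths (%d)",
               nb)
  if (any(n_informative + n_redundant > block_widths))
    stop_ecgwo("informative + redundant exceeds width in block %d",
               which(n_informative + n_redundant > block_widths)[1])
  if (sum(n_informative) == 0 && sum(n_redundant) > 0)
    stop_ecgwo("redundant columns need at least one informative parent")
  check_scalar(effect_size, "effect_size", lower = 0)
  check_scalar(redundancy_noise_sd, "redundancy_noise_sd", lower = 0)
  check_scalar(seed, "seed")
  structure(list(n_samples = as.integer(n_samples),
                 class_proportions = class_proportions,
                 block_widths = as.integer(block_widths),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 effect_size = effect_size,
                 redundancy_noise_sd = redundancy_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic multi-block feature dataset
#'
#' Informative columns are class-conditional Gaussians with unit SD and
#' class means placed `effect_size` apart (for two classes: -delta/2 and
#' +delta/2, the positive class high).  Redundant columns are random
#' linear combinations of 1-3 informative columns plus
#' `N(0, redundancy_noise_sd^2)` noise.  All remaining columns are
#' standard Gaussian noise independent of class.  Column roles are
#' scattered within each block.  The output is bit-reproducible for a
#' given spec.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (a `feature_dataset`) and `truth`
#'   (a `synthetic_truth`: fused-coordinate index sets
#'   `informative_columns`, `redundant_columns`, `noise_columns`,
#'   per-redundant-column `parents`/`weights`, and the spec echo).
#' @examples
#' sim <- generate_synthetic(synthetic_spec(
#'   n_samples = 40, block_widths = c(2, 10), n_informative = c(0, 3),
#'   n_redundant = c(0, 2), seed = 1))
#' sim$dataset
#' @export
generate_synthetic <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop_ecgwo("spec must be a synthetic_spec")
  with_seed(spec$seed, {
    n <- spec$n_samples
    classes <- names(spec$class_proportions)
    counts <- as.integer(round_half_away(spec$class_proportions * n))
    counts[length(counts)] <- n - sum(counts[-length(counts)])
    if (any(counts < 2L))
      stop_ecgwo("class proportions leave a class with fewer than 2 samples")
    y <- sample(rep(classes, counts))
    # centered, equally spaced class scores; adjacent classes are
    # effect_size apart on informative columns
    score <- seq_along(classes) - (length(classes) + 1) / 2
    s <- score[match(y, classes)]

    d <- sum(spec$block_widths)
    offsets <- cumsum(c(0L, spec$block_widths[-length(spec$block_widths)]))
    informative <- integer(0)
    redundant <- integer(0)
    for (b in seq_along(spec$block_widths)) {
      roles <- sample.int(spec$block_widths[b],
                          spec$n_informative[b] + spec$n_redundant[b])
      informative <- c(informative,
                       offsets[b] + roles[seq_len(spec$n_informative[b])])
      if (spec$n_redundant[b] > 0)
        redundant <- c(redundant,
                       offsets[b] + roles[spec$n_informative[b] +
                                            seq_len(spec$n_redundant[b])])
    }
    informative <- sort(informative)
    redundant <- sort(redundant)

    x <- matrix(stats::rnorm(n * d), n, d)
    for (j in informative)
      x[, j] <- x[, j] + spec$effect_size * s
    parents <- list()
    weights <- list()
    for (j in redundant) {
      np <- sample.int(min(3L, length(informative)), 1L)
      par <- sort(sample(informative, np))
      w <- stats::runif(np, 0.5, 1.5) * sample(c(-1, 1), np, replace = TRUE)
      combo <- x[, par, drop = FALSE] %*% w
      x[, j] <- combo + stats::rnorm(n, sd = spec$redundancy_noise_sd)
      parents[[as.character(j)]] <- par
      weights[[as.character(j)]] <- w
    }

    blocks <- lapply(seq_along(spec$block_widths), function(b) {
      cols <- offsets[b] + seq_len(spec$block_widths[b])
      feature_block(x[, cols, drop = FALSE], paste0("FV", b),
                    source_tag = "synthetic")
    })
    dataset <- assemble_dataset(blocks, label_vector(
      y, classes = classes, positive_class = classes[length(classes)]))
    truth <- structure(list(
      informative_columns = informative,
      redundant_columns = redundant,
      noise_columns = setdiff(seq_len(d), c(informative, redundant)),
      parents = parents, weights = weights, spec = spec),
      class = "synthetic_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Oracle separability estimate
#'
#' An upper reference for feature-recovery tests: the hold-out accuracy of
#' a Gaussian nearest-centroid rule with class-prior correction
#' (discriminant `-||x - mu_c||^2 / 2 + log pi_c`), using only the truly
#' informative columns, on a fresh stratified 70:30 split.  At zero effect
#' size this approaches the majority-class rate; at large effect sizes it
#' approaches 1.
#'
#' @param dataset a `feature_dataset` from [generate_synthetic()].
#' @param truth the matching `synthetic_truth`.
#' @param seed split seed, default 0.
#' @return Estimated achievable accuracy in `[0, 1]`.
#' @export
oracle_separability <- function(dataset, truth, seed = 0) {
  fused <- fuse(unname(dataset$blocks))
  x <- fused$values[, truth$informative_columns, drop = FALSE]
  y <- dataset$labels$labels
  classes <- dataset$labels$classes
  split <- holdout_split(dataset$labels, 0.7, seed = seed)
  xtr <- x[split$train, , drop = FALSE]
  ytr <- y[split$train]
  xte <- x[split$test, , drop = FALSE]
  yte <- y[split$test]
  centroids <- t(vapply(classes, function(cl)
    colMeans(xtr[ytr == cl, , drop = FALSE]), numeric(ncol(x))))
  logprior <- log(as.numeric(table(factor(ytr, classes))) / length(ytr))
  disc <- vapply(seq_along(classes), function(c_i) {
    -rowSums(sweep(xte, 2, centroids[c_i, ])^2) / 2 + logprior[c_i]
  }, numeric(nrow(xte)))
  pred <- classes[max.col(disc, ties.method = "first")]
  mean(pred == yte)
}
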