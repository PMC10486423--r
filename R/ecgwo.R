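# Entropy-controlled grey wolf feature selection.  Wolves move in the
# continuous unit hypercube [0,1]^d; a candidate position decodes to a
# binary feature-inclusion mask by thresholding, and the subset is scored
# by the Shannon entropy of a probability distribution over the selected
# features (optionally blended with an inner-validation classifier
# accuracy in hybrid mode), minus a sparsity penalty.

#' Selector configuration
#'
#' @param gwo a [gwo_config()]; its `seed` seeds the whole selection run and
#'   its `bounds` are forced to `[0, 1]`.
#' @param binarize_threshold decode threshold in (0, 1): positions at or
#'   above it switch a feature on.  Default 0.5.
#' @param fitness_mode `"entropy"` (default; label-free filter objective) or
#'   `"hybrid"` (adds an inner-validation wrapper accuracy term).
#' @param sparsity_weight lambda >= 0 multiplying the selected fraction
#'   `k/d` subtracted from the fitness; `lambda = 0` recovers the pure
#'   normalized-entropy objective.  Default 0.5.
#' @param hybrid_accuracy_weight weight `w` in `[0, 1]` on the accuracy
#'   term in hybrid mode.  Default 0.9.
#' @param inner_validation_fraction fraction of training data held out
#'   inside the hybrid fitness.  Default 0.2.
#' @param hybrid_classifier [classifier_spec()] used by the hybrid wrapper
#'   term; default fine KNN (1 neighbour, Euclidean).
#' @return An object of class `selector_config`.
#' @export
selector_config <- function(gwo = gwo_config(),
                            binarize_threshold = 0.5,
                            fitness_mode = c("entropy", "hybrid"),
                            sparsity_weight = 0.5,
                            hybrid_accuracy_weight = 0.9,
                            inner_validation_fraction = 0.2,
                            hybrid_classifier = classifier_spec("fine-knn")) {
  if (!inherits(gwo, "gwo_config")) stop_ecgwo("gwo must be a gwo_config")
  fitness_mode <- match.arg(fitness_mode)
  check_scalar(binarize_threshold, "binarize_threshold", lower = 0, upper = 1)
  if (binarize_threshold <= 0 || binarize_threshold >= 1)
    stop_ecgwo("binarize_threshold must lie strictly in (0, 1)")
  check_scalar(sparsity_weight, "sparsity_weight", lower = 0)
  check_scalar(hybrid_accuracy_weight, "hybrid_accuracy_weight",
               lower = 0, upper = 1)
  check_scalar(inner_validation_fraction, "inner_validation_fraction",
               lower = 0, upper = 1)
  gwo$bounds <- c(0, 1)
  structure(list(gwo = gwo,
                 binarize_threshold = binarize_threshold,
                 fitness_mode = fitness_mode,
                 sparsity_weight = sparsity_weight,
                 hybrid_accuracy_weight = hybrid_accuracy_weight,
                 inner_validation_fraction = inner_validation_fraction,
                 hybrid_classifier = hybrid_classifier),
            class = "selector_config")
}

#' Decode a continuous position into a selection mask
#'
#' Bit j is 1 iff `position[j] >= threshold`.  If no bit would be set, the
#' single largest component is switched on (ties break to the lowest
#' index), so a mask is never empty.
#'
#' @param position numeric vector with components in `[0, 1]`.
#' @param threshold decode threshold, default 0.5.
#' @return A [selection_mask()].
#' @examples
#' binarize(c(0.7, 0.2, 0.5))$bits          # 1 0 1
#' binarize(c(0.1, 0.4, 0.2))$bits          # 0 1 0 (repair)
#' @export
binarize <- function(position, threshold = 0.5) {
  if (any(position < 0 | position > 1))
    stop_ecgwo("position components must lie in [0, 1]")
  bits <- as.integer(position >= threshold)
  if (sum(bits) == 0L) bits[which.max(position)] <- 1L
  selection_mask(bits)
}

#' Per-feature energy of selected columns
#'
#' The energy of column j is the mean over samples of `|x_ij|`; it is the
#' non-negative magnitude from which the entropy distribution over the
#' selected subset is formed.
#'
#' @param x numeric matrix (samples x features) or `fused_features`.
#' @param support integer indices of the selected columns.
#' @return Non-negative numeric vector, one energy per selected column.
#' @export
feature_energy <- function(x, support) {
  if (inherits(x, "fused_features")) x <- x$values
  if (!length(support)) stop_ecgwo("support must be non-empty")
  colMeans(abs(x[, support, drop = FALSE]))
}

#' Probability distribution over selected features
#'
#' Normalizes per-feature energies to a probability vector
#' `eta_j = energy_j / sum(energy)`.  If all energies are zero (degenerate
#' all-zero columns) the distribution falls back to uniform `1/k`.
#'
#' @param energies non-negative numeric vector.
#' @param support optional column indices carried along for reporting.
#' @return An object of class `entropy_distribution` with elements `eta`
#'   and `support`.
#' @export
entropy_distribution <- function(energies, support = seq_along(energies)) {
  if (!length(energies)) stop_ecgwo("need at least one energy value")
  if (any(energies < 0)) stop_ecgwo("energies must be non-negative")
  total <- sum(energies)
  eta <- if (total == 0) rep(1 / length(energies), length(energies))
         else energies / total
  structure(list(eta = eta, support = support),
            class = "entropy_distribution")
}

#' Shannon entropy in bits
#'
#' `H = -sum(eta * log2(eta))` with `0 * log2(0)` defined as 0; bounded by
#' `0 <= H <= log2(k)` for a distribution over k outcomes.
#'
#' @param eta an [entropy_distribution()] or a plain probability vector.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(0.25, 4))        # 2 bits
#' shannon_entropy(c(1, 0, 0))          # 0 bits
#' @export
shannon_entropy <- function(eta) {
  if (inherits(eta, "entropy_distribution")) eta <- eta$eta
  if (abs(sum(eta) - 1) > 1e-9 || any(eta < 0))
    stop_ecgwo("eta must be a probability vector summing to 1")
  p <- eta[eta > 0]
  -sum(p * log2(p))
}

# fast path used inside the optimization loop: energies for all columns are
# precomputed once, so a candidate evaluation is O(k).
entropy_fitness_from_energy <- function(energy_all, support, d, lambda) {
  k <- length(support)
  H <- shannon_entropy(entropy_distribution(energy_all[support]))
  H / log2(max(k, 2)) - lambda * (k / d)
}

#' Entropy-controlled fitness of a feature subset
#'
#' The information term is the Shannon entropy of the energy distribution
#' over the selected columns, normalized by `log2(max(k, 2))` so it lies in
#' `[0, 1]`; a sparsity penalty `lambda * k/d` creates pressure toward
#' small subsets.  The fitness is maximized.
#'
#' @param x numeric matrix or `fused_features`.
#' @param mask a [selection_mask()] (or 0/1 vector).
#' @param lambda sparsity weight, default 0.5.
#' @return Scalar fitness.
#' @export
entropy_fitness <- function(x, mask, lambda = 0.5) {
  if (inherits(x, "fused_features")) x <- x$values
  if (!inherits(mask, "selection_mask")) mask <- selection_mask(mask)
  if (length(mask$bits) != ncol(x))
    stop_ecgwo("mask length %d does not match %d columns",
               length(mask$bits), ncol(x))
  support <- which(mask$bits == 1L)
  entropy_fitness_from_energy(colMeans(abs(x)), support, ncol(x), lambda)
}

#' Hybrid wrapper fitness
#'
#' Blends an inner-validation classification accuracy with the entropy
#' fitness: `w * accuracy + (1 - w) * entropy_fitness`.  The inner split is
#' stratified by class and fully determined by `inner_seed`, so the
#' objective is deterministic within a selection run.
#'
#' @param x numeric matrix or `fused_features`.
#' @param labels a [label_vector()] or plain vector.
#' @param mask a [selection_mask()] (or 0/1 vector).
#' @param config a [selector_config()] in hybrid mode (supplies the weight,
#'   inner fraction and wrapper classifier).
#' @param inner_seed seed for the stratified inner split; defaults to the
#'   run seed in `config$gwo$seed`.
#' @return Scalar fitness.
#' @export
hybrid_fitness <- function(x, labels, mask, config,
                           inner_seed = config$gwo$seed) {
  if (inherits(x, "fused_features")) x <- x$values
  if (!inherits(labels, "label_vector")) labels <- label_vector(labels)
  if (!inherits(mask, "selection_mask")) mask <- selection_mask(mask)
  split <- holdout_split(labels,
                         train_fraction = 1 - config$inner_validation_fraction,
                         seed = inner_seed)
  support <- which(mask$bits == 1L)
  acc <- inner_accuracy(x, labels, support, split, config)
  w <- config$hybrid_accuracy_weight
  w * acc + (1 - w) * entropy_fitness_from_energy(
    colMeans(abs(x)), support, ncol(x), config$sparsity_weight)
}

inner_accuracy <- function(x, labels, support, split, config) {
  ytr <- labels$labels[split$train]
  yva <- labels$labels[split$test]
  if (length(unique(ytr)) < 2L)
    stop_ecgwo("inner training split contains a single class")
  xtr <- x[split$train, support, drop = FALSE]
  xva <- x[split$test, support, drop = FALSE]
  model <- fit_classifier(config$hybrid_classifier, xtr, ytr,
                          classes = labels$classes)
  pred <- predict(model, xva)
  mean(pred == yva)
}

#' Entropy-controlled grey wolf feature selection
#'
#' Runs the grey wolf optimizer over the continuous unit hypercube
#' `[0,1]^d` (one coordinate per fused feature column), maximizing the
#' configured fitness; the final alpha position decodes to the selected
#' feature subset.  In `"entropy"` mode the selector never sees labels
#' (a pure filter); `"hybrid"` mode additionally scores candidates by an
#' inner-validation classifier accuracy and requires `labels`.
#'
#' @param x a `fused_features` object or plain numeric matrix
#'   (samples x features) with at least 2 columns.
#' @param labels class labels (required in hybrid mode only).
#' @param config a [selector_config()].
#' @return An object of class `ecgwo` with components `mask`
#'   ([selection_mask()]), `fitness_trace` (best fitness per iteration,
#'   length `n_iterations + 1`), `d_in`, `d_out`, `reduction_pct`,
#'   `best_position`, `column_origin` (when `x` is fused), `config` and
#'   `seed`.  Supported methods: `print`, `summary`, `coef` (mask bits),
#'   `predict` (apply the mask to a matrix), `plot` (fitness trace).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 24), 60, 24)
#' sel <- ecgwo(x, config = selector_config(
#'   gwo = gwo_config(n_wolves = 10, n_iterations = 20, seed = 1)))
#' sel$reduction_pct
#' @export
ecgwo <- function(x, labels = NULL, config = selector_config()) {
  if (!inherits(config, "selector_config"))
    stop_ecgwo("config must be a selector_config")
  origin <- NULL
  if (inherits(x, "feature_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- fuse(unname(x$blocks))
  }
  if (inherits(x, "fused_features")) {
    origin <- x$column_origin
    x <- x$values
  }
  x <- as.matrix(x)
  d <- ncol(x)
  if (d < 2L) stop_ecgwo("need at least 2 feature columns, got %d", d)
  lambda <- config$sparsity_weight
  thr <- config$binarize_threshold
  energy_all <- colMeans(abs(x))

  if (config$fitness_mode == "entropy") {
    objective <- function(pos) {
      support <- which(pos >= thr)
      if (!length(support)) support <- which.max(pos)
      entropy_fitness_from_energy(energy_all, support, d, lambda)
    }
  } else {
    if (is.null(labels))
      stop_ecgwo("hybrid mode requires labels")
    if (!inherits(labels, "label_vector")) labels <- label_vector(labels)
    if (length(labels$labels) != nrow(x))
      stop_ecgwo("label length %d does not match %d samples",
                 length(labels$labels), nrow(x))
    split <- holdout_split(labels,
                           train_fraction =
                             1 - config$inner_validation_fraction,
                           seed = config$gwo$seed)
    w <- config$hybrid_accuracy_weight
    objective <- function(pos) {
      support <- which(pos >= thr)
      if (!length(support)) support <- which.max(pos)
      acc <- inner_accuracy(x, labels, support, split, config)
      w * acc + (1 - w) *
        entropy_fitness_from_energy(energy_all, support, d, lambda)
    }
  }

  fit <- gwo(objective, dim = d, sense = "maximize", config = config$gwo)
  mask <- binarize(fit$best_position, thr)
  structure(list(mask = mask,
                 fitness_trace = fit$trace,
                 d_in = d, d_out = mask$selected_count,
                 reduction_pct = reduction_percentage(d, mask$selected_count),
                 best_position = fit$best_position,
                 best_fitness = fit$best_fitness,
                 column_origin = origin,
                 config = config, seed = config$gwo$seed),
            class = "ecgwo")
}

#' @export
print.ecgwo <- function(x, ...) {
  cat("Entropy-controlled grey wolf feature selection\n")
  cat(sprintf("  mode: %s  (lambda = %g, seed = %d)\n",
              x$config$fitness_mode, x$config$sparsity_weight, x$seed))
  cat(sprintf("  input dimension:  %d\n", x$d_in))
  cat(sprintf("  output dimension: %d\n", x$d_out))
  cat(sprintf("  reduction:        %d%%\n", x$reduction_pct))
  cat(sprintf("  best fitness:     %.6g\n", x$best_fitness))
  invisible(x)
}

#' @export
summary.ecgwo <- function(object, ...) {
  out <- list(d_in = object$d_in, d_out = object$d_out,
              reduction_pct = object$reduction_pct,
              best_fitness = object$best_fitness,
              n_iterations = length(object$fitness_trace) - 1L,
              mode = object$config$fitness_mode,
              seed = object$seed)
  if (!is.null(object$column_origin)) {
    sel <- which(object$mask$bits == 1L)
    out$selected_by_block <- table(object$column_origin$block[sel])
  }
  class(out) <- "summary.ecgwo"
  out
}

#' @export
print.summary.ecgwo <- function(x, ...) {
  cat(sprintf(
    "ECGWO selection (%s mode): %d -> %d columns (%d%% reduction)\n",
    x$mode, x$d_in, x$d_out, x$reduction_pct))
  cat(sprintf("  %d iterations, seed %d, best fitness %.6g\n",
              x$n_iterations, x$seed, x$best_fitness))
  if (!is.null(x$selected_by_block)) {
    cat("  selected columns per source block:\n")
    print(x$selected_by_block)
  }
  invisible(x)
}

#' @export
coef.ecgwo <- function(object, ...) object$mask$bits

#' Apply a fitted selection to new data
#'
#' @param object an `ecgwo` fit.
#' @param newdata matrix or `fused_features` with the same column count the
#'   selector was fitted on.
#' @param ... unused.
#' @return The column-filtered matrix (selected columns only, order
#'   preserved).
#' @export
predict.ecgwo <- function(object, newdata, ...) {
  if (inherits(newdata, "fused_features")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d_in)
    stop_ecgwo("newdata has %d columns; selector was fitted on %d",
               ncol(newdata), object$d_in)
  newdata[, object$mask$bits == 1L, drop = FALSE]
}

#' @export
plot.ecgwo <- function(x, ...) {
  graphics::plot(seq_along(x$fitness_trace) - 1L, x$fitness_trace,
                 type = "l", xlab = "iteration",
                 ylab = "best fitness",
                 main = "ECGWO fitness trace", ...)
  invisible(x)
}
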