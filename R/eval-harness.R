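# Stratified hold-out evaluation harness: 70:30 split, confusion counts
# against a declared positive (malignant) class, the metric panel
# (accuracy, sensitivity, specificity, FNR, FPR, F1), and the
# with/without-selection comparison table.

#' Stratified hold-out split
#'
#' Partitions sample indices into disjoint, exhaustive train and test sets,
#' stratified by class: within each class, `round(train_fraction * n_c)`
#' samples go to training, adjusted so every class keeps at least one
#' sample on each side.  Fully determined by `seed`.
#'
#' @param labels a [label_vector()], plain label vector, or
#'   `feature_dataset`.
#' @param train_fraction fraction of each class used for training;
#'   default 0.7.
#' @param seed split seed.
#' @return List with integer vectors `train` and `test`.
#' @examples
#' y <- rep(c("benign", "melanoma"), c(160, 40))
#' sp <- holdout_split(y, 0.7, seed = 1)
#' length(sp$train)  # 140
#' @export
holdout_split <- function(labels, train_fraction = 0.7, seed = 0) {
  if (inherits(labels, "feature_dataset")) labels <- labels$labels
  if (!inherits(labels, "label_vector")) labels <- label_vector(labels)
  check_scalar(train_fraction, "train_fraction", lower = 0, upper = 1)
  y <- labels$labels
  counts <- table(y)
  if (any(counts < 2L))
    stop_ecgwo("every class needs at least 2 samples; class '%s' has %d",
               names(counts)[which.min(counts)], min(counts))
  with_seed(seed, {
    train <- integer(0)
    for (cl in names(counts)) {
      idx <- which(y == cl)
      n_c <- length(idx)
      n_tr <- as.integer(round_half_away(train_fraction * n_c))
      n_tr <- min(max(n_tr, 1L), n_c - 1L)  # >=1 sample on each side
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

#' Confusion counts against a positive class
#'
#' Binary confusion accounting: the declared positive class (typically
#' "malignant") against everything else.
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param positive_class the positive class.
#' @return Object of class `confusion_counts`: integers `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive_class) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop_ecgwo("truth and predicted lengths differ")
  tp <- truth == positive_class
  pp <- predicted == positive_class
  structure(list(TP = sum(tp & pp), FP = sum(!tp & pp),
                 TN = sum(!tp & !pp), FN = sum(tp & !pp)),
            class = "confusion_counts")
}

#' Metric panel from confusion counts
#'
#' Computes accuracy = (TP+TN)/n, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), FNR = 1 - sensitivity, FPR = 1 - specificity,
#' and F1 = 2TP/(2TP+FP+FN).  A ratio with zero denominator is reported as
#' `NA` with a warning, never silently as 0.
#'
#' @param counts a [confusion_counts()] or list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @return Named list: `accuracy`, `accuracy_pct`, `sensitivity`,
#'   `specificity`, `fnr`, `fpr`, `f1`, and `n_test`.
#' @examples
#' m <- metrics_from_counts(list(TP = 9, FN = 1, TN = 8, FP = 2))
#' m$sensitivity  # 0.9
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  for (v in c(tp, fp, tn, fn))
    check_scalar(v, "confusion count", lower = 0, integer = TRUE)
  n <- tp + fp + tn + fn
  if (n == 0L) stop_ecgwo("all confusion counts are zero")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NA",
                      what), call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  list(accuracy = (tp + tn) / n,
       accuracy_pct = 100 * (tp + tn) / n,
       sensitivity = sens,
       specificity = spec,
       fnr = 1 - sens,
       fpr = 1 - spec,
       f1 = ratio(2 * tp, 2 * tp + fp + fn, "F1"),
       n_test = n)
}

#' Hold-out evaluation of a classifier
#'
#' Splits the data 70:30 (stratified), optionally applies a selection mask
#' as a column filter, trains the classifier on the training rows only,
#' and reports the confusion counts and metric panel on the held-out test
#' rows.  All model fitting (including any stochastic ensemble draws) is
#' seeded, so a repeated call reproduces the report exactly.
#'
#' @param x `fused_features` or numeric matrix.
#' @param labels a [label_vector()] or plain vector.
#' @param spec a [classifier_spec()].
#' @param mask optional [selection_mask()] (or `ecgwo` fit) applied as a
#'   column filter before training.
#' @param train_fraction training fraction, default 0.7.
#' @param seed split / fitting seed.
#' @param split optional precomputed `list(train, test)` index partition
#'   (as from [holdout_split()]); overrides the seeded split.
#' @return Object of class `evaluation_report`: `classifier`, `condition`
#'   (`"fused-only"` or `"fused+selected"`), `counts`, the metric panel,
#'   and `split_seed`.
#' @export
evaluate <- function(x, labels, spec, mask = NULL,
                     train_fraction = 0.7, seed = 0, split = NULL) {
  if (inherits(x, "fused_features")) x <- x$values
  x <- as.matrix(x)
  if (!inherits(labels, "label_vector")) labels <- label_vector(labels)
  if (length(labels$labels) != nrow(x))
    stop_ecgwo("label length %d does not match %d samples",
               length(labels$labels), nrow(x))
  if (inherits(mask, "ecgwo")) mask <- mask$mask
  condition <- "fused-only"
  if (!is.null(mask)) {
    if (!inherits(mask, "selection_mask")) mask <- selection_mask(mask)
    if (length(mask$bits) != ncol(x))
      stop_ecgwo("mask length %d does not match %d columns",
                 length(mask$bits), ncol(x))
    x <- x[, mask$bits == 1L, drop = FALSE]
    condition <- "fused+selected"
  }
  if (is.null(split)) split <- holdout_split(labels, train_fraction, seed)
  ytr <- labels$labels[split$train]
  yte <- labels$labels[split$test]
  if (length(unique(ytr)) < 2L)
    stop_ecgwo("training split contains a single class")
  pred <- with_seed(seed, {
    model <- fit_classifier(spec, x[split$train, , drop = FALSE], ytr,
                            classes = labels$classes)
    predict(model, x[split$test, , drop = FALSE])
  })
  counts <- confusion_counts(yte, pred, labels$positive_class)
  metrics <- metrics_from_counts(counts)
  structure(c(list(classifier = spec, condition = condition,
                   counts = counts, split_seed = seed),
              metrics),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation [%s] classifier '%s' (seed %d)\n",
              x$condition, x$classifier$name, x$split_seed))
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$counts$TP, x$counts$FP, x$counts$TN, x$counts$FN, x$n_test))
  cat(sprintf(paste0("  accuracy %.2f%%  sensitivity %.3f  specificity",
                     " %.3f  FNR %.3f  FPR %.3f  F1 %.3f\n"),
              x$accuracy_pct, x$sensitivity, x$specificity,
              x$fnr, x$fpr, x$f1))
  invisible(x)
}

#' Compare fused-only against fused+selected conditions
#'
#' For every classifier and every split seed, evaluates both the raw fused
#' matrix and the mask-filtered matrix, reporting hold-out accuracy (%)
#' per row plus per-condition means — the with/without-selection
#' comparison layout.
#'
#' @param x `fused_features` or numeric matrix.
#' @param labels labels.
#' @param selection a [selection_mask()] or `ecgwo` fit.
#' @param specs list of [classifier_spec()]s (or preset names).
#' @param seeds integer vector of split seeds.
#' @param train_fraction default 0.7.
#' @return Object of class `condition_comparison`: `table` (one row per
#'   classifier x condition x seed) and `means` (per classifier x
#'   condition).
#' @export
compare_conditions <- function(x, labels, selection, specs, seeds = 1,
                               train_fraction = 0.7) {
  if (!length(specs)) stop_ecgwo("at least one classifier spec is required")
  specs <- lapply(specs, function(s)
    if (inherits(s, "classifier_spec")) s else classifier_spec(s))
  rows <- list()
  for (spec in specs) {
    for (seed in seeds) {
      for (cond in c("fused-only", "fused+selected")) {
        rep <- evaluate(x, labels, spec,
                        mask = if (cond == "fused+selected") selection,
                        train_fraction = train_fraction, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          classifier = spec$name, condition = cond, seed = seed,
          accuracy_pct = rep$accuracy_pct, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  means <- stats::aggregate(accuracy_pct ~ classifier + condition,
                            data = tab, FUN = mean)
  structure(list(table = tab, means = means),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Accuracy (%) by classifier and condition (mean over seeds):\n")
  wide <- stats::reshape(x$means, idvar = "classifier",
                         timevar = "condition", direction = "wide")
  names(wide) <- sub("^accuracy_pct\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
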