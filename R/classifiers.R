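# Pluggable fit/predict classifier contract with adapters for the
# framework's classifier panel: SVMs (linear / quadratic / cubic kernels),
# k-nearest-neighbour variants, and boosted / subspace / RUSBoost
# ensembles.  SVMs go through e1071, plain KNN through class::knn; the
# squared-inverse-weighted KNN and the three ensembles are implemented
# here over rpart / class primitives.

CLASSIFIER_PRESETS <- list(
  "linear-svm"    = list(family = "svm", degree = 1),
  "quadratic-svm" = list(family = "svm", degree = 2),
  "cubic-svm"     = list(family = "svm", degree = 3),
  "fine-knn"      = list(family = "knn", k = 1,  weight = "equal"),
  "medium-knn"    = list(family = "knn", k = 10, weight = "equal"),
  "weighted-knn"  = list(family = "knn", k = 10, weight = "squared-inverse"),
  "ensemble-subspace-knn" = list(family = "subspace-knn",
                                 n_learners = 30, k = 1),
  "ensemble-boosted-tree" = list(family = "boosted-tree",
                                 n_learners = 30, max_splits = 20),
  "ensemble-rusboost"     = list(family = "rusboost",
                                 n_learners = 30, max_splits = 20)
)

#' Classifier specification
#'
#' Names a classifier family together with its functional parameters.
#' The recognized presets mirror the evaluation panel: `"linear-svm"`,
#' `"quadratic-svm"`, `"cubic-svm"` (one-vs-one polynomial kernels),
#' `"fine-knn"` (1 neighbour, Euclidean, equal weights), `"medium-knn"`
#' (10 neighbours), `"weighted-knn"` (10 neighbours, squared-inverse
#' distance weights), `"ensemble-subspace-knn"` (30 random-subspace 1-NN
#' learners), `"ensemble-boosted-tree"` (AdaBoost over depth-limited
#' trees, 30 learners, at most 20 splits), and `"ensemble-rusboost"`
#' (AdaBoost with per-learner random undersampling of majority classes).
#'
#' @param name preset name (see above).
#' @param ... parameter overrides for the preset (e.g. `k = 5`,
#'   `n_learners = 10`).
#' @return An object of class `classifier_spec`.
#' @examples
#' classifier_spec("fine-knn")
#' classifier_spec("medium-knn", k = 7)
#' @export
classifier_spec <- function(name, ...) {
  if (!name %in% names(CLASSIFIER_PRESETS))
    stop_ecgwo("unknown classifier '%s'; available: %s", name,
               paste(names(CLASSIFIER_PRESETS), collapse = ", "))
  params <- utils::modifyList(CLASSIFIER_PRESETS[[name]], list(...))
  if (!is.null(params$k)) check_scalar(params$k, "k", lower = 1,
                                       integer = TRUE)
  if (!is.null(params$n_learners))
    check_scalar(params$n_learners, "n_learners", lower = 1, integer = TRUE)
  structure(c(list(name = name), params), class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  p <- x[setdiff(names(x), c("name", "family"))]
  cat(sprintf("Classifier '%s' (family %s)%s\n", x$name, x$family,
              if (length(p)) paste0(": ", paste(names(p), unlist(p),
                                                sep = "=", collapse = ", "))
              else ""))
  invisible(x)
}

#' Fit a classifier from its specification
#'
#' @param spec a [classifier_spec()].
#' @param x numeric training matrix (samples x features).
#' @param y training labels (character/factor).
#' @param classes ordered class levels; defaults to sorted unique labels.
#' @return A fitted model of class `ecgwo_classifier`; predict with
#'   `predict(model, newdata)`, which returns character labels.
#' @export
fit_classifier <- function(spec, x, y, classes = NULL) {
  if (!inherits(spec, "classifier_spec"))
    stop_ecgwo("spec must be a classifier_spec")
  x <- as.matrix(x)
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  yf <- factor(y, levels = classes)
  if (length(unique(y)) < 2L)
    stop_ecgwo("training data contains a single class")
  fitted <- switch(spec$family,
    "svm" = fit_svm(spec, x, yf),
    "knn" = list(x = x, y = yf),
    "subspace-knn" = fit_subspace_knn(spec, x, yf),
    "boosted-tree" = fit_adaboost(spec, x, yf, undersample = FALSE),
    "rusboost" = fit_adaboost(spec, x, yf, undersample = TRUE),
    stop_ecgwo("unknown classifier family '%s'", spec$family))
  structure(list(spec = spec, model = fitted, classes = classes),
            class = "ecgwo_classifier")
}

#' @export
predict.ecgwo_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  spec <- object$spec
  out <- switch(spec$family,
    "svm" = as.character(stats::predict(object$model, newdata)),
    "knn" = predict_knn(spec, object$model, newdata),
    "subspace-knn" = predict_subspace_knn(object$model, newdata),
    "boosted-tree" = ,
    "rusboost" = predict_adaboost(object$model, newdata, object$classes),
    stop_ecgwo("unknown classifier family '%s'", spec$family))
  out
}

## ---- SVM -------------------------------------------------------------------

fit_svm <- function(spec, x, yf) {
  kernel <- if (spec$degree == 1) "linear" else "polynomial"
  args <- list(x = x, y = yf, kernel = kernel, scale = FALSE)
  if (kernel == "polynomial") {
    args$degree <- spec$degree
    args$coef0 <- 1          # inhomogeneous polynomial kernel
  }
  do.call(e1071::svm, args)
}

## ---- KNN -------------------------------------------------------------------

predict_knn <- function(spec, model, newdata) {
  k <- min(spec$k, nrow(model$x))
  if (identical(spec$weight, "squared-inverse"))
    return(predict_weighted_knn(model$x, model$y, newdata, k))
  as.character(class::knn(model$x, newdata, model$y, k = k))
}

# squared-inverse distance weighting: each of the k nearest neighbours
# votes with weight 1/d^2; an exact-match neighbour decides outright.
predict_weighted_knn <- function(xtr, ytr, xte, k) {
  lv <- levels(ytr)
  d2 <- outer(rowSums(xte^2), rep(1, nrow(xtr))) +
    outer(rep(1, nrow(xte)), rowSums(xtr^2)) -
    2 * xte %*% t(xtr)
  d2[d2 < 0] <- 0
  apply_rows <- vapply(seq_len(nrow(xte)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    dd <- d2[i, nn]
    if (any(dd == 0)) return(as.character(ytr[nn[dd == 0][1]]))
    w <- 1 / dd
    votes <- tapply(w, ytr[nn], sum)
    lv[which.max(replace(rep(0, length(lv)),
                         match(names(votes), lv), votes))]
  }, character(1))
  apply_rows
}

## ---- random-subspace KNN ensemble ------------------------------------------

fit_subspace_knn <- function(spec, x, yf) {
  d <- ncol(x)
  sub_dim <- max(1L, floor(d / 2))
  subspaces <- lapply(seq_len(spec$n_learners), function(i)
    sort(sample.int(d, sub_dim)))
  list(x = x, y = yf, subspaces = subspaces, k = spec$k)
}

predict_subspace_knn <- function(model, newdata) {
  lv <- levels(model$y)
  votes <- matrix(0L, nrow(newdata), length(lv))
  for (sub in model$subspaces) {
    pred <- class::knn(model$x[, sub, drop = FALSE],
                       newdata[, sub, drop = FALSE],
                       model$y, k = model$k)
    idx <- cbind(seq_len(nrow(newdata)), as.integer(pred))
    votes[idx] <- votes[idx] + 1L
  }
  lv[max.col(votes, ties.method = "first")]
}

## ---- AdaBoost (SAMME) / RUSBoost over depth-limited trees ------------------

# max_splits caps the number of internal splits per tree; rpart limits
# depth, so the depth is chosen as the largest with 2^depth - 1 <= max_splits.
depth_for_splits <- function(max_splits) {
  max(1L, floor(log2(max_splits + 1)))
}

fit_adaboost <- function(spec, x, yf, undersample) {
  n <- nrow(x)
  K <- nlevels(yf)
  w <- rep(1 / n, n)
  depth <- depth_for_splits(spec$max_splits %||% 20)
  ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0, minsplit = 2,
                               xval = 0)
  learners <- list()
  alphas <- numeric(0)
  df_all <- data.frame(.y = yf, x, check.names = FALSE)
  for (m in seq_len(spec$n_learners)) {
    if (undersample) {
      idx <- rus_indices(yf)
      df <- df_all[idx, , drop = FALSE]
      wm <- w[idx]
    } else {
      df <- df_all
      wm <- w
    }
    tree <- rpart::rpart(.y ~ ., data = df, weights = wm / sum(wm),
                         method = "class", control = ctrl)
    pred <- predict_rpart_class(tree, df_all, levels(yf))
    miss <- pred != as.character(yf)
    err <- sum(w[miss]) / sum(w)
    if (err >= 1 - 1 / K) {            # no better than chance: reset and skip
      w <- rep(1 / n, n)
      next
    }
    alpha <- log((1 - err) / max(err, 1e-10)) + log(K - 1)
    learners[[length(learners) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    if (err < 1e-10) break             # perfect learner; voting is decided
  }
  list(learners = learners, alphas = alphas)
}

rus_indices <- function(yf) {
  counts <- table(yf)
  m <- min(counts)
  unlist(lapply(levels(yf), function(cl) {
    idx <- which(yf == cl)
    if (length(idx) > m) sample(idx, m) else idx
  }), use.names = FALSE)
}

predict_rpart_class <- function(tree, df, lv) {
  pr <- stats::predict(tree, df, type = "class")
  as.character(pr)
}

predict_adaboost <- function(model, newdata, classes) {
  df <- data.frame(as.data.frame(newdata), check.names = FALSE)
  if (!length(model$learners))
    return(rep(classes[1], nrow(newdata)))
  score <- matrix(0, nrow(newdata), length(classes),
                  dimnames = list(NULL, classes))
  for (m in seq_along(model$learners)) {
    pred <- predict_rpart_class(model$learners[[m]], df, classes)
    idx <- cbind(seq_len(nrow(newdata)), match(pred, classes))
    score[idx] <- score[idx] + model$alphas[m]
  }
  classes[max.col(score, ties.method = "first")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
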