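test_that("stratified hold-out reproduces the 70:30 protocol", {
  y <- rep(c("benign", "melanoma"), c(160, 40))
  sp <- holdout_split(y, 0.7, seed = 1)
  expect_length(sp$train, 140)
  expect_length(sp$test, 60)
  expect_setequal(c(sp$train, sp$test), 1:200)
  # per-class training proportion within one sample of 0.7
  for (cl in c("benign", "melanoma")) {
    n_cl <- sum(y == cl)
    n_tr <- sum(y[sp$train] == cl)
    expect_lte(abs(n_tr - 0.7 * n_cl), 1)
  }
  expect_identical(holdout_split(y, 0.7, seed = 1), sp)
  expect_false(identical(holdout_split(y, 0.7, seed = 2)$train, sp$train))
  expect_error(holdout_split(c("a", "a", "b"), 0.7, 1), "at least 2")
})

test_that("metric panel identities hold exactly", {
  m <- metrics_from_counts(list(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 18 / 21)
  expect_identical(m$fnr + m$sensitivity, 1)
  expect_identical(m$fpr + m$specificity, 1)

  perfect <- metrics_from_counts(list(TP = 10, FN = 0, TN = 30, FP = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$fnr, 0)
  expect_equal(perfect$fpr, 0)

  set.seed(8)
  for (i in 1:50) {
    cts <- as.list(rmultinom(1, 60, c(0.3, 0.1, 0.45, 0.15))[, 1] + 1L)
    names(cts) <- c("TP", "FP", "TN", "FN")
    mm <- metrics_from_counts(cts)
    expect_identical(mm$fnr + mm$sensitivity, 1)
    expect_identical(mm$fpr + mm$specificity, 1)
    expect_true(mm$accuracy >= 0 && mm$accuracy <= 1)
    expect_true(mm$f1 >= 0 && mm$f1 <= 1)
  }

  expect_warning(m0 <- metrics_from_counts(list(TP = 0, FN = 0, TN = 5,
                                                FP = 5)),
                 "sensitivity undefined")
  expect_true(is.na(m0$sensitivity))
  expect_error(metrics_from_counts(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "all-zero|zero")
})

test_that("every classifier family fits, predicts, and separates", {
  d <- separable_data(n_per_class = 20, p = 6)
  for (nm in c("linear-svm", "quadratic-svm", "cubic-svm", "fine-knn",
               "medium-knn", "weighted-knn", "ensemble-subspace-knn",
               "ensemble-boosted-tree", "ensemble-rusboost")) {
    rep <- evaluate(d$x, d$y, classifier_spec(nm), seed = 1)
    expect_equal(rep$accuracy, 1,
                 info = paste(nm, "on well-separated data"))
  }
  expect_error(classifier_spec("my-net"), "unknown classifier")
})

test_that("evaluation is seeded and an all-ones mask is a no-op", {
  sim <- generate_synthetic(synthetic_spec(
    n_samples = 60, block_widths = c(2, 12, 8, 14),
    n_informative = c(0, 3, 2, 3), n_redundant = c(0, 2, 1, 2),
    effect_size = 3, seed = 5))
  f <- fuse(unname(sim$dataset$blocks))
  spec <- classifier_spec("fine-knn")
  r1 <- evaluate(f, sim$dataset$labels, spec, seed = 3)
  r2 <- evaluate(f, sim$dataset$labels, spec, seed = 3)
  expect_identical(unclass(r1)[names(r1) != "classifier"],
                   unclass(r2)[names(r2) != "classifier"])
  r3 <- evaluate(f, sim$dataset$labels, spec,
                 mask = selection_mask(rep(1, ncol(f$values))), seed = 3)
  expect_identical(r1$counts, r3$counts)
  expect_equal(r3$condition, "fused+selected")
})

test_that("test labels never leak into training (canary)", {
  sim <- generate_synthetic(synthetic_spec(
    n_samples = 80, block_widths = c(2, 10, 8, 10),
    n_informative = c(0, 2, 2, 2), n_redundant = c(0, 0, 0, 0),
    effect_size = 1, seed = 9))
  f <- fuse(unname(sim$dataset$blocks))
  lv <- sim$dataset$labels
  split <- holdout_split(lv, 0.7, seed = 4)
  # shuffle the labels of the held-out rows only
  lv2 <- lv
  set.seed(99)
  lv2$labels[split$test] <- sample(lv$labels[split$test])
  for (nm in c("fine-knn", "quadratic-svm", "ensemble-boosted-tree")) {
    spec <- classifier_spec(nm)
    a <- evaluate(f, lv, spec, seed = 4, split = split)
    b <- evaluate(f, lv2, spec, seed = 4, split = split)
    # identical trained model => identical predictions => identical
    # predicted-positive and predicted-negative totals
    expect_identical(a$counts$TP + a$counts$FP, b$counts$TP + b$counts$FP,
                     info = nm)
    expect_identical(a$counts$TN + a$counts$FN, b$counts$TN + b$counts$FN,
                     info = nm)
  }
})

test_that("condition comparison emits one row per spec x condition x seed", {
  sim <- generate_synthetic(synthetic_spec(
    n_samples = 60, block_widths = c(2, 12, 8, 14),
    n_informative = c(0, 3, 2, 3), n_redundant = c(0, 2, 1, 2),
    effect_size = 3, seed = 2))
  f <- fuse(unname(sim$dataset$blocks))
  sel <- ecgwo(f, config = selector_config(
    gwo = gwo_config(n_wolves = 8, n_iterations = 10, seed = 1)))
  cmp <- compare_conditions(f, sim$dataset$labels, sel,
                            specs = c("fine-knn", "medium-knn",
                                      "linear-svm"),
                            seeds = 1:5)
  expect_equal(nrow(cmp$table), 30)
  expect_equal(nrow(cmp$means), 6)
  # identical conditions (mask of all ones) -> zero accuracy differences
  ones <- selection_mask(rep(1, ncol(f$values)))
  cmp0 <- compare_conditions(f, sim$dataset$labels, ones,
                             specs = "fine-knn", seeds = 1:3)
  wide <- split(cmp0$table$accuracy_pct, cmp0$table$condition)
  expect_identical(wide[["fused-only"]], wide[["fused+selected"]])
})
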