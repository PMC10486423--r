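test_that("binarization thresholds at 0.5 and repairs empty masks", {
  expect_identical(binarize(c(0.7, 0.2, 0.5))$bits, c(1L, 0L, 1L))
  expect_identical(binarize(c(0.1, 0.4, 0.2))$bits, c(0L, 1L, 0L))
  # tie in the repair breaks to the lowest index
  expect_identical(binarize(c(0.3, 0.3, 0.1))$bits, c(1L, 0L, 0L))
  expect_error(binarize(c(-0.1, 0.5)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:1000) {
    m <- binarize(runif(8))
    expect_gte(m$selected_count, 1L)
  }
})

test_that("feature energy equals the brute-force mean absolute value", {
  x <- matrix(3.5, 6, 2)
  expect_equal(unname(feature_energy(x, 1:2)), c(3.5, 3.5))
  expect_equal(unname(feature_energy(-x, 1)), 3.5)
  expect_equal(unname(feature_energy(matrix(0, 4, 3), 1:3)), rep(0, 3))
  set.seed(2)
  m <- matrix(rnorm(160), 20, 8)
  sup <- c(2, 5, 7)
  brute <- vapply(sup, function(j) sum(abs(m[, j])) / 20, numeric(1))
  expect_equal(unname(feature_energy(m, sup)), brute)
})

test_that("entropy distribution normalizes energies with uniform fallback", {
  expect_equal(entropy_distribution(c(1, 1, 1, 1))$eta, rep(0.25, 4))
  expect_equal(entropy_distribution(c(3, 1))$eta, c(0.75, 0.25))
  expect_equal(entropy_distribution(rep(0, 5))$eta, rep(0.2, 5))
  expect_error(entropy_distribution(numeric(0)), "at least one")
  expect_error(entropy_distribution(c(-1, 2)), "non-negative")
})

test_that("Shannon entropy matches hand values and stays within bounds", {
  expect_identical(shannon_entropy(rep(0.25, 4)), 2)
  expect_identical(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  set.seed(6)
  for (i in 1:200) {
    k <- sample(2:12, 1)
    eta <- entropy_distribution(runif(k))
    H <- shannon_entropy(eta)
    expect_gte(H, 0)
    expect_lte(H, log2(k) + 1e-12)
  }
  expect_error(shannon_entropy(c(0.5, 0.4)), "summing to 1")
})

test_that("entropy fitness is normalized entropy minus sparsity penalty", {
  x <- matrix(1, 5, 8)   # all energies equal -> uniform eta
  expect_equal(entropy_fitness(x, c(rep(1, 4), rep(0, 4)), lambda = 0), 1)
  expect_equal(entropy_fitness(x, c(rep(1, 4), rep(0, 4)), lambda = 0.5),
               0.75)
  # lambda = 0 endpoint: pure normalized entropy
  set.seed(3)
  m <- matrix(rnorm(40), 5, 8)
  mask <- selection_mask(c(1, 0, 1, 1, 0, 0, 1, 0))
  H <- shannon_entropy(entropy_distribution(
    feature_energy(m, which(mask$bits == 1L))))
  expect_equal(entropy_fitness(m, mask, 0), H / log2(4))
})

test_that("hybrid fitness reduces to wrapper accuracy at w = 1", {
  d <- separable_data(n_per_class = 20, p = 5)
  cfg <- selector_config(gwo = gwo_config(seed = 1),
                         fitness_mode = "hybrid",
                         hybrid_accuracy_weight = 1)
  f <- hybrid_fitness(d$x, d$y, rep(1, 5), cfg)
  expect_equal(f, 1)   # perfectly separable: accuracy term 1.0
  # seeded repeat -> identical fitness
  cfg2 <- selector_config(gwo = gwo_config(seed = 1),
                          fitness_mode = "hybrid")
  expect_identical(hybrid_fitness(d$x, d$y, c(1, 1, 0, 1, 0), cfg2),
                   hybrid_fitness(d$x, d$y, c(1, 1, 0, 1, 0), cfg2))
})

test_that("selection is seeded-reproducible with consistent reporting", {
  set.seed(20)
  x <- matrix(rnorm(60 * 30), 60, 30)
  cfg <- selector_config(gwo = gwo_config(n_wolves = 10, n_iterations = 25,
                                          seed = 11))
  s1 <- ecgwo(x, config = cfg)
  s2 <- ecgwo(x, config = cfg)
  expect_identical(s1$mask$bits, s2$mask$bits)
  expect_identical(s1$fitness_trace, s2$fitness_trace)
  expect_equal(s1$d_out, s1$mask$selected_count)
  expect_equal(s1$reduction_pct,
               reduction_percentage(s1$d_in, s1$d_out))
  expect_length(s1$fitness_trace, 26)
  expect_true(all(diff(s1$fitness_trace) >= 0))   # best-so-far, maximized
  expect_lte(s1$d_out, s1$d_in)

  expect_error(selector_config(gwo = gwo_config(n_wolves = 3)), "n_wolves")
  expect_error(ecgwo(matrix(1:5, 5, 1)), "at least 2")
  expect_error(ecgwo(x, config = selector_config(
    fitness_mode = "hybrid")), "requires labels")
})

test_that("ecgwo methods expose the mask, trace and reduced matrix", {
  sim <- generate_synthetic(synthetic_spec(
    n_samples = 40, block_widths = c(2, 10, 8, 12),
    n_informative = c(0, 2, 1, 2), n_redundant = c(0, 1, 1, 1), seed = 3))
  fit <- ecgwo(sim$dataset, config = selector_config(
    gwo = gwo_config(n_wolves = 8, n_iterations = 15, seed = 2)))
  expect_length(coef(fit), 32)
  red <- predict(fit, fuse(unname(sim$dataset$blocks)))
  expect_equal(ncol(red), fit$d_out)
  expect_equal(nrow(red), 40)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.ecgwo")
  expect_equal(sum(sm$selected_by_block), fit$d_out)
  expect_output(print(fit), "reduction")
})
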