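test_that("pack initialization is seeded, bounded, and leader-ordered", {
  cfg <- gwo_config(n_wolves = 10, n_iterations = 5, bounds = c(-2, 3),
                    seed = 7)
  s1 <- init_pack(cfg, 2, benchmark_sphere, "minimize")
  s2 <- init_pack(cfg, 2, benchmark_sphere, "minimize")
  expect_identical(s1$positions, s2$positions)
  expect_true(all(s1$positions >= -2 & s1$positions <= 3))
  # alpha is the pack minimum (direct oracle)
  s3 <- init_pack(gwo_config(n_wolves = 30, n_iterations = 5,
                             bounds = c(-5, 5), seed = 1),
                  3, benchmark_sphere, "minimize")
  expect_equal(s3$alpha$fitness, min(s3$fitnesses))
  expect_true(s3$alpha$fitness <= s3$beta$fitness)
  expect_true(s3$beta$fitness <= s3$delta$fitness)

  expect_error(gwo_config(n_wolves = 3), "n_wolves")
  expect_error(init_pack(cfg, 2, function(x) NaN), "wolf 1")
})

test_that("coefficient vectors follow A = 2*a*r1 - a, C = 2*r2", {
  co0 <- gwo_coefficients(0, 4)
  expect_equal(co0$A, rep(0, 4))
  co <- gwo_coefficients(1, 3, r1 = rep(0.5, 3), r2 = rep(0.25, 3))
  expect_equal(co$A, rep(0, 3))   # 2*1*0.5 - 1
  expect_equal(co$C, rep(0.5, 3))
  set.seed(11)
  draws <- replicate(1e4, unlist(gwo_coefficients(2, 1)))
  expect_true(all(draws["A", ] >= -2 & draws["A", ] <= 2))
  expect_true(all(draws["C", ] >= 0 & draws["C", ] <= 2))
})

test_that("encircling distance is |C*prey - wolf| and non-negative", {
  expect_equal(encircle_distance(rep(1, 3), c(1, 2, 3), c(1, 2, 3)),
               rep(0, 3))
  expect_equal(encircle_distance(2, 1, 0), 2)
  set.seed(4)
  for (i in 1:100) {
    d <- encircle_distance(runif(3, 0, 2), rnorm(3), rnorm(3))
    expect_true(all(d >= 0))
  }
  expect_error(encircle_distance(1:2, 1:3, 1:3), "equal dimension")
})

test_that("leader-guided update collapses to the leaders at a = 0", {
  cfg <- gwo_config(n_wolves = 4, n_iterations = 10, bounds = c(-5, 5),
                    seed = 2)
  st <- init_pack(cfg, 3, benchmark_sphere, "minimize")
  p <- c(1, -2, 0.5)
  st$alpha$position <- st$beta$position <- st$delta$position <- p
  st$a <- 0
  expect_equal(leader_guided_position(st, c(4, 4, 4)), p)
})

test_that("positions stay clamped to bounds and updates are seeded", {
  cfg <- gwo_config(n_wolves = 8, n_iterations = 10, bounds = c(-1, 1),
                    seed = 9)
  st <- init_pack(cfg, 4, benchmark_sphere, "minimize")
  set.seed(42)
  for (i in 1:100) {
    newp <- leader_guided_position(st, runif(4, -1, 1))
    expect_true(all(newp >= -1 & newp <= 1))
  }
  # two steps from identical states agree exactly
  a <- gwo_step(st, benchmark_sphere)
  b <- gwo_step(st, benchmark_sphere)
  expect_identical(a$positions, b$positions)
})

test_that("stepping improves monotonically and schedules a to zero", {
  cfg <- gwo_config(n_wolves = 12, n_iterations = 50, bounds = c(-10, 10),
                    seed = 5)
  st <- init_pack(cfg, 3, benchmark_sphere, "minimize")
  best <- st$alpha$fitness
  for (i in 1:50) {
    st <- gwo_step(st, benchmark_sphere)
    expect_true(st$alpha$fitness <= best)
    expect_true(st$alpha$fitness <= st$beta$fitness)
    expect_true(st$beta$fitness <= st$delta$fitness)
    best <- st$alpha$fitness
  }
  expect_identical(st$iteration, 50L)
  expect_lt(abs(st$a), 1e-12)
})

test_that("the optimizer converges on the sphere and is reproducible", {
  cfg <- gwo_config(n_wolves = 30, n_iterations = 200, bounds = c(-5, 5),
                    seed = 3)
  fit <- gwo(benchmark_sphere, dim = 2, config = cfg)
  expect_lt(fit$best_fitness, 1e-4)
  expect_length(fit$trace, 201)
  expect_true(all(diff(fit$trace) <= 0))   # monotone non-increasing
  fit2 <- gwo(benchmark_sphere, dim = 2, config = cfg)
  expect_identical(fit$trace, fit2$trace)

  const <- gwo(function(x) 42, dim = 2,
               config = gwo_config(n_wolves = 5, n_iterations = 5, seed = 1))
  expect_equal(const$best_fitness, 42)
})

test_that("maximization sense and the literal update rule are honoured", {
  fit <- gwo(function(x) -sum(x^2), dim = 2, sense = "maximize",
             config = gwo_config(n_wolves = 20, n_iterations = 100,
                                 bounds = c(-5, 5), seed = 2))
  expect_gt(fit$best_fitness, -1e-3)
  expect_true(all(diff(fit$trace) >= 0))
  # literal nested-absolute-value rule: runs, stays within bounds
  lit <- gwo(benchmark_sphere, dim = 2,
             config = gwo_config(n_wolves = 10, n_iterations = 30,
                                 bounds = c(0, 5), seed = 4,
                                 update_rule = "literal"))
  expect_true(all(lit$best_position >= 0 & lit$best_position <= 5))
})
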