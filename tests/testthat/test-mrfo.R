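make_state <- function(positions, best, lower = -10, upper = 10) {
  D <- ncol(positions)
  list(positions = positions, best_position = best,
       bounds = cbind(rep(lower, D), rep(upper, D)))
}

test_that("chain step matches hand values and leaves fixed points alone", {
  st <- make_state(matrix(2, 3, 2), best = c(2, 2))
  for (i in 1:3) {
    expect_equal(mrfo_chain_step(st, i, r = 0.7, r1 = 0.3), c(2, 2))
  }
  # 1-D: x=0, best=1, r=0.5, r1 chosen so alpha = 2r*sqrt(|ln r1|) = 0.5
  st1 <- make_state(matrix(0, 1, 1), best = 1)
  r1 <- exp(-0.25)
  expect_equal(mrfo_chain_step(st1, 1, r = 0.5, r1 = r1), 1.0)
  expect_error(mrfo_chain_step(st1, 5, 0.5, 0.5), "out of range")
})

test_that("all three step equations match the formula oracles", {
  set.seed(51)
  for (rep in 1:10) {
    pos <- matrix(runif(15, -5, 5), 5, 3)
    best <- runif(3, -5, 5)
    st <- make_state(pos, best, lower = -6, upper = 6)
    r <- runif(1); r1 <- runif(1); t <- sample(1:20, 1); T_max <- 20
    for (i in 1:5) {
      pred <- if (i == 1) best else pos[i - 1, ]
      expect_lt(max(abs(mrfo_chain_step(st, i, r, r1) -
        oracle_chain(pos[i, ], pred, best, r, r1, -6, 6))), 1e-12)
      expect_lt(max(abs(mrfo_cyclone_step(st, i, r, r1, t, T_max) -
        oracle_cyclone(pos[i, ], pos[max(i - 1, 1), ], best, r, r1, t, T_max,
                       -6, 6, first = i == 1))), 1e-12)
      rnd <- -6 + r * 12
      expect_lt(max(abs(
        mrfo_cyclone_step(st, i, r, r1, t, T_max, use_random_reference = TRUE) -
        oracle_cyclone(pos[i, ], pos[max(i - 1, 1), ], rep(rnd, 3), r, r1, t,
                       T_max, -6, 6, first = i == 1))), 1e-12)
      r2 <- runif(1); r3 <- runif(1)
      expect_lt(max(abs(mrfo_somersault_step(st, i, r2, r3, 2) -
        oracle_somersault(pos[i, ], best, 2, r2, r3, -6, 6))), 1e-12)
    }
  }
})

test_that("cyclone degenerates as the equations dictate", {
  # x_i equal to reference and predecessor: position unchanged
  st <- make_state(matrix(1.5, 2, 2), best = c(1.5, 1.5))
  expect_equal(mrfo_cyclone_step(st, 1, 0.4, 0.8, 3, 10), c(1.5, 1.5))
  expect_equal(mrfo_cyclone_step(st, 2, 0.4, 0.8, 3, 10), c(1.5, 1.5))
  # r1 = 0.5 makes beta = 0: pure chain-toward-reference motion
  pos <- matrix(c(1, 2, -1, 3), 2, 2)
  best <- c(0.5, -0.5)
  st <- make_state(pos, best)
  got <- mrfo_cyclone_step(st, 2, r = 0.3, r1 = 0.5, t = 1, t_max = 5)
  expect_equal(got, best + 0.3 * (pos[1, ] - pos[2, ]), tolerance = 1e-12)
  expect_error(mrfo_cyclone_step(st, 1, 0.3, 0.5, t = 6, t_max = 5), "budget")
})

test_that("somersault flips about the pivot and clips at the bounds", {
  st <- make_state(matrix(1, 1, 1), best = 1, lower = -10, upper = 10)
  expect_equal(mrfo_somersault_step(st, 1, r2 = 0.4, r3 = 0.4, 2), 1)
  expect_equal(mrfo_somersault_step(st, 1, r2 = 1, r3 = 0, 2), 3)
  st_clip <- make_state(matrix(1, 1, 1), best = 1, lower = -2, upper = 2)
  expect_equal(mrfo_somersault_step(st_clip, 1, r2 = 1, r3 = 0, 2), 2)
})

test_that("optimization is elitist, feasible and deterministic", {
  sphere <- function(x) sum(x^2)
  cfg <- mrfo_config(population = 10, max_iter = 30, bounds = c(-10, 10),
                     seed = 77)
  seen <- new.env(); seen$bad <- 0L
  watched <- function(x) {
    if (any(x < -10 - 1e-12) || any(x > 10 + 1e-12)) seen$bad <- seen$bad + 1L
    sphere(x)
  }
  a <- mrfo_optimize(watched, 3, cfg)
  expect_equal(seen$bad, 0L)                       # feasibility
  expect_true(all(diff(a$trace) <= 0))             # elitism
  b <- mrfo_optimize(sphere, 3, cfg)
  expect_identical(a[c("best_position", "best_fitness", "trace")],
                   b[c("best_position", "best_fitness", "trace")])

  flat <- mrfo_optimize(function(x) 3.25, 2,
                        mrfo_config(population = 5, max_iter = 10, seed = 1))
  expect_equal(flat$best_fitness, 3.25)
  expect_true(all(flat$trace == 3.25))

  expect_error(
    mrfo_optimize(function(x) NaN, 2,
                  mrfo_config(population = 3, max_iter = 2, seed = 1)),
    "non-finite")
})

test_that("longer budgets improve the sphere optimum", {
  sphere <- function(x) sum(x^2)
  med <- vapply(c(10, 50, 200), function(T_max) {
    stats::median(vapply(1:5, function(s)
      mrfo_optimize(sphere, 2, mrfo_config(population = 20, max_iter = T_max,
                                           bounds = c(-10, 10),
                                           seed = s))$best_fitness,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("a corner objective is located to within 0.1", {
  corner <- function(x) sqrt(sum((x - c(5, 5))^2))
  finals <- vapply(1:10, function(s)
    max(abs(mrfo_optimize(corner, 2,
                          mrfo_config(population = 20, max_iter = 200,
                                      bounds = c(-5, 5),
                                      seed = s))$best_position - c(5, 5))),
    numeric(1))
  expect_lt(stats::median(finals), 0.1)
})

test_that("the error-rate fitness is the misclassification percentage", {
  layout <- param_layout(2, 3)
  set.seed(61)
  X <- matrix(rnorm(300), 150, 2)
  labs <- rep(c("melanoma", "benign"), 75)
  # decode a random vector and compare against a direct recount
  v <- rnorm(layout$length)
  params <- unflatten_params(v, layout)
  pred <- cascade_predict(params, X)
  expect_equal(error_rate_fitness(v, X, labs, n_hidden = 3),
               100 * mean(pred != labs))
  # perfect and degenerate predictors
  sep <- matrix(c(rep(5, 75), rep(-5, 75)), 150, 1)
  labs2 <- rep(c("melanoma", "benign"), each = 75)
  l1 <- param_layout(1, 1)
  v1 <- rep(0, l1$length); v1[1] <- 3   # direct weight: sign(x) rule
  expect_equal(error_rate_fitness(v1, sep, labs2, n_hidden = 1), 0)
  v0 <- rep(0, l1$length)               # all-zero net scores ~0.62: all melanoma
  expect_equal(error_rate_fitness(v0, sep, labs2, n_hidden = 1), 50)
  expect_error(error_rate_fitness(v1, sep[0, , drop = FALSE], character(0), 1),
               "empty")
})
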