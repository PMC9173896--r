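#' Manta Ray Foraging Optimization configuration
#'
#' @param population number of agents `N` (>= 2).
#' @param max_iter iteration budget `T` (>= 1).
#' @param bounds either `c(lower, upper)` applied to every dimension or a
#'   `D x 2` matrix of per-dimension `(L, U)` with `L < U`.
#' @param somersault_factor somersault step scale `S` (> 0, canonical
#'   value 2).
#' @param seed integer seed; the whole run is deterministic given it.
#' @return an object of class `mrfo_config`.
#' @export
mrfo_config <- function(population = 30L, max_iter = 100L,
                        bounds = c(-5, 5), somersault_factor = 2,
                        seed = 1L) {
  check_scalar_number(population, "population", lower = 2)
  check_scalar_number(max_iter, "max_iter", lower = 1)
  check_scalar_number(somersault_factor, "somersault_factor",
                      lower = 0, strict_lower = TRUE)
  if (is.matrix(bounds)) {
    if (ncol(bounds) != 2L || any(!is.finite(bounds)) ||
        any(bounds[, 1] >= bounds[, 2])) {
      stop("`bounds` matrix must have finite columns L < U", call. = FALSE)
    }
  } else if (length(bounds) != 2L || any(!is.finite(bounds)) ||
             bounds[1] >= bounds[2]) {
    stop("`bounds` must be finite c(lower, upper) with lower < upper", call. = FALSE)
  }
  structure(list(population = as.integer(population),
                 max_iter = as.integer(max_iter), bounds = bounds,
                 somersault_factor = somersault_factor,
                 seed = as.integer(seed)),
            class = "mrfo_config")
}

.expand_bounds <- function(bounds, D) {
  if (is.matrix(bounds)) {
    stopifnot(nrow(bounds) == D)
    bounds
  } else {
    cbind(rep(bounds[1], D), rep(bounds[2], D))
  }
}

.clip_bounds <- function(x, bounds) {
  pmin(bounds[, 2], pmax(bounds[, 1], x))
}

.check_agent_index <- function(state, i) {
  if (i < 1L || i > nrow(state$positions)) {
    stop(sprintf("agent index %d out of range 1..%d", i, nrow(state$positions)),
         call. = FALSE)
  }
}

#' MRFO chain-foraging step
#'
#' Moves agent `i` towards the best-so-far position and (for `i >= 2`) its
#' chain predecessor:
#' `x_1 <- x_1 + r (x_best - x_1) + alpha (x_best - x_1)` and
#' `x_i <- x_i + r (x_{i-1} - x_i) + alpha (x_best - x_i)` with
#' `alpha = 2 r sqrt(|ln r1|)`.  The result is clipped to the bounds.
#'
#' @param state list with `positions` (`N x D`), `best_position` (length
#'   `D`) and `bounds` (`D x 2`).
#' @param i agent index (1-based).
#' @param r,r1 uniform draws in (0, 1).
#' @return the new length-`D` position of agent `i`.
#' @export
mrfo_chain_step <- function(state, i, r, r1) {
  .check_agent_index(state, i)
  x <- state$positions[i, ]
  best <- state$best_position
  alpha <- 2 * r * sqrt(abs(log(r1)))
  pred <- if (i == 1L) best else state$positions[i - 1L, ]
  .clip_bounds(x + r * (pred - x) + alpha * (best - x), state$bounds)
}

#' MRFO cyclone-foraging step
#'
#' Spirals agent `i` around a reference point — the best-so-far position,
#' or a fresh uniform point in the box when `use_random_reference` is set
#' (the exploration variant):
#' `x_1 <- ref + r (ref - x_1) + beta (ref - x_1)` and
#' `x_i <- ref + r (x_{i-1} - x_i) + beta (ref - x_i)` with
#' `beta = 2 exp(r1 (T - t + 1) / T) sin(2 pi r1)`.  Clipped to bounds.
#'
#' @inheritParams mrfo_chain_step
#' @param t current iteration (1-based); must satisfy `t <= t_max`.
#' @param t_max iteration budget `T`.
#' @param use_random_reference use a random in-box reference instead of the
#'   best-so-far position (exploration mode).
#' @return the new length-`D` position of agent `i`.
#' @export
mrfo_cyclone_step <- function(state, i, r, r1, t, t_max,
                              use_random_reference = FALSE) {
  .check_agent_index(state, i)
  if (t > t_max) stop("iteration t exceeds the budget T", call. = FALSE)
  x <- state$positions[i, ]
  ref <- if (use_random_reference) {
    state$bounds[, 1] + r * (state$bounds[, 2] - state$bounds[, 1])
  } else {
    state$best_position
  }
  beta <- 2 * exp(r1 * (t_max - t + 1) / t_max) * sin(2 * pi * r1)
  pred <- if (i == 1L) x else state$positions[i - 1L, ]
  moved <- if (i == 1L) {
    ref + r * (ref - x) + beta * (ref - x)
  } else {
    ref + r * (pred - x) + beta * (ref - x)
  }
  .clip_bounds(moved, state$bounds)
}

#' MRFO somersault-foraging step
#'
#' Flips agent `i` about the best-so-far position (the pivot):
#' `x_i <- x_i + S (r2 x_best - r3 x_i)`, clipped to bounds.
#'
#' @inheritParams mrfo_chain_step
#' @param r2,r3 uniform draws in `[0, 1]`.
#' @param somersault_factor step scale `S` (default 2).
#' @return the new length-`D` position of agent `i`.
#' @export
mrfo_somersault_step <- function(state, i, r2, r3, somersault_factor = 2) {
  .check_agent_index(state, i)
  x <- state$positions[i, ]
  .clip_bounds(x + somersault_factor *
                 (r2 * state$best_position - r3 * x), state$bounds)
}

.eval_fitness <- function(fitness, x) {
  v <- fitness(x)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    stop(paste0("fitness returned a non-finite value at position [",
                paste(signif(x, 6), collapse = ", "), "]"), call. = FALSE)
  }
  v
}

#' Minimize a fitness function with Manta Ray Foraging Optimization
#'
#' Runs the canonical MRFO schedule: each iteration, every agent either
#' cyclone-forages (probability 1/2; around a random in-box reference early
#' on — whenever `t/T` is below a fresh uniform draw — and around the best
#' position otherwise) or chain-forages; positions update sequentially so
#' each agent chains off its already-updated predecessor.  After all agents
#' move and are evaluated, every agent performs one somersault about the
#' best-so-far position and is re-evaluated.  The best-ever position is
#' tracked separately (elitism), all positions are clipped to the box, and
#' the entire run is deterministic given the seed.
#'
#' @param fitness function mapping a length-`D` numeric vector to a finite
#'   scalar (smaller is better).
#' @param n_dim problem dimension `D`.
#' @param config an [mrfo_config()].
#' @return a list with `best_position`, `best_fitness`, `trace` (best-so-far
#'   fitness after each iteration, non-increasing) and `evaluations`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' out <- mrfo_optimize(sphere, 2, mrfo_config(population = 10, max_iter = 50,
#'                                             bounds = c(-10, 10), seed = 1))
#' out$best_fitness
#' @export
mrfo_optimize <- function(fitness, n_dim, config = mrfo_config()) {
  stopifnot(inherits(config, "mrfo_config"))
  D <- as.integer(n_dim)
  bounds <- .expand_bounds(config$bounds, D)
  N <- config$population
  T_max <- config$max_iter
  S <- config$somersault_factor
  with_seed(config$seed, {
    positions <- sapply(seq_len(D), function(d)
      stats::runif(N, bounds[d, 1], bounds[d, 2]))
    positions <- matrix(positions, N, D)
    fitnesses <- apply(positions, 1L, function(x) .eval_fitness(fitness, x))
    best_i <- which.min(fitnesses)
    best_position <- positions[best_i, ]
    best_fitness <- fitnesses[best_i]
    evals <- N
    trace <- numeric(T_max)
    state <- list(positions = positions, bounds = bounds,
                  best_position = best_position)
    for (t in seq_len(T_max)) {
      for (i in seq_len(N)) {
        u <- stats::runif(1)
        r <- stats::runif(1)
        r1 <- stats::runif(1)
        state$best_position <- best_position
        new_x <- if (u < 0.5) {
          explore <- t / T_max < stats::runif(1)
          mrfo_cyclone_step(state, i, r, r1, t, T_max,
                            use_random_reference = explore)
        } else {
          mrfo_chain_step(state, i, r, r1)
        }
        state$positions[i, ] <- new_x
        f <- .eval_fitness(fitness, new_x)
        evals <- evals + 1L
        if (f < best_fitness) {
          best_fitness <- f
          best_position <- new_x
        }
      }
      state$best_position <- best_position
      for (i in seq_len(N)) {
        r2 <- stats::runif(1)
        r3 <- stats::runif(1)
        new_x <- mrfo_somersault_step(state, i, r2, r3, S)
        state$positions[i, ] <- new_x
        f <- .eval_fitness(fitness, new_x)
        evals <- evals + 1L
        if (f < best_fitness) {
          best_fitness <- f
          best_position <- new_x
        }
      }
      trace[t] <- best_fitness
    }
    list(best_position = best_position, best_fitness = best_fitness,
         trace = trace, evaluations = evals)
  })
}

#' Error-rate fitness for cascade-network training
#'
#' Decodes a flat parameter vector into a cascade-forward network, predicts
#' the supplied features, and returns the percentage of misclassified
#' samples — the quantity MRFO minimizes when training the classifier.
#'
#' @param param_vector flat weight vector (see [flatten_params()]).
#' @param features `m x n` feature matrix.
#' @param labels character vector of `"melanoma"` / `"benign"` truths.
#' @param n_hidden hidden-layer width of the decoded network.
#' @param activations activation triple of the decoded network.
#' @param threshold decision threshold (default 0.5).
#' @return misclassification rate in percent (`100 * wrong / total`).
#' @export
error_rate_fitness <- function(param_vector, features, labels,
                               n_hidden = 10L,
                               activations = c("identity", "logistic", "logistic"),
                               threshold = 0.5) {
  features <- as.matrix(features)
  if (length(labels) == 0L || nrow(features) == 0L) {
    stop("empty labelled set", call. = FALSE)
  }
  stopifnot(nrow(features) == length(labels))
  layout <- param_layout(ncol(features), n_hidden, activations)
  params <- unflatten_params(param_vector, layout)
  pred <- cascade_predict(params, features, threshold)
  100 * sum(pred != labels) / length(labels)
}

#' Train a cascade-forward classifier with MRFO
#'
#' Flattens the network's weight vector into MRFO's search space (box
#' `bounds` per dimension) and minimizes the error-rate fitness on the
#' training features.
#'
#' @param features `m x n` training feature matrix.
#' @param labels character vector of training labels.
#' @param n_hidden hidden-layer width (default 10).
#' @param activations activation triple.
#' @param config an [mrfo_config()].
#' @return a list with `params` (the trained [cascade_params()]),
#'   `best_fitness` (training error rate, percent), `trace` and `layout`.
#' @export
train_cascade_mrfo <- function(features, labels, n_hidden = 10L,
                               activations = c("identity", "logistic", "logistic"),
                               config = mrfo_config()) {
  features <- as.matrix(features)
  layout <- param_layout(ncol(features), n_hidden, activations)
  fit_fun <- function(v) error_rate_fitness(v, features, labels,
                                            n_hidden, activations)
  out <- mrfo_optimize(fit_fun, layout$length, config)
  list(params = unflatten_params(out$best_position, layout),
       best_fitness = out$best_fitness, trace = out$trace, layout = layout)
}
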