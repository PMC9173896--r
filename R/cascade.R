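#' Cascade-forward network parameters
#'
#' A cascade-forward network augments a one-hidden-layer perceptron with
#' direct input-to-output connections.  Its raw output is
#' `y = f_i(sum_i w_i x_i) + f_o(w_b + sum_j w_j^o f_h(w_jb + sum_i w_ji x_i))`,
#' i.e. a direct linear path through activation `f_i` plus a standard
#' hidden-layer path through `f_h` and `f_o`.  Because `y` is the unbounded
#' sum of two terms, classification scores are produced by a final logistic
#' squash of `y` (see [cascade_forward()]).
#'
#' @param n_inputs number of input features `n`.
#' @param n_hidden number of hidden units `k`.
#' @param direct_weights length-`n` vector (input -> output path).
#' @param hidden_weights `n_hidden x n` matrix (input -> hidden).
#' @param output_weights length-`n_hidden` vector (hidden -> output).
#' @param hidden_biases length-`n_hidden` vector.
#' @param output_bias scalar.
#' @param activations character vector `c(input, hidden, output)`, each one
#'   of `"identity"`, `"logistic"`, `"tanh"`.
#' @return an object of class `cascade_params`.
#' @export
cascade_params <- function(n_inputs, n_hidden = 10L,
                           direct_weights = numeric(n_inputs),
                           hidden_weights = matrix(0, n_hidden, n_inputs),
                           output_weights = numeric(n_hidden),
                           hidden_biases = numeric(n_hidden),
                           output_bias = 0,
                           activations = c("identity", "logistic", "logistic")) {
  n_inputs <- as.integer(n_inputs); n_hidden <- as.integer(n_hidden)
  acts <- match.arg(activations, c("identity", "logistic", "tanh"),
                    several.ok = TRUE)
  if (length(acts) != 3L) stop("`activations` must have 3 entries", call. = FALSE)
  p <- list(n_inputs = n_inputs, n_hidden = n_hidden,
            direct_weights = as.numeric(direct_weights),
            hidden_weights = matrix(as.numeric(hidden_weights), n_hidden, n_inputs),
            output_weights = as.numeric(output_weights),
            hidden_biases = as.numeric(hidden_biases),
            output_bias = as.numeric(output_bias),
            activations = acts)
  if (length(p$direct_weights) != n_inputs ||
      length(p$output_weights) != n_hidden ||
      length(p$hidden_biases) != n_hidden ||
      length(p$output_bias) != 1L) {
    stop("cascade parameter dimensions are inconsistent", call. = FALSE)
  }
  if (!all(vapply(p[3:7], function(v) all(is.finite(v)), logical(1)))) {
    stop("cascade parameters must be finite", call. = FALSE)
  }
  structure(p, class = "cascade_params")
}

.activation <- function(name) {
  switch(name,
         identity = function(x) x,
         logistic = stats::plogis,
         tanh = tanh,
         stop(sprintf("unknown activation `%s`", name), call. = FALSE))
}

#' Forward pass of the cascade-forward network
#'
#' Evaluates `y = f_i(sum_i w_i x_i) + f_o(w_b + sum_j w_j^o f_h(w_jb +
#' sum_i w_ji x_i))` for each row of `X`, then squashes `y` through the
#' logistic function so scores are comparable probabilities in (0, 1).
#'
#' @param params a [cascade_params()].
#' @param x a numeric vector of length `n_inputs`, or an `m x n_inputs`
#'   matrix of row vectors.
#' @param squash logical; if `FALSE`, return the raw `y` instead of
#'   `plogis(y)`.
#' @return numeric vector of scores (one per input row).
#' @export
cascade_forward <- function(params, x, squash = TRUE) {
  stopifnot(inherits(params, "cascade_params"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != params$n_inputs) {
    stop(sprintf("input has %d columns but the network expects %d",
                 ncol(X), params$n_inputs), call. = FALSE)
  }
  f_i <- .activation(params$activations[1])
  f_h <- .activation(params$activations[2])
  f_o <- .activation(params$activations[3])
  direct <- f_i(drop(X %*% params$direct_weights))
  hidden <- f_h(sweep(X %*% t(params$hidden_weights), 2L,
                      params$hidden_biases, "+"))
  y <- direct + f_o(params$output_bias +
                    drop(hidden %*% params$output_weights))
  if (squash) stats::plogis(y) else y
}

#' Classify feature vectors with a cascade-forward network
#'
#' @param params a [cascade_params()].
#' @param X `m x n_inputs` matrix (or a single vector).
#' @param threshold decision threshold on the squashed score; a score
#'   exactly at the threshold is labelled melanoma.
#' @return character vector of `"melanoma"` / `"benign"` labels.
#' @export
cascade_predict <- function(params, X, threshold = 0.5) {
  scores <- cascade_forward(params, X)
  ifelse(scores >= threshold, "melanoma", "benign")
}

#' Flatten cascade parameters into a vector (and back)
#'
#' The layout, in order, is: direct weights (`n`), hidden weights
#' (`n_hidden x n`, column-major), output weights (`n_hidden`), hidden
#' biases (`n_hidden`), output bias (1) — total
#' `n + n_hidden*n + 2*n_hidden + 1`.
#'
#' @param params a [cascade_params()].
#' @return for `flatten_params`, a numeric vector with attribute `layout`;
#'   for `unflatten_params`, the reconstructed [cascade_params()].
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "cascade_params"))
  v <- c(params$direct_weights, as.vector(params$hidden_weights),
         params$output_weights, params$hidden_biases, params$output_bias)
  attr(v, "layout") <- param_layout(params$n_inputs, params$n_hidden,
                                    params$activations)
  v
}

#' @rdname flatten_params
#' @param n_inputs,n_hidden,activations network shape for the layout.
#' @export
param_layout <- function(n_inputs, n_hidden,
                         activations = c("identity", "logistic", "logistic")) {
  list(n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
       activations = activations,
       length = as.integer(n_inputs + n_hidden * n_inputs + 2L * n_hidden + 1L))
}

#' @rdname flatten_params
#' @param vector flat numeric vector of length `layout$length`.
#' @param layout a [param_layout()] (taken from the vector's attribute when
#'   omitted).
#' @export
unflatten_params <- function(vector, layout = attr(vector, "layout")) {
  if (is.null(layout)) stop("no layout supplied", call. = FALSE)
  n <- layout$n_inputs; k <- layout$n_hidden
  if (length(vector) != layout$length) {
    stop(sprintf("expected a vector of length %d, got %d",
                 layout$length, length(vector)), call. = FALSE)
  }
  pos <- 0L
  take <- function(m) {
    out <- vector[(pos + 1L):(pos + m)]
    pos <<- pos + m
    out
  }
  cascade_params(n_inputs = n, n_hidden = k,
                 direct_weights = take(n),
                 hidden_weights = matrix(take(k * n), k, n),
                 output_weights = take(k),
                 hidden_biases = take(k),
                 output_bias = take(1L),
                 activations = layout$activations)
}
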