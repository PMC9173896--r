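# Independent brute-force oracles, written as plain loops so they share no
# code path with the vectorized implementations they check.

# Bilateral filter on a single channel, quadruple loop, replicate padding.
oracle_bilateral <- function(x, sigma_s, sigma_r, radius) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in 1:h) {
    for (j in 1:w) {
      num <- 0; den <- 0
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          qi <- min(h, max(1, i + di))
          qj <- min(w, max(1, j + dj))
          ws <- exp(-(di^2 + dj^2) / (2 * sigma_s^2))
          wr <- exp(-(x[qi, qj] - x[i, j])^2 / (2 * sigma_r^2))
          num <- num + ws * wr * x[qi, qj]
          den <- den + ws * wr
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# Fuzzy objective, double loop over points and clusters.
oracle_fkm_objective <- function(b, x, centroids, f) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(centroids))) {
      g <- sum((x[i, ] - centroids[j, ])^2)
      total <- total + b[i, j]^f * g
    }
  }
  total
}

# Valid convolution, quadruple loop.
oracle_conv2d <- function(x, k, stride = 1) {
  kh <- nrow(k); kw <- ncol(k)
  oi <- seq(1, nrow(x) - kh + 1, by = stride)
  oj <- seq(1, ncol(x) - kw + 1, by = stride)
  out <- matrix(0, length(oi), length(oj))
  for (a in seq_along(oi)) {
    for (b in seq_along(oj)) {
      acc <- 0
      for (u in 1:kh) {
        for (v in 1:kw) {
          acc <- acc + x[oi[a] + u - 1, oj[b] + v - 1] * k[u, v]
        }
      }
      out[a, b] <- acc
    }
  }
  out
}

# Non-overlapping max pool with -Inf padding, loop form.
oracle_max_pool <- function(x, p) {
  ph <- ceiling(nrow(x) / p); pw <- ceiling(ncol(x) / p)
  out <- matrix(-Inf, ph, pw)
  for (a in 1:ph) {
    for (b in 1:pw) {
      for (u in 1:p) {
        for (v in 1:p) {
          i <- (a - 1) * p + u; j <- (b - 1) * p + v
          if (i <= nrow(x) && j <= ncol(x) && x[i, j] > out[a, b]) {
            out[a, b] <- x[i, j]
          }
        }
      }
    }
  }
  out
}

# Plain one-hidden-layer MLP forward (no direct connections), loop form.
oracle_mlp_forward <- function(x, Wh, bh, wo, bo, act_h, act_o) {
  k <- nrow(Wh)
  h <- numeric(k)
  for (j in 1:k) {
    s <- bh[j]
    for (i in seq_along(x)) s <- s + Wh[j, i] * x[i]
    h[j] <- act_h(s)
  }
  s <- bo
  for (j in 1:k) s <- s + wo[j] * h[j]
  act_o(s)
}

# MRFO step equations, straight from their formulas.
oracle_chain <- function(x, pred, best, r, r1, lower, upper) {
  alpha <- 2 * r * sqrt(abs(log(r1)))
  pmin(upper, pmax(lower, x + r * (pred - x) + alpha * (best - x)))
}
oracle_cyclone <- function(x, pred, ref, r, r1, t, t_max, lower, upper, first) {
  beta <- 2 * exp(r1 * (t_max - t + 1) / t_max) * sin(2 * pi * r1)
  moved <- if (first) ref + r * (ref - x) + beta * (ref - x)
           else ref + r * (pred - x) + beta * (ref - x)
  pmin(upper, pmax(lower, moved))
}
oracle_somersault <- function(x, best, S, r2, r3, lower, upper) {
  pmin(upper, pmax(lower, x + S * (r2 * best - r3 * x)))
}

# Per-definition confusion/metric oracle on prediction vectors.
oracle_metrics <- function(truth, pred) {
  tp <- sum(truth == "melanoma" & pred == "melanoma")
  fn <- sum(truth == "melanoma" & pred == "benign")
  fp <- sum(truth == "benign" & pred == "melanoma")
  tn <- sum(truth == "benign" & pred == "benign")
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  mel <- prf(tp, fp, fn)
  ben <- prf(tn, fn, fp)
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       accuracy = 100 * (tp + tn) / length(truth),
       melanoma = 100 * mel, benign = 100 * ben,
       macro = 100 * (mel + ben) / 2)
}

random_rgb <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

tiny_synth <- function(n = 4, seed = 1, size = 32) {
  generate_dataset(synth_config(n_per_class = n, image_size = c(size, size),
                                seed = seed))
}
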