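# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  Keeps every exported operation free
# of global random-state side effects.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is outside its allowed range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

check_rgb_image <- function(image, name = "image") {
  if (!is_rgb_image(image)) {
    stop(sprintf("`%s` must be an H x W x 3 numeric array", name), call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(image)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Rec. 601 luma of an RGB triple (or matrix of triples in columns R,G,B).
luminance <- function(rgb) {
  rgb <- matrix(rgb, ncol = 3L)
  drop(rgb %*% c(0.299, 0.587, 0.114))
}

# Nearest-neighbour resize of an H x W matrix or H x W x C array.
resize_nearest <- function(img, out_h, out_w) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  ri <- pmin(h, pmax(1L, ceiling((seq_len(out_h) - 0.5) * h / out_h)))
  ci <- pmin(w, pmax(1L, ceiling((seq_len(out_w) - 0.5) * w / out_w)))
  if (length(d) == 2L) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
}

# Round half-up to `digits` decimals (report-time convention; R's round()
# uses round-half-even which would turn 96.075 into 96.07).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# Flatten an H x W x 3 image to an (H*W) x 3 matrix of pixel rows.
pixels_of <- function(image) {
  matrix(image, ncol = 3L)
}
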