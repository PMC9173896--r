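#' Bilateral filter parameters
#'
#' The bilateral filter averages each pixel's neighbourhood with weights
#' that are the product of a spatial Gaussian (scale `sigma_spatial`, in
#' pixels) and a range Gaussian on intensity differences (scale
#' `sigma_range`, in intensity units), so smoothing stops at strong edges.
#'
#' @param sigma_spatial spatial Gaussian scale in pixels (> 0).
#' @param sigma_range range (intensity) Gaussian scale (> 0); intensities
#'   are in `[0, 1]`, so 0.1 preserves edges of height ~0.3 and above.
#' @param radius neighbourhood half-width in pixels (>= 1); defaults to
#'   `ceiling(3 * sigma_spatial)`, which captures over 99% of the spatial
#'   kernel mass.
#' @return an object of class `bilateral_params`.
#' @export
bilateral_params <- function(sigma_spatial = 2, sigma_range = 0.1,
                             radius = NULL) {
  check_scalar_number(sigma_spatial, "sigma_spatial", lower = 0, strict_lower = TRUE)
  check_scalar_number(sigma_range, "sigma_range", lower = 0, strict_lower = TRUE)
  if (is.null(radius)) radius <- ceiling(3 * sigma_spatial)
  check_scalar_number(radius, "radius", lower = 1)
  structure(list(sigma_spatial = sigma_spatial, sigma_range = sigma_range,
                 radius = as.integer(radius)),
            class = "bilateral_params")
}

# Filter one channel (matrix).  Replicate padding; weights
# w = exp(-d^2 / (2 s_s^2)) * exp(-(F(q)-F(p))^2 / (2 s_r^2)).
.bilateral_channel <- function(x, sigma_spatial, sigma_range, radius) {
  h <- nrow(x); w <- ncol(x); r <- radius
  pad <- matrix(0, h + 2 * r, w + 2 * r)
  ri <- pmin(h, pmax(1L, seq_len(h + 2 * r) - r))
  ci <- pmin(w, pmax(1L, seq_len(w + 2 * r) - r))
  pad <- x[ri, ci, drop = FALSE]
  num <- matrix(0, h, w)
  den <- matrix(0, h, w)
  inv2ss <- 1 / (2 * sigma_spatial^2)
  inv2sr <- 1 / (2 * sigma_range^2)
  for (dy in -r:r) {
    for (dx in -r:r) {
      ws <- exp(-(dy * dy + dx * dx) * inv2ss)
      q <- pad[(1 + r + dy):(h + r + dy), (1 + r + dx):(w + r + dx), drop = FALSE]
      wgt <- ws * exp(-(q - x)^2 * inv2sr)
      num <- num + wgt * q
      den <- den + wgt
    }
  }
  num / den
}

#' Edge-preserving bilateral filtering of an RGB image
#'
#' Applies the bilateral filter independently to each channel: the output at
#' pixel `p` is `(1/N) * sum_q w_s(p,q) w_r(F(q),F(p)) F(q)` over the square
#' neighbourhood of half-width `radius`, with `w_s = exp(-||q-p||^2 /
#' (2 sigma_spatial^2))`, `w_r = exp(-(F(q)-F(p))^2 / (2 sigma_range^2))`
#' and `N` the sum of the weights.  Every output pixel is therefore a convex
#' combination of its neighbourhood and stays within the neighbourhood's
#' intensity range.  Borders use replicate padding.
#'
#' @param image `H x W x 3` array (values in `[0, 1]`), or an `H x W`
#'   matrix for single-channel use.
#' @param params a [bilateral_params()].
#' @return filtered image of the same shape.
#' @examples
#' img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
#' out <- bilateral_filter(img, bilateral_params(sigma_spatial = 1.5))
#' @export
bilateral_filter <- function(image, params = bilateral_params()) {
  stopifnot(inherits(params, "bilateral_params"))
  if (is.matrix(image)) {
    if (!all(is.finite(image))) stop("`image` contains non-finite values", call. = FALSE)
    return(.bilateral_channel(image, params$sigma_spatial, params$sigma_range,
                              params$radius))
  }
  check_rgb_image(image)
  out <- image
  for (c in 1:3) {
    out[, , c] <- .bilateral_channel(image[, , c], params$sigma_spatial,
                                     params$sigma_range, params$radius)
  }
  out
}
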