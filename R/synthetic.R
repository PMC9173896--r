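#' Configuration for the synthetic lesion-image generator
#'
#' Describes a two-class set of dermoscopic-style images: an elliptical
#' lesion with a radially perturbed border sits on a skin-toned background
#' with smooth texture, and the melanoma class receives stronger asymmetry,
#' border irregularity and colour variance according to `melanoma_effect`.
#'
#' @param n_per_class number of images generated per class (>= 0).
#' @param image_size integer `c(height, width)`, both >= 16.
#' @param lesion_area_range numeric `c(min, max)` fraction of the image area
#'   covered by the lesion, both in (0, 1) with `min < max`.
#' @param melanoma_effect list with elements `asymmetry` (>= 0, scales the
#'   off-centre bulge of the border), `border_irregularity` (>= 0, relative
#'   amplitude of low-order sinusoidal border perturbations) and
#'   `color_variance` (>= 1, multiplier on the within-lesion colour noise
#'   standard deviation).  Benign images use the baseline values 0.3, 0.05
#'   and 1 in the same slots.
#' @param noise list with `gaussian_sigma` (>= 0, intensity units) and
#'   `salt_pepper_fraction` (in `[0, 1]`) passed to [add_noise()].
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#'
#' @return an object of class `synth_config`.
#' @seealso [generate_dataset()]
#' @export
synth_config <- function(n_per_class = 50L,
                         image_size = c(64L, 64L),
                         lesion_area_range = c(0.08, 0.25),
                         melanoma_effect = list(asymmetry = 2,
                                                border_irregularity = 0.3,
                                                color_variance = 2),
                         noise = list(gaussian_sigma = 0.02,
                                      salt_pepper_fraction = 0.005),
                         seed = 1L) {
  check_scalar_number(n_per_class, "n_per_class", lower = 0)
  if (length(image_size) != 2L || any(image_size < 16)) {
    stop("`image_size` must be c(height, width) with both >= 16", call. = FALSE)
  }
  if (length(lesion_area_range) != 2L ||
      any(!is.finite(lesion_area_range)) ||
      lesion_area_range[1] <= 0 || lesion_area_range[2] >= 1 ||
      lesion_area_range[1] >= lesion_area_range[2]) {
    stop("`lesion_area_range` must satisfy 0 < min < max < 1", call. = FALSE)
  }
  check_scalar_number(melanoma_effect$asymmetry, "melanoma_effect$asymmetry", lower = 0)
  check_scalar_number(melanoma_effect$border_irregularity,
                      "melanoma_effect$border_irregularity", lower = 0)
  check_scalar_number(melanoma_effect$color_variance,
                      "melanoma_effect$color_variance", lower = 1)
  check_scalar_number(noise$gaussian_sigma, "noise$gaussian_sigma", lower = 0)
  check_scalar_number(noise$salt_pepper_fraction, "noise$salt_pepper_fraction",
                      lower = 0, upper = 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 lesion_area_range = as.numeric(lesion_area_range),
                 melanoma_effect = melanoma_effect,
                 noise = noise,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Baseline (benign) lesion shape/colour settings; melanoma knobs multiply or
# replace these.
.benign_effect <- list(asymmetry = 0.3, border_irregularity = 0.05,
                       color_variance = 1)
.lesion_color_sd <- 0.05   # within-lesion per-pixel colour sd, benign
.skin_base <- c(0.85, 0.62, 0.52)
.lesion_base <- c(0.38, 0.24, 0.17)

# Draw one lesion image.  All randomness comes from the caller's RNG state.
.generate_one <- function(height, width, area_range, effect, noise) {
  # --- background: skin tone + smooth low-amplitude texture -------------
  tone <- .skin_base + stats::runif(3, -0.03, 0.03)
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  tex <- matrix(0, height, width)
  for (j in 1:3) {
    fy <- stats::runif(1, 0.5, 2) * 2 * pi / height
    fx <- stats::runif(1, 0.5, 2) * 2 * pi / width
    ph <- stats::runif(2, 0, 2 * pi)
    tex <- tex + stats::runif(1, 0.005, 0.015) *
      sin(fy * yy + ph[1]) * sin(fx * xx + ph[2])
  }
  img <- array(0, dim = c(height, width, 3L))
  for (c in 1:3) img[, , c] <- tone[c] + tex

  # --- lesion geometry: perturbed ellipse -------------------------------
  frac <- stats::runif(1, area_range[1] + 0.1 * diff(area_range),
                       area_range[2] - 0.1 * diff(area_range))
  target_area <- frac * height * width
  ratio <- stats::runif(1, 0.6, 0.95)          # minor/major axis ratio
  theta0 <- stats::runif(1, 0, 2 * pi)          # orientation
  cy <- height / 2 + stats::runif(1, -0.05, 0.05) * height
  cx <- width / 2 + stats::runif(1, -0.05, 0.05) * width

  dy <- (yy - cy)
  dx <- (xx - cx)
  # rotate into lesion frame
  u <- cos(theta0) * dx + sin(theta0) * dy
  v <- -sin(theta0) * dx + cos(theta0) * dy
  ang <- atan2(v / ratio, u)                    # elliptical angle
  rad_e <- sqrt(u^2 + (v / ratio)^2)            # elliptical radius

  # border perturbation: low-order sinusoids (irregularity) plus a
  # first-harmonic bulge (asymmetry)
  m_orders <- 3:6
  amp <- effect$border_irregularity * stats::runif(length(m_orders), 0.5, 1) /
    seq_along(m_orders)
  phs <- stats::runif(length(m_orders), 0, 2 * pi)
  asym_amp <- 0.08 * effect$asymmetry
  asym_ph <- stats::runif(1, 0, 2 * pi)
  pert <- function(a) {
    s <- asym_amp * cos(a - asym_ph)
    for (k in seq_along(m_orders)) s <- s + amp[k] * sin(m_orders[k] * a + phs[k])
    s
  }
  # area of r0^2*(1+p(theta))^2/2 integrated over theta; normalise r0 so the
  # realised area matches target_area regardless of the perturbation energy
  grid <- seq(0, 2 * pi, length.out = 721L)[-721L]
  mean_sq <- mean((1 + pert(grid))^2)
  r0 <- sqrt(target_area / (pi * ratio * mean_sq))

  boundary <- r0 * (1 + pert(ang))
  boundary <- pmax(boundary, 1e-6)
  inside <- rad_e <= boundary
  # soft blend over ~1.5 px so the bilateral filter sees a realistic edge
  alpha <- clamp01((boundary - rad_e) / 1.5 + 0.5)

  # --- lesion colouring --------------------------------------------------
  lesion_tone <- .lesion_base + stats::runif(3, -0.04, 0.04)
  depth <- clamp01(1 - rad_e / boundary)        # darker towards the centre
  col_sd <- .lesion_color_sd * effect$color_variance
  n_px <- height * width
  for (c in 1:3) {
    lesion_col <- lesion_tone[c] - 0.08 * depth +
      matrix(stats::rnorm(n_px, 0, col_sd), height, width)
    img[, , c] <- alpha * lesion_col + (1 - alpha) * img[, , c]
  }
  img <- clamp01(img)
  list(image = img, mask = matrix(as.integer(inside), height, width))
}

#' Generate a labelled synthetic two-class lesion dataset
#'
#' Produces `2 * n_per_class` images: `n_per_class` melanoma-like and
#' `n_per_class` benign-like, each with a ground-truth lesion mask.  Lesions
#' are darker than the skin background; melanoma images get stronger
#' asymmetry, border irregularity and within-lesion colour variance, as set
#' by `config$melanoma_effect`.  Gaussian and salt-and-pepper noise are
#' applied last via [add_noise()].
#'
#' @param config a [synth_config()].
#' @return a list of labelled images, each a list with elements `image`
#'   (`H x W x 3` array in `[0,1]`), `label` (`"melanoma"` or `"benign"`),
#'   `truth_mask` (`H x W` 0/1 matrix) and `id` (character).
#' @examples
#' ds <- generate_dataset(synth_config(n_per_class = 2, seed = 7))
#' sapply(ds, `[[`, "label")
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  h <- config$image_size[1]
  w <- config$image_size[2]
  n <- config$n_per_class
  if (n == 0L) return(list())
  labels <- rep(c("melanoma", "benign"), each = n)
  with_seed(config$seed, {
    lapply(seq_along(labels), function(i) {
      lab <- labels[i]
      eff <- if (lab == "melanoma") config$melanoma_effect else .benign_effect
      gen <- .generate_one(h, w, config$lesion_area_range, eff, config$noise)
      noise_seed <- (config$seed + 7919L * i) %% .Machine$integer.max
      img <- add_noise(gen$image, config$noise$gaussian_sigma,
                       config$noise$salt_pepper_fraction, seed = noise_seed)
      list(image = img, label = lab, truth_mask = gen$mask,
           id = sprintf("%s_%03d", lab, ((i - 1L) %% n) + 1L))
    })
  })
}

#' Add Gaussian and salt-and-pepper noise to an RGB image
#'
#' Exactly `round(salt_pepper_fraction * H * W)` pixel sites are replaced by
#' pure black or pure white (all three channels); every remaining pixel is
#' perturbed by zero-mean Gaussian noise with standard deviation
#' `gaussian_sigma` per channel.  The result is clipped to `[0, 1]`.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param gaussian_sigma Gaussian noise sd (>= 0, intensity units).
#' @param salt_pepper_fraction fraction of pixels replaced, in `[0, 1]`.
#' @param seed integer seed for the noise draw.
#' @return the noisy image, same shape, clipped to `[0, 1]`.
#' @export
add_noise <- function(image, gaussian_sigma, salt_pepper_fraction, seed = 1L) {
  check_rgb_image(image)
  check_scalar_number(gaussian_sigma, "gaussian_sigma", lower = 0)
  check_scalar_number(salt_pepper_fraction, "salt_pepper_fraction",
                      lower = 0, upper = 1)
  if (gaussian_sigma == 0 && salt_pepper_fraction == 0) return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  n_px <- h * w
  n_sp <- round(salt_pepper_fraction * n_px)
  with_seed(seed, {
    out <- image
    if (gaussian_sigma > 0) {
      out <- out + array(stats::rnorm(length(out), 0, gaussian_sigma), dim = dim(out))
    }
    if (n_sp > 0) {
      sites <- sample.int(n_px, n_sp)
      vals <- sample(c(0, 1), n_sp, replace = TRUE)
      for (c in 1:3) {
        plane <- out[, , c]
        plane[sites] <- vals
        out[, , c] <- plane
      }
    }
    clamp01(out)
  })
}

#' Write a generated dataset to disk
#'
#' Images are written as 8-bit RGB PNG, masks as single-channel 0/255 PNG,
#' plus a manifest CSV with columns `filename`, `label`, `mask_filename`.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the manifest CSV.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(item) {
    fn <- paste0(item$id, ".png")
    mfn <- paste0(item$id, "_mask.png")
    png::writePNG(item$image, file.path(dir, fn))
    png::writePNG(item$truth_mask * 1.0, file.path(dir, mfn))
    data.frame(filename = fn, label = item$label, mask_filename = mfn,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from a manifest CSV
#'
#' Reads the manifest written by [write_dataset()] (or any CSV with columns
#' `filename`, `label` and optionally `mask_filename`); image paths are
#' resolved relative to the manifest's directory.  PNG and JPEG images are
#' supported.
#'
#' @param manifest_path path to the manifest CSV.
#' @return a list of labelled images as in [generate_dataset()]
#'   (`truth_mask` is `NULL` when no mask column or file is present).
#' @export
read_dataset <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("filename", "label") %in% names(manifest))) {
    stop("manifest must have columns `filename` and `label`", call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image(file.path(base, manifest$filename[i]))
    mask <- NULL
    if ("mask_filename" %in% names(manifest) &&
        nzchar(manifest$mask_filename[i])) {
      m <- read_image(file.path(base, manifest$mask_filename[i]))
      if (length(dim(m)) == 3L) m <- m[, , 1]
      mask <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    }
    list(image = img, label = manifest$label[i], truth_mask = mask,
         id = tools::file_path_sans_ext(manifest$filename[i]))
  })
}

#' Read a PNG or JPEG image as an RGB array in \[0, 1\]
#'
#' Greyscale inputs are replicated across the three channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path image file path (`.png`, `.jpg` or `.jpeg`).
#' @return `H x W x 3` numeric array in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the `jpeg` package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    stop(sprintf("unsupported image format `%s`", ext), call. = FALSE))
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    img <- array(rep(img[, , 1], 3L), dim = c(dim(img)[1:2], 3L))
  }
  img
}

#' Write an RGB image or mask as PNG
#'
#' @param image `H x W x 3` array in `[0,1]`, or an `H x W` matrix
#'   (masks are written as 0/255 single-channel PNG).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_image <- function(image, path) {
  png::writePNG(image * 1.0, path)
  invisible(path)
}
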