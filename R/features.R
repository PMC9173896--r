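#' Configuration of the convolutional feature extractor
#'
#' The default `compact_cnn` backend is a small from-scratch convolutional
#' network — three valid-convolution blocks (ReLU, non-overlapping max
#' pooling) followed by global average pooling, a fully connected ReLU
#' feature layer of width `feature_dim` (the extracted representation) and
#' a softmax classification head — trained end to end with mini-batch
#' stochastic gradient descent on the cross-entropy loss.  A
#' `nasnet_pretrained` backend slot exists behind the same interface for
#' users who supply their own pretrained forward function.
#'
#' @param backend `"compact_cnn"` (default) or `"nasnet_pretrained"`.
#' @param conv_blocks list of `c(n_filters, kernel_size, stride)` triples;
#'   kernel sizes must be odd, strides >= 1.
#' @param pool_size non-overlapping max-pool window (pixels).
#' @param feature_dim length of the extracted feature vector (>= 2).
#' @param input_size images are mask-zeroed and resized to
#'   `input_size x input_size` before the forward pass.
#' @param sgd list with `learning_rate` (> 0), `epochs` (>= 1) and
#'   `batch_size` (>= 1).
#' @param seed integer seed for weight initialization and batch shuffling.
#' @return an object of class `extractor_config`.
#' @export
extractor_config <- function(backend = c("compact_cnn", "nasnet_pretrained"),
                             conv_blocks = list(c(8L, 3L, 1L),
                                                c(16L, 3L, 1L),
                                                c(32L, 3L, 1L)),
                             pool_size = 2L,
                             feature_dim = 32L,
                             input_size = 64L,
                             sgd = list(learning_rate = 0.05, epochs = 30L,
                                        batch_size = 8L),
                             seed = 1L) {
  backend <- match.arg(backend)
  for (blk in conv_blocks) {
    if (length(blk) != 3L) stop("each conv block must be c(n_filters, kernel_size, stride)", call. = FALSE)
    if (blk[2] %% 2 != 1 || blk[2] < 1) stop("kernel sizes must be odd and >= 1", call. = FALSE)
    if (blk[3] < 1) stop("strides must be >= 1", call. = FALSE)
  }
  check_scalar_number(pool_size, "pool_size", lower = 1)
  check_scalar_number(feature_dim, "feature_dim", lower = 2)
  check_scalar_number(input_size, "input_size", lower = 8)
  check_scalar_number(sgd$learning_rate, "sgd$learning_rate", lower = 0)
  check_scalar_number(sgd$epochs, "sgd$epochs", lower = 1)
  check_scalar_number(sgd$batch_size, "sgd$batch_size", lower = 1)
  structure(list(backend = backend, conv_blocks = conv_blocks,
                 pool_size = as.integer(pool_size),
                 feature_dim = as.integer(feature_dim),
                 input_size = as.integer(input_size),
                 sgd = sgd, seed = as.integer(seed)),
            class = "extractor_config")
}

#' Valid 2-D convolution (sliding-window dot product)
#'
#' Computes the sliding-window dot product of `kernel` over `input` on the
#' valid region only (no padding), sampling windows every `stride` pixels.
#' This is cross-correlation in the CNN convention (the kernel is not
#' flipped).
#'
#' @param input 2-D numeric matrix.
#' @param kernel 2-D numeric matrix, no larger than `input`.
#' @param stride sampling step (>= 1).
#' @return the `floor((H-kh)/stride)+1` by `floor((W-kw)/stride)+1` output.
#' @export
conv2d_valid <- function(input, kernel, stride = 1L) {
  input <- as.matrix(input); kernel <- as.matrix(kernel)
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh > nrow(input) || kw > ncol(input)) {
    stop("kernel larger than input", call. = FALSE)
  }
  check_scalar_number(stride, "stride", lower = 1)
  oh <- nrow(input) - kh + 1L
  ow <- ncol(input) - kw + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      out <- out + kernel[i, j] *
        input[i:(i + oh - 1L), j:(j + ow - 1L), drop = FALSE]
    }
  }
  if (stride > 1) {
    out <- out[seq(1L, oh, by = stride), seq(1L, ow, by = stride), drop = FALSE]
  }
  out
}

#' Non-overlapping max pooling
#'
#' Partitions the input into `pool_size x pool_size` windows (padding with
#' `-Inf` when the dimensions do not divide evenly) and returns each
#' window's maximum.
#'
#' @param input 2-D numeric matrix.
#' @param pool_size window side length (>= 1).
#' @return the pooled `ceiling(H/p) x ceiling(W/p)` matrix.
#' @export
max_pool <- function(input, pool_size) {
  check_scalar_number(pool_size, "pool_size", lower = 1)
  .pool_forward(as.matrix(input), as.integer(pool_size))$out
}

# ---- internal CNN machinery -------------------------------------------

relu <- function(x) pmax(x, 0)

# Max pool with argmax bookkeeping for backprop.  First-encountered maximum
# wins ties (deterministic).
.pool_forward <- function(a, p) {
  if (p == 1L) {
    return(list(out = a, argr = row(a), argc = col(a), h = nrow(a), w = ncol(a)))
  }
  h <- nrow(a); w <- ncol(a)
  ph <- ceiling(h / p); pw <- ceiling(w / p)
  H <- ph * p; W <- pw * p
  pad <- matrix(-Inf, H, W)
  pad[seq_len(h), seq_len(w)] <- a
  best <- matrix(-Inf, ph, pw)
  argr <- matrix(1L, ph, pw); argc <- matrix(1L, ph, pw)
  for (r in seq_len(p)) {
    rows <- seq(r, H, by = p)
    rmat <- matrix(rows, ph, pw)
    for (s in seq_len(p)) {
      cols <- seq(s, W, by = p)
      v <- pad[rows, cols, drop = FALSE]
      upd <- v > best
      best[upd] <- v[upd]
      argr[upd] <- rmat[upd]
      argc[upd] <- matrix(cols, ph, pw, byrow = TRUE)[upd]
    }
  }
  list(out = best, argr = argr, argc = argc, h = h, w = w)
}

.pool_backward <- function(dout, cache) {
  dx <- matrix(0, cache$h, cache$w)
  keep <- cache$argr <= cache$h & cache$argc <= cache$w
  dx[cbind(as.vector(cache$argr[keep]), as.vector(cache$argc[keep]))] <-
    as.vector(dout[keep])
  dx
}

# im2col: channels is a list of C matrices (h x w).  Column order is
# channel-major, then kernel column, then kernel row — matching the
# column-major flattening of a (kh, kw, C, F) weight array, so the conv is
# a single matrix product Xcol %*% matrix(W, kh*kw*C, F).
.im2col <- function(channels, kh, kw, stride) {
  h <- nrow(channels[[1]]); w <- ncol(channels[[1]])
  oh <- (h - kh) %/% stride + 1L
  ow <- (w - kw) %/% stride + 1L
  cols <- vector("list", length(channels) * kw * kh)
  idx <- 0L
  for (cc in seq_along(channels)) {
    x <- channels[[cc]]
    for (j in seq_len(kw)) {
      jc <- seq(j, by = stride, length.out = ow)
      for (i in seq_len(kh)) {
        idx <- idx + 1L
        ir <- seq(i, by = stride, length.out = oh)
        cols[[idx]] <- as.vector(x[ir, jc, drop = FALSE])
      }
    }
  }
  list(X = do.call(cbind, cols), oh = oh, ow = ow)
}

.col2im <- function(dXcol, h, w, C, kh, kw, stride, oh, ow) {
  dx <- lapply(seq_len(C), function(i) matrix(0, h, w))
  idx <- 0L
  for (cc in seq_len(C)) {
    for (j in seq_len(kw)) {
      jc <- seq(j, by = stride, length.out = ow)
      for (i in seq_len(kh)) {
        idx <- idx + 1L
        ir <- seq(i, by = stride, length.out = oh)
        dx[[cc]][ir, jc] <- dx[[cc]][ir, jc] + matrix(dXcol[, idx], oh, ow)
      }
    }
  }
  dx
}

.init_extractor_params <- function(config) {
  blocks <- list()
  c_in <- 3L
  for (b in seq_along(config$conv_blocks)) {
    blk <- config$conv_blocks[[b]]
    f <- blk[1]; k <- blk[2]
    sd <- sqrt(2 / (k * k * c_in))
    blocks[[b]] <- list(
      W = array(stats::rnorm(k * k * c_in * f, 0, sd), dim = c(k, k, c_in, f)),
      b = numeric(f), kernel = k, stride = blk[3])
    c_in <- f
  }
  list(blocks = blocks,
       Wf = matrix(stats::rnorm(config$feature_dim * c_in, 0,
                                sqrt(2 / c_in)), config$feature_dim, c_in),
       bf = numeric(config$feature_dim),
       Wo = matrix(stats::rnorm(2 * config$feature_dim, 0,
                                sqrt(2 / config$feature_dim)),
                   2L, config$feature_dim),
       bo = numeric(2L))
}

# Forward pass on a preprocessed tensor (list of 3 input_size^2 matrices).
# Returns features, class probabilities and (optionally) caches for backprop.
.extractor_forward <- function(params, channels, pool_size, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(params$blocks)) else NULL
  x <- channels
  for (b in seq_along(params$blocks)) {
    blk <- params$blocks[[b]]
    k <- blk$kernel
    ic <- .im2col(x, k, k, blk$stride)
    f_out <- dim(blk$W)[4]
    Wmat <- matrix(blk$W, ncol = f_out)
    S <- ic$X %*% Wmat
    S <- sweep(S, 2L, blk$b, "+")
    A <- relu(S)
    pooled <- vector("list", f_out)
    pcaches <- if (keep_cache) vector("list", f_out) else NULL
    for (f in seq_len(f_out)) {
      pf <- .pool_forward(matrix(A[, f], ic$oh, ic$ow), pool_size)
      pooled[[f]] <- pf$out
      if (keep_cache) pcaches[[f]] <- pf
    }
    if (keep_cache) {
      caches[[b]] <- list(Xcol = ic$X, S = S, oh = ic$oh, ow = ic$ow,
                          in_h = nrow(x[[1]]), in_w = ncol(x[[1]]),
                          in_c = length(x), pools = pcaches)
    }
    x <- pooled
  }
  gap <- vapply(x, mean, numeric(1))
  u <- drop(params$Wf %*% gap) + params$bf
  feat <- relu(u)
  logits <- drop(params$Wo %*% feat) + params$bo
  m <- max(logits)
  e <- exp(logits - m)
  probs <- e / sum(e)
  list(features = feat, probs = probs, gap = gap, u = u,
       final_maps = x, caches = caches)
}

# Backward pass for one sample; returns gradient list mirroring params.
.extractor_backward <- function(params, fwd, y_index, pool_size) {
  dlogits <- fwd$probs
  dlogits[y_index] <- dlogits[y_index] - 1
  g <- list()
  g$Wo <- outer(dlogits, fwd$features)
  g$bo <- dlogits
  dfeat <- drop(t(params$Wo) %*% dlogits)
  du <- dfeat * (fwd$u > 0)
  g$Wf <- outer(du, fwd$gap)
  g$bf <- du
  dgap <- drop(t(params$Wf) %*% du)
  # gradient w.r.t. the final pooled maps (mean over each map)
  dmaps <- lapply(seq_along(fwd$final_maps), function(f) {
    m <- fwd$final_maps[[f]]
    matrix(dgap[f] / length(m), nrow(m), ncol(m))
  })
  g$blocks <- vector("list", length(params$blocks))
  for (b in rev(seq_along(params$blocks))) {
    blk <- params$blocks[[b]]
    cache <- fwd$caches[[b]]
    f_out <- dim(blk$W)[4]
    dS <- matrix(0, nrow(cache$S), f_out)
    for (f in seq_len(f_out)) {
      dA <- .pool_backward(dmaps[[f]], cache$pools[[f]])
      dS[, f] <- as.vector(dA) * (cache$S[, f] > 0)
    }
    k <- blk$kernel
    dWmat <- crossprod(cache$Xcol, dS)
    g$blocks[[b]] <- list(W = array(dWmat, dim = dim(blk$W)), b = colSums(dS))
    if (b > 1L) {
      Wmat <- matrix(blk$W, ncol = f_out)
      dXcol <- tcrossprod(dS, Wmat)
      dmaps <- .col2im(dXcol, cache$in_h, cache$in_w, cache$in_c,
                       k, k, blk$stride, cache$oh, cache$ow)
    }
  }
  g
}

.zero_like <- function(params) {
  list(blocks = lapply(params$blocks, function(b)
         list(W = array(0, dim = dim(b$W)), b = numeric(length(b$b)))),
       Wf = params$Wf * 0, bf = params$bf * 0,
       Wo = params$Wo * 0, bo = params$bo * 0)
}

.axpy_params <- function(acc, g, a = 1) {
  for (b in seq_along(acc$blocks)) {
    acc$blocks[[b]]$W <- acc$blocks[[b]]$W + a * g$blocks[[b]]$W
    acc$blocks[[b]]$b <- acc$blocks[[b]]$b + a * g$blocks[[b]]$b
  }
  acc$Wf <- acc$Wf + a * g$Wf; acc$bf <- acc$bf + a * g$bf
  acc$Wo <- acc$Wo + a * g$Wo; acc$bo <- acc$bo + a * g$bo
  acc
}

.sgd_apply <- function(params, grads, lr) {
  for (b in seq_along(params$blocks)) {
    params$blocks[[b]]$W <- params$blocks[[b]]$W - lr * grads$blocks[[b]]$W
    params$blocks[[b]]$b <- params$blocks[[b]]$b - lr * grads$blocks[[b]]$b
  }
  params$Wf <- params$Wf - lr * grads$Wf; params$bf <- params$bf - lr * grads$bf
  params$Wo <- params$Wo - lr * grads$Wo; params$bo <- params$bo - lr * grads$bo
  params
}

# Mask-zero, resize and standardize an image, returning a list of 3 channel
# matrices.  Per-image standardization (zero mean, unit variance over the
# whole tensor) keeps activations on the scale the He initialization
# assumes; without it the masked inputs are mostly zeros and gradients
# vanish.
.prep_input <- function(image, mask, input_size) {
  check_rgb_image(image)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(image)[1:2]))
    image <- image * array(rep(as.numeric(mask != 0), 3L), dim = dim(image))
  }
  r <- resize_nearest(image, input_size, input_size)
  s <- stats::sd(r)
  r <- (r - mean(r)) / (if (is.finite(s) && s > 1e-8) s else 1)
  lapply(1:3, function(c) r[, , c])
}

#' Train the compact CNN feature extractor
#'
#' Trains the convolutional stack and heads with mini-batch SGD on the
#' softmax cross-entropy of the two class labels.  Images are background-
#' zeroed with their lesion masks and resized to the configured input size.
#' The extractor's representation is the penultimate (fully connected ReLU)
#' activation of width `feature_dim`.
#'
#' @param dataset list of labelled images as produced by
#'   [generate_dataset()] (elements need `image` and `label`).
#' @param masks optional list of `H x W` 0/1 masks, one per image; defaults
#'   to each element's `truth_mask` (use the segmentation module's masks in
#'   the full pipeline).
#' @param config an [extractor_config()].
#' @return an object of class `derm_extractor` with elements `params`,
#'   `config`, `classes` and `loss_history` (running mean cross-entropy
#'   over each epoch's mini-batches).
#' @export
train_extractor <- function(dataset, masks = NULL, config = extractor_config()) {
  stopifnot(inherits(config, "extractor_config"))
  if (config$backend != "compact_cnn") {
    stop("only the compact_cnn backend supports training; supply a forward function for pretrained backends", call. = FALSE)
  }
  labels <- vapply(dataset, `[[`, character(1), "label")
  classes <- c("melanoma", "benign")
  if (length(unique(labels)) < 2L) {
    stop("training requires both classes to be present", call. = FALSE)
  }
  if (!all(labels %in% classes)) {
    stop("labels must be 'melanoma' or 'benign'", call. = FALSE)
  }
  y <- match(labels, classes)
  if (is.null(masks)) masks <- lapply(dataset, `[[`, "truth_mask")
  inputs <- lapply(seq_along(dataset), function(i)
    .prep_input(dataset[[i]]$image, masks[[i]], config$input_size))
  n <- length(inputs)
  lr <- config$sgd$learning_rate
  bs <- min(config$sgd$batch_size, n)
  with_seed(config$seed, {
    params <- .init_extractor_params(config)
    loss_history <- numeric(0)
    for (epoch in seq_len(config$sgd$epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        batch <- ord[start:min(start + bs - 1L, n)]
        grads <- .zero_like(params)
        for (i in batch) {
          fwd <- .extractor_forward(params, inputs[[i]], config$pool_size,
                                    keep_cache = TRUE)
          epoch_loss <- epoch_loss - log(max(fwd$probs[y[i]], 1e-12))
          g <- .extractor_backward(params, fwd, y[i], config$pool_size)
          grads <- .axpy_params(grads, g, 1 / length(batch))
        }
        params <- .sgd_apply(params, grads, lr)
      }
      loss_history <- c(loss_history, epoch_loss / n)
    }
    structure(list(params = params, config = config, classes = classes,
                   loss_history = loss_history, trained = TRUE),
              class = "derm_extractor")
  })
}

#' Extract a feature vector from one image
#'
#' The image is background-zeroed with `mask`, resized to the extractor's
#' input size and passed forward; the penultimate ReLU activation is the
#' feature vector.
#'
#' @param extractor a trained [train_extractor()] object.
#' @param image `H x W x 3` array.
#' @param mask optional `H x W` 0/1 lesion mask (`NULL` keeps the full
#'   image).
#' @return numeric vector of length `feature_dim`.
#' @export
extract_features <- function(extractor, image, mask = NULL) {
  if (!inherits(extractor, "derm_extractor") || !isTRUE(extractor$trained)) {
    stop("`extractor` must be a trained derm_extractor", call. = FALSE)
  }
  channels <- .prep_input(image, mask, extractor$config$input_size)
  .extractor_forward(extractor$params, channels,
                     extractor$config$pool_size)$features
}

#' Extract features for a whole dataset
#'
#' @param extractor a trained [train_extractor()] object.
#' @param dataset list of labelled images.
#' @param masks optional list of masks (defaults to each `truth_mask`).
#' @return an `n x feature_dim` matrix with `rownames` taken from image ids.
#' @export
extract_features_dataset <- function(extractor, dataset, masks = NULL) {
  if (is.null(masks)) masks <- lapply(dataset, `[[`, "truth_mask")
  feats <- t(vapply(seq_along(dataset), function(i)
    extract_features(extractor, dataset[[i]]$image, masks[[i]]),
    numeric(extractor$config$feature_dim)))
  rownames(feats) <- vapply(dataset, function(d)
    if (is.null(d$id)) "" else d$id, character(1))
  feats
}
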