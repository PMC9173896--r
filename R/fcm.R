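#' Fuzzy k-means configuration
#'
#' @param k number of clusters (>= 2; lesion/skin separation needs two).
#' @param fuzzifier membership softness exponent `f` (> 1; the objective
#'   degenerates to hard k-means as `f -> 1`).
#' @param tol convergence threshold on the change in the objective (> 0).
#' @param max_iter maximum number of alternating updates (>= 1).
#' @param seed integer seed for the centroid initialization.
#' @return an object of class `fkm_config`.
#' @export
fkm_config <- function(k = 2L, fuzzifier = 2, tol = 1e-5, max_iter = 100L,
                       seed = 1L) {
  check_scalar_number(k, "k", lower = 2)
  check_scalar_number(fuzzifier, "fuzzifier", lower = 1, strict_lower = TRUE)
  check_scalar_number(tol, "tol", lower = 0, strict_lower = TRUE)
  check_scalar_number(max_iter, "max_iter", lower = 1)
  structure(list(k = as.integer(k), fuzzifier = fuzzifier, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "fkm_config")
}

# Squared Euclidean distances between rows of x (n x d) and rows of
# centroids (k x d); returns n x k.
.sq_dist <- function(x, centroids) {
  n <- nrow(x); k <- nrow(centroids)
  d <- matrix(rowSums(x^2), n, k) +
    matrix(rowSums(centroids^2), n, k, byrow = TRUE) -
    2 * x %*% t(centroids)
  pmax(d, 0)
}

#' Fuzzy k-means objective
#'
#' Computes `L = sum_j sum_i b_ij^f * g_ij`, where `b_ij` is the membership
#' of point `i` in cluster `j`, `f` the fuzzifier and `g_ij` the squared
#' Euclidean distance between point `i` and centroid `j`.
#'
#' @param memberships `n x k` row-stochastic membership matrix.
#' @param points `n x d` data matrix.
#' @param centroids `k x d` centroid matrix.
#' @param fuzzifier fuzzifier exponent `f` (> 1).
#' @return the scalar objective value (>= 0).
#' @export
fkm_objective <- function(memberships, points, centroids, fuzzifier) {
  points <- as.matrix(points); centroids <- as.matrix(centroids)
  memberships <- as.matrix(memberships)
  if (nrow(memberships) != nrow(points) ||
      ncol(memberships) != nrow(centroids) ||
      ncol(points) != ncol(centroids)) {
    stop("shape mismatch between memberships, points and centroids", call. = FALSE)
  }
  sum(memberships^fuzzifier * .sq_dist(points, centroids))
}

# Membership update: b_ij = 1 / sum_l (g_ij / g_il)^(1/(f-1)).  Points at
# zero distance from a centroid get a crisp one-hot membership (the limit of
# the update).
.fkm_memberships <- function(g, fuzzifier) {
  expo <- 1 / (fuzzifier - 1)
  # work on inverse powers for stability: b_ij = g_ij^-e / sum_l g_il^-e
  invp <- (1 / pmax(g, .Machine$double.xmin))^expo
  b <- invp / rowSums(invp)
  zero_rows <- which(apply(g, 1L, min) == 0)
  if (length(zero_rows)) {
    b[zero_rows, ] <- 0
    first_zero <- apply(g[zero_rows, , drop = FALSE], 1L, function(r) which(r == 0)[1])
    b[cbind(zero_rows, first_zero)] <- 1
  }
  b
}

# Seeded farthest-point initialization: first centroid drawn uniformly, the
# rest greedily maximize the minimum distance to those already chosen.
.fkm_init <- function(points, k, seed) {
  n <- nrow(points)
  with_seed(seed, {
    idx <- integer(k)
    idx[1] <- sample.int(n, 1L)
    mind <- .sq_dist(points, points[idx[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      idx[j] <- which.max(mind)
      mind <- pmin(mind, .sq_dist(points, points[idx[j], , drop = FALSE])[, 1])
    }
    points[idx, , drop = FALSE]
  })
}

#' Fit fuzzy k-means by alternating minimization
#'
#' Alternates the exact per-block minimizers of the fuzzy objective:
#' membership update `b_ij = 1 / sum_l (g_ij/g_il)^(1/(f-1))` followed by
#' centroid update `C_j = sum_i b_ij^f x_i / sum_i b_ij^f`, until the
#' objective changes by less than `tol` or `max_iter` iterations elapse.
#' Initialization is seeded farthest-point sampling of `k` data points, so
#' runs are reproducible and centroids start distinct.
#'
#' @param points `n x d` numeric matrix (rows are observations); at least
#'   `k` distinct rows are required.
#' @param config an [fkm_config()].
#' @return an object of class `fkm_result`: list with `memberships`
#'   (`n x k`, rows sum to 1), `centroids` (`k x d`), `objective_trace`
#'   (non-increasing, one value per iteration) and `iterations`.
#' @export
fkm_fit <- function(points, config = fkm_config()) {
  stopifnot(inherits(config, "fkm_config"))
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("`points` contains non-finite values", call. = FALSE)
  k <- config$k
  if (nrow(unique(points)) < k) {
    stop(sprintf("need at least k = %d distinct points", k), call. = FALSE)
  }
  f <- config$fuzzifier
  centroids <- .fkm_init(points, k, config$seed)
  trace <- numeric(0)
  b <- NULL
  prev <- Inf
  for (it in seq_len(config$max_iter)) {
    g <- .sq_dist(points, centroids)
    b <- .fkm_memberships(g, f)
    bf <- b^f
    wsum <- colSums(bf)
    centroids <- (t(bf) %*% points) / wsum
    obj <- fkm_objective(b, points, centroids, f)
    trace <- c(trace, obj)
    if (is.finite(prev) && abs(prev - obj) < config$tol) break
    prev <- obj
  }
  structure(list(memberships = b, centroids = centroids,
                 objective_trace = trace, iterations = length(trace),
                 fuzzifier = f),
            class = "fkm_result")
}

#' Pick the lesion cluster from a fitted segmentation
#'
#' Lesions are darker than the surrounding skin, so the lesion cluster is
#' the one whose centroid has the lowest luminance
#' (`0.299 R + 0.587 G + 0.114 B`).  Ties go to the lowest cluster index.
#'
#' @param result an [fkm_fit()] result whose centroids live in RGB space.
#' @param image the segmented image (unused by the default rule; part of
#'   the interface so alternative selection rules can inspect it).
#' @return the 1-based lesion cluster index.
#' @export
select_lesion_cluster <- function(result, image = NULL) {
  stopifnot(inherits(result, "fkm_result"))
  lum <- luminance(result$centroids)
  which.min(lum)   # which.min breaks ties by lowest index
}

#' Segment an image into a binary lesion mask
#'
#' Clusters the per-pixel RGB values with fuzzy k-means, selects the darkest
#' (lesion) cluster, and returns the hard mask of pixels whose maximal
#' membership lies in that cluster.
#'
#' @param image `H x W x 3` array, typically bilateral-filtered first.
#' @param config an [fkm_config()].
#' @return a list with `mask` (`H x W` 0/1 matrix), `fit` (the
#'   [fkm_fit()] result) and `lesion_cluster` (index).
#' @export
segment_image <- function(image, config = fkm_config()) {
  check_rgb_image(image)
  px <- pixels_of(image)
  fit <- fkm_fit(px, config)
  lesion <- select_lesion_cluster(fit, image)
  hard <- max.col(fit$memberships, ties.method = "first")
  mask <- matrix(as.integer(hard == lesion), dim(image)[1], dim(image)[2])
  list(mask = mask, fit = fit, lesion_cluster = lesion)
}

#' Dice overlap between two binary masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b 0/1 matrices of identical dimensions.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}
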