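test_that("the fuzzy objective matches hand values and the loop oracle", {
  # every point at its sole centroid with crisp memberships: L = 0
  x <- matrix(c(1, 2, 1, 2), 2, 2)
  expect_equal(fkm_objective(matrix(1, 1, 1), x[1, , drop = FALSE],
                             x[1, , drop = FALSE], 2), 0)

  # two points 0 and 1, one centroid at 0.5, memberships 1, f = 2
  pts <- matrix(c(0, 1), 2, 1)
  expect_equal(fkm_objective(matrix(1, 2, 1), pts, matrix(0.5, 1, 1), 2), 0.5)

  # random instance against the double-loop oracle
  set.seed(3)
  pts <- matrix(rnorm(30), 10, 3)
  cen <- matrix(rnorm(9), 3, 3)
  b <- matrix(runif(30), 10, 3)
  b <- b / rowSums(b)
  expect_lt(abs(fkm_objective(b, pts, cen, 2.3) -
                  oracle_fkm_objective(b, pts, cen, 2.3)), 1e-12)

  expect_error(fkm_objective(b, pts, cen[, 1:2], 2), "shape")
})

test_that("well-separated clouds get near-crisp memberships", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
               matrix(rnorm(40, 10, 0.3), 20, 2))
  fit <- fkm_fit(pts, fkm_config(k = 2, seed = 1))
  # identify each cloud's cluster by the centroid midpoint rule
  own <- ifelse(rowMeans(pts) < 5,
                which.min(rowSums(fit$centroids)),
                which.max(rowSums(fit$centroids)))
  for (i in seq_len(nrow(pts))) {
    expect_gt(fit$memberships[i, own[i]], 0.99)
  }
  expect_equal(rowSums(fit$memberships), rep(1, 40), tolerance = 1e-9)
})

test_that("k = number of distinct points drives the objective to zero", {
  pts <- matrix(c(0, 0, 5, 5, 0, 9), 3, 2)
  fit <- fkm_fit(pts, fkm_config(k = 3, tol = 1e-10, max_iter = 200, seed = 2))
  expect_lt(min(fit$objective_trace), 1e-6)
})

test_that("the objective trace never increases and memberships stay stochastic", {
  for (seed in 1:10) {
    set.seed(seed)
    pts <- matrix(rnorm(60), 20, 3)
    fit <- fkm_fit(pts, fkm_config(k = 3, fuzzifier = 1.7, seed = seed))
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    expect_equal(rowSums(fit$memberships), rep(1, 20), tolerance = 1e-9)
  }
})

test_that("fits are deterministic given the seed", {
  set.seed(8)
  pts <- matrix(runif(80), 40, 2)
  a <- fkm_fit(pts, fkm_config(k = 2, seed = 123))
  b <- fkm_fit(pts, fkm_config(k = 2, seed = 123))
  expect_identical(a, b)
})

test_that("near-crisp fuzzifier reproduces k-means assignments on separated data", {
  set.seed(6)
  pts <- rbind(matrix(rnorm(50, 0, 0.4), 25, 2),
               matrix(rnorm(50, 8, 0.4), 25, 2))
  init <- dermclass:::.fkm_init(pts, 2, seed = 4)
  fit <- fkm_fit(pts, fkm_config(k = 2, fuzzifier = 1.05, seed = 4))
  km <- stats::kmeans(pts, centers = init)
  hard <- max.col(fit$memberships)
  # same partition up to label permutation
  agree <- mean(hard == km$cluster)
  expect_true(agree == 1 || agree == 0)
})

test_that("cluster relabelling permutes memberships and centroids consistently", {
  set.seed(9)
  pts <- matrix(rnorm(60), 20, 3)
  fit <- fkm_fit(pts, fkm_config(k = 3, seed = 11))
  perm <- c(3, 1, 2)
  l_orig <- fkm_objective(fit$memberships, pts, fit$centroids, 2)
  l_perm <- fkm_objective(fit$memberships[, perm], pts,
                          fit$centroids[perm, ], 2)
  expect_equal(l_orig, l_perm, tolerance = 1e-12)
})

test_that("lesion cluster selection follows lowest luminance with index ties", {
  res <- structure(list(memberships = matrix(0.5, 2, 2),
                        centroids = rbind(c(0.8, 0.7, 0.6), c(0.3, 0.2, 0.2)),
                        objective_trace = 1, iterations = 1, fuzzifier = 2),
                   class = "fkm_result")
  expect_equal(select_lesion_cluster(res), 2)
  res$centroids <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(select_lesion_cluster(res), 1)
})

test_that("a two-level image segments into exactly its darker half", {
  img <- array(0.7, dim = c(12, 12, 3))
  img[, 1:6, ] <- 0.2
  seg <- segment_image(img, fkm_config(k = 2, seed = 1))
  want <- matrix(0L, 12, 12); want[, 1:6] <- 1L
  expect_identical(seg$mask, want)
})

test_that("degenerate inputs are refused", {
  flat <- array(0.5, dim = c(8, 8, 3))
  expect_error(segment_image(flat, fkm_config(k = 2)), "distinct")
  expect_error(fkm_fit(matrix(1, 5, 2), fkm_config(k = 2)), "distinct")
  expect_error(fkm_fit(matrix(c(1, NA, 2, 3), 2, 2), fkm_config(k = 2)),
               "non-finite")
  expect_error(fkm_config(fuzzifier = 1), "fuzzifier")
})

test_that("segmentation masks of generated lesions overlap the truth", {
  ds <- tiny_synth(n = 2, seed = 17, size = 32)
  dices <- vapply(ds, function(item) {
    filtered <- bilateral_filter(item$image, bilateral_params())
    seg <- segment_image(filtered, fkm_config(seed = 3))
    dice_coefficient(seg$mask, item$truth_mask)
  }, numeric(1))
  expect_gt(min(dices), 0.8)
})

test_that("final centroids agree with an independent fuzzy c-means fit", {
  skip_if_not_installed("e1071")
  set.seed(12)
  pts <- rbind(matrix(rnorm(60, 0, 0.5), 30, 2),
               matrix(rnorm(60, 6, 0.5), 30, 2))
  fit <- fkm_fit(pts, fkm_config(k = 2, tol = 1e-9, max_iter = 300, seed = 5))
  ref <- e1071::cmeans(pts, centers = fit$centroids, m = 2, iter.max = 300)
  ord <- order(fit$centroids[, 1])
  ord_ref <- order(ref$centers[, 1])
  expect_equal(fit$centroids[ord, ], unname(ref$centers[ord_ref, ]),
               tolerance = 1e-3, ignore_attr = TRUE)
})
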