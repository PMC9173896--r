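test_that("conv2d_valid matches forced cases and the loop oracle", {
  x <- matrix(runif(25), 5, 5)
  expect_equal(conv2d_valid(x, matrix(1)), x)

  ones4 <- matrix(1, 4, 4)
  expect_equal(conv2d_valid(ones4, matrix(1, 2, 2), stride = 2),
               matrix(4, 2, 2))

  set.seed(14)
  a <- matrix(rnorm(36), 6, 6)
  k <- matrix(rnorm(9), 3, 3)
  expect_lt(max(abs(conv2d_valid(a, k) - oracle_conv2d(a, k))), 1e-12)
  expect_lt(max(abs(conv2d_valid(a, k, stride = 2) -
                      oracle_conv2d(a, k, stride = 2))), 1e-12)

  expect_error(conv2d_valid(matrix(1, 2, 2), matrix(1, 3, 3)), "larger")
})

test_that("max_pool matches forced cases and the loop oracle", {
  expect_equal(max_pool(matrix(0.3, 6, 6), 2), matrix(0.3, 3, 3))
  expect_equal(max_pool(matrix(1:4, 2, 2, byrow = TRUE), 2), matrix(4))

  set.seed(15)
  a <- matrix(rnorm(64), 8, 8)
  expect_equal(max_pool(a, 2), oracle_max_pool(a, 2))
  # non-divisible size pads with -Inf
  b <- matrix(rnorm(35), 5, 7)
  expect_equal(max_pool(b, 2), oracle_max_pool(b, 2))

  expect_error(max_pool(a, 0), "pool_size")
})

test_that("the network's im2col convolution agrees with the conv primitive", {
  set.seed(16)
  channels <- lapply(1:3, function(i) matrix(rnorm(100), 10, 10))
  W <- array(rnorm(3 * 3 * 3 * 4), dim = c(3, 3, 3, 4))
  ic <- dermclass:::.im2col(channels, 3, 3, 1)
  S <- ic$X %*% matrix(W, ncol = 4)
  for (f in 1:4) {
    direct <- Reduce(`+`, lapply(1:3, function(c)
      conv2d_valid(channels[[c]], W[, , c, f])))
    expect_lt(max(abs(matrix(S[, f], ic$oh, ic$ow) - direct)), 1e-12)
  }
})

test_that("a zero learning rate leaves parameters untouched", {
  ds <- tiny_synth(n = 3, seed = 19, size = 24)
  cfg0 <- extractor_config(input_size = 16,
                           sgd = list(learning_rate = 0, epochs = 2,
                                      batch_size = 4), seed = 7)
  ex <- train_extractor(ds, config = cfg0)
  ref <- dermclass:::with_seed(7, dermclass:::.init_extractor_params(cfg0))
  expect_equal(ex$params$Wf, ref$Wf)
  expect_equal(ex$params$blocks[[1]]$W, ref$blocks[[1]]$W)
})

test_that("SGD training reduces the cross-entropy on synthetic data", {
  ds <- tiny_synth(n = 10, seed = 23, size = 32)
  cfg <- extractor_config(input_size = 32,
                          sgd = list(learning_rate = 0.05, epochs = 8,
                                     batch_size = 5), seed = 3)
  ex <- train_extractor(ds, config = cfg)
  expect_lt(utils::tail(ex$loss_history, 1), ex$loss_history[1])
})

test_that("single-class training sets are rejected", {
  ds <- tiny_synth(n = 2, seed = 29, size = 24)
  mel_only <- Filter(function(d) d$label == "melanoma", ds)
  expect_error(train_extractor(mel_only), "both classes")
})

test_that("extraction is deterministic and shape-stable across image sizes", {
  ds <- tiny_synth(n = 2, seed = 31, size = 24)
  cfg <- extractor_config(input_size = 16, feature_dim = 32,
                          sgd = list(learning_rate = 0.05, epochs = 1,
                                     batch_size = 4), seed = 5)
  ex <- train_extractor(ds, config = cfg)
  f1 <- extract_features(ex, ds[[1]]$image, ds[[1]]$truth_mask)
  f2 <- extract_features(ex, ds[[1]]$image, ds[[1]]$truth_mask)
  expect_identical(f1, f2)
  expect_length(f1, 32)
  # different input resolution, same feature length (resize contract)
  big <- array(runif(50 * 70 * 3), dim = c(50, 70, 3))
  expect_length(extract_features(ex, big), 32)
})

test_that("a zero network maps any masked image to the zero feature vector", {
  cfg <- extractor_config(input_size = 16,
                          sgd = list(learning_rate = 0.05, epochs = 1,
                                     batch_size = 4), seed = 1)
  params <- dermclass:::with_seed(1, dermclass:::.init_extractor_params(cfg))
  zero <- params
  zero$Wf <- params$Wf * 0; zero$bf <- params$bf * 0
  zero$Wo <- params$Wo * 0; zero$bo <- params$bo * 0
  zero$blocks <- lapply(params$blocks, function(b)
    list(W = b$W * 0, b = b$b * 0, kernel = b$kernel, stride = b$stride))
  ex <- structure(list(params = zero, config = cfg,
                       classes = c("melanoma", "benign"),
                       loss_history = numeric(0), trained = TRUE),
                  class = "derm_extractor")
  img <- random_rgb(20, 20, seed = 2)
  feats <- extract_features(ex, img, matrix(0L, 20, 20))
  expect_equal(feats, rep(0, cfg$feature_dim))
})

test_that("untrained extractors are refused", {
  expect_error(extract_features(list(), random_rgb(8, 8, 1)), "trained")
})

test_that("trained features separate the two synthetic classes", {
  ds <- tiny_synth(n = 12, seed = 37, size = 32)
  cfg <- extractor_config(input_size = 32,
                          sgd = list(learning_rate = 0.05, epochs = 10,
                                     batch_size = 6), seed = 9)
  ex <- train_extractor(ds, config = cfg)
  feats <- extract_features_dataset(ex, ds)
  labs <- vapply(ds, `[[`, character(1), "label")
  mu_m <- colMeans(feats[labs == "melanoma", , drop = FALSE])
  mu_b <- colMeans(feats[labs == "benign", , drop = FALSE])
  between <- sqrt(sum((mu_m - mu_b)^2))
  within <- mean(c(
    apply(feats[labs == "melanoma", , drop = FALSE], 1,
          function(r) sqrt(sum((r - mu_m)^2))),
    apply(feats[labs == "benign", , drop = FALSE], 1,
          function(r) sqrt(sum((r - mu_b)^2)))))
  expect_gt(between, 0)
  expect_gt(between / within, 0.3)
})
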