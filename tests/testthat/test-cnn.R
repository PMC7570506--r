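test_that("layer shape arithmetic follows the closed-form floor formula", {
  nb <- cnn_build(cnn2d_spec(17, 10, 4))
  rep2 <- nb$shape_report
  expect_identical(rep2$output[rep2$layer == "conv"], "7x7x20")
  expect_identical(rep2$output[rep2$layer == "maxpool"], "3x3x20")
  expect_identical(rep2$output[rep2$layer == "dropout"], "180")
  expect_identical(rep2$params[rep2$layer == "conv"], 5L * 5L * 10L * 20L + 20L)
  n3 <- cnn_build(cnn3d_spec(7, 101, 4))
  rep3 <- n3$shape_report
  expect_identical(rep3$output[rep3$layer == "conv3d"], "5x5x92x10")
  # property: random specs agree with the floor formula
  set.seed(30)
  for (i in 1:20) {
    k <- sample(seq(7L, 21L, 2L), 1); d <- sample(2:6, 1)
    f <- sample(2:5, 1); s <- sample(1:3, 1)
    oh <- (k - f) %/% s + 1L
    pz <- 2L; ps <- sample(1:2, 1)
    ph <- (oh - pz) %/% ps + 1L
    if (oh < 1L || ph < 1L) next
    r <- cnn_build(cnn2d_spec(k, d, 3, filter_size = f, conv_stride = s,
                              pool_size = pz, pool_stride = ps))$shape_report
    expect_identical(r$output[r$layer == "conv"],
                     sprintf("%dx%dx%d", oh, oh, 20L))
    expect_identical(r$output[r$layer == "maxpool"],
                     sprintf("%dx%dx%d", ph, ph, 20L))
  }
  expect_error(cnn_build(cnn2d_spec(3, 5, 2)), "collapses")
  expect_error(cnn_build(cnn3d_spec(7, 8, 2)), "collapses")
})

test_that("training is deterministic given the seed and learns a separable problem", {
  ps <- tiny_patch_problem()
  net <- cnn_build(cnn2d_spec(5, 3, 2, n_filters = 8, filter_size = 3,
                              conv_stride = 1))
  cfg <- train_config(epochs = 20L, batch_size = 32L, seed = 99)
  t1 <- cnn_train(net, ps, cfg)
  t2 <- cnn_train(net, ps, cfg)
  expect_identical(t1$weights, t2$weights)
  # history curve rises then flattens: last-quarter mean >= first-quarter mean
  acc <- t1$history$iterations$accuracy
  q <- length(acc) %/% 4L
  expect_gte(mean(tail(acc, q)), mean(head(acc, q)))
  # inference is deterministic and probabilities normalize
  p1 <- cnn_predict(t1, ps)
  p2 <- cnn_predict(t1, ps)
  expect_identical(p1$probs, p2$probs)
  expect_lt(max(abs(rowSums(p1$probs) - 1)), 1e-6)
  expect_gt(mean(p1$class == ps$labels), 0.99)
})

test_that("uninformative inputs keep the loss near ln(C)", {
  set.seed(31)
  ps <- tiny_patch_problem()
  ps$patches[] <- 0
  ps$labels <- rep(1:2, 60)
  net <- cnn_build(cnn2d_spec(5, 3, 2, n_filters = 4, filter_size = 3,
                              conv_stride = 1))
  tr <- cnn_train(net, ps, train_config(epochs = 10L, batch_size = 40L,
                                        seed = 5))
  expect_lt(max(abs(tr$history$iterations$loss - log(2))), 0.01 * log(2) + 0.02)
})

test_that("the 3-D network trains with batch norm and stays deterministic", {
  set.seed(32)
  n <- 80L
  X <- matrix(rnorm(n * 3 * 3 * 12, sd = 0.3), n)
  lab <- rep(1:2, each = n / 2L)
  # class 2 carries a spectral edge in the deeper bands of the center pixel
  X[lab == 2L, 9L * 6L + 5L] <- X[lab == 2L, 9L * 6L + 5L] + 2
  ps <- structure(list(patches = X, centers = cbind(rep(1L, n), seq_len(n)),
                       labels = lab, k = 3L, d = 12L,
                       source_shape = c(1L, n)),
                  class = "patch_set")
  net <- cnn_build(cnn3d_spec(3, 12, 2, n_filters = 4, filter_spatial = 2,
                              filter_spectral = 4))
  cfg <- train_config(epochs = 25L, batch_size = 40L, seed = 11)
  tr <- cnn_train(net, ps, cfg)
  tr2 <- cnn_train(net, ps, cfg)
  expect_identical(tr$weights, tr2$weights)
  pr <- cnn_predict(tr, ps)
  expect_gt(mean(pr$class == lab), 0.95)
  expect_lt(max(abs(rowSums(pr$probs) - 1)), 1e-6)
})

test_that("predict_map refolds argmax labels and zeroes the background", {
  set.seed(33)
  nr <- 9L; nc <- 10L; d <- 3L
  stack <- array(rnorm(nr * nc * d, sd = 0.2), c(nr, nc, d))
  truth <- matrix(0L, nr, nc)
  truth[2:8, 2:5] <- 1L; truth[2:8, 6:9] <- 2L
  stack[, , 1][truth == 2L] <- stack[, , 1][truth == 2L] + 2
  mask <- truth > 0L
  ps <- extract_patches(stack, mask, labels = label_image(truth, c("a", "b")),
                        k = 3L)
  net <- cnn_build(cnn2d_spec(3, d, 2, n_filters = 6, filter_size = 2,
                              conv_stride = 1, pool_size = 1, pool_stride = 1))
  tr <- cnn_train(net, ps, train_config(epochs = 30L, batch_size = 32L,
                                        seed = 3),
                  class_names = c("a", "b"))
  out <- predict_map(tr, stack, mask)
  expect_s3_class(out$map, "label_image")
  expect_true(all(out$map$labels[!mask] == 0L))
  expect_gt(mean(out$map$labels[mask] == truth[mask]), 0.95)
  sums <- apply(out$probs, c(1, 2), sum)
  expect_true(all(abs(sums[mask] - 1) < 1e-6))
  expect_true(all(sums[!mask] == 0))
  # identical model applied twice yields identical maps
  expect_identical(predict_map(tr, stack, mask)$map$labels, out$map$labels)
})

test_that("training histories are recorded per iteration and per epoch", {
  ps <- tiny_patch_problem(n_per_class = 40L)
  val <- tiny_patch_problem(n_per_class = 15L, seed = 8L)
  net <- cnn_build(cnn2d_spec(5, 3, 2, n_filters = 4, filter_size = 3,
                              conv_stride = 1))
  cfg <- train_config(epochs = 6L, batch_size = 32L, seed = 2,
                      validation = val)
  tr <- cnn_train(net, ps, cfg)
  expect_identical(nrow(tr$history$validation), 6L)
  expect_identical(nrow(tr$history$iterations), 6L * 3L)  # ceil(80/32) = 3
  expect_identical(tr$config$seed, 2L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_training_history(tr, p)
  expect_identical(nrow(utils::read.csv(p)), 18L)
  expect_true(file.exists(sub("\\.csv$", "_validation.csv", p)))
  expect_error(cnn_train(net, ps,
                         train_config(epochs = 3L, batch_size = 8L,
                                      seed = 1, learning_rate = 1e8)),
               "non-finite")
})
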