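test_that("pca_fit matches a covariance eigendecomposition", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20)
  pm <- pca_fit(X, 5)
  ev <- eigen(cov(X), symmetric = TRUE)
  L <- ev$vectors[, 1:5]
  for (j in 1:5) {
    jm <- which.max(abs(L[, j]))
    if (L[jm, j] < 0) L[, j] <- -L[, j]
  }
  expect_lt(max(abs(pm$loadings - L)), 1e-8)
  expect_equal(pm$explained_variance_ratio,
               ev$values[1:5] / sum(ev$values), tolerance = 1e-8)
  expect_lt(max(abs(crossprod(pm$loadings) - diag(5))), 1e-10)
  expect_true(all(diff(pm$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pm$explained_variance_ratio), 1 + 1e-12)
})

test_that("pca handles rank-1 data and the sign convention", {
  set.seed(9)
  t_ <- rnorm(30)
  X <- outer(t_, c(0, 0, -2, 0))  # variance only along -2 * e3
  pm <- pca_fit(X + 1, 1)
  expect_equal(abs(pm$loadings[3, 1]), 1, tolerance = 1e-12)
  expect_gt(pm$loadings[3, 1], 0)  # largest-magnitude element positive
  expect_error(pca_fit(matrix(1, 10, 4), 2), "variance")
  expect_error(pca_fit(X, 10), "n_components")
})

test_that("pca_project refolds training scores and zeros the background", {
  cb <- random_cube(8, 9, 6, seed = 10, mask = TRUE)
  fl <- unfold(cb, use_mask = TRUE)
  pm <- pca_fit(fl$values, 3)
  st <- pca_project(cb, pm, 3)
  sc <- pca_transform(fl$values, pm, 3)
  expect_equal(st, refold(fl, sc, fill = 0))
  for (j in 1:3) expect_true(all(st[, , j][!cb$mask] == 0))
  expect_error(pca_project(random_cube(4, 4, 3, seed = 2), pm, 3), "features")
})

test_that("plsda with full LVs reproduces least squares on one-hot Y", {
  set.seed(11)
  X <- matrix(rnorm(25 * 6), 25)
  y <- rep(1:3, length.out = 25)
  fit <- plsda_fit(X, y, 6)
  Yh <- predict(fit, X, type = "response")
  Y <- diag(3)[y, ]
  Xc <- scale(X, scale = FALSE)
  B <- solve(crossprod(Xc), crossprod(Xc, scale(Y, scale = FALSE)))
  Yols <- Xc %*% B + matrix(colMeans(Y), 25, 3, byrow = TRUE)
  expect_lt(max(abs(Yh - Yols)), 1e-6)
})

test_that("plsda separates offset classes with one LV and argmax rule", {
  set.seed(12)
  X <- rbind(matrix(rnorm(30 * 4), 30),
             sweep(matrix(rnorm(30 * 4), 30), 2, c(6, 0, 0, 0), `+`))
  y <- rep(c("a", "b"), each = 30)
  fit <- plsda_fit(X, y, 1)
  expect_identical(fit$class_names, c("a", "b"))
  expect_equal(mean(predict(fit, X) == y), 1)
  resp <- predict(fit, X, type = "response")
  expect_identical(as.character(predict(fit, X)),
                   colnames(resp)[max.col(resp, ties.method = "first")])
  # training accuracy is non-decreasing in the number of LVs
  set.seed(13)
  Xr <- matrix(rnorm(40 * 8), 40)
  yr <- rep(1:2, 20)
  fit8 <- plsda_fit(Xr, yr, 8)
  accs <- vapply(1:8, function(a)
    mean(as.integer(predict(fit8, Xr, n_lv = a)) == yr), numeric(1))
  expect_true(all(diff(accs) >= -1e-12))
  expect_error(plsda_fit(X, y, 50), "n_lv")
})

test_that("venetian blinds picks LV 1 on separable data, chance on noise", {
  set.seed(14)
  X <- rbind(matrix(rnorm(60 * 5), 60),
             sweep(matrix(rnorm(60 * 5), 60), 2, c(8, 0, 0, 0, 0), `+`))
  y <- rep(1:2, each = 60)
  ix <- sample(120)
  sel <- select_lvs_venetian(X[ix, ], y[ix], max_lv = 4, n_splits = 10)
  expect_identical(sel$n_lv, 1L)
  expect_equal(sel$curve[1], 1)
  # pure-noise labels: CV accuracy ~ 1/C
  set.seed(15)
  Xn <- matrix(rnorm(300 * 6), 300)
  yn <- sample(1:3, 300, TRUE)
  seln <- select_lvs_venetian(Xn, yn, max_lv = 3, n_splits = 5)
  expect_true(all(abs(seln$curve - 1 / 3) < 3 * sqrt(1 / 3 * 2 / 3 / 300)))
  # a fold losing a class is refused with advice
  expect_error(select_lvs_venetian(X[1:4, ], c(1, 1, 1, 2), 2, n_splits = 2),
               "missing")
})

test_that("ecoc reduces to the binary classifier for C = 2", {
  set.seed(16)
  X <- rbind(matrix(rnorm(40 * 3), 40),
             sweep(matrix(rnorm(40 * 3), 40), 2, c(4, 0, 0), `+`))
  y <- rep(1:2, each = 40)
  em <- ecoc_fit(X, y)
  expect_identical(length(em$binary_fits), 1L)
  lrn <- svm_binary_learner()(X, ifelse(y == 1, 1, -1))
  expect_identical(as.integer(predict(em, X)),
                   unname(ifelse(lrn(X) > 0, 1L, 2L)))
})

test_that("ecoc separates 4 Gaussian blobs and counts codes correctly", {
  set.seed(17)
  mu <- rbind(c(0, 0), c(7, 0), c(0, 7), c(7, 7))
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(40 * 2), 40), 2, mu[k, ], `+`)))
  y <- rep(1:4, each = 40)
  tr <- c(outer(1:30, (0:3) * 40, `+`))
  te <- setdiff(seq_len(160), tr)
  em <- ecoc_fit(X[tr, ], y[tr], coding = "one-vs-one")
  expect_identical(length(em$binary_fits), 6L)   # C(C-1)/2
  pred <- predict(em, X[te, ])
  # reference: nearest centroid on the same blobs
  cent <- t(vapply(1:4, function(k) colMeans(X[tr, ][y[tr] == k, ]),
                   numeric(2)))
  ref <- apply(X[te, ], 1, function(r)
    which.min(colSums((t(cent) - r)^2)))
  expect_gte(mean(as.integer(pred) == ref), 0.95)
  expect_gte(mean(as.integer(pred) == y[te]), 0.95)
  ova <- ecoc_fit(X[tr, ], y[tr], coding = "one-vs-all")
  expect_identical(length(ova$binary_fits), 4L)
  expect_gte(mean(as.integer(predict(ova, X[te, ])) == y[te]), 0.95)
  # prediction is invariant to row order
  sh <- sample(length(te))
  expect_identical(as.integer(predict(em, X[te, ][sh, ])),
                   as.integer(pred)[sh])
})

test_that("chemometric models serialize and reload to identical predictions", {
  set.seed(18)
  X <- matrix(rnorm(50 * 6), 50)
  y <- rep(1:2, 25)
  td <- withr::local_tempdir()
  pm <- pca_fit(X, 3)
  fit <- plsda_fit(X, y, 3)
  save_model(fit, file.path(td, "m.rds"))
  fit2 <- load_model(file.path(td, "m.rds"))
  expect_identical(predict(fit2, X, type = "response"),
                   predict(fit, X, type = "response"))
  expect_true(file.exists(file.path(td, "m.json")))
  save_model(pm, file.path(td, "p.rds"))
  expect_identical(pca_transform(X, load_model(file.path(td, "p.rds"))),
                   pca_transform(X, pm))
})
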