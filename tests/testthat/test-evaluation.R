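test_that("a perfect prediction gives a diagonal table and CCR 1", {
  set.seed(40)
  truth <- label_image(matrix(sample(0:3, 100, TRUE), 10, 10),
                       c("a", "b", "c"))
  rep_ <- confusion(truth, truth)
  expect_identical(sum(rep_$counts) , sum(truth$labels > 0L))
  expect_identical(sum(diag(rep_$counts)), sum(rep_$counts))
  expect_equal(rep_$ccr, 1)
  expect_true(all(rep_$per_class$tpr == 1))
  expect_true(all(rep_$per_class$ppv == 1))
})

test_that("the binary closed forms hold on the fixed table", {
  # TP = 90, FN = 10, FP = 5, TN = 95 laid out as pixels
  t_ <- matrix(c(rep(1L, 100L), rep(2L, 100L)), 10, 20)
  p_ <- t_
  p_[1:10] <- 2L      # 10 FN for class 1
  p_[101:105] <- 1L   # 5 FP for class 1
  rep_ <- confusion(label_image(t_, c("pos", "neg")),
                    label_image(p_, c("pos", "neg")))
  r1 <- rep_$per_class[1L, ]
  expect_equal(r1$tpr, 0.90)
  expect_equal(r1$fnr, 0.10)
  expect_equal(r1$ppv, 90 / 95)
  expect_equal(r1$fdr, 5 / 95)            # 1 - PPV convention
  expect_equal(r1$fdr_printed, 5 / 100)   # FP / (FP + TN) as printed
  expect_equal(r1$tpr + r1$fnr, 1)
  expect_equal(r1$ppv + r1$fdr, 1)
})

test_that("confusion counts are conserved and CCR is permutation-invariant", {
  set.seed(41)
  for (i in 1:10) {
    t_ <- matrix(sample(0:3, 150, TRUE), 10, 15)
    p_ <- matrix(sample(1:3, 150, TRUE), 10, 15)
    if (!any(t_ > 0L)) t_[1] <- 1L
    rep_ <- confusion(label_image(t_, letters[1:3]),
                      label_image(p_, letters[1:3]))
    keep <- t_ > 0L
    expect_equal(unname(rowSums(rep_$counts)),
                 vapply(1:3, function(k) sum(t_[keep] == k), numeric(1)))
    expect_equal(unname(colSums(rep_$counts)),
                 vapply(1:3, function(k) sum(p_[keep] == k), numeric(1)))
    # micro-averaged TPR equals CCR
    expect_equal(sum(diag(rep_$counts)) / sum(rep_$counts), rep_$ccr)
    # consistent relabeling leaves CCR unchanged
    perm <- sample(3)
    t2 <- t_; p2 <- p_
    t2[keep] <- perm[t_[keep]]; p2[] <- perm[p_]
    rep2 <- confusion(label_image(t2, letters[1:3]),
                      label_image(p2, letters[1:3]))
    expect_equal(rep2$ccr, rep_$ccr)
  }
  # random 3-class agreement sits near 1/3
  set.seed(42)
  t_ <- matrix(sample(1:3, 1000, TRUE), 25, 40)
  p_ <- matrix(sample(1:3, 1000, TRUE), 25, 40)
  rep_ <- confusion(label_image(t_, letters[1:3]),
                    label_image(p_, letters[1:3]))
  expect_lt(abs(rep_$ccr - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 1000))
  expect_error(confusion(label_image(t_, letters[1:3]),
                         label_image(t_[, 1:10], letters[1:3])), "shape")
  expect_error(confusion(label_image(matrix(0L, 2, 2), "a"),
                         label_image(matrix(1L, 2, 2), "a")), "empty")
})

test_that("misclassification maps flag exactly the labelled disagreements", {
  set.seed(43)
  t_ <- matrix(sample(0:2, 60, TRUE), 6, 10)
  p_ <- matrix(sample(1:2, 60, TRUE), 6, 10)
  m <- misclassification_map(t_, p_)
  expect_identical(m, t_ > 0L & p_ != t_)
  expect_true(all(!m[t_ == 0L]))
  expect_identical(m, misclassification_map(label_image(t_, c("a", "b")),
                                            label_image(p_, c("a", "b"))))
  # conservation: flagged pixels = evaluated total - trace
  rep_ <- confusion(label_image(t_, c("a", "b")),
                    label_image(p_, c("a", "b")))
  expect_identical(sum(m), sum(rep_$counts) - sum(diag(rep_$counts)))
  expect_identical(sum(misclassification_map(t_, t_)), 0L)
})

test_that("local thresholding recovers bimodal structure per tile", {
  # bimodal tile values {0, 1} separate perfectly at any inner threshold
  v <- matrix(rep(c(0, 1), 50), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  li <- local_threshold_truth(v, mask, tile_grid = c(1, 1))
  expect_identical(li$labels == 1L, v > 0.5)
  # a 1x1 grid equals global thresholding with the same rule
  set.seed(44)
  sc <- matrix(rnorm(100), 10, 10)
  g1 <- local_threshold_truth(sc, mask, c(1, 1))
  thr <- hsipix:::otsu_threshold(as.vector(sc))
  expect_identical(g1$labels == 1L, sc > thr)
  # slow drift defeats a global threshold but not the tiled one
  drift <- outer(seq(0, 3, length.out = 20), rep(1, 20))
  stripes <- matrix(rep(c(0, 0.8), 10), 20, 20, byrow = TRUE)
  img <- stripes + drift
  truth <- stripes > 0.4
  tiled <- local_threshold_truth(img, matrix(TRUE, 20, 20), c(4, 1))
  expect_gt(mean((tiled$labels == 1L) == truth), 0.95)
  # empty tiles are skipped and counted
  m2 <- matrix(FALSE, 10, 10); m2[1:5, 1:5] <- TRUE
  li2 <- local_threshold_truth(sc, m2, c(2, 2))
  expect_identical(attr(li2, "skipped_tiles"), 3L)
  expect_true(all(li2$labels[!m2] == 0L))
})

test_that("confusion reports serialize to JSON and CSV", {
  t_ <- matrix(sample(1:2, 40, TRUE), 5, 8)
  rep_ <- confusion(label_image(t_, c("a", "b")), label_image(t_, c("a", "b")))
  td <- withr::local_tempdir()
  write_confusion(rep_, file.path(td, "r.json"))
  js <- jsonlite::fromJSON(file.path(td, "r.json"))
  expect_equal(js$ccr, 1)
  expect_identical(js$class_names, c("a", "b"))
  write_confusion(rep_, file.path(td, "r.csv"))
  expect_identical(nrow(utils::read.csv(file.path(td, "r.csv"))), 2L)
})
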