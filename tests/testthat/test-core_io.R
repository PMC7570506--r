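test_that("hypercube validates its invariants", {
  arr <- array(runif(24), c(2, 3, 4))
  expect_error(hypercube(arr, c(1000, 1010, 1020)), "bands")
  expect_error(hypercube(arr, c(1000, 990, 1020, 1030)), "increasing")
  bad <- arr; bad[1] <- NaN
  expect_error(hypercube(bad, c(1, 2, 3, 4) * 100), "NA")
  expect_error(hypercube(arr, 1:4 * 100, mask = matrix(TRUE, 3, 2)))
  cb <- hypercube(arr, c(1000, 1007, 1014, 1021))
  expect_s3_class(cb, "hypercube")
  expect_identical(dim(cb), c(2L, 3L, 4L))
})

test_that("ENVI interleave dialects round-trip to identical arrays", {
  # hand-built 4 x 5 x 3 payload with distinguishable values
  arr <- array(as.double(1:60), c(4, 5, 3))
  cb <- hypercube(arr, c(950, 960, 970))
  td <- withr::local_tempdir()
  loaded <- lapply(c("bsq", "bil", "bip"), function(il) {
    p <- file.path(td, paste0("cube_", il, ".hdr"))
    write_cube(cb, p, interleave = il)
    read_cube(p)$data
  })
  expect_identical(loaded[[1]], arr)
  expect_identical(loaded[[2]], arr)
  expect_identical(loaded[[3]], arr)
  # oracle: explicit index arithmetic on the BIP payload bytes
  con <- file(file.path(td, "cube_bip.dat"), "rb")
  raw <- readBin(con, "double", 60)
  close(con)
  # BIP stores bands fastest, then samples (cols), then lines (rows)
  expect_equal(raw[1:3], arr[1, 1, ])
  expect_equal(raw[4:6], arr[1, 2, ])
  expect_equal(raw[16:18], arr[2, 1, ])
})

test_that("portable container round-trips data, mask and label", {
  cb <- random_cube(mask = TRUE)
  cb$label <- "sceneA"
  p <- withr::local_tempfile(fileext = ".rds")
  write_cube(cb, p)
  cb2 <- read_cube(p)
  expect_identical(cb2$data, cb$data)
  expect_identical(cb2$mask, cb$mask)
  expect_identical(cb2$label, "sceneA")
})

test_that("header/payload inconsistencies are hard errors", {
  cb <- random_cube()
  td <- withr::local_tempdir()
  p <- file.path(td, "c.hdr")
  write_cube(cb, p)
  # corrupt: header claims one extra band
  hdr <- readLines(p)
  hdr <- sub("^bands = 5", "bands = 6", hdr)
  hdr <- sub("wavelength = \\{", "wavelength = {1050, ", hdr)
  writeLines(hdr, p)
  expect_error(read_cube(p), "size mismatch")
  # missing wavelength metadata names the field
  writeLines(grep("wavelength =", readLines(file.path(td, "c.hdr")),
                  invert = TRUE, value = TRUE), file.path(td, "d.hdr"))
  file.copy(file.path(td, "c.dat"), file.path(td, "d.dat"))
  expect_error(read_cube(file.path(td, "d.hdr")), "wavelength")
})

test_that("band_index resolves nearest centers with low-index ties", {
  wl <- seq(943, 1643, by = 7)  # 101 bands
  expect_identical(band_index(wl, 957), 3L)   # exact hit on the third center
  expect_identical(band_index(wl, 1496), which.min(abs(wl - 1496)))
  expect_identical(band_index(wl, 946.5), 1L) # midway: tie breaks low
  expect_error(band_index(wl, 2000), "outside")
  expect_error(band_index(wl, 900), "outside")
  # monotone in the target
  targets <- sort(runif(50, 943, 1643))
  idx <- vapply(targets, band_index, integer(1L), wavelengths = wl)
  expect_true(all(diff(idx) >= 0L))
})

test_that("unfold enumerates pixels in row-major order", {
  arr <- array(as.double(1:12), c(2, 2, 3))
  cb <- hypercube(arr, c(1, 2, 3) * 100)
  fl <- unfold(cb)
  expect_identical(dim(fl$values), c(4L, 3L))
  expect_identical(unname(fl$coords),
                   cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L)))
  expect_equal(fl$values[2L, ], arr[1, 2, ])
  # masked single pixel
  cb$mask <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2)
  fl1 <- unfold(cb, use_mask = TRUE)
  expect_identical(nrow(fl1$values), 1L)
  expect_equal(fl1$values[1L, ], arr[1, 2, ])
  cb$mask <- matrix(FALSE, 2, 2)
  expect_error(unfold(cb, use_mask = TRUE), "empty")
})

test_that("unfold/refold are mutually inverse on the foreground", {
  for (seed in 1:25) {
    set.seed(seed)
    nr <- sample(2:9, 1); nc <- sample(2:9, 1); nb <- sample(1:6, 1)
    cb <- hypercube(array(runif(nr * nc * nb), c(nr, nc, nb)),
                    sort(sample(900:1700, nb)))
    cb$mask <- matrix(runif(nr * nc) > 0.3, nr, nc)
    if (!any(cb$mask)) cb$mask[1, 1] <- TRUE
    fl <- unfold(cb, use_mask = TRUE)
    back <- refold(fl, fill = -99)
    for (b in seq_len(nb)) {
      expect_equal(back[, , b][cb$mask], cb$data[, , b][cb$mask])
      expect_true(all(back[, , b][!cb$mask] == -99))
    }
    # conservation: refolded sums equal value sums
    expect_equal(sum(refold(fl, fill = 0)), sum(fl$values))
  }
})

test_that("refold validates row counts and builds classification maps", {
  cb <- random_cube(mask = TRUE)
  fl <- unfold(cb, use_mask = TRUE)
  expect_error(refold(fl, matrix(0, nrow(fl$values) + 1L, 1L)), "row count")
  cls <- matrix(sample(1:3, nrow(fl$values), TRUE), ncol = 1L)
  m <- refold(fl, cls, fill = 0, drop = TRUE)
  expect_identical(dim(m), dim(cb$mask))
  expect_identical(sort(unique(m[cb$mask])), sort(unique(as.vector(cls))))
  expect_true(all(m[!cb$mask] == 0))
})

test_that("label_from_scene paints the mask with one class", {
  cb <- random_cube(mask = TRUE)
  li <- label_from_scene(cb, 3L, c("a", "b", "c"))
  expect_identical(sum(li$labels > 0L), sum(cb$mask))
  expect_true(all(li$labels[cb$mask] == 3L))
  expect_error(label_from_scene(cb, 0L), "background")
  cb$mask <- matrix(TRUE, nrow(cb$mask), ncol(cb$mask))
  li2 <- label_from_scene(cb, 2L, c("a", "b"))
  expect_true(all(li2$labels == 2L))
})

test_that("label TIFF export round-trips labels and class table", {
  li <- label_image(matrix(sample(0:3, 30, TRUE), 5, 6),
                    c("RFM", "Mint", "Teeth"))
  p <- withr::local_tempfile(fileext = ".tif")
  write_label_tiff(li, p)
  li2 <- read_label_tiff(p)
  expect_identical(li2$labels, li$labels)
  expect_identical(li2$class_names, li$class_names)
})
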