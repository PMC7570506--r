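#' Apply a preprocessing chain to a whole hypercube
#'
#' Unfolds the foreground, runs the chain on the pixel spectra, and refolds
#' into a new hypercube whose band axis is the chain's surviving feature
#' axis (a derivative step shrinks it). Background pixels are 0.
#'
#' @param cube a masked [hypercube] (an unmasked cube is processed whole).
#' @param chain a [pp_chain].
#' @return A [hypercube] with preprocessed data; mask and label carried over.
#' @export
preprocess_cube <- function(cube, chain) {
  stopifnot(inherits(cube, "hypercube"))
  flat <- unfold(cube, use_mask = !is.null(cube$mask))
  Xp <- apply_chain(flat$values, chain)
  kept <- attr(Xp, "kept")
  stack <- refold(flat, Xp, fill = 0)
  hypercube(stack, cube$wavelengths[kept], mask = cube$mask,
            label = cube$label)
}

#' Per-pixel patches from an image stack
#'
#' Extracts one k x k x d patch per foreground pixel, centered on that
#' pixel. Pixels near the sample edge naturally include background voxels
#' (value 0, matching the background fill of score images); pixels near the
#' image border are handled by zero-padding the stack by (k-1)/2 on each
#' side, keeping both edge cases consistent.
#'
#' Patches are stored flattened, one row per pixel, in column-major
#' (row, col, channel) voxel order; `patch_array()` restores the 4-D view.
#'
#' @param stack numeric array (rows, cols, d), e.g. a PC score-image stack.
#' @param mask logical foreground matrix (rows x cols).
#' @param labels optional [label_image] (or integer matrix) supplying a
#'   label per center; absent labels are stored as 0 (predict-time patches).
#' @param k odd patch window size.
#' @return A `patch_set`: list with `patches` (n x k*k*d matrix), `centers`
#'   (n x 2, 1-based, row-major order), `labels` (n integers), `k`, `d` and
#'   `source_shape`.
#' @export
extract_patches <- function(stack, mask, labels = NULL, k) {
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("`k` must be odd and >= 1")
  d <- dim(stack)[3L]
  x <- dim(stack)[1L]; y <- dim(stack)[2L]
  if (is.null(mask)) mask <- matrix(TRUE, x, y)
  if (!identical(dim(mask), c(x, y))) stop("mask shape mismatch")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no foreground pixels to extract patches from")
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  h <- (k - 1L) %/% 2L
  X2 <- x + 2L * h; Y2 <- y + 2L * h
  padded <- array(0, c(X2, Y2, d))
  padded[(h + 1L):(h + x), (h + 1L):(h + y), ] <- stack
  # linear offsets of the k*k*d patch voxels relative to the patch origin
  rel <- as.vector(outer(outer(0:(k - 1L), (0:(k - 1L)) * X2, `+`),
                         (0:(d - 1L)) * (X2 * Y2), `+`))
  base <- idx[, 1L] + (idx[, 2L] - 1L) * X2 + (1L - 1L) * X2 * Y2
  n <- nrow(idx)
  patches <- matrix(0, n, length(rel))
  chunk <- max(1L, as.integer(2e7 / length(rel)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    patches[s:e, ] <- padded[outer(base[s:e], rel, `+`)]
  }
  labv <- rep(0L, n)
  if (!is.null(labels)) {
    lm <- if (inherits(labels, "label_image")) labels$labels else labels
    if (!identical(dim(lm), c(x, y))) stop("labels shape mismatch")
    labv <- as.integer(lm[idx])
  }
  structure(list(patches = patches, centers = idx, labels = labv,
                 k = k, d = d, source_shape = c(x, y)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d x %d (%d labelled)\n",
              nrow(x$patches), x$k, x$k, x$d, sum(x$labels > 0L)))
  invisible(x)
}

#' 4-D array view of a patch set
#' @param ps a `patch_set`.
#' @return Array (k, k, d, n).
#' @export
patch_array <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  array(t(ps$patches), c(ps$k, ps$k, ps$d, nrow(ps$patches)))
}

#' Spectral-spatial patches straight from a hypercube
#'
#' Same contract as [extract_patches()] with the feature depth equal to the
#' (preprocessed) band count: each patch is k x k x lambda, so a classifier
#' sees the full spectral context of the pixel neighborhood.
#'
#' @param cube a masked [hypercube]; background voxels contribute 0.
#' @param k odd window size.
#' @param labels optional [label_image].
#' @return A `patch_set` with `d = ` number of bands.
#' @export
extract_patches_3d <- function(cube, k, labels = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  stack <- cube$data
  if (!is.null(cube$mask)) {
    bg <- !cube$mask
    if (any(bg)) {
      nb <- dim(stack)[3L]
      lin <- which(bg)
      npx <- prod(dim(stack)[1:2])
      stack[rep(lin, nb) + rep((0:(nb - 1L)) * npx, each = length(lin))] <- 0
    }
  }
  extract_patches(stack, cube$mask, labels = labels, k = k)
}

#' Export patch centers and labels for audit
#'
#' Writes one row per patch with its center coordinate (1-based row/col)
#' and label, so a patch set's provenance can be checked without loading
#' the array data.
#'
#' @param ps a `patch_set`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_patch_index <- function(ps, path) {
  stopifnot(inherits(ps, "patch_set"))
  utils::write.csv(data.frame(row = ps$centers[, 1L], col = ps$centers[, 2L],
                              label = ps$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' Keep every m-th observation of a patch set
#'
#' Reduces a training set by keeping observations at positions 1, 1+m,
#' 1+2m, ... (order preserved), the standard remedy when the full 5-D patch
#' tensor does not fit in memory.
#'
#' @param ps a `patch_set`.
#' @param m keep-one-in-m factor (>= 1); `m = 1` is the identity.
#' @return A `patch_set` with `ceiling(n / m)` observations.
#' @export
subsample_every <- function(ps, m) {
  stopifnot(inherits(ps, "patch_set"))
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1")
  keep <- seq(1L, nrow(ps$patches), by = m)
  ps$patches <- ps$patches[keep, , drop = FALSE]
  ps$centers <- ps$centers[keep, , drop = FALSE]
  ps$labels <- ps$labels[keep]
  ps
}
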