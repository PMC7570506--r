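#' Hypercube container
#'
#' A hypercube is a 3-D reflectance array with dimensions (rows, cols, bands)
#' together with the vector of band-center wavelengths in nanometres, an
#' optional boolean foreground mask and an optional scene-level class label.
#' Reflectance is stored as double regardless of the on-disk type so that
#' 12-bit camera data never truncates during preprocessing.
#'
#' @param data 3-D numeric array, dimensions (rows, cols, bands). Reflectance
#'   is nominally in \[0, ~1.2\]; saturated specular pixels may exceed 1.
#' @param wavelengths numeric vector of band centers in nm, strictly
#'   increasing, length equal to `dim(data)[3]`.
#' @param mask optional logical matrix (rows x cols); `TRUE` marks foreground.
#' @param label optional scene-level class name (single string).
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, mask = NULL, label = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows, cols, bands)")
  storage.mode(data) <- "double"
  if (anyNA(data))
    stop("`data` contains NA/NaN values")
  wavelengths <- as.double(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length(wavelengths) [", length(wavelengths),
         "] != number of bands [", dim(data)[3L], "]")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (!is.null(mask)) {
    if (!is.logical(mask)) stop("`mask` must be logical")
    if (!is.matrix(mask) || !identical(dim(mask), dim(data)[1:2]))
      stop("`mask` shape must equal the spatial shape of `data`")
  }
  if (!is.null(label)) label <- as.character(label)[1L]
  structure(list(data = data, wavelengths = wavelengths,
                 mask = mask, label = label),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$mask))
    cat(sprintf("  mask: %d foreground pixels\n", sum(x$mask)))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Nearest band index for a target wavelength
#'
#' Resolves a wavelength in nm to the index of the nearest band center.
#' Ties between two equally distant centers break toward the lower index.
#' Targets further than one median band spacing outside the grid are an
#' error, which prevents silently picking an end band for a wavelength the
#' instrument never measured.
#'
#' @param wavelengths strictly increasing numeric vector of band centers (nm).
#' @param target wavelength to resolve, nm (scalar).
#' @return Integer band index (1-based).
#' @export
band_index <- function(wavelengths, target) {
  if (length(wavelengths) == 0L) stop("`wavelengths` is empty")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  stopifnot(length(target) == 1L, is.finite(target))
  delta <- if (length(wavelengths) > 1L) stats::median(diff(wavelengths)) else Inf
  if (target < min(wavelengths) - delta || target > max(wavelengths) + delta)
    stop(sprintf("target %.6g nm is outside the covered range [%.6g, %.6g] nm (+/- %.6g)",
                 target, min(wavelengths), max(wavelengths), delta))
  which.min(abs(wavelengths - target))
}

#' Unfold a hypercube into a pixel-by-wavelength matrix
#'
#' Rearranges the cube into a matrix whose rows are pixel spectra, in
#' row-major scan order of the retained pixels (all pixels, or foreground
#' only). The pixel coordinates are kept so the matrix can be refolded
#' losslessly into images.
#'
#' @param cube a [hypercube].
#' @param use_mask if `TRUE`, keep only pixels where `cube$mask` is `TRUE`.
#' @return An object of class `flat_spectra`: list with `values`
#'   (n_pixels x n_bands matrix), `coords` (n_pixels x 2 integer matrix of
#'   1-based (row, col)), `source_shape` and `feature_axis`.
#' @export
unfold <- function(cube, use_mask = FALSE) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (use_mask) {
    if (is.null(cube$mask)) stop("`use_mask = TRUE` but the cube has no mask")
    keep <- cube$mask
  } else {
    keep <- matrix(TRUE, d[1L], d[2L])
  }
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty foreground: no pixels to unfold")
  # row-major scan order: sort by row then col
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])  # pixel linear index x band
  lin <- (idx[, 2L] - 1L) * d[1L] + idx[, 1L]
  values <- flat[lin, , drop = FALSE]
  flat_spectra(values, idx, c(d[1L], d[2L]), cube$wavelengths)
}

#' Construct a flat_spectra object
#'
#' @param values n_pixels x n_features matrix.
#' @param coords n_pixels x 2 integer matrix of 1-based (row, col).
#' @param source_shape integer vector (rows, cols) of the source image.
#' @param feature_axis numeric feature axis: wavelengths (nm) or PC indices.
#' @return `flat_spectra` object.
#' @export
flat_spectra <- function(values, coords, source_shape, feature_axis = NULL) {
  values <- as.matrix(values)
  coords <- matrix(as.integer(coords), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(values) != nrow(coords))
    stop("values and coords disagree on the number of pixels")
  source_shape <- as.integer(source_shape)
  if (any(coords[, 1L] < 1L) || any(coords[, 1L] > source_shape[1L]) ||
      any(coords[, 2L] < 1L) || any(coords[, 2L] > source_shape[2L]))
    stop("coords outside source_shape")
  if (anyDuplicated(coords[, 1L] + (coords[, 2L] - 1) * source_shape[1L]))
    stop("duplicated pixel coordinates")
  structure(list(values = values, coords = coords,
                 source_shape = source_shape, feature_axis = feature_axis),
            class = "flat_spectra")
}

#' @export
print.flat_spectra <- function(x, ...) {
  cat(sprintf("<flat_spectra> %d pixels x %d features from a %d x %d image\n",
              nrow(x$values), ncol(x$values),
              x$source_shape[1L], x$source_shape[2L]))
  invisible(x)
}

#' Refold per-pixel values into an image stack
#'
#' Places each row of `values` at its recorded pixel coordinate; every other
#' pixel takes the fill value. With class predictions as `values` this
#' produces classification maps.
#'
#' @param flat a [flat_spectra] carrying the coordinates.
#' @param values n_pixels x m matrix (or vector, treated as m = 1); defaults
#'   to `flat$values`.
#' @param fill scalar used outside the recorded pixels.
#' @return Array (rows, cols, m); a matrix is returned if `drop = TRUE` and
#'   m = 1.
#' @param drop drop the trailing unit dimension for m = 1.
#' @export
refold <- function(flat, values = flat$values, fill = 0, drop = FALSE) {
  stopifnot(inherits(flat, "flat_spectra"))
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (nrow(values) != nrow(flat$coords))
    stop("row count of `values` [", nrow(values),
         "] != number of recorded pixels [", nrow(flat$coords), "]")
  m <- ncol(values)
  sh <- flat$source_shape
  if (is.integer(values)) fill <- as.integer(fill)
  out <- array(fill, c(sh[1L], sh[2L], m))
  lin <- flat$coords[, 1L] + (flat$coords[, 2L] - 1L) * sh[1L]
  npx <- sh[1L] * sh[2L]
  for (j in seq_len(m)) out[lin + (j - 1L) * npx] <- values[, j]
  if (drop && m == 1L) out <- out[, , 1L]
  out
}

#' Label image
#'
#' Integer image of per-pixel class labels: 0 marks background, 1..C the
#' classes named in `class_names`.
#'
#' @param labels integer matrix (rows x cols), values in 0..C.
#' @param class_names character vector of C class names.
#' @return `label_image` object.
#' @export
label_image <- function(labels, class_names) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be nonnegative integers")
  if (max(labels) > length(class_names))
    stop("label value ", max(labels), " exceeds the number of class names (",
         length(class_names), ")")
  structure(list(labels = labels, class_names = as.character(class_names)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d x %d, %d classes (%s); %d labelled pixels\n",
              nrow(x$labels), ncol(x$labels), length(x$class_names),
              paste(x$class_names, collapse = ", "), sum(x$labels > 0L)))
  invisible(x)
}

#' Scene-level ground truth from a foreground mask
#'
#' For scenes that contain a single object class, the per-pixel ground truth
#' is the scene class on the foreground and background elsewhere.
#'
#' @param cube a masked [hypercube].
#' @param class_id integer class id, >= 1 (0 is reserved for background).
#' @param class_names class name vector covering `class_id`.
#' @return A [label_image].
#' @export
label_from_scene <- function(cube, class_id, class_names) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(cube$mask)) stop("cube has no mask; run background_mask() first")
  class_id <- as.integer(class_id)
  if (class_id < 1L) stop("class_id must be >= 1; 0 is reserved for background")
  lab <- matrix(0L, nrow(cube$mask), ncol(cube$mask))
  lab[cube$mask] <- class_id
  label_image(lab, class_names)
}
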