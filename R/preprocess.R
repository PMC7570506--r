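#' Background mask by band arithmetic
#'
#' Subtracts a low-reflectance band image from a high-reflectance band image
#' and thresholds the difference: sample pixels contrast strongly against the
#' support (white tile or stage) in the difference image. Presets used for
#' the two scenarios: sweets 957 / 1496 nm with threshold 0.22; salmon
#' 944 / 1450 nm with threshold 0.2.
#'
#' @param cube a [hypercube].
#' @param high_nm wavelength (nm) of the high-reflectance band.
#' @param low_nm wavelength (nm) of the low-reflectance band.
#' @param threshold reflectance-difference threshold; pixels with
#'   `R[high] - R[low] > threshold` become foreground.
#' @return The cube with `$mask` set (invisibly also returned). An empty
#'   mask raises a warning, not an error.
#' @export
background_mask <- function(cube, high_nm, low_nm, threshold) {
  stopifnot(inherits(cube, "hypercube"))
  hi <- band_index(cube$wavelengths, high_nm)
  lo <- band_index(cube$wavelengths, low_nm)
  diffimg <- cube$data[, , hi] - cube$data[, , lo]
  mask <- diffimg > threshold
  if (!any(mask))
    warning("background_mask produced an empty foreground (threshold ",
            threshold, ")")
  cube$mask <- mask
  cube
}

#' Standard normal variate
#'
#' Centers each spectrum and scales it to unit sample standard deviation,
#' removing per-pixel multiplicative scatter and additive offsets.
#'
#' @param spectra n x p numeric matrix, one spectrum per row, p >= 2.
#' @return Matrix of the same shape; every row has mean 0 and sample
#'   (n-1 denominator) standard deviation 1.
#' @export
snv <- function(spectra) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) < 2L) stop("SNV needs at least 2 spectral variables")
  mu <- rowMeans(spectra)
  centered <- spectra - mu
  sds <- sqrt(rowSums(centered^2) / (ncol(spectra) - 1L))
  bad <- which(sds < 1e-12)
  if (length(bad))
    stop("SNV: near-zero standard deviation in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  centered / sds
}

#' Savitzky-Golay first derivative
#'
#' Per-row first derivative by local polynomial least squares with respect to
#' band index (unit spacing). The (window - 1)/2 bands at each end, where the
#' full window does not fit, are dropped rather than padded, so the output
#' has `p - window + 1` bands.
#'
#' @param spectra n x p matrix, one spectrum per row.
#' @param window odd filter length (default 11).
#' @param polyorder polynomial degree, < window (default 3).
#' @return n x (p - window + 1) matrix of first derivatives at the retained
#'   band centers. The retained feature indices are attached as attribute
#'   `"kept"`.
#' @export
sg_first_derivative <- function(spectra, window = 11L, polyorder = 3L) {
  spectra <- as.matrix(spectra)
  p <- ncol(spectra)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be < `window`")
  if (p < window)
    stop("spectrum has ", p, " bands; need at least window = ", window)
  # derivative coefficients for the window center (m = 1 differentiation)
  coef <- signal::sgolay(p = polyorder, n = window, m = 1L)
  h <- (window - 1L) %/% 2L
  w <- as.numeric(coef[h + 1L, ])
  pp <- p - window + 1L
  out <- matrix(0, nrow(spectra), pp)
  for (j in seq_len(window))
    out <- out + spectra[, j:(j + pp - 1L), drop = FALSE] * w[j]
  attr(out, "kept") <- (h + 1L):(p - h)
  out
}

#' Fit an external parameter orthogonalization model
#'
#' Estimates the parasitic ("interference") subspace from a set of spectra
#' that vary only through the external factor (e.g. the per-sample mean
#' spectra of the training fillets), as the leading right singular vectors
#' of the column-centered interference matrix, and builds the projector
#' `P = I - V V'` onto its orthogonal complement.
#'
#' @param interference_spectra m x p matrix of interference spectra.
#' @param n_components number of parasitic directions c, 1 <= c <= m.
#' @return An `epo_model`: list with `interference_loadings` (p x c,
#'   orthonormal), `n_components` and `projection` (p x p, symmetric,
#'   idempotent).
#' @export
epo_fit <- function(interference_spectra, n_components = 1L) {
  D <- as.matrix(interference_spectra)
  c_ <- as.integer(n_components)
  if (c_ < 1L) stop("n_components must be >= 1")
  if (nrow(D) < c_) stop("need at least n_components interference spectra")
  Dc <- sweep(D, 2L, colMeans(D))
  sv <- svd(Dc)
  rank <- sum(sv$d > max(dim(Dc)) * .Machine$double.eps * max(sv$d, 1))
  if (c_ > rank)
    stop("n_components = ", c_, " exceeds the rank (", rank,
         ") of the centered interference matrix")
  V <- sv$v[, seq_len(c_), drop = FALSE]
  P <- diag(ncol(D)) - V %*% t(V)
  structure(list(interference_loadings = V, n_components = c_,
                 projection = P),
            class = "epo_model")
}

#' Apply an EPO model
#'
#' Projects spectra onto the orthogonal complement of the parasitic subspace:
#' `X P`. Corrected spectra are orthogonal to the interference directions,
#' so adding any amount of interference to a spectrum does not change its
#' EPO output.
#'
#' @param spectra n x p matrix.
#' @param model an `epo_model` fitted on p bands.
#' @return n x p matrix of corrected spectra.
#' @export
epo_apply <- function(spectra, model) {
  stopifnot(inherits(model, "epo_model"))
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != nrow(model$projection))
    stop("spectra have ", ncol(spectra), " bands; EPO model expects ",
         nrow(model$projection))
  spectra %*% model$projection
}

# ---- preprocessing chains ----------------------------------------------

#' Preprocessing chain steps
#'
#' A chain is an ordered list of named steps applied to unfolded spectra:
#' `pp_snv()`, `pp_sg(window, polyorder)` and `pp_epo(model)`. The fitted
#' EPO state travels with the chain so training and test spectra always see
#' identical operators. `pp_chain()` bundles steps; `apply_chain()` runs
#' them in order.
#'
#' @param window,polyorder Savitzky-Golay parameters.
#' @param model a fitted `epo_model`.
#' @param ... chain steps, applied left to right.
#' @return `pp_chain()` returns a `pp_chain` object; step constructors
#'   return single steps.
#' @name pp_chain
NULL

#' @rdname pp_chain
#' @export
pp_snv <- function() structure(list(name = "snv", params = list()),
                               class = "pp_step")

#' @rdname pp_chain
#' @export
pp_sg <- function(window = 11L, polyorder = 3L)
  structure(list(name = "sg_derivative",
                 params = list(window = as.integer(window),
                               polyorder = as.integer(polyorder))),
            class = "pp_step")

#' @rdname pp_chain
#' @export
pp_epo <- function(model) {
  stopifnot(inherits(model, "epo_model"))
  structure(list(name = "epo", params = list(model = model)),
            class = "pp_step")
}

#' @rdname pp_chain
#' @export
pp_chain <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && is.list(steps[[1L]]) &&
      !inherits(steps[[1L]], "pp_step"))
    steps <- steps[[1L]]
  ok <- vapply(steps, inherits, logical(1L), what = "pp_step")
  if (!all(ok)) stop("all chain elements must be pp_* steps")
  structure(list(steps = steps), class = "pp_chain")
}

#' @export
print.pp_chain <- function(x, ...) {
  if (!length(x$steps)) {
    cat("<pp_chain> identity (no steps)\n")
    return(invisible(x))
  }
  desc <- vapply(x$steps, function(s) {
    if (s$name == "sg_derivative")
      sprintf("sg_derivative(window=%d, polyorder=%d)",
              s$params$window, s$params$polyorder)
    else if (s$name == "epo")
      sprintf("epo(c=%d)", s$params$model$n_components)
    else s$name
  }, character(1L))
  cat("<pp_chain>", paste(desc, collapse = " -> "), "\n")
  invisible(x)
}

#' Apply a preprocessing chain
#'
#' @param spectra n x p matrix of raw spectra.
#' @param chain a [pp_chain] (empty chain = identity).
#' @return Preprocessed matrix; the surviving feature indices relative to
#'   the input axis are attached as attribute `"kept"` (derivative steps
#'   shrink the axis).
#' @export
apply_chain <- function(spectra, chain) {
  stopifnot(inherits(chain, "pp_chain"))
  out <- as.matrix(spectra)
  kept <- seq_len(ncol(out))
  for (i in seq_along(chain$steps)) {
    s <- chain$steps[[i]]
    attr(out, "kept") <- NULL  # arithmetic can carry a stale attribute over
    out <- tryCatch(
      switch(s$name,
             snv = snv(out),
             sg_derivative = sg_first_derivative(out, s$params$window,
                                                 s$params$polyorder),
             epo = epo_apply(out, s$params$model),
             stop("unknown step: ", s$name)),
      error = function(e)
        stop("chain step ", i, " (", s$name, "): ", conditionMessage(e),
             call. = FALSE))
    if (!is.null(attr(out, "kept"))) kept <- kept[attr(out, "kept")]
  }
  attr(out, "kept") <- kept
  out
}

#' Serialize / restore a preprocessing chain description
#'
#' `chain_describe()` renders the chain as a plain list (step names and
#' parameters; EPO loadings included as numeric matrices) suitable for JSON
#' via \pkg{jsonlite}; `chain_restore()` rebuilds the chain from it.
#'
#' @param chain a [pp_chain].
#' @param desc a description produced by `chain_describe()` (possibly after
#'   a JSON round trip).
#' @return A list / a [pp_chain].
#' @export
chain_describe <- function(chain) {
  stopifnot(inherits(chain, "pp_chain"))
  lapply(chain$steps, function(s) {
    if (s$name == "epo")
      list(name = "epo",
           n_components = s$params$model$n_components,
           interference_loadings = unclass(s$params$model$interference_loadings))
    else c(list(name = s$name), s$params)
  })
}

#' @rdname chain_describe
#' @export
chain_restore <- function(desc) {
  steps <- lapply(desc, function(d) {
    switch(d$name,
           snv = pp_snv(),
           sg_derivative = pp_sg(d$window, d$polyorder),
           epo = {
             V <- as.matrix(d$interference_loadings)
             qrv <- qr.Q(qr(V))  # restore exact orthonormality after text round trip
             qrv <- qrv * sign(colSums(qrv * V))[col(qrv)]
             m <- structure(list(interference_loadings = qrv,
                                 n_components = as.integer(d$n_components),
                                 projection = diag(nrow(V)) - qrv %*% t(qrv)),
                            class = "epo_model")
             pp_epo(m)
           },
           stop("unknown step in description: ", d$name))
  })
  pp_chain(steps)
}
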