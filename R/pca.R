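#' Fit a principal component analysis model on pixel spectra
#'
#' Mean-centering only (no autoscaling): preprocessing already normalizes
#' scale, and the loadings should describe raw spectral variance. The sign
#' of each loading is fixed so that its element of largest magnitude is
#' positive, making fits reproducible across SVD implementations.
#'
#' @param training a [flat_spectra] or a plain n x p matrix of spectra.
#' @param n_components number of components A,
#'   `<= min(n_pixels - 1, p)`.
#' @return A `pca_model`: list with `mean_spectrum` (p), `loadings`
#'   (p x A, orthonormal columns) and `explained_variance_ratio` (A,
#'   non-increasing fractions of total variance).
#' @export
pca_fit <- function(training, n_components) {
  X <- if (inherits(training, "flat_spectra")) training$values else as.matrix(training)
  n <- nrow(X); p <- ncol(X)
  A <- as.integer(n_components)
  if (A < 1L || A > min(n - 1L, p))
    stop("n_components must be in [1, min(n_pixels - 1, p)] = [1, ",
         min(n - 1L, p), "]")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  totvar <- sum(Xc^2)
  if (totvar < 1e-24) stop("degenerate input: zero variance")
  sv <- svd(Xc, nu = 0L, nv = A)
  V <- sv$v
  # sign convention: largest-magnitude element of each loading is positive
  for (j in seq_len(A)) {
    jm <- which.max(abs(V[, j]))
    if (V[jm, j] < 0) V[, j] <- -V[, j]
  }
  evr <- (sv$d[seq_len(A)]^2) / totvar
  structure(list(mean_spectrum = mu, loadings = V,
                 explained_variance_ratio = evr),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d bands, %d components (%.1f%% variance)\n",
              length(x$mean_spectrum), ncol(x$loadings),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project spectra onto PCA loadings
#'
#' @param spectra n x p matrix (same feature axis as the training spectra).
#' @param model a `pca_model`.
#' @param d number of score columns to return (default: all fitted).
#' @return n x d score matrix `(X - mean) %*% loadings[, 1:d]`.
#' @export
pca_transform <- function(spectra, model, d = ncol(model$loadings)) {
  stopifnot(inherits(model, "pca_model"))
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(model$mean_spectrum))
    stop("spectra have ", ncol(spectra), " features; PCA model expects ",
         length(model$mean_spectrum))
  d <- as.integer(d)
  if (d > ncol(model$loadings)) stop("d exceeds the fitted component count")
  sweep(spectra, 2L, model$mean_spectrum) %*% model$loadings[, seq_len(d), drop = FALSE]
}

#' Score-image stack for a hypercube
#'
#' Unfolds the foreground of a cube, applies the (already fitted)
#' preprocessing chain used at training time, projects onto the first `d`
#' PC loadings and refolds the scores into a (rows, cols, d) image stack.
#' Background pixels carry 0.
#'
#' @param cube a masked [hypercube].
#' @param model a `pca_model` fitted on chain-preprocessed training spectra.
#' @param d number of score images.
#' @param chain the [pp_chain] used at training time (default: identity).
#' @return Array (rows, cols, d) of PC scores, 0 on background.
#' @export
pca_project <- function(cube, model, d, chain = pp_chain()) {
  stopifnot(inherits(cube, "hypercube"))
  flat <- unfold(cube, use_mask = !is.null(cube$mask))
  Xp <- apply_chain(flat$values, chain)
  scores <- pca_transform(Xp, model, d)
  refold(flat, scores, fill = 0)
}
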