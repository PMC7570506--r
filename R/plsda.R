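#' Fit a PLS2 discriminant analysis model
#'
#' One-hot encodes the class labels and extracts latent variables by NIPALS
#' PLS2 with X-deflation: at each step the X-weight is the dominant left
#' singular vector of the cross-product `X'Y`, scores are `t = X w`, and X
#' is deflated by its rank-one reconstruction. X and Y are mean-centered
#' only. With as many latent variables as the rank of X, the predictions
#' coincide with ordinary least squares on the one-hot indicator matrix.
#'
#' @param X n x p matrix of (preprocessed) spectra.
#' @param labels length-n integer or factor class labels (>= 2 classes).
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @return A `plsda_model`: centering vectors, per-LV weights / loadings
#'   (`W`, `P`, `Q`), `regression_coefficients` (p x C, for the full n_lv)
#'   and `class_names`. Class assignment is by argmax over the C predicted
#'   indicator columns.
#' @export
plsda_fit <- function(X, labels, n_lv) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  f <- factor(labels)
  class_names <- levels(f)
  C <- nlevels(f)
  if (C < 2L) stop("need at least 2 classes")
  A <- as.integer(n_lv)
  if (A < 1L || A > min(n - 1L, p))
    stop("n_lv must be in [1, min(n - 1, p)]")
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), as.integer(f))] <- 1
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2L, x_mean)
  Yc <- sweep(Y, 2L, y_mean)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, C, A)
  for (a in seq_len(A)) {
    S <- crossprod(Xc, Yc)                 # p x C
    w <- svd(S, nu = 1L, nv = 0L)$u[, 1L]
    tt <- Xc %*% w
    t2 <- sum(tt^2)
    if (t2 < 1e-12 * n)
      stop("n_lv = ", A, " exceeds the effective rank of X (failed at LV ",
           a, ")")
    pl <- crossprod(Xc, tt) / t2
    ql <- crossprod(Yc, tt) / t2
    Xc <- Xc - tt %*% t(pl)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- ql
  }
  B <- plsda_coefficients(W, P, Q, A)
  structure(list(n_lv = A, x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, Q = Q,
                 regression_coefficients = B,
                 class_names = class_names),
            class = "plsda_model")
}

# B_a = W_a (P_a' W_a)^{-1} Q_a'  (standard PLS2 coefficient identity)
plsda_coefficients <- function(W, P, Q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  Qa <- Q[, seq_len(a), drop = FALSE]
  Wa %*% solve(crossprod(Pa, Wa), t(Qa))
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d LVs, %d features, classes: %s\n",
              x$n_lv, length(x$x_mean), paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Predict from a PLSDA model
#'
#' @param object a `plsda_model`.
#' @param newdata n x p matrix on the model's feature axis.
#' @param n_lv number of latent variables to use (default: all fitted).
#' @param type `"class"` for argmax labels, `"response"` for the predicted
#'   indicator matrix.
#' @param ... unused.
#' @return Factor of class labels, or an n x C numeric matrix.
#' @export
predict.plsda_model <- function(object, newdata, n_lv = object$n_lv,
                                type = c("class", "response"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object$x_mean))
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > object$n_lv)
    stop("n_lv must be in [1, ", object$n_lv, "]")
  B <- if (n_lv == object$n_lv) object$regression_coefficients
       else plsda_coefficients(object$W, object$P, object$Q, n_lv)
  Yhat <- sweep(newdata, 2L, object$x_mean) %*% B
  Yhat <- sweep(Yhat, 2L, object$y_mean, `+`)
  colnames(Yhat) <- object$class_names
  if (type == "response") return(Yhat)
  factor(object$class_names[max.col(Yhat, ties.method = "first")],
         levels = object$class_names)
}

#' Choose the number of latent variables by venetian-blinds cross-validation
#'
#' Observations are dealt into `n_splits` interleaved folds by index modulo
#' the fold count (the "blinds"). For each fold, a PLSDA model is fitted on
#' the remaining observations and the held-out accuracy is recorded for
#' every LV count up to `max_lv`. The chosen model size is the smallest LV
#' count whose cross-validated accuracy is within `tol` of the curve
#' maximum: the accuracy typically rises rapidly over the first few LVs and
#' then flattens, and the elbow is where extra LVs stop paying.
#'
#' @param X n x p matrix.
#' @param labels length-n class labels.
#' @param max_lv largest LV count to scan.
#' @param n_splits number of interleaved folds (>= 2, default 10).
#' @param tol accuracy tolerance (fraction) for "within reach of the
#'   maximum"; default 0.005 (half a percentage point).
#' @return List with `n_lv` (chosen count) and `curve` (CV accuracy per LV
#'   count, fractions).
#' @export
select_lvs_venetian <- function(X, labels, max_lv, n_splits = 10L,
                                tol = 0.005) {
  X <- as.matrix(X)
  f <- factor(labels)
  n <- nrow(X)
  n_splits <- as.integer(n_splits)
  if (n_splits < 2L) stop("n_splits must be >= 2")
  max_lv <- as.integer(max_lv)
  if (max_lv < 1L) stop("max_lv must be >= 1")
  fold <- (seq_len(n) - 1L) %% n_splits + 1L
  for (s in seq_len(n_splits))
    if (nlevels(droplevels(f[fold != s])) < nlevels(f))
      stop("venetian-blinds split ", s, " leaves a training set missing a ",
           "class; use fewer splits or more observations per class")
  correct <- numeric(max_lv)
  for (s in seq_len(n_splits)) {
    tr <- fold != s
    fit <- plsda_fit(X[tr, , drop = FALSE], f[tr], max_lv)
    for (a in seq_len(max_lv)) {
      pred <- predict(fit, X[!tr, , drop = FALSE], n_lv = a)
      correct[a] <- correct[a] + sum(pred == f[!tr])
    }
  }
  curve <- correct / n
  n_lv <- which(curve >= max(curve) - tol)[1L]
  list(n_lv = n_lv, curve = curve)
}
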