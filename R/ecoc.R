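#' Default binary max-margin learner for ECOC
#'
#' Wraps a linear support vector machine (\pkg{e1071}, libsvm) as the
#' pluggable binary learner: given features and labels in \{-1, +1\}, it
#' returns a function mapping new rows to signed decision values (positive
#' means class +1).
#'
#' @param kernel,cost passed to [e1071::svm()]; defaults linear, C = 1.
#' @return A function `(X, y)` returning a prediction closure.
#' @export
svm_binary_learner <- function(kernel = "linear", cost = 1) {
  function(X, y) {
    yf <- factor(y, levels = c(-1, 1))
    fit <- e1071::svm(X, yf, kernel = kernel, cost = cost, scale = FALSE)
    # libsvm's decision-value sign follows its internal label order; align it
    # so positive values mean class +1
    dv_tr <- attr(stats::predict(fit, X, decision.values = TRUE),
                  "decision.values")[, 1L]
    flip <- if (sum(sign(dv_tr) == y) >= sum(sign(dv_tr) == -y)) 1 else -1
    function(newX) {
      flip * attr(stats::predict(fit, newX, decision.values = TRUE),
                  "decision.values")[, 1L]
    }
  }
}

ecoc_codebook <- function(C, coding) {
  if (coding == "one-vs-all") {
    M <- matrix(-1, C, C)
    diag(M) <- 1
  } else {
    pairs <- utils::combn(C, 2L)
    M <- matrix(0, C, ncol(pairs))
    for (b in seq_len(ncol(pairs))) {
      M[pairs[1L, b], b] <- 1
      M[pairs[2L, b], b] <- -1
    }
  }
  M
}

#' Multiclass classification by error-correcting output codes
#'
#' Encodes a C-class problem as B binary problems (one-vs-one: C(C-1)/2
#' dichotomies with the unused classes coded 0 and excluded; one-vs-all: C
#' dichotomies), fits the pluggable binary learner on each, and decodes
#' test decisions against the class codewords with loss-weighted (hinge)
#' Hamming distance. With C = 2 either coding reduces to the single binary
#' classifier.
#'
#' @param X n x p feature matrix.
#' @param labels length-n class labels (>= 2 classes).
#' @param coding `"one-vs-one"` (default) or `"one-vs-all"`.
#' @param learner binary learner factory, default [svm_binary_learner()].
#' @return An `ecoc_model` with the codebook, fitted binary classifiers and
#'   class names.
#' @export
ecoc_fit <- function(X, labels, coding = c("one-vs-one", "one-vs-all"),
                     learner = svm_binary_learner()) {
  coding <- match.arg(coding)
  X <- as.matrix(X)
  f <- factor(labels)
  C <- nlevels(f)
  if (C < 2L) stop("need at least 2 classes")
  M <- ecoc_codebook(C, coding)
  cls <- as.integer(f)
  fits <- vector("list", ncol(M))
  for (b in seq_len(ncol(M))) {
    y <- M[cls, b]
    keep <- y != 0
    fits[[b]] <- learner(X[keep, , drop = FALSE], y[keep])
  }
  structure(list(codebook = M, binary_fits = fits,
                 coding = coding, class_names = levels(f)),
            class = "ecoc_model")
}

#' @export
print.ecoc_model <- function(x, ...) {
  cat(sprintf("<ecoc_model> %s coding, %d binary classifiers, classes: %s\n",
              x$coding, length(x$binary_fits),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Predict classes from an ECOC model
#'
#' Each class is scored by the hinge-loss-weighted distance between its
#' codeword and the vector of binary decision values; the class with the
#' smallest loss wins. Exact ties go to the lowest class index and are
#' counted in the `"ties"` attribute.
#'
#' @param object an `ecoc_model`.
#' @param newdata n x p matrix.
#' @param ... unused.
#' @return Factor of predicted labels with a `"ties"` attribute.
#' @export
predict.ecoc_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  B <- length(object$binary_fits)
  n <- nrow(newdata)
  F <- matrix(0, n, B)
  for (b in seq_len(B)) F[, b] <- object$binary_fits[[b]](newdata)
  M <- object$codebook
  C <- nrow(M)
  loss <- matrix(0, n, C)
  for (cc in seq_len(C)) {
    active <- M[cc, ] != 0
    H <- pmax(1 - sweep(F[, active, drop = FALSE], 2L, M[cc, active], `*`), 0)
    loss[, cc] <- rowSums(H) / sum(active)
  }
  pick <- max.col(-loss, ties.method = "first")
  ties <- sum(apply(loss, 1L, function(r) sum(r == min(r)) > 1L))
  out <- factor(object$class_names[pick], levels = object$class_names)
  attr(out, "ties") <- ties
  out
}
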