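#' 2-D CNN architecture on PC score patches
#'
#' Layer stack: input (k x k x d score patch) -> strided convolution ->
#' ReLU -> max pooling -> dropout -> fully connected -> softmax. Defaults
#' follow the reference architecture: 20 feature maps of size 5 x 5 with
#' stride (2, 2), 2 x 2 max pooling with stride 2, one FC layer to the
#' class logits.
#'
#' @param k odd patch window size.
#' @param d feature depth (number of PC score images).
#' @param n_classes number of classes C.
#' @param n_filters,filter_size,conv_stride convolution hyperparameters.
#' @param pool_size,pool_stride max-pooling hyperparameters.
#' @param dropout dropout rate applied before the FC layer.
#' @return A `cnn_spec_2d` object.
#' @export
cnn2d_spec <- function(k, d, n_classes, n_filters = 20L, filter_size = 5L,
                       conv_stride = 2L, pool_size = 2L, pool_stride = 2L,
                       dropout = 0.5) {
  structure(list(k = as.integer(k), d = as.integer(d),
                 n_classes = as.integer(n_classes),
                 n_filters = as.integer(n_filters),
                 filter_size = as.integer(filter_size),
                 conv_stride = as.integer(conv_stride)[1L],
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 dropout = dropout),
            class = "cnn_spec_2d")
}

#' 3-D CNN architecture on spectral-spatial patches
#'
#' Layer stack: input (k x k x bands patch) -> 3-D convolution ->
#' batch normalization -> ReLU -> dropout -> fully connected -> softmax
#' (no pooling layer). Defaults follow the reference architecture: 10
#' feature maps with 3 x 3 x 10 filters at unit stride.
#'
#' @param k odd patch window size.
#' @param bands spectral depth of the input patches.
#' @param n_classes number of classes C.
#' @param n_filters number of 3-D feature maps.
#' @param filter_spatial,filter_spectral filter extent in the two spatial
#'   axes and the spectral axis.
#' @param dropout dropout rate applied before the FC layer.
#' @return A `cnn_spec_3d` object.
#' @export
cnn3d_spec <- function(k, bands, n_classes, n_filters = 10L,
                       filter_spatial = 3L, filter_spectral = 10L,
                       dropout = 0.5) {
  structure(list(k = as.integer(k), bands = as.integer(bands),
                 n_classes = as.integer(n_classes),
                 n_filters = as.integer(n_filters),
                 filter_spatial = as.integer(filter_spatial),
                 filter_spectral = as.integer(filter_spectral),
                 dropout = dropout),
            class = "cnn_spec_3d")
}

#' Training configuration
#'
#' @param learning_rate SGD learning rate (default 0.01).
#' @param epochs number of passes over the training set (default 100); no
#'   early stopping, the last epoch's weights are the model.
#' @param batch_size mini-batch size (default 1024).
#' @param momentum classical momentum coefficient (default 0.9).
#' @param seed mandatory RNG seed controlling initialization, shuffling and
#'   dropout; recorded in the trained network.
#' @param validation optional labelled `patch_set` scored once per epoch.
#' @param standardize divide inputs by the global standard deviation of the
#'   training patches (a single stored scalar; keeps zeros at zero).
#' @param verbose print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 100L,
                         batch_size = 1024L, momentum = 0.9, seed,
                         validation = NULL, standardize = TRUE,
                         verbose = FALSE) {
  if (missing(seed)) stop("`seed` is mandatory for reproducible training")
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed), validation = validation,
                 standardize = isTRUE(standardize),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

conv_out <- function(inp, f, s) (inp - f) %/% s + 1L

# precompute index geometry shared by forward and backward passes
cnn_geometry <- function(spec) {
  if (inherits(spec, "cnn_spec_2d")) {
    k <- spec$k; d <- spec$d; f <- spec$filter_size; s <- spec$conv_stride
    oh <- conv_out(k, f, s)
    if (oh < 1L)
      stop("conv layer output collapses to ", oh, " (k = ", k,
           ", filter = ", f, ", stride = ", s, ")")
    P <- oh * oh
    Fin <- f * f * d
    rel <- integer(Fin * P)
    pos <- 0L
    for (oj in 0:(oh - 1L)) for (oi in 0:(oh - 1L)) {
      orig_r <- oi * s; orig_c <- oj * s
      v <- as.vector(outer(outer(orig_r + 1:f, (orig_c + 1:f - 1L) * k, `+`),
                           (0:(d - 1L)) * (k * k), `+`))
      rel[pos * Fin + seq_len(Fin)] <- v
      pos <- pos + 1L
    }
    pz <- spec$pool_size; ps <- spec$pool_stride
    ph <- conv_out(oh, pz, ps)
    if (ph < 1L)
      stop("pool layer output collapses to ", ph, " (conv grid ", oh,
           ", pool = ", pz, ", stride = ", ps, ")")
    npool <- ph * ph
    gmat <- matrix(0L, pz * pz, npool)
    q <- 0L
    for (qj in 0:(ph - 1L)) for (qi in 0:(ph - 1L)) {
      q <- q + 1L
      cells <- as.vector(outer(qi * ps + 1:pz, (qj * ps + 1:pz - 1L) * oh, `+`))
      gmat[, q] <- cells
    }
    nfeat <- npool * spec$n_filters
    list(kind = "2d", Fin = Fin, P = P, oh = oh, rel = rel,
         ph = ph, npool = npool, gmat = gmat, nfeat = nfeat,
         n_in = k * k * d)
  } else if (inherits(spec, "cnn_spec_3d")) {
    k <- spec$k; nb <- spec$bands
    fs <- spec$filter_spatial; fb <- spec$filter_spectral
    oh <- conv_out(k, fs, 1L)
    ob <- conv_out(nb, fb, 1L)
    if (oh < 1L || ob < 1L)
      stop("3-D conv output collapses (spatial ", oh, ", spectral ", ob, ")")
    P <- oh * oh * ob
    Fin <- fs * fs * fb
    rel <- integer(Fin * P)
    pos <- 0L
    for (obnd in 0:(ob - 1L)) for (oj in 0:(oh - 1L)) for (oi in 0:(oh - 1L)) {
      v <- as.vector(outer(outer(oi + 1:fs, (oj + 1:fs - 1L) * k, `+`),
                           (obnd + 0:(fb - 1L)) * (k * k), `+`))
      rel[pos * Fin + seq_len(Fin)] <- v
      pos <- pos + 1L
    }
    nfeat <- P * spec$n_filters
    list(kind = "3d", Fin = Fin, P = P, oh = oh, ob = ob, rel = rel,
         nfeat = nfeat, n_in = k * k * nb)
  } else stop("unknown spec class")
}

#' Build an untrained network from an architecture spec
#'
#' Checks the layer arithmetic analytically — every convolution/pooling
#' output dimension follows `floor((in - f)/s) + 1` and must stay >= 1 —
#' and reports each layer's output shape and parameter count.
#'
#' @param spec a `cnn_spec_2d` or `cnn_spec_3d`.
#' @return A `cnn_network` with `$shape_report` (data frame) and
#'   uninitialized weights (initialization is seeded and happens in
#'   [cnn_train()]).
#' @export
cnn_build <- function(spec) {
  g <- cnn_geometry(spec)
  C <- spec$n_classes
  if (g$kind == "2d") {
    report <- data.frame(
      layer = c("input", "conv", "relu", "maxpool", "dropout", "fc", "softmax"),
      output = c(sprintf("%dx%dx%d", spec$k, spec$k, spec$d),
                 sprintf("%dx%dx%d", g$oh, g$oh, spec$n_filters),
                 sprintf("%dx%dx%d", g$oh, g$oh, spec$n_filters),
                 sprintf("%dx%dx%d", g$ph, g$ph, spec$n_filters),
                 sprintf("%d", g$nfeat),
                 sprintf("%d", C),
                 sprintf("%d", C)),
      params = c(0L, g$Fin * spec$n_filters + spec$n_filters, 0L, 0L, 0L,
                 g$nfeat * C + C, 0L))
  } else {
    report <- data.frame(
      layer = c("input", "conv3d", "batchnorm", "relu", "dropout", "fc",
                "softmax"),
      output = c(sprintf("%dx%dx%d", spec$k, spec$k, spec$bands),
                 sprintf("%dx%dx%dx%d", g$oh, g$oh, g$ob, spec$n_filters),
                 sprintf("%dx%dx%dx%d", g$oh, g$oh, g$ob, spec$n_filters),
                 sprintf("%dx%dx%dx%d", g$oh, g$oh, g$ob, spec$n_filters),
                 sprintf("%d", g$nfeat),
                 sprintf("%d", C),
                 sprintf("%d", C)),
      params = c(0L, g$Fin * spec$n_filters + spec$n_filters,
                 2L * spec$n_filters, 0L, 0L, g$nfeat * C + C, 0L))
  }
  structure(list(spec = spec, geometry = g, shape_report = report,
                 weights = NULL, class_names = NULL, history = NULL,
                 feature_scale = 1),
            class = "cnn_network")
}

#' @export
print.cnn_network <- function(x, ...) {
  cat(sprintf("<cnn_network> %s, %s\n",
              if (x$geometry$kind == "2d") "2-D (PCA-CNN)" else "3-D",
              if (is.null(x$weights)) "untrained" else "trained"))
  print(x$shape_report, row.names = FALSE)
  invisible(x)
}

glorot <- function(nin, nout, nrow_, ncol_)
  matrix(stats::runif(nrow_ * ncol_, -sqrt(6 / (nin + nout)),
                      sqrt(6 / (nin + nout))), nrow_, ncol_)

cnn_init_weights <- function(net) {
  g <- net$geometry; spec <- net$spec
  nf <- spec$n_filters; C <- spec$n_classes
  w <- list(Wc = glorot(g$Fin, nf, g$Fin, nf),
            bc = numeric(nf),
            Wfc = glorot(g$nfeat, C, g$nfeat, C),
            bfc = numeric(C))
  if (g$kind == "3d") {
    w$gamma <- rep(1, nf); w$beta <- numeric(nf)
    w$run_mean <- numeric(nf); w$run_var <- rep(1, nf)
  }
  w
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

# im2col for a block of flattened patches: returns (n_block * P) x Fin with
# the sample index fastest in the rows (compiled gather; this movement of
# ~n * P * Fin doubles is the hot spot of both CNNs)
im2col <- function(Xb, g) {
  cpp_im2col(Xb, g$rel, g$Fin, g$P)
}

cnn_forward_2d <- function(net, Xb, train = FALSE, Bpre = NULL) {
  g <- net$geometry; spec <- net$spec; w <- net$weights
  n <- nrow(Xb)
  B <- if (is.null(Bpre)) im2col(Xb, g) else Bpre
  Z <- B %*% w$Wc
  Z <- col_affine(Z, rep(1, spec$n_filters), w$bc)
  Rm <- Z > 0
  Zr <- Z * Rm
  A <- Zr; dim(A) <- c(n, g$P, spec$n_filters)
  gm <- g$gmat
  M <- A[, gm[1L, ], , drop = FALSE]
  argm <- array(1L, dim(M))
  if (nrow(gm) > 1L) for (j in 2:nrow(gm)) {
    Cand <- A[, gm[j, ], , drop = FALSE]
    sel <- Cand > M
    M[sel] <- Cand[sel]
    argm[sel] <- j
  }
  H <- M; dim(H) <- c(n, g$nfeat)
  drop_mask <- NULL
  if (train && spec$dropout > 0) {
    drop_mask <- matrix((stats::runif(length(H)) >= spec$dropout) /
                          (1 - spec$dropout), n, g$nfeat)
    H <- H * drop_mask
  }
  logits <- H %*% w$Wfc
  logits <- logits + rep(w$bfc, each = n)
  probs <- softmax_rows(logits)
  list(probs = probs, cache = list(B = B, Rm = Rm, argm = argm, H = H,
                                   drop_mask = drop_mask, n = n))
}

cnn_backward_2d <- function(net, cache, probs, Y) {
  g <- net$geometry; spec <- net$spec; w <- net$weights
  n <- cache$n
  dlog <- (probs - Y) / n
  gWfc <- crossprod(cache$H, dlog)
  gbfc <- colSums(dlog)
  dH <- dlog %*% t(w$Wfc)
  if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
  dM <- dH; dim(dM) <- c(n, g$npool, spec$n_filters)
  dA <- array(0, c(n, g$P, spec$n_filters))
  gm <- g$gmat
  for (j in seq_len(nrow(gm))) {
    contrib <- dM * (cache$argm == j)
    dA[, gm[j, ], ] <- dA[, gm[j, ], , drop = FALSE] + contrib
  }
  dim(dA) <- c(n * g$P, spec$n_filters)
  dA[!cache$Rm] <- 0
  gWc <- crossprod(cache$B, dA)
  gbc <- colSums(dA)
  list(Wc = gWc, bc = gbc, Wfc = gWfc, bfc = gbfc)
}

# 3-D passes chunk the im2col product to bound memory; the chunk im2col is
# recomputed in the backward pass instead of cached.
cnn_conv3d_chunks <- function(n, g) {
  chunk <- max(1L, min(n, as.integer(1e8 / (g$Fin * g$P))))  # ~800 MB im2col cap
  split(seq_len(n), ceiling(seq_len(n) / chunk))
}

# column-wise (per-filter) affine ops on tall (N x nf) matrices; cheaper
# than building N * nf recycling vectors
col_center_scale <- function(Z, mu, sc) {
  for (f in seq_len(ncol(Z))) Z[, f] <- (Z[, f] - mu[f]) * sc[f]
  Z
}
col_affine <- function(Z, a, b) {
  for (f in seq_len(ncol(Z))) Z[, f] <- Z[, f] * a[f] + b[f]
  Z
}

cnn_forward_3d <- function(net, Xb, train = FALSE) {
  g <- net$geometry; spec <- net$spec; w <- net$weights
  n <- nrow(Xb); nf <- spec$n_filters
  keepB <- train && as.double(n) * g$P * g$Fin <= 1.5e8
  Bkeep <- if (keepB) vector("list", 0L) else NULL
  Z <- array(0, c(n, g$P, nf))
  for (ix in cnn_conv3d_chunks(n, g)) {
    Bc <- im2col(Xb[ix, , drop = FALSE], g)
    if (keepB) Bkeep[[length(Bkeep) + 1L]] <- Bc
    Zc <- Bc %*% w$Wc
    Zc <- col_affine(Zc, rep(1, nf), w$bc)
    dim(Zc) <- c(length(ix), g$P, nf)
    Z[ix, , ] <- Zc
  }
  dim(Z) <- c(n * g$P, nf)
  eps <- 1e-5
  if (train) {
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2
    invstd <- 1 / sqrt(va + eps)
    Xhat <- col_center_scale(Z, mu, invstd)
    bn_stats <- list(mu = mu, va = va, invstd = invstd)
  } else {
    invstd <- 1 / sqrt(w$run_var + eps)
    Xhat <- col_center_scale(Z, w$run_mean, invstd)
    bn_stats <- NULL
  }
  Y <- col_affine(Xhat, w$gamma, w$beta)
  Rm <- Y > 0
  Yr <- Y * Rm
  H <- Yr; dim(H) <- c(n, g$nfeat)
  drop_mask <- NULL
  if (train && spec$dropout > 0) {
    drop_mask <- matrix((stats::runif(length(H)) >= spec$dropout) /
                          (1 - spec$dropout), n, g$nfeat)
    H <- H * drop_mask
  }
  logits <- H %*% w$Wfc
  logits <- logits + rep(w$bfc, each = n)
  probs <- softmax_rows(logits)
  list(probs = probs,
       cache = list(Xb = Xb, Bkeep = Bkeep, Xhat = Xhat, Rm = Rm, H = H,
                    drop_mask = drop_mask, bn = bn_stats, n = n))
}

cnn_backward_3d <- function(net, cache, probs, Y) {
  g <- net$geometry; spec <- net$spec; w <- net$weights
  n <- cache$n; nf <- spec$n_filters
  dlog <- (probs - Y) / n
  gWfc <- crossprod(cache$H, dlog)
  gbfc <- colSums(dlog)
  dH <- dlog %*% t(w$Wfc)
  if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
  dYr <- dH; dim(dYr) <- c(n * g$P, nf)
  dYr[!cache$Rm] <- 0
  Xhat <- cache$Xhat
  ggamma <- colSums(dYr * Xhat)
  gbeta <- colSums(dYr)
  N <- nrow(dYr)
  invstd <- cache$bn$invstd
  dZ <- dYr
  for (f in seq_len(nf)) {
    dxh <- dYr[, f] * w$gamma[f]
    dZ[, f] <- (dxh - mean(dxh) - Xhat[, f] * mean(dxh * Xhat[, f])) *
      invstd[f]
  }
  dim(dZ) <- c(n, g$P, nf)
  gWc <- matrix(0, g$Fin, nf)
  gbc <- numeric(nf)
  chunks <- cnn_conv3d_chunks(n, g)
  for (ci in seq_along(chunks)) {
    ix <- chunks[[ci]]
    Bc <- if (!is.null(cache$Bkeep)) cache$Bkeep[[ci]]
          else im2col(cache$Xb[ix, , drop = FALSE], g)
    dZc <- dZ[ix, , , drop = FALSE]
    dim(dZc) <- c(length(ix) * g$P, nf)
    gWc <- gWc + crossprod(Bc, dZc)
    gbc <- gbc + colSums(dZc)
  }
  list(Wc = gWc, bc = gbc, Wfc = gWfc, bfc = gbfc,
       gamma = ggamma, beta = gbeta,
       bn_mu = cache$bn$mu, bn_va = cache$bn$va)
}

cnn_forward <- function(net, Xb, train = FALSE) {
  if (net$geometry$kind == "2d") cnn_forward_2d(net, Xb, train)
  else cnn_forward_3d(net, Xb, train)
}

#' Train a CNN by mini-batch SGD with momentum
#'
#' Deterministic given the seed in `config`: weight initialization
#' (Glorot-uniform), per-epoch shuffling and dropout all draw from one
#' seeded stream, so rerunning with the same configuration reproduces the
#' weights bit for bit. The final model is the last epoch's weights (no
#' early stopping). Per-iteration loss and accuracy are recorded on the
#' training mini-batch; the validation set, when given, is scored once per
#' epoch.
#'
#' @param network an untrained network from [cnn_build()].
#' @param train_patches a labelled `patch_set` (labels in 1..C).
#' @param config a [train_config()].
#' @param class_names optional class names (length C).
#' @return The trained `cnn_network`, with `$weights`, `$history`
#'   (`$iterations` and `$validation` data frames) and `$config`.
#' @export
cnn_train <- function(network, train_patches, config, class_names = NULL) {
  stopifnot(inherits(network, "cnn_network"),
            inherits(train_patches, "patch_set"),
            inherits(config, "train_config"))
  g <- network$geometry; spec <- network$spec
  X <- train_patches$patches
  if (ncol(X) != g$n_in)
    stop("patch feature size ", ncol(X), " does not match the network input ",
         g$n_in)
  yl <- train_patches$labels
  C <- spec$n_classes
  if (any(yl < 1L) || any(yl > C))
    stop("training labels must lie in 1..", C)
  n <- nrow(X)
  set.seed(config$seed)
  if (config$standardize) {
    sc <- stats::sd(X)
    network$feature_scale <- if (is.finite(sc) && sc > 0) sc else 1
  } else network$feature_scale <- 1
  X <- X / network$feature_scale
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), yl)] <- 1
  w <- cnn_init_weights(network)
  network$weights <- w
  vel <- lapply(w[c("Wc", "bc", "Wfc", "bfc",
                    if (g$kind == "3d") c("gamma", "beta"))],
                function(z) z * 0)
  lr <- config$learning_rate; mom <- config$momentum
  # for the 2-D net the im2col expansion of the whole training set fits in
  # memory at these problem sizes; computing it once removes the dominant
  # per-iteration gather cost
  Bfull <- NULL
  if (g$kind == "2d" && as.double(n) * g$P * g$Fin <= 6e7)
    Bfull <- im2col(X, g)
  it_epoch <- integer(0); it_loss <- numeric(0); it_acc <- numeric(0)
  val_loss <- numeric(0); val_acc <- numeric(0)
  has_val <- !is.null(config$validation)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      ix <- perm[s:min(n, s + config$batch_size - 1L)]
      fw <- if (!is.null(Bfull)) {
        rows <- rep(ix, g$P) + rep((0:(g$P - 1L)) * n, each = length(ix))
        cnn_forward_2d(network, X[ix, , drop = FALSE], train = TRUE,
                       Bpre = Bfull[rows, , drop = FALSE])
      } else cnn_forward(network, X[ix, , drop = FALSE], train = TRUE)
      pr <- fw$probs
      loss <- -mean(log(pmax(pr[cbind(seq_along(ix), yl[ix])], 1e-300)))
      if (!is.finite(loss))
        stop("training loss became non-finite at epoch ", ep,
             "; try a smaller learning rate")
      acc <- mean(max.col(pr, ties.method = "first") == yl[ix])
      it_epoch <- c(it_epoch, ep); it_loss <- c(it_loss, loss)
      it_acc <- c(it_acc, acc)
      gr <- if (g$kind == "2d")
        cnn_backward_2d(network, fw$cache, pr, Y[ix, , drop = FALSE])
      else
        cnn_backward_3d(network, fw$cache, pr, Y[ix, , drop = FALSE])
      for (nm in names(vel)) {
        vel[[nm]] <- mom * vel[[nm]] - lr * gr[[nm]]
        network$weights[[nm]] <- network$weights[[nm]] + vel[[nm]]
      }
      if (g$kind == "3d") {
        network$weights$run_mean <- 0.9 * network$weights$run_mean +
          0.1 * gr$bn_mu
        network$weights$run_var <- 0.9 * network$weights$run_var +
          0.1 * gr$bn_va
      }
    }
    if (has_val) {
      vp <- cnn_predict(network, config$validation)
      vy <- config$validation$labels
      vl <- -mean(log(pmax(vp$probs[cbind(seq_along(vy), vy)], 1e-300)))
      va <- mean(vp$class == vy)
      val_loss <- c(val_loss, vl); val_acc <- c(val_acc, va)
      if (config$verbose)
        message(sprintf("epoch %3d  train loss %.4f acc %.4f | val loss %.4f acc %.4f",
                        ep, loss, acc, vl, va))
    } else if (config$verbose) {
      message(sprintf("epoch %3d  train loss %.4f acc %.4f", ep, loss, acc))
    }
  }
  network$class_names <- if (is.null(class_names))
    as.character(seq_len(C)) else as.character(class_names)
  network$history <- list(
    iterations = data.frame(iteration = seq_along(it_loss), epoch = it_epoch,
                            loss = it_loss, accuracy = it_acc),
    validation = data.frame(epoch = seq_along(val_loss), loss = val_loss,
                            accuracy = val_acc))
  network$config <- config[c("learning_rate", "epochs", "batch_size",
                             "momentum", "seed", "standardize")]
  network
}

#' Export training curves as CSV
#'
#' Writes the per-iteration training loss/accuracy and, when a validation
#' set was tracked, the per-epoch validation curve.
#'
#' @param network a trained `cnn_network`.
#' @param path output `.csv` path; the validation curve goes to
#'   `*_validation.csv` beside it.
#' @return `path`, invisibly.
#' @export
write_training_history <- function(network, path) {
  stopifnot(inherits(network, "cnn_network"))
  if (is.null(network$history)) stop("network has no training history")
  utils::write.csv(network$history$iterations, path, row.names = FALSE)
  if (nrow(network$history$validation))
    utils::write.csv(network$history$validation,
                     sub("\\.csv$", "_validation.csv", path),
                     row.names = FALSE)
  invisible(path)
}

#' Per-patch class probabilities and labels
#'
#' Inference pass (dropout off, batch-norm in running-statistics mode);
#' deterministic.
#'
#' @param network a trained `cnn_network`.
#' @param newdata a `patch_set` or an n x (k*k*d) matrix of flattened
#'   patches.
#' @param batch rows scored per forward pass.
#' @param scaled internal: set `FALSE` when `newdata` is already divided by
#'   the stored feature scale.
#' @return List with `class` (integer labels 1..C) and `probs` (n x C, rows
#'   sum to 1).
#' @export
cnn_predict <- function(network, newdata, batch = 4096L, scaled = TRUE) {
  stopifnot(inherits(network, "cnn_network"))
  if (is.null(network$weights)) stop("network is untrained")
  X <- if (inherits(newdata, "patch_set")) newdata$patches else as.matrix(newdata)
  if (ncol(X) != network$geometry$n_in)
    stop("feature size ", ncol(X), " does not match the network input ",
         network$geometry$n_in)
  if (scaled) X <- X / network$feature_scale
  n <- nrow(X)
  probs <- matrix(0, n, network$spec$n_classes)
  for (s in seq(1L, n, by = batch)) {
    e <- min(n, s + batch - 1L)
    probs[s:e, ] <- cnn_forward(network, X[s:e, , drop = FALSE],
                                train = FALSE)$probs
  }
  colnames(probs) <- network$class_names
  list(class = max.col(probs, ties.method = "first"), probs = probs)
}

#' Pixel-wise classification map from a trained CNN
#'
#' Extracts the per-pixel patches from a score-image stack (2-D network) or
#' a preprocessed hypercube (3-D network), scores them, and refolds argmax
#' labels and class probabilities into images. Background pixels are 0.
#'
#' @param network a trained `cnn_network`.
#' @param x score-image stack (rows, cols, d) for a 2-D network, or a
#'   masked [hypercube] for a 3-D network.
#' @param mask logical foreground matrix (taken from the cube if absent).
#' @return List with `map` (a [label_image]) and `probs` (rows x cols x C
#'   array, 0 on background).
#' @export
predict_map <- function(network, x, mask = NULL) {
  stopifnot(inherits(network, "cnn_network"))
  k <- network$spec$k
  if (inherits(x, "hypercube")) {
    if (is.null(mask)) mask <- x$mask
    ps <- extract_patches_3d(x, k)
  } else {
    if (is.null(mask)) stop("`mask` is required for a score-image stack")
    ps <- extract_patches(x, mask, k = k)
  }
  pr <- cnn_predict(network, ps)
  sh <- ps$source_shape
  fl <- flat_spectra(matrix(0, nrow(ps$centers), 1L), ps$centers, sh)
  lab <- refold(fl, matrix(pr$class, ncol = 1L), fill = 0, drop = TRUE)
  probs <- refold(fl, pr$probs, fill = 0)
  list(map = label_image(lab, network$class_names), probs = probs)
}
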