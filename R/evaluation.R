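#' Confusion matrix and per-class rates for pixel classification
#'
#' Compares two label images on the pixels where the truth is labelled
#' (truth > 0). Counts have truth in rows and predictions in columns; each
#' class's TP/FP/FN/TN come from the one-vs-rest reduction. Per-class rates:
#' TPR = TP/(TP+FN) (sensitivity/recall), FNR = FN/(FN+TP),
#' PPV = TP/(TP+FP) (precision). Two false-discovery conventions are
#' reported side by side: `fdr` = FP/(FP+TP) = 1 - PPV (the complement of
#' precision) and `fdr_printed` = FP/(FP+TN) (the false-positive rate, the
#' form some confusion-matrix displays print in the FDR slot); both are
#' kept so no downstream consumer silently diverges. CCR is
#' trace(counts)/sum(counts).
#'
#' @param truth,pred [label_image]s (or integer matrices) of equal shape.
#' @return A `confusion_report`: `counts` (C x C), `per_class` data frame
#'   (tpr, fnr, ppv, fdr, fdr_printed), `ccr` (fraction), `class_names`.
#' @export
confusion <- function(truth, pred) {
  tl <- if (inherits(truth, "label_image")) truth$labels else truth
  pl <- if (inherits(pred, "label_image")) pred$labels else pred
  if (!identical(dim(tl), dim(pl)))
    stop("truth and pred shapes differ")
  cn <- if (inherits(truth, "label_image")) truth$class_names
        else as.character(seq_len(max(tl)))
  C <- length(cn)
  keep <- tl > 0L
  if (!any(keep)) stop("empty evaluation set: no labelled truth pixels")
  tv <- factor(tl[keep], levels = seq_len(C))
  pv <- factor(pl[keep], levels = seq_len(C))
  counts <- table(truth = tv, predicted = pv)
  counts <- matrix(as.integer(counts), C, C,
                   dimnames = list(truth = cn, predicted = cn))
  total <- sum(counts)
  tp <- diag(counts)
  fn <- rowSums(counts) - tp
  fp <- colSums(counts) - tp
  tn <- total - tp - fn - fp
  per_class <- data.frame(
    class = cn,
    tpr = tp / (tp + fn),
    fnr = fn / (fn + tp),
    ppv = tp / (tp + fp),
    fdr = fp / (fp + tp),
    fdr_printed = fp / (fp + tn),
    row.names = NULL)
  structure(list(counts = counts, per_class = per_class,
                 ccr = sum(tp) / total, class_names = cn, n = total),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, digits = 2L, ...) {
  cat(sprintf("<confusion_report> %d pixels, CCR = %.2f%%\n", x$n,
              100 * x$ccr))
  print(x$counts)
  pc <- x$per_class
  pc[-1L] <- lapply(pc[-1L], function(v) round(100 * v, digits))
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Serialize a confusion report
#'
#' @param report a `confusion_report`.
#' @param path target `.json` or `.csv` path (format by extension).
#' @return `path`, invisibly.
#' @export
write_confusion <- function(report, path) {
  stopifnot(inherits(report, "confusion_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(ccr = report$ccr, n = report$n,
           counts = unclass(report$counts),
           class_names = report$class_names,
           per_class = report$per_class),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(report$per_class, path, row.names = FALSE)
  }
  invisible(path)
}

#' Map of misclassified pixels
#'
#' `TRUE` exactly where the truth is labelled and the prediction disagrees;
#' background pixels are never flagged.
#'
#' @param truth,pred [label_image]s (or integer matrices) of equal shape.
#' @return Logical matrix.
#' @export
misclassification_map <- function(truth, pred) {
  tl <- if (inherits(truth, "label_image")) truth$labels else truth
  pl <- if (inherits(pred, "label_image")) pred$labels else pred
  if (!identical(dim(tl), dim(pl))) stop("truth and pred shapes differ")
  tl > 0L & pl != tl
}

# threshold minimizing within-class variance of a continuous sample
# (equivalently maximizing between-class variance); candidates are the
# midpoints between consecutive sorted unique values, so the optimum is exact
otsu_threshold <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) return(u[1L])
  cand <- (u[-1L] + u[-length(u)]) / 2
  vs <- sort(v)
  n <- length(vs)
  csum <- cumsum(vs); csq <- cumsum(vs^2)
  # for each candidate, lower group = values <= cand
  kk <- findInterval(cand, vs)
  within <- vapply(seq_along(cand), function(i) {
    k <- kk[i]
    lo <- csq[k] - csum[k]^2 / k
    hi <- (csq[n] - csq[k]) - (csum[n] - csum[k])^2 / (n - k)
    lo + hi
  }, numeric(1L))
  cand[which.min(within)]
}

#' Two-class ground truth by local thresholding of a score image
#'
#' Mirrors the manual ground-truthing procedure for zebra-striped tissue:
#' the score image (typically PC2) is divided into a grid of tiles and a
#' threshold is chosen per tile, which absorbs slow spatial drift that
#' defeats any single global threshold. Per tile, foreground pixels above
#' the threshold become class 1 and the rest class 2 (flip with
#' `high_is_class1 = FALSE`). In `"auto"` mode the tile threshold minimizes
#' the within-class variance of the tile's foreground values (an automated
#' stand-in for a manually picked optimum); explicit per-tile thresholds
#' may be supplied instead. Tiles without foreground are skipped and
#' reported in the `"skipped_tiles"` attribute.
#'
#' @param score_image numeric matrix (one score image).
#' @param mask logical foreground matrix.
#' @param tile_grid integer (rows, cols) of the tile grid; `c(1, 1)`
#'   reduces to global thresholding.
#' @param thresholds `"auto"` or a numeric r x c matrix of per-tile
#'   thresholds.
#' @param high_is_class1 orientation of the two classes.
#' @param class_names two class names.
#' @return A [label_image] with classes 1..2 on the foreground.
#' @export
local_threshold_truth <- function(score_image, mask, tile_grid = c(2L, 2L),
                                  thresholds = "auto",
                                  high_is_class1 = TRUE,
                                  class_names = c("high", "low")) {
  stopifnot(is.matrix(score_image), identical(dim(score_image), dim(mask)))
  r <- as.integer(tile_grid[1L]); cc <- as.integer(tile_grid[2L])
  auto <- identical(thresholds, "auto")
  if (!auto) {
    thresholds <- matrix(as.numeric(thresholds), r, cc)
  }
  nr <- nrow(score_image); nc <- ncol(score_image)
  row_breaks <- round(seq(0L, nr, length.out = r + 1L))
  col_breaks <- round(seq(0L, nc, length.out = cc + 1L))
  lab <- matrix(0L, nr, nc)
  skipped <- 0L
  for (i in seq_len(r)) for (j in seq_len(cc)) {
    rows <- (row_breaks[i] + 1L):row_breaks[i + 1L]
    cols <- (col_breaks[j] + 1L):col_breaks[j + 1L]
    m <- mask[rows, cols]
    if (!any(m)) { skipped <- skipped + 1L; next }
    vals <- score_image[rows, cols][m]
    thr <- if (auto) otsu_threshold(vals) else thresholds[i, j]
    cls <- ifelse(vals > thr, 1L, 2L)
    if (!high_is_class1) cls <- 3L - cls
    sub <- lab[rows, cols]
    sub[m] <- cls
    lab[rows, cols] <- sub
  }
  out <- label_image(lab, class_names)
  attr(out, "skipped_tiles") <- skipped
  out
}
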