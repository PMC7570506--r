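#' Read a hypercube from disk
#'
#' Supports the ENVI format (ASCII `.hdr` beside a flat binary payload, any
#' of the three band-interleave dialects) and the package's portable RDS
#' container. All dialects load to the same in-memory (rows, cols, bands)
#' layout.
#'
#' @param path path to the `.hdr` (ENVI) or `.rds` (container) file.
#' @param format `"auto"` (by extension), `"envi"` or `"rds"`.
#' @return A [hypercube].
#' @export
read_cube <- function(path, format = c("auto", "envi", "rds")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "envi"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "rds") read_cube_rds(path) else read_cube_envi(path)
}

read_cube_rds <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$wavelengths))
    stop("portable container missing required fields `data`/`wavelengths`")
  hypercube(obj$data, obj$wavelengths, mask = obj$mask, label = obj$label)
}

parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  # join continued brace lists onto single logical lines
  joined <- character(0)
  buf <- ""
  open <- FALSE
  for (ln in txt) {
    if (!open) {
      buf <- ln
      open <- grepl("\\{", ln) && !grepl("\\}", ln)
    } else {
      buf <- paste(buf, ln)
      open <- !grepl("\\}", ln)
    }
    if (!open) joined <- c(joined, buf)
  }
  joined <- joined[grepl("=", joined)]
  keys <- tolower(trimws(sub("=.*$", "", joined)))
  vals <- trimws(sub("^[^=]*=", "", joined))
  stats::setNames(as.list(vals), keys)
}

envi_value <- function(hdr, key) {
  v <- hdr[[key]]
  if (is.null(v))
    stop("ENVI header is missing the required field `", key, "`")
  v
}

envi_numlist <- function(v) {
  v <- gsub("[{}]", "", v)
  as.double(strsplit(v, ",")[[1]])
}

read_cube_envi <- function(hdr_path) {
  hdr <- parse_envi_header(hdr_path)
  samples <- as.integer(envi_value(hdr, "samples"))  # columns
  lines   <- as.integer(envi_value(hdr, "lines"))    # rows
  bands   <- as.integer(envi_value(hdr, "bands"))
  dtype   <- as.integer(envi_value(hdr, "data type"))
  interleave <- tolower(envi_value(hdr, "interleave"))
  byte_order <- as.integer(if (is.null(hdr[["byte order"]])) 0L else hdr[["byte order"]])
  wl <- envi_numlist(envi_value(hdr, "wavelength"))
  if (length(wl) != bands)
    stop("ENVI header declares ", bands, " bands but lists ",
         length(wl), " wavelengths")
  dat_path <- sub("\\.hdr$", ".dat", hdr_path, ignore.case = TRUE)
  if (!file.exists(dat_path))
    stop("ENVI payload not found: ", dat_path)
  n <- samples * lines * bands
  spec <- switch(as.character(dtype),
                 "1"  = list(what = "integer", size = 1L),
                 "2"  = list(what = "integer", size = 2L),
                 "3"  = list(what = "integer", size = 4L),
                 "4"  = list(what = "double",  size = 4L),
                 "5"  = list(what = "double",  size = 8L),
                 "12" = list(what = "integer", size = 2L),
                 stop("unsupported ENVI data type: ", dtype))
  expected_bytes <- n * spec$size
  actual_bytes <- file.size(dat_path)
  if (actual_bytes != expected_bytes)
    stop("ENVI payload size mismatch: header implies ", expected_bytes,
         " bytes (", samples, " x ", lines, " x ", bands,
         "), file has ", actual_bytes)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, spec$what, n = n, size = spec$size,
                 endian = if (byte_order == 1L) "big" else "little",
                 signed = dtype != 12L || spec$size > 2L)
  raw <- as.double(raw)
  # fastest-varying index first, per dialect; then permute to (row, col, band)
  arr <- switch(interleave,
                bsq = aperm(array(raw, c(samples, lines, bands)), c(2L, 1L, 3L)),
                bil = aperm(array(raw, c(samples, bands, lines)), c(3L, 1L, 2L)),
                bip = aperm(array(raw, c(bands, samples, lines)), c(3L, 2L, 1L)),
                stop("unsupported interleave: ", interleave))
  hypercube(arr, wl)
}

#' Write a hypercube to disk
#'
#' @param cube a [hypercube].
#' @param path output path: `.hdr` for ENVI (payload goes to the matching
#'   `.dat`), `.rds` for the portable container.
#' @param format `"auto"`, `"envi"` or `"rds"`.
#' @param interleave ENVI interleave dialect to write.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("auto", "envi", "rds"),
                       interleave = c("bsq", "bil", "bip")) {
  stopifnot(inherits(cube, "hypercube"))
  format <- match.arg(format)
  interleave <- match.arg(interleave)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "envi"
  if (format == "rds") {
    saveRDS(list(data = cube$data, wavelengths = cube$wavelengths,
                 mask = cube$mask, label = cube$label), path)
    return(invisible(path))
  }
  d <- dim(cube$data)
  perm <- switch(interleave,
                 bsq = c(2L, 1L, 3L),
                 bil = c(2L, 3L, 1L),
                 bip = c(3L, 2L, 1L))
  payload <- as.double(aperm(cube$data, perm))
  hdr <- c("ENVI",
           "description = {hsipix hypercube}",
           paste0("samples = ", d[2L]),
           paste0("lines = ", d[1L]),
           paste0("bands = ", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("wavelength units = Nanometers"),
           paste0("wavelength = {",
                  paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
                  "}"))
  writeLines(hdr, path)
  dat_path <- sub("\\.hdr$", ".dat", path, ignore.case = TRUE)
  con <- file(dat_path, "wb")
  on.exit(close(con))
  writeBin(payload, con, size = 8L, endian = "little")
  invisible(path)
}

#' Export a label image as an 8-bit single-band TIFF
#'
#' Labels are written verbatim as 8-bit integers (0 = background); the class
#' table goes to a CSV sidecar so the map stays auditable.
#'
#' @param li a [label_image] with at most 255 classes.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(li, path) {
  stopifnot(inherits(li, "label_image"))
  if (max(li$labels) > 255L) stop("more than 255 classes cannot be 8-bit encoded")
  tiff::writeTIFF(li$labels / 255, path, bits.per.sample = 8L)
  side <- sub("\\.tiff?$", "_classes.csv", path, ignore.case = TRUE)
  utils::write.csv(data.frame(value = seq_along(li$class_names),
                              class = li$class_names),
                   side, row.names = FALSE)
  invisible(path)
}

#' Read back a label TIFF written by [write_label_tiff()]
#' @param path `.tif` path.
#' @return A [label_image].
#' @export
read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  lab <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  side <- sub("\\.tiff?$", "_classes.csv", path, ignore.case = TRUE)
  cn <- if (file.exists(side)) utils::read.csv(side)$class
        else as.character(seq_len(max(lab)))
  label_image(lab, cn)
}
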