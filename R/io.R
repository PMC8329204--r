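# On-disk dialects.
#
# Canonical interchange format: 16-page grayscale 32-bit float TIFF, pages
# in row-major Mueller-element order M00..M33, plus a JSON sidecar carrying
# the acquisition metadata.  TIFF float samples are stored affinely coded
# into [0, 1] (per-page lo/hi recorded in the sidecar), so coefficients of
# any sign survive writers that clamp to the unit range; round trips are
# exact to float32 precision.
#
# Exact container: a single-file binary array ("<path>.mmraw"): one JSON
# header line followed by the 16 planes as little-endian float64.  Round
# trips are bit-identical.

.sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a Mueller image as multi-page float TIFF
#'
#' @param img a [mueller_image].
#' @param path TIFF file path; the JSON sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_mueller_tiff()` returns `path` invisibly;
#'   `read_mueller_tiff()` returns a [mueller_image].
#' @seealso [write_mueller_raw()] for bit-exact storage.
#' @export
write_mueller_tiff <- function(img, path) {
  stopifnot(inherits(img, "mueller_image"))
  d <- dim(img)
  pages <- vector("list", 16L)
  lo <- numeric(16L); hi <- numeric(16L)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {   # row-major element order M00..M33
    k <- k + 1L
    p <- img$coefficients[, , i, j]
    dim(p) <- d
    lo[k] <- min(p); hi[k] <- max(p)
    if (hi[k] <= lo[k]) hi[k] <- lo[k] + 1
    pages[[k]] <- (p - lo[k]) / (hi[k] - lo[k])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(format = "lmmd-mueller-tiff", version = 1L,
               wavelength_nm = img$wavelength,
               pixel_pitch_mm = img$pixel_pitch,
               label = img$label,
               page_order = "row-major M00..M33",
               encoding = list(lo = lo, hi = hi))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mueller_tiff
#' @export
read_mueller_tiff <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 16L)
    stop("format error: expected 16 pages (Mueller elements M00..M33), ",
         "got ", length(pages))
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("format error: page shapes differ across the 16 planes")
  h <- dims[[1]][1]; w <- dims[[1]][2]

  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    lo <- meta$encoding$lo; hi <- meta$encoding$hi
    if (length(lo) != 16L || length(hi) != 16L)
      stop("format error: sidecar encoding must give 16 lo/hi pairs")
  } else {
    meta <- list(wavelength_nm = 533, pixel_pitch_mm = NA_real_,
                 label = "")
    lo <- rep(0, 16L); hi <- rep(1, 16L)   # pages taken as stored
  }

  a <- array(0, c(h, w, 4L, 4L))
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    a[, , i, j] <- pages[[k]] * (hi[k] - lo[k]) + lo[k]
  }
  mueller_image(a, wavelength = meta$wavelength_nm,
                pixel_pitch = if (is.null(meta$pixel_pitch_mm)) NA_real_
                              else meta$pixel_pitch_mm,
                label = if (is.null(meta$label)) "" else meta$label,
                passivity = "none")
}

#' Write / read a Mueller image as an exact binary container
#'
#' Single file: one JSON header line (dimensions and metadata) terminated
#' by a newline, then the 16 coefficient planes in row-major element order
#' as little-endian float64.  Round trips are bit-identical.
#'
#' @param img a [mueller_image].
#' @param path output path (conventional extension `.mmraw`).
#' @return `write_mueller_raw()` returns `path` invisibly;
#'   `read_mueller_raw()` returns a [mueller_image].
#' @export
write_mueller_raw <- function(img, path) {
  stopifnot(inherits(img, "mueller_image"))
  d <- dim(img)
  hdr <- jsonlite::toJSON(list(format = "lmmd-mueller-raw", version = 1L,
                               height = d[1], width = d[2],
                               wavelength_nm = img$wavelength,
                               pixel_pitch_mm = img$pixel_pitch,
                               label = img$label,
                               page_order = "row-major M00..M33"),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(as.character(hdr), "\n")), con)
  for (i in 1:4) for (j in 1:4) {
    p <- img$coefficients[, , i, j]
    writeBin(as.vector(p), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_mueller_raw
#' @export
read_mueller_raw <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_bytes <- raw()
  repeat {
    b <- readBin(con, "raw", 1L)
    if (!length(b)) stop("format error: missing header terminator")
    if (b == charToRaw("\n")) break
    hdr_bytes <- c(hdr_bytes, b)
  }
  meta <- jsonlite::fromJSON(rawToChar(hdr_bytes))
  if (is.null(meta$height) || is.null(meta$width))
    stop("format error: header lacks image dimensions")
  h <- meta$height; w <- meta$width
  a <- array(0, c(h, w, 4L, 4L))
  for (i in 1:4) for (j in 1:4) {
    v <- readBin(con, "numeric", h * w, size = 8L, endian = "little")
    if (length(v) != h * w)
      stop("format error: truncated plane data at element M",
           i - 1, j - 1)
    a[, , i, j] <- v
  }
  mueller_image(a, wavelength = meta$wavelength_nm,
                pixel_pitch = if (is.null(meta$pixel_pitch_mm)) NA_real_
                              else meta$pixel_pitch_mm,
                label = if (is.null(meta$label)) "" else meta$label,
                passivity = "none")
}

#' Write named scalar maps as a multi-page float TIFF
#'
#' Stores a set of same-shaped parameter planes (e.g. `R_L`, `alpha22`,
#' `azimuth`) as 32-bit float pages with the same sidecar-coded dialect as
#' [write_mueller_tiff()]; the valid mask, if given, is appended as a
#' final 0/1 page.
#'
#' @param planes named list of H x W numeric matrices.
#' @param path TIFF path.
#' @param mask optional logical H x W matrix.
#' @return `path`, invisibly.
#' @export
write_maps_tiff <- function(planes, path, mask = NULL) {
  stopifnot(is.list(planes), length(planes) >= 1L,
            !is.null(names(planes)))
  nm <- names(planes)
  if (!is.null(mask)) {
    planes <- c(planes, list(valid_mask = mask * 1))
    nm <- c(nm, "valid_mask")
  }
  lo <- numeric(length(planes)); hi <- numeric(length(planes))
  pages <- vector("list", length(planes))
  for (k in seq_along(planes)) {
    p <- planes[[k]]
    p[!is.finite(p)] <- 0
    lo[k] <- min(p); hi[k] <- max(p)
    if (hi[k] <= lo[k]) hi[k] <- lo[k] + 1
    pages[[k]] <- (p - lo[k]) / (hi[k] - lo[k])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(format = "lmmd-maps-tiff", version = 1L,
                            pages = nm,
                            encoding = list(lo = lo, hi = hi)),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
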