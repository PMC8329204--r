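#' Mueller matrix image
#'
#' Container for a per-pixel 4x4 real Mueller matrix field measured (or
#' simulated) in transmission, together with its acquisition metadata.
#' Element \eqn{M_{00}} is the total transmittance, normalized to the
#' incident intensity, so for a physical sample it lies in (0, 1].
#'
#' @param coefficients numeric array of dimension `c(H, W, 4, 4)`
#'   (`[h, w, i, j]`, 1-based row/column indices of the Mueller matrix), or
#'   `c(H, W, 16)` with planes in row-major element order M00, M01, ...,
#'   M33.
#' @param wavelength illumination wavelength in nm.
#' @param pixel_pitch physical size of one pixel in mm, or `NA`.
#' @param label free-text label (e.g. `"day6_lower"`).
#' @param passivity how to treat pixels violating the passivity bound
#'   \eqn{|M_{ij}| \le M_{00}}: `"warn"` (default, appropriate for measured
#'   or noisy data), `"error"` (noiseless synthetic data), or `"none"`.
#'
#' @return an object of class `mueller_image`.
#' @examples
#' a <- array(0, c(2, 2, 4, 4))
#' for (i in 1:4) a[, , i, i] <- 1
#' img <- mueller_image(a, label = "identity")
#' img
#' @export
mueller_image <- function(coefficients, wavelength = 533,
                          pixel_pitch = NA_real_, label = "",
                          passivity = c("warn", "error", "none")) {
  passivity <- match.arg(passivity)
  d <- dim(coefficients)
  if (length(d) == 3L && d[3L] == 16L) {
    coefficients <- array(coefficients, dim = c(d[1L], d[2L], 4L, 4L))
    # planes are row-major M00..M33: plane index k = 4*(i-1) + j maps to
    # [i, j]; array() above filled [ , , i, j] column-major in (i, j), i.e.
    # plane k -> i = ((k-1) %% 4) + 1, j = ((k-1) %/% 4) + 1 -- transpose.
    coefficients <- aperm(coefficients, c(1L, 2L, 4L, 3L))
    d <- dim(coefficients)
  }
  if (length(d) != 4L || d[3L] != 4L || d[4L] != 4L)
    stop("format error: coefficients must be an H x W x 4 x 4 array ",
         "(or H x W x 16 planes); got dimension [",
         paste(d, collapse = ", "), "]")
  if (!is.numeric(coefficients))
    stop("format error: coefficients must be numeric")
  storage.mode(coefficients) <- "double"

  m00 <- coefficients[, , 1L, 1L, drop = FALSE]
  dim(m00) <- d[1:2]
  n_bad_m00 <- sum(m00 <= 0, na.rm = TRUE) + sum(is.na(m00))
  if (n_bad_m00 > 0L)
    warning(n_bad_m00, " pixel(s) have M00 <= 0 or missing; they will be ",
            "invalidated by the decomposition", call. = FALSE)

  if (passivity != "none") {
    amax <- apply(abs(coefficients), c(1L, 2L), max)
    viol <- sum(amax > m00 + 1e-12 & m00 > 0, na.rm = TRUE)
    if (viol > 0L) {
      msg <- paste0(viol, " pixel(s) violate passivity (|M_ij| > M00)")
      if (passivity == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
  }

  structure(list(coefficients = coefficients,
                 wavelength = wavelength,
                 pixel_pitch = pixel_pitch,
                 label = label),
            class = "mueller_image")
}

#' Total transmittance plane of a Mueller image
#'
#' @param x a [mueller_image].
#' @return an H x W numeric matrix of \eqn{M_{00}} values.
#' @export
m00 <- function(x) {
  stopifnot(inherits(x, "mueller_image"))
  d <- dim(x$coefficients)
  out <- x$coefficients[, , 1L, 1L]
  dim(out) <- d[1:2]
  out
}

#' @export
dim.mueller_image <- function(x) dim(x$coefficients)[1:2]

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x)
  m <- m00(x)
  cat("Mueller matrix image", if (nzchar(x$label)) paste0(" '", x$label, "'"),
      "\n", sep = "")
  cat(sprintf("  %d x %d pixels, wavelength %g nm, pixel pitch %s mm\n",
              d[1], d[2], x$wavelength,
              ifelse(is.na(x$pixel_pitch), "?", format(x$pixel_pitch))))
  cat(sprintf("  M00 range: [%.4g, %.4g]; %d pixel(s) with M00 <= 0\n",
              min(m), max(m), sum(m <= 0)))
  invisible(x)
}

#' Pixel validity from total transmittance
#'
#' Flags opaque or empty pixels before decomposition: a pixel is valid when
#' its total transmittance exceeds `m00_floor`.  The matrix logarithm is
#' undefined where \eqn{M_{00} \le 0} and numerically meaningless where the
#' sample is essentially opaque.
#'
#' @param M a [mueller_image].
#' @param m00_floor transmittance floor (default `1e-4`); must be >= 0.
#' @return logical H x W matrix, `TRUE` where the pixel is processable.
#' @export
validity_mask <- function(M, m00_floor = 1e-4) {
  stopifnot(inherits(M, "mueller_image"), m00_floor >= 0)
  m <- m00(M)
  ok <- is.finite(m) & m > m00_floor
  ok
}
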