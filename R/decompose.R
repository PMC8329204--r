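#' Minkowski-symmetry split of a differential Mueller matrix
#'
#' Splits a (field of) 4x4 matrix logarithm(s) `L` into the G-antisymmetric
#' part `L_m` (mean polarization properties: dichroism and retardance) and
#' the G-symmetric part `L_u` (depolarization and isotropic attenuation),
#' where `G = diag(1, -1, -1, -1)` is the Minkowski metric:
#' \deqn{L_m = (L - G L^T G)/2, \qquad L_u = (L + G L^T G)/2.}
#' The split is exact: `L_m + L_u == L`, `G L_m^T G == -L_m` and
#' `G L_u^T G == L_u`.
#'
#' @param L a 4x4 numeric matrix or an `H x W x 4 x 4` array.
#' @return a list with components `L_m` and `L_u` of the same shape as `L`.
#' @examples
#' L <- matrix(0, 4, 4); L[3, 4] <- 0.1; L[4, 3] <- -0.1
#' g_symmetry_split(L)$L_u   # zero: pure retardance is G-antisymmetric
#' @export
g_symmetry_split <- function(L) {
  s <- c(1, -1, -1, -1)
  sign_outer <- outer(s, s)        # (G L^T G)[i,j] = s_i s_j L[j,i]
  if (is.matrix(L)) {
    glg <- sign_outer * t(L)
    return(list(L_m = (L - glg) / 2, L_u = (L + glg) / 2))
  }
  d <- dim(L)
  if (length(d) != 4L || d[3L] != 4L || d[4L] != 4L)
    stop("L must be a 4x4 matrix or an H x W x 4 x 4 array")
  Lt <- aperm(L, c(1L, 2L, 4L, 3L))
  glg <- Lt * rep(sign_outer, each = d[1L] * d[2L])
  list(L_m = (L - glg) / 2, L_u = (L + glg) / 2)
}

#' Per-pixel logarithmic decomposition of a Mueller matrix image
#'
#' Computes the principal matrix logarithm \eqn{L = \ln M} at every valid
#' pixel by eigendecomposition, realifies it (recording the discarded
#' imaginary magnitude), and splits it by Minkowski symmetry into the mean
#' polarization part `L_m` and the depolarization part `L_u` (see
#' [g_symmetry_split()]).  For a medium that is homogeneous along the beam,
#' `L_m` accumulates the mean polarization properties linearly with
#' thickness while `L_u` accumulates their variances (depolarization)
#' quadratically.
#'
#' Pixels are invalidated, not raised, when the logarithm is untrustworthy;
#' the cause is recorded per pixel:
#' \describe{
#'   \item{1}{`M00` at or below `m00_floor` (opaque/empty pixel);}
#'   \item{2}{branch failure: an eigenvalue with zero modulus or on the
#'     closed negative real axis, where the principal logarithm is
#'     undefined;}
#'   \item{3}{numerically defective eigenvector basis;}
#'   \item{4}{discarded imaginary magnitude above `tol_imag`.}
#' }
#'
#' @param M a [mueller_image].
#' @param tol_imag maximum tolerated imaginary magnitude discarded when
#'   realifying the logarithm.  Default `1e-6`, suitable for noiseless
#'   synthetic data; use ~`1e-2` for measured (noisy) images.
#' @param m00_floor transmittance floor passed to [validity_mask()].
#' @return an object of class `lmmd_decomposition`: list with per-pixel
#'   arrays `L`, `L_m`, `L_u` (`H x W x 4 x 4`), matrices `imag_residual`
#'   and `invalid_code` (`H x W`), logical `valid_mask`, and the image
#'   metadata.
#' @seealso [extract_maps()] for the scalar parameter maps.
#' @examples
#' a <- array(0, c(4, 4, 4, 4))
#' for (i in 1:4) a[, , i, i] <- 1
#' dec <- matrix_log_field(mueller_image(a))
#' max(abs(dec$L))     # log of identity is 0
#' @export
matrix_log_field <- function(M, tol_imag = 1e-6, m00_floor = 1e-4) {
  stopifnot(inherits(M, "mueller_image"))
  if (!(is.numeric(tol_imag) && length(tol_imag) == 1L && tol_imag > 0))
    stop("tol_imag must be a positive scalar")
  d <- dim(M$coefficients)
  h <- d[1L]; w <- d[2L]

  mask0 <- validity_mask(M, m00_floor)
  code <- matrix(0L, h, w)
  code[!mask0] <- 1L

  L <- array(0, dim = c(h, w, 4L, 4L))
  resid <- matrix(0, h, w)

  idx <- which(mask0)
  if (length(idx)) {
    cols <- .array_to_cols(M$coefficients)[, idx, drop = FALSE]
    res <- cpp_field_logm(cols, tol_imag)
    code[idx] <- res$code
    resid[idx] <- res$imag_residual
    # scatter the 16 log coefficients back into the (H, W, 4, 4) array
    Lc <- res$L                                     # 16 x n_valid
    for (k in seq_len(16L)) {
      i <- ((k - 1L) %% 4L) + 1L
      j <- ((k - 1L) %/% 4L) + 1L
      plane <- matrix(0, h, w)
      plane[idx] <- Lc[k, ]
      L[, , i, j] <- plane
    }
  }

  valid <- code == 0L
  if (!any(valid)) {
    tab <- table(factor(code, levels = 1:4,
                        labels = c("non-positive M00", "branch failure",
                                   "defective basis", "imag residual > tol")))
    stop("all pixels invalid; causes: ",
         paste(names(tab), tab, sep = " = ", collapse = ", "))
  }

  sp <- g_symmetry_split(L)
  structure(list(L = L, L_m = sp$L_m, L_u = sp$L_u,
                 imag_residual = resid,
                 invalid_code = code,
                 valid_mask = valid,
                 tol_imag = tol_imag, m00_floor = m00_floor,
                 wavelength = M$wavelength,
                 pixel_pitch = M$pixel_pitch,
                 label = M$label),
            class = "lmmd_decomposition")
}

#' @export
print.lmmd_decomposition <- function(x, ...) {
  d <- dim(x$valid_mask)
  n <- prod(d)
  cat("Logarithmic Mueller matrix decomposition",
      if (nzchar(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  cat(sprintf("  %d x %d pixels, %d valid (%.1f%%)\n", d[1], d[2],
              sum(x$valid_mask), 100 * sum(x$valid_mask) / n))
  bad <- table(factor(x$invalid_code[x$invalid_code != 0L], levels = 1:4,
                      labels = c("M00<=floor", "branch", "defective",
                                 "imag>tol")))
  bad <- bad[bad > 0]
  if (length(bad))
    cat("  invalid causes: ",
        paste(names(bad), bad, sep = " = ", collapse = ", "), "\n", sep = "")
  cat(sprintf("  max discarded imaginary magnitude (valid px): %.3g\n",
              if (any(x$valid_mask)) max(x$imag_residual[x$valid_mask]) else NA))
  invisible(x)
}
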