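#' Polarimetric parameter maps from a logarithmic decomposition
#'
#' Reads the scalar polarization and depolarization coefficients off the
#' G-antisymmetric (`L_m`) and G-symmetric (`L_u`) parts of the per-pixel
#' matrix logarithm, and derives the maps used for collagen scoring:
#'
#' \describe{
#'   \item{`p1, p2, p3`}{linear (x-y), linear (+/-45 deg) and circular
#'     dichroism (dimensionless, thickness-accumulated);}
#'   \item{`p4, p5`}{linear (x-y) and linear (+/-45 deg) retardance (rad);}
#'   \item{`p6`}{circular retardance (rad);}
#'   \item{`d0`}{isotropic attenuation, `ln M00`;}
#'   \item{`d1..d9`}{depolarization-matrix coefficients (`d7, d8, d9` the
#'     anisotropic depolarization diagonals, off-diagonals the property
#'     uncertainties);}
#'   \item{`R_L`}{total linear retardance `sqrt(p4^2 + p5^2)` (rad, >= 0),
#'     invariant under in-plane sample rotation;}
#'   \item{`alpha22`}{linear (x-y) depolarization, the attenuation-free
#'     (1,1) diagonal of `L_u`, i.e. `L_u[1,1] - d0 = -d7` in 0-based
#'     element indexing: 0 for a non-depolarizing sample, more negative
#'     for stronger depolarization;}
#'   \item{`azimuth`}{optical-axis orientation `atan2(p5, p4) / 2` in
#'     degrees, wrapped to \[0, 180); a proxy for the local collagen fiber
#'     orientation (axial quantity, 180 deg period, 0 = image x-axis).}
#' }
#'
#' @param dec an `lmmd_decomposition` from [matrix_log_field()].
#' @return object of class `polarimetric_maps`: a list of H x W numeric
#'   matrices (the planes above), `valid_mask`, and metadata.
#' @examples
#' ph <- simulate_phantom(phantom_spec("day6", image_size = 48, seed = 1,
#'                                     noise_sigma = 0))
#' maps <- extract_maps(matrix_log_field(ph$image))
#' range(maps$R_L[maps$valid_mask])
#' @export
extract_maps <- function(dec) {
  stopifnot(inherits(dec, "lmmd_decomposition"))
  Lm <- dec$L_m; Lu <- dec$L_u
  pl <- function(a, i, j) { x <- a[, , i, j]; dim(x) <- dim(a)[1:2]; x }

  p1 <- pl(Lm, 1, 2); p2 <- pl(Lm, 1, 3); p3 <- pl(Lm, 1, 4)
  p6 <- pl(Lm, 2, 3); p5 <- -pl(Lm, 2, 4); p4 <- pl(Lm, 3, 4)

  d0 <- pl(Lu, 1, 1)
  d1 <- pl(Lu, 1, 2); d2 <- pl(Lu, 1, 3); d3 <- pl(Lu, 1, 4)
  d4 <- pl(Lu, 3, 4); d5 <- pl(Lu, 2, 4); d6 <- pl(Lu, 2, 3)
  d7 <- d0 - pl(Lu, 2, 2)
  d8 <- d0 - pl(Lu, 3, 3)
  d9 <- d0 - pl(Lu, 4, 4)

  R_L <- sqrt(p4^2 + p5^2)
  alpha22 <- -d7
  azimuth <- (0.5 * atan2(p5, p4) * 180 / pi) %% 180

  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6,
                 d0 = d0, d1 = d1, d2 = d2, d3 = d3, d4 = d4, d5 = d5,
                 d6 = d6, d7 = d7, d8 = d8, d9 = d9,
                 R_L = R_L, alpha22 = alpha22, azimuth = azimuth,
                 valid_mask = dec$valid_mask,
                 wavelength = dec$wavelength,
                 pixel_pitch = dec$pixel_pitch,
                 label = dec$label),
            class = "polarimetric_maps")
}

#' @export
print.polarimetric_maps <- function(x, ...) {
  v <- x$valid_mask
  cat("Polarimetric maps",
      if (nzchar(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  cat(sprintf("  %d x %d pixels, %d valid\n", nrow(v), ncol(v), sum(v)))
  for (nm in c("R_L", "alpha22", "azimuth"))
    cat(sprintf("  %-8s mean %.4g  sd %.4g\n", nm,
                mean(x[[nm]][v]), stats::sd(x[[nm]][v])))
  invisible(x)
}

#' Quick-look display of the main polarimetric maps
#'
#' Renders the total linear retardance, linear depolarization and
#' optical-axis azimuth planes.  The azimuth uses a cyclic colormap with a
#' 180 degree period, since fiber orientation is an axial quantity.
#'
#' @param x a `polarimetric_maps` object.
#' @param ... unused.
#' @export
plot.polarimetric_maps <- function(x, ...) {
  op <- par(mfrow = c(1, 3), mar = c(1, 1, 3, 1))
  on.exit(par(op))
  show <- function(p, main, col, zlim = NULL) {
    p[!x$valid_mask] <- NA
    if (is.null(zlim)) zlim <- range(p, na.rm = TRUE)
    if (!all(is.finite(zlim)) || diff(zlim) <= 0) zlim <- c(0, 1)
    image(t(p)[, nrow(p):1], axes = FALSE, main = main, col = col,
          zlim = zlim, useRaster = TRUE)
  }
  show(x$R_L, "total linear retardance (rad)", hcl.colors(64, "viridis"))
  show(x$alpha22, "linear depolarization", hcl.colors(64, "Blues 3"))
  show(x$azimuth, "azimuth (deg)", hsv(seq(0, 1, length.out = 64)),
       zlim = c(0, 180))
  invisible(x)
}
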