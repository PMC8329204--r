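#' Thickness-mitigating normalized and fused maps
#'
#' In a thin section measured in transmission, the accumulated linear
#' retardance grows linearly with local thickness (`R_L = A z`), the linear
#' depolarization quadratically (`alpha22 = -B z^2`), and the Beer-Lambert
#' law ties the transmittance to thickness (`ln M00 = -mu_T z`, with
#' `mu_T = mu_s + mu_a` the total attenuation coefficient).  Pixel-wise
#' ratios therefore cancel the local thickness and respond only to the
#' tissue's optical densities:
#' \deqn{\frac{R_L}{|\ln M_{00}|} = \frac{A}{\mu_T},\qquad
#'       \frac{\ln^2 M_{00}}{\alpha_{22}} = \frac{\mu_T^2}{B},\qquad
#'       \frac{\alpha_{22}}{R_L^2} = \frac{B}{A^2}.}
#'
#' Pixels whose denominator falls below its guard threshold are masked
#' (`NA`), never raised.
#'
#' @param maps a `polarimetric_maps` object from [extract_maps()].
#' @param M00 the H x W total transmittance plane (see [m00()]).
#' @param eps_ln guard on `|ln M00|` (default `1e-3`).
#' @param eps_alpha guard on `|alpha22|` (default `1e-5`).
#' @param eps_R guard on `R_L` (default `1e-4` rad).
#'
#' @return `normalized_retardance()`, `reciprocal_norm_depolarization()`
#'   and `fused_polar_depol()` return an H x W plane with guarded or
#'   invalid pixels `NA`.  `fuse_maps()` returns a `fused_maps` object
#'   bundling all three planes plus `guard_mask` (`TRUE` where any
#'   requested ratio was guarded at a decomposition-valid pixel).
#' @examples
#' ph <- simulate_phantom(phantom_spec("day6", image_size = 48, seed = 1,
#'                                     noise_sigma = 0))
#' maps <- extract_maps(matrix_log_field(ph$image))
#' fz <- fuse_maps(maps, m00(ph$image))
#' fz
#' @name fusion
NULL

.guard <- function(valid, ok) valid & ok

#' @rdname fusion
#' @export
normalized_retardance <- function(maps, M00, eps_ln = 1e-3) {
  stopifnot(inherits(maps, "polarimetric_maps"), eps_ln > 0)
  den <- abs(log(pmax(M00, .Machine$double.xmin)))
  keep <- .guard(maps$valid_mask, is.finite(den) & den > eps_ln & M00 > 0)
  out <- matrix(NA_real_, nrow(M00), ncol(M00))
  out[keep] <- maps$R_L[keep] / den[keep]
  out
}

#' @rdname fusion
#' @export
reciprocal_norm_depolarization <- function(maps, M00, eps_alpha = 1e-5) {
  stopifnot(inherits(maps, "polarimetric_maps"), eps_alpha > 0)
  ln <- log(pmax(M00, .Machine$double.xmin))
  keep <- .guard(maps$valid_mask,
                 abs(maps$alpha22) > eps_alpha & is.finite(ln) & M00 > 0)
  out <- matrix(NA_real_, nrow(M00), ncol(M00))
  out[keep] <- ln[keep]^2 / maps$alpha22[keep]
  out
}

#' @rdname fusion
#' @export
fused_polar_depol <- function(maps, eps_R = 1e-4) {
  stopifnot(inherits(maps, "polarimetric_maps"), eps_R > 0)
  keep <- .guard(maps$valid_mask, maps$R_L > eps_R)
  out <- matrix(NA_real_, nrow(maps$R_L), ncol(maps$R_L))
  out[keep] <- maps$alpha22[keep] / maps$R_L[keep]^2
  out
}

#' @rdname fusion
#' @export
fuse_maps <- function(maps, M00, eps_ln = 1e-3, eps_alpha = 1e-5,
                      eps_R = 1e-4) {
  nr <- normalized_retardance(maps, M00, eps_ln)
  rd <- reciprocal_norm_depolarization(maps, M00, eps_alpha)
  fp <- fused_polar_depol(maps, eps_R)
  guard <- maps$valid_mask & (is.na(nr) | is.na(rd) | is.na(fp))
  structure(list(norm_retardance = nr,
                 recip_norm_depol = rd,
                 fused_polar_depol = fp,
                 guard_mask = guard,
                 eps = c(ln = eps_ln, alpha = eps_alpha, R = eps_R),
                 label = maps$label),
            class = "fused_maps")
}

#' @export
print.fused_maps <- function(x, ...) {
  cat("Thickness-normalized / fused maps",
      if (nzchar(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  for (nm in c("norm_retardance", "recip_norm_depol", "fused_polar_depol")) {
    v <- x[[nm]][!is.na(x[[nm]])]
    cat(sprintf("  %-18s n %d  mean %.4g  sd %.4g\n", nm, length(v),
                mean(v), stats::sd(v)))
  }
  cat(sprintf("  %d pixel(s) guarded\n", sum(x$guard_mask)))
  invisible(x)
}
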