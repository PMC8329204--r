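#' Whole-image moments of a parameter map
#'
#' Mean, population standard deviation, skewness and kurtosis of all valid
#' pixels of a map, with no region-of-interest selection: scoring the whole
#' image removes any operator bias in choosing regions.  Skewness is
#' \eqn{m_3 / m_2^{3/2}} and kurtosis is excess (Fisher) kurtosis
#' \eqn{m_4 / m_2^2 - 3} by default, with \eqn{m_k} the population central
#' moments (1/n normalization; whole images provide n >> 30).
#'
#' @param map H x W numeric matrix (or numeric vector).
#' @param mask optional logical field selecting the valid pixels; `NULL`
#'   uses every finite pixel.
#' @param map_name label stored in the report.
#' @param excess if `FALSE`, report raw kurtosis (`+3`).
#' @return object of class `moment_report`: `map_name`, `n_pixels`, `mean`,
#'   `std`, `skewness`, `kurtosis`, `excess` and `degenerate` (`TRUE` when
#'   the variance is zero, in which case skewness/kurtosis are `NA`).
#' @examples
#' image_moments(c(0, 0, 0, 1))   # skewness 2/sqrt(3), excess kurtosis -2/3
#' @export
image_moments <- function(map, mask = NULL, map_name = "map", excess = TRUE) {
  x <- as.vector(map)
  if (!is.null(mask)) x <- x[as.vector(mask)]
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("image_moments: need at least 2 valid pixels, got ", n)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  degenerate <- m2 == 0
  if (degenerate) {
    sk <- NA_real_; ku <- NA_real_
  } else {
    m3 <- mean((x - mu)^3)
    m4 <- mean((x - mu)^4)
    sk <- m3 / m2^1.5
    ku <- m4 / m2^2 - if (excess) 3 else 0
  }
  structure(list(map_name = map_name, n_pixels = n, mean = mu,
                 std = sqrt(m2), skewness = sk, kurtosis = ku,
                 excess = excess, degenerate = degenerate),
            class = "moment_report")
}

#' @export
print.moment_report <- function(x, ...) {
  cat(sprintf("Moments of '%s' (n = %d pixels)\n", x$map_name, x$n_pixels))
  cat(sprintf("  mean %.5g  std %.5g  skewness %.4g  %skurtosis %.4g\n",
              x$mean, x$std, x$skewness,
              if (x$excess) "excess " else "raw ", x$kurtosis))
  if (x$degenerate)
    cat("  (zero variance: skewness/kurtosis undefined)\n")
  invisible(x)
}

#' @export
as.data.frame.moment_report <- function(x, ...) {
  data.frame(map = x$map_name, n_pixels = x$n_pixels, mean = x$mean,
             std = x$std, skewness = x$skewness, kurtosis = x$kurtosis,
             stringsAsFactors = FALSE)
}

#' Density histogram of a parameter map
#'
#' @param map H x W numeric matrix or vector.
#' @param mask optional logical field of valid pixels.
#' @param n_bins number of equal-width bins (>= 10, default 100).
#' @param range optional length-2 numeric range; default spans the valid
#'   pixel values.
#' @return a list of class `map_histogram`: `bin_centers`, `density`
#'   (integrates to 1), `bin_width`, `n` (pixels counted), and the raw
#'   pixel quartiles used to initialize mixture fits.
#' @export
build_histogram <- function(map, mask = NULL, n_bins = 100, range = NULL) {
  stopifnot(n_bins >= 10)
  x <- as.vector(map)
  if (!is.null(mask)) x <- x[as.vector(mask)]
  x <- x[is.finite(x)]
  if (!length(x)) stop("build_histogram: no valid pixels")
  if (is.null(range)) range <- c(min(x), max(x))
  if (diff(range) <= 0) range <- range + c(-0.5, 0.5)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  x <- x[x >= range[1] & x <= range[2]]
  counts <- tabulate(pmin(pmax(findInterval(x, breaks,
                                            rightmost.closed = TRUE), 1L),
                          n_bins),
                     nbins = n_bins)
  bw <- diff(breaks)[1]
  structure(list(bin_centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 density = counts / (sum(counts) * bw),
                 bin_width = bw, n = sum(counts),
                 quartiles = stats::quantile(x, c(0.25, 0.5, 0.75),
                                             names = FALSE)),
            class = "map_histogram")
}

.two_gauss <- function(x, p) {
  p["a1"] * exp(-(x - p["c1"])^2 / (2 * p["s1"]^2)) +
    p["a2"] * exp(-(x - p["c2"])^2 / (2 * p["s2"]^2))
}

#' Two-Gaussian fit of a map histogram
#'
#' Fits the density histogram of a parameter map with the sum of two
#' Gaussian components
#' \deqn{a_1 e^{-(x-c_1)^2/2\sigma_1^2} + a_2 e^{-(x-c_2)^2/2\sigma_2^2}}
#' by bounded Levenberg-Marquardt least squares.  In cervical tissue the
#' two components separate the low-retardance background pixels (canal,
#' fornix, unaligned stroma) from the birefringent aligned-collagen pixels,
#' so the second peak tracks the aligned-fiber population without any
#' image segmentation.
#'
#' Initialization: centers at the 25th/75th pixel percentiles, widths at
#' half the interquartile range, amplitudes at the density values nearest
#' the initial centers.  Bounds: centers within the data range, widths in
#' `[bin_width/2, data range]`, amplitudes >= 0.  Components are reordered
#' so `c1 <= c2`.  Non-convergence returns the last iterate with
#' `converged = FALSE`; near-coincident centers
#' (`|c2 - c1| < max(s1, s2)/2`) raise the `degenerate` flag.
#'
#' @param hist a `map_histogram` from [build_histogram()], or a numeric
#'   map/vector (then `mask`, `n_bins` are used to build one).
#' @param mask,n_bins forwarded to [build_histogram()] when `hist` is raw
#'   data.
#' @return object of class `two_gaussian_fit` with fields `amplitudes`,
#'   `centers`, `widths`, `r_squared`, `n_bins`, `converged`, `degenerate`,
#'   and the histogram it was fit to.  Methods: `coef`, `predict`,
#'   `fitted`, `residuals`, `print`, `summary`, `plot`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(6e3, 0.03, 0.01), rnorm(4e3, 0.09, 0.02))
#' fit <- fit_two_gaussians(x)
#' coef(fit)
#' @export
fit_two_gaussians <- function(hist, mask = NULL, n_bins = 100) {
  if (!inherits(hist, "map_histogram"))
    hist <- build_histogram(hist, mask = mask, n_bins = n_bins)
  x <- hist$bin_centers
  y <- hist$density
  if (sum(y > 0) < 10L)
    stop("fit_two_gaussians: need at least 10 bins with nonzero density")

  q <- hist$quartiles
  iqr <- max(q[3] - q[1], hist$bin_width)
  rng <- range(x)
  span <- diff(rng)
  start <- c(a1 = max(y[which.min(abs(x - q[1]))], 1e-3 * max(y)),
             c1 = unname(q[1]), s1 = iqr / 2,
             a2 = max(y[which.min(abs(x - q[3]))], 1e-3 * max(y)),
             c2 = unname(q[3]), s2 = iqr / 2)
  lower <- c(a1 = 0, c1 = rng[1], s1 = hist$bin_width / 2,
             a2 = 0, c2 = rng[1], s2 = hist$bin_width / 2)
  upper <- c(a1 = Inf, c1 = rng[2], s1 = span,
             a2 = Inf, c2 = rng[2], s2 = span)
  start <- pmin(pmax(start, lower), upper)

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = function(p) .two_gauss(x, setNames(p, names(start))) - y,
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           maxfev = 10000)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    p <- start                                 # last resort: the initializer
    converged <- FALSE
  } else {
    p <- setNames(unlist(fit$par), names(start))
    converged <- fit$info %in% 1:4             # LM convergence codes
  }

  if (p["c1"] > p["c2"])                       # ordering convention c1 <= c2
    p <- p[c("a2", "c2", "s2", "a1", "c1", "s1")]
  names(p) <- c("a1", "c1", "s1", "a2", "c2", "s2")

  yhat <- .two_gauss(x, p)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  structure(list(amplitudes = unname(p[c("a1", "a2")]),
                 centers = unname(p[c("c1", "c2")]),
                 widths = unname(p[c("s1", "s2")]),
                 r_squared = r2,
                 n_bins = length(x),
                 converged = converged,
                 degenerate = unname(abs(p["c2"] - p["c1"]) <
                   max(p["s1"], p["s2"]) / 2),
                 histogram = hist),
            class = "two_gaussian_fit")
}

#' @export
coef.two_gaussian_fit <- function(object, ...) {
  c(a1 = object$amplitudes[1], c1 = object$centers[1],
    s1 = object$widths[1],
    a2 = object$amplitudes[2], c2 = object$centers[2],
    s2 = object$widths[2])
}

#' @export
predict.two_gaussian_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$histogram$bin_centers
       else if (is.list(newdata)) newdata$x else newdata
  .two_gauss(x, coef(object))
}

#' @export
fitted.two_gaussian_fit <- function(object, ...) predict(object)

#' @export
residuals.two_gaussian_fit <- function(object, ...)
  object$histogram$density - fitted(object)

#' @export
print.two_gaussian_fit <- function(x, ...) {
  cat("Two-Gaussian histogram fit",
      if (!x$converged) " (NOT converged)",
      if (x$degenerate) " (degenerate: near-coincident centers)",
      "\n", sep = "")
  cat(sprintf("  component 1: a = %.4g  center = %.5g  width = %.5g\n",
              x$amplitudes[1], x$centers[1], x$widths[1]))
  cat(sprintf("  component 2: a = %.4g  center = %.5g  width = %.5g\n",
              x$amplitudes[2], x$centers[2], x$widths[2]))
  cat(sprintf("  R^2 = %.6f over %d bins\n", x$r_squared, x$n_bins))
  invisible(x)
}

#' @export
summary.two_gaussian_fit <- function(object, ...) {
  print(object)
  res <- residuals(object)
  cat(sprintf("  residual density: rms %.4g  max |r| %.4g\n",
              sqrt(mean(res^2)), max(abs(res))))
  invisible(object)
}

#' @export
plot.two_gaussian_fit <- function(x, ...) {
  h <- x$histogram
  p <- coef(x)
  barplot(h$density, names.arg = NULL, space = 0, border = NA,
          col = "grey80", ylab = "density", ...)
  xx <- seq_along(h$bin_centers) - 0.5
  lines(xx, .two_gauss(h$bin_centers, p), lwd = 2)
  g1 <- p; g1["a2"] <- 0
  g2 <- p; g2["a1"] <- 0
  lines(xx, .two_gauss(h$bin_centers, g1), lty = 2)
  lines(xx, .two_gauss(h$bin_centers, g2), lty = 3)
  legend("topright", c("fit", "component 1", "component 2"),
         lty = 1:3, bty = "n")
  invisible(x)
}

#' Circular statistics of the optical-axis azimuth
#'
#' Fiber orientation is axial (180 degree period), so azimuths are doubled
#' onto the full circle, trigonometric moments computed, and directional
#' statistics mapped back to the axis domain.  Note that a circumferential
#' fiber ring covers all orientations just like spatially random fibers do,
#' so whole-image azimuth statistics cannot distinguish an ordered ring
#' from disordered tissue.
#'
#' @param azimuth plane of azimuth angles in degrees (any real values;
#'   interpreted mod 180).
#' @param mask optional logical field of valid pixels.
#' @return object of class `circular_stats`: `mean_direction` (deg in
#'   \[0, 180)), `resultant_length` in \[0, 1\], `variance` (`1 - R`),
#'   `skewness` and `kurtosis` (standard circular b and k statistics on the
#'   doubled angles), `n`.
#' @export
circular_azimuth_stats <- function(azimuth, mask = NULL) {
  th <- as.vector(azimuth)
  if (!is.null(mask)) th <- th[as.vector(mask)]
  th <- th[is.finite(th)]
  n <- length(th)
  if (n < 2L) stop("circular_azimuth_stats: need at least 2 valid pixels")
  a <- 2 * th * pi / 180                     # axial -> circular
  C1 <- mean(cos(a)); S1 <- mean(sin(a))
  R1 <- sqrt(C1^2 + S1^2)
  mu1 <- atan2(S1, C1)
  C2 <- mean(cos(2 * a)); S2 <- mean(sin(2 * a))
  R2 <- sqrt(C2^2 + S2^2)
  mu2 <- atan2(S2, C2)
  V <- 1 - R1
  b <- if (V > 0) R2 * sin(mu2 - 2 * mu1) / V^1.5 else NA_real_
  k <- if (V > 0) (R2 * cos(mu2 - 2 * mu1) - R1^4) / V^2 else NA_real_
  structure(list(mean_direction = ((mu1 / 2) * 180 / pi) %% 180,
                 resultant_length = R1,
                 variance = V,
                 skewness = b,
                 kurtosis = k,
                 n = n),
            class = "circular_stats")
}

#' @export
print.circular_stats <- function(x, ...) {
  cat(sprintf(paste0("Circular azimuth statistics (n = %d)\n",
                     "  mean direction %.2f deg  resultant length %.4f\n",
                     "  variance %.4f  skewness %.4g  kurtosis %.4g\n"),
              x$n, x$mean_direction, x$resultant_length, x$variance,
              x$skewness, x$kurtosis))
  invisible(x)
}

#' Per-group aggregation of two-Gaussian fit parameters
#'
#' Averages the peak centers and widths of several animals' fits within a
#' study group (e.g. one gestation day), reporting the mean and population
#' standard deviation of each parameter across animals.
#'
#' @param fits list of `two_gaussian_fit` objects (one per animal/image).
#' @param label group label.
#' @return object of class `group_summary`: `label`, `n_animals`, and a
#'   data frame `stats` with one row per parameter (`c1`, `c2`, `s1`, `s2`)
#'   holding `mean` and `sd` (population; 0 when `n = 1`).
#' @export
score_group <- function(fits, label = "group") {
  if (!length(fits)) stop("score_group: empty fit list")
  stopifnot(all(vapply(fits, inherits, TRUE, "two_gaussian_fit")))
  grab <- function(f) c(c1 = f$centers[1], c2 = f$centers[2],
                        s1 = f$widths[1], s2 = f$widths[2])
  m <- t(vapply(fits, grab, numeric(4)))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  structure(list(label = label,
                 n_animals = nrow(m),
                 stats = data.frame(parameter = colnames(m),
                                    mean = colMeans(m),
                                    sd = apply(m, 2, pop_sd),
                                    row.names = NULL,
                                    stringsAsFactors = FALSE)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group '%s' (%d animal(s))\n", x$label, x$n_animals))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.group_summary <- function(x, ...) {
  out <- data.frame(group = x$label, n_animals = x$n_animals)
  for (i in seq_len(nrow(x$stats))) {
    out[[paste0(x$stats$parameter[i], "_mean")]] <- x$stats$mean[i]
    out[[paste0(x$stats$parameter[i], "_sd")]] <- x$stats$sd[i]
  }
  out
}

#' Full statistical score of one image's maps
#'
#' Convenience wrapper producing, for one decomposed image: moments of the
#' retardance and depolarization maps, their histograms and two-Gaussian
#' fits, and circular statistics of the azimuth — the whole-image scoring
#' set, computed with no region-of-interest selection.
#'
#' @param maps a `polarimetric_maps` object.
#' @param n_bins histogram bin count (default 100).
#' @param excess_kurtosis report excess (Fisher) kurtosis (default) or raw.
#' @return object of class `score_report` with components `label`,
#'   `moments` (list), `fits` (list of `two_gaussian_fit`), `circular`.
#' @export
score_image <- function(maps, n_bins = 100, excess_kurtosis = TRUE) {
  stopifnot(inherits(maps, "polarimetric_maps"))
  v <- maps$valid_mask
  moments <- list(
    R_L = image_moments(maps$R_L, v, "R_L", excess = excess_kurtosis),
    alpha22 = image_moments(maps$alpha22, v, "alpha22",
                            excess = excess_kurtosis))
  fits <- list(
    R_L = fit_two_gaussians(maps$R_L, mask = v, n_bins = n_bins),
    alpha22 = fit_two_gaussians(maps$alpha22, mask = v, n_bins = n_bins))
  structure(list(label = maps$label,
                 moments = moments,
                 fits = fits,
                 circular = circular_azimuth_stats(maps$azimuth, v)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("Score report",
      if (nzchar(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  for (m in x$moments) print(m)
  for (nm in names(x$fits)) {
    cat(nm, ": ", sep = "")
    print(x$fits[[nm]])
  }
  print(x$circular)
  invisible(x)
}

#' @export
as.data.frame.score_report <- function(x, ...) {
  rows <- lapply(names(x$moments), function(nm) {
    mo <- as.data.frame(x$moments[[nm]])
    f <- x$fits[[nm]]
    cbind(data.frame(label = x$label), mo,
          data.frame(a1 = f$amplitudes[1], c1 = f$centers[1],
                     s1 = f$widths[1], a2 = f$amplitudes[2],
                     c2 = f$centers[2], s2 = f$widths[2],
                     r_squared = f$r_squared,
                     converged = f$converged,
                     degenerate = f$degenerate,
                     az_mean_direction = x$circular$mean_direction,
                     az_resultant_length = x$circular$resultant_length,
                     az_variance = x$circular$variance))
  })
  do.call(rbind, rows)
}
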