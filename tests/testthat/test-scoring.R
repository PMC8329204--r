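test_that("moments match brute-force definitional sums", {
  m <- image_moments(c(0, 0, 0, 1))
  expect_equal(m$mean, 0.25)
  expect_equal(m$std, sqrt(3) / 4)
  b <- brute_moments(c(0, 0, 0, 1))
  expect_equal(m$skewness, unname(b["skewness"]))
  expect_equal(m$kurtosis, unname(b["kurtosis"]))

  set.seed(11)
  x <- matrix(rlnorm(1e4, -3, 0.5), 100, 100)
  m2 <- image_moments(x)
  b2 <- brute_moments(as.vector(x))
  expect_equal(c(m2$mean, m2$std, m2$skewness, m2$kurtosis),
               unname(b2), tolerance = 1e-12)
  # raw-kurtosis convention offset
  expect_equal(image_moments(x, excess = FALSE)$kurtosis,
               m2$kurtosis + 3)
})

test_that("moment estimators are unbiased at scale on Gaussian data", {
  set.seed(202)
  n <- 1e6
  x <- rnorm(n, 0.05, 0.02)
  m <- image_moments(x)
  expect_lt(abs(m$skewness), 3 * sqrt(6 / n))
  expect_lt(abs(m$kurtosis), 3 * sqrt(24 / n))
})

test_that("degenerate and undersized inputs are handled per contract", {
  m <- image_moments(rep(0.3, 10))
  expect_equal(m$mean, 0.3)
  expect_equal(m$std, 0)
  expect_true(m$degenerate)
  expect_true(is.na(m$skewness))
  expect_error(image_moments(1), "at least 2")
})

test_that("histogram is density-normalized with correct occupancy", {
  h <- build_histogram(rep(0.5, 100), n_bins = 20)
  expect_equal(sum(h$density > 0), 1L)

  x <- c(rep(0.02, 30), rep(0.09, 70))
  h2 <- build_histogram(x, n_bins = 10)
  occ <- which(h2$density > 0)
  expect_length(occ, 2L)
  expect_equal(h2$density[occ[1]] / h2$density[occ[2]], 30 / 70)

  set.seed(5)
  h3 <- build_histogram(rnorm(5e4), n_bins = 57)
  expect_equal(sum(h3$density) * h3$bin_width, 1, tolerance = 1e-12)
  expect_error(build_histogram(c(NA_real_, NaN)), "no valid pixels")
  expect_error(build_histogram(rnorm(100), n_bins = 5), "n_bins")
})

test_that("two-Gaussian fit recovers an exact curve and a seeded mixture", {
  xg <- seq(0, 0.15, length.out = 100)
  truth <- c(a1 = 2, c1 = 0.04, s1 = 0.012, a2 = 1.2, c2 = 0.1, s2 = 0.02)
  yg <- truth["a1"] * exp(-(xg - truth["c1"])^2 / (2 * truth["s1"]^2)) +
        truth["a2"] * exp(-(xg - truth["c2"])^2 / (2 * truth["s2"]^2))
  hh <- structure(list(bin_centers = xg, density = yg,
                       bin_width = xg[2] - xg[1], n = 1e5,
                       quartiles = c(0.03, 0.06, 0.09)),
                  class = "map_histogram")
  f <- fit_two_gaussians(hh)
  expect_true(f$converged)
  expect_lt(max(abs(coef(f) - truth)), 1e-6)
  expect_gt(f$r_squared, 1 - 1e-10)

  set.seed(17)
  x <- c(rnorm(6e4, 0.03, 0.01), rnorm(4e4, 0.09, 0.02))
  fm <- fit_two_gaussians(x)
  expect_true(fm$converged)
  expect_lt(abs(fm$centers[1] - 0.03), 0.005)
  expect_lt(abs(fm$centers[2] - 0.09), 0.005)
  expect_lt(abs(fm$widths[1] / 0.01 - 1), 0.2)
  expect_lt(abs(fm$widths[2] / 0.02 - 1), 0.2)
})

test_that("fit is invariant to swapping the initial component labels", {
  set.seed(23)
  x <- c(rnorm(3e4, 0.02, 0.008), rnorm(2e4, 0.07, 0.015))
  h <- build_histogram(x)
  f1 <- fit_two_gaussians(h)
  hswap <- h
  hswap$quartiles <- h$quartiles[c(3, 2, 1)]   # start components reversed
  f2 <- fit_two_gaussians(hswap)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
  expect_lte(f1$centers[1], f1$centers[2])
  expect_lte(f2$centers[1], f2$centers[2])
})

test_that("single-mode data raises the degeneracy flag", {
  set.seed(3)
  f <- fit_two_gaussians(rnorm(1e5, 0.05, 0.01))
  expect_true(f$degenerate)
})

test_that("fit methods behave like a fitted model object", {
  set.seed(29)
  x <- c(rnorm(2e4, 0.03, 0.01), rnorm(2e4, 0.09, 0.02))
  f <- fit_two_gaussians(x)
  expect_named(coef(f), c("a1", "c1", "s1", "a2", "c2", "s2"))
  expect_length(fitted(f), f$n_bins)
  expect_equal(residuals(f), f$histogram$density - fitted(f))
  expect_equal(predict(f, newdata = f$centers[2]),
               sum(coef(f)[c("a1", "a2")] *
                   exp(-(f$centers[2] - f$centers)^2 /
                       (2 * f$widths^2))),
               ignore_attr = TRUE)
})

test_that("scoring depends only on the valid-pixel multiset", {
  set.seed(41)
  map <- matrix(rlnorm(2500, -3, 0.6), 50, 50)
  perm <- matrix(sample(as.vector(map)), 50, 50)
  m1 <- image_moments(map); m2 <- image_moments(perm)
  expect_equal(c(m1$mean, m1$std, m1$skewness, m1$kurtosis),
               c(m2$mean, m2$std, m2$skewness, m2$kurtosis))
  expect_equal(build_histogram(map)$density, build_histogram(perm)$density)
  expect_equal(coef(fit_two_gaussians(map)), coef(fit_two_gaussians(perm)))
})

test_that("circular azimuth statistics honor the axial period", {
  cs <- circular_azimuth_stats(rep(30, 100))
  expect_equal(cs$mean_direction, 30, tolerance = 1e-10)
  expect_equal(cs$resultant_length, 1, tolerance = 1e-12)

  set.seed(8)
  u <- runif(1e5, 0, 180)
  expect_lt(circular_azimuth_stats(u)$resultant_length, 0.01)

  # invariance under a global axis rotation
  set.seed(9)
  th <- runif(5000, 0, 180)^1.3 %% 180
  a <- circular_azimuth_stats(th)
  b <- circular_azimuth_stats((th + 54.3) %% 180)
  expect_equal(b$resultant_length, a$resultant_length, tolerance = 1e-12)
  expect_equal(b$variance, a$variance, tolerance = 1e-12)
  expect_equal(b$skewness, a$skewness, tolerance = 1e-8)
  expect_equal(b$kurtosis, a$kurtosis, tolerance = 1e-8)
  expect_equal((b$mean_direction - a$mean_direction) %% 180, 54.3,
               tolerance = 1e-8)
  expect_error(circular_azimuth_stats(10), "at least 2")
})

test_that("group aggregation averages fit parameters with population sd", {
  g1 <- score_group(list(fake_fit(0.02, 0.08)), label = "solo")
  expect_equal(g1$n_animals, 1L)
  expect_true(all(g1$stats$sd == 0))
  expect_equal(g1$stats$mean[g1$stats$parameter == "c2"], 0.08)

  fits <- list(fake_fit(0.02, 0.08), fake_fit(0.02, 0.09),
               fake_fit(0.02, 0.10))
  g3 <- score_group(fits, label = "day6")
  expect_equal(g3$stats$mean[g3$stats$parameter == "c2"], 0.09)
  expect_equal(g3$stats$sd[g3$stats$parameter == "c2"], sqrt(2e-4 / 3))
  expect_error(score_group(list()), "empty")
})
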