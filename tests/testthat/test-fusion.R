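ramp_maps <- function(h = 20, w = 60, A = 0.1, theta = 30, mu_T = 0.8,
                      B = 0.02, zlim = c(0.5, 1.5)) {
  fld <- slab_field(h, w, A, theta, mu_T, B)
  z <- matrix(rep(seq(zlim[1], zlim[2], length.out = w), each = h), h, w)
  img <- forward_mueller(fld$m_m, fld$m_u, z)
  list(maps = extract_maps(matrix_log_field(img, m00_floor = 0)),
       M00 = m00(img), z = z)
}

test_that("normalized retardance has the closed-form value and guards", {
  # R_L = 0.1 at M00 = exp(-1): |ln M00| = 1
  m <- matrix(0, 4, 4); m[3, 4] <- 0.1; m[4, 3] <- -0.1; diag(m) <- -1
  img <- as_image(oracle_expm(m))
  maps <- extract_maps(matrix_log_field(img, m00_floor = 0))
  expect_equal(as.vector(normalized_retardance(maps, m00(img))), 0.1,
               tolerance = 1e-12)

  # no attenuation: |ln M00| = 0 is guarded, not divided
  img1 <- as_image(oracle_retarder(0.1, 10))
  maps1 <- extract_maps(matrix_log_field(img1, m00_floor = 0))
  expect_true(is.na(normalized_retardance(maps1, m00(img1))))
})

test_that("reciprocal normalized depolarization matches direct arithmetic", {
  # ln M00 = -0.5, alpha22 = -0.01 -> 0.25 / -0.01 = -25
  Lu <- diag(c(-0.5, -0.51, -0.51, -0.51))
  img <- as_image(oracle_expm(Lu))
  maps <- extract_maps(matrix_log_field(img, m00_floor = 0))
  expect_equal(as.vector(reciprocal_norm_depolarization(maps, m00(img))),
               -25, tolerance = 1e-8)

  # pure retarder: alpha22 = 0 is guarded for the reciprocal ratio but
  # passes through as 0 in the fused polarization-depolarization ratio
  img1 <- as_image(oracle_retarder(0.2, 75))
  maps1 <- extract_maps(matrix_log_field(img1, m00_floor = 0))
  expect_true(is.na(reciprocal_norm_depolarization(maps1, m00(img1))))
  expect_equal(as.vector(fused_polar_depol(maps1)), 0)
})

test_that("fused polarization-depolarization ratio and its guard", {
  Lu <- diag(c(-0.3, -0.31, -0.31, -0.31))    # alpha22 = -0.01
  m <- Lu; m[3, 4] <- 0.1; m[4, 3] <- -0.1    # R_L = 0.1
  img <- as_image(oracle_expm(m))
  maps <- extract_maps(matrix_log_field(img, m00_floor = 0))
  expect_equal(as.vector(fused_polar_depol(maps)), -1, tolerance = 1e-8)

  img0 <- as_image(oracle_expm(Lu))           # R_L = 0: guarded
  maps0 <- extract_maps(matrix_log_field(img0, m00_floor = 0))
  expect_true(is.na(fused_polar_depol(maps0)))
})

test_that("all three ratios are spatially constant across a thickness ramp", {
  r <- ramp_maps()
  fz <- fuse_maps(r$maps, r$M00)
  cv <- function(p) { v <- p[!is.na(p)]; sd(v) / abs(mean(v)) }
  expect_lt(cv(fz$norm_retardance), 1e-6)
  expect_lt(cv(fz$recip_norm_depol), 1e-6)
  expect_lt(cv(fz$fused_polar_depol), 1e-6)
  expect_equal(mean(fz$norm_retardance, na.rm = TRUE), 0.1 / 0.8,
               tolerance = 1e-6)
  expect_equal(mean(fz$recip_norm_depol, na.rm = TRUE), -0.8^2 / 0.02,
               tolerance = 1e-6)
  expect_equal(mean(fz$fused_polar_depol, na.rm = TRUE), -0.02 / 0.1^2,
               tolerance = 1e-6)
})

test_that("rescaling the thickness field leaves the ratios unchanged", {
  base <- ramp_maps()
  f0 <- fuse_maps(base$maps, base$M00)
  for (k in c(0.5, 2)) {
    fld <- slab_field(20, 60, 0.1, 30, 0.8, 0.02)
    img <- forward_mueller(fld$m_m, fld$m_u, base$z * k)
    fk <- fuse_maps(extract_maps(matrix_log_field(img, m00_floor = 0)),
                    m00(img))
    for (nm in c("norm_retardance", "recip_norm_depol",
                 "fused_polar_depol"))
      expect_equal(fk[[nm]], f0[[nm]], tolerance = 1e-6)
  }
})

test_that("regions differing only in retardance density stay distinct", {
  h <- 10; w <- 40
  fld <- slab_field(h, w, 0.06, 20, 0.9, 0.015)
  hi <- slab_field(h, w, 0.12, 20, 0.9, 0.015)
  right <- rep(rep(c(FALSE, TRUE), each = w / 2), each = h)
  m_m <- fld$m_m; m_m[right] <- hi$m_m[right]
  z <- matrix(runif(h * w, 0.6, 1.4), h, w)
  img <- forward_mueller(m_m, fld$m_u, z)
  nr <- normalized_retardance(
    extract_maps(matrix_log_field(img, m00_floor = 0)), m00(img))
  vals <- unique(round(as.vector(nr), 9))
  expect_equal(sort(vals), sort(round(c(0.06, 0.12) / 0.9, 9)))
})
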