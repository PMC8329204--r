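test_that("circumferential azimuth is tangential; fornix has no retardance", {
  sp <- phantom_spec("day6", image_size = 101, seed = 1,
                     azimuth_kappa = 1e8, z_fluct_amp = 0, A_cv = 0,
                     noise_sigma = 0)
  fld <- build_differential_field(sp)
  # pixel due east of center inside the midstroma ring: tangent is vertical
  east <- c(51, 51 + 31)
  expect_equal(fld$truth$label[east[1], east[2]], 3L)
  expect_equal(fld$truth$azimuth[east[1], east[2]], 90, tolerance = 1e-6)
  A <- fld$truth$A[east[1], east[2]]
  expect_equal(fld$m_m[east[1], east[2], 3, 4], -A, tolerance = 1e-9)
  expect_equal(fld$m_m[east[1], east[2], 2, 4], 0, tolerance = 1e-6)

  expect_true(all(fld$truth$A[fld$truth$label %in% c(1L, 4L)] == 0))
  expect_true(all(fld$truth$label[fld$truth$tissue] > 0L))
})

test_that("fully disordered azimuth has a uniform marginal", {
  fld <- build_differential_field(phantom_spec("day18", image_size = 317,
                                               seed = 9))
  expect_lt(circular_azimuth_stats(fld$truth$azimuth)$resultant_length,
            0.02)
})

test_that("forward model reduces to the closed-form retarder slab", {
  fld <- slab_field(1, 1, A = 0.1, theta_deg = 25, mu_T = 1, B = 0)
  img <- forward_mueller(fld$m_m, fld$m_u, z = 1)
  expect_equal(px_mat(img$coefficients),
               exp(-1) * oracle_retarder(0.1, 25), tolerance = 1e-12)
})

test_that("retardance scales linearly and depolarization quadratically", {
  fld <- slab_field(1, 1, A = 0.08, theta_deg = 70, mu_T = 0.9, B = 0.015)
  get <- function(z) {
    img <- forward_mueller(fld$m_m, fld$m_u, z)
    mp <- extract_maps(matrix_log_field(img, m00_floor = 0))
    c(rl = as.vector(mp$R_L), a22 = as.vector(mp$alpha22),
      ln = log(as.vector(m00(img))))
  }
  a <- get(0.7); b <- get(1.4)
  expect_equal(b[["rl"]], 2 * a[["rl"]], tolerance = 1e-10)
  expect_equal(b[["a22"]], 4 * a[["a22"]], tolerance = 1e-10)
  expect_equal(b[["ln"]], 2 * a[["ln"]], tolerance = 1e-10)
  expect_equal(a[["a22"]], -0.015 * 0.7^2, tolerance = 1e-10)
})

test_that("zero-thickness limit approaches the identity", {
  fld <- slab_field(1, 1, A = 0.1, theta_deg = 10, mu_T = 1, B = 0.02)
  img <- forward_mueller(fld$m_m, fld$m_u, z = 1e-9)
  expect_equal(px_mat(img$coefficients), diag(4), tolerance = 1e-8)
})

test_that("forward model rejects invalid thickness", {
  fld <- slab_field(1, 1, 0.1, 0, 1, 0.02)
  expect_error(forward_mueller(fld$m_m, fld$m_u, z = 0))
})

test_that("measurement noise is seed-deterministic and proportional", {
  ph <- simulate_phantom(phantom_spec("day6", image_size = 48, seed = 2,
                                      noise_sigma = 0))
  expect_identical(add_measurement_noise(ph$image, 0), ph$image)
  n1 <- add_measurement_noise(ph$image, 0.01, seed = 77)
  n2 <- add_measurement_noise(ph$image, 0.01, seed = 77)
  expect_identical(n1$coefficients, n2$coefficients)
  # opaque pixels (M00 = 0) stay exactly opaque
  bg <- !ph$truth$tissue
  expect_true(all(n1$coefficients[bg] == 0))
})

test_that("decomposition recovers the phantom ground truth", {
  sp <- phantom_spec("day6", image_size = 96, seed = 12, noise_sigma = 0)
  ph <- simulate_phantom(sp)
  maps <- extract_maps(matrix_log_field(ph$image))
  tr <- ph$truth
  px <- tr$tissue & maps$valid_mask
  expect_lt(max(abs(maps$R_L[px] - tr$A[px] * tr$z[px])), 1e-8)
  expect_lt(max(abs(maps$alpha22[px] + tr$B_L[px] * tr$z[px]^2)), 1e-8)
  ret <- px & tr$A > 0.01
  dth <- abs(maps$azimuth[ret] - tr$azimuth[ret]) %% 180
  expect_lt(max(pmin(dth, 180 - dth)), 1e-6)
})

test_that("noise keeps nearly all pixels decomposable at measured tolerance", {
  ph <- simulate_phantom(phantom_spec("day6", image_size = 128, seed = 31,
                                      noise_sigma = 0.005))
  dec <- matrix_log_field(ph$image, tol_imag = 1e-2)
  expect_gt(mean(dec$valid_mask[ph$truth$tissue]), 0.99)
})

test_that("cohorts are reproducible and stage-contrasted by construction", {
  c1 <- generate_cohort(2, 1, base_seed = 3, image_size = 48)
  c2 <- generate_cohort(2, 1, base_seed = 3, image_size = 48)
  expect_identical(lapply(c1, function(x) x$image$coefficients),
                   lapply(c2, function(x) x$image$coefficients))
  expect_equal(vapply(c1, `[[`, "", "stage"), c("day6", "day6", "day18"))

  # day-6 stroma azimuth hugs the tangential direction; day-18 does not
  dev_tang <- function(ph) {
    sp <- ph$spec
    g <- ph$truth
    sel <- g$label == 3L
    d <- abs(g$azimuth[sel] -
             ((atan2(row(g$label)[sel] -
                     (nrow(g$label) + 1) / 2 - (sp$center_frac[1] - 0.5) *
                       nrow(g$label),
                     col(g$label)[sel] -
                     (ncol(g$label) + 1) / 2 - (sp$center_frac[2] - 0.5) *
                       ncol(g$label)) * 180 / pi + 90) %% 180)) %% 180
    mean(pmin(d, 180 - d))
  }
  expect_lt(dev_tang(c1[[1]]), 20)
  expect_gt(dev_tang(c1[[3]]), 30)
})

test_that("phantom specification validates its invariants", {
  expect_error(phantom_spec("day6", r_sub_frac = 0.8), "nested")
  expect_error(phantom_spec("day6", A = c(canal = -1, sub = 0, mid = 0,
                                          fornix = 0)), ">= 0")
  expect_error(phantom_spec("day6", banana = 1), "unknown field")
  expect_error(phantom_spec("day6", noise_sigma = -0.1), "invalid scalar")
})
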