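# Independent oracles used across the suite.  These deliberately do not
# share code with the package internals they check.

# Stokes rotation matrix for an in-plane rotation by `a_deg` degrees
oracle_rotation <- function(a_deg) {
  a <- 2 * a_deg * pi / 180
  matrix(c(1, 0, 0, 0,
           0, cos(a), -sin(a), 0,
           0, sin(a), cos(a), 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

# Closed-form Mueller matrix of a linear retarder: retardance `delta` (rad),
# fast axis at `theta_deg`, built by rotation conjugation
oracle_retarder <- function(delta, theta_deg) {
  M0 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, cos(delta), sin(delta),
                 0, 0, -sin(delta), cos(delta)), 4, 4, byrow = TRUE)
  oracle_rotation(theta_deg) %*% M0 %*% oracle_rotation(-theta_deg)
}

# Independent matrix exponential (scaling-and-squaring, Matrix package)
oracle_expm <- function(m) as.matrix(Matrix::expm(m))

# Random differential matrix split into its G-antisymmetric (p1..p6) and
# G-symmetric (d0..d9) parts, drawn from the full coefficient layout
random_generator <- function(pmax = 0.3) {
  p <- runif(6, -pmax, pmax)
  d <- runif(10, -pmax, pmax)
  m_m <- matrix(c(0,     p[1],  p[2],  p[3],
                  p[1],  0,     p[6], -p[5],
                  p[2], -p[6],  0,     p[4],
                  p[3],  p[5], -p[4],  0), 4, 4, byrow = TRUE)
  m_u <- matrix(c(d[1],        d[2],        d[3],        d[4],
                 -d[2],        d[1] - d[8], d[7],        d[6],
                 -d[3],        d[7],        d[1] - d[9], d[5],
                 -d[4],        d[6],        d[5],        d[1] - d[10]),
                4, 4, byrow = TRUE)
  list(m_m = m_m, m_u = m_u)
}

# Build a mueller_image from a list (or single) of 4x4 matrices laid out on
# a 1 x n grid
as_image <- function(mats, ...) {
  if (is.matrix(mats)) mats <- list(mats)
  a <- array(0, c(1, length(mats), 4, 4))
  for (k in seq_along(mats)) a[1, k, , ] <- mats[[k]]
  suppressWarnings(mueller_image(a, passivity = "none", ...))
}

# Matrix of one pixel of a decomposition component
px_mat <- function(arr, i = 1, j = 1) {
  m <- arr[i, j, , ]
  dim(m) <- c(4, 4)
  m
}

# Brute-force definitional moments (population convention)
brute_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu, std = sqrt(m2), skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2 - 3)
}

# Minimal two_gaussian_fit stub for aggregation tests
fake_fit <- function(c1, c2, s1 = 0.01, s2 = 0.02, a1 = 1, a2 = 1) {
  structure(list(amplitudes = c(a1, a2), centers = c(c1, c2),
                 widths = c(s1, s2), r_squared = 1, n_bins = 100,
                 converged = TRUE, degenerate = FALSE, histogram = NULL),
            class = "two_gaussian_fit")
}

# Homogeneous-slab generator densities (retardance A at axis theta,
# attenuation mu_T, isotropic depolarization B) on an h x w grid
slab_field <- function(h, w, A, theta_deg, mu_T, B) {
  th2 <- 2 * theta_deg * pi / 180
  m_m <- array(0, c(h, w, 4, 4))
  m_m[, , 3, 4] <- A * cos(th2);  m_m[, , 4, 3] <- -A * cos(th2)
  m_m[, , 2, 4] <- -A * sin(th2); m_m[, , 4, 2] <- A * sin(th2)
  m_u <- array(0, c(h, w, 4, 4))
  m_u[, , 1, 1] <- -mu_T
  m_u[, , 2, 2] <- -mu_T - B
  m_u[, , 3, 3] <- -mu_T - B
  m_u[, , 4, 4] <- -mu_T - B
  list(m_m = m_m, m_u = m_u)
}
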