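test_that("attenuation path factor matches the closed-form line integral", {
  g <- grid_geometry(c(16, 16, 16), 2.46)
  # no attenuation anywhere
  mu0 <- array(0, g$shape)
  expect_identical(attenuation_path_factor(mu0, c(8, 10, 8), g), 1.0)
  # uniform mu, voxel 10 full steps below the anterior face + half self-step
  mu <- array(0.01, g$shape)
  expect_equal(attenuation_path_factor(mu, c(8, 11, 8), g),
               exp(-0.01 * 2.46 * 10.5), tolerance = 1e-12)
  # voxel on the anterior face: half self-voxel only
  expect_equal(attenuation_path_factor(mu, c(8, 1, 8), g),
               exp(-0.01 * 2.46 / 2), tolerance = 1e-12)
  expect_error(attenuation_path_factor(mu, c(0, 1, 8), g), "outside")
})

test_that("planar forward model reduces to a ray sum without attenuation", {
  g <- small_grid(12, vox = 2)
  act <- blob_activity(g)
  mu0 <- array(0, g$shape)
  img <- simulate_planar(act, mu0, g, noiseless = TRUE)
  expect_equal(img$matrix, 2 * apply(act, c(1, 3), sum), tolerance = 1e-12)
  # count conservation in the unattenuated limit
  expect_equal(sum(img$matrix), 2 * sum(act), tolerance = 1e-12)
  # zero activity maps to a zero image
  img0 <- simulate_planar(array(0, g$shape), mu0, g, noiseless = TRUE)
  expect_true(all(img0$matrix == 0))
})

test_that("point source projects to its attenuated closed form", {
  g <- grid_geometry(c(12, 12, 12), 2.46)
  act <- array(0, g$shape); act[6, 9, 7] <- 1   # depth index 9
  mu <- array(0.012, g$shape)
  img <- simulate_planar(act, mu, g, noiseless = TRUE)
  expect_equal(sum(img$matrix > 0), 1L)
  expect_equal(img$matrix[6, 7],
               2.46 * attenuation_path_factor(mu, c(6, 9, 7), g),
               tolerance = 1e-12)
})

test_that("planar forward model is linear and monotone in attenuation", {
  g <- small_grid(12)
  a <- blob_activity(g, center = c(0.4, 0.5, 0.4))
  b <- blob_activity(g, center = c(0.6, 0.5, 0.6), amplitude = 3)
  mu <- uniform_mu(g, 0.008)
  p <- function(x) simulate_planar(x, mu, g, noiseless = TRUE)$matrix
  expect_equal(p(2 * a + 0.5 * b), 2 * p(a) + 0.5 * p(b), tolerance = 1e-10)
  # raising mu anywhere never raises any pixel
  mu2 <- mu; mu2[6, 6, 6] <- 0.05
  p_hi <- simulate_planar(a, mu2, g, noiseless = TRUE)$matrix
  expect_true(all(p_hi <= p(a) + 1e-12))
})

test_that("Poisson realizations are seeded, integer, and unbiased", {
  g <- small_grid(10)
  act <- blob_activity(g, amplitude = 40)
  mu <- uniform_mu(g, 0.005)
  i1 <- simulate_planar(act, mu, g, seed = 9)
  i2 <- simulate_planar(act, mu, g, seed = 9)
  i3 <- simulate_planar(act, mu, g, seed = 10)
  expect_identical(i1$matrix, i2$matrix)
  expect_false(identical(i1$matrix, i3$matrix))
  expect_true(all(i1$matrix == round(i1$matrix)))
  # law of large numbers on one bright pixel over 200 seeded draws
  noiseless <- simulate_planar(act, mu, g, noiseless = TRUE)$matrix
  px <- which(noiseless == max(noiseless), arr.ind = TRUE)[1, ]
  lam <- noiseless[px[1], px[2]]
  draws <- vapply(1:200, function(s)
    simulate_planar(act, mu, g, seed = s)$matrix[px[1], px[2]], numeric(1))
  se <- sqrt(lam / 200)
  expect_lt(abs(mean(draws) - lam), 3 * se)
})

test_that("SPECT projection at angle zero equals the planar forward model", {
  g <- small_grid(16)
  ph <- make_phantom(phantom_spec(g))
  det <- detector_model(sensitivity = 2)
  ps <- simulate_spect(ph$activity, ph$mu, g, det,
                       angles = c(0, 90, 180, 270), noiseless = TRUE)
  pl <- simulate_planar(ph$activity, ph$mu, g, det, noiseless = TRUE)
  expect_equal(ps$projections[[1]], pl$matrix, tolerance = 1e-12)
  expect_error(simulate_spect(ph$activity, ph$mu, g, det, angles = 10),
               "2 angles")
})

test_that("a centered uniform cylinder projects identically at every angle", {
  g <- small_grid(20)
  d <- g$shape
  fy <- (slice.index(array(0, d), 2) - 0.5) / d[2]
  fx <- (slice.index(array(0, d), 3) - 0.5) / d[3]
  # smooth radial profile: rotation invariance then holds up to bilinear
  # interpolation error rather than voxelisation of a hard edge
  r2 <- (fy - 0.5)^2 + (fx - 0.5)^2
  cyl <- exp(-r2 / (2 * 0.15^2))
  mu <- cyl * 0.01
  ps <- simulate_spect(cyl, mu, g, angles = seq(0, 315, by = 45),
                       noiseless = TRUE)
  ref <- ps$projections[[1]]
  for (a in 2:8)
    expect_lt(max(abs(ps$projections[[a]] - ref)) / max(ref), 0.02)
})

test_that("CT-number conversion hits the water and air anchors", {
  g <- small_grid(8)
  ct <- array(0, g$shape)
  expect_true(all(hu_to_mu(ct, g) == 0.0154))
  ct[] <- -1000
  expect_true(all(hu_to_mu(ct, g) == 0))
  ct[] <- 1000
  mu <- hu_to_mu(ct, g)
  # bone-like voxel lands in the trabecular-to-cortical range at 140 keV
  expect_true(all(mu > 0.02 & mu < 0.03))
  expect_equal(mu[1], 0.0154 + 1000 * 9.6e-6, tolerance = 1e-12)
  ct[] <- -2000
  expect_error(hu_to_mu(ct, g), "-1024")
})
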