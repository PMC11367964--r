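# helpers working directly on the internal projector pair
make_geom <- function(mu, g, angles, det = detector_model()) {
  replanar:::spect_geometry(mu, g, angles, det)
}
test_that("forward and backprojector form an exact adjoint pair", {
  g <- small_grid(12, vox = 2)
  mu <- uniform_mu(g, 0.008)
  for (det in list(detector_model(sensitivity = 1.3),
                   detector_model(sensitivity = 1, psf = TRUE))) {
    geom <- make_geom(mu, g, c(0, 33, 90, 147), det)
    set.seed(11)
    f <- array(runif(prod(g$shape)), c(geom$ny, geom$nx, geom$nz))
    p <- lapply(seq_along(geom$angles),
                function(a) matrix(runif(geom$nz * geom$nx), geom$nz, geom$nx))
    lhs <- sum(mapply(function(pf, pm) sum(pf * pm),
                      replanar:::spect_forward(f, geom), p))
    rhs <- sum(f * replanar:::spect_backward(p, geom))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("relative difference prior matches its closed form", {
  # single pair (4, 2), gamma 4: (4-2)^2 / (4+2+4*|4-2|+eps)
  eps <- 1e-9
  expect_equal(rdp_penalty(c(4, 2), gamma = 4, eps = eps),
               4 / (14 + eps), tolerance = 1e-12)
  # uniform volumes carry zero penalty
  expect_identical(rdp_penalty(array(3.7, c(5, 5, 5)), gamma = 4), 0)
  # symmetric in the pair ordering
  expect_equal(rdp_penalty(c(2, 4)), rdp_penalty(c(4, 2)))
  # larger gamma saturates edges: penalty decreases
  f <- array(c(1, 5), c(2, 4, 4))
  expect_lt(rdp_penalty(f, gamma = 10), rdp_penalty(f, gamma = 1))
})

test_that("RDP gradient agrees with numerical differentiation", {
  set.seed(3)
  f <- array(runif(4 * 4 * 4, 0.5, 3), c(4, 4, 4))
  gr <- replanar:::rdp_gradient(f, gamma = 4)
  h <- 1e-6
  for (idx in c(1L, 22L, 43L, 64L)) {
    fp <- f; fp[idx] <- fp[idx] + h
    fm <- f; fm[idx] <- fm[idx] - h
    num <- (rdp_penalty(fp, gamma = 4) - rdp_penalty(fm, gamma = 4)) / (2 * h)
    expect_equal(gr[idx], num, tolerance = 1e-5)
  }
  # gradient of a uniform volume vanishes
  expect_equal(max(abs(replanar:::rdp_gradient(array(2, c(4, 4, 4)), 4))), 0)
})

test_that("truth is a fixed point of MLEM on noiseless consistent data", {
  g <- small_grid(12, vox = 2)
  act <- mask_to_fov(blob_activity(g, radius = 0.15))
  mu <- uniform_mu(g, 0.01)
  proj <- simulate_spect(act, mu, g, angles = seq(0, 330, by = 30),
                         noiseless = TRUE)
  cfg <- recon_config("mlem", n_iterations = 1L)
  rec <- mlem_reconstruct(proj, mu, g, cfg, init = act)
  # inside the field of view the update leaves the truth untouched
  keep <- rec$volume > 0
  expect_lt(max(abs(rec$volume[keep] - act[keep]) / max(act)), 1e-10)
})

test_that("MLEM solves a two-voxel toy system exactly", {
  g <- small_grid(8, vox = 2)
  mu <- uniform_mu(g, 0.01)
  angles <- c(0, 90)
  # two sources in one x-column: mixed at angle 0, separated at angle 90
  truth <- array(0, g$shape)
  truth[4, 4, 4] <- 2
  truth[4, 6, 4] <- 5
  proj <- simulate_spect(truth, mu, g, angles = angles, noiseless = TRUE)
  cfg <- recon_config("mlem", n_iterations = 400L)
  init <- array(0, g$shape); init[4, 4, 4] <- 1; init[4, 6, 4] <- 1
  rec <- mlem_reconstruct(proj, mu, g, cfg, init = init)
  # multiplicative updates preserve the restricted support ...
  expect_equal(sum(rec$volume > 0), 2L)
  # ... and converge to the unique nonnegative solution, the truth
  expect_equal(rec$volume[4, 4, 4], 2, tolerance = 1e-6)
  expect_equal(rec$volume[4, 6, 4], 5, tolerance = 1e-6)
  # cross-check: the direct linear solve of the 2-unknown system agrees
  e1 <- array(0, g$shape); e1[4, 4, 4] <- 1
  e2 <- array(0, g$shape); e2[4, 6, 4] <- 1
  cols <- lapply(list(e1, e2), function(e)
    unlist(simulate_spect(e, mu, g, angles = angles,
                          noiseless = TRUE)$projections))
  A <- do.call(cbind, cols)
  y <- unlist(proj$projections)
  fhat <- qr.solve(A, y)
  expect_equal(unname(fhat), c(2, 5), tolerance = 1e-10)
})

test_that("BSREM with beta = 0 and unit relaxation reproduces OSEM exactly", {
  g <- small_grid(10, vox = 2)
  act <- blob_activity(g, radius = 0.2, amplitude = 30)
  mu <- uniform_mu(g, 0.008)
  proj <- simulate_spect(act, mu, g, angles = seq(0, 315, by = 45), seed = 4)
  co <- recon_config("osem", n_iterations = 3L, n_subsets = 4L)
  cb <- recon_config("bsrem_rdp", n_iterations = 3L, n_subsets = 4L,
                     beta = 0, relax_alpha0 = 1, relax_lambda = 0)
  ro <- osem_reconstruct(proj, mu, g, co)
  rb <- bsrem_rdp_reconstruct(proj, mu, g, cb)
  expect_identical(rb$volume, ro$volume)
})

test_that("reconstructions are nonnegative and deterministic", {
  g <- small_grid(10, vox = 2)
  act <- blob_activity(g, radius = 0.2, amplitude = 30)
  mu <- uniform_mu(g, 0.008)
  proj <- simulate_spect(act, mu, g, angles = seq(0, 315, by = 45), seed = 8)
  cfg <- recon_config("bsrem_rdp", n_iterations = 4L, n_subsets = 4L,
                      beta = 0.4, gamma = 4)
  r1 <- bsrem_rdp_reconstruct(proj, mu, g, cfg)
  r2 <- bsrem_rdp_reconstruct(proj, mu, g, cfg)
  expect_true(all(r1$volume >= 0))
  expect_identical(r1$volume, r2$volume)
})

test_that("noiseless OSEM recovers a smooth phantom inside the field of view", {
  g <- small_grid(16, vox = 2.46)
  act <- mask_to_fov(blob_activity(g, radius = 0.18, amplitude = 20))
  mu <- uniform_mu(g, 0.01)
  proj <- simulate_spect(act, mu, g, angles = seq(0, 345, by = 15),
                         noiseless = TRUE)
  cfg <- recon_config("osem", n_iterations = 40L, n_subsets = 4L)
  rec <- osem_reconstruct(proj, mu, g, cfg)
  cyx <- (16 + 1) / 2
  circ <- outer(seq_len(16) - cyx, seq_len(16) - cyx,
                function(a, b) a^2 + b^2) <= (16 / 2 - 1)^2
  fov <- aperm(array(circ, c(16, 16, 16)), c(3, 1, 2))  # to [z, y, x]
  nrmse <- sqrt(mean((rec$volume[fov] - act[fov])^2)) / max(act)
  expect_lt(nrmse, 0.05)
})

test_that("MLEM log-likelihood is monotonically non-decreasing", {
  g <- small_grid(10, vox = 2)
  act <- blob_activity(g, radius = 0.2, amplitude = 50)
  mu <- uniform_mu(g, 0.008)
  proj <- simulate_spect(act, mu, g, angles = seq(0, 315, by = 45), seed = 2)
  cfg <- recon_config("mlem", n_iterations = 12L, track_objective = TRUE)
  rec <- mlem_reconstruct(proj, mu, g, cfg)
  ll <- rec$log$objective
  expect_length(ll, 12L)
  expect_true(all(diff(ll) > -1e-8 * abs(ll[1])))
})

test_that("stronger RDP penalty yields smoother reconstructions", {
  g <- small_grid(10, vox = 2)
  act <- blob_activity(g, radius = 0.2, amplitude = 40)
  mu <- uniform_mu(g, 0.008)
  proj <- simulate_spect(act, mu, g, angles = seq(0, 315, by = 45), seed = 6)
  pen_of <- function(beta) {
    cfg <- recon_config("bsrem_rdp", n_iterations = 6L, n_subsets = 4L,
                        beta = beta, gamma = 4)
    rdp_penalty(bsrem_rdp_reconstruct(proj, mu, g, cfg)$volume, gamma = 4)
  }
  expect_lt(pen_of(2), pen_of(0.05))
})

test_that("degenerate inputs are handled explicitly", {
  g <- small_grid(8, vox = 2)
  mu <- uniform_mu(g, 0.01)
  expect_error(replanar:::subset_indices(10, 3), "divide")
  expect_equal(replanar:::subset_indices(8, 4),
               list(c(1, 5), c(2, 6), c(3, 7), c(4, 8)))
  proj <- simulate_spect(array(0, g$shape), mu, g, angles = c(0, 90),
                         noiseless = TRUE)
  expect_warning(rec <- mlem_reconstruct(proj, mu, g, recon_config("mlem")),
                 "all-zero")
  expect_true(all(rec$volume == 0))
  expect_error(recon_config(beta = -1))
})
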