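# shared fixtures built in code

small_grid <- function(n = 16L, vox = 2.46) grid_geometry(c(n, n, n), vox)

# smooth positive blob activity on an n^3 grid, entirely inside the
# inscribed rotation circle so it is fully visible to the SPECT geometry
blob_activity <- function(grid, center = c(0.5, 0.5, 0.5), radius = 0.28,
                          amplitude = 10) {
  d <- grid$shape
  fz <- (slice.index(array(0, d), 1) - 0.5) / d[1]
  fy <- (slice.index(array(0, d), 2) - 0.5) / d[2]
  fx <- (slice.index(array(0, d), 3) - 0.5) / d[3]
  r2 <- (fz - center[1])^2 + (fy - center[2])^2 + (fx - center[3])^2
  amplitude * exp(-r2 / (2 * radius^2))
}

uniform_mu <- function(grid, mu = 0.01) array(mu, grid$shape)

# restrict a [z, y, x] volume to the inscribed rotation circle, the
# support the reconstruction operates on
mask_to_fov <- function(vol) {
  d <- dim(vol)
  cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  circ <- outer(seq_len(d[2]) - cy, seq_len(d[3]) - cx,
                function(a, b) a^2 + b^2) <= (min(d[2], d[3]) / 2 - 1)^2
  fov <- aperm(array(circ, c(d[2], d[3], d[1])), c(3, 1, 2))
  vol * fov
}

# uniform disc image: bright circular blob on constant background
disc_image <- function(n = 64L, pixel_mm = 2.46, center_pix = c(40, 44),
                       radius_mm = 30, fg = 10, bg = 1) {
  m <- matrix(bg, n, n)
  pz <- (seq_len(n) - 0.5) * pixel_mm
  px <- (seq_len(n) - 0.5) * pixel_mm
  cz <- (center_pix[1] - 0.5) * pixel_mm
  cx <- (center_pix[2] - 0.5) * pixel_mm
  r2 <- outer((pz - cz)^2, (px - cx)^2, `+`)
  m[r2 <= radius_mm^2] <- fg
  replanar:::new_planar_image(m, pixel_mm, "conventional")
}

as_planar <- function(m, pixel_mm = 1) {
  replanar:::new_planar_image(m, pixel_mm, "conventional")
}
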