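#' Gamma-camera detector model
#'
#' Collects the detector response parameters shared by the planar and
#' SPECT forward models: a sensitivity scale (expected counts per
#' activity-unit times mm of ray path) and an optional depth-dependent
#' Gaussian point-spread function approximating a low-energy
#' high-resolution collimator, with full width at half maximum
#' `psf_fwhm_mm + psf_slope * distance` where distance is measured from
#' the detector face.
#'
#' @param sensitivity expected counts per (activity unit x mm).
#' @param psf logical; apply the depth-dependent PSF.
#' @param psf_fwhm_mm FWHM at the collimator face (default 4 mm).
#' @param psf_slope FWHM growth per mm of source-detector distance
#'   (default 0.04, representative of LEHR collimation).
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(sensitivity = 1, psf = FALSE,
                           psf_fwhm_mm = 4, psf_slope = 0.04) {
  stop_if_not_scalar_pos(sensitivity, "sensitivity")
  if (psf_fwhm_mm < 0 || psf_slope < 0)
    stop("PSF parameters must be >= 0", call. = FALSE)
  structure(list(sensitivity = sensitivity, psf = isTRUE(psf),
                 psf_fwhm_mm = psf_fwhm_mm, psf_slope = psf_slope),
            class = "detector_model")
}

#' Anterior attenuation path factor for one voxel
#'
#' Survival probability of a photon emitted in a voxel and travelling
#' along the anterior direction (-y) to the anterior grid face:
#' `exp(-sum(mu * delta))` where the discrete line integral accumulates
#' full voxel steps from the anterior face up to the voxel, with the
#' emitting voxel itself contributing half a step (midpoint convention).
#' The grid edge stands in for the edge of the object; air voxels carry
#' mu = 0 and contribute nothing.
#'
#' @param mu attenuation map, array `c(nz, ny, nx)` of per-mm coefficients.
#' @param voxel_index integer `c(z, y, x)` (1-based).
#' @param grid the [grid_geometry()] of `mu`.
#' @return scalar in (0, 1].
#' @export
attenuation_path_factor <- function(mu, voxel_index, grid) {
  check_volume_on_grid(mu, grid, "mu")
  vi <- as.integer(voxel_index)
  if (any(vi < 1L) || any(vi > grid$shape))
    stop("voxel_index outside grid", call. = FALSE)
  delta <- grid$voxel_size_mm
  ray <- mu[vi[1], seq_len(vi[2]), vi[3]]
  exp(-delta * (sum(ray) - ray[vi[2]] / 2))
}

## Full attenuation-factor array in internal [y, x, z] layout (compiled
## column-wise cumulative line integral, midpoint convention).
att_array_internal <- function(mu_int, voxel_mm) {
  att_factors_c(mu_int, dim(mu_int), voxel_mm)
}

## separable Gaussian blur of a (nz, nx) slab image, sigma in pixels;
## zero-padded with a symmetric kernel, hence exactly self-adjoint, which
## keeps the SPECT forward/backprojector pair matched under resolution
## recovery
gauss_blur_2d <- function(img, sigma_pix) {
  if (sigma_pix <= 1e-6) return(img)
  half <- max(1L, ceiling(3 * sigma_pix))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_pix^2))
  k <- k / sum(k)
  blur1 <- function(m) {    # along rows (dim 1)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) - off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(img))))
}

## Anterior attenuated projection of an internal-layout volume pair.
## Returns the planar matrix in user orientation (nz, nx).
project_anterior_internal <- function(act_int, att_int, det, voxel_mm) {
  d <- dim(act_int)   # (ny, nx, nz)
  if (det$psf && (det$psf_fwhm_mm > 0 || det$psf_slope > 0)) {
    ## blur each depth slab in the (z, x) detector plane before summation
    wa <- act_int * att_int
    acc <- matrix(0, d[3], d[2])          # (nz, nx)
    for (y in seq_len(d[1])) {
      slab <- t(matrix(wa[y, , ], d[2], d[3]))   # (nz, nx)
      fwhm <- det$psf_fwhm_mm + det$psf_slope * (y - 0.5) * voxel_mm
      sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_mm
      acc <- acc + gauss_blur_2d(slab, sigma)
    }
    det$sensitivity * voxel_mm * acc
  } else {
    project_sum_c(act_int, att_int, d, det$sensitivity * voxel_mm)
  }
}

new_planar_image <- function(mat, pixel_size_mm, provenance) {
  structure(list(matrix = mat, pixel_size_mm = pixel_size_mm,
                 view = "anterior", provenance = provenance),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("planar_image (%s, %s): %d x %d pixels, %.4g mm, total counts %.4g\n",
              x$view, x$provenance, nrow(x$matrix), ncol(x$matrix),
              x$pixel_size_mm, sum(x$matrix)))
  invisible(x)
}

#' Simulate a conventional anterior planar acquisition
#'
#' Forward-projects an activity volume onto a virtual anterior detector:
#' each planar pixel (z, x) is `sensitivity * delta * sum_y activity *
#' attenuation_path_factor`, with an optional depth-dependent Gaussian
#' PSF applied per depth slab before summation. With `noiseless = FALSE`
#' every pixel is replaced by a seeded Poisson draw with that mean,
#' giving integer counts.
#'
#' @param activity,mu matched 3D arrays on `grid`.
#' @param grid [grid_geometry()].
#' @param det [detector_model()].
#' @param seed seed for the Poisson draw.
#' @param noiseless logical; TRUE returns the real-valued expectation.
#' @return A `planar_image` with provenance `"conventional"`; matrix dims
#'   `(nz, nx)`, pixel size equal to the voxel size.
#' @export
simulate_planar <- function(activity, mu, grid, det = detector_model(),
                            seed = 1L, noiseless = FALSE) {
  check_volume_on_grid(activity, grid, "activity")
  check_volume_on_grid(mu, grid, "mu")
  act_int <- vol_to_internal(activity)
  att <- att_array_internal(vol_to_internal(mu), grid$voxel_size_mm)
  img <- project_anterior_internal(act_int, att, det, grid$voxel_size_mm)
  if (!noiseless)
    img <- matrix(with_seed(seed, rpois(length(img), lambda = img)),
                  nrow(img), ncol(img))
  new_planar_image(img, grid$voxel_size_mm, "conventional")
}

## sparse bilinear in-plane rotation operator for the (y, x) plane,
## mapping the unrotated pixel vector (y fastest) to the rotated one;
## samples outside the grid are treated as air (zero)
rotation_operator <- function(theta_deg, ny, nx) {
  th <- theta_deg * pi / 180
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  gy <- rep(seq_len(ny), times = nx)
  gx <- rep(seq_len(nx), each = ny)
  dy <- gy - cy; dx <- gx - cx
  sy <- cy + cos(th) * dy - sin(th) * dx
  sx <- cx + sin(th) * dy + cos(th) * dx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  tgt <- seq_len(ny * nx)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (oy in 0:1) for (ox in 0:1) {
    yy <- y0 + oy; xx <- x0 + ox
    wt <- (if (oy == 0) 1 - fy else fy) * (if (ox == 0) 1 - fx else fx)
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx & wt > 0
    rows <- c(rows, tgt[ok])
    cols <- c(cols, yy[ok] + ny * (xx[ok] - 1))
    vals <- c(vals, wt[ok])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(ny * nx, ny * nx))
}

## Precomputed acquisition geometry: per-angle rotation operators and
## attenuation-factor arrays. Shared by SPECT simulation, reconstruction
## system model, and their adjoints.
.rot_cache <- new.env(parent = emptyenv())

rotation_operators <- function(angles, ny, nx) {
  key <- paste(ny, nx, paste(format(angles, digits = 12), collapse = ","),
               sep = "|")
  if (!is.null(.rot_cache[[key]])) return(.rot_cache[[key]])
  ops <- lapply(angles, rotation_operator, ny = ny, nx = nx)
  .rot_cache[[key]] <- ops
  ops
}

spect_geometry <- function(mu, grid, angles, det) {
  check_volume_on_grid(mu, grid, "mu")
  if (length(angles) < 2L) stop("need at least 2 angles", call. = FALSE)
  if (any(diff(angles) <= 0) || any(angles < 0) || any(angles >= 360))
    stop("angles must be strictly increasing within [0, 360)", call. = FALSE)
  d <- grid$shape   # (nz, ny, nx)
  ny <- d[2]; nx <- d[3]; nz <- d[1]
  mu_m <- matrix(vol_to_internal(mu), ny * nx, nz)
  ops <- rotation_operators(angles, ny, nx)
  atts <- lapply(ops, function(S) {
    mur <- as.matrix(S %*% mu_m)
    dim(mur) <- c(ny, nx, nz)
    att_array_internal(mur, grid$voxel_size_mm)
  })
  list(angles = angles, ops = ops, atts = atts, det = det, grid = grid,
       ny = ny, nx = nx, nz = nz)
}

## forward: internal volume -> list of (nz, nx) projections
spect_forward <- function(act_int, geom) {
  fm <- matrix(act_int, geom$ny * geom$nx, geom$nz)
  lapply(seq_along(geom$angles), function(a) {
    fr <- as.matrix(geom$ops[[a]] %*% fm)
    dim(fr) <- c(geom$ny, geom$nx, geom$nz)
    project_anterior_internal(fr, geom$atts[[a]], geom$det,
                              geom$grid$voxel_size_mm)
  })
}

## matched adjoint: list of (nz, nx) projections -> internal volume
spect_backward <- function(projs, geom) {
  ny <- geom$ny; nx <- geom$nx; nz <- geom$nz
  det <- geom$det
  vox <- geom$grid$voxel_size_mm
  w <- det$sensitivity * vox
  use_psf <- det$psf && (det$psf_fwhm_mm > 0 || det$psf_slope > 0)
  acc <- matrix(0, ny * nx, nz)
  for (a in seq_along(geom$angles)) {
    pr <- projs[[a]]                        # (nz, nx)
    if (use_psf) {
      ## adjoint of the per-slab blur: blur the projection with each
      ## slab's (self-adjoint) kernel before spreading along y
      sp <- array(0, c(ny, nx, nz))
      for (y in seq_len(ny)) {
        fwhm <- det$psf_fwhm_mm + det$psf_slope * (y - 0.5) * vox
        sigma <- fwhm / (2 * sqrt(2 * log(2))) / vox
        sp[y, , ] <- t(gauss_blur_2d(pr, sigma))
      }
      sp <- sp * geom$atts[[a]]
    } else {
      sp <- spread_weight_c(pr, geom$atts[[a]], c(ny, nx, nz))
    }
    acc <- acc + Matrix::crossprod(geom$ops[[a]], matrix(sp, ny * nx, nz)) * w
  }
  out <- as.matrix(acc)
  dim(out) <- c(ny, nx, nz)
  out
}

new_projection_set <- function(projs, angles, pixel_size_mm, poisson) {
  structure(list(projections = projs, angles = angles,
                 n_angles = length(angles), pixel_size_mm = pixel_size_mm,
                 poisson = poisson),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("projection_set: %d angles, %d x %d pixels each, %s counts\n",
              x$n_angles, nrow(x$projections[[1]]), ncol(x$projections[[1]]),
              if (x$poisson) "Poisson" else "noiseless expected"))
  invisible(x)
}

#' Simulate a multi-angle SPECT acquisition
#'
#' Parallel-beam abstraction of a rotating (or ring) camera: for each
#' detector angle the activity and attenuation volumes are rotated about
#' the z axis (bilinear in-plane interpolation) and projected exactly as
#' in [simulate_planar()]. The 0-degree projection therefore coincides
#' with the anterior planar forward model.
#'
#' @param activity,mu matched 3D arrays on `grid`.
#' @param grid [grid_geometry()].
#' @param det [detector_model()].
#' @param angles strictly increasing detector angles in degrees within
#'   `[0, 360)`; default 60 evenly spaced views.
#' @param seed seed for Poisson draws.
#' @param noiseless logical.
#' @return A `projection_set`.
#' @export
simulate_spect <- function(activity, mu, grid, det = detector_model(),
                           angles = seq(0, 354, by = 6), seed = 1L,
                           noiseless = FALSE) {
  check_volume_on_grid(activity, grid, "activity")
  geom <- spect_geometry(mu, grid, angles, det)
  projs <- spect_forward(vol_to_internal(activity), geom)
  if (!noiseless) {
    projs <- with_seed(seed, lapply(projs, function(p)
      matrix(rpois(length(p), lambda = p), nrow(p), ncol(p))))
  }
  new_projection_set(projs, angles, grid$voxel_size_mm, poisson = !noiseless)
}

#' Convert CT numbers to a 140 keV attenuation map
#'
#' Piecewise-linear (bilinear) calibration: for HU <= 0,
#' `mu = mu_water * (1 + HU/1000)` (air-water segment); for HU > 0,
#' `mu = mu_water + HU * k_bone` (water-bone segment). Output is clipped
#' at zero.
#'
#' @param ct 3D array of CT numbers (HU, >= -1024).
#' @param grid [grid_geometry()].
#' @param mu_water water attenuation per mm at 140 keV (default 0.0154).
#' @param k_bone bone-segment slope per HU per mm; the default 9.6e-6
#'   places a ~1100 HU cortical-like voxel near 0.026 per mm, consistent
#'   with standard attenuation tables.
#' @return attenuation map array on `grid`.
#' @export
hu_to_mu <- function(ct, grid, mu_water = 0.0154, k_bone = 9.6e-6) {
  check_volume_on_grid(ct, grid, "ct")
  if (any(ct < -1024)) stop("CT numbers must be >= -1024", call. = FALSE)
  mu <- ifelse(ct <= 0, mu_water * (1 + ct / 1000), mu_water + ct * k_bone)
  mu[mu < 0] <- 0
  array(mu, dim(ct))
}
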