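#' Reproject a reconstructed volume to a virtual anterior planar image
#'
#' The central operator of the verification: from a reconstructed
#' activity volume and its attenuation map, synthesize the planar image a
#' conventional anterior detector would have seen. Each planar pixel
#' (z, x) is `scale * delta * sum_y recon(z,y,x) * exp(-integral of mu
#' from the voxel to the anterior edge of the object)`, the same
#' attenuated line integral as the planar forward model (midpoint
#' self-voxel convention, grid face standing in for the object edge, air
#' contributing mu = 0). No point-spread function is applied here —
#' resolution handling lives in the reconstruction system model.
#'
#' With `recon` equal to the true activity, the reprojected image equals
#' the noiseless conventional planar simulation pixel for pixel.
#'
#' @param recon nonnegative activity volume, dims `c(nz, ny, nx)`.
#' @param mu matched attenuation map.
#' @param grid [grid_geometry()].
#' @param scale overall intensity scale (default 1).
#' @return A `planar_image` with provenance `"reprojected"`, matrix dims
#'   `(nz, nx)`, pixel size equal to the voxel size.
#' @export
reproject_planar <- function(recon, mu, grid, scale = 1) {
  check_volume_on_grid(recon, grid, "recon")
  check_volume_on_grid(mu, grid, "mu")
  if (any(recon < 0)) stop("recon must be nonnegative", call. = FALSE)
  att <- att_array_internal(vol_to_internal(mu), grid$voxel_size_mm)
  det <- detector_model(sensitivity = scale, psf = FALSE)
  img <- project_anterior_internal(vol_to_internal(recon), att, det,
                                   grid$voxel_size_mm)
  new_planar_image(img, grid$voxel_size_mm, "reprojected")
}

#' Paired study images for one subject
#'
#' Produces the two images compared by the study design for a single
#' phantom: (a) the conventional anterior planar acquisition simulated
#' directly from the true activity, and (b) the reprojected planar image
#' obtained by simulating a SPECT acquisition, reconstructing it with the
#' study-default BSREM-RDP settings, and forward-projecting the
#' reconstruction through the attenuation map. Both images live on the
#' same pixel grid (the reconstruction grid), so no resampling is needed.
#'
#' @param phantom a `phantom` from [make_phantom()].
#' @param det [detector_model()] used for both acquisitions.
#' @param seed master seed for this subject; planar and SPECT noise
#'   streams are derived from it independently.
#' @param noiseless logical; TRUE skips Poisson noise in both pathways.
#' @param perfect_recon logical; TRUE bypasses reconstruction and
#'   reprojects the true activity (end-to-end consistency shortcut).
#' @param angles SPECT detector angles.
#' @param n_iterations,n_subsets reconstruction schedule passed to
#'   [reconstruct_for_study()].
#' @return list with elements `conventional` and `reprojected` (both
#'   `planar_image`) and `recon_log`.
#' @export
paired_study_images <- function(phantom, det = detector_model(),
                                seed = 1L, noiseless = FALSE,
                                perfect_recon = FALSE,
                                angles = seq(0, 354, by = 6),
                                n_iterations = 20L, n_subsets = 6L) {
  stopifnot(inherits(phantom, "phantom"))
  grid <- phantom$grid
  conv <- simulate_planar(phantom$activity, phantom$mu, grid, det,
                          seed = derive_seed(seed, "planar"),
                          noiseless = noiseless)
  if (perfect_recon) {
    rp <- reproject_planar(phantom$activity, phantom$mu, grid,
                           scale = det$sensitivity)
    recon_log <- list(algorithm = "perfect", note = "truth used as recon")
  } else {
    proj <- simulate_spect(phantom$activity, phantom$mu, grid, det,
                           angles = angles,
                           seed = derive_seed(seed, "spect"),
                           noiseless = noiseless)
    rec <- reconstruct_for_study(proj, phantom$mu, grid, det,
                                 n_iterations = n_iterations,
                                 n_subsets = n_subsets)
    rp <- reproject_planar(rec$volume, phantom$mu, grid,
                           scale = det$sensitivity)
    recon_log <- rec$log
  }
  list(conventional = conv, reprojected = rp, recon_log = recon_log)
}
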