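#' Write a volume as NIfTI-1
#'
#' Stores the array with its voxel size (mm) in the header. The package's
#' `[z, y, x]` index convention is preserved as the on-disk axis order.
#'
#' @param vol 3D array on `grid`.
#' @param grid [grid_geometry()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(vol, grid, path) {
  check_volume_on_grid(vol, grid, "vol")
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(grid$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path NIfTI file with isotropic voxels.
#' @return list with `volume` (array) and `grid` ([grid_geometry()]).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)
  if (length(vox) < 3 || diff(range(vox[1:3])) > 1e-6)
    stop("expected an isotropic 3D NIfTI volume", call. = FALSE)
  vol <- array(as.numeric(img), dim(img))
  list(volume = vol, grid = grid_geometry(dim(vol), vox[1]))
}

#' Write a planar image as a 2D NIfTI with a provenance sidecar
#'
#' @param img a `planar_image`.
#' @param path output file; a matching `.json` sidecar records the view,
#'   provenance, and pixel size.
#' @return the path, invisibly.
#' @export
write_planar_nifti <- function(img, path) {
  stopifnot(inherits(img, "planar_image"))
  ni <- RNifti::asNifti(img$matrix)
  RNifti::pixdim(ni) <- rep(img$pixel_size_mm, 2)
  RNifti::writeNifti(ni, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(view = img$view, provenance = img$provenance,
                            pixel_size_mm = img$pixel_size_mm),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' Read a planar image written by [write_planar_nifti()]
#'
#' @param path NIfTI file; the `.json` sidecar is read when present.
#' @return a `planar_image`.
#' @export
read_planar_nifti <- function(path) {
  ni <- RNifti::readNifti(path)
  m <- as.matrix(ni)
  vox <- RNifti::pixdim(ni)[1]
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  prov <- "conventional"
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    prov <- meta$provenance
    if (!is.null(meta$pixel_size_mm)) vox <- meta$pixel_size_mm
  }
  new_planar_image(m, vox, prov)
}
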