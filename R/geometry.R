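#' Voxel grid geometry
#'
#' Defines the common metric voxel grid shared by activity volumes and
#' attenuation maps. The axis convention is fixed throughout the package:
#' volumes are arrays indexed `[z, y, x]` with axis z running caudal to
#' cranial, axis y anterior to posterior (index 1 is the anterior face,
#' i.e. the virtual detector side), and axis x patient-right to
#' patient-left (index 1 is the patient's right).
#'
#' @param shape integer vector `c(nz, ny, nx)`; every dimension must be
#'   at least 8 voxels.
#' @param voxel_size_mm isotropic voxel edge length in mm (default 2.46,
#'   the reconstruction voxel size used throughout the package).
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(c(64, 64, 64))
#' g$voxel_size_mm
#' @export
grid_geometry <- function(shape = c(64L, 64L, 64L), voxel_size_mm = 2.46) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)))
    stop("'shape' must be three integers (nz, ny, nx)", call. = FALSE)
  if (any(shape < 8L))
    stop("all grid dimensions must be >= 8 voxels", call. = FALSE)
  stop_if_not_scalar_pos(voxel_size_mm, "voxel_size_mm")
  structure(
    list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels (z, y, x), %.4g mm isotropic\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size_mm))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm))
}

check_volume_on_grid <- function(vol, grid, name = "volume") {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop(sprintf("'%s' must be a 3D array", name), call. = FALSE)
  if (!identical(as.integer(dim(vol)), grid$shape))
    stop(sprintf("'%s' dimensions %s do not match grid %s", name,
                 paste(dim(vol), collapse = "x"),
                 paste(grid$shape, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

## Internal compute layout: [y, x, z]. The y axis (projection axis) comes
## first so attenuation cumsums and ray sums are contiguous column ops,
## and the (y, x) rotation plane maps onto the leading matrix dimension.
vol_to_internal <- function(vol) aperm(vol, c(2L, 3L, 1L))
vol_from_internal <- function(v) aperm(v, c(3L, 1L, 2L))

## metric coordinate (mm) of pixel/voxel center for 1-based index i
index_to_mm <- function(i, voxel_size_mm) (i - 0.5) * voxel_size_mm
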