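#' Circular region of interest on a planar image
#'
#' ROI centers are given in metric image coordinates: `z_mm` along the
#' first matrix dimension and `x_mm` along the second, measured from the
#' image edge with pixel centers at `(i - 0.5) * pixel_size_mm`. The
#' default diameter is 70 mm, the clinical heart-ROI size.
#'
#' @param center_z_mm,center_x_mm ROI center (mm).
#' @param diameter_mm ROI diameter (default 70).
#' @param side `"heart"` or `"contralateral"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center_z_mm, center_x_mm, diameter_mm = 70,
                     side = c("heart", "contralateral")) {
  side <- match.arg(side)
  stop_if_not_scalar_pos(diameter_mm, "diameter_mm")
  structure(list(center_z_mm = center_z_mm, center_x_mm = center_x_mm,
                 diameter_mm = diameter_mm, side = side),
            class = "roi_spec")
}

## logical pixel-membership mask: pixel center strictly inside or on the
## circle (no partial-area weighting)
roi_mask <- function(img, roi) {
  d <- dim(img$matrix)
  pz <- index_to_mm(seq_len(d[1]), img$pixel_size_mm)
  px <- index_to_mm(seq_len(d[2]), img$pixel_size_mm)
  r2 <- outer((pz - roi$center_z_mm)^2, (px - roi$center_x_mm)^2, `+`)
  r2 <= (roi$diameter_mm / 2)^2
}

roi_inside_image <- function(img, roi) {
  r <- roi$diameter_mm / 2
  d <- dim(img$matrix)
  roi$center_z_mm - r >= 0 && roi$center_x_mm - r >= 0 &&
    roi$center_z_mm + r <= d[1] * img$pixel_size_mm &&
    roi$center_x_mm + r <= d[2] * img$pixel_size_mm
}

#' Automatically place the heart ROI
#'
#' Deterministic stand-in for manual ROI placement: among all feasible
#' centers (ROI fully inside the image) whose pixel lies in the search
#' region, pick the one maximizing mean counts inside the 70-mm disc.
#' Ties are broken toward the smallest z, then the smallest x. The
#' default search region is the patient-left half of the image with the
#' lowest 30% of z rows excluded (keeping high-uptake kidneys out of the
#' search).
#'
#' @param img a `planar_image`.
#' @param diameter_mm ROI diameter (default 70).
#' @param search optional logical matrix, same dims as the image, marking
#'   admissible center pixels.
#' @return A `roi_spec` with side `"heart"`.
#' @export
auto_place_heart_roi <- function(img, diameter_mm = 70, search = NULL) {
  d <- dim(img$matrix)
  ps <- img$pixel_size_mm
  r <- diameter_mm / 2
  if (d[1] * ps < diameter_mm || d[2] * ps < diameter_mm)
    stop(sprintf("image (%.0f x %.0f mm) cannot contain a %.0f-mm ROI",
                 d[1] * ps, d[2] * ps, diameter_mm), call. = FALSE)
  if (is.null(search)) {
    search <- matrix(FALSE, d[1], d[2])
    zmin <- floor(0.30 * d[1]) + 1L
    xmid <- ceiling(d[2] / 2) + 1L
    search[zmin:d[1], xmid:d[2]] <- TRUE
  }
  pz <- index_to_mm(seq_len(d[1]), ps)
  px <- index_to_mm(seq_len(d[2]), ps)
  feas_z <- pz - r >= 0 & pz + r <= d[1] * ps
  feas_x <- px - r >= 0 & px + r <= d[2] * ps
  cand <- which(search & outer(feas_z, feas_x, `&`), arr.ind = TRUE)
  if (nrow(cand) == 0) stop("no feasible ROI center in search region",
                            call. = FALSE)
  ## disc mean at every candidate via 2D convolution with the disc kernel
  rad_pix <- r / ps
  half <- floor(rad_pix)
  off <- seq(-half, half)
  disc <- outer(off^2, off^2, `+`) <= rad_pix^2
  npix <- sum(disc)
  m <- img$matrix
  best <- -Inf; best_zi <- NA; best_xi <- NA
  ## candidates ordered so the first maximum found honours the tie-break
  ord <- order(cand[, 1], cand[, 2])
  for (i in ord) {
    zi <- cand[i, 1]; xi <- cand[i, 2]
    zr <- zi + off; xr <- xi + off
    okz <- zr >= 1 & zr <= d[1]; okx <- xr >= 1 & xr <= d[2]
    s <- sum(m[zr[okz], xr[okx], drop = FALSE] * disc[okz, okx, drop = FALSE])
    val <- s / npix
    if (val > best + 1e-12) { best <- val; best_zi <- zi; best_xi <- xi }
  }
  roi_spec(index_to_mm(best_zi, ps), index_to_mm(best_xi, ps),
           diameter_mm, side = "heart")
}

#' Mirror the heart ROI into the contralateral thorax
#'
#' Reflects the ROI center across the mid-sagittal line
#' `x_mid = image width / 2`, preserving z and diameter. If the mirrored
#' disc would leave the image it is shifted minimally inward along x and
#' the adjustment is recorded in the `adjusted_mm` attribute (the manual
#' analogue adjusts the contralateral ROI to an equivalent area).
#' Mirroring a heart ROI centered exactly on the midline returns the same
#' center with a warning.
#'
#' @param heart a `roi_spec` (side `"heart"`).
#' @param img the `planar_image` the ROI lives on.
#' @return A `roi_spec` with side `"contralateral"`.
#' @export
mirror_roi <- function(heart, img) {
  stopifnot(inherits(heart, "roi_spec"))
  if (!roi_inside_image(img, heart))
    stop("heart ROI not fully inside image", call. = FALSE)
  width_mm <- ncol(img$matrix) * img$pixel_size_mm
  x_mid <- width_mm / 2
  xr <- 2 * x_mid - heart$center_x_mm
  if (abs(heart$center_x_mm - x_mid) < 1e-9)
    warning("heart ROI centered on the mid-sagittal line; mirrored ROI coincides")
  r <- heart$diameter_mm / 2
  adj <- 0
  if (xr - r < 0) { adj <- r - xr; xr <- r }
  if (xr + r > width_mm) { adj <- (width_mm - r) - xr; xr <- width_mm - r }
  out <- roi_spec(heart$center_z_mm, xr, heart$diameter_mm,
                  side = "contralateral")
  attr(out, "adjusted_mm") <- adj
  out
}

#' Heart-to-contralateral ratio
#'
#' `H/CL = (heart ROI mean counts/pixel) / (contralateral ROI mean
#' counts/pixel)`, with arithmetic means over pixels whose centers fall
#' inside each disc. A ratio of at least 1.5 is classified positive
#' (boundary inclusive).
#'
#' @param img a `planar_image`.
#' @param heart,cl `roi_spec` objects, both fully inside the image.
#' @return An object of class `hcl_result`: heart_mean, cl_mean, ratio,
#'   positive_flag, n_pixels per ROI.
#' @export
compute_hcl <- function(img, heart, cl) {
  for (roi in list(heart, cl))
    if (!roi_inside_image(img, roi))
      stop(sprintf("%s ROI not fully inside image", roi$side), call. = FALSE)
  mh <- roi_mask(img, heart)
  mc <- roi_mask(img, cl)
  heart_mean <- mean(img$matrix[mh])
  cl_mean <- mean(img$matrix[mc])
  if (cl_mean <= 0)
    stop("contralateral ROI mean is zero: H/CL ratio undefined", call. = FALSE)
  ratio <- heart_mean / cl_mean
  structure(list(heart_mean = heart_mean, cl_mean = cl_mean, ratio = ratio,
                 positive_flag = ratio >= 1.5,
                 n_pixels = c(heart = sum(mh), contralateral = sum(mc))),
            class = "hcl_result")
}

#' @export
print.hcl_result <- function(x, ...) {
  cat(sprintf("H/CL = %.3f (%s): heart %.3f, contralateral %.3f counts/pixel\n",
              x$ratio, if (x$positive_flag) "positive" else "negative",
              x$heart_mean, x$cl_mean))
  invisible(x)
}

#' One-call H/CL measurement with automatic ROI placement
#'
#' @param img a `planar_image`.
#' @param center optional `c(z_mm, x_mm)` heart-ROI center overriding the
#'   automatic placement (the manual-workflow analogue).
#' @param diameter_mm ROI diameter (default 70).
#' @return An `hcl_result` with the two `roi_spec`s attached as
#'   attributes `heart_roi` and `cl_roi`.
#' @export
measure_hcl <- function(img, center = NULL, diameter_mm = 70) {
  heart <- if (is.null(center))
    auto_place_heart_roi(img, diameter_mm)
  else roi_spec(center[1], center[2], diameter_mm, side = "heart")
  cl <- mirror_roi(heart, img)
  res <- compute_hcl(img, heart, cl)
  attr(res, "heart_roi") <- heart
  attr(res, "cl_roi") <- cl
  res
}
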