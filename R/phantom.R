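#' Map a myocardial-to-rib uptake ratio to a visual-score class
#'
#' The 4-point visual grading of myocardial bone-tracer uptake is anchored
#' to rib uptake: grade 0 means no myocardial uptake, grade 1 uptake below
#' rib level, grade 2 uptake equal to rib level, and grade 3 uptake above
#' rib level with faint ribs. The package maps its continuous
#' myocardial-to-rib concentration ratio onto these classes with fixed
#' thresholds: 0 for a ratio of exactly 0, 1 for ratios below 0.8, 2 for
#' ratios in [0.8, 1.3], and 3 above 1.3.
#'
#' @param ratio non-negative myocardial-to-rib concentration ratio.
#' @return integer class in 0..3 (vectorised).
#' @export
class_from_ratio <- function(ratio) {
  if (any(ratio < 0)) stop("ratio must be >= 0", call. = FALSE)
  ifelse(ratio == 0, 0L, ifelse(ratio < 0.8, 1L, ifelse(ratio <= 1.3, 2L, 3L)))
}

#' Digital thorax phantom specification
#'
#' Describes a simplified anthropomorphic thorax built from analytic
#' axis-aligned primitives (elliptical body cylinder, lung ellipsoids,
#' spine and sternum bone, rib bands, myocardial shell with ventricular
#' blood pool, kidneys), each carrying an activity concentration
#' (arbitrary units) and a linear attenuation coefficient (per mm at
#' 140 keV). The myocardial shell concentration is always
#' `myo_to_rib_ratio * rib_uptake`, so the simulated cohort spans the
#' visual-score classes by construction.
#'
#' Organ positions and sizes are expressed as fractions of the grid extent
#' so phantoms scale with the grid. Overlapping primitives are resolved by
#' a fixed precedence (later wins): soft tissue, lungs, spine, sternum,
#' ribs, kidneys, blood pool, myocardium.
#'
#' @param grid a [grid_geometry()].
#' @param rib_uptake activity concentration of bone (spine, sternum, ribs).
#' @param myo_to_rib_ratio myocardial-to-rib concentration ratio (>= 0).
#' @param soft_uptake,lung_uptake,blood_uptake,kidney_uptake background
#'   activity concentrations.
#' @param mu_soft,mu_lung,mu_bone linear attenuation coefficients per mm at
#'   140 keV; defaults 0.0154 (water-equivalent soft tissue), 0.004
#'   (inflated lung), 0.025 (bone surrogate).
#' @param heart_center fractional (z, y, x) heart center; x must be
#'   strictly > 0.5 (patient-left half).
#' @param heart_outer_frac,heart_wall_frac outer myocardial radius as a
#'   fraction of grid extent, and wall thickness as a fraction of the
#'   outer radius.
#' @param jitter logical; when TRUE, [make_phantom()] draws a seeded
#'   anatomical perturbation (translation up to `jitter_shift_mm`, size
#'   scale within `1 +/- jitter_size_frac`).
#' @param jitter_shift_mm,jitter_size_frac jitter bounds (defaults 10 mm,
#'   0.10).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = grid_geometry(),
                         rib_uptake = 4,
                         myo_to_rib_ratio = 1,
                         soft_uptake = 0.7,
                         lung_uptake = 0.2,
                         blood_uptake = 0.8,
                         kidney_uptake = 4,
                         mu_soft = 0.0154,
                         mu_lung = 0.004,
                         mu_bone = 0.025,
                         heart_center = c(z = 0.45, y = 0.35, x = 0.62),
                         heart_outer_frac = 0.22,
                         heart_wall_frac = 0.45,
                         jitter = FALSE,
                         jitter_shift_mm = 10,
                         jitter_size_frac = 0.10) {
  if (!inherits(grid, "grid_geometry")) stop("'grid' must be a grid_geometry")
  if (myo_to_rib_ratio < 0) stop("myo_to_rib_ratio must be >= 0")
  conc <- c(rib_uptake, soft_uptake, lung_uptake, blood_uptake, kidney_uptake)
  if (any(conc < 0)) stop("activity concentrations must be >= 0")
  if (heart_center[["x"]] <= 0.5)
    stop("heart center must lie strictly in the patient-left half (x > 0.5)")
  if (!(mu_lung < mu_soft && mu_soft < mu_bone))
    stop("attenuation ordering violated: need mu_lung < mu_soft < mu_bone")
  structure(list(
    grid = grid, rib_uptake = rib_uptake, myo_to_rib_ratio = myo_to_rib_ratio,
    soft_uptake = soft_uptake, lung_uptake = lung_uptake,
    blood_uptake = blood_uptake, kidney_uptake = kidney_uptake,
    mu_soft = mu_soft, mu_lung = mu_lung, mu_bone = mu_bone,
    heart_center = heart_center, heart_outer_frac = heart_outer_frac,
    heart_wall_frac = heart_wall_frac,
    perugini_class_truth = class_from_ratio(myo_to_rib_ratio),
    jitter = isTRUE(jitter), jitter_shift_mm = jitter_shift_mm,
    jitter_size_frac = jitter_size_frac
  ), class = "phantom_spec")
}

## fractional coordinate arrays in user layout [z, y, x]
frac_coords <- function(grid) {
  d <- grid$shape
  list(
    fz = (slice.index(array(0, d), 1) - 0.5) / d[1],
    fy = (slice.index(array(0, d), 2) - 0.5) / d[2],
    fx = (slice.index(array(0, d), 3) - 0.5) / d[3]
  )
}

ellipsoid_mask <- function(co, cz, cy, cx, rz, ry, rx) {
  ((co$fz - cz) / rz)^2 + ((co$fy - cy) / ry)^2 + ((co$fx - cx) / rx)^2 <= 1
}

#' Build one digital thorax phantom
#'
#' Rasterises a [phantom_spec()] onto its grid, producing a matched
#' activity volume and attenuation map plus a ground-truth record that
#' replaces human visual scoring in the synthetic study.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; controls the anatomical jitter draw when
#'   `spec$jitter` is TRUE. The same (spec, seed) pair always yields
#'   bit-identical volumes.
#' @param subject_id identifier stored in the truth record.
#' @return An object of class `phantom`: list with `activity` and `mu`
#'   arrays (dims `c(nz, ny, nx)`), `grid`, `truth` (subject_id,
#'   perugini_class_truth, myo_to_rib_ratio, heart_center_mm,
#'   total_activity) and organ `masks` (myocardium, blood pool, ribs,
#'   bone, lungs, body).
#' @export
make_phantom <- function(spec, seed = 1L, subject_id = "s1") {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  d <- grid$shape
  extent_mm <- d * grid$voxel_size_mm   # (z, y, x) extents

  shift <- c(0, 0, 0); scale <- 1
  if (spec$jitter) {
    draws <- with_seed(seed, runif(4, -1, 1))
    shift <- draws[1:3] * spec$jitter_shift_mm / extent_mm   # fractional
    scale <- 1 + draws[4] * spec$jitter_size_frac
  }

  hc <- c(spec$heart_center[["z"]] + shift[1],
          spec$heart_center[["y"]] + shift[2],
          spec$heart_center[["x"]] + shift[3])
  ## keep the laterality invariant under jitter
  hc[3] <- max(hc[3], 0.52)

  co <- frac_coords(grid)
  act <- array(0, d)
  mu <- array(0, d)
  label <- array("air", d)
  assign_organ <- function(mask, a, m, name) {
    act[mask] <<- a
    mu[mask] <<- m
    label[mask] <<- name
  }

  ## body: elliptical cylinder along z
  body <- ((co$fy - 0.52) / 0.42)^2 + ((co$fx - 0.5) / 0.46)^2 <= 1
  assign_organ(body, spec$soft_uptake, spec$mu_soft, "soft")

  ## lungs
  lr <- 0.16 * scale
  lungL <- ellipsoid_mask(co, 0.55, 0.48, 0.72, 0.32 * scale, 0.28 * scale, lr)
  lungR <- ellipsoid_mask(co, 0.55, 0.48, 0.28, 0.32 * scale, 0.28 * scale, lr)
  lungs <- (lungL | lungR) & body
  assign_organ(lungs, spec$lung_uptake, spec$mu_lung, "lung")

  ## spine: posterior cylinder along z
  spine <- (((co$fy - 0.80) / 0.07)^2 + ((co$fx - 0.5) / 0.07)^2 <= 1) & body
  assign_organ(spine, spec$rib_uptake, spec$mu_bone, "bone")

  ## sternum: anterior midline bar
  sternum <- abs(co$fy - 0.13) < 0.035 & abs(co$fx - 0.5) < 0.06 &
    co$fz > 0.35 & co$fz < 0.85 & body
  assign_organ(sternum, spec$rib_uptake, spec$mu_bone, "bone")

  ## ribs: thin shell just under the body surface, in periodic z bands
  r2 <- ((co$fy - 0.52) / 0.42)^2 + ((co$fx - 0.5) / 0.46)^2
  zb <- (co$fz %% 0.125) < 0.05
  ribs <- r2 > 0.70 & r2 <= 0.94 & zb & body
  assign_organ(ribs, spec$rib_uptake, spec$mu_bone, "rib")

  ## kidneys: low, posterior, paired
  kid <- ellipsoid_mask(co, 0.10, 0.62, 0.34, 0.08, 0.07, 0.06) |
    ellipsoid_mask(co, 0.10, 0.62, 0.66, 0.08, 0.07, 0.06)
  kid <- kid & body
  assign_organ(kid, spec$kidney_uptake, spec$mu_soft, "kidney")

  ## heart: myocardial shell + blood pool, patient-left anterior
  r_out <- spec$heart_outer_frac * scale
  r_in <- r_out * (1 - spec$heart_wall_frac)
  outer <- ellipsoid_mask(co, hc[1], hc[2], hc[3], r_out, r_out, r_out)
  inner <- ellipsoid_mask(co, hc[1], hc[2], hc[3], r_in, r_in, r_in)
  blood <- inner & body
  myo <- outer & !inner & body
  assign_organ(blood, spec$blood_uptake, spec$mu_soft, "blood")
  assign_organ(myo, spec$myo_to_rib_ratio * spec$rib_uptake, spec$mu_soft, "myo")

  truth <- list(
    subject_id = subject_id,
    perugini_class_truth = spec$perugini_class_truth,
    myo_to_rib_ratio = spec$myo_to_rib_ratio,
    heart_center_mm = hc * extent_mm,
    total_activity = sum(act)
  )
  structure(list(
    activity = act, mu = mu, grid = grid, truth = truth,
    ## masks reflect the final precedence-resolved labels, so a voxel in
    ## masks$bone is guaranteed to carry bone activity and attenuation
    masks = list(myocardium = label == "myo", blood = label == "blood",
                 ribs = label == "rib", bone = label == "bone" | label == "rib",
                 lungs = label == "lung", body = body)
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom '%s': class %d, myo/rib ratio %.3g, total activity %.4g\n",
              x$truth$subject_id, x$truth$perugini_class_truth,
              x$truth$myo_to_rib_ratio, x$truth$total_activity))
  print(x$grid)
  invisible(x)
}

#' Cohort specification
#'
#' Describes a synthetic study population: the number of subjects, how
#' many fall in each visual-score class, the expected total planar count
#' level, and a master seed from which every per-subject seed is derived.
#' Defaults emulate the verification study's population of 30 subjects
#' with all four classes represented.
#'
#' @param n_subjects cohort size (default 30).
#' @param class_mix named integer vector of per-class counts, names
#'   "0".."3"; must sum to `n_subjects`.
#' @param count_level expected total counts in a conventional planar
#'   acquisition (default 2e6; clinical 8-min scans collect more, the
#'   default keeps the noise level realistic at desk scale).
#' @param seed master seed.
#' @param grid a [grid_geometry()] shared by all subjects.
#' @param rib_suppression multiplicative rib-uptake factor applied to
#'   class-3 subjects (default 0.4), reflecting the faint rib uptake that
#'   defines the top visual grade.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 30L,
                        class_mix = c("0" = 8L, "1" = 7L, "2" = 7L, "3" = 8L),
                        count_level = 2e6,
                        seed = 1L,
                        grid = grid_geometry(),
                        rib_suppression = 0.4) {
  n_subjects <- as.integer(n_subjects)
  if (is.null(names(class_mix)) ||
      !setequal(names(class_mix), c("0", "1", "2", "3")))
    stop("class_mix must be named with classes \"0\"..\"3\"", call. = FALSE)
  class_mix <- class_mix[c("0", "1", "2", "3")]
  if (sum(class_mix) != n_subjects)
    stop(sprintf("class_mix sums to %d but n_subjects is %d",
                 sum(class_mix), n_subjects), call. = FALSE)
  stop_if_not_scalar_pos(count_level, "count_level")
  structure(list(
    n_subjects = n_subjects, class_mix = class_mix,
    count_level = count_level, seed = as.integer(seed), grid = grid,
    rib_suppression = rib_suppression
  ), class = "cohort_spec")
}

## per-class sampling ranges for the myocardial-to-rib ratio, consistent
## with class_from_ratio() thresholds and kept off the class boundaries
ratio_ranges <- list(
  "0" = c(0, 0),
  "1" = c(0.30, 0.70),
  "2" = c(0.85, 1.25),
  "3" = c(1.40, 2.20)
)

#' Generate a seeded phantom cohort
#'
#' Draws one phantom per subject: the class label follows the requested
#' mix, the myocardial-to-rib ratio is sampled uniformly within the
#' class's ratio range, anatomical jitter is applied per subject, and
#' class-3 subjects get their rib uptake scaled by the cohort's
#' rib-suppression factor. All randomness derives deterministically from
#' the master seed, so the same `cohort_spec` always reproduces the same
#' cohort bit for bit.
#'
#' @param cohort a [cohort_spec()].
#' @return list of `phantom` objects, one per subject.
#' @export
make_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  classes <- rep(c(0L, 1L, 2L, 3L), times = cohort$class_mix)
  phantoms <- vector("list", cohort$n_subjects)
  for (i in seq_len(cohort$n_subjects)) {
    cl <- classes[i]
    rng <- ratio_ranges[[as.character(cl)]]
    ratio <- with_seed(derive_seed(cohort$seed, "ratio", i),
                      runif(1, rng[1], rng[2]))
    rib <- if (cl == 3L) 4 * cohort$rib_suppression else 4
    spec <- phantom_spec(grid = cohort$grid, rib_uptake = rib,
                         myo_to_rib_ratio = ratio, jitter = TRUE)
    phantoms[[i]] <- make_phantom(spec,
                                  seed = derive_seed(cohort$seed, "phantom", i),
                                  subject_id = sprintf("s%02d", i))
  }
  phantoms
}

#' Cohort truth table
#'
#' @param phantoms list of `phantom` objects from [make_cohort()].
#' @return data.frame with one row per subject: subject_id, class, ratio,
#'   heart center coordinates (mm) and total activity.
#' @export
cohort_truth <- function(phantoms) {
  do.call(rbind, lapply(phantoms, function(p) {
    data.frame(subject_id = p$truth$subject_id,
               perugini_class_truth = p$truth$perugini_class_truth,
               myo_to_rib_ratio = p$truth$myo_to_rib_ratio,
               heart_z_mm = p$truth$heart_center_mm[1],
               heart_y_mm = p$truth$heart_center_mm[2],
               heart_x_mm = p$truth$heart_center_mm[3],
               total_activity = p$truth$total_activity)
  }))
}
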