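#' Study configuration
#'
#' Bundles everything the end-to-end verification needs: the cohort
#' specification, the detector and acquisition settings for both imaging
#' pathways, the reconstruction schedule, ROI options, and the simulated
#' reader model. All per-stage random streams are derived from the
#' cohort's master seed.
#'
#' The conventional-pathway detector sensitivity is calibrated per
#' subject so the expected total planar counts equal the cohort's
#' `count_level`; the SPECT pathway distributes the same expected total
#' over its acquisition angles (equal scan time on both systems), scaled
#' by `spect_count_factor`.
#'
#' @param cohort a [cohort_spec()].
#' @param angles SPECT detector angles (default 60 even views).
#' @param n_iterations,n_subsets reconstruction schedule (default 20 x 6,
#'   BSREM-RDP with the frozen study settings beta 0.4, gamma 4).
#' @param psf logical; enable the depth-dependent PSF in both forward
#'   models and the reconstruction system model (default FALSE).
#' @param spect_count_factor SPECT-to-planar total-count ratio (default
#'   1).
#' @param noiseless logical; TRUE disables Poisson noise everywhere.
#' @param reader_p simulated-reader misclassification probability.
#' @param n_readers number of simulated readers.
#' @param roi_diameter_mm heart/contralateral ROI diameter (default 70).
#' @param hcl_cutoff positivity cutoff on the H/CL ratio (default 1.5).
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(),
                         angles = seq(0, 354, by = 6),
                         n_iterations = 20L, n_subsets = 6L,
                         psf = FALSE, spect_count_factor = 1,
                         noiseless = FALSE,
                         reader_p = 0.05, n_readers = 3L,
                         roi_diameter_mm = 70, hcl_cutoff = 1.5) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (length(angles) %% as.integer(n_subsets) != 0)
    stop("n_subsets must divide the number of angles", call. = FALSE)
  structure(list(cohort = cohort, angles = angles,
                 n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 psf = isTRUE(psf), spect_count_factor = spect_count_factor,
                 noiseless = isTRUE(noiseless),
                 reader_p = reader_p, n_readers = as.integer(n_readers),
                 roi_diameter_mm = roi_diameter_mm, hcl_cutoff = hcl_cutoff),
            class = "study_config")
}

#' Run the full synthetic verification study
#'
#' For every subject of the cohort: build the phantom; simulate the
#' conventional anterior planar acquisition; simulate the SPECT
#' acquisition, reconstruct it with the study-default BSREM-RDP settings
#' and reproject it to a virtual anterior planar image; measure the H/CL
#' ratio on both images with automatically placed 70-mm ROIs; and record
#' the noiseless-truth H/CL for reference. The pooled pairs are then
#' compared with linear regression, Bland-Altman analysis, and
#' classification concordance at the positivity cutoff, and simulated
#' readers provide score tables for Cohen/Fleiss kappa and per-reader
#' concordance summaries.
#'
#' The run is a pure function of the configuration: the same
#' `study_config` always reproduces the identical report.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional directory; when given, per-subject volumes and
#'   planar images are written as NIfTI, the per-subject table as CSV,
#'   and the report as JSON.
#' @param progress print one line per subject.
#' @return An object of class `hcl_study`.
#' @export
run_study <- function(cfg = study_config(), out_dir = NULL,
                      progress = interactive()) {
  stopifnot(inherits(cfg, "study_config"))
  cohort <- cfg$cohort
  phantoms <- make_cohort(cohort)
  truth <- cohort_truth(phantoms)
  n <- cohort$n_subjects

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- phantoms[[i]]
    grid <- ph$grid
    sid <- ph$truth$subject_id

    ## per-subject sensitivity calibration to the cohort count level
    base <- simulate_planar(ph$activity, ph$mu, grid,
                            detector_model(sensitivity = 1, psf = cfg$psf),
                            noiseless = TRUE)
    sens <- cohort$count_level / sum(base$matrix)
    conv_det <- detector_model(sensitivity = sens, psf = cfg$psf)
    spect_det <- detector_model(
      sensitivity = sens * cfg$spect_count_factor / length(cfg$angles),
      psf = cfg$psf)

    conv <- simulate_planar(ph$activity, ph$mu, grid, conv_det,
                            seed = derive_seed(cohort$seed, "planar", i),
                            noiseless = cfg$noiseless)
    proj <- simulate_spect(ph$activity, ph$mu, grid, spect_det,
                           angles = cfg$angles,
                           seed = derive_seed(cohort$seed, "spect", i),
                           noiseless = cfg$noiseless)
    rec <- reconstruct_for_study(proj, ph$mu, grid, spect_det,
                                 n_iterations = cfg$n_iterations,
                                 n_subsets = cfg$n_subsets)
    repro <- reproject_planar(rec$volume, ph$mu, grid, scale = sens)

    h_conv <- measure_hcl(conv, diameter_mm = cfg$roi_diameter_mm)
    h_repro <- measure_hcl(repro, diameter_mm = cfg$roi_diameter_mm)
    ## noiseless-truth H/CL: ideal planar of the true activity
    truth_img <- new_planar_image(base$matrix * sens, grid$voxel_size_mm,
                                  "conventional")
    h_truth <- measure_hcl(truth_img, diameter_mm = cfg$roi_diameter_mm)

    rows[[i]] <- data.frame(
      subject_id = sid,
      perugini_class_truth = ph$truth$perugini_class_truth,
      myo_to_rib_ratio = ph$truth$myo_to_rib_ratio,
      hcl_truth = h_truth$ratio,
      hcl_conventional = h_conv$ratio,
      hcl_reprojected = h_repro$ratio,
      positive_conventional = h_conv$ratio >= cfg$hcl_cutoff,
      positive_reprojected = h_repro$ratio >= cfg$hcl_cutoff
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_volume_nifti(rec$volume, grid,
                         file.path(out_dir, paste0(sid, "_recon.nii.gz")))
      write_planar_nifti(conv, file.path(out_dir, paste0(sid, "_conv.nii.gz")))
      write_planar_nifti(repro, file.path(out_dir, paste0(sid, "_repro.nii.gz")))
    }
    if (progress)
      message(sprintf("[%d/%d] %s: H/CL conv %.2f, repro %.2f",
                      i, n, sid, h_conv$ratio, h_repro$ratio))
  }
  subjects <- do.call(rbind, rows)

  reg <- pearson_regression(subjects$hcl_conventional,
                            subjects$hcl_reprojected)
  ba <- bland_altman(subjects$hcl_conventional, subjects$hcl_reprojected)
  concord_all <- 100 * mean(subjects$positive_conventional ==
                              subjects$positive_reprojected)
  sep <- abs(subjects$hcl_truth - cfg$hcl_cutoff) >= 0.2
  concord_sep <- if (any(sep))
    100 * mean(subjects$positive_conventional[sep] ==
                 subjects$positive_reprojected[sep]) else NA_real_

  scores <- simulate_readers(truth, n_readers = cfg$n_readers,
                             p = cfg$reader_p,
                             seed = derive_seed(cohort$seed, "readers"))
  per_reader <- concordance_summary(scores)
  cohen <- lapply(sort(unique(scores$reader)), function(r) {
    s <- scores[scores$reader == r, ]
    a <- s$score[s$modality == "conventional"][order(s$subject_id[s$modality == "conventional"])]
    b <- s$score[s$modality == "reprojected"][order(s$subject_id[s$modality == "reprojected"])]
    cohens_kappa(a, b, levels = 0:3,
                 seed = derive_seed(cohort$seed, "boot_cohen"))
  })
  names(cohen) <- sort(unique(scores$reader))
  fleiss <- lapply(c("conventional", "reprojected"), function(mod)
    fleiss_kappa(score_matrix(scores, mod), levels = 0:3,
                 seed = derive_seed(cohort$seed, "boot_fleiss")))
  names(fleiss) <- c("conventional", "reprojected")

  report <- structure(list(
    subjects = subjects,
    regression = reg,
    bland_altman = ba,
    classification_concordance_pct = concord_all,
    classification_concordance_separated_pct = concord_sep,
    n_separated = sum(sep),
    scores = scores,
    per_reader = per_reader,
    cohen = cohen,
    fleiss = fleiss,
    config = cfg
  ), class = "hcl_study")

  if (!is.null(out_dir)) {
    write.csv(subjects, file.path(out_dir, "subjects.csv"),
              row.names = FALSE)
    write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    jsonlite::write_json(study_report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

## plain-list view of the report for JSON serialisation
study_report_json <- function(x) {
  list(
    n_subjects = nrow(x$subjects),
    regression = unclass(x$regression),
    bland_altman = x$bland_altman[c("bias", "sd_diff", "loa_lower",
                                    "loa_upper", "n")],
    classification_concordance_pct = x$classification_concordance_pct,
    classification_concordance_separated_pct =
      x$classification_concordance_separated_pct,
    n_separated = x$n_separated,
    cohen = lapply(x$cohen, unclass),
    fleiss = lapply(x$fleiss, unclass),
    per_reader = x$per_reader,
    seed = x$config$cohort$seed
  )
}

#' @export
print.hcl_study <- function(x, ...) {
  cat(sprintf("Synthetic verification study: %d subjects\n",
              nrow(x$subjects)))
  cat(sprintf("  H/CL Pearson r = %.3f (P = %.2g), slope %.3f\n",
              x$regression$r, x$regression$p_value, x$regression$slope))
  cat(sprintf("  Bland-Altman bias %.3f, LoA [%.3f, %.3f]\n",
              x$bland_altman$bias, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper))
  cat(sprintf("  Classification concordance at %.1f: %.0f%% (all), %.0f%% (separated, n=%d)\n",
              x$config$hcl_cutoff, x$classification_concordance_pct,
              x$classification_concordance_separated_pct, x$n_separated))
  invisible(x)
}

#' @export
summary.hcl_study <- function(object, ...) {
  print(object)
  cat("\nSimulated-reader agreement (conventional vs reprojected):\n")
  for (r in names(object$cohen)) {
    k <- object$cohen[[r]]
    cat(sprintf("  %s: kappa %.2f (95%% CI %.2f-%.2f), agreement %g%%\n",
                r, k$kappa, k$ci_lower, k$ci_upper, k$percent_agreement))
  }
  cat("Inter-reader (Fleiss):\n")
  for (mod in names(object$fleiss)) {
    k <- object$fleiss[[mod]]
    cat(sprintf("  %s: kappa %.2f (95%% CI %.2f-%.2f)\n",
                mod, k$kappa, k$ci_lower, k$ci_upper))
  }
  invisible(object)
}

#' Diagnostic plots for a study report
#'
#' `which = 1` draws the correlation scatter of reprojected vs
#' conventional H/CL ratios with the identity and regression lines;
#' `which = 2` draws the Bland-Altman plot with bias and limits of
#' agreement. Points are filled for subjects with true class 2-3 and open
#' for class 0-1.
#'
#' @param x an `hcl_study`.
#' @param which 1, 2, or both.
#' @param ... passed to [plot()].
#' @export
plot.hcl_study <- function(x, which = c(1, 2), ...) {
  s <- x$subjects
  high <- s$perugini_class_truth >= 2
  pch <- ifelse(high, 19, 1)
  if (1 %in% which) {
    plot(s$hcl_conventional, s$hcl_reprojected, pch = pch,
         xlab = "H/CL, conventional planar",
         ylab = "H/CL, reprojected planar",
         main = "H/CL correlation", ...)
    abline(0, 1, lty = 2)
    abline(x$regression$intercept, x$regression$slope)
    legend("topleft", pch = c(1, 19), bty = "n",
           legend = c("class 0-1", "class 2-3"))
  }
  if (2 %in% which) {
    ba <- x$bland_altman
    plot(ba$averages, ba$differences, pch = pch,
         xlab = "mean of paired H/CL ratios",
         ylab = "difference (reprojected - conventional)",
         main = "Bland-Altman", ...)
    abline(h = ba$bias)
    abline(h = c(ba$loa_lower, ba$loa_upper), lty = 2)
  }
  invisible(x)
}

#' @importFrom graphics plot abline legend
NULL
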