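#' Percent agreement between two raters
#'
#' Share of subjects with identical categorical scores, as a percentage.
#'
#' @param a,b equal-length categorical score vectors.
#' @param digits rounding for the reported percentage (default 0, i.e.
#'   nearest integer, the convention used for reported agreement levels).
#' @return percentage in `[0, 100]`.
#' @export
percent_agreement <- function(a, b, digits = 0) {
  if (length(a) != length(b)) stop("score vectors differ in length")
  if (length(a) < 1) stop("need at least one pair")
  round(100 * mean(a == b), digits)
}

new_kappa_result <- function(kappa, ci, pa, n, flavor) {
  structure(list(kappa = kappa, ci_lower = ci[1], ci_upper = ci[2],
                 percent_agreement = pa, n = n, flavor = flavor),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("%s's kappa = %.3f (95%% CI %.3f-%.3f), agreement %g%%, n = %d\n",
              if (x$flavor == "cohen") "Cohen" else "Fleiss",
              x$kappa, x$ci_lower, x$ci_upper, x$percent_agreement, x$n))
  invisible(x)
}

cohen_point <- function(a, b, levels) {
  ta <- factor(a, levels = levels)
  tb <- factor(b, levels = levels)
  tab <- table(ta, tb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 8) {
    warning("degenerate marginals (p_e = 1); kappa defined as 1")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` computed from the product of the two raters'
#' marginal distributions. The 95% confidence interval is a seeded
#' percentile bootstrap over subjects.
#'
#' @param a,b categorical score vectors of equal length (n >= 2).
#' @param levels category alphabet; defaults to the union of observed
#'   values.
#' @param n_boot bootstrap replicates (default 2000); 0 skips the CI.
#' @param seed bootstrap seed.
#' @return A `kappa_result`.
#' @export
cohens_kappa <- function(a, b, levels = sort(unique(c(a, b))),
                         n_boot = 2000L, seed = 1L) {
  if (length(a) != length(b)) stop("score vectors differ in length")
  n <- length(a)
  if (n < 2) stop("need at least 2 subjects")
  k <- cohen_point(a, b, levels)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ks <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cohen_point(a[idx], b[idx], levels))
    }, numeric(1)))
    ci <- unname(quantile(ks, c(0.025, 0.975), na.rm = TRUE))
  }
  new_kappa_result(k, ci, percent_agreement(a, b), n, "cohen")
}

fleiss_point <- function(tab, levels) {
  ## tab: subjects x raters matrix of categorical scores
  n <- nrow(tab); m <- ncol(tab)
  counts <- t(apply(tab, 1, function(r)
    tabulate(factor(r, levels = levels), nbins = length(levels))))
  if (length(levels) == 1L) counts <- matrix(m, n, 1)
  p_j <- colSums(counts) / (n * m)
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (abs(1 - P_e) < .Machine$double.eps * 8) {
    warning("degenerate category distribution (P_e = 1); kappa defined as 1")
    return(1)
  }
  (P_bar - P_e) / (1 - P_e)
}

#' Fleiss's kappa for multiple raters
#'
#' Standard multi-rater chance-corrected agreement from per-subject
#' pairwise agreement `P_i` and overall category proportions `p_j`, with
#' a seeded percentile-bootstrap 95% CI over subjects. The reported
#' percent agreement is the mean pairwise percent agreement across rater
#' pairs.
#'
#' @param tab subjects x raters matrix of categorical scores (>= 2
#'   raters, no missing cells).
#' @param levels category alphabet; defaults to observed values.
#' @param n_boot,seed bootstrap settings as in [cohens_kappa()].
#' @return A `kappa_result`.
#' @export
fleiss_kappa <- function(tab, levels = sort(unique(as.vector(tab))),
                         n_boot = 2000L, seed = 1L) {
  tab <- as.matrix(tab)
  if (ncol(tab) < 2) stop("need at least 2 raters")
  n <- nrow(tab)
  k <- fleiss_point(tab, levels)
  ci <- c(NA_real_, NA_real_)
  if (n == 1) {
    warning("single subject: CI undefined")
  } else if (n_boot > 0) {
    ks <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(fleiss_point(tab[idx, , drop = FALSE], levels))
    }, numeric(1)))
    ci <- unname(quantile(ks, c(0.025, 0.975), na.rm = TRUE))
  }
  pairs <- utils::combn(ncol(tab), 2)
  pa <- mean(apply(pairs, 2, function(p)
    100 * mean(tab[, p[1]] == tab[, p[2]])))
  new_kappa_result(k, ci, round(pa), n, "fleiss")
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `y - x` (second pathway minus first,
#' matching the convention that the reprojected pathway is reported
#' relative to the conventional one). Bias is the mean difference and the
#' limits of agreement are `bias +/- 1.96 * SD` with the sample (n-1)
#' standard deviation.
#'
#' @param x,y paired measurements (n >= 2); `x` conventional, `y`
#'   reprojected.
#' @return An object of class `bland_altman_result`: bias, sd_diff,
#'   loa_lower, loa_upper, and per-pair `averages` and `differences`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors differ in length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 averages = (x + y) / 2, differences = d, n = length(x)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, LoA [%.4f, %.4f], n = %d\n",
              x$bias, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' Pearson correlation and least-squares regression
#'
#' Fits `y ~ x` by ordinary least squares and reports the Pearson
#' correlation with its two-sided p-value from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 3, `x` with nonzero variance.
#' @return An object of class `regression_result`: r, p_value, slope,
#'   intercept, n.
#' @export
pearson_regression <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors differ in length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0) stop("x has zero variance")
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (P = %.3g), y = %.3f x + %.3f, n = %d\n",
              x$r, x$p_value, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Per-reader concordance summary across modalities
#'
#' Partitions each reader's subjects into concordant (identical scores on
#' the two modalities), minor discordance (shift of exactly one unit) and
#' major discordance (shift of more than one unit).
#'
#' @param scores data.frame with columns `subject_id`, `reader`,
#'   `modality`, `score`; every reader must score every subject on
#'   exactly two modalities.
#' @return data.frame with one row per reader: concordant, minor, major,
#'   n, percent_agreement.
#' @export
concordance_summary <- function(scores) {
  req <- c("subject_id", "reader", "modality", "score")
  if (!all(req %in% names(scores)))
    stop("scores must have columns subject_id, reader, modality, score")
  mods <- unique(scores$modality)
  if (length(mods) != 2) stop("exactly two modalities required")
  readers <- sort(unique(scores$reader))
  out <- lapply(readers, function(r) {
    s <- scores[scores$reader == r, ]
    s1 <- s[s$modality == mods[1], ]
    s2 <- s[s$modality == mods[2], ]
    s1 <- s1[order(s1$subject_id), ]
    s2 <- s2[order(s2$subject_id), ]
    if (!identical(s1$subject_id, s2$subject_id))
      stop(sprintf("reader %s: subjects differ between modalities", r))
    shift <- abs(s1$score - s2$score)
    data.frame(reader = r,
               concordant = sum(shift == 0),
               minor = sum(shift == 1),
               major = sum(shift > 1),
               n = length(shift),
               percent_agreement = percent_agreement(s1$score, s2$score))
  })
  do.call(rbind, out)
}
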