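#' Simulate blinded visual scoring by multiple readers
#'
#' Stands in for human visual grading: each reader scores each subject on
#' each modality as the subject's true class, perturbed independently
#' with probability `p` by a one-unit shift (direction uniform, result
#' clipped to the 0-3 scale). All draws derive from one seed, so a score
#' table is reproducible.
#'
#' @param truth data.frame with columns `subject_id` and
#'   `perugini_class_truth` (e.g. from [cohort_truth()]).
#' @param n_readers number of readers (default 3).
#' @param p per-cell misclassification probability in `[0, 0.5]`.
#' @param modalities modality labels (default conventional/reprojected).
#' @param seed seed.
#' @return data.frame in long format: subject_id, reader, modality,
#'   score.
#' @export
simulate_readers <- function(truth, n_readers = 3L, p = 0.05,
                             modalities = c("conventional", "reprojected"),
                             seed = 1L) {
  if (p < 0 || p > 0.5) stop("p must be in [0, 0.5]", call. = FALSE)
  n <- nrow(truth)
  grid <- expand.grid(subject = seq_len(n),
                      reader = seq_len(n_readers),
                      modality = modalities,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ncell <- nrow(grid)
  draws <- with_seed(seed, {
    err <- rbinom(ncell, 1, p)
    sgn <- sample(c(-1L, 1L), ncell, replace = TRUE)
    err * sgn
  })
  score <- truth$perugini_class_truth[grid$subject] + draws
  score <- pmin(pmax(score, 0L), 3L)
  data.frame(subject_id = truth$subject_id[grid$subject],
             reader = paste0("reader", grid$reader),
             modality = grid$modality,
             score = as.integer(score))
}

#' Reshape a long score table into a subjects x raters matrix
#'
#' @param scores long-format data.frame (subject_id, reader, modality,
#'   score).
#' @param modality which modality to extract.
#' @return integer matrix, rows = subjects (sorted by id), columns =
#'   readers.
#' @export
score_matrix <- function(scores, modality) {
  s <- scores[scores$modality == modality, ]
  readers <- sort(unique(s$reader))
  ids <- sort(unique(s$subject_id))
  m <- sapply(readers, function(r) {
    sr <- s[s$reader == r, ]
    sr$score[match(ids, sr$subject_id)]
  })
  rownames(m) <- ids
  m
}
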