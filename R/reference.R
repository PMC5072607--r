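#' Count abnormal quantitative sensory testing parameters
#'
#' Counts, per patient, how many of the 13 sensory-testing z-scores fall
#' outside the two-sided normative band `|z| > z_threshold`.
#'
#' @param qst_z numeric vector of length 13, or an n x 13 matrix / data frame
#'   (one row per patient).
#' @param z_threshold positive normative threshold (default 1.96, the
#'   two-sided 95% band).
#' @return integer count (vector of counts for matrix input).
#' @export
qst_abnormal_count <- function(qst_z, z_threshold = 1.96) {
  if (z_threshold <= 0) stop("'z_threshold' must be > 0")
  if (is.data.frame(qst_z)) qst_z <- as.matrix(qst_z)
  if (is.matrix(qst_z)) {
    if (ncol(qst_z) != 13) stop("'qst_z' must have exactly 13 parameters")
    return(as.integer(rowSums(abs(qst_z) > z_threshold)))
  }
  if (length(qst_z) != 13) stop("'qst_z' must have exactly 13 parameters")
  as.integer(sum(abs(qst_z) > z_threshold))
}

#' Composite 2-of-3 neuropathy case definition
#'
#' Applies the deep-phenotype case definition: a patient is a case when at
#' least `2` of the following three components are abnormal: clinical signs
#' of distal sensory neuropathy, `qst_min` or more abnormal sensory-testing
#' parameters, and an intraepidermal nerve fibre density at or below
#' `ienfd_cut` fibres/mm (boundary inclusive).
#'
#' @param signs logical, clinical-sign flag.
#' @param qst_count integer, abnormal sensory parameters
#'   (see [qst_abnormal_count()]).
#' @param ienfd fibre density, fibres/mm (>= 0).
#' @param ienfd_cut inclusive density cutoff (default 7.63).
#' @param qst_min minimum abnormal parameters (default 2).
#' @return data frame with `signs`, `qst_abnormal`, `ienfd_low`,
#'   `criteria_met` (0-3) and `is_case` (criteria_met >= 2). All arguments
#'   are vectorised.
#' @export
hiv_pins_case <- function(signs, qst_count, ienfd,
                          ienfd_cut = 7.63, qst_min = 2L) {
  if (any(ienfd < 0)) stop("'ienfd' must be non-negative")
  comp <- cbind(signs = as.logical(signs),
                qst_abnormal = qst_count >= qst_min,
                ienfd_low = ienfd <= ienfd_cut)
  met <- as.integer(rowSums(comp))
  data.frame(signs = comp[, 1], qst_abnormal = comp[, 2],
             ienfd_low = comp[, 3], criteria_met = met, is_case = met >= 2L)
}

#' Symmetric examination-score reference standard
#'
#' Classifies by the examination total (right + left) at `total_cutoff`,
#' requiring the score to be distributed over both feet: patients whose
#' total reaches the cutoff but whose smaller side carries less than
#' `asymmetry_fraction` of it are flagged `asymmetric_excluded` (their
#' verdict is `NA`, not negative) — high unilateral scores suggest a focal
#' lesion rather than a symmetric polyneuropathy.
#'
#' @param right,left non-negative per-side scores (right + left <= 42).
#' @param total_cutoff positivity cutoff on the total (default 8).
#' @param asymmetry_fraction minimum share of the total carried by the
#'   smaller side (default 0.25).
#' @return data frame with `total`, `asymmetric_excluded`, and `positive`
#'   (logical, `NA` where excluded).
#' @export
uens_classify <- function(right, left, total_cutoff = 8L,
                          asymmetry_fraction = 0.25) {
  if (any(right < 0) || any(left < 0)) stop("scores must be non-negative")
  total <- right + left
  if (any(total > 42)) stop("right + left must not exceed 42")
  min_share <- ifelse(total > 0, pmin(right, left) / total, 0.5)
  excluded <- total >= total_cutoff & min_share < asymmetry_fraction
  positive <- ifelse(excluded, NA, total >= total_cutoff)
  data.frame(total = as.integer(total), asymmetric_excluded = excluded,
             positive = as.logical(positive))
}

#' Reference-standard labels for a cohort
#'
#' Convenience wrapper that applies either the composite 2-of-3 case
#' definition (`"hiv_pins"`) or the symmetric examination-score proxy
#' (`"uens"`) to a cohort's columns.
#'
#' @param cohort a `chant_cohort` data frame.
#' @param standard which reference standard to apply.
#' @param ... passed on to [hiv_pins_case()] or [uens_classify()].
#' @return logical vector of case labels (`NA` for asymmetric exclusions
#'   under the examination proxy).
#' @export
reference_labels <- function(cohort, standard = c("hiv_pins", "uens"), ...) {
  standard <- match.arg(standard)
  if (standard == "hiv_pins") {
    qc <- qst_abnormal_count(cohort[, paste0("qst_z_", 1:13)])
    hiv_pins_case(cohort$clinical_signs, qc, cohort$ienfd, ...)$is_case
  } else {
    uens_classify(cohort$uens_right, cohort$uens_left, ...)$positive
  }
}
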