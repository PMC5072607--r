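#' Write a cohort to CSV
#'
#' One row per patient. Numeric columns are written with 17 significant
#' digits so that [read_cohort()] recovers every double bit-exactly.
#'
#' Column dictionary: `id` (identifier); `latent_status` (TRUE = neuropathy);
#' `pain_right/left`, `numb_right/left` (0-10 numeric rating);
#' `vib_right/left` (timed great-toe vibration, seconds, lower = abnormal);
#' `reflex_right/left` (0 normal, 1 hypoactive, 2 absent);
#' `clinical_signs` (examination flag); `qst_z_1..13` (sensory-testing
#' z-scores); `ienfd` (fibres/mm); `uens_right/left` (examination score per
#' side, total <= 42); `bfp` (bilateral feet pain on body map);
#' `dn4_1..7` (pain-interview items).
#'
#' @param cohort a `chant_cohort` (or compatible) data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path file path.
#' @return a `chant_cohort` data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  logical_cols <- c("latent_status", "clinical_signs", "bfp", paste0("dn4_", 1:7))
  for (cn in intersect(logical_cols, names(df))) df[[cn]] <- as.logical(df[[cn]])
  int_cols <- c("reflex_right", "reflex_left", "uens_right", "uens_left")
  for (cn in intersect(int_cols, names(df))) df[[cn]] <- as.integer(df[[cn]])
  class(df) <- c("chant_cohort", "data.frame")
  df
}

#' Write / read a cohort configuration as YAML
#'
#' Round-trips all fields of a [cohort_config()] (17-digit numeric precision,
#' so reading back reproduces the configuration exactly).
#'
#' @param config a `cohort_config` object.
#' @param path file path.
#' @return `path` invisibly for the writer; a `cohort_config` for the reader.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$item_cutoffs <- unclass(x$item_cutoffs)
  # yaml serialises named atomic vectors as plain sequences; keep the names
  x$item_noise <- as.list(x$item_noise)
  x$item_scale <- as.list(x$item_scale)
  x$target_item_accuracy <- lapply(x$target_item_accuracy, as.list)
  x$pain_params$dn4_prob <- list(control = unname(x$pain_params$dn4_prob[1, ]),
                                 case = unname(x$pain_params$dn4_prob[2, ]))
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  dn4 <- rbind(control = x$pain_params$dn4_prob$control,
               case = x$pain_params$dn4_prob$case)
  cohort_config(
    n_patients = x$n_patients, prevalence = x$prevalence,
    severity_shift = x$severity_shift,
    item_noise = unlist(x$item_noise), side_noise = x$side_noise,
    item_cutoffs = measurand_thresholds(
      pain_cut = x$item_cutoffs$pain_cut, numb_cut = x$item_cutoffs$numb_cut,
      vib_cut = x$item_cutoffs$vib_cut,
      reflex_abnormal_grades = as.integer(x$item_cutoffs$reflex_abnormal_grades)),
    target_item_accuracy = lapply(x$target_item_accuracy, unlist),
    item_scale = unlist(x$item_scale), reflex_step = x$reflex_step,
    signs_prob = unlist(x$signs_prob),
    qst_params = list(n_params = as.integer(x$qst_params$n_params),
                      p_abnormal = unlist(x$qst_params$p_abnormal),
                      z_threshold = x$qst_params$z_threshold),
    ienfd_params = list(meanlog = unlist(x$ienfd_params$meanlog),
                        sdlog = unlist(x$ienfd_params$sdlog)),
    uens_params = lapply(x$uens_params, identity),
    pain_params = list(bfp_prob = unlist(x$pain_params$bfp_prob),
                       dn4_prob = dn4),
    rater2_agreement = x$rater2_agreement,
    seed = x$seed)
}
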