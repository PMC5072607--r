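#' Score the 7-item pain interview
#'
#' Counts positive responses to the seven interview items (burning, painful
#' cold, electric shocks, tingling, pins-and-needles, numbness, itching).
#' A score of 3 or more of 7 indicates neuropathic pain.
#'
#' @param items logical vector of length 7, or an n x 7 matrix / data frame.
#' @return integer score(s) 0-7.
#' @export
dn4i_score <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.matrix(items)) {
    if (ncol(items) != 7) stop("exactly 7 interview items required")
    return(as.integer(rowSums(items)))
  }
  if (length(items) != 7) stop("exactly 7 interview items required")
  as.integer(sum(items))
}

#' Interview positivity cutoff
#' @param score integer score(s) from [dn4i_score()].
#' @param cutoff inclusive positivity cutoff (default 3).
#' @return logical.
#' @export
dn4i_positive <- function(score, cutoff = 3L) score >= cutoff

bodymap_vocabulary <- function() {
  c("left_foot", "right_foot", "left_leg", "right_leg",
    "left_hand", "right_hand", "trunk", "head", "other")
}

#' Bilateral feet pain from a body map
#'
#' TRUE iff both foot regions are marked on the pain body map — the
#' neuroanatomically plausible distribution for a length-dependent distal
#' symmetrical polyneuropathy.
#'
#' @param marked_regions character vector of marked regions (one patient),
#'   or a semicolon-separated string; see the documented vocabulary
#'   (`left_foot`, `right_foot`, `left_leg`, `right_leg`, `left_hand`,
#'   `right_hand`, `trunk`, `head`, `other`).
#' @return logical.
#' @export
bfp_from_bodymap <- function(marked_regions) {
  if (length(marked_regions) == 1 && grepl(";", marked_regions))
    marked_regions <- strsplit(marked_regions, ";")[[1]]
  marked_regions <- trimws(marked_regions)
  marked_regions <- marked_regions[nzchar(marked_regions)]
  unknown <- setdiff(marked_regions, bodymap_vocabulary())
  if (length(unknown))
    stop("unknown body-map region label(s): ", paste(unknown, collapse = ", "))
  all(c("left_foot", "right_foot") %in% marked_regions)
}

triage_categories <- function() {
  c("NeP", "POPNO", "neuropathy_no_BFP", "no_neuropathy_BFP_followup",
    "no_neuropathy")
}

#' Two-stage neuropathic-pain triage
#'
#' Combines the screening verdict, the body-map bilateral-feet-pain flag and
#' the interview score into one of five mutually exclusive categories:
#' screen-positive with bilateral feet pain and interview score >= 3 is
#' neuropathic pain (`NeP`); screen-positive with bilateral feet pain but a
#' sub-threshold interview is pain of probably neuropathic origin (`POPNO`,
#' pending confirmatory follow-up); screen-positive without bilateral feet
#' pain is `neuropathy_no_BFP`; screen-negative with bilateral feet pain is
#' referred for closer follow-up (`no_neuropathy_BFP_followup`, possible
#' subclinical neuropathy); otherwise `no_neuropathy`.
#'
#' @param chant_positive logical screening verdict(s).
#' @param bfp logical bilateral-feet-pain flag(s).
#' @param dn4_score integer interview score(s) 0-7.
#' @param dn4_cutoff inclusive interview positivity cutoff (default 3).
#' @return data frame of class `triage_result`: inputs plus `category`
#'   (factor over the five categories).
#' @export
classify_triage <- function(chant_positive, bfp, dn4_score, dn4_cutoff = 3L) {
  if (any(dn4_score < 0 | dn4_score > 7)) stop("dn4_score must lie in 0..7")
  nep <- dn4i_positive(dn4_score, dn4_cutoff)
  category <- ifelse(chant_positive & bfp & nep, "NeP",
              ifelse(chant_positive & bfp, "POPNO",
              ifelse(chant_positive, "neuropathy_no_BFP",
              ifelse(bfp, "no_neuropathy_BFP_followup", "no_neuropathy"))))
  out <- data.frame(chant_positive = as.logical(chant_positive),
                    bfp = as.logical(bfp),
                    dn4_score = as.integer(dn4_score),
                    category = factor(category, levels = triage_categories()))
  class(out) <- c("triage_result", "data.frame")
  out
}

#' Triage a whole cohort
#'
#' Scores the items, applies the combination rule, and classifies every
#' patient.
#'
#' @param cohort a `chant_cohort` data frame.
#' @param thresholds a [measurand_thresholds()] object.
#' @param rule combination rule for [chant_positive()].
#' @return `triage_result` data frame with an `id` column prepended.
#' @export
triage_cohort <- function(cohort, thresholds = measurand_thresholds(),
                          rule = "verbal") {
  tallies <- score_items(cohort, thresholds)
  verdict <- chant_positive(tallies, rule)
  score <- dn4i_score(cohort[, paste0("dn4_", 1:7)])
  out <- classify_triage(verdict, cohort$bfp, score)
  cbind(data.frame(id = cohort$id, stringsAsFactors = FALSE), out)
}
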