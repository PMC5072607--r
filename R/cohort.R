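#' Configuration for a synthetic neuropathy cohort
#'
#' Builds and validates the full parameter set of the synthetic-cohort
#' generator. A single latent severity score per patient drives all four
#' screening items, which induces the inter-item correlation a multi-item
#' scale of one construct requires; per-item noise controls attenuation.
#' Each item is calibrated so that dichotomising it at its clinical cutoff
#' reproduces a target (sensitivity, specificity) against latent disease
#' status (see Details).
#'
#' @details
#' For an item with target accuracy (se, sp) define
#' \eqn{k = \Phi^{-1}(se) + \Phi^{-1}(sp)}. With latent severity
#' \eqn{S \sim N(0,1)} in controls and \eqn{N(\delta,1)} in cases, the item
#' latent is \eqn{T = wS + \sigma\epsilon_{item} + \tau\epsilon_{side}} and
#' the loading \eqn{w = \sigma_{tot} k / \delta} is solved from
#' \eqn{w\delta = \sigma_{tot} k}, which requires \eqn{\delta > k}. The
#' within-class inter-item correlation is then bounded by \eqn{k^2/\delta^2},
#' so `severity_shift` controls internal consistency while the per-item
#' accuracies stay fixed: `severity_shift = 3` emulates a well-separated
#' deep-phenotype development cohort, `severity_shift = 1.7` a clinic
#' validation cohort whose four items cohere strongly (Cronbach alpha near
#' 0.88).
#'
#' @param n_patients number of patients to generate.
#' @param prevalence probability of latent neuropathy (default 0.42, the
#'   development-cohort prevalence 28/66).
#' @param severity_shift mean latent severity difference between cases and
#'   controls, in standard-deviation units.
#' @param item_noise named positive numerics `pain`, `numb`, `vib`, `reflex`:
#'   item-specific noise SD shared by both sides.
#' @param side_noise positive SD of the side-specific noise added on top of
#'   the shared item signal (small values give strong right/left agreement).
#' @param item_cutoffs a [measurand_thresholds()] object; the generator places
#'   each item's decision threshold exactly at these cutoffs.
#' @param target_item_accuracy named list of `c(sens, spec)` pairs per item.
#'   Defaults are the reported per-item accuracies: pain (0.74, 0.81),
#'   numbness (0.778, 0.632), vibration (0.74, 0.81), reflex (0.857, 0.684).
#' @param item_scale named positive numerics: observed units per latent SD for
#'   the three continuous items (pain, numb on 0-10; vib in seconds).
#' @param reflex_step gap, in latent SD units, between the hypoactive and
#'   absent reflex thresholds.
#' @param signs_prob length-2 probabilities of clinical signs in
#'   (control, case).
#' @param qst_params list: `n_params` (13), `p_abnormal` length-2 per-class
#'   probability that a single parameter is abnormal, `z_threshold`.
#' @param ienfd_params list of `meanlog`, `sdlog`, each length-2
#'   (control, case), for lognormal fibre densities.
#' @param uens_params list: `slope`, `intercept`, `noise_sd` mapping latent
#'   severity to the examination total (0-42), split binomially across sides.
#' @param pain_params list: `bfp_prob` length-2 per-class probability of
#'   bilateral feet pain on the body map; `dn4_prob` 2 x 7 matrix of per-class
#'   pain-interview item probabilities (rows control, case).
#' @param rater2_agreement list: `flip_prob` (in \[0, 0.5\]) for binary items
#'   and `noise_sd` for continuous items, used by [generate_rater_pair()].
#' @param seed integer seed; generation is fully reproducible from it.
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 100,
                          prevalence = 0.42,
                          severity_shift = 3,
                          item_noise = c(pain = 1, numb = 1, vib = 1, reflex = 1),
                          side_noise = 0.2,
                          item_cutoffs = measurand_thresholds(),
                          target_item_accuracy = list(
                            pain   = c(sens = 0.740, spec = 0.810),
                            numb   = c(sens = 0.778, spec = 0.632),
                            vib    = c(sens = 0.740, spec = 0.810),
                            reflex = c(sens = 0.857, spec = 0.684)),
                          item_scale = c(pain = 2, numb = 1.5, vib = 3),
                          reflex_step = 0.6,
                          signs_prob = c(0.10, 0.80),
                          qst_params = list(n_params = 13L,
                                            p_abnormal = c(0.05, 0.35),
                                            z_threshold = 1.96),
                          ienfd_params = list(meanlog = c(log(11), log(5.5)),
                                              sdlog = c(0.35, 0.45)),
                          uens_params = list(slope = 2.5, intercept = 2,
                                             noise_sd = 2),
                          pain_params = list(
                            bfp_prob = c(0.10, 0.70),
                            dn4_prob = rbind(
                              control = rep(0.05, 7),
                              case = c(0.44, 0.11, 0.56, 0.33, 0.44, 0.56, 0.22))),
                          rater2_agreement = list(flip_prob = 0.02,
                                                  noise_sd = 0.15),
                          seed = 1L) {
  stopifnot(length(n_patients) == 1, n_patients >= 0,
            n_patients == as.integer(n_patients))
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1)
    stop("'prevalence' must be a probability in [0, 1]")
  items <- c("pain", "numb", "vib", "reflex")
  if (!all(items %in% names(item_noise)) || any(item_noise[items] <= 0))
    stop("'item_noise' must be positive for items pain, numb, vib, reflex")
  if (side_noise <= 0) stop("'side_noise' must be > 0")
  if (!inherits(item_cutoffs, "measurand_thresholds"))
    stop("'item_cutoffs' must be a measurand_thresholds() object")
  for (it in items) {
    acc <- target_item_accuracy[[it]]
    if (is.null(acc) || length(acc) != 2 || any(acc <= 0) || any(acc >= 1))
      stop("'target_item_accuracy$", it, "' must be (sens, spec) in (0, 1)")
    k <- stats::qnorm(acc[[1]]) + stats::qnorm(acc[[2]])
    if (severity_shift <= k)
      stop("severity_shift must exceed qnorm(sens) + qnorm(spec) = ",
           signif(k, 4), " for item '", it,
           "'; the requested accuracy is unreachable at this class separation")
  }
  if (any(item_scale[c("pain", "numb", "vib")] <= 0))
    stop("'item_scale' entries must be > 0")
  fp <- rater2_agreement$flip_prob
  if (is.null(fp) || fp < 0 || fp > 0.5)
    stop("rater2_agreement$flip_prob must be in [0, 0.5]")
  if (rater2_agreement$noise_sd < 0)
    stop("rater2_agreement$noise_sd must be >= 0")
  p <- qst_params$p_abnormal
  if (any(p < 0 | p > 1)) stop("qst_params$p_abnormal must be probabilities")
  if (qst_params$z_threshold <= 0) stop("qst_params$z_threshold must be > 0")
  if (any(ienfd_params$sdlog <= 0)) stop("ienfd_params$sdlog must be > 0")
  if (uens_params$noise_sd <= 0) stop("uens_params$noise_sd must be > 0")
  if (any(pain_params$bfp_prob < 0 | pain_params$bfp_prob > 1) ||
      any(pain_params$dn4_prob < 0 | pain_params$dn4_prob > 1))
    stop("pain_params probabilities must lie in [0, 1]")
  if (!identical(dim(pain_params$dn4_prob), c(2L, 7L)))
    stop("pain_params$dn4_prob must be a 2 x 7 matrix (control, case rows)")
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 severity_shift = severity_shift, item_noise = item_noise,
                 side_noise = side_noise, item_cutoffs = item_cutoffs,
                 target_item_accuracy = target_item_accuracy,
                 item_scale = item_scale, reflex_step = reflex_step,
                 signs_prob = signs_prob, qst_params = qst_params,
                 ienfd_params = ienfd_params, uens_params = uens_params,
                 pain_params = pain_params,
                 rater2_agreement = rater2_agreement,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# run expr with a local, restorable RNG stream
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# calibration geometry for one item: loading, total SD, latent threshold
item_calibration <- function(config, item) {
  acc <- config$target_item_accuracy[[item]]
  sens <- acc[[1]]; spec <- acc[[2]]
  k <- stats::qnorm(sens) + stats::qnorm(spec)
  sigma <- config$item_noise[[item]]
  tau <- config$side_noise
  delta <- config$severity_shift
  # w*delta = sigma_tot * k with sigma_tot^2 = w^2 + sigma^2 + tau^2
  w <- sqrt((sigma^2 + tau^2) * k^2 / (delta^2 - k^2))
  sigma_tot <- sqrt(w^2 + sigma^2 + tau^2)
  list(w = w, sigma = sigma, tau = tau, sigma_tot = sigma_tot,
       t = sigma_tot * stats::qnorm(spec))
}

cohort_columns <- function() {
  c("id", "latent_status",
    "pain_right", "pain_left", "numb_right", "numb_left",
    "vib_right", "vib_left", "reflex_right", "reflex_left",
    "clinical_signs", paste0("qst_z_", 1:13), "ienfd",
    "uens_right", "uens_left", "bfp", paste0("dn4_", 1:7))
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` records with the generative structure described in
#' [cohort_config()]: a latent class (neuropathy yes/no) at the configured
#' prevalence, a one-dimensional latent severity, four bilateral screening
#' items that are monotone in severity plus noise and calibrated to the target
#' per-item accuracies, deep-phenotype reference components (clinical signs,
#' 13 sensory-testing z-scores, fibre density), an examination score split
#' over sides, and pain-interview / body-map fields.
#'
#' @param config a [cohort_config()] object.
#' @return a `data.frame` of class `chant_cohort`, one row per patient, with
#'   the column dictionary given in [write_cohort()]. Equal seeds give
#'   identical cohorts.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 50, seed = 7))
#' table(cohort$latent_status)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be created by cohort_config()")
  n <- config$n_patients
  if (n == 0L) {
    out <- stats::setNames(
      as.data.frame(lapply(cohort_columns(), function(x) logical(0))),
      cohort_columns())
    class(out) <- c("chant_cohort", "data.frame")
    attr(out, "config") <- config
    return(out)
  }
  with_local_seed(config$seed, {
    status <- stats::runif(n) < config$prevalence
    S <- stats::rnorm(n, mean = ifelse(status, config$severity_shift, 0), sd = 1)

    cuts <- config$item_cutoffs
    side_latents <- function(item) {
      cal <- item_calibration(config, item)
      shared <- cal$w * S + cal$sigma * stats::rnorm(n)
      list(right = shared + cal$tau * stats::rnorm(n),
           left  = shared + cal$tau * stats::rnorm(n),
           t = cal$t)
    }
    # continuous items: observed = cutoff +/- scale * (T - t), clamped
    pl <- side_latents("pain")
    sc <- config$item_scale[["pain"]]
    pain_r <- pmin(10, pmax(0, cuts$pain_cut + sc * (pl$right - pl$t)))
    pain_l <- pmin(10, pmax(0, cuts$pain_cut + sc * (pl$left - pl$t)))
    nl <- side_latents("numb")
    sc <- config$item_scale[["numb"]]
    numb_r <- pmin(10, pmax(0, cuts$numb_cut + sc * (nl$right - nl$t)))
    numb_l <- pmin(10, pmax(0, cuts$numb_cut + sc * (nl$left - nl$t)))
    vl <- side_latents("vib")  # lower seconds = abnormal
    sc <- config$item_scale[["vib"]]
    vib_r <- pmax(0, cuts$vib_cut - sc * (vl$right - vl$t))
    vib_l <- pmax(0, cuts$vib_cut - sc * (vl$left - vl$t))
    rl <- side_latents("reflex")
    cal_r <- item_calibration(config, "reflex")
    t2 <- rl$t + config$reflex_step * cal_r$sigma_tot
    reflex_r <- (rl$right >= rl$t) + (rl$right >= t2)
    reflex_l <- (rl$left >= rl$t) + (rl$left >= t2)

    signs <- stats::runif(n) < config$signs_prob[status + 1L]

    qp <- config$qst_params
    thr <- qp$z_threshold
    p_ab <- qp$p_abnormal[status + 1L]
    qst <- matrix(NA_real_, n, qp$n_params)
    for (j in seq_len(qp$n_params)) {
      ab <- stats::runif(n) < p_ab
      mag <- thr + stats::rexp(n)
      sign_ab <- ifelse(stats::runif(n) < 0.5, -1, 1)
      inner <- stats::qnorm(stats::runif(n, stats::pnorm(-thr), stats::pnorm(thr)))
      qst[, j] <- ifelse(ab, sign_ab * mag, inner)
    }

    ip <- config$ienfd_params
    ienfd <- stats::rlnorm(n, meanlog = ip$meanlog[status + 1L],
                           sdlog = ip$sdlog[status + 1L])

    up <- config$uens_params
    total <- pmin(42, pmax(0, round(up$intercept + up$slope * S +
                                      stats::rnorm(n, 0, up$noise_sd))))
    uens_r <- stats::rbinom(n, size = total, prob = 0.5)
    uens_l <- total - uens_r

    pp <- config$pain_params
    bfp <- stats::runif(n) < pp$bfp_prob[status + 1L]
    dn4 <- matrix(NA, n, 7)
    for (j in 1:7)
      dn4[, j] <- stats::runif(n) < pp$dn4_prob[status + 1L, j]

    out <- data.frame(id = sprintf("P%05d", seq_len(n)),
                      latent_status = status,
                      pain_right = pain_r, pain_left = pain_l,
                      numb_right = numb_r, numb_left = numb_l,
                      vib_right = vib_r, vib_left = vib_l,
                      reflex_right = as.integer(reflex_r),
                      reflex_left = as.integer(reflex_l),
                      clinical_signs = signs,
                      stringsAsFactors = FALSE)
    colnames(qst) <- paste0("qst_z_", 1:13)
    out <- cbind(out, as.data.frame(qst))
    out$ienfd <- ienfd
    out$uens_right <- as.integer(uens_r)
    out$uens_left <- as.integer(uens_l)
    out$bfp <- bfp
    colnames(dn4) <- paste0("dn4_", 1:7)
    out <- cbind(out, as.data.frame(dn4))
    class(out) <- c("chant_cohort", "data.frame")
    attr(out, "config") <- config
    out
  })
}

#' Second-rater measurements for a cohort
#'
#' Re-measures a cohort by an imperfect second rater: binary fields (body-map
#' bilateral feet pain, the seven pain-interview items, clinical signs) are
#' flipped independently with probability `flip_prob`; continuous side values
#' (pain, numbness, vibration) receive additive Gaussian noise and are clamped
#' back to their ranges; ordinal reflex grades take a one-step move with
#' probability `flip_prob`.
#'
#' @param cohort a `chant_cohort` data frame (rater 1).
#' @param rater2_agreement list with `flip_prob` in \[0, 0.5\] and `noise_sd`;
#'   defaults to the cohort config's setting.
#' @param seed integer seed.
#' @return a data frame with the same `id`s and the measurement columns.
#' @export
generate_rater_pair <- function(cohort, rater2_agreement = NULL, seed = 1L) {
  if (nrow(cohort) == 0) stop("'cohort' must be non-empty")
  if (is.null(rater2_agreement))
    rater2_agreement <- attr(cohort, "config")$rater2_agreement
  fp <- rater2_agreement$flip_prob
  sdn <- rater2_agreement$noise_sd
  if (is.null(fp) || fp < 0 || fp > 0.5)
    stop("flip probability must be in [0, 0.5]")
  n <- nrow(cohort)
  with_local_seed(seed, {
    jitter01 <- function(x, lo, hi) pmin(hi, pmax(lo, x + stats::rnorm(n, 0, sdn)))
    out <- data.frame(id = cohort$id,
                      pain_right = jitter01(cohort$pain_right, 0, 10),
                      pain_left = jitter01(cohort$pain_left, 0, 10),
                      numb_right = jitter01(cohort$numb_right, 0, 10),
                      numb_left = jitter01(cohort$numb_left, 0, 10),
                      vib_right = pmax(0, cohort$vib_right + stats::rnorm(n, 0, sdn)),
                      vib_left = pmax(0, cohort$vib_left + stats::rnorm(n, 0, sdn)),
                      stringsAsFactors = FALSE)
    step_ord <- function(g) {
      move <- stats::runif(n) < fp
      dir <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
      as.integer(pmin(2L, pmax(0L, g + ifelse(move, dir, 0L))))
    }
    out$reflex_right <- step_ord(cohort$reflex_right)
    out$reflex_left <- step_ord(cohort$reflex_left)
    flip <- function(b) xor(b, stats::runif(n) < fp)
    out$clinical_signs <- flip(cohort$clinical_signs)
    out$bfp <- flip(cohort$bfp)
    for (j in 1:7) {
      cn <- paste0("dn4_", j)
      out[[cn]] <- flip(cohort[[cn]])
    }
    out
  })
}

#' Per-side binary item matrix
#'
#' Dichotomises the eight side-level measurements of a cohort (or a
#' second-rater measurement set) at the clinical thresholds, producing the
#' 0/1 matrix used for inter-tester reliability: columns
#' `pain_right, pain_left, ..., reflex_left`.
#'
#' @param measurements data frame holding the eight side columns.
#' @param thresholds a [measurand_thresholds()] object.
#' @return integer matrix, rownames taken from `id`.
#' @export
side_item_matrix <- function(measurements, thresholds = measurand_thresholds()) {
  m <- cbind(
    pain_right = measurements$pain_right >= thresholds$pain_cut,
    pain_left = measurements$pain_left >= thresholds$pain_cut,
    numb_right = measurements$numb_right >= thresholds$numb_cut,
    numb_left = measurements$numb_left >= thresholds$numb_cut,
    vib_right = measurements$vib_right <= thresholds$vib_cut,
    vib_left = measurements$vib_left <= thresholds$vib_cut,
    reflex_right = measurements$reflex_right %in% thresholds$reflex_abnormal_grades,
    reflex_left = measurements$reflex_left %in% thresholds$reflex_abnormal_grades)
  storage.mode(m) <- "integer"
  rownames(m) <- measurements$id
  m
}

#' Expert-panel essentiality ratings
#'
#' Simulates a content-validity panel: each panelist rates each item as
#' `essential`, `useful`, or `not_necessary`. An item is rated essential with
#' its configured probability; the remaining mass is split equally between
#' the other two levels.
#'
#' @param n_panelists number of subject-matter experts (>= 1).
#' @param per_item_essential_prob probability, per item, of an "essential"
#'   rating; the vector length sets the number of items.
#' @param seed integer seed.
#' @param item_names optional item labels.
#' @return character matrix (panelists x items).
#' @seealso [cvr()], [panel_from_counts()]
#' @export
generate_panel_responses <- function(n_panelists, per_item_essential_prob,
                                     seed = 1L, item_names = NULL) {
  if (n_panelists < 1) stop("'n_panelists' must be >= 1")
  if (any(per_item_essential_prob < 0 | per_item_essential_prob > 1))
    stop("'per_item_essential_prob' must be probabilities")
  k <- length(per_item_essential_prob)
  with_local_seed(seed, {
    m <- matrix("", n_panelists, k)
    for (j in seq_len(k)) {
      u <- stats::runif(n_panelists)
      p <- per_item_essential_prob[j]
      m[, j] <- ifelse(u < p, "essential",
                       ifelse(u < p + (1 - p) / 2, "useful", "not_necessary"))
    }
    colnames(m) <- item_names %||% paste0("item_", seq_len(k))
    m
  })
}

#' Panel matrix from essential counts
#'
#' Deterministically reconstructs a rating matrix in which exactly
#' `essential_counts[j]` of `n_panelists` rated item `j` essential and the
#' rest rated it useful-but-not-essential.
#'
#' @param essential_counts integer vector of per-item essential counts.
#' @param n_panelists panel size.
#' @param item_names optional item labels.
#' @return character matrix (panelists x items).
#' @export
panel_from_counts <- function(essential_counts, n_panelists, item_names = NULL) {
  if (any(essential_counts < 0 | essential_counts > n_panelists))
    stop("essential counts must lie in [0, n_panelists]")
  m <- matrix(unlist(lapply(essential_counts, function(ne)
    rep(c("essential", "useful"), c(ne, n_panelists - ne)))),
    nrow = n_panelists)
  colnames(m) <- item_names %||% paste0("item_", seq_along(essential_counts))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
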