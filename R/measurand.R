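#' Oriented measurand
#'
#' Wraps a vector of per-patient values together with its abnormality
#' orientation: `higher_abnormal` (e.g. pain 0-10) or `lower_abnormal`
#' (e.g. timed vibration in seconds, where short times are abnormal). All
#' cutoff machinery in the package is inclusive on the abnormal side:
#' `>= cutoff` for `higher_abnormal`, `<= cutoff` for `lower_abnormal`.
#'
#' @param values finite numeric vector, one value per patient.
#' @param orientation which side of a cutoff counts as abnormal.
#' @param name label used in reports.
#' @return an object of class `oriented_measurand`.
#' @export
oriented_measurand <- function(values,
                               orientation = c("higher_abnormal", "lower_abnormal"),
                               name = "measurand") {
  orientation <- match.arg(orientation)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("'values' must be finite")
  structure(list(values = values, orientation = orientation, name = name),
            class = "oriented_measurand")
}

# canonical scale: higher = abnormal; positive call is xc >= c
canonical_values <- function(m) {
  if (m$orientation == "lower_abnormal") -m$values else m$values
}
canonical_to_cutoff <- function(m, c) {
  if (m$orientation == "lower_abnormal") -c else c
}

#' 2x2 table at a cutoff
#'
#' Dichotomises an oriented measurand at `cutoff` (inclusive on the abnormal
#' side) and cross-tabulates against reference labels.
#'
#' @param measurand an [oriented_measurand()].
#' @param labels logical reference labels (TRUE = disease), same length.
#' @param cutoff decision threshold on the measurand's own scale.
#' @return a [confusion_table()].
#' @export
confusion_at_cutoff <- function(measurand, labels, cutoff) {
  stopifnot(length(measurand$values) == length(labels),
            length(measurand$values) >= 1)
  labels <- as.logical(labels)
  pos <- if (measurand$orientation == "higher_abnormal")
    measurand$values >= cutoff else measurand$values <= cutoff
  confusion_table(tp = sum(pos & labels), fp = sum(pos & !labels),
                  fn = sum(!pos & labels), tn = sum(!pos & !labels))
}

# Per-cutoff operating characteristics over midpoint thresholds.
# Thresholds sit strictly between adjacent unique values (plus one beyond
# each end), so inclusive/strict comparison coincides and the lenient end is
# all-positive, the strict end all-negative. Ascending canonical cutoff =
# lenient -> strict.
curve_stats <- function(measurand, labels) {
  labels <- as.logical(labels)
  xc <- canonical_values(measurand)
  u <- sort(unique(xc))
  if (length(u) < 2) {
    gap <- 1
    thr <- c(u - gap, u + gap)
  } else {
    gap <- stats::median(diff(u)) / 2
    thr <- c(u[1] - gap, (u[-length(u)] + u[-1]) / 2, u[length(u)] + gap)
  }
  sp <- sort(xc[labels]); sn <- sort(xc[!labels])
  npos <- length(sp); nneg <- length(sn)
  tp <- npos - findInterval(thr, sp)
  fp <- nneg - findInterval(thr, sn)
  fn <- npos - tp
  tn <- nneg - fp
  data.frame(cutoff = canonical_to_cutoff(measurand, thr), canonical = thr,
             tp = tp, fp = fp, fn = fn, tn = tn,
             sens = if (npos > 0) tp / npos else NA_real_,
             spec = if (nneg > 0) tn / nneg else NA_real_,
             ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
             npv = ifelse(tn + fn > 0, tn / (tn + fn), NA_real_))
}

require_both_classes <- function(labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present in the reference labels")
  labels
}

#' Empirical ROC curve and AUC
#'
#' Operating points over all distinct cutoffs of an oriented measurand, with
#' the area under the curve computed as the concordance probability (ties
#' counted 1/2), which equals the trapezoidal area over the empirical curve.
#'
#' @param measurand an [oriented_measurand()].
#' @param labels logical reference labels; both classes must be present.
#' @return object of class `chant_roc`: `points` (fpr, tpr, cutoff, ordered
#'   from (0,0) to (1,1)), `auc`, class counts.
#' @export
empirical_roc <- function(measurand, labels) {
  labels <- require_both_classes(labels)
  cs <- curve_stats(measurand, labels)
  xc <- canonical_values(measurand)
  r <- rank(xc)  # midranks
  npos <- sum(labels); nneg <- sum(!labels)
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  pts <- data.frame(fpr = 1 - cs$spec, tpr = cs$sens, cutoff = cs$cutoff)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  structure(list(points = pts, auc = auc, n_pos = npos, n_neg = nneg,
                 name = measurand$name),
            class = "chant_roc")
}

#' @export
print.chant_roc <- function(x, ...) {
  cat("Empirical ROC for", x$name, "\n")
  cat(sprintf("  %d cases / %d controls, AUC = %.4f\n", x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
plot.chant_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("%s (AUC = %.3f)", x$name, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# locate crossings of a piecewise-linear difference curve; zero runs return
# their midpoint; multiple crossings resolve to their median
find_crossings <- function(x, d, tol = 1e-12) {
  z <- abs(d) < tol
  crossings <- numeric(0)
  # zero runs
  if (any(z)) {
    r <- rle(z)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      crossings <- c(crossings, (x[starts[i]] + x[ends[i]]) / 2)
    }
  }
  # sign changes between adjacent nonzero points
  nz <- which(!z)
  if (length(nz) >= 2) {
    for (i in seq_len(length(nz) - 1)) {
      a <- nz[i]; b <- nz[i + 1]
      if (b - a == 1 && sign(d[a]) != sign(d[b])) {
        crossings <- c(crossings,
                       x[a] + (x[b] - x[a]) * d[a] / (d[a] - d[b]))
      }
    }
  }
  crossings
}

#' Crossover cutoff for a paired-statistic criterion
#'
#' Evaluates the two statistics of the chosen criterion at every distinct
#' cutoff, treats each as piecewise linear in the cutoff, and returns the
#' cutoff where they cross. The three criteria are: `sens_spec` (sensitivity
#' and specificity curves), `ppv_npv` (positive and negative predictive
#' values), and `lr` (likelihood-ratio evidence balance: the cutoff at which
#' the log positive likelihood ratio equals minus the log negative likelihood
#' ratio, i.e. a positive and a negative result carry equal evidence; this is
#' the interior operating point of the positive/negative likelihood-ratio
#' trade-off). If the curves coincide over an interval the interval midpoint
#' is returned; several distinct crossings (small-sample wobble) resolve to
#' their median.
#'
#' @param measurand an [oriented_measurand()].
#' @param labels logical reference labels; both classes required.
#' @param criterion which pair of curves to cross.
#' @return cutoff on the measurand's own scale.
#' @export
crossover_cutoff <- function(measurand, labels,
                             criterion = c("sens_spec", "ppv_npv", "lr")) {
  criterion <- match.arg(criterion)
  labels <- require_both_classes(labels)
  cs <- curve_stats(measurand, labels)
  if (criterion == "sens_spec") {
    valid <- rep(TRUE, nrow(cs))
    d <- cs$sens - cs$spec
  } else if (criterion == "ppv_npv") {
    valid <- !is.na(cs$ppv) & !is.na(cs$npv)
    d <- cs$ppv - cs$npv
  } else {
    # log LR+ = -log LR-  <=>  sens(1-sens) = spec(1-spec); the product form
    # has the same crossings and stays defined at degenerate operating points
    valid <- rep(TRUE, nrow(cs))
    d <- cs$sens * (1 - cs$sens) - cs$spec * (1 - cs$spec)
  }
  x <- cs$canonical[valid]
  dv <- d[valid]
  if (length(x) < 1)
    stop("criterion '", criterion, "' is undefined everywhere for these data")
  cr <- find_crossings(x, dv)
  if (length(cr) == 0)
    stop("criterion curves never cross for '", criterion,
         "' (degenerate data): difference ranges [",
         signif(min(dv), 4), ", ", signif(max(dv), 4), "]")
  canonical_to_cutoff(measurand, stats::median(cr))
}

#' Misdiagnosis cost weights
#'
#' Relative misdiagnosis costs. Only the error weights enter the adopted
#' cost formula (see [min_cost_cutoff()]); `c_tp` and `c_tn` are retained
#' for completeness and are inert. The defaults weight a missed case twice
#' a false alarm (false-positive : false-negative ratio 0.5).
#'
#' @param c_tp,c_tn,c_fp,c_fn non-negative weights.
#' @return object of class `cost_weights`.
#' @export
cost_weights <- function(c_tp = 1, c_tn = 1, c_fp = 1, c_fn = 2) {
  w <- c(c_tp = c_tp, c_tn = c_tn, c_fp = c_fp, c_fn = c_fn)
  if (any(w < 0)) stop("cost weights must be non-negative")
  if (c_fp + c_fn <= 0) stop("c_fp + c_fn must be positive")
  structure(as.list(w), class = "cost_weights")
}

#' Minimum-cost cutoff
#'
#' Normalised expected misdiagnosis cost at cutoff `c`:
#' \deqn{cost(c) = (c_{fp} FP(c) + c_{fn} FN(c)) / (c_{fp} N_{-} + c_{fn} N_{+})}
#' so cost lies in \[0, 1\] and is 0 only for perfect classification. Returns
#' the cutoff minimising cost over all distinct cutoffs; exact ties resolve
#' to the tied cutoff closest to the sensitivity/specificity crossover.
#'
#' @param measurand an [oriented_measurand()].
#' @param labels logical reference labels; both classes required.
#' @param weights a [cost_weights()] object.
#' @return list with `cutoff`, `cost` (the minimum), and `cost_curve`
#'   (data frame of cutoff, cost).
#' @export
min_cost_cutoff <- function(measurand, labels, weights = cost_weights()) {
  labels <- require_both_classes(labels)
  if (!inherits(weights, "cost_weights")) stop("'weights' must be cost_weights()")
  cs <- curve_stats(measurand, labels)
  npos <- sum(labels); nneg <- sum(!labels)
  denom <- weights$c_fp * nneg + weights$c_fn * npos
  cost <- (weights$c_fp * cs$fp + weights$c_fn * cs$fn) / denom
  tied <- which(cost <= min(cost) + 1e-12)
  if (length(tied) > 1) {
    anchor <- tryCatch(crossover_cutoff(measurand, labels, "sens_spec"),
                       error = function(e) NA_real_)
    pick <- if (is.na(anchor)) tied[ceiling(length(tied) / 2)]
    else tied[which.min(abs(cs$cutoff[tied] - anchor))]
  } else pick <- tied
  list(cutoff = cs$cutoff[pick], cost = cost[pick],
       cost_curve = data.frame(cutoff = cs$cutoff, cost = cost))
}

#' Geometric-mean consensus cutoff
#'
#' Combines criterion-specific cutoffs into a consensus with central
#' tendency: \eqn{(c_1 c_2 \cdots c_m)^{1/m}}. Requires a positive scale;
#' for scales containing zero, supply `offset` (applied before, removed
#' after: \eqn{gm = \exp(\mathrm{mean}(\log(c_i + o))) - o}).
#'
#' @param cutoffs numeric vector of cutoffs (typically the four criteria).
#' @param offset non-negative shift for scales containing zero.
#' @return the consensus cutoff; always within \[min, max\] of the inputs.
#' @export
geometric_mean_cutoff <- function(cutoffs, offset = 0) {
  shifted <- cutoffs + offset
  if (any(shifted <= 0))
    stop("geometric mean requires strictly positive cutoffs; ",
         "apply the documented offset transform (e.g. offset = 1) ",
         "for scales containing zero")
  exp(mean(log(shifted))) - offset
}

#' Partial eta-squared effect size
#'
#' Effect size of a grouping factor on a dependent variable, optionally with
#' covariates partialled out first (covariance-adjusted decomposition):
#' \eqn{\eta^2_p = SS_{effect} / (SS_{effect} + SS_{error})}, with the factor
#' entered after the covariates. Without covariates this is classical
#' eta-squared.
#'
#' @param dependent numeric (or logical) response.
#' @param factor grouping variable; at least two non-empty groups.
#' @param covariates optional numeric vector, matrix or data frame.
#' @return object of class `effect_size`: `partial_eta_squared`,
#'   `ss_effect`, `ss_error`.
#' @export
partial_eta_squared <- function(dependent, factor, covariates = NULL) {
  y <- as.numeric(dependent)
  g <- base::factor(factor)
  if (nlevels(droplevels(g)) < 2) stop("at least 2 non-empty groups required")
  if (any(tabulate(g) < 1)) stop("every group needs at least one observation")
  dat <- data.frame(.y = y, .g = droplevels(g))
  form <- .y ~ .g
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    names(cov_df) <- paste0(".x", seq_along(cov_df))
    dat <- cbind(dat, cov_df)
    form <- stats::reformulate(c(names(cov_df), ".g"), response = ".y")
  }
  # only the sums of squares are used; F-test warnings on perfect fits are moot
  a <- suppressWarnings(stats::anova(stats::lm(form, data = dat)))
  ss_effect <- a[".g", "Sum Sq"]
  ss_error <- a["Residuals", "Sum Sq"]
  eta2 <- if (ss_effect + ss_error > 0) ss_effect / (ss_effect + ss_error) else NA_real_
  structure(list(partial_eta_squared = eta2, ss_effect = ss_effect,
                 ss_error = ss_error),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("partial eta-squared = %.4f (SS effect %.4g, SS error %.4g)\n",
              x$partial_eta_squared, x$ss_effect, x$ss_error))
  invisible(x)
}

#' Evaluate one measurand against a reference
#'
#' Fits the full accuracy deconstruction of a candidate screening measurand:
#' empirical ROC and AUC, the four cutoff-selection criteria
#' (sensitivity/specificity crossover, predictive-value crossover,
#' likelihood-ratio balance, minimum weighted misdiagnosis cost), their
#' geometric-mean consensus cutoff, the cost curve, and the effect size of
#' disease status on the measurand.
#'
#' @param measurand an [oriented_measurand()].
#' @param labels logical reference labels; both classes required.
#' @param weights a [cost_weights()] object for the cost criterion.
#' @param gm_offset offset passed to [geometric_mean_cutoff()] for scales
#'   containing zero.
#' @return an object of class `measurand_eval` with `print`, `summary`,
#'   `coef`, `predict` and `plot` methods. `coef` returns the four cutoffs
#'   and the consensus; `predict` dichotomises new values at the consensus
#'   cutoff (or any supplied cutoff).
#' @examples
#' set.seed(1)
#' x <- c(rnorm(60, 2), rnorm(40, 4))
#' lab <- rep(c(FALSE, TRUE), c(60, 40))
#' fit <- evaluate_measurand(oriented_measurand(x, "higher_abnormal", "toy"), lab)
#' coef(fit)
#' @export
evaluate_measurand <- function(measurand, labels, weights = cost_weights(),
                               gm_offset = 0) {
  labels <- require_both_classes(labels)
  roc <- empirical_roc(measurand, labels)
  c_ss <- crossover_cutoff(measurand, labels, "sens_spec")
  c_pn <- crossover_cutoff(measurand, labels, "ppv_npv")
  c_lr <- crossover_cutoff(measurand, labels, "lr")
  mc <- min_cost_cutoff(measurand, labels, weights)
  cuts <- c(sens_spec = c_ss, ppv_npv = c_pn, lr = c_lr,
            min_cost = mc$cutoff)
  gm <- geometric_mean_cutoff(cuts, offset = gm_offset)
  ct <- confusion_at_cutoff(measurand, labels, c_ss)
  cross_acc <- (ct$tp / (ct$tp + ct$fn) + ct$tn / (ct$tn + ct$fp)) / 2
  es <- partial_eta_squared(measurand$values, labels)
  structure(list(name = measurand$name, orientation = measurand$orientation,
                 n = length(labels), n_pos = sum(labels),
                 auc = roc$auc, roc = roc,
                 crossover_accuracy = cross_acc,
                 effect_size = es, cutoffs = cuts, geometric_mean = gm,
                 min_cost = mc$cost, cost_curve = mc$cost_curve,
                 weights = weights),
            class = "measurand_eval")
}

#' @export
print.measurand_eval <- function(x, ...) {
  rel <- if (x$orientation == "higher_abnormal") ">=" else "<="
  cat("Measurand evaluation:", x$name,
      sprintf("(abnormal %s cutoff)\n", rel))
  cat(sprintf("  n = %d (%d cases), AUC = %.3f, crossover sens/spec = %.1f%%\n",
              x$n, x$n_pos, x$auc, 100 * x$crossover_accuracy))
  cat(sprintf("  partial eta-squared = %.3f\n",
              x$effect_size$partial_eta_squared))
  cat(sprintf(paste0("  cutoffs: sens/spec %.3f | PPV/NPV %.3f | LR %.3f | ",
                     "min-cost %.3f\n"),
              x$cutoffs[["sens_spec"]], x$cutoffs[["ppv_npv"]],
              x$cutoffs[["lr"]], x$cutoffs[["min_cost"]]))
  cat(sprintf("  geometric-mean cutoff %s %.3f, minimum cost %.3f\n",
              rel, x$geometric_mean, x$min_cost))
  invisible(x)
}

#' @export
summary.measurand_eval <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.measurand_eval <- function(object, ...) {
  c(object$cutoffs, geometric_mean = object$geometric_mean)
}

#' @rdname evaluate_measurand
#' @param object a fitted `measurand_eval`.
#' @param newdata numeric values on the measurand scale.
#' @param cutoff decision threshold (defaults to the consensus cutoff).
#' @param ... ignored.
#' @export
predict.measurand_eval <- function(object, newdata, cutoff = NULL, ...) {
  cutoff <- cutoff %||% object$geometric_mean
  if (object$orientation == "higher_abnormal") newdata >= cutoff
  else newdata <= cutoff
}

#' @export
plot.measurand_eval <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$roc)
  graphics::plot(x$cost_curve$cutoff, x$cost_curve$cost, type = "l",
                 xlab = paste(x$name, "cutoff"), ylab = "normalised cost",
                 main = "Misdiagnosis cost")
  graphics::abline(v = x$geometric_mean, lty = 2)
  invisible(x)
}

#' Develop the four-item instrument from a cohort
#'
#' Runs [evaluate_measurand()] for each of the four screening items against a
#' reference label, using the per-patient mean of the two sides as the item
#' summary (the instrument is explicitly bilateral; the side mean is the
#' symmetric per-patient value). Produces the development report: one row per
#' measurand with AUC, crossover accuracy, effect size, the four cutoffs,
#' their consensus, and the minimum cost.
#'
#' @param cohort a `chant_cohort` data frame.
#' @param labels reference labels; defaults to the latent status (use
#'   [reference_labels()] for a composite standard).
#' @param weights a [cost_weights()] object.
#' @return object of class `chant_development`: `evals` (named list of
#'   `measurand_eval`) and `table` (the report data frame).
#' @export
develop_chant <- function(cohort, labels = cohort$latent_status,
                          weights = cost_weights()) {
  side_mean <- function(a, b) (a + b) / 2
  ms <- list(
    feet_pain = oriented_measurand(
      side_mean(cohort$pain_right, cohort$pain_left), "higher_abnormal",
      "feet_pain"),
    feet_numbness = oriented_measurand(
      side_mean(cohort$numb_right, cohort$numb_left), "higher_abnormal",
      "feet_numbness"),
    vibration = oriented_measurand(
      side_mean(cohort$vib_right, cohort$vib_left), "lower_abnormal",
      "vibration"),
    ankle_reflex = oriented_measurand(
      side_mean(cohort$reflex_right, cohort$reflex_left), "higher_abnormal",
      "ankle_reflex"))
  evals <- lapply(ms, function(m) {
    off <- if (min(m$values) <= 0 || m$name == "ankle_reflex") 1 else 0
    evaluate_measurand(m, labels, weights, gm_offset = off)
  })
  tab <- do.call(rbind, lapply(evals, function(e)
    data.frame(measurand = e$name, orientation = e$orientation,
               auc = e$auc, crossover_accuracy = e$crossover_accuracy,
               partial_eta_squared = e$effect_size$partial_eta_squared,
               cutoff_sens_spec = e$cutoffs[["sens_spec"]],
               cutoff_ppv_npv = e$cutoffs[["ppv_npv"]],
               cutoff_lr = e$cutoffs[["lr"]],
               cutoff_min_cost = e$cutoffs[["min_cost"]],
               geometric_mean = e$geometric_mean,
               min_cost = e$min_cost, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  structure(list(evals = evals, table = tab), class = "chant_development")
}

#' @export
print.chant_development <- function(x, digits = 3, ...) {
  cat("Four-item instrument development report\n")
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.chant_development <- function(x, ...) x$table

#' Write / read the development report
#'
#' @param development a `chant_development` object (writer) .
#' @param path CSV path.
#' @return `path` invisibly (writer); the report data frame (reader).
#' @export
write_table1_report <- function(development, path) {
  tab <- development$table
  for (cn in names(tab)) if (is.double(tab[[cn]]))
    tab[[cn]] <- sprintf("%.17g", tab[[cn]])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table1_report
#' @export
read_table1_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
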