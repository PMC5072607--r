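#' 2x2 confusion table
#'
#' @param tp,fp,fn,tn non-negative cell counts (index test vs reference).
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  cells <- as.integer(round(cells))
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4]),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("case", "non-case")))
  print(m)
  invisible(x)
}

#' Confusion table from paired labels
#'
#' Pairs with a missing value in either label (e.g. asymmetric exclusions
#' under the examination reference) are dropped.
#'
#' @param test logical index-test verdicts.
#' @param reference logical reference-standard labels.
#' @return a [confusion_table()].
#' @export
confusion_from_labels <- function(test, reference) {
  keep <- !is.na(test) & !is.na(reference)
  test <- as.logical(test)[keep]; reference <- as.logical(reference)[keep]
  confusion_table(tp = sum(test & reference), fp = sum(test & !reference),
                  fn = sum(!test & reference), tn = sum(!test & !reference))
}

#' Diagnostic accuracy metrics with likelihood ratios
#'
#' Standard 2x2 metrics: sensitivity, specificity, predictive values,
#' and likelihood ratios LR+ = sens/(1-spec) (`Inf` at perfect specificity,
#' no continuity correction) and LR- = (1-sens)/spec. Zero denominators for
#' sensitivity or specificity are errors; a zero denominator for a
#' predictive value yields `NA` with a warning naming the metric.
#'
#' @param table a [confusion_table()].
#' @return object of class `diagnostic_metrics`.
#' @examples
#' diagnostic_metrics(confusion_table(tp = 10, fp = 3, fn = 0, tn = 17))
#' @export
diagnostic_metrics <- function(table) {
  if (!inherits(table, "confusion_table"))
    stop("'table' must be a confusion_table()")
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  if (tp + fn == 0) stop("sensitivity undefined: no reference-positive cases")
  if (fp + tn == 0) stop("specificity undefined: no reference-negative cases")
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("PPV undefined: no test positives"); NA_real_
  }
  npv <- if (tn + fn > 0) tn / (tn + fn) else {
    warning("NPV undefined: no test negatives"); NA_real_
  }
  lr_pos <- if (spec < 1) sens / (1 - spec) else Inf
  lr_neg <- if (spec > 0) (1 - sens) / spec else Inf
  n <- tp + fp + fn + tn
  structure(list(table = table, sensitivity = sens, specificity = spec,
                 ppv = ppv, npv = npv, lr_pos = lr_pos, lr_neg = lr_neg,
                 prevalence = (tp + fn) / n, n = n),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("n = %d, prevalence = %.1f%%\n", x$n, 100 * x$prevalence))
  cat(sprintf("sensitivity = %.2f%%, specificity = %.2f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("PPV = %s, NPV = %s\n",
              if (is.na(x$ppv)) "undefined" else sprintf("%.2f%%", 100 * x$ppv),
              if (is.na(x$npv)) "undefined" else sprintf("%.2f%%", 100 * x$npv)))
  cat(sprintf("LR+ = %s, LR- = %s\n",
              if (is.infinite(x$lr_pos)) "Inf" else sprintf("%.2f", x$lr_pos),
              if (is.infinite(x$lr_neg)) "Inf" else sprintf("%.2f", x$lr_neg)))
  invisible(x)
}

#' Post-test probability (nomogram arithmetic)
#'
#' Converts a pre-test probability through a likelihood ratio by exact odds
#' arithmetic: post-odds = pre-odds x LR; returns post-odds/(1 + post-odds).
#'
#' @param pretest pre-test probability, strictly inside (0, 1).
#' @param lr positive likelihood ratio to apply.
#' @return post-test probability.
#' @examples
#' fagan_posttest(0.43, 6.67)  # 0.834
#' @export
fagan_posttest <- function(pretest, lr) {
  if (any(pretest <= 0 | pretest >= 1))
    stop("'pretest' must lie strictly inside (0, 1)")
  if (any(lr <= 0)) stop("'lr' must be positive")
  odds <- pretest / (1 - pretest) * lr
  odds / (1 + odds)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1) (1 - \sum_i v_i / v_{total})} with unbiased
#' (denominator n-1) variances.
#'
#' @param item_matrix numeric matrix or data frame, patients x items
#'   (>= 2 items, >= 2 patients).
#' @return alpha (<= 1).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  k <- ncol(m); n <- nrow(m)
  if (k < 2 || n < 2) stop("need at least 2 items and 2 patients")
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) stop("total-score variance is zero")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

# Spearman rho with midranks for ties
spearman_rho <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Corrected item-total correlations
#'
#' For each item, the Spearman rank correlation (midranks for ties) between
#' the item and the rest-score (scale total minus that item). The corrected
#' form avoids the self-correlation inflation of correlating an item with a
#' total that contains it; set `corrected = FALSE` for the uncorrected
#' variant.
#'
#' @param item_matrix numeric matrix or data frame, patients x items.
#' @param corrected use the rest-score (default) or the full total.
#' @return list of class `item_total`: `per_item` (named, `NA` with a warning
#'   for items or rest-scores without variance) and `mean`.
#' @export
item_total_correlation <- function(item_matrix, corrected = TRUE) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2 || nrow(m) < 2) stop("need at least 2 items and 2 patients")
  total <- rowSums(m)
  per_item <- vapply(seq_len(ncol(m)), function(j) {
    other <- if (corrected) total - m[, j] else total
    spearman_rho(m[, j], other)
  }, numeric(1))
  names(per_item) <- colnames(m) %||% paste0("item_", seq_len(ncol(m)))
  if (anyNA(per_item))
    warning("item-total correlation undefined (zero variance) for: ",
            paste(names(per_item)[is.na(per_item)], collapse = ", "))
  structure(list(per_item = per_item, mean = mean(per_item, na.rm = TRUE)),
            class = "item_total")
}

#' @export
print.item_total <- function(x, ...) {
  cat("Item-total Spearman correlations (corrected):\n")
  print(round(x$per_item, 4))
  cat(sprintf("mean = %.4f\n", x$mean))
  invisible(x)
}

#' Inter-tester concordance
#'
#' Per-item Spearman rank correlation between two raters' matched
#' measurement matrices.
#'
#' @param rater1_matrix,rater2_matrix patients x items matrices with
#'   identical dimensions, column names, and row order (row names, when
#'   present, must match: same patients).
#' @return named numeric vector of per-item rank correlations.
#' @export
inter_tester <- function(rater1_matrix, rater2_matrix) {
  m1 <- as.matrix(rater1_matrix); m2 <- as.matrix(rater2_matrix)
  if (!identical(dim(m1), dim(m2)))
    stop("rater matrices must have identical dimensions")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("rater matrices are not matched: patient ids differ")
  if (!is.null(colnames(m1)) && !is.null(colnames(m2)) &&
      !identical(colnames(m1), colnames(m2)))
    stop("rater matrices are not matched: item names differ")
  rho <- vapply(seq_len(ncol(m1)),
                function(j) spearman_rho(m1[, j], m2[, j]), numeric(1))
  names(rho) <- colnames(m1) %||% paste0("item_", seq_len(ncol(m1)))
  rho
}

#' Content validity ratio
#'
#' Lawshe's ratio for expert-panel essentiality:
#' \eqn{CVR = (n_e - N/2)/(N/2)}, where \eqn{n_e} panelists of \eqn{N} rated
#' the item essential. Ranges over \[-1, 1\]; positive values mean more than
#' half the panel rated the item essential.
#'
#' @param n_essential per-item counts of "essential" ratings (vectorised).
#' @param n_panelists total panel size N (>= 1).
#' @return list of class `cvr_result`: `per_item` and `mean`.
#' @examples
#' cvr(c(4, 5, 5, 5), 5)  # 0.6, 1, 1, 1; mean 0.9
#' @export
cvr <- function(n_essential, n_panelists) {
  if (n_panelists < 1) stop("'n_panelists' must be >= 1")
  if (any(n_essential < 0 | n_essential > n_panelists))
    stop("'n_essential' must lie in [0, n_panelists]")
  v <- (n_essential - n_panelists / 2) / (n_panelists / 2)
  structure(list(per_item = v, mean = mean(v)), class = "cvr_result")
}

#' @export
print.cvr_result <- function(x, ...) {
  cat("Content validity ratio per item:", paste(round(x$per_item, 3),
                                                collapse = ", "), "\n")
  cat(sprintf("mean CVR = %.3f\n", x$mean))
  invisible(x)
}

#' CVR from a panel rating matrix
#'
#' @param ratings character matrix (panelists x items) with levels
#'   `essential`, `useful`, `not_necessary`
#'   (see [generate_panel_responses()]).
#' @return as [cvr()].
#' @export
panel_cvr <- function(ratings) {
  bad <- setdiff(unique(as.vector(ratings)),
                 c("essential", "useful", "not_necessary"))
  if (length(bad)) stop("unknown rating level(s): ", paste(bad, collapse = ", "))
  out <- cvr(colSums(ratings == "essential"), nrow(ratings))
  names(out$per_item) <- colnames(ratings)
  out
}

#' Validate the screen against a reference standard
#'
#' Builds the 2x2 table from paired verdicts (or accepts one directly),
#' computes the accuracy metrics, and carries the positive likelihood ratio
#' through exact nomogram arithmetic to a post-test probability. The default
#' pre-test probability is the sample prevalence, which makes the post-test
#' probability of a positive result coincide with the PPV.
#'
#' @param test logical index-test verdicts (ignored if `table` is given).
#' @param reference logical reference labels.
#' @param table optionally, a [confusion_table()] directly.
#' @param pretest pre-test probability (default: sample prevalence).
#' @return object of class `chant_validation`: `metrics`, `pretest`,
#'   `posttest`.
#' @export
validate_chant <- function(test = NULL, reference = NULL, table = NULL,
                           pretest = NULL) {
  if (is.null(table)) table <- confusion_from_labels(test, reference)
  metrics <- diagnostic_metrics(table)
  pretest <- pretest %||% metrics$prevalence
  posttest <- if (is.infinite(metrics$lr_pos)) 1
  else fagan_posttest(pretest, metrics$lr_pos)
  structure(list(metrics = metrics, pretest = pretest, posttest = posttest),
            class = "chant_validation")
}

#' @export
print.chant_validation <- function(x, ...) {
  print(x$metrics)
  cat(sprintf("pre-test probability %.0f%% -> post-test %.0f%% for a positive screen\n",
              100 * x$pretest, 100 * x$posttest))
  invisible(x)
}
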