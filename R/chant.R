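#' Clinical thresholds for the four screening items
#'
#' The per-item decision thresholds used to dichotomise each side: feet pain
#' `>= 5.5` (0-10 rating), feet numbness `>= 2.55` (0-10), great-toe
#' vibration `<= 13.2` seconds (shorter = abnormal), and an ankle reflex
#' graded hypoactive or absent.
#'
#' @param pain_cut pain threshold, higher abnormal (default 5.5).
#' @param numb_cut numbness threshold, higher abnormal (default 2.55).
#' @param vib_cut vibration threshold in seconds, lower abnormal
#'   (default 13.2).
#' @param reflex_abnormal_grades reflex grades counted abnormal
#'   (default `c(1, 2)`, hypoactive and absent).
#' @return object of class `measurand_thresholds`.
#' @export
measurand_thresholds <- function(pain_cut = 5.5, numb_cut = 2.55,
                                 vib_cut = 13.2,
                                 reflex_abnormal_grades = c(1L, 2L)) {
  if (pain_cut < 0 || pain_cut > 10 || numb_cut < 0 || numb_cut > 10)
    stop("pain/numbness cutoffs must lie in [0, 10]")
  if (vib_cut < 0) stop("'vib_cut' must be non-negative")
  if (!all(reflex_abnormal_grades %in% 0:2))
    stop("'reflex_abnormal_grades' must be a subset of {0, 1, 2}")
  structure(list(pain_cut = pain_cut, numb_cut = numb_cut, vib_cut = vib_cut,
                 reflex_abnormal_grades = as.integer(reflex_abnormal_grades)),
            class = "measurand_thresholds")
}

#' Score the four items per side
#'
#' Dichotomises each side of each item at the clinical thresholds and tallies
#' the number of abnormal sides (0, 1, or 2) per item. A tally of 2 means
#' bilateral abnormality, which is what the combination rule requires.
#'
#' @param x a `chant_cohort` data frame (or any data frame with the eight
#'   side columns `pain_right`, ..., `reflex_left`).
#' @param thresholds a [measurand_thresholds()] object.
#' @return data frame of class `chant_score`: `id` plus `pain_tally`,
#'   `numb_tally`, `vib_tally`, `reflex_tally`, each in 0..2.
#' @export
score_items <- function(x, thresholds = measurand_thresholds()) {
  need <- c("pain_right", "pain_left", "numb_right", "numb_left",
            "vib_right", "vib_left", "reflex_right", "reflex_left")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("missing side values: ", paste(missing_cols, collapse = ", "))
  for (cn in need) {
    if (anyNA(x[[cn]])) {
      parts <- strsplit(cn, "_")[[1]]
      stop("missing value for item '", parts[1], "', side '", parts[2],
           "' (rows ", paste(utils::head(which(is.na(x[[cn]])), 5),
                             collapse = ", "), ")")
    }
  }
  ab <- side_item_matrix(x, thresholds)
  out <- data.frame(
    id = if (!is.null(x$id)) x$id else seq_len(nrow(ab)),
    pain_tally = ab[, "pain_right"] + ab[, "pain_left"],
    numb_tally = ab[, "numb_right"] + ab[, "numb_left"],
    vib_tally = ab[, "vib_right"] + ab[, "vib_left"],
    reflex_tally = ab[, "reflex_right"] + ab[, "reflex_left"],
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("chant_score", "data.frame")
  out
}

# tallies as an n x 4 integer matrix from the accepted input shapes
tally_matrix <- function(tallies) {
  if (is.data.frame(tallies))
    tallies <- as.matrix(tallies[, c("pain_tally", "numb_tally",
                                     "vib_tally", "reflex_tally")])
  if (is.null(dim(tallies))) tallies <- matrix(tallies, nrow = 1)
  if (ncol(tallies) != 4) stop("tallies must have four items")
  if (!all(tallies %in% 0:2)) stop("tallies must be integers in {0, 1, 2}")
  storage.mode(tallies) <- "integer"
  tallies
}

# the 21 printed rubric rows (pain, numb, vib, reflex), as published
table2_rows <- function() {
  m <- matrix(c(
    2, 2, 0, 0,
    2, 2, 1, 0,
    2, 2, 0, 1,
    2, 2, 1, 1,
    0, 2, 2, 0,
    1, 2, 2, 0,
    0, 2, 2, 1,
    1, 2, 2, 1,
    0, 0, 2, 2,
    0, 1, 2, 2,
    1, 0, 2, 2,
    1, 1, 2, 2,
    0, 2, 2, 2,
    1, 2, 2, 2,
    2, 0, 2, 2,
    2, 1, 2, 2,
    2, 2, 0, 2,
    2, 2, 1, 2,
    2, 2, 2, 0,
    2, 2, 2, 1,
    2, 2, 2, 2), ncol = 4, byrow = TRUE)
  colnames(m) <- c("pain_tally", "numb_tally", "vib_tally", "reflex_tally")
  m
}

#' Combination decision rule
#'
#' Applies the instrument's positivity rule to the four item tallies. The
#' canonical `verbal` rule is: positive iff (bilateral feet pain OR bilateral
#' reduced vibration) AND (bilateral feet numbness OR bilateral reduced ankle
#' reflex). The `table2_strict` rule instead declares positive exactly the 21
#' tally quadruples enumerated in the published rubric, which omits four
#' quadruples the verbal rule accepts (bilateral pain with bilateral absent
#' reflex but neither numbness nor vibration bilateral); see
#' [rubric_discrepancy()].
#'
#' @param tallies a `chant_score` data frame, an n x 4 matrix, or a length-4
#'   vector of tallies in `{0, 1, 2}` ordered pain, numbness, vibration,
#'   reflex.
#' @param rule which rubric to apply.
#' @return logical vector of verdicts.
#' @export
chant_positive <- function(tallies, rule = c("verbal", "table2_strict")) {
  rule <- match.arg(rule)
  m <- tally_matrix(tallies)
  if (rule == "verbal") {
    (m[, 1] == 2L | m[, 3] == 2L) & (m[, 2] == 2L | m[, 4] == 2L)
  } else {
    keys <- apply(table2_rows(), 1, paste, collapse = "")
    apply(m, 1, paste, collapse = "") %in% keys
  }
}

#' Enumerate the positivity rubric
#'
#' Scans all 3^4 = 81 tally quadruples and returns those classified positive
#' under the chosen rule.
#'
#' @param rule rubric to enumerate.
#' @return integer matrix of positive quadruples (columns `pain_tally`,
#'   `numb_tally`, `vib_tally`, `reflex_tally`), in lexicographic order.
#' @export
enumerate_rubric <- function(rule = c("verbal", "table2_strict")) {
  rule <- match.arg(rule)
  g <- as.matrix(expand.grid(reflex_tally = 0:2, vib_tally = 0:2,
                             numb_tally = 0:2, pain_tally = 0:2))
  g <- g[, c("pain_tally", "numb_tally", "vib_tally", "reflex_tally")]
  pos <- chant_positive(g, rule)
  out <- g[pos, , drop = FALSE]
  out[order(out[, 1], out[, 2], out[, 3], out[, 4]), , drop = FALSE]
}

#' Quadruples where the two rubrics disagree
#'
#' The verbal rule accepts four tally quadruples that the published 21-row
#' rubric omits. This function surfaces them; the package never silently
#' reconciles the two rules.
#'
#' @return integer matrix of the disagreement quadruples.
#' @export
rubric_discrepancy <- function() {
  v <- enumerate_rubric("verbal")
  s <- enumerate_rubric("table2_strict")
  keys_s <- apply(s, 1, paste, collapse = "")
  v[!apply(v, 1, paste, collapse = "") %in% keys_s, , drop = FALSE]
}

# cache for the monotone boolean function enumeration
.chant_cache <- new.env(parent = emptyenv())

#' All monotone Boolean combination rules of the four bilateral indicators
#'
#' Enumerates, by brute force over all 2^16 truth tables, every monotone
#' Boolean function of the four bilateral-abnormality indicators
#' (tally == 2), excluding the two constants. Monotonicity is imposed
#' because a clinical abnormality can only add evidence for disease. There
#' are 168 monotone functions of four variables, hence 166 candidates.
#'
#' @return integer vector of truth-table encodings (bit i of the encoding is
#'   the verdict for the input whose indicator pattern is the binary
#'   expansion of i, ordered pain, numbness, vibration, reflex).
#' @export
monotone_rule_encodings <- function() {
  if (!is.null(.chant_cache$monotone)) return(.chant_cache$monotone)
  f <- 0:65535
  bits <- vapply(0:15, function(i) bitwAnd(bitwShiftR(f, i), 1L),
                 integer(length(f)))
  ok <- rep(TRUE, length(f))
  for (i in 0:15) {
    for (j in 0:3) {
      if (bitwAnd(bitwShiftR(i, j), 1L) == 0L) {
        k <- i + bitwShiftL(1L, j)
        ok <- ok & (bits[, i + 1L] <= bits[, k + 1L])
      }
    }
  }
  enc <- f[ok]
  enc <- enc[enc != 0L & enc != 65535L]
  .chant_cache$monotone <- enc
  enc
}

# verdicts of an encoded rule for indicator patterns 0..15
rule_truth_table <- function(encoding) {
  as.logical(bitwAnd(bitwShiftR(encoding, 0:15), 1L))
}

#' Apply an encoded combination rule
#'
#' @param encoding a truth-table encoding from [monotone_rule_encodings()].
#' @param tallies tallies as in [chant_positive()].
#' @return logical verdicts.
#' @export
rule_predict <- function(encoding, tallies) {
  m <- tally_matrix(tallies)
  idx <- (m[, 1] == 2L) + 2L * (m[, 2] == 2L) + 4L * (m[, 3] == 2L) +
    8L * (m[, 4] == 2L)
  rule_truth_table(encoding)[idx + 1L]
}

# encoding of the verbal rule, for reference in alpha-test output
verbal_rule_encoding <- function() {
  idx <- 0:15
  p <- bitwAnd(idx, 1L) == 1L
  n <- bitwAnd(bitwShiftR(idx, 1L), 1L) == 1L
  v <- bitwAnd(bitwShiftR(idx, 2L), 1L) == 1L
  r <- bitwAnd(bitwShiftR(idx, 3L), 1L) == 1L
  val <- (p | v) & (n | r)
  sum(bitwShiftL(1L, idx[val]))
}

#' In-silico alpha test over all candidate combination rules
#'
#' Evaluates every non-constant monotone Boolean function of the four
#' bilateral-abnormality indicators against a reference label, computing
#' sensitivity and specificity for each and ranking by the Youden index
#' (sens + spec - 1); ties break deterministically by ascending truth-table
#' encoding.
#'
#' @param tallies a `chant_score` data frame or n x 4 tally matrix.
#' @param reference_labels logical reference; both classes required.
#' @return data frame of class `alpha_test` sorted best-first: `encoding`,
#'   `sens`, `spec`, `youden`, `is_verbal` (flags the canonical verbal rule).
#' @export
alpha_test_rules <- function(tallies, reference_labels) {
  reference_labels <- require_both_classes(reference_labels)
  m <- tally_matrix(tallies)
  if (nrow(m) != length(reference_labels))
    stop("tallies and reference labels differ in length")
  idx <- (m[, 1] == 2L) + 2L * (m[, 2] == 2L) + 4L * (m[, 3] == 2L) +
    8L * (m[, 4] == 2L)
  cell_pos <- tabulate(idx[reference_labels] + 1L, nbins = 16L)
  cell_neg <- tabulate(idx[!reference_labels] + 1L, nbins = 16L)
  npos <- sum(cell_pos); nneg <- sum(cell_neg)
  enc <- monotone_rule_encodings()
  tt <- vapply(enc, rule_truth_table, logical(16))  # 16 x 166
  sens <- as.numeric(cell_pos %*% tt) / npos
  spec <- as.numeric(cell_neg %*% (!tt)) / nneg
  out <- data.frame(encoding = enc, sens = sens, spec = spec,
                    youden = sens + spec - 1,
                    is_verbal = enc == verbal_rule_encoding())
  out <- out[order(-out$youden, out$encoding), ]
  rownames(out) <- NULL
  class(out) <- c("alpha_test", "data.frame")
  out
}

#' @export
print.alpha_test <- function(x, n = 10, ...) {
  cat("Alpha test over", nrow(x), "monotone combination rules (best first)\n")
  print(utils::head(as.data.frame(x), n), digits = 3, row.names = FALSE)
  v <- which(x$is_verbal)
  cat(sprintf("verbal rule ranks %d/%d (sens %.3f, spec %.3f)\n",
              v, nrow(x), x$sens[v], x$spec[v]))
  invisible(x)
}
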