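# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: pair loops instead of rank formulas, explicit sums of
# squares instead of anova(), hand-built midranks instead of cor().

# concordance probability by explicit pair counting (ties = 1/2)
oracle_auc <- function(values, labels, higher_abnormal = TRUE) {
  x <- if (higher_abnormal) values else -values
  pos <- x[labels]; neg <- x[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# midranks built by hand
oracle_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman rho as Pearson correlation of hand-built midranks
oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# classical eta-squared by explicit sums of squares
oracle_eta2 <- function(y, g) {
  grand <- mean(y)
  ss_b <- 0; ss_w <- 0
  for (lev in unique(g)) {
    yi <- y[g == lev]
    ss_b <- ss_b + length(yi) * (mean(yi) - grand)^2
    ss_w <- ss_w + sum((yi - mean(yi))^2)
  }
  ss_b / (ss_b + ss_w)
}

# truth-table evaluation of the verbal combination rule
oracle_verbal <- function(p, n, v, r) {
  (p == 2 || v == 2) && (n == 2 || r == 2)
}

# all 81 tally quadruples
all_tally_quadruples <- function() {
  as.matrix(expand.grid(pain_tally = 0:2, numb_tally = 0:2,
                        vib_tally = 0:2, reflex_tally = 0:2))
}

# a small overlapping two-class sample for curve machinery tests
make_overlap_sample <- function(n = 200, seed = 42, prevalence = 0.5,
                                shift = 1.5) {
  set.seed(seed)
  lab <- seq_len(n) <= round(n * prevalence)
  x <- rnorm(n, mean = ifelse(lab, shift, 0))
  list(values = x, labels = lab)
}

# compact London-profile generator settings (validation-cohort conditions)
london_config <- function(n, seed) {
  cohort_config(n_patients = n, prevalence = 0.43, severity_shift = 1.7,
                seed = seed)
}
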