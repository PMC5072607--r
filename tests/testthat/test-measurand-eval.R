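test_that("confusion tables respect orientation and inclusive cutoffs", {
  m <- oriented_measurand(c(1, 2, 9, 10), "higher_abnormal")
  ct <- confusion_at_cutoff(m, c(FALSE, FALSE, TRUE, TRUE), 5)
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]), c(tp = 2, fp = 0, fn = 0, tn = 2))

  # timed vibration: shorter is abnormal, boundary inclusive on the low side
  v <- oriented_measurand(c(20, 10), "lower_abnormal", "vibration")
  ct <- confusion_at_cutoff(v, c(FALSE, TRUE), 13.2)
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]), c(tp = 1, fp = 0, fn = 0, tn = 1))
  ct <- confusion_at_cutoff(v, c(FALSE, TRUE), 10)  # boundary value counts
  expect_equal(ct$tp, 1)

  ct <- confusion_at_cutoff(m, c(FALSE, FALSE, FALSE, FALSE), 5)
  expect_equal(ct$tp + ct$fn, 0)
})

test_that("empirical AUC equals the pair-counting oracle and handles ties", {
  m <- oriented_measurand(c(1, 2, 2, 3), "higher_abnormal")
  lab <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(empirical_roc(m, lab)$auc, 0.875)

  m2 <- oriented_measurand(c(1, 2, 9, 10), "higher_abnormal")
  expect_equal(empirical_roc(m2, c(FALSE, FALSE, TRUE, TRUE))$auc, 1.0)

  expect_error(empirical_roc(m2, rep(TRUE, 4)), "both classes")

  # exact oracle agreement on tied, discrete data (both orientations)
  set.seed(7)
  for (rep in 1:5) {
    x <- sample(0:8, 120, replace = TRUE)
    lab <- runif(120) < plogis((x - 4) / 2)
    if (!any(lab) || all(lab)) next
    mh <- oriented_measurand(x, "higher_abnormal")
    expect_equal(empirical_roc(mh, lab)$auc, oracle_auc(x, lab, TRUE))
    ml <- oriented_measurand(x, "lower_abnormal")
    expect_equal(empirical_roc(ml, lab)$auc, oracle_auc(x, lab, FALSE))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  x <- rnorm(150) + rep(c(0, 1.2), c(90, 60))
  lab <- rep(c(FALSE, TRUE), c(90, 60))
  ours <- empirical_roc(oriented_measurand(x, "higher_abnormal"), lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, x, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("an uninformative measurand sits on the chance line", {
  set.seed(13)
  x <- rnorm(2000)
  lab <- rep(c(TRUE, FALSE), 1000)
  auc <- empirical_roc(oriented_measurand(x, "higher_abnormal"), lab)$auc
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("sensitivity and specificity are monotone across cutoffs", {
  s <- make_overlap_sample(n = 150, seed = 19)
  m <- oriented_measurand(s$values, "higher_abnormal")
  cuts <- sort(unique(s$values))
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    ct <- confusion_at_cutoff(m, s$labels, cuts[i])
    sens[i] <- ct$tp / (ct$tp + ct$fn)
    spec[i] <- ct$tn / (ct$tn + ct$fp)
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("crossover cutoffs match hand-computed and symmetric cases", {
  # two equal-variance symmetric classes cross at the midpoint
  set.seed(23)
  n <- 4000
  lab <- rep(c(FALSE, TRUE), each = n / 2)
  x <- rnorm(n, mean = ifelse(lab, 1, -1))
  m <- oriented_measurand(x, "higher_abnormal")
  expect_lt(abs(crossover_cutoff(m, lab, "sens_spec")), 0.1)

  # step-curve hand evaluation: sens = spec = 1 over the gap (2, 3)
  m4 <- oriented_measurand(c(1, 2, 3, 4), "higher_abnormal")
  lab4 <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(crossover_cutoff(m4, lab4, "sens_spec"), 2.5)
  expect_equal(crossover_cutoff(m4, lab4, "ppv_npv"), 2.5)
  expect_equal(crossover_cutoff(m4, lab4, "lr"), 2.5)

  # at prevalence 1/2 the predictive-value crossover coincides with the
  # sensitivity/specificity crossover (same bracketing interval)
  s <- make_overlap_sample(n = 200, seed = 29, prevalence = 0.5)
  m <- oriented_measurand(s$values, "higher_abnormal")
  c_ss <- crossover_cutoff(m, s$labels, "sens_spec")
  c_pn <- crossover_cutoff(m, s$labels, "ppv_npv")
  max_gap <- max(diff(sort(unique(s$values))))
  expect_lt(abs(c_ss - c_pn), max_gap)

  expect_error(crossover_cutoff(m, rep(TRUE, 200), "sens_spec"),
               "both classes")
})

test_that("minimum-cost cutoff behaves at the corners and under FN weighting", {
  m4 <- oriented_measurand(c(1, 2, 3, 4), "higher_abnormal")
  lab4 <- c(FALSE, FALSE, TRUE, TRUE)
  mc <- min_cost_cutoff(m4, lab4)
  expect_equal(mc$cost, 0)
  expect_true(mc$cutoff > 2 && mc$cutoff <= 3)
  expect_true(all(mc$cost_curve$cost >= 0 & mc$cost_curve$cost <= 1))

  # doubling the miss cost never makes the cutoff more restrictive:
  # verified against a brute-force scan of the cost at every cutoff
  s <- make_overlap_sample(n = 300, seed = 37)
  m <- oriented_measurand(s$values, "higher_abnormal")
  c_eq <- min_cost_cutoff(m, s$labels, cost_weights(c_fn = 1))$cutoff
  c_fn2 <- min_cost_cutoff(m, s$labels, cost_weights(c_fn = 2))$cutoff
  expect_lte(c_fn2, c_eq)
  brute <- function(cfp, cfn) {
    cuts <- sort(unique(s$values))
    cost <- vapply(cuts, function(cc) {
      ct <- confusion_at_cutoff(m, s$labels, cc)
      (cfp * ct$fp + cfn * ct$fn) /
        (cfp * sum(!s$labels) + cfn * sum(s$labels))
    }, numeric(1))
    min(cost)
  }
  expect_equal(min_cost_cutoff(m, s$labels, cost_weights(c_fn = 2))$cost,
               brute(1, 2), tolerance = 1e-12)

  # permutation invariance
  set.seed(41)
  p <- sample(length(s$values))
  mp <- oriented_measurand(s$values[p], "higher_abnormal")
  mcp <- min_cost_cutoff(mp, s$labels[p])
  expect_equal(mcp$cost, min_cost_cutoff(m, s$labels)$cost)
  expect_equal(mcp$cutoff, min_cost_cutoff(m, s$labels)$cutoff)
})

test_that("geometric-mean consensus obeys mean properties and the offset rule", {
  expect_equal(geometric_mean_cutoff(c(3, 3, 3, 3)), 3)
  expect_equal(geometric_mean_cutoff(c(2, 8, 4, 4)), 4)
  set.seed(43)
  for (i in 1:20) {
    cs <- runif(4, 0.5, 20)
    g <- geometric_mean_cutoff(cs)
    expect_gte(g, min(cs)); expect_lte(g, max(cs))
  }
  expect_error(geometric_mean_cutoff(c(0, 1, 2, 3)), "offset")
  # the offset transform handles zero-containing scales and reduces to the
  # plain geometric mean in the limit of equal cutoffs
  expect_equal(geometric_mean_cutoff(c(2, 2, 2, 2), offset = 1), 2)
  g <- geometric_mean_cutoff(c(0, 1, 2, 3), offset = 1)
  expect_gte(g, 0); expect_lte(g, 3)
})

test_that("partial eta-squared equals the explicit sums-of-squares oracle", {
  y <- c(0, 0, 1, 1, 1, 1, 2, 2)
  g <- rep(c("a", "b"), each = 4)
  es <- partial_eta_squared(y, g)
  expect_equal(es$partial_eta_squared, oracle_eta2(y, g))
  expect_equal(es$partial_eta_squared, 0.5)
  expect_equal(es$ss_effect, 2); expect_equal(es$ss_error, 2)

  # identical within groups, different between: eta2 = 1
  expect_equal(partial_eta_squared(c(1, 1, 5, 5),
                                   c("a", "a", "b", "b"))$partial_eta_squared, 1)

  # independence: eta2 near 0
  set.seed(47)
  expect_lt(partial_eta_squared(rnorm(2000),
                                rep(c("a", "b"), 1000))$partial_eta_squared,
            0.01)

  # random fixtures, both orderings
  for (i in 1:5) {
    y <- rnorm(60) + rep(c(0, 0.8, 1.5), each = 20)
    g <- rep(c("a", "b", "c"), each = 20)
    expect_equal(partial_eta_squared(y, g)$partial_eta_squared,
                 oracle_eta2(y, g))
  }

  expect_error(partial_eta_squared(1:4, rep("a", 4)), "2 non-empty groups")

  # with a covariate the factor effect is partialled after the covariate
  set.seed(49)
  x <- rnorm(100); g <- rep(c("a", "b"), 50)
  y <- 2 * x + (g == "b") + rnorm(100)
  es_cov <- partial_eta_squared(y, g, covariates = x)
  a <- anova(lm(y ~ x + g))
  expect_equal(es_cov$partial_eta_squared,
               a["g", "Sum Sq"] / (a["g", "Sum Sq"] + a["Residuals", "Sum Sq"]))
})

test_that("a perfect measurand yields a degenerate-but-correct evaluation", {
  m <- oriented_measurand(c(1, 1.5, 2, 7, 8, 9), "higher_abnormal", "perfect")
  lab <- rep(c(FALSE, TRUE), each = 3)
  e <- evaluate_measurand(m, lab)
  expect_equal(e$auc, 1)
  expect_equal(e$min_cost, 0)
  expect_true(all(e$cutoffs > 2 & e$cutoffs <= 7))
  expect_gte(e$geometric_mean, min(e$cutoffs))
  expect_lte(e$geometric_mean, max(e$cutoffs))
})

test_that("the calibrated feet-pain item reproduces its implied AUC", {
  # the equal-variance generator calibrated to (sens, spec) implies
  # AUC = pnorm((qnorm(sens) + qnorm(spec)) / sqrt(2))
  co <- generate_cohort(cohort_config(n_patients = 4000, seed = 53))
  dev_row <- develop_chant(co)$table
  implied <- pnorm((qnorm(0.74) + qnorm(0.81)) / sqrt(2))
  expect_lt(abs(dev_row$auc[dev_row$measurand == "feet_pain"] - implied), 0.03)
})

test_that("the development report round-trips through CSV", {
  co <- generate_cohort(cohort_config(n_patients = 300, seed = 59))
  dev <- develop_chant(co)
  f <- tempfile(fileext = ".csv")
  write_table1_report(dev, f)
  back <- read_table1_report(f)
  expect_equal(back$auc, dev$table$auc)
  expect_equal(back$geometric_mean, dev$table$geometric_mean)
  expect_identical(back$measurand, dev$table$measurand)
  unlink(f)
})
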