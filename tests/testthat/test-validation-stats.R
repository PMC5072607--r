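test_that("accuracy metrics reproduce the printed worked examples", {
  # internal validation cohort: 10/3/0/17
  m <- diagnostic_metrics(confusion_table(tp = 10, fp = 3, fn = 0, tn = 17))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0.85)
  expect_equal(m$ppv, 10 / 13)
  expect_equal(m$npv, 1)
  expect_equal(m$lr_pos, 1 / 0.15)
  expect_equal(m$lr_neg, 0)

  # field-test cohort: 32/1/11/6
  m <- diagnostic_metrics(confusion_table(tp = 32, fp = 1, fn = 11, tn = 6))
  expect_equal(m$sensitivity, 32 / 43, tolerance = 1e-12)
  expect_equal(m$specificity, 6 / 7, tolerance = 1e-12)
  expect_equal(m$ppv, 32 / 33, tolerance = 1e-12)
  expect_equal(m$npv, 6 / 17, tolerance = 1e-12)

  # perfect specificity flags an infinite positive likelihood ratio
  m <- diagnostic_metrics(confusion_table(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_true(is.infinite(m$lr_pos))

  expect_error(diagnostic_metrics(confusion_table(0, 3, 0, 17)),
               "sensitivity undefined")
  expect_error(diagnostic_metrics(confusion_table(10, 0, 2, 0)),
               "specificity undefined")
  expect_warning(diagnostic_metrics(confusion_table(0, 0, 5, 5)),
                 "PPV undefined")
})

test_that("post-test probability follows exact odds arithmetic", {
  expect_equal(fagan_posttest(0.43, 6.67), 0.834, tolerance = 5e-4)
  expect_equal(fagan_posttest(0.37, 1.0), 0.37)
  expect_equal(fagan_posttest(0.66, 5.29), 0.911, tolerance = 5e-4)
  expect_error(fagan_posttest(0, 2), "inside")
  expect_error(fagan_posttest(0.4, 0), "positive")

  # round trip: applying 1/LR recovers the pre-test probability
  set.seed(83)
  for (i in 1:20) {
    p <- runif(1, 0.01, 0.99); lr <- exp(rnorm(1))
    expect_equal(fagan_posttest(fagan_posttest(p, lr), 1 / lr), p,
                 tolerance = 1e-12)
  }
})

test_that("PPV equals the post-test probability at pre-test = prevalence", {
  set.seed(89)
  for (i in 1:25) {
    cells <- rmultinom(1, 60, prob = runif(4, 0.05, 1))
    ct <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    if (ct$tp + ct$fn == 0 || ct$fp + ct$tn == 0 || ct$tp + ct$fp == 0) next
    m <- suppressWarnings(diagnostic_metrics(ct))
    if (!is.finite(m$lr_pos) || m$lr_pos == 0) next
    expect_equal(fagan_posttest(m$prevalence, m$lr_pos), m$ppv,
                 tolerance = 1e-12)
  }
})

test_that("Cronbach's alpha matches its closed forms", {
  # identical columns: alpha = 1
  x <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  expect_equal(cronbach_alpha(x), 1)

  # two standardised items with correlation r: alpha = 2r/(1+r)
  set.seed(97)
  z1 <- scale(rnorm(400)); z2 <- scale(0.5 * z1 + rnorm(400))
  r <- cor(z1, z2)[1]
  expect_equal(cronbach_alpha(cbind(z1, z2)), 2 * r / (1 + r),
               tolerance = 1e-12)

  # k standardised exchangeable items: alpha = k rbar / (1 + (k-1) rbar)
  f <- rnorm(300)
  m <- sapply(1:4, function(i) as.numeric(scale(f + rnorm(300))))
  rbar <- mean(cor(m)[lower.tri(cor(m))])
  expect_equal(cronbach_alpha(m), 4 * rbar / (1 + 3 * rbar),
               tolerance = 1e-12)

  expect_error(cronbach_alpha(cbind(c(1, 1), c(2, 2))), "variance")
})

test_that("generator settings for the validation profile reproduce the reported internal consistency", {
  co <- generate_cohort(london_config(n = 1000, seed = 1))
  ta <- score_items(co)
  bin <- cbind(pain = ta$pain_tally == 2, numb = ta$numb_tally == 2,
               vib = ta$vib_tally == 2, reflex = ta$reflex_tally == 2) * 1L
  expect_lt(abs(cronbach_alpha(bin) - 0.88), 0.08)
  # the spec'd pilot-size instance of the same calibration
  co30 <- generate_cohort(london_config(n = 30, seed = 1))
  ta30 <- score_items(co30)
  bin30 <- cbind(ta30$pain_tally == 2, ta30$numb_tally == 2,
                 ta30$vib_tally == 2, ta30$reflex_tally == 2) * 1L
  expect_lt(abs(cronbach_alpha(bin30) - 0.88), 0.08)
})

test_that("item-total correlations equal a hand-built midrank oracle", {
  # 8-patient, 4-item fixture with ties
  m <- rbind(c(0, 1, 0, 2), c(1, 1, 0, 2), c(2, 0, 1, 1), c(0, 0, 0, 0),
             c(2, 2, 1, 0), c(1, 2, 2, 1), c(0, 2, 2, 2), c(2, 1, 1, 1))
  colnames(m) <- paste0("i", 1:4)
  it <- item_total_correlation(m)
  for (j in 1:4) {
    expect_equal(unname(it$per_item[j]),
                 oracle_spearman(m[, j], rowSums(m) - m[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(it$mean, mean(it$per_item))

  # identical items: perfect discrimination
  ident <- cbind(a = 1:6, b = 1:6, c = 1:6)
  expect_equal(unname(item_total_correlation(ident)$per_item), rep(1, 3))

  # an unrelated item decorrelates from the rest
  set.seed(101)
  big <- cbind(f1 <- rnorm(800), f1 + rnorm(800, 0, 0.3),
               f1 + rnorm(800, 0, 0.3), rnorm(800))
  it2 <- item_total_correlation(big)
  expect_lt(abs(it2$per_item[4]), 0.1)

  # a constant item is flagged, not silently zeroed
  expect_warning(item_total_correlation(cbind(a = rep(1, 5), b = 1:5,
                                              c = 5:1)),
                 "undefined")
})

test_that("inter-tester concordance matches the oracle and checks matching", {
  co <- generate_cohort(london_config(n = 60, seed = 2))
  m1 <- side_item_matrix(co)
  expect_equal(unname(inter_tester(m1, m1)),
               rep(1, 8))
  r2 <- generate_rater_pair(co, seed = 3)
  m2 <- side_item_matrix(r2)
  rho <- inter_tester(m1, m2)
  for (j in seq_len(ncol(m1))) {
    if (is.na(rho[j])) next
    expect_equal(unname(rho[j]), oracle_spearman(m1[, j], m2[, j]),
                 tolerance = 1e-12)
  }
  # independent raters decorrelate
  set.seed(103)
  a <- matrix(rnorm(2000), ncol = 2); b <- matrix(rnorm(2000), ncol = 2)
  expect_lt(max(abs(inter_tester(a, b))), 0.1)
  expect_error(inter_tester(m1, m2[, 1:4]), "dimensions")
  m3 <- m2; rownames(m3) <- rev(rownames(m2))
  expect_error(inter_tester(m1, m3), "ids differ")
})

test_that("calibrated rater agreement reaches the reported concordance floor", {
  co <- generate_cohort(london_config(n = 1000, seed = 4))
  r2 <- generate_rater_pair(co, seed = 5)
  rho <- inter_tester(side_item_matrix(co), side_item_matrix(r2))
  expect_true(all(rho >= 0.93))
})

test_that("content validity ratio follows Lawshe's formula", {
  v <- cvr(c(4, 5, 5, 5), 5)
  expect_equal(unname(v$per_item), c(0.6, 1, 1, 1))
  expect_equal(v$mean, 0.9)
  expect_equal(unname(cvr(5, 5)$per_item), 1)
  expect_equal(unname(cvr(1, 4)$per_item), -0.5)
  expect_error(cvr(6, 5), "n_panelists")
  # antisymmetry around n_e = N/2
  for (N in c(4, 5, 8)) for (ne in 0:N) {
    expect_equal(unname(cvr(ne, N)$per_item), -unname(cvr(N - ne, N)$per_item))
  }
})
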