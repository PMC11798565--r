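test_that("crude prevalence is the positive fraction with guarded inputs", {
  expect_equal(crude_prevalence(62, 750), 62 / 750)
  expect_equal(format_prevalence(crude_prevalence(62, 750)), "8.3%")
  expect_equal(crude_prevalence(0, 750), 0)
  expect_equal(crude_prevalence(750, 750), 1)
  expect_error(crude_prevalence(1, 0), "positive")
  expect_error(crude_prevalence(-1, 10))
  expect_error(crude_prevalence(11, 10))
})

test_that("expected false positives follow the confuser-mix formula", {
  fp <- expected_false_positives(misclassification_profile(), 750)
  expect_equal(fp$n_fp_real, (0.80 * 0.031 + 0.079 * 0.554 + 0.004 * 0.594) * 750)
  expect_equal(fp$n_fp_real, 53.2065, tolerance = 1e-10)
  expect_equal(fp$n_fp, 53L)
  # unrounded per-class components are reported alongside
  comp <- fp$components[[1]]
  expect_equal(comp$expected, c(18.6, 32.8245, 1.782), tolerance = 1e-10)
  expect_equal(sum(comp$expected), fp$n_fp_real)

  zero <- expected_false_positives(
    misclassification_profile(r_healthy = 0, r_mdd = 0, r_bd = 0), 750)
  expect_equal(zero$n_fp_real, 0)
  expect_equal(zero$n_fp, 0L)

  ten <- expected_false_positives(
    misclassification_profile(p_healthy = 1, r_healthy = 0.1,
                              p_mdd = 0, p_bd = 0), 100)
  expect_equal(ten$n_fp_real, 10)
  expect_equal(ten$n_fp, 10L)
})

test_that("count back-calculation applies the TP:FN ratio with clamping", {
  cc <- correct_counts(62, 53, 46 / 15)
  expect_equal(cc$n_tp, 9)
  expect_equal(cc$n_fn_real, 9 * 15 / 46, tolerance = 1e-12)
  expect_equal(cc$n_fn_real, 2.935, tolerance = 1e-3)
  expect_equal(cc$n_fn, 3L)

  expect_equal(correct_counts(100, 8, 2)$n_tp, 92)
  expect_equal(correct_counts(100, 8, 2)$n_fn, 46L)

  boundary <- correct_counts(10, 10, 3)
  expect_equal(boundary$n_tp, 0)
  expect_equal(boundary$n_fn, 0L)
  expect_warning(correct_counts(5, 10, 3), "clamped")
  expect_error(correct_counts(10, 5, 0), "positive")
})

test_that("the full correction reproduces the worked example", {
  cx <- correct_prevalence(62, 750)
  expect_equal(cx$n_fp, 53L)
  expect_equal(cx$n_tp, 9)
  expect_equal(cx$n_fn, 3L)
  expect_equal(cx$n_adjusted, 12)
  expect_equal(cx$adjusted_prevalence, 0.016)
  expect_equal(format_prevalence(cx$adjusted_prevalence), "1.6%")
  expect_equal(adjusted_prevalence(cx), 0.016)

  m <- confusion_table(cx)
  expect_equal(as.numeric(m), c(9, 3, 53, 685))
  expect_equal(sum(m), 750)

  g <- glance(cx)
  expect_equal(g$n_crude, 62)
  expect_equal(g$adjusted_prevalence, 0.016)
  td <- tidy(cx)
  expect_equal(td$value[td$quantity == "n_fp_real"], 53.2065,
               tolerance = 1e-10)
})

test_that("derived confusion tables keep row/column arithmetic", {
  # engineered profile: n_fp = 8 at n = 1000, ratio 2 -> tp 92, fn 46
  prof <- misclassification_profile(p_healthy = 1, r_healthy = 0.008,
                                    p_mdd = 0, p_bd = 0, tp_fn_ratio = 2)
  cx <- correct_prevalence(100, 1000, prof)
  expect_equal(cx$adjusted_prevalence, (100 - 8 + 46) / 1000)
  m <- confusion_table(cx)
  expect_equal(as.numeric(m), c(92, 46, 8, 854))
  expect_equal(sum(m), 1000)
})

test_that("with no confusers and an infinite TP:FN ratio the correction is the identity", {
  prof <- misclassification_profile(r_healthy = 0, r_mdd = 0, r_bd = 0,
                                    tp_fn_ratio = 1e12)
  for (k in c(0, 5, 62, 750)) {
    cx <- correct_prevalence(k, 750, prof)
    expect_identical(cx$adjusted_prevalence, cx$crude_prevalence)
  }
})

test_that("adjusted prevalence is monotone in crude count and confuser rates", {
  prof <- misclassification_profile()
  adj <- vapply(50:80, function(k)
    suppressWarnings(correct_prevalence(k, 750, prof))$adjusted_prevalence,
    numeric(1))
  expect_true(all(diff(adj) >= 0))

  for (r in c("r_healthy", "r_mdd", "r_bd")) {
    args <- list(62, 750)
    vals <- vapply(seq(0, 0.6, by = 0.06), function(rate) {
      a <- list(p_healthy = 0.80, r_healthy = 0.031, p_mdd = 0.079,
                r_mdd = 0.554, p_bd = 0.004, r_bd = 0.594)
      a[[r]] <- rate
      suppressWarnings(
        correct_prevalence(62, 750, do.call(misclassification_profile, a))
      )$adjusted_prevalence
    }, numeric(1))
    expect_true(all(diff(vals) <= 0))
  }
})

test_that("confusion cells are non-negative and sum to n for random valid inputs", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(100:2000, 1)
    prof <- misclassification_profile(
      p_healthy = 0.7, r_healthy = runif(1, 0, 0.05),
      p_mdd = 0.2, r_mdd = runif(1, 0, 0.6),
      p_bd = 0.05, r_bd = runif(1, 0, 0.6),
      tp_fn_ratio = runif(1, 0.5, 10)
    )
    fp_max <- expected_false_positives(prof, n)$n_fp
    n_crude <- sample(seq(fp_max, floor(n / (1 + 1 / prof$tp_fn_ratio))), 1)
    cx <- suppressWarnings(correct_prevalence(n_crude, n, prof))
    m <- suppressWarnings(confusion_table(cx))
    expect_true(all(m >= 0))
    expect_equal(sum(m), n)
    expect_gte(cx$adjusted_prevalence, 0)
    expect_lte(cx$adjusted_prevalence, 1)
  }
})

test_that("profiles round-trip through YAML and validate their fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  prof <- misclassification_profile()
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$p, prof$p)
  expect_equal(back$r, prof$r)
  expect_equal(back$tp_fn_ratio, prof$tp_fn_ratio)
  expect_error(misclassification_profile(r_mdd = 1.2), "rates")
  expect_error(misclassification_profile(tp_fn_ratio = -1), "positive")
  expect_error(misclassification_profile(p_healthy = 0.9, p_mdd = 0.2),
               "sum")
})
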