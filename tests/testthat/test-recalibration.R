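test_that("the correction factor is the truncated integer percent", {
  expect_equal(correction_factor_from_percent(8.49)$f_pct, 8L)
  expect_equal(correction_factor_from_percent(7.999)$f_pct, 7L)
  expect_equal(correction_factor_from_percent(-0.4)$f_pct, 0L)
  expect_error(correction_factor_from_percent(-3), "0-50")
  expect_error(correction_factor_from_percent(60), "0-50")

  tp <- toy_tape()
  co <- cohort_with_pct_diff(c(60, 80, 120), c(9, 8, 10), tp)
  cf <- estimate_correction_factor(co, tp)
  expect_equal(cf$raw_mean_pct, 9)
  expect_equal(cf$f_pct, 9L)
  expect_equal(cf$f, 0.09)
  expect_error(estimate_correction_factor(co[0, ], tp), "empty")

  zero <- cohort_with_pct_diff(c(60, 80, 120), c(0, 0, 0), tp)
  expect_equal(estimate_correction_factor(zero, tp)$f_pct, 0L)
})

test_that("apply_correction scales weight ranges and preserves structure", {
  out <- apply_correction("broselow_2007b", 0.08)
  expect_equal(out$zones$weight_lo[1], 2.76)
  expect_equal(out$zones$weight_hi[1], 4.6)
  expect_equal(out$zones$height_lo, builtin_tape("broselow_2007b")$zones$height_lo)

  same <- apply_correction("broselow_2007b", 0)
  expect_equal(same$zones, builtin_tape("broselow_2007b")$zones)

  for (f in seq(0, 0.4, by = 0.05)) {
    z <- apply_correction("ipwet", f)$zones
    expect_true(all(diff(z$weight_lo) > 0))
    expect_true(all(diff(z$weight_hi) > 0))
  }
  expect_error(apply_correction("ipwet", 1), "\\[0, 1\\)")

  # a zero-bias cohort yields f = 0 and a correction that is the identity
  zero <- generate_cohort(cohort_config(n = 200, seed = 4, bias_mean = 0, bias_sd = 0))
  cf <- estimate_correction_factor(zero, "broselow_2007b")
  expect_equal(cf$f_pct, 0L)
  expect_equal(apply_correction("broselow_2007b", cf)$zones,
               builtin_tape("broselow_2007b")$zones)
})

test_that("rebin_heights bridges per-zone confidence intervals into a partition", {
  tp <- tape_spec("two", data.frame(
    name = c("a", "b"), height_lo = c(50, 65), height_hi = c(65, 150),
    weight_lo = c(4, 16), weight_hi = c(16, 36)))
  # tight clusters at 60 and 70 with vanishing spread: the bridged boundary
  # is the midpoint 65 and the outer bounds are the observed extremes
  co <- make_cohort(c(rep(60, 4), rep(70, 4)), rep(10, 8))
  co$height_cm <- co$height_cm + rep(c(-0.001, 0.001), 4)
  rb <- rebin_heights(co, tp)
  expect_equal(rb$intervals$height_hi[1], 65, tolerance = 1e-3)
  expect_equal(rb$intervals$height_lo[1], 59)  # floor of min height
  expect_equal(rb$intervals$height_hi[2], 71)  # ceiling of max height
  expect_equal(rb$audit$zone_ci$n, c(4, 4))

  lone <- make_cohort(c(60, 61, 70), c(10, 10, 10))
  expect_error(rebin_heights(lone[1:2, ], tp), "'b' has 0")
  expect_error(rebin_heights(lone, tp), "'b' has 1")
})

test_that("re-binned intervals are contiguous and ordered on generated cohorts", {
  for (s in 1:20) {
    co <- generate_cohort(cohort_config(n = 600, seed = 100 + s))
    rb <- rebin_heights(co, "broselow_2007b")
    iv <- rb$intervals
    expect_equal(iv$height_hi[-9], iv$height_lo[-1])
    expect_true(all(iv$height_hi > iv$height_lo))
    expect_true(all(diff(rb$audit$boundaries) > 0))
  }
})

test_that("the height-weight regression recovers exact and noisy fits", {
  h <- seq(50, 140, length.out = 20)
  exact <- make_cohort(h, 0.2 * h - 5)
  fit <- suppressWarnings(fit_height_weight_regression(exact))
  expect_equal(fit$slope, 0.2, tolerance = 1e-10)
  expect_equal(fit$intercept, -5, tolerance = 1e-8)
  expect_equal(fit$r2, 1)
  expect_error(fit_height_weight_regression(exact[1:2, ]), "n >= 3")
  expect_error(fit_height_weight_regression(make_cohort(rep(100, 5), 1:5)),
               "zero variance")

  co <- generate_cohort(cohort_config(n = 4000, seed = 6))
  expect_gt(fit_height_weight_regression(co)$r2, 0.85)
  # the cubic fit tracks the convex weight-for-height curve more closely
  expect_gt(fit_height_weight_regression(co, degree = 3)$r2,
            fit_height_weight_regression(co)$r2)
})

test_that("derive_weight_ranges snaps boundary weights onto the half-kg grid", {
  fit <- structure(list(coefficients = c(-15, 0.30), degree = 1L,
                        intercept = -15, slope = 0.30, r2 = 1, n = 100),
                   class = "hw_fit")
  iv <- tibble::tibble(zone = c("a", "b"), height_lo = c(55, 65),
                       height_hi = c(65, 80))
  out <- derive_weight_ranges(fit, iv)
  expect_equal(out$audit$pre_rounding, c(1.5, 4.5, 9))
  expect_equal(out$ranges$weight_lo, c(1.5, 4.5))
  expect_equal(out$ranges$weight_hi, c(4.5, 9))
  # contiguity by construction
  expect_equal(out$ranges$weight_hi[1], out$ranges$weight_lo[2])

  neg <- structure(list(coefficients = c(30, -0.1), degree = 1L,
                        intercept = 30, slope = -0.1, r2 = 1, n = 100),
                   class = "hw_fit")
  expect_error(derive_weight_ranges(neg, iv), "slope")
  gap_iv <- tibble::tibble(zone = c("a", "b"), height_lo = c(55, 70),
                           height_hi = c(65, 80))
  expect_error(derive_weight_ranges(fit, gap_iv), "contiguous")
  # zones too narrow for the half-kg grid collapse after snapping
  narrow <- tibble::tibble(zone = c("a", "b", "c"),
                           height_lo = c(55, 55.2, 55.4),
                           height_hi = c(55.2, 55.4, 80))
  expect_error(derive_weight_ranges(fit, narrow), "not strictly increasing")
})

test_that("build_ipwet chains the stages into a valid rebuilt tape", {
  co <- generate_cohort(cohort_config(n = 769, seed = 1))
  res <- build_ipwet(co, "broselow_2007b")
  expect_s3_class(res$new_tape, "tape_spec")
  expect_equal(nrow(res$new_tape$zones), 9)
  expect_equal(res$new_tape$zones$name, builtin_tape("broselow_2007b")$zones$name)
  z <- res$new_tape$zones
  expect_equal(z$height_hi[-9], z$height_lo[-1])
  expect_true(all(diff(z$weight_lo) > 0))
  expect_named(res$audit, c("correction_factor", "rebin_heights",
                            "regression", "weight_ranges"))

  zero <- generate_cohort(cohort_config(n = 769, seed = 2, bias_mean = 0, bias_sd = 0.05))
  expect_equal(build_ipwet(zero, "broselow_2007b")$correction$f_pct, 0L)

  # stage errors carry the stage name
  expect_error(build_ipwet(co[0, ], "broselow_2007b"), "correction_factor")
})

test_that("estimated factors concentrate on the truncated injected bias", {
  # derivation-sized cohorts: sampling spread of the mean (SE ~ 0.5%)
  # makes the truncated factor land on 8 +/- 1
  f_small <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(n = 769, seed = 400 + s))
    estimate_correction_factor(co, "broselow_2007b")$f_pct
  }, integer(1))
  expect_true(all(f_small %in% c(7L, 8L, 9L)))
  expect_equal(as.integer(names(which.max(table(f_small)))), 8L)

  # interior bias levels away from integer boundaries recover exactly
  for (b in c(0.025, 0.055, 0.125)) {
    f <- vapply(1:5, function(s) {
      co <- generate_cohort(cohort_config(n = 10000, seed = 600 + s, bias_mean = b))
      estimate_correction_factor(co, "broselow_2007b")$f_pct
    }, integer(1))
    expect_true(all(f == trunc(100 * b)))
  }
})

test_that("sample_size_plan reproduces the validation design", {
  plan <- sample_size_plan()
  expect_equal(plan$n_total, plan$n_per_zone * plan$n_zones)
  expect_gte(plan$n_per_zone, 40)
  expect_gte(plan$n_total, 360)
  expect_equal(plan$n_zones, 9L)
  strict <- sample_size_plan(alpha = 0.01)
  expect_gt(strict$n_per_zone, plan$n_per_zone)
  expect_error(sample_size_plan(alpha = 0), "alpha")
  expect_error(sample_size_plan(power = 1.2), "power")
  expect_error(sample_size_plan(baseline_sensitivity = 0.9), "inside")
})

test_that("validate_tape pools confusion counts across cohorts", {
  c1 <- generate_cohort(cohort_config(n = 400, seed = 31))
  c2 <- generate_cohort(cohort_config(n = 200, seed = 32))
  solo <- validate_tape(c1, "broselow_2007b")
  expect_equal(solo$pooled, solo$per_cohort[[1]])
  expect_equal(solo$n_total, 400)

  both <- validate_tape(c1, "broselow_2007b", c2)
  expect_equal(both$n_total, 600)
  expect_length(both$per_cohort, 2)
  conf1 <- confusion_by_zone(c1, "broselow_2007b")
  conf2 <- confusion_by_zone(c2, "broselow_2007b")
  expect_equal(both$pooled_confusion$tp, conf1$tp + conf2$tp)
  expect_equal(both$pooled_sensitivity,
               sum(both$pooled_confusion$tp) /
                 sum(both$pooled_confusion$tp + both$pooled_confusion$fn))

  empty <- validate_tape(c1, "broselow_2007b", c2[0, ])
  expect_equal(empty$pooled, solo$pooled)
})

test_that("a low-bias cohort agrees better with ipwet than with the biased base tape", {
  # children drawn around the ipwet weight-for-height relation: the tape
  # whose zones were built for that population should match more often
  sens <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(n = 1000, seed = 700 + s, bias_mean = 0,
                                        reference_tape = "ipwet"))
    on_ipwet <- validate_tape(apply_exclusions(co, "ipwet")$cohort, "ipwet")
    on_base <- validate_tape(apply_exclusions(co, "broselow_2007b")$cohort,
                             "broselow_2007b")
    on_ipwet$pooled_sensitivity - on_base$pooled_sensitivity
  }, numeric(1))
  expect_gt(mean(sens), 0)
  expect_gt(mean(sens > 0), 0.7)
})
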