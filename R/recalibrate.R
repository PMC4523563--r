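#' Estimate the truncated percent correction factor
#'
#' The overall mean directed percent difference of tape-predicted over actual
#' weight, truncated toward zero to an integer percent. The truncated factor
#' is the fraction by which every predicted weight on the tape is reduced.
#'
#' @inheritParams assign_zones
#' @return An object of class `correction_factor`: list with `raw_mean_pct`,
#'   `f_pct` (integer percent) and `f` (`f_pct / 100`).
#' @examples
#' # a raw mean overestimate of 8.49% truncates to an 8% factor
#' correction_factor_from_percent(8.49)
#' @export
estimate_correction_factor <- function(cohort, tape) {
  if (nrow(cohort) == 0) abort_usage("cohort is empty")
  tape <- .as_tape(tape)
  b <- predicted_weight(cohort$height_cm, tape)
  correction_factor_from_percent(mean(percent_difference(b, cohort$weight_kg)))
}

#' @rdname estimate_correction_factor
#' @param raw_mean_pct Overall mean percent difference (e.g. 8.49).
#' @export
correction_factor_from_percent <- function(raw_mean_pct) {
  if (!is_scalar_number(raw_mean_pct)) {
    abort_usage("`raw_mean_pct` must be a single number")
  }
  f_pct <- trunc(raw_mean_pct)
  if (f_pct < 0 || f_pct > 50) {
    abort_validation(sprintf(
      "correction factor %d%% outside the supported 0-50%% range (raw mean %.2f%%)",
      f_pct, raw_mean_pct))
  }
  structure(list(raw_mean_pct = raw_mean_pct, f_pct = as.integer(f_pct),
                 f = f_pct / 100),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor> raw mean %.2f%% -> truncated factor %d%%\n",
              x$raw_mean_pct, x$f_pct))
  invisible(x)
}

#' Scale a tape's weight ranges down by a correction fraction
#'
#' Multiplies every zone's weight bounds by `(1 - f)`; heights are unchanged.
#'
#' @inheritParams zone_for_height
#' @param f Correction fraction in `[0, 1)` or a `correction_factor`.
#' @return A [tape_spec] with scaled weight ranges.
#' @export
apply_correction <- function(tape, f) {
  if (inherits(f, "correction_factor")) f <- f$f
  if (!is_scalar_number(f) || f < 0 || f >= 1) {
    abort_usage("`f` must lie in [0, 1)")
  }
  tape <- .as_tape(tape)
  z <- tape$zones
  z$weight_lo <- (1 - f) * z$weight_lo
  z$weight_hi <- (1 - f) * z$weight_hi
  tape_spec(paste0(tape$tape_name, if (f > 0) sprintf("_minus_%g_pct", 100 * f) else ""),
            z)
}

#' Re-bin zone height boundaries from per-zone confidence intervals
#'
#' Step 1: for each height zone, the normal-approximation confidence interval
#' `mean +/- z * sd / sqrt(n)` of the measured heights of the children the
#' tape assigns to the zone. Step 2: because intervals of means leave gaps,
#' each interior boundary is bridged to the midpoint between adjacent zones'
#' interval edges. Step 3: the outer boundaries are extended to the cohort's
#' observed height range, rounded outward to whole cm. The result is a strict
#' ordered partition with one interval per zone.
#'
#' @inheritParams assign_zones
#' @param ci_level Confidence level for the per-zone intervals.
#' @return List with `intervals` (tibble `zone`, `height_lo`, `height_hi`)
#'   and `audit` (per-zone CI table and the bridged boundary vector).
#' @export
rebin_heights <- function(cohort, tape, ci_level = 0.95) {
  stopifnot_scalar_prob(ci_level, "ci_level")
  tape <- .as_tape(tape)
  asg <- assign_zones(cohort, tape)
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci <- dplyr::bind_rows(lapply(tape$zones$name, function(zn) {
    h <- cohort$height_cm[asg$height_zone == zn]
    if (length(h) < 2) {
      abort_validation(sprintf(
        "zone '%s' has %d child(ren); re-binning needs at least 2 per zone",
        zn, length(h)))
    }
    half <- zq * stats::sd(h) / sqrt(length(h))
    tibble::tibble(zone = zn, n = length(h), mean = mean(h), sd = stats::sd(h),
                   ci_lo = mean(h) - half, ci_hi = mean(h) + half)
  }))
  k <- nrow(ci)
  inner <- (ci$ci_hi[-k] + ci$ci_lo[-1]) / 2
  bounds <- c(floor(min(cohort$height_cm)), inner, ceiling(max(cohort$height_cm)))
  if (any(diff(bounds) <= 0)) {
    abort_validation("bridged height boundaries are not strictly increasing")
  }
  intervals <- tibble::tibble(zone = ci$zone,
                              height_lo = bounds[-length(bounds)],
                              height_hi = bounds[-1])
  list(intervals = intervals,
       audit = list(ci_level = ci_level, zone_ci = ci, boundaries = bounds))
}

#' Least-squares regression of weight on height
#'
#' The univariate height-weight model (Gaussian GLM, identity link) used to
#' translate height boundaries into weight boundaries: an ordinary
#' least-squares polynomial of the chosen degree. Degree 1 is the familiar
#' straight-line fit; the recalibration pipeline uses degree 3 by default
#' because weight-for-height is convex over the tape's span and a straight
#' line systematically undershoots both ends (see the methods vignette).
#'
#' @param cohort Cohort data frame.
#' @param degree Polynomial degree (>= 1).
#' @return Object of class `hw_fit`: list with `coefficients` (raw
#'   polynomial, ascending powers), `degree`, `intercept` and `slope` (the
#'   constant and linear coefficients; for `degree = 1` these are the usual
#'   line parameters), `r2`, `n`.
#' @export
fit_height_weight_regression <- function(cohort, degree = 1) {
  if (nrow(cohort) < degree + 2) {
    abort_usage(sprintf("regression of degree %d requires n >= %d", degree, degree + 2))
  }
  if (!is_scalar_number(degree) || degree < 1 || degree != round(degree)) {
    abort_usage("`degree` must be a positive integer")
  }
  if (stats::sd(cohort$height_cm) == 0) {
    abort_validation("degenerate design: heights have zero variance")
  }
  fit <- stats::lm(weight_kg ~ stats::poly(height_cm, degree, raw = TRUE),
                   data = cohort)
  coefs <- unname(stats::coef(fit))
  if (anyNA(coefs)) abort_validation("degenerate design: collinear polynomial basis")
  structure(list(coefficients = coefs, degree = as.integer(degree),
                 intercept = coefs[1], slope = coefs[2],
                 r2 = summary(fit)$r.squared,
                 n = nrow(cohort)),
            class = "hw_fit")
}

# evaluate an hw_fit at heights h
predict_hw <- function(fit, h) {
  drop(outer(h, 0:fit$degree, `^`) %*% fit$coefficients)
}

#' @export
print.hw_fit <- function(x, ...) {
  cat(sprintf("<hw_fit> degree-%d fit, weight(h) = %s (R2 = %.3f, n = %d)\n",
              x$degree,
              paste(sprintf("%.4g h^%d", x$coefficients, 0:x$degree), collapse = " + "),
              x$r2, x$n))
  invisible(x)
}

#' Derive zone weight ranges from a height-weight fit
#'
#' Evaluates the regression curve at every height boundary, then snaps the
#' bounds to the half-kg classification grid: each zone's lower bound is its
#' boundary weight rounded to the nearest 0.5 kg (floored at 0.5 kg so bounds
#' stay positive where the line extrapolates low), and each upper bound is
#' the next zone's lower bound (exclusive; the last zone's upper bound is the
#' snapped top boundary weight). Pre-rounding values are kept in the audit.
#'
#' @param fit An `hw_fit` from [fit_height_weight_regression()].
#' @param height_intervals Tibble `zone`, `height_lo`, `height_hi` forming a
#'   partition (e.g. from [rebin_heights()]).
#' @return List with `ranges` (tibble `zone`, `weight_lo`, `weight_hi`) and
#'   `audit` (pre-rounding boundary weights and whether the floor clamp
#'   fired).
#' @export
derive_weight_ranges <- function(fit, height_intervals) {
  if (!inherits(fit, "hw_fit")) abort_usage("`fit` must come from fit_height_weight_regression()")
  if (fit$degree == 1 && fit$slope <= 0) {
    abort_validation("height-weight slope must be positive to derive weight ranges")
  }
  hi <- height_intervals
  if (any(abs(hi$height_hi[-nrow(hi)] - hi$height_lo[-1]) > 1e-9)) {
    abort_validation("height intervals must form a contiguous partition")
  }
  bounds_h <- c(hi$height_lo, hi$height_hi[nrow(hi)])
  raw_w <- predict_hw(fit, bounds_h)
  if (any(diff(raw_w) <= 0)) {
    abort_validation("fitted weights are not increasing across the height boundaries")
  }
  snapped <- pmax(round_to(raw_w, 0.5), 0.5)
  if (any(diff(snapped) <= 0)) {
    abort_validation("snapped weight bounds are not strictly increasing; zones too narrow for the half-kg grid")
  }
  ranges <- tibble::tibble(zone = hi$zone,
                           weight_lo = snapped[-length(snapped)],
                           weight_hi = snapped[-1])
  list(ranges = ranges,
       audit = list(boundary_heights = bounds_h, pre_rounding = raw_w,
                    clamped_to_floor = any(round_to(raw_w, 0.5) < 0.5)))
}

#' Rebuild a tape for a target population
#'
#' End-to-end recalibration on a derivation cohort: estimate the truncated
#' percent correction factor, re-bin zone heights from per-zone confidence
#' intervals, fit the height-weight regression, and derive the new weight
#' ranges, assembling a complete new tape plus a per-stage audit trail.
#'
#' @inheritParams rebin_heights
#' @param base_tape Tape (or built-in name) being recalibrated.
#' @param degree Polynomial degree of the height-weight regression.
#' @param new_name Name for the rebuilt tape.
#' @return Object of class `recalibration_result`: list with `correction`
#'   (a `correction_factor`), `reference_heights`, `fit`, `new_tape` (a valid
#'   [tape_spec]) and `audit` (one entry per stage).
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 769, seed = 1))
#' res <- build_ipwet(cohort, "broselow_2007b")
#' res$correction
#' @export
build_ipwet <- function(cohort, base_tape, ci_level = 0.95, degree = 3,
                        new_name = "rebuilt") {
  base_tape <- .as_tape(base_tape)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("recalibration stage '%s' failed: %s",
                           name, conditionMessage(e)),
                   class = "pedtape_validation_error", parent = e)
    })
  }
  correction <- stage("correction_factor",
                      estimate_correction_factor(cohort, base_tape))
  rebin <- stage("rebin_heights", rebin_heights(cohort, base_tape, ci_level))
  fit <- stage("regression", fit_height_weight_regression(cohort, degree = degree))
  ranges <- stage("weight_ranges", derive_weight_ranges(fit, rebin$intervals))
  new_tape <- stage("assemble_tape", tape_spec(new_name, tibble::tibble(
    name = rebin$intervals$zone,
    height_lo = rebin$intervals$height_lo,
    height_hi = rebin$intervals$height_hi,
    weight_lo = ranges$ranges$weight_lo,
    weight_hi = ranges$ranges$weight_hi)))
  structure(list(
    correction = correction,
    reference_heights = rebin$intervals,
    fit = fit,
    new_tape = new_tape,
    audit = list(
      correction_factor = list(raw_mean_pct = correction$raw_mean_pct,
                               f_pct = correction$f_pct),
      rebin_heights = rebin$audit,
      regression = unclass(fit),
      weight_ranges = ranges$audit)),
    class = "recalibration_result")
}

#' @export
print.recalibration_result <- function(x, ...) {
  print(x$correction)
  print(x$fit)
  print(x$new_tape)
  invisible(x)
}

#' Validation sample-size plan
#'
#' Reconstructs the per-zone validation sample size as a two-proportion power
#' calculation: the number of children per zone needed to detect an absolute
#' improvement in zone sensitivity of `detectable_improvement` over a
#' baseline of `baseline_sensitivity`, at the given significance level and
#' power, with children restricted to the middle `1 - 2 * overlap_exclusion`
#' band of each zone (the band where zone membership is unambiguous).
#'
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param n_zones Number of color zones.
#' @param overlap_exclusion Fraction of each zone's span excluded on each
#'   side when defining the unambiguous middle band.
#' @param baseline_sensitivity Assumed pre-correction zone sensitivity.
#' @param detectable_improvement Absolute sensitivity improvement to detect.
#' @return Object of class `sample_size_plan`: list with `alpha`, `power`,
#'   `n_per_zone`, `n_zones`, `n_total` (`= n_per_zone * n_zones`).
#' @export
sample_size_plan <- function(alpha = 0.05, power = 0.80, n_zones = 9,
                             overlap_exclusion = 0.20,
                             baseline_sensitivity = 2 / 3,
                             detectable_improvement = 0.25) {
  stopifnot_scalar_prob(alpha, "alpha")
  stopifnot_scalar_prob(power, "power")
  stopifnot_scalar_prob(overlap_exclusion, "overlap_exclusion", 0, 0.5)
  if (!is_scalar_number(n_zones) || n_zones < 1) abort_usage("`n_zones` must be >= 1")
  p2 <- baseline_sensitivity + detectable_improvement
  if (p2 >= 1 || baseline_sensitivity <= 0) {
    abort_usage("sensitivities must stay inside (0, 1)")
  }
  pt <- stats::power.prop.test(p1 = baseline_sensitivity, p2 = p2,
                               sig.level = alpha, power = power)
  n_per_zone <- as.integer(ceiling(pt$n))
  structure(list(alpha = alpha, power = power,
                 overlap_exclusion = overlap_exclusion,
                 baseline_sensitivity = baseline_sensitivity,
                 detectable_improvement = detectable_improvement,
                 n_per_zone = n_per_zone, n_zones = as.integer(n_zones),
                 n_total = n_per_zone * as.integer(n_zones)),
            class = "sample_size_plan")
}

#' @export
print.sample_size_plan <- function(x, ...) {
  cat(sprintf(
    "<sample_size_plan> %d per zone x %d zones = %d (alpha %.2g, power %.2g)\n",
    x$n_per_zone, x$n_zones, x$n_total, x$alpha, x$power))
  invisible(x)
}

# pooled one-vs-rest counts across cohorts (element-wise sum by zone)
pool_confusion <- function(...) {
  tabs <- list(...)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  out <- tabs[[1]]
  for (tb in tabs[-1]) {
    if (!identical(tb$zone, out$zone)) {
      abort_usage("confusion tables must share the same zone set and order")
    }
    for (col in c("tp", "fp", "fn", "tn")) out[[col]] <- out[[col]] + tb[[col]]
  }
  out
}

#' Validate a tape on one or two cohorts
#'
#' Computes per-zone diagnostic metrics for a validation cohort (and
#' optionally a second cohort), plus metrics and the overall zone-match
#' sensitivity from the pooled confusion counts. With a single cohort the
#' pooled metrics equal that cohort's metrics.
#'
#' @inheritParams assign_zones
#' @param cohort2 Optional second cohort pooled with the first.
#' @return List with `per_cohort` (list of metric tibbles), `pooled`
#'   (metric tibble from summed counts), `pooled_confusion`,
#'   `pooled_sensitivity` (summed tp over summed tp + fn) and `n_total`.
#' @export
validate_tape <- function(cohort, tape, cohort2 = NULL) {
  tape <- .as_tape(tape)
  conf1 <- confusion_by_zone(cohort, tape)
  conf2 <- if (!is.null(cohort2) && nrow(cohort2) > 0) {
    confusion_by_zone(cohort2, tape)
  }
  pooled_conf <- pool_confusion(conf1, conf2)
  per_cohort <- lapply(Filter(Negate(is.null), list(conf1, conf2)), zone_metrics)
  list(per_cohort = per_cohort,
       pooled = zone_metrics(pooled_conf),
       pooled_confusion = pooled_conf,
       pooled_sensitivity = sum(pooled_conf$tp) /
         sum(pooled_conf$tp + pooled_conf$fn),
       n_total = nrow(cohort) + if (is.null(cohort2)) 0L else nrow(cohort2))
}
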