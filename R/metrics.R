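#' Directed percent difference between predicted and actual weight
#'
#' `100 * (predicted - actual) / actual`; positive values mean the tape
#' overestimates the child's weight.
#'
#' @param predicted Predicted weight(s), kg.
#' @param actual Actual measured weight(s), kg; must be strictly positive.
#' @return Numeric vector of percent differences.
#' @examples
#' percent_difference(10.85, 10)  # 8.5
#' @export
percent_difference <- function(predicted, actual) {
  if (!is.numeric(actual) || any(is.na(actual)) || any(actual <= 0)) {
    abort_usage("`actual` weights must be positive")
  }
  100 * (predicted - actual) / actual
}

# per-child percent differences for a cohort against a tape, with the
# out-of-range guard shared by the summary functions
.cohort_pct_diff <- function(cohort, tape) {
  asg <- assign_zones(cohort, tape)
  tibble::tibble(zone = asg$height_zone,
                 d = percent_difference(asg$predicted_weight, cohort$weight_kg))
}

#' Per-zone summary of percent differences
#'
#' Mean and sample SD of the directed percent difference per height-derived
#' color zone, plus a `total` row over all children (whose mean equals the
#' n-weighted mean of the zone means). Zones with a single child report
#' `sd_d = 0` and are flagged degenerate.
#'
#' @inheritParams assign_zones
#' @return Tibble with `zone`, `n`, `mean_d`, `sd_d`, `degenerate`; zones in
#'   tape order, `total` last.
#' @export
summarize_percent_difference_by_zone <- function(cohort, tape) {
  tape <- .as_tape(tape)
  pd <- .cohort_pct_diff(cohort, tape)
  one <- function(zone, d) {
    tibble::tibble(zone = zone, n = length(d), mean_d = mean(d),
                   sd_d = if (length(d) > 1) stats::sd(d) else 0,
                   degenerate = length(d) == 1)
  }
  per_zone <- dplyr::bind_rows(lapply(
    intersect(tape$zones$name, unique(pd$zone)),
    function(zn) one(zn, pd$d[pd$zone == zn])))
  dplyr::bind_rows(per_zone, one("total", pd$d))
}

#' Apply a fractional weight correction to a percent-difference summary
#'
#' Scaling every predicted weight by `(1 - f)` transforms each per-child
#' percent difference exactly: `d' = (1 - f) * d - 100 * f`. Means transform
#' the same way and SDs scale by `(1 - f)`.
#'
#' @param summary A tibble from [summarize_percent_difference_by_zone()] (or
#'   any tibble with `mean_d`, `sd_d` columns).
#' @param f Correction fraction in `[0, 1)`, e.g. 0.08 for an 8% reduction.
#' @return The summary with `mean_d`/`sd_d` transformed.
#' @examples
#' s <- tibble::tibble(zone = "pink", n = 93, mean_d = 4.30, sd_d = 12.98)
#' corrected_summary(s, 0.08)  # mean -4.044
#' @export
corrected_summary <- function(summary, f) {
  if (!is_scalar_number(f) || f < 0 || f >= 1) {
    abort_usage("`f` must lie in [0, 1)")
  }
  summary$mean_d <- (1 - f) * summary$mean_d - 100 * f
  summary$sd_d <- (1 - f) * summary$sd_d
  summary
}

#' Within-tolerance accuracy of tape predictions
#'
#' Fraction of children whose predicted weight falls within `tol` (default
#' 10%) of measured weight, overall and per height zone.
#'
#' @inheritParams assign_zones
#' @param tol Relative tolerance (fraction), > 0.
#' @return List with `overall` (a fraction) and `by_zone` (tibble of `zone`,
#'   `n`, `accuracy`).
#' @export
within_tolerance_accuracy <- function(cohort, tape, tol = 0.10) {
  if (!is_scalar_number(tol) || tol <= 0) abort_usage("`tol` must be > 0")
  tape <- .as_tape(tape)
  pd <- .cohort_pct_diff(cohort, tape)
  hit <- abs(pd$d) <= 100 * tol
  by_zone <- dplyr::bind_rows(lapply(
    intersect(tape$zones$name, unique(pd$zone)),
    function(zn) tibble::tibble(zone = zn, n = sum(pd$zone == zn),
                                accuracy = mean(hit[pd$zone == zn]))))
  list(overall = mean(hit), by_zone = by_zone)
}

#' One-vs-rest confusion counts per color zone
#'
#' For each zone, condition positive = the child's actual weight lies in the
#' zone's weight range; test positive = the tape assigns the child's height
#' to the zone. Children whose weight falls outside every weight range (in a
#' gap or beyond the span) are condition-negative for all zones; their count
#' is attached as attribute `n_weight_unclassified`.
#'
#' @inheritParams assign_zones
#' @return Tibble with `zone`, `tp`, `fp`, `fn`, `tn` (each row sums to the
#'   cohort size).
#' @export
confusion_by_zone <- function(cohort, tape) {
  tape <- .as_tape(tape)
  asg <- assign_zones(cohort, tape)
  res <- dplyr::bind_rows(lapply(tape$zones$name, function(zn) {
    test <- asg$height_zone == zn
    cond <- !is.na(asg$weight_zone) & asg$weight_zone == zn
    tibble::tibble(zone = zn,
                   tp = sum(test & cond), fp = sum(test & !cond),
                   fn = sum(!test & cond), tn = sum(!test & !cond))
  }))
  attr(res, "n_weight_unclassified") <- sum(is.na(asg$weight_zone))
  res
}

#' Diagnostic metrics from per-zone confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)` on the 2x2 table, and the Pearson chi-square
#' p-value (1 df, no continuity correction). A metric whose margins are
#' degenerate (empty condition or test margin) is reported as `NA`.
#'
#' @param confusion Tibble from [confusion_by_zone()] (columns `zone`, `tp`,
#'   `fp`, `fn`, `tn`).
#' @return Tibble with `zone`, `n`, `sensitivity`, `specificity`, `kappa`,
#'   `chi2_p`.
#' @export
zone_metrics <- function(confusion) {
  tp <- as.numeric(confusion$tp); fp <- as.numeric(confusion$fp)
  fn <- as.numeric(confusion$fn); tn <- as.numeric(confusion$tn)
  if (any(c(tp, fp, fn, tn) < 0)) abort_usage("confusion counts must be >= 0")
  n <- tp + fp + fn + tn
  se <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  sp <- ifelse(fp + tn > 0, tn / (fp + tn), NA_real_)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  all_margins <- (tp + fn) > 0 & (fp + tn) > 0 & (tp + fp) > 0 & (fn + tn) > 0
  kappa <- ifelse(all_margins & p_e < 1, (p_o - p_e) / (1 - p_e), NA_real_)
  # Pearson X^2 for a 2x2 table, closed form, no Yates correction
  chi2 <- ifelse(all_margins,
                 n * (tp * tn - fp * fn)^2 /
                   ((tp + fp) * (fn + tn) * (tp + fn) * (fp + tn)),
                 NA_real_)
  tibble::tibble(zone = confusion$zone, n = n,
                 sensitivity = se, specificity = sp, kappa = kappa,
                 chi2_p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-zone measured, predicted and corrected weight summary
#'
#' For each height zone: mean/SD of measured weight, tape-predicted weight,
#' and the `(1 - f)`-scaled predicted weight (computed per child, then
#' averaged), with two-sided paired t-tests of measured vs predicted and
#' measured vs corrected. Zones with fewer than two children report `NA`
#' p-values.
#'
#' @inheritParams assign_zones
#' @param f Correction fraction in `[0, 1)`.
#' @return Tibble with `zone`, `n`, `mean_measured`, `sd_measured`,
#'   `mean_predicted`, `sd_predicted`, `mean_corrected`, `sd_corrected`,
#'   `p_uncorrected`, `p_corrected`.
#' @export
zone_weight_table <- function(cohort, tape, f = 0.08) {
  if (!is_scalar_number(f) || f < 0 || f >= 1) {
    abort_usage("`f` must lie in [0, 1)")
  }
  tape <- .as_tape(tape)
  asg <- assign_zones(cohort, tape)
  a <- cohort$weight_kg
  b <- asg$predicted_weight
  dplyr::bind_rows(lapply(intersect(tape$zones$name, unique(asg$height_zone)),
                          function(zn) {
    i <- asg$height_zone == zn
    corr <- (1 - f) * b[i]
    pt <- function(x, y) {
      if (sum(i) < 2 || stats::sd(x - y) == 0) return(NA_real_)
      stats::t.test(x, y, paired = TRUE)$p.value
    }
    tibble::tibble(
      zone = zn, n = sum(i),
      mean_measured = mean(a[i]),
      sd_measured = if (sum(i) > 1) stats::sd(a[i]) else 0,
      mean_predicted = mean(b[i]),
      sd_predicted = if (sum(i) > 1) stats::sd(b[i]) else 0,
      mean_corrected = mean(corr),
      sd_corrected = if (sum(i) > 1) stats::sd(corr) else 0,
      p_uncorrected = pt(a[i], b[i]),
      p_corrected = pt(a[i], corr))
  }))
}

#' Cohort-level descriptive summary
#'
#' Means/SDs of age, height, actual weight and tape-predicted weight; the
#' predicted-minus-actual weight difference; the directed percent difference
#' in both sign conventions; pairwise Pearson correlations
#' (weight~height, weight~predicted, height~predicted, weight~age); and the
#' per-sex R-squared of an ordinary least-squares fit of weight on height.
#'
#' @inheritParams assign_zones
#' @return List with tibbles `moments`, `correlations`, `r2_by_sex`.
#' @export
cohort_summary <- function(cohort, tape) {
  if (nrow(cohort) < 3) abort_usage("cohort_summary requires n >= 3")
  tape <- .as_tape(tape)
  b <- predicted_weight(cohort$height_cm, tape)
  a <- cohort$weight_kg
  d <- percent_difference(b, a)
  ms <- function(name, x) tibble::tibble(statistic = name,
                                         mean = mean(x), sd = stats::sd(x))
  moments <- dplyr::bind_rows(
    ms("age_months", cohort$age_months),
    ms("height_cm", cohort$height_cm),
    ms("weight_kg", a),
    ms("predicted_weight_kg", b),
    ms("weight_diff_kg_predicted_minus_actual", b - a),
    ms("pct_diff_predicted_minus_actual", d),
    ms("pct_diff_actual_minus_predicted", -d),
    ms("abs_pct_diff", abs(d)))
  correlations <- tibble::tibble(
    pair = c("weight~height", "weight~predicted", "height~predicted", "weight~age"),
    r = c(stats::cor(a, cohort$height_cm),
          stats::cor(a, b),
          stats::cor(cohort$height_cm, b),
          stats::cor(a, cohort$age_months)))
  r2_by_sex <- dplyr::bind_rows(lapply(intersect(c("M", "F"), unique(cohort$sex)),
                                       function(s) {
    i <- cohort$sex == s
    r2 <- if (sum(i) >= 3 && stats::sd(cohort$height_cm[i]) > 0) {
      summary(stats::lm(a[i] ~ cohort$height_cm[i]))$r.squared
    } else NA_real_
    tibble::tibble(sex = s, n = sum(i), r2 = r2)
  }))
  list(moments = moments, correlations = correlations, r2_by_sex = r2_by_sex)
}
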