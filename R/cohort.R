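#' Configuration for a synthetic pediatric cohort
#'
#' The generator emulates a clinic-recruited cohort aged 1 month to 12 years
#' with a prescribed height distribution, a prescribed height-weight coupling,
#' and a tunable relative bias of the reference tape's predicted weight over
#' actual weight. Defaults reproduce the derivation-cohort structure the
#' package targets: mean height 96.64 cm (SD 26.06), a tape overestimation of
#' actual weight averaging 8.49% with per-child dispersion giving a percent
#' difference SD near 14.6 and a height-weight correlation near 0.95.
#'
#' @param n Number of children after exclusion filtering.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   config.
#' @param height_mean,height_sd Target mean/SD (cm) of the generated heights
#'   *after* truncation to the reference tape's height range.
#' @param bias_mean Target mean of the per-child relative bias
#'   (predicted - actual)/actual; e.g. 0.0849 for an 8.49% mean overestimate.
#' @param bias_sd Dispersion (SD) of the per-child relative bias.
#' @param sex_ratio Fraction male.
#' @param reference_tape Tape (or built-in name) whose prediction induces the
#'   bias and whose height range truncates the height distribution.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 769, seed = 1,
                          height_mean = 96.64, height_sd = 26.06,
                          bias_mean = 0.0849, bias_sd = 0.1459,
                          sex_ratio = 0.529,
                          reference_tape = "broselow_2007b") {
  if (!is_scalar_number(n) || n < 1 || n != round(n)) {
    abort_usage("`n` must be a positive integer")
  }
  if (!is_scalar_number(seed) || seed != round(seed)) {
    abort_usage("`seed` must be an integer")
  }
  if (!is_scalar_number(height_sd) || height_sd <= 0) {
    abort_usage("`height_sd` must be > 0")
  }
  if (!is_scalar_number(bias_sd) || bias_sd < 0) {
    abort_usage("`bias_sd` must be >= 0")
  }
  if (!is_scalar_number(bias_mean) || bias_mean <= -0.5 || bias_mean >= 0.5) {
    abort_usage("`bias_mean` must lie in (-0.5, 0.5)")
  }
  stopifnot_scalar_prob(sex_ratio, "sex_ratio")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 height_mean = height_mean, height_sd = height_sd,
                 bias_mean = bias_mean, bias_sd = bias_sd,
                 sex_ratio = sex_ratio, reference_tape = reference_tape),
            class = "cohort_config")
}

# Per-height admissible bias window. The weight exclusion (actual > w_max)
# corresponds to delta below B(h)/w_max - 1; rejecting those alone would
# bias E[delta] upward for tall children, so the window is mirrored about
# bias_mean, which preserves the injected mean bias exactly.
.bias_window <- function(b, bias_mean, w_max) {
  d_lo <- pmax(b / w_max - 1, -0.9)
  list(lo = d_lo, hi = 2 * bias_mean - d_lo)
}

# Probability that a child of predicted weight b survives the bias-window
# rejection.
.keep_prob <- function(b, bias_mean, bias_sd, w_max) {
  win <- .bias_window(b, bias_mean, w_max)
  if (bias_sd == 0) {
    as.numeric(win$lo <= bias_mean & bias_mean <= win$hi)
  } else {
    stats::pnorm(win$hi, bias_mean, bias_sd) - stats::pnorm(win$lo, bias_mean, bias_sd)
  }
}

# Parent normal parameters for the height draw. The realized height density
# is proportional to dnorm(h; mu, sigma) * keep_prob(h) on [lo, hi]: plain
# truncation shrinks the SD below its nominal value and the bias-window
# rejection further thins the tallest children, so the parent is solved
# numerically (moments of the weighted density on a fine grid) to make the
# *realized* mean/SD match the configured targets.
.height_parent <- function(config, tape) {
  lo <- min(tape$zones$height_lo)
  hi <- max(tape$zones$height_hi)
  w_max <- max(tape$zones$weight_hi)
  if (config$height_mean <= lo || config$height_mean >= hi) {
    abort_usage(sprintf("height_mean must lie inside the tape range (%g, %g)", lo, hi))
  }
  if (config$height_sd >= (hi - lo) / sqrt(12) * 0.99) {
    abort_usage(sprintf(
      "height_sd %g is not attainable on [%g, %g] (uniform limit %.2f)",
      config$height_sd, lo, hi, (hi - lo) / sqrt(12)))
  }
  h <- seq(lo, hi, length.out = 2001L)
  k <- .keep_prob(predicted_weight(h, tape, round = FALSE),
                  config$bias_mean, config$bias_sd, w_max)
  obj <- function(par) {
    dens <- stats::dnorm(h, par[1], exp(par[2])) * k
    z <- sum(dens)
    m <- sum(dens * h) / z
    s <- sqrt(sum(dens * (h - m)^2) / z)
    (m - config$height_mean)^2 + (s - config$height_sd)^2
  }
  fit <- stats::optim(c(config$height_mean, log(config$height_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-4) {
    abort_validation("could not match the requested truncated height moments")
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Piecewise-linear height-for-age curve (months -> cm) used only to back-fill
# a plausible age from height; anchors span 1 month to 12 years.
.hfa_anchors <- function() {
  list(age = c(1, 12, 60, 144), height = c(54, 75, 109, 149))
}

.age_from_height <- function(h, noise_sd = 4) {
  an <- .hfa_anchors()
  age <- stats::approx(an$height, an$age, xout = h, rule = 2)$y
  # linear extrapolation below/above the anchor heights before clamping
  lo_slope <- diff(an$age[1:2]) / diff(an$height[1:2])
  hi_slope <- diff(an$age[3:4]) / diff(an$height[3:4])
  age[h < an$height[1]] <- an$age[1] + (h[h < an$height[1]] - an$height[1]) * lo_slope
  age[h > an$height[4]] <- an$age[4] + (h[h > an$height[4]] - an$height[4]) * hi_slope
  age <- age + stats::rnorm(length(h), 0, noise_sd)
  pmin(pmax(round(age), 1), 144)
}

#' Generate a synthetic pediatric cohort
#'
#' Heights are drawn from a normal distribution truncated to the reference
#' tape's height range, with parent parameters solved so the truncated sample
#' matches the configured mean/SD. Each child's weight is the tape's
#' predicted weight divided by `(1 + delta)`, where `delta` is the child's
#' relative bias drawn from `N(bias_mean, bias_sd)`; this makes the injected
#' mean tape overestimation equal to `bias_mean` by construction. Ages are
#' back-filled from height through a monotone height-for-age curve plus
#' noise. Heights are recorded to 0.1 cm and weights to 0.1 kg, mirroring
#' measurement resolution. Records violating the exclusion criteria
#' (weight above the tape maximum) are regenerated so exactly `n` survive;
#' because that rejection alone would left-truncate the bias distribution
#' for children near the tape's top weight, each child's admissible bias
#' window is made symmetric about `bias_mean`, so the injected mean bias is
#' preserved exactly under regeneration.
#'
#' @param config A [cohort_config].
#' @return Tibble with columns `child_id`, `age_months`, `sex` (`"M"`/`"F"`),
#'   `height_cm`, `weight_kg`; the config is attached as attribute `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 100, seed = 7))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_usage("`config` must be built with cohort_config()")
  }
  tape <- .as_tape(config$reference_tape)
  lo <- min(tape$zones$height_lo)
  hi <- max(tape$zones$height_hi)
  w_max <- max(tape$zones$weight_hi)
  parent <- .height_parent(config, tape)

  withr::with_seed(config$seed, {
    height <- numeric(0); weight <- numeric(0)
    while (length(height) < config$n) {
      need <- config$n - length(height)
      m <- max(2L * need, 100L)
      h <- stats::rnorm(m, parent$mu, parent$sigma)
      h <- round_to(h[h >= lo & h <= hi], 0.1)
      h <- h[h >= lo & h <= hi]  # guard edge rounding
      if (length(h) == 0) next
      b <- predicted_weight(h, tape)
      delta <- stats::rnorm(length(h), config$bias_mean, config$bias_sd)
      win <- .bias_window(b, config$bias_mean, w_max)
      keep_d <- delta >= win$lo & delta <= win$hi
      a <- round_to(b / (1 + delta), 0.1)
      ok <- keep_d & a > 0 & a <= w_max
      height <- c(height, h[ok])[seq_len(min(config$n, length(height) + sum(ok)))]
      weight <- c(weight, a[ok])[seq_len(length(height))]
    }
    age <- .age_from_height(height)
    sex <- ifelse(stats::runif(config$n) < config$sex_ratio, "M", "F")
    cohort <- tibble::tibble(
      child_id = sprintf("C%05d", seq_len(config$n)),
      age_months = as.integer(age),
      sex = sex,
      height_cm = height,
      weight_kg = weight)
  })
  attr(cohort, "config") <- config
  cohort
}

#' Apply the study exclusion criteria to a cohort
#'
#' Children with height below the tape's first zone or above its last zone,
#' or weighing strictly more than the tape's maximum weight, are removed. The
#' log counts each criterion separately (a child may trip several).
#'
#' @param cohort Cohort data frame.
#' @inheritParams zone_for_height
#' @return List with `cohort` (the kept rows) and `log`, a tibble of
#'   `reason`/`n` counts.
#' @export
apply_exclusions <- function(cohort, tape) {
  tape <- .as_tape(tape)
  lo <- min(tape$zones$height_lo)
  hi <- max(tape$zones$height_hi)
  w_max <- max(tape$zones$weight_hi)
  below <- cohort$height_cm < lo
  above <- cohort$height_cm > hi
  heavy <- cohort$weight_kg > w_max
  keep <- !(below | above | heavy)
  log <- tibble::tibble(
    reason = c("height_below_range", "height_above_range", "weight_above_max"),
    n = c(sum(below), sum(above), sum(heavy)))
  list(cohort = cohort[keep, , drop = FALSE], log = log[log$n > 0, , drop = FALSE])
}

.cohort_columns <- c("child_id", "age_months", "sex", "height_cm", "weight_kg")

#' Read / write a cohort CSV
#'
#' The on-disk schema is a UTF-8 CSV with header
#' `child_id,age_months,sex,height_cm,weight_kg`, sex coded `M`/`F`, one row
#' per child. `read_cohort()` rejects malformed rows with their row number.
#'
#' @param path File path.
#' @return `read_cohort()` returns a cohort tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_io(paste0("cohort file not found: ", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_io(paste0("cannot parse cohort CSV: ",
                                                     conditionMessage(e))))
  missing <- setdiff(.cohort_columns, names(df))
  if (length(missing) > 0) {
    abort_validation(paste0("cohort CSV missing column(s): ",
                            paste(missing, collapse = ", ")))
  }
  df <- df[, .cohort_columns]
  for (col in c("age_months", "height_cm", "weight_kg")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | (col != "age_months" & v <= 0))
    if (length(bad) > 0) {
      abort_validation(sprintf("cohort CSV row %d: invalid value '%s' in column %s",
                               bad[1], df[[col]][bad[1]], col))
    }
    df[[col]] <- v
  }
  df$age_months <- as.integer(round(df$age_months))
  bad_sex <- which(!df$sex %in% c("M", "F"))
  if (length(bad_sex) > 0) {
    abort_validation(sprintf("cohort CSV row %d: sex must be 'M' or 'F'", bad_sex[1]))
  }
  tibble::as_tibble(df)
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, .cohort_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
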