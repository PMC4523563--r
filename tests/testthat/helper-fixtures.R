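# Shared fixtures: small hand-built tapes and cohorts constructed in code.

toy_tape <- function() {
  tape_spec("toy", data.frame(
    name = c("a", "b"),
    height_lo = c(50, 100), height_hi = c(100, 150),
    weight_lo = c(4, 16), weight_hi = c(16, 36)))
}

# cohort with explicit heights/weights; ages/sex are irrelevant filler
make_cohort <- function(height_cm, weight_kg, sex = NULL) {
  n <- length(height_cm)
  tibble::tibble(
    child_id = sprintf("T%03d", seq_len(n)),
    age_months = as.integer(seq(12, 120, length.out = n)),
    sex = if (is.null(sex)) rep(c("M", "F"), length.out = n) else sex,
    height_cm = height_cm,
    weight_kg = weight_kg)
}

# cohort whose percent differences against `tape` are exactly `d_pct`
cohort_with_pct_diff <- function(height_cm, d_pct, tape) {
  b <- predicted_weight(height_cm, tape)
  make_cohort(height_cm, b / (1 + d_pct / 100))
}

# independent brute-force confusion counts: per-child enumeration
oracle_confusion <- function(cohort, tape) {
  hz <- zone_for_height(cohort$height_cm, tape)
  wz <- zone_for_weight(cohort$weight_kg, tape)
  zones <- if (inherits(tape, "tape_spec")) tape$zones$name else builtin_tape(tape)$zones$name
  do.call(rbind, lapply(zones, function(zn) {
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in seq_len(nrow(cohort))) {
      test_pos <- identical(hz[i], zn)
      cond_pos <- !is.na(wz[i]) && wz[i] == zn
      if (test_pos && cond_pos) tp <- tp + 1
      else if (test_pos) fp <- fp + 1
      else if (cond_pos) fn <- fn + 1
      else tn <- tn + 1
    }
    data.frame(zone = zn, tp = tp, fp = fp, fn = fn, tn = tn)
  }))
}

# kappa from first principles: observed agreement minus the agreement
# expected from independent raters with the table's margins
oracle_kappa <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  p_pos_test <- (tp + fp) / n
  p_pos_cond <- (tp + fn) / n
  p_obs <- (tp + tn) / n
  p_exp <- p_pos_test * p_pos_cond + (1 - p_pos_test) * (1 - p_pos_cond)
  (p_obs - p_exp) / (1 - p_exp)
}
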