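#' Construct a color-zone tape specification
#'
#' A tape spec is an ordered partition of supine height (cm) into contiguous
#' color zones, each paired with a weight range (kg). All intervals follow the
#' half-open convention `[lo, hi)`; the final zone is closed at its upper
#' height and weight bound. Height zones must tile their span with no gaps or
#' overlaps. Weight ranges must be weakly increasing across zones but are
#' allowed to leave gaps (the printed Broselow ranges do: 3-5 kg, 6-7 kg, ...);
#' a weight falling in a gap is unclassifiable by weight.
#'
#' @param tape_name Identifier for the tape.
#' @param zones Data frame with columns `name`, `height_lo`, `height_hi`,
#'   `weight_lo`, `weight_hi`, one row per zone, ordered by increasing height.
#' @return An object of class `tape_spec`: a list with `tape_name`,
#'   `interval_convention` (always `"half_open_upper"`) and `zones` (a tibble).
#' @examples
#' tp <- tape_spec("toy", data.frame(
#'   name = c("a", "b"), height_lo = c(50, 100), height_hi = c(100, 150),
#'   weight_lo = c(4, 16), weight_hi = c(16, 36)))
#' zone_for_height(120, tp)
#' @export
tape_spec <- function(tape_name, zones) {
  zones <- tibble::as_tibble(zones)
  tape <- structure(
    list(tape_name = as.character(tape_name)[1],
         interval_convention = "half_open_upper",
         zones = zones),
    class = "tape_spec")
  check_tape(tape)
  tape
}

# Validate every tape_spec invariant; names the offending zone on failure.
check_tape <- function(tape) {
  z <- tape$zones
  required <- c("name", "height_lo", "height_hi", "weight_lo", "weight_hi")
  missing <- setdiff(required, names(z))
  if (length(missing) > 0) {
    abort_validation(paste0("tape spec is missing zone column(s): ",
                            paste(missing, collapse = ", ")))
  }
  if (nrow(z) < 1) abort_validation("tape spec must contain at least one zone")
  if (anyDuplicated(z$name)) abort_validation("zone names must be unique")
  num <- c("height_lo", "height_hi", "weight_lo", "weight_hi")
  for (col in num) {
    v <- z[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      abort_validation(sprintf("zone bounds in `%s` must be finite and positive", col))
    }
  }
  bad <- which(z$height_lo >= z$height_hi)
  if (length(bad) > 0) {
    abort_validation(sprintf("zone '%s': height_lo must be < height_hi", z$name[bad[1]]))
  }
  bad <- which(z$weight_lo >= z$weight_hi)
  if (length(bad) > 0) {
    abort_validation(sprintf("zone '%s': weight_lo must be < weight_hi", z$name[bad[1]]))
  }
  if (nrow(z) > 1) {
    if (any(diff(z$height_lo) <= 0)) {
      abort_validation("zones must be ordered by strictly increasing height_lo")
    }
    gap <- which(abs(z$height_hi[-nrow(z)] - z$height_lo[-1]) > 1e-9)
    if (length(gap) > 0) {
      i <- gap[1]
      abort_validation(sprintf(
        "height zones must be contiguous: '%s' ends at %g but '%s' starts at %g",
        z$name[i], z$height_hi[i], z$name[i + 1], z$height_lo[i + 1]))
    }
    if (any(diff(z$weight_hi) < -1e-9) || any(diff(z$weight_lo) < -1e-9)) {
      abort_validation("zone weight ranges must be weakly increasing across zones")
    }
  }
  invisible(tape)
}

#' @export
print.tape_spec <- function(x, ...) {
  cat(sprintf("<tape_spec '%s'> %d zones, heights %g-%g cm, weights %g-%g kg (%s)\n",
              x$tape_name, nrow(x$zones),
              min(x$zones$height_lo), max(x$zones$height_hi),
              min(x$zones$weight_lo), max(x$zones$weight_hi),
              x$interval_convention))
  print(x$zones, ...)
  invisible(x)
}

# Built-in zone tables. Printed upper edges like "64.99"/"8.49" are
# canonicalized to exclusive bounds (65, 8.5); the 66.5 cm boundary printed
# for both pink and red on the Broselow tape is assigned to red.
.builtin_tapes <- function() {
  broselow <- tibble::tibble(
    name      = c("gray", "pink", "red", "purple", "yellow", "white", "blue", "orange", "green"),
    height_lo = c(46, 59.5, 66.5, 74, 84.5, 97.5, 110, 120.75, 133.4),
    height_hi = c(59.5, 66.5, 74, 84.5, 97.5, 110, 120.75, 133.4, 146.5),
    weight_lo = c(3, 6, 8, 10, 12, 15, 19, 24, 30),
    weight_hi = c(5, 7, 9, 11, 14, 18, 23, 29, 36))
  # IPWET classification weight bins are the half-kg bins used for the
  # validation statistics; its printed integer ranges are display labels.
  ipwet <- tibble::tibble(
    name      = c("gray", "pink", "red", "purple", "yellow", "white", "blue", "orange", "green"),
    height_lo = c(50, 65, 74, 81, 95, 107, 121, 133, 138),
    height_hi = c(65, 74, 81, 95, 107, 121, 133, 138, 150),
    weight_lo = c(4, 6.5, 8.5, 10.5, 12.5, 15.5, 19.5, 24.5, 28.5),
    weight_hi = c(6.5, 8.5, 10.5, 12.5, 15.5, 19.5, 24.5, 28.5, 36))
  list(broselow_2007b = broselow, ipwet = ipwet)
}

#' Built-in tape definitions
#'
#' Returns one of the two tapes the package ships: `"broselow_2007b"`, the
#' Broselow Pediatric Emergency Tape (2007 Edition B; heights 46-146.5 cm,
#' weights 3-36 kg), or `"ipwet"`, the Indian Pediatric Weight Estimation
#' Tool derived from it (heights 50-150 cm, weights 4-36 kg).
#'
#' @param name One of `"broselow_2007b"`, `"ipwet"`.
#' @return A [tape_spec].
#' @examples
#' builtin_tape("broselow_2007b")
#' @export
builtin_tape <- function(name) {
  tapes <- .builtin_tapes()
  if (!is.character(name) || length(name) != 1 || !name %in% names(tapes)) {
    abort_usage(paste0("unknown tape '", paste(name, collapse = ","),
                       "'; valid identifiers: ",
                       paste(names(tapes), collapse = ", ")))
  }
  tape_spec(name, tapes[[name]])
}

.as_tape <- function(tape) {
  if (is.character(tape)) return(builtin_tape(tape))
  if (!inherits(tape, "tape_spec")) {
    abort_usage("`tape` must be a tape_spec or a built-in tape name")
  }
  tape
}

# Shared interval lookup under the half-open convention (last bin closed).
.zone_lookup <- function(x, lo, hi, names) {
  idx <- findInterval(x, c(lo, hi[length(hi)]), rightmost.closed = TRUE)
  out <- rep(NA_character_, length(x))
  inside <- idx >= 1 & idx <= length(lo)
  # findInterval treats the vector as one partition: a value inside a weight
  # gap lands in bin i with x >= hi[i]; flag those as unclassified
  cand <- which(inside)
  ok <- x[cand] < hi[idx[cand]] | (idx[cand] == length(lo) & x[cand] <= hi[length(hi)])
  out[cand[ok]] <- names[idx[cand[ok]]]
  out
}

#' Map heights to color zones
#'
#' @param h Height(s) in cm; must be strictly positive.
#' @param tape A [tape_spec] or built-in tape name.
#' @return Character vector of zone names; `NA` flags a height outside the
#'   tape's range.
#' @examples
#' zone_for_height(100, "broselow_2007b")
#' @export
zone_for_height <- function(h, tape) {
  tape <- .as_tape(tape)
  if (!is.numeric(h) || any(is.na(h)) || any(h <= 0)) {
    abort_usage("heights must be positive numbers")
  }
  z <- tape$zones
  .zone_lookup(h, z$height_lo, z$height_hi, z$name)
}

#' Map weights to color zones
#'
#' Classifies a measured weight into the zone whose weight range contains it,
#' under the half-open convention. Weights outside the tape's overall span,
#' or inside a gap between consecutive zone weight ranges, return `NA`.
#'
#' @param w Weight(s) in kg; must be strictly positive.
#' @inheritParams zone_for_height
#' @return Character vector of zone names with `NA` for unclassifiable weights.
#' @examples
#' zone_for_weight(6.49, "ipwet")  # gray: the gray bin is [4, 6.5)
#' @export
zone_for_weight <- function(w, tape) {
  tape <- .as_tape(tape)
  if (!is.numeric(w) || any(is.na(w)) || any(w <= 0)) {
    abort_usage("weights must be positive numbers")
  }
  z <- tape$zones
  out <- rep(NA_character_, length(w))
  for (i in seq_len(nrow(z))) {
    last <- i == nrow(z)
    inb <- w >= z$weight_lo[i] & (w < z$weight_hi[i] | (last & w <= z$weight_hi[i]))
    out[inb] <- z$name[i]
  }
  out
}

#' Predicted weight for a height
#'
#' The weight a tape reads off for a measured height: linear interpolation
#' between the containing zone's weight endpoints, rounded to the 0.1 kg
#' resolution of the printed tape. Monotone non-decreasing in height across
#' the whole tape.
#'
#' @inheritParams zone_for_height
#' @param round Round to 0.1 kg (the default)? Set `FALSE` for the exact
#'   interpolated value, e.g. when composing lookups in analyses sensitive to
#'   rounding at zone edges.
#' @return Numeric vector of predicted weights (kg).
#' @examples
#' predicted_weight(46, "broselow_2007b")  # lower edge of gray: 3 kg
#' @export
predicted_weight <- function(h, tape, round = TRUE) {
  tape <- .as_tape(tape)
  zone <- zone_for_height(h, tape)
  if (anyNA(zone)) {
    abort_usage(sprintf("height(s) out of tape range (%g-%g cm): %s",
                        min(tape$zones$height_lo), max(tape$zones$height_hi),
                        paste(utils::head(h[is.na(zone)], 5), collapse = ", ")))
  }
  z <- tape$zones
  i <- match(zone, z$name)
  frac <- (h - z$height_lo[i]) / (z$height_hi[i] - z$height_lo[i])
  w <- z$weight_lo[i] + (z$weight_hi[i] - z$weight_lo[i]) * frac
  if (round) round_to(w, 0.1) else w
}

#' Assign each child to height- and weight-derived zones
#'
#' Produces the per-child zone assignment table: the zone the tape selects
#' from measured height, the tape's predicted weight, the zone the child's
#' actual weight belongs to, and whether the two zones match. A mismatch
#' against an unclassifiable weight (`NA` weight zone) counts as no match.
#'
#' @param cohort Cohort data frame (see [generate_cohort()] for the schema).
#' @inheritParams zone_for_height
#' @return Tibble with `child_id`, `height_zone`, `predicted_weight`,
#'   `weight_zone`, `match`.
#' @export
assign_zones <- function(cohort, tape) {
  tape <- .as_tape(tape)
  hz <- zone_for_height(cohort$height_cm, tape)
  if (anyNA(hz)) {
    abort_validation(paste0(
      "children outside tape height range (filter with apply_exclusions): ",
      paste(utils::head(cohort$child_id[is.na(hz)], 10), collapse = ", ")))
  }
  wz <- zone_for_weight(cohort$weight_kg, tape)
  tibble::tibble(
    child_id = cohort$child_id,
    height_zone = hz,
    predicted_weight = predicted_weight(cohort$height_cm, tape),
    weight_zone = wz,
    match = !is.na(wz) & hz == wz)
}

#' Read / write a tape specification as JSON
#'
#' The on-disk format is a JSON object
#' `{"tape_name": ..., "interval_convention": "half_open_upper", "zones": [...]}`
#' with zones in height order and bounds in cm/kg. All tape invariants are
#' re-checked at read time; violations name the offending zone.
#'
#' @param path File path.
#' @return `read_tape()` returns a [tape_spec]; `write_tape()` returns `path`
#'   invisibly.
#' @export
read_tape <- function(path) {
  if (!file.exists(path)) abort_io(paste0("tape file not found: ", path))
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) abort_io(paste0("malformed tape JSON: ",
                                                      conditionMessage(e))))
  if (is.null(doc$tape_name) || is.null(doc$zones)) {
    abort_validation("tape JSON must contain 'tape_name' and 'zones'")
  }
  tape_spec(doc$tape_name, doc$zones)
}

#' @rdname read_tape
#' @param tape A [tape_spec].
#' @export
write_tape <- function(tape, path) {
  tape <- .as_tape(tape)
  doc <- list(tape_name = tape$tape_name,
              interval_convention = tape$interval_convention,
              zones = as.data.frame(tape$zones))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
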