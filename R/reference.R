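#' Published derivation-study reference tables
#'
#' Per-zone summary statistics published by the Indian derivation study
#' (n = 769 children measured against the Broselow tape) from which the
#' built-in IPWET tape descends. `reference_zone_bias()` returns the per-zone
#' mean/SD of the directed percent difference before correction together with
#' the published after-correction values; `reference_zone_weights()` returns
#' the per-zone measured, predicted and 8%-reduced mean weights with the
#' published paired-test p-values. These tables serve as fixed inputs for
#' reproducing the study's closed-form correction arithmetic; they are
#' summaries, not raw data.
#'
#' @return A tibble with one row per color zone.
#' @examples
#' reference_zone_bias()
#' @export
reference_zone_bias <- function() {
  path <- system.file("extdata", "broselow_derivation_zone_bias.csv",
                      package = "pedtape", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname reference_zone_bias
#' @export
reference_zone_weights <- function() {
  path <- system.file("extdata", "broselow_derivation_zone_weights.csv",
                      package = "pedtape", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
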