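# Percent-specific-lysis formulas and the dynamic-range metric.

#' Percent specific lysis from supernatant release
#'
#' `100 * (test - spontaneous) / (maximum - spontaneous)`, where the three
#' releases are the (replicate-averaged) supernatant fluorescences of test,
#' spontaneous and maximum (Triton X-100) wells. Values below 0% or above
#' 100% are returned unmodified — clamping would hide assay failures; use
#' [lysis_qc_flag()] to mark them.
#'
#' @param test_release,spontaneous_release,maximum_release supernatant
#'   fluorescence, arbitrary units. The result is invariant to rescaling all
#'   three by a common positive constant, so the supernatant sampling
#'   fraction cancels.
#' @return percent specific lysis (may be outside `[0, 100]`).
#' @export
percent_lysis_release <- function(test_release, spontaneous_release,
                                  maximum_release) {
  if (any(maximum_release <= spontaneous_release)) {
    abort_param("maximum release must exceed spontaneous release (no dynamic range)")
  }
  100 * (test_release - spontaneous_release) /
    (maximum_release - spontaneous_release)
}

#' Percent specific lysis from live-cell counts
#'
#' `100 * (spontaneous_count - test_count) / spontaneous_count`, the
#' image-cytometry readout: live fluorescent cells are counted after gating
#' against the spontaneous control, and lysis is the fractional loss of live
#' cells relative to that control.
#'
#' @param spontaneous_live_count live count in spontaneous controls
#'   (replicate mean), must be positive.
#' @param test_live_count live count in the test well.
#' @return percent specific lysis (may be negative; see [lysis_qc_flag()]).
#' @export
percent_lysis_imaging <- function(spontaneous_live_count, test_live_count) {
  if (any(spontaneous_live_count <= 0)) {
    abort_param("spontaneous live count must be positive")
  }
  100 * (spontaneous_live_count - test_live_count) / spontaneous_live_count
}

#' Flag out-of-range percent-lysis values
#'
#' @param value percent lysis.
#' @return `TRUE` where the value lies outside `[0, 100]`.
#' @export
lysis_qc_flag <- function(value) value < 0 | value > 100

#' Dynamic range of the release assay
#'
#' With maximum release normalized to 100%, the spontaneous release as a
#' percentage of maximum bounds the usable signal: the dynamic range is the
#' remainder. Cell lines with high spontaneous leak or poor loading have a
#' narrow dynamic range and a correspondingly less sensitive release assay.
#'
#' @param maximum_release,spontaneous_release replicate-mean supernatant
#'   fluorescence of the two controls.
#' @return named list with `spont_pct_of_max` and `dynamic_range_pct`.
#' @export
dynamic_range <- function(maximum_release, spontaneous_release) {
  if (any(maximum_release <= 0)) {
    abort_param("maximum release must be positive")
  }
  spont_pct <- 100 * spontaneous_release / maximum_release
  list(spont_pct_of_max = spont_pct, dynamic_range_pct = 100 - spont_pct)
}
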