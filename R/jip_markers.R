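#' Fiducial fluorescence levels of the OJIP transient
#'
#' Extracts the five fiducial values of a fast fluorescence rise: Fo at the
#' origin (O), F300 at 300 us, FJ at the J step (~2 ms), FI at the I step
#' (~30 ms), and Fm, the peak (P) taken as the global maximum of the record.
#' Fo, F300, FJ and FI are read at fixed times by linear interpolation of
#' fluorescence against log10(time); Fm is the maximum sample, with ties
#' broken by the earliest time.
#'
#' A physically plausible rise has Fo <= F300 <= FJ <= FI <= Fm. Curves that
#' violate the marker ordering are returned with `flagged = TRUE` rather than
#' raising, so that batch summaries can exclude them with a count; a record
#' with Fm <= Fo carries no variable fluorescence at all and is an error.
#'
#' @param curve An [induction_curve].
#' @param t_fo Time at which Fo is read, seconds. Default 2e-5 (20 us, the
#'   first reliable sample of fast fluorimeters).
#' @param t_f300 Time of the F300 read, seconds (default 3e-4).
#' @param t_fj Time of the J-step read, seconds (default 2e-3).
#' @param t_fi Time of the I-step read, seconds (default 3e-2).
#'
#' @return An object of class `ojip_markers`: list with `fo`, `f300`, `fj`,
#'   `fi`, `fm`, `t_fm`, the read times, `flagged` and `label`.
#' @export
extract_markers <- function(curve, t_fo = 2e-5, t_f300 = 3e-4,
                            t_fj = 2e-3, t_fi = 3e-2) {
  assert_that(inherits(curve, "induction_curve"),
              "curve must be an induction_curve")
  reads <- c(fo = t_fo, f300 = t_f300, fj = t_fj, fi = t_fi)
  assert_that(all(diff(reads) > 0),
              "marker times must satisfy t_fo < t_f300 < t_fj < t_fi")
  vals <- log_time_interp(curve$times, curve$values, reads)
  i_max <- which.max(curve$values)   # which.max returns the first maximum
  fm <- curve$values[i_max]
  markers <- list(
    fo = vals[[1]], f300 = vals[[2]], fj = vals[[3]], fi = vals[[4]],
    fm = fm, t_fm = curve$times[i_max],
    t_fo = t_fo, t_f300 = t_f300, t_fj = t_fj, t_fi = t_fi,
    label = curve$label
  )
  if (markers$fm <= markers$fo) {
    pj_stop(sprintf(
      "degenerate transient '%s': Fm (%.6g) does not exceed Fo (%.6g)",
      curve$label, markers$fm, markers$fo),
      class = "phytojip_degenerate_error")
  }
  markers$flagged <- !(markers$fo <= markers$f300 &&
                         markers$f300 <= markers$fj &&
                         markers$fj <= markers$fi)
  structure(markers, class = "ojip_markers")
}

#' Construct a marker set directly from known fluorescence levels
#'
#' Convenience constructor for working with fiducial values that did not come
#' from a sampled curve (e.g. published marker levels).
#'
#' @param fo,f300,fj,fi,fm Fluorescence values at O, 300 us, J, I and the peak.
#' @param t_fm Time of the peak in seconds.
#' @return An `ojip_markers` object.
#' @export
ojip_markers <- function(fo, f300, fj, fi = NA_real_, fm, t_fm = 1) {
  assert_that(is.finite(fo) && is.finite(f300) && is.finite(fj) &&
                is.finite(fm), "markers must be finite")
  assert_that(fo > 0, "Fo must be > 0")
  if (fm <= fo) {
    pj_stop("degenerate marker set: Fm must exceed Fo",
            class = "phytojip_degenerate_error")
  }
  flagged <- !(fo <= f300 && f300 <= fj && (is.na(fi) || fj <= fi))
  structure(
    list(fo = fo, f300 = f300, fj = fj, fi = fi, fm = fm, t_fm = t_fm,
         t_fo = 2e-5, t_f300 = 3e-4, t_fj = 2e-3, t_fi = 3e-2,
         label = "", flagged = flagged),
    class = "ojip_markers"
  )
}

#' @export
print.ojip_markers <- function(x, ...) {
  cat(sprintf(
    "<ojip_markers> Fo=%.4g F300=%.4g FJ=%.4g FI=%.4g Fm=%.4g (t_Fm=%.3g s)%s\n",
    x$fo, x$f300, x$fj, x$fi, x$fm, x$t_fm,
    if (isTRUE(x$flagged)) " [flagged: non-monotone rise]" else ""))
  invisible(x)
}
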