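#' Maximum quantum yield of PSII photochemistry, Fv/Fm
#'
#' `Fv/Fm = (Fm - Fo)/Fm`, the fraction of absorbed excitation that a
#' dark-adapted leaf can use for PSII photochemistry; ~0.8 in healthy leaves.
#'
#' @param markers An `ojip_markers` object (see [extract_markers()]).
#' @return Dimensionless ratio in `[0, 1)`.
#' @export
fv_fm <- function(markers) {
  assert_that(inherits(markers, "ojip_markers"), "need an ojip_markers object")
  assert_that(markers$fm > 0, "Fm must be > 0")
  assert_that(markers$fo <= markers$fm,
              "inconsistent markers: Fo exceeds Fm")
  (markers$fm - markers$fo) / markers$fm
}

#' Initial slope M0 of the relative variable fluorescence rise
#'
#' The O-to-300 us chord slope of V(t), `M0 = 4 (F300 - Fo) / (Fm - Fo)` per
#' millisecond (the factor 4 is 1/0.25 ms). M0 is proportional to the maximum
#' rate of Q_A reduction. An alternative least-squares estimate fits V against
#' time over 50-300 us on the sampled curve.
#'
#' @inheritParams fv_fm
#' @param curve Optional [induction_curve]; required for `method = "fit"`.
#' @param method `"chord"` (default, the classical definition) or `"fit"`.
#' @return Initial slope in 1/ms.
#' @export
initial_slope <- function(markers, curve = NULL, method = c("chord", "fit")) {
  method <- match.arg(method)
  assert_that(inherits(markers, "ojip_markers"), "need an ojip_markers object")
  fv <- markers$fm - markers$fo
  assert_that(fv > 0, "Fm must exceed Fo", class = "phytojip_degenerate_error")
  if (method == "chord") {
    return(4 * (markers$f300 - markers$fo) / fv)
  }
  assert_that(inherits(curve, "induction_curve"),
              "method = 'fit' needs the sampled curve")
  win <- curve$times >= 5e-5 & curve$times <= 3e-4
  assert_that(sum(win) >= 2, "need >= 2 samples in the 50-300 us window")
  v <- (curve$values[win] - markers$fo) / fv
  t_ms <- curve$times[win] * 1e3
  unname(stats::coef(stats::lm(v ~ t_ms))[2])
}

#' Density of active PSII reaction centers per absorbed photon flux, RC/ABS
#'
#' `RC/ABS = (1 - Fo/Fm) / [4 (F300 - Fo) / (FJ - Fo)]`: the trapping yield
#' divided by the relative initial rise, an inverse proxy for PSII antenna
#' size.
#'
#' @inheritParams fv_fm
#' @return Dimensionless, > 0.
#' @export
rc_abs <- function(markers) {
  assert_that(inherits(markers, "ojip_markers"), "need an ojip_markers object")
  assert_that(markers$fm > markers$fo, "Fm must exceed Fo",
              class = "phytojip_degenerate_error")
  assert_that(markers$f300 > markers$fo,
              "RC/ABS undefined: F300 must exceed Fo",
              class = "phytojip_degenerate_error")
  assert_that(markers$fj > markers$fo,
              "RC/ABS undefined: FJ must exceed Fo",
              class = "phytojip_degenerate_error")
  phi <- 1 - markers$fo / markers$fm
  m0 <- 4 * (markers$f300 - markers$fo) / (markers$fj - markers$fo)
  phi / m0
}

#' Performance index PI(abs)
#'
#' `PI(abs) = RC/ABS * [(Fv/Fm)/(1 - Fv/Fm)] * [(Fm - FJ)/(FJ - Fo)]`,
#' combining reaction-center density, the trapping ratio, and the efficiency
#' of electron transfer past Q_A into a single PSII performance score.
#'
#' @inheritParams fv_fm
#' @return Dimensionless, >= 0; 0 exactly when FJ = Fm.
#' @export
pi_abs <- function(markers) {
  rc <- rc_abs(markers)
  phi <- fv_fm(markers)
  assert_that(phi < 1, "PI(abs) undefined at Fv/Fm = 1")
  rc * (phi / (1 - phi)) *
    ((markers$fm - markers$fj) / (markers$fj - markers$fo))
}

v_curve <- function(times, v_values, span_tag, label = "") {
  structure(list(times = times, v_values = v_values, span_tag = span_tag,
                 label = label),
            class = "v_curve")
}

#' @export
print.v_curve <- function(x, ...) {
  cat(sprintf("<v_curve> span %s: %d samples, V in [%.3g, %.3g]\n",
              x$span_tag, length(x$times), min(x$v_values), max(x$v_values)))
  invisible(x)
}

#' Relative variable fluorescence V(t)
#'
#' `V_t = (F_t - Fo) / (Fm - Fo)`: the transient rescaled so that the O level
#' maps to 0 and the peak to 1.
#'
#' @param curve An [induction_curve].
#' @param markers Its `ojip_markers`.
#' @return A `v_curve` with `span_tag = "OP"`.
#' @export
relative_variable_fluorescence <- function(curve, markers) {
  double_normalize(curve, markers, span = "OP")
}

#' Double-normalized fluorescence rise over a chosen span
#'
#' `W_t = (F_t - Fo) / (F_anchor - Fo)` with the anchor FJ (span `"OJ"`),
#' FI (`"OI"`) or Fm (`"OP"`). Double normalization makes the shape of a
#' phase comparable across samples with different Fo and Fm.
#'
#' @inheritParams relative_variable_fluorescence
#' @param span `"OJ"`, `"OI"` or `"OP"`.
#' @return A `v_curve`.
#' @export
double_normalize <- function(curve, markers, span = c("OP", "OJ", "OI")) {
  span <- match.arg(span)
  assert_that(inherits(curve, "induction_curve"),
              "curve must be an induction_curve")
  assert_that(inherits(markers, "ojip_markers"), "need an ojip_markers object")
  anchor <- switch(span, OJ = markers$fj, OI = markers$fi, OP = markers$fm)
  assert_that(is.finite(anchor), sprintf("anchor for span %s is missing", span))
  if (anchor <= markers$fo) {
    pj_stop(sprintf("span %s anchor (%.6g) does not exceed Fo (%.6g)",
                    span, anchor, markers$fo),
            class = "phytojip_degenerate_error")
  }
  v_curve(curve$times, (curve$values - markers$fo) / (anchor - markers$fo),
          span_tag = span, label = curve$label)
}

#' Difference kinetics between two normalized transients
#'
#' `dV(t) = V_treated(t) - V_control(t)` on the control's time grid, the
#' treated curve resampled by linear interpolation in log time. Negative
#' values around 2 ms indicate a lowered J step in the treated sample.
#'
#' @param treated,control `v_curve` objects sharing the same `span_tag`.
#' @return A `v_curve` of differences, restricted to the common time window.
#' @export
difference_kinetics <- function(treated, control) {
  assert_that(inherits(treated, "v_curve") && inherits(control, "v_curve"),
              "need two v_curve objects")
  assert_that(identical(treated$span_tag, control$span_tag),
              sprintf("span tags differ: %s vs %s",
                      treated$span_tag, control$span_tag))
  lo <- max(treated$times[1], control$times[1])
  hi <- min(treated$times[length(treated$times)],
            control$times[length(control$times)])
  assert_that(lo < hi, "curves have disjoint time ranges",
              class = "phytojip_range_error")
  keep <- control$times >= lo & control$times <= hi
  grid <- control$times[keep]
  tre <- approx(log10(treated$times), treated$v_values, log10(grid))$y
  v_curve(grid, tre - control$v_values[keep], span_tag = treated$span_tag,
          label = sprintf("d[%s - %s]", treated$label, control$label))
}

#' Area over the OJIP transient
#'
#' Trapezoidal integral of `(Fm - F_t)` over linear time from the Fo read
#' time to the time of the peak. The complementary area is proportional to
#' the pool of electron acceptors that must be reduced to close all PSII
#' centers. With `normalized = TRUE` the area is divided by Fv (the Sm
#' convention), giving a value in seconds.
#'
#' @inheritParams relative_variable_fluorescence
#' @param normalized Divide by `Fv = Fm - Fo`?
#' @return Area in fluorescence x seconds, or seconds if normalized.
#' @export
area_over_curve <- function(curve, markers, normalized = FALSE) {
  assert_that(inherits(curve, "induction_curve"),
              "curve must be an induction_curve")
  assert_that(inherits(markers, "ojip_markers"), "need an ojip_markers object")
  fv <- markers$fm - markers$fo
  assert_that(fv > 0, "Fm must exceed Fo", class = "phytojip_degenerate_error")
  t0 <- markers$t_fo
  t1 <- markers$t_fm
  assert_that(t1 > t0, "peak time must lie after the Fo read time",
              class = "phytojip_range_error")
  inner <- curve$times > t0 & curve$times < t1
  tt <- c(t0, curve$times[inner], t1)
  ff <- c(log_time_interp(curve$times, curve$values, t0),
          curve$values[inner],
          log_time_interp(curve$times, curve$values, t1))
  deficit <- markers$fm - ff
  area <- sum(diff(tt) * (head(deficit, -1) + tail(deficit, -1)) / 2)
  area <- max(area, 0)
  if (normalized) area / fv else area
}

#' All JIP-test parameters for one transient
#'
#' @inheritParams extract_markers
#' @return A one-row data frame with the markers and the derived quantities
#'   `fv_fm`, `v_j`, `v_i`, `m0` (1/ms), `rc_abs`, `pi_abs`, `area`
#'   (fluorescence x s), `sm` (s), plus a `flagged` column.
#' @export
jip_parameters <- function(curve, t_fo = 2e-5, t_f300 = 3e-4,
                           t_fj = 2e-3, t_fi = 3e-2) {
  mk <- extract_markers(curve, t_fo = t_fo, t_f300 = t_f300,
                        t_fj = t_fj, t_fi = t_fi)
  fv <- mk$fm - mk$fo
  data.frame(
    label = if (nzchar(mk$label)) mk$label else NA_character_,
    Fo = mk$fo, F300 = mk$f300, FJ = mk$fj, FI = mk$fi, Fm = mk$fm,
    fv_fm = fv_fm(mk),
    v_j = (mk$fj - mk$fo) / fv,
    v_i = (mk$fi - mk$fo) / fv,
    m0 = initial_slope(mk),
    rc_abs = rc_abs(mk),
    pi_abs = pi_abs(mk),
    area = area_over_curve(curve, mk),
    sm = area_over_curve(curve, mk, normalized = TRUE),
    flagged = mk$flagged,
    stringsAsFactors = FALSE
  )
}

#' Batch JIP summary with group statistics
#'
#' Computes [jip_parameters()] for every curve, then per-group mean and
#' standard error (sd/sqrt(n)) of each parameter, and percent change of each
#' group mean against a named reference group. Degenerate transients (no
#' variable fluorescence) and curves with a non-monotone marker ladder are
#' flagged and excluded from the group statistics; their count is reported.
#'
#' @param curves List of [induction_curve] objects.
#' @param groups Character vector assigning each curve to a group; defaults
#'   to each curve's `metadata$group`, then its label.
#' @param reference Optional reference group name for percent change.
#' @return List with `per_curve` (one row per curve), `group_stats`
#'   (group x parameter mean/se, with `pct_change_vs_ref` when a reference is
#'   given) and `n_excluded`.
#' @export
jip_summary <- function(curves, groups = NULL, reference = NULL) {
  assert_that(is.list(curves) && length(curves) >= 1, "need at least one curve")
  if (is.null(groups)) {
    groups <- vapply(curves, function(c)
      as.character(c$metadata$group %||% c$label), character(1))
  }
  assert_that(length(groups) == length(curves),
              "groups must match curves in length")
  rows <- lapply(seq_along(curves), function(i) {
    row <- tryCatch(jip_parameters(curves[[i]]), phytojip_error = function(e) {
      data.frame(label = curves[[i]]$label, Fo = NA_real_, F300 = NA_real_,
                 FJ = NA_real_, FI = NA_real_, Fm = NA_real_,
                 fv_fm = NA_real_, v_j = NA_real_, v_i = NA_real_,
                 m0 = NA_real_, rc_abs = NA_real_, pi_abs = NA_real_,
                 area = NA_real_, sm = NA_real_, flagged = TRUE,
                 stringsAsFactors = FALSE)
    })
    row$group <- groups[i]
    row
  })
  per_curve <- do.call(rbind, rows)
  ok <- !per_curve$flagged
  params <- c("fv_fm", "v_j", "v_i", "m0", "rc_abs", "pi_abs", "area", "sm")
  gs <- do.call(rbind, lapply(split(per_curve[ok, , drop = FALSE],
                                    per_curve$group[ok]), function(d) {
    do.call(rbind, lapply(params, function(p) {
      x <- d[[p]]
      data.frame(group = d$group[1], parameter = p, n = length(x),
                 mean = mean(x),
                 se = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(gs) <- NULL
  if (!is.null(reference)) {
    assert_that(reference %in% gs$group,
                sprintf("reference group '%s' not present", reference))
    ref <- gs[gs$group == reference, c("parameter", "mean")]
    gs$pct_change_vs_ref <- mapply(function(p, m) {
      r <- ref$mean[ref$parameter == p]
      if (r == 0) NA_real_ else percent_change(m, r)
    }, gs$parameter, gs$mean)
  }
  list(per_curve = per_curve, group_stats = gs,
       n_excluded = sum(per_curve$flagged))
}
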