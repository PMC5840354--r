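#' 820 nm transmittance curves (P700 redox proxy)
#'
#' Far-red (820 nm) transmittance of a leaf drops as P700, the primary
#' electron donor of PSI, is oxidized under actinic light, and recovers as
#' electrons arrive from PSII. A `transmittance_curve` holds the sampled
#' intensity record; analysis reduces it to a trough depth (oxidation
#' amplitude), the time of the trough, and the final recovery level.
#'
#' @param times Numeric vector of sampling times in seconds, strictly
#'   increasing; the record may start at t = 0.
#' @param i820 Transmitted-light intensities, finite and > 0.
#' @param label Sample identifier.
#' @param metadata Named list of tags.
#' @return An object of class `transmittance_curve`.
#' @export
transmittance_curve <- function(times, i820, label = "", metadata = list()) {
  assert_that(is.numeric(times) && is.numeric(i820), "inputs must be numeric")
  assert_that(length(times) == length(i820),
              "times and i820 must have equal length")
  assert_that(length(times) >= 2, "need at least 2 samples")
  assert_that(all(is.finite(times)) && all(is.finite(i820)),
              "times and i820 must be finite",
              class = "phytojip_validation_error")
  assert_that(all(diff(times) > 0), "times must be strictly increasing",
              class = "phytojip_validation_error")
  assert_that(all(i820 > 0), "transmittance must be > 0",
              class = "phytojip_validation_error")
  structure(list(times = as.numeric(times), i820 = as.numeric(i820),
                 label = as.character(label), metadata = metadata),
            class = "transmittance_curve")
}

#' @export
print.transmittance_curve <- function(x, ...) {
  cat(sprintf("<transmittance_curve> %s: %d samples, I/I0 min %.4g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times), min(x$i820) / x$i820[1]))
  invisible(x)
}

#' Read an 820 nm transmittance record
#'
#' Same two-column delimited layout as [read_transient()].
#'
#' @inheritParams read_transient
#' @return A [transmittance_curve].
#' @export
read_transmittance <- function(path, time_unit = c("s", "ms", "us"),
                               label = basename(path), metadata = list()) {
  time_unit <- match.arg(time_unit)
  tab <- parse_delim_table(path)
  scale <- switch(time_unit, s = 1, ms = 1e-3, us = 1e-6)
  ord <- order(tab$time)
  transmittance_curve(tab$time[ord] * scale, tab$value[ord], label = label,
                      metadata = metadata)
}

#' Normalize a transmittance record to its initial intensity
#'
#' Divides the whole record by its first sample so that curves measured at
#' different gains are comparable; idempotent.
#'
#' @param curve A [transmittance_curve].
#' @return A [transmittance_curve] with first value exactly 1.
#' @export
normalize_transmittance <- function(curve) {
  assert_that(inherits(curve, "transmittance_curve"),
              "need a transmittance_curve")
  assert_that(curve$i820[1] > 0, "first sample must be > 0")
  transmittance_curve(curve$times, curve$i820 / curve$i820[1],
                      label = curve$label, metadata = curve$metadata)
}

is_normalized <- function(curve, tol = 1e-6) {
  abs(curve$i820[1] - 1) <= tol
}

#' P700 oxidation amplitude of a normalized transmittance record
#'
#' The trough depth `1 - min(I/I0)` and the time of the minimum, located on
#' the raw sampled grid. A deeper trough means more P700 oxidized.
#'
#' @param curve A normalized [transmittance_curve] (first value 1 within 1e-6).
#' @return List with `amplitude` (in `[0, 1)`), `t_min` (s) and
#'   `recovery_level` (final sample).
#' @export
oxidation_amplitude <- function(curve) {
  assert_that(inherits(curve, "transmittance_curve"),
              "need a transmittance_curve")
  assert_that(is_normalized(curve),
              "curve is not normalized; call normalize_transmittance() first")
  i_min <- which.min(curve$i820)
  list(amplitude = 1 - curve$i820[i_min],
       t_min = curve$times[i_min],
       recovery_level = curve$i820[length(curve$i820)])
}

#' Rank sample groups by mean minimum transmittance
#'
#' Groups are ordered ascending by the mean of their curves' minimum
#' normalized transmittance: the first group is the most oxidized (deepest
#' trough). Ties are broken lexicographically and flagged.
#'
#' @param curves List of normalized [transmittance_curve] objects.
#' @param groups Character vector of group labels, one per curve; defaults to
#'   each curve's `metadata$group`, then its label.
#' @return Data frame with `group`, `n`, `mean_min` and `tied`, ordered from
#'   lowest (most oxidation) to highest mean minimum.
#' @export
rank_groups_by_transmittance <- function(curves, groups = NULL) {
  assert_that(is.list(curves) && length(curves) >= 1, "need curves")
  if (is.null(groups)) {
    groups <- vapply(curves, function(c)
      as.character(c$metadata$group %||% c$label), character(1))
  }
  assert_that(length(groups) == length(curves),
              "groups must match curves in length")
  assert_that(all(nzchar(groups)), "empty group label",
              class = "phytojip_validation_error")
  assert_that(length(unique(groups)) >= 2, "need at least 2 groups")
  mins <- vapply(curves, function(c) {
    assert_that(is_normalized(c),
                sprintf("curve '%s' is not normalized", c$label))
    min(c$i820)
  }, numeric(1))
  agg <- do.call(rbind, lapply(split(mins, groups), function(x) {
    data.frame(n = length(x), mean_min = mean(x))
  }))
  agg$group <- rownames(agg)
  rownames(agg) <- NULL
  # ascending mean minimum; lexicographic group name breaks exact ties
  agg <- agg[order(agg$mean_min, agg$group), c("group", "n", "mean_min")]
  agg$tied <- duplicated(agg$mean_min) | duplicated(agg$mean_min, fromLast = TRUE)
  rownames(agg) <- NULL
  agg
}
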