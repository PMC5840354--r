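#' Fast fluorescence induction curves
#'
#' An `induction_curve` holds one sampled fast chlorophyll *a* fluorescence
#' transient: strictly increasing times in seconds spanning the microsecond to
#' second range, and strictly positive fluorescence values in instrument units.
#' The same container is used for any kinetic record sampled on a log-spaced
#' time grid.
#'
#' @param times Numeric vector of sampling times in seconds, strictly
#'   increasing. The record must start no later than 2e-5 s, end at 0.5 s or
#'   later, contain at least 20 samples and span at least four decades of time.
#' @param values Numeric vector of fluorescence values, finite and > 0, same
#'   length as `times`.
#' @param label Free-text sample identifier.
#' @param metadata Named list of tags (genotype, treatment, ...).
#'
#' @return An object of class `induction_curve`: a list with elements `times`,
#'   `values`, `label` and `metadata`.
#' @export
induction_curve <- function(times, values, label = "", metadata = list()) {
  assert_that(is.numeric(times) && is.numeric(values),
              "times and values must be numeric")
  assert_that(length(times) == length(values),
              "times and values must have equal length")
  assert_that(length(times) >= 20,
              sprintf("an induction curve needs at least 20 samples, got %d",
                      length(times)),
              class = "phytojip_validation_error")
  assert_that(all(is.finite(times)) && all(is.finite(values)),
              "times and values must be finite",
              class = "phytojip_validation_error")
  dup <- anyDuplicated(times)
  if (dup > 0) {
    pj_stop(sprintf("duplicated sampling time at t = %g s", times[dup]),
            class = "phytojip_validation_error")
  }
  assert_that(all(diff(times) > 0), "times must be strictly increasing",
              class = "phytojip_validation_error")
  assert_that(all(times > 0), "times must be positive",
              class = "phytojip_validation_error")
  assert_that(all(values > 0), "fluorescence values must be > 0",
              class = "phytojip_validation_error")
  assert_that(times[1] <= 2e-5,
              sprintf("record must start by 2e-5 s, starts at %g s", times[1]),
              class = "phytojip_validation_error")
  assert_that(times[length(times)] >= 0.5,
              sprintf("record must reach 0.5 s, ends at %g s",
                      times[length(times)]),
              class = "phytojip_validation_error")
  assert_that(log10(times[length(times)] / times[1]) >= 4,
              "record must span at least 4 decades of time",
              class = "phytojip_validation_error")
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         label = as.character(label), metadata = metadata),
    class = "induction_curve"
  )
}

#' @export
print.induction_curve <- function(x, ...) {
  cat(sprintf("<induction_curve> %s: %d samples, %.2g-%.2g s, F in [%.4g, %.4g]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times), x$times[1], x$times[length(x$times)],
              min(x$values), max(x$values)))
  invisible(x)
}

# linear interpolation of a signal against log10(time); the native
# interpolation scale for log-spaced fast-fluorimeter records
log_time_interp <- function(times, values, t_out) {
  assert_that(all(t_out >= times[1] - 1e-12) &&
                all(t_out <= times[length(times)] + 1e-12),
              sprintf("interpolation time outside sampled range [%g, %g] s",
                      times[1], times[length(times)]),
              class = "phytojip_range_error")
  approx(x = log10(times), y = values, xout = log10(t_out), rule = 1)$y
}

parse_delim_table <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  has_header <- {
    cells <- strsplit(first, sep, fixed = TRUE)[[1]]
    any(is.na(suppressWarnings(as.numeric(cells))))
  }
  raw <- read.csv(path, sep = sep, header = has_header,
                  colClasses = "character", strip.white = TRUE)
  assert_that(ncol(raw) >= 2,
              sprintf("expected a two-column table in %s, got %d column(s)",
                      path, ncol(raw)))
  out <- data.frame(
    time = suppressWarnings(as.numeric(raw[[1]])),
    value = suppressWarnings(as.numeric(raw[[2]]))
  )
  bad <- which(is.na(out$time) | is.na(out$value))
  if (length(bad)) {
    pj_stop(sprintf("non-numeric cell in %s at data row %d", path, bad[1]),
            class = "phytojip_parse_error")
  }
  out
}

#' Read a kinetic transient from a delimited text file
#'
#' Reads a two-column (time, signal) table, comma- or tab-separated, with an
#' optional single header line, converts times to seconds and returns a
#' validated [induction_curve]. Rows are sorted by time; duplicated times are
#' an error.
#'
#' @param path Path to the delimited file.
#' @param time_unit Unit of the time column: `"s"`, `"ms"` or `"us"`.
#' @inheritParams induction_curve
#' @return An [induction_curve].
#' @export
read_transient <- function(path, time_unit = c("s", "ms", "us"),
                           label = basename(path), metadata = list()) {
  time_unit <- match.arg(time_unit)
  tab <- parse_delim_table(path)
  scale <- switch(time_unit, s = 1, ms = 1e-3, us = 1e-6)
  tab$time <- tab$time * scale
  ord <- order(tab$time)
  induction_curve(tab$time[ord], tab$value[ord], label = label,
                  metadata = metadata)
}

#' Write a kinetic transient to CSV
#'
#' Writes times (seconds) and signal values at full double precision so that
#' `read_transient(write_transient(x))` round-trips within 1e-9 relative.
#'
#' @param curve An [induction_curve] (or transmittance curve).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transient <- function(curve, path) {
  vals <- if (inherits(curve, "transmittance_curve")) curve$i820 else curve$values
  df <- data.frame(time_s = sprintf("%.17g", curve$times),
                   value = sprintf("%.17g", vals))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate transients
#'
#' Pointwise mean of two or more transients on the grid of the first curve,
#' after resampling the others by linear interpolation in log time. Only the
#' time window common to all records is kept. Instruments report averaged
#' transients over replicate leaves; this reproduces that reduction.
#'
#' @param curves List of [induction_curve] objects (>= 2).
#' @param label Label for the averaged curve; defaults to recording `n`.
#' @return An [induction_curve] whose metadata records `n_averaged`.
#' @export
average_transients <- function(curves, label = NULL) {
  assert_that(is.list(curves) && length(curves) >= 2,
              "need at least 2 curves to average")
  assert_that(all(vapply(curves, inherits, logical(1), "induction_curve")),
              "all elements must be induction_curve objects")
  lo <- max(vapply(curves, function(c) c$times[1], numeric(1)))
  hi <- min(vapply(curves, function(c) c$times[length(c$times)], numeric(1)))
  assert_that(lo < hi, "curves have disjoint time ranges",
              class = "phytojip_range_error")
  grid <- curves[[1]]$times
  grid <- grid[grid >= lo & grid <= hi]
  resampled <- vapply(curves, function(c) log_time_interp(c$times, c$values, grid),
                      numeric(length(grid)))
  n <- length(curves)
  induction_curve(
    grid, rowMeans(resampled),
    label = label %||% sprintf("mean of %d transients", n),
    metadata = list(n_averaged = n)
  )
}
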