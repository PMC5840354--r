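#' Read a qPCR Ct table
#'
#' CSV with columns `sample,gene,role,ct`; `role` is `"target"` or
#' `"reference"`. Several rows per (sample, gene) are replicate Cts.
#'
#' @param path CSV path.
#' @return Data frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  ct_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_ct_table
#' @param df Data frame with the four required columns.
#' @export
ct_table <- function(df) {
  need <- c("sample", "gene", "role", "ct")
  assert_that(all(need %in% names(df)),
              sprintf("Ct table must have columns %s",
                      paste(need, collapse = ", ")))
  assert_that(all(df$role %in% c("target", "reference")),
              "role must be 'target' or 'reference'")
  assert_that(all(is.finite(df$ct)) && all(df$ct > 0) && all(df$ct < 45),
              "Ct values must lie in (0, 45)",
              class = "phytojip_validation_error")
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Relative expression by the ddCt method
#'
#' For each sample, `dCt = mean(Ct_target) - mean(Ct_reference)` over its
#' replicate wells; `ddCt = dCt_sample - dCt_calibrator`; and the relative
#' quantity `RQ = 2^-ddCt` (amplification efficiency assumed 2 per cycle).
#' The calibrator sample has RQ = 1 by construction. `log_rq` applies
#' [display_transform()] with the chosen base.
#'
#' @param cts A [ct_table()] (or data frame with its columns).
#' @param calibrator Sample label whose dCt anchors the scale.
#' @param log_base Base of the display log, 10 (default) or 2.
#' @return Data frame with one row per sample: `sample`, `dct`, `ddct`,
#'   `rq`, `log_rq`.
#' @export
relative_expression <- function(cts, calibrator, log_base = 10) {
  if (!inherits(cts, "ct_table")) cts <- ct_table(cts)
  samples <- unique(cts$sample)
  assert_that(calibrator %in% samples,
              sprintf("calibrator sample '%s' not present", calibrator))
  dct <- vapply(samples, function(s) {
    d <- cts[cts$sample == s, ]
    tgt <- d$ct[d$role == "target"]
    ref <- d$ct[d$role == "reference"]
    assert_that(length(tgt) >= 1,
                sprintf("sample '%s' has no target-gene Ct", s))
    assert_that(length(ref) >= 1,
                sprintf("sample '%s' has no reference-gene Ct", s))
    mean(tgt) - mean(ref)
  }, numeric(1))
  ddct <- dct - dct[[calibrator]]
  rq <- 2^(-ddct)
  data.frame(sample = samples, dct = unname(dct), ddct = unname(ddct),
             rq = unname(rq),
             log_rq = display_transform(unname(rq), base = log_base),
             stringsAsFactors = FALSE)
}

#' Display transform for relative quantities
#'
#' `log_base(RQ)`; base 10 by default (fold changes shown on a decimal log
#' axis), base 2 optional.
#'
#' @param rq Positive relative quantities.
#' @param base 10 or 2.
#' @return `log(rq, base)`.
#' @export
display_transform <- function(rq, base = 10) {
  assert_that(base %in% c(2, 10), "base must be 2 or 10")
  assert_that(all(rq > 0), "relative quantities must be > 0")
  log(rq, base = base)
}
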