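# Independent oracles and small fixture builders used across the suite.

# Brute-force one-way ANOVA from raw sums of squares (no model fitting):
# the textbook between/within decomposition, kept independent of stats::aov.
anova_oracle <- function(groups) {
  y <- unlist(groups)
  grand <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  n <- lengths(groups)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(seq_along(groups),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- sum(n) - length(groups)
  msb <- ssb / dfb
  msw <- ssw / dfw
  list(f = msb / msw, ssb = ssb, ssw = ssw, dfb = dfb, dfw = dfw, mse = msw)
}

# Random physically plausible OJIP marker set: Fo < F300 < FJ < FI < Fm.
random_markers <- function() {
  fo <- runif(1, 200, 1000)
  steps <- sort(runif(4, 0.05, 1))
  fm <- fo * runif(1, 2.5, 6)
  lv <- fo + (fm - fo) * steps
  ojip_markers(fo = fo, f300 = lv[1], fj = lv[2], fi = lv[3], fm = fm)
}

# A valid induction-curve grid that contains the four marker read times
# exactly, so interpolation at those knots returns the samples themselves.
knot_grid <- function(n_extra = 40) {
  sort(unique(c(10^seq(-5, 0, length.out = n_extra),
                2e-5, 3e-4, 2e-3, 3e-2)))
}

# Linear O-to-P ramp over [t0, t1] embedded in a valid log-spanning record:
# closed-form area over the curve = Fv * (t1 - t0) / 2 once F holds at Fm
# beyond t1.
linear_rise_curve <- function(fo = 500, fm = 2500, t0 = 2e-5, t1 = 0.1,
                              n = 2000) {
  times <- sort(unique(c(10^seq(log10(t0), 0, length.out = n), t0, t1)))
  f <- ifelse(times <= t1, fo + (fm - fo) * (times - t0) / (t1 - t0), fm)
  induction_curve(times, pmin(f, fm))
}
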