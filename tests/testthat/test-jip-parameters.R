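worked <- ojip_markers(fo = 500, f300 = 900, fj = 1500, fi = 2000, fm = 2500)

test_that("JIP formulas reproduce hand-computed values exactly", {
  expect_equal(fv_fm(worked), 0.8, tolerance = 1e-12)
  expect_equal(initial_slope(worked), 0.8, tolerance = 1e-12)  # per ms
  expect_equal(rc_abs(worked), 0.5, tolerance = 1e-12)
  expect_equal(pi_abs(worked), 2.0, tolerance = 1e-12)
})

test_that("formula boundary cases behave as defined", {
  expect_equal(fv_fm(ojip_markers(1000, 1000, 1000, 1000, 1000 + 1e-9)),
               1e-12, tolerance = 1e-3)
  # FJ = Fm kills the electron-transport factor
  expect_equal(pi_abs(ojip_markers(500, 900, 2500, fi = 2500, fm = 2500)), 0)
  # F300 = Fo: flat initial rise
  expect_equal(initial_slope(ojip_markers(500, 500, 1500, fm = 2500)), 0)
  expect_error(rc_abs(ojip_markers(500, 500, 1500, fm = 2500)),
               class = "phytojip_degenerate_error")
  expect_error(rc_abs(ojip_markers(500, 900, 500, fm = 2500)),
               class = "phytojip_degenerate_error")
  expect_error(ojip_markers(500, 900, 1500, fm = 500),
               class = "phytojip_degenerate_error")
})

test_that("M0 increases monotonically in F300 at fixed Fo, Fm", {
  f300 <- seq(520, 1400, by = 40)
  m0 <- vapply(f300, function(x)
    initial_slope(ojip_markers(500, x, 1500, fm = 2500)), numeric(1))
  expect_true(all(diff(m0) > 0))
})

test_that("PI(abs) equals its three factors recomputed independently (1000 draws)", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      mk <- random_markers()
      direct <- rc_abs(mk) * (fv_fm(mk) / (1 - fv_fm(mk))) *
        ((mk$fm - mk$fj) / (mk$fj - mk$fo))
      expect_equal(pi_abs(mk), direct, tolerance = 1e-12)
    }
  })
})

test_that("marker ratios are invariant to fluorescence scale", {
  for (c_scale in c(0.5, 2, 17)) {
    scaled <- ojip_markers(worked$fo * c_scale, worked$f300 * c_scale,
                           worked$fj * c_scale, worked$fi * c_scale,
                           worked$fm * c_scale)
    expect_equal(fv_fm(scaled), fv_fm(worked), tolerance = 1e-12)
    expect_equal(rc_abs(scaled), rc_abs(worked), tolerance = 1e-12)
    expect_equal(pi_abs(scaled), pi_abs(worked), tolerance = 1e-12)
  }
})

test_that("markers read at sampled knots equal the samples exactly", {
  times <- knot_grid()
  f <- 500 + 2000 * seq_along(times) / length(times)
  curve <- induction_curve(times, f)
  mk <- extract_markers(curve)
  expect_equal(mk$f300, f[which(times == 3e-4)])
  expect_equal(mk$fj, f[which(times == 2e-3)])
  expect_equal(mk$fi, f[which(times == 3e-2)])
  expect_equal(mk$fm, max(f))
  expect_equal(mk$t_fm, times[which.max(f)])
})

test_that("constant and non-monotone transients are caught", {
  times <- knot_grid()
  expect_error(extract_markers(induction_curve(times, rep(1000, length(times)))),
               class = "phytojip_degenerate_error")
  # J above I: flagged, not an error
  dip <- 500 + 2000 * seq(0, 1, length.out = length(times))
  dip[times >= 2.5e-3 & times <= 5e-2] <- 600
  mk <- extract_markers(induction_curve(times, dip))
  expect_true(mk$flagged)
  # marker time outside the sampled range
  short <- induction_curve(10^seq(-5, 0, length.out = 50),
                           seq(500, 2500, length.out = 50))
  expect_error(extract_markers(short, t_fo = 1e-6),
               class = "phytojip_range_error")
})

test_that("V and double-normalized curves hit their anchors", {
  sim <- generate_ojip(noise_cv = 0, seed = 1)
  mk <- extract_markers(sim$curve)
  v <- relative_variable_fluorescence(sim$curve, mk)
  expect_identical(v$span_tag, "OP")
  expect_equal(log_interp_at <- approx(log10(v$times), v$v_values,
                                       log10(mk$t_fo))$y, 0,
               tolerance = 1e-9)
  expect_equal(v$v_values[which(v$times == mk$t_fm)], 1, tolerance = 1e-9)

  w_oj <- double_normalize(sim$curve, mk, "OJ")
  expect_equal(approx(log10(w_oj$times), w_oj$v_values, log10(2e-3))$y, 1,
               tolerance = 1e-9)
  # OJ normalization sits above OP from the Fo read up to the J step
  # (below 20 us the curve sits under the interpolated Fo, flipping the sign)
  pre_j <- v$times >= mk$t_fo & v$times <= 2e-3
  expect_true(all(w_oj$v_values[pre_j] >= v$v_values[pre_j] - 1e-12))

  # OP span is plain V
  w_op <- double_normalize(sim$curve, mk, "OP")
  expect_equal(w_op$v_values, v$v_values)
})

test_that("difference kinetics recover programmed J-step differences", {
  a <- generate_ojip(noise_cv = 0, seed = 1)
  mk_a <- extract_markers(a$curve)
  v_a <- relative_variable_fluorescence(a$curve, mk_a)

  expect_equal(difference_kinetics(v_a, v_a)$v_values,
               rep(0, length(v_a$times)))

  shifted <- v_a
  shifted$v_values <- shifted$v_values + 0.1
  expect_equal(difference_kinetics(shifted, v_a)$v_values,
               rep(0.1, length(v_a$times)))

  # lowered J weight in the treated curve depresses dV near 2 ms
  b <- generate_ojip(weights = c(0.35, 0.40, 0.25), noise_cv = 0, seed = 1)
  v_b <- relative_variable_fluorescence(b$curve, extract_markers(b$curve))
  dv <- difference_kinetics(v_b, v_a)
  at_j <- which.min(abs(dv$times - 2e-3))
  expect_lt(dv$v_values[at_j], -0.05)

  mismatch <- double_normalize(a$curve, mk_a, "OJ")
  expect_error(difference_kinetics(mismatch, v_a), regexp = "span tags differ")
})

test_that("area over the curve matches the linear-rise closed form", {
  fo <- 500; fm <- 2500; t0 <- 2e-5; t1 <- 0.1
  curve <- linear_rise_curve(fo, fm, t0, t1)
  mk <- extract_markers(curve)
  analytic <- (fm - fo) * (t1 - t0) / 2
  expect_equal(area_over_curve(curve, mk), analytic, tolerance = 1e-6)
  expect_equal(area_over_curve(curve, mk, normalized = TRUE),
               (t1 - t0) / 2, tolerance = 1e-6)
  # flat-at-Fm record has zero area
  times <- knot_grid()
  flat <- induction_curve(times, c(seq(500, 2500,
                                       length.out = 10),
                                   rep(2500, length(times) - 10)))
  mk_flat <- extract_markers(flat)
  expect_lt(area_over_curve(flat, mk_flat) /
              area_over_curve(curve, mk), 0.2)
})

test_that("area is stable under halving the sampling density", {
  sim <- generate_ojip(noise_cv = 0, n_points = 471, seed = 1)
  mk <- extract_markers(sim$curve)
  full <- area_over_curve(sim$curve, mk)
  half_idx <- seq(1, 471, by = 2)
  half_curve <- induction_curve(sim$curve$times[half_idx],
                                sim$curve$values[half_idx])
  half <- area_over_curve(half_curve, extract_markers(half_curve))
  expect_lt(abs(half - full) / full, 0.005)
})

test_that("scale invariance holds for every derived parameter on real grids", {
  sim <- generate_ojip(noise_cv = 0.01, seed = 3)
  p1 <- jip_parameters(sim$curve)
  for (c_scale in c(0.1, 3)) {
    scaled <- induction_curve(sim$curve$times, sim$curve$values * c_scale)
    p2 <- jip_parameters(scaled)
    for (col in c("fv_fm", "v_j", "v_i", "m0", "rc_abs", "pi_abs", "sm")) {
      expect_equal(p2[[col]], p1[[col]], tolerance = 1e-9)
    }
    expect_equal(p2$area, c_scale * p1$area, tolerance = 1e-9)
  }
})

test_that("jip_summary aggregates groups and flags degenerate members", {
  curves <- lapply(1:6, function(r)
    generate_ojip(noise_cv = 0, seed = r, label = sprintf("c%d", r))$curve)
  groups <- rep(c("WT", "OEIF2"), each = 3)
  js <- jip_summary(curves, groups, reference = "WT")
  expect_equal(nrow(js$per_curve), 6)
  expect_equal(js$n_excluded, 0)
  # identical noise-free curves within a group: SE = 0
  se_fvfm <- js$group_stats$se[js$group_stats$parameter == "fv_fm"]
  expect_equal(se_fvfm, c(0, 0), tolerance = 1e-12)
  expect_equal(js$group_stats$pct_change_vs_ref[
    js$group_stats$group == "WT"], rep(0, 8), tolerance = 1e-9)

  # group pairs differing only in Fo/Fm order correctly in fv_fm
  lo <- lapply(1:3, function(r) generate_ojip(fo = 625, noise_cv = 0,
                                              seed = r)$curve)
  hi <- lapply(1:3, function(r) generate_ojip(fo = 375, noise_cv = 0,
                                              seed = r)$curve)
  js2 <- jip_summary(c(lo, hi), rep(c("lo", "hi"), each = 3),
                     reference = "hi")
  pct <- js2$group_stats$pct_change_vs_ref[
    js2$group_stats$group == "lo" & js2$group_stats$parameter == "fv_fm"]
  expect_lt(pct, 0)   # higher Fo/Fm means lower Fv/Fm than the reference

  # a flat curve is excluded, not fatal
  flat <- induction_curve(knot_grid(), rep(1000, length(knot_grid())))
  js3 <- jip_summary(c(curves, list(flat)), c(groups, "WT"))
  expect_equal(js3$n_excluded, 1)
  expect_equal(nrow(js3$per_curve), 7)
})
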