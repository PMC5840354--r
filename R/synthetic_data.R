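#' Closed-form OJIP model curve
#'
#' The synthetic transient is a weighted sum of three Hill-type sigmoids in
#' time, one per rise phase (O-J, J-I, I-P):
#' `F(t) = Fo + (Fm - Fo) * sum_k w_k / (1 + (tau_k / t)^h_k)`.
#' This is not a mechanistic PSII model; it reproduces the O-J-I-P phase
#' geometry with an analytically known relative variable fluorescence at any
#' time, so recovery can be checked against exact ground truth.
#'
#' @param times Times in seconds.
#' @param fo,fm Asymptotic minimum and maximum fluorescence.
#' @param weights Phase weights `(wJ, wI, wP)`, nonnegative, summing to 1.
#' @param tau Phase half-times in seconds, increasing.
#' @param steepness Hill exponents, >= 1.
#' @return Noise-free fluorescence values at `times`.
#' @export
ojip_closed_form <- function(times, fo = 500, fm = 2500,
                             weights = c(0.5, 0.25, 0.25),
                             tau = c(4e-4, 1e-2, 1e-1),
                             steepness = c(2, 2, 2)) {
  assert_that(length(weights) == 3 && length(tau) == 3 &&
                length(steepness) == 3, "need 3 phases")
  assert_that(all(weights >= 0) && abs(sum(weights) - 1) <= 1e-12,
              "weights must be nonnegative and sum to 1")
  assert_that(all(diff(tau) > 0), "half-times must be increasing")
  assert_that(all(steepness >= 1), "steepness must be >= 1")
  assert_that(fm > fo && fo > 0, "need Fm > Fo > 0")
  rise <- Reduce(`+`, lapply(1:3, function(k) {
    weights[k] / (1 + (tau[k] / times)^steepness[k])
  }))
  fo + (fm - fo) * rise
}

#' Simulate a fast fluorescence induction curve with known ground truth
#'
#' Evaluates [ojip_closed_form()] on a log-spaced grid and applies
#' multiplicative Gaussian noise `(1 + e_t)`, `e_t ~ N(0, noise_cv^2)`
#' independently per sample. The same seed gives bitwise-identical output.
#'
#' @inheritParams ojip_closed_form
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_points Number of log-spaced samples (default 118).
#' @param t_min,t_max Grid limits in seconds.
#' @param seed Integer seed.
#' @param label Curve label.
#' @param metadata Metadata tags for the curve.
#' @return List with `curve` (an [induction_curve]) and `truth`: the
#'   generating parameters plus the exact noise-free `fv_fm`
#'   (`1 - Fo/Fm`) and the closed-form V at the standard marker times.
#' @export
generate_ojip <- function(fo = 500, fm = 2500, weights = c(0.5, 0.25, 0.25),
                          tau = c(4e-4, 1e-2, 1e-1), steepness = c(2, 2, 2),
                          noise_cv = 0.01, n_points = 118,
                          t_min = 1e-5, t_max = 1, seed = 1,
                          label = sprintf("sim-ojip-%d", seed),
                          metadata = list()) {
  assert_that(noise_cv >= 0, "noise_cv must be >= 0")
  assert_that(n_points >= 20, "need at least 20 points")
  times <- 10^seq(log10(t_min), log10(t_max), length.out = n_points)
  f <- ojip_closed_form(times, fo, fm, weights, tau, steepness)
  noisy <- withr::with_seed(seed, f * (1 + rnorm(n_points, 0, noise_cv)))
  v_at <- function(t) {
    (ojip_closed_form(t, fo, fm, weights, tau, steepness) - fo) / (fm - fo)
  }
  list(
    curve = induction_curve(times, noisy, label = label, metadata = metadata),
    truth = list(fo = fo, fm = fm, weights = weights, tau = tau,
                 steepness = steepness, noise_cv = noise_cv, seed = seed,
                 fv_fm = 1 - fo / fm,
                 v_j = v_at(2e-3), v_i = v_at(3e-2),
                 f_20us = ojip_closed_form(2e-5, fo, fm, weights, tau,
                                           steepness))
  )
}

#' Simulate an 820 nm transmittance record with known trough depth
#'
#' The normalized deterministic shape is
#' `I(t)/I0 = 1 - A * g(t) / max(g)` with
#' `g(t) = (1 - exp(-t/tau_ox)) * exp(-t/tau_red)`: a monotone oxidation
#' phase followed by re-reduction (recovery). Scaling `g` by its maximum
#' makes the programmed amplitude `A` the exact realized trough depth, so
#' recovery checks have analytic ground truth. Multiplicative Gaussian noise
#' as in [generate_ojip()].
#'
#' @param amplitude Trough depth `A` in (0, 1).
#' @param tau_ox,tau_red Oxidation and re-reduction time constants, seconds,
#'   `tau_ox < tau_red`.
#' @param noise_cv Multiplicative noise CV (default 0.002).
#' @param n_points Number of samples (default 120).
#' @param t_max Record length in seconds (default 2).
#' @param i0 Initial intensity in instrument units.
#' @param seed Integer seed.
#' @param label Curve label.
#' @param metadata Metadata tags.
#' @return List with `curve` (a [transmittance_curve], un-normalized) and
#'   `truth` (parameters, exact trough time `t_min` and amplitude).
#' @export
generate_820 <- function(amplitude = 0.05, tau_ox = 0.02, tau_red = 0.5,
                         noise_cv = 0.002, n_points = 120, t_max = 2,
                         i0 = 1000, seed = 1,
                         label = sprintf("sim-820-%d", seed),
                         metadata = list()) {
  assert_that(amplitude > 0 && amplitude < 1, "amplitude must be in (0, 1)")
  assert_that(tau_ox > 0 && tau_red > 0 && tau_ox < tau_red,
              "need 0 < tau_ox < tau_red")
  assert_that(noise_cv >= 0, "noise_cv must be >= 0")
  times <- seq(0, t_max, length.out = n_points)
  g <- (1 - exp(-times / tau_ox)) * exp(-times / tau_red)
  # analytic argmax of g: exp(-t/tau_ox) = tau_ox/(tau_ox + tau_red)
  t_star <- tau_ox * log((tau_ox + tau_red) / tau_ox)
  g_max <- (1 - exp(-t_star / tau_ox)) * exp(-t_star / tau_red)
  shape <- 1 - amplitude * g / g_max
  noisy <- withr::with_seed(seed,
                            i0 * shape * (1 + rnorm(n_points, 0, noise_cv)))
  list(
    curve = transmittance_curve(times, noisy, label = label,
                                metadata = metadata),
    truth = list(amplitude = amplitude, tau_ox = tau_ox, tau_red = tau_red,
                 noise_cv = noise_cv, seed = seed, t_min = t_star, i0 = i0)
  )
}

#' Simulate a long-format trait table from group means and SEs
#'
#' Each replicate value is `mean + N(0, (se * sqrt(n))^2)`: the configured
#' `se` is the standard error of the group mean at the configured group size,
#' matching how agronomic tables report mean +/- SE.
#'
#' @param config Data frame with columns `genotype, treatment, trait, mean,
#'   se`; defaults to the packaged yield-trait fixture
#'   ([yield_trait_fixture()]).
#' @param n Replicates per group (default 9: three biological x three
#'   technical replicates).
#' @param seed Integer seed.
#' @return List with `table` (a [trait_table()]) and `truth` (the config).
#' @export
generate_traits <- function(config = yield_trait_fixture(), n = 9, seed = 1) {
  need <- c("genotype", "treatment", "trait", "mean", "se")
  assert_that(all(need %in% names(config)),
              sprintf("config needs columns %s", paste(need, collapse = ", ")))
  assert_that(all(config$se >= 0), "SEs must be >= 0")
  assert_that(n >= 1, "need n >= 1")
  rows <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(config)), function(i) {
      data.frame(
        genotype = config$genotype[i], treatment = config$treatment[i],
        replicate = seq_len(n), trait = config$trait[i],
        value = config$mean[i] + rnorm(n, 0, config$se[i] * sqrt(n)),
        stringsAsFactors = FALSE
      )
    }))
  })
  list(table = trait_table(rows), truth = config)
}

#' Simulate qPCR Ct records with programmed relative quantities
#'
#' Reference-gene Cts are `N(ct_ref_mean, noise_sd^2)`; target Cts are
#' `Ct_ref + dct_calibrator - log2(rq_true) + noise`, so that the ddCt method
#' recovers `rq_true` exactly at zero noise and in expectation otherwise.
#' The first sample in `rq_true` is the intended calibrator and should have
#' `rq_true = 1`.
#'
#' @param rq_true Named positive vector: true relative quantity per sample.
#' @param ct_ref_mean Mean reference-gene Ct (default 20).
#' @param dct_calibrator dCt of the calibrator sample (default 2).
#' @param noise_sd Ct noise standard deviation (default 0.1).
#' @param replicates Replicate wells per (sample, gene) (default 3).
#' @param seed Integer seed.
#' @return List with `cts` (a [ct_table()]) and `truth`.
#' @export
generate_ct <- function(rq_true, ct_ref_mean = 20, dct_calibrator = 2,
                        noise_sd = 0.1, replicates = 3, seed = 1) {
  assert_that(is.numeric(rq_true) && all(rq_true > 0),
              "rq_true must be positive")
  assert_that(!is.null(names(rq_true)) && all(nzchar(names(rq_true))),
              "rq_true must be a named vector of samples")
  assert_that(noise_sd >= 0 && replicates >= 1, "invalid noise/replicates")
  rows <- withr::with_seed(seed, {
    do.call(rbind, lapply(names(rq_true), function(s) {
      ref <- ct_ref_mean + rnorm(replicates, 0, noise_sd)
      tgt <- ct_ref_mean + dct_calibrator - log2(rq_true[[s]]) +
        rnorm(replicates, 0, noise_sd)
      rbind(
        data.frame(sample = s, gene = "ref_gene", role = "reference",
                   ct = ref, stringsAsFactors = FALSE),
        data.frame(sample = s, gene = "target_gene", role = "target",
                   ct = tgt, stringsAsFactors = FALSE)
      )
    }))
  })
  list(cts = ct_table(rows), truth = list(rq_true = rq_true,
                                          dct_calibrator = dct_calibrator,
                                          noise_sd = noise_sd, seed = seed))
}

#' Simulate a metabolite matrix with programmed up/down sets
#'
#' Intensities follow
#' `2^(baseline_m + effect_m * [stress]) * loading_s * (1 + N(0, cv^2))`,
#' where `loading_s` is a per-sample extraction/injection factor and the
#' internal-standard column carries the loading alone, so ribitol
#' normalization removes it exactly. Disjoint up and down sets per time point
#' receive log2 effects `+effect` and `-effect`.
#'
#' @param n_metabolites Number of metabolites beside the internal standard.
#' @param n_up,n_down Sizes of the programmed up/down sets per time point.
#' @param effect Programmed |log2 fold change| (default 1.5).
#' @param cv Multiplicative noise CV (default 0.1).
#' @param replicates Replicates per (genotype, condition, time point).
#' @param genotypes Genotype labels (default WT and OEIF2).
#' @param timepoints Time-point labels (default 24 h/48 h/72 h).
#' @param loading_sd SD of log2 per-sample loading factors (default 0.2).
#' @param seed Integer seed.
#' @return List with `matrix` (a [metabolite_matrix()]) and `truth`: per
#'   genotype and time point the programmed `up` and `down` metabolite sets.
#' @export
generate_metabolites <- function(n_metabolites = 60, n_up = 8, n_down = 8,
                                 effect = 1.5, cv = 0.1, replicates = 3,
                                 genotypes = c("WT", "OEIF2"),
                                 timepoints = c("24h", "48h", "72h"),
                                 loading_sd = 0.2, seed = 1) {
  assert_that(n_up + n_down <= n_metabolites,
              "up and down sets must be disjoint subsets of the metabolites")
  assert_that(cv >= 0 && effect >= 0, "cv and effect must be >= 0")
  mets <- sprintf("met_%03d", seq_len(n_metabolites))
  withr::with_seed(seed, {
    baseline <- rnorm(n_metabolites, mean = 10, sd = 1.5)
    names(baseline) <- mets
    truth <- list()
    effects <- list()
    for (g in genotypes) {
      truth[[g]] <- list()
      effects[[g]] <- list()
      for (tp in timepoints) {
        pick <- sample(mets, n_up + n_down)
        up <- sort(pick[seq_len(n_up)])
        down <- sort(pick[n_up + seq_len(n_down)])
        truth[[g]][[tp]] <- list(up = up, down = down)
        e <- setNames(numeric(n_metabolites), mets)
        e[up] <- effect
        e[down] <- -effect
        effects[[g]][[tp]] <- e
      }
    }
    rows <- list()
    for (g in genotypes) for (tp in timepoints) {
      for (cond in c("control", "stress")) for (r in seq_len(replicates)) {
        loading <- 2^rnorm(1, 0, loading_sd)
        mu <- baseline + if (cond == "stress") effects[[g]][[tp]] else 0
        intens <- 2^mu * loading * (1 + rnorm(n_metabolites, 0, cv))
        intens <- pmax(intens, 0)
        row <- data.frame(
          sample = sprintf("%s_%s_%s_r%d", g, cond, tp, r),
          genotype = g, condition = cond, timepoint = tp, replicate = r,
          ribitol = loading, stringsAsFactors = FALSE
        )
        row[mets] <- as.list(intens)
        rows[[length(rows) + 1L]] <- row
      }
    }
    mat <- metabolite_matrix(do.call(rbind, rows))
    list(matrix = mat,
         truth = list(sets = truth, baseline = baseline, effect = effect,
                      cv = cv, seed = seed))
  })
}
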