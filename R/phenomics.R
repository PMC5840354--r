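#' Percent change and percent reduction
#'
#' `percent_change(v, r) = 100 (v - r) / r` (signed) and
#' `percent_reduction(v, r) = 100 (1 - v / r) = -percent_change(v, r)`.
#' These are the quantities behind statements like "yield fell by 77%
#' relative to the tolerant line".
#'
#' @param value Observed value.
#' @param reference Reference (baseline) value, nonzero.
#' @return Percent, signed, unrounded.
#' @export
percent_change <- function(value, reference) {
  assert_that(is.numeric(value) && is.numeric(reference),
              "inputs must be numeric")
  assert_that(all(reference != 0), "reference must be nonzero")
  100 * (value - reference) / reference
}

#' @rdname percent_change
#' @export
percent_reduction <- function(value, reference) {
  -percent_change(value, reference)
}

#' Germination percentage
#'
#' @param n_germinated,n_total Counts, `0 <= n_germinated <= n_total`.
#' @return Percent germinated.
#' @export
germination_percentage <- function(n_germinated, n_total) {
  assert_that(all(n_total > 0), "n_total must be > 0")
  assert_that(all(n_germinated >= 0), "n_germinated must be >= 0")
  assert_that(all(n_germinated <= n_total),
              "n_germinated cannot exceed n_total")
  100 * n_germinated / n_total
}

#' Potassium to sodium concentration ratio
#'
#' Higher shoot K+/Na+ under salinity indicates better ion homeostasis.
#'
#' @param k_conc,na_conc Concentrations in the same unit; `na_conc > 0`.
#' @return Dimensionless ratio.
#' @export
kna_ratio <- function(k_conc, na_conc) {
  assert_that(all(na_conc > 0), "Na+ concentration must be > 0")
  k_conc / na_conc
}

#' Electrolyte leakage percentage
#'
#' Ratio of the initial conductivity of the tissue bathing solution to the
#' total conductivity after complete lysis, times 100 (the EC1/EC2
#' convention of the standard membrane-injury protocol).
#'
#' @param ec_initial,ec_total Conductivities, `0 <= ec_initial <= ec_total`.
#' @return Percent leakage in `[0, 100]`.
#' @export
electrolyte_leakage <- function(ec_initial, ec_total) {
  assert_that(all(ec_total > 0), "total conductivity must be > 0")
  assert_that(all(ec_initial >= 0), "initial conductivity must be >= 0")
  assert_that(all(ec_initial <= ec_total),
              "initial conductivity cannot exceed total")
  100 * ec_initial / ec_total
}

#' Read a long-format trait table
#'
#' Expects CSV columns `genotype,treatment,replicate,trait,value`; duplicate
#' (genotype, treatment, replicate, trait) keys are rejected.
#'
#' @param path CSV path.
#' @return A data frame of class `trait_table`.
#' @export
read_trait_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  trait_table(df)
}

#' @rdname read_trait_table
#' @param df Data frame with the five required columns.
#' @export
trait_table <- function(df) {
  need <- c("genotype", "treatment", "replicate", "trait", "value")
  assert_that(all(need %in% names(df)),
              sprintf("trait table must have columns %s",
                      paste(need, collapse = ", ")))
  assert_that(nrow(df) >= 1, "trait table is empty")
  assert_that(all(is.finite(df$value)), "trait values must be finite",
              class = "phytojip_validation_error")
  key <- paste(df$genotype, df$treatment, df$replicate, df$trait, sep = "\r")
  dup <- anyDuplicated(key)
  if (dup > 0) {
    pj_stop(sprintf("duplicate trait record: %s / %s / rep %s / %s",
                    df$genotype[dup], df$treatment[dup], df$replicate[dup],
                    df$trait[dup]),
            class = "phytojip_validation_error")
  }
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Per-group mean and standard error for every trait
#'
#' One row per (genotype, treatment, trait) with `n`, `mean` and
#' `se = sd/sqrt(n)`. Groups with a single replicate get `se = 0` and are
#' flagged.
#'
#' @param table A [trait_table()] (or plain data frame with its columns).
#' @return Data frame with columns genotype, treatment, trait, n, mean, se,
#'   flagged.
#' @export
group_summaries <- function(table) {
  if (!inherits(table, "trait_table")) table <- trait_table(table)
  out <- do.call(rbind, lapply(
    split(table, list(table$genotype, table$treatment, table$trait),
          drop = TRUE),
    function(d) {
      n <- nrow(d)
      data.frame(genotype = d$genotype[1], treatment = d$treatment[1],
                 trait = d$trait[1], n = n, mean = mean(d$value),
                 se = if (n > 1) sd(d$value) / sqrt(n) else 0,
                 flagged = n == 1, stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$trait, out$treatment, out$genotype), ]
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA via [stats::aov()]: between/within
#' sums of squares, `F = MSB/MSW`, and the upper-tail F p value.
#'
#' @param groups List of >= 2 numeric vectors, each with n >= 2.
#' @return List with `f`, `p`, `df` (c(between, within)), `mse` (the pooled
#'   within-group mean square) and `group_means`.
#' @export
one_way_anova <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2,
              "need at least 2 groups")
  sizes <- lengths(groups)
  assert_that(all(sizes >= 2), "every group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  fit <- aov(y ~ g)
  tab <- summary(fit)[[1]]
  msw <- tab["Residuals", "Mean Sq"]
  msb <- tab[1, "Mean Sq"]
  # guard against rounding dust when the data are exactly constant
  eps <- 1e-12 * (mean(y^2) + 1)
  if (msb < eps && msw < eps) {
    f <- 0; p <- 1; msw <- 0   # no variance to partition at all
  } else if (msw < eps) {
    f <- Inf; p <- 0; msw <- 0 # separated constants: infinitely strong signal
  } else {
    f <- tab[1, "F value"]
    p <- tab[1, "Pr(>F)"]
  }
  list(f = f, p = p, df = c(between = tab[1, "Df"],
                            within = tab["Residuals", "Df"]),
       mse = msw, group_means = vapply(groups, mean, numeric(1)),
       group_n = sizes)
}

#' Protected least-significant-difference pairwise comparisons
#'
#' Fisher's LSD applied only when the omnibus one-way ANOVA is significant
#' at `alpha` ("protected"): if the ANOVA p value is >= alpha, no pair is
#' declared significant; otherwise pair (i, j) is significant when
#' `|mean_i - mean_j| > t(1 - alpha/2, dfW) * sqrt(MSE (1/n_i + 1/n_j))`.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return List with the `anova` result, `lsd` (matrix of least significant
#'   differences), `significant` (logical matrix) and `protected` (TRUE when
#'   the omnibus gate blocked all comparisons).
#' @export
protected_lsd <- function(groups, alpha = 0.05) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  an <- one_way_anova(groups)
  k <- length(groups)
  nm <- names(groups) %||% paste0("g", seq_len(k))
  means <- an$group_means
  n <- an$group_n
  tcrit <- qt(1 - alpha / 2, df = an$df[["within"]])
  lsd <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  sig <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  gate_open <- is.finite(an$p) && an$p < alpha
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      lsd[i, j] <- lsd[j, i] <- tcrit * sqrt(an$mse * (1 / n[i] + 1 / n[j]))
      if (gate_open) {
        sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > lsd[i, j]
      }
    }
  }
  list(anova = an, lsd = lsd, significant = sig, protected = !gate_open,
       alpha = alpha)
}

#' Student's two-sample t test
#'
#' Pooled-variance (classical Student) unpaired test by default, or a paired
#' test; two-sided. Welch's unequal-variance form is available with
#' `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors with n >= 2 (equal lengths if paired).
#' @param paired Paired test?
#' @param var_equal Pool the variances (classical Student)? Default TRUE.
#' @return List with `t`, `p` and `df`.
#' @export
two_sample_t <- function(a, b, paired = FALSE, var_equal = TRUE) {
  assert_that(length(a) >= 2 && length(b) >= 2, "need n >= 2 in each sample")
  if (paired) {
    assert_that(length(a) == length(b), "paired samples must have equal n")
  }
  if (identical(as.numeric(a), as.numeric(b))) {
    # degenerate zero-difference case: t.test errors on zero variance
    return(list(t = 0, p = 1,
                df = if (paired) length(a) - 1 else length(a) + length(b) - 2))
  }
  ht <- t.test(a, b, paired = paired, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}
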