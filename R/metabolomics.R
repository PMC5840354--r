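#' Metabolite intensity matrices
#'
#' A `metabolite_matrix` is a data frame with one row per GC-MS sample: the
#' metadata columns `sample, genotype, condition, timepoint, replicate`
#' followed by one numeric column per metabolite, one of which is the spiked
#' internal standard (ribitol by convention) used to correct for extraction
#' and injection variation.
#'
#' @param df Data frame as described above.
#' @param internal_standard Name of the internal-standard column.
#' @return Data frame of class `metabolite_matrix` with attributes
#'   `internal_standard` and `normalized`.
#' @export
metabolite_matrix <- function(df, internal_standard = "ribitol") {
  meta_cols <- c("sample", "genotype", "condition", "timepoint", "replicate")
  assert_that(all(meta_cols %in% names(df)),
              sprintf("metabolite matrix needs metadata columns %s",
                      paste(meta_cols, collapse = ", ")))
  mets <- setdiff(names(df), meta_cols)
  assert_that(length(mets) >= 2, "need at least 2 metabolite columns")
  assert_that(internal_standard %in% mets,
              sprintf("internal standard column '%s' not found",
                      internal_standard))
  assert_that(all(vapply(df[mets], is.numeric, logical(1))),
              "metabolite columns must be numeric")
  assert_that(!anyNA(df[meta_cols]), "sample metadata must be complete",
              class = "phytojip_validation_error")
  key <- do.call(paste, c(df[meta_cols], sep = "\r"))
  assert_that(anyDuplicated(key) == 0, "duplicate sample rows",
              class = "phytojip_validation_error")
  vals <- as.matrix(df[mets])
  assert_that(all(is.na(vals) | vals >= 0),
              "metabolite intensities must be nonnegative",
              class = "phytojip_validation_error")
  bad <- which(!(df[[internal_standard]] > 0))
  if (length(bad)) {
    pj_stop(sprintf("internal standard is not positive in sample '%s'",
                    df$sample[bad[1]]),
            class = "phytojip_validation_error")
  }
  structure(df, class = c("metabolite_matrix", "data.frame"),
            internal_standard = internal_standard,
            normalized = isTRUE(attr(df, "normalized")))
}

#' @rdname metabolite_matrix
#' @param path CSV path (samples as rows, metadata columns first).
#' @export
read_metabolite_matrix <- function(path, internal_standard = "ribitol") {
  metabolite_matrix(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                    internal_standard = internal_standard)
}

metabolite_names <- function(m) {
  setdiff(names(m), c("sample", "genotype", "condition", "timepoint",
                      "replicate"))
}

#' Internal-standard (ribitol) normalization
#'
#' Divides every metabolite intensity of a sample by that sample's
#' internal-standard intensity, cancelling per-sample extraction/injection
#' loading; the internal-standard column becomes 1.
#'
#' @param m A [metabolite_matrix()].
#' @return The normalized [metabolite_matrix()] (`normalized` attribute set).
#' @export
normalize_internal_standard <- function(m) {
  assert_that(inherits(m, "metabolite_matrix"), "need a metabolite_matrix")
  std <- attr(m, "internal_standard")
  mets <- metabolite_names(m)
  m[mets] <- m[mets] / m[[std]]
  attr(m, "normalized") <- TRUE
  metabolite_matrix_keep_attrs(m)
}

metabolite_matrix_keep_attrs <- function(m) {
  out <- metabolite_matrix(as.data.frame(m, check.names = FALSE),
                           internal_standard = attr(m, "internal_standard"))
  attr(out, "normalized") <- isTRUE(attr(m, "normalized"))
  out
}

#' Drop metabolites missing in too many samples
#'
#' Zero or NA intensities are treated as missing (not imputed); metabolites
#' missing in more than `max_missing_frac` of the samples are removed,
#' mirroring the convention of reporting a compound only when detected in at
#' least half of the samples.
#'
#' @param m A [metabolite_matrix()].
#' @param max_missing_frac Maximum tolerated missing fraction (default 0.5).
#' @return A [metabolite_matrix()]; dropped names in attribute `dropped`.
#' @export
drop_sparse_metabolites <- function(m, max_missing_frac = 0.5) {
  assert_that(inherits(m, "metabolite_matrix"), "need a metabolite_matrix")
  mets <- metabolite_names(m)
  frac <- vapply(m[mets], function(x) mean(is.na(x) | x == 0), numeric(1))
  drop <- names(frac)[frac > max_missing_frac]
  std <- attr(m, "internal_standard")
  was_normalized <- isTRUE(attr(m, "normalized"))
  drop <- setdiff(drop, std)
  sub <- as.data.frame(m)[, setdiff(names(m), drop), drop = FALSE]
  out <- metabolite_matrix(sub, internal_standard = std)
  attr(out, "normalized") <- was_normalized
  attr(out, "dropped") <- drop
  out
}

#' Decimal log transform of intensities
#'
#' `log10(value + offset)` applied to every metabolite column; the offset
#' (default 1e-9 of the median positive intensity) keeps structural zeros
#' finite without materially moving detected signals.
#'
#' @param m A [metabolite_matrix()].
#' @param offset Small positive shift; `NULL` for the default.
#' @return A [metabolite_matrix()] of log10 intensities (attribute
#'   `log_transformed` set; not suitable for [fold_change_matrix()], which
#'   expects linear-scale intensities).
#' @export
log_transform <- function(m, offset = NULL) {
  assert_that(inherits(m, "metabolite_matrix"), "need a metabolite_matrix")
  mets <- metabolite_names(m)
  vals <- as.matrix(m[mets])
  assert_that(all(is.na(vals) | vals >= 0), "negative intensity")
  if (is.null(offset)) {
    offset <- 1e-9 * stats::median(vals[is.finite(vals) & vals > 0])
  }
  assert_that(is.finite(offset) && offset >= 0, "offset must be >= 0")
  m[mets] <- log10(m[mets] + offset)
  out <- m
  class(out) <- c("metabolite_matrix", "data.frame")
  attr(out, "log_transformed") <- TRUE
  out
}

#' log2 stress/control fold-change matrix
#'
#' For one genotype, the entry for metabolite m at time point t is
#' `log2(mean stress intensity / mean control intensity)`, computed on
#' internal-standard-normalized intensities (normalization is applied first
#' if the matrix is still raw). Entries whose control or stress group mean
#' is not positive, or whose condition is absent at a time point, are NA and
#' listed in the `flagged` attribute — never silently zeroed.
#'
#' @param m A [metabolite_matrix()].
#' @param genotype Genotype label to extract.
#' @param conditions Length-2 character vector naming the control and stress
#'   levels of the `condition` column.
#' @return Matrix (metabolites x time points) of class `fold_change_matrix`
#'   with attributes `genotype` and `flagged`.
#' @export
fold_change_matrix <- function(m, genotype,
                               conditions = c(control = "control",
                                              stress = "stress")) {
  assert_that(inherits(m, "metabolite_matrix"), "need a metabolite_matrix")
  if (!isTRUE(attr(m, "normalized"))) m <- normalize_internal_standard(m)
  d <- m[m$genotype == genotype, , drop = FALSE]
  assert_that(nrow(d) > 0, sprintf("no samples for genotype '%s'", genotype))
  mets <- setdiff(metabolite_names(m), attr(m, "internal_standard"))
  tps <- unique(d$timepoint)
  fc <- matrix(NA_real_, length(mets), length(tps),
               dimnames = list(mets, tps))
  flagged <- character(0)
  for (tp in tps) {
    ctrl <- d[d$timepoint == tp & d$condition == conditions[["control"]], mets,
              drop = FALSE]
    strs <- d[d$timepoint == tp & d$condition == conditions[["stress"]], mets,
              drop = FALSE]
    if (nrow(ctrl) == 0 || nrow(strs) == 0) {
      flagged <- c(flagged, sprintf("%s: missing condition", tp))
      next
    }
    mc <- colMeans(as.matrix(ctrl))
    ms <- colMeans(as.matrix(strs))
    ok <- is.finite(mc) & is.finite(ms) & mc > 0 & ms > 0
    fc[ok, tp] <- log2(ms[ok] / mc[ok])
    if (any(!ok)) {
      flagged <- c(flagged,
                   sprintf("%s: undefined ratio for %s", tp,
                           paste(mets[!ok], collapse = ", ")))
    }
  }
  structure(fc, class = c("fold_change_matrix", "matrix", "array"),
            genotype = genotype, flagged = flagged)
}

#' Classify metabolites into up/down Venn sets per time point
#'
#' A metabolite is "up" in a genotype when its log2 fold change exceeds
#' `threshold` and "down" when it is below `-threshold` (default 0: the sign
#' rule). For each time point the up and down sets of the two genotypes are
#' partitioned into first-only, second-only and shared members.
#'
#' @param fc_a,fc_b `fold_change_matrix` objects on the same metabolite and
#'   time-point axes (e.g. wild type and an overexpression line).
#' @param threshold Nonnegative log2 cutoff.
#' @return Named list per time point, each with `up` and `down`, each holding
#'   `a_only`, `b_only`, `shared` membership vectors and `counts`.
#' @export
classify_venn <- function(fc_a, fc_b, threshold = 0) {
  assert_that(inherits(fc_a, "fold_change_matrix") &&
                inherits(fc_b, "fold_change_matrix"),
              "need two fold_change_matrix objects")
  assert_that(identical(dimnames(fc_a), dimnames(fc_b)),
              "fold-change matrices must share metabolite and time-point axes")
  assert_that(threshold >= 0, "threshold must be >= 0")
  out <- lapply(colnames(fc_a), function(tp) {
    a <- fc_a[, tp]; b <- fc_b[, tp]
    sets <- function(up) {
      pick <- function(x) {
        names(x)[!is.na(x) & (if (up) x > threshold else x < -threshold)]
      }
      sa <- pick(a); sb <- pick(b)
      list(a_only = setdiff(sa, sb), b_only = setdiff(sb, sa),
           shared = intersect(sa, sb),
           counts = c(a_only = length(setdiff(sa, sb)),
                      b_only = length(setdiff(sb, sa)),
                      shared = length(intersect(sa, sb))))
    }
    list(up = sets(TRUE), down = sets(FALSE))
  })
  names(out) <- colnames(fc_a)
  attr(out, "genotypes") <- c(a = attr(fc_a, "genotype"),
                              b = attr(fc_b, "genotype"))
  out
}

#' Unsupervised PCA of a metabolite matrix
#'
#' Principal component analysis of the internal-standard-normalized
#' intensities via [stats::prcomp()]: columns are mean-centered and (by
#' default) unit-variance scaled; zero-variance metabolites (including the
#' normalized internal standard) are removed first.
#'
#' @param m A [metabolite_matrix()] (normalized first if raw).
#' @param scale. Unit-variance scaling (default TRUE).
#' @return List with `scores` (samples x PC), `loadings` (metabolites x PC),
#'   `explained` (variance fractions, summing to 1) and `dropped`
#'   (zero-variance metabolites).
#' @export
metab_pca <- function(m, scale. = TRUE) {
  assert_that(inherits(m, "metabolite_matrix"), "need a metabolite_matrix")
  if (!isTRUE(attr(m, "normalized"))) m <- normalize_internal_standard(m)
  mets <- metabolite_names(m)
  x <- as.matrix(m[mets])
  assert_that(nrow(x) >= 2, "PCA needs at least 2 samples")
  assert_that(!anyNA(x), "PCA input has missing entries; handle them first")
  v <- apply(x, 2, var)
  dropped <- colnames(x)[v == 0]
  x <- x[, v > 0, drop = FALSE]
  assert_that(ncol(x) >= 2, "fewer than 2 metabolites with nonzero variance",
              class = "phytojip_degenerate_error")
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  rownames(pc$x) <- m$sample
  list(scores = pc$x, loadings = pc$rotation, explained = expl,
       dropped = dropped)
}

#' Mean and 1.96 sd box-whisker summary
#'
#' Per-group mean with whisker half-width `1.96 * sd`: under normality the
#' whiskers span an approximate 95% range of the observations.
#'
#' @param groups Named list of numeric vectors.
#' @return Data frame with `group`, `n`, `mean`, `whisker`, `flagged`
#'   (groups with n < 2 get an NA whisker and a flag).
#' @export
box_whisker_summary <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 1, "need groups")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    x <- groups[[i]]
    n <- length(x)
    data.frame(group = nm[i], n = n, mean = mean(x),
               whisker = if (n >= 2) 1.96 * sd(x) else NA_real_,
               flagged = n < 2, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
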