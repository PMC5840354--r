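toy_matrix <- function(values, mets = paste0("m", seq_len(ncol(values))),
                       std = rep(1, nrow(values))) {
  n <- nrow(values)
  df <- data.frame(
    sample = paste0("s", 1:n),
    genotype = "WT",
    condition = rep(c("control", "stress"), length.out = n),
    timepoint = "24h",
    replicate = seq_len(n),
    ribitol = std
  )
  df[mets] <- as.data.frame(values)
  metabolite_matrix(df)
}

test_that("internal-standard normalization cancels per-sample loading exactly", {
  withr::with_seed(1, {
    base <- matrix(runif(40, 10, 100), nrow = 4)
    loading <- c(0.5, 1, 2, 4)
    m <- toy_matrix(base * loading, std = loading)
    norm <- normalize_internal_standard(m)
    vals <- as.matrix(as.data.frame(norm)[paste0("m", 1:10)])
    expect_equal(vals, base, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(norm$ribitol, rep(1, 4))
    # identity when the standard is already 1
    m1 <- toy_matrix(base)
    expect_equal(as.matrix(as.data.frame(normalize_internal_standard(m1))[
      paste0("m", 1:10)]), base, tolerance = 1e-12, ignore_attr = TRUE)
  })
  bad <- data.frame(sample = "s1", genotype = "WT", condition = "control",
                    timepoint = "24h", replicate = 1, ribitol = 0,
                    m1 = 5, m2 = 3)
  err <- tryCatch(metabolite_matrix(bad), error = identity)
  expect_match(conditionMessage(err), "s1")
})

test_that("generator loading factors vanish after normalization", {
  sim <- generate_metabolites(cv = 0, loading_sd = 0.5, seed = 4)
  norm <- normalize_internal_standard(sim$matrix)
  # control replicates of the same condition become identical rows
  d <- as.data.frame(norm)
  ctrl <- d[d$genotype == "WT" & d$condition == "control" &
              d$timepoint == "24h", grep("^met_", names(d))]
  expect_lt(max(apply(ctrl, 2, var)), 1e-18 * max(ctrl)^2)
})

test_that("log transform is monotone and tames skew", {
  sim <- generate_metabolites(cv = 0.3, seed = 2)
  norm <- normalize_internal_standard(sim$matrix)
  lg <- log_transform(norm)
  d0 <- as.data.frame(norm); d1 <- as.data.frame(lg)
  col <- "met_001"
  expect_equal(order(d1[[col]]), order(d0[[col]]))
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  sk0 <- abs(skew(unlist(d0[grep("^met_", names(d0))])))
  sk1 <- abs(skew(unlist(d1[grep("^met_", names(d1))])))
  expect_lt(sk1, sk0)
  expect_equal(log_transform(toy_matrix(matrix(1, 2, 2)), offset = 0)$m1,
               c(0, 0))
})

test_that("fold changes are exact for constructed ratios and flag zeros", {
  vals <- rbind(c(10, 8, 2), c(10, 8, 2),    # control
                c(10, 32, 2), c(10, 32, 2))  # stress
  m <- toy_matrix(vals[c(1, 3, 2, 4), ])     # interleave control/stress
  fc <- fold_change_matrix(m, "WT")
  expect_equal(unname(fc["m1", "24h"]), 0)
  expect_equal(unname(fc["m2", "24h"]), 2)
  # zero control mean flagged as NA, not zeroed
  vals0 <- vals; vals0[c(1, 3), 3] <- 0; vals0[2, 3] <- 0; vals0[4, 3] <- 0
  fc0 <- fold_change_matrix(toy_matrix(vals0[c(1, 3, 2, 4), ]), "WT")
  expect_true(is.na(fc0["m3", "24h"]))
  expect_true(length(attr(fc0, "flagged")) > 0)
})

test_that("programmed effects are recovered exactly without noise", {
  sim <- generate_metabolites(cv = 0, effect = 2, seed = 9)
  norm <- normalize_internal_standard(sim$matrix)
  fc <- fold_change_matrix(norm, "WT")
  for (tp in colnames(fc)) {
    up <- sim$truth$sets$WT[[tp]]$up
    down <- sim$truth$sets$WT[[tp]]$down
    rest <- setdiff(rownames(fc), c(up, down))
    expect_equal(unname(fc[up, tp]), rep(2, length(up)), tolerance = 1e-9)
    expect_equal(unname(fc[down, tp]), rep(-2, length(down)),
                 tolerance = 1e-9)
    expect_equal(unname(fc[rest, tp]), rep(0, length(rest)),
                 tolerance = 1e-9)
  }
})

test_that("Venn classification matches brute-force enumeration on a toy case", {
  fc_a <- matrix(c(1.2, -0.8, 0.3, 0, -2, 0.9), ncol = 1,
                 dimnames = list(paste0("m", 1:6), "24h"))
  fc_b <- matrix(c(1.5, 0.7, -0.4, 0, -1, 0.9), ncol = 1,
                 dimnames = list(paste0("m", 1:6), "24h"))
  class(fc_a) <- class(fc_b) <- c("fold_change_matrix", "matrix", "array")
  venn <- classify_venn(fc_a, fc_b, threshold = 0)
  # by hand: up_a = {m1,m3,m6}, up_b = {m1,m2,m6}; down_a = {m2,m5}, down_b = {m3,m5}
  expect_setequal(venn[["24h"]]$up$shared, c("m1", "m6"))
  expect_setequal(venn[["24h"]]$up$a_only, "m3")
  expect_setequal(venn[["24h"]]$up$b_only, "m2")
  expect_setequal(venn[["24h"]]$down$shared, "m5")
  expect_equal(unname(venn[["24h"]]$down$counts), c(1, 1, 1))

  # identical matrices: everything shared
  same <- classify_venn(fc_a, fc_a)
  expect_length(same[["24h"]]$up$a_only, 0)
  expect_length(same[["24h"]]$down$b_only, 0)

  # opposite signs: nothing shared
  neg <- fc_a * -1
  class(neg) <- class(fc_a)
  dimnames(neg) <- dimnames(fc_a)
  opp <- classify_venn(fc_a, neg)
  expect_length(opp[["24h"]]$up$shared, 0)
  expect_length(opp[["24h"]]$down$shared, 0)

  short <- fc_a[1:5, , drop = FALSE]
  class(short) <- class(fc_a)
  expect_error(classify_venn(fc_a, short), regexp = "axes")
})

test_that("end-to-end up/down recovery: exact at zero noise, sensitive at 10% CV", {
  sim0 <- generate_metabolites(cv = 0, effect = 1.5, seed = 21)
  fc_wt0 <- fold_change_matrix(sim0$matrix, "WT")
  fc_oe0 <- fold_change_matrix(sim0$matrix, "OEIF2")
  venn0 <- classify_venn(fc_wt0, fc_oe0, threshold = 0.5)
  for (tp in names(venn0)) {
    t_wt <- sim0$truth$sets$WT[[tp]]
    got_up <- c(venn0[[tp]]$up$a_only, venn0[[tp]]$up$shared)
    got_down <- c(venn0[[tp]]$down$a_only, venn0[[tp]]$down$shared)
    expect_setequal(got_up, t_wt$up)
    expect_setequal(got_down, t_wt$down)
  }

  sens <- vapply(1:15, function(s) {
    sim <- generate_metabolites(cv = 0.1, effect = 1.5, replicates = 3,
                                seed = s)
    fc_wt <- fold_change_matrix(sim$matrix, "WT")
    fc_oe <- fold_change_matrix(sim$matrix, "OEIF2")
    venn <- classify_venn(fc_wt, fc_oe, threshold = 0.5)
    found <- 0; total <- 0
    for (tp in names(venn)) {
      t_wt <- sim$truth$sets$WT[[tp]]
      got_up <- c(venn[[tp]]$up$a_only, venn[[tp]]$up$shared)
      got_down <- c(venn[[tp]]$down$a_only, venn[[tp]]$down$shared)
      found <- found + length(intersect(t_wt$up, got_up)) +
        length(intersect(t_wt$down, got_down))
      total <- total + length(t_wt$up) + length(t_wt$down)
    }
    found / total
  }, numeric(1))
  expect_true(all(sens >= 0.9))
})

test_that("normalize-then-subset equals subset-then-normalize", {
  sim <- generate_metabolites(cv = 0.1, seed = 6)
  m <- sim$matrix
  keep <- as.data.frame(m)$genotype == "WT"
  a <- normalize_internal_standard(m)
  a_sub <- as.matrix(as.data.frame(a)[keep, grep("^met_", names(a))])
  sub <- metabolite_matrix(as.data.frame(m)[keep, ])
  b_sub <- as.matrix(as.data.frame(normalize_internal_standard(sub))[
    grep("^met_", names(sub))])
  expect_equal(a_sub, b_sub, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sparse metabolites are dropped at the 50% rule", {
  vals <- matrix(5, nrow = 4, ncol = 3)
  vals[1:3, 2] <- 0          # missing in 75% of samples
  vals[1, 3] <- 0            # missing in 25%
  m <- toy_matrix(vals)
  out <- drop_sparse_metabolites(m)
  expect_equal(attr(out, "dropped"), "m2")
  expect_true(all(c("m1", "m3") %in% names(out)))
})

test_that("PCA fractions sum to 1, scores decorrelate, and match an svd oracle", {
  sim <- generate_metabolites(n_metabolites = 50, cv = 0.2, seed = 13)
  norm <- normalize_internal_standard(sim$matrix)
  pca <- metab_pca(norm)
  expect_equal(sum(pca$explained), 1, tolerance = 1e-9)
  cc <- crossprod(pca$scores) / (nrow(pca$scores) - 1)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8 * max(diag(cc)))

  # oracle: singular values of the centered+scaled matrix
  x <- as.matrix(as.data.frame(norm)[grep("^met_", names(norm))])
  xs <- scale(x[, apply(x, 2, var) > 0])
  sv <- svd(xs)$d
  oracle <- sv^2 / sum(sv^2)
  expect_equal(pca$explained[1:3], oracle[1:3], tolerance = 1e-8)

  # rank-1 case: two perfectly correlated metabolites
  r1 <- toy_matrix(cbind(1:6, 2 * (1:6)) + 0)
  pca1 <- metab_pca(r1, scale. = TRUE)
  expect_equal(pca1$explained[1], 1, tolerance = 1e-12)

  const <- toy_matrix(matrix(3, 4, 3))
  expect_error(metab_pca(const), class = "phytojip_degenerate_error")
})

test_that("box-whisker summaries use the 1.96 sd convention", {
  bw <- box_whisker_summary(list(a = c(0, 2), b = rep(5, 4), c = 1))
  expect_equal(bw$mean, c(1, 5, 1))
  expect_equal(bw$whisker[1], 1.96 * sqrt(2))
  expect_equal(bw$whisker[2], 0)
  expect_true(is.na(bw$whisker[3]) && bw$flagged[3])

  withr::with_seed(31, {
    x <- rnorm(10000, 3, 2)
    bw1 <- box_whisker_summary(list(x = x))
    inside <- mean(abs(x - bw1$mean) <= bw1$whisker)
    expect_lt(abs(inside - 0.95), 0.01)
  })
})
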