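#' Packaged yield-trait reference table
#'
#' Group means and standard errors of six agronomic traits for a rice
#' wild type (WT), an overexpression line (OEIF2) and a knock-down line
#' (KDIF2) under control, salinity and heat treatments, transcribed from a
#' published yield table (n = 9 per group: three biological x three
#' technical replicates). Used as the default configuration of
#' [generate_traits()] and by [yield_reduction_report()].
#'
#' @return Data frame with columns `genotype, treatment, trait, mean, se`.
#' @export
yield_trait_fixture <- function() {
  read.csv(system.file("extdata", "table1_yield_traits.csv",
                       package = "phytojip"),
           stringsAsFactors = FALSE)
}

#' Stress-induced percent reductions from the yield table
#'
#' Applies [percent_reduction()] to the packaged yield-trait means to
#' reproduce the headline stress-deficit percentages: each row names the
#' compared cells (genotype/treatment/trait vs a reference cell) and gives
#' the unrounded percent reduction alongside its integer display rounding.
#'
#' @param fixture Yield-trait table (defaults to [yield_trait_fixture()]).
#' @return Data frame with one row per comparison.
#' @export
yield_reduction_report <- function(fixture = yield_trait_fixture()) {
  cell <- function(g, tr, trait) {
    v <- fixture$mean[fixture$genotype == g & fixture$treatment == tr &
                        fixture$trait == trait]
    assert_that(length(v) == 1,
                sprintf("fixture cell missing: %s/%s/%s", g, tr, trait))
    v
  }
  comparisons <- list(
    list(id = "salinity_panicles_wt_vs_oe",
         desc = "salinity: WT panicles per plant vs OEIF2",
         value = cell("WT", "salinity", "panicles_per_plant"),
         reference = cell("OEIF2", "salinity", "panicles_per_plant")),
    list(id = "salinity_spikelets_wt_vs_oe",
         desc = "salinity: WT spikelets per panicle vs OEIF2",
         value = cell("WT", "salinity", "spikelets_per_panicle"),
         reference = cell("OEIF2", "salinity", "spikelets_per_panicle")),
    list(id = "heat_panicles_wt_vs_oe",
         desc = "heat: WT panicles per plant vs OEIF2",
         value = cell("WT", "heat", "panicles_per_plant"),
         reference = cell("OEIF2", "heat", "panicles_per_plant")),
    list(id = "heat_panicles_kd_vs_oe",
         desc = "heat: KDIF2 panicles per plant vs OEIF2",
         value = cell("KDIF2", "heat", "panicles_per_plant"),
         reference = cell("OEIF2", "heat", "panicles_per_plant")),
    list(id = "heat_filled_wt_vs_oe",
         desc = "heat: WT filled spikelets per panicle vs OEIF2",
         value = cell("WT", "heat", "filled_spikelets_per_panicle"),
         reference = cell("OEIF2", "heat", "filled_spikelets_per_panicle")),
    list(id = "heat_filled_kd_vs_oe",
         desc = "heat: KDIF2 filled spikelets per panicle vs OEIF2",
         value = cell("KDIF2", "heat", "filled_spikelets_per_panicle"),
         reference = cell("OEIF2", "heat", "filled_spikelets_per_panicle")),
    list(id = "heat_yield_wt_vs_oe",
         desc = "heat: WT total yield vs OEIF2",
         value = cell("WT", "heat", "total_yield_grains"),
         reference = cell("OEIF2", "heat", "total_yield_grains")),
    list(id = "heat_yield_kd_vs_oe",
         desc = "heat: KDIF2 total yield vs OEIF2",
         value = cell("KDIF2", "heat", "total_yield_grains"),
         reference = cell("OEIF2", "heat", "total_yield_grains")),
    list(id = "heat_yield_wt_vs_wt_control",
         desc = "heat: WT total yield vs WT control",
         value = cell("WT", "heat", "total_yield_grains"),
         reference = cell("WT", "control", "total_yield_grains"))
  )
  out <- do.call(rbind, lapply(comparisons, function(cm) {
    pct <- percent_reduction(cm$value, cm$reference)
    data.frame(id = cm$id, description = cm$desc, value = cm$value,
               reference = cm$reference, pct_reduction = pct,
               pct_display = round(pct), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

default_pipeline_config <- function(seed = 1, alpha = 0.05) {
  list(
    seed = seed,
    alpha = alpha,
    stages = c("traits", "ojip", "p700", "qpcr", "metabolomics"),
    reference_genotype = "WT",
    ojip = list(n_per_group = 6, noise_cv = 0.01,
                groups = list(WT = 0.20, OEIF2 = 0.19, KDIF2 = 0.21)),
    p700 = list(n_per_group = 6, noise_cv = 0.002,
                groups = list(OEIF2 = 0.07, KDIF2 = 0.05, WT = 0.03)),
    qpcr = list(rq_true = c(calibrator = 1, salt_24h = 2, salt_48h = 4),
                noise_sd = 0.1),
    metabolomics = list(n_metabolites = 60, n_up = 8, n_down = 8,
                        effect = 1.5, cv = 0.1, replicates = 3,
                        threshold = 0.5)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config),
                sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a list or a YAML path")
  base <- default_pipeline_config()
  cfg <- utils::modifyList(base, config)
  assert_that(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  cfg
}

log_stage <- function(lines, stage, msg) {
  c(lines, sprintf("%s [%s] %s",
                   format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg))
}

#' Run the full demonstration pipeline
#'
#' Simulates all five input kinds with the package generators (all
#' randomness derived from one top-level seed), analyzes each with the
#' corresponding module, and writes a report bundle: per-stage CSV tables,
#' a JSON summary (including the yield-table percent-reduction block), a
#' machine-parsable log and a MANIFEST listing every file with its producing
#' stage. Outputs are removed again if any stage fails.
#'
#' @param config A config list, a YAML file path, or `NULL` for the packaged
#'   demo configuration. Keys override [the defaults]: `seed`, `alpha`,
#'   `stages`, and per-stage generator settings.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("phytojip_run_"),
                         seed = NULL) {
  cfg <- read_pipeline_config(config %||% list())
  if (!is.null(seed)) cfg$seed <- seed
  assert_that(is.numeric(cfg$seed) && length(cfg$seed) == 1,
              "seed must be a single number")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  log_lines <- character(0)
  manifest <- data.frame(file = character(0), stage = character(0),
                         stringsAsFactors = FALSE)
  emit <- function(obj, file, stage, writer = write.csv) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    created <<- c(created, path)
    manifest <<- rbind(manifest, data.frame(file = file, stage = stage,
                                            stringsAsFactors = FALSE))
    path
  }
  csv_writer <- function(obj, path) write.csv(obj, path, row.names = FALSE)
  summary <- list(seed = cfg$seed, alpha = cfg$alpha, stages = list())

  ok <- tryCatch({
    for (stage in cfg$stages) {
      summary$stages[[stage]] <- switch(
        stage,
        traits = {
          sim <- generate_traits(n = 9, seed = cfg$seed)
          gs <- group_summaries(sim$table)
          emit(as.data.frame(sim$table), "traits_simulated.csv", "traits",
               csv_writer)
          emit(gs, "traits_group_summaries.csv", "traits", csv_writer)
          red <- yield_reduction_report()
          emit(red, "traits_percent_reductions.csv", "traits", csv_writer)
          log_lines <- log_stage(log_lines, "traits",
                                 sprintf("rows=%d groups=%d",
                                         nrow(sim$table), nrow(gs)))
          yld <- lapply(split(sim$table, sim$table$genotype), function(d)
            d$value[d$trait == "total_yield_grains" & d$treatment == "heat"])
          an <- one_way_anova(yld)
          list(n_records = nrow(sim$table),
               percent_reductions = red,
               heat_yield_anova = list(f = an$f, p = an$p))
        },
        ojip = {
          curves <- list(); groups <- character(0); i <- 0
          for (g in names(cfg$ojip$groups)) {
            for (r in seq_len(cfg$ojip$n_per_group)) {
              i <- i + 1
              sim <- generate_ojip(
                fo = 2500 * cfg$ojip$groups[[g]], fm = 2500,
                noise_cv = cfg$ojip$noise_cv,
                seed = cfg$seed * 1000 + i,
                label = sprintf("%s_%d", g, r))
              curves[[i]] <- sim$curve
              groups <- c(groups, g)
            }
          }
          js <- jip_summary(curves, groups,
                            reference = cfg$reference_genotype)
          emit(js$per_curve, "ojip_parameters.csv", "ojip", csv_writer)
          emit(js$group_stats, "ojip_group_stats.csv", "ojip", csv_writer)
          log_lines <- log_stage(log_lines, "ojip",
                                 sprintf("curves=%d excluded=%d",
                                         length(curves), js$n_excluded))
          list(n_curves = length(curves), n_excluded = js$n_excluded)
        },
        p700 = {
          curves <- list(); groups <- character(0); i <- 0
          for (g in names(cfg$p700$groups)) {
            for (r in seq_len(cfg$p700$n_per_group)) {
              i <- i + 1
              sim <- generate_820(amplitude = cfg$p700$groups[[g]],
                                  noise_cv = cfg$p700$noise_cv,
                                  seed = cfg$seed * 1000 + i,
                                  label = sprintf("%s_%d", g, r))
              curves[[i]] <- normalize_transmittance(sim$curve)
              groups <- c(groups, g)
            }
          }
          rk <- rank_groups_by_transmittance(curves, groups)
          emit(rk, "p700_group_ranking.csv", "p700", csv_writer)
          log_lines <- log_stage(log_lines, "p700",
                                 sprintf("curves=%d groups=%d",
                                         length(curves), nrow(rk)))
          list(ranking = rk$group)
        },
        qpcr = {
          rq <- unlist(cfg$qpcr$rq_true)
          sim <- generate_ct(rq, noise_sd = cfg$qpcr$noise_sd,
                             seed = cfg$seed)
          rel <- relative_expression(sim$cts, calibrator = names(rq)[1])
          emit(rel, "qpcr_relative_expression.csv", "qpcr", csv_writer)
          log_lines <- log_stage(log_lines, "qpcr",
                                 sprintf("samples=%d", nrow(rel)))
          list(rq = stats::setNames(rel$rq, rel$sample))
        },
        metabolomics = {
          mc <- cfg$metabolomics
          sim <- generate_metabolites(
            n_metabolites = mc$n_metabolites, n_up = mc$n_up,
            n_down = mc$n_down, effect = mc$effect, cv = mc$cv,
            replicates = mc$replicates, seed = cfg$seed)
          norm <- normalize_internal_standard(sim$matrix)
          emit(as.data.frame(norm), "metab_normalized.csv", "metabolomics",
               csv_writer)
          fc_wt <- fold_change_matrix(norm, "WT")
          fc_oe <- fold_change_matrix(norm, "OEIF2")
          emit(as.data.frame(unclass(fc_wt)), "metab_fc_WT.csv",
               "metabolomics", function(o, p) write.csv(o, p))
          emit(as.data.frame(unclass(fc_oe)), "metab_fc_OEIF2.csv",
               "metabolomics", function(o, p) write.csv(o, p))
          venn <- classify_venn(fc_wt, fc_oe, threshold = mc$threshold)
          emit(venn, "metab_venn.json", "metabolomics",
               function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                                   pretty = TRUE))
          pca <- metab_pca(norm)
          emit(as.data.frame(pca$scores), "metab_pca_scores.csv",
               "metabolomics", function(o, p) write.csv(o, p))
          log_lines <- log_stage(
            log_lines, "metabolomics",
            sprintf("samples=%d metabolites=%d", nrow(norm),
                    length(metabolite_names(norm)) - 1))
          list(venn_counts_24h = venn[["24h"]]$up$counts,
               pc1_fraction = pca$explained[1],
               pc2_fraction = pca$explained[2])
        },
        pj_stop(sprintf("unknown stage '%s'", stage))
      )
    }
    TRUE
  }, error = function(e) {
    unlink(created)   # no partial bundles
    stop(e)
  })

  emit(manifest, "MANIFEST.csv", "pipeline", csv_writer)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
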