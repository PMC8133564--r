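# End-to-end orchestration: depletion data + plant records -> uptake records
# -> 50-trait table -> population statistics, with a QC report and a run
# manifest. Each stage is a pure function of tables, enabling partial reruns.

#' Run the uptake stage of the pipeline
#'
#' Interval selection, net influx, and specific-rate normalization for every
#' chamber, then assembly of the standardized 50-trait table, with a QC
#' report (efflux flags, fallback intervals, missing series).
#'
#' @param conc Long concentration tibble (`chamber_id`, `time_h`, `ion`,
#'   `conc_uM`).
#' @param chamber_map Chamber map tibble.
#' @param plants Plant-record tibble.
#' @param threshold Depletion threshold for interval selection.
#' @param volume_ml,sample_volume_ml,volume_ledger See [compute_uptake()].
#' @return List: `uptake` (per plant x ion records), `traits` (trait table),
#'   `qc` (flag counts per type), `manifest` (row counts and settings).
#' @export
run_uptake_pipeline <- function(conc, chamber_map, plants, threshold = 0.1,
                                volume_ml = 250, sample_volume_ml = 1.5,
                                volume_ledger = FALSE) {
  uptake <- compute_uptake(conc, chamber_map, plants, threshold = threshold,
                           volume_ml = volume_ml,
                           sample_volume_ml = sample_volume_ml,
                           volume_ledger = volume_ledger)
  meta_cols <- c("genotype", "treatment", "run", "block")
  traits <- compute_trait_table(
    plants %>%
      select(-dplyr::any_of(c(meta_cols, "chamber_id", "well", "replicate"))) %>%
      dplyr::semi_join(chamber_map, by = "plant_id") %>%
      left_join(chamber_map %>% select("plant_id", all_of(meta_cols)),
                by = "plant_id"),
    uptake)
  flags <- unlist(strsplit(uptake$qc[nzchar(uptake$qc)], ";"))
  qc <- tibble(flag = names(table(flags)), n = as.integer(table(flags)))
  expected <- nrow(chamber_map) * length(focal_ions())
  manifest <- tibble(
    stage = "compute_uptake",
    n_chambers = dplyr::n_distinct(conc$chamber_id),
    n_records = nrow(uptake), n_expected = expected,
    n_plants = nrow(traits), n_flags = sum(nzchar(uptake$qc)),
    threshold = threshold, volume_ml = volume_ml,
    volume_ledger = volume_ledger
  )
  list(uptake = uptake, traits = traits, qc = qc, manifest = manifest)
}

#' Run the statistics stage of the pipeline
#'
#' Per-trait variance components and broad-sense heritability (within each
#' concentration level), genotype x concentration ANOVA per trait, and a
#' correlation matrix + PCA per concentration level.
#'
#' @param traits Trait table with `genotype`, `treatment` metadata.
#' @param stat_traits Trait columns to analyse; defaults to the five
#'   length-specific uptake-rate traits.
#' @param vc_method `"moments"` or `"reml"`.
#' @param block Optional block column for the ANOVA.
#' @return List: `heritability` (per treatment x trait), `anova` (per
#'   trait), `correlations` (per treatment), `pca` (per treatment).
#' @export
run_stats_pipeline <- function(traits,
                               stat_traits = paste0(focal_ions(), "_sur_len_umol_cm_h"),
                               vc_method = "moments", block = NULL) {
  if (length(stat_traits) == 0) abort("run_stats_pipeline: empty trait subset")
  .require_cols(traits, c("genotype", "treatment", stat_traits),
                "run_stats_pipeline input")
  if (dplyr::n_distinct(traits$genotype) < 2) {
    abort("run_stats_pipeline: need at least 2 genotypes")
  }
  by_trt <- split(traits, traits$treatment)
  herit <- imap(by_trt, function(df, trt) {
    variance_components(df, stat_traits, method = vc_method) %>%
      mutate(treatment = trt, .before = 1)
  }) %>% list_rbind()
  anova_tabs <- map(stat_traits, function(tr) {
    anova_gxc(traits, tr, block = block) %>% mutate(trait = tr, .before = 1)
  }) %>% list_rbind()
  cors <- map(by_trt, ~ correlation_matrix(.x, stat_traits))
  pcas <- map(by_trt, function(df) {
    ok <- tryCatch(pca_summary(df, stat_traits), error = function(e) NULL)
    ok
  })
  list(heritability = herit, anova = anova_tabs, correlations = cors, pca = pcas)
}

#' Write a statistics report
#'
#' CSV tables (heritability, ANOVA, correlations) plus a JSON summary.
#'
#' @param stats Output of [run_stats_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_stats_report <- function(stats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    heritability = file.path(dir, "heritability.csv"),
    anova = file.path(dir, "anova_gxc.csv"),
    summary = file.path(dir, "stats_summary.json")
  )
  readr::write_csv(stats$heritability, paths$heritability)
  readr::write_csv(stats$anova, paths$anova)
  for (trt in names(stats$correlations)) {
    p <- file.path(dir, sprintf("correlations_%s.csv", trt))
    readr::write_csv(stats$correlations[[trt]], p)
    paths[[paste0("correlations_", trt)]] <- p
  }
  summary <- list(
    h2 = stats$heritability %>% select("treatment", "trait", "h2"),
    anova_p = stats$anova %>% filter(.data$term == "genotype:concentration") %>%
      select("trait", "p.value"),
    pca_pc12 = map(stats$pca, function(p) {
      if (is.null(p)) NA_real_ else sum(p$variance$prop_variance[1:2])
    })
  )
  jsonlite::write_json(summary, paths$summary, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "rows")
  invisible(paths)
}
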