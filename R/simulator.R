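# Seeded synthetic-experiment generator: known per-plant Michaelis-Menten
# ground truth, forward-modelled depletion series with instrument-like
# multiplicative noise, root/biomass/respiration records, and on-disk
# fixture experiments for end-to-end pipeline runs.

#' Simulation configuration
#'
#' Defaults emulate the platform's study design: 26 genotypes x 6 replicates
#' x 2 concentration levels (the packaged high/low recipes), runs of 48
#' chambers (2 modules x 24), the 0-8 h sampling schedule, 250 mL chambers,
#' and 1.5 mL samples. Population kinetic parameters are lognormal across
#' genotypes with configurable genetic coefficients of variation and
#' cross-ion correlation of genetic effects; within-genotype biological
#' variation and run effects act multiplicatively on `Imax`. The per-ion
#' means put the typical plant's high-treatment depletion at 4 h around
#' 12-33% and low-treatment depletion at 1 h around 13-21%, so the 10%
#' interval-selection rule lands on the (0, 4) h and (0, 1) h operating
#' points.
#'
#' @param genotypes Number of genotypes G (>= 2).
#' @param replicates Replicates per genotype and concentration (>= 1).
#' @param treatments Character vector of recipe labels (default
#'   `c("high", "low")`).
#' @param ion_params Tibble with one row per focal ion: `ion`,
#'   `mean_imax` (µmol cm⁻¹ h⁻¹), `mean_km` (µM).
#' @param genetic_cv_imax,genetic_cv_km Genetic coefficients of variation.
#' @param plant_cv Within-genotype biological CV on `Imax` and `Km`.
#' @param ion_cor Cross-ion correlation of genetic effects (log scale).
#' @param noise_cv Multiplicative measurement noise CV on concentrations.
#' @param run_sd Run effect SD on log `Imax`.
#' @param root_mean_cm,root_cv Gamma-distributed total root length.
#' @param srl_cm_g Mean specific root length (for dry-weight generation).
#' @param resp_specific_nmol_m_s Mean specific root respiration.
#' @param schedule_h Sampling times (must start at 0).
#' @param volume_ml,sample_volume_ml Chamber and sample volumes (mL).
#' @param chambers_per_run Chamber throughput per experimental run.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genotypes = 26,
                       replicates = 6,
                       treatments = c("high", "low"),
                       ion_params = default_ion_params(),
                       genetic_cv_imax = 0.3,
                       genetic_cv_km = 0.2,
                       plant_cv = 0.25,
                       ion_cor = 0.6,
                       noise_cv = 0.02,
                       run_sd = 0.05,
                       root_mean_cm = 500,
                       root_cv = 0.3,
                       srl_cm_g = 5000,
                       resp_specific_nmol_m_s = 0.5,
                       schedule_h = c(0, 0.5, 1, 2, 3, 4, 6, 8),
                       volume_ml = 250,
                       sample_volume_ml = 1.5,
                       chambers_per_run = 48) {
  stopifnot(genotypes >= 2, replicates >= 1, schedule_h[1] == 0,
            all(diff(schedule_h) > 0),
            genetic_cv_imax >= 0, genetic_cv_km >= 0, plant_cv >= 0,
            noise_cv >= 0, run_sd >= 0, abs(ion_cor) <= 1)
  structure(list(
    genotypes = genotypes, replicates = replicates, treatments = treatments,
    ion_params = ion_params, genetic_cv_imax = genetic_cv_imax,
    genetic_cv_km = genetic_cv_km, plant_cv = plant_cv, ion_cor = ion_cor,
    noise_cv = noise_cv, run_sd = run_sd, root_mean_cm = root_mean_cm,
    root_cv = root_cv, srl_cm_g = srl_cm_g,
    resp_specific_nmol_m_s = resp_specific_nmol_m_s,
    schedule_h = schedule_h, volume_ml = volume_ml,
    sample_volume_ml = sample_volume_ml, chambers_per_run = chambers_per_run
  ), class = "sim_config")
}

#' Default per-ion population kinetic parameters
#'
#' @return Tibble `ion`, `mean_imax` (µmol cm⁻¹ h⁻¹), `mean_km` (µM).
#' @export
default_ion_params <- function() {
  tibble(
    ion = c("ammonium", "nitrate", "phosphate", "potassium", "sulfate"),
    mean_imax = c(0.020, 0.018, 0.012, 0.016, 0.010),
    mean_km = c(120, 150, 80, 140, 100)
  )
}

#' Plan experimental runs for a chamber count
#'
#' With two modules of 24 chambers the platform processes 48 plants per run;
#' an experiment of `n_plants` chambers therefore needs
#' `ceiling(n_plants / 48)` runs.
#'
#' @param n_plants Number of plants (chambers) to phenotype.
#' @param modules Number of modules (default 2).
#' @param chambers_per_module Chambers per module (default 24).
#' @return Tibble `n_plants`, `plants_per_run`, `runs`.
#' @export
plan_runs <- function(n_plants, modules = 2, chambers_per_module = 24) {
  per_run <- modules * chambers_per_module
  tibble(n_plants = n_plants, plants_per_run = per_run,
         runs = ceiling(n_plants / per_run))
}

#' Draw per-plant ground-truth parameters
#'
#' Genetic effects are multivariate normal on the log scale (a Gaussian
#' copula across ions with correlation `ion_cor`), giving each genotype a
#' lognormal `(Imax, Km)` per ion with the configured genetic CV; plants add
#' independent lognormal biological variation (`plant_cv`) and a shared run
#' effect on log `Imax`. Root lengths are gamma distributed; dry weights and
#' respiration derive from specific root length and specific respiration
#' with lognormal scatter. Fully determined by the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `genotype_truth` (genotype x ion x treatment-free
#'   kinetic parameters) and `plants` (per-plant records incl. chamber
#'   assignment, run, block, and true per-ion `imax`, `km`).
#' @export
draw_population <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  ions <- config$ion_params$ion
  ni <- length(ions)
  G <- config$genotypes
  R <- length(config$treatments) * config$replicates

  cmat <- matrix(config$ion_cor, ni, ni)
  diag(cmat) <- 1
  ev <- eigen(cmat, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) abort("draw_population: cross-ion correlation matrix not positive definite")

  sd_gi <- sqrt(log(1 + config$genetic_cv_imax^2))
  sd_gk <- sqrt(log(1 + config$genetic_cv_km^2))
  zi <- MASS::mvrnorm(G, mu = rep(0, ni), Sigma = cmat)
  zk <- MASS::mvrnorm(G, mu = rep(0, ni), Sigma = cmat)
  geno_truth <- purrr::map(seq_len(G), function(g) {
    tibble(genotype = sprintf("G%02d", g), ion = ions,
           imax_g = config$ion_params$mean_imax *
             exp(sd_gi * zi[g, ] - sd_gi^2 / 2),
           km_g = config$ion_params$mean_km *
             exp(sd_gk * zk[g, ] - sd_gk^2 / 2))
  }) %>% list_rbind()

  n_plants <- G * R
  runs <- rep(seq_len(ceiling(n_plants / config$chambers_per_run)),
              each = config$chambers_per_run)[seq_len(n_plants)]
  # randomized assignment of plants to chambers/runs
  ord <- sample.int(n_plants)
  plants <- tidyr::expand_grid(
    genotype = sprintf("G%02d", seq_len(G)),
    treatment = config$treatments,
    replicate = seq_len(config$replicates)
  ) %>%
    mutate(plant_id = sprintf("P%04d", seq_len(n_plants)),
           chamber_id = sprintf("C%04d", ord),
           run = runs[ord], block = .data$run)

  run_eff <- rnorm(max(plants$run), 0, config$run_sd)
  sd_p <- sqrt(log(1 + config$plant_cv^2))

  shape <- 1 / config$root_cv^2
  plants <- plants %>%
    mutate(
      root_total_cm = rgamma(n_plants, shape = shape,
                             scale = config$root_mean_cm / shape),
      root_seminal_cm = .data$root_total_cm * 0.25,
      root_lateral_cm = .data$root_total_cm * 0.55,
      root_secondary_cm = .data$root_total_cm * 0.20,
      dw_root_g = .data$root_total_cm / (config$srl_cm_g *
                                           exp(rnorm(n_plants, 0, 0.1))),
      dw_leaf_g = .data$dw_root_g * 1.5 * exp(rnorm(n_plants, 0, 0.1)),
      dw_stem_g = .data$dw_root_g * 1.0 * exp(rnorm(n_plants, 0, 0.1)),
      resp_total_nmol_s = config$resp_specific_nmol_m_s *
        (.data$root_total_cm / 100) * exp(rnorm(n_plants, 0, 0.15)),
      leaf_area_cm2 = 50 * exp(rnorm(n_plants, 0, 0.2)),
      leaf_len_cm = 30 * exp(rnorm(n_plants, 0, 0.15))
    )

  plant_truth <- tidyr::expand_grid(plant_id = plants$plant_id, ion = ions) %>%
    left_join(plants %>% select("plant_id", "genotype", "run"), by = "plant_id") %>%
    left_join(geno_truth, by = c("genotype", "ion")) %>%
    mutate(
      imax = .data$imax_g *
        exp(rnorm(n(), 0, sd_p) - sd_p^2 / 2 + run_eff[.data$run]),
      km = .data$km_g * exp(rnorm(n(), 0, sd_p) - sd_p^2 / 2)
    ) %>%
    select("plant_id", "genotype", "run", "ion", "imax", "km")

  list(genotype_truth = geno_truth, plants = plants, plant_truth = plant_truth)
}

#' Simulate a depletion series for one chamber and ion
#'
#' Evaluates the closed-form Michaelis-Menten depletion trajectory at the
#' sampling schedule and applies multiplicative Gaussian measurement noise
#' (`CV` as configured), floored at zero. Noiseless when `noise_cv = 0`.
#'
#' @param c0_uM Starting concentration (µM).
#' @param imax,km True kinetic parameters.
#' @param root_length_cm,volume_ml Chamber geometry.
#' @param schedule_h Sampling times (h).
#' @param noise_cv Measurement noise CV.
#' @return Tibble `time_h`, `conc_uM`.
#' @export
simulate_depletion <- function(c0_uM, imax, km, root_length_cm,
                               volume_ml = 250,
                               schedule_h = c(0, 0.5, 1, 2, 3, 4, 6, 8),
                               noise_cv = 0) {
  clean <- mm_depletion_conc(schedule_h, c0_uM, imax, km, root_length_cm, volume_ml)
  if (noise_cv > 0) {
    clean <- pmax(clean * (1 + rnorm(length(clean), 0, noise_cv)), 0)
  }
  tibble(time_h = schedule_h, conc_uM = clean)
}

#' Simulate a complete experiment in memory
#'
#' Draws the population, forward-models every chamber's five focal-ion
#' depletion series from the treatment recipe's designed concentrations, and
#' returns all pipeline inputs plus the generating truth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the experiment
#'   exactly.
#' @param recipes Named recipe list; defaults to the packaged
#'   [nutrient_recipes()].
#' @return List: `concentrations` (long tibble), `chamber_map`, `plants`,
#'   `truth` (per-plant kinetic parameters), `config`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1,
                                recipes = nutrient_recipes()) {
  pop <- draw_population(config, seed = seed)
  withr::local_seed(seed + 1L)
  miss <- setdiff(config$treatments, names(recipes))
  if (length(miss)) {
    abort(sprintf("simulate_experiment: no recipe for treatment(s): %s",
                  paste(miss, collapse = ", ")))
  }
  comps <- map(recipes[config$treatments], focal_composition)
  conc <- pop$plants %>%
    select("plant_id", "chamber_id", "treatment", "root_total_cm") %>%
    left_join(pop$plant_truth, by = "plant_id") %>%
    pmap(function(plant_id, chamber_id, treatment, root_total_cm,
                  genotype, run, ion, imax, km) {
      comp <- comps[[treatment]]
      c0 <- comp$conc_uM[comp$ion == ion]
      if (length(c0) != 1 || c0 <= 0) {
        abort(sprintf("simulate_experiment: recipe '%s' lacks focal ion '%s'",
                      treatment, ion))
      }
      simulate_depletion(c0, imax, km, root_total_cm,
                         volume_ml = config$volume_ml,
                         schedule_h = config$schedule_h,
                         noise_cv = config$noise_cv) %>%
        mutate(chamber_id = chamber_id, ion = ion, .before = 1)
    }) %>%
    list_rbind() %>%
    select("chamber_id", "time_h", "ion", "conc_uM") %>%
    arrange(.data$chamber_id, .data$ion, .data$time_h)

  chamber_map <- pop$plants %>%
    select("chamber_id", "plant_id", "genotype", "treatment", "run", "block") %>%
    group_by(.data$run) %>%
    mutate(well = sprintf("%s%d", LETTERS[((dplyr::row_number() - 1) %/% 12) %% 8 + 1],
                          (dplyr::row_number() - 1) %% 12 + 1)) %>%
    ungroup()

  list(concentrations = conc, chamber_map = chamber_map,
       plants = pop$plants, truth = pop$plant_truth,
       genotype_truth = pop$genotype_truth, config = config)
}

#' Write a synthetic fixture experiment to disk
#'
#' Emits a complete, immediately-runnable input set: long-format
#' ion-chromatography CSV, chamber map CSV, classified root-trait CSV, the
#' recipes YAML, and a ground-truth JSON for recovery tests. Byte-stable for
#' a given seed.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param force Overwrite a non-empty directory (default FALSE: refuses).
#' @return Invisibly, a named list of the written paths.
#' @export
make_fixture_experiment <- function(dir, config = sim_config(), seed = 1,
                                    force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    abort(sprintf("make_fixture_experiment: directory not empty: %s (use force = TRUE)", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(config, seed = seed)
  paths <- list(
    concentrations = file.path(dir, "ic_export_long.csv"),
    chamber_map = file.path(dir, "chamber_map.csv"),
    root_traits = file.path(dir, "root_traits.csv"),
    recipes = file.path(dir, "recipes.yaml"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_ic_export(sim$concentrations, paths$concentrations)
  readr::write_csv(sim$chamber_map, paths$chamber_map)
  readr::write_csv(
    sim$plants %>%
      select("plant_id", "root_seminal_cm", "root_lateral_cm",
             "root_secondary_cm", "dw_root_g", "dw_leaf_g", "dw_stem_g",
             "resp_total_nmol_s", "leaf_area_cm2", "leaf_len_cm"),
    paths$root_traits)
  file.copy(system.file("extdata", "recipes.yaml", package = "ionuptake"),
            paths$recipes, overwrite = TRUE)
  jsonlite::write_json(
    list(seed = seed,
         config = config[setdiff(names(config), "ion_params")],
         ion_params = sim$config$ion_params,
         plant_truth = sim$truth,
         genotype_truth = sim$genotype_truth),
    paths$truth, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Simulate genotype-replicate trait values
#'
#' Draws a single trait from the one-way genetic model
#' `y_ij = g_i + e_ij`, `g_i ~ N(0, sigma_g2)`, `e_ij ~ N(mu, sigma_e2)` —
#' the generating model under which broad-sense heritability is
#' `sigma_g2 / (sigma_g2 + sigma_e2 / r)`. Used for heritability-recovery
#' simulation studies.
#'
#' @param genotypes,replicates Design size.
#' @param sigma_g2,sigma_e2 Generating variances.
#' @param mu Grand mean.
#' @param seed Optional integer seed.
#' @return Tibble `genotype`, `replicate`, `value`.
#' @export
simulate_trait_values <- function(genotypes, replicates, sigma_g2, sigma_e2,
                                  mu = 0, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  g <- rnorm(genotypes, 0, sqrt(sigma_g2))
  tibble(
    genotype = rep(sprintf("G%02d", seq_len(genotypes)), each = replicates),
    replicate = rep(seq_len(replicates), genotypes),
    value = mu + rep(g, each = replicates) +
      rnorm(genotypes * replicates, 0, sqrt(sigma_e2))
  )
}
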