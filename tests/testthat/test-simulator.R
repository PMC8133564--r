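test_that("population draws are seed-deterministic", {
  cfg <- sim_config(genotypes = 5, replicates = 2)
  a <- draw_population(cfg, seed = 3)
  b <- draw_population(cfg, seed = 3)
  expect_identical(a$plant_truth, b$plant_truth)
  expect_identical(a$plants, b$plants)
  c_ <- draw_population(cfg, seed = 4)
  expect_false(isTRUE(all.equal(a$plant_truth$imax, c_$plant_truth$imax)))
})

test_that("zero genetic CV collapses genotypes onto shared parameters", {
  cfg <- sim_config(genotypes = 6, replicates = 1, genetic_cv_imax = 0,
                    genetic_cv_km = 0)
  pop <- draw_population(cfg, seed = 1)
  per_ion <- split(pop$genotype_truth, pop$genotype_truth$ion)
  for (g in per_ion) {
    expect_equal(max(g$imax_g) - min(g$imax_g), 0, tolerance = 1e-12)
    expect_equal(max(g$km_g) - min(g$km_g), 0, tolerance = 1e-12)
  }
})

test_that("realized genetic variance matches the configured CV at large G", {
  cfg <- sim_config(genotypes = 1000, replicates = 1, treatments = "high",
                    genetic_cv_imax = 0.3)
  pop <- draw_population(cfg, seed = 10)
  nitrate <- pop$genotype_truth[pop$genotype_truth$ion == "nitrate", ]
  target_var <- log(1 + 0.3^2)
  expect_equal(var(log(nitrate$imax_g)), target_var, tolerance = 0.05)
})

test_that("noiseless simulation equals the closed form; noise is honest", {
  s <- simulate_depletion(1000, 0.02, 150, 500, noise_cv = 0)
  expect_equal(s$conc_uM,
               mm_depletion_conc(s$time_h, 1000, 0.02, 150, 500, 250),
               tolerance = 1e-15)
  set.seed(8)
  clean <- mm_depletion_conc(paper_schedule, 1000, 0.02, 150, 500, 250)
  reps <- replicate(1000, simulate_depletion(1000, 0.02, 150, 500,
                                             noise_cv = 0.02)$conc_uM)
  # mean within 3 SE of the noiseless trajectory at every timepoint
  se <- apply(reps, 1, sd) / sqrt(1000)
  expect_true(all(abs(rowMeans(reps) - clean) <= 3 * se + 1e-9))
  # empirical CV within 10% of configured
  cvs <- apply(reps[-1, ], 1, sd) / clean[-1]
  expect_true(all(abs(cvs - 0.02) <= 0.1 * 0.02 + 3 * 0.02 / sqrt(2 * 999)))
})

test_that("default truth reproduces the low/high interval operating points", {
  cfg <- sim_config()
  comps <- purrr::map(nutrient_recipes()[c("high", "low")], focal_composition)
  series <- purrr::imap(comps, function(comp, trt) {
    purrr::pmap(cfg$ion_params, function(ion, mean_imax, mean_km) {
      c0 <- comp$conc_uM[comp$ion == ion]
      simulate_depletion(c0, mean_imax, mean_km, cfg$root_mean_cm,
                         schedule_h = cfg$schedule_h, noise_cv = 0) %>%
        dplyr::mutate(ion = ion)
    }) %>% purrr::list_rbind()
  })
  expect_equal(select_interval(series$high)$t_h, 4)
  expect_equal(select_interval(series$low)$t_h, 1)
})

test_that("fixture experiments are sized, planned, and reproducible", {
  expect_equal(plan_runs(26 * 6 * 2)$runs, 7)
  expect_equal(plan_runs(26 * 6 * 2)$plants_per_run, 48)
  expect_equal(plan_runs(2)$runs, 1)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- sim_config(genotypes = 2, replicates = 1, treatments = "high")
  p1 <- make_fixture_experiment(file.path(dir1, "fx"), cfg, seed = 6)
  p2 <- make_fixture_experiment(file.path(dir2, "fx"), cfg, seed = 6)
  cm <- read_chamber_map(p1$chamber_map)
  expect_equal(nrow(cm), 2)
  expect_identical(readLines(p1$truth), readLines(p2$truth))
  expect_identical(readLines(p1$concentrations), readLines(p2$concentrations))
  # refuses to clobber
  expect_error(make_fixture_experiment(file.path(dir1, "fx"), cfg, seed = 6),
               "not empty")
})

test_that("the pipeline recovers simulated kinetic ground truth", {
  cfg <- sim_config(genotypes = 3, replicates = 1, treatments = "high",
                    noise_cv = 0, plant_cv = 0, run_sd = 0)
  sim <- simulate_experiment(cfg, seed = 12)
  truth <- sim$truth[sim$truth$ion == "nitrate", ]
  for (i in seq_len(nrow(truth))) {
    pl <- sim$plants[sim$plants$plant_id == truth$plant_id[i], ]
    ch <- sim$chamber_map$chamber_id[sim$chamber_map$plant_id == truth$plant_id[i]]
    s <- sim$concentrations[sim$concentrations$chamber_id == ch &
                              sim$concentrations$ion == "nitrate", ]
    f <- fit_depletion(s, pl$root_total_cm, cfg$volume_ml, c0_uM = 1000)
    est <- setNames(tidy(f)$estimate, tidy(f)$term)
    expect_equal(unname(est["imax"]), truth$imax[i], tolerance = 0.01)
    expect_equal(unname(est["km"]), truth$km[i], tolerance = 0.02)
  }
})
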