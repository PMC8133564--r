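# shared fixture builders and independent oracles

paper_schedule <- c(0, 0.5, 1, 2, 3, 4, 6, 8)

# independent Runge-Kutta oracle for the depletion ODE (deSolve, tight
# tolerances); used to cross-check the Lambert-W closed form
rk_depletion <- function(c0, imax, km, L, V_ml, times, cmin = 0) {
  k <- imax * L / (V_ml / 1000)
  out <- deSolve::ode(
    y = c(C = c0), times = times,
    func = function(t, y, p) list(-k * pmax(y - cmin, 0) / (km + pmax(y - cmin, 0))),
    parms = NULL, method = "lsoda", rtol = 1e-12, atol = 1e-14
  )
  unname(out[, "C"])
}

# a complete synthetic plant record for trait assembly tests
toy_plant <- function(plant_id = "P1") {
  tibble::tibble(
    plant_id = plant_id, genotype = "G01", treatment = "high",
    run = 1L, block = 1L,
    root_seminal_cm = 100, root_lateral_cm = 250, root_secondary_cm = 50,
    root_total_cm = 400, dw_root_g = 0.2, dw_leaf_g = 0.3, dw_stem_g = 0.1,
    resp_total_nmol_s = 2, leaf_area_cm2 = 55, leaf_len_cm = 32
  )
}

toy_uptake <- function(plant_id = "P1",
                       rates = c(ammonium = 0.02, nitrate = 0.01,
                                 phosphate = 0.005, potassium = 0.015,
                                 sulfate = 0.004)) {
  tibble::tibble(
    plant_id = plant_id, ion = names(rates),
    influx_umol_h = unname(rates) * 400,
    sur_len_umol_cm_h = unname(rates),
    sur_mass_umol_g_h = unname(rates) * 400 / 0.2,
    depletion_frac = 0.2, qc = ""
  )
}

# depletion tibble for one chamber from per-ion fractional depletions over a
# schedule (depl[[ion]] aligned with times[-1])
chamber_series <- function(depl, times = c(0, 0.5, 1, 2, 3, 4, 6, 8), c0 = 100) {
  purrr::imap(depl, function(fr, ion) {
    tibble::tibble(ion = ion, time_h = times,
                   conc_uM = c0 * c(1, 1 - fr))
  }) %>% purrr::list_rbind()
}
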