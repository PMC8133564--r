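# Net influx and specific uptake rates from depletion time series.
#
# Canonical internal units: concentration uM, time h, length cm, mass g,
# volume mL, amount umol. Net influx multiplies the concentration drop by the
# chamber volume (in litres), so the reported rates carry the units
# umol h^-1 and, after normalization, umol cm^-1 h^-1 or umol g^-1 h^-1.

#' Net influx from a two-point depletion measurement
#'
#' Depletion of a nutrient from a closed chamber is taken as equal to the net
#' uptake by the root system (influx minus efflux). The influx is the
#' concentration drop times the chamber volume over the elapsed time:
#' `(C0 - Ct) * V / (t - t0)`, in µmol h⁻¹. Positive when the solution is
#' depleted; negative values indicate net efflux and are retained.
#'
#' @param c0_uM,ct_uM Concentration (µM) at the start and end of the interval.
#' @param t0_h,t_h Interval endpoints in hours (`t_h > t0_h`).
#' @param volume_ml Chamber volume in mL (default 250).
#' @return Net influx in µmol h⁻¹ (vectorized).
#' @examples
#' net_influx(100, 80, 0, 1, 250) # 5 umol/h
#' @export
net_influx <- function(c0_uM, ct_uM, t0_h, t_h, volume_ml = 250) {
  if (any(t_h <= t0_h)) abort("net_influx: interval must have t > t0")
  if (any(volume_ml <= 0)) abort("net_influx: chamber volume must be positive")
  (c0_uM - ct_uM) * (volume_ml / 1000) / (t_h - t0_h)
}

#' Specific uptake rate
#'
#' Net influx normalized per unit root length (cm) or root dry mass (g).
#'
#' @param influx_umol_h Net influx (µmol h⁻¹); sign preserved.
#' @param denominator Root length in cm or dry weight in g; must be positive.
#' @return Rate in µmol cm⁻¹ h⁻¹ or µmol g⁻¹ h⁻¹.
#' @export
specific_rate <- function(influx_umol_h, denominator) {
  if (any(!is.finite(denominator)) || any(denominator <= 0)) {
    abort("specific_rate: denominator must be positive and finite")
  }
  influx_umol_h / denominator
}

#' Specific root respiration
#'
#' Total root CO₂ efflux divided by total root length, reported per metre.
#'
#' @param resp_nmol_s Total root respiration (nmol CO₂ s⁻¹).
#' @param root_length_cm Total root length (cm); must be positive.
#' @return Specific respiration in nmol CO₂ m⁻¹ s⁻¹.
#' @export
specific_respiration <- function(resp_nmol_s, root_length_cm) {
  if (any(root_length_cm <= 0)) abort("specific_respiration: root length must be positive")
  resp_nmol_s / (root_length_cm / 100)
}

#' Specific root length
#'
#' @param root_length_cm Total root length (cm).
#' @param root_dw_g Root dry weight (g); must be positive.
#' @return Length per unit mass (cm g⁻¹).
#' @export
specific_root_length <- function(root_length_cm, root_dw_g) {
  if (any(root_dw_g <= 0)) abort("specific_root_length: root dry weight must be positive")
  root_length_cm / root_dw_g
}

#' Classify diameter-binned root length into root classes
#'
#' Diameter-binned root length (a WinRhizo-style histogram) is aggregated into
#' seminal, lateral, and secondary-order lateral classes using diameter
#' thresholds of 0.8–4.25, 0.15–0.8, and 0–0.15 mm respectively. Intervals are
#' half-open `[low, high)` with the seminal class closed at 4.25 mm, so a bin
#' landing exactly on a threshold joins the coarser class. Bins above 4.25 mm
#' are excluded from all classes and reported in `oversize_cm`.
#'
#' @param histogram Tibble with columns `diameter_mm` (bin diameter) and
#'   `length_cm`.
#' @return One-row tibble: `seminal_cm`, `lateral_cm`, `secondary_cm`,
#'   `total_cm` (sum of the three classes), `oversize_cm`.
#' @export
classify_root_lengths <- function(histogram) {
  stopifnot(all(c("diameter_mm", "length_cm") %in% names(histogram)))
  d <- histogram$diameter_mm
  len <- histogram$length_cm
  if (any(d < 0)) abort("classify_root_lengths: negative diameter")
  if (any(len < 0)) abort("classify_root_lengths: negative length")
  secondary <- sum(len[d < 0.15])
  lateral <- sum(len[d >= 0.15 & d < 0.8])
  seminal <- sum(len[d >= 0.8 & d <= 4.25])
  oversize <- sum(len[d > 4.25])
  tibble(
    seminal_cm = seminal, lateral_cm = lateral, secondary_cm = secondary,
    total_cm = seminal + lateral + secondary, oversize_cm = oversize
  )
}

#' Select the sampling interval by the minimum-depletion rule
#'
#' The processed interval is `(0, t*)` where `t*` is the earliest sampling
#' time at which every focal ion has been depleted by at least `threshold`
#' (default 10%) of its starting concentration. If no sampling time qualifies,
#' the last time is returned with a fallback flag. Missing observations at a
#' time disqualify that time (the rule cannot be verified there).
#'
#' @param conc Long tibble for one chamber: `time_h`, `ion`, `conc_uM`.
#' @param threshold Required fractional depletion (default 0.10).
#' @param ions Ions the rule must hold for (default [focal_ions()]).
#' @return One-row tibble: `t0_h`, `t_h`, `fallback` (logical).
#' @export
select_interval <- function(conc, threshold = 0.1, ions = focal_ions()) {
  stopifnot(all(c("time_h", "ion", "conc_uM") %in% names(conc)))
  conc <- conc[conc$ion %in% ions, , drop = FALSE]
  absent <- setdiff(ions, unique(conc$ion))
  if (length(absent)) {
    abort(sprintf("select_interval: no series for ion(s): %s", paste(absent, collapse = ", ")))
  }
  t0 <- min(conc$time_h)
  c0 <- conc %>%
    group_by(.data$ion) %>%
    filter(.data$time_h == min(.data$time_h)) %>%
    ungroup() %>%
    select("ion", c0_uM = "conc_uM")
  if (any(c0$c0_uM <= 0)) {
    abort(sprintf("select_interval: zero starting concentration for ion(s): %s",
                  paste(c0$ion[c0$c0_uM <= 0], collapse = ", ")))
  }
  later <- conc %>%
    filter(.data$time_h > t0) %>%
    left_join(c0, by = "ion") %>%
    mutate(depl = (.data$c0_uM - .data$conc_uM) / .data$c0_uM)
  if (nrow(later) == 0) abort("select_interval: need at least two timepoints")
  qual <- later %>%
    group_by(.data$time_h) %>%
    summarise(ok = n() == length(.env$ions) && all(.data$depl >= .env$threshold),
              .groups = "drop") %>%
    filter(.data$ok)
  if (nrow(qual) > 0) {
    tibble(t0_h = t0, t_h = min(qual$time_h), fallback = FALSE)
  } else {
    tibble(t0_h = t0, t_h = max(later$time_h), fallback = TRUE)
  }
}

# Sample-withdrawal-corrected uptake: each draw removes `vs` mL at the current
# concentration. Interval i (between draws i and i+1) holds volume
# V0 - vs*(i+1) (litre-converted later), so the amount taken up is
# sum (C_i - C_{i+1}) * (V0 - vs*(i+1)).
.ledger_uptake_umol <- function(times, concs, t0, tstar, volume_ml, sample_ml) {
  keep <- times >= t0 & times <= tstar & !is.na(concs)
  tt <- times[keep][order(times[keep])]
  cc <- concs[keep][order(times[keep])]
  if (length(tt) < 2) return(NA_real_)
  vols <- (volume_ml - sample_ml * seq_along(tt)) / 1000 # L after each draw
  if (any(vols <= 0)) abort("volume ledger: sampling exhausted the chamber volume")
  sum((cc[-length(cc)] - cc[-1]) * vols[-length(vols)])
}

#' Compute per-plant uptake records from depletion data
#'
#' Applies the interval-selection rule per chamber, computes net influx for
#' every focal ion over the selected interval, and normalizes by the plant's
#' total root length and root dry weight. Negative influxes (net efflux) are
#' retained and flagged. With `volume_ledger = TRUE` each 1.5 mL sample draw
#' is debited from the chamber volume and the influx is computed from the
#' amount balance across all observed timepoints in the interval; by default
#' the chamber volume is treated as constant.
#'
#' @param conc Long concentration tibble: `chamber_id`, `time_h`, `ion`,
#'   `conc_uM`.
#' @param chamber_map Tibble mapping `chamber_id` to `plant_id` (plus any
#'   metadata columns, carried through).
#' @param plants Plant-record tibble with `plant_id`, `root_total_cm`,
#'   `dw_root_g` (other columns ignored here).
#' @param threshold Fractional-depletion threshold for [select_interval()].
#' @param volume_ml,sample_volume_ml Chamber and per-draw sample volumes (mL).
#' @param volume_ledger Apply the sample-withdrawal correction (default FALSE).
#' @param ions Focal ions (default [focal_ions()]).
#' @return Tibble with one row per plant × ion: interval, concentrations,
#'   `influx_umol_h`, `sur_len_umol_cm_h`, `sur_mass_umol_g_h`,
#'   `depletion_frac`, and a `qc` flag string (`efflux`,
#'   `fallback_interval`, or empty).
#' @export
compute_uptake <- function(conc, chamber_map, plants, threshold = 0.1,
                           volume_ml = 250, sample_volume_ml = 1.5,
                           volume_ledger = FALSE, ions = focal_ions()) {
  stopifnot(all(c("chamber_id", "time_h", "ion", "conc_uM") %in% names(conc)))
  unmapped <- setdiff(unique(conc$chamber_id), chamber_map$chamber_id)
  if (length(unmapped)) {
    abort(sprintf("compute_uptake: chambers missing from the chamber map: %s",
                  paste(unmapped, collapse = ", ")))
  }
  recs <- conc %>%
    filter(.data$ion %in% ions) %>%
    group_by(.data$chamber_id) %>%
    dplyr::group_modify(function(df, key) {
      present <- intersect(ions, unique(df$ion))
      iv <- select_interval(df[df$ion %in% present, ], threshold = threshold,
                            ions = present)
      purrr::map(present, function(io) {
        s <- df[df$ion == io, ]
        s <- s[order(s$time_h), ]
        c0 <- s$conc_uM[s$time_h == iv$t0_h]
        ct <- s$conc_uM[s$time_h == iv$t_h]
        if (length(c0) != 1 || length(ct) != 1 || is.na(c0) || is.na(ct)) {
          return(tibble(ion = io, t0_h = iv$t0_h, t_h = iv$t_h,
                        c0_uM = NA_real_, ct_uM = NA_real_,
                        influx_umol_h = NA_real_, depletion_frac = NA_real_,
                        qc = "missing_endpoint"))
        }
        influx <- if (volume_ledger) {
          up <- .ledger_uptake_umol(s$time_h, s$conc_uM, iv$t0_h, iv$t_h,
                                    volume_ml, sample_volume_ml)
          up / (iv$t_h - iv$t0_h)
        } else {
          net_influx(c0, ct, iv$t0_h, iv$t_h, volume_ml)
        }
        flags <- c(if (!is.na(influx) && influx < 0) "efflux",
                   if (iv$fallback) "fallback_interval")
        tibble(ion = io, t0_h = iv$t0_h, t_h = iv$t_h, c0_uM = c0, ct_uM = ct,
               influx_umol_h = influx, depletion_frac = (c0 - ct) / c0,
               qc = paste(flags, collapse = ";"))
      }) %>% list_rbind()
    }) %>%
    ungroup()
  out <- recs %>%
    left_join(chamber_map, by = "chamber_id") %>%
    left_join(plants %>% select("plant_id", "root_total_cm", "dw_root_g"),
              by = "plant_id") %>%
    mutate(
      sur_len_umol_cm_h = ifelse(
        !is.na(.data$root_total_cm) & .data$root_total_cm > 0,
        .data$influx_umol_h / .data$root_total_cm, NA_real_),
      sur_mass_umol_g_h = ifelse(
        !is.na(.data$dw_root_g) & .data$dw_root_g > 0,
        .data$influx_umol_h / .data$dw_root_g, NA_real_)
    ) %>%
    select(-"root_total_cm", -"dw_root_g")
  out
}
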