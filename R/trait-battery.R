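# The standardized per-plant trait battery: 35 uptake parameters (per-ion
# rates, pairwise ratios, stoichiometric fractions) + 15 plant traits = 50.
# Column naming: <ion>_<quantity>_<units>; ratio pairs are ordered
# alphabetically by ion identifier.

#' Unordered focal-ion pairs
#'
#' The 10 unordered pairs of focal ions in alphabetical order, used for the
#' pairwise uptake-rate ratio traits.
#'
#' @return Tibble with columns `a`, `b` (`a` < `b` alphabetically).
#' @export
ion_pairs <- function() {
  ions <- focal_ions()
  idx <- utils::combn(length(ions), 2)
  tibble(a = ions[idx[1, ]], b = ions[idx[2, ]])
}

#' The 50-trait schema
#'
#' Enumerates the standardized trait battery: 35 uptake parameters (per ion:
#' net uptake rate, specific rates per root length and mass, fractional
#' depletion; the 10 pairwise rate ratios; the 5 stoichiometric fractions)
#' and 15 plant traits (root class and total lengths, dry weights, specific
#' root length, respiration, leaf measures, root:shoot ratio). This is a
#' pinned reconstruction of the battery; its version tag lets a revised
#' enumeration replace it without touching downstream code.
#'
#' @return Tibble with `trait`, `block` (`"uptake"`/`"plant"`), `unit`.
#' @export
trait_schema <- function() {
  ions <- focal_ions()
  pairs <- ion_pairs()
  uptake <- bind_rows(
    tibble(trait = paste0(rep(ions, each = 4), "_",
                          rep(c("uptake_umol_h", "sur_len_umol_cm_h",
                                "sur_mass_umol_g_h", "depletion_frac"), 5)),
           unit = rep(c("umol/h", "umol/cm/h", "umol/g/h", "1"), 5)),
    tibble(trait = paste0("ratio_", pairs$a, "_", pairs$b), unit = "1"),
    tibble(trait = paste0("frac_", ions), unit = "1")
  ) %>% mutate(block = "uptake")
  plant <- tibble(
    trait = c("root_len_seminal_cm", "root_len_lateral_cm",
              "root_len_secondary_cm", "root_len_total_cm",
              "dw_root_g", "dw_leaf_g", "dw_stem_g", "dw_shoot_g", "dw_total_g",
              "srl_cm_g", "resp_total_nmol_s", "resp_specific_nmol_m_s",
              "leaf_area_cm2", "leaf_len_cm", "root_shoot_dw_ratio"),
    unit = c("cm", "cm", "cm", "cm", "g", "g", "g", "g", "g",
             "cm/g", "nmol/s", "nmol/m/s", "cm2", "cm", "1"),
    block = "plant"
  )
  out <- bind_rows(uptake, plant)
  attr(out, "schema_version") <- "1.0"
  out[, c("trait", "block", "unit")]
}

#' Pairwise uptake-rate ratio
#'
#' Ratio of two net uptake rates. A zero denominator yields `NA` (flagged
#' downstream) rather than an error; negative (efflux) rates pass through.
#'
#' @param rate_a,rate_b Numerator and denominator rates (vectorized).
#' @return `rate_a / rate_b`, `NA` where `rate_b` is 0 or missing.
#' @export
uptake_ratio <- function(rate_a, rate_b) {
  ifelse(is.na(rate_b) | rate_b == 0, NA_real_, rate_a / rate_b)
}

#' Stoichiometric fractions of focal-ion uptake
#'
#' Each positive net uptake rate divided by the sum of positive rates;
#' negative (efflux) rates contribute zero and are flagged, since fractions
#' of a signed total are uninterpretable. If no rate is positive all
#' fractions are missing.
#'
#' @param rates Named numeric vector of net uptake rates (names are ions).
#' @return Tibble `ion`, `fraction`, `flagged` (TRUE for efflux/missing
#'   contributions).
#' @export
stoichiometric_fractions <- function(rates) {
  stopifnot(!is.null(names(rates)))
  pos <- !is.na(rates) & rates > 0
  flagged <- is.na(rates) | rates < 0
  total <- sum(rates[pos])
  frac <- if (total > 0) ifelse(pos, rates / total, 0) else rep(NA_real_, length(rates))
  frac[is.na(rates)] <- NA_real_
  tibble(ion = names(rates), fraction = unname(frac), flagged = unname(flagged))
}

#' Assemble the 50-trait row for one plant
#'
#' Combines a plant record (root classes, dry weights, respiration, leaf
#' measures) with its five focal-ion uptake records into one standardized
#' trait row. Missing measurements propagate as missing traits; the row is
#' always emitted with the full 50-trait schema.
#'
#' @param plant One-row tibble with `plant_id`, `genotype`, `treatment`,
#'   `run`, `block`, `root_seminal_cm`, `root_lateral_cm`,
#'   `root_secondary_cm`, `root_total_cm`, `dw_root_g`, `dw_leaf_g`,
#'   `dw_stem_g`, `resp_total_nmol_s`, `leaf_area_cm2`, `leaf_len_cm`.
#' @param uptake Uptake records for this plant (one row per focal ion) with
#'   `ion`, `influx_umol_h`, `sur_len_umol_cm_h`, `sur_mass_umol_g_h`,
#'   `depletion_frac`.
#' @return One-row tibble: 5 metadata columns + 50 trait columns.
#' @export
compute_traits <- function(plant, uptake) {
  stopifnot(nrow(plant) == 1)
  if (anyDuplicated(uptake$ion)) {
    abort(sprintf("compute_traits: duplicate uptake records for ion(s): %s",
                  paste(unique(uptake$ion[duplicated(uptake$ion)]), collapse = ", ")))
  }
  ions <- focal_ions()
  up <- left_join(tibble(ion = ions), uptake, by = "ion")
  grab <- function(col) setNames(up[[col]] %||% rep(NA_real_, 5), ions)
  rate <- grab("influx_umol_h")
  surl <- grab("sur_len_umol_cm_h")
  surm <- grab("sur_mass_umol_g_h")
  depl <- grab("depletion_frac")

  vals <- c(
    rbind(rate, surl, surm, depl) %>%
      as.vector() %>%
      setNames(paste0(rep(ions, each = 4), "_",
                      rep(c("uptake_umol_h", "sur_len_umol_cm_h",
                            "sur_mass_umol_g_h", "depletion_frac"), 5)))
  )
  pairs <- ion_pairs()
  ratios <- setNames(uptake_ratio(rate[pairs$a], rate[pairs$b]),
                     paste0("ratio_", pairs$a, "_", pairs$b))
  fr <- stoichiometric_fractions(rate)
  fracs <- setNames(fr$fraction, paste0("frac_", fr$ion))

  num <- function(col) {
    v <- plant[[col]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  shoot <- num("dw_leaf_g") + num("dw_stem_g")
  root <- num("dw_root_g")
  total_len <- num("root_total_cm")
  plant_traits <- c(
    root_len_seminal_cm = num("root_seminal_cm"),
    root_len_lateral_cm = num("root_lateral_cm"),
    root_len_secondary_cm = num("root_secondary_cm"),
    root_len_total_cm = total_len,
    dw_root_g = root,
    dw_leaf_g = num("dw_leaf_g"),
    dw_stem_g = num("dw_stem_g"),
    dw_shoot_g = shoot,
    dw_total_g = shoot + root,
    srl_cm_g = if (!is.na(root) && root > 0) total_len / root else NA_real_,
    resp_total_nmol_s = num("resp_total_nmol_s"),
    resp_specific_nmol_m_s = if (!is.na(total_len) && total_len > 0) {
      num("resp_total_nmol_s") / (total_len / 100)
    } else NA_real_,
    leaf_area_cm2 = num("leaf_area_cm2"),
    leaf_len_cm = num("leaf_len_cm"),
    root_shoot_dw_ratio = if (!is.na(shoot) && shoot > 0) root / shoot else NA_real_
  )

  meta <- plant %>% select(dplyr::any_of(c("plant_id", "genotype", "treatment",
                                           "run", "block")))
  bind_cols(meta, as_tibble(as.list(c(vals, ratios, fracs, plant_traits))))
}

#' Assemble the trait table for a whole experiment
#'
#' Maps [compute_traits()] over every plant, joining its uptake records.
#'
#' @param plants Plant-record tibble (one row per plant; see
#'   [compute_traits()]).
#' @param uptake Uptake-record tibble for all plants (from
#'   [compute_uptake()]).
#' @return Tibble with one row per plant: metadata + 50 trait columns.
#' @export
compute_trait_table <- function(plants, uptake) {
  plants %>%
    dplyr::group_split(.data$plant_id) %>%
    map(function(p) compute_traits(p, uptake[uptake$plant_id == p$plant_id[1], ])) %>%
    list_rbind()
}
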