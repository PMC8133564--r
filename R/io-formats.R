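# Readers/writers for the tabular formats the pipeline touches. CSV
# throughout; long format is canonical for concentrations (wide exports are
# melted on read). Number parsing is strict: decimal commas and thousands
# separators are rejected, not guessed.

.read_csv_chr <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  comment = "#", progress = FALSE)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
}

# strict numeric conversion; errors with data row numbers on anything that is
# not a plain decimal/scientific number (catches decimal commas, thousands
# separators, stray text)
.parse_num <- function(x, col, path) {
  ok <- is.na(x) | grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
  if (!all(ok)) {
    bad <- which(!ok)
    abort(sprintf("%s: non-numeric value(s) in column '%s' at data row(s): %s",
                  path, col, paste(head(bad, 5), collapse = ", ")))
  }
  as.numeric(x)
}

#' Read a chamber map
#'
#' The chamber map ties each hydroponic chamber to a plant, genotype,
#' treatment label, run, block, and its well in the 96-well collection plate
#' (row-major A1..H12 convention).
#'
#' @param path CSV with columns `chamber_id`, `plant_id`, `genotype`,
#'   `treatment`, `run`, `block`, and optionally `well`.
#' @return Tibble; chamber ids checked unique, wells checked unique within a
#'   run.
#' @export
read_chamber_map <- function(path) {
  df <- .read_csv_chr(path)
  .require_cols(df, c("chamber_id", "plant_id", "genotype", "treatment", "run", "block"),
                path)
  if (anyDuplicated(df$chamber_id)) {
    abort(sprintf("%s: duplicate chamber ids: %s", path,
                  paste(unique(df$chamber_id[duplicated(df$chamber_id)]), collapse = ", ")))
  }
  if ("well" %in% names(df)) {
    dup <- df %>% group_by(.data$run) %>% filter(duplicated(.data$well)) %>% pull("well")
    if (length(dup)) {
      abort(sprintf("%s: duplicate wells within a run: %s", path,
                    paste(unique(dup), collapse = ", ")))
    }
  }
  df
}

#' Read an ion-chromatography concentration export
#'
#' Parses the concentration table exported from the ion-chromatography
#' software into the canonical long form, one row per (chamber, time, ion).
#' The `wide` dialect has one column per ion alongside `time_h` and a
#' `chamber_id` or `well` column; the `long` dialect already carries `ion`
#' and `conc_uM` columns. When the export addresses samples by collection
#' well, a chamber map translates wells to chambers; wells absent from the
#' map are excluded and reported in the `orphans` attribute (with a warning).
#'
#' @param path CSV path.
#' @param dialect `"wide"` or `"long"`.
#' @param chamber_map Optional chamber map (needed for well-addressed
#'   exports).
#' @return Tibble `chamber_id`, `time_h`, `ion`, `conc_uM`, with attributes
#'   `source` (the path) and `orphans` (excluded wells).
#' @export
read_ic_export <- function(path, dialect = c("wide", "long"), chamber_map = NULL) {
  dialect <- match.arg(dialect)
  df <- .read_csv_chr(path)
  orphans <- character()
  if (!"chamber_id" %in% names(df)) {
    if (!"well" %in% names(df)) {
      abort(sprintf("%s: needs a 'chamber_id' or 'well' column", path))
    }
    if (is.null(chamber_map) || !"well" %in% names(chamber_map)) {
      abort(sprintf("%s: well-addressed export needs a chamber map with wells", path))
    }
    wmap <- chamber_map %>% select("chamber_id", "well")
    orphans <- setdiff(unique(df$well), wmap$well)
    if (length(orphans)) {
      warn(sprintf("%s: %d well(s) not in the chamber map, excluded: %s", path,
                   length(orphans), paste(orphans, collapse = ", ")))
    }
    df <- df %>% dplyr::inner_join(wmap, by = "well") %>% select(-"well")
  }
  if (dialect == "long") {
    .require_cols(df, c("time_h", "ion", "conc_uM"), path)
    out <- df %>% select("chamber_id", "time_h", "ion", "conc_uM")
  } else {
    .require_cols(df, "time_h", path)
    ion_cols <- setdiff(names(df), c("chamber_id", "time_h"))
    if (length(ion_cols) == 0) abort(sprintf("%s: wide export has no ion columns", path))
    out <- df %>%
      tidyr::pivot_longer(all_of(ion_cols), names_to = "ion", values_to = "conc_uM")
  }
  out <- out %>%
    mutate(time_h = .parse_num(.data$time_h, "time_h", path),
           conc_uM = .parse_num(.data$conc_uM, "conc_uM", path))
  if (any(out$time_h < 0, na.rm = TRUE)) abort(sprintf("%s: negative sampling time", path))
  if (any(out$conc_uM < 0, na.rm = TRUE)) abort(sprintf("%s: negative concentration", path))
  dup <- duplicated(out[, c("chamber_id", "time_h", "ion")])
  if (any(dup)) {
    abort(sprintf("%s: duplicate (chamber, time, ion) combinations, e.g. %s/%s/%s",
                  path, out$chamber_id[dup][1], out$time_h[dup][1], out$ion[dup][1]))
  }
  out <- out %>% filter(!is.na(.data$conc_uM)) %>% arrange(.data$chamber_id, .data$ion, .data$time_h)
  attr(out, "source") <- path
  attr(out, "orphans") <- orphans
  out
}

#' Write a concentration table (canonical long CSV)
#'
#' @param conc Long tibble (`chamber_id`, `time_h`, `ion`, `conc_uM`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ic_export <- function(conc, path) {
  readr::write_csv(conc[, c("chamber_id", "time_h", "ion", "conc_uM")], path)
  invisible(path)
}

#' Read a root-trait table
#'
#' `classified` mode expects the three class lengths directly (WinRhizo
#' post-processing already applied); `binned` mode expects diameter-binned
#' lengths, which are aggregated into the seminal/lateral/secondary classes
#' by [classify_root_lengths()]. Dry weights, respiration, and leaf measures
#' are carried through when present.
#'
#' @param path CSV path. Classified mode: `plant_id`, `root_seminal_cm`,
#'   `root_lateral_cm`, `root_secondary_cm` + optional measurement columns.
#'   Binned mode: `plant_id`, `diameter_mm`, `length_cm` (+ optional
#'   per-plant measurement columns, constant within plant).
#' @param mode `"classified"` or `"binned"`.
#' @return Tibble with one row per plant including `root_total_cm`.
#' @export
read_root_traits <- function(path, mode = c("classified", "binned")) {
  mode <- match.arg(mode)
  df <- .read_csv_chr(path)
  if (nrow(df) == 0) {
    warn(sprintf("%s: empty root-trait file", path))
    return(tibble(plant_id = character(), root_seminal_cm = double(),
                  root_lateral_cm = double(), root_secondary_cm = double(),
                  root_total_cm = double()))
  }
  extra_cols <- c("dw_root_g", "dw_leaf_g", "dw_stem_g", "resp_total_nmol_s",
                  "leaf_area_cm2", "leaf_len_cm")
  if (mode == "classified") {
    .require_cols(df, c("plant_id", "root_seminal_cm", "root_lateral_cm",
                        "root_secondary_cm"), path)
    num_cols <- intersect(c("root_seminal_cm", "root_lateral_cm",
                            "root_secondary_cm", extra_cols), names(df))
    out <- df
    for (cl in num_cols) out[[cl]] <- .parse_num(out[[cl]], cl, path)
    lens <- c("root_seminal_cm", "root_lateral_cm", "root_secondary_cm")
    if (any(as.matrix(out[, lens]) < 0, na.rm = TRUE)) {
      abort(sprintf("%s: negative root length", path))
    }
    out$root_total_cm <- rowSums(out[, lens])
    out %>% select("plant_id", all_of(lens), "root_total_cm",
                   all_of(intersect(extra_cols, names(out))))
  } else {
    .require_cols(df, c("plant_id", "diameter_mm", "length_cm"), path)
    df$diameter_mm <- .parse_num(df$diameter_mm, "diameter_mm", path)
    df$length_cm <- .parse_num(df$length_cm, "length_cm", path)
    if (any(df$length_cm < 0, na.rm = TRUE)) abort(sprintf("%s: negative root length", path))
    extras <- df %>%
      select("plant_id", all_of(intersect(extra_cols, names(df)))) %>%
      distinct(.data$plant_id, .keep_all = TRUE)
    for (cl in intersect(extra_cols, names(extras))) {
      extras[[cl]] <- .parse_num(extras[[cl]], cl, path)
    }
    classes <- df %>%
      group_by(.data$plant_id) %>%
      dplyr::group_modify(~ classify_root_lengths(.x)) %>%
      ungroup() %>%
      rename(root_seminal_cm = "seminal_cm", root_lateral_cm = "lateral_cm",
             root_secondary_cm = "secondary_cm", root_total_cm = "total_cm") %>%
      select(-"oversize_cm")
    left_join(classes, extras, by = "plant_id")
  }
}

#' Write the standardized trait table
#'
#' One row per plant in the 50-trait schema, preceded by a sidecar header of
#' `#`-prefixed lines documenting the unit of every trait column. Re-reading
#' with [read_trait_table()] reproduces the values exactly.
#'
#' @param traits Trait table from [compute_trait_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  schema <- trait_schema()
  miss <- setdiff(schema$trait, names(traits))
  if (length(miss)) {
    abort(sprintf("trait table does not match the 50-trait schema; missing: %s",
                  paste(miss, collapse = ", ")))
  }
  meta <- setdiff(names(traits), schema$trait)
  ordered <- traits[, c(meta, schema$trait)]
  hdr <- c(sprintf("# ionuptake trait table (schema 1.0): %d uptake + %d plant traits",
                   sum(schema$block == "uptake"), sum(schema$block == "plant")),
           sprintf("# %s: %s", schema$trait, schema$unit))
  writeLines(hdr, path)
  readr::write_csv(ordered, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a trait table written by [write_trait_table()]
#'
#' @param path CSV path.
#' @return Tibble with metadata and trait columns.
#' @export
read_trait_table <- function(path) {
  df <- .read_csv_chr(path)
  schema <- trait_schema()
  for (cl in intersect(schema$trait, names(df))) df[[cl]] <- .parse_num(df[[cl]], cl, path)
  if ("run" %in% names(df)) df$run <- .parse_num(df$run, "run", path)
  if ("block" %in% names(df)) df$block <- .parse_num(df$block, "block", path)
  df
}

#' Read an experiment configuration
#'
#' YAML with an `experiment` block: `modules`, `chambers_per_module`,
#' `schedule_h`, `volume_ml`, `sample_volume_ml`, `depletion_threshold`.
#' Missing entries fall back to the platform defaults (2 modules of 24
#' chambers, schedule 0, 0.5, 1, 2, 3, 4, 6, 8 h, 250 mL chambers, 1.5 mL
#' samples, 10% depletion rule).
#'
#' @param path YAML path.
#' @return Named list of settings.
#' @export
read_experiment_config <- function(path) {
  defaults <- list(modules = 2L, chambers_per_module = 24L,
                   schedule_h = c(0, 0.5, 1, 2, 3, 4, 6, 8),
                   volume_ml = 250, sample_volume_ml = 1.5,
                   depletion_threshold = 0.1)
  if (is.null(path)) return(defaults)
  y <- yaml::read_yaml(path)
  modifyList(defaults, y$experiment %||% list())
}
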