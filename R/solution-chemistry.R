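# Salt-based nutrient recipes resolved to ionic compositions by stoichiometry.
# Hydration water in salt formulas is ignored; the dihydrogen-phosphate anion is
# reported under the field's usual shorthand "phosphate".

#' The five focal macronutrient ions
#'
#' Fixed identifiers (alphabetical) for the ions whose uptake the pipeline
#' quantifies: ammonium, nitrate, phosphate (dihydrogen-phosphate), potassium,
#' and sulfate.
#'
#' @return Character vector of length 5.
#' @export
focal_ions <- function() {
  c("ammonium", "nitrate", "phosphate", "potassium", "sulfate")
}

# stoichiometry (ions per formula unit), role, and per-entry charge for the
# salts used across the growth, deprivation, and assay solutions
.salt_library <- list(
  "KNO3"               = list(ions = c(potassium = 1, nitrate = 1), role = "macronutrient"),
  "NH4Cl"              = list(ions = c(ammonium = 1, chloride = 1), role = "macronutrient"),
  "Ca(H2PO4)2.H2O"     = list(ions = c(calcium = 1, phosphate = 2), role = "macronutrient"),
  "MgSO4"              = list(ions = c(magnesium = 1, sulfate = 1), role = "macronutrient"),
  "CaCl2"              = list(ions = c(calcium = 1, chloride = 2), role = "macronutrient"),
  "KH2PO4"             = list(ions = c(potassium = 1, phosphate = 1), role = "macronutrient"),
  "NH4NO3"             = list(ions = c(ammonium = 1, nitrate = 1), role = "macronutrient"),
  "CaSO4"              = list(ions = c(calcium = 1, sulfate = 1), role = "macronutrient"),
  "H3BO3"              = list(ions = c(borate = 1), role = "micronutrient"),
  "ZnSO4.7H2O"         = list(ions = c(zinc = 1, sulfate = 1), role = "micronutrient"),
  "MnCl2.4H2O"         = list(ions = c(manganese = 1, chloride = 2), role = "micronutrient"),
  "CuSO4.5H2O"         = list(ions = c(copper = 1, sulfate = 1), role = "micronutrient"),
  "(NH4)6Mo7O24.4H2O"  = list(ions = c(ammonium = 6, molybdate = 7), role = "micronutrient"),
  "Fe(III)-EDTA"       = list(ions = c(iron_edta = 1), role = "micronutrient"),
  "MES"                = list(ions = c(mes = 1), role = "buffer")
)

.ion_charge <- c(
  ammonium = 1, nitrate = -1, phosphate = -1, potassium = 1, sulfate = -2,
  calcium = 2, magnesium = 2, chloride = -1, borate = 0, zinc = 2,
  manganese = 2, copper = 2, molybdate = -6 / 7, iron_edta = -1, mes = 0
)

#' Known salt stoichiometries
#'
#' @return A tibble with one row per salt known to the package: `name`,
#'   `role` (macronutrient, micronutrient, or buffer) and `ions`, a
#'   list-column of named stoichiometric counts per formula unit.
#' @export
salt_library <- function() {
  tibble(
    name = names(.salt_library),
    role = map_chr(.salt_library, "role"),
    ions = map(.salt_library, "ions")
  )
}

#' Define a salt
#'
#' @param name Salt identifier, e.g. `"KNO3"`.
#' @param conc_uM Molar concentration of the salt in the solution (µM).
#' @param ions Named numeric vector of stoichiometric counts per formula unit
#'   (e.g. `c(calcium = 1, chloride = 2)`). Defaults to the packaged library
#'   entry for `name`.
#' @param role One of `"macronutrient"`, `"micronutrient"`, `"buffer"`.
#'   Defaults to the library entry, or `"macronutrient"` for unknown salts.
#' @return A one-row tibble (`name`, `conc_uM`, `role`, `ions` list-column).
#' @export
salt <- function(name, conc_uM, ions = NULL, role = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(conc_uM) || length(conc_uM) != 1 || is.na(conc_uM) || conc_uM < 0) {
    abort(sprintf("salt '%s': concentration must be a single non-negative number", name))
  }
  lib <- .salt_library[[name]]
  if (is.null(ions)) {
    if (is.null(lib)) abort(sprintf("unknown salt '%s': supply its ion stoichiometry", name))
    ions <- lib$ions
  }
  if (is.null(role)) role <- if (is.null(lib)) "macronutrient" else lib$role
  if (length(ions) == 0 || is.null(names(ions)) || any(!nzchar(names(ions))) ||
      !any(ions >= 1)) {
    abort(sprintf("salt '%s': needs at least one named ion with count >= 1", name))
  }
  if (any(ions < 0)) abort(sprintf("salt '%s': negative stoichiometric count", name))
  tibble(name = name, conc_uM = conc_uM, role = role, ions = list(ions))
}

#' Define a nutrient solution recipe
#'
#' A recipe is a labelled set of salts at molar concentrations; the ionic
#' composition follows by stoichiometry (see [compose_ions()]).
#'
#' @param label Recipe label, e.g. `"high"`, `"low"`, `"growth"`.
#' @param salts Either a named numeric vector of salt concentrations in µM
#'   (names resolved through [salt_library()]) or a tibble of [salt()] rows.
#' @param ph Solution pH (informational).
#' @return A tibble of salts with attributes `label` and `ph`, class
#'   `"nutrient_recipe"`.
#' @examples
#' high <- recipe("high", c(
#'   "KNO3" = 1000, "NH4Cl" = 1000, "Ca(H2PO4)2.H2O" = 125,
#'   "MgSO4" = 250, "CaCl2" = 375, "MES" = 1000
#' ))
#' compose_ions(high)
#' @export
recipe <- function(label, salts, ph = 6) {
  stopifnot(is.character(label), length(label) == 1)
  if (is.numeric(salts)) {
    if (is.null(names(salts))) abort("numeric `salts` must be named by salt")
    salts <- purrr::imap(salts, function(conc, nm) salt(nm, conc)) %>% list_rbind()
  }
  if (!is.data.frame(salts) || !all(c("name", "conc_uM", "role", "ions") %in% names(salts))) {
    abort("`salts` must be a named numeric vector or a tibble of salt() rows")
  }
  if (anyDuplicated(salts$name)) {
    abort(sprintf("recipe '%s': duplicate salt names: %s", label,
                  paste(unique(salts$name[duplicated(salts$name)]), collapse = ", ")))
  }
  if (any(salts$conc_uM < 0)) abort(sprintf("recipe '%s': negative salt concentration", label))
  out <- as_tibble(salts)
  attr(out, "label") <- label
  attr(out, "ph") <- ph
  class(out) <- c("nutrient_recipe", class(out))
  out
}

#' @export
print.nutrient_recipe <- function(x, ...) {
  cat(sprintf("<nutrient_recipe> label: %s, pH %s, %d salts\n",
              recipe_label(x), attr(x, "ph"), nrow(x)))
  NextMethod()
}

#' Recipe label accessor
#' @param recipe A [recipe()].
#' @return The label string.
#' @export
recipe_label <- function(recipe) attr(recipe, "label")

#' Resolve a recipe into its ionic composition
#'
#' Totals each ion over all salts as salt concentration times stoichiometric
#' count; additive and linear in salt concentrations. Ions absent from every
#' salt are absent from the result.
#'
#' @param recipe A [recipe()].
#' @param roles Salt roles to include; default all
#'   (`macronutrient`, `micronutrient`, `buffer`).
#' @param ions Optional ion subset to keep (after totalling).
#' @return A tibble with columns `ion` and `conc_uM`, sorted by ion.
#' @export
compose_ions <- function(recipe, roles = c("macronutrient", "micronutrient", "buffer"),
                         ions = NULL) {
  stopifnot(inherits(recipe, "nutrient_recipe") || is.data.frame(recipe))
  if (any(recipe$conc_uM < 0)) abort("negative salt concentration")
  use <- recipe[recipe$role %in% roles, , drop = FALSE]
  if (nrow(use) == 0) return(tibble(ion = character(), conc_uM = double()))
  contrib <- purrr::map2(use$ions, use$conc_uM, function(st, conc) {
    tibble(ion = names(st), conc_uM = unname(st) * conc)
  }) %>% list_rbind()
  out <- contrib %>%
    group_by(.data$ion) %>%
    summarise(conc_uM = sum(.data$conc_uM), .groups = "drop") %>%
    arrange(.data$ion)
  if (!is.null(ions)) out <- out[out$ion %in% ions, , drop = FALSE]
  out
}

#' Focal-ion composition of a recipe
#'
#' The designed starting concentrations of the five focal macronutrient ions.
#' Only macronutrient-role salts contribute, so e.g. the trace ammonium carried
#' by the molybdate micronutrient salt is recorded in [compose_ions()] but
#' excluded here.
#'
#' @param recipe A [recipe()].
#' @return Tibble `ion`, `conc_uM` with one row per focal ion present.
#' @export
focal_composition <- function(recipe) {
  compose_ions(recipe, roles = "macronutrient", ions = focal_ions())
}

#' Fold difference between two ionic compositions
#'
#' @param a,b Compositions as returned by [compose_ions()] (numerator `a`).
#' @param ions Ions to compare; default all ions shared by both.
#' @return Tibble with `ion`, `a_uM`, `b_uM`, `ratio` (= a/b).
#' @export
fold_difference <- function(a, b, ions = NULL) {
  stopifnot(all(c("ion", "conc_uM") %in% names(a)), all(c("ion", "conc_uM") %in% names(b)))
  if (is.null(ions)) ions <- intersect(a$ion, b$ion)
  missing_a <- setdiff(ions, a$ion)
  missing_b <- setdiff(ions, b$ion)
  if (length(missing_a) || length(missing_b)) {
    abort(sprintf("ions missing from composition: %s",
                  paste(unique(c(missing_a, missing_b)), collapse = ", ")))
  }
  av <- setNames(a$conc_uM, a$ion)[ions]
  bv <- setNames(b$conc_uM, b$ion)[ions]
  zero <- ions[bv <= 0]
  if (length(zero)) {
    abort(sprintf("zero denominator concentration for ion(s): %s",
                  paste(zero, collapse = ", ")))
  }
  tibble(ion = ions, a_uM = unname(av), b_uM = unname(bv), ratio = unname(av / bv))
}

#' Informational charge balance of a recipe
#'
#' Net charge of the composed solution in µeq L⁻¹. Reported for inspection
#' only; printed recipes need not balance once buffers and pH adjustment are
#' included, so no check is enforced.
#'
#' @param recipe A [recipe()].
#' @return Tibble `ion`, `conc_uM`, `charge`, `ueq`, plus attribute
#'   `net_ueq` with the signed total.
#' @export
charge_balance <- function(recipe) {
  comp <- compose_ions(recipe)
  comp$charge <- unname(.ion_charge[comp$ion])
  comp$charge[is.na(comp$charge)] <- 0
  comp$ueq <- comp$conc_uM * comp$charge
  attr(comp, "net_ueq") <- sum(comp$ueq)
  comp
}

# ---- design rules ------------------------------------------------------------

#' Design rules for solution sets
#'
#' `rule_constant()` requires an ion to sit at a fixed total concentration in
#' each listed recipe; `rule_fold()` requires a fixed numerator:denominator
#' concentration ratio for each listed ion between two recipes.
#'
#' @param ion,ions Ion identifier(s).
#' @param value_uM Required total concentration (µM).
#' @param labels Recipe labels the constant applies to.
#' @param ratio Required fold ratio.
#' @param numerator,denominator Recipe labels for the ratio.
#' @param tol Comparison tolerance.
#' @return A rule object consumed by [check_design()].
#' @export
rule_constant <- function(ion, value_uM, labels, tol = 1e-9) {
  structure(list(ion = ion, value_uM = value_uM, labels = labels, tol = tol),
            class = c("rule_constant", "design_rule"))
}

#' @rdname rule_constant
#' @export
rule_fold <- function(ions, ratio, numerator, denominator, tol = 1e-9) {
  structure(list(ions = ions, ratio = ratio, numerator = numerator,
                 denominator = denominator, tol = tol),
            class = c("rule_fold", "design_rule"))
}

#' The default assay design rules
#'
#' Calcium held at 500 µM in the high and low assay solutions, and every focal
#' macronutrient exactly 10-fold higher in the high than the low solution.
#'
#' @return List of design rules.
#' @export
design_rules <- function() {
  list(
    rule_constant("calcium", 500, c("high", "low")),
    rule_fold(focal_ions(), 10, "high", "low")
  )
}

#' Check a set of recipes against design rules
#'
#' @param recipes A list of [recipe()]s (named by label, or labels are taken
#'   from the recipes themselves).
#' @param rules List of rules from [rule_constant()] / [rule_fold()].
#' @return Tibble report: `rule`, `ion`, `recipe`, `expected`, `observed`,
#'   `pass`. Empty rules give an empty report.
#' @export
check_design <- function(recipes, rules = design_rules()) {
  if (!length(names(recipes)) || any(!nzchar(names(recipes)))) {
    names(recipes) <- vapply(recipes, recipe_label, character(1))
  }
  comps <- map(recipes, compose_ions)
  get_comp <- function(label) {
    if (!label %in% names(comps)) {
      abort(sprintf("design rule references unknown recipe label '%s'", label))
    }
    comps[[label]]
  }
  conc_of <- function(comp, ion) {
    v <- comp$conc_uM[comp$ion == ion]
    if (length(v) == 0) 0 else v
  }
  rows <- map(rules, function(rule) {
    if (inherits(rule, "rule_constant")) {
      label <- sprintf("%s constant at %g uM", rule$ion, rule$value_uM)
      io <- rule$ion
      target <- rule$value_uM
      tol <- rule$tol
      map(rule$labels, function(lab) {
        obs <- conc_of(get_comp(lab), io)
        tibble(rule = label, ion = io, recipe = lab,
               expected = target, observed = obs,
               pass = abs(obs - target) <= tol)
      }) %>% list_rbind()
    } else if (inherits(rule, "rule_fold")) {
      num <- get_comp(rule$numerator)
      den <- get_comp(rule$denominator)
      label <- sprintf("%g-fold %s:%s", rule$ratio, rule$numerator, rule$denominator)
      pair <- paste(rule$numerator, rule$denominator, sep = "/")
      target <- rule$ratio
      tol <- rule$tol
      map(rule$ions, function(io) {
        fd <- fold_difference(num, den, io)
        tibble(rule = label, ion = io, recipe = pair,
               expected = target, observed = fd$ratio,
               pass = abs(fd$ratio - target) <= tol)
      }) %>% list_rbind()
    } else {
      abort("unknown design rule type")
    }
  })
  if (length(rows) == 0) {
    return(tibble(rule = character(), ion = character(), recipe = character(),
                  expected = double(), observed = double(), pass = logical()))
  }
  list_rbind(rows)
}

# ---- packaged recipes --------------------------------------------------------

#' Read recipes from a YAML file
#'
#' Expected layout: a top-level `recipes` list, each entry with `label`,
#' optional `ph`, and `salts` entries `{name, conc_uM, ions (optional),
#' role (optional)}`. Unknown salts must carry an inline `ions` map.
#'
#' @param path Path to the YAML file.
#' @return Named list of [recipe()]s.
#' @export
read_recipes <- function(path) {
  if (!file.exists(path)) abort(sprintf("recipe file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$recipes)) abort("recipe file lacks a top-level 'recipes' list")
  out <- map(y$recipes, function(r) {
    salts <- map(r$salts, function(s) {
      ions <- if (!is.null(s$ions)) unlist(s$ions) else NULL
      salt(s$name, s$conc_uM, ions = ions, role = s$role)
    }) %>% list_rbind()
    recipe(r$label, salts, ph = r$ph %||% 6)
  })
  setNames(out, vapply(out, recipe_label, character(1)))
}

#' The packaged nutrient solution recipes
#'
#' The four solutions of the assay workflow: `growth` (modified half-strength
#' Hoagland), `deprivation` (macronutrient-free, 48 h before assay), and the
#' `high` / `low` assay solutions (10-fold macronutrient contrast, calcium
#' held at 500 µM, 1 mM MES, pH 6).
#'
#' @return Named list of [recipe()]s.
#' @export
nutrient_recipes <- function() {
  read_recipes(system.file("extdata", "recipes.yaml", package = "ionuptake",
                           mustWork = TRUE))
}

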