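## Biomass objective construction: measured macromolecular mass fractions
## -> mmol/gDCW precursor coefficients -> biomass pseudo-reaction, elemental
## biomass formula, degree of reduction and photosynthetic quotient.

#' Default monomer templates
#'
#' Loads the monomer templates shipped with the package: amino-acid usage
#' for protein (and phycobiliproteins), equimolar NMP/dNMP profiles for RNA
#' and DNA, glucosyl residues for glycogen and other carbohydrate, a
#' C16:0/C18:1 acyl profile for lipid, and single-molecule entries for the
#' pigments. See the package vignette for the rationale; every entry can be
#' replaced by a user template.
#'
#' @param path optional YAML file overriding the shipped template.
#' @return named list: component -> tibble(monomer, mole_fraction, formula,
#'   residue_mass, metabolite).
#' @export
default_monomer_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "monomer_templates.yaml",
                        package = "cyanoflux")
  }
  raw <- yaml::read_yaml(path)
  ## resolve profile aliases (e.g. phycobiliproteins -> protein)
  resolve <- function(nm) {
    entry <- raw[[nm]]
    if (!is.null(entry$use_profile_of)) entry <- raw[[entry$use_profile_of]]
    dplyr::bind_rows(lapply(entry$monomers, tibble::as_tibble)) |>
      dplyr::rename(monomer = "id")
  }
  stats::setNames(lapply(names(raw), resolve), names(raw))
}

#' Read a macromolecular composition CSV
#'
#' Expected columns: `component`, `mass_fraction` (mg per mg DCW) and
#' optionally `sd`.
#'
#' @param path CSV file.
#' @return tibble.
#' @export
read_composition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("component", "mass_fraction") %in% names(df))) {
    stop("composition CSV needs columns 'component' and 'mass_fraction'",
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Assemble a biomass composition object
#'
#' Joins measured mass fractions (mg/mg DCW) with monomer templates and
#' checks closure: fractions must be non-negative and their sum close to 1.
#' Components not summing to unity (common when soluble pool, inorganic ions
#' and peptidoglycan are taken from literature rather than measured) are
#' tolerated within `closure_tol`; beyond that a warning is issued.
#'
#' @param fractions tibble with `component`, `mass_fraction` and optional `sd`,
#'   or a path to such a CSV.
#' @param templates monomer templates, see [default_monomer_templates()].
#' @param closure_tol allowed deviation of `sum(mass_fraction)` from 1.
#' @return object of class `biomass_composition`.
#' @export
biomass_composition <- function(fractions,
                                templates = default_monomer_templates(),
                                closure_tol = 0.05) {
  if (is.character(fractions)) fractions <- read_composition_csv(fractions)
  fractions <- tibble::as_tibble(fractions)
  if (any(fractions$mass_fraction < 0)) {
    stop("negative mass fractions", call. = FALSE)
  }
  unknown <- setdiff(fractions$component, names(templates))
  if (length(unknown)) {
    stop("no monomer template for component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (comp in fractions$component) {
    tpl <- templates[[comp]]
    if (any(tpl$residue_mass <= 0)) {
      stop("non-positive residue mass in template for ", comp, call. = FALSE)
    }
    if (abs(sum(tpl$mole_fraction) - 1) > 1e-6) {
      templates[[comp]]$mole_fraction <-
        tpl$mole_fraction / sum(tpl$mole_fraction)
    }
  }
  closure <- sum(fractions$mass_fraction)
  if (abs(closure - 1) > closure_tol) {
    warning(sprintf(
      "mass fractions sum to %.3f; more than %.2f away from 1 %s", closure,
      closure_tol, "(declare a remainder component or check the input)"),
      call. = FALSE)
  }
  structure(list(fractions = fractions,
                 templates = templates[fractions$component],
                 closure = closure),
            class = "biomass_composition")
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("<biomass_composition>", nrow(x$fractions), "components, mass closure",
      sprintf("%.3f", x$closure), "\n")
  print(x$fractions)
  invisible(x)
}

#' Convert mass fractions to biomass-equation coefficients
#'
#' For a polymer with mass fraction `w` and mole-fraction-weighted residue
#' molar mass `M` (g/mol), the coefficient of monomer `m` with mole fraction
#' `x_m` is `1000 * w * x_m / M` mmol per gDCW. Single molecules are the
#' one-monomer special case. Zero-fraction components are dropped.
#'
#' @param composition a [biomass_composition()].
#' @return tibble with `component`, `monomer`, `metabolite`, `formula`,
#'   `residue_mass`, `coefficient` (mmol/gDCW).
#' @export
normalize_composition <- function(composition) {
  stopifnot(inherits(composition, "biomass_composition"))
  purrr::map2_dfr(
    composition$fractions$component, composition$fractions$mass_fraction,
    function(comp, w) {
      if (w == 0) return(NULL)
      tpl <- composition$templates[[comp]]
      mbar <- sum(tpl$mole_fraction * tpl$residue_mass)
      tibble::tibble(
        component = comp, monomer = tpl$monomer, metabolite = tpl$metabolite,
        formula = tpl$formula, residue_mass = tpl$residue_mass,
        coefficient = 1000 * w * tpl$mole_fraction / mbar)
    }) |>
    ## a metabolite contributed by several components (e.g. glucosyl from
    ## glycogen and other carbohydrate) keeps separate rows; summing happens
    ## when the reaction is composed
    dplyr::filter(.data$coefficient > 0)
}

#' Mass closure of a normalised composition
#'
#' @param normalized output of [normalize_composition()].
#' @return total precursor mass in mg per gDCW
#'   (`sum(coefficient * residue_mass)`); close to `1000 * sum(mass_fraction)`.
#' @export
mass_closure <- function(normalized) {
  sum(normalized$coefficient * normalized$residue_mass)
}

#' Growth and non-growth associated maintenance parameters
#'
#' @param gam growth-associated maintenance, mmol ATP per gDCW (appears as
#'   the ATP coefficient of the biomass equation).
#' @param ngam non-growth-associated maintenance, mmol ATP/(gDCW h) (a fixed
#'   flux through the ATP-hydrolysis maintenance reaction).
#' @param provenance free-text note on where the values come from.
#' @return object of class `energy_parameters`.
#' @export
energy_parameters <- function(gam = 53, ngam = 1.3,
                              provenance = "adopted from published Synechococcus sp. PCC 7002 models") {
  stopifnot(gam >= 0, ngam >= 0)
  structure(list(gam = gam, ngam = ngam, provenance = provenance),
            class = "energy_parameters")
}

#' Compose the biomass pseudo-reaction
#'
#' Builds a reaction consuming every precursor at its mmol/gDCW coefficient
#' plus `gam` ATP and `gam` H2O, producing one unit of biomass plus `gam`
#' ADP and `gam` Pi. Metabolite ids come from the monomer templates.
#'
#' @param composition a [biomass_composition()].
#' @param energy an [energy_parameters()].
#' @param id reaction id.
#' @param model optional target `metabolic_model`; if given, an error lists
#'   precursor metabolites absent from it.
#' @param energy_mets named character vector mapping `atp`, `adp`, `pi`,
#'   `h2o` to model metabolite ids.
#' @param biomass_met id of the biomass product pseudo-metabolite.
#' @return one-row reaction tibble (columns as in `metabolic_model` reactions).
#' @export
compose_biomass_reaction <- function(composition, energy = energy_parameters(),
                                     id = "BIOMASS", model = NULL,
                                     energy_mets = c(atp = "atp_c", adp = "adp_c",
                                                     pi = "pi_c", h2o = "h2o_c"),
                                     biomass_met = "biomass_c") {
  normalized <- normalize_composition(composition)
  coefs <- tapply(normalized$coefficient,
                  factor(normalized$metabolite,
                         levels = unique(normalized$metabolite)), sum)
  stoich <- c(
    stats::setNames(-as.vector(coefs), names(coefs)),
    stats::setNames(c(-energy$gam, -energy$gam, energy$gam, energy$gam),
                    energy_mets[c("atp", "h2o", "adp", "pi")]),
    stats::setNames(1, biomass_met))
  ## merge in case a precursor id coincides with an energy metabolite
  stoich <- tapply(unname(stoich),
                   factor(names(stoich), levels = unique(names(stoich))), sum)
  stoich <- stats::setNames(as.vector(stoich), names(stoich))
  if (!is.null(model)) {
    missing <- setdiff(names(stoich), model$metabolites$id)
    if (length(missing)) {
      stop("precursor metabolite(s) absent from model: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  tibble::tibble(
    id = id, name = "Biomass equation",
    stoichiometry = list(stoich[stoich != 0]),
    lower_bound = 0, upper_bound = 1000,
    subsystem = "biomass", category = "biomass",
    gene_association = "", evidence = "annotated")
}

#' Per-carbon elemental biomass formula
#'
#' Sums `coefficient * element count` over all precursors (energy species
#' are not part of the normalised table and therefore excluded) and
#' normalises to one carbon.
#'
#' @param normalized output of [normalize_composition()], or any tibble with
#'   `coefficient` and `formula` columns.
#' @return object of class `elemental_formula`: named numeric per-carbon
#'   counts with attribute `total_c_mmol` (mmol C per gDCW).
#' @export
elemental_formula <- function(normalized) {
  if (any(!nzchar(normalized$formula) | is.na(normalized$formula))) {
    stop("precursor(s) without elemental formula: ",
         paste(normalized$metabolite[!nzchar(normalized$formula) |
                                       is.na(normalized$formula)],
               collapse = ", "), call. = FALSE)
  }
  tot <- sum_formulas(normalized$formula, normalized$coefficient)
  if (!"C" %in% names(tot) || tot[["C"]] <= 0) {
    stop("biomass contains no carbon; cannot normalise per C-mol",
         call. = FALSE)
  }
  structure(tot / tot[["C"]], total_c_mmol = tot[["C"]],
            class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", format_formula(unclass(x)), "\n")
  cat("  total C:", sprintf("%.2f", attr(x, "total_c_mmol")), "mmol/gDCW\n")
  invisible(x)
}

## electrons per mole of element relative to the reference states CO2, H2O,
## H3PO4/P(V), SO4/S(VI); nitrogen depends on the chosen N source
REDUCTION_WEIGHTS <- c(C = 4, H = 1, O = -2, P = 5, S = 6)
N_REFERENCE_WEIGHTS <- c(NH3 = -3, NO3 = 5)

#' Degree of reduction of a compound or biomass formula
#'
#' Computes `gamma = sum(weight_e * count_e)` per C-mol. Default element
#' weights are C=4, H=1, O=-2, P=5, S=6; the nitrogen weight depends on the
#' reference N source: -3 for ammonia, +5 for nitrate. Both conventions are
#' common in the bioprocess literature; reports should state which is used.
#'
#' @param formula an `elemental_formula`, a named numeric vector of element
#'   counts, or a formula string (normalised per carbon internally).
#' @param n_reference `"NH3"` (default, the usual biomass convention) or
#'   `"NO3"`.
#' @param weights optional replacement weight vector (element -> electrons).
#' @return electrons per C-mol, with attribute `n_reference`.
#' @export
#' @examples
#' degree_of_reduction("CH2O")   # carbohydrate: 4
#' degree_of_reduction("CO2")    # reference state: 0
degree_of_reduction <- function(formula, n_reference = c("NH3", "NO3"),
                                weights = NULL) {
  n_reference <- match.arg(n_reference)
  if (is.character(formula)) formula <- parse_formula(formula)
  counts <- unclass(formula)
  if (!"C" %in% names(counts) || counts[["C"]] == 0) {
    stop("formula must contain carbon", call. = FALSE)
  }
  counts <- counts / counts[["C"]]
  w <- c(REDUCTION_WEIGHTS, N = N_REFERENCE_WEIGHTS[[n_reference]])
  if (!is.null(weights)) w[names(weights)] <- weights
  unknown <- setdiff(names(counts), names(w))
  if (length(unknown)) {
    stop("no reduction weight for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(sum(w[names(counts)] * counts), n_reference = n_reference)
}

#' Oxygen evolution estimate from the photosynthetic quotient
#'
#' The photosynthetic quotient (mol O2 evolved per mol CO2 fixed) equals a
#' quarter of the biomass degree of reduction computed on the nitrate
#' reference (each C-mol of biomass stores `gamma` electrons, and each O2
#' carries 4). Multiplying by the CO2 uptake rate gives an O2 evolution
#' estimate independent of the flux model.
#'
#' @param gamma biomass degree of reduction (NO3 reference when nitrate is
#'   the N source).
#' @param co2_uptake CO2 uptake rate, mmol/(gDCW h).
#' @return list with `quotient` (dimensionless) and `o2_rate` (mmol/(gDCW h)).
#' @export
photosynthetic_quotient_o2 <- function(gamma, co2_uptake) {
  if (gamma < 0 || co2_uptake < 0) {
    stop("gamma and co2_uptake must be non-negative", call. = FALSE)
  }
  q <- as.numeric(gamma) / 4
  list(quotient = q, o2_rate = q * co2_uptake)
}

#' Biomass formula and degree-of-reduction report
#'
#' Convenience wrapper: normalises a composition, computes the per-carbon
#' elemental formula and the degree of reduction under both N-reference
#' conventions.
#'
#' @param composition a [biomass_composition()].
#' @return one-row tibble with formula string, per-element counts, mass
#'   closure (mg/gDCW) and `gamma_nh3` / `gamma_no3`.
#' @export
biomass_formula_report <- function(composition) {
  nz <- normalize_composition(composition)
  ef <- elemental_formula(nz)
  counts <- unclass(ef)
  grab <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  tibble::tibble(
    formula = format_formula(counts),
    C = 1, H = grab("H"), O = grab("O"), N = grab("N"),
    P = grab("P"), S = grab("S"),
    mass_closure_mg = mass_closure(nz),
    gamma_nh3 = as.numeric(degree_of_reduction(ef, "NH3")),
    gamma_no3 = as.numeric(degree_of_reduction(ef, "NO3")))
}
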