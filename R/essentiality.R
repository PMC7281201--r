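## Single-reaction deletion screening, active-reaction classification, and
## the maintenance-energy (GAM/NGAM) sensitivity scan.

#' Analysis thresholds
#'
#' @param essentiality_growth_threshold growth rate (1/h) at or below which
#'   a deletion is called essential.
#' @param active_flux_threshold flux magnitude (mmol/gDCW/h) at or above
#'   which a reaction is called active.
#' @return object of class `analysis_settings`.
#' @export
analysis_settings <- function(essentiality_growth_threshold = 1e-4,
                              active_flux_threshold = 1e-8) {
  stopifnot(essentiality_growth_threshold > 0, active_flux_threshold > 0)
  structure(list(
    essentiality_growth_threshold = essentiality_growth_threshold,
    active_flux_threshold = active_flux_threshold),
    class = "analysis_settings")
}

#' Single-reaction essentiality screen
#'
#' Fixes the flux of one reaction at a time to zero and maximises growth
#' under the given constraints (any growth fixation in the constraints is
#' released for the screen; the medium, oxygen window and maintenance flux
#' are kept). A reaction is essential when the maximal growth after its
#' deletion is at or below the threshold (infeasible deletions count as
#' zero growth). Reactions are screened in sorted id order.
#'
#' @param model a `metabolic_model` with a biomass objective.
#' @param constraints [simulation_constraints()].
#' @param settings [analysis_settings()].
#' @param backend LP backend.
#' @return object of class `essentiality_report`: tibble of per-reaction
#'   results plus baseline growth as attribute.
#' @export
essential_reactions <- function(model, constraints = NULL,
                                settings = analysis_settings(),
                                backend = "simplex") {
  if (!is.null(constraints)) constraints$growth <- NULL
  base <- solve_fba(model, constraints = constraints, backend = backend)
  if (base$status != "optimal") {
    stop("baseline growth problem is ", base$status,
         "; check medium and maintenance constraints", call. = FALSE)
  }
  constrained <- apply_constraints(model, constraints)
  ids <- sort(constrained$reactions$id)
  res <- purrr::map_dfr(ids, function(rid) {
    m2 <- set_bounds(constrained, rid, 0, 0)
    st <- solve_fba(m2, backend = backend)
    g <- if (st$status == "optimal") st$objective_value else 0
    tibble::tibble(
      reaction = rid,
      subsystem = constrained$reactions$subsystem[
        match(rid, constrained$reactions$id)],
      growth_after_deletion = g,
      essential = g <= settings$essentiality_growth_threshold)
  })
  structure(res, class = c("essentiality_report", class(res)),
            baseline_growth = base$objective_value,
            threshold = settings$essentiality_growth_threshold)
}

#' @export
print.essentiality_report <- function(x, ...) {
  cat("<essentiality_report>", sum(x$essential), "essential of", nrow(x),
      "reactions screened (baseline growth",
      sprintf("%.4g", attr(x, "baseline_growth")), "1/h)\n")
  NextMethod()
}

#' @rdname glance.metabolic_model
#' @method glance essentiality_report
#' @export
glance.essentiality_report <- function(x, ...) {
  tibble::tibble(n_screened = nrow(x), n_essential = sum(x$essential),
                 baseline_growth = attr(x, "baseline_growth"),
                 threshold = attr(x, "threshold"))
}

#' Classify active reactions in a flux state
#'
#' @param state a `flux_state`.
#' @param settings [analysis_settings()].
#' @return tibble of reactions with `|flux| >=` the active threshold,
#'   with subsystem labels.
#' @export
active_reactions <- function(state, settings = analysis_settings()) {
  stopifnot(state$status == "optimal")
  dplyr::filter(state$fluxes,
                abs(.data$flux) >= settings$active_flux_threshold) |>
    dplyr::select("reaction", "flux", "subsystem")
}

#' Per-subsystem totals of total / active / essential reactions
#'
#' The layout of the classic pathway-distribution figure of genome-scale
#' models: for every subsystem, the number of reactions, how many carry
#' flux in the given state, and how many are essential.
#'
#' @param model a `metabolic_model`.
#' @param state optional `flux_state` (for active counts).
#' @param essentiality optional [essential_reactions()] report.
#' @param settings [analysis_settings()].
#' @return tibble with `subsystem`, `total`, `active`, `essential`.
#' @export
subsystem_summary <- function(model, state = NULL, essentiality = NULL,
                              settings = analysis_settings()) {
  out <- dplyr::count(model$reactions, .data$subsystem, name = "total")
  if (!is.null(state)) {
    act <- active_reactions(state, settings) |>
      dplyr::count(.data$subsystem, name = "active")
    out <- dplyr::left_join(out, act, by = "subsystem")
  } else out$active <- NA_integer_
  if (!is.null(essentiality)) {
    ess <- dplyr::filter(essentiality, .data$essential) |>
      dplyr::count(.data$subsystem, name = "essential")
    out <- dplyr::left_join(out, ess, by = "subsystem")
  } else out$essential <- NA_integer_
  dplyr::mutate(out,
                active = dplyr::coalesce(.data$active, 0L),
                essential = dplyr::coalesce(.data$essential, 0L))
}

#' Maintenance-energy sensitivity scan
#'
#' Rebuilds the biomass equation for every growth-associated maintenance
#' (GAM) value, pins the maintenance reaction at every non-growth-associated
#' maintenance (NGAM) value, re-solves the parsimonious FBA, and reports
#' photon uptake, O2 evolution, CO2 uptake and the L1 distance of the
#' central-carbon fluxes from the base solution. Infeasible cells are
#' marked and the scan continues.
#'
#' @param model a `metabolic_model`.
#' @param composition the [biomass_composition()] used to rebuild the
#'   biomass equation at each GAM.
#' @param constraints [simulation_constraints()] with a fixed growth rate.
#' @param gam_values,ngam_values grids, mmol/gDCW and mmol/(gDCW h).
#' @param central_subsystems subsystems entering the L1 flux distance.
#' @param photon_exchange,co2_exchange,o2_exchange exchange reaction ids.
#' @param backend LP backend.
#' @return tibble with one row per (GAM, NGAM) cell; the first row is the
#'   base (current GAM of the model, NGAM from `constraints`).
#' @export
energy_sensitivity_scan <- function(model, composition, constraints,
                                    gam_values, ngam_values,
                                    central_subsystems = c("central_carbon",
                                                           "carbon_fixation"),
                                    photon_exchange = "EX_photon",
                                    co2_exchange = "EX_co2",
                                    o2_exchange = "EX_o2",
                                    backend = "simplex") {
  base <- solve_pfba(model, constraints = constraints, backend = backend)
  if (base$status != "optimal") {
    stop("base pFBA is ", base$status, "; scan needs a feasible base",
         call. = FALSE)
  }
  central <- function(st) {
    dplyr::filter(st$fluxes, .data$subsystem %in% central_subsystems)$flux
  }
  base_central <- central(base)
  bid <- find_biomass_id(model, constraints)
  grid <- tidyr::expand_grid(gam = gam_values, ngam = ngam_values)
  cells <- purrr::pmap_dfr(grid, function(gam, ngam) {
    bm <- compose_biomass_reaction(composition, energy_parameters(gam, ngam),
                                   id = bid)
    m2 <- model
    i <- match(bid, m2$reactions$id)
    m2$reactions$stoichiometry[[i]] <- bm$stoichiometry[[1]]
    cons2 <- constraints; cons2$ngam <- ngam
    st <- solve_pfba(m2, constraints = cons2, backend = backend)
    if (st$status != "optimal") {
      return(tibble::tibble(gam = gam, ngam = ngam, status = st$status,
                            photon_uptake = NA_real_, o2_evolution = NA_real_,
                            co2_uptake = NA_real_, total_flux = NA_real_,
                            l1_central = NA_real_))
    }
    tibble::tibble(
      gam = gam, ngam = ngam, status = "optimal",
      photon_uptake = -get_flux(st, photon_exchange),
      o2_evolution = get_flux(st, o2_exchange),
      co2_uptake = -get_flux(st, co2_exchange),
      total_flux = st$total_flux,
      l1_central = sum(abs(central(st) - base_central)))
  })
  base_row <- tibble::tibble(
    gam = NA_real_, ngam = if (is.null(constraints$ngam)) NA_real_ else
      constraints$ngam,
    status = "base",
    photon_uptake = -get_flux(base, photon_exchange),
    o2_evolution = get_flux(base, o2_exchange),
    co2_uptake = -get_flux(base, co2_exchange),
    total_flux = base$total_flux, l1_central = 0)
  dplyr::bind_rows(base_row, cells)
}
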