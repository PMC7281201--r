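## Model-quality procedures: biomass-precursor gap finding, detection of
## thermodynamically infeasible (energy-generating) loops, and the
## ATP-from-nothing test. All checks work on modified copies; the input
## model is never changed.

## default energy/bookkeeping species excluded from the precursor list
ENERGY_MET_DEFAULTS <- c("atp_c", "adp_c", "pi_c", "h2o_c", "h_c")

#' Find biomass-precursor gaps
#'
#' For every precursor consumed by the biomass reaction, a temporary demand
#' reaction is added and maximised under the given (photoautotrophic)
#' constraints; the precursor is producible if the maximal demand flux
#' exceeds `tol`. Precursors absent from the model are reported as
#' structurally missing.
#'
#' @param model a `metabolic_model` with a biomass reaction.
#' @param constraints [simulation_constraints()], typically from
#'   [set_photoautotrophic_medium()].
#' @param exclude metabolite ids not treated as precursors (energy and
#'   bookkeeping species).
#' @param tol producibility threshold on the demand flux.
#' @param backend LP backend.
#' @return tibble with `precursor`, `in_model`, `producible`, `max_flux`.
#' @export
find_gaps <- function(model, constraints = NULL,
                      exclude = ENERGY_MET_DEFAULTS, tol = 1e-8,
                      backend = "simplex") {
  bid <- find_biomass_id(model, constraints)
  s <- model$reactions$stoichiometry[[match(bid, model$reactions$id)]]
  precursors <- setdiff(names(s)[s < 0], exclude)
  purrr::map_dfr(precursors, function(met) {
    if (!met %in% model$metabolites$id) {
      return(tibble::tibble(precursor = met, in_model = FALSE,
                            producible = FALSE, max_flux = NA_real_))
    }
    dm_id <- paste0("DM_gaptest_", met)
    m2 <- add_reactions(model, toy_rxn(
      dm_id, paste("demand for", met), stats::setNames(-1, met),
      lb = 0, ub = 1000, subsystem = "gap_test", category = "demand"))
    st <- solve_fba(m2, objective = dm_id, sense = "max",
                    constraints = constraints, backend = backend)
    mx <- if (st$status == "optimal") st$objective_value else 0
    tibble::tibble(precursor = met, in_model = TRUE,
                   producible = mx > tol, max_flux = mx)
  })
}

#' Detect thermodynamically infeasible loops
#'
#' Fixes every exchange flux to zero and the ATP synthase flux to a positive
#' value. If the problem is still feasible, the reactions carrying flux in
#' the minimal-total-flux solution form an energy-generating loop; a curated
#' model is infeasible under this fixation.
#'
#' @param model a `metabolic_model`.
#' @param atp_synthase_id id of the ATP synthase reaction.
#' @param value positive flux to fix the ATP synthase at (the result should
#'   not depend on the choice).
#' @param tol membership threshold on `|flux|`.
#' @param backend LP backend.
#' @return list with `feasible` (logical) and `loop_reactions` (ids; empty
#'   when infeasible).
#' @export
detect_infeasible_loops <- function(model, atp_synthase_id, value = 1,
                                    tol = 1e-8, backend = "simplex") {
  i <- match(atp_synthase_id, model$reactions$id)
  if (is.na(i)) stop("ATP synthase reaction not in model: ", atp_synthase_id,
                     call. = FALSE)
  if (model$reactions$upper_bound[i] < value ||
      model$reactions$lower_bound[i] > value) {
    stop("contradictory fixation: bounds of ", atp_synthase_id, " are [",
         model$reactions$lower_bound[i], ", ", model$reactions$upper_bound[i],
         "], cannot fix at ", value, call. = FALSE)
  }
  m2 <- model
  for (rid in m2$reactions$id[m2$reactions$category == "exchange"]) {
    m2 <- set_bounds(m2, rid, 0, 0)
  }
  m2 <- set_bounds(m2, atp_synthase_id, value, value)
  st <- solve_pfba(m2, backend = backend)
  if (st$status != "optimal") {
    return(list(feasible = FALSE, loop_reactions = character(0)))
  }
  list(feasible = TRUE,
       loop_reactions = st$fluxes$reaction[abs(st$fluxes$flux) > tol])
}

#' ATP production from nothing
#'
#' Closes the uptake of every carbon-bearing exchange (including CO2 and
#' bicarbonate: no carbon source at all) and maximises the flux through the
#' ATP maintenance (hydrolysis) reaction. Two variants are run: photon
#' uptake closed (any positive value indicates an energy-generating loop)
#' and photon uptake open (a positive value is expected
#' photophosphorylation, not an error).
#'
#' @param model a `metabolic_model`.
#' @param atp_maintenance_id id of the ATP hydrolysis maintenance reaction.
#' @param backend LP backend.
#' @return tibble with `variant` (`photon_closed`, `photon_open`) and
#'   `max_atp_flux`.
#' @export
check_atp_from_nothing <- function(model, atp_maintenance_id = "ATPM",
                                   backend = "simplex") {
  if (!atp_maintenance_id %in% model$reactions$id) {
    stop("maintenance reaction not in model: ", atp_maintenance_id,
         call. = FALSE)
  }
  fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  nmap <- stats::setNames(model$metabolites$name, model$metabolites$id)
  m2 <- model
  photon_ex <- character(0)
  for (rid in m2$reactions$id[m2$reactions$category == "exchange"]) {
    s <- m2$reactions$stoichiometry[[match(rid, m2$reactions$id)]]
    met <- names(s)[1]
    f <- fmap[[met]]
    if (grepl("photon|hnu|light", met, ignore.case = TRUE) ||
        grepl("photon|hnu|light", nmap[[met]], ignore.case = TRUE)) {
      photon_ex <- c(photon_ex, rid)
    } else if (!is.na(f) && nzchar(f) && "C" %in% names(parse_formula(f))) {
      m2 <- set_bounds(m2, rid, lower = 0)   # no carbon uptake of any kind
    }
  }
  ## release any fixed maintenance flux so it can be maximised
  m2 <- set_bounds(m2, atp_maintenance_id, 0, 1000)
  run <- function(m) {
    st <- solve_fba(m, objective = atp_maintenance_id, sense = "max",
                    backend = backend)
    if (st$status == "optimal") st$objective_value else 0
  }
  m_closed <- m2
  for (rid in photon_ex) m_closed <- set_bounds(m_closed, rid, lower = 0)
  tibble::tibble(variant = c("photon_closed", "photon_open"),
                 max_atp_flux = c(run(m_closed), run(m2)))
}

#' Apply a directionality patch file
#'
#' Loop repairs are recorded as a TSV patch (`reaction_id`, `lb`, `ub`,
#' optional `citation`) and applied before checks; no database lookups are
#' performed.
#'
#' @param model a `metabolic_model`.
#' @param patch path to a TSV file or a data frame.
#' @return patched model.
#' @export
apply_bounds_patch <- function(model, patch) {
  if (is.character(patch)) {
    patch <- utils::read.delim(patch, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("reaction_id", "lb", "ub") %in% names(patch)))
  for (i in seq_len(nrow(patch))) {
    model <- set_bounds(model, patch$reaction_id[i], patch$lb[i], patch$ub[i])
  }
  model
}
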