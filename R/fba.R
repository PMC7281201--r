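## Flux balance analysis and parsimonious FBA under photoautotrophic
## constraints. All LPs are built over reactions sorted by id so results are
## deterministic and backend-independent.

#' Simulation constraints
#'
#' Bundle of the constraints applied to flux simulations: an optional fixed
#' growth rate, an optional oxygen-evolution window (central value +/-
#' halfwidth on the O2 exchange flux, positive = evolution), medium bounds
#' for exchange reactions, and the non-growth-associated maintenance flux.
#'
#' @param growth fixed specific growth rate (1/h), or `NULL` to leave growth
#'   free.
#' @param o2 central O2 evolution rate (mmol/gDCW/h), or `NULL`.
#' @param o2_halfwidth halfwidth of the O2 window; the O2 exchange flux is
#'   bounded to `[o2 - o2_halfwidth, o2 + o2_halfwidth]`.
#' @param medium tibble with `reaction`, `lower_bound`, `upper_bound`.
#' @param ngam non-growth-associated maintenance, mmol ATP/(gDCW h), applied
#'   as a fixed flux on the maintenance reaction; `NULL` leaves it alone.
#' @param biomass_id biomass reaction id (default: the reaction with
#'   category `biomass`).
#' @param o2_exchange_id,atpm_id ids of the O2 exchange and ATP maintenance
#'   reactions.
#' @return object of class `simulation_constraints`.
#' @export
simulation_constraints <- function(growth = NULL, o2 = NULL, o2_halfwidth = 0,
                                   medium = NULL, ngam = NULL,
                                   biomass_id = NULL,
                                   o2_exchange_id = "EX_o2",
                                   atpm_id = "ATPM") {
  stopifnot(o2_halfwidth >= 0)
  if (is.null(medium)) {
    medium <- tibble::tibble(reaction = character(0), lower_bound = numeric(0),
                             upper_bound = numeric(0))
  }
  structure(list(growth = growth, o2 = o2, o2_halfwidth = o2_halfwidth,
                 medium = tibble::as_tibble(medium), ngam = ngam,
                 biomass_id = biomass_id, o2_exchange_id = o2_exchange_id,
                 atpm_id = atpm_id),
            class = "simulation_constraints")
}

find_biomass_id <- function(model, constraints = NULL) {
  if (!is.null(constraints) && !is.null(constraints$biomass_id)) {
    return(constraints$biomass_id)
  }
  ids <- model$reactions$id[model$reactions$category == "biomass"]
  if (length(ids) != 1L) {
    stop("cannot identify a unique biomass reaction (found ", length(ids),
         "); set biomass_id in the constraints", call. = FALSE)
  }
  ids
}

## returns the model with all constraint bounds applied
apply_constraints <- function(model, constraints) {
  if (is.null(constraints)) return(model)
  stopifnot(inherits(constraints, "simulation_constraints"))
  for (i in seq_len(nrow(constraints$medium))) {
    model <- set_bounds(model, constraints$medium$reaction[i],
                        constraints$medium$lower_bound[i],
                        constraints$medium$upper_bound[i])
  }
  if (!is.null(constraints$growth)) {
    bid <- find_biomass_id(model, constraints)
    model <- set_bounds(model, bid, constraints$growth, constraints$growth)
  }
  if (!is.null(constraints$o2)) {
    model <- set_bounds(model, constraints$o2_exchange_id,
                        constraints$o2 - constraints$o2_halfwidth,
                        constraints$o2 + constraints$o2_halfwidth)
  }
  if (!is.null(constraints$ngam)) {
    if (!constraints$atpm_id %in% model$reactions$id) {
      stop("maintenance reaction not in model: ", constraints$atpm_id,
           call. = FALSE)
    }
    model <- set_bounds(model, constraints$atpm_id, constraints$ngam,
                        constraints$ngam)
  }
  model
}

new_flux_state <- function(model, v, objective_value, status,
                           total_flux = NA_real_) {
  if (!is.null(v)) v[abs(v) < 1e-12] <- 0    # strip solver noise
  ord <- order(model$reactions$id)
  fluxes <- tibble::tibble(
    reaction = model$reactions$id[ord],
    flux = if (is.null(v)) NA_real_ else unname(v[model$reactions$id[ord]]),
    subsystem = model$reactions$subsystem[ord],
    category = model$reactions$category[ord],
    lower_bound = model$reactions$lower_bound[ord],
    upper_bound = model$reactions$upper_bound[ord])
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, total_flux = total_flux),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state>", x$status)
  if (x$status == "optimal") {
    cat(", objective", sprintf("%.6g", x$objective_value))
    if (!is.na(x$total_flux)) cat(", total |v|", sprintf("%.6g", x$total_flux))
  }
  cat("\n")
  invisible(x)
}

#' @rdname tidy.metabolic_model
#' @method tidy flux_state
#' @export
tidy.flux_state <- function(x, ...) x$fluxes

#' @rdname glance.metabolic_model
#' @method glance flux_state
#' @export
glance.flux_state <- function(x, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value,
                 total_flux = x$total_flux,
                 n_active = sum(abs(x$fluxes$flux) >= 1e-8, na.rm = TRUE))
}

#' Look up one flux in a flux state
#' @param state a `flux_state`.
#' @param reaction reaction id.
#' @return numeric flux value.
#' @export
get_flux <- function(state, reaction) {
  i <- match(reaction, state$fluxes$reaction)
  if (is.na(i)) stop("unknown reaction: ", reaction, call. = FALSE)
  state$fluxes$flux[i]
}

#' Flux balance analysis
#'
#' Solves `max/min c'v` subject to `N v = 0` and the model's (constrained)
#' flux bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id, named numeric weight vector, or `NULL` to
#'   use the model objective.
#' @param sense `"max"` or `"min"`; defaults to the model objective
#'   direction, or `"max"`.
#' @param constraints optional [simulation_constraints()].
#' @param backend LP backend (see [lp_solve]); `"simplex"` is the internal
#'   deterministic solver.
#' @return a `flux_state`.
#' @export
solve_fba <- function(model, objective = NULL, sense = NULL,
                      constraints = NULL, backend = "simplex") {
  if (!nrow(model$reactions)) stop("model has no reactions", call. = FALSE)
  model <- apply_constraints(model, constraints)
  if (is.null(objective)) {
    if (is.null(model$objective)) {
      stop("no objective: supply one or set it on the model", call. = FALSE)
    }
    objective <- model$objective$reaction
    if (is.null(sense)) sense <- model$objective$direction
  }
  if (is.null(sense)) sense <- "max"
  ids <- sort(model$reactions$id)
  N <- build_matrix(model)[, ids, drop = FALSE]
  idx <- match(ids, model$reactions$id)
  lb <- model$reactions$lower_bound[idx]
  ub <- model$reactions$upper_bound[idx]
  obj <- stats::setNames(numeric(length(ids)), ids)
  if (is.character(objective)) {
    if (!all(objective %in% ids)) {
      stop("objective reaction(s) not in model: ",
           paste(setdiff(objective, ids), collapse = ", "), call. = FALSE)
    }
    obj[objective] <- 1
  } else {
    if (!all(names(objective) %in% ids)) {
      stop("objective reaction(s) not in model: ",
           paste(setdiff(names(objective), ids), collapse = ", "),
           call. = FALSE)
    }
    obj[names(objective)] <- objective
  }
  res <- lp_solve(unname(obj), N, rep(0, nrow(N)), lb, ub,
                  maximize = (sense == "max"), backend = backend)
  if (res$status != "optimal") {
    return(new_flux_state(model, NULL, NA_real_, infeasibility_status(res, model)))
  }
  v <- stats::setNames(res$x, ids)
  check_steady_state(N, res$x)
  new_flux_state(model, v, res$objective, "optimal")
}

infeasibility_status <- function(res, model) {
  if (res$status == "infeasible") {
    fixed <- model$reactions$id[model$reactions$lower_bound ==
                                  model$reactions$upper_bound &
                                  model$reactions$lower_bound != 0]
    attr(res$status, "fixed_fluxes") <- fixed
  }
  res$status
}

check_steady_state <- function(N, x, tol = 1e-6) {
  imb <- max(abs(as.vector(N %*% x)))
  if (imb > tol) {
    warning(sprintf("steady-state residual %.2e exceeds %.0e", imb, tol),
            call. = FALSE)
  }
  invisible(imb)
}

#' Parsimonious flux balance analysis
#'
#' Minimises the total absolute flux `sum(|v|)` subject to `N v = 0`, the
#' model bounds, and the fixations in `constraints` (typically: growth fixed
#' at the measured rate, O2 evolution within its measured window, and the
#' maintenance flux pinned). The absolute value is linearised by splitting
#' every flux into non-negative forward and reverse parts.
#'
#' @inheritParams solve_fba
#' @return a `flux_state` with `total_flux` set.
#' @export
solve_pfba <- function(model, constraints = NULL, backend = "simplex") {
  model <- apply_constraints(model, constraints)
  ids <- sort(model$reactions$id)
  N <- as.matrix(build_matrix(model)[, ids, drop = FALSE])
  idx <- match(ids, model$reactions$id)
  lb <- model$reactions$lower_bound[idx]
  ub <- model$reactions$upper_bound[idx]
  ## v = f - r, f in [max(lb,0), max(ub,0)], r in [max(-ub,0), max(-lb,0)]
  A <- cbind(N, -N)
  lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  n <- length(ids)
  res <- lp_solve(rep(1, 2 * n), A, rep(0, nrow(N)), lb2, ub2,
                  maximize = FALSE, backend = backend)
  if (res$status != "optimal") {
    return(new_flux_state(model, NULL, NA_real_, infeasibility_status(res, model)))
  }
  v <- stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)], ids)
  check_steady_state(N, v)
  new_flux_state(model, v, res$objective, "optimal", total_flux = res$objective)
}

#' Flux variability analysis
#'
#' Minimum and maximum flux of each reaction under the given constraints,
#' optionally with the total absolute flux capped at a parsimonious optimum
#' (to flag range-dependent activity calls under degenerate optima).
#'
#' @inheritParams solve_fba
#' @param reactions reaction ids to scan (default: all).
#' @param total_flux_cap optional cap on `sum(|v|)` (e.g. the `total_flux`
#'   of a pFBA solution, times a small relaxation).
#' @return tibble with `reaction`, `min_flux`, `max_flux`.
#' @export
flux_variability <- function(model, constraints = NULL, reactions = NULL,
                             total_flux_cap = NULL, backend = "simplex") {
  model <- apply_constraints(model, constraints)
  ids <- sort(model$reactions$id)
  if (is.null(reactions)) reactions <- ids
  N <- as.matrix(build_matrix(model)[, ids, drop = FALSE])
  idx <- match(ids, model$reactions$id)
  lb <- model$reactions$lower_bound[idx]
  ub <- model$reactions$upper_bound[idx]
  n <- length(ids)
  if (is.null(total_flux_cap)) {
    A <- N; lbv <- lb; ubv <- ub
    objvec <- function(r) { o <- numeric(n); o[match(r, ids)] <- 1; o }
    getv <- function(x, r) x[match(r, ids)]
  } else {
    ## split formulation plus slack row: sum(f + r) + s = cap, s >= 0
    A <- rbind(cbind(N, -N, 0), c(rep(1, 2 * n), 1))
    lbv <- c(pmax(lb, 0), pmax(-ub, 0), 0)
    ubv <- c(pmax(ub, 0), pmax(-lb, 0), total_flux_cap)
    objvec <- function(r) {
      o <- numeric(2 * n + 1); j <- match(r, ids); o[j] <- 1; o[n + j] <- -1; o
    }
    getv <- function(x, r) { j <- match(r, ids); x[j] - x[n + j] }
  }
  rhs <- c(rep(0, nrow(N)), if (!is.null(total_flux_cap)) total_flux_cap)
  purrr::map_dfr(reactions, function(r) {
    o <- objvec(r)
    lo <- lp_solve(o, A, rhs, lbv, ubv, maximize = FALSE, backend = backend)
    hi <- lp_solve(o, A, rhs, lbv, ubv, maximize = TRUE, backend = backend)
    tibble::tibble(
      reaction = r,
      min_flux = if (lo$status == "optimal") lo$objective else NA_real_,
      max_flux = if (hi$status == "optimal") hi$objective else NA_real_)
  })
}

## inorganic carbon species that stay open in a photoautotrophic medium
INORGANIC_C_FORMULAS <- c("CO2", "CHO3", "CO3", "CH1O3")

#' Photoautotrophic medium constraints
#'
#' Opens the exchanges for CO2, photons, nitrate, phosphate, sulfate, water,
#' protons and O2, and closes the uptake (lower bound to 0) of every
#' organic-carbon exchange; secretion stays open. Organic carbon is
#' identified from the exchanged metabolite's formula (contains C and is not
#' CO2/bicarbonate/carbonate).
#'
#' @param model a `metabolic_model`.
#' @param photon_bound maximal photon uptake, mmol/(gDCW h); `NULL` (the
#'   default) keeps the photon exchange's current lower bound.
#' @param uptake_bound uptake bound magnitude for the open inorganic
#'   exchanges.
#' @param ... passed to [simulation_constraints()] (e.g. `ngam`, `o2`).
#' @return a [simulation_constraints()] whose `medium` covers every exchange
#'   reaction; attribute `closed` lists the closed organic exchanges.
#' @export
set_photoautotrophic_medium <- function(model, photon_bound = NULL,
                                        uptake_bound = 1000, ...) {
  ex_ids <- find_exchanges(model)
  if (!length(ex_ids)) stop("model has no exchange reactions", call. = FALSE)
  rows <- list(); closed <- character(0); photon_found <- FALSE
  fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  nmap <- stats::setNames(model$metabolites$name, model$metabolites$id)
  for (rid in ex_ids) {
    s <- model$reactions$stoichiometry[[match(rid, model$reactions$id)]]
    met <- names(s)[1]
    is_photon <- grepl("photon|hnu|light", met, ignore.case = TRUE) ||
      grepl("photon|hnu|light", nmap[[met]], ignore.case = TRUE)
    f <- fmap[[met]]
    has_c <- !is.na(f) && nzchar(f) &&
      "C" %in% names(parse_formula(f)) && !(toupper(f) %in% INORGANIC_C_FORMULAS)
    ub_cur <- model$reactions$upper_bound[match(rid, model$reactions$id)]
    if (is_photon) {
      photon_found <- TRUE
      lb_cur <- model$reactions$lower_bound[match(rid, model$reactions$id)]
      rows[[rid]] <- tibble::tibble(
        reaction = rid,
        lower_bound = if (is.null(photon_bound)) lb_cur else -photon_bound,
        upper_bound = 0)
    } else if (has_c) {
      closed <- c(closed, rid)
      rows[[rid]] <- tibble::tibble(reaction = rid, lower_bound = 0,
                                    upper_bound = max(ub_cur, 0))
    } else {
      rows[[rid]] <- tibble::tibble(reaction = rid,
                                    lower_bound = -uptake_bound,
                                    upper_bound = uptake_bound)
    }
  }
  if (!photon_found) {
    stop("no photon exchange found; model is not photoautotrophic-ready",
         call. = FALSE)
  }
  cons <- simulation_constraints(medium = dplyr::bind_rows(rows), ...)
  attr(cons, "closed") <- closed
  cons
}
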