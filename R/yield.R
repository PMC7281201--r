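## Maximum theoretical product yields under a growth floor, for native and
## heterologous products. Yield = product flux / CO2 uptake flux
## (mol product per mol CO2), with bicarbonate uptake folded into the
## denominator when such an exchange exists.

ensure_product_exchange <- function(model, product) {
  ## `product` may be an exchange reaction id or a metabolite id
  added <- character(0)
  if (product %in% model$reactions$id &&
      model$reactions$category[match(product, model$reactions$id)] == "exchange") {
    return(list(model = model, exchange = product, added = added,
                metabolite = names(model$reactions$stoichiometry[[
                  match(product, model$reactions$id)]])[1]))
  }
  if (!product %in% model$metabolites$id) {
    stop("product '", product, "' is neither an exchange reaction nor a ",
         "metabolite of the model; supply a heterologous pathway first ",
         "(add_heterologous_pathway)", call. = FALSE)
  }
  ## existing exchange for this metabolite (or its extracellular twin)?
  base <- sub("_[a-z]$", "", product)
  met_e <- paste0(base, "_e")
  for (i in which(model$reactions$category == "exchange")) {
    m <- names(model$reactions$stoichiometry[[i]])[1]
    if (m %in% c(product, met_e)) {
      return(list(model = model, exchange = model$reactions$id[i],
                  added = added, metabolite = product))
    }
  }
  mi <- match(product, model$metabolites$id)
  if (!met_e %in% model$metabolites$id) {
    model$metabolites <- dplyr::bind_rows(
      model$metabolites,
      tibble::tibble(id = met_e, name = model$metabolites$name[mi],
                     compartment = "extracellular",
                     formula = model$metabolites$formula[mi],
                     charge = model$metabolites$charge[mi]))
  }
  tr_id <- paste0("TR_", base); ex_id <- paste0("EX_", base)
  new_rxns <- dplyr::bind_rows(
    toy_rxn(tr_id, paste(base, "export"),
            stats::setNames(c(-1, 1), c(product, met_e)),
            subsystem = "transport", category = "transport"),
    toy_rxn(ex_id, paste(base, "exchange"), stats::setNames(-1, met_e),
            lb = 0, ub = 1000, subsystem = "exchange", category = "exchange"))
  model <- add_reactions(model, new_rxns)
  list(model = model, exchange = ex_id, added = c(tr_id, ex_id),
       metabolite = product)
}

co2_uptake_flux <- function(state, model, carbon_exchanges = NULL) {
  if (is.null(carbon_exchanges)) {
    fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
    carbon_exchanges <- character(0)
    for (i in which(model$reactions$category == "exchange")) {
      met <- names(model$reactions$stoichiometry[[i]])[1]
      f <- fmap[[met]]
      if (!is.na(f) && toupper(f) %in% INORGANIC_C_FORMULAS) {
        carbon_exchanges <- c(carbon_exchanges, model$reactions$id[i])
      }
    }
  }
  sum(vapply(carbon_exchanges,
             function(r) max(-get_flux(state, r), 0), 1))
}

#' Maximum theoretical yield of one product
#'
#' Maximises the product's exchange flux subject to growth being at least
#' `growth_fraction` of the wild-type maximum under the same constraints,
#' then reports the yield as product flux over inorganic-carbon uptake
#' (mol/mol). Transport and exchange reactions are added automatically
#' (and reported) when the product metabolite has none.
#'
#' @param model a `metabolic_model`.
#' @param product product metabolite id (e.g. `"ac_c"`) or exchange
#'   reaction id.
#' @param constraints [simulation_constraints()]; any growth fixation is
#'   released (the floor replaces it).
#' @param growth_fraction fraction of wild-type maximal growth the mutant
#'   must retain (growth >= fraction * wild type).
#' @param wild_type_growth optional externally supplied growth rate used
#'   for the floor (e.g. a measured rate) instead of the FBA maximum.
#' @param backend LP backend.
#' @return one-row tibble: `product`, `exchange`, `vobj`, `vc`, `yield`,
#'   `carbon_moles`, `growth_floor`, `added_reactions` (list), `status`.
#' @export
max_product_yield <- function(model, product, constraints = NULL,
                              growth_fraction = 0.8,
                              wild_type_growth = NULL, backend = "simplex") {
  if (!is.null(constraints)) constraints$growth <- NULL
  prep <- ensure_product_exchange(model, product)
  m <- prep$model
  if (is.null(wild_type_growth)) {
    wt <- solve_fba(m, constraints = constraints, backend = backend)
    if (wt$status != "optimal") {
      stop("wild-type growth problem is ", wt$status, call. = FALSE)
    }
    wild_type_growth <- wt$objective_value
  }
  floor <- growth_fraction * wild_type_growth
  m2 <- apply_constraints(m, constraints)
  bid <- find_biomass_id(m2, constraints)
  m2 <- set_bounds(m2, bid, lower = floor)
  st <- solve_fba(m2, objective = prep$exchange, sense = "max")
  if (st$status != "optimal") {
    return(tibble::tibble(product = product, exchange = prep$exchange,
                          vobj = NA_real_, vc = NA_real_, yield = NA_real_,
                          carbon_moles = NA_integer_, growth_floor = floor,
                          added_reactions = list(prep$added),
                          status = st$status))
  }
  vobj <- get_flux(st, prep$exchange)
  vc <- co2_uptake_flux(st, m2)
  f <- m$metabolites$formula[match(prep$metabolite, m$metabolites$id)]
  nC <- if (!is.na(f) && nzchar(f)) {
    pf <- parse_formula(f); if ("C" %in% names(pf)) as.integer(pf[["C"]]) else 0L
  } else NA_integer_
  tibble::tibble(product = product, exchange = prep$exchange,
                 vobj = vobj, vc = vc,
                 yield = if (vc > 0) vobj / vc else NA_real_,
                 carbon_moles = nC, growth_floor = floor,
                 added_reactions = list(prep$added), status = "optimal")
}

#' Add a heterologous production pathway
#'
#' Extends a copy of the model with the pathway's metabolites and reactions
#' (tagged `evidence = "gap_filled"`). Added reactions are mass-balance
#' checked when all involved formulas are known; an imbalance is an error.
#'
#' @param model a `metabolic_model`.
#' @param pathway list with elements `metabolites` (tibble or list of
#'   records: id, name, compartment, formula) and `reactions` (records: id,
#'   stoichiometry as named list, bounds, subsystem), or a name from the
#'   shipped pathway file, or a YAML path.
#' @param pathway_file YAML file of named pathways (default: shipped toy
#'   pathway definitions).
#' @return extended model copy.
#' @export
add_heterologous_pathway <- function(model, pathway,
                                     pathway_file = system.file(
                                       "extdata", "toy_pathways.yaml",
                                       package = "cyanoflux")) {
  if (is.character(pathway)) {
    defs <- yaml::read_yaml(
      if (file.exists(pathway)) pathway else pathway_file)
    if (!is.null(defs[[pathway]])) {
      pathway <- defs[[pathway]]
    } else if (file.exists(pathway)) {
      pathway <- defs
    } else {
      stop("unknown pathway: ", pathway, call. = FALSE)
    }
  }
  if (!length(pathway$reactions)) return(model)
  mets <- if (!is.null(pathway$metabolites)) {
    dplyr::bind_rows(lapply(pathway$metabolites, tibble::as_tibble))
  } else NULL
  if (!is.null(mets)) {
    new <- mets[!mets$id %in% model$metabolites$id, ]
    if (nrow(new)) {
      if (!"charge" %in% names(new)) new$charge <- NA_integer_
      model$metabolites <- dplyr::bind_rows(model$metabolites, new)
    }
  }
  rxns <- purrr::map_dfr(pathway$reactions, function(r) {
    toy_rxn(r$id, if (is.null(r$name)) r$id else r$name,
            unlist(r$stoichiometry),
            lb = if (is.null(r$lower_bound)) 0 else r$lower_bound,
            ub = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
            subsystem = if (is.null(r$subsystem)) "heterologous" else
              r$subsystem,
            category = "metabolic")
  })
  rxns$evidence <- "gap_filled"
  out <- add_reactions(model, rxns)
  mb <- check_mass_balance(out)
  bad <- intersect(mb$imbalanced$reaction, rxns$id)
  if (length(bad)) {
    stop("added reaction(s) are not mass balanced: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Yield panel over several products
#'
#' Runs [max_product_yield()] for every product, inserting heterologous
#' pathways where declared; per-product failures are recorded and the panel
#' continues. Rows are sorted by decreasing yield.
#'
#' @param model a `metabolic_model`.
#' @param products character vector of product metabolite ids, or a tibble
#'   with columns `product` and optional `pathway` (name/path understood by
#'   [add_heterologous_pathway()]).
#' @inheritParams max_product_yield
#' @return tibble of yield results with a `heterologous` flag.
#' @export
yield_panel <- function(model, products, constraints = NULL,
                        growth_fraction = 0.8, backend = "simplex") {
  if (is.character(products)) {
    products <- tibble::tibble(product = products, pathway = NA_character_)
  }
  if (!"pathway" %in% names(products)) products$pathway <- NA_character_
  rows <- purrr::pmap_dfr(products, function(product, pathway, ...) {
    res <- tryCatch({
      m <- if (!is.na(pathway)) add_heterologous_pathway(model, pathway)
           else model
      out <- max_product_yield(m, product, constraints = constraints,
                               growth_fraction = growth_fraction,
                               backend = backend)
      out$heterologous <- !is.na(pathway)
      out
    }, error = function(e) {
      tibble::tibble(product = product, exchange = NA_character_,
                     vobj = NA_real_, vc = NA_real_, yield = NA_real_,
                     carbon_moles = NA_integer_, growth_floor = NA_real_,
                     added_reactions = list(character(0)),
                     status = paste("error:", conditionMessage(e)),
                     heterologous = !is.na(pathway))
    })
    res
  })
  dplyr::arrange(rows, dplyr::desc(!is.na(.data$yield)),
                 dplyr::desc(.data$yield))
}
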