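## Report writers and the YAML-driven pipeline behind the command-line
## interface: load or generate a model, set the photoautotrophic medium,
## run the requested analyses, and write TSV/JSON artifacts plus a run
## manifest from which every output can be regenerated.

#' Write a flux report TSV
#' @param state a `flux_state`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(state, path) {
  utils::write.table(state$fluxes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write any report tibble/list as JSON
#' @param x report object (tibble or list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Model summary as a tibble (genes, reactions, metabolites, categories)
#'
#' @param model a `metabolic_model`.
#' @param state optional `flux_state` for the active-reaction count.
#' @param essentiality optional essentiality report for the essential count.
#' @return one-row tibble in the layout of published model-comparison
#'   tables.
#' @export
model_summary <- function(model, state = NULL, essentiality = NULL) {
  g <- glance.metabolic_model(model)
  tibble::tibble(
    n_genes = g$n_genes, n_reactions = g$n_reactions,
    n_metabolites = g$n_metabolites,
    n_active = if (is.null(state)) NA_integer_ else
      nrow(active_reactions(state)),
    n_essential = if (is.null(essentiality)) NA_integer_ else
      sum(essentiality$essential))
}

#' Run the full analysis pipeline from a configuration
#'
#' One configuration drives a complete run: load an SBML model (or generate
#' the synthetic photoautotroph), optionally rebuild the biomass equation
#' from a composition CSV, apply the photoautotrophic medium, then execute
#' the requested stages (`simulate`, `gaps`, `loops`, `essentiality`,
#' `yields`, `summary`). All artifacts land in `output_dir` together with a
#' manifest recording inputs, settings, seed and package version.
#'
#' @param config YAML file path or an equivalent named list. Recognised
#'   fields: `model` (SBML path) or `toy` (list: `seed`, `photon_bound`),
#'   `composition` (CSV path), `constraints` (growth, o2, o2_halfwidth,
#'   ngam), `stages` (character vector), `products`, `growth_fraction`,
#'   `atp_synthase`, `seed`.
#' @param output_dir directory for artifacts (created if needed).
#' @return named list of the computed results, invisibly.
#' @export
run_pipeline <- function(config, output_dir = ".") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)

  gt <- NULL
  if (!is.null(cfg$model)) {
    model <- read_sbml(cfg$model)
  } else {
    toyspec <- toy_model_spec(
      photon_bound = if (is.null(cfg$toy$photon_bound)) 26 else
        cfg$toy$photon_bound,
      random_seed = if (is.null(cfg$toy$seed)) seed else cfg$toy$seed)
    gen <- generate_toy_photoautotroph(toyspec)
    model <- gen$model; gt <- gen$ground_truth
    write_sbml(model, file.path(output_dir, "toy_model.xml"))
    write_report_json(list(max_growth = gt$max_growth,
                           essential = gt$essential,
                           quantum_demand_per_co2 = gt$quantum_demand_per_co2),
                      file.path(output_dir, "toy_ground_truth.json"))
  }

  if (!is.null(cfg$composition)) {
    comp <- biomass_composition(cfg$composition)
    report <- biomass_formula_report(comp)
    utils::write.table(report, file.path(output_dir, "biomass_formula.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cc <- cfg$constraints
  cons <- set_photoautotrophic_medium(
    model,
    growth = cc$growth, o2 = cc$o2,
    o2_halfwidth = if (is.null(cc$o2_halfwidth)) 0 else cc$o2_halfwidth,
    ngam = cc$ngam)

  stages <- if (is.null(cfg$stages)) "simulate" else cfg$stages
  results <- list(model = model, constraints = cons, ground_truth = gt)

  if ("simulate" %in% stages) {
    st <- if (is.null(cc$growth)) solve_fba(model, constraints = cons)
          else solve_pfba(model, constraints = cons)
    if (st$status != "optimal") {
      stop("simulation ", st$status, call. = FALSE)
    }
    write_flux_tsv(st, file.path(output_dir, "fluxes.tsv"))
    results$flux_state <- st
  }
  if ("gaps" %in% stages) {
    gaps <- find_gaps(model, constraints = cons)
    write_report_json(gaps, file.path(output_dir, "gap_report.json"))
    results$gaps <- gaps
  }
  if ("loops" %in% stages) {
    atps <- if (is.null(cfg$atp_synthase)) "ATPS" else cfg$atp_synthase
    loops <- detect_infeasible_loops(model, atps)
    loops$atp_from_nothing <- check_atp_from_nothing(model)
    write_report_json(loops, file.path(output_dir, "loop_report.json"))
    results$loops <- loops
  }
  if ("essentiality" %in% stages) {
    ess <- essential_reactions(model, constraints = cons)
    utils::write.table(ess, file.path(output_dir, "essentiality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$essentiality <- ess
  }
  if ("yields" %in% stages) {
    prods <- cfg$products
    if (is.null(prods)) prods <- c("ac_c")
    panel <- yield_panel(
      model, unlist(prods), constraints = cons,
      growth_fraction = if (is.null(cfg$growth_fraction)) 0.8 else
        cfg$growth_fraction)
    utils::write.table(
      dplyr::mutate(panel, added_reactions = vapply(
        .data$added_reactions, paste, "", collapse = ";")),
      file.path(output_dir, "yields.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$yields <- panel
  }
  if ("summary" %in% stages) {
    smry <- model_summary(model, results$flux_state, results$essentiality)
    utils::write.table(smry, file.path(output_dir, "model_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$summary <- smry
  }

  manifest <- list(
    package = "cyanoflux",
    version = as.character(utils::packageVersion("cyanoflux")),
    seed = seed, stages = stages, config = cfg,
    defaults = list(default_bounds = c(-1000, 1000),
                    essentiality_growth_threshold = 1e-4,
                    active_flux_threshold = 1e-8))
  write_report_json(manifest, file.path(output_dir, "manifest.json"))
  invisible(results)
}
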