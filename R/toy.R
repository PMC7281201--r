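## Synthetic photoautotroph generator. Produces small (25-35 reaction)
## models with the architecture of cyanobacterial photoautotrophy --
## lumped photosystem II (water splitting, NADPH and proton-motive force),
## cyclic electron flow, ATP synthase, CBB-style CO2 fixation to triose
## phosphate, lower glycolysis, an incomplete TCA cycle with the
## 2-oxoglutarate -> succinic semialdehyde -> succinate shunt, GS-GOGAT
## nitrogen assimilation from nitrate, glycogen and fatty-acid branches,
## and a composition-derived biomass equation -- together with analytically
## derived ground truth (maximal growth, parsimonious flux map, essential
## set) for validating every pipeline stage.
##
## Stoichiometries use simple integer coefficients and exactly balanced
## CHONPS formulas (cofactor formulas are simplified so that redox pairs
## differ by H2, avoiding proton/charge bookkeeping). The photon and the
## proton-motive force carrier "pmf" are massless pseudo-species.

#' Specification of a synthetic photoautotroph
#'
#' @param photon_bound maximal photon uptake, mmol/(gDCW h). The default
#'   (26) puts the model's maximal growth at the 0.05/h scale typical of
#'   fast-growing marine cyanobacteria.
#' @param include_glycogen_branch,include_tca_shunt,include_gs_gogat
#'   optional network branches; without GS-GOGAT a glutamate-dehydrogenase
#'   reaction assimilates ammonia directly.
#' @param composition a [biomass_composition()]; default is a three-pool mix
#'   (protein-like glutamyl 0.41, glycogen 0.52, lipid-like palmitoyl 0.07,
#'   mass fractions at the magnitudes measured for high-polyglucan marine
#'   *Synechococcus*).
#' @param gam,ngam maintenance parameters, mmol ATP/gDCW and mmol
#'   ATP/(gDCW h).
#' @param random_seed integer; stored on the spec (generation itself is
#'   deterministic; the seed feeds seeded fixture edits such as random gap
#'   injection).
#' @return object of class `toy_model_spec`.
#' @export
toy_model_spec <- function(photon_bound = 26,
                           include_glycogen_branch = TRUE,
                           include_tca_shunt = TRUE,
                           include_gs_gogat = TRUE,
                           composition = NULL,
                           gam = 53, ngam = 1.3,
                           random_seed = 1L) {
  stopifnot(photon_bound > 0)
  if (is.null(composition)) {
    composition <- toy_composition(
      glycogen = if (include_glycogen_branch) 0.52 else 0,
      protein_like = if (include_glycogen_branch) 0.41 else 0.80,
      lipid_like = if (include_glycogen_branch) 0.07 else 0.20)
  }
  if (!include_glycogen_branch &&
      "glycogen" %in% composition$fractions$component &&
      composition$fractions$mass_fraction[
        composition$fractions$component == "glycogen"] > 0) {
    stop("composition contains glycogen but the glycogen branch is disabled",
         call. = FALSE)
  }
  structure(list(photon_bound = photon_bound,
                 include_glycogen_branch = include_glycogen_branch,
                 include_tca_shunt = include_tca_shunt,
                 include_gs_gogat = include_gs_gogat,
                 composition = composition, gam = gam, ngam = ngam,
                 random_seed = as.integer(random_seed)),
            class = "toy_model_spec")
}

#' Three-pool toy biomass composition
#'
#' @param protein_like,glycogen,lipid_like mass fractions (mg/mg DCW) of the
#'   glutamyl, glucosyl and palmitoyl pools.
#' @return a [biomass_composition()].
#' @export
toy_composition <- function(protein_like = 0.41, glycogen = 0.52,
                            lipid_like = 0.07) {
  templates <- list(
    protein_like = tibble::tibble(
      monomer = "glutamyl", mole_fraction = 1, formula = "C5H7NO3",
      residue_mass = 129.115, metabolite = "glu_c"),
    glycogen = tibble::tibble(
      monomer = "glucosyl", mole_fraction = 1, formula = "C6H10O5",
      residue_mass = 162.141, metabolite = "glucosyl_c"),
    lipid_like = tibble::tibble(
      monomer = "palmitoyl", mole_fraction = 1, formula = "C16H32O2",
      residue_mass = 256.424, metabolite = "palm_c"))
  fr <- tibble::tibble(
    component = c("protein_like", "glycogen", "lipid_like"),
    mass_fraction = c(protein_like, glycogen, lipid_like))
  fr <- fr[fr$mass_fraction > 0, ]
  biomass_composition(fr, templates = templates[fr$component])
}

toy_met <- function(id, name, compartment, formula) {
  tibble::tibble(id = id, name = name, compartment = compartment,
                 formula = formula, charge = NA_integer_)
}

toy_rxn <- function(id, name, stoich, lb = 0, ub = 1000,
                    subsystem = "unassigned", category = "metabolic",
                    gpr = "") {
  tibble::tibble(id = id, name = name, stoichiometry = list(stoich),
                 lower_bound = lb, upper_bound = ub, subsystem = subsystem,
                 category = category, gene_association = gpr,
                 evidence = "annotated")
}

#' Generate a synthetic photoautotroph with known ground truth
#'
#' @param spec a [toy_model_spec()].
#' @return list with `model` (a `metabolic_model`, biomass objective set)
#'   and `ground_truth`: `max_growth` (closed form), `pfba_fluxes` (named
#'   vector: the minimal-total-flux map at maximal growth), `essential`
#'   (reaction ids), per-gram ATP/NADPH/CO2/photon demands, and the quantum
#'   demand (photons per CO2 fixed). The generator verifies internally that
#'   its flux map satisfies the steady-state condition.
#' @export
generate_toy_photoautotroph <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  gly <- spec$include_glycogen_branch
  tca <- spec$include_tca_shunt
  gsg <- spec$include_gs_gogat

  mets <- dplyr::bind_rows(
    toy_met("photon_e", "photon", "extracellular", ""),
    toy_met("co2_e", "CO2", "extracellular", "CO2"),
    toy_met("o2_e", "O2", "extracellular", "O2"),
    toy_met("no3_e", "nitrate", "extracellular", "HNO3"),
    toy_met("pi_e", "phosphate", "extracellular", "H3PO4"),
    toy_met("h2o_e", "water", "extracellular", "H2O"),
    toy_met("glc_e", "glucose", "extracellular", "C6H12O6"),
    toy_met("photon_u", "photon", "thylakoid", ""),
    toy_met("pmf_u", "proton-motive force", "thylakoid", ""),
    toy_met("co2_c", "CO2", "cytosol", "CO2"),
    toy_met("o2_c", "O2", "cytosol", "O2"),
    toy_met("no3_c", "nitrate", "cytosol", "HNO3"),
    toy_met("nh3_c", "ammonia", "cytosol", "NH3"),
    toy_met("pi_c", "phosphate", "cytosol", "H3PO4"),
    toy_met("h2o_c", "water", "cytosol", "H2O"),
    toy_met("atp_c", "ATP", "cytosol", "C10H16N5O13P3"),
    toy_met("adp_c", "ADP", "cytosol", "C10H15N5O10P2"),
    toy_met("nadp_c", "NADP", "cytosol", "C21H28N7O17P3"),
    toy_met("nadph_c", "NADPH", "cytosol", "C21H30N7O17P3"),
    toy_met("gap_c", "glyceraldehyde 3-phosphate", "cytosol", "C3H7O6P"),
    toy_met("pyr_c", "pyruvate", "cytosol", "C3H4O3"),
    toy_met("ac_c", "acetate", "cytosol", "C2H4O2"),
    toy_met("oaa_c", "oxaloacetate", "cytosol", "C4H4O5"),
    toy_met("akg_c", "2-oxoglutarate", "cytosol", "C5H6O5"),
    toy_met("glu_c", "glutamate", "cytosol", "C5H9NO4"),
    toy_met("glc_c", "glucose", "cytosol", "C6H12O6"),
    toy_met("palm_c", "palmitate", "cytosol", "C16H32O2"),
    toy_met("biomass_c", "biomass", "cytosol", ""))
  if (gsg) mets <- dplyr::bind_rows(mets,
    toy_met("gln_c", "glutamine", "cytosol", "C5H10N2O3"))
  if (gly) mets <- dplyr::bind_rows(mets,
    toy_met("glucosyl_c", "glycogen glucosyl unit", "cytosol", "C6H10O5"))
  if (tca) mets <- dplyr::bind_rows(mets,
    toy_met("ssa_c", "succinic semialdehyde", "cytosol", "C4H6O3"),
    toy_met("succ_c", "succinate", "cytosol", "C4H6O4"))

  rxns <- dplyr::bind_rows(
    toy_rxn("EX_photon", "photon exchange", c(photon_e = -1),
            lb = -spec$photon_bound, ub = 0, subsystem = "exchange",
            category = "exchange"),
    toy_rxn("EX_co2", "CO2 exchange", c(co2_e = -1), lb = -1000,
            subsystem = "exchange", category = "exchange"),
    toy_rxn("EX_o2", "O2 exchange", c(o2_e = -1), lb = -1000,
            subsystem = "exchange", category = "exchange"),
    toy_rxn("EX_no3", "nitrate exchange", c(no3_e = -1), lb = -1000,
            subsystem = "exchange", category = "exchange"),
    toy_rxn("EX_pi", "phosphate exchange", c(pi_e = -1), lb = -1000,
            subsystem = "exchange", category = "exchange"),
    toy_rxn("EX_h2o", "water exchange", c(h2o_e = -1), lb = -1000,
            subsystem = "exchange", category = "exchange"),
    toy_rxn("EX_glc", "glucose exchange", c(glc_e = -1), lb = -1000,
            subsystem = "exchange", category = "exchange"),
    toy_rxn("TR_photon", "photon capture", c(photon_e = -1, photon_u = 1),
            subsystem = "transport", category = "transport"),
    toy_rxn("TR_co2", "CO2 diffusion", c(co2_e = -1, co2_c = 1), lb = -1000,
            subsystem = "transport", category = "transport"),
    toy_rxn("TR_o2", "O2 diffusion", c(o2_c = -1, o2_e = 1), lb = -1000,
            subsystem = "transport", category = "transport"),
    toy_rxn("TR_no3", "nitrate uptake", c(no3_e = -1, no3_c = 1),
            subsystem = "transport", category = "transport", gpr = "nrtA"),
    toy_rxn("TR_pi", "phosphate uptake", c(pi_e = -1, pi_c = 1), lb = -1000,
            subsystem = "transport", category = "transport", gpr = "pstS"),
    toy_rxn("TR_h2o", "water diffusion", c(h2o_e = -1, h2o_c = 1),
            lb = -1000, subsystem = "transport", category = "transport"),
    toy_rxn("TR_glc", "glucose uptake", c(glc_e = -1, glc_c = 1),
            subsystem = "transport", category = "transport", gpr = "glcP"),
    ## lumped linear electron flow: water splitting at PSII, NADP reduction,
    ## proton pumping; 8 photons -> 1 O2 + 2 NADPH + 12 pmf
    toy_rxn("PSII", "linear electron flow (lumped)",
            c(photon_u = -8, h2o_c = -2, nadp_c = -2,
              o2_c = 1, nadph_c = 2, pmf_u = 12),
            subsystem = "photosynthesis", category = "metabolic",
            gpr = "psbA and psaA"),
    toy_rxn("CEF", "cyclic electron flow", c(photon_u = -1, pmf_u = 2),
            subsystem = "photosynthesis", category = "metabolic",
            gpr = "ndhF or pgr5"),
    toy_rxn("ATPS", "ATP synthase",
            c(pmf_u = -4, adp_c = -1, pi_c = -1, atp_c = 1, h2o_c = 1),
            subsystem = "photosynthesis", category = "metabolic",
            gpr = "atpA and atpB"),
    toy_rxn("MEHLER", "Mehler-like alternative electron sink",
            c(nadph_c = -2, o2_c = -1, nadp_c = 2, h2o_c = 2),
            subsystem = "photosynthesis", category = "metabolic"),
    toy_rxn("PMF_LEAK", "proton leak", c(pmf_u = -1),
            subsystem = "photosynthesis", category = "metabolic"),
    toy_rxn("CBB", "CO2 fixation to triose phosphate (lumped CBB)",
            c(co2_c = -3, atp_c = -9, nadph_c = -6, h2o_c = -5,
              gap_c = 1, adp_c = 9, pi_c = 8, nadp_c = 6),
            subsystem = "carbon_fixation", category = "metabolic",
            gpr = "rbcL and rbcS and prk"),
    toy_rxn("PGM", "lower glycolysis (GAP to pyruvate)",
            c(gap_c = -1, adp_c = -2, pi_c = -1, nadp_c = -1,
              pyr_c = 1, atp_c = 2, nadph_c = 1, h2o_c = 1),
            subsystem = "central_carbon", category = "metabolic",
            gpr = "gapA or gapB"),
    toy_rxn("GLK", "glucose phosphorylation and cleavage",
            c(glc_c = -1, atp_c = -2, gap_c = 2, adp_c = 2),
            subsystem = "central_carbon", category = "metabolic",
            gpr = "glk"),
    toy_rxn("PDH", "pyruvate oxidation to acetate units",
            c(pyr_c = -1, h2o_c = -1, nadp_c = -1,
              ac_c = 1, co2_c = 1, nadph_c = 1),
            subsystem = "central_carbon", category = "metabolic",
            gpr = "pdhA and pdhB"),
    toy_rxn("PC", "pyruvate carboxylation",
            c(pyr_c = -1, co2_c = -1, atp_c = -1, h2o_c = -1,
              oaa_c = 1, adp_c = 1, pi_c = 1),
            subsystem = "central_carbon", category = "metabolic",
            gpr = "ppc"),
    toy_rxn("CS", "oxidative TCA branch to 2-oxoglutarate (lumped)",
            c(ac_c = -1, oaa_c = -1, nadp_c = -1,
              akg_c = 1, co2_c = 1, nadph_c = 1),
            subsystem = "central_carbon", category = "metabolic",
            gpr = "gltA and icd"),
    toy_rxn("NR", "nitrate reduction to ammonia",
            c(no3_c = -1, nadph_c = -4, nh3_c = 1, h2o_c = 3, nadp_c = 4),
            subsystem = "nitrogen", category = "metabolic",
            gpr = "narB and nirA"),
    toy_rxn("FAS", "fatty acid synthesis (lumped, C16:0)",
            c(ac_c = -8, atp_c = -7, nadph_c = -14,
              palm_c = 1, adp_c = 7, pi_c = 7, nadp_c = 14, h2o_c = 7),
            subsystem = "lipid", category = "metabolic",
            gpr = "accA and fabD"),
    toy_rxn("ATPM", "ATP maintenance",
            c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
            subsystem = "maintenance", category = "maintenance"))
  if (gsg) {
    rxns <- dplyr::bind_rows(rxns,
      toy_rxn("GS", "glutamine synthetase",
              c(glu_c = -1, nh3_c = -1, atp_c = -1,
                gln_c = 1, adp_c = 1, pi_c = 1),
              subsystem = "nitrogen", category = "metabolic", gpr = "glnA"),
      toy_rxn("GOGAT", "glutamate synthase",
              c(gln_c = -1, akg_c = -1, nadph_c = -1, glu_c = 2, nadp_c = 1),
              subsystem = "nitrogen", category = "metabolic", gpr = "gltS"))
  } else {
    rxns <- dplyr::bind_rows(rxns,
      toy_rxn("GDH", "glutamate dehydrogenase",
              c(akg_c = -1, nh3_c = -1, nadph_c = -1,
                glu_c = 1, h2o_c = 1, nadp_c = 1),
              subsystem = "nitrogen", category = "metabolic", gpr = "gdhA"))
  }
  if (gly) {
    rxns <- dplyr::bind_rows(rxns,
      toy_rxn("GLYS", "glycogen synthesis (per glucosyl unit)",
              c(gap_c = -2, atp_c = -1, h2o_c = -2,
                glucosyl_c = 1, adp_c = 1, pi_c = 3),
              subsystem = "glycogen", category = "metabolic",
              gpr = "glgA and glgC"))
  }
  if (tca) {
    rxns <- dplyr::bind_rows(rxns,
      toy_rxn("OGDC", "2-oxoglutarate decarboxylase",
              c(akg_c = -1, ssa_c = 1, co2_c = 1),
              subsystem = "tca_shunt", category = "metabolic"),
      toy_rxn("SSADH", "succinic semialdehyde dehydrogenase",
              c(ssa_c = -1, h2o_c = -1, nadp_c = -1,
                succ_c = 1, nadph_c = 1),
              subsystem = "tca_shunt", category = "metabolic", gpr = "gabD"))
  }
  biomass <- compose_biomass_reaction(
    spec$composition, energy_parameters(spec$gam, spec$ngam),
    id = "BIOMASS")
  biomass$subsystem <- "biomass"
  rxns <- dplyr::bind_rows(
    rxns, biomass,
    toy_rxn("SK_biomass", "biomass drain", c(biomass_c = -1),
            subsystem = "biomass", category = "sink"))

  model <- metabolic_model(
    mets, rxns, objective = list(reaction = "BIOMASS", direction = "max"),
    compartments = c("extracellular", "cytosol", "thylakoid", "periplasm"))

  gt <- toy_ground_truth(spec, model)
  list(model = model, ground_truth = gt)
}

## analytic bookkeeping: per-gram demands, closed-form maximal growth,
## minimal-total-flux map at that growth, and the essential set
toy_ground_truth <- function(spec, model) {
  nz <- normalize_composition(spec$composition)
  coef_of <- function(met) {
    if (met %in% nz$metabolite) sum(nz$coefficient[nz$metabolite == met]) else 0
  }
  g_glu <- coef_of("glu_c"); g_gly <- coef_of("glucosyl_c")
  g_palm <- coef_of("palm_c")
  gam <- spec$gam; ngam <- spec$ngam

  ## per-gram pathway fluxes (unit growth)
  u <- c(BIOMASS = 1,
         NR = g_glu, PDH = g_glu + 8 * g_palm, CS = g_glu, PC = g_glu,
         PGM = 2 * g_glu + 8 * g_palm, FAS = g_palm,
         CBB = 2 * g_glu + 2 * g_gly + 8 * g_palm)
  if (spec$include_gs_gogat) {
    u <- c(u, GS = g_glu, GOGAT = g_glu)
  } else {
    u <- c(u, GDH = g_glu)
  }
  if (spec$include_glycogen_branch) u <- c(u, GLYS = g_gly)

  atp_gross <- 9 * u[["CBB"]] + (if (spec$include_glycogen_branch) u[["GLYS"]] else 0) +
    7 * u[["FAS"]] + u[["PC"]] + (if (spec$include_gs_gogat) u[["GS"]] else 0) + gam
  atp_made_pgm <- 2 * u[["PGM"]]
  A_b <- atp_gross - atp_made_pgm              # net ATP per gDCW (ex NGAM)
  nadph_gross <- 6 * u[["CBB"]] + 4 * u[["NR"]] + 14 * u[["FAS"]] +
    (if (spec$include_gs_gogat) u[["GOGAT"]] else u[["GDH"]])
  nadph_made <- u[["PGM"]] + u[["PDH"]] + u[["CS"]]
  N_b <- nadph_gross - nadph_made              # net NADPH per gDCW
  co2_b <- 3 * u[["CBB"]] + u[["PC"]] - u[["PDH"]] - u[["CS"]]
  if (2 * A_b < 3 * N_b) {
    stop("toy spec is not ATP-limited; the closed-form optimum assumes ",
         "cyclic electron flow tops up ATP", call. = FALSE)
  }
  photon_per_g <- N_b + 2 * A_b                # photons per gDCW (ex NGAM)
  mu_max <- (spec$photon_bound - 2 * ngam) / photon_per_g
  if (mu_max <= 0) stop("photon bound too small for maintenance", call. = FALSE)

  ## minimal-total-flux map at mu_max
  mu <- mu_max
  v <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  v[names(u)] <- u * mu
  v["SK_biomass"] <- mu
  v["ATPM"] <- ngam
  v["ATPS"] <- A_b * mu + ngam
  v["PSII"] <- N_b * mu / 2
  v["CEF"] <- 2 * v[["ATPS"]] - 6 * v[["PSII"]]
  v["TR_photon"] <- 8 * v[["PSII"]] + v[["CEF"]]
  v["EX_photon"] <- -v[["TR_photon"]]
  v["TR_o2"] <- v[["PSII"]]; v["EX_o2"] <- v[["PSII"]]
  v["TR_co2"] <- co2_b * mu; v["EX_co2"] <- -co2_b * mu
  v["TR_no3"] <- g_glu * mu; v["EX_no3"] <- -g_glu * mu
  ## water closes the balance
  h2o_net <- 0
  for (i in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoichiometry[[i]]
    rid <- model$reactions$id[i]
    if (rid %in% c("TR_h2o", "EX_h2o")) next
    if ("h2o_c" %in% names(s)) h2o_net <- h2o_net + s[["h2o_c"]] * v[[rid]]
  }
  v["TR_h2o"] <- -h2o_net; v["EX_h2o"] <- h2o_net

  ## internal consistency: the map must be at steady state
  N <- build_matrix(model)
  resid <- max(abs(as.vector(N %*% v[colnames(N)])))
  if (resid > 1e-8) {
    stop(sprintf("toy ground truth violates steady state (residual %.2e)",
                 resid), call. = FALSE)
  }

  ## essential = reactions carrying flux in the (unique) optimum, except
  ## cyclic electron flow (bypassable via PSII + the Mehler sink) and the
  ## maintenance hydrolysis (its flux is forced by the NGAM constraint, and
  ## deleting it only removes an ATP drain); zero-flux reactions are never
  ## essential (the optimum stays feasible without them)
  carrying <- names(v)[abs(v) > 1e-9]
  essential <- sort(setdiff(carrying, c("CEF", "ATPM")))

  list(max_growth = mu_max, pfba_fluxes = v, essential = essential,
       atp_per_g = A_b, nadph_per_g = N_b, co2_per_g = co2_b,
       photon_per_g = photon_per_g,
       quantum_demand_per_co2 = photon_per_g / co2_b,
       precursor_coefficients = c(glu_c = g_glu, glucosyl_c = g_gly,
                                  palm_c = g_palm))
}

#' Remove reactions to create biomass-precursor gaps
#'
#' Test fixture for gap finding: deletes the given reactions (or `count`
#' randomly chosen metabolic/transport reactions) and returns the removal
#' list as ground truth.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to remove; exchange and biomass reactions
#'   are refused.
#' @param count alternatively, how many eligible reactions to remove at
#'   random.
#' @param seed RNG seed for the random choice.
#' @return list with `model` and `removed`.
#' @export
inject_gaps <- function(model, reaction_ids = NULL, count = NULL, seed = 1L) {
  if (is.null(reaction_ids)) {
    if (is.null(count)) stop("give reaction_ids or count", call. = FALSE)
    eligible <- model$reactions$id[
      model$reactions$category %in% c("metabolic", "transport")]
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    reaction_ids <- sample(sort(eligible), count)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }
  cat_of <- model$reactions$category[match(reaction_ids, model$reactions$id)]
  if (any(cat_of %in% c("exchange", "biomass"), na.rm = TRUE)) {
    stop("refusing to remove exchange or biomass reactions", call. = FALSE)
  }
  list(model = remove_reactions(model, reaction_ids), removed = reaction_ids)
}

#' Inject a thermodynamically infeasible energy-generating loop
#'
#' Adds two isomer pseudo-metabolites and a pair of irreversible reactions
#' whose cycle releases proton-motive force with no net input -- the classic
#' erroneous-directionality loop that lets ATP synthase run with all
#' exchanges closed and generates ATP from nothing.
#'
#' @param model a `metabolic_model` containing the `pmf_u` carrier.
#' @return list with `model` and `loop_reactions` (the injected ids).
#' @export
inject_loop <- function(model) {
  if (!"pmf_u" %in% model$metabolites$id) {
    stop("model has no proton-motive force carrier (pmf_u)", call. = FALSE)
  }
  mets <- dplyr::bind_rows(
    toy_met("loopA_c", "loop isomer A (synthetic)", "cytosol", "C6H12O6"),
    toy_met("loopB_c", "loop isomer B (synthetic)", "cytosol", "C6H12O6"))
  model$metabolites <- dplyr::bind_rows(model$metabolites, mets)
  loop <- dplyr::bind_rows(
    toy_rxn("LOOP_A2B", "isomerase with spurious proton pumping",
            c(loopA_c = -1, loopB_c = 1, pmf_u = 6),
            subsystem = "injected_loop", category = "metabolic"),
    toy_rxn("LOOP_B2A", "isomerase back-reaction",
            c(loopB_c = -1, loopA_c = 1),
            subsystem = "injected_loop", category = "metabolic"))
  loop$evidence <- "orphan"
  list(model = add_reactions(model, loop),
       loop_reactions = c("LOOP_A2B", "LOOP_B2A"))
}
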