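test_that("the essentiality screen matches the generator's ground truth", {
  toy <- toy_fixture()
  ess <- essential_reactions(toy$model, constraints = toy_medium(
    o2 = 1.6, o2_halfwidth = 1))
  expect_setequal(ess$reaction[ess$essential], toy$ground_truth$essential)
  ## counts are a partition of the screened set
  expect_equal(sum(ess$essential) + sum(!ess$essential), nrow(ess))
  expect_equal(nrow(ess), nrow(toy$model$reactions))
})

test_that("deleting the biomass reaction itself is essential", {
  toy <- toy_fixture()
  ess <- essential_reactions(toy$model, constraints = toy_medium())
  expect_true(ess$essential[ess$reaction == "BIOMASS"])
  expect_true(ess$essential[ess$reaction == "SK_biomass"])
})

test_that("a duplicated pathway step makes neither copy essential", {
  toy <- toy_fixture()
  m <- toy$model
  i <- match("CBB", m$reactions$id)
  dup <- m$reactions[i, ]
  dup$id <- "CBB_copy"
  m2 <- add_reactions(m, dup)
  ess <- essential_reactions(m2, constraints = set_photoautotrophic_medium(
    m2, ngam = 1.3))
  expect_false(ess$essential[ess$reaction == "CBB"])
  expect_false(ess$essential[ess$reaction == "CBB_copy"])
  ## while in the unduplicated model the step is essential
  ess1 <- essential_reactions(m, constraints = toy_medium())
  expect_true(ess1$essential[ess1$reaction == "CBB"])
})

test_that("deleting a zero-flux reaction never lowers maximal growth", {
  toy <- toy_fixture()
  cons <- toy_medium()
  base <- solve_fba(toy$model, constraints = cons)
  pf <- solve_pfba(toy$model,
                   constraints = toy_medium(growth = toy$ground_truth$max_growth))
  idle <- pf$fluxes$reaction[abs(pf$fluxes$flux) < 1e-9]
  ess <- essential_reactions(toy$model, constraints = cons)
  for (r in idle) {
    expect_equal(ess$growth_after_deletion[ess$reaction == r],
                 base$objective_value, tolerance = 1e-7)
  }
})

test_that("an infeasible baseline aborts the screen with a diagnostic", {
  toy <- toy_fixture()
  m <- toy$model
  cons <- set_photoautotrophic_medium(m, photon_bound = 0, ngam = 1.3)
  expect_error(essential_reactions(m, constraints = cons),   # dark + NGAM
               "baseline")
})

test_that("active reactions follow the flux threshold", {
  toy <- toy_fixture()
  pf <- solve_pfba(toy$model,
                   constraints = toy_medium(growth = toy$ground_truth$max_growth))
  act <- active_reactions(pf)
  gt_active <- names(which(abs(toy$ground_truth$pfba_fluxes) >= 1e-8))
  expect_setequal(act$reaction, gt_active)
  ## an extreme threshold empties the set; threshold ~0 catches any nonzero
  act_hi <- active_reactions(pf, analysis_settings(active_flux_threshold = 1e6))
  expect_equal(nrow(act_hi), 0L)
  act_lo <- active_reactions(pf, analysis_settings(active_flux_threshold = 1e-300))
  expect_true(all(abs(act_lo$flux) > 0))
})

test_that("per subsystem, essential <= active <= total at the optimum", {
  toy <- toy_fixture()
  cons <- toy_medium(o2 = 1.6, o2_halfwidth = 1)
  pf <- solve_pfba(toy$model,
                   constraints = toy_medium(growth = toy$ground_truth$max_growth,
                                            o2 = 1.6, o2_halfwidth = 1))
  ess <- essential_reactions(toy$model, constraints = cons)
  smry <- subsystem_summary(toy$model, pf, ess)
  expect_true(all(smry$essential <= smry$total))
  expect_true(all(smry$active <= smry$total))
  ## the essential set is contained in the active set here: every reaction
  ## carrying flux in the unique optimum except CEF/ATPM is essential
  expect_true(all(smry$essential <= smry$active + 1L))
  expect_equal(sum(smry$total), nrow(toy$model$reactions))
})

test_that("photon demand increases with NGAM at fixed growth, flux map stable", {
  toy <- toy_fixture()
  cons <- toy_medium(growth = 0.03, o2 = 1.6, o2_halfwidth = 1)
  scan <- energy_sensitivity_scan(toy$model, toy_composition(), cons,
                                  gam_values = c(35, 40, 53),
                                  ngam_values = c(1.3, 3, 4, 5))
  cells <- scan[scan$status == "optimal", ]
  for (g in unique(cells$gam)) {
    ph <- cells$photon_uptake[cells$gam == g][order(cells$ngam[cells$gam == g])]
    expect_true(all(diff(ph) > 0))
  }
  ## the central-carbon flux distribution is set by the biomass equation,
  ## not by the maintenance parameters
  expect_true(all(cells$l1_central < 1e-6))
})

test_that("the GAM-unchanged cell reproduces the base biomass equation", {
  toy <- toy_fixture()
  bm_base <- toy$model$reactions$stoichiometry[[
    match("BIOMASS", toy$model$reactions$id)]]
  bm_rebuilt <- compose_biomass_reaction(
    toy_composition(), energy_parameters(53, 1.3))$stoichiometry[[1]]
  expect_equal(bm_rebuilt[names(bm_base)], bm_base)
})

test_that("dropping NGAM to zero cannot increase the total flux", {
  toy <- toy_fixture()
  t_base <- solve_pfba(toy$model,
                       constraints = toy_medium(growth = 0.03))$total_flux
  cons0 <- toy_medium(growth = 0.03)
  cons0$ngam <- 0
  t_zero <- solve_pfba(toy$model, constraints = cons0)$total_flux
  expect_lte(t_zero, t_base + 1e-9)
})
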