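test_that("a single linear pathway carries its uptake bound to the objective", {
  m <- mini_model(a_uptake = 10)
  st <- solve_fba(m)
  expect_equal(st$status, "optimal")
  expect_equal(st$objective_value, 10)
  ## closing every exchange forces all-zero flux in this loop-free network
  m2 <- m
  for (r in c("EX_A", "EX_B")) m2 <- set_bounds(m2, r, 0, 0)
  st2 <- solve_fba(m2, objective = "R_direct", sense = "max")
  expect_equal(st2$objective_value, 0)
})

test_that("FBA optimum matches exhaustive vertex enumeration on the mini model", {
  m <- mini_model(a_uptake = 6)
  verts <- enumerate_vertices(m)
  expect_gt(length(verts), 0)
  best <- max(vapply(verts, function(v) v[["EX_B"]], 1))
  st <- solve_fba(m)
  expect_equal(st$objective_value, best, tolerance = 1e-8)
})

test_that("pFBA is at least as parsimonious as every enumerated vertex", {
  m <- mini_model(a_uptake = 6)
  cons <- simulation_constraints(biomass_id = "EX_B")
  m2 <- set_bounds(m, "EX_B", 5, 5)     # fix export, minimise total flux
  pf <- solve_pfba(m2)
  expect_equal(pf$status, "optimal")
  verts <- enumerate_vertices(m, extra_fix = list(EX_B = 5))
  totals <- vapply(verts, function(v) sum(abs(v)), 1)
  expect_equal(pf$total_flux, min(totals), tolerance = 1e-8)
  ## the short route is chosen, the two-step route stays silent
  expect_equal(get_flux(pf, "R_direct"), 5)
  expect_equal(get_flux(pf, "R_viaC1"), 0)
})

test_that("toy maximal growth equals the closed-form optimum to 1e-8", {
  toy <- toy_fixture()
  st <- solve_fba(toy$model, constraints = toy_medium())
  expect_equal(st$status, "optimal")
  expect_equal(st$objective_value, toy$ground_truth$max_growth,
               tolerance = 1e-8)
})

test_that("toy pFBA flux map equals the analytically derived minimal map", {
  toy <- toy_fixture()
  cons <- toy_medium(growth = toy$ground_truth$max_growth)
  pf <- solve_pfba(toy$model, constraints = cons)
  expect_equal(pf$status, "optimal")
  v <- stats::setNames(pf$fluxes$flux, pf$fluxes$reaction)
  gt <- toy$ground_truth$pfba_fluxes
  expect_equal(v[names(gt)], gt, tolerance = 1e-7)
  expect_equal(pf$total_flux, sum(abs(gt)), tolerance = 1e-8)
})

test_that("fixed growth zero with no maintenance yields the all-zero flux state", {
  toy <- toy_fixture()
  cons <- toy_medium(growth = 0)
  cons$ngam <- 0
  ## close the medium entirely
  cons$medium$lower_bound <- 0
  cons$medium$upper_bound <- 0
  pf <- solve_pfba(toy$model, constraints = cons)
  expect_equal(pf$status, "optimal")
  expect_equal(pf$total_flux, 0, tolerance = 1e-9)
})

test_that("every optimal state satisfies steady state within 1e-6", {
  toy <- toy_fixture()
  N <- build_matrix(toy$model)
  for (growth in c(0.02, 0.04, toy$ground_truth$max_growth)) {
    pf <- solve_pfba(toy$model, constraints = toy_medium(growth = growth))
    v <- stats::setNames(pf$fluxes$flux, pf$fluxes$reaction)
    expect_lt(max(abs(as.vector(N %*% v[colnames(N)]))), 1e-6)
    expect_true(all(pf$fluxes$flux >= pf$fluxes$lower_bound - 1e-9))
    expect_true(all(pf$fluxes$flux <= pf$fluxes$upper_bound + 1e-9))
  }
})

test_that("tightening the photon bound never increases maximal growth", {
  toy <- toy_fixture()
  bounds <- c(26, 20, 14, 8, 4)
  growth <- vapply(bounds, function(p) {
    st <- solve_fba(toy$model,
                    constraints = set_photoautotrophic_medium(
                      toy$model, photon_bound = p, ngam = 1.3))
    st$objective_value
  }, 1)
  expect_true(all(diff(growth) <= 1e-9))
})

test_that("objective values agree across two LP backends to 1e-6 relative", {
  toy <- toy_fixture()
  cons <- toy_medium()
  s1 <- solve_fba(toy$model, constraints = cons, backend = "simplex")
  s2 <- solve_fba(toy$model, constraints = cons, backend = "scipy")
  expect_equal(s1$objective_value, s2$objective_value, tolerance = 1e-6)
  cons2 <- toy_medium(growth = 0.04)
  p1 <- solve_pfba(toy$model, constraints = cons2, backend = "simplex")
  p2 <- solve_pfba(toy$model, constraints = cons2, backend = "scipy")
  expect_equal(p1$total_flux, p2$total_flux, tolerance = 1e-6)
})

test_that("an impossible growth fixation is reported infeasible with fixations", {
  toy <- toy_fixture()
  pf <- solve_pfba(toy$model, constraints = toy_medium(growth = 10))
  expect_equal(as.character(pf$status), "infeasible")
  expect_true("BIOMASS" %in% attr(pf$status, "fixed_fluxes"))
})

test_that("the photoautotrophic medium closes organic carbon only", {
  toy <- toy_fixture()
  cons <- toy_medium()
  expect_identical(attr(cons, "closed"), "EX_glc")
  med <- cons$medium
  expect_equal(med$lower_bound[med$reaction == "EX_glc"], 0)
  expect_lt(med$lower_bound[med$reaction == "EX_co2"], 0)
  ## a model without a photon exchange is rejected
  m2 <- remove_reactions(toy$model, "EX_photon")
  expect_error(set_photoautotrophic_medium(m2), "photoautotrophic-ready")
})

test_that("flux variability brackets the parsimonious solution", {
  toy <- toy_fixture()
  cons <- toy_medium(growth = 0.04)
  pf <- solve_pfba(toy$model, constraints = cons)
  fva <- flux_variability(toy$model, constraints = cons,
                          reactions = c("CBB", "CEF", "GLYS", "OGDC"),
                          total_flux_cap = pf$total_flux * (1 + 1e-9))
  for (r in fva$reaction) {
    v <- get_flux(pf, r)
    row <- fva[fva$reaction == r, ]
    expect_gte(v, row$min_flux - 1e-6)
    expect_lte(v, row$max_flux + 1e-6)
  }
})
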