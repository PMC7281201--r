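test_that("polymer coefficients follow 1000 * w * x / residue mass", {
  ## glycogen at the measured 0.417 mg/mg: 0.417/162.141 * 1000 mmol glucosyl
  comp <- biomass_composition(
    tibble::tibble(component = "glycogen", mass_fraction = 0.417),
    templates = default_monomer_templates()["glycogen"],
    closure_tol = 1)
  nz <- normalize_composition(comp)
  expect_equal(nz$coefficient, 0.417 / 162.141 * 1000, tolerance = 1e-6)
  expect_equal(round(nz$coefficient, 3), 2.572)
})

test_that("zero-fraction components are dropped from the equation", {
  comp <- biomass_composition(
    tibble::tibble(component = c("glycogen", "lipid"),
                   mass_fraction = c(1, 0)),
    closure_tol = 1)
  nz <- normalize_composition(comp)
  expect_setequal(unique(nz$component), "glycogen")
  expect_equal(sum(nz$coefficient), 1000 / 162.141, tolerance = 1e-6)
})

test_that("equal mole fractions with equal residue masses give equal coefficients", {
  tpl <- list(duo = tibble::tibble(
    monomer = c("m1", "m2"), mole_fraction = c(0.5, 0.5),
    formula = c("C2H4O2", "C2H4O2"), residue_mass = c(60, 60),
    metabolite = c("m1_c", "m2_c")))
  comp <- biomass_composition(
    tibble::tibble(component = "duo", mass_fraction = 1), templates = tpl)
  nz <- normalize_composition(comp)
  expect_equal(nz$coefficient[1], nz$coefficient[2])
})

test_that("swapping two components' fractions swaps their coefficients only", {
  c1 <- toy_composition(protein_like = 0.41, glycogen = 0.52,
                        lipid_like = 0.07)
  c2 <- toy_composition(protein_like = 0.52, glycogen = 0.41,
                        lipid_like = 0.07)
  n1 <- normalize_composition(c1); n2 <- normalize_composition(c2)
  get <- function(nz, comp) nz$coefficient[nz$component == comp]
  expect_equal(get(n1, "lipid_like"), get(n2, "lipid_like"))
  ## same residue-mass ratio transfers across the swap
  expect_equal(get(n1, "protein_like") / 0.41, get(n2, "protein_like") / 0.52)
})

test_that("mass closure holds for generated compositions (property)", {
  set.seed(11)
  for (i in 1:10) {
    w <- abs(rnorm(3)); w <- w / sum(w)
    comp <- toy_composition(w[1], w[2], w[3])
    nz <- normalize_composition(comp)
    expect_equal(mass_closure(nz), 1000, tolerance = 1e-6)
  }
})

test_that("biomass reaction carries GAM as its ATP coefficient", {
  comp <- toy_composition()
  bm <- compose_biomass_reaction(comp, energy_parameters(gam = 53, ngam = 1.3))
  s <- bm$stoichiometry[[1]]
  expect_equal(s[["atp_c"]], -53)
  expect_equal(s[["adp_c"]], 53)
  expect_equal(s[["pi_c"]], 53)
  expect_equal(s[["biomass_c"]], 1)
  expect_true(all(s[c("glu_c", "glucosyl_c", "palm_c")] < 0))
  ## missing precursor in a target model is an error listing the ids
  toy <- toy_fixture()$model
  tpl <- list(bogus = tibble::tibble(
    monomer = "zz", mole_fraction = 1, formula = "CH2O",
    residue_mass = 30, metabolite = "zz_c"))
  comp2 <- biomass_composition(
    tibble::tibble(component = "bogus", mass_fraction = 1), templates = tpl)
  expect_error(
    compose_biomass_reaction(comp2, model = toy),
    "zz_c")
})

test_that("elemental formula is normalised per carbon and scale invariant", {
  nz <- tibble::tibble(component = "x", monomer = "glc", metabolite = "glc_c",
                       formula = "C6H12O6", residue_mass = 180,
                       coefficient = 2.5)
  ef <- elemental_formula(nz)
  expect_equal(unclass(ef)[c("C", "H", "O")], c(C = 1, H = 2, O = 1))
  nz2 <- nz; nz2$coefficient <- nz$coefficient * 7.3
  expect_equal(unclass(elemental_formula(nz2)), unclass(ef),
               ignore_attr = TRUE)
  ## missing formula errors
  nz3 <- nz; nz3$formula <- ""
  expect_error(elemental_formula(nz3), "without elemental formula")
})

test_that("degree of reduction reproduces the textbook reference values", {
  expect_equal(as.numeric(degree_of_reduction("CO2")), 0)
  expect_equal(as.numeric(degree_of_reduction("CH2O")), 4)
  expect_equal(as.numeric(degree_of_reduction("C6H12O6")), 4)
  ## monotonicity in H (weight +1) and O (weight -2)
  g1 <- as.numeric(degree_of_reduction(c(C = 1, H = 1.5, O = 0.5)))
  g2 <- as.numeric(degree_of_reduction(c(C = 1, H = 1.8, O = 0.5)))
  g3 <- as.numeric(degree_of_reduction(c(C = 1, H = 1.5, O = 0.7)))
  expect_gt(g2, g1)
  expect_lt(g3, g1)
  ## the two N references differ by 8 electrons per N
  f <- c(C = 1, H = 1.6, O = 0.5, N = 0.2)
  expect_equal(as.numeric(degree_of_reduction(f, "NO3")) -
                 as.numeric(degree_of_reduction(f, "NH3")), 8 * 0.2)
  expect_error(degree_of_reduction(c(C = 1, Mg = 0.1)), "no reduction weight")
})

test_that("photosynthetic quotient follows gamma / 4", {
  pq <- photosynthetic_quotient_o2(4, 1)
  expect_equal(pq$quotient, 1)
  expect_equal(pq$o2_rate, 1)
  expect_equal(photosynthetic_quotient_o2(0, 5)$o2_rate, 0)
  expect_error(photosynthetic_quotient_o2(-1, 1), "non-negative")
})

test_that("toy compositions round-trip to their generating coefficients", {
  set.seed(23)
  for (i in 1:5) {
    w <- abs(rnorm(3)); w <- w / sum(w)
    comp <- toy_composition(w[1], w[2], w[3])
    nz <- normalize_composition(comp)
    expect_equal(nz$coefficient[nz$metabolite == "glu_c"],
                 1000 * w[1] / 129.115, tolerance = 1e-9)
    expect_equal(nz$coefficient[nz$metabolite == "glucosyl_c"],
                 1000 * w[2] / 162.141, tolerance = 1e-9)
    expect_equal(nz$coefficient[nz$metabolite == "palm_c"],
                 1000 * w[3] / 256.424, tolerance = 1e-9)
  }
})

test_that("composition validation catches unknown components and bad closure", {
  expect_error(
    biomass_composition(tibble::tibble(component = "vibranium",
                                       mass_fraction = 0.5)),
    "vibranium")
  expect_warning(
    biomass_composition(tibble::tibble(component = "glycogen",
                                       mass_fraction = 0.2)),
    "sum to")
  expect_error(
    biomass_composition(tibble::tibble(component = "glycogen",
                                       mass_fraction = -0.1)),
    "negative")
})
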