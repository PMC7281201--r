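test_that("write/read round-trip is the identity on model content", {
  m <- toy_fixture()$model
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$reactions[order(m2$reactions$id), ],
               m$reactions[order(m$reactions$id), ],
               ignore_attr = TRUE)
  expect_identical(m2$objective, m$objective)
  expect_identical(sort(m2$genes), sort(m$genes))
  expect_identical(m2$compartments, m$compartments)
})

test_that("ids outside the SBML alphabet are escaped reversibly", {
  m <- toy_fixture()$model
  i <- match("GLK", m$reactions$id)
  m$reactions$id[i] <- "GLK-alt.1"
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_true("GLK-alt.1" %in% m2$reactions$id)
})

test_that("nested gene associations survive the FBC encoding", {
  m <- toy_fixture()$model
  i <- match("CBB", m$reactions$id)
  m$reactions$gene_association[i] <- "(rbcL and rbcS) or rbcX"
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_equal(m2$reactions$gene_association[match("CBB", m2$reactions$id)],
               "(rbcL and rbcS) or rbcX")
  expect_true("rbcX" %in% m2$genes)
})

test_that("reactions without bound information get defaults with a warning", {
  ## minimal SBML without FBC bounds or kinetic-law parameters
  src <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'level="3" version="1"><model id="m">',
    '<listOfCompartments><compartment id="c" constant="true"/>',
    '</listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_a_c" name="a" compartment="c" constant="false"/>',
    '<species id="M_b_c" name="b" compartment="c" constant="false"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R_r1" reversible="true">',
    '<listOfReactants><speciesReference species="M_a_c" stoichiometry="1"/>',
    '</listOfReactants>',
    '<listOfProducts><speciesReference species="M_b_c" stoichiometry="1"/>',
    '</listOfProducts></reaction>',
    '<reaction id="R_r2" reversible="false">',
    '<listOfReactants><speciesReference species="M_b_c" stoichiometry="1"/>',
    '</listOfReactants></reaction>',
    '</listOfReactions></model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(src, f)
  expect_warning(m <- read_sbml(f), "defaults applied")
  expect_equal(m$reactions$lower_bound[m$reactions$id == "r1"], -1000)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "r1"], 1000)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "r2"], 0)
  ## single-metabolite reaction without category notes -> exchange heuristic
  expect_equal(m$reactions$category[m$reactions$id == "r2"], "exchange")
})

test_that("legacy kinetic-law LOWER_BOUND/UPPER_BOUND parameters are read", {
  src <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" ',
    'level="2" version="4"><model id="m">',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_a_c" name="a" compartment="c"/>',
    '<species id="M_b_c" name="b" compartment="c"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R_r1" reversible="true">',
    '<listOfReactants><speciesReference species="M_a_c" stoichiometry="1"/>',
    '</listOfReactants>',
    '<listOfProducts><speciesReference species="M_b_c" stoichiometry="1"/>',
    '</listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-12.5"/>',
    '<parameter id="UPPER_BOUND" value="42"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction></listOfReactions></model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(src, f)
  m <- read_sbml(f)
  expect_equal(m$reactions$lower_bound, -12.5)
  expect_equal(m$reactions$upper_bound, 42)
})

test_that("malformed XML raises a parse error naming the location", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><oops></model></sbml>", f)
  expect_error(read_sbml(f))
})

test_that("written SBML is accepted by an independent SBML library", {
  ## cobrapy/libSBML as external validator: counts and the FBA optimum must
  ## agree with the in-memory model
  toy <- toy_fixture()
  m <- toy$model
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  out <- withr::local_tempfile(fileext = ".json")
  script <- sprintf(paste0(
    "import json, cobra\n",
    "m = cobra.io.read_sbml_model('%s')\n",
    "m.objective = 'BIOMASS'\n",
    "m.reactions.EX_glc.lower_bound = 0\n",
    "m.reactions.ATPM.bounds = (1.3, 1.3)\n",
    "sol = m.optimize()\n",
    "json.dump({'n_rxn': len(m.reactions), 'n_met': len(m.metabolites),\n",
    "           'n_gene': len(m.genes), 'growth': sol.objective_value},\n",
    "          open('%s', 'w'))\n"), f, out)
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  rc <- system2(Sys.which("python"), sf, stdout = FALSE, stderr = FALSE)
  expect_equal(rc, 0L)
  res <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(res$n_rxn, nrow(m$reactions))
  expect_equal(res$n_met, nrow(m$metabolites))
  expect_equal(res$n_gene, length(m$genes))
  expect_equal(res$growth, toy$ground_truth$max_growth, tolerance = 1e-6)
})
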