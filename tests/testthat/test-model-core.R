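test_that("model construction enforces the structural invariants", {
  mets <- tibble::tibble(id = c("a_c", "b_c"), name = id,
                         compartment = "cytosol",
                         formula = c("CH2O", "CH2O"), charge = NA_integer_)
  rx <- tibble::tibble(id = "R1", name = "R1",
                       stoichiometry = list(c(a_c = -1, b_c = 1)),
                       lower_bound = 0, upper_bound = 1000,
                       subsystem = "s", category = "metabolic",
                       gene_association = "", evidence = "annotated")
  m <- metabolic_model(mets, rx)
  expect_s3_class(m, "metabolic_model")

  ## unknown metabolite reference
  bad <- rx; bad$stoichiometry <- list(c(zz_c = -1, b_c = 1))
  expect_error(metabolic_model(mets, bad), "unknown metabolites")
  ## inverted bounds
  bad <- rx; bad$lower_bound <- 5; bad$upper_bound <- 1
  expect_error(metabolic_model(mets, bad), "lower_bound")
  ## multi-metabolite exchange
  bad <- rx; bad$category <- "exchange"
  expect_error(metabolic_model(mets, bad), "exactly one metabolite")
  ## duplicate ids
  expect_error(metabolic_model(mets, dplyr::bind_rows(rx, rx)), "duplicate")
  ## compartment outside the declared set
  expect_error(metabolic_model(mets, rx, compartments = "thylakoid"),
               "compartments")
})

test_that("N %*% v equals reaction-by-reaction accumulation for random v", {
  m <- toy_fixture()$model
  N <- build_matrix(m)
  expect_equal(dim(N), c(nrow(m$metabolites), nrow(m$reactions)))
  set.seed(7)
  for (rep in 1:5) {
    v <- stats::setNames(rnorm(nrow(m$reactions)), m$reactions$id)
    direct <- stats::setNames(rep(0, nrow(m$metabolites)), m$metabolites$id)
    for (i in seq_len(nrow(m$reactions))) {
      s <- m$reactions$stoichiometry[[i]]
      direct[names(s)] <- direct[names(s)] + s * v[[m$reactions$id[i]]]
    }
    expect_equal(as.vector(N %*% v[colnames(N)]), unname(direct[rownames(N)]),
                 tolerance = 1e-12)
  }
  ## column j reproduces reaction j exactly
  j <- match("CBB", colnames(N))
  s <- m$reactions$stoichiometry[[match("CBB", m$reactions$id)]]
  col <- N[, j]
  expect_equal(col[col != 0][names(s)], s)
})

test_that("empty model yields a 0x0 matrix and zero counts", {
  empty <- metabolic_model(
    tibble::tibble(id = character(0), name = character(0),
                   compartment = character(0), formula = character(0),
                   charge = integer(0)),
    tibble::tibble(id = character(0), name = character(0),
                   stoichiometry = list(), lower_bound = numeric(0),
                   upper_bound = numeric(0), subsystem = character(0),
                   category = character(0), gene_association = character(0),
                   evidence = character(0)),
    compartments = character(0))
  expect_equal(dim(build_matrix(empty)), c(0L, 0L))
  cc <- count_by_category(empty)
  expect_equal(nrow(cc$category), 0L)
})

test_that("mass balance flags net atom counts and skips unknown formulas", {
  mets <- tibble::tibble(
    id = c("glc_c", "trio_c", "x_c"), name = id, compartment = "cytosol",
    formula = c("C6H12O6", "C3H6O3", NA), charge = NA_integer_)
  rx <- function(id, s) tibble::tibble(
    id = id, name = id, stoichiometry = list(s), lower_bound = 0,
    upper_bound = 1000, subsystem = "s", category = "metabolic",
    gene_association = "", evidence = "annotated")
  m <- metabolic_model(mets, dplyr::bind_rows(
    rx("SPLIT_OK", c(glc_c = -1, trio_c = 2)),     # C6H12O6 -> 2 C3H6O3
    rx("SPLIT_BAD", c(glc_c = -1, trio_c = 1)),    # loses C3H6O3
    rx("UNKNOWN", c(glc_c = -1, x_c = 1))))
  res <- check_mass_balance(m)
  expect_false("SPLIT_OK" %in% res$imbalanced$reaction)
  bad <- res$imbalanced[res$imbalanced$reaction == "SPLIT_BAD", ]
  expect_equal(bad$net[match(c("C", "H", "O"), bad$element)], c(3, 6, 3))
  expect_equal(res$skipped, "UNKNOWN")
})

test_that("the generated toy model is elementally balanced throughout", {
  res <- check_mass_balance(toy_fixture()$model)
  expect_equal(nrow(res$imbalanced), 0L)
  expect_length(res$skipped, 0L)
})

test_that("category and subsystem counts partition the reactions", {
  m <- toy_fixture()$model
  cc <- count_by_category(m)
  expect_equal(sum(cc$category$n), nrow(m$reactions))
  expect_equal(sum(cc$subsystem$n), nrow(m$reactions))
  expect_equal(cc$category$n[cc$category$category == "exchange"],
               sum(lengths(m$reactions$stoichiometry)[
                 m$reactions$category == "exchange"] == 1L))
})

test_that("evidence tagging stores, overwrites and summarises", {
  m <- toy_fixture()$model
  s0 <- evidence_summary(m)
  expect_equal(s0$n[s0$evidence == "annotated"], nrow(m$reactions))
  ## tag a batch as gap-filled, as model curation would
  targets <- utils::head(m$reactions$id[m$reactions$category == "metabolic"], 5)
  for (r in targets) m <- record_evidence(m, r, "gap_filled")
  s1 <- evidence_summary(m)
  expect_equal(s1$n[s1$evidence == "gap_filled"], 5L)
  expect_equal(sum(s1$n), nrow(m$reactions))
  ## re-tagging overwrites, count conserved
  m <- record_evidence(m, targets[1], "orphan")
  s2 <- evidence_summary(m)
  expect_equal(s2$n[s2$evidence == "gap_filled"], 4L)
  expect_equal(s2$n[s2$evidence == "orphan"], 1L)
  expect_equal(sum(s2$n), nrow(m$reactions))
  expect_error(record_evidence(m, targets[1], "guessed"), "unknown evidence")
})

test_that("tidy and glance return the documented tabular views", {
  m <- toy_fixture()$model
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("id", "equation", "subsystem", "category") %in% names(td)))
  expect_match(td$equation[td$id == "PDH"], "-->")
  gl <- glance(m)
  expect_equal(gl$n_reactions, nrow(m$reactions))
  expect_equal(gl$n_genes, length(m$genes))
})
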