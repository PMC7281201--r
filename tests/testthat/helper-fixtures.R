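## Shared fixtures. The toy photoautotroph is deterministic, so it is built
## once per test run and reused.

.fixture_env <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.fixture_env$toy)) {
    .fixture_env$toy <- generate_toy_photoautotroph(toy_model_spec())
  }
  .fixture_env$toy
}

toy_medium <- function(...) {
  set_photoautotrophic_medium(toy_fixture()$model, ngam = 1.3, ...)
}

## A minimal 7-reaction network with two alternative routes, small enough
## for exhaustive vertex enumeration: A is imported and converted to B
## either directly (R_direct) or via C (R_viaC1 + R_viaC2); B is exported.
mini_model <- function(a_uptake = 10) {
  mets <- tibble::tibble(
    id = c("A_e", "A_c", "B_c", "C_c", "B_e"),
    name = id, compartment = c("extracellular", "cytosol", "cytosol",
                               "cytosol", "extracellular"),
    formula = c("C2H4O2", "C2H4O2", "C2H4O2", "C2H4O2", "C2H4O2"),
    charge = NA_integer_)
  rx <- function(id, s, lb = 0, ub = 1000, cat = "metabolic") {
    tibble::tibble(id = id, name = id, stoichiometry = list(s),
                   lower_bound = lb, upper_bound = ub,
                   subsystem = "mini", category = cat,
                   gene_association = "", evidence = "annotated")
  }
  metabolic_model(
    mets,
    dplyr::bind_rows(
      rx("EX_A", c(A_e = -1), lb = -a_uptake, cat = "exchange"),
      rx("EX_B", c(B_e = -1), cat = "exchange"),
      rx("TR_A", c(A_e = -1, A_c = 1)),
      rx("TR_B", c(B_c = -1, B_e = 1)),
      rx("R_direct", c(A_c = -1, B_c = 1)),
      rx("R_viaC1", c(A_c = -1, C_c = 1)),
      rx("R_viaC2", c(C_c = -1, B_c = 1))),
    objective = list(reaction = "EX_B", direction = "max"))
}

## Exhaustive vertex enumeration over {N v = 0, lb <= v <= ub}: every basic
## feasible solution arises from fixing n - rank(N) variables at a bound and
## solving for the rest. Independent of the package's LP code.
enumerate_vertices <- function(model, extra_fix = list()) {
  N <- as.matrix(build_matrix(model))
  ids <- colnames(N)
  lb <- model$reactions$lower_bound[match(ids, model$reactions$id)]
  ub <- model$reactions$upper_bound[match(ids, model$reactions$id)]
  for (nm in names(extra_fix)) {
    j <- match(nm, ids); lb[j] <- extra_fix[[nm]]; ub[j] <- extra_fix[[nm]]
  }
  n <- ncol(N); r <- qr(N)$rank
  k <- n - r
  verts <- list()
  for (free_idx in utils::combn(n, r, simplify = FALSE)) {
    fixed_idx <- setdiff(seq_len(n), free_idx)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[fixed_idx] <- ifelse(unlist(grid[g, ]), ub[fixed_idx], lb[fixed_idx])
      rhs <- -N[, fixed_idx, drop = FALSE] %*% v[fixed_idx]
      B <- N[, free_idx, drop = FALSE]
      if (qr(B)$rank < r) next
      sol <- tryCatch(qr.solve(B, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      v[free_idx] <- sol
      if (all(v >= lb - 1e-9) && all(v <= ub + 1e-9) &&
          max(abs(N %*% v)) < 1e-9) {
        verts[[length(verts) + 1L]] <- stats::setNames(v, ids)
      }
    }
  }
  verts
}
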