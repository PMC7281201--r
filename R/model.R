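REACTION_CATEGORIES <- c("metabolic", "transport", "exchange", "biomass",
                         "maintenance", "demand", "sink")
EVIDENCE_TAGS <- c("annotated", "gap_filled", "orphan")
## categories excluded from elemental balance checks (boundary/pseudo reactions)
BOUNDARY_CATEGORIES <- c("exchange", "biomass", "demand", "sink", "maintenance")

#' Construct a compartmentalised stoichiometric model
#'
#' The central container of the package: a set of metabolites and reactions
#' with flux bounds, subsystem labels, reaction categories, gene associations
#' and an objective. All analysis functions consume and return this class.
#'
#' @param metabolites tibble with columns `id`, `name`, `compartment`,
#'   `formula` (chemical formula string, may be `""` for pseudo-species),
#'   `charge` (optional).
#' @param reactions tibble with columns `id`, `name`, `stoichiometry`
#'   (list-column of named numeric vectors, metabolite id -> signed
#'   coefficient, negative = consumed), `lower_bound`, `upper_bound`
#'   (mmol/gDCW/h), `subsystem`, `category` (one of metabolic, transport,
#'   exchange, biomass, maintenance, demand, sink), `gene_association`
#'   (boolean expression string over gene ids, may be `""`), `evidence`
#'   (annotated, gap_filled or orphan).
#' @param objective list with elements `reaction` (reaction id) and
#'   `direction` (`"max"` or `"min"`), or `NULL`.
#' @param compartments character vector of valid compartments; defaults to
#'   those used by the metabolites.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = NULL,
                            compartments = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- ""
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  ## formula "" = massless pseudo-species (photon, biomass unit);
  ## formula NA = unknown, reactions touching it are skipped in balance checks
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- "unassigned"
  if (!"gene_association" %in% names(reactions)) reactions$gene_association <- ""
  reactions$gene_association[is.na(reactions$gene_association)] <- ""
  if (!"evidence" %in% names(reactions)) reactions$evidence <- "annotated"
  if (is.null(compartments)) compartments <- unique(metabolites$compartment)

  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         compartments = compartments,
         genes = extract_genes(reactions$gene_association),
         objective = objective),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

extract_genes <- function(gpr) {
  toks <- unlist(strsplit(gpr, "[()\\s]+", perl = TRUE))
  sort(unique(setdiff(toks[nzchar(toks)], c("and", "or", "AND", "OR"))))
}

validate_model <- function(model) {
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids", call. = FALSE)
  bad_comp <- setdiff(unique(mets$compartment), model$compartments)
  if (length(bad_comp)) {
    stop("metabolite compartments outside the declared set: ",
         paste(bad_comp, collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(unique(rxns$category), REACTION_CATEGORIES)
  if (length(bad_cat)) stop("unknown reaction categories: ",
                            paste(bad_cat, collapse = ", "), call. = FALSE)
  if (nrow(rxns)) {
    if (any(lengths(rxns$stoichiometry) == 0)) {
      stop("reactions with empty stoichiometry: ",
           paste(rxns$id[lengths(rxns$stoichiometry) == 0], collapse = ", "),
           call. = FALSE)
    }
    refs <- unique(unlist(lapply(rxns$stoichiometry, names)))
    missing <- setdiff(refs, mets$id)
    if (length(missing)) stop("reactions reference unknown metabolites: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    if (any(rxns$lower_bound > rxns$upper_bound)) {
      stop("lower_bound > upper_bound for: ",
           paste(rxns$id[rxns$lower_bound > rxns$upper_bound], collapse = ", "),
           call. = FALSE)
    }
    ex <- rxns$category == "exchange"
    if (any(lengths(rxns$stoichiometry[ex]) != 1)) {
      stop("exchange reactions must touch exactly one metabolite: ",
           paste(rxns$id[ex][lengths(rxns$stoichiometry[ex]) != 1],
                 collapse = ", "), call. = FALSE)
    }
    bad_ev <- setdiff(unique(rxns$evidence), EVIDENCE_TAGS)
    if (length(bad_ev)) stop("unknown evidence tags: ",
                             paste(bad_ev, collapse = ", "), call. = FALSE)
  }
  if (!is.null(model$objective) &&
      !model$objective$reaction %in% rxns$id) {
    stop("objective reaction not in model: ", model$objective$reaction,
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", nrow(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites,", length(x$genes), "genes\n")
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  if (!is.null(x$objective)) {
    cat("  objective:", x$objective$direction, x$objective$reaction, "\n")
  }
  invisible(x)
}

#' Human-readable reaction equation
#' @param stoich named numeric vector (metabolite id -> coefficient).
#' @param reversible logical, controls the arrow.
#' @return character scalar such as `"a + 2 b --> c"`.
#' @export
reaction_equation <- function(stoich, reversible = FALSE) {
  fmt <- function(v) {
    paste(ifelse(abs(v) == 1, names(v), paste(format(abs(v), trim = TRUE), names(v))),
          collapse = " + ")
  }
  lhs <- fmt(stoich[stoich < 0]); rhs <- fmt(stoich[stoich > 0])
  arrow <- if (reversible) "<==>" else "-->"
  paste(lhs, arrow, rhs)
}

#' Tidy a metabolic model into a reaction table
#'
#' @param x a `metabolic_model`.
#' @param ... unused.
#' @return tibble with one row per reaction, including a rendered equation.
#' @method tidy metabolic_model
#' @export
tidy.metabolic_model <- function(x, ...) {
  r <- x$reactions
  tibble::tibble(
    id = r$id, name = r$name,
    equation = purrr::map2_chr(r$stoichiometry, r$lower_bound < 0,
                               reaction_equation),
    lower_bound = r$lower_bound, upper_bound = r$upper_bound,
    subsystem = r$subsystem, category = r$category,
    gene_association = r$gene_association, evidence = r$evidence
  )
}

#' One-line model summary
#'
#' @param x a `metabolic_model`.
#' @param ... unused.
#' @return one-row tibble with gene/reaction/metabolite/compartment counts.
#' @method glance metabolic_model
#' @export
glance.metabolic_model <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_reactions = nrow(x$reactions),
    n_metabolites = nrow(x$metabolites),
    n_compartments = length(x$compartments),
    n_exchange = sum(x$reactions$category == "exchange")
  )
}

#' Build the stoichiometric matrix N
#'
#' Rows are metabolites, columns reactions; `N %*% v` gives the net
#' production rate of every metabolite under flux vector `v`.
#'
#' @param model a `metabolic_model`.
#' @return sparse `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
build_matrix <- function(model) {
  mets <- model$metabolites$id; rxns <- model$reactions$id
  if (!length(rxns) || !length(mets)) {
    return(Matrix::Matrix(0, length(mets), length(rxns), sparse = TRUE,
                          dimnames = list(mets, rxns)))
  }
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (j in seq_along(rxns)) {
    s <- model$reactions$stoichiometry[[j]]
    ii <- c(ii, match(names(s), mets)); jj <- c(jj, rep(j, length(s)))
    vv <- c(vv, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Check elemental mass balance of model reactions
#'
#' Computes per-reaction, per-element net atom counts from metabolite
#' formulas. Boundary pseudo-reactions (exchange, biomass, demand, sink,
#' maintenance) are excluded. Reactions involving a metabolite without a
#' formula are skipped and listed separately.
#'
#' @param model a `metabolic_model`.
#' @param tol absolute tolerance on the net atom count.
#' @return list with `imbalanced` (tibble reaction/element/net, where a
#'   positive net means atoms are lost from reactants to products) and
#'   `skipped` (character vector of reaction ids lacking formulas).
#' @export
check_mass_balance <- function(model, tol = 1e-6) {
  fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  rows <- list(); skipped <- character(0)
  keep <- !(model$reactions$category %in% BOUNDARY_CATEGORIES)
  for (j in which(keep)) {
    s <- model$reactions$stoichiometry[[j]]
    fs <- fmap[names(s)]
    if (any(is.na(fs))) { skipped <- c(skipped, model$reactions$id[j]); next }
    net <- -sum_formulas(fs, unname(s))   # positive = atoms lost L -> R
    bad <- net[abs(net) > tol]
    if (length(bad)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reaction = model$reactions$id[j], element = names(bad),
        net = unname(bad))
    }
  }
  imb <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(reaction = character(0), element = character(0),
                   net = numeric(0))
  }
  list(imbalanced = imb, skipped = skipped)
}

#' Count reactions by category and subsystem
#'
#' @param model a `metabolic_model`.
#' @return list of two tibbles, `category` and `subsystem`, each with counts
#'   (`n`) that sum to the total number of reactions.
#' @export
count_by_category <- function(model) {
  r <- model$reactions
  if (!nrow(r)) {
    return(list(
      category = tibble::tibble(category = character(0), n = integer(0)),
      subsystem = tibble::tibble(subsystem = character(0), n = integer(0))))
  }
  list(
    category = dplyr::count(r, .data$category, name = "n") |>
      dplyr::rename(category = "category"),
    subsystem = dplyr::count(r, .data$subsystem, name = "n") |>
      dplyr::rename(subsystem = "subsystem")
  )
}

#' Identify exchange reactions
#'
#' Uses the category tag where present; otherwise falls back to the
#' single-external-metabolite heuristic (one metabolite in the
#' stoichiometry), with a message.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
find_exchanges <- function(model) {
  r <- model$reactions
  tagged <- r$id[r$category == "exchange"]
  if (length(tagged)) return(tagged)
  heur <- r$id[lengths(r$stoichiometry) == 1 & r$category == "metabolic"]
  if (length(heur)) {
    message("no reactions tagged 'exchange'; using single-metabolite heuristic (",
            length(heur), " candidates)")
  }
  heur
}

## ---- small model-editing helpers ------------------------------------------

#' Add reactions to a model
#' @param model a `metabolic_model`.
#' @param reactions tibble of reaction rows (same columns as `model$reactions`).
#' @return extended model (the input is not modified).
#' @export
add_reactions <- function(model, reactions) {
  dup <- intersect(reactions$id, model$reactions$id)
  if (length(dup)) stop("duplicate reaction id(s): ",
                        paste(dup, collapse = ", "), call. = FALSE)
  model$reactions <- dplyr::bind_rows(model$reactions,
                                      tibble::as_tibble(reactions))
  model$genes <- extract_genes(model$reactions$gene_association)
  validate_model(model)
}

#' Remove reactions from a model
#' @param model a `metabolic_model`.
#' @param ids reaction ids to drop.
#' @return reduced model.
#' @export
remove_reactions <- function(model, ids) {
  missing <- setdiff(ids, model$reactions$id)
  if (length(missing)) stop("cannot remove unknown reaction(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  model$reactions <- model$reactions[!model$reactions$id %in% ids, ]
  model$genes <- extract_genes(model$reactions$gene_association)
  model
}

#' Set flux bounds on one reaction
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lower,upper new bounds (mmol/gDCW/h); `NULL` leaves one unchanged.
#' @return modified model.
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", id, call. = FALSE)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  model
}

#' Tag the genomic evidence status of a reaction
#'
#' Stores one of `annotated`, `gap_filled` or `orphan` on the reaction;
#' reactions default to `annotated`. Use [evidence_summary()] for counts.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @param evidence_tag one of `"annotated"`, `"gap_filled"`, `"orphan"`.
#' @return modified model.
#' @export
record_evidence <- function(model, reaction_id, evidence_tag) {
  if (!evidence_tag %in% EVIDENCE_TAGS) {
    stop("unknown evidence tag: ", evidence_tag, " (expected one of ",
         paste(EVIDENCE_TAGS, collapse = ", "), ")", call. = FALSE)
  }
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", reaction_id, call. = FALSE)
  model$reactions$evidence[i] <- evidence_tag
  model
}

#' Count reactions per evidence tag
#' @param model a `metabolic_model`.
#' @return tibble with columns `evidence`, `n` (all tags present, zero-filled).
#' @export
evidence_summary <- function(model) {
  tibble::tibble(evidence = EVIDENCE_TAGS) |>
    dplyr::left_join(dplyr::count(model$reactions, .data$evidence, name = "n"),
                     by = "evidence") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}
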