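## SBML input/output, Level 3 Version 1 + FBC v2 on write; FBC and legacy
## Level 2 kinetic-law bound annotations on read. Implemented directly on
## xml2 (no libSBML binding exists for R); the dialect follows what cobrapy
## and libSBML emit so models interchange cleanly.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

## SId sanitation: reversible escaping of characters outside [A-Za-z0-9_]
sid_escape <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    bad <- !grepl("^[A-Za-z0-9_]$", chars)
    if (any(bad)) {
      chars[bad] <- sprintf("__x%02X__", vapply(chars[bad], utf8ToInt, 1L))
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

sid_unescape <- function(x) {
  vapply(x, function(s) {
    m <- gregexpr("__x([0-9A-F]{2})__", s)
    regmatches(s, m) <- lapply(regmatches(s, m), function(hits) {
      vapply(hits, function(h) {
        intToUtf8(strtoi(sub("__x([0-9A-F]{2})__", "\\1", h), 16L))
      }, character(1))
    })
    s
  }, character(1), USE.NAMES = FALSE)
}

num_attr <- function(x) sprintf("%.17g", x)

## ---- gene-association boolean expressions ---------------------------------

## grammar: expr := term ("or" term)* ; term := factor ("and" factor)* ;
## factor := gene-id | "(" expr ")"
parse_gpr <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    terms <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); terms[[length(terms) + 1L]] <- parse_term()
    }
    if (length(terms) == 1L) terms[[1L]] else list(op = "or", args = terms)
  }
  parse_term <- function() {
    facs <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); facs[[length(facs) + 1L]] <- parse_factor()
    }
    if (length(facs) == 1L) facs[[1L]] else list(op = "and", args = facs)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("truncated gene association: ", s, call. = FALSE)
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop("unbalanced parentheses in: ", s,
                                        call. = FALSE)
      e
    } else if (t == ")") {
      stop("unexpected ')' in gene association: ", s, call. = FALSE)
    } else {
      list(op = "gene", gene = t)
    }
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in gene association: ", s,
                                call. = FALSE)
  out
}

deparse_gpr <- function(node, parent_op = "") {
  if (node$op == "gene") return(node$gene)
  inner <- vapply(node$args, deparse_gpr, character(1), parent_op = node$op)
  s <- paste(inner, collapse = paste0(" ", node$op, " "))
  if (parent_op != "" && parent_op != node$op) paste0("(", s, ")") else s
}

gpr_add_xml <- function(parent, node) {
  if (node$op == "gene") {
    ref <- xml2::xml_add_child(parent, "fbc:geneProductRef")
    xml2::xml_set_attr(ref, "fbc:geneProduct",
                       paste0("G_", sid_escape(node$gene)))
  } else {
    el <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
    for (a in node$args) gpr_add_xml(el, a)
  }
}

gpr_from_xml <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    list(op = "gene", gene = sid_unescape(sub("^G_", "", g)))
  } else if (nm %in% c("and", "or")) {
    list(op = nm, args = lapply(xml2::xml_children(node), gpr_from_xml))
  } else {
    stop("unexpected element in geneProductAssociation: ", nm, call. = FALSE)
  }
}

## ---- writer ----------------------------------------------------------------

#' Write a model as SBML Level 3 + FBC v2
#'
#' Flux bounds are encoded as FBC bound parameters, the objective as an FBC
#' objective, gene associations as nested `fbc:and`/`fbc:or` trees, and
#' subsystem/category/evidence labels as structured reaction notes. Ids with
#' characters outside the SBML SId alphabet are escaped reversibly.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param model_id id recorded on the SBML model element.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, model_id = "model") {
  doc <- xml2::xml_new_root(
    "sbml",
    "xmlns" = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model_id,
                             "fbc:strict" = "false")

  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in model$compartments) {
    xml2::xml_add_child(loc, "compartment", id = sid_escape(cp),
                        constant = "true")
  }

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      los, "species", id = paste0("M_", sid_escape(m$id)), name = m$name,
      compartment = sid_escape(m$compartment),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
    if (!is.na(m$charge)) {
      xml2::xml_set_attr(sp, "fbc:charge", as.character(m$charge))
    }
  }

  ## shared bound parameters, one per distinct value, deterministic order
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  bid <- stats::setNames(sprintf("cf_bound_%d", seq_along(bounds) - 1L),
                         num_attr(bounds))
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (b in bounds) {
    xml2::xml_add_child(lop, "parameter", id = bid[[num_attr(b)]],
                        value = num_attr(b), constant = "true")
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rx <- xml2::xml_add_child(
      lor, "reaction", id = paste0("R_", sid_escape(r$id)), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false", fast = "false")
    xml2::xml_set_attr(rx, "fbc:lowerFluxBound", bid[[num_attr(r$lower_bound)]])
    xml2::xml_set_attr(rx, "fbc:upperFluxBound", bid[[num_attr(r$upper_bound)]])
    notes <- xml2::xml_add_child(rx, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
    xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    xml2::xml_add_child(body, "p", paste0("CATEGORY: ", r$category))
    xml2::xml_add_child(body, "p", paste0("EVIDENCE: ", r$evidence))
    s <- r$stoichiometry[[1]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_along(reac)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", sid_escape(names(reac)[k])),
                            stoichiometry = num_attr(-reac[[k]]),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_along(prod)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", sid_escape(names(prod)[k])),
                            stoichiometry = num_attr(prod[[k]]),
                            constant = "true")
      }
    }
    if (nzchar(r$gene_association)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      gpr_add_xml(gpa, parse_gpr(r$gene_association))
    }
  }

  if (!is.null(model$objective)) {
    loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = paste0(
                                if (model$objective$direction == "max")
                                  "maximize" else "minimize"))
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    fo <- xml2::xml_add_child(lfo, "fbc:fluxObjective")
    xml2::xml_set_attr(fo, "fbc:reaction",
                       paste0("R_", sid_escape(model$objective$reaction)))
    xml2::xml_set_attr(fo, "fbc:coefficient", "1")
  }

  if (length(model$genes)) {
    lgp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      gp <- xml2::xml_add_child(lgp, "fbc:geneProduct")
      xml2::xml_set_attr(gp, "fbc:id", paste0("G_", sid_escape(g)))
      xml2::xml_set_attr(gp, "fbc:label", g)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

## ---- reader ----------------------------------------------------------------

#' Read a model from SBML
#'
#' Accepts Level 3 + FBC (bounds as FBC parameters, objective and gene
#' products as FBC constructs) as well as legacy Level 2 files carrying
#' `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters. Reactions without
#' bound information receive defaults (-1000/1000 if reversible, 0/1000
#' otherwise) with a warning.
#'
#' @param path SBML file.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)  # work with local names; fbc attrs keep their names
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path,
                                         call. = FALSE)

  comps <- sid_unescape(
    xml2::xml_attr(xml2::xml_find_all(mdl, ".//listOfCompartments/compartment"),
                   "id"))

  sp_nodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  strip_m <- function(x) sid_unescape(sub("^M_", "", x))
  sp_id_raw <- xml2::xml_attr(sp_nodes, "id")
  metabolites <- tibble::tibble(
    id = strip_m(sp_id_raw),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"), strip_m(sp_id_raw)),
    compartment = sid_unescape(xml2::xml_attr(sp_nodes, "compartment")),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula"),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp_nodes, "charge")))
  )
  sp_map <- stats::setNames(metabolites$id, sp_id_raw)

  params <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  n <- length(rx_nodes)
  ids <- character(n); nms <- character(n); stoich <- vector("list", n)
  lbv <- numeric(n); ubv <- numeric(n); subs <- character(n)
  cats <- character(n); gpr <- character(n); evid <- character(n)
  defaulted <- character(0)
  for (i in seq_len(n)) {
    rx <- rx_nodes[[i]]
    ids[i] <- sid_unescape(sub("^R_", "", xml2::xml_attr(rx, "id")))
    nm <- xml2::xml_attr(rx, "name")
    nms[i] <- if (is.na(nm)) ids[i] else nm
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")

    sref <- function(xp, sign) {
      nodes <- xml2::xml_find_all(rx, xp)
      if (!length(nodes)) return(stats::setNames(numeric(0), character(0)))
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
        unname(sp_map[xml2::xml_attr(nodes, "species")]))
    }
    s <- c(sref("./listOfReactants/speciesReference", -1),
           sref("./listOfProducts/speciesReference", 1))
    ## merge duplicate species references
    merged <- tapply(unname(s), factor(names(s), levels = unique(names(s))),
                     sum)[unique(names(s))]
    stoich[[i]] <- stats::setNames(as.vector(merged), names(merged))

    ## bounds: FBC attributes, then legacy kinetic-law parameters, then default
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    if (!is.na(lb_ref) && !is.na(ub_ref)) {
      lbv[i] <- pval[[lb_ref]]; ubv[i] <- pval[[ub_ref]]
    } else {
      kl <- xml2::xml_find_all(rx, "./kineticLaw//parameter")
      klv <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                             xml2::xml_attr(kl, "id"))
      if (all(c("LOWER_BOUND", "UPPER_BOUND") %in% names(klv))) {
        lbv[i] <- klv[["LOWER_BOUND"]]; ubv[i] <- klv[["UPPER_BOUND"]]
      } else {
        lbv[i] <- if (rev) -1000 else 0; ubv[i] <- 1000
        defaulted <- c(defaulted, ids[i])
      }
    }

    ps <- xml2::xml_text(xml2::xml_find_all(rx, "./notes//p"))
    grab <- function(tag, fallback) {
      hit <- ps[startsWith(ps, paste0(tag, ": "))]
      if (length(hit)) sub(paste0("^", tag, ": "), "", hit[1]) else fallback
    }
    subs[i] <- grab("SUBSYSTEM", "unassigned")
    cats[i] <- grab("CATEGORY",
                    if (length(stoich[[i]]) == 1L) "exchange" else "metabolic")
    evid[i] <- grab("EVIDENCE", "annotated")

    gpa <- xml2::xml_find_first(
      rx, "./*[local-name()='geneProductAssociation']/*")
    gpr[i] <- if (inherits(gpa, "xml_missing")) "" else
      deparse_gpr(gpr_from_xml(gpa))
  }
  if (length(defaulted)) {
    warning("no flux bounds for ", length(defaulted),
            " reaction(s); defaults applied (-1000/1000 reversible, 0/1000 ",
            "irreversible): ", paste(utils::head(defaulted, 5), collapse = ", "),
            if (length(defaulted) > 5) ", ..." else "", call. = FALSE)
  }

  objective <- NULL
  fo <- xml2::xml_find_first(mdl, ".//*[local-name()='objective']")
  if (!inherits(fo, "xml_missing")) {
    rid <- xml2::xml_attr(
      xml2::xml_find_first(fo, ".//*[local-name()='fluxObjective']"),
      "reaction")
    objective <- list(
      reaction = sid_unescape(sub("^R_", "", rid)),
      direction = if (identical(xml2::xml_attr(fo, "type"), "maximize"))
        "max" else "min")
  }

  metabolic_model(
    metabolites = metabolites,
    reactions = tibble::tibble(
      id = ids, name = nms, stoichiometry = stoich,
      lower_bound = lbv, upper_bound = ubv, subsystem = subs,
      category = cats, gene_association = gpr, evidence = evid),
    objective = objective,
    compartments = if (length(comps)) comps else unique(metabolites$compartment))
}
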