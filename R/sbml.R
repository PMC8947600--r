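# SBML Level 3 + FBC (version 2) reading and writing with xml2.
#
# Covers the subset of the standard that constraint-based analysis
# needs: species, reactions with stoichiometry, flux-bound parameters,
# gene-product associations (fbc:and / fbc:or / fbc:geneProductRef) and
# the active objective, which designates the biomass reaction. The
# conventional M_/R_/G_ identifier prefixes are added on write and
# stripped on read.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML file '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) {
    stop("SBML file '", path, "' has no <model> element", call. = FALSE)
  }

  sp <- xml2::xml_find_all(model_node, ".//s:listOfSpecies/s:species", ns)
  if (length(sp) == 0L) stop("SBML file '", path, "' lists no species", call. = FALSE)
  mets <- tibble::tibble(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           strip_prefix(xml2::xml_attr(sp, "id"), "M_")),
    compartment = dplyr::coalesce(xml2::xml_attr(sp, "compartment"), "c")
  )

  pars <- xml2::xml_find_all(model_node, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  gps <- xml2::xml_find_all(model_node, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(
    dplyr::coalesce(xml2::xml_attr(gps, "label"),
                    strip_prefix(xml2::xml_attr(gps, "id"), "G_")),
    xml2::xml_attr(gps, "id")
  )

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lab <- gp_label[[ref]] %||% strip_prefix(ref, "G_")
      return(gpr_gene(lab))
    }
    kids <- xml2::xml_children(node)
    args <- lapply(kids, parse_assoc)
    if (nm == "and") return(gpr_node("and", args))
    if (nm == "or") return(gpr_node("or", args))
    stop("unsupported gene association element <", nm, "> in '", path, "'",
         call. = FALSE)
  }

  rx_nodes <- xml2::xml_find_all(model_node, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx_nodes) == 0L) {
    stop("SBML file '", path, "' lists no reactions", call. = FALSE)
  }
  rx_list <- vector("list", length(rx_nodes))
  st_list <- vector("list", length(rx_nodes))
  for (k in seq_along(rx_nodes)) {
    node <- rx_nodes[[k]]
    rid <- strip_prefix(xml2::xml_attr(node, "id"), "R_")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) {
      par_val[[lb_ref]]
    } else if (reversible) -BIG_BOUND else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) {
      par_val[[ub_ref]]
    } else {
      BIG_BOUND
    }
    assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(assoc, "xml_missing")) gpr_true() else parse_assoc(assoc)

    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    coef_of <- function(nodes, sign) {
      if (length(nodes) == 0L) return(NULL)
      sto <- as.numeric(dplyr::coalesce(xml2::xml_attr(nodes, "stoichiometry"), "1"))
      tibble::tibble(
        reaction_id = rid,
        metabolite_id = strip_prefix(xml2::xml_attr(nodes, "species"), "M_"),
        coefficient = sign * sto
      )
    }
    st_list[[k]] <- dplyr::bind_rows(coef_of(reac, -1), coef_of(prod, 1))
    if (is.null(st_list[[k]]) || nrow(st_list[[k]]) == 0L) {
      stop("reaction '", rid, "' in '", path, "' has no stoichiometry", call. = FALSE)
    }
    gpr_str <- gpr_to_string(gpr)
    rx_list[[k]] <- tibble::tibble(
      id = rid, lower_bound = lb, upper_bound = ub,
      gpr = list(gpr), gpr_string = gpr_str
    )
  }

  obj_ref <- xml2::xml_find_first(
    model_node, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns
  )
  if (inherits(obj_ref, "xml_missing")) {
    stop("SBML file '", path,
         "' declares no flux objective; cannot determine the biomass reaction",
         call. = FALSE)
  }
  biomass <- strip_prefix(xml2::xml_attr(obj_ref, "reaction"), "R_")

  metabolic_model(mets, dplyr::bind_rows(rx_list), dplyr::bind_rows(st_list),
                  biomass = biomass)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  bounds <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  bnd_id <- function(v) paste0("bnd_", match(v, bounds))

  assoc_xml <- function(e) {
    switch(e$type,
      gene = sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>', esc(e$gene)),
      and = paste0("<fbc:and>", paste(vapply(e$args, assoc_xml, character(1)),
                                      collapse = ""), "</fbc:and>"),
      or = paste0("<fbc:or>", paste(vapply(e$args, assoc_xml, character(1)),
                                    collapse = ""), "</fbc:or>")
    )
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    '<model id="model" fbc:strict="true">',
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>',
            esc(unique(model$metabolites$compartment))),
    "</listOfCompartments>",
    "<listOfSpecies>"
  )
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, sprintf(
      '<species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(m$id), esc(m$name), esc(m$compartment)
    ))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>")
  for (k in seq_along(bounds)) {
    lines <- c(lines, sprintf(
      '<parameter id="bnd_%d" value="%s" constant="true"/>',
      k, format(bounds[k], trim = TRUE, scientific = FALSE)
    ))
  }
  lines <- c(lines, "</listOfParameters>", "<listOfReactions>")
  st_by_rxn <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    s <- st_by_rxn[[r$id]]
    lines <- c(lines, sprintf(
      '<reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(r$id), tolower(r$lower_bound < 0), bnd_id(r$lower_bound), bnd_id(r$upper_bound)
    ))
    reac <- s[s$coefficient < 0, ]
    prod <- s[s$coefficient > 0, ]
    if (nrow(reac) > 0L) {
      lines <- c(lines, "<listOfReactants>",
                 sprintf('<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                         esc(reac$metabolite_id),
                         format(-reac$coefficient, trim = TRUE, scientific = FALSE)),
                 "</listOfReactants>")
    }
    if (nrow(prod) > 0L) {
      lines <- c(lines, "<listOfProducts>",
                 sprintf('<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                         esc(prod$metabolite_id),
                         format(prod$coefficient, trim = TRUE, scientific = FALSE)),
                 "</listOfProducts>")
    }
    if (!is_gpr_true(r$gpr[[1L]])) {
      lines <- c(lines, "<fbc:geneProductAssociation>",
                 assoc_xml(r$gpr[[1L]]), "</fbc:geneProductAssociation>")
    }
    lines <- c(lines, "</reaction>")
  }
  lines <- c(
    lines, "</listOfReactions>",
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    "<fbc:listOfFluxObjectives>",
    sprintf('<fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            esc(model$biomass)),
    "</fbc:listOfFluxObjectives>", "</fbc:objective>", "</fbc:listOfObjectives>"
  )
  if (length(model$genes) > 0L) {
    lines <- c(lines, "<fbc:listOfGeneProducts>",
               sprintf('<fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                       esc(model$genes), esc(model$genes)),
               "</fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
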