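# Constraint-based metabolic model container.
#
# A model is an S3 list holding tibbles for metabolites, reactions (with
# parsed GPR trees in a list-column) and stoichiometry in long form, a
# gene catalogue, and the identifier of the biomass reaction. Flux bounds
# use the convention that exchange reactions are written as exports
# (metabolite -> nothing), so uptake is negative flux.

# conventional big bound standing in for "unbounded" flux (mmol/gDW/h)
BIG_BOUND <- 1000

#' Construct a constraint-based metabolic model
#'
#' @param metabolites data frame with columns `id`, and optionally `name`
#'   and `compartment`.
#' @param reactions data frame with columns `id`, `lower_bound`,
#'   `upper_bound` and either `gpr` (list of parsed `gpr` trees) or
#'   `gpr_string` (rule text; empty = no gene association).
#' @param stoichiometry data frame with columns `reaction_id`,
#'   `metabolite_id`, `coefficient` (nonzero).
#' @param biomass identifier of the biomass (target) reaction.
#' @param genes gene catalogue; defaults to the union of genes referenced
#'   by the GPRs.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry, biomass,
                            genes = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  reactions <- tibble::as_tibble(reactions)
  if (!"gpr" %in% names(reactions)) {
    if (!"gpr_string" %in% names(reactions)) reactions$gpr_string <- ""
    reactions$gpr_string[is.na(reactions$gpr_string)] <- ""
    reactions$gpr <- lapply(reactions$gpr_string, parse_gpr)
  }
  if (!"gpr_string" %in% names(reactions)) {
    reactions$gpr_string <- vapply(reactions$gpr, gpr_to_string, character(1))
  }
  stoichiometry <- tibble::as_tibble(stoichiometry)
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))), method = "radix")
  }
  model <- structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      stoichiometry = stoichiometry,
      genes = as.character(genes),
      biomass = biomass
    ),
    class = "metabolic_model"
  )
  validate_model(model)
}

#' Validate a metabolic model against its structural invariants
#'
#' Checks bound ordering, finiteness and nonzeroness of stoichiometric
#' coefficients, existence of the biomass reaction, referential integrity
#' of the stoichiometry, and that every GPR gene is in the catalogue.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly usable in pipes; errors name the
#'   offending element.
#' @export
validate_model <- function(model) {
  rx <- model$reactions
  st <- model$stoichiometry
  if (anyDuplicated(rx$id)) {
    stop("duplicate reaction id: ", rx$id[duplicated(rx$id)][1L], call. = FALSE)
  }
  if (anyDuplicated(model$metabolites$id)) {
    stop("duplicate metabolite id: ",
         model$metabolites$id[duplicated(model$metabolites$id)][1L], call. = FALSE)
  }
  bad <- rx$id[rx$lower_bound > rx$upper_bound]
  if (length(bad) > 0L) {
    stop("reaction with lower_bound > upper_bound: ", bad[1L], call. = FALSE)
  }
  bad <- !is.finite(st$coefficient) | st$coefficient == 0
  if (any(bad)) {
    stop("non-finite or zero stoichiometric coefficient in reaction ",
         st$reaction_id[bad][1L], call. = FALSE)
  }
  if (!model$biomass %in% rx$id) {
    stop("biomass reaction '", model$biomass, "' not found in the model", call. = FALSE)
  }
  unknown_rxn <- setdiff(st$reaction_id, rx$id)
  if (length(unknown_rxn) > 0L) {
    stop("stoichiometry references unknown reaction: ", unknown_rxn[1L], call. = FALSE)
  }
  unknown_met <- setdiff(st$metabolite_id, model$metabolites$id)
  if (length(unknown_met) > 0L) {
    stop("stoichiometry references unknown metabolite: ", unknown_met[1L], call. = FALSE)
  }
  gpr_g <- unique(unlist(lapply(rx$gpr, gpr_genes)))
  missing_g <- setdiff(gpr_g, model$genes)
  if (length(missing_g) > 0L) {
    stop("GPR references gene absent from catalogue: ", missing_g[1L], call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "<metabolic_model> %d reactions, %d metabolites, %d genes; biomass: %s\n",
    nrow(x$reactions), nrow(x$metabolites), length(x$genes), x$biomass
  ))
  invisible(x)
}

#' Dense stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  st <- model$stoichiometry
  S[cbind(match(st$metabolite_id, mets), match(st$reaction_id, rxns))] <- st$coefficient
  S
}

reaction_row <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", id, call. = FALSE)
  i
}

#' Read a metabolic model from file
#'
#' Supports SBML Level 3 with the FBC package and a compact JSON dialect
#' (fields `metabolites`, `reactions` with `metabolites`/`lower_bound`/
#' `upper_bound`/`gene_reaction_rule`, `genes`, `biomass`).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"`, or `"sbml"`.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "sbml") return(read_model_sbml(path))
  read_model_json(path)
}

#' Write a metabolic model to file
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param format `"auto"` (by extension), `"json"`, or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "sbml") write_model_sbml(model, path) else write_model_json(model, path)
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON model file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  for (field in c("metabolites", "reactions", "biomass")) {
    if (is.null(doc[[field]])) {
      stop("model file '", path, "' lacks required field '", field, "'", call. = FALSE)
    }
  }
  mets <- dplyr::bind_rows(lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without id in '", path, "'", call. = FALSE)
    tibble::tibble(
      id = m$id,
      name = m$name %||% m$id,
      compartment = m$compartment %||% "c"
    )
  }))
  rx_list <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in '", path, "'", call. = FALSE)
    tibble::tibble(
      id = r$id,
      lower_bound = r$lower_bound %||% 0,
      upper_bound = r$upper_bound %||% BIG_BOUND,
      gpr_string = r$gene_reaction_rule %||% ""
    )
  })
  rxns <- dplyr::bind_rows(rx_list)
  st <- dplyr::bind_rows(lapply(doc$reactions, function(r) {
    if (length(r$metabolites) == 0L) {
      stop("reaction '", r$id, "' has empty stoichiometry", call. = FALSE)
    }
    tibble::tibble(
      reaction_id = r$id,
      metabolite_id = names(r$metabolites),
      coefficient = unlist(r$metabolites, use.names = FALSE)
    )
  }))
  genes <- unlist(doc$genes) %||% NULL
  metabolic_model(mets, rxns, st, biomass = doc$biomass, genes = genes)
}

write_model_json <- function(model, path) {
  st_by_rxn <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  reactions <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    s <- st_by_rxn[[r$id]]
    list(
      id = r$id,
      metabolites = stats::setNames(as.list(s$coefficient), s$metabolite_id),
      lower_bound = r$lower_bound,
      upper_bound = r$upper_bound,
      gene_reaction_rule = r$gpr_string
    )
  })
  doc <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      as.list(model$metabolites[i, c("id", "name", "compartment")])
    }),
    reactions = reactions,
    genes = model$genes,
    biomass = model$biomass
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
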