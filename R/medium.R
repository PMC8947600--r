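# Growth media and model patches.
#
# A medium is a tibble mapping nutrient metabolites to their input
# exchange reactions with a maximal uptake (mM concentrations used
# directly as uptake bounds, mmol/gDW/h). Applying a medium opens the
# listed input exchanges and closes every other input exchange to import;
# the export direction is never touched, so secretion stays possible.

#' Build a growth-medium table
#'
#' @param metabolite_id nutrient metabolite identifiers.
#' @param exchange_id matching input exchange reaction identifiers.
#' @param max_uptake maximal uptake per nutrient (mmol/gDW/h); `Inf` means
#'   unbounded (the conventional big bound is used).
#' @return a tibble with class `ngmcs_medium`.
#' @export
medium <- function(metabolite_id, exchange_id, max_uptake = Inf) {
  out <- tibble::tibble(
    metabolite_id = as.character(metabolite_id),
    exchange_id = as.character(exchange_id),
    max_uptake = rep_len(as.numeric(max_uptake), length(metabolite_id))
  )
  if (anyDuplicated(out[c("metabolite_id", "exchange_id")])) {
    stop("nutrient listed twice for the same exchange reaction", call. = FALSE)
  }
  class(out) <- c("ngmcs_medium", class(out))
  out
}

#' Read a growth-medium TSV
#'
#' Expected header: `metabolite_id  exchange_id  max_uptake_mM`; the value
#' `inf` marks unbounded uptake.
#'
#' @param path file path.
#' @return a medium tibble (see [medium()]).
#' @export
read_medium <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("metabolite_id", "exchange_id", "max_uptake_mM")
  if (!all(need %in% names(tb))) {
    stop("medium file '", path, "' must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  up <- suppressWarnings(as.numeric(sub("^inf$", "Inf", tb$max_uptake_mM, ignore.case = TRUE)))
  if (anyNA(up)) {
    stop("medium file '", path, "': non-numeric max_uptake_mM at line ",
         which(is.na(up))[1L] + 1L, call. = FALSE)
  }
  medium(tb$metabolite_id, tb$exchange_id, up)
}

#' Write a growth-medium TSV
#'
#' @param med a medium tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_medium <- function(med, path) {
  out <- tibble::tibble(
    metabolite_id = med$metabolite_id,
    exchange_id = med$exchange_id,
    max_uptake_mM = ifelse(is.infinite(med$max_uptake), "inf",
                           format(med$max_uptake, trim = TRUE))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

# single-metabolite boundary reactions and the sign of their import
# direction: +1 if positive flux imports the metabolite, -1 if negative
# flux does (the export-written convention)
exchange_info <- function(model) {
  st <- model$stoichiometry
  counts <- table(st$reaction_id)
  singles <- names(counts)[counts == 1L]
  st1 <- st[st$reaction_id %in% singles, ]
  i <- match(st1$reaction_id, model$reactions$id)
  tibble::tibble(
    reaction_id = st1$reaction_id,
    metabolite_id = st1$metabolite_id,
    import_sign = ifelse(st1$coefficient > 0, 1, -1),
    lower_bound = model$reactions$lower_bound[i],
    upper_bound = model$reactions$upper_bound[i]
  )
}

#' Find the input exchange reactions of a model
#'
#' An input exchange exchanges a single metabolite with the environment
#' and its bounds permit net import of it (for export-written exchanges,
#' a negative lower bound).
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction identifiers.
#' @export
find_input_exchanges <- function(model) {
  ex <- exchange_info(model)
  open <- ifelse(ex$import_sign > 0, ex$upper_bound > 0, ex$lower_bound < 0)
  sort(ex$reaction_id[open], method = "radix")
}

#' Apply a growth medium to a model
#'
#' Opens the input exchanges listed in the medium at their maximal uptake
#' and closes the import direction of every other single-metabolite
#' boundary reaction. Export (secretion) bounds are untouched. The
#' operation is idempotent.
#'
#' @param model a `metabolic_model`.
#' @param med a medium tibble (see [medium()]).
#' @return the modified `metabolic_model`.
#' @export
apply_medium <- function(model, med) {
  ex <- exchange_info(model)
  unknown <- setdiff(med$exchange_id, ex$reaction_id)
  if (length(unknown) > 0L) {
    stop("medium references reaction '", unknown[1L],
         "' which is not an exchange reaction of the model", call. = FALSE)
  }
  mism <- med$metabolite_id != ex$metabolite_id[match(med$exchange_id, ex$reaction_id)]
  if (any(mism)) {
    stop("medium pairs nutrient '", med$metabolite_id[mism][1L],
         "' with exchange '", med$exchange_id[mism][1L],
         "', which exchanges a different metabolite", call. = FALSE)
  }
  rx <- model$reactions
  for (k in seq_len(nrow(ex))) {
    i <- match(ex$reaction_id[k], rx$id)
    j <- match(ex$reaction_id[k], med$exchange_id)
    if (is.na(j)) { # not in medium: close to import
      if (ex$import_sign[k] > 0) {
        rx$upper_bound[i] <- min(rx$upper_bound[i], 0)
      } else {
        rx$lower_bound[i] <- max(rx$lower_bound[i], 0)
      }
    } else {
      up <- med$max_uptake[j]
      if (is.infinite(up) || up > BIG_BOUND) up <- BIG_BOUND
      if (ex$import_sign[k] > 0) {
        rx$upper_bound[i] <- up
        rx$lower_bound[i] <- min(rx$lower_bound[i], 0)
      } else {
        rx$lower_bound[i] <- -up
        rx$upper_bound[i] <- max(rx$upper_bound[i], 0)
      }
    }
  }
  model$reactions <- rx
  validate_model(model)
  model
}

#' Read a model patch TSV
#'
#' Expected header: `action  reaction_id  lower_bound  upper_bound`, with
#' actions `delete` (bounds ignored) and `set_bounds`.
#'
#' @param path file path.
#' @return a patch tibble.
#' @export
read_patch <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          action = readr::col_character(),
                          reaction_id = readr::col_character(),
                          .default = readr::col_double()
                        ))
  need <- c("action", "reaction_id", "lower_bound", "upper_bound")
  if (!all(need %in% names(tb))) {
    stop("patch file '", path, "' must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tb
}

#' Apply a patch (reaction deletions / bound edits) to a model
#'
#' @param model a `metabolic_model`.
#' @param patch data frame with columns `action` (`"delete"` or
#'   `"set_bounds"`), `reaction_id`, `lower_bound`, `upper_bound`.
#' @return the patched `metabolic_model`.
#' @export
apply_patch <- function(model, patch) {
  patch <- tibble::as_tibble(patch)
  if (nrow(patch) == 0L) return(model)
  unknown <- setdiff(patch$reaction_id, model$reactions$id)
  if (length(unknown) > 0L) {
    stop("patch references unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_action <- setdiff(patch$action, c("delete", "set_bounds"))
  if (length(bad_action) > 0L) {
    stop("unknown patch action: ", bad_action[1L], call. = FALSE)
  }
  del <- patch$reaction_id[patch$action == "delete"]
  if (model$biomass %in% del) {
    stop("patch would delete the biomass reaction '", model$biomass, "'", call. = FALSE)
  }
  if (length(del) > 0L) {
    model$reactions <- model$reactions[!model$reactions$id %in% del, ]
    model$stoichiometry <- model$stoichiometry[!model$stoichiometry$reaction_id %in% del, ]
  }
  edits <- patch[patch$action == "set_bounds", ]
  for (k in seq_len(nrow(edits))) {
    i <- match(edits$reaction_id[k], model$reactions$id)
    if (is.na(i)) next # deleted by the same patch
    model$reactions$lower_bound[i] <- edits$lower_bound[k]
    model$reactions$upper_bound[i] <- edits$upper_bound[k]
  }
  validate_model(model)
  model
}
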