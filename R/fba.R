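# Flux balance analysis: the LP oracle that decides whether a knockout
# set blocks the biomass reaction, and the reversible-to-irreversible
# conversion required by the duality construction.

#' Convert a model to irreversible form
#'
#' Every reversible reaction (negative lower bound) is split into a
#' forward and a backward copy with swapped stoichiometry and the same
#' GPR, so that a gene knockout removes both directions. The mapping is
#' kept in the `reversible_map` field.
#'
#' @param model a `metabolic_model`.
#' @return an object of classes `irreversible_model`, `metabolic_model`,
#'   whose feasible flux projections equal those of the input.
#' @export
split_reversible <- function(model) {
  rx <- model$reactions
  st <- model$stoichiometry
  map <- tibble::tibble(
    original_id = rx$id,
    forward_id = rx$id,
    backward_id = NA_character_
  )
  rev_idx <- which(rx$lower_bound < 0)
  for (i in rev_idx) {
    orig <- rx$id[i]
    bid <- paste0(orig, "_rev")
    while (bid %in% rx$id) bid <- paste0(bid, "_")
    map$backward_id[map$original_id == orig] <- bid
    back <- rx[i, ]
    back$id <- bid
    back$lower_bound <- 0
    back$upper_bound <- -rx$lower_bound[i]
    rx <- dplyr::bind_rows(rx, back)
    s <- st[st$reaction_id == orig, ]
    s$reaction_id <- bid
    s$coefficient <- -s$coefficient
    st <- dplyr::bind_rows(st, s)
  }
  if (length(rev_idx) > 0L) {
    rx$lower_bound[rev_idx] <- 0
    rx$upper_bound[rev_idx] <- pmax(rx$upper_bound[rev_idx], 0)
  }
  model$reactions <- rx
  model$stoichiometry <- st
  model$reversible_map <- map
  class(model) <- unique(c("irreversible_model", class(model)))
  validate_model(model)
  model
}

# expand original reaction ids to their irreversible counterparts;
# passes ids through unchanged for plain models
expand_reaction_ids <- function(model, ids) {
  if (!inherits(model, "irreversible_model") || length(ids) == 0L) return(ids)
  map <- model$reversible_map
  hit <- map[map$original_id %in% ids, ]
  extra <- setdiff(ids, map$original_id) # already-split ids given directly
  unique(c(hit$forward_id, hit$backward_id[!is.na(hit$backward_id)], extra))
}

#' Maximal flux through a target reaction
#'
#' Solves the flux balance LP: maximise the target flux subject to steady
#' state (`S v = 0`), the model's flux bounds, and zero flux on the
#' knocked reactions. For an `irreversible_model`, knocked original
#' reaction identifiers are expanded to both directions.
#'
#' @param model a `metabolic_model`.
#' @param target reaction identifier; defaults to the biomass reaction.
#' @param knocked_reactions reaction identifiers forced to zero flux.
#' @return the LP maximum (numeric scalar).
#' @export
max_target_flux <- function(model, target = model$biomass,
                            knocked_reactions = character(0)) {
  rx <- model$reactions
  reaction_row(model, target) # existence check
  bad <- setdiff(knocked_reactions, c(rx$id,
    if (inherits(model, "irreversible_model")) model$reversible_map$original_id))
  if (length(bad) > 0L) {
    stop("knocked reaction not in model: ", bad[1L], call. = FALSE)
  }
  knocked <- expand_reaction_ids(model, knocked_reactions)

  lb <- pmax(rx$lower_bound, -BIG_BOUND)
  ub <- pmin(rx$upper_bound, BIG_BOUND)
  ko <- rx$id %in% knocked
  lb[ko] <- 0
  ub[ko] <- 0
  n <- nrow(rx)
  S <- stoich_matrix(model)
  m <- nrow(S)

  # substitute x = v - lb >= 0; upper bounds become explicit rows
  A <- rbind(S, diag(n))
  dir <- c(rep("==", m), rep("<=", n))
  rhs <- c(as.vector(-S %*% lb), ub - lb)
  obj <- numeric(n)
  ti <- match(target, rx$id)
  obj[ti] <- 1
  sol <- lp_solve(obj, A, dir, rhs, maximize = TRUE)
  if (sol$status != "optimal") {
    stop("flux LP returned status '", sol$status, "' for target ", target, call. = FALSE)
  }
  sol$objective + lb[ti]
}

#' Is a metabolic task blocked by a knockout set?
#'
#' @param model a `metabolic_model`.
#' @param target reaction identifier; defaults to the biomass reaction.
#' @param knocked_reactions reaction identifiers forced to zero flux.
#' @param epsilon flux tolerance below which the target counts as blocked.
#' @return logical scalar.
#' @export
is_blocked <- function(model, target = model$biomass,
                       knocked_reactions = character(0), epsilon = 1e-6) {
  max_target_flux(model, target, knocked_reactions) < epsilon
}

#' Reactions disabled by a set of gene losses and nutrient deprivations
#'
#' A reaction is disabled by the gene losses when its GPR evaluates to
#' false with those genes inactive; a nutrient deprivation disables its
#' input exchange reaction.
#'
#' @param model a `metabolic_model`.
#' @param genes inactive gene identifiers.
#' @param exchanges input exchange reaction identifiers to close.
#' @return character vector of (original) reaction identifiers.
#' @export
disabled_reactions <- function(model, genes = character(0), exchanges = character(0)) {
  rx <- model$reactions
  hit <- character(0)
  if (length(genes) > 0L) {
    dead <- vapply(rx$gpr, function(g) !eval_gpr(g, inactive = genes), logical(1))
    hit <- rx$id[dead]
  }
  unknown <- setdiff(exchanges, rx$id)
  if (length(unknown) > 0L) {
    stop("unknown exchange reaction: ", unknown[1L], call. = FALSE)
  }
  union(hit, exchanges)
}
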