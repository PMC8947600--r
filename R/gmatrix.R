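# The binary G matrix: knockout units x reactions.
#
# Each row is a knockout unit -- a minimal gene set that jointly
# disables at least one reaction, or a single nutrient whose deprivation
# closes its input exchange. Entry (i, j) is 1 iff knocking out row i's
# members disables reaction j. Minimal combinations of rows that block
# the biomass reaction are the cut sets the engine enumerates.

set_key <- function(members) paste(sort(members, method = "radix"), collapse = ";")

new_g_matrix <- function(rows) {
  rows <- tibble::as_tibble(rows)
  class(rows) <- c("g_matrix", class(rows))
  rows
}

#' @export
print.g_matrix <- function(x, ...) {
  cat(sprintf("<g_matrix> %d knockout units (%d gene rows, %d nutrient rows)\n",
              nrow(x), sum(x$kind == "gene_set"), sum(x$kind == "nutrient")))
  NextMethod()
}

#' Build the G matrix of a model
#'
#' For every reaction with a gene association, computes the minimal
#' falsifying gene sets of its GPR; identical gene sets across reactions
#' are merged into one row whose support is every reaction the set
#' disables (by direct GPR evaluation). Rows using genes outside `scope`
#' are dropped. A row is pruned only when another row has a member subset
#' and a support superset (total dominance), which cannot remove any cut
#' set from the search space.
#'
#' @param model a `metabolic_model`.
#' @param scope optional gene identifiers restricting the search space;
#'   rows whose members are not all in `scope` are dropped.
#' @return a `g_matrix` tibble with columns `row_id`, `kind`
#'   (`"gene_set"` / `"nutrient"`), `members` and `reactions`
#'   (list-columns).
#' @export
build_g_matrix <- function(model, scope = NULL) {
  if (!is.null(scope)) {
    unknown <- setdiff(scope, model$genes)
    if (length(unknown) > 0L) {
      stop("scope gene not in catalogue: ", unknown[1L], call. = FALSE)
    }
  }
  rx <- model$reactions
  sets <- list()
  for (i in seq_len(nrow(rx))) {
    if (is_gpr_true(rx$gpr[[i]])) next
    for (s in minimal_falsifying_sets(rx$gpr[[i]])) {
      sets[[set_key(s)]] <- s
    }
  }
  if (!is.null(scope)) {
    sets <- sets[vapply(sets, function(s) all(s %in% scope), logical(1))]
  }
  if (length(sets) == 0L) {
    return(new_g_matrix(tibble::tibble(
      row_id = character(0), kind = character(0),
      members = list(), reactions = list()
    )))
  }
  sets <- sets[order(lengths(sets), names(sets))]
  # full support of each member set, by direct GPR evaluation
  support <- lapply(sets, function(s) {
    dead <- vapply(rx$gpr, function(g) !eval_gpr(g, inactive = s), logical(1))
    rx$id[dead]
  })
  # prune totally dominated rows
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j || !keep[j]) next
      if (length(sets[[j]]) <= length(sets[[i]]) &&
          all(sets[[j]] %in% sets[[i]]) &&
          all(support[[i]] %in% support[[j]]) &&
          !(length(sets[[j]]) == length(sets[[i]]))) {
        keep[i] <- FALSE
        break
      }
    }
  }
  new_g_matrix(tibble::tibble(
    row_id = paste0("gs", seq_len(sum(keep))),
    kind = "gene_set",
    members = unname(sets[keep]),
    reactions = unname(support[keep])
  ))
}

#' Append nutrient pseudo-gene rows to a G matrix
#'
#' One row is appended per open input exchange in the medium: an
#' artificial knockout unit whose only disabled reaction is that
#' exchange, which lets the cut-set search treat nutrient deprivations
#' like gene knockouts. Gene rows are unchanged.
#'
#' @param g a `g_matrix` built from the same model.
#' @param model the `metabolic_model`, with the medium already applied.
#' @param med a medium tibble (see [medium()]).
#' @return the extended `g_matrix`.
#' @export
extend_with_nutrients <- function(g, model, med) {
  if (nrow(med) == 0L) return(g)
  ex <- exchange_info(model)
  unknown <- setdiff(med$exchange_id, ex$reaction_id)
  if (length(unknown) > 0L) {
    stop("medium exchange absent from model: ", unknown[1L], call. = FALSE)
  }
  nut <- tibble::tibble(
    row_id = paste0("nutrient:", med$metabolite_id),
    kind = "nutrient",
    members = as.list(med$metabolite_id),
    reactions = as.list(med$exchange_id)
  )
  new_g_matrix(dplyr::bind_rows(tibble::as_tibble(g), nut))
}

#' Binary incidence matrix of a G matrix
#'
#' @param g a `g_matrix`.
#' @param reaction_ids column order; defaults to the union of supports.
#' @return 0/1 integer matrix, rows x reactions, with dimnames.
#' @export
g_incidence <- function(g, reaction_ids = NULL) {
  if (is.null(reaction_ids)) reaction_ids <- sort(unique(unlist(g$reactions)), method = "radix")
  M <- matrix(0L, nrow(g), length(reaction_ids),
              dimnames = list(g$row_id, reaction_ids))
  for (i in seq_len(nrow(g))) {
    M[i, intersect(g$reactions[[i]], reaction_ids)] <- 1L
  }
  M
}

#' Write a G matrix as TSV plus JSON sidecar
#'
#' The TSV has columns `row_id  kind  members  reactions` with `;`-joined
#' member and reaction lists; the sidecar (same path plus `.json`)
#' records the row count for round-trip checking.
#'
#' @param g a `g_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_g_matrix <- function(g, path) {
  out <- tibble::tibble(
    row_id = g$row_id,
    kind = g$kind,
    members = vapply(g$members, paste, character(1), collapse = ";"),
    reactions = vapply(g$reactions, paste, character(1), collapse = ";")
  )
  readr::write_tsv(out, path)
  jsonlite::write_json(list(rows = nrow(g), format = "ngmcs_g_matrix"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a G matrix written by [write_g_matrix()]
#'
#' @param path TSV path.
#' @return a `g_matrix`.
#' @export
read_g_matrix <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  new_g_matrix(tibble::tibble(
    row_id = tb$row_id,
    kind = tb$kind,
    members = strsplit(tb$members, ";", fixed = TRUE),
    reactions = strsplit(tb$reactions, ";", fixed = TRUE)
  ))
}
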