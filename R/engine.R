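# Cut-set enumeration engine.
#
# "Biomass blocked" is encoded by Farkas duality on the irreversible
# model: the flux system {S v = 0, v >= 0, v_target >= 1} is infeasible
# iff there is a dual vector u with (S'u)_j >= 0 for every reaction j
# that can still carry flux and (S'u)_target >= 1. Selecting a G-matrix
# row (binary z_i) relaxes the dual constraint of every reaction the row
# disables through a big-M slack, so minimal row selections whose
# combined knockouts admit a Farkas certificate are exactly the minimal
# cut sets. The objective counts *elements* (genes via indicator
# variables y_g >= z_i, nutrients via their own row binaries), so
# enumeration is by increasing cut-set size. Every MILP solution is
# re-checked by plain LPs before it is reported.

#' Engine options for cut-set enumeration
#'
#' @param time_limit wall-clock seconds allowed per solution (default 60);
#'   an incumbent found at timeout is still verified and may be accepted.
#' @param max_solutions stop after this many accepted cut sets.
#' @param max_cutset_size largest cut-set cardinality (in elements) to search.
#' @param epsilon flux tolerance: a target is blocked when its LP maximum
#'   falls below this.
#' @param big_M dual relaxation constant.
#' @param solver_seed optional integer recorded for provenance (the
#'   deterministic search itself does not consume randomness).
#' @return list of class `engine_options`.
#' @export
engine_options <- function(time_limit = 60, max_solutions = 1000L,
                           max_cutset_size = Inf, epsilon = 1e-6,
                           big_M = 1000, solver_seed = NULL) {
  stopifnot(time_limit > 0, epsilon > 0, big_M > 0, max_solutions >= 0)
  structure(
    list(
      time_limit = time_limit,
      max_solutions = max_solutions,
      max_cutset_size = max_cutset_size,
      epsilon = epsilon,
      big_M = big_M,
      solver_seed = solver_seed
    ),
    class = "engine_options"
  )
}

cutset_key <- function(elements) paste(sort(elements, method = "radix"), collapse = ";")

empty_cutsets <- function() {
  tibble::tibble(
    elements = list(), genes = list(), nutrients = list(),
    classification = character(0), size = integer(0),
    verified_cut = logical(0), verified_minimal = logical(0)
  )
}

# split a candidate element vector into genes and nutrients, resolving
# nutrients to their input exchange reactions through the G matrix
resolve_elements <- function(model, g, elements) {
  nut_rows <- g[g$kind == "nutrient", ]
  nut_ids <- as.character(unlist(nut_rows$members))
  nutrients <- as.character(intersect(elements, nut_ids))
  genes <- as.character(setdiff(elements, nutrients))
  unknown <- setdiff(genes, model$genes)
  if (length(unknown) > 0L) {
    stop("cut-set element '", unknown[1L],
         "' is neither a catalogue gene nor a nutrient row of the G matrix",
         call. = FALSE)
  }
  exchanges <- vapply(nutrients, function(n) {
    nut_rows$reactions[[match(n, nut_ids)]][1L]
  }, character(1))
  list(genes = genes, nutrients = nutrients, exchanges = unname(exchanges))
}

cutset_row <- function(elements, genes, nutrients, verified_cut, verified_minimal) {
  elements <- as.character(elements)
  genes <- as.character(genes)
  nutrients <- as.character(nutrients)
  cls <- if (length(nutrients) > 0L) "ngMCS" else "gMCS"
  n <- length(elements)
  tibble::tibble(
    elements = list(sort(elements, method = "radix")),
    genes = list(sort(genes, method = "radix")),
    nutrients = list(sort(nutrients, method = "radix")),
    classification = cls,
    size = n,
    verified_cut = verified_cut,
    verified_minimal = verified_minimal
  )
}

#' Verify a candidate cut set by plain LPs
#'
#' `verified_cut` is set by one LP: with every reaction disabled by the
#' candidate knocked, the maximal target flux must fall below `epsilon`.
#' `verified_minimal` needs one LP per element: each leave-one-out
#' knockout must restore target flux. Non-minimal candidates are flagged,
#' never shrunk.
#'
#' @param model a `metabolic_model` (the medium-applied network).
#' @param g the `g_matrix` the candidate was drawn from (resolves
#'   nutrients to exchanges).
#' @param elements character vector of gene and/or nutrient identifiers.
#' @param target reaction identifier; defaults to the biomass reaction.
#' @param epsilon flux tolerance.
#' @return one-row cut-set tibble with the verification flags set.
#' @export
verify_cutset <- function(model, g, elements, target = model$biomass,
                          epsilon = 1e-6) {
  parts <- resolve_elements(model, g, elements)
  ko <- disabled_reactions(model, parts$genes, parts$exchanges)
  cut_ok <- max_target_flux(model, target, ko) < epsilon
  minimal_ok <- cut_ok
  if (cut_ok) {
    for (e in elements) {
      rest <- setdiff(elements, e)
      p <- resolve_elements(model, g, rest)
      ko1 <- disabled_reactions(model, p$genes, p$exchanges)
      if (max_target_flux(model, target, ko1) < epsilon) {
        minimal_ok <- FALSE
        break
      }
    }
  }
  cutset_row(elements, parts$genes, parts$nutrients, cut_ok, minimal_ok)
}

# Assemble the dual MILP. Returns the constraint system plus index maps.
build_dual_milp <- function(imodel, g, target, opts) {
  rx <- imodel$reactions
  ti <- match(target, rx$id)
  if (is.na(ti)) stop("unknown target reaction: ", target, call. = FALSE)
  if (rx$upper_bound[ti] <= opts$epsilon) {
    stop("target reaction '", target, "' has no forward capacity", call. = FALSE)
  }
  S <- stoich_matrix(imodel)
  m <- nrow(S)
  # reactions with no forward capacity cannot carry flux in the
  # irreversible cone and impose no dual constraint
  active <- which(pmin(rx$upper_bound, BIG_BOUND) > 1e-9)
  if (!(ti %in% active)) stop("target reaction is closed", call. = FALSE)

  r <- nrow(g)
  gene_rows <- which(g$kind == "gene_set")
  nut_rows <- which(g$kind == "nutrient")
  ygenes <- sort(unique(unlist(g$members[gene_rows])), method = "radix")
  ng <- length(ygenes)
  # variable layout: p (m) | q (m) | z (r) | y (ng)
  nvar <- 2L * m + r + ng
  zcol <- function(i) 2L * m + i
  ycol <- function(k) 2L * m + r + k

  # incidence of rows on irreversible reactions
  G_inc <- matrix(0L, r, nrow(rx))
  for (i in seq_len(r)) {
    ids <- expand_reaction_ids(imodel, g$reactions[[i]])
    G_inc[i, match(ids, rx$id)] <- 1L
  }

  rows <- list()
  dir <- character(0)
  rhs <- numeric(0)
  add_row <- function(row, d, b) {
    rows[[length(rows) + 1L]] <<- row
    dir <<- c(dir, d)
    rhs <<- c(rhs, b)
  }
  for (j in active) {
    row <- numeric(nvar)
    sj <- S[, j]
    row[seq_len(m)] <- sj
    row[m + seq_len(m)] <- -sj
    if (j == ti) {
      add_row(row, ">=", 1)
    } else {
      if (r > 0L) row[2L * m + seq_len(r)] <- opts$big_M * G_inc[, j]
      add_row(row, ">=", 0)
    }
  }
  for (i in seq_len(r)) {
    row <- numeric(nvar)
    row[zcol(i)] <- 1
    add_row(row, "<=", 1)
  }
  # y_g >= z_i for every gene row i containing g
  for (i in gene_rows) {
    for (gene in g$members[[i]]) {
      row <- numeric(nvar)
      row[zcol(i)] <- 1
      row[ycol(match(gene, ygenes))] <- -1
      add_row(row, "<=", 0)
    }
  }
  obj <- numeric(nvar)
  if (ng > 0L) obj[ycol(seq_len(ng))] <- 1
  for (i in nut_rows) obj[zcol(i)] <- 1
  size_row <- obj # element-count expression, reused for caps and cuts
  if (is.finite(opts$max_cutset_size)) {
    add_row(size_row, "<=", opts$max_cutset_size)
  }
  list(
    A = do.call(rbind, rows), dir = dir, rhs = rhs, obj = obj,
    nvar = nvar, m = m, r = r, ygenes = ygenes,
    zcols = if (r > 0L) 2L * m + seq_len(r) else integer(0),
    ycols = if (ng > 0L) 2L * m + r + seq_len(ng) else integer(0)
  )
}

# an element-level integer cut: forbids any solution whose element set
# contains `elements`; a row-level cut forbids one exact row selection
element_cut <- function(milp, g, elements) {
  row <- numeric(milp$nvar)
  n_cov <- 0L
  for (e in elements) {
    yi <- match(e, milp$ygenes)
    if (!is.na(yi)) {
      row[milp$ycols[yi]] <- 1
      n_cov <- n_cov + 1L
    } else {
      i <- which(g$kind == "nutrient" &
                   vapply(g$members, function(mm) e %in% mm, logical(1)))
      if (length(i) > 0L) {
        row[milp$zcols[i[1L]]] <- 1
        n_cov <- n_cov + 1L
      }
    }
  }
  list(row = row, dir = "<=", rhs = n_cov - 1L)
}

selection_cut <- function(milp, rows_sel) {
  row <- numeric(milp$nvar)
  row[milp$zcols[rows_sel]] <- 1
  list(row = row, dir = "<=", rhs = length(rows_sel) - 1L)
}

solve_shortest <- function(imodel, g, target, cuts, opts) {
  milp <- build_dual_milp(imodel, g, target, opts)
  A <- milp$A
  dir <- milp$dir
  rhs <- milp$rhs
  for (ct in cuts) {
    A <- rbind(A, ct$row)
    dir <- c(dir, ct$dir)
    rhs <- c(rhs, ct$rhs)
  }
  sol <- milp_solve(milp$obj, A, dir, rhs, int_idx = milp$zcols,
                    maximize = FALSE, time_limit = opts$time_limit,
                    integral_objective = TRUE)
  if (sol$status %in% c("infeasible", "timeout")) {
    return(list(status = sol$status, rows = NULL, milp = milp))
  }
  rows_sel <- which(sol$x[milp$zcols] > 0.5)
  list(status = sol$status, rows = rows_sel, milp = milp)
}

rows_to_elements <- function(g, rows_sel) {
  sort(as.character(unique(unlist(g$members[rows_sel]))), method = "radix")
}

#' Shortest cut set for a target reaction
#'
#' Solves the dual MILP once (optionally with exclusions) and verifies
#' the solution by LP. Returns `NULL` when no further cut set exists
#' within the size cap.
#'
#' @param imodel an `irreversible_model` (see [split_reversible()]).
#' @param g a `g_matrix` built from the same (pre-split) model.
#' @param target reaction identifier; defaults to the biomass reaction.
#' @param exclusions list of previously found element sets (character
#'   vectors); solutions containing any of them are excluded.
#' @param opts an [engine_options()] list.
#' @return one-row cut-set tibble (verified) or `NULL`.
#' @export
shortest_cutset <- function(imodel, g, target = imodel$biomass,
                            exclusions = list(), opts = engine_options()) {
  milp0 <- build_dual_milp(imodel, g, target, opts)
  cuts <- lapply(exclusions, function(e) element_cut(milp0, g, e))
  res <- solve_shortest(imodel, g, target, cuts, opts)
  if (is.null(res$rows)) {
    if (res$status == "timeout") {
      warning("MILP timed out with no incumbent; no cut set returned", call. = FALSE)
    }
    return(NULL)
  }
  elements <- rows_to_elements(g, res$rows)
  verify_cutset(imodel, g, elements, target, opts$epsilon)
}

#' Enumerate cut sets by increasing size
#'
#' Repeatedly solves the dual MILP, after each solution adding an
#' integer cut that excludes the found element set and all its supersets,
#' so the output is an antichain ordered by non-decreasing size. Every
#' solution is LP-verified; candidates that fail verification (possible
#' under time limits or big-M artifacts) are discarded and the search is
#' re-posed with that selection excluded, so the reported list stays
#' clean.
#'
#' @param model a `metabolic_model` with its medium applied (a plain
#'   model is split internally; an `irreversible_model` is used as is).
#' @param g a `g_matrix` built from the (pre-split) model, optionally
#'   extended with nutrient rows.
#' @param target reaction identifier; defaults to the biomass reaction.
#' @param opts an [engine_options()] list.
#' @return tibble of class `ngmcs_cutsets`, one row per cut set, columns
#'   `elements`, `genes`, `nutrients`, `classification` (`gMCS` /
#'   `ngMCS`), `size`, `verified_cut`, `verified_minimal`; attribute
#'   `closed` says whether enumeration ended by proven infeasibility.
#' @export
#' @examples
#' cm1 <- toy_network("CM1")
#' g <- build_g_matrix(cm1$model)
#' enumerate_cutsets(cm1$model, g)
enumerate_cutsets <- function(model, g, target = model$biomass,
                              opts = engine_options()) {
  imodel <- if (inherits(model, "irreversible_model")) model else split_reversible(model)
  out <- empty_cutsets()
  closed <- FALSE
  if (opts$max_solutions == 0L) {
    return(structure(out, class = c("ngmcs_cutsets", class(out)),
                     closed = FALSE, target = target))
  }
  if (max_target_flux(imodel, target) < opts$epsilon) {
    warning("target is already blocked in the wild type; no cut sets to enumerate",
            call. = FALSE)
    return(structure(out, class = c("ngmcs_cutsets", class(out)),
                     closed = TRUE, target = target))
  }
  milp <- build_dual_milp(imodel, g, target, opts)
  cuts <- list()
  accepted_keys <- character(0)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10000L) {
      warning("enumeration stopped by iteration guard", call. = FALSE)
      break
    }
    res <- solve_shortest(imodel, g, target, cuts, opts)
    if (is.null(res$rows)) {
      closed <- res$status == "infeasible"
      if (res$status == "timeout") {
        warning("MILP timed out with no incumbent; enumeration truncated", call. = FALSE)
      }
      break
    }
    elements <- rows_to_elements(g, res$rows)
    key <- cutset_key(elements)
    superseded <- key %in% accepted_keys ||
      any(vapply(out$elements, function(e) all(e %in% elements), logical(1)))
    if (superseded) {
      # same or dominated element set reached through another row
      # selection: exclude that selection and continue
      cuts <- c(cuts, list(selection_cut(milp, res$rows)))
      next
    }
    cs <- verify_cutset(imodel, g, elements, target, opts$epsilon)
    if (cs$verified_cut && cs$verified_minimal) {
      out <- dplyr::bind_rows(out, cs)
      accepted_keys <- c(accepted_keys, key)
      cuts <- c(cuts, list(element_cut(milp, g, elements)))
      if (nrow(out) >= opts$max_solutions) break
    } else if (cs$verified_cut) {
      # a cut but not minimal (e.g. timeout incumbent): its supersets
      # are non-minimal too, so an element cut is safe
      cuts <- c(cuts, list(element_cut(milp, g, elements)))
    } else {
      # not even a cut (big-M artifact): exclude only this selection
      cuts <- c(cuts, list(selection_cut(milp, res$rows)))
    }
  }
  ord <- order(out$size, vapply(out$elements, paste, character(1), collapse = ";"),
               method = "radix")
  out <- out[ord, ]
  structure(out, class = c("ngmcs_cutsets", class(out)),
            closed = closed, target = target)
}

#' Exhaustive cut-set enumeration (test oracle)
#'
#' Enumerates element sets arising from every subset of G-matrix rows in
#' order of increasing cardinality, testing each by an LP blocking check
#' (direct GPR evaluation, independent of the duality encoding). Being
#' exponential in the row count it refuses more than `max_rows` rows and
#' exists as the ground truth against which the MILP engine is checked
#' on small fixtures.
#'
#' @param model a `metabolic_model` with its medium applied.
#' @param g a `g_matrix`.
#' @param target reaction identifier; defaults to the biomass reaction.
#' @param max_size largest cut-set cardinality to report.
#' @param epsilon flux tolerance.
#' @param max_rows guard on the row count.
#' @return tibble of class `ngmcs_cutsets` (all rows verified), ordered
#'   by size then lexicographically.
#' @export
brute_force_cutsets <- function(model, g, target = model$biomass,
                                max_size = Inf, epsilon = 1e-6,
                                max_rows = 20L) {
  r <- nrow(g)
  if (r > max_rows) {
    stop("brute_force_cutsets refuses ", r, " G-matrix rows (guard ", max_rows, ")",
         call. = FALSE)
  }
  out <- empty_cutsets()
  if (max_size >= 1 && r > 0L && max_target_flux(model, target) >= epsilon) {
    universe <- sort(unique(unlist(g$members)), method = "radix")
    nu <- length(universe)
    row_mask <- vapply(g$members, function(mm) {
      sum(bitwShiftL(1, match(mm, universe) - 1L))
    }, numeric(1))
    # union of member masks over every row subset, by dropping-lowest-bit DP
    n_sub <- 2^r
    union_mask <- numeric(n_sub)
    if (r > 0L) {
      for (s in seq_len(n_sub - 1L)) {
        low <- bitwAnd(s, -s)
        union_mask[s + 1L] <- bitwOr(union_mask[bitwXor(s, low) + 1L],
                                     row_mask[which(bitwAnd(s, bitwShiftL(1, seq_len(r) - 1L)) != 0)[1L]])
      }
    }
    masks <- unique(union_mask[-1L])
    sizes <- vapply(masks, function(mk) {
      sum(bitwAnd(bitwShiftR(mk, seq_len(nu) - 1L), 1) == 1)
    }, numeric(1))
    keep <- sizes <= max_size
    masks <- masks[keep]
    sizes <- sizes[keep]
    mask_elems <- lapply(masks, function(mk) {
      universe[bitwAnd(bitwShiftR(mk, seq_len(nu) - 1L), 1) == 1]
    })
    ord <- order(sizes, vapply(mask_elems, paste, character(1), collapse = ";"),
                 method = "radix")
    masks <- masks[ord]
    mask_elems <- mask_elems[ord]
    found_masks <- numeric(0)
    for (k in seq_along(masks)) {
      mk <- masks[k]
      if (any(bitwAnd(found_masks, mk) == found_masks)) next # contains a found cut
      elements <- mask_elems[[k]]
      parts <- resolve_elements(model, g, elements)
      ko <- disabled_reactions(model, parts$genes, parts$exchanges)
      if (max_target_flux(model, target, ko) < epsilon) {
        found_masks <- c(found_masks, mk)
        out <- dplyr::bind_rows(out, cutset_row(elements, parts$genes,
                                                parts$nutrients, TRUE, TRUE))
      }
    }
  }
  structure(out, class = c("ngmcs_cutsets", class(out)),
            closed = TRUE, target = target)
}

#' @export
print.ngmcs_cutsets <- function(x, ...) {
  cat(sprintf("<ngmcs_cutsets> %d cut sets (%d gMCS, %d ngMCS) for target %s%s\n",
              nrow(x), sum(x$classification == "gMCS"),
              sum(x$classification == "ngMCS"),
              attr(x, "target") %||% "?",
              if (isTRUE(attr(x, "closed"))) "; enumeration closed" else ""))
  NextMethod()
}

#' Canonical element-set keys of a cut-set table
#'
#' @param cutsets a cut-set tibble.
#' @return character vector, one `;`-joined sorted key per cut set.
#' @export
cutset_keys <- function(cutsets) {
  vapply(cutsets$elements, function(e) paste(sort(e, method = "radix"), collapse = ";"), character(1))
}
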