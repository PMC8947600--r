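# Fixture networks.
#
# toy_network() reconstructs the didactic two-medium example network:
# one carbon source M1 feeding the growth precursor C through two
# redundant branches (r1/r3 and r2/r4), with a second medium adding an
# alternative, gene-less route from a second nutrient M2. The drawing it
# derives from fixes the species counts and every lethality statement but
# not the coefficients; all coefficients are 1, the smallest consistent
# choice. random_network() produces small growing models with random
# AND/OR GPRs for property testing.

#' The two-medium toy network
#'
#' Under CM1 (only nutrient M1) the gene pairs behave as: `{g3}` and
#' `{g1, g2}` are the minimal gene cut sets; under CM2 (M1 and M2) the
#' gene-less route r5 from M2 rescues every purely genetic knockout.
#'
#' @param medium_id `"CM1"` or `"CM2"`.
#' @param uptake maximal uptake per nutrient (mmol/gDW/h).
#' @return list with elements `model` (a `metabolic_model`, medium already
#'   applied) and `medium` (the medium tibble).
#' @export
#' @examples
#' cm1 <- toy_network("CM1")
#' max_target_flux(cm1$model)
toy_network <- function(medium_id = c("CM1", "CM2"), uptake = 10) {
  medium_id <- match.arg(medium_id)
  mets <- tibble::tibble(
    id = c("M1", "A", "B", "C"),
    name = c("nutrient M1", "intermediate A", "intermediate B", "growth precursor C"),
    compartment = c("e", "c", "c", "c")
  )
  rxns <- tibble::tibble(
    id = c("r_E1", "r1", "r2", "r3", "r4", "r_BM"),
    lower_bound = c(-BIG_BOUND, 0, 0, 0, 0, 0),
    upper_bound = BIG_BOUND,
    gpr_string = c("", "g1", "g2", "g3", "g3", "")
  )
  st <- tibble::tribble(
    ~reaction_id, ~metabolite_id, ~coefficient,
    "r_E1", "M1", -1,
    "r1", "M1", -1, "r1", "A", 1,
    "r2", "M1", -1, "r2", "B", 1,
    "r3", "A", -1, "r3", "C", 1,
    "r4", "B", -1, "r4", "C", 1,
    "r_BM", "C", -1
  )
  if (medium_id == "CM2") {
    mets <- dplyr::bind_rows(mets, tibble::tibble(
      id = "M2", name = "nutrient M2", compartment = "e"
    ))
    rxns <- dplyr::bind_rows(rxns, tibble::tibble(
      id = c("r_E2", "r5"),
      lower_bound = c(-BIG_BOUND, 0),
      upper_bound = BIG_BOUND,
      gpr_string = c("", "")
    ))
    st <- dplyr::bind_rows(st, tibble::tribble(
      ~reaction_id, ~metabolite_id, ~coefficient,
      "r_E2", "M2", -1,
      "r5", "M2", -1, "r5", "C", 1
    ))
  }
  med <- if (medium_id == "CM1") {
    medium("M1", "r_E1", uptake)
  } else {
    medium(c("M1", "M2"), c("r_E1", "r_E2"), uptake)
  }
  model <- metabolic_model(mets, rxns, st, biomass = "r_BM")
  model <- apply_medium(model, med)
  list(model = model, medium = med)
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_gpr <- function(gene_pool, max_genes = 3L) {
  k <- sample.int(max_genes, 1L)
  genes <- sample(gene_pool, min(k, length(gene_pool)))
  if (length(genes) == 1L) return(genes)
  op <- sample(c(" and ", " or "), 1L)
  if (length(genes) == 3L && stats::runif(1) < 0.5) {
    inner_op <- if (op == " and ") " or " else " and "
    return(paste0(genes[1L], op, "(", genes[2L], inner_op, genes[3L], ")"))
  }
  paste(genes, collapse = op)
}

#' Generate a random small metabolic network
#'
#' Builds a connected, growing model: a few nutrients with input
#' exchanges, branching linear pathways converging on a growth precursor,
#' random AND/OR GPRs drawn from a shared gene pool (so pathways share
#' genes and non-trivial cut sets arise), and a demand reaction as the
#' biomass target. Deterministic for a given seed; regenerated (up to a
#' retry cap) if the knockable-unit count exceeds `max_units` or the
#' model fails to grow.
#'
#' @param seed integer RNG seed.
#' @param n_nutrients number of nutrients (each with its input exchange).
#' @param n_pathways number of pathways from nutrients to the precursor.
#' @param max_len maximal pathway length (internal reactions).
#' @param gene_pool_size size of the shared gene pool.
#' @param gpr_max_genes maximal genes per reaction GPR.
#' @param max_units cap on knockable units (G-matrix gene rows plus
#'   nutrient rows).
#' @param p_geneless probability that an internal reaction has no gene
#'   association.
#' @param p_reversible probability that an internal reaction is reversible.
#' @param uptake maximal uptake per nutrient.
#' @param retries regeneration attempts before giving up.
#' @return list with `model` (medium applied) and `medium`, as in
#'   [toy_network()].
#' @export
random_network <- function(seed, n_nutrients = 2L, n_pathways = 3L, max_len = 3L,
                           gene_pool_size = 6L, gpr_max_genes = 3L,
                           max_units = 12L, p_geneless = 0.15,
                           p_reversible = 0.15, uptake = 10, retries = 25L) {
  with_preserved_seed(seed, {
    for (attempt in seq_len(retries)) {
      genes <- paste0("g", seq_len(gene_pool_size))
      mets <- tibble::tibble(id = paste0("N", seq_len(n_nutrients)),
                             name = paste0("nutrient N", seq_len(n_nutrients)),
                             compartment = "e")
      rxns <- tibble::tibble(
        id = paste0("EX_N", seq_len(n_nutrients)),
        lower_bound = -BIG_BOUND, upper_bound = BIG_BOUND, gpr_string = ""
      )
      st <- tibble::tibble(reaction_id = rxns$id,
                           metabolite_id = mets$id,
                           coefficient = -1)
      mets <- dplyr::bind_rows(mets, tibble::tibble(
        id = "P", name = "growth precursor", compartment = "c"
      ))
      mk <- 0L
      for (p in seq_len(n_pathways)) {
        src <- paste0("N", sample.int(n_nutrients, 1L))
        len <- sample.int(max_len, 1L)
        chain <- src
        if (len > 1L) {
          new_mets <- paste0("X", mk + seq_len(len - 1L))
          mk <- mk + len - 1L
          mets <- dplyr::bind_rows(mets, tibble::tibble(
            id = new_mets, name = new_mets, compartment = "c"
          ))
          chain <- c(chain, new_mets)
        }
        chain <- c(chain, "P")
        for (s in seq_len(length(chain) - 1L)) {
          rid <- paste0("r_p", p, "_", s)
          gpr <- if (stats::runif(1) < p_geneless) "" else random_gpr(genes, gpr_max_genes)
          lb <- if (stats::runif(1) < p_reversible) -BIG_BOUND else 0
          rxns <- dplyr::bind_rows(rxns, tibble::tibble(
            id = rid, lower_bound = lb, upper_bound = BIG_BOUND, gpr_string = gpr
          ))
          st <- dplyr::bind_rows(st, tibble::tibble(
            reaction_id = rid,
            metabolite_id = c(chain[s], chain[s + 1L]),
            coefficient = c(-1, 1)
          ))
        }
      }
      rxns <- dplyr::bind_rows(rxns, tibble::tibble(
        id = "r_BM", lower_bound = 0, upper_bound = BIG_BOUND, gpr_string = ""
      ))
      st <- dplyr::bind_rows(st, tibble::tibble(
        reaction_id = "r_BM", metabolite_id = "P", coefficient = -1
      ))
      med <- medium(paste0("N", seq_len(n_nutrients)),
                    paste0("EX_N", seq_len(n_nutrients)), uptake)
      model <- metabolic_model(mets, rxns, st, biomass = "r_BM",
                               genes = genes)
      model <- apply_medium(model, med)
      g <- build_g_matrix(model)
      n_units <- nrow(g) + n_nutrients
      if (n_units > max_units) next
      if (max_target_flux(model) < 1e-6) next
      return(list(model = model, medium = med))
    }
    stop("random_network: could not generate a growing model within ",
         retries, " attempts (seed ", seed, ")", call. = FALSE)
  })
}
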