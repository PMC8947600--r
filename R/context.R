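# Context-specific essentiality.
#
# Cut sets are structural properties of the network under a medium;
# mapping expression data onto them gives context-specific calls: a gene
# or nutrient is essential for a sample when it is the only active
# element in at least one cut set (gene active = expression at or above
# the TPM threshold; nutrient active = present in the medium). Expression
# is a proxy for enzyme activity, with 1 TPM as the default activity
# threshold.

#' Build an activity context from expression and nutrient presence
#'
#' @param expression numeric gene x sample matrix of TPM values, or a
#'   data frame whose first column is the gene identifier.
#' @param threshold TPM below which a gene counts as inactive (default 1).
#' @param nutrient_presence logical nutrient x sample matrix; when `NULL`
#'   it is derived from `med`: every listed nutrient present in every
#'   sample (the global-medium default).
#' @param med optional medium tibble used to derive `nutrient_presence`.
#' @return an `activity_context` object.
#' @export
activity_context <- function(expression, threshold = 1,
                             nutrient_presence = NULL, med = NULL) {
  if (is.data.frame(expression)) {
    genes <- as.character(expression[[1L]])
    expression <- as.matrix(expression[, -1L, drop = FALSE])
    rownames(expression) <- genes
  }
  storage.mode(expression) <- "double"
  if (any(expression < 0, na.rm = TRUE)) {
    stop("TPM values must be non-negative", call. = FALSE)
  }
  if (is.null(colnames(expression))) {
    stop("expression matrix must have sample names as columns", call. = FALSE)
  }
  samples <- colnames(expression)
  if (is.null(nutrient_presence)) {
    nuts <- if (is.null(med)) character(0) else med$metabolite_id
    nutrient_presence <- matrix(TRUE, length(nuts), length(samples),
                                dimnames = list(nuts, samples))
  } else {
    nutrient_presence <- as.matrix(nutrient_presence)
    storage.mode(nutrient_presence) <- "logical"
    if (!identical(colnames(nutrient_presence), samples)) {
      nutrient_presence <- nutrient_presence[, samples, drop = FALSE]
    }
  }
  stopifnot(threshold >= 0)
  structure(
    list(expression = expression, threshold = threshold,
         nutrient_presence = nutrient_presence),
    class = "activity_context"
  )
}

#' @export
print.activity_context <- function(x, ...) {
  cat(sprintf(
    "<activity_context> %d genes x %d samples (threshold %g TPM), %d nutrients tracked\n",
    nrow(x$expression), ncol(x$expression), x$threshold, nrow(x$nutrient_presence)
  ))
  invisible(x)
}

#' Read an expression TSV (genes x samples, TPM)
#'
#' First column is the gene identifier, remaining columns are samples.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(tb) < 2L) {
    stop("expression file '", path, "' needs a gene column plus at least one sample",
         call. = FALSE)
  }
  vals <- as.matrix(tb[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tb[-1L], is.numeric, logical(1)))[1L] + 1L
    stop("expression file '", path, "': column ", bad, " is not numeric", call. = FALSE)
  }
  rownames(vals) <- as.character(tb[[1L]])
  vals
}

# activity of each element of a cut set in one sample; genes missing from
# the expression matrix are conservatively treated as active
element_activity <- function(context, genes, nutrients, sample) {
  ex <- context$expression
  ga <- vapply(genes, function(g) {
    if (!g %in% rownames(ex)) return(TRUE)
    ex[g, sample] >= context$threshold
  }, logical(1))
  np <- context$nutrient_presence
  na_ <- vapply(nutrients, function(n) {
    if (!n %in% rownames(np)) return(TRUE)
    isTRUE(np[n, sample])
  }, logical(1))
  list(genes = ga, nutrients = na_)
}

#' Genes queried by cut sets but absent from the expression matrix
#'
#' These are treated as active in every sample; inspect this report when
#' interpreting essentiality calls.
#'
#' @param cutsets a cut-set tibble.
#' @param context an `activity_context`.
#' @return character vector of gene identifiers.
#' @export
unmeasured_genes <- function(cutsets, context) {
  sort(setdiff(unique(unlist(cutsets$genes)), rownames(context$expression)),
       method = "radix")
}

#' Context-specific essential elements of one sample
#'
#' An element (gene or nutrient) is essential for the sample iff some cut
#' set has every other member inactive while the element itself is
#' active; those cut sets are attached as witnesses.
#'
#' @param cutsets a cut-set tibble (see [enumerate_cutsets()]).
#' @param context an `activity_context`.
#' @param sample sample name (must be a column of the expression matrix).
#' @return tibble with columns `sample`, `element`, `kind`, `essential`,
#'   `witness` (list of witnessing element sets).
#' @export
essential_elements <- function(cutsets, context, sample) {
  if (!sample %in% colnames(context$expression)) {
    stop("sample '", sample, "' not in the activity context", call. = FALSE)
  }
  hits <- list()
  for (i in seq_len(nrow(cutsets))) {
    genes <- cutsets$genes[[i]]
    nutrients <- cutsets$nutrients[[i]]
    act <- element_activity(context, genes, nutrients, sample)
    active <- c(genes[act$genes], nutrients[act$nutrients])
    if (length(active) == 1L) {
      el <- active
      hits[[el]] <- c(hits[[el]], list(cutsets$elements[[i]]))
    }
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(sample = character(0), element = character(0),
                          kind = character(0), essential = logical(0),
                          witness = list()))
  }
  els <- sort(names(hits), method = "radix")
  nut_universe <- unique(unlist(cutsets$nutrients))
  tibble::tibble(
    sample = sample,
    element = els,
    kind = ifelse(els %in% nut_universe, "nutrient", "gene"),
    essential = TRUE,
    witness = unname(hits[els])
  )
}

#' Nutrient dependency (auxotrophy) matrix across samples
#'
#' Entry (nutrient, sample) is 1 iff the essentiality rule calls that
#' nutrient essential for that sample: its genetic backup routes are all
#' below the expression threshold in at least one cut set.
#'
#' @param cutsets a cut-set tibble.
#' @param context an `activity_context`.
#' @return integer 0/1 matrix of class `nutrient_dependency`, nutrients x
#'   samples.
#' @export
nutrient_dependency_matrix <- function(cutsets, context) {
  nuts <- sort(unique(unlist(cutsets$nutrients)), method = "radix")
  samples <- colnames(context$expression)
  M <- matrix(0L, length(nuts), length(samples), dimnames = list(nuts, samples))
  for (s in samples) {
    calls <- essential_elements(cutsets, context, s)
    ess <- calls$element[calls$kind == "nutrient"]
    M[intersect(ess, nuts), s] <- 1L
  }
  class(M) <- c("nutrient_dependency", class(M))
  M
}

#' Write a nutrient dependency matrix as TSV
#'
#' One row per nutrient, one 0/1 column per sample.
#'
#' @param M a `nutrient_dependency` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dependency_matrix <- function(M, path) {
  tb <- tibble::as_tibble(unclass(M), rownames = "nutrient")
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Most limiting gene for a nutrient dependency
#'
#' Within each cut set containing the nutrient, the best genetic backup
#' is the partner gene with the highest expression; across cut sets the
#' nutrient's limiting value is the maximum of those per-set values (the
#' strongest backup route). The sample is auxotrophic for the nutrient
#' when this value falls below the threshold. A cut set with no partner
#' genes contributes 0 (no genetic backup).
#'
#' @param cutsets a cut-set tibble.
#' @param nutrient nutrient identifier; must occur in some cut set.
#' @param context an `activity_context`.
#' @param sample sample name.
#' @return one-row tibble with `nutrient`, `sample`, `gene` (the gene
#'   realising the limiting value, `NA` if there is no genetic backup)
#'   and `tpm` (the limiting expression; unmeasured genes count as
#'   `Inf`, i.e. assumed active).
#' @export
limiting_gene <- function(cutsets, nutrient, context, sample) {
  idx <- which(vapply(cutsets$nutrients, function(n) nutrient %in% n, logical(1)))
  if (length(idx) == 0L) {
    stop("nutrient '", nutrient, "' occurs in no cut set", call. = FALSE)
  }
  ex <- context$expression
  best_gene <- NA_character_
  best_tpm <- 0
  for (i in idx) {
    partners <- cutsets$genes[[i]]
    if (length(partners) == 0L) next
    tpms <- vapply(partners, function(g) {
      if (!g %in% rownames(ex)) Inf else ex[g, sample]
    }, numeric(1))
    k <- which.max(tpms)
    if (tpms[[k]] > best_tpm) {
      best_tpm <- tpms[[k]]
      best_gene <- partners[k]
    }
  }
  tibble::tibble(nutrient = nutrient, sample = sample,
                 gene = best_gene, tpm = best_tpm)
}

#' Read a linked-knockout configuration TSV
#'
#' Expected header: `gene_id  reaction_id`; multiple rows per gene allowed.
#'
#' @param path file path.
#' @return named list mapping gene id to character vector of reaction ids.
#' @export
read_linked_knockouts <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("gene_id", "reaction_id") %in% names(tb))) {
    stop("linked-knockout file '", path,
         "' must have columns gene_id and reaction_id", call. = FALSE)
  }
  split(tb$reaction_id, tb$gene_id)
}

#' Knock out a gene together with regulatorily linked reactions
#'
#' Zeroes the bounds of every reaction disabled by the gene's loss (via
#' GPR evaluation) plus any additional reactions linked to it, modelling
#' indirect inhibition that the GPRs do not carry (e.g. metabolite
#' accumulation shutting down downstream enzymes). Use before a cut-set
#' search when such regulatory couplings are part of the biology being
#' modelled.
#'
#' @param model a `metabolic_model`.
#' @param gene gene identifier to knock out.
#' @param links named list mapping gene ids to additional reaction ids
#'   (as from [read_linked_knockouts()]); entries for other genes are
#'   ignored.
#' @return the model with the affected reaction bounds set to zero.
#' @export
apply_linked_knockouts <- function(model, gene, links = list()) {
  extra <- links[[gene]] %||% character(0)
  unknown <- setdiff(extra, model$reactions$id)
  if (length(unknown) > 0L) {
    stop("linked knockout references unknown reaction: ", unknown[1L], call. = FALSE)
  }
  ko <- union(disabled_reactions(model, genes = gene), extra)
  i <- model$reactions$id %in% ko
  model$reactions$lower_bound[i] <- 0
  model$reactions$upper_bound[i] <- 0
  model
}

#' Encode linked knockouts into the GPRs before a cut-set search
#'
#' For each linked pair the reaction's GPR is AND-ed with the gene, so
#' that losing the gene disables the linked reaction everywhere: in the
#' G matrix, in verification and in the brute-force oracle alike. Use
#' this instead of [apply_linked_knockouts()] when the gene is part of
#' the search space rather than knocked up front.
#'
#' @param model a `metabolic_model`.
#' @param links named list mapping gene ids to reaction ids.
#' @return the model with augmented GPRs.
#' @export
link_gene_reactions <- function(model, links) {
  for (gene in names(links)) {
    for (rid in links[[gene]]) {
      i <- reaction_row(model, rid)
      old <- model$reactions$gpr[[i]]
      new <- if (is_gpr_true(old)) gpr_gene(gene) else gpr_node("and", list(old, gpr_gene(gene)))
      model$reactions$gpr[[i]] <- new
      model$reactions$gpr_string[i] <- gpr_to_string(new)
    }
  }
  model$genes <- sort(unique(c(model$genes, names(links))), method = "radix")
  validate_model(model)
  model
}
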