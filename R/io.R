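# Result serialisation: JSON-lines for programmatic use, TSV mirrors in
# the layout of the supplementary-table style (one row per cut set,
# ;-joined elements).

#' Write cut sets as JSON-lines
#'
#' One JSON object per line with fields `elements`, `genes`, `nutrients`,
#' `classification`, `size`, `verified_cut`, `verified_minimal`.
#'
#' @param cutsets a cut-set tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cutsets <- function(cutsets, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(cutsets))) {
    rec <- list(
      elements = cutsets$elements[[i]],
      genes = cutsets$genes[[i]],
      nutrients = cutsets$nutrients[[i]],
      classification = cutsets$classification[i],
      size = cutsets$size[i],
      verified_cut = cutsets$verified_cut[i],
      verified_minimal = cutsets$verified_minimal[i]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read cut sets written by [write_cutsets()]
#'
#' @param path JSON-lines path.
#' @return a cut-set tibble of class `ngmcs_cutsets`.
#' @export
read_cutsets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- empty_cutsets()
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    out <- dplyr::bind_rows(out, cutset_row(
      as.character(rec$elements),
      as.character(rec$genes),
      as.character(rec$nutrients),
      isTRUE(rec$verified_cut),
      isTRUE(rec$verified_minimal)
    ))
  }
  structure(out, class = c("ngmcs_cutsets", class(out)), closed = NA, target = NA)
}

#' Write the TSV mirror of a cut-set table
#'
#' @param cutsets a cut-set tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cutsets_tsv <- function(cutsets, path) {
  tb <- tibble::tibble(
    id = seq_len(nrow(cutsets)),
    classification = cutsets$classification,
    size = cutsets$size,
    elements = vapply(cutsets$elements, paste, character(1), collapse = ";"),
    genes = vapply(cutsets$genes, paste, character(1), collapse = ";"),
    nutrients = vapply(cutsets$nutrients, paste, character(1), collapse = ";"),
    verified_cut = cutsets$verified_cut,
    verified_minimal = cutsets$verified_minimal
  )
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Write essentiality calls as JSON-lines
#'
#' @param calls tibble from [essential_elements()] (possibly several
#'   samples bound together).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_essentiality <- function(calls, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(calls))) {
    rec <- list(
      sample = calls$sample[i],
      element = calls$element[i],
      kind = calls$kind[i],
      essential = calls$essential[i],
      witness = calls$witness[[i]]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
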