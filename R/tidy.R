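# Tidy and plotting methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cut-set enumeration result
#'
#' @param x an `ngmcs_cutsets` tibble.
#' @param ... unused.
#' @return a plain tibble, one row per cut set, with `;`-joined element
#'   strings instead of list-columns.
#' @export
tidy.ngmcs_cutsets <- function(x, ...) {
  tibble::tibble(
    cutset = cutset_keys(x),
    classification = x$classification,
    size = x$size,
    n_genes = lengths(x$genes),
    n_nutrients = lengths(x$nutrients),
    verified_cut = x$verified_cut,
    verified_minimal = x$verified_minimal
  )
}

#' One-row summary of a cut-set enumeration
#'
#' @param x an `ngmcs_cutsets` tibble.
#' @param ... unused.
#' @return tibble with counts by classification, the size range, and
#'   whether enumeration closed (proven complete within its limits).
#' @export
glance.ngmcs_cutsets <- function(x, ...) {
  tibble::tibble(
    n_cutsets = nrow(x),
    n_gmcs = sum(x$classification == "gMCS"),
    n_ngmcs = sum(x$classification == "ngMCS"),
    min_size = if (nrow(x)) min(x$size) else NA_integer_,
    max_size = if (nrow(x)) max(x$size) else NA_integer_,
    closed = isTRUE(attr(x, "closed"))
  )
}

#' Bar chart of cut-set sizes by classification
#'
#' @param object an `ngmcs_cutsets` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ngmcs_cutsets <- function(object, ...) {
  df <- tidy.ngmcs_cutsets(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$size), fill = .data$classification)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "cut-set size (elements)", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a nutrient dependency matrix
#'
#' @param object a `nutrient_dependency` matrix.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nutrient_dependency <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object), rownames = "nutrient")
  df <- tidyr::pivot_longer(df, -"nutrient", names_to = "sample",
                            values_to = "essential")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$nutrient,
                                   fill = factor(.data$essential))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "firebrick"),
                               name = "essential") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
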