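#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Turn a conceptlit object into a tidy tibble
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a conceptlit object
#' @param x object to summarize.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy a compiled dictionary into its entry table
#' @param x a `compiled_dictionary`.
#' @param ... unused.
#' @return the entries tibble (`surface_form`, `concept_id`, `vocabulary`,
#'   `case_class`, `match_tokens`, `key`).
#' @export
tidy.compiled_dictionary <- function(x, ...) x$entries

#' One-row summary of a compiled dictionary
#' @param x a `compiled_dictionary`.
#' @param ... unused.
#' @export
glance.compiled_dictionary <- function(x, ...) {
  tibble::tibble(
    vocabulary = x$vocabulary,
    n_entries = nrow(x$entries),
    n_sensitive = sum(x$entries$case_class == "sensitive"),
    n_concepts = length(unique(x$entries$concept_id)),
    n_hierarchy = length(x$descendants_index)
  )
}

#' Tidy an inverted index into per-document statistics
#' @param x an `inverted_index`.
#' @param ... unused.
#' @export
tidy.inverted_index <- function(x, ...) {
  pmids <- names(x$doc_lengths)
  tibble::tibble(
    pmid = as.integer(pmids),
    doc_length = unname(x$doc_lengths),
    pub_year = unname(x$doc_years[pmids])
  )
}

#' One-row summary of an inverted index
#' @param x an `inverted_index`.
#' @param ... unused.
#' @export
glance.inverted_index <- function(x, ...) {
  tibble::tibble(
    n_docs = x$n_docs,
    n_text_tokens = length(ls(x$text)),
    n_concepts = length(ls(x$concepts))
  )
}

#' Plot facet counts as per-vocabulary bars
#'
#' Mirrors the tabbed filters zone of a curation interface: for each
#' vocabulary, the concepts that would refine the current result set, sized
#' by their predicted post-filter result counts.
#'
#' @param facets facet tibble from [evaluate()] or [facet_counts()].
#' @param top_n bars shown per vocabulary.
#' @return a ggplot object.
#' @export
plot_facets <- function(facets, top_n = 10) {
  dat <- facets |>
    dplyr::group_by(.data$vocabulary) |>
    dplyr::slice_max(.data$count, n = top_n, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$count,
    y = stats::reorder(.data$concept_id, .data$count)
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$vocabulary), scales = "free_y") +
    ggplot2::labs(x = "predicted result count", y = NULL)
}

#' Plot a ranked result list
#'
#' Relevance scores against publication year, one point per article — a
#' quick view of whether high-ranking literature is recent.
#'
#' @param object result tibble from [evaluate()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.conceptlit_results <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pub_year, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "publication year", y = "relevance score")
}
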