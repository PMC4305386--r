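#' Build an inverted index over a tagged corpus
#'
#' Text postings are built over the lowercased, stemmed tokens of title and
#' abstract (term frequency per document); concept postings over the
#' annotation tibble (occurrence count per document). Document token counts
#' and publication years are recorded for scoring and date filtering.
#'
#' @param annotations annotation tibble from [tag_corpus()].
#' @param articles article tibble; every annotated PMID must be present.
#' @return an `inverted_index` object.
#' @export
build_index <- function(annotations, articles) {
  missing <- setdiff(unique(annotations$pmid), articles$pmid)
  if (length(missing)) {
    stop("annotated PMID without a stored article: ", missing[1], call. = FALSE)
  }
  idx <- new.env(parent = emptyenv())
  idx$text <- new.env(parent = emptyenv())
  idx$concepts <- new.env(parent = emptyenv())
  idx$concept_vocab <- new.env(parent = emptyenv())
  n <- nrow(articles)
  pmids <- as.character(articles$pmid)
  doc_lengths <- integer(n)
  for (i in seq_len(n)) {
    toks <- c(tokenize_text(articles$title[i]), tokenize_text(articles$abstract[i]))
    doc_lengths[i] <- length(toks)
    if (length(toks)) {
      tf <- table(stem_token(tolower(toks)))
      for (t in names(tf)) {
        idx$text[[t]] <- c(idx$text[[t]],
                           stats::setNames(as.integer(tf[[t]]), pmids[i]))
      }
    }
  }
  if (nrow(annotations)) {
    counts <- annotations |>
      dplyr::count(.data$concept_id, .data$vocabulary, .data$pmid, name = "n")
    for (cid in unique(counts$concept_id)) {
      sub <- counts[counts$concept_id == cid, ]
      idx$concepts[[cid]] <- stats::setNames(sub$n, as.character(sub$pmid))
      idx$concept_vocab[[cid]] <- sub$vocabulary[1]
    }
  }
  idx$doc_lengths <- stats::setNames(doc_lengths, pmids)
  idx$doc_years <- stats::setNames(articles$year, pmids)
  idx$n_docs <- n
  class(idx) <- "inverted_index"
  idx
}

#' @export
print.inverted_index <- function(x, ...) {
  cat("<inverted_index> ", x$n_docs, " documents, ",
      length(ls(x$text)), " text tokens, ",
      length(ls(x$concepts)), " concepts\n", sep = "")
  invisible(x)
}

# ---- query clauses -------------------------------------------------------

new_clause <- function(kind, raw, expansion) {
  stopifnot(length(expansion) > 0)
  structure(list(kind = kind, raw = raw, expansion = expansion),
            class = "query_clause")
}

#' Expand an ontology accession into a concept clause
#'
#' A concept query matches a document tagged with the accession *or any of
#' its is_a descendants*, so a query for a parent term (e.g. a disease
#' category) covers the whole subtree without the curator typing the
#' children.
#'
#' @param accession ontology accession.
#' @param dictionaries a `compiled_dictionary` or list of them; the first
#'   whose hierarchy knows the accession is used.
#' @return a `query_clause` of kind `"concept"`; its expansion always
#'   contains `accession`.
#' @export
expand_concept_clause <- function(accession, dictionaries) {
  if (inherits(dictionaries, "compiled_dictionary")) {
    dictionaries <- list(dictionaries)
  }
  for (d in dictionaries) {
    if (!is.null(d$descendants_index[[accession]])) {
      return(new_clause("concept", accession, descendants(d, accession)))
    }
  }
  stop("accession not in any supplied hierarchy: ", accession, call. = FALSE)
}

#' Expand a gene id into its keyword clause
#'
#' The gene's symbol, name and synonyms are pooled with those of every
#' ortholog and deduplicated case-insensitively. The resulting keywords are
#' matched against text postings (gene mentions are not concept-indexed, so
#' gene search is keyword search).
#'
#' @param gene_id id present in the gene table.
#' @param gene_table tibble from [parse_gene_table()].
#' @return a `query_clause` of kind `"gene"`.
#' @export
expand_gene_clause <- function(gene_id, gene_table) {
  row <- which(gene_table$gene_id == gene_id)
  if (length(row) == 0) stop("unknown gene id: ", gene_id, call. = FALSE)
  collect <- function(i) {
    c(gene_table$symbol[i], gene_table$name[i], gene_table$synonyms[[i]])
  }
  kws <- collect(row)
  for (o in gene_table$ortholog_ids[[row]]) {
    orow <- which(gene_table$gene_id == o)
    if (length(orow) == 0) {
      warning("unknown ortholog id skipped: ", o, call. = FALSE)
      next
    }
    kws <- c(kws, collect(orow))
  }
  kws <- kws[nzchar(kws)]
  kws <- kws[!duplicated(tolower(kws))]
  new_clause("gene", gene_id, kws)
}

#' Free-text keyword clause
#' @param text one or more keywords (any one of them satisfies the clause).
#' @return a `query_clause` of kind `"keyword"`.
#' @export
keyword_clause <- function(text) {
  new_clause("keyword", text[1], text)
}

# ---- query condition -----------------------------------------------------

#' Assemble a query condition
#'
#' Clauses are joined by AND; within a clause the expansion members are
#' joined by OR. A species filter restricts results to documents with an
#' organism annotation for one of the taxa; the filter path holds
#' refinement filters applied in order.
#'
#' @param ... `query_clause` objects.
#' @param species character vector of taxon accessions (empty = no
#'   constraint).
#' @return a `query_condition` object.
#' @export
query_condition <- function(..., species = character()) {
  clauses <- list(...)
  stopifnot(all(vapply(clauses, inherits, logical(1), "query_clause")))
  structure(
    list(clauses = clauses, species_filter = species,
         filter_path = list(), species_explicit = length(species) > 0),
    class = "query_condition"
  )
}

#' Append the default species constraint for gene-driven queries
#'
#' Gene-disease curation targets rat, human and mouse literature, so any
#' condition containing a gene clause gets those three taxa appended —
#' unless the caller set species explicitly.
#'
#' @param condition a `query_condition`.
#' @return the condition, possibly with `species_filter` set.
#' @export
apply_default_species <- function(condition) {
  has_gene <- any(vapply(condition$clauses, function(cl) cl$kind == "gene",
                         logical(1)))
  if (has_gene && !isTRUE(condition$species_explicit)) {
    condition$species_filter <- unname(default_species_taxa())
  }
  condition
}

#' Result-refinement filters
#'
#' A concept filter keeps documents tagged with the concept or any of its
#' descendants; a date filter keeps documents whose publication year falls
#' in the inclusive range.
#'
#' @param concept_id accession to filter on.
#' @return a `result_filter` object.
#' @export
concept_filter <- function(concept_id) {
  structure(list(kind = "concept", concept_id = concept_id),
            class = "result_filter")
}

#' @rdname concept_filter
#' @param from,to inclusive year bounds.
#' @export
date_filter <- function(from, to) {
  stopifnot(from <= to)
  structure(list(kind = "date_range", year_range = c(from, to)),
            class = "result_filter")
}

#' Append a filter to the condition's filter path
#' @param condition a `query_condition`.
#' @param filter a `result_filter`.
#' @return the condition with the filter appended.
#' @export
apply_filter <- function(condition, filter) {
  stopifnot(inherits(filter, "result_filter"))
  condition$filter_path <- c(condition$filter_path, list(filter))
  condition
}

#' Truncate the filter path (remove a node and everything below it)
#' @param condition a `query_condition`.
#' @param keep number of leading filters to keep (0 clears the path).
#' @return the condition with the truncated path.
#' @export
truncate_filters <- function(condition, keep) {
  stopifnot(keep >= 0, keep <= length(condition$filter_path))
  condition$filter_path <- condition$filter_path[seq_len(keep)]
  condition
}

# ---- evaluation ----------------------------------------------------------

concept_docs <- function(index, concept_id) {
  names(index$concepts[[concept_id]])
}

# docs satisfied by a keyword: every stemmed token of the keyword present
keyword_docs <- function(index, keyword) {
  toks <- unique(stem_token(tolower(tokenize_text(keyword))))
  if (length(toks) == 0) return(character())
  sets <- lapply(toks, function(t) names(index$text[[t]]))
  Reduce(intersect, sets)
}

clause_docs <- function(index, clause) {
  if (clause$kind == "concept") {
    docs <- unlist(lapply(clause$expansion, concept_docs, index = index))
  } else {
    docs <- unlist(lapply(clause$expansion, keyword_docs, index = index))
  }
  unique(docs)
}

# closure of a filter concept: descendants when a hierarchy knows it
filter_concept_set <- function(concept_id, dictionaries) {
  if (!is.null(dictionaries)) {
    if (inherits(dictionaries, "compiled_dictionary")) {
      dictionaries <- list(dictionaries)
    }
    for (d in dictionaries) {
      if (!is.null(d$descendants_index[[concept_id]])) {
        return(descendants(d, concept_id))
      }
    }
  }
  concept_id
}

filter_docs <- function(index, filter, dictionaries) {
  if (filter$kind == "concept") {
    ids <- filter_concept_set(filter$concept_id, dictionaries)
    unique(unlist(lapply(ids, concept_docs, index = index)))
  } else {
    yr <- index$doc_years
    names(yr)[!is.na(yr) & yr >= filter$year_range[1] & yr <= filter$year_range[2]]
  }
}

result_doc_set <- function(condition, index, dictionaries = NULL) {
  docs <- names(index$doc_lengths)
  for (cl in condition$clauses) {
    docs <- intersect(docs, clause_docs(index, cl))
  }
  if (length(condition$species_filter)) {
    sp <- unique(unlist(lapply(condition$species_filter, concept_docs,
                               index = index)))
    docs <- intersect(docs, sp)
  }
  for (f in condition$filter_path) {
    docs <- intersect(docs, filter_docs(index, f, dictionaries))
  }
  docs
}

idf <- function(n_docs, df) 1 + log(n_docs / (df + 1))

posting_tf <- function(post, doc) {
  if (is.null(post)) return(NULL)
  v <- post[doc]
  if (is.na(v)) NULL else unname(v)
}

#' Relevance score of one document for a condition
#'
#' Classic TF-IDF with coordination and inverse-square-root length
#' normalization:
#' `coord * sum_t sqrt(tf(t, doc)) * idf(t)^2 / sqrt(doc_length)`, with
#' `idf(t) = 1 + ln(n_docs / (df(t) + 1))` and `coord` the fraction of
#' clauses the document matches. Keyword clauses contribute one summand per
#' distinct matching stemmed token; concept clauses contribute per matching
#' expansion concept, with tf equal to the concept's occurrence count in
#' the document.
#'
#' @param condition a `query_condition`.
#' @param pmid document id (must satisfy the condition).
#' @param index an `inverted_index`.
#' @return a non-negative number.
#' @export
score_document <- function(condition, pmid, index) {
  doc <- as.character(pmid)
  len <- index$doc_lengths[[doc]]
  if (is.null(len) || len == 0) return(0)
  norm <- 1 / sqrt(len)
  total_clauses <- length(condition$clauses)
  if (total_clauses == 0) return(0)
  matched_clauses <- 0L
  s <- 0
  for (cl in condition$clauses) {
    clause_hit <- FALSE
    if (cl$kind == "concept") {
      for (cid in cl$expansion) {
        post <- index$concepts[[cid]]
        tf <- posting_tf(post, doc)
        if (!is.null(tf)) {
          clause_hit <- TRUE
          s <- s + sqrt(tf) * idf(index$n_docs, length(post))^2 * norm
        }
      }
    } else {
      toks <- character()
      for (kw in cl$expansion) {
        kt <- unique(stem_token(tolower(tokenize_text(kw))))
        if (length(kt) && all(vapply(kt, function(t) {
          !is.null(index$text[[t]]) && doc %in% names(index$text[[t]])
        }, logical(1)))) {
          clause_hit <- TRUE
          toks <- c(toks, kt)
        }
      }
      for (t in unique(toks)) {
        post <- index$text[[t]]
        tf <- posting_tf(post, doc)
        if (is.null(tf)) next
        s <- s + sqrt(tf) * idf(index$n_docs, length(post))^2 * norm
      }
    }
    if (clause_hit) matched_clauses <- matched_clauses + 1L
  }
  (matched_clauses / total_clauses) * s
}

# concepts from the query's concept clauses that tag the document,
# with occurrence counts, sorted by count descending then concept id
matched_concepts_for <- function(condition, doc, index) {
  ids <- unique(unlist(lapply(condition$clauses, function(cl) {
    if (cl$kind == "concept") cl$expansion else character()
  })))
  rows <- purrr::compact(lapply(ids, function(cid) {
    tf <- posting_tf(index$concepts[[cid]], doc)
    if (is.null(tf)) NULL else tibble::tibble(concept_id = cid, n = tf)
  }))
  if (length(rows) == 0) {
    return(tibble::tibble(concept_id = character(), n = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$n), .data$concept_id)
}

#' Facet counts over a result set
#'
#' For every concept tagging at least one result document, the count is the
#' number of results that would remain if the concept filter were applied —
#' i.e. documents tagged with the concept or (when a hierarchy knows the
#' concept) any of its descendants. Facets are grouped per vocabulary and
#' the top `top_n` per vocabulary are kept, sorted by count descending then
#' concept id.
#'
#' @param result_pmids character vector of result document ids.
#' @param index an `inverted_index`.
#' @param dictionaries optional dictionaries supplying hierarchies.
#' @param top_n facets kept per vocabulary.
#' @return tibble `vocabulary`, `concept_id`, `count`.
#' @export
facet_counts <- function(result_pmids, index, dictionaries = NULL, top_n = 20) {
  if (length(result_pmids) == 0 || top_n <= 0) {
    return(tibble::tibble(vocabulary = character(), concept_id = character(),
                          count = integer()))
  }
  concepts <- ls(index$concepts)
  rows <- purrr::compact(lapply(concepts, function(cid) {
    direct <- intersect(names(index$concepts[[cid]]), result_pmids)
    if (length(direct) == 0) return(NULL)
    ids <- filter_concept_set(cid, dictionaries)
    n <- if (length(ids) > 1) {
      length(intersect(
        unique(unlist(lapply(ids, concept_docs, index = index))),
        result_pmids
      ))
    } else {
      length(direct)
    }
    tibble::tibble(vocabulary = index$concept_vocab[[cid]],
                   concept_id = cid, count = n)
  }))
  if (length(rows) == 0) {
    return(tibble::tibble(vocabulary = character(), concept_id = character(),
                          count = integer()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$concept_id) |>
    dplyr::group_by(.data$vocabulary) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup()
}

#' Evaluate a query condition
#'
#' Returns the documents satisfying every clause (any expansion member
#' satisfies its clause), intersected with the species constraint and every
#' filter on the filter path, ranked by relevance, together with the facet
#' counts computed on the final result set.
#'
#' @param condition a `query_condition` (clauses already expanded).
#' @param index an `inverted_index`.
#' @param dictionaries optional dictionaries supplying hierarchies for
#'   concept filters and facet prediction.
#' @param facet_top_n facets kept per vocabulary.
#' @return list with `results` (tibble `pmid`, `score`, `pub_year`,
#'   `matched_concepts` list-column, relevance-sorted) and `facets` (tibble
#'   from [facet_counts()]).
#' @export
evaluate <- function(condition, index, dictionaries = NULL, facet_top_n = 20) {
  docs <- result_doc_set(condition, index, dictionaries)
  if (length(docs) == 0) {
    results <- tibble::tibble(pmid = integer(), score = numeric(),
                              pub_year = integer(), matched_concepts = list())
  } else {
    results <- tibble::tibble(
      pmid = as.integer(docs),
      score = vapply(docs, function(d) score_document(condition, d, index),
                     numeric(1)),
      pub_year = unname(index$doc_years[docs]),
      matched_concepts = lapply(docs, matched_concepts_for,
                                condition = condition, index = index)
    )
    results <- sort_results(results, "relevance")
  }
  class(results) <- c("conceptlit_results", class(results))
  list(results = results,
       facets = facet_counts(docs, index, dictionaries, facet_top_n))
}

#' Number of documents a condition would return
#'
#' The result-set size without ranking or facet computation — the quantity a
#' filter hyperlink displays before the filter is applied.
#'
#' @inheritParams evaluate
#' @return a non-negative integer.
#' @export
result_count <- function(condition, index, dictionaries = NULL) {
  length(result_doc_set(condition, index, dictionaries))
}

#' Sort a result tibble
#'
#' `relevance`: score descending, ties by PMID descending. `pub_date`: year
#' descending, ties by PMID descending. `pmid`: PMID descending. Descending
#' PMID favors recently assigned identifiers, i.e. recent literature.
#'
#' @param results result tibble from [evaluate()].
#' @param order `"relevance"`, `"pub_date"` or `"pmid"`.
#' @return the sorted tibble.
#' @export
sort_results <- function(results, order = c("relevance", "pub_date", "pmid")) {
  order <- match.arg(order)
  switch(order,
    relevance = dplyr::arrange(results, dplyr::desc(.data$score),
                               dplyr::desc(.data$pmid)),
    pub_date = dplyr::arrange(results, dplyr::desc(.data$pub_year),
                              dplyr::desc(.data$pmid)),
    pmid = dplyr::arrange(results, dplyr::desc(.data$pmid))
  )
}
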