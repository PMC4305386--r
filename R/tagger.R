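#' Tokenize a text field into offset-anchored tokens
#'
#' Tokens are maximal runs of ASCII letters and digits; every other
#' character (hyphens, slashes, punctuation, whitespace) separates tokens.
#' Offsets are 0-based, half-open character positions into the original
#' string, so `substr(text, start + 1, end)` recovers each token.
#'
#' @param field_text a single string.
#' @return tibble with columns `text`, `start`, `end`.
#' @export
tokenize <- function(field_text) {
  stopifnot(length(field_text) == 1)
  if (is.na(field_text) || !nzchar(field_text)) {
    return(tibble::tibble(text = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[A-Za-z0-9]+", field_text)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(text = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tibble::tibble(
    text = regmatches(field_text, gregexpr("[A-Za-z0-9]+", field_text))[[1]],
    start = start,
    end = start + len
  )
}

empty_annotations <- function() {
  tibble::tibble(
    pmid = integer(), concept_id = character(), vocabulary = character(),
    field = character(), start = integer(), end = integer(),
    matched_text = character()
  )
}

# Leftmost-longest gazetteer scan of one field against one dictionary.
# Sensitive entries are compared against verbatim tokens, insensitive entries
# against lowercased stems; the longest window at a position wins (both case
# classes may fire at the same length) and the scan resumes after it, so
# overlapping shorter matches within one vocabulary are suppressed.
scan_field <- function(pmid, field, field_text, dictionary) {
  toks <- tokenize(field_text)
  n <- nrow(toks)
  if (n == 0) return(empty_annotations())
  verbatim <- toks$text
  folded <- stem_token(tolower(toks$text))
  lookup <- dictionary$lookup
  max_len <- dictionary$max_tokens
  out <- list()
  i <- 1L
  while (i <= n) {
    hit_idx <- integer()
    hit_len <- 0L
    for (L in seq(min(max_len, n - i + 1L), 1L)) {
      j <- i + L - 1L
      ks <- match_key(verbatim[i:j])
      ki <- match_key(folded[i:j])
      idx <- c(lookup$sensitive[[ks]], lookup$insensitive[[ki]])
      if (length(idx)) {
        hit_idx <- idx
        hit_len <- L
        break
      }
    }
    if (hit_len > 0L) {
      j <- i + hit_len - 1L
      s <- toks$start[i]
      e <- toks$end[j]
      ids <- unique(dictionary$entries$concept_id[hit_idx])
      out[[length(out) + 1L]] <- tibble::tibble(
        pmid = pmid, concept_id = ids, vocabulary = dictionary$vocabulary,
        field = field, start = s, end = e,
        matched_text = substr(field_text, s + 1L, e)
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) empty_annotations() else dplyr::bind_rows(out)
}

scan_record <- function(record, dictionary, fields) {
  pmid <- record$pmid[[1]]
  dplyr::bind_rows(purrr::map(fields, function(f) {
    scan_field(pmid, f, article_field_text(record, f), dictionary)
  }))
}

#' Tag an article with ontology concepts
#'
#' Runs the two-gazetteer dictionary scan over the title, abstract and MeSH
#' fields for every supplied dictionary. Matches from different vocabularies
#' may overlap freely; within one vocabulary the leftmost-longest match wins.
#'
#' @param record one-row article tibble.
#' @param dictionaries a `compiled_dictionary` or list of them.
#' @param fields fields to scan (default title, abstract, mesh).
#' @return annotation tibble: `pmid`, `concept_id`, `vocabulary`, `field`,
#'   `start`, `end`, `matched_text`.
#' @export
tag_concepts <- function(record, dictionaries,
                         fields = c("title", "abstract", "mesh")) {
  if (inherits(dictionaries, "compiled_dictionary")) {
    dictionaries <- list(dictionaries)
  }
  dplyr::bind_rows(purrr::map(dictionaries, scan_record,
                              record = record, fields = fields))
}

#' Tag organism mentions (common and Latin names, MeSH headings included)
#'
#' @param record one-row article tibble.
#' @param organism_dict dictionary from [organism_dictionary()].
#' @return annotation tibble with vocabulary `"organism"` and taxon
#'   accessions as `concept_id`.
#' @export
tag_organisms <- function(record, organism_dict = organism_dictionary()) {
  scan_record(record, organism_dict, c("title", "abstract", "mesh"))
}

.mutation_patterns <- c(
  # protein substitution shorthand: A123T (trailing capital excludes "T3")
  protein_sub = "\\b[A-Z][0-9]+[A-Z]\\b",
  # HGVS-like coding/genomic expressions: c.123A>G, c.76delA, g.5dupT
  hgvs_nt = "\\b[cgmn]\\.[0-9]+(?:[ACGT]>[ACGT]|del[ACGT]*|ins[ACGT]+|dup[ACGT]*)",
  # HGVS protein: p.Ala123Thr, p.Trp24*, p.Gly12fs
  hgvs_prot = "\\bp\\.[A-Z][a-z]{2}[0-9]+(?:[A-Z][a-z]{2}|\\*|fs)",
  # dbSNP identifiers
  rsid = "\\brs[0-9]+\\b"
)

#' Tag mutation mentions with regular-expression families
#'
#' Three notation families are recognized in title and abstract: protein
#' substitution shorthand (`A123T`), HGVS-like nucleotide/protein
#' expressions (`c.123A>G`, `p.Ala123Thr`) and dbSNP identifiers
#' (`rs12345`). The matched text itself (verbatim) is the concept id;
#' mutation mentions are not normalized to any database.
#'
#' @param record one-row article tibble.
#' @return annotation tibble with vocabulary `"mutation"`.
#' @export
tag_mutations <- function(record) {
  pmid <- record$pmid[[1]]
  out <- list()
  for (f in c("title", "abstract")) {
    text <- article_field_text(record, f)
    if (!nzchar(text)) next
    taken <- rep(FALSE, nchar(text))
    for (pat in .mutation_patterns) {
      m <- gregexpr(pat, text, perl = TRUE)[[1]]
      if (m[1] == -1) next
      for (k in seq_along(m)) {
        s <- as.integer(m[k])
        len <- attr(m, "match.length")[k]
        if (any(taken[s:(s + len - 1L)])) next  # first family wins on overlap
        taken[s:(s + len - 1L)] <- TRUE
        matched <- substr(text, s, s + len - 1L)
        out[[length(out) + 1L]] <- tibble::tibble(
          pmid = pmid, concept_id = matched, vocabulary = "mutation",
          field = f, start = s - 1L, end = s - 1L + len,
          matched_text = matched
        )
      }
    }
  }
  if (length(out) == 0) return(empty_annotations())
  dplyr::arrange(dplyr::bind_rows(out), .data$field, .data$start)
}

#' Mark gene mentions in title and abstract
#'
#' Gene mentions are marked, not normalized: the concept id of a gene
#' annotation is the dictionary surface form that matched (e.g. `"Retn"`),
#' never a gene database id. Marked mentions drive highlighting only; gene
#' search goes through query expansion instead.
#'
#' @param record one-row article tibble.
#' @param gene_dict dictionary compiled from a gene table with
#'   `concept = "surface"` (see [compile_dictionary()]).
#' @return annotation tibble with vocabulary `"gene"`.
#' @export
tag_genes <- function(record, gene_dict) {
  scan_record(record, gene_dict, c("title", "abstract"))
}

#' Tag one article with every pipeline
#'
#' @param record one-row article tibble.
#' @param dictionaries list of concept dictionaries (may be empty).
#' @param organism_dict optional organism dictionary.
#' @param gene_dict optional gene dictionary.
#' @param mutations whether to run the mutation regex families.
#' @return combined annotation tibble.
#' @export
tag_document <- function(record, dictionaries = list(),
                         organism_dict = NULL, gene_dict = NULL,
                         mutations = TRUE) {
  parts <- list(tag_concepts(record, dictionaries))
  if (!is.null(organism_dict)) {
    parts <- c(parts, list(tag_organisms(record, organism_dict)))
  }
  if (!is.null(gene_dict)) parts <- c(parts, list(tag_genes(record, gene_dict)))
  if (mutations) parts <- c(parts, list(tag_mutations(record)))
  dplyr::bind_rows(parts)
}

#' Tag a whole corpus
#'
#' @param articles article tibble.
#' @inheritParams tag_document
#' @return annotation tibble over all articles.
#' @export
tag_corpus <- function(articles, dictionaries = list(),
                       organism_dict = NULL, gene_dict = NULL,
                       mutations = TRUE) {
  if (nrow(articles) == 0) return(empty_annotations())
  dplyr::bind_rows(purrr::map(seq_len(nrow(articles)), function(i) {
    tag_document(articles[i, ], dictionaries, organism_dict, gene_dict,
                 mutations)
  }))
}

#' Occurrence counts per concept
#'
#' Projects an annotation tibble to per-concept occurrence counts — the
#' numbers shown after each term in a curation display, sorted descending.
#'
#' @param annotations annotation tibble.
#' @return tibble `concept_id`, `vocabulary`, `n`, sorted by `n` descending
#'   then `concept_id`.
#' @export
term_counts <- function(annotations) {
  annotations |>
    dplyr::count(.data$concept_id, .data$vocabulary, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$concept_id)
}
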