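#' Parse an OBO 1.2 ontology into a term tibble
#'
#' Reads `[Term]` stanzas and collects, per term: accession (`id:`), name,
#' synonyms of every scope (EXACT/RELATED/... are not distinguished), `is_a`
#' parents and the obsolete flag. Non-term stanzas (`[Typedef]` etc.) and
#' header lines are ignored.
#'
#' @param source path to an OBO file, or a single string of OBO text.
#' @param vocabulary short label for the vocabulary (e.g. `"RDO"`), attached
#'   to the result.
#' @return tibble with columns `accession`, `name`, `synonyms` (list),
#'   `parents` (list), `is_obsolete` (logical), plus attribute `vocabulary`.
#' @export
parse_obo <- function(source, vocabulary = "ontology") {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  terms <- list()
  cur <- NULL
  cur_start <- NA_integer_
  in_term <- FALSE
  flush <- function(cur, cur_start) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$accession)) {
      stop("OBO [Term] stanza starting at line ", cur_start, " has no id",
           call. = FALSE)
    }
    cur
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "[Term]") {
      t <- flush(cur, cur_start)
      if (!is.null(t)) terms[[length(terms) + 1L]] <- t
      cur <- list(accession = NULL, name = "", synonyms = character(),
                  parents = character(), is_obsolete = FALSE)
      cur_start <- i
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", line)) {
      t <- flush(cur, cur_start)
      if (!is.null(t)) terms[[length(terms) + 1L]] <- t
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(line)) next
    if (startsWith(line, "id:")) {
      cur$accession <- trimws(substring(line, 4))
    } else if (startsWith(line, "name:")) {
      cur$name <- trimws(substring(line, 6))
    } else if (startsWith(line, "synonym:")) {
      m <- stringr::str_match(line, 'synonym:\\s*"([^"]*)"')
      if (!is.na(m[1, 2])) cur$synonyms <- c(cur$synonyms, m[1, 2])
    } else if (startsWith(line, "is_a:")) {
      target <- trimws(sub("!.*$", "", substring(line, 6)))
      cur$parents <- c(cur$parents, target)
    } else if (startsWith(line, "is_obsolete:")) {
      cur$is_obsolete <- grepl("true", line, fixed = TRUE)
    }
  }
  t <- flush(cur, cur_start)
  if (!is.null(t)) terms[[length(terms) + 1L]] <- t
  out <- tibble::tibble(
    accession = vapply(terms, `[[`, character(1), "accession"),
    name = vapply(terms, `[[`, character(1), "name"),
    synonyms = purrr::map(terms, "synonyms"),
    parents = purrr::map(terms, function(t) {
      if (t$is_obsolete) character() else t$parents
    }),
    is_obsolete = vapply(terms, `[[`, logical(1), "is_obsolete")
  )
  bad <- !grepl("^[A-Za-z_]+:[0-9]+$", out$accession)
  if (any(bad)) {
    stop("OBO accession not of PREFIX:digits form: ", out$accession[which(bad)[1]],
         call. = FALSE)
  }
  attr(out, "vocabulary") <- vocabulary
  out
}

#' Parse a tab-delimited gene table
#'
#' Expected header: `gene_id`, `symbol`, `name`, `synonyms`, `ortholog_ids`;
#' the last two cells are pipe-separated lists (empty cell = empty list).
#'
#' @param source path to a TSV file, or a single string of TSV text.
#' @return tibble with `gene_id`, `symbol`, `name` (character) and
#'   `synonyms`, `ortholog_ids` (lists of character).
#' @export
parse_gene_table <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty gene table", call. = FALSE)
  split_row <- function(line) {
    # strsplit drops trailing empty fields; pad back to the real field count
    cells <- strsplit(line, "\t", fixed = TRUE)[[1]]
    n_fields <- nchar(gsub("[^\t]", "", line)) + 1L
    c(cells, rep("", n_fields - length(cells)))
  }
  header <- split_row(lines[1])
  ncol <- length(header)
  if (!identical(header[1:2], c("gene_id", "symbol"))) {
    stop("gene table must start with columns gene_id, symbol", call. = FALSE)
  }
  rows <- purrr::imap(lines[-1], function(line, i) {
    cells <- split_row(line)
    if (length(cells) != ncol) {
      stop("gene table row ", i + 1L, " has ", length(cells),
           " columns, expected ", ncol, call. = FALSE)
    }
    cells
  })
  split_list <- function(cell) {
    if (!nzchar(cell)) character() else strsplit(cell, "|", fixed = TRUE)[[1]]
  }
  out <- tibble::tibble(
    gene_id = vapply(rows, `[[`, character(1), 1),
    symbol = vapply(rows, `[[`, character(1), 2),
    name = vapply(rows, `[[`, character(1), 3),
    synonyms = purrr::map(rows, function(r) split_list(r[[4]])),
    ortholog_ids = purrr::map(rows, function(r) split_list(r[[5]]))
  )
  if (any(!nzchar(out$symbol))) stop("gene with empty symbol", call. = FALSE)
  if (anyDuplicated(out$gene_id)) stop("duplicate gene_id in table", call. = FALSE)
  out
}

#' Case class of a dictionary surface form
#'
#' A surface form is matched case-sensitively when it is short (4 characters
#' or fewer) or carries an uppercase letter after its first character —
#' short symbols and mixed-case tokens (gene symbols like `FIZZ3`) collide
#' with ordinary words if case-folded. Everything else is matched
#' case-insensitively over stemmed tokens.
#'
#' @param surface_form character vector of non-empty surface forms.
#' @return character vector, each element `"sensitive"` or `"insensitive"`.
#' @export
assign_case_class <- function(surface_form) {
  stopifnot(all(nzchar(surface_form)))
  sensitive <- nchar(surface_form) <= 4 |
    grepl("[A-Z]", substring(surface_form, 2))
  ifelse(sensitive, "sensitive", "insensitive")
}

tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  regmatches(text, gregexpr("[A-Za-z0-9]+", text))[[1]]
}

match_key <- function(tokens) paste(tokens, collapse = " ")

#' Compile a stemmed, case-split matching dictionary
#'
#' Turns ontology terms or gene records into a two-gazetteer dictionary: one
#' gazetteer for case-sensitive surface forms (matched verbatim) and one for
#' case-insensitive forms (matched over lowercased, stemmed tokens). For
#' ontology input the reflexive-transitive `is_a` closure is compiled as the
#' descendant index that drives query expansion; obsolete terms enter
#' neither the gazetteers nor the hierarchy.
#'
#' @param x a term tibble from [parse_obo()] or a gene tibble from
#'   [parse_gene_table()].
#' @param vocabulary label stored on every annotation this dictionary emits.
#' @param case_class optional override: `"sensitive"` or `"insensitive"`
#'   applied to every entry instead of [assign_case_class()] (used e.g. by
#'   the bundled organism dictionary, whose short common names must stem).
#' @param concept what a match reports as its concept id: the record's
#'   identifier (`"id"`, default) or the surface form itself (`"surface"`,
#'   used for gene marking, which never normalizes mentions to gene ids).
#' @return a `compiled_dictionary` object.
#' @export
compile_dictionary <- function(x, vocabulary, case_class = NULL,
                               concept = c("id", "surface")) {
  concept <- match.arg(concept)
  if (nrow(x) == 0) stop("cannot compile an empty dictionary", call. = FALSE)
  is_ontology <- "accession" %in% names(x)
  if (is_ontology) {
    active <- x[!x$is_obsolete, ]
    surfaces <- tibble::tibble(
      surface_form = unlist(purrr::map2(active$name, active$synonyms, c)),
      concept_id = rep(active$accession,
                       lengths(active$synonyms) + 1L)
    )
  } else {
    surfaces <- tibble::tibble(
      surface_form = unlist(purrr::pmap(
        list(x$symbol, x$name, x$synonyms),
        function(sym, nm, syn) c(sym, nm, syn)
      )),
      concept_id = rep(x$gene_id, lengths(x$synonyms) + 2L)
    )
  }
  surfaces <- surfaces[nzchar(surfaces$surface_form), ]
  if (concept == "surface") surfaces$concept_id <- surfaces$surface_form
  surfaces <- dplyr::distinct(surfaces, .data$surface_form, .data$concept_id)
  cls <- if (is.null(case_class)) {
    assign_case_class(surfaces$surface_form)
  } else {
    rep(match.arg(case_class, c("sensitive", "insensitive")),
        nrow(surfaces))
  }
  match_tokens <- purrr::map2(surfaces$surface_form, cls, function(s, cl) {
    toks <- tokenize_text(s)
    if (cl == "insensitive") stem_token(tolower(toks)) else toks
  })
  keep <- lengths(match_tokens) > 0
  entries <- tibble::tibble(
    surface_form = surfaces$surface_form[keep],
    concept_id = surfaces$concept_id[keep],
    vocabulary = vocabulary,
    case_class = cls[keep],
    match_tokens = match_tokens[keep],
    key = vapply(match_tokens[keep], match_key, character(1))
  )
  lookup <- list(sensitive = new.env(parent = emptyenv()),
                 insensitive = new.env(parent = emptyenv()))
  for (i in seq_len(nrow(entries))) {
    env <- lookup[[entries$case_class[i]]]
    k <- entries$key[i]
    env[[k]] <- c(env[[k]], i)
  }
  desc <- if (is_ontology) build_descendants_index(x) else list()
  structure(
    list(
      vocabulary = vocabulary,
      entries = entries,
      lookup = lookup,
      max_tokens = max(lengths(entries$match_tokens)),
      descendants_index = desc
    ),
    class = "compiled_dictionary"
  )
}

# reflexive-transitive closure of is_a, obsolete terms excluded
build_descendants_index <- function(terms) {
  active <- terms[!terms$is_obsolete, ]
  acc <- active$accession
  parents <- stats::setNames(active$parents, acc)
  obsolete <- terms$accession[terms$is_obsolete]
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(a) {
    if (!is.null(anc_cache[[a]])) return(anc_cache[[a]])
    anc_cache[[a]] <- a  # guard against accidental cycles
    ps <- setdiff(parents[[a]], obsolete)
    ps <- ps[ps %in% acc]
    out <- unique(c(a, unlist(lapply(ps, ancestors))))
    anc_cache[[a]] <- out
    out
  }
  idx <- stats::setNames(vector("list", length(acc)), acc)
  for (a in acc) {
    for (anc in ancestors(a)) idx[[anc]] <- c(idx[[anc]], a)
  }
  lapply(idx, function(v) sort(unique(v)))
}

#' @export
print.compiled_dictionary <- function(x, ...) {
  cat("<compiled_dictionary> ", x$vocabulary, ": ", nrow(x$entries),
      " entries (", sum(x$entries$case_class == "sensitive"), " sensitive), ",
      length(x$descendants_index), " hierarchy nodes\n", sep = "")
  invisible(x)
}

#' Reflexive-transitive descendants of an ontology term
#'
#' The accession itself plus every term reachable from it downward through
#' `is_a` edges — the set a concept query is expanded to.
#'
#' @param dictionary a `compiled_dictionary` built from ontology terms.
#' @param accession accession present in the dictionary's hierarchy.
#' @return sorted character vector of accessions (always contains
#'   `accession`).
#' @export
descendants <- function(dictionary, accession) {
  stopifnot(inherits(dictionary, "compiled_dictionary"))
  out <- dictionary$descendants_index[[accession]]
  if (is.null(out)) {
    stop("accession not in hierarchy: ", accession, call. = FALSE)
  }
  out
}

#' Bundled organism dictionary
#'
#' Common and Latin names for the model organisms the curation workflow
#' cares about (rat, mouse, human), mapped to NCBI Taxonomy accessions, plus
#' any extra species rows supplied by a fixture generator. Names are matched
#' case-insensitively over stems so that plural common names ("rats") hit.
#'
#' @param extra optional tibble with columns `accession`, `name`,
#'   `synonyms` (list) for additional species.
#' @return a `compiled_dictionary` with vocabulary `"organism"`.
#' @export
organism_dictionary <- function(extra = NULL) {
  base <- tibble::tibble(
    accession = c("NCBITaxon:10116", "NCBITaxon:10090", "NCBITaxon:9606"),
    name = c("Rattus norvegicus", "Mus musculus", "Homo sapiens"),
    synonyms = list(c("rat", "rats"), c("mouse", "mice"),
                    c("human", "humans")),
    parents = list(character(), character(), character()),
    is_obsolete = FALSE
  )
  if (!is.null(extra)) {
    if (!"parents" %in% names(extra)) extra$parents <- list(character())
    if (!"is_obsolete" %in% names(extra)) extra$is_obsolete <- FALSE
    base <- dplyr::bind_rows(base, extra)
  }
  compile_dictionary(base, "organism", case_class = "insensitive")
}

#' Default species constraint (rat, human, mouse)
#' @return named character vector of NCBI Taxonomy accessions.
#' @export
default_species_taxa <- function() {
  c(rat = "NCBITaxon:10116", human = "NCBITaxon:9606",
    mouse = "NCBITaxon:10090")
}
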