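# Independent oracles: these deliberately re-derive results through a
# different code path than the implementation (window enumeration instead of
# hash lookup, per-document predicates instead of posting intersections,
# straight-line arithmetic instead of the scorer).

# exhaustive-window gazetteer oracle: every token window is compared against
# every dictionary entry, then leftmost-longest selection per vocabulary
oracle_scan_field <- function(pmid, field, text, dict) {
  toks <- tokenize(text)
  n <- nrow(toks)
  if (n == 0) return(NULL)
  verb <- toks$text
  fold <- stem_token(tolower(toks$text))
  entries <- dict$entries
  raw <- list()
  for (i in seq_len(n)) {
    for (j in i:min(n, i + dict$max_tokens - 1L)) {
      wv <- paste(verb[i:j], collapse = " ")
      wf <- paste(fold[i:j], collapse = " ")
      hit <- (entries$case_class == "sensitive" & entries$key == wv) |
        (entries$case_class == "insensitive" & entries$key == wf)
      if (any(hit)) {
        raw[[length(raw) + 1L]] <- data.frame(
          i = i, j = j, concept_id = unique(entries$concept_id[hit])
        )
      }
    }
  }
  if (length(raw) == 0) return(NULL)
  raw <- do.call(rbind, raw)
  # leftmost-longest: walk positions, take the longest window starting there
  out <- list()
  pos <- 1L
  while (pos <= n) {
    here <- raw[raw$i == pos, ]
    if (nrow(here) == 0) {
      pos <- pos + 1L
      next
    }
    jmax <- max(here$j)
    sel <- here[here$j == jmax, ]
    out[[length(out) + 1L]] <- data.frame(
      pmid = pmid,
      concept_id = unique(sel$concept_id),
      vocabulary = dict$vocabulary,
      field = field,
      start = toks$start[pos],
      end = toks$end[jmax],
      matched_text = substr(text, toks$start[pos] + 1L, toks$end[jmax])
    )
    pos <- jmax + 1L
  }
  do.call(rbind, out)
}

oracle_tag <- function(articles, dicts, fields = c("title", "abstract", "mesh")) {
  rows <- list()
  for (i in seq_len(nrow(articles))) {
    rec <- articles[i, ]
    for (d in dicts) {
      for (f in fields) {
        r <- oracle_scan_field(rec$pmid, f, article_field_text(rec, f), d)
        if (!is.null(r)) rows[[length(rows) + 1L]] <- r
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pmid = integer(), concept_id = character(),
                      vocabulary = character(), field = character(),
                      start = integer(), end = integer(),
                      matched_text = character()))
  }
  do.call(rbind, rows)
}

ann_key <- function(x) {
  sort(paste(x$pmid, x$vocabulary, x$field, x$start, x$end, x$concept_id,
             sep = "|"))
}

# brute-force reflexive-transitive descendant closure by BFS over edges
bfs_closure <- function(edges, accessions) {
  out <- lapply(accessions, function(a) {
    seen <- a
    frontier <- a
    while (length(frontier)) {
      nxt <- edges$child[edges$parent %in% frontier]
      frontier <- setdiff(nxt, seen)
      seen <- union(seen, frontier)
    }
    sort(seen)
  })
  stats::setNames(out, accessions)
}

# per-document predicate evaluation of a query condition
oracle_evaluate <- function(condition, articles, annotations, dictionaries) {
  doc_tokens <- lapply(seq_len(nrow(articles)), function(i) {
    unique(stem_token(tolower(c(
      tokenize(articles$title[i])$text, tokenize(articles$abstract[i])$text
    ))))
  })
  names(doc_tokens) <- as.character(articles$pmid)
  closure_of <- function(cid) {
    for (d in dictionaries) {
      if (!is.null(d$descendants_index[[cid]])) return(descendants(d, cid))
    }
    cid
  }
  doc_ok <- vapply(seq_len(nrow(articles)), function(i) {
    p <- articles$pmid[i]
    adoc <- annotations[annotations$pmid == p, ]
    toks <- doc_tokens[[as.character(p)]]
    for (cl in condition$clauses) {
      ok <- if (cl$kind == "concept") {
        any(cl$expansion %in% adoc$concept_id)
      } else {
        any(vapply(cl$expansion, function(kw) {
          kt <- unique(stem_token(tolower(tokenize(kw)$text)))
          length(kt) > 0 && all(kt %in% toks)
        }, logical(1)))
      }
      if (!ok) return(FALSE)
    }
    if (length(condition$species_filter)) {
      org <- adoc$concept_id[adoc$vocabulary == "organism"]
      if (!any(condition$species_filter %in% org)) return(FALSE)
    }
    for (f in condition$filter_path) {
      ok <- if (f$kind == "concept") {
        any(closure_of(f$concept_id) %in% adoc$concept_id)
      } else {
        !is.na(articles$year[i]) &&
          articles$year[i] >= f$year_range[1] &&
          articles$year[i] <= f$year_range[2]
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(articles$pmid[doc_ok])
}

# straight-line reimplementation of the relevance formula from raw text
oracle_score <- function(condition, pmid, articles, annotations) {
  n_docs <- nrow(articles)
  stems_of <- function(i) {
    stem_token(tolower(c(tokenize(articles$title[i])$text,
                         tokenize(articles$abstract[i])$text)))
  }
  all_stems <- lapply(seq_len(n_docs), stems_of)
  i <- which(articles$pmid == pmid)
  doc_stems <- all_stems[[i]]
  len <- length(doc_stems)
  idf2 <- function(df) (1 + log(n_docs / (df + 1)))^2
  total <- 0
  matched <- 0
  for (cl in condition$clauses) {
    hit <- FALSE
    if (cl$kind == "concept") {
      for (cid in cl$expansion) {
        tf <- sum(annotations$concept_id == cid & annotations$pmid == pmid)
        if (tf > 0) {
          hit <- TRUE
          df <- length(unique(annotations$pmid[annotations$concept_id == cid]))
          total <- total + sqrt(tf) * idf2(df) / sqrt(len)
        }
      }
    } else {
      toks <- character()
      for (kw in cl$expansion) {
        kt <- unique(stem_token(tolower(tokenize(kw)$text)))
        if (length(kt) && all(kt %in% doc_stems)) {
          hit <- TRUE
          toks <- c(toks, kt)
        }
      }
      for (t in unique(toks)) {
        tf <- sum(doc_stems == t)
        df <- sum(vapply(all_stems, function(s) t %in% s, logical(1)))
        total <- total + sqrt(tf) * idf2(df) / sqrt(len)
      }
    }
    if (hit) matched <- matched + 1
  }
  (matched / length(condition$clauses)) * total
}

# handwritten 6-term OBO fixture: a tree with one obsolete term and synonyms
tiny_obo <- function() {
  paste(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: RDO:0000001",
    "name: kidney diseases",
    'synonym: "renal disorders" EXACT []',
    'synonym: "nephropathies" RELATED []',
    "",
    "[Term]",
    "id: RDO:0000002",
    "name: cystic kidney diseases",
    "is_a: RDO:0000001 ! kidney diseases",
    "",
    "[Term]",
    "id: RDO:0000003",
    "name: polycystic kidney syndrome",
    "is_a: RDO:0000002 ! cystic kidney diseases",
    "",
    "[Term]",
    "id: RDO:0000004",
    "name: glomerular fibrosis",
    "is_a: RDO:0000001 ! kidney diseases",
    "",
    "[Term]",
    "id: RDO:0000005",
    "name: tubular necrosis",
    "is_a: RDO:0000001 ! kidney diseases",
    "",
    "[Term]",
    "id: RDO:0000006",
    "name: renal dropsy",
    "is_a: RDO:0000001 ! kidney diseases",
    "is_obsolete: true",
    sep = "\n"
  )
}

# one-row article builder for targeted tagging tests
make_article <- function(pmid, title = "A fixture title", abstract = "",
                         mesh = character(), year = 2010L) {
  tibble::tibble(pmid = as.integer(pmid), title = title, abstract = abstract,
                 mesh_terms = list(mesh), year = year, month = NA_integer_,
                 day = NA_integer_, journal = "J Fixture")
}

# serialize a gene tibble back to TSV (round-trip tests)
gene_table_text <- function(genes) {
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$gene_id[i], genes$symbol[i], genes$name[i],
          paste(genes$synonyms[[i]], collapse = "|"),
          paste(genes$ortholog_ids[[i]], collapse = "|"), sep = "\t")
  }, character(1))
  paste(c("gene_id\tsymbol\tname\tsynonyms\tortholog_ids", rows),
        collapse = "\n")
}

# standard fixture bundle used across test files
fixture_world <- function(seed = 11, n_docs = 40, n_terms = 15,
                          mention_rate = 0.7, collision_mode = FALSE) {
  ont <- generate_mini_ontology(n_terms, seed = seed)
  terms <- parse_obo(ont$obo, "TST")
  dict <- compile_dictionary(terms, "TST")
  org <- organism_dictionary()
  genes <- parse_gene_table(fixture_gene_table(seed = seed))
  gdict <- compile_dictionary(genes, "gene", concept = "surface")
  cfg <- generator_config(seed = seed + 1, n_docs = n_docs,
                          n_terms = n_terms, mention_rate = mention_rate,
                          collision_mode = collision_mode)
  corpus <- generate_corpus(cfg, list(dict), organism_dict = org,
                            gene_dict = gdict)
  list(ont = ont, terms = terms, dict = dict, org = org, genes = genes,
       gdict = gdict, cfg = cfg, corpus = corpus)
}
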