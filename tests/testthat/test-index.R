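# shared indexed world for the query tests
indexed_world <- function(seed = 61, n_docs = 40, ...) {
  w <- fixture_world(seed = seed, n_docs = n_docs, ...)
  w$articles <- parse_medline_xml(w$corpus$xml)
  w$ann <- tag_corpus(w$articles, list(w$dict), organism_dict = w$org,
                      gene_dict = w$gdict)
  w$index <- build_index(w$ann, w$articles)
  w$dicts <- list(w$dict, w$org)
  w
}

test_that("text postings carry stemmed term frequencies", {
  arts <- make_article(1, title = "t", abstract = "kidney kidney")
  idx <- build_index(empty_ann <- tag_corpus(arts), arts)
  expect_identical(idx$text[["kidney"]], c(`1` = 2L))
  expect_identical(glance(idx)$n_docs, 1L)
})

test_that("an empty corpus indexes to zero documents", {
  arts <- make_article(1)[0, ]
  idx <- build_index(tag_corpus(arts), arts)
  expect_identical(idx$n_docs, 0L)
})

test_that("indexing an annotation without a stored article names the PMID", {
  arts <- make_article(1)
  ann <- tag_mutations(make_article(99, abstract = "the A123T variant"))
  expect_error(build_index(ann, arts), "99")
})

test_that("postings equal a brute-force recount from raw text", {
  w <- indexed_world(seed = 62, n_docs = 50)
  # recount text postings
  for (t in sample(ls(w$index$text), 25)) {
    tfs <- vapply(seq_len(nrow(w$articles)), function(i) {
      stems <- stem_token(tolower(c(tokenize(w$articles$title[i])$text,
                                    tokenize(w$articles$abstract[i])$text)))
      sum(stems == t)
    }, integer(1))
    want <- setNames(tfs[tfs > 0], as.character(w$articles$pmid[tfs > 0]))
    got <- w$index$text[[t]]
    expect_identical(got[order(names(got))], want[order(names(want))])
  }
  # recount concept postings
  for (cid in sample(ls(w$index$concepts), 15)) {
    sub <- w$ann[w$ann$concept_id == cid, ]
    want <- table(sub$pmid)
    got <- w$index$concepts[[cid]]
    expect_identical(as.integer(got[order(names(got))]),
                     unname(as.integer(want[order(names(want))])))
  }
  expect_identical(
    unname(w$index$doc_lengths),
    vapply(seq_len(nrow(w$articles)), function(i) {
      nrow(tokenize(w$articles$title[i])) + nrow(tokenize(w$articles$abstract[i]))
    }, integer(1))
  )
})

test_that("concept clauses expand to the descendant closure", {
  w <- fixture_world(seed = 63)
  leaves <- setdiff(w$ont$terms$accession, w$ont$edges$parent)
  cl <- expand_concept_clause(leaves[1], w$dict)
  expect_identical(cl$expansion, leaves[1])
  root <- w$ont$terms$accession[1]
  cl2 <- expand_concept_clause(root, w$dict)
  expect_identical(cl2$expansion,
                   bfs_closure(w$ont$edges, root)[[root]])
  expect_true(root %in% cl2$expansion)
  expect_error(expand_concept_clause("TST:9999999", w$dict), "hierarchy")
})

test_that("gene clauses pool symbol, name, synonyms and ortholog keywords", {
  genes <- parse_gene_table(fixture_gene_table())
  cl <- expand_gene_clause("RGD:628781", genes)
  expect_setequal(tolower(cl$expansion),
                  tolower(c("ADSF", "RSTN", "XCP1", "FIZZ3", "Retn", "resistin")))
  bare <- parse_gene_table(
    "gene_id\tsymbol\tname\tsynonyms\tortholog_ids\nRGD:1\tAbc1\talpha channel\t\t")
  expect_setequal(expand_gene_clause("RGD:1", bare)$expansion,
                  c("Abc1", "alpha channel"))
  expect_error(expand_gene_clause("RGD:404", genes), "unknown gene")
  # ortholog union oracle
  tri <- parse_gene_table(paste(
    "gene_id\tsymbol\tname\tsynonyms\tortholog_ids",
    "RGD:1\tAaa1\talpha channel\tA1\tRGD:2|RGD:3",
    "RGD:2\tBbb2\tbeta channel\tB2|ALPHA channel\t",
    "RGD:3\tCcc3\tgamma channel\t\t",
    sep = "\n"))
  got <- expand_gene_clause("RGD:1", tri)$expansion
  want <- c("Aaa1", "alpha channel", "A1", "Bbb2", "beta channel", "B2",
            "Ccc3", "gamma channel")
  expect_setequal(tolower(got), tolower(want))
  # deduplication is case-insensitive ("ALPHA channel" folds into "alpha channel")
  expect_identical(anyDuplicated(tolower(got)), 0L)
  # unknown orthologs are skipped with a warning
  dangling <- parse_gene_table(paste(
    "gene_id\tsymbol\tname\tsynonyms\tortholog_ids",
    "RGD:1\tAaa1\talpha channel\t\tRGD:77",
    sep = "\n"))
  expect_warning(cl <- expand_gene_clause("RGD:1", dangling), "ortholog")
  expect_setequal(cl$expansion, c("Aaa1", "alpha channel"))
})

test_that("gene queries default to the rat/human/mouse species constraint", {
  genes <- parse_gene_table(fixture_gene_table())
  gcl <- expand_gene_clause("RGD:628781", genes)
  cond <- apply_default_species(query_condition(gcl))
  expect_setequal(cond$species_filter, unname(default_species_taxa()))
  explicit <- apply_default_species(
    query_condition(gcl, species = "NCBITaxon:10116"))
  expect_identical(explicit$species_filter, "NCBITaxon:10116")
  kw <- apply_default_species(query_condition(keyword_clause("kidney")))
  expect_identical(kw$species_filter, character())
})

test_that("a planted concept in 3 of 10 documents yields 3 results and an honest facet", {
  terms <- parse_obo(tiny_obo(), "RDO")
  d <- compile_dictionary(terms, "RDO")
  arts <- dplyr::bind_rows(lapply(1:10, function(p) {
    make_article(p, abstract = if (p <= 3) "Severe glomerular fibrosis found."
                 else "Nothing of note here.")
  }))
  ann <- tag_corpus(arts, list(d))
  idx <- build_index(ann, arts)
  out <- evaluate(query_condition(expand_concept_clause("RDO:0000004", d)),
                  idx, list(d))
  expect_setequal(out$results$pmid, 1:3)
  f <- out$facets[out$facets$concept_id == "RDO:0000004", ]
  expect_identical(f$count, 3L)
})

test_that("a concept absent from the corpus evaluates to empty results and facets", {
  w <- indexed_world(seed = 64, n_docs = 10)
  obo <- "[Term]\nid: ZZ:0000001\nname: unobtainium syndrome\n"
  dz <- compile_dictionary(parse_obo(obo, "ZZ"), "ZZ")
  out <- evaluate(query_condition(expand_concept_clause("ZZ:0000001", dz)),
                  w$index, list(dz))
  expect_identical(nrow(out$results), 0L)
  expect_identical(nrow(out$facets), 0L)
})

test_that("evaluation equals per-document brute-force predicates on random conditions", {
  w <- indexed_world(seed = 65, n_docs = 50)
  accs <- w$ont$terms$accession
  genes <- w$genes
  set.seed(66)
  for (trial in 1:25) {
    clauses <- list(expand_concept_clause(sample(accs, 1), w$dict))
    if (trial %% 2 == 0) {
      clauses <- c(clauses, list(expand_gene_clause(sample(genes$gene_id, 1),
                                                    genes)))
    }
    if (trial %% 3 == 0) {
      clauses <- c(clauses, list(keyword_clause(
        sample(conceptlit:::.filler_words, 1))))
    }
    cond <- rlang::exec(query_condition, !!!clauses,
                        species = if (trial %% 5 == 0) "NCBITaxon:10116"
                                  else character())
    if (trial %% 4 == 0) {
      cond <- apply_filter(cond, concept_filter(sample(accs, 1)))
    }
    if (trial %% 7 == 0) {
      cond <- apply_filter(cond, date_filter(2000, 2015))
    }
    got <- sort(evaluate(cond, w$index, w$dicts)$results$pmid)
    want <- oracle_evaluate(cond, w$articles, w$ann, w$dicts)
    expect_identical(got, want)
  }
})

test_that("relevance scores follow the TF-IDF formula exactly", {
  w <- indexed_world(seed = 67, n_docs = 20)
  accs <- w$ont$terms$accession
  set.seed(68)
  conds <- c(
    lapply(sample(accs, 5), function(a) {
      query_condition(expand_concept_clause(a, w$dict))
    }),
    list(query_condition(expand_concept_clause(accs[1], w$dict),
                         expand_gene_clause("RGD:628781", w$genes)),
         query_condition(keyword_clause("kidney"),
                         keyword_clause(sample(conceptlit:::.filler_words, 1))))
  )
  for (cond in conds) {
    res <- evaluate(cond, w$index, w$dicts)$results
    for (p in res$pmid) {
      expect_equal(
        unname(res$score[res$pmid == p]),
        oracle_score(cond, p, w$articles, w$ann),
        tolerance = 1e-9
      )
    }
  }
})

test_that("equal-length documents with tf 4 vs 1 score in ratio 2:1", {
  arts <- dplyr::bind_rows(
    make_article(1, title = "x", abstract = "kidney kidney kidney kidney pad pad"),
    make_article(2, title = "x", abstract = "kidney pad pad pad pad pad")
  )
  idx <- build_index(tag_corpus(arts), arts)
  cond <- query_condition(keyword_clause("kidney"))
  s1 <- score_document(cond, 1, idx)
  s2 <- score_document(cond, 2, idx)
  expect_gt(s2, 0)
  expect_equal(s1 / s2, 2, tolerance = 1e-12)
})

test_that("all three sort orders behave with descending-PMID tie-breaks", {
  res <- tibble::tibble(
    pmid = c(11L, 12L, 13L),
    score = c(1, 1, 0.5),
    pub_year = c(2001L, 1999L, 2005L),
    matched_concepts = list(NULL, NULL, NULL)
  )
  expect_identical(sort_results(res, "relevance")$pmid, c(12L, 11L, 13L))
  expect_identical(sort_results(res, "pub_date")$pmid, c(13L, 11L, 12L))
  expect_identical(sort_results(res, "pmid")$pmid, c(13L, 12L, 11L))
  expect_error(sort_results(res, "alphabetical"))
  # reference sort oracle on random lists
  set.seed(69)
  for (i in 1:10) {
    n <- 15
    r <- tibble::tibble(pmid = sample.int(1000, n),
                        score = sample(c(0.5, 1, 2), n, replace = TRUE),
                        pub_year = sample(1990:2020, n, replace = TRUE),
                        matched_concepts = vector("list", n))
    want <- r[order(-r$score, -r$pmid), ]
    expect_identical(sort_results(r, "relevance")$pmid, want$pmid)
    want2 <- r[order(-r$pub_year, -r$pmid), ]
    expect_identical(sort_results(r, "pub_date")$pmid, want2$pmid)
  }
})

test_that("every emitted facet count is exactly the post-filter result size", {
  w <- indexed_world(seed = 70, n_docs = 40)
  accs <- w$ont$terms$accession
  set.seed(71)
  for (trial in 1:12) {
    cond <- query_condition(expand_concept_clause(sample(accs, 1), w$dict))
    out <- evaluate(cond, w$index, w$dicts)
    for (k in seq_len(nrow(out$facets))) {
      f <- out$facets[k, ]
      refined <- evaluate(apply_filter(cond, concept_filter(f$concept_id)),
                          w$index, w$dicts)
      expect_identical(nrow(refined$results), as.integer(f$count))
    }
  }
})

test_that("filters chain, commute and truncate back to the original results", {
  w <- indexed_world(seed = 72, n_docs = 40)
  accs <- w$ont$terms$accession
  cond0 <- query_condition(keyword_clause("study"))
  base <- evaluate(cond0, w$index, w$dicts)$results$pmid
  f1 <- concept_filter(accs[1])
  f2 <- date_filter(2000, 2018)
  a <- evaluate(apply_filter(apply_filter(cond0, f1), f2), w$index, w$dicts)
  b <- evaluate(apply_filter(apply_filter(cond0, f2), f1), w$index, w$dicts)
  expect_setequal(a$results$pmid, b$results$pmid)
  # removing a filter = truncating the path at its node
  trunc <- truncate_filters(apply_filter(apply_filter(cond0, f1), f2), 0)
  expect_setequal(evaluate(trunc, w$index, w$dicts)$results$pmid, base)
  expect_identical(length(trunc$filter_path), 0L)
  # concept filters include descendants
  root <- accs[1]
  direct_only <- unique(w$ann$pmid[w$ann$concept_id == root])
  closure_docs <- unique(w$ann$pmid[w$ann$concept_id %in% descendants(w$dict, root)])
  got <- evaluate(apply_filter(cond0, concept_filter(root)), w$index, w$dicts)
  expect_setequal(got$results$pmid, intersect(base, closure_docs))
})

test_that("duplicating every document preserves the result set and score positivity", {
  w <- indexed_world(seed = 73, n_docs = 15)
  dup_arts <- dplyr::bind_rows(
    w$articles,
    dplyr::mutate(w$articles, pmid = pmid + 10000L)
  )
  dup_ann <- dplyr::bind_rows(
    w$ann, dplyr::mutate(w$ann, pmid = pmid + 10000L)
  )
  idx2 <- build_index(dup_ann, dup_arts)
  cond <- query_condition(expand_concept_clause(w$ont$terms$accession[1], w$dict))
  r1 <- evaluate(cond, w$index, w$dicts)$results
  r2 <- evaluate(cond, idx2, w$dicts)$results
  expect_true(all(r1$score > 0))
  expect_true(all(r2$score > 0))
  # every original result and its duplicate are returned
  orig <- r2[r2$pmid <= 10000, ]
  expect_setequal(orig$pmid, r1$pmid)
  expect_setequal(r2$pmid[r2$pmid > 10000] - 10000L, r1$pmid)
  # within each index scores depend on tf/idf only, so a document and its
  # duplicate always score identically
  merged <- merge(orig, data.frame(pmid = r2$pmid[r2$pmid > 10000] - 10000L,
                                   dup_score = r2$score[r2$pmid > 10000]),
                  by = "pmid")
  expect_equal(merged$score, merged$dup_score, tolerance = 1e-12)
})

test_that("documents returned for an accession are tagged with a member of its closure", {
  w <- indexed_world(seed = 74, n_docs = 30)
  for (a in sample(w$ont$terms$accession, 5)) {
    cond <- query_condition(expand_concept_clause(a, w$dict))
    res <- evaluate(cond, w$index, w$dicts)$results
    closure <- descendants(w$dict, a)
    for (p in res$pmid) {
      expect_true(any(w$ann$concept_id[w$ann$pmid == p] %in% closure))
    }
  }
})
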