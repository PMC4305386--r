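test_that("tokens are maximal alphanumeric runs with 0-based half-open offsets", {
  toks <- tokenize("kidney disease")
  expect_identical(toks$text, c("kidney", "disease"))
  expect_identical(toks$start, c(0L, 7L))
  expect_identical(toks$end, c(6L, 14L))
  expect_identical(nrow(tokenize("")), 0L)
  expect_identical(tokenize("pre-clinical x/y")$text,
                   c("pre", "clinical", "x", "y"))
})

test_that("token offsets always slice back to the token text", {
  w <- fixture_world(seed = 51, n_docs = 15)
  for (i in seq_len(nrow(w$corpus$articles))) {
    for (f in c("title", "abstract", "mesh")) {
      text <- article_field_text(w$corpus$articles[i, ], f)
      toks <- tokenize(text)
      if (nrow(toks)) {
        expect_identical(substr(rep(text, nrow(toks)), toks$start + 1, toks$end),
                         toks$text)
      }
    }
  }
})

test_that("a planted multiword mention is tagged with its exact span", {
  terms <- parse_obo(tiny_obo(), "RDO")
  d <- compile_dictionary(terms, "RDO")
  rec <- make_article(7, abstract = "Chronic kidney diseases worsen.")
  ann <- tag_concepts(rec, d)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$concept_id, "RDO:0000001")
  expect_identical(ann$matched_text, "kidney diseases")
  expect_identical(substr(rec$abstract, ann$start + 1, ann$end),
                   "kidney diseases")
})

test_that("stemming bridges inflection between text and dictionary", {
  d <- compile_dictionary(parse_obo(tiny_obo(), "RDO"), "RDO")
  rec <- make_article(8, abstract = "A chronic kidney disease was found.")
  ann <- tag_concepts(rec, d)
  expect_identical(ann$concept_id, "RDO:0000001")
  expect_identical(ann$matched_text, "kidney disease")
})

test_that("empty fields yield zero annotations", {
  d <- compile_dictionary(parse_obo(tiny_obo(), "RDO"), "RDO")
  rec <- make_article(9, abstract = "")
  expect_identical(nrow(tag_concepts(rec, d, fields = c("abstract", "mesh"))), 0L)
})

test_that("within one vocabulary the leftmost-longest match suppresses overlaps", {
  obo <- paste(
    "[Term]\nid: XX:0000001\nname: cystic kidney diseases\n",
    "[Term]\nid: XX:0000002\nname: kidney diseases\n",
    sep = "\n"
  )
  d <- compile_dictionary(parse_obo(obo, "XX"), "XX")
  rec <- make_article(1, abstract = "Severe cystic kidney diseases progress.")
  ann <- tag_concepts(rec, d)
  expect_identical(ann$concept_id, "XX:0000001")
  expect_identical(ann$matched_text, "cystic kidney diseases")
})

test_that("overlapping matches from different vocabularies are all kept", {
  d1 <- compile_dictionary(parse_obo("[Term]\nid: AA:0000001\nname: cystic kidney diseases\n", "AA"), "AA")
  d2 <- compile_dictionary(parse_obo("[Term]\nid: BB:0000001\nname: kidney diseases\n", "BB"), "BB")
  rec <- make_article(1, abstract = "Severe cystic kidney diseases progress.")
  ann <- tag_concepts(rec, list(d1, d2))
  expect_setequal(ann$vocabulary, c("AA", "BB"))
  expect_identical(nrow(ann), 2L)
})

test_that("concept tagging equals the exhaustive-window oracle on a generated corpus", {
  w <- fixture_world(seed = 52, n_docs = 60)
  arts <- parse_medline_xml(w$corpus$xml)
  got <- dplyr::bind_rows(lapply(
    seq_len(nrow(arts)), function(i) tag_concepts(arts[i, ], w$dict)
  ))
  oracle <- oracle_tag(arts, list(w$dict))
  expect_identical(ann_key(got), ann_key(oracle))
  # and both equal the planted ground truth for the concept vocabulary
  planted <- w$corpus$mentions[w$corpus$mentions$vocabulary == "TST", ]
  expect_identical(ann_key(got), ann_key(planted))
})

test_that("organism tagging hits common names, Latin names and MeSH headings", {
  org <- organism_dictionary()
  rec <- make_article(3, abstract = "Hypertensive rats were examined.")
  ann <- tag_organisms(rec, org)
  expect_identical(ann$concept_id, "NCBITaxon:10116")
  expect_identical(ann$matched_text, "rats")
  none <- make_article(4, abstract = "No species words here.")
  expect_identical(nrow(tag_organisms(none, org)), 0L)
  meshed <- make_article(5, mesh = c("Biomarkers", "Rattus norvegicus"))
  annm <- tag_organisms(meshed, org)
  expect_identical(annm$field, "mesh")
  expect_identical(annm$concept_id, "NCBITaxon:10116")
})

test_that("generated species plantings are recovered exactly", {
  w <- fixture_world(seed = 53, n_docs = 50)
  arts <- parse_medline_xml(w$corpus$xml)
  got <- dplyr::bind_rows(lapply(seq_len(nrow(arts)), function(i) {
    tag_organisms(arts[i, ], w$org)
  }))
  planted <- w$corpus$mentions[w$corpus$mentions$vocabulary == "organism", ]
  expect_identical(ann_key(got), ann_key(planted))
  # every doc with a planted species has at least one organism annotation
  expect_true(all(w$corpus$species$pmid %in% got$pmid))
})

test_that("mutation regex families match variants and ignore decoys", {
  rec <- make_article(6, abstract = "the A123T variant and rs12345 were genotyped")
  ann <- tag_mutations(rec)
  expect_identical(ann$concept_id, c("A123T", "rs12345"))
  expect_identical(ann$vocabulary, c("mutation", "mutation"))
  hgvs <- make_article(7, abstract = "carriers of c.123A>G and p.Ala123Thr alleles")
  expect_identical(tag_mutations(hgvs)$concept_id, c("c.123A>G", "p.Ala123Thr"))
  decoys <- make_article(8, abstract = "T3 and T4 with CO2 at p53 levels near IL6")
  expect_identical(nrow(tag_mutations(decoys)), 0L)
})

test_that("generated mutation plantings are recovered exactly despite decoys", {
  w <- fixture_world(seed = 54, n_docs = 60)
  arts <- parse_medline_xml(w$corpus$xml)
  got <- dplyr::bind_rows(lapply(seq_len(nrow(arts)), function(i) {
    tag_mutations(arts[i, ])
  }))
  expect_identical(ann_key(got), ann_key(w$corpus$mutations))
})

test_that("gene mentions are marked by surface form, case-sensitively for symbols", {
  w <- fixture_world(seed = 55)
  rec <- make_article(2, abstract = "expression of Retn increased")
  ann <- tag_genes(rec, w$gdict)
  expect_identical(ann$concept_id, "Retn")
  expect_identical(ann$vocabulary, "gene")
  shouty <- make_article(3, abstract = "expression of RETN increased")
  expect_identical(nrow(tag_genes(shouty, w$gdict)), 0L)
})

test_that("gene tagging equals the exhaustive-window oracle on a generated corpus", {
  w <- fixture_world(seed = 56, n_docs = 40)
  arts <- parse_medline_xml(w$corpus$xml)
  got <- dplyr::bind_rows(lapply(seq_len(nrow(arts)), function(i) {
    tag_genes(arts[i, ], w$gdict)
  }))
  oracle <- oracle_tag(arts, list(w$gdict), fields = c("title", "abstract"))
  expect_identical(ann_key(got), ann_key(oracle))
})

test_that("annotations slice to their matched text and counts are consistent", {
  w <- fixture_world(seed = 57, n_docs = 30)
  arts <- parse_medline_xml(w$corpus$xml)
  ann <- tag_corpus(arts, list(w$dict), organism_dict = w$org,
                    gene_dict = w$gdict)
  for (i in seq_len(nrow(ann))) {
    rec <- arts[arts$pmid == ann$pmid[i], ]
    text <- article_field_text(rec, ann$field[i])
    expect_identical(substr(text, ann$start[i] + 1, ann$end[i]),
                     ann$matched_text[i])
  }
  counts <- term_counts(ann)
  recount <- table(ann$concept_id)
  expect_identical(counts$n[match(names(recount), counts$concept_id)],
                   unname(as.integer(recount)))
  # determinism
  ann2 <- tag_corpus(arts, list(w$dict), organism_dict = w$org,
                     gene_dict = w$gdict)
  expect_identical(ann, ann2)
})

test_that("collision-mode decoys produce no spurious annotations", {
  w <- fixture_world(seed = 58, n_docs = 30, collision_mode = TRUE)
  arts <- parse_medline_xml(w$corpus$xml)
  ann <- tag_corpus(arts, list(w$dict), organism_dict = w$org,
                    gene_dict = w$gdict)
  planted <- dplyr::bind_rows(w$corpus$mentions, w$corpus$mutations)
  expect_identical(ann_key(ann), ann_key(planted))
})
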