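# conceptlit

Concept-based literature tagging and search for biocuration, on a single
machine.

Model-organism databases convert findings from free-text abstracts into
structured annotations by hand. The bottleneck is triage: finding the
articles worth curating and the concepts inside them. `conceptlit`
implements the full pipeline that supports such a workflow:

1. **Corpus management** — parse MEDLINE/PubMed article-set XML into tidy
   article tibbles and keep them in a versioned key-value store whose keys
   are zero-padded, character-reversed PMIDs and which retains the three
   highest-timestamped versions per article, so nightly re-tagging never
   needs explicit deletes.
2. **Dictionaries** — compile OBO ontologies and tab-delimited gene tables
   into two-gazetteer matching dictionaries: case-sensitive surface forms
   (short or internally capitalized, e.g. gene symbols like `FIZZ3`) are
   matched verbatim; everything else is matched case-insensitively over
   **Snowball-stemmed** tokens (`"creatures"` → `"creatur"`), so plural or
   inflected text still hits the dictionary. The `is_a` hierarchy is
   compiled into a reflexive-transitive descendant index.
3. **Tagging** — offset-anchored annotation of titles, abstracts and MeSH
   headings with ontology concepts, organism names (rat / mouse / human,
   common and Latin), unnormalized gene mentions, and mutation patterns
   (`A123T`, `c.123A>G`, `p.Ala123Thr`, `rs12345`). Within a vocabulary the
   leftmost-longest match wins; across vocabularies overlaps are kept.
4. **Search** — an inverted index over stemmed text tokens and concept
   annotations. Queries are boolean AND-of-OR conditions whose clauses are
   expanded automatically: an ontology accession expands to itself plus all
   descendants; a gene id expands to symbol, name, synonyms and the same
   for every ortholog; gene clauses pull in a default rat/human/mouse
   species constraint. Results carry TF-IDF relevance scores
   (`coord · Σ_t √tf(t,d) · idf(t)² / √|d|`, `idf = 1 + ln(N/(df+1))`),
   facet counts that predict exactly how many results each refinement
   filter would leave, and chainable, order-independent concept/date
   filters.
5. **Curation log** — append-only curator events (read / import / add-term /
   full-text) that decorate results with read-by and annotation-aspect
   indicators so nobody re-reads an already-curated paper.

A deterministic fixture generator emits mini-ontologies, gene tables and
MEDLINE XML corpora with *planted, ground-truth-known* mentions, so the
whole pipeline is testable offline, without any downloads.

## Worked example

```r
library(conceptlit)

stem_token(c("creatures", "kidneys", "diseases"))
#> [1] "creatur" "kidney"  "diseas"

# a seeded world: ontology, gene table, and a 50-abstract corpus with
# planted mentions
ont   <- generate_mini_ontology(n_terms = 12, seed = 7)
terms <- parse_obo(ont$obo, "TST")
dict  <- compile_dictionary(terms, "TST")
org   <- organism_dictionary()
genes <- parse_gene_table(fixture_gene_table())
gdict <- compile_dictionary(genes, "gene", concept = "surface")
corpus   <- generate_corpus(generator_config(seed = 7, n_docs = 50),
                            list(dict), organism_dict = org, gene_dict = gdict)
articles <- parse_medline_xml(corpus$xml)

ann <- tag_corpus(articles, list(dict), organism_dict = org, gene_dict = gdict)
ann
#> # A tibble: 293 × 7
#>    pmid concept_id      vocabulary field    start   end matched_text
#>   <int> <chr>           <chr>      <chr>    <int> <int> <chr>
#> 1  1001 NCBITaxon:10116 organism   abstract   126   129 rat
#> 2  1001 TGFB9X          gene       abstract    62    68 TGFB9X
#> 3  1001 TGFB10L         gene       abstract    84    91 TGFB10L
#> 4  1002 TST:0000004     TST        abstract    30    60 inflammation sclerosis …
```

Every row is one mention: `substr(field, start + 1, end)` equals
`matched_text`, organism and concept mentions carry database accessions,
and gene mentions carry the matched surface form (gene mentions are
deliberately *not* normalized to gene ids — gene search goes through query
expansion instead).

```r
idx <- build_index(ann, articles)

# a gene-disease query as a curation tool would issue it: one ontology id,
# one gene id -- expansion is automatic
retn <- expand_gene_clause("RGD:628781", genes)
sort(retn$expansion)
#> [1] "ADSF"     "FIZZ3"    "resistin" "Retn"     "RSTN"     "XCP1"

cond <- apply_default_species(query_condition(
  expand_concept_clause("TST:0000002", dict), retn))
cond$species_filter
#> [1] "NCBITaxon:10116" "NCBITaxon:9606"  "NCBITaxon:10090"

out <- evaluate(cond, idx, list(dict, org))
out$results
#> # A tibble: 10 × 4
#>     pmid score pub_year matched_concepts
#>    <int> <dbl>    <int> <list>
#>  1  1004  4.33     2011 <tibble [1 × 2]>
#>  2  1010  3.68     2006 <tibble [2 × 2]>
#>  3  1021  3.41     2014 <tibble [1 × 2]>
#>  # … 7 more rows
out$facets
#> # A tibble: 34 × 3
#>   vocabulary concept_id  count
#>   <chr>      <chr>       <int>
#> 1 TST        TST:0000002    10
#> 2 TST        TST:0000005     7
#> 3 TST        TST:0000006     7
#> # … 31 more rows
```

Ten of the fifty abstracts satisfy both clauses and the species constraint,
ranked by relevance (ties break toward higher PMID, i.e. newer articles).
Each facet count is a promise: applying `concept_filter("TST:0000005")`
will leave exactly 7 results. `plot_facets(out$facets)` draws the filter
zone; `sort_results(out$results, "pub_date")` re-sorts by year.

A command-line front end wrapping the same functions lives at
`inst/cli/conceptlit.R` (subcommands `gen`, `load`, `build-dicts`, `tag`,
`index`, `query`, `log`).

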