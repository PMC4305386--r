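---
title: "Methods: dictionary tagging, query expansion and ranking in conceptlit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary tagging, query expansion and ranking in conceptlit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conceptlit)
```

`conceptlit` supports a biocuration triage workflow: tag MEDLINE abstracts
with the concepts a curator cares about, index them, and answer expanded,
filterable, ranked queries. This vignette explains the methods, the
parameters that matter, the numerical choices, and what the bundled
synthetic corpora do and do not establish about behavior on real text.

## The tagging model

Tagging is dictionary-based (gazetteer) named-entity recognition, not
statistical NER. The choice is deliberate: vocabularies at a curation
database change with every release, so tagging must be cheap to re-run and
its behavior must be exactly explainable from the dictionary contents. A
statistical gene tagger would add recall on novel names at the price of
unreproducible boundaries; here gene mentions are dictionary-marked and
carry their **surface form** as annotation id, never a gene database id.
Gene *search* therefore does not rely on mention normalization at all — it
goes through query-side expansion of a gene id into its symbol, name,
synonyms and orthologs' keywords.

### Case split

Every dictionary surface form is assigned to one of two gazetteers:

* **sensitive** — matched verbatim — when the form has 4 characters or
  fewer, or has an uppercase letter after its first character;
* **insensitive** — matched over lowercased, stemmed tokens — otherwise.

The rationale: short forms and mixed-case forms are overwhelmingly symbols
(`Retn`, `FIZZ3`, `XCP1`), and case-folding them collides with ordinary
words (*was* vs *WAS*). The threshold of 4 is a design choice, not a
measured quantity; it interacts with one known trade-off: a legitimate
short common word in a vocabulary (e.g. *rat* in the organism list) would
become case-sensitive and lose its plural. `compile_dictionary()` therefore
accepts a per-dictionary `case_class` override, and the bundled
`organism_dictionary()` forces all species names insensitive so that
*rats*/*Rats* both stem onto *rat*.

### Stemming

Both dictionary entries and article text go through the English Snowball
(Porter2) stemmer, implemented in `stem_token()` directly from the
published algorithm (regions R1/R2, steps 0–5, exceptional forms). Two
properties worth knowing:

* stemming is **not idempotent** (`diseases` → `diseas` → `disea`); the
  package always stems raw tokens exactly once, on both sides, so the
  asymmetry never matters;
* stems are not English words; they are only meaningful as join keys
  between text and dictionary.

### Matching semantics

`tokenize()` splits on anything that is not a letter or digit and reports
0-based, half-open character offsets; hyphens and slashes separate tokens.
Within one vocabulary the scan is **leftmost-longest**: at each position
the longest matching window (across both gazetteers) wins, the scan resumes
after it, and shorter overlapping matches are suppressed — this makes
occurrence counts well-defined. Matches from *different* vocabularies may
overlap freely, since a span can legitimately be both a disease concept and
a gene name. Concepts and organisms are tagged in title, abstract and the
MeSH field (headings joined with `" ; "` so offsets are stable); gene and
mutation tagging covers title and abstract only, because MeSH headings are
controlled vocabulary where free-text gene symbols and variant strings do
not occur.

### Mutation patterns

Three regex families, chosen to cover the notations common in the targeted
literature: protein substitution shorthand (`[A-Z]\d+[A-Z]`, so `T3` or
`CO2` never match), HGVS-like nucleotide and protein expressions
(`c.123A>G`, `c.76delA`, `p.Ala123Thr`, `p.Trp24*`), and dbSNP ids
(`rs\d+`). The matched text is the annotation id; no normalization across
notations is attempted. When families overlap on a span, the first family
wins.

## The article store

Articles are kept under zero-padded, character-reversed PMID keys. The
reversal spreads sequential PMIDs across the key space — the standard
load-balancing trick for ordered key-value stores — and the 9-digit
padding makes the mapping injective and uniform-width. Each key retains the
`max_versions` (default 3) highest-timestamped payloads ever written:
re-running a tagger or re-loading a nightly batch simply writes with a newer
timestamp and old versions age out; stale writes are counted
(`n_ignored_stale`), never errors. Reads return the max-timestamp payload.
Batches share a single timestamp, modeling nightly-run granularity. The
store is a single-node, JSON-lines-persisted emulation of a distributed
versioned column store; distribution itself is out of scope.

## Query evaluation and ranking

A query condition is an AND of clauses; each clause is an OR over its
expansion:

* **concept clause** — an accession plus its reflexive-transitive `is_a`
  descendants (other OBO relations are ignored by default; obsolete terms
  are excluded from hierarchy and matching);
* **gene clause** — symbol, name and synonyms of the gene and of every
  ortholog, deduplicated case-insensitively, matched as keywords;
* **keyword clause** — free text.

Keywords are matched against the stemmed text postings; a multiword keyword
requires all its stemmed tokens in the document (conjunctive token
semantics — a deliberate simplification over positional phrase search).
Gene keyword matching is case-insensitive; the symbol's case sensitivity
applies to *tagging*, not to *search*. A condition with a gene clause and no
explicit species gets the default rat/human/mouse constraint, implemented
through organism concept postings.

Relevance follows classic TF-IDF with coordination and inverse-square-root
length normalization:

$$\mathrm{score}(q,d) = \mathrm{coord}(q,d) \sum_{t}
\sqrt{tf(t,d)}\; \mathrm{idf}(t)^2 \;/\; \sqrt{|d|},
\qquad \mathrm{idf}(t) = 1 + \ln\frac{N}{df(t)+1}$$

where keyword clauses contribute one summand per distinct matching stemmed
token and concept clauses one per matching expansion concept with `tf` the
concept's occurrence count. The constants are fixed so that behavior is
deterministic and testable; note that the `+1` smoothing makes scores only
*approximately* invariant under exact corpus duplication (the n/df ratio
changes from $N/df$ to $2N/(2df+1)$), which is why the package's property
tests assert result-set invariance and per-document score equality rather
than identical orderings. Ties everywhere break by descending PMID,
favoring recent literature. Dates are tracked at year granularity because
PubMed month/day fields are frequently absent.

### Facets and filters

A facet `(c, k)` promises that applying the concept filter `c` leaves
exactly `k` results. Because a concept filter keeps documents tagged with
`c` *or any descendant*, the facet count is computed over the same closure
— otherwise the promise would break for non-leaf concepts. Facets are
reported per vocabulary (top 20 by default), sorted by count then id.
Filters form an ordered path for display, but evaluation is a pure
conjunction: any permutation of the same filters yields the same result
set, and removing a filter truncates the path at that node.

## The synthetic corpus generator

`generate_corpus()` emits PubMed article-set XML whose ground truth is
exact by construction:

* filler words come from a fixed list and are dropped if their stem
  collides with any dictionary token, so no unplanned window can match;
* planted surface forms are optionally plural-inflected, but only when the
  inflected form provably stems back onto the entry's tokens;
* planted units are interleaved so no two touch, preventing accidental
  longer matches across boundaries;
* species evidence is planted in the abstract or (30% of species-bearing
  documents) only as a MeSH heading, exercising the MeSH pathway;
* regex decoys (`T3`, `CO2`, `p53`, …) are always present; *collision
  mode* additionally injects case-flipped sensitive surfaces and single
  words of multiword names for negative testing.

Defaults (50 documents, 70% mention intensity, species mix 40% rat / 30%
human / 20% mouse / 10% none, 30% mutation-bearing) describe a small,
rat-dominated curation corpus. Test and acceptance runs use 200–300
document corpora and 20–25-term ontologies — sizes at which the exhaustive
oracles are still exact yet the suite runs in minutes on one core.

What passing these tests shows: the matcher, expansions, facets, filters,
store and scorer are *exactly* correct with respect to their specifications
on any input the generator can produce. What it does not show: recall on
real English (misspellings, abbreviations, hyphenation variants,
discontinuous mentions), robustness to malformed real-world XML beyond the
error paths tested, or retrieval quality of the scoring constants — those
are calibration questions that need curated relevance judgments, not
synthetic text.

## Numerical and degenerate-input choices

* `parse_medline_xml()` rejects citations without PMID or title (warning,
  skip) — downstream displays hinge on titles; missing abstracts become
  empty strings, missing months/days become `NA`.
* Publication years outside [1800, 2100] are treated as corruption and
  refused.
* Duplicate `(surface form, concept)` dictionary pairs collapse silently;
  duplicate surface forms across *different* concepts are kept and yield
  one annotation per concept on a match.
* An accidental `is_a` cycle would be broken at the revisited node rather
  than looping (a guard in the closure computation); well-formed ontologies
  never trigger it.
* Scores are compared to the straight-line oracle at 1e-9 relative
  tolerance; observed agreement is at machine precision (~2e-16).
* The store accepts equal-timestamp rewrites by overwriting that version's
  payload, mirroring cell-overwrite semantics of versioned column stores.

## Known limitations

* Dictionary matching cannot find mentions absent from the vocabulary; the
  statistical gene tagger it stands in for would.
* Conjunctive keyword semantics can over-match multiword names whose words
  appear far apart in an abstract.
* The mutation grammar covers the three families above only — structural
  variants, IVS notation and protein deletions are not recognized.
* MeSH hierarchy is not modeled; MeSH terms participate as flat text.
* One process, in-memory index: the design target is a curation group's
  corpus slice, not all of MEDLINE.
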