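#' Deterministic fixture generators
#'
#' Every other module of the package is exercised against corpora generated
#' here: mini-ontologies, gene tables and MEDLINE XML article sets with
#' *planted*, ground-truth-known concept, organism, gene and mutation
#' mentions. Filler words are drawn from a fixed list kept disjoint (after
#' stemming) from every dictionary token, so on a generated corpus the set
#' of true mentions is exactly the planted set.
#'
#' @name fixtures
NULL

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.term_name_words <- c(
  "renal", "cortical", "fibrosis", "glomerular", "tubular", "nephropathy",
  "cystic", "chronic", "vascular", "hepatic", "cardiac", "ischemic",
  "necrosis", "atrophy", "sclerosis", "dysplasia", "stenosis", "hypertrophy",
  "lesion", "carcinoma", "adenoma", "inflammation", "degeneration", "edema",
  "thrombosis", "hyperplasia", "amyloidosis", "dystrophy", "infarction",
  "nephritis"
)

.filler_words <- c(
  "study", "results", "analysis", "observed", "measured", "levels",
  "treatment", "control", "significant", "increase", "decrease", "effect",
  "tissue", "protein", "expression", "pathway", "response", "method",
  "model", "data", "group", "compared", "baseline", "outcome", "subjects",
  "samples", "assay", "experiment", "evidence", "reported", "after",
  "during", "between", "within", "showed", "suggests", "findings",
  "approach", "performed", "collected"
)

.gene_name_words <- c(
  "resistance", "transporter", "channel", "receptor", "kinase",
  "phosphatase", "ligase", "transferase", "oxidase", "reductase",
  "binding", "factor", "subunit", "homolog", "member"
)

.mesh_fillers <- c("Longitudinal Studies", "Biomarkers", "Cohort Studies",
                   "Immunohistochemistry")

.decoy_tokens <- c("T3", "T4", "CO2", "IL6", "p53", "rs", "5HT")

#' Generator configuration
#'
#' Bundles the knobs of the corpus generator. Defaults describe a small but
#' realistic curation corpus: most abstracts carry a taggable concept, rat
#' literature dominates, and roughly a third of abstracts mention a variant.
#'
#' @param seed integer RNG seed; everything generated from one config is
#'   byte-identical across runs.
#' @param n_docs number of citations.
#' @param n_terms ontology size used by [generate_mini_ontology()].
#' @param ontology_depth maximum is_a depth of the generated ontology.
#' @param mention_rate per-document, per-dictionary planting intensity in
#'   \[0, 1\] (0 plants nothing).
#' @param species_mix named probabilities over taxon accessions plus
#'   `"none"`; must sum to 1.
#' @param mutation_rate probability that a document carries planted mutation
#'   strings.
#' @param collision_mode when TRUE, near-miss decoys (case variants of
#'   case-sensitive surfaces, single words of multiword names) are injected
#'   for negative testing.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_docs = 50L, n_terms = 20L,
                             ontology_depth = 4L, mention_rate = 0.7,
                             species_mix = c("NCBITaxon:10116" = 0.4,
                                             "NCBITaxon:9606" = 0.3,
                                             "NCBITaxon:10090" = 0.2,
                                             none = 0.1),
                             mutation_rate = 0.3,
                             collision_mode = FALSE) {
  stopifnot(n_docs >= 1, n_terms >= 1, mention_rate >= 0, mention_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            abs(sum(species_mix) - 1) < 1e-9)
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 n_terms = as.integer(n_terms),
                 ontology_depth = as.integer(ontology_depth),
                 mention_rate = mention_rate, species_mix = species_mix,
                 mutation_rate = mutation_rate,
                 collision_mode = isTRUE(collision_mode)),
            class = "generator_config")
}

#' Generate a mini-ontology in OBO 1.2 format
#'
#' Builds a random is_a tree (with occasional extra edges, making a DAG) of
#' `n_terms` terms with unique multiword names and up to two synonyms each,
#' serialized as parseable OBO text. The edge list is returned as the oracle
#' for parser and closure tests.
#'
#' @param n_terms number of terms (>= 1).
#' @param seed RNG seed.
#' @param prefix accession prefix.
#' @param p_extra_edge probability a non-root node gets a second parent.
#' @param max_depth maximum is_a depth.
#' @return list with `obo` (text), `edges` (tibble `child`, `parent`) and
#'   `terms` (tibble as from [parse_obo()]).
#' @export
generate_mini_ontology <- function(n_terms, seed = 1L, prefix = "TST",
                                   p_extra_edge = 0.2, max_depth = 4L) {
  stopifnot(n_terms >= 1)
  local_seed(seed, {
    acc <- sprintf("%s:%07d", prefix, seq_len(n_terms))
    used <- character()
    fresh_surface <- function(n_words) {
      repeat {
        s <- paste(sample(.term_name_words, n_words), collapse = " ")
        if (!s %in% used) {
          used <<- c(used, s)
          return(s)
        }
      }
    }
    names_ <- vapply(seq_len(n_terms), function(i) {
      fresh_surface(sample(2:3, 1))
    }, character(1))
    synonyms <- lapply(seq_len(n_terms), function(i) {
      k <- sample(0:2, 1)
      if (k == 0) return(character())
      vapply(seq_len(k), function(j) fresh_surface(2), character(1))
    })
    depth <- integer(n_terms)
    parents <- vector("list", n_terms)
    edges <- list()
    for (i in seq_len(n_terms)[-1]) {
      eligible <- which(depth[seq_len(i - 1)] < max(1L, max_depth))
      p1 <- sample(eligible, 1)
      parents[[i]] <- acc[p1]
      depth[i] <- depth[p1] + 1L
      if (i > 2 && stats::runif(1) < p_extra_edge) {
        p2 <- sample(setdiff(seq_len(i - 1), p1), 1)
        parents[[i]] <- unique(c(parents[[i]], acc[p2]))
      }
      for (p in parents[[i]]) {
        edges[[length(edges) + 1L]] <- c(acc[i], p)
      }
    }
    stanzas <- vapply(seq_len(n_terms), function(i) {
      lines <- c("[Term]", paste0("id: ", acc[i]), paste0("name: ", names_[i]))
      for (s in synonyms[[i]]) {
        lines <- c(lines, sprintf('synonym: "%s" EXACT []', s))
      }
      for (p in parents[[i]]) {
        lines <- c(lines, sprintf("is_a: %s ! %s", p, names_[match(p, acc)]))
      }
      paste(lines, collapse = "\n")
    }, character(1))
    obo <- paste0("format-version: 1.2\n\n",
                  paste(stanzas, collapse = "\n\n"), "\n")
    edges_tbl <- if (length(edges)) {
      tibble::tibble(child = vapply(edges, `[[`, character(1), 1),
                     parent = vapply(edges, `[[`, character(1), 2))
    } else {
      tibble::tibble(child = character(), parent = character())
    }
    terms <- tibble::tibble(accession = acc, name = names_,
                            synonyms = synonyms, parents = parents2list(parents),
                            is_obsolete = FALSE)
    list(obo = obo, edges = edges_tbl, terms = terms)
  })
}

parents2list <- function(parents) {
  lapply(parents, function(p) if (is.null(p)) character() else p)
}

#' Bundled gene-table fixture
#'
#' A tab-delimited gene table containing the resistin record (`RGD:628781`,
#' symbol `Retn`, name `resistin`, synonyms `ADSF|RSTN|XCP1|FIZZ3`) plus
#' seeded random genes, some with ortholog links into the table.
#'
#' @param n_random number of random genes added.
#' @param seed RNG seed.
#' @return the gene table as a single TSV string.
#' @export
fixture_gene_table <- function(n_random = 10L, seed = 42L) {
  local_seed(seed, {
    header <- "gene_id\tsymbol\tname\tsynonyms\tortholog_ids"
    retn <- "RGD:628781\tRetn\tresistin\tADSF|RSTN|XCP1|FIZZ3\t"
    roots <- c("Abcb", "Slc", "Cyp", "Nfk", "Tgfb", "Col", "Myh", "Pax",
               "Wnt", "Fgf", "Egfr", "Kcn")
    ids <- sprintf("RGD:%d", 100000L + sample.int(899999L, n_random))
    rows <- character(n_random)
    symbols <- character(n_random)
    for (i in seq_len(n_random)) {
      symbols[i] <- paste0(sample(roots, 1), i)
      name <- paste(sample(.gene_name_words, 2), collapse = " ")
      syn <- if (stats::runif(1) < 0.6) {
        paste(toupper(paste0(symbols[i], sample(c("L", "X", "R"), 1))),
              sep = "")
      } else ""
      orth <- if (i > 2 && stats::runif(1) < 0.4) {
        paste(ids[sample(i - 1, 1)], collapse = "|")
      } else ""
      rows[i] <- paste(ids[i], symbols[i], name, syn, orth, sep = "\t")
    }
    paste(c(header, retn, rows), collapse = "\n")
  })
}

# candidate surfaces of one dictionary, with optional plural inflection that
# provably stems back onto the entry's match tokens
plant_surface <- function(dictionary, inflect) {
  e <- dictionary$entries[sample.int(nrow(dictionary$entries), 1), ]
  surface <- e$surface_form
  if (inflect && e$case_class == "insensitive" && stats::runif(1) < 0.4) {
    plural <- paste0(surface, "s")
    toks <- stem_token(tolower(tokenize_text(plural)))
    if (identical(toks, e$match_tokens[[1]])) surface <- plural
  }
  list(surface = surface, concept_id = e$concept_id,
       vocabulary = e$vocabulary)
}

mutation_string <- function() {
  aa <- c("Ala", "Arg", "Gly", "Thr", "Ser", "Leu", "Val", "Trp")
  kind <- sample(4, 1)
  switch(kind,
    sprintf("%s%d%s", sample(LETTERS, 1), sample(30:999, 1), sample(LETTERS, 1)),
    sprintf("rs%d", sample(1000:9999999, 1)),
    sprintf("c.%d%s>%s", sample(10:999, 1), sample(c("A", "C", "G", "T"), 1),
            sample(c("A", "C", "G", "T"), 1)),
    sprintf("p.%s%d%s", sample(aa, 1), sample(10:999, 1), sample(aa, 1))
  )
}

# interleave planted units between fillers so no two planted units touch
interleave_units <- function(fillers, planted) {
  k <- length(fillers)
  n <- length(planted)
  if (n == 0) {
    return(tibble::tibble(text = fillers, planted = FALSE,
                          concept_id = NA_character_,
                          vocabulary = NA_character_))
  }
  gaps <- sort(sample.int(k - 1L, n))
  units <- list()
  prev <- 0L
  for (g in seq_along(gaps)) {
    units <- c(units, as.list(fillers[(prev + 1L):gaps[g]]),
               list(planted[[g]]))
    prev <- gaps[g]
  }
  units <- c(units, as.list(fillers[(prev + 1L):k]))
  tibble::tibble(
    text = vapply(units, function(u) if (is.list(u)) u$surface else u,
                  character(1)),
    planted = vapply(units, is.list, logical(1)),
    concept_id = vapply(units, function(u) {
      if (is.list(u)) u$concept_id else NA_character_
    }, character(1)),
    vocabulary = vapply(units, function(u) {
      if (is.list(u)) u$vocabulary else NA_character_
    }, character(1))
  )
}

assemble_field <- function(units) {
  n <- nrow(units)
  width <- nchar(units$text)
  start <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    start[i] <- pos
    pos <- pos + width[i] + 1L
  }
  units$start <- start
  units$end <- start + width
  units$field_text <- paste(units$text, collapse = " ")
  units
}

# filler words whose stems collide with any dictionary token are dropped so
# that exact-recovery oracles hold
safe_fillers <- function(dictionaries) {
  banned <- unique(unlist(lapply(dictionaries, function(d) {
    unlist(d$entries$match_tokens)
  })))
  ok <- !(stem_token(tolower(.filler_words)) %in% banned) &
    !(tolower(.filler_words) %in% tolower(banned))
  .filler_words[ok]
}

collision_decoys <- function(dictionaries) {
  out <- character()
  for (d in dictionaries) {
    sens <- d$entries$surface_form[d$entries$case_class == "sensitive"]
    if (length(sens)) {
      flip <- ifelse(sens == tolower(sens), toupper(sens), tolower(sens))
      out <- c(out, flip)
    }
    multi <- d$entries[lengths(d$entries$match_tokens) > 1, ]
    words <- unique(unlist(lapply(multi$surface_form, tokenize_text)))
    keys <- unique(d$entries$key)
    words <- words[!stem_token(tolower(words)) %in% keys & !words %in% keys]
    out <- c(out, words)
  }
  unique(out)
}

#' Generate a MEDLINE XML corpus with planted, ground-truth-known mentions
#'
#' Each citation is filler text with dictionary surface forms (optionally
#' plural-inflected so they only match via stemming), species words,
#' mutation strings and regex decoys planted at recorded character offsets.
#' Species evidence sometimes appears only as a MeSH heading. The returned
#' ground truth is exact: on the emitted corpus the true annotation set of
#' each tagging pipeline equals the planted set.
#'
#' @param config a [generator_config()].
#' @param dictionaries list of compiled concept dictionaries (may be empty).
#' @param organism_dict optional organism dictionary for species planting.
#' @param gene_dict optional gene dictionary (compiled with
#'   `concept = "surface"`) for gene-mention planting.
#' @return list with `xml` (article-set XML text), `articles` (the article
#'   tibble the XML encodes), `mentions` (tibble `pmid`, `field`, `start`,
#'   `end`, `concept_id`, `vocabulary`, `matched_text` covering concept,
#'   organism and gene plantings), `mutations` (same shape, vocabulary
#'   `"mutation"`) and `species` (tibble `pmid`, `taxon`).
#' @export
generate_corpus <- function(config, dictionaries = list(),
                            organism_dict = NULL, gene_dict = NULL) {
  stopifnot(inherits(config, "generator_config"))
  all_dicts <- c(dictionaries,
                 if (!is.null(organism_dict)) list(organism_dict),
                 if (!is.null(gene_dict)) list(gene_dict))
  fillers <- safe_fillers(all_dicts)
  decoy_pool <- .decoy_tokens
  if (config$collision_mode && length(all_dicts)) {
    decoy_pool <- c(decoy_pool, collision_decoys(all_dicts))
  }
  local_seed(config$seed, {
    pmids <- 1000L + seq_len(config$n_docs)
    journals <- c("J Renal Res", "Exp Physiol Rep", "Mol Curation")
    arts <- vector("list", config$n_docs)
    mentions <- list()
    mutations <- list()
    species <- list()
    for (di in seq_len(config$n_docs)) {
      pmid <- pmids[di]
      planted_abs <- list()
      # concept / gene plantings
      for (d in c(dictionaries, if (!is.null(gene_dict)) list(gene_dict))) {
        k <- stats::rbinom(1, 3, config$mention_rate)
        for (j in seq_len(k)) {
          planted_abs <- c(planted_abs, list(plant_surface(d, inflect = TRUE)))
        }
      }
      # species planting
      taxon <- sample(names(config$species_mix), 1, prob = config$species_mix)
      mesh_species <- NULL
      if (taxon != "none" && !is.null(organism_dict)) {
        species[[length(species) + 1L]] <- tibble::tibble(pmid = pmid,
                                                          taxon = taxon)
        cand <- organism_dict$entries[
          organism_dict$entries$concept_id == taxon, ]
        pick <- cand[sample.int(nrow(cand), 1), ]
        if (stats::runif(1) < 0.3) {
          # species evidence only in the MeSH field (the Latin name heading)
          latin <- cand$surface_form[which.max(nchar(cand$surface_form))]
          mesh_species <- list(surface = latin, concept_id = taxon,
                               vocabulary = "organism")
        } else {
          planted_abs <- c(planted_abs, list(list(
            surface = pick$surface_form, concept_id = taxon,
            vocabulary = "organism")))
        }
      }
      # mutation planting + decoys
      mut_strings <- character()
      if (stats::runif(1) < config$mutation_rate) {
        mut_strings <- vapply(seq_len(sample(1:2, 1)),
                              function(i) mutation_string(), character(1))
        for (m in mut_strings) {
          planted_abs <- c(planted_abs, list(list(
            surface = m, concept_id = m, vocabulary = "mutation")))
        }
      }
      n_decoys <- sample(0:2, 1)
      decoys <- sample(decoy_pool, n_decoys)
      planted_abs <- sample(planted_abs)
      n_fill <- max(18L, 2L * (length(planted_abs) + n_decoys) + 4L)
      abs_fillers <- c(sample(fillers, n_fill, replace = TRUE), decoys)
      abs_fillers <- sample(abs_fillers)
      abs_units <- assemble_field(interleave_units(abs_fillers, planted_abs))
      title_words <- sample(fillers, sample(3:6, 1), replace = TRUE)
      title_words[1] <- paste0(toupper(substr(title_words[1], 1, 1)),
                               substring(title_words[1], 2))
      title <- paste(title_words, collapse = " ")
      mesh <- sample(.mesh_fillers, sample(0:2, 1))
      if (!is.null(mesh_species)) {
        mesh <- c(mesh, mesh_species$surface)
      }
      # ground-truth rows
      pl <- abs_units[abs_units$planted, ]
      if (nrow(pl)) {
        gt <- tibble::tibble(pmid = pmid, field = "abstract",
                             start = pl$start, end = pl$end,
                             concept_id = pl$concept_id,
                             vocabulary = pl$vocabulary,
                             matched_text = pl$text)
        mentions[[length(mentions) + 1L]] <- gt[gt$vocabulary != "mutation", ]
        mutations[[length(mutations) + 1L]] <- gt[gt$vocabulary == "mutation", ]
      }
      if (!is.null(mesh_species)) {
        mesh_text <- paste(mesh, collapse = " ; ")
        s <- regexpr(mesh_species$surface, mesh_text, fixed = TRUE)
        mentions[[length(mentions) + 1L]] <- tibble::tibble(
          pmid = pmid, field = "mesh", start = as.integer(s) - 1L,
          end = as.integer(s) - 1L + nchar(mesh_species$surface),
          concept_id = mesh_species$concept_id, vocabulary = "organism",
          matched_text = mesh_species$surface
        )
      }
      arts[[di]] <- tibble::tibble(
        pmid = pmid, title = title, abstract = abs_units$field_text[1],
        mesh_terms = list(mesh),
        year = sample(1990:2024, 1),
        month = if (stats::runif(1) < 0.6) sample(1:12, 1) else NA_integer_,
        day = NA_integer_,
        journal = sample(journals, 1)
      )
      if (stats::runif(1) < 0.3) arts[[di]]$day <- sample(1:28, 1)
    }
    articles <- dplyr::bind_rows(arts)
    list(
      xml = write_medline_xml(articles),
      articles = articles,
      mentions = if (length(mentions)) dplyr::bind_rows(mentions)
                 else empty_annotations()[, c("pmid", "field", "start", "end",
                                              "concept_id", "vocabulary",
                                              "matched_text")],
      mutations = if (length(mutations)) dplyr::bind_rows(mutations)
                  else empty_annotations()[, c("pmid", "field", "start", "end",
                                               "concept_id", "vocabulary",
                                               "matched_text")],
      species = if (length(species)) dplyr::bind_rows(species)
                else tibble::tibble(pmid = integer(), taxon = character())
    )
  })
}
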