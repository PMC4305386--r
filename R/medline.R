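#' Parse MEDLINE/PubMed article-set XML into an article tibble
#'
#' Reads the NLM `PubmedArticleSet` dialect (as distributed by PubMed) and
#' returns one row per citation, in document order. Only the fields the
#' downstream tagging pipeline consumes are kept: PMID, title, abstract,
#' MeSH descriptor names, publication date and journal title.
#'
#' Citations without a PMID are skipped with a warning; citations without a
#' title are rejected with a warning, since every curation display hinges on
#' the title. A missing abstract yields `abstract = ""`.
#'
#' @param source path to an XML file, or a single string of XML.
#' @return A tibble with columns `pmid` (integer), `title`, `abstract`
#'   (character), `mesh_terms` (list of character), `year`, `month`, `day`
#'   (integers, month/day possibly `NA`), `journal` (character).
#' @export
parse_medline_xml <- function(source) {
  doc <- tryCatch(
    xml2::read_xml(source),
    error = function(e) {
      stop("malformed MEDLINE XML: ", conditionMessage(e), call. = FALSE)
    }
  )
  citations <- xml2::xml_find_all(doc, ".//MedlineCitation")
  rows <- purrr::map(citations, parse_citation_node)
  rows <- purrr::compact(rows)
  out <- if (length(rows) == 0) empty_article_tibble() else dplyr::bind_rows(rows)
  validate_articles(out)
  out
}

parse_citation_node <- function(cit) {
  pmid_txt <- xml2::xml_text(xml2::xml_find_first(cit, "./PMID"))
  pmid <- suppressWarnings(as.integer(pmid_txt))
  if (is.na(pmid) || pmid <= 0) {
    warning("citation without a valid PMID skipped", call. = FALSE)
    return(NULL)
  }
  title <- xml2::xml_text(xml2::xml_find_first(cit, "./Article/ArticleTitle"))
  if (is.na(title) || !nzchar(title)) {
    warning("citation ", pmid, " has no title; rejected", call. = FALSE)
    return(NULL)
  }
  abs_nodes <- xml2::xml_find_all(cit, "./Article/Abstract/AbstractText")
  abstract <- paste(xml2::xml_text(abs_nodes), collapse = " ")
  mesh <- xml2::xml_text(
    xml2::xml_find_all(cit, "./MeshHeadingList/MeshHeading/DescriptorName")
  )
  pd <- xml2::xml_find_first(cit, "./Article/Journal/JournalIssue/PubDate")
  year <- suppressWarnings(as.integer(xml2::xml_text(xml2::xml_find_first(pd, "./Year"))))
  month <- suppressWarnings(as.integer(xml2::xml_text(xml2::xml_find_first(pd, "./Month"))))
  day <- suppressWarnings(as.integer(xml2::xml_text(xml2::xml_find_first(pd, "./Day"))))
  journal <- xml2::xml_text(xml2::xml_find_first(cit, "./Article/Journal/Title"))
  tibble::tibble(
    pmid = pmid, title = title, abstract = abstract,
    mesh_terms = list(mesh),
    year = year, month = month, day = day,
    journal = if (is.na(journal)) "" else journal
  )
}

empty_article_tibble <- function() {
  tibble::tibble(
    pmid = integer(), title = character(), abstract = character(),
    mesh_terms = list(), year = integer(), month = integer(),
    day = integer(), journal = character()
  )
}

validate_articles <- function(articles) {
  if (nrow(articles) == 0) return(invisible(articles))
  if (anyDuplicated(articles$pmid)) {
    stop("duplicate PMIDs within one parsed batch", call. = FALSE)
  }
  bad_year <- !is.na(articles$year) & (articles$year < 1800 | articles$year > 2100)
  if (any(bad_year)) {
    stop("publication year outside [1800, 2100] for PMID ",
         articles$pmid[which(bad_year)[1]], call. = FALSE)
  }
  invisible(articles)
}

#' Serialize an article tibble as PubMed article-set XML
#'
#' The inverse of [parse_medline_xml()]: emits a `PubmedArticleSet` document
#' that parses back field-for-field. Used by the fixture generator and as the
#' article-store payload format.
#'
#' @param articles article tibble as returned by [parse_medline_xml()].
#' @param path optional file path; when given the XML is written there.
#' @return The XML as a single string (invisibly when `path` is given).
#' @export
write_medline_xml <- function(articles, path = NULL) {
  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(articles))) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", as.character(articles$pmid[i]))
    a <- xml2::xml_add_child(cit, "Article")
    jr <- xml2::xml_add_child(a, "Journal")
    xml2::xml_add_child(jr, "Title", articles$journal[i])
    ji <- xml2::xml_add_child(jr, "JournalIssue")
    pd <- xml2::xml_add_child(ji, "PubDate")
    if (!is.na(articles$year[i])) {
      xml2::xml_add_child(pd, "Year", as.character(articles$year[i]))
    }
    if (!is.na(articles$month[i])) {
      xml2::xml_add_child(pd, "Month", as.character(articles$month[i]))
    }
    if (!is.na(articles$day[i])) {
      xml2::xml_add_child(pd, "Day", as.character(articles$day[i]))
    }
    xml2::xml_add_child(a, "ArticleTitle", articles$title[i])
    if (nzchar(articles$abstract[i])) {
      ab <- xml2::xml_add_child(a, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", articles$abstract[i])
    }
    mesh <- articles$mesh_terms[[i]]
    if (length(mesh)) {
      ml <- xml2::xml_add_child(cit, "MeshHeadingList")
      for (m in mesh) {
        mh <- xml2::xml_add_child(ml, "MeshHeading")
        xml2::xml_add_child(mh, "DescriptorName", m)
      }
    }
  }
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Text of one taggable field of an article
#'
#' The tagger and indexer address three fields per article: `title`,
#' `abstract` and `mesh`. MeSH descriptor names are joined with `" ; "` so
#' the mesh field is one string with stable character offsets.
#'
#' @param article one-row article tibble.
#' @param field `"title"`, `"abstract"` or `"mesh"`.
#' @return a single string (possibly empty).
#' @export
article_field_text <- function(article, field) {
  switch(field,
    title = article$title[[1]],
    abstract = article$abstract[[1]],
    mesh = paste(article$mesh_terms[[1]], collapse = " ; "),
    stop("unknown field: ", field, call. = FALSE)
  )
}

article_fields <- c("title", "abstract", "mesh")
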