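#' Create a curation event log
#'
#' Curator interactions — opening an abstract (`read`), importing an article
#' (`import`), bucketing a term (`add_term`), accessing full text
#' (`fulltext`) — are recorded as an append-only event stream, optionally
#' persisted as a JSON-lines file.
#'
#' @param path optional JSON-lines file; existing events are loaded and new
#'   ones appended.
#' @return a `curation_log` object.
#' @export
curation_log <- function(path = NULL) {
  events <- empty_events()
  if (!is.null(path) && file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    rows <- lapply(lines[nzchar(lines)], function(l) {
      e <- jsonlite::fromJSON(l)
      tibble::tibble(
        event_kind = e$event_kind, pmid = as.integer(e$pmid),
        curator = e$curator, timestamp = as.numeric(e$timestamp),
        concept_id = if (is.null(e$concept_id)) NA_character_ else e$concept_id
      )
    })
    if (length(rows)) events <- dplyr::bind_rows(rows)
  }
  structure(list(events = events, path = path), class = "curation_log")
}

empty_events <- function() {
  tibble::tibble(event_kind = character(), pmid = integer(),
                 curator = character(), timestamp = numeric(),
                 concept_id = character())
}

#' Append one curation event
#'
#' @param log a `curation_log`.
#' @param event_kind one of `"read"`, `"import"`, `"add_term"`,
#'   `"fulltext"`.
#' @param pmid article PMID.
#' @param curator curator name.
#' @param timestamp epoch seconds.
#' @param concept_id required for `add_term` events, ignored otherwise.
#' @return the updated log.
#' @export
log_event <- function(log, event_kind, pmid, curator, timestamp,
                      concept_id = NA_character_) {
  stopifnot(inherits(log, "curation_log"))
  event_kind <- match.arg(event_kind, c("read", "import", "add_term", "fulltext"))
  if (event_kind == "add_term" && (is.na(concept_id) || !nzchar(concept_id))) {
    stop("add_term events require a concept_id", call. = FALSE)
  }
  row <- tibble::tibble(event_kind = event_kind, pmid = as.integer(pmid),
                        curator = curator, timestamp = as.numeric(timestamp),
                        concept_id = concept_id)
  log$events <- dplyr::bind_rows(log$events, row)
  if (!is.null(log$path)) {
    con <- file(log$path, open = "a")
    on.exit(close(con))
    writeLines(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), con)
  }
  log
}

#' Most recent reader of an article
#'
#' @param log a `curation_log`.
#' @param pmid article PMID.
#' @return one-row tibble `curator`, `timestamp` (the latest read event), or
#'   `NULL` when the article was never read.
#' @export
read_by <- function(log, pmid) {
  reads <- log$events[log$events$event_kind == "read" &
                        log$events$pmid == pmid, ]
  if (nrow(reads) == 0) return(NULL)
  top <- reads[which.max(reads$timestamp), ]
  tibble::tibble(curator = top$curator, timestamp = top$timestamp)
}

#' Read a tab-delimited annotation store
#'
#' Three columns, no header: `pmid`, `aspect` (one-letter code, e.g. D for
#' disease, C/F/P for GO aspects), `concept_id`.
#'
#' @param path TSV file path.
#' @return tibble `pmid`, `aspect`, `concept_id`.
#' @export
read_annotation_store <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("pmid", "aspect", "concept_id"),
                          colClasses = c("integer", "character", "character"))
  tibble::as_tibble(df)
}

#' Decorate query results with curation indicators
#'
#' For each result: whether the article is already in the reference
#' database, the distinct aspect letters of its existing annotations
#' (e.g. `D` for disease, `C`/`F`/`P` for GO), and who last opened its
#' abstract. These are the signals that prevent unnecessary re-reading.
#'
#' @param results result tibble with a `pmid` column.
#' @param annotation_store tibble `pmid`, `aspect`, `concept_id`.
#' @param log a `curation_log`.
#' @return tibble `pmid`, `in_database`, `aspects` (list of character),
#'   `read_by_curator`, `read_by_timestamp`.
#' @export
decorate_results <- function(results, annotation_store, log) {
  purrr::map_dfr(results$pmid, function(p) {
    ann <- annotation_store[annotation_store$pmid == p, ]
    rb <- read_by(log, p)
    tibble::tibble(
      pmid = p,
      in_database = nrow(ann) > 0,
      aspects = list(sort(unique(ann$aspect))),
      read_by_curator = if (is.null(rb)) NA_character_ else rb$curator,
      read_by_timestamp = if (is.null(rb)) NA_real_ else rb$timestamp
    )
  })
}
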