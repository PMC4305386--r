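#' Reversed, zero-padded store key for a PMID
#'
#' PMIDs are rendered as 9-digit zero-padded decimals and character-reversed
#' before use as store keys. Reversal spreads sequentially assigned PMIDs
#' across the key space (the load-balancing trick of distributed key-value
#' stores); the fixed-width padding keeps the mapping injective and key
#' lengths uniform.
#'
#' @param pmid vector of positive integers below 10^9.
#' @return character vector of 9-character keys.
#' @examples
#' make_store_key(24716958) # "859617420"
#' @export
make_store_key <- function(pmid) {
  pmid <- as.numeric(pmid)
  if (any(is.na(pmid)) || any(pmid <= 0) || any(pmid >= 1e9)) {
    stop("pmid must be a positive integer below 10^9", call. = FALSE)
  }
  padded <- sprintf("%09d", as.integer(pmid))
  vapply(strsplit(padded, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Recover the PMID from a store key
#' @param key 9-character store key from [make_store_key()].
#' @return integer PMID.
#' @export
store_key_to_pmid <- function(key) {
  as.integer(vapply(strsplit(key, "", fixed = TRUE),
                    function(ch) paste(rev(ch), collapse = ""), character(1)))
}

#' Open (or create) a versioned article store
#'
#' A single-node, file-persisted key-value store emulating a versioned
#' column store: each key retains the `max_versions` highest-timestamped
#' payloads ever written, and reads return the payload with the maximum
#' timestamp. Payloads are single-citation MEDLINE XML strings.
#'
#' @param path optional path to a JSON-lines persistence file. When the file
#'   exists its entries are loaded; [store_save()] writes the store back.
#' @param max_versions number of timestamped versions retained per key.
#' @return an `article_store` object (environment-backed).
#' @export
article_store <- function(path = NULL, max_versions = 3L) {
  stopifnot(max_versions >= 1L)
  store <- new.env(parent = emptyenv())
  store$entries <- new.env(parent = emptyenv())
  store$max_versions <- as.integer(max_versions)
  store$path <- path
  class(store) <- "article_store"
  if (!is.null(path) && file.exists(path)) {
    for (line in readLines(path, warn = FALSE)) {
      if (!nzchar(line)) next
      e <- jsonlite::fromJSON(line, simplifyVector = FALSE)
      store$entries[[e$key]] <- list(
        timestamps = vapply(e$versions, function(v) as.numeric(v$timestamp), numeric(1)),
        payloads = vapply(e$versions, function(v) v$payload, character(1))
      )
    }
  }
  store
}

#' @export
print.article_store <- function(x, ...) {
  cat("<article_store> ", length(ls(x$entries)), " keys, max_versions = ",
      x$max_versions, "\n", sep = "")
  invisible(x)
}

#' Write one article into the store
#'
#' The write is compared by timestamp with the versions already held for the
#' article's key: it is retained iff its timestamp is among the
#' `max_versions` largest ever written for that key. Stale writes are
#' counted, never raised as errors.
#'
#' @param store an [article_store()].
#' @param record one-row article tibble.
#' @param timestamp integer epoch seconds for this write.
#' @return invisibly, a one-row tibble with counters `n_seen`, `n_new`,
#'   `n_replaced`, `n_ignored_stale` (exactly one of the last three is 1).
#' @export
put_article <- function(store, record, timestamp) {
  stopifnot(inherits(store, "article_store"), nrow(record) == 1)
  if (is.na(record$title) || !nzchar(record$title)) {
    # rejected records are counted among the ignored writes
    warning("record ", record$pmid, " has no title; not stored", call. = FALSE)
    return(invisible(update_stats(1L, 0L, 0L, 1L)))
  }
  key <- make_store_key(record$pmid)
  payload <- write_medline_xml(record)
  timestamp <- as.numeric(timestamp)
  cur <- store$entries[[key]]
  if (is.null(cur)) {
    store$entries[[key]] <- list(timestamps = timestamp, payloads = payload)
    return(invisible(update_stats(1L, 1L, 0L, 0L)))
  }
  replaced <- timestamp >= max(cur$timestamps)
  ts <- c(cur$timestamps, timestamp)
  pl <- c(cur$payloads, payload)
  # overwrite an existing cell at the same timestamp
  dup <- which(cur$timestamps == timestamp)
  if (length(dup)) {
    ts <- ts[-dup]
    pl <- pl[-dup]
  }
  ord <- order(ts, decreasing = TRUE)
  keep <- ord[seq_len(min(length(ord), store$max_versions))]
  store$entries[[key]] <- list(timestamps = ts[keep], payloads = pl[keep])
  if (replaced) {
    invisible(update_stats(1L, 0L, 1L, 0L))
  } else {
    invisible(update_stats(1L, 0L, 0L, 1L))
  }
}

update_stats <- function(n_seen, n_new, n_replaced, n_ignored_stale) {
  tibble::tibble(n_seen = n_seen, n_new = n_new,
                 n_replaced = n_replaced, n_ignored_stale = n_ignored_stale)
}

#' Read the latest version of an article
#'
#' @param store an [article_store()].
#' @param pmid positive integer.
#' @return a one-row article tibble (the max-timestamp payload, re-parsed),
#'   or `NULL` when the PMID was never written.
#' @export
get_article <- function(store, pmid) {
  stopifnot(inherits(store, "article_store"))
  key <- make_store_key(pmid)
  cur <- store$entries[[key]]
  if (is.null(cur)) return(NULL)
  payload <- cur$payloads[which.max(cur$timestamps)]
  rec <- tryCatch(parse_medline_xml(payload), error = function(e) {
    stop("corrupt payload for store key ", key, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (nrow(rec) != 1) stop("corrupt payload for store key ", key, call. = FALSE)
  rec
}

#' Retained versions for a PMID
#' @param store an [article_store()].
#' @param pmid positive integer.
#' @return tibble with `timestamp` (descending) and `payload` columns.
#' @export
store_versions <- function(store, pmid) {
  cur <- store$entries[[make_store_key(pmid)]]
  if (is.null(cur)) {
    return(tibble::tibble(timestamp = numeric(), payload = character()))
  }
  ord <- order(cur$timestamps, decreasing = TRUE)
  tibble::tibble(timestamp = cur$timestamps[ord], payload = cur$payloads[ord])
}

#' PMIDs currently held in the store
#' @param store an [article_store()].
#' @return sorted integer vector of PMIDs.
#' @export
store_pmids <- function(store) {
  sort(store_key_to_pmid(ls(store$entries)))
}

#' Apply a nightly-style batch update
#'
#' Writes every record of a parsed batch under one batch timestamp and
#' partitions the batch into new, replaced and stale writes.
#'
#' @param store an [article_store()].
#' @param records article tibble (possibly empty).
#' @param timestamp integer epoch seconds for the whole batch.
#' @return one-row tibble of counters; `n_seen = n_new + n_replaced +
#'   n_ignored_stale`.
#' @export
incremental_update <- function(store, records, timestamp) {
  stats <- update_stats(0L, 0L, 0L, 0L)
  for (i in seq_len(nrow(records))) {
    stats <- stats + put_article(store, records[i, ], timestamp)
  }
  tibble::as_tibble(stats)
}

#' Persist the store to its JSON-lines file
#' @param store an [article_store()].
#' @param path optional override of the path given to [article_store()].
#' @return the path, invisibly.
#' @export
store_save <- function(store, path = NULL) {
  path <- path %||% store$path
  if (is.null(path)) stop("no persistence path set for this store", call. = FALSE)
  keys <- sort(ls(store$entries))
  lines <- vapply(keys, function(k) {
    cur <- store$entries[[k]]
    ord <- order(cur$timestamps, decreasing = TRUE)
    jsonlite::toJSON(list(
      key = k,
      versions = purrr::map(ord, function(i) {
        list(timestamp = cur$timestamps[i], payload = cur$payloads[i])
      })
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
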