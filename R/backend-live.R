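# Live E-utilities client. Requests are plain URLs against the esearch/
# elink/esummary/efetch/einfo endpoints; responses are XML. The transport
# is pluggable: the default opens HTTP connections with rate limiting and
# exponential backoff, and a replay transport serving recorded XML
# documents exercises the identical parsing path offline.

#' Build an E-utilities request URL
#'
#' @param base_url Endpoint base, e.g.
#'   `https://eutils.ncbi.nlm.nih.gov/entrez/eutils`.
#' @param endpoint One of `esearch`, `elink`, `esummary`, `efetch`, `einfo`.
#' @param params Named list of query parameters; `NULL` entries dropped.
#' @return The request URL string.
#' @export
eutils_url <- function(base_url, endpoint, params = list()) {
  params <- params[!vapply(params, is.null, logical(1))]
  q <- paste(sprintf("%s=%s", names(params),
                     vapply(params, function(v)
                       utils::URLencode(as.character(v), reserved = TRUE),
                       character(1))),
             collapse = "&")
  sprintf("%s/%s.fcgi%s", sub("/$", "", base_url), endpoint,
          if (nzchar(q)) paste0("?", q) else "")
}

#' Default HTTP transport
#'
#' Fetches a URL with a minimum inter-request delay and exponential
#' backoff on failure.
#'
#' @param min_delay Minimum seconds between requests (default 1/3 s,
#'   the documented public-etiquette rate of 3 requests/second).
#' @param retries Retry attempts on transport failure.
#' @return A function `url -> response text`.
#' @export
http_transport <- function(min_delay = 1 / 3, retries = 3) {
  last <- 0
  function(url) {
    wait <- min_delay - (as.numeric(Sys.time()) - last)
    if (wait > 0) Sys.sleep(wait)
    for (attempt in seq_len(retries + 1)) {
      res <- tryCatch({
        con <- url(url, open = "rb")
        on.exit(close(con), add = TRUE)
        paste(readLines(con, warn = FALSE), collapse = "\n")
      }, error = function(e) e)
      last <<- as.numeric(Sys.time())
      if (!inherits(res, "error")) return(res)
      if (attempt > retries)
        stop(sprintf("transport error after %d attempt(s): %s",
                     attempt, conditionMessage(res)), call. = FALSE)
      Sys.sleep(min_delay * 2^attempt)
    }
  }
}

#' Replay transport over recorded responses
#'
#' Serves recorded XML documents keyed by request URL, so the live
#' client's URL construction and XML parsing run without a network.
#'
#' @param responses Named list: request URL -> response text.
#' @return A function `url -> response text`; unknown URLs error.
#' @export
replay_transport <- function(responses) {
  function(url) {
    if (is.null(responses[[url]]))
      stop(sprintf("replay transport: no recorded response for %s", url),
           call. = FALSE)
    responses[[url]]
  }
}

#' Live E-utilities backend
#'
#' @param base_url Endpoint base URL.
#' @param registry The `entrez_registry` this endpoint serves (used for
#'   link validation); may be built first via [build_registry()] from
#'   documents fetched over the same transport.
#' @param transport A `url -> text` function; defaults to
#'   [http_transport()].
#' @param retmax Page size for UID list retrieval.
#' @return A `live_backend` implementing the backend operation contract.
#' @export
live_backend <- function(base_url, registry = NULL,
                         transport = http_transport(), retmax = 500) {
  be <- new.env(parent = emptyenv())
  be$base_url <- base_url
  be$registry <- registry
  be$transport <- transport
  be$retmax <- retmax
  be$log <- list()
  class(be) <- c("live_backend", "entrez_backend")
  be
}

#' @export
backend_registry.live_backend <- function(backend) backend$registry

#' @export
request_log.live_backend <- function(backend) backend$log

#' @export
print.live_backend <- function(x, ...) {
  cat(sprintf("<live_backend> %s (%d request(s) logged)\n",
              x$base_url, length(x$log)))
  invisible(x)
}

live_get_xml <- function(backend, endpoint, params) {
  url <- eutils_url(backend$base_url, endpoint, params)
  log_request(backend, endpoint, url, params)
  text <- backend$transport(url)
  doc <- xml2::read_xml(text)
  err <- xml2::xml_find_first(doc, ".//ERROR")
  if (!inherits(err, "xml_missing"))
    stop(sprintf("E-utilities server error (%s): %s", endpoint,
                 xml2::xml_text(err)), call. = FALSE)
  doc
}

#' @export
eu_search.live_backend <- function(backend, db, term, history = TRUE) {
  doc <- live_get_xml(backend, "esearch", list(
    db = db, term = term, retmax = backend$retmax, retstart = 0,
    usehistory = if (history) "y" else NULL))
  total <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, ".//Count")))
  uids <- xml2::xml_text(xml2::xml_find_all(doc, ".//IdList/Id"))
  key <- NULL
  if (history) {
    we <- xml2::xml_find_first(doc, ".//WebEnv")
    qk <- xml2::xml_find_first(doc, ".//QueryKey")
    if (!inherits(we, "xml_missing"))
      key <- list(web_env = xml2::xml_text(we),
                  query_key = xml2::xml_text(qk))
  }
  # page through the remainder with retstart/retmax
  while (length(uids) < total) {
    page <- live_get_xml(backend, "esearch", list(
      db = db, term = term, retmax = backend$retmax, retstart = length(uids),
      WebEnv = key$web_env, query_key = key$query_key))
    more <- xml2::xml_text(xml2::xml_find_all(page, ".//IdList/Id"))
    if (length(more) == 0) break
    uids <- c(uids, more)
  }
  list(uids = unique(uids), total_count = total, history_key = key)
}

#' @export
eu_link.live_backend <- function(backend, source_db, target_db, link_name, uid) {
  if (!is.null(backend$registry)) {
    lk <- registry_link(backend$registry, source_db, link_name)
    if (is.null(lk) || lk$target_db != target_db)
      stop(sprintf("undeclared link '%s' from '%s' to '%s'",
                   link_name, source_db, target_db), call. = FALSE)
  }
  doc <- live_get_xml(backend, "elink", list(
    dbfrom = source_db, db = target_db, linkname = link_name, id = uid))
  sets <- xml2::xml_find_all(doc, ".//LinkSetDb")
  uids <- character(0)
  for (s in sets) {
    nm <- xml2::xml_text(xml2::xml_find_first(s, "./LinkName"))
    if (identical(nm, link_name))
      uids <- c(uids, xml2::xml_text(xml2::xml_find_all(s, "./Link/Id")))
  }
  list(uids = unique(uids[nzchar(uids)]))
}

#' @export
eu_fetch.live_backend <- function(backend, db, uids, fields) {
  if (length(uids) == 0) return(list())
  supports_efetch <- is.null(backend$registry) ||
    isTRUE(backend$registry$databases[[db]]$supports_efetch)
  endpoint <- if (supports_efetch) "efetch" else "esummary"
  doc <- live_get_xml(backend, endpoint, list(
    db = db, id = paste(uids, collapse = ","), retmode = "xml"))
  # one record element per UID: leaf elements are field values, Id the UID
  recs <- xml2::xml_find_all(doc, if (endpoint == "esummary") ".//DocSum"
                                  else "./*")
  by_uid <- list()
  for (r in recs) {
    uid <- xml2::xml_text(xml2::xml_find_first(r, ".//Id"))
    leaves <- xml2::xml_find_all(r, ".//*[not(*)]")
    codes <- toupper(xml2::xml_name(leaves))
    vals <- xml2::xml_text(leaves)
    keep <- codes %in% fields
    by_uid[[uid]] <- stats::setNames(vals[keep], codes[keep])
  }
  lapply(uids, function(uid) {
    vals <- by_uid[[uid]]
    if (is.null(vals)) {
      es_warn("fetch[%s]: no record returned for uid %s", db, uid)
      vals <- stats::setNames(character(0), character(0))
    }
    list(uid = uid, values = vals)
  })
}

#' Fetch and assemble registry metadata from a live endpoint
#'
#' Convenience wrapper: retrieves the master list and each per-database
#' EInfo document over the backend's transport, then delegates to
#' [build_registry()]. Retrievable-field evidence documents are fetched
#' from `evidence_urls` when supplied (the DTD service has no fixed URL
#' scheme, so callers provide the mapping).
#'
#' @param base_url Endpoint base URL.
#' @param transport A transport function.
#' @param evidence_urls Optional named list (db -> URL of DTD or sample
#'   document).
#' @return An `entrez_registry`.
#' @export
fetch_live_registry <- function(base_url, transport = http_transport(),
                                evidence_urls = list()) {
  master <- transport(eutils_url(base_url, "einfo", list()))
  db_names <- parse_einfo_master(master)
  per_db <- list(); evidence <- list()
  for (nm in db_names) {
    per_db[[nm]] <- tryCatch(
      transport(eutils_url(base_url, "einfo", list(db = nm))),
      error = function(e) NULL)
    if (!is.null(evidence_urls[[nm]]))
      evidence[[nm]] <- transport(evidence_urls[[nm]])
  }
  build_registry(master, per_db, evidence)
}
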