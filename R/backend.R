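# Backend contract: the three E-utilities operations the executor needs.
# Two implementations exist — an offline mock over synthetic fixtures and
# a live HTTP client — sharing one generic surface so the executor never
# knows which it is talking to. Every backend keeps an ordered request
# log; the log is the test surface for request-minimization properties.

#' E-utilities backend operations
#'
#' `eu_search` returns the UIDs of one database's entries matching an
#' Entrez term (optionally parking the list on the history server and
#' returning a `(web_env, query_key)` handle). `eu_link` returns the UIDs
#' in a target database related to one source UID through a named link.
#' `eu_fetch` returns the records for a batch of UIDs (one backend request
#' regardless of batch size), restricted to the requested field codes.
#'
#' @param backend A backend object ([mock_backend()] or [live_backend()]).
#' @param db,source_db,target_db Database names.
#' @param term Entrez term string, e.g. `"wilms tumor"[TITL]`.
#' @param history Logical: park the UID list on the history server.
#' @param link_name Declared link identifier, e.g. `pubmed_gene`.
#' @param uid A single UID string.
#' @param uids Character vector of UIDs.
#' @param fields Field codes to retrieve (must be retrievable in `db`).
#' @return `eu_search`: list(uids, total_count, history_key);
#'   `eu_link`: list(uids); `eu_fetch`: list of records, each
#'   list(uid, values = named character).
#' @name backend-ops
NULL

#' @rdname backend-ops
#' @export
eu_search <- function(backend, db, term, history = TRUE) UseMethod("eu_search")

#' @rdname backend-ops
#' @export
eu_link <- function(backend, source_db, target_db, link_name, uid)
  UseMethod("eu_link")

#' @rdname backend-ops
#' @export
eu_fetch <- function(backend, db, uids, fields) UseMethod("eu_fetch")

#' Registry a backend serves
#' @param backend A backend object.
#' @export
backend_registry <- function(backend) UseMethod("backend_registry")

#' The backend's ordered request log
#'
#' One entry per backend request: `op`, the canonical request `key`
#' (used for duplicate detection) and the arguments.
#' @param backend A backend object.
#' @export
request_log <- function(backend) UseMethod("request_log")

log_request <- function(backend, op, key, args) {
  backend$log[[length(backend$log) + 1L]] <- list(op = op, key = key, args = args)
  invisible(NULL)
}

# --- Entrez term grammar (mock side) ---------------------------------------
# "value"[FIELD] conjuncts joined by AND. Inverse of term_expression().
parse_term <- function(term) {
  parts <- strsplit(term, " AND ", fixed = TRUE)[[1]]
  out <- data.frame(field = character(), value = character(),
                    stringsAsFactors = FALSE)
  for (p in parts) {
    m <- regmatches(p, regexec('^\\s*"(.*)"\\[([A-Za-z0-9]+)\\]\\s*$', p))[[1]]
    if (length(m) != 3)
      stop(sprintf("unparseable term conjunct: %s", p), call. = FALSE)
    out <- rbind(out, data.frame(field = toupper(m[3]), value = m[2],
                                 stringsAsFactors = FALSE))
  }
  out
}

# --- Mock dataset -----------------------------------------------------------

#' Construct a mock dataset
#'
#' The offline stand-in for the remote repositories: per-database record
#' tables and per-link adjacency tables, bound to a registry.
#'
#' @param registry An `entrez_registry`.
#' @param tables Named list (db -> named list uid -> named character of
#'   field values).
#' @param link_tables Named list (link name -> named list source uid ->
#'   character vector of target uids).
#' @param summary_fields Named list (db -> field codes served by the
#'   summary operation); defaults to each database's retrievable fields.
#' @param manifest Free-form ground-truth summary from the generator.
#' @param validate Check referential integrity (default TRUE). Disable to
#'   build datasets with deliberately stale links.
#' @return A `mock_dataset`.
#' @export
mock_dataset <- function(registry, tables, link_tables = list(),
                         summary_fields = NULL, manifest = list(),
                         validate = TRUE) {
  if (is.null(summary_fields))
    summary_fields <- lapply(registry$databases, function(db)
      db$fields$name[db$fields$retrievable])
  if (validate) {
    for (db in names(tables)) {
      descr <- registry_db(registry, db)
      for (uid in names(tables[[db]])) {
        bad <- setdiff(names(tables[[db]][[uid]]), descr$fields$name)
        if (length(bad) > 0)
          stop(sprintf("mock dataset: record %s/%s carries undeclared field(s) %s",
                       db, uid, paste(bad, collapse = ",")), call. = FALSE)
      }
    }
    for (lk in names(link_tables)) {
      found <- FALSE
      for (db in registry$databases) {
        i <- match(lk, db$links$name)
        if (!is.na(i)) {
          found <- TRUE
          tgt <- db$links$target[i]
          for (src in names(link_tables[[lk]])) {
            missing <- setdiff(link_tables[[lk]][[src]],
                               names(tables[[tgt]] %||% list()))
            if (length(missing) > 0)
              stop(sprintf("mock dataset: link %s targets unknown uid(s) %s in '%s'",
                           lk, paste(missing, collapse = ","), tgt), call. = FALSE)
          }
        }
      }
      if (!found)
        stop(sprintf("mock dataset: link table '%s' is not declared in the registry", lk),
             call. = FALSE)
    }
  }
  structure(list(registry = registry, tables = tables,
                 link_tables = link_tables, summary_fields = summary_fields,
                 manifest = manifest),
            class = "mock_dataset")
}

#' @export
print.mock_dataset <- function(x, ...) {
  cat(sprintf("<mock_dataset> %d database(s), %d link table(s)\n",
              length(x$tables), length(x$link_tables)))
  for (db in names(x$tables))
    cat(sprintf("  %-12s %d record(s)\n", db, length(x$tables[[db]])))
  invisible(x)
}

#' Offline mock backend over a synthetic dataset
#'
#' Implements the full operation contract against in-memory tables.
#' Search semantics: a record matches a term when, for every
#' `"value"[FIELD]` conjunct, its FIELD value contains the value
#' case-insensitively. The history server is an in-memory map issuing
#' sequential `(web_env, query_key)` handles. All operations are pure
#' functions of (dataset, arguments); only the request log and history
#' map mutate.
#'
#' @param dataset A `mock_dataset`.
#' @return A `mock_backend`.
#' @export
mock_backend <- function(dataset) {
  stopifnot(inherits(dataset, "mock_dataset"))
  be <- new.env(parent = emptyenv())
  be$dataset <- dataset
  be$log <- list()
  be$history <- list()
  be$next_env <- 1L
  class(be) <- c("mock_backend", "entrez_backend")
  be
}

#' @export
backend_registry.mock_backend <- function(backend) backend$dataset$registry

#' @export
request_log.mock_backend <- function(backend) backend$log

#' @export
print.mock_backend <- function(x, ...) {
  cat(sprintf("<mock_backend> %d request(s) logged\n", length(x$log)))
  invisible(x)
}

#' @export
eu_search.mock_backend <- function(backend, db, term, history = TRUE) {
  ds <- backend$dataset
  descr <- registry_db(ds$registry, db)
  log_request(backend, "search",
              sprintf("search|%s|%s|%d", db, term, as.integer(history)),
              list(db = db, term = term, history = history))
  filters <- parse_term(term)
  unknown <- setdiff(filters$field, descr$fields$name)
  if (length(unknown) > 0) {
    es_warn("search[%s]: unknown field(s) %s in term; empty result",
            db, paste(unknown, collapse = ","))
    return(list(uids = character(0), total_count = 0L, history_key = NULL))
  }
  tab <- ds$tables[[db]] %||% list()
  hit <- character(0)
  for (uid in names(tab)) {
    vals <- tab[[uid]]
    ok <- TRUE
    for (j in seq_len(nrow(filters))) {
      v <- if (filters$field[j] %in% names(vals)) vals[[filters$field[j]]] else NULL
      # case-insensitive fixed substring match
      if (is.null(v) || !grepl(tolower(filters$value[j]), tolower(v), fixed = TRUE)) {
        ok <- FALSE; break
      }
    }
    if (ok) hit <- c(hit, uid)
  }
  key <- NULL
  if (history) {
    key <- list(web_env = sprintf("WE%04d", backend$next_env), query_key = "1")
    backend$next_env <- backend$next_env + 1L
    backend$history[[key$web_env]] <- hit
  }
  list(uids = hit, total_count = length(hit), history_key = key)
}

#' @export
eu_link.mock_backend <- function(backend, source_db, target_db, link_name, uid) {
  ds <- backend$dataset
  lk <- registry_link(ds$registry, source_db, link_name)
  if (is.null(lk) || lk$target_db != target_db)
    stop(sprintf("undeclared link '%s' from '%s' to '%s'",
                 link_name, source_db, target_db), call. = FALSE)
  log_request(backend, "link",
              sprintf("link|%s|%s|%s|%s", source_db, target_db, link_name, uid),
              list(source_db = source_db, target_db = target_db,
                   link_name = link_name, uid = uid))
  targets <- ds$link_tables[[link_name]][[uid]] %||% character(0)
  list(uids = unique(targets))
}

#' @export
eu_fetch.mock_backend <- function(backend, db, uids, fields) {
  ds <- backend$dataset
  descr <- registry_db(ds$registry, db)
  log_request(backend, "fetch",
              sprintf("fetch|%s|%s|%s", db, paste(uids, collapse = ","),
                      paste(sort(fields), collapse = ",")),
              list(db = db, uids = uids, fields = fields))
  if (length(uids) == 0) return(list())
  available <- if (descr$supports_efetch) descr$fields$name
               else ds$summary_fields[[db]] %||% character(0)
  if (!descr$supports_efetch && length(available) == 0)
    stop(sprintf("database '%s' supports neither fetch nor summary", db),
         call. = FALSE)
  tab <- ds$tables[[db]] %||% list()
  lapply(uids, function(uid) {
    vals <- tab[[uid]]
    if (is.null(vals)) {
      es_warn("fetch[%s]: unknown uid %s; empty record", db, uid)
      return(list(uid = uid, values = stats::setNames(character(0), character(0))))
    }
    keep <- intersect(intersect(fields, names(vals)), available)
    list(uid = uid, values = vals[keep])
  })
}
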