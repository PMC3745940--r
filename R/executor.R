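# Query execution: resolve a path-shaped chain against a backend by
# building the tree of results depth-first. Each tree level holds entries
# of one database in the chain; each root-to-leaf path is one solution.
# Traversal is lazy: the root search runs at cursor open, but records are
# fetched in batches only as their level is entered, links are followed
# one node at a time, and exhausted branches are pruned so retained state
# stays bounded by the sum (never the product) of sibling-list sizes
# along the current path.

#' Open a cursor over a query chain
#'
#' Issues exactly one search (history enabled) for the root node's filter
#' term. Root UIDs are queued but not fetched yet; no link calls are made
#' until rows are demanded. Cursors from repeated calls are independent,
#' each with its own request log and record cache.
#'
#' @param chain A `query_chain`.
#' @param backend A backend implementing the operation contract.
#' @param fetch_batch Root records are fetched in batches of this size as
#'   traversal consumes them (default 200). Non-root sibling sets are
#'   fetched in one batch when their level is first entered.
#' @param limit Optional client-side row limit; traversal stops cleanly
#'   after this many rows without expanding further branches.
#' @return An `entrez_cursor`.
#' @export
open_cursor <- function(chain, backend, fetch_batch = 200, limit = Inf) {
  stopifnot(inherits(chain, "query_chain"))
  cur <- new.env(parent = emptyenv())
  cur$chain <- chain
  cur$backend <- backend
  cur$fetch_batch <- as.integer(fetch_batch)
  cur$limit <- limit
  cur$log <- list()
  cur$cache <- new.env(parent = emptyenv())
  cur$transcript <- character(0)
  cur$pending <- NULL
  cur$emitted <- 0L
  cur$expanded <- 0L
  cur$peak_nodes <- 0L
  cur$exhausted <- FALSE
  class(cur) <- "entrez_cursor"

  root <- chain$nodes[[1]]
  term <- term_expression(root$filters)
  cur$log[[length(cur$log) + 1L]] <-
    list(op = "search", key = sprintf("search|%s|%s|1", root$db, term))
  sr <- eu_search(backend, root$db, term, history = TRUE)
  cur$history_key <- sr$history_key
  cur$frames <- list(list(uids = sr$uids, idx = 1L, fetched_upto = 0L))
  cur$peak_nodes <- length(sr$uids)
  if (length(sr$uids) == 0) cur$exhausted <- TRUE
  cur
}

#' @export
print.entrez_cursor <- function(x, ...) {
  cat(sprintf("<entrez_cursor> %d level(s), %d row(s) emitted%s\n",
              length(x$chain$nodes), x$emitted,
              if (x$exhausted) ", exhausted" else ""))
  invisible(x)
}

cache_key <- function(db, uid, fields) {
  paste(db, uid, paste(sort(fields), collapse = ","), sep = "\x1f")
}

# Fetch the records a frame still needs, in one batched request; cached
# records (shared children already fetched on another branch) are skipped.
ensure_fetched <- function(cur, depth) {
  node <- cur$chain$nodes[[depth]]
  fields <- node$projections$field
  if (length(fields) == 0) return(invisible(NULL))
  fr <- cur$frames[[depth]]
  n <- length(fr$uids)
  if (fr$idx > fr$fetched_upto) {
    upto <- if (depth == 1L) min(n, fr$fetched_upto + cur$fetch_batch) else n
    want <- fr$uids[(fr$fetched_upto + 1L):upto]
    keys <- vapply(want, function(u) cache_key(node$db, u, fields), character(1))
    new <- want[!vapply(keys, exists, logical(1), envir = cur$cache)]
    if (length(new) > 0) {
      cur$log[[length(cur$log) + 1L]] <- list(
        op = "fetch",
        key = sprintf("fetch|%s|%s|%s", node$db, paste(new, collapse = ","),
                      paste(sort(fields), collapse = ",")))
      recs <- eu_fetch(cur$backend, node$db, new, fields)
      for (r in recs)
        assign(cache_key(node$db, r$uid, fields), r$values, envir = cur$cache)
    }
    cur$frames[[depth]]$fetched_upto <- upto
  }
  invisible(NULL)
}

build_row <- function(cur) {
  bindings <- character(0)
  for (d in seq_along(cur$chain$nodes)) {
    node <- cur$chain$nodes[[d]]
    fr <- cur$frames[[d]]
    uid <- fr$uids[fr$idx - 1L]
    if (!is.null(node$uid_variable)) bindings[[node$uid_variable]] <- uid
    if (nrow(node$projections) > 0) {
      vals <- get0(cache_key(node$db, uid, node$projections$field),
                   envir = cur$cache, ifnotfound = character(0))
      for (j in seq_len(nrow(node$projections))) {
        code <- node$projections$field[j]
        if (code %in% names(vals) && !is.na(vals[[code]]))
          bindings[[node$projections$variable[j]]] <- vals[[code]]
      }
    }
  }
  bindings[cur$chain$variables[cur$chain$variables %in% names(bindings)]]
}

# Core DFS step: walk until the next root-to-leaf path is complete.
advance_cursor <- function(cur) {
  if (cur$emitted >= cur$limit) { cur$exhausted <- TRUE; return(NULL) }
  n_levels <- length(cur$chain$nodes)
  repeat {
    d <- length(cur$frames)
    if (d == 0L) { cur$exhausted <- TRUE; return(NULL) }
    fr <- cur$frames[[d]]
    if (fr$idx > length(fr$uids)) {
      # all siblings used: prune this branch and go up one level
      cur$frames[[d]] <- NULL
      if (d > 1L) cur$transcript <- c(cur$transcript, "up")
      next
    }
    ensure_fetched(cur, d)
    uid <- fr$uids[fr$idx]
    cur$frames[[d]]$idx <- fr$idx + 1L
    if (d == n_levels) {
      cur$transcript <- c(cur$transcript, "row")
      return(build_row(cur))
    }
    # expand node: one link call for the next level
    node <- cur$chain$nodes[[d]]
    nxt <- cur$chain$nodes[[d + 1L]]
    cur$log[[length(cur$log) + 1L]] <- list(
      op = "link",
      key = sprintf("link|%s|%s|%s|%s", node$db, nxt$db, cur$chain$edges[d], uid))
    lr <- eu_link(cur$backend, node$db, nxt$db, cur$chain$edges[d], uid)
    cur$expanded <- cur$expanded + 1L
    if (length(lr$uids) == 0L) next  # dead branch: stay on this level
    cur$frames[[d + 1L]] <- list(uids = lr$uids, idx = 1L, fetched_upto = 0L)
    cur$transcript <- c(cur$transcript, "down")
    retained <- sum(vapply(cur$frames, function(f) length(f$uids), numeric(1)))
    cur$peak_nodes <- max(cur$peak_nodes, retained)
  }
}

#' Iterate a cursor
#'
#' `cursor_has_next` reports whether another root-to-leaf solution
#' exists; it is idempotent (repeated calls perform no backend requests
#' beyond the single lookahead needed for the first call).
#' `cursor_next` returns the next solution's bindings — a named
#' character vector, variables with no value omitted — in depth-first
#' order: root UIDs in search order, children in link-result order.
#'
#' @param cursor An `entrez_cursor`.
#' @return `cursor_has_next`: logical. `cursor_next`: named character
#'   vector of bindings; calling it on an exhausted cursor is an error.
#' @export
cursor_has_next <- function(cursor) {
  if (!is.null(cursor$pending)) return(TRUE)
  if (cursor$exhausted) return(FALSE)
  cursor$pending <- advance_cursor(cursor)
  !is.null(cursor$pending)
}

#' @rdname cursor_has_next
#' @export
cursor_next <- function(cursor) {
  if (!cursor_has_next(cursor))
    stop("cursor exhausted: no more results", call. = FALSE)
  row <- cursor$pending
  cursor$pending <- NULL
  cursor$emitted <- cursor$emitted + 1L
  row
}

#' Collect rows from a cursor
#'
#' @param cursor An `entrez_cursor`.
#' @param n Maximum number of rows (default: all).
#' @return List of binding vectors.
#' @export
cursor_collect <- function(cursor, n = Inf) {
  rows <- list()
  while (length(rows) < n && cursor_has_next(cursor))
    rows[[length(rows) + 1L]] <- cursor_next(cursor)
  rows
}

#' Per-cursor request log
#' @param cursor An `entrez_cursor`.
#' @return List of (op, key) entries in request order.
#' @export
cursor_log <- function(cursor) cursor$log

#' Traversal transcript
#'
#' The ordered sequence of traversal events: `"row"` (a solution
#' emitted), `"down"` (a new level entered under an expanded node),
#' `"up"` (a pruned branch abandoned, one level up).
#' @param cursor An `entrez_cursor`.
#' @export
cursor_transcript <- function(cursor) cursor$transcript

#' Audit a consumed cursor's request plan
#'
#' Summarizes the cursor's request log for minimization checks: exactly
#' one root search is expected, one link call per expanded non-leaf node,
#' batched per-level fetches (at most one fetch per non-empty sibling
#' set), and no two identical requests.
#'
#' @param cursor An exhausted `entrez_cursor`.
#' @return A `request_audit`: counts per operation, number of expanded
#'   nodes, duplicate request count, peak retained node count.
#' @export
request_plan_audit <- function(cursor) {
  if (!cursor$exhausted && cursor_has_next(cursor))
    stop("request_plan_audit requires a cursor consumed to exhaustion",
         call. = FALSE)
  ops <- vapply(cursor$log, function(e) e$op, character(1))
  keys <- vapply(cursor$log, function(e) e$key, character(1))
  structure(list(
    n_requests = length(ops),
    n_search = sum(ops == "search"),
    n_link = sum(ops == "link"),
    n_fetch = sum(ops == "fetch"),
    expanded_nodes = cursor$expanded,
    duplicate_requests = sum(duplicated(keys)),
    peak_retained_nodes = cursor$peak_nodes,
    rows_emitted = cursor$emitted
  ), class = "request_audit")
}

#' @export
print.request_audit <- function(x, ...) {
  cat(sprintf(
    "<request_audit> %d request(s): %d search, %d link, %d fetch; %d node(s) expanded; %d duplicate(s); peak %d retained node(s); %d row(s)\n",
    x$n_requests, x$n_search, x$n_link, x$n_fetch, x$expanded_nodes,
    x$duplicate_requests, x$peak_retained_nodes, x$rows_emitted))
  invisible(x)
}
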