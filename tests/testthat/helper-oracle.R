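# Independent brute-force oracle: a plain nested-loop join over the
# fixture tables, written against the dataset structures directly (no
# backend, no cursor) so it shares no code with the execution path it
# checks.

oracle_match <- function(record, filters) {
  for (j in seq_len(nrow(filters))) {
    f <- filters$field[j]
    if (!(f %in% names(record))) return(FALSE)
    if (!grepl(tolower(filters$value[j]), tolower(record[[f]]), fixed = TRUE))
      return(FALSE)
  }
  TRUE
}

oracle_bindings <- function(node, uid, record) {
  out <- character(0)
  if (!is.null(node$uid_variable)) out[[node$uid_variable]] <- uid
  for (j in seq_len(nrow(node$projections))) {
    code <- node$projections$field[j]
    if (code %in% names(record))
      out[[node$projections$variable[j]]] <- record[[code]]
  }
  out
}

# Full multiset of solutions for a chain over a mock dataset, in no
# particular order. Duplicate root-to-leaf paths yield duplicate rows.
oracle_join <- function(chain, ds) {
  rows <- list()
  recurse <- function(level, uid, acc) {
    node <- chain$nodes[[level]]
    record <- ds$tables[[node$db]][[uid]] %||% character(0)
    acc <- c(acc, oracle_bindings(node, uid, record))
    if (level == length(chain$nodes)) {
      keep <- chain$variables[chain$variables %in% names(acc)]
      rows[[length(rows) + 1L]] <<- acc[keep]
      return(invisible(NULL))
    }
    kids <- ds$link_tables[[chain$edges[level]]][[uid]] %||% character(0)
    for (k in kids) recurse(level + 1L, k, acc)
  }
  root <- chain$nodes[[1]]
  tab <- ds$tables[[root$db]] %||% list()
  for (uid in names(tab))
    if (oracle_match(tab[[uid]], root$filters)) recurse(1L, uid, character(0))
  rows
}

# Canonical multiset representation for comparing row collections.
row_multiset <- function(rows) {
  sort(vapply(rows, function(r) {
    if (length(r) == 0) return("<empty>")
    paste(sprintf("%s=%s", names(r), unname(r)), collapse = "\x1f")
  }, character(1)))
}

# Number of expanded (non-leaf, visited) nodes: root matches plus all
# intermediate-level nodes reached — each costs exactly one link call.
oracle_expanded_nodes <- function(chain, ds) {
  n_levels <- length(chain$nodes)
  if (n_levels == 1) return(0L)
  count <- 0L
  recurse <- function(level, uid) {
    if (level == n_levels) return(invisible(NULL))
    count <<- count + 1L
    kids <- ds$link_tables[[chain$edges[level]]][[uid]] %||% character(0)
    for (k in kids) recurse(level + 1L, k)
  }
  root <- chain$nodes[[1]]
  tab <- ds$tables[[root$db]] %||% list()
  for (uid in names(tab))
    if (oracle_match(tab[[uid]], root$filters)) recurse(1L, uid)
  count
}
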