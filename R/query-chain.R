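# Chain compilation: turn a validated basic graph pattern into a
# path-shaped query plan. Each typed instance variable becomes one chain
# node (a database); object-property triples between instance variables
# become the chain's edges (named links); literal-object field triples
# become filters, variable-object field triples projections. Validation
# enforces the schema and the side documentation: filtering requires a
# filterable field, projecting a retrievable one.

new_query_chain <- function(nodes, edges, variables) {
  structure(list(nodes = nodes, edges = edges, variables = variables),
            class = "query_chain")
}

#' Compile a basic graph pattern into a query chain
#'
#' The instance-variable graph must be a simple directed path; its root is
#' the endpoint carrying filters (searching an entire database unfiltered
#' is refused). If both endpoints carry filters, the one whose triples
#' appear first in the query text wins.
#'
#' @param bgp A `sparql_bgp` from [parse_sparql()].
#' @param registry An `entrez_registry`.
#' @param base_namespace The namespace the schema was generated with.
#' @return A `query_chain`: `$nodes` (list of db/filters/projections/
#'   uid_variable), `$edges` (link names, one per adjacent node pair),
#'   `$variables` (projected variables in query order).
#' @export
compile_chain <- function(bgp, registry,
                          base_namespace = "http://example.org/entrez#") {
  ns <- base_namespace
  tr <- bgp$triples
  rdf_type <- paste0(RDF_NS, "type")

  # instance variables: subjects of a type triple
  type_rows <- tr[tr$predicate %in% c("a", rdf_type), , drop = FALSE]
  if (nrow(type_rows) == 0)
    stop("schema mismatch: no typed instance variable in the pattern", call. = FALSE)
  inst <- list()
  for (i in seq_len(nrow(type_rows))) {
    v <- type_rows$subject[i]
    if (type_rows$object_kind[i] != "iri")
      stop("schema mismatch: rdf:type object must be a class IRI", call. = FALSE)
    cls <- type_rows$object[i]
    if (!startsWith(cls, ns))
      stop(sprintf("schema mismatch: unknown class <%s>", cls), call. = FALSE)
    db <- tolower(substring(cls, nchar(ns) + 1))
    if (is.null(registry$databases[[db]]))
      stop(sprintf("schema mismatch: class <%s> matches no database", cls),
           call. = FALSE)
    if (!is.null(inst[[v]]) && inst[[v]]$db != db)
      stop(sprintf("variable ?%s typed with two different classes", v), call. = FALSE)
    inst[[v]] <- list(db = db, first_order = type_rows$order[i],
                      filters = data.frame(field = character(), value = character(),
                                           stringsAsFactors = FALSE),
                      projections = data.frame(field = character(), variable = character(),
                                               stringsAsFactors = FALSE),
                      uid_variable = NULL)
  }

  # classify remaining triples
  edges <- list()
  other <- tr[!(tr$predicate %in% c("a", rdf_type)), , drop = FALSE]
  for (i in seq_len(nrow(other))) {
    row <- other[i, ]
    v <- row$subject
    node <- inst[[v]]
    if (is.null(node))
      stop(sprintf("schema mismatch: variable ?%s has no rdf:type triple", v),
           call. = FALSE)
    if (!startsWith(row$predicate, ns))
      stop(sprintf("schema mismatch: unknown property <%s>", row$predicate),
           call. = FALSE)
    local <- substring(row$predicate, nchar(ns) + 1)
    inst[[v]]$first_order <- min(inst[[v]]$first_order, row$order)

    if (row$object_kind == "var" && !is.null(inst[[row$object]])) {
      # object property joining two instance variables
      link_name <- sub("^[a-z0-9]+\\.", "", local)  # strip collision qualifier
      lk <- registry_link(registry, node$db, link_name)
      if (is.null(lk))
        stop(sprintf("schema mismatch: '%s' is not a declared link from '%s'",
                     link_name, node$db), call. = FALSE)
      if (lk$target_db != inst[[row$object]]$db)
        stop(sprintf("schema mismatch: link '%s' targets '%s', not '%s'",
                     link_name, lk$target_db, inst[[row$object]]$db), call. = FALSE)
      edges[[length(edges) + 1L]] <- list(from = v, to = row$object,
                                          link = link_name, order = row$order)
      next
    }

    if (local == "uid") {
      if (row$object_kind != "var")
        stop("the uid property must be projected into a variable", call. = FALSE)
      inst[[v]]$uid_variable <- row$object
      next
    }

    # datatype property: must be <db>_<CODE> for this node's database
    pfx <- paste0(node$db, "_")
    if (!startsWith(local, pfx))
      stop(sprintf("schema mismatch: property <%s> does not belong to database '%s'",
                   row$predicate, node$db), call. = FALSE)
    code <- toupper(substring(local, nchar(pfx) + 1))
    f <- registry$databases[[node$db]]$fields
    j <- match(code, f$name)
    if (is.na(j))
      stop(sprintf("schema mismatch: unknown field '%s' on database '%s'",
                   code, node$db), call. = FALSE)
    if (row$object_kind == "literal") {
      if (!f$filterable[j])
        stop(sprintf("asymmetry violation: field '%s' of '%s' is retrieve-only and cannot be filtered",
                     code, node$db), call. = FALSE)
      inst[[v]]$filters <- rbind(inst[[v]]$filters,
                                 data.frame(field = code, value = row$object,
                                            stringsAsFactors = FALSE))
    } else if (row$object_kind == "var") {
      if (!f$retrievable[j])
        stop(sprintf("asymmetry violation: field '%s' of '%s' is filter-only and cannot be retrieved",
                     code, node$db), call. = FALSE)
      inst[[v]]$projections <- rbind(inst[[v]]$projections,
                                     data.frame(field = code, variable = row$object,
                                                stringsAsFactors = FALSE))
    } else {
      stop(sprintf("schema mismatch: field property '%s' needs a literal or variable object",
                   code), call. = FALSE)
    }
  }

  # path-shape check on the instance graph
  vars <- names(inst)
  if (length(edges) != length(vars) - 1L)
    stop("unsupported join shape: instance-variable graph is not a simple path",
         call. = FALSE)
  deg <- stats::setNames(integer(length(vars)), vars)
  for (e in edges) { deg[e$from] <- deg[e$from] + 1L; deg[e$to] <- deg[e$to] + 1L }
  if (length(vars) > 1 && (any(deg > 2) || sum(deg == 1) != 2))
    stop("unsupported join shape: instance-variable graph is not a simple path",
         call. = FALSE)

  # connectivity + orientation: walk from a degree-1 endpoint
  order_path <- function(start) {
    path <- start
    used <- rep(FALSE, length(edges))
    while (TRUE) {
      cur <- path[length(path)]
      nxt <- NULL
      for (k in seq_along(edges)) {
        if (used[k]) next
        if (edges[[k]]$from == cur) { nxt <- edges[[k]]$to; used[k] <- TRUE; break }
        if (edges[[k]]$to == cur) { nxt <- edges[[k]]$from; used[k] <- TRUE; break }
      }
      if (is.null(nxt)) break
      path <- c(path, nxt)
    }
    path
  }
  endpoints <- if (length(vars) == 1) vars else vars[deg == 1]
  has_filters <- vapply(endpoints, function(v) nrow(inst[[v]]$filters) > 0, logical(1))
  root <- if (length(vars) == 1) {
    vars
  } else if (sum(has_filters) == 1) {
    endpoints[has_filters]
  } else if (sum(has_filters) == 2) {
    fo <- vapply(endpoints, function(v) inst[[v]]$first_order, numeric(1))
    endpoints[which.min(fo)]
  } else {
    stop("unbounded root search: neither endpoint of the chain carries a filter",
         call. = FALSE)
  }
  path_vars <- order_path(root)
  if (length(path_vars) != length(vars))
    stop("unsupported join shape: instance-variable graph is disconnected",
         call. = FALSE)
  if (nrow(inst[[root]]$filters) == 0)
    stop("unbounded root search: the chain root carries no filter", call. = FALSE)

  # edges must run root -> leaf in link direction
  edge_names <- character(0)
  for (k in seq_len(length(path_vars) - 1L)) {
    hit <- NULL
    for (e in edges)
      if (e$from == path_vars[k] && e$to == path_vars[k + 1L]) { hit <- e; break }
    if (is.null(hit))
      stop(sprintf("unsupported join shape: link between ?%s and ?%s runs against the chain direction",
                   path_vars[k], path_vars[k + 1L]), call. = FALSE)
    edge_names <- c(edge_names, hit$link)
  }

  nodes <- lapply(path_vars, function(v) {
    n <- inst[[v]]
    list(var = v, db = n$db, filters = n$filters, projections = n$projections,
         uid_variable = n$uid_variable)
  })

  bound <- unlist(lapply(nodes, function(n)
    c(n$projections$variable, n$uid_variable)), use.names = FALSE)
  if (identical(bgp$select_vars, "*")) {
    variables <- bound
  } else {
    unknown <- setdiff(bgp$select_vars, bound)
    if (length(unknown) > 0)
      stop(sprintf("SELECT variable(s) not bound by any projection: %s",
                   paste0("?", unknown, collapse = ", ")), call. = FALSE)
    variables <- bgp$select_vars
  }
  new_query_chain(nodes, edge_names, variables)
}

#' Render a chain's root filters as an Entrez search term
#'
#' Each filter becomes `"value"[FIELD]`; conjuncts are joined by
#' `" AND "` in declaration order.
#'
#' @param filters data.frame with `field` and `value` columns.
#' @return A single term string.
#' @export
term_expression <- function(filters) {
  if (is.null(filters) || nrow(filters) == 0)
    stop("the chain root must carry at least one filter", call. = FALSE)
  paste(sprintf("\"%s\"[%s]", filters$value, filters$field), collapse = " AND ")
}

#' Pretty-print a chain back to SPARQL
#'
#' Inverse of [compile_chain()] up to variable naming; used for plan
#' inspection and round-trip checks.
#'
#' @param chain A `query_chain`.
#' @param base_namespace Namespace for class/property IRIs.
#' @return SPARQL query text.
#' @export
chain_to_sparql <- function(chain, base_namespace = "http://example.org/entrez#") {
  ns <- base_namespace
  lines <- c(sprintf("PREFIX e: <%s>", ns),
             sprintf("SELECT %s WHERE {",
                     paste0("?", chain$variables, collapse = " ")))
  for (i in seq_along(chain$nodes)) {
    n <- chain$nodes[[i]]
    v <- paste0("?", n$var)
    lines <- c(lines, sprintf("  %s a e:%s .", v, capitalize(n$db)))
    for (j in seq_len(nrow(n$filters)))
      lines <- c(lines, sprintf("  %s e:%s_%s \"%s\" .", v, n$db,
                                n$filters$field[j],
                                gsub("\"", "\\\"", n$filters$value[j], fixed = TRUE)))
    for (j in seq_len(nrow(n$projections)))
      lines <- c(lines, sprintf("  %s e:%s_%s ?%s .", v, n$db,
                                n$projections$field[j], n$projections$variable[j]))
    if (!is.null(n$uid_variable))
      lines <- c(lines, sprintf("  %s e:uid ?%s .", v, n$uid_variable))
    if (i < length(chain$nodes))
      lines <- c(lines, sprintf("  %s e:%s ?%s .", v, chain$edges[i],
                                chain$nodes[[i + 1L]]$var))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
print.query_chain <- function(x, ...) {
  cat("<query_chain>\n  ")
  parts <- character(0)
  for (i in seq_along(x$nodes)) {
    parts <- c(parts, x$nodes[[i]]$db)
    if (i < length(x$nodes)) parts <- c(parts, sprintf("-%s->", x$edges[i]))
  }
  cat(paste(parts, collapse = " "), "\n")
  for (i in seq_along(x$nodes)) {
    n <- x$nodes[[i]]
    cat(sprintf("  [%d] %s", i, n$db))
    if (nrow(n$filters) > 0)
      cat(sprintf("  filters: %s", term_expression(n$filters)))
    if (nrow(n$projections) > 0)
      cat(sprintf("  projects: %s",
                  paste(sprintf("%s->?%s", n$projections$field,
                                n$projections$variable), collapse = ", ")))
    if (!is.null(n$uid_variable)) cat(sprintf("  uid->?%s", n$uid_variable))
    cat("\n")
  }
  invisible(x)
}
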