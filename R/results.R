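# SPARQL Results serialization. Rows are streamed: each solution is
# written as soon as the cursor produces it, so long-running queries
# return results progressively. XML follows the W3C SPARQL Results XML
# format, JSON the SPARQL 1.1 Results JSON format; TSV is a convenience
# format (header of ?-prefixed variables, unbound values encoded as the
# empty string — a documented lossy corner).

#' Write a result stream in a SPARQL Results format
#'
#' @param rows An `entrez_cursor` or a list of binding vectors (named
#'   character; unbound variables absent).
#' @param variables Ordered projected variable names (the header). When
#'   `rows` is a cursor, defaults to its chain's projection list.
#' @param format `"xml"` (SPARQL Results XML), `"json"` (SPARQL Results
#'   JSON) or `"tsv"`.
#' @param sink Output file path or connection.
#' @return The number of bytes written, invisibly.
#' @export
write_sparql_results <- function(rows, variables = NULL,
                                 format = c("xml", "json", "tsv"), sink) {
  format <- match.arg(format)
  if (inherits(rows, "entrez_cursor")) {
    variables <- variables %||% rows$chain$variables
    cur <- rows
    nxt <- function() if (cursor_has_next(cur)) cursor_next(cur) else NULL
  } else {
    if (is.null(variables))
      stop("variables must be given when rows is a list", call. = FALSE)
    i <- 0L
    nxt <- function() {
      i <<- i + 1L
      if (i <= length(rows)) rows[[i]] else NULL
    }
  }

  binary <- !inherits(sink, "connection")
  con <- if (binary) {
    con_new <- file(sink, open = "wb")
    on.exit(close(con_new), add = TRUE)
    con_new
  } else sink
  bytes <- 0L
  emit <- function(text) {
    if (binary) writeChar(text, con, eos = NULL, useBytes = TRUE)
    else cat(text, file = con, sep = "")
    bytes <<- bytes + nchar(text, type = "bytes")
  }

  if (format == "xml") {
    emit("<?xml version=\"1.0\"?>\n")
    emit("<sparql xmlns=\"http://www.w3.org/2005/sparql-results#\">\n")
    emit("  <head>\n")
    for (v in variables) emit(sprintf("    <variable name=\"%s\"/>\n", xml_escape(v)))
    emit("  </head>\n  <results>\n")
    repeat {
      row <- nxt()
      if (is.null(row)) break
      emit("    <result>\n")
      for (v in intersect(variables, names(row)))
        emit(sprintf("      <binding name=\"%s\"><literal>%s</literal></binding>\n",
                     xml_escape(v), xml_escape(row[[v]])))
      emit("    </result>\n")
    }
    emit("  </results>\n</sparql>\n")
  } else if (format == "json") {
    emit(sprintf("{\"head\":{\"vars\":%s},\"results\":{\"bindings\":[",
                 jsonlite::toJSON(variables)))
    first <- TRUE
    repeat {
      row <- nxt()
      if (is.null(row)) break
      if (!first) emit(",")
      first <- FALSE
      bound <- intersect(variables, names(row))
      cells <- vapply(bound, function(v)
        sprintf("%s:{\"type\":\"literal\",\"value\":%s}",
                jsonlite::toJSON(v, auto_unbox = TRUE),
                jsonlite::toJSON(unname(row[[v]]), auto_unbox = TRUE)),
        character(1))
      emit(sprintf("{%s}", paste(cells, collapse = ",")))
    }
    emit("]}}\n")
  } else {
    emit(paste0(paste0("?", variables, collapse = "\t"), "\n"))
    repeat {
      row <- nxt()
      if (is.null(row)) break
      vals <- vapply(variables, function(v)
        if (v %in% names(row)) row[[v]] else "", character(1))
      emit(paste0(paste(vals, collapse = "\t"), "\n"))
    }
  }
  invisible(bytes)
}

#' Read a SPARQL Results document
#'
#' Independent readers for the three serializations, used for round-trip
#' verification and for consuming third-party result documents.
#'
#' @param path File path (or text for `format = "xml"`/`"json"`).
#' @param format `"xml"`, `"json"` or `"tsv"`.
#' @return list(variables, rows = list of named character vectors).
#' @export
read_sparql_results <- function(path, format = c("xml", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "xml") {
    doc <- xml2::read_xml(path)
    nsmap <- c(sr = "http://www.w3.org/2005/sparql-results#")
    vars <- xml2::xml_attr(
      xml2::xml_find_all(doc, ".//sr:head/sr:variable", nsmap), "name")
    results <- xml2::xml_find_all(doc, ".//sr:results/sr:result", nsmap)
    rows <- lapply(results, function(r) {
      bnodes <- xml2::xml_find_all(r, "./sr:binding", nsmap)
      stats::setNames(
        vapply(bnodes, xml2::xml_text, character(1)),
        xml2::xml_attr(bnodes, "name"))
    })
  } else if (format == "json") {
    payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    vars <- as.character(unlist(payload$head$vars))
    rows <- lapply(payload$results$bindings, function(b)
      vapply(b, function(cell) cell$value, character(1)))
    rows <- lapply(rows, function(r) stats::setNames(as.character(r), names(r)))
  } else {
    lines <- readLines(path, warn = FALSE)
    vars <- sub("^\\?", "", strsplit(lines[1], "\t", fixed = TRUE)[[1]])
    rows <- lapply(lines[-1], function(l) {
      vals <- strsplit(l, "\t", fixed = TRUE)[[1]]
      length(vals) <- length(vars)
      vals[is.na(vals)] <- ""
      keep <- nzchar(vals)
      stats::setNames(vals[keep], vars[keep])
    })
  }
  list(variables = vars, rows = rows)
}
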