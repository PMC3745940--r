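#' entrezsparql: SPARQL query federation over Entrez-style databases
#'
#' Virtual SPARQL endpoint over Entrez-style biomedical databases:
#' metadata registry, RDF schema generation, SPARQL chain compilation,
#' depth-first lazy query resolution and SPARQL Results serialization.
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG state
#'
#' Seeds R's RNG locally so generators are deterministic without
#' clobbering the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Structured warnings/logs go to stderr; results stay on stdout.
es_warn <- function(...) warning(sprintf(...), call. = FALSE)
es_log <- function(...) message(sprintf(...))

# XML escaping for hand-streamed documents (results writer, fixtures).
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Turtle literal escaping.
ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

read_text <- function(path) {
  paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}

write_text <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(text, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
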