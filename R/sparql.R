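# SPARQL SELECT subset parser. The supported fragment is exactly what the
# chain executor can resolve: PREFIX declarations, SELECT with an explicit
# variable list or *, and a basic graph pattern of rdf:type triples,
# datatype-property triples (literal object = filter, variable object =
# projection) and object-property triples linking typed instance
# variables. Everything else (CONSTRUCT/ASK/DESCRIBE, FILTER, OPTIONAL,
# UNION, aggregates, LIMIT/OFFSET) is rejected with a named error; row
# limits are applied client-side by the cursor instead.

sparql_tokenize <- function(text) {
  patterns <- c(
    ws = "\\s+|#[^\\n]*",
    iri = "<[^<>\"{}|^`\\\\ ]*>",
    string = "\"(\\\\.|[^\"\\\\])*\"",
    var = "\\?[A-Za-z_][A-Za-z0-9_]*",
    num = "[0-9]+(\\.[0-9]+)?",
    pname = "[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*",
    word = "[A-Za-z][A-Za-z0-9_]*",
    punct = "[{}();,.*]",
    op = "[<>=!&|+-]+"
  )
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    matched <- FALSE
    for (ty in names(patterns)) {
      m <- regexpr(paste0("^(", patterns[[ty]], ")"), substring(text, pos),
                   perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        if (ty != "ws")
          tokens[[length(tokens) + 1L]] <-
            list(type = ty, value = substring(text, pos, pos + len - 1L), pos = pos)
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop(sprintf("SPARQL syntax error at character %d: unexpected '%s'",
                   pos, substring(text, pos, pos)), call. = FALSE)
  }
  tokens
}

#' Parse a SPARQL SELECT query into a basic graph pattern
#'
#' Accepts the chain-query fragment: `PREFIX` declarations, `SELECT`
#' (explicit variables or `*`) and a `WHERE` block whose triples type
#' instance variables, attach field filters/projections to them and join
#' them through object properties. Predicate lists with `;` and object
#' lists with `,` are accepted; other query forms and graph-pattern
#' operators raise named errors.
#'
#' @param text SPARQL query text.
#' @return A `sparql_bgp`: `$select_vars` (character, or "*"),
#'   `$triples` (data.frame: subject, predicate IRI or "a", object,
#'   object_kind in var/literal/iri, order).
#' @export
parse_sparql <- function(text) {
  toks <- sparql_tokenize(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  fail <- function(tok, what) {
    stop(sprintf("SPARQL syntax error at character %d: %s",
                 if (is.null(tok)) nchar(text) + 1L else tok$pos, what),
         call. = FALSE)
  }
  kw <- function(tok) if (!is.null(tok) && tok$type %in% c("word", "pname"))
    toupper(tok$value) else ""

  prefixes <- list()
  while (kw(peek()) == "PREFIX") {
    advance()
    p <- peek()
    if (is.null(p) || p$type != "pname") fail(p, "expected prefix name after PREFIX")
    advance()
    pfx <- sub(":.*$", "", p$value)
    iri_tok <- peek()
    if (is.null(iri_tok) || iri_tok$type != "iri") fail(iri_tok, "expected IRI in PREFIX")
    advance()
    prefixes[[pfx]] <- substring(iri_tok$value, 2, nchar(iri_tok$value) - 1L)
  }

  form <- kw(peek())
  if (form %in% c("CONSTRUCT", "ASK", "DESCRIBE"))
    stop(sprintf("unsupported query form: %s (only SELECT is supported)", form),
         call. = FALSE)
  if (form != "SELECT") fail(peek(), "expected SELECT")
  advance()

  select_vars <- character(0)
  star <- FALSE
  repeat {
    t <- peek()
    if (is.null(t)) fail(t, "unterminated SELECT clause")
    if (t$type == "var") { select_vars <- c(select_vars, substring(t$value, 2)); advance() }
    else if (t$value == "*") { star <- TRUE; advance() }
    else break
  }
  if (!star && length(select_vars) == 0) fail(peek(), "SELECT lists no variables")

  if (kw(peek()) == "WHERE") advance()
  t <- peek()
  if (is.null(t) || t$value != "{") fail(t, "expected '{' opening the graph pattern")
  advance()

  expand <- function(tok) {
    if (tok$type == "iri") return(substring(tok$value, 2, nchar(tok$value) - 1L))
    if (tok$type == "pname") {
      pfx <- sub(":.*$", "", tok$value)
      local <- sub("^[^:]*:", "", tok$value)
      base <- prefixes[[pfx]]
      if (is.null(base)) stop(sprintf("undeclared prefix '%s:'", pfx), call. = FALSE)
      return(paste0(base, local))
    }
    fail(tok, "expected an IRI or prefixed name")
  }

  rejected <- c("FILTER", "OPTIONAL", "UNION", "GRAPH", "SERVICE", "BIND",
                "VALUES", "MINUS")
  triples <- list()
  ord <- 0L
  repeat {
    t <- peek()
    if (is.null(t)) fail(t, "unterminated graph pattern (missing '}')")
    if (t$value == "}") { advance(); break }
    if (kw(t) %in% rejected)
      stop(sprintf("unsupported SPARQL construct: %s (only chain basic graph patterns are supported)",
                   kw(t)), call. = FALSE)
    if (t$type != "var") fail(t, "triple subject must be a variable")
    subj <- substring(advance()$value, 2)
    repeat {  # predicate-object lists separated by ';'
      pt <- peek()
      if (is.null(pt)) fail(pt, "expected a predicate")
      pred <- if (pt$type == "word" && pt$value == "a") { advance(); "a" }
              else { expand(advance()) }
      repeat {  # object lists separated by ','
        ot <- peek()
        if (is.null(ot)) fail(ot, "expected an object")
        if (ot$type == "var") {
          obj <- substring(ot$value, 2); okind <- "var"
        } else if (ot$type == "string") {
          raw <- substring(ot$value, 2, nchar(ot$value) - 1L)
          obj <- gsub("\\\\(.)", "\\1", raw); okind <- "literal"
        } else if (ot$type %in% c("iri", "pname")) {
          obj <- expand(ot); okind <- "iri"
        } else fail(ot, "object must be a variable, string literal or IRI")
        advance()
        ord <- ord + 1L
        triples[[length(triples) + 1L]] <- data.frame(
          subject = subj, predicate = pred, object = obj,
          object_kind = okind, order = ord, stringsAsFactors = FALSE)
        if (!is.null(peek()) && peek()$value == ",") advance() else break
      }
      if (!is.null(peek()) && peek()$value == ";") {
        advance()
        if (!is.null(peek()) && peek()$value %in% c(".", "}")) break
      } else break
    }
    if (!is.null(peek()) && peek()$value == ".") advance()
  }

  tail_kw <- kw(peek())
  if (tail_kw %in% c("LIMIT", "OFFSET", "ORDER", "GROUP", "HAVING"))
    stop(sprintf("unsupported SPARQL construct: %s (apply row limits client-side via the cursor)",
                 tail_kw), call. = FALSE)
  if (!is.null(peek())) fail(peek(), "trailing tokens after graph pattern")
  if (length(triples) == 0) stop("empty graph pattern", call. = FALSE)

  structure(list(
    select_vars = if (star) "*" else select_vars,
    triples = do.call(rbind, triples)
  ), class = "sparql_bgp")
}

#' @export
print.sparql_bgp <- function(x, ...) {
  cat(sprintf("<sparql_bgp> %d triple pattern(s), select: %s\n",
              nrow(x$triples), paste(x$select_vars, collapse = " ")))
  invisible(x)
}
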