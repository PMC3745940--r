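# RDF schema generation. Each database becomes an RDFS class, each field a
# string-ranged datatype property on its database's class, each directed
# link an object property between the two classes. The schema cannot carry
# the filterable/retrievable asymmetry natively, so it is accompanied by
# side documentation, emitted both as annotation triples on the field
# properties and as a standalone document.

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

capitalize <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

class_iri <- function(ns, db) paste0(ns, capitalize(db))
field_iri <- function(ns, db, code) paste0(ns, db, "_", code)
uid_iri <- function(ns) paste0(ns, "uid")

triple <- function(s, p, o, type) {
  data.frame(subject = s, predicate = p, object = o, type = type,
             stringsAsFactors = FALSE)
}

#' Generate the RDF schema for a registry
#'
#' Class IRIs are `base_namespace` + capitalized database name; field
#' property IRIs are `base_namespace` + dbname + "_" + FIELDCODE; link
#' property IRIs are `base_namespace` + link name. If two databases
#' declare links with the same name, later ones are qualified with their
#' source database name (with a warning) so IRIs stay unique. Field
#' properties additionally carry `filterable`/`retrievable` annotation
#' triples, the machine-readable form of the side documentation. A
#' designated `uid` property is declared for binding entry identifiers.
#'
#' @param registry An `entrez_registry`.
#' @param base_namespace IRI prefix ending in `#` or `/`.
#' @return An `rdf_schema` object: `$classes`, `$datatype_properties`,
#'   `$object_properties`, `$triples` (one row per triple) and
#'   `$serialized_text` (canonical Turtle).
#' @export
generate_schema <- function(registry,
                            base_namespace = "http://example.org/entrez#") {
  if (!inherits(registry, "entrez_registry") || length(registry$databases) == 0)
    stop("schema error: registry is empty", call. = FALSE)
  ns <- base_namespace
  dbs <- registry$databases[order(names(registry$databases))]

  triples <- list()
  classes <- data.frame(db = character(), iri = character(), stringsAsFactors = FALSE)
  dprops <- data.frame(db = character(), field = character(), iri = character(),
                       stringsAsFactors = FALSE)
  oprops <- data.frame(source = character(), name = character(),
                       target = character(), iri = character(),
                       stringsAsFactors = FALSE)

  for (db in dbs) {
    ci <- class_iri(ns, db$name)
    classes <- rbind(classes, data.frame(db = db$name, iri = ci,
                                         stringsAsFactors = FALSE))
    triples[[length(triples) + 1L]] <- rbind(
      triple(ci, paste0(RDF_NS, "type"), paste0(RDFS_NS, "Class"), "iri"),
      triple(ci, paste0(RDFS_NS, "label"), db$name, "literal"),
      if (nzchar(db$description))
        triple(ci, paste0(RDFS_NS, "comment"), db$description, "literal")
    )
    flds <- db$fields[order(db$fields$name), , drop = FALSE]
    for (i in seq_len(nrow(flds))) {
      fi <- field_iri(ns, db$name, flds$name[i])
      dprops <- rbind(dprops, data.frame(db = db$name, field = flds$name[i],
                                         iri = fi, stringsAsFactors = FALSE))
      triples[[length(triples) + 1L]] <- rbind(
        triple(fi, paste0(RDF_NS, "type"), paste0(RDF_NS, "Property"), "iri"),
        triple(fi, paste0(RDFS_NS, "domain"), ci, "iri"),
        triple(fi, paste0(RDFS_NS, "range"), paste0(XSD_NS, "string"), "iri"),
        triple(fi, paste0(RDFS_NS, "label"), flds$full_name[i], "literal"),
        triple(fi, paste0(ns, "filterable"),
               if (flds$filterable[i]) "true" else "false", "literal"),
        triple(fi, paste0(ns, "retrievable"),
               if (flds$retrievable[i]) "true" else "false", "literal")
      )
    }
  }

  seen_links <- character(0)
  for (db in dbs) {
    lks <- db$links[order(db$links$name), , drop = FALSE]
    for (i in seq_len(nrow(lks))) {
      li <- paste0(ns, lks$name[i])
      if (li %in% seen_links) {
        es_warn("schema: link IRI collision for '%s'; qualifying with source '%s'",
                lks$name[i], db$name)
        li <- paste0(ns, db$name, ".", lks$name[i])
      }
      seen_links <- c(seen_links, li)
      oprops <- rbind(oprops, data.frame(
        source = db$name, name = lks$name[i], target = lks$target[i],
        iri = li, stringsAsFactors = FALSE))
      triples[[length(triples) + 1L]] <- rbind(
        triple(li, paste0(RDF_NS, "type"), paste0(RDF_NS, "Property"), "iri"),
        triple(li, paste0(RDFS_NS, "domain"), class_iri(ns, db$name), "iri"),
        triple(li, paste0(RDFS_NS, "range"), class_iri(ns, lks$target[i]), "iri"),
        triple(li, paste0(RDFS_NS, "label"), lks$name[i], "literal")
      )
    }
  }

  # entry-UID property, projectable on any class
  ui <- uid_iri(ns)
  triples[[length(triples) + 1L]] <- rbind(
    triple(ui, paste0(RDF_NS, "type"), paste0(RDF_NS, "Property"), "iri"),
    triple(ui, paste0(RDFS_NS, "range"), paste0(XSD_NS, "string"), "iri"),
    triple(ui, paste0(RDFS_NS, "label"), "entry UID", "literal")
  )

  tr <- do.call(rbind, triples)
  rownames(tr) <- NULL
  schema <- structure(list(
    base_namespace = ns,
    classes = classes,
    datatype_properties = dprops,
    object_properties = oprops,
    triples = tr,
    serialized_text = NULL
  ), class = "rdf_schema")
  schema$serialized_text <- serialize_turtle(schema)
  schema
}

# Canonical Turtle: fixed prefix block, triples sorted by (subject,
# predicate, object) with rdf:type first per subject, one triple per line.
serialize_turtle <- function(schema) {
  ns <- schema$base_namespace
  tr <- schema$triples
  shorten <- function(iri) {
    ifelse(startsWith(iri, ns), paste0(":", substring(iri, nchar(ns) + 1)),
    ifelse(startsWith(iri, RDF_NS), paste0("rdf:", substring(iri, nchar(RDF_NS) + 1)),
    ifelse(startsWith(iri, RDFS_NS), paste0("rdfs:", substring(iri, nchar(RDFS_NS) + 1)),
    ifelse(startsWith(iri, XSD_NS), paste0("xsd:", substring(iri, nchar(XSD_NS) + 1)),
           paste0("<", iri, ">")))))
  }
  obj <- ifelse(tr$type == "iri", shorten(tr$object),
                paste0("\"", ttl_escape(tr$object), "\""))
  pred <- shorten(tr$predicate)
  pred[tr$predicate == paste0(RDF_NS, "type")] <- "a"
  subj <- shorten(tr$subject)
  is_type <- tr$predicate == paste0(RDF_NS, "type")
  ord <- order(subj, !is_type, pred, obj, method = "radix")
  lines <- c(
    sprintf("@prefix : <%s> .", ns),
    sprintf("@prefix rdf: <%s> .", RDF_NS),
    sprintf("@prefix rdfs: <%s> .", RDFS_NS),
    sprintf("@prefix xsd: <%s> .", XSD_NS),
    "",
    paste0(subj[ord], " ", pred[ord], " ", obj[ord], " .")
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

serialize_rdfxml <- function(schema) {
  tr <- schema$triples
  doc <- xml2::xml_new_root("rdf:RDF",
                            "xmlns:rdf" = RDF_NS, "xmlns:rdfs" = RDFS_NS)
  split_iri <- function(iri) {
    pos <- max(regexpr("[#/](?=[^#/]*$)", iri, perl = TRUE))
    c(substring(iri, 1, pos), substring(iri, pos + 1))
  }
  subj <- unique(tr$subject[order(tr$subject, method = "radix")])
  for (s in subj) {
    node <- xml2::xml_add_child(doc, "rdf:Description", "rdf:about" = s)
    rows <- tr[tr$subject == s, , drop = FALSE]
    rows <- rows[order(rows$predicate, rows$object, method = "radix"), , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      p <- split_iri(rows$predicate[i])
      el <- xml2::xml_add_child(node, paste0("p:", p[2]), "xmlns:p" = p[1])
      if (rows$type[i] == "iri") xml2::xml_set_attr(el, "rdf:resource", rows$object[i])
      else xml2::xml_set_text(el, rows$object[i])
    }
  }
  doc
}

#' Write the schema to disk
#'
#' @param schema An `rdf_schema`.
#' @param path Output file path.
#' @param format `"turtle"` (canonical) or `"rdfxml"`.
#' @export
write_schema <- function(schema, path, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  if (format == "turtle") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(schema$serialized_text, con, eos = NULL, useBytes = TRUE)
  } else {
    xml2::write_xml(serialize_rdfxml(schema), path)
  }
  invisible(path)
}

#' @export
print.rdf_schema <- function(x, ...) {
  cat(sprintf("<rdf_schema> %d class(es), %d datatype propertie(s), %d object propertie(s)\n",
              nrow(x$classes), nrow(x$datatype_properties),
              nrow(x$object_properties)))
  cat(sprintf("  namespace: %s\n", x$base_namespace))
  invisible(x)
}

#' Side documentation of the filterable/retrievable asymmetry
#'
#' The RDF schema alone cannot express that some fields may only appear
#' in search filters and others only in retrieved results. This document
#' lists, per database, the filter-only and retrieve-only field codes;
#' fields usable in both roles appear in neither list.
#'
#' @param registry An `entrez_registry`.
#' @return A `side_doc`: named list (db -> list(filter_only, retrieve_only)).
#' @export
generate_side_doc <- function(registry) {
  if (!inherits(registry, "entrez_registry") || length(registry$databases) == 0)
    stop("side-doc error: registry is empty", call. = FALSE)
  dbs <- registry$databases[order(names(registry$databases))]
  out <- lapply(dbs, function(db) {
    f <- db$fields
    list(filter_only = sort(f$name[f$filterable & !f$retrievable]),
         retrieve_only = sort(f$name[!f$filterable & f$retrievable]))
  })
  structure(out, class = "side_doc")
}

#' @export
print.side_doc <- function(x, ...) {
  cat("<side_doc> filterable/retrievable asymmetry\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: filter-only {%s}; retrieve-only {%s}\n", nm,
                paste(x[[nm]]$filter_only, collapse = ", "),
                paste(x[[nm]]$retrieve_only, collapse = ", ")))
  }
  invisible(x)
}

#' Write side documentation (JSON and plain text)
#'
#' @param side A `side_doc`.
#' @param json_path,text_path Output paths (either may be `NULL` to skip).
#' @export
write_side_doc <- function(side, json_path = NULL, text_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(side), json_path, auto_unbox = FALSE, pretty = TRUE)
  if (!is.null(text_path)) {
    lines <- c("Filterable/retrievable field asymmetry", "")
    for (nm in names(side)) {
      lines <- c(lines, sprintf("%s:", nm),
                 sprintf("  filter-only (usable in search terms, never in results): %s",
                         paste(side[[nm]]$filter_only, collapse = " ") %||% ""),
                 sprintf("  retrieve-only (present in results, not searchable): %s",
                         paste(side[[nm]]$retrieve_only, collapse = " ")))
    }
    write_text(paste(lines, collapse = "\n"), text_path)
  }
  invisible(side)
}
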