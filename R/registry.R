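# Metadata registry: parse EInfo-dialect documents describing Entrez-style
# databases (fields, inter-database links) and classify each field as
# filterable (usable in search terms) and/or retrievable (present in
# fetched results). The two sets differ per database, and the asymmetry is
# load-bearing for query validation downstream.

#' Parse the EInfo master database list
#'
#' The master document enumerates every database exposed by the
#' repository, one `DbName` element per database under `DbList`.
#'
#' @param document XML text (EInfo master dialect).
#' @return Character vector of database names in document order,
#'   lowercased, duplicates removed keeping the first occurrence. An empty
#'   `DbList` yields `character(0)`.
#' @examples
#' parse_einfo_master(
#'   "<eInfoResult><DbList><DbName>pubmed</DbName>
#'    <DbName>gene</DbName></DbList></eInfoResult>")
#' @export
parse_einfo_master <- function(document) {
  doc <- tryCatch(
    xml2::read_xml(document),
    error = function(e) stop("EInfo master parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  names <- xml2::xml_text(xml2::xml_find_all(doc, ".//DbList/DbName"))
  names <- tolower(trimws(names))
  names <- names[nzchar(names)]
  unique(names)
}

new_entrez_db <- function(name, description = "", fields = NULL, links = NULL,
                          supports_efetch = TRUE) {
  structure(list(
    name = name,
    description = description,
    fields = fields %||% data.frame(name = character(), full_name = character(),
                                    filterable = logical(), retrievable = logical(),
                                    stringsAsFactors = FALSE),
    links = links %||% data.frame(name = character(), target = character(),
                                  stringsAsFactors = FALSE),
    supports_efetch = isTRUE(supports_efetch)
  ), class = "entrez_db")
}

#' Parse a per-database EInfo document
#'
#' Reads one database description: name, free-text description, the field
#' list and the link list. Every declared field is marked filterable;
#' retrievable flags stay `FALSE` until [classify_retrievable()] supplies
#' evidence (a DTD or a sample summary document).
#'
#' @param document XML text (EInfo per-database dialect:
#'   `DbInfo/DbName`, `Description`, `FieldList/Field/Name`+`FullName`,
#'   `LinkList/Link/Name`+`DbTo`).
#' @return An `entrez_db` descriptor.
#' @export
parse_einfo_db <- function(document) {
  doc <- tryCatch(
    xml2::read_xml(document),
    error = function(e) stop("EInfo parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  name_node <- xml2::xml_find_first(doc, ".//DbInfo/DbName")
  if (inherits(name_node, "xml_missing"))
    stop("EInfo document has no DbInfo/DbName element", call. = FALSE)
  db_name <- tolower(trimws(xml2::xml_text(name_node)))
  descr <- xml2::xml_find_first(doc, ".//DbInfo/Description")
  descr <- if (inherits(descr, "xml_missing")) "" else trimws(xml2::xml_text(descr))

  fnodes <- xml2::xml_find_all(doc, ".//DbInfo/FieldList/Field")
  fname <- character(0); ffull <- character(0)
  for (fn in fnodes) {
    nm <- xml2::xml_find_first(fn, "./Name")
    if (inherits(nm, "xml_missing") || !nzchar(trimws(xml2::xml_text(nm)))) {
      es_warn("einfo[%s]: field entry without a name skipped", db_name)
      next
    }
    code <- toupper(trimws(xml2::xml_text(nm)))
    if (code %in% fname) next
    full <- xml2::xml_find_first(fn, "./FullName")
    full <- if (inherits(full, "xml_missing")) code else trimws(xml2::xml_text(full))
    fname <- c(fname, code); ffull <- c(ffull, full)
  }

  lnodes <- xml2::xml_find_all(doc, ".//DbInfo/LinkList/Link")
  lname <- character(0); ltarget <- character(0)
  for (ln in lnodes) {
    nm <- xml2::xml_find_first(ln, "./Name")
    to <- xml2::xml_find_first(ln, "./DbTo")
    if (inherits(nm, "xml_missing") || inherits(to, "xml_missing")) {
      es_warn("einfo[%s]: link entry missing Name or DbTo skipped", db_name)
      next
    }
    nmv <- tolower(trimws(xml2::xml_text(nm)))
    if (nmv %in% lname) next
    lname <- c(lname, nmv)
    ltarget <- c(ltarget, tolower(trimws(xml2::xml_text(to))))
  }

  new_entrez_db(
    name = db_name, description = descr,
    fields = data.frame(name = fname, full_name = ffull,
                        filterable = rep(TRUE, length(fname)),
                        retrievable = rep(FALSE, length(fname)),
                        stringsAsFactors = FALSE),
    links = data.frame(name = lname, target = ltarget, stringsAsFactors = FALSE)
  )
}

# Leaf elements declared as (#PCDATA) in a DTD are the retrievable fields;
# structural elements (those with child content models) are skipped.
dtd_field_codes <- function(dtd_text) {
  m <- gregexpr("<!ELEMENT\\s+([A-Za-z0-9_.:-]+)\\s+\\(\\s*#PCDATA\\s*\\)",
                dtd_text, perl = TRUE)
  hits <- regmatches(dtd_text, m)[[1]]
  if (length(hits) == 0) return(character(0))
  codes <- sub("<!ELEMENT\\s+([A-Za-z0-9_.:-]+).*", "\\1", hits, perl = TRUE)
  unique(toupper(codes))
}

# Sample-document rule: the tag names of leaf elements under each result
# item are the retrievable field codes. `Id` carries the UID, not a field.
sample_doc_field_codes <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  root_name <- xml2::xml_name(xml2::xml_root(doc))
  leaves <- xml2::xml_find_all(doc, "//*[not(*)]")
  codes <- xml2::xml_name(leaves)
  codes <- codes[!tolower(codes) %in% c("id", tolower(root_name))]
  unique(toupper(codes))
}

#' Classify retrievable fields from fetch evidence
#'
#' Databases that support the fetch operation publish a DTD whose
#' `#PCDATA` elements name the retrievable fields; for the others a sample
#' summary result document is analysed instead (the tag names of leaf
#' elements under each result item). Fields named by the evidence are
#' flagged retrievable; evidence fields absent from the EInfo field list
#' are added as retrieve-only fields (their label defaults to the code);
#' EInfo fields absent from the evidence stay filter-only.
#'
#' @param db An `entrez_db` descriptor from [parse_einfo_db()].
#' @param evidence DTD text or sample-document XML text.
#' @param kind `"auto"` (detect a DTD by its `<!ELEMENT` declarations),
#'   `"dtd"` or `"esummary"`. The kind also fixes `supports_efetch`.
#' @return The descriptor with retrievable flags (and possibly new
#'   retrieve-only fields) filled in.
#' @export
classify_retrievable <- function(db, evidence, kind = c("auto", "dtd", "esummary")) {
  kind <- match.arg(kind)
  if (kind == "auto")
    kind <- if (grepl("<!ELEMENT", evidence, fixed = TRUE)) "dtd" else "esummary"
  codes <- tryCatch(
    if (kind == "dtd") dtd_field_codes(evidence) else sample_doc_field_codes(evidence),
    error = function(e) stop(sprintf("retrievable-field classification failed for '%s': %s",
                                     db$name, conditionMessage(e)), call. = FALSE)
  )
  db$supports_efetch <- kind == "dtd"
  if (length(codes) == 0) {
    es_warn("classify[%s]: evidence names zero fields; no retrievable fields", db$name)
    db$fields$retrievable <- FALSE
    return(db)
  }
  db$fields$retrievable <- db$fields$name %in% codes
  extra <- setdiff(codes, db$fields$name)
  if (length(extra) > 0) {
    db$fields <- rbind(db$fields, data.frame(
      name = extra, full_name = extra,
      filterable = FALSE, retrievable = TRUE, stringsAsFactors = FALSE))
  }
  rownames(db$fields) <- NULL
  db
}

#' Build a registry from metadata documents
#'
#' Assembles the full catalogue: parses the master list, each per-database
#' EInfo document and each piece of retrievable-field evidence, then
#' enforces closure. Databases named by the master but missing a
#' per-database document are skipped with a warning; links pointing at a
#' database outside the registry are pruned with a warning; fields that
#' end up neither filterable nor retrievable are dropped with a warning.
#'
#' @param master XML text of the master database list.
#' @param per_db Named list (database name -> EInfo XML text).
#' @param evidence Named list (database name -> DTD or sample-document
#'   text); databases without evidence keep filter-only fields.
#' @return An `entrez_registry`.
#' @export
build_registry <- function(master, per_db, evidence = list()) {
  names_master <- parse_einfo_master(master)
  if (length(names_master) == 0)
    stop("registry error: master document lists no databases", call. = FALSE)
  dbs <- list()
  for (nm in names_master) {
    if (is.null(per_db[[nm]])) {
      es_warn("registry: no EInfo document for '%s'; database skipped", nm)
      next
    }
    db <- tryCatch(parse_einfo_db(per_db[[nm]]), error = function(e) {
      es_warn("registry: EInfo for '%s' unparseable (%s); database skipped",
              nm, conditionMessage(e))
      NULL
    })
    if (is.null(db)) next
    if (!is.null(evidence[[nm]]))
      db <- classify_retrievable(db, evidence[[nm]])
    keep <- db$fields$filterable | db$fields$retrievable
    if (any(!keep)) {
      es_warn("registry[%s]: dropping field(s) neither filterable nor retrievable: %s",
              nm, paste(db$fields$name[!keep], collapse = ", "))
      db$fields <- db$fields[keep, , drop = FALSE]
      rownames(db$fields) <- NULL
    }
    dbs[[db$name]] <- db
  }
  if (length(dbs) == 0)
    stop("registry error: zero parseable databases", call. = FALSE)
  # closure: prune links whose target is outside the registry
  for (nm in names(dbs)) {
    lk <- dbs[[nm]]$links
    ok <- lk$target %in% names(dbs)
    if (any(!ok)) {
      es_warn("registry[%s]: pruning link(s) to unknown database(s): %s",
              nm, paste(lk$name[!ok], collapse = ", "))
      dbs[[nm]]$links <- lk[ok, , drop = FALSE]
      rownames(dbs[[nm]]$links) <- NULL
    }
  }
  structure(list(
    databases = dbs,
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "entrez_registry")
}

#' @export
print.entrez_registry <- function(x, ...) {
  cat(sprintf("<entrez_registry> %d database(s), generated %s\n",
              length(x$databases), x$generated_at))
  for (db in x$databases) {
    cat(sprintf("  %-12s %2d field(s) [%d filterable / %d retrievable], %d link(s)%s\n",
                db$name, nrow(db$fields), sum(db$fields$filterable),
                sum(db$fields$retrievable), nrow(db$links),
                if (db$supports_efetch) "" else " (summary only)"))
  }
  invisible(x)
}

#' @export
print.entrez_db <- function(x, ...) {
  cat(sprintf("<entrez_db> %s: %d field(s), %d link(s), efetch=%s\n",
              x$name, nrow(x$fields), nrow(x$links), x$supports_efetch))
  invisible(x)
}

registry_db <- function(registry, name) {
  db <- registry$databases[[name]]
  if (is.null(db)) stop(sprintf("unknown database '%s'", name), call. = FALSE)
  db
}

registry_link <- function(registry, source_db, link_name) {
  db <- registry_db(registry, source_db)
  i <- match(link_name, db$links$name)
  if (is.na(i)) return(NULL)
  list(name = link_name, source_db = source_db, target_db = db$links$target[i])
}

#' Write / read the registry cache
#'
#' The cache is a single JSON document: one entry per database carrying
#' its description, field table (with both flags) and link table.
#'
#' @param registry An `entrez_registry`.
#' @param path File path for the JSON cache.
#' @return `write_registry` returns `path` invisibly; `read_registry`
#'   returns the reloaded `entrez_registry`.
#' @export
write_registry <- function(registry, path) {
  payload <- list(
    generated_at = registry$generated_at,
    databases = lapply(registry$databases, function(db) list(
      name = db$name,
      description = db$description,
      supports_efetch = db$supports_efetch,
      fields = db$fields,
      links = db$links
    ))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  dbs <- lapply(payload$databases, function(d) {
    fields <- d$fields
    links <- d$links
    if (length(fields) == 0 || is.null(dim(fields)))
      fields <- data.frame(name = character(), full_name = character(),
                           filterable = logical(), retrievable = logical(),
                           stringsAsFactors = FALSE)
    if (length(links) == 0 || is.null(dim(links)))
      links <- data.frame(name = character(), target = character(),
                          stringsAsFactors = FALSE)
    new_entrez_db(d$name, d$description %||% "", as.data.frame(fields),
                  as.data.frame(links), isTRUE(d$supports_efetch))
  })
  names(dbs) <- vapply(dbs, function(d) d$name, character(1))
  structure(list(databases = dbs, generated_at = payload$generated_at),
            class = "entrez_registry")
}
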