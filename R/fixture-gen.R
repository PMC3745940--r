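# Seeded synthetic fixture generator. The fixtures emulate the structural
# features the query-resolution algorithm exploits: several databases,
# named directed links (consecutive databases are linked in both
# directions, so a reciprocal pair always exists when there are at least
# two databases), asymmetric filterable/retrievable field sets, and
# variable fan-out (0, 1, many) in the link tables. Field values are drawn
# from a small word pool so search-term selectivity is controllable.

DB_NAME_POOL <- c("pubmed", "gene", "protein", "nuccore", "taxonomy",
                  "snp", "omim", "structure", "biosample", "sra")
FIELD_POOL <- c("TITL", "ABST", "AUTH", "PDAT", "LANG", "MESH", "JOUR",
                "ORGN", "ACCN", "SYMB", "DESC", "CHRM", "LOCN", "FUNC")
WORD_POOL <- c("wilms", "tumor", "kidney", "cancer", "gene", "protein",
               "human", "mouse", "liver", "brain", "signal", "pathway")

sample_fanout <- function(spec, n) {
  if (is.null(names(spec))) {
    if (!is.numeric(spec) || length(spec) == 0 || any(spec < 0) ||
        any(spec != floor(spec)))
      stop("invalid fan-out spec: need non-negative integers", call. = FALSE)
    spec[sample.int(length(spec), n, replace = TRUE)]
  } else {
    vals <- suppressWarnings(as.numeric(names(spec)))
    if (any(is.na(vals)) || any(vals < 0) || any(spec < 0) || sum(spec) <= 0)
      stop("invalid fan-out spec: names must be counts, weights non-negative",
           call. = FALSE)
    vals[sample.int(length(vals), n, replace = TRUE, prob = spec)]
  }
}

#' Generate a seeded synthetic mock dataset
#'
#' Deterministic for a given seed. Databases are linked pairwise along a
#' chain in both directions (e.g. `pubmed_gene` and `gene_pubmed`), each
#' database gets 4–8 fields of which a configurable fraction is
#' asymmetric (filter-only or retrieve-only), and each source record's
#' fan-out per link is drawn from `fanout`. The manifest records the
#' exact ground truth (counts, per-link fan-outs, field classification)
#' so test oracles can read it instead of re-deriving it.
#'
#' @param seed Integer RNG seed.
#' @param n_dbs Number of databases (>= 1).
#' @param records_per_db Integer range `c(lo, hi)` (or a single count).
#' @param fanout Allowed per-record fan-outs: an unnamed integer vector
#'   (uniform) or a named numeric vector of weights, e.g.
#'   `c("0" = 1, "1" = 2, "5" = 1)`.
#' @param asymmetric_field_fraction Fraction of fields made filter-only
#'   or retrieve-only (split evenly).
#' @return A `mock_dataset` whose `$manifest` holds the ground truth.
#' @export
generate_fixture <- function(seed, n_dbs = 3, records_per_db = c(8, 15),
                             fanout = c(0, 1, 2),
                             asymmetric_field_fraction = 0.25) {
  if (n_dbs < 1) stop("n_dbs must be >= 1", call. = FALSE)
  if (length(records_per_db) == 1) records_per_db <- rep(records_per_db, 2)
  with_seed(seed, {
    db_names <- sample(DB_NAME_POOL, min(n_dbs, length(DB_NAME_POOL)))
    if (n_dbs > length(DB_NAME_POOL))
      db_names <- c(db_names, sprintf("db%02d", seq_len(n_dbs - length(DB_NAME_POOL))))

    dbs <- list(); tables <- list(); field_class <- list()
    for (nm in db_names) {
      k <- sample(4:8, 1)
      codes <- sort(sample(FIELD_POOL, k))
      n_asym <- round(k * asymmetric_field_fraction)
      roles <- rep("both", k)
      if (n_asym > 0) {
        idx <- sample(k, n_asym)
        roles[idx] <- sample(c("filter_only", "retrieve_only"), n_asym,
                             replace = TRUE)
      }
      # every database must keep at least one field usable in each role
      if (!any(roles %in% c("both", "filter_only"))) roles[1] <- "filter_only"
      if (!any(roles %in% c("both", "retrieve_only"))) roles[k] <- "retrieve_only"
      fields <- data.frame(
        name = codes,
        full_name = paste0(codes, " field"),
        filterable = roles %in% c("both", "filter_only"),
        retrievable = roles %in% c("both", "retrieve_only"),
        stringsAsFactors = FALSE)
      dbs[[nm]] <- new_entrez_db(nm, sprintf("Synthetic %s database", nm),
                                 fields, NULL,
                                 supports_efetch = stats::runif(1) < 0.5)
      field_class[[nm]] <- stats::setNames(roles, codes)

      rr <- records_per_db[1]:records_per_db[2]
      n_rec <- rr[sample.int(length(rr), 1)]
      tab <- list()
      for (i in seq_len(n_rec)) {
        uid <- sprintf("%05d", i)
        vals <- character(0)
        for (code in codes) {
          if (stats::runif(1) < 0.8)
            vals[[code]] <- paste(sample(WORD_POOL, sample(1:3, 1),
                                         replace = TRUE), collapse = " ")
        }
        tab[[uid]] <- vals
      }
      tables[[nm]] <- tab
    }

    # directed links between consecutive databases, both ways
    link_tables <- list()
    link_manifest <- list()
    if (n_dbs >= 2) {
      for (i in seq_len(n_dbs - 1)) {
        for (dir in list(c(i, i + 1), c(i + 1, i))) {
          src <- db_names[dir[1]]; tgt <- db_names[dir[2]]
          lname <- paste(src, tgt, sep = "_")
          dbs[[src]]$links <- rbind(dbs[[src]]$links,
                                    data.frame(name = lname, target = tgt,
                                               stringsAsFactors = FALSE))
          src_uids <- names(tables[[src]]); tgt_uids <- names(tables[[tgt]])
          fo <- sample_fanout(fanout, length(src_uids))
          lt <- list()
          for (j in seq_along(src_uids)) {
            k <- min(fo[j], length(tgt_uids))
            if (k > 0) lt[[src_uids[j]]] <- sort(sample(tgt_uids, k))
          }
          link_tables[[lname]] <- lt
          link_manifest[[lname]] <- list(source = src, target = tgt,
                                         fanout = stats::setNames(fo, src_uids))
        }
      }
    }

    registry <- structure(list(databases = dbs, generated_at = "fixture"),
                          class = "entrez_registry")
    manifest <- list(
      seed = seed, n_dbs = n_dbs,
      records_per_db = records_per_db,
      asymmetric_field_fraction = asymmetric_field_fraction,
      databases = db_names,
      record_counts = stats::setNames(
        vapply(db_names, function(nm) length(tables[[nm]]), integer(1)), db_names),
      field_class = field_class,
      links = link_manifest,
      supports_efetch = stats::setNames(
        vapply(db_names, function(nm) dbs[[nm]]$supports_efetch, logical(1)),
        db_names)
    )
    mock_dataset(registry, tables, link_tables, manifest = manifest)
  })
}

# --- EInfo-dialect serialization of a fixture ------------------------------
# These let the metadata module be exercised end to end against synthetic
# datasets: the generator's registry is rendered back into the same XML
# dialect the parsers consume.

#' Render EInfo-dialect documents for a dataset
#'
#' Produces the master list, one per-database EInfo document (fields and
#' links only; retrievable flags are evidence, not EInfo content) and one
#' piece of retrievable-field evidence per database: a DTD for databases
#' supporting fetch, otherwise a sample summary document built from the
#' first record.
#'
#' @param dataset A `mock_dataset`.
#' @return list(master, per_db = named list of XML, evidence = named list).
#' @export
fixture_einfo_docs <- function(dataset) {
  reg <- dataset$registry
  master <- paste0(
    "<eInfoResult><DbList>",
    paste(sprintf("<DbName>%s</DbName>", names(reg$databases)), collapse = ""),
    "</DbList></eInfoResult>")
  per_db <- lapply(reg$databases, function(db) {
    flds <- db$fields[db$fields$filterable, , drop = FALSE]
    paste0(
      "<eInfoResult><DbInfo>",
      sprintf("<DbName>%s</DbName>", db$name),
      sprintf("<Description>%s</Description>", xml_escape(db$description)),
      "<FieldList>",
      paste(sprintf("<Field><Name>%s</Name><FullName>%s</FullName></Field>",
                    flds$name, xml_escape(flds$full_name)), collapse = ""),
      "</FieldList><LinkList>",
      paste(sprintf("<Link><Name>%s</Name><DbTo>%s</DbTo></Link>",
                    db$links$name, db$links$target), collapse = ""),
      "</LinkList></DbInfo></eInfoResult>")
  })
  evidence <- lapply(reg$databases, function(db) {
    codes <- db$fields$name[db$fields$retrievable]
    if (db$supports_efetch) {
      root <- sprintf("%sRecordSet", capitalize(db$name))
      paste(c(sprintf("<!ELEMENT %s (Record*)>", root),
              sprintf("<!ELEMENT Record (Id%s)>",
                      if (length(codes)) paste0(", ", paste(codes, collapse = "?, "), "?")
                      else ""),
              sprintf("<!ELEMENT %s (#PCDATA)>", codes)),
            collapse = "\n")
    } else {
      tab <- dataset$tables[[db$name]]
      uid <- if (length(tab) > 0) names(tab)[1] else "00000"
      vals <- if (length(tab) > 0) tab[[1]] else character(0)
      items <- vapply(codes, function(code) {
        v <- if (code %in% names(vals)) vals[[code]] else ""
        sprintf("<%s>%s</%s>", code, xml_escape(v), code)
      }, character(1))
      paste0("<eSummaryResult><DocSum><Id>", uid, "</Id>",
             paste(items, collapse = ""), "</DocSum></eSummaryResult>")
    }
  })
  list(master = master, per_db = per_db, evidence = evidence)
}

# --- Fixture directory round-trip ------------------------------------------

#' Write a mock dataset as a fixture directory
#'
#' Layout: `registry.json`, `manifest.json`, `tables/<db>.json`,
#' `links/<name>.json`, plus `einfo/` holding the EInfo-dialect master,
#' per-database documents and evidence texts. All files are plain text
#' and byte-stable for a given dataset.
#'
#' @param dataset A `mock_dataset`.
#' @param dir Target directory (created if needed).
#' @export
write_fixture <- function(dataset, dir) {
  for (d in c(dir, file.path(dir, c("tables", "links", "einfo"))))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  write_registry(dataset$registry, file.path(dir, "registry.json"))
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(dataset$summary_fields, file.path(dir, "summary_fields.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  for (db in names(dataset$tables))
    jsonlite::write_json(lapply(dataset$tables[[db]], as.list),
                         file.path(dir, "tables", paste0(db, ".json")),
                         auto_unbox = TRUE, pretty = TRUE)
  for (lk in names(dataset$link_tables))
    jsonlite::write_json(dataset$link_tables[[lk]],
                         file.path(dir, "links", paste0(lk, ".json")),
                         auto_unbox = FALSE, pretty = TRUE)
  docs <- fixture_einfo_docs(dataset)
  write_text(docs$master, file.path(dir, "einfo", "master.xml"))
  for (nm in names(docs$per_db))
    write_text(docs$per_db[[nm]], file.path(dir, "einfo", paste0(nm, ".xml")))
  for (nm in names(docs$evidence)) {
    ext <- if (dataset$registry$databases[[nm]]$supports_efetch) "dtd" else "sample.xml"
    write_text(docs$evidence[[nm]],
               file.path(dir, "einfo", paste0(nm, ".", ext)))
  }
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  registry <- read_registry(file.path(dir, "registry.json"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sf_path <- file.path(dir, "summary_fields.json")
  summary_fields <- if (file.exists(sf_path))
    lapply(jsonlite::read_json(sf_path, simplifyVector = TRUE), as.character)
  else NULL
  tables <- list()
  for (f in sort(list.files(file.path(dir, "tables"), full.names = TRUE))) {
    db <- sub("\\.json$", "", basename(f))
    tab <- jsonlite::read_json(f, simplifyVector = FALSE)
    tables[[db]] <- lapply(tab, function(v) unlist(v) %||% character(0))
  }
  link_tables <- list()
  for (f in sort(list.files(file.path(dir, "links"), full.names = TRUE))) {
    lk <- sub("\\.json$", "", basename(f))
    lt <- jsonlite::read_json(f, simplifyVector = FALSE)
    link_tables[[lk]] <- lapply(lt, function(v) as.character(unlist(v)))
  }
  mock_dataset(registry, tables, link_tables, summary_fields = summary_fields,
               manifest = manifest)
}
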