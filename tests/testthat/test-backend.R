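# Mock backend semantics (search/link/fetch, history server, request
# log) and the seeded fixture generator.

test_that("search matches terms by case-insensitive substring per conjunct", {
  ds <- topology_dataset(R = 3, L = 5)
  be <- mock_backend(ds)
  sr <- eu_search(be, "pubmed", "\"wilms tumor\"[TITL]")
  # oracle: linear scan of the fixture table
  truth <- names(ds$tables$pubmed)[vapply(ds$tables$pubmed, function(r)
    grepl("wilms tumor", tolower(r[["TITL"]]), fixed = TRUE), logical(1))]
  expect_equal(sr$uids, truth)
  expect_equal(sr$total_count, length(truth))
  # conjunction narrows
  sr2 <- eu_search(be, "pubmed", "\"wilms\"[TITL] AND \"kidney\"[ABST]")
  expect_true(all(sr2$uids %in% sr$uids))
  # no match
  expect_equal(eu_search(be, "pubmed", "\"zzz\"[TITL]")$uids, character(0))
  # unknown field: empty result with warning, not an error
  expect_warning(sr3 <- eu_search(be, "pubmed", "\"x\"[NOPE]"), "unknown field")
  expect_equal(sr3$total_count, 0)
  expect_error(eu_search(be, "nosuch", "\"x\"[TITL]"), "unknown database")
})

test_that("the history server stores searched UID lists under issued keys", {
  ds <- topology_dataset()
  be <- mock_backend(ds)
  sr <- eu_search(be, "pubmed", "\"wilms\"[TITL]", history = TRUE)
  expect_false(is.null(sr$history_key))
  expect_equal(be$history[[sr$history_key$web_env]], sr$uids)
  sr2 <- eu_search(be, "pubmed", "\"gene\"[TITL]", history = TRUE)
  expect_false(identical(sr$history_key$web_env, sr2$history_key$web_env))
  expect_null(eu_search(be, "pubmed", "\"wilms\"[TITL]", history = FALSE)$history_key)
})

test_that("link returns the link table's targets and errors on undeclared links", {
  ds <- topology_dataset(R = 3, L = 5)
  be <- mock_backend(ds)
  expect_equal(eu_link(be, "pubmed", "gene", "pubmed_gene", "R01")$uids, "G1")
  # reciprocal traversal, checked against the fixture table
  expect_equal(eu_link(be, "gene", "pubmed", "gene_pubmed", "G1")$uids,
               ds$link_tables$gene_pubmed$G1)
  # zero fan-out and unknown uid are both empty, not errors
  expect_equal(eu_link(be, "pubmed", "gene", "pubmed_gene", "R03")$uids,
               character(0))
  expect_equal(eu_link(be, "pubmed", "gene", "pubmed_gene", "nouid")$uids,
               character(0))
  expect_error(eu_link(be, "gene", "pubmed", "pubmed_gene", "G1"),
               "undeclared link")
})

test_that("fetch is batched, ordered, and restricted to requested fields", {
  ds <- topology_dataset(R = 3, L = 12)
  be <- mock_backend(ds)
  uids <- rev(names(ds$tables$pubmed))
  n0 <- length(request_log(be))
  recs <- eu_fetch(be, "pubmed", uids, c("TITL", "LANG"))
  # one batch request regardless of batch size
  expect_equal(length(request_log(be)), n0 + 1)
  expect_equal(vapply(recs, function(r) r$uid, character(1)), uids)
  expect_true(all(unlist(lapply(recs, function(r) names(r$values))) %in%
                    c("TITL", "LANG")))
  expect_equal(eu_fetch(be, "pubmed", character(0), "TITL"), list())
  # unknown uid: empty record with warning
  expect_warning(r <- eu_fetch(be, "pubmed", "missing", "TITL"), "unknown uid")
  expect_length(r[[1]]$values, 0)
  # record lacking a requested field simply omits it
  ds2 <- topology_dataset()
  ds2$tables$pubmed$R01 <- ds2$tables$pubmed$R01[c("TITL", "ABST")]
  be2 <- mock_backend(ds2)
  expect_false("LANG" %in% names(eu_fetch(be2, "pubmed", "R01",
                                          c("TITL", "LANG"))[[1]]$values))
})

test_that("summary-only databases serve their configured field subset", {
  ds <- topology_dataset()
  expect_false(ds$registry$databases$gene$supports_efetch)
  ds$summary_fields$gene <- "SYMB"
  be <- mock_backend(ds)
  r <- eu_fetch(be, "gene", "G1", c("SYMB", "DESC"))[[1]]
  expect_equal(names(r$values), "SYMB")
  # a database with neither fetch nor summary capability is an error
  ds$summary_fields$gene <- character(0)
  expect_error(eu_fetch(mock_backend(ds), "gene", "G1", "SYMB"),
               "neither fetch nor summary")
})

test_that("mock operations are pure functions of dataset and arguments", {
  ds <- generate_fixture(31, n_dbs = 2)
  be <- mock_backend(ds)
  db <- names(ds$tables)[1]
  fld <- ds$registry$databases[[db]]$fields$name[
    ds$registry$databases[[db]]$fields$filterable][1]
  term <- sprintf("\"wilms\"[%s]", fld)
  expect_equal(eu_search(be, db, term)$uids, eu_search(be, db, term)$uids)
})

test_that("dataset invariants are validated at construction", {
  reg <- bibdb_registry()
  expect_error(
    mock_dataset(reg, tables = list(pubmed = list(P1 = c(NOPE = "x"))),
                 link_tables = list()),
    "undeclared field")
  expect_error(
    mock_dataset(reg,
                 tables = list(pubmed = list(P1 = c(TITL = "t")), gene = list()),
                 link_tables = list(pubmed_gene = list(P1 = "GHOST"))),
    "unknown uid")
  # validate = FALSE admits deliberately stale links
  stale <- mock_dataset(reg,
                        tables = list(pubmed = list(P1 = c(TITL = "t")), gene = list()),
                        link_tables = list(pubmed_gene = list(P1 = "GHOST")),
                        validate = FALSE)
  expect_s3_class(stale, "mock_dataset")
})

test_that("fixture generation is deterministic and honors its manifest", {
  d1 <- generate_fixture(99, n_dbs = 3, records_per_db = c(5, 9))
  d2 <- generate_fixture(99, n_dbs = 3, records_per_db = c(5, 9))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_fixture(d1, dir1); write_fixture(d2, dir2)
  files <- list.files(dir1, recursive = TRUE)
  expect_setequal(files, list.files(dir2, recursive = TRUE))
  for (f in files)
    expect_identical(readBin(file.path(dir1, f), "raw", file.size(file.path(dir1, f))),
                     readBin(file.path(dir2, f), "raw", file.size(file.path(dir2, f))),
                     label = f)
  # manifest reflects the data
  expect_equal(unname(d1$manifest$record_counts),
               unname(vapply(d1$tables, length, integer(1))))
  # reciprocal pair between consecutive databases
  dbs <- d1$manifest$databases
  expect_true(paste(dbs[1], dbs[2], sep = "_") %in% names(d1$link_tables) ||
                length(d1$link_tables) == 0)
  expect_true(paste(dbs[2], dbs[1], sep = "_") %in% names(d1$link_tables))
  # different seeds differ
  expect_false(identical(d1$tables, generate_fixture(100, n_dbs = 3,
                                                     records_per_db = c(5, 9))$tables))
})

test_that("fixture directories round-trip through read_fixture", {
  ds <- generate_fixture(77, n_dbs = 3)
  dir <- withr::local_tempdir()
  write_fixture(ds, dir)
  back <- read_fixture(dir)
  expect_equal(names(back$tables), sort(names(ds$tables)))
  for (db in names(ds$tables))
    expect_equal(back$tables[[db]], ds$tables[[db]])
  for (lk in names(ds$link_tables))
    expect_equal(back$link_tables[[lk]], ds$link_tables[[lk]])
  expect_equal(sort(names(back$registry$databases)),
               sort(names(ds$registry$databases)))
})

test_that("unit fan-out makes every link table a partial function", {
  ds <- generate_fixture(55, n_dbs = 3, fanout = 1)
  for (lt in ds$link_tables)
    expect_true(all(vapply(lt, length, integer(1)) == 1L))
  # fan-out 0 allowed: some sources may have no entry at all
  ds0 <- generate_fixture(56, n_dbs = 2, fanout = c(0, 2))
  lens <- unlist(lapply(ds0$link_tables, function(lt) vapply(lt, length, integer(1))))
  expect_true(all(lens %in% c(2L)))  # zero-fanout sources are absent from the table
  expect_error(generate_fixture(1, fanout = -1), "invalid fan-out")
})

test_that("records_per_db = 0 yields a valid empty-table fixture", {
  ds <- generate_fixture(5, n_dbs = 2, records_per_db = 0)
  expect_true(all(vapply(ds$tables, length, integer(1)) == 0))
  be <- mock_backend(ds)
  db <- names(ds$tables)[1]
  fld <- ds$registry$databases[[db]]$fields$name[1]
  expect_equal(eu_search(be, db, sprintf("\"x\"[%s]", fld))$total_count, 0)
})
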