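# Depth-first tree-of-results traversal: laziness, iteration contract,
# backtracking order, request minimization, memory bounds.

test_that("opening a cursor issues exactly one root search and nothing else", {
  ds <- topology_dataset()
  chain <- topology_chain(ds)
  cur <- open_cursor(chain, mock_backend(ds))
  ops <- vapply(cursor_log(cur), function(e) e$op, character(1))
  expect_equal(ops, "search")
  # two cursors on one chain are independent, with independent logs
  cur2 <- open_cursor(chain, mock_backend(ds))
  suppressWarnings(cursor_next(cur2))
  expect_equal(length(cursor_log(cur)), 1)
  expect_gt(length(cursor_log(cur2)), 1)
})

test_that("an empty root search exhausts the cursor immediately", {
  ds <- topology_dataset()
  reg <- ds$registry
  q <- paste0("PREFIX e: <", NS, "> SELECT ?t WHERE {
    ?a a e:Pubmed . ?a e:pubmed_TITL \"no such title anywhere\" .
    ?a e:pubmed_TITL ?t . }")
  cur <- open_cursor(compile_chain(parse_sparql(q), reg, NS), mock_backend(ds))
  expect_false(cursor_has_next(cur))
  expect_equal(vapply(cursor_log(cur), function(e) e$op, character(1)), "search")
  expect_error(cursor_next(cur), "exhausted")
})

test_that("has_next is idempotent and issues no requests beyond the lookahead", {
  ds <- topology_dataset()
  cur <- open_cursor(topology_chain(ds), mock_backend(ds))
  expect_true(cursor_has_next(cur))
  n <- length(cursor_log(cur))
  for (k in 1:10) expect_true(cursor_has_next(cur))
  expect_equal(length(cursor_log(cur)), n)
})

test_that("rows stream in depth-first order with the documented backtracking", {
  L <- 5
  ds <- topology_dataset(R = 3, L = L)
  cur <- open_cursor(topology_chain(ds), mock_backend(ds))
  rows <- cursor_collect(cur)
  # root 1 -> single gene -> L leaves: first L rows share the root/gene
  # bindings and differ only in the leaf
  expect_equal(length(rows), L + 2)  # root 2 contributes 2, root 3 dies
  first <- rows[1:L]
  expect_equal(unique(vapply(first, function(r) r[["t"]], character(1))),
               "wilms tumor study R01")
  expect_equal(unique(vapply(first, function(r) r[["sym"]], character(1))), "WT1")
  expect_equal(vapply(first, function(r) r[["u"]], character(1)),
               ds$link_tables$gene_pubmed$G1)
  # row L+1 switches to root 2 after the traversal moves up twice
  expect_equal(rows[[L + 1]][["t"]], "wilms tumor study R02")
  tr <- cursor_transcript(cur)
  row_idx <- which(tr == "row")
  between <- tr[(row_idx[L] + 1):(row_idx[L + 1] - 1)]
  expect_equal(between, c("up", "up", "down", "down"))
})

test_that("a single-node chain yields the fetched root records in search order", {
  ds <- topology_dataset()
  q <- paste0("PREFIX e: <", NS, "> SELECT ?t ?u WHERE {
    ?a a e:Pubmed . ?a e:pubmed_TITL \"wilms tumor\" .
    ?a e:pubmed_TITL ?t . ?a e:uid ?u . }")
  chain <- compile_chain(parse_sparql(q), ds$registry, NS)
  rows <- cursor_collect(open_cursor(chain, mock_backend(ds)))
  sr <- eu_search(mock_backend(ds), "pubmed", "\"wilms tumor\"[TITL]")
  expect_equal(vapply(rows, function(r) r[["u"]], character(1)), sr$uids)
  expect_equal(vapply(rows, function(r) r[["t"]], character(1)),
               vapply(sr$uids, function(u) ds$tables$pubmed[[u]][["TITL"]],
                      character(1), USE.NAMES = FALSE))
})

test_that("the row multiset equals the brute-force nested-loop join", {
  for (seed in c(101, 202, 303)) {
    ds <- generate_fixture(seed, n_dbs = 3, records_per_db = c(5, 12),
                           fanout = c(0, 1, 2))
    q <- with_seed(seed, random_chain_query(ds, len = 3))
    chain <- compile_chain(parse_sparql(q), ds$registry, NS)
    rows <- suppressWarnings(cursor_collect(open_cursor(chain, mock_backend(ds))))
    expect_identical(row_multiset(rows), row_multiset(oracle_join(chain, ds)),
                     label = sprintf("seed %d", seed))
  }
})

test_that("duplicate paths to one leaf yield duplicate rows", {
  ds <- topology_dataset(R = 3, L = 5)
  # both genes point at leaf L001, and both roots reach their gene
  rows <- cursor_collect(open_cursor(topology_chain(ds), mock_backend(ds)))
  leaves <- vapply(rows, function(r) r[["u"]], character(1))
  expect_equal(sum(leaves == "L001"), 2)
})

test_that("missing field values yield unbound variables, not empty strings", {
  ds <- topology_dataset()
  ds$tables$pubmed$L001 <- ds$tables$pubmed$L001[setdiff(
    names(ds$tables$pubmed$L001), "TITL")]
  rows <- cursor_collect(open_cursor(topology_chain(ds), mock_backend(ds)))
  hit <- rows[vapply(rows, function(r) identical(unname(r["u"]), "L001"),
                     logical(1))]
  expect_gt(length(hit), 0)
  expect_false("leaf" %in% names(hit[[1]]))
})

test_that("stale links produce rows with unbound leaf fields and a warning", {
  reg <- bibdb_registry()
  ds <- mock_dataset(
    reg,
    tables = list(pubmed = list(P1 = c(TITL = "wilms tumor")),
                  gene = list()),
    link_tables = list(pubmed_gene = list(P1 = "GHOST")),
    validate = FALSE)
  q <- paste0("PREFIX e: <", NS, "> SELECT ?t ?s ?u WHERE {
    ?a a e:Pubmed . ?a e:pubmed_TITL \"wilms\" . ?a e:pubmed_TITL ?t .
    ?a e:pubmed_gene ?g . ?g a e:Gene . ?g e:gene_SYMB ?s . ?g e:uid ?u . }")
  chain <- compile_chain(parse_sparql(q), reg, NS)
  expect_warning(rows <- cursor_collect(open_cursor(chain, mock_backend(ds))),
                 "unknown uid")
  expect_length(rows, 1)
  expect_equal(unname(rows[[1]]["u"]), "GHOST")
  expect_false("s" %in% names(rows[[1]]))
})

test_that("the iterator count equals the oracle row count and has_next never flips back", {
  ds <- generate_fixture(404, n_dbs = 3, records_per_db = c(6, 10),
                         fanout = c(0, 1, 2))
  q <- with_seed(404, random_chain_query(ds, len = 3))
  chain <- compile_chain(parse_sparql(q), ds$registry, NS)
  truth <- length(oracle_join(chain, ds))
  cur <- open_cursor(chain, mock_backend(ds))
  n <- 0L
  while (cursor_has_next(cur)) { cursor_next(cur); n <- n + 1L }
  expect_equal(n, truth)
  expect_false(cursor_has_next(cur))
  expect_false(cursor_has_next(cur))
})

test_that("request audit matches the closed-form counts from the fixture", {
  ds <- topology_dataset(R = 4, L = 6)
  chain <- topology_chain(ds)
  cur <- open_cursor(chain, mock_backend(ds))
  cursor_collect(cur)
  audit <- request_plan_audit(cur)
  expect_equal(audit$n_search, 1)
  expect_equal(audit$n_link, oracle_expanded_nodes(chain, ds))
  expect_equal(audit$duplicate_requests, 0)
  # fetches: <= one batch per non-empty sibling set, and shared leaves
  # (cache hits) are fetched once but served on every path
  expect_lte(audit$n_fetch, 1 + 2 + 2)  # root batch + 2 gene sets + <=2 leaf sets
  expect_error(request_plan_audit(open_cursor(chain, mock_backend(ds))),
               "consumed to exhaustion")
})

test_that("a shared child is fetched once and served on every path (cache on)", {
  ds <- topology_dataset(R = 3, L = 5)
  cur <- open_cursor(topology_chain(ds), mock_backend(ds))
  cursor_collect(cur)
  keys <- vapply(cursor_log(cur), function(e) e$key, character(1))
  fetch_keys <- keys[startsWith(keys, "fetch|pubmed")]
  fetched_uids <- unlist(strsplit(vapply(strsplit(fetch_keys, "|", fixed = TRUE),
                                         `[`, character(1), 3), ",", fixed = TRUE))
  expect_equal(anyDuplicated(fetched_uids), 0)
})

test_that("consuming k rows expands no sibling branches beyond what k needs", {
  ds <- topology_dataset(R = 4, L = 6)
  cur <- open_cursor(topology_chain(ds), mock_backend(ds), limit = 3)
  rows <- cursor_collect(cur)
  expect_length(rows, 3)
  expect_false(cursor_has_next(cur))
  keys <- vapply(cursor_log(cur), function(e) e$key, character(1))
  # only root R01 was ever expanded: no link call mentions R02..R04
  expect_length(grep("link\\|pubmed\\|gene\\|pubmed_gene\\|R01", keys), 1)
  expect_length(grep("link\\|pubmed\\|gene\\|pubmed_gene\\|R0[234]", keys), 0)
})

test_that("retained state stays within the sum of per-level sibling sets", {
  ds <- topology_dataset(R = 5, L = 8)
  cur <- open_cursor(topology_chain(ds), mock_backend(ds))
  cursor_collect(cur)
  audit <- request_plan_audit(cur)
  # bound: matched roots + largest gene set + largest leaf set, never the product
  expect_lte(audit$peak_retained_nodes, 5 + 1 + 8)
})

test_that("root records are fetched in batches as traversal consumes them", {
  reg <- bibdb_registry()
  n <- 25
  pubmed <- stats::setNames(
    lapply(seq_len(n), function(i) c(TITL = sprintf("wilms %02d", i))),
    sprintf("P%03d", seq_len(n)))
  ds <- mock_dataset(reg, tables = list(pubmed = pubmed, gene = list()),
                     link_tables = list())
  q <- paste0("PREFIX e: <", NS, "> SELECT ?t WHERE {
    ?a a e:Pubmed . ?a e:pubmed_TITL \"wilms\" . ?a e:pubmed_TITL ?t . }")
  chain <- compile_chain(parse_sparql(q), reg, NS)
  cur <- open_cursor(chain, mock_backend(ds), fetch_batch = 10)
  cursor_collect(cur, 5)
  expect_equal(sum(vapply(cursor_log(cur), function(e) e$op, character(1)) == "fetch"), 1)
  cursor_collect(cur)
  expect_equal(sum(vapply(cursor_log(cur), function(e) e$op, character(1)) == "fetch"), 3)
})
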