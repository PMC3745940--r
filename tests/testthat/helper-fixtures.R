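# Hand-built fixtures used across tests. All built in code, no files.

NS <- "http://example.org/entrez#"

# Two-database registry mirroring the canonical literature/gene pair:
# TITL usable both ways, PDAT filter-only, LANG retrieve-only, plus a
# reciprocal link pair between the two databases.
bibdb_registry <- function(pubmed_efetch = TRUE, gene_efetch = FALSE) {
  pubmed <- new_entrez_db(
    "pubmed", "Citations and abstracts",
    fields = data.frame(
      name = c("TITL", "ABST", "PDAT", "LANG"),
      full_name = c("Title", "Abstract", "Publication date", "Language"),
      filterable = c(TRUE, TRUE, TRUE, FALSE),
      retrievable = c(TRUE, TRUE, FALSE, TRUE),
      stringsAsFactors = FALSE),
    links = data.frame(name = "pubmed_gene", target = "gene",
                       stringsAsFactors = FALSE),
    supports_efetch = pubmed_efetch)
  gene <- new_entrez_db(
    "gene", "Gene records",
    fields = data.frame(
      name = c("SYMB", "DESC"),
      full_name = c("Symbol", "Description"),
      filterable = c(TRUE, TRUE),
      retrievable = c(TRUE, TRUE),
      stringsAsFactors = FALSE),
    links = data.frame(name = "gene_pubmed", target = "pubmed",
                       stringsAsFactors = FALSE),
    supports_efetch = gene_efetch)
  structure(list(databases = list(pubmed = pubmed, gene = gene),
                 generated_at = "test"),
            class = "entrez_registry")
}

# Three-level worked-example topology: a root search matching R citation
# records; root 1 links to exactly one gene, which links back to L
# citation leaves; root 2 links to a second gene with 2 leaves (shared
# with root 1's leaf set, exercising the record cache); root 3 has no
# gene links at all (a dead branch the traversal must backtrack past).
topology_dataset <- function(R = 3, L = 5) {
  stopifnot(R >= 3, L >= 2)
  reg <- bibdb_registry()
  roots <- sprintf("R%02d", seq_len(R))
  leaves <- sprintf("L%03d", seq_len(L))
  pubmed <- list()
  for (u in roots)
    pubmed[[u]] <- c(TITL = sprintf("wilms tumor study %s", u),
                     ABST = "kidney cancer abstract", LANG = "eng")
  for (u in leaves)
    pubmed[[u]] <- c(TITL = sprintf("article about the gene %s", u),
                     LANG = "eng")
  genes <- list(G1 = c(SYMB = "WT1", DESC = "wilms tumor 1"),
                G2 = c(SYMB = "IGF2", DESC = "insulin-like growth factor"))
  link_pg <- list()
  link_pg[[roots[1]]] <- "G1"
  link_pg[[roots[2]]] <- "G2"
  # roots 3..R have no outgoing links
  link_gp <- list(G1 = leaves, G2 = leaves[1:2])
  mock_dataset(reg, tables = list(pubmed = pubmed, gene = genes),
               link_tables = list(pubmed_gene = link_pg,
                                  gene_pubmed = link_gp),
               manifest = list(R = R, L = L))
}

# The three-level chain query over the topology dataset: root citations
# filtered on TITL, gene symbol projected, leaf title + uid projected.
topology_query <- function() {
  paste0(
    "PREFIX e: <", NS, ">\n",
    "SELECT ?t ?sym ?leaf ?u WHERE {\n",
    "  ?a a e:Pubmed .\n",
    "  ?a e:pubmed_TITL \"wilms tumor\" .\n",
    "  ?a e:pubmed_TITL ?t .\n",
    "  ?a e:pubmed_gene ?g .\n",
    "  ?g a e:Gene .\n",
    "  ?g e:gene_SYMB ?sym .\n",
    "  ?g e:gene_pubmed ?b .\n",
    "  ?b a e:Pubmed .\n",
    "  ?b e:pubmed_TITL ?leaf .\n",
    "  ?b e:uid ?u .\n",
    "}\n")
}

topology_chain <- function(ds = topology_dataset()) {
  compile_chain(parse_sparql(topology_query()), ds$registry, NS)
}

# Random chain query over a generated fixture: a walk of `len` databases
# through declared links, a root filter drawn from the generator's word
# pool, one projection per level plus a uid variable on the leaf.
# Returns NULL when the fixture admits no such chain (shouldn't happen
# with >= 2 linked databases).
random_chain_query <- function(ds, len = 2) {
  reg <- ds$registry
  start <- sample(names(reg$databases), 1)
  path <- start
  edges <- character(0)
  while (length(path) < len) {
    db <- reg$databases[[path[length(path)]]]
    if (nrow(db$links) == 0) break
    i <- sample(nrow(db$links), 1)
    edges <- c(edges, db$links$name[i])
    path <- c(path, db$links$target[i])
  }
  root <- reg$databases[[path[1]]]
  filt_fields <- root$fields$name[root$fields$filterable]
  word <- sample(entrezsparql:::WORD_POOL, 1)
  lines <- c(sprintf("PREFIX e: <%s>", NS), "SELECT * WHERE {")
  vars <- sprintf("n%d", seq_along(path))
  for (i in seq_along(path)) {
    db <- reg$databases[[path[i]]]
    lines <- c(lines, sprintf("  ?%s a e:%s .", vars[i],
                              entrezsparql:::capitalize(path[i])))
    if (i == 1)
      lines <- c(lines, sprintf("  ?%s e:%s_%s \"%s\" .", vars[i], path[i],
                                sample(filt_fields, 1), word))
    retr <- db$fields$name[db$fields$retrievable]
    if (length(retr) > 0)
      lines <- c(lines, sprintf("  ?%s e:%s_%s ?v%d .", vars[i], path[i],
                                sample(retr, 1), i))
    if (i == length(path))
      lines <- c(lines, sprintf("  ?%s e:uid ?leafuid .", vars[i]))
    if (i < length(path))
      lines <- c(lines, sprintf("  ?%s e:%s ?%s .", vars[i], edges[i],
                                vars[i + 1]))
  }
  paste(c(lines, "}"), collapse = "\n")
}
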