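# entrezsparql

A virtual SPARQL endpoint over Entrez-style biomedical databases, for
bioinformaticians and data integrators who need RDF-compliant access to
repositories that only expose an E-utilities-style REST interface
(eSearch / eLink / eFetch / eSummary). The Entrez protocol cannot express
joins: every request targets a single database, and related records in
another database are reachable only by following named links one entry
at a time. `entrezsparql` closes that gap by

1. **generating an RDF schema from the repository's own metadata** — each
   database becomes an RDFS class, each field a string-valued datatype
   property, each directed inter-database link an object property — and
2. **resolving SPARQL SELECT queries against the live protocol** by
   compiling the basic graph pattern into a path-shaped *query chain*
   and simulating the join as a depth-first **tree of results**: the
   chain root is answered with one search, each node is expanded with
   one link call per entry, records are fetched in batches, and every
   root-to-leaf path is one solution, streamed back lazily in SPARQL
   Results format.

## The model

A query chain is an ordered list of database nodes
`db_1 → db_2 → … → db_k` connected by declared links, where `db_1`
carries at least one filter `"value"[FIELD]` and every node carries
projections of retrievable fields. Resolution maintains, per level, the
sibling UID list returned by the search (level 1) or by the parent's
link call (levels 2…k), and walks depth-first:

```
1. search(db_1, term)            -> level-1 UIDs           (1 request)
2. for the current node i at level l < k:
     link(db_l, db_l+1, edge_l, uid_i) -> level-(l+1) UIDs (1 request per node)
     fetch(db_l+1, sibling UIDs, fields)                   (1 batched request)
3. at level k every node closes one root-to-leaf path -> one result row
4. when a sibling list is exhausted, prune the branch and go up a level
```

Retained state is bounded by the *sum* of sibling-list sizes along the
current path (never their product), rows are produced one at a time
through a `has_next`/`next` cursor, and a request audit verifies that no
two identical requests are ever issued (repeated UID-list access goes
through the protocol's history server, and fetched records are cached
per cursor).

The metadata layer preserves a subtlety the RDF schema cannot express:
fields that are *filterable* (usable in search terms) and fields that
are *retrievable* (present in fetched records) are different sets —
e.g. a publication date field that can be searched but never returned,
or a language field that is returned but not searchable. The schema is
therefore accompanied by machine-readable *side documentation*, and the
query compiler rejects filters on retrieve-only fields and projections
of filter-only fields before anything reaches the backend.

Two backends implement the protocol contract: a live HTTP client
(rate-limited, paged, with a pluggable transport) and an offline mock
over seeded synthetic fixtures whose generator controls database count,
record counts, link fan-out (including 0 and many) and the asymmetric
field fraction.

## Worked example

Generate a seeded 3-database fixture, derive its schema, and run a
two-database chain query from the command line (the same calls are
available in R via `generate_fixture()`, `generate_schema()`,
`parse_sparql()` / `compile_chain()` / `open_cursor()`):

```sh
Rscript inst/cli/entrezsparql.R mockgen --seed 42 --n-dbs 3 --out demo/fix
Rscript inst/cli/entrezsparql.R schema --fixtures demo/fix --out demo/schema
```

`demo/schema/schema.ttl` begins:

```turtle
@prefix : <http://example.org/entrez#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .

:Pubmed a rdfs:Class .
:Pubmed rdfs:comment "Synthetic pubmed database" .
:Pubmed rdfs:label "pubmed" .
...
```

With `demo/query.rq` asking for citation records whose SYMB field
mentions "wilms", joined through the `pubmed_taxonomy` link:

```sparql
PREFIX e: <http://example.org/entrez#>
SELECT ?sym ?desc ?tax WHERE {
  ?a a e:Pubmed .
  ?a e:pubmed_SYMB "wilms" .
  ?a e:pubmed_SYMB ?sym .
  ?a e:pubmed_taxonomy ?t .
  ?t a e:Taxonomy .
  ?t e:taxonomy_DESC ?desc .
  ?t e:uid ?tax .
}
```

```sh
Rscript inst/cli/entrezsparql.R query --sparql demo/query.rq \
    --fixtures demo/fix --format tsv --audit
```

prints

```
?sym	?desc	?tax
wilms		00002
wilms	human tumor	00003
<request_audit> 5 request(s): 1 search, 2 link, 2 fetch; 2 node(s) expanded; 0 duplicate(s); peak 4 retained node(s); 2 row(s)
```

Two matching roots were found with one search; each was expanded with
one link call; the taxonomy records were fetched in one batch per
sibling set. The first row's `?desc` is unbound (empty TSV cell): that
record has no DESC value, and SPARQL solutions simply omit the binding.
`--explain` prints the compiled plan without executing:

```
<query_chain>
  pubmed -pubmed_taxonomy-> taxonomy
  [1] pubmed  filters: "wilms"[SYMB]  projects: SYMB->?sym
  [2] taxonomy  projects: DESC->?desc  uid->?tax
```

Formats `srx` (SPARQL Results XML, default) and `srj` (SPARQL Results
JSON) are the standard serializations; `--limit N` truncates traversal
without expanding unvisited branches.

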