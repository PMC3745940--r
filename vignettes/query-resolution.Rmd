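---
title: "Chain-join query resolution over Entrez-style databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain-join query resolution over Entrez-style databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrezsparql)
```

## The problem

Entrez-style repositories expose dozens of interlinked biomedical
databases (citations, genes, proteins, taxa, …) through a URL-based
protocol in which every request addresses exactly one database: a
*search* returns the UIDs of one database's entries matching a term, a
*link* returns the UIDs in a second database related to one entry
through a named directed relation, and a *fetch*/*summary* returns
entry records. Joins are not expressible. This package provides an
RDF/SPARQL view of such a repository: it derives an RDF schema from the
repository's own machine-readable metadata, and resolves SPARQL SELECT
queries by compiling them into a chain of per-database accesses whose
results are composed client-side.

## Metadata model

The registry is built from three kinds of evidence:

* the **master list** of database names;
* one **per-database description** declaring the fields usable in
  search terms and the named links to other databases;
* **retrievable-field evidence**: for databases supporting the full
  fetch operation, a DTD whose `#PCDATA` elements name the fields a
  fetched record can carry; for the others, a sample summary result
  document, from which we take the tag names of leaf elements under
  each result item (the `Id` element carries the UID and is not a
  field).

The two field sets differ: a field may be *filterable* but not
*retrievable* (a date field usable in a search term but never present
in results) or *retrievable* only (a language field returned but not
searchable). Fields named by evidence but absent from the database
description are added as retrieve-only fields, with their code as their
label — no other label source exists. A field that ends up neither
filterable nor retrievable is dropped with a warning, as are links
whose target database is not in the registry (closure) and databases
whose description is missing. Reading evidence from text makes the
whole stage automatic and offline-testable; the sample-document rule is
a deterministic automation of what is otherwise a manual inspection
step, and it is deliberately conservative: it can only see fields the
sample record actually carries.

Database names are stored lowercase and field codes uppercase,
mirroring Entrez conventions and making matching deterministic. The
registry is cached as a single JSON document (`write_registry()` /
`read_registry()`), chosen over ad hoc per-database files so the cache
round-trips exactly.

## Schema mapping

`generate_schema()` maps the registry onto RDFS: one class per database
(`:Pubmed`), one string-ranged datatype property per field
(`:pubmed_TITL`, domain = the class), one object property per link
(`:pubmed_gene`, domain/range = the two classes). RDFS suffices — no
OWL construct is needed to express classes, property domains and
ranges — and Turtle is the canonical serialization, with triples sorted
(subject, `rdf:type` first, predicate, object) so identical registries
serialize byte-identically; RDF/XML is available behind a flag.
Database descriptions become `rdfs:comment` annotations. When two
databases declare links with the same name, the later property IRI is
qualified with its source database (`:pubmed.pubmed_gene`) under a
logged warning, keeping IRIs unique without discarding either link.

RDF cannot express the filterable/retrievable asymmetry, so the schema
is accompanied by **side documentation** (`generate_side_doc()`),
emitted three ways: human-readable text, JSON, and — so that query
validation needs no side channel — `:filterable` / `:retrievable`
annotation triples on every field property. A dedicated `:uid` property
lets queries bind an entry's UID on any node.

## The SPARQL subset and chain compilation

`parse_sparql()` accepts exactly the fragment the executor can resolve:
`PREFIX`, `SELECT` (explicit variables or `*`), and a basic graph
pattern of `rdf:type` triples, field-property triples and
link-property triples, with `;`/`,` abbreviations. `CONSTRUCT`, `ASK`,
`DESCRIBE`, `FILTER`, `OPTIONAL`, `UNION`, `GRAPH`, aggregates and
`LIMIT`/`OFFSET` are rejected with named errors — row limits are
honored client-side by the cursor instead, which keeps truncation lazy.
Which constructs the original protocol-facing endpoint admitted is not
documentable from the outside; this subset is a declared dialect.

`compile_chain()` validates the pattern against the registry and builds
the plan. The instance-variable graph must be a simple directed path:
trees, cycles and disconnected patterns raise `unsupported join shape`.
A literal-object field triple becomes a filter (checked filterable), a
variable-object one a projection (checked retrievable); violations
raise `asymmetry violation` naming the field, which is the machine
check corresponding to the side documentation. Orientation rules:

* if exactly one endpoint of the path carries filters, it is the root;
* if both do, the endpoint whose triples appear first in the query text
  wins (a deterministic, inspectable tie-break);
* if neither does, the query is rejected (`unbounded root search`) —
  an unfiltered root would enumerate an entire database, and whether
  the original system permitted that is unknown, so we forbid it;
* every link along the path must run root→leaf in its declared
  direction, since the protocol's link operation is directed.

A filter on a field that is both filterable and retrievable does not
additionally project it (SQL `WHERE` semantics). The root's filters are
rendered by `term_expression()` as `"value"[FIELD]` conjuncts joined by
`AND` — deterministic and round-trippable through the mock backend's
term grammar.

## Execution: the tree of results

`open_cursor()` issues exactly one history-enabled search for the root
term and queues the UIDs; nothing else happens until rows are demanded.
`cursor_next()` advances a depth-first traversal in which level *l*
holds entries of the *l*-th chain database: expanding a node costs one
link call, and each newly entered level's sibling set is fetched in one
batched request restricted to that level's projection codes. Each
root-to-leaf path is one solution; when a sibling list is exhausted the
branch is pruned and the traversal moves up one level. The transcript
of `row`/`down`/`up` events is exposed (`cursor_transcript()`) because
the backtracking order is part of the observable contract: all rows
under the first root stream before any second-root binding appears.

Design choices worth stating:

* **Lazy fetching.** A strictly eager reading of the algorithm would
  fetch the whole first level right after the root search. Because
  results must stream progressively (some chains produce enormous
  result sets) and requests must be minimized, root records are instead
  fetched in batches of `fetch_batch` (default 200 — large enough that
  a root level of typical size costs one request, small enough that a
  `--limit 5` query never pays for thousands of records) as traversal
  consumes them. This changes request *timing*, never results.
* **Duplicate paths are duplicate rows** (SQL join semantics): one
  result per leaf means per-path multiplicity, and collapsing would
  silently change counts.
* **Missing field values yield unbound variables**, omitted from the
  row's bindings — standard SPARQL semantics — never empty strings.
* **Per-cursor record cache** keyed by (database, UID, projection set):
  a child reachable from two parents is fetched once and served on
  every path. Combined with the history server this makes "no two
  identical requests per cursor" an invariant the audit
  (`request_plan_audit()`) verifies rather than hopes for.
* **Order is authoritative**: root rows follow search order, children
  follow link-result order, nothing is re-sorted. Determinism for free.
* **Memory contract**: retained state is the sum of sibling-list sizes
  along the current path — never the cross-level product — because
  exhausted branches are pruned. The cursor tracks its peak retained
  node count so the bound is testable.
* A **stale link** (a linked UID whose record cannot be fetched)
  produces a row with unbound leaf fields and a warning, rather than
  aborting the traversal; the UID itself is still bindable.

## Backends

The executor talks to an abstract operation contract with two
implementations.

The **mock backend** serves a `mock_dataset` entirely in memory. Search
semantics are case-insensitive substring match per term conjunct — the
real repository's term matching (stemming, phrase handling) is
undocumented, and substring is deterministic and sufficient to exercise
every control path. Its history server is an in-memory map issuing
sequential web-environment keys. Fetch honors the capability split:
databases without full-fetch support serve a configured summary subset
(defaulting to the retrievable fields).

The **live backend** builds protocol URLs (`esearch`/`elink`/
`esummary`/`efetch`/`einfo` with `db`, `term`, `id`, `dbfrom`,
`linkname`, `usehistory`, `WebEnv`, `query_key`, `retstart`, `retmax`),
parses the XML dialects, pages long UID lists, surfaces server `ERROR`
elements verbatim, and rate-limits itself to 3 requests/second with
exponential backoff — the publicly documented etiquette default, since
the historical penalty policy is not quantifiable. The transport is a
plain `url -> text` function, so a replay transport serving recorded
response documents exercises the identical URL-construction and parsing
code offline; the test suite asserts the executor produces identical
rows on the mock backend and on a replay-live backend.

## The synthetic generator as study conditions

`generate_fixture(seed, ...)` builds datasets with the structural
features the algorithm exploits: several databases; named directed
links with consecutive databases linked in *both* directions, so a
reciprocal link pair always exists; per-database field sets of 4–8
codes of which a fraction (default 0.25) is made filter-only or
retrieve-only; and per-record link fan-out drawn from a configurable
set — 0 (dead branches forcing backtracking), 1 (chains), and larger
values (shared children and multiplicities). Field values are 1–3 words
from a 12-word pool, so single-word search terms have controllable,
middling selectivity; each field is present with probability 0.8 so
unbound bindings actually occur. Defaults (3 databases, 8–15 records,
fan-outs {0,1,2}) are deliberately small: the point is structural
coverage, not volume. The manifest records ground truth (counts,
per-link fan-outs, field classification) so tests read it instead of
re-deriving it.

What the generator does *not* emulate: realistic term-matching
semantics, result-set sizes in the millions, server latency and
failures, schema drift over time, and the real repositories' link
topology. Passing tests therefore demonstrate the correctness of the
resolution algorithm and its contracts, not performance against the
live service.

## Verification

The oracle for execution is a brute-force nested-loop join written
directly over the fixture tables, sharing no code with the cursor. The
test suite compares full row multisets over 100 seeded fixtures
(2–4 databases, up to 30 records each, fan-outs {0,1,2,5}, asymmetric
fields present), and separately checks the worked three-level topology
(R roots; root 1 → one mid-level node → L leaves) for streaming order
and the double backtrack between the last first-root row and the first
second-root row. Problem sizes keep the whole suite under a minute;
`scripts/acceptance.R` recomputes the same properties end to end.
Schema serializations are additionally reloaded with an independent
conformant RDF parser and compared by triple count.

## Known limitations

* Only path-shaped joins; no trees, cycles, optional parts or unions.
* One relation per adjacent database pair per query; when a pair has
  several named links, the query selects one by name.
* The SPARQL dialect, namespace scheme and CLI packaging are this
  package's own conventions, not a reconstruction of any historical
  API surface.
* Live-service behavior (matching semantics, penalties, metadata
  quirks requiring human intervention) is out of reach of the offline
  test bed; the live client is exercised only through recorded
  responses.
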