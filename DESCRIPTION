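Package: entrezsparql
Title: SPARQL Query Federation over Entrez-Style Biomedical Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual SPARQL endpoint over Entrez-style biomedical
    databases. Parses E-utilities metadata (EInfo master and per-database
    documents, DTDs, sample summary documents) into a registry of
    databases, fields and links; generates an RDFS schema plus side
    documentation of the filterable/retrievable field asymmetry; compiles
    SPARQL SELECT queries into path-shaped chain plans; resolves them
    against an E-utilities backend (live HTTP or an offline seeded mock)
    by building a depth-first tree of results with backtracking, lazy
    batched fetching and request minimization; and streams solutions in
    SPARQL Results XML/JSON/TSV. Includes a seeded synthetic fixture
    generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    optparse,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
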