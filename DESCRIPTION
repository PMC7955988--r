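Package: medlinedb
Title: Build and Maintain a Relational Database of PubMed/MEDLINE Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses PubMed/MEDLINE XML files (baseline and daily update
    releases) into a set of relational tables organized by data type and
    linked by PubMed Identifier (PMID). Supports incremental maintenance of
    the database: staging update files into temporary tables, resolving the
    most recent version of each PMID across files, tombstone handling of
    deletion notices, and wholesale refresh of an open citation edge-list
    table. Includes a synthetic fixture generator that emits schema-valid
    PubMed-style XML together with an independent replay oracle for the
    expected database state, plus example bibliometric queries (authors per
    publication by year, ORCID uptake by month).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    xml2,
    DBI,
    RSQLite,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Collate: 
    'build_pipeline.R'
    'citation_loader.R'
    'fixture_gen.R'
    'medlinedb-package.R'
    'query_examples.R'
    'registry.R'
    'schema_store.R'
    'update_pipeline.R'
    'xml_ingest.R'
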