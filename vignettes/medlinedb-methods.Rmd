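---
title: "From PubMed XML to a relational database: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From PubMed XML to a relational database: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

PubMed/MEDLINE is distributed as deeply nested XML: an annual *baseline*
dump of the whole corpus released each December, followed by daily
*post-baseline* files that carry new records, revised records, and deletion
notices. The XML form is convenient for archival but hostile to analysis:
answering even a simple bibliometric question (how many authors per paper
per year?) requires joining data that lives at different depths of
different documents. `medlinedb` converts these files into a set of flat
relational tables — one table per data type, every row keyed by the PubMed
Identifier (PMID) — and keeps the database current as update files arrive.

Three complications make this more than a bulk XML-to-CSV conversion, and
they drive most of the design below:

1. **Versions.** A PMID is not immutable: some journals (F1000Research is
   the well-known case) publish successive article versions under one PMID,
   and the XML's `PMID` element carries a `Version` attribute. The database
   must hold exactly one version per PMID — the latest.
2. **Updates.** A daily file may revise a PMID that the baseline (or an
   earlier daily file) already delivered. The same PMID can be touched by
   several files; the merge rule is *most recent wins*, ordered first by
   version number and then by file sequence.
3. **Deletions.** A `DeleteCitation` element lists PMIDs removed from
   PubMed. All of a deleted PMID's rows must disappear from every table,
   and nothing is appended in their place (tombstone semantics).

## The relational schema

`pmdb_registry()` defines the tables. Article data is *versioned*: every
such table begins with `(pmid, version)`. The registry covers publication
metadata (`pub`, `journal`, `pub_type`, `article_id`), people (`author`,
`author_identifier`, `investigator`), content (`abstract`, `keyword`,
`mesh_term`, `chemical`, `data_bank`), funding (`grant_item`),
cross-references (`comment_correction`) and the per-article status history
(`pub_history`). Two tables are unversioned: `xml_processed`, the ledger of
already-ingested files, and `citation`, the open citation edge list, which
is replaced wholesale rather than maintained incrementally.

The registry is data-driven: most tables are described by XPath rules
(node path plus column-to-path mapping), so columns can be added without
touching parser code. Three extractors are hand-written because they
enforce structural constraints the rule language cannot express: authors
(exactly one of `last_name`/`collective_name`; positions `1..k` contiguous
after dropping malformed entries), author identifiers (must reference an
emitted author position; ORCIDs normalized to the canonical 19-character
dashed form, check character upper-cased, URL prefixes stripped), and the
history (dates with a missing day are stored as the first of the month
with a `date_precision` flag of `"month"`, keeping the column sortable
without inventing day-level accuracy; structurally invalid dates are
stored null with a warning).

One open representational choice: abstracts are stored one row per
`AbstractText` paragraph with its label, not concatenated. This is
lossless, closer to the source structure, and lets queries target labelled
sections; consumers who want one string can aggregate.

## Streaming ingest

Baseline files contain tens of thousands of articles each; loading a whole
file's DOM before extracting rows would make peak memory proportional to
file size. `parse_file()` instead splits the input stream into one
top-level element at a time — relying on the convention, true of NLM
releases and of this package's fixture generator, that each top-level
open/close tag starts its own line — and DOM-parses each `PubmedArticle`
individually. Peak memory is then bounded by the largest single article
plus the accumulated output rows, not by the file. Accumulated per-article
row fragments are consolidated every 1024 articles so the number of live
small objects stays bounded on long streams.

The package's test suite checks this contract directly: a generated
50,000-article file must stream-parse within a fixed 512 MiB peak-RSS
ceiling that a whole-document parse of the same file exceeds. The 512 MiB
constant was chosen to sit between the two regimes with roughly a factor
of two of headroom on each side at that problem size.

Within one file, if a PMID appears twice, the last occurrence in document
order wins — the same "most recent" principle the update merge applies
across files.

## Building and updating

**Build.** Files are parsed concurrently (forked workers); appends are
serialized in file-sequence order, so the result is independent of worker
count. Each file's append and its ledger entry share one transaction,
which makes an interrupted build resumable: already-logged files are
skipped on re-run. After all files load, every versioned table is reduced
to the latest version of each PMID.

That reduction deserves a note. `keep_latest()` by default removes rows
whose version is below the table's own per-PMID maximum. But a newer
article version may legitimately *drop* a data type — version 2 of an
article can have no abstract where version 1 had one — and then the
abstract table alone cannot know that version 1 is stale. The latest
version is a property of the article, not of one table, so the build
passes `version_table = "pub"`: the `pub` table, populated by every
article, is the authority for each PMID's maximal version.

If two baseline files carry the same `(pmid, version)` — as happens when a
record is re-issued without a version bump — the later file in sequence
order wins. Main tables carry no source-file column, so this is
implemented by deleting matching `(pmid, version)` pairs just before each
file's append; the end state equals what a tagged-and-resolved load would
produce.

**Update.** Post-baseline files are first parsed into staging twins of
every versioned table (`tmp_` prefix, plus a `source_file` column;
deletion notices go to `tmp_delete_citation`). Staging twins are ordinary
tables rather than connection-scoped temporaries so that a crashed run can
be inspected; they are dropped after a successful apply. `resolve_plan()`
then chooses, per PMID, the maximal version, ties broken by the latest
file, and routes a PMID to the deletion set when its last event in file
order is a deletion notice. A deletion and an update in the same file
resolve to the deletion, because `DeleteCitation` closes the file and so
is the later event in document order; an update in a strictly later file
re-inserts a previously deleted PMID. `apply_plan()` executes the plan
set-based in one transaction: delete all rows of every touched PMID from
every versioned table, then insert exactly the winning
`(pmid, version, source_file)` rows from staging. Replacement is always
whole-PMID; the pipeline never diffs fields.

Deletions do not touch the `citation` table: that table is refreshed
wholesale from its upstream, so filtering it against deletions would only
create a transient inconsistency with the next refresh.

**Citations.** `load_citations()` reads the two-column edge list in
chunks, skipping (and counting) malformed lines, into a shadow table that
replaces the live `citation` table only on success — an overwrite without
a read-unavailable window, and a failed load leaves the previous table and
its version tag intact. Whether a refresh is needed at all is decided by
label inequality (`needs_refresh()`): the upstream names its releases, and
ordering those names is outside this package's contract.

## The fixture generator and its oracle

Everything above is tested against synthetic data, because the real corpus
is tens of gigabytes and its ground truth is unknowable. An
`event_script()` is a seeded, validated list of `create`/`update`/`delete`
events assigned to numbered files; `generate_fixture_files()` serializes
it to gzip-compressed PubMed-style XML, and `replay_oracle()` computes the
expected final database state by replaying events in order — deliberately
sharing no code with the parser or the pipelines, so agreement between the
two paths is evidence about the whole system.

Article content is derived deterministically from the script seed and the
event's position, which has two useful consequences: the same script
always produces byte-identical files, and two updates of the same PMID at
the same version carry *different* content, so the latest-file tie-break
is observable in the data rather than vacuous.

What the generator emulates: nested author lists with collective names
(~12% of entries), ORCIDs with valid ISO 7064 check characters serialized
in the mixed raw forms seen in the wild (bare, dashed, URL-prefixed,
case-varying), history sections with entry dates spanning 2010–2020 and
occasional month-precision dates, MeSH headings, keywords, labelled
abstract paragraphs, grants, chemicals, data-bank accessions,
investigators and comment/correction links; PMIDs reappearing across files
with bumped or tied versions; deletion notices only in update files, with
occasional reappearance afterwards. Default event mix (2 baseline + 3
update files, ~10% multi-version PMIDs, ~10% deletions) follows the
observation that the vast majority of PMIDs have a single version.

What it does not emulate — and hence what passing tests cannot show:
real-world character-encoding pathologies beyond standard entity escaping,
the long-tail element diversity of the full MEDLINE DTD (only the
registry's data types are produced), historically truncated author lists
(PMIDs entered 1984–1995 recorded at most 10 authors, 1996–1999 at most
25 — these truncations bias the *mean* authors-per-publication in those
years, though not the median or interquartile range), and corpus-scale
row counts. Problem sizes in the test suite are desk-scale stand-ins: the
headline property runs 100 random scripts of 10–120 PMIDs over 5 files
each, and the streaming bound uses a single 50,000-article file.

## Example queries

Two demonstration analyses ship as functions. `authors_per_pub_by_year()`
joins `pub_history` and `author` on `pmid` and reports per-year
publication counts with mean, median and quartiles of authors per
publication. `orcid_fraction_by_month()` joins `pub_history`, `author` and
`author_identifier` on `pmid` and `author_pos` and reports the monthly
percentage of author names carrying an ORCID; author names with no
identifier rows count in the denominator only.

Both need a rule for assigning a publication to a point in time. The
history section offers several statuses (`received`, `accepted`,
`pubmed`, `entrez`, `medline`); this package defaults to `entrez` — the
database-entry event, which is present for essentially every record and
reflects when the record became visible — and exposes the choice as a
`pub_status` argument. Where a status occurs with several dates for one
PMID, the earliest is used. Months or years with no assignable
publications are omitted rather than zero-filled, so consumers can
distinguish "no data" from "zero of something".

## Numerical and operational choices

- Dates are stored as ISO-8601 text, booleans as 0/1 integers: portable
  across DBI backends and correctly ordered by string comparison.
- Timestamps in the ledger are UTC.
- The transaction unit is one source file (append + ledger entry),
  implemented with savepoints so the unit composes inside larger
  transactions (the dry-run mode wraps a whole update in an outer
  transaction and rolls it back).
- File ordering is lexicographic on the zero-padded numeric segments of
  the standard `pubmed<yy>n<seq>.xml.gz` pattern; unrecognized names fall
  back to whole-name comparison, which keeps the order total and
  deterministic.
- The embedded SQLite backend is the tested reference; every function
  accepts an arbitrary DBI connection and the SQL is kept to the portable
  core (plus savepoints), but no server driver is bundled.
- `keep_latest` is a set-based anti-join executed in the database, not a
  per-row cursor loop, so it scales to tables with millions of rows.

## Known limitations

- The line-oriented streaming splitter assumes top-level tags start their
  own lines; a single-line article-set document would have to be parsed
  via the DOM path instead.
- Only SQLite is exercised in tests; other DBI backends should work at the
  SQL level used here but are unverified.
- The registry intentionally covers the commonly analysed data types, not
  the complete MEDLINE element inventory; extending it is a data change
  (new `table_spec` with XPath rules), not a code change, unless the new
  type carries structural constraints.
- No network access: obtaining baseline/update files and citation releases
  is the caller's responsibility.
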