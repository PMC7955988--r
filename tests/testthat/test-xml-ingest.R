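test_that("an empty article set parses to empty tables and no deletions", {
  path <- write_article_set(character(0L))
  batch <- parse_file(path)
  expect_s3_class(batch, "record_batch")
  expect_setequal(names(batch$rows_by_table), versioned_tables())
  expect_true(all(vapply(batch$rows_by_table, nrow, integer(1L)) == 0L))
  expect_identical(batch$deleted_pmids, integer(0L))
  expect_identical(parse_deletions(path), integer(0L))
})

test_that("author rows match an independent element count over the fixture", {
  sc <- event_script(
    data.frame(file_index = 1L, type = "create", pmid = c(101L, 102L),
               version = 1L, n_authors = 3L, n_orcid = 1L),
    n_baseline_files = 1L, seed = 42L)
  dir <- withr::local_tempdir()
  path <- generate_fixture_files(sc, dir)[[1L]]

  # independent oracle: whole-document path walk with xml2, no package code
  doc <- xml2::read_xml(path)
  n_authors_oracle <- length(xml2::xml_find_all(
    doc, "//PubmedArticle//AuthorList/Author"))

  batch <- parse_file(path)
  au <- batch$rows_by_table$author
  expect_identical(nrow(au), n_authors_oracle)
  expect_identical(nrow(au), 6L)
  for (pm in c(101L, 102L)) {
    expect_identical(sort(au[au$pmid == pm, ]$author_pos), 1:3)
  }
})

test_that("a PMID without a Version attribute defaults to version 1", {
  path <- write_article_set(article_xml(555L, version = NULL, authors = "Roe"))
  batch <- parse_file(path)
  expect_identical(batch$rows_by_table$pub$version, 1L)
  expect_identical(batch$rows_by_table$author$version, 1L)
})

test_that("extract_article_tables returns only the data types present", {
  path <- write_article_set(article_xml(7L, version = 2L))
  doc <- xml2::read_xml(path)
  node <- xml2::xml_find_first(doc, "//PubmedArticle")
  tabs <- extract_article_tables(node)
  expect_false("author" %in% names(tabs))
  expect_true("pub" %in% names(tabs))
  expect_identical(tabs$pub$pmid, 7L)
  expect_identical(tabs$pub$version, 2L)
})

test_that("one author with one ORCID yields matched author and identifier rows", {
  path <- write_article_set(article_xml(
    9L, version = 1L, authors = "Dane",
    orcid = "https://orcid.org/0000-0002-1825-0097"))
  doc <- xml2::read_xml(path)
  tabs <- extract_article_tables(xml2::xml_find_first(doc, "//PubmedArticle"))
  expect_identical(nrow(tabs$author), 1L)
  expect_identical(nrow(tabs$author_identifier), 1L)
  expect_identical(tabs$author_identifier$author_pos, tabs$author$author_pos)
  expect_identical(tabs$author_identifier$identifier, "0000-0002-1825-0097")
})

test_that("a collective author has collective_name set and last_name null", {
  path <- write_article_set(article_xml(11L, version = 1L,
                                        collective = "Study Group"))
  batch <- parse_file(path)
  au <- batch$rows_by_table$author
  expect_identical(au$collective_name, "Study Group")
  expect_true(is.na(au$last_name))
})

test_that("exactly one of last_name/collective_name must be present", {
  bad <- c("<PubmedArticle>", "  <MedlineCitation>",
           "    <PMID>13</PMID>", "    <Article>",
           "      <AuthorList>",
           "        <Author>", "          <ForeName>No Last</ForeName>",
           "        </Author>",
           "        <Author>", "          <LastName>Kept</LastName>",
           "        </Author>",
           "      </AuthorList>",
           "    </Article>", "  </MedlineCitation>", "</PubmedArticle>")
  path <- write_article_set(bad)
  expect_warning(batch <- parse_file(path), "LastName/CollectiveName")
  au <- batch$rows_by_table$author
  expect_identical(nrow(au), 1L)
  expect_identical(au$last_name, "Kept")
  expect_identical(au$author_pos, 1L)
})

test_that("ORCID normalization canonicalizes URL, case and dashing", {
  raw <- c("https://orcid.org/0000-0002-1825-0097",
           "http://orcid.org/0000-0001-5109-353x",
           "0000000218250097",
           "0000-0002-1825-0097",
           "not an orcid at all")
  out <- normalize_orcid(raw)
  expect_identical(out[1:4], c("0000-0002-1825-0097", "0000-0001-5109-353X",
                               "0000-0002-1825-0097", "0000-0002-1825-0097"))
  expect_identical(out[5], "not an orcid at all")
})

test_that("history dates handle missing days and reject invalid components", {
  extra <- c("  <PubmedData>", "    <History>",
             "      <PubMedPubDate PubStatus=\"entrez\">",
             "        <Year>2015</Year><Month>Mar</Month><Day>14</Day>",
             "      </PubMedPubDate>",
             "      <PubMedPubDate PubStatus=\"received\">",
             "        <Year>2015</Year><Month>2</Month>",
             "      </PubMedPubDate>",
             "      <PubMedPubDate PubStatus=\"accepted\">",
             "        <Year>2015</Year><Month>0</Month><Day>9</Day>",
             "      </PubMedPubDate>",
             "    </History>", "  </PubmedData>")
  body <- c("<PubmedArticle>", "  <MedlineCitation>", "    <PMID>21</PMID>",
            "    <Article><ArticleTitle>t</ArticleTitle></Article>",
            "  </MedlineCitation>", extra, "</PubmedArticle>")
  path <- write_article_set(body)
  expect_warning(batch <- parse_file(path), "invalid history date")
  h <- batch$rows_by_table$pub_history
  expect_identical(h[h$pub_status == "entrez", ]$event_date, "2015-03-14")
  expect_identical(h[h$pub_status == "entrez", ]$date_precision, "day")
  expect_identical(h[h$pub_status == "received", ]$event_date, "2015-02-01")
  expect_identical(h[h$pub_status == "received", ]$date_precision, "month")
  expect_true(is.na(h[h$pub_status == "accepted", ]$event_date))
})

test_that("deletion notices are returned in document order, duplicates kept", {
  body <- c(article_xml(30L, version = 1L),
            "<DeleteCitation>",
            "  <PMID Version=\"1\">11</PMID>",
            "  <PMID Version=\"1\">12</PMID>",
            "  <PMID Version=\"1\">11</PMID>",
            "</DeleteCitation>")
  path <- write_article_set(body)
  expect_identical(parse_deletions(path), c(11L, 12L, 11L))
  batch <- parse_file(path)
  expect_identical(batch$deleted_pmids, c(11L, 12L, 11L))
})

test_that("malformed XML errors name the file; missing PMID is record-level", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<?xml version=\"1.0\"?>", "<PubmedArticleSet>",
               "<PubmedArticle>", "  <MedlineCitation>",
               "  <broken", "</PubmedArticle>", "</PubmedArticleSet>"), path)
  expect_error(parse_file(path, file_name = "bad01.xml"), "bad01\\.xml")

  nopmid <- c("<PubmedArticle>", "  <MedlineCitation>",
              "    <Article><ArticleTitle>t</ArticleTitle></Article>",
              "  </MedlineCitation>", "</PubmedArticle>")
  path2 <- write_article_set(nopmid)
  expect_error(parse_file(path2), "missing its PMID")
})

test_that("unknown top-level elements are skipped with a warning", {
  body <- c("<BookDocument>", "  <PMID>99</PMID>", "</BookDocument>",
            article_xml(40L, version = 1L, authors = "Kim"))
  path <- write_article_set(body)
  expect_warning(batch <- parse_file(path), "BookDocument")
  expect_identical(batch$rows_by_table$pub$pmid, 40L)
})

test_that("the last occurrence of a duplicated PMID within a file wins", {
  body <- c(article_xml(50L, version = 1L, authors = c("First", "Author")),
            article_xml(50L, version = 1L, authors = "Second"))
  path <- write_article_set(body)
  batch <- parse_file(path)
  au <- batch$rows_by_table$author
  expect_identical(nrow(au), 1L)
  expect_identical(au$last_name, "Second")
})

test_that("parsing the same bytes twice yields identical batches", {
  sc <- random_event_script(5L, n_pmids = 15L)
  dir <- withr::local_tempdir()
  path <- generate_fixture_files(sc, dir)[[1L]]
  b1 <- parse_file(path)
  b2 <- parse_file(path)
  expect_identical(b1$rows_by_table, b2$rows_by_table)
  expect_identical(b1$deleted_pmids, b2$deleted_pmids)
})

test_that("gzip input is detected by magic bytes, not file extension", {
  sc <- event_script(data.frame(file_index = 1L, type = "create", pmid = 60L,
                                version = 1L, n_authors = 2L),
                     n_baseline_files = 1L, seed = 3L)
  dir <- withr::local_tempdir()
  gz <- generate_fixture_files(sc, dir)[[1L]]
  renamed <- file.path(dir, "no_extension_hint")
  file.copy(gz, renamed)
  batch <- parse_file(renamed)
  expect_identical(batch$rows_by_table$pub$pmid, 60L)
  expect_identical(nrow(batch$rows_by_table$author), 2L)
})

test_that("referential closure holds between author and identifier rows", {
  for (s in 1:5) {
    sc <- random_event_script(s, n_pmids = 12L, n_update_files = 0L,
                              n_baseline_files = 1L)
    dir <- withr::local_tempdir()
    path <- generate_fixture_files(sc, dir)[[1L]]
    batch <- parse_file(path)
    ids <- batch$rows_by_table$author_identifier
    au <- batch$rows_by_table$author
    if (nrow(ids) > 0L) {
      key <- paste(ids$pmid, ids$version, ids$author_pos)
      aukey <- paste(au$pmid, au$version, au$author_pos)
      expect_true(all(key %in% aukey))
    }
  }
})
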