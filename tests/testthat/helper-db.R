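# shared helpers: in-memory databases, fixture pipelines, state comparison

new_con <- function(path = ":memory:", init = TRUE) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  if (init) init_tables(con)
  con
}

# generate a script's files, build the baseline and apply the updates;
# returns the open connection (caller disconnects)
run_full_pipeline <- function(script, dir = withr::local_tempdir(),
                              con = new_con(), workers = 1L,
                              update_batches = 1L) {
  paths <- generate_fixture_files(script, dir)
  nm <- fixture_file_names(script)
  build_baseline(file.path(dir, nm$baseline), con, workers = workers)
  upd <- file.path(dir, nm$update)
  if (length(upd) > 0L) {
    splits <- split(upd, ceiling(seq_along(upd) / ceiling(length(upd) / update_batches)))
    for (batch in splits) update_database(batch, con, workers = workers)
  }
  con
}

expect_state_equal <- function(state_a, state_b, label = "state") {
  for (tb in union(names(state_a), names(state_b))) {
    expect_equal(as.data.frame(state_a[[tb]]), as.data.frame(state_b[[tb]]),
                 ignore_attr = TRUE,
                 label = paste0(label, " table '", tb, "' (left)"),
                 expected.label = paste0(label, " table '", tb, "' (right)"))
  }
}

# minimal hand-written article XML, for parser edge cases
article_xml <- function(pmid, version = NULL, authors = character(0L),
                        collective = NULL, orcid = NULL, extra = character(0L)) {
  pm <- if (is.null(version)) {
    sprintf("    <PMID>%d</PMID>", pmid)
  } else {
    sprintf("    <PMID Version=\"%d\">%d</PMID>", version, pmid)
  }
  au <- character(0L)
  if (length(authors) > 0L || !is.null(collective)) {
    au <- c("      <AuthorList>")
    for (i in seq_along(authors)) {
      au <- c(au, "        <Author>",
              sprintf("          <LastName>%s</LastName>", authors[[i]]),
              "          <ForeName>Alex</ForeName>",
              if (!is.null(orcid) && i == 1L) {
                sprintf("          <Identifier Source=\"ORCID\">%s</Identifier>", orcid)
              },
              "        </Author>")
    }
    if (!is.null(collective)) {
      au <- c(au,
              "        <Author>",
              sprintf("          <CollectiveName>%s</CollectiveName>", collective),
              "        </Author>")
    }
    au <- c(au, "      </AuthorList>")
  }
  c("<PubmedArticle>",
    "  <MedlineCitation>", pm,
    "    <Article>",
    "      <ArticleTitle>A test article</ArticleTitle>",
    au,
    "    </Article>",
    extra,
    "  </MedlineCitation>",
    "</PubmedArticle>")
}

write_article_set <- function(body_lines,
                              path = withr::local_tempfile(
                                fileext = ".xml", .local_envir = parent.frame())) {
  writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               "<PubmedArticleSet>", body_lines, "</PubmedArticleSet>"), path)
  path
}
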