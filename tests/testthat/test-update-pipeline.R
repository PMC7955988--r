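# build a small baseline with one pmid, then stage given update files
stage_fixture <- function(script) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- generate_fixture_files(script, dir)
  nm <- fixture_file_names(script)
  con <- new_con()
  build_baseline(file.path(dir, nm$baseline), con)
  init_tables(con, temporary = TRUE)
  stage_updates(file.path(dir, nm$update), con)
  con
}

test_that("staging is append-only and tags rows with their source file", {
  sc <- event_script(data.frame(
    file_index = c(1L, 2L, 3L), type = c("create", "update", "update"),
    pmid = 5L, version = 1L),
    n_baseline_files = 1L, n_update_files = 2L, seed = 21L)
  con <- stage_fixture(sc)
  withr::defer(DBI::dbDisconnect(con))
  staged <- DBI::dbReadTable(con, "tmp_pub")
  expect_identical(nrow(staged), 2L)
  expect_setequal(staged$source_file,
                  c("pubmed26n0002.xml.gz", "pubmed26n0003.xml.gz"))
})

test_that("the latest file wins a version tie; a higher version dominates", {
  # same version updated in two files: the later file's rows win
  sc <- event_script(data.frame(
    file_index = c(1L, 2L, 3L), type = c("create", "update", "update"),
    pmid = 5L, version = 1L),
    n_baseline_files = 1L, n_update_files = 2L, seed = 22L)
  con <- stage_fixture(sc)
  withr::defer(DBI::dbDisconnect(con))
  plan <- resolve_plan(con)
  expect_identical(plan$winners$pmid, 5L)
  expect_identical(plan$winners$version, 1L)
  expect_identical(plan$winners$source_file, "pubmed26n0003.xml.gz")

  # version 2 beats version 1 regardless of file order
  sc2 <- event_script(data.frame(
    file_index = c(1L, 2L, 3L), type = c("create", "update", "update"),
    pmid = 9L, version = c(1L, 2L, 2L)),
    n_baseline_files = 1L, n_update_files = 2L, seed = 23L)
  con2 <- stage_fixture(sc2)
  withr::defer(DBI::dbDisconnect(con2))
  plan2 <- resolve_plan(con2)
  expect_identical(plan2$winners$version, 2L)
  expect_identical(plan2$winners$source_file, "pubmed26n0003.xml.gz")
})

test_that("resolve_plan matches a brute-force last-event oracle", {
  for (s in 1:10) {
    sc <- random_event_script(100L + s, n_pmids = 10L, n_baseline_files = 1L,
                              n_update_files = 4L, p_multi_version = 0.6,
                              p_delete = 0.4)
    dir <- withr::local_tempdir()
    paths <- generate_fixture_files(sc, dir)
    nm <- fixture_file_names(sc)
    con <- new_con()
    build_baseline(file.path(dir, nm$baseline), con)
    init_tables(con, temporary = TRUE)
    stage_updates(file.path(dir, nm$update), con)
    plan <- resolve_plan(con)

    # oracle: replay events one by one (deletes after articles per file)
    ev <- sc$events[sc$events$file_index > sc$n_baseline_files, ]
    ev <- ev[order(ev$file_index, ev$type == "delete", ev$event_pos), ]
    fin <- list()
    for (i in seq_len(nrow(ev))) {
      fin[[as.character(ev$pmid[i])]] <-
        if (ev$type[i] == "delete") "deleted" else
          c(ev$version[i], ev$file_index[i])
    }
    exp_del <- sort(as.integer(names(fin)[vapply(fin, identical, logical(1L), "deleted")]))
    expect_identical(plan$deletions, exp_del)
    live <- fin[!vapply(fin, identical, logical(1L), "deleted")]
    # winner version per surviving staged pmid must be the maximum staged
    for (pm in names(live)) {
      staged_v <- DBI::dbGetQuery(con,
        "SELECT MAX(version) AS v FROM tmp_pub WHERE pmid = ?",
        params = list(as.integer(pm)))$v
      w <- plan$winners[plan$winners$pmid == as.integer(pm), ]
      expect_identical(w$version, staged_v)
    }
    DBI::dbDisconnect(con)
  }
})

test_that("an empty plan applies as a no-op", {
  con <- new_con()
  withr::defer(DBI::dbDisconnect(con))
  init_tables(con, temporary = TRUE)
  plan <- update_plan(data.frame(pmid = integer(0L), version = integer(0L),
                                 source_file = character(0L)), integer(0L))
  chg <- apply_plan(con, plan)
  expect_true(all(chg$rows_deleted == 0L))
  expect_true(all(chg$rows_appended == 0L))
})

test_that("a brand-new pmid in an update file is inserted, deleting nothing", {
  sc <- event_script(data.frame(
    file_index = c(1L, 2L), type = "create", pmid = c(1L, 2L), version = 1L,
    n_authors = 2L),
    n_baseline_files = 1L, n_update_files = 1L, seed = 25L)
  dir <- withr::local_tempdir()
  paths <- generate_fixture_files(sc, dir)
  nm <- fixture_file_names(sc)
  con <- new_con()
  withr::defer(DBI::dbDisconnect(con))
  build_baseline(file.path(dir, nm$baseline), con)
  res <- update_database(file.path(dir, nm$update), con)
  expect_identical(res$changes$rows_deleted[["author"]], 0L)
  expect_identical(res$changes$rows_appended[["author"]], 2L)
  expect_setequal(DBI::dbReadTable(con, "pub")$pmid, c(1L, 2L))
})

test_that("every ordering of create/update/delete ends as its last event", {
  # create in the baseline; the update/delete pair lands in two update
  # files in both orders; a delete-final schedule leaves no rows, an
  # update-final schedule reinserts the pmid
  cases <- list(
    list(types = c("update", "delete"), survives = FALSE),
    list(types = c("delete", "update"), survives = TRUE))
  for (cs in cases) {
    sc <- event_script(data.frame(
      file_index = 1:3,
      type = c("create", cs$types),
      pmid = 77L,
      version = c(1L, ifelse(cs$types == "delete", NA_integer_, 2L))),
      n_baseline_files = 1L, n_update_files = 2L, seed = 26L)
    con <- run_full_pipeline(sc)
    for (tb in versioned_tables()) {
      n <- DBI::dbGetQuery(con, paste0(
        "SELECT COUNT(*) AS n FROM ", tb, " WHERE pmid = 77"))$n
      if (cs$survives) {
        if (tb == "pub") expect_identical(n, 1L)
      } else {
        expect_identical(n, 0L, label = paste("rows in", tb))
      }
    }
    if (cs$survives) {
      expect_identical(DBI::dbReadTable(con, "pub")$version, 2L)
    }
    DBI::dbDisconnect(con)
  }

  # orderings that put update or delete before create are invalid scripts
  expect_error(event_script(data.frame(
    file_index = 1:2, type = c("update", "create"), pmid = 1L, version = 1L),
    n_baseline_files = 1L, n_update_files = 1L), "update before create")
  expect_error(event_script(data.frame(
    file_index = 2:3, type = c("delete", "create"), pmid = 1L, version = 1L),
    n_baseline_files = 1L, n_update_files = 2L), "delete before create")
})

test_that("deleting a never-seen pmid is a silent no-op on the tables", {
  body <- c("<DeleteCitation>", "  <PMID Version=\"1\">424242</PMID>",
            "</DeleteCitation>")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pubmed26n0002.xml.gz")
  con_out <- gzfile(path, "wt")
  writeLines(c("<?xml version=\"1.0\"?>", "<PubmedArticleSet>", body,
               "</PubmedArticleSet>"), con_out)
  close(con_out)
  con <- new_con()
  withr::defer(DBI::dbDisconnect(con))
  res <- update_database(path, con)
  expect_identical(res$plan$deletions, 424242L)
  expect_identical(DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM pub")$n, 0L)
})

test_that("re-running an update on processed files changes nothing", {
  sc <- random_event_script(61L, n_pmids = 20L)
  dir <- withr::local_tempdir()
  generate_fixture_files(sc, dir)
  nm <- fixture_file_names(sc)
  con <- new_con()
  withr::defer(DBI::dbDisconnect(con))
  build_baseline(file.path(dir, nm$baseline), con)
  update_database(file.path(dir, nm$update), con)
  before <- state_snapshot(con)
  res <- update_database(file.path(dir, nm$update), con)
  expect_length(res$staged$files_staged, 0L)
  expect_null(res$changes)
  expect_state_equal(state_snapshot(con), before)
})

test_that("appended rows equal the staged winning rows (conservation)", {
  sc <- random_event_script(62L, n_pmids = 25L)
  dir <- withr::local_tempdir()
  generate_fixture_files(sc, dir)
  nm <- fixture_file_names(sc)
  con <- new_con()
  withr::defer(DBI::dbDisconnect(con))
  build_baseline(file.path(dir, nm$baseline), con)
  init_tables(con, temporary = TRUE)
  stage_updates(file.path(dir, nm$update), con)
  plan <- resolve_plan(con)
  staged_winning <- vapply(versioned_tables(), function(tb) {
    tot <- 0L
    for (i in seq_len(nrow(plan$winners))) {
      w <- plan$winners[i, ]
      tot <- tot + DBI::dbGetQuery(con, paste0(
        "SELECT COUNT(*) AS n FROM tmp_", tb,
        " WHERE pmid = ? AND version = ? AND source_file = ?"),
        params = list(w$pmid, w$version, w$source_file))$n
    }
    tot
  }, integer(1L))
  chg <- apply_plan(con, plan)
  expect_identical(chg$rows_appended[versioned_tables()],
                   staged_winning[versioned_tables()])
})

test_that("a dry run reports the plan but leaves the database untouched", {
  sc <- random_event_script(63L, n_pmids = 15L)
  dir <- withr::local_tempdir()
  generate_fixture_files(sc, dir)
  nm <- fixture_file_names(sc)
  con <- new_con()
  withr::defer(DBI::dbDisconnect(con))
  build_baseline(file.path(dir, nm$baseline), con)
  before <- state_snapshot(con)
  res <- update_database(file.path(dir, nm$update), con, dry_run = TRUE)
  expect_s3_class(res$plan, "update_plan")
  expect_state_equal(state_snapshot(con), before)
  # ledger untouched: the same files are still unprocessed
  expect_length(unprocessed(file.path(dir, nm$update), con),
                length(nm$update))
})

test_that("after an update, each pmid holds at most one version everywhere", {
  sc <- random_event_script(64L, n_pmids = 40L, p_multi_version = 0.4,
                            p_delete = 0.2)
  con <- run_full_pipeline(sc)
  withr::defer(DBI::dbDisconnect(con))
  for (tb in versioned_tables()) {
    nv <- DBI::dbGetQuery(con, paste0(
      "SELECT pmid, COUNT(DISTINCT version) AS k FROM ", tb,
      " GROUP BY pmid HAVING k > 1"))
    expect_identical(nrow(nv), 0L, label = paste("multi-version pmids in", tb))
  }
})
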