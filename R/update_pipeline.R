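#' Resolved merge decision for one update batch
#'
#' An `update_plan` holds, per PMID touched by the staged files, the
#' winning `(version, source_file)` whose rows will replace the PMID's main
#' rows, and the set of PMIDs whose last event in file order is a deletion
#' notice. A PMID never appears in both: the later event wins.
#'
#' @param winners data.table with columns `pmid`, `version`, `source_file`.
#' @param deletions Integer vector of PMIDs to tombstone.
#' @return An object of class `update_plan`.
#' @export
update_plan <- function(winners, deletions) {
  winners <- data.table::as.data.table(winners)
  stopifnot(all(c("pmid", "version", "source_file") %in% names(winners)))
  deletions <- sort(unique(as.integer(deletions)))
  if (length(intersect(winners$pmid, deletions)) > 0L) {
    stop("update_plan: a pmid cannot be both a winner and a deletion")
  }
  structure(list(winners = winners, deletions = deletions),
            class = "update_plan")
}

#' @export
print.update_plan <- function(x, ...) {
  cat("<update_plan> ", nrow(x$winners), " updated PMID(s), ",
      length(x$deletions), " deletion(s)\n", sep = "")
  invisible(x)
}

#' Stage update files into the temporary tables
#'
#' Parses every not-yet-processed post-baseline file and appends its rows
#' to the `tmp_*` staging twins, each row tagged with its source file;
#' deletion notices land in `tmp_delete_citation`. Each file's append and
#' ledger entry share one transaction, so staging is resumable. Resolution
#' of competing versions happens later ([resolve_plan()]); staging itself
#' is append-only.
#'
#' @param file_list Paths to post-baseline XML files.
#' @param con A DBI connection; main tables and staging twins must exist.
#' @param workers Number of parallel parser processes.
#' @param registry Table registry.
#' @return A list with `files_staged`, `files_skipped` and
#'   `rows_per_table` (rows staged per table in this call).
#' @export
stage_updates <- function(file_list, con, workers = 1L,
                          registry = pmdb_registry()) {
  ordered <- file_list[order(file_sequence_key(basename(file_list)))]
  todo <- unprocessed(ordered, con)
  skipped <- setdiff(basename(ordered), basename(todo))
  batches <- parse_files_parallel(todo, workers, registry)
  staged <- integer(0L)
  for (batch in batches) {
    with_savepoint(con, {
      counts <- append_batch(con, batch, into_temporary = TRUE,
                             registry = registry, transactional = FALSE)
      log_file(con, batch$source_file)
      for (tb in names(counts)) {
        staged[tb] <- (if (tb %in% names(staged)) staged[tb] else 0L) + counts[tb]
      }
    })
  }
  list(files_staged = basename(todo), files_skipped = skipped,
       rows_per_table = staged)
}

#' Resolve the winning version and file for every staged PMID
#'
#' Determines, from the staging tables, the set of PMIDs whose data have
#' been updated together with each PMID's most recent version and the most
#' recent file in which it appeared: the winner is the maximal version,
#' ties broken by the maximal source file in sequence order. A PMID whose
#' last event in file order is a deletion notice goes to the deletion set
#' instead (a deletion and an update in the same file resolve to the
#' deletion, as `DeleteCitation` reflects the end state of that day's
#' file).
#'
#' @param con A DBI connection with populated staging tables.
#' @param registry Table registry.
#' @return An [update_plan()].
#' @export
resolve_plan <- function(con, registry = pmdb_registry()) {
  # every staged article emits a pub row, so tmp_pub enumerates all updates
  upd <- data.table::as.data.table(DBI::dbGetQuery(
    con, "SELECT DISTINCT pmid, version, source_file FROM tmp_pub"))
  del <- data.table::as.data.table(DBI::dbGetQuery(
    con, paste0("SELECT pmid, source_file FROM ", DELETION_STAGING)))

  if (nrow(upd) > 0L) {
    upd[, file_seq := file_sequence_key(source_file)]
    winners <- upd[order(version, file_seq), .SD[.N], by = "pmid"]
  } else {
    winners <- data.table::data.table(
      pmid = integer(0L), version = integer(0L),
      source_file = character(0L), file_seq = character(0L))
  }
  deletions <- integer(0L)
  if (nrow(del) > 0L) {
    del[, file_seq := file_sequence_key(source_file)]
    last_del <- del[, list(file_seq = max(file_seq)), by = "pmid"]
    last_upd <- if (nrow(upd) > 0L) {
      upd[, list(file_seq = max(file_seq)), by = "pmid"]
    } else {
      data.table::data.table(pmid = integer(0L), file_seq = character(0L))
    }
    both <- merge(last_del, last_upd,
                  by = "pmid", all.x = TRUE, suffixes = c("_del", "_upd"))
    # deletion wins unless a strictly later file re-updates the pmid
    dead <- both[is.na(file_seq_upd) | file_seq_del >= file_seq_upd, pmid]
    deletions <- sort(unique(dead))
    winners <- winners[!pmid %in% deletions]
  }
  update_plan(winners[, c("pmid", "version", "source_file"), with = FALSE],
              deletions)
}

#' Apply a resolved update plan to the main tables
#'
#' For every winner PMID: all of its existing rows are deleted from every
#' versioned main table, then exactly the rows of its winning
#' `(version, source_file)` are appended from staging — whole-PMID
#' replacement, never a field-level diff. For every deletion PMID: rows are
#' removed from every versioned table and nothing is appended (tombstone).
#' The whole batch is one transaction; on success the staging tables are
#' dropped. On failure everything rolls back and staging is retained for
#' retry.
#'
#' @param con A DBI connection.
#' @param plan An [update_plan()] resolved from the current staging.
#' @param registry Table registry.
#' @param drop_staging Drop the `tmp_*` tables after a successful apply.
#' @return A list with `rows_deleted` and `rows_appended`, per table.
#' @export
apply_plan <- function(con, plan, registry = pmdb_registry(),
                       drop_staging = TRUE) {
  stopifnot(inherits(plan, "update_plan"))
  vt <- versioned_tables(registry)
  deleted <- appended <- setNames(integer(length(vt)), vt)
  touched <- unique(c(plan$winners$pmid, plan$deletions))
  with_savepoint(con, {
    if (length(touched) > 0L) {
      DBI::dbExecute(con, "DROP TABLE IF EXISTS tmp__touched")
      DBI::dbExecute(con, "CREATE TABLE tmp__touched (pmid INTEGER)")
      DBI::dbAppendTable(con, "tmp__touched", data.frame(pmid = touched))
      DBI::dbExecute(con, "DROP TABLE IF EXISTS tmp__winners")
      DBI::dbExecute(con,
        "CREATE TABLE tmp__winners (pmid INTEGER, version INTEGER, source_file TEXT)")
      if (nrow(plan$winners) > 0L) {
        DBI::dbAppendTable(con, "tmp__winners", as.data.frame(plan$winners))
      }
      for (tb in vt) {
        deleted[tb] <- DBI::dbExecute(con, paste0(
          "DELETE FROM ", tb,
          " WHERE pmid IN (SELECT pmid FROM tmp__touched)"))
        cols <- paste(names(registry[[tb]]$columns), collapse = ", ")
        scols <- paste0("s.", names(registry[[tb]]$columns), collapse = ", ")
        appended[tb] <- DBI::dbExecute(con, paste0(
          "INSERT INTO ", tb, " (", cols, ") SELECT ", scols,
          " FROM ", TEMP_PREFIX, tb, " s JOIN tmp__winners w ON ",
          "s.pmid = w.pmid AND s.version = w.version AND ",
          "s.source_file = w.source_file"))
      }
      DBI::dbExecute(con, "DROP TABLE tmp__touched")
      DBI::dbExecute(con, "DROP TABLE tmp__winners")
    }
    if (drop_staging) {
      for (tb in vt) {
        DBI::dbExecute(con, paste0("DROP TABLE IF EXISTS ", TEMP_PREFIX, tb))
      }
      DBI::dbExecute(con, paste0("DROP TABLE IF EXISTS ", DELETION_STAGING))
    }
  })
  list(rows_deleted = deleted, rows_appended = appended)
}

#' Apply post-baseline update files to the database
#'
#' The full update procedure: initialize staging twins, stage every
#' unprocessed file ([stage_updates()]), resolve the per-PMID winners and
#' deletions ([resolve_plan()]), and apply the plan ([apply_plan()]).
#' Re-running on already-processed files is a no-op, guarded by the
#' processed-file ledger.
#'
#' With `dry_run = TRUE` the whole procedure runs inside a transaction that
#' is rolled back at the end: the plan and the change counts are computed
#' and returned, but the database (including the ledger) is untouched.
#'
#' @param file_list Paths to post-baseline XML files.
#' @param con A DBI connection holding a built database.
#' @param workers Number of parallel parser processes.
#' @param dry_run Compute and report, change nothing.
#' @param registry Table registry.
#' @return A list with `staged`, `plan` and `changes`.
#' @export
update_database <- function(file_list, con, workers = 1L, dry_run = FALSE,
                            registry = pmdb_registry()) {
  run <- function() {
    init_tables(con, registry, temporary = TRUE)
    staged <- stage_updates(file_list, con, workers = workers,
                            registry = registry)
    if (length(staged$files_staged) == 0L) {
      # nothing new: clean up the (empty) staging twins and stop here
      for (tb in versioned_tables(registry)) {
        DBI::dbExecute(con, paste0("DROP TABLE IF EXISTS ", TEMP_PREFIX, tb))
      }
      DBI::dbExecute(con, paste0("DROP TABLE IF EXISTS ", DELETION_STAGING))
      return(list(staged = staged,
                  plan = update_plan(data.table::data.table(
                    pmid = integer(0L), version = integer(0L),
                    source_file = character(0L)), integer(0L)),
                  changes = NULL))
    }
    plan <- resolve_plan(con, registry)
    changes <- apply_plan(con, plan, registry)
    list(staged = staged, plan = plan, changes = changes)
  }
  if (dry_run) {
    DBI::dbBegin(con)
    on.exit(DBI::dbRollback(con), add = TRUE)
    run()
  } else {
    run()
  }
}
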