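#' Build the database from baseline files
#'
#' Runs the baseline creation procedure: parse every baseline file, append
#' its rows to the main tables and log it in the processed-file ledger
#' (append and log share one per-file transaction), then reduce every
#' versioned table so that only the latest version of each PMID remains.
#'
#' Parsing is done concurrently across `workers` processes; appends are
#' serialized in file-sequence order, so the final state is independent of
#' worker count. If two baseline files carry the same `(pmid, version)`,
#' the later file (in sequence order) wins, mirroring the
#' most-recent-file rule the update pipeline applies.
#'
#' Files already present in the ledger are skipped, which makes an
#' interrupted build resumable: re-running continues where it stopped and
#' converges to the same final state.
#'
#' @param file_list Paths to baseline XML files (plain or gzip).
#' @param con A DBI connection with initialized, empty-or-partial tables
#'   (see [init_tables()]).
#' @param workers Number of parallel parser processes (forked; on platforms
#'   without fork this falls back to sequential parsing).
#' @param registry Table registry.
#' @return A list with `files_processed`, `files_skipped`, `rows_per_table`
#'   (post-reduction counts) and `rows_removed` (by [keep_latest()]).
#' @export
build_baseline <- function(file_list, con, workers = 1L,
                           registry = pmdb_registry()) {
  stopifnot(length(file_list) > 0L)
  ordered <- file_list[order(file_sequence_key(basename(file_list)))]
  todo <- unprocessed(ordered, con)
  skipped <- setdiff(basename(ordered), basename(todo))

  batches <- parse_files_parallel(todo, workers, registry)
  for (i in seq_along(batches)) {
    batch <- batches[[i]]
    if (length(batch$deleted_pmids) > 0L) {
      stop("baseline file '", batch$source_file,
           "' contains deletion notices; deletions belong to update files")
    }
    with_savepoint(con, {
      # same (pmid, version) seen in an earlier file: later file wins
      keys <- unique(batch$rows_by_table$pub[, c("pmid", "version"), with = FALSE])
      if (!is.null(keys) && nrow(keys) > 0L) {
        delete_version_pairs(con, keys, registry)
      }
      append_batch(con, batch, into_temporary = FALSE,
                   registry = registry, transactional = FALSE)
      log_file(con, batch$source_file)
    })
  }

  removed <- integer(0L)
  for (tb in versioned_tables(registry)) {
    removed[tb] <- keep_latest(con, tb, version_table = "pub")
  }
  counts <- vapply(versioned_tables(registry), function(tb) {
    DBI::dbGetQuery(con, paste0("SELECT COUNT(*) AS n FROM ", tb))$n
  }, numeric(1L))
  list(files_processed = basename(todo), files_skipped = skipped,
       rows_per_table = counts, rows_removed = removed)
}

# parse files concurrently (pure computation; database untouched),
# preserving input order
parse_files_parallel <- function(files, workers, registry) {
  if (length(files) == 0L) return(list())
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(files, parse_file, registry = registry,
                       mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(files, parse_file, registry = registry)
  }
  for (i in seq_along(res)) {
    if (inherits(res[[i]], "try-error")) {
      stop("failed to parse '", basename(files[[i]]), "': ",
           attr(res[[i]], "condition")$message)
    }
  }
  res
}

# remove all rows matching any of the given (pmid, version) pairs from
# every versioned table, set-based via a transient key table
delete_version_pairs <- function(con, keys, registry) {
  DBI::dbExecute(con, "DROP TABLE IF EXISTS tmp__dupkeys")
  DBI::dbExecute(con, "CREATE TABLE tmp__dupkeys (pmid INTEGER, version INTEGER)")
  DBI::dbAppendTable(con, "tmp__dupkeys", as.data.frame(keys))
  for (tb in versioned_tables(registry)) {
    DBI::dbExecute(con, paste0(
      "DELETE FROM ", tb, " WHERE EXISTS (SELECT 1 FROM tmp__dupkeys k ",
      "WHERE k.pmid = ", tb, ".pmid AND k.version = ", tb, ".version)"))
  }
  DBI::dbExecute(con, "DROP TABLE tmp__dupkeys")
}

#' Keep only the latest version of each PMID
#'
#' Reduces one versioned table so that, for every PMID, only the rows with
#' the maximal version remain. Most PMIDs have a single version; multiple
#' versions arise from journals that publish revisions under one PMID. The
#' reduction is a set-based anti-join executed in the database, so it
#' scales to tables with millions of rows.
#'
#' A PMID's latest version is a property of the article, not of one table:
#' a revision may legitimately drop a data type (say, its abstract), and
#' the stale rows must still go. `version_table` names the table whose
#' `(pmid, version)` pairs define each PMID's maximal version; the build
#' pipeline passes `"pub"`, which every article populates. The default
#' reduces the table against itself.
#'
#' @param con A DBI connection.
#' @param table_name Name of a versioned table.
#' @param version_table Table defining the authoritative max version per
#'   PMID.
#' @return Number of rows removed.
#' @export
keep_latest <- function(con, table_name, version_table = table_name) {
  DBI::dbExecute(con, paste0(
    "DELETE FROM ", table_name, " WHERE EXISTS (",
    "SELECT 1 FROM (SELECT pmid, MAX(version) AS maxv FROM ", version_table,
    " GROUP BY pmid) m WHERE m.pmid = ", table_name, ".pmid AND ",
    table_name, ".version < m.maxv)"))
}
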