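#' @include registry.R
NULL

TEMP_PREFIX <- "tmp_"
DELETION_STAGING <- "tmp_delete_citation"

# map a semantic type to a portable SQL type
sql_type_of <- function(semantic) {
  switch(semantic,
    integer = "INTEGER", text = "TEXT", date = "TEXT", boolean = "INTEGER",
    stop("unknown semantic type: ", semantic))
}

# run code inside a named savepoint; works standalone and nested inside an
# outer transaction, which keeps the per-file transaction unit composable
.sp_counter <- local({n <- 0L; function() {n <<- n + 1L; n}})
with_savepoint <- function(con, code, name = NULL) {
  if (is.null(name)) name <- paste0("sp_", .sp_counter())
  DBI::dbExecute(con, paste0("SAVEPOINT ", name))
  ok <- FALSE
  tryCatch({
    res <- force(code)
    ok <- TRUE
    res
  }, finally = {
    if (ok) {
      DBI::dbExecute(con, paste0("RELEASE SAVEPOINT ", name))
    } else {
      DBI::dbExecute(con, paste0("ROLLBACK TO SAVEPOINT ", name))
      DBI::dbExecute(con, paste0("RELEASE SAVEPOINT ", name))
    }
  })
}

#' Create the database tables
#'
#' Creates every table in the registry. With `temporary = TRUE`, creates
#' name-prefixed staging twins (`tmp_*`) of every versioned table instead,
#' each carrying an extra `source_file` column so staged rows keep their
#' provenance, plus a `tmp_delete_citation` staging table for deletion
#' notices. Staging twins are ordinary tables (not connection-scoped
#' temporaries) so a crashed run can be inspected; they are dropped when an
#' update batch is applied successfully.
#'
#' Refuses to re-initialize over an existing non-empty main table: an
#' existing database must be updated, not silently rebuilt.
#'
#' @param con A DBI connection.
#' @param registry Table registry; see [pmdb_registry()].
#' @param temporary Create staging twins instead of main tables.
#' @return Invisibly, the names of the tables created.
#' @export
init_tables <- function(con, registry = pmdb_registry(), temporary = FALSE) {
  created <- character(0L)
  specs <- if (temporary) registry[versioned_tables(registry)] else registry
  for (spec in specs) {
    name <- if (temporary) paste0(TEMP_PREFIX, spec$name) else spec$name
    if (DBI::dbExistsTable(con, name)) {
      n <- DBI::dbGetQuery(con, paste0("SELECT COUNT(*) AS n FROM ", name))$n
      if (!temporary && n > 0L) {
        stop("table '", name, "' already exists and is not empty; ",
             "refusing to re-initialize (use the update pipeline instead)")
      }
      if (temporary && n > 0L) {
        # leftover staging from a crashed run: start clean
        DBI::dbExecute(con, paste0("DELETE FROM ", name))
      }
      next
    }
    cols <- spec$columns
    if (temporary) cols <- c(cols, source_file = "text")
    ddl <- paste0(
      "CREATE TABLE ", name, " (",
      paste(names(cols), vapply(unname(cols), sql_type_of, character(1L)),
            collapse = ", "),
      ")")
    DBI::dbExecute(con, ddl)
    created <- c(created, name)
  }
  if (temporary && !DBI::dbExistsTable(con, DELETION_STAGING)) {
    DBI::dbExecute(con, paste0(
      "CREATE TABLE ", DELETION_STAGING,
      " (pmid INTEGER, source_file TEXT)"))
    created <- c(created, DELETION_STAGING)
  } else if (temporary) {
    DBI::dbExecute(con, paste0("DELETE FROM ", DELETION_STAGING))
  }
  invisible(created)
}

#' Append a parsed batch to the database
#'
#' Appends every table of a [record_batch()] to the corresponding main
#' table (or staging twin). The append is atomic per batch: a failure on
#' any table rolls back the whole batch's contribution. The processed-file
#' ledger is not touched; see [log_file()].
#'
#' @param con A DBI connection.
#' @param batch A [record_batch()].
#' @param into_temporary Append into the `tmp_*` staging twins, tagging
#'   every row with the batch's source file.
#' @param registry Table registry.
#' @param transactional Wrap the append in its own savepoint. Pipelines
#'   that already hold a per-file transaction pass `FALSE`.
#' @return Named integer vector: rows appended per table.
#' @export
append_batch <- function(con, batch, into_temporary = FALSE,
                         registry = pmdb_registry(), transactional = TRUE) {
  stopifnot(inherits(batch, "record_batch"))
  unknown <- setdiff(names(batch$rows_by_table), names(registry))
  if (length(unknown) > 0L) {
    stop("batch contains tables not in the registry: ",
         paste(unknown, collapse = ", "))
  }
  do_append <- function() {
    counts <- integer(0L)
    for (tb in names(batch$rows_by_table)) {
      dt <- batch$rows_by_table[[tb]]
      spec <- registry[[tb]]
      expected <- names(spec$columns)
      if (!identical(sort(names(dt)), sort(expected))) {
        extra <- setdiff(names(dt), expected)
        miss <- setdiff(expected, names(dt))
        stop("column mismatch in table '", tb, "': ",
             if (length(extra)) paste0("unexpected [", paste(extra, collapse = ", "), "] "),
             if (length(miss)) paste0("missing [", paste(miss, collapse = ", "), "]"))
      }
      target <- tb
      out <- dt[, expected, with = FALSE]
      if (into_temporary) {
        if (!spec$keyed_by_version) next
        target <- paste0(TEMP_PREFIX, tb)
        out[, source_file := batch$source_file]
      }
      if (nrow(out) > 0L) {
        # booleans as 0/1 for backends without a native boolean
        for (cn in names(out)) if (is.logical(out[[cn]])) {
          out[[cn]] <- as.integer(out[[cn]])
        }
        DBI::dbAppendTable(con, target, out)
      }
      counts[tb] <- nrow(out)
    }
    if (into_temporary && length(batch$deleted_pmids) > 0L) {
      DBI::dbWriteTable(con, DELETION_STAGING,
                        data.frame(pmid = batch$deleted_pmids,
                                   source_file = batch$source_file),
                        append = TRUE, row.names = FALSE)
    }
    counts
  }
  if (transactional) with_savepoint(con, do_append()) else do_append()
}

#' Record a source file in the processed-file ledger
#'
#' Adds one row to the `xml_processed` table recording when the file was
#' ingested (UTC). A file may be logged at most once; the uniqueness check
#' is what makes re-running a pipeline idempotent.
#'
#' @param con A DBI connection.
#' @param file_name Source file name.
#' @param processed_at Timestamp; defaults to now.
#' @param md5 Optional checksum of the source file.
#' @return Invisibly, `file_name`.
#' @export
log_file <- function(con, file_name, processed_at = Sys.time(), md5 = NA_character_) {
  n <- DBI::dbGetQuery(
    con, "SELECT COUNT(*) AS n FROM xml_processed WHERE file_name = ?",
    params = list(file_name))$n
  if (n > 0L) stop("file '", file_name, "' is already logged as processed")
  DBI::dbExecute(
    con, "INSERT INTO xml_processed (file_name, processed_at, md5) VALUES (?, ?, ?)",
    params = list(file_name,
                  format(processed_at, "%Y-%m-%d %H:%M:%OS3", tz = "UTC"),
                  md5))
  invisible(file_name)
}

#' Files not yet processed
#'
#' Set-difference of the available files against the processed-file ledger,
#' sorted by file sequence: NLM file names encode a zero-padded sequence
#' number (`pubmed26n0042.xml.gz`), and the update merge rule needs a total
#' order on files.
#'
#' @param available_files Character vector of file names or paths.
#' @param con A DBI connection.
#' @return The unprocessed file names/paths, in sequence order.
#' @export
unprocessed <- function(available_files, con) {
  if (length(available_files) == 0L) return(character(0L))
  done <- DBI::dbGetQuery(con, "SELECT file_name FROM xml_processed")$file_name
  left <- available_files[!basename(available_files) %in% done]
  left[order(file_sequence_key(basename(left)))]
}

#' Ordering key of an NLM-style file name
#'
#' Extracts the zero-padded numeric segment after the `n` of the standard
#' `pubmed<yy>n<seq>.xml[.gz]` pattern, prefixed by the year segment so
#' ordering is lexicographic across annual baselines. Names that do not
#' match fall back to the whole name, which still yields a deterministic
#' order.
#'
#' @param file_names Character vector of file names.
#' @return Character sort keys, same length.
#' @export
file_sequence_key <- function(file_names) {
  m <- regmatches(file_names,
                  regexec("([0-9]+)n([0-9]+)\\.xml(\\.gz)?$", file_names))
  vapply(seq_along(file_names), function(i) {
    if (length(m[[i]]) >= 3L) paste0(m[[i]][2L], "~", m[[i]][3L])
    else file_names[[i]]
  }, character(1L))
}

#' Snapshot the logical state of the database
#'
#' Reads every versioned table back into R, coerced to the registry's
#' column types and sorted canonically by all columns, so that two
#' databases (or a database and the replay oracle's expected state) can be
#' compared with `identical()` regardless of backend or insertion order.
#'
#' @param con A DBI connection.
#' @param registry Table registry.
#' @param tables Which tables to snapshot; defaults to all versioned ones.
#' @return Named list of sorted data.tables.
#' @export
state_snapshot <- function(con, registry = pmdb_registry(),
                           tables = versioned_tables(registry)) {
  out <- list()
  for (tb in tables) {
    dt <- if (DBI::dbExistsTable(con, tb)) {
      data.table::as.data.table(DBI::dbReadTable(con, tb))
    } else {
      empty_table(registry[[tb]])
    }
    dt <- canonicalize_table(dt, registry[[tb]])
    data.table::setorderv(dt, names(dt), na.last = TRUE)
    out[[tb]] <- dt
  }
  out
}
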