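#' Version tag of a citation-collection release
#'
#' @param version_label Non-empty label the upstream gives its release.
#' @param retrieved_at Timestamp the release was obtained.
#' @return An object of class `source_version_tag`.
#' @export
source_version_tag <- function(version_label, retrieved_at = Sys.time()) {
  stopifnot(is.character(version_label), length(version_label) == 1L,
            nzchar(version_label))
  structure(list(version_label = version_label, retrieved_at = retrieved_at),
            class = "source_version_tag")
}

#' Should the citation table be refreshed?
#'
#' `TRUE` iff no version is currently loaded or the candidate's label
#' differs from the current one. Labels are compared for inequality only:
#' the upstream names its releases, and ordering those names is not this
#' package's contract.
#'
#' @param current The currently stored [source_version_tag()], or `NULL`.
#' @param candidate The candidate release's tag.
#' @return Logical scalar.
#' @export
needs_refresh <- function(current, candidate) {
  stopifnot(inherits(candidate, "source_version_tag"))
  is.null(current) || !identical(current$version_label, candidate$version_label)
}

#' Read the stored citation version tag
#'
#' @param con A DBI connection.
#' @return A [source_version_tag()], or `NULL` if none is stored.
#' @export
citation_version <- function(con) {
  if (!DBI::dbExistsTable(con, "citation_source_version")) return(NULL)
  df <- DBI::dbReadTable(con, "citation_source_version")
  if (nrow(df) == 0L) return(NULL)
  source_version_tag(df$version_label[[1L]],
                     as.POSIXct(df$retrieved_at[[1L]], tz = "UTC"))
}

#' Load the open citation edge list, replacing the previous table
#'
#' Reads a comma-delimited file (optionally gzipped) whose header names two
#' PMID columns, one directed citing → cited edge per line, and replaces
#' the `citation` table with its contents. Lines whose fields are not both
#' positive integers are skipped and counted, never fatal. Self-citations
#' (citing equals cited) are loaded but counted in the report.
#'
#' The load lands in a shadow table that is swapped in only on success, so
#' a failed load leaves the previous table (and its version tag) intact and
#' readers never see a half-loaded table.
#'
#' @param csv_source Path to the CSV file, or an open text connection.
#' @param con A DBI connection.
#' @param tag [source_version_tag()] of the release being loaded.
#' @param chunk_size Lines read per chunk; bounds memory on large files.
#' @param .before_swap Internal testing hook: a function run after the
#'   shadow table is fully loaded, before it replaces the live table.
#' @return A list with `edges_loaded`, `lines_skipped`, `self_citations`.
#' @export
load_citations <- function(csv_source, con, tag, chunk_size = 100000L,
                           .before_swap = NULL) {
  stopifnot(inherits(tag, "source_version_tag"))
  oc <- open_xml_connection(csv_source)  # same gzip-by-magic-bytes handling
  src <- oc$con
  if (oc$owned) on.exit(close(src), add = TRUE)

  header <- readLines(src, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("citation source is empty (no header row)")

  DBI::dbExecute(con, "DROP TABLE IF EXISTS citation__shadow")
  DBI::dbExecute(con,
    "CREATE TABLE citation__shadow (citing_pmid INTEGER, cited_pmid INTEGER)")
  loaded <- skipped <- selfc <- 0L
  ok <- FALSE
  tryCatch({
    repeat {
      lines <- readLines(src, n = chunk_size, warn = FALSE)
      if (length(lines) == 0L) break
      lines <- lines[nzchar(lines)]
      if (length(lines) == 0L) next
      parts <- data.table::tstrsplit(lines, ",", fixed = TRUE, keep = 1:2)
      citing <- suppressWarnings(as.integer(parts[[1L]]))
      cited <- suppressWarnings(as.integer(parts[[2L]]))
      n_fields <- lengths(regmatches(lines, gregexpr(",", lines, fixed = TRUE))) + 1L
      good <- !is.na(citing) & !is.na(cited) & citing >= 1L & cited >= 1L &
        n_fields == 2L
      skipped <- skipped + sum(!good)
      if (any(good)) {
        dt <- data.table::data.table(citing_pmid = citing[good],
                                     cited_pmid = cited[good])
        selfc <- selfc + sum(dt$citing_pmid == dt$cited_pmid)
        DBI::dbAppendTable(con, "citation__shadow", dt)
        loaded <- loaded + nrow(dt)
      }
    }
    if (is.function(.before_swap)) .before_swap()
    with_savepoint(con, {
      DBI::dbExecute(con, "DROP TABLE IF EXISTS citation")
      DBI::dbExecute(con, "ALTER TABLE citation__shadow RENAME TO citation")
      DBI::dbExecute(con, "DROP TABLE IF EXISTS citation_source_version")
      DBI::dbExecute(con,
        "CREATE TABLE citation_source_version (version_label TEXT, retrieved_at TEXT)")
      DBI::dbExecute(con,
        "INSERT INTO citation_source_version VALUES (?, ?)",
        params = list(tag$version_label,
                      format(tag$retrieved_at, "%Y-%m-%d %H:%M:%OS3", tz = "UTC")))
    })
    ok <- TRUE
  }, finally = {
    if (!ok) DBI::dbExecute(con, "DROP TABLE IF EXISTS citation__shadow")
  })
  list(edges_loaded = loaded, lines_skipped = skipped, self_citations = selfc)
}
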