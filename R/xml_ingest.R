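#' Parsed contents of one PubMed XML file
#'
#' A `record_batch` is the parser's output for a single source file: a map
#' from table name to a `data.table` of rows (every row carries `pmid`, and
#' `version` for article data), plus the list of PMIDs the file marks as
#' deleted, in document order.
#'
#' @param source_file File name the batch was parsed from.
#' @param rows_by_table Named list of data.tables; names must be registry
#'   table names.
#' @param deleted_pmids Integer vector of deleted PMIDs (duplicates kept).
#' @param registry Registry used to validate table names.
#' @return An object of class `record_batch`.
#' @export
record_batch <- function(source_file, rows_by_table, deleted_pmids = integer(0),
                         registry = pmdb_registry()) {
  unknown <- setdiff(names(rows_by_table), names(registry))
  if (length(unknown) > 0L) {
    stop("record_batch tables not in registry: ", paste(unknown, collapse = ", "))
  }
  structure(
    list(source_file = source_file,
         rows_by_table = rows_by_table,
         deleted_pmids = as.integer(deleted_pmids)),
    class = "record_batch"
  )
}

#' @export
print.record_batch <- function(x, ...) {
  cat("<record_batch> ", x$source_file, "\n", sep = "")
  n <- vapply(x$rows_by_table, nrow, integer(1L))
  for (tb in names(n)) cat(sprintf("  %-20s %d rows\n", tb, n[[tb]]))
  cat("  deleted PMIDs: ", length(x$deleted_pmids), "\n", sep = "")
  invisible(x)
}

# MEDLINE XML carries no namespaces; an empty map skips per-call namespace
# discovery in libxml2
.no_ns <- character(0L)

# open a text connection over a path, transparently handling gzip by magic
# bytes; an already-open connection is passed through untouched
open_xml_connection <- function(xml_source) {
  if (inherits(xml_source, "connection")) return(list(con = xml_source, owned = FALSE))
  stopifnot(is.character(xml_source), length(xml_source) == 1L)
  if (!file.exists(xml_source)) stop("no such file: ", xml_source)
  magic <- readBin(xml_source, "raw", n = 2L)
  con <- if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    gzfile(xml_source, "rt", encoding = "UTF-8")
  } else {
    file(xml_source, "rt", encoding = "UTF-8")
  }
  list(con = con, owned = TRUE)
}

# Stream over the top-level elements of a PubmedArticleSet document.
# Articles and DeleteCitation blocks are handed to callbacks one complete
# element at a time, so peak memory is bounded by the largest element plus
# the read buffer, not by the file. Relies on each top-level open/close tag
# starting its own line, which holds for NLM release files and for the
# fixture generator. Unknown top-level elements are skipped with one warning
# per element name.
stream_article_set <- function(xml_source, file_name,
                               on_article, on_deletion,
                               chunk_lines = 4096L) {
  oc <- open_xml_connection(xml_source)
  con <- oc$con
  if (oc$owned) on.exit(close(con), add = TRUE)

  inside <- NULL        # NULL, "article" or "delete"
  skip_until <- NULL    # close tag of an unknown element being skipped
  buf <- character(0L)
  line_no <- 0L
  byte_off <- 0L
  article_idx <- 0L
  seen_root <- FALSE
  warned <- character(0L)

  known_close <- c(article = "</PubmedArticle>", delete = "</DeleteCitation>")

  repeat {
    lines <- readLines(con, n = chunk_lines, warn = FALSE)
    if (length(lines) == 0L) break
    for (ln in lines) {
      line_no <- line_no + 1L
      start_off <- byte_off
      byte_off <- byte_off + nchar(ln, type = "bytes") + 1L
      if (!is.null(skip_until)) {
        if (grepl(skip_until, ln, fixed = TRUE)) skip_until <- NULL
        next
      }
      if (is.null(inside)) {
        trimmed <- sub("^\\s+", "", ln)
        if (grepl("^<\\?xml|^<!DOCTYPE|^<PubmedArticleSet[\\s>]|^<PubmedArticleSet$|^</PubmedArticleSet>|^\\s*$",
                  trimmed, perl = TRUE)) {
          if (startsWith(trimmed, "<PubmedArticleSet")) seen_root <- TRUE
          next
        } else if (grepl("^<PubmedArticle[\\s>]", trimmed, perl = TRUE)) {
          inside <- "article"
          buf <- ln
        } else if (grepl("^<DeleteCitation[\\s>]", trimmed, perl = TRUE)) {
          inside <- "delete"
          buf <- ln
        } else if (grepl("^<[A-Za-z]", trimmed)) {
          el <- sub("^<([A-Za-z][A-Za-z0-9]*).*$", "\\1", trimmed)
          if (!el %in% warned) {
            warning("skipping unknown top-level element <", el, "> in ",
                    file_name, call. = FALSE)
            warned <- c(warned, el)
          }
          close_tag <- paste0("</", el, ">")
          self_closed <- grepl("/>\\s*$", trimmed) ||
            grepl(close_tag, trimmed, fixed = TRUE)
          if (!self_closed) skip_until <- close_tag
          next
        } else if (nzchar(trimmed)) {
          stop("malformed XML in ", file_name, " near byte ", start_off,
               " (line ", line_no, "): unexpected content outside any element")
        }
      } else {
        buf <- c(buf, ln)
      }
      if (!is.null(inside) && grepl(known_close[[inside]], ln, fixed = TRUE)) {
        chunk <- paste(buf, collapse = "\n")
        node <- tryCatch(
          xml2::read_xml(chunk),
          error = function(e) {
            stop("malformed XML in ", file_name, " near byte ", start_off,
                 " (line ", line_no, "): ", conditionMessage(e), call. = FALSE)
          })
        if (inside == "article") {
          article_idx <- article_idx + 1L
          on_article(node, article_idx)
        } else {
          on_deletion(node)
        }
        inside <- NULL
        buf <- character(0L)
      }
    }
  }
  if (!is.null(inside)) {
    stop("malformed XML in ", file_name, ": unterminated <",
         if (inside == "article") "PubmedArticle" else "DeleteCitation",
         "> element at end of file")
  }
  if (!seen_root && article_idx == 0L) {
    stop("malformed XML in ", file_name, ": no PubmedArticleSet root found")
  }
  invisible(article_idx)
}

#' Parse one PubMed XML file into per-table rows
#'
#' Stream-parses a baseline or post-baseline MEDLINE XML file (plain or
#' gzip-compressed) into a [record_batch()]: one `data.table` per data type
#' present in the document, every row keyed by `(pmid, version)`, plus the
#' PMIDs listed in any `DeleteCitation` element. Articles are processed one
#' at a time, so memory use is bounded by the largest single article, not by
#' the file.
#'
#' If the same PMID occurs more than once in one file, the last occurrence
#' in document order wins (consistent with the "most recent data" rule used
#' when merging update files).
#'
#' @param xml_source Path to the XML file (gzip detected by magic bytes), or
#'   an open text connection.
#' @param file_name Name recorded as the batch's source file; defaults to
#'   the basename of `xml_source`.
#' @param registry Table registry; see [pmdb_registry()].
#' @return A [record_batch()].
#' @export
parse_file <- function(xml_source, file_name = NULL, registry = pmdb_registry()) {
  if (is.null(file_name)) {
    file_name <- if (is.character(xml_source)) basename(xml_source) else "<connection>"
  }
  vtables <- versioned_tables(registry)
  acc <- new.env(parent = emptyenv())
  for (tb in vtables) assign(tb, list(), envir = acc)
  acc$deleted <- list()
  acc$pending <- 0L

  consolidate <- function() {
    # fold accumulated per-article pieces into one data.table per table to
    # keep the number of live small objects bounded during long streams
    for (tb in vtables) {
      pieces <- get(tb, envir = acc)
      if (length(pieces) > 1L) {
        assign(tb, list(data.table::rbindlist(pieces, use.names = TRUE)), envir = acc)
      }
    }
    acc$pending <- 0L
  }

  on_article <- function(node, idx) {
    tabs <- extract_article_tables(node, registry = registry,
                                   .element_index = idx, .canonical = FALSE)
    for (tb in names(tabs)) {
      piece <- tabs[[tb]]
      piece[[".aseq"]] <- rep.int(idx, length(piece[[1L]]))
      pieces <- get(tb, envir = acc)
      pieces[[length(pieces) + 1L]] <- piece
      assign(tb, pieces, envir = acc)
    }
    acc$pending <- acc$pending + 1L
    if (acc$pending >= 1024L) consolidate()
  }
  on_deletion <- function(node) {
    pmids <- xml2::xml_integer(xml2::xml_find_all(node, "./PMID", ns = .no_ns))
    acc$deleted[[length(acc$deleted) + 1L]] <- pmids
  }

  stream_article_set(xml_source, file_name, on_article, on_deletion)

  rows_by_table <- list()
  # last occurrence of a pmid in the file wins: every article emits a pub
  # row, so the pub table defines each pmid's final article sequence number
  pub_pieces <- get("pub", envir = acc)
  keep_aseq <- if (length(pub_pieces) > 0L) {
    pub_all <- data.table::rbindlist(pub_pieces, use.names = TRUE)
    pub_all[, list(.aseq = max(.aseq)), by = "pmid"]
  } else NULL
  for (tb in vtables) {
    pieces <- get(tb, envir = acc)
    dt <- if (length(pieces) == 0L) {
      empty_table(registry[[tb]])
    } else {
      dt <- data.table::rbindlist(pieces, use.names = TRUE)
      if (!is.null(keep_aseq)) {
        dt <- dt[keep_aseq, on = c("pmid", ".aseq"), nomatch = NULL]
      }
      dt[, .aseq := NULL]
      dt
    }
    rows_by_table[[tb]] <- canonicalize_table(dt, registry[[tb]])
  }
  record_batch(file_name, rows_by_table,
               deleted_pmids = unlist(acc$deleted, use.names = FALSE),
               registry = registry)
}

#' List the PMIDs a file marks as deleted
#'
#' Scans a PubMed XML file for `DeleteCitation` elements and returns the
#' listed PMIDs in document order, duplicates preserved. Baseline files
#' contain no deletion notices, so the result is empty for them.
#'
#' @inheritParams parse_file
#' @return Integer vector of PMIDs.
#' @export
parse_deletions <- function(xml_source, file_name = NULL) {
  if (is.null(file_name)) {
    file_name <- if (is.character(xml_source)) basename(xml_source) else "<connection>"
  }
  out <- list()
  stream_article_set(
    xml_source, file_name,
    on_article = function(node, idx) NULL,
    on_deletion = function(node) {
      out[[length(out) + 1L]] <<- xml2::xml_integer(xml2::xml_find_all(node, "./PMID", ns = .no_ns))
    })
  as.integer(unlist(out, use.names = FALSE))
}

#' Extract the relational rows of one article element
#'
#' Decomposes a single `PubmedArticle` element into rows for every
#' registered data type present in it. All rows share the article's
#' `(pmid, version)`; the `Version` attribute defaults to 1 when absent,
#' matching the MEDLINE DTD default. Data types absent from the article are
#' absent from the result. A malformed sub-record (for example an author
#' with neither a last name nor a collective name) is dropped with a
#' warning rather than emitted as a partial row.
#'
#' @param article_node An `xml2` node for one `PubmedArticle` element.
#' @param registry Table registry.
#' @param .element_index Optional 1-based index of the article within its
#'   file, used only in error messages.
#' @param .canonical Coerce each table to the registry's column order and
#'   types; the streaming parser defers this to the end of the file.
#' @return Named list of data.tables (possibly empty tables omitted).
#' @export
extract_article_tables <- function(article_node, registry = pmdb_registry(),
                                   .element_index = NA_integer_,
                                   .canonical = TRUE) {
  pmid_node <- xml2::xml_find_first(article_node, ".//MedlineCitation/PMID", ns = .no_ns)
  if (inherits(pmid_node, "xml_missing")) {
    stop("article", if (!is.na(.element_index)) paste0(" #", .element_index),
         " is missing its PMID element", call. = FALSE)
  }
  pmid <- suppressWarnings(as.integer(xml2::xml_text(pmid_node)))
  if (is.na(pmid) || pmid < 1L) {
    stop("article", if (!is.na(.element_index)) paste0(" #", .element_index),
         " has an unreadable PMID: '", xml2::xml_text(pmid_node), "'",
         call. = FALSE)
  }
  vattr <- xml2::xml_attr(pmid_node, "Version")
  version <- if (is.na(vattr)) 1L else suppressWarnings(as.integer(vattr))
  if (is.na(version) || version < 1L) version <- 1L

  out <- list()
  for (tb in versioned_tables(registry)) {
    spec <- registry[[tb]]
    ex <- spec$extract
    dt <- if (is.function(ex)) {
      ex(article_node, pmid, version)
    } else if (is.list(ex)) {
      extract_generic(article_node, pmid, version, ex, spec)
    } else NULL
    if (!is.null(dt) && length(dt[[1L]]) > 0L) {
      out[[tb]] <- if (.canonical) canonicalize_table(dt, spec) else dt
    }
  }
  out
}

# generic xpath-rule extractor for registry entries described as data
extract_generic <- function(article_node, pmid, version, rule, spec) {
  nodes <- xml2::xml_find_all(article_node, rule$node_xpath, ns = .no_ns)
  if (length(nodes) == 0L) return(NULL)
  cols <- list(pmid = rep.int(pmid, length(nodes)),
               version = rep.int(version, length(nodes)))
  if (!is.null(rule$pos_column)) cols[[rule$pos_column]] <- seq_along(nodes)
  for (cn in names(rule$columns)) {
    xp <- rule$columns[[cn]]
    vals <- if (identical(xp, ".")) {
      xml2::xml_text(nodes)
    } else if (startsWith(xp, "@")) {
      xml2::xml_attr(nodes, substring(xp, 2L))
    } else {
      vapply(nodes, function(nd) {
        hit <- xml2::xml_find_first(nd, xp, ns = .no_ns)
        if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
      }, character(1L))
    }
    if (identical(spec$columns[[cn]], "integer")) {
      vals <- suppressWarnings(as.integer(vals))
    } else if (identical(spec$columns[[cn]], "boolean")) {
      vals <- vals %in% c("Y", "y", "true", "1")
    }
    cols[[cn]] <- vals
  }
  cols
}

extract_pub <- function(article_node, pmid, version) {
  title_node <- xml2::xml_find_first(article_node, ".//Article/ArticleTitle", ns = .no_ns)
  title <- if (inherits(title_node, "xml_missing")) NA_character_ else
    xml2::xml_text(title_node)
  list(pmid = pmid, version = version, title = title)
}

extract_mesh <- function(article_node, pmid, version) {
  nodes <- xml2::xml_find_all(article_node, ".//MeshHeadingList/MeshHeading/DescriptorName", ns = .no_ns)
  if (length(nodes) == 0L) return(NULL)
  n <- length(nodes)
  list(
    pmid = rep.int(pmid, n), version = rep.int(version, n),
    term_pos = seq_len(n),
    descriptor_name = xml2::xml_text(nodes),
    descriptor_ui = xml2::xml_attr(nodes, "UI"),
    major_topic = xml2::xml_attr(nodes, "MajorTopicYN") %in% "Y")
}

extract_pub_history <- function(article_node, pmid, version) {
  nodes <- xml2::xml_find_all(article_node, ".//PubmedData/History/PubMedPubDate", ns = .no_ns)
  if (length(nodes) == 0L) return(NULL)
  status <- xml2::xml_attr(nodes, "PubStatus")
  keep <- !is.na(status) & nzchar(status)
  if (any(!keep)) {
    warning("history entry without PubStatus dropped for pmid ", pmid,
            call. = FALSE)
    nodes <- nodes[keep]
    status <- status[keep]
    if (length(nodes) == 0L) return(NULL)
  }
  years <- xml2::xml_text(xml2::xml_find_first(nodes, "./Year", ns = .no_ns))
  months <- xml2::xml_text(xml2::xml_find_first(nodes, "./Month", ns = .no_ns))
  days <- xml2::xml_text(xml2::xml_find_first(nodes, "./Day", ns = .no_ns))
  dates <- character(length(nodes))
  precisions <- character(length(nodes))
  for (k in seq_along(nodes)) {
    dd <- parse_history_date(years[k], months[k], days[k], pmid = pmid)
    dates[k] <- dd$date
    precisions[k] <- dd$precision
  }
  n <- length(nodes)
  list(pmid = rep.int(pmid, n), version = rep.int(version, n),
       pub_status = status, event_date = dates, date_precision = precisions)
}

# A date with a missing day is stored with day = 1 and precision "month"
# so that the column stays sortable without inventing day-level accuracy.
# Invalid components give a null date with precision "invalid" plus a
# warning; month names (Jan..Dec) are accepted as MEDLINE uses both forms.
parse_history_date <- function(year, month, day, pmid = NA_integer_) {
  y <- suppressWarnings(as.integer(year))
  m <- suppressWarnings(as.integer(month))
  if (is.na(m) && !is.na(month)) {
    m <- match(tolower(substr(month, 1L, 3L)), tolower(month.abb))
  }
  d <- suppressWarnings(as.integer(day))
  if (is.na(y) || is.na(m) || m < 1L || m > 12L ||
      (!is.na(day) && (is.na(d) || d < 1L || d > 31L))) {
    warning("invalid history date (", year, "-", month, "-", day,
            ") stored as null for pmid ", pmid, call. = FALSE)
    return(list(date = NA_character_, precision = "invalid"))
  }
  if (is.na(day)) {
    list(date = sprintf("%04d-%02d-01", y, m), precision = "month")
  } else {
    list(date = sprintf("%04d-%02d-%02d", y, m, d), precision = "day")
  }
}

extract_authors <- function(article_node, pmid, version) {
  nodes <- xml2::xml_find_all(article_node, ".//Article/AuthorList/Author", ns = .no_ns)
  if (length(nodes) == 0L) return(NULL)
  last <- xml2::xml_text(xml2::xml_find_first(nodes, "./LastName", ns = .no_ns))
  coll <- xml2::xml_text(xml2::xml_find_first(nodes, "./CollectiveName", ns = .no_ns))
  keep <- is.na(last) != is.na(coll)  # exactly one of the two
  if (any(!keep)) {
    warning("author entry for pmid ", pmid,
            " has neither or both of LastName/CollectiveName; dropped",
            call. = FALSE)
    if (!any(keep)) return(NULL)
    nodes <- nodes[keep]
    last <- last[keep]
    coll <- coll[keep]
  }
  n <- length(nodes)
  list(
    pmid = rep.int(pmid, n), version = rep.int(version, n),
    author_pos = seq_len(n),
    last_name = last,
    fore_name = xml2::xml_text(xml2::xml_find_first(nodes, "./ForeName", ns = .no_ns)),
    initials = xml2::xml_text(xml2::xml_find_first(nodes, "./Initials", ns = .no_ns)),
    suffix = xml2::xml_text(xml2::xml_find_first(nodes, "./Suffix", ns = .no_ns)),
    collective_name = coll)
}

extract_author_identifiers <- function(article_node, pmid, version) {
  nodes <- xml2::xml_find_all(article_node, ".//Article/AuthorList/Author", ns = .no_ns)
  if (length(nodes) == 0L) return(NULL)
  last <- xml2::xml_text(xml2::xml_find_first(nodes, "./LastName", ns = .no_ns))
  coll <- xml2::xml_text(xml2::xml_find_first(nodes, "./CollectiveName", ns = .no_ns))
  keep <- is.na(last) != is.na(coll)  # positions after the author filter
  nodes <- nodes[keep]
  rows <- list()
  for (pos in seq_along(nodes)) {
    ids <- xml2::xml_find_all(nodes[[pos]], "./Identifier", ns = .no_ns)
    if (length(ids) == 0L) next
    src <- xml2::xml_attr(ids, "Source")
    raw <- trimws(xml2::xml_text(ids))
    ok <- !is.na(raw) & nzchar(raw)
    if (!any(ok)) next
    src <- src[ok]
    raw <- raw[ok]
    val <- ifelse(src %in% "ORCID", normalize_orcid(raw), raw)
    k <- length(val)
    rows[[length(rows) + 1L]] <- list(
      pmid = rep.int(pmid, k), version = rep.int(version, k),
      author_pos = rep.int(pos, k),
      identifier_source = ifelse(is.na(src), "unknown", src),
      identifier = val)
  }
  if (length(rows) == 0L) return(NULL)
  as.list(data.table::rbindlist(rows))
}

#' Normalize an ORCID identifier
#'
#' Strips any `https://orcid.org/` style URL prefix, upper-cases the check
#' character, and returns the canonical 19-character dashed form. PubMed
#' records carry ORCIDs in several shapes (bare, dashed, URL); queries that
#' join on the identifier need one canonical key. Values that do not look
#' like an ORCID at all are returned verbatim (trimmed), so no information
#' is lost.
#'
#' @param x Character vector of raw identifier strings.
#' @return Character vector of the same length.
#' @export
normalize_orcid <- function(x) {
  out <- trimws(x)
  stripped <- sub("^(https?://)?(www\\.)?orcid\\.org/", "", out, ignore.case = TRUE)
  compact <- gsub("-", "", stripped)
  is_orcid <- grepl("^[0-9]{15}[0-9Xx]$", compact)
  canon <- toupper(compact[is_orcid])
  out[is_orcid] <- paste(substr(canon, 1, 4), substr(canon, 5, 8),
                         substr(canon, 9, 12), substr(canon, 13, 16), sep = "-")
  out
}
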