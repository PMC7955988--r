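#' Table specification
#'
#' A `table_spec` describes one relational table: its name, its ordered
#' columns with semantic types, and whether its rows are keyed by
#' `(pmid, version)` (i.e. hold versioned article data).
#'
#' Semantic types are one of `"integer"`, `"text"`, `"date"`, `"boolean"`.
#' Dates are stored as ISO-8601 text so that they sort correctly on every
#' supported backend; booleans map to 0/1 integers on backends without a
#' native boolean type.
#'
#' @param name Lowercase snake-case table name, unique within a registry.
#' @param columns Named character vector mapping column name to semantic type.
#' @param keyed_by_version Logical; if `TRUE` the first two columns must be
#'   `pmid` and `version`.
#' @param extract Optional extraction rule used by the XML parser: either a
#'   function `(article_node, pmid, version) -> data.table or NULL`, or a
#'   list with elements `node_xpath` (XPath selecting one node per row,
#'   relative to the article element), `columns` (named list mapping column
#'   name to an XPath relative to the row node; a leading `"@"` selects an
#'   attribute of the row node, `"."` its text), and optionally `pos_column`
#'   (name of a 1-based position column filled automatically).
#' @return An object of class `table_spec`.
#' @export
table_spec <- function(name, columns, keyed_by_version = TRUE, extract = NULL) {
  stopifnot(is.character(name), length(name) == 1L, grepl("^[a-z][a-z0-9_]*$", name))
  stopifnot(is.character(columns), !is.null(names(columns)))
  bad <- setdiff(unname(columns), c("integer", "text", "date", "boolean"))
  if (length(bad) > 0L) {
    stop("unknown semantic type(s) in table '", name, "': ", paste(bad, collapse = ", "))
  }
  if (isTRUE(keyed_by_version) &&
      !identical(names(columns)[1:2], c("pmid", "version"))) {
    stop("versioned table '", name, "' must begin with columns (pmid, version)")
  }
  structure(
    list(name = name, columns = columns,
         keyed_by_version = isTRUE(keyed_by_version), extract = extract),
    class = "table_spec"
  )
}

#' @export
print.table_spec <- function(x, ...) {
  cat("<table_spec> ", x$name,
      if (x$keyed_by_version) " (versioned)" else "", "\n", sep = "")
  cat("  columns: ", paste(names(x$columns), unname(x$columns),
                           sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The default table registry
#'
#' Returns the registry of relational tables that the parser populates: one
#' table per MEDLINE data type, each linked by `pmid` (and `version` for
#' article data). The registry is data-driven: generic tables are described
#' by XPath rules, so columns can be extended without touching parser code.
#' Tables with structural constraints (authors and their identifiers, the
#' publication history) use dedicated extractors.
#'
#' The two unversioned tables are `xml_processed` (the ledger of source
#' files already ingested) and `citation` (the open citation edge list,
#' refreshed wholesale rather than incrementally).
#'
#' @return A named list of [table_spec()] objects.
#' @export
pmdb_registry <- function() {
  specs <- list(
    table_spec("pub",
      c(pmid = "integer", version = "integer", title = "text"),
      extract = extract_pub),
    table_spec("journal",
      c(pmid = "integer", version = "integer", journal_name = "text",
        journal_iso = "text", issn = "text", volume = "text", issue = "text"),
      extract = list(
        node_xpath = ".//Article/Journal",
        columns = list(journal_name = "./Title", journal_iso = "./ISOAbbreviation",
                       issn = "./ISSN", volume = "./JournalIssue/Volume",
                       issue = "./JournalIssue/Issue"))),
    table_spec("pub_history",
      c(pmid = "integer", version = "integer", pub_status = "text",
        event_date = "date", date_precision = "text"),
      extract = extract_pub_history),
    table_spec("author",
      c(pmid = "integer", version = "integer", author_pos = "integer",
        last_name = "text", fore_name = "text", initials = "text",
        suffix = "text", collective_name = "text"),
      extract = extract_authors),
    table_spec("author_identifier",
      c(pmid = "integer", version = "integer", author_pos = "integer",
        identifier_source = "text", identifier = "text"),
      extract = extract_author_identifiers),
    table_spec("abstract",
      c(pmid = "integer", version = "integer", paragraph_pos = "integer",
        label = "text", text = "text"),
      extract = list(
        node_xpath = ".//Article/Abstract/AbstractText",
        columns = list(label = "@Label", text = "."),
        pos_column = "paragraph_pos")),
    table_spec("mesh_term",
      c(pmid = "integer", version = "integer", term_pos = "integer",
        descriptor_name = "text", descriptor_ui = "text",
        major_topic = "boolean"),
      extract = extract_mesh),
    table_spec("keyword",
      c(pmid = "integer", version = "integer", keyword_pos = "integer",
        keyword = "text"),
      extract = list(
        node_xpath = ".//KeywordList/Keyword",
        columns = list(keyword = "."),
        pos_column = "keyword_pos")),
    table_spec("grant_item",
      c(pmid = "integer", version = "integer", grant_id = "text",
        agency = "text", country = "text"),
      extract = list(
        node_xpath = ".//Article/GrantList/Grant",
        columns = list(grant_id = "./GrantID", agency = "./Agency",
                       country = "./Country"))),
    table_spec("pub_type",
      c(pmid = "integer", version = "integer", type_name = "text",
        type_ui = "text"),
      extract = list(
        node_xpath = ".//Article/PublicationTypeList/PublicationType",
        columns = list(type_name = ".", type_ui = "@UI"))),
    table_spec("article_id",
      c(pmid = "integer", version = "integer", id_type = "text",
        id_value = "text"),
      extract = list(
        node_xpath = ".//PubmedData/ArticleIdList/ArticleId",
        columns = list(id_type = "@IdType", id_value = "."))),
    table_spec("chemical",
      c(pmid = "integer", version = "integer", registry_number = "text",
        substance_name = "text"),
      extract = list(
        node_xpath = ".//ChemicalList/Chemical",
        columns = list(registry_number = "./RegistryNumber",
                       substance_name = "./NameOfSubstance"))),
    table_spec("data_bank",
      c(pmid = "integer", version = "integer", data_bank_name = "text",
        accession_number = "text"),
      extract = list(
        node_xpath = ".//Article/DataBankList/DataBank/AccessionNumberList/AccessionNumber",
        columns = list(data_bank_name = "../../DataBankName",
                       accession_number = "."))),
    table_spec("investigator",
      c(pmid = "integer", version = "integer", investigator_pos = "integer",
        last_name = "text", fore_name = "text", initials = "text"),
      extract = list(
        node_xpath = ".//InvestigatorList/Investigator",
        columns = list(last_name = "./LastName", fore_name = "./ForeName",
                       initials = "./Initials"),
        pos_column = "investigator_pos")),
    table_spec("comment_correction",
      c(pmid = "integer", version = "integer", ref_type = "text",
        ref_pmid = "integer"),
      extract = list(
        node_xpath = ".//CommentsCorrectionsList/CommentsCorrections",
        columns = list(ref_type = "@RefType", ref_pmid = "./PMID"))),
    table_spec("xml_processed",
      c(file_name = "text", processed_at = "text", md5 = "text"),
      keyed_by_version = FALSE),
    table_spec("citation",
      c(citing_pmid = "integer", cited_pmid = "integer"),
      keyed_by_version = FALSE)
  )
  names(specs) <- vapply(specs, `[[`, character(1L), "name")
  if (anyDuplicated(names(specs))) stop("duplicate table names in registry")
  specs
}

#' Names of the versioned article-data tables in a registry
#' @param registry A registry as returned by [pmdb_registry()].
#' @return Character vector of table names.
#' @export
versioned_tables <- function(registry = pmdb_registry()) {
  names(registry)[vapply(registry, `[[`, logical(1L), "keyed_by_version")]
}

# R storage mode for a semantic type (used to build typed empty tables and
# to canonicalize values read back from a backend)
r_type_of <- function(semantic) {
  switch(semantic,
    integer = "integer", text = "character", date = "character",
    boolean = "logical",
    stop("unknown semantic type: ", semantic))
}

# 0-row data.table with the spec's columns and R classes
empty_table <- function(spec) {
  cols <- lapply(unname(spec$columns), function(tt) vector(r_type_of(tt), 0L))
  names(cols) <- names(spec$columns)
  data.table::as.data.table(cols)
}

# coerce a table read back from a backend to the registry's R classes,
# so states are comparable across backends and with oracle output
canonicalize_table <- function(dt, spec) {
  dt <- data.table::as.data.table(dt)
  for (cn in names(spec$columns)) {
    target <- r_type_of(spec$columns[[cn]])
    if (!cn %in% names(dt)) {
      dt[[cn]] <- vector(target, nrow(dt))
      dt[[cn]][] <- NA
    } else if (target == "integer") {
      dt[[cn]] <- as.integer(dt[[cn]])
    } else if (target == "logical") {
      dt[[cn]] <- as.logical(dt[[cn]])
    } else {
      dt[[cn]] <- as.character(dt[[cn]])
    }
  }
  data.table::setcolorder(dt, names(spec$columns))
  dt[, names(spec$columns), with = FALSE]
}
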