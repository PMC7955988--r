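#' Event scripts for synthetic PubMed-style fixtures
#'
#' An `event_script` is a seeded, ordered list of record-level events —
#' `create(pmid, version)`, `update(pmid, version)`, `delete(pmid)` — each
#' assigned to a numbered file. [generate_fixture_files()] serializes the
#' script to gzip-compressed PubMed-style XML files (baseline files first,
#' then update files; deletion notices only in update files), and
#' [replay_oracle()] computes the ground-truth final database state by
#' replaying the events in order, sharing no code with the parsing or
#' pipeline modules. Together they form the package's primary test surface.
#'
#' Article content (names, dates, MeSH terms, ORCIDs, ...) is derived
#' deterministically from the script seed and the event's position, so the
#' same script always serializes to byte-identical files. Per-event payload
#' sizes can be fixed through optional columns of `events` (`n_authors`,
#' `n_orcid`, `n_history`, `n_mesh`, `n_keywords`, `n_abstract`,
#' `n_grants`, `n_chemicals`, `n_investigators`, `n_databank`,
#' `n_comment_corrections`); where absent or `NA` they are drawn from
#' seeded distributions chosen to look like typical MEDLINE records.
#'
#' @param events data.frame/data.table with columns `file_index` (1-based),
#'   `type` (`"create"`, `"update"`, `"delete"`), `pmid`, `version`
#'   (ignored for deletes), plus optional payload-size columns.
#' @param n_baseline_files Number of leading files that form the baseline.
#' @param n_update_files Number of post-baseline files after the baseline.
#' @param seed Integer seed for all content generation.
#' @return An object of class `event_script`.
#' @export
event_script <- function(events, n_baseline_files, n_update_files = 0L,
                         seed = 1L) {
  ev <- data.table::as.data.table(events)
  req <- c("file_index", "type", "pmid")
  if (!all(req %in% names(ev))) {
    stop("events must have columns: ", paste(req, collapse = ", "))
  }
  if (!"version" %in% names(ev)) ev[, version := 1L]
  ev[, file_index := as.integer(file_index)]
  ev[, pmid := as.integer(pmid)]
  ev[, version := as.integer(version)]
  ev[, event_pos := seq_len(.N)]
  n_files <- n_baseline_files + n_update_files

  offend <- function(i, why) {
    stop("invalid event script at event ", i, " (", ev$type[i], " pmid ",
         ev$pmid[i], ", file ", ev$file_index[i], "): ", why)
  }
  seen <- new.env(parent = emptyenv())
  last_file <- 0L
  for (i in seq_len(nrow(ev))) {
    tp <- ev$type[i]
    if (!tp %in% c("create", "update", "delete")) offend(i, "unknown event type")
    if (ev$file_index[i] < 1L || ev$file_index[i] > n_files) {
      offend(i, "file_index outside the script's files")
    }
    if (ev$file_index[i] < last_file) {
      offend(i, "events must be ordered by file_index")
    }
    last_file <- ev$file_index[i]
    key <- as.character(ev$pmid[i])
    prev <- if (exists(key, envir = seen)) get(key, envir = seen) else NULL
    if (tp == "create") {
      if (!is.null(prev)) offend(i, "pmid already created")
      if (is.na(ev$version[i]) || ev$version[i] < 1L) offend(i, "bad version")
      assign(key, ev$version[i], envir = seen)
    } else if (tp == "update") {
      if (is.null(prev)) offend(i, "update before create")
      if (is.na(ev$version[i]) || ev$version[i] < prev) {
        offend(i, "versions must be non-decreasing")
      }
      assign(key, ev$version[i], envir = seen)
    } else {
      if (is.null(prev)) offend(i, "delete before create")
      if (ev$file_index[i] <= n_baseline_files) {
        offend(i, "deletions are only allowed in update files")
      }
    }
  }
  structure(
    list(events = ev, n_baseline_files = as.integer(n_baseline_files),
         n_update_files = as.integer(n_update_files), seed = as.integer(seed)),
    class = "event_script")
}

#' @export
print.event_script <- function(x, ...) {
  cat("<event_script> seed ", x$seed, ": ", nrow(x$events), " events (",
      sum(x$events$type == "create"), " create, ",
      sum(x$events$type == "update"), " update, ",
      sum(x$events$type == "delete"), " delete) over ",
      x$n_baseline_files, " baseline + ", x$n_update_files,
      " update files\n", sep = "")
  invisible(x)
}

#' Draw a random, valid event script
#'
#' Emulates the shape of real PubMed releases at desk scale: most PMIDs are
#' created once in a baseline file and never touched again; a fraction gain
#' later versions (as with journals that publish article revisions under
#' one PMID); some arrive only in update files; some are deleted, and a few
#' deleted PMIDs later reappear. Payload sizes per record are drawn inside
#' the content generator.
#'
#' @param seed Integer seed.
#' @param n_pmids Number of distinct PMIDs in the script.
#' @param n_baseline_files,n_update_files File counts.
#' @param p_multi_version Probability a PMID receives at least one update
#'   event with a bumped or tied version.
#' @param p_delete Probability a PMID receives a deletion notice.
#' @return An [event_script()].
#' @export
random_event_script <- function(seed, n_pmids = 50L, n_baseline_files = 2L,
                                n_update_files = 3L, p_multi_version = 0.1,
                                p_delete = 0.1) {
  stopifnot(n_pmids >= 1L, n_baseline_files >= 1L)
  set.seed(seed)
  pmids <- sample(1000:999999, n_pmids)
  rows <- list()
  for (pm in pmids) {
    in_update <- n_update_files > 0L && stats::runif(1) < 0.2
    cfile <- if (in_update) {
      n_baseline_files + sample.int(n_update_files, 1L)
    } else {
      sample.int(n_baseline_files, 1L)
    }
    vers <- 1L
    rows[[length(rows) + 1L]] <- list(cfile, "create", pm, vers)
    lastf <- cfile
    if (stats::runif(1) < p_multi_version) {
      n_up <- sample.int(2L, 1L)
      for (k in seq_len(n_up)) {
        # updates live in the same or a later file; versions bump or tie
        nf <- if (lastf < n_baseline_files + n_update_files && stats::runif(1) < 0.85) {
          sample1(seq.int(lastf + 1L, n_baseline_files + n_update_files))
        } else lastf
        vers <- if (stats::runif(1) < 0.6) vers + 1L else vers
        rows[[length(rows) + 1L]] <- list(nf, "update", pm, vers)
        lastf <- nf
      }
    }
    if (n_update_files > 0L && stats::runif(1) < p_delete) {
      first_upd <- max(lastf, n_baseline_files + 1L)
      if (first_upd <= n_baseline_files + n_update_files) {
        dfile <- sample1(seq.int(first_upd, n_baseline_files + n_update_files))
        rows[[length(rows) + 1L]] <- list(dfile, "delete", pm, NA_integer_)
        if (dfile < n_baseline_files + n_update_files && stats::runif(1) < 0.3) {
          # a deleted PMID occasionally reappears in a later file
          rfile <- sample1(seq.int(dfile + 1L, n_baseline_files + n_update_files))
          vers <- vers + 1L
          rows[[length(rows) + 1L]] <- list(rfile, "update", pm, vers)
        }
      }
    }
  }
  ev <- data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(file_index = r[[1L]], type = r[[2L]],
                           pmid = r[[3L]], version = r[[4L]])
  }))
  data.table::setorderv(ev, "file_index")
  event_script(ev, n_baseline_files, n_update_files, seed = seed)
}

#' File names of a script's fixture set
#'
#' Names follow the NLM zero-padded sequence pattern so that the
#' file-ordering logic of the pipelines is exercised. Baseline files come
#' first in the sequence, update files continue it.
#'
#' @param script An [event_script()].
#' @return Named list with `baseline` and `update` character vectors.
#' @export
fixture_file_names <- function(script) {
  n <- script$n_baseline_files + script$n_update_files
  all <- sprintf("pubmed26n%04d.xml.gz", seq_len(n))
  list(baseline = all[seq_len(script$n_baseline_files)],
       update = if (script$n_update_files > 0L) {
         all[seq.int(script$n_baseline_files + 1L, n)]
       } else character(0L))
}

# ---- deterministic content generation ------------------------------------

.vocab <- list(
  words = c("circadian", "rhythm", "genome", "cohort", "signaling", "tumor",
            "receptor", "kinase", "expression", "clinical", "trial", "model",
            "pathway", "inflammation", "microbiome", "sequencing", "neural",
            "protein", "variant", "risk", "Q&A", "<i>in vivo</i> assay"),
  last_names = c("Smith", "Garcia", "Chen", "Muller", "Okafor", "Ivanov",
                 "Tanaka", "Rossi", "Nguyen", "Kaur", "O'Brien", "Silva"),
  fore_names = c("Alex", "Maria", "Wei", "Fatima", "John", "Aiko", "Lena",
                 "Carlos", "Priya", "Tom", "Anna", "Yusuf"),
  collectives = c("ENCODE Project Consortium", "Global Burden of Disease Study",
                  "COVID-19 Genomics Consortium", "ALSPAC Study Team"),
  journals = list(
    c("Journal of Synthetic Biology", "J Synth Biol", "1234-5678"),
    c("Annals of Test Medicine", "Ann Test Med", "2345-6789"),
    c("Fixture Letters", "Fixt Lett", "3456-7890"),
    c("Archives of Reproducible Research", "Arch Reprod Res", "4567-8901")),
  mesh = c("Humans", "Animals", "Mice", "Female", "Male", "Aged", "Adult",
           "Neoplasms", "Signal Transduction", "Mutation", "Prognosis",
           "Risk Factors"),
  keywords = c("machine learning", "biomarker", "epidemiology", "CRISPR",
               "meta-analysis", "public health", "aging", "immunotherapy"),
  agencies = c("NIGMS NIH HHS", "Wellcome Trust", "NSF", "ERC"),
  countries = c("United States", "United Kingdom", "Germany", "Japan"),
  chemicals = c("Doxorubicin", "Glucose", "Tamoxifen", "Caffeine"),
  databanks = c("GENBANK", "ClinicalTrials.gov", "PDB"),
  ref_types = c("Cites", "ErratumFor", "CommentOn"))

# sample exactly from the elements of x, even when length(x) == 1
sample1 <- function(x) x[sample.int(length(x), 1L)]
sample_n <- function(x, n) x[sample.int(length(x), n)]

# ISO 7064 mod 11-2 check character over 15 base digits
orcid_check_char <- function(digits15) {
  total <- 0L
  for (d in as.integer(strsplit(digits15, "")[[1L]])) {
    total <- (total + d) * 2L
  }
  res <- (12L - (total %% 11L)) %% 11L
  if (res == 10L) "X" else as.character(res)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# resolve one event's payload sizes: explicit columns win, otherwise seeded
# draws shaped like typical MEDLINE records
resolve_sizes <- function(ev, i) {
  pick <- function(col, draw) {
    v <- if (col %in% names(ev)) ev[[col]][i] else NA
    if (length(v) == 1L && !is.na(v)) as.integer(v) else draw()
  }
  list(
    n_authors = pick("n_authors", function() sample.int(6L, 1L)),
    n_orcid = pick("n_orcid", function() stats::rbinom(1L, 3L, 0.25)),
    n_history = pick("n_history", function() sample(2:5, 1L)),
    n_mesh = pick("n_mesh", function() sample(0:8, 1L)),
    n_keywords = pick("n_keywords", function() sample(0:5, 1L)),
    n_abstract = pick("n_abstract", function() sample(0:3, 1L)),
    n_grants = pick("n_grants", function() sample(0:2, 1L, prob = c(.6, .3, .1))),
    n_chemicals = pick("n_chemicals", function() sample(0:2, 1L, prob = c(.6, .3, .1))),
    n_investigators = pick("n_investigators", function() sample(0:2, 1L, prob = c(.7, .2, .1))),
    n_databank = pick("n_databank", function() stats::rbinom(1L, 1L, 0.15)),
    n_comment_corrections = pick("n_comment_corrections",
                                 function() stats::rbinom(1L, 2L, 0.1)))
}

# Deterministic payload for one create/update event: the normalized rows
# every table should hold for this (pmid, version), plus the serialization
# quirks (raw ORCID form, month-name dates, omitted Version attribute) the
# XML writer reproduces and the parser is expected to normalize away.
event_payload <- function(script, i) {
  pmid <- script$events$pmid[i]
  version <- script$events$version[i]
  # event position enters the seed so that same-version re-updates in later
  # files carry different content, making file-order resolution observable
  set.seed((abs(script$seed) * 7919L + pmid %% 100000L * 131L +
              version * 1009L + i * 17L) %% 2147483587L)
  sz <- resolve_sizes(script$events, i)
  v <- .vocab
  tb <- list()

  title <- paste(sample(v$words, sample(3:7, 1L), replace = TRUE), collapse = " ")
  tb$pub <- list(pmid = pmid, version = version, title = title)

  jr <- v$journals[[sample.int(length(v$journals), 1L)]]
  tb$journal <- list(
    pmid = pmid, version = version, journal_name = jr[1L], journal_iso = jr[2L],
    issn = jr[3L], volume = as.character(sample.int(60L, 1L)),
    issue = as.character(sample.int(12L, 1L)))

  # history: an entrez (database entry) event always present; extra statuses
  # precede it; ~10% of received/accepted dates carry only month precision
  entrez <- as.Date(sprintf("%d-%02d-%02d", sample(2010:2020, 1L),
                            sample.int(12L, 1L), sample.int(28L, 1L)))
  statuses <- c("entrez", sample(c("pubmed", "medline", "received", "accepted"),
                                 min(sz$n_history - 1L, 4L)))
  offsets <- c(0L, 5L, 10L, 90L, 30L)[seq_along(statuses)]
  hist_rows <- list()
  hist_aux <- list()
  for (k in seq_along(statuses)) {
    dt_k <- entrez - offsets[k]
    month_only <- statuses[k] %in% c("received", "accepted") && stats::runif(1) < 0.1
    iso <- if (month_only) format(dt_k, "%Y-%m-01") else format(dt_k, "%Y-%m-%d")
    hist_rows[[k]] <- list(
      pmid = pmid, version = version, pub_status = statuses[k],
      event_date = iso, date_precision = if (month_only) "month" else "day")
    hist_aux[[k]] <- list(
      year = format(dt_k, "%Y"),
      month = if (stats::runif(1) < 0.2) format(dt_k, "%b") else
        as.character(as.integer(format(dt_k, "%m"))),
      day = if (month_only) NA_character_ else
        as.character(as.integer(format(dt_k, "%d"))))
  }
  tb$pub_history <- as.list(data.table::rbindlist(hist_rows))

  # authors: mostly personal names, occasionally a collective; ORCIDs only
  # on personal names, serialized in mixed raw forms
  au_rows <- list()
  id_rows <- list()
  id_aux <- character(0L)
  personal_pos <- integer(0L)
  for (k in seq_len(sz$n_authors)) {
    if (stats::runif(1) < 0.12) {
      au_rows[[k]] <- list(
        pmid = pmid, version = version, author_pos = k,
        last_name = NA_character_, fore_name = NA_character_,
        initials = NA_character_, suffix = NA_character_,
        collective_name = sample(v$collectives, 1L))
    } else {
      fn <- sample(v$fore_names, 1L)
      au_rows[[k]] <- list(
        pmid = pmid, version = version, author_pos = k,
        last_name = sample(v$last_names, 1L), fore_name = fn,
        initials = substr(fn, 1L, 1L),
        suffix = if (stats::runif(1) < 0.05) "Jr" else NA_character_,
        collective_name = NA_character_)
      personal_pos <- c(personal_pos, k)
    }
  }
  if (sz$n_authors > 0L) tb$author <- as.list(data.table::rbindlist(au_rows))
  n_orcid <- min(sz$n_orcid, length(personal_pos))
  if (n_orcid > 0L) {
    for (pos in sort(sample_n(personal_pos, n_orcid))) {
      base15 <- paste(sample(0:9, 15L, replace = TRUE), collapse = "")
      digits16 <- paste0(base15, orcid_check_char(base15))
      dashed <- paste(substring(digits16, c(1, 5, 9, 13), c(4, 8, 12, 16)),
                      collapse = "-")
      raw <- switch(sample.int(4L, 1L),
        dashed,
        paste0("https://orcid.org/", dashed),
        paste0("http://orcid.org/", tolower(dashed)),
        gsub("-", "", dashed))
      id_rows[[length(id_rows) + 1L]] <- list(
        pmid = pmid, version = version, author_pos = pos,
        identifier_source = "ORCID", identifier = toupper(dashed))
      id_aux <- c(id_aux, raw)
    }
    tb$author_identifier <- as.list(data.table::rbindlist(id_rows))
  }

  if (sz$n_abstract > 0L) {
    labels <- c("BACKGROUND", "METHODS", "RESULTS", "CONCLUSIONS")
    tb$abstract <- list(
      pmid = rep.int(pmid, sz$n_abstract),
      version = rep.int(version, sz$n_abstract),
      paragraph_pos = seq_len(sz$n_abstract),
      label = if (sz$n_abstract > 1L) labels[seq_len(sz$n_abstract)] else
        NA_character_,
      text = vapply(seq_len(sz$n_abstract), function(j) {
        paste(sample(v$words, sample(6:12, 1L), replace = TRUE), collapse = " ")
      }, character(1L)))
  }
  if (sz$n_mesh > 0L) {
    terms <- sample_n(v$mesh, min(sz$n_mesh, length(v$mesh)))
    tb$mesh_term <- list(
      pmid = rep.int(pmid, length(terms)),
      version = rep.int(version, length(terms)),
      term_pos = seq_along(terms),
      descriptor_name = terms,
      descriptor_ui = sprintf("D%06d", match(terms, v$mesh)),
      major_topic = stats::runif(length(terms)) < 0.3)
  }
  if (sz$n_keywords > 0L) {
    kw <- sample_n(v$keywords, min(sz$n_keywords, length(v$keywords)))
    tb$keyword <- list(
      pmid = rep.int(pmid, length(kw)), version = rep.int(version, length(kw)),
      keyword_pos = seq_along(kw), keyword = kw)
  }
  if (sz$n_grants > 0L) {
    tb$grant_item <- list(
      pmid = rep.int(pmid, sz$n_grants), version = rep.int(version, sz$n_grants),
      grant_id = sprintf("R01 GM%06d", sample.int(999999L, sz$n_grants)),
      agency = sample(v$agencies, sz$n_grants, replace = TRUE),
      country = sample(v$countries, sz$n_grants, replace = TRUE))
  }
  tb$pub_type <- list(
    pmid = pmid, version = version,
    type_name = "Journal Article", type_ui = "D016428")
  tb$article_id <- list(
    pmid = rep.int(pmid, 2L), version = rep.int(version, 2L),
    id_type = c("pubmed", "doi"),
    id_value = c(as.character(pmid),
                 sprintf("10.5555/synth.%d.v%d", pmid, version)))
  if (sz$n_chemicals > 0L) {
    ch <- sample_n(v$chemicals, sz$n_chemicals)
    tb$chemical <- list(
      pmid = rep.int(pmid, length(ch)), version = rep.int(version, length(ch)),
      registry_number = sprintf("%d-%02d-%d", sample.int(99999L, length(ch)),
                                sample.int(99L, length(ch)), sample.int(9L, length(ch))),
      substance_name = ch)
  }
  if (sz$n_databank > 0L) {
    acc_n <- sample.int(2L, 1L)
    tb$data_bank <- list(
      pmid = rep.int(pmid, acc_n), version = rep.int(version, acc_n),
      data_bank_name = rep.int(sample(v$databanks, 1L), acc_n),
      accession_number = sprintf("ACC%06d", sample.int(999999L, acc_n)))
  }
  if (sz$n_investigators > 0L) {
    fn <- sample_n(v$fore_names, sz$n_investigators)
    tb$investigator <- list(
      pmid = rep.int(pmid, sz$n_investigators),
      version = rep.int(version, sz$n_investigators),
      investigator_pos = seq_len(sz$n_investigators),
      last_name = sample(v$last_names, sz$n_investigators), fore_name = fn,
      initials = substr(fn, 1L, 1L))
  }
  if (sz$n_comment_corrections > 0L) {
    k <- sz$n_comment_corrections
    tb$comment_correction <- list(
      pmid = rep.int(pmid, k), version = rep.int(version, k),
      ref_type = sample(v$ref_types, sz$n_comment_corrections, replace = TRUE),
      ref_pmid = sample.int(999999L, sz$n_comment_corrections))
  }

  # constructors already emit the registry's column order and types
  list(tables = tb,
       aux = list(omit_version_attr = version == 1L && stats::runif(1) < 0.5,
                  orcid_raw = id_aux, history = hist_aux))
}

# serialize one event's payload as PubmedArticle XML lines; the open and
# close tags start their own lines (the streaming parser's contract)
article_xml_lines <- function(payload) {
  tb <- payload$tables
  aux <- payload$aux
  pmid <- tb$pub$pmid[1L]
  version <- tb$pub$version[1L]
  L <- character(0L)
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add("<PubmedArticle>")
  add("  <MedlineCitation Status=\"MEDLINE\" Owner=\"NLM\">")
  if (isTRUE(aux$omit_version_attr)) {
    add("    <PMID>", pmid, "</PMID>")
  } else {
    add("    <PMID Version=\"", version, "\">", pmid, "</PMID>")
  }
  add("    <Article PubModel=\"Print\">")
  j <- tb$journal
  add("      <Journal>")
  add("        <ISSN IssnType=\"Print\">", xml_escape(j$issn), "</ISSN>")
  add("        <JournalIssue CitedMedium=\"Print\">")
  add("          <Volume>", xml_escape(j$volume), "</Volume>")
  add("          <Issue>", xml_escape(j$issue), "</Issue>")
  add("        </JournalIssue>")
  add("        <Title>", xml_escape(j$journal_name), "</Title>")
  add("        <ISOAbbreviation>", xml_escape(j$journal_iso), "</ISOAbbreviation>")
  add("      </Journal>")
  add("      <ArticleTitle>", xml_escape(tb$pub$title[1L]), "</ArticleTitle>")
  if (!is.null(tb$abstract)) {
    add("      <Abstract>")
    for (k in seq_len(length(tb$abstract$pmid))) {
      lab <- tb$abstract$label[k]
      add("        <AbstractText",
          if (!is.na(lab)) paste0(" Label=\"", xml_escape(lab), "\""), ">",
          xml_escape(tb$abstract$text[k]), "</AbstractText>")
    }
    add("      </Abstract>")
  }
  if (!is.null(tb$author)) {
    add("      <AuthorList CompleteYN=\"Y\">")
    ids_by_pos <- if (!is.null(tb$author_identifier)) {
      split(seq_len(length(tb$author_identifier$pmid)), tb$author_identifier$author_pos)
    } else list()
    au <- tb$author
    for (k in seq_len(length(au$pmid))) {
      add("        <Author ValidYN=\"Y\">")
      if (!is.na(au$collective_name[k])) {
        add("          <CollectiveName>", xml_escape(au$collective_name[k]),
            "</CollectiveName>")
      } else {
        add("          <LastName>", xml_escape(au$last_name[k]), "</LastName>")
        add("          <ForeName>", xml_escape(au$fore_name[k]), "</ForeName>")
        add("          <Initials>", xml_escape(au$initials[k]), "</Initials>")
        if (!is.na(au$suffix[k])) {
          add("          <Suffix>", xml_escape(au$suffix[k]), "</Suffix>")
        }
      }
      for (ii in ids_by_pos[[as.character(au$author_pos[k])]]) {
        add("          <Identifier Source=\"ORCID\">",
            xml_escape(aux$orcid_raw[ii]), "</Identifier>")
      }
      add("        </Author>")
    }
    add("      </AuthorList>")
  }
  if (!is.null(tb$grant_item)) {
    add("      <GrantList CompleteYN=\"Y\">")
    g <- tb$grant_item
    for (k in seq_len(length(g$pmid))) {
      add("        <Grant>")
      add("          <GrantID>", xml_escape(g$grant_id[k]), "</GrantID>")
      add("          <Agency>", xml_escape(g$agency[k]), "</Agency>")
      add("          <Country>", xml_escape(g$country[k]), "</Country>")
      add("        </Grant>")
    }
    add("      </GrantList>")
  }
  add("      <PublicationTypeList>")
  for (k in seq_len(length(tb$pub_type$pmid))) {
    add("        <PublicationType UI=\"", tb$pub_type$type_ui[k], "\">",
        xml_escape(tb$pub_type$type_name[k]), "</PublicationType>")
  }
  add("      </PublicationTypeList>")
  if (!is.null(tb$data_bank)) {
    add("      <DataBankList CompleteYN=\"Y\">")
    add("        <DataBank>")
    add("          <DataBankName>", xml_escape(tb$data_bank$data_bank_name[1L]),
        "</DataBankName>")
    add("          <AccessionNumberList>")
    for (k in seq_len(length(tb$data_bank$pmid))) {
      add("            <AccessionNumber>",
          xml_escape(tb$data_bank$accession_number[k]), "</AccessionNumber>")
    }
    add("          </AccessionNumberList>")
    add("        </DataBank>")
    add("      </DataBankList>")
  }
  add("    </Article>")
  if (!is.null(tb$chemical)) {
    add("    <ChemicalList>")
    for (k in seq_len(length(tb$chemical$pmid))) {
      add("      <Chemical>")
      add("        <RegistryNumber>", xml_escape(tb$chemical$registry_number[k]),
          "</RegistryNumber>")
      add("        <NameOfSubstance UI=\"D000000\">",
          xml_escape(tb$chemical$substance_name[k]), "</NameOfSubstance>")
      add("      </Chemical>")
    }
    add("    </ChemicalList>")
  }
  if (!is.null(tb$mesh_term)) {
    add("    <MeshHeadingList>")
    m <- tb$mesh_term
    for (k in seq_len(length(m$pmid))) {
      add("      <MeshHeading>")
      add("        <DescriptorName UI=\"", m$descriptor_ui[k], "\" MajorTopicYN=\"",
          if (m$major_topic[k]) "Y" else "N", "\">",
          xml_escape(m$descriptor_name[k]), "</DescriptorName>")
      add("      </MeshHeading>")
    }
    add("    </MeshHeadingList>")
  }
  if (!is.null(tb$keyword)) {
    add("    <KeywordList Owner=\"NOTNLM\">")
    for (k in seq_len(length(tb$keyword$pmid))) {
      add("      <Keyword MajorTopicYN=\"N\">", xml_escape(tb$keyword$keyword[k]),
          "</Keyword>")
    }
    add("    </KeywordList>")
  }
  if (!is.null(tb$investigator)) {
    add("    <InvestigatorList>")
    iv <- tb$investigator
    for (k in seq_len(length(iv$pmid))) {
      add("      <Investigator ValidYN=\"Y\">")
      add("        <LastName>", xml_escape(iv$last_name[k]), "</LastName>")
      add("        <ForeName>", xml_escape(iv$fore_name[k]), "</ForeName>")
      add("        <Initials>", xml_escape(iv$initials[k]), "</Initials>")
      add("      </Investigator>")
    }
    add("    </InvestigatorList>")
  }
  if (!is.null(tb$comment_correction)) {
    add("    <CommentsCorrectionsList>")
    cc <- tb$comment_correction
    for (k in seq_len(length(cc$pmid))) {
      add("      <CommentsCorrections RefType=\"", cc$ref_type[k], "\">")
      add("        <RefSource>synthetic</RefSource>")
      add("        <PMID Version=\"1\">", cc$ref_pmid[k], "</PMID>")
      add("      </CommentsCorrections>")
    }
    add("    </CommentsCorrectionsList>")
  }
  add("  </MedlineCitation>")
  add("  <PubmedData>")
  add("    <History>")
  for (k in seq_len(length(tb$pub_history$pmid))) {
    h <- aux$history[[k]]
    add("      <PubMedPubDate PubStatus=\"", tb$pub_history$pub_status[k], "\">")
    add("        <Year>", h$year, "</Year>")
    add("        <Month>", h$month, "</Month>")
    if (!is.na(h$day)) add("        <Day>", h$day, "</Day>")
    add("      </PubMedPubDate>")
  }
  add("    </History>")
  add("    <PublicationStatus>ppublish</PublicationStatus>")
  add("    <ArticleIdList>")
  for (k in seq_len(length(tb$article_id$pmid))) {
    add("      <ArticleId IdType=\"", tb$article_id$id_type[k], "\">",
        xml_escape(tb$article_id$id_value[k]), "</ArticleId>")
  }
  add("    </ArticleIdList>")
  add("  </PubmedData>")
  add("</PubmedArticle>")
  L
}

#' Serialize an event script to PubMed-style XML fixture files
#'
#' Writes one gzip-compressed `PubmedArticleSet` file per file index:
#' articles in event order, then (in update files) a single
#' `DeleteCitation` element listing the file's deletion notices in event
#' order — matching where NLM places deletions in real releases. The same
#' script always yields byte-identical files.
#'
#' @param script An [event_script()].
#' @param output_dir Directory to write into (created if needed).
#' @return Character vector of full paths, baseline files first.
#' @export
generate_fixture_files <- function(script, output_dir) {
  stopifnot(inherits(script, "event_script"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  nm <- fixture_file_names(script)
  all_names <- c(nm$baseline, nm$update)
  paths <- file.path(output_dir, all_names)
  ev <- script$events
  for (fi in seq_along(all_names)) {
    con <- gzfile(paths[fi], "wt")
    writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
                 "<PubmedArticleSet>"), con)
    idx <- which(ev$file_index == fi)
    buf <- character(0L)
    for (i in idx) {
      if (ev$type[i] == "delete") next
      buf <- c(buf, article_xml_lines(event_payload(script, i)))
      if (length(buf) > 20000L) {
        writeLines(buf, con)
        buf <- character(0L)
      }
    }
    if (length(buf) > 0L) writeLines(buf, con)
    dels <- ev$pmid[idx][ev$type[idx] == "delete"]
    if (length(dels) > 0L) {
      writeLines(c("<DeleteCitation>",
                   sprintf("  <PMID Version=\"1\">%d</PMID>", dels),
                   "</DeleteCitation>"), con)
    }
    writeLines("</PubmedArticleSet>", con)
    close(con)
  }
  paths
}

#' Per-file counts declared by a script
#'
#' The article and deletion counts each generated file will contain, plus
#' the per-table row counts [parse_file()] is expected to report for it
#' (after the within-file last-occurrence rule for repeated PMIDs).
#'
#' @param script An [event_script()].
#' @return data.table with one row per (file, table) plus article/deletion
#'   summaries as attributes `articles` and `deletions` (integer vectors
#'   indexed by file).
#' @export
script_counts <- function(script) {
  ev <- script$events
  n_files <- script$n_baseline_files + script$n_update_files
  articles <- integer(n_files)
  deletions <- integer(n_files)
  rows <- list()
  for (fi in seq_len(n_files)) {
    idx <- which(ev$file_index == fi)
    arts <- idx[ev$type[idx] != "delete"]
    articles[fi] <- length(arts)
    deletions[fi] <- sum(ev$type[idx] == "delete")
    if (length(arts) > 0L) {
      # last occurrence of a pmid within one file wins at parse time
      last_per_pmid <- tapply(arts, ev$pmid[arts], max)
      for (i in sort(as.integer(last_per_pmid))) {
        pl <- event_payload(script, i)
        for (tn in names(pl$tables)) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            file_index = fi, table = tn, n = length(pl$tables[[tn]]$pmid))
        }
      }
    }
  }
  out <- if (length(rows) > 0L) {
    data.table::rbindlist(rows)[, list(n = sum(n)), by = c("file_index", "table")]
  } else {
    data.table::data.table(file_index = integer(0L), table = character(0L),
                           n = integer(0L))
  }
  data.table::setattr(out, "articles", articles)
  data.table::setattr(out, "deletions", deletions)
  out
}

#' Ground-truth final database state of a script
#'
#' Replays the script's events in order — within a file, creates and
#' updates first, then deletion notices, matching document order — and
#' keeps, per PMID, only the outcome of its last event: absent after a
#' deletion, the event's rows otherwise. This brute-force replay shares no
#' code with the parsing, build or update modules, so agreement between a
#' built database and the oracle is an end-to-end check of the whole
#' pipeline.
#'
#' @param script An [event_script()].
#' @return Named list of data.tables (one per versioned table), each sorted
#'   canonically, directly comparable with [state_snapshot()].
#' @export
replay_oracle <- function(script) {
  ev <- script$events
  # effective order: deletions sort after the articles of their file
  ord <- order(ev$file_index, ev$type == "delete", ev$event_pos)
  final <- new.env(parent = emptyenv())
  for (i in ord) {
    key <- as.character(ev$pmid[i])
    if (ev$type[i] == "delete") {
      assign(key, NA_integer_, envir = final)
    } else {
      assign(key, i, envir = final)
    }
  }
  registry <- pmdb_registry()
  vt <- versioned_tables(registry)
  acc <- setNames(vector("list", length(vt)), vt)
  for (key in ls(final)) {
    i <- get(key, envir = final)
    if (is.na(i)) next
    pl <- event_payload(script, i)
    for (tn in names(pl$tables)) {
      acc[[tn]] <- c(acc[[tn]], list(pl$tables[[tn]]))
    }
  }
  out <- list()
  for (tn in vt) {
    dt <- if (is.null(acc[[tn]])) empty_table(registry[[tn]]) else
      data.table::rbindlist(acc[[tn]], use.names = TRUE)
    dt <- canonicalize_table(dt, registry[[tn]])
    data.table::setorderv(dt, names(dt), na.last = TRUE)
    out[[tn]] <- dt
  }
  out
}
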