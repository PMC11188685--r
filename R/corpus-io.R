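## Reading PubMed abstract exports and PMC JATS full texts, section
## filtering, and writing the per-step CSV outputs.

#' Read a PubMed abstract export CSV
#'
#' Reads the abstract CSV a user downloads from PubMed into one record per
#' article. Rows with a missing PMID are dropped and counted; duplicated
#' PMIDs keep the first occurrence. Column names default to the PubMed
#' export convention (`PMID`, `Title`, `Abstract`, optional `Year`) and can
#' be remapped for other exports.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional named character vector mapping the canonical
#'   names `pmid`, `title`, `abstract`, `year` to the file's column names,
#'   e.g. `c(pmid = "pubmed_id")`.
#' @return A data frame with columns `pmid`, `title`, `abstract`, `year`
#'   (NA when absent). The attribute `"load_report"` records rows read,
#'   dropped for missing PMID, and dropped as duplicates.
#' @export
read_pubmed_csv <- function(path, column_map = NULL) {
  stopifnot_scalar_string(path, "path")
  if (!file.exists(path)) err_io(sprintf("abstract CSV not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  cols <- c(pmid = "PMID", title = "Title", abstract = "Abstract", year = "Year")
  if (!is.null(column_map)) cols[names(column_map)] <- unname(column_map)
  for (required in c("pmid", "abstract")) {
    if (!cols[[required]] %in% names(raw)) {
      err_format(sprintf("required column '%s' (%s) not found in %s",
                         cols[[required]], required, path))
    }
  }
  pick <- function(key) {
    if (cols[[key]] %in% names(raw)) raw[[cols[[key]]]] else rep(NA_character_, nrow(raw))
  }
  rec <- new_df(pmid = trimws(pick("pmid")),
                title = ifelse(is.na(pick("title")), "", pick("title")),
                abstract = ifelse(is.na(pick("abstract")), "", pick("abstract")))
  rec$year <- suppressWarnings(as.integer(pick("year")))
  n_read <- nrow(rec)
  keep <- !is.na(rec$pmid) & nzchar(rec$pmid)
  n_missing <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  dup <- duplicated(rec$pmid)
  n_dup <- sum(dup)
  if (n_dup > 0L) crmlit_log(sprintf("%d duplicated PMID rows dropped", n_dup),
                            stage = "read")
  rec <- rec[!dup, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "load_report") <- list(read = n_read, dropped_missing_pmid = n_missing,
                                   dropped_duplicate_pmid = n_dup)
  rec
}

#' Keep only abstracts mentioning at least one keyword
#'
#' Case-insensitive whole-word matching on the title and the abstract; a
#' record is retained when any keyword occurs in either. "fly" therefore
#' does not match "butterfly".
#'
#' @param records Data frame from [read_pubmed_csv()].
#' @param keywords Non-empty character vector of keywords.
#' @return The retained rows of `records`, input order preserved.
#' @export
keyword_prefilter <- function(records, keywords) {
  if (length(keywords) == 0L || !all(nzchar(keywords))) {
    err_config("keyword filter enabled but no keywords given")
  }
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", keywords)
  pat <- paste0("\\b(?:", paste(esc, collapse = "|"), ")\\b")
  hay <- paste(records$title, records$abstract)
  records[grepl(pat, hay, perl = TRUE, ignore.case = TRUE), , drop = FALSE]
}

#' Full-text transports
#'
#' A transport is any object with a `get(pmid)` function returning the JATS
#' XML for an article as a raw vector or string, or `NULL` when no
#' open-access full text exists. Transports isolate all retrieval so the
#' whole pipeline runs offline: `local_dir_transport()` serves `<pmid>.xml`
#' files from a directory (the layout of an unpacked PMC OA package), and
#' `list_transport()` serves an in-memory named list (used in tests).
#'
#' @param dir Directory containing `<pmid>.xml` files.
#' @return A `fulltext_transport` object.
#' @export
local_dir_transport <- function(dir) {
  stopifnot_scalar_string(dir, "dir")
  if (!dir.exists(dir)) err_io(sprintf("full-text directory not found: %s", dir))
  structure(list(
    get = function(pmid) {
      f <- file.path(dir, paste0(pmid, ".xml"))
      if (!file.exists(f)) return(NULL)
      readBin(f, "raw", n = file.size(f))
    },
    description = sprintf("local directory %s", dir)
  ), class = "fulltext_transport")
}

#' @rdname local_dir_transport
#' @param docs Named list (names = PMIDs) of XML strings; missing names mean
#'   "no full text available".
#' @export
list_transport <- function(docs) {
  structure(list(
    get = function(pmid) {
      if (!pmid %in% names(docs)) return(NULL)
      docs[[pmid]]
    },
    description = "in-memory list"
  ), class = "fulltext_transport")
}

#' Fetch and parse one article's full text
#'
#' Asks the transport for the article's JATS XML and parses it. An article
#' with no available full text yields `NULL` (the caller then falls back to
#' the abstract); a transport failure raises a retriable retrieval error; a
#' malformed document raises a parse error. The three outcomes are distinct
#' condition classes so batch runs can skip rather than abort.
#'
#' @param pmid PubMed identifier.
#' @param transport A `fulltext_transport`.
#' @return An `article_fulltext` or `NULL` when unavailable.
#' @export
fetch_fulltext <- function(pmid, transport) {
  stopifnot_scalar_string(pmid, "pmid")
  if (!is.list(transport) || !is.function(transport$get)) {
    err_contract("transport must provide a get(pmid) function")
  }
  xml <- tryCatch(transport$get(pmid), error = function(e) {
    err_retrieval(sprintf("transport failed for pmid %s: %s", pmid,
                          conditionMessage(e)))
  })
  if (is.null(xml)) return(NULL)
  doc <- parse_jats(xml)
  doc$pmid <- pmid
  doc
}

#' Parse a JATS XML document into sections of paragraphs
#'
#' Collects every `<p>` under `<body>`, assigning each to the title of its
#' innermost enclosing `<sec>` ("" when untitled). Consecutive paragraphs
#' sharing a section title form one section; source order is preserved. The
#' abstract is not part of the body and is never included.
#'
#' @param xml JATS XML as raw bytes, a string, or an `xml2` document.
#' @return An `article_fulltext`: list with `pmid` (filled by
#'   [fetch_fulltext()]) and `sections`, a list of `list(title, paragraphs)`.
#' @export
parse_jats <- function(xml) {
  doc <- tryCatch(xml2::read_xml(xml), error = function(e) {
    err_parse(sprintf("malformed JATS XML: %s", conditionMessage(e)))
  })
  body <- xml2::xml_find_first(doc, ".//body")
  if (inherits(body, "xml_missing")) err_format("JATS document has no <body> element")
  ps <- xml2::xml_find_all(body, ".//p")
  titles <- vapply(ps, function(p) {
    t <- xml2::xml_find_first(p, "ancestor::sec[1]/title")
    if (inherits(t, "xml_missing")) "" else xml2::xml_text(t)
  }, character(1))
  texts <- trimws(xml2::xml_text(ps))
  keep <- nzchar(texts)
  titles <- titles[keep]
  texts <- texts[keep]
  sections <- list()
  if (length(texts) > 0L) {
    grp <- cumsum(c(TRUE, titles[-1L] != titles[-length(titles)]))
    sections <- lapply(split(seq_along(texts), grp), function(i) {
      list(title = titles[i[1L]], paragraphs = texts[i])
    })
    names(sections) <- NULL
  }
  structure(list(pmid = NA_character_, sections = sections),
            class = "article_fulltext")
}

#' @export
print.article_fulltext <- function(x, ...) {
  cat(sprintf("<article_fulltext pmid=%s: %d sections, %d paragraphs>\n",
              x$pmid, length(x$sections),
              sum(vapply(x$sections, function(s) length(s$paragraphs), integer(1)))))
  invisible(x)
}

#' Default list of removed section titles
#'
#' Methods, abbreviations, acknowledgements, references and supplementary
#' sections rarely explain experimental results, so their paragraphs are
#' excluded before mention pairing. Matching is case-insensitive substring
#' matching on punctuation-stripped titles, which also covers spelling
#' variants ("Acknowledgments"/"Acknowledgements").
#'
#' @export
default_removal_titles <- function() {
  c("materials and methods", "methods", "abbreviations",
    "acknowledgments", "acknowledgements", "references", "supplementary")
}

#' Drop paragraphs from non-result sections
#'
#' @param article An `article_fulltext`.
#' @param removal_titles Titles (or title fragments) of sections to drop;
#'   defaults to [default_removal_titles()]. An empty vector keeps all
#'   paragraphs.
#' @return Data frame of retained paragraphs: `pmid`, `section_title`,
#'   `index` (0-based, document order over retained paragraphs), `text`.
#' @export
filter_sections <- function(article, removal_titles = default_removal_titles()) {
  stopifnot(inherits(article, "article_fulltext"))
  removal <- normalize_title(removal_titles)
  removal <- removal[nzchar(removal)]
  rows <- lapply(article$sections, function(s) {
    norm <- normalize_title(s$title)
    drop <- length(removal) > 0L &&
      any(vapply(removal, function(r) grepl(r, norm, fixed = TRUE), logical(1)))
    if (drop) return(NULL)
    new_df(section_title = s$title, text = s$paragraphs)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- new_df(section_title = character(), text = character())
  }
  new_df(pmid = rep(article$pmid, nrow(out)),
         section_title = out$section_title,
         index = seq_len(nrow(out)) - 1L,
         text = out$text)
}

#' Write the per-step result CSVs and a run manifest
#'
#' @param results Named list with any of `step1` (pmid, probability,
#'   decision), `step3` (pair-level labels) and `step4` (per-article
#'   summary) data frames; missing entries produce header-only files.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a data frame manifest (`file`, `path`, `rows`); also
#'   written as `manifest.json` alongside the CSVs.
#' @export
write_outputs <- function(results, out_dir) {
  stopifnot_scalar_string(out_dir, "out_dir")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) err_io(sprintf("cannot create output directory: %s", out_dir))
  templates <- list(
    step1_articles.csv = new_df(pmid = character(), probability = numeric(),
                                decision = logical()),
    step3_pairs.csv = new_df(pmid = character(), gene = character(),
                             paragraph_index = integer(), section = character(),
                             target_gene_prob = numeric(), tf_prob = numeric(),
                             target_gene = logical(), regulatory_tf = logical(),
                             text = character()),
    step4_summary.csv = new_df(pmid = character(), gene = character(),
                               target_gene = logical(), regulatory_tf = logical(),
                               max_target_prob = numeric(), max_tf_prob = numeric(),
                               supporting_target = character(),
                               supporting_tf = character())
  )
  key_of <- c(step1_articles.csv = "step1", step3_pairs.csv = "step3",
              step4_summary.csv = "step4")
  manifest <- lapply(names(templates), function(f) {
    df <- results[[key_of[[f]]]] %||% templates[[f]]
    path <- file.path(out_dir, f)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    new_df(file = f, path = path, rows = nrow(df))
  })
  manifest <- do.call(rbind, manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
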