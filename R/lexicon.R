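## Gene/protein synonym lexicon: construction, ambiguity filtering, and
## dictionary mention finding on tokenized paragraphs.

#' Build a gene/protein synonym lexicon
#'
#' Every synonym, and the canonical symbol itself, becomes a lookup entry
#' mapping the surface form to the canonical symbol. A surface form claimed
#' by two different symbols is ambiguous and is dropped (and reported),
#' mirroring manual disambiguation of gene synonym tables. Lookup is
#' case-sensitive for surface forms containing an uppercase letter (fly gene
#' symbols are case-meaningful) and case-insensitive for all-lowercase
#' forms.
#'
#' @param table One of: a named list mapping symbol to a character vector of
#'   synonyms; a data frame with columns `symbol` and `synonyms`
#'   (pipe-separated); or a path to a two-column TSV in that layout.
#' @return A `synonym_lexicon`. The attribute `"dropped"` lists ambiguous
#'   surface forms that were removed.
#' @export
load_synonyms <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    if (!file.exists(table)) err_io(sprintf("synonym table not found: %s", table))
    df <- utils::read.delim(table, stringsAsFactors = FALSE,
                            colClasses = "character")
    table <- df
  }
  if (is.data.frame(table)) {
    if (!all(c("symbol", "synonyms") %in% names(table))) {
      err_format("synonym table needs 'symbol' and 'synonyms' columns")
    }
    syn <- strsplit(table$synonyms, "|", fixed = TRUE)
    syn <- lapply(syn, function(s) trimws(s[nzchar(trimws(s))]))
    table <- stats::setNames(syn, table$symbol)
  }
  if (!is.list(table) || length(table) == 0L) {
    err_config("synonym table is empty")
  }
  symbols <- names(table)
  if (is.null(symbols) || any(!nzchar(symbols))) {
    err_format("every synonym list must be named by its gene symbol")
  }
  surface <- c(symbols, unlist(table, use.names = FALSE))
  owner <- c(symbols, rep(symbols, lengths(table)))
  keep <- nzchar(surface)
  surface <- surface[keep]; owner <- owner[keep]
  ## same (surface, owner) listed twice is harmless; a surface claimed by two
  ## owners is ambiguous and dropped
  pair_dup <- duplicated(paste0(surface, "\r", owner))
  surface <- surface[!pair_dup]; owner <- owner[!pair_dup]
  ambiguous <- unique(surface[duplicated(surface)])
  if (length(ambiguous) > 0L) {
    crmlit_log(sprintf("%d ambiguous surface forms dropped: %s",
                       length(ambiguous),
                       paste(utils::head(ambiguous, 10L), collapse = ", ")),
               stage = "lexicon")
    keep <- !(surface %in% ambiguous)
    surface <- surface[keep]; owner <- owner[keep]
  }
  new_lexicon(surface, owner, stoplist = character(), dropped = ambiguous)
}

new_lexicon <- function(surface, owner, stoplist, dropped = character()) {
  has_upper <- grepl("[A-Z]", surface)
  exact <- stats::setNames(owner[has_upper], surface[has_upper])
  lower <- stats::setNames(owner[!has_upper], tolower(surface[!has_upper]))
  max_len <- if (length(surface) == 0L) 0L else {
    max(vapply(surface, function(s) length(tokenize(s)$pieces), integer(1)))
  }
  structure(list(exact = exact, lower = lower, stoplist = stoplist,
                 max_pieces = max_len),
            class = "synonym_lexicon", dropped = dropped)
}

#' @export
print.synonym_lexicon <- function(x, ...) {
  cat(sprintf("<synonym_lexicon: %d surface forms (%d case-sensitive), %d stop words>\n",
              length(x$exact) + length(x$lower), length(x$exact),
              length(x$stoplist)))
  invisible(x)
}

#' Remove surface forms identical to common English words
#'
#' Fly gene synonyms such as "if" or "can" collide with ordinary words and
#' would flood the mention finder; entries whose lowercased form appears in
#' the stoplist are removed.
#'
#' @param lexicon A `synonym_lexicon`.
#' @param stoplist Character vector of lowercase words, or a path to a
#'   one-word-per-line file.
#' @return The filtered lexicon; attribute `"removed"` gives the number of
#'   entries removed.
#' @export
apply_stoplist <- function(lexicon, stoplist) {
  stopifnot(inherits(lexicon, "synonym_lexicon"))
  if (is.character(stoplist) && length(stoplist) == 1L && file.exists(stoplist)) {
    stoplist <- readLines(stoplist, warn = FALSE)
  }
  stoplist <- unique(trimws(stoplist))
  stoplist <- stoplist[nzchar(stoplist)]
  if (any(stoplist != tolower(stoplist))) {
    err_config("stoplist entries must be lowercase")
  }
  drop_exact <- tolower(names(lexicon$exact)) %in% stoplist
  drop_lower <- names(lexicon$lower) %in% stoplist
  n_removed <- sum(drop_exact) + sum(drop_lower)
  surface <- c(names(lexicon$exact)[!drop_exact], names(lexicon$lower)[!drop_lower])
  owner <- c(unname(lexicon$exact)[!drop_exact], unname(lexicon$lower)[!drop_lower])
  out <- new_lexicon(surface, owner, stoplist = sort(unique(c(lexicon$stoplist, stoplist))),
                     dropped = attr(lexicon, "dropped"))
  attr(out, "removed") <- n_removed
  out
}

lexicon_lookup <- function(lexicon, surface) {
  i <- match(surface, names(lexicon$exact))
  if (!is.na(i)) return(unname(lexicon$exact[i]))
  j <- match(tolower(surface), names(lexicon$lower))
  if (!is.na(j)) return(unname(lexicon$lower[j]))
  NULL
}

#' Find gene mentions in a paragraph
#'
#' Scans the paragraph's word-piece sequence for maximal token-boundary
#' matches of lexicon surface forms. Overlaps resolve longest-match-first,
#' then leftmost; matched pieces are consumed so mentions never overlap.
#' A match must align exactly with token boundaries, so "fly" never matches
#' inside "butterfly".
#'
#' @param paragraph A one-row data frame (or list) with `pmid`, `index`, and
#'   `text` as produced by [filter_sections()].
#' @param lexicon A `synonym_lexicon`.
#' @param tokens Optional pre-computed `token_seq` for `paragraph$text`.
#' @return Data frame of mentions: `symbol`, `surface`, `pmid`,
#'   `paragraph_index`, `token_start`, `token_end` (half-open piece span).
#' @export
find_mentions <- function(paragraph, lexicon, tokens = NULL) {
  stopifnot(inherits(lexicon, "synonym_lexicon"))
  text <- paragraph$text
  stopifnot_scalar_string(text, "paragraph$text")
  if (is.null(tokens)) tokens <- tokenize(text)
  n <- length(tokens$pieces)
  empty <- new_df(symbol = character(), surface = character(),
                  pmid = character(), paragraph_index = integer(),
                  token_start = integer(), token_end = integer())
  if (n == 0L || lexicon$max_pieces == 0L) return(empty)
  rows <- vector("list", n)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(lexicon$max_pieces, n - i + 1L), 1L)) {
      j <- i + len - 1L
      surface <- substring(text, tokens$start[i], tokens$end[j] - 1L)
      symbol <- lexicon_lookup(lexicon, surface)
      if (!is.null(symbol)) {
        rows[[i]] <- new_df(symbol = symbol, surface = surface,
                            pmid = paragraph$pmid %||% NA_character_,
                            paragraph_index = paragraph$index %||% NA_integer_,
                            token_start = i, token_end = j + 1L)
        i <- j + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
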