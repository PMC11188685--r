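## Word-piece tokenizer contract and the fixed-budget context window used to
## bound paragraph length around a gene mention.

#' Tokenize text into word pieces with character offsets
#'
#' The default desk-scale tokenizer splits text into alphanumeric runs and
#' single punctuation characters. Every piece carries its half-open character
#' span `[start, end)` into the source string, so a run of pieces can always
#' be mapped back to the exact source substring. Tokenization is
#' deterministic: the same text always yields the same pieces.
#'
#' @param text A single character string.
#' @return A `token_seq` object: list with `pieces` (character vector),
#'   `start` and `end` (integer character offsets, 1-based, `end` exclusive),
#'   and `text` (the source string).
#' @examples
#' ts <- tokenize("the sickie gene drives expression")
#' ts$pieces
#' @export
tokenize <- function(text) {
  stopifnot_scalar_string(text, "text")
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", text, perl = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) {
    return(new_token_seq(character(), integer(), integer(), text))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  pieces <- substring(text, start, start + len - 1L)
  new_token_seq(pieces, start, start + as.integer(len), text)
}

new_token_seq <- function(pieces, start, end, text) {
  structure(list(pieces = pieces, start = start, end = end, text = text),
            class = "token_seq")
}

#' @export
length.token_seq <- function(x) length(x$pieces)

#' @export
print.token_seq <- function(x, ...) {
  cat(sprintf("<token_seq: %d pieces over %d chars>\n",
              length(x$pieces), nchar(x$text)))
  invisible(x)
}

#' Map a token sequence back to its source substring
#'
#' Returns the source text spanned by the sequence's pieces (including any
#' whitespace between them), so `tokenize(detokenize(ts))` reproduces the
#' same pieces.
#'
#' @param ts A `token_seq`.
#' @return A character string ("" for an empty sequence).
#' @export
detokenize <- function(ts) {
  stopifnot(inherits(ts, "token_seq"))
  n <- length(ts$pieces)
  if (n == 0L) return("")
  substring(ts$text, ts$start[1L], ts$end[n] - 1L)
}

#' Clip a token sequence to a fixed word-piece budget around a mention
#'
#' Paragraphs longer than `budget` word pieces are reduced to the mention
#' plus up to `flank` pieces on each side. Short paragraphs pass through
#' unchanged. When the mention sits near an edge, the window shifts toward
#' the available side instead of padding, so the output keeps
#' `min(length(tokens), 2 * flank + span length)` pieces and always contains
#' the full mention. The mention's own pieces do not count against the
#' flanks, so a multi-piece name may make the window slightly exceed the
#' budget.
#'
#' @param tokens A `token_seq`.
#' @param span Integer vector `c(first, last)`: 1-based inclusive word-piece
#'   positions of the mention within `tokens`.
#' @param flank Pieces to keep on each side of the mention (default 256).
#' @param budget Length at or below which the sequence is returned unchanged
#'   (default 512).
#' @return A `token_seq`; its `span` attribute holds the mention's position
#'   in the returned sequence.
#' @export
window_around_mention <- function(tokens, span, flank = 256L, budget = 512L) {
  stopifnot(inherits(tokens, "token_seq"))
  n <- length(tokens$pieces)
  span <- as.integer(span)
  if (length(span) != 2L || span[1L] > span[2L] || span[1L] < 1L || span[2L] > n) {
    err_contract("mention span out of token bounds")
  }
  if (flank < 0L) err_contract("flank must be >= 0")
  span_len <- span[2L] - span[1L] + 1L
  if (budget < span_len) err_contract("budget smaller than the mention span")
  if (n <= budget) {
    out <- tokens
    attr(out, "span") <- span
    return(out)
  }
  want <- min(n, 2L * flank + span_len)
  lo <- span[1L] - flank
  lo <- max(1L, min(lo, n - want + 1L))
  hi <- lo + want - 1L
  idx <- lo:hi
  out <- new_token_seq(tokens$pieces[idx], tokens$start[idx], tokens$end[idx],
                       tokens$text)
  attr(out, "span") <- span - lo + 1L
  out
}
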