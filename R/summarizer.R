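## Step 4: aggregate per-paragraph label probabilities into per-article
## target-gene and regulatory-TF lists, plus the name-occurrence baseline.

#' Summarize labeled pairs into an article's gene lists
#'
#' A gene is assigned a role for the article when at least one of its
#' paragraph pairs clears the threshold for that label; equivalently, the
#' article-level score per label is the maximum of the gene's paragraph
#' probabilities. Genes with neither role are still listed with both flags
#' false.
#'
#' @param labeled_pairs Labeled pairs for a single article, as returned by
#'   [label_pair()] (must have columns `pmid`, `symbol`, `paragraph_index`,
#'   `target_gene_prob`, `tf_prob`).
#' @param threshold Decision threshold (default 0.7, >= rule).
#' @return An `article_summary` data frame: `pmid`, `symbol`, `target_gene`,
#'   `regulatory_tf`, `max_target_prob`, `max_tf_prob`,
#'   `supporting_target`/`supporting_tf` (semicolon-joined paragraph indices
#'   whose probability cleared the threshold).
#' @export
summarize_article <- function(labeled_pairs, threshold = 0.7) {
  empty <- new_df(pmid = character(), symbol = character(),
                  target_gene = logical(), regulatory_tf = logical(),
                  max_target_prob = numeric(), max_tf_prob = numeric(),
                  supporting_target = character(), supporting_tf = character())
  class(empty) <- c("article_summary", "data.frame")
  if (nrow(labeled_pairs) == 0L) return(empty)
  if (length(unique(labeled_pairs$pmid)) > 1L) {
    err_contract("summarize_article expects pairs from a single article")
  }
  out <- lapply(split(seq_len(nrow(labeled_pairs)), labeled_pairs$symbol),
                function(i) {
    g <- labeled_pairs[i, , drop = FALSE]
    sup <- function(p) paste(sort(g$paragraph_index[p >= threshold]), collapse = ";")
    new_df(pmid = g$pmid[1L], symbol = g$symbol[1L],
           target_gene = max(g$target_gene_prob) >= threshold,
           regulatory_tf = max(g$tf_prob) >= threshold,
           max_target_prob = max(g$target_gene_prob),
           max_tf_prob = max(g$tf_prob),
           supporting_target = sup(g$target_gene_prob),
           supporting_tf = sup(g$tf_prob))
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  class(out) <- c("article_summary", "data.frame")
  out
}

#' Name-occurrence-counting baseline
#'
#' The label-agnostic baseline: count how often each gene name occurs across
#' an article's (section-filtered) paragraphs and call the gene reported
#' when the count is strictly larger than the threshold. Sweeping the
#' threshold yields the baseline's ROC/PR curves; the same count score is
#' evaluated against both the target-gene and the TF truth.
#'
#' @param article_paragraphs Paragraph data frame for one article, filtered
#'   identically to the main pipeline.
#' @param lexicon A `synonym_lexicon`.
#' @param count_threshold Integer threshold (decision = count > threshold).
#' @param symbols Optional character vector: report exactly these symbols,
#'   with score 0 for genes never mentioned. Default: mentioned genes only.
#' @return Data frame `symbol`, `score` (occurrence count), `decision`.
#' @export
occurrence_baseline <- function(article_paragraphs, lexicon, count_threshold = 1L,
                                symbols = NULL) {
  stopifnot(inherits(lexicon, "synonym_lexicon"))
  counts <- integer(0)
  if (nrow(article_paragraphs) > 0L) {
    men <- lapply(seq_len(nrow(article_paragraphs)), function(r) {
      find_mentions(article_paragraphs[r, ], lexicon)
    })
    men <- do.call(rbind, men)
    if (nrow(men) > 0L) counts <- c(table(men$symbol))
  }
  if (!is.null(symbols)) {
    full <- stats::setNames(integer(length(symbols)), symbols)
    full[names(counts)[names(counts) %in% symbols]] <-
      counts[names(counts) %in% symbols]
    counts <- full
  }
  new_df(symbol = names(counts) %||% character(),
         score = as.integer(counts),
         decision = as.integer(counts) > count_threshold)
}
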