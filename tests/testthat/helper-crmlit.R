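## Shared fixture builders. Everything is constructed in code; no binary or
## downloaded fixtures.

make_records <- function(pmid, title = NULL, abstract = NULL) {
  data.frame(pmid = as.character(pmid),
             title = title %||% paste("title", pmid),
             abstract = abstract %||% paste("abstract", pmid),
             year = NA_integer_, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## minimal JATS document
jats_doc <- function(sections) {
  secs <- vapply(sections, function(s) {
    paste0("<sec><title>", s$title, "</title>",
           paste0("<p>", s$paragraphs, "</p>", collapse = ""), "</sec>")
  }, character(1))
  paste0("<article><body>", paste(secs, collapse = ""), "</body></article>")
}

tiny_lexicon <- function(table = list(sickie = c("sick"),
                                      cv = character(),
                                      `cv-2` = character(),
                                      gt7 = c("gt7syn"))) {
  load_synonyms(table)
}

para_df <- function(texts, pmid = "p1", section = "Results") {
  data.frame(pmid = pmid, section_title = section,
             index = seq_along(texts) - 1L, text = texts,
             stringsAsFactors = FALSE)
}

## hand-built labeled pair table (no model needed) for summarizer tests
labeled_pairs_df <- function(pmid, symbol, paragraph_index, tprob, fprob) {
  data.frame(pmid = pmid, symbol = symbol, paragraph_index = paragraph_index,
             target_gene_prob = tprob, tf_prob = fprob,
             stringsAsFactors = FALSE)
}

## abstracts where a cue token appears iff positive, plus background noise
separable_abstracts <- function(n, seed, cue = "enhancerassay",
                                p_positive = 0.4) {
  set.seed(seed)
  vocab <- sprintf("bg%03d", 1:80)
  label <- runif(n) < p_positive
  abstract <- vapply(seq_len(n), function(i) {
    bg <- paste(sample(vocab, 12, replace = TRUE), collapse = " ")
    if (label[i]) paste(bg, cue, paste(sample(vocab, 3), collapse = " ")) else bg
  }, character(1))
  list(records = make_records(sprintf("pm%04d", seq_len(n)),
                              title = "study", abstract = abstract),
       labels = label)
}

## mention-pair table with planted role cues, for labeler training tests
cue_pairs <- function(n, seed, p_target = 0.4, p_tf = 0.3,
                      target_cue = "drives-expression", tf_cue = "binds-enhancer",
                      cue_strength = 1, tf_false_cue = 0) {
  set.seed(seed)
  vocab <- sprintf("bg%03d", 1:80)
  tg <- runif(n) < p_target
  tf <- runif(n) < p_tf
  win <- vapply(seq_len(n), function(i) {
    parts <- c(sample(vocab, 8, replace = TRUE), "genex")
    if (tg[i] && runif(1) < cue_strength) parts <- c(parts, target_cue)
    if (tf[i] && runif(1) < cue_strength) parts <- c(parts, tf_cue)
    if (!tf[i] && runif(1) < tf_false_cue) parts <- c(parts, tf_cue)
    paste(sample(parts), collapse = " ")
  }, character(1))
  structure(data.frame(pmid = sprintf("a%03d", sample.int(40, n, replace = TRUE)),
                       symbol = "genex", paragraph_index = seq_len(n) - 1L,
                       section_title = "Results", window_text = win,
                       target_gene = tg, regulatory_tf = tf, weight = 1,
                       stringsAsFactors = FALSE),
            class = c("mention_pairs", "data.frame"))
}

## independent scalar-loop oracle for the weighted BCE loss
wbce_oracle <- function(probs, truths, p_c, w, eps = 1e-7) {
  total <- 0
  for (i in seq_len(nrow(probs))) {
    s <- 0
    for (c in 1:2) {
      L <- min(max(probs[i, c], eps), 1 - eps)
      s <- s + p_c[c] * truths[i, c] * log(L) + (1 - truths[i, c]) * log(1 - L)
    }
    total <- total - w[i] * s
  }
  total
}

## pairwise Mann-Whitney oracle for the ROC area
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## exhaustive best single axis-aligned split (decision stump oracle)
best_single_split_accuracy <- function(X, y) {
  y <- as.logical(y)
  best <- max(mean(y), mean(!y))  # constant classifiers
  for (j in seq_len(ncol(X))) {
    for (t in sort(unique(X[, j]))) {
      left <- X[, j] <= t
      for (sign in c(TRUE, FALSE)) {
        pred <- if (sign) left else !left
        best <- max(best, mean(pred == y))
      }
    }
  }
  best
}
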