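## Seeded synthetic corpora: abstracts, JATS full texts, synonym table,
## stoplist and ground truth, with the statistical structure the pipeline
## assumes (imbalanced CRM prevalence, planted mentions, role cues planted
## independently of mention frequency, decoy mentions in removable
## sections). Everything is written in the exact formats the corpus readers
## consume, so every stage is testable offline.

CRM_CUE <- "modular transcription regulation"
TOPIC_VOCAB <- c("enhancer", "promoter", "silencer", "genomic", "fragment",
                 "construct", "tissue", "embryo", "pattern", "assay")
TARGET_CUE <- "drives reporter expression of"
TF_CUE <- "binds the upstream element near"
STOPLIST_WORDS <- c("the", "of", "and", "in", "to", "a", "is", "was", "for",
                    "with", "if", "can", "not", "all", "on", "by", "at",
                    "an", "as", "we")

#' Configuration of a synthetic corpus
#'
#' The generator plants three separable signals: CRM-positive abstracts
#' carry a multiword CRM cue phrase (probability `cue_strength`) and a
#' tilted topical vocabulary; target-gene paragraphs carry a target cue
#' phrase and TF paragraphs a TF cue phrase adjacent to the gene mention
#' (each labeled gene gets at least one cue-bearing paragraph in a retained
#' section; further paragraphs carry the cue with probability
#' `cue_strength`). Role cues are planted independently of how often a gene
#' is mentioned, so name-occurrence counting cannot recover the roles.
#' Removable sections (Methods, Acknowledgements) receive decoy mentions
#' that must never reach the pair dataset.
#'
#' @param n_articles Number of articles.
#' @param positive_fraction CRM-related prevalence; the positive count is
#'   exact (`round(n_articles * positive_fraction)`). Default 0.1, emulating
#'   triage imbalance.
#' @param genes_per_article Integer range `c(min, max)` of genes mentioned
#'   per article.
#' @param cue_strength Probability that a role-bearing paragraph (beyond the
#'   guaranteed first) carries its cue phrase, and that a positive abstract
#'   carries the CRM cue.
#' @param leak_rate Probability that a negative abstract carries the CRM cue
#'   or a topic word.
#' @param distractor_vocab_size Background vocabulary size.
#' @param sections Section titles, including removable ones.
#' @param target_prevalence,tf_prevalence Per-gene role probabilities inside
#'   CRM-positive articles (independent draws; both may hold).
#' @param n_genes,synonyms_per_gene Lexicon size and synonyms per symbol.
#' @param stoplist_collision_fraction Fraction of genes given an extra
#'   synonym identical to a common English word (exercises the stoplist
#'   filter).
#' @param paragraphs_per_gene Range of paragraphs mentioning each gene.
#' @param seed Integer seed; corpora are byte-identical given the seed.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_articles = 100L, positive_fraction = 0.1,
                          genes_per_article = c(2L, 5L), cue_strength = 0.9,
                          leak_rate = 0.02, distractor_vocab_size = 500L,
                          sections = c("Introduction", "Results", "Discussion",
                                       "Materials and Methods", "Acknowledgements"),
                          target_prevalence = 0.6, tf_prevalence = 0.35,
                          n_genes = 120L, synonyms_per_gene = 2L,
                          stoplist_collision_fraction = 0.1,
                          paragraphs_per_gene = c(1L, 3L), seed = 1L) {
  cfg <- list(n_articles = as.integer(n_articles),
              positive_fraction = positive_fraction,
              genes_per_article = as.integer(genes_per_article),
              cue_strength = cue_strength, leak_rate = leak_rate,
              distractor_vocab_size = as.integer(distractor_vocab_size),
              sections = sections, target_prevalence = target_prevalence,
              tf_prevalence = tf_prevalence, n_genes = as.integer(n_genes),
              synonyms_per_gene = as.integer(synonyms_per_gene),
              stoplist_collision_fraction = stoplist_collision_fraction,
              paragraphs_per_gene = as.integer(paragraphs_per_gene),
              seed = as.integer(seed))
  probs <- c(positive_fraction, cue_strength, leak_rate, target_prevalence,
             tf_prevalence, stoplist_collision_fraction)
  if (any(probs < 0 | probs > 1)) err_config("probabilities must be in [0, 1]")
  if (cfg$genes_per_article[2L] > cfg$n_genes) {
    err_config("genes_per_article exceeds the lexicon size")
  }
  structure(cfg, class = "corpus_config")
}

words_of <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

## sample() with the surprising scalar behaviour removed
pick_one <- function(x) x[sample.int(length(x), 1L)]
pick_int <- function(range) {
  if (range[1L] == range[2L]) return(range[1L])
  sample(seq(range[1L], range[2L]), 1L)
}

draw_background <- function(vocab, n) paste(sample(vocab, n, replace = TRUE),
                                            collapse = " ")

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_jats <- function(path, sections) {
  body <- vapply(sections, function(s) {
    ps <- paste0("      <p>", xml_escape(s$paragraphs), "</p>", collapse = "\n")
    paste0("    <sec>\n      <title>", xml_escape(s$title), "</title>\n",
           ps, "\n    </sec>")
  }, character(1))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<article>", "  <body>", body, "  </body>", "</article>"),
             path)
}

#' Generate a synthetic corpus on disk
#'
#' Writes `abstracts.csv` (PubMed export layout), `fulltext/<pmid>.xml`
#' (JATS) for every CRM-positive article, `synonyms.tsv`, `stoplist.txt`,
#' and returns the ground truth. Same seed, same bytes.
#'
#' @param config A [corpus_config()].
#' @param dir Output directory (created).
#' @return A `synthetic_corpus`: list with `paths` (named file paths),
#'   `config`, and `truth` (list of data frames: `articles` with
#'   `pmid`/`is_crm`, `genes` with per-(pmid, gene) role labels, `mentions`
#'   with planted mention bookkeeping incl. decoys, and
#'   `stoplist_collisions`, the planted ambiguous synonyms).
#' @export
generate_corpus <- function(config = corpus_config(), dir = tempfile("corpus")) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ft_dir <- file.path(dir, "fulltext")
  dir.create(ft_dir, showWarnings = FALSE)

  n <- config$n_articles
  pmids <- sprintf("9%06d", seq_len(n))
  n_pos <- round(n * config$positive_fraction)
  is_crm <- rep(FALSE, n)
  is_crm[sample.int(n, n_pos)] <- TRUE

  distractors <- words_of("w", config$distractor_vocab_size)

  ## lexicon: symbols g###x, synonyms g###a, g###b, ...; a configurable
  ## fraction of genes gets one stoplist-colliding synonym
  symbols <- sprintf("g%03dx", seq_len(config$n_genes))
  synonyms <- lapply(seq_len(config$n_genes), function(i) {
    sprintf("g%03d%s", i, letters[seq_len(config$synonyms_per_gene)])
  })
  n_collide <- round(config$n_genes * config$stoplist_collision_fraction)
  collide_idx <- if (n_collide > 0L) sample.int(config$n_genes, n_collide) else integer(0)
  collide_words <- if (n_collide > 0L) {
    sample(STOPLIST_WORDS, n_collide, replace = n_collide > length(STOPLIST_WORDS))
  } else character(0)
  for (i in seq_along(collide_idx)) {
    synonyms[[collide_idx[i]]] <- c(synonyms[[collide_idx[i]]], collide_words[i])
  }
  syn_path <- file.path(dir, "synonyms.tsv")
  utils::write.table(
    new_df(symbol = symbols,
           synonyms = vapply(synonyms, paste, character(1), collapse = "|")),
    syn_path, sep = "\t", row.names = FALSE, quote = FALSE)
  stop_path <- file.path(dir, "stoplist.txt")
  writeLines(STOPLIST_WORDS, stop_path)

  ## abstracts
  titles <- character(n); abstracts <- character(n)
  for (a in seq_len(n)) {
    bg <- draw_background(distractors, 30L)
    if (is_crm[a]) {
      topical <- paste(sample(TOPIC_VOCAB, 6L, replace = TRUE), collapse = " ")
      cue <- if (stats::runif(1) < config$cue_strength) CRM_CUE else ""
      abstracts[a] <- trimws(paste("We studied", cue, topical, bg))
    } else {
      extra <- character(0)
      if (stats::runif(1) < config$leak_rate) extra <- c(extra, CRM_CUE)
      if (stats::runif(1) < config$leak_rate) extra <- c(extra, sample(TOPIC_VOCAB, 1L))
      abstracts[a] <- trimws(paste("We studied", paste(extra, collapse = " "), bg))
    }
    titles[a] <- paste("Drosophila genome study", pmids[a])
  }
  abs_path <- file.path(dir, "abstracts.csv")
  utils::write.csv(new_df(PMID = pmids, Title = titles, Abstract = abstracts,
                          Year = rep(2020L, n)),
                   abs_path, row.names = FALSE)

  ## full texts for positive articles, with ground truth bookkeeping
  gene_rows <- list(); mention_rows <- list()
  surface_pool <- lapply(seq_len(config$n_genes), function(i) {
    c(symbols[i], setdiff(synonyms[[i]], STOPLIST_WORDS))
  })
  for (a in which(is_crm)) {
    n_genes_a <- pick_int(config$genes_per_article)
    gene_idx <- sample.int(config$n_genes, n_genes_a)
    is_target <- stats::runif(n_genes_a) < config$target_prevalence
    is_tf <- stats::runif(n_genes_a) < config$tf_prevalence
    intro <- draw_background(distractors, 25L)
    results_paras <- character(0)
    para_meta <- list()
    for (g in seq_len(n_genes_a)) {
      n_par <- pick_int(config$paragraphs_per_gene)
      for (p in seq_len(n_par)) {
        surface <- pick_one(surface_pool[[gene_idx[g]]])
        lead <- draw_background(distractors, 6L)
        tail_bg <- draw_background(distractors, 6L)
        with_cue <- p == 1L || stats::runif(1) < config$cue_strength
        phrase <- surface
        cue_t <- is_target[g] && with_cue
        cue_f <- is_tf[g] && with_cue
        if (cue_t) phrase <- paste(TARGET_CUE, phrase)
        if (cue_f) phrase <- paste(phrase, TF_CUE, draw_background(distractors, 1L))
        results_paras <- c(results_paras, paste(lead, phrase, tail_bg))
        para_meta[[length(para_meta) + 1L]] <-
          new_df(pmid = pmids[a], symbol = symbols[gene_idx[g]],
                 surface = surface, section = "Results",
                 target_cue = cue_t, tf_cue = cue_f, decoy = FALSE)
      }
      gene_rows[[length(gene_rows) + 1L]] <-
        new_df(pmid = pmids[a], symbol = symbols[gene_idx[g]],
               target_gene = is_target[g], regulatory_tf = is_tf[g])
    }
    ## decoy mentions in removable sections
    decoy_gene <- sample.int(config$n_genes, 1L)
    methods <- paste(draw_background(distractors, 10L), symbols[decoy_gene],
                     draw_background(distractors, 10L))
    ack <- paste("We thank colleagues for", symbols[decoy_gene], "reagents")
    para_meta[[length(para_meta) + 1L]] <-
      new_df(pmid = pmids[a], symbol = symbols[decoy_gene],
             surface = symbols[decoy_gene], section = "Materials and Methods",
             target_cue = FALSE, tf_cue = FALSE, decoy = TRUE)
    para_meta[[length(para_meta) + 1L]] <-
      new_df(pmid = pmids[a], symbol = symbols[decoy_gene],
             surface = symbols[decoy_gene], section = "Acknowledgements",
             target_cue = FALSE, tf_cue = FALSE, decoy = TRUE)
    mention_rows <- c(mention_rows, para_meta)
    write_jats(file.path(ft_dir, paste0(pmids[a], ".xml")), list(
      list(title = "Introduction", paragraphs = intro),
      list(title = "Results", paragraphs = results_paras),
      list(title = "Discussion", paragraphs = draw_background(distractors, 20L)),
      list(title = "Materials and Methods", paragraphs = methods),
      list(title = "Acknowledgements", paragraphs = ack)
    ))
  }
  truth <- list(
    articles = new_df(pmid = pmids, is_crm = is_crm),
    genes = if (length(gene_rows)) do.call(rbind, gene_rows) else
      new_df(pmid = character(), symbol = character(),
             target_gene = logical(), regulatory_tf = logical()),
    mentions = if (length(mention_rows)) do.call(rbind, mention_rows) else
      new_df(pmid = character(), symbol = character(), surface = character(),
             section = character(), target_cue = logical(),
             tf_cue = logical(), decoy = logical()),
    stoplist_collisions = new_df(symbol = symbols[collide_idx],
                                 synonym = collide_words)
  )
  ta_path <- file.path(dir, "truth_articles.csv")
  tg_path <- file.path(dir, "truth_genes.csv")
  utils::write.csv(truth$articles, ta_path, row.names = FALSE)
  utils::write.csv(truth$genes, tg_path, row.names = FALSE)
  structure(list(
    paths = list(dir = dir, abstracts = abs_path, fulltext_dir = ft_dir,
                 synonyms = syn_path, stoplist = stop_path,
                 truth_articles = ta_path, truth_genes = tg_path),
    config = config, truth = truth
  ), class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus: %d articles (%d CRM-positive) in %s>\n",
              x$config$n_articles, sum(x$truth$articles$is_crm), x$paths$dir))
  invisible(x)
}

#' Plant controlled defects into a generated corpus
#'
#' Corrupts a synthetic corpus in place for robustness testing: blanks
#' abstracts, truncates full-text XML files into malformed documents, and
#' appends colliding synonym rows (an existing surface form claimed by a
#' second symbol). Returns the exact defect manifest so tests can assert
#' that the pipeline skips or drops precisely the planted defects.
#'
#' @param corpus A `synthetic_corpus`.
#' @param rates Named list of rates in `[0, 1]`: `missing_abstract` (of all
#'   articles), `malformed_xml` (of full-text files), `synonym_collision`
#'   (of lexicon symbols). Rate 0 leaves the corpus untouched.
#' @param seed Seed for choosing which items to corrupt.
#' @return The corpus with a `defects` element: per defect type, the
#'   affected identifiers.
#' @export
corruption_suite <- function(corpus,
                             rates = list(missing_abstract = 0,
                                          malformed_xml = 0,
                                          synonym_collision = 0),
                             seed = 1L) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  r <- function(k) rates[[k]] %||% 0
  if (any(vapply(c("missing_abstract", "malformed_xml", "synonym_collision"),
                 function(k) r(k) < 0 || r(k) > 1, logical(1)))) {
    err_config("corruption rates must be in [0, 1]")
  }
  set.seed(seed)
  defects <- list(missing_abstract = character(0),
                  malformed_xml = character(0),
                  synonym_collision = character(0))

  abs_df <- utils::read.csv(corpus$paths$abstracts, stringsAsFactors = FALSE,
                            colClasses = "character")
  n_blank <- round(r("missing_abstract") * nrow(abs_df))
  if (n_blank > 0L) {
    hit <- sample.int(nrow(abs_df), n_blank)
    abs_df$Abstract[hit] <- ""
    defects$missing_abstract <- abs_df$PMID[hit]
    utils::write.csv(abs_df, corpus$paths$abstracts, row.names = FALSE)
  }

  xmls <- list.files(corpus$paths$fulltext_dir, pattern = "\\.xml$",
                     full.names = TRUE)
  n_bad <- round(r("malformed_xml") * length(xmls))
  if (n_bad > 0L) {
    hit <- sample(xmls, n_bad)
    for (f in hit) writeLines("<article><body><sec><p>truncated", f)
    defects$malformed_xml <- sub("\\.xml$", "", basename(hit))
  }

  syn_df <- utils::read.delim(corpus$paths$synonyms, stringsAsFactors = FALSE,
                              colClasses = "character")
  n_coll <- round(r("synonym_collision") * nrow(syn_df))
  if (n_coll > 0L) {
    hit <- sample.int(nrow(syn_df), n_coll)
    extra <- new_df(symbol = sprintf("fake%03d", seq_len(n_coll)),
                    synonyms = syn_df$symbol[hit])
    utils::write.table(rbind(syn_df, extra), corpus$paths$synonyms,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    defects$synonym_collision <- syn_df$symbol[hit]
  }
  corpus$defects <- defects
  corpus
}
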