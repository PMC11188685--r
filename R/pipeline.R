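## End-to-end orchestration of the four steps, run configuration, and model
## persistence.

#' Pipeline run configuration
#'
#' Bundles input paths, thresholds, seeds and the trained models for one
#' end-to-end run. Unknown arguments are rejected so typos cannot silently
#' change a run; the configuration is serialized with every run manifest.
#'
#' @param abstracts Path to the PubMed abstract CSV.
#' @param synonyms Path to the synonym TSV (or a prebuilt lexicon).
#' @param stoplist Path to the stoplist file (or a character vector);
#'   `NULL` to skip stoplist filtering.
#' @param transport A `fulltext_transport`, or a directory path (wrapped in
#'   [local_dir_transport()]); `NULL` runs every article abstract-only.
#' @param triage_model A trained `triage_ensemble`.
#' @param labeler_model A trained `paragraph_labeler`.
#' @param keywords Keyword prefilter terms; `NULL` disables the filter.
#' @param step1_threshold,step3_threshold Decision thresholds (defaults 0.5
#'   and 0.7).
#' @param removal_titles Section titles dropped before pairing.
#' @param out_dir Output directory for the step CSVs and manifest.
#' @param column_map Optional CSV column remapping for
#'   [read_pubmed_csv()].
#' @return A `run_config` list.
#' @export
run_config <- function(abstracts, synonyms, stoplist = NULL, transport = NULL,
                       triage_model = NULL, labeler_model = NULL,
                       keywords = NULL, step1_threshold = 0.5,
                       step3_threshold = 0.7,
                       removal_titles = default_removal_titles(),
                       out_dir = tempfile("crmlit_run"), column_map = NULL) {
  structure(list(abstracts = abstracts, synonyms = synonyms,
                 stoplist = stoplist, transport = transport,
                 triage_model = triage_model, labeler_model = labeler_model,
                 keywords = keywords, step1_threshold = step1_threshold,
                 step3_threshold = step3_threshold,
                 removal_titles = removal_titles, out_dir = out_dir,
                 column_map = column_map),
            class = "run_config")
}

#' Run the four-step pipeline
#'
#' Step 1 classifies every abstract; Step 2 fetches full texts for the
#' triage-positive articles (an unavailable full text falls back to the
#' abstract as a single untitled paragraph; a malformed one is skipped with
#' a logged error); Step 3 builds and labels mention pairs; Step 4
#' summarizes per-article gene lists. Per-article failures are logged and
#' skipped, never aborting the batch. All outputs are written as CSVs via
#' [write_outputs()].
#'
#' @param config A [run_config()] with trained models.
#' @return Invisibly, a list with `manifest` (file manifest), `counts`
#'   (articles in, CRM-positive, full texts found, abstract-only, skipped,
#'   pairs labeled, genes summarized), and the three result data frames.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!inherits(config$triage_model, "triage_ensemble")) {
    err_config("run_config needs a trained triage_model")
  }
  if (!inherits(config$labeler_model, "paragraph_labeler")) {
    err_config("run_config needs a trained labeler_model")
  }
  records <- read_pubmed_csv(config$abstracts, config$column_map)
  n_in <- nrow(records)
  if (!is.null(config$keywords)) {
    records <- keyword_prefilter(records, config$keywords)
  }
  lexicon <- if (inherits(config$synonyms, "synonym_lexicon")) {
    config$synonyms
  } else load_synonyms(config$synonyms)
  if (!is.null(config$stoplist)) lexicon <- apply_stoplist(lexicon, config$stoplist)
  transport <- config$transport
  if (is.character(transport)) transport <- local_dir_transport(transport)

  ## Step 1
  model <- config$triage_model
  model$threshold <- config$step1_threshold
  step1 <- classify_article(model, records)
  positive <- step1$pmid[step1$decision]

  ## Steps 2-3 per article
  n_fulltext <- 0L; n_abstract_only <- 0L; n_skipped <- 0L
  para_list <- list()
  for (pm in positive) {
    rec <- records[records$pmid == pm, , drop = FALSE]
    paras <- tryCatch({
      ft <- if (is.null(transport)) NULL else fetch_fulltext(pm, transport)
      if (is.null(ft)) {
        crmlit_log("no full text available, using abstract only",
                   pmid = pm, stage = "step2")
        n_abstract_only <- n_abstract_only + 1L
        new_df(pmid = pm, section_title = "", index = 0L,
               text = rec$abstract[1L])
      } else {
        n_fulltext <- n_fulltext + 1L
        filter_sections(ft, config$removal_titles)
      }
    }, crmlit_error = function(e) {
      crmlit_log("skipped: ", conditionMessage(e), pmid = pm, stage = "step2")
      n_skipped <<- n_skipped + 1L
      NULL
    })
    if (!is.null(paras) && nrow(paras) > 0L) {
      para_list[[length(para_list) + 1L]] <- paras
    }
  }
  paragraphs <- if (length(para_list)) do.call(rbind, para_list) else
    new_df(pmid = character(), section_title = character(),
           index = integer(), text = character())

  pairs <- build_pair_dataset(paragraphs, lexicon, truth = NULL)
  labeled <- label_pair(config$labeler_model, pairs,
                        threshold = config$step3_threshold)

  ## Step 4
  summaries <- lapply(split(labeled, labeled$pmid), summarize_article,
                      threshold = config$step3_threshold)
  step4 <- if (length(summaries)) do.call(rbind, summaries) else
    summarize_article(labeled[0, , drop = FALSE])
  rownames(step4) <- NULL

  step3 <- new_df(pmid = labeled$pmid, gene = labeled$symbol,
                  paragraph_index = labeled$paragraph_index,
                  section = labeled$section_title,
                  target_gene_prob = labeled$target_gene_prob,
                  tf_prob = labeled$tf_prob,
                  target_gene = labeled$target_gene_label,
                  regulatory_tf = labeled$tf_label,
                  text = labeled$window_text)
  step4_out <- new_df(pmid = step4$pmid, gene = step4$symbol,
                      target_gene = step4$target_gene,
                      regulatory_tf = step4$regulatory_tf,
                      max_target_prob = step4$max_target_prob,
                      max_tf_prob = step4$max_tf_prob,
                      supporting_target = step4$supporting_target,
                      supporting_tf = step4$supporting_tf)
  manifest <- write_outputs(list(step1 = step1, step3 = step3,
                                 step4 = step4_out), config$out_dir)
  counts <- list(articles_in = n_in, classified = nrow(step1),
                 crm_positive = length(positive), fulltext = n_fulltext,
                 abstract_only = n_abstract_only, skipped = n_skipped,
                 pairs_labeled = nrow(step3),
                 genes_summarized = nrow(step4_out))
  jsonlite::write_json(counts, file.path(config$out_dir, "counts.json"),
                       auto_unbox = TRUE)
  invisible(list(manifest = manifest, counts = counts, step1 = step1,
                 step3 = step3, step4 = step4_out))
}

#' Save or load a trained model
#'
#' Versioned archive for `triage_ensemble` and `paragraph_labeler` objects.
#'
#' @param model A trained model.
#' @param path Archive path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("triage_ensemble", "paragraph_labeler"))) {
    err_contract("save_model handles triage_ensemble and paragraph_labeler objects")
  }
  saveRDS(list(format = "crmlit-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) err_io(sprintf("model archive not found: %s", path))
  obj <- readRDS(path)
  if (!identical(obj$format, "crmlit-model")) {
    err_format("not a crmlit model archive")
  }
  obj$model
}
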