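## Step 3: build (gene, article, paragraph) mention pairs, weight them, and
## train/apply the two-label (target gene / regulatory TF) comprehension
## model with a positive- and instance-weighted binary cross-entropy loss.

#' Build the mention-pair dataset
#'
#' One pair per non-duplicate (gene, paragraph) mention: the paragraph is
#' tokenized, mentions are found with the lexicon, duplicates within a
#' paragraph collapse onto the first occurrence, and the token window around
#' the mention is clipped to the word-piece budget. In training mode
#' (`truth` supplied), article-level ground truth labels every pair of that
#' gene in the article, pairs of unlabeled genes are down-sampled per
#' article to the article's count of target-gene-labeled pairs, and each
#' pair's instance weight is the reciprocal of the number of retained
#' paragraphs mentioning the same gene in the same article (so every gene in
#' an article contributes total weight 1). In inference mode (`truth =
#' NULL`) labels are NA, nothing is down-sampled, and weights are computed
#' over all pairs.
#'
#' @param paragraphs Data frame of section-filtered paragraphs (`pmid`,
#'   `section_title`, `index`, `text`), one or more articles.
#' @param lexicon A `synonym_lexicon`.
#' @param truth Optional article-level truth: data frame `pmid`, `symbol`,
#'   `target_gene`, `regulatory_tf`. Symbols absent from the lexicon are
#'   skipped with a warning.
#' @param neg_sampling_seed Seed for the per-article negative down-sampling.
#' @param flank,budget Word-piece window parameters (defaults 256 / 512).
#' @return A `mention_pairs` data frame: `pmid`, `symbol`, `paragraph_index`,
#'   `section_title`, `window_text`, `target_gene`, `regulatory_tf`,
#'   `weight`.
#' @export
build_pair_dataset <- function(paragraphs, lexicon, truth = NULL,
                               neg_sampling_seed = 1L,
                               flank = 256L, budget = 512L) {
  stopifnot(inherits(lexicon, "synonym_lexicon"))
  empty <- new_df(pmid = character(), symbol = character(),
                  paragraph_index = integer(), section_title = character(),
                  window_text = character(), target_gene = logical(),
                  regulatory_tf = logical(), weight = numeric())
  class(empty) <- c("mention_pairs", "data.frame")
  if (nrow(paragraphs) == 0L) return(empty)
  if (!is.null(truth) && nrow(truth) > 0L) {
    known <- vapply(truth$symbol, function(s) !is.null(lexicon_lookup(lexicon, s)),
                    logical(1))
    if (any(!known)) {
      warning(sprintf("truth symbols absent from lexicon skipped: %s",
                      paste(unique(truth$symbol[!known]), collapse = ", ")),
              call. = FALSE)
      truth <- truth[known, , drop = FALSE]
    }
  }
  ## deterministic paragraph processing order regardless of input order
  paragraphs <- paragraphs[order(paragraphs$pmid, paragraphs$index), , drop = FALSE]
  rows <- vector("list", nrow(paragraphs))
  for (r in seq_len(nrow(paragraphs))) {
    para <- paragraphs[r, ]
    tokens <- tokenize(para$text)
    men <- find_mentions(para, lexicon, tokens)
    if (nrow(men) == 0L) next
    men <- men[!duplicated(men$symbol), , drop = FALSE]  # first occurrence per gene
    win_text <- character(nrow(men))
    for (m in seq_len(nrow(men))) {
      win <- window_around_mention(tokens,
                                   c(men$token_start[m], men$token_end[m] - 1L),
                                   flank = flank, budget = budget)
      win_text[m] <- detokenize(win)
    }
    rows[[r]] <- new_df(pmid = men$pmid, symbol = men$symbol,
                        paragraph_index = men$paragraph_index,
                        section_title = rep(para$section_title, nrow(men)),
                        window_text = win_text)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL

  if (is.null(truth)) {
    pairs$target_gene <- NA
    pairs$regulatory_tf <- NA
  } else {
    key <- paste0(pairs$pmid, "\r", pairs$symbol)
    tkey <- paste0(truth$pmid, "\r", truth$symbol)
    hit <- match(key, tkey)
    pairs$target_gene <- !is.na(hit) & truth$target_gene[hit]
    pairs$regulatory_tf <- !is.na(hit) & truth$regulatory_tf[hit]
    ## a gene with neither role is unlabeled even when truth lists it
    labeled <- pairs$target_gene | pairs$regulatory_tf
    ## per-article negative down-sampling to the target-gene pair count
    set.seed(neg_sampling_seed)
    keep <- rep(TRUE, nrow(pairs))
    for (pm in unique(pairs$pmid)) {
      in_art <- pairs$pmid == pm
      n_target <- sum(in_art & pairs$target_gene)
      unlabeled <- which(in_art & !labeled)
      if (length(unlabeled) > n_target) {
        keep[setdiff(unlabeled, sample(unlabeled, n_target))] <- FALSE
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
  }
  grp <- paste0(pairs$pmid, "\r", pairs$symbol)
  pairs$weight <- 1 / as.numeric(table(grp)[grp])
  rownames(pairs) <- NULL
  class(pairs) <- c("mention_pairs", "data.frame")
  pairs
}

#' Label-specific positive weights for the comprehension loss
#'
#' The positive weight `p_c` for each label counteracts positive/negative
#' imbalance. In `"ratio"` mode it is the negative/positive pair-count ratio
#' on the training data; `"fixed"` mode returns configured constants
#' (defaults 1.39 for the target-gene label and 4.35 for the TF label).
#'
#' @param pairs A labeled `mention_pairs` data frame (ratio mode).
#' @param mode `"ratio"` or `"fixed"`.
#' @param fixed Named numeric of length 2 used in fixed mode.
#' @return A list `p_target`, `p_tf` of class `label_weights`.
#' @export
compute_label_weights <- function(pairs = NULL, mode = c("ratio", "fixed"),
                                  fixed = c(p_target = 1.39, p_tf = 4.35)) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    return(structure(list(p_target = unname(fixed[[1L]]), p_tf = unname(fixed[[2L]])),
                     class = "label_weights"))
  }
  ratio <- function(y, what) {
    npos <- sum(y); nneg <- sum(!y)
    if (npos == 0L || nneg == 0L) {
      err_config(sprintf("ratio mode needs positives and negatives for the %s label", what))
    }
    nneg / npos
  }
  structure(list(p_target = ratio(pairs$target_gene, "target-gene"),
                 p_tf = ratio(pairs$regulatory_tf, "TF")),
            class = "label_weights")
}

#' @export
print.label_weights <- function(x, ...) {
  cat(sprintf("<label_weights: p_target=%.4g, p_tf=%.4g>\n", x$p_target, x$p_tf))
  invisible(x)
}

#' Weighted binary cross-entropy loss
#'
#' The two-label loss minimized by the paragraph comprehension model. For
#' pair i with predicted probabilities `L_i` and truths `y_i`:
#' `-w_i * sum_c [ p_c * y_ci * log(L_i[c]) + (1 - y_ci) * log(1 - L_i[c]) ]`,
#' where `p_c` counteracts label imbalance and the instance weight `w_i`
#' (reciprocal of the gene's paragraph count within the article) removes the
#' article-length bias. Probabilities are clamped to `[eps, 1 - eps]` so the
#' loss stays finite at saturated outputs.
#'
#' @param probs n-by-2 matrix (or 2-vector) of predicted probabilities,
#'   columns = (target gene, regulatory TF).
#' @param truths n-by-2 matrix of 0/1 truths.
#' @param weights A `label_weights` (or numeric length 2: p_target, p_tf).
#' @param w Instance weights, length n (default all 1).
#' @param eps Clamp bound, default 1e-7.
#' @param reduction `"sum"` (default) or `"mean"` over pairs.
#' @return Nonnegative scalar loss.
#' @export
wbce_loss <- function(probs, truths, weights = compute_label_weights(mode = "fixed"),
                      w = NULL, eps = 1e-7, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  probs <- matrix(as.numeric(probs), ncol = 2L)
  truths <- matrix(as.numeric(truths), ncol = 2L)
  if (!all(dim(probs) == dim(truths))) err_contract("probs/truths dimension mismatch")
  if (is.null(w)) w <- rep(1, nrow(probs))
  if (length(w) != nrow(probs)) err_contract("instance weights length mismatch")
  if (any(w <= 0)) err_contract("instance weights must be positive")
  p_c <- if (inherits(weights, "label_weights")) {
    c(weights$p_target, weights$p_tf)
  } else as.numeric(weights)
  if (any(p_c <= 0)) err_contract("label weights must be positive")
  L <- pmin(pmax(probs, eps), 1 - eps)
  per <- -(sweep(truths * log(L), 2L, p_c, "*") + (1 - truths) * log(1 - L))
  total <- sum(w * rowSums(per))
  if (reduction == "mean") total / nrow(probs) else total
}

#' Training configuration for the paragraph comprehension model
#'
#' Defaults mirror the comprehension network's published recipe: 10 epochs,
#' batch size 32, linear warmup then cosine decay, dropout 0.1 throughout,
#' loss = weighted binary cross-entropy. `max_lr` is the desk-scale default
#' for the hashed encoder trained from scratch.
#'
#' @param epochs,batch_size,max_lr,hidden,dropout,seed Training
#'   hyperparameters.
#' @param weights_mode `"ratio"` (computed from the training pairs) or
#'   `"fixed"` (use `fixed_weights`).
#' @param fixed_weights Positive label weights used in fixed mode.
#' @param threshold Per-label decision threshold (default 0.7, >= rule).
#' @return A list of class `labeler_config`.
#' @export
labeler_config <- function(epochs = 10L, batch_size = 32L, max_lr = 0.05,
                           hidden = 64L, dropout = c(0.1, 0.1), seed = 1L,
                           weights_mode = c("ratio", "fixed"),
                           fixed_weights = c(p_target = 1.39, p_tf = 4.35),
                           threshold = 0.7) {
  cfg <- net_config(epochs = epochs, batch_size = batch_size, max_lr = max_lr,
                    schedule = "warmup_cosine", warmup_epochs = 1L,
                    hidden = hidden, dropout = dropout, seed = seed,
                    loss = "wbce")
  cfg$weights_mode <- match.arg(weights_mode)
  cfg$fixed_weights <- fixed_weights
  cfg$threshold <- threshold
  structure(cfg, class = "labeler_config")
}

#' Train the paragraph comprehension model
#'
#' Fits the two-label (target gene / regulatory TF) model on mention-pair
#' windows. The encoder's hashing stage is frozen; the projection and head
#' are trained with the weighted binary cross-entropy of [wbce_loss()],
#' using each pair's instance weight.
#'
#' @param pairs Labeled `mention_pairs` from [build_pair_dataset()].
#' @param encoder A text encoder (default [hash_encoder()]).
#' @param config A [labeler_config()].
#' @return A `paragraph_labeler` model.
#' @export
train_labeler <- function(pairs, encoder = hash_encoder(),
                          config = labeler_config()) {
  if (nrow(pairs) == 0L) err_data("no training pairs")
  if (any(is.na(pairs$target_gene))) err_data("training pairs must be labeled")
  if (config$epochs > 0L &&
      (all(pairs$target_gene) || !any(pairs$target_gene) ||
       all(pairs$regulatory_tf) || !any(pairs$regulatory_tf))) {
    err_data("each label needs positive and negative training pairs")
  }
  lw <- if (config$weights_mode == "ratio") {
    compute_label_weights(pairs, mode = "ratio")
  } else {
    compute_label_weights(mode = "fixed", fixed = config$fixed_weights)
  }
  cfg <- config
  cfg$label_weights <- c(lw$p_target, lw$p_tf)
  X <- encoder$encode(pairs$window_text)
  Y <- cbind(as.numeric(pairs$target_gene), as.numeric(pairs$regulatory_tf))
  fit <- fit_text_net(X, Y, cfg, w = pairs$weight)
  structure(list(encoder = encoder, params = fit$params,
                 loss_trace = fit$loss_trace, config = config,
                 label_weights = lw, threshold = config$threshold),
            class = "paragraph_labeler")
}

#' @export
print.paragraph_labeler <- function(x, ...) {
  cat(sprintf(paste0("<paragraph_labeler: encoder dim %d, hidden %d, ",
                     "p_target=%.3g, p_tf=%.3g, threshold %.2f>\n"),
              x$encoder$dim, x$config$hidden, x$label_weights$p_target,
              x$label_weights$p_tf, x$threshold))
  invisible(x)
}

#' Label mention pairs with a trained comprehension model
#'
#' Adds the two label probabilities and their thresholded decisions (a label
#' is set iff its probability >= the threshold; both, one or neither may be
#' set) to the pair table.
#'
#' @param model A `paragraph_labeler`.
#' @param pairs A `mention_pairs` data frame (or anything with a
#'   `window_text` column).
#' @param threshold Decision threshold, defaulting to the model's.
#' @return `pairs` with columns `target_gene_prob`, `tf_prob`,
#'   `target_gene_label`, `tf_label` appended.
#' @export
label_pair <- function(model, pairs, threshold = model$threshold) {
  if (!inherits(model, "paragraph_labeler")) {
    err_state("model is not a fitted paragraph_labeler")
  }
  if (nrow(pairs) == 0L) {
    pairs$target_gene_prob <- numeric(0)
    pairs$tf_prob <- numeric(0)
    pairs$target_gene_label <- logical(0)
    pairs$tf_label <- logical(0)
    return(pairs)
  }
  X <- model$encoder$encode(pairs$window_text)
  P <- net_probs(model$params, X, "wbce")
  pairs$target_gene_prob <- P[, 1L]
  pairs$tf_prob <- P[, 2L]
  pairs$target_gene_label <- P[, 1L] >= threshold
  pairs$tf_label <- P[, 2L] >= threshold
  pairs
}

#' @export
predict.paragraph_labeler <- function(object, newdata, threshold = object$threshold, ...) {
  label_pair(object, newdata, threshold)
}
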