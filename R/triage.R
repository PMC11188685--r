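## Step 1: abstract triage. Five base classifiers, each trained on all
## positives plus a bootstrap-sampled balanced negative subset, aggregated
## by AdaBoost over the base probabilities.

#' Plan balanced negative subsets for the bootstrap ensemble
#'
#' The positive class (CRM-related articles) is far rarer than the negative
#' pool, so each base classifier trains on every positive plus one balanced
#' negative subset sampled without replacement. Subsets may overlap across
#' folds but never repeat an id within one fold.
#'
#' @param positives Character or integer vector of positive record ids.
#' @param negatives Vector of negative record ids; must be at least as large
#'   as `subset_size`.
#' @param k Number of subsets / base classifiers (default 5).
#' @param seed Integer seed; plans are reproducible from it.
#' @param subset_size Size of each negative subset; defaults to
#'   `length(positives)` (balanced folds).
#' @return A `bootstrap_plan`: list with `k`, `subset_size`, `seed`, and
#'   `subsets` (list of k id vectors).
#' @export
sample_bootstrap_sets <- function(positives, negatives, k = 5L, seed = 1L,
                                  subset_size = length(positives)) {
  k <- as.integer(k)
  if (k < 1L) err_config("k must be >= 1")
  if (length(negatives) < subset_size) {
    err_data(sprintf(paste0("negative pool (%d) smaller than subset size (%d); ",
                            "pass a smaller subset_size"),
                     length(negatives), subset_size))
  }
  set.seed(seed)
  subsets <- lapply(seq_len(k), function(i) sample(negatives, subset_size))
  structure(list(k = k, subset_size = subset_size, seed = as.integer(seed),
                 subsets = subsets),
            class = "bootstrap_plan")
}

#' @export
print.bootstrap_plan <- function(x, ...) {
  cat(sprintf("<bootstrap_plan: %d subsets of %d negatives (seed %d)>\n",
              x$k, x$subset_size, x$seed))
  invisible(x)
}

#' Training configuration for one triage base classifier
#'
#' Defaults mirror the triage network's published training recipe: 3 epochs,
#' batch size 16, cosine learning-rate decay, dropout 0.1 on the encoder
#' part and 0.4 on the final layer, categorical cross-entropy loss, adaptive
#' (Adam) optimization. `max_lr` is the desk-scale default for the hashed
#' encoder trained from scratch.
#'
#' @param epochs,batch_size,max_lr,hidden,dropout,seed Training
#'   hyperparameters; see Details in the package vignette.
#' @return A list of class `triage_config`.
#' @export
triage_config <- function(epochs = 3L, batch_size = 16L, max_lr = 0.05,
                          hidden = 64L, dropout = c(0.1, 0.4), seed = 1L) {
  structure(net_config(epochs = epochs, batch_size = batch_size,
                       max_lr = max_lr, schedule = "cosine", hidden = hidden,
                       dropout = dropout, seed = seed, loss = "softmax_ce"),
            class = "triage_config")
}

triage_text <- function(records) paste(records$title, records$abstract)

#' Train one base abstract classifier
#'
#' Encodes title + abstract with the encoder contract and fits a two-class
#' softmax head on top; the positive-class probability is the classifier's
#' output.
#'
#' @param records Abstract data frame (`pmid`, `title`, `abstract`).
#' @param labels Logical (or 0/1) vector: TRUE for CRM-related articles.
#' @param encoder A text encoder (default [hash_encoder()]).
#' @param config A [triage_config()].
#' @return A `base_classifier` with a `predict()` method returning
#'   positive-class probabilities.
#' @export
train_base_classifier <- function(records, labels, encoder = hash_encoder(),
                                  config = triage_config()) {
  labels <- as.logical(labels)
  if (length(labels) != nrow(records)) err_contract("labels must match records")
  if (length(unique(labels)) < 2L && config$epochs > 0L) {
    err_data("training set must contain both classes")
  }
  X <- encoder$encode(triage_text(records))
  Y <- cbind(1 - labels, as.numeric(labels))
  fit <- fit_text_net(X, Y, config)
  structure(list(encoder = encoder, params = fit$params,
                 loss_trace = fit$loss_trace, config = config),
            class = "base_classifier")
}

#' @export
predict.base_classifier <- function(object, newdata, ...) {
  texts <- if (is.data.frame(newdata)) triage_text(newdata) else newdata
  X <- object$encoder$encode(texts)
  unname(net_probs(object$params, X, "softmax_ce")[, 2L])
}

#' @export
print.base_classifier <- function(x, ...) {
  cat(sprintf("<base_classifier: encoder dim %d, hidden %d, %d epochs>\n",
              x$encoder$dim, x$config$hidden, x$config$epochs))
  invisible(x)
}

#' Train the probability aggregator
#'
#' Fits the boosted-tree model that maps the k base-classifier probabilities
#' to the final article probability. Must be trained on data the base
#' classifiers never saw (the "ensemble" split) to avoid leakage.
#'
#' @param base_probs n-by-k matrix of base probabilities.
#' @param labels Length-n logical/binary labels.
#' @param config An [aggregator_config()].
#' @return An `adaboost_model`.
#' @export
train_aggregator <- function(base_probs, labels, config = aggregator_config()) {
  base_probs <- as.matrix(base_probs)
  if (nrow(base_probs) < 10L) {
    err_data("aggregator needs at least 10 ensemble-split examples")
  }
  if (nrow(base_probs) != length(labels)) err_contract("labels must match rows")
  fit_adaboost(base_probs, as.numeric(as.logical(labels)), config)
}

#' Train the full triage ensemble
#'
#' Draws `k` balanced bootstrap folds from the negative pool, trains one
#' base classifier per fold (each fold = all positives + its negative
#' subset), then fits the AdaBoost aggregator on the held-out ensemble
#' split's base probabilities.
#'
#' @param train_records,train_labels The base-training split.
#' @param ensemble_records,ensemble_labels The held-out split used only to
#'   fit the aggregator.
#' @param k Number of base classifiers (default 5).
#' @param encoder Text encoder shared by all bases.
#' @param config A [triage_config()]; base i trains with seed
#'   `config$seed + i`.
#' @param aggregator `"adaboost"` (default) or `"identity"` (mean of base
#'   probabilities; with k = 1 the ensemble reduces to its single base).
#' @param aggregator_cfg An [aggregator_config()].
#' @param threshold Decision threshold on the final probability (default
#'   0.5; decisions use the >= rule).
#' @param seed Seed for the bootstrap plan.
#' @return A `triage_ensemble` model.
#' @export
train_triage_ensemble <- function(train_records, train_labels,
                                  ensemble_records, ensemble_labels,
                                  k = 5L, encoder = hash_encoder(),
                                  config = triage_config(),
                                  aggregator = c("adaboost", "identity"),
                                  aggregator_cfg = aggregator_config(),
                                  threshold = 0.5, seed = 1L) {
  aggregator <- match.arg(aggregator)
  train_labels <- as.logical(train_labels)
  pos <- which(train_labels); neg <- which(!train_labels)
  plan <- sample_bootstrap_sets(pos, neg, k = k, seed = seed)
  bases <- lapply(seq_len(k), function(i) {
    idx <- c(pos, plan$subsets[[i]])
    cfg <- config; cfg$seed <- config$seed + i
    train_base_classifier(train_records[idx, , drop = FALSE],
                          train_labels[idx], encoder, cfg)
  })
  base_probs <- vapply(bases, predict, numeric(nrow(ensemble_records)),
                       newdata = ensemble_records)
  base_probs <- matrix(base_probs, ncol = k)
  agg <- if (aggregator == "adaboost") {
    train_aggregator(base_probs, ensemble_labels, aggregator_cfg)
  } else NULL
  structure(list(bases = bases, aggregator = agg, k = k,
                 threshold = threshold, plan = plan),
            class = "triage_ensemble")
}

#' @export
print.triage_ensemble <- function(x, ...) {
  cat(sprintf("<triage_ensemble: %d base classifiers, %s aggregator, threshold %.2f>\n",
              x$k, if (is.null(x$aggregator)) "identity" else "AdaBoost",
              x$threshold))
  invisible(x)
}

#' Classify abstracts with a trained triage ensemble
#'
#' @param model A `triage_ensemble`.
#' @param records Abstract data frame.
#' @return Data frame `pmid`, `probability`, `decision` (probability >=
#'   threshold). Records with an empty abstract get probability NA and
#'   decision FALSE, with a logged warning.
#' @export
classify_article <- function(model, records) {
  if (!inherits(model, "triage_ensemble")) err_state("model is not a fitted triage_ensemble")
  usable <- nzchar(trimws(records$abstract))
  if (any(!usable)) {
    for (p in records$pmid[!usable]) {
      crmlit_log("empty abstract, excluded from classification",
                 pmid = p, stage = "step1")
    }
  }
  prob <- rep(NA_real_, nrow(records))
  if (any(usable)) {
    sub <- records[usable, , drop = FALSE]
    base_probs <- vapply(model$bases, predict, numeric(nrow(sub)), newdata = sub)
    base_probs <- matrix(base_probs, ncol = model$k)
    prob[usable] <- if (is.null(model$aggregator)) {
      rowMeans(base_probs)
    } else {
      predict_adaboost(model$aggregator, base_probs)
    }
  }
  new_df(pmid = records$pmid, probability = prob,
         decision = !is.na(prob) & prob >= model$threshold)
}
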