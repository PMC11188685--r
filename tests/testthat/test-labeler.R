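test_that("build_pair_dataset weights pairs by per-gene paragraph counts", {
  lex <- load_synonyms(list(ga = character(), gb = character(), gc = character()))
  paras <- para_df(c("ga here", "ga again", "ga third", "ga fourth", "gb once"))
  truth <- data.frame(pmid = "p1", symbol = c("ga", "gb"),
                      target_gene = c(TRUE, FALSE),
                      regulatory_tf = c(FALSE, TRUE))
  pairs <- build_pair_dataset(paras, lex, truth)
  ga <- pairs[pairs$symbol == "ga", ]
  expect_equal(nrow(ga), 4)
  expect_equal(ga$weight, rep(0.25, 4))
  expect_true(all(ga$target_gene) && !any(ga$regulatory_tf))
  expect_true(all(pairs$weight[pairs$symbol == "gb"] == 1))
  ## per-(article, gene) weights sum to one
  sums <- tapply(pairs$weight, paste(pairs$pmid, pairs$symbol), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("unlabeled pairs are down-sampled to the target-gene pair count", {
  syms <- c("tg", sprintf("u%02d", 1:10))
  lex <- load_synonyms(setNames(replicate(11, character(), simplify = FALSE), syms))
  texts <- c(rep("tg mentioned here", 3), paste(sprintf("u%02d", 1:10), "alone"))
  truth <- data.frame(pmid = "p1", symbol = "tg",
                      target_gene = TRUE, regulatory_tf = FALSE)
  pairs <- build_pair_dataset(para_df(texts), lex, truth, neg_sampling_seed = 4)
  expect_equal(sum(pairs$target_gene), 3)
  expect_equal(sum(!pairs$target_gene & !pairs$regulatory_tf), 3)
  ## reproducible sampling
  pairs2 <- build_pair_dataset(para_df(texts), lex, truth, neg_sampling_seed = 4)
  expect_identical(pairs$symbol, pairs2$symbol)
  ## fewer unlabeled than targets: all kept
  texts2 <- c(rep("tg mentioned here", 3), "u01 alone")
  pairs3 <- build_pair_dataset(para_df(texts2), lex, truth)
  expect_equal(sum(!pairs3$target_gene), 1)
})

test_that("inference mode keeps all pairs unlabeled and unsampled", {
  lex <- load_synonyms(list(ga = character()))
  pairs <- build_pair_dataset(para_df("nothing relevant"), lex)
  expect_equal(nrow(pairs), 0)
  pairs <- build_pair_dataset(para_df(c("ga one", "ga two")), lex)
  expect_equal(nrow(pairs), 2)
  expect_true(all(is.na(pairs$target_gene)))
  expect_equal(pairs$weight, c(0.5, 0.5))
})

test_that("truth symbols missing from the lexicon are skipped with a warning", {
  lex <- load_synonyms(list(ga = character()))
  truth <- data.frame(pmid = "p1", symbol = c("ga", "ghost"),
                      target_gene = TRUE, regulatory_tf = FALSE)
  expect_warning(pairs <- build_pair_dataset(para_df("ga here"), lex, truth),
                 "ghost")
  expect_equal(nrow(pairs), 1)
})

test_that("pair construction is invariant to paragraph input order", {
  lex <- load_synonyms(list(ga = character(), gb = character()))
  paras <- para_df(c("ga one", "gb two", "ga three", "filler text"))
  truth <- data.frame(pmid = "p1", symbol = c("ga", "gb"),
                      target_gene = c(TRUE, TRUE), regulatory_tf = c(FALSE, TRUE))
  p1 <- build_pair_dataset(paras, lex, truth, neg_sampling_seed = 2)
  p2 <- build_pair_dataset(paras[c(3, 1, 4, 2), ], lex, truth, neg_sampling_seed = 2)
  key <- function(p) p[order(p$symbol, p$paragraph_index),
                       c("symbol", "paragraph_index", "target_gene",
                         "regulatory_tf", "weight")]
  expect_equal(key(p1), key(p2), ignore_attr = TRUE)
})

test_that("compute_label_weights implements ratio and fixed modes", {
  pairs <- data.frame(target_gene = rep(c(TRUE, FALSE), each = 50),
                      regulatory_tf = rep(c(TRUE, FALSE), c(10, 90)))
  lw <- compute_label_weights(pairs, mode = "ratio")
  expect_equal(lw$p_target, 1.0)
  expect_equal(lw$p_tf, 9.0)

  fixed <- compute_label_weights(mode = "fixed")
  expect_equal(fixed$p_target, 1.39)
  expect_equal(fixed$p_tf, 4.35)

  bad <- data.frame(target_gene = rep(FALSE, 10), regulatory_tf = rep(TRUE, 10))
  expect_error(compute_label_weights(bad, mode = "ratio"),
               class = "crmlit_config_error")
})

test_that("wbce_loss matches its closed forms and the scalar-loop oracle", {
  ## perfect prediction: loss ~ 0
  expect_lt(wbce_loss(cbind(1, 1), cbind(1, 1), c(2, 3), w = 5), 1e-5)

  ## single effective label: -log(0.5)
  loss <- wbce_loss(cbind(0.5, 1e-7), cbind(1, 0), c(1, 1), w = 1)
  expect_equal(loss, -log(0.5), tolerance = 1e-6)

  ## random batches match an independently coded scalar loop to 1e-9
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(1:20, 1)
    probs <- matrix(runif(n * 2), n, 2)
    truths <- matrix(rbinom(n * 2, 1, 0.5), n, 2)
    p_c <- runif(2, 0.5, 5)
    w <- runif(n, 0.1, 2)
    expect_equal(wbce_loss(probs, truths, p_c, w),
                 wbce_oracle(probs, truths, p_c, w), tolerance = 1e-9)
    expect_gte(wbce_loss(probs, truths, p_c, w), 0)
  }

  ## with p_c = 1 and w = 1 it is the standard summed BCE
  set.seed(14)
  probs <- matrix(runif(20), 10, 2); truths <- matrix(rbinom(20, 1, 0.5), 10, 2)
  bce <- -sum(truths * log(probs) + (1 - truths) * log(1 - probs))
  expect_equal(wbce_loss(probs, truths, c(1, 1)), bce, tolerance = 1e-9)

  ## reduction and contract errors
  expect_equal(wbce_loss(probs, truths, c(1, 1), reduction = "mean") * 10,
               wbce_loss(probs, truths, c(1, 1)), tolerance = 1e-12)
  expect_error(wbce_loss(cbind(0.5, 0.5), cbind(1, 0, 1, 0), c(1, 1)),
               class = "crmlit_contract_error")
  expect_error(wbce_loss(probs, truths, c(1, 1), w = rep(-1, 10)),
               class = "crmlit_contract_error")
})

test_that("the labeler recovers planted role cues", {
  pairs <- cue_pairs(400, seed = 5)
  model <- train_labeler(pairs, config = labeler_config(epochs = 15, seed = 5))
  out <- label_pair(model, pairs, threshold = 0.5)
  cc_t <- list(tp = sum(out$target_gene_label & pairs$target_gene),
               fp = sum(out$target_gene_label & !pairs$target_gene),
               tn = sum(!out$target_gene_label & !pairs$target_gene),
               fn = sum(!out$target_gene_label & pairs$target_gene))
  cc_f <- list(tp = sum(out$tf_label & pairs$regulatory_tf),
               fp = sum(out$tf_label & !pairs$regulatory_tf),
               tn = sum(!out$tf_label & !pairs$regulatory_tf),
               fn = sum(!out$tf_label & pairs$regulatory_tf))
  macro_f1 <- (prf_metrics(cc_t)$f1 + prf_metrics(cc_f)$f1) / 2
  expect_gte(macro_f1, 0.9)
})

test_that("scaling all instance weights does not change the fitted predictions", {
  pairs <- cue_pairs(150, seed = 6)
  doubled <- pairs
  doubled$weight <- pairs$weight * 2
  cfg <- labeler_config(epochs = 5, seed = 6)
  m1 <- train_labeler(pairs, config = cfg)
  m2 <- train_labeler(doubled, config = cfg)
  p1 <- label_pair(m1, pairs)
  p2 <- label_pair(m2, pairs)
  expect_equal(p1$target_gene_prob, p2$target_gene_prob, tolerance = 1e-3)
  expect_equal(p1$tf_prob, p2$tf_prob, tolerance = 1e-3)
})

test_that("a large TF positive weight raises TF recall when positives are scarce", {
  ## the weighting matters where the evidence conflicts: TF positives are
  ## rare (8%) and a quarter of the negatives carry the same cue, so the
  ## unweighted optimum calls cue-bearing windows negative; a small
  ## background vocabulary keeps the windows non-memorizable
  mk <- function(n, seed, p_tf = 0.08, false_cue = 0.25) {
    set.seed(seed)
    vocab <- sprintf("bg%02d", 1:10)
    tf <- runif(n) < p_tf
    win <- vapply(seq_len(n), function(i) {
      parts <- c(sample(vocab, 4, replace = TRUE), "genex")
      if (tf[i] || runif(1) < false_cue) parts <- c(parts, "binds-enhancer")
      if (runif(1) < 0.4) parts <- c(parts, "drives-expression")
      paste(sample(parts), collapse = " ")
    }, character(1))
    structure(data.frame(pmid = "a", symbol = "genex",
                         paragraph_index = seq_len(n) - 1L, section_title = "R",
                         window_text = win,
                         target_gene = grepl("drives-expression", win),
                         regulatory_tf = tf, weight = 1,
                         stringsAsFactors = FALSE),
              class = c("mention_pairs", "data.frame"))
  }
  train <- mk(600, seed = 7)
  test <- mk(600, seed = 77)
  recall_tf <- function(ptf) {
    cfg <- labeler_config(epochs = 8, seed = 7, weights_mode = "fixed",
                          fixed_weights = c(1, ptf))
    out <- label_pair(train_labeler(train, config = cfg), test, threshold = 0.5)
    sum(out$tf_label & test$regulatory_tf) / sum(test$regulatory_tf)
  }
  expect_gt(recall_tf(12), recall_tf(1))
})

test_that("label_pair applies the >= threshold rule per label", {
  pairs <- cue_pairs(60, seed = 8)
  model <- train_labeler(pairs, config = labeler_config(epochs = 10, seed = 8))
  out <- label_pair(model, pairs)
  expect_identical(out$target_gene_label, out$target_gene_prob >= 0.7)
  expect_identical(out$tf_label, out$tf_prob >= 0.7)
  ## tie: threshold set to an observed probability flags that pair
  t0 <- out$target_gene_prob[1]
  out2 <- label_pair(model, pairs, threshold = t0)
  expect_true(out2$target_gene_label[1])
  ## both labels can be set simultaneously
  both <- out$target_gene_prob >= 0.5 & out$tf_prob >= 0.5
  expect_true(any(both[pairs$target_gene & pairs$regulatory_tf]))

  expect_error(label_pair(structure(list(), class = "lm"), pairs),
               class = "crmlit_state_error")
  expect_error(train_labeler(pairs[0, ]), class = "crmlit_data_error")
})
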