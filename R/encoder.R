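## Text encoder contract and the small trainable network used by both the
## abstract triage base classifiers and the paragraph comprehension model.
##
## The encoder contract: any object with fields `dim` (integer) and
## `encode(texts)` returning a numeric matrix with one row per text. The
## default desk-scale encoder hashes bag-of-n-grams counts into a fixed
## width; a transformer adapter satisfying the same contract can be dropped
## in without touching the training code.

#' Hashed bag-of-n-grams text encoder
#'
#' Produces a fixed-length vector per text (the analog of a sequence
#' encoder's pooled CLS vector) by hashing lowercased word unigrams and
#' bigrams into `dim` buckets, accumulating counts, applying `log1p` and
#' L2-normalizing. Hashing is deterministic, so encoding requires no fitted
#' vocabulary and no downloads.
#'
#' @param dim Number of hash buckets (output width). The default 2048
#'   keeps hash collisions rare for desk-scale vocabularies.
#' @param ngram Maximum n-gram order (1 = unigrams only), default 2.
#' @return A `text_encoder` object with `$dim` and `$encode(texts)`.
#' @export
hash_encoder <- function(dim = 2048L, ngram = 2L) {
  dim <- as.integer(dim); ngram <- as.integer(ngram)
  if (dim < 2L) err_config("encoder dim must be >= 2")
  cache <- new.env(parent = emptyenv())
  hash_one <- function(s) {
    h <- cache[[s]]
    if (!is.null(h)) return(h)
    v <- 0
    for (b in utf8ToInt(s)) v <- (v * 131 + b) %% 2147483647
    h <- as.integer(v %% dim) + 1L
    cache[[s]] <- h
    h
  }
  encode <- function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (r in seq_along(texts)) {
      toks <- tolower(tokenize(texts[[r]])$pieces)
      if (length(toks) == 0L) next
      grams <- toks
      if (ngram >= 2L && length(toks) >= 2L) {
        for (k in 2:min(ngram, length(toks))) {
          grams <- c(grams, paste(
            utils::head(toks, -(k - 1L)),
            utils::tail(toks, -(k - 1L)), sep = "_"))
        }
      }
      idx <- vapply(grams, hash_one, integer(1), USE.NAMES = FALSE)
      tab <- tabulate(idx, nbins = dim)
      v <- log1p(tab)
      nrm <- sqrt(sum(v * v))
      if (nrm > 0) v <- v / nrm
      out[r, ] <- v
    }
    out
  }
  structure(list(dim = dim, ngram = ngram, encode = encode),
            class = "text_encoder")
}

#' @export
print.text_encoder <- function(x, ...) {
  cat(sprintf("<text_encoder: hashed bag-of-%d-grams, dim=%d>\n", x$ngram, x$dim))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Dense head: encoded vector -> tanh hidden layer -> 2 scores.
## The hashing stage is the frozen lower block; the projection W0 is the
## tunable upper block; W1 is the task head. Trained with Adam and a cosine
## (optionally warmup-then-cosine) learning-rate schedule.

net_config <- function(epochs, batch_size, max_lr, min_lr = 1e-7,
                       schedule = c("cosine", "warmup_cosine"),
                       warmup_epochs = 1L, hidden = 64L,
                       dropout = c(0.1, 0.1), seed = 1L,
                       loss = c("softmax_ce", "wbce"),
                       label_weights = c(1, 1)) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       max_lr = max_lr, min_lr = min_lr, schedule = match.arg(schedule),
       warmup_epochs = as.integer(warmup_epochs), hidden = as.integer(hidden),
       dropout = dropout, seed = as.integer(seed), loss = match.arg(loss),
       label_weights = label_weights)
}

net_init <- function(d, h, seed) {
  set.seed(seed)
  list(W0 = matrix(stats::rnorm(d * h, sd = 0.05), d, h),
       b0 = numeric(h),
       W1 = matrix(stats::rnorm(h * 2L, sd = 0.05), h, 2L),
       b1 = numeric(2L))
}

net_forward <- function(params, X) {
  H <- tanh(sweep(X %*% params$W0, 2L, params$b0, "+"))
  S <- sweep(H %*% params$W1, 2L, params$b1, "+")
  list(H = H, S = S)
}

net_probs <- function(params, X, loss) {
  S <- net_forward(params, X)$S
  if (loss == "softmax_ce") {
    m <- pmax(S[, 1L], S[, 2L])
    e1 <- exp(S[, 1L] - m); e2 <- exp(S[, 2L] - m)
    cbind(neg = e1 / (e1 + e2), pos = e2 / (e1 + e2))
  } else {
    1 / (1 + exp(-S))
  }
}

lr_at <- function(step, total, cfg) {
  if (cfg$schedule == "warmup_cosine") {
    warm <- max(1L, round(total * cfg$warmup_epochs / max(1L, cfg$epochs)))
    if (step <= warm) return(cfg$max_lr * step / warm)
    frac <- (step - warm) / max(1L, total - warm)
    return(cfg$min_lr + (cfg$max_lr - cfg$min_lr) * 0.5 * (1 + cos(pi * frac)))
  }
  cfg$max_lr * 0.5 * (1 + cos(pi * (step - 1L) / max(1L, total)))
}

## X: n x d encoded inputs; Y: n x 2 (one-hot for softmax_ce, independent
## binary labels for wbce); w: per-instance weights (wbce only).
fit_text_net <- function(X, Y, cfg, w = NULL) {
  n <- nrow(X); d <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  params <- net_init(d, cfg$hidden, cfg$seed)
  state <- lapply(params, function(p) list(m = p * 0, v = p * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  total <- cfg$epochs * steps_per_epoch
  trace <- numeric(cfg$epochs)
  p_c <- cfg$label_weights
  if (total > 0L) set.seed(cfg$seed + 1L)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (bi in seq_len(steps_per_epoch)) {
      step <- step + 1L
      idx <- ord[(((bi - 1L) * cfg$batch_size) + 1L):min(bi * cfg$batch_size, n)]
      B <- length(idx)
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      wb <- w[idx]
      if (cfg$dropout[1L] > 0) {
        mask0 <- matrix(stats::rbinom(B * d, 1L, 1 - cfg$dropout[1L]), B, d) /
          (1 - cfg$dropout[1L])
        Xb <- Xb * mask0
      }
      H <- tanh(sweep(Xb %*% params$W0, 2L, params$b0, "+"))
      Hd <- H
      if (cfg$dropout[2L] > 0) {
        mask1 <- matrix(stats::rbinom(B * cfg$hidden, 1L, 1 - cfg$dropout[2L]),
                        B, cfg$hidden) / (1 - cfg$dropout[2L])
        Hd <- H * mask1
      }
      S <- sweep(Hd %*% params$W1, 2L, params$b1, "+")
      if (cfg$loss == "softmax_ce") {
        m <- pmax(S[, 1L], S[, 2L])
        E <- exp(S - m)
        P <- E / rowSums(E)
        loss <- -sum(log(pmax(rowSums(P * Yb), 1e-12))) / B
        dS <- (P - Yb) / B
      } else {
        L <- 1 / (1 + exp(-S))
        Lc <- pmin(pmax(L, 1e-7), 1 - 1e-7)
        per <- -(sweep(Yb * log(Lc), 2L, p_c, "*") + (1 - Yb) * log(1 - Lc))
        loss <- sum(wb * rowSums(per)) / B
        dS <- (wb / B) * ((1 - Yb) * L - sweep(Yb * (1 - L), 2L, p_c, "*"))
      }
      epoch_loss <- epoch_loss + loss
      dW1 <- crossprod(Hd, dS)
      db1 <- colSums(dS)
      dHd <- dS %*% t(params$W1)
      if (cfg$dropout[2L] > 0) dHd <- dHd * mask1
      dH <- dHd * (1 - H * H)
      dW0 <- crossprod(Xb, dH)
      db0 <- colSums(dH)
      grads <- list(W0 = dW0, b0 = db0, W1 = dW1, b1 = db1)
      lr <- lr_at(step, total, cfg)
      for (nm in names(params)) {
        st <- state[[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * grads[[nm]]
        st$v <- beta2 * st$v + (1 - beta2) * grads[[nm]]^2
        mhat <- st$m / (1 - beta1^step)
        vhat <- st$v / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        state[[nm]] <- st
      }
    }
    trace[epoch] <- epoch_loss / steps_per_epoch
  }
  list(params = params, loss_trace = trace)
}
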