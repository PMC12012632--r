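## Decoder-only transformer over state tokens.  The compiled backend does the
## forward/backward passes; this file owns configuration, initialization, the
## Adam training loop, evaluation, and attention-map analysis.

#' Transformer configuration
#'
#' Desk-scale defaults: embedding dimension 32, 4 heads, 2 blocks, context
#' length 64, dropout 0, 2000 training steps of batch 16 at learning rate
#' 3e-4 with gradient clipping at 1.0.  \code{attentionEnabled = FALSE}
#' removes the masked self-attention sublayer only, keeping the position-wise
#' feed-forward path and norms — the ablated variant used to probe what
#' attention contributes.  \code{scalePerHead} controls the attention score
#' scaling: \code{TRUE} (default) divides by \code{sqrt(d / nHeads)} per
#' head, \code{FALSE} uses the full \code{sqrt(d)}.
#'
#' @param vocabSize number of states in the vocabulary.
#' @param embedDim embedding dimension d (divisible by \code{nHeads}).
#' @param nHeads attention heads N_h.
#' @param nBlocks transformer blocks N_b.
#' @param blockSize context length l (>= 2).
#' @param dropout residual dropout fraction.
#' @param epochs training steps (one random minibatch of windows per step).
#' @param learningRate Adam learning rate.
#' @param lrDecay cosine-decay the learning rate to 10\% of its initial
#'   value over the training run (reduces late-training optimizer noise).
#' @param batchSize windows per step.
#' @param seed RNG seed for initialization, batching and dropout.
#' @param attentionEnabled include the attention sublayer.
#' @param scalePerHead score scaling convention (see above).
#' @param valFraction trailing fraction of each training sequence held out
#'   for validation loss.
#' @export
gptConfig <- function(vocabSize, embedDim = 32L, nHeads = 4L, nBlocks = 2L,
                      blockSize = 64L, dropout = 0, epochs = 2000L,
                      learningRate = 3e-4, batchSize = 16L, seed = 1L,
                      attentionEnabled = TRUE, scalePerHead = TRUE,
                      valFraction = 0.2, lrDecay = FALSE) {
  if (embedDim %% nHeads != 0L)
    stop("embedDim must be divisible by nHeads")
  if (blockSize < 2L) stop("blockSize must be >= 2")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(vocab_size = as.integer(vocabSize),
                 embed_dim = as.integer(embedDim), n_heads = as.integer(nHeads),
                 n_blocks = as.integer(nBlocks), block_size = as.integer(blockSize),
                 dropout = dropout, epochs = as.integer(epochs),
                 learning_rate = learningRate, batch_size = as.integer(batchSize),
                 seed = as.integer(seed), attention_enabled = isTRUE(attentionEnabled),
                 scale_per_head = isTRUE(scalePerHead), val_fraction = valFraction,
                 lr_decay = isTRUE(lrDecay)),
            class = c("GPTConfig", "list"))
}

#' Attention-ablated copy of a configuration
#'
#' Returns the configuration with \code{attention_enabled = FALSE}; a model
#' trained with it has no communication path between positions, so its
#' logits at position t depend only on the token at t.
#'
#' @param config a [gptConfig()].
#' @export
ablateAttention <- function(config) {
  stopifnot(inherits(config, "GPTConfig"))
  config$attention_enabled <- FALSE
  config
}

#' Sinusoidal positional encoding table
#'
#' \code{PE(k, 2i) = sin(k / 10000^(2i/d))},
#' \code{PE(k, 2i + 1) = cos(k / 10000^(2i/d))} for positions
#' \code{k = 0..l-1} (returned as rows) and \code{i = 0..d/2-1}.
#'
#' @param l number of positions.
#' @param d embedding dimension (even).
#' @return numeric matrix \code{[l, d]}; row 1 alternates 0 and 1.
#' @export
positionalEncoding <- function(l, d) {
  if (d %% 2L != 0L) stop("d must be even")
  k <- 0:(l - 1)
  i <- 0:(d / 2 - 1)
  angle <- outer(k, 1 / 10000^(2 * i / d))
  pe <- matrix(0, l, d)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  pe
}

# fresh parameter list for a configuration (draws from the current RNG)
gpt_init_params <- function(config) {
  d <- config$embed_dim; V <- config$vocab_size
  nrm <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, sd = sd), nr, nc)
  p <- list(wte = nrm(V, d),
            pe = positionalEncoding(config$block_size, d))
  for (b in seq_len(config$n_blocks) - 1L) {
    pre <- sprintf("b%d_", b)
    if (config$attention_enabled) {
      p[[paste0(pre, "ln1_g")]] <- matrix(1, 1, d)
      p[[paste0(pre, "ln1_b")]] <- matrix(0, 1, d)
      p[[paste0(pre, "attn_wqkv")]] <- nrm(d, 3 * d)
      p[[paste0(pre, "attn_bqkv")]] <- matrix(0, 1, 3 * d)
      p[[paste0(pre, "attn_wo")]] <- nrm(d, d)
      p[[paste0(pre, "attn_bo")]] <- matrix(0, 1, d)
    }
    p[[paste0(pre, "ln2_g")]] <- matrix(1, 1, d)
    p[[paste0(pre, "ln2_b")]] <- matrix(0, 1, d)
    p[[paste0(pre, "ff_w1")]] <- nrm(d, 4 * d)
    p[[paste0(pre, "ff_b1")]] <- matrix(0, 1, 4 * d)
    p[[paste0(pre, "ff_w2")]] <- nrm(4 * d, d)
    p[[paste0(pre, "ff_b2")]] <- matrix(0, 1, d)
  }
  p$lnf_g <- matrix(1, 1, d)
  p$lnf_b <- matrix(0, 1, d)
  p$head_w <- nrm(d, V)
  p$head_b <- matrix(0, 1, V)
  p
}

# normalize training input to a list of integer token vectors
.as_token_list <- function(x) {
  if (is(x, "StateSequence")) return(list(tokens(x)))
  if (is.numeric(x)) return(list(as.integer(x)))
  if (is.list(x))
    return(lapply(x, function(s)
      if (is(s, "StateSequence")) tokens(s) else as.integer(s)))
  stop("expected a StateSequence, an integer vector, or a list of them")
}

# sample a batch of (input, target) windows from token sequences
.sample_windows <- function(seqs, Tlen, B) {
  ok <- which(vapply(seqs, length, integer(1)) >= Tlen + 1L)
  if (!length(ok)) stop("sequences shorter than blockSize + 1")
  X <- matrix(0L, B, Tlen); Y <- matrix(0L, B, Tlen)
  for (b in seq_len(B)) {
    s <- seqs[[if (length(ok) == 1L) ok else sample(ok, 1L)]]
    st <- sample.int(length(s) - Tlen, 1L)
    X[b, ] <- s[st:(st + Tlen - 1L)]
    Y[b, ] <- s[(st + 1L):(st + Tlen)]
  }
  list(X = X, Y = Y)
}

#' Train the transformer on token sequences
#'
#' Autoregressive next-token training: each step samples \code{batchSize}
#' random windows of \code{blockSize} tokens and minimizes the mean
#' cross-entropy of the one-step-ahead predictions with Adam.  The trailing
#' \code{valFraction} of every input sequence is held out and scored every
#' 25 steps (and at the last step).
#'
#' @param seqs a [StateSequence-class], an integer token vector, or a list
#'   of either — every vocabulary state must appear.
#' @param config a [gptConfig()].
#' @return a [GPTModel-class].
#' @export
trainGPT <- function(seqs, config) {
  stopifnot(inherits(config, "GPTConfig"))
  toks <- .as_token_list(seqs)
  seen <- sort(unique(unlist(toks)))
  if (max(seen) >= config$vocab_size || min(seen) < 0L)
    stop("token outside the configured vocabulary")
  if (length(seen) < config$vocab_size)
    warning("not every vocabulary state appears in the training data")
  nval <- function(n) floor(config$val_fraction * n)
  train <- lapply(toks, function(s) s[seq_len(length(s) - nval(length(s)))])
  val <- lapply(toks, function(s)
    if (nval(length(s)) > 0) tail(s, nval(length(s))) else integer())
  val <- val[vapply(val, length, integer(1)) >= config$block_size + 1L]
  withSeed(config$seed, {
    params <- gpt_init_params(config)
    fixed <- "pe"
    st <- adam_init(params[setdiff(names(params), fixed)])
    # fixed validation batch for a comparable curve
    valBatch <- if (length(val))
      .sample_windows(val, config$block_size, min(32L, config$batch_size * 2L))
    hist <- data.frame(epoch = seq_len(config$epochs), trainLoss = NA_real_,
                       valLoss = NA_real_)
    for (ep in seq_len(config$epochs)) {
      bt <- .sample_windows(train, config$block_size, config$batch_size)
      lg <- gpt_loss_grad_cpp(params, config, bt$X, bt$Y)
      hist$trainLoss[ep] <- lg$loss
      lr <- if (isTRUE(config$lr_decay))
        config$learning_rate * (0.55 + 0.45 * cos(pi * ep / config$epochs))
      else config$learning_rate
      upd <- adam_step(params[setdiff(names(params), fixed)], lg$grads, st,
                       lr, clip = 1.0)
      params[names(upd$params)] <- upd$params
      st <- upd$state
      if (length(val) && (ep %% 25L == 0L || ep == config$epochs))
        hist$valLoss[ep] <- gpt_loss_cpp(params, config, valBatch$X, valBatch$Y)
    }
    new("GPTModel", config = unclass(config), params = params,
        vocabSize = config$vocab_size, lossHistory = hist)
  })
}

#' @rdname nextTokenProbs
#' @export
setMethod("nextTokenProbs", "GPTModel", function(model, tokens) {
  tokens <- as.integer(tokens)
  if (any(tokens < 0L | tokens >= model@vocabSize))
    stop("token outside the model vocabulary")
  gpt_probs_cpp(model@params, model@config, tokens)
})

#' Validation loss of a model on held-out tokens
#'
#' Mean next-token cross-entropy over consecutive windows of the model's
#' context length; the quantity whose floor is 0 for a deterministic source
#' and log(V) for an i.i.d. uniform V-state source.
#'
#' @param model a trained [SequenceModel-class].
#' @param tokens integer token vector to score.
#' @return mean cross-entropy in nats.
#' @export
sequenceLoss <- function(model, tokens) {
  tokens <- as.integer(tokens)
  Tlen <- if (is(model, "GPTModel")) model@config$block_size
          else min(length(tokens) - 1L, 128L)
  if (length(tokens) < Tlen + 1L) stop("sequence shorter than one window")
  starts <- seq(1L, length(tokens) - Tlen, by = Tlen)
  tot <- 0
  for (s in starts) {
    win <- tokens[s:(s + Tlen - 1L)]
    tgt <- tokens[(s + 1L):(s + Tlen)]
    P <- nextTokenProbs(model, win)
    tot <- tot - mean(log(pmax(P[cbind(seq_len(Tlen), tgt + 1L)], 1e-300)))
  }
  tot / length(starts)
}

#' Averaged masked attention map
#'
#' Feeds \code{nChunks} random windows of \code{chunkLength} tokens (drawn
#' from the supplied data, typically model-generated) through the trained
#' model and averages the raw pre-softmax attention scores over heads,
#' chunks and (by default) blocks.  The causal mask zeroes everything above
#' the diagonal.
#'
#' @param model a trained [GPTModel-class] with attention enabled.
#' @param data a [StateSequence-class] or integer vector to draw chunks from.
#' @param nChunks number of random chunks (20 in the reference analysis).
#' @param chunkLength window length (128 in the reference analysis, capped
#'   at the model's context length).
#' @param block which block's scores to report; \code{NULL} averages blocks.
#' @param seed RNG seed for chunk placement.
#' @return an [AttentionMap-class].
#' @export
attentionScores <- function(model, data, nChunks = 20L, chunkLength = NULL,
                            block = NULL, seed = 1L) {
  stopifnot(is(model, "GPTModel"))
  if (!model@config$attention_enabled)
    stop("unsupported operation: model was trained without attention")
  toks <- .as_token_list(data)[[1]]
  if (is.null(chunkLength)) chunkLength <- model@config$block_size
  chunkLength <- min(chunkLength, model@config$block_size)
  if (length(toks) < chunkLength) stop("data shorter than one chunk")
  withSeed(seed, {
    acc <- matrix(0, chunkLength, chunkLength)
    for (ch in seq_len(nChunks)) {
      st <- sample.int(length(toks) - chunkLength + 1L, 1L)
      per_block <- gpt_attention_cpp(model@params, model@config,
                                     toks[st:(st + chunkLength - 1L)])
      acc <- acc + if (is.null(block))
        Reduce(`+`, per_block) / length(per_block) else per_block[[block]]
    }
    new("AttentionMap", scores = acc / nChunks,
        averaging = list(n_heads = model@config$n_heads, n_chunks = nChunks,
                         block = if (is.null(block)) "mean" else block))
  })
}

#' Save / load a trained sequence model
#'
#' One-file checkpoint holding the configuration and weight arrays.
#'
#' @param model a [SequenceModel-class].
#' @param path checkpoint file.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(class = class(model), config = model@config,
               params = model@params, vocabSize = model@vocabSize,
               lossHistory = model@lossHistory, schema = 1L), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  new(x$class, config = x$config, params = x$params,
      vocabSize = x$vocabSize, lossHistory = x$lossHistory)
}
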