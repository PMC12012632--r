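## LSTM baseline: a single recurrent layer over embedded tokens with a
## softmax head, trained with truncated BPTT on random windows.  It exposes
## the same nextTokenProbs()/generateTokens() contract as the transformer so
## every kinetics metric applies unchanged.

#' LSTM baseline configuration
#'
#' Defaults mirror the transformer's desk-scale settings: the embedding
#' dimension equals the transformer's and the hidden width equals the
#' embedding dimension, one recurrent layer, same training budget.
#'
#' @param vocabSize number of states.
#' @param embedDim token embedding dimension.
#' @param hiddenDim LSTM hidden width.
#' @param blockSize BPTT window length.
#' @param epochs training steps (one minibatch per step).
#' @param learningRate Adam learning rate.
#' @param batchSize windows per step.
#' @param seed RNG seed.
#' @param valFraction trailing fraction held out for validation.
#' @export
lstmConfig <- function(vocabSize, embedDim = 32L, hiddenDim = embedDim,
                       blockSize = 64L, epochs = 2000L, learningRate = 3e-3,
                       batchSize = 16L, seed = 1L, valFraction = 0.2) {
  structure(list(vocab_size = as.integer(vocabSize),
                 embed_dim = as.integer(embedDim),
                 hidden_dim = as.integer(hiddenDim),
                 block_size = as.integer(blockSize),
                 epochs = as.integer(epochs), learning_rate = learningRate,
                 batch_size = as.integer(batchSize), seed = as.integer(seed),
                 val_fraction = valFraction),
            class = c("LSTMConfig", "list"))
}

.sigm <- function(x) 1 / (1 + exp(-x))

lstm_init_params <- function(cfg) {
  d <- cfg$embed_dim; H <- cfg$hidden_dim; V <- cfg$vocab_size
  nrm <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)
  b <- matrix(0, 1, 4 * H)
  b[1, (H + 1):(2 * H)] <- 1   # forget-gate bias
  list(emb = nrm(V, d, 0.02),
       wx = nrm(d, 4 * H, sqrt(1 / d)),
       wh = nrm(H, 4 * H, sqrt(1 / H)),
       b = b,
       why = nrm(H, V, sqrt(1 / H)),
       by = matrix(0, 1, V))
}

# forward over a batch of windows X (B x T); returns caches for BPTT
lstm_forward <- function(p, X) {
  B <- nrow(X); Tlen <- ncol(X); H <- ncol(p$wh)/ 4 * 1
  H <- nrow(p$wh)
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  cache <- vector("list", Tlen)
  logits <- vector("list", Tlen)
  for (t in seq_len(Tlen)) {
    xe <- p$emb[X[, t] + 1L, , drop = FALSE]
    z <- xe %*% p$wx + h %*% p$wh
    z <- sweep(z, 2, p$b, "+")
    i <- .sigm(z[, 1:H, drop = FALSE])
    f <- .sigm(z[, (H + 1):(2 * H), drop = FALSE])
    o <- .sigm(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cNew <- f * cst + i * g
    tc <- tanh(cNew)
    hNew <- o * tc
    cache[[t]] <- list(xe = xe, hPrev = h, cPrev = cst, i = i, f = f, o = o,
                       g = g, c = cNew, tc = tc, h = hNew, tok = X[, t])
    h <- hNew; cst <- cNew
    logits[[t]] <- sweep(h %*% p$why, 2, p$by, "+")
  }
  list(logits = logits, cache = cache)
}

lstm_loss_grad <- function(p, X, Y) {
  B <- nrow(X); Tlen <- ncol(X); H <- nrow(p$wh); V <- ncol(p$why)
  fw <- lstm_forward(p, X)
  g <- lapply(p, function(m) m * 0)
  inv <- 1 / (B * Tlen)
  loss <- 0
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tlen))) {
    cc <- fw$cache[[t]]
    z <- fw$logits[[t]]
    P <- exp(z - apply(z, 1, max))
    P <- P / rowSums(P)
    loss <- loss - sum(log(pmax(P[cbind(seq_len(B), Y[, t] + 1L)], 1e-300))) * inv
    dlog <- P
    dlog[cbind(seq_len(B), Y[, t] + 1L)] <-
      dlog[cbind(seq_len(B), Y[, t] + 1L)] - 1
    dlog <- dlog * inv
    g$why <- g$why + crossprod(cc$h, dlog)
    g$by <- g$by + colSums(dlog)
    dh <- dlog %*% t(p$why) + dh_next
    do <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$cPrev
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    g$wx <- g$wx + crossprod(cc$xe, dz)
    g$wh <- g$wh + crossprod(cc$hPrev, dz)
    g$b <- g$b + colSums(dz)
    dh_next <- dz %*% t(p$wh)
    dxe <- dz %*% t(p$wx)
    for (bi in seq_len(B))
      g$emb[cc$tok[bi] + 1L, ] <- g$emb[cc$tok[bi] + 1L, ] + dxe[bi, ]
  }
  if (!is.finite(loss)) stop("training diverged: non-finite loss")
  list(loss = loss, grads = g)
}

lstm_loss <- function(p, X, Y) {
  fw <- lstm_forward(p, X)
  B <- nrow(X); Tlen <- ncol(X)
  loss <- 0
  for (t in seq_len(Tlen)) {
    z <- fw$logits[[t]]
    P <- exp(z - apply(z, 1, max)); P <- P / rowSums(P)
    loss <- loss - sum(log(pmax(P[cbind(seq_len(B), Y[, t] + 1L)], 1e-300)))
  }
  loss / (B * Tlen)
}

#' Train the LSTM baseline
#'
#' Same sampling scheme and objective as [trainGPT()]: random windows,
#' next-token cross-entropy, Adam with gradient clipping.
#'
#' @param seqs training sequences as in [trainGPT()].
#' @param config an [lstmConfig()].
#' @return an [LSTMModel-class].
#' @export
trainLSTM <- function(seqs, config) {
  stopifnot(inherits(config, "LSTMConfig"))
  toks <- .as_token_list(seqs)
  if (max(unlist(toks)) >= config$vocab_size)
    stop("token outside the configured vocabulary")
  nval <- function(n) floor(config$val_fraction * n)
  train <- lapply(toks, function(s) s[seq_len(length(s) - nval(length(s)))])
  val <- lapply(toks, function(s)
    if (nval(length(s)) > 0) tail(s, nval(length(s))) else integer())
  val <- val[vapply(val, length, integer(1)) >= config$block_size + 1L]
  withSeed(config$seed, {
    p <- lstm_init_params(config)
    st <- adam_init(p)
    valBatch <- if (length(val))
      .sample_windows(val, config$block_size, min(32L, config$batch_size * 2L))
    hist <- data.frame(epoch = seq_len(config$epochs), trainLoss = NA_real_,
                       valLoss = NA_real_)
    for (ep in seq_len(config$epochs)) {
      bt <- .sample_windows(train, config$block_size, config$batch_size)
      lg <- lstm_loss_grad(p, bt$X, bt$Y)
      hist$trainLoss[ep] <- lg$loss
      upd <- adam_step(p, lg$grads, st, config$learning_rate, clip = 1.0)
      p <- upd$params; st <- upd$state
      if (length(val) && (ep %% 25L == 0L || ep == config$epochs))
        hist$valLoss[ep] <- lstm_loss(p, valBatch$X, valBatch$Y)
    }
    new("LSTMModel", config = unclass(config), params = p,
        vocabSize = config$vocab_size, lossHistory = hist)
  })
}

#' @rdname nextTokenProbs
#' @export
setMethod("nextTokenProbs", "LSTMModel", function(model, tokens) {
  tokens <- as.integer(tokens)
  if (any(tokens < 0L | tokens >= model@vocabSize))
    stop("token outside the model vocabulary")
  fw <- lstm_forward(model@params, matrix(tokens, nrow = 1))
  P <- t(vapply(fw$logits, function(z) {
    e <- exp(z[1, ] - max(z[1, ])); e / sum(e)
  }, numeric(model@vocabSize)))
  P
})

# recurrent-state generation (the natural O(1)-per-token path for an RNN)
lstm_generate_tokens <- function(model, prompt, nTokens, temperature = 1) {
  p <- model@params
  H <- nrow(p$wh); V <- ncol(p$why)
  h <- matrix(0, 1, H); cst <- matrix(0, 1, H)
  stepfn <- function(tok) {
    xe <- p$emb[tok + 1L, , drop = FALSE]
    z <- xe %*% p$wx + h %*% p$wh
    z <- sweep(z, 2, p$b, "+")
    i <- .sigm(z[, 1:H, drop = FALSE]); f <- .sigm(z[, (H + 1):(2 * H), drop = FALSE])
    o <- .sigm(z[, (2 * H + 1):(3 * H), drop = FALSE]); g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cst <<- f * cst + i * g
    h <<- o * tanh(cst)
    zlog <- (h %*% p$why + p$by)[1, ] / temperature
    e <- exp(zlog - max(zlog)); e / sum(e)
  }
  for (tok in prompt[-length(prompt)]) stepfn(tok)
  out <- integer(nTokens)
  cur <- prompt[length(prompt)]
  for (k in seq_len(nTokens)) {
    pr <- stepfn(cur)
    cur <- sample.int(V, 1L, prob = pr) - 1L
    out[k] <- cur
  }
  out
}
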