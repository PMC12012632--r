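# Transformer: positional encoding, gradients, causality, attention, training.

test_that("sinusoidal positional encoding matches the closed form", {
  pe <- positionalEncoding(8, 6)
  expect_equal(pe[1, c(1, 3, 5)], c(0, 0, 0))          # sin(0)
  expect_equal(pe[1, c(2, 4, 6)], c(1, 1, 1))          # cos(0)
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_equal(pe[2, 2], cos(1), tolerance = 1e-12)
  expect_equal(round(pe[2, 1], 5), 0.84147)
  expect_equal(round(pe[2, 2], 5), 0.54030)
  # general entry: k = 5, i = 2 (third sin/cos pair)
  expect_equal(pe[6, 5], sin(5 / 10000^(4 / 6)), tolerance = 1e-12)
  expect_error(positionalEncoding(4, 5), "even")
})

test_that("analytic gradients match finite differences", {
  for (attn in c(TRUE, FALSE)) {
    cfg <- gptConfig(vocabSize = 3, embedDim = 8, nHeads = 2, nBlocks = 2,
                     blockSize = 6, attentionEnabled = attn)
    set.seed(42)
    params <- kinseq:::gpt_init_params(cfg)
    X <- matrix(sample(0:2, 12, TRUE), 2, 6)
    Y <- matrix(sample(0:2, 12, TRUE), 2, 6)
    lg <- kinseq:::gpt_loss_grad_cpp(params, cfg, X, Y)
    h <- 1e-5
    set.seed(7)
    for (nm in setdiff(names(params), "pe")) {
      for (k in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        pp <- params; pp[[nm]][k] <- pp[[nm]][k] + h
        pm <- params; pm[[nm]][k] <- pm[[nm]][k] - h
        num <- (kinseq:::gpt_loss_cpp(pp, cfg, X, Y) -
                kinseq:::gpt_loss_cpp(pm, cfg, X, Y)) / (2 * h)
        expect_lt(abs(num - lg$grads[[nm]][k]), 1e-7)
      }
    }
  }
})

test_that("outputs are normalized distributions and causal", {
  cfg <- tiny_gpt_cfg(3)
  set.seed(1)
  params <- kinseq:::gpt_init_params(cfg)
  model <- new("GPTModel", config = unclass(cfg), params = params,
               vocabSize = 3L, lossHistory = data.frame())
  toks <- sample(0:2, 20, TRUE)
  P <- nextTokenProbs(model, toks)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-6)
  # causality by perturbation: changing token t+1 leaves rows <= t unchanged
  toks2 <- toks
  toks2[13] <- (toks2[13] + 1L) %% 3L
  P2 <- nextTokenProbs(model, toks2)
  expect_equal(P2[1:12, ], P[1:12, ], tolerance = 1e-12)
  expect_gt(max(abs(P2[13, ] - P[13, ])), 1e-8)
  # forward on a prefix equals the prefix rows of the full forward
  expect_equal(nextTokenProbs(model, toks[1:8]), P[1:8, ], tolerance = 1e-10)
  expect_error(nextTokenProbs(model, c(0L, 5L)), "vocabulary")
})

test_that("zeroed query/key weights give uniform causal attention", {
  cfg <- gptConfig(vocabSize = 3, embedDim = 8, nHeads = 2, nBlocks = 1,
                   blockSize = 8)
  set.seed(2)
  params <- kinseq:::gpt_init_params(cfg)
  params$b0_attn_wqkv[, 1:16] <- 0       # Q and K projections
  params$b0_attn_bqkv[, 1:16] <- 0
  W <- kinseq:::gpt_attn_weights_cpp(params, cfg, sample(0:2, 5, TRUE), 0L)
  for (hd in 1:2) {
    P <- W[, , hd]
    expect_true(all(P[upper.tri(P)] == 0))            # exact causal mask
    expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-12)
    for (t in 1:5)                                     # uniform over prefix
      expect_equal(P[t, 1:t], rep(1 / t, t), tolerance = 1e-12)
  }
  # length-1 window: single weight 1
  W1 <- kinseq:::gpt_attn_weights_cpp(params, cfg, 1L, 0L)
  expect_equal(as.numeric(W1[1, 1, ]), c(1, 1))
})

test_that("training drives the loss to the entropy floor of the source", {
  # deterministic cycle: floor 0, continuation exactly periodic
  cyc <- makeFixture("periodic", list(period = 3, n = 2000))
  m <- trainGPT(cyc, gptConfig(vocabSize = 3, epochs = 800, seed = 1))
  hist <- lossHistory(m)
  expect_lt(tail(hist$trainLoss, 1), 0.02)
  expect_lt(tail(hist$trainLoss, 1), hist$trainLoss[1])
  # the learned one-step map is exactly the cycle ...
  P <- nextTokenProbs(m, rep_len(0:2, 30))
  expect_identical(max.col(P)[-30] - 1L, rep_len(0:2, 30)[-1])
  # ... and a sampled continuation follows it near-deterministically
  g <- generateTokens(m, c(0L, 1L), 30, seed = 5)
  expect_gte(mean(tokens(g) == rep_len(c(2L, 0L, 1L), 30)), 0.9)
  # i.i.d. uniform: floor log(3)
  set.seed(9)
  iid <- sample(0:2, 20000, TRUE)
  m2 <- trainGPT(iid, gptConfig(vocabSize = 3, epochs = 250, seed = 2))
  v <- lossHistory(m2)$valLoss
  expect_equal(tail(v[!is.na(v)], 1), log(3), tolerance = 0.03)
})

test_that("the attention-ablated model sees only the current token", {
  so <- makeFixture("second_order", list(n = 6000), seed = 3)
  cfg <- tiny_gpt_cfg(3, epochs = 150)
  m <- trainGPT(so, ablateAttention(cfg))
  toks <- tokens(so)[1:12]
  P <- nextTokenProbs(m, toks)
  toks2 <- toks
  toks2[2] <- (toks2[2] + 1L) %% 3L     # perturb an early token
  P2 <- nextTokenProbs(m, toks2)
  expect_equal(P2[8, ], P[8, ], tolerance = 1e-12)
  expect_error(attentionScores(m, so), "unsupported|without attention")
})

test_that("attention separates a second-order source; ablation cannot", {
  so <- makeFixture("second_order", list(n = 20000), seed = 4)
  cfg <- gptConfig(vocabSize = 3, epochs = 400, learningRate = 1e-3, seed = 1)
  mFull <- trainGPT(so, cfg)
  mAbl <- trainGPT(so, ablateAttention(cfg))
  held <- tail(tokens(so), 3000)
  lFull <- sequenceLoss(mFull, held)
  lAbl <- sequenceLoss(mAbl, held)
  expect_gt(lAbl - lFull, 0.1)
  # the i.i.d. floor needs no context: both reach log(V)
  set.seed(5)
  iid <- sample(0:2, 15000, TRUE)
  mAblIid <- trainGPT(iid, ablateAttention(tiny_gpt_cfg(3, epochs = 200)))
  expect_equal(sequenceLoss(mAblIid, tail(iid, 2000)), log(3),
               tolerance = 0.03)
})

test_that("attention maps are causal and averaged as documented", {
  cyc <- makeFixture("periodic", list(period = 4, n = 4000))
  m <- trainGPT(cyc, gptConfig(vocabSize = 4, embedDim = 16, nHeads = 1,
                               nBlocks = 1, blockSize = 32, epochs = 250,
                               seed = 6))
  am <- attentionScores(m, cyc, nChunks = 5, chunkLength = 32, seed = 2)
  S <- attentionMatrix(am)
  expect_true(all(S[upper.tri(S)] == 0))
  # single head, single chunk: equals that head's raw score matrix
  am1 <- attentionScores(m, cyc, nChunks = 1, chunkLength = 16, seed = 3)
  raw <- kinseq:::withSeed(3, {
    st <- sample.int(4000 - 16 + 1, 1)
    kinseq:::gpt_attention_cpp(m@params, m@config,
                               tokens(cyc)[st:(st + 15)])[[1]]
  })
  expect_equal(attentionMatrix(am1), raw, tolerance = 1e-12)
})

test_that("the generation fast path equals the full forward pass", {
  for (attn in c(TRUE, FALSE)) {
    cfg <- gptConfig(vocabSize = 4, nBlocks = 2, seed = 1,
                     attentionEnabled = attn)
    set.seed(4 + attn)
    params <- kinseq:::gpt_init_params(cfg)
    for (L in c(1, 7, 64)) {
      tok <- sample(0:3, L, TRUE)
      full <- kinseq:::gpt_probs_cpp(params, cfg, tok)[L, ]
      fast <- as.numeric(kinseq:::gpt_last_probs_cpp(params, cfg, tok))
      expect_equal(fast, full, tolerance = 1e-12)
    }
  }
})

test_that("training is reproducible and checkpoints round-trip", {
  mc <- makeFixture("markov_chain", list(T = ref_T3, n = 4000), seed = 5)
  cfg <- tiny_gpt_cfg(3, epochs = 50)
  m1 <- trainGPT(mc, cfg)
  m2 <- trainGPT(mc, cfg)
  expect_equal(m1@params, m2@params, tolerance = 1e-12)
  f <- tempfile(fileext = ".rds")
  saveModel(m1, f)
  m3 <- loadModel(f)
  expect_equal(nextTokenProbs(m3, c(0L, 1L, 2L)),
               nextTokenProbs(m1, c(0L, 1L, 2L)), tolerance = 1e-12)
})
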