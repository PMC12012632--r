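# Markov state model and LSTM baselines.

seq2 <- function(x, ns = max(x) + 1L)
  new("StateSequence", tokens = as.integer(x), nStates = as.integer(ns))

test_that("sliding-window counts and row-normalization are exact", {
  m <- estimateMSM(seq2(rep(c(0, 1), 10)), lag = 1)
  expect_equal(transitionMatrix(m), matrix(c(0, 1, 1, 0), 2), tolerance = 1e-12)
  m2 <- estimateMSM(seq2(c(0, 0, 1, 1, 0)), lag = 1)
  expect_equal(countMatrix(m2), matrix(c(1, 1, 1, 1), 2), tolerance = 1e-12)
  expect_equal(transitionMatrix(m2), matrix(0.5, 2, 2), tolerance = 1e-12)
  # a constant sequence has a single absorbing state: estimation must refuse
  expect_error(estimateMSM(seq2(rep(0L, 10), 2), 1), "absorbing|connected")
})

test_that("rows are stochastic and the spectrum is bounded by 1", {
  s <- makeFixture("markov_chain", list(T = ref_T3, n = 30000), seed = 1)
  for (lag in c(1L, 3L, 7L)) {
    m <- estimateMSM(s, lag)
    expect_equal(rowSums(transitionMatrix(m)), rep(1, 3), tolerance = 1e-12)
    ev <- eigen(transitionMatrix(m), only.values = TRUE)$values
    expect_lt(max(Mod(ev)), 1 + 1e-10)
    expect_equal(max(Re(ev)), 1, tolerance = 1e-10)
  }
})

test_that("the lag-1 estimate recovers the true chain within counting error", {
  n <- 100000
  s <- makeFixture("markov_chain", list(T = ref_T3, n = n), seed = 2)
  m <- estimateMSM(s, 1)
  Te <- transitionMatrix(m)
  rowN <- rowSums(countMatrix(m))
  for (i in 1:3) for (j in 1:3)
    expect_lt(abs(Te[i, j] - ref_T3[i, j]),
              3 * p_se(ref_T3[i, j], rowN[i]) + 1e-9)
})

test_that("implied timescales follow the closed form and are flat in lag", {
  # lambda2 = 0.5 at lag 1 for T = [[.75,.25],[.25,.75]] -> t2 = 1/log 2
  T2 <- matrix(c(.75, .25, .25, .75), 2, byrow = TRUE)
  s <- makeFixture("markov_chain", list(T = T2, n = 200000), seed = 3)
  its <- impliedTimescales(s, c(1L, 2L, 4L))
  t2 <- its$its[its$lag == 1 & its$index == 2]
  expect_equal(t2, 1 / log(2), tolerance = 0.05)
  expect_equal(t2, 1.4427, tolerance = 0.05)
  # Markov property: flat across lags within estimation error
  spread <- range(its$its[its$flag == "ok"])
  expect_lt(diff(spread) / mean(spread), 0.12)
  # alternating sequence: negative eigenvalue is flagged, not dropped
  its2 <- impliedTimescales(seq2(rep(c(0, 1), 200)), 1L)
  expect_equal(its2$flag, "nonpositive")
  expect_true(is.na(its2$its))
})

test_that("lag selection picks the level-off point", {
  s <- makeFixture("markov_chain", list(T = ref_T3, n = 50000), seed = 4)
  its <- impliedTimescales(s, c(1L, 2L, 4L, 8L))
  expect_equal(selectLag(its), 1L)    # already Markovian at lag 1
})

test_that("the Chapman-Kolmogorov test passes for a true Markov chain", {
  s <- makeFixture("markov_chain", list(T = ref_T3, n = 60000), seed = 5)
  m <- estimateMSM(s, 1)
  ck <- ckTest(m, s, kMultiples = c(1L, 2L, 3L), seed = 2)
  k1 <- ck[ck$k == 1, ]
  expect_equal(k1$predicted, k1$estimated, tolerance = 1e-12)  # identical at k=1
  for (k in 2:3) {
    sub <- ck[ck$k == k, ]
    expect_true(all(abs(sub$predicted - sub$estimated) < 0.02))
    expect_true(all(sub$predicted >= sub$lower - 0.02 &
                    sub$predicted <= sub$upper + 0.02))
  }
  expect_true(all(ck$predicted >= 0 & ck$predicted <= 1))
})

test_that("a second-order source visibly violates the CK prediction", {
  # noise-free variant: the deterministic pair-cycle makes T(1)^2 and T(2)
  # disagree strongly on the self-transition of state 0
  so <- makeFixture("second_order", list(n = 60000, eps = 0), seed = 6)
  m <- estimateMSM(so, 1)
  ck <- ckTest(m, so, kMultiples = 2L, seed = 3)
  expect_gt(max(abs(ck$predicted - ck$estimated)), 0.2)
})

test_that("Markov generation reproduces stationarity and edge cases", {
  mId <- new("MarkovModel", lag = 1L, countMatrix = diag(2),
             transitionMatrix = diag(2), states = 0:1, dropped = integer(),
             reversible = FALSE)
  expect_equal(tokens(msmGenerate(mId, 0, 50, seed = 1)), rep(0L, 50))
  mAlt <- new("MarkovModel", lag = 1L, countMatrix = matrix(c(0, 5, 5, 0), 2),
              transitionMatrix = matrix(c(0, 1, 1, 0), 2), states = 0:1,
              dropped = integer(), reversible = FALSE)
  expect_equal(tokens(msmGenerate(mAlt, 0, 6, seed = 1)),
               c(1L, 0L, 1L, 0L, 1L, 0L))
  s <- makeFixture("markov_chain", list(T = ref_T3, n = 50000), seed = 7)
  m <- estimateMSM(s, 1)
  g <- msmGenerate(m, 0, 100000, seed = 8)
  pi_hat <- tabulate(tokens(g) + 1L, 3) / 1e5
  pi_true <- stationaryDistribution(m)
  expect_true(all(abs(pi_hat - pi_true) < 3 * p_se(pi_true, 1e5) + 0.01))
  expect_error(msmGenerate(m, 7, 10), "active set")
  # generation at lag tau carries the coarser time step
  m3 <- estimateMSM(s, 3)
  expect_equal(dtPerFrame(msmGenerate(m3, 0, 10, seed = 1, dtPerFrame = 0.1)),
               0.3)
})

test_that("reversible estimation enforces detailed balance", {
  s <- makeFixture("markov_chain", list(T = ref_T3, n = 40000), seed = 9)
  m <- estimateMSM(s, 1, reversible = TRUE)
  Tm <- transitionMatrix(m)
  pi <- stationaryDistribution(m)
  flux <- outer(unname(pi), rep(1, 3)) * Tm
  expect_equal(flux, t(flux), tolerance = 1e-6)
})

test_that("the LSTM honours the shared sequence-model contract", {
  cyc <- makeFixture("periodic", list(period = 3, n = 2000))
  lm <- trainLSTM(cyc, lstmConfig(vocabSize = 3, epochs = 500, seed = 1))
  expect_lt(tail(lossHistory(lm)$trainLoss, 1), 0.05)
  P <- nextTokenProbs(lm, rep_len(0:2, 30))
  expect_identical(max.col(P)[-30] - 1L, rep_len(0:2, 30)[-1])
  g <- generateTokens(lm, c(0L, 1L), 24, seed = 2)
  expect_gte(mean(tokens(g) == rep_len(c(2L, 0L, 1L), 24)), 0.9)
  # normalized rows, causality by perturbation, vocabulary bound
  set.seed(3)
  toks <- sample(0:2, 15, TRUE)
  P <- nextTokenProbs(lm, toks)
  expect_equal(rowSums(P), rep(1, 15), tolerance = 1e-9)
  toks2 <- toks; toks2[10] <- (toks2[10] + 1L) %% 3L
  expect_equal(nextTokenProbs(lm, toks2)[1:9, ], P[1:9, ], tolerance = 1e-12)
  set.seed(4)
  iid <- sample(0:2, 15000, TRUE)
  lm2 <- trainLSTM(iid, lstmConfig(vocabSize = 3, epochs = 250, seed = 2))
  v <- lossHistory(lm2)$valLoss
  expect_equal(tail(v[!is.na(v)], 1), log(3), tolerance = 0.04)
  g2 <- generateTokens(lm2, c(0L, 1L), 2000, seed = 5)
  expect_true(all(tokens(g2) >= 0L & tokens(g2) < 3L))
  expect_identical(tokens(generateTokens(lm2, c(0L, 1L), 50, seed = 6)),
                   tokens(generateTokens(lm2, c(0L, 1L), 50, seed = 6)))
})

test_that("LSTM gradients match finite differences", {
  cfg <- lstmConfig(vocabSize = 3, embedDim = 6, hiddenDim = 5, blockSize = 6)
  set.seed(1)
  p <- kinseq:::lstm_init_params(cfg)
  X <- matrix(sample(0:2, 12, TRUE), 2, 6)
  Y <- matrix(sample(0:2, 12, TRUE), 2, 6)
  lg <- kinseq:::lstm_loss_grad(p, X, Y)
  h <- 1e-5
  set.seed(2)
  for (nm in names(p)) {
    for (k in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      pp <- p; pp[[nm]][k] <- pp[[nm]][k] + h
      pm <- p; pm[[nm]][k] <- pm[[nm]][k] - h
      num <- (kinseq:::lstm_loss(pp, X, Y) - kinseq:::lstm_loss(pm, X, Y)) / (2 * h)
      expect_lt(abs(num - lg$grads[[nm]][k]), 1e-7)
    }
  }
})
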