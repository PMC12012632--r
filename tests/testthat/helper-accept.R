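# Builders for the heavy end-to-end study fixtures shared across the
# acceptance-style checks.  Everything is seeded; artifacts are cached for
# the duration of one test run.

# Three-well end-to-end study: a 1e5-frame trajectory at kT = 0.2 saved
# every 0.4 tau_BD (the coarsest stride that keeps clear dwell structure
# while the 99th-percentile dwell stays inside the 64-frame context),
# k = 3 states, n_s = 3 transformers, 1e5 generated tokens per member.
acc_toy <- function() cached("acc_toy", function() {
  spec <- toyPotentialSpec("three_state")
  integ <- integratorSpec(dt = 0.01, gamma = 1, kT = 0.2, nSteps = 4e6,
                          saveStride = 40, seed = 101)
  traj <- runBDToy(spec, integ)
  src <- kmeansDiscretize(frames(traj)[, 1, ], 3, seed = 11,
                          dtPerFrame = dtPerFrame(traj))
  segs <- segmentSequence(src, segmentPlan(3, 60000, seed = 12),
                          promptLength = 64)
  models <- lapply(1:3, function(i)
    trainGPT(c(segs[[i]]$train, segs[[i]]$val),
             gptConfig(vocabSize = 3, epochs = 2000, learningRate = 1e-3,
                       batchSize = 24, lrDecay = TRUE, seed = 100 + i)))
  ens <- generateEnsemble(models, lapply(segs, `[[`, "prompt"), 1e5,
                          masterSeed = 77)
  # block standard error of the source occupancies (10 blocks)
  blocks <- split(tokens(src), cut(seq_along(tokens(src)), 10))
  bp <- t(vapply(blocks, function(b) tabulate(b + 1L, 3) / length(b),
                 numeric(3)))
  cen <- src@labelMap
  D <- as.matrix(dist(cen))
  far <- sort(which(D == max(D), arr.ind = TRUE)[1, ]) - 1L
  list(src = src, models = models, ens = ens,
       seSrc = apply(bp, 2, sd) / sqrt(nrow(bp)),
       grid = kinseq:::.default_grid(list(src)), far = far)
})

# Known-chain study for the parameter-recovery oracle.
acc_markov <- function() cached("acc_markov", function() {
  mc <- makeFixture("markov_chain", list(T = ref_T3, n = 50000), seed = 41)
  m <- trainGPT(mc, gptConfig(vocabSize = 3, epochs = 2000, learningRate = 1e-3,
                              batchSize = 32, lrDecay = TRUE, seed = 42))
  g <- generateTokens(m, tail(tokens(mc), 64), 50000, seed = 43)
  list(mc = mc, model = m, gen = g)
})

# Second-order study shared by the attention-ablation and MSM-deficiency
# checks: same data, full and ablated transformers, MSM, all generating.
acc_second <- function() cached("acc_second", function() {
  so <- makeFixture("second_order", list(n = 30000), seed = 51)
  cfg <- gptConfig(vocabSize = 3, epochs = 1200, learningRate = 1e-3,
                   batchSize = 32, lrDecay = TRUE, seed = 52)
  mFull <- trainGPT(so, cfg)
  mAbl <- trainGPT(so, ablateAttention(cfg))
  prompt <- tail(tokens(so), 64)
  gFull <- generateTokens(mFull, prompt, 30000, seed = 53)
  gAbl <- generateTokens(mAbl, prompt, 30000, seed = 54)
  msm <- estimateMSM(so, 1)
  gMsm <- msmGenerate(msm, tokens(so)[length(tokens(so))], 30000, seed = 55)
  chunks <- lapply(split(tokens(so), cut(seq_along(tokens(so)), 3)),
                   kinseq:::as_state_sequence, nStates = 3L)
  list(so = so, chunks = unname(chunks), mFull = mFull, mAbl = mAbl,
       gFull = gFull, gAbl = gAbl, msm = msm, gMsm = gMsm, grid = 1:5)
})

# Active-chain study: one long spiral-start trajectory for the autoencoder
# (2e5 frames at stride 50) plus 12 further spiral-start members (6000
# tau_BD each, long enough to capture the spiral breakup) at coarse stride
# for the detailed-balance kinetics.  The latent coordinates are smoothed
# with a ~200 tau_BD running mean before clustering — fast recrossings of
# the latent boundary are not state transitions — and states come from a
# 2-state K-means fitted on the long member (where spiral and extended
# frames are balanced), assigned to every other member so all share one
# state definition.
smooth_cv <- function(v, w = 101L) {
  apply(v, 2, function(col) {
    f <- stats::filter(col, rep(1 / w, w), sides = 2)
    f[is.na(f)] <- col[is.na(f)]
    as.numeric(f)
  })
}

acc_active <- function() cached("acc_active", function() {
  spec <- polymerSpec()
  sel <- seq(1, 29, by = 4)
  integL <- integratorSpec(dt = 0.001, gamma = 200, kT = 1, nSteps = 1e7,
                           saveStride = 50, seed = 501)
  trajL <- runBDPolymer(spec, integL, init = spiralChain(spec))
  featsL <- pairwiseDistances(trajL, sel)
  ae <- trainAutoencoder(featsL, autoencoderSpec(latentDim = 2, epochs = 8,
                                                 batchSize = 256, seed = 7))
  sub <- seq(1, nFrames(trajL), by = 40)          # effective stride 2000
  ref <- kmeansDiscretize(smooth_cv(cvValues(encodeFeatures(ae, featsL))[sub, ]),
                          2, seed = 9, dtPerFrame = 2)
  members <- list(ref)
  for (s in 1:12) {
    integ <- integratorSpec(dt = 0.001, gamma = 200, kT = 1, nSteps = 6e6,
                            saveStride = 2000, seed = 510 + s)
    tr <- runBDPolymer(spec, integ, init = spiralChain(spec))
    cv <- smooth_cv(cvValues(encodeFeatures(ae, pairwiseDistances(tr, sel))))
    members[[s + 1]] <- assignStates(cv, ref, dtPerFrame = 2)
  }
  list(fve = ae@fve, nFrames = nFrames(trajL), members = members)
})

# Passive-chain control members (f_m = 0): equilibrium dynamics whose
# forward/backward transition statistics must balance.
acc_passive <- function() cached("acc_passive", function() {
  spec <- polymerSpec(propulsion = 0)
  members <- lapply(1:4, function(s) {
    integ <- integratorSpec(dt = 0.001, gamma = 200, kT = 1, nSteps = 2e6,
                            saveStride = 500, seed = 530 + s)
    tr <- runBDPolymer(spec, integ)
    radiusOfGyration(tr)
  })
  pool <- matrix(unlist(members), ncol = 1)
  km <- kmeansDiscretize(pool, 2, seed = 10)
  idx <- cumsum(c(0, vapply(members, length, integer(1))))
  lapply(seq_along(members), function(i)
    kinseq:::as_state_sequence(tokens(km)[(idx[i] + 1):idx[i + 1]], 2L))
})
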