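# Shared fixtures built in code.  Heavy artifacts (polymer trajectory,
# autoencoder, trained transformer ensembles) are built once per test run and
# cached in this environment so several test files can reuse them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .cache)) assign(key, builder(), .cache)
  get(key, .cache)
}

# reference 3-state transition matrix with known spectrum, used across files
ref_T3 <- matrix(c(0.90, 0.08, 0.02,
                   0.10, 0.80, 0.10,
                   0.05, 0.15, 0.80), 3, 3, byrow = TRUE)

# quick small transformer config for unit tests
tiny_gpt_cfg <- function(vocab, epochs = 200L, seed = 1L, ...) {
  gptConfig(vocabSize = vocab, embedDim = 16L, nHeads = 2L, nBlocks = 2L,
            blockSize = 32L, epochs = epochs, batchSize = 8L, seed = seed, ...)
}

# multinomial standard error for a probability p estimated from n draws
p_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)
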