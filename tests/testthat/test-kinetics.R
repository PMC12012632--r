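# Kinetic evaluation: probabilities, commit-time counting, detailed balance,
# free-energy profiles, curve comparison.

seq_of <- function(x, ns = max(x) + 1L)
  new("StateSequence", tokens = as.integer(x), nStates = as.integer(ns))

# brute-force oracle: enumerate adjacent run pairs directly
brute_commit <- function(x, from, to, tau) {
  r <- rle(x)
  n <- 0
  for (k in seq_len(length(r$values) - 1))
    if (r$values[k] == from && r$values[k + 1] == to &&
        min(r$lengths[k], r$lengths[k + 1]) >= tau)
      n <- n + 1
  n
}

test_that("state probabilities count occurrences with ensemble errors", {
  p <- stateProbabilities(seq_of(c(0, 1, 1)))
  expect_equal(p$mean, c(1 / 3, 2 / 3))
  expect_equal(p$stderr, c(0, 0))
  ens <- list(seq_of(c(0, 1, 1)), seq_of(c(0, 1, 1)))
  expect_equal(stateProbabilities(ens)$stderr, c(0, 0))
  set.seed(1)
  long <- seq_of(sample(0:2, 60000, TRUE), 3)
  p3 <- stateProbabilities(long)
  expect_true(all(abs(p3$mean - 1 / 3) < 3 * p_se(1 / 3, 60000)))
  expect_error(stateProbabilities(seq_of(integer(), 2)), "empty")
})

test_that("commit-time counts match the brute-force run enumeration", {
  x <- c(0, 0, 1, 0, 0, 0, 1, 1)
  cv01 <- commitTimeCounts(seq_of(x), c(0, 1), 1:3)
  cv10 <- commitTimeCounts(seq_of(x), c(1, 0), 1:3)
  raw01 <- cv01@meta$raw[1, ]
  raw10 <- cv10@meta$raw[1, ]
  expect_equal(raw01, c(2, 1, 0))        # hand-checked
  expect_equal(raw10, c(1, 0, 0))
  set.seed(2)
  y <- sample(0:2, 400, TRUE, prob = c(.5, .3, .2))
  for (pair in list(c(0, 1), c(2, 0), c(1, 2))) {
    cv <- commitTimeCounts(seq_of(y, 3), pair, 1:6)
    expect_equal(cv@meta$raw[1, ],
                 vapply(1:6, function(tau)
                   brute_commit(y, pair[1], pair[2], tau), numeric(1)))
  }
})

test_that("curves are monotone and tau = 1 totals equal token changes", {
  set.seed(3)
  y <- sample(0:2, 2000, TRUE)
  s <- seq_of(y, 3)
  curves <- transitionCurves(s, 1:8)
  tot1 <- sum(vapply(curves, function(cv) cv@meta$raw[1, 1], numeric(1)))
  expect_equal(tot1, sum(diff(y) != 0))
  for (cv in curves) expect_true(all(diff(cv@counts) <= 1e-12))
  const <- commitTimeCounts(seq_of(rep(0, 50), 2), c(0, 1), 1:3)
  expect_equal(const@counts, c(0, 0, 0))
  expect_error(commitTimeCounts(s, c(1, 1)), "distinct")
  expect_error(commitTimeCounts(s, c(0, 1), 0:2), ">= 1")
})

test_that("reversible dynamics are not flagged; exact symmetry gives zero", {
  set.seed(4)
  Trev <- matrix(c(.85, .1, .05, .1, .8, .1, .05, .1, .85), 3, byrow = TRUE)
  ens <- lapply(1:5, function(i)
    makeFixture("markov_chain", list(T = Trev, n = 20000), seed = 40 + i))
  rep <- detailedBalanceReport(ens)
  expect_false(any(rep$flagged))
  # identical forward and backward curves: asymmetry exactly zero
  # (trailing 0-run makes the 0->1 and 1->0 crossing counts equal)
  x <- c(rep(c(0, 0, 1, 1), 100), 0, 0)
  curves <- transitionCurves(seq_of(x, 2), 1:2)
  rep2 <- detailedBalanceReport(curves)
  expect_equal(rep2$asymmetry, 0)
  expect_equal(rep2$z, 0)
  expect_error(detailedBalanceReport(curves["0->1"]), "missing reverse")
})

test_that("free-energy profiles follow -kT log P", {
  # uniform occupancy: flat zero profile
  u <- rep(0:3, each = 25)
  fp <- freeEnergy1d(u + 0.001 * seq_along(u) / length(u), nBins = 4)
  expect_equal(fp@F, rep(0, 4), tolerance = 1e-9)
  # two bins with count ratio e: gap of exactly 1 kT
  x <- c(rep(0.25, 272), rep(0.75, 100))   # 272/100 ~ e
  fp2 <- freeEnergy1d(x, nBins = 2, kT = 1)
  expect_equal(diff(fp2@F), log(272 / 100), tolerance = 1e-9)
  expect_equal(min(fp2@F), 0)
  # Boltzmann samples from a quadratic well reproduce the parabola
  set.seed(5)
  z <- rnorm(2e5)                         # V(x) = x^2/2 at kT = 1
  fp3 <- freeEnergy1d(z[abs(z) < 3], nBins = 24)
  ok <- !fp3@mask & abs(fp3@binCenters) < 2
  expect_lt(max(abs((fp3@F - fp3@binCenters^2 / 2)[ok])), 0.15)
})

test_that("curve comparison scores agreement in pooled-error units", {
  # two independent halves of one long chain: Poisson errors, z ~ N(0,1)
  long <- makeFixture("markov_chain", list(T = ref_T3, n = 60000), seed = 6)
  h1 <- seq_of(tokens(long)[1:30000], 3)
  h2 <- seq_of(tokens(long)[30001:60000], 3)
  grid <- 1:10
  agree <- vapply(list(c(0, 1), c(1, 0), c(1, 2)), function(pr)
    compareCurves(commitTimeCounts(h1, pr, grid),
                  commitTimeCounts(h2, pr, grid))$agreement, numeric(1))
  expect_true(all(agree >= 0.9))          # same chain, sampling error only
  ensA <- lapply(1:4, function(i)
    makeFixture("markov_chain", list(T = ref_T3, n = 15000), seed = 60 + i))
  a <- commitTimeCounts(ensA, c(0, 1), grid)
  expect_equal(compareCurves(a, a)$agreement, 1.0)
  # shift one curve by 10 pooled errors everywhere: agreement collapses to 0
  b <- a
  b@counts <- a@counts + 10 * sqrt(2) * pmax(a@stderr, 1e-6)
  expect_equal(compareCurves(a, b)$agreement, 0.0)
  d <- commitTimeCounts(ensA, c(0, 1), 1:5)
  expect_error(compareCurves(a, d), "grids differ")
  expect_error(compareCurves(a, commitTimeCounts(ensA, c(1, 0), grid)),
               "different state pairs")
})

test_that("commit curves of a known chain match an equal-length resimulation", {
  # small ensembles give heavy-tailed (t-like) z values, so judge the
  # agreement jointly across pairs rather than point-by-point
  grid <- 1:8
  ensA <- lapply(1:8, function(i)
    makeFixture("markov_chain", list(T = ref_T3, n = 20000), seed = 200 + i))
  ensB <- lapply(1:8, function(i)
    makeFixture("markov_chain", list(T = ref_T3, n = 20000), seed = 300 + i))
  agree <- vapply(list(c(0, 1), c(1, 2), c(2, 0)), function(pr)
    compareCurves(commitTimeCounts(ensA, pr, grid),
                  commitTimeCounts(ensB, pr, grid))$agreement, numeric(1))
  expect_gte(mean(agree), 0.9)
  expect_gte(min(agree), 0.8)
})
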