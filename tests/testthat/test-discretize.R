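# K-means discretization, binning, and segment planning.

test_that("two separated 1D clusters are assigned by within-cluster SSE", {
  s <- kmeansDiscretize(c(0.0, 0.1, 5.0, 5.1), k = 2, seed = 1)
  # equal populations: tie broken by ascending center coordinate
  expect_equal(tokens(s), c(0L, 0L, 1L, 1L))
  expect_equal(sort(as.numeric(s@labelMap)), c(0.05, 5.05), tolerance = 1e-9)
})

test_that("k = n gives a zero-inertia singleton partition", {
  s <- kmeansDiscretize(c(1, 4, 9, 16), k = 4, seed = 2)
  expect_equal(sort(unique(tokens(s))), 0:3)
  expect_lt(s@meta$inertia, 1e-12)
})

test_that("duplicating every frame leaves the labels unchanged", {
  set.seed(3)
  x <- c(rnorm(30), rnorm(30, 8))
  a <- kmeansDiscretize(x, 2, seed = 5)
  b <- kmeansDiscretize(rep(x, each = 2), 2, seed = 5)
  expect_equal(tokens(b), rep(tokens(a), each = 2))
})

test_that("token histogram equals the cluster populations, deterministically", {
  set.seed(4)
  x <- cbind(rnorm(200), rnorm(200))
  s1 <- kmeansDiscretize(x, 3, seed = 7)
  s2 <- kmeansDiscretize(x, 3, seed = 7)
  expect_identical(tokens(s1), tokens(s2))
  tab <- tabulate(tokens(s1) + 1L, 3)
  expect_true(all(diff(tab) <= 0))      # descending-population relabeling
  expect_equal(sum(tab), 200L)
  expect_true(all(tokens(s1) >= 0 & tokens(s1) < 3))
})

test_that("uniform binning covers the range and keeps every state occupied", {
  set.seed(5)
  x <- rnorm(2000)
  s <- binDiscretize(x, nBins = 25)
  expect_true(all(tabulate(tokens(s) + 1L, nStates(s)) > 0))
  expect_equal(length(tokens(s)), 2000L)
  # bin centers are increasing along the CV
  expect_true(all(diff(s@labelMap[, 1]) > 0))
})

test_that("segments are placed reproducibly with prompts and continuations", {
  s <- as(new("StateSequence", tokens = as.integer(0:999 %% 3), nStates = 3L),
          "StateSequence")
  plan <- segmentPlan(10, 200, seed = 11)
  segs <- segmentSequence(s, plan, promptLength = 16)
  expect_length(segs, 10)
  for (sg in segs) {
    expect_true(sg$start >= 1 && sg$start + 199 <= 1000)
    expect_length(sg$tokens, 200)
    expect_length(sg$train, 120)   # 60% of the segment
    expect_length(sg$prompt, 16)
    expect_identical(sg$prompt, tail(sg$train, 16))
    # continuation starts right after the training portion
    expect_identical(sg$continuation[1], tokens(s)[sg$start + 120])
  }
  segs2 <- segmentSequence(s, plan, promptLength = 16)
  expect_identical(vapply(segs, `[[`, integer(1), "start"),
                   vapply(segs2, `[[`, integer(1), "start"))
  expect_error(segmentSequence(s, segmentPlan(1, 2000)), "exceeds")
})

test_that("state sequences round-trip through the text format", {
  s <- makeFixture("markov_chain", list(T = ref_T3, n = 500), seed = 2)
  f <- tempfile(fileext = ".txt")
  writeStateSequence(s, f)
  back <- readStateSequence(f)
  expect_identical(tokens(back), tokens(s))
  expect_identical(nStates(back), nStates(s))
  writeLines(c("# n_states 2", "0", "x", "1"), f)
  expect_error(readStateSequence(f), "line 2")
})
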