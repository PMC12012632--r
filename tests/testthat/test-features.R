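# Featurization and collective variables.

.traj_from <- function(coords) {
  # coords: [frame, particle, dim] array builder shortcut
  new("Trajectory", frames = coords, dtPerFrame = 1)
}

test_that("pairwise-distance featurization has the combinatorial width", {
  set.seed(1)
  mk <- function(np) .traj_from(array(rnorm(4 * np * 2), c(4, np, 2)))
  expect_equal(ncol(featureValues(pairwiseDistances(mk(20)))), 190L)
  expect_equal(ncol(featureValues(pairwiseDistances(mk(8)))), 28L)
  expect_equal(ncol(featureValues(pairwiseDistances(mk(32),
                                                    seq(1, 29, 4)))), 28L)
})

test_that("distances are Euclidean and invariant to rigid motions", {
  co <- array(0, c(1, 2, 2))
  co[1, 2, ] <- c(3, 4)
  expect_equal(as.numeric(featureValues(pairwiseDistances(.traj_from(co)))), 5)
  set.seed(2)
  co <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  d0 <- featureValues(pairwiseDistances(.traj_from(co)))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- co
  for (f in 1:6) moved[f, , ] <- co[f, , ] %*% R + rep(c(5, -2), each = 5)
  expect_equal(featureValues(pairwiseDistances(.traj_from(moved))), d0,
               tolerance = 1e-12)
  expect_error(pairwiseDistances(.traj_from(co), c(1, 1, 2)), "distinct")
})

test_that("radius of gyration follows its definition", {
  one <- .traj_from(array(rnorm(10), c(5, 1, 2)))
  expect_equal(radiusOfGyration(one), rep(0, 5))
  two <- array(0, c(3, 2, 2))
  for (f in 1:3) two[f, 2, ] <- c(4 * f, 0)
  expect_equal(radiusOfGyration(.traj_from(two)), c(2, 4, 6))
  shifted <- two
  for (f in 1:3) shifted[f, , ] <- two[f, , ] + rep(c(-3, 11), each = 2)
  expect_equal(radiusOfGyration(.traj_from(shifted)),
               radiusOfGyration(.traj_from(two)), tolerance = 1e-12)
})

test_that("FVE handles the exact, mean and hand-computed cases", {
  X <- matrix(c(0, 2), 2, 1)
  expect_equal(fveScore(X, X), 1)
  expect_equal(fveScore(X, matrix(1, 2, 1)), 0)   # column-mean prediction
  expect_equal(fveScore(X, matrix(c(0, 1), 2, 1)), 0.5)  # 1 - 1/2
  set.seed(3)
  Y <- matrix(rnorm(20), 5, 4)
  expect_equal(fveScore(Y, sweep(Y * 0, 2, colMeans(Y), "+")), 0,
               tolerance = 1e-12)
  expect_error(fveScore(matrix(1, 4, 2), matrix(1, 4, 2)), "zero total variance")
  expect_error(fveScore(Y, Y[1:4, ]), "same shape")
})

test_that("autoencoder recovers an exactly low-dimensional subspace", {
  set.seed(7)
  Z <- matrix(rnorm(2 * 600), 600, 2)
  X <- Z %*% matrix(rnorm(2 * 6), 2, 6)         # rank-2 data, 6 features
  ae <- trainAutoencoder(X, autoencoderSpec(latentDim = 2, epochs = 120,
                                            batchSize = 64, seed = 2))
  expect_gte(ae@fve, 0.99)
  # training reduced the loss and beats untrained (frozen random) weights
  expect_lt(tail(ae@trainingCurve$loss, 1), ae@trainingCurve$loss[1])
  frozen <- trainAutoencoder(X, autoencoderSpec(latentDim = 2, epochs = 1,
                                                batchSize = 64, seed = 2))
  expect_gt(ae@fve, frozen@fve)
})

test_that("a linear autoencoder approaches the PCA optimum", {
  set.seed(8)
  X <- matrix(rnorm(400 * 5), 400, 5) %*% diag(c(3, 2, 1, 0.5, 0.2))
  L <- 2
  ae <- trainAutoencoder(X, autoencoderSpec(latentDim = L, hiddenLayers = 4L,
                                            activation = "linear",
                                            epochs = 300, batchSize = 50,
                                            seed = 4))
  Xs <- scale(X)
  pc <- prcomp(Xs)
  pca_ev <- sum(pc$sdev[1:L]^2) / sum(pc$sdev^2)  # PCA explained variance
  expect_gt(ae@fve, pca_ev - 0.02)
})

test_that("encoding returns one latent coordinate set per frame", {
  set.seed(9)
  X <- cbind(matrix(rnorm(300), 150, 2) %*% matrix(rnorm(6), 2, 3))
  ae <- trainAutoencoder(X, autoencoderSpec(latentDim = 2, epochs = 40,
                                            batchSize = 32, seed = 1))
  cv <- encodeFeatures(ae, X)
  expect_s4_class(cv, "CVTrajectory")
  expect_equal(dim(cvValues(cv)), c(150L, 2L))
  expect_equal(fve(cv), ae@fve)
  expect_error(trainAutoencoder(X, autoencoderSpec(latentDim = 3)), "smaller")
})
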