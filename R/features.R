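## Featurization and collective variables: pairwise distances, radius of
## gyration, and an encoder-decoder autoencoder scored by the fraction of
## variation explained (FVE).

#' Pairwise-distance features
#'
#' Euclidean distances between all pairs of the selected particles, one
#' feature per unordered pair, ordered lexicographically by index pair:
#' 20 selected particles give choose(20, 2) = 190 features, 8 give 28.
#'
#' @param traj a [Trajectory-class].
#' @param selection integer indices (1-based) of the particles to use;
#'   default all.  For the 32-bead chain the published choice is 8 beads in
#'   arithmetic progression with step 4: \code{seq(1, 29, by = 4)}.
#' @return a [FeatureMatrix-class] with \code{choose(k, 2)} columns.
#' @export
pairwiseDistances <- function(traj, selection = NULL) {
  stopifnot(is(traj, "Trajectory"))
  fr <- frames(traj)
  np <- dim(fr)[2]
  if (is.null(selection)) selection <- seq_len(np)
  selection <- as.integer(selection)
  if (anyDuplicated(selection) || any(selection < 1L | selection > np))
    stop("selection indices must be distinct and within 1..nParticles")
  k <- length(selection)
  if (k < 2L) stop("need at least two selected particles")
  pairs <- utils::combn(selection, 2L)
  vals <- matrix(0, dim(fr)[1], ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    d2 <- 0
    for (dd in seq_len(dim(fr)[3])) d2 <- d2 + (fr[, i, dd] - fr[, j, dd])^2
    vals[, c] <- sqrt(d2)
  }
  new("FeatureMatrix", values = vals,
      featureNames = sprintf("d_%d_%d", pairs[1, ], pairs[2, ]),
      source = list(mode = "pairdist", selection = selection))
}

#' Radius of gyration per frame
#'
#' \code{Rg(t) = sqrt(mean_i |r_i - r_cm|^2)} with equal masses.
#'
#' @param traj a [Trajectory-class].
#' @return numeric vector, one value per frame.
#' @export
radiusOfGyration <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  fr <- frames(traj)
  d <- dim(fr)
  out <- numeric(d[1])
  for (dd in seq_len(d[3])) {
    x <- fr[, , dd, drop = FALSE][, , 1]
    if (d[2] == 1L) x <- matrix(x, ncol = 1)
    out <- out + rowMeans((x - rowMeans(x))^2)
  }
  sqrt(out)
}

#' Fraction of variation explained
#'
#' \code{FVE = 1 - sum_i ||X(i) - Y(i)||^2 / sum_i ||X(i) - Xbar||^2} with
#' \code{Xbar} the column-mean frame of \code{X}.  1 for a perfect
#' reconstruction, 0 when \code{Y} is the mean frame, negative for worse.
#'
#' @param X input features: matrix or [FeatureMatrix-class].
#' @param Y reconstruction of the same shape.
#' @return a single number in \code{(-Inf, 1]}.
#' @export
fveScore <- function(X, Y) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  if (is(Y, "FeatureMatrix")) Y <- featureValues(Y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!identical(dim(X), dim(Y))) stop("X and Y must have the same shape")
  tot <- sum(sweep(X, 2, colMeans(X), "-")^2)
  if (tot == 0) stop("degenerate input: X has zero total variance")
  1 - sum((X - Y)^2) / tot
}

#' Autoencoder configuration
#'
#' Symmetric encoder/decoder around a linear latent layer.  Defaults:
#' two hidden layers of widths \code{max(16, n_features)} and 16 with tanh
#' activations, linear latent and output layers, adaptive-moment training at
#' learning rate 1e-3.
#'
#' @param latentDim latent dimension (>= 1, < n_features at train time).
#' @param hiddenLayers integer widths of the encoder hidden layers (mirrored
#'   in the decoder); \code{NULL} for the default.
#' @param activation \code{"tanh"} or \code{"linear"} hidden activation.
#' @param epochs passes over the training data.
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param seed RNG seed for initialization and batch shuffling.
#' @export
autoencoderSpec <- function(latentDim = 2L, hiddenLayers = NULL,
                            activation = c("tanh", "linear"), epochs = 30L,
                            learningRate = 1e-3, batchSize = 256L, seed = 1L) {
  activation <- match.arg(activation)
  if (latentDim < 1L) stop("latentDim must be >= 1")
  structure(list(latent_dim = as.integer(latentDim),
                 hidden_layers = hiddenLayers, activation = activation,
                 epochs = as.integer(epochs), learning_rate = learningRate,
                 batch_size = as.integer(batchSize), seed = as.integer(seed)),
            class = c("AutoencoderSpec", "list"))
}

#' Trained autoencoder
#'
#' @slot layers list of dense layers (weights, biases, activation).
#' @slot nEncoderLayers how many leading layers form the encoder.
#' @slot center,scale per-feature standardization applied before training.
#' @slot spec the [autoencoderSpec()] used.
#' @slot fve fraction of variation explained on the (standardized) training
#'   features.
#' @slot trainingCurve data.frame with columns epoch, loss.
#' @export
setClass("Autoencoder",
  representation(layers = "list", nEncoderLayers = "integer",
                 center = "numeric", scale = "numeric", spec = "list",
                 fve = "numeric", trainingCurve = "data.frame"))

setMethod("show", "Autoencoder", function(object) {
  cat(sprintf("Autoencoder: %d -> %d latent, FVE = %.4f (training set)\n",
              length(object@center), object@spec$latent_dim, object@fve))
})

#' Train an autoencoder on a feature matrix
#'
#' Features are z-scored per column, then a symmetric encoder/decoder MLP is
#' trained with minibatch Adam to minimize mean squared reconstruction error.
#' The reported FVE is computed on the standardized training features.
#'
#' @param features a [FeatureMatrix-class] or numeric matrix.
#' @param spec an [autoencoderSpec()].
#' @return an [Autoencoder-class].
#' @export
trainAutoencoder <- function(features, spec = autoencoderSpec()) {
  X <- if (is(features, "FeatureMatrix")) featureValues(features) else as.matrix(features)
  nf <- ncol(X); n <- nrow(X)
  if (spec$latent_dim >= nf)
    stop("latentDim must be smaller than the number of features")
  if (n <= spec$batch_size)
    stop("need more frames than the batch size")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  hidden <- spec$hidden_layers
  if (is.null(hidden)) hidden <- c(max(16L, nf), 16L)
  widths <- c(nf, hidden, spec$latent_dim, rev(hidden), nf)
  acts <- c(rep(spec$activation, length(hidden)), "linear",
            rep(spec$activation, length(hidden)), "linear")
  nEnc <- length(hidden) + 1L
  withSeed(spec$seed, {
    layers <- mlp_init(widths, acts)
    flat <- flatten_layers(layers)
    st <- adam_init(flat)
    curve <- numeric(spec$epochs)
    nb <- floor(n / spec$batch_size)
    for (ep in seq_len(spec$epochs)) {
      idx <- sample.int(n)
      eploss <- 0
      for (b in seq_len(nb)) {
        rows <- idx[((b - 1) * spec$batch_size + 1):(b * spec$batch_size)]
        Xb <- Xs[rows, , drop = FALSE]
        fw <- mlp_forward(layers, Xb)
        err <- fw$out - Xb
        loss <- mean(err^2)
        if (!is.finite(loss)) stop("training diverged: non-finite loss")
        eploss <- eploss + loss
        grads <- mlp_backward(layers, fw$caches, 2 * err / length(err))
        gflat <- flatten_layers(grads)
        up <- adam_step(flat, gflat, st, spec$learning_rate)
        flat <- up$params; st <- up$state
        layers <- unflatten_layers(flat, layers)
      }
      curve[ep] <- eploss / nb
    }
    rec <- mlp_forward(layers, Xs)$out
    new("Autoencoder", layers = layers, nEncoderLayers = nEnc,
        center = ctr, scale = scl, spec = unclass(spec),
        fve = fveScore(Xs, rec),
        trainingCurve = data.frame(epoch = seq_len(spec$epochs), loss = curve))
  })
}

#' Encode features into latent collective variables
#'
#' @param ae a trained [Autoencoder-class].
#' @param features features with the same columns as at training.
#' @return a [CVTrajectory-class] whose columns are the latent coordinates
#'   (the first two are the conventional CV pair for free-energy surfaces).
#' @export
encodeFeatures <- function(ae, features) {
  X <- if (is(features, "FeatureMatrix")) featureValues(features) else as.matrix(features)
  Xs <- sweep(sweep(X, 2, ae@center, "-"), 2, ae@scale, "/")
  A <- Xs
  for (l in seq_len(ae@nEncoderLayers))
    A <- .act_fwd(sweep(A %*% ae@layers[[l]]$W, 2, ae@layers[[l]]$b, "+"),
                  ae@layers[[l]]$act)
  new("CVTrajectory", values = A, fve = ae@fve,
      encoderRef = list(latent_dim = ae@spec$latent_dim))
}

#' Reconstruct features through the full autoencoder
#'
#' Returns the reconstruction on the standardized scale, the scale on which
#' FVE is defined.
#'
#' @inheritParams encodeFeatures
#' @export
reconstructFeatures <- function(ae, features) {
  X <- if (is(features, "FeatureMatrix")) featureValues(features) else as.matrix(features)
  Xs <- sweep(sweep(X, 2, ae@center, "-"), 2, ae@scale, "/")
  mlp_forward(ae@layers, Xs)$out
}
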