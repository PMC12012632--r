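## Core S4 containers.  Trajectories hold continuous coordinates; state
## sequences hold the discretized tokens that every downstream module speaks.

#' Trajectory of particle coordinates
#'
#' Time-ordered frames of particle coordinates from a Brownian-dynamics
#' simulation (or supplied by the user), with the time spacing between
#' saved frames in reduced Brownian-time units.
#'
#' @slot frames numeric array \code{[n_frames, n_particles, dims]}.
#' @slot dtPerFrame time between saved frames (tau_BD units).
#' @slot meta provenance list (system spec, integrator settings, seed).
#' @export
setClass("Trajectory",
  representation(frames = "array", dtPerFrame = "numeric", meta = "list"),
  prototype(dtPerFrame = 1, meta = list()))

setValidity("Trajectory", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3D array [frame, particle, dim]")
  if (!all(is.finite(object@frames))) return("non-finite coordinates in frames")
  if (length(object@dtPerFrame) != 1L || object@dtPerFrame <= 0)
    return("dtPerFrame must be a single positive number")
  TRUE
})

#' Feature matrix derived from a trajectory
#'
#' @slot values numeric matrix \code{[n_frames, n_features]}.
#' @slot featureNames character labels, one per column.
#' @slot source provenance list.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", featureNames = "character",
                 source = "list"),
  prototype(source = list()))

setValidity("FeatureMatrix", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (length(object@featureNames) &&
      length(object@featureNames) != ncol(object@values))
    return("featureNames length must match the number of columns")
  TRUE
})

#' Collective-variable trajectory
#'
#' Low-dimensional projection of a feature matrix (autoencoder latent
#' coordinates, radius of gyration, ...), with the fraction of variation
#' explained by the generating model when one applies.
#'
#' @slot values numeric matrix \code{[n_frames, latent_dim]}.
#' @slot fve fraction of variation explained on the training set
#'   (\code{NA} when the CV is not a learned reconstruction).
#' @slot encoderRef provenance list.
#' @export
setClass("CVTrajectory",
  representation(values = "matrix", fve = "numeric", encoderRef = "list"),
  prototype(fve = NA_real_, encoderRef = list()))

setValidity("CVTrajectory", function(object) {
  if (!all(is.finite(object@values))) return("non-finite CV values")
  TRUE
})

#' Discrete state sequence (token sequence)
#'
#' Integer tokens in \code{[0, nStates)}, the lingua franca between the
#' discretization, sequence-model, generation and kinetics modules.
#'
#' @slot tokens integer vector of states, 0-based.
#' @slot nStates vocabulary size.
#' @slot dtPerFrame time per token (tau_BD units).
#' @slot labelMap matrix of cluster centers (one row per state) or a
#'   0-row matrix when no center information exists.
#' @slot meta provenance list.
#' @export
setClass("StateSequence",
  representation(tokens = "integer", nStates = "integer",
                 dtPerFrame = "numeric", labelMap = "matrix", meta = "list"),
  prototype(dtPerFrame = 1, labelMap = matrix(numeric(), 0, 0), meta = list()))

setValidity("StateSequence", function(object) {
  if (length(object@nStates) != 1L || object@nStates < 1L)
    return("nStates must be a single positive integer")
  if (length(object@tokens) &&
      (min(object@tokens) < 0L || max(object@tokens) >= object@nStates))
    return("tokens must lie in [0, nStates)")
  TRUE
})

#' Trained autoregressive sequence model (virtual)
#'
#' Common contract of the transformer and LSTM models: a configuration, a
#' vocabulary, trained weights, and a per-epoch loss history.  Both expose
#' [nextTokenProbs()] and can be passed to [generateTokens()].
#'
#' @slot config model configuration list.
#' @slot params named list of weight matrices.
#' @slot vocabSize number of states in the vocabulary.
#' @slot lossHistory data.frame with columns epoch, trainLoss, valLoss.
#' @export
setClass("SequenceModel",
  representation("VIRTUAL", config = "list", params = "list",
                 vocabSize = "integer", lossHistory = "data.frame"))

#' Decoder-only transformer model
#' @export
setClass("GPTModel", contains = "SequenceModel")

#' LSTM baseline sequence model
#' @export
setClass("LSTMModel", contains = "SequenceModel")

#' Averaged masked attention map
#'
#' @slot scores matrix \code{[l, l]}; entries above the diagonal are masked
#'   and reported as zero.
#' @slot averaging list recording the numbers of heads, chunks and the block.
#' @export
setClass("AttentionMap",
  representation(scores = "matrix", averaging = "list"))

#' Ensemble of generated state sequences
#'
#' @slot sequences list of [StateSequence-class] objects sharing a vocabulary.
#' @slot seeds per-member RNG seeds derived from the master seed.
#' @slot meta provenance list (model references, master seed).
#' @export
setClass("GeneratedEnsemble",
  representation(sequences = "list", seeds = "integer", meta = "list"))

setValidity("GeneratedEnsemble", function(object) {
  if (!length(object@sequences)) return("empty ensemble")
  ns <- vapply(object@sequences, function(s) s@nStates, integer(1))
  if (length(unique(ns)) != 1L) return("members must share a vocabulary")
  TRUE
})

#' Commit-time transition-count curve
#'
#' Counts of i -> j transitions filtered by commit time: a transition is
#' counted at commit time tau only when both the dwell before and after the
#' crossing last at least tau frames (symmetric rule; a pre-dwell-only rule
#' is available).  Curves are non-increasing in tau by construction.
#'
#' @slot pair ordered integer pair (from, to).
#' @slot commitTimes commit-time grid in frames.
#' @slot counts ensemble-mean counts, normalized per 1e4 frames.
#' @slot stderr standard error over ensemble members (Poisson-based for a
#'   single sequence).
#' @slot perMember matrix \code{[n_members, n_grid]} of normalized counts.
#' @slot dtPerFrame time per frame, to express the grid in tau_BD.
#' @slot meta list: counting rule, raw totals, sequence lengths.
#' @export
setClass("TransitionCountCurve",
  representation(pair = "integer", commitTimes = "numeric",
                 counts = "numeric", stderr = "numeric",
                 perMember = "matrix", dtPerFrame = "numeric", meta = "list"))

setValidity("TransitionCountCurve", function(object) {
  if (length(object@pair) != 2L || object@pair[1] == object@pair[2])
    return("pair must be two distinct states")
  if (any(diff(object@counts) > 1e-9))
    return("counts must be non-increasing in commit time")
  TRUE
})

#' One-dimensional free-energy profile
#'
#' \code{F = -kT log P} from a histogram along a collective variable, shifted
#' so the minimum is zero; empty bins are masked, not interpolated.
#'
#' @slot binCenters bin centers in CV units.
#' @slot F free energy in kT units (\code{NA} for masked bins).
#' @slot mask logical, \code{TRUE} where the bin is empty.
#' @slot kT thermal energy used for the conversion.
#' @export
setClass("FreeEnergyProfile",
  representation(binCenters = "numeric", F = "numeric", mask = "logical",
                 kT = "numeric"))

#' Markov state model estimated from a token sequence
#'
#' @slot lag lag time in frames.
#' @slot countMatrix sliding-window transition counts on the active state set.
#' @slot transitionMatrix row-stochastic transition matrix.
#' @slot states original state labels of the active (largest strongly
#'   connected) set; rows/columns of the matrices follow this order.
#' @slot dropped state labels excluded as not strongly connected.
#' @slot reversible whether reversible (detailed-balance) estimation was used.
#' @export
setClass("MarkovModel",
  representation(lag = "integer", countMatrix = "matrix",
                 transitionMatrix = "matrix", states = "integer",
                 dropped = "integer", reversible = "logical"))

setValidity("MarkovModel", function(object) {
  Tm <- object@transitionMatrix
  if (nrow(Tm) != ncol(Tm)) return("transition matrix must be square")
  if (any(abs(rowSums(Tm) - 1) > 1e-12)) return("rows must sum to 1")
  if (any(Tm < -1e-15)) return("negative transition probabilities")
  TRUE
})
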