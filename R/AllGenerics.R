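#' @name kinseq-accessors
#' @title Accessors for kinseq containers
#' @description Slot accessors for the core S4 classes; user code should use
#'   these rather than reaching into slots.
#' @param object a kinseq S4 object.
NULL

#' @rdname kinseq-accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname kinseq-accessors
#' @export
setGeneric("dtPerFrame", function(object) standardGeneric("dtPerFrame"))
#' @rdname kinseq-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname kinseq-accessors
#' @export
setGeneric("nParticles", function(object) standardGeneric("nParticles"))
#' @rdname kinseq-accessors
#' @export
setGeneric("tokens", function(object) standardGeneric("tokens"))
#' @rdname kinseq-accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @rdname kinseq-accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname kinseq-accessors
#' @export
setGeneric("cvValues", function(object) standardGeneric("cvValues"))
#' @rdname kinseq-accessors
#' @export
setGeneric("fve", function(object) standardGeneric("fve"))
#' @rdname kinseq-accessors
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))
#' @rdname kinseq-accessors
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))
#' @rdname kinseq-accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))
#' @rdname kinseq-accessors
#' @export
setGeneric("countMatrix", function(object) standardGeneric("countMatrix"))
#' @rdname kinseq-accessors
#' @export
setGeneric("activeStates", function(object) standardGeneric("activeStates"))
#' @rdname kinseq-accessors
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))
#' @rdname kinseq-accessors
#' @export
setGeneric("attentionMatrix", function(object) standardGeneric("attentionMatrix"))

#' Per-position next-token distributions
#'
#' Runs the model forward (deterministic evaluation mode) on a token window
#' and returns one categorical distribution over the vocabulary per input
#' position: row \code{t} is the model's distribution for the token following
#' position \code{t}.  Rows sum to 1; causality guarantees row \code{t}
#' depends only on tokens at positions \code{<= t}.
#'
#' @param model a trained [SequenceModel-class] (GPT or LSTM).
#' @param tokens integer vector of tokens (0-based), at most
#'   \code{blockSize} long for the transformer.
#' @return numeric matrix \code{[length(tokens), vocabSize]}.
#' @export
setGeneric("nextTokenProbs", function(model, tokens) standardGeneric("nextTokenProbs"))

## ---- methods ----

#' @rdname kinseq-accessors
#' @export
setMethod("frames", "Trajectory", function(object) object@frames)
#' @rdname kinseq-accessors
#' @export
setMethod("dtPerFrame", "Trajectory", function(object) object@dtPerFrame)
#' @rdname kinseq-accessors
#' @export
setMethod("dtPerFrame", "StateSequence", function(object) object@dtPerFrame)
#' @rdname kinseq-accessors
#' @export
setMethod("nFrames", "Trajectory", function(object) dim(object@frames)[1])
#' @rdname kinseq-accessors
#' @export
setMethod("nParticles", "Trajectory", function(object) dim(object@frames)[2])
#' @rdname kinseq-accessors
#' @export
setMethod("tokens", "StateSequence", function(object) object@tokens)
#' @rdname kinseq-accessors
#' @export
setMethod("nStates", "StateSequence", function(object) object@nStates)
#' @rdname kinseq-accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)
#' @rdname kinseq-accessors
#' @export
setMethod("cvValues", "CVTrajectory", function(object) object@values)
#' @rdname kinseq-accessors
#' @export
setMethod("fve", "CVTrajectory", function(object) object@fve)
#' @rdname kinseq-accessors
#' @export
setMethod("modelConfig", "SequenceModel", function(object) object@config)
#' @rdname kinseq-accessors
#' @export
setMethod("lossHistory", "SequenceModel", function(object) object@lossHistory)
#' @rdname kinseq-accessors
#' @export
setMethod("transitionMatrix", "MarkovModel", function(object) object@transitionMatrix)
#' @rdname kinseq-accessors
#' @export
setMethod("countMatrix", "MarkovModel", function(object) object@countMatrix)
#' @rdname kinseq-accessors
#' @export
setMethod("activeStates", "MarkovModel", function(object) object@states)
#' @rdname kinseq-accessors
#' @export
setMethod("sequences", "GeneratedEnsemble", function(object) object@sequences)
#' @rdname kinseq-accessors
#' @export
setMethod("attentionMatrix", "AttentionMap", function(object) object@scores)

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Trajectory: %d frames, %d particle(s), %dD, dt/frame = %g tau_BD\n",
              d[1], d[2], d[3], object@dtPerFrame))
})

setMethod("show", "StateSequence", function(object) {
  cat(sprintf("StateSequence: %d tokens over %d states, dt/frame = %g\n",
              length(object@tokens), object@nStates, object@dtPerFrame))
  if (length(object@tokens)) {
    tab <- tabulate(object@tokens + 1L, nbins = object@nStates)
    cat("  occupancy:", paste(sprintf("%d:%.3f", seq_along(tab) - 1L,
                                      tab / length(object@tokens)),
                              collapse = " "), "\n")
  }
})

setMethod("show", "GPTModel", function(object) {
  c <- object@config
  cat(sprintf(paste0("GPTModel: vocab %d, d=%d, heads=%d, blocks=%d, ",
                     "context=%d, attention %s\n"),
              object@vocabSize, c$embed_dim, c$n_heads, c$n_blocks,
              c$block_size, if (c$attention_enabled) "on" else "ablated"))
  if (nrow(object@lossHistory))
    cat(sprintf("  final train loss %.4f\n",
                tail(object@lossHistory$trainLoss, 1)))
})

setMethod("show", "LSTMModel", function(object) {
  c <- object@config
  cat(sprintf("LSTMModel: vocab %d, embed=%d, hidden=%d\n",
              object@vocabSize, c$embed_dim, c$hidden_dim))
})

setMethod("show", "MarkovModel", function(object) {
  cat(sprintf("MarkovModel: lag %d, %d active state(s)%s\n", object@lag,
              length(object@states),
              if (object@reversible) ", reversible" else ""))
  if (length(object@dropped))
    cat("  dropped states:", paste(object@dropped, collapse = ", "), "\n")
})

setMethod("show", "TransitionCountCurve", function(object) {
  cat(sprintf("TransitionCountCurve %d->%d: %d commit times, count(tau=1) = %.2f per 1e4 frames\n",
              object@pair[1], object@pair[2], length(object@commitTimes),
              object@counts[1]))
})

setMethod("show", "GeneratedEnsemble", function(object) {
  cat(sprintf("GeneratedEnsemble: %d sequence(s) of %s tokens\n",
              length(object@sequences),
              paste(unique(vapply(object@sequences,
                                  function(s) length(s@tokens), integer(1))),
                    collapse = "/")))
})
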