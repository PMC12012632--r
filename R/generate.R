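## Autoregressive multinomial generation of future state tokens, single-model
## and ensembled over independently trained models.

#' Generate future state tokens from a trained model
#'
#' Iteratively samples the next token from the model's distribution at the
#' last position of the current context (multinomial at temperature 1 by
#' default), appends it, and slides the context window.  A generated
#' sequence can never contain a token outside the training vocabulary.
#'
#' @param model a trained [SequenceModel-class] (GPT or LSTM).
#' @param prompt non-empty integer token vector; a prompt longer than the
#'   context window is truncated to its trailing block (with a warning).
#' @param nTokens number of new tokens to generate (the prompt is excluded
#'   from the output).
#' @param seed RNG seed; identical (model, prompt, nTokens, seed) give
#'   identical output.
#' @param temperature softmax temperature (1 = the model's distribution).
#' @param dtPerFrame frame time attached to the output sequence.
#' @return a [StateSequence-class] of exactly \code{nTokens} tokens.
#' @export
generateTokens <- function(model, prompt, nTokens, seed = NULL,
                           temperature = 1, dtPerFrame = 1) {
  stopifnot(is(model, "SequenceModel"))
  prompt <- as.integer(prompt)
  if (!length(prompt)) stop("prompt must be non-empty")
  if (any(prompt < 0L | prompt >= model@vocabSize))
    stop("prompt token outside the model vocabulary")
  if (nTokens < 1L) stop("nTokens must be >= 1")
  if (is(model, "GPTModel") && length(prompt) > model@config$block_size) {
    warning("prompt longer than the context window; using its trailing block")
    prompt <- tail(prompt, model@config$block_size)
  }
  toks <- withSeed(seed, {
    if (is(model, "GPTModel"))
      as.integer(gpt_generate_cpp(model@params, model@config, prompt,
                                  as.integer(nTokens), temperature))
    else
      lstm_generate_tokens(model, prompt, as.integer(nTokens), temperature)
  })
  as_state_sequence(toks, model@vocabSize, dtPerFrame,
                    meta = list(prompt_length = length(prompt), seed = seed))
}

#' Generate an ensemble of sequences from independently trained models
#'
#' One sequence per (model, prompt) pair, with per-member RNG seeds derived
#' deterministically from a master seed so members are independent yet
#' reproducible.  Downstream statistics are reported as mean +/- standard
#' error over the members.
#'
#' @param models list of trained [SequenceModel-class] objects (one per
#'   training segment).
#' @param prompts list of prompts, one per model (e.g. the trailing block of
#'   each model's training segment).
#' @param nTokens new tokens per member.
#' @param masterSeed master RNG seed.
#' @param temperature softmax temperature.
#' @param dtPerFrame frame time attached to the members.
#' @return a [GeneratedEnsemble-class].
#' @export
generateEnsemble <- function(models, prompts, nTokens, masterSeed = 1L,
                             temperature = 1, dtPerFrame = 1) {
  if (!is.list(models)) models <- list(models)
  if (!is.list(prompts)) prompts <- list(prompts)
  if (length(models) != length(prompts))
    stop("need exactly one prompt per model")
  vs <- unique(vapply(models, function(m) m@vocabSize, integer(1)))
  if (length(vs) != 1L) stop("models must share a vocabulary")
  seeds <- deriveSeeds(masterSeed, length(models))
  seqs <- vector("list", length(models))
  for (i in seq_along(models))
    seqs[[i]] <- generateTokens(models[[i]], prompts[[i]], nTokens,
                                seed = seeds[i], temperature = temperature,
                                dtPerFrame = dtPerFrame)
  new("GeneratedEnsemble", sequences = seqs, seeds = as.integer(seeds),
      meta = list(master_seed = masterSeed, n_tokens = nTokens,
                  model_classes = vapply(models, function(m) class(m)[1],
                                         character(1))))
}
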