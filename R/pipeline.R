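## End-to-end pipeline driver: simulate -> featurize -> discretize ->
## train (x n_s) -> generate -> kinetics -> baselines, with a run manifest
## that records config, seeds and output digests and allows finished stages
## to be skipped on re-run.

.pipeline_allowed <- list(
  top = c("system", "seed", "simulate", "featurize", "cv", "discretize",
          "segments", "model", "generate", "kinetics", "baselines"),
  simulate = c("n_steps", "save_stride", "dt", "gamma", "kT", "propulsion",
               "n_beads", "x0"),
  featurize = c("mode", "selection"),
  cv = c("latent_dim", "epochs", "batch_size", "learning_rate", "hidden_layers"),
  discretize = c("k", "nstart"),
  segments = c("n_segments", "segment_length", "prompt_length", "split"),
  model = c("embed_dim", "n_heads", "n_blocks", "block_size", "epochs",
            "learning_rate", "batch_size", "dropout", "attention_enabled"),
  generate = c("n_tokens", "temperature"),
  kinetics = c("rule", "commit_max"),
  baselines = c("msm_lags", "lstm", "lstm_epochs"))

.validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), .pipeline_allowed$top)
  if (length(bad)) stop("unknown config key: ", bad[1], call. = FALSE)
  for (sec in intersect(names(cfg), names(.pipeline_allowed))) {
    if (sec == "top") next
    bad <- setdiff(names(cfg[[sec]]), .pipeline_allowed[[sec]])
    if (length(bad))
      stop(sprintf("unknown config key: %s.%s", sec, bad[1]), call. = FALSE)
  }
  if (is.null(cfg$system) ||
      !cfg$system %in% c("three_state", "four_state", "polymer"))
    stop("config must set system to three_state, four_state or polymer",
         call. = FALSE)
  cfg
}

.manifest_path <- function(outDir) file.path(outDir, "manifest.json")

.load_manifest <- function(outDir) {
  p <- .manifest_path(outDir)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else
    list(stages = list())
}

.save_manifest <- function(man, outDir) {
  jsonlite::write_json(man, .manifest_path(outDir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.stage_done <- function(man, name, digest, files) {
  st <- man$stages[[name]]
  !is.null(st) && identical(st$config_digest, digest) &&
    all(file.exists(files))
}

.cfg_digest <- function(cfg) {
  # order-independent structural digest; no package dependency on digest()
  paste(utils::capture.output(utils::str(cfg[order(names(cfg))])), collapse = "|")
}

#' Run the full sequence-generation pipeline
#'
#' Executes simulate, featurize, discretize, per-segment model training,
#' generation, kinetic evaluation and baselines according to a YAML (or
#' list) configuration, writing all outputs plus a run manifest into
#' \code{outDir}.  Re-running with an identical configuration skips stages
#' whose outputs already exist.
#'
#' @param config path to a YAML file or a configuration list.  Mandatory
#'   key: \code{system} (\code{three_state}, \code{four_state} or
#'   \code{polymer}); every stage section is optional with desk-scale
#'   defaults.  Unknown keys raise an error naming the key.
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with the main in-memory artifacts (source
#'   sequence, models, generated ensemble, reports).
#' @export
runPipeline <- function(config, outDir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- .validate_config(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  man <- .load_manifest(outDir)
  digest <- .cfg_digest(cfg)
  seed <- cfg$seed %||% 1L
  seeds <- deriveSeeds(seed, 6L)
  mark <- function(name, files) {
    man$stages[[name]] <<- list(config_digest = digest, files = files,
                                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    .save_manifest(man, outDir)
  }

  ## --- simulate ---
  trajFile <- file.path(outDir, "trajectory.npy")
  sim <- cfg$simulate %||% list()
  if (!.stage_done(man, "simulate", digest, trajFile)) {
    traj <- if (cfg$system == "polymer") {
      spec <- polymerSpec(nBeads = sim$n_beads %||% 32L,
                          propulsion = sim$propulsion %||% 5.0)
      integ <- integratorSpec(dt = sim$dt %||% 0.001,
                              gamma = sim$gamma %||% 200,
                              kT = sim$kT %||% 1,
                              nSteps = sim$n_steps %||% 200000L,
                              saveStride = sim$save_stride %||% 100L,
                              seed = seeds[1])
      runBDPolymer(spec, integ)
    } else {
      spec <- toyPotentialSpec(cfg$system)
      integ <- integratorSpec(dt = sim$dt %||% 0.01,
                              gamma = sim$gamma %||% 1,
                              kT = sim$kT %||% 0.2,
                              nSteps = sim$n_steps %||% 200000L,
                              saveStride = sim$save_stride %||% 10L,
                              seed = seeds[1])
      runBDToy(spec, integ, x0 = sim$x0)
    }
    writeTrajectory(traj, trajFile)
    mark("simulate", trajFile)
  } else traj <- readTrajectory(trajFile)

  ## --- featurize + CV ---
  feat <- cfg$featurize %||%
    list(mode = if (cfg$system == "polymer") "pairdist" else "coords")
  cvFile <- file.path(outDir, "cv.npy")
  if (!.stage_done(man, "featurize", digest, cvFile)) {
    cvVals <- switch(feat$mode,
      coords = frames(traj)[, 1, ],
      rg = matrix(radiusOfGyration(traj), ncol = 1),
      pairdist = {
        sel <- feat$selection %||% seq(1, nParticles(traj), by = 4)
        fm <- pairwiseDistances(traj, sel)
        aecfg <- cfg$cv %||% list()
        ae <- trainAutoencoder(fm, autoencoderSpec(
          latentDim = aecfg$latent_dim %||% 2L,
          epochs = aecfg$epochs %||% 15L,
          batchSize = aecfg$batch_size %||% 256L,
          learningRate = aecfg$learning_rate %||% 1e-3,
          seed = seeds[2]))
        cv <- encodeFeatures(ae, fm)
        jsonlite::write_json(list(fve = ae@fve,
                                  curve = ae@trainingCurve$loss),
                             file.path(outDir, "cv_report.json"),
                             auto_unbox = TRUE, digits = NA)
        cvValues(cv)
      },
      stop("unknown featurize mode: ", feat$mode))
    if (is.null(dim(cvVals))) cvVals <- matrix(cvVals, ncol = 1)
    npyWrite(cvVals, cvFile)
    mark("featurize", cvFile)
  } else cvVals <- npyRead(cvFile)
  if (is.null(dim(cvVals))) cvVals <- matrix(cvVals, ncol = 1)

  ## --- discretize ---
  statesFile <- file.path(outDir, "states.txt")
  kDefault <- c(three_state = 3L, four_state = 4L, polymer = 2L)[[cfg$system]]
  if (!.stage_done(man, "discretize", digest, statesFile)) {
    sseq <- kmeansDiscretize(cvVals, k = (cfg$discretize %||% list())$k %||% kDefault,
                             seed = seeds[3], dtPerFrame = dtPerFrame(traj))
    writeStateSequence(sseq, statesFile)
    mark("discretize", statesFile)
  } else sseq <- readStateSequence(statesFile)

  ## --- segment + train ---
  segc <- cfg$segments %||% list()
  nSeg <- segc$n_segments %||% 3L
  segLen <- segc$segment_length %||% max(1000L, floor(length(tokens(sseq)) * 0.5))
  plan <- segmentPlan(nSeg, segLen, seed = seeds[4])
  segs <- segmentSequence(sseq, plan,
                          promptLength = segc$prompt_length %||% 64L)
  mc <- cfg$model %||% list()
  modelFiles <- file.path(outDir, sprintf("model_%02d.rds", seq_len(nSeg)))
  if (!.stage_done(man, "train", digest, modelFiles)) {
    mseeds <- deriveSeeds(seeds[5], nSeg)
    models <- lapply(seq_len(nSeg), function(i) {
      cfgM <- gptConfig(vocabSize = nStates(sseq),
                        embedDim = mc$embed_dim %||% 32L,
                        nHeads = mc$n_heads %||% 4L,
                        nBlocks = mc$n_blocks %||% 2L,
                        blockSize = mc$block_size %||% 64L,
                        epochs = mc$epochs %||% 500L,
                        learningRate = mc$learning_rate %||% 3e-4,
                        batchSize = mc$batch_size %||% 16L,
                        dropout = mc$dropout %||% 0,
                        attentionEnabled = mc$attention_enabled %||% TRUE,
                        seed = mseeds[i])
      m <- trainGPT(c(segs[[i]]$train, segs[[i]]$val), cfgM)
      saveModel(m, modelFiles[i])
      write.csv(m@lossHistory, file.path(outDir, sprintf("loss_%02d.csv", i)),
                row.names = FALSE)
      m
    })
    mark("train", modelFiles)
  } else models <- lapply(modelFiles, loadModel)

  ## --- generate ---
  genc <- cfg$generate %||% list()
  genFiles <- file.path(outDir, sprintf("generated_%02d.txt", seq_len(nSeg)))
  if (!.stage_done(man, "generate", digest, genFiles)) {
    ens <- generateEnsemble(models, lapply(segs, `[[`, "prompt"),
                            nTokens = genc$n_tokens %||% 20000L,
                            masterSeed = seeds[6],
                            temperature = genc$temperature %||% 1,
                            dtPerFrame = dtPerFrame(sseq))
    for (i in seq_len(nSeg)) writeStateSequence(sequences(ens)[[i]], genFiles[i])
    mark("generate", genFiles)
  } else {
    ens <- new("GeneratedEnsemble",
               sequences = lapply(genFiles, readStateSequence),
               seeds = integer(length(genFiles)), meta = list(resumed = TRUE))
  }

  ## --- kinetics report ---
  kinDir <- file.path(outDir, "kinetics")
  report <- kineticsReport(sseq, ens, kinDir,
                           rule = (cfg$kinetics %||% list())$rule %||% "sym")
  mark("kinetics", file.path(kinDir, "state_probabilities.tsv"))

  ## --- baselines ---
  basc <- cfg$baselines %||% list()
  lags <- unlist(basc$msm_lags %||% c(1L, 2L, 5L))
  its <- impliedTimescales(sseq, lags)
  msm <- estimateMSM(sseq, selectLag(its))
  msmSeq <- msmGenerate(msm, start = tokens(sseq)[length(tokens(sseq))],
                        n = genc$n_tokens %||% 20000L, seed = seeds[6],
                        dtPerFrame = dtPerFrame(sseq))
  writeStateSequence(msmSeq, file.path(outDir, "generated_msm.txt"))
  jsonlite::write_json(
    list(lag = msm@lag, states = msm@states,
         transition_matrix = msm@transitionMatrix, its = its),
    file.path(outDir, "msm.json"), auto_unbox = TRUE, digits = NA)
  lstmModel <- NULL
  if (isTRUE(basc$lstm)) {
    lstmModel <- trainLSTM(c(segs[[1]]$train, segs[[1]]$val),
                           lstmConfig(vocabSize = nStates(sseq),
                                      epochs = basc$lstm_epochs %||% 300L,
                                      seed = seeds[5]))
    lstmSeq <- generateTokens(lstmModel, segs[[1]]$prompt,
                              genc$n_tokens %||% 20000L, seed = seeds[6])
    writeStateSequence(lstmSeq, file.path(outDir, "generated_lstm.txt"))
  }
  mark("baselines", file.path(outDir, "msm.json"))

  invisible(list(trajectory = traj, states = sseq, segments = segs,
                 models = models, ensemble = ens, kinetics = report,
                 msm = msm, lstm = lstmModel))
}

#' Write a kinetics comparison report
#'
#' State probabilities, commit-time curves for every ordered pair (actual
#' vs generated, with agreement scores), and the detailed-balance summary,
#' as TSV/JSON under \code{dir}.
#'
#' @param actual the source [StateSequence-class].
#' @param generated generated sequence(s) (any input accepted by
#'   [stateProbabilities()]).
#' @param dir output directory.
#' @param rule commit-time counting rule.
#' @return invisibly, a list with the computed tables.
#' @export
kineticsReport <- function(actual, generated, dir, rule = "sym") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pa <- stateProbabilities(actual)
  pg <- stateProbabilities(generated)
  probs <- merge(pa, pg, by = "state", suffixes = c("_actual", "_generated"))
  write.table(probs, file.path(dir, "state_probabilities.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  grid <- .default_grid(.as_seq_list(actual))
  ca <- transitionCurves(actual, grid, rule)
  cg <- transitionCurves(generated, grid, rule)
  rows <- NULL
  cmp <- list()
  for (key in names(ca)) {
    cc <- compareCurves(ca[[key]], cg[[key]])
    cmp[[key]] <- cc
    rows <- rbind(rows, data.frame(pair = key, commitTime = grid,
                                   actual = ca[[key]]@counts,
                                   actual_se = ca[[key]]@stderr,
                                   generated = cg[[key]]@counts,
                                   generated_se = cg[[key]]@stderr,
                                   z = cc$perPoint$z))
  }
  write.table(rows, file.path(dir, "transition_curves.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  db <- detailedBalanceReport(cg)
  write.table(db, file.path(dir, "detailed_balance_generated.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(agreement = lapply(cmp, `[[`, "agreement"),
         rule = rule, commit_grid_max = max(grid)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(probabilities = probs, curves = rows, agreement = cmp,
                 detailed_balance = db))
}
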