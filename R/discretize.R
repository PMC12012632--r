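## Discretization of continuous CV trajectories into integer token sequences
## (K-means or 1D binning) and carving of sequences into training segments.

#' K-means discretization of a CV trajectory
#'
#' Standard squared-Euclidean K-means with multiple restarts; cluster labels
#' are arbitrary, so clusters are renumbered in descending order of
#' population (ties broken by ascending first-coordinate of the center) to
#' make runs comparable.
#'
#' @param cv a [CVTrajectory-class], numeric matrix or vector of per-frame
#'   coordinates.
#' @param k number of states (>= 2); conventional choices are 3 for the
#'   three-well system, 4 for the four-well system, 2 for the bead chain, and
#'   20 for a fine-grained state space.
#' @param seed RNG seed.
#' @param nstart K-means restarts (lowest inertia kept).
#' @param dtPerFrame time per frame carried into the sequence.
#' @return a [StateSequence-class]; \code{labelMap} holds the cluster
#'   centers, one row per state, and \code{meta$inertia} the final
#'   within-cluster sum of squares.
#' @export
kmeansDiscretize <- function(cv, k, seed = 1L, nstart = 10L, dtPerFrame = NULL) {
  vals <- if (is(cv, "CVTrajectory")) cvValues(cv) else as.matrix(cv)
  if (is.null(dtPerFrame)) dtPerFrame <- 1
  if (k < 2L) stop("k must be >= 2")
  if (nrow(vals) < k) stop("need at least k frames")
  if (k == nrow(vals)) {
    # degenerate limit: every frame is its own state (zero inertia)
    ord <- order(vals[, 1])
    relabel <- integer(k); relabel[ord] <- seq_len(k) - 1L
    return(new("StateSequence", tokens = relabel, nStates = as.integer(k),
               dtPerFrame = dtPerFrame, labelMap = vals[ord, , drop = FALSE],
               meta = list(method = "kmeans", inertia = 0, seed = seed)))
  }
  km <- withSeed(seed,
    kmeans(vals, centers = k, nstart = nstart, iter.max = 100L))
  pop <- km$size
  ord <- order(-pop, km$centers[, 1])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k) - 1L
  toks <- relabel[km$cluster]
  new("StateSequence", tokens = as.integer(toks), nStates = as.integer(k),
      dtPerFrame = dtPerFrame, labelMap = km$centers[ord, , drop = FALSE],
      meta = list(method = "kmeans", inertia = km$tot.withinss, seed = seed))
}

#' Assign frames to the states of an existing discretization
#'
#' Nearest-center assignment against the \code{labelMap} of a reference
#' [StateSequence-class] (e.g. a K-means discretization of a reference
#' trajectory), so several trajectories share one consistent state
#' definition.
#'
#' @param cv a [CVTrajectory-class], numeric matrix or vector of per-frame
#'   coordinates in the same CV space as the reference centers.
#' @param reference a [StateSequence-class] with a non-empty \code{labelMap}.
#' @param dtPerFrame time per frame of the new sequence.
#' @return a [StateSequence-class] over the reference vocabulary.
#' @export
assignStates <- function(cv, reference, dtPerFrame = NULL) {
  stopifnot(is(reference, "StateSequence"))
  centers <- reference@labelMap
  if (!nrow(centers)) stop("reference carries no cluster centers")
  vals <- if (is(cv, "CVTrajectory")) cvValues(cv) else as.matrix(cv)
  if (ncol(vals) != ncol(centers))
    stop("CV dimension does not match the reference centers")
  d2 <- vapply(seq_len(nrow(centers)), function(k)
    rowSums(sweep(vals, 2, centers[k, ], "-")^2), numeric(nrow(vals)))
  toks <- max.col(-d2, ties.method = "first") - 1L
  new("StateSequence", tokens = as.integer(toks), nStates = reference@nStates,
      dtPerFrame = if (is.null(dtPerFrame)) reference@dtPerFrame else dtPerFrame,
      labelMap = centers, meta = list(method = "assign"))
}

#' Uniform-bin discretization along a 1D collective variable
#'
#' Bins the observed range into \code{nBins} equal-width states, the
#' construction used for one-dimensional free-energy reconstruction.
#' Empty bins are dropped and the remaining states renumbered in bin order,
#' so every state appears in the sequence.
#'
#' @param series numeric per-frame CV values (e.g. radius of gyration).
#' @param nBins number of uniform bins over the observed range.
#' @param dtPerFrame time per frame.
#' @return a [StateSequence-class]; \code{labelMap} holds the kept bin
#'   centers and \code{meta$breaks} the full break set.
#' @export
binDiscretize <- function(series, nBins = 30L, dtPerFrame = 1) {
  series <- as.numeric(series)
  if (!all(is.finite(series))) stop("series must be finite")
  breaks <- seq(min(series), max(series), length.out = nBins + 1L)
  idx <- findInterval(series, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  keep <- sort(unique(idx))
  relabel <- integer(nBins)
  relabel[keep] <- seq_along(keep) - 1L
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  new("StateSequence", tokens = as.integer(relabel[idx]),
      nStates = length(keep), dtPerFrame = dtPerFrame,
      labelMap = matrix(centers[keep], ncol = 1,
                        dimnames = list(NULL, "center")),
      meta = list(method = "bins", breaks = breaks, keptBins = keep))
}

#' Segmentation plan for model-ensemble training
#'
#' @param nSegments number of independent segments n_s (one model is trained
#'   per segment; 10 in the reference workflow).
#' @param segmentLength segment length in frames.
#' @param split train/validation/test fractions of each segment (sums to 1).
#' @param seed RNG seed for segment placement.
#' @export
segmentPlan <- function(nSegments, segmentLength,
                        split = c(train = 0.6, val = 0.2, test = 0.2),
                        seed = 1L) {
  if (nSegments < 1L) stop("nSegments must be >= 1")
  if (abs(sum(split) - 1) > 1e-9 || any(split < 0))
    stop("split fractions must be non-negative and sum to 1")
  structure(list(n_segments = as.integer(nSegments),
                 segment_length = as.integer(segmentLength),
                 split = split, seed = as.integer(seed)),
            class = c("SegmentPlan", "list"))
}

#' Carve a state sequence into training segments with prompts
#'
#' Samples \code{nSegments} segment start positions (seeded, without
#' replacement when possible).  For each segment the prompt is the trailing
#' block of the segment's training portion and the held-out continuation is
#' the actual data that follows it, used only for evaluation.
#'
#' @param seq a [StateSequence-class].
#' @param plan a [segmentPlan()].
#' @param promptLength trailing tokens used as the generation prompt
#'   (default \code{min(64, segmentLength \%/\% 4)}).
#' @return list with one element per segment: \code{tokens} (the full
#'   segment), \code{train}, \code{val}, \code{test} splits, \code{prompt},
#'   \code{continuation} (data following the prompt to the end of the
#'   sequence, capped at \code{segmentLength}), and \code{start}.
#' @export
segmentSequence <- function(seq, plan, promptLength = NULL) {
  stopifnot(is(seq, "StateSequence"), inherits(plan, "SegmentPlan"))
  toks <- tokens(seq)
  L <- plan$segment_length
  n <- length(toks)
  if (L > n) stop("segment_length exceeds the sequence length")
  if (is.null(promptLength)) promptLength <- min(64L, L %/% 4L)
  maxStart <- n - L + 1L
  starts <- withSeed(plan$seed, {
    if (maxStart >= plan$n_segments)
      sort(sample.int(maxStart, plan$n_segments))
    else sort(sample.int(maxStart, plan$n_segments, replace = TRUE))
  })
  lapply(starts, function(s) {
    seg <- toks[s:(s + L - 1L)]
    ntr <- floor(plan$split[["train"]] * L)
    nva <- floor(plan$split[["val"]] * L)
    train <- seg[seq_len(ntr)]
    val <- if (nva > 0) seg[(ntr + 1L):(ntr + nva)] else integer()
    test <- if (ntr + nva < L) seg[(ntr + nva + 1L):L] else integer()
    prompt <- tail(train, promptLength)
    contStart <- s + ntr
    contEnd <- min(n, contStart + L - 1L)
    list(tokens = seg, train = train, val = val, test = test,
         prompt = prompt,
         continuation = if (contStart <= n) toks[contStart:contEnd] else integer(),
         start = s)
  })
}

#' Write a state sequence as plain text
#'
#' One integer token per line, preceded by \code{#}-header lines carrying the
#' vocabulary size and frame time.
#'
#' @param seq a [StateSequence-class].
#' @param path output file.
#' @export
writeStateSequence <- function(seq, path) {
  stopifnot(is(seq, "StateSequence"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_states %d", nStates(seq)),
               sprintf("# dt_per_frame %.12g", dtPerFrame(seq)),
               as.character(tokens(seq))), con)
  invisible(path)
}

#' Read a state sequence written by [writeStateSequence()]
#'
#' @param path input file.
#' @return a [StateSequence-class].
#' @export
readStateSequence <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  toks <- suppressWarnings(as.integer(body))
  if (anyNA(toks)) {
    bad <- which(is.na(toks))[1]
    stop(sprintf("parse error: non-integer token at data line %d", bad))
  }
  ns <- sub(".*n_states\\s+", "", grep("n_states", hdr, value = TRUE)[1])
  dt <- sub(".*dt_per_frame\\s+", "", grep("dt_per_frame", hdr, value = TRUE)[1])
  ns <- if (is.na(ns) || !nzchar(ns)) max(toks) + 1L else as.integer(ns)
  dt <- if (is.na(dt) || !nzchar(dt)) 1 else as.numeric(dt)
  new("StateSequence", tokens = toks, nStates = ns, dtPerFrame = dt,
      meta = list(source = path))
}

# internal: make a StateSequence from raw tokens
as_state_sequence <- function(tokens, nStates, dtPerFrame = 1, meta = list()) {
  new("StateSequence", tokens = as.integer(tokens),
      nStates = as.integer(nStates), dtPerFrame = dtPerFrame, meta = meta)
}
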