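## Kinetic evaluation surface: state probabilities, commit-time transition
## counting, detailed-balance diagnostics, 1D free-energy reconstruction, and
## curve comparison with ensemble error bars.

# normalize input to a list of StateSequence
.as_seq_list <- function(seqs) {
  if (is(seqs, "GeneratedEnsemble")) return(sequences(seqs))
  if (is(seqs, "StateSequence")) return(list(seqs))
  if (is.list(seqs) && all(vapply(seqs, is, logical(1), "StateSequence")))
    return(seqs)
  stop("expected a StateSequence, a list of them, or a GeneratedEnsemble")
}

#' State probabilities with ensemble error bars
#'
#' The probability of a state is its occurrence count divided by the total
#' count, per sequence; over an ensemble the per-sequence probabilities are
#' averaged and the standard error across members reported.
#'
#' @param seqs a [StateSequence-class], list of them, or a
#'   [GeneratedEnsemble-class] sharing one vocabulary.
#' @return data.frame with columns \code{state}, \code{mean}, \code{stderr}
#'   (\code{stderr} is 0 for a single sequence).
#' @export
stateProbabilities <- function(seqs) {
  sl <- .as_seq_list(seqs)
  if (any(vapply(sl, function(s) length(tokens(s)) == 0L, logical(1))))
    stop("empty sequence")
  ns <- unique(vapply(sl, nStates, integer(1)))
  if (length(ns) != 1L) stop("sequences must share a vocabulary")
  P <- t(vapply(sl, function(s)
    tabulate(tokens(s) + 1L, nbins = ns) / length(tokens(s)), numeric(ns)))
  data.frame(
    state = seq_len(ns) - 1L,
    mean = colMeans(P),
    stderr = if (nrow(P) > 1) apply(P, 2, sd) / sqrt(nrow(P)) else rep(0, ns))
}

# per-sequence raw commit-time counts for one ordered pair over a grid
.commit_counts_one <- function(toks, from, to, grid, rule) {
  r <- rle(toks)
  v <- r$values; L <- r$lengths
  if (length(v) < 2L) return(rep(0, length(grid)))
  sel <- which(v[-length(v)] == from & v[-1L] == to)
  if (!length(sel)) return(rep(0, length(grid)))
  m <- if (rule == "sym") pmin(L[sel], L[sel + 1L]) else L[sel]
  vapply(grid, function(tau) sum(m >= tau), numeric(1))
}

# shared commit grid: 1 .. 99th percentile of dwell lengths
.default_grid <- function(sl) {
  lens <- unlist(lapply(sl, function(s) rle(tokens(s))$lengths))
  tmax <- max(1, ceiling(quantile(lens, 0.99)))
  seq_len(tmax)
}

#' Commit-time transition-count curve for one ordered state pair
#'
#' Decomposes each sequence into maximal constant runs; at commit time tau a
#' transition \code{from -> to} is counted for each adjacent run pair whose
#' dwells both last at least tau frames (\code{rule = "sym"}, the default)
#' or whose preceding dwell does (\code{rule = "pre"}).  Counts are
#' normalized to counts per 1e4 frames so sequences of different lengths are
#' comparable; raw totals stay in \code{meta}.
#'
#' @param seqs input sequence(s) as in [stateProbabilities()].
#' @param pair ordered integer pair \code{c(from, to)}, distinct states.
#' @param commitGrid commit times in frames (default 1 to the 99th
#'   percentile of dwell lengths).
#' @param rule dwell-filter rule, \code{"sym"} or \code{"pre"}.
#' @return a [TransitionCountCurve-class]; standard errors are the ensemble
#'   spread floored by the Poisson counting error of the pooled rate
#'   (\code{sqrt(total + 1)} events), which is also the error used for a
#'   single sequence.
#' @export
commitTimeCounts <- function(seqs, pair, commitGrid = NULL,
                             rule = c("sym", "pre")) {
  rule <- match.arg(rule)
  sl <- .as_seq_list(seqs)
  ns <- nStates(sl[[1]])
  pair <- as.integer(pair)
  if (pair[1] == pair[2] || any(pair < 0L | pair >= ns))
    stop("pair must be two distinct states within the vocabulary")
  if (is.null(commitGrid)) commitGrid <- .default_grid(sl)
  if (any(commitGrid < 1)) stop("commit times must be >= 1 frame")
  lens <- vapply(sl, function(s) length(tokens(s)), numeric(1))
  raw <- t(vapply(sl, function(s)
    .commit_counts_one(tokens(s), pair[1], pair[2], commitGrid, rule),
    numeric(length(commitGrid))))
  norm <- raw / lens * 1e4
  mean_ <- colMeans(norm)
  # ensemble spread, floored by the Poisson counting error of the pooled
  # rate (with the +1 regularization so a zero count has the ~1-event
  # uncertainty instead of an exactly-zero standard error)
  sePois <- sqrt(colSums(raw) + 1) / sum(lens) * 1e4
  se <- if (nrow(norm) > 1)
    pmax(apply(norm, 2, sd) / sqrt(nrow(norm)), sePois)
  else sePois
  new("TransitionCountCurve", pair = pair, commitTimes = as.numeric(commitGrid),
      counts = mean_, stderr = se, perMember = norm,
      dtPerFrame = dtPerFrame(sl[[1]]),
      meta = list(rule = rule, raw = raw, lengths = lens,
                  normalization = "per 1e4 frames"))
}

#' Commit-time curves for all ordered state pairs
#'
#' @inheritParams commitTimeCounts
#' @return named list of [TransitionCountCurve-class], keys \code{"i->j"}.
#' @export
transitionCurves <- function(seqs, commitGrid = NULL, rule = c("sym", "pre")) {
  rule <- match.arg(rule)
  sl <- .as_seq_list(seqs)
  ns <- nStates(sl[[1]])
  if (is.null(commitGrid)) commitGrid <- .default_grid(sl)
  out <- list()
  for (i in 0:(ns - 1)) for (j in 0:(ns - 1)) if (i != j)
    out[[sprintf("%d->%d", i, j)]] <-
      commitTimeCounts(sl, c(i, j), commitGrid, rule)
  out
}

#' Detailed-balance diagnostic from forward/backward curves
#'
#' For each unordered state pair, compares the forward and backward
#' commit-time curves point by point: \code{|forward - backward|} in units
#' of the pooled standard error, scanned across the commit grid, with the
#' pair reported at its largest z.  A scan is used because irreversibility
#' often lives in a commit-time band (fast symmetric flicker masks it at
#' small tau; counts vanish at very large tau), and curve points within a
#' band are strongly correlated, so the scan costs little multiplicity.
#' Pairs exceeding 3 are flagged: equilibrium dynamics produce no flags;
#' driven systems are expected to produce at least one.
#'
#' @param x either input sequences (as in [stateProbabilities()]) or a named
#'   list of curves from [transitionCurves()] containing both directions of
#'   every pair.
#' @param ... passed to [transitionCurves()] when \code{x} is raw sequences.
#' @return data.frame with columns \code{from}, \code{to}, \code{asymmetry}
#'   (signed difference at the most discrepant commit time), \code{z} (the
#'   scan maximum), \code{flagged}.
#' @export
detailedBalanceReport <- function(x, ...) {
  curves <- if (is.list(x) && length(x) &&
                all(vapply(x, is, logical(1), "TransitionCountCurve"))) x
            else transitionCurves(x, ...)
  pairs <- t(vapply(curves, function(cv) cv@pair, integer(2)))
  out <- NULL
  done <- character()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    key <- paste(sort(c(i, j)), collapse = "-")
    if (key %in% done) next
    done <- c(done, key)
    fwd <- curves[[sprintf("%d->%d", min(i, j), max(i, j))]]
    bwd <- curves[[sprintf("%d->%d", max(i, j), min(i, j))]]
    if (is.null(fwd) || is.null(bwd))
      stop(sprintf("missing reverse curve for pair %s", key))
    d <- fwd@counts - bwd@counts
    pooled <- sqrt(fwd@stderr^2 + bwd@stderr^2)
    zs <- ifelse(pooled > 0, abs(d) / pooled,
                 ifelse(abs(d) < 1e-12, 0, Inf))
    k <- which.max(zs)
    out <- rbind(out, data.frame(from = min(i, j), to = max(i, j),
                                 asymmetry = d[k], z = zs[k],
                                 flagged = zs[k] > 3))
  }
  out
}

#' One-dimensional free-energy profile
#'
#' Histograms a CV series (or uses the bin populations of a bin-discretized
#' [StateSequence-class]) and converts probabilities to free energies,
#' \code{F = -kT log P}, shifted so the minimum is 0.  Empty bins are masked
#' (\code{NA}), never interpolated.  For driven systems this is an effective
#' free energy: an occupancy measure, not a thermodynamic potential.
#'
#' @param series numeric per-frame CV values, or a [StateSequence-class]
#'   produced by [binDiscretize()].
#' @param nBins number of uniform bins (ignored for a StateSequence input).
#' @param kT thermal energy for the conversion.
#' @return a [FreeEnergyProfile-class].
#' @export
freeEnergy1d <- function(series, nBins = 30L, kT = 1) {
  if (is(series, "StateSequence")) {
    if (!identical(series@meta$method, "bins"))
      stop("StateSequence input must come from binDiscretize()")
    counts <- tabulate(tokens(series) + 1L, nbins = nStates(series))
    centers <- series@labelMap[, 1]
  } else {
    series <- as.numeric(series)
    breaks <- seq(min(series), max(series), length.out = nBins + 1L)
    idx <- findInterval(series, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(idx, nbins = nBins)
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  }
  if (!any(counts > 0)) stop("no occupied bins")
  if (sum(counts > 0) == 1L)
    warning("degenerate profile: all mass in a single bin")
  P <- counts / sum(counts)
  F <- ifelse(P > 0, -kT * log(P), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  new("FreeEnergyProfile", binCenters = as.numeric(centers), F = F,
      mask = counts == 0, kT = kT)
}

#' Agreement between actual and generated transition curves
#'
#' Point-wise z-scores of the difference between two commit-time curves
#' (both normalized per 1e4 frames) against the pooled standard error; the
#' agreement score is the fraction of grid points with \code{|z| <= 3}.
#'
#' @param actual,generated [TransitionCountCurve-class] objects for the same
#'   ordered pair on the same commit grid.
#' @return list with \code{agreement} (fraction in \code{[0, 1]}),
#'   \code{maxZ}, and \code{perPoint} data.frame.
#' @export
compareCurves <- function(actual, generated) {
  stopifnot(is(actual, "TransitionCountCurve"),
            is(generated, "TransitionCountCurve"))
  if (!identical(actual@pair, generated@pair))
    stop("curves describe different state pairs")
  if (!isTRUE(all.equal(actual@commitTimes, generated@commitTimes)))
    stop("commit grids differ")
  d <- actual@counts - generated@counts
  pooled <- sqrt(actual@stderr^2 + generated@stderr^2)
  z <- ifelse(pooled > 0, abs(d) / pooled,
              ifelse(abs(d) < 1e-12, 0, Inf))
  list(agreement = mean(z <= 3), maxZ = max(z),
       perPoint = data.frame(commitTime = actual@commitTimes,
                             actual = actual@counts,
                             generated = generated@counts,
                             pooledStderr = pooled, z = z))
}
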