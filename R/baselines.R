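## Markov-state-model baseline: sliding-window count matrices, implied
## timescales, Chapman-Kolmogorov test, and generative sampling at the model
## lag.  (The LSTM baseline lives in nn-lstm.R.)

#' Estimate a Markov state model from a token sequence
#'
#' Sliding-window counts \code{C[i, j] = #\{t : s_t = i, s_{t+lag} = j\}},
#' restricted to the largest strongly connected set of states at that lag
#' (dropped states are recorded).  The non-reversible estimate row-normalizes
#' \code{C}; the reversible option runs the iterative detailed-balance
#' maximum-likelihood fixed point.
#'
#' @param seq a [StateSequence-class] (or integer token vector).
#' @param lag lag time in frames.
#' @param reversible enforce detailed balance in the estimate.
#' @return a [MarkovModel-class].
#' @export
estimateMSM <- function(seq, lag = 1L, reversible = FALSE) {
  toks <- if (is(seq, "StateSequence")) tokens(seq) else as.integer(seq)
  ns <- if (is(seq, "StateSequence")) nStates(seq) else max(toks) + 1L
  lag <- as.integer(lag)
  if (lag < 1L || lag >= length(toks)) stop("lag must be in [1, length - 1]")
  a <- toks[seq_len(length(toks) - lag)] + 1L
  b <- toks[(lag + 1L):length(toks)] + 1L
  C <- matrix(0, ns, ns)
  tab <- table(factor(a, levels = seq_len(ns)), factor(b, levels = seq_len(ns)))
  C[] <- as.numeric(tab)
  # largest strongly connected component on observed transitions
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  keepComp <- which.max(tabulate(comp$membership, comp$no))
  keep <- which(comp$membership == keepComp)
  visited <- which(rowSums(C) + colSums(C) > 0)
  keep <- intersect(keep, visited)
  if (!length(keep)) stop("no strongly connected state set at this lag")
  dropped <- setdiff(visited, keep)
  Ck <- C[keep, keep, drop = FALSE]
  if (any(rowSums(Ck) == 0))
    stop(sprintf("estimation error: absorbing state %d at lag %d",
                 keep[which(rowSums(Ck) == 0)[1]] - 1L, lag))
  Tm <- if (reversible) .reversible_mle(Ck) else Ck / rowSums(Ck)
  new("MarkovModel", lag = lag, countMatrix = Ck, transitionMatrix = Tm,
      states = as.integer(keep - 1L), dropped = as.integer(dropped - 1L),
      reversible = reversible)
}

# reversible maximum-likelihood transition matrix (fixed-point iteration)
.reversible_mle <- function(C, tol = 1e-10, maxit = 1000L) {
  Csym <- C + t(C)
  ci <- rowSums(C)
  X <- Csym / sum(C)          # symmetric initial guess
  for (it in seq_len(maxit)) {
    q <- ci / rowSums(X)
    Xnew <- Csym / (outer(q, q, "+"))
    Xnew <- (Xnew + t(Xnew)) / 2
    if (max(abs(Xnew - X)) < tol) { X <- Xnew; break }
    X <- Xnew
  }
  X / rowSums(X)
}

#' Implied relaxation timescales as a function of lag
#'
#' For each lag the transition matrix is estimated and the non-unit
#' eigenvalues converted via \code{t_i(tau) = -tau / log(lambda_i(tau))}.
#' Eigenvalues outside \code{(0, 1)} (negative, complex, or unit) give
#' undefined timescales and are flagged rather than dropped.  Flat curves in
#' lag indicate Markovian behaviour at that discretization.
#'
#' @param seq a [StateSequence-class] or token vector.
#' @param lags integer lag times to scan.
#' @param nTimescales how many of the slowest timescales to report.
#' @return data.frame with columns \code{lag}, \code{index}, \code{eigenvalue},
#'   \code{its}, \code{flag} (\code{"ok"}, \code{"nonpositive"},
#'   \code{"complex"}, or \code{"unit"}).
#' @export
impliedTimescales <- function(seq, lags, nTimescales = NULL) {
  if (any(lags < 1)) stop("lags must be >= 1")
  out <- NULL
  for (tau in as.integer(lags)) {
    m <- estimateMSM(seq, tau)
    ev <- eigen(m@transitionMatrix, only.values = TRUE)$values
    ev <- ev[order(-Mod(ev))][-1]          # drop the stationary eigenvalue
    if (!is.null(nTimescales)) ev <- head(ev, nTimescales)
    for (k in seq_along(ev)) {
      lam <- ev[k]
      if (abs(Im(lam)) > 1e-10) {
        out <- rbind(out, data.frame(lag = tau, index = k + 1L,
                                     eigenvalue = Mod(lam), its = NA_real_,
                                     flag = "complex"))
      } else {
        lam <- Re(lam)
        flag <- if (lam <= 0) "nonpositive"
                else if (lam >= 1 - 1e-12) "unit" else "ok"
        its <- if (flag == "ok") -tau / log(lam)
               else if (flag == "unit") Inf else NA_real_
        out <- rbind(out, data.frame(lag = tau, index = k + 1L,
                                     eigenvalue = lam, its = its, flag = flag))
      }
    }
  }
  out
}

#' Heuristic lag selection from implied timescales
#'
#' Smallest scanned lag at which the slowest implied timescale changes by
#' less than \code{relTol} when the lag doubles (the level-off criterion);
#' falls back to the largest scanned lag.
#'
#' @param its data.frame from [impliedTimescales()].
#' @param relTol relative-change threshold.
#' @export
selectLag <- function(its, relTol = 0.10) {
  slow <- its[its$index == 2L & its$flag == "ok", ]
  if (!nrow(slow)) {
    warning("no usable slowest timescale; falling back to the smallest lag")
    return(min(its$lag))
  }
  lags <- sort(unique(slow$lag))
  for (tau in lags) {
    tau2 <- lags[lags >= 2 * tau]
    if (!length(tau2)) break
    t1 <- slow$its[slow$lag == tau][1]
    t2 <- slow$its[slow$lag == tau2[1]][1]
    if (is.finite(t1) && is.finite(t2) && abs(t2 - t1) / t1 < relTol)
      return(tau)
  }
  max(lags)
}

#' Chapman-Kolmogorov test
#'
#' Compares the self-transition probabilities predicted by propagating the
#' lag-tau model, \code{[T(tau)^k]_ii}, against those estimated directly at
#' \code{k tau}, with bootstrap confidence bands obtained by resampling
#' contiguous blocks of the sequence.
#'
#' @param model a [MarkovModel-class] estimated at lag tau.
#' @param seq the sequence the model was estimated from.
#' @param kMultiples integer lag multiples to test.
#' @param nBoot bootstrap replicates for the bands.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with columns \code{k}, \code{state}, \code{predicted},
#'   \code{estimated}, \code{lower}, \code{upper} (95% band).
#' @export
ckTest <- function(model, seq, kMultiples = c(2L, 3L), nBoot = 50L, seed = 1L) {
  toks <- if (is(seq, "StateSequence")) tokens(seq) else as.integer(seq)
  tau <- model@lag
  if (max(kMultiples) * tau >= length(toks))
    stop("insufficient data at the largest lag multiple")
  sseq <- if (is(seq, "StateSequence")) seq else
    as_state_sequence(toks, max(toks) + 1L)
  out <- NULL
  withSeed(seed, {
    nblock <- 20L
    bl <- floor(length(toks) / nblock)
    blocks <- lapply(seq_len(nblock), function(b)
      toks[((b - 1) * bl + 1):(b * bl)])
    for (k in as.integer(kMultiples)) {
      pred <- diag(.matpow(model@transitionMatrix, k))
      est_model <- estimateMSM(sseq, k * tau)
      boot <- matrix(NA_real_, nBoot, length(model@states))
      for (r in seq_len(nBoot)) {
        rs <- unlist(blocks[sample.int(nblock, nblock, replace = TRUE)])
        bm <- tryCatch(estimateMSM(as_state_sequence(rs, nStates(sseq)), k * tau),
                       error = function(e) NULL)
        if (is.null(bm)) next
        idx <- match(model@states, bm@states)
        boot[r, ] <- diag(bm@transitionMatrix)[idx]
      }
      for (s in seq_along(model@states)) {
        st <- model@states[s]
        i2 <- match(st, est_model@states)
        out <- rbind(out, data.frame(
          k = k, state = st, predicted = pred[s],
          estimated = if (is.na(i2)) NA_real_ else diag(est_model@transitionMatrix)[i2],
          lower = quantile(boot[, s], 0.025, na.rm = TRUE),
          upper = quantile(boot[, s], 0.975, na.rm = TRUE)))
      }
    }
  })
  rownames(out) <- NULL
  out
}

.matpow <- function(M, k) {
  R <- diag(nrow(M))
  for (i in seq_len(k)) R <- R %*% M
  R
}

#' Generate a token sequence from a Markov model
#'
#' Plain Markov-chain sampling at the model's lag resolution: when the lag
#' exceeds one frame the generated sequence's \code{dtPerFrame} is the lag
#' times the source frame time — the model cannot emit finer time steps.
#'
#' @param model a [MarkovModel-class].
#' @param start starting state (must be in the active set).
#' @param n number of tokens to generate.
#' @param seed RNG seed.
#' @param dtPerFrame source frame time (default 1).
#' @return a [StateSequence-class] over the full original vocabulary.
#' @export
msmGenerate <- function(model, start, n, seed = 1L, dtPerFrame = 1) {
  idx <- match(as.integer(start), model@states)
  if (is.na(idx)) stop("start state is not in the model's active set")
  Tm <- model@transitionMatrix
  k <- nrow(Tm)
  toks <- withSeed(seed, {
    out <- integer(n)
    cur <- idx
    # row-wise cumulative probabilities for fast inversion sampling
    cum <- t(apply(Tm, 1, cumsum))
    u <- runif(n)
    for (t in seq_len(n)) {
      cur <- findInterval(u[t], cum[cur, ]) + 1L
      if (cur > k) cur <- k
      out[t] <- model@states[cur]
      cur <- match(out[t], model@states)
    }
    out
  })
  as_state_sequence(toks, max(model@states) + 1L,
                    dtPerFrame = dtPerFrame * model@lag,
                    meta = list(lag = model@lag, start = start, seed = seed))
}

#' Stationary distribution of a Markov model
#'
#' Left Perron eigenvector of the transition matrix, normalized to sum to 1.
#'
#' @param model a [MarkovModel-class].
#' @return named numeric vector over the active states.
#' @export
stationaryDistribution <- function(model) {
  e <- eigen(t(model@transitionMatrix))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v <- v / sum(v)
  setNames(v, model@states)
}
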