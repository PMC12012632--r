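## Seeded synthetic fixtures with known ground truth, used by tests and by
## anyone wanting a controlled token source: Markov chains, periodic and
## second-order sequences, and a small toy-potential trajectory.

#' Synthetic data with known ground truth
#'
#' \describe{
#'   \item{markov_chain}{first-order chain sampled from a supplied transition
#'     matrix \code{params$T} (row-stochastic); the truth is attached in
#'     \code{meta$truth}.}
#'   \item{periodic}{deterministic cycle \code{0, 1, ..., period-1, 0, ...}
#'     (or a supplied \code{params$pattern}) — a zero-entropy source.}
#'   \item{second_order}{three-state sequence with
#'     \code{s[t+1] = (s[t] + s[t-1]) mod 3} applied with probability
#'     \code{1 - params$eps} (default eps 0.05, else a uniform random state):
#'     the next token is nearly uninformative given the current token alone
#'     but nearly deterministic given the previous two — the construction
#'     that separates models with and without cross-token communication.}
#'   \item{toy_traj}{short Brownian-dynamics run in the three-well potential
#'     (params passed to [integratorSpec()]).}
#' }
#'
#' @param kind fixture kind (see above).
#' @param params kind-specific parameters; \code{params$n} is the length.
#' @param seed RNG seed.
#' @return a [StateSequence-class] (or a [Trajectory-class] for
#'   \code{toy_traj}) with ground truth in \code{meta$truth}.
#' @examples
#' s <- makeFixture("markov_chain",
#'                  list(T = matrix(c(.9, .1, .1, .9), 2, byrow = TRUE),
#'                       n = 1000), seed = 1)
#' @export
makeFixture <- function(kind = c("markov_chain", "periodic", "second_order",
                                 "toy_traj"),
                        params = list(), seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    markov_chain = {
      Tm <- params$T
      if (is.null(Tm) || any(abs(rowSums(Tm) - 1) > 1e-9))
        stop("params$T must be a row-stochastic matrix")
      n <- params$n %||% 10000L
      k <- nrow(Tm)
      toks <- withSeed(seed, {
        cum <- t(apply(Tm, 1, cumsum))
        out <- integer(n)
        cur <- params$start %||% sample.int(k, 1L)
        u <- runif(n)
        for (t in seq_len(n)) {
          cur <- findInterval(u[t], cum[cur, ]) + 1L
          if (cur > k) cur <- k
          out[t] <- cur - 1L
        }
        out
      })
      as_state_sequence(toks, k, meta = list(truth = Tm, kind = kind))
    },
    periodic = {
      pat <- params$pattern %||% (seq_len(params$period %||% 3L) - 1L)
      n <- params$n %||% 1000L
      toks <- rep_len(as.integer(pat), n)
      as_state_sequence(toks, max(toks) + 1L,
                        meta = list(truth = pat, kind = kind))
    },
    second_order = {
      n <- params$n %||% 10000L
      eps <- params$eps %||% 0.05
      toks <- withSeed(seed, {
        out <- integer(n)
        # default start (1, 2) lies on the deterministic 8-cycle, keeping the
        # eps = 0 variant away from the absorbing (0, 0) pair
        out[1:2] <- params$start %||% c(1L, 2L)
        u <- runif(n)
        for (t in 3:n) {
          out[t] <- if (u[t] < 1 - eps) (out[t - 1] + out[t - 2]) %% 3L
                    else sample(0:2, 1L)
        }
        out
      })
      as_state_sequence(toks, 3L,
                        meta = list(truth = list(rule = "(s[t] + s[t-1]) mod 3",
                                                 eps = eps), kind = kind))
    },
    toy_traj = {
      spec <- toyPotentialSpec("three_state")
      integ <- integratorSpec(dt = params$dt %||% 0.01,
                              gamma = params$gamma %||% 1,
                              kT = params$kT %||% 0.2,
                              nSteps = params$n_steps %||% 10000L,
                              saveStride = params$save_stride %||% 10L,
                              seed = seed)
      runBDToy(spec, integ)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
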