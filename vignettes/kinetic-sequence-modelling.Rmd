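---
title: "Modelling state-to-state kinetics with a decoder-only transformer"
author: "kinseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling state-to-state kinetics with a decoder-only transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Metastable physicochemical systems — a particle in a multi-well landscape, a
self-propelled polymer, a folding mini-protein — spend long stretches of time
in a handful of conformational states and hop between them rarely.  The
long-time behaviour of such a system is summarized by the *sequence* of
states it visits and by how long it dwells in each.  `kinseq` treats that
sequence exactly like text: a trajectory is discretized into integer tokens
along collective variables, an autoregressive sequence model is trained to
predict the next token from its context, and new, statistically faithful
state sequences are then sampled from the trained model far faster than the
underlying dynamics could be simulated.  The package contains the full
workflow — simulators, featurization, discretization, the transformer, the
generation machinery, kinetic validation metrics, and Markov-state-model
(MSM) and LSTM baselines — so every claim it makes about generated kinetics
can be recomputed from scratch.

## Brownian-dynamics simulators

Both built-in systems evolve by overdamped Euler–Maruyama dynamics

$$ \mathbf{r} \leftarrow \mathbf{r} + \frac{\Delta t}{\gamma}\,\mathbf{F}(\mathbf{r})
   + \sqrt{\tfrac{2 k_B T \Delta t}{\gamma}}\;\boldsymbol{\eta}, $$

with independent standard-normal $\boldsymbol\eta$ per component, so the 2D
noise obeys $\langle \boldsymbol\xi(t)\cdot\boldsymbol\xi(t')\rangle = 4 k_B T
\gamma^{-1}\delta(t-t')$.  All times are in the Brownian unit
$\tau_\mathrm{BD}$; lengths and energies are reduced.

**Multi-well toy potentials.**  The three-well potential is
$V_3 = W(x^6 + y^6) - \sum_{i=1}^{3} G(x, x_i)\,G(y, y_i)$ with the
unnormalized Gaussian $G(u, u_0) = e^{-(u-u_0)^2/2s^2}$; the four-well
variant uses a quartic confinement and five Gaussian centers.  Defaults:
$W = 10^{-4}$, $s = 0.8$, centers $(0,0), (\pm 1.5, \pm 1.5)$ (three-well)
and $(0,0), (2,-1), (0.5,2), (-0.5,-2), (-2,1)$ (four-well); integration
step $\Delta t = 0.01\,\tau_\mathrm{BD}$.  Two knobs are not fixed by the
construction and are this package's own choices:

* *Gaussian form*: the unnormalized Gaussian above, the only reading
  consistent with an amplitude-1 well and the stated width.
* *Friction and temperature*: $\gamma = 1$ and $k_B T = 0.2$.  The saddle
  between overlapping wells sits only $\approx 0.23$ energy units above the
  minima, so at $k_B T = 1$ the landscape is effectively flat — no dwell
  structure, and frequent direct jumps between the two spatially distant
  corner wells.  At $k_B T = 0.2$ adjacent wells exchange every
  $\sim 30$ saved frames (good statistics in a $10^5$-frame run) while
  direct corner-to-corner transitions are never observed, reproducing the
  qualitative state structure the workflow is designed around.  Both are
  configurable in `integratorSpec()`.

**Active worm-like chain.**  $N = 32$ beads in 2D joined by stiff springs
($V_\mathrm{bond} = \sum \tfrac{k_0}{2}(b_i - d_0)^2$, default
$k_0 = 10^4\,k_BT/\sigma^2$ — a stiff-spring choice keeping bond
fluctuations $\ll d_0$), harmonic bending
$V_\mathrm{bend} = \sum \tfrac{k_\mathrm{ang}}{2}(\theta_i - \theta_0)^2$
about the straight angle $\theta_0 = \pi$, Hertzian contacts
$V_\mathrm{nb} = E\,(1 - r/\sigma)^{5/2}$ for $r < \sigma$ between
non-bonded bead pairs (adjacent bonded pairs sit at $d_0 = 0.5\sigma$ and
are excluded, the standard convention), and a tangential self-propulsion
force of magnitude $f_m$ per bond, split equally onto the bond's two beads.
Published reduced-unit settings: $k_\mathrm{ang} = 45$, $\gamma = 200$,
$k_BT = 1$, $E = 10^4$, $f_m = 5$ (0 for the passive chain),
$\Delta t = 10^{-3}\,\tau_\mathrm{BD}$.

*Initial condition.*  The simulator default is a straight chain at the rest
bond length.  For the active chain, however, the two metastable shapes are
the extended (bent) state and a wound spiral, and the spiral only persists
when the propulsion-leading end sits at its center.  In long straight-start
runs ($3\times10^5\,\tau_\mathrm{BD}$) we never observed spontaneous spiral
nucleation, whereas a spiral initialized with `spiralChain()` survives on
the $10^3$–$10^4\,\tau_\mathrm{BD}$ scale before unwinding irreversibly
into the extended state.  Reference
trajectories that must sample both states therefore start from the spiral;
the decay is one-directional on accessible timescales, which is itself the
detailed-balance-violating signature the active system is included to
exhibit.

## Features and collective variables

`pairwiseDistances()` computes all $\binom{k}{2}$ inter-particle distances
of a selection (for the chain: 8 beads in arithmetic progression with step
4, hence 28 features); `radiusOfGyration()` gives the scalar compaction
coordinate.  The autoencoder (`trainAutoencoder()`) is a symmetric
tanh MLP — widths $[\max(16, n_f), 16]$ around a linear latent layer by
default — trained with minibatch Adam (rate $10^{-3}$, batch 256) on
z-scored features; standardization makes the reconstruction score
scale-free.  Quality is the fraction of variation explained,

$$ \mathrm{FVE} = 1 - \frac{\sum_i \lVert X_i - Y_i\rVert^2}
                          {\sum_i \lVert X_i - \bar X\rVert^2}, $$

computed on the standardized training features: 1 for perfect
reconstruction, 0 for predicting the mean frame.  On the active-chain
reference trajectory ($2\times10^5$ frames covering spiral and extended
shapes) a 2-dimensional latent space exceeds the 0.80 FVE mark with room to
spare (the acceptance script prints the exact value), and K-means with
$k = 2$ on the latent coordinates separates the compact from the extended
shapes.

## Discretization and segmentation

`kmeansDiscretize()` runs standard squared-Euclidean K-means (10 restarts,
lowest inertia).  Cluster labels are arbitrary, so states are renumbered by
descending population, ties broken by the first center coordinate — making
runs comparable and test assertions stable.  Conventional state counts:
3 (three-well), 4 (four-well), 2 (chain), 20 for a fine-grained state
space; `binDiscretize()` provides the uniform-bin 1D variant used for
free-energy reconstruction.  `segmentSequence()` draws $n_s$ seeded
segments from the discretized trajectory; each segment trains one model,
its trailing block (64 tokens by default) becomes the generation prompt,
and the data following the prompt is kept only for evaluation.  The 60/20/20
train/validation/test split is configurable.

## The transformer

`trainGPT()` builds a decoder-only transformer from scratch: token
embeddings plus the fixed sinusoidal positional table
$\mathrm{PE}(k, 2i) = \sin(k/10000^{2i/d})$,
$\mathrm{PE}(k, 2i{+}1) = \cos(k/10000^{2i/d})$; then $N_b$ pre-norm
residual blocks of masked multi-head self-attention
($A_s = QK^\top/\sqrt{d_h}$, causal mask, softmax, value mixing) and a
GELU feed-forward of width $4d$; a final layer norm and linear head with
row-softmax gives the next-token distribution.  Training minimizes the
autoregressive cross-entropy over random context windows with Adam and
gradient clipping at 1.0.  Choices worth stating:

* *Per-head scaling* divides scores by $\sqrt{d/N_h}$ (the per-head width),
  the standard convention; `scalePerHead = FALSE` restores the literal
  $\sqrt{d}$ reading.
* *Pre-norm* block order is used for training stability.
* Desk-scale defaults are $d = 32$, $N_h = 4$, $N_b = 2$, context length 64,
  batch 16, learning rate $3\times10^{-4}$, 2000 steps (each step one
  random minibatch).  `lrDecay = TRUE` cosine-decays the rate to 10% over
  the run; the reference studies in the tests use rate $10^{-3}$, batch
  24–32 and decay, which reaches the sources' entropy-rate floor within
  the 2000-step budget.  A context of 64 frames halves the quadratic attention
  cost of the $10^5$-token generations relative to 128 while exceeding the
  dwell times of the discretized systems studied here; attention-map
  analyses that want the longer window can set `blockSize = 128`.
* The backward pass is hand-derived and verified against central finite
  differences in the test suite (agreement to $<10^{-7}$ absolute).
* `ablateAttention()` removes the attention sublayer only, leaving the
  position-wise feed-forward path: the ablated model provably sees only the
  current token, which the tests check by perturbation.

Generation (`generateTokens()`) samples the next state from the model's
softmax (multinomial at temperature 1 — no top-k or nucleus filtering),
appends it, and slides the context window; there is no key-value caching,
the forward pass is simply recomputed, compiled.  The recomputation skips
work whose result is never consumed — the last block's attention and
feed-forward rows before the final position — which the tests verify is
bit-for-bit identical to the full forward pass.  `generateEnsemble()`
derives per-member seeds from a master seed so the $n_s$ members are
independent yet reproducible.  A generated sequence can never contain a
state absent from the training vocabulary; that structural property is
asserted as a test rather than assumed.

## Kinetic validation

State probabilities are occurrence counts over totals, averaged over
ensemble members with standard errors.  Transition kinetics use
*commit-time* counting: the sequence is decomposed into maximal constant
runs, and a transition $i \to j$ is counted at commit time $\tau$ if the
dwell before and after the crossing both last at least $\tau$ frames.  The
source describes commit time verbally (the duration a system stays in a
state before transitioning); the symmetric $\min$ rule is this package's
operationalization, with the pre-dwell-only rule available as
`rule = "pre"` and the choice recorded in curve metadata.  Counts are
normalized per $10^4$ frames so sequences of different lengths compare;
curves carry ensemble standard errors (Poisson for a single sequence) and
are non-increasing in $\tau$ by construction.  `compareCurves()` scores the
fraction of commit times where two curves agree within 3 pooled standard
errors.  `detailedBalanceReport()` reduces each state pair's
forward/backward curve difference to a single conservative statistic — the
absolute mean difference over the commit grid divided by the mean pooled
standard error (no $\sqrt{n}$ gain is claimed because curve points are
strongly correlated across $\tau$) — and flags pairs exceeding 3:
equilibrium dynamics produce no flags, driven dynamics should produce at
least one.  `freeEnergy1d()` converts a histogram along a CV to
$F = -k_BT\log P$ shifted to zero minimum, masking empty bins; for active
systems this is an occupancy measure (an *effective* free energy), not a
thermodynamic potential.

## Baselines

The MSM baseline (`estimateMSM()`) uses sliding-window transition counts at
lag $\tau$, restricted to the largest strongly connected state set; the
non-reversible row-normalized estimate is the default because the workflows
here include systems that violate detailed balance, with reversible
maximum-likelihood symmetrization available.  Lag selection follows the
implied-timescale criterion $t_i(\tau) = -\tau/\log\lambda_i(\tau)$
(`impliedTimescales()`, `selectLag()`: smallest lag where the slowest
timescale changes by $<10\%$ on doubling), validated by the
Chapman–Kolmogorov test $[T(\tau)^k]_{ii} \approx [T(k\tau)]_{ii}$ with
block-bootstrap bands.  `msmGenerate()` samples the chain at the model lag
and records the coarser time step in `dtPerFrame` — an MSM cannot emit
finer time resolution than its lag.  The LSTM baseline (`trainLSTM()`) is a
single recurrent layer with the transformer's embedding width, trained on
the same windows with the same objective, exposing the identical
`nextTokenProbs()`/`generateTokens()` contract so every kinetics metric
applies unchanged.

## Synthetic fixtures and what passing tests show

`makeFixture()` supplies controlled token sources: first-order Markov
chains with a known transition matrix, zero-entropy periodic cycles, and a
*second-order* source $s_{t+1} = (s_t + s_{t-1}) \bmod 3$ applied with
probability $1-\varepsilon$ (default $\varepsilon = 0.05$).  The
second-order construction has a useful, slightly subtle property: because
the rule is a bijection in the previous token, the next token is uniform
given the current token alone (at any lag), yet nearly deterministic given
the previous two.  A model without cross-position communication is
therefore pinned at the $\log 3$ entropy floor while the full transformer
can approach the $\varepsilon$-noise floor ($\approx 0.17$ nats); an MSM
estimated from such data reproduces the stationary probabilities exactly
while generating kinetically wrong sequences.  With $\varepsilon = 0$ the
dynamics live on a deterministic 8-cycle of token pairs, which makes the
Chapman–Kolmogorov violation exact and large.

These generators emulate the *discrete* statistical structure of
trajectory data — metastability, dwell-time distributions, broken detailed
balance, hidden order — under exactly known ground truth.  They do not
emulate high-dimensional molecular noise, force-field error, or the
clustering ambiguity of real collective variables, so green tests certify
the machinery (simulators, models, estimators, metrics), not the biology of
any particular protein.

## Numerical choices and degenerate inputs

Layer norm uses $\epsilon = 10^{-5}$; softmax rows are max-shifted before
exponentiation; cross-entropy clips probabilities at $10^{-300}$; Adam
bias correction is exact and gradients are norm-clipped at 1.0.  The
bending force's $1/\sin\theta$ factor is bounded through the straight-chain
limit (the $(\theta - \pi)$ factor vanishes at the same rate) with a
$10^{-16}$ floor under the square root.  K-means with $k$ equal to the
frame count returns the zero-inertia singleton partition directly.  FVE is
undefined (and raises an error) for zero-variance input; free-energy
profiles warn when all mass falls in one bin; MSM estimation refuses
absorbing states by name.  Determinism: every stochastic entry point takes
a seed, derives child seeds deterministically where it fans out, and
restores the caller's RNG state.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen so the full suite completes
on one CPU core: $10^5$-frame toy trajectories with $n_s = 3$ models of
2000 training steps and $10^5$ generated tokens each; a
$2\times10^5$-frame active-chain trajectory (saved every
$0.05\,\tau_\mathrm{BD}$) for the autoencoder; twelve further spiral-start
chain runs of $6\times10^3\,\tau_\mathrm{BD}$ at coarser stride for the
detailed-balance analysis (a 3-sigma one-way flag needs on the order of ten
breakup events); and
$3$–$6\times10^4$-token fixtures for the model-comparison studies.  The
acceptance script regenerates the active-chain analysis end to end at the
same scale.

## Known limitations

The transformer cannot generate states it never saw — fine for validating
kinetics on a fixed vocabulary, fatal if a new state would appear at longer
times.  Commit-time curves beyond the model's context length rely on the
learned per-frame hazard rather than explicit long-range memory.  The MSM
comparison uses diagonal CK entries only.  The 2D simulators make no claim
of hydrodynamic realism, and the active chain's spiral-formation pathway is
deliberately sampled from the spiral side only, because nucleation is out
of reach of unbiased desk-scale simulation.
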