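## Overdamped Brownian dynamics of the 2D multi-well toy potentials and the
## (active) worm-like bead chain.  Euler integration as stated in the source
## construction: x <- x + (dt/gamma) f + sqrt(2 kT dt / gamma) eta per
## component, so the 2D noise satisfies <xi.xi'> = 4 kT gamma^-1 delta(t-t').

.toy_defaults <- list(
  three_state = list(
    p = 6L, well_amplitude = 1e-4, gaussian_width = 0.8,
    centers = rbind(c(0, 0), c(-1.5, -1.5), c(1.5, 1.5))),
  four_state = list(
    p = 4L, well_amplitude = 1e-4, gaussian_width = 0.8,
    centers = rbind(c(0, 0), c(2, -1), c(0.5, 2), c(-0.5, -2), c(-2, 1)))
)

#' Specification of a 2D multi-well toy potential
#'
#' The potential is a polynomial confinement minus a sum of unnormalized
#' Gaussian wells: \code{V(x, y) = W (x^p + y^p) - sum_i G(x, x_i) G(y, y_i)}
#' with \code{G(u, u0) = exp(-(u - u0)^2 / (2 s^2))}, \code{p = 6} for the
#' three-well model and \code{p = 4} for the four-well model (which carries
#' five Gaussian centers).  Defaults are the published reduced-unit values
#' (\code{W = 1e-4}, \code{s = 0.8}, and the standard center layouts).
#'
#' @param kind \code{"three_state"} or \code{"four_state"}.
#' @param wellAmplitude confining amplitude W (> 0 unless you want free
#'   diffusion, in which case 0 with no centers is allowed).
#' @param gaussianWidth Gaussian width s (> 0).
#' @param wellCenters numeric matrix of (x, y) centers; three rows for
#'   \code{three_state}, five for \code{four_state}.
#' @return a list-based spec consumed by [toyPotentialEnergy()],
#'   [toyForce()] and [runBDToy()].
#' @examples
#' spec <- toyPotentialSpec("three_state")
#' toyPotentialEnergy(spec, c(0, 0))
#' @export
toyPotentialSpec <- function(kind = c("three_state", "four_state"),
                             wellAmplitude = NULL, gaussianWidth = NULL,
                             wellCenters = NULL) {
  kind <- match.arg(kind)
  def <- .toy_defaults[[kind]]
  spec <- list(
    kind = kind, p = def$p,
    well_amplitude = if (is.null(wellAmplitude)) def$well_amplitude else wellAmplitude,
    gaussian_width = if (is.null(gaussianWidth)) def$gaussian_width else gaussianWidth,
    centers = if (is.null(wellCenters)) def$centers else as.matrix(wellCenters))
  if (spec$well_amplitude < 0) stop("wellAmplitude must be >= 0")
  stopifnot_scalar(spec$gaussian_width, "gaussianWidth")
  nexp <- if (kind == "three_state") 3L else 5L
  if (nrow(spec$centers) && nrow(spec$centers) != nexp)
    stop(sprintf("%s expects exactly %d Gaussian centers", kind, nexp))
  if (nrow(spec$centers) && ncol(spec$centers) != 2L)
    stop("wellCenters must have two columns (x, y)")
  structure(spec, class = c("ToyPotentialSpec", "list"))
}

#' Specification of the 2D worm-like bead chain
#'
#' A chain of \code{nBeads} beads joined by stiff harmonic springs, with a
#' harmonic bending potential about the straight-chain angle, Hertzian
#' contact repulsion \code{E (1 - r/sigma)^{5/2}} between non-bonded beads,
#' and an optional tangential self-propulsion force of magnitude
#' \code{propulsion} along every bond (\code{propulsion = 0} is the passive
#' chain).  Defaults are the published reduced-unit parameters of the active
#' chain; the bond constant is a stiff-spring default (bond-length
#' fluctuations much smaller than the rest length).
#'
#' @param nBeads number of beads N (>= 3).
#' @param beadDiameter contact diameter sigma.
#' @param restLength equilibrium bond length d0.
#' @param bondK bond spring constant k0 (energy / length^2).
#' @param bendK bending rigidity k_ang (energy).
#' @param restAngle equilibrium bond angle theta0 (radians; pi = straight).
#' @param hertzE Hertzian amplitude E (energy / length^3 in reduced units).
#' @param propulsion self-propulsion force magnitude f_m per bond.
#' @return a list-based spec consumed by [runBDPolymer()] and friends.
#' @export
polymerSpec <- function(nBeads = 32L, beadDiameter = 1.0, restLength = 0.5,
                        bondK = 1e4, bendK = 45.0, restAngle = pi,
                        hertzE = 1e4, propulsion = 5.0) {
  if (nBeads < 3L) stop("nBeads must be >= 3")
  for (nm in c("beadDiameter", "restLength", "bondK", "bendK", "hertzE"))
    stopifnot_scalar(get(nm), nm)
  structure(list(n_beads = as.integer(nBeads), bead_diameter = beadDiameter,
                 rest_length = restLength, bond_k = bondK, bend_k = bendK,
                 rest_angle = restAngle, hertz_E = hertzE,
                 propulsion = propulsion, dims = 2L),
            class = c("PolymerSpec", "list"))
}

#' Integrator settings for Brownian dynamics
#'
#' @param dt Euler time step in tau_BD units (0.01 for the toy potentials,
#'   0.001 for the bead chain, as published).
#' @param gamma friction coefficient.
#' @param kT thermal energy.
#' @param nSteps number of integration steps.
#' @param saveStride save every \code{saveStride}-th step (the initial
#'   configuration is always frame 1).
#' @param seed RNG seed; identical (spec, integrator, seed) give
#'   bit-identical trajectories.
#' @export
integratorSpec <- function(dt, gamma = 1.0, kT = 1.0, nSteps = 1000L,
                           saveStride = 1L, seed = 1L) {
  stopifnot_scalar(dt, "dt"); stopifnot_scalar(gamma, "gamma")
  if (kT < 0) stop("kT must be >= 0")
  if (nSteps < 1L || saveStride < 1L) stop("nSteps and saveStride must be >= 1")
  structure(list(dt = dt, gamma = gamma, kT = kT, nSteps = as.integer(nSteps),
                 save_stride = as.integer(saveStride), seed = as.integer(seed)),
            class = c("IntegratorSpec", "list"))
}

#' Toy-potential energy
#'
#' @param spec a [toyPotentialSpec()].
#' @param point numeric (x, y) or an n x 2 matrix of points.
#' @return energy value(s).
#' @export
toyPotentialEnergy <- function(spec, point) {
  stopifnot(inherits(spec, "ToyPotentialSpec"))
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  if (!all(is.finite(pts))) stop("point must be finite")
  vapply(seq_len(nrow(pts)), function(i)
    toy_energy_cpp(pts[i, 1], pts[i, 2], spec$well_amplitude, spec$p,
                   spec$gaussian_width, spec$centers), numeric(1))
}

#' Toy-potential force (-grad V, analytic)
#'
#' @inheritParams toyPotentialEnergy
#' @return numeric (fx, fy), or an n x 2 matrix for matrix input.
#' @export
toyForce <- function(spec, point) {
  stopifnot(inherits(spec, "ToyPotentialSpec"))
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  if (!all(is.finite(pts))) stop("point must be finite")
  out <- t(vapply(seq_len(nrow(pts)), function(i)
    toy_force_cpp(pts[i, 1], pts[i, 2], spec$well_amplitude, spec$p,
                  spec$gaussian_width, spec$centers), numeric(2)))
  if (!is.matrix(point)) out[1, ] else out
}

#' Simulate a particle in a toy potential
#'
#' Euler-Maruyama integration of overdamped motion.  The default initial
#' condition is a well center chosen uniformly at random (seeded); with no
#' centers the origin is used.
#'
#' @param spec a [toyPotentialSpec()].
#' @param integ an [integratorSpec()] (use \code{dt = 0.01}).
#' @param x0 optional (x, y) initial position.
#' @return a [Trajectory-class] with one particle.
#' @examples
#' spec <- toyPotentialSpec("three_state")
#' integ <- integratorSpec(dt = 0.01, nSteps = 1000, saveStride = 10, seed = 7)
#' traj <- runBDToy(spec, integ)
#' @export
runBDToy <- function(spec, integ, x0 = NULL) {
  stopifnot(inherits(spec, "ToyPotentialSpec"), inherits(integ, "IntegratorSpec"))
  withSeed(integ$seed, {
    if (is.null(x0)) {
      x0 <- if (nrow(spec$centers))
        spec$centers[sample.int(nrow(spec$centers), 1L), ] else c(0, 0)
    }
    if (!all(is.finite(x0))) stop("x0 must be finite")
    xy <- bd_toy_cpp(x0[1], x0[2], spec$well_amplitude, spec$p,
                     spec$gaussian_width, spec$centers, integ$dt, integ$gamma,
                     integ$kT, integ$nSteps, integ$save_stride)
    fr <- array(xy, dim = c(nrow(xy), 1L, 2L))
    new("Trajectory", frames = fr,
        dtPerFrame = integ$dt * integ$save_stride,
        meta = list(system = unclass(spec), integrator = unclass(integ)))
  })
}

#' Total potential energy of a bead-chain configuration
#'
#' Bond + bending + Hertzian contact terms (self-propulsion is
#' non-conservative and carries no potential).
#'
#' @param spec a [polymerSpec()].
#' @param pos numeric matrix \code{[nBeads, 2]}.
#' @export
polymerEnergy <- function(spec, pos) {
  stopifnot(inherits(spec, "PolymerSpec"))
  polymer_energy_cpp(as.matrix(pos), spec$rest_length, spec$bond_k,
                     spec$bend_k, spec$rest_angle, spec$hertz_E,
                     spec$bead_diameter)
}

#' Per-bead force on a bead-chain configuration
#'
#' \code{-grad} of [polymerEnergy()] plus, when \code{includePropulsion},
#' the tangential self-propulsion (f_m along each bond, split equally onto
#' the bond's two beads).
#'
#' @inheritParams polymerEnergy
#' @param includePropulsion include the active force term.
#' @return numeric matrix \code{[nBeads, 2]}.
#' @export
polymerForce <- function(spec, pos, includePropulsion = TRUE) {
  stopifnot(inherits(spec, "PolymerSpec"))
  polymer_force_cpp(as.matrix(pos), spec$rest_length, spec$bond_k,
                    spec$bend_k, spec$rest_angle, spec$hertz_E,
                    spec$bead_diameter,
                    if (includePropulsion) spec$propulsion else 0.0)
}

#' Straight-chain initial configuration
#'
#' Beads along the x axis at the rest bond length, the default start of
#' [runBDPolymer()].
#'
#' @param spec a [polymerSpec()].
#' @export
straightChain <- function(spec) {
  cbind(x = (seq_len(spec$n_beads) - 1) * spec$rest_length,
        y = rep(0, spec$n_beads))
}

#' Spiral initial configuration
#'
#' A tightly wound planar spiral with the leading end (the end the tangential
#' propulsion drives towards) at the center.  The spiral is a metastable
#' state of the active chain; with the published parameters its spontaneous
#' nucleation from a straight chain is far rarer than its breakup, so
#' trajectories meant to sample both the spiral and the extended state start
#' here.  Beads sit at the rest bond length; non-bonded neighbours start
#' inside the Hertzian contact range, which relaxes within a few time steps.
#'
#' @param spec a [polymerSpec()].
#' @param startRadius radius of the innermost turn, in bead diameters.
#' @export
spiralChain <- function(spec, startRadius = 0.8) {
  n <- spec$n_beads
  d0 <- spec$rest_length
  pos <- matrix(0, n, 2)
  ang <- 0
  rad <- startRadius * spec$bead_diameter
  for (i in 2:n) {
    dth <- d0 / rad
    ang <- ang + dth
    rad <- rad + 0.25 * d0 * dth / (2 * pi)
    pos[i, ] <- pos[i - 1, ] + d0 * c(cos(ang), sin(ang))
  }
  pos[n:1, , drop = FALSE]   # leading bead (highest index) at the center
}

#' Simulate the worm-like bead chain
#'
#' Per-bead Euler-Maruyama integration of the overdamped chain with bond,
#' bending and Hertzian contact forces plus tangential self-propulsion.
#'
#' @param spec a [polymerSpec()].
#' @param integ an [integratorSpec()] (published settings: \code{dt = 0.001},
#'   \code{gamma = 200}, \code{kT = 1}).
#' @param init optional \code{[nBeads, 2]} initial configuration; default is
#'   a straight chain along x at the rest bond length.
#' @return a [Trajectory-class] with \code{nBeads} particles.
#' @export
runBDPolymer <- function(spec, integ, init = NULL) {
  stopifnot(inherits(spec, "PolymerSpec"), inherits(integ, "IntegratorSpec"))
  if (is.null(init)) init <- straightChain(spec)
  init <- as.matrix(init)
  if (nrow(init) != spec$n_beads || ncol(init) != 2L)
    stop("init must be an [nBeads, 2] matrix")
  if (min(dist(init)) <= 0) stop("initial configuration has overlapping beads")
  withSeed(integ$seed, {
    cube <- bd_polymer_cpp(init, spec$rest_length, spec$bond_k, spec$bend_k,
                           spec$rest_angle, spec$hertz_E, spec$bead_diameter,
                           spec$propulsion, integ$dt, integ$gamma, integ$kT,
                           integ$nSteps, integ$save_stride)
    fr <- aperm(cube, c(3L, 1L, 2L))   # -> [frame, bead, dim]
    new("Trajectory", frames = fr,
        dtPerFrame = integ$dt * integ$save_stride,
        meta = list(system = unclass(spec), integrator = unclass(integ)))
  })
}
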