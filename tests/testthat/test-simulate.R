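# Brownian-dynamics simulators: potentials, forces, integrator statistics.

test_that("three-well potential matches a direct scalar evaluation", {
  spec <- toyPotentialSpec("three_state")
  # independent one-line oracle: W*(x^6+y^6) - sum_i G(x,xi)G(yi)
  G <- function(u, u0) exp(-(u - u0)^2 / (2 * 0.8^2))
  oracle <- function(x, y)
    1e-4 * (x^6 + y^6) - G(x, 0) * G(y, 0) -
      G(x, -1.5) * G(y, -1.5) - G(x, 1.5) * G(y, 1.5)
  expect_equal(toyPotentialEnergy(spec, c(0, 0)), oracle(0, 0), tolerance = 1e-12)
  expect_equal(round(toyPotentialEnergy(spec, c(0, 0)), 4), -1.0595)
  for (p in list(c(0.3, -0.7), c(2, 1), c(-1.2, 1.4)))
    expect_equal(toyPotentialEnergy(spec, p), oracle(p[1], p[2]),
                 tolerance = 1e-12)
})

test_that("symmetric wells have equal energies and the far field confines", {
  spec <- toyPotentialSpec("three_state")
  expect_equal(toyPotentialEnergy(spec, c(1.5, 1.5)),
               toyPotentialEnergy(spec, c(-1.5, -1.5)))
  v <- toyPotentialEnergy(spec, rbind(c(3, 3), c(5, 5), c(8, 8)))
  expect_true(all(diff(v) > 0) && v[3] > 10)
})

test_that("analytic toy forces match central finite differences", {
  h <- 1e-5
  for (kind in c("three_state", "four_state")) {
    spec <- toyPotentialSpec(kind)
    set.seed(4)
    pts <- matrix(runif(12, -2, 2), ncol = 2)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      fd <- c((toyPotentialEnergy(spec, c(p[1] - h, p[2])) -
               toyPotentialEnergy(spec, c(p[1] + h, p[2]))) / (2 * h),
              (toyPotentialEnergy(spec, c(p[1], p[2] - h)) -
               toyPotentialEnergy(spec, c(p[1], p[2] + h))) / (2 * h))
      expect_equal(toyForce(spec, p), fd, tolerance = 1e-6)
    }
  }
  # both center layouts are inversion-symmetric: the origin is stationary
  expect_equal(toyForce(toyPotentialSpec("three_state"), c(0, 0)), c(0, 0),
               tolerance = 1e-12)
  expect_equal(toyForce(toyPotentialSpec("four_state"), c(0, 0)), c(0, 0),
               tolerance = 1e-12)
})

test_that("zero-temperature dynamics at a stationary point stay put", {
  spec <- toyPotentialSpec("three_state")
  integ <- integratorSpec(dt = 0.01, kT = 0, nSteps = 200, saveStride = 10,
                          seed = 1)
  traj <- runBDToy(spec, integ, x0 = c(0, 0))
  expect_true(all(abs(frames(traj)) < 1e-12))
})

test_that("identical spec and seed give bit-identical trajectories", {
  spec <- toyPotentialSpec("three_state")
  integ <- integratorSpec(dt = 0.01, nSteps = 500, saveStride = 5, seed = 99)
  expect_identical(frames(runBDToy(spec, integ)), frames(runBDToy(spec, integ)))
})

test_that("free diffusion satisfies the fluctuation-dissipation relation", {
  # V == 0: zero confinement, no Gaussian wells
  free <- toyPotentialSpec("three_state", wellAmplitude = 0,
                           wellCenters = matrix(numeric(), 0, 2))
  kT <- 1.3; gamma <- 2; dt <- 0.01
  integ <- integratorSpec(dt = dt, gamma = gamma, kT = kT, nSteps = 50000,
                          saveStride = 1, seed = 5)
  xy <- frames(runBDToy(free, integ, x0 = c(0, 0)))[, 1, ]
  inc <- diff(xy)
  v_hat <- mean(inc^2)              # per-component increment variance
  v_true <- 2 * kT * dt / gamma
  se <- v_true * sqrt(2 / length(inc))
  expect_lt(abs(v_hat - v_true), 3 * se)

  # mean-squared displacement after n steps over replicas: 4 (kT/gamma) n dt
  n <- 20; nrep <- 1000
  msd <- vapply(seq_len(nrep), function(r) {
    integ_r <- integratorSpec(dt = dt, gamma = gamma, kT = kT, nSteps = n,
                              saveStride = n, seed = 1000 + r)
    f <- frames(runBDToy(free, integ_r, x0 = c(0, 0)))
    sum((f[2, 1, ] - f[1, 1, ])^2)
  }, numeric(1))
  msd_true <- 4 * (kT / gamma) * n * dt
  expect_lt(abs(mean(msd) - msd_true), 3 * sd(msd) / sqrt(nrep))
})

test_that("long runs sample the Boltzmann weights of the wells", {
  spec <- toyPotentialSpec("three_state")
  integ <- integratorSpec(dt = 0.01, gamma = 1, kT = 1, nSteps = 4e5,
                          saveStride = 10, seed = 21)
  xy <- frames(runBDToy(spec, integ))[, 1, ]
  centers <- spec$centers
  assign_well <- function(p) which.min(colSums((t(centers) - p)^2))
  occ <- tabulate(apply(xy, 1, assign_well), 3) / nrow(xy)
  # oracle: 2D quadrature of exp(-V/kT) over the Voronoi basin of each center
  # (the weak x^6 confinement lets the particle roam to ~|x| = 6.5, so the
  # quadrature domain must cover the full accessible region)
  g <- seq(-7, 7, by = 0.035)
  grid <- expand.grid(x = g, y = g)
  w <- exp(-toyPotentialEnergy(spec, as.matrix(grid)))
  basin <- apply(as.matrix(grid), 1, assign_well)
  theo <- vapply(1:3, function(k) sum(w[basin == k]), numeric(1))
  theo <- theo / sum(theo)
  # block standard error over 10 trajectory blocks
  blocks <- split(seq_len(nrow(xy)), cut(seq_len(nrow(xy)), 10))
  bocc <- t(vapply(blocks, function(ix)
    tabulate(apply(xy[ix, ], 1, assign_well), 3) / length(ix), numeric(3)))
  se <- apply(bocc, 2, sd) / sqrt(nrow(bocc))
  expect_true(all(abs(occ - theo) < 3 * se + 0.01))
})

test_that("polymer forces are the exact gradient of the chain energy", {
  spec <- polymerSpec(nBeads = 6)
  set.seed(2)
  pos <- straightChain(spec) + matrix(rnorm(12, sd = 0.07), 6, 2)
  Fa <- polymerForce(spec, pos, includePropulsion = FALSE)
  h <- 1e-5
  Fn <- Fa * 0
  for (i in 1:6) for (d in 1:2) {
    pp <- pos; pm <- pos
    pp[i, d] <- pp[i, d] + h; pm[i, d] <- pm[i, d] - h
    Fn[i, d] <- (polymerEnergy(spec, pm) - polymerEnergy(spec, pp)) / (2 * h)
  }
  expect_lt(max(abs(Fa - Fn)) / max(abs(Fa)), 1e-5)
})

test_that("the passive straight chain at its minimum is force-free and static", {
  spec <- polymerSpec(propulsion = 0)
  pos <- straightChain(spec)
  expect_lt(max(abs(polymerForce(spec, pos))), 1e-10)
  integ <- integratorSpec(dt = 0.001, gamma = 200, kT = 0, nSteps = 100,
                          saveStride = 10, seed = 1)
  traj <- runBDPolymer(spec, integ)
  expect_lt(max(abs(sweep(frames(traj), c(2, 3), pos))), 1e-10)
})

test_that("tangential propulsion adds f_m per bond split across its beads", {
  spec <- polymerSpec(propulsion = 5)
  pos <- straightChain(spec)
  dF <- polymerForce(spec, pos, TRUE) - polymerForce(spec, pos, FALSE)
  # straight chain along x: every bond tangent is +x
  expect_equal(dF[1, 1], 2.5, tolerance = 1e-12)      # one bond's half
  expect_equal(dF[2, 1], 5.0, tolerance = 1e-12)      # two half-shares
  expect_equal(sum(dF[, 1]), 5 * (spec$n_beads - 1), tolerance = 1e-9)
  expect_equal(dF[, 2], rep(0, spec$n_beads))
})

test_that("overlapping initial beads are rejected", {
  spec <- polymerSpec(nBeads = 4)
  pos <- straightChain(spec)
  pos[2, ] <- pos[1, ]
  expect_error(runBDPolymer(spec, integratorSpec(dt = 1e-3, nSteps = 10),
                            init = pos), "overlap")
})

test_that("trajectory files round-trip through npy, csv and xyz", {
  spec <- toyPotentialSpec("three_state")
  traj <- runBDToy(spec, integratorSpec(dt = 0.01, nSteps = 20, saveStride = 10,
                                        seed = 3))
  for (fmt in c("npy", "csv", "xyz")) {
    f <- tempfile(fileext = paste0(".", fmt))
    writeTrajectory(traj, f)
    back <- readTrajectory(f, dtPerFrame = dtPerFrame(traj))
    expect_equal(frames(back), frames(traj), tolerance = 1e-10)
  }
})

test_that("malformed trajectory files raise parse errors naming the spot", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("frame,particle,x,y", "1,1,0.0,oops"), f)
  expect_error(readTrajectory(f), "non-numeric")
  g <- tempfile(fileext = ".xyz")
  writeLines(c("3", "frame 1", "X 0 0 0", "X 1 1 0"), g)
  expect_error(readTrajectory(g), "truncated|parse")
})
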