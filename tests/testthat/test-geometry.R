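test_that("superposition recovers rigid motions exactly", {
  set.seed(1)
  x <- matrix(rnorm(15), 5, 3)

  id <- superpose(x, x)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$rotation, diag(3), tolerance = 1e-8)

  # reference rotated 90 degrees about z and translated
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  ref <- sweep(x %*% Rz, 2, c(5, 0, 0), `+`)
  tr <- superpose(x, ref)
  expect_equal(tr$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-8)
  expect_equal(applyTransform(x, tr), ref, tolerance = 1e-8)
  # transform preserves pairwise distances
  expect_equal(as.matrix(dist(applyTransform(x, tr))), as.matrix(dist(x)),
               tolerance = 1e-8)

  expect_error(superpose(x[1:2, ], x[1:2, ]), "at least 3")
  line <- cbind(1:4, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("Kabsch rmsd matches the exhaustive rotation-grid oracle", {
  set.seed(42)
  for (i in 1:25) {
    a <- matrix(rnorm(15, sd = 2), 5, 3)
    b <- matrix(rnorm(15, sd = 2), 5, 3)
    expect_equal(superpose(a, b)$rmsd, oracleRmsd(a, b), tolerance = 1e-3)
  }
})

test_that("rmsd series: fit on one selection, measure on another", {
  pep <- makePeptide(resnos = 1:3)
  n <- nrow(pep$xyz)
  # frames: identical, ligand-like subset translated 2 A, identical
  moved <- pep$xyz
  moved[9:12, ] <- moved[9:12, ] + matrix(rep(c(2, 0, 0), each = 4), 4, 3)
  traj <- makeTraj(pep$topology, list(pep$xyz, pep$xyz, moved))

  s0 <- rmsdSeries(traj, "backbone")
  expect_equal(s0$value[1], 0)
  expect_true(all(s0$value >= 0))

  # fit on residues 1-2 (static), measure residue 3 (rigidly shifted)
  s <- rmsdSeries(traj, "resid 1:2", "resid 3")
  expect_equal(s$value, c(0, 0, 2), tolerance = 1e-8)

  # static trajectory gives all-zero series
  st <- makeTraj(pep$topology, list(pep$xyz, pep$xyz, pep$xyz))
  expect_equal(rmsdSeries(st, "backbone")$value, c(0, 0, 0),
               tolerance = 1e-10)
})

test_that("pairwise rmsd matrix matches frame-by-frame superposition", {
  pep <- makePeptide(resnos = 1:3)
  set.seed(7)
  frames <- lapply(1:6, function(i) pep$xyz + matrix(rnorm(36, sd = 0.4),
                                                     12, 3))
  traj <- makeTraj(pep$topology, frames)
  m <- pairwiseRmsd(traj, "backbone")
  expect_equal(diag(m), rep(0, 6))
  expect_equal(max(abs(m - t(m))), 0, tolerance = 1e-6)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(m[i, j],
                   superpose(frames[[i]], frames[[j]])$rmsd,
                   tolerance = 1e-9)
    }
  }
  # frames {A, A, B}: off-diagonals {0, d, d}
  A <- pep$xyz
  B <- sweep(pep$xyz %*% randomRotation(), 2, c(3, -1, 2), `+`)
  B[5, ] <- B[5, ] + 1
  tr2 <- makeTraj(pep$topology, list(A, A, B))
  m2 <- pairwiseRmsd(tr2, "backbone")
  d <- superpose(A, B)$rmsd
  expect_equal(m2[1, 2], 0, tolerance = 1e-8)
  expect_equal(m2[1, 3], d, tolerance = 1e-8)
  expect_equal(m2[2, 3], d, tolerance = 1e-8)
})

test_that("rmsf closed forms: static, oscillating, and Gaussian cases", {
  pep <- makePeptide(resnos = 1:3)
  st <- makeTraj(pep$topology, list(pep$xyz, pep$xyz, pep$xyz, pep$xyz))
  expect_equal(rmsf(st, "backbone")$rmsf, rep(0, 12), tolerance = 1e-10)
  expect_error(rmsf(makeTraj(pep$topology, list(pep$xyz)), "backbone"),
               "at least 2")

  # one atom oscillating +/- a along x about its mean, fit on others
  a <- 0.7
  up <- pep$xyz; up[5, 1] <- up[5, 1] + a
  dn <- pep$xyz; dn[5, 1] <- dn[5, 1] - a
  osc <- makeTraj(pep$topology, list(up, dn, up, dn))
  r <- rmsf(osc, "all", fit_selection = "not resid 2")
  expect_equal(r$rmsf[5], a, tolerance = 1e-8)
  expect_equal(max(r$rmsf[-5]), 0, tolerance = 1e-8)

  # per-residue aggregation averages over the residue's atoms
  rr <- rmsf(osc, "all", fit_selection = "not resid 2", by = "residue")
  expect_equal(rr$rmsf[rr$resno == 2], a / 4, tolerance = 1e-8)
})

test_that("rmsf of isotropic Gaussian jitter approaches sigma * sqrt(3)", {
  pep <- makePeptide(resnos = 1:2)
  sigma <- 0.3
  set.seed(11)
  nf <- 10000
  coords <- array(rep(pep$xyz, nf), c(8, 3, nf))
  # anchor atoms 1:4 fixed; atoms 5:8 jittered isotropically
  coords[5:8, , ] <- coords[5:8, , ] + rnorm(4 * 3 * nf, sd = sigma)
  traj <- Trajectory(pep$topology, coords)
  r <- rmsf(traj, "resid 2", fit_selection = "resid 1")
  expect_equal(mean(r$rmsf), sigma * sqrt(3), tolerance = 0.02)
})

test_that("sasa matches closed form and integration oracle", {
  # isolated sphere: 4 pi (r + probe)^2
  single <- sasa(matrix(0, 1, 3), elements = "C")
  expect_equal(as.numeric(single), 4 * pi * 3.1^2, tolerance = 0.02)

  # full overlap collapses to one sphere
  both <- sasa(matrix(0, 2, 3), elements = c("C", "C"))
  expect_equal(as.numeric(both), 4 * pi * 3.1^2, tolerance = 0.03)

  # dimers at several separations vs fine-grid integration oracle
  for (d in c(1.0, 2.5, 4.0, 5.5)) {
    got <- as.numeric(sasa(rbind(c(0, 0, 0), c(d, 0, 0)),
                           elements = c("C", "N")))
    want <- dimerSasaOracle(1.70, 1.55, d)
    expect_equal(got, want, tolerance = 0.03)
  }

  # monotone decrease on approach
  areas <- vapply(c(6.5, 5, 3.5, 2, 0.5),
                  function(d) as.numeric(sasa(rbind(c(0, 0, 0), c(d, 0, 0)),
                                              elements = c("C", "C"))),
                  numeric(1))
  expect_true(all(diff(areas) <= 1e-9))

  expect_error(sasa(matrix(0, 1, 3), elements = "XX"),
               "no van der Waals radius")
})

test_that("center-of-mass distances: closed forms and mass weighting", {
  atoms <- data.frame(eleno = 1:3, elety = c("C1", "C2", "O1"),
                      resid = c("LIG", "LIG", "HOH"),
                      resno = c(1, 1, 2), chain = "A",
                      elesy = c("C", "C", "O"))
  topo <- Topology(atoms, xyz = matrix(0, 3, 3))
  fr <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0))
  traj <- makeTraj(topo, list(fr))

  # two single atoms at distance 5
  fr2 <- rbind(c(0, 0, 0), c(99, 99, 99), c(3, 4, 0))
  t2 <- makeTraj(topo, list(fr2))
  expect_equal(comDistanceSeries(t2, 1, 3)$value, 5)

  # equal-mass pair's midpoint coincides with the third atom
  expect_equal(comDistanceSeries(traj, c(1, 2), 3)$value, 0,
               tolerance = 1e-12)

  # unequal masses shift the center of mass: C (12.011) + O (15.999)
  atoms2 <- atoms; atoms2$elesy <- c("C", "O", "C")
  topo2 <- Topology(atoms2, xyz = matrix(0, 3, 3))
  t3 <- makeTraj(topo2, list(fr))
  mw <- comDistanceSeries(t3, c(1, 2), 3)$value
  uw <- comDistanceSeries(t3, c(1, 2), 3, mass_weighted = FALSE)$value
  com_x <- 2 * 15.999 / (12.011 + 15.999)
  expect_equal(mw, abs(com_x - 1), tolerance = 1e-9)
  expect_equal(uw, 0, tolerance = 1e-12)
})

test_that("geometric descriptors are invariant under a global rigid motion", {
  spec <- syntheticSpec(n_residues = 10, n_frames = 12, seed = 9)
  g <- generateSystem(spec)
  tr <- g$trajectory
  R <- randomRotation()
  moved <- tr
  for (f in seq_len(nFrames(tr)))
    moved$coords[, , f] <- sweep(tr$coords[, , f] %*% R, 2, c(10, -4, 7), `+`)

  expect_equal(rmsdSeries(moved, "backbone")$value,
               rmsdSeries(tr, "backbone")$value, tolerance = 1e-6)
  expect_equal(unclass(pairwiseRmsd(moved, "backbone")),
               unclass(pairwiseRmsd(tr, "backbone")), tolerance = 1e-6)
  expect_equal(comDistanceSeries(moved, "ligand", "resid 5")$value,
               comDistanceSeries(tr, "ligand", "resid 5")$value,
               tolerance = 1e-6)
  expect_equal(rmsf(moved, "backbone")$rmsf, rmsf(tr, "backbone")$rmsf,
               tolerance = 1e-6)
})
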