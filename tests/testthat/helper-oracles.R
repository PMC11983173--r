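# Independent oracles and small in-code fixtures used across tests.

# --- exhaustive rotation-grid RMSD oracle ---------------------------
# Evaluates the superposition objective over a dense random quaternion
# grid with local grid refinement; no SVD involved.

quatRotCols <- function(Q) {
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
}

oracleRmsd <- function(mobile, ref, n_coarse = 20000, n_refine = 4000) {
  M <- sweep(mobile, 2, colMeans(mobile))
  N <- sweep(ref, 2, colMeans(ref))
  A <- as.vector(t(M) %*% N)
  n <- nrow(M)
  c0 <- (sum(M^2) + sum(N^2)) / n
  # rmsd^2 under rotation R is c0 - 2 tr(R^T M^T N)/n; the trace is a
  # dot product with the 9 rotation-matrix entries
  evalQ <- function(Q) sqrt(pmax(0, c0 - 2 * (quatRotCols(Q) %*% A) / n))
  Q <- matrix(stats::rnorm(n_coarse * 4), ncol = 4)
  Q <- Q / sqrt(rowSums(Q^2))
  r <- evalQ(Q)
  i <- which.min(r)
  best <- r[i]; bestq <- Q[i, ]
  for (eps in c(0.1, 0.03, 0.01, 0.003, 0.001)) {
    P <- matrix(stats::rnorm(n_refine * 4, sd = eps), ncol = 4)
    P <- sweep(P, 2, bestq, `+`)
    P <- P / sqrt(rowSums(P^2))
    r <- evalQ(P)
    i <- which.min(r)
    if (r[i] < best) { best <- r[i]; bestq <- P[i, ] }
  }
  as.numeric(best)
}

# --- fine-grid integration oracle for two-sphere SASA ---------------
# Sphere A at the origin, B at (d, 0, 0). Points on A's solvent sphere
# are parameterised by z = cos(angle to the x axis), uniform z being
# equal-area; the exposed fraction is a 1-D integral over z.

dimerSasaOracle <- function(r1, r2, d, probe = 1.4, npts = 2e5) {
  Ra <- r1 + probe; Rb <- r2 + probe
  z <- seq(-1 + 0.5 / npts, 1 - 0.5 / npts, length.out = npts)
  fracA <- mean(Ra^2 - 2 * Ra * z * d + d^2 >= Rb^2)
  fracB <- mean(Rb^2 - 2 * Rb * z * d + d^2 >= Ra^2)
  4 * pi * (Ra^2 * fracA + Rb^2 * fracB)
}

# --- tiny peptide fixtures -----------------------------------------

helixCA <- function(i) c(2.3 * cos(i * 100 * pi / 180),
                         2.3 * sin(i * 100 * pi / 180), 1.5 * i)

makePeptide <- function(resnos = 1:3, resnames = rep("ALA", length(resnos)),
                        extra = NULL) {
  atoms <- NULL
  xyz <- NULL
  eleno <- 0L
  for (j in seq_along(resnos)) {
    ca <- helixCA(j)
    local_atoms <- data.frame(
      elety = c("N", "CA", "C", "O"),
      off = I(list(c(-0.85, -0.90, -0.55), c(0, 0, 0),
                   c(1.00, 0.62, 0.58), c(1.32, 1.70, 0.75))))
    for (r in seq_len(nrow(local_atoms))) {
      eleno <- eleno + 1L
      atoms <- rbind(atoms, data.frame(
        eleno = eleno, elety = local_atoms$elety[r],
        resid = resnames[j], resno = resnos[j], chain = "A",
        elesy = substr(local_atoms$elety[r], 1, 1)))
      xyz <- rbind(xyz, ca + local_atoms$off[[r]])
    }
    if (!is.null(extra) && resnos[j] %in% extra$resno) {
      nm <- extra$elety[extra$resno == resnos[j]]
      for (e in nm) {
        eleno <- eleno + 1L
        atoms <- rbind(atoms, data.frame(
          eleno = eleno, elety = e, resid = resnames[j],
          resno = resnos[j], chain = "A", elesy = substr(e, 1, 1)))
        xyz <- rbind(xyz, ca + c(2.0, 1.0, 0.3))
      }
    }
  }
  list(topology = Topology(atoms, xyz = xyz), xyz = xyz)
}

# trajectory holding explicit coordinate frames for a given topology
makeTraj <- function(topo, frames, dt = 1) {
  coords <- array(NA_real_, c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  Trajectory(topo, coords, dt = dt)
}

# donor/acceptor fixture: residue 1 carries N-H, residue 2 an O
# acceptor whose position is supplied per frame
makeHBondSystem <- function(acceptor_pos_frames) {
  atoms <- data.frame(
    eleno = 1:5,
    elety = c("N", "H", "CA", "CB", "O"),
    resid = c("ALA", "ALA", "ALA", "ALA", "SER"),
    resno = c(1, 1, 1, 1, 2),
    chain = "A",
    elesy = c("N", "H", "C", "C", "O"))
  bonds <- rbind(c(1L, 2L))
  topo <- Topology(atoms, bonds = bonds)
  frames <- lapply(acceptor_pos_frames, function(p) {
    rbind(c(0, 0, 0),      # N donor
          c(1, 0, 0),      # H along +x
          c(-1.2, 0.8, 0), # CA
          c(-1.2, -0.8, 0.6),
          p)               # acceptor O
  })
  makeTraj(topo, frames)
}

randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(quatRotCols(matrix(q, 1)), 3, 3)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
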