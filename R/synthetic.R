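#' Specification for a synthetic receptor-ligand system
#'
#' Describes the planted ground truth of a generated system: a rigid
#' helical receptor with thermal jitter and slow rigid-body drift, a
#' ligand hopping between `n_modes` rigid poses (metastable binding
#' modes realised as contiguous dwell blocks), and side-chain
#' donor/acceptor pairs whose hydrogen-bond geometry is switched
#' on/off to hit scheduled occupancies exactly.
#'
#' Defaults emulate the statistical structure binding-mode clustering
#' assumes: a few well-separated modes (separation several times the
#' thermal noise), frames stored every 10 ps, and dwell times long
#' enough that modes form contiguous stretches rather than i.i.d.
#' shuffles.
#'
#' @param n_residues receptor length (residues; 5 backbone atoms each).
#' @param n_ligand_atoms atoms in the rigid ligand.
#' @param n_modes number of planted binding modes (1-5).
#' @param mode_fractions frame fraction per mode; must sum to 1.
#' @param mode_separation distance between planted ligand poses,
#'   Angstrom.
#' @param noise_sigma stationary per-coordinate amplitude of thermal
#'   jitter, Angstrom.
#' @param noise_rho frame-to-frame correlation of the jitter (AR(1)).
#'   Thermal displacements in stored MD frames are time-correlated —
#'   the very reason stride sampling is used before clustering; 0
#'   gives white noise.
#' @param hbond_schedule data.frame (`donor_res`, `acceptor_res`,
#'   `occupancy` in percent) of scheduled side-chain hydrogen bonds.
#' @param n_frames frames to generate (>= 10).
#' @param dt_ps time between stored frames, ps.
#' @param min_dwell minimum consecutive frames per mode visit.
#' @param drift_sigma per-frame rigid-body translation random-walk
#'   step, Angstrom (rotation drift scales with it).
#' @param induced_fit fraction of the ligand's mode displacement that
#'   the pocket residues (see [syntheticContacts()]) follow. Real
#'   binding modes are accompanied by receptor-side rearrangement,
#'   which is what makes backbone and interacting-residue RMSD
#'   informative descriptors; 0 gives a perfectly rigid receptor.
#' @param tail_flex stationary transverse amplitude (Angstrom) of the
#'   flexible N- and C-terminal quarters, which swing slowly about a
#'   hinge (independent AR(1) processes, lag correlation 0.9, ramping
#'   to full amplitude at the termini). Mimics the enhanced terminal
#'   mobility real RMSF profiles show and gives the backbone-RMSD
#'   descriptor its realistic slow spread; 0 freezes the tails.
#' @param seed RNG seed; same spec + seed reproduces the system
#'   exactly.
#' @return object of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(n_residues = 24, n_ligand_atoms = 8, n_modes = 3,
                          mode_fractions = rep(1 / n_modes, n_modes),
                          mode_separation = 3.0, noise_sigma = 0.25,
                          noise_rho = 0.6,
                          hbond_schedule = NULL, n_frames = 1000,
                          dt_ps = 10, min_dwell = 10, drift_sigma = 0.03,
                          induced_fit = 0.3, tail_flex = 0.8, seed = 1) {
  if (n_frames < 10) stop("n_frames must be at least 10")
  if (n_modes < 1 || n_modes > 5) stop("n_modes must be 1-5")
  if (length(mode_fractions) != n_modes)
    stop("mode_fractions must have one entry per mode")
  if (abs(sum(mode_fractions) - 1) > 1e-9)
    stop("mode_fractions must sum to 1")
  if (mode_separation <= 0) stop("mode separation must be positive")
  if (!is.null(hbond_schedule)) {
    need <- c("donor_res", "acceptor_res", "occupancy")
    if (!all(need %in% names(hbond_schedule)))
      stop("hbond_schedule needs columns ", paste(need, collapse = ", "))
    if (any(hbond_schedule$occupancy < 0 | hbond_schedule$occupancy > 100))
      stop("infeasible schedule: occupancies must lie in [0, 100]")
    if (any(hbond_schedule$donor_res > n_residues |
              hbond_schedule$acceptor_res > n_residues))
      stop("scheduled residue beyond the receptor")
  }
  structure(list(n_residues = n_residues, n_ligand_atoms = n_ligand_atoms,
                 n_modes = n_modes, mode_fractions = mode_fractions,
                 mode_separation = mode_separation,
                 noise_sigma = noise_sigma, noise_rho = noise_rho,
                 hbond_schedule = hbond_schedule, n_frames = n_frames,
                 dt_ps = dt_ps, min_dwell = min_dwell,
                 drift_sigma = drift_sigma, induced_fit = induced_fit,
                 tail_flex = tail_flex, seed = seed),
            class = "SyntheticSpec")
}

# exact per-mode frame counts, honoring the fractions
modeCounts <- function(fractions, n) {
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# split `count` frames into blocks of >= min_dwell (one block if small)
dwellBlocks <- function(count, min_dwell) {
  nb <- max(1L, count %/% (3L * min_dwell))
  if (nb == 1L) return(count)
  extra <- count - nb * min_dwell
  cuts <- sort(sample.int(extra + nb - 1L, nb - 1L))
  parts <- diff(c(0L, cuts, extra + nb)) - 1L
  as.integer(min_dwell + parts)
}

planModeSequence <- function(spec) {
  counts <- modeCounts(spec$mode_fractions, spec$n_frames)
  blocks <- list()
  for (m in seq_len(spec$n_modes)) {
    if (counts[m] == 0) next
    for (b in dwellBlocks(counts[m], spec$min_dwell))
      blocks[[length(blocks) + 1]] <- c(m, b)
  }
  ord <- sample.int(length(blocks))
  unlist(lapply(blocks[ord], function(bl) rep(bl[1], bl[2])))
}

# planted displacements for up to 5 modes, in units of mode_separation.
# Directions are radial/axial w.r.t. the receptor helix (tangential
# moves would change ligand-residue distances only to second order)
# and magnitudes are graded so every pair of poses differs both in
# distance signature and in ligand RMSD; the minimum pairwise pose
# distance equals mode_separation exactly.
MODE_DIRECTIONS <- rbind(c(0, 0, 0),
                         c(1, 0, 0),
                         c(0.5, 0, 1.2),
                         c(-1.1, 0, 0.4),
                         c(-0.4, 0, -1.2))

#' Generate a synthetic receptor-ligand trajectory with ground truth
#'
#' Builds the system described by a [syntheticSpec()]: an idealised
#' helical receptor (backbone N, CA, C, O per residue; no backbone
#' hydrogens), arginine-like side chains (NE/HE) on scheduled donor
#' residues and glutamate-like carboxylates (OE1) on scheduled
#' acceptors, plus a rigid ring-shaped ligand in the pocket. Per
#' frame, the ligand sits in one planted mode pose (contiguous dwell
#' blocks with exact per-mode frame counts), all atoms receive thermal
#' jitter, the whole complex undergoes a slow rigid-body random walk,
#' and each scheduled donor-H...acceptor geometry is placed exactly
#' inside (2.9 Angstrom, linear) or outside (5.5 Angstrom) the
#' detection criterion according to an exact-count random schedule, so
#' realised occupancies match the targets to within one frame.
#'
#' @param spec a `SyntheticSpec`.
#' @param dir optional output directory; when given, writes
#'   `system.pdb` (topology + first frame), `traj.dcd` and
#'   `ground_truth.json`.
#' @return list with `trajectory` (a [Trajectory()]), `ground_truth`
#'   (per-frame `mode`, `hbond_mask` matrix keyed like "R5-E12",
#'   `displacements`), and `files` (paths, when `dir` was given).
#' @export
generateSystem <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  nres <- spec$n_residues
  sched <- spec$hbond_schedule

  # --- topology ------------------------------------------------------
  donors <- unique(sched$donor_res)
  acceptors <- unique(sched$acceptor_res)
  atoms <- list()
  ideal <- list()
  addAtom <- function(elety, resid, resno, elesy, xyz) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      eleno = length(atoms) + 1L, elety = elety, resid = resid,
      resno = resno, chain = "A", elesy = elesy, stringsAsFactors = FALSE)
    ideal[[length(ideal) + 1]] <<- xyz
  }
  caPos <- function(i) c(2.3 * cos(i * 100 * pi / 180),
                         2.3 * sin(i * 100 * pi / 180), 1.5 * i)
  for (i in seq_len(nres)) {
    resname <- if (i %in% donors) "ARG" else if (i %in% acceptors) "GLU"
               else "ALA"
    ca <- caPos(i)
    addAtom("N", resname, i, "N", ca + c(-0.85, -0.90, -0.55))
    addAtom("CA", resname, i, "C", ca)
    addAtom("C", resname, i, "C", ca + c(1.00, 0.62, 0.58))
    addAtom("O", resname, i, "O", ca + c(1.32, 1.70, 0.75))
  }
  # scheduled side chains: donor NE/HE point toward the acceptor CA
  schedAtoms <- integer(0)
  pairGeom <- list()
  if (!is.null(sched)) {
    for (r in seq_len(nrow(sched))) {
      d <- sched$donor_res[r]; a <- sched$acceptor_res[r]
      u <- caPos(a) - caPos(d)
      u <- u / sqrt(sum(u^2))
      ne <- caPos(d) + 2.5 * u
      addAtom("NE", "ARG", d, "N", ne)
      schedAtoms <- c(schedAtoms, length(atoms))
      addAtom("HE", "ARG", d, "H", ne + 1.0 * u)
      schedAtoms <- c(schedAtoms, length(atoms))
      addAtom("OE1", "GLU", a, "O", ne + 2.9 * u)  # "on" position
      schedAtoms <- c(schedAtoms, length(atoms))
      pairGeom[[r]] <- list(ne_idx = length(atoms) - 2L,
                            he_idx = length(atoms) - 1L,
                            oe_idx = length(atoms), u = u, ne = ne)
    }
  }
  # ligand: rigid ring near the middle of the helix, offset from axis
  lig0 <- caPos(nres / 2) + c(5.5, 0, 0)
  ang <- 2 * pi * (seq_len(spec$n_ligand_atoms) - 1) / spec$n_ligand_atoms
  for (j in seq_len(spec$n_ligand_atoms)) {
    addAtom(paste0("L", j), "LIG", nres + 1L, "C",
            lig0 + c(1.5 * cos(ang[j]), 1.5 * sin(ang[j]),
                     0.4 * (-1)^j))
  }
  atomdf <- do.call(rbind, atoms)
  base <- do.call(rbind, ideal)
  natom <- nrow(atomdf)
  ligIdx <- which(atomdf$resid == "LIG")

  bonds <- NULL
  if (length(schedAtoms) > 0) {
    bonds <- do.call(rbind, lapply(pairGeom, function(g)
      c(g$ne_idx, g$he_idx)))
  }
  topo <- Topology(atomdf, xyz = base, bonds = bonds)

  # --- per-frame ground truth ---------------------------------------
  mode <- planModeSequence(spec)
  disp <- MODE_DIRECTIONS[seq_len(spec$n_modes), , drop = FALSE] *
    spec$mode_separation
  hmask <- NULL
  if (!is.null(sched)) {
    hmask <- matrix(FALSE, spec$n_frames, nrow(sched))
    colnames(hmask) <- paste0("R", sched$donor_res, "-E",
                              sched$acceptor_res)
    for (r in seq_len(nrow(sched))) {
      non <- round(sched$occupancy[r] / 100 * spec$n_frames)
      hmask[sample.int(spec$n_frames, non), r] <- TRUE
    }
  }

  # --- assemble frames ----------------------------------------------
  coords <- array(NA_real_, c(natom, 3, spec$n_frames))
  shift <- c(0, 0, 0)
  angle <- 0
  pocketIdx <- which(atomdf$resno %in% syntheticContacts(spec) &
                       atomdf$resid != "LIG")
  rho <- spec$noise_rho
  jitter <- matrix(stats::rnorm(natom * 3, sd = spec$noise_sigma),
                   natom, 3)
  # flexible terminal quarters: hinged transverse swing, AR(1) in time
  ntail <- max(1L, nres %/% 4L)
  tailN <- which(atomdf$resno <= ntail & atomdf$resid != "LIG")
  tailC <- which(atomdf$resno > nres - ntail & atomdf$resid != "LIG")
  rampN <- (ntail + 1 - atomdf$resno[tailN]) / ntail
  rampC <- (atomdf$resno[tailC] - (nres - ntail)) / ntail
  trho <- 0.9
  wN <- stats::rnorm(3, sd = spec$tail_flex)
  wC <- stats::rnorm(3, sd = spec$tail_flex)
  for (f in seq_len(spec$n_frames)) {
    if (f > 1) {
      jitter <- rho * jitter +
        matrix(stats::rnorm(natom * 3,
                            sd = spec$noise_sigma * sqrt(1 - rho^2)),
               natom, 3)
      wN <- trho * wN + stats::rnorm(3, sd = spec$tail_flex *
                                       sqrt(1 - trho^2))
      wC <- trho * wC + stats::rnorm(3, sd = spec$tail_flex *
                                       sqrt(1 - trho^2))
    }
    x <- base + jitter
    x[tailN, ] <- x[tailN, , drop = FALSE] + outer(rampN, wN)
    x[tailC, ] <- x[tailC, , drop = FALSE] + outer(rampC, wC)
    # induced fit: pocket residues follow a fraction of the ligand move
    x[pocketIdx, ] <- sweep(x[pocketIdx, , drop = FALSE], 2,
                            spec$induced_fit * disp[mode[f], ], `+`)
    # scheduled geometry is exact (jitter would blur the criterion)
    if (!is.null(sched)) {
      for (r in seq_len(nrow(sched))) {
        g <- pairGeom[[r]]
        x[g$ne_idx, ] <- g$ne
        x[g$he_idx, ] <- g$ne + 1.0 * g$u
        dOn <- if (hmask[f, r]) 2.9 else 5.5
        x[g$oe_idx, ] <- g$ne + dOn * g$u
      }
    }
    x[ligIdx, ] <- sweep(x[ligIdx, , drop = FALSE], 2,
                         disp[mode[f], ], `+`)
    # slow rigid-body drift: random-walk rotation about z + translation
    shift <- shift + stats::rnorm(3, sd = spec$drift_sigma)
    angle <- angle + stats::rnorm(1, sd = spec$drift_sigma * 0.02)
    R <- matrix(c(cos(angle), sin(angle), 0,
                  -sin(angle), cos(angle), 0, 0, 0, 1), 3, 3)
    coords[, , f] <- sweep(x %*% R, 2, shift, `+`)
  }
  traj <- Trajectory(topo, coords, dt = spec$dt_ps)
  gt <- list(mode = mode, hbond_mask = hmask, displacements = disp)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pdb <- file.path(dir, "system.pdb")
    dcd <- file.path(dir, "traj.dcd")
    gtf <- file.path(dir, "ground_truth.json")
    writePDB(traj, pdb, frames = 1)
    writeDCD(traj, dcd)
    jsonlite::write_json(
      list(mode = mode,
           hbond_mask = hmask,
           displacements = disp,
           spec = unclass(spec)[c("n_residues", "n_ligand_atoms",
                                  "n_modes", "mode_fractions",
                                  "mode_separation", "noise_sigma",
                                  "n_frames", "dt_ps", "seed")]),
      gtf, auto_unbox = TRUE, digits = NA)
    files <- list(topology = pdb, trajectory = dcd, ground_truth = gtf)
  }
  list(trajectory = traj, ground_truth = gt, files = files)
}

#' Contact residues of a synthetic system
#'
#' The pocket-lining residues of the generated system: the `n`
#' residues closest (along the helix) to the ligand site, which sits
#' against the middle of the receptor. These are the residues whose
#' ligand-COM distances make informative descriptors — like real
#' pocket contacts, they surround the ligand so displacements in any
#' direction project strongly onto at least some of the distances.
#'
#' @param spec a `SyntheticSpec`.
#' @param n how many residues.
#' @export
syntheticContacts <- function(spec, n = 6) {
  mid <- round(spec$n_residues / 2)
  res <- mid + seq(-(n - 1), n - 1, by = 2)  # every other residue
  pmax(1, pmin(spec$n_residues, res))
}

#' Biased double-well walker (metadynamics oracle)
#'
#' Overdamped Langevin dynamics on the analytic double well
#' `U(x) = barrier * ((x/a)^2 - 1)^2` (wells at x = -a, +a; barrier at
#' x = 0 of height `barrier`), with well-tempered hill deposition:
#' every `hill_stride` steps a Gaussian of width `width` is added at
#' the walker position with height `h0 * exp(-V_bias(x) / dT)`,
#' `dT = (bias_factor - 1) * kT`. At `kT = 0` the dynamics is plain
#' gradient descent and hills keep their initial height.
#'
#' The accumulated bias (value and gradient) is tabulated on a fine
#' grid so the walk costs O(1) per step.
#'
#' @param barrier well depth, kcal/mol.
#' @param a half-separation of the wells, Angstrom.
#' @param kT thermal energy, kcal/mol (0.596 is ~300 K).
#' @param n_hills number of hills to deposit.
#' @param hill_stride steps between depositions.
#' @param dt integration step (Angstrom^2 / (kcal/mol) per step at
#'   unit mobility).
#' @param h0 initial hill height, kcal/mol.
#' @param width Gaussian width (sigma), Angstrom.
#' @param bias_factor well-tempered bias factor gamma > 1.
#' @param x0 starting position.
#' @param seed RNG seed.
#' @return list with `hills` (a [HillLog()]; times in ps taking one
#'   step = 1 fs so depositions are `hill_stride/1000` ps apart), `cv`
#'   (positions at every step), `analytic` (the exact potential as a
#'   function), and the parameters.
#' @export
toyWalker <- function(barrier = 3, a = 1, kT = 0.596, n_hills = 1500,
                      hill_stride = 20, dt = 0.004, h0 = 0.4,
                      width = 0.2, bias_factor = 5, x0 = -1, seed = 1) {
  if (barrier <= 0) stop("barrier must be positive")
  set.seed(seed)
  xmax <- 2.5 * a
  ngrid <- 1201
  gx <- seq(-xmax, xmax, length.out = ngrid)
  Vg <- numeric(ngrid)     # deposited bias value on the grid
  dVg <- numeric(ngrid)    # its gradient
  gstep <- gx[2] - gx[1]
  biasAt <- function(x, tab) {
    i <- pmin(pmax((x + xmax) / gstep, 0), ngrid - 1)
    i0 <- floor(i); w <- i - i0
    (1 - w) * tab[i0 + 1] + w * tab[pmin(i0 + 2, ngrid)]
  }
  dU <- function(x) 4 * barrier * x * ((x / a)^2 - 1) / a^2

  nsteps <- n_hills * hill_stride
  x <- x0
  cv <- numeric(nsteps)
  times <- numeric(n_hills)
  centers <- numeric(n_hills)
  heights <- numeric(n_hills)
  noise <- if (kT > 0) stats::rnorm(nsteps, sd = sqrt(2 * kT * dt))
           else numeric(nsteps)
  hi <- 0L
  for (s in seq_len(nsteps)) {
    f <- -dU(x) - biasAt(x, dVg)
    x <- x + dt * f + noise[s]
    if (x > xmax) x <- 2 * xmax - x
    if (x < -xmax) x <- -2 * xmax - x
    cv[s] <- x
    if (s %% hill_stride == 0) {
      hi <- hi + 1L
      h <- if (kT > 0) h0 * exp(-biasAt(x, Vg) / ((bias_factor - 1) * kT))
           else h0
      g <- exp(-(gx - x)^2 / (2 * width^2))
      Vg <- Vg + h * g
      dVg <- dVg - h * g * (gx - x) / width^2
      times[hi] <- s / 1000   # ps at 1 fs per step
      centers[hi] <- x
      heights[hi] <- h
    }
  }
  list(hills = HillLog(times, centers, heights, width),
       cv = cv,
       analytic = function(x) barrier * ((x / a)^2 - 1)^2,
       barrier = barrier, a = a, kT = kT, bias_factor = bias_factor)
}
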