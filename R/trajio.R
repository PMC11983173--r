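#' @importFrom stats sd dist prcomp kmeans setNames aggregate median rnorm
#' @importFrom utils read.csv write.csv head tail combn
NULL

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

SOLVENT_RESNAMES <- c("HOH", "WAT", "TIP3", "SPC", "SOL",
                      "NA", "CL", "K", "MG", "ZN", "CA2")

#' Build a topology from per-atom tables
#'
#' A `Topology` holds the static description of a system: one row per
#' atom (serial number, atom name, element, residue number and name,
#' chain), plus the hydrogen-to-heavy-atom bonding needed for
#' hydrogen-bond detection. Hydrogen attachment is inferred
#' geometrically from a reference coordinate set when no explicit bond
#' list is given: each hydrogen is assigned to the nearest heavy atom
#' within 1.6 Angstrom, and it is an error for a hydrogen to have none.
#'
#' Donor/acceptor flags follow the usual geometric convention: any N or
#' O heavy atom is a potential acceptor; an N or O carrying at least one
#' bonded hydrogen is a potential donor.
#'
#' @param atoms data.frame with columns `eleno` (serial), `elety` (atom
#'   name), `resid` (residue name), `resno` (residue number), `chain`,
#'   and optionally `elesy` (element symbol; inferred from `elety` when
#'   missing or blank).
#' @param xyz reference coordinates, an `natom x 3` matrix, used to
#'   infer hydrogen bonding when `bonds` is `NULL`.
#' @param bonds optional two-column integer matrix of bonded atom-index
#'   pairs (1-based row indices into `atoms`).
#' @return an object of class `Topology`.
#' @export
Topology <- function(atoms, xyz = NULL, bonds = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("eleno", "elety", "resid", "resno", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$eleno))
    stop("atom serial numbers must be unique")
  atoms$eleno <- as.integer(atoms$eleno)
  atoms$resno <- as.integer(atoms$resno)
  atoms$elety <- as.character(atoms$elety)
  atoms$resid <- as.character(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  n <- nrow(atoms)
  if (is.null(atoms$elesy) || all(!nzchar(trimws(as.character(atoms$elesy))))) {
    atoms$elesy <- guessElement(atoms$elety)
  } else {
    blank <- !nzchar(trimws(as.character(atoms$elesy))) | is.na(atoms$elesy)
    atoms$elesy[blank] <- guessElement(atoms$elety[blank])
  }
  atoms$elesy <- toupper(trimws(atoms$elesy))

  if (is.null(bonds)) {
    bonds <- inferHydrogenBondsFromGeometry(atoms, xyz)
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) != 2) stop("bonds must be a two-column matrix")
    if (any(bonds < 1 | bonds > n)) stop("bond references a nonexistent atom")
  }
  validateHydrogens(atoms, bonds)

  is_h <- atoms$elesy == "H"
  heavyNO <- atoms$elesy %in% c("N", "O")
  has_h <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    hpart <- c(bonds[is_h[bonds[, 1]], 2], bonds[is_h[bonds[, 2]], 1])
    has_h[unique(hpart)] <- TRUE
  }
  structure(list(
    atoms = atoms,
    bonds = bonds,
    donor = heavyNO & has_h & !is_h,
    acceptor = heavyNO & !is_h,
    natom = n
  ), class = "Topology")
}

guessElement <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", trimws(as.character(name))))
  two <- substr(nm, 1, 2)
  el <- substr(nm, 1, 1)
  known2 <- c("CL", "BR", "MG", "ZN", "FE", "MN", "SE")
  el[two %in% known2] <- two[two %in% known2]
  # names like "HB2", "1HG" are hydrogens; "HG" as mercury never occurs here
  el[substr(nm, 1, 1) == "H"] <- "H"
  el
}

inferHydrogenBondsFromGeometry <- function(atoms, xyz) {
  is_h <- guessedH <- toupper(atoms$elesy) == "H"
  if (!any(is_h)) return(matrix(integer(0), ncol = 2))
  if (is.null(xyz))
    stop("reference coordinates are required to infer hydrogen bonding")
  xyz <- as.matrix(xyz)
  heavy <- which(!is_h)
  out <- matrix(integer(0), ncol = 2)
  for (h in which(is_h)) {
    d2 <- rowSums(sweep(xyz[heavy, , drop = FALSE], 2, xyz[h, ])^2)
    j <- heavy[which.min(d2)]
    if (min(d2) > 1.6^2)
      stop("hydrogen atom ", atoms$eleno[h],
           " has no heavy atom within 1.6 Angstrom")
    out <- rbind(out, c(j, h))
  }
  out
}

validateHydrogens <- function(atoms, bonds) {
  is_h <- toupper(atoms$elesy) == "H"
  if (!any(is_h)) return(invisible(TRUE))
  cnt <- integer(nrow(atoms))
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      if (is_h[i]) cnt[i] <- cnt[i] + 1L
      if (is_h[j]) cnt[j] <- cnt[j] + 1L
    }
  }
  bad <- which(is_h & cnt != 1L)
  if (length(bad) > 0)
    stop("hydrogen(s) without exactly one bonded heavy atom: ",
         paste(atoms$eleno[bad], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.Topology <- function(x, ...) {
  cat("Topology:", x$natom, "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      sum(x$atoms$elesy == "H"), "hydrogens\n")
  cat("  donors:", sum(x$donor), " acceptors:", sum(x$acceptor), "\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' A `Trajectory` couples a [Topology()] with a coordinate array of
#' dimension `natom x 3 x nframes` (Angstrom) and the time step between
#' stored frames in picoseconds. Frame `i` is at time `(i - 1) * dt` ps.
#'
#' @param topology a `Topology`.
#' @param coords numeric array `natom x 3 x nframes`.
#' @param dt time between stored frames, ps (> 0).
#' @return object of class `Trajectory`.
#' @export
Trajectory <- function(topology, coords, dt = 1) {
  stopifnot(inherits(topology, "Topology"))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an natom x 3 x nframes array")
  if (dim(coords)[1] != topology$natom)
    stop("coordinate array has ", dim(coords)[1],
         " atoms but the topology has ", topology$natom)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be a positive time step (ps)")
  structure(list(topology = topology, coords = coords, dt = as.numeric(dt)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  nf <- nFrames(x)
  cat("Trajectory:", nf, "frames x", x$topology$natom, "atoms, dt =",
      x$dt, "ps (", format((nf - 1) * x$dt), "ps span )\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @export
nFrames <- function(traj) dim(traj$coords)[3]

#' Frame times in picoseconds
#' @param traj a `Trajectory`.
#' @export
frameTimes <- function(traj) (seq_len(nFrames(traj)) - 1) * traj$dt

#' Extract one frame's coordinates
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return `natom x 3` matrix.
#' @export
frameCoords <- function(traj, i) {
  stopifnot(i >= 1, i <= nFrames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' Load a system from a topology file and a trajectory file
#'
#' Reads a PDB topology and, optionally, coordinates from a DCD file or
#' a multi-model PDB. With no trajectory file the PDB's own model(s)
#' provide the coordinates. The atom count of the coordinate source
#' must match the topology, otherwise loading fails with both counts
#' named. XTC is not read; convert to DCD first.
#'
#' @param topology_path path to a PDB file.
#' @param trajectory_path optional path to a DCD file (or a multi-model
#'   PDB used purely as a coordinate source).
#' @param dt time between stored frames, ps; default 1.
#' @return a [Trajectory()].
#' @export
loadSystem <- function(topology_path, trajectory_path = NULL, dt = 1) {
  if (!file.exists(topology_path))
    stop("topology file not found: ", topology_path)
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(
    eleno = pdb$atom$eleno,
    elety = trimws(pdb$atom$elety),
    resid = trimws(pdb$atom$resid),
    resno = pdb$atom$resno,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    elesy = if (!is.null(pdb$atom$elesy)) trimws(pdb$atom$elesy) else "",
    stringsAsFactors = FALSE
  )
  natom <- nrow(atoms)
  ref_xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  topo <- Topology(atoms, xyz = ref_xyz)

  if (is.null(trajectory_path)) {
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else {
    if (!file.exists(trajectory_path))
      stop("trajectory file not found: ", trajectory_path)
    ext <- tolower(tools::file_ext(trajectory_path))
    if (ext == "xtc")
      stop("XTC trajectories are not supported; convert to DCD")
    if (ext == "dcd") {
      xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
    } else if (ext %in% c("pdb", "ent")) {
      mp <- bio3d::read.pdb(trajectory_path, multi = TRUE, verbose = FALSE)
      xyz <- mp$xyz
      if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    } else {
      stop("unreadable trajectory format: .", ext, " (expected DCD or PDB)")
    }
  }
  traj_natom <- ncol(xyz) / 3
  if (traj_natom != natom)
    stop("atom-count mismatch: topology has ", natom,
         " atoms but trajectory has ", traj_natom)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(natom, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  Trajectory(topo, coords, dt = dt)
}

#' Subsample a trajectory at a fixed time stride
#'
#' Returns the frames whose time is a multiple of the nearest achievable
#' stride (an integer multiple of the storage interval). Sampling at a
#' stride coarser than the storage interval reduces short-term frame
#' correlation before clustering; the stride actually achieved is
#' recorded in the `achieved_stride_ps` attribute.
#'
#' @param traj a `Trajectory`.
#' @param stride_ps requested sampling interval, ps; must be at least
#'   the trajectory's storage interval.
#' @return a `Trajectory` view with attributes `achieved_stride_ps` and
#'   `frame_index` (indices into the parent trajectory).
#' @export
sampleFrames <- function(traj, stride_ps) {
  stopifnot(inherits(traj, "Trajectory"))
  if (stride_ps < traj$dt)
    stop("requested stride (", stride_ps, " ps) is finer than the ",
         "trajectory's native resolution of ", traj$dt, " ps per frame")
  step <- max(1L, as.integer(round(stride_ps / traj$dt)))
  keep <- seq(1L, nFrames(traj), by = step)
  out <- Trajectory(traj$topology, traj$coords[, , keep, drop = FALSE],
                    dt = traj$dt * step)
  attr(out, "achieved_stride_ps") <- traj$dt * step
  attr(out, "frame_index") <- keep
  out
}

#' Write one or more frames as a (multi-model) PDB file
#'
#' Used mainly to export cluster-centroid structures. Coordinates are
#' written at PDB precision (1e-3 Angstrom).
#'
#' @param traj a `Trajectory`.
#' @param path output file.
#' @param frames frame indices to write; default all.
#' @export
writePDB <- function(traj, path, frames = seq_len(nFrames(traj))) {
  at <- traj$topology$atoms
  xyz <- t(vapply(frames, function(f) as.numeric(t(frameCoords(traj, f))),
                  numeric(3 * traj$topology$natom)))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(at)),
    eleno = at$eleno, elety = at$elety, resid = at$resid,
    resno = at$resno, chain = at$chain, elesy = at$elesy
  )
  invisible(path)
}

#' One-line summary of a loaded system
#'
#' @param traj a `Trajectory`.
#' @return invisibly, a list with `frames`, `atoms`, `duration_ps`.
#' @export
trajInfo <- function(traj) {
  out <- list(frames = nFrames(traj), atoms = traj$topology$natom,
              duration_ps = (nFrames(traj) - 1) * traj$dt)
  cat(sprintf("%d frames, %d atoms, %.1f ps (dt = %g ps)\n",
              out$frames, out$atoms, out$duration_ps, traj$dt))
  invisible(out)
}
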