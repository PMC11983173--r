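# Bondi van der Waals radii (Angstrom)
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90)

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation + translation minimizing the RMSD between two
#' coordinate sets over the fitted atoms, by SVD of the covariance
#' matrix with the usual determinant correction so the result is a
#' proper rotation (no reflection).
#'
#' @param mobile `n x 3` coordinates to move.
#' @param reference `n x 3` target coordinates (same atom order).
#' @return a list of class `RigidTransform` with elements `rotation`
#'   (3x3, det +1), `translation` (length-3, Angstrom; the transform is
#'   `x %*% rotation + translation`) and `rmsd` (Angstrom) at the
#'   optimum.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have the same dimensions")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); N <- sweep(reference, 2, cr)
  if (qr(M)$rank < 2 || qr(N)$rank < 2)
    stop("degenerate (collinear) geometry: superposition is ill-posed")
  A <- t(M) %*% N
  s <- svd(A)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- M %*% R
  rmsd <- sqrt(mean(rowSums((fitted - N)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - cm %*% R),
                 rmsd = rmsd),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#' @param xyz `n x 3` matrix.
#' @param tr a `RigidTransform`.
#' @export
applyTransform <- function(xyz, tr) {
  sweep(as.matrix(xyz) %*% tr$rotation, 2, tr$translation, `+`)
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat(sprintf("RigidTransform: rmsd %.4f A, rotation angle %.1f deg\n",
              x$rmsd,
              acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) *
                180 / pi))
  invisible(x)
}

plainRMSD <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

newSeries <- function(metric, times, values, selection) {
  if (any(!is.finite(values))) stop("non-finite value in ", metric, " series")
  structure(
    data.frame(time_ps = times, value = values),
    metric = metric, selection = selection, class = c("SeriesResult",
                                                      "data.frame"))
}

#' @export
print.SeriesResult <- function(x, ...) {
  cat(attr(x, "metric"), "series over", nrow(x), "frames;",
      sprintf("median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$value), min(x$value), max(x$value)))
  invisible(x)
}

#' RMSD time series with separate fit and measure selections
#'
#' Each frame is superposed onto the reference frame using
#' `fit_selection` only (typically the protein backbone); the RMSD is
#' then measured on `measure_selection` without re-fitting. This is
#' the convention for ligand RMSD "aligned to the protein": the fit
#' removes global receptor motion and the measurement reports how far
#' the ligand has moved in the receptor frame.
#'
#' @param traj a `Trajectory`.
#' @param fit_selection selection used for the superposition.
#' @param measure_selection selection the RMSD is computed on; default
#'   the fit selection.
#' @param reference_frame frame index of the reference structure
#'   (default 1, the initial frame).
#' @return a `SeriesResult` (time_ps, value in Angstrom).
#' @export
rmsdSeries <- function(traj, fit_selection, measure_selection = fit_selection,
                       reference_frame = 1) {
  fit <- asSelection(traj, fit_selection)
  meas <- asSelection(traj, measure_selection)
  nf <- nFrames(traj)
  if (reference_frame < 1 || reference_frame > nf)
    stop("reference frame ", reference_frame, " out of range")
  ref <- frameCoords(traj, reference_frame)
  vals <- vapply(seq_len(nf), function(f) {
    x <- frameCoords(traj, f)
    tr <- superpose(x[fit, , drop = FALSE], ref[fit, , drop = FALSE])
    plainRMSD(applyTransform(x[meas, , drop = FALSE], tr),
              ref[meas, , drop = FALSE])
  }, numeric(1))
  newSeries("RMSD", frameTimes(traj), vals,
            paste0("fit=", attr(fit, "expression"),
                   "; measure=", attr(meas, "expression")))
}

#' All-vs-all frame RMSD matrix
#'
#' Superposition RMSD between every pair of sampled frames on the fit
#' selection. Low off-diagonal values late in the simulation indicate
#' convergence to a stable conformational basin.
#'
#' @param traj a `Trajectory` (>= 2 frames).
#' @param fit_selection selection fitted and measured.
#' @return `PairwiseMatrix`: symmetric matrix (Angstrom, zero diagonal)
#'   with frame times in attribute `time_ps`.
#' @export
pairwiseRmsd <- function(traj, fit_selection) {
  sel <- asSelection(traj, fit_selection)
  nf <- nFrames(traj)
  if (nf < 2) stop("pairwise RMSD needs at least 2 frames")
  coords <- lapply(seq_len(nf), function(f)
    frameCoords(traj, f)[sel, , drop = FALSE])
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in seq(i + 1, nf)) {
      m[i, j] <- m[j, i] <- superpose(coords[[i]], coords[[j]])$rmsd
    }
  }
  structure(m, time_ps = frameTimes(traj), class = "PairwiseMatrix")
}

#' @export
print.PairwiseMatrix <- function(x, ...) {
  cat("PairwiseMatrix:", nrow(x), "frames, max off-diagonal",
      sprintf("%.3f A\n", max(x)))
  invisible(x)
}

#' Root-mean-square fluctuation per atom or residue
#'
#' Frames are first superposed (on `fit_selection`) onto the reference
#' frame, the time-averaged structure is computed, and every frame is
#' re-superposed onto that mean (one iteration). RMSF of atom i is the
#' square root of the mean squared displacement from its time-averaged
#' position.
#'
#' @param traj a `Trajectory` with >= 2 frames.
#' @param selection atoms to report.
#' @param fit_selection atoms used for the superposition (default:
#'   `selection`).
#' @param by `"atom"` or `"residue"` (residue value = mean over its
#'   selected atoms).
#' @return a data.frame with columns (`atom` or `resno`) and `rmsf`
#'   (Angstrom).
#' @export
rmsf <- function(traj, selection, fit_selection = selection, by = "atom") {
  sel <- asSelection(traj, selection)
  fit <- asSelection(traj, fit_selection)
  nf <- nFrames(traj)
  if (nf < 2) stop("RMSF needs at least 2 frames")
  by <- match.arg(by, c("atom", "residue"))

  alignAll <- function(target) {
    lapply(seq_len(nf), function(f) {
      x <- frameCoords(traj, f)
      tr <- superpose(x[fit, , drop = FALSE], target)
      applyTransform(x, tr)
    })
  }
  ref <- frameCoords(traj, 1)[fit, , drop = FALSE]
  pass1 <- alignAll(ref)
  meanfit <- Reduce(`+`, lapply(pass1, function(x) x[fit, , drop = FALSE])) / nf
  pass2 <- alignAll(meanfit)
  meansel <- Reduce(`+`, lapply(pass2, function(x) x[sel, , drop = FALSE])) / nf
  msd <- Reduce(`+`, lapply(pass2, function(x)
    rowSums((x[sel, , drop = FALSE] - meansel)^2))) / nf
  vals <- sqrt(msd)
  if (by == "atom")
    return(data.frame(atom = as.integer(sel), rmsf = vals))
  resno <- traj$topology$atoms$resno[sel]
  agg <- aggregate(vals, list(resno = resno), mean)
  data.frame(resno = agg$resno, rmsf = agg$x)
}

# near-uniform unit sphere points (Fibonacci / golden-spiral lattice)
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's SASA is the fraction of test points on its solvent
#' sphere (vdW radius + probe) not buried inside any neighbour's
#' solvent sphere, times the sphere area. Radii are Bondi vdW values.
#'
#' @param traj a `Trajectory` (one frame is analysed) or an `n x 3`
#'   coordinate matrix with an `elements` argument.
#' @param selection atoms to include; the area reported is for this
#'   group in isolation (other atoms do not occlude).
#' @param frame frame index, default 1.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4,
#'   water).
#' @param n_points test points per atom (default 960).
#' @param elements element symbols when `traj` is a bare matrix.
#' @return total SASA in Angstrom^2, with per-atom areas in attribute
#'   `per_atom`.
#' @export
sasa <- function(traj, selection = "all", frame = 1, probe_radius = 1.4,
                 n_points = 960, elements = NULL) {
  if (inherits(traj, "Trajectory")) {
    sel <- asSelection(traj, selection)
    xyz <- frameCoords(traj, frame)[sel, , drop = FALSE]
    el <- toupper(traj$topology$atoms$elesy[sel])
  } else {
    xyz <- as.matrix(traj)
    if (is.null(elements)) stop("elements required for bare coordinates")
    el <- toupper(elements)
  }
  unknown <- setdiff(unique(el), names(VDW_RADII))
  if (length(unknown) > 0)
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "),
         " (atoms ", paste(which(el %in% unknown), collapse = ", "), ")")
  r <- VDW_RADII[el] + probe_radius
  n <- nrow(xyz)
  pts <- spherePoints(n_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij2 <- sum((xyz[i, ] - xyz[j, ])^2)
      if (dij2 >= (r[i] + r[j])^2) next
      if (dij2 < 1e-12) {
        # coincident atoms: only the larger sphere (first, on ties) counts
        if (r[j] > r[i] || (r[j] == r[i] && j < i)) {
          exposed[] <- FALSE
          break
        }
        next
      }
      buried <- rowSums(sweep(p, 2, xyz[j, ])^2) < r[j]^2
      exposed <- exposed & !buried
      if (!any(exposed)) break
    }
    per_atom[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  structure(sum(per_atom), per_atom = per_atom)
}

#' Center-of-mass distance time series (collective variable)
#'
#' Per-frame Euclidean distance between the centers of mass of two atom
#' groups, the collective-variable construction used to map
#' helix-repositioning free-energy surfaces (e.g. COM distances between
#' a helix-12 residue and anchor residues on neighbouring helices).
#'
#' @param traj a `Trajectory`.
#' @param groupA,groupB atom selections.
#' @param mass_weighted use atomic masses (default); otherwise the
#'   geometric center.
#' @return a `SeriesResult` (time_ps, value in Angstrom).
#' @export
comDistanceSeries <- function(traj, groupA, groupB, mass_weighted = TRUE) {
  a <- asSelection(traj, groupA)
  b <- asSelection(traj, groupB)
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
              P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, SE = 78.971)
  wt <- function(sel) {
    if (!mass_weighted) return(rep(1, length(sel)))
    el <- toupper(traj$topology$atoms$elesy[sel])
    m <- masses[el]
    m[is.na(m)] <- 12.011
    m
  }
  wa <- wt(a); wb <- wt(b)
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    x <- frameCoords(traj, f)
    ca <- colSums(x[a, , drop = FALSE] * wa) / sum(wa)
    cb <- colSums(x[b, , drop = FALSE] * wb) / sum(wb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  newSeries("COM distance", frameTimes(traj), vals,
            paste0(attr(a, "expression"), " <-> ", attr(b, "expression")))
}
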