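#' Build the standardized binding-mode feature matrix
#'
#' One row per sampled frame. Columns are the geometric descriptors of
#' the binding arrangement:
#'
#' * the center-of-mass distance between the ligand and each named
#'   contact residue in the binding pocket,
#' * backbone RMSD of the protein,
#' * ligand RMSD (fit on backbone, measured on the ligand), and
#' * RMSD of the interacting residues (fit on backbone),
#'
#' all RMSDs relative to `reference_frame` (default the initial frame).
#' Every column is standardized to mean 0, standard deviation 1
#' (population denominator); columns with zero variance carry no
#' information for clustering and are dropped with a warning.
#'
#' @param traj a (sampled) `Trajectory`.
#' @param ligand_selection selection for the ligand (default
#'   `"ligand"`).
#' @param contact_residues residue numbers whose ligand-COM distances
#'   become distance features.
#' @param interacting_residues residue numbers pooled into the
#'   interacting-residue RMSD feature; default `contact_residues`.
#' @param reference_frame RMSD reference, default 1.
#' @return a `FeatureMatrix`: numeric matrix with attributes
#'   `descriptors` (per-column provenance), `center`, `scale`.
#' @export
buildFeatures <- function(traj, ligand_selection = "ligand",
                          contact_residues,
                          interacting_residues = contact_residues,
                          reference_frame = 1) {
  lig <- asSelection(traj, ligand_selection)
  cols <- list()
  desc <- character(0)
  for (r in contact_residues) {
    s <- comDistanceSeries(traj, lig, paste("protein and resid", r))
    cols[[length(cols) + 1]] <- s$value
    desc <- c(desc, paste0("dist:ligand-res", r))
  }
  bb <- rmsdSeries(traj, "backbone", reference_frame = reference_frame)
  cols[[length(cols) + 1]] <- bb$value
  desc <- c(desc, "rmsd:backbone")
  ligr <- rmsdSeries(traj, "backbone", lig, reference_frame = reference_frame)
  cols[[length(cols) + 1]] <- ligr$value
  desc <- c(desc, "rmsd:ligand")
  ir_expr <- paste("protein and resid",
                   paste(interacting_residues, collapse = " "))
  irr <- rmsdSeries(traj, "backbone", ir_expr,
                    reference_frame = reference_frame)
  cols[[length(cols) + 1]] <- irr$value
  desc <- c(desc, "rmsd:interacting-residues")

  raw <- do.call(cbind, cols)
  colnames(raw) <- desc
  standardizeFeatures(raw)
}

#' Standardize a raw feature matrix
#'
#' @param raw frames x descriptors numeric matrix.
#' @return `FeatureMatrix` (see [buildFeatures()]).
#' @export
standardizeFeatures <- function(raw) {
  raw <- as.matrix(raw)
  if (any(!is.finite(raw))) stop("feature matrix contains missing values")
  n <- nrow(raw)
  ctr <- colMeans(raw)
  scl <- sqrt(colMeans(sweep(raw, 2, ctr)^2))  # population sd
  keep <- scl > 1e-12
  if (!any(keep))
    stop("all feature columns are constant; nothing to cluster")
  if (!all(keep))
    warning("dropping constant feature column(s): ",
            paste(colnames(raw)[!keep], collapse = ", "))
  z <- sweep(sweep(raw[, keep, drop = FALSE], 2, ctr[keep]), 2,
             scl[keep], `/`)
  structure(z, descriptors = colnames(raw)[keep], center = ctr[keep],
            scale = scl[keep], class = c("FeatureMatrix", "matrix"))
}

#' Reduce a feature matrix by PCA at a variance target
#'
#' Principal components are retained up to the smallest number whose
#' cumulative explained-variance ratio reaches `variance_fraction`
#' (default 0.90). Features are standardized beforehand, so this is the
#' correlation-matrix form of PCA. Component signs follow a fixed
#' convention (the largest-magnitude loading of each component is
#' positive), making scores reproducible.
#'
#' @param fm a `FeatureMatrix` (or any numeric matrix, >= 2 rows).
#' @param variance_fraction target cumulative explained variance in
#'   (0, 1].
#' @return a `ReducedMatrix`: frames x n_components score matrix with
#'   attributes `explained` (all ratios), `n_components`, `loadings`.
#' @export
pcaReduce <- function(fm, variance_fraction = 0.90) {
  if (nrow(fm) < 2) stop("PCA needs at least 2 frames")
  if (variance_fraction <= 0 || variance_fraction > 1)
    stop("variance_fraction must be in (0, 1]")
  p <- prcomp(fm, center = TRUE, scale. = FALSE)
  ratio <- p$sdev^2 / sum(p$sdev^2)
  ncomp <- which(cumsum(ratio) >= variance_fraction - 1e-12)[1]
  rot <- p$rotation[, seq_len(ncomp), drop = FALSE]
  flip <- vapply(seq_len(ncomp), function(j) {
    w <- rot[which.max(abs(rot[, j])), j]
    if (w < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(p$x[, seq_len(ncomp), drop = FALSE], 2, flip, `*`)
  structure(scores, explained = ratio, n_components = ncomp,
            loadings = rot, class = c("ReducedMatrix", "matrix"))
}

#' @export
print.ReducedMatrix <- function(x, ...) {
  nc <- attr(x, "n_components")
  cat("ReducedMatrix:", nrow(x), "frames x", nc, "components (",
      sprintf("%.1f%%", 100 * sum(attr(x, "explained")[seq_len(nc)])),
      "of variance )\n")
  invisible(x)
}

# k-means++ seeding (D^2 sampling) followed by Lloyd iterations
kmeansPP <- function(x, k, seed = NULL, iter_max = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(NA_real_, k, ncol(x))
  i1 <- sample.int(n, 1)
  centers[1, ] <- x[i1, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  if (k > 1) {
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        pick <- sample.int(n, 1)
      } else {
        pick <- sample.int(n, 1, prob = d2 / sum(d2))
      }
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  km <- suppressWarnings(
    kmeans(x, centers = centers, iter.max = iter_max, algorithm = "Lloyd"))
  km
}

bestOfKmeansPP <- function(x, k, n_init = 10, seed = 1) {
  best <- NULL
  for (r in seq_len(n_init)) {
    km <- kmeansPP(x, k, seed = seed + 7919L * (r - 1L))
    if (any(km$size == 0)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best))
    stop("k-means produced an empty cluster in every initialisation")
  best
}

#' Internal cluster-validation indices
#'
#' * `SI` — mean silhouette width, in \[-1, 1\].
#' * `DI` — Dunn index: smallest inter-cluster point distance divided
#'   by the largest intra-cluster diameter.
#' * `pSF` — Calinski-Harabasz pseudo-F: `(B/(k-1)) / (W/(n-k))` with
#'   `B` the between- and `W` the within-cluster sum of squares.
#' * `WSS` — within-cluster sum of squared distances to the assigned
#'   centroid.
#'
#' @param x data matrix.
#' @param labels integer cluster labels.
#' @return named numeric vector `c(SI, DI, pSF, WSS)`.
#' @export
validationIndices <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(labels))
  dmat <- as.matrix(dist(x))
  sil <- if (k > 1 && k < n)
    mean(cluster::silhouette(labels, dmatrix = dmat)[, "sil_width"])
  else NA_real_
  # Dunn
  inter <- Inf
  intra <- 0
  for (a in unique(labels)) {
    ia <- which(labels == a)
    if (length(ia) > 1)
      intra <- max(intra, max(dmat[ia, ia]))
    for (b in unique(labels)) {
      if (b <= a) next
      ib <- which(labels == b)
      inter <- min(inter, min(dmat[ia, ib, drop = FALSE]))
    }
  }
  di <- if (intra > 0) inter / intra else Inf
  # pseudo-F and WSS
  grand <- colMeans(x)
  wss <- 0; bss <- 0
  for (a in unique(labels)) {
    ia <- which(labels == a)
    ctr <- colMeans(x[ia, , drop = FALSE])
    wss <- wss + sum(sweep(x[ia, , drop = FALSE], 2, ctr)^2)
    bss <- bss + length(ia) * sum((ctr - grand)^2)
  }
  psf <- if (k > 1 && k < n && wss > 0)
    (bss / (k - 1)) / (wss / (n - k)) else Inf
  c(SI = sil, DI = di, pSF = psf, WSS = wss)
}

#' Scan cluster counts with K-means++
#'
#' Fits best-of-`n_init` K-means++ for every k in `k_min:k_max` and
#' scores each solution with the four internal validation indices.
#'
#' @param rm a `ReducedMatrix` (or numeric matrix).
#' @param k_min,k_max cluster-count range (default 2..10).
#' @param n_init random initialisations per k, best kept by lowest WSS.
#' @param seed base RNG seed; each (k, init) derives its own stream.
#' @return a `KScanTable`: data.frame (k, SI, DI, pSF, WSS) with the
#'   fitted labels in attribute `labels` (list by k) and the seed used.
#' @export
kscan <- function(rm, k_min = 2, k_max = 10, n_init = 10, seed = 42) {
  x <- as.matrix(rm)
  n <- nrow(x)
  if (k_max > n) stop("k_max (", k_max, ") exceeds the ", n,
                      " available frames")
  ks <- seq(k_min, k_max)
  rows <- list()
  labs <- list()
  for (k in ks) {
    km <- bestOfKmeansPP(x, k, n_init = n_init, seed = seed + 104729L * k)
    idx <- validationIndices(x, km$cluster)
    rows[[length(rows) + 1]] <- data.frame(k = k, SI = idx["SI"],
                                           DI = idx["DI"], pSF = idx["pSF"],
                                           WSS = idx["WSS"])
    labs[[as.character(k)]] <- km$cluster
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, labels = labs, seed = seed, n_init = n_init,
            class = c("KScanTable", "data.frame"))
}

#' Choose the cluster count by 3-of-4 criterion convergence
#'
#' Each index casts one vote: SI, DI and pSF vote for their maximising
#' k; WSS votes for its elbow, the k with the largest positive second
#' difference of WSS (the sharpest change of slope). The selected k is
#' any value gathering at least three votes; when none does, the k with
#' the most votes wins, ties broken toward smaller k (parsimony). The
#' full vote and decision path is kept in attribute `votes`.
#'
#' @param scan a `KScanTable` covering >= 2 values of k.
#' @return the selected k (integer) with attribute `votes`.
#' @export
selectK <- function(scan) {
  stopifnot(inherits(scan, "KScanTable"), nrow(scan) >= 2)
  ks <- scan$k
  votes <- c(SI = ks[which.max(scan$SI)],
             DI = ks[which.max(scan$DI)],
             pSF = ks[which.max(scan$pSF)])
  if (nrow(scan) >= 3) {
    d2 <- diff(scan$WSS, differences = 2)  # WSS[i-1] - 2 WSS[i] + WSS[i+1]
    votes <- c(votes, WSS = ks[which.max(d2) + 1L])
  }
  tab <- table(votes)
  kvals <- as.integer(names(tab))
  winners <- kvals[tab >= 3]
  if (length(winners) >= 1) {
    k <- min(winners)
    path <- "3-of-4 convergence"
  } else {
    best <- kvals[tab == max(tab)]
    k <- min(best)
    path <- sprintf("no 3-vote convergence; most votes (%d), ties to smaller k",
                    max(tab))
  }
  structure(as.integer(k), votes = votes, decision = path)
}

#' Fit the final cluster model
#'
#' Runs best-of-`n_init` K-means++ at the chosen k, relabels clusters
#' by decreasing population, and reports for each cluster its weight
#' W% (percentage of frames, rounded; unrounded fractions are kept for
#' energy weighting) and its centroid frame — the sampled frame whose
#' reduced-space coordinates lie nearest to the cluster mean.
#'
#' @param rm a `ReducedMatrix`.
#' @param k number of clusters (from [selectK()] or forced).
#' @param n_init initialisations, best kept by WSS.
#' @param seed RNG seed.
#' @return a `ClusterModel`: list with `k`, `labels`, `weights_pct`
#'   (rounded, descending), `weights_frac` (unrounded), `centroid_frames`,
#'   `centers`, `wss`.
#' @export
fitModel <- function(rm, k, n_init = 10, seed = 42) {
  x <- as.matrix(rm)
  if (k == 1) {
    labels <- rep(1L, nrow(x))
    centers <- matrix(colMeans(x), 1)
  } else {
    km <- bestOfKmeansPP(x, k, n_init = n_init, seed = seed + 104729L * k)
    labels <- km$cluster
    centers <- km$centers
  }
  size <- tabulate(labels, nbins = k)
  ord <- order(-size)
  relab <- match(labels, ord)
  centers <- centers[ord, , drop = FALSE]
  size <- size[ord]
  frac <- size / length(relab)
  centroid_frames <- vapply(seq_len(k), function(c) {
    ic <- which(relab == c)
    d2 <- rowSums(sweep(x[ic, , drop = FALSE], 2, centers[c, ])^2)
    ic[which.min(d2)]
  }, integer(1))
  wss <- sum(vapply(seq_len(k), function(c) {
    ic <- which(relab == c)
    sum(sweep(x[ic, , drop = FALSE], 2, centers[c, ])^2)
  }, numeric(1)))
  structure(list(k = as.integer(k), labels = relab,
                 weights_pct = as.integer(round(100 * frac)),
                 weights_frac = frac,
                 centroid_frames = centroid_frames,
                 centers = centers, wss = wss, seed = seed),
            class = "ClusterModel")
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat("ClusterModel: k =", x$k, "\n")
  cat("  W% :", paste(x$weights_pct, collapse = ", "), "\n")
  cat("  centroid frames:", paste(x$centroid_frames, collapse = ", "), "\n")
  invisible(x)
}

#' Full binding-mode clustering pipeline
#'
#' Convenience wrapper: feature matrix -> PCA at the variance target ->
#' k scan -> 3-of-4 selection -> final model.
#'
#' @inheritParams buildFeatures
#' @inheritParams kscan
#' @param variance_fraction PCA variance target, default 0.90.
#' @return list with `features`, `reduced`, `scan`, `k`, `model`.
#' @export
clusterBindingModes <- function(traj, ligand_selection = "ligand",
                                contact_residues,
                                interacting_residues = contact_residues,
                                reference_frame = 1,
                                variance_fraction = 0.90,
                                k_min = 2, k_max = 10, n_init = 10,
                                seed = 42) {
  fm <- buildFeatures(traj, ligand_selection, contact_residues,
                      interacting_residues, reference_frame)
  rm_ <- pcaReduce(fm, variance_fraction)
  scan <- kscan(rm_, k_min = k_min, k_max = k_max, n_init = n_init,
                seed = seed)
  k <- selectK(scan)
  model <- fitModel(rm_, k, n_init = n_init, seed = seed)
  list(features = fm, reduced = rm_, scan = scan, k = k, model = model)
}
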