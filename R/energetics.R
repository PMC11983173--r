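#' Binding energy from component energies
#'
#' End-point (MM-GBSA style) difference form: the binding free energy
#' of a structure is the optimized complex energy minus the energies of
#' the free ligand and the free receptor,
#' `dG_b = G_complex - G_ligand - G_receptor` (kcal/mol). More negative
#' values indicate stronger predicted binding; reports sort ascending.
#'
#' @param records data.frame with columns `id`, `complex`, `ligand`,
#'   `receptor` (kcal/mol), e.g. from [readEnergyTable()].
#' @return data.frame (`id`, `dG_b`) sorted by `dG_b` ascending.
#' @export
bindingEnergy <- function(records) {
  need <- c("id", "complex", "ligand", "receptor")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("energy table missing column(s): ", paste(miss, collapse = ", "))
  for (cn in c("complex", "ligand", "receptor")) {
    bad <- which(!is.finite(records[[cn]]))
    if (length(bad) > 0)
      stop("missing/non-finite '", cn, "' component for structure id ",
           paste(records$id[bad], collapse = ", "))
  }
  out <- data.frame(id = records$id,
                    dG_b = records$complex - records$ligand -
                      records$receptor)
  out[order(out$dG_b), , drop = FALSE]
}

#' Linear two-backend rescoring combiner
#'
#' Combines binding energies from two scoring backends (a dispersion-
#' corrected DFT score and a neural-network potential score) into a
#' single estimate through an externally optimized linear map:
#' `alpha * dg_dft + beta * dg_ani + gamma`. The coefficients are
#' calibration output of an external fitting procedure and must carry a
#' provenance note; the defaults `(1, 0, 0)` pass the first backend
#' through unchanged.
#'
#' @param dg_dft,dg_ani backend binding energies (kcal/mol), same
#'   structure set and order. Statistical use presumes more than one
#'   configuration per system.
#' @param coef list/vector with `alpha`, `beta`, `gamma` (gamma in
#'   kcal/mol).
#' @param provenance character note on where the coefficients came
#'   from.
#' @return numeric vector of combined energies (kcal/mol), with the
#'   provenance attached as an attribute.
#' @export
rescoreMlAni <- function(dg_dft, dg_ani,
                         coef = c(alpha = 1, beta = 0, gamma = 0),
                         provenance = "identity passthrough (default)") {
  if (length(dg_dft) != length(dg_ani))
    stop("backend score vectors differ in length")
  cf <- as.numeric(coef[c("alpha", "beta", "gamma")])
  if (any(!is.finite(cf))) stop("coefficients must be finite and named")
  if (is.null(provenance) || !nzchar(provenance))
    stop("a provenance note for the coefficients is required")
  if (any(!is.finite(dg_dft)) || any(!is.finite(dg_ani)))
    stop("backend energies must be finite")
  structure(cf[1] * dg_dft + cf[2] * dg_ani + cf[3],
            provenance = provenance)
}

#' Cluster-weighted average binding energy
#'
#' Aggregates per-centroid binding energies into a single estimate,
#' weighting each centroid by its cluster's (unrounded) frame fraction,
#' so that heavily populated binding modes dominate. Weights are
#' normalized to sum to 1; with equal weights this is the plain mean.
#'
#' @param values per-centroid binding energies (kcal/mol), one per
#'   cluster.
#' @param weights non-negative cluster weights (frame fractions or
#'   counts).
#' @return a `WeightedEnergySummary`: list with `values`, `weights`
#'   (normalized), and `mean` (kcal/mol).
#' @export
weightedAverage <- function(values, weights) {
  if (length(values) != length(weights))
    stop("got ", length(values), " energies but ", length(weights),
         " weights")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights sum to zero")
  w <- weights / sum(weights)
  m <- sum(w * values)
  structure(list(values = values, weights = w, mean = m),
            class = "WeightedEnergySummary")
}

#' @export
print.WeightedEnergySummary <- function(x, ...) {
  cat(sprintf("Weighted mean dG_b = %.2f kcal/mol over %d centroids\n",
              x$mean, length(x$values)))
  df <- data.frame(dG_b = x$values, weight = sprintf("%.3f", x$weights))
  print.data.frame(df[order(x$values), ])
  invisible(x)
}

#' Read a per-structure energy table (CSV)
#'
#' Accepts either component form (`id, complex, ligand, receptor`) or
#' two-backend form (`id, dg_dft, dg_ani`).
#'
#' @param path CSV file.
#' @return data.frame with a `format` attribute, `"components"` or
#'   `"backends"`.
#' @export
readEnergyTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("id", "complex", "ligand", "receptor") %in% names(df))) {
    attr(df, "format") <- "components"
  } else if (all(c("id", "dg_dft", "dg_ani") %in% names(df))) {
    attr(df, "format") <- "backends"
  } else {
    stop("unrecognised energy table: expected columns ",
         "(id, complex, ligand, receptor) or (id, dg_dft, dg_ani)")
  }
  df
}
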