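#' Construct a free-energy-surface grid
#'
#' A `FESGrid` holds free energy (kcal/mol) over a uniform 1-D or 2-D
#' collective-variable grid. Values are normalized so the minimum over
#' visited cells is 0.
#'
#' @param values numeric vector (1-D) or matrix (2-D, rows = axis 1).
#' @param axes list of axis definitions, each `list(name, min, max,
#'   bins)`; CV units are Angstrom for the distance CVs used here.
#' @param replica optional replica identifier.
#' @param normalize shift so `min(values) == 0` (default TRUE).
#' @return object of class `FESGrid`.
#' @export
FESGrid <- function(values, axes, replica = NA, normalize = TRUE) {
  if (is.matrix(values)) {
    ndim <- 2L
    if (length(axes) != 2) stop("2-D values need two axis definitions")
    if (nrow(values) != axes[[1]]$bins || ncol(values) != axes[[2]]$bins)
      stop("value matrix shape does not match axis bins")
  } else {
    ndim <- 1L
    values <- as.numeric(values)
    if (length(axes) != 1) stop("1-D values need one axis definition")
    if (length(values) != axes[[1]]$bins)
      stop("value length does not match axis bins")
  }
  for (ax in axes) {
    if (!all(c("name", "min", "max", "bins") %in% names(ax)))
      stop("each axis needs name, min, max, bins")
    if (ax$max <= ax$min || ax$bins < 2) stop("bad axis definition")
  }
  if (any(!is.finite(values))) stop("non-finite free-energy values")
  if (normalize) values <- values - min(values)
  structure(list(ndim = ndim, values = values, axes = axes,
                 replica = replica),
            class = "FESGrid")
}

#' @export
print.FESGrid <- function(x, ...) {
  cat("FESGrid:", x$ndim, "D,",
      paste(vapply(x$axes, function(a)
        sprintf("%s[%g..%g, %d bins]", a$name, a$min, a$max, a$bins),
        ""), collapse = " x "),
      sprintf("; range 0..%.3f kcal/mol\n", max(x$values)))
  invisible(x)
}

axisCenters <- function(ax) {
  w <- (ax$max - ax$min) / ax$bins
  ax$min + w * (seq_len(ax$bins) - 0.5)
}

#' Hill deposition log
#'
#' Times must be strictly increasing and heights positive. `centers`
#' is a vector (1-D) or a matrix with one row per hill (2-D).
#'
#' @param times deposition times, ps.
#' @param centers CV value(s) at deposition.
#' @param heights hill heights, kcal/mol.
#' @param widths Gaussian widths (sigma), Angstrom; recycled.
#' @return object of class `HillLog`.
#' @export
HillLog <- function(times, centers, heights, widths) {
  if (any(diff(times) <= 0)) stop("hill times must be strictly increasing")
  if (any(heights <= 0)) stop("hill heights must be positive")
  if (any(widths <= 0)) stop("hill widths must be positive")
  centers <- if (is.matrix(centers)) centers else matrix(centers, ncol = 1)
  n <- length(times)
  if (nrow(centers) != n)
    stop("times and centers must agree in length")
  heights <- rep_len(heights, n)
  widths <- rep_len(widths, n)
  structure(list(times = times, centers = centers, heights = heights,
                 widths = widths, ndim = ncol(centers)),
            class = "HillLog")
}

#' Reconstruct a free-energy surface from deposited hills
#'
#' The estimate is the negative of the summed Gaussian bias,
#' `F(s) = -sum_i h_i exp(-|s - s_i|^2 / (2 w_i^2))`, rescaled by
#' `(T + dT)/dT = gamma/(gamma - 1)` when a well-tempered bias factor
#' `gamma` is supplied, then normalized to minimum 0.
#'
#' @param hills a `HillLog`.
#' @param axes grid axes as in [FESGrid()]; must cover all hill
#'   centers.
#' @param bias_factor optional well-tempered bias factor
#'   `gamma = (T + dT)/T > 1`.
#' @return a `FESGrid`.
#' @export
fesFromHills <- function(hills, axes, bias_factor = NULL) {
  stopifnot(inherits(hills, "HillLog"))
  if (length(axes) != hills$ndim)
    stop("grid dimensionality does not match the hill log")
  for (d in seq_len(hills$ndim)) {
    out <- which(hills$centers[, d] < axes[[d]]$min |
                   hills$centers[, d] > axes[[d]]$max)
    if (length(out) > 0)
      stop("hill(s) outside the grid on axis ", axes[[d]]$name,
           ": deposition time(s) ",
           paste(utils::head(hills$times[out], 3), collapse = ", "), " ps")
  }
  scale <- 1
  if (!is.null(bias_factor)) {
    if (bias_factor <= 1) stop("bias factor must exceed 1")
    scale <- bias_factor / (bias_factor - 1)
  }
  if (hills$ndim == 1) {
    s <- axisCenters(axes[[1]])
    bias <- numeric(length(s))
    for (i in seq_along(hills$heights)) {
      bias <- bias + hills$heights[i] *
        exp(-(s - hills$centers[i, 1])^2 / (2 * hills$widths[i]^2))
    }
    return(FESGrid(-scale * bias, axes))
  }
  s1 <- axisCenters(axes[[1]])
  s2 <- axisCenters(axes[[2]])
  bias <- matrix(0, length(s1), length(s2))
  for (i in seq_along(hills$heights)) {
    g1 <- exp(-(s1 - hills$centers[i, 1])^2 / (2 * hills$widths[i]^2))
    g2 <- exp(-(s2 - hills$centers[i, 2])^2 / (2 * hills$widths[i]^2))
    bias <- bias + hills$heights[i] * outer(g1, g2)
  }
  FESGrid(-scale * bias, axes)
}

sameGridSpec <- function(a, b) {
  if (a$ndim != b$ndim) return(FALSE)
  for (d in seq_len(a$ndim)) {
    ax <- a$axes[[d]]; bx <- b$axes[[d]]
    if (ax$bins != bx$bins || abs(ax$min - bx$min) > 1e-9 ||
        abs(ax$max - bx$max) > 1e-9) return(FALSE)
  }
  TRUE
}

#' Average free-energy surfaces across replicas
#'
#' Cell-wise arithmetic mean of replica surfaces on identical grids,
#' re-normalized to minimum 0. Replica averaging is the standard way
#' to damp the statistical noise of independent metadynamics runs.
#'
#' @param replicas list of `FESGrid`s with identical grid specs.
#' @return the averaged `FESGrid`.
#' @export
averageFes <- function(replicas) {
  if (length(replicas) < 1) stop("no replicas supplied")
  ref <- replicas[[1]]
  for (r in replicas[-1]) {
    if (!sameGridSpec(ref, r))
      stop("replica grids differ in axes/bins; cannot average")
  }
  vals <- Reduce(`+`, lapply(replicas, `[[`, "values")) / length(replicas)
  FESGrid(vals, ref$axes, replica = "average")
}

neighborOffsets <- function(ndim) {
  if (ndim == 1) return(matrix(c(-1L, 1L), ncol = 1))
  g <- as.matrix(expand.grid(-1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]  # 8-connected
}

#' Locate free-energy minima
#'
#' Finds strict local minima of a normalized surface (2-connected in
#' 1-D, 8-connected in 2-D) and keeps those whose basin prominence —
#' the lowest rim level at which the basin merges with a deeper one,
#' minus the minimum value — is at least `depth_cut`. Minima are
#' labelled A, B, C, ... in order of increasing free energy, global
#' minimum first.
#'
#' @param grid a `FESGrid`.
#' @param depth_cut minimum basin prominence, kcal/mol (default 0.5).
#' @return data.frame with `label`, one CV-coordinate column per axis,
#'   `value` (kcal/mol above the global minimum) and `prominence`.
#' @export
findMinima <- function(grid, depth_cut = 0.5) {
  stopifnot(inherits(grid, "FESGrid"))
  v <- grid$values
  if (max(v) - min(v) < 1e-12)
    return(data.frame(label = character(0), value = numeric(0)))
  dims <- if (grid$ndim == 1) length(v) else dim(v)
  coord <- function(i) if (grid$ndim == 1) i else arrayInd(i, dims)
  offs <- neighborOffsets(grid$ndim)
  ncell <- length(v)
  getv <- function(ci) if (grid$ndim == 1) v[ci[1]] else v[ci[1], ci[2]]

  neighbors <- function(i) {
    ci <- coord(i)
    out <- integer(0)
    for (r in seq_len(nrow(offs))) {
      cj <- ci + offs[r, ]
      if (any(cj < 1) || any(cj > dims)) next
      out <- c(out, if (grid$ndim == 1) cj[1]
               else (cj[2] - 1L) * dims[1] + cj[1])
    }
    out
  }

  is_min <- vapply(seq_len(ncell), function(i) {
    nb <- neighbors(i)
    all(v[nb] > v[i])
  }, logical(1))
  mins <- which(is_min)
  if (length(mins) == 0)
    return(data.frame(label = character(0), value = numeric(0)))

  # prominence by flooding: process cells by increasing value with
  # union-find; a basin's merge level is where it meets a deeper basin
  ord <- order(v)
  parent <- integer(ncell)           # 0 = unvisited
  basin_min <- integer(ncell)        # representative -> its minimum cell
  merge_level <- setNames(rep(NA_real_, length(mins)), mins)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in ord) {
    parent[i] <- i
    basin_min[i] <- i
    for (j in neighbors(i)) {
      if (parent[j] == 0L) next
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      mi <- basin_min[ri]; mj <- basin_min[rj]
      # shallower basin dies here: record its merge (saddle) level
      if (v[mi] <= v[mj]) {
        if (as.character(mj) %in% names(merge_level) &&
            is.na(merge_level[as.character(mj)]))
          merge_level[as.character(mj)] <- v[i]
        parent[rj] <- ri
        basin_min[ri] <- mi
      } else {
        if (as.character(mi) %in% names(merge_level) &&
            is.na(merge_level[as.character(mi)]))
          merge_level[as.character(mi)] <- v[i]
        parent[ri] <- rj
        basin_min[rj] <- mj
      }
    }
  }
  prom <- vapply(mins, function(m) {
    ml <- merge_level[as.character(m)]
    if (is.na(ml)) max(v) - v[m] else ml - v[m]   # global basin
  }, numeric(1))

  keep <- prom >= depth_cut
  mins <- mins[keep]; prom <- prom[keep]
  ordm <- order(v[mins])
  mins <- mins[ordm]; prom <- prom[ordm]
  out <- data.frame(label = LETTERS[seq_along(mins)])
  for (d in seq_len(grid$ndim)) {
    cc <- axisCenters(grid$axes[[d]])
    idx <- vapply(mins, function(m) coord(m)[d], numeric(1))
    out[[grid$axes[[d]]$name]] <- cc[idx]
  }
  out$value <- v[mins]
  out$prominence <- prom
  out
}

#' Hill-height convergence diagnostic
#'
#' In well-tempered metadynamics the effective hill height decays as
#' minima flood; a sustained decrease therefore signals convergence.
#' Hills are grouped into consecutive windows of `window` depositions;
#' the diagnostic reports the windowed mean height, a Kendall-type
#' trend score in \[-1, 1\] (all window pairs decreasing = -1, constant
#' = 0) and a `converging` flag set when the last window's mean falls
#' below `late_fraction` of the first window's.
#'
#' @param hills a `HillLog`.
#' @param window hills per window (>= 1); there must be >= 2 windows.
#' @param late_fraction convergence threshold on last/first window
#'   mean, default 0.5.
#' @return list with `window_times`, `window_means`, `trend`,
#'   `converging`.
#' @export
hillConvergence <- function(hills, window = 50, late_fraction = 0.5) {
  stopifnot(inherits(hills, "HillLog"))
  n <- length(hills$heights)
  nw <- n %/% window
  if (nw < 2) stop("need at least two windows of ", window, " hills")
  idx <- rep(seq_len(nw), each = window)
  h <- hills$heights[seq_len(nw * window)]
  tm <- hills$times[seq_len(nw * window)]
  means <- as.numeric(tapply(h, idx, mean))
  wt <- as.numeric(tapply(tm, idx, max))
  pairs <- combn(nw, 2)
  sgn <- sign(means[pairs[2, ]] - means[pairs[1, ]])
  trend <- sum(sgn) / ncol(pairs)
  list(window_times = wt, window_means = means, trend = trend,
       converging = means[nw] < late_fraction * means[1])
}

#' Read / write FES grids and hill logs as CSV
#'
#' Grid CSV: columns are one CV-center column per axis plus
#' `free_energy`; a header comment line carries axis names and units.
#' Hill CSV: `time_ps`, `cv1` (and `cv2`), `height`, `width`.
#'
#' @param path CSV file.
#' @param grid,hills object to write.
#' @name fes-io
#' @export
readFesCsv <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- read.csv(path, comment.char = "#")
  axcols <- setdiff(names(df), "free_energy")
  if (!"free_energy" %in% names(df)) stop("no free_energy column in ", path)
  axes <- lapply(axcols, function(nm) {
    u <- sort(unique(df[[nm]]))
    w <- if (length(u) > 1) u[2] - u[1] else 1
    list(name = nm, min = min(u) - w / 2, max = max(u) + w / 2,
         bins = length(u))
  })
  if (length(axes) == 1) {
    v <- df$free_energy[order(df[[axcols[1]]])]
  } else {
    v <- matrix(NA_real_, axes[[1]]$bins, axes[[2]]$bins)
    i <- match(df[[axcols[1]]], sort(unique(df[[axcols[1]]])))
    j <- match(df[[axcols[2]]], sort(unique(df[[axcols[2]]])))
    v[cbind(i, j)] <- df$free_energy
    if (any(is.na(v))) stop("grid CSV does not cover the full grid")
  }
  FESGrid(v, axes)
}

#' @rdname fes-io
#' @export
writeFesCsv <- function(grid, path) {
  stopifnot(inherits(grid, "FESGrid"))
  axn <- vapply(grid$axes, `[[`, "", "name")
  if (grid$ndim == 1) {
    df <- data.frame(axisCenters(grid$axes[[1]]), grid$values)
  } else {
    g <- expand.grid(axisCenters(grid$axes[[1]]),
                     axisCenters(grid$axes[[2]]))
    df <- data.frame(g[, 1], g[, 2], as.numeric(grid$values))
  }
  names(df) <- c(axn, "free_energy")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# FES: ", paste(axn, collapse = ", "),
                    " in Angstrom; free_energy in kcal/mol"), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname fes-io
#' @export
readHillsCsv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  cvcols <- grep("^cv", names(df), value = TRUE)
  HillLog(df$time_ps, as.matrix(df[, cvcols, drop = FALSE]),
          df$height, df$width)
}

#' @rdname fes-io
#' @export
writeHillsCsv <- function(hills, path) {
  stopifnot(inherits(hills, "HillLog"))
  df <- data.frame(time_ps = hills$times)
  for (d in seq_len(hills$ndim)) df[[paste0("cv", d)]] <- hills$centers[, d]
  df$height <- hills$heights
  df$width <- hills$widths
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# metadynamics hills: time in ps, cv in Angstrom, height in kcal/mol", con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
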