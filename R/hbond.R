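resLabel <- function(topo, atom_idx) {
  rn <- topo$atoms$resid[atom_idx]
  one <- AA3[rn]
  one[is.na(one)] <- rn[is.na(one)]
  paste0(one, topo$atoms$resno[atom_idx])
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: a donor heavy atom D (N/O with a bonded H) and
#' an acceptor heavy atom A (N/O) in a different residue form a
#' hydrogen bond when the D...A distance is at most `d_cut` and the
#' D-H...A angle (at the hydrogen) is at least `angle_cut` for at least
#' one hydrogen on the donor. Defaults (3.5 Angstrom, 150 degrees) are
#' the standard analysis-toolkit settings.
#'
#' Side-chain salt bridges between basic (Arg/Lys/His) side-chain
#' nitrogens and acidic (Asp/Glu) side-chain oxygens are additionally
#' reported, with an N...O distance criterion of `salt_cut` and no
#' angle condition; their residue-pair key is canonicalised by sorting,
#' so R357-E460 and E460-R357 are the same interaction.
#'
#' @param traj a `Trajectory`.
#' @param frame frame index.
#' @param d_cut donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_cut donor-H-acceptor angle cutoff, degrees.
#' @param salt_cut side-chain N...O distance cutoff for salt bridges.
#' @param restrict optional residue-number set; only interactions with
#'   both partners in the set are reported.
#' @return data.frame (class `InteractionSet`) with columns `key`,
#'   `donor`, `acceptor`, `class`, `atoms` — one row per residue-level
#'   interaction present in the frame.
#' @export
detectHBonds <- function(traj, frame = 1, d_cut = 3.5, angle_cut = 150,
                         salt_cut = 4.0, restrict = NULL) {
  topo <- traj$topology
  if (!any(topo$atoms$elesy == "H"))
    stop("the geometric hydrogen-bond criterion requires explicit ",
         "hydrogens, and this topology has none")
  xyz <- frameCoords(traj, frame)
  at <- topo$atoms
  inRestrict <- function(i) is.null(restrict) | at$resno[i] %in% restrict

  # hydrogens per donor
  hmap <- split(
    c(topo$bonds[at$elesy[topo$bonds[, 2]] == "H", 2],
      topo$bonds[at$elesy[topo$bonds[, 1]] == "H", 1]),
    c(topo$bonds[at$elesy[topo$bonds[, 2]] == "H", 1],
      topo$bonds[at$elesy[topo$bonds[, 1]] == "H", 2]))

  donors <- which(topo$donor)
  acceptors <- which(topo$acceptor)
  rows <- list()
  addRow <- function(key, donor, acceptor, cls, atoms) {
    rows[[length(rows) + 1]] <<- data.frame(
      key = key, donor = donor, acceptor = acceptor, class = cls,
      atoms = atoms, stringsAsFactors = FALSE)
  }

  for (d in donors) {
    hs <- hmap[[as.character(d)]]
    if (is.null(hs)) next
    cand <- acceptors[at$resno[acceptors] != at$resno[d] |
                        at$chain[acceptors] != at$chain[d]]
    if (length(cand) == 0) next
    da2 <- rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[d, ])^2)
    cand <- cand[da2 <= d_cut^2]
    for (a in cand) {
      ok <- FALSE
      for (h in hs) {
        v1 <- xyz[d, ] - xyz[h, ]
        v2 <- xyz[a, ] - xyz[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang >= angle_cut) { ok <- TRUE; break }
      }
      if (!ok) next
      if (!(inRestrict(d) && inRestrict(a))) next
      addRow(paste0(resLabel(topo, d), "-", resLabel(topo, a)),
             resLabel(topo, d), resLabel(topo, a), "hbond",
             paste0(at$elety[d], "...", at$elety[a]))
    }
  }

  basicN <- which(at$resid %in% c("ARG", "LYS", "HIS") & at$elesy == "N" &
                    !(at$elety %in% c("N")))
  acidO <- which(at$resid %in% c("ASP", "GLU") & at$elesy == "O" &
                   !(at$elety %in% c("O", "OXT")))
  for (i in basicN) {
    for (j in acidO) {
      if (at$resno[i] == at$resno[j] && at$chain[i] == at$chain[j]) next
      if (sum((xyz[i, ] - xyz[j, ])^2) > salt_cut^2) next
      if (!(inRestrict(i) && inRestrict(j))) next
      # canonical order: basic residue first, matching R357-E460 style
      lab <- c(resLabel(topo, i), resLabel(topo, j))
      addRow(paste0(lab[1], "-", lab[2]), lab[1], lab[2], "salt_bridge",
             paste0(at$elety[i], "...", at$elety[j]))
    }
  }

  out <- if (length(rows) == 0) {
    data.frame(key = character(0), donor = character(0),
               acceptor = character(0), class = character(0),
               atoms = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  # residue-pair level: one row per (key, class), atom pairs collapsed
  out <- unique(out[, c("key", "donor", "acceptor", "class")])
  class(out) <- c("InteractionSet", "data.frame")
  out
}

#' Hydrogen-bond / salt-bridge occupancy over a trajectory
#'
#' Occupancy of a residue-pair interaction is the percentage of
#' analysed frames in which it satisfies the geometric criterion
#' (aggregation is at residue-pair level: a pair counts as present in a
#' frame when any of its atom pairs qualifies). Pairs never detected do
#' not appear in the table.
#'
#' @inheritParams detectHBonds
#' @param system label for the system (used by [compareNetworks()]).
#' @return an `OccupancyTable`: data.frame with `key`, `donor`,
#'   `acceptor`, `class`, `occupancy` (percent of frames, 0-100), plus
#'   attributes `system` and `frames`.
#' @export
occupancy <- function(traj, d_cut = 3.5, angle_cut = 150, salt_cut = 4.0,
                      restrict = NULL, system = "system") {
  nf <- nFrames(traj)
  if (nf < 1) stop("occupancy needs at least one frame")
  counts <- list()
  meta <- list()
  for (f in seq_len(nf)) {
    det <- detectHBonds(traj, f, d_cut = d_cut, angle_cut = angle_cut,
                        salt_cut = salt_cut, restrict = restrict)
    if (nrow(det) == 0) next
    ids <- paste(det$key, det$class, sep = "|")
    for (r in seq_len(nrow(det))) {
      id <- ids[r]
      counts[[id]] <- (counts[[id]] %||% 0L) + 1L
      if (is.null(meta[[id]])) meta[[id]] <- det[r, ]
    }
  }
  occupancyTable(
    keys = do.call(rbind, unname(meta)),
    counts = unlist(counts[names(meta)]) %||% integer(0),
    frames = nf, system = system)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble an occupancy table from counts or percentages
#'
#' Constructor used both by [occupancy()] and directly when occupancies
#' come from an external analysis (e.g. published per-pair
#' percentages).
#'
#' @param keys data.frame with columns `key`, `donor`, `acceptor`,
#'   `class` (missing ones are filled from `key`).
#' @param counts frames-present per key (used with `frames`), or `NULL`
#'   when `percent` is given.
#' @param percent occupancy percentages per key (0-100).
#' @param frames number of frames analysed.
#' @param system system label.
#' @return an `OccupancyTable`.
#' @export
occupancyTable <- function(keys, counts = NULL, percent = NULL,
                           frames = 1L, system = "system") {
  if (is.character(keys)) keys <- data.frame(key = keys,
                                             stringsAsFactors = FALSE)
  if (is.null(keys) || nrow(keys) == 0) {
    out <- data.frame(key = character(0), donor = character(0),
                      acceptor = character(0), class = character(0),
                      occupancy = numeric(0), stringsAsFactors = FALSE)
  } else {
    if (is.null(keys$class)) keys$class <- "hbond"
    if (is.null(keys$donor)) {
      parts <- strsplit(keys$key, "-", fixed = TRUE)
      keys$donor <- vapply(parts, `[`, "", 1)
      keys$acceptor <- vapply(parts, function(p)
        paste(p[-1], collapse = "-"), "")
    }
    occ <- if (!is.null(percent)) as.numeric(percent)
           else 100 * as.numeric(counts) / frames
    if (any(occ < 0 | occ > 100))
      stop("occupancies must lie in [0, 100]")
    out <- data.frame(keys[, c("key", "donor", "acceptor", "class")],
                      occupancy = occ, stringsAsFactors = FALSE)
    out <- out[order(-out$occupancy, out$key), ]
    rownames(out) <- NULL
  }
  if (frames <= 0) stop("frames analysed must be positive")
  structure(out, system = system, frames = as.integer(frames),
            class = c("OccupancyTable", "data.frame"))
}

#' @export
print.OccupancyTable <- function(x, ...) {
  cat("OccupancyTable [", attr(x, "system"), "]: ", nrow(x),
      " interactions over ", attr(x, "frames"), " frames\n", sep = "")
  if (nrow(x) > 0)
    print.data.frame(head(
      transform(x, occupancy = sprintf("%.2f%%", occupancy)), 10))
  invisible(x)
}

#' Stable interactions at an occupancy threshold
#'
#' An interaction is considered stable when present in at least
#' `threshold` percent of frames; the boundary is inclusive (an
#' occupancy of exactly 60 percent is stable at the default threshold).
#'
#' @param table an `OccupancyTable`.
#' @param threshold percent, in (0, 100]; default 60.
#' @return character vector of stable interaction keys.
#' @export
stableInteractions <- function(table, threshold = 60) {
  stopifnot(inherits(table, "OccupancyTable"))
  if (threshold <= 0 || threshold > 100)
    stop("threshold must be in (0, 100]")
  table$key[table$occupancy >= threshold]
}

#' Compare interaction networks across systems
#'
#' Splits stable interactions into the shared core (stable in every
#' system) and per-system differential sets. The cross-system matrix
#' reports each system's occupancy per key, with `"NOB"` (not observed)
#' for pairs a system never formed.
#'
#' @param tables list of `OccupancyTable`s (>= 2), ideally named.
#' @param threshold stability threshold, percent.
#' @return list with `shared` (keys stable everywhere), `differential`
#'   (per-system stable keys minus shared) and `matrix` (key x system
#'   occupancy data.frame, `"NOB"` where absent).
#' @export
compareNetworks <- function(tables, threshold = 60) {
  if (length(tables) < 2) stop("need at least two systems to compare")
  labels <- names(tables) %||% rep(NA_character_, length(tables))
  labels <- ifelse(is.na(labels) | labels == "",
                   vapply(tables, attr, "", "system"), labels)
  stable <- lapply(tables, stableInteractions, threshold = threshold)
  shared <- Reduce(intersect, stable)
  differential <- lapply(stable, setdiff, y = shared)
  names(differential) <- labels

  keys <- unique(unlist(lapply(tables, `[[`, "key")))
  m <- data.frame(key = keys, stringsAsFactors = FALSE)
  for (s in seq_along(tables)) {
    v <- rep("NOB", length(keys))
    hit <- match(keys, tables[[s]]$key)
    v[!is.na(hit)] <- sprintf("%.2f%%",
                              tables[[s]]$occupancy[hit[!is.na(hit)]])
    m[[labels[s]]] <- v
  }
  list(shared = shared, differential = differential, matrix = m)
}
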