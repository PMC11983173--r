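#' Resolve an atom-selection expression
#'
#' A small selection language over the topology, sufficient for the
#' descriptors used in binding-mode analysis:
#'
#' * `backbone` — protein N, CA, C, O atoms
#' * `protein` — atoms in standard amino-acid residues
#' * `ligand` — atoms in non-protein, non-solvent residues
#' * `all` — every atom
#' * `resid 288` / `resid 10:20 35` — residue numbers and ranges
#' * `name CA CZ` — atom names
#' * `resname ARG GLU` — residue names
#' * `chain A` — chain identifiers
#' * `element N O` — element symbols
#' * combinators `and`, `or`, `not`, parentheses
#'
#' Resolution is deterministic: the same expression on the same
#' topology always yields the same (sorted) atom index list. An empty
#' result is an error, as is any token the grammar does not know.
#'
#' @param traj a `Trajectory` (or a `Topology`).
#' @param expression selection text.
#' @return object of class `Selection`: integer atom indices (1-based)
#'   with the expression kept in attribute `expression`.
#' @export
resolveSelection <- function(traj, expression) {
  topo <- if (inherits(traj, "Trajectory")) traj$topology else traj
  stopifnot(inherits(topo, "Topology"))
  toks <- tokenizeSelection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parseOr(st, topo)
  if (st$pos <= length(st$toks$text))
    selError(st, "unexpected trailing token")
  idx <- which(mask)
  if (length(idx) == 0)
    stop("selection '", expression, "' matches no atoms")
  structure(idx, class = "Selection", expression = expression)
}

#' @export
print.Selection <- function(x, ...) {
  cat("Selection '", attr(x, "expression"), "': ", length(x), " atoms\n",
      sep = "")
  invisible(x)
}

tokenizeSelection <- function(expression) {
  stopifnot(is.character(expression), length(expression) == 1)
  pat <- "\\(|\\)|[A-Za-z0-9_':*-]+"
  m <- gregexpr(pat, expression)[[1]]
  if (m[1] == -1) stop("empty selection expression")
  text <- regmatches(expression, gregexpr(pat, expression))[[1]]
  # anything outside matched tokens must be whitespace
  probe <- expression
  for (t in text) probe <- sub(pat, strrep(" ", nchar(t)), probe)
  if (grepl("[^ \t]", probe))
    stop("unparseable character(s) in selection: '", expression, "'")
  list(text = text, start = as.integer(m))
}

selError <- function(st, msg) {
  if (st$pos <= length(st$toks$text)) {
    stop(msg, " at position ", st$toks$start[st$pos],
         ": '", st$toks$text[st$pos], "'")
  }
  stop(msg, " at end of expression")
}

peek <- function(st) {
  if (st$pos > length(st$toks$text)) return(NA_character_)
  st$toks$text[st$pos]
}
advance <- function(st) st$pos <- st$pos + 1L

KEYWORDS <- c("and", "or", "not", "(", ")",
              "backbone", "protein", "ligand", "all",
              "resid", "name", "resname", "chain", "element")

parseOr <- function(st, topo) {
  left <- parseAnd(st, topo)
  while (identical(peek(st), "or")) {
    advance(st)
    left <- left | parseAnd(st, topo)
  }
  left
}

parseAnd <- function(st, topo) {
  left <- parseUnary(st, topo)
  while (identical(peek(st), "and")) {
    advance(st)
    left <- left & parseUnary(st, topo)
  }
  left
}

parseUnary <- function(st, topo) {
  tk <- peek(st)
  if (is.na(tk)) selError(st, "expected a selection term")
  if (tk == "not") {
    advance(st)
    return(!parseUnary(st, topo))
  }
  if (tk == "(") {
    advance(st)
    inner <- parseOr(st, topo)
    if (!identical(peek(st), ")")) selError(st, "expected ')'")
    advance(st)
    return(inner)
  }
  parsePrimary(st, topo)
}

isProteinAtom <- function(topo) topo$atoms$resid %in% names(AA3)
isLigandAtom <- function(topo) {
  !isProteinAtom(topo) & !(topo$atoms$resid %in% SOLVENT_RESNAMES)
}

parsePrimary <- function(st, topo) {
  tk <- peek(st)
  at <- topo$atoms
  if (is.na(tk)) selError(st, "expected a selection term")
  switch(tk,
    backbone = {
      advance(st)
      isProteinAtom(topo) & at$elety %in% c("N", "CA", "C", "O")
    },
    protein = { advance(st); isProteinAtom(topo) },
    ligand = { advance(st); isLigandAtom(topo) },
    all = { advance(st); rep(TRUE, nrow(at)) },
    resid = {
      advance(st)
      nums <- collectValues(st, numeric_ok = TRUE)
      at$resno %in% nums
    },
    name = {
      advance(st)
      at$elety %in% collectValues(st)
    },
    resname = {
      advance(st)
      at$resid %in% collectValues(st)
    },
    chain = {
      advance(st)
      at$chain %in% collectValues(st)
    },
    element = {
      advance(st)
      toupper(at$elesy) %in% toupper(collectValues(st))
    },
    selError(st, "unknown token")
  )
}

collectValues <- function(st, numeric_ok = FALSE) {
  vals <- character(0)
  repeat {
    tk <- peek(st)
    if (is.na(tk) || tk %in% KEYWORDS) break
    vals <- c(vals, tk)
    advance(st)
  }
  if (length(vals) == 0) selError(st, "expected value(s)")
  if (!numeric_ok) return(vals)
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
      ab <- as.integer(strsplit(v, ":")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      stop("expected a residue number or range, got '", v, "'")
    }
  }
  out
}

asSelection <- function(traj, sel) {
  if (inherits(sel, "Selection")) return(sel)
  if (is.character(sel)) return(resolveSelection(traj, sel))
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    topo <- if (inherits(traj, "Trajectory")) traj$topology else traj
    if (length(idx) == 0) stop("empty atom selection")
    if (any(idx < 1 | idx > topo$natom)) stop("atom index out of range")
    return(structure(idx, class = "Selection", expression = "<indices>"))
  }
  stop("selection must be a Selection, an expression string, or indices")
}
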