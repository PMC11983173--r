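#' Write a trajectory to a CHARMM-format DCD file
#'
#' Minimal single-precision DCD writer (CORD, no unit cell, no fixed
#' atoms), producing files readable by the usual MD analysis tools.
#' Intended mainly for the synthetic-trajectory generator, so that
#' downstream tests exercise the real on-disk format rather than
#' in-memory shortcuts.
#'
#' @param traj a `Trajectory`.
#' @param path output file.
#' @param title one 80-character title line (truncated/padded).
#' @return `path`, invisibly.
#' @export
writeDCD <- function(traj, path, title = "written by mdmodes") {
  stopifnot(inherits(traj, "Trajectory"))
  nf <- nFrames(traj)
  natom <- traj$topology$natom
  con <- file(path, "wb")
  on.exit(close(con))

  writeRecord <- function(payload) {
    writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  }

  # header record (84 bytes): "CORD" + 20 control integers
  icntrl <- integer(20)
  icntrl[1] <- nf        # frames in file
  icntrl[2] <- 1L        # first step
  icntrl[3] <- 1L        # save frequency
  icntrl[4] <- nf        # total steps
  icntrl[20] <- 24L      # CHARMM version flag
  hdr <- c(charToRaw("CORD"),
           writeBin(icntrl, raw(), size = 4, endian = "little"))
  writeRecord(hdr)

  t80 <- formatC(substr(title, 1, 80), width = 80, flag = "-")
  writeRecord(c(writeBin(1L, raw(), size = 4, endian = "little"),
                charToRaw(t80)))
  writeRecord(writeBin(as.integer(natom), raw(), size = 4,
                       endian = "little"))

  for (f in seq_len(nf)) {
    xyz <- frameCoords(traj, f)
    for (axis in 1:3)
      writeRecord(writeBin(as.numeric(xyz[, axis]), raw(), size = 4,
                           endian = "little"))
  }
  invisible(path)
}
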