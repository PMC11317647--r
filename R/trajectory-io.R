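#' Read a trajectory from topology + coordinate files
#'
#' The topology (atom metadata) is read from a PDB or GRO file; coordinates
#' come from a multi-frame PDB, a multi-frame (concatenated) GRO, or a
#' CHARMM-style DCD file.  XTC is not supported (its 3dfcoord compression
#' has no reader in this environment); convert with e.g.
#' \code{gmx trjconv} first.  Species tags are assigned from residue/atom
#' name rules (see [assignSpecies()]); unassignable atoms become
#' \code{"other"} with a warning giving the count.
#'
#' All coordinates are stored in Angstrom (GRO nm values are converted on
#' read), times in ns.
#'
#' @param topology_path path to a PDB or GRO file.
#' @param coords_path path to multi-frame PDB/GRO or DCD; may equal
#'   \code{topology_path}.
#' @param species_rules optional rule overrides for [assignSpecies()].
#' @param dt frame spacing in ns, used when the coordinate file carries no
#'   time information (default 0.1, i.e. one frame per 100 ps).
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(topology_path, coords_path = topology_path,
                           species_rules = list(), dt = 0.1) {
  for (p in unique(c(topology_path, coords_path)))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  top <- switch(.traj_format(topology_path),
    pdb = .read_pdb(topology_path)$topology,
    gro = .read_gro(topology_path)$topology,
    stop("unsupported topology format: ", topology_path, call. = FALSE))
  crd <- switch(.traj_format(coords_path),
    pdb = .read_pdb(coords_path),
    gro = .read_gro(coords_path),
    dcd = .read_dcd(coords_path),
    xtc = stop("XTC is not supported (compressed format); ",
               "convert to GRO/PDB/DCD", call. = FALSE),
    stop("unsupported coordinate format: ", coords_path, call. = FALSE))
  ncrd <- nrow(crd$positions[[1]])
  if (ncrd != nrow(top))
    stop(sprintf("atom-count mismatch: topology has %d atoms, coordinates have %d",
                 nrow(top), ncrd), call. = FALSE)
  top$species <- assignSpecies(top, species_rules)
  times <- crd$times
  if (is.null(times) || anyNA(times) || length(times) != length(crd$positions) ||
      (length(times) > 1 && any(diff(times) <= 0)))
    times <- (seq_along(crd$positions) - 1) * dt
  makeTrajectory(top, crd$positions, times, crd$box)
}

#' Write a trajectory
#'
#' Formats: \code{"pdb"} (multi-MODEL), \code{"gro"} (concatenated frames,
#' nm), \code{"dcd"} (CHARMM binary).  DCD stores coordinates only; write a
#' PDB/GRO topology alongside for re-reading.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output file.
#' @param format "pdb", "gro" or "dcd"; default from the file extension.
#' @return invisibly, \code{path}.
#' @export
writeTrajectory <- function(traj, path, format = .traj_format(path)) {
  switch(format,
    pdb = .write_pdb(traj, path),
    gro = .write_gro(traj, path),
    dcd = .write_dcd(traj, path),
    stop("unsupported output format: ", format, call. = FALSE))
  invisible(path)
}

.traj_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) "pdb"
  else if (ext == "gro") "gro"
  else if (ext == "dcd") "dcd"
  else if (ext == "xtc") "xtc"
  else ext
}

## ---- PDB ------------------------------------------------------------------

.read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_end <- trimws(rec) %in% c("ENDMDL", "END")
  ## frame boundaries: atoms between ENDMDL/END markers (or one frame total)
  frame_id <- cumsum(is_end)
  frame_id <- frame_id - frame_id * 0  # keep as is
  atom_lines <- lines[is_atom]
  atom_frame <- frame_id[is_atom]
  if (!length(atom_lines)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  atom_frame <- match(atom_frame, sort(unique(atom_frame)))
  nfr <- max(atom_frame)
  f1 <- atom_lines[atom_frame == 1]
  topo <- data.frame(
    name    = trimws(substr(f1, 13, 16)),
    resname = trimws(substr(f1, 18, 21)),
    chain   = trimws(substr(f1, 22, 22)),
    resid   = as.integer(trimws(substr(f1, 23, 26))),
    element = trimws(substr(f1, 77, 78)),
    stringsAsFactors = FALSE
  )
  topo$chain[topo$chain == ""] <- "A"
  noel <- topo$element == "" | is.na(topo$element)
  topo$element[noel] <- guessElement(topo$name[noel])
  xyz <- cbind(as.numeric(substr(atom_lines, 31, 38)),
               as.numeric(substr(atom_lines, 39, 46)),
               as.numeric(substr(atom_lines, 47, 54)))
  na <- nrow(topo)
  counts <- tabulate(atom_frame, nfr)
  if (any(counts != na))
    stop(sprintf("PDB frames have unequal atom counts (%d vs %d)",
                 na, counts[which(counts != na)[1]]), call. = FALSE)
  positions <- lapply(seq_len(nfr), function(i)
    xyz[atom_frame == i, , drop = FALSE])
  cr <- lines[rec == "CRYST1"]
  box <- if (length(cr)) {
    b1 <- c(as.numeric(substr(cr[1], 7, 15)), as.numeric(substr(cr[1], 16, 24)),
            as.numeric(substr(cr[1], 25, 33)))
    matrix(b1, nfr, 3, byrow = TRUE)
  } else matrix(999, nfr, 3)  # effectively non-periodic
  list(topology = topo, positions = positions, box = box, times = NULL)
}

.write_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj@topology
  nfr <- nFrames(traj)
  for (i in seq_len(nfr)) {
    b <- traj@box[i, ]
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       b[1], b[2], b[3]), con)
    if (nfr > 1) writeLines(sprintf("MODEL     %4d", i), con)
    p <- traj@positions[[i]]
    nm <- ifelse(nchar(top$name) < 4, paste0(" ", top$name), top$name)
    writeLines(sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       (seq_len(nrow(top)) - 1L) %% 99999L + 1L, nm,
                       substr(top$resname, 1, 4), substr(top$chain, 1, 1),
                       top$resid %% 10000L, p[, 1], p[, 2], p[, 3],
                       substr(top$element, 1, 2)), con)
    writeLines(if (nfr > 1) "ENDMDL" else "END", con)
  }
}

## ---- GRO (nm on disk, Angstrom in memory) ---------------------------------

.read_gro <- function(path) {
  lines <- readLines(path)
  i <- 1L
  positions <- list(); boxes <- list(); times <- numeric()
  topo <- NULL
  while (i <= length(lines)) {
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(nat)) stop("malformed GRO atom count at line ", i + 1, call. = FALSE)
    at <- lines[(i + 2):(i + 1 + nat)]
    if (is.null(topo)) {
      topo <- data.frame(
        resid   = as.integer(substr(at, 1, 5)),
        resname = trimws(substr(at, 6, 10)),
        name    = trimws(substr(at, 11, 15)),
        stringsAsFactors = FALSE)
      topo$chain <- "A"
      topo$element <- guessElement(topo$name)
    } else if (nat != nrow(topo))
      stop(sprintf("GRO frames have unequal atom counts (%d vs %d)",
                   nrow(topo), nat), call. = FALSE)
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44))) * 10  # nm -> A
    positions[[length(positions) + 1L]] <- xyz
    bl <- as.numeric(strsplit(trimws(lines[i + 2 + nat]), "\\s+")[[1]])[1:3] * 10
    boxes[[length(boxes) + 1L]] <- bl
    tm <- regmatches(title, regexpr("t=\\s*[0-9.eE+-]+", title))
    times <- c(times, if (length(tm))
      as.numeric(sub("t=\\s*", "", tm)) / 1000 else NA_real_)  # ps -> ns
    i <- i + 3L + nat
  }
  list(topology = topo, positions = positions,
       box = do.call(rbind, boxes),
       times = if (anyNA(times)) NULL else times)
}

.write_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj@topology
  for (i in seq_len(nFrames(traj))) {
    writeLines(sprintf("poreperm frame %d, t= %.4f", i,
                       traj@times[i] * 1000), con)  # ns -> ps
    writeLines(sprintf("%5d", nAtoms(traj)), con)
    p <- traj@positions[[i]] / 10  # A -> nm
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       top$resid %% 100000L, substr(top$resname, 1, 5),
                       substr(top$name, 1, 5),
                       (seq_len(nrow(top)) - 1L) %% 99999L + 1L,
                       p[, 1], p[, 2], p[, 3]), con)
    b <- traj@box[i, ] / 10
    writeLines(sprintf("%10.5f%10.5f%10.5f", b[1], b[2], b[3]), con)
  }
}

## ---- DCD (CHARMM dialect, native endianness) ------------------------------

.read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rec_start <- function() readBin(con, "integer", 1, 4)
  len <- rec_start()
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "CORD")) stop("not a DCD file: ", path, call. = FALSE)
  icntrl <- readBin(con, "integer", 20, 4)
  ## delta is a float stored in icntrl slot 10
  delta <- readBin(writeBin(icntrl[10], raw(), size = 4), "numeric", 1, 4)
  has_cell <- icntrl[11] == 1
  readBin(con, "integer", 1, 4)  # end marker
  tl <- rec_start()
  readBin(con, "raw", tl)
  readBin(con, "integer", 1, 4)
  rec_start()
  natoms <- readBin(con, "integer", 1, 4)
  readBin(con, "integer", 1, 4)
  nfr <- icntrl[1]
  positions <- vector("list", nfr)
  boxes <- matrix(0, nfr, 3)
  for (i in seq_len(nfr)) {
    if (has_cell) {
      rec_start()
      cell <- readBin(con, "numeric", 6, 8)
      boxes[i, ] <- cell[c(1, 3, 6)]
      readBin(con, "integer", 1, 4)
    }
    xyz <- matrix(0, natoms, 3)
    for (k in 1:3) {
      rec_start()
      xyz[, k] <- readBin(con, "numeric", natoms, 4)
      readBin(con, "integer", 1, 4)
    }
    positions[[i]] <- xyz
  }
  dt <- if (is.finite(delta) && delta > 0) delta * max(icntrl[3], 1) else NA
  times <- if (is.finite(dt)) (icntrl[2] + seq_len(nfr) - 1) * dt else NULL
  list(topology = NULL, positions = positions, box = boxes, times = times)
}

.write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, 4)
    payload_writer()
    writeBin(as.integer(nbytes), con, 4)
  }
  nfr <- nFrames(traj)
  dtf <- if (nfr > 1) traj@times[2] - traj@times[1] else 0.1
  delta_int <- readBin(writeBin(as.numeric(dtf), raw(), size = 4), "integer", 1, 4)
  icntrl <- integer(20)
  icntrl[1] <- nfr; icntrl[2] <- 0L; icntrl[3] <- 1L; icntrl[4] <- nfr
  icntrl[10] <- delta_int; icntrl[11] <- 1L; icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl, con, 4)
  }, 84)
  title <- formatC("poreperm trajectory", width = -80)
  rec(function() {
    writeBin(1L, con, 4)
    writeChar(title, con, 80, eos = NULL)
  }, 84)
  rec(function() writeBin(nAtoms(traj), con, 4), 4)
  na <- nAtoms(traj)
  for (i in seq_len(nfr)) {
    b <- traj@box[i, ]
    rec(function() writeBin(c(b[1], 0, b[2], 0, 0, b[3]), con, 8), 48)
    p <- traj@positions[[i]]
    for (k in 1:3)
      rec(function() writeBin(as.numeric(p[, k]), con, 4), 4 * na)
  }
}
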