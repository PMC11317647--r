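# Independent oracles and tiny fixture builders used across the suite.

# Brute-force crossing counter: per ion, walk the frames, classify bulk
# zones directly, and count luminal->cytosolic bulk-to-bulk passages whose
# intermediate frames all lie inside the cylinder.  Deliberately written as
# a plain scalar scan over bulk-frame intervals, independent of the
# package's state machine.
bruteCrossings <- function(traj, pore, species = "cation", margin = 2) {
  top <- topology(traj)
  ions <- which(top$species == species)
  csel <- selectAtoms(traj, pore@centerSelection)
  sgn <- pore@luminalSide
  nfr <- nFrames(traj)
  fwd <- 0L; rev <- 0L
  for (a in ions) {
    zone <- character(nfr); inside <- logical(nfr)
    for (f in seq_len(nfr)) {
      p <- framePositions(traj, f)
      ctr <- colMeans(p[csel, , drop = FALSE])
      box <- boxLengths(traj)[f, ]
      d <- p[a, ] - ctr
      d <- d - box * round(d / box)
      s <- sum(d * pore@axis)
      r <- sqrt(sum((d - s * pore@axis)^2))
      zone[f] <- if (sgn * (s - pore@zSF) > margin) "L"
                 else if (sgn * (s - pore@zGate) < -margin) "C" else "M"
      inside[f] <- r <= pore@cylinderRadius
    }
    bulk <- which(zone != "M")
    if (length(bulk) < 2) next
    for (k in seq_len(length(bulk) - 1)) {
      f1 <- bulk[k]; f2 <- bulk[k + 1]
      if (zone[f1] == zone[f2]) next
      if (f2 - f1 < 2) next            # no intermediate frame: no evidence
      if (!all(inside[(f1 + 1):(f2 - 1)])) next
      if (zone[f1] == "L") fwd <- fwd + 1L else rev <- rev + 1L
    }
  }
  c(forward = fwd, reverse = rev)
}

# All-pairs coordination count with explicit 27-image periodic distances.
bruteCoordination <- function(traj, frame, ion, partners, cutoff) {
  p <- framePositions(traj, frame)
  box <- boxLengths(traj)[frame, ]
  n <- 0L
  for (w in partners) {
    best <- Inf
    for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
      dd <- p[w, ] + c(ix, iy, iz) * box - p[ion, ]
      best <- min(best, sqrt(sum(dd^2)))
    }
    if (best < cutoff) n <- n + 1L
  }
  n
}

# Minimum distance between two atom sets over the 27 periodic images.
bruteMinDist27 <- function(traj, frame, a, b) {
  p <- framePositions(traj, frame)
  box <- boxLengths(traj)[frame, ]
  best <- Inf
  for (i in a) for (j in b)
    for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
      dd <- p[j, ] + c(ix, iy, iz) * box - p[i, ]
      best <- min(best, sqrt(sum(dd^2)))
    }
  best
}

# Manual trajectory: POR anchor dimer at the box center plus ions whose
# axial coordinate follows prescribed per-frame values (radial offset
# optional), for scripted permeation scenarios.
makeIonPath <- function(svals, roff = 0, box = c(40, 40, 80), dt = 0.1,
                        extra_ion_pos = NULL) {
  svals <- as.matrix(svals)            # frames x ions
  nfr <- nrow(svals); ni <- ncol(svals)
  roff <- matrix(roff, nfr, ni)
  center <- box / 2
  anchors <- rbind(center + c(0, 9, -5), center - c(0, 9, -5),
                   center + c(9, 0, 5), center - c(9, 0, 5))
  n_extra <- if (is.null(extra_ion_pos)) 0 else nrow(extra_ion_pos[[1]])
  topo <- data.frame(
    name = c(rep("POR", 4), rep("NA", ni + n_extra)),
    resname = c(rep("POR", 4), rep("NA", ni + n_extra)),
    resid = seq_len(4 + ni + n_extra), chain = "A",
    stringsAsFactors = FALSE)
  pos <- lapply(seq_len(nfr), function(f) {
    ion <- t(vapply(seq_len(ni), function(i)
      center + c(roff[f, i], 0, svals[f, i]), numeric(3)))
    out <- rbind(anchors, ion)
    if (n_extra) out <- rbind(out, extra_ion_pos[[f]])
    out
  })
  suppressWarnings(makeTrajectory(topo, pos, (seq_len(nfr) - 1) * dt, box))
}

defaultPore <- function() poreSpec(centerSelection = "resname POR",
                                   zSF = 12, zGate = -12)

# shared double-well stated world for the WHAM oracle
doubleWellWindows <- function(seed, n_samples = 5000) {
  kA <- permConstants$kJnm2_to_kcalA2
  tab <- seq(-35, 22, 0.25)
  spec <- pmfTabulated(tab, 8 * exp(-tab^2 / (2 * 3^2)))
  centers <- seq(-35, 22, 1)
  k <- ifelse(abs(centers) <= 5, 2500, 1000) * kA
  list(windows = sampleUmbrellaWindows(spec, centers, k,
                                       n_samples = n_samples, seed = seed),
       truth_fun = spec$fun, barrier = 8)
}
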