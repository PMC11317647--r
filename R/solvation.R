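#' Per-frame coordination number of an ion
#'
#' Counts partner atoms strictly within \code{cutoff} (minimum-image
#' distance \code{< cutoff}; the boundary is measure-zero and the strict
#' inequality is deterministic) of one ion, per frame.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param ion atom index, or a selection expression resolving to one atom.
#' @param partner_selection selection for the coordinating atoms (default
#'   water oxygens).
#' @param cutoff Angstrom (default 4.5, the first minimum of the bulk
#'   ion-water oxygen RDF).
#' @param stride frame stride.
#' @return data.frame \code{time}, \code{count}, with attributes
#'   \code{mean} and \code{min}.
#' @export
coordinationNumber <- function(traj, ion,
                               partner_selection = "species water-oxygen",
                               cutoff = 4.5, stride = 1) {
  if (is.character(ion)) ion <- selectAtoms(traj, ion)
  if (length(ion) != 1) stop("ion must resolve to exactly one atom",
                             call. = FALSE)
  part <- selectAtoms(traj, partner_selection)
  part <- setdiff(part, ion)
  idx <- seq(1, nFrames(traj), by = stride)
  cnt <- vapply(idx, function(i) {
    if (!length(part)) return(0L)
    sum(minImageDist(traj@positions[[i]][ion, ],
                     traj@positions[[i]][part, , drop = FALSE],
                     traj@box[i, ]) < cutoff)
  }, 0L)
  structure(data.frame(time = traj@times[idx], count = cnt),
            mean = mean(cnt), min = min(cnt))
}

#' Water and protein coordination of an ion over time
#'
#' Convenience wrapper returning both the water-oxygen coordination and
#' the protein (oxygen/nitrogen) coordination per frame.
#'
#' @inheritParams coordinationNumber
#' @return data.frame \code{time}, \code{water}, \code{protein}.
#' @export
coordinationSeries <- function(traj, ion, cutoff = 4.5, stride = 1) {
  w <- coordinationNumber(traj, ion, "species water-oxygen", cutoff, stride)
  p <- coordinationNumber(traj, ion,
                          "species protein and (element O or element N)",
                          cutoff, stride)
  data.frame(time = w$time, water = w$count, protein = p$count)
}

#' Radial distribution function between two selections
#'
#' Standard pair-distribution normalization: counts in spherical shells
#' divided by the ideal-gas expectation
#' \code{N_a N_b (4/3) pi (r2^3 - r1^3) / V} per frame, under the
#' minimum-image convention.  With fewer than 100 pair samples in total a
#' warning is issued and no first minimum should be trusted.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selection_a,selection_b selection expressions (shared atoms are
#'   excluded from pairing with themselves).
#' @param r_max maximum distance (Angstrom); must be <= half the smallest
#'   box length.
#' @param bin shell width (Angstrom, default 0.1).
#' @param stride frame stride.
#' @return data.frame \code{r} (shell centers), \code{g}.
#' @export
rdf <- function(traj, selection_a, selection_b, r_max = 10, bin = 0.1,
                stride = 1) {
  a <- selectAtoms(traj, selection_a)
  b <- selectAtoms(traj, selection_b)
  if (!length(a) || !length(b)) stop("empty RDF selection", call. = FALSE)
  idx <- seq(1, nFrames(traj), by = stride)
  if (r_max > min(traj@box[idx, ]) / 2)
    stop("r_max must be <= half the smallest box length", call. = FALSE)
  edges <- seq(0, r_max, by = bin)
  counts <- numeric(length(edges) - 1)
  npairs_tot <- 0
  norm <- 0
  for (i in idx) {
    box <- traj@box[i, ]
    V <- prod(box)
    pa <- traj@positions[[i]][a, , drop = FALSE]
    pb <- traj@positions[[i]][b, , drop = FALSE]
    for (k in seq_len(nrow(pa))) {
      dd <- minImageDist(pa[k, ], pb, box)
      dd <- dd[dd > 1e-9 & dd < r_max]   # drop self-pairs
      counts <- counts + graphics::hist(dd, breaks = edges,
                                        plot = FALSE)$counts
      npairs_tot <- npairs_tot + length(dd)
    }
    n_self <- length(intersect(a, b))
    norm <- norm + (length(a) * length(b) - n_self) / V
  }
  shell <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (norm * shell)
  if (npairs_tot < 100)
    warning("fewer than 100 pair samples; RDF is unreliable", call. = FALSE)
  data.frame(r = edges[-1] - bin / 2, g = g)
}

#' First minimum of a radial distribution function
#'
#' Locates the first local minimum after the first maximum of g(r), and
#' refines it by quadratic interpolation through the three grid points
#' around the discrete minimum.
#'
#' @param gr data.frame from [rdf()].
#' @return position of the first minimum (Angstrom), or NA if none found.
#' @export
rdfFirstMinimum <- function(gr) {
  g <- gr$g; r <- gr$r
  n <- length(g)
  ## first maximum = first local max comparable to the global peak
  ## (low-r noise bumps from near-empty shells are not the first shell)
  thr <- 0.5 * max(g)
  imax <- NA
  for (i in 2:(n - 1))
    if (g[i] > g[i - 1] && g[i] >= g[i + 1] && g[i] >= thr) { imax <- i; break }
  if (is.na(imax)) return(NA_real_)
  imin <- NA
  for (i in (imax + 1):(n - 1))
    if (g[i] <= g[i - 1] && g[i] < g[i + 1]) { imin <- i; break }
  if (is.na(imin)) return(NA_real_)
  ## quadratic through (r[imin-1..imin+1], g[...])
  x <- r[(imin - 1):(imin + 1)]; y <- g[(imin - 1):(imin + 1)]
  den <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  A <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / den
  B <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
          x[1]^2 * (y[2] - y[3])) / den
  if (A <= 0) return(r[imin])
  -B / (2 * A)
}

#' Fraction of frames with an ion-residue contact
#'
#' Fraction of frames on which any atom of \code{ion_selection} lies
#' strictly within \code{cutoff} of any atom of \code{residue_selection},
#' plus a per-residue breakdown.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param ion_selection,residue_selection selection expressions.
#' @param cutoff Angstrom.
#' @param stride frame stride.
#' @return list: \code{fraction} in [0,1]; \code{per_residue} data.frame
#'   (\code{resid}, \code{fraction}).
#' @export
contactFraction <- function(traj, ion_selection, residue_selection,
                            cutoff = 4.5, stride = 1) {
  a <- selectAtoms(traj, ion_selection)
  b <- selectAtoms(traj, residue_selection)
  if (!length(a) || !length(b)) stop("empty contact selection", call. = FALSE)
  resb <- traj@topology$resid[b]
  resu <- sort(unique(resb))
  idx <- seq(1, nFrames(traj), by = stride)
  any_hit <- logical(length(idx))
  res_hit <- matrix(FALSE, length(idx), length(resu))
  for (j in seq_along(idx)) {
    i <- idx[j]
    box <- traj@box[i, ]
    pb <- traj@positions[[i]][b, , drop = FALSE]
    hit <- rep(FALSE, length(b))
    for (k in a)
      hit <- hit | (minImageDist(traj@positions[[i]][k, ], pb, box) < cutoff)
    any_hit[j] <- any(hit)
    res_hit[j, ] <- vapply(resu, function(r) any(hit[resb == r]), TRUE)
  }
  list(fraction = mean(any_hit),
       per_residue = data.frame(resid = resu,
                                fraction = colMeans(res_hit)))
}

#' Nearest-luminal-ion distance distribution (knock-on statistics)
#'
#' For each frame holding a "bound" ion -- the tracked-species ion inside
#' the selectivity-filter band \code{sf_band} and inside the pore cylinder
#' (when several qualify, the one closest to the SF plane) -- measures the
#' minimum-image distance to the nearest same-species ion on the luminal
#' side of the SF plane.  Frames with no bound ion, or no luminal ion, are
#' skipped.  Reports the normalized distance density, the modal distance
#' and \code{P(d < threshold)}.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param pore a \linkS4class{PoreSpec}.
#' @param species species tag to track (default "cation").
#' @param sf_band axial band (Angstrom, relative to center) defining
#'   "bound at the SF"; default \code{zSF +/- 2}.
#' @param threshold proximity threshold (Angstrom, default 7).
#' @param bin histogram bin (Angstrom, default 0.25).
#' @param stride frame stride.
#' @return list: \code{mids}, \code{density} (integrates to 1),
#'   \code{P_below} (P(d < threshold); NA if no qualifying frame),
#'   \code{threshold}, \code{mode} (modal distance), \code{distances}
#'   (raw per-frame values), \code{n_frames_used}.
#' @export
nearestIonDistribution <- function(traj, pore, species = "cation",
                                   sf_band = pore@zSF + c(-2, 2),
                                   threshold = 7, bin = 0.25, stride = 1) {
  ions <- which(traj@topology$species == species)
  if (length(ions) < 2)
    stop("need at least two ions of species '", species, "'", call. = FALSE)
  csel <- selectAtoms(traj, pore@centerSelection)
  sgn <- pore@luminalSide
  idx <- seq(1, nFrames(traj), by = stride)
  dists <- numeric()
  used <- 0L
  for (i in idx) {
    ctr <- poreCenter(traj, csel, i)
    box <- traj@box[i, ]
    pos <- traj@positions[[i]][ions, , drop = FALSE]
    ar <- axialRadial(pos, ctr, pore@axis, box)
    bound <- which(ar$s >= min(sf_band) & ar$s <= max(sf_band) &
                     ar$r <= pore@cylinderRadius)
    if (!length(bound)) next
    bound <- bound[which.min(abs(ar$s[bound] - pore@zSF))]
    lum <- which(sgn * (ar$s - pore@zSF) > 0)
    lum <- setdiff(lum, bound)
    if (!length(lum)) next
    d <- min(minImageDist(pos[bound, ], pos[lum, , drop = FALSE], box))
    dists <- c(dists, d)
    used <- used + 1L
  }
  if (!used)
    return(list(mids = numeric(), density = numeric(), P_below = NA_real_,
                threshold = threshold, mode = NA_real_,
                distances = numeric(), n_frames_used = 0L))
  edges <- seq(0, ceiling(max(dists) / bin) * bin + bin, by = bin)
  h <- graphics::hist(dists, breaks = edges, plot = FALSE)
  dens <- h$counts / (sum(h$counts) * bin)
  list(mids = h$mids, density = dens,
       P_below = mean(dists < threshold), threshold = threshold,
       mode = h$mids[which.max(dens)], distances = dists,
       n_frames_used = used)
}
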