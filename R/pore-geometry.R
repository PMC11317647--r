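#' Pore radius profile of one frame (maximal inscribed sphere)
#'
#' HOLE-style algorithm, re-implemented: at each axial level z the radius
#' reported is that of the largest sphere centered in the plane through z
#' (perpendicular to the pore axis) that overlaps no atom, i.e. the
#' maximum over in-plane center positions of
#' \code{min_i(|c - x_i| - vdw_i)}, found by multi-start Nelder-Mead
#' within a search disc.  Levels are processed outward from the level
#' nearest the pore center, and each level's disc is centered on the
#' previous level's optimal sphere center -- the center-following used by
#' pore-profiling tools, which keeps the sphere inside the channel
#' instead of escaping through the pore mouth.  Radii are capped at
#' \code{max_radius}; levels with no atoms in capture range report the
#' cap and are flagged.  \code{search_radius = 0} pins the sphere center
#' to the (followed) axis point.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame frame index (default 1).
#' @param protein_selection selection for the pore-forming atoms (default
#'   all protein).
#' @param axis pore axis unit vector.
#' @param center pore center; default the center of geometry of
#'   \code{protein_selection} in this frame.
#' @param z_range,z_step axial grid relative to the center (Angstrom).
#' @param vdw_table named vector element -> vdW radius (Angstrom);
#'   defaults C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80.  Unknown
#'   elements fall back to 1.70 with a warning.
#' @param max_radius radius cap (Angstrom, default 10).
#' @param search_radius in-plane search disc radius around the followed
#'   center (Angstrom, default 2).
#' @param n_starts multi-start count (default 8, seeded).
#' @param seed RNG seed for the start points.
#' @return data.frame: \code{z}, \code{radius}, \code{capped}.
#' @export
radiusProfile <- function(traj, frame = 1,
                          protein_selection = "species protein",
                          axis = c(0, 0, 1), center = NULL,
                          z_range = c(-10, 10), z_step = 0.5,
                          vdw_table = NULL, max_radius = 10,
                          search_radius = 2, n_starts = 8, seed = 1) {
  sel <- selectAtoms(traj, protein_selection)
  if (!length(sel)) stop("protein selection is empty", call. = FALSE)
  vdw_table <- c(vdw_table, .vdw_defaults)
  vdw_table <- vdw_table[!duplicated(names(vdw_table))]
  axis <- axis / sqrt(sum(axis^2))
  pos <- traj@positions[[frame]][sel, , drop = FALSE]
  if (is.null(center)) center <- colMeans(pos)
  el <- toupper(traj@topology$element[sel])
  el[el == "NA"] <- "NA."
  vdw <- vdw_table[el]
  if (anyNA(vdw)) {
    warning("unknown elements in vdW table (",
            paste(unique(el[is.na(vdw)]), collapse = ", "),
            "); using 1.70 A", call. = FALSE)
    vdw[is.na(vdw)] <- 1.70
  }
  vdw <- unname(vdw)
  basis <- axisBasis(axis)
  d <- sweep(pos, 2, center)
  s <- drop(d %*% axis)
  uu <- drop(d %*% basis[, 1]); vv <- drop(d %*% basis[, 2])
  set.seed(as.integer(seed))
  zs <- seq(z_range[1], z_range[2], by = z_step)
  capture <- max_radius + max(vdw)
  jitter <- if (n_starts > 1)
    cbind(stats::runif(n_starts - 1, -1, 1),
          stats::runif(n_starts - 1, -1, 1)) * max(search_radius, 1e-6) /
      sqrt(2)
  else NULL
  level <- function(z, c0) {
    near <- abs(s - z) <= capture
    if (!any(near)) return(list(r = max_radius, capped = TRUE, c = c0))
    au <- uu[near]; av <- vv[near]; as_ <- s[near] - z; ar <- vdw[near]
    obj <- function(c2) {
      if (sqrt(sum((c2 - c0)^2)) > search_radius) return(-1e6)
      min(sqrt((au - c2[1])^2 + (av - c2[2])^2 + as_^2) - ar)
    }
    if (search_radius <= 0) {
      best <- obj(c0); copt <- c0
    } else {
      starts <- rbind(c0, sweep(jitter, 2, c0, "+"))
      fits <- apply(starts, 1, function(s0)
        stats::optim(s0, obj, control = list(fnscale = -1, reltol = 1e-10,
                                             maxit = 500)))
      vals <- vapply(fits, `[[`, 0, "value")
      best <- max(vals); copt <- fits[[which.max(vals)]]$par
    }
    r <- min(max(best, 0), max_radius)
    list(r = r, capped = r >= max_radius - 1e-9, c = copt)
  }
  nlev <- length(zs)
  rad <- numeric(nlev); cap <- logical(nlev)
  i0 <- which.min(abs(zs))            # start at the level nearest the center
  c_prev <- c(0, 0)
  for (i in i0:nlev) {
    lv <- level(zs[i], c_prev)
    rad[i] <- lv$r; cap[i] <- lv$capped; c_prev <- lv$c
  }
  if (i0 > 1) {
    c_prev <- c(0, 0)
    lv0 <- level(zs[i0], c_prev)      # re-anchor downward walk at the middle
    c_prev <- lv0$c
    for (i in (i0 - 1):1) {
      lv <- level(zs[i], c_prev)
      rad[i] <- lv$r; cap[i] <- lv$capped; c_prev <- lv$c
    }
  }
  data.frame(z = zs, radius = rad, capped = cap)
}

#' Mean pore radius profile over frames and repeats
#'
#' Computes per-frame profiles over a time window (optionally across
#' several repeat trajectories) and returns the mean and SD across all
#' contributing frames.
#'
#' @param trajs a \linkS4class{Trajectory} or list of them (repeats).
#' @param window frames to use: \code{NULL} (all), a numeric
#'   \code{c(tmin, tmax)} in ns, or a string \code{"last X\%"}.
#' @param stride frame stride.
#' @param ... passed to [radiusProfile()].
#' @return a \linkS4class{RadiusProfile}.
#' @export
meanRadiusProfile <- function(trajs, window = NULL, stride = 1, ...) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  profs <- list()
  for (tr in trajs) {
    idx <- seq(1, nFrames(tr), by = stride)
    tt <- frameTimes(tr)[idx]
    if (is.character(window)) {
      frac <- as.numeric(sub("last\\s+([0-9.]+)%", "\\1", window)) / 100
      if (is.na(frac)) stop("window string must look like 'last 60%'",
                            call. = FALSE)
      keep <- idx > (1 - frac) * nFrames(tr)
      idx <- idx[keep]
    } else if (is.numeric(window) && length(window) == 2) {
      idx <- idx[tt >= window[1] & tt <= window[2]]
    }
    for (i in idx) profs[[length(profs) + 1L]] <-
      radiusProfile(tr, frame = i, ...)
  }
  if (!length(profs)) stop("window selects no frames", call. = FALSE)
  R <- vapply(profs, function(p) p$radius, numeric(nrow(profs[[1]])))
  R <- matrix(R, nrow = nrow(profs[[1]]))
  sdv <- if (ncol(R) > 1) apply(R, 1, stats::sd) else rep(0, nrow(R))
  new("RadiusProfile", z = profs[[1]]$z, mean = rowMeans(R), sd = sdv,
      capped = Reduce(`|`, lapply(profs, function(p) p$capped)))
}

#' Minimum inter-selection distance time series
#'
#' Per frame, the minimum over all pairs (atom of a) x (atom of b) of
#' minimum-image distances.  By default only heavy atoms (element != H)
#' participate, matching how selectivity-filter separations are usually
#' reported; pass \code{heavy = FALSE} to keep hydrogens.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selection_a,selection_b selection expressions; must not select
#'   identical atom sets.
#' @param stride frame stride.
#' @param heavy drop hydrogens (default TRUE).
#' @param label series label; default built from the selections.
#' @param reference optional reference separation (Angstrom), e.g. the
#'   value in a cryo-EM structure.
#' @return data.frame \code{time}, \code{value} (Angstrom), with
#'   attributes \code{label} and \code{reference}.
#' @export
minPairDistance <- function(traj, selection_a, selection_b, stride = 1,
                            heavy = TRUE, label = NULL, reference = NULL) {
  a <- selectAtoms(traj, selection_a)
  b <- selectAtoms(traj, selection_b)
  if (heavy) {
    a <- a[toupper(traj@topology$element[a]) != "H"]
    b <- b[toupper(traj@topology$element[b]) != "H"]
  }
  if (!length(a) || !length(b))
    stop("empty selection for minimum pair distance", call. = FALSE)
  if (identical(sort(a), sort(b)))
    stop("selections are identical; minimum pair distance is degenerate",
         call. = FALSE)
  idx <- seq(1, nFrames(traj), by = stride)
  val <- vapply(idx, function(i) {
    pa <- traj@positions[[i]][a, , drop = FALSE]
    pb <- traj@positions[[i]][b, , drop = FALSE]
    box <- traj@box[i, ]
    min(vapply(seq_len(nrow(pa)), function(k)
      min(minImageDist(pa[k, ], pb, box)), 0))
  }, 0)
  structure(data.frame(time = traj@times[idx], value = val),
            label = if (is.null(label))
              paste(selection_a, "--", selection_b) else label,
            reference = reference)
}

#' Probability density of one or two distance series
#'
#' Normalized histogram (integrates to 1) of a distance series, or the
#' joint 2D density of two series; local maxima exceeding
#' \code{prominence} times the global maximum are reported as modes
#' (bimodality detection).
#'
#' @param d1 numeric vector of distances (Angstrom), or a data.frame with
#'   a \code{value} column (as returned by [minPairDistance()]).
#' @param d2 optional second series for a joint 2D density.
#' @param bin bin width (Angstrom, default 0.25).
#' @param prominence mode threshold as a fraction of the tallest peak.
#' @return list: \code{breaks}, \code{mids}, \code{density} (vector, or
#'   matrix for 2D), \code{modes} (1D only: mode locations, Angstrom),
#'   \code{n_modes}.
#' @export
distanceDistribution <- function(d1, d2 = NULL, bin = 0.25,
                                 prominence = 0.05) {
  getv <- function(d) if (is.data.frame(d)) d$value else d
  x <- getv(d1)
  brk <- function(v) seq(floor(min(v) / bin) * bin,
                         ceiling(max(v) / bin) * bin + bin / 2, by = bin)
  if (is.null(d2)) {
    bx <- brk(x)
    h <- graphics::hist(x, breaks = bx, plot = FALSE)
    dens <- h$counts / (sum(h$counts) * bin)
    dmax <- max(dens)
    is_mode <- vapply(seq_along(dens), function(i) {
      l <- if (i > 1) dens[i - 1] else -Inf
      r <- if (i < length(dens)) dens[i + 1] else -Inf
      dens[i] >= l && dens[i] >= r && dens[i] > prominence * dmax &&
        (dens[i] > l || dens[i] > r)
    }, TRUE)
    list(breaks = bx, mids = h$mids, density = dens,
         modes = h$mids[is_mode], n_modes = sum(is_mode))
  } else {
    y <- getv(d2)
    bx <- brk(x); by <- brk(y)
    cx <- cut(x, bx, include.lowest = TRUE)
    cy <- cut(y, by, include.lowest = TRUE)
    cnt <- table(cx, cy)
    dens <- unclass(cnt) / (sum(cnt) * bin * bin)
    list(breaks = list(x = bx, y = by),
         mids = list(x = bx[-length(bx)] + bin / 2,
                     y = by[-length(by)] + bin / 2),
         density = dens, modes = NULL, n_modes = NA_integer_)
  }
}
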