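#' Synthetic drift-diffusion ion trajectory with planted crossings
#'
#' Generates a periodic-box trajectory emulating applied-field permeation
#' MD: a static ring of "protein" atoms (resname POR) anchors the pore
#' center; ions undergo overdamped Langevin dynamics (Euler-Maruyama,
#' Gaussian noise of variance \code{2 D dt} per axis per step) with a
#' drift applied only inside the pore cylinder, directed from the luminal
#' to the cytosolic side; waters diffuse freely.  Optionally,
#' \code{planted_crossings} ions follow deterministic straight-line paths
#' from beyond the selectivity-filter plane, through the cylinder, past
#' the gate plane, so the exact number of full luminal-to-cytosolic
#' crossings is known by construction.  All positions are wrapped into the
#' primary box before storage, as conventional MD output is.
#'
#' With \code{diffusion = 0} the detected event count equals
#' \code{planted_crossings} exactly.
#'
#' @param n_ions number of permeant ions.
#' @param n_waters number of water oxygens.
#' @param box box lengths (Angstrom).
#' @param pore a \linkS4class{PoreSpec}; default anchors on
#'   \code{"resname POR"} with zSF = +12, zGate = -12, radius 6.
#' @param drift drift speed inside the cylinder (Angstrom/ns, toward the
#'   cytosolic side).
#' @param diffusion diffusion coefficient (Angstrom^2/ns).
#' @param n_frames,dt frame count and spacing (ns).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param planted_crossings number of deterministic crossers (<= n_ions).
#' @param ion_resname "NA" (Na+) or "CA" (Ca2+) etc.
#' @return list with elements \code{trajectory} (a
#'   \linkS4class{Trajectory}), \code{pore} (the PoreSpec used) and
#'   \code{truth} (list: \code{planted_crossings}, \code{crosser_atoms} --
#'   topology indices of the deterministic crossers).
#' @export
generateDriftTrajectory <- function(n_ions = 10, n_waters = 50,
                                    box = c(40, 40, 80),
                                    pore = poreSpec(centerSelection = "resname POR",
                                                    zSF = 12, zGate = -12),
                                    drift = 20, diffusion = 5,
                                    n_frames = 100, dt = 0.1, seed,
                                    planted_crossings = 0,
                                    ion_resname = "NA") {
  stopifnot(dt > 0, diffusion >= 0, planted_crossings <= n_ions,
            n_frames >= 2)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  axis <- pore@axis
  center <- box / 2
  basis <- axisBasis(axis)

  ## static anchor atoms: two rings of 4, symmetric about the center
  ring <- function(z, rad, n, phase = 0) {
    ang <- phase + 2 * pi * (seq_len(n) - 1) / n
    sweep(outer(rad * cos(ang), basis[, 1]) + outer(rad * sin(ang), basis[, 2]) +
            outer(rep(z, n), axis), 2, center, "+")
  }
  prot <- rbind(ring(-5, 9, 4), ring(5, 9, 4))
  np <- nrow(prot)

  topo <- data.frame(
    name = c(rep("POR", np), rep(toupper(ion_resname), n_ions),
             rep("OW", n_waters)),
    resname = c(rep("POR", np), rep(toupper(ion_resname), n_ions),
                rep("SOL", n_waters)),
    resid = c(rep(1L, np), seq_len(n_ions) + 1L,
              seq_len(n_waters) + n_ions + 1L),
    chain = "A", stringsAsFactors = FALSE)
  topo$element <- guessElement(topo$name)
  topo$species <- assignSpecies(topo)

  sgn <- pore@luminalSide
  s_lum <- pore@zSF + 6 * sgn   # luminal bulk (axial coordinate)
  s_cyt <- pore@zGate - 6 * sgn # cytosolic bulk
  n_mobile <- n_ions + n_waters
  ## initial positions: uniform, but keep free ions out of the pore region
  init <- matrix(stats::runif(3 * n_mobile), ncol = 3) %*% diag(box)
  ar0 <- axialRadial(init, center, axis, box)
  inpore <- ar0$r < pore@cylinderRadius + 2 &
    sgn * (ar0$s - pore@zSF) <= 2 & sgn * (ar0$s - pore@zGate) >= -2
  init[inpore, ] <- sweep(matrix(stats::rnorm(3 * sum(inpore), 0, 2),
                                 ncol = 3), 2,
                          center + (pore@zSF + 10 * sgn) * axis, "+")

  crossers <- seq_len(planted_crossings)
  if (planted_crossings) {
    ang <- 2 * pi * (crossers - 1) / max(planted_crossings, 1)
    off <- outer(cos(ang), basis[, 1]) + outer(sin(ang), basis[, 2])
    init[crossers, ] <- sweep(off, 2, center + s_lum * axis, "+")
  }

  positions <- vector("list", n_frames)
  pos <- init
  total_t <- (n_frames - 1) * dt
  for (f in seq_len(n_frames)) {
    t <- (f - 1) * dt
    if (planted_crossings) {
      s_t <- s_lum + (s_cyt - s_lum) * t / total_t
      pos[crossers, ] <- sweep(off, 2, center + s_t * axis, "+")
    }
    positions[[f]] <- rbind(prot, wrapPositions(pos, box))
    ## advance mobile atoms (free ions + waters) for the next frame
    free <- setdiff(seq_len(n_mobile), crossers)
    if (length(free)) {
      step <- matrix(stats::rnorm(3 * length(free), 0,
                                  sqrt(2 * diffusion * dt)), ncol = 3)
      freeion <- free[free <= n_ions]
      if (length(freeion) && drift != 0) {
        ar <- axialRadial(pos[freeion, , drop = FALSE], center, axis, box)
        inside <- ar$r <= pore@cylinderRadius &
          sgn * (ar$s - pore@zSF) <= 2 & sgn * (ar$s - pore@zGate) >= -2
        di <- match(freeion[inside], free)
        if (length(di))
          step[di, ] <- step[di, ] - drift * dt * sgn *
            matrix(axis, length(di), 3, byrow = TRUE)
      }
      pos[free, ] <- pos[free, ] + step
    }
  }
  traj <- makeTrajectory(topo, positions, (seq_len(n_frames) - 1) * dt, box)
  list(trajectory = traj, pore = pore,
       truth = list(planted_crossings = planted_crossings,
                    crosser_atoms = if (planted_crossings) np + crossers
                                    else integer()))
}

## ---- analytic 1D free-energy surfaces -------------------------------------

#' Analytic 1D free-energy surfaces for umbrella-sampling oracles
#'
#' Constructors for known potentials U(xi) (kcal/mol) on a finite domain,
#' used as ground truth for the WHAM solver:
#' \itemize{
#'   \item \code{pmfFlat(domain)}: U = 0 (Boltzmann density uniform).
#'   \item \code{pmfHarmonic(k0, xi0, domain)}: U = k0/2 (xi - xi0)^2.
#'   \item \code{pmfDoubleWell(barrier, width, domain)}: two flat wells
#'     separated by a Gaussian barrier at xi = 0,
#'     U = barrier * exp(-xi^2 / (2 width^2)).  A quartic double well is
#'     astronomically steep over a wide channel-like domain and would
#'     destroy window overlap, so this bounded form is used for the
#'     channel-scale oracle.
#'   \item \code{pmfTabulated(xi, U)}: cubic-spline interpolation of a
#'     tabulated curve.
#' }
#'
#' @param domain c(min, max) in Angstrom.
#' @param temperature K.
#' @param k0 harmonic constant (kcal/mol/A^2); \code{xi0} its center.
#' @param barrier barrier height (kcal/mol); \code{width} Gaussian sigma (A).
#' @param xi,U tabulated curve (Angstrom, kcal/mol).
#' @return an object of class \code{"PMFSpec"}: list with \code{fun},
#'   \code{domain}, \code{temperature}, \code{type}.
#' @name pmfSpecs
NULL

.pmf_spec <- function(type, fun, domain, temperature) {
  stopifnot(length(domain) == 2, domain[1] < domain[2],
            all(is.finite(fun(seq(domain[1], domain[2], length.out = 101)))))
  structure(list(type = type, fun = fun, domain = domain,
                 temperature = temperature), class = "PMFSpec")
}

#' @rdname pmfSpecs
#' @export
pmfFlat <- function(domain = c(-5, 5), temperature = 310)
  .pmf_spec("flat", function(xi) rep(0, length(xi)), domain, temperature)

#' @rdname pmfSpecs
#' @export
pmfHarmonic <- function(k0 = 1, xi0 = 0, domain = c(-6, 6), temperature = 310)
  .pmf_spec("harmonic", function(xi) 0.5 * k0 * (xi - xi0)^2, domain,
            temperature)

#' @rdname pmfSpecs
#' @export
pmfDoubleWell <- function(barrier = 8, width = 3, domain = c(-35, 22),
                          temperature = 310)
  .pmf_spec("double-well",
            function(xi) barrier * exp(-xi^2 / (2 * width^2)),
            domain, temperature)

#' @rdname pmfSpecs
#' @export
pmfTabulated <- function(xi, U, temperature = 310) {
  f <- stats::splinefun(xi, U, method = "natural")
  .pmf_spec("tabulated", f, range(xi), temperature)
}

#' Draw biased samples from an analytic free-energy surface
#'
#' For each window center xi0 with harmonic force constant k
#' (kcal mol-1 A-2), samples are drawn from the Boltzmann density
#' proportional to \code{exp(-(U(xi) + k/2 (xi - xi0)^2) / kBT)} by
#' Metropolis Monte Carlo.  The proposal step is auto-tuned to 30-50\%
#' acceptance during burn-in; proposals outside the domain are rejected.
#' Fully reproducible under a fixed seed.
#'
#' @param pmf a \code{"PMFSpec"} (see [pmfSpecs]).
#' @param centers window centers xi0 (Angstrom); must be non-empty.
#' @param k force constant(s), kcal mol-1 A-2; scalar or one per window
#'   (0 = unbiased).
#' @param n_samples samples kept per window.
#' @param seed RNG seed.
#' @param burnin,thin Metropolis burn-in sweeps and thinning stride.
#' @return list of \linkS4class{UmbrellaWindow}.
#' @export
sampleUmbrellaWindows <- function(pmf, centers, k, n_samples = 5000, seed,
                                  burnin = 1000, thin = 5) {
  if (!length(centers)) stop("centers must be non-empty", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(inherits(pmf, "PMFSpec"), all(k >= 0), n_samples > 0)
  set.seed(as.integer(seed))
  nw <- length(centers)
  k <- rep_len(k, nw)
  kT <- permConstants$kB * pmf$temperature
  lo <- pmf$domain[1]; hi <- pmf$domain[2]
  utot <- function(x) pmf$fun(x) + 0.5 * k * (x - centers)^2
  x <- pmin(pmax(centers, lo), hi)
  u <- utot(x)
  step <- rep(1, nw)
  acc_n <- rep(0, nw); try_n <- rep(0, nw)
  do_sweep <- function() {
    prop <- x + step * stats::runif(nw, -1, 1)
    ok <- prop >= lo & prop <= hi
    up <- u
    up[ok] <- utot(prop)[ok]
    acc <- ok & (stats::runif(nw) < exp(-(up - u) / kT))
    x[acc] <<- prop[acc]; u[acc] <<- up[acc]
    try_n <<- try_n + 1; acc_n <<- acc_n + acc
  }
  for (b in seq_len(burnin)) {
    do_sweep()
    if (b %% 50 == 0) {
      rate <- acc_n / try_n
      step[rate > 0.5] <- step[rate > 0.5] * 1.3
      step[rate < 0.3] <- pmax(step[rate < 0.3] * 0.7, 1e-3)
      acc_n[] <- 0; try_n[] <- 0
    }
  }
  out <- matrix(0, n_samples, nw)
  for (s in seq_len(n_samples)) {
    for (tt in seq_len(thin)) do_sweep()
    out[s, ] <- x
  }
  lapply(seq_len(nw), function(i)
    new("UmbrellaWindow", center = centers[i], k = k[i],
        samples = out[, i], times = numeric(),
        meta = list(seed = seed, pmf_type = pmf$type,
                    temperature = pmf$temperature)))
}

#' Build a toy pore with an analytically known radius profile
#'
#' Places rings of \code{n_per_ring} atoms of van der Waals radius
#' \code{atom_radius} on circles of radius \code{R(z) + atom_radius} at
#' each z level, so the maximal inscribed sphere on the axis has radius
#' exactly \code{R(z)} (valid for \code{n_per_ring >= 6} and ring spacing
#' \code{<= atom_radius}).
#'
#' Where the requested profile varies along z, a sphere at level z can
#' also touch rings at neighbouring levels, so the exact on-axis
#' maximal-inscribed-sphere radius of the constructed arrangement is
#' \code{min over levels z' of sqrt((R(z') + a)^2 + (z - z')^2) - a}
#' (equal to R(z) wherever the profile is flat or gently varying); the
#' ground-truth record reports both this exact value (\code{radius}) and
#' the requested \code{radius_requested}.
#'
#' @param radius_profile function z -> R(z) (Angstrom); must be > 0.
#' @param atom_radius atom vdW radius (Angstrom).
#' @param n_per_ring atoms per ring; with fewer than ~16 per ring a
#'   sphere can bulge slightly between atoms of a narrow ring.
#' @param z_range c(min, max) of ring levels (Angstrom, relative to the
#'   pore center).
#' @param spacing ring spacing (Angstrom).
#' @return list: \code{trajectory} (single-frame
#'   \linkS4class{Trajectory}; toy atoms have element "X"),
#'   \code{vdw_table} (named vector mapping "X" to \code{atom_radius}),
#'   \code{truth} (data.frame z, radius, radius_requested),
#'   \code{center} (pore center in box coordinates).
#' @export
buildToyPore <- function(radius_profile, atom_radius = 1.5, n_per_ring = 16,
                         z_range = c(-10, 10), spacing = 1) {
  zs <- seq(z_range[1], z_range[2], by = spacing)
  R <- radius_profile(zs)
  if (any(!is.finite(R)) || any(R <= 0))
    stop("radius profile must be positive and finite over z_range",
         call. = FALSE)
  maxr <- max(R) + atom_radius
  box <- c(2 * maxr + 20, 2 * maxr + 20, diff(z_range) + 20)
  center <- box / 2
  coords <- do.call(rbind, lapply(seq_along(zs), function(i) {
    ang <- 2 * pi * (seq_len(n_per_ring) - 1) / n_per_ring +
      (i %% 2) * pi / n_per_ring
    cbind(center[1] + (R[i] + atom_radius) * cos(ang),
          center[2] + (R[i] + atom_radius) * sin(ang),
          center[3] + zs[i])
  }))
  n <- nrow(coords)
  topo <- data.frame(name = "X", resname = "POR",
                     resid = rep(seq_along(zs), each = n_per_ring),
                     chain = "A", element = "X", species = "protein",
                     stringsAsFactors = FALSE)
  traj <- makeTrajectory(topo, list(coords), 0, box)
  ## exact on-axis inscribed radius, accounting for neighbouring rings
  exact <- vapply(zs, function(z)
    min(sqrt((R + atom_radius)^2 + (z - zs)^2)) - atom_radius, 0)
  list(trajectory = traj, vdw_table = c(X = atom_radius),
       truth = data.frame(z = zs, radius = exact, radius_requested = R),
       center = center)
}

#' Build a single frame of an ion with waters at exact distances
#'
#' Water oxygens are placed at the requested distances from the ion in
#' random (seeded) directions, rejecting placements that put two waters
#' closer than 2 Angstrom to each other.  An oracle for coordination
#' counting.
#'
#' @param ion_position 3-vector (Angstrom); default box center.
#' @param water_distances distances (Angstrom).
#' @param seed RNG seed.
#' @param box box lengths (Angstrom).
#' @param ion_resname ion residue name (default "NA").
#' @return single-frame \linkS4class{Trajectory} (ion first, then waters).
#' @export
buildHydrationFrame <- function(water_distances, ion_position = NULL,
                                seed, box = c(60, 60, 60),
                                ion_resname = "NA") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(ion_position)) ion_position <- box / 2
  nw <- length(water_distances)
  placed <- matrix(0, 0, 3)
  for (d in water_distances) {
    repeat {
      v <- stats::rnorm(3)
      p <- ion_position + d * v / sqrt(sum(v^2))
      if (!nrow(placed) ||
          min(sqrt(rowSums(sweep(placed, 2, p)^2))) >= 2) break
    }
    placed <- rbind(placed, p)
  }
  topo <- data.frame(
    name = c(toupper(ion_resname), rep("OW", nw)),
    resname = c(toupper(ion_resname), rep("SOL", nw)),
    resid = seq_len(nw + 1), chain = "A", stringsAsFactors = FALSE)
  topo$element <- guessElement(topo$name)
  topo$species <- assignSpecies(topo)
  makeTrajectory(topo, list(rbind(ion_position, placed)), 0, box)
}
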