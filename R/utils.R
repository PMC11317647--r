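#' Construct a PoreSpec
#'
#' @param axis unit 3-vector of the pore axis (default +z).
#' @param centerSelection selection expression for the pore-forming atoms
#'   whose per-frame center of geometry anchors the cylinder.
#' @param cylinderRadius cylinder radius (Angstrom, default 6).
#' @param zSF,zGate axial planes of the selectivity filter and the
#'   cytosolic gate, relative to the pore center (Angstrom).
#' @param luminalSide +1 if the lumen lies at larger axial coordinate.
#' @return a \linkS4class{PoreSpec}.
#' @examples
#' poreSpec(zSF = 10, zGate = -10, centerSelection = "resname POR")
#' @export
poreSpec <- function(axis = c(0, 0, 1), centerSelection = "species protein",
                     cylinderRadius = 6, zSF = 12, zGate = -12,
                     luminalSide = 1) {
  a <- axis / sqrt(sum(axis^2))
  new("PoreSpec", axis = a, centerSelection = centerSelection,
      cylinderRadius = cylinderRadius, zGate = zGate, zSF = zSF,
      luminalSide = luminalSide)
}

#' Construct AnalysisParams
#'
#' @param coordinationCutoff water-coordination cutoff (Angstrom, 4.5).
#' @param proximityThreshold knock-on proximity threshold (Angstrom, 7).
#' @param densityGridSpacing density voxel edge (Angstrom, 1).
#' @param histogramBin generic histogram bin (Angstrom, 0.25).
#' @param temperature simulation temperature (K, 310).
#' @return an \linkS4class{AnalysisParams}.
#' @export
analysisParams <- function(coordinationCutoff = 4.5, proximityThreshold = 7,
                           densityGridSpacing = 1, histogramBin = 0.25,
                           temperature = 310) {
  new("AnalysisParams", coordinationCutoff = coordinationCutoff,
      proximityThreshold = proximityThreshold,
      densityGridSpacing = densityGridSpacing, histogramBin = histogramBin,
      temperature = temperature)
}

#' Build a Trajectory from components
#'
#' Low-level constructor used by the readers and the synthetic generators.
#'
#' @param topology per-atom data.frame with columns name, element, resname,
#'   resid, chain, species (missing columns are filled with defaults).
#' @param positions list of n_atoms x 3 matrices (Angstrom).
#' @param times frame times (ns).
#' @param box one row of box lengths per frame, or a single 3-vector
#'   recycled to all frames (Angstrom).
#' @return a \linkS4class{Trajectory}.
#' @export
makeTrajectory <- function(topology, positions, times, box) {
  if (is.null(topology$element))
    topology$element <- guessElement(topology$name)
  if (is.null(topology$chain)) topology$chain <- "A"
  if (is.null(topology$species))
    topology$species <- assignSpecies(topology)
  if (!is.matrix(box)) box <- matrix(box, nrow = length(positions),
                                     ncol = 3, byrow = TRUE)
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p); dimnames(p) <- NULL; storage.mode(p) <- "double"; p
  })
  new("Trajectory", topology = as.data.frame(topology, stringsAsFactors = FALSE),
      positions = positions, times = as.numeric(times), box = box)
}

#' Guess the element from an atom name
#'
#' PDB-style heuristic: strip digits, ion names map to themselves (NA, CL,
#' CA as residue-context ions are handled by [assignSpecies()]), otherwise
#' the first letter.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
guessElement <- function(name) {
  up <- toupper(gsub("[0-9'\"]", "", name))
  two <- c("NA", "CL", "MG", "FE", "ZN", "BR", "MN", "CU")
  ifelse(up %in% two, up, substr(up, 1, 1))
}

#' Assign species tags from residue/atom-name rules
#'
#' Default rules: water residues (SOL, TIP3, TIP3P, HOH, WAT, SPC) are
#' water-oxygen when the atom name is OW/OH2/O, water-other otherwise;
#' NA/SOD/K/POT/CA/CAL/MG ions are cations; CL/CLA are anions; standard
#' amino-acid residues are protein; everything else is "other" (with a
#' warning giving the count).
#'
#' @param topology data.frame with name and resname columns.
#' @param rules optional named list overriding any of \code{water_res},
#'   \code{water_o_names}, \code{cation_res}, \code{anion_res},
#'   \code{protein_res}.
#' @return character vector of species tags.
#' @export
assignSpecies <- function(topology, rules = list()) {
  r <- utils::modifyList(list(
    water_res     = c("SOL", "TIP3", "TIP3P", "HOH", "WAT", "SPC"),
    water_o_names = c("OW", "OH2", "O"),
    cation_res    = c("NA", "SOD", "K", "POT", "CA", "CAL", "MG"),
    anion_res     = c("CL", "CLA"),
    protein_res   = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                      "GLY", "HIS", "HSD", "HSE", "ILE", "LEU", "LYS",
                      "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
                      "VAL", "POR")
  ), rules)
  rn <- toupper(topology$resname)
  an <- toupper(topology$name)
  sp <- rep("other", nrow(topology))
  w <- rn %in% r$water_res
  sp[w] <- ifelse(an[w] %in% r$water_o_names, "water-oxygen", "water-other")
  sp[rn %in% r$cation_res] <- "cation"
  sp[rn %in% r$anion_res] <- "anion"
  sp[rn %in% r$protein_res] <- "protein"
  n_other <- sum(sp == "other")
  if (n_other)
    warning(sprintf("%d atoms not matched by species rules; tagged 'other'",
                    n_other), call. = FALSE)
  sp
}

#' Formal charge of an ion atom
#'
#' Looks up the formal charge (units of e) from residue or atom name:
#' Na/SOD/K/POT +1, Ca/CAL/Mg +2, Cl/CLA -1.
#'
#' @param resname,name character vectors.
#' @return numeric charges; NA when unknown.
#' @export
ionCharge <- function(resname, name = resname) {
  key <- toupper(resname)
  key[key == "NA"] <- "NA."
  z <- .ion_charges[key]
  alt <- toupper(name); alt[alt == "NA"] <- "NA."
  z[is.na(z)] <- .ion_charges[alt[is.na(z)]]
  unname(z)
}

# minimum-image displacement of an n x 3 matrix under orthorhombic box
minImage <- function(d, box) {
  if (is.null(dim(d))) d <- matrix(d, ncol = 3)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# minimum-image distances from one point to rows of a matrix
minImageDist <- function(p, mat, box) {
  d <- minImage(sweep(mat, 2, p), box)
  sqrt(rowSums(d * d))
}

# center of geometry of selected atoms in frame i, robust to the selection
# straddling a periodic boundary (per-dimension circular mean)
poreCenter <- function(traj, sel, i) {
  p <- traj@positions[[i]][sel, , drop = FALSE]
  box <- traj@box[i, ]
  vapply(1:3, function(k) {
    th <- 2 * pi * p[, k] / box[k]
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    (ang %% (2 * pi)) * box[k] / (2 * pi)
  }, 0)
}

# orthonormal basis completing a unit axis
axisBasis <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  cbind(u, v)
}

# axial (s) and radial (r) coordinates of atoms relative to a pore center,
# minimum-imaged; rows of pos
axialRadial <- function(pos, center, axis, box) {
  d <- minImage(sweep(pos, 2, center), box)
  s <- drop(d %*% axis)
  perp <- d - outer(s, axis)
  r <- sqrt(rowSums(perp * perp))
  list(s = s, r = r)
}

# wrap absolute positions into [0, L) per dimension
wrapPositions <- function(pos, box) {
  for (k in 1:3) pos[, k] <- pos[, k] %% box[k]
  pos
}

#' Write a data.frame to CSV with a JSON metadata sidecar
#'
#' Every tabular output of the package carries a `<file>.meta.json` sidecar
#' recording the package version, parameters, and the seed, so results are
#' traceable.
#'
#' @param df data.frame.
#' @param path output CSV path.
#' @param meta named list of run metadata.
#' @return invisibly, the sidecar path.
#' @export
writeCSVWithMeta <- function(df, path, meta = list()) {
  utils::write.csv(df, path, row.names = FALSE)
  meta$version <- as.character(utils::packageVersion("poreperm"))
  meta$written <- "poreperm"
  side <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}
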