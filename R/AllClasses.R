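#' Trajectory: frames of labelled atom positions in a periodic box
#'
#' The universal input of every analysis in this package.  Atom metadata
#' lives in the \code{topology} data.frame (one row per atom: \code{name},
#' \code{element}, \code{resname}, \code{resid}, \code{chain},
#' \code{species}); coordinates live in \code{positions}, a list with one
#' numeric \code{n_atoms x 3} matrix per frame (Angstrom).  Box lengths are
#' orthorhombic, one row per frame (Angstrom).  Times are in ns and must
#' strictly increase.
#'
#' Species tags are one of \code{"protein"}, \code{"water-oxygen"},
#' \code{"water-other"}, \code{"cation"}, \code{"anion"}, \code{"other"}.
#'
#' @slot topology data.frame of per-atom records.
#' @slot positions list of n_atoms x 3 matrices (Angstrom), one per frame.
#' @slot times numeric vector of frame times (ns), strictly increasing.
#' @slot box numeric n_frames x 3 matrix of box lengths (Angstrom).
#'
#' @seealso [readTrajectory()], [generateDriftTrajectory()]
#' @export
setClass("Trajectory",
  representation(
    topology  = "data.frame",
    positions = "list",
    times     = "numeric",
    box       = "matrix"
  )
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  need <- c("name", "element", "resname", "resid", "chain", "species")
  miss <- setdiff(need, names(object@topology))
  if (length(miss))
    msgs <- c(msgs, paste("topology lacks columns:", paste(miss, collapse = ", ")))
  na <- nrow(object@topology)
  nf <- length(object@positions)
  if (length(object@times) != nf)
    msgs <- c(msgs, "length(times) must equal number of frames")
  if (nf && nrow(object@box) != nf)
    msgs <- c(msgs, "box must have one row per frame")
  if (nf && ncol(object@box) != 3)
    msgs <- c(msgs, "box must have 3 columns")
  bad_n <- which(vapply(object@positions, nrow, 0L) != na)
  if (length(bad_n))
    msgs <- c(msgs, sprintf("frame %d has %d atoms; topology has %d",
                            bad_n[1], nrow(object@positions[[bad_n[1]]]), na))
  if (nf > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "frame times must strictly increase")
  if (nf && any(object@box <= 0))
    msgs <- c(msgs, "box lengths must be > 0")
  if (nf && !all(vapply(object@positions, function(p) all(is.finite(p)), TRUE)))
    msgs <- c(msgs, "positions must be finite")
  if (na && !all(object@topology$species %in% .species_levels))
    msgs <- c(msgs, "unknown species tag in topology")
  if (length(msgs)) msgs else TRUE
})

#' PoreSpec: the geometric contract shared by all permeation analyses
#'
#' Defines the pore cylinder used for permeation counting: its axis
#' (a unit vector, default +z), the selection expression whose per-frame
#' center of geometry anchors the cylinder, the cylinder radius (default
#' 6 Angstrom), and the two axial planes bounding the pore: the
#' selectivity filter at \code{zSF} and the cytosolic gate at \code{zGate}
#' (both relative to the pore center along the axis).  \code{luminalSide}
#' is +1 when the lumen lies at larger axial coordinate.
#'
#' @slot axis unit 3-vector.
#' @slot centerSelection selection expression (see [selectAtoms()]).
#' @slot cylinderRadius numeric, Angstrom.
#' @slot zGate,zSF numeric planes (Angstrom, relative to center).
#' @slot luminalSide +1 or -1.
#' @export
setClass("PoreSpec",
  representation(
    axis           = "numeric",
    centerSelection = "character",
    cylinderRadius = "numeric",
    zGate          = "numeric",
    zSF            = "numeric",
    luminalSide    = "numeric"
  ),
  prototype(
    axis = c(0, 0, 1), centerSelection = "species protein",
    cylinderRadius = 6, zGate = -12, zSF = 12, luminalSide = 1
  )
)

setValidity("PoreSpec", function(object) {
  msgs <- character()
  if (length(object@axis) != 3 || abs(sqrt(sum(object@axis^2)) - 1) > 1e-6)
    msgs <- c(msgs, "axis must be a unit 3-vector")
  if (object@cylinderRadius <= 0)
    msgs <- c(msgs, "cylinderRadius must be > 0")
  if (object@zGate == object@zSF)
    msgs <- c(msgs, "zGate must differ from zSF")
  if (!object@luminalSide %in% c(-1, 1))
    msgs <- c(msgs, "luminalSide must be +1 or -1")
  if (length(msgs)) msgs else TRUE
})

#' AnalysisParams: shared numerical parameters
#'
#' Defaults follow the conventions used throughout: water coordination
#' cutoff 4.5 Angstrom, knock-on proximity threshold 7 Angstrom, density
#' grid spacing 1 Angstrom, histogram bin 0.25 Angstrom, temperature 310 K.
#'
#' @slot coordinationCutoff,proximityThreshold,densityGridSpacing,histogramBin,temperature numeric, all > 0.
#' @export
setClass("AnalysisParams",
  representation(
    coordinationCutoff = "numeric",
    proximityThreshold = "numeric",
    densityGridSpacing = "numeric",
    histogramBin       = "numeric",
    temperature        = "numeric"
  ),
  prototype(coordinationCutoff = 4.5, proximityThreshold = 7,
            densityGridSpacing = 1, histogramBin = 0.25, temperature = 310)
)

setValidity("AnalysisParams", function(object) {
  v <- c(object@coordinationCutoff, object@proximityThreshold,
         object@densityGridSpacing, object@histogramBin, object@temperature)
  if (any(!is.finite(v)) || any(v <= 0)) "all parameters must be strictly positive"
  else TRUE
})

#' RadiusProfile: mean pore radius along the channel axis
#'
#' @slot z axial grid (Angstrom, relative to the pore center), increasing.
#' @slot mean mean radius per level (Angstrom).
#' @slot sd standard deviation across frames/repeats (Angstrom).
#' @slot capped logical, TRUE where the search hit the radius cap.
#' @export
setClass("RadiusProfile",
  representation(z = "numeric", mean = "numeric", sd = "numeric",
                 capped = "logical"))

setValidity("RadiusProfile", function(object) {
  msgs <- character()
  n <- length(object@z)
  if (length(object@mean) != n || length(object@sd) != n ||
      length(object@capped) != n)
    msgs <- c(msgs, "z, mean, sd, capped must have equal length")
  if (n > 1 && any(diff(object@z) <= 0))
    msgs <- c(msgs, "z grid must strictly increase")
  if (any(object@mean < 0)) msgs <- c(msgs, "radius must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' DensityGrid: a 3D occupancy histogram of one species over a trajectory
#'
#' Voxel counts accumulate the number of (frame, atom) pairs whose position
#' falls in each voxel; \code{density} (ions per cubic Angstrom) is
#' \code{counts / (nFrames * spacing^3)}.  Atoms outside the grid bounds
#' are tallied in \code{overflow}.
#'
#' @slot origin numeric 3-vector (Angstrom).
#' @slot spacing numeric voxel edge (Angstrom).
#' @slot counts 3D array of non-negative counts.
#' @slot species character tag.
#' @slot nFrames integer.
#' @slot overflow numeric, atoms outside bounds (frame-atom pairs).
#' @export
setClass("DensityGrid",
  representation(origin = "numeric", spacing = "numeric", counts = "array",
                 species = "character", nFrames = "integer",
                 overflow = "numeric"))

setValidity("DensityGrid", function(object) {
  msgs <- character()
  if (length(object@origin) != 3) msgs <- c(msgs, "origin must be a 3-vector")
  if (object@spacing <= 0) msgs <- c(msgs, "spacing must be > 0")
  if (length(dim(object@counts)) != 3) msgs <- c(msgs, "counts must be 3D")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' UmbrellaWindow: biased reaction-coordinate samples from one window
#'
#' Holds the samples of the reaction coordinate xi (Angstrom) collected
#' under a harmonic bias of force constant \code{k} (kcal mol-1 A-2;
#' convert from kJ mol-1 nm-2 with
#' \code{permConstants$kJnm2_to_kcalA2}) centered at \code{center}.
#' \code{times} (ns) may be empty when the source carries no time column.
#'
#' @slot center numeric, bias center xi0 (Angstrom).
#' @slot k numeric, force constant (kcal mol-1 A-2); 0 means unbiased.
#' @slot samples numeric vector of xi values (Angstrom).
#' @slot times numeric vector (ns), same length as samples or empty.
#' @slot meta list of source metadata.
#' @export
setClass("UmbrellaWindow",
  representation(center = "numeric", k = "numeric", samples = "numeric",
                 times = "numeric", meta = "list"),
  prototype(times = numeric(), meta = list()))

setValidity("UmbrellaWindow", function(object) {
  msgs <- character()
  if (object@k < 0) msgs <- c(msgs, "k must be >= 0")
  if (!length(object@samples)) msgs <- c(msgs, "samples must be non-empty")
  if (length(object@times) && length(object@times) != length(object@samples))
    msgs <- c(msgs, "times must match samples in length (or be empty)")
  if (length(msgs)) msgs else TRUE
})

#' PMFProfile: a reconstructed potential of mean force
#'
#' Free energy W(xi) in kcal/mol on a xi grid (Angstrom), shifted so the
#' minimum over the grid is zero ("minimum-zero" convention) unless a bulk
#' reference was requested.  \code{err} holds per-bin bootstrap SDs (zero
#' when no bootstrap was run).
#'
#' @slot xi numeric grid (Angstrom), bin centers, increasing.
#' @slot W numeric free energy (kcal/mol).
#' @slot err numeric bootstrap SD (kcal/mol), >= 0.
#' @slot zero character, zero convention used ("min" or "bulk").
#' @slot meta list (iterations, residual, temperature, bin width ...).
#' @export
setClass("PMFProfile",
  representation(xi = "numeric", W = "numeric", err = "numeric",
                 zero = "character", meta = "list"),
  prototype(zero = "min", meta = list()))

setValidity("PMFProfile", function(object) {
  msgs <- character()
  n <- length(object@xi)
  if (length(object@W) != n || length(object@err) != n)
    msgs <- c(msgs, "xi, W, err must have equal length")
  if (n > 1 && any(diff(object@xi) <= 0))
    msgs <- c(msgs, "xi grid must strictly increase")
  if (any(object@err < 0)) msgs <- c(msgs, "errors must be >= 0")
  if (identical(object@zero, "min") && n &&
      abs(min(object@W)) > 1e-8)
    msgs <- c(msgs, "minimum-zero convention violated")
  if (length(msgs)) msgs else TRUE
})
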