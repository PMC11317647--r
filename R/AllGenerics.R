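#' @title Accessors for poreperm classes
#' @description Generic accessors: number of frames and atoms, frame times,
#'   per-frame positions, box lengths, topology table.
#' @param x a \linkS4class{Trajectory} (or other poreperm object).
#' @param i frame index (for \code{framePositions}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("framePositions", function(x, i) standardGeneric("framePositions"))
#' @rdname accessors
#' @export
setGeneric("boxLengths", function(x) standardGeneric("boxLengths"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname accessors
setMethod("nFrames", "Trajectory", function(x) length(x@positions))
#' @rdname accessors
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology))
#' @rdname accessors
setMethod("frameTimes", "Trajectory", function(x) x@times)
#' @rdname accessors
setMethod("framePositions", "Trajectory", function(x, i) x@positions[[i]])
#' @rdname accessors
setMethod("boxLengths", "Trajectory", function(x) x@box)
#' @rdname accessors
setMethod("topology", "Trajectory", function(x) x@topology)

#' Subset a trajectory by frame
#'
#' `traj[i]` keeps frames `i` (logical or integer indexing), preserving
#' topology.
#'
#' @param x a Trajectory.
#' @param i frame indices.
#' @param j,...,drop ignored.
#' @return a Trajectory with the selected frames.
#' @export
setMethod("[", c("Trajectory", "ANY", "missing", "ANY"),
  function(x, i, j, ..., drop = FALSE) {
    idx <- seq_len(nFrames(x))[i]
    new("Trajectory", topology = x@topology, positions = x@positions[idx],
        times = x@times[idx], box = x@box[idx, , drop = FALSE])
  })

setMethod("show", "Trajectory", function(object) {
  sp <- table(object@topology$species)
  cat(sprintf("Trajectory: %d atoms, %d frames", nAtoms(object), nFrames(object)))
  if (nFrames(object))
    cat(sprintf(", t = %.4g..%.4g ns", object@times[1],
                object@times[nFrames(object)]))
  cat("\n  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "),
      "\n")
})

setMethod("show", "PoreSpec", function(object) {
  cat(sprintf(paste0("PoreSpec: axis [%g %g %g], R = %g A, zSF = %g, ",
                     "zGate = %g, luminal side %+d\n  center: \"%s\"\n"),
              object@axis[1], object@axis[2], object@axis[3],
              object@cylinderRadius, object@zSF, object@zGate,
              as.integer(object@luminalSide), object@centerSelection))
})

setMethod("show", "RadiusProfile", function(object) {
  cat(sprintf("RadiusProfile: %d levels, z in [%g, %g] A, min radius %.2f A at z = %.2f A\n",
              length(object@z), min(object@z), max(object@z),
              min(object@mean), object@z[which.min(object@mean)]))
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@counts)
  cat(sprintf("DensityGrid (%s): %d x %d x %d voxels @ %g A, %d frames, total counts %g (overflow %g)\n",
              object@species, d[1], d[2], d[3], object@spacing,
              object@nFrames, sum(object@counts), object@overflow))
})

setMethod("show", "UmbrellaWindow", function(object) {
  cat(sprintf("UmbrellaWindow: xi0 = %g A, k = %g kcal/mol/A^2, %d samples (mean %.2f A)\n",
              object@center, object@k, length(object@samples),
              mean(object@samples)))
})

setMethod("show", "PMFProfile", function(object) {
  cat(sprintf("PMFProfile: %d bins, xi in [%g, %g] A, barrier %.2f kcal/mol (zero: %s)\n",
              length(object@xi), min(object@xi), max(object@xi),
              max(object@W) - min(object@W), object@zero))
})
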