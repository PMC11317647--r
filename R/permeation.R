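#' Detect directional permeation events through the pore cylinder
#'
#' Runs a per-ion finite-state machine over the axial position relative to
#' the per-frame pore center (center of geometry of
#' \code{pore@centerSelection}, so the pore may drift).  Bulk states are
#' hysteretic: luminal bulk lies beyond the selectivity-filter plane plus
#' \code{margin}; cytosolic bulk beyond the gate plane minus \code{margin}.
#' An event is emitted when an ion goes from luminal bulk to cytosolic
#' bulk; in \code{strict} mode (default) it must have been inside the
#' cylinder (radial distance <= \code{cylinderRadius}) on every
#' intermediate frame -- an ion that exits the cylinder radially mid-pore
#' restarts its state machine.  In lenient mode (\code{strict = FALSE})
#' only the final in-pore frame before emerging must be inside the
#' cylinder.  Ions that enter and retreat emit nothing; re-entrant ions
#' can emit multiple events.  Reverse crossings are recorded with
#' \code{direction = -1} and are excluded from conductance counts.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param pore a \linkS4class{PoreSpec}.
#' @param species species tag to track (default \code{"cation"}), or a
#'   selection expression when \code{selection = TRUE}.
#' @param stride frame stride (>= 1).
#' @param margin bulk-plane hysteresis margin (Angstrom, default 2).
#' @param strict require in-cylinder containment on every transit frame.
#' @param charge formal charge override (units of e); default looked up
#'   from residue names via [ionCharge()].
#' @param selection treat \code{species} as a selection expression.
#' @return data.frame with one row per event: \code{atom} (topology
#'   index), \code{name}, \code{species}, \code{charge}, \code{t_entry}
#'   (ns, last time in the origin bulk before the traversal),
#'   \code{t_cross} (ns, first frame in the destination bulk),
#'   \code{direction} (+1 luminal to cytosolic, -1 reverse), ordered by
#'   \code{t_cross}.
#' @export
detectPermeationEvents <- function(traj, pore, species = "cation",
                                   stride = 1, margin = 2, strict = TRUE,
                                   charge = NULL, selection = FALSE) {
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  if (nFrames(traj) < 2) stop("trajectory must have >= 2 frames", call. = FALSE)
  csel <- selectAtoms(traj, pore@centerSelection)
  if (!length(csel))
    stop("centerSelection matches no atoms: ", pore@centerSelection,
         call. = FALSE)
  ions <- if (selection) selectAtoms(traj, species)
          else which(traj@topology$species == species)
  empty <- data.frame(atom = integer(), name = character(),
                      species = character(), charge = numeric(),
                      t_entry = numeric(), t_cross = numeric(),
                      direction = numeric())
  if (!length(ions)) {
    warning("no atoms with species '", species, "'", call. = FALSE)
    return(empty)
  }
  fr <- seq(1, nFrames(traj), by = stride)
  nf <- length(fr); ni <- length(ions)
  S <- matrix(0, nf, ni); Rr <- matrix(0, nf, ni)
  for (j in seq_len(nf)) {
    i <- fr[j]
    ctr <- poreCenter(traj, csel, i)
    ar <- axialRadial(traj@positions[[i]][ions, , drop = FALSE], ctr,
                      pore@axis, traj@box[i, ])
    S[j, ] <- ar$s; Rr[j, ] <- ar$r
  }
  sgn <- pore@luminalSide
  tms <- traj@times[fr]
  ## zones: 1 = luminal bulk, -1 = cytosolic bulk, 0 = in between
  Z <- ifelse(sgn * (S - pore@zSF) > margin, 1L,
              ifelse(sgn * (S - pore@zGate) < -margin, -1L, 0L))
  inside <- Rr <= pore@cylinderRadius
  zch <- if (is.null(charge)) ionCharge(traj@topology$resname[ions],
                                        traj@topology$name[ions])
         else rep_len(charge, ni)
  ev <- vector("list", 0)
  for (a in seq_len(ni)) {
    st <- c("1" = "LUM", "-1" = "CYT", "0" = "NONE")[as.character(Z[1, a])]
    last_bulk_t <- tms[1]
    last_mid_inside <- FALSE
    for (j in 2:nf) {
      z <- Z[j, a]
      if (z == 0L) {
        if (st %in% c("LUM", "CYT")) {
          if (inside[j, a] || !strict) {
            last_bulk_t <- tms[j - 1]
            st <- if (st == "LUM") "T_LC" else "T_CL"
            last_mid_inside <- inside[j, a]
          } else st <- "NONE"
        } else if (st %in% c("T_LC", "T_CL")) {
          if (strict && !inside[j, a]) st <- "NONE"
          else last_mid_inside <- inside[j, a]
        }
        ## NONE stays NONE in the middle zone
      } else if (z == 1L) {
        if (st == "T_CL" && (strict || last_mid_inside)) {
          ev[[length(ev) + 1L]] <- data.frame(
            atom = ions[a], name = traj@topology$name[ions[a]],
            species = traj@topology$species[ions[a]], charge = zch[a],
            t_entry = last_bulk_t, t_cross = tms[j], direction = -1)
        }
        st <- "LUM"
      } else {
        if (st == "T_LC" && (strict || last_mid_inside)) {
          ev[[length(ev) + 1L]] <- data.frame(
            atom = ions[a], name = traj@topology$name[ions[a]],
            species = traj@topology$species[ions[a]], charge = zch[a],
            t_entry = last_bulk_t, t_cross = tms[j], direction = 1)
        }
        st <- "CYT"
      }
    }
  }
  if (!length(ev)) return(empty)
  out <- do.call(rbind, ev)
  out[order(out$t_cross, out$atom), , drop = FALSE]
}

#' Cumulative permeation events versus time
#'
#' Non-decreasing step function of forward (+1) events on a time grid; one
#' column per species present in \code{events}.
#'
#' @param events data.frame from [detectPermeationEvents()] (possibly
#'   rbind-ed across species).
#' @param t_grid numeric time grid (ns).
#' @return data.frame: \code{time} plus one count column per species (all
#'   zeros column \code{count} when no events).
#' @export
cumulativeEvents <- function(events, t_grid) {
  fwd <- events[events$direction == 1, , drop = FALSE]
  out <- data.frame(time = t_grid)
  if (!nrow(fwd)) {
    out$count <- 0L
    return(out)
  }
  for (sp in unique(fwd$species)) {
    tc <- sort(fwd$t_cross[fwd$species == sp])
    out[[sp]] <- vapply(t_grid, function(t) sum(tc <= t), 0L)
  }
  out
}

#' Single-channel conductance from permeation event counts
#'
#' \code{C = N_event * Q_ion / (t * V_tm)} with \code{Q_ion = z e}: in the
#' package's units, \code{C[pS] = N * z * 1.602177e5 / (t[ns] * V[mV])}.
#' Fractional \code{N} is accepted (mean event counts over repeats).
#'
#' @param N_event forward permeation events (may be fractional).
#' @param z ion formal charge (units of e).
#' @param t_ns trajectory length (ns), > 0.
#' @param V_mV transmembrane voltage (mV), non-zero.
#' @return conductance in pS.
#' @examples
#' conductance(44.1, 1, 500, 750)  # 18.8 pS
#' @export
conductance <- function(N_event, z, t_ns, V_mV) {
  if (any(t_ns <= 0)) stop("t_ns must be > 0", call. = FALSE)
  if (any(V_mV == 0)) stop("V_mV must be non-zero (conductance undefined)",
                           call. = FALSE)
  N_event * z * permConstants$e_pS / (t_ns * V_mV)
}

#' Mean and SD of conductance over repeats
#'
#' Per-repeat conductances from per-repeat event counts, with unweighted
#' mean and sample SD.
#'
#' @param N_events numeric vector of event counts, one per repeat.
#' @param z,t_ns,V_mV as in [conductance()]; \code{t_ns} may be a vector.
#' @return list: \code{per_repeat} (pS), \code{mean}, \code{sd}.
#' @export
conductanceSummary <- function(N_events, z, t_ns, V_mV) {
  g <- conductance(N_events, z, t_ns, V_mV)
  list(per_repeat = g, mean = mean(g), sd = stats::sd(g))
}

#' Permeability ratio of two species from event rates
#'
#' Ratio of permeation event rates under identical conditions, as
#' \code{rate_a / rate_b}, with the conventional "x.x:1" label.
#'
#' @param rate_a,rate_b events per unit time; \code{rate_b} > 0.
#' @return list: \code{ratio} (numeric) and \code{label} ("x.x:1").
#' @examples
#' permeabilityRatio(44.1 / 500, 5.7 / 500)$label  # "7.7:1"
#' @export
permeabilityRatio <- function(rate_a, rate_b) {
  if (rate_b <= 0) stop("rate_b must be > 0", call. = FALSE)
  r <- rate_a / rate_b
  list(ratio = r, label = sprintf("%.1f:1", r))
}
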