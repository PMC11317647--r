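#' Construct an UmbrellaWindow
#'
#' @param center bias center xi0 (Angstrom).
#' @param k harmonic force constant (kcal mol-1 A-2); use
#'   \code{k_kJ_nm2 * permConstants$kJnm2_to_kcalA2} to convert from
#'   kJ mol-1 nm-2 (1000 kJ mol-1 nm-2 = 2.390 kcal mol-1 A-2).
#' @param samples reaction-coordinate samples (Angstrom).
#' @param times optional sample times (ns).
#' @param meta metadata list.
#' @return an \linkS4class{UmbrellaWindow}.
#' @export
umbrellaWindow <- function(center, k, samples, times = numeric(),
                           meta = list())
  new("UmbrellaWindow", center = center, k = k, samples = samples,
      times = times, meta = meta)

#' Weighted histogram analysis method (WHAM) for 1D umbrella sampling
#'
#' Self-consistent WHAM: with per-window bias
#' \code{u_i(xi) = k_i/2 (xi - xi0_i)^2}, iterate
#' \deqn{p(b) = \sum_i n_i(b) / \sum_i N_i \exp[(f_i - u_i(b))/k_BT]}
#' \deqn{f_i = -k_BT \ln \sum_b p(b) \exp(-u_i(b)/k_BT)}
#' from \code{f_i = 0} until the largest change in any window free energy
#' \code{f_i} falls below \code{tol}.  The PMF is
#' \code{W = -kBT ln p}, shifted so its minimum is zero (or so the mean
#' over a bulk reference range is zero).  Only occupied bins are
#' reported.
#'
#' Adjacent windows (by center) whose sample histograms share no occupied
#' bin trigger a warning; if the overlap graph is disconnected the chain
#' cannot be stitched and an error lists the gap.
#'
#' @param windows list of \linkS4class{UmbrellaWindow}.
#' @param bin histogram bin width (Angstrom, default 0.2).
#' @param temperature K (default 310).
#' @param tol convergence tolerance on max |delta f_i| (kcal/mol,
#'   default 1e-7).
#' @param max_iter iteration cap; non-convergence is an error reporting
#'   the residual.
#' @param zero "min" (global minimum = 0) or "bulk" (mean over
#'   \code{bulk_range} = 0).
#' @param bulk_range xi range for the bulk reference (required when
#'   \code{zero = "bulk"}).
#' @param f_init optional warm-start window free energies.
#' @return a \linkS4class{PMFProfile}; \code{meta} records iterations,
#'   residual, temperature, bin width and the converged window free
#'   energies \code{f}.
#' @export
wham <- function(windows, bin = 0.2, temperature = 310, tol = 1e-7,
                 max_iter = 100000, zero = c("min", "bulk"),
                 bulk_range = NULL, f_init = NULL) {
  zero <- match.arg(zero)
  stopifnot(length(windows) >= 1)
  kT <- permConstants$kB * temperature
  centers <- vapply(windows, function(w) w@center, 0)
  kk <- vapply(windows, function(w) w@k, 0)
  samples <- lapply(windows, function(w) w@samples)
  rng <- range(unlist(samples))
  edges <- seq(floor(rng[1] / bin) * bin, ceiling(rng[2] / bin) * bin + bin,
               by = bin)
  mids <- edges[-1] - bin / 2
  nb <- length(mids); nw <- length(windows)
  Nmat <- vapply(samples, function(s)
    graphics::hist(s, breaks = edges, plot = FALSE)$counts, numeric(nb))
  Nmat <- matrix(Nmat, nrow = nb)
  .wham_check_overlap(Nmat, centers)
  Ni <- colSums(Nmat)
  U <- 0.5 * outer(mids, centers, "-")^2 %*% diag(kk, nw)
  expu <- exp(-U / kT)
  num <- rowSums(Nmat)
  f <- if (is.null(f_init)) rep(0, nw) else f_init
  it <- 0; resid <- Inf
  while (it < max_iter) {
    it <- it + 1
    den <- drop(expu %*% (Ni * exp(f / kT)))
    p <- num / den
    z <- drop(crossprod(expu, p))
    f_new <- -kT * log(z)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) break
  }
  if (resid >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                 max_iter, resid), call. = FALSE)
  keep <- num > 0
  W <- -kT * log(p[keep])
  xi <- mids[keep]
  if (zero == "bulk") {
    if (is.null(bulk_range)) stop("bulk_range required for zero = 'bulk'",
                                  call. = FALSE)
    inb <- xi >= bulk_range[1] & xi <= bulk_range[2]
    if (!any(inb)) stop("bulk_range covers no occupied bins", call. = FALSE)
    W <- W - mean(W[inb])
  } else W <- W - min(W)
  new("PMFProfile", xi = xi, W = W, err = rep(0, length(W)), zero = zero,
      meta = list(iterations = it, residual = resid,
                  temperature = temperature, bin = bin, f = f,
                  edges = edges, keep = keep))
}

.wham_check_overlap <- function(Nmat, centers) {
  nw <- length(centers)
  if (nw < 2) return(invisible())
  ord <- order(centers)
  occ <- Nmat > 0
  ## adjacency by shared occupied bins
  adj <- matrix(FALSE, nw, nw)
  for (i in seq_len(nw - 1)) for (j in (i + 1):nw)
    adj[i, j] <- adj[j, i] <- any(occ[, i] & occ[, j])
  for (k in seq_len(nw - 1)) {
    a <- ord[k]; b <- ord[k + 1]
    if (!adj[a, b])
      warning(sprintf("no histogram overlap between windows at xi0 = %g and %g",
                      centers[a], centers[b]), call. = FALSE)
  }
  ## connectivity of the overlap graph
  comp <- seq_len(nw)
  repeat {
    changed <- FALSE
    for (i in seq_len(nw)) for (j in seq_len(nw))
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    if (!changed) break
  }
  if (length(unique(comp)) > 1) {
    cc <- comp[ord]
    brk <- which(diff(cc) != 0)[1]
    stop(sprintf("umbrella window chain is disconnected: gap between xi0 = %g and %g",
                 centers[ord[brk]], centers[ord[brk + 1]]), call. = FALSE)
  }
  invisible()
}

#' Bootstrap errors for a WHAM profile
#'
#' Window-wise bootstrap: each replicate resamples every window's
#' reaction-coordinate samples with replacement (equivalently, redraws
#' its histogram counts from a multinomial), reruns WHAM (warm-started
#' from the full-data solution), re-zeroes the replicate profile, and the
#' per-bin standard deviation across replicates is reported.  Fully
#' reproducible under a fixed seed.
#'
#' @param windows list of \linkS4class{UmbrellaWindow}.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @param ... passed to [wham()].
#' @return a \linkS4class{PMFProfile}: full-data W with bootstrap SD in
#'   \code{err} (zero when \code{n_boot = 1}).
#' @export
whamBootstrap <- function(windows, n_boot = 100, seed, ...) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  full <- wham(windows, ...)
  if (n_boot == 1) return(full)
  Wb <- matrix(NA_real_, length(full@xi), n_boot)
  for (r in seq_len(n_boot)) {
    wb <- lapply(windows, function(w) {
      s <- w@samples
      new("UmbrellaWindow", center = w@center, k = w@k,
          samples = s[sample.int(length(s), replace = TRUE)],
          times = numeric(), meta = w@meta)
    })
    pr <- wham(wb, f_init = full@meta$f, ...)
    m <- match(round(full@xi, 9), round(pr@xi, 9))
    Wb[, r] <- pr@W[m]
  }
  err <- apply(Wb, 1, stats::sd, na.rm = TRUE)
  err[!is.finite(err)] <- 0
  new("PMFProfile", xi = full@xi, W = full@W, err = err, zero = full@zero,
      meta = c(full@meta, list(n_boot = n_boot, seed = seed)))
}

#' Observable as a function of the reaction coordinate
#'
#' Combines per-sample observable series (e.g. water coordination
#' numbers) across umbrella windows into a profile over xi, either as the
#' per-window statistic plotted at each window center, or pooled and
#' binned by the sampled xi values.
#'
#' @param windows list of \linkS4class{UmbrellaWindow}.
#' @param observables list of numeric vectors, parallel to each window's
#'   samples.
#' @param statistic summary function (default mean).
#' @param mode "per_window" or "binned".
#' @param bin bin width for "binned" mode (Angstrom).
#' @return data.frame \code{xi}, \code{value}.
#' @export
observableVsXi <- function(windows, observables, statistic = mean,
                           mode = c("per_window", "binned"), bin = 0.2) {
  mode <- match.arg(mode)
  stopifnot(length(windows) == length(observables))
  for (i in seq_along(windows))
    if (length(observables[[i]]) != length(windows[[i]]@samples))
      stop("observable series ", i, " does not match its window's samples",
           call. = FALSE)
  if (mode == "per_window") {
    xi <- vapply(windows, function(w) w@center, 0)
    val <- vapply(observables, statistic, 0)
    o <- order(xi)
    return(data.frame(xi = xi[o], value = val[o]))
  }
  x <- unlist(lapply(windows, function(w) w@samples))
  y <- unlist(observables)
  edges <- seq(floor(min(x) / bin) * bin, ceiling(max(x) / bin) * bin + bin,
               by = bin)
  cuts <- cut(x, edges, include.lowest = TRUE)
  agg <- tapply(y, cuts, statistic)
  mids <- edges[-1] - bin / 2
  keep <- !is.na(agg)
  data.frame(xi = mids[keep], value = unname(agg[keep]))
}

#' Read umbrella windows from a manifest
#'
#' The manifest (CSV with a header, or a JSON array of objects) lists one
#' window per row with fields \code{path} (two-column plain-text file:
#' time, xi; comment lines starting with # or @ are skipped),
#' \code{center}, \code{k}, and optionally \code{equilibration_cut} (ns,
#' default 2: samples earlier than this are discarded),
#' \code{time_unit} ("ps" default, or "ns"), \code{xi_unit} ("A" default,
#' or "nm") and \code{k_unit} ("kcal_A2" default, or "kJ_nm2").  Relative
#' paths are resolved against the manifest's directory.
#'
#' @param manifest_path path to the manifest file.
#' @return list of \linkS4class{UmbrellaWindow}.
#' @export
readUmbrellaWindows <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  dir <- dirname(manifest_path)
  man <- if (grepl("\\.json$", manifest_path, ignore.case = TRUE))
    jsonlite::fromJSON(manifest_path)
  else utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path", "center", "k")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest lacks fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(man)
  get <- function(col, default) if (col %in% names(man)) man[[col]]
                                else rep(default, n)
  cut_ns <- get("equilibration_cut", 2)
  t_unit <- get("time_unit", "ps")
  x_unit <- get("xi_unit", "A")
  k_unit <- get("k_unit", "kcal_A2")
  lapply(seq_len(n), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(dir, man$path[i])
    if (!file.exists(p)) stop("window file not found: ", man$path[i],
                              call. = FALSE)
    ln <- readLines(p)
    ln <- trimws(ln)
    ln <- ln[nzchar(ln) & !grepl("^[#@]", ln)]
    fields <- strsplit(ln, "[\\s,]+", perl = TRUE)
    tm <- as.numeric(vapply(fields, `[`, "", 1))
    xi <- as.numeric(vapply(fields, `[`, "", 2))
    if (t_unit[i] == "ps") tm <- tm / 1000
    if (x_unit[i] == "nm") xi <- xi * 10
    k <- man$k[i]
    if (k_unit[i] == "kJ_nm2") k <- k * permConstants$kJnm2_to_kcalA2
    keep <- tm >= cut_ns[i]
    if (!any(keep))
      stop("window ", man$path[i], " has no samples after the ",
           cut_ns[i], " ns equilibration cut", call. = FALSE)
    umbrellaWindow(center = man$center[i], k = k, samples = xi[keep],
                   times = tm[keep],
                   meta = list(path = man$path[i],
                               equilibration_cut = cut_ns[i]))
  })
}

#' Write umbrella windows to plain-text files plus a manifest
#'
#' Inverse of [readUmbrellaWindows()] (times written in ps, xi in
#' Angstrom, k in kcal mol-1 A-2, equilibration_cut 0 since synthetic
#' samples need no equilibration discard).
#'
#' @param windows list of \linkS4class{UmbrellaWindow}.
#' @param dir output directory (created if needed).
#' @return the manifest path.
#' @export
writeUmbrellaWindows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    fn <- sprintf("window_%03d.dat", i)
    tm <- if (length(w@times)) w@times * 1000
          else seq_along(w@samples)  # ps
    utils::write.table(data.frame(time = tm, xi = w@samples),
                       file.path(dir, fn), row.names = FALSE,
                       col.names = FALSE)
    data.frame(path = fn, center = w@center, k = w@k,
               equilibration_cut = 0, time_unit = "ps", xi_unit = "A",
               k_unit = "kcal_A2", stringsAsFactors = FALSE)
  })
  man <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), man, row.names = FALSE)
  man
}
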