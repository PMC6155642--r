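## Trajectory analyses: fluctuation heat capacity, radial distribution
## functions, and intramolecular hydrogen-bond histograms.

#' Heat capacity from canonical potential-energy fluctuations
#'
#' \code{Cv = (<U^2> - <U>^2) / (NA kB T^2)} with \code{U} in kcal/mol, so
#' the denominator constant \code{NA kB} is the gas constant in
#' kcal mol^-1 K^-1 and \code{Cv} comes out in kcal mol^-1 K^-1 per system.
#' Population (not sample) moments are used.
#'
#' @param U numeric vector of sampled potential energies (kcal/mol)
#' @param T temperature (K)
#' @return Cv in kcal mol^-1 K^-1
#' @export
#' @examples
#' heat_capacity(c(0, 2), 90)  # variance 1 => 1/(R * 90^2)
heat_capacity <- function(U, T) {
  if (T <= 0) stop("temperature must be positive")
  stopifnot(length(U) >= 2)
  (mean(U^2) - mean(U)^2) / (.KB * T^2)
}

#' Heat-capacity scan over a temperature grid
#'
#' For each temperature an independent NVT run is performed (Berendsen
#' thermostat) after its own equilibration, and Cv is computed from the
#' production potential-energy samples with the wall term excluded from U.
#' The transition temperature is read off as the grid argmax, optionally
#' after 3-point smoothing. Evaporation is flagged when any atom strays
#' beyond \code{evap_factor} times the wall radius (or 3x the initial system
#' extent when no wall is present).
#'
#' @param builder zero-argument function returning the simulation-ready
#'   \code{molsys} (called once per temperature, so each point starts from
#'   an identical configuration)
#' @param ff an \code{ffparams}
#' @param temps sorted temperature grid (K)
#' @param equil_steps,prod_steps MD steps per phase
#' @param dt time step (ps)
#' @param stride sampling stride for U
#' @param seed base RNG seed; point i uses seed + i
#' @param smooth apply 3-point running-mean smoothing before peak detection
#' @param evap_factor evaporation detection multiplier
#' @return object of class \code{cv_curve}: data.frame \code{curve}
#'   (T, Cv, n_samples, evaporated), \code{peak_T}
#' @export
heat_capacity_scan <- function(builder, ff, temps, equil_steps, prod_steps,
                               dt = 5e-4, stride = 20, seed = 1,
                               smooth = TRUE, evap_factor = 3) {
  stopifnot(!is.unsorted(temps))
  cv <- ns <- numeric(length(temps))
  evap <- logical(length(temps))
  for (i in seq_along(temps)) {
    sys <- builder()
    sys <- initialize_velocities(sys, temps[i], seed = seed + i)
    traj <- run_md_protocol(sys, ff, equil_steps, prod_steps, dt = dt,
                            stride = stride,
                            thermostat = list(T = temps[i], tau = 0.1))
    U <- traj$scalars$U - traj$scalars$wall
    cv[i] <- heat_capacity(U, temps[i])
    ns[i] <- length(U)
    lim <- if (!is.null(sys$wall)) evap_factor * sys$wall$radius else
      evap_factor * max(sqrt(rowSums(
        sweep(sys$xyz, 2, colMeans(sys$xyz), "-")^2)))
    ctr <- if (!is.null(sys$wall)) sys$wall$center else colMeans(sys$xyz)
    rmax <- max(sqrt(rowSums(sweep(traj$final$xyz, 2, ctr, "-")^2)))
    evap[i] <- is.null(sys$cell) && rmax > lim
  }
  cvs <- cv
  if (smooth && length(cv) >= 3) {
    cvs <- cv
    for (i in 2:(length(cv) - 1)) cvs[i] <- mean(cv[(i - 1):(i + 1)])
  }
  out <- list(curve = data.frame(T = temps, Cv = cv, Cv_smooth = cvs,
                                 n_samples = ns, evaporated = evap),
              peak_T = temps[which.max(cvs)])
  class(out) <- "cv_curve"
  out
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("Heat-capacity curve over", nrow(x$curve), "temperatures; peak at",
      x$peak_T, "K\n")
  invisible(x)
}

.pair_indices <- function(sys, sel_a, sel_b) {
  ia <- which(sys$classes == sel_a)
  ib <- which(sys$classes == sel_b)
  if (!length(ia) || !length(ib))
    stop("empty selection: ", sel_a, " / ", sel_b)
  pairs <- if (sel_a == sel_b) {
    if (length(ia) < 2) stop("selection ", sel_a, " has fewer than 2 atoms")
    t(utils::combn(ia, 2))
  } else as.matrix(expand.grid(ia, ib))
  # intermolecular only
  pairs[sys$mol[pairs[, 1]] != sys$mol[pairs[, 2]], , drop = FALSE]
}

.frame_dists <- function(xyz, pairs, cell) {
  d <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
  if (!is.null(cell))
    d <- d - sweep(round(sweep(d, 2, cell, "/")), 2, cell, "*")
  sqrt(rowSums(d * d))
}

#' Radial distribution function from trajectory frames
#'
#' Standard pair-histogram g(r) between two atom-class selections,
#' intermolecular pairs only, normalized by the ideal-gas shell count at the
#' mean density of the selected pair over the primary cell (for non-periodic
#' systems, over the bounding volume given by \code{volume}).
#'
#' @param traj a \code{trajectory} with stored frames
#' @param sys the template \code{molsys} (defaults to the trajectory's)
#' @param sel_a,sel_b atom class names (e.g. \code{"C_co2"})
#' @param r_max histogram range (Angstrom)
#' @param dr bin width (Angstrom)
#' @param frames integer indices of frames to use (default all)
#' @param volume override volume for non-periodic systems (A^3)
#' @return object of class \code{rdf_result}: data.frame \code{table}
#'   (r, g), plus the selection labels and frame count
#' @export
rdf <- function(traj, sys = traj$template, sel_a, sel_b, r_max = 10,
                dr = 0.05, frames = seq_along(traj$frames), volume = NULL) {
  if (!length(traj$frames)) stop("trajectory has no stored frames")
  if (!length(frames)) stop("empty frame window")
  pairs <- .pair_indices(sys, sel_a, sel_b)
  edges <- seq(0, r_max, by = dr)
  mids <- edges[-1] - dr / 2
  acc <- numeric(length(mids))
  vsum <- 0
  for (fi in frames) {
    xyz <- traj$frames[[fi]]
    cell <- if (!is.null(sys$cell)) traj$frame_cell[fi, ] else NULL
    rr <- .frame_dists(xyz, pairs, cell)
    acc <- acc + tabulate(findInterval(rr[rr < r_max], edges,
                                       left.open = TRUE),
                          nbins = length(mids))
    vsum <- vsum + if (!is.null(cell)) prod(cell) else
      if (!is.null(volume)) volume else
        4 / 3 * pi * (max(rr) / 2 + r_max)^3
  }
  nfr <- length(frames)
  V <- vsum / nfr
  shell <- 4 * pi * mids^2 * dr
  g <- acc / nfr / (nrow(pairs) * shell / V)
  out <- list(table = data.frame(r = mids, g = g),
              sel = c(sel_a, sel_b), n_frames = nfr,
              n_pairs = nrow(pairs), volume = V, dr = dr)
  class(out) <- "rdf_result"
  out
}

#' @export
print.rdf_result <- function(x, ...) {
  cat("g(r) ", x$sel[1], "-", x$sel[2], ": ", nrow(x$table), " bins, ",
      x$n_frames, " frames; first peak ",
      signif(x$table$r[which.max(x$table$g)], 3), " A\n", sep = "")
  invisible(x)
}

#' Evaluate g at a probe distance
#' @param x an \code{rdf_result}
#' @param r_probe probe distance (Angstrom)
#' @return g in the bin containing \code{r_probe}
#' @export
rdf_at <- function(x, r_probe) {
  i <- findInterval(r_probe, seq(0, max(x$table$r) + x$dr / 2, by = x$dr),
                    left.open = TRUE)
  x$table$g[max(1, min(i, nrow(x$table)))]
}

#' Time evolution of g(r) at a probe distance
#'
#' Splits the stored frames into sequential windows and evaluates the RDF at
#' the probe bin in each window.
#'
#' @inheritParams rdf
#' @param r_probe probe distance (Angstrom)
#' @param window_frames frames per window
#' @return data.frame with window start time (ps) and g(r_probe)
#' @export
rdf_time_evolution <- function(traj, sys = traj$template, sel_a, sel_b,
                               r_probe = 3.65, window_frames = 10,
                               dr = 0.05) {
  nf <- length(traj$frames)
  if (window_frames > nf) stop("window exceeds the trajectory span")
  starts <- seq(1, nf - window_frames + 1, by = window_frames)
  g <- vapply(starts, function(s) {
    r <- rdf(traj, sys, sel_a, sel_b, r_max = r_probe + 5 * dr, dr = dr,
             frames = s:(s + window_frames - 1))
    rdf_at(r, r_probe)
  }, 0)
  data.frame(time = (starts - 1) * traj$frame_stride * traj$dt, g = g)
}

#' Histogram of intramolecular amine-N to hydroxyl-H distances
#'
#' For each sampled MEA molecule and snapshot, measures the distance from
#' the amine nitrogen to the hydroxyl hydrogen of the same molecule and
#' histograms it; geometries below \code{criterion} (default 2.2 A) are
#' counted as intramolecular hydrogen bonds.
#'
#' @param traj a \code{trajectory} with stored frames
#' @param sys the template \code{molsys}
#' @param n_molecules number of MEA molecules to monitor (first n by
#'   molecule index among MEA molecules)
#' @param n_snapshots number of snapshots (evenly spaced over the frames)
#' @param criterion hydrogen-bond distance criterion (Angstrom)
#' @param breaks histogram bin edges (Angstrom)
#' @return object of class \code{hb_histogram}: \code{counts}, \code{breaks},
#'   \code{n_below} (count below criterion), \code{distances},
#'   \code{n_molecules}, \code{n_snapshots}
#' @export
intra_hb_histogram <- function(traj, sys = traj$template, n_molecules = 10,
                               n_snapshots = 200, criterion = 2.2,
                               breaks = seq(0, 8, by = 0.1)) {
  nf <- length(traj$frames)
  if (n_snapshots > nf)
    stop("trajectory has only ", nf, " stored frames (need ", n_snapshots, ")")
  # MEA molecules are those containing an amine nitrogen
  has_n <- unique(sys$mol[sys$classes == "N_amine"])
  if (n_molecules > length(has_n))
    stop("selection exceeds the number of MEA molecules")
  mols <- has_n[seq_len(n_molecules)]
  iN <- iH <- integer(length(mols))
  for (k in seq_along(mols)) {
    idx <- which(sys$mol == mols[k])
    iN[k] <- idx[sys$classes[idx] == "N_amine"][1]
    iH[k] <- idx[sys$classes[idx] == "H_O"][1]
  }
  snap <- round(seq(1, nf, length.out = n_snapshots))
  dists <- numeric(0)
  for (fi in snap) {
    xyz <- traj$frames[[fi]]
    d <- xyz[iN, , drop = FALSE] - xyz[iH, , drop = FALSE]
    if (!is.null(sys$cell)) {
      cell <- traj$frame_cell[fi, ]
      d <- d - sweep(round(sweep(d, 2, cell, "/")), 2, cell, "*")
    }
    dists <- c(dists, sqrt(rowSums(d * d)))
  }
  h <- hist(dists, breaks = c(breaks, Inf), plot = FALSE)
  out <- list(counts = h$counts, breaks = c(breaks, Inf),
              n_below = sum(dists < criterion), distances = dists,
              n_molecules = n_molecules, n_snapshots = n_snapshots,
              criterion = criterion)
  class(out) <- "hb_histogram"
  out
}

#' @export
print.hb_histogram <- function(x, ...) {
  cat("Intramolecular N...H(O) histogram: ", x$n_molecules, " molecules x ",
      x$n_snapshots, " snapshots; ", x$n_below, " geometries below ",
      x$criterion, " A\n", sep = "")
  invisible(x)
}

#' @importFrom graphics hist
NULL
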