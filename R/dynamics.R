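## Molecular dynamics: velocity Verlet with Berendsen temperature coupling,
## Berendsen-style pressure coupling (NPH: pressure coupling without a
## thermostat), periodic boxes and spherical confinement.

#' Draw Maxwell-Boltzmann velocities
#'
#' Gaussian draw at temperature \code{T}, net linear momentum removed, then
#' rescaled so the instantaneous temperature (with 3N-3 degrees of freedom)
#' equals the target exactly. Deterministic per seed.
#'
#' @param sys a \code{molsys}
#' @param T target temperature (K)
#' @param seed RNG seed
#' @return the system with \code{vel} set (Angstrom/ps)
#' @export
initialize_velocities <- function(sys, T, seed = 1) {
  stopifnot(T > 0)
  set.seed(seed)
  n <- nrow(sys$xyz)
  sd <- sqrt(.KB * T * .KCAL_AKMA / sys$mass)
  v <- matrix(rnorm(3 * n), n, 3) * sd
  # remove net momentum
  p <- colSums(v * sys$mass)
  v <- sweep(v, 2, p / sum(sys$mass), "-")
  ndof <- max(3 * n - 3, 1)
  Tinst <- sum(sys$mass * rowSums(v^2)) / .KCAL_AKMA / (ndof * .KB)
  sys$vel <- v * sqrt(T / Tinst)
  sys
}

#' Berendsen velocity-scaling factor
#'
#' \code{lambda = sqrt(1 + (dt/tau) (T0/T_inst - 1))}, the weak-coupling
#' rescale applied each step by the thermostat.
#'
#' @param T_inst instantaneous temperature (K)
#' @param T0 target temperature (K)
#' @param dt time step (ps)
#' @param tau coupling time (ps)
#' @return scaling factor lambda
#' @export
berendsen_factor <- function(T_inst, T0, dt, tau) {
  stopifnot(T_inst > 0)
  sqrt(1 + (dt / tau) * (T0 / T_inst - 1))
}

#' Run molecular dynamics
#'
#' Velocity-Verlet integration at time step \code{dt} (default 0.0005 ps =
#' 0.5 fs). Optional Berendsen thermostat (NVT), optional Berendsen-style
#' isotropic pressure coupling using the atomic virial (with thermostat off
#' this realizes an NPH-like ensemble), optional one-sided harmonic
#' spherical wall carried on the system. Per-frame potential-energy
#' decomposition, kinetic energy, instantaneous temperature and pressure are
#' logged every \code{stride} steps; coordinates every \code{frame_stride}
#' steps. Runs are bitwise reproducible: the integrator uses no random
#' numbers, so a run restarted from the returned state continues a longer
#' run exactly.
#'
#' @param sys a \code{molsys} with velocities (see
#'   \code{\link{initialize_velocities}})
#' @param ff an \code{ffparams}
#' @param steps number of MD steps
#' @param dt time step (ps)
#' @param stride scalar-logging stride (steps)
#' @param frame_stride coordinate-logging stride (steps; 0 = no frames)
#' @param thermostat NULL or \code{list(T = , tau = 0.1)} (K, ps)
#' @param barostat NULL or \code{list(P = , tau = 1, beta = 4.6e-5)}
#'   (atm, ps, atm^-1)
#' @param nlist_every neighbor-list rebuild cadence (steps)
#' @param skin neighbor-list skin (Angstrom)
#' @return object of class \code{trajectory}: \code{scalars} (data.frame:
#'   time, U, decomposition, K, T, P, V), \code{frames} (list of coordinate
#'   matrices), \code{frame_cell}, \code{final} (a \code{molsys} holding the
#'   final state), \code{dt}, \code{stride}, \code{frame_stride},
#'   \code{template} (the input system)
#' @export
run_md <- function(sys, ff, steps, dt = 5e-4, stride = 20,
                   frame_stride = 0, thermostat = NULL, barostat = NULL,
                   nlist_every = 10, skin = 1.0) {
  .check_cell(sys, ff)
  if (is.null(sys$vel)) stop("system has no velocities; call ",
                             "initialize_velocities() first")
  stopifnot(dt > 0, stride >= 1)
  if (!is.null(thermostat)) {
    thermostat <- modifyList(list(tau = 0.1), thermostat)
    stopifnot(thermostat$T > 0, thermostat$tau >= dt)
  }
  if (!is.null(barostat)) {
    barostat <- modifyList(list(tau = 1.0, beta = 4.6e-5), barostat)
    stopifnot(barostat$tau >= dt)
    if (is.null(sys$cell)) stop("pressure coupling needs a periodic cell")
  }
  comp <- .compile(sys, ff)
  out <- cpp_run_md(comp, sys$xyz, sys$vel, .cell_or_zero(sys),
                    .wall_vec(sys), dt, as.integer(steps),
                    as.integer(stride), as.integer(frame_stride),
                    !is.null(thermostat),
                    if (is.null(thermostat)) 0 else thermostat$T,
                    if (is.null(thermostat)) 1 else thermostat$tau,
                    !is.null(barostat),
                    if (is.null(barostat)) 0 else barostat$P,
                    if (is.null(barostat)) 1 else barostat$tau,
                    if (is.null(barostat)) 0 else barostat$beta,
                    as.integer(nlist_every), skin)
  final <- sys
  final$xyz <- out$xyz
  final$vel <- out$vel
  if (!is.null(sys$cell)) final$cell <- as.numeric(out$cell)
  traj <- list(scalars = as.data.frame(out$scalars),
               frames = out$frames, frame_cell = out$frame_cell,
               final = final, dt = dt, stride = stride,
               frame_stride = frame_stride, template = sys)
  class(traj) <- "trajectory"
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  ns <- nrow(x$scalars)
  cat("Trajectory: ", ns, " logged points (dt ", x$dt * 1000, " fs), ",
      length(x$frames), " stored frames\n", sep = "")
  if (ns) {
    last <- x$scalars[ns, ]
    cat(sprintf("  final: t = %.4g ps, U = %.4g kcal/mol, T = %.1f K\n",
                last$time, last$U, last$T))
  }
  invisible(x)
}

#' One MD segment convenience wrapper: equilibration then production
#'
#' Runs an equilibration segment (not logged in the returned production
#' trajectory) followed by a production segment, both under the same
#' thermo-/barostat settings.
#'
#' @inheritParams run_md
#' @param equil_steps equilibration steps
#' @param prod_steps production steps
#' @return production \code{trajectory}
#' @export
run_md_protocol <- function(sys, ff, equil_steps, prod_steps, dt = 5e-4,
                            stride = 20, frame_stride = 0, thermostat = NULL,
                            barostat = NULL, nlist_every = 10, skin = 1.0) {
  if (equil_steps > 0) {
    eq <- run_md(sys, ff, equil_steps, dt = dt, stride = max(equil_steps, 1),
                 frame_stride = 0, thermostat = thermostat,
                 barostat = barostat, nlist_every = nlist_every, skin = skin)
    sys <- eq$final
  }
  run_md(sys, ff, prod_steps, dt = dt, stride = stride,
         frame_stride = frame_stride, thermostat = thermostat,
         barostat = barostat, nlist_every = nlist_every, skin = skin)
}
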