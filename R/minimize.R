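## Constrained geometry optimization, normal modes, and the CO2-MEA
## physisorption distance scan.

.wrap_pi <- function(x) atan2(sin(x), cos(x))

## energy + gradient of the harmonic restraints used to impose constraints
.restraints_eg <- function(xyz, constraints, k) {
  e <- 0
  g <- matrix(0, nrow(xyz), 3)
  for (cn in constraints) {
    a <- cn$atoms
    if (cn$kind == "frozen_distance") {
      d <- xyz[a[1], ] - xyz[a[2], ]
      r <- sqrt(sum(d * d))
      dr <- r - cn$target
      e <- e + k * dr * dr
      gg <- 2 * k * dr * d / r
      g[a[1], ] <- g[a[1], ] + gg
      g[a[2], ] <- g[a[2], ] - gg
    } else if (cn$kind == "frozen_angle") {
      u <- xyz[a[1], ] - xyz[a[2], ]; v <- xyz[a[3], ] - xyz[a[2], ]
      nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
      ct <- max(-1, min(1, sum(u * v) / (nu * nv)))
      th <- acos(ct)
      st <- max(sqrt(1 - ct^2), 1e-8)
      dth <- th - cn$target * pi / 180
      e <- e + k * dth * dth
      dEdth <- 2 * k * dth
      gi <- (ct * u / nu - v / nv) / (nu * st)
      gk <- (ct * v / nv - u / nu) / (nv * st)
      g[a[1], ] <- g[a[1], ] + dEdth * gi
      g[a[3], ] <- g[a[3], ] + dEdth * gk
      g[a[2], ] <- g[a[2], ] - dEdth * (gi + gk)
    } else if (cn$kind == "frozen_dihedral") {
      # finite-difference gradient; dihedral restraints are only used to
      # pin symmetry and never appear in reported energies
      phi0 <- cn$target * pi / 180
      val <- function(xx) {
        b1 <- xx[a[2], ] - xx[a[1], ]; b2 <- xx[a[3], ] - xx[a[2], ]
        b3 <- xx[a[4], ] - xx[a[3], ]
        n1 <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3],
                b1[1]*b2[2]-b1[2]*b2[1])
        n2 <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3],
                b2[1]*b3[2]-b2[2]*b3[1])
        m1 <- c(n1[2]*b2[3]-n1[3]*b2[2], n1[3]*b2[1]-n1[1]*b2[3],
                n1[1]*b2[2]-n1[2]*b2[1])
        atan2(sum(m1 * n2) / sqrt(sum(b2^2)), sum(n1 * n2))
      }
      phi <- val(xyz)
      dphi <- .wrap_pi(phi - phi0)
      e <- e + k * dphi * dphi
      h <- 1e-6
      for (ai in a) for (m in 1:3) {
        xp <- xyz; xp[ai, m] <- xp[ai, m] + h
        xm <- xyz; xm[ai, m] <- xm[ai, m] - h
        g[ai, m] <- g[ai, m] +
          2 * k * dphi * .wrap_pi(val(xp) - val(xm)) / (2 * h)
      }
    } else stop("unknown constraint kind: ", cn$kind)
  }
  list(e = e, g = g)
}

.constraint_value <- function(xyz, cn) {
  a <- cn$atoms
  if (cn$kind == "frozen_distance") {
    sqrt(sum((xyz[a[1], ] - xyz[a[2], ])^2))
  } else if (cn$kind == "frozen_angle") {
    u <- xyz[a[1], ] - xyz[a[2], ]; v <- xyz[a[3], ] - xyz[a[2], ]
    acos(max(-1, min(1, sum(u * v) /
                       sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  } else NA_real_
}

#' Minimize the potential energy, optionally under constraints
#'
#' Limited-memory quasi-Newton (L-BFGS-B) on the analytic gradient.
#' Constraints (\code{frozen_distance} in Angstrom, \code{frozen_angle} in
#' degrees, \code{frozen_dihedral} in degrees) are imposed through stiff
#' harmonic restraints whose stiffness escalates over stages
#' (1e3 to 1e6 kcal mol^-1 unit^-2), warm-starting each stage; restraint
#' energy is excluded from all reported energies. Convergence is judged on
#' the RMS of the unrestrained gradient projected orthogonal to the
#' constraint normals.
#'
#' @param sys a \code{molsys}
#' @param ff an \code{ffparams}
#' @param constraints list of constraint specs, each
#'   \code{list(kind=, atoms=, target=)}
#' @param tol RMS gradient tolerance (kcal mol^-1 A^-1)
#' @param maxit iteration cap per stage
#' @param stages override the restraint-stiffness escalation schedule
#' @param factr L-BFGS-B convergence factor (smaller = tighter)
#' @return list with \code{system} (optimized), \code{energy} (decomposed,
#'   restraints excluded), \code{grad_rms}, \code{converged},
#'   \code{constraint_dev} (max |deviation| from targets, A or deg)
#' @export
minimize <- function(sys, ff, constraints = list(), tol = 1e-4,
                     maxit = 5000, stages = NULL, factr = 10) {
  .check_cell(sys, ff)
  comp <- .compile(sys, ff)
  eng <- cpp_make_engine(comp)
  cell <- .cell_or_zero(sys)
  wall <- .wall_vec(sys)
  n <- nrow(sys$xyz)
  if (is.null(stages))
    stages <- if (length(constraints)) c(1e3, 1e4, 1e5, 1e6) else 1
  x <- as.vector(t(sys$xyz))
  for (k in stages) {
    fn <- function(p) {
      xm <- matrix(p, n, 3, byrow = TRUE)
      e <- cpp_energy_ptr(eng, xm, cell, wall, FALSE)$total
      if (length(constraints))
        e <- e + .restraints_eg(xm, constraints, k)$e
      e
    }
    gr <- function(p) {
      xm <- matrix(p, n, 3, byrow = TRUE)
      out <- cpp_energy_ptr(eng, xm, cell, wall, TRUE)
      g <- -out$forces
      if (length(constraints))
        g <- g + .restraints_eg(xm, constraints, k)$g
      as.vector(t(g))
    }
    res <- optim(x, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = factr, pgtol = 1e-8))
    x <- res$par
  }
  xm <- matrix(x, n, 3, byrow = TRUE)
  out <- cpp_energy_ptr(eng, xm, cell, wall, TRUE)
  g <- as.vector(t(-out$forces))
  # project out constraint normals before judging convergence
  if (length(constraints)) {
    B <- sapply(constraints, function(cn) {
      eg <- .restraints_eg(xm, list(modifyList(cn, list())), 1)
      # direction of the restraint gradient at unit stiffness
      as.vector(t(eg$g))
    })
    B <- matrix(B, ncol = length(constraints))
    keep <- colSums(B^2) > 1e-14
    if (any(keep)) {
      Q <- qr.Q(qr(B[, keep, drop = FALSE]))
      g <- g - Q %*% (t(Q) %*% g)
    }
  }
  grad_rms <- sqrt(mean(g^2))
  dev <- if (length(constraints)) {
    max(abs(vapply(constraints, function(cn)
      .constraint_value(xm, cn) - cn$target, 0)), na.rm = TRUE)
  } else 0
  sys$xyz <- xm
  list(system = sys,
       energy = cpp_energy_ptr(eng, xm, cell, wall, FALSE),
       grad_rms = grad_rms,
       converged = grad_rms < tol,
       constraint_dev = dev)
}

#' Harmonic vibrational frequencies by finite-difference normal modes
#'
#' Builds the Hessian by central finite differences of the analytic forces
#' (step 1e-3 A), symmetrizes, mass-weights, and diagonalizes. Negative
#' eigenvalues are reported as negative (imaginary) frequencies.
#'
#' @param sys a \code{molsys} at a stationary point
#' @param ff an \code{ffparams}
#' @param step finite-difference displacement (Angstrom)
#' @param grad_tol refuse if the RMS gradient exceeds this
#' @return list with \code{freq} (cm^-1, ascending; negative = imaginary),
#'   \code{modes} (mass-weighted eigenvectors, columns), \code{hessian_asym}
#'   (max asymmetry before symmetrization)
#' @export
normal_modes <- function(sys, ff, step = 1e-3, grad_tol = 1e-3) {
  comp <- .compile(sys, ff)
  eng <- cpp_make_engine(comp)
  cell <- .cell_or_zero(sys)
  wall <- .wall_vec(sys)
  n <- nrow(sys$xyz)
  g0 <- cpp_energy_ptr(eng, sys$xyz, cell, wall, TRUE)$forces
  if (sqrt(mean(g0^2)) > grad_tol)
    stop("system is not at a stationary point (RMS gradient ",
         signif(sqrt(mean(g0^2)), 3), " > ", grad_tol,
         "); minimize first")
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (m in 1:3) {
    xp <- sys$xyz; xp[i, m] <- xp[i, m] + step
    xm <- sys$xyz; xm[i, m] <- xm[i, m] - step
    fp <- cpp_energy_ptr(eng, xp, cell, wall, TRUE)$forces
    fm <- cpp_energy_ptr(eng, xm, cell, wall, TRUE)$forces
    # d(grad)/dx = -d(force)/dx
    H[, 3 * (i - 1) + m] <- as.vector(t(-(fp - fm) / (2 * step)))
  }
  asym <- max(abs(H - t(H)))
  H <- (H + t(H)) / 2
  invsm <- rep(1 / sqrt(sys$mass), each = 3)
  Hmw <- H * outer(invsm, invsm)
  ev <- eigen(Hmw, symmetric = TRUE)
  lam <- rev(ev$values)              # ascending
  vec <- ev$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  freq <- sign(lam) * sqrt(abs(lam) * .KCAL_AKMA) / (2 * pi * .C_CMPS)
  list(freq = freq, modes = vec, hessian_asym = asym)
}

#' Relaxed scan of the CO2 carbon to MEA nitrogen distance
#'
#' At each grid distance the C(CO2)-N(MEA) separation is frozen and all other
#' degrees of freedom relaxed; energies are reported relative to the profile
#' minimum. Consecutive points are warm-started from the previous relaxed
#' geometry. Points that fail to converge are flagged and the scan continues.
#'
#' @param sys a CO2 + MEA two-molecule \code{molsys} (e.g. from
#'   \code{build_dimer("co2_amino")})
#' @param ff an \code{ffparams}
#' @param grid strictly monotone vector of C-N distances in (1.5, 6.0) A
#' @return object of class \code{scan_result}: data.frame \code{profile}
#'   (r, energy, rel_energy, converged), \code{r_min} (grid point of minimum
#'   energy), \code{geometries} (list of relaxed systems)
#' @export
scan_rcn <- function(sys, ff, grid = seq(2.0, 4.0, by = 0.1)) {
  stopifnot(all(diff(grid) > 0) || all(diff(grid) < 0))
  if (any(grid <= 1.5 | grid >= 6.0)) stop("grid must lie within (1.5, 6) A")
  iC <- which(sys$classes == "C_co2")
  iN <- which(sys$classes == "N_amine")
  if (length(iC) != 1 || length(iN) != 1)
    stop("system must contain exactly one CO2 carbon and one amine nitrogen")
  cur <- sys
  E <- numeric(length(grid)); conv <- logical(length(grid))
  geoms <- vector("list", length(grid))
  # walk from the grid point closest to the current separation outward
  r_now <- sqrt(sum((sys$xyz[iC, ] - sys$xyz[iN, ])^2))
  ord <- order(abs(grid - r_now))
  first <- ord[1]
  idx_order <- c(seq(first, length(grid)), rev(seq_len(first - 1)))
  for (pass in 1:2) {
    run <- if (pass == 1) seq(first, length(grid)) else
      rev(seq_len(first - 1))
    cur <- sys
    for (i in run) {
      # move the CO2 along the C-N axis to the target distance first
      d <- cur$xyz[iC, ] - cur$xyz[iN, ]
      r0 <- sqrt(sum(d * d))
      shift <- (grid[i] / r0 - 1) * d
      co2_atoms <- which(cur$mol == cur$mol[iC])
      cur$xyz[co2_atoms, ] <- sweep(cur$xyz[co2_atoms, , drop = FALSE],
                                    2, shift, "+")
      res <- minimize(cur, ff, constraints = list(
        list(kind = "frozen_distance", atoms = c(iC, iN),
             target = grid[i])))
      E[i] <- res$energy$total
      conv[i] <- res$converged && res$constraint_dev < 1e-3
      geoms[[i]] <- res$system
      cur <- res$system
    }
  }
  rel <- E - min(E[conv | !any(conv)])
  out <- list(profile = data.frame(r = grid, energy = E, rel_energy = rel,
                                   converged = conv),
              r_min = grid[which.min(E)], geometries = geoms)
  class(out) <- "scan_result"
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Relaxed distance scan:", nrow(x$profile), "points, minimum at r =",
      x$r_min, "A\n")
  invisible(x)
}
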