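## Programmatic generation of every structure used by the study protocols:
## monomers, characteristic dimers, clusters, liquid boxes and the gas-liquid
## interfacial composite.

## NeRF-style placement: position of a new atom at distance r from A, angle
## theta (deg) to B, dihedral phi (deg) to C.
.place <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  ab <- A - B; ab <- ab / sqrt(sum(ab^2))
  cb <- C - B
  n <- c(cb[2] * ab[3] - cb[3] * ab[2],
         cb[3] * ab[1] - cb[1] * ab[3],
         cb[1] * ab[2] - cb[2] * ab[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * ab[3] - n[3] * ab[2],
         n[3] * ab[1] - n[1] * ab[3],
         n[1] * ab[2] - n[2] * ab[1])
  d <- c(-r * cos(th), -r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  A + d[1] * ab + d[2] * m + d[3] * n
}

.ff_r0 <- function(ff, key) ff$bonds$r0[.ff_bond_row(ff, key)]

#' Build a monomer at force-field equilibrium internal coordinates
#'
#' CO2 is exactly linear with two equal C=O bonds. MEA
#' (HO-CH2-CH2-NH2, 11 atoms) is constructed from a z-matrix at the
#' parameter set's equilibrium bond lengths and angles in one of two
#' conformers: \code{"trans"} (anti O-C-C-N backbone) or
#' \code{"gauche_intraHB"} (gauche backbone with the hydroxyl H directed at
#' the amine N, the intramolecular-hydrogen-bond geometry).
#'
#' @param species \code{"CO2"} or \code{"MEA"}
#' @param conformer MEA conformer name (ignored for CO2)
#' @param ff parameter set supplying equilibrium values
#' @return a \code{molsys}
#' @export
build_monomer <- function(species = c("CO2", "MEA"),
                          conformer = c("gauche_intraHB", "trans"),
                          ff = mm_parameters()) {
  species <- match.arg(species)
  if (species == "CO2") {
    r0 <- .ff_r0(ff, "C_co2:O_co2")
    xyz <- rbind(c(0, 0, 0), c(r0, 0, 0), c(-r0, 0, 0))
    return(molecular_system(c("C_co2", "O_co2", "O_co2"), xyz,
                            rbind(c(1, 2), c(1, 3))))
  }
  conformer <- match.arg(conformer)
  rOH <- .ff_r0(ff, "O_hydroxyl:H_O"); rCO <- .ff_r0(ff, "C_sp3:O_hydroxyl")
  rCC <- .ff_r0(ff, "C_sp3:C_sp3");   rCN <- .ff_r0(ff, "C_sp3:N_amine")
  rNH <- .ff_r0(ff, "N_amine:H_N");   rCH <- .ff_r0(ff, "C_sp3:H_C")
  # backbone dihedrals per conformer
  if (conformer == "trans") {
    tOCCN <- 180; tHOCC <- 180
  } else {
    tOCCN <- 55; tHOCC <- -45
  }
  xyz <- matrix(0, 11, 3)
  # order: O1 H2 C3 H4 H5 C6 H7 H8 N9 H10 H11
  xyz[1, ] <- c(0, 0, 0)                       # O1
  xyz[3, ] <- c(rCO, 0, 0)                     # C3
  xyz[6, ] <- .place(xyz[3, ], xyz[1, ], c(0, 0, 1), rCC, 109.5, 90)  # C6
  xyz[2, ] <- .place(xyz[1, ], xyz[3, ], xyz[6, ], rOH, 108.5, tHOCC) # H2
  xyz[9, ] <- .place(xyz[6, ], xyz[3, ], xyz[1, ], rCN, 109.5, tOCCN) # N9
  xyz[4, ] <- .place(xyz[3, ], xyz[6, ], xyz[9, ],
                     rCH, 109.5, 120 + tOCCN)                          # H4
  xyz[5, ] <- .place(xyz[3, ], xyz[6, ], xyz[9, ],
                     rCH, 109.5, -120 + tOCCN)                         # H5
  xyz[7, ] <- .place(xyz[6, ], xyz[3, ], xyz[1, ], rCH, 109.5,
                     tOCCN + 120)                                      # H7
  xyz[8, ] <- .place(xyz[6, ], xyz[3, ], xyz[1, ], rCH, 109.5,
                     tOCCN - 120)                                      # H8
  xyz[10, ] <- .place(xyz[9, ], xyz[6, ], xyz[3, ], rNH, 109.5, 60)   # H10
  xyz[11, ] <- .place(xyz[9, ], xyz[6, ], xyz[3, ], rNH, 109.5, 180)  # H11
  cls <- c("O_hydroxyl", "H_O", "C_sp3", "H_C", "H_C", "C_sp3", "H_C",
           "H_C", "N_amine", "H_N", "H_N")
  bonds <- rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5), c(3, 6), c(6, 7),
                 c(6, 8), c(6, 9), c(9, 10), c(9, 11))
  molecular_system(cls, xyz, bonds)
}

.rotmat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y)),
        c(2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x)),
        c(2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)))
}

.com <- function(sys, idx = seq_len(nrow(sys$xyz))) {
  m <- sys$mass[idx]
  colSums(sys$xyz[idx, , drop = FALSE] * m) / sum(m)
}

.transform <- function(sys, R = diag(3), shift = c(0, 0, 0)) {
  sys$xyz <- sys$xyz %*% t(R)
  sys$xyz <- sweep(sys$xyz, 2, shift, "+")
  if (!is.null(sys$vel)) sys$vel <- sys$vel %*% t(R)
  sys
}

## rotate `sys` so the unit vector `from` maps onto `to`
.align_rot <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- c(from[2]*to[3] - from[3]*to[2], from[3]*to[1] - from[1]*to[3],
         from[1]*to[2] - from[2]*to[1])
  c2 <- sum(from * to)
  if (c2 < -1 + 1e-12) return(diag(c(-1, -1, 1)))
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx / (1 + c2)
}

#' Build a characteristic dimer with its optimization constraints
#'
#' Arrangements:
#' \describe{
#'   \item{\code{min}}{(CO2)2 slipped-parallel start for the unconstrained
#'     global minimum; no constraints.}
#'   \item{\code{parallel}}{(CO2)2 with parallel axes; C-C distance frozen at
#'     4.0 A and both axis-to-axis angles at 90 degrees.}
#'   \item{\code{T}}{(CO2)2 T-shape; one molecular axis aimed at the other's
#'     carbon (collinearity frozen at 180 degrees) and perpendicularity of
#'     the target axis frozen at 90 degrees.}
#'   \item{\code{NHN}}{(MEA)2 amine-donor hydrogen bond, donor N-H...N angle
#'     frozen at 180 degrees.}
#'   \item{\code{OHO}}{(MEA)2 hydroxyl-donor hydrogen bond, donor O-H...O
#'     angle frozen at 180 degrees.}
#'   \item{\code{co2_amino}}{CO2 presented to the amine N of one MEA
#'     (unconstrained physisorption start).}
#'   \item{\code{co2_hydroxyl}}{CO2 presented to the hydroxyl O
#'     (unconstrained).}
#' }
#'
#' @param arrangement one of the labels above
#' @param ff parameter set used for the monomer geometries
#' @return list with \code{system} (a two-molecule \code{molsys}) and
#'   \code{constraints} (list of constraint specs for \code{\link{minimize}})
#' @export
build_dimer <- function(arrangement = c("min", "parallel", "T", "NHN", "OHO",
                                        "co2_amino", "co2_hydroxyl"),
                        ff = mm_parameters()) {
  arrangement <- match.arg(arrangement)
  if (arrangement %in% c("min", "parallel", "T")) {
    a <- build_monomer("CO2", ff = ff)
    b <- build_monomer("CO2", ff = ff)
    if (arrangement == "min") {
      b <- .transform(b, shift = c(1.8, 3.0, 0))
      sys <- combine_systems(a, b)
      return(list(system = sys, constraints = list()))
    }
    if (arrangement == "parallel") {
      b <- .transform(b, shift = c(0, 4.0, 0))
      sys <- combine_systems(a, b)
      cons <- list(
        list(kind = "frozen_distance", atoms = c(1, 4), target = 4.0),
        list(kind = "frozen_angle", atoms = c(2, 1, 4), target = 90),
        list(kind = "frozen_angle", atoms = c(5, 4, 1), target = 90))
      return(list(system = sys, constraints = cons))
    }
    # T-type: molecule b perpendicular, axis through a's carbon
    b <- .transform(b, .align_rot(c(1, 0, 0), c(0, 1, 0)),
                    shift = c(0, 3.5, 0))
    sys <- combine_systems(a, b)
    cons <- list(
      list(kind = "frozen_angle", atoms = c(5, 4, 1), target = 180),
      list(kind = "frozen_angle", atoms = c(2, 1, 4), target = 90))
    return(list(system = sys, constraints = cons))
  }
  if (arrangement %in% c("NHN", "OHO")) {
    a <- build_monomer("MEA", "trans", ff = ff)
    b <- build_monomer("MEA", "trans", ff = ff)
    if (arrangement == "NHN") {
      don <- c(9, 10)     # N9 - H10 of molecule a
      acc <- 9            # N9 of molecule b
      rHA <- 2.1
    } else {
      don <- c(1, 2)      # O1 - H2 of molecule a
      acc <- 1            # O1 of molecule b
      rHA <- 1.85
    }
    dvec <- a$xyz[don[2], ] - a$xyz[don[1], ]
    dvec <- dvec / sqrt(sum(dvec^2))
    target <- a$xyz[don[2], ] + rHA * dvec
    # orient b so its acceptor lone-pair side faces the donor: align the
    # acceptor's bond-average direction against the donor axis
    nb <- b$bonds[b$bonds[, 1] == acc | b$bonds[, 2] == acc, , drop = FALSE]
    partners <- setdiff(unique(as.vector(nb)), acc)
    lp <- -colMeans(b$xyz[partners, , drop = FALSE] -
                      matrix(b$xyz[acc, ], length(partners), 3, byrow = TRUE))
    b <- .transform(b, .align_rot(lp, -dvec))
    b <- .transform(b, shift = target - b$xyz[acc, ])
    sys <- combine_systems(a, b)
    cons <- list(list(kind = "frozen_angle",
                      atoms = c(don[1], don[2], acc + 11), target = 180))
    return(list(system = sys, constraints = cons))
  }
  # CO2 presented to a binding motif of the intraHB MEA conformer; the
  # carbon-to-site distance is frozen at the physisorption distance so each
  # arrangement stays in its own basin (drop the constraint for a free
  # relaxation)
  mea <- build_monomer("MEA", "gauche_intraHB", ff = ff)
  co2 <- build_monomer("CO2", ff = ff)
  site <- if (arrangement == "co2_amino") 9 else 1
  nb <- mea$bonds[mea$bonds[, 1] == site | mea$bonds[, 2] == site,
                  , drop = FALSE]
  partners <- setdiff(unique(as.vector(nb)), site)
  lp <- -colMeans(mea$xyz[partners, , drop = FALSE] -
                    matrix(mea$xyz[site, ], length(partners), 3, byrow = TRUE))
  lp <- lp / sqrt(sum(lp^2))
  # CO2 axis roughly perpendicular to the approach direction
  co2 <- .transform(co2, .align_rot(c(1, 0, 0),
                                    if (abs(lp[1]) < 0.9) c(1, 0, 0) else
                                      c(0, 1, 0)))
  perp <- co2$xyz[2, ] - co2$xyz[1, ]
  perp <- perp - sum(perp * lp) * lp
  if (sqrt(sum(perp^2)) > 1e-6)
    co2 <- .transform(co2, .align_rot(co2$xyz[2, ] - co2$xyz[1, ],
                                      perp / sqrt(sum(perp^2))))
  co2 <- .transform(co2, shift = mea$xyz[site, ] + 2.7 * lp - co2$xyz[1, ])
  sys <- combine_systems(mea, co2)
  iC <- which(sys$classes == "C_co2")
  cons <- list(list(kind = "frozen_distance", atoms = c(iC, site),
                    target = 2.7))
  list(system = sys, constraints = cons)
}

.random_unit_quat <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

.min_interdist_ok <- function(xyz_new, xyz_all, min_dist, cell = NULL) {
  if (is.null(xyz_all) || nrow(xyz_all) == 0) return(TRUE)
  for (i in seq_len(nrow(xyz_new))) {
    d <- sweep(xyz_all, 2, xyz_new[i, ], "-")
    if (!is.null(cell))
      d <- d - sweep(round(sweep(d, 2, cell, "/")), 2, cell, "*")
    if (min(rowSums(d * d)) < min_dist^2) return(FALSE)
  }
  TRUE
}

#' Pack a spherical cluster of rigid monomers
#'
#' Random sequential insertion of monomer copies with uniformly random
#' positions inside the sphere and uniformly random orientations, rejecting
#' insertions that put any atom within \code{min_dist} of an existing atom.
#' A one-sided harmonic spherical wall is attached. Deterministic for a given
#' seed.
#'
#' @param species \code{"CO2"} or \code{"MEA"}
#' @param count number of molecules
#' @param radius sphere radius (Angstrom)
#' @param seed RNG seed
#' @param min_dist minimum intermolecular atom-atom distance (Angstrom)
#' @param wall_k wall stiffness (kcal mol^-1 A^-2)
#' @param conformer MEA conformer
#' @param ff parameter set
#' @param max_tries insertion attempts per molecule before failing
#' @return a \code{molsys} with wall attached
#' @export
pack_cluster <- function(species, count, radius, seed = 1, min_dist = 2.0,
                         wall_k = 100, conformer = "gauche_intraHB",
                         ff = mm_parameters(), max_tries = 2000) {
  set.seed(seed)
  mono <- build_monomer(species, conformer, ff = ff)
  mono$xyz <- sweep(mono$xyz, 2, .com(mono), "-")
  sys <- NULL
  placed <- 0
  # candidate sites: jittered cubic sublattice inside the sphere, visited in
  # random order, with random insertion as a top-up
  for (npl in 2:12) {
    if (npl^3 < count) next
    a <- 2 * radius / npl
    g <- seq(-radius + a / 2, radius - a / 2, length.out = npl)
    sites <- as.matrix(expand.grid(g, g, g))
    sites <- sites[sqrt(rowSums(sites^2)) <= radius - a / 4, , drop = FALSE]
    if (nrow(sites) >= count) break
  }
  sites <- sites[sample.int(nrow(sites)), , drop = FALSE]
  si <- 1
  tries <- 0
  while (placed < count && tries < max_tries) {
    tries <- tries + 1
    pos <- if (si <= nrow(sites)) {
      p <- sites[si, ] + runif(3, -0.1, 0.1); si <- si + 1; p
    } else {
      p <- c(Inf, Inf, Inf)
      while (sum(p^2) > radius^2) p <- (2 * runif(3) - 1) * radius
      p
    }
    cand <- .transform(mono, .rotmat(.random_unit_quat()), shift = pos)
    if (.min_interdist_ok(cand$xyz,
                          if (is.null(sys)) NULL else sys$xyz, min_dist)) {
      sys <- if (is.null(sys)) cand else combine_systems(sys, cand)
      placed <- placed + 1
    }
  }
  if (placed < count)
    stop("packing failed after ", max_tries,
         " tries; increase the radius")
  sys$wall <- list(center = c(0, 0, 0), radius = radius, k = wall_k)
  sys
}

#' Best packed-and-minimized cluster over several packing seeds
#'
#' Packs \code{restarts} clusters from consecutive seeds, relaxes each to a
#' local minimum, and returns the lowest-energy structure. This is the
#' cheap basin-search used to prepare a crystalline cluster start for
#' heat-capacity scans: a single packed configuration relaxes to a glassy
#' local minimum, whose melting behavior is not the solid's.
#'
#' @inheritParams pack_cluster
#' @param restarts number of packing seeds tried
#' @return a \code{molsys} at the best minimum found, wall attached
#' @export
pack_cluster_annealed <- function(species, count, radius, seed = 1,
                                  min_dist = 2.0, wall_k = 100,
                                  conformer = "gauche_intraHB",
                                  ff = mm_parameters(), restarts = 8,
                                  cycles = 6, T_anneal = 70) {
  best <- NULL
  for (s in seq(seed, seed + restarts - 1)) {
    cl <- pack_cluster(species, count, radius, seed = s,
                       min_dist = min_dist, wall_k = wall_k,
                       conformer = conformer, ff = ff)
    res <- minimize(cl, ff, maxit = 3000, factr = 100)
    if (is.null(best) || res$energy$total < best$energy$total) best <- res
  }
  # thermal basin hopping: heat, run briefly, quench; keep improvements
  for (cy in seq_len(cycles)) {
    sys <- initialize_velocities(best$system, T_anneal, seed = seed + 1000 + cy)
    traj <- run_md(sys, ff, steps = 20000, thermostat = list(T = T_anneal),
                   stride = 20000)
    res <- minimize(traj$final, ff, maxit = 3000, factr = 100)
    if (res$energy$total < best$energy$total) best <- res
  }
  best$system
}

#' Pack a periodic liquid box at a target density
#'
#' A cubic cell with edge set by \code{(count * M / density)^(1/3)} is filled
#' by random sequential insertion with minimum-image distance rejection.
#'
#' @param species \code{"CO2"} or \code{"MEA"}
#' @param count number of molecules
#' @param density target mass density in g/cm^3
#' @param seed RNG seed
#' @param min_dist minimum intermolecular atom-atom distance (Angstrom)
#' @param conformer MEA conformer
#' @param ff parameter set
#' @param max_tries insertion attempts per molecule
#' @return a periodic \code{molsys}
#' @export
pack_liquid_box <- function(species, count, density = 1.01, seed = 1,
                            min_dist = 2.0, conformer = "gauche_intraHB",
                            ff = mm_parameters(), max_tries = 5000) {
  set.seed(seed)
  mono <- build_monomer(species, conformer, ff = ff)
  mono$xyz <- sweep(mono$xyz, 2, .com(mono), "-")
  mmass <- sum(mono$mass)
  # amu/A^3 -> g/cm^3 conversion factor is 1/0.602214
  edge <- (count * mmass * 1.660539 / density)^(1 / 3)
  cell <- rep(edge, 3)
  # jittered cubic sublattice: dense liquids are not reachable by random
  # sequential insertion
  npl <- ceiling(count^(1 / 3))
  a <- edge / npl
  g <- seq(a / 2, edge - a / 2, length.out = npl)
  sites <- as.matrix(expand.grid(g, g, g))
  sites <- sites[sample.int(nrow(sites))[seq_len(count)], , drop = FALSE]
  sys <- NULL
  for (m in seq_len(count)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      pos <- sites[m, ] + runif(3, -0.15 * a, 0.15 * a)
      cand <- .transform(mono, .rotmat(.random_unit_quat()), shift = pos)
      if (.min_interdist_ok(cand$xyz,
                            if (is.null(sys)) NULL else sys$xyz, min_dist,
                            cell = cell)) {
        sys <- if (is.null(sys)) cand else combine_systems(sys, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("box packing failed after ", max_tries,
                  " tries; lower the density or min_dist")
  }
  sys$cell <- cell
  sys
}

#' Carve a spherical cavity out of a periodic box
#'
#' Removes every molecule whose center of mass lies within \code{radius} of
#' the cell center (minimum image); velocities of the survivors are kept.
#'
#' @param sys a periodic \code{molsys}
#' @param radius cavity radius (Angstrom), must not exceed half the smallest
#'   cell edge
#' @return list with \code{system} (the reduced system) and \code{removed}
#'   (number of molecules removed)
#' @export
carve_cavity <- function(sys, radius = 9.5) {
  if (is.null(sys$cell)) stop("carve_cavity needs a periodic box")
  if (radius > min(sys$cell) / 2)
    stop("cavity radius exceeds half the cell edge")
  ctr <- sys$cell / 2
  keep <- integer(0)
  for (m in seq_len(n_molecules(sys))) {
    com <- .com(sys, which(sys$mol == m))
    d <- com - ctr
    d <- d - round(d / sys$cell) * sys$cell
    if (sqrt(sum(d * d)) >= radius) keep <- c(keep, m)
  }
  out <- subset_molecules(sys, keep)
  out$cell <- sys$cell
  list(system = out, removed = n_molecules(sys) - length(keep))
}

#' Merge a gas cluster into a carved liquid box
#'
#' Centers the cluster's center of mass at the cell center of the carved box,
#' strips the cluster's wall, concatenates topology and carries velocities
#' over from both parents. Fails listing the offending pairs if any
#' cluster-box atom distance falls below \code{min_dist}.
#'
#' @param cluster a \code{molsys} (typically from \code{\link{pack_cluster}})
#' @param carved a periodic \code{molsys} with a cavity
#' @param min_dist steric clash threshold (Angstrom)
#' @return a combined periodic \code{molsys}
#' @export
merge_interface <- function(cluster, carved, min_dist = 1.6) {
  if (is.null(carved$cell)) stop("merge_interface needs a periodic box")
  cluster$wall <- NULL
  cluster <- .transform(cluster,
                        shift = carved$cell / 2 - .com(cluster))
  ncl <- nrow(cluster$xyz)
  sys <- combine_systems(cluster, carved, cell = carved$cell, wall = NULL)
  # clash check, minimum image
  bad <- NULL
  for (i in seq_len(ncl)) {
    d <- sweep(carved$xyz, 2, cluster$xyz[i, ], "-")
    d <- d - sweep(round(sweep(d, 2, carved$cell, "/")), 2, carved$cell, "*")
    r2 <- rowSums(d * d)
    j <- which(r2 < min_dist^2)
    if (length(j)) bad <- rbind(bad, cbind(i, ncl + j, sqrt(r2[j])))
  }
  if (!is.null(bad))
    stop("steric clash after merge between atom pairs: ",
         paste(apply(bad, 1, function(r)
           sprintf("%d-%d (%.2f A)", r[1], r[2], r[3])), collapse = ", "))
  sys
}
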