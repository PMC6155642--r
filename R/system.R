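## MolecularSystem: topology + coordinates (+ velocities, cell, wall).

#' Construct a molecular system
#'
#' Builds a \code{molsys} object from atom classes, coordinates and a bond
#' list. Angles and torsions are enumerated from the bond graph; molecules are
#' its connected components.
#'
#' @param classes character vector of atom classes (one of the enumerated set)
#' @param xyz N x 3 numeric matrix of positions (Angstrom)
#' @param bonds 2-column integer matrix of bonded atom index pairs
#' @param cell optional numeric(3) orthorhombic cell edge lengths (Angstrom)
#' @param wall optional list(center = numeric(3), radius, k) one-sided
#'   harmonic spherical confinement, \code{E = k (r - radius)^2} outside
#' @param vel optional N x 3 velocity matrix (Angstrom/ps)
#' @return object of class \code{molsys} with fields \code{classes},
#'   \code{element}, \code{mass}, \code{xyz}, \code{bonds}, \code{angles},
#'   \code{torsions}, \code{mol}, \code{cell}, \code{wall}, \code{vel}
#' @export
molecular_system <- function(classes, xyz, bonds, cell = NULL, wall = NULL,
                             vel = NULL) {
  xyz <- as.matrix(xyz)
  n <- length(classes)
  stopifnot(nrow(xyz) == n, ncol(xyz) == 3)
  el <- .class_element(classes)
  mass <- .class_mass(classes)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > n))
    stop("bond list references invalid atom indices")
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    if (i == j) stop("self-bond at atom ", i)
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  # angles: every pair of neighbors of a central atom
  ang <- list()
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      for (k in seq_len(ncol(cmb)))
        ang[[length(ang) + 1L]] <- c(cmb[1, k], j, cmb[2, k])
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else
    matrix(integer(0), ncol = 3)
  # torsions: i-j-k-l over every central bond j-k
  tor <- list()
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j))
      if (i != l) tor[[length(tor) + 1L]] <- c(i, j, k, l)
  }
  torsions <- if (length(tor)) do.call(rbind, tor) else
    matrix(integer(0), ncol = 4)
  # molecules: connected components
  mol <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (mol[s] == 0L) {
      cur <- cur + 1L
      stack <- s
      while (length(stack)) {
        a <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        if (mol[a] == 0L) {
          mol[a] <- cur
          stack <- c(stack, adj[[a]][mol[adj[[a]]] == 0L])
        }
      }
    }
  }
  if (!is.null(cell)) stopifnot(length(cell) == 3, all(cell > 0))
  sys <- list(classes = classes, element = el, mass = mass, xyz = xyz,
              bonds = bonds, angles = angles, torsions = torsions,
              mol = mol, cell = cell, wall = wall, vel = vel)
  class(sys) <- "molsys"
  sys
}

#' @export
print.molsys <- function(x, ...) {
  cat("Molecular system: ", nrow(x$xyz), " atoms, ", max(0, x$mol),
      " molecule(s), ", nrow(x$bonds), " bonds\n", sep = "")
  if (!is.null(x$cell))
    cat("  periodic cell: ", paste(signif(x$cell, 6), collapse = " x "),
        " A\n", sep = "")
  if (!is.null(x$wall))
    cat("  spherical wall: R = ", x$wall$radius, " A, k = ", x$wall$k,
        "\n", sep = "")
  invisible(x)
}

#' Number of molecules in a system
#' @param sys a \code{molsys}
#' @return integer count
#' @export
n_molecules <- function(sys) if (length(sys$mol)) max(sys$mol) else 0L

#' Concatenate two molecular systems
#'
#' Topologies are concatenated with shifted indices; the cell/wall of the
#' first system is kept unless overridden.
#' @param a,b \code{molsys} objects
#' @param cell,wall overrides for the combined system
#' @return a \code{molsys}
#' @export
combine_systems <- function(a, b, cell = a$cell, wall = a$wall) {
  off <- nrow(a$xyz)
  vel <- if (!is.null(a$vel) && !is.null(b$vel)) rbind(a$vel, b$vel) else NULL
  molecular_system(c(a$classes, b$classes), rbind(a$xyz, b$xyz),
                   rbind(a$bonds, b$bonds + off), cell = cell, wall = wall,
                   vel = vel)
}

## Compile a system + parameters into the flat argument list used by the
## C++ engine. Numeric indices are 0-based on the C++ side.
.compile <- function(sys, ff) {
  validate_ff(ff)
  n <- nrow(sys$xyz)
  cls <- match(sys$classes, ff$atoms$class)
  if (anyNA(cls)) stop("no LJ parameters for atom class: ",
                       paste(unique(sys$classes[is.na(cls)]), collapse = ", "))
  # bonds
  nb <- nrow(sys$bonds)
  bks <- br0 <- bmu <- numeric(nb)
  bsign <- rep(1, nb)
  for (b in seq_len(nb)) {
    ci <- sys$classes[sys$bonds[b, 1]]; cj <- sys$classes[sys$bonds[b, 2]]
    key <- bond_class(ci, cj)
    r <- .ff_bond_row(ff, key)
    bks[b] <- ff$bonds$ks[r]; br0[b] <- ff$bonds$r0[r]
    bmu[b] <- ff$bonds$mu[r]
    # canonical key direction vs stored atom order
    first <- strsplit(key, ":")[[1]][1]
    bsign[b] <- if (ci == first) 1 else -1
  }
  # angles
  na <- nrow(sys$angles)
  akb <- ath <- numeric(na)
  for (a in seq_len(na)) {
    key <- .angle_class(sys$classes[sys$angles[a, 1]],
                        sys$classes[sys$angles[a, 2]],
                        sys$classes[sys$angles[a, 3]])
    r <- match(key, ff$angles$class)
    if (is.na(r)) stop("no angle parameters for class: ", key)
    akb[a] <- ff$angles$kb[r]; ath[a] <- ff$angles$theta0[r] * pi / 180
  }
  # torsions (wildcard on the central bond; silently zero if no record)
  nt <- nrow(sys$torsions)
  tv <- matrix(0, nrow = max(nt, 0), ncol = 3)
  keep <- logical(nt)
  for (t in seq_len(nt)) {
    key <- .torsion_class(sys$classes[sys$torsions[t, 2]],
                          sys$classes[sys$torsions[t, 3]])
    r <- match(key, ff$torsions$class)
    if (!is.na(r)) {
      tv[t, ] <- as.numeric(ff$torsions[r, c("V1", "V2", "V3")])
      keep[t] <- any(tv[t, ] != 0)
    }
  }
  tors <- sys$torsions[keep, , drop = FALSE]
  tv <- tv[keep, , drop = FALSE]
  # dipoles: one per polar bond (mu != 0), direction canonical-first ->
  # canonical-second mapped onto stored atom order via bsign
  dip <- which(bmu != 0)
  dmu <- bmu[dip] * bsign[dip]
  dij <- sys$bonds[dip, , drop = FALSE]
  # 1-2/1-3 LJ exclusions as a sorted pair key vector
  adj <- vector("list", n)
  for (b in seq_len(nb)) {
    i <- sys$bonds[b, 1]; j <- sys$bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  exk <- character(0)
  for (b in seq_len(nb)) {
    i <- sys$bonds[b, 1]; j <- sys$bonds[b, 2]
    exk <- c(exk, paste(min(i, j), max(i, j)))
  }
  for (j in seq_len(n)) {
    nbr <- adj[[j]]
    if (length(nbr) >= 2) {
      cmb <- utils::combn(sort(nbr), 2)
      exk <- c(exk, paste(cmb[1, ], cmb[2, ]))
    }
  }
  exk <- unique(exk)
  exm <- do.call(rbind, strsplit(exk, " "))
  ex_i <- as.integer(exm[, 1]); ex_j <- as.integer(exm[, 2])
  list(
    n = n, mass = sys$mass, cls = cls - 1L,
    lj_rv = ff$atoms$rv, lj_eps = ff$atoms$eps,
    b_i = sys$bonds[, 1] - 1L, b_j = sys$bonds[, 2] - 1L,
    b_ks = bks, b_r0 = br0,
    a_i = sys$angles[, 1] - 1L, a_j = sys$angles[, 2] - 1L,
    a_k = sys$angles[, 3] - 1L, a_kb = akb, a_th = ath,
    t_i = tors[, 1] - 1L, t_j = tors[, 2] - 1L,
    t_k = tors[, 3] - 1L, t_l = tors[, 4] - 1L,
    t_v = tv,
    d_i = dij[, 1] - 1L, d_j = dij[, 2] - 1L, d_mu = dmu,
    ex_i = ex_i - 1L, ex_j = ex_j - 1L,
    mol = sys$mol - 1L,
    dielectric = ff$dielectric, cut_vdw = ff$cut_vdw,
    cut_dip = ff$cut_dip, taper = ff$taper)
}

.cell_or_zero <- function(sys) if (is.null(sys$cell)) c(0, 0, 0) else sys$cell

.wall_vec <- function(sys) {
  if (is.null(sys$wall)) c(0, 0, 0, -1, 0)
  else c(sys$wall$center, sys$wall$radius, sys$wall$k)
}

.check_cell <- function(sys, ff) {
  if (!is.null(sys$cell) && any(sys$cell < 2 * ff$cut_vdw))
    stop("periodic cell edge smaller than twice the vdW cutoff (",
         paste(signif(sys$cell, 5), collapse = ", "), " vs cutoff ",
         ff$cut_vdw, " A)")
}
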