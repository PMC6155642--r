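# Independent brute-force energy evaluator used as the oracle for the
# compiled engine: plain double loops over all interactions, written against
# the model definition only (no neighbor lists, no shared code paths).

oracle_taper <- function(r, rcut, w) {
  if (r <= rcut - w) return(1)
  if (r >= rcut) return(0)
  t <- (r - (rcut - w)) / w
  1 - t^2 * (3 - 2 * t)
}

oracle_minimg <- function(d, cell) {
  if (is.null(cell)) return(d)
  d - round(d / cell) * cell
}

oracle_angle <- function(u, v) {
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                         a[1]*b[2]-a[2]*b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  atan2(sum(cr(n1, b2) * n2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

# full potential-energy decomposition by exhaustive loops
oracle_energy <- function(sys, ff) {
  K <- unname(co2mea::mm_constants()["kdip"])
  x <- sys$xyz; cell <- sys$cell
  n <- nrow(x)
  cls <- sys$classes
  e <- c(stretch = 0, bend = 0, torsion = 0, lj = 0, dipole = 0, wall = 0)

  # bonded terms
  bpar <- function(ci, cj) ff$bonds[match(co2mea::bond_class(ci, cj),
                                          ff$bonds$class), ]
  for (b in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds[b, 1]; j <- sys$bonds[b, 2]
    p <- bpar(cls[i], cls[j])
    d <- oracle_minimg(x[i, ] - x[j, ], cell)
    e["stretch"] <- e["stretch"] + p$ks * (sqrt(sum(d^2)) - p$r0)^2
  }
  for (a in seq_len(nrow(sys$angles))) {
    i <- sys$angles[a, 1]; j <- sys$angles[a, 2]; k <- sys$angles[a, 3]
    ends <- sort(match(cls[c(i, k)], names(co2mea:::.CLASSES)))
    key <- paste(names(co2mea:::.CLASSES)[ends[1]], cls[j],
                 names(co2mea:::.CLASSES)[ends[2]], sep = ":")
    row <- match(key, ff$angles$class)
    th <- oracle_angle(oracle_minimg(x[i, ] - x[j, ], cell),
                       oracle_minimg(x[k, ] - x[j, ], cell))
    e["bend"] <- e["bend"] +
      ff$angles$kb[row] * (th - ff$angles$theta0[row] * pi / 180)^2
  }
  for (t in seq_len(nrow(sys$torsions))) {
    q <- sys$torsions[t, ]
    key <- paste("X", co2mea::bond_class(cls[q[2]], cls[q[3]]), "X",
                 sep = ":")
    row <- match(key, ff$torsions$class)
    if (is.na(row)) next
    phi <- oracle_dihedral(x[q[1], ], x[q[2], ], x[q[3], ], x[q[4], ])
    V <- as.numeric(ff$torsions[row, c("V1", "V2", "V3")])
    e["torsion"] <- e["torsion"] + V[1]/2*(1+cos(phi)) +
      V[2]/2*(1-cos(2*phi)) + V[3]/2*(1+cos(3*phi))
  }

  # exclusion map: 1-2 and 1-3
  excl <- matrix(FALSE, n, n)
  adj <- vector("list", n)
  for (b in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds[b, 1]; j <- sys$bonds[b, 2]
    excl[i, j] <- excl[j, i] <- TRUE
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) for (p in utils::combn(nb, 2, simplify = FALSE))
      excl[p[1], p[2]] <- excl[p[2], p[1]] <- TRUE
  }

  # Lennard-Jones
  arow <- function(ci) match(ci, ff$atoms$class)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (excl[i, j]) next
    d <- oracle_minimg(x[i, ] - x[j, ], cell)
    r <- sqrt(sum(d^2))
    if (r >= ff$cut_vdw) next
    rm <- ff$atoms$rv[arow(cls[i])] + ff$atoms$rv[arow(cls[j])]
    eps <- sqrt(ff$atoms$eps[arow(cls[i])] * ff$atoms$eps[arow(cls[j])])
    e["lj"] <- e["lj"] + eps * ((rm / r)^12 - 2 * (rm / r)^6) *
      oracle_taper(r, ff$cut_vdw, ff$taper)
  }

  # bond-centered dipoles: direction along the canonical class order
  dip <- list()
  for (b in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds[b, 1]; j <- sys$bonds[b, 2]
    key <- co2mea::bond_class(cls[i], cls[j])
    mu <- ff$bonds$mu[match(key, ff$bonds$class)]
    if (mu == 0) next
    if (strsplit(key, ":")[[1]][1] != cls[i]) mu <- -mu
    dip[[length(dip) + 1]] <- list(i = i, j = j, mu = mu)
  }
  cutd <- ff$cut_dip
  if (!is.null(cell)) cutd <- min(cutd, min(cell) / 2 * (1 - 1e-9))
  nd <- length(dip)
  if (nd >= 2) for (a in seq_len(nd - 1)) for (b in (a + 1):nd) {
    d1 <- dip[[a]]; d2 <- dip[[b]]
    if (length(intersect(c(d1$i, d1$j), c(d2$i, d2$j)))) next
    u1 <- oracle_minimg(x[d1$j, ] - x[d1$i, ], cell)
    u2 <- oracle_minimg(x[d2$j, ] - x[d2$i, ], cell)
    m1 <- x[d1$i, ] + u1 / 2; m2 <- x[d2$i, ] + u2 / 2
    rv <- oracle_minimg(m2 - m1, cell)
    r <- sqrt(sum(rv^2))
    if (r >= cutd) next
    e1 <- u1 / sqrt(sum(u1^2)); e2 <- u2 / sqrt(sum(u2^2))
    ornt <- sum(e1 * e2) - 3 * sum(e1 * rv) * sum(e2 * rv) / r^2
    e["dipole"] <- e["dipole"] + K * d1$mu * d2$mu * ornt /
      (ff$dielectric * r^3) * oracle_taper(r, cutd, ff$taper)
  }

  if (!is.null(sys$wall)) {
    for (i in seq_len(n)) {
      r <- sqrt(sum((x[i, ] - sys$wall$center)^2))
      if (r > sys$wall$radius)
        e["wall"] <- e["wall"] + sys$wall$k * (r - sys$wall$radius)^2
    }
  }
  e
}

# random small mixed system for property tests (non-periodic)
random_test_system <- function(n_co2 = 2, n_mea = 1, spread = 6, seed = 1,
                               ff = co2mea::mm_start_parameters()) {
  set.seed(seed)
  sys <- NULL
  add <- function(sys, mono) {
    mono$xyz <- sweep(mono$xyz, 2, colMeans(mono$xyz), "-")
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    mono <- co2mea:::.transform(mono, co2mea:::.rotmat(q),
                                shift = runif(3, -spread, spread))
    if (is.null(sys)) mono else co2mea::combine_systems(sys, mono)
  }
  for (i in seq_len(n_co2)) sys <- add(sys, co2mea::build_monomer("CO2", ff = ff))
  for (i in seq_len(n_mea))
    sys <- add(sys, co2mea::build_monomer("MEA", "gauche_intraHB", ff = ff))
  sys
}
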