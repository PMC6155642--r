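ff <- mm_start_parameters()

test_that("monomers are built at equilibrium internal coordinates", {
  co2 <- build_monomer("CO2", ff = ff)
  expect_equal(nrow(co2$xyz), 3)
  r1 <- sqrt(sum((co2$xyz[2, ] - co2$xyz[1, ])^2))
  r2 <- sqrt(sum((co2$xyz[3, ] - co2$xyz[1, ])^2))
  expect_equal(r1, r2)
  u <- co2$xyz[2, ] - co2$xyz[1, ]; v <- co2$xyz[3, ] - co2$xyz[1, ]
  ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(ang, 180, tolerance = 1e-8)
  mea <- build_monomer("MEA", "gauche_intraHB", ff = ff)
  expect_equal(nrow(mea$xyz), 11)
  expect_equal(n_molecules(mea), 1)
  # intraHB conformer presents the hydroxyl H to the amine N
  iN <- which(mea$classes == "N_amine")
  iH <- which(mea$classes == "H_O")
  expect_lt(sqrt(sum((mea$xyz[iN, ] - mea$xyz[iH, ])^2)), 2.5)
  tr <- build_monomer("MEA", "trans", ff = ff)
  expect_gt(sqrt(sum((tr$xyz[iN, ] - tr$xyz[iH, ])^2)), 3.5)
  expect_error(build_monomer("MEA", "boat", ff = ff))
})

test_that("dimer arrangements start in their labelled geometry", {
  p <- build_dimer("parallel", ff = ff)
  expect_equal(sqrt(sum((p$system$xyz[4, ] - p$system$xyz[1, ])^2)), 4.0)
  ax1 <- p$system$xyz[2, ] - p$system$xyz[3, ]
  ax2 <- p$system$xyz[5, ] - p$system$xyz[6, ]
  cosang <- sum(ax1 * ax2) / sqrt(sum(ax1^2) * sum(ax2^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-8)
  tt <- build_dimer("T", ff = ff)
  ax1 <- tt$system$xyz[2, ] - tt$system$xyz[3, ]
  ax2 <- tt$system$xyz[5, ] - tt$system$xyz[6, ]
  expect_lt(abs(sum(ax1 * ax2)), 1e-8)
  nhn <- build_dimer("NHN", ff = ff)
  cn <- nhn$constraints[[1]]
  expect_equal(cn$kind, "frozen_angle")
  expect_equal(cn$target, 180)
  val <- co2mea:::.constraint_value(nhn$system$xyz, cn)
  expect_lt(abs(val - 180), 1)
  expect_error(build_dimer("sandwich", ff = ff))
})

test_that("cluster packing respects the wall, spacing and determinism", {
  cl <- pack_cluster("CO2", 12, radius = 6, seed = 7, min_dist = 2.0,
                     ff = ff)
  expect_equal(n_molecules(cl), 12)
  expect_equal(cl$wall$radius, 6)
  # all pairwise intermolecular atom distances >= min_dist
  dmin <- Inf
  for (i in seq_len(nrow(cl$xyz) - 1)) {
    js <- which(cl$mol != cl$mol[i]); js <- js[js > i]
    if (length(js)) {
      d <- sqrt(rowSums(sweep(cl$xyz[js, , drop = FALSE], 2,
                              cl$xyz[i, ], "-")^2))
      dmin <- min(dmin, d)
    }
  }
  expect_gte(dmin, 2.0)
  cl2 <- pack_cluster("CO2", 12, radius = 6, seed = 7, min_dist = 2.0,
                      ff = ff)
  expect_identical(cl$xyz, cl2$xyz)
  expect_error(pack_cluster("CO2", 200, radius = 4, seed = 1, ff = ff,
                            max_tries = 50), "packing failed")
})

test_that("liquid box edge follows the mass-density arithmetic", {
  # (MEA)n at 1.01 g/cm^3: edge = (n * 61.084 amu / rho)^(1/3)
  box <- pack_liquid_box("MEA", 24, density = 0.35, seed = 2, ff = ff)
  mmea <- sum(build_monomer("MEA", ff = ff)$mass)
  expect_equal(mmea, 61.084, tolerance = 1e-3)
  edge_expect <- (24 * mmea * 1.660539 / 0.35)^(1 / 3)
  expect_equal(box$cell[1], edge_expect, tolerance = 1e-6)
  # density recomputed from the built cell within 0.1%
  rho <- 24 * mmea * 1.660539 / prod(box$cell)
  expect_equal(rho, 0.35, tolerance = 1e-3)
  expect_equal(n_molecules(box), 24)
})

test_that("carve + merge conserves atoms and clears the cavity", {
  ffs <- mm_start_parameters(); ffs$cut_vdw <- 6; ffs$cut_dip <- 7
  box <- pack_liquid_box("MEA", 18, density = 0.30, seed = 5, ff = ffs)
  carved <- carve_cavity(box, radius = 5)
  expect_equal(n_molecules(carved$system) + carved$removed, 18)
  ctr <- box$cell / 2
  for (m in seq_len(n_molecules(carved$system))) {
    idx <- which(carved$system$mol == m)
    com <- colSums(carved$system$xyz[idx, , drop = FALSE] *
                     carved$system$mass[idx]) / sum(carved$system$mass[idx])
    d <- com - ctr; d <- d - round(d / box$cell) * box$cell
    expect_gte(sqrt(sum(d^2)), 5)
  }
  # radius 0 removes nothing
  expect_equal(carve_cavity(box, radius = 1e-12)$removed, 0)
  expect_error(carve_cavity(box, radius = 0.6 * box$cell[1]), "half the cell")
  cl <- pack_cluster("CO2", 4, radius = 2.8, seed = 9, ff = ffs)
  merged <- merge_interface(cl, carved$system)
  expect_equal(nrow(merged$xyz), 4 * 3 + 11 * n_molecules(carved$system))
  expect_null(merged$wall)
  expect_equal(merged$cell, box$cell)
})

test_that("scaling one bond dipole changes that magnitude only", {
  f1 <- scale_bond_dipole(ff, factor = 1.0)
  expect_identical(f1$bonds$mu, ff$bonds$mu)
  f01 <- scale_bond_dipole(ff, factor = 0.1)
  i <- match("O_hydroxyl:H_O", ff$bonds$class)
  expect_equal(f01$bonds$mu[i], 0.1 * ff$bonds$mu[i])
  expect_identical(f01$bonds$mu[-i], ff$bonds$mu[-i])
  expect_identical(f01$atoms, ff$atoms)
  expect_error(scale_bond_dipole(ff, "Q:Z", 0.5))
  # weaker hydroxyl dipole weakens the OHO hydrogen bond
  d <- build_dimer("OHO", ff = ff)
  e_full <- interaction_energy(d$system, ff, constraints = d$constraints)
  e_weak <- interaction_energy(d$system, f01, constraints = d$constraints)
  expect_gt(e_weak$Eint, e_full$Eint)
})
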