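test_that("LJ pair energy has its minimum at rm and vanishes beyond cutoff", {
  ff <- mm_start_parameters()
  i <- match("C_co2", ff$atoms$class); j <- match("O_co2", ff$atoms$class)
  rm <- ff$atoms$rv[i] + ff$atoms$rv[j]
  eps <- sqrt(ff$atoms$eps[i] * ff$atoms$eps[j])
  expect_equal(lj_pair_energy("C_co2", "O_co2", rm, ff), -eps)
  expect_identical(lj_pair_energy("C_co2", "O_co2", ff$cut_vdw + 0.5, ff), 0)
  # combining-rule symmetry
  r <- seq(2.5, 9.5, by = 0.7)
  expect_equal(lj_pair_energy("C_co2", "N_amine", r, ff),
               lj_pair_energy("N_amine", "C_co2", r, ff))
  expect_error(lj_pair_energy("Z_bogus", "O_co2", 3, ff), "Z_bogus")
})

test_that("dipole pair energy matches the closed form and its zeros", {
  ff <- mm_start_parameters()
  d1 <- list(a = c(-0.5, 0, 0), b = c(0.5, 0, 0), mu = 1)
  d2 <- list(a = c(2.5, 0, 0), b = c(3.5, 0, 0), mu = 1)
  K <- unname(mm_constants()["kdip"])
  # collinear head-to-tail: (cos 0 - 3)/27
  expect_equal(dipole_pair_energy(d1, d2, ff), K * (1 - 3) / 27,
               tolerance = 1e-12)
  expect_equal(dipole_pair_energy(d1, d2, ff), -1.0662, tolerance = 1e-3)
  # perpendicular to each other and to the separation: orientation factor 0
  d3 <- list(a = c(0, -0.5, 0), b = c(0, 0.5, 0), mu = 1)
  d4 <- list(a = c(3, 0, -0.5), b = c(3, 0, 0.5), mu = 1)
  expect_equal(dipole_pair_energy(d3, d4, ff), 0, tolerance = 1e-14)
  expect_error(dipole_pair_energy(d1, d1, ff), "singular")
})

test_that("bonded energy is harmonic and zero at equilibrium", {
  ff <- mm_start_parameters()
  co2 <- build_monomer("CO2", ff = ff)
  expect_equal(unname(sum(bonded_energy(co2, ff))), 0, tolerance = 1e-20)
  # single stretched bond: E = ks dr^2
  r0 <- ff$bonds$r0[match("C_co2:O_co2", ff$bonds$class)]
  ks <- ff$bonds$ks[match("C_co2:O_co2", ff$bonds$class)]
  co2$xyz[2, 1] <- r0 + 0.1
  expect_equal(unname(bonded_energy(co2, ff)["stretch"]), ks * 0.01,
               tolerance = 1e-10)
})

test_that("decomposition matches the brute-force oracle on random systems", {
  ff <- mm_start_parameters()
  for (seed in 1:10) {
    sys <- random_test_system(n_co2 = 2, n_mea = 2, spread = 5, seed = seed,
                              ff = ff)
    e <- total_energy(sys, ff)
    o <- oracle_energy(sys, ff)
    expect_equal(as.numeric(e$decomp), as.numeric(o), tolerance = 1e-10,
                 label = paste("seed", seed))
    expect_equal(e$total, sum(o), tolerance = 1e-10)
  }
})

test_that("neighbor-list evaluation equals brute force, periodic included", {
  ff <- mm_start_parameters(); ff$cut_vdw <- 6; ff$cut_dip <- 7
  box <- pack_liquid_box("MEA", 6, density = 0.15, seed = 3, ff = ff)
  comp <- co2mea:::.compile(box, ff)
  nowall <- c(0, 0, 0, -1, 0)
  e_bf <- co2mea:::cpp_energy(comp, box$xyz, box$cell, nowall, FALSE, -1)
  e_nl <- co2mea:::cpp_energy(comp, box$xyz, box$cell, nowall, FALSE, 1.0)
  expect_identical(e_bf$total, e_nl$total)
  o <- oracle_energy(box, ff)
  expect_equal(as.numeric(e_bf$decomp), as.numeric(o), tolerance = 1e-10)
})

test_that("analytic forces agree with central differences", {
  ff <- mm_start_parameters()
  h <- 1e-5
  for (seed in c(2, 5)) {
    sys <- random_test_system(n_co2 = 1, n_mea = 1, spread = 3.2,
                              seed = seed, ff = ff)
    set.seed(seed)
    sys$xyz <- sys$xyz + matrix(rnorm(length(sys$xyz), 0, 0.03),
                                nrow(sys$xyz), 3)
    fa <- forces(sys, ff)
    for (i in seq_len(nrow(sys$xyz))) for (m in 1:3) {
      xp <- sys; xp$xyz[i, m] <- xp$xyz[i, m] + h
      xm <- sys; xm$xyz[i, m] <- xm$xyz[i, m] - h
      fd <- -(total_energy(xp, ff)$total - total_energy(xm, ff)$total) /
        (2 * h)
      expect_equal(fa[i, m], fd, tolerance = 1e-5 * max(1, abs(fd)))
    }
    # translation invariance: forces sum to zero
    expect_lt(max(abs(colSums(fa))), 1e-8)
    # net torque about the origin vanishes for an isolated system
    tq <- colSums(cbind(
      sys$xyz[, 2] * fa[, 3] - sys$xyz[, 3] * fa[, 2],
      sys$xyz[, 3] * fa[, 1] - sys$xyz[, 1] * fa[, 3],
      sys$xyz[, 1] * fa[, 2] - sys$xyz[, 2] * fa[, 1]))
    expect_lt(max(abs(tq)), 1e-8)
  }
})

test_that("energy is invariant under isometries and cell translations", {
  ff <- mm_start_parameters()
  sys <- random_test_system(n_co2 = 2, n_mea = 1, spread = 4, seed = 9,
                            ff = ff)
  e0 <- total_energy(sys, ff)$total
  rot <- co2mea:::.transform(sys, co2mea:::.rotmat(c(0.2, -0.4, 0.7, 0.5)),
                             shift = c(10, -3, 2))
  expect_equal(total_energy(rot, ff)$total, e0, tolerance = 1e-8)
  ffs <- mm_start_parameters(); ffs$cut_vdw <- 6; ffs$cut_dip <- 7
  box <- pack_liquid_box("MEA", 5, density = 0.12, seed = 4, ff = ffs)
  eb <- total_energy(box, ffs)$total
  idx <- which(box$mol == 2)
  box$xyz[idx, ] <- sweep(box$xyz[idx, , drop = FALSE], 2,
                          box$cell * c(1, -2, 1), "+")
  expect_equal(total_energy(box, ffs)$total, eb, tolerance = 1e-9)
})

test_that("swapping the stored direction of a bond changes no energy", {
  ff <- mm_start_parameters()
  sys <- random_test_system(n_co2 = 1, n_mea = 1, spread = 3.5, seed = 11,
                            ff = ff)
  e0 <- total_energy(sys, ff)$decomp
  sys2 <- sys
  sys2$bonds <- sys$bonds[, 2:1]
  sys2 <- molecular_system(sys2$classes, sys2$xyz, sys2$bonds)
  expect_equal(as.numeric(total_energy(sys2, ff)$decomp), as.numeric(e0),
               tolerance = 1e-12)
})

test_that("intermolecular terms vanish beyond all cutoffs", {
  ff <- mm_start_parameters()
  a <- build_monomer("CO2", ff = ff)
  b <- co2mea:::.transform(build_monomer("CO2", ff = ff),
                           shift = c(ff$cut_dip + 5, 0, 0))
  e <- total_energy(combine_systems(a, b), ff)$decomp
  expect_identical(unname(e["lj"]), 0)
  expect_identical(unname(e["dipole"]), 0)
})

test_that("a too-small periodic cell is rejected", {
  ff <- mm_start_parameters()
  sys <- build_monomer("CO2", ff = ff)
  sys$cell <- c(12, 30, 30)
  expect_error(total_energy(sys, ff), "cell edge")
})
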