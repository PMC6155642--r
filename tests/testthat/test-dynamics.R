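ff <- co2_intramolecular_fit(mm_start_parameters())$ff

test_that("velocity initialization hits the target exactly and is seeded", {
  sys <- pack_cluster("CO2", 8, radius = 5.5, seed = 3, ff = ff)
  s1 <- initialize_velocities(sys, 300, seed = 42)
  kB <- unname(mm_constants()["kB"]); akma <- unname(mm_constants()["kcal_akma"])
  K <- 0.5 * sum(s1$mass * rowSums(s1$vel^2)) / akma
  Tinst <- 2 * K / ((3 * nrow(s1$xyz) - 3) * kB)
  expect_equal(Tinst, 300, tolerance = 1e-10)
  p <- colSums(s1$vel * s1$mass)
  expect_lt(max(abs(p)), 1e-10)
  s2 <- initialize_velocities(sys, 300, seed = 42)
  expect_identical(s1$vel, s2$vel)
})

test_that("Berendsen factor follows the weak-coupling formula", {
  expect_equal(berendsen_factor(300, 300, 5e-4, 0.1), 1)
  expect_equal(berendsen_factor(100, 400, 0.1, 0.1), 2)
  expect_error(berendsen_factor(-5, 300, 5e-4, 0.1))
})

test_that("NVE conserves energy on a CO2 dimer over 10 ps", {
  d <- build_dimer("min", ff = ff)
  sys <- minimize(d$system, ff)$system
  sys <- initialize_velocities(sys, 50, seed = 7)
  traj <- run_md(sys, ff, steps = 20000, dt = 5e-4, stride = 100)
  etot <- traj$scalars$U + traj$scalars$K
  expect_lt(max(etot) - min(etot), 0.01)
  # conservation degrades roughly quadratically with the time step
  sys2 <- initialize_velocities(minimize(d$system, ff)$system, 50, seed = 7)
  traj2 <- run_md(sys2, ff, steps = 5000, dt = 2e-3, stride = 100)
  drift2 <- diff(range(traj2$scalars$U + traj2$scalars$K))
  expect_gt(drift2, (max(etot) - min(etot)) / 4)
})

test_that("trajectory energies match re-evaluation of stored frames", {
  cl <- pack_cluster("CO2", 6, radius = 5, seed = 5, ff = ff)
  cl <- initialize_velocities(cl, 60, seed = 6)
  traj <- run_md(cl, ff, steps = 400, stride = 100, frame_stride = 100,
                 thermostat = list(T = 60))
  expect_length(traj$frames, 5)          # floor(steps/stride) + 1
  for (k in seq_along(traj$frames)) {
    fsys <- cl; fsys$xyz <- traj$frames[[k]]
    expect_equal(total_energy(fsys, ff)$total, traj$scalars$U[k],
                 tolerance = 1e-9)
  }
})

test_that("wall force is one-sided harmonic toward the center", {
  sys <- molecular_system("O_co2", matrix(c(7, 0, 0), 1, 3),
                          matrix(integer(0), ncol = 2),
                          wall = list(center = c(0, 0, 0), radius = 5,
                                      k = 100))
  f <- forces(sys, ff)
  expect_equal(f[1, ], c(-2 * 100 * 2, 0, 0), tolerance = 1e-10)
  sys$xyz[1, 1] <- 4.0                    # inside: no force
  expect_equal(max(abs(forces(sys, ff))), 0)
})

test_that("a restarted run continues a longer run bitwise", {
  cl <- pack_cluster("CO2", 5, radius = 4.5, seed = 8, ff = ff)
  cl <- initialize_velocities(cl, 70, seed = 9)
  full <- run_md(cl, ff, steps = 200, stride = 50,
                 thermostat = list(T = 70), nlist_every = 10)
  half <- run_md(cl, ff, steps = 100, stride = 50,
                 thermostat = list(T = 70), nlist_every = 10)
  rest <- run_md(half$final, ff, steps = 100, stride = 50,
                 thermostat = list(T = 70), nlist_every = 10)
  expect_identical(rest$final$xyz, full$final$xyz)
  expect_identical(rest$final$vel, full$final$vel)
})

test_that("thermostatted runs hold the target temperature", {
  cl <- pack_cluster("CO2", 8, radius = 5.0, seed = 12, ff = ff)
  cl <- initialize_velocities(cl, 90, seed = 13)
  traj <- run_md_protocol(cl, ff, equil_steps = 4000, prod_steps = 20000,
                          stride = 20, thermostat = list(T = 90, tau = 0.1))
  expect_equal(mean(traj$scalars$T), 90, tolerance = 0.03)
  # canonical kinetic-energy mean: (3N-3)/2 kB T
  kB <- unname(mm_constants()["kB"])
  expect_equal(mean(traj$scalars$K),
               (3 * nrow(cl$xyz) - 3) / 2 * kB * 90, tolerance = 0.03)
})

test_that("virial pressure reduces to the ideal gas law without forces", {
  # monatomic ideal gas: unbonded atoms with negligible LJ, no dipoles
  ffi <- mm_start_parameters()
  ffi$cut_vdw <- 4; ffi$cut_dip <- 4.5
  ffi$atoms$eps[] <- 1e-13
  set.seed(21)
  n <- 100; L <- 20
  gas <- molecular_system(rep("O_co2", n), matrix(runif(3 * n, 0, L), n, 3),
                          matrix(integer(0), ncol = 2), cell = rep(L, 3))
  gas <- initialize_velocities(gas, 200, seed = 22)
  traj <- run_md(gas, ffi, steps = 2000, stride = 10)
  kB <- unname(mm_constants()["kB"])
  pexp <- mean(n * kB * traj$scalars$T / L^3) * 68568.5
  pobs <- mean(traj$scalars$P)
  expect_equal(pobs, pexp, tolerance = 0.02)
})

test_that("NPH pressure coupling drives the cell toward the set point", {
  ffs <- mm_start_parameters(); ffs$cut_vdw <- 5; ffs$cut_dip <- 6
  box <- pack_liquid_box("CO2", 20, density = 0.65, seed = 31, ff = ffs)
  box <- initialize_velocities(box, 250, seed = 32)
  traj <- run_md(box, ffs, steps = 8000, stride = 40,
                 barostat = list(P = 1000, tau = 0.5))
  p_late <- mean(tail(traj$scalars$P, 40))
  p_early <- mean(head(traj$scalars$P, 10))
  expect_lt(abs(p_late - 1000), abs(p_early - 1000) + 2000)
  expect_false(isTRUE(all.equal(traj$final$cell, box$cell)))
})
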