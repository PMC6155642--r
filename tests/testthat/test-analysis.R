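ff <- co2_intramolecular_fit(mm_start_parameters())$ff

test_that("heat capacity follows the fluctuation formula", {
  kB <- unname(mm_constants()["kB"])
  expect_equal(heat_capacity(rep(3.2, 50), 90), 0)
  # two-point sample {0, 2}: population variance 1
  expect_equal(heat_capacity(c(0, 2), 90), 1 / (kB * 90^2))
  expect_error(heat_capacity(c(0, 1), -5), "positive")
})

test_that("thermostatted harmonic oscillator recovers kB/2 per mode", {
  # single stiff diatomic at moderate T: one vibrational mode; the
  # potential-energy fluctuation Cv should approach kB/2
  ffd <- ff
  sys <- molecular_system(c("C_co2", "O_co2"),
                          rbind(c(0, 0, 0), c(1.16, 0, 0)),
                          rbind(c(1, 2)))
  kB <- unname(mm_constants()["kB"])
  sys <- initialize_velocities(sys, 300, seed = 5)
  traj <- run_md_protocol(sys, ffd, equil_steps = 20000,
                          prod_steps = 400000, stride = 10,
                          thermostat = list(T = 300, tau = 0.05))
  cv <- heat_capacity(traj$scalars$U, 300)
  expect_equal(cv, kB / 2, tolerance = 0.10)
})

test_that("heat-capacity estimator matches dU/dT on the harmonic system", {
  ffd <- ff
  kB <- unname(mm_constants()["kB"])
  mkrun <- function(T, seed) {
    sys <- molecular_system(c("C_co2", "O_co2"),
                            rbind(c(0, 0, 0), c(1.16, 0, 0)),
                            rbind(c(1, 2)))
    sys <- initialize_velocities(sys, T, seed = seed)
    run_md_protocol(sys, ffd, equil_steps = 10000, prod_steps = 200000,
                    stride = 10, thermostat = list(T = T, tau = 0.05))
  }
  t1 <- mkrun(250, 11); t2 <- mkrun(350, 12)
  dUdT <- (mean(t2$scalars$U) - mean(t1$scalars$U)) / 100
  cv_mid <- heat_capacity(t1$scalars$U, 250) / 2 +
    heat_capacity(t2$scalars$U, 350) / 2
  expect_equal(cv_mid, dUdT, tolerance = 0.25)
})

test_that("RDF is flat at 1 for ideal-gas configurations", {
  # uniform random single-site molecules in a periodic box, no interactions
  set.seed(99)
  n <- 400
  L <- 30
  xyz <- matrix(runif(3 * n, 0, L), n, 3)
  sys <- molecular_system(rep("O_co2", n), xyz, matrix(integer(0), ncol = 2),
                          cell = rep(L, 3))
  traj <- list(frames = list(xyz), frame_cell = matrix(L, 1, 3),
               template = sys, dt = 5e-4, frame_stride = 1)
  class(traj) <- "trajectory"
  r <- rdf(traj, sys, "O_co2", "O_co2", r_max = 10, dr = 0.25)
  inner <- r$table$g[r$table$r > 2 & r$table$r < 10]
  expect_equal(mean(inner), 1, tolerance = 0.05)
  expect_true(all(r$table$g >= 0))
})

test_that("RDF puts a single pair's mass in the right bin", {
  xyz <- rbind(c(0, 0, 0), c(3.42, 0, 0))
  sys <- molecular_system(c("C_co2", "C_co2"), xyz,
                          matrix(integer(0), ncol = 2))
  traj <- list(frames = list(xyz), frame_cell = matrix(0, 1, 3),
               template = sys, dt = 5e-4, frame_stride = 1)
  class(traj) <- "trajectory"
  r <- rdf(traj, sys, "C_co2", "C_co2", r_max = 6, dr = 0.1, volume = 1000)
  expect_equal(r$table$r[which.max(r$table$g)], 3.45, tolerance = 0.051)
  expect_equal(sum(r$table$g > 0), 1)
  expect_error(rdf(traj, sys, "N_amine", "N_amine"), "empty selection")
})

test_that("g(r) time series equals per-window RDF evaluation", {
  set.seed(7)
  frames <- lapply(1:6, function(i) matrix(runif(30, 0, 12), 10, 3))
  sys <- molecular_system(rep("C_co2", 10),
                          frames[[1]], matrix(integer(0), ncol = 2),
                          cell = rep(12, 3))
  traj <- list(frames = frames, frame_cell = matrix(12, 6, 3),
               template = sys, dt = 5e-4, frame_stride = 10)
  class(traj) <- "trajectory"
  ts <- rdf_time_evolution(traj, sys, "C_co2", "C_co2", r_probe = 3.65,
                           window_frames = 2)
  expect_equal(nrow(ts), 3)
  w2 <- rdf(traj, sys, "C_co2", "C_co2", r_max = 3.65 + 0.25, dr = 0.05,
            frames = 3:4)
  expect_equal(ts$g[2], rdf_at(w2, 3.65))
  # static configuration gives a constant series
  traj$frames <- rep(frames[1], 6)
  ts2 <- rdf_time_evolution(traj, sys, "C_co2", "C_co2", window_frames = 2)
  expect_equal(length(unique(ts2$g)), 1)
})

test_that("intramolecular H-bond histogram counts and criterion", {
  # synthetic trajectory: alternating gauche (intraHB) and trans conformers
  g <- build_monomer("MEA", "gauche_intraHB", ff = ff)
  t <- build_monomer("MEA", "trans", ff = ff)
  two <- combine_systems(g, co2mea:::.transform(t, shift = c(12, 0, 0)))
  frames <- rep(list(two$xyz), 20)
  traj <- list(frames = frames, frame_cell = matrix(0, 20, 3),
               template = two, dt = 5e-4, frame_stride = 1)
  class(traj) <- "trajectory"
  h <- intra_hb_histogram(traj, two, n_molecules = 2, n_snapshots = 20,
                          criterion = 2.5)
  expect_equal(sum(h$counts), 2 * 20)       # totals conserved exactly
  expect_equal(h$n_below, 20)               # only the gauche copies count
  h2 <- intra_hb_histogram(traj, two, n_molecules = 2, n_snapshots = 20,
                           criterion = 2.2)
  expect_lte(h2$n_below, h$n_below)
  expect_error(intra_hb_histogram(traj, two, n_molecules = 5,
                                  n_snapshots = 20), "exceeds")
  expect_error(intra_hb_histogram(traj, two, n_molecules = 2,
                                  n_snapshots = 50), "stored frames")
})
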