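ff <- co2_intramolecular_fit(mm_start_parameters())$ff

test_that("minimization restores the linear CO2 geometry from a bent start", {
  co2 <- build_monomer("CO2", ff = ff)
  co2$xyz[2, ] <- c(1.05, 0.45, 0)
  co2$xyz[3, ] <- c(-1.15, 0.30, 0.10)
  res <- minimize(co2, ff)
  expect_true(res$converged)
  u <- res$system$xyz[2, ] - res$system$xyz[1, ]
  v <- res$system$xyz[3, ] - res$system$xyz[1, ]
  ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(ang, 180, tolerance = 1e-4)
  expect_lt(res$energy$total, 1e-10)
  # starting at the minimum returns it unchanged (to optimizer tolerance)
  res2 <- minimize(res$system, ff)
  expect_equal(res2$system$xyz, res$system$xyz, tolerance = 1e-8)
})

test_that("constrained minimization satisfies its constraints tightly", {
  d <- build_dimer("parallel", ff = ff)
  res <- minimize(d$system, ff, constraints = d$constraints)
  expect_lt(res$constraint_dev, 1e-3)
  r <- sqrt(sum((res$system$xyz[4, ] - res$system$xyz[1, ])^2))
  expect_equal(r, 4.0, tolerance = 1e-3)
  # restraint energy never leaks into the reported energy
  expect_equal(res$energy$total, total_energy(res$system, ff)$total,
               tolerance = 1e-10)
})

test_that("normal modes: diatomic closed form and Hessian symmetry", {
  # two bonded CO2-class atoms: nu = sqrt(2 ks / mu_red) / (2 pi c)
  ffd <- ff
  r0 <- ffd$bonds$r0[match("C_co2:O_co2", ffd$bonds$class)]
  ks <- ffd$bonds$ks[match("C_co2:O_co2", ffd$bonds$class)]
  sys <- molecular_system(c("C_co2", "O_co2"),
                          rbind(c(0, 0, 0), c(r0, 0, 0)), rbind(c(1, 2)))
  nm <- normal_modes(sys, ffd)
  cc <- mm_constants()
  mu_red <- 12.011 * 15.999 / (12.011 + 15.999)
  nu_expect <- sqrt(2 * ks * cc["kcal_akma"] / mu_red) /
    (2 * pi * cc["c_cmps"])
  expect_equal(max(nm$freq), unname(nu_expect), tolerance = 1e-4)
  expect_lt(nm$hessian_asym, 1e-6)
})

test_that("calibrated CO2 shows 3N-5 vibrations at the tabulated positions", {
  mono <- minimize(build_monomer("CO2", ff = ff), ff)$system
  nm <- normal_modes(mono, ff)
  vib <- nm$freq[abs(nm$freq) >= 15]
  expect_length(vib, 4)                  # linear molecule: 3N-5
  expect_equal(vib[1], vib[2], tolerance = 1e-3)   # degenerate bend
  expect_equal(vib[1:2], rep(629, 2), tolerance = 0.01)
  expect_equal(vib[3], 1240, tolerance = 0.01)
  expect_equal(vib[4], 1240 * sqrt(1 + 2 * 15.999 / 12.011),
               tolerance = 0.001)
  # all non-rigid-body eigenvalues are non-negative at a minimum
  expect_true(all(vib > 0))
  # frequencies invariant under rigid rotation of the input
  rot <- co2mea:::.transform(mono, co2mea:::.rotmat(c(0.6, 0.2, -0.3, 0.7)))
  nm2 <- normal_modes(rot, ff)
  expect_equal(nm2$freq[abs(nm2$freq) >= 15], vib, tolerance = 1e-3)
  expect_lt(max(abs(nm2$freq[abs(nm2$freq) >= 15] - vib)), 0.1)
})

test_that("normal modes refuse a non-stationary geometry", {
  co2 <- build_monomer("CO2", ff = ff)
  co2$xyz[2, 1] <- co2$xyz[2, 1] + 0.2
  expect_error(normal_modes(co2, ff), "stationary")
})

test_that("doubling the stretch constant scales stretches by sqrt(2)", {
  f2 <- ff
  i <- match("C_co2:O_co2", f2$bonds$class)
  f2$bonds$ks[i] <- 2 * f2$bonds$ks[i]
  mono <- minimize(build_monomer("CO2", ff = ff), ff)$system
  v1 <- normal_modes(mono, ff)$freq
  v2 <- normal_modes(mono, f2)$freq
  s1 <- v1[abs(v1) >= 15][3:4]; s2 <- v2[abs(v2) >= 15][3:4]
  expect_equal(s2 / s1, rep(sqrt(2), 2), tolerance = 1e-6)
})

test_that("the distance scan relaxes, flags and is anchored at its minimum", {
  sc_grid <- seq(2.4, 3.4, by = 0.2)
  d <- build_dimer("co2_amino", ff = ff)
  sc <- scan_rcn(d$system, ff, grid = sc_grid)
  expect_equal(sc$profile$r, sc_grid)
  expect_equal(min(sc$profile$rel_energy), 0)
  expect_equal(sc$profile$rel_energy[sc$profile$r == sc$r_min], 0)
  expect_error(scan_rcn(d$system, ff, grid = c(1.0, 2.0)), "within")
})
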