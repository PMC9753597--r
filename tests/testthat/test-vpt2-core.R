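test_that("derived tensors reduce to the force constants without kinetic terms", {
  sys <- random_system(3, seed = 11)
  t0 <- derived_tensors(sys$ff, NULL)
  expect_equal(t0$rho, sys$ff$f3)
  expect_equal(t0$sigma, sys$ff$f3)
  for (i in 1:3) for (k in 1:3)
    expect_equal(t0$eta[i, k], sys$ff$f4[i, i, k, k])
  # all zero input -> all tensors zero
  ff0 <- qff(sys$omega)
  tz <- derived_tensors(ff0, kinetic_derivatives(sys$omega))
  expect_true(all(tz$rho == 0) && all(tz$sigma == 0) && all(tz$eta == 0))
})

test_that("component split and eta/sigma/rho recast are algebraically identical", {
  for (seed in 1:25) {
    M <- 2L + (seed %% 3L)
    sys <- random_system(M, seed = 1000 + seed)
    comp <- chi_components(sys$ff, sys$kin)
    rec <- chi_curvilinear(derived_tensors(sys$ff, sys$kin))
    scale <- max(abs(rec$chi), 1)
    expect_lt(max(abs(comp$total - rec$chi)) / scale, 1e-10)
    # chi symmetric, components sum to total
    expect_equal(rec$chi, t(rec$chi))
    expect_equal(comp$pot + comp$kin + comp$cross, comp$total)
  }
})

test_that("closed-form transition energies match the sum-over-states oracle", {
  # 2-mode, mixed potential + kinetic
  sys2 <- random_system(2, seed = 7, scale3 = 5, kscale = 4)
  expect_lt(oracle_max_dev(sys2$omega, sys2$ff, sys2$kin, nmax = 16L), 1e-6)
  # 3-mode, potential only
  sys3 <- random_system(3, seed = 5, scale3 = 5, kscale = 0)
  expect_lt(oracle_max_dev(sys3$omega, sys3$ff, NULL, nmax = 10L), 1e-6)
  # 3-mode, kinetic only
  sys3k <- random_system(3, seed = 9, scale3 = 0, scale4 = 0, kscale = 4)
  expect_lt(oracle_max_dev(sys3k$omega, sys3k$ff, sys3k$kin, nmax = 10L), 1e-6)
})

test_that("VPT2 is exact for the Morse oscillator with analytic derivatives", {
  pes <- co_morse()
  ff <- morse_qff(pes)
  chi <- chi_curvilinear(derived_tensors(ff))
  expect_equal(state_energy(chi, 1), pes$we - 2 * pes$wexe, tolerance = 1e-9)
  expect_equal(chi$chi[1, 1], -pes$wexe, tolerance = 1e-9)
  # every bound transition is exact for Morse at second order
  expect_equal(state_energy(chi, 2), 2 * pes$we - 6 * pes$wexe,
               tolerance = 1e-9)
})

test_that("zero kinetic derivatives plus Coriolis reproduces the Cartesian chi", {
  geom <- water_geom()
  fitc <- gvpt2(water_pes(geom), geom = geom, frame = "cartesian")
  cor <- fitc$coriolis
  ff <- fitc$ff
  chi_cart <- chi_cartesian(ff, coriolis = cor)
  chi_curv0 <- chi_curvilinear(derived_tensors(ff, NULL))
  M <- length(ff$omega)
  corio <- matrix(0, M, M)
  for (i in 1:M) for (j in 1:M) if (i != j)
    corio[i, j] <- sum(cor$Be * cor$zeta[i, j, ]^2) *
      (ff$omega[i] / ff$omega[j] + ff$omega[j] / ff$omega[i])
  expect_equal(chi_cart$chi, chi_curv0$chi + corio)
  # zeta = 0 is identical to switching Coriolis off
  cor0 <- cor; cor0$zeta[] <- 0
  expect_equal(chi_cartesian(ff, cor0)$chi,
               chi_cartesian(ff, cor, include_coriolis = FALSE)$chi)
})

test_that("state energies follow the chi bilinear form", {
  sys <- random_system(3, seed = 21)
  chi <- chi_curvilinear(derived_tensors(sys$ff, sys$kin))
  expect_equal(state_energy(chi, c(0, 0, 0)), 0)
  k <- 2
  v <- c(0, 1, 0)
  expect_equal(state_energy(chi, v),
               sys$omega[k] + 2 * chi$chi[k, k] +
                 0.5 * sum(chi$chi[k, -k]), tolerance = 1e-12)
})

test_that("transition energies are invariant under mode reordering", {
  sys <- random_system(3, seed = 31)
  perm <- c(3, 1, 2)
  ffp <- qff(sys$omega[perm],
             cubic = sys$ff$f3[perm, perm, perm],
             quartic = sys$ff$f4[perm, perm, perm, perm])
  kinp <- kinetic_derivatives(sys$omega[perm],
                              g1 = sys$kin$g1[perm, perm, perm],
                              g2 = sys$kin$g2[perm, perm, perm, perm])
  chi <- chi_curvilinear(derived_tensors(sys$ff, sys$kin))
  chip <- chi_curvilinear(derived_tensors(ffp, kinp))
  v <- c(1, 0, 2)
  expect_equal(state_energy(chip, v[perm]), state_energy(chi, v),
               tolerance = 1e-10)
})

test_that("coupling-order restriction and decoupled fundamentals behave", {
  sys <- random_system(3, seed = 41)
  r3 <- restrict_coupling_order(sys$ff, sys$kin, 3L)
  expect_identical(r3$ff, sys$ff)
  r1 <- restrict_coupling_order(sys$ff, sys$kin, 1L)
  expect_true(all(r1$ff$f3[1, 2, ] == 0))
  expect_equal(r1$ff$f3[1, 1, 1], sys$ff$f3[1, 1, 1])
  expect_equal(r1$kin$g2[2, 2, 2, 2], sys$kin$g2[2, 2, 2, 2])
  # purely off-diagonal force field at order 1 -> no anharmonicity at all
  ffo <- qff(sys$omega, cubic = list(list(idx = c(1, 2, 3), value = 10)),
             quartic = list(list(idx = c(1, 1, 2, 2), value = 5)))
  ro <- restrict_coupling_order(ffo, NULL, 1L)
  expect_true(all(ro$ff$f3 == 0) && all(ro$ff$f4 == 0))

  # harmonic mode: decoupled fundamental is omega
  ffh <- qff(c(1000, 2000))
  expect_equal(single_mode_anharmonic(ffh, NULL, 2), 2000)
  # Morse: decoupled fundamental is the exact Morse fundamental
  pes <- co_morse()
  ffm <- morse_qff(pes)
  expect_equal(single_mode_anharmonic(ffm, NULL, 1), pes$we - 2 * pes$wexe,
               tolerance = 1e-9)
})

test_that("coupling counts recover planted constants", {
  w <- c(800, 1500, 2300, 3100)
  ff <- qff(w,
    cubic = list(list(idx = c(1, 2, 3), value = 30),
                 list(idx = c(2, 3, 4), value = 0.5),
                 list(idx = c(1, 1, 2), value = 90)),
    quartic = list(list(idx = c(1, 2, 3, 3), value = 12),
                   list(idx = c(1, 4, 2, 2), value = 0.2),
                   list(idx = c(1, 1, 2, 2), value = 40)))
  kin <- kinetic_derivatives(w,
    g1 = list(list(idx = c(1, 2, 3), value = 5)),
    g2 = list(list(idx = c(1, 2, 3, 3), value = 2)))
  n0 <- count_couplings(ff, kin, 0)
  expect_equal(unname(n0), c(2L, 2L, 1L, 1L))
  n1 <- count_couplings(ff, kin, 1)
  expect_equal(unname(n1), c(1L, 1L, 1L, 1L))
  expect_equal(unname(count_couplings(ff, kin, 1e6)), c(0L, 0L, 0L, 0L))
})

test_that("an exact resonance that is not deperturbed raises a named error", {
  w <- c(1000, 2000)   # exact 2:1
  ff <- qff(w, cubic = list(list(idx = c(1, 1, 2), value = 30)))
  expect_error(chi_curvilinear(derived_tensors(ff)), "F1:1;2")
  # with the resonance deperturbed the matrix is finite
  chi <- chi_curvilinear(derived_tensors(ff), deperturb = "F1:1;2")
  expect_true(all(is.finite(chi$chi)))
})
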