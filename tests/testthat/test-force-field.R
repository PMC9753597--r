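ff_setup <- local({
  geom <- water_geom()
  set <- detect_primitives(geom)
  pes <- water_pes(geom, set)
  r0 <- pes$eval(geom)
  m_au <- geom$masses * 1822.888486209
  B <- b_matrix(geom, set)
  sol <- gf_solve(g_matrix(B, m_au),
                  hessian_to_internal(r0$hessian, r0$gradient, B,
                                      b_prime(geom, set)))
  list(geom = geom, set = set, pes = pes, sol = sol,
       sref = coord_values(geom, set))
})

test_that("displacements hit the requested internal step exactly", {
  s <- ff_setup
  expect_identical(displace(s$geom, s$sol, 1, 0, set = s$set, sref = s$sref),
                   s$geom)
  dp <- displace(s$geom, s$sol, 2, 0.02, set = s$set, sref = s$sref)
  dm <- displace(s$geom, s$sol, 2, -0.02, set = s$set, sref = s$sref)
  dt <- drop(t(s$sol$U) %*% (coord_values(dp, s$set, ref = s$sref) - s$sref))
  expect_lt(max(abs(dt - s$sol$Lt[, 2] * 0.02 * sqrt(1822.888486209))), 1e-8)
  # +/- displacement pair brackets the reference internal values
  tp <- coord_values(dp, s$set, ref = s$sref)
  tm <- coord_values(dm, s$set, ref = s$sref)
  expect_lt(max(abs((tp + tm) / 2 - s$sref)), 1e-8)
})

test_that("gradient and Hessian transformations obey projection identities", {
  s <- ff_setup
  # zero Cartesian gradient -> zero internal gradient
  B <- b_matrix(s$geom, s$set)
  expect_equal(gradient_to_internal(rep(0, 9), B), rep(0, 3))

  # diatomic: g_s = dV/dr, F = d2V/dr2 exactly
  pes <- co_morse()
  gd2 <- geometry(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 2.2)),
                  masses = pes$geom$masses)
  r <- pes$eval(gd2)
  set2 <- detect_primitives(gd2)
  B2 <- b_matrix(gd2, set2)
  gs <- gradient_to_internal(r$gradient, B2)
  xi <- 2.2 - 2.132; a <- pes$a_morse; D <- pes$D_morse
  expect_equal(gs, 2 * D * a * exp(-a * xi) * (1 - exp(-a * xi)),
               tolerance = 1e-10)
  Fm <- hessian_to_internal(r$hessian, r$gradient, B2, b_prime(gd2, set2))
  expect_equal(Fm[1, 1], 2 * D * a^2 * exp(-a * xi) * (2 * exp(-a * xi) - 1),
               tolerance = 1e-10)

  # B^T g_s reproduces the projected Cartesian gradient
  gd <- displace(s$geom, s$sol, 1, 0.05, set = s$set, sref = s$sref)
  rd <- s$pes$eval(gd)
  Bd <- b_matrix(gd, s$set)
  gs <- gradient_to_internal(rd$gradient, Bd)
  P <- b_projector(Bd)
  expect_lt(max(abs(t(Bd) %*% gs - P %*% rd$gradient)), 1e-10)

  # at a displaced (non-stationary) geometry the transformed Hessian equals
  # the analytic internal-coordinate second derivatives of the model PES:
  # the B' gradient term at work (without it the comparison fails by ~1e-3)
  Fd <- hessian_to_internal(rd$hessian, rd$gradient, Bd, b_prime(gd, s$set))
  sd <- coord_values(gd, s$set, ref = s$sref)
  F_exact <- s$pes$vfun(sd)$d2V
  expect_lt(max(abs(Fd - F_exact)), 1e-9)
  F_nogrbadterm <- hessian_to_internal(rd$hessian, rd$gradient, Bd,
                                       0 * b_prime(gd, s$set))
  expect_gt(max(abs(F_nogrbadterm - F_exact)), 1e-5)

  # at a stationary point F is independent of the B' term
  r0 <- s$pes$eval(s$geom)
  B0 <- b_matrix(s$geom, s$set)
  Bp0 <- b_prime(s$geom, s$set)
  expect_equal(hessian_to_internal(r0$hessian, r0$gradient, B0, Bp0),
               hessian_to_internal(r0$hessian, r0$gradient, B0, 0 * Bp0),
               tolerance = 1e-12)
})

test_that("finite differences recover planted force constants at O(dQ^2)", {
  # 1-D quartic PES V = 1/2 k q^2 + a q^3 + b q^4 in the bond coordinate
  geom <- geometry(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 2.132)),
                   masses = c(12, 15.99491462))
  set <- detect_primitives(geom)
  k <- 0.6; a3 <- -0.5; b4 <- 0.4
  pes <- synthetic_polyatomic(geom, matrix(k, 1, 1), set = set,
    cubic = list(list(idx = c(1, 1, 1), value = 6 * a3)),
    quartic = list(list(idx = c(1, 1, 1, 1), value = 24 * b4)))
  run1 <- function(dq) {
    r0 <- pes$eval(geom)
    m_au <- geom$masses * 1822.888486209
    B <- b_matrix(geom, set)
    sol <- gf_solve(g_matrix(B, m_au),
                    hessian_to_internal(r0$hessian, r0$gradient, B,
                                        b_prime(geom, set)))
    surf <- run_surface(geom, pes, sol, delta_q = dq, set = set,
                        sref = coord_values(geom, set))
    assemble_force_field(surf, sol, geom, set = set,
                         sref = coord_values(geom, set))
  }
  ff1 <- run1(0.02)
  # for a potential that is exactly quartic in the (single) internal
  # coordinate the central differences are exact, not just O(dQ^2)
  mu <- prod(geom$masses) / sum(geom$masses) * 1822.888486209
  w_au <- sqrt(k / mu)
  conv <- 219474.6313632
  f3_exp <- 6 * a3 / (mu * w_au)^1.5 * conv
  f4_exp <- 24 * b4 / (mu * w_au)^2 * conv
  expect_equal(ff1$f3[1, 1, 1], f3_exp, tolerance = 1e-10)
  expect_equal(ff1$f4[1, 1, 1, 1], f4_exp, tolerance = 1e-10)

  # Morse (all higher derivatives nonzero): halving the step reduces the
  # cubic-constant error by about 4x
  pesm <- co_morse()
  ffm_exact <- morse_qff(pesm)
  runm <- function(dq) {
    r0 <- pesm$eval(pesm$geom)
    m_au <- pesm$geom$masses * 1822.888486209
    setm <- detect_primitives(pesm$geom)
    B <- b_matrix(pesm$geom, setm)
    sol <- gf_solve(g_matrix(B, m_au),
                    hessian_to_internal(r0$hessian, r0$gradient, B,
                                        b_prime(pesm$geom, setm)))
    surf <- run_surface(pesm$geom, pesm, sol, delta_q = dq, set = setm,
                        sref = coord_values(pesm$geom, setm))
    assemble_force_field(surf, sol, pesm$geom, set = setm,
                         sref = coord_values(pesm$geom, setm))
  }
  e1 <- abs(runm(0.04)$f3[1, 1, 1] - ffm_exact$f3[1, 1, 1])
  e2 <- abs(runm(0.02)$f3[1, 1, 1] - ffm_exact$f3[1, 1, 1])
  expect_gt(e1 / e2, 3.5)
  expect_lt(e1 / e2, 4.5)

  # purely harmonic PES: all anharmonic constants at finite-difference noise
  s <- ff_setup
  pes_h <- water_pes(s$geom, s$set, anharmonic = FALSE)
  r0 <- pes_h$eval(s$geom)
  m_au <- s$geom$masses * 1822.888486209
  B <- b_matrix(s$geom, s$set)
  sol <- gf_solve(g_matrix(B, m_au),
                  hessian_to_internal(r0$hessian, r0$gradient, B,
                                      b_prime(s$geom, s$set)))
  surf <- run_surface(s$geom, pes_h, sol, set = s$set, sref = s$sref)
  ffh <- assemble_force_field(surf, sol, s$geom, set = s$set, sref = s$sref)
  # the potential is harmonic in the *internal* coordinates; the curvilinear
  # normal-coordinate expansion is exactly harmonic too
  expect_lt(max(abs(ffh$f3)), 1e-4)
  expect_lt(max(abs(ffh$f4)), 1e-2)
})

test_that("surface runs are idempotent and self-healing through the archive", {
  s <- ff_setup
  arch <- tempfile(fileext = ".json")
  surf1 <- run_surface(s$geom, s$pes, s$sol, set = s$set, sref = s$sref,
                       archive = arch)
  expect_equal(surf1$engine_calls, 2L * 3L + 1L)
  expect_equal(length(surf1$results), 7L)
  # rerun: zero engine calls
  surf2 <- run_surface(s$geom, s$pes, s$sol, set = s$set, sref = s$sref,
                       archive = arch)
  expect_equal(surf2$engine_calls, 0L)
  expect_equal(surf2$results[["+2"]]$hessian, surf1$results[["+2"]]$hessian)
  # corrupt one entry: only that label is recomputed
  stored <- jsonlite::fromJSON(readLines(arch), simplifyVector = TRUE,
                               simplifyMatrix = FALSE,
                               simplifyDataFrame = FALSE)
  stored$results[["-1"]]$hessian <- stored$results[["-1"]]$hessian[1:5]
  writeLines(jsonlite::toJSON(stored, digits = I(17), auto_unbox = TRUE), arch)
  surf3 <- run_surface(s$geom, s$pes, s$sol, set = s$set, sref = s$sref,
                       archive = arch)
  expect_equal(surf3$engine_calls, 1L)
  expect_equal(surf3$results[["-1"]]$hessian, surf1$results[["-1"]]$hessian)
})

test_that("archives round-trip bit-exactly and refuse future versions", {
  s <- ff_setup
  surf <- run_surface(s$geom, s$pes, s$sol, set = s$set, sref = s$sref)
  arch <- tempfile(fileext = ".json")
  write_archive(surf, arch, s$geom)
  back <- read_archive(arch)
  for (lab in surf$labels) {
    expect_identical(back$results[[lab]]$hessian, surf$results[[lab]]$hessian)
    expect_identical(back$results[[lab]]$gradient,
                     as.numeric(surf$results[[lab]]$gradient))
    expect_identical(back$results[[lab]]$energy, surf$results[[lab]]$energy)
  }
  txt <- readLines(arch)
  writeLines(sub('"version":1', '"version":99', txt), arch)
  expect_error(read_archive(arch), "version")
})

test_that("kinetic derivatives match Richardson finite differences of g", {
  s <- ff_setup
  m_au <- s$geom$masses * 1822.888486209
  gq <- function(geomx) {
    Bt <- t(s$sol$U) %*% b_matrix(geomx, s$set)
    core <- s$sol$Lt_inv %*% g_matrix(Bt, m_au) %*% t(s$sol$Lt_inv)
    w_au <- abs(s$sol$omega_au)
    core * outer(sqrt(w_au), sqrt(w_au)) * 219474.6313632
  }
  g1 <- curvib:::.g1_at(s$geom, s$sol, s$set, s$sref)
  fd <- function(dQ) {
    dq <- dQ * sqrt(1822.888486209) * sqrt(abs(s$sol$omega_au))
    out <- array(0, dim(g1))
    for (k in 1:3) {
      gp <- gq(displace(s$geom, s$sol, k, dQ, set = s$set, sref = s$sref))
      gm <- gq(displace(s$geom, s$sol, k, -dQ, set = s$set, sref = s$sref))
      out[, , k] <- (gp - gm) / (2 * dq[k])
    }
    out
  }
  a1 <- fd(0.004); a2 <- fd(0.002)
  expect_lt(max(abs((4 * a2 - a1) / 3 - g1)), 1e-6)

  # g1 symmetric in its first two indices; all zero for the Cartesian frame
  for (k in 1:3) expect_equal(g1[, , k], t(g1[, , k]))
  surf <- run_surface(s$geom, s$pes, s$sol, set = s$set, sref = s$sref)
  kin <- assemble_kinetic_derivatives(surf, s$sol, s$geom, set = s$set,
                                      sref = s$sref)
  for (k in 1:3) for (l in 1:3) {
    expect_equal(kin$g2[, , k, l], t(kin$g2[, , k, l]))
    expect_equal(kin$g2[, , k, l], kin$g2[, , l, k])
  }
  solc <- cartesian_harmonic(s$pes$eval(s$geom)$hessian, s$geom)
  kin0 <- assemble_kinetic_derivatives(surf, solc, s$geom)
  expect_true(all(kin0$g1 == 0) && all(kin0$g2 == 0))

  # diatomic (constant metric): g1 = g2 = 0
  pes <- co_morse()
  set2 <- detect_primitives(pes$geom)
  r0 <- pes$eval(pes$geom)
  m2 <- pes$geom$masses * 1822.888486209
  B2 <- b_matrix(pes$geom, set2)
  sol2 <- gf_solve(g_matrix(B2, m2),
                   hessian_to_internal(r0$hessian, r0$gradient, B2,
                                       b_prime(pes$geom, set2)))
  surf2 <- run_surface(pes$geom, pes, sol2, set = set2,
                       sref = coord_values(pes$geom, set2))
  kin2 <- assemble_kinetic_derivatives(surf2, sol2, pes$geom, set = set2,
                                       sref = coord_values(pes$geom, set2))
  expect_lt(max(abs(kin2$g1)), 1e-8)
  expect_lt(max(abs(kin2$g2)), 1e-6)
})
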