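# shared fixtures, all generated in code

## bent triatomic (water-like) reference geometry, Bohr
water_geom <- function() {
  geometry(c("O", "H", "H"),
           rbind(c(0, 0, 0), c(1.81, 0, 0), c(-0.45, 1.75, 0)))
}

## synthetic quartic PES on the water frame (hartree/Bohr/rad internals)
water_pes <- function(geom = water_geom(), set = detect_primitives(geom),
                      anharmonic = TRUE) {
  F2 <- matrix(c(0.45, 0.02, 0.01,
                 0.02, 0.48, 0.015,
                 0.01, 0.015, 0.12), 3, 3)
  cubic <- if (anharmonic) list(
    list(idx = c(1, 1, 1), value = -0.9),
    list(idx = c(2, 2, 2), value = -0.95),
    list(idx = c(1, 2, 3), value = -0.05),
    list(idx = c(3, 3, 3), value = -0.04),
    list(idx = c(1, 3, 3), value = -0.06)) else list()
  quartic <- if (anharmonic) list(
    list(idx = c(1, 1, 1, 1), value = 1.4),
    list(idx = c(2, 2, 2, 2), value = 1.5),
    list(idx = c(3, 3, 3, 3), value = 0.05)) else list()
  synthetic_polyatomic(geom, F2, set = set, cubic = cubic, quartic = quartic)
}

## CO-like Morse benchmark (omega_e ~ 2170, omega_e x_e ~ 13.3 cm^-1)
co_morse <- function() {
  morse_diatomic(D = 0.4035, a = 1.2304, r_e = 2.132,
                 masses = c(12, 15.99491462), symbols = c("C", "O"))
}

## exact dimensionless-coordinate Morse force field (analytic derivatives)
morse_qff <- function(pes) {
  mu <- prod(pes$geom$masses) / sum(pes$geom$masses) * 1822.888486209
  a <- pes$a_morse; D <- pes$D_morse
  w_au <- a * sqrt(2 * D / mu)
  conv <- 219474.6313632
  qff(pes$we,
      cubic = list(list(idx = c(1, 1, 1),
                        value = -6 * D * a^3 / (mu * w_au)^1.5 * conv)),
      quartic = list(list(idx = c(1, 1, 1, 1),
                          value = 14 * D * a^4 / (mu * w_au)^2 * conv)))
}

## random non-resonant toy system in dimensionless wavenumber units
random_system <- function(M, seed, scale3 = 4, scale4 = 2, kscale = 3) {
  set.seed(seed)
  repeat {
    w <- sort(runif(M, 600, 3600))
    ok <- TRUE
    for (i in seq_len(M)) for (k in seq_len(M)) {
      if (i != k && abs(2 * w[i] - w[k]) < 250) ok <- FALSE
    }
    if (M > 2) for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M)) {
      if (i < j && k != i && k != j && abs(w[i] + w[j] - w[k]) < 250) ok <- FALSE
    }
    if (ok) break
  }
  f3 <- array(0, c(M, M, M)); g1 <- array(0, c(M, M, M))
  for (i in 1:M) for (j in i:M) for (k in j:M) {
    v <- runif(1, -1, 1) * scale3
    for (p in curvib:::.perms(c(i, j, k))) f3[matrix(p, 1)] <- v
  }
  for (i in 1:M) for (j in i:M) for (k in 1:M) {
    v <- runif(1, -1, 1) * kscale
    g1[i, j, k] <- v; g1[j, i, k] <- v
  }
  f4 <- array(0, c(M, M, M, M)); g2 <- array(0, c(M, M, M, M))
  for (i in 1:M) for (k in i:M) {
    v <- runif(1, -1, 1) * scale4
    for (p in curvib:::.perms(c(i, i, k, k))) f4[matrix(p, 1)] <- v
  }
  for (i in 1:M) for (j in i:M) for (k in 1:M) for (l in k:M) {
    v <- runif(1, -1, 1) * kscale / 2
    for (ij in list(c(i, j), c(j, i))) for (kl in list(c(k, l), c(l, k)))
      g2[ij[1], ij[2], kl[1], kl[2]] <- v
  }
  list(omega = w,
       ff = qff(w, cubic = f3, quartic = f4),
       kin = kinetic_derivatives(w, g1 = g1, g2 = g2))
}

## oracle-vs-closed-form comparison over low states; returns max |dev|
oracle_max_dev <- function(omega, ff, kin = NULL, nmax = 14L,
                           states = NULL) {
  M <- length(omega)
  spec <- oracle_spec(omega,
                      f3 = ff$f3, f4 = ff$f4,
                      g1 = if (is.null(kin)) NULL else kin$g1,
                      g2 = if (is.null(kin)) NULL else kin$g2,
                      nmax = nmax)
  chi <- chi_curvilinear(derived_tensors(ff, kin))
  if (is.null(states)) {
    states <- c(lapply(seq_len(M), function(k) {
      v <- integer(M); v[k] <- 1L; v }),
      lapply(seq_len(M), function(k) { v <- integer(M); v[k] <- 2L; v }))
    if (M > 1) {
      v <- integer(M); v[1] <- 1L; v[2] <- 1L
      states <- c(states, list(v))
    }
  }
  o0 <- sum_over_states_pt2(spec, integer(M))
  max(vapply(states, function(v) {
    o <- sum_over_states_pt2(spec, v)
    abs((o$total - o0$total) - state_energy(chi, v))
  }, 0))
}
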