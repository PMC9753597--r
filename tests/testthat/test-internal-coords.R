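test_that("primitive detection reproduces minimal and redundant topologies", {
  # diatomic: one bond, nothing else
  di <- geometry(c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 1.75)))
  set <- detect_primitives(di)
  expect_equal(length(set), 1L)
  expect_equal(set$coords[[1]]$kind, "bond")

  # bent water: 2 bonds + 1 angle = 3Na - 6, non-redundant
  set_w <- detect_primitives(water_geom())
  kinds <- vapply(set_w$coords, `[[`, "", "kind")
  expect_equal(sum(kinds == "bond"), 2L)
  expect_equal(sum(kinds == "angle"), 1L)
  expect_equal(length(set_w), 3L)

  # oxirane ring: hand enumeration gives 7 bonds, 13 angles, 12 dihedrals,
  # exceeding 3Na - 6 = 15 (redundant set)
  ang <- 0.5291772
  ox <- geometry(c("C", "C", "O", "H", "H", "H", "H"), rbind(
    c(-0.735, -0.44, 0), c(0.735, -0.44, 0), c(0, 0.72, 0),
    c(-1.26, -0.87, 0.91), c(-1.26, -0.87, -0.91),
    c(1.26, -0.87, 0.91), c(1.26, -0.87, -0.91)) / ang)
  set_ox <- detect_primitives(ox)
  kinds <- vapply(set_ox$coords, `[[`, "", "kind")
  expect_equal(sum(kinds == "bond"), 7L)
  expect_equal(sum(kinds == "angle"), 13L)
  expect_equal(sum(kinds == "dihedral"), 12L)
  expect_gt(length(set_ox), 3L * 7L - 6L)

  # disconnected topology errors naming the fragments
  far <- geometry(c("H", "H", "H", "H"),
                  rbind(c(0, 0, 0), c(0, 0, 1.4),
                        c(50, 0, 0), c(50, 0, 1.4)))
  expect_error(detect_primitives(far), "disconnected")
})

test_that("B matrix rows are analytic first derivatives", {
  di <- geometry(c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 1.75)))
  set <- detect_primitives(di)
  B <- b_matrix(di, set)
  expect_equal(as.numeric(B), c(0, 0, -1, 0, 0, 1))

  geom <- water_geom()
  set <- detect_primitives(geom)
  B <- b_matrix(geom, set)
  # translational invariance: B annihilates uniform translations
  for (k in 1:3) {
    t <- rep(0, 9); t[seq(k, 9, 3)] <- 1
    expect_lt(max(abs(B %*% t)), 1e-12)
  }
  # central finite differences of the coordinate values
  x0 <- as.numeric(t(geom$coords)); h <- 1e-5
  for (c1 in seq_along(x0)) {
    xp <- x0; xp[c1] <- xp[c1] + h
    xm <- x0; xm[c1] <- xm[c1] - h
    gp <- geometry(geom$symbols, matrix(xp, ncol = 3, byrow = TRUE))
    gm <- geometry(geom$symbols, matrix(xm, ncol = 3, byrow = TRUE))
    fd <- (coord_values(gp, set) - coord_values(gm, set)) / (2 * h)
    expect_lt(max(abs(B[, c1] - fd)), 1e-8)
  }
})

test_that("B' blocks match analytic expectations and finite differences", {
  di <- geometry(c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 2.0)))
  set <- detect_primitives(di)
  Bp <- b_prime(di, set)
  u <- c(0, 0, 1); r <- 2.0
  blk <- (diag(3) - outer(u, u)) / r     # (a,a) Cartesian block of a bond
  expect_equal(Bp[1, 1:3, 1:3], blk, tolerance = 1e-12)

  geom <- water_geom(); set <- detect_primitives(geom)
  Bp <- b_prime(geom, set)
  # exact symmetry in the two Cartesian indices
  for (i in seq_len(length(set)))
    expect_identical(Bp[i, , ], t(Bp[i, , ]))
  # translation invariance in either slot
  for (k in 1:3) {
    t <- rep(0, 9); t[seq(k, 9, 3)] <- 1
    for (i in seq_len(length(set)))
      expect_lt(max(abs(Bp[i, , ] %*% t)), 1e-12)
  }
  # FD of b_matrix
  x0 <- as.numeric(t(geom$coords)); h <- 1e-5
  for (c1 in seq_along(x0)) {
    xp <- x0; xp[c1] <- xp[c1] + h
    xm <- x0; xm[c1] <- xm[c1] - h
    Bpfd <- (b_matrix(geometry(geom$symbols, matrix(xp, 3, 3, byrow = TRUE)), set) -
             b_matrix(geometry(geom$symbols, matrix(xm, 3, 3, byrow = TRUE)), set)) /
            (2 * h)
    expect_lt(max(abs(Bp[, , c1] - Bpfd)), 1e-6)
  }
})

test_that("G and G' follow the Wilson construction", {
  di <- geometry(c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 1.75)),
                 masses = c(2, 5))
  set <- detect_primitives(di)
  B <- b_matrix(di, set)
  expect_equal(g_matrix(B, c(2, 5))[1, 1], 1 / 2 + 1 / 5)
  # constant metric for a diatomic: G' = 0
  Gp <- g_prime(B, b_prime(di, set), c(2, 5))
  expect_lt(max(abs(Gp)), 1e-14)

  geom <- water_geom(); set <- detect_primitives(geom)
  m <- geom$masses
  B <- b_matrix(geom, set)
  G <- g_matrix(B, m)
  # independent textbook GF-method elements (bonds 1,2 share apex O = atom 1)
  x <- geom$coords
  r1 <- sqrt(sum((x[2, ] - x[1, ])^2)); r2 <- sqrt(sum((x[3, ] - x[1, ])^2))
  u <- (x[2, ] - x[1, ]) / r1; v <- (x[3, ] - x[1, ]) / r2
  phi <- acos(sum(u * v))
  expect_equal(G[1, 1], 1 / m[2] + 1 / m[1])
  expect_equal(G[1, 2], cos(phi) / m[1])
  expect_equal(G[1, 3], -sin(phi) / (r2 * m[1]))
  expect_equal(G[3, 3],
               1 / (m[2] * r1^2) + 1 / (m[3] * r2^2) +
                 (1 / r1^2 + 1 / r2^2 - 2 * cos(phi) / (r1 * r2)) / m[1])

  # G' vs FD of G, and (i,j) symmetry
  Bp <- b_prime(geom, set)
  Gp <- g_prime(B, Bp, m)
  for (cc in seq_len(dim(Gp)[3]))
    expect_identical(Gp[, , cc], t(Gp[, , cc]))
  x0 <- as.numeric(t(x)); h <- 1e-5
  for (c1 in seq_along(x0)) {
    xp <- x0; xp[c1] <- xp[c1] + h
    xm <- x0; xm[c1] <- xm[c1] - h
    Gfd <- (g_matrix(b_matrix(geometry(geom$symbols, matrix(xp, 3, 3, byrow = TRUE),
                                       masses = m), set), m) -
            g_matrix(b_matrix(geometry(geom$symbols, matrix(xm, 3, 3, byrow = TRUE),
                                       masses = m), set), m)) / (2 * h)
    expect_lt(max(abs(Gp[, , c1] - Gfd)), 1e-6)
  }

  # redundant set: at least N - (3 Na - 6) vanishing G eigenvalues
  set_r <- structure(list(coords = c(set$coords,
    list(curvib:::.new_ic("bond", c(2L, 3L))))), class = "cv_internal_set")
  Gr <- g_matrix(b_matrix(geom, set_r), m)
  ev <- eigen(Gr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(sum(ev < 1e-10 * max(ev)), length(set_r) - 3L)
})

test_that("coordinate values are frame invariant and dihedrals unwrap", {
  # butane-like 4-atom chain with a dihedral
  geom <- geometry(c("C", "C", "C", "C"), rbind(
    c(0, 0, 0), c(2.9, 0, 0), c(3.9, 2.7, 0), c(6.8, 2.9, 1.9)))
  set <- detect_primitives(geom)
  v0 <- coord_values(geom, set)
  # random rotation + translation
  th <- 0.73
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ax <- matrix(c(1, 0, 0, 0, cos(1.1), -sin(1.1), 0, sin(1.1), cos(1.1)), 3, 3)
  xr <- t((R %*% ax) %*% t(geom$coords)) + rep(1, 4) %o% c(3, -2, 5)
  vr <- coord_values(geometry(geom$symbols, xr), set)
  expect_lt(max(abs(v0 - vr)), 1e-10)

  dih <- which(vapply(set$coords, `[[`, "", "kind") == "dihedral")
  expect_true(all(v0[dih] > -pi & v0[dih] <= pi))
  # continuous unwrapping across the branch cut
  ref <- v0; ref[dih] <- ref[dih] + 2 * pi
  v_un <- coord_values(geom, set, ref = ref)
  expect_equal(v_un[dih], v0[dih] + 2 * pi, tolerance = 1e-12)
})

test_that("near-linear angles require the linear-angle kind", {
  lin <- geometry(c("O", "C", "O"),
                  rbind(c(-2.2, 0, 0), c(0, 0, 0), c(2.2, 0.001, 0)))
  set <- detect_primitives(lin)
  kinds <- vapply(set$coords, `[[`, "", "kind")
  expect_equal(sum(kinds == "linear-angle"), 2L)
  expect_equal(length(set), 4L)   # 3 Na - 5
  B <- b_matrix(lin, set)
  expect_equal(qr(B)$rank, 4L)
  for (k in 1:3) {
    t <- rep(0, 9); t[seq(k, 9, 3)] <- 1
    expect_lt(max(abs(B %*% t)), 1e-12)
  }
  # a plain angle evaluated at linearity is a hard error
  set_bad <- structure(list(coords = list(curvib:::.new_ic("angle", 1:3))),
                       class = "cv_internal_set")
  lin0 <- geometry(c("O", "C", "O"),
                   rbind(c(-2.2, 0, 0), c(0, 0, 0), c(2.2, 0, 0)))
  expect_error(b_matrix(lin0, set_bad), "linear-angle")
})

test_that("XYZ files round-trip through the reader", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("3", "water", "O 0.0 0.0 0.0",
               "H 0.9578 0.0 0.0", "H -0.24 0.927 0.0"), f)
  g <- read_xyz(f)
  expect_equal(g$symbols, c("O", "H", "H"))
  expect_equal(g$coords[2, 1] * 0.529177210903, 0.9578, tolerance = 1e-10)
  suppressWarnings(expect_error(read_xyz(tempfile(fileext = ".xyz"))))
})
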