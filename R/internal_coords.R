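# Primitive internal coordinates (PICs): all bond lengths, valence angles
# (plain or linear pairs) and dihedral angles implied by the molecular
# topology.  The set is generally redundant; redundancy is removed after the
# harmonic problem is solved (see gf_solve).

.coord_atoms <- function(ic) ic$atoms

.new_ic <- function(kind, atoms, axis = NULL, component = NA_integer_) {
  structure(list(kind = kind, atoms = as.integer(atoms), axis = axis,
                 component = component),
            class = "cv_internal_coordinate")
}

#' @export
format.cv_internal_coordinate <- function(x, ...) {
  lab <- paste(x$atoms, collapse = "-")
  if (x$kind == "linear-angle") lab <- paste0(lab, " (", x$component, ")")
  paste0(x$kind, " ", lab)
}

#' @export
print.cv_internal_coordinate <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Detect primitive internal coordinates from the molecular topology
#'
#' Bonds are atom pairs closer than `bond_scale` times the sum of their
#' covalent radii; angles are formed between bonded pairs sharing an atom;
#' dihedrals around every bond that has at least one further neighbour on
#' each side.  Valence angles beyond `linear_thresh` degrees are replaced by
#' a pair of orthogonal linear-angle coordinates whose perpendicular axes are
#' fixed deterministically from the reference geometry.
#'
#' @param geom a [geometry()] object (at least two atoms).
#' @param bond_scale bond detection threshold as a multiple of the covalent
#'   radius sum (default 1.3).
#' @param linear_thresh angle (degrees) beyond which a valence angle is
#'   treated as linear.
#' @return An object of class `cv_internal_set`: an ordered list of
#'   coordinates (bonds, then angles, then dihedrals, each sorted by its
#'   canonical atom-index tuple).
#' @export
detect_primitives <- function(geom, bond_scale = 1.3, linear_thresh = 175) {
  na <- .n_atoms(geom)
  if (na < 2L) stop("need at least two atoms to define internal coordinates")
  x <- geom$coords
  rcov <- .covalent_radii[geom$symbols] / .cv$bohr_to_ang
  if (anyNA(rcov))
    stop("no covalent radius tabulated for element(s): ",
         paste(unique(geom$symbols[is.na(rcov)]), collapse = ", "))

  bonds <- list()
  adj <- vector("list", na)
  for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
    d <- sqrt(sum((x[i, ] - x[j, ])^2))
    if (d <= bond_scale * (rcov[i] + rcov[j])) {
      bonds[[length(bonds) + 1L]] <- c(i, j)
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  if (length(bonds) == 0L) stop("no bonds detected: disconnected topology")

  # connectivity
  seen <- logical(na); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[cur]]) if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
  }
  if (!all(seen))
    stop("disconnected topology: fragments {",
         paste(which(seen), collapse = ","), "} and {",
         paste(which(!seen), collapse = ","), "}")

  coords <- list()
  ord <- order(vapply(bonds, `[[`, 0L, 1L), vapply(bonds, `[[`, 0L, 2L))
  for (b in bonds[ord]) coords[[length(coords) + 1L]] <- .new_ic("bond", b)

  # angles
  angs <- list()
  for (b in seq_len(na)) {
    nb <- sort(adj[[b]])
    if (length(nb) < 2L) next
    for (p in seq_len(length(nb) - 1L)) for (q in (p + 1L):length(nb)) {
      angs[[length(angs) + 1L]] <- c(nb[p], b, nb[q])
    }
  }
  if (length(angs)) {
    key <- vapply(angs, function(a) sprintf("%04d%04d%04d", a[1], a[2], a[3]), "")
    for (a in angs[order(key)]) {
      th <- .angle_value(x[a[1], ], x[a[2], ], x[a[3], ])
      if (th > linear_thresh * pi / 180) {
        ax <- .linear_axes(x[a[1], ], x[a[3], ])
        coords[[length(coords) + 1L]] <- .new_ic("linear-angle", a, ax$p1, 1L)
        coords[[length(coords) + 1L]] <- .new_ic("linear-angle", a, ax$p2, 2L)
      } else {
        coords[[length(coords) + 1L]] <- .new_ic("angle", a)
      }
    }
  }

  # dihedrals a-b-c-d around each bond b-c
  dihs <- list()
  for (bc in bonds[ord]) {
    b <- bc[1L]; c <- bc[2L]
    for (a in sort(adj[[b]])) {
      if (a == c) next
      if (.angle_value(x[a, ], x[b, ], x[c, ]) > linear_thresh * pi / 180) next
      for (d in sort(adj[[c]])) {
        if (d == b || d == a) next
        if (.angle_value(x[b, ], x[c, ], x[d, ]) > linear_thresh * pi / 180) next
        dihs[[length(dihs) + 1L]] <- c(a, b, c, d)
      }
    }
  }
  if (length(dihs)) {
    dihs <- lapply(dihs, function(d) if (d[2] < d[3]) d else rev(d))
    key <- vapply(dihs, function(d) paste(sprintf("%04d", d), collapse = ""), "")
    dihs <- dihs[order(key)]
    dihs <- dihs[!duplicated(vapply(dihs, paste, "", collapse = "-"))]
    for (d in dihs) coords[[length(coords) + 1L]] <- .new_ic("dihedral", d)
  }

  structure(list(coords = coords), class = "cv_internal_set")
}

#' @export
print.cv_internal_set <- function(x, ...) {
  kinds <- vapply(x$coords, `[[`, "", "kind")
  cat(sprintf("<cv_internal_set: %d coordinates (%d bond, %d angle, %d linear-angle, %d dihedral)>\n",
              length(kinds), sum(kinds == "bond"), sum(kinds == "angle"),
              sum(kinds == "linear-angle"), sum(kinds == "dihedral")))
  invisible(x)
}

#' @export
length.cv_internal_set <- function(x) length(x$coords)

.angle_value <- function(a, b, c) {
  u <- a - b; v <- c - b
  atan2(sqrt(sum(.cross3(u, v)^2)), sum(u * v))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## deterministic perpendicular axis pair for a near-linear a..c direction
.linear_axes <- function(xa, xc) {
  e <- xc - xa; e <- e / sqrt(sum(e^2))
  k <- which.min(abs(e))
  p1 <- numeric(3); p1[k] <- 1
  p1 <- p1 - sum(p1 * e) * e
  p1 <- p1 / sqrt(sum(p1^2))
  p2 <- .cross3(e, p1)
  list(p1 = p1, p2 = p2)
}

## t2 evaluation of one internal coordinate over its own atoms ------------
.ic_t2 <- function(ic, x) {
  at <- ic$atoms
  n <- 3L * length(at)
  vecs <- lapply(seq_along(at), function(k) .t2_vec(x[at[k], ], 3L * (k - 1L), n))
  switch(ic$kind,
    bond = .t2_norm(.t2_vdiff(vecs[[1]], vecs[[2]])),
    angle = {
      u <- .t2_vdiff(vecs[[1]], vecs[[2]])
      v <- .t2_vdiff(vecs[[3]], vecs[[2]])
      cr <- .t2_cross(u, v)
      s <- .t2_norm(cr)
      if (s$v / (.t2_norm(u)$v * .t2_norm(v)$v) < 1e-7)
        stop("valence angle at 0 or pi for atoms ",
             paste(at, collapse = "-"),
             ": use the linear-angle coordinate kind instead")
      .t2_atan2(s, .t2_dot(u, v))
    },
    "linear-angle" = {
      u <- .t2_unit(.t2_vdiff(vecs[[1]], vecs[[2]]))
      v <- .t2_unit(.t2_vdiff(vecs[[3]], vecs[[2]]))
      p <- .t2_vconst(ic$axis, n)
      .t2_dot(p, .t2_vadd(u, v))
    },
    dihedral = {
      b1 <- .t2_vdiff(vecs[[2]], vecs[[1]])
      b2 <- .t2_vdiff(vecs[[3]], vecs[[2]])
      b3 <- .t2_vdiff(vecs[[4]], vecs[[3]])
      n1 <- .t2_cross(b1, b2)
      n2 <- .t2_cross(b2, b3)
      m <- .t2_cross(n1, .t2_unit(b2))
      .t2_atan2(.t2_dot(m, n2), .t2_dot(n1, n2))
    },
    stop("unknown coordinate kind: ", ic$kind))
}

## plain numeric value of one coordinate
.ic_value <- function(ic, x) {
  at <- ic$atoms
  switch(ic$kind,
    bond = sqrt(sum((x[at[1], ] - x[at[2], ])^2)),
    angle = .angle_value(x[at[1], ], x[at[2], ], x[at[3], ]),
    "linear-angle" = {
      u <- x[at[1], ] - x[at[2], ]; u <- u / sqrt(sum(u^2))
      v <- x[at[3], ] - x[at[2], ]; v <- v / sqrt(sum(v^2))
      sum(ic$axis * (u + v))
    },
    dihedral = {
      b1 <- x[at[2], ] - x[at[1], ]
      b2 <- x[at[3], ] - x[at[2], ]
      b3 <- x[at[4], ] - x[at[3], ]
      n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
      m <- .cross3(n1, b2 / sqrt(sum(b2^2)))
      atan2(sum(m * n2), sum(n1 * n2))
    })
}

#' Values of internal coordinates at a geometry
#'
#' Bond values are in Bohr, angles and dihedrals in radians.  When `ref`
#' (a vector of reference values) is supplied, dihedral values are unwrapped
#' continuously onto the branch of the reference, so that finite differences
#' across the \eqn{(-\pi,\pi]} branch cut remain valid.
#'
#' @param geom a [geometry()] object.
#' @param set a [detect_primitives()] coordinate set.
#' @param ref optional reference values used for dihedral unwrapping.
#' @return Numeric vector of coordinate values.
#' @export
coord_values <- function(geom, set, ref = NULL) {
  x <- geom$coords
  v <- vapply(set$coords, .ic_value, 0, x = x)
  if (!is.null(ref)) {
    dih <- vapply(set$coords, function(ic) ic$kind == "dihedral", TRUE)
    dv <- v[dih] - ref[dih]
    v[dih] <- ref[dih] + (dv - 2 * pi * round(dv / (2 * pi)))
  }
  v
}

#' Wilson B matrix
#'
#' Analytic first derivatives of every internal coordinate with respect to
#' the Cartesian coordinates, `B[i, x] = ds_i/dx`.
#'
#' @inheritParams coord_values
#' @return N x 3Na matrix.
#' @export
b_matrix <- function(geom, set) {
  na <- .n_atoms(geom); x <- geom$coords
  B <- matrix(0, length(set$coords), 3L * na)
  for (i in seq_along(set$coords)) {
    ic <- set$coords[[i]]
    t2 <- .ic_t2(ic, x)
    for (k in seq_along(ic$atoms)) {
      cols <- (3L * (ic$atoms[k] - 1L) + 1L):(3L * ic$atoms[k])
      B[i, cols] <- t2$g[(3L * (k - 1L) + 1L):(3L * k)]
    }
  }
  B
}

#' Wilson B' tensor
#'
#' Analytic second derivatives `Bp[i, x, y] = d^2 s_i / dx dy`, exactly
#' symmetric in the two Cartesian indices.
#'
#' @inheritParams coord_values
#' @return N x 3Na x 3Na array.
#' @export
b_prime <- function(geom, set) {
  na <- .n_atoms(geom); x <- geom$coords
  Bp <- array(0, c(length(set$coords), 3L * na, 3L * na))
  for (i in seq_along(set$coords)) {
    ic <- set$coords[[i]]
    t2 <- .ic_t2(ic, x)
    idx <- unlist(lapply(ic$atoms, function(a) (3L * (a - 1L) + 1L):(3L * a)))
    Bp[i, idx, idx] <- (t2$H + t(t2$H)) / 2
  }
  Bp
}

#' Wilson G matrix
#'
#' `G = B M^-1 B^T` with the diagonal matrix of nuclear masses expanded per
#' Cartesian component.  Masses are used exactly as supplied, so the unit of
#' G is 1/(mass unit).
#'
#' @param B Wilson B matrix.
#' @param masses per-atom masses.
#' @return symmetric N x N matrix.
#' @export
g_matrix <- function(B, masses) {
  if (3L * length(masses) != ncol(B))
    stop("masses inconsistent with B matrix dimension")
  w <- rep(1 / masses, each = 3L)
  G <- B %*% (t(B) * w)
  (G + t(G)) / 2
}

#' Cartesian derivatives of the Wilson G matrix
#'
#' `Gp[i, j, c] = dG_ij/dx_c`, assembled from `B' M^-1 B^T + B M^-1 B'^T`,
#' exactly symmetric in (i, j).
#'
#' @param B Wilson B matrix.
#' @param Bp Wilson B' tensor.
#' @param masses per-atom masses.
#' @return N x N x 3Na array.
#' @export
g_prime <- function(B, Bp, masses) {
  if (3L * length(masses) != ncol(B))
    stop("masses inconsistent with B matrix dimension")
  w <- rep(1 / masses, each = 3L)
  n <- nrow(B); nc <- ncol(B)
  Bw <- t(B) * w                      # 3Na x N, rows scaled by 1/m
  Gp <- array(0, c(n, n, nc))
  for (cc in seq_len(nc)) {
    S <- Bp[, , cc] %*% Bw            # dB/dx_c M^-1 B^T
    Gp[, , cc] <- S + t(S)
  }
  Gp
}
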