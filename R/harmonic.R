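# Harmonic analysis: Wilson GF method in (possibly redundant) internal
# coordinates, the standard mass-weighted normal-mode analysis in Cartesian
# coordinates, and the Coriolis data needed by the Cartesian-frame VPT2.

#' Solve the harmonic problem by the Wilson GF method
#'
#' The GF eigenproblem is symmetrized: G is diagonalized, its null space
#' (redundancies) removed, and `G^{1/2} F G^{1/2}` diagonalized on the
#' remaining subspace.  Eigenvectors with vanishing G eigenvalue are
#' discarded, so redundant coordinate sets are handled transparently.
#'
#' @param G Wilson G matrix in atomic units (masses in electron masses).
#' @param F Hessian of the potential with respect to the internal
#'   coordinates (hartree, Bohr/radians).
#' @param null_tol relative threshold below which G eigenvalues count as
#'   redundancies.
#' @return An object of class `cv_harmonic` with elements `omega` (cm^-1,
#'   ascending), `omega_au`, `L` (N x M normal modes in internal
#'   coordinates, normalized so that `t(L) %*% solve(G) %*% L = I` on the
#'   non-null subspace), `Lt`/`Lt_inv` (square mode matrix in the
#'   redundancy-free basis `U`), `U`, `imaginary` flags and
#'   `frame = "curvilinear"`.
#' @export
gf_solve <- function(G, F, null_tol = 1e-8) {
  stopifnot(nrow(G) == ncol(G), all(dim(G) == dim(F)))
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- eg$values > null_tol * max(eg$values)
  U <- eg$vectors[, keep, drop = FALSE]
  ghalf <- sqrt(eg$values[keep])
  Ft <- t(U) %*% ((F + t(F)) / 2) %*% U
  X <- Ft * outer(ghalf, ghalf)          # G^{1/2} F G^{1/2} in the U basis
  ex <- eigen((X + t(X)) / 2, symmetric = TRUE)
  ord <- order(.au_omega_to_cm(ex$values))
  lam <- ex$values[ord]
  C <- ex$vectors[, ord, drop = FALSE]
  Lt <- C * ghalf                         # G_t^{1/2} C
  Lt_inv <- t(C) / rep(ghalf, each = ncol(C))
  sol <- structure(list(
    omega = .au_omega_to_cm(lam),
    omega_au = sign(lam) * sqrt(abs(lam)),
    L = U %*% Lt, Lt = Lt, Lt_inv = Lt_inv, U = U,
    imaginary = lam < -(null_tol * max(abs(lam), 1e-30)),
    frame = "curvilinear"), class = "cv_harmonic")
  fix_mode_phases(sol)
}

#' Harmonic analysis in Cartesian coordinates
#'
#' Mass-weighted normal-mode analysis with rigid translations and rotations
#' projected out.
#'
#' @param Hx Cartesian Hessian (hartree/Bohr^2), symmetric 3Na x 3Na.
#' @param geom the [geometry()] the Hessian belongs to.
#' @return A `cv_harmonic` object with `omega` (cm^-1), mass-weighted modes
#'   `lmw` (3Na x M, orthonormal) and `frame = "cartesian"`.
#' @export
cartesian_harmonic <- function(Hx, geom) {
  na <- .n_atoms(geom)
  stopifnot(nrow(Hx) == 3L * na, ncol(Hx) == 3L * na)
  m <- .mass_vector_au(geom)
  Hmw <- Hx / sqrt(outer(m, m))
  if (max(abs(Hmw)) == 0) {
    warning("zero Hessian: no vibrational modes")
    return(structure(list(omega = numeric(0), omega_au = numeric(0),
                          lmw = matrix(0, 3L * na, 0L),
                          imaginary = logical(0), frame = "cartesian"),
                     class = "cv_harmonic"))
  }
  Vtr <- .trans_rot_basis(geom)
  P <- diag(3L * na) - Vtr %*% t(Vtr)
  Hp <- P %*% ((Hmw + t(Hmw)) / 2) %*% P
  eh <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE)
  ovl <- colSums((t(Vtr) %*% eh$vectors)^2)
  keep <- ovl < 0.5
  lam <- eh$values[keep]
  vec <- eh$vectors[, keep, drop = FALSE]
  ord <- order(.au_omega_to_cm(lam))
  lam <- lam[ord]; vec <- vec[, ord, drop = FALSE]
  sol <- structure(list(
    omega = .au_omega_to_cm(lam),
    omega_au = sign(lam) * sqrt(abs(lam)),
    lmw = vec,
    imaginary = lam < -1e-8 * max(abs(lam)),
    frame = "cartesian"), class = "cv_harmonic")
  fix_mode_phases(sol)
}

## orthonormal basis of rigid translations and infinitesimal rotations in
## mass-weighted coordinates
.trans_rot_basis <- function(geom) {
  na <- .n_atoms(geom)
  m <- geom$masses * .cv$amu_to_me
  com <- colSums(geom$coords * m) / sum(m)
  xc <- sweep(geom$coords, 2L, com)
  V <- matrix(0, 3L * na, 6L)
  for (k in 1:3) V[seq(k, 3L * na, by = 3L), k] <- sqrt(m)
  ax <- diag(3)
  for (k in 1:3) {
    r <- t(vapply(seq_len(na), function(a) .cross3(ax[k, ], xc[a, ]), numeric(3)))
    V[, 3L + k] <- as.numeric(t(r * sqrt(m)))
  }
  qr_ <- qr(V)
  qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
}

#' Fix normal-mode phases
#'
#' Flips the sign of every mode so that its largest-magnitude component is
#' positive (ties broken by the lowest index), making the signs of cubic
#' force constants reproducible across runs.  Idempotent.
#'
#' @param sol a `cv_harmonic` solution.
#' @return The solution with deterministic mode signs.
#' @export
fix_mode_phases <- function(sol) {
  main <- if (sol$frame == "cartesian") "lmw" else "L"
  M <- sol[[main]]
  if (is.null(M) || ncol(M) == 0L) return(sol)
  sgn <- vapply(seq_len(ncol(M)), function(j) {
    col <- M[, j]
    i <- which(abs(col) >= max(abs(col)) - 0)[1L]
    if (col[i] < 0) -1 else 1
  }, 0)
  sol[[main]] <- sweep(M, 2L, sgn, `*`)
  if (sol$frame == "curvilinear") {
    sol$Lt <- sweep(sol$Lt, 2L, sgn, `*`)
    sol$Lt_inv <- sweep(sol$Lt_inv, 1L, sgn, `*`)
  }
  sol
}

#' @export
print.cv_harmonic <- function(x, ...) {
  cat(sprintf("<cv_harmonic (%s): %d modes>\n", x$frame, length(x$omega)))
  if (length(x$omega))
    cat("  omega [cm^-1]:", paste(sprintf("%.1f", x$omega), collapse = " "), "\n")
  if (any(x$imaginary)) cat("  ** imaginary frequencies flagged **\n")
  invisible(x)
}

#' Coriolis zeta constants and equilibrium rotational constants
#'
#' Computes the Coriolis coupling constants
#' \eqn{\zeta^\alpha_{ij} = \sum_a (l_{ai} \times l_{aj})_\alpha} from the
#' mass-weighted Cartesian normal modes expressed in the principal inertia
#' frame, together with the equilibrium rotational constants (cm^-1).
#' Principal axes with vanishing moment of inertia (linear molecules) get a
#' zero rotational constant so the corresponding term drops out.
#'
#' @param geom a [geometry()].
#' @param sol the matching Cartesian-frame `cv_harmonic` solution.
#' @return Object of class `cv_coriolis`: list with `zeta` (M x M x 3,
#'   antisymmetric in the mode indices) and `Be` (length 3, cm^-1).
#' @export
coriolis_constants <- function(geom, sol) {
  if (sol$frame != "cartesian")
    stop("Coriolis constants require a Cartesian-frame harmonic solution")
  na <- .n_atoms(geom)
  m <- geom$masses
  com <- colSums(geom$coords * m) / sum(m)
  xc <- sweep(geom$coords, 2L, com)
  Imat <- matrix(0, 3, 3)
  for (a in seq_len(na)) {
    r <- xc[a, ]
    Imat <- Imat + m[a] * (sum(r^2) * diag(3) - outer(r, r))
  }
  ei <- eigen(Imat, symmetric = TRUE)
  axes <- ei$vectors                     # columns: principal axes
  Be <- ifelse(ei$values > 1e-8, .cv$rotconst_fac / ei$values, 0)
  M <- ncol(sol$lmw)
  zeta <- array(0, c(M, M, 3))
  lrot <- vector("list", M)
  for (i in seq_len(M))
    lrot[[i]] <- matrix(sol$lmw[, i], ncol = 3L, byrow = TRUE) %*% axes
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (i >= j) next
    z <- colSums(t(vapply(seq_len(na),
                          function(a) .cross3(lrot[[i]][a, ], lrot[[j]][a, ]),
                          numeric(3))))
    zeta[i, j, ] <- z
    zeta[j, i, ] <- -z
  }
  structure(list(zeta = zeta, Be = Be), class = "cv_coriolis")
}
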