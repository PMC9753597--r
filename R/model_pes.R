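# Engine-free analytic potentials.  A `cv_pes` object implements the engine
# adapter contract: `pes$eval(geom)` returns energy (hartree), Cartesian
# gradient (hartree/Bohr) and Cartesian Hessian (hartree/Bohr^2) at any
# geometry, with derivatives exact by construction (chain rule through the
# analytic B and B' tensors).

.new_pes <- function(eval, info = list()) {
  structure(c(list(eval = eval), info), class = "cv_pes")
}

#' @export
print.cv_pes <- function(x, ...) {
  cat("<cv_pes:", if (!is.null(x$kind)) x$kind else "custom", ">\n")
  invisible(x)
}

## generic: potential defined in internal coordinates with analytic
## derivatives up to second order; Cartesian derivatives by chain rule
## g_x = B^T dV, H_x = B^T d2V B + sum_i dV_i B'_i  (exact)
.pes_from_internal <- function(geom_ref, set, vfun, kind = "internal") {
  sref <- coord_values(geom_ref, set)
  evalf <- function(geom) {
    s <- coord_values(geom, set, ref = sref)
    d <- vfun(s)
    B <- b_matrix(geom, set)
    Bp <- b_prime(geom, set)
    gx <- drop(t(B) %*% d$dV)
    Hx <- t(B) %*% d$d2V %*% B
    for (i in seq_along(d$dV))
      if (d$dV[i] != 0) Hx <- Hx + d$dV[i] * Bp[i, , ]
    list(energy = d$V, gradient = gx, hessian = (Hx + t(Hx)) / 2)
  }
  .new_pes(evalf, list(kind = kind, set = set, geom_ref = geom_ref,
                       sref = sref, vfun = vfun))
}

#' Morse diatomic model potential
#'
#' \eqn{V(r) = D (1 - e^{-a (r - r_e)})^2}, the standard exactness benchmark
#' for VPT2: with analytic derivatives, the VPT2 fundamental equals the
#' exact Morse fundamental \eqn{\omega_e - 2 \omega_e x_e}.
#'
#' @param D well depth (hartree).
#' @param a Morse range parameter (1/Bohr).
#' @param r_e equilibrium distance (Bohr).
#' @param masses the two atomic masses (amu).
#' @param symbols element symbols used for the reference geometry.
#' @return A `cv_pes` with extra fields `we` and `wexe` (cm^-1), the exact
#'   Morse constants \eqn{\omega_e = a \sqrt{2 D / \mu}} and
#'   \eqn{\omega_e x_e = a^2 / (2 \mu)} (atomic units converted to cm^-1),
#'   and the reference `geom` (atoms on the z axis).
#' @export
morse_diatomic <- function(D, a, r_e, masses = c(1.00782503, 18.99840316),
                           symbols = c("H", "F")) {
  stopifnot(D > 0, a > 0, r_e > 0, length(masses) == 2L)
  geom <- geometry(symbols, rbind(c(0, 0, 0), c(0, 0, r_e)), masses = masses)
  set <- structure(list(coords = list(.new_ic("bond", c(1L, 2L)))),
                   class = "cv_internal_set")
  vfun <- function(s) {
    xi <- s[1] - r_e
    e <- exp(-a * xi)
    list(V = D * (1 - e)^2,
         dV = 2 * D * a * e * (1 - e),
         d2V = matrix(2 * D * a^2 * e * (2 * e - 1), 1, 1))
  }
  mu <- prod(masses) / sum(masses) * .cv$amu_to_me
  pes <- .pes_from_internal(geom, set, vfun, kind = "morse")
  pes$we <- a * sqrt(2 * D / mu) * .cv$hartree_to_cm
  pes$wexe <- a^2 / (2 * mu) * .cv$hartree_to_cm
  pes$D_morse <- D
  pes$a_morse <- a
  pes$geom <- geom
  pes
}

#' Synthetic polyatomic quartic model potential
#'
#' A quartic polynomial PES in the internal coordinates of a small molecular
#' frame, with exact Cartesian gradients and Hessians by chain rule through
#' the analytic B and B' tensors.  Together with [sum_over_states_pt2()] and
#' [fvci_reference()] this makes the whole anharmonic pipeline testable
#' without any electronic-structure computation.
#'
#' @param geom reference geometry (assumed stationary).
#' @param set internal coordinate set; detected from the topology when
#'   omitted.
#' @param F2 harmonic (second-derivative) matrix in internal coordinates
#'   (hartree, Bohr/rad units); must be positive definite on the non-null
#'   subspace.
#' @param cubic,quartic lists of anharmonic force constants, each entry
#'   `list(idx = c(i,j,...), value = v)` giving the fully symmetric third or
#'   fourth derivative of V with respect to the internal coordinates.
#' @return A `cv_pes`.
#' @export
synthetic_polyatomic <- function(geom, F2, set = NULL,
                                 cubic = list(), quartic = list()) {
  if (is.null(set)) set <- detect_primitives(geom)
  n <- length(set$coords)
  stopifnot(nrow(F2) == n, ncol(F2) == n)
  C3 <- array(0, c(n, n, n))
  for (e in cubic) {
    for (p in .perms(e$idx)) C3[matrix(p, 1)] <- e$value
  }
  Q4 <- array(0, c(n, n, n, n))
  for (e in quartic) {
    for (p in .perms(e$idx)) Q4[matrix(p, 1)] <- e$value
  }
  vfun <- function(s) {
    ds <- s - coord_values(geom, set)    # displacement from reference
    V <- 0.5 * drop(t(ds) %*% F2 %*% ds)
    dV <- drop(F2 %*% ds)
    d2V <- F2
    if (length(cubic)) {
      c2 <- apply(C3, c(1, 2), function(v) sum(v * ds))   # C3 . ds (last idx)
      c1 <- apply(c2, 1, function(v) sum(v * ds))
      V <- V + sum(c1 * ds) / 6
      dV <- dV + c1 / 2
      d2V <- d2V + c2
    }
    if (length(quartic)) {
      q3 <- apply(Q4, c(1, 2, 3), function(v) sum(v * ds))
      q2 <- apply(q3, c(1, 2), function(v) sum(v * ds))
      q1 <- apply(q2, 1, function(v) sum(v * ds))
      V <- V + sum(q1 * ds) / 24
      dV <- dV + q1 / 6
      d2V <- d2V + q2 / 2
    }
    list(V = V, dV = dV, d2V = d2V)
  }
  .pes_from_internal(geom, set, vfun, kind = "synthetic_polyatomic")
}

## all permutations of a small index vector
.perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  unique(out)
}
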