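# Brute-force quantum-mechanical oracles: the perturbed vibrational
# Hamiltonian is represented explicitly in a harmonic-oscillator product
# basis via ladder-operator algebra, and second-order Rayleigh-Schrodinger
# perturbation theory (or full diagonalization) is evaluated by direct
# summation.  These oracles are intentionally independent of the closed-form
# VPT2 implementation they validate.
#
# Operator content and ordering:
#   H0 = 1/2 sum_i w_i (p_i^2 + q_i^2)
#   H1 = (1/6) sum f3_ijk q_i q_j q_k + (1/2) sum g1_ij,k p_i q_k p_j
#   H2 = (1/24) sum f4 q^4            + (1/4) sum g2_ij,kl p_i q_k q_l p_j
# The kinetic terms keep the symmetrized p .. q .. p ordering; every factor
# p contributes i * Pr with the real ladder matrix Pr, so each (even-p) term
# carries a sign (-1)^(#p/2).

#' Specification of an oracle Hamiltonian
#'
#' @param omega harmonic wavenumbers (cm^-1), length M (M <= 4 recommended).
#' @param f3 cubic force constants: full M x M x M symmetric array (cm^-1),
#'   or NULL.
#' @param f4 quartic force constants: full M^4 symmetric array, or NULL.
#' @param g1 first kinetic-metric derivatives g_ij,k: M x M x M array
#'   symmetric in (i, j), or NULL.
#' @param g2 second kinetic-metric derivatives g_ij,kl: M^4 array symmetric
#'   in (i, j) and (k, l), or NULL.
#' @param nmax harmonic-oscillator quanta per mode kept in the product basis.
#' @return An object of class `cv_oracle` carrying the dense H0 (diagonal),
#'   H1 and H2 matrices and the basis enumeration.
#' @export
oracle_spec <- function(omega, f3 = NULL, f4 = NULL, g1 = NULL, g2 = NULL,
                        nmax = 12L) {
  M <- length(omega)
  d <- nmax + 1L
  z3 <- array(0, c(M, M, M)); z4 <- array(0, c(M, M, M, M))
  if (is.null(f3)) f3 <- z3
  if (is.null(g1)) g1 <- z3
  if (is.null(f4)) f4 <- z4
  if (is.null(g2)) g2 <- z4
  stopifnot(all(dim(f3) == M), all(dim(f4) == M),
            all(dim(g1) == M), all(dim(g2) == M))

  Qm <- matrix(0, d, d); Pm <- matrix(0, d, d)
  for (n in 0:(nmax - 1L)) {
    Qm[n + 2L, n + 1L] <- sqrt((n + 1) / 2); Qm[n + 1L, n + 2L] <- sqrt((n + 1) / 2)
    Pm[n + 2L, n + 1L] <- sqrt((n + 1) / 2); Pm[n + 1L, n + 2L] <- -sqrt((n + 1) / 2)
  }
  dim_tot <- d^M
  lift <- function(permode) {
    # permode: list over modes of per-mode matrices (NULL = identity);
    # returns kron with mode 1 slowest
    out <- NULL
    for (m in seq_len(M)) {
      A <- if (is.null(permode[[m]])) diag(d) else permode[[m]]
      out <- if (is.null(out)) A else kronecker(out, A)
    }
    out
  }
  term_matrix <- function(seq_ops) {
    # seq_ops: list of (mode, 'q'|'p') in operator order; even # of p's
    permode <- vector("list", M)
    np <- 0L
    for (so in seq_ops) {
      m <- so[[1]]; ch <- so[[2]]
      if (ch == 'p') np <- np + 1L
      A <- if (ch == 'q') Qm else Pm
      permode[[m]] <- if (is.null(permode[[m]])) A else permode[[m]] %*% A
    }
    (-1)^(np %/% 2) * lift(permode)
  }

  # basis enumeration (mode 1 slowest) and H0
  grid <- as.matrix(expand.grid(rev(lapply(seq_len(M), function(m) 0:nmax))))
  states <- grid[, rev(seq_len(M)), drop = FALSE]
  colnames(states) <- NULL
  E0 <- as.numeric(states %*% (omega)) + sum(omega) / 2

  H1 <- matrix(0, dim_tot, dim_tot)
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M)) {
    if (f3[i, j, k] != 0)
      H1 <- H1 + (f3[i, j, k] / 6) *
        term_matrix(list(list(i, 'q'), list(j, 'q'), list(k, 'q')))
    if (g1[i, j, k] != 0)
      H1 <- H1 + (g1[i, j, k] / 2) *
        term_matrix(list(list(i, 'p'), list(k, 'q'), list(j, 'p')))
  }
  H2 <- matrix(0, dim_tot, dim_tot)
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M))
    for (l in seq_len(M)) {
      if (f4[i, j, k, l] != 0)
        H2 <- H2 + (f4[i, j, k, l] / 24) *
          term_matrix(list(list(i, 'q'), list(j, 'q'), list(k, 'q'), list(l, 'q')))
      if (g2[i, j, k, l] != 0)
        H2 <- H2 + (g2[i, j, k, l] / 4) *
          term_matrix(list(list(i, 'p'), list(k, 'q'), list(l, 'q'), list(j, 'p')))
    }

  structure(list(omega = omega, M = M, nmax = nmax, states = states,
                 E0 = E0, H1 = H1, H2 = H2),
            class = "cv_oracle")
}

.state_index <- function(spec, v) {
  stopifnot(length(v) == spec$M)
  if (any(v < 0) || any(v > spec$nmax))
    stop("state outside the oracle basis")
  idx <- which(apply(spec$states, 1L, function(s) all(s == v)))
  idx[1L]
}

#' Sum-over-states second-order perturbation energy
#'
#' Evaluates the Rayleigh-Schrodinger series through second order for one
#' vibrational state by explicit summation over the product basis.  The
#' first-order correction vanishes for every state because H1 is odd.
#'
#' @param spec an [oracle_spec()].
#' @param state integer vector of quantum numbers.
#' @param res_tol smallest tolerated energy denominator (cm^-1) for coupled
#'   intermediate states; the oracle declines (errors) on resonance.
#' @return List with `E0`, `E1`, `E2` and `total` (cm^-1, absolute energies
#'   including zero-point).
#' @export
sum_over_states_pt2 <- function(spec, state, res_tol = 1e-2) {
  r <- .state_index(spec, state)
  den <- spec$E0[r] - spec$E0
  c1 <- spec$H1[r, ]
  bad <- abs(den) < res_tol & abs(c1) > 1e-10
  bad[r] <- FALSE
  if (any(bad))
    stop("oracle declines: resonant intermediate state(s) ",
         paste(apply(spec$states[bad, , drop = FALSE], 1L, paste, collapse = ","),
               collapse = " | "))
  sel <- seq_along(den) != r & abs(c1) > 0
  E2 <- spec$H2[r, r] + sum(c1[sel]^2 / den[sel])
  list(E0 = spec$E0[r], E1 = spec$H1[r, r], E2 = E2,
       total = spec$E0[r] + spec$H1[r, r] + E2)
}

#' Variational (FVCI) reference energies
#'
#' Full diagonalization of the oracle Hamiltonian; each requested state is
#' assigned to the eigenvector with the largest squared overlap with the
#' corresponding harmonic basis state.
#'
#' @param spec an [oracle_spec()].
#' @param states list of quantum-number vectors (the ground state is always
#'   included).
#' @return data.frame with columns `label`, `energy` (absolute, cm^-1) and
#'   `transition` (cm^-1, relative to the variational ground state).
#' @export
fvci_reference <- function(spec, states) {
  H <- diag(spec$E0) + spec$H1 + spec$H2
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  pick <- function(v) {
    i <- .state_index(spec, v)
    j <- which.max(e$vectors[i, ]^2)
    e$values[j]
  }
  g0 <- pick(rep(0L, spec$M))
  lab <- vapply(states, paste, "", collapse = ",")
  en <- vapply(states, pick, 0)
  data.frame(label = lab, energy = en, transition = en - g0)
}
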