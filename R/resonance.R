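# Fermi-resonance machinery: the extended Martin test (two-step detuning +
# interaction-strength filter on the rho tensor), deperturbation of the chi
# matrix (DVPT2), polyad construction and the variational correction (GVPT2).

#' Extended Martin test for Fermi resonances
#'
#' Two-step screening of type I (2 w_i ~ w_k) and type II (w_i + w_j ~ w_k)
#' resonances: a detuning filter \eqn{\Delta \le \Delta\omega^{1-2}} followed
#' by a strength filter \eqn{\rho_{iik}^4 / (256 \Delta^3) \ge K^{1-2}}
#' (type I) or \eqn{\rho_{ijk}^4 / (64 \Delta^3) \ge K^{1-2}} (type II).
#' In the Cartesian frame rho reduces to the cubic force constant, so the
#' same test applies to both formulations.  An exactly degenerate candidate
#' (\eqn{\Delta = 0}) is auto-accepted with infinite strength.
#'
#' @param omega harmonic wavenumbers (cm^-1).
#' @param rho the rho tensor from [derived_tensors()] (or a plain M^3 array;
#'   a `cv_tensors` object is also accepted).
#' @param dw_thresh detuning threshold (cm^-1), default 200.
#' @param k_thresh strength threshold (cm^-1), default 1.
#' @return data.frame of class `cv_resonances` with columns `type`, `i`,
#'   `j`, `k`, `delta`, `K`, `accepted` and the term registry `key`.
#' @export
martin_test <- function(omega, rho, dw_thresh = 200, k_thresh = 1) {
  stopifnot(dw_thresh > 0, k_thresh > 0)
  if (inherits(rho, "cv_tensors")) rho <- rho$rho
  M <- length(omega)
  rows <- list()
  for (i in seq_len(M)) for (k in seq_len(M)) {
    if (i == k) next
    delta <- 2 * omega[i] - omega[k]
    if (abs(delta) > dw_thresh) next
    K <- if (delta == 0) Inf else rho[i, i, k]^4 / (256 * abs(delta)^3)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "I", i = i, j = NA_integer_, k = k, delta = abs(delta), K = K,
      accepted = K >= k_thresh, key = .res_key_I(i, k),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M)) {
    if (i >= j || k == i || k == j) next
    delta <- omega[i] + omega[j] - omega[k]
    if (abs(delta) > dw_thresh) next
    K <- if (delta == 0) Inf else rho[i, j, k]^4 / (64 * abs(delta)^3)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "II", i = i, j = j, k = k, delta = abs(delta), K = K,
      accepted = K >= k_thresh, key = .res_key_II(i, j, k),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), i = integer(0), j = integer(0),
               k = integer(0), delta = numeric(0), K = numeric(0),
               accepted = logical(0), key = character(0))
  class(out) <- c("cv_resonances", class(out))
  out
}

#' Deperturb the chi matrix (DVPT2)
#'
#' Discards from the recast chi sums every term whose denominator
#' corresponds to an accepted Fermi resonance; the discarded terms are
#' registered so they can be re-added analytically.
#'
#' @param tensors [derived_tensors()] output.
#' @param candidates a [martin_test()] table (only accepted rows are used),
#'   or a character vector of resonance keys.
#' @param omega harmonic wavenumbers; defaults to `tensors$omega`.
#' @param frame `"curvilinear"` or `"cartesian"`.
#' @param coriolis Coriolis data for the Cartesian frame.
#' @param ff Cartesian-frame force field (when `frame = "cartesian"`).
#' @return A `cv_chi` object with the `removed` registry filled.
#' @export
deperturb <- function(tensors, candidates, omega = NULL,
                      frame = c("curvilinear", "cartesian"),
                      coriolis = NULL, ff = NULL) {
  frame <- match.arg(frame)
  keys <- .accepted_keys(candidates)
  if (frame == "curvilinear")
    chi_curvilinear(tensors, omega = omega, deperturb = keys)
  else
    chi_cartesian(ff, coriolis = coriolis, omega = omega, deperturb = keys)
}

.accepted_keys <- function(candidates) {
  if (is.character(candidates)) return(candidates)
  if (is.data.frame(candidates)) return(candidates$key[candidates$accepted])
  as.character(unlist(candidates))
}

## ---- polyads --------------------------------------------------------------

.state_key <- function(v) paste(v, collapse = ",")

## partner states of `v` under one resonance (both directions)
.res_partners <- function(v, cand) {
  out <- list()
  if (cand$type == "I") {
    i <- cand$i; k <- cand$k
    if (v[k] >= 1) { p <- v; p[k] <- p[k] - 1L; p[i] <- p[i] + 2L
                     out[[length(out) + 1L]] <- p }
    if (v[i] >= 2) { p <- v; p[i] <- p[i] - 2L; p[k] <- p[k] + 1L
                     out[[length(out) + 1L]] <- p }
  } else {
    i <- cand$i; j <- cand$j; k <- cand$k
    if (v[k] >= 1) { p <- v; p[k] <- p[k] - 1L; p[i] <- p[i] + 1L
                     p[j] <- p[j] + 1L; out[[length(out) + 1L]] <- p }
    if (v[i] >= 1 && v[j] >= 1) { p <- v; p[i] <- p[i] - 1L
                                  p[j] <- p[j] - 1L; p[k] <- p[k] + 1L
                                  out[[length(out) + 1L]] <- p }
  }
  out
}

#' Build resonance polyads
#'
#' Transitive closure of the requested states under the accepted resonances:
#' states connected (directly or through intermediate states generated by a
#' resonance) end up in the same polyad; unaffected states become singleton
#' polyads.
#'
#' @param candidates [martin_test()] table; only accepted rows generate
#'   connections.
#' @param states list of quantum-number vectors of interest.
#' @param max_states safety cap on the closure size.
#' @return list of polyads, each a list with a `states` matrix (rows are
#'   quantum-number vectors).
#' @export
build_polyads <- function(candidates, states, max_states = 200L) {
  acc <- if (is.data.frame(candidates))
    candidates[candidates$accepted, , drop = FALSE] else candidates
  pool <- lapply(states, as.integer)
  names(pool) <- vapply(pool, .state_key, "")
  pool <- pool[!duplicated(names(pool))]
  edges <- list()
  queue <- pool
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (nrow(as.data.frame(acc)) == 0L) next
    for (r in seq_len(nrow(acc))) {
      for (p in .res_partners(v, acc[r, ])) {
        edges[[length(edges) + 1L]] <- c(.state_key(v), .state_key(p))
        if (!.state_key(p) %in% names(pool)) {
          if (length(pool) >= max_states)
            stop("polyad closure exceeded ", max_states, " states")
          pool[[.state_key(p)]] <- p
          queue[[.state_key(p)]] <- p
        }
      }
    }
  }
  # union-find over pool
  parent <- seq_along(pool)
  names(parent) <- names(pool)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (e in edges) {
    ra <- find(which(names(pool) == e[1])); rb <- find(which(names(pool) == e[2]))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(pool), find, 0)
  out <- lapply(unique(roots), function(r) {
    sts <- do.call(rbind, pool[roots == r])
    sts <- sts[order(apply(sts, 1L, .state_key)), , drop = FALSE]
    list(states = sts)
  })
  # deterministic polyad order: by the first state key
  out[order(vapply(out, function(p) .state_key(p$states[1, ]), ""))]
}

## ---- interaction elements -------------------------------------------------

#' Fermi interaction element of the contact-transformed Hamiltonian
#'
#' Leading-order matrix elements between resonant states, obtained from the
#' Cartesian expressions with the cubic constants replaced by the rho
#' tensor:
#' \deqn{\langle v+2_i | \tilde H | v+1_k \rangle =
#'   \frac{\rho_{iik}}{4} \sqrt{\frac{(v_i+1)(v_i+2)(v_k+1)}{2}}}
#' \deqn{\langle v+1_i+1_j | \tilde H | v+1_k \rangle =
#'   \rho_{ijk} \sqrt{\frac{(v_i+1)(v_j+1)(v_k+1)}{8}}}
#' With `aux = TRUE` the second-order contact-transformation correction
#' \eqn{\tfrac12 \sum_S \langle A|H_1|S\rangle \langle S|H_1|B\rangle
#' [ (E_A - E_S)^{-1} + (E_B - E_S)^{-1} ]} is added by explicit summation
#' over intermediate states outside the polyad.
#'
#' @param tensors [derived_tensors()] output (must carry `f3`/`g1`, as
#'   produced by [assemble_force_field()] inputs, for `aux = TRUE`).
#' @param kind `"I"` or `"II"`.
#' @param modes `c(i, k)` for type I, `c(i, j, k)` for type II.
#' @param v base quantum numbers (defaults to the ground state).
#' @param omega harmonic wavenumbers (needed for `aux`).
#' @param aux include the second-order correction.
#' @param exclude states (list of quantum vectors) excluded from the
#'   intermediate-state sum, typically the polyad members.
#' @return interaction element (cm^-1).
#' @export
interaction_element <- function(tensors, kind = c("I", "II"), modes,
                                v = NULL, omega = NULL, aux = FALSE,
                                exclude = list()) {
  kind <- match.arg(kind)
  M <- dim(tensors$rho)[1]
  if (is.null(v)) v <- rep(0L, M)
  if (kind == "I") {
    i <- modes[1]; k <- modes[2]
    A <- v; A[i] <- A[i] + 2L
    B <- v; B[k] <- B[k] + 1L
    W <- tensors$rho[i, i, k] / 4 *
      sqrt((v[i] + 1) * (v[i] + 2) * (v[k] + 1) / 2)
  } else {
    i <- modes[1]; j <- modes[2]; k <- modes[3]
    A <- v; A[i] <- A[i] + 1L; A[j] <- A[j] + 1L
    B <- v; B[k] <- B[k] + 1L
    W <- tensors$rho[i, j, k] *
      sqrt((v[i] + 1) * (v[j] + 1) * (v[k] + 1) / 8)
  }
  if (aux) {
    if (is.null(omega)) omega <- tensors$omega
    W <- W + .contact_correction(tensors, A, B, omega,
                                 exclude = c(exclude, list(A, B)))
  }
  W
}

## per-mode harmonic-oscillator matrices used by the explicit ladder sums
.ladder_mats <- function(nmax) {
  d <- nmax + 1L
  Q <- matrix(0, d, d); P <- matrix(0, d, d)   # p = i P
  for (n in 0:(nmax - 1L)) {
    s <- sqrt((n + 1) / 2)
    Q[n + 2L, n + 1L] <- s; Q[n + 1L, n + 2L] <- s
    P[n + 2L, n + 1L] <- s; P[n + 1L, n + 2L] <- -s
  }
  list(Q = Q, P = P)
}

## <X| H1 |Y> by ladder algebra (exact); f3/g1 taken from the tensors object
.h1_element <- function(tensors, X, Y) {
  f3 <- tensors$f3; g1 <- tensors$g1
  M <- dim(f3)[1]
  nmax <- max(X, Y) + 3L
  lm <- .ladder_mats(nmax)
  Q <- lm$Q; P <- lm$P
  dX <- X - Y
  if (sum(abs(dX)) > 3L || sum(abs(dX)) %% 2L == 0L) return(0)
  el <- function(mode_strings) {
    # mode_strings: named list mode -> matrix product string already built
    val <- 1
    for (m in seq_len(M)) {
      A <- mode_strings[[m]]
      if (is.null(A)) {
        if (X[m] != Y[m]) return(0)
        next
      }
      e <- A[X[m] + 1L, Y[m] + 1L]
      if (e == 0) return(0)
      val <- val * e
    }
    val
  }
  tot <- 0
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M)) {
    if (f3[i, j, k] != 0) {
      ms <- vector("list", M)
      for (m in c(i, j, k)) ms[[m]] <- if (is.null(ms[[m]])) Q else ms[[m]] %*% Q
      tot <- tot + f3[i, j, k] / 6 * el(ms)
    }
    if (g1[i, j, k] != 0) {
      # (1/2) g p_i q_k p_j with sign -1 from p = iP (two momenta)
      ms <- vector("list", M)
      app <- function(m, A) ms[[m]] <<- if (is.null(ms[[m]])) A else ms[[m]] %*% A
      app(i, P); app(k, Q); app(j, P)
      tot <- tot - g1[i, j, k] / 2 * el(ms)
    }
  }
  tot
}

## second-order contact-transformation correction to <A|Htilde|B>
.contact_correction <- function(tensors, A, B, omega, exclude = list(),
                                den_tol = 1e-6) {
  M <- length(A)
  excl <- vapply(exclude, .state_key, "")
  # enumerate intermediate states reachable from A by one cubic operator
  deltas <- list()
  for (m in seq_len(M)) for (d in c(-3L, -1L, 1L, 3L)) {
    dd <- integer(M); dd[m] <- d; deltas[[length(deltas) + 1L]] <- dd
  }
  if (M >= 2L) for (m1 in seq_len(M)) for (m2 in seq_len(M)) {
    if (m1 == m2) next
    for (d1 in c(-2L, 2L)) for (d2 in c(-1L, 1L)) {
      dd <- integer(M); dd[m1] <- d1; dd[m2] <- d2
      deltas[[length(deltas) + 1L]] <- dd
    }
  }
  if (M >= 3L) {
    cmb <- utils::combn(M, 3L)
    for (cc in seq_len(ncol(cmb))) {
      for (s1 in c(-1L, 1L)) for (s2 in c(-1L, 1L)) for (s3 in c(-1L, 1L)) {
        dd <- integer(M); dd[cmb[, cc]] <- c(s1, s2, s3)
        deltas[[length(deltas) + 1L]] <- dd
      }
    }
  }
  EA <- sum(omega * A); EB <- sum(omega * B)
  corr <- 0
  seen <- character(0)
  for (dd in deltas) {
    S <- A + dd
    if (any(S < 0)) next
    sk <- .state_key(S)
    if (sk %in% seen || sk %in% excl) next
    seen <- c(seen, sk)
    if (sum(abs(S - B)) > 3L) next
    a1 <- .h1_element(tensors, A, S)
    if (a1 == 0) next
    a2 <- .h1_element(tensors, S, B)
    if (a2 == 0) next
    ES <- sum(omega * S)
    d1 <- EA - ES; d2 <- EB - ES
    if (abs(d1) < den_tol || abs(d2) < den_tol)
      stop("contact-transformation correction hits a resonant intermediate ",
           sk, "; enlarge the polyad")
    corr <- corr + 0.5 * a1 * a2 * (1 / d1 + 1 / d2)
  }
  corr
}

## ---- GVPT2 ---------------------------------------------------------------

#' Variational polyad energies (GVPT2)
#'
#' Builds, for every polyad, the small variational matrix whose diagonal
#' holds the deperturbed (DVPT2) transition energies and whose off-diagonal
#' elements are the Fermi interaction terms between states differing by an
#' accepted resonance pattern, then diagonalizes it.  Eigenvalues are
#' assigned to basis states by the largest squared eigenvector component
#' (ties broken deterministically towards the lower basis index and
#' flagged).
#'
#' @param polyads output of [build_polyads()].
#' @param chi a deperturbed `cv_chi` (DVPT2) used for the diagonal energies.
#' @param tensors [derived_tensors()] output carrying `rho` (and `f3`/`g1`
#'   for `aux`).
#' @param candidates accepted resonances ([martin_test()] table).
#' @param aux include the second-order contact-transformation correction in
#'   the off-diagonal elements.
#' @return list of polyads augmented with `H` (variational matrix),
#'   `energies` (eigenvalues), `assign` (eigenvalue index per basis state)
#'   and `flag_ties`.
#' @export
gvpt2_energies <- function(polyads, chi, tensors, candidates, aux = FALSE) {
  acc <- if (is.data.frame(candidates))
    candidates[candidates$accepted, , drop = FALSE] else candidates
  omega <- chi$omega
  lapply(polyads, function(p) {
    sts <- p$states
    n <- nrow(sts)
    H <- matrix(0, n, n)
    for (a in seq_len(n))
      H[a, a] <- state_energy(chi, sts[a, ])
    if (n > 1L && nrow(acc) > 0L) {
      all_states <- lapply(seq_len(n), function(a) sts[a, ])
      for (a in seq_len(n)) for (b in seq_len(n)) {
        if (a >= b) next
        W <- .pair_element(sts[a, ], sts[b, ], acc, tensors, omega,
                           aux = aux, exclude = all_states)
        H[a, b] <- W; H[b, a] <- W
      }
    }
    ev <- eigen(H, symmetric = TRUE)
    # assignment: greedy over all (basis state, eigenvector) pairs by
    # descending squared component; ambiguity within 1e-6 is flagged and
    # broken towards the lower basis-state index (ensured by the stable
    # order of equal components in `order`)
    assign <- rep(NA_integer_, n)
    ties <- FALSE
    taken <- logical(n)
    comp <- abs(ev$vectors)
    ord <- order(-comp)
    for (pos in ord) {
      col <- (pos - 1L) %/% n + 1L  # eigenvector index
      row <- (pos - 1L) %% n + 1L   # basis state index
      if (taken[col] || !is.na(assign[row])) next
      if (any(abs(comp[, col] - comp[row, col]) < 1e-6 &
              seq_len(n) < row & is.na(assign)))
        ties <- TRUE
      assign[row] <- col; taken[col] <- TRUE
    }
    p$H <- H
    p$energies <- ev$values
    p$assign <- assign
    p$flag_ties <- ties
    p
  })
}

## interaction element between two specific polyad states if they differ by
## an accepted resonance pattern, else 0
.pair_element <- function(va, vb, acc, tensors, omega, aux = FALSE,
                          exclude = list()) {
  for (r in seq_len(nrow(acc))) {
    cand <- acc[r, ]
    if (cand$type == "I") {
      i <- cand$i; k <- cand$k
      d <- va - vb
      for (swap in c(FALSE, TRUE)) {
        dd <- if (swap) -d else d
        lo <- if (swap) va else vb   # the |v + 1_k> member
        if (dd[i] == 2 && dd[k] == -1 && sum(abs(dd)) == 3) {
          base <- lo; base[k] <- base[k] - 1L
          return(interaction_element(tensors, "I", c(i, k), v = base,
                                     omega = omega, aux = aux,
                                     exclude = exclude))
        }
      }
    } else {
      i <- cand$i; j <- cand$j; k <- cand$k
      d <- va - vb
      for (swap in c(FALSE, TRUE)) {
        dd <- if (swap) -d else d
        lo <- if (swap) va else vb
        if (dd[i] == 1 && dd[j] == 1 && dd[k] == -1 && sum(abs(dd)) == 3) {
          base <- lo; base[k] <- base[k] - 1L
          return(interaction_element(tensors, "II", c(i, j, k), v = base,
                                     omega = omega, aux = aux,
                                     exclude = exclude))
        }
      }
    }
  }
  0
}
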