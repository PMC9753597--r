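# VPT2 in curvilinear (or Cartesian) coordinates: the anharmonicity matrix
# chi computed from the quartic force field and the kinetic-metric
# derivatives.
#
# Two independent algebraic routes are implemented:
#
#  * chi_components(): the "raw" second-order expressions, with potential,
#    kinetic and potential-kinetic cross contributions kept separate and
#    compound denominators such as omega_k (4 omega_i^2 - omega_k^2).
#
#  * chi_curvilinear()/chi_cartesian(): the recast form, a sum over simple
#    resonance denominators built from the derived tensors eta, sigma and
#    rho.  This is the form used for deperturbation (DVPT2), because every
#    term carries an explicit Fermi-resonance identity.
#
# Both routes were derived by Rayleigh-Schrodinger perturbation theory for
# the Hamiltonian
#   H = 1/2 sum w_i (p_i^2 + q_i^2) + (1/6) f_ijk q^3 + (1/24) f_ijkl q^4
#     + (1/2) g_ij,k p_i q_k p_j + (1/4) g_ij,kl p_i q_k q_l p_j
# and agree identically; the sum-over-states oracle validates them.

#' Construct a quartic force field from explicit constants
#'
#' Convenience constructor for model systems: cubic and quartic constants
#' are given directly in dimensionless-normal-coordinate wavenumber units
#' and symmetrized over index permutations.
#'
#' @param omega harmonic wavenumbers (cm^-1).
#' @param cubic,quartic lists of `list(idx = c(...), value = v)` entries
#'   (cm^-1), or full symmetric arrays.
#' @param frame `"curvilinear"` or `"cartesian"`.
#' @return A `cv_qff` object.
#' @export
qff <- function(omega, cubic = list(), quartic = list(),
                frame = "curvilinear") {
  M <- length(omega)
  f3 <- if (is.array(cubic)) cubic else {
    a <- array(0, c(M, M, M))
    for (e in cubic) for (p in .perms(e$idx)) a[matrix(p, 1)] <- e$value
    a
  }
  f4 <- if (is.array(quartic)) quartic else {
    a <- array(0, c(M, M, M, M))
    for (e in quartic) for (p in .perms(e$idx)) a[matrix(p, 1)] <- e$value
    a
  }
  structure(list(omega = omega, f3 = f3, f4 = f4, frame = frame),
            class = "cv_qff")
}

#' Construct kinetic-metric derivatives from explicit constants
#'
#' @param omega harmonic wavenumbers (defines the mode count).
#' @param g1 list of `list(idx = c(i,j,k), value = v)` entries for
#'   \eqn{g_{ij,k}} (symmetrized in i,j), or a full array.
#' @param g2 list of `list(idx = c(i,j,k,l), value = v)` entries for
#'   \eqn{g_{ij,kl}} (symmetrized in (i,j) and (k,l)), or a full array.
#' @return A `cv_kin` object.
#' @export
kinetic_derivatives <- function(omega, g1 = list(), g2 = list()) {
  M <- length(omega)
  a1 <- if (is.array(g1)) g1 else {
    a <- array(0, c(M, M, M))
    for (e in g1) {
      i <- e$idx[1]; j <- e$idx[2]; k <- e$idx[3]
      a[i, j, k] <- e$value; a[j, i, k] <- e$value
    }
    a
  }
  a2 <- if (is.array(g2)) g2 else {
    a <- array(0, c(M, M, M, M))
    for (e in g2) {
      i <- e$idx[1]; j <- e$idx[2]; k <- e$idx[3]; l <- e$idx[4]
      for (ij in list(c(i, j), c(j, i))) for (kl in list(c(k, l), c(l, k)))
        a[ij[1], ij[2], kl[1], kl[2]] <- e$value
    }
    a
  }
  structure(list(g1 = a1, g2 = a2, frame = "curvilinear"), class = "cv_kin")
}

#' Derived tensors eta, sigma, rho
#'
#' Recast combinations of the cubic/quartic force constants with the
#' kinetic-metric derivatives that make the curvilinear chi matrix formally
#' identical to its Cartesian counterpart:
#' \deqn{\rho_{ij;k} = f_{ijk} - g_{ij,k} + g_{ik,j} + g_{jk,i}}
#' (modes i,j gaining one quantum and k losing one; the combination entering
#' Fermi-resonance denominators and interaction elements),
#' \deqn{\sigma_{ijk} = f_{ijk} - g_{ij,k} - g_{ik,j} - g_{jk,i}}
#' (fully symmetric; anti-resonant denominators), and
#' \deqn{\eta_{ik} = f_{iikk} + g_{ii,kk} + g_{kk,ii}}
#' (with \eqn{\eta_{ii} = f_{iiii} + 2 g_{ii,ii}}).  With all kinetic
#' derivatives zero, `rho = sigma = f3` and `eta = f4`.
#'
#' @param ff a quartic force field (see [assemble_force_field()]), or any
#'   list with `omega` (cm^-1), `f3` (M^3 symmetric array, cm^-1) and `f4`
#'   (M^4 array with the semi-diagonal patterns filled).
#' @param kin kinetic derivatives (see [assemble_kinetic_derivatives()]):
#'   list with `g1` (M^3, symmetric in the first two indices) and `g2`
#'   (M^4, symmetric in each index pair); `NULL` for the Cartesian frame.
#' @return Object of class `cv_tensors` with `rho` (M^3, `rho[i,j,k]`
#'   symmetric in i,j), `sigma` (M^3 fully symmetric), `eta` (M x M) and
#'   `omega`.
#' @export
derived_tensors <- function(ff, kin = NULL) {
  M <- length(ff$omega)
  f3 <- ff$f3; f4 <- ff$f4
  if (is.null(kin)) {
    g1 <- array(0, c(M, M, M)); g2 <- array(0, c(M, M, M, M))
  } else {
    g1 <- kin$g1; g2 <- kin$g2
  }
  rho <- array(0, c(M, M, M)); sig <- array(0, c(M, M, M))
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M)) {
    rho[i, j, k] <- f3[i, j, k] - g1[i, j, k] + g1[i, k, j] + g1[j, k, i]
    sig[i, j, k] <- f3[i, j, k] - g1[i, j, k] - g1[i, k, j] - g1[j, k, i]
  }
  eta <- matrix(0, M, M)
  for (i in seq_len(M)) for (k in seq_len(M))
    eta[i, k] <- f4[i, i, k, k] + g2[i, i, k, k] + g2[k, k, i, i]
  structure(list(rho = rho, sigma = sig, eta = eta, omega = ff$omega,
                 f3 = f3, g1 = g1),
            class = "cv_tensors")
}

## ---- recast route: explicit term list with resonance identities ---------

.res_key_I <- function(i, k) sprintf("F1:%d;%d", i, k)
.res_key_II <- function(i, j, k) sprintf("F2:%d,%d;%d", min(i, j), max(i, j), k)

## one row per chi contribution; `key` is the Fermi-resonance identity of the
## denominator (NA for non-resonant terms)
.chi_term_rows <- function(i, j, value, den, key) {
  data.frame(i = i, j = j, value = value, den = den,
             key = key, stringsAsFactors = FALSE)
}

.chi_terms <- function(tensors, omega, den_tol = 1e-6) {
  M <- length(omega)
  rho <- tensors$rho; sig <- tensors$sigma; eta <- tensors$eta
  rows <- vector("list", 0L)
  # value = num / den; a vanishing numerator silences the term even at an
  # exactly zero denominator (no spurious 0/0)
  add <- function(i, j, num, den = NA_real_, key = NA_character_) {
    value <- if (num == 0) 0 else if (is.na(den)) num else num / den
    rows[[length(rows) + 1L]] <<- .chi_term_rows(i, j, value, den, key)
  }

  for (i in seq_len(M)) {
    add(i, i, eta[i, i] / 16)
    for (k in seq_len(M)) {
      add(i, i, -rho[i, k, i]^2 / (8 * omega[k]))
      d <- 2 * omega[i] - omega[k]
      add(i, i, rho[i, i, k]^2 / 32, den = d,
          key = if (k != i) .res_key_I(i, k) else NA_character_)
      add(i, i, -sig[i, i, k]^2 / (32 * (2 * omega[i] + omega[k])))
    }
  }
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (i >= j) next
    add(i, j, eta[i, j] / 4)
    for (k in seq_len(M))
      add(i, j, -rho[i, k, i] * rho[j, k, j] / (4 * omega[k]))
    d1 <- 2 * omega[i] - omega[j]
    add(i, j, -rho[i, i, j]^2 / 8, den = d1, key = .res_key_I(i, j))
    add(i, j, -sig[i, i, j]^2 / (8 * (2 * omega[i] + omega[j])))
    d2 <- 2 * omega[j] - omega[i]
    add(i, j, -rho[j, j, i]^2 / 8, den = d2, key = .res_key_I(j, i))
    add(i, j, -sig[i, j, j]^2 / (8 * (2 * omega[j] + omega[i])))
    for (k in seq_len(M)) {
      if (k == i || k == j) next
      dij <- omega[i] + omega[j] - omega[k]
      dik <- omega[i] + omega[k] - omega[j]
      djk <- omega[j] + omega[k] - omega[i]
      add(i, j, rho[i, j, k]^2 / 8, den = dij, key = .res_key_II(i, j, k))
      add(i, j, -rho[i, k, j]^2 / 8, den = dik, key = .res_key_II(i, k, j))
      add(i, j, -rho[j, k, i]^2 / 8, den = djk, key = .res_key_II(j, k, i))
      add(i, j, -sig[i, j, k]^2 / (8 * (omega[i] + omega[j] + omega[k])))
    }
  }
  do.call(rbind, rows)
}

.assemble_chi <- function(terms, M, deperturb, den_tol = 1e-6) {
  keys <- vapply(deperturb, identity, "")
  drop <- !is.na(terms$key) & terms$key %in% keys
  live <- terms[!drop, , drop = FALSE]
  bad <- !is.na(live$den) & abs(live$den) < den_tol &
    (!is.finite(live$value) | abs(live$value) > 0)
  if (any(bad)) {
    stop("near-singular VPT2 denominator for resonance(s) ",
         paste(unique(live$key[bad]), collapse = ", "),
         ": handle explicitly via the deperturbation list")
  }
  chi <- matrix(0, M, M)
  for (r in seq_len(nrow(live))) {
    i <- live$i[r]; j <- live$j[r]
    chi[i, j] <- chi[i, j] + live$value[r]
    if (i != j) chi[j, i] <- chi[j, i] + live$value[r]
  }
  list(chi = chi, removed = terms[drop, , drop = FALSE])
}

#' Curvilinear-frame chi matrix (recast eta/sigma/rho form)
#'
#' Assembles the anharmonicity matrix as a sum over simple resonance
#' denominators built from the [derived_tensors()].  Terms whose denominator
#' corresponds to an entry of `deperturb` are omitted and logged in the
#' `removed` registry (DVPT2).  An exact or near-zero denominator that is
#' not deperturbed raises an error naming the resonance.
#'
#' @param tensors [derived_tensors()] output (or a force field, in which
#'   case tensors are derived on the fly with `kin`).
#' @param omega harmonic wavenumbers; defaults to `tensors$omega`.
#' @param deperturb character vector / list of resonance keys as produced by
#'   [martin_test()] (`"F1:i;k"` for 2 w_i ~ w_k, `"F2:i,j;k"` for
#'   w_i + w_j ~ w_k).
#' @param kin kinetic derivatives, used only when `tensors` is a force field.
#' @param den_tol denominator magnitude (cm^-1) below which an
#'   un-deperturbed resonant term is an error.
#' @return Object of class `cv_chi`: `chi` (M x M, cm^-1), `removed`
#'   (registry of discarded terms), `omega`, `frame`.
#' @export
chi_curvilinear <- function(tensors, omega = NULL, deperturb = list(),
                            kin = NULL, den_tol = 1e-6) {
  if (!inherits(tensors, "cv_tensors")) tensors <- derived_tensors(tensors, kin)
  if (is.null(omega)) omega <- tensors$omega
  terms <- .chi_terms(tensors, omega, den_tol)
  out <- .assemble_chi(terms, length(omega), deperturb, den_tol)
  structure(list(chi = out$chi, removed = out$removed, omega = omega,
                 frame = "curvilinear"), class = "cv_chi")
}

#' Cartesian-frame chi matrix
#'
#' Standard rectilinear VPT2: the same recast machinery with all kinetic
#' derivatives zero, plus the Coriolis contribution
#' \eqn{\chi^{Cor}_{ij} = \sum_\alpha B^e_\alpha (\zeta^\alpha_{ij})^2
#' (\omega_i/\omega_j + \omega_j/\omega_i)}.
#'
#' @param ff Cartesian-frame quartic force field.
#' @param coriolis a [coriolis_constants()] object (or NULL).
#' @param omega harmonic wavenumbers; defaults to `ff$omega`.
#' @param deperturb resonance keys to deperturb, as in [chi_curvilinear()].
#' @param include_coriolis logical toggle for the Coriolis contribution.
#' @param den_tol see [chi_curvilinear()].
#' @return A `cv_chi` object with `frame = "cartesian"`.
#' @export
chi_cartesian <- function(ff, coriolis = NULL, omega = NULL,
                          deperturb = list(), include_coriolis = TRUE,
                          den_tol = 1e-6) {
  tensors <- derived_tensors(ff, kin = NULL)
  if (is.null(omega)) omega <- ff$omega
  terms <- .chi_terms(tensors, omega, den_tol)
  out <- .assemble_chi(terms, length(omega), deperturb, den_tol)
  chi <- out$chi
  if (include_coriolis && !is.null(coriolis)) {
    chi <- chi + .coriolis_chi(coriolis, omega)
  }
  structure(list(chi = chi, removed = out$removed, omega = omega,
                 frame = "cartesian"), class = "cv_chi")
}

.coriolis_chi <- function(coriolis, omega) {
  M <- length(omega)
  add <- matrix(0, M, M)
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (i == j) next
    z2 <- sum(coriolis$Be * coriolis$zeta[i, j, ]^2)
    add[i, j] <- z2 * (omega[i] / omega[j] + omega[j] / omega[i])
  }
  add
}

#' @export
print.cv_chi <- function(x, ...) {
  cat(sprintf("<cv_chi (%s): %d modes, %d deperturbed term(s)>\n",
              x$frame, length(x$omega), nrow(x$removed)))
  invisible(x)
}

## ---- component route: raw second-order expressions -----------------------

#' Chi matrix split into potential, kinetic and cross components
#'
#' Evaluates the raw (pre-partial-fraction) second-order expressions, with
#' the three physically distinct contributions kept separate: `pot` (cubic
#' and quartic force constants; in the Cartesian frame this also houses the
#' Coriolis contribution), `kin` (first/second kinetic-metric derivatives)
#' and `cross` (potential-kinetic interference).  The component sum equals
#' the recast eta/sigma/rho form of [chi_curvilinear()] identically; this
#' independent route exists to validate that identity.
#'
#' @inheritParams derived_tensors
#' @param coriolis optional [coriolis_constants()] data added to `pot`.
#' @return List of three M x M matrices `pot`, `kin`, `cross` and their
#'   `total`.
#' @export
chi_components <- function(ff, kin = NULL, coriolis = NULL) {
  w <- ff$omega; M <- length(w)
  f3 <- ff$f3; f4 <- ff$f4
  if (is.null(kin)) {
    g1 <- array(0, c(M, M, M)); g2 <- array(0, c(M, M, M, M))
  } else {
    g1 <- kin$g1; g2 <- kin$g2
  }
  pot <- matrix(0, M, M); kinm <- matrix(0, M, M); crs <- matrix(0, M, M)

  for (i in seq_len(M)) {
    pot[i, i] <- f4[i, i, i, i] / 16
    kinm[i, i] <- g2[i, i, i, i] / 8
    for (k in seq_len(M)) {
      A <- (8 * w[i]^2 - 3 * w[k]^2) / (16 * w[k] * (4 * w[i]^2 - w[k]^2))
      pot[i, i] <- pot[i, i] - f3[i, i, k]^2 * A
      kinm[i, i] <- kinm[i, i] - g1[i, i, k]^2 * A -
        g1[i, i, k] * g1[i, k, i] * w[i] / (2 * (4 * w[i]^2 - w[k]^2)) +
        g1[i, k, i]^2 * w[k] / (4 * (4 * w[i]^2 - w[k]^2))
      crs[i, i] <- crs[i, i] -
        f3[i, i, k] * g1[i, i, k] * (8 * w[i]^2 - w[k]^2) /
          (8 * w[k] * (4 * w[i]^2 - w[k]^2)) +
        f3[i, i, k] * g1[i, k, i] * w[i] / (2 * (4 * w[i]^2 - w[k]^2))
    }
  }

  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (i >= j) next
    pot[i, j] <- f4[i, i, j, j] / 4
    kinm[i, j] <- (g2[i, i, j, j] + g2[j, j, i, i]) / 4
    for (k in seq_len(M)) {
      pot[i, j] <- pot[i, j] - f3[i, i, k] * f3[j, j, k] / (4 * w[k])
      kinm[i, j] <- kinm[i, j] - g1[i, i, k] * g1[j, j, k] / (4 * w[k])
      crs[i, j] <- crs[i, j] -
        (f3[i, i, k] * g1[j, j, k] + f3[j, j, k] * g1[i, i, k]) / (4 * w[k])
    }
    dij <- 4 * w[i]^2 - w[j]^2
    dji <- 4 * w[j]^2 - w[i]^2
    pot[i, j] <- pot[i, j] - f3[i, i, j]^2 * w[i] / (2 * dij) -
      f3[i, j, j]^2 * w[j] / (2 * dji)
    kinm[i, j] <- kinm[i, j] -
      g1[i, i, j]^2 * w[i] / (2 * dij) +
      g1[i, i, j] * g1[i, j, i] * w[j] / dij -
      g1[i, j, i]^2 * 2 * w[i] / dij -
      g1[j, j, i]^2 * w[j] / (2 * dji) +
      g1[j, j, i] * g1[i, j, j] * w[i] / dji -
      g1[i, j, j]^2 * 2 * w[j] / dji
    crs[i, j] <- crs[i, j] +
      f3[i, i, j] * (g1[i, i, j] * w[i] - g1[i, j, i] * w[j]) / dij +
      f3[i, j, j] * (g1[j, j, i] * w[j] - g1[i, j, j] * w[i]) / dji
    for (k in seq_len(M)) {
      if (k == i || k == j) next
      Dl <- w[i]^4 + w[j]^4 + w[k]^4 -
        2 * (w[i]^2 * w[j]^2 + w[i]^2 * w[k]^2 + w[j]^2 * w[k]^2)
      ck <- w[k] * (w[i]^2 + w[j]^2 - w[k]^2) / (2 * Dl)
      pot[i, j] <- pot[i, j] + f3[i, j, k]^2 * ck
      kinm[i, j] <- kinm[i, j] +
        (g1[i, j, k]^2 + g1[i, k, j]^2 + g1[j, k, i]^2) * ck +
        (g1[i, j, k] * g1[i, k, j] * w[j] * (w[i]^2 - w[j]^2 + w[k]^2) +
         g1[i, j, k] * g1[j, k, i] * w[i] * (w[j]^2 - w[i]^2 + w[k]^2) -
         g1[i, k, j] * g1[j, k, i] * 2 * w[i] * w[j] * w[k]) / Dl
      crs[i, j] <- crs[i, j] + f3[i, j, k] *
        (g1[i, j, k] * 2 * w[i] * w[j] * w[k] +
         g1[i, k, j] * w[i] * (w[i]^2 - w[j]^2 - w[k]^2) +
         g1[j, k, i] * w[j] * (w[j]^2 - w[i]^2 - w[k]^2)) / Dl
    }
  }

  if (!is.null(coriolis)) pot <- pot + .coriolis_chi(coriolis, w)
  pot <- pot + t(pot) - diag(diag(pot))
  kinm <- kinm + t(kinm) - diag(diag(kinm))
  crs <- crs + t(crs) - diag(diag(crs))
  list(pot = pot, kin = kinm, cross = crs, total = pot + kinm + crs)
}

## ---- state energies and analysis utilities -------------------------------

#' Vibrational state energy relative to the zero-point level
#'
#' \eqn{\epsilon(v) - \epsilon(0) = \sum_i \omega_i v_i + \sum_{i \le j}
#' \chi_{ij} [(v_i + 1/2)(v_j + 1/2) - 1/4]}.
#'
#' @param chi a `cv_chi` object (or plain M x M matrix with `omega` given).
#' @param v quantum-number vector.
#' @param omega harmonic wavenumbers when `chi` is a plain matrix.
#' @return transition energy in cm^-1.
#' @export
state_energy <- function(chi, v, omega = NULL) {
  if (inherits(chi, "cv_chi")) { omega <- chi$omega; chi <- chi$chi }
  stopifnot(length(v) == length(omega))
  t <- v + 0.5
  e <- sum(omega * v)
  for (i in seq_along(v)) for (j in i:length(v))
    e <- e + chi[i, j] * (t[i] * t[j] - 0.25)
  e
}

#' Restrict a force field and kinetic derivatives to a coupling order
#'
#' Order 1 keeps only single-mode constants, order 2 adds all two-mode
#' couplings, order 3 is the identity.  Constants involving more distinct
#' modes than the order are zeroed in both the potential and kinetic parts.
#'
#' @param ff quartic force field.
#' @param kin kinetic derivatives (may be NULL).
#' @param order 1, 2 or 3.
#' @return list with restricted `ff` and `kin`.
#' @export
restrict_coupling_order <- function(ff, kin = NULL, order = 3L) {
  stopifnot(order %in% 1:3)
  if (order == 3L) return(list(ff = ff, kin = kin))
  nuniq <- function(idx) length(unique(idx))
  zap3 <- function(a) {
    M <- dim(a)[1]
    for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M))
      if (nuniq(c(i, j, k)) > order) a[i, j, k] <- 0
    a
  }
  zap4 <- function(a) {
    M <- dim(a)[1]
    for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M))
      for (l in seq_len(M))
        if (nuniq(c(i, j, k, l)) > order) a[i, j, k, l] <- 0
    a
  }
  ff$f3 <- zap3(ff$f3); ff$f4 <- zap4(ff$f4)
  if (!is.null(kin)) { kin$g1 <- zap3(kin$g1); kin$g2 <- zap4(kin$g2) }
  list(ff = ff, kin = kin)
}

#' Single-mode (decoupled) anharmonic fundamental
#'
#' Fundamental of mode `k` with every inter-mode coupling discarded: only
#' the diagonal cubic/quartic force constants and (in the curvilinear frame)
#' the diagonal kinetic derivatives of that mode are retained, i.e.
#' \eqn{\omega_k + 2 \chi^{(1)}_{kk}}.
#'
#' @param ff quartic force field.
#' @param kin kinetic derivatives (NULL in the Cartesian frame).
#' @param k mode index.
#' @return fundamental wavenumber (cm^-1).
#' @export
single_mode_anharmonic <- function(ff, kin = NULL, k) {
  sub_ff <- list(omega = ff$omega[k],
                 f3 = array(ff$f3[k, k, k], c(1, 1, 1)),
                 f4 = array(ff$f4[k, k, k, k], c(1, 1, 1, 1)))
  sub_kin <- if (is.null(kin)) NULL else
    list(g1 = array(kin$g1[k, k, k], c(1, 1, 1)),
         g2 = array(kin$g2[k, k, k, k], c(1, 1, 1, 1)))
  chi <- chi_curvilinear(derived_tensors(sub_ff, sub_kin))
  ff$omega[k] + 2 * chi$chi[1, 1]
}

#' Count inter-mode couplings above a threshold
#'
#' Counts the symmetry-unique three-mode cubic constants `|f_ijk|`
#' (i < j < k), quartic constants `|f_ijkk|` (i < j, k distinct from both),
#' and three-mode kinetic derivatives `|g_ij,k|` and `|g_ij,kl|` above
#' `threshold` (cm^-1).
#'
#' @param ff quartic force field.
#' @param kin kinetic derivatives (may be NULL).
#' @param threshold absolute magnitude cutoff, cm^-1.
#' @return named integer vector with counts `cubic`, `quartic`, `g1`, `g2`.
#' @export
count_couplings <- function(ff, kin = NULL, threshold = 0) {
  stopifnot(threshold >= 0)
  M <- length(ff$omega)
  nc <- 0L; nq <- 0L
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M)) {
    if (i < j && j < k && abs(ff$f3[i, j, k]) > threshold) nc <- nc + 1L
    if (i < j && k != i && k != j && abs(ff$f4[i, j, k, k]) > threshold)
      nq <- nq + 1L
  }
  n1 <- 0L; n2 <- 0L
  if (!is.null(kin)) {
    seen <- character(0)
    for (i in seq_len(M)) for (j in i:M) for (k in seq_len(M)) {
      if (length(unique(c(i, j, k))) == 3L && abs(kin$g1[i, j, k]) > threshold)
        n1 <- n1 + 1L
    }
    for (i in seq_len(M)) for (j in i:M) for (k in seq_len(M)) for (l in k:M) {
      if (length(unique(c(i, j, k, l))) < 3L) next
      if (abs(kin$g2[i, j, k, l]) <= threshold) next
      key <- paste(c(min(i, j), max(i, j), min(k, l), max(k, l)), collapse = ",")
      if (!key %in% seen) { seen <- c(seen, key); n2 <- n2 + 1L }
    }
  }
  c(cubic = nc, quartic = nq, g1 = n1, g2 = n2)
}
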