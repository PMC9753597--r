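# Quartic force field and kinetic-metric derivatives by finite differences
# of analytic Hessians (and of the analytic first G derivatives) at
# geometries displaced along the normal modes.
#
# Unit conventions: displacements delta_Q are given in amu^(1/2) Bohr (the
# customary mass-weighted normal-coordinate unit, default 0.02); internally
# everything is converted to atomic units (electron masses).  Dimensionless
# normal coordinates are q_k = sqrt(omega_k[au]) Q_k[au], so a step delta_Q
# corresponds to delta_q_k = delta_Q[au] sqrt(omega_k[au]) in mode k.  Force
# constants are returned in cm^-1 as derivatives of V (or of the metric g)
# with respect to the dimensionless q.

.dq_au <- function(delta_q) delta_q * sqrt(.cv$amu_to_me)

## plain Moore-Penrose machinery for the (redundancy-reduced) B matrix
.b_pinv <- function(B, tol = 1e-10) {
  BBt <- B %*% t(B)
  e <- eigen((BBt + t(BBt)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  if (!all(keep))
    stop("rank-deficient B matrix in pseudo-inverse: revise the coordinate set")
  if (max(e$values) / min(e$values[keep]) > 1e12)
    stop("ill-conditioned B matrix: revise the internal coordinate set")
  t(B) %*% e$vectors[, keep] %*% (t(e$vectors[, keep]) / e$values[keep])
}

#' Projection matrix onto the internal-coordinate space
#'
#' `P = B^+ B`, the symmetric projector whose range is spanned by the
#' internal-coordinate gradients; applying it to Cartesian gradients and
#' Hessians factors out the rigid translations and rotations.
#'
#' @param B Wilson B matrix (rows may be redundancy-reduced combinations).
#' @return 3Na x 3Na symmetric projector.
#' @export
b_projector <- function(B) .b_pinv(B) %*% B

#' Transform a Cartesian gradient to internal coordinates
#'
#' `g_s = (B^+)^T P g_x`, the Moore-Penrose back-transformation of the
#' (projected) Cartesian gradient.
#'
#' @param gx Cartesian gradient (hartree/Bohr).
#' @param B Wilson B matrix (or redundancy-reduced `U^T B`).
#' @return internal gradient (length = rows of B).
#' @export
gradient_to_internal <- function(gx, B) {
  Bp_inv <- .b_pinv(B)
  P <- Bp_inv %*% B
  drop(t(Bp_inv) %*% (P %*% gx))
}

#' Transform a Cartesian Hessian to internal coordinates
#'
#' \deqn{F = (B^+)^T P (H_x - \sum_i g_{s,i} B'_i) P B^+}
#' where the internal gradient term removes the curvature the coordinates
#' themselves carry at non-stationary geometries, and the projector
#' `P = B^+ B` factors out translations and rotations.
#'
#' @param Hx Cartesian Hessian (hartree/Bohr^2).
#' @param gx Cartesian gradient (hartree/Bohr).
#' @param B Wilson B matrix (possibly redundancy-reduced).
#' @param Bp matching B' tensor (first dimension = rows of B).
#' @return internal Hessian F (symmetric).
#' @export
hessian_to_internal <- function(Hx, gx, B, Bp) {
  Bpi <- .b_pinv(B)
  P <- Bpi %*% B
  gs <- drop(t(Bpi) %*% (P %*% gx))
  K <- Hx
  for (i in seq_along(gs))
    if (gs[i] != 0) K <- K - gs[i] * Bp[i, , ]
  K <- P %*% K %*% P
  F <- t(Bpi) %*% K %*% Bpi
  (F + t(F)) / 2
}

## redundancy-reduced B and B' at a geometry, for a fixed U
.bt_at <- function(geom, set, U) {
  B <- b_matrix(geom, set)
  Bt <- t(U) %*% B
  Bt
}

.bpt_at <- function(geom, set, U) {
  Bp <- b_prime(geom, set)
  n3 <- dim(Bp)[2]
  Bpt <- array(0, c(ncol(U), n3, n3))
  for (c1 in seq_len(n3)) Bpt[, , c1] <- t(U) %*% Bp[, , c1]
  Bpt
}

#' Displace a geometry along one normal mode
#'
#' Cartesian-frame modes displace the Cartesian coordinates directly
#' (`x + M^{-1/2} l_k dQ`); curvilinear modes displace the internal
#' coordinates (`t + L_k dQ`) and back-transform iteratively to Cartesians,
#' with step-halving damping, until the internal-coordinate residual falls
#' below `tol`.
#'
#' @param geom reference [geometry()].
#' @param sol `cv_harmonic` solution defining the modes.
#' @param mode mode index.
#' @param step displacement in amu^(1/2) Bohr (signed); 0 returns the
#'   geometry unchanged.
#' @param set,sref internal coordinate set and its reference values
#'   (curvilinear frame only).
#' @param tol back-transformation convergence threshold on the internal
#'   values.
#' @param maxit iteration cap; non-convergence is an error.
#' @return displaced [geometry()].
#' @export
displace <- function(geom, sol, mode, step, set = NULL, sref = NULL,
                     tol = 1e-10, maxit = 100L) {
  if (step == 0) return(geom)
  dq <- .dq_au(step)
  if (sol$frame == "cartesian") {
    m <- .mass_vector_au(geom)
    x <- .xvec(geom) + sol$lmw[, mode] / sqrt(m) * dq
    return(.with_coords(geom, x))
  }
  stopifnot(!is.null(set))
  if (is.null(sref)) sref <- coord_values(geom, set)
  U <- sol$U
  t0 <- drop(t(U) %*% (coord_values(geom, set, ref = sref) - sref))
  tgt <- t0 + sol$Lt[, mode] * dq
  cur <- geom
  scale <- 1
  last <- Inf
  for (it in seq_len(maxit)) {
    tv <- drop(t(U) %*% (coord_values(cur, set, ref = sref) - sref))
    dt <- tgt - tv
    if (max(abs(dt)) < tol) return(cur)
    if (max(abs(dt)) > last * 1.000001) {
      scale <- scale / 2            # damping on divergence
      if (scale < 1e-4)
        stop("curvilinear back-transformation diverged for mode ", mode)
    } else {
      last <- max(abs(dt))
    }
    Bt <- .bt_at(cur, set, U)
    dx <- drop(.b_pinv(Bt) %*% dt) * scale
    cur <- .with_coords(cur, .xvec(cur) + dx)
  }
  stop("curvilinear back-transformation did not converge for mode ", mode,
       " after ", maxit, " iterations")
}

## ---- surface runs ---------------------------------------------------------

.surface_labels <- function(M) {
  c("ref", paste0("+", seq_len(M)), paste0("-", seq_len(M)))
}

#' Run (or resume) the displaced-geometry Hessian surface
#'
#' Executes the 2M+1 engine jobs (reference plus one pair per active mode)
#' through the engine adapter and optionally persists the results in a
#' versioned JSON archive.  Completed archive entries are reused, so a rerun
#' over a complete archive performs no engine calls; corrupted entries are
#' recomputed individually.
#'
#' @param geom reference geometry.
#' @param pes engine adapter: any object with an `eval(geom)` function
#'   returning `energy`, `gradient`, `hessian` (a [morse_diatomic()] or
#'   [synthetic_polyatomic()] `cv_pes`, or a user adapter).
#' @param sol harmonic solution defining the modes.
#' @param delta_q displacement step (amu^(1/2) Bohr), default 0.02.
#' @param set,sref internal set / reference values for curvilinear modes.
#' @param archive optional path of the JSON archive.
#' @param modes mode indices to displace (default: all).
#' @return Object of class `cv_surface`: per-label engine results and
#'   geometries, plus bookkeeping (`delta_q`, `frame`, `engine_calls`).
#' @export
run_surface <- function(geom, pes, sol, delta_q = 0.02, set = NULL,
                        sref = NULL, archive = NULL, modes = NULL) {
  stopifnot(delta_q > 0)
  M <- length(sol$omega)
  if (is.null(modes)) modes <- seq_len(M)
  labels <- c("ref", paste0("+", modes), paste0("-", modes))
  stored <- if (!is.null(archive) && file.exists(archive))
    read_archive(archive) else NULL
  results <- list(); geoms <- list()
  calls <- 0L
  for (lab in labels) {
    g <- if (lab == "ref") geom else {
      s <- if (startsWith(lab, "+")) 1 else -1
      k <- as.integer(substring(lab, 2L))
      displace(geom, sol, k, s * delta_q, set = set, sref = sref)
    }
    geoms[[lab]] <- g
    entry <- stored$results[[lab]]
    if (!is.null(entry) && .valid_entry(entry, .n_atoms(geom))) {
      results[[lab]] <- entry
    } else if (is.null(pes)) {
      stop("no engine adapter given and archive entry '", lab,
           "' is missing or invalid")
    } else {
      r <- tryCatch(pes$eval(g), error = function(e)
        stop("engine failure at geometry '", lab, "': ", conditionMessage(e)))
      r$label <- lab
      results[[lab]] <- r
      calls <- calls + 1L
    }
  }
  surf <- structure(list(results = results, geoms = geoms,
                         delta_q = delta_q, frame = sol$frame,
                         labels = labels, engine_calls = calls),
                    class = "cv_surface")
  if (!is.null(archive)) write_archive(surf, archive, geom, sol = sol)
  surf
}

.valid_entry <- function(e, na) {
  is.list(e) && length(e$gradient) == 3L * na &&
    is.matrix(e$hessian) && all(dim(e$hessian) == 3L * na) &&
    !anyNA(e$hessian) && max(abs(e$hessian - t(e$hessian))) < 1e-10 &&
    is.numeric(e$energy) && length(e$energy) == 1L && !is.na(e$energy)
}

#' @export
print.cv_surface <- function(x, ...) {
  cat(sprintf("<cv_surface (%s): %d geometries, delta_Q = %g, %d engine call(s)>\n",
              x$frame, length(x$labels), x$delta_q, x$engine_calls))
  invisible(x)
}

## dimensionless normal-coordinate Hessian f_ij(q) [cm^-1] at one surface
## geometry
.normal_hessian <- function(res, geomx, sol, geom_ref, set, sref) {
  w_au <- sol$omega_au
  if (sol$frame == "cartesian") {
    m <- .mass_vector_au(geomx)
    Hmw <- res$hessian / sqrt(outer(m, m))
    Hqq <- t(sol$lmw) %*% Hmw %*% sol$lmw
  } else {
    Bt <- .bt_at(geomx, set, sol$U)
    Bpt <- .bpt_at(geomx, set, sol$U)
    Ft <- hessian_to_internal(res$hessian, res$gradient, Bt, Bpt)
    Hqq <- t(sol$Lt) %*% Ft %*% sol$Lt
  }
  Hqq / sqrt(outer(abs(w_au), abs(w_au))) * .cv$hartree_to_cm
}

#' Assemble the quartic force field from displaced Hessians
#'
#' Cubic constants from antisymmetric differences of dimensionless
#' normal-coordinate Hessian elements over the +/- displacements,
#' \eqn{f_{ijk} = [H_{ij}(+\delta_k) - H_{ij}(-\delta_k)] / 2\delta q_k},
#' averaged over the displacement roles of the three indices; semi-diagonal
#' quartics \eqn{f_{iikk}}-type from symmetric second differences.  All
#' results fully index-symmetric by construction, in cm^-1.
#'
#' @param surface a [run_surface()] result covering all modes.
#' @param sol the harmonic solution used to generate it.
#' @param geom reference geometry.
#' @param set,sref internal coordinate set / reference values (curvilinear).
#' @return Object of class `cv_qff`: `omega` (cm^-1), `f3` (M^3), `f4`
#'   (M^4, semi-diagonal patterns), `frame`.
#' @export
assemble_force_field <- function(surface, sol, geom, set = NULL, sref = NULL) {
  M <- length(sol$omega)
  need <- .surface_labels(M)
  miss <- setdiff(need, names(surface$results))
  if (length(miss))
    stop("missing displaced geometries: ", paste(miss, collapse = ", "))
  dq <- .dq_au(surface$delta_q) * sqrt(abs(sol$omega_au))  # per-mode, dimensionless
  H0 <- .normal_hessian(surface$results[["ref"]], surface$geoms[["ref"]],
                        sol, geom, set, sref)
  Hp <- lapply(seq_len(M), function(k)
    .normal_hessian(surface$results[[paste0("+", k)]],
                    surface$geoms[[paste0("+", k)]], sol, geom, set, sref))
  Hm <- lapply(seq_len(M), function(k)
    .normal_hessian(surface$results[[paste0("-", k)]],
                    surface$geoms[[paste0("-", k)]], sol, geom, set, sref))

  D <- lapply(seq_len(M), function(k) (Hp[[k]] - Hm[[k]]) / (2 * dq[k]))
  S <- lapply(seq_len(M), function(k) (Hp[[k]] + Hm[[k]] - 2 * H0) / dq[k]^2)

  f3 <- array(0, c(M, M, M))
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M)) {
    if (i > j || j > k) next
    est <- c(D[[k]][i, j], D[[j]][i, k], D[[i]][j, k])
    v <- mean(est)
    for (p in .perms(c(i, j, k))) f3[matrix(p, 1)] <- v
  }
  f4 <- array(0, c(M, M, M, M))
  for (i in seq_len(M)) f4[i, i, i, i] <- S[[i]][i, i]
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (i >= j) next
    v <- mean(c(S[[j]][i, i], S[[i]][j, j]))
    for (p in .perms(c(i, i, j, j))) f4[matrix(p, 1)] <- v
  }
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M)) {
    if (i >= j || k == i || k == j) next
    v <- S[[k]][i, j]
    for (p in .perms(c(i, j, k, k))) f4[matrix(p, 1)] <- v
  }
  structure(list(omega = sol$omega, f3 = f3, f4 = f4, frame = sol$frame),
            class = "cv_qff")
}

#' @export
print.cv_qff <- function(x, ...) {
  cat(sprintf("<cv_qff (%s): %d modes>\n", x$frame, length(x$omega)))
  invisible(x)
}

## analytic g1 (cm^-1, dimensionless coordinates) at one geometry, using the
## fixed reference transformation (U, Lt)
.g1_at <- function(geomx, sol, set, sref) {
  w_au <- abs(sol$omega_au)
  M <- length(w_au)
  m_au <- geomx$masses * .cv$amu_to_me
  mvec <- .mass_vector_au(geomx)
  B <- b_matrix(geomx, set)
  Bp <- b_prime(geomx, set)
  Bt <- t(sol$U) %*% B
  Gt <- g_matrix(Bt, m_au)
  Gpt <- g_prime(Bt, .contract_u(Bp, sol$U), m_au)
  # dx/dQ_k = M^-1 Bt^T Gt^-1 Lt[,k]
  dxdQ <- (t(Bt) / mvec) %*% solve(Gt, sol$Lt)
  Li <- sol$Lt_inv
  g1 <- array(0, c(M, M, M))
  for (k in seq_len(M)) {
    dG <- matrix(0, nrow(Gt), ncol(Gt))
    for (cc in seq_len(dim(Gpt)[3]))
      dG <- dG + Gpt[, , cc] * dxdQ[cc, k]
    core <- Li %*% dG %*% t(Li)
    g1[, , k] <- core * outer(sqrt(w_au), sqrt(w_au)) / sqrt(w_au[k]) *
      .cv$hartree_to_cm
  }
  g1
}

.contract_u <- function(Bp, U) {
  n3 <- dim(Bp)[2]
  out <- array(0, c(ncol(U), n3, n3))
  for (cc in seq_len(n3)) out[, , cc] <- t(U) %*% Bp[, , cc]
  out
}

#' Assemble kinetic-metric derivatives
#'
#' First derivatives \eqn{g_{ij,k}} of the wavenumber-scaled metric with
#' respect to the dimensionless normal coordinates are computed analytically
#' from the G' tensor (chain rule through dx/dQ); second derivatives
#' \eqn{g_{ij,kl}} by central finite differences of the analytic first
#' derivatives over the same displaced geometries used for the force field,
#' symmetrized over (k, l).  For a Cartesian-frame solution all derivatives
#' vanish identically.
#'
#' @param surface a [run_surface()] result (geometries are reused; no engine
#'   data needed).
#' @param sol harmonic solution.
#' @param geom reference geometry.
#' @param set,sref internal coordinate set and reference values.
#' @return Object of class `cv_kin`: `g1` (M^3, cm^-1), `g2` (M^4, cm^-1),
#'   `frame`.
#' @export
assemble_kinetic_derivatives <- function(surface, sol, geom, set = NULL,
                                         sref = NULL) {
  M <- length(sol$omega)
  if (sol$frame == "cartesian") {
    return(structure(list(g1 = array(0, c(M, M, M)),
                          g2 = array(0, c(M, M, M, M)),
                          frame = "cartesian"), class = "cv_kin"))
  }
  need <- .surface_labels(M)
  miss <- setdiff(need, names(surface$geoms))
  if (length(miss))
    stop("missing displaced geometries: ", paste(miss, collapse = ", "))
  dq <- .dq_au(surface$delta_q) * sqrt(abs(sol$omega_au))
  g1 <- .g1_at(surface$geoms[["ref"]], sol, set, sref)
  g1p <- lapply(seq_len(M), function(l)
    .g1_at(surface$geoms[[paste0("+", l)]], sol, set, sref))
  g1m <- lapply(seq_len(M), function(l)
    .g1_at(surface$geoms[[paste0("-", l)]], sol, set, sref))
  g2 <- array(0, c(M, M, M, M))
  for (l in seq_len(M)) {
    d <- (g1p[[l]] - g1m[[l]]) / (2 * dq[l])   # d g1[, , k] / d q_l
    g2[, , , l] <- d
  }
  # symmetrize the (k, l) pair (two independent finite-difference estimates)
  for (k in seq_len(M)) for (l in seq_len(M)) {
    if (k >= l) next
    avg <- (g2[, , k, l] + g2[, , l, k]) / 2
    g2[, , k, l] <- avg; g2[, , l, k] <- avg
  }
  structure(list(g1 = g1, g2 = g2, frame = "curvilinear"), class = "cv_kin")
}
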