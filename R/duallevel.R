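# Dual-level (hybrid) schemes: a high-level harmonic description combined
# with low-level anharmonic corrections, either additively (Add) or by
# substituting the high-level frequencies into every perturbative
# denominator and harmonic term (Sub).

#' Match normal modes across two levels of theory
#'
#' Optimal one-to-one assignment maximizing the total squared overlap
#' between the two mode sets (Hungarian algorithm on `-overlap^2`), robust
#' against near-degenerate reorderings that break frequency-order matching.
#'
#' @param modes_low,modes_high column matrices of normal modes expressed in
#'   the same basis (mass-weighted Cartesian or internal).
#' @return integer vector `map` with `map[k]` = high-level mode matched to
#'   low-level mode k.
#' @export
match_modes <- function(modes_low, modes_high) {
  if (ncol(modes_low) != ncol(modes_high))
    stop("mode counts differ between levels: ", ncol(modes_low), " vs ",
         ncol(modes_high))
  ov <- abs(t(modes_low) %*% modes_high)
  .hungarian(-ov^2)
}

## Hungarian algorithm (O(n^3), Jonker-style row reduction + augmenting
## paths) for a square cost matrix; returns assignment col index per row
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)        # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}

#' Additive dual-level scheme (Add)
#'
#' Adds the low-level anharmonic shift `nu_low - omega_low` of each
#' transition to the high-level harmonic transition energy.
#'
#' @param table a transition table with columns `omega` and the anharmonic
#'   column(s) (`vpt2`, `dvpt2`, `gvpt2` as present), as produced by
#'   [gvpt2()]; or a `gvpt2` fit object.
#' @param omega_high high-level harmonic wavenumbers, mode-matched to the
#'   low level (use [match_modes()] or supply `map`).
#' @param map optional permutation mapping low-level mode k to
#'   `omega_high[map[k]]`.
#' @return the table with the harmonic and anharmonic columns replaced by
#'   the Add-composed values.
#' @export
add_scheme <- function(table, omega_high, map = NULL) {
  if (inherits(table, "gvpt2")) table <- table$table
  if (!is.null(map)) omega_high <- omega_high[map]
  wH <- vapply(seq_len(nrow(table)), function(r) {
    v <- .parse_state(table$state[r])
    sum(omega_high[seq_along(v)] * v)
  }, 0)
  shift <- wH - table$omega
  out <- table
  out$omega <- wH
  for (col in intersect(c("vpt2", "dvpt2", "gvpt2"), names(table)))
    out[[col]] <- table[[col]] + shift
  out
}

#' Substitution dual-level scheme (Sub)
#'
#' Re-runs the full VPT2/DVPT2/GVPT2 machinery with the high-level harmonic
#' frequencies substituted in all denominators and harmonic terms, while the
#' low-level force field and kinetic derivatives are retained.  The Martin
#' test is re-evaluated with the substituted frequencies, so the accepted
#' resonance set may differ between levels.
#'
#' @param ff low-level quartic force field.
#' @param kin low-level kinetic derivatives (NULL in the Cartesian frame).
#' @param omega_high high-level harmonic wavenumbers (mode-matched).
#' @param map optional mode permutation as in [add_scheme()].
#' @param coriolis Coriolis data (Cartesian frame).
#' @param ... thresholds and state selection passed to the VPT2 stage
#'   (`dw_thresh`, `k_thresh`, `states`, `aux`).
#' @return a transition table as produced by [gvpt2()].
#' @export
sub_scheme <- function(ff, kin = NULL, omega_high, map = NULL,
                       coriolis = NULL, ...) {
  if (!is.null(map)) omega_high <- omega_high[map]
  if (length(omega_high) != length(ff$omega))
    stop("mode counts differ between levels")
  .vpt2_stage(ff, kin, coriolis = coriolis, omega = omega_high, ...)$table
}
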