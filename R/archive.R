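# Versioned JSON archive for surface runs: labelled gradients and Hessians
# with geometry provenance and full-precision numbers (bit-exact round trip
# of IEEE doubles through 17-digit decimal).

.archive_version <- 1L

#' Write a surface archive
#'
#' @param surface a [run_surface()] result.
#' @param path output file (JSON).
#' @param geom reference geometry recorded for provenance.
#' @param sol optional harmonic solution; storing it pins the normal-mode
#'   basis so that a replay displaces along exactly the modes the archived
#'   Hessians were computed at (the eigenbasis of a redundancy-reduced G
#'   matrix is not stable under tiny geometry perturbations when G has
#'   near-degenerate eigenvalues).
#' @return `path`, invisibly.
#' @export
write_archive <- function(surface, path, geom = NULL, sol = NULL) {
  entry <- function(r, g) list(
    energy = r$energy,
    gradient = as.numeric(r$gradient),
    hessian = as.numeric(r$hessian),
    coords = as.numeric(t(g$coords)))
  obj <- list(
    format = "curvib-surface",
    version = .archive_version,
    delta_q = surface$delta_q,
    frame = surface$frame,
    natoms = if (!is.null(geom)) .n_atoms(geom) else
      length(surface$results[[1]]$gradient) / 3L,
    symbols = if (!is.null(geom)) geom$symbols else NULL,
    masses = if (!is.null(geom)) geom$masses else NULL,
    labels = surface$labels,
    results = Map(entry, surface$results, surface$geoms[names(surface$results)])
  )
  if (!is.null(sol)) {
    obj$sol <- list(frame = sol$frame, omega = sol$omega,
                    omega_au = sol$omega_au,
                    imaginary = sol$imaginary,
                    U = if (!is.null(sol$U)) as.numeric(sol$U),
                    U_dim = if (!is.null(sol$U)) dim(sol$U),
                    Lt = if (!is.null(sol$Lt)) as.numeric(sol$Lt),
                    Lt_inv = if (!is.null(sol$Lt_inv)) as.numeric(sol$Lt_inv),
                    lmw = if (!is.null(sol$lmw)) as.numeric(sol$lmw))
  }
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a surface archive
#'
#' Refuses archives written by a future format version.
#'
#' @param path archive file.
#' @return Object of class `cv_surface` (geometries reconstructed from the
#'   stored coordinates when symbols/masses are present).
#' @export
read_archive <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE,
                            simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "curvib-surface"))
    stop("not a curvib surface archive: ", path)
  if (obj$version > .archive_version)
    stop("archive version ", obj$version, " is newer than supported (",
         .archive_version, ")")
  na <- obj$natoms
  res <- lapply(obj$results, function(e) {
    h <- as.numeric(unlist(e$hessian))
    list(energy = as.numeric(e$energy),
         gradient = as.numeric(unlist(e$gradient)),
         # wrong-sized (corrupted) entries surface as invalid, not as errors
         hessian = if (length(h) == (3L * na)^2)
           matrix(h, 3L * na, 3L * na) else NULL,
         coords = as.numeric(unlist(e$coords)))
  })
  geoms <- NULL
  if (!is.null(obj$symbols)) {
    geoms <- lapply(res, function(e)
      geometry(unlist(obj$symbols), matrix(e$coords, ncol = 3L, byrow = TRUE),
               masses = unlist(obj$masses)))
  }
  sol <- NULL
  if (!is.null(obj$sol)) {
    s <- obj$sol
    M <- length(unlist(s$omega))
    sol <- structure(list(
      omega = unlist(s$omega), omega_au = unlist(s$omega_au),
      imaginary = as.logical(unlist(s$imaginary)),
      frame = s$frame), class = "cv_harmonic")
    if (length(s$U)) {
      sol$U <- matrix(unlist(s$U), unlist(s$U_dim)[1], unlist(s$U_dim)[2])
      sol$Lt <- matrix(unlist(s$Lt), M, M)
      sol$Lt_inv <- matrix(unlist(s$Lt_inv), M, M)
      sol$L <- sol$U %*% sol$Lt
    }
    if (length(s$lmw)) sol$lmw <- matrix(unlist(s$lmw), ncol = M)
  }
  structure(list(results = res, geoms = geoms, delta_q = obj$delta_q,
                 frame = obj$frame, labels = unlist(obj$labels),
                 engine_calls = 0L, sol = sol),
            class = "cv_surface")
}
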