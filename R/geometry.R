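# Molecular geometries: element symbols, masses (amu) and Cartesian
# coordinates (Bohr).  The reference configuration anchors every Taylor
# expansion in the package.

# Atomic masses of the most abundant isotopes (amu) and single-bond covalent
# radii (Angstrom, Pyykko-Atsumi) for the elements this package is likely to
# meet.  Stored in source so that the package ships no binary data.
.atomic_masses <- c(
  H = 1.00782503, D = 2.01410178, He = 4.00260325,
  Li = 7.01600344, Be = 9.01218307, B = 11.00930536,
  C = 12, N = 14.00307401, O = 15.99491462, F = 18.99840316,
  Ne = 19.99244018, Na = 22.98976928, Mg = 23.98504170,
  Al = 26.98153853, Si = 27.97692653, P = 30.97376200,
  S = 31.97207117, Cl = 34.96885268, Ar = 39.96238312,
  K = 38.96370649, Ca = 39.96259086, Br = 78.91833760, I = 126.90447
)

.covalent_radii <- c(
  H = 0.32, D = 0.32, He = 0.46, Li = 1.33, Be = 1.02, B = 0.85,
  C = 0.75, N = 0.71, O = 0.63, F = 0.64, Ne = 0.67, Na = 1.55,
  Mg = 1.39, Al = 1.26, Si = 1.16, P = 1.11, S = 1.03, Cl = 0.99,
  Ar = 0.96, K = 1.96, Ca = 1.71, Br = 1.14, I = 1.33
)

#' Construct a molecular geometry
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix (N x 3) of Cartesian coordinates, or a
#'   length-3N vector laid out per atom.
#' @param masses atomic masses in amu; looked up from the element symbols
#'   when omitted.
#' @param units `"bohr"` (default) or `"angstrom"` for the input coordinates;
#'   coordinates are stored in Bohr.
#' @return An object of class `cv_geometry` with fields `symbols`, `masses`
#'   (amu) and `coords` (N x 3, Bohr).
#' @export
geometry <- function(symbols, coords, masses = NULL,
                     units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3L, byrow = TRUE)
  stopifnot(nrow(coords) == length(symbols), ncol(coords) == 3L)
  if (units == "angstrom") coords <- coords / .cv$bohr_to_ang
  if (is.null(masses)) {
    masses <- .atomic_masses[symbols]
    if (anyNA(masses))
      stop("no mass tabulated for element(s): ",
           paste(unique(symbols[is.na(masses)]), collapse = ", "))
  }
  masses <- as.numeric(masses)
  if (any(masses <= 0)) stop("atomic masses must be positive")
  structure(list(symbols = as.character(symbols), masses = masses,
                 coords = unname(coords)),
            class = "cv_geometry")
}

#' Read a geometry from an XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then one `symbol x y z`
#' line per atom.
#'
#' @param path file path.
#' @param units units of the coordinates in the file (XYZ files are
#'   conventionally in Angstrom).
#' @return A [geometry()] object.
#' @export
read_xyz <- function(path, units = c("angstrom", "bohr")) {
  units <- match.arg(units)
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 2L)
    stop("malformed XYZ file: ", path)
  rec <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  sym <- vapply(rec, `[[`, "", 1L)
  xyz <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3L)))
  geometry(sym, xyz, units = units)
}

#' @export
print.cv_geometry <- function(x, ...) {
  cat(sprintf("<cv_geometry: %d atoms [%s]>\n", length(x$symbols),
              paste(x$symbols, collapse = " ")))
  invisible(x)
}

.n_atoms <- function(geom) length(geom$symbols)

## flattened coordinate vector (3N, Bohr)
.xvec <- function(geom) as.numeric(t(geom$coords))

.with_coords <- function(geom, xvec) {
  geom$coords <- matrix(xvec, ncol = 3L, byrow = TRUE)
  geom
}

## masses in electron-mass units, replicated over x,y,z
.mass_vector_au <- function(geom) {
  rep(geom$masses * .cv$amu_to_me, each = 3L)
}
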