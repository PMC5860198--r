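#' Uniform force orientations on the unit sphere
#'
#' Spherical Fibonacci lattice: heights z_k are uniformly spaced midpoints
#' in (-1, 1) and azimuths advance by the golden angle 2*pi/phi^2 (phi the
#' golden ratio), giving a deterministic, near-uniform point set for any n.
#'
#' @param n Number of orientations (>= 1).
#' @return n x 3 matrix of unit vectors, one per row.
#' @export
fibonacci_orientations <- function(n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  k <- seq_len(n) - 1
  z <- 1 - (2 * k + 1) / n
  phi <- (1 + sqrt(5)) / 2
  az <- 2 * pi * k / phi^2
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(az), y = r * sin(az), z = z)
}

#' Force orientation basis for double force scanning
#'
#' Bundles a deterministic spherical-Fibonacci orientation set with a base
#' force magnitude. The same basis is applied at every site; the magnitude
#' is arbitrary because all rescuability indices are invariant under
#' uniform force scaling within linear response.
#'
#' @param n_orientations Orientations per site (default 12, near-icosahedral
#'   coverage).
#' @param magnitude Base force magnitude (default 1, arbitrary units).
#' @return A `force_basis` tibble with columns `orientation`, `x`, `y`, `z`.
#' @export
force_basis <- function(n_orientations = 12, magnitude = 1) {
  o <- fibonacci_orientations(n_orientations)
  out <- tibble::tibble(
    orientation = seq_len(n_orientations),
    x = o[, 1], y = o[, 2], z = o[, 3]
  )
  attr(out, "magnitude") <- magnitude
  class(out) <- c("force_basis", class(tibble::tibble()))
  out
}

# n x 3 orientation matrix of a basis
basis_matrix <- function(basis) {
  if (inherits(basis, "force_basis") || is.data.frame(basis)) {
    as.matrix(basis[, c("x", "y", "z")])
  } else {
    basis
  }
}

basis_magnitude <- function(basis) {
  m <- attr(basis, "magnitude")
  if (is.null(m)) 1 else m
}

#' Assemble a single-site external force vector
#'
#' All 3N components are zero except the three belonging to `site`, which
#' equal `magnitude * orientation`.
#'
#' @param n_res Number of residues N.
#' @param site Residue index in 1..N.
#' @param orientation Unit 3-vector.
#' @param magnitude Scalar force magnitude.
#' @return Numeric 3N force vector.
#' @export
assemble_force_vector <- function(n_res, site, orientation, magnitude = 1) {
  if (site < 1 || site > n_res) stop("site out of range", call. = FALSE)
  f <- numeric(3 * n_res)
  f[(3 * site - 2):(3 * site)] <- magnitude * orientation
  f
}

#' Fixed-RMSD magnitude multiplier for the second-site force
#'
#' In the fixed-RMSD (FR) scheme the second-site force is rescaled so that,
#' applied alone, it deforms the structure exactly as much as the
#' first-site force: given the structural distances `d_i_unit` and
#' `d_j_unit` produced by unit-magnitude forces at the two sites, the
#' multiplier is `d_i_unit / d_j_unit` (exact under linear response).
#'
#' @param d_i_unit Structural distance of the unit first-site response (A).
#' @param d_j_unit Structural distance of the unit second-site response (A).
#' @param tol Smallest admissible `d_j_unit`; below it the force lies in
#'   the rigid null space, which signals a broken network.
#' @return Magnitude multiplier for the second-site force.
#' @export
fr_rescale <- function(d_i_unit, d_j_unit, tol = 1e-12) {
  if (d_j_unit <= tol) {
    stop("second-site unit force produced no deformation (d_j <= tol): broken network",
      call. = FALSE
    )
  }
  d_i_unit / d_j_unit
}
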