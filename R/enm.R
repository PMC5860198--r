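#' Build an anisotropic network model
#'
#' Connects C-alpha nodes closer than the cutoff `r_c` with Hookean springs
#' of stiffness `gamma` and assembles the 3N x 3N ANM hessian: the
#' off-diagonal 3x3 block of a connected pair (i, j) is
#' `-gamma * e_ij %*% t(e_ij)` with `e_ij` the unit inter-node vector, and
#' each diagonal block is minus the sum of its row's off-diagonal blocks
#' (so rigid translations cost no energy).
#'
#' @param s A [cg_structure()] with at least 2 residues.
#' @param r_c Spring cutoff in Angstrom (default 15).
#' @param gamma Spring constant, arbitrary energy/Angstrom^2 units
#'   (default 1); it cancels out of all rescuability indices.
#' @return An `elastic_network`: list with `hessian` (3N x 3N), `degree`
#'   (neighbours within `r_c` per node, self excluded), `r_c`, `gamma`, and
#'   the structure.
#' @export
build_network <- function(s, r_c = 15, gamma = 1) {
  coords <- cg_coords(s)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 residues", call. = FALSE)
  if (r_c <= 0 || gamma <= 0) stop("r_c and gamma must be positive", call. = FALSE)

  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
    2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  diag(dmat) <- Inf
  if (any(dmat < 1e-6)) {
    stop("coincident nodes (distance < 1e-6 Angstrom): spring direction undefined",
      call. = FALSE
    )
  }
  adj <- dmat < r_c
  degree <- rowSums(adj)

  hess <- matrix(0, 3 * n, 3 * n)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]
    j <- pairs[p, 2]
    e <- (coords[j, ] - coords[i, ]) / dmat[i, j]
    blk <- -gamma * tcrossprod(e)
    bi <- (3 * i - 2):(3 * i)
    bj <- (3 * j - 2):(3 * j)
    hess[bi, bj] <- blk
    hess[bj, bi] <- blk
    hess[bi, bi] <- hess[bi, bi] - blk
    hess[bj, bj] <- hess[bj, bj] - blk
  }
  keys <- cg_keys(s)
  dn <- paste(rep(keys, each = 3), c("x", "y", "z"), sep = ".")
  dimnames(hess) <- list(dn, dn)

  structure(
    list(
      hessian = hess, degree = setNames(as.integer(degree), keys),
      r_c = r_c, gamma = gamma, structure = s
    ),
    class = "elastic_network"
  )
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(
    "# Anisotropic network model: N =", length(x$degree),
    " r_c =", x$r_c, "A  gamma =", x$gamma, "\n",
    "# degree range:", min(x$degree), "-", max(x$degree), "\n"
  )
  invisible(x)
}

# Full eigendecomposition of the hessian, ascending eigenvalues.
enm_eigen <- function(net) {
  e <- eigen(net$hessian, symmetric = TRUE)
  list(values = rev(e$values), vectors = e$vectors[, rev(seq_along(e$values))])
}

#' Pseudo-inverse response operator of an elastic network
#'
#' Inverts the ANM hessian over its non-rigid modes:
#' `H+ = sum_k 1/lambda_k v_k t(v_k)` over eigenvalues above the zero
#' threshold. Under linear response theory the displacement field produced
#' by an external force vector F is `H+ F`. A connected, non-planar
#' structure must have exactly 6 rigid-body zero modes; any other count is
#' an error (floppy/planar/disconnected network, or a numerically broken
#' hessian).
#'
#' @param net An `elastic_network`.
#' @param zero_tol Relative eigenvalue threshold: eigenvalues below
#'   `zero_tol * max(eigenvalue)` count as rigid (default 1e-6).
#' @return Symmetric 3N x 3N matrix annihilating the rigid-body subspace.
#' @export
pseudo_inverse <- function(net, zero_tol = 1e-6) {
  e <- enm_eigen(net)
  lam <- e$values
  thr <- zero_tol * max(lam)
  n_zero <- sum(lam < thr)
  if (n_zero > 6L) {
    stop(
      n_zero, " near-zero eigenvalues (expected 6): ",
      "network is floppy, planar or disconnected; increase r_c",
      call. = FALSE
    )
  }
  if (n_zero < 6L) {
    stop(
      n_zero, " near-zero eigenvalues (expected 6): ",
      "hessian is numerically broken",
      call. = FALSE
    )
  }
  keep <- which(lam >= thr)
  v <- e$vectors[, keep, drop = FALSE]
  op <- v %*% (t(v) / lam[keep])
  op <- (op + t(op)) / 2
  dimnames(op) <- dimnames(net$hessian)
  attr(op, "n_zero") <- n_zero
  op
}

#' First k non-rigid normal modes of an elastic network
#'
#' Rigid-body modes (eigenvalues below `zero_tol * lambda_max`) are
#' excluded; the remaining modes are returned in ascending eigenvalue
#' order. The low-frequency end of this spectrum is the protein's
#' "essential space" onto which compensatory motions are decomposed.
#'
#' @param net An `elastic_network`.
#' @param k Number of modes, at most `3N - 6`.
#' @param zero_tol Relative zero threshold as in [pseudo_inverse()].
#' @return A `mode_spectrum`: list with `eigenvalues` (length k, ascending),
#'   `vectors` (3N x k, orthonormal) and `n_zero`.
#' @export
normal_modes <- function(net, k = 10, zero_tol = 1e-6) {
  n3 <- nrow(net$hessian)
  if (k < 1L || k > n3 - 6L) {
    stop("k must be between 1 and 3N - 6 = ", n3 - 6L, call. = FALSE)
  }
  e <- enm_eigen(net)
  lam <- e$values
  thr <- zero_tol * max(lam)
  n_zero <- sum(lam < thr)
  nonrigid <- which(lam >= thr)
  if (k > length(nonrigid)) {
    stop("only ", length(nonrigid), " non-rigid modes available", call. = FALSE)
  }
  keep <- nonrigid[seq_len(k)]
  structure(
    list(
      eigenvalues = lam[keep],
      vectors = e$vectors[, keep, drop = FALSE],
      n_zero = n_zero
    ),
    class = "mode_spectrum"
  )
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(
    "# Normal-mode spectrum:", length(x$eigenvalues), "non-rigid modes,",
    x$n_zero, "rigid modes excluded\n"
  )
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a mode spectrum into a per-mode table
#'
#' @param x A `mode_spectrum`.
#' @param ... Unused.
#' @return Tibble with `mode`, `eigenvalue`, `collectivity`.
#' @export
tidy.mode_spectrum <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    collectivity = apply(x$vectors, 2, collectivity)
  )
}

#' Collectivity index of a displacement pattern
#'
#' Exponential-entropy measure of how many residues participate in a 3N
#' displacement vector: with per-residue squared displacements normalized
#' to sum to one, `kappa = exp(-sum u_i^2 log u_i^2) / N`. Ranges from
#' `1/N` (motion confined to one residue) to 1 (uniform motion); invariant
#' under global scaling of the vector.
#'
#' @param mode A 3N displacement vector.
#' @return Collectivity in (0, 1].
#' @export
collectivity <- function(mode) {
  if (all(mode == 0)) stop("collectivity of the zero vector is undefined", call. = FALSE)
  if (length(mode) %% 3 != 0) stop("length must be a multiple of 3", call. = FALSE)
  n <- length(mode) / 3
  u2 <- rowSums(matrix(mode^2, ncol = 3, byrow = TRUE))
  u2 <- u2 / sum(u2)
  h <- -sum(ifelse(u2 > 0, u2 * log(u2), 0))
  exp(h) / n
}
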