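#' Deterministic synthetic C-alpha structures
#'
#' Generates connected, non-planar C-alpha geometries so the whole pipeline
#' is testable without downloads:
#' * `tetrahedron` — regular tetrahedron, edge 3.8 Angstrom (N fixed at 4);
#' * `helix` — ideal alpha-helical trace: rise 1.5 Angstrom/residue, 100
#'   degree turn, radius 2.3 Angstrom (consecutive C-alpha spacing ~3.8);
#' * `lattice3d` — cubic grid (spacing 3.8) with seeded uniform jitter;
#' * `random_globule` — seeded self-avoiding cluster with minimum
#'   inter-node distance 3.5 Angstrom at protein-like density.
#'
#' The same `kind`, `n_residues`, parameters and `seed` always give
#' bit-identical coordinates. Residues are alanines on chain A, numbered
#' from 1.
#'
#' @param kind One of `"tetrahedron"`, `"helix"`, `"lattice3d"`,
#'   `"random_globule"`.
#' @param n_residues Number of residues (>= 4 for non-planar kinds;
#'   ignored for the tetrahedron).
#' @param seed Integer seed; required for the stochastic kinds.
#' @param edge Tetrahedron edge length (Angstrom).
#' @param rise,turn_deg,radius Helix parameters (Angstrom, degrees,
#'   Angstrom).
#' @param spacing,jitter Lattice spacing and uniform jitter amplitude
#'   (Angstrom).
#' @param min_dist Globule minimum inter-node distance (Angstrom).
#' @return A [cg_structure()].
#' @export
make_structure <- function(kind = c("tetrahedron", "helix", "lattice3d", "random_globule"),
                           n_residues = 20, seed = NULL,
                           edge = 3.8, rise = 1.5, turn_deg = 100,
                           radius = 2.3, spacing = 3.8, jitter = 0.5,
                           min_dist = 3.5) {
  kind <- match.arg(kind)
  coords <- switch(kind,
    tetrahedron = {
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      v * edge / (2 * sqrt(2))
    },
    helix = {
      if (n_residues < 4) stop("need n_residues >= 4", call. = FALSE)
      k <- seq_len(n_residues) - 1
      th <- k * turn_deg * pi / 180
      cbind(radius * cos(th), radius * sin(th), k * rise)
    },
    lattice3d = {
      if (n_residues < 4) stop("need n_residues >= 4", call. = FALSE)
      if (is.null(seed)) stop("lattice3d requires a seed", call. = FALSE)
      side <- ceiling(n_residues^(1 / 3))
      g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
      g <- as.matrix(g[seq_len(n_residues), ]) * spacing
      with_seed(seed, g + matrix(runif(3 * n_residues, -jitter, jitter), ncol = 3))
    },
    random_globule = {
      if (n_residues < 4) stop("need n_residues >= 4", call. = FALSE)
      if (is.null(seed)) stop("random_globule requires a seed", call. = FALSE)
      side <- (60 * n_residues)^(1 / 3) # ~60 A^3 per residue
      with_seed(seed, {
        pts <- matrix(NA_real_, n_residues, 3)
        n_acc <- 0L
        tries <- 0L
        while (n_acc < n_residues) {
          tries <- tries + 1L
          if (tries > 10000L * n_residues) {
            stop("could not place nodes at the requested density", call. = FALSE)
          }
          p <- runif(3, 0, side)
          if (n_acc == 0L ||
            min(sqrt(rowSums((pts[seq_len(n_acc), , drop = FALSE] -
              matrix(p, n_acc, 3, byrow = TRUE))^2))) >= min_dist) {
            n_acc <- n_acc + 1L
            pts[n_acc, ] <- p
          }
        }
        pts
      })
    }
  )
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  if (any(d < 1e-6)) stop("fixture parameters produce coincident nodes", call. = FALSE)
  cg_structure(tibble::tibble(
    chain = "A", resnum = seq_len(n), icode = "", aa = "ALA",
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  ))
}

#' Synthetic reference site labels
#'
#' Seeded disjoint random draws of pathogenic (PS) and rescue (RS) sites
#' from a structure's residues, in the same table dialect as real
#' reference files, to exercise the evaluation layer end to end.
#'
#' @param s A [cg_structure()].
#' @param n_PS,n_RS Numbers of pathogenic and rescue sites
#'   (`n_PS + n_RS <= N`).
#' @param seed Integer seed.
#' @return Reference tibble: `chain`, `resnum`, `icode`, `label`, `source`,
#'   `key`.
#' @export
make_reference_labels <- function(s, n_PS, n_RS, seed) {
  n <- nrow(s)
  if (n_PS + n_RS > n) stop("n_PS + n_RS exceeds the number of residues", call. = FALSE)
  idx <- with_seed(seed, sample.int(n, n_PS + n_RS))
  ps <- idx[seq_len(n_PS)]
  rs <- idx[n_PS + seq_len(n_RS)]
  sel <- c(ps, rs)
  tibble::tibble(
    chain = s$chain[sel], resnum = s$resnum[sel], icode = s$icode[sel],
    label = c(rep("PS", n_PS), rep("RS", n_RS)),
    source = "synthetic",
    key = cg_keys(s)[sel]
  )
}

#' Read / write reference site tables as TSV
#'
#' Columns: chain, resnum, icode, label (`PS`, `RS` or `PS+RS`), source.
#'
#' @param reference Reference tibble.
#' @param path File path.
#' @return `path` (write) or the reference tibble with a `key` column
#'   (read).
#' @export
write_reference_sites <- function(reference, path) {
  cols <- c("chain", "resnum", "icode", "label", "source")
  write.table(reference[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_sites
#' @export
read_reference_sites <- function(path) {
  df <- tibble::as_tibble(read.delim(path,
    sep = "\t",
    colClasses = c(chain = "character", icode = "character"),
    na.strings = NULL
  ))
  df$key <- res_key(df$chain, df$resnum, df$icode)
  df
}

#' Read / write pocket membership tables as TSV
#'
#' One row per member residue: pocket_id, chain, resnum (plus optional
#' icode) — compatible with a plain export of fpocket residue lists.
#'
#' @param pockets Pockets tibble.
#' @param path File path.
#' @return `path` (write) or the pockets tibble with a `key` column (read).
#' @export
write_pockets <- function(pockets, path) {
  cols <- intersect(c("pocket_id", "chain", "resnum", "icode"), names(pockets))
  write.table(pockets[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pockets
#' @export
read_pockets <- function(path) {
  df <- tibble::as_tibble(read.delim(path,
    sep = "\t",
    colClasses = c(chain = "character"), na.strings = NULL
  ))
  if (!"icode" %in% names(df)) df$icode <- ""
  df$icode <- as.character(df$icode)
  df$key <- res_key(df$chain, df$resnum, df$icode)
  df
}
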