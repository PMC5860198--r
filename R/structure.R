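#' Coarse-grained protein structures
#'
#' A `cg_structure` is a tibble with one row per residue: `chain`, `resnum`,
#' `icode`, `aa` (3-letter code), the C-alpha coordinate `x`, `y`, `z` in
#' Angstrom, and a list-column `atoms` holding the heavy-atom coordinate
#' matrix of each residue (used for proximity analysis; reduces to the
#' C-alpha alone for synthetic fixtures). Row order is the order of
#' appearance in the source file or generator.
#'
#' @param nodes Data frame with columns `chain`, `resnum`, `icode`, `aa`,
#'   `x`, `y`, `z` and optionally `atoms`.
#' @return A `cg_structure` tibble.
#' @export
cg_structure <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("chain", "resnum", "icode", "aa", "x", "y", "z")
  missing <- setdiff(required, names(nodes))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  nodes$resnum <- as.integer(nodes$resnum)
  nodes$icode <- ifelse(is.na(nodes$icode), "", as.character(nodes$icode))
  if (!"atoms" %in% names(nodes)) {
    nodes$atoms <- lapply(seq_len(nrow(nodes)), function(i) {
      matrix(c(nodes$x[i], nodes$y[i], nodes$z[i]), 1, 3)
    })
  }
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    stop("non-finite C-alpha coordinates", call. = FALSE)
  }
  keys <- res_key(nodes$chain, nodes$resnum, nodes$icode)
  if (anyDuplicated(keys)) {
    stop("duplicated (chain, resnum, icode) residue keys: ",
      paste(unique(keys[duplicated(keys)]), collapse = ", "),
      call. = FALSE
    )
  }
  class(nodes) <- c("cg_structure", class(tibble::tibble()))
  nodes
}

#' @export
print.cg_structure <- function(x, ...) {
  cat(
    "# C-alpha coarse-grained structure:", nrow(x), "residues,",
    length(unique(x$chain)), "chain(s)\n"
  )
  NextMethod()
}

#' C-alpha coordinate matrix of a structure
#'
#' @param s A `cg_structure`.
#' @return Numeric N x 3 matrix, rows in residue order.
#' @export
cg_coords <- function(s) {
  m <- as.matrix(s[, c("x", "y", "z")])
  rownames(m) <- res_key(s$chain, s$resnum, s$icode)
  m
}

#' Residue keys of a structure
#'
#' @param s A `cg_structure`.
#' @return Character vector `"chain:resnum[icode]"`, one per residue.
#' @export
cg_keys <- function(s) res_key(s$chain, s$resnum, s$icode)

#' Read a C-alpha coarse-grained structure from a PDB file
#'
#' Parses ATOM records (HETATM, waters and non-protein polymers are
#' excluded), selects one chain or all, selects one MODEL of a multi-model
#' file, resolves alternate locations by highest occupancy (ties broken by
#' file order), and keeps one node per residue that has a C-alpha atom.
#' Heavy-atom coordinates of each retained residue are stored for proximity
#' analysis. Residue numbering and insertion codes are taken verbatim.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier, or `"ALL"` (default) for every chain.
#' @param model Model number for multi-model (NMR-style) files; default 1.
#' @return A [cg_structure()]. Residues lacking a C-alpha are skipped with a
#'   warning; the number skipped is stored in the `n_skipped` attribute.
#' @export
read_calpha_structure <- function(path, chain = "ALL", model = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models) {
    stop("model ", model, " not present (file has ", n_models, ")",
      call. = FALSE
    )
  }
  at <- tibble::as_tibble(pdb$atom)
  idx <- seq_len(nrow(at))
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[idx, 1]
  at$y <- xyz[idx, 2]
  at$z <- xyz[idx, 3]

  at <- dplyr::filter(at, .data$type == "ATOM", .data$resid %in% .aa3)
  if (!identical(chain, "ALL")) {
    at <- dplyr::filter(at, .data$chain %in% !!chain)
  }
  if (nrow(at) == 0L || !any(at$elety == "CA")) {
    stop(
      "no C-alpha atoms in selection (chain ",
      paste(chain, collapse = ","), ")",
      call. = FALSE
    )
  }

  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$o <- ifelse(is.na(at$o), 1, at$o)

  # altloc: within (residue, atom name) keep highest occupancy, ties -> first
  at$file_order <- seq_len(nrow(at))
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$file_order, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$file_order)

  # drop hydrogens for the heavy-atom store
  elesy <- at$elesy
  guess_h <- grepl("^[0-9]*H", at$elety)
  is_h <- ifelse(!is.na(elesy) & elesy != "", elesy == "H", guess_h)
  at <- at[!is_h, , drop = FALSE]

  rid <- paste(at$chain, at$resno, at$insert, sep = "\r")
  rid <- factor(rid, levels = unique(rid))
  groups <- split(at, rid)

  has_ca <- vapply(groups, function(g) any(g$elety == "CA"), logical(1))
  n_skipped <- sum(!has_ca)
  if (n_skipped > 0L) {
    warning(n_skipped, " residue(s) lacking a C-alpha atom were skipped",
      call. = FALSE
    )
  }
  groups <- groups[has_ca]
  if (length(groups) == 0L) {
    stop(
      "no C-alpha atoms in selection (chain ",
      paste(chain, collapse = ","), ")",
      call. = FALSE
    )
  }

  nodes <- purrr::map_dfr(groups, function(g) {
    ca <- g[g$elety == "CA", , drop = FALSE][1, ]
    tibble::tibble(
      chain = ca$chain, resnum = ca$resno, icode = ca$insert,
      aa = ca$resid, x = ca$x, y = ca$y, z = ca$z
    )
  })
  nodes$atoms <- lapply(groups, function(g) {
    unname(as.matrix(g[, c("x", "y", "z")]))
  })
  s <- cg_structure(nodes)
  attr(s, "n_skipped") <- n_skipped
  s
}

#' Write the C-alpha trace of a structure as a minimal PDB file
#'
#' Emits one ATOM record (element CA) per residue, preserving chain,
#' numbering and insertion codes, so synthetic fixtures and real inputs go
#' through the same reading path.
#'
#' @param s A `cg_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calpha_pdb <- function(s, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(cg_coords(s))),
    resno = s$resnum,
    resid = s$aa,
    chain = s$chain,
    insert = ifelse(s$icode == "", NA, s$icode),
    elety = rep("CA", nrow(s)),
    o = rep(1, nrow(s)), b = rep(0, nrow(s))
  )
  invisible(path)
}

#' Serialize / read the C-alpha node table as TSV
#'
#' Columns: chain, resnum, icode, aa, x, y, z. Coordinates are written with
#' enough digits to round-trip PDB precision (1e-3 Angstrom). Heavy-atom
#' coordinates are not serialized; a structure read back from TSV falls back
#' to C-alpha-only proximity distances.
#'
#' @param s A `cg_structure`.
#' @param path File path.
#' @return `path` (write) or a `cg_structure` (read).
#' @export
write_structure_tsv <- function(s, path) {
  out <- tibble::as_tibble(s)[, c("chain", "resnum", "icode", "aa", "x", "y", "z")]
  out$x <- sprintf("%.6f", out$x)
  out$y <- sprintf("%.6f", out$y)
  out$z <- sprintf("%.6f", out$z)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure_tsv
#' @export
read_structure_tsv <- function(path) {
  df <- read.delim(path,
    sep = "\t", colClasses = c(
      chain = "character", icode = "character", aa = "character"
    ), na.strings = NULL
  )
  cg_structure(df)
}

#' Minimum heavy-atom distance between two residues
#'
#' Minimum Euclidean distance over all heavy-atom pairs of residues `i` and
#' `j`, used for the contact analysis of unpredicted rescue sites. When a
#' residue has no stored heavy atoms the C-alpha coordinate is used and the
#' result carries attribute `calpha_fallback = TRUE`.
#'
#' @param s A `cg_structure`.
#' @param i,j Residue indices (row numbers); must differ.
#' @return Distance in Angstrom (symmetric in `i`, `j`).
#' @export
min_heavy_atom_distance <- function(s, i, j) {
  if (i == j) stop("self-distance (i == j) is undefined", call. = FALSE)
  fallback <- FALSE
  get_atoms <- function(k) {
    a <- s$atoms[[k]]
    if (is.null(a) || nrow(a) == 0L) {
      fallback <<- TRUE
      a <- matrix(c(s$x[k], s$y[k], s$z[k]), 1, 3)
    }
    a
  }
  a <- get_atoms(i)
  b <- get_atoms(j)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d <- sqrt(max(min(d2), 0))
  attr(d, "calpha_fallback") <- fallback
  d
}
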