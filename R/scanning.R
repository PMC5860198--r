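#' Structural distance of a displacement field
#'
#' Root-mean-square of the per-residue displacement magnitudes:
#' `sqrt(sum ||dr_i||^2 / N)`. No superposition step is applied:
#' pseudo-inverse responses are orthogonal to the rigid-body subspace, so a
#' rigid refit is a no-op to first order.
#'
#' @param displacement 3N displacement vector in Angstrom.
#' @return Distance d in Angstrom.
#' @export
structural_distance <- function(displacement) {
  if (length(displacement) %% 3 != 0) {
    stop("displacement length must be a multiple of 3", call. = FALSE)
  }
  sqrt(sum(displacement^2) / (length(displacement) / 3))
}

#' Rescuability index
#'
#' Relative reduction of structural deformation when a second-site force is
#' added to a first-site force: `rho = (d_i - d_ij) / d_i`, where `d_i` is
#' the deformation under the single force and `d_ij` under the pair. A
#' value in (0, 1] means the double perturbation deforms the structure less
#' than the single one (a compensatory effect); rho = 1 is exact
#' cancellation; negative values mean aggravation. rho <= 1 always.
#'
#' @param d_i Deformation under the first-site force alone (> 0), Angstrom.
#' @param d_ij Deformation under both forces, Angstrom.
#' @param tol Smallest admissible `d_i`.
#' @return Dimensionless rescuability index.
#' @export
rescuability <- function(d_i, d_ij, tol = 1e-12) {
  if (any(d_i <= tol)) {
    stop("first-site force produced no deformation (d_i <= tol): network defect",
      call. = FALSE
    )
  }
  (d_i - d_ij) / d_i
}

# Per-site unit-force responses: list over sites of 3N x n response
# matrices (columns = basis orientations, unit magnitude), plus their
# squared norms. The whole scan reuses these; no repeated linear solves.
site_responses <- function(invH, orient) {
  n3 <- nrow(invH)
  n_res <- n3 / 3
  ot <- t(orient)
  resp <- vector("list", n_res)
  sq <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    u <- invH[, (3 * i - 2):(3 * i), drop = FALSE] %*% ot
    resp[[i]] <- u
    sq[[i]] <- colSums(u^2)
  }
  list(resp = resp, sq = sq, n_res = n_res)
}

# rho grid for an ordered pair (i, j): rows = first-site orientations a,
# cols = second-site orientations b. Uses squared-norm algebra:
# ||u_a + m u_b||^2 = ||u_a||^2 + m^2 ||u_b||^2 + 2 m <u_a, u_b>.
# Also returns the FR multiplier grid (all ones under FF).
pair_rho_grid <- function(sr, i, j, scheme) {
  sq_i <- sr$sq[[i]]
  sq_j <- sr$sq[[j]]
  if (any(sq_i <= 1e-24) || any(sq_j <= 1e-24)) {
    stop("unit force produced no deformation: network defect", call. = FALSE)
  }
  cross <- crossprod(sr$resp[[i]], sr$resp[[j]])
  if (scheme == "FF") {
    mult <- matrix(1, length(sq_i), length(sq_j))
    s2 <- outer(sq_i, sq_j, "+") + 2 * cross
  } else if (scheme == "FR") {
    mult <- sqrt(outer(sq_i, 1 / sq_j))
    s2 <- 2 * sq_i + 2 * mult * cross
  } else {
    stop("unknown scheme: ", scheme, call. = FALSE)
  }
  s2[s2 < 0] <- 0 # guard exact cancellation against roundoff
  rho <- 1 - sqrt(s2 / sq_i)
  list(rho = rho, mult = mult)
}

#' Rescuability score of one ordered site pair
#'
#' For each first-site force orientation, the rescuability index is
#' maximized over all second-site orientations (the best-case rescue for
#' that perturbation); the score `S_ij` is the mean of those maxima over
#' first-site orientations. Double-force responses are obtained by
#' superposition of the precomputed single-site responses (exact within
#' linear response).
#'
#' @param invH Response operator from [pseudo_inverse()].
#' @param i First (pathogenic) site index.
#' @param j Second (candidate rescue) site index; `i != j`.
#' @param basis A [force_basis()].
#' @param scheme `"FF"` (fixed force) or `"FR"` (fixed RMSD).
#' @return Scalar score `S_ij` (<= 1).
#' @export
pair_score <- function(invH, i, j, basis, scheme = "FF") {
  if (i == j) stop("pair score undefined for i == j", call. = FALSE)
  sr <- site_responses(invH, basis_matrix(basis))
  g <- pair_rho_grid(sr, i, j, scheme)
  mean(apply(g$rho, 1, max))
}

#' Double-force scan of all residue pairs
#'
#' Computes the rescuability matrix S for every ordered pair (i, j), i != j,
#' under each requested magnitude scheme. Row i is the first (pathogenic)
#' site, column j the candidate rescue site; the diagonal is undefined and
#' stored as NA. The scan reuses one table of unit-force responses per site
#' and superposes them, so no linear solve is repeated.
#'
#' @param net An `elastic_network` (or `invH` supplied directly via
#'   `invH`).
#' @param basis A [force_basis()].
#' @param schemes Character subset of `c("FF", "FR")`.
#' @param zero_tol Passed to [pseudo_inverse()] when `invH` is NULL.
#' @param invH Optional precomputed response operator.
#' @return Named list of `rescuability_matrix` objects, one per scheme
#'   (N x N, dimnames = residue keys, `scheme` attribute set).
#' @export
scan_rescuability <- function(net, basis = force_basis(),
                              schemes = c("FF", "FR"),
                              zero_tol = 1e-6, invH = NULL) {
  schemes <- match.arg(schemes, c("FF", "FR"), several.ok = TRUE)
  if (is.null(invH)) invH <- pseudo_inverse(net, zero_tol)
  n_res <- nrow(invH) / 3
  if (n_res < 3) stop("need at least 3 residues to scan", call. = FALSE)
  keys <- names(net$degree)
  sr <- site_responses(invH, basis_matrix(basis))

  out <- lapply(schemes, function(sch) {
    s <- matrix(NA_real_, n_res, n_res, dimnames = list(keys, keys))
    for (i in seq_len(n_res)) {
      for (j in seq_len(n_res)) {
        if (i == j) next
        g <- pair_rho_grid(sr, i, j, sch)
        # row maxima via max.col on the grid (ties immaterial for the value)
        s[i, j] <- mean(g$rho[cbind(
          seq_len(nrow(g$rho)),
          max.col(g$rho, ties.method = "first")
        )])
      }
    }
    structure(s, class = c("rescuability_matrix", "matrix", "array"), scheme = sch)
  })
  names(out) <- schemes
  out
}

#' Tidy a rescuability matrix into a long pair table
#'
#' @param x A `rescuability_matrix`.
#' @param ... Unused.
#' @return Tibble with `first_site`, `rescue_site`, `score`, `scheme`
#'   (diagonal omitted).
#' @export
tidy.rescuability_matrix <- function(x, ...) {
  keys <- rownames(x)
  df <- tibble::tibble(
    first_site = rep(keys, times = ncol(x)),
    rescue_site = rep(keys, each = nrow(x)),
    score = as.vector(unclass(x)),
    scheme = attr(x, "scheme")
  )
  df[df$first_site != df$rescue_site, ]
}

#' Per-residue compensatory power
#'
#' For each candidate rescue site j and each scheme, the number of first
#' sites it rescues (`S_ij > 0` over all i != j) is divided by j's contact
#' degree in the elastic network; each scheme's ratio vector is min-max
#' rescaled to \[0, 1\] across residues, and the compensatory power `P` is
#' the mean of the rescaled components. With a single scheme, `P` equals
#' that scheme's component. A flat ratio vector (max == min) rescales to
#' all zeros: a constant signal carries no compensatory information.
#'
#' @param s_matrices Named list of `rescuability_matrix` objects (e.g. the
#'   output of [scan_rescuability()]).
#' @param degree Per-node contact counts (named by residue key); all >= 1.
#' @return Tibble with `key`, `degree`, one `count_*` and `component_*`
#'   column per scheme, and `P`.
#' @export
compensatory_power <- function(s_matrices, degree) {
  if (any(degree == 0)) {
    stop("isolated node(s) with degree 0: increase r_c", call. = FALSE)
  }
  if (is.null(names(s_matrices))) {
    names(s_matrices) <- vapply(s_matrices, attr, "", "scheme")
  }
  keys <- names(degree)
  out <- tibble::tibble(key = keys, degree = as.integer(degree))
  comps <- list()
  for (sch in names(s_matrices)) {
    s <- s_matrices[[sch]]
    counts <- colSums(s > 0, na.rm = TRUE)
    ratio <- counts / degree
    rng <- range(ratio)
    comp <- if (rng[2] > rng[1]) (ratio - rng[1]) / (rng[2] - rng[1]) else rep(0, length(ratio))
    out[[paste0("count_", sch)]] <- as.integer(counts)
    out[[paste0("component_", sch)]] <- unname(comp)
    comps[[sch]] <- comp
  }
  out$P <- unname(Reduce(`+`, comps) / length(comps))
  out
}

#' Classify rescue sites from a compensatory-power profile
#'
#' Residues whose `P` strictly exceeds the `(1 - percentile)` quantile of
#' the `P` distribution (linear-interpolation quantile) are classified as
#' predicted rescue sites; ties at the threshold are excluded. The default
#' keeps the top 28 percent of residues.
#'
#' @param profile Tibble with columns `key` and `P` (e.g. from
#'   [compensatory_power()]).
#' @param percentile Top fraction to keep, in (0, 1); default 0.28.
#' @return The profile with a logical `predicted` column; the score
#'   threshold is stored in attribute `threshold`.
#' @export
classify_rescue_sites <- function(profile, percentile = 0.28) {
  if (percentile <= 0 || percentile >= 1) {
    stop("percentile must be in (0, 1)", call. = FALSE)
  }
  thr <- unname(quantile(profile$P, 1 - percentile))
  profile$predicted <- profile$P > thr
  attr(profile, "threshold") <- thr
  profile
}

#' Extract the predicted rescue-site keys from a classified profile
#'
#' @param profile Output of [classify_rescue_sites()].
#' @return Character vector of residue keys with `predicted == TRUE`.
#' @export
predicted_sites <- function(profile) profile$key[profile$predicted]

#' Best compensatory motion of a site pair
#'
#' Returns the double-force displacement field at the (first-site
#' orientation, second-site orientation) pair attaining the global maximum
#' of the rescuability index over the orientation grid; exact ties are
#' broken by the lowest first-site, then lowest second-site orientation
#' index. These "compensatory motions" are the displacements analysed
#' against the protein's essential space.
#'
#' @inheritParams pair_score
#' @return 3N displacement vector, with attributes `rho` (the maximal
#'   index) and `orientations` (the winning index pair).
#' @export
compensatory_motion <- function(invH, i, j, basis = force_basis(),
                                scheme = "FF") {
  if (i == j) stop("undefined for i == j", call. = FALSE)
  orient <- basis_matrix(basis)
  mag <- basis_magnitude(basis)
  sr <- site_responses(invH, orient)
  g <- pair_rho_grid(sr, i, j, scheme)
  hits <- which(g$rho == max(g$rho), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  a <- hits[1, 1]
  b <- hits[1, 2]
  disp <- mag * (sr$resp[[i]][, a] + g$mult[a, b] * sr$resp[[j]][, b])
  attr(disp, "rho") <- g$rho[a, b]
  attr(disp, "orientations") <- c(first = a, second = b)
  disp
}

#' Run the full double-force-scanning pipeline
#'
#' Builds the elastic network, inverts it over the non-rigid modes, scans
#' all ordered residue pairs under the requested schemes, aggregates the
#' rescuability matrices into the per-residue compensatory power and
#' classifies predicted rescue sites at the percentile threshold.
#'
#' @param s A [cg_structure()].
#' @param r_c,gamma Network parameters, see [build_network()].
#' @param n_orientations,magnitude Force basis parameters, see
#'   [force_basis()].
#' @param schemes Magnitude schemes to scan, subset of `c("FF", "FR")`.
#' @param percentile Classification percentile, see
#'   [classify_rescue_sites()].
#' @param zero_tol Rigid-mode threshold, see [pseudo_inverse()].
#' @return A `dfs_result`: list with `S` (rescuability matrices), `profile`
#'   (classified compensatory-power tibble joined to residue identity),
#'   `network`, `basis` and `config`.
#' @export
dfs <- function(s, r_c = 15, gamma = 1, n_orientations = 12, magnitude = 1,
                schemes = c("FF", "FR"), percentile = 0.28,
                zero_tol = 1e-6) {
  schemes <- match.arg(schemes, c("FF", "FR"), several.ok = TRUE)
  net <- build_network(s, r_c, gamma)
  invH <- pseudo_inverse(net, zero_tol)
  basis <- force_basis(n_orientations, magnitude)
  s_mats <- scan_rescuability(net, basis, schemes, invH = invH)
  profile <- compensatory_power(s_mats, net$degree)
  profile <- classify_rescue_sites(profile, percentile)
  ident <- tibble::tibble(
    key = cg_keys(s), chain = s$chain, resnum = s$resnum,
    icode = s$icode, aa = s$aa
  )
  prof <- dplyr::left_join(ident, profile, by = "key")
  attr(prof, "threshold") <- attr(profile, "threshold")
  structure(
    list(
      S = s_mats, profile = prof, network = net, basis = basis,
      config = list(
        r_c = r_c, gamma = gamma, n_orientations = n_orientations,
        magnitude = magnitude, schemes = schemes, percentile = percentile,
        zero_tol = zero_tol
      )
    ),
    class = "dfs_result"
  )
}

#' @export
print.dfs_result <- function(x, ...) {
  cat(
    "# Double force scan:", nrow(x$profile), "residues,",
    paste(names(x$S), collapse = "+"), "schemes,",
    x$config$n_orientations, "orientations/site\n",
    "# predicted rescue sites:", sum(x$profile$predicted),
    sprintf(
      "(top %d%%, P > %.3f)\n", round(100 * x$config$percentile),
      attr(x$profile, "threshold")
    )
  )
  print(x$profile, ...)
  invisible(x)
}

#' Tidy / summarize a double-force-scan result
#'
#' `tidy()` returns the per-residue compensatory-power profile; `glance()`
#' a one-row run summary.
#'
#' @param x A `dfs_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dfs_result <- function(x, ...) x$profile

#' @rdname tidy.dfs_result
#' @export
glance.dfs_result <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x$profile),
    n_predicted = sum(x$profile$predicted),
    threshold = attr(x$profile, "threshold"),
    percentile = x$config$percentile,
    r_c = x$config$r_c,
    gamma = x$config$gamma,
    n_orientations = x$config$n_orientations,
    schemes = paste(names(x$S), collapse = "+")
  )
}

#' Orientation-count convergence of the rescuability scores
#'
#' Re-scans the structure with an increasing number of force orientations
#' per site and reports, for each consecutive pair of counts and each
#' scheme, the largest absolute change of any S_ij entry. A decreasing
#' drift indicates the orientation sampling has converged.
#'
#' @param s A [cg_structure()].
#' @param n_seq Increasing integer vector of orientation counts
#'   (default 6, 12, 24).
#' @inheritParams dfs
#' @return Tibble with `n_from`, `n_to`, `scheme`, `max_delta_S`.
#' @export
dfs_convergence <- function(s, n_seq = c(6, 12, 24), r_c = 15, gamma = 1,
                            schemes = c("FF", "FR"), zero_tol = 1e-6) {
  schemes <- match.arg(schemes, c("FF", "FR"), several.ok = TRUE)
  net <- build_network(s, r_c, gamma)
  invH <- pseudo_inverse(net, zero_tol)
  scans <- lapply(n_seq, function(n) {
    scan_rescuability(net, force_basis(n), schemes, invH = invH)
  })
  purrr::map_dfr(seq_len(length(n_seq) - 1), function(k) {
    purrr::map_dfr(schemes, function(sch) {
      d <- abs(scans[[k + 1]][[sch]] - scans[[k]][[sch]])
      tibble::tibble(
        n_from = n_seq[k], n_to = n_seq[k + 1], scheme = sch,
        max_delta_S = max(d, na.rm = TRUE)
      )
    })
  })
}
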