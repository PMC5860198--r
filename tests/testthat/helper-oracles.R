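# Independent oracles used across the suite. Everything here is written
# from first principles (explicit loops, generic pseudo-inverse, KKT
# solves) and deliberately shares no code path with the package engine.

# --- hand-assembled ANM hessian (explicit double loop over 3x3 blocks) ---
naive_hessian <- function(coords, r_c, gamma) {
  n <- nrow(coords)
  h <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dv <- coords[j, ] - coords[i, ]
      dist <- sqrt(sum(dv^2))
      if (dist >= r_c) next
      e <- dv / dist
      blk <- -gamma * (e %o% e)
      bi <- (3 * i - 2):(3 * i)
      bj <- (3 * j - 2):(3 * j)
      h[bi, bj] <- blk
      h[bi, bi] <- h[bi, bi] - blk
    }
  }
  h
}

# --- rigid-body basis built analytically from coordinates (3 translations
# + 3 rotations about the centroid), orthonormalized ---
rigid_basis <- function(coords) {
  n <- nrow(coords)
  cen <- colMeans(coords)
  cc <- sweep(coords, 2, cen)
  z <- matrix(0, 3 * n, 6)
  for (ax in 1:3) z[seq(ax, 3 * n, by = 3), ax] <- 1
  cross3 <- function(a, b) {
    c(
      a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1]
    )
  }
  axes <- diag(3)
  for (ax in 1:3) {
    for (i in seq_len(n)) {
      z[(3 * i - 2):(3 * i), 3 + ax] <- cross3(axes[ax, ], cc[i, ])
    }
  }
  qr.Q(qr(z))
}

# --- equality-constrained quadratic solve: minimize 1/2 x'Hx - F'x with
# x orthogonal to the rigid subspace, via the KKT system ---
constrained_response <- function(hess, f, coords) {
  z <- rigid_basis(coords)
  n3 <- nrow(hess)
  kkt <- rbind(
    cbind(hess, z),
    cbind(t(z), matrix(0, 6, 6))
  )
  sol <- solve(kkt, c(f, rep(0, 6)))
  unname(sol[seq_len(n3)])
}

# --- per-residue RMS distance via explicit loop ---
naive_distance <- function(disp) {
  n <- length(disp) / 3
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + sum(disp[(3 * i - 2):(3 * i)]^2)
  }
  sqrt(acc / n)
}

# --- naive DFS scan: generic pseudo-inverse (MASS::ginv), fresh force
# vectors and fresh linear responses per orientation pair, no
# superposition shortcut, no precomputation ---
naive_scan <- function(s, r_c, gamma, orient, scheme) {
  coords <- dfscan::cg_coords(s)
  n <- nrow(coords)
  hess <- naive_hessian(coords, r_c, gamma)
  ginv <- MASS::ginv(hess)
  n_or <- nrow(orient)
  smat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      rho_max <- numeric(n_or)
      for (a in seq_len(n_or)) {
        f_i <- numeric(3 * n)
        f_i[(3 * i - 2):(3 * i)] <- orient[a, ]
        dr_i <- ginv %*% f_i
        d_i <- naive_distance(dr_i)
        rhos <- numeric(n_or)
        for (b in seq_len(n_or)) {
          f_j <- numeric(3 * n)
          f_j[(3 * j - 2):(3 * j)] <- orient[b, ]
          if (scheme == "FR") {
            d_j <- naive_distance(ginv %*% f_j)
            f_j <- f_j * d_i / d_j
          }
          dr_ij <- ginv %*% (f_i + f_j)
          rhos[b] <- (d_i - naive_distance(dr_ij)) / d_i
        }
        rho_max[a] <- max(rhos)
      }
      smat[i, j] <- mean(rho_max)
    }
  }
  smat
}

# --- naive per-residue compensatory power ---
naive_power <- function(s_ff, s_fr, degree) {
  n <- length(degree)
  comp <- function(smat) {
    ratio <- numeric(n)
    for (j in seq_len(n)) {
      cnt <- 0
      for (i in seq_len(n)) {
        if (i != j && !is.na(smat[i, j]) && smat[i, j] > 0) cnt <- cnt + 1
      }
      ratio[j] <- cnt / degree[j]
    }
    if (max(ratio) == min(ratio)) {
      return(rep(0, n))
    }
    (ratio - min(ratio)) / (max(ratio) - min(ratio))
  }
  (comp(s_ff) + comp(s_fr)) / 2
}

# --- brute-force D-minimizing threshold over observed cut points ---
naive_optimal_threshold <- function(score, pos) {
  best <- NULL
  for (t in sort(unique(score))) {
    pred <- score > t
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    d <- (1 - sens)^2 + (1 - spec)^2
    if (is.null(best) || d < best$D - 1e-15 ||
      (abs(d - best$D) <= 1e-15 && sum(pred) < best$n)) {
      best <- list(threshold = t, D = d, n = sum(pred))
    }
  }
  best
}

# --- rotation matrix from axis-angle, for equivariance checks ---
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

block_rotation <- function(rot, n) {
  br <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    idx <- (3 * i - 2):(3 * i)
    br[idx, idx] <- rot
  }
  br
}

# strip class/dimnames/attrs for value-only matrix comparisons
bare_matrix <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}
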