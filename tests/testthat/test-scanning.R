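test_that("structural distance is the per-residue RMS", {
  expect_equal(structural_distance(rep(0, 12)), 0)
  # one residue of four displaced by 1 A
  expect_equal(structural_distance(c(1, rep(0, 11))), 0.5)
  withr::with_seed(2, d <- rnorm(30))
  expect_equal(structural_distance(d), naive_distance(d))
  expect_error(structural_distance(1:4), "multiple of 3")
})

test_that("rescuability reproduces its closed forms and bounds", {
  expect_equal(rescuability(2, 2), 0)
  expect_equal(rescuability(2, 0), 1)
  expect_equal(rescuability(2, 3), -0.5)
  expect_error(rescuability(0, 1), "network defect")
})

test_that("a zero second-site force leaves rho at exactly zero", {
  s <- make_structure("helix", 12)
  op <- pseudo_inverse(build_network(s))
  o <- fibonacci_orientations(4)
  f_i <- assemble_force_vector(12, 3, o[1, ], 1)
  d_i <- structural_distance(op %*% f_i)
  f_j0 <- assemble_force_vector(12, 9, o[2, ], 0)
  d_ij <- structural_distance(op %*% (f_i + f_j0))
  expect_identical(rescuability(d_i, d_ij), 0)
})

test_that("pair score is the degenerate rho for a single orientation", {
  s <- make_structure("tetrahedron")
  net <- build_network(s, r_c = 5)
  op <- pseudo_inverse(net)
  basis <- force_basis(1)
  o <- as.matrix(basis[, c("x", "y", "z")])
  f_i <- assemble_force_vector(4, 1, o[1, ], 1)
  f_j <- assemble_force_vector(4, 3, o[1, ], 1)
  d_i <- structural_distance(op %*% f_i)
  d_ij <- structural_distance(op %*% (f_i + f_j))
  expect_equal(pair_score(op, 1, 3, basis, "FF"), rescuability(d_i, d_ij),
    tolerance = 1e-12
  )
  expect_error(pair_score(op, 2, 2, basis), "i == j")
})

test_that("scan matrices have the right shape and masked diagonal", {
  s <- make_structure("tetrahedron")
  net <- build_network(s, r_c = 5)
  mats <- scan_rescuability(net, force_basis(4))
  expect_named(mats, c("FF", "FR"))
  for (m in mats) {
    expect_equal(dim(m), c(4, 4))
    expect_true(all(is.na(diag(m))))
    expect_equal(sum(!is.na(m)), 12)
    expect_true(all(m[!is.na(m)] <= 1 + 1e-12))
  }
})

test_that("optimized scan equals the naive from-scratch reference", {
  s <- make_structure("helix", 5)
  net <- build_network(s)
  orient <- fibonacci_orientations(4)
  mats <- scan_rescuability(net, force_basis(4))
  for (sch in c("FF", "FR")) {
    expect_equal(bare_matrix(mats[[sch]]), naive_scan(s, 15, 1, orient, sch),
      tolerance = 1e-10
    )
  }
  prof <- compensatory_power(mats, net$degree)
  expect_equal(
    prof$P,
    naive_power(mats$FF, mats$FR, unname(net$degree)),
    tolerance = 1e-10
  )
})

test_that("S is invariant to force magnitude (FF) and to the spring constant", {
  s <- make_structure("helix", 10)
  net1 <- build_network(s, gamma = 1)
  base <- scan_rescuability(net1, force_basis(5, magnitude = 1))
  up <- scan_rescuability(net1, force_basis(5, magnitude = 10))
  dn <- scan_rescuability(net1, force_basis(5, magnitude = 0.1))
  for (sch in c("FF", "FR")) {
    expect_equal(base[[sch]], up[[sch]], tolerance = 1e-10)
    expect_equal(base[[sch]], dn[[sch]], tolerance = 1e-10)
  }
  net_g <- build_network(s, gamma = 3.7)
  scaled <- scan_rescuability(net_g, force_basis(5))
  for (sch in c("FF", "FR")) {
    expect_equal(base[[sch]], scaled[[sch]], tolerance = 1e-10)
  }
})

test_that("scan is equivariant under rigid rotation with a co-rotated basis", {
  s <- make_structure("helix", 8)
  rot <- rotation_matrix(c(-1, 0.4, 2), 1.13)
  cr <- cg_coords(s) %*% t(rot)
  sr <- cg_structure(tibble::tibble(
    chain = "A", resnum = 1:8, icode = "", aa = "ALA",
    x = cr[, 1], y = cr[, 2], z = cr[, 3]
  ))
  orient <- fibonacci_orientations(5)
  m1 <- scan_rescuability(build_network(s), orient)
  m2 <- scan_rescuability(build_network(sr), orient %*% t(rot))
  for (sch in c("FF", "FR")) {
    expect_equal(m1[[sch]], m2[[sch]], tolerance = 1e-8)
  }
})

test_that("an exactly cancelling second force yields rho = 1", {
  s <- make_structure("helix", 10)
  net <- build_network(s)
  op <- pseudo_inverse(net)
  f_i <- assemble_force_vector(10, 4, fibonacci_orientations(3)[1, ], 1)
  dr_i <- op %*% f_i
  d_i <- structural_distance(dr_i)
  # direct construction: F_j whose response is exactly -dr_i
  f_j <- -net$hessian %*% dr_i
  dr_ij <- op %*% (f_i + f_j)
  d_ij <- structural_distance(dr_ij)
  expect_lt(d_ij, 1e-10)
  expect_equal(rescuability(d_i, d_ij), 1, tolerance = 1e-10)
})

test_that("compensatory power reproduces the worked 3-residue example", {
  keys <- c("A:1", "A:2", "A:3")
  mk <- function(cols_pos) {
    m <- matrix(-1, 3, 3, dimnames = list(keys, keys))
    diag(m) <- NA
    for (j in seq_along(cols_pos)) {
      rows <- cols_pos[[j]]
      if (length(rows)) m[rows, j] <- 0.5
    }
    structure(m, class = c("rescuability_matrix", "matrix", "array"), scheme = "FF")
  }
  # counts_FF = [2,1,0], counts_FR = [0,1,1], degrees = [2,1,1]
  s_ff <- mk(list(c(2, 3), 3, integer(0)))
  s_fr <- mk(list(integer(0), 3, 2))
  degree <- setNames(c(2L, 1L, 1L), keys)
  prof <- compensatory_power(list(FF = s_ff, FR = s_fr), degree)
  expect_equal(prof$count_FF, c(2L, 1L, 0L))
  expect_equal(prof$component_FF, c(1, 1, 0))
  expect_equal(prof$component_FR, c(0, 1, 1))
  expect_equal(prof$P, c(0.5, 1.0, 0.5))
})

test_that("flat rescuability signals give an all-zero compensatory power", {
  keys <- c("A:1", "A:2", "A:3")
  m <- matrix(-0.2, 3, 3, dimnames = list(keys, keys))
  diag(m) <- NA
  m <- structure(m, class = c("rescuability_matrix", "matrix", "array"), scheme = "FF")
  prof <- compensatory_power(list(FF = m, FR = m), setNames(c(2L, 2L, 2L), keys))
  expect_equal(prof$P, c(0, 0, 0))
  expect_error(
    compensatory_power(list(FF = m), setNames(c(2L, 0L, 2L), keys)),
    "isolated"
  )
})

test_that("random matrices: engine power equals the naive per-residue loop", {
  withr::with_seed(31, {
    n <- 7
    keys <- paste0("A:", 1:n)
    mk_rand <- function() {
      m <- matrix(runif(n * n, -1, 1), n, n, dimnames = list(keys, keys))
      diag(m) <- NA
      structure(m, class = c("rescuability_matrix", "matrix", "array"), scheme = "FF")
    }
    for (rep in 1:5) {
      s_ff <- mk_rand()
      s_fr <- mk_rand()
      degree <- setNames(sample(1:5, n, replace = TRUE), keys)
      prof <- compensatory_power(list(FF = s_ff, FR = s_fr), degree)
      expect_equal(prof$P, naive_power(s_ff, s_fr, unname(degree)), tolerance = 1e-10)
    }
  })
})

test_that("percentile classification uses a strict threshold", {
  prof <- tibble::tibble(key = paste0("A:", 1:4), P = c(0.9, 0.1, 0.5, 0.3))
  cl <- classify_rescue_sites(prof, 0.25)
  expect_equal(predicted_sites(cl), "A:1")
  # all-equal scores: strict inequality admits nothing
  flat <- tibble::tibble(key = paste0("A:", 1:5), P = rep(0.4, 5))
  expect_equal(predicted_sites(classify_rescue_sites(flat, 0.28)), character(0))
  expect_error(classify_rescue_sites(prof, 1), "percentile")
})

test_that("compensatory motion is the grid argmax and rigid-orthogonal", {
  s <- make_structure("tetrahedron")
  net <- build_network(s, r_c = 5)
  op <- pseudo_inverse(net)
  basis <- force_basis(6)
  orient <- fibonacci_orientations(6)

  # single-orientation basis returns the unique displacement
  b1 <- force_basis(1)
  o1 <- fibonacci_orientations(1)
  f_i <- assemble_force_vector(4, 1, o1[1, ], 1)
  f_j <- assemble_force_vector(4, 2, o1[1, ], 1)
  expect_equal(
    as.vector(compensatory_motion(op, 1, 2, b1, "FF")),
    as.vector(op %*% (f_i + f_j)),
    tolerance = 1e-12
  )

  # engine argmax equals exhaustive grid search
  for (sch in c("FF", "FR")) {
    m <- compensatory_motion(op, 1, 3, basis, sch)
    best <- -Inf
    for (a in 1:6) {
      f_a <- assemble_force_vector(4, 1, orient[a, ], 1)
      d_a <- structural_distance(op %*% f_a)
      for (b in 1:6) {
        f_b <- assemble_force_vector(4, 3, orient[b, ], 1)
        if (sch == "FR") {
          f_b <- f_b * d_a / structural_distance(op %*% f_b)
        }
        r <- rescuability(d_a, structural_distance(op %*% (f_a + f_b)))
        if (r > best) best <- r
      }
    }
    expect_equal(attr(m, "rho"), best, tolerance = 1e-10)
    # in the range of the pseudo-inverse: orthogonal to all rigid modes
    z <- rigid_basis(cg_coords(s))
    expect_lt(max(abs(crossprod(z, as.vector(m)))), 1e-8)
  }
})

test_that("the dfs() pipeline ties the pieces together coherently", {
  s <- make_structure("helix", 12)
  res <- dfs(s, n_orientations = 4)
  prof <- tidy(res)
  expect_equal(nrow(prof), 12)
  expect_true(all(prof$P >= 0 & prof$P <= 1))
  expect_equal(prof$P, (prof$component_FF + prof$component_FR) / 2)
  g <- glance(res)
  expect_equal(g$n_predicted, sum(prof$predicted))
  # single-scheme run: P collapses onto the FF component
  res_ff <- dfs(s, n_orientations = 4, schemes = "FF")
  prof_ff <- tidy(res_ff)
  expect_false("component_FR" %in% names(prof_ff))
  expect_equal(prof_ff$P, prof_ff$component_FF)
})
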