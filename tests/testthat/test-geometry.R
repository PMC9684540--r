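test_that("internal-coordinate construction reproduces ideal helix geometry", {
  tor <- foldsmith:::ideal_helix_torsions(12)
  ch <- torsions_to_coords(tor)
  ca <- ca_coords(ch)
  d <- sqrt(rowSums((ca[-1, ] - ca[-12, ])^2))
  expect_true(all(abs(d - 3.8) < 0.05))
  # extended chain of the same length spans further end to end
  ext <- torsions_to_coords(matrix(180, 12, 3))
  cae <- ca_coords(ext)
  expect_gt(sqrt(sum((cae[12, ] - cae[1, ])^2)),
            sqrt(sum((ca[12, ] - ca[1, ])^2)))
})

test_that("torsions -> coords -> torsions is the identity within 1e-6 degrees", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    tor <- cbind(runif(n, -179, 180), runif(n, -179, 180),
                 runif(n, -179, 180))
    ch <- torsions_to_coords(tor)
    m <- measure_torsions(ch)
    expect_length(m$breaks, 0)
    got <- m$torsions
    expect_lt(max(ang_diff(got[-1, 1], tor[-1, 1])), 1e-6)
    expect_lt(max(ang_diff(got[-n, 2], tor[-n, 2])), 1e-6)
    expect_lt(max(ang_diff(got[-n, 3], tor[-n, 3])), 1e-6)
    # terminal angles are undefined sentinels
    expect_true(is.na(got[1, 1]) && is.na(got[n, 2]) && is.na(got[n, 3]))
  }
  expect_error(torsions_to_coords(matrix(NaN, 5, 3)), "non-finite")
})

test_that("chain breaks are flagged, not silently measured through", {
  ch <- make_fixture("three-helix-bundle", length = 10)$chain
  m <- measure_torsions(ch)
  expect_true(all(c(10, 20) %in% m$breaks))
  expect_true(is.na(m$torsions[10, 2]))
})

test_that("dihedral matches a brute-force projection oracle and handles degeneracy", {
  # independent oracle: angle between plane normals via atan2 in the frame of
  # the central bond, with the IUPAC sign taken from the scalar triple product
  oracle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3], b1[1]*b2[2]-b1[2]*b2[1])
    n2 <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3], b2[1]*b3[2]-b2[2]*b3[1])
    x <- sum(n1 * n2)
    y <- sum(c(n1[2]*n2[3]-n1[3]*n2[2], n1[3]*n2[1]-n1[1]*n2[3],
               n1[1]*n2[2]-n1[2]*n2[1]) * b2) / sqrt(sum(b2^2))
    a <- atan2(y, x) * 180 / pi
    if (a <= -180) a + 360 else a
  }
  set.seed(21)
  for (k in 1:100) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_lt(ang_diff(dihedral(p[1,], p[2,], p[3,], p[4,]),
                       oracle(p[1,], p[2,], p[3,], p[4,])), 1e-9)
  }
  # cis- and trans-planar quadruples
  expect_equal(dihedral(c(1,1,0), c(1,0,0), c(2,0,0), c(2,1,0)), 0)
  expect_equal(abs(dihedral(c(1,1,0), c(1,0,0), c(2,0,0), c(2,-1,0))), 180)
  # collinear central axis is undefined
  expect_true(is.na(dihedral(c(0,0,0), c(1,0,0), c(2,0,0), c(3,0,0))))
})

test_that("superposition finds the rigid-motion optimum", {
  set.seed(31)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(A, A)$rmsd, 0, tolerance = 1e-12)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  B <- A %*% t(R) + matrix(rep(c(3, -1, 2), each = 10), 10)
  expect_lt(superpose_rmsd(A, B)$rmsd, 1e-9)
  expect_equal(det(superpose_rmsd(A, B)$rotation), 1, tolerance = 1e-9)
  # symmetry in the arguments
  C <- A + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(superpose_rmsd(A, C)$rmsd, superpose_rmsd(C, A)$rmsd,
               tolerance = 1e-9)
  expect_error(superpose_rmsd(A, B[1:5, ]), "cardinality")
})

test_that("single-point displacement follows the least-squares law", {
  # displacing one point by d bounds the refit RMSD by d/sqrt(n); the exact
  # optimum (allowing re-translation and re-rotation) is cross-checked
  # against an independent optimiser over rigid transforms
  set.seed(41)
  A <- matrix(rnorm(30, sd = 4), 10, 3)
  d <- 2.5
  B <- A; B[4, ] <- B[4, ] + c(d, 0, 0)
  got <- superpose_rmsd(A, B)$rmsd
  expect_lte(got, d / sqrt(10) + 1e-9)
  rigid_rmsd <- function(par) {
    ang <- par[1:3]
    Rx <- matrix(c(1,0,0, 0,cos(ang[1]),-sin(ang[1]), 0,sin(ang[1]),cos(ang[1])), 3, byrow=TRUE)
    Ry <- matrix(c(cos(ang[2]),0,sin(ang[2]), 0,1,0, -sin(ang[2]),0,cos(ang[2])), 3, byrow=TRUE)
    Rz <- matrix(c(cos(ang[3]),-sin(ang[3]),0, sin(ang[3]),cos(ang[3]),0, 0,0,1), 3, byrow=TRUE)
    Bf <- B %*% t(Rz %*% Ry %*% Rx) + matrix(rep(par[4:6], each = 10), 10)
    sqrt(mean(rowSums((A - Bf)^2)))
  }
  opt <- optim(rep(0, 6), rigid_rmsd, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(got, opt$value, tolerance = 1e-5)
})

test_that("helix bend is near zero for ideal helices and tracks built kinks", {
  ideal <- make_fixture("ideal-helix", length = 16)$chain
  expect_lt(helix_bend(ideal, 1:16), 2)
  k20 <- make_fixture("kinked-helix", length = 16, angle = 20)
  expect_lt(abs(helix_bend(k20$chain, 1:16) - 20), 3)
  k10 <- make_fixture("kinked-helix", length = 16, angle = 10)
  expect_lt(abs(helix_bend(k10$chain, 1:16) - 10), 3)
  # doubling a straight helix does not create bend
  long <- torsions_to_coords(foldsmith:::ideal_helix_torsions(24))
  expect_equal(helix_bend(long, 1:24), helix_bend(long, 1:12), tolerance = 0.5)
  # invariance under rigid motion
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, byrow = TRUE)
  moved <- backbone_chain(sweep(k20$chain$xyz %*% t(R), 2, c(5, 5, 5), "+"))
  expect_equal(helix_bend(moved, 1:16), helix_bend(k20$chain, 1:16),
               tolerance = 1e-6)
  expect_true(is.na(helix_bend(ideal, 1:6)))
})

test_that("clash counting matches a pairwise scan oracle", {
  helix <- make_fixture("ideal-helix", length = 14)$chain
  expect_identical(count_clashes(helix, 2.5), 0L)
  expect_identical(count_clashes(helix, 0), 0L)
  # fold a chain onto itself: two identical helices superposed
  dbl <- backbone_chain(rbind(helix$xyz, helix$xyz))
  expect_gt(count_clashes(dbl, 2.5), 0)
  # oracle comparison on a random decoy
  decoy <- make_fixture("scrambled-decoy", length = 15, seed = 3)$chain
  oracle <- function(xyz, cutoff) {
    cnt <- 0
    for (a in seq_len(nrow(xyz))) for (b in seq_len(nrow(xyz))) {
      if (b <= a) next
      if (((b - 1) %/% 4) - ((a - 1) %/% 4) < 2) next
      if (sqrt(sum((xyz[a, ] - xyz[b, ])^2)) < cutoff) cnt <- cnt + 1
    }
    cnt
  }
  expect_equal(count_clashes(decoy, 3), oracle(decoy$xyz, 3))
})
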