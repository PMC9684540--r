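aligned_helix_pair <- function(len = 12, sep = 10) {
  h <- torsions_to_coords(foldsmith:::ideal_helix_torsions(len))
  ca <- ca_coords(h)
  ax <- foldsmith:::helix_axis(ca)
  z <- c(0, 0, 1)
  v <- c(ax[2]*z[3]-ax[3]*z[2], ax[3]*z[1]-ax[1]*z[3], ax[1]*z[2]-ax[2]*z[1])
  s <- sqrt(sum(v^2)); cth <- sum(ax * z)
  vx <- matrix(c(0,-v[3],v[2], v[3],0,-v[1], -v[2],v[1],0), 3, byrow = TRUE)
  R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  base <- h$xyz %*% t(R)
  zmax <- max(base[seq(2, nrow(base), 4), 3])
  flip <- base %*% diag(c(1, -1, -1))
  flip[, 3] <- flip[, 3] + zmax
  h2 <- sweep(flip, 2, c(sep, 0, 0), "+")
  loop <- sweep(base[(4 * len - 7):(4 * len), ], 2, c(sep / 2, 3, 3), "+")
  backbone_chain(rbind(base, loop, h2),
                 ss = c(rep("H", len), "L", "L", rep("H", len)))
}

hh_fold <- function(len = 12) {
  parse_fold_definition(sprintf("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [%d, %d]}
  - {name: L1, kind: loop, length: [2, 2], abego: [GG]}
  - {name: H2, kind: helix, length: [%d, %d]}
pairings:
  - {type: helix, first: H1, second: H2, orientation: antiparallel}
", len, len, len, len))
}

sheet4_fold <- function() {
  parse_fold_definition("
foldsmith: 1
segments:
  - {name: E1, kind: strand, length: [5, 5]}
  - {name: L1, kind: loop, length: [2, 2], abego: [GG]}
  - {name: E2, kind: strand, length: [5, 5]}
  - {name: L2, kind: loop, length: [2, 2], abego: [GG]}
  - {name: E3, kind: strand, length: [5, 5]}
  - {name: L3, kind: loop, length: [2, 2], abego: [GG]}
  - {name: E4, kind: strand, length: [5, 5]}
sheets:
  - {strands: [E1, E2, E3, E4]}
pairings:
  - {type: strand, first: E1, second: E2, orientation: antiparallel}
  - {type: strand, first: E2, second: E3, orientation: antiparallel}
  - {type: strand, first: E3, second: E4, orientation: antiparallel}
")
}

test_that("helix pair descriptors match their analytic construction", {
  ch <- aligned_helix_pair(12, 10)
  rec <- element_geometry(ch, hh_fold(12), list(H1 = 12, L1 = 2, H2 = 12))
  expect_lt(abs(rec$Hm_d - 10), 0.6)
  expect_lt(abs(rec$H_dih), 2)
  # sheet descriptors are not-applicable sentinels in an all-helix fold
  expect_true(is.na(rec$H1a) && is.na(rec$H2a) && is.na(rec$sheet_dih))
})

test_that("a flat idealised sheet has a 180-degree sheet dihedral", {
  fs <- make_fixture("flat-sheet", n_strands = 4, length = 5)
  lens <- list(E1 = 5, L1 = 2, E2 = 5, L2 = 2, E3 = 5, L3 = 2, E4 = 5)
  rec <- element_geometry(fs$chain, sheet4_fold(), lens)
  expect_equal(abs(rec$sheet_dih), 180, tolerance = 1)
  expect_identical(rec$reg_E1_E2, 0L)
  expect_identical(rec$reg_E2_E3, 0L)
  # helix terms are sentinels here
  expect_true(is.na(rec$Hm_d))
})

test_that("descriptors are invariant under rigid motion", {
  ch <- aligned_helix_pair(12, 10)
  fold <- hh_fold(12)
  lens <- list(H1 = 12, L1 = 2, H2 = 12)
  rec1 <- element_geometry(ch, fold, lens)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  moved <- backbone_chain(sweep(ch$xyz %*% t(R), 2, c(-4, 8, 2), "+"), ss = ch$ss)
  rec2 <- element_geometry(moved, fold, lens)
  num <- vapply(rec1, is.numeric, logical(1))
  for (col in names(rec1)[num])
    expect_equal(rec1[[col]], rec2[[col]], tolerance = 1e-6, info = col)
  # mirroring flips the sign of the dihedral descriptor
  mirrored <- backbone_chain(ch$xyz %*% diag(c(1, 1, -1)), ss = ch$ss)
  rec3 <- element_geometry(mirrored, fold, lens)
  expect_equal(rec3$H_dih, -rec1$H_dih, tolerance = 1e-6)
})

test_that("ensemble correlations equal a brute-force Pearson oracle", {
  set.seed(13)
  n <- 40
  recs <- data.frame(id = as.character(1:n), Hm_d = rnorm(n, 10),
                     H1a = rnorm(n, 30, 5))
  recs$H_dih <- 2 * recs$Hm_d   # exact linear dependence
  m <- ensemble_correlations(recs)
  expect_equal(m["H_dih", "Hm_d"], 1, tolerance = 1e-12)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 1))
  pearson <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (a in colnames(m)) for (b in colnames(m))
    expect_equal(m[a, b], pearson(recs[[a]], recs[[b]]), tolerance = 1e-12)
  # independent features stay near zero
  set.seed(14)
  big <- data.frame(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(ensemble_correlations(big)["x", "y"]), 0.1)
  # zero variance gives NA entries, not an error
  recs$flat <- 1
  m2 <- suppressWarnings(ensemble_correlations(recs))
  expect_true(is.na(m2["flat", "Hm_d"]))
  expect_error(ensemble_correlations(recs[1:2, ]), "at least 3")
})

test_that("combined stability is the minimum over the two proteases", {
  expect_equal(combine_stability(1.2, -0.3), -0.3)
  expect_equal(combine_stability(0.7, 0.7), 0.7)
  expect_equal(combine_stability(0.2, 0.9), combine_stability(0.9, 0.2))
  expect_error(combine_stability(NA, 1), "finite")
})

test_that("success rates use a strict threshold and tabulate score bins", {
  sr <- success_rate(c(0.6, 0.4, 0.51, -1), rep("f1", 4))
  expect_equal(sr$success_rate, 0.5)
  expect_equal(success_rate(rep(0.5, 6), rep("f", 6))$success_rate, 0)
  expect_equal(success_rate(rep(1, 5), rep("f", 5))$success_rate, 1)
  # monotone non-increasing in the threshold
  set.seed(15)
  sc <- rnorm(200)
  rates <- vapply(seq(-1, 1, 0.2), function(th)
    success_rate(sc, rep("f", 200), threshold = th)$success_rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
  # cumulative bins count designs at or above each score
  sr2 <- success_rate(c(-0.5, 0.1, 0.6, 1.4), rep("f1", 4))
  cum <- attr(sr2, "cumulative")
  expect_equal(unname(cum["-1", "f1"]), 4)
  expect_equal(unname(cum["1.5", "f1"]), 0)
  # empty groups surface as NA, and grouping is per fold
  sr3 <- success_rate(c(0.8, 0.2, NA), c("a", "a", "b"))
  expect_equal(sr3$success_rate[sr3$fold == "a"], 0.5)
  expect_true(is.na(sr3$success_rate[sr3$fold == "b"]))
})
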