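# Shared test helpers: angular comparison, synthetic chains with controlled
# CA positions, and small fold definitions built in code.

ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# backbone chain whose CA positions are given exactly; N/C/O placed nearby
# (for filters and descriptors that only read CA geometry)
make_ca_chain <- function(ca, ss = NULL) {
  n <- nrow(ca)
  xyz <- matrix(NA_real_, 4 * n, 3)
  for (i in seq_len(n)) {
    xyz[(i - 1) * 4 + 1, ] <- ca[i, ] + c(-0.6, -1.2, 0.3)
    xyz[(i - 1) * 4 + 2, ] <- ca[i, ]
    xyz[(i - 1) * 4 + 3, ] <- ca[i, ] + c(0.6, 1.2, 0.3)
    xyz[(i - 1) * 4 + 4, ] <- ca[i, ] + c(1.3, 1.2, 1.0)
  }
  backbone_chain(xyz, ss = ss)
}

two_strand_fold <- function(lenrange = c(5, 5), register = 0) {
  parse_fold_definition(sprintf("
foldsmith: 1
name: hairpin
segments:
  - {name: E1, kind: strand, length: [%d, %d]}
  - {name: L1, kind: loop, length: [2, 2], abego: [GG, EA, AA]}
  - {name: E2, kind: strand, length: [%d, %d]}
sheets:
  - {strands: [E1, E2]}
pairings:
  - {type: strand, first: E1, second: E2, orientation: antiparallel, register: %d}
", lenrange[1], lenrange[2], lenrange[1], lenrange[2], register))
}

bbab_fold <- function() {
  parse_fold_definition(system.file("extdata", "folds", "bbab.yml",
                                    package = "foldsmith"))
}

ferredoxin_fold <- function() {
  parse_fold_definition(system.file("extdata", "folds", "ferredoxin.yml",
                                    package = "foldsmith"))
}

threehelix_fold <- function() {
  parse_fold_definition(system.file("extdata", "folds", "threehelix.yml",
                                    package = "foldsmith"))
}

# fast Monte-Carlo limits for tests
test_limits <- function(...) {
  utils::modifyList(list(n_traj = 6L, n_perturb = 15L, n_restarts = 2L,
                         n_moves = 2500L), list(...))
}
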