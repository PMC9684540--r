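test_that("minimal documents parse in both dialects with defaults applied", {
  y <- parse_fold_definition("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [10, 14]}
")
  expect_s3_class(y, "fold_definition")
  expect_length(y$segments, 1)
  expect_length(y$pairings, 0)
  x <- parse_fold_definition(
    '<FoldDefinition schema="foldsmith/1"><Segment name="H1" kind="helix" min="10" max="14"/></FoldDefinition>')
  expect_equal(x$segments[[1]], y$segments[[1]])
})

test_that("constraints default to an 8 Angstrom harmonic with 2 Angstrom SD", {
  fold <- parse_fold_definition("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [10, 12]}
  - {name: L1, kind: loop, length: [2, 3]}
  - {name: E1, kind: strand, length: [4, 6]}
constraints:
  - {a: [H1, midpoint], b: [E1, midpoint]}
")
  cn <- fold$constraints[[1]]
  expect_equal(cn$target, 8)
  expect_equal(cn$sd, 2)
  expect_identical(cn$func, "harmonic")
})

test_that("per-constraint overrides leave the other defaults intact", {
  fold <- parse_fold_definition(system.file("extdata", "folds", "betagrasp.yml",
                                            package = "foldsmith"))
  targets <- vapply(fold$constraints, `[[`, numeric(1), "target")
  expect_true(9 %in% targets)
  expect_true(all(targets[targets != 9] == 8))
  expect_true(all(vapply(fold$constraints, `[[`, numeric(1), "sd") == 2))
})

test_that("schema violations are hard errors naming the offender", {
  expect_error(parse_fold_definition("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [10, 12]}
  - {name: L1, kind: loop, length: [2, 3]}
  - {name: H1, kind: helix, length: [10, 12]}
"), "duplicate.*H1")
  expect_error(parse_fold_definition("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [10, 12]}
pairings:
  - {type: helix, first: H1, second: H9, orientation: parallel}
"), "H9")
  expect_error(parse_fold_definition("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [12, 10]}
"), "length range")
  expect_error(parse_fold_definition("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [10, 12]}
unknown_block: [1]
"), "unknown")
  expect_error(parse_fold_definition("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [10, 12]}
  - {name: H2, kind: helix, length: [10, 12]}
"), "separated by a loop")
})

test_that("parse/serialize/parse is a fixed point", {
  for (f in c("threehelix", "bbab", "ferredoxin", "betagrasp")) {
    fold <- parse_fold_definition(system.file("extdata", "folds",
                                              paste0(f, ".yml"),
                                              package = "foldsmith"))
    txt1 <- serialize_fold_definition(fold)
    fold2 <- parse_fold_definition(txt1)
    expect_identical(serialize_fold_definition(fold2), txt1)
  }
})

test_that("segment anchors resolve by index arithmetic", {
  fold <- parse_fold_definition("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [10, 10]}
  - {name: L1, kind: loop, length: [3, 3]}
  - {name: H2, kind: helix, length: [12, 12]}
")
  lens <- list(H1 = 10, L1 = 3, H2 = 12)
  expect_identical(resolve_segment(fold, lens, "H2", "N-end"), 14L)
  expect_identical(resolve_segment(fold, lens, "H1", "N-end"), 1L)
  expect_identical(resolve_segment(fold, lens, "H1", "midpoint"), 5L)
  expect_identical(resolve_segment(fold, lens, "H2", "C-end"), 25L)
  expect_error(resolve_segment(fold, lens, "H9", "N-end"), "unknown")
  expect_error(resolve_segment(fold, list(H1 = 20, L1 = 3, H2 = 12), "H1", "N-end"),
               "outside")
})

test_that("segment index ranges tile the chain exactly once", {
  fold <- ferredoxin_fold()
  lens <- setNames(lapply(fold$segments, `[[`, "min"),
                   foldsmith:::segment_names(fold))
  ranges <- foldsmith:::segment_ranges(fold, lens)
  covered <- unname(unlist(lapply(ranges, function(r) seq(r[1], r[2]))))
  expect_identical(covered, seq_len(sum(unlist(lens))))
})

test_that("sheet validity requires interior strands to be fully paired", {
  expect_true(validate_sheet(two_strand_fold()))
  # middle strand shorter than its neighbours: outer overhang is fine
  ok <- parse_fold_definition("
foldsmith: 1
segments:
  - {name: E1, kind: strand, length: [5, 5]}
  - {name: L1, kind: loop, length: [2, 2]}
  - {name: E2, kind: strand, length: [3, 3]}
  - {name: L2, kind: loop, length: [2, 2]}
  - {name: E3, kind: strand, length: [5, 5]}
sheets:
  - {strands: [E1, E2, E3]}
pairings:
  - {type: strand, first: E1, second: E2, orientation: antiparallel}
  - {type: strand, first: E2, second: E3, orientation: antiparallel}
")
  expect_true(validate_sheet(ok))
  # middle strand longer than its neighbours can cover: violation names it
  bad <- parse_fold_definition("
foldsmith: 1
segments:
  - {name: E1, kind: strand, length: [3, 3]}
  - {name: L1, kind: loop, length: [2, 2]}
  - {name: E2, kind: strand, length: [7, 7]}
  - {name: L2, kind: loop, length: [2, 2]}
  - {name: E3, kind: strand, length: [3, 3]}
sheets:
  - {strands: [E1, E2, E3]}
pairings:
  - {type: strand, first: E1, second: E2, orientation: antiparallel}
  - {type: strand, first: E2, second: E3, orientation: antiparallel}
")
  v <- validate_sheet(bad)
  expect_false(isTRUE(v))
  expect_true(any(grepl("E2", v)))
  # a strand paired to itself is rejected
  selfp <- parse_fold_definition("
foldsmith: 1
segments:
  - {name: E1, kind: strand, length: [5, 5]}
  - {name: L1, kind: loop, length: [2, 2]}
  - {name: E2, kind: strand, length: [5, 5]}
sheets:
  - {strands: [E1, E2]}
pairings:
  - {type: strand, first: E1, second: E2, orientation: antiparallel}
  - {type: strand, first: E1, second: E1, orientation: antiparallel}
")
  v2 <- validate_sheet(selfp)
  expect_true(any(grepl("itself", v2)))
})

test_that("sheet validity agrees with brute-force coverage over length combos", {
  fold <- parse_fold_definition("
foldsmith: 1
segments:
  - {name: E1, kind: strand, length: [3, 5]}
  - {name: L1, kind: loop, length: [2, 2]}
  - {name: E2, kind: strand, length: [3, 7]}
  - {name: L2, kind: loop, length: [2, 2]}
  - {name: E3, kind: strand, length: [3, 5]}
sheets:
  - {strands: [E1, E2, E3]}
pairings:
  - {type: strand, first: E1, second: E2, orientation: antiparallel}
  - {type: strand, first: E2, second: E3, orientation: antiparallel}
")
  # brute force: enumerate every length combo and check middle-strand coverage
  brute_bad <- list()
  for (l1 in 3:5) for (l2 in 3:7) for (l3 in 3:5) {
    cov <- logical(l2)
    pm1 <- foldsmith:::pairing_partners(l1, l2, "antiparallel", 0)
    pm2 <- foldsmith:::pairing_partners(l2, l3, "antiparallel", 0)
    cov[pm1$b] <- TRUE; cov[pm2$a] <- TRUE
    if (!all(cov)) brute_bad[[length(brute_bad) + 1]] <- c(l1, l2, l3)
  }
  v <- validate_sheet(fold)
  expect_false(isTRUE(v))          # some combos leave E2 uncovered
  expect_gt(length(brute_bad), 0)  # and brute force agrees there are such combos
  # every brute-force-bad combo appears in the violation report
  for (combo in brute_bad) {
    pat <- sprintf("E1=%d E2=%d E3=%d", combo[1], combo[2], combo[3])
    expect_true(any(grepl(pat, v, fixed = TRUE)), info = pat)
  }
})

test_that("bulges shift the register past their position and stay unpaired", {
  pm <- foldsmith:::pairing_partners(6, 5, "antiparallel", 0,
                                     bulges = list(list(segment = "E1", index = 3)),
                                     name_a = "E1", name_b = "E2")
  expect_false(3 %in% pm$a)              # the bulge residue itself is unpaired
  # partner of residue 4 equals what residue 3 would have had without a bulge
  plain <- foldsmith:::pairing_partners(6, 5, "antiparallel", 0)
  expect_identical(pm$b[pm$a == 4], plain$b[plain$a == 3])
})

test_that("register shifts leaving under 2 paired residues are rejected", {
  expect_error(two_strand_fold(c(3, 3), register = 2), "fewer than 2")
})
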