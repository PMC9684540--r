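test_that("the planner reproduces the canonical beta-beta-alpha-beta division", {
  fold <- bbab_fold()
  plan <- plan_divisions(fold)
  new_elems <- lapply(plan$tasks, `[[`, "new_elements")
  expect_identical(new_elems, list(c("E1", "E2"), "H1", "E3"))
  expect_identical(vapply(plan$tasks, `[[`, character(1), "direction"),
                   c("seed", "forward", "forward"))
})

test_that("degenerate and multi-helix folds plan as expected", {
  single <- parse_fold_definition("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [12, 12]}
")
  plan1 <- plan_divisions(single)
  expect_length(plan1$tasks, 1)
  plan3 <- plan_divisions(threehelix_fold())
  expect_identical(lapply(plan3$tasks, `[[`, "new_elements"),
                   list(c("H1", "H2"), "H3"))
  # brute check: the chosen seed window is the smallest pairing-complete one
  fold <- ferredoxin_fold()
  plan <- plan_divisions(fold)
  expect_identical(plan$tasks[[1]]$new_elements, c("E2", "E3"))
  # plan covers every segment exactly once
  segs <- unlist(lapply(plan$tasks, `[[`, "segments"))
  expect_identical(sort(segs), sort(foldsmith:::segment_names(fold)))
  expect_false(anyDuplicated(segs) > 0)
  # determinism
  expect_identical(plan, plan_divisions(fold))
})

test_that("an element pairing nothing in reach is a planning error", {
  fold <- parse_fold_definition("
foldsmith: 1
segments:
  - {name: E1, kind: strand, length: [5, 5]}
  - {name: L1, kind: loop, length: [2, 2]}
  - {name: E2, kind: strand, length: [5, 5]}
  - {name: L2, kind: loop, length: [2, 2]}
  - {name: E3, kind: strand, length: [5, 5]}
  - {name: L3, kind: loop, length: [2, 2]}
  - {name: E4, kind: strand, length: [5, 5]}
pairings:
  - {type: strand, first: E1, second: E2, orientation: antiparallel}
  - {type: strand, first: E3, second: E4, orientation: antiparallel}
")
  expect_error(plan_divisions(fold), "unanchorable")
})

test_that("the perturber resamples one parameter class and respects budgets", {
  fold <- bbab_fold()
  set.seed(3)
  task <- foldsmith:::new_task(fold, c("E1", "L1", "E2"), c("E1", "E2"),
                               "seed", budget = 1000)
  # loop resampling never returns the current menu entry
  menus <- foldsmith:::loop_menu_for(fold, 2)
  t2 <- task
  for (k in 1:30) {
    cur <- t2$params$loop_abegos$L1
    t2 <- perturb_task(t2, fold)
    if (!identical(cur, t2$params$loop_abegos$L1))
      expect_false(identical(t2$params$loop_abegos$L1, cur))
  }
  # a long perturbation walk stays inside the declared ranges
  t3 <- foldsmith:::new_task(fold, c("E1", "L1", "E2"), c("E1", "E2"),
                             "seed", budget = 1000)
  seen <- character(0)
  for (k in 1:1000) {
    prev <- t3$params
    t3 <- perturb_task(t3, fold)
    expect_true(t3$params$lengths$E1 %in% 4:6)
    expect_true(t3$params$lengths$E2 %in% 4:6)
    expect_true(t3$params$loop_abegos$L1 %in% menus)
    expect_true(t3$params$registers[["E1-E2"]] %in% 0:0 ||
                  is.null(t3$params$registers[["E1-E2"]]))
    # never the identical tuple twice in a row
    expect_false(identical(c(prev, reseed = 0), c(t3$params, reseed = 0)) &&
                   t3$reseed == 0)
    seen <- c(seen, t3$params$loop_abegos$L1)
  }
  expect_gt(length(unique(seen)), 1)
  # budget exhaustion is a terminal signal, not an exception
  t4 <- foldsmith:::new_task(fold, c("E1", "L1", "E2"), c("E1", "E2"),
                             "seed", budget = 0)
  expect_s3_class(perturb_task(t4, fold), "task_failure")
})

test_that("an unconstrained helix folds with an all-A interior", {
  fold <- parse_fold_definition("
foldsmith: 1
segments:
  - {name: H1, kind: helix, length: [12, 12]}
")
  res <- build_backbone(fold, seed = 7, limits = test_limits())
  expect_identical(res$status, "success")
  ab <- abego_string(res$chain)
  expect_identical(substr(ab, 2, 11), paste(rep("A", 10), collapse = ""))
})

test_that("a folded hairpin pairs its strands inside the pleated-sheet window", {
  fold <- two_strand_fold(c(5, 5))
  res <- build_backbone(fold, seed = 11, limits = test_limits())
  expect_identical(res$status, "success")
  ca <- ca_coords(res$chain)
  n <- res$total_length
  d <- vapply(1:5, function(i) sqrt(sum((ca[i, ] - ca[n - i + 1, ])^2)),
              numeric(1))
  expect_true(all(d >= 4.2 & d <= 5.7))
})

test_that("builds are reproducible: same fold, seed and limits give identical chains", {
  fold <- two_strand_fold(c(4, 6))
  a <- build_backbone(fold, seed = 5, limits = test_limits())
  b <- build_backbone(fold, seed = 5, limits = test_limits())
  expect_identical(a$status, b$status)
  expect_identical(a$chain$xyz, b$chain$xyz)
  expect_identical(a$lengths, b$lengths)
})

test_that("context coordinates are bit-identical across a subsegment trajectory", {
  fold <- bbab_fold()
  plan <- plan_divisions(fold)
  set.seed(19)
  tk <- plan$tasks[[1]]
  ctx <- NULL
  for (k in 1:20) {
    task <- foldsmith:::new_task(fold, tk$segments, tk$new_elements, "seed", 50)
    r <- foldsmith:::fold_subsegment(task, NULL, fold, test_limits())
    if (r$success) { ctx <- r$context; break }
  }
  expect_false(is.null(ctx))
  before <- ctx$xyz
  tk2 <- plan$tasks[[2]]
  task2 <- foldsmith:::new_task(fold, tk2$segments, tk2$new_elements,
                                tk2$direction, 50,
                                window_segs = union(ctx$segments, tk2$segments))
  r2 <- foldsmith:::fold_subsegment(task2, ctx, fold, test_limits())
  expect_identical(ctx$xyz, before)
  if (r2$success) {
    # context occupies the first rows of the extended window (forward build)
    expect_identical(r2$context$xyz[seq_len(nrow(before)), ], before)
  }
})

test_that("an invalid sheet fails before any Monte Carlo", {
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
  res <- build_backbone(bad, seed = 1)
  expect_identical(res$status, "failed")
  expect_identical(res$reason, "invalid sheet")
  expect_null(res$stats$attempts)
})

test_that("successful builds re-pass the complete filter battery", {
  fold <- threehelix_fold()
  res <- build_backbone(fold, seed = 2, limits = test_limits())
  expect_identical(res$status, "success")
  verdict <- run_filters(res$chain, fold, res$lengths,
                         registers = res$registers)
  expect_true(verdict$pass)
  # all realised parameters are inside their declared ranges
  for (s in fold$segments)
    expect_true(res$lengths[[s$name]] >= s$min && res$lengths[[s$name]] <= s$max)
  expect_true(all(vapply(seq_along(fold$segments), function(i) {
    s <- fold$segments[[i]]
    s$kind != "helix" ||
      helix_bend(res$chain,
                 seq(foldsmith:::segment_ranges(fold, res$lengths)[[s$name]][1],
                     foldsmith:::segment_ranges(fold, res$lengths)[[s$name]][2])) < 15
  }, logical(1))))
})
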