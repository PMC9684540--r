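# Divide-and-conquer build planning plus Monte-Carlo fragment-insertion
# folding of each subsegment.  The planner splits a fold into the smallest
# contiguous subsegments that contain a complete pairing and extends the
# built context one paired element at a time; the perturber permutes the
# mutable parameters of a subsegment (lengths, loop ABEGO, register, torsion
# reseed) whenever the filters reject a build.

# Packaged connector menus: loop ABEGO strings commonly observed between
# helix/strand junctions, keyed by the flanking element kinds.
.loop_menus <- list(
  HH = c("GB", "GG", "BB", "GBB", "BAB", "BAAB", "GBBB"),
  HE = c("GB", "BB", "GBB", "BAB", "GBBA", "BBBB"),
  EH = c("AB", "GB", "BA", "AAB", "BAB", "GBBA"),
  EE = c("GG", "EA", "AA", "AG", "AAG", "GGA", "BAAB")
)

# size-safe scalar draw (sample() would treat a length-1 vector as 1:n)
sample1 <- function(x) x[sample.int(length(x), 1)]

default_build_limits <- function() {
  list(n_moves = 3000L, n_traj = 8L, n_perturb = 30L, n_restarts = 3L,
       t_hi = 10, t_lo = 0.3, clash_cutoff = 2.5, w_clash = 10,
       abort_after = 1200L, abort_score = 25,
       bank_size = 120L, ss_sd_scale = 0.6, max_bend = 15,
       pair_target = 4.9, pair_sd = 0.5, pack_target = 8, pack_sd = 2)
}

loop_menu_for <- function(fold, i) {
  # menu of ABEGO strings for loop segment index i, restricted to its range
  s <- fold$segments[[i]]
  menu <- s$abego
  if (is.null(menu)) {
    kinds <- segment_kinds(fold)
    left <- if (i > 1) kinds[i - 1] else NA
    right <- if (i < length(kinds)) kinds[i + 1] else NA
    key <- paste0(ifelse(left == "helix", "H", "E"), ifelse(right == "helix", "H", "E"))
    menu <- if (!is.na(left) && !is.na(right) && key %in% names(.loop_menus))
      .loop_menus[[key]] else unlist(.loop_menus, use.names = FALSE)
  }
  menu <- menu[nchar(menu) >= s$min & nchar(menu) <= s$max]
  if (!length(menu))
    stop("no loop ABEGO menu entry within the length range of '", s$name,
         "'; provide an explicit abego menu")
  unique(menu)
}

# --- planning ---------------------------------------------------------------

pairing_elements <- function(p) {
  if (p$type == "helix_sheet") c(p$helix, p$strands) else c(p$first, p$second)
}

#' Plan the divide-and-conquer build order of a fold
#'
#' Splits the fold into contiguous subsegments as small as possible that
#' contain a complete pairing: the first task is the smallest window (by
#' minimum residue count, ties broken by document order) spanning a strand or
#' helix pairing; subsequent tasks extend the window by one secondary
#' structure element at a time, always choosing an element that pairs with the
#' already-built context (elements participating in no pairing attach by
#' adjacency).  A fold with no pairings folds as a single task.  Deterministic
#' for a given fold.
#'
#' @param fold a `fold_definition`.
#' @return a `build_plan`: list of tasks, each with `segments` (all covered
#'   segment names, document order), `new_elements` (the secondary-structure
#'   elements this task adds) and `direction` (`seed`, `forward` or
#'   `backward`).
#' @export
plan_divisions <- function(fold) {
  nms <- segment_names(fold)
  kinds <- segment_kinds(fold)
  minlen <- vapply(fold$segments, `[[`, integer(1), "min")
  ss_idx <- which(kinds != "loop")
  prs <- fold$pairings

  if (!length(prs) || length(ss_idx) <= 1) {
    plan <- list(list(segments = nms, new_elements = nms[ss_idx], direction = "seed"))
    return(structure(list(tasks = plan), class = "build_plan"))
  }

  paired_elems <- unique(unlist(lapply(prs, pairing_elements)))
  # seed candidates: contiguous spans of strand/helix pairings
  cands <- list()
  for (p in prs) {
    if (p$type == "helix_sheet") next
    span <- range(match(c(p$first, p$second), nms))
    cands[[length(cands) + 1]] <- span
  }
  if (!length(cands)) stop("fold needs at least one strand or helix pairing to seed a build")
  sizes <- vapply(cands, function(sp) sum(minlen[sp[1]:sp[2]]), numeric(1))
  starts <- vapply(cands, `[[`, numeric(1), 1)
  best <- order(sizes, starts)[1]
  win <- cands[[best]]

  anchored <- function(elem, built) {
    has_pairing <- elem %in% paired_elems
    if (!has_pairing) return(TRUE)  # attach by adjacency
    for (p in prs) {
      if (p$type == "strand" || p$type == "helix") {
        if (p$first == elem && p$second %in% built) return(TRUE)
        if (p$second == elem && p$first %in% built) return(TRUE)
      } else {
        if (p$helix == elem && any(p$strands %in% built)) return(TRUE)
        if (elem %in% p$strands && p$helix %in% built) return(TRUE)
      }
    }
    FALSE
  }

  # attach boundary loops once the window reaches a chain terminus
  with_terminal_loops <- function(lo, hi) {
    while (lo > 1 && kinds[lo - 1] == "loop" &&
           !any(kinds[seq_len(lo - 1)] != "loop")) lo <- lo - 1
    while (hi < length(nms) && kinds[hi + 1] == "loop" &&
           !any(kinds[seq(hi + 1, length(nms))] != "loop")) hi <- hi + 1
    c(lo, hi)
  }

  win <- with_terminal_loops(win[1], win[2])
  tasks <- list(list(segments = nms[win[1]:win[2]],
                     new_elements = nms[intersect(ss_idx, win[1]:win[2])],
                     direction = "seed"))
  built <- tasks[[1]]$new_elements

  repeat {
    left_ss <- rev(ss_idx[ss_idx < win[1]])
    right_ss <- ss_idx[ss_idx > win[2]]
    if (!length(left_ss) && !length(right_ss)) break
    opts <- list()
    if (length(left_ss) && anchored(nms[left_ss[1]], built)) {
      ext <- c(left_ss[1], win[1] - 1)
      opts$left <- list(range = ext, size = sum(minlen[ext[1]:ext[2]]), pos = left_ss[1])
    }
    if (length(right_ss) && anchored(nms[right_ss[1]], built)) {
      ext <- c(win[2] + 1, right_ss[1])
      opts$right <- list(range = ext, size = sum(minlen[ext[1]:ext[2]]), pos = right_ss[1])
    }
    if (!length(opts)) {
      rem <- c(if (length(left_ss)) nms[left_ss[1]], if (length(right_ss)) nms[right_ss[1]])
      stop("unanchorable element(s): ", paste(rem, collapse = ", "),
           " participate in pairings but none connect to the built context")
    }
    pick <- names(opts)[order(vapply(opts, `[[`, numeric(1), "size"),
                              vapply(opts, `[[`, numeric(1), "pos"))][1]
    ext <- opts[[pick]]$range
    newwin <- if (pick == "left") c(ext[1], win[2]) else c(win[1], ext[2])
    newwin <- with_terminal_loops(newwin[1], newwin[2])
    segs_new <- setdiff(nms[newwin[1]:newwin[2]], nms[win[1]:win[2]])
    elem <- nms[opts[[pick]]$pos]
    tasks[[length(tasks) + 1]] <- list(
      segments = segs_new, new_elements = elem,
      direction = if (pick == "left") "backward" else "forward")
    built <- c(built, elem)
    win <- newwin
  }
  structure(list(tasks = tasks), class = "build_plan")
}

#' @export
print.build_plan <- function(x, ...) {
  cat("build_plan with", length(x$tasks), "task(s):\n")
  for (i in seq_along(x$tasks)) {
    t <- x$tasks[[i]]
    cat(sprintf("  %d. [%s] +{%s}  (%s)\n", i, t$direction,
                paste(t$new_elements, collapse = ","),
                paste(t$segments, collapse = " ")))
  }
  invisible(x)
}

# --- parameter handling -----------------------------------------------------

sample_task_params <- function(fold, segs, window_segs = segs) {
  nms <- segment_names(fold)
  lengths <- list(); loops <- list(); registers <- list()
  for (s in fold$segments) {
    if (!(s$name %in% segs)) next
    if (s$kind == "loop") {
      menu <- loop_menu_for(fold, match(s$name, nms))
      ab <- menu[sample.int(length(menu), 1)]
      loops[[s$name]] <- ab
      lengths[[s$name]] <- nchar(ab)
    } else {
      lengths[[s$name]] <- sample1(seq(s$min, s$max))
    }
  }
  # registers are realised by the task that completes the pairing in-window
  for (p in fold$pairings) {
    if (p$type != "strand") next
    if (p$first %in% window_segs && p$second %in% window_segs &&
        (p$first %in% segs || p$second %in% segs)) {
      key <- paste0(p$first, "-", p$second)
      registers[[key]] <- sample1(seq(p$register[1], p$register[2]))
    }
  }
  list(lengths = lengths, loop_abegos = loops, registers = registers)
}

new_task <- function(fold, segments, new_elements, direction, budget,
                     window_segs = segments) {
  params <- sample_task_params(fold, segments, window_segs)
  structure(list(segments = segments, new_elements = new_elements,
                 direction = direction, params = params, budget = budget,
                 rotation = 0L, reseed = 0L),
            class = "subsegment_task")
}

#' Perturb a failed subsegment task
#'
#' Resamples exactly one parameter class uniformly from its allowed set,
#' cycling through the classes in rotation (secondary-structure lengths, then
#' loop ABEGO, then register shift, then torsion reseed); the resample never
#' reproduces the identical parameter tuple.  Decrements the retry budget and
#' signals terminal failure when it is exhausted.
#'
#' @param task a `subsegment_task`.
#' @param fold the `fold_definition`.
#' @param failure optional failure report from [fold_subsegment()] (carried
#'   for diagnostics; not used to bias the resampling).
#' @return the perturbed task, or an object of class `task_failure` when the
#'   budget is exhausted.
#' @export
perturb_task <- function(task, fold, failure = NULL) {
  if (task$budget <= 0)
    return(structure(list(task = task, reason = "retry budget exhausted"),
                     class = "task_failure"))
  nms <- segment_names(fold)
  segs <- task$segments
  ss_new <- Filter(function(s) {
    sg <- get_segment(fold, s)
    sg$kind != "loop" && sg$max > sg$min
  }, task$new_elements)
  loop_segs <- Filter(function(s) {
    i <- match(s, nms)
    fold$segments[[i]]$kind == "loop" && length(loop_menu_for(fold, i)) > 1
  }, segs)
  reg_keys <- Filter(function(k) {
    p <- Find(function(p) p$type == "strand" && paste0(p$first, "-", p$second) == k,
              fold$pairings)
    p$register[2] > p$register[1]
  }, names(task$params$registers))
  classes <- c(if (length(ss_new)) "lengths", if (length(loop_segs)) "loop",
               if (length(reg_keys)) "register", "reseed")
  cls <- classes[(task$rotation %% length(classes)) + 1]
  task$rotation <- task$rotation + 1L
  task$budget <- task$budget - 1L
  if (cls == "lengths") {
    s <- ss_new[[((task$rotation - 1) %/% length(classes)) %% length(ss_new) + 1]]
    sg <- get_segment(fold, s)
    cur <- task$params$lengths[[s]]
    task$params$lengths[[s]] <- sample1(setdiff(seq(sg$min, sg$max), cur))
  } else if (cls == "loop") {
    s <- loop_segs[[((task$rotation - 1) %/% length(classes)) %% length(loop_segs) + 1]]
    menu <- loop_menu_for(fold, match(s, nms))
    cur <- task$params$loop_abegos[[s]]
    pick <- sample1(setdiff(menu, cur))
    task$params$loop_abegos[[s]] <- pick
    task$params$lengths[[s]] <- nchar(pick)
  } else if (cls == "register") {
    k <- reg_keys[[((task$rotation - 1) %/% length(classes)) %% length(reg_keys) + 1]]
    p <- Find(function(p) p$type == "strand" && paste0(p$first, "-", p$second) == k,
              fold$pairings)
    cur <- task$params$registers[[k]]
    task$params$registers[[k]] <- sample1(setdiff(seq(p$register[1], p$register[2]), cur))
  } else {
    task$reseed <- task$reseed + 1L
  }
  task
}

# --- folding ----------------------------------------------------------------

# reduced fold holding only the window's segments (document order preserved)
window_fold <- function(fold, segs) {
  keep <- vapply(fold$segments, function(s) s$name %in% segs, logical(1))
  wsegs <- fold$segments[keep]
  wnames <- vapply(wsegs, `[[`, character(1), "name")
  prs <- Filter(function(p) all(pairing_elements(p) %in% wnames) ||
                  (p$type == "helix_sheet" && p$helix %in% wnames &&
                   any(p$strands %in% wnames)), fold$pairings)
  prs <- lapply(prs, function(p) {
    if (p$type == "helix_sheet") p$strands <- intersect(p$strands, wnames)
    p
  })
  cons <- Filter(function(cn) cn$a$segment %in% wnames && cn$b$segment %in% wnames,
                 fold$constraints)
  structure(list(name = fold$name, segments = wsegs, sheets = list(),
                 pairings = prs, constraints = cons),
            class = "fold_definition")
}

# scoring tables (window-local 1-based residue indices) for the MC objective
mc_tables <- function(wfold, lengths, registers, limits) {
  ranges <- segment_ranges(wfold, lengths)
  mid <- function(r) as.integer(floor((r[1] + r[2]) / 2))
  cons <- matrix(numeric(0), 0, 6)
  for (cn in wfold$constraints) {
    ia <- resolve_segment(wfold, lengths, cn$a$segment, cn$a$anchor)
    ib <- resolve_segment(wfold, lengths, cn$b$segment, cn$b$anchor)
    cons <- rbind(cons, c(ia, ib, cn$target, cn$sd,
                          if (cn$func == "bounded") 1 else 0, cn$width))
  }
  pairs <- matrix(numeric(0), 0, 4)
  for (p in wfold$pairings) {
    if (p$type == "strand") {
      r1 <- ranges[[p$first]]; r2 <- ranges[[p$second]]
      key <- paste0(p$first, "-", p$second)
      reg <- if (key %in% names(registers)) registers[[key]] else p$register[1]
      pm <- pairing_partners(r1[2] - r1[1] + 1, r2[2] - r2[1] + 1,
                             p$orientation, reg, p$bulges, p$first, p$second)
      if (length(pm$a))
        pairs <- rbind(pairs, cbind(r1[1] + pm$a - 1, r2[1] + pm$b - 1,
                                    limits$pair_target, limits$pair_sd))
    } else if (p$type == "helix") {
      r1 <- ranges[[p$first]]; r2 <- ranges[[p$second]]
      ends1 <- c(r1[1], r1[2]); ends2 <- c(r2[1], r2[2])
      if (p$orientation == "antiparallel") ends2 <- rev(ends2)
      pairs <- rbind(pairs,
                     c(mid(r1), mid(r2), limits$pack_target, limits$pack_sd),
                     c(ends1[1], ends2[1], limits$pack_target, limits$pack_sd),
                     c(ends1[2], ends2[2], limits$pack_target, limits$pack_sd))
    } else {
      rh <- ranges[[p$helix]]
      for (s in p$strands) {
        rs <- ranges[[s]]
        pairs <- rbind(pairs, c(mid(rh), mid(rs), limits$pack_target, limits$pack_sd))
      }
    }
  }
  list(cons = cons, pairs = pairs)
}

# per-residue ABEGO letters the fold prescribes (helix A, strand B, loops
# from their realised menu strings)
expected_letters <- function(fold, lengths, loop_abegos) {
  unlist(lapply(fold$segments, function(s) {
    l <- as.integer(lengths[[s$name]])
    if (s$kind == "helix") rep("A", l)
    else if (s$kind == "strand") rep("B", l)
    else strsplit(loop_abegos[[s$name]], "")[[1]]
  }), use.names = FALSE)
}

window_labels <- function(wfold, lengths) {
  ss <- character(0); ab <- character(0)
  for (s in wfold$segments) {
    l <- as.integer(lengths[[s$name]])
    if (s$kind == "helix") { ss <- c(ss, rep("H", l)); ab <- c(ab, rep("A", l)) }
    else if (s$kind == "strand") { ss <- c(ss, rep("E", l)); ab <- c(ab, rep("B", l)) }
    else { ss <- c(ss, rep("L", l)); ab <- c(ab, rep("?", l)) }
  }
  list(ss = ss, abego = ab)
}

#' Fold one subsegment by Metropolis fragment insertion
#'
#' Runs up to `n_traj` annealed Monte-Carlo trajectories of 3-mer
#' torsion-fragment insertions (fragments drawn per position from the ABEGO
#' sampler) over the task's mobile residues, with the context residues frozen.
#' The objective is a clash penalty plus harmonic/bounded distance-constraint
#' penalties plus residue-pairing penalties derived from the fold's pairings.
#' A trajectory succeeds when the extended chain passes the full filter
#' battery (secondary-structure identity, helix kink, constraints, strand
#' pairing with every intended partner pair formed, rama/omega, clash).
#'
#' @param task a `subsegment_task`.
#' @param context `NULL` for the first task, else the `build_context` from the
#'   previous successful task.
#' @param fold the `fold_definition`.
#' @param limits list of Monte-Carlo settings; see `default_build_limits()`.
#' @return list with `success` flag; on success `context` (the extended build
#'   context), `chain`, `reports`; on failure `reports` of the best trajectory.
#' @export
fold_subsegment <- function(task, context, fold, limits = default_build_limits()) {
  limits <- utils::modifyList(default_build_limits(), limits)
  ctx_segs <- if (is.null(context)) character(0) else context$segments
  wsegs <- union(ctx_segs, task$segments)
  nms <- segment_names(fold)
  wsegs <- nms[sort(match(wsegs, nms))]
  wfold <- window_fold(fold, wsegs)
  lengths <- c(if (!is.null(context)) context$lengths,
               task$params$lengths[task$segments])
  registers <- c(if (!is.null(context)) context$registers, task$params$registers)
  registers <- registers[!duplicated(names(registers))]
  n <- sum(unlist(lengths[wsegs]))
  ranges <- segment_ranges(wfold, lengths)

  # mobile letters: helix -> A, strand -> B, loops -> their chosen ABEGO
  letters <- character(n)
  for (s in wfold$segments) {
    r <- ranges[[s$name]]
    letters[r[1]:r[2]] <-
      if (s$kind == "helix") "A"
      else if (s$kind == "strand") "B"
      else strsplit(if (s$name %in% names(task$params$loop_abegos))
                      task$params$loop_abegos[[s$name]]
                    else context$loop_abegos[[s$name]], "")[[1]]
  }
  frozen <- logical(n)
  if (!is.null(context)) {
    for (s in ctx_segs) { r <- ranges[[s]]; frozen[r[1]:r[2]] <- TRUE }
  }
  forward <- task$direction != "backward"
  n_fixed <- sum(frozen)
  fixed_xyz <- if (n_fixed) context$xyz else NULL

  # per-letter torsion banks (SS letters sampled tighter than loop letters)
  mob_letters <- unique(letters[!frozen])
  banks <- lapply(mob_letters, function(L) {
    scale <- if (L %in% c("A", "B")) limits$ss_sd_scale else 1
    sample_torsions_for_abego(L, limits$bank_size, sd_scale = scale)
  })
  names(banks) <- mob_letters
  letter_idx <- ifelse(frozen, -1L, match(letters, mob_letters) - 1L)

  tabs <- mc_tables(wfold, lengths, registers, limits)
  labs <- window_labels(wfold, lengths)

  tor0 <- matrix(180, n, 3)
  if (!is.null(context)) {
    r <- range(which(frozen))
    tor0[r[1]:r[2], ] <- context$torsions
  }

  best_reports <- NULL; best_chain <- NULL; best_score <- Inf; attempts <- 0L
  for (traj in seq_len(limits$n_traj)) {
    attempts <- attempts + 1L
    res <- mc_fold_cpp(tor0, n_fixed, forward, fixed_xyz,
                       as.integer(letter_idx), unname(banks),
                       tabs$cons, tabs$pairs,
                       limits$clash_cutoff, limits$w_clash,
                       as.integer(limits$n_moves), limits$t_hi, limits$t_lo,
                       0.05, 3L, 0.5,
                       as.integer(limits$abort_after), limits$abort_score)
    chain <- backbone_chain(res$xyz, ss = labs$ss, abego = letters)
    verdict <- run_filters(chain, wfold, lengths, registers = registers,
                           max_bend = limits$max_bend,
                           clash_cutoff = limits$clash_cutoff)
    full_pairing <- verdict$reports$strand_pairing$diagnostic >= 1 ||
      is.na(verdict$reports$strand_pairing$diagnostic)
    if (verdict$pass && full_pairing) {
      ctx <- list(segments = wsegs, lengths = lengths, registers = registers,
                  loop_abegos = c(if (!is.null(context)) context$loop_abegos,
                                  task$params$loop_abegos),
                  torsions = res$torsions, xyz = res$xyz)
      return(list(success = TRUE, context = ctx, chain = chain,
                  reports = verdict$reports, score = res$score,
                  trajectories = attempts))
    }
    if (res$score < best_score) {
      best_score <- res$score
      best_reports <- verdict$reports
      best_chain <- chain
    }
  }
  list(success = FALSE, reports = best_reports, score = best_score,
       best_chain = best_chain, trajectories = attempts)
}

#' Build a full backbone from a fold definition
#'
#' Validates the fold's sheets, plans the divide-and-conquer task order and
#' executes each task with a fold/perturb loop: a task whose trajectories all
#' fail the filters has its parameters permuted by [perturb_task()] and is
#' retried until its budget is exhausted.  On success the finished chain
#' passes the complete filter battery.
#'
#' @param fold a `fold_definition`.
#' @param seed integer seed controlling every random choice.
#' @param limits Monte-Carlo and retry settings; any subset of
#'   `default_build_limits()` entries.
#' @return a `build_result` with `status` (`success`/`failed`), `chain`,
#'   realised `lengths`, `registers` and `loop_abegos`, per-filter `reports`
#'   and trajectory statistics.
#' @export
build_backbone <- function(fold, seed = 1, limits = list()) {
  limits <- utils::modifyList(default_build_limits(), limits)
  set.seed(as.integer(seed))
  sheet_ok <- validate_sheet(fold)
  if (!isTRUE(sheet_ok)) {
    return(structure(list(status = "failed", reason = "invalid sheet",
                          violations = sheet_ok, seed = seed),
                     class = "build_result"))
  }
  plan <- plan_divisions(fold)
  stats <- list(attempts = 0L, perturbations = 0L, restarts = 0L)
  last_fail <- NULL
  for (restart in seq_len(max(1L, limits$n_restarts))) {
  context <- NULL
  failed <- FALSE
  for (ti in seq_along(plan$tasks)) {
    tk <- plan$tasks[[ti]]
    wsegs <- union(if (!is.null(context)) context$segments else character(0),
                   tk$segments)
    task <- new_task(fold, tk$segments, tk$new_elements, tk$direction,
                     budget = limits$n_perturb, window_segs = wsegs)
    repeat {
      res <- fold_subsegment(task, context, fold, limits)
      stats$attempts <- stats$attempts + res$trajectories
      if (isTRUE(limits$verbose)) {
        fails <- if (res$success) "ok" else
          paste(names(Filter(function(x) !x$pass, res$reports)), collapse = "+")
        message(sprintf("task %d {%s}: %s score=%.2f traj=%d budget=%d", ti,
                        paste(tk$new_elements, collapse = ","), fails,
                        res$score, res$trajectories, task$budget))
      }
      if (res$success) { context <- res$context; break }
      task <- perturb_task(task, fold, failure = res)
      if (inherits(task, "task_failure")) {
        last_fail <- list(failed_task = ti, task_segments = tk$segments,
                          reports = res$reports, best_partial = context)
        failed <- TRUE
        break
      }
      stats$perturbations <- stats$perturbations + 1L
    }
    if (failed) break
  }
  if (!failed) break
  stats$restarts <- stats$restarts + 1L
  }
  if (failed) {
    return(structure(c(list(status = "failed", stats = stats, seed = seed),
                       last_fail), class = "build_result"))
  }
  # final verification over the complete chain
  lengths <- context$lengths
  labs <- window_labels(fold, lengths)
  chain <- backbone_chain(context$xyz, ss = labs$ss,
                          abego = expected_letters(fold, lengths, context$loop_abegos))
  verdict <- run_filters(chain, fold, lengths, registers = context$registers,
                         max_bend = limits$max_bend,
                         clash_cutoff = limits$clash_cutoff)
  structure(list(status = if (verdict$pass) "success" else "failed",
                 chain = chain, lengths = lengths, registers = context$registers,
                 loop_abegos = context$loop_abegos, reports = verdict$reports,
                 stats = stats, total_length = chain$n, seed = seed),
            class = "build_result")
}

#' @export
print.build_result <- function(x, ...) {
  cat("build_result:", x$status)
  if (!is.null(x$total_length)) cat(",", x$total_length, "residues")
  if (!is.null(x$stats))
    cat(sprintf("  (%d trajectories, %d perturbations)", x$stats$attempts,
                x$stats$perturbations))
  cat("\n")
  invisible(x)
}
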