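# Accept/reject gates applied to each folded subsegment and to finished
# backbones.  Every filter is pure: the same chain and configuration always
# yield the same report.

filter_report <- function(name, pass, diagnostic, detail = NULL, note = NULL) {
  structure(list(name = name, pass = pass, diagnostic = diagnostic,
                 detail = detail, note = note), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] %s  (diagnostic = %s)%s\n", x$name,
              if (x$pass) "PASS" else "FAIL", format(x$diagnostic),
              if (!is.null(x$note)) paste0("  ", x$note) else ""))
  invisible(x)
}

# SS labels implied by the fold for a concrete length assignment
expected_ss <- function(fold, lengths) {
  kinds <- segment_kinds(fold)
  unlist(lapply(seq_along(fold$segments), function(i) {
    l <- as.integer(lengths[[fold$segments[[i]]$name]])
    rep(switch(kinds[i], helix = "H", strand = "E", loop = "L"), l)
  }), use.names = FALSE)
}

#' Secondary-structure identity filter
#'
#' Derives per-residue labels from the measured ABEGO letters (A maps to H,
#' B/E to E, anything else to L) and requires that every helix/strand interior
#' residue (termini of each element, +/- 1 residue, are exempt) matches the
#' fold's prescription.  Loop residues are unconstrained.
#'
#' @param chain a `backbone_chain`.
#' @param fold a `fold_definition`.
#' @param lengths named lengths realising the fold.
#' @param segments optional subset of segment names to evaluate.
#' @return a `filter_report`; diagnostic is the matching fraction over
#'   evaluated interior residues.
#' @export
ss_identity_filter <- function(chain, fold, lengths, segments = NULL) {
  ab <- strsplit(abego_string(chain), "")[[1]]
  derived <- ifelse(ab == "A", "H", ifelse(ab %in% c("B", "E"), "E", "L"))
  want <- expected_ss(fold, lengths)
  ranges <- segment_ranges(fold, lengths)
  eval_segs <- if (is.null(segments)) segment_names(fold) else segments
  checked <- 0L; matched <- 0L; bad <- integer(0)
  for (s in fold$segments) {
    if (s$kind == "loop" || !(s$name %in% eval_segs)) next
    r <- ranges[[s$name]]
    if (r[2] - r[1] < 4) next  # element too short to have an interior
    interior <- seq(r[1] + 2L, r[2] - 2L)
    ok <- derived[interior] == want[interior]
    checked <- checked + length(interior)
    matched <- matched + sum(ok)
    bad <- c(bad, interior[!ok])
  }
  frac <- if (checked) matched / checked else 1
  filter_report("ss_identity", frac == 1, frac, detail = bad)
}

#' Helix kink filter
#'
#' Monitors the curvature of every helix and requires the bend (angle between
#' the local axes of the first and last 4-residue windows) to stay below
#' `max_bend`; the default allows bending of less than 15 degrees.  Helices
#' too short to evaluate pass with a note.
#'
#' @inheritParams ss_identity_filter
#' @param max_bend threshold in degrees.
#' @return a `filter_report`; diagnostic is the worst helix bend.
#' @export
helix_kink_filter <- function(chain, fold, lengths, max_bend = 15, segments = NULL) {
  ranges <- segment_ranges(fold, lengths)
  eval_segs <- if (is.null(segments)) segment_names(fold) else segments
  bends <- c(); note <- NULL
  for (s in fold$segments) {
    if (s$kind != "helix" || !(s$name %in% eval_segs)) next
    b <- helix_bend(chain, ranges[[s$name]])
    if (is.na(b)) note <- paste0(c(note, paste0(s$name, " too short to evaluate")),
                                 collapse = "; ")
    else bends[s$name] <- b
  }
  if (!length(bends))
    return(filter_report("helix_kink", TRUE, NA_real_, note = note %||% "no evaluable helix"))
  filter_report("helix_kink", all(bends < max_bend), max(bends),
                detail = bends, note = note)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Distance-constraint filter
#'
#' Resolves each constraint's named-segment anchors to CA atoms and checks the
#' measured distance: harmonic constraints pass when |d - target| is within
#' `tol_mult` standard deviations; bounded constraints allow an extra
#' flat-bottom half-width on either side.
#'
#' @inheritParams ss_identity_filter
#' @param tol_mult pass tolerance in units of the constraint SD (default 2).
#' @param constraints optional subset (list of constraint specs); defaults to
#'   all constraints of the fold.
#' @return a `filter_report`; diagnostic is the worst violation in SD units.
#' @export
constraint_filter <- function(chain, fold, lengths, tol_mult = 2, constraints = NULL) {
  cons <- constraints %||% fold$constraints
  if (!length(cons)) return(filter_report("constraint", TRUE, 0))
  ca <- ca_coords(chain)
  viols <- vapply(cons, function(cn) {
    ia <- resolve_segment(fold, lengths, cn$a$segment, cn$a$anchor)
    ib <- resolve_segment(fold, lengths, cn$b$segment, cn$b$anchor)
    d <- sqrt(sum((ca[ia, ] - ca[ib, ])^2))
    dev <- abs(d - cn$target)
    if (cn$func == "bounded") dev <- max(0, dev - cn$width)
    dev / cn$sd
  }, numeric(1))
  filter_report("constraint", all(viols <= tol_mult), max(viols), detail = viols)
}

# CA distance window regarded as a formed pleated-sheet pairing
.pair_window <- c(4.2, 5.7)

measure_register <- function(ca1, ca2, orientation, shifts = -6:6) {
  counts <- vapply(shifts, function(r) {
    pm <- pairing_partners(nrow(ca1), nrow(ca2), orientation, r)
    if (!length(pm$a)) return(0L)
    d <- sqrt(rowSums((ca1[pm$a, , drop = FALSE] - ca2[pm$b, , drop = FALSE])^2))
    sum(d >= .pair_window[1] & d <= .pair_window[2])
  }, integer(1))
  shifts[which.max(counts)]
}

#' Strand-pairing filter
#'
#' For every strand pairing, measures the realised register as the shift that
#' maximises the number of partner CA pairs within the pleated-sheet window
#' (4.2-5.7 Angstrom) and compares it with the intended register (after bulge
#' offsets); orientation is checked via the dot product of the two strand
#' direction vectors.
#'
#' @inheritParams ss_identity_filter
#' @param registers named numeric vector of intended registers, one per strand
#'   pairing keyed `first-second`; defaults to each pairing's lower register
#'   bound.
#' @param pairings optional subset of pairing specs.
#' @return a `filter_report`; diagnostic is the smallest fraction of intended
#'   partner pairs inside the distance window across pairings.
#' @export
strand_pairing_filter <- function(chain, fold, lengths, registers = NULL,
                                  pairings = NULL) {
  prs <- Filter(function(p) p$type == "strand", pairings %||% fold$pairings)
  if (!length(prs)) return(filter_report("strand_pairing", TRUE, 1))
  ca <- ca_coords(chain)
  ranges <- segment_ranges(fold, lengths)
  pass <- TRUE; fracs <- c(); detail <- list()
  for (p in prs) {
    key <- paste0(p$first, "-", p$second)
    want_reg <- if (!is.null(registers) && key %in% names(registers))
      as.integer(registers[[key]]) else as.integer(p$register[1])
    r1 <- ranges[[p$first]]; r2 <- ranges[[p$second]]
    ca1 <- ca[seq(r1[1], r1[2]), , drop = FALSE]
    ca2 <- ca[seq(r2[1], r2[2]), , drop = FALSE]
    meas <- measure_register(ca1, ca2, p$orientation)
    d1 <- ca1[nrow(ca1), ] - ca1[1, ]; d2 <- ca2[nrow(ca2), ] - ca2[1, ]
    dt <- sum(d1 * d2)
    orient_ok <- if (p$orientation == "antiparallel") dt < 0 else dt > 0
    pm <- pairing_partners(nrow(ca1), nrow(ca2), p$orientation, want_reg,
                           p$bulges, p$first, p$second)
    d <- sqrt(rowSums((ca1[pm$a, , drop = FALSE] - ca2[pm$b, , drop = FALSE])^2))
    frac <- mean(d >= .pair_window[1] & d <= .pair_window[2])
    fracs[key] <- frac
    detail[[key]] <- list(measured = meas, intended = want_reg,
                          orientation_ok = orient_ok, fraction = frac)
    if (meas != want_reg || !orient_ok) pass <- FALSE
  }
  filter_report("strand_pairing", pass, min(fracs), detail = detail)
}

#' Ramachandran / omega filter
#'
#' Requires every non-terminal omega to be trans within 20 degrees (no
#' unintended cis peptide; residues whose assigned ABEGO letter is `O` are
#' exempt) and every (phi, psi) to lie inside its assigned ABEGO region with
#' at most `margin` degrees of drift beyond the region boundary.
#'
#' @param chain a `backbone_chain`; uses the chain's `abego` assignment when
#'   present, else the measured letters (which then trivially pass).
#' @param margin allowed boundary drift in degrees.
#' @param omega_tol allowed deviation from trans omega in degrees.
#' @return a `filter_report`; diagnostic is the number of offending residues.
#' @export
rama_omega_filter <- function(chain, margin = 5, omega_tol = 20) {
  tor <- measure_torsions(chain)$torsions
  n <- nrow(tor)
  assigned <- chain$abego
  if (is.null(assigned)) {
    assigned <- vapply(seq_len(n), function(i) {
      t <- tor[i, ]
      if (any(!is.finite(t))) "-" else classify_abego(t[1], t[2], t[3])
    }, character(1))
  }
  bad <- integer(0)
  for (i in seq_len(n)) {
    let <- assigned[i]
    omega <- tor[i, 3]
    if (i < n && is.finite(omega) && let != "O" && let != "-") {
      if (180 - abs(omega) > omega_tol) { bad <- c(bad, i); next }
    }
    phi <- tor[i, 1]; psi <- tor[i, 2]
    if (!is.finite(phi) || !is.finite(psi) || let %in% c("O", "-")) next
    ok <- switch(let,
      A = phi < margin && psi >= -75 - margin && psi < 50 + margin,
      B = phi < margin && (psi >= 50 - margin || psi < -75 + margin),
      G = phi >= -margin && psi >= -100 - margin && psi < 100 + margin,
      E = phi >= -margin && (psi >= 100 - margin || psi < -100 + margin),
      TRUE)
    if (!ok) bad <- c(bad, i)
  }
  bad <- unique(bad)
  filter_report("rama_omega", length(bad) == 0, length(bad), detail = bad)
}

#' Run the full filter battery on a realised backbone
#'
#' @inheritParams ss_identity_filter
#' @param registers realised registers (see [strand_pairing_filter()]).
#' @param max_bend helix-kink threshold in degrees.
#' @param clash_cutoff clash distance in Angstrom.
#' @param segments optional subset of segments to evaluate (used on partial
#'   builds); constraints and pairings are restricted to segments in the set.
#' @return list with `pass` (logical) and `reports` (list of `filter_report`).
#' @export
run_filters <- function(chain, fold, lengths, registers = NULL, max_bend = 15,
                        clash_cutoff = 2.5, segments = NULL) {
  segs <- segments %||% segment_names(fold)
  cons <- Filter(function(cn) cn$a$segment %in% segs && cn$b$segment %in% segs,
                 fold$constraints)
  prs <- Filter(function(p) p$type == "strand" && p$first %in% segs && p$second %in% segs,
                fold$pairings)
  nclash <- count_clashes(chain, clash_cutoff)
  reports <- list(
    ss_identity = ss_identity_filter(chain, fold, lengths, segments = segs),
    helix_kink = helix_kink_filter(chain, fold, lengths, max_bend = max_bend,
                                   segments = segs),
    constraint = constraint_filter(chain, fold, lengths, constraints = cons),
    strand_pairing = strand_pairing_filter(chain, fold, lengths,
                                           registers = registers, pairings = prs),
    rama_omega = rama_omega_filter(chain),
    clash = filter_report("clash", nclash == 0, nclash)
  )
  list(pass = all(vapply(reports, `[[`, logical(1), "pass")), reports = reports)
}
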