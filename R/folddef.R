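# Ranged fold definitions: ordered segments with length ranges, loop ABEGO
# menus, element pairings (strand/helix/helix-sheet), sheet declarations and
# ambiguous distance constraints.  Parsed from a YAML or XML document
# (schema "foldsmith/1"); the two forms are equivalent.

.schema_id <- "foldsmith/1"
.default_constraint <- list(target = 8, sd = 2, func = "harmonic", width = 1)

#' Parse a fold definition document
#'
#' Accepts either the YAML or the XML dialect (detected from content: a
#' document starting with `<` is XML).  Defaults are applied on parse:
#' distance constraints default to an 8 Angstrom harmonic target with a loose
#' 2 Angstrom standard deviation (bounded constraints additionally get a
#' 1 Angstrom flat-bottom half-width); strand pairings default to register 0.
#' Unknown document elements are a hard error, never silently skipped.
#'
#' @param document path to a file, or a character string holding the document.
#' @return a `fold_definition` object.
#' @export
parse_fold_definition <- function(document) {
  txt <- document
  if (length(document) == 1 && !grepl("\n", document) && file.exists(document))
    txt <- paste(readLines(document), collapse = "\n")
  txt <- paste(txt, collapse = "\n")
  if (grepl("^\\s*<", txt)) parse_fold_xml(txt) else parse_fold_yaml(txt)
}

parse_fold_yaml <- function(txt) {
  doc <- yaml::yaml.load(txt)
  known <- c("foldsmith", "name", "segments", "sheets", "pairings", "constraints")
  extra <- setdiff(names(doc), known)
  if (length(extra)) stop("unknown fold-definition element(s): ", paste(extra, collapse = ", "))
  if (is.null(doc$foldsmith) || as.character(doc$foldsmith) != "1")
    stop("missing or unsupported schema version (need foldsmith: 1)")
  segs <- lapply(doc$segments, function(s) {
    extra <- setdiff(names(s), c("name", "kind", "length", "abego"))
    if (length(extra)) stop("unknown segment field(s) in '", s$name, "': ",
                            paste(extra, collapse = ", "))
    list(name = as.character(s$name), kind = as.character(s$kind),
         min = as.integer(s$length[[1]]),
         max = as.integer(s$length[[length(s$length)]]),
         abego = if (!is.null(s$abego)) as.character(unlist(s$abego)) else NULL)
  })
  sheets <- lapply(doc$sheets, function(sh) as.character(unlist(sh$strands)))
  pairings <- lapply(doc$pairings, function(p) {
    typ <- as.character(p$type)
    if (typ == "strand") {
      reg <- if (is.null(p$register)) c(0L, 0L) else as.integer(unlist(p$register))
      if (length(reg) == 1) reg <- c(reg, reg)
      bul <- if (is.null(p$bulges)) list() else
        lapply(p$bulges, function(b) list(segment = as.character(b$segment),
                                          index = as.integer(b$index)))
      list(type = "strand", first = as.character(p$first),
           second = as.character(p$second),
           orientation = as.character(p$orientation),
           register = reg, bulges = bul)
    } else if (typ == "helix") {
      list(type = "helix", first = as.character(p$first),
           second = as.character(p$second),
           orientation = as.character(p$orientation))
    } else if (typ == "helix_sheet") {
      list(type = "helix_sheet", helix = as.character(p$helix),
           strands = as.character(unlist(p$strands)))
    } else stop("unknown pairing type: ", typ)
  })
  constraints <- lapply(doc$constraints, function(cn) {
    list(a = list(segment = as.character(cn$a[[1]]), anchor = as.character(cn$a[[2]])),
         b = list(segment = as.character(cn$b[[1]]), anchor = as.character(cn$b[[2]])),
         target = if (is.null(cn$target)) .default_constraint$target else as.numeric(cn$target),
         sd = if (is.null(cn$sd)) .default_constraint$sd else as.numeric(cn$sd),
         func = if (is.null(cn$func)) .default_constraint$func else as.character(cn$func),
         width = if (is.null(cn$width)) .default_constraint$width else as.numeric(cn$width))
  })
  new_fold_definition(if (is.null(doc$name)) "fold" else as.character(doc$name),
                      segs, sheets, pairings, constraints)
}

parse_fold_xml <- function(txt) {
  root <- xml2::xml_root(xml2::read_xml(txt))
  if (xml2::xml_name(root) != "FoldDefinition") stop("root element must be <FoldDefinition>")
  if (!identical(xml2::xml_attr(root, "schema"), .schema_id))
    stop("missing or unsupported schema version (need schema=\"foldsmith/1\")")
  segs <- list(); sheets <- list(); pairings <- list(); constraints <- list()
  for (node in xml2::xml_children(root)) {
    nm <- xml2::xml_name(node)
    at <- function(a) xml2::xml_attr(node, a)
    if (nm == "Segment") {
      ab <- at("abego")
      segs[[length(segs) + 1]] <- list(
        name = at("name"), kind = at("kind"),
        min = as.integer(at("min")), max = as.integer(at("max")),
        abego = if (!is.na(ab)) strsplit(ab, ",")[[1]] else NULL)
    } else if (nm == "Sheet") {
      sheets[[length(sheets) + 1]] <- strsplit(at("strands"), ",")[[1]]
    } else if (nm == "StrandPairing") {
      reg <- at("register")
      reg <- if (is.na(reg)) c(0L, 0L) else as.integer(strsplit(reg, ",")[[1]])
      if (length(reg) == 1) reg <- c(reg, reg)
      bul <- list()
      for (bn in xml2::xml_find_all(node, "Bulge"))
        bul[[length(bul) + 1]] <- list(segment = xml2::xml_attr(bn, "segment"),
                                       index = as.integer(xml2::xml_attr(bn, "index")))
      pairings[[length(pairings) + 1]] <- list(
        type = "strand", first = at("first"), second = at("second"),
        orientation = at("orientation"), register = reg, bulges = bul)
    } else if (nm == "HelixPairing") {
      pairings[[length(pairings) + 1]] <- list(
        type = "helix", first = at("first"), second = at("second"),
        orientation = at("orientation"))
    } else if (nm == "HelixSheetPairing") {
      pairings[[length(pairings) + 1]] <- list(
        type = "helix_sheet", helix = at("helix"),
        strands = strsplit(at("strands"), ",")[[1]])
    } else if (nm == "Constraint") {
      pa <- strsplit(at("a"), ":")[[1]]; pb <- strsplit(at("b"), ":")[[1]]
      constraints[[length(constraints) + 1]] <- list(
        a = list(segment = pa[1], anchor = pa[2]),
        b = list(segment = pb[1], anchor = pb[2]),
        target = if (is.na(at("target"))) .default_constraint$target else as.numeric(at("target")),
        sd = if (is.na(at("sd"))) .default_constraint$sd else as.numeric(at("sd")),
        func = if (is.na(at("func"))) .default_constraint$func else at("func"),
        width = if (is.na(at("width"))) .default_constraint$width else as.numeric(at("width")))
    } else stop("unknown fold-definition element: <", nm, ">")
  }
  nmattr <- xml2::xml_attr(root, "name")
  new_fold_definition(if (is.na(nmattr)) "fold" else nmattr,
                      segs, sheets, pairings, constraints)
}

new_fold_definition <- function(name, segments, sheets, pairings, constraints) {
  nms <- vapply(segments, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate segment name(s): ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  kinds <- vapply(segments, `[[`, character(1), "kind")
  if (!all(kinds %in% c("helix", "strand", "loop")))
    stop("segment kind must be helix, strand or loop")
  for (s in segments) {
    if (is.na(s$min) || is.na(s$max) || s$max < s$min || s$min < 1)
      stop("empty or invalid length range for segment '", s$name, "'")
    if (s$kind == "helix" && s$min < 6)
      stop("helix '", s$name, "' must allow length >= 6")
    if (s$kind == "strand" && s$min < 3)
      stop("strand '", s$name, "' must allow length >= 3")
    if (s$kind == "loop" && !is.null(s$abego)) {
      bad <- nchar(s$abego) < s$min | nchar(s$abego) > s$max
      if (any(bad)) stop("loop '", s$name, "' ABEGO menu entries ",
                         paste(s$abego[bad], collapse = ", "),
                         " fall outside its length range")
    }
    if (s$kind != "loop" && !is.null(s$abego))
      stop("ABEGO menus are only allowed on loop segments ('", s$name, "')")
  }
  # adjacent secondary-structure elements must be separated by a loop
  for (i in seq_along(segments)[-1]) {
    if (kinds[i] != "loop" && kinds[i - 1] != "loop")
      stop("adjacent elements '", nms[i - 1], "' and '", nms[i],
           "' must be separated by a loop")
  }
  kind_of <- setNames(kinds, nms)
  check_ref <- function(ref, what, expect = NULL) {
    if (!ref %in% nms) stop(what, " references unknown segment '", ref, "'")
    if (!is.null(expect) && kind_of[[ref]] != expect)
      stop(what, " requires a ", expect, " but '", ref, "' is a ", kind_of[[ref]])
  }
  for (sh in sheets) for (s in sh) check_ref(s, "sheet", "strand")
  for (p in pairings) {
    if (p$type == "strand") {
      check_ref(p$first, "StrandPairing", "strand")
      check_ref(p$second, "StrandPairing", "strand")
      if (!p$orientation %in% c("parallel", "antiparallel"))
        stop("StrandPairing orientation must be parallel or antiparallel")
      for (b in p$bulges) check_ref(b$segment, "Bulge", "strand")
    } else if (p$type == "helix") {
      check_ref(p$first, "HelixPairing", "helix")
      check_ref(p$second, "HelixPairing", "helix")
    } else {
      check_ref(p$helix, "HelixSheetPairing", "helix")
      for (s in p$strands) check_ref(s, "HelixSheetPairing", "strand")
    }
  }
  for (cn in constraints) {
    check_ref(cn$a$segment, "Constraint"); check_ref(cn$b$segment, "Constraint")
    if (!cn$a$anchor %in% c("N-end", "C-end", "midpoint") ||
        !cn$b$anchor %in% c("N-end", "C-end", "midpoint"))
      stop("constraint anchors must be N-end, C-end or midpoint")
    if (cn$target <= 0 || cn$sd <= 0) stop("constraint target and sd must be > 0")
    if (!cn$func %in% c("harmonic", "bounded"))
      stop("constraint function must be harmonic or bounded")
  }
  # register ranges must leave at least 2 paired residues for every length pair
  for (p in pairings) {
    if (p$type != "strand") next
    s1 <- segments[[match(p$first, nms)]]; s2 <- segments[[match(p$second, nms)]]
    for (r in seq(p$register[1], p$register[2])) {
      npaired <- length(pairing_partners(s1$min, s2$min, p$orientation, r, p$bulges,
                                         p$first, p$second)$a)
      if (npaired < 2)
        stop("StrandPairing ", p$first, "-", p$second, " register ", r,
             " leaves fewer than 2 paired residues at minimum lengths")
    }
  }
  structure(list(name = name, segments = segments, sheets = sheets,
                 pairings = pairings, constraints = constraints),
            class = "fold_definition")
}

#' @export
print.fold_definition <- function(x, ...) {
  cat("fold_definition '", x$name, "': ", length(x$segments), " segments, ",
      length(x$pairings), " pairings, ", length(x$constraints), " constraints\n",
      sep = "")
  for (s in x$segments)
    cat(sprintf("  %-4s %-6s %d-%d%s\n", s$name, s$kind, s$min, s$max,
                if (!is.null(s$abego)) paste0("  [", paste(s$abego, collapse = ","), "]") else ""))
  invisible(x)
}

segment_names <- function(fold) vapply(fold$segments, `[[`, character(1), "name")
segment_kinds <- function(fold) vapply(fold$segments, `[[`, character(1), "kind")

get_segment <- function(fold, name) {
  i <- match(name, segment_names(fold))
  if (is.na(i)) stop("unknown segment '", name, "'")
  fold$segments[[i]]
}

#' Serialise a fold definition to its canonical YAML form
#'
#' `parse_fold_definition(serialize_fold_definition(f))` is a fixed point.
#'
#' @param fold a `fold_definition`.
#' @return a YAML string.
#' @export
serialize_fold_definition <- function(fold) {
  doc <- list(foldsmith = 1L, name = fold$name,
    segments = lapply(fold$segments, function(s) {
      out <- list(name = s$name, kind = s$kind, length = c(s$min, s$max))
      if (!is.null(s$abego)) out$abego <- as.list(s$abego)
      out
    }))
  if (length(fold$sheets))
    doc$sheets <- lapply(fold$sheets, function(sh) list(strands = as.list(sh)))
  if (length(fold$pairings))
    doc$pairings <- lapply(fold$pairings, function(p) {
      if (p$type == "strand") {
        out <- list(type = "strand", first = p$first, second = p$second,
                    orientation = p$orientation, register = as.integer(p$register))
        if (length(p$bulges)) out$bulges <- p$bulges
        out
      } else if (p$type == "helix") p
      else list(type = "helix_sheet", helix = p$helix, strands = as.list(p$strands))
    })
  if (length(fold$constraints))
    doc$constraints <- lapply(fold$constraints, function(cn)
      list(a = list(cn$a$segment, cn$a$anchor), b = list(cn$b$segment, cn$b$anchor),
           target = cn$target, sd = cn$sd, func = cn$func, width = cn$width))
  yaml::as.yaml(doc)
}

# Strand-local pairing map.  Returns the paired index vectors (a in strand 1,
# b in strand 2) for lengths la/lb at the given register shift.  Antiparallel
# register 0 aligns residue 1 of the first strand with the last residue of the
# second; parallel register 0 aligns starts.  A bulge at strand-local index k
# is itself unpaired and shifts the register of all later residues by one.
pairing_partners <- function(la, lb, orientation, register, bulges = list(),
                             name_a = NULL, name_b = NULL) {
  eff <- function(idx, len, seg_name) {
    ks <- vapply(bulges, function(b)
      if (!is.null(seg_name) && identical(b$segment, seg_name))
        as.numeric(b$index) else NA_real_, numeric(1))
    ks <- ks[!is.na(ks)]
    e <- idx
    for (k in ks) e <- ifelse(idx == k, NA_integer_, e - (idx > k))
    e
  }
  ia <- seq_len(la)
  ea <- eff(ia, la, name_a)
  # effective index -> actual index lookup in strand b
  ib_all <- seq_len(lb)
  eb_all <- eff(ib_all, lb, name_b)
  partner_eff <- if (orientation == "antiparallel") {
    max(eb_all, na.rm = TRUE) - ea + 1 - register
  } else {
    ea + register
  }
  ib <- ib_all[match(partner_eff, eb_all)]
  ok <- !is.na(ea) & !is.na(ib)
  list(a = ia[ok], b = ib[ok])
}

#' Validate sheet declarations of a fold
#'
#' A sheet is valid only if, for every combination of strand-length and
#' register choices, the fully built sheet has no unpaired residues on
#' interior strands (edge strands may overhang; declared bulge positions count
#' as intentionally unpaired).  Strands are paired to their spatial neighbours
#' in the declared sheet order.
#'
#' @param fold a `fold_definition`.
#' @return `TRUE` when valid, else a character vector of violations naming the
#'   strand and the offending length/register combination.
#' @export
validate_sheet <- function(fold) {
  violations <- character(0)
  nms <- segment_names(fold)
  for (sh in fold$sheets) {
    if (anyDuplicated(sh)) {
      violations <- c(violations, paste0("sheet lists strand '",
                                         sh[duplicated(sh)][1], "' more than once"))
      next
    }
    # pairing lookup between spatial neighbours
    find_pairing <- function(s1, s2) {
      for (p in fold$pairings)
        if (p$type == "strand" &&
            ((p$first == s1 && p$second == s2) || (p$first == s2 && p$second == s1)))
          return(p)
      NULL
    }
    for (p in fold$pairings)
      if (p$type == "strand" && p$first == p$second)
        violations <- c(violations, paste0("strand '", p$first, "' paired to itself"))
    neigh <- list()
    for (i in seq_along(sh)[-1]) {
      p <- find_pairing(sh[i - 1], sh[i])
      if (is.null(p)) {
        violations <- c(violations, paste0("no pairing declared between sheet neighbours '",
                                           sh[i - 1], "' and '", sh[i], "'"))
      }
      neigh[[i - 1]] <- p
    }
    if (length(violations)) next
    # enumerate length and register combinations (capped cartesian product)
    ranges <- lapply(sh, function(s) { sg <- get_segment(fold, s); seq(sg$min, sg$max) })
    regs <- lapply(neigh, function(p) seq(p$register[1], p$register[2]))
    all_ranges <- c(ranges, regs)
    ncomb <- prod(vapply(all_ranges, length, numeric(1)))
    combos <- if (ncomb <= 20000) {
      as.matrix(expand.grid(all_ranges))
    } else {
      as.matrix(expand.grid(lapply(all_ranges, range)))
    }
    ns <- length(sh)
    for (ci in seq_len(nrow(combos))) {
      lens <- combos[ci, seq_len(ns)]
      rgs <- combos[ci, -seq_len(ns), drop = TRUE]
      covered <- lapply(lens, function(l) logical(l))
      names(covered) <- sh
      for (j in seq_len(ns - 1)) {
        p <- neigh[[j]]
        s1 <- p$first; s2 <- p$second
        pm <- pairing_partners(lens[match(s1, sh)], lens[match(s2, sh)],
                               p$orientation, rgs[j], p$bulges, s1, s2)
        covered[[s1]][pm$a] <- TRUE
        covered[[s2]][pm$b] <- TRUE
      }
      for (p in fold$pairings) if (p$type == "strand")
        for (b in p$bulges) if (b$segment %in% sh && b$index <= lens[match(b$segment, sh)])
          covered[[b$segment]][b$index] <- TRUE
      interior <- sh[-c(1, ns)]
      for (s in interior) {
        if (!all(covered[[s]])) {
          violations <- c(violations, paste0(
            "strand '", s, "' has unpaired residue(s) ",
            paste(which(!covered[[s]]), collapse = ","), " at lengths [",
            paste(sh, lens, sep = "=", collapse = " "), "] registers [",
            paste(rgs, collapse = ","), "]"))
        }
      }
    }
  }
  if (length(violations)) unique(violations) else TRUE
}

#' Resolve a named-segment anchor to a residue index
#'
#' Tracks element residue numbering for a concrete choice of segment lengths:
#' segments are concatenated in document order, and the anchor is resolved to
#' a 1-based index in the resulting chain.  The midpoint is the floor of the
#' arithmetic mean of the segment's first and last residue indices.
#'
#' @param fold a `fold_definition`.
#' @param lengths named integer vector assigning every segment a length within
#'   its range.
#' @param name segment name.
#' @param anchor one of `N-end`, `C-end`, `midpoint`.
#' @return 1-based residue index.
#' @export
resolve_segment <- function(fold, lengths, name, anchor = c("N-end", "C-end", "midpoint")) {
  anchor <- match.arg(anchor)
  nms <- segment_names(fold)
  if (!all(nms %in% names(lengths))) stop("lengths must name every segment")
  for (s in fold$segments) {
    l <- lengths[[s$name]]
    if (l < s$min || l > s$max)
      stop("length ", l, " for segment '", s$name, "' outside its range [",
           s$min, ",", s$max, "]")
  }
  i <- match(name, nms)
  if (is.na(i)) stop("unknown segment '", name, "'")
  start <- if (i == 1) 1L else sum(vapply(nms[seq_len(i - 1)],
                                          function(n) as.integer(lengths[[n]]), integer(1))) + 1L
  end <- start + as.integer(lengths[[name]]) - 1L
  switch(anchor,
         "N-end" = start,
         "C-end" = end,
         "midpoint" = as.integer(floor((start + end) / 2)))
}

# residue index ranges of all segments for a concrete length assignment
segment_ranges <- function(fold, lengths) {
  nms <- segment_names(fold)
  out <- list()
  pos <- 1L
  for (s in fold$segments) {
    l <- as.integer(lengths[[s$name]])
    out[[s$name]] <- c(pos, pos + l - 1L)
    pos <- pos + l
  }
  out
}
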