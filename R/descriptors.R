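# Shape-diversity descriptors of finished designs (inter-element distances,
# helix midpoint distance, helix and sheet dihedrals, opening angles,
# measured registers) and the protease-stability utilities (combined
# stability score, per-fold success rates).

seg_centroid <- function(ca, r) colMeans(ca[seq(r[1], r[2]), , drop = FALSE])

#' Geometric shape descriptors of one design
#'
#' Measures, for a realised fold: pairwise distances between consecutive
#' secondary-structure element centroids; the helix midpoint distance `Hm_d`
#' and helix dihedral `H_dih` (dihedral of H1-start, H1-mid, H2-mid, H2-end
#' axis points) for the first two helices; opening angles `H1a`/`H2a` between
#' each helix axis and the sheet's mean CA plane; the sheet dihedral through
#' the outer-strand end CA centroids (180 degrees = flat sheet); and the
#' measured register shift of every strand pairing.  Descriptor classes
#' absent from the fold (e.g. sheet terms in an all-helix bundle) are `NA`.
#' All values are invariant under rigid motion of the chain.
#'
#' @param chain a `backbone_chain`.
#' @param fold the `fold_definition` it realises.
#' @param lengths named per-segment lengths.
#' @param id design identifier carried into the record.
#' @return one-row data frame (`descriptor_record`).
#' @export
element_geometry <- function(chain, fold, lengths, id = "design") {
  ca <- ca_coords(chain)
  ranges <- segment_ranges(fold, lengths)
  kinds <- segment_kinds(fold)
  nms <- segment_names(fold)
  ss_idx <- which(kinds != "loop")

  rec <- list(id = id, total_length = chain$n)

  # consecutive element centroid distances
  for (k in seq_along(ss_idx)[-1]) {
    a <- nms[ss_idx[k - 1]]; b <- nms[ss_idx[k]]
    d <- sqrt(sum((seg_centroid(ca, ranges[[a]]) - seg_centroid(ca, ranges[[b]]))^2))
    rec[[paste0("d_", a, "_", b)]] <- d
  }

  helices <- nms[ss_idx][kinds[ss_idx] == "helix"]
  strands <- nms[ss_idx][kinds[ss_idx] == "strand"]

  rec$Hm_d <- NA_real_; rec$H_dih <- NA_real_
  if (length(helices) >= 2) {
    r1 <- ranges[[helices[1]]]; r2 <- ranges[[helices[2]]]
    m1 <- seg_centroid(ca, r1); m2 <- seg_centroid(ca, r2)
    rec$Hm_d <- sqrt(sum((m1 - m2)^2))
    # axis points: the first/last CA projected onto the helix axis line
    ax1 <- helix_axis(ca[seq(r1[1], r1[2]), , drop = FALSE])
    ax2 <- helix_axis(ca[seq(r2[1], r2[2]), , drop = FALSE])
    p1 <- m1 + sum((ca[r1[1], ] - m1) * ax1) * ax1
    p2 <- m2 + sum((ca[r2[2], ] - m2) * ax2) * ax2
    rec$H_dih <- dihedral(p1, m1, m2, p2)
  }

  # sheet plane from all sheet-strand CAs; opening angle = angle between a
  # helix axis and the plane (0 = helix parallel to the sheet)
  rec$H1a <- NA_real_; rec$H2a <- NA_real_; rec$sheet_dih <- NA_real_
  sheet <- if (length(fold$sheets)) fold$sheets[[1]] else
    if (length(strands) >= 2) strands else NULL
  if (!is.null(sheet) && length(sheet) >= 2) {
    rows <- unlist(lapply(sheet, function(s) seq(ranges[[s]][1], ranges[[s]][2])))
    pc <- prcomp(ca[rows, , drop = FALSE], center = TRUE)
    normal <- pc$rotation[, 3]
    for (k in seq_len(min(2, length(helices)))) {
      rh <- ranges[[helices[k]]]
      ax <- helix_axis(ca[seq(rh[1], rh[2]), , drop = FALSE])
      elev <- abs(90 - acos(abs(sum(ax * normal))) * 180 / pi)
      rec[[paste0("H", k, "a")]] <- elev
    }
    s1 <- ranges[[sheet[1]]]; sk <- ranges[[sheet[length(sheet)]]]
    end2 <- function(r, head) {
      idx <- if (head) seq(r[1], min(r[1] + 1, r[2])) else seq(max(r[2] - 1, r[1]), r[2])
      colMeans(ca[idx, , drop = FALSE])
    }
    rec$sheet_dih <- dihedral(end2(s1, TRUE), end2(s1, FALSE),
                              end2(sk, FALSE), end2(sk, TRUE))
  }

  for (p in fold$pairings) {
    if (p$type != "strand") next
    r1 <- ranges[[p$first]]; r2 <- ranges[[p$second]]
    reg <- measure_register(ca[seq(r1[1], r1[2]), , drop = FALSE],
                            ca[seq(r2[1], r2[2]), , drop = FALSE], p$orientation)
    rec[[paste0("reg_", p$first, "_", p$second)]] <- reg
  }

  out <- as.data.frame(rec, stringsAsFactors = FALSE)
  class(out) <- c("descriptor_record", class(out))
  out
}

#' Pairwise correlations across an ensemble of descriptor records
#'
#' Pearson correlation matrix over the chosen numeric features, with
#' pairwise-complete handling of `NA` sentinels; zero-variance features give
#' `NA` rows/columns rather than failing.
#'
#' @param records data frame of stacked descriptor records (or any numeric
#'   feature table).
#' @param features character vector of column names; default all numeric
#'   columns except `total_length`-excluded ids.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
ensemble_correlations <- function(records, features = NULL) {
  num <- vapply(records, is.numeric, logical(1))
  if (is.null(features)) features <- names(records)[num & names(records) != "id"]
  if (nrow(records) < 3) stop("need at least 3 records")
  m <- as.matrix(records[, features, drop = FALSE])
  suppressWarnings(cor(m, use = "pairwise.complete.obs"))
}

#' Combine per-protease stability scores
#'
#' The combined stability score of a design is the minimum of its trypsin and
#' chymotrypsin scores: resistance to one protease cannot compensate for
#' cleavage by the other (a high trypsin score with a negative chymotrypsin
#' score still indicates an unfolded protein).
#'
#' @param trypsin,chymotrypsin numeric scores (vectorised).
#' @return elementwise minimum.
#' @export
combine_stability <- function(trypsin, chymotrypsin) {
  if (any(!is.finite(trypsin)) || any(!is.finite(chymotrypsin)))
    stop("stability scores must be finite")
  pmin(trypsin, chymotrypsin)
}

#' Per-fold design success rates
#'
#' The success rate of a fold is the fraction of its designs with combined
#' stability score strictly greater than `threshold` (default 0.5).  Also
#' tabulates, per fold, the cumulative number of designs at or above a ladder
#' of score bins.
#'
#' @param scores numeric combined stability scores.
#' @param folds fold label per design.
#' @param threshold success cutoff (strict inequality).
#' @param bins score bin edges for the cumulative counts.
#' @return data frame with `fold`, `n`, `n_success`, `success_rate` (empty
#'   folds give `NA`), with the cumulative count table in attribute
#'   `cumulative`.
#' @export
success_rate <- function(scores, folds, threshold = 0.5,
                         bins = seq(-1, 2, by = 0.25)) {
  stopifnot(length(scores) == length(folds))
  folds <- as.character(folds)
  levels <- unique(folds)
  out <- do.call(rbind, lapply(levels, function(f) {
    s <- scores[folds == f & !is.na(scores)]
    data.frame(fold = f, n = length(s), n_success = sum(s > threshold),
               success_rate = if (length(s)) sum(s > threshold) / length(s)
                              else NA_real_,
               stringsAsFactors = FALSE)
  }))
  cum <- vapply(levels, function(f) {
    s <- scores[folds == f & !is.na(scores)]
    vapply(bins, function(b) sum(s >= b), numeric(1))
  }, numeric(length(bins)))
  cum <- matrix(cum, nrow = length(bins),
                dimnames = list(as.character(bins), levels))
  attr(out, "cumulative") <- cum
  out
}
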