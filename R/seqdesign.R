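# Simplified two-protocol sequence design: solvent-exposure layer assignment
# from a backbone-only burial proxy, then palette-constrained residue
# assignment, optionally seeded with interacting residue pair-motifs in the
# core.  No rotamer packing or all-atom scoring: the palettes and motifs
# capture the combinatorial layer of the protocol.

.layer_palettes <- list(
  core     = c("A", "I", "L", "M", "F", "V", "W"),
  boundary = c("A", "I", "L", "V", "M", "S", "T", "N", "Q", "Y", "E", "K"),
  surface  = c("D", "E", "K", "R", "N", "Q", "S", "T", "H")
)
.hydrophobic <- c("A", "I", "L", "M", "F", "V", "W", "Y", "C")
.ncap_palette <- c("S", "T", "N", "D")

# virtual CB at the ideal tetrahedral position from N/CA/C (standard
# backbone-frame construction)
pseudo_cb <- function(chain) {
  n <- chain$n
  xyz <- chain$xyz
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    N <- xyz[(i - 1) * 4 + 1, ]; CA <- xyz[(i - 1) * 4 + 2, ]; C <- xyz[(i - 1) * 4 + 3, ]
    b <- CA - N; c <- C - CA
    a <- c(b[2] * c[3] - b[3] * c[2], b[3] * c[1] - b[1] * c[3], b[1] * c[2] - b[2] * c[1])
    cb[i, ] <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * c + CA
  }
  cb
}

#' Assign burial layers from backbone geometry
#'
#' Burial of residue i is the number of other CA atoms lying within
#' `radius` Angstrom of CA(i) and inside a cone (half-angle `cone_deg`)
#' around the CA-to-pseudo-CB direction (the side-chain pointing direction).
#' Residues with burial of at least `core_min` are core, at most `surf_max`
#' surface, anything between boundary.
#'
#' @param chain a `backbone_chain`.
#' @param core_min,surf_max burial thresholds (defaults 5 and 2).
#' @param radius cone depth in Angstrom.
#' @param cone_deg cone half-angle in degrees.
#' @return list with `layer` (character vector) and `burial` (integer vector).
#' @export
assign_layers <- function(chain, core_min = 5, surf_max = 2, radius = 8,
                          cone_deg = 100) {
  ca <- ca_coords(chain)
  cb <- pseudo_cb(chain)
  n <- chain$n
  burial <- integer(n)
  cosmin <- cos(cone_deg * pi / 180)
  for (i in seq_len(n)) {
    dir <- cb[i, ] - ca[i, ]
    dir <- dir / sqrt(sum(dir^2))
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      v <- ca[j, ] - ca[i, ]
      d <- sqrt(sum(v^2))
      if (d > radius || d < 1e-9) next
      if (sum(v * dir) / d >= cosmin) burial[i] <- burial[i] + 1L
    }
  }
  layer <- ifelse(burial >= core_min, "core",
                  ifelse(burial <= surf_max, "surface", "boundary"))
  list(layer = layer, burial = burial)
}

#' Read a pair-motif table
#'
#' Delimited text with columns `res_a res_b dmin dmax orientation`; the
#' packaged toy table (hydrophobic-pair biased) stands in for a
#' crystal-structure-derived motif database and uses the same format.
#'
#' @param path file path; default the packaged table.
#' @return data frame of motifs (stored symmetrically: (a,b) equals (b,a)).
#' @export
read_motif_table <- function(path = system.file("extdata", "pair_motifs.tsv",
                                                package = "foldsmith")) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("res_a", "res_b", "dmin", "dmax", "orientation")
  if (!all(need %in% names(tab))) stop("motif table needs columns: ",
                                       paste(need, collapse = " "))
  tab
}

#' Seed core positions with pair motifs
#'
#' Greedily walks unassigned core position pairs in order of increasing
#' pseudo-CB distance and, whenever a motif's distance window contains the
#' pair's CB-CB distance, assigns the motif's two residue types (orientation
#' drawn at random among eligible motifs).  Each position is assigned at most
#' once.  Deterministic under the R RNG seed.
#'
#' @param chain a `backbone_chain`.
#' @param layers output of [assign_layers()].
#' @param motif_table data frame from [read_motif_table()] (may be empty).
#' @return named character vector of seeded residues (names = positions);
#'   empty when nothing can be seeded.
#' @export
seed_pair_motifs <- function(chain, layers, motif_table = read_motif_table()) {
  core <- which(layers$layer == "core")
  out <- character(0)
  if (length(core) < 2 || !nrow(motif_table)) return(out)
  cb <- pseudo_cb(chain)
  prs <- t(utils::combn(core, 2))
  d <- sqrt(rowSums((cb[prs[, 1], , drop = FALSE] - cb[prs[, 2], , drop = FALSE])^2))
  ord <- order(d, prs[, 1], prs[, 2])
  assigned <- integer(0)
  for (k in ord) {
    i <- prs[k, 1]; j <- prs[k, 2]
    if (i %in% assigned || j %in% assigned) next
    hits <- which(motif_table$dmin <= d[k] & motif_table$dmax >= d[k])
    if (!length(hits)) next
    m <- motif_table[sample1(hits), ]
    flip <- sample1(c(TRUE, FALSE))
    out[as.character(i)] <- if (flip) m$res_b else m$res_a
    out[as.character(j)] <- if (flip) m$res_a else m$res_b
    assigned <- c(assigned, i, j)
  }
  out
}

#' Design an amino-acid sequence onto a backbone
#'
#' `plain` draws every position from its burial layer's palette; `motif`
#' first seeds core position pairs from the pair-motif table, then fills the
#' rest from palettes.  Helix N-cap positions prefer capping residues
#' (S/T/N/D) and loop residues in positive-phi ABEGO bins (G/E) are assigned
#' glycine, following the loop-rule menus.
#'
#' @param chain a `backbone_chain` (uses `ss`/`abego` labels when present).
#' @param protocol `plain` or `motif`.
#' @param motif_table motif data frame (motif protocol only).
#' @param layers optional precomputed [assign_layers()] result.
#' @return list with `sequence` (string), `layers`, and `seeded` positions.
#' @export
design_sequence <- function(chain, protocol = c("plain", "motif"),
                            motif_table = read_motif_table(), layers = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(layers)) layers <- assign_layers(chain)
  n <- chain$n
  seq_out <- character(n)
  seeded <- character(0)
  if (protocol == "motif") {
    seeded <- seed_pair_motifs(chain, layers, motif_table)
    if (length(seeded)) seq_out[as.integer(names(seeded))] <- seeded
  }
  ss <- chain$ss %||% rep("L", n)
  ab <- chain$abego %||% rep("-", n)
  for (i in seq_len(n)) {
    if (nzchar(seq_out[i])) next
    if (ss[i] == "L" && ab[i] %in% c("G", "E")) {
      seq_out[i] <- "G"  # positive-phi loop bins strongly prefer glycine
    } else if (ss[i] == "H" && (i == 1 || ss[i - 1] != "H")) {
      seq_out[i] <- sample1(.ncap_palette)
    } else {
      seq_out[i] <- sample1(.layer_palettes[[layers$layer[i]]])
    }
  }
  list(sequence = paste(seq_out, collapse = ""), layers = layers,
       seeded = seeded)
}
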