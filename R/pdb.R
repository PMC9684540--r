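# PDB backbone I/O.  Parsing and serialisation are delegated to bio3d; this
# layer validates completeness (every residue needs N, CA, C and O), selects
# the highest-occupancy altloc, and converts to/from `backbone_chain`.

#' Read a backbone chain from a PDB file
#'
#' Reads ATOM records, keeps the highest-occupancy alternate location per
#' atom, and requires every residue to carry complete N/CA/C/O backbone
#' coordinates; residues with missing backbone atoms are rejected with a
#' message naming them.
#'
#' @param path PDB file path.
#' @param chain_id chain identifier to read (default: first chain in file).
#' @return a `backbone_chain` with a `sequence` attribute when residue names
#'   are informative.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("malformed PDB '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  ch <- at$chain[1]
  at <- at[at$chain %in% ch, , drop = FALSE]
  # highest-occupancy altloc per atom slot
  at <- at[order(at$resno, at$elety, -replace(at$o, is.na(at$o), 1)), , drop = FALSE]
  at <- at[!duplicated(at[, c("resno", "elety")]), , drop = FALSE]
  resnos <- sort(unique(at$resno))
  need <- c("N", "CA", "C", "O")
  xyz <- matrix(NA_real_, 4 * length(resnos), 3)
  aa3 <- character(length(resnos))
  for (k in seq_along(resnos)) {
    rows <- at[at$resno == resnos[k], , drop = FALSE]
    for (j in seq_along(need)) {
      hit <- which(rows$elety == need[j])
      if (!length(hit))
        stop("residue ", resnos[k], " is missing backbone atom ", need[j])
      xyz[(k - 1) * 4 + j, ] <- as.numeric(rows[hit[1], c("x", "y", "z")])
    }
    aa3[k] <- rows$resid[1]
  }
  chain <- backbone_chain(xyz)
  attr(chain, "sequence") <- paste(vapply(aa3, function(a) {
    out <- bio3d::aa321(a)
    if (is.na(out) || !nzchar(out)) "X" else out
  }, character(1)), collapse = "")
  chain
}

#' Write a backbone chain to a PDB file
#'
#' Chain id `A`; residues are written as glycine unless a designed sequence
#' is supplied.  A write/read cycle preserves coordinates to the fixed-width
#' PDB precision (1e-3 Angstrom).
#'
#' @param chain a `backbone_chain`.
#' @param path output path.
#' @param sequence optional one-letter amino-acid sequence of length n.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(chain, path, sequence = NULL) {
  n <- chain$n
  if (is.null(sequence)) sequence <- strsplit(paste(rep("G", n), collapse = ""), "")[[1]]
  else {
    sequence <- strsplit(paste(sequence, collapse = ""), "")[[1]]
    stopifnot(length(sequence) == n)
  }
  aa3 <- vapply(sequence, function(a) {
    out <- bio3d::aa123(a)
    if (is.na(out)) "GLY" else out
  }, character(1))
  atom_names <- rep(c("N", "CA", "C", "O"), n)
  resno <- rep(seq_len(n), each = 4)
  bio3d::write.pdb(file = path, xyz = as.vector(t(chain$xyz)),
                   type = rep("ATOM", 4 * n), resno = resno,
                   resid = rep(aa3, each = 4), elety = atom_names,
                   chain = rep("A", 4 * n), o = rep(1, 4 * n),
                   b = rep(0, 4 * n))
  invisible(path)
}
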