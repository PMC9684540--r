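# Five-letter ABEGO torsion alphabet: A (alpha region), B (beta region),
# E and G (positive-phi regions), O (cis omega).  The five regions partition
# the full (phi, psi, omega) torus.

.abego_centers <- list(
  A = c(-63, -42, 180), B = c(-135, 135, 180),
  E = c(75, 170, 180),  G = c(75, -10, 180),
  O = c(-75, 160, 0)
)
.abego_sd <- c(A = 10, B = 20, E = 20, G = 20, O = 20)

#' Classify backbone torsions into the ABEGO alphabet
#'
#' `O` iff |omega| < 90 (cis peptide).  Otherwise for phi < 0: `A` when psi is
#' in [-75, 50), else `B`; for phi >= 0: `G` when psi is in [-100, 100), else
#' `E`.  Angles are reduced modulo 360 into (-180, 180] first, so the function
#' is total on finite inputs.  Vectorised over its arguments.
#'
#' @param phi,psi,omega torsions in degrees.
#' @return character vector of letters in `A,B,E,G,O`.
#' @export
classify_abego <- function(phi, psi, omega) {
  if (any(!is.finite(phi) | !is.finite(psi) | !is.finite(omega)))
    stop("non-finite torsion angle")
  wrap <- function(x) {
    x <- x %% 360
    ifelse(x > 180, x - 360, x)
  }
  phi <- wrap(phi); psi <- wrap(psi); omega <- wrap(omega)
  out <- ifelse(abs(omega) < 90, "O",
         ifelse(phi < 0,
                ifelse(psi >= -75 & psi < 50, "A", "B"),
                ifelse(psi >= -100 & psi < 100, "G", "E")))
  out
}

#' ABEGO string of a chain
#'
#' One letter per residue; terminal residues whose torsions are undefined
#' (and residues flanking chain breaks) are emitted as `-`.
#'
#' @param chain a `backbone_chain`.
#' @return a single string of length n.
#' @export
abego_string <- function(chain) {
  tor <- measure_torsions(chain)$torsions
  letters_out <- vapply(seq_len(nrow(tor)), function(i) {
    t <- tor[i, ]
    if (any(!is.finite(t))) "-" else classify_abego(t[1], t[2], t[3])
  }, character(1))
  paste(letters_out, collapse = "")
}

#' Sample torsions for an ABEGO letter
#'
#' Draws (phi, psi, omega) from a Gaussian around the letter's canonical
#' centre (A: -63/-42, B: -135/135, E: 75/170, G: 75/-10; omega trans 180 with
#' SD 3, cis 0 for O), rejection-sampled so the draw always classifies back to
#' the requested letter.  Uses R's global RNG stream; seed with `set.seed()`.
#'
#' @param letter one of `A,B,E,G,O`.
#' @param n number of draws.
#' @param sd_scale multiplier on the per-letter torsion SDs (default regions:
#'   10 degrees for A, 20 for B/E/G/O).
#' @return n x 3 matrix of (phi, psi, omega) in degrees.
#' @export
sample_torsions_for_abego <- function(letter, n = 1, sd_scale = 1) {
  stopifnot(length(letter) == 1, letter %in% names(.abego_centers))
  ctr <- .abego_centers[[letter]]
  s <- .abego_sd[[letter]] * sd_scale
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  wrap <- function(x) {
    x <- x %% 360
    ifelse(x > 180, x - 360, x)
  }
  for (i in seq_len(n)) {
    repeat {
      phi <- wrap(rnorm(1, ctr[1], s))
      psi <- wrap(rnorm(1, ctr[2], s))
      omega <- wrap(rnorm(1, ctr[3], 3))
      if (classify_abego(phi, psi, omega) == letter) break
    }
    out[i, ] <- c(phi, psi, omega)
  }
  out
}

#' Read a torsion fragment file
#'
#' Optional replacement for analytic ABEGO sampling: fragments harvested from
#' real structures, one block per fragment.  Format: a header line
#' `#abego <string>`, then one `phi psi omega` triple per residue.
#'
#' @param path file path.
#' @return list of fragments, each a list with `abego` (string) and
#'   `torsions` (len x 3 matrix).
#' @export
read_fragment_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frags <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "#abego ")) stop("expected '#abego' header at line ", i)
    ab <- trimws(sub("^#abego ", "", lines[i]))
    len <- nchar(ab)
    if (i + len > length(lines)) stop("truncated fragment '", ab, "'")
    tor <- t(vapply(lines[(i + 1):(i + len)],
                    function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3]),
                    numeric(3)))
    dimnames(tor) <- list(NULL, c("phi", "psi", "omega"))
    if (any(!is.finite(tor))) stop("malformed torsion row in fragment '", ab, "'")
    frags[[length(frags) + 1]] <- list(abego = ab, torsions = tor)
    i <- i + len + 1
  }
  frags
}
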