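#' @useDynLib foldsmith, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor prcomp rnorm runif sd setNames predict
#' @importFrom utils head read.table write.csv
NULL

# Ideal backbone geometry shared with the compiled builder (Engh-Huber-style).
.ideal_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7
)

#' Construct a backbone chain object
#'
#' A `backbone_chain` holds per-residue N/CA/C/O coordinates (Angstrom), the
#' backbone torsions phi/psi/omega (degrees), and optional per-residue
#' secondary-structure (`H`/`E`/`L`) and ABEGO labels.  Torsions at chain
#' termini that are geometrically undefined (phi of the first residue, psi and
#' omega of the last) are `NA` sentinels.
#'
#' @param xyz numeric matrix, 4*n x 3; atom rows ordered N, CA, C, O per residue.
#' @param torsions numeric matrix, n x 3 (phi, psi, omega in degrees), or NULL
#'   to measure them from `xyz`.
#' @param ss optional per-residue secondary structure labels (`H`, `E`, `L`).
#' @param abego optional per-residue ABEGO letters.
#' @return an object of class `backbone_chain`.
#' @export
backbone_chain <- function(xyz, torsions = NULL, ss = NULL, abego = NULL) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, nrow(xyz) %% 4 == 0)
  n <- nrow(xyz) / 4
  if (is.null(torsions)) torsions <- measure_torsions_xyz(xyz)
  stopifnot(nrow(torsions) == n)
  colnames(torsions) <- c("phi", "psi", "omega")
  if (!is.null(ss)) stopifnot(length(ss) == n, all(ss %in% c("H", "E", "L")))
  structure(list(xyz = xyz, torsions = torsions, ss = ss, abego = abego, n = n),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat("backbone_chain:", x$n, "residues\n")
  if (!is.null(x$ss)) cat("  ss:    ", paste(x$ss, collapse = ""), "\n")
  if (!is.null(x$abego)) cat("  abego: ", paste(x$abego, collapse = ""), "\n")
  invisible(x)
}

#' @export
length.backbone_chain <- function(x) x$n

#' CA coordinates of a chain
#' @param chain a `backbone_chain`.
#' @return n x 3 matrix of CA positions.
#' @export
ca_coords <- function(chain) {
  chain$xyz[seq(2, nrow(chain$xyz), by = 4), , drop = FALSE]
}

atom_rows <- function(i, atom = c(1, 2, 3, 4)) {
  # rows of residues i for the given atom slots (1=N, 2=CA, 3=C, 4=O)
  as.vector(outer(atom, (i - 1) * 4, "+"))
}

#' Build backbone coordinates from torsions
#'
#' Sequential internal-coordinate (NeRF) construction with ideal bond lengths
#' and angles; the first residue is placed in a fixed canonical frame.  The
#' carbonyl O of residue i is placed in the C(i) plane trans to N(i+1) (a
#' virtual trans next-N for the terminal residue).
#'
#' @param torsions n x 3 matrix (or data frame) of (phi, psi, omega) in
#'   degrees, n >= 2.  phi of residue 1 and psi/omega of residue n may be `NA`.
#' @param ss,abego optional per-residue labels carried onto the chain.
#' @return a `backbone_chain`.
#' @export
torsions_to_coords <- function(torsions, ss = NULL, abego = NULL) {
  torsions <- as.matrix(torsions)
  if (nrow(torsions) < 2) stop("need at least 2 residues")
  interior <- torsions
  interior[1, 1] <- 0  # placeholder, unused by the builder
  used <- c(interior[-1, 1], interior[-nrow(interior), 2:3])
  if (any(!is.finite(used))) stop("non-finite torsion angle")
  if (any(used <= -180 | used > 180)) stop("torsions must lie in (-180, 180]")
  xyz <- build_chain_cpp(interior, 0L, TRUE, NULL)
  tor <- torsions
  tor[1, 1] <- NA_real_
  tor[nrow(tor), 2:3] <- NA_real_
  backbone_chain(xyz, tor, ss = ss, abego = abego)
}

measure_torsions_xyz <- function(xyz) {
  n <- nrow(xyz) / 4
  N <- xyz[seq(1, 4 * n, 4), , drop = FALSE]
  CA <- xyz[seq(2, 4 * n, 4), , drop = FALSE]
  C <- xyz[seq(3, 4 * n, 4), , drop = FALSE]
  tor <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  for (i in seq_len(n)) {
    if (i > 1) tor[i, 1] <- dihedral(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < n) {
      tor[i, 2] <- dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
      tor[i, 3] <- dihedral(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ])
    }
  }
  tor
}

#' Measure backbone torsions from coordinates
#'
#' Standard IUPAC convention: phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) =
#' N(i)-CA(i)-C(i)-N(i+1), omega(i) = CA(i)-C(i)-N(i+1)-CA(i+1).  Undefined
#' terminal angles are returned as `NA`.  Residues followed by a chain break
#' (C-N distance >= 2 A) are flagged, and their psi/omega set to `NA`.
#'
#' @param chain a `backbone_chain`.
#' @return list with `torsions` (n x 3 matrix, degrees) and `breaks`
#'   (integer indices i where the i -> i+1 peptide bond is broken).
#' @export
measure_torsions <- function(chain) {
  xyz <- chain$xyz
  n <- chain$n
  tor <- measure_torsions_xyz(xyz)
  breaks <- integer(0)
  for (i in seq_len(n - 1)) {
    d <- sqrt(sum((xyz[(i - 1) * 4 + 3, ] - xyz[i * 4 + 1, ])^2))
    if (!is.finite(d) || d >= 2.0) {
      breaks <- c(breaks, i)
      tor[i, 2:3] <- NA_real_
      tor[i + 1, 1] <- NA_real_
    }
  }
  list(torsions = tor, breaks = breaks)
}

#' Signed dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees in (-180, 180]; `NA` when the central axis or an
#'   outer bond is degenerate (collinear points).
#' @export
dihedral <- function(p1, p2, p3, p4) {
  dihedral_cpp(as.numeric(p1), as.numeric(p2), as.numeric(p3), as.numeric(p4))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of `B` onto
#' `A` and returns the minimised RMSD.
#'
#' @param A,B point matrices (n x 3), equal n >= 3.
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3, det +1) and
#'   `translation` such that `B %*% t(rotation) + translation` superposes on A.
#' @export
superpose_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("point sets must have equal cardinality")
  if (nrow(A) < 3) stop("need at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bfit)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.numeric(ca - cb %*% t(R)))
}

# Local helix axis from a window of >= 4 CA positions: for each consecutive
# CA quadruple, the cross product of successive second differences of the
# CA trace points along the axis (the second differences are centripetal);
# estimates are averaged and oriented N->C.
helix_axis <- function(ca) {
  n <- nrow(ca)
  if (n < 4) return(NULL)
  acc <- c(0, 0, 0)
  for (i in seq_len(n - 3)) {
    v1 <- ca[i + 1, ] - ca[i, ]
    v2 <- ca[i + 2, ] - ca[i + 1, ]
    v3 <- ca[i + 3, ] - ca[i + 2, ]
    w1 <- v2 - v1
    w2 <- v3 - v2
    ax <- c(w1[2] * w2[3] - w1[3] * w2[2],
            w1[3] * w2[1] - w1[1] * w2[3],
            w1[1] * w2[2] - w1[2] * w2[1])
    nrm <- sqrt(sum(ax^2))
    if (nrm < 1e-9) next
    ax <- ax / nrm
    if (sum(ax * (ca[n, ] - ca[1, ])) < 0) ax <- -ax
    acc <- acc + ax
  }
  nrm <- sqrt(sum(acc^2))
  if (nrm < 1e-9) {
    v <- ca[n, ] - ca[1, ]
    return(v / sqrt(sum(v^2)))
  }
  acc / nrm
}

#' Helix bend angle
#'
#' Angle between local helix axes fitted to the first and last 4-residue
#' windows of the range (axes via least-squares through sliding CA centroids).
#' 0 degrees means a straight helix.
#'
#' @param chain a `backbone_chain`.
#' @param range integer residue indices (inclusive) of the helix.
#' @return bend in degrees, or `NA` if the range is shorter than 8 residues.
#' @export
helix_bend <- function(chain, range) {
  idx <- seq(min(range), max(range))
  if (length(idx) < 8) return(NA_real_)
  ca <- ca_coords(chain)[idx, , drop = FALSE]
  a1 <- helix_axis(ca[1:4, , drop = FALSE])
  a2 <- helix_axis(ca[(nrow(ca) - 3):nrow(ca), , drop = FALSE])
  cosang <- max(-1, min(1, sum(a1 * a2)))
  acos(cosang) * 180 / pi
}

#' Count backbone heavy-atom clashes
#'
#' Number of backbone (N, CA, C, O) atom pairs from residues at least 2 apart
#' in sequence that lie closer than `cutoff`.
#'
#' @param chain a `backbone_chain`.
#' @param cutoff distance threshold in Angstrom (> 0 to count anything).
#' @return integer clash count.
#' @export
count_clashes <- function(chain, cutoff = 2.5) {
  if (cutoff <= 0) return(0L)
  clash_count_cpp(chain$xyz, cutoff, 2L)
}
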