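# Synthetic test fixtures with known ground truth: ideal and kinked helices,
# strands, a geometrically calibrated beta-hairpin, rigid-placement bundles
# and sheets, and scrambled decoys.  Generation is deterministic for a given
# seed, and every fixture carries the parameters it was built from.

# Hairpin torsions calibrated (deterministic least-squares fit at package
# development time) so that antiparallel register-0 partners sit inside the
# pleated-sheet CA window for strand lengths 4-6: per-strand (phi, psi) plus
# a two-residue positive-phi (GG) turn.
.hairpin_torsions <- list(
  strand1 = c(-134.711, 137.204),
  strand2 = c(-114.215, 140.672),
  turn = matrix(c(79.95, 36.122, 89.889, 32.857), 2, 2, byrow = TRUE)
)

ideal_helix_torsions <- function(n) {
  matrix(rep(c(-57, -47, 180), n), ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("phi", "psi", "omega")))
}

#' Build a synthetic test fixture
#'
#' Available kinds:
#' \describe{
#'   \item{ideal-helix}{straight alpha helix of `length` residues.}
#'   \item{kinked-helix}{helix with a mid-chain psi perturbation calibrated
#'     by bisection so the measured [helix_bend()] matches `angle` within
#'     0.5 degrees.}
#'   \item{ideal-strand}{extended beta strand.}
#'   \item{hairpin}{two antiparallel strands of `length` residues joined by a
#'     calibrated two-residue turn; passes [strand_pairing_filter()] at its
#'     ground-truth register 0.}
#'   \item{three-helix-bundle}{three ideal helices rigidly placed on a
#'     triangle with `separation` Angstrom between axes (a synthetic
#'     placement fixture: the two junctions are not covalently closed).}
#'   \item{flat-sheet}{`n_strands` idealised strands on a planar lattice
#'     (synthetic placement fixture).}
#'   \item{scrambled-decoy}{chain with uniformly random torsions; fails
#'     [rama_omega_filter()].}
#' }
#'
#' @param kind fixture kind (see above).
#' @param length residues per element (helix/strand/hairpin-strand); default
#'   12 for helices/strands, 16 for the kinked helix, 5 for hairpin and sheet
#'   strands.
#' @param angle requested kink angle in degrees (kinked-helix; must be < 90).
#' @param separation axis separation in Angstrom (bundle).
#' @param n_strands strand count (flat-sheet).
#' @param seed RNG seed (scrambled-decoy only; other kinds are analytic).
#' @return list with `chain` (a `backbone_chain`) and `truth` (the ground
#'   truth parameters of the construction).
#' @export
make_fixture <- function(kind = c("ideal-helix", "kinked-helix", "ideal-strand",
                                  "hairpin", "three-helix-bundle", "flat-sheet",
                                  "scrambled-decoy"),
                         length = NULL, angle = 20, separation = 10,
                         n_strands = 4, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(length))
    length <- switch(kind, "hairpin" = 5, "flat-sheet" = 5,
                     "kinked-helix" = 16, 12)
  switch(kind,
    "ideal-helix" = {
      chain <- torsions_to_coords(ideal_helix_torsions(length),
                                  ss = rep("H", length))
      list(chain = chain, truth = list(kind = kind, length = length, bend = 0))
    },
    "kinked-helix" = fixture_kinked_helix(length, angle),
    "ideal-strand" = {
      tor <- matrix(rep(c(-135, 135, 180), length), ncol = 3, byrow = TRUE)
      chain <- torsions_to_coords(tor, ss = rep("E", length))
      list(chain = chain, truth = list(kind = kind, length = length))
    },
    "hairpin" = fixture_hairpin(length),
    "three-helix-bundle" = fixture_bundle(length, separation),
    "flat-sheet" = fixture_flat_sheet(n_strands, length),
    "scrambled-decoy" = fixture_decoy(length, seed)
  )
}

fixture_kinked_helix <- function(length, angle) {
  if (length < 12) stop("kinked helix needs at least 12 residues")
  if (angle <= 0 || angle >= 90) stop("kink angle must be in (0, 90) degrees")
  mid <- ceiling(length / 2)
  bend_for <- function(delta) {
    tor <- ideal_helix_torsions(length)
    tor[mid, 2] <- -47 - delta
    helix_bend(torsions_to_coords(tor), seq_len(length))
  }
  lo <- 0; hi <- 120
  for (it in 1:60) {
    mid_d <- (lo + hi) / 2
    if (bend_for(mid_d) < angle) lo <- mid_d else hi <- mid_d
  }
  delta <- (lo + hi) / 2
  tor <- ideal_helix_torsions(length)
  tor[mid, 2] <- -47 - delta
  chain <- torsions_to_coords(tor, ss = rep("H", length))
  list(chain = chain,
       truth = list(kind = "kinked-helix", length = length, angle = angle,
                    delta_psi = delta, measured = helix_bend(chain, seq_len(length))))
}

fixture_hairpin <- function(length) {
  if (length < 3 || length > 6)
    stop("hairpin fixture supports strand lengths 3-6")
  hp <- .hairpin_torsions
  tor <- rbind(
    matrix(rep(c(hp$strand1, 180), length), ncol = 3, byrow = TRUE),
    cbind(hp$turn, c(180, 180)),
    matrix(rep(c(hp$strand2, 180), length), ncol = 3, byrow = TRUE))
  ss <- c(rep("E", length), "L", "L", rep("E", length))
  chain <- torsions_to_coords(tor, ss = ss)
  chain$abego <- c(rep("B", length), "G", "G", rep("B", length))
  list(chain = chain,
       truth = list(kind = "hairpin", strand_length = length, register = 0L,
                    orientation = "antiparallel",
                    strand1 = c(1, length), strand2 = c(length + 3, 2 * length + 2)))
}

rigid_copy <- function(xyz, flip, translate) {
  out <- xyz
  if (flip) {  # 180-degree rotation about the z axis, then reverse sense
    out[, 1] <- -out[, 1]
    out[, 2] <- -out[, 2]
  }
  sweep(out, 2, translate, "+")
}

fixture_bundle <- function(length, separation) {
  one <- torsions_to_coords(ideal_helix_torsions(length))
  ax <- helix_axis(ca_coords(one))
  # rotate so the helix axis lies along z, then place three copies on a triangle
  z <- c(0, 0, 1)
  v <- c(ax[2] * z[3] - ax[3] * z[2], ax[3] * z[1] - ax[1] * z[3],
         ax[1] * z[2] - ax[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(ax * z)
  R <- if (s < 1e-9) diag(3) else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  base <- one$xyz %*% t(R)
  offs <- rbind(c(0, 0, 0), c(separation, 0, 0),
                c(separation / 2, separation * sqrt(3) / 2, 0))
  xyz <- rbind(rigid_copy(base, FALSE, offs[1, ]),
               rigid_copy(base, TRUE, offs[2, ]),
               rigid_copy(base, FALSE, offs[3, ]))
  chain <- backbone_chain(xyz, ss = rep("H", 3 * length))
  list(chain = chain,
       truth = list(kind = "three-helix-bundle", length = length,
                    separation = separation,
                    helices = list(c(1, length), c(length + 1, 2 * length),
                                   c(2 * length + 1, 3 * length))))
}

fixture_flat_sheet <- function(n_strands, length) {
  res_at <- function(ca, dir) rbind(
    ca + c(-0.6, -1.2 * dir, 0.4),  # N
    ca,                              # CA
    ca + c(0.6, 1.2 * dir, 0.4),     # C
    ca + c(1.4, 1.1 * dir, 1.2))     # O
  rows <- list(); ss <- character(0); strands <- list()
  pos <- 0L
  for (s in seq_len(n_strands)) {
    x <- (s - 1) * 4.8
    dir <- if (s %% 2 == 1) 1 else -1
    ys <- if (dir == 1) seq(0, by = 3.45, length.out = length) else
      seq((length - 1) * 3.45, by = -3.45, length.out = length)
    strands[[s]] <- c(pos + 1L, pos + length)
    for (i in seq_len(length)) {
      rows[[length(rows) + 1]] <- res_at(c(x, ys[i], 0), dir)
      ss <- c(ss, "E"); pos <- pos + 1L
    }
    if (s < n_strands) {  # two turn residues bridging to the next strand
      ytop <- ys[length]
      for (k in 1:2) {
        rows[[length(rows) + 1]] <- res_at(c(x + 4.8 * (k - 0.5) / 2,
                                             ytop + 2.2 * dir, 1.5), dir)
        ss <- c(ss, "L"); pos <- pos + 1L
      }
    }
  }
  xyz <- do.call(rbind, rows)
  chain <- backbone_chain(xyz, ss = ss)
  list(chain = chain,
       truth = list(kind = "flat-sheet", n_strands = n_strands,
                    length = length, strands = strands, loop_length = 2))
}

fixture_decoy <- function(length, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  tor <- matrix(runif(length * 3, -179.999, 180), ncol = 3)
  chain <- torsions_to_coords(tor, ss = rep("L", length))
  chain$abego <- rep("A", length)  # deliberately mislabelled: a decoy
  list(chain = chain, truth = list(kind = "scrambled-decoy", length = length,
                                   seed = seed))
}
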