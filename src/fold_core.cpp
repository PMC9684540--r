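#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ideal backbone bond geometry (Engh-Huber-style values).
static const double B_N_CA = 1.458;
static const double B_CA_C = 1.525;
static const double B_C_N  = 1.329;
static const double B_C_O  = 1.231;
static const double A_N_CA_C = 111.2;   // angle at CA
static const double A_CA_C_N = 116.2;   // angle at C
static const double A_C_N_CA = 121.7;   // angle at N
static const double A_CA_C_O = 120.8;

static const double DEG = M_PI / 180.0;

struct V3 { double x, y, z; };

static inline V3 sub(const V3 &a, const V3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline V3 add(const V3 &a, const V3 &b) { return {a.x+b.x, a.y+b.y, a.z+b.z}; }
static inline V3 scale(const V3 &a, double s)  { return {a.x*s, a.y*s, a.z*s}; }
static inline double dot(const V3 &a, const V3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3 &a) { double n = norm(a); return {a.x/n, a.y/n, a.z/n}; }
static inline double dist(const V3 &a, const V3 &b) { return norm(sub(a, b)); }

// NeRF placement: position D such that |C-D| = bond, angle(B,C,D) = theta and
// dihedral(A,B,C,D) = chi (degrees, IUPAC sign; chi = 0 is cis).
static V3 place_atom(const V3 &A, const V3 &B, const V3 &C,
                     double bond, double theta_deg, double chi_deg) {
  double theta = theta_deg * DEG, chi = chi_deg * DEG;
  V3 b1 = unit(sub(B, A));
  V3 b2 = unit(sub(C, B));
  V3 n  = unit(cross(b1, b2));
  V3 m  = cross(n, b2);
  double dx = -bond * std::cos(theta);
  double dy =  bond * std::sin(theta) * std::cos(chi);
  double dz =  bond * std::sin(theta) * std::sin(chi);
  V3 D = C;
  D = add(D, scale(b2, dx));
  D = add(D, scale(m,  dy));
  D = add(D, scale(n,  dz));
  return D;
}

// Chain coordinate layout: 4 atoms per residue, rows 4*i .. 4*i+3 = N, CA, C, O.
static inline V3 getv(const NumericMatrix &m, int row) {
  return {m(row, 0), m(row, 1), m(row, 2)};
}
static inline void setv(NumericMatrix &m, int row, const V3 &v) {
  m(row, 0) = v.x; m(row, 1) = v.y; m(row, 2) = v.z;
}

// Carbonyl O of residue i, placed trans to the (possibly virtual) next N.
static void place_O(NumericMatrix &xyz, int i, const V3 &nextN) {
  V3 CA = getv(xyz, 4*i + 1), C = getv(xyz, 4*i + 2);
  setv(xyz, 4*i + 3, place_atom(nextN, CA, C, B_C_O, A_CA_C_O, 180.0));
}

// Build residues [from, n) forward.  Residue `from` must have N/CA/C already
// set if from > 0; for from == 0 the first residue is placed in the canonical
// frame (N at origin, CA on +x, C in the xy-plane).
static void build_forward(NumericMatrix &xyz, const NumericMatrix &tor, int from) {
  int n = tor.nrow();
  if (from == 0) {
    setv(xyz, 0, {0.0, 0.0, 0.0});
    setv(xyz, 1, {B_N_CA, 0.0, 0.0});
    double th = A_N_CA_C * DEG;
    setv(xyz, 2, {B_N_CA - B_CA_C * std::cos(th), B_CA_C * std::sin(th), 0.0});
    from = 1;
  }
  for (int i = from; i < n; i++) {
    V3 Np = getv(xyz, 4*(i-1)), CAp = getv(xyz, 4*(i-1)+1), Cp = getv(xyz, 4*(i-1)+2);
    double psi = tor(i-1, 1), omg = tor(i-1, 2), phi = tor(i, 0);
    V3 Ni  = place_atom(Np, CAp, Cp, B_C_N, A_CA_C_N, psi);
    V3 CAi = place_atom(CAp, Cp, Ni, B_N_CA, A_C_N_CA, omg);
    V3 Ci  = place_atom(Cp, Ni, CAi, B_CA_C, A_N_CA_C, phi);
    setv(xyz, 4*i, Ni); setv(xyz, 4*i + 1, CAi); setv(xyz, 4*i + 2, Ci);
    place_O(xyz, i - 1, Ni);
  }
  // Terminal O from a virtual next N (psi falls back to trans when undefined).
  double psiL = tor(n-1, 1);
  if (!std::isfinite(psiL)) psiL = 180.0;
  V3 Nv = place_atom(getv(xyz, 4*(n-1)), getv(xyz, 4*(n-1)+1), getv(xyz, 4*(n-1)+2),
                     B_C_N, A_CA_C_N, psiL);
  place_O(xyz, n - 1, Nv);
}

// Build residues [0, upto) backward from residue `upto`, whose N/CA/C must be set.
static void build_backward(NumericMatrix &xyz, const NumericMatrix &tor, int upto) {
  for (int i = upto - 1; i >= 0; i--) {
    V3 Nn = getv(xyz, 4*(i+1)), CAn = getv(xyz, 4*(i+1)+1), Cn = getv(xyz, 4*(i+1)+2);
    double phi_n = tor(i+1, 0), omg = tor(i, 2), psi = tor(i, 1);
    V3 Ci  = place_atom(Cn, CAn, Nn, B_C_N, A_C_N_CA, phi_n);
    V3 CAi = place_atom(CAn, Nn, Ci, B_CA_C, A_CA_C_N, omg);
    V3 Ni  = place_atom(Nn, Ci, CAi, B_N_CA, A_N_CA_C, psi);
    setv(xyz, 4*i, Ni); setv(xyz, 4*i + 1, CAi); setv(xyz, 4*i + 2, Ci);
    place_O(xyz, i, Nn);
  }
}

// Full-chain coordinates from torsions.  fixed_xyz (4*n_fixed x 3) holds frozen
// atoms: the first n_fixed residues when forward, the last n_fixed otherwise.
// [[Rcpp::export]]
NumericMatrix build_chain_cpp(NumericMatrix tor, int n_fixed, bool forward,
                              Nullable<NumericMatrix> fixed_xyz) {
  int n = tor.nrow();
  NumericMatrix xyz(4 * n, 3);
  if (n_fixed > 0) {
    NumericMatrix fx(fixed_xyz.get());
    if (forward) {
      for (int r = 0; r < 4 * n_fixed; r++)
        for (int c = 0; c < 3; c++) xyz(r, c) = fx(r, c);
      build_forward(xyz, tor, n_fixed);
    } else {
      int off = 4 * (n - n_fixed);
      for (int r = 0; r < 4 * n_fixed; r++)
        for (int c = 0; c < 3; c++) xyz(off + r, c) = fx(r, c);
      build_backward(xyz, tor, n - n_fixed);
    }
  } else {
    build_forward(xyz, tor, 0);
  }
  return xyz;
}

// Signed dihedral (degrees) of four points; NA for a degenerate central axis.
// [[Rcpp::export]]
double dihedral_cpp(NumericVector p1, NumericVector p2,
                    NumericVector p3, NumericVector p4) {
  V3 a = {p1[0], p1[1], p1[2]}, b = {p2[0], p2[1], p2[2]};
  V3 c = {p3[0], p3[1], p3[2]}, d = {p4[0], p4[1], p4[2]};
  V3 b1 = sub(b, a), b2 = sub(c, b), b3 = sub(d, c);
  V3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  double nb2 = norm(b2);
  if (nb2 < 1e-12 || norm(n1) < 1e-9 || norm(n2) < 1e-9) return NA_REAL;
  V3 m = cross(n1, scale(b2, 1.0 / nb2));
  double ang = -std::atan2(dot(m, n2), dot(n1, n2)) / DEG;
  if (ang <= -180.0) ang += 360.0;
  return ang;
}

// Backbone heavy-atom clash count: pairs of atoms from residues separated by
// at least `min_sep` in sequence closer than `cutoff`.
// [[Rcpp::export]]
int clash_count_cpp(NumericMatrix xyz, double cutoff, int min_sep = 2) {
  int natom = xyz.nrow();
  double c2 = cutoff * cutoff;
  int count = 0;
  for (int a = 0; a < natom; a++) {
    int ra = a / 4;
    for (int b = a + 1; b < natom; b++) {
      int rb = b / 4;
      if (rb - ra < min_sep) continue;
      double dx = xyz(a,0) - xyz(b,0);
      double dy = xyz(a,1) - xyz(b,1);
      double dz = xyz(a,2) - xyz(b,2);
      if (dx*dx + dy*dy + dz*dz < c2) count++;
    }
  }
  return count;
}

// ABEGO letter of a torsion triple (0=A,1=B,2=E,3=G,4=O), mirroring the
// R-level classifier boundaries.
static inline double wrap180(double x) {
  x -= 360.0 * std::floor(x / 360.0 + 0.5);
  if (x <= -180.0) x += 360.0;
  return x;
}

static int abego_of(double phi, double psi, double omega) {
  phi = wrap180(phi); psi = wrap180(psi); omega = wrap180(omega);
  if (std::fabs(omega) < 90.0) return 4;
  if (phi < 0.0) return (psi >= -75.0 && psi < 50.0) ? 0 : 1;
  return (psi >= -100.0 && psi < 100.0) ? 3 : 2;
}

// fr_lo..fr_hi (inclusive, 0-based) mark a frozen residue block whose
// internal clash pairs are constant and can be skipped during MC scoring.
static int clash_count_skip(const NumericMatrix &xyz, double cutoff,
                            int min_sep, int fr_lo, int fr_hi) {
  int natom = xyz.nrow();
  double c2 = cutoff * cutoff;
  int count = 0;
  for (int a = 0; a < natom; a++) {
    int ra = a / 4;
    for (int b = a + 1; b < natom; b++) {
      int rb = b / 4;
      if (rb - ra < min_sep) continue;
      if (ra >= fr_lo && rb <= fr_hi) continue;  // both frozen
      double dx = xyz(a,0) - xyz(b,0);
      double dy = xyz(a,1) - xyz(b,1);
      double dz = xyz(a,2) - xyz(b,2);
      if (dx*dx + dy*dy + dz*dz < c2) count++;
    }
  }
  return count;
}

static double score_chain(const NumericMatrix &xyz, const NumericMatrix &cons,
                          const NumericMatrix &pairs, double clash_cutoff,
                          double w_clash, int min_sep, int fr_lo = 1, int fr_hi = -1) {
  double s = 0.0;
  int nc = cons.nrow();
  for (int k = 0; k < nc; k++) {
    int ia = (int)cons(k, 0) - 1, ib = (int)cons(k, 1) - 1;
    double d = dist(getv(xyz, 4*ia + 1), getv(xyz, 4*ib + 1));
    double target = cons(k, 2), sd = cons(k, 3), width = cons(k, 5);
    double dev = std::fabs(d - target);
    if (cons(k, 4) > 0.5) dev = std::max(0.0, dev - width);  // bounded
    s += (dev / sd) * (dev / sd);
  }
  int np = pairs.nrow();
  for (int k = 0; k < np; k++) {
    int ia = (int)pairs(k, 0) - 1, ib = (int)pairs(k, 1) - 1;
    double d = dist(getv(xyz, 4*ia + 1), getv(xyz, 4*ib + 1));
    double dev = (d - pairs(k, 2)) / pairs(k, 3);
    s += dev * dev;
  }
  s += w_clash * clash_count_skip(xyz, clash_cutoff, min_sep, fr_lo, fr_hi);
  return s;
}

// [[Rcpp::export]]
double score_chain_cpp(NumericMatrix xyz, NumericMatrix cons, NumericMatrix pairs,
                       double clash_cutoff, double w_clash) {
  return score_chain(xyz, cons, pairs, clash_cutoff, w_clash, 2);
}

// Metropolis Monte-Carlo fragment-insertion folding of one subsegment.
//
// tor       : n x 3 starting torsions for the whole window
// n_fixed   : frozen residue count (prefix when forward, suffix otherwise)
// fixed_xyz : frozen atom coordinates (4*n_fixed x 3), or empty
// letter    : per-residue bank index (0-based) into `banks`; -1 for frozen
// banks     : list of K x 3 torsion-sample matrices, one per distinct letter
// cons/pairs: scoring tables (1-based CA anchor indices)
//
// Moves replace the torsions of up to `frag_len` consecutive mobile residues
// with fresh draws from each residue's bank; temperature anneals
// geometrically from t_hi to t_lo.  Uses R's RNG stream for reproducibility.
// [[Rcpp::export]]
List mc_fold_cpp(NumericMatrix tor, int n_fixed, bool forward,
                 Nullable<NumericMatrix> fixed_xyz,
                 IntegerVector letter, List banks,
                 NumericMatrix cons, NumericMatrix pairs,
                 double clash_cutoff, double w_clash,
                 int n_moves, double t_hi, double t_lo,
                 double stop_score, int frag_len = 3, double w_ss = 0.5,
                 int abort_after = 0, double abort_score = 0.0) {
  int n = tor.nrow();
  NumericMatrix cur(clone(tor));
  std::vector<int> mobile;
  for (int i = 0; i < n; i++) if (letter[i] >= 0) mobile.push_back(i);
  if (mobile.empty()) stop("no mobile residues");

  // SS-identity term: mobile residues keep a penalty until a fragment
  // insertion has set their torsions from their letter's bank (the extended
  // starting chain does not satisfy the prescribed secondary structure).
  std::vector<char> placed(n, 0);
  int unplaced = (int)mobile.size();
  int fr_lo = 1, fr_hi = -1;  // empty block by default
  if (n_fixed > 0) {
    if (forward) { fr_lo = 0; fr_hi = n_fixed - 1; }
    else { fr_lo = n - n_fixed; fr_hi = n - 1; }
  }

  NumericMatrix xyz = build_chain_cpp(cur, n_fixed, forward, fixed_xyz);
  double cur_score = score_chain(xyz, cons, pairs, clash_cutoff, w_clash, 2, fr_lo, fr_hi)
                     + w_ss * unplaced;
  NumericMatrix best(clone(cur));
  double best_score = cur_score;
  int accepted = 0, moves_done = 0;

  double cool = (n_moves > 1) ? std::pow(t_lo / t_hi, 1.0 / (n_moves - 1)) : 1.0;
  double temp = t_hi;
  int nmob = (int)mobile.size();

  for (int mv = 0; mv < n_moves; mv++, temp *= cool) {
    moves_done++;
    int pick = (int)(unif_rand() * nmob);
    if (pick >= nmob) pick = nmob - 1;
    // Collect up to frag_len consecutive mobile residues starting there.
    std::vector<int> win;
    for (int k = pick; k < nmob && (int)win.size() < frag_len; k++) {
      if (k > pick && mobile[k] != mobile[k-1] + 1) break;
      win.push_back(mobile[k]);
    }
    // half the moves are fragment insertions from the banks; the other half
    // are small Gaussian tweaks of already-placed torsions that keep each
    // residue inside its assigned ABEGO region (local refinement)
    bool tweak = placed[win[0]] && (unif_rand() < 0.5);
    std::vector<double> old_t(win.size() * 3);
    for (size_t w = 0; w < win.size(); w++) {
      int i = win[w];
      old_t[3*w] = cur(i,0); old_t[3*w+1] = cur(i,1); old_t[3*w+2] = cur(i,2);
      if (tweak && placed[i]) {
        int want = abego_of(cur(i,0), cur(i,1), cur(i,2));
        for (int attempt = 0; attempt < 4; attempt++) {
          double p = cur(i,0) + norm_rand() * 4.0;
          double s = cur(i,1) + norm_rand() * 4.0;
          double o = cur(i,2) + norm_rand() * 1.0;
          double ow = wrap180(o);
          bool omega_ok = (want == 4) || (180.0 - std::fabs(ow) <= 12.0);
          if (omega_ok && abego_of(p, s, o) == want) {
            cur(i,0) = p; cur(i,1) = s; cur(i,2) = o;
            break;
          }
        }
      } else {
        NumericMatrix bank = banks[letter[i]];
        int row = (int)(unif_rand() * bank.nrow());
        if (row >= bank.nrow()) row = bank.nrow() - 1;
        cur(i,0) = bank(row,0); cur(i,1) = bank(row,1); cur(i,2) = bank(row,2);
      }
    }
    int newly = 0;
    for (size_t w = 0; w < win.size(); w++) if (!placed[win[w]]) newly++;
    xyz = build_chain_cpp(cur, n_fixed, forward, fixed_xyz);
    double trial = score_chain(xyz, cons, pairs, clash_cutoff, w_clash, 2, fr_lo, fr_hi)
                   + w_ss * (unplaced - newly);
    double delta = trial - cur_score;
    bool accept = (delta <= 0.0) || (unif_rand() < std::exp(-delta / temp));
    if (accept) {
      cur_score = trial;
      unplaced -= newly;
      for (size_t w = 0; w < win.size(); w++) placed[win[w]] = 1;
      accepted++;
      if (trial < best_score) {
        best_score = trial;
        best = clone(cur);
      }
    } else {
      for (size_t w = 0; w < win.size(); w++) {
        int i = win[w];
        cur(i,0) = old_t[3*w]; cur(i,1) = old_t[3*w+1]; cur(i,2) = old_t[3*w+2];
      }
    }
    if (best_score <= stop_score) break;
    // hopeless-trajectory abort: geometry still far off after a grace period
    if (abort_after > 0 && moves_done == abort_after && best_score > abort_score)
      break;
  }

  NumericMatrix best_xyz = build_chain_cpp(best, n_fixed, forward, fixed_xyz);
  return List::create(_["torsions"] = best, _["xyz"] = best_xyz,
                      _["score"] = best_score, _["accepted"] = accepted,
                      _["moves"] = moves_done);
}
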