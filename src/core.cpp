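// Coarse-grained sticker-spacer polymer core: energy model, Metropolis
// sweeps, replica-exchange driver, and the heavy geometric kernels
// (residue-residue minimum-distance contacts, Shrake-Rupley SASA).
//
// Bead layout: residues are numbered globally r = chain * n_res + i
// (i = 0..n_res-1 within a chain); bead 2*r is the backbone (BB) bead,
// bead 2*r+1 the side-chain (SC) bead.  Coordinates are kept unwrapped;
// the minimum-image convention is applied inside every distance.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/(mol K)

struct System {
  int n_res;            // residues per chain
  int n_chains;
  int n_restot;         // n_res * n_chains
  int n_beads;          // 2 * n_restot
  double box;           // periodic cube edge (nm)
  std::vector<int> cat;         // per global residue, 0 sticker, 1 hydrophobic,
                                // 2 polar, 3 flexible
  std::vector<double> eps_sc;   // per global residue attraction well depth
  // lock registry (global residue indices); the directional site well
  // acts between the residues' oriented amide pseudo-sites
  std::vector<int> lockA, lockB;
  double eps_lock, r_lock, w_lock;
  // weak zipper extension of the registry towards the chain ends
  std::vector<int> extA, extB;
  double eps_ext;
  // cross-strand side-chain packing wells of the locked sheet
  std::vector<int> packA, packB;
  double eps_pack, r_pack, w_pack;
  // bonded
  double k_bond, r0_bb, r0_sc, k_angle, theta0;
  // excluded volume + attraction
  double sigma_bb, sigma_sc, eps_rep, rc_att;
  double eps_hb, r_hb, w_hb;    // generic backbone amide well
  double inv_box, rc2;          // derived
  // LCST temperature scaling of sticker/hydrophobic attractions
  double alpha, T_ref;
  // steeper falling coefficient of the enthalpic (zipper/packing) terms
  double alpha_enth;
  // optional harmonic restraints between beads (used for preparation)
  std::vector<int> restr_a, restr_b;
  std::vector<double> restr_k, restr_r0;
};

static System parse_system(const List& s) {
  System y;
  y.n_res = as<int>(s["n_res"]);
  y.n_chains = as<int>(s["n_chains"]);
  y.n_restot = y.n_res * y.n_chains;
  y.n_beads = 2 * y.n_restot;
  y.box = as<double>(s["box"]);
  y.cat = as<std::vector<int> >(s["cat"]);
  y.eps_sc = as<std::vector<double> >(s["eps_sc"]);
  y.lockA = as<std::vector<int> >(s["lock_a"]);
  y.lockB = as<std::vector<int> >(s["lock_b"]);
  y.eps_lock = as<double>(s["eps_lock"]);
  y.r_lock = as<double>(s["r_lock"]);
  y.w_lock = as<double>(s["w_lock"]);
  y.extA = as<std::vector<int> >(s["ext_a"]);
  y.extB = as<std::vector<int> >(s["ext_b"]);
  y.eps_ext = as<double>(s["eps_ext"]);
  y.packA = as<std::vector<int> >(s["pack_a"]);
  y.packB = as<std::vector<int> >(s["pack_b"]);
  y.eps_pack = as<double>(s["eps_pack"]);
  y.r_pack = as<double>(s["r_pack"]);
  y.w_pack = as<double>(s["w_pack"]);
  y.k_bond = as<double>(s["k_bond"]);
  y.r0_bb = as<double>(s["r0_bb"]);
  y.r0_sc = as<double>(s["r0_sc"]);
  y.k_angle = as<double>(s["k_angle"]);
  y.theta0 = as<double>(s["theta0"]);
  y.sigma_bb = as<double>(s["sigma_bb"]);
  y.sigma_sc = as<double>(s["sigma_sc"]);
  y.eps_rep = as<double>(s["eps_rep"]);
  y.rc_att = as<double>(s["rc_att"]);
  y.eps_hb = as<double>(s["eps_hb"]);
  y.r_hb = as<double>(s["r_hb"]);
  y.w_hb = as<double>(s["w_hb"]);
  y.alpha = as<double>(s["alpha"]);
  y.T_ref = as<double>(s["t_ref"]);
  y.alpha_enth = as<double>(s["alpha_enth"]);
  y.inv_box = 1.0 / y.box;
  y.rc2 = y.rc_att * y.rc_att;
  if (s.containsElementNamed("restr_a")) {
    y.restr_a = as<std::vector<int> >(s["restr_a"]);
    y.restr_b = as<std::vector<int> >(s["restr_b"]);
    y.restr_k = as<std::vector<double> >(s["restr_k"]);
    y.restr_r0 = as<std::vector<double> >(s["restr_r0"]);
  }
  return y;
}

// round-to-nearest minimum image without a libm call (coordinates are
// unwrapped but distances of interest are far below huge multiples of
// the box, so the cast is safe)
static inline double mind(double d, double box) {
  double t = d / box;
  t -= (double)(long long)(t + (t >= 0.0 ? 0.5 : -0.5));
  return t * box;
}

// same, with a precomputed reciprocal (hot path)
static inline double mindi(double d, double box, double inv_box) {
  double t = d * inv_box;
  t -= (double)(long long)(t + (t >= 0.0 ? 0.5 : -0.5));
  return t * box;
}

static inline double dist(const std::vector<double>& x, int a, int b,
                          double box) {
  double dx = mind(x[3 * a] - x[3 * b], box);
  double dy = mind(x[3 * a + 1] - x[3 * b + 1], box);
  double dz = mind(x[3 * a + 2] - x[3 * b + 2], box);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// temperature factor for sticker/hydrophobic attraction (LCST encoding)
static inline double tfac(const System& s, int ci, int cj, double T) {
  if ((ci <= 1) && (cj <= 1))
    return 1.0 + s.alpha * (T - s.T_ref) / s.T_ref;
  return 1.0;
}

// non-bonded pair energy between beads a < b
static double pair_energy(const System& s, const std::vector<double>& x,
                          int a, int b, double T) {
  double dx = mindi(x[3 * a] - x[3 * b], s.box, s.inv_box);
  double dy = mindi(x[3 * a + 1] - x[3 * b + 1], s.box, s.inv_box);
  double dz = mindi(x[3 * a + 2] - x[3 * b + 2], s.box, s.inv_box);
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= s.rc2) return 0.0; // global quick reject
  int ra = a / 2, rb = b / 2;
  if (ra == rb) return 0.0;                       // BB-SC bonded
  bool bbA = (a % 2) == 0, bbB = (b % 2) == 0;
  int chA = ra / s.n_res, chB = rb / s.n_res;
  if (bbA && bbB && chA == chB && std::abs(ra - rb) == 1)
    return 0.0;                                   // bonded backbone
  double sig = 0.5 * ((bbA ? s.sigma_bb : s.sigma_sc) +
                      (bbB ? s.sigma_bb : s.sigma_sc));
  // attraction only between side-chain beads, sequence separation >= 2
  bool att = !bbA && !bbB && (chA != chB || std::abs(ra - rb) >= 2);
  double eps = 0.0;
  if (att) {
    eps = std::sqrt(s.eps_sc[ra] * s.eps_sc[rb]) *
          tfac(s, s.cat[ra], s.cat[rb], T);
    if (eps < 0) eps = 0;
  }
  double s2 = sig * sig / r2;
  double sr6 = s2 * s2 * s2;
  if (eps > 0) {
    double src2 = sig * sig / (s.rc_att * s.rc_att);
    double src6 = src2 * src2 * src2;
    return 4.0 * eps * (sr6 * sr6 - sr6) - 4.0 * eps * (src6 * src6 - src6);
  }
  double e = 0.0;
  // weak isotropic backbone amide-amide well (transient hydrogen-bond
  // crowding), for backbone pairs at sequence separation >= 3 or on
  // different chains; the depth carries the LCST temperature factor
  // (dehydration on collapse strengthens backbone hydrogen bonding)
  if (bbA && bbB && s.eps_hb > 0 && r2 < 0.25 &&
      (chA != chB || std::abs(ra - rb) >= 3)) {
    double eps_hb_T = s.eps_hb * (1.0 + s.alpha * (T - s.T_ref) / s.T_ref);
    if (eps_hb_T > 0) {
      double r = std::sqrt(r2);
      double d = (r - s.r_hb) / s.w_hb;
      e -= eps_hb_T * std::exp(-0.5 * d * d);
    }
  }
  // purely repulsive (WCA): cutoff at 2^(1/6) sigma, i.e. sr6 > 1/2
  if (sr6 <= 0.5) return e;
  return e + 4.0 * s.eps_rep * (sr6 * sr6 - sr6) + s.eps_rep;
}

// Pseudo-amide axis of residue r: the cross product of the local
// backbone tangent and the side-chain direction.  In a beta-strand
// with side chains perpendicular to the sheet this axis lies in the
// sheet plane, pointing at the partner strand on either side (real
// backbone N-H and C=O point both ways), which is the geometry the
// hydrogen-bond detection convention mirrors.
static inline void amide_axis(const System& s, const std::vector<double>& x,
                              int r, double* u) {
  int within = r % s.n_res;
  int rprev = (within > 0) ? r - 1 : r;
  int rnext = (within < s.n_res - 1) ? r + 1 : r;
  double t[3], sc[3];
  for (int k = 0; k < 3; ++k) {
    t[k] = x[3 * (2 * rnext) + k] - x[3 * (2 * rprev) + k];
    sc[k] = x[3 * (2 * r) + 1 * 3 + k] - x[3 * (2 * r) + k];
  }
  u[0] = t[1] * sc[2] - t[2] * sc[1];
  u[1] = t[2] * sc[0] - t[0] * sc[2];
  u[2] = t[0] * sc[1] - t[1] * sc[0];
  double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  if (n < 1e-9) { u[0] = 1; u[1] = 0; u[2] = 0; n = 1; }
  for (int k = 0; k < 3; ++k) u[k] /= n;
}

// Directional well between the backbone beads of two residues: a
// Gaussian in the backbone distance modulated by the squared alignment
// of each residue's (sign-free) amide axis with the pair direction.
// A bound pair therefore satisfies the hydrogen-bond detection
// geometry (donor-acceptor distance and donor angle).  Used with
// eps_lock for the registry pairs of a lock and eps_ext for the
// zipper extension.
static double amide_pair_energy(const System& s,
                                const std::vector<double>& x, int ra,
                                int rb, double eps, double r0, double w) {
  double v[3];
  v[0] = mind(x[3 * (2 * rb)] - x[3 * (2 * ra)], s.box);
  v[1] = mind(x[3 * (2 * rb) + 1] - x[3 * (2 * ra) + 1], s.box);
  v[2] = mind(x[3 * (2 * rb) + 2] - x[3 * (2 * ra) + 2], s.box);
  double r2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  double rcap = r0 + 4.0 * w;
  if (r2 >= rcap * rcap) return 0.0;
  double r = std::sqrt(r2);
  if (r < 1e-9) return -eps;
  double ua[3], ub[3];
  amide_axis(s, x, ra, ua);
  amide_axis(s, x, rb, ub);
  double ca = (ua[0] * v[0] + ua[1] * v[1] + ua[2] * v[2]) / r;
  double cb = (ub[0] * v[0] + ub[1] * v[1] + ub[2] * v[2]) / r;
  double d = (r - r0) / w;
  return -eps * std::exp(-0.5 * d * d) * ca * ca * cb * cb;
}

static double lock_pair_energy(const System& s, const std::vector<double>& x,
                               size_t k) {
  if (s.eps_lock <= 0) return 0.0;
  return amide_pair_energy(s, x, s.lockA[k], s.lockB[k], s.eps_lock,
                           s.r_lock, s.w_lock);
}

// Zipper extension pairs are weak, solvent-exposed flank hydrogen
// bonds: enthalpy-dominated, so their effective strength falls with
// temperature (mirror image of the entropy-driven sticker scaling).
static double ext_pair_energy(const System& s, const std::vector<double>& x,
                              size_t k, double T) {
  if (s.eps_ext <= 0) return 0.0;
  double eps = s.eps_ext * (1.0 - s.alpha_enth * (T - s.T_ref) / s.T_ref);
  if (eps <= 0) return 0.0;
  return amide_pair_energy(s, x, s.extA[k], s.extB[k], eps,
                           s.r_lock, s.w_lock);
}

// Cross-strand side-chain packing: Gaussian well between the
// side-chain beads of a packed pair of the locked sheet.  These are
// polar, hydrogen-bonding side-chain contacts: enthalpy-dominated,
// so like the zipper their strength falls with temperature.
static double pack_pair_energy(const System& s, const std::vector<double>& x,
                               size_t k, double T) {
  if (s.eps_pack <= 0) return 0.0;
  double eps = s.eps_pack * (1.0 - s.alpha_enth * (T - s.T_ref) / s.T_ref);
  if (eps <= 0) return 0.0;
  int a = 2 * s.packA[k] + 1, b = 2 * s.packB[k] + 1;
  double r = dist(x, a, b, s.box);
  double d = (r - s.r_pack) / s.w_pack;
  return -eps * std::exp(-0.5 * d * d);
}

static double bond_energy(const System& s, const std::vector<double>& x,
                          int a, int b, double r0) {
  double d = dist(x, a, b, s.box) - r0;
  return 0.5 * s.k_bond * d * d;
}

static double angle_energy(const System& s, const std::vector<double>& x,
                           int a, int b, int c) {
  double v1[3], v2[3];
  for (int k = 0; k < 3; ++k) {
    v1[k] = mind(x[3 * a + k] - x[3 * b + k], s.box);
    v2[k] = mind(x[3 * c + k] - x[3 * b + k], s.box);
  }
  double n1 = std::sqrt(v1[0] * v1[0] + v1[1] * v1[1] + v1[2] * v1[2]);
  double n2 = std::sqrt(v2[0] * v2[0] + v2[1] * v2[1] + v2[2] * v2[2]);
  double cth = (v1[0] * v2[0] + v1[1] * v2[1] + v1[2] * v2[2]) / (n1 * n2);
  if (cth > 1) cth = 1;
  if (cth < -1) cth = -1;
  double d = std::acos(cth) - s.theta0;
  return 0.5 * s.k_angle * d * d;
}

static double restraint_energy(const System& s, const std::vector<double>& x,
                               size_t k) {
  double d = dist(x, s.restr_a[k], s.restr_b[k], s.box) - s.restr_r0[k];
  return 0.5 * s.restr_k[k] * d * d;
}

static double total_energy(const System& s, const std::vector<double>& x,
                           double T) {
  double e = 0.0;
  for (int a = 0; a < s.n_beads; ++a)
    for (int b = a + 1; b < s.n_beads; ++b) e += pair_energy(s, x, a, b, T);
  for (size_t k = 0; k < s.lockA.size(); ++k) e += lock_pair_energy(s, x, k);
  for (size_t k = 0; k < s.extA.size(); ++k)
    e += ext_pair_energy(s, x, k, T);
  for (size_t k = 0; k < s.packA.size(); ++k)
    e += pack_pair_energy(s, x, k, T);
  for (int c = 0; c < s.n_chains; ++c) {
    int off = c * s.n_res;
    for (int i = 0; i < s.n_res; ++i) {
      int r = off + i;
      e += bond_energy(s, x, 2 * r, 2 * r + 1, s.r0_sc);
      if (i + 1 < s.n_res)
        e += bond_energy(s, x, 2 * r, 2 * (r + 1), s.r0_bb);
      if (i >= 1 && i + 1 < s.n_res)
        e += angle_energy(s, x, 2 * (r - 1), 2 * r, 2 * (r + 1));
    }
  }
  for (size_t k = 0; k < s.restr_a.size(); ++k)
    e += restraint_energy(s, x, k);
  return e;
}

// Energy of the terms that can change under a move of the flagged bead
// set.  All move types displace the moved set rigidly (or move a single
// bead), so terms internal to the moved set are invariant and skipped;
// only moved-unmoved interactions and bonded terms with a mix of moved
// and unmoved participants are summed.
static double partial_energy(const System& s, const std::vector<double>& x,
                             const std::vector<char>& moved,
                             const std::vector<int>& mlist, double T) {
  double e = 0.0;
  for (size_t mi = 0; mi < mlist.size(); ++mi) {
    int a = mlist[mi];
    for (int b = 0; b < s.n_beads; ++b) {
      if (b == a || moved[b]) continue;
      int lo = a < b ? a : b, hi = a < b ? b : a;
      e += pair_energy(s, x, lo, hi, T);
    }
  }
  // directional wells involve the pair residues' beads plus the
  // neighbouring backbone beads (through the tangent in the amide axis)
  auto res_flags = [&](int r, char& any, char& all) {
    any = moved[2 * r] || moved[2 * r + 1];
    all = moved[2 * r] && moved[2 * r + 1];
    int within = r % s.n_res;
    if (within > 0) {
      any = any || moved[2 * (r - 1)];
      all = all && moved[2 * (r - 1)];
    }
    if (within < s.n_res - 1) {
      any = any || moved[2 * (r + 1)];
      all = all && moved[2 * (r + 1)];
    }
  };
  for (size_t k = 0; k < s.lockA.size(); ++k) {
    char ma, mb, aa, ab;
    res_flags(s.lockA[k], ma, aa);
    res_flags(s.lockB[k], mb, ab);
    if ((ma || mb) && !(aa && ab)) e += lock_pair_energy(s, x, k);
  }
  for (size_t k = 0; k < s.extA.size(); ++k) {
    char ma, mb, aa, ab;
    res_flags(s.extA[k], ma, aa);
    res_flags(s.extB[k], mb, ab);
    if ((ma || mb) && !(aa && ab)) e += ext_pair_energy(s, x, k, T);
  }
  for (size_t k = 0; k < s.packA.size(); ++k) {
    char ma = moved[2 * s.packA[k] + 1], mb = moved[2 * s.packB[k] + 1];
    if ((ma || mb) && !(ma && mb)) e += pack_pair_energy(s, x, k, T);
  }
  for (int c = 0; c < s.n_chains; ++c) {
    int off = c * s.n_res;
    for (int i = 0; i < s.n_res; ++i) {
      int r = off + i;
      char m0 = moved[2 * r], m1 = moved[2 * r + 1];
      if ((m0 || m1) && !(m0 && m1))
        e += bond_energy(s, x, 2 * r, 2 * r + 1, s.r0_sc);
      if (i + 1 < s.n_res) {
        char mn = moved[2 * (r + 1)];
        if ((m0 || mn) && !(m0 && mn))
          e += bond_energy(s, x, 2 * r, 2 * (r + 1), s.r0_bb);
      }
      if (i >= 1 && i + 1 < s.n_res) {
        char mp = moved[2 * (r - 1)], mn = moved[2 * (r + 1)];
        if ((mp || m0 || mn) && !(mp && m0 && mn))
          e += angle_energy(s, x, 2 * (r - 1), 2 * r, 2 * (r + 1));
      }
    }
  }
  for (size_t k = 0; k < s.restr_a.size(); ++k) {
    char ma = moved[s.restr_a[k]], mb = moved[s.restr_b[k]];
    if ((ma || mb) && !(ma && mb)) e += restraint_energy(s, x, k);
  }
  return e;
}

// ---------------------------------------------------------------- moves

struct MoveSet {
  double p_local, p_crank; // pivot gets the rest
  double step_local, amax_crank, amax_pivot;
  int crank_span;
};

static void rotate_about(std::vector<double>& x, const std::vector<int>& idx,
                         const double* origin, const double* axis,
                         double angle) {
  double c = std::cos(angle), s = std::sin(angle);
  for (size_t m = 0; m < idx.size(); ++m) {
    int b = idx[m];
    double v[3];
    for (int k = 0; k < 3; ++k) v[k] = x[3 * b + k] - origin[k];
    double dot = v[0] * axis[0] + v[1] * axis[1] + v[2] * axis[2];
    double cr[3] = {axis[1] * v[2] - axis[2] * v[1],
                    axis[2] * v[0] - axis[0] * v[2],
                    axis[0] * v[1] - axis[1] * v[0]};
    for (int k = 0; k < 3; ++k)
      x[3 * b + k] = origin[k] + v[k] * c + cr[k] * s +
                     axis[k] * dot * (1.0 - c);
  }
}

// one attempted Metropolis move; returns 1 if accepted.
// The move is applied in place after evaluating the old partial energy
// and rolled back on rejection (avoids copying the full frame).
static int attempt_move(const System& s, std::vector<double>& x, double T,
                        const MoveSet& mv, double& energy) {
  double beta = 1.0 / (KB * T);
  double u = unif_rand();
  static std::vector<int> mlist;
  mlist.clear();
  double disp[3];
  double origin[3], axis[3], angle = 0.0;
  bool is_local = false;
  if (u < mv.p_local) {
    is_local = true;
    int b = (int)(unif_rand() * s.n_beads);
    if (b >= s.n_beads) b = s.n_beads - 1;
    for (int k = 0; k < 3; ++k) disp[k] = mv.step_local * norm_rand();
    mlist.push_back(b);
  } else if (u < mv.p_local + mv.p_crank && s.n_res >= 4) {
    int c = (int)(unif_rand() * s.n_chains);
    int off = c * s.n_res;
    int i = (int)(unif_rand() * (s.n_res - 2));
    int span = 2 + (int)(unif_rand() * mv.crank_span);
    int j = i + span;
    if (j > s.n_res - 1) j = s.n_res - 1;
    if (j - i < 2) return 0;
    int ba = 2 * (off + i), bb = 2 * (off + j);
    double n = 0;
    for (int k = 0; k < 3; ++k) {
      origin[k] = x[3 * ba + k];
      axis[k] = mind(x[3 * bb + k] - x[3 * ba + k], s.box);
      n += axis[k] * axis[k];
    }
    n = std::sqrt(n);
    if (n < 1e-9) return 0;
    for (int k = 0; k < 3; ++k) axis[k] /= n;
    for (int r = i + 1; r <= j - 1; ++r) {
      mlist.push_back(2 * (off + r));
      mlist.push_back(2 * (off + r) + 1);
    }
    angle = (2.0 * unif_rand() - 1.0) * mv.amax_crank;
  } else {
    int c = (int)(unif_rand() * s.n_chains);
    int off = c * s.n_res;
    int p = 1 + (int)(unif_rand() * (s.n_res - 2));
    bool tail = (s.n_res - 1 - p) <= p; // rotate the shorter side
    int bp = 2 * (off + p);
    for (int k = 0; k < 3; ++k) origin[k] = x[3 * bp + k];
    // random unit axis
    double n = 0;
    do {
      n = 0;
      for (int k = 0; k < 3; ++k) {
        axis[k] = norm_rand();
        n += axis[k] * axis[k];
      }
      n = std::sqrt(n);
    } while (n < 1e-9);
    for (int k = 0; k < 3; ++k) axis[k] /= n;
    if (tail) {
      for (int r = p + 1; r < s.n_res; ++r) {
        mlist.push_back(2 * (off + r));
        mlist.push_back(2 * (off + r) + 1);
      }
    } else {
      for (int r = 0; r < p; ++r) {
        mlist.push_back(2 * (off + r));
        mlist.push_back(2 * (off + r) + 1);
      }
    }
    mlist.push_back(2 * (off + p) + 1); // side chain of the pivot residue
    angle = (2.0 * unif_rand() - 1.0) * mv.amax_pivot;
  }
  static std::vector<char> moved;
  moved.assign(s.n_beads, 0);
  for (size_t m = 0; m < mlist.size(); ++m) moved[mlist[m]] = 1;
  double e_old = partial_energy(s, x, moved, mlist, T);
  // save old positions, then apply the move in place
  static std::vector<double> saved;
  saved.resize(3 * mlist.size());
  for (size_t m = 0; m < mlist.size(); ++m)
    for (int k = 0; k < 3; ++k) saved[3 * m + k] = x[3 * mlist[m] + k];
  if (is_local) {
    for (int k = 0; k < 3; ++k) x[3 * mlist[0] + k] += disp[k];
  } else {
    rotate_about(x, mlist, origin, axis, angle);
  }
  double e_new = partial_energy(s, x, moved, mlist, T);
  double dE = e_new - e_old;
  if (std::isfinite(dE) &&
      (dE <= 0.0 || unif_rand() < std::exp(-beta * dE))) {
    energy += dE;
    return 1;
  }
  for (size_t m = 0; m < mlist.size(); ++m) // reject: roll back
    for (int k = 0; k < 3; ++k) x[3 * mlist[m] + k] = saved[3 * m + k];
  return 0;
}

static MoveSet parse_moves(const List& m) {
  MoveSet mv;
  mv.p_local = as<double>(m["p_local"]);
  mv.p_crank = as<double>(m["p_crank"]);
  mv.step_local = as<double>(m["step_local"]);
  mv.amax_crank = as<double>(m["amax_crank"]);
  mv.amax_pivot = as<double>(m["amax_pivot"]);
  mv.crank_span = as<int>(m["crank_span"]);
  return mv;
}

// [[Rcpp::export(name = ".cpp_total_energy")]]
double cpp_total_energy(NumericMatrix coords, List sys, double temperature) {
  System s = parse_system(sys);
  std::vector<double> x(3 * s.n_beads);
  for (int b = 0; b < s.n_beads; ++b)
    for (int k = 0; k < 3; ++k) x[3 * b + k] = coords(b, k);
  return total_energy(s, x, temperature);
}

// [[Rcpp::export(name = ".cpp_run_mc")]]
List cpp_run_mc(NumericMatrix coords, List sys, List moves, double temperature,
                int n_sweeps) {
  System s = parse_system(sys);
  MoveSet mv = parse_moves(moves);
  std::vector<double> x(3 * s.n_beads);
  for (int b = 0; b < s.n_beads; ++b)
    for (int k = 0; k < 3; ++k) x[3 * b + k] = coords(b, k);
  double e = total_energy(s, x, temperature);
  long acc = 0, att = 0;
  for (int sw = 0; sw < n_sweeps; ++sw)
    for (int m = 0; m < s.n_beads; ++m) {
      acc += attempt_move(s, x, temperature, mv, e);
      ++att;
    }
  NumericMatrix out(s.n_beads, 3);
  for (int b = 0; b < s.n_beads; ++b)
    for (int k = 0; k < 3; ++k) out(b, k) = x[3 * b + k];
  return List::create(_["coords"] = out,
                      _["energy"] = total_energy(s, x, temperature),
                      _["accepted"] = (double)acc,
                      _["attempted"] = (double)att);
}

// Replica-exchange driver.  `init` is a list of n_rungs coordinate
// matrices; rung k runs at temps[k].  Nearest-neighbour swaps are
// attempted every `exchange_interval` sweeps with alternating even/odd
// pair parity; frames are recorded every `stride` sweeps.
// [[Rcpp::export(name = ".cpp_run_remd")]]
List cpp_run_remd(List init, List sys, List moves, NumericVector temps,
                  int n_sweeps, int exchange_interval, int stride) {
  System s = parse_system(sys);
  MoveSet mv = parse_moves(moves);
  int nr = temps.size();
  std::vector<std::vector<double> > x(nr);
  std::vector<double> e(nr);
  std::vector<int> rep(nr); // replica id currently at each rung
  for (int r = 0; r < nr; ++r) {
    NumericMatrix m0 = init[r];
    x[r].resize(3 * s.n_beads);
    for (int b = 0; b < s.n_beads; ++b)
      for (int k = 0; k < 3; ++k) x[r][3 * b + k] = m0(b, k);
    e[r] = total_energy(s, x[r], temps[r]);
    rep[r] = r;
  }
  int n_frames = n_sweeps / stride;
  List frames(nr);
  NumericMatrix energies(n_frames, nr);
  IntegerVector fsweep(n_frames);
  std::vector<NumericVector> farr(nr);
  for (int r = 0; r < nr; ++r) {
    NumericVector a(Dimension(s.n_beads, 3, n_frames));
    farr[r] = a;
    frames[r] = a;
  }
  int n_ep = (exchange_interval > 0 && nr > 1)
                 ? n_sweeps / exchange_interval : 0;
  NumericVector exch_att(nr > 1 ? nr - 1 : 0), exch_acc(nr > 1 ? nr - 1 : 0);
  IntegerMatrix walk(n_ep, nr);
  long acc = 0, att = 0;
  int fi = 0, ep = 0;
  for (int sw = 1; sw <= n_sweeps; ++sw) {
    for (int r = 0; r < nr; ++r)
      for (int m = 0; m < s.n_beads; ++m) {
        acc += attempt_move(s, x[r], temps[r], mv, e[r]);
        ++att;
      }
    if (nr > 1 && exchange_interval > 0 && sw % exchange_interval == 0) {
      int parity = ep % 2;
      for (int r = parity; r + 1 < nr; r += 2) {
        exch_att[r] += 1;
        double bi = 1.0 / (KB * temps[r]), bj = 1.0 / (KB * temps[r + 1]);
        // energies are temperature-dependent (LCST scaling), so evaluate
        // both configurations at both rung temperatures
        double Ei_i = total_energy(s, x[r], temps[r]);
        double Ej_j = total_energy(s, x[r + 1], temps[r + 1]);
        double Ei_j = total_energy(s, x[r], temps[r + 1]);
        double Ej_i = total_energy(s, x[r + 1], temps[r]);
        double lnp = -bi * (Ej_i - Ei_i) - bj * (Ei_j - Ej_j);
        if (lnp >= 0 || unif_rand() < std::exp(lnp)) {
          std::swap(x[r], x[r + 1]);
          std::swap(rep[r], rep[r + 1]);
          e[r] = Ej_i;
          e[r + 1] = Ei_j;
          exch_acc[r] += 1;
        }
      }
      if (ep < n_ep)
        for (int r = 0; r < nr; ++r) walk(ep, r) = rep[r] + 1;
      ++ep;
    }
    if (sw % stride == 0 && fi < n_frames) {
      for (int r = 0; r < nr; ++r) {
        e[r] = total_energy(s, x[r], temps[r]); // refresh running energy
        energies(fi, r) = e[r];
        for (int b = 0; b < s.n_beads; ++b)
          for (int k = 0; k < 3; ++k)
            farr[r][b + s.n_beads * k + 3 * s.n_beads * fi] = x[r][3 * b + k];
      }
      fsweep[fi] = sw;
      ++fi;
    }
  }
  return List::create(
      _["frames"] = frames, _["energies"] = energies, _["sweeps"] = fsweep,
      _["exch_attempts"] = exch_att, _["exch_accepts"] = exch_acc,
      _["replica_walk"] = walk, _["move_accept_rate"] = (double)acc / att);
}

// ------------------------------------------------------- metric kernels

// Residue-residue contact matrix for one frame: contact iff the minimum
// distance over the selected atoms of the two residues is below `cutoff`.
// scope 0 = intramolecular (same chain, |i-j| > adjacency), 1 =
// intermolecular (different chains, no adjacency exclusion).
// [[Rcpp::export(name = ".cpp_contact_frame")]]
LogicalMatrix cpp_contact_frame(NumericMatrix coords, IntegerVector atom_res,
                                IntegerVector res_chain,
                                IntegerVector res_index, int n_res,
                                double cutoff, int adjacency, int scope,
                                double box) {
  int n_atoms = coords.nrow();
  std::vector<std::vector<int> > byres(n_res);
  for (int a = 0; a < n_atoms; ++a) {
    int r = atom_res[a] - 1;
    if (r >= 0 && r < n_res) byres[r].push_back(a);
  }
  LogicalMatrix out(n_res, n_res);
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n_res; ++i) {
    if (byres[i].empty()) continue;
    for (int j = i + 1; j < n_res; ++j) {
      if (byres[j].empty()) continue;
      bool same = res_chain[i] == res_chain[j];
      if (scope == 0) {
        if (!same) continue;
        if (std::abs(res_index[i] - res_index[j]) <= adjacency) continue;
      } else {
        if (same) continue;
      }
      bool hit = false;
      for (size_t ai = 0; ai < byres[i].size() && !hit; ++ai)
        for (size_t aj = 0; aj < byres[j].size() && !hit; ++aj) {
          int a = byres[i][ai], b = byres[j][aj];
          double dx = coords(a, 0) - coords(b, 0);
          double dy = coords(a, 1) - coords(b, 1);
          double dz = coords(a, 2) - coords(b, 2);
          if (box > 0) {
            dx = mind(dx, box);
            dy = mind(dy, box);
            dz = mind(dz, box);
          }
          if (dx * dx + dy * dy + dz * dz < c2) hit = true;
        }
      if (hit) {
        out(i, j) = true;
        out(j, i) = true;
      }
    }
  }
  return out;
}

// Shrake-Rupley SASA with a deterministic golden-spiral point set.
// [[Rcpp::export(name = ".cpp_sasa")]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  int n = coords.nrow();
  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_points; ++i) {
    double z = 1.0 - (2.0 * i + 1.0) / n_points;
    double rad = std::sqrt(1.0 - z * z);
    double th = golden * i;
    px[i] = rad * std::cos(th);
    py[i] = rad * std::sin(th);
    pz[i] = z;
  }
  NumericVector area(n);
  for (int a = 0; a < n; ++a) {
    double ra = radii[a] + probe;
    // neighbours that can occlude a
    std::vector<int> nb;
    for (int b = 0; b < n; ++b) {
      if (b == a) continue;
      double dx = coords(a, 0) - coords(b, 0);
      double dy = coords(a, 1) - coords(b, 1);
      double dz = coords(a, 2) - coords(b, 2);
      double rb = radii[b] + probe;
      if (dx * dx + dy * dy + dz * dz < (ra + rb) * (ra + rb)) nb.push_back(b);
    }
    int nacc = 0;
    for (int i = 0; i < n_points; ++i) {
      double qx = coords(a, 0) + ra * px[i];
      double qy = coords(a, 1) + ra * py[i];
      double qz = coords(a, 2) + ra * pz[i];
      bool buried = false;
      for (size_t k = 0; k < nb.size() && !buried; ++k) {
        int b = nb[k];
        double rb = radii[b] + probe;
        double dx = qx - coords(b, 0);
        double dy = qy - coords(b, 1);
        double dz = qz - coords(b, 2);
        if (dx * dx + dy * dy + dz * dz < rb * rb) buried = true;
      }
      if (!buried) ++nacc;
    }
    area[a] = 4.0 * M_PI * ra * ra * nacc / n_points;
  }
  return area;
}
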