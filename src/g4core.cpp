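// Core numerics: hard-cylinder geometry, square-well energetics, the NVT
// Metropolis kernel, and pair-distance utilities for scattering.
//
// Conventions used throughout:
//   * lengths in nm, energies in units of u0 (a stacking bond contributes -1)
//   * cubic periodic box [0, box) in each coordinate, minimum-image pair
//     displacements
//   * a particle is (center, axis, ex) with |axis| = 1; ex is a body-frame
//     basal vector (perpendicular to axis), only meaningful in trimer mode
//     where covalent sites sit on the rim of the bases.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 operator*(double s, Vec3 a) { return v3(s * a.x, s * a.y, s * a.z); }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm2(Vec3 a) { return dot(a, a); }
static inline double norm(Vec3 a) { return std::sqrt(norm2(a)); }
static inline Vec3 normalize(Vec3 a) {
  double n = norm(a);
  return (1.0 / n) * a;
}

// minimum-image displacement for a cubic box
static inline Vec3 min_image(Vec3 d, double box) {
  d.x -= box * std::nearbyint(d.x / box);
  d.y -= box * std::nearbyint(d.y / box);
  d.z -= box * std::nearbyint(d.z / box);
  return d;
}

// ---------------------------------------------------------------------------
// Segment-segment closest approach (Eberly).  Returns squared distance and
// the clamped parameters s, t in [0,1]; *interior reports whether neither
// parameter was clamped (closest points strictly inside both segments).
// Segments are c +/- h*u, parameterised as c - h*u + s*(2h*u).
// ---------------------------------------------------------------------------
static double segseg_dist2(Vec3 p1, Vec3 d1, Vec3 p2, Vec3 d2,
                           double* s_out, double* t_out, bool* interior) {
  // p: segment start, d: full segment vector
  Vec3 r = p1 - p2;
  double a = dot(d1, d1), e = dot(d2, d2), f = dot(d2, r);
  double c = dot(d1, r), b = dot(d1, d2);
  double denom = a * e - b * b;
  double s, t;
  bool clamped = false;
  if (denom > 1e-14 * a * e) {
    s = (b * f - c * e) / denom;
    if (s < 0.0) { s = 0.0; clamped = true; }
    if (s > 1.0) { s = 1.0; clamped = true; }
  } else {
    s = 0.0;
    clamped = true;  // parallel: treat as boundary case
  }
  t = (b * s + f) / e;
  if (t < 0.0) {
    t = 0.0; clamped = true;
    s = -c / a;
    if (s < 0.0) { s = 0.0; } else if (s > 1.0) { s = 1.0; }
  } else if (t > 1.0) {
    t = 1.0; clamped = true;
    s = (b - c) / a;
    if (s < 0.0) { s = 0.0; } else if (s > 1.0) { s = 1.0; }
  }
  Vec3 cp1 = p1 + s * d1;
  Vec3 cp2 = p2 + t * d2;
  *s_out = s;
  *t_out = t;
  *interior = !clamped && s > 1e-9 && s < 1.0 - 1e-9 && t > 1e-9 && t < 1.0 - 1e-9;
  return norm2(cp1 - cp2);
}

// ---------------------------------------------------------------------------
// GJK boolean intersection for two finite flat-capped cylinders (both convex).
// ---------------------------------------------------------------------------
struct Cyl {
  Vec3 c;    // center
  Vec3 u;    // unit axis
  double h;  // half length L/2
  double r;  // radius D/2
};

static inline Vec3 cyl_support(const Cyl& C, Vec3 d) {
  double w = dot(d, C.u);
  Vec3 p = C.c + ((w >= 0.0) ? C.h : -C.h) * C.u;
  Vec3 dperp = d - w * C.u;
  double n = norm(dperp);
  if (n > 1e-13) p = p + (C.r / n) * dperp;
  return p;
}

static inline Vec3 mink_support(const Cyl& A, const Cyl& B, Vec3 d) {
  return cyl_support(A, d) - cyl_support(B, v3(-d.x, -d.y, -d.z));
}

// Simplex update ("do simplex"): returns true if origin is enclosed,
// otherwise updates simplex and search direction.
static bool do_simplex(Vec3* S, int* n, Vec3* dir) {
  const double EPS = 1e-18;
  Vec3 A = S[*n - 1];          // most recently added
  Vec3 ao = v3(-A.x, -A.y, -A.z);
  if (*n == 2) {
    Vec3 B = S[0];
    Vec3 ab = B - A;
    if (dot(ab, ao) > 0.0) {
      Vec3 d = cross(cross(ab, ao), ab);
      if (norm2(d) < EPS) return true;  // origin on the segment
      *dir = d;
    } else {
      S[0] = A; *n = 1; *dir = ao;
    }
    return false;
  }
  if (*n == 3) {
    Vec3 B = S[1], C = S[0];
    Vec3 ab = B - A, ac = C - A;
    Vec3 abc = cross(ab, ac);
    if (norm2(abc) < EPS) {
      // degenerate triangle: fall back to the segment A-B
      S[0] = B; S[1] = A; *n = 2;
      Vec3 d = cross(cross(ab, ao), ab);
      if (norm2(d) < EPS) return true;
      *dir = d;
      return false;
    }
    Vec3 abcxac = cross(abc, ac);
    if (dot(abcxac, ao) > 0.0) {
      if (dot(ac, ao) > 0.0) {
        S[0] = C; S[1] = A; *n = 2;
        Vec3 d = cross(cross(ac, ao), ac);
        if (norm2(d) < EPS) return true;
        *dir = d;
      } else {
        S[0] = B; S[1] = A; *n = 2;
        Vec3 d = cross(cross(ab, ao), ab);
        if (norm2(d) < EPS) return true;
        *dir = d;
      }
      return false;
    }
    Vec3 abxabc = cross(ab, abc);
    if (dot(abxabc, ao) > 0.0) {
      S[0] = B; S[1] = A; *n = 2;
      Vec3 d = cross(cross(ab, ao), ab);
      if (norm2(d) < EPS) return true;
      *dir = d;
      return false;
    }
    if (dot(abc, ao) > 0.0) {
      // keep winding so that abc points to the origin side: [C,B,A]
      *dir = abc;
    } else {
      Vec3 tmp = S[0]; S[0] = S[1]; S[1] = tmp;  // swap B,C
      *dir = v3(-abc.x, -abc.y, -abc.z);
    }
    return false;
  }
  // n == 4: tetrahedron [D,C,B,A] with A on top; faces ABC, ACD, ADB
  Vec3 B = S[2], C = S[1], Dv = S[0];
  Vec3 ab = B - A, ac = C - A, ad = Dv - A;
  Vec3 abc = cross(ab, ac);
  Vec3 acd = cross(ac, ad);
  Vec3 adb = cross(ad, ab);
  if (dot(abc, ao) > 0.0) {
    S[0] = C; S[1] = B; S[2] = A; *n = 3; *dir = abc;
    return false;
  }
  if (dot(acd, ao) > 0.0) {
    S[0] = Dv; S[1] = C; S[2] = A; *n = 3; *dir = acd;
    return false;
  }
  if (dot(adb, ao) > 0.0) {
    S[0] = B; S[1] = Dv; S[2] = A; *n = 3; *dir = adb;
    return false;
  }
  return true;  // origin inside tetrahedron
}

static bool gjk_intersect(const Cyl& A, const Cyl& B) {
  Vec3 d = A.c - B.c;
  if (norm2(d) < 1e-20) d = v3(1.0, 0.0, 0.0);
  Vec3 S[4];
  int n = 0;
  S[n++] = mink_support(A, B, d);
  d = v3(-S[0].x, -S[0].y, -S[0].z);
  for (int iter = 0; iter < 128; ++iter) {
    if (norm2(d) < 1e-18) return true;  // origin on current simplex feature
    Vec3 P = mink_support(A, B, d);
    if (dot(P, d) < 1e-12) return false;  // support never crosses origin
    S[n++] = P;
    if (do_simplex(S, &n, &d)) return true;
  }
  return true;  // failed to converge (grazing contact): treat as overlap
}

// full overlap test with prefilters; positions already minimum-imaged by caller
static bool cyl_overlap(Vec3 c1, Vec3 u1, double h1, double r1,
                        Vec3 c2, Vec3 u2, double h2, double r2) {
  double d2c = norm2(c1 - c2);
  double rc1 = std::sqrt(h1 * h1 + r1 * r1), rc2 = std::sqrt(h2 * h2 + r2 * r2);
  if (d2c > (rc1 + rc2) * (rc1 + rc2)) return false;  // circumscribed spheres
  // axis segments
  Vec3 p1 = c1 - h1 * u1, d1v = (2.0 * h1) * u1;
  Vec3 p2 = c2 - h2 * u2, d2v = (2.0 * h2) * u2;
  double s, t;
  bool interior;
  double ss2 = segseg_dist2(p1, d1v, p2, d2v, &s, &t, &interior);
  double rsum = r1 + r2;
  if (ss2 >= rsum * rsum) return false;  // contained in spherocylinders
  // If the closest points are interior to both axes the connecting vector is
  // perpendicular to both, and the two basal disks through the closest points
  // overlap: guaranteed intersection.
  if (interior) return true;
  Cyl A{c1, u1, h1, r1}, B{c2, u2, h2, r2};
  return gjk_intersect(A, B);
}

// [[Rcpp::export]]
LogicalVector cylinders_overlap_cpp(NumericMatrix c1, NumericMatrix u1,
                                    NumericMatrix c2, NumericMatrix u2,
                                    NumericVector D1, NumericVector L1,
                                    NumericVector D2, NumericVector L2) {
  int n = c1.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 a = v3(c1(i, 0), c1(i, 1), c1(i, 2));
    Vec3 ua = normalize(v3(u1(i, 0), u1(i, 1), u1(i, 2)));
    Vec3 b = v3(c2(i, 0), c2(i, 1), c2(i, 2));
    Vec3 ub = normalize(v3(u2(i, 0), u2(i, 1), u2(i, 2)));
    out[i] = cyl_overlap(a, ua, L1[i] / 2.0, D1[i] / 2.0,
                         b, ub, L2[i] / 2.0, D2[i] / 2.0);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Site bookkeeping.
//
// Stacking sites sit on the symmetry axis at +/- (L/2 + 0.15*D/2) from the
// center; site_plus/site_minus flag whether the face carries a site (trimer
// terminal bases have none on their outward faces).  Covalent sites (trimer
// mode) sit on the rim: center +/- (L/2)*axis + (D/2)*ex.
// ---------------------------------------------------------------------------
struct Model {
  double h;         // L/2
  double r;         // D/2
  double site_off;  // L/2 + 0.15 * D/2
  double delta2;    // squared SW range
  double delta_cov2;
  double box;
  double Tstar;
};

// squared distance between stacking sites of particles i (at ci,ui) and j
// (at position cj displaced by minimum image relative to ci)
static inline double sw_energy_pair(Vec3 ci, Vec3 ui, int spi, int smi,
                                    Vec3 cj, Vec3 uj, int spj, int smj,
                                    const Model& M) {
  // returns energy in u0 units (0 or negative integers)
  double e = 0.0;
  Vec3 si[2], sj[2];
  int fi[2], fj[2];
  si[0] = ci + M.site_off * ui; fi[0] = spi;
  si[1] = ci - M.site_off * ui; fi[1] = smi;
  sj[0] = cj + M.site_off * uj; fj[0] = spj;
  sj[1] = cj - M.site_off * uj; fj[1] = smj;
  for (int a = 0; a < 2; ++a) {
    if (!fi[a]) continue;
    for (int b = 0; b < 2; ++b) {
      if (!fj[b]) continue;
      if (norm2(si[a] - sj[b]) < M.delta2) e -= 1.0;
    }
  }
  return e;
}

// ---------------------------------------------------------------------------
// Cell list
// ---------------------------------------------------------------------------
struct CellList {
  int m;  // cells per dimension (m >= 3 to be useful, else brute force)
  double box;
  std::vector<int> head;
  std::vector<int> nxt;
  bool brute;

  void build(const std::vector<Vec3>& c, double box_, double cutoff) {
    box = box_;
    m = (int)std::floor(box / cutoff);
    brute = (m < 3);
    int n = (int)c.size();
    nxt.assign(n, -1);
    if (brute) return;
    head.assign((size_t)m * m * m, -1);
    for (int i = 0; i < n; ++i) insert(i, c[i]);
  }
  inline int cell_of(Vec3 p) const {
    int ix = (int)std::floor(p.x / box * m); if (ix >= m) ix = m - 1; if (ix < 0) ix = 0;
    int iy = (int)std::floor(p.y / box * m); if (iy >= m) iy = m - 1; if (iy < 0) iy = 0;
    int iz = (int)std::floor(p.z / box * m); if (iz >= m) iz = m - 1; if (iz < 0) iz = 0;
    return (ix * m + iy) * m + iz;
  }
  inline void insert(int i, Vec3 p) {
    int c = cell_of(p);
    nxt[i] = head[c];
    head[c] = i;
  }
  inline void remove(int i, Vec3 p) {
    int c = cell_of(p);
    int j = head[c];
    if (j == i) { head[c] = nxt[i]; return; }
    while (j >= 0) {
      if (nxt[j] == i) { nxt[j] = nxt[i]; return; }
      j = nxt[j];
    }
  }
  // gather indices in the 27 cells around p into out (may contain duplicates
  // across calls; caller dedupes with a mark array)
  template <typename F>
  void for_neighbors(Vec3 p, int nparticles, F f) const {
    if (brute) {
      for (int j = 0; j < nparticles; ++j) f(j);
      return;
    }
    int ix = (int)std::floor(p.x / box * m); if (ix >= m) ix = m - 1; if (ix < 0) ix = 0;
    int iy = (int)std::floor(p.y / box * m); if (iy >= m) iy = m - 1; if (iy < 0) iy = 0;
    int iz = (int)std::floor(p.z / box * m); if (iz >= m) iz = m - 1; if (iz < 0) iz = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int cx = (ix + dx + m) % m, cy = (iy + dy + m) % m, cz = (iz + dz + m) % m;
          int j = head[(cx * m + cy) * m + cz];
          while (j >= 0) { f(j); j = nxt[j]; }
        }
  }
};

// ---------------------------------------------------------------------------
// Full-system energy (all pairs, O(N^2)); exported for cache validation.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double total_energy_cpp(NumericMatrix centers, NumericMatrix axes,
                        IntegerVector site_plus, IntegerVector site_minus,
                        double D, double L, double delta, double box) {
  int n = centers.nrow();
  Model M;
  M.h = L / 2.0;
  M.r = D / 2.0;
  M.site_off = L / 2.0 + 0.15 * D / 2.0;
  M.delta2 = delta * delta;
  M.box = box;
  double E = 0.0;
  for (int i = 0; i < n; ++i) {
    Vec3 ci = v3(centers(i, 0), centers(i, 1), centers(i, 2));
    Vec3 ui = v3(axes(i, 0), axes(i, 1), axes(i, 2));
    for (int j = i + 1; j < n; ++j) {
      Vec3 cj = v3(centers(j, 0), centers(j, 1), centers(j, 2));
      Vec3 uj = v3(axes(j, 0), axes(j, 1), axes(j, 2));
      Vec3 dc = min_image(cj - ci, box);
      E += sw_energy_pair(ci, ui, site_plus[i], site_minus[i],
                          ci + dc, uj, site_plus[j], site_minus[j], M);
    }
  }
  return E;
}

// any overlap among all pairs (validation helper)
// [[Rcpp::export]]
IntegerMatrix overlapping_pairs_cpp(NumericMatrix centers, NumericMatrix axes,
                                    double D, double L, double box) {
  int n = centers.nrow();
  double h = L / 2.0, r = D / 2.0;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    Vec3 ci = v3(centers(i, 0), centers(i, 1), centers(i, 2));
    Vec3 ui = v3(axes(i, 0), axes(i, 1), axes(i, 2));
    for (int j = i + 1; j < n; ++j) {
      Vec3 cj = v3(centers(j, 0), centers(j, 1), centers(j, 2));
      Vec3 uj = v3(axes(j, 0), axes(j, 1), axes(j, 2));
      Vec3 dc = min_image(cj - ci, box);
      if (cyl_overlap(ci, ui, h, r, ci + dc, uj, h, r)) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out((int)ii.size(), 2);
  for (int k = 0; k < (int)ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// ---------------------------------------------------------------------------
// Metropolis MC kernel.
//
// cov_partner / cov_face encode trimer tethers: for particle i, cov_partner
// lists tethered particles (0-based; -1 = none, up to 2 entries), cov_face
// the face of i carrying the covalent site for that tether (+1/-1).
// ---------------------------------------------------------------------------
static inline Vec3 rim_site(Vec3 c, Vec3 u, Vec3 e, int face, double h, double r) {
  return c + (face * h) * u + r * e;
}

static inline Vec3 rodrigues(Vec3 v, Vec3 k, double ct, double st) {
  return ct * v + st * cross(k, v) + (dot(k, v) * (1.0 - ct)) * k;
}

// [[Rcpp::export]]
List run_mc_cpp(NumericMatrix centers0, NumericMatrix axes0, NumericMatrix ex0,
                IntegerVector site_plus, IntegerVector site_minus,
                IntegerMatrix cov_partner, IntegerMatrix cov_face,
                double D, double L, double D0,
                double delta, double delta_cov, double Tstar, double box,
                int n_equil, int n_prod, int sample_every,
                double max_tr, double max_rot, bool tune, bool trimer) {
  int n = centers0.nrow();
  Model M;
  M.h = L / 2.0;
  M.r = D / 2.0;
  M.site_off = L / 2.0 + 0.15 * D / 2.0;
  M.delta2 = delta * delta;
  M.delta_cov2 = delta_cov * delta_cov;
  M.box = box;
  M.Tstar = Tstar;

  std::vector<Vec3> C(n), U(n), E(n);
  for (int i = 0; i < n; ++i) {
    C[i] = v3(centers0(i, 0), centers0(i, 1), centers0(i, 2));
    U[i] = normalize(v3(axes0(i, 0), axes0(i, 1), axes0(i, 2)));
    E[i] = v3(ex0(i, 0), ex0(i, 1), ex0(i, 2));
  }

  // interaction cutoff: larger of hard-core reach and site reach
  double reach_hc = 2.0 * std::sqrt(M.h * M.h + M.r * M.r);
  double reach_sw = 2.0 * M.site_off + delta;
  double cutoff = std::max(reach_hc, reach_sw) * 1.001;
  CellList cl;
  cl.build(C, box, cutoff);

  // initial energy
  double Etot = 0.0;
  {
    std::vector<char> seen(n, 0);
    for (int i = 0; i < n; ++i) {
      Vec3 ci = C[i], ui = U[i];
      double Ei = 0.0;
      cl.for_neighbors(ci, n, [&](int j) {
        if (j <= i || seen[j]) return;
        seen[j] = 1;
        Vec3 dc = min_image(C[j] - ci, box);
        Ei += sw_energy_pair(ci, ui, site_plus[i], site_minus[i],
                             ci + dc, U[j], site_plus[j], site_minus[j], M);
      });
      cl.for_neighbors(ci, n, [&](int j) { seen[j] = 0; });
      Etot += Ei;
    }
  }

  int n_sweeps = n_equil + n_prod;
  NumericVector energy_trace(n_sweeps);
  std::vector<char> mark(n, 0);
  std::vector<int> nbrs;
  nbrs.reserve(256);

  long acc_tr = 0, att_tr = 0, acc_rot = 0, att_rot = 0;
  long tune_acc_tr = 0, tune_att_tr = 0, tune_acc_rot = 0, tune_att_rot = 0;
  const int TUNE_EVERY = 200;  // sweeps

  int n_samples = n_prod / sample_every;
  List snap_list(n_samples);  // pre-allocated: entries stay GC-protected
  int snap_at = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int step = 0; step < n; ++step) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      bool is_tr = unif_rand() < 0.5;
      Vec3 cn = C[i], un = U[i], en = E[i];
      if (is_tr) {
        ++att_tr; ++tune_att_tr;
        cn.x += (2.0 * unif_rand() - 1.0) * max_tr;
        cn.y += (2.0 * unif_rand() - 1.0) * max_tr;
        cn.z += (2.0 * unif_rand() - 1.0) * max_tr;
        cn.x -= box * std::floor(cn.x / box);
        cn.y -= box * std::floor(cn.y / box);
        cn.z -= box * std::floor(cn.z / box);
      } else {
        ++att_rot; ++tune_att_rot;
        // Marsaglia random unit axis
        double a1, a2, s;
        do {
          a1 = 2.0 * unif_rand() - 1.0;
          a2 = 2.0 * unif_rand() - 1.0;
          s = a1 * a1 + a2 * a2;
        } while (s >= 1.0);
        double root = 2.0 * std::sqrt(1.0 - s);
        Vec3 k = v3(a1 * root, a2 * root, 1.0 - 2.0 * s);
        double ang = (2.0 * unif_rand() - 1.0) * max_rot;
        double ct = std::cos(ang), st = std::sin(ang);
        un = normalize(rodrigues(U[i], k, ct, st));
        if (trimer) {
          en = rodrigues(E[i], k, ct, st);
          en = normalize(en - dot(en, un) * un);  // keep frame orthonormal
        }
      }

      // covalent tethers (trimer mode): reject if any exceeds delta_cov
      bool ok = true;
      if (trimer) {
        for (int t = 0; t < 2 && ok; ++t) {
          int j = cov_partner(i, t);
          if (j < 0) continue;
          int fi = cov_face(i, t);
          Vec3 site_i = rim_site(v3(0, 0, 0), un, en, fi, M.h, M.r);  // body offset
          // partner face is the opposite-facing one stored on j's side
          int tj = (cov_partner(j, 0) == i) ? 0 : 1;
          int fj = cov_face(j, tj);
          Vec3 dc = min_image(C[j] - cn, box);
          Vec3 site_j = dc + rim_site(v3(0, 0, 0), U[j], E[j], fj, M.h, M.r);
          if (norm2(site_i - site_j) > M.delta_cov2) ok = false;
        }
        if (!ok) continue;
      }

      // neighbor union over old and new positions
      nbrs.clear();
      cl.for_neighbors(C[i], n, [&](int j) {
        if (j != i && !mark[j]) { mark[j] = 1; nbrs.push_back(j); }
      });
      if (is_tr) {
        cl.for_neighbors(cn, n, [&](int j) {
          if (j != i && !mark[j]) { mark[j] = 1; nbrs.push_back(j); }
        });
      }

      // hard-core overlap at the proposed configuration
      for (size_t q = 0; q < nbrs.size() && ok; ++q) {
        int j = nbrs[q];
        Vec3 dc = min_image(C[j] - cn, box);
        if (norm2(dc) > cutoff * cutoff) continue;
        if (cyl_overlap(cn, un, M.h, M.r, cn + dc, U[j], M.h, M.r)) ok = false;
      }

      double dE = 0.0;
      if (ok) {
        double Eold = 0.0, Enew = 0.0;
        for (size_t q = 0; q < nbrs.size(); ++q) {
          int j = nbrs[q];
          Vec3 dco = min_image(C[j] - C[i], box);
          Eold += sw_energy_pair(C[i], U[i], site_plus[i], site_minus[i],
                                 C[i] + dco, U[j], site_plus[j], site_minus[j], M);
          Vec3 dcn = min_image(C[j] - cn, box);
          Enew += sw_energy_pair(cn, un, site_plus[i], site_minus[i],
                                 cn + dcn, U[j], site_plus[j], site_minus[j], M);
        }
        dE = Enew - Eold;
        if (dE > 0.0 && unif_rand() >= std::exp(-dE / Tstar)) ok = false;
      }

      for (size_t q = 0; q < nbrs.size(); ++q) mark[nbrs[q]] = 0;

      if (ok) {
        if (is_tr) {
          if (!cl.brute) {
            cl.remove(i, C[i]);
            cl.insert(i, cn);
          }
          C[i] = cn;
          ++acc_tr; ++tune_acc_tr;
        } else {
          U[i] = un;
          if (trimer) E[i] = en;
          ++acc_rot; ++tune_acc_rot;
        }
        Etot += dE;
      }
    }

    energy_trace[sweep] = Etot;

    // amplitude tuning during equilibration only
    if (tune && sweep < n_equil && (sweep + 1) % TUNE_EVERY == 0) {
      if (tune_att_tr > 0) {
        double r = (double)tune_acc_tr / tune_att_tr;
        if (r > 0.5) max_tr *= 1.2; else if (r < 0.3) max_tr *= 0.8;
        if (max_tr > box / 4.0) max_tr = box / 4.0;
        if (max_tr < 1e-3) max_tr = 1e-3;
      }
      if (tune_att_rot > 0) {
        double r = (double)tune_acc_rot / tune_att_rot;
        if (r > 0.5) max_rot *= 1.2; else if (r < 0.3) max_rot *= 0.8;
        if (max_rot > M_PI) max_rot = M_PI;
        if (max_rot < 1e-3) max_rot = 1e-3;
      }
      tune_acc_tr = tune_att_tr = tune_acc_rot = tune_att_rot = 0;
    }

    // production sampling
    if (sweep >= n_equil && ((sweep - n_equil + 1) % sample_every == 0)) {
      NumericMatrix sc(n, 3), sa(n, 3), se(n, 3);
      for (int i = 0; i < n; ++i) {
        sc(i, 0) = C[i].x; sc(i, 1) = C[i].y; sc(i, 2) = C[i].z;
        sa(i, 0) = U[i].x; sa(i, 1) = U[i].y; sa(i, 2) = U[i].z;
        se(i, 0) = E[i].x; se(i, 1) = E[i].y; se(i, 2) = E[i].z;
      }
      if (snap_at < n_samples) {
        snap_list[snap_at++] = List::create(_["centers"] = sc, _["axes"] = sa,
                                            _["ex"] = se, _["energy"] = Etot,
                                            _["sweep"] = sweep + 1);
      }
    }
    if ((sweep & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fc(n, 3), fa(n, 3), fe(n, 3);
  for (int i = 0; i < n; ++i) {
    fc(i, 0) = C[i].x; fc(i, 1) = C[i].y; fc(i, 2) = C[i].z;
    fa(i, 0) = U[i].x; fa(i, 1) = U[i].y; fa(i, 2) = U[i].z;
    fe(i, 0) = E[i].x; fe(i, 1) = E[i].y; fe(i, 2) = E[i].z;
  }

  return List::create(
      _["snapshots"] = snap_list, _["energy_trace"] = energy_trace,
      _["centers"] = fc, _["axes"] = fa, _["ex"] = fe, _["energy"] = Etot,
      _["acc_translation"] = att_tr > 0 ? (double)acc_tr / att_tr : NA_REAL,
      _["acc_rotation"] = att_rot > 0 ? (double)acc_rot / att_rot : NA_REAL,
      _["max_translation"] = max_tr, _["max_rotation"] = max_rot);
}

// ---------------------------------------------------------------------------
// Pair-distance histogram (optionally minimum-image), for S(Q) and Debye sums.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector pair_histogram_cpp(NumericMatrix pts, double box, double dr,
                                 double rmax, bool minimage) {
  int n = pts.nrow();
  int nb = (int)std::ceil(rmax / dr);
  NumericVector counts(nb);
  for (int i = 0; i < n; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      if (minimage) {
        dx -= box * std::nearbyint(dx / box);
        dy -= box * std::nearbyint(dy / box);
        dz -= box * std::nearbyint(dz / box);
      }
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < rmax) counts[(int)(r / dr)] += 1.0;
    }
  }
  return counts;
}

// exact Debye sum over a (small) point set: I(Q) = sum_jk sinc(Q r_jk)
// [[Rcpp::export]]
NumericVector debye_sum_cpp(NumericMatrix pts, NumericVector Q) {
  int n = pts.nrow(), nq = Q.size();
  NumericVector I(nq);
  std::vector<double> rr;
  rr.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j, 0) - pts(i, 0), dy = pts(j, 1) - pts(i, 1),
             dz = pts(j, 2) - pts(i, 2);
      rr.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
    }
  for (int q = 0; q < nq; ++q) {
    double s = (double)n;  // self terms
    double Qv = Q[q];
    if (Qv <= 0.0) {
      s += 2.0 * rr.size();
    } else {
      for (size_t k = 0; k < rr.size(); ++k) {
        double x = Qv * rr[k];
        s += 2.0 * (x < 1e-8 ? 1.0 : std::sin(x) / x);
      }
    }
    I[q] = s;
  }
  return I;
}

// overlap + SW bond count for a batch of two-particle configurations
// (brute-force configurational-integral oracle support)
// [[Rcpp::export]]
List pair_config_stats_cpp(NumericMatrix c2, NumericMatrix u1, NumericMatrix u2,
                           double D, double L, double delta) {
  int n = c2.nrow();
  double h = L / 2.0, r = D / 2.0, off = L / 2.0 + 0.15 * D / 2.0;
  double d2 = delta * delta;
  LogicalVector ov(n);
  IntegerVector bonds(n);
  for (int i = 0; i < n; ++i) {
    Vec3 c = v3(c2(i, 0), c2(i, 1), c2(i, 2));
    Vec3 ua = normalize(v3(u1(i, 0), u1(i, 1), u1(i, 2)));
    Vec3 ub = normalize(v3(u2(i, 0), u2(i, 1), u2(i, 2)));
    ov[i] = cyl_overlap(v3(0, 0, 0), ua, h, r, c, ub, h, r);
    int nb = 0;
    for (int a = -1; a <= 1; a += 2)
      for (int b = -1; b <= 1; b += 2) {
        Vec3 sa = (a * off) * ua;
        Vec3 sb = c + (b * off) * ub;
        if (norm2(sa - sb) < d2) ++nb;
      }
    bonds[i] = nb;
  }
  return List::create(_["overlap"] = ov, _["bonds"] = bonds);
}
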