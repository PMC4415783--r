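// Overdamped mass-spring dynamics of gliding rod-shaped cells.
//
// Internal unit system: micrometre, second, piconewton.
//   spring constants      pN/um   (1 N/m  == 1e6 pN/um)
//   angular stiffness     pN*um   (1 N*m  == 1e18 pN*um)
//   drag coefficients     pN*s/um
//   energies              pN*um   (1 pN*um == 1e-18 J)
//
// Particle layout: positions is a (n_cells * np) x 2 matrix, cells in
// blocks of np consecutive rows. Segment g (global) belongs to cell
// g / (np - 1) and joins particles g%(np-1) and g%(np-1)+1 of that cell.
//
// Head convention: particle 0 is the head when polarity ke = +1, particle
// np-1 when ke = -1 (the chain tangent runs along increasing index, the
// gliding direction is -ke * tangent).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3,unroll-loops")
#endif

static inline double wrapc(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x = 0.0; // floor rounding edge
  return x;
}
// minimum-image difference
static inline double mi(double dx, double L) {
  return dx - L * std::round(dx / L);
}

struct Par {
  int np;
  double W, l0, klin, ka, kc, Feng, gpar, dt;
  double Lx, Ly;
  double dg, Fg, kg, Fs, dxs, TR; // TR in minutes, may be +Inf
  int mode;                       // 0 none, 1 passive, 2 active, 3 adhesion, 4 slime
  int guide_all;                  // 0: nearest qualifying tail per head; 1: all in range
  bool periodic;
};

static Par parse_par(const List& p) {
  Par q;
  q.np   = as<int>(p["n_particles"]);
  q.W    = as<double>(p["W"]);
  q.l0   = as<double>(p["seg_len"]);
  q.klin = as<double>(p["k_lin"]);
  q.ka   = as<double>(p["k_a"]);
  q.kc   = as<double>(p["k_c"]);
  q.Feng = as<double>(p["F_engine"]);
  q.gpar = as<double>(p["gamma_particle"]);
  q.dt   = as<double>(p["dt"]);
  q.Lx   = as<double>(p["Lx"]);
  q.Ly   = as<double>(p["Ly"]);
  q.dg   = as<double>(p["d_g"]);
  q.Fg   = as<double>(p["F_g_max"]);
  q.kg   = q.Fg / q.dg;
  q.Fs   = as<double>(p["F_s_max"]);
  q.dxs  = as<double>(p["dx_slime"]);
  q.TR   = as<double>(p["T_R"]);
  q.mode = as<int>(p["mode"]);
  q.guide_all = p.containsElementNamed("guide_all") ?
    as<int>(p["guide_all"]) : 0;
  q.periodic = true;
  return q;
}

// ---------------------------------------------------------------------------
// closest points between two 2D segments (p1,p2) and (q1,q2).
// Returns s, t in [0,1] and the distance. For (near-)parallel segments with
// a continuum of minimisers the midpoint of the overlap interval is used.
struct Closest { double s, t, d, ux, uy; };
// cheap variant: closest-point parameters and the squared distance, no sqrt
struct Closest2 { double s, t, d2, vx, vy; };

static Closest2 seg_closest_raw2(double p1x, double p1y, double p2x, double p2y,
                                 double q1x, double q1y, double q2x, double q2y) {
  const double d1x = p2x - p1x, d1y = p2y - p1y;
  const double d2x = q2x - q1x, d2y = q2y - q1y;
  const double rx = p1x - q1x, ry = p1y - q1y;
  const double a = d1x * d1x + d1y * d1y;
  const double e = d2x * d2x + d2y * d2y;
  const double f = d2x * rx + d2y * ry;
  const double c = d1x * rx + d1y * ry;
  const double b = d1x * d2x + d1y * d2y;
  const double denom = a * e - b * b;
  double s, t;
  if (a <= 0 || e <= 0) stop("zero-length segment in closest-point query");
  if (denom > 1e-12 * a * e) {
    s = (b * f - c * e) / denom;
    s = std::min(1.0, std::max(0.0, s));
    t = (b * s + f) / e;
    if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
  } else {
    // parallel: project q's endpoints on p's axis, take overlap midpoint
    double u1 = -c / a;                 // param of q1 on p
    double u2 = (b - c) / a;            // param of q2 on p
    double lo = std::max(0.0, std::min(u1, u2));
    double hi = std::min(1.0, std::max(u1, u2));
    if (lo <= hi) {
      s = 0.5 * (lo + hi);
    } else {
      s = (std::min(u1, u2) > 1.0) ? 1.0 : 0.0;
    }
    t = ((p1x + s * d1x - q1x) * d2x + (p1y + s * d1y - q1y) * d2y) / e;
    t = std::min(1.0, std::max(0.0, t));
  }
  const double cx = p1x + s * d1x, cy = p1y + s * d1y;
  const double ex = q1x + t * d2x, ey = q1y + t * d2y;
  Closest2 out;
  out.s = s; out.t = t;
  out.vx = ex - cx; out.vy = ey - cy;
  out.d2 = out.vx * out.vx + out.vy * out.vy;
  return out;
}

static Closest finish_closest(const Closest2& c2) {
  Closest out;
  out.s = c2.s; out.t = c2.t;
  out.d = std::sqrt(c2.d2);
  if (out.d > 1e-12) { out.ux = c2.vx / out.d; out.uy = c2.vy / out.d; }
  else { out.ux = 1.0; out.uy = 0.0; } // degenerate fallback axis
  return out;
}

static Closest seg_closest_raw(double p1x, double p1y, double p2x, double p2y,
                               double q1x, double q1y, double q2x, double q2y) {
  return finish_closest(seg_closest_raw2(p1x, p1y, p2x, p2y,
                                         q1x, q1y, q2x, q2y));
}

// periodic version: each segment is first unwrapped about its own first
// endpoint (stored endpoints may straddle the seam), then q is shifted by
// the minimum image of the midpoint gap
static Closest2 seg_closest_per2(const double* P, int i1, int i2, int j1,
                                 int j2, const Par& par) {
  const double p1x = P[2 * i1], p1y = P[2 * i1 + 1];
  const double p2x = p1x + mi(P[2 * i2] - p1x, par.Lx);
  const double p2y = p1y + mi(P[2 * i2 + 1] - p1y, par.Ly);
  const double q1x = P[2 * j1], q1y = P[2 * j1 + 1];
  const double q2x = q1x + mi(P[2 * j2] - q1x, par.Lx);
  const double q2y = q1y + mi(P[2 * j2 + 1] - q1y, par.Ly);
  double dmx = 0.5 * (q1x + q2x) - 0.5 * (p1x + p2x);
  double dmy = 0.5 * (q1y + q2y) - 0.5 * (p1y + p2y);
  double shx = mi(dmx, par.Lx) - dmx;
  double shy = mi(dmy, par.Ly) - dmy;
  return seg_closest_raw2(p1x, p1y, p2x, p2y,
                          q1x + shx, q1y + shy, q2x + shx, q2y + shy);
}

static Closest seg_closest_per(const double* P, int i1, int i2, int j1, int j2,
                               const Par& par) {
  return finish_closest(seg_closest_per2(P, i1, i2, j1, j2, par));
}

// ---------------------------------------------------------------------------
// internal forces of one cell block starting at particle base

static void add_linear(const double* P, double* F, int base, const Par& par) {
  for (int i = 0; i < par.np - 1; ++i) {
    int ia = base + i, ib = base + i + 1;
    double dx = mi(P[2 * ib] - P[2 * ia], par.Lx);
    double dy = mi(P[2 * ib + 1] - P[2 * ia + 1], par.Ly);
    double l = std::sqrt(dx * dx + dy * dy);
    if (l < 1e-12) stop("degenerate zero-length segment");
    double fmag = par.klin * (l - par.l0);
    double fx = fmag * dx / l, fy = fmag * dy / l;
    F[2 * ia] += fx;  F[2 * ia + 1] += fy;
    F[2 * ib] -= fx;  F[2 * ib + 1] -= fy;
  }
}

static void add_angular(const double* P, double* F, int base, const Par& par) {
  if (par.ka <= 0) return;
  for (int i = 1; i < par.np - 1; ++i) {
    int im = base + i - 1, i0 = base + i, ip = base + i + 1;
    double v1x = mi(P[2 * i0] - P[2 * im], par.Lx);
    double v1y = mi(P[2 * i0 + 1] - P[2 * im + 1], par.Ly);
    double v2x = mi(P[2 * ip] - P[2 * i0], par.Lx);
    double v2y = mi(P[2 * ip + 1] - P[2 * i0 + 1], par.Ly);
    double a2 = v1x * v1x + v1y * v1y;
    double b2 = v2x * v2x + v2y * v2y;
    if (a2 < 1e-24 || b2 < 1e-24) stop("degenerate segment at bending joint");
    double cross = v1x * v2y - v1y * v2x;
    double dot = v1x * v2x + v1y * v2y;
    double th = std::atan2(cross, dot); // deviation from straight
    // dtheta/dp via polar-angle gradients of the two bond vectors
    double g1x = -v1y / a2, g1y = v1x / a2; // d(phi1)/d v1 = perp(v1)/|v1|^2
    double g2x = -v2y / b2, g2y = v2x / b2;
    double k = -par.ka * th; // force = -ka * th * dth/dp
    // dth/dp_{i-1} = +perp(v1)/a2 ; dth/dp_i = -perp(v1)/a2 - perp(v2)/b2 ;
    // dth/dp_{i+1} = +perp(v2)/b2
    F[2 * im] += k * g1x;      F[2 * im + 1] += k * g1y;
    F[2 * i0] += k * (-g1x - g2x); F[2 * i0 + 1] += k * (-g1y - g2y);
    F[2 * ip] += k * g2x;      F[2 * ip + 1] += k * g2y;
  }
}

// unit tangent at particle i of the cell starting at base (along increasing
// index; central difference inside, one-sided at the ends)
static inline void tangent_at(const double* P, int base, int i, const Par& par,
                              double* tx, double* ty) {
  int a = (i == 0) ? base : base + i - 1;
  int b = (i == par.np - 1) ? base + i : base + i + 1;
  double dx = mi(P[2 * b] - P[2 * a], par.Lx);
  double dy = mi(P[2 * b + 1] - P[2 * a + 1], par.Ly);
  double l = std::sqrt(dx * dx + dy * dy);
  if (l < 1e-12) stop("degenerate tangent");
  *tx = dx / l; *ty = dy / l;
}

static void add_engine(const double* P, double* F, int base, int ke,
                       double mult, const Par& par) {
  double fpp = mult * par.Feng / par.np;
  for (int i = 0; i < par.np; ++i) {
    double tx, ty;
    tangent_at(P, base, i, par, &tx, &ty);
    // gliding direction is -ke * tangent (head sits at index 0 for ke=+1)
    F[2 * (base + i)] += -ke * fpp * tx;
    F[2 * (base + i) + 1] += -ke * fpp * ty;
  }
}

// ---------------------------------------------------------------------------
// broad phase: uniform spatial hash over segment midpoints

static void build_pairs(const double* P, int nc, const Par& par, double rlist,
                        std::vector<std::pair<int,int> >& pairs) {
  pairs.clear();
  const int nseg_per = par.np - 1;
  const int S = nc * nseg_per;
  const double reach = rlist + par.l0; // midpoint distance bound
  std::vector<double> mx(S), my(S);
  for (int g = 0; g < S; ++g) {
    int c = g / nseg_per, i = g % nseg_per;
    int ia = c * par.np + i, ib = ia + 1;
    double ax = P[2 * ia], ay = P[2 * ia + 1];
    double bx = ax + mi(P[2 * ib] - ax, par.Lx);
    double by = ay + mi(P[2 * ib + 1] - ay, par.Ly);
    mx[g] = wrapc(0.5 * (ax + bx), par.Lx);
    my[g] = wrapc(0.5 * (ay + by), par.Ly);
  }
  auto consider = [&](int g, int h) {
    if (g == h) return;
    int cg = g / nseg_per, ch = h / nseg_per;
    if (cg == ch && std::abs(g - h) == 1) return; // same-cell adjacent
    double dx = mi(mx[g] - mx[h], par.Lx), dy = mi(my[g] - my[h], par.Ly);
    if (dx * dx + dy * dy < reach * reach)
      pairs.push_back(std::make_pair(std::min(g, h), std::max(g, h)));
  };
  const double binmin = par.l0 + rlist;
  int nbx = std::max(1, (int)std::floor(par.Lx / binmin));
  int nby = std::max(1, (int)std::floor(par.Ly / binmin));
  if (nbx < 4 || nby < 4 || S < 64) {
    for (int g = 0; g < S; ++g)
      for (int h = g + 1; h < S; ++h) consider(g, h);
    return;
  }
  const double bx = par.Lx / nbx, by = par.Ly / nby;
  std::vector<std::vector<int> > bins((size_t)nbx * nby);
  for (int g = 0; g < S; ++g) {
    int ix = std::min(nbx - 1, (int)(mx[g] / bx));
    int iy = std::min(nby - 1, (int)(my[g] / by));
    bins[(size_t)iy * nbx + ix].push_back(g);
  }
  const int offs[4][2] = { {1, 0}, {-1, 1}, {0, 1}, {1, 1} };
  for (int iy = 0; iy < nby; ++iy) {
    for (int ix = 0; ix < nbx; ++ix) {
      const std::vector<int>& B = bins[(size_t)iy * nbx + ix];
      for (size_t u = 0; u < B.size(); ++u)
        for (size_t v = u + 1; v < B.size(); ++v) consider(B[u], B[v]);
      for (int o = 0; o < 4; ++o) {
        int jx = (ix + offs[o][0] + nbx) % nbx;
        int jy = (iy + offs[o][1] + nby) % nby;
        const std::vector<int>& C = bins[(size_t)jy * nbx + jx];
        for (size_t u = 0; u < B.size(); ++u)
          for (size_t v = 0; v < C.size(); ++v) consider(B[u], C[v]);
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_broad_phase(NumericMatrix pos, List params) {
  Par par = parse_par(params);
  int nc = pos.nrow() / par.np;
  std::vector<double> P(pos.nrow() * 2);
  for (int i = 0; i < pos.nrow(); ++i) { P[2*i] = pos(i,0); P[2*i+1] = pos(i,1); }
  std::vector<std::pair<int,int> > pairs;
  build_pairs(P.data(), nc, par, par.W + par.dg, pairs);
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  IntegerMatrix out(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first; out(k, 1) = pairs[k].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// narrow phase: contacts (collisions) with the double-contact and
// adjacent-segment de-duplication, and head-to-tail guiding pair selection

struct Contact { int ga, gb; double s, t, d, ux, uy; };
struct GuidePair {
  int follower, leader;      // cell ids
  double d, ux, uy;          // closest distance, unit vector head -> tail
};

static inline int head_particle(int c, int ke, const Par& par) {
  return c * par.np + (ke == 1 ? 0 : par.np - 1);
}
static inline int tail_particle(int c, int ke, const Par& par) {
  return c * par.np + (ke == 1 ? par.np - 1 : 0);
}
static inline int head_segment(int c, int ke, const Par& par) {
  return c * (par.np - 1) + (ke == 1 ? 0 : par.np - 2);
}
static inline int tail_segment(int c, int ke, const Par& par) {
  return c * (par.np - 1) + (ke == 1 ? par.np - 2 : 0);
}

// Remove, among contacts sharing one segment and hitting two adjacent
// segments of the same other cell, the farther of the two (the shared
// endpoint otherwise yields doubled contact forces and spurious friction).
static void dedup_contacts(std::vector<Contact>& con, const Par& par) {
  const int nseg_per = par.np - 1;
  size_t n = con.size();
  if (n < 2) return;
  std::vector<char> alive(n, 1);
  std::vector<int> idx(n);
  for (size_t i = 0; i < n; ++i) idx[i] = (int)i;
  // pass keyed on (ga, gb) then on (gb, ga); contacts already arrive
  // sorted by (ga, gb) because the pair list is sorted, so only the
  // second pass needs a sort
  for (int pass = 0; pass < 2; ++pass) {
    if (pass == 1)
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      const Contact &A = con[a], &B = con[b];
      int a1 = pass == 0 ? A.ga : A.gb, a2 = pass == 0 ? A.gb : A.ga;
      int b1 = pass == 0 ? B.ga : B.gb, b2 = pass == 0 ? B.gb : B.ga;
      if (a1 != b1) return a1 < b1;
      return a2 < b2;
    });
    for (size_t k = 1; k < n; ++k) {
      int i = idx[k - 1], j = idx[k];
      if (!alive[i] || !alive[j]) continue;
      const Contact &A = con[i], &B = con[j];
      int a1 = pass == 0 ? A.ga : A.gb, a2 = pass == 0 ? A.gb : A.ga;
      int b1 = pass == 0 ? B.ga : B.gb, b2 = pass == 0 ? B.gb : B.ga;
      if (a1 != b1) continue;
      if (a2 / nseg_per != b2 / nseg_per) continue; // different cells
      if (std::abs(a2 - b2) != 1) continue;         // not adjacent
      if (A.d < B.d) alive[j] = 0;
      else if (B.d < A.d) alive[i] = 0;
      else alive[(a2 < b2) ? j : i] = 0;            // tie: keep lower index
    }
  }
  std::vector<Contact> keep;
  keep.reserve(n);
  for (size_t i = 0; i < n; ++i) if (alive[i]) keep.push_back(con[i]);
  con.swap(keep);
}

struct Workspace {
  std::vector<double> bestd;
  std::vector<int> bestl;
  std::vector<GuidePair> cand;
  Workspace(int nc) : bestd(nc), bestl(nc), cand(nc) {}
};

// precomputed pair record for the inner loop: particle indices, owning
// cells, and whether the pair may straddle the periodic boundary
struct PairRec { int g, h, ia, ja, cg, ch; bool wrap; };

static void make_pair_recs(const std::vector<std::pair<int,int> >& pairs,
                           const double* P, const Par& par,
                           std::vector<PairRec>& recs) {
  const int nseg_per = par.np - 1;
  // margin inside which minimum-image arithmetic is required; the Verlet
  // skin keeps displacements between rebuilds far below this
  const double margin = 3.0;
  recs.clear();
  recs.reserve(pairs.size());
  for (size_t k = 0; k < pairs.size(); ++k) {
    PairRec r;
    r.g = pairs[k].first; r.h = pairs[k].second;
    r.cg = r.g / nseg_per; r.ch = r.h / nseg_per;
    r.ia = r.cg * par.np + r.g % nseg_per;
    r.ja = r.ch * par.np + r.h % nseg_per;
    bool near = false;
    const int ids[4] = { r.ia, r.ia + 1, r.ja, r.ja + 1 };
    for (int m = 0; m < 4; ++m) {
      double x = P[2 * ids[m]], y = P[2 * ids[m] + 1];
      if (x < margin || x > par.Lx - margin ||
          y < margin || y > par.Ly - margin) near = true;
    }
    r.wrap = near;
    recs.push_back(r);
  }
}

static void find_contacts(const double* P, int nc, const IntegerVector& ke,
                          const Par& par,
                          const std::vector<std::pair<int,int> >& pairs,
                          std::vector<Contact>& contacts,
                          std::vector<GuidePair>& guides,
                          Workspace& ws) {
  const int nseg_per = par.np - 1;
  const double W2 = par.W * par.W;
  const double R2 = (par.W + par.dg) * (par.W + par.dg);
  const bool short_range = par.mode >= 1 && par.mode <= 3;
  std::vector<GuidePair> all_guides;
  contacts.clear();
  std::fill(ws.bestd.begin(), ws.bestd.end(), R_PosInf);
  std::fill(ws.bestl.begin(), ws.bestl.end(), -1);
  for (size_t k = 0; k < pairs.size(); ++k) {
    int g = pairs[k].first, h = pairs[k].second;
    int cg = g / nseg_per, chh = h / nseg_per;
    int ia = cg * par.np + g % nseg_per;
    int ja = chh * par.np + h % nseg_per;
    Closest2 c2 = seg_closest_per2(P, ia, ia + 1, ja, ja + 1, par);
    if (c2.d2 >= R2) continue;
    if (c2.d2 < W2) {
      Closest cl = finish_closest(c2);
      Contact ct;
      ct.ga = g; ct.gb = h; ct.s = cl.s; ct.t = cl.t; ct.d = cl.d;
      ct.ux = cl.ux; ct.uy = cl.uy;
      contacts.push_back(ct);
    } else if (short_range && c2.d2 > W2) {
      // head of one cell vs tail of the other (self pairs allowed)
      for (int dir = 0; dir < 2; ++dir) {
        int gh = dir == 0 ? g : h, gt = dir == 0 ? h : g;
        int cf = gh / nseg_per, clr = gt / nseg_per;
        if (gh != head_segment(cf, ke[cf], par)) continue;
        if (gt != tail_segment(clr, ke[clr], par)) continue;
        Closest cl = finish_closest(c2);
        GuidePair gp;
        gp.follower = cf; gp.leader = clr; gp.d = cl.d;
        // unit vector from head closest point toward tail closest point
        if (dir == 0) { gp.ux = cl.ux; gp.uy = cl.uy; }
        else { gp.ux = -cl.ux; gp.uy = -cl.uy; }
        if (par.guide_all) {
          all_guides.push_back(gp);
        } else {
          double better = cl.d < ws.bestd[cf] ||
            (cl.d == ws.bestd[cf] && clr < ws.bestl[cf]);
          if (better) {
            ws.bestd[cf] = cl.d; ws.bestl[cf] = clr;
            ws.cand[cf] = gp;
          }
        }
      }
    }
  }
  dedup_contacts(contacts, par);
  guides.clear();
  if (par.guide_all) {
    guides.swap(all_guides);
  } else {
    for (int c = 0; c < nc; ++c)
      if (ws.bestl[c] >= 0) guides.push_back(ws.cand[c]);
  }
}

static void find_contacts_fast(const double* P, int nc,
                               const IntegerVector& ke, const Par& par,
                               const std::vector<PairRec>& recs,
                               std::vector<Contact>& contacts,
                               std::vector<GuidePair>& guides,
                               Workspace& ws) {
  const double W2 = par.W * par.W;
  const double R2 = (par.W + par.dg) * (par.W + par.dg);
  const bool short_range = par.mode >= 1 && par.mode <= 3;
  std::vector<GuidePair> all_guides;
  contacts.clear();
  std::fill(ws.bestd.begin(), ws.bestd.end(), R_PosInf);
  std::fill(ws.bestl.begin(), ws.bestl.end(), -1);
  for (size_t k = 0; k < recs.size(); ++k) {
    const PairRec& r = recs[k];
    Closest2 c2 = r.wrap
      ? seg_closest_per2(P, r.ia, r.ia + 1, r.ja, r.ja + 1, par)
      : seg_closest_raw2(P[2 * r.ia], P[2 * r.ia + 1],
                         P[2 * r.ia + 2], P[2 * r.ia + 3],
                         P[2 * r.ja], P[2 * r.ja + 1],
                         P[2 * r.ja + 2], P[2 * r.ja + 3]);
    if (c2.d2 >= R2) continue;
    if (c2.d2 < W2) {
      Closest cl = finish_closest(c2);
      Contact ct;
      ct.ga = r.g; ct.gb = r.h; ct.s = cl.s; ct.t = cl.t; ct.d = cl.d;
      ct.ux = cl.ux; ct.uy = cl.uy;
      contacts.push_back(ct);
    } else if (short_range && c2.d2 > W2) {
      for (int dir = 0; dir < 2; ++dir) {
        int gh = dir == 0 ? r.g : r.h, gt = dir == 0 ? r.h : r.g;
        int cf = dir == 0 ? r.cg : r.ch, clr = dir == 0 ? r.ch : r.cg;
        if (gh != head_segment(cf, ke[cf], par)) continue;
        if (gt != tail_segment(clr, ke[clr], par)) continue;
        Closest cl = finish_closest(c2);
        GuidePair gp;
        gp.follower = cf; gp.leader = clr; gp.d = cl.d;
        if (dir == 0) { gp.ux = cl.ux; gp.uy = cl.uy; }
        else { gp.ux = -cl.ux; gp.uy = -cl.uy; }
        if (par.guide_all) {
          all_guides.push_back(gp);
        } else {
          double better = cl.d < ws.bestd[cf] ||
            (cl.d == ws.bestd[cf] && clr < ws.bestl[cf]);
          if (better) {
            ws.bestd[cf] = cl.d; ws.bestl[cf] = clr;
            ws.cand[cf] = gp;
          }
        }
      }
    }
  }
  dedup_contacts(contacts, par);
  guides.clear();
  if (par.guide_all) {
    guides.swap(all_guides);
  } else {
    for (int c = 0; c < nc; ++c)
      if (ws.bestl[c] >= 0) guides.push_back(ws.cand[c]);
  }
}

// unified per-cell internal pass: bond vectors computed once and shared by
// the linear springs, bending springs, and engine (plus the optional
// constant head pull)
static void add_internal(const double* P, double* F, int base, int ke,
                         double mult, double pull, const Par& par) {
  const int nb = par.np - 1;
  double vx[64], vy[64], vl[64];
  if (nb >= 64) stop("n_particles too large for the internal-force buffer");
  // minimum-image arithmetic is only needed when the cell straddles the
  // periodic boundary; L + 1 um around particle 0 is a safe envelope
  const double m0x = P[2 * base], m0y = P[2 * base + 1];
  const double env = 2 * par.l0 * nb + 1.0;
  const bool nowrap = m0x > env && m0x < par.Lx - env &&
                      m0y > env && m0y < par.Ly - env;
  for (int i = 0; i < nb; ++i) {
    int ia = base + i;
    if (nowrap) {
      vx[i] = P[2 * ia + 2] - P[2 * ia];
      vy[i] = P[2 * ia + 3] - P[2 * ia + 1];
    } else {
      vx[i] = mi(P[2 * ia + 2] - P[2 * ia], par.Lx);
      vy[i] = mi(P[2 * ia + 3] - P[2 * ia + 1], par.Ly);
    }
    double l2 = vx[i] * vx[i] + vy[i] * vy[i];
    if (l2 < 1e-24) stop("degenerate zero-length segment");
    vl[i] = std::sqrt(l2);
  }
  // linear springs
  for (int i = 0; i < nb; ++i) {
    double fmag = par.klin * (vl[i] - par.l0) / vl[i];
    double fx = fmag * vx[i], fy = fmag * vy[i];
    int ia = base + i;
    F[2 * ia] += fx;     F[2 * ia + 1] += fy;
    F[2 * ia + 2] -= fx; F[2 * ia + 3] -= fy;
  }
  // bending springs
  if (par.ka > 0) {
    for (int i = 1; i < nb; ++i) {
      double a2 = vl[i - 1] * vl[i - 1], b2 = vl[i] * vl[i];
      double cross = vx[i - 1] * vy[i] - vy[i - 1] * vx[i];
      double dot = vx[i - 1] * vx[i] + vy[i - 1] * vy[i];
      double th = std::atan2(cross, dot);
      double g1x = -vy[i - 1] / a2, g1y = vx[i - 1] / a2;
      double g2x = -vy[i] / b2, g2y = vx[i] / b2;
      double kk = -par.ka * th;
      int i0 = base + i;
      F[2 * i0 - 2] += kk * g1x;          F[2 * i0 - 1] += kk * g1y;
      F[2 * i0] += kk * (-g1x - g2x);     F[2 * i0 + 1] += kk * (-g1y - g2y);
      F[2 * i0 + 2] += kk * g2x;          F[2 * i0 + 3] += kk * g2y;
    }
  }
  // engine, uniform shares along local tangents
  const double fpp = -ke * mult * par.Feng / par.np;
  for (int i = 0; i <= nb; ++i) {
    double tx, ty;
    if (i == 0) { tx = vx[0] / vl[0]; ty = vy[0] / vl[0]; }
    else if (i == nb) { tx = vx[nb - 1] / vl[nb - 1]; ty = vy[nb - 1] / vl[nb - 1]; }
    else {
      double sx = vx[i - 1] + vx[i], sy = vy[i - 1] + vy[i];
      double sl = std::sqrt(sx * sx + sy * sy);
      tx = sx / sl; ty = sy / sl;
    }
    F[2 * (base + i)] += fpp * tx;
    F[2 * (base + i) + 1] += fpp * ty;
  }
  if (pull != 0) {
    int hp = (ke == 1) ? 0 : par.np - 1;
    double tx, ty;
    if (hp == 0) { tx = vx[0] / vl[0]; ty = vy[0] / vl[0]; }
    else { tx = vx[nb - 1] / vl[nb - 1]; ty = vy[nb - 1] / vl[nb - 1]; }
    F[2 * (base + hp)] += pull * (-ke) * tx;
    F[2 * (base + hp) + 1] += pull * (-ke) * ty;
  }
}

// exact-distance refinement of the broad-phase candidates: keep pairs whose
// axes are currently within rcut (Verlet list with exact cutoff)
static void refine_pairs(const double* P, const Par& par, double rcut,
                         std::vector<std::pair<int,int> >& pairs) {
  const int nseg_per = par.np - 1;
  const double rc2 = rcut * rcut;
  size_t keep = 0;
  for (size_t k = 0; k < pairs.size(); ++k) {
    int g = pairs[k].first, h = pairs[k].second;
    int ia = (g / nseg_per) * par.np + g % nseg_per;
    int ja = (h / nseg_per) * par.np + h % nseg_per;
    Closest2 c2 = seg_closest_per2(P, ia, ia + 1, ja, ja + 1, par);
    if (c2.d2 < rc2) pairs[keep++] = pairs[k];
  }
  pairs.resize(keep);
}

static void add_contact_forces(const std::vector<Contact>& contacts,
                               double* F, const Par& par) {
  const int nseg_per = par.np - 1;
  for (size_t k = 0; k < contacts.size(); ++k) {
    const Contact& ct = contacts[k];
    double fmag = par.kc * (par.W - ct.d);
    double fx = fmag * ct.ux, fy = fmag * ct.uy; // push a away from b: -u
    int ia = (ct.ga / nseg_per) * par.np + ct.ga % nseg_per;
    int ib = (ct.gb / nseg_per) * par.np + ct.gb % nseg_per;
    F[2 * ia]     -= (1 - ct.s) * fx; F[2 * ia + 1] -= (1 - ct.s) * fy;
    F[2 * ia + 2] -= ct.s * fx;       F[2 * ia + 3] -= ct.s * fy;
    F[2 * ib]     += (1 - ct.t) * fx; F[2 * ib + 1] += (1 - ct.t) * fy;
    F[2 * ib + 2] += ct.t * fx;       F[2 * ib + 3] += ct.t * fy;
  }
}

static void add_guiding_forces(const std::vector<GuidePair>& guides,
                               const double* P, double* F,
                               const IntegerVector& ke, const Par& par,
                               std::vector<char>* engaged) {
  for (size_t k = 0; k < guides.size(); ++k) {
    const GuidePair& gp = guides[k];
    double fmag = std::min(par.kg * (gp.d - par.W), par.Fg);
    double fx = fmag * gp.ux, fy = fmag * gp.uy; // pulls head toward tail
    int hp = head_particle(gp.follower, ke[gp.follower], par);
    int tp = tail_particle(gp.leader, ke[gp.leader], par);
    if (par.mode == 1) { // passive: normal component at the head only
      double tx, ty;
      tangent_at(P, gp.follower * par.np, hp - gp.follower * par.np, par,
                 &tx, &ty);
      // outward head orientation o = -ke * tangent; normal = perp(o)
      double ox = -ke[gp.follower] * tx, oy = -ke[gp.follower] * ty;
      double nx = -oy, ny = ox;
      double fn = fx * nx + fy * ny;
      F[2 * hp] += fn * nx; F[2 * hp + 1] += fn * ny;
    } else { // active following or adhesion: full force on the head
      F[2 * hp] += fx; F[2 * hp + 1] += fy;
      if (par.mode == 3) { // adhesion: reaction on the leader's tail
        F[2 * tp] -= fx; F[2 * tp + 1] -= fy;
      }
    }
    if (engaged) {
      (*engaged)[gp.follower] = 1;
      (*engaged)[gp.leader] = 1;
    }
  }
}

// slime force on the head particle: component of sgn(o.s) Fs s along the
// body normal; sgn(0) := +1
static void add_slime_forces(const double* P, double* F, int nc,
                             const IntegerVector& ke, const Par& par,
                             const NumericMatrix& sx, const NumericMatrix& sy) {
  int nx = sx.nrow(), ny = sx.ncol();
  for (int c = 0; c < nc; ++c) {
    int hp = head_particle(c, ke[c], par);
    int ix = (int)(wrapc(P[2 * hp], par.Lx) / par.dxs); if (ix >= nx) ix = nx - 1;
    int iy = (int)(wrapc(P[2 * hp + 1], par.Ly) / par.dxs); if (iy >= ny) iy = ny - 1;
    double vx = sx(ix, iy), vy = sy(ix, iy);
    if (vx == 0 && vy == 0) continue;
    double tx, ty;
    tangent_at(P, c * par.np, hp - c * par.np, par, &tx, &ty);
    double ox = -ke[c] * tx, oy = -ke[c] * ty;
    double sg = (ox * vx + oy * vy) >= 0 ? 1.0 : -1.0;
    double gx = sg * par.Fs * vx, gy = sg * par.Fs * vy;
    double nxv = -oy, nyv = ox;
    double fn = gx * nxv + gy * nyv;
    F[2 * hp] += fn * nxv; F[2 * hp + 1] += fn * nyv;
  }
}

static void deposit_slime(const double* P, int nc, const IntegerVector& ke,
                          const Par& par, NumericMatrix& sx, NumericMatrix& sy) {
  int nx = sx.nrow(), ny = sx.ncol();
  for (int c = 0; c < nc; ++c) { // ascending id: deterministic override
    int rp = tail_particle(c, ke[c], par);
    double tx, ty;
    tangent_at(P, c * par.np, rp - c * par.np, par, &tx, &ty);
    int ix = (int)(wrapc(P[2 * rp], par.Lx) / par.dxs); if (ix >= nx) ix = nx - 1;
    int iy = (int)(wrapc(P[2 * rp + 1], par.Ly) / par.dxs); if (iy >= ny) iy = ny - 1;
    // store the gliding-direction tangent (trails are bidirectional anyway)
    sx(ix, iy) = -ke[c] * tx;
    sy(ix, iy) = -ke[c] * ty;
  }
}

// ---------------------------------------------------------------------------
// exported one-shot force evaluators (shared kernels, used by R-level API)

// [[Rcpp::export]]
NumericMatrix cpp_linear_forces(NumericMatrix pos, double k_lin, double l0,
                                double Lx, double Ly) {
  Par par; par.np = pos.nrow(); par.klin = k_lin; par.l0 = l0;
  par.Lx = Lx; par.Ly = Ly;
  std::vector<double> P(par.np * 2), F(par.np * 2, 0.0);
  for (int i = 0; i < par.np; ++i) { P[2*i] = pos(i,0); P[2*i+1] = pos(i,1); }
  add_linear(P.data(), F.data(), 0, par);
  NumericMatrix out(par.np, 2);
  for (int i = 0; i < par.np; ++i) { out(i,0) = F[2*i]; out(i,1) = F[2*i+1]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_angular_forces(NumericMatrix pos, double k_a,
                                 double Lx, double Ly) {
  Par par; par.np = pos.nrow(); par.ka = k_a; par.Lx = Lx; par.Ly = Ly;
  std::vector<double> P(par.np * 2), F(par.np * 2, 0.0);
  for (int i = 0; i < par.np; ++i) { P[2*i] = pos(i,0); P[2*i+1] = pos(i,1); }
  add_angular(P.data(), F.data(), 0, par);
  NumericMatrix out(par.np, 2);
  for (int i = 0; i < par.np; ++i) { out(i,0) = F[2*i]; out(i,1) = F[2*i+1]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_engine_forces(NumericMatrix pos, int ke, double F_engine,
                                double Lx, double Ly) {
  Par par; par.np = pos.nrow(); par.Feng = F_engine; par.Lx = Lx; par.Ly = Ly;
  std::vector<double> P(par.np * 2), F(par.np * 2, 0.0);
  for (int i = 0; i < par.np; ++i) { P[2*i] = pos(i,0); P[2*i+1] = pos(i,1); }
  add_engine(P.data(), F.data(), 0, ke, 1.0, par);
  NumericMatrix out(par.np, 2);
  for (int i = 0; i < par.np; ++i) { out(i,0) = F[2*i]; out(i,1) = F[2*i+1]; }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_seg_closest(NumericVector a, NumericVector b,
                              double Lx, double Ly, bool periodic) {
  Closest cl;
  if (periodic) {
    Par par; par.Lx = Lx; par.Ly = Ly;
    double P[8] = { a[0], a[1], a[2], a[3], b[0], b[1], b[2], b[3] };
    cl = seg_closest_per(P, 0, 1, 2, 3, par);
  } else {
    cl = seg_closest_raw(a[0], a[1], a[2], a[3], b[0], b[1], b[2], b[3]);
  }
  return NumericVector::create(_["p1"] = cl.s, _["p2"] = cl.t, _["d"] = cl.d,
                               _["ux"] = cl.ux, _["uy"] = cl.uy);
}

// contacts + guiding pairs of a static state (after de-duplication)
// [[Rcpp::export]]
List cpp_find_interactions(NumericMatrix pos, IntegerVector ke, List params) {
  Par par = parse_par(params);
  int nc = pos.nrow() / par.np;
  std::vector<double> P(pos.nrow() * 2);
  for (int i = 0; i < pos.nrow(); ++i) { P[2*i] = pos(i,0); P[2*i+1] = pos(i,1); }
  std::vector<std::pair<int,int> > pairs;
  build_pairs(P.data(), nc, par, par.W + par.dg, pairs);
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  std::vector<Contact> contacts;
  std::vector<GuidePair> guides;
  Workspace ws(nc);
  find_contacts(P.data(), nc, ke, par, pairs, contacts, guides, ws);
  NumericMatrix cm(contacts.size(), 7);
  for (size_t k = 0; k < contacts.size(); ++k) {
    cm(k, 0) = contacts[k].ga; cm(k, 1) = contacts[k].gb;
    cm(k, 2) = contacts[k].s;  cm(k, 3) = contacts[k].t;
    cm(k, 4) = contacts[k].d;
    cm(k, 5) = contacts[k].ux; cm(k, 6) = contacts[k].uy;
  }
  NumericMatrix gm(guides.size(), 5);
  for (size_t k = 0; k < guides.size(); ++k) {
    gm(k, 0) = guides[k].follower; gm(k, 1) = guides[k].leader;
    gm(k, 2) = guides[k].d; gm(k, 3) = guides[k].ux; gm(k, 4) = guides[k].uy;
  }
  return List::create(_["contacts"] = cm, _["guides"] = gm);
}

// per-particle forces of a static state, by source
// [[Rcpp::export]]
NumericMatrix cpp_state_forces(NumericMatrix pos, IntegerVector ke, List params,
                               std::string source) {
  Par par = parse_par(params);
  int nc = pos.nrow() / par.np;
  std::vector<double> P(pos.nrow() * 2), F(pos.nrow() * 2, 0.0);
  for (int i = 0; i < pos.nrow(); ++i) { P[2*i] = pos(i,0); P[2*i+1] = pos(i,1); }
  std::vector<std::pair<int,int> > pairs;
  build_pairs(P.data(), nc, par, par.W + par.dg, pairs);
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  std::vector<Contact> contacts;
  std::vector<GuidePair> guides;
  Workspace ws(nc);
  find_contacts(P.data(), nc, ke, par, pairs, contacts, guides, ws);
  if (source == "collision") {
    add_contact_forces(contacts, F.data(), par);
  } else if (source == "guiding") {
    add_guiding_forces(guides, P.data(), F.data(), ke, par, NULL);
  } else {
    stop("unknown force source");
  }
  NumericMatrix out(pos.nrow(), 2);
  for (int i = 0; i < pos.nrow(); ++i) { out(i,0) = F[2*i]; out(i,1) = F[2*i+1]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_slime_force(NumericMatrix pos, IntegerVector ke, List params,
                              NumericMatrix sx, NumericMatrix sy) {
  Par par = parse_par(params);
  int nc = pos.nrow() / par.np;
  std::vector<double> P(pos.nrow() * 2), F(pos.nrow() * 2, 0.0);
  for (int i = 0; i < pos.nrow(); ++i) { P[2*i] = pos(i,0); P[2*i+1] = pos(i,1); }
  add_slime_forces(P.data(), F.data(), nc, ke, par, sx, sy);
  NumericMatrix out(pos.nrow(), 2);
  for (int i = 0; i < pos.nrow(); ++i) { out(i,0) = F[2*i]; out(i,1) = F[2*i+1]; }
  return out;
}

// [[Rcpp::export]]
List cpp_deposit_slime(NumericMatrix pos, IntegerVector ke, List params,
                       NumericMatrix sx, NumericMatrix sy) {
  Par par = parse_par(params);
  int nc = pos.nrow() / par.np;
  std::vector<double> P(pos.nrow() * 2);
  for (int i = 0; i < pos.nrow(); ++i) { P[2*i] = pos(i,0); P[2*i+1] = pos(i,1); }
  NumericMatrix sx2 = clone(sx), sy2 = clone(sy);
  deposit_slime(P.data(), nc, ke, par, sx2, sy2);
  return List::create(_["sx"] = sx2, _["sy"] = sy2);
}

// cell pairs with any segment-segment distance below W + d_g
// [[Rcpp::export]]
IntegerMatrix cpp_proximity_edges(NumericMatrix pos, List params) {
  Par par = parse_par(params);
  const int nseg_per = par.np - 1;
  int nc = pos.nrow() / par.np;
  std::vector<double> P(pos.nrow() * 2);
  for (int i = 0; i < pos.nrow(); ++i) { P[2*i] = pos(i,0); P[2*i+1] = pos(i,1); }
  std::vector<std::pair<int,int> > pairs;
  build_pairs(P.data(), nc, par, par.W + par.dg, pairs);
  std::vector<std::pair<int,int> > edges;
  for (size_t k = 0; k < pairs.size(); ++k) {
    int g = pairs[k].first, h = pairs[k].second;
    int cg = g / nseg_per, ch = h / nseg_per;
    if (cg == ch) continue;
    int ia = cg * par.np + g % nseg_per;
    int ja = ch * par.np + h % nseg_per;
    Closest cl = seg_closest_per(P.data(), ia, ia + 1, ja, ja + 1, par);
    if (cl.d < par.W + par.dg)
      edges.push_back(std::make_pair(std::min(cg, ch), std::max(cg, ch)));
  }
  std::sort(edges.begin(), edges.end());
  edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
  IntegerMatrix out(edges.size(), 2);
  for (size_t k = 0; k < edges.size(); ++k) {
    out(k, 0) = edges[k].first; out(k, 1) = edges[k].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// main integration loop

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, IntegerVector ke0, NumericVector phase0,
             List params, int n_steps, int record_every,
             NumericVector engine_mult, NumericVector pull_pn,
             NumericMatrix sx0, NumericMatrix sy0) {
  Par par = parse_par(params);
  const int N = pos.nrow();
  const int nc = N / par.np;
  std::vector<double> P(N * 2), F(N * 2);
  for (int i = 0; i < N; ++i) { P[2*i] = pos(i,0); P[2*i+1] = pos(i,1); }
  IntegerVector ke = clone(ke0);
  NumericVector phase = clone(phase0);
  NumericMatrix sx = clone(sx0), sy = clone(sy0);
  const bool use_slime = (par.mode == 4);

  const double skin = 0.15; // um, Verlet margin on the pair list
  const double rlist = par.W + par.dg + skin;
  std::vector<std::pair<int,int> > pairs;
  std::vector<PairRec> recs;
  std::vector<Contact> contacts;
  std::vector<GuidePair> guides;
  Workspace ws(nc);
  std::vector<char> engaged(nc);
  double acc_disp = 0.0; // max accumulated displacement since last rebuild
  bool need_build = true;

  const int n_frames = n_steps / record_every + 1;
  NumericVector traj((R_xlen_t)n_frames * N * 2);
  IntegerMatrix ke_frames(n_frames, nc);
  NumericVector times(n_frames);
  NumericMatrix log(n_frames, 3); // time_s, n_collisions, n_guiding_pairs
  const double guard = 0.1 * par.W;
  const double dt_min = par.dt / 60.0;

  int frame = 0;
  auto record = [&](int step, int ncol, int ngd) {
    times[frame] = step * par.dt;
    for (int i = 0; i < N; ++i) {
      traj[(R_xlen_t)frame * N * 2 + 2 * i] = P[2 * i];
      traj[(R_xlen_t)frame * N * 2 + 2 * i + 1] = P[2 * i + 1];
    }
    for (int c = 0; c < nc; ++c) ke_frames(frame, c) = ke[c];
    log(frame, 0) = step * par.dt; log(frame, 1) = ncol; log(frame, 2) = ngd;
    ++frame;
  };

  int ncol_last = 0, ngd_last = 0;
  for (int step = 0; step < n_steps; ++step) {
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
    if (need_build || acc_disp > 0.5 * skin) {
      build_pairs(P.data(), nc, par, rlist, pairs);
      std::sort(pairs.begin(), pairs.end());
      pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
      refine_pairs(P.data(), par, rlist, pairs);
      make_pair_recs(pairs, P.data(), par, recs);
      acc_disp = 0.0;
      need_build = false;
    }
    find_contacts_fast(P.data(), nc, ke, par, recs, contacts, guides, ws);
    ncol_last = (int)contacts.size(); ngd_last = (int)guides.size();
    if (step % record_every == 0)
      record(step, ncol_last, ngd_last);
    std::fill(F.begin(), F.end(), 0.0);
    std::fill(engaged.begin(), engaged.end(), 0);
    for (int c = 0; c < nc; ++c)
      add_internal(P.data(), F.data(), c * par.np, ke[c], engine_mult[c],
                   pull_pn[c], par);
    add_contact_forces(contacts, F.data(), par);
    if (par.mode >= 1 && par.mode <= 3)
      add_guiding_forces(guides, P.data(), F.data(), ke, par, &engaged);
    if (use_slime)
      add_slime_forces(P.data(), F.data(), nc, ke, par, sx, sy);

    // overdamped Euler update
    double maxd = 0.0;
    const double mob = par.dt / par.gpar;
    for (int i = 0; i < N; ++i) {
      double dx = F[2 * i] * mob, dy = F[2 * i + 1] * mob;
      double m = std::max(std::fabs(dx), std::fabs(dy));
      if (m > maxd) maxd = m;
      P[2 * i] = wrapc(P[2 * i] + dx, par.Lx);
      P[2 * i + 1] = wrapc(P[2 * i + 1] + dy, par.Ly);
    }
    if (maxd > guard)
      stop("integration unstable at step %d: displacement %.3g um exceeds 0.1*W; reduce dt", step, maxd);
    acc_disp += maxd;

    if (use_slime) deposit_slime(P.data(), nc, ke, par, sx, sy);

    // reversal clock: engaged cells are suppressed (clock paused)
    if (R_finite(par.TR)) {
      for (int c = 0; c < nc; ++c) {
        if (engaged[c]) continue;
        phase[c] += dt_min;
        if (phase[c] >= par.TR) { ke[c] = -ke[c]; phase[c] = 0.0; }
      }
    }
  }
  if (n_steps % record_every == 0 && frame < n_frames) {
    if (need_build) {
      build_pairs(P.data(), nc, par, rlist, pairs);
      std::sort(pairs.begin(), pairs.end());
      pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
      refine_pairs(P.data(), par, rlist, pairs);
      make_pair_recs(pairs, P.data(), par, recs);
    }
    find_contacts_fast(P.data(), nc, ke, par, recs, contacts, guides, ws);
    record(n_steps, (int)contacts.size(), (int)guides.size());
  }
  (void)ncol_last; (void)ngd_last;

  NumericMatrix pos_out(N, 2);
  for (int i = 0; i < N; ++i) { pos_out(i,0) = P[2*i]; pos_out(i,1) = P[2*i+1]; }
  traj.attr("dim") = IntegerVector::create(2, N, n_frames);
  return List::create(
    _["traj"] = traj, _["times"] = times, _["ke_frames"] = ke_frames,
    _["log"] = log, _["pos"] = pos_out, _["ke"] = ke, _["phase"] = phase,
    _["sx"] = sx, _["sy"] = sy, _["n_frames"] = frame);
}
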