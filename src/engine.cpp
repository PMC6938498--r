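// Hard-spherocylinder Monte Carlo engine and length-weighted order-field
// accumulation. All lengths are in units of the rod diameter d. The container
// is the intersection of two disks of radius R centred at (+/-c, 0), extruded
// to z in [0, h]; it is convex, so a capsule lies inside iff both centreline
// endpoints lie in the region eroded by d/2.
//
// Randomness comes from R's RNG (unif_rand) so that runs are reproducible
// from set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// minimum distance between closed segments a0-a1 and b0-b1 (Eberly-style
// clamped quadratic); robust for degenerate (point) segments.
static double seg_dist2(const double* a0, const double* a1,
                        const double* b0, const double* b1) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = a1[k] - a0[k];
    d2[k] = b1[k] - b0[k];
    r[k] = a0[k] - b0[k];
  }
  const double a = dot3(d1, d1), e = dot3(d2, d2), f = dot3(d2, r);
  const double c = dot3(d1, r), b = dot3(d1, d2);
  const double EPS = 1e-14;
  double s = 0.0, t = 0.0;
  if (a <= EPS && e <= EPS) {
    s = t = 0.0;
  } else if (a <= EPS) {
    t = f / e;
    t = t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
  } else if (e <= EPS) {
    s = -c / a;
    s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
  } else {
    const double denom = a * e - b * b;
    if (denom > EPS) {
      s = (b * f - c * e) / denom;
      s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
    } else {
      s = 0.0;
    }
    t = (b * s + f) / e;
    if (t < 0.0) {
      t = 0.0;
      s = -c / a;
      s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
    } else if (t > 1.0) {
      t = 1.0;
      s = (b - c) / a;
      s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
    }
  }
  double diff[3];
  for (int k = 0; k < 3; ++k) diff[k] = (a0[k] + s * d1[k]) - (b0[k] + t * d2[k]);
  return dot3(diff, diff);
}

// [[Rcpp::export]]
double cpp_segment_distance(NumericVector a0, NumericVector a1,
                            NumericVector b0, NumericVector b1) {
  return std::sqrt(seg_dist2(&a0[0], &a1[0], &b0[0], &b1[0]));
}

struct Geom {
  double R, c, h, Lx, Ly;
};

static inline bool point_ok(const Geom& g, double x, double y, double z,
                            double margin) {
  if (z < margin || z > g.h - margin) return false;
  const double rr = (g.R - margin) * (g.R - margin);
  const double dxp = x - g.c, dxm = x + g.c;
  if (dxp * dxp + y * y > rr) return false;
  if (dxm * dxm + y * y > rr) return false;
  return true;
}

static inline bool capsule_ok(const Geom& g, const double* r, const double* u,
                              double L, double d) {
  const double hl = 0.5 * L, m = 0.5 * d;
  if (!point_ok(g, r[0] + hl * u[0], r[1] + hl * u[1], r[2] + hl * u[2], m))
    return false;
  if (!point_ok(g, r[0] - hl * u[0], r[1] - hl * u[1], r[2] - hl * u[2], m))
    return false;
  return true;
}

static Geom make_geom(NumericVector gv) {
  // gv = c(R, c, h, Lx, Ly)
  Geom g;
  g.R = gv[0];
  g.c = gv[1];
  g.h = gv[2];
  g.Lx = gv[3];
  g.Ly = gv[4];
  return g;
}

// ---- cell list over the lens bounding box (2D, by rod centre) -------------

struct CellList {
  int ncx, ncy;
  double x0, y0, ex, ey;
  std::vector<int> head;   // first rod in cell, -1 if empty
  std::vector<int> nxt;    // linked list
  std::vector<int> cell;   // cell of rod i

  void init(const Geom& g, double reach, int N) {
    x0 = -0.5 * g.Lx - 1e-9;
    y0 = -0.5 * g.Ly - 1e-9;
    const double wx = g.Lx + 2e-9, wy = g.Ly + 2e-9;
    ncx = std::max(1, (int)std::floor(wx / reach));
    ncy = std::max(1, (int)std::floor(wy / reach));
    ex = wx / ncx;
    ey = wy / ncy;
    head.assign((size_t)ncx * ncy, -1);
    nxt.assign(N, -1);
    cell.assign(N, -1);
  }
  int index(double x, double y) const {
    int ix = (int)std::floor((x - x0) / ex);
    int iy = (int)std::floor((y - y0) / ey);
    ix = ix < 0 ? 0 : (ix >= ncx ? ncx - 1 : ix);
    iy = iy < 0 ? 0 : (iy >= ncy ? ncy - 1 : iy);
    return iy * ncx + ix;
  }
  void insert(int i, double x, double y) {
    const int c = index(x, y);
    cell[i] = c;
    nxt[i] = head[c];
    head[c] = i;
  }
  void remove(int i) {
    const int c = cell[i];
    int j = head[c];
    if (j == i) {
      head[c] = nxt[i];
    } else {
      while (nxt[j] != i) j = nxt[j];
      nxt[j] = nxt[i];
    }
    cell[i] = -1;
  }
};

// endpoints for rod i from flat arrays
static inline void endpoints(const double* pos, const double* u, int i, int N,
                             double L, double* e0, double* e1) {
  const double hl = 0.5 * L;
  for (int k = 0; k < 3; ++k) {
    const double p = pos[i + k * N], d = u[i + k * N];
    e0[k] = p - hl * d;
    e1[k] = p + hl * d;
  }
}

// does rod i (with trial endpoints te0/te1) overlap any neighbour != i?
static bool overlaps_neighbours(const CellList& cl, const double* pos,
                                const double* u, int N, double L, double d,
                                int i, const double* te0, const double* te1,
                                double cx, double cy) {
  const double d2 = d * d;
  // two spherocylinders cannot overlap if their centres are farther apart
  // than L + d (collinear worst case); cheap prefilter before the exact test
  const double reach2 = (L + d) * (L + d);
  const double tcx = 0.5 * (te0[0] + te1[0]), tcy = 0.5 * (te0[1] + te1[1]),
               tcz = 0.5 * (te0[2] + te1[2]);
  const int c = cl.index(cx, cy);
  const int ix = c % cl.ncx, iy = c / cl.ncx;
  double e0[3], e1[3];
  for (int dy = -1; dy <= 1; ++dy) {
    const int jy = iy + dy;
    if (jy < 0 || jy >= cl.ncy) continue;
    for (int dx = -1; dx <= 1; ++dx) {
      const int jx = ix + dx;
      if (jx < 0 || jx >= cl.ncx) continue;
      for (int j = cl.head[jy * cl.ncx + jx]; j != -1; j = cl.nxt[j]) {
        if (j == i) continue;
        const double ddx = pos[j] - tcx, ddy = pos[j + N] - tcy,
                     ddz = pos[j + 2 * N] - tcz;
        if (ddx * ddx + ddy * ddy + ddz * ddz > reach2) continue;
        endpoints(pos, u, j, N, L, e0, e1);
        // axis-aligned bounding boxes expanded by d/2 each; very effective
        // for the nearly-parallel pairs that dominate a nematic
        bool apart = false;
        for (int k = 0; k < 3 && !apart; ++k) {
          const double alo = std::min(te0[k], te1[k]),
                       ahi = std::max(te0[k], te1[k]);
          const double blo = std::min(e0[k], e1[k]),
                       bhi = std::max(e0[k], e1[k]);
          if (alo > bhi + d || blo > ahi + d) apart = true;
        }
        if (apart) continue;
        if (seg_dist2(te0, te1, e0, e1) < d2) return true;
      }
    }
  }
  return false;
}

// all-pairs overlap count + wall violations (oracle / validation)
// [[Rcpp::export]]
List cpp_check_config(NumericMatrix pos, NumericMatrix u, double L, double d,
                      NumericVector gv) {
  const Geom g = make_geom(gv);
  const int N = pos.nrow();
  int n_overlap = 0, n_wall = 0;
  const double d2 = d * d;
  std::vector<double> E0(3 * N), E1(3 * N);
  for (int i = 0; i < N; ++i) {
    endpoints(&pos[0], &u[0], i, N, L, &E0[3 * i], &E1[3 * i]);
    double r[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double uu[3] = {u(i, 0), u(i, 1), u(i, 2)};
    if (!capsule_ok(g, r, uu, L, d)) ++n_wall;
  }
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j)
      if (seg_dist2(&E0[3 * i], &E1[3 * i], &E0[3 * j], &E1[3 * j]) < d2)
        ++n_overlap;
  return List::create(_["n_overlap"] = n_overlap, _["n_wall"] = n_wall);
}

static void random_axis(double* k) {
  double x, y, s;
  do {
    x = 2.0 * unif_rand() - 1.0;
    y = 2.0 * unif_rand() - 1.0;
    s = x * x + y * y;
  } while (s >= 1.0 || s == 0.0);
  const double f = 2.0 * std::sqrt(1.0 - s);
  k[0] = x * f;
  k[1] = y * f;
  k[2] = 1.0 - 2.0 * s;
}

static void rotate_about(const double* u, const double* k, double t,
                         double* out) {
  // Rodrigues rotation of u about unit axis k by angle t
  const double ct = std::cos(t), st = std::sin(t);
  const double kd = dot3(k, u);
  double kx[3] = {k[1] * u[2] - k[2] * u[1], k[2] * u[0] - k[0] * u[2],
                  k[0] * u[1] - k[1] * u[0]};
  for (int i = 0; i < 3; ++i)
    out[i] = u[i] * ct + kx[i] * st + k[i] * kd * (1.0 - ct);
  // renormalise to keep |u| = 1 over long runs
  const double n = std::sqrt(dot3(out, out));
  for (int i = 0; i < 3; ++i) out[i] /= n;
}

// [[Rcpp::export]]
List cpp_run_sweeps(NumericMatrix pos_in, NumericMatrix u_in, double L,
                    double d, NumericVector gv, int sweeps, double dr_max,
                    double dth_max, int sample_every) {
  const Geom g = make_geom(gv);
  const int N = pos_in.nrow();
  NumericMatrix pos = clone(pos_in), u = clone(u_in);

  CellList cl;
  cl.init(g, L + d, N);
  for (int i = 0; i < N; ++i) cl.insert(i, pos(i, 0), pos(i, 1));

  std::vector<int> sample_at;
  for (int s = 0; s <= sweeps; s += sample_every) sample_at.push_back(s);
  if (sample_at.back() != sweeps) sample_at.push_back(sweeps);
  const int nf = (int)sample_at.size();
  List frames_pos(nf), frames_u(nf);
  IntegerVector frame_sweep(nf);
  int fi = 0;

  long long n_acc = 0, n_try = 0;
  double te0[3], te1[3];

  for (int s = 0; s <= sweeps; ++s) {
    if (fi < nf && s == sample_at[fi]) {
      frames_pos[fi] = clone(pos);
      frames_u[fi] = clone(u);
      frame_sweep[fi] = s;
      ++fi;
    }
    if (s == sweeps) break;
    for (int m = 0; m < N; ++m) {
      const int i = (int)std::floor(unif_rand() * N) % N;
      double r[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
      double uo[3] = {u(i, 0), u(i, 1), u(i, 2)};
      double rn[3], un[3], axis[3];
      for (int k = 0; k < 3; ++k)
        rn[k] = r[k] + dr_max * (2.0 * unif_rand() - 1.0);
      random_axis(axis);
      rotate_about(uo, axis, dth_max * unif_rand(), un);
      ++n_try;
      if (!capsule_ok(g, rn, un, L, d)) continue;
      const double hl = 0.5 * L;
      for (int k = 0; k < 3; ++k) {
        te0[k] = rn[k] - hl * un[k];
        te1[k] = rn[k] + hl * un[k];
      }
      if (overlaps_neighbours(cl, &pos[0], &u[0], N, L, d, i, te0, te1, rn[0],
                              rn[1]))
        continue;
      // accept
      const int cnew = cl.index(rn[0], rn[1]);
      if (cnew != cl.cell[i]) {
        cl.remove(i);
        for (int k = 0; k < 3; ++k) {
          pos(i, k) = rn[k];
          u(i, k) = un[k];
        }
        cl.insert(i, rn[0], rn[1]);
      } else {
        for (int k = 0; k < 3; ++k) {
          pos(i, k) = rn[k];
          u(i, k) = un[k];
        }
      }
      ++n_acc;
    }
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["frames_pos"] = frames_pos, _["frames_u"] = frames_u,
                      _["frame_sweep"] = frame_sweep,
                      _["acceptance"] =
                          n_try > 0 ? (double)n_acc / (double)n_try : NA_REAL);
}

// randomized sequential insertion of N rods with a given orientation mode.
// mode: 0 along_major (y), 1 along_minor (x), 2 tilt45, 3 hedgehog (radial)
// [[Rcpp::export]]
List cpp_build_initial(NumericVector gv, int N, double L, double d, int mode,
                       double jitter_rad, int max_attempts) {
  const Geom g = make_geom(gv);
  NumericMatrix pos(N, 3), u(N, 3);
  CellList cl;
  cl.init(g, L + d, N);
  int placed = 0;
  double te0[3], te1[3];
  const double zlo = 0.5 * d, zhi = g.h - 0.5 * d;

  for (int i = 0; i < N; ++i) {
    bool ok = false;
    for (int a = 0; a < max_attempts; ++a) {
      const double x = g.Lx * (unif_rand() - 0.5);
      const double y = g.Ly * (unif_rand() - 0.5);
      const double z = zlo + (zhi - zlo) * unif_rand();
      double base[2];
      if (mode == 0) {
        base[0] = 0.0;
        base[1] = 1.0;
      } else if (mode == 1) {
        base[0] = 1.0;
        base[1] = 0.0;
      } else if (mode == 2) {
        base[0] = M_SQRT1_2;
        base[1] = M_SQRT1_2;
      } else {
        const double nrm = std::sqrt(x * x + y * y);
        if (nrm < 1e-8) continue;
        base[0] = x / nrm;
        base[1] = y / nrm;
      }
      const double eps = jitter_rad * (2.0 * unif_rand() - 1.0);
      const double ce = std::cos(eps), se = std::sin(eps);
      double rr[3] = {x, y, z};
      double uu[3] = {base[0] * ce - base[1] * se,
                      base[0] * se + base[1] * ce, 0.0};
      if (!capsule_ok(g, rr, uu, L, d)) continue;
      const double hl = 0.5 * L;
      for (int k = 0; k < 3; ++k) {
        te0[k] = rr[k] - hl * uu[k];
        te1[k] = rr[k] + hl * uu[k];
      }
      if (overlaps_neighbours(cl, &pos[0], &u[0], N, L, d, -1, te0, te1, x, y))
        continue;
      for (int k = 0; k < 3; ++k) {
        pos(placed, k) = rr[k];
        u(placed, k) = uu[k];
      }
      cl.insert(placed, x, y);
      ++placed;
      ok = true;
      break;
    }
    if (!ok) break;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["pos"] = pos, _["u"] = u, _["placed"] = placed);
}

// length-weighted tensor order parameter accumulated on an nx-by-ny grid of
// cuboidal sub-volumes (full container height). Returns per-cell clipped
// length and the six independent components of sum_i l_i * (3/2 u u^T - I/2).
// [[Rcpp::export]]
List cpp_local_Q(NumericMatrix pos, NumericMatrix u, double L, double x0,
                 double y0, double cell, int nx, int ny) {
  const int N = pos.nrow();
  NumericVector wsum(nx * ny);
  NumericMatrix Q(nx * ny, 6);  // xx, yy, zz, xy, xz, yz

  for (int i = 0; i < N; ++i) {
    const double hl = 0.5 * L;
    double e0[3], e1[3];
    for (int k = 0; k < 3; ++k) {
      e0[k] = pos(i, k) - hl * u(i, k);
      e1[k] = pos(i, k) + hl * u(i, k);
    }
    const double ux = u(i, 0), uy = u(i, 1), uz = u(i, 2);
    const double q[6] = {1.5 * ux * ux - 0.5, 1.5 * uy * uy - 0.5,
                         1.5 * uz * uz - 0.5, 1.5 * ux * uy,
                         1.5 * ux * uz,       1.5 * uy * uz};
    int ixlo = (int)std::floor((std::min(e0[0], e1[0]) - x0) / cell);
    int ixhi = (int)std::floor((std::max(e0[0], e1[0]) - x0) / cell);
    int iylo = (int)std::floor((std::min(e0[1], e1[1]) - y0) / cell);
    int iyhi = (int)std::floor((std::max(e0[1], e1[1]) - y0) / cell);
    ixlo = std::max(ixlo, 0);
    iylo = std::max(iylo, 0);
    ixhi = std::min(ixhi, nx - 1);
    iyhi = std::min(iyhi, ny - 1);
    const double dx = e1[0] - e0[0], dy = e1[1] - e0[1];
    for (int iy = iylo; iy <= iyhi; ++iy) {
      for (int ix = ixlo; ix <= ixhi; ++ix) {
        double t0 = 0.0, t1 = 1.0;
        const double xa = x0 + ix * cell, xb = xa + cell;
        const double ya = y0 + iy * cell, yb = ya + cell;
        bool empty = false;
        // x slab
        if (std::fabs(dx) < 1e-14) {
          // half-open membership so a segment lying exactly on a cell face
          // is not counted twice
          if (e0[0] < xa || e0[0] >= xb) empty = true;
        } else {
          double ta = (xa - e0[0]) / dx, tb = (xb - e0[0]) / dx;
          if (ta > tb) std::swap(ta, tb);
          t0 = std::max(t0, ta);
          t1 = std::min(t1, tb);
        }
        // y slab
        if (!empty) {
          if (std::fabs(dy) < 1e-14) {
            if (e0[1] < ya || e0[1] >= yb) empty = true;
          } else {
            double ta = (ya - e0[1]) / dy, tb = (yb - e0[1]) / dy;
            if (ta > tb) std::swap(ta, tb);
            t0 = std::max(t0, ta);
            t1 = std::min(t1, tb);
          }
        }
        if (empty || t1 <= t0) continue;
        const double l = (t1 - t0) * L;
        const int c = iy * nx + ix;
        wsum[c] += l;
        for (int k = 0; k < 6; ++k) Q(c, k) += l * q[k];
      }
    }
  }
  return List::create(_["wsum"] = wsum, _["Q"] = Q);
}
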