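#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic, platform-independent PRNG (splitmix64) so that a given
// schedule seed reproduces the same relaxation on any machine, independent
// of R's RNG state.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline double spring_energy(double dx, double dy, double k, double l0) {
  double l = std::sqrt(dx * dx + dy * dy);
  double d = l - l0;
  return 0.5 * k * d * d;
}

// Total energy: elastic sum over unbroken springs + gravitational potential
// sum(gmass_i * y_i), with gmass_i = g * n_below_i.
// [[Rcpp::export]]
double cpp_energy(NumericMatrix pos, IntegerVector a, IntegerVector b,
                  NumericVector k, NumericVector l0, LogicalVector broken,
                  NumericVector gmass) {
  const int ns = a.size();
  double e = 0.0;
  for (int s = 0; s < ns; ++s) {
    if (broken[s]) continue;
    int i = a[s] - 1, j = b[s] - 1;
    e += spring_energy(pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1), k[s], l0[s]);
  }
  const int n = pos.nrow();
  for (int i = 0; i < n; ++i) e += gmass[i] * pos(i, 1);
  return e;
}

// Analytic nodal forces: spring tension k*(l-l0) along the axis (tension
// pulls the endpoints together) plus the gravity load (0, -gmass_i).
// Forces on fixed nodes are reported as zero when zero_fixed is true.
// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerVector a, IntegerVector b,
                         NumericVector k, NumericVector l0, LogicalVector broken,
                         NumericVector gmass, LogicalVector fixed,
                         bool zero_fixed = true) {
  const int n = pos.nrow(), ns = a.size();
  NumericMatrix f(n, 2);
  int n_zero_len = 0;
  for (int s = 0; s < ns; ++s) {
    if (broken[s]) continue;
    int i = a[s] - 1, j = b[s] - 1;
    double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
    double l = std::sqrt(dx * dx + dy * dy);
    if (l <= 0.0) { ++n_zero_len; continue; }  // direction undefined: no force
    double t = k[s] * (l - l0[s]) / l;         // force per unit separation
    f(i, 0) += t * dx; f(i, 1) += t * dy;
    f(j, 0) -= t * dx; f(j, 1) -= t * dy;
  }
  for (int i = 0; i < n; ++i) f(i, 1) -= gmass[i];
  if (zero_fixed)
    for (int i = 0; i < n; ++i)
      if (fixed[i]) { f(i, 0) = 0.0; f(i, 1) = 0.0; }
  if (n_zero_len > 0) {
    f.attr("n_zero_length") = n_zero_len;
    Rf_warning("%d zero-length spring(s): force direction undefined, treated as zero", n_zero_len);
  }
  return f;
}

// Energy minimization by the force-directed simulated-annealing variant:
// each free node is proposed a displacement proportional to (and in the
// direction of) its current resulting force; downhill moves are accepted,
// uphill moves with probability exp(-dE/T); T is cooled each sweep.
// step_gain <= 0 selects the per-node adaptive gain relax_factor/sum(k_inc).
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos0, LogicalVector fixed, IntegerVector a,
               IntegerVector b, NumericVector k, NumericVector l0,
               LogicalVector broken, NumericVector gmass, double T0,
               double cool, double step_gain, double relax_factor,
               double conv_tol, int max_sweeps, int seed, bool trace = false) {
  const int n = pos0.nrow(), ns = a.size();
  NumericMatrix pos = clone(pos0);

  // incidence lists
  std::vector<std::vector<int>> inc(n);
  for (int s = 0; s < ns; ++s) {
    if (broken[s]) continue;
    inc[a[s] - 1].push_back(s);
    inc[b[s] - 1].push_back(s);
  }
  // BFS from fixed nodes over unbroken springs: free nodes in components
  // with no fixed anchor (detached debris) have no equilibrium under the
  // gravity load and are frozen in place, like orphans
  std::vector<char> anchored(n, 0);
  {
    std::vector<int> q;
    for (int i = 0; i < n; ++i) if (fixed[i]) { anchored[i] = 1; q.push_back(i); }
    size_t head = 0;
    while (head < q.size()) {
      int v = q[head++];
      for (size_t m = 0; m < inc[v].size(); ++m) {
        int s = inc[v][m];
        int w = (a[s] - 1 == v) ? b[s] - 1 : a[s] - 1;
        if (!anchored[w]) { anchored[w] = 1; q.push_back(w); }
      }
    }
  }
  std::vector<int> free_nodes;
  for (int i = 0; i < n; ++i)
    if (!fixed[i] && !inc[i].empty() && anchored[i]) free_nodes.push_back(i);

  double E = cpp_energy(pos, a, b, k, l0, broken, gmass);
  const double E_init = E;
  std::vector<double> energy_trace;
  if (free_nodes.empty()) {
    LogicalVector anch0(n);
    for (int i = 0; i < n; ++i) anch0[i] = anchored[i] != 0;
    return List::create(_["pos"] = pos, _["energy"] = E,
                        _["initial_energy"] = E_init, _["sweeps"] = 0,
                        _["accepted_uphill"] = 0,
                        _["anchored"] = anch0,
                        _["trace"] = NumericVector(0));
  }

  SplitMix rng((uint64_t)seed * 0x2545F4914F6CDD1DULL + 0x9E3779B9ULL);
  double T = T0;
  int sweeps = 0;
  long accepted_uphill = 0;
  int calm = 0, rising = 0;
  const int nf = (int)free_nodes.size();
  std::vector<int> order(free_nodes);

  // flat CSR-style neighbour arrays for the hot loop
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; ++i) off[i + 1] = off[i] + (int)inc[i].size();
  std::vector<int> nb_node(off[n]);
  std::vector<double> nb_k(off[n]), nb_l0(off[n]);
  for (int i = 0; i < n; ++i)
    for (size_t m = 0; m < inc[i].size(); ++m) {
      int s = inc[i][m];
      int w = (a[s] - 1 == i) ? b[s] - 1 : a[s] - 1;
      nb_node[off[i] + m] = w;
      nb_k[off[i] + m] = k[s];
      nb_l0[off[i] + m] = l0[s];
    }
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); }

  for (sweeps = 1; sweeps <= max_sweeps; ++sweeps) {
    // fresh permutation per sweep
    for (int i = nf - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }
    double E_start = E;
    for (int oi = 0; oi < nf; ++oi) {
      int v = order[oi];
      double x = px[v], y = py[v];
      double fx = 0.0, fy = -gmass[v], ksum = 0.0, e_old = gmass[v] * y;
      for (int m = off[v]; m < off[v + 1]; ++m) {
        int w = nb_node[m];
        double dx = px[w] - x, dy = py[w] - y;
        double l = std::sqrt(dx * dx + dy * dy);
        double d = l - nb_l0[m];
        e_old += 0.5 * nb_k[m] * d * d;
        ksum += nb_k[m];
        if (l > 0.0) {
          double t = nb_k[m] * d / l;
          fx += t * dx; fy += t * dy;
        }
      }
      double gain = (step_gain > 0.0) ? step_gain : relax_factor / ksum;
      double nx = x + gain * fx, ny = y + gain * fy;
      double e_new = gmass[v] * ny;
      for (int m = off[v]; m < off[v + 1]; ++m) {
        int w = nb_node[m];
        double dx = px[w] - nx, dy = py[w] - ny;
        double l = std::sqrt(dx * dx + dy * dy);
        double d = l - nb_l0[m];
        e_new += 0.5 * nb_k[m] * d * d;
      }
      double dE = e_new - e_old;
      bool accept = dE < 0.0;
      if (!accept && T > 0.0) {
        if (rng.unif() < std::exp(-dE / T)) { accept = true; ++accepted_uphill; }
      }
      if (accept) {
        px[v] = nx; py[v] = ny;
        E += dE;
      }
    }
    if (trace) energy_trace.push_back(E);
    double rel = std::fabs(E - E_start) / std::max(std::fabs(E_start), 1e-12);
    if (rel < conv_tol) { if (++calm >= 3) break; } else calm = 0;
    if (T <= 1e-14 && E > E_start) {
      if (++rising >= 10)
        stop("solver diverging: energy grew for 10 consecutive sweeps at T ~ 0; reduce step_gain");
    } else rising = 0;
    T *= cool;
  }
  if (sweeps > max_sweeps) sweeps = max_sweeps;
  for (int i = 0; i < n; ++i) { pos(i, 0) = px[i]; pos(i, 1) = py[i]; }

  // recompute exactly to avoid incremental drift
  E = cpp_energy(pos, a, b, k, l0, broken, gmass);
  LogicalVector anch(n);
  for (int i = 0; i < n; ++i) anch[i] = anchored[i] != 0;
  return List::create(_["pos"] = pos, _["energy"] = E,
                      _["initial_energy"] = E_init, _["sweeps"] = sweeps,
                      _["accepted_uphill"] = (double)accepted_uphill,
                      _["anchored"] = anch,
                      _["trace"] = wrap(energy_trace));
}

// Rasterize unbroken springs as ~1-px-wide segments on a grid of ppu pixels
// per unit length, then label enclosed background regions by 4-connectivity.
// Output labels: 0 = strut pixel, -1 = background connected to the raster
// frame (outside the network hull), 1..K = enclosed airspaces.
// [[Rcpp::export]]
List cpp_airspace_map(NumericVector x0, NumericVector y0, NumericVector x1,
                      NumericVector y1, double xmin, double ymin, double xmax,
                      double ymax, double ppu, int pad = 2) {
  const int nseg = x0.size();
  int nx = (int)std::ceil((xmax - xmin) * ppu) + 2 * pad + 1;
  int ny = (int)std::ceil((ymax - ymin) * ppu) + 2 * pad + 1;
  if (nx < 3 || ny < 3) stop("raster degenerate: bounding box too small");
  std::vector<int> lab((size_t)nx * ny, 0);  // 0 = empty for now

  // draw: dense sampling along each segment (step < half pixel)
  for (int s = 0; s < nseg; ++s) {
    double ax = (x0[s] - xmin) * ppu + pad, ay = (y0[s] - ymin) * ppu + pad;
    double bx = (x1[s] - xmin) * ppu + pad, by = (y1[s] - ymin) * ppu + pad;
    double len = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay));
    int npts = (int)std::ceil(len / 0.4) + 1;
    for (int t = 0; t <= npts; ++t) {
      double u = (npts == 0) ? 0.0 : (double)t / npts;
      int px = (int)std::lround(ax + u * (bx - ax));
      int py = (int)std::lround(ay + u * (by - ay));
      if (px >= 0 && px < nx && py >= 0 && py < ny) lab[(size_t)py * nx + px] = -2;  // strut
    }
  }

  // BFS label background (lab == 0) with 4-connectivity
  std::vector<int> qx, qy;
  int next_label = 0;
  std::vector<double> area, cx, cy;
  std::vector<int> touches;
  for (int yy = 0; yy < ny; ++yy) {
    for (int xx = 0; xx < nx; ++xx) {
      if (lab[(size_t)yy * nx + xx] != 0) continue;
      ++next_label;
      int border = 0;
      double npix = 0.0, sx = 0.0, sy = 0.0;
      qx.clear(); qy.clear();
      qx.push_back(xx); qy.push_back(yy);
      lab[(size_t)yy * nx + xx] = next_label;
      size_t head = 0;
      while (head < qx.size()) {
        int px = qx[head], py = qy[head]; ++head;
        npix += 1.0; sx += px; sy += py;
        if (px == 0 || px == nx - 1 || py == 0 || py == ny - 1) border = 1;
        const int dx4[4] = {1, -1, 0, 0}, dy4[4] = {0, 0, 1, -1};
        for (int d = 0; d < 4; ++d) {
          int ux = px + dx4[d], uy = py + dy4[d];
          if (ux < 0 || ux >= nx || uy < 0 || uy >= ny) continue;
          size_t idx = (size_t)uy * nx + ux;
          if (lab[idx] == 0) { lab[idx] = next_label; qx.push_back(ux); qy.push_back(uy); }
        }
      }
      area.push_back(npix); cx.push_back(sx / npix); cy.push_back(sy / npix);
      touches.push_back(border);
    }
  }

  // relabel: frame-touching regions -> -1; enclosed airspaces -> 1..K
  std::vector<int> remap(next_label + 1, 0);
  NumericVector out_area, out_cx, out_cy;
  int kcount = 0;
  for (int l = 1; l <= next_label; ++l) {
    if (touches[l - 1]) { remap[l] = -1; continue; }
    remap[l] = ++kcount;
    out_area.push_back(area[l - 1]);
    // convert pixel centroids back to world coordinates
    out_cx.push_back((cx[l - 1] - pad) / ppu + xmin);
    out_cy.push_back((cy[l - 1] - pad) / ppu + ymin);
  }
  IntegerMatrix labels(ny, nx);
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      int v = lab[(size_t)yy * nx + xx];
      labels(yy, xx) = (v == -2) ? 0 : remap[v];
    }
  return List::create(_["labels"] = labels, _["area_px"] = out_area,
                      _["centroid_x"] = out_cx, _["centroid_y"] = out_cy,
                      _["ppu"] = ppu, _["pad"] = pad,
                      _["origin"] = NumericVector::create(xmin, ymin));
}
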