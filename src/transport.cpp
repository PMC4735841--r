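// Monte Carlo photon transport through the layered LaBr3 stack.
// Hot kernel behind transport_photons(); all randomness comes from the R
// RNG stream so results are reproducible with set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double M_E_KEV = 511.0;
static const double EPS = 1e-9;

// log-log linear interpolation on a precomputed log grid
static inline double interp_loglog(const std::vector<double>& le,
                                   const std::vector<double>& lmu,
                                   double e) {
  double x = std::log(e);
  size_t n = le.size();
  if (x <= le[0]) return std::exp(lmu[0]);
  if (x >= le[n - 1]) return std::exp(lmu[n - 1]);
  size_t hi = std::upper_bound(le.begin(), le.end(), x) - le.begin();
  size_t lo = hi - 1;
  double f = (x - le[lo]) / (le[hi] - le[lo]);
  return std::exp(lmu[lo] + f * (lmu[hi] - lmu[lo]));
}

// Klein-Nishina rejection sampling of cos(theta); the density scaled so
// its forward value (the maximum) is 1
static inline double kn_sample(double e0) {
  double k = e0 / M_E_KEV;
  for (;;) {
    double ct = unif_rand() * 2.0 - 1.0;
    double ratio = 1.0 / (1.0 + k * (1.0 - ct));
    double val = 0.5 * ratio * ratio *
      (ratio + 1.0 / ratio - (1.0 - ct * ct));
    if (unif_rand() < val) return ct;
  }
}

// ray / axis-aligned box intersection
static inline void ray_box1(const double* p, const double* u,
                            const double* lo, const double* hi,
                            double& tn, double& tf) {
  tn = -INFINITY; tf = INFINITY;
  for (int ax = 0; ax < 3; ++ax) {
    if (u[ax] == 0.0) {
      if (p[ax] < lo[ax] || p[ax] > hi[ax]) { tn = INFINITY; tf = -INFINITY; return; }
    } else {
      double t1 = (lo[ax] - p[ax]) / u[ax];
      double t2 = (hi[ax] - p[ax]) / u[ax];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tn) tn = t1;
      if (t2 < tf) tf = t2;
    }
  }
}

static inline void rotate_dir(double* u, double ct, double phi) {
  double a[3], b[3], h[3];
  if (std::fabs(u[2]) < 0.9) { h[0] = 0; h[1] = 0; h[2] = 1; }
  else { h[0] = 1; h[1] = 0; h[2] = 0; }
  a[0] = u[1] * h[2] - u[2] * h[1];
  a[1] = u[2] * h[0] - u[0] * h[2];
  a[2] = u[0] * h[1] - u[1] * h[0];
  double na = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
  for (int i = 0; i < 3; ++i) a[i] /= na;
  b[0] = u[1] * a[2] - u[2] * a[1];
  b[1] = u[2] * a[0] - u[0] * a[2];
  b[2] = u[0] * a[1] - u[1] * a[0];
  double st = std::sqrt(std::max(1.0 - ct * ct, 0.0));
  double cp = std::cos(phi), sp = std::sin(phi);
  double v[3];
  for (int i = 0; i < 3; ++i) v[i] = u[i] * ct + (a[i] * cp + b[i] * sp) * st;
  double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  for (int i = 0; i < 3; ++i) u[i] = v[i] / nv;
}

// photons: n x 7 matrix (x, y, z, ux, uy, uz, e_kev)
// boxes:   3 x 6 matrix (lo_x, lo_y, lo_z, hi_x, hi_y, hi_z) per layer
// att:     attenuation grid (energy_kev, mu_compton_mm, mu_pe_mm)
// [[Rcpp::export(name = ".cpp_transport")]]
List cpp_transport(NumericMatrix photons, NumericMatrix boxes,
                   NumericVector att_e, NumericVector att_muc,
                   NumericVector att_mupe, double e_cut) {
  int n = photons.nrow();
  int nl = boxes.nrow();
  size_t ng = att_e.size();
  std::vector<double> le(ng), lmc(ng), lmp(ng), lmt(ng);
  for (size_t i = 0; i < ng; ++i) {
    le[i] = std::log(att_e[i]);
    lmc[i] = std::log(att_muc[i]);
    lmp[i] = std::log(att_mupe[i]);
    lmt[i] = std::log(att_muc[i] + att_mupe[i]);
  }
  std::vector<int> r_pid, r_seq, r_layer, r_proc;
  std::vector<double> r_x, r_y, r_z, r_e;
  std::vector<double> escape(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    double p[3] = {photons(i, 0), photons(i, 1), photons(i, 2)};
    double u[3] = {photons(i, 3), photons(i, 4), photons(i, 5)};
    double E = photons(i, 6);
    int seq = 0;
    for (int step = 0; step < 100000; ++step) {
      // which layer (if any) contains the current point
      int inl = -1;
      for (int l = 0; l < nl; ++l) {
        if (p[0] > boxes(l, 0) && p[0] < boxes(l, 3) &&
            p[1] > boxes(l, 1) && p[1] < boxes(l, 4) &&
            p[2] > boxes(l, 2) && p[2] < boxes(l, 5)) { inl = l; break; }
      }
      if (inl < 0) {
        double best = INFINITY;
        for (int l = 0; l < nl; ++l) {
          double lo[3] = {boxes(l, 0), boxes(l, 1), boxes(l, 2)};
          double hi[3] = {boxes(l, 3), boxes(l, 4), boxes(l, 5)};
          double tn, tf;
          ray_box1(p, u, lo, hi, tn, tf);
          if (tf > std::max(tn, EPS) && tn > EPS && tn < best) best = tn;
        }
        if (!std::isfinite(best)) { escape[i] = E; break; }
        for (int ax = 0; ax < 3; ++ax) p[ax] += u[ax] * (best + EPS);
        continue;
      }
      double lo[3] = {boxes(inl, 0), boxes(inl, 1), boxes(inl, 2)};
      double hi[3] = {boxes(inl, 3), boxes(inl, 4), boxes(inl, 5)};
      double tn, tf;
      ray_box1(p, u, lo, hi, tn, tf);
      double mu_c = interp_loglog(le, lmc, E);
      double mu_pe = interp_loglog(le, lmp, E);
      double mu_t = interp_loglog(le, lmt, E);
      double s = exp_rand() / mu_t;
      if (s >= tf) { // leaves the crystal without interacting
        for (int ax = 0; ax < 3; ++ax) p[ax] += u[ax] * (tf + EPS);
        continue;
      }
      for (int ax = 0; ax < 3; ++ax) p[ax] += u[ax] * s;
      ++seq;
      if (unif_rand() < mu_pe / (mu_c + mu_pe)) { // photoelectric
        r_pid.push_back(i + 1); r_seq.push_back(seq);
        r_layer.push_back(inl + 1); r_proc.push_back(1);
        r_x.push_back(p[0]); r_y.push_back(p[1]); r_z.push_back(p[2]);
        r_e.push_back(E);
        break;
      }
      double ct = kn_sample(E);
      double ep = E / (1.0 + (E / M_E_KEV) * (1.0 - ct));
      double dep = E - ep;
      bool stop = ep < e_cut; // below-cutoff residual deposits locally
      if (stop) dep = E;
      r_pid.push_back(i + 1); r_seq.push_back(seq);
      r_layer.push_back(inl + 1); r_proc.push_back(2);
      r_x.push_back(p[0]); r_y.push_back(p[1]); r_z.push_back(p[2]);
      r_e.push_back(dep);
      if (stop) break;
      E = ep;
      rotate_dir(u, ct, unif_rand() * 2.0 * M_PI);
    }
  }
  return List::create(_["photon_id"] = wrap(r_pid), _["seq"] = wrap(r_seq),
                      _["layer"] = wrap(r_layer), _["proc"] = wrap(r_proc),
                      _["x_mm"] = wrap(r_x), _["y_mm"] = wrap(r_y),
                      _["z_mm"] = wrap(r_z), _["e_kev"] = wrap(r_e),
                      _["escape_kev"] = wrap(escape));
}
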