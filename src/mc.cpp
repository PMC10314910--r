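// Metropolis Monte Carlo relaxation of the (q0, qm) nematic texture on a
// fixed axisymmetric surface grid.  The lattice energy mirrors the R-side
// fields exactly: condensation + deviatoric densities on nodes, the
// intrinsic elastic term on links (staggered derivatives with midpoint
// geometric factors -- a centered scheme would leave checkerboard modes
// unpenalized and the sampler would populate them).  A consistency test
// asserts agreement with the R implementation.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Geom {
  int n_s, n_phi;
  double ds, dphi;
  const double *inv_rho;   // 1/rho on interior rows, 0 at poles
  const double *kg2;       // geodesic curvature of parallels, 0 at poles
  const double *H;         // mean curvature
  const double *Dv;        // curvature deviator
  const double *W;         // node area weight: simpson_w * rho * dphi
  const double *As;        // s-link area (link i: rows i,i+1; 0 if excluded)
  const double *ext;       // ki*(C1^2+C2^2) when extrinsic terms included
};

struct Par {
  double alpha, beta, ki, ke, Cp, lam0, lam_iso, lam_blend;
};

// deterministic RNG: xorshift64* uniform + Box-Muller normals
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  double unif() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    uint64_t x = s * 0x2545F4914F6CDD1DULL;
    return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  void normal2(double &g1, double &g2) {
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    g1 = r * std::cos(2.0 * M_PI * u2);
    g2 = r * std::sin(2.0 * M_PI * u2);
  }
};

inline int wrapj(int j, int n_phi) {
  if (j < 0) return j + n_phi;
  if (j >= n_phi) return j - n_phi;
  return j;
}

// condensation + deviatoric (+ optional extrinsic) energy of node (i, j)
double node_energy(const double *q0, const double *qm,
                   const Geom &g, const Par &p, int i, int j) {
  const int n = g.n_s;
  if (i == 0 || i == n - 1) return 0.0;
  const int idx = i + n * j;
  const double a = q0[idx], b = qm[idx];

  const double t = 2.0 * (a * a + b * b);
  double f = -p.alpha * t + 0.5 * p.beta * t * t;

  const double iso = (g.H[i] - p.Cp) * (g.H[i] - p.Cp) +
                     0.5 * g.Dv[i] * g.Dv[i];
  if (p.lam0 > 0.0) {
    const double lam = std::sqrt(a * a + b * b);
    const double c2e = lam > 0.0 ? a / lam : 1.0;
    const double cc = g.H[i] + g.Dv[i] * c2e - p.Cp;
    double tb = (lam / p.lam0 - p.lam_iso) / (p.lam_blend - p.lam_iso);
    tb = tb < 0.0 ? 0.0 : (tb > 1.0 ? 1.0 : tb);
    f += 0.5 * p.ke * ((1.0 - tb) * iso + tb * cc * cc);
  } else {
    f += 0.5 * p.ke * iso;
  }
  f += g.ext[i] * (a * a + b * b);
  return f * g.W[i];
}

// s-link between rows i and i+1 (0-based); As is 0 for excluded links
double slink_energy(const double *q0, const double *qm,
                    const Geom &g, const Par &p, int i, int j) {
  const int n = g.n_s;
  if (i < 0 || i >= n - 1 || g.As[i] == 0.0) return 0.0;
  const double d0 = q0[i + 1 + n * j] - q0[i + n * j];
  const double dm = qm[i + 1 + n * j] - qm[i + n * j];
  return p.ki * (d0 * d0 + dm * dm) / (g.ds * g.ds) * g.As[i];
}

// phi-link between (i, j) and (i, j+1)
double plink_energy(const double *q0, const double *qm,
                    const Geom &g, const Par &p, int i, int j) {
  const int n = g.n_s;
  if (i <= 0 || i >= n - 1) return 0.0;
  const int jp = wrapj(j + 1, g.n_phi);
  const int ia = i + n * j, ib = i + n * jp;
  const double d0 = (q0[ib] - q0[ia]) / g.dphi;
  const double dm = (qm[ib] - qm[ia]) / g.dphi;
  const double q0m = 0.5 * (q0[ib] + q0[ia]);
  const double qmm = 0.5 * (qm[ib] + qm[ia]);
  const double g0 = d0 * g.inv_rho[i] - 2.0 * g.kg2[i] * qmm;
  const double gm = dm * g.inv_rho[i] + 2.0 * g.kg2[i] * q0m;
  return p.ki * (g0 * g0 + gm * gm) * g.W[i];
}

// energy terms affected by a flip of site (i, j)
double local_energy(const double *q0, const double *qm,
                    const Geom &g, const Par &p, int i, int j) {
  return node_energy(q0, qm, g, p, i, j) +
    slink_energy(q0, qm, g, p, i - 1, j) +
    slink_energy(q0, qm, g, p, i, j) +
    plink_energy(q0, qm, g, p, i, wrapj(j - 1, g.n_phi)) +
    plink_energy(q0, qm, g, p, i, j);
}

Geom make_geom(const List &geom) {
  Geom g;
  g.n_s = as<int>(geom["n_s"]);
  g.n_phi = as<int>(geom["n_phi"]);
  g.ds = as<double>(geom["ds"]);
  g.dphi = 2.0 * M_PI / g.n_phi;
  g.inv_rho = REAL(as<NumericVector>(geom["inv_rho"]));
  g.kg2 = REAL(as<NumericVector>(geom["kg2"]));
  g.H = REAL(as<NumericVector>(geom["H"]));
  g.Dv = REAL(as<NumericVector>(geom["D"]));
  g.W = REAL(as<NumericVector>(geom["W"]));
  g.As = REAL(as<NumericVector>(geom["As"]));
  g.ext = REAL(as<NumericVector>(geom["ext"]));
  return g;
}

Par make_par(const List &par) {
  Par p;
  p.alpha = as<double>(par["alpha"]);
  p.beta = as<double>(par["beta"]);
  p.ki = as<double>(par["ki"]);
  p.ke = as<double>(par["ke"]);
  p.Cp = as<double>(par["Cp"]);
  p.lam0 = as<double>(par["lam0"]);
  p.lam_iso = as<double>(par["lam_iso"]);
  p.lam_blend = as<double>(par["lam_blend"]);
  return p;
}

} // namespace

// [[Rcpp::export]]
double cpp_texture_energy(NumericMatrix q0, NumericMatrix qm,
                          List geom, List par) {
  Geom g = make_geom(geom);
  Par p = make_par(par);
  const double *a = REAL(q0), *b = REAL(qm);
  double e = 0.0;
  for (int j = 0; j < g.n_phi; ++j) {
    for (int i = 1; i < g.n_s - 1; ++i) {
      e += node_energy(a, b, g, p, i, j);
      e += slink_energy(a, b, g, p, i, j);
      e += plink_energy(a, b, g, p, i, j);
    }
  }
  return e;
}

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix q0_in, NumericMatrix qm_in, List geom,
                List par, NumericVector temps, double sigma,
                double seed) {
  Geom g = make_geom(geom);
  Par p = make_par(par);
  NumericMatrix q0(clone(q0_in)), qm(clone(qm_in));
  double *a = REAL(q0), *b = REAL(qm);
  const int n = g.n_s, n_sweeps = temps.size();
  Rng rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL +
          1442695040888963407ULL);

  NumericVector acc(n_sweeps), e_trace(n_sweeps), mean_abs_de(n_sweeps);
  double E = cpp_texture_energy(q0, qm, geom, par);

  for (int sw = 0; sw < n_sweeps; ++sw) {
    const double T = temps[sw];
    long n_acc = 0, n_try = 0;
    double sum_abs = 0.0;
    for (int j = 0; j < g.n_phi; ++j) {
      for (int i = 1; i < n - 1; ++i) {
        double g1, g2;
        rng.normal2(g1, g2);
        const int idx = i + n * j;
        const double old0 = a[idx], oldm = b[idx];
        const double new0 = old0 + sigma * g1, newm = oldm + sigma * g2;
        ++n_try;
        if (new0 * new0 + newm * newm > 0.25) { rng.unif(); continue; }
        const double e_old = local_energy(a, b, g, p, i, j);
        a[idx] = new0; b[idx] = newm;
        const double e_new = local_energy(a, b, g, p, i, j);
        const double dE = e_new - e_old;
        sum_abs += std::fabs(dE);
        bool ok;
        double u = rng.unif();        // always draw: keeps streams aligned
        if (dE <= 0.0) ok = true;
        else if (T > 0.0) ok = u < std::exp(-dE / T);
        else ok = false;
        if (ok) { E += dE; ++n_acc; }
        else { a[idx] = old0; b[idx] = oldm; }
      }
    }
    acc[sw] = static_cast<double>(n_acc) / n_try;
    e_trace[sw] = E;
    mean_abs_de[sw] = sum_abs / n_try;
  }

  return List::create(_["q0"] = q0, _["qm"] = qm, _["accept"] = acc,
                      _["energy"] = e_trace,
                      _["mean_abs_de"] = mean_abs_de,
                      _["energy_final"] = cpp_texture_energy(q0, qm, geom, par),
                      _["energy_tracked"] = E);
}
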