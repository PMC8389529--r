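// Compiled inner loop: underdamped Langevin (BAOAB) + well-tempered
// metadynamics on either the first coordinate ("identity" CV) or toy-mode
// path collective variables (S, Z) with an upper wall on Z.
//
// The bias potential and its CV-space gradient are tabulated on a fine
// grid, updated analytically at every deposition and read back by
// bilinear interpolation; the exact hills are returned to R where all
// analysis re-sums them. Units: kcal/mol, nm, amu, ps; the single
// conversion factor 4.184 makes (kJ/mol, nm, amu, ps) dynamics
// consistent. Random numbers come from R's RNG, so runs are reproducible
// given set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KCAL2KJ = 4.184;
static const double KB_KCAL = 0.0019872;

struct ToySystem {
  int code; // 1 = double well (1D), 2 = funnel (2D)
  std::vector<double> p;

  double energy(const double* x) const {
    if (code == 1) {
      double r = x[0] / p[1];
      double q = r * r - 1.0;
      return p[0] * q * q;
    }
    // funnel: p = (D, sb, B, xb, st, kyb, kyu, xsw, sww, xlo, xhi, kw)
    double vx = -p[0] * std::exp(-x[0] * x[0] / (2 * p[1] * p[1])) +
                p[2] * std::exp(-(x[0] - p[3]) * (x[0] - p[3]) / (2 * p[4] * p[4]));
    if (x[0] > p[10]) vx += p[11] * (x[0] - p[10]) * (x[0] - p[10]);
    if (x[0] < p[9])  vx += p[11] * (p[9] - x[0]) * (p[9] - x[0]);
    double ky = p[6] + (p[5] - p[6]) / (1.0 + std::exp((x[0] - p[7]) / p[8]));
    return vx + 0.5 * ky * x[1] * x[1];
  }

  void grad(const double* x, double* g) const {
    if (code == 1) {
      double r2 = x[0] * x[0] / (p[1] * p[1]);
      g[0] = 4.0 * p[0] * x[0] * (r2 - 1.0) / (p[1] * p[1]);
      return;
    }
    double dvx = p[0] * x[0] / (p[1] * p[1]) *
                   std::exp(-x[0] * x[0] / (2 * p[1] * p[1])) -
                 p[2] * (x[0] - p[3]) / (p[4] * p[4]) *
                   std::exp(-(x[0] - p[3]) * (x[0] - p[3]) / (2 * p[4] * p[4]));
    if (x[0] > p[10]) dvx += 2 * p[11] * (x[0] - p[10]);
    if (x[0] < p[9])  dvx -= 2 * p[11] * (p[9] - x[0]);
    double e = std::exp((x[0] - p[7]) / p[8]);
    double ky = p[6] + (p[5] - p[6]) / (1.0 + e);
    double dky = -(p[5] - p[6]) * e / (p[8] * (1.0 + e) * (1.0 + e));
    g[0] = dvx + 0.5 * dky * x[1] * x[1];
    g[1] = ky * x[1];
  }
};

// Bias tables on a regular (s, z) grid: value and both partials.
struct BiasGrid {
  int ns, nz;
  double s0, ds, z0, dz;
  std::vector<double> v, gs, gz;

  void init(double smin, double smax, int ns_, double zmin, double zmax,
            int nz_) {
    ns = ns_; nz = nz_;
    s0 = smin; z0 = zmin;
    ds = (ns > 1) ? (smax - smin) / (ns - 1) : 1.0;
    dz = (nz > 1) ? (zmax - zmin) / (nz - 1) : 1.0;
    v.assign((size_t)ns * nz, 0.0);
    gs.assign((size_t)ns * nz, 0.0);
    gz.assign((size_t)ns * nz, 0.0);
  }

  void add_hill(double sc, double zc, double ss, double sz, double h) {
    int ilo = 0, ihi = ns - 1, jlo = 0, jhi = nz - 1;
    double cut = 6.0;
    ilo = std::max(0, (int)std::floor((sc - cut * ss - s0) / ds));
    ihi = std::min(ns - 1, (int)std::ceil((sc + cut * ss - s0) / ds));
    if (nz > 1) {
      jlo = std::max(0, (int)std::floor((zc - cut * sz - z0) / dz));
      jhi = std::min(nz - 1, (int)std::ceil((zc + cut * sz - z0) / dz));
    }
    for (int i = ilo; i <= ihi; ++i) {
      double es = (s0 + i * ds - sc) / ss;
      double fs = std::exp(-0.5 * es * es);
      for (int j = jlo; j <= jhi; ++j) {
        double g;
        size_t k = (size_t)i * nz + j;
        if (nz > 1) {
          double ez = (z0 + j * dz - zc) / sz;
          g = h * fs * std::exp(-0.5 * ez * ez);
          gz[k] += -g * ez / sz;
        } else {
          g = h * fs;
        }
        v[k] += g;
        gs[k] += -g * es / ss;
      }
    }
  }

  // bilinear interpolation (clamped at the borders)
  void eval(double s, double z, double* val, double* dvs, double* dvz) const {
    double fi = (s - s0) / ds, fj = (nz > 1) ? (z - z0) / dz : 0.0;
    if (fi < 0) fi = 0; if (fi > ns - 1.000001) fi = ns - 1.000001;
    if (fj < 0) fj = 0; if (fj > ((nz > 1) ? nz - 1.000001 : 0)) fj = nz - 1.000001;
    int i = (int)fi, j = (int)fj;
    double a = fi - i, b = fj - j;
    int i1 = std::min(i + 1, ns - 1), j1 = std::min(j + 1, nz - 1);
    size_t k00 = (size_t)i * nz + j, k10 = (size_t)i1 * nz + j;
    size_t k01 = (size_t)i * nz + j1, k11 = (size_t)i1 * nz + j1;
    double w00 = (1 - a) * (1 - b), w10 = a * (1 - b);
    double w01 = (1 - a) * b, w11 = a * b;
    *val = w00 * v[k00] + w10 * v[k10] + w01 * v[k01] + w11 * v[k11];
    *dvs = w00 * gs[k00] + w10 * gs[k10] + w01 * gs[k01] + w11 * gs[k11];
    *dvz = w00 * gz[k00] + w10 * gz[k10] + w01 * gz[k01] + w11 * gz[k11];
  }
};

// toy-mode PCV evaluation with gradients
static void pcv_eval(const double* x, int dim, const NumericMatrix& refs,
                     double lambda, double* s, double* z,
                     double* dsdx, double* dzdx) {
  int P = refs.nrow();
  std::vector<double> d2(P);
  double m = R_PosInf;
  for (int i = 0; i < P; ++i) {
    double acc = 0.0;
    for (int k = 0; k < dim; ++k) {
      double d = x[k] - refs(i, k);
      acc += d * d;
    }
    d2[i] = acc;
    if (acc < m) m = acc;
  }
  double W = 0.0, Wi = 0.0;
  std::vector<double> w(P);
  for (int i = 0; i < P; ++i) {
    w[i] = std::exp(-lambda * (d2[i] - m));
    W += w[i];
    Wi += (i + 1) * w[i];
  }
  double s_raw = Wi / W;
  *s = s_raw;
  *z = m - std::log(W) / lambda;
  for (int k = 0; k < dim; ++k) { dsdx[k] = 0.0; dzdx[k] = 0.0; }
  for (int i = 0; i < P; ++i) {
    for (int k = 0; k < dim; ++k) {
      double gd2 = 2.0 * (x[k] - refs(i, k));
      dsdx[k] += -lambda * ((i + 1) - s_raw) * w[i] * gd2 / W;
      dzdx[k] += w[i] * gd2 / W;
    }
  }
}

// [[Rcpp::export]]
List run_wtmetad_cpp(int system_code, NumericVector sys_params,
                     double temperature, double mass, int cv_code,
                     NumericMatrix refs, double lambda, double height0,
                     double biasf, double sigma_s, double sigma_z, int pace,
                     double wall_z, double wall_k, int n_steps, double dt,
                     double friction, NumericVector x0, int colvar_stride,
                     double grid_s_min, double grid_s_max, int grid_ns,
                     double grid_z_min, double grid_z_max, int grid_nz) {
  ToySystem sys;
  sys.code = system_code;
  sys.p.assign(sys_params.begin(), sys_params.end());
  int dim = (system_code == 1) ? 1 : 2;

  BiasGrid grid;
  grid.init(grid_s_min, grid_s_max, grid_ns, grid_z_min, grid_z_max, grid_nz);

  double kT = KB_KCAL * temperature;
  double kT_kj = kT * KCAL2KJ;
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * kT_kj / mass);

  std::vector<double> x(x0.begin(), x0.end()), vel(dim, 0.0);
  if ((int)x.size() != dim) stop("x0 dimension mismatch");

  // total force (kcal/mol/nm) = -dU/dx - dVbias/ds * ds/dx - ... - wall
  double s_cur = 0.0, z_cur = 0.0, bias_cur = 0.0;
  std::vector<double> f(dim, 0.0);
  std::vector<double> dsdx(dim, 0.0), dzdx(dim, 0.0);

  auto compute_force = [&]() {
    std::vector<double> g(dim, 0.0);
    sys.grad(x.data(), g.data());
    if (cv_code == 0) {
      s_cur = x[0];
      z_cur = 0.0;
      double val, dvs, dvz;
      grid.eval(s_cur, 0.0, &val, &dvs, &dvz);
      bias_cur = val;
      g[0] += dvs;
    } else {
      pcv_eval(x.data(), dim, refs, lambda, &s_cur, &z_cur,
               dsdx.data(), dzdx.data());
      double val, dvs, dvz;
      grid.eval(s_cur, z_cur, &val, &dvs, &dvz);
      bias_cur = val;
      double dwall = (z_cur > wall_z) ? 2.0 * wall_k * (z_cur - wall_z) : 0.0;
      for (int k = 0; k < dim; ++k)
        g[k] += dvs * dsdx[k] + (dvz + dwall) * dzdx[k];
    }
    for (int k = 0; k < dim; ++k) {
      if (!std::isfinite(g[k])) stop("non-finite force");
      f[k] = -g[k] * KCAL2KJ; // kJ/mol/nm
    }
  };
  compute_force();

  int n_hills_max = n_steps / pace + 1;
  int n_colvar_max = n_steps / colvar_stride + 2;
  NumericMatrix hills(n_hills_max, 7);
  NumericMatrix colvar(n_colvar_max, 4);
  int nh = 0, nc = 0;

  colvar(nc, 0) = 0.0; colvar(nc, 1) = s_cur; colvar(nc, 2) = z_cur;
  colvar(nc, 3) = bias_cur; ++nc;

  RNGScope scope;
  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < dim; ++k) {
      vel[k] += 0.5 * dt * f[k] / mass;
      x[k] += 0.5 * dt * vel[k];
      vel[k] = c1 * vel[k] + c2 * norm_rand();
      x[k] += 0.5 * dt * vel[k];
    }
    compute_force();
    for (int k = 0; k < dim; ++k) vel[k] += 0.5 * dt * f[k] / mass;

    if (step % pace == 0) {
      double h = height0 * std::exp(-bias_cur / ((biasf - 1.0) * kT));
      grid.add_hill(s_cur, z_cur, sigma_s, sigma_z, h);
      hills(nh, 0) = step * dt;
      hills(nh, 1) = s_cur;
      hills(nh, 2) = (cv_code == 0) ? 0.0 : z_cur;
      hills(nh, 3) = sigma_s;
      hills(nh, 4) = sigma_z;
      hills(nh, 5) = h;
      hills(nh, 6) = biasf;
      ++nh;
      compute_force(); // bias changed under our feet
    }
    if (step % colvar_stride == 0) {
      colvar(nc, 0) = step * dt;
      colvar(nc, 1) = s_cur;
      colvar(nc, 2) = z_cur;
      colvar(nc, 3) = bias_cur;
      ++nc;
    }
  }

  NumericMatrix hills_out(nh, 7), colvar_out(nc, 4);
  for (int i = 0; i < nh; ++i)
    for (int j = 0; j < 7; ++j) hills_out(i, j) = hills(i, j);
  for (int i = 0; i < nc; ++i)
    for (int j = 0; j < 4; ++j) colvar_out(i, j) = colvar(i, j);
  colnames(hills_out) = CharacterVector::create("time", "s", "z", "sigma_s",
                                                "sigma_z", "height", "biasf");
  colnames(colvar_out) = CharacterVector::create("time", "s", "z", "bias");
  return List::create(_["hills"] = hills_out, _["colvar"] = colvar_out);
}
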