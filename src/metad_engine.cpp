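// Desk-scale well-tempered PT-metadynamics engine: overdamped Langevin
// dynamics in a 2-D CV space on analytic model potentials, with hills
// accumulated on a grid (analytic Gaussian increments, 6-sigma
// truncation) and bilinear interpolation of the bias and its gradient.
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 0.0019872041; // kcal/mol/K

struct GaussWells {
  std::vector<double> cx, cy, d, w2; // centers, depths, squared widths
  double wall_k, lo, hi;
};

struct Harmonic { double cx, cy, kx, ky; };

struct TablePot {
  double x0, dx, y0, dy;
  int nx, ny;
  std::vector<double> v;
};

struct Potential {
  int kind; // 0 wells, 1 harmonic, 2 table
  GaussWells gw;
  Harmonic h;
  TablePot tp;
};

static Potential parse_potential(List pot) {
  Potential P;
  std::string kind = as<std::string>(pot["kind"]);
  List par = pot["parameters"];
  if (kind == "gaussian_wells" || kind == "double_well_2d" ||
      kind == "triple_well_2d") {
    P.kind = 0;
    NumericMatrix centers = par["centers"];
    NumericVector depths = par["depths"];
    NumericVector widths = par["widths"];
    for (int i = 0; i < centers.nrow(); ++i) {
      P.gw.cx.push_back(centers(i, 0));
      P.gw.cy.push_back(centers(i, 1));
      P.gw.d.push_back(depths[i]);
      double w = widths[i % widths.size()];
      P.gw.w2.push_back(w * w);
    }
    P.gw.wall_k = as<double>(par["wall_k"]);
    P.gw.lo = as<double>(par["wall_lo"]);
    P.gw.hi = as<double>(par["wall_hi"]);
  } else if (kind == "harmonic") {
    P.kind = 1;
    NumericVector c = par["center"];
    NumericVector k = par["stiffness"];
    P.h.cx = c[0]; P.h.cy = c[1];
    P.h.kx = k[0]; P.h.ky = k.size() > 1 ? k[1] : k[0];
  } else if (kind == "user_table") {
    P.kind = 2;
    NumericVector ax = par["ax"], ay = par["ay"];
    NumericMatrix v = par["values"];
    P.tp.x0 = ax[0]; P.tp.dx = ax[1] - ax[0]; P.tp.nx = ax.size();
    P.tp.y0 = ay[0]; P.tp.dy = ay[1] - ay[0]; P.tp.ny = ay.size();
    P.tp.v.assign(v.begin(), v.end()); // column-major [i + nx*j]
  } else {
    stop("unsupported potential kind: " + kind);
  }
  return P;
}

static double pot_eval(const Potential& P, double x, double y,
                       double* gx, double* gy) {
  double U = 0.0; *gx = 0.0; *gy = 0.0;
  if (P.kind == 0) {
    for (size_t i = 0; i < P.gw.d.size(); ++i) {
      double ddx = x - P.gw.cx[i], ddy = y - P.gw.cy[i];
      double e = std::exp(-(ddx * ddx + ddy * ddy) / (2.0 * P.gw.w2[i]));
      U -= P.gw.d[i] * e;
      *gx += P.gw.d[i] * e * ddx / P.gw.w2[i];
      *gy += P.gw.d[i] * e * ddy / P.gw.w2[i];
    }
    double lo = P.gw.lo, hi = P.gw.hi, k = P.gw.wall_k;
    if (x < lo) { U += k * (lo - x) * (lo - x); *gx += -2 * k * (lo - x); }
    if (x > hi) { U += k * (x - hi) * (x - hi); *gx += 2 * k * (x - hi); }
    if (y < lo) { U += k * (lo - y) * (lo - y); *gy += -2 * k * (lo - y); }
    if (y > hi) { U += k * (y - hi) * (y - hi); *gy += 2 * k * (y - hi); }
  } else if (P.kind == 1) {
    double ddx = x - P.h.cx, ddy = y - P.h.cy;
    U = 0.5 * P.h.kx * ddx * ddx + 0.5 * P.h.ky * ddy * ddy;
    *gx = P.h.kx * ddx; *gy = P.h.ky * ddy;
  } else {
    const TablePot& T = P.tp;
    double fx = (x - T.x0) / T.dx, fy = (y - T.y0) / T.dy;
    int i = (int)std::floor(fx), j = (int)std::floor(fy);
    if (i < 0) i = 0; if (i > T.nx - 2) i = T.nx - 2;
    if (j < 0) j = 0; if (j > T.ny - 2) j = T.ny - 2;
    double tx = fx - i, ty = fy - j;
    if (tx < 0) tx = 0; if (tx > 1) tx = 1;
    if (ty < 0) ty = 0; if (ty > 1) ty = 1;
    double v00 = T.v[i + T.nx * j], v10 = T.v[i + 1 + T.nx * j];
    double v01 = T.v[i + T.nx * (j + 1)], v11 = T.v[i + 1 + T.nx * (j + 1)];
    U = v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
        v01 * (1 - tx) * ty + v11 * tx * ty;
    *gx = ((v10 - v00) * (1 - ty) + (v11 - v01) * ty) / T.dx;
    *gy = ((v01 - v00) * (1 - tx) + (v11 - v10) * tx) / T.dy;
  }
  return U;
}

struct BiasGrid {
  double x0, dx, y0, dy;
  int nx, ny;
  std::vector<double> v, gx, gy;
  BiasGrid(double x0_, double dx_, int nx_, double y0_, double dy_, int ny_)
      : x0(x0_), dx(dx_), y0(y0_), dy(dy_), nx(nx_), ny(ny_),
        v(nx_ * ny_, 0.0), gx(nx_ * ny_, 0.0), gy(nx_ * ny_, 0.0) {}

  void deposit(double cx, double cy, double s1, double s2, double h) {
    int i0 = std::max(0, (int)std::ceil((cx - 6 * s1 - x0) / dx));
    int i1 = std::min(nx - 1, (int)std::floor((cx + 6 * s1 - x0) / dx));
    int j0 = std::max(0, (int)std::ceil((cy - 6 * s2 - y0) / dy));
    int j1 = std::min(ny - 1, (int)std::floor((cy + 6 * s2 - y0) / dy));
    for (int j = j0; j <= j1; ++j) {
      double ddy = y0 + j * dy - cy;
      double ey = std::exp(-ddy * ddy / (2 * s2 * s2));
      for (int i = i0; i <= i1; ++i) {
        double ddx = x0 + i * dx - cx;
        double g = h * std::exp(-ddx * ddx / (2 * s1 * s1)) * ey;
        int idx = i + nx * j;
        v[idx] += g;
        gx[idx] += -g * ddx / (s1 * s1);
        gy[idx] += -g * ddy / (s2 * s2);
      }
    }
  }

  void interp(double x, double y, double* V, double* Gx, double* Gy) const {
    double fx = (x - x0) / dx, fy = (y - y0) / dy;
    int i = (int)std::floor(fx), j = (int)std::floor(fy);
    if (i < 0) i = 0; if (i > nx - 2) i = nx - 2;
    if (j < 0) j = 0; if (j > ny - 2) j = ny - 2;
    double tx = fx - i, ty = fy - j;
    if (tx < 0) tx = 0; if (tx > 1) tx = 1;
    if (ty < 0) ty = 0; if (ty > 1) ty = 1;
    double w00 = (1 - tx) * (1 - ty), w10 = tx * (1 - ty);
    double w01 = (1 - tx) * ty, w11 = tx * ty;
    int a = i + nx * j, b = i + 1 + nx * j;
    int c = i + nx * (j + 1), d = i + 1 + nx * (j + 1);
    *V = w00 * v[a] + w10 * v[b] + w01 * v[c] + w11 * v[d];
    *Gx = w00 * gx[a] + w10 * gx[b] + w01 * gx[c] + w11 * gx[d];
    *Gy = w00 * gy[a] + w10 * gy[b] + w01 * gy[c] + w11 * gy[d];
  }
};

// 1-D static energy-bias table with linear interpolation
struct EnergyBias {
  bool active;
  double e0, de, scale;
  std::vector<double> b;
  double value(double U, double* dBdU) const {
    if (!active || scale == 0.0) { *dBdU = 0.0; return 0.0; }
    double f = (U - e0) / de;
    int i = (int)std::floor(f);
    int n = (int)b.size();
    if (i < 0) i = 0; if (i > n - 2) i = n - 2;
    double t = f - i;
    if (t < 0) t = 0; if (t > 1) t = 1;
    *dBdU = scale * (b[i + 1] - b[i]) / de;
    return scale * (b[i] * (1 - t) + b[i + 1] * t);
  }
};

// [[Rcpp::export]]
List cpp_metad_run(List pot, NumericMatrix x0, NumericVector temps,
                   double dt, double friction, int n_steps, int dep_stride,
                   double w0, double biasf, NumericVector sigma,
                   int exch_stride, int record_stride, int seed,
                   List grid_spec, List wte, bool deposit) {
  Potential P = parse_potential(pot);
  int n_rep = temps.size();
  std::vector<double> X(n_rep), Y(n_rep);
  for (int r = 0; r < n_rep; ++r) { X[r] = x0(r, 0); Y[r] = x0(r, 1); }

  BiasGrid grid(as<double>(grid_spec["x0"]), as<double>(grid_spec["dx"]),
                as<int>(grid_spec["nx"]), as<double>(grid_spec["y0"]),
                as<double>(grid_spec["dy"]), as<int>(grid_spec["ny"]));

  EnergyBias eb;
  eb.active = wte.containsElementNamed("bias") && !Rf_isNull(wte["bias"]);
  if (eb.active) {
    NumericVector e = wte["energies"], bb = wte["bias"];
    eb.e0 = e[0]; eb.de = e[1] - e[0];
    eb.b.assign(bb.begin(), bb.end());
    eb.scale = as<double>(wte["scale"]);
  } else { eb.e0 = 0; eb.de = 1; eb.scale = 0; }

  std::vector<std::mt19937_64> eng;
  for (int r = 0; r < n_rep; ++r) {
    eng.emplace_back(1000003ULL * (unsigned long long)seed + r + 1);
  }
  std::mt19937_64 eng_ex(1000003ULL * (unsigned long long)seed + 900001ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  int n_rec = n_steps / record_stride;
  int max_hills = dep_stride > 0 ? n_steps / dep_stride : 0;
  NumericMatrix hills(max_hills, 7);
  int n_hills = 0;
  NumericVector traj(n_rec * n_rep * 2);
  traj.attr("dim") = IntegerVector::create(n_rec, n_rep, 2);
  NumericVector rec_time(n_rec);
  int n_pairs = n_rep - 1;
  IntegerVector ex_att(std::max(n_pairs, 0)), ex_acc(std::max(n_pairs, 0));

  double mob = dt / friction;
  std::vector<double> noise_pref(n_rep);
  for (int r = 0; r < n_rep; ++r) {
    noise_pref[r] = std::sqrt(2.0 * KB * temps[r] * dt / friction);
  }
  int rec_i = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int r = 0; r < n_rep; ++r) {
      double gx, gy, V, bgx, bgy, dBdU;
      double U = pot_eval(P, X[r], Y[r], &gx, &gy);
      grid.interp(X[r], Y[r], &V, &bgx, &bgy);
      eb.value(U, &dBdU);
      double fx = (1.0 + dBdU) * gx + bgx;
      double fy = (1.0 + dBdU) * gy + bgy;
      if (!std::isfinite(fx) || !std::isfinite(fy)) {
        stop("non-finite force at replica %d, step %d", r + 1, step);
      }
      X[r] += -mob * fx + noise_pref[r] * gauss(eng[r]);
      Y[r] += -mob * fy + noise_pref[r] * gauss(eng[r]);
    }

    if (deposit && dep_stride > 0 && step % dep_stride == 0 &&
        n_hills < max_hills) {
      double V, d1, d2;
      grid.interp(X[0], Y[0], &V, &d1, &d2);
      double h = w0 * std::exp(-V / (KB * (biasf - 1.0) * temps[0]));
      grid.deposit(X[0], Y[0], sigma[0], sigma[1], h);
      hills(n_hills, 0) = step * dt;
      hills(n_hills, 1) = X[0];
      hills(n_hills, 2) = Y[0];
      hills(n_hills, 3) = sigma[0];
      hills(n_hills, 4) = sigma[1];
      hills(n_hills, 5) = h;
      hills(n_hills, 6) = biasf;
      ++n_hills;
    }

    if (exch_stride > 0 && n_rep > 1 && step % exch_stride == 0) {
      int phase = (step / exch_stride) % 2;
      for (int i = phase; i + 1 < n_rep; i += 2) {
        double g1, g2, V, dBdU;
        double Ui = pot_eval(P, X[i], Y[i], &g1, &g2);
        double Bi = eb.value(Ui, &dBdU);
        grid.interp(X[i], Y[i], &V, &g1, &g2);
        double Ei = Ui + Bi + V;
        double Uj = pot_eval(P, X[i + 1], Y[i + 1], &g1, &g2);
        double Bj = eb.value(Uj, &dBdU);
        grid.interp(X[i + 1], Y[i + 1], &V, &g1, &g2);
        double Ej = Uj + Bj + V;
        double delta = (1.0 / (KB * temps[i]) - 1.0 / (KB * temps[i + 1])) *
                       (Ei - Ej);
        ex_att[i] += 1;
        if (std::log(unif(eng_ex)) < delta) {
          std::swap(X[i], X[i + 1]);
          std::swap(Y[i], Y[i + 1]);
          ex_acc[i] += 1;
        } else {
          // keep stream usage identical regardless of outcome
        }
      }
    }

    if (record_stride > 0 && step % record_stride == 0 && rec_i < n_rec) {
      for (int r = 0; r < n_rep; ++r) {
        traj[rec_i + n_rec * r] = X[r];
        traj[rec_i + n_rec * (r + n_rep)] = Y[r];
      }
      rec_time[rec_i] = step * dt;
      ++rec_i;
    }
  }

  NumericMatrix hills_out(n_hills, 7);
  for (int i = 0; i < n_hills; ++i) {
    for (int j = 0; j < 7; ++j) hills_out(i, j) = hills(i, j);
  }
  NumericVector vgrid(grid.v.begin(), grid.v.end());
  vgrid.attr("dim") = IntegerVector::create(grid.nx, grid.ny);
  return List::create(
      _["hills"] = hills_out, _["traj"] = traj, _["rec_time"] = rec_time,
      _["exch_attempts"] = ex_att, _["exch_accepts"] = ex_acc,
      _["bias_grid"] = vgrid,
      _["final_x"] = NumericVector(X.begin(), X.end()),
      _["final_y"] = NumericVector(Y.begin(), Y.end()));
}
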