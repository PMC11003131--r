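// Minimal CG dynamics engine: harmonic bonds and angles, truncated 12-6
// Lennard-Jones pairs, BAOAB Langevin integration (friction 0 reduces
// exactly to velocity Verlet). Consistent GROMACS-style units (nm, ps, amu,
// kJ/mol) need no conversion factor: 1 kJ mol^-1 nm^-1 / amu = 1 nm ps^-2.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline void min_image3(double* d, const double* box, bool has_box) {
  if (!has_box) return;
  for (int k = 0; k < 3; ++k)
    d[k] -= box[k] * std::round(d[k] / box[k]);
}

// Evaluate potential energy and (optionally) forces. Coordinates and forces
// are flat length-3n arrays (x0,y0,z0,x1,...). LJ pairs are restricted to
// the candidate list `pairs` (pairs of 0-based indices) with per-pair
// epsilon/sigma; exclusions are handled upstream by omitting pairs.
static double eval_system(const std::vector<double>& x, int n,
                          const std::vector<int>& bond_i,
                          const std::vector<int>& bond_j,
                          const std::vector<double>& b0,
                          const std::vector<double>& kb,
                          const std::vector<int>& ang_i,
                          const std::vector<int>& ang_j,
                          const std::vector<int>& ang_k,
                          const std::vector<double>& th0,
                          const std::vector<double>& ka,
                          const std::vector<int>& lj_a,
                          const std::vector<int>& lj_b,
                          const std::vector<double>& lj_eps,
                          const std::vector<double>& lj_sig,
                          double cutoff2,
                          const double* box, bool has_box,
                          std::vector<double>* F) {
  double E = 0.0;
  if (F) std::fill(F->begin(), F->end(), 0.0);

  for (size_t t = 0; t < bond_i.size(); ++t) {
    const int i = bond_i[t], j = bond_j[t];
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    min_image3(d, box, has_box);
    const double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    const double dr = r - b0[t];
    E += 0.5 * kb[t] * dr * dr;
    if (F && r > 1e-12) {
      const double fmag = -kb[t] * dr / r;  // along d, applied to i
      for (int c = 0; c < 3; ++c) {
        (*F)[3 * i + c] += fmag * d[c];
        (*F)[3 * j + c] -= fmag * d[c];
      }
    }
  }

  for (size_t t = 0; t < ang_i.size(); ++t) {
    const int i = ang_i[t], j = ang_j[t], k = ang_k[t];
    double u[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    double v[3] = {x[3 * k] - x[3 * j], x[3 * k + 1] - x[3 * j + 1],
                   x[3 * k + 2] - x[3 * j + 2]};
    min_image3(u, box, has_box);
    min_image3(v, box, has_box);
    const double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    const double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    if (nu < 1e-12 || nv < 1e-12)
      stop("zero-length angle arm in angle term %d", (int)t + 1);
    double c = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (nu * nv);
    c = std::max(-1.0, std::min(1.0, c));
    const double th = std::acos(c);
    const double dth = th - th0[t];
    E += 0.5 * ka[t] * dth * dth;
    if (F) {
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;  // collinear guard
      const double dUdth = ka[t] * dth;
      // dtheta/dri = -(vhat - c uhat) / (|u| s); F_i = -dU/dth * dtheta/dri
      for (int cc = 0; cc < 3; ++cc) {
        const double uh = u[cc] / nu, vh = v[cc] / nv;
        const double fi = dUdth * (vh - c * uh) / (nu * s);
        const double fk = dUdth * (uh - c * vh) / (nv * s);
        (*F)[3 * i + cc] += fi;
        (*F)[3 * k + cc] += fk;
        (*F)[3 * j + cc] -= fi + fk;
      }
    }
  }

  for (size_t t = 0; t < lj_a.size(); ++t) {
    const int i = lj_a[t], j = lj_b[t];
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    min_image3(d, box, has_box);
    const double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= cutoff2 || r2 < 1e-20) continue;
    const double s2 = lj_sig[t] * lj_sig[t] / r2;
    const double s6 = s2 * s2 * s2;
    E += 4.0 * lj_eps[t] * (s6 * s6 - s6);
    if (F) {
      const double fmag = 24.0 * lj_eps[t] * (2.0 * s6 * s6 - s6) / r2;
      for (int c = 0; c < 3; ++c) {
        (*F)[3 * i + c] += fmag * d[c];
        (*F)[3 * j + c] -= fmag * d[c];
      }
    }
  }
  return E;
}

static void build_vectors(const IntegerMatrix& bonds, const NumericVector& b0,
                          const NumericVector& kb, std::vector<int>& bi,
                          std::vector<int>& bj, std::vector<double>& vb0,
                          std::vector<double>& vkb) {
  const int nb = bonds.nrow();
  bi.resize(nb); bj.resize(nb); vb0.resize(nb); vkb.resize(nb);
  for (int t = 0; t < nb; ++t) {
    bi[t] = bonds(t, 0); bj[t] = bonds(t, 1);
    vb0[t] = b0[t]; vkb[t] = kb[t];
  }
}

// candidate LJ pairs within cutoff + skin; eps(i,j) == 0 encodes "no
// interaction" (absent pair type or bonded exclusion).
static void build_pairs(const std::vector<double>& x, int n,
                        const NumericMatrix& eps, const NumericMatrix& sig,
                        double rlist2, const double* box, bool has_box,
                        std::vector<int>& a, std::vector<int>& b,
                        std::vector<double>& e, std::vector<double>& s) {
  a.clear(); b.clear(); e.clear(); s.clear();
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (eps(i, j) <= 0.0) continue;
      double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      min_image3(d, box, has_box);
      if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < rlist2) {
        a.push_back(i); b.push_back(j);
        e.push_back(eps(i, j)); s.push_back(sig(i, j));
      }
    }
}

// [[Rcpp::export(name = ".cg_eval_cpp")]]
List cg_eval_cpp(NumericMatrix X, IntegerMatrix bonds, NumericVector b0,
                 NumericVector kb, IntegerMatrix angles, NumericVector th0,
                 NumericVector ka, NumericMatrix eps, NumericMatrix sig,
                 double cutoff, NumericVector box) {
  const int n = X.nrow();
  const bool has_box = box.size() == 3;
  double boxv[3] = {0, 0, 0};
  if (has_box) { boxv[0] = box[0]; boxv[1] = box[1]; boxv[2] = box[2]; }

  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = X(i, c);

  std::vector<int> bi, bj, ai, aj, ak;
  std::vector<double> vb0, vkb, vth0, vka;
  build_vectors(bonds, b0, kb, bi, bj, vb0, vkb);
  const int na = angles.nrow();
  ai.resize(na); aj.resize(na); ak.resize(na); vth0.resize(na); vka.resize(na);
  for (int t = 0; t < na; ++t) {
    ai[t] = angles(t, 0); aj[t] = angles(t, 1); ak[t] = angles(t, 2);
    vth0[t] = th0[t]; vka[t] = ka[t];
  }
  std::vector<int> la, lb;
  std::vector<double> le, ls;
  build_pairs(x, n, eps, sig, 1e30, boxv, has_box, la, lb, le, ls);

  std::vector<double> F(3 * n);
  const double E = eval_system(x, n, bi, bj, vb0, vkb, ai, aj, ak, vth0, vka,
                               la, lb, le, ls, cutoff * cutoff, boxv, has_box,
                               &F);
  NumericMatrix Fout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) Fout(i, c) = F[3 * i + c];
  return List::create(_["forces"] = Fout, _["potential"] = E);
}

// BAOAB Langevin / velocity-Verlet integrator. Uses R's RNG (seeded from R
// with set.seed) for the O-step noise, so runs are reproducible and
// bitwise-identical for identical seed + config.
// [[Rcpp::export(name = ".cg_run_cpp")]]
List cg_run_cpp(NumericMatrix X0, NumericMatrix V0, NumericVector masses,
                IntegerMatrix bonds, NumericVector b0, NumericVector kb,
                IntegerMatrix angles, NumericVector th0, NumericVector ka,
                NumericMatrix eps, NumericMatrix sig, double cutoff,
                NumericVector box, double dt, int n_steps, double gamma,
                double kT, int save_interval, int nlist_interval,
                double t0) {
  const int n = X0.nrow();
  const bool has_box = box.size() == 3;
  double boxv[3] = {0, 0, 0};
  if (has_box) { boxv[0] = box[0]; boxv[1] = box[1]; boxv[2] = box[2]; }

  std::vector<double> x(3 * n), v(3 * n), m(n), invm(n);
  for (int i = 0; i < n; ++i) {
    m[i] = masses[i];
    invm[i] = 1.0 / masses[i];
    for (int c = 0; c < 3; ++c) {
      x[3 * i + c] = X0(i, c);
      v[3 * i + c] = V0(i, c);
    }
  }

  std::vector<int> bi, bj, ai, aj, ak;
  std::vector<double> vb0, vkb, vth0, vka;
  build_vectors(bonds, b0, kb, bi, bj, vb0, vkb);
  const int na = angles.nrow();
  ai.resize(na); aj.resize(na); ak.resize(na); vth0.resize(na); vka.resize(na);
  for (int t = 0; t < na; ++t) {
    ai[t] = angles(t, 0); aj[t] = angles(t, 1); ak[t] = angles(t, 2);
    vth0[t] = th0[t]; vka[t] = ka[t];
  }

  bool any_lj = false;
  for (int i = 0; i < n && !any_lj; ++i)
    for (int j = i + 1; j < n; ++j)
      if (eps(i, j) > 0) { any_lj = true; break; }
  const double skin = 0.3;
  const double rlist2 = (cutoff + skin) * (cutoff + skin);
  std::vector<int> la, lb;
  std::vector<double> le, ls;
  if (any_lj) build_pairs(x, n, eps, sig, rlist2, boxv, has_box, la, lb, le, ls);

  const double cut2 = cutoff * cutoff;
  // O-step coefficients
  const double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  const double c2 = (gamma > 0) ? std::sqrt((1.0 - c1 * c1) * kT) : 0.0;

  const int n_saved = 1 + (save_interval > 0 ? n_steps / save_interval : 0);
  NumericVector coords(static_cast<R_xlen_t>(n) * 3 * n_saved);
  coords.attr("dim") = IntegerVector::create(n, 3, n_saved);
  NumericVector times(n_saved), pot(n_saved), kin(n_saved);
  IntegerVector steps(n_saved);

  std::vector<double> F(3 * n);
  double E = eval_system(x, n, bi, bj, vb0, vkb, ai, aj, ak, vth0, vka,
                         la, lb, le, ls, cut2, boxv, has_box, &F);

  // kinetic energy with mass-weighted COM velocity removed (matches the
  // 3N - 3 degree-of-freedom convention of kinetic_temperature)
  auto kinetic = [&](void) {
    double vcm[3] = {0, 0, 0}, M = 0;
    for (int i = 0; i < n; ++i) {
      M += m[i];
      for (int c = 0; c < 3; ++c) vcm[c] += m[i] * v[3 * i + c];
    }
    for (int c = 0; c < 3; ++c) vcm[c] /= M;
    double ke = 0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) {
        const double dv = v[3 * i + c] - vcm[c];
        ke += 0.5 * m[i] * dv * dv;
      }
    return ke;
  };

  int isave = 0;
  auto record = [&](int step, double epot) {
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        coords[static_cast<R_xlen_t>(isave) * 3 * n + c * n + i] = x[3 * i + c];
    times[isave] = t0 + step * dt;
    pot[isave] = epot;
    kin[isave] = kinetic();
    steps[isave] = step;
    ++isave;
  };
  record(0, E);

  const int ndof = 3 * n - 3;
  double temp_accum = 0.0;

  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] += 0.5 * dt * F[3 * i + c] * invm[i];
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        const double sd = c2 * std::sqrt(invm[i]);
        for (int c = 0; c < 3; ++c)
          v[3 * i + c] = c1 * v[3 * i + c] + sd * norm_rand();
      }
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];

    if (any_lj && nlist_interval > 0 && step % nlist_interval == 0)
      build_pairs(x, n, eps, sig, rlist2, boxv, has_box, la, lb, le, ls);

    E = eval_system(x, n, bi, bj, vb0, vkb, ai, aj, ak, vth0, vka,
                    la, lb, le, ls, cut2, boxv, has_box, &F);
    // B
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] += 0.5 * dt * F[3 * i + c] * invm[i];

    if (!std::isfinite(E))
      stop("non-finite energy at step %d", step);
    for (int i = 0; i < 3 * n; ++i)
      if (!std::isfinite(x[i]) || !std::isfinite(F[i]))
        stop("non-finite coordinate or force at step %d", step);

    if (ndof > 0) temp_accum += 2.0 * kinetic() / (ndof * 0.0083144621);

    if (save_interval > 0 && step % save_interval == 0) record(step, E);
  }

  NumericMatrix Vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) Vout(i, c) = v[3 * i + c];

  return List::create(
      _["coords"] = coords, _["times"] = times, _["steps"] = steps,
      _["potential"] = pot, _["kinetic"] = kin, _["final_velocities"] = Vout,
      _["avg_temperature"] = n_steps > 0 ? temp_accum / n_steps : NA_REAL);
}
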