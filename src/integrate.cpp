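#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Delay-differential dynamics of the nine-genotype, two-sex gene drive model,
// integrated by the method of steps with classical RK4 and cubic Hermite
// dense history.  The single constant delay tau (egg-to-adult development) is
// an exact multiple of the step, so every derivative discontinuity generated
// by the t = 0 release propagates onto mesh points at t = k * tau.

struct ModelParams {
  const double* crossT;   // 9 x 81, column (j*9 + k) = offspring dist of father j x mother k
  const double* OmM;      // 9, male total relative fitness
  const double* OmF;      // 9, female
  double alpha, beta, rho, mu, psi;
  int ndeme;
  bool early;
};

// Offspring pools for one deme: v_i = w_i = sum_k F_k sum_j (M_j/M.) P(i|j,k).
// Each female contributes one male-egg unit and one female-egg unit per unit
// time (1:1 primary sex ratio); male genotypes enter as frequencies.
static inline void pools(const double* M, const double* F, const double* crossT,
                         double* p) {
  double Mtot = 0.0;
  double Mc[9], Fc[9];
  for (int j = 0; j < 9; ++j) {
    Mc[j] = M[j] > 0.0 ? M[j] : 0.0;  // guard vanishing interpolation noise
    Fc[j] = F[j] > 0.0 ? F[j] : 0.0;
    Mtot += Mc[j];
  }
  for (int i = 0; i < 9; ++i) p[i] = 0.0;
  if (Mtot <= 0.0) return;
  for (int j = 0; j < 9; ++j) {
    if (Mc[j] == 0.0) continue;
    double mf = Mc[j] / Mtot;
    for (int k = 0; k < 9; ++k) {
      double w = mf * Fc[k];
      if (w == 0.0) continue;
      const double* col = crossT + 9 * (j * 9 + k);
      for (int i = 0; i < 9; ++i) p[i] += w * col[i];
    }
  }
}

// Right-hand side; y and ylag have length 18 * ndeme, layout per deme
// [M_1..M_9, F_1..F_9].  Migration couples current-time states only.
static void rhs(const double* y, const double* ylag, double* dy,
                const ModelParams& pm) {
  for (int d = 0; d < pm.ndeme; ++d) {
    const double* M = y + 18 * d;
    const double* F = M + 9;
    const double* Ml = ylag + 18 * d;
    const double* Fl = Ml + 9;
    double p[9];
    pools(Ml, Fl, pm.crossT, p);
    double darg = 0.0;
    if (pm.early) {
      for (int i = 0; i < 9; ++i) darg += p[i] * (pm.OmM[i] + pm.OmF[i]);
    } else {
      for (int i = 0; i < 9; ++i) darg += 2.0 * p[i];
    }
    darg *= pm.alpha;
    double den = 1.0 + (darg > 0.0 ? std::pow(darg, pm.beta) : 0.0);
    double* dM = dy + 18 * d;
    double* dF = dM + 9;
    for (int i = 0; i < 9; ++i) {
      dM[i] = pm.rho * p[i] * pm.OmM[i] / den - pm.mu * M[i];
      dF[i] = pm.rho * p[i] * pm.OmF[i] / den - pm.mu * F[i];
    }
  }
  if (pm.ndeme == 2 && pm.psi != 0.0) {
    for (int i = 0; i < 18; ++i) {
      double ex = pm.psi * (y[18 + i] - y[i]);
      dy[i] += ex;
      dy[18 + i] -= ex;
    }
  }
}

// [[Rcpp::export]]
NumericVector dd_rhs_cpp(NumericVector y, NumericVector ylag,
                         NumericMatrix crossT, NumericVector OmM,
                         NumericVector OmF, double alpha, double beta,
                         double rho, double mu, double psi, int ndeme,
                         bool early) {
  ModelParams pm{REAL(crossT), REAL(OmM), REAL(OmF),
                 alpha, beta, rho, mu, psi, ndeme, early};
  NumericVector dy(y.size());
  rhs(REAL(y), REAL(ylag), REAL(dy), pm);
  return dy;
}

// Cubic Hermite interpolation of the stored mesh at fractional step index x
// (x <= 0 returns the constant pre-release history).
static inline void lag_lookup(double x, int dim, const std::vector<double>& ys,
                              const std::vector<double>& fs,
                              const double* hist, double h, double* out) {
  if (x <= 1e-12) {
    for (int i = 0; i < dim; ++i) out[i] = hist[i];
    return;
  }
  double xr = std::floor(x + 0.5);
  if (std::fabs(x - xr) < 1e-9) {
    const double* row = ys.data() + dim * (size_t)xr;
    for (int i = 0; i < dim; ++i) out[i] = row[i];
    return;
  }
  int k0 = (int)std::floor(x);
  double t = x - k0;
  const double* y0 = ys.data() + dim * (size_t)k0;
  const double* y1 = y0 + dim;
  const double* f0 = fs.data() + dim * (size_t)k0;
  const double* f1 = f0 + dim;
  double t2 = t * t, t3 = t2 * t;
  double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + t;
  double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
  for (int i = 0; i < dim; ++i)
    out[i] = h00 * y0[i] + h * h10 * f0[i] + h01 * y1[i] + h * h11 * f1[i];
}

// [[Rcpp::export]]
List dd_integrate_cpp(NumericVector y0, NumericVector history, double t_end,
                      double h, double tau, NumericMatrix crossT,
                      NumericVector OmM, NumericVector OmF, double alpha,
                      double beta, double rho, double mu, double psi,
                      int ndeme, bool early, int save_every,
                      double nonneg_tol) {
  const int dim = 18 * ndeme;
  if (y0.size() != dim || history.size() != dim)
    stop("state dimension mismatch");
  ModelParams pm{REAL(crossT), REAL(OmM), REAL(OmF),
                 alpha, beta, rho, mu, psi, ndeme, early};
  const int nsteps = (int)std::ceil(t_end / h - 1e-9);
  const int lagk = (int)std::floor(tau / h + 0.5);
  if (tau > 0.0 && std::fabs(lagk * h - tau) > 1e-8 * std::max(1.0, tau))
    stop("step size must divide the delay");

  std::vector<double> ys((size_t)(nsteps + 1) * dim), fs((size_t)(nsteps + 1) * dim);
  const double* hist = REAL(history);
  for (int i = 0; i < dim; ++i) ys[i] = y0[i];

  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), ytmp(dim), ylag(dim);
  const int nsave = nsteps / save_every + 1 + (nsteps % save_every ? 1 : 0);
  NumericMatrix out(nsave, dim);
  NumericVector tout(nsave);
  int isave = 0;
  auto save_row = [&](int k) {
    const double* row = ys.data() + dim * (size_t)k;
    for (int i = 0; i < dim; ++i) out(isave, i) = row[i];
    tout[isave] = k * h;
    ++isave;
  };
  save_row(0);

  for (int k = 0; k < nsteps; ++k) {
    double* yk = ys.data() + dim * (size_t)k;
    // stage 1 (also the stored mesh derivative)
    if (lagk == 0) {
      rhs(yk, yk, k1.data(), pm);
    } else {
      lag_lookup((double)k - lagk, dim, ys, fs, hist, h, ylag.data());
      rhs(yk, ylag.data(), k1.data(), pm);
    }
    for (int i = 0; i < dim; ++i) fs[dim * (size_t)k + i] = k1[i];
    // stages 2, 3 at the midpoint
    if (lagk > 0)
      lag_lookup((double)k + 0.5 - lagk, dim, ys, fs, hist, h, ylag.data());
    for (int i = 0; i < dim; ++i) ytmp[i] = yk[i] + 0.5 * h * k1[i];
    rhs(ytmp.data(), lagk == 0 ? ytmp.data() : ylag.data(), k2.data(), pm);
    for (int i = 0; i < dim; ++i) ytmp[i] = yk[i] + 0.5 * h * k2[i];
    rhs(ytmp.data(), lagk == 0 ? ytmp.data() : ylag.data(), k3.data(), pm);
    // stage 4
    if (lagk > 0)
      lag_lookup((double)k + 1.0 - lagk, dim, ys, fs, hist, h, ylag.data());
    for (int i = 0; i < dim; ++i) ytmp[i] = yk[i] + h * k3[i];
    rhs(ytmp.data(), lagk == 0 ? ytmp.data() : ylag.data(), k4.data(), pm);

    double* yk1 = ys.data() + dim * (size_t)(k + 1);
    for (int i = 0; i < dim; ++i) {
      yk1[i] = yk[i] + h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(yk1[i]))
        stop("integration produced a non-finite state at t = %f", (k + 1) * h);
      if (yk1[i] < -nonneg_tol)
        stop("integration produced a negative count (%e) at t = %f",
             yk1[i], (k + 1) * h);
    }
    if ((k + 1) % save_every == 0 || k + 1 == nsteps) save_row(k + 1);
  }
  if (isave < nsave) {
    tout = tout[Range(0, isave - 1)];
    out = out(Range(0, isave - 1), _);
  }
  return List::create(_["time"] = tout, _["state"] = out);
}
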