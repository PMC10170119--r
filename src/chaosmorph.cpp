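#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Reaction-diffusion explicit stepper (method of lines, RK4 + Euler-Maruyama)
//
// Fields are ny x nx matrices flattened column-major (y fastest), periodic in
// x, Neumann (mirrored ghost) or homogeneous Dirichlet (pinned rows) in y.
// Reaction codes: 0 = none, 1 = Brusselator, 2 = embedding coefficient
// fields f = a u + b v + d u v + e u^2 + h v^2, g = cg u.
// ---------------------------------------------------------------------------

struct RDParams {
  int nx, ny, m;
  double hx2i, hy2i;
  std::vector<double> D, lambda;
  std::vector<int> bc0, bc1;            // 0 = neumann, 1 = dirichlet
  std::vector<const double*> src;       // per-component source fields
  int rcode;
  double A, B;                          // brusselator
  const double *ca, *cb, *cd, *ce, *ch, *ccg;  // embedding fields
};

static inline void rd_rhs(const RDParams& p,
                          const std::vector<std::vector<double>>& u,
                          std::vector<std::vector<double>>& out) {
  const int nx = p.nx, ny = p.ny;
  for (int c = 0; c < p.m; ++c) {
    const double* uc = u[c].data();
    double* oc = out[c].data();
    const double Dc = p.D[c], lc = p.lambda[c];
    const double* sc = p.src[c];
    for (int j = 0; j < nx; ++j) {
      const int jl = (j == 0 ? nx - 1 : j - 1) * ny;
      const int jr = (j == nx - 1 ? 0 : j + 1) * ny;
      const int jc = j * ny;
      for (int i = 0; i < ny; ++i) {
        const int k = jc + i;
        double lap = (uc[jl + i] + uc[jr + i] - 2.0 * uc[k]) * p.hx2i;
        if (i == 0) {
          if (p.bc0[c] == 1) { oc[k] = 0.0; continue; }
          lap += 2.0 * (uc[k + 1] - uc[k]) * p.hy2i;
        } else if (i == ny - 1) {
          if (p.bc1[c] == 1) { oc[k] = 0.0; continue; }
          lap += 2.0 * (uc[k - 1] - uc[k]) * p.hy2i;
        } else {
          lap += (uc[k - 1] + uc[k + 1] - 2.0 * uc[k]) * p.hy2i;
        }
        double reac = 0.0;
        if (p.rcode == 1) {
          const double U = u[0][k], V = u[1][k];
          reac = (c == 0) ? p.A - (p.B + 1.0) * U + U * U * V
                          : p.B * U - U * U * V;
        } else if (p.rcode == 2) {
          const double U = u[0][k], V = u[1][k];
          reac = (c == 0)
            ? p.ca[k] * U + p.cb[k] * V + p.cd[k] * U * V +
                p.ce[k] * U * U + p.ch[k] * V * V
            : p.ccg[k] * U;
        }
        oc[k] = Dc * lap - lc * uc[k] + reac + sc[k];
      }
    }
  }
}

static inline bool rd_finite(const std::vector<std::vector<double>>& u,
                             double cap) {
  for (const auto& uc : u)
    for (double v : uc)
      if (!std::isfinite(v) || std::fabs(v) > cap) return false;
  return true;
}

// [[Rcpp::export]]
List rd_integrate_cpp(List init, int nx, int ny, double hx, double hy,
                      NumericVector D, NumericVector lambda,
                      IntegerVector bc0, IntegerVector bc1,
                      List sources, int rcode, List rparams,
                      double dt, int nsteps, int save_every,
                      double noise_amp, double blowup_cap) {
  const int m = D.size();
  RDParams p;
  p.nx = nx; p.ny = ny; p.m = m;
  p.hx2i = 1.0 / (hx * hx); p.hy2i = 1.0 / (hy * hy);
  p.D.assign(D.begin(), D.end());
  p.lambda.assign(lambda.begin(), lambda.end());
  p.bc0.assign(bc0.begin(), bc0.end());
  p.bc1.assign(bc1.begin(), bc1.end());
  std::vector<NumericMatrix> srcm(m);
  for (int c = 0; c < m; ++c) {
    srcm[c] = as<NumericMatrix>(sources[c]);
    p.src.push_back(srcm[c].begin());
  }
  p.rcode = rcode;
  NumericMatrix am, bm, dm, em, hm, cgm;   // keep alive
  p.A = p.B = 0.0;
  p.ca = p.cb = p.cd = p.ce = p.ch = p.ccg = nullptr;
  if (rcode == 1) {
    p.A = as<double>(rparams["A"]); p.B = as<double>(rparams["B"]);
  } else if (rcode == 2) {
    am = as<NumericMatrix>(rparams["a"]); bm = as<NumericMatrix>(rparams["b"]);
    dm = as<NumericMatrix>(rparams["d"]); em = as<NumericMatrix>(rparams["e"]);
    hm = as<NumericMatrix>(rparams["h"]);
    cgm = as<NumericMatrix>(rparams["cg"]);
    p.ca = am.begin(); p.cb = bm.begin(); p.cd = dm.begin(); p.ce = em.begin();
    p.ch = hm.begin(); p.ccg = cgm.begin();
  }

  const int npt = nx * ny;
  std::vector<std::vector<double>> u(m), y0(m), k1(m), k2(m), k3(m), k4(m),
      tmp(m);
  for (int c = 0; c < m; ++c) {
    NumericMatrix ic = as<NumericMatrix>(init[c]);
    u[c].assign(ic.begin(), ic.end());
    if (p.bc0[c] == 1) for (int j = 0; j < nx; ++j) u[c][j * ny] = 0.0;
    if (p.bc1[c] == 1) for (int j = 0; j < nx; ++j) u[c][j * ny + ny - 1] = 0.0;
    y0[c].resize(npt); k1[c].resize(npt); k2[c].resize(npt);
    k3[c].resize(npt); k4[c].resize(npt); tmp[c].resize(npt);
  }

  std::vector<double> times;
  List snaps;
  auto snapshot = [&](double t) {
    List s(m);
    for (int c = 0; c < m; ++c) {
      NumericMatrix out(ny, nx);
      std::copy(u[c].begin(), u[c].end(), out.begin());
      s[c] = out;
    }
    times.push_back(t);
    snaps.push_back(s);
  };
  snapshot(0.0);

  const double sq = noise_amp * std::sqrt(dt);
  std::string status = "ok";
  int step = 0;
  for (step = 1; step <= nsteps; ++step) {
    for (int c = 0; c < m; ++c) y0[c] = u[c];
    rd_rhs(p, u, k1);
    for (int c = 0; c < m; ++c)
      for (int k = 0; k < npt; ++k) tmp[c][k] = y0[c][k] + 0.5 * dt * k1[c][k];
    rd_rhs(p, tmp, k2);
    for (int c = 0; c < m; ++c)
      for (int k = 0; k < npt; ++k) tmp[c][k] = y0[c][k] + 0.5 * dt * k2[c][k];
    rd_rhs(p, tmp, k3);
    for (int c = 0; c < m; ++c)
      for (int k = 0; k < npt; ++k) tmp[c][k] = y0[c][k] + dt * k3[c][k];
    rd_rhs(p, tmp, k4);
    for (int c = 0; c < m; ++c)
      for (int k = 0; k < npt; ++k)
        u[c][k] = y0[c][k] + dt / 6.0 *
          (k1[c][k] + 2.0 * k2[c][k] + 2.0 * k3[c][k] + k4[c][k]);
    if (noise_amp > 0) {
      for (int c = 0; c < m; ++c) {
        for (int k = 0; k < npt; ++k) u[c][k] += sq * norm_rand();
        if (p.bc0[c] == 1) for (int j = 0; j < nx; ++j) u[c][j * ny] = 0.0;
        if (p.bc1[c] == 1)
          for (int j = 0; j < nx; ++j) u[c][j * ny + ny - 1] = 0.0;
      }
    }
    if (!rd_finite(u, blowup_cap)) {
      status = "blowup";
      break;
    }
    if (step % save_every == 0 || step == nsteps) snapshot(step * dt);
  }
  const double last_t = (status == "ok") ? nsteps * dt : (step - 1) * dt;
  return List::create(_["times"] = times, _["snapshots"] = snaps,
                      _["status"] = status, _["last_time"] = last_t);
}

// ---------------------------------------------------------------------------
// Amplitude ODE families
//
// family 1 "quadratic_cubic":
//   dX_i/dt = c0_i + sum_j L_ij X_j + X_i * sum_j B_ij X_j + cub_i X_i^3
//   (covers linear systems, the Roessler field, and the reduced Galerkin
//    projection of the embedding construction)
// family 2 "segment_groups": weakly coupled groups, each either a bistable
//   scalar unit dX = X - X^3 or a planar unit with a stable focus at 0 and a
//   stable unit limit cycle: dp = g(s) p - w q, dq = w p + g(s) q,
//   g(s) = cs (s - a)(1 - s), s = p^2 + q^2. Inter-group coupling adds
//   g_cpl * sum over first variables of the other groups.
// ---------------------------------------------------------------------------

struct OdeSys {
  int family = 1;
  int n = 0;
  std::vector<double> c0, cub;
  std::vector<double> L, B;             // n x n column-major
  std::vector<int> gfirst, gtype, gof;  // segment_groups layout
  double gcpl = 0, osc_a = 0.25, osc_w = 1.0, osc_c = 1.0;

  void rhs(const double* X, double* F) const {
    if (family == 1) {
      for (int i = 0; i < n; ++i) {
        double lin = c0[i], bil = 0.0;
        for (int j = 0; j < n; ++j) {
          lin += L[i + j * n] * X[j];
          bil += B[i + j * n] * X[j];
        }
        F[i] = lin + X[i] * bil + cub[i] * X[i] * X[i] * X[i];
      }
    } else {
      const int ng = (int)gfirst.size();
      double csum = 0.0;
      for (int k = 0; k < ng; ++k) csum += X[gfirst[k]];
      for (int k = 0; k < ng; ++k) {
        const int f = gfirst[k];
        const double other = gcpl * (csum - X[f]);
        if (gtype[k] == 0) {
          F[f] = X[f] - X[f] * X[f] * X[f] + other;
        } else {
          const double pp = X[f], qq = X[f + 1];
          const double s = pp * pp + qq * qq;
          const double g = osc_c * (s - osc_a) * (1.0 - s);
          F[f] = g * pp - osc_w * qq + other;
          F[f + 1] = osc_w * pp + g * qq + other;
        }
      }
    }
  }

  void jac(const double* X, double* J) const {  // J column-major n x n
    std::fill(J, J + n * n, 0.0);
    if (family == 1) {
      std::vector<double> BX(n, 0.0);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) BX[i] += B[i + j * n] * X[j];
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
          double v = L[i + j * n] + X[i] * B[i + j * n];
          if (i == j) v += BX[i] + 3.0 * cub[i] * X[i] * X[i];
          J[i + j * n] = v;
        }
    } else {
      const int ng = (int)gfirst.size();
      for (int k = 0; k < ng; ++k) {
        const int f = gfirst[k];
        if (gtype[k] == 0) {
          J[f + f * n] = 1.0 - 3.0 * X[f] * X[f];
        } else {
          const double pp = X[f], qq = X[f + 1];
          const double s = pp * pp + qq * qq;
          const double g = osc_c * (s - osc_a) * (1.0 - s);
          const double dg = osc_c * ((1.0 - s) - (s - osc_a));  // dg/ds
          J[f + f * n] = g + dg * 2.0 * pp * pp;
          J[f + (f + 1) * n] = dg * 2.0 * qq * pp - osc_w;
          J[(f + 1) + f * n] = osc_w + dg * 2.0 * pp * qq;
          J[(f + 1) + (f + 1) * n] = g + dg * 2.0 * qq * qq;
        }
        for (int k2 = 0; k2 < ng; ++k2) {
          if (k2 == k) continue;
          J[f + gfirst[k2] * n] += gcpl;
          if (gtype[k] == 1) J[(f + 1) + gfirst[k2] * n] += gcpl;
        }
      }
    }
  }
};

static OdeSys make_sys(List sys) {
  OdeSys s;
  s.family = as<int>(sys["family_code"]);
  s.n = as<int>(sys["n"]);
  if (s.family == 1) {
    NumericVector c0 = sys["c0"], cub = sys["cub"];
    NumericMatrix L = sys["L"], B = sys["B"];
    s.c0.assign(c0.begin(), c0.end());
    s.cub.assign(cub.begin(), cub.end());
    s.L.assign(L.begin(), L.end());
    s.B.assign(B.begin(), B.end());
  } else {
    IntegerVector gf = sys["gfirst"], gt = sys["gtype"];
    s.gfirst.assign(gf.begin(), gf.end());
    s.gtype.assign(gt.begin(), gt.end());
    s.gcpl = as<double>(sys["coupling"]);
    s.osc_a = as<double>(sys["osc_a"]);
    s.osc_w = as<double>(sys["osc_w"]);
    s.osc_c = as<double>(sys["osc_c"]);
  }
  return s;
}

static inline bool rk4_step(const OdeSys& s, std::vector<double>& X,
                            double dt, std::vector<double>& k1,
                            std::vector<double>& k2, std::vector<double>& k3,
                            std::vector<double>& k4, std::vector<double>& tmp) {
  const int n = s.n;
  s.rhs(X.data(), k1.data());
  for (int i = 0; i < n; ++i) tmp[i] = X[i] + 0.5 * dt * k1[i];
  s.rhs(tmp.data(), k2.data());
  for (int i = 0; i < n; ++i) tmp[i] = X[i] + 0.5 * dt * k2[i];
  s.rhs(tmp.data(), k3.data());
  for (int i = 0; i < n; ++i) tmp[i] = X[i] + dt * k3[i];
  s.rhs(tmp.data(), k4.data());
  for (int i = 0; i < n; ++i) {
    X[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (!std::isfinite(X[i]) || std::fabs(X[i]) > 1e8) return false;
  }
  return true;
}

// [[Rcpp::export]]
List ode_integrate_cpp(List sys, NumericVector X0, double dt, int nsteps,
                       int save_every) {
  OdeSys s = make_sys(sys);
  const int n = s.n;
  std::vector<double> X(X0.begin(), X0.end()), k1(n), k2(n), k3(n), k4(n),
      tmp(n);
  const int nsave = nsteps / save_every + 2;
  NumericMatrix traj(nsave, n);
  NumericVector times(nsave);
  int row = 0;
  for (int i = 0; i < n; ++i) traj(row, i) = X[i];
  times[row++] = 0.0;
  std::string status = "ok";
  int step;
  for (step = 1; step <= nsteps; ++step) {
    if (!rk4_step(s, X, dt, k1, k2, k3, k4, tmp)) { status = "blowup"; break; }
    if (step % save_every == 0 || step == nsteps) {
      for (int i = 0; i < n; ++i) traj(row, i) = X[i];
      times[row++] = step * dt;
    }
  }
  return List::create(_["times"] = times[Range(0, row - 1)],
                      _["X"] = traj(Range(0, row - 1), _),
                      _["status"] = status,
                      _["last_time"] = (status == "ok" ? nsteps * dt
                                                       : (step - 1) * dt));
}

// Benettin: integrate flow + tangent vector (variational equation via the
// analytic Jacobian), renormalize every renorm_steps, return per-interval
// log growth factors after the run (the caller discards the transient).
// [[Rcpp::export]]
List lyapunov_benettin_cpp(List sys, NumericVector X0, double dt, int nsteps,
                           int renorm_steps) {
  OdeSys s = make_sys(sys);
  const int n = s.n;
  std::vector<double> X(X0.begin(), X0.end()), k1(n), k2(n), k3(n), k4(n),
      tmp(n), w(n), J(n * n), wk1(n), wk2(n), wk3(n), wk4(n), wt(n);
  // deterministic initial tangent direction
  for (int i = 0; i < n; ++i) w[i] = 1.0 / std::sqrt((double)n);
  std::vector<double> logs;
  auto jmul = [&](const std::vector<double>& v, std::vector<double>& out) {
    for (int i = 0; i < n; ++i) {
      double a = 0.0;
      for (int j = 0; j < n; ++j) a += J[i + j * n] * v[j];
      out[i] = a;
    }
  };
  std::string status = "ok";
  for (int step = 1; step <= nsteps; ++step) {
    // tangent RK4 with Jacobian frozen at the current state (O(dt) accurate
    // per step for the tangent; growth-rate bias is O(dt) and negligible at
    // the step sizes used)
    s.jac(X.data(), J.data());
    jmul(w, wk1);
    for (int i = 0; i < n; ++i) wt[i] = w[i] + 0.5 * dt * wk1[i];
    jmul(wt, wk2);
    for (int i = 0; i < n; ++i) wt[i] = w[i] + 0.5 * dt * wk2[i];
    jmul(wt, wk3);
    for (int i = 0; i < n; ++i) wt[i] = w[i] + dt * wk3[i];
    jmul(wt, wk4);
    for (int i = 0; i < n; ++i)
      w[i] += dt / 6.0 * (wk1[i] + 2.0 * wk2[i] + 2.0 * wk3[i] + wk4[i]);
    if (!rk4_step(s, X, dt, k1, k2, k3, k4, tmp)) { status = "blowup"; break; }
    if (step % renorm_steps == 0) {
      double nrm = 0.0;
      for (int i = 0; i < n; ++i) nrm += w[i] * w[i];
      nrm = std::sqrt(nrm);
      logs.push_back(std::log(nrm));
      for (int i = 0; i < n; ++i) w[i] /= nrm;
    }
  }
  return List::create(_["log_growth"] = logs, _["status"] = status,
                      _["final_state"] = NumericVector(X.begin(), X.end()));
}

// ---------------------------------------------------------------------------
// Stochastic Turing machine primitives (use R's RNG for reproducibility)
// ---------------------------------------------------------------------------

// Absorption times for a finite chain given row-cumulative kernel (n x n,
// row i = cumulative probabilities of transitions out of state i).
// Returns -1 for censored replicates.
// [[Rcpp::export]]
IntegerVector markov_absorb_cpp(NumericMatrix cumP, int target0,
                                IntegerVector starts0, int max_steps) {
  const int n = cumP.nrow();
  const int R = starts0.size();
  IntegerVector taus(R);
  for (int r = 0; r < R; ++r) {
    int s = starts0[r];
    int t = 0;
    bool done = (s == target0);
    while (!done && t < max_steps) {
      const double u = unif_rand();
      int nxt = 0;
      while (nxt < n - 1 && cumP(s, nxt) < u) ++nxt;
      s = nxt;
      ++t;
      done = (s == target0);
    }
    taus[r] = done ? t : -1;
  }
  return taus;
}

// Staged nearest-neighbour random walk on the Boolean hypercube.
// stage_lens partitions the m coordinates; within stage j only those
// coordinates are flipped (uniformly) until they match the target substring,
// then they are frozen. Censoring applies to the total step count.
// [[Rcpp::export]]
List hypercube_walk_cpp(IntegerVector target, IntegerVector start,
                        IntegerVector stage_lens, int max_steps) {
  const int m = target.size();
  std::vector<int> s(start.begin(), start.end());
  const int K = stage_lens.size();
  IntegerVector stage_tau(K);
  int total = 0;
  bool censored = false;
  int off = 0;
  for (int k = 0; k < K && !censored; ++k) {
    const int mk = stage_lens[k];
    int mismatch = 0;
    for (int i = 0; i < mk; ++i) mismatch += (s[off + i] != target[off + i]);
    int t = 0;
    while (mismatch > 0) {
      if (total >= max_steps) { censored = true; break; }
      const int flip = off + (int)(unif_rand() * mk);
      const bool was = (s[flip] == target[flip]);
      s[flip] = 1 - s[flip];
      mismatch += was ? 1 : -1;
      ++t;
      ++total;
    }
    stage_tau[k] = t;
    off += mk;
  }
  return List::create(_["stage_tau"] = stage_tau, _["tau"] = total,
                      _["censored"] = censored);
}
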