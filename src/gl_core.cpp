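// Explicit Grunwald-Letnikov integration of the fractional-order
// Hodgkin-Huxley equations: membrane patch, 1-D cable (method of lines),
// and randomly connected network.  The membrane potential advances by
//   v_{n+1} = sum_{k=1}^{n+1} c_k^alpha v_{n+1-k} + (dt)^alpha f(t_n, state_n)
// while gates advance by forward Euler.  Three policies evaluate the memory
// sum: full history (exact), truncated (most recent L terms), and compressed
// (exact weights for the most recent K0 steps plus a sum-of-exponentials
// tail carried as recursively updated moments).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// x/(exp(x/y)-1), series fallback near the removable singularity
static inline double vtrap(double x, double y) {
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 - r / 2.0 + r * r / 12.0);
  return x / (std::exp(r) - 1.0);
}

struct Rates { double am, bm, ah, bh, an, bn; };

static inline Rates hh_rates(double v) {
  Rates r;
  r.am = 0.1 * vtrap(25.0 - v, 10.0);
  r.bm = 4.0 * std::exp(-v / 18.0);
  r.ah = 0.07 * std::exp(-v / 20.0);
  r.bh = 1.0 / (std::exp((30.0 - v) / 10.0) + 1.0);
  r.an = 0.01 * vtrap(10.0 - v, 10.0);
  r.bn = 0.125 * std::exp(-v / 80.0);
  return r;
}

// Memory engine for n_units fractional variables sharing one weight table.
// policy: 0 = full, 1 = truncated(L), 2 = compressed(K0 + SOE tail)
class GLMemory {
public:
  GLMemory(int policy, int n_units, long n_steps,
           const NumericVector& w, int L, int K0,
           const NumericVector& soe_w, const NumericVector& soe_rho)
    : policy_(policy), n_units_(n_units), w_(w), L_(L), K0_(K0) {
    wp_ = w_.size() ? &w_[0] : nullptr;
    if (policy_ == 2) {
      ring_.assign((size_t)(K0_ + 1) * n_units_, 0.0);
      M_ = soe_w.size();
      sw_.assign(soe_w.begin(), soe_w.end());
      srho_.assign(soe_rho.begin(), soe_rho.end());
      srho_k1_.resize(M_);
      for (int m = 0; m < M_; ++m)
        srho_k1_[m] = sw_[m] * std::pow(srho_[m], (double)(K0_ + 1));
      A_.assign((size_t)M_ * n_units_, 0.0);
    } else {
      hist_.assign((size_t)(n_steps + 1) * n_units_, 0.0);
    }
  }

  // record y_n (must be called for n = 0 before stepping, then after each step)
  void push(long n, const double* y) {
    if (policy_ == 2) {
      double* slot = &ring_[(size_t)(n % (K0_ + 1)) * n_units_];
      for (int u = 0; u < n_units_; ++u) slot[u] = y[u];
      // carry the tail moments forward: A(n+1) = rho*A(n) + w*rho^(K0+1)*y_{n-K0}
      if (n - K0_ >= 0) {
        const double* yold = &ring_[(size_t)((n - K0_) % (K0_ + 1)) * n_units_];
        for (int m = 0; m < M_; ++m) {
          double* Am = &A_[(size_t)m * n_units_];
          for (int u = 0; u < n_units_; ++u)
            Am[u] = srho_[m] * Am[u] + srho_k1_[m] * yold[u];
        }
      }
    } else {
      double* slot = &hist_[(size_t)n * n_units_];
      for (int u = 0; u < n_units_; ++u) slot[u] = y[u];
    }
  }

  // S_u = sum_{k=1}^{n+1} c_k y_{n+1-k}[u], written into out (length n_units)
  void memsum(long n, double* out) {
    for (int u = 0; u < n_units_; ++u) out[u] = 0.0;
    if (policy_ == 2) {
      long kmax = std::min((long)K0_, n + 1);
      for (long k = 1; k <= kmax; ++k) {
        double ck = wp_[k - 1];
        const double* yk = &ring_[(size_t)((n + 1 - k) % (K0_ + 1)) * n_units_];
        for (int u = 0; u < n_units_; ++u) out[u] += ck * yk[u];
      }
      if (n + 1 > K0_) {
        for (int m = 0; m < M_; ++m) {
          const double* Am = &A_[(size_t)m * n_units_];
          for (int u = 0; u < n_units_; ++u) out[u] += Am[u];
        }
      }
    } else {
      long kmax = n + 1;
      if (policy_ == 1) kmax = std::min(kmax, (long)L_);
      if (n_units_ == 1) {
        // contiguous dot product, newest to oldest
        const double* h = hist_.data();
        double acc = 0.0;
        for (long k = 1; k <= kmax; ++k) acc += wp_[k - 1] * h[n + 1 - k];
        out[0] = acc;
      } else {
        for (long k = 1; k <= kmax; ++k) {
          double ck = wp_[k - 1];
          const double* yk = &hist_[(size_t)(n + 1 - k) * n_units_];
          for (int u = 0; u < n_units_; ++u) out[u] += ck * yk[u];
        }
      }
    }
  }

private:
  int policy_, n_units_, L_, K0_, M_ = 0;
  NumericVector w_;
  const double* wp_ = nullptr;
  std::vector<double> hist_, ring_, A_, sw_, srho_, srho_k1_;
};

// gates are probabilities; clamping keeps the explicit update bounded even
// when extreme hyperpolarization makes the rates stiff
static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

static inline void check_state(double v, long n, double t) {
  if (!std::isfinite(v) || std::fabs(v) > 1e3)
    stop("numerical instability at step %d (t = %.6g ms): |v| exceeded 1000 mV or became non-finite; try a smaller dt",
         (int)n, t);
}

// ---------------------------------------------------------------- patch ----

// [[Rcpp::export]]
List cpp_hh_patch(double alpha, double dt, long n_steps,
                  NumericVector stim, NumericVector gbar, NumericVector erev,
                  NumericVector m0h0n0,
                  int policy, NumericVector w, int L, int K0,
                  NumericVector soe_w, NumericVector soe_rho,
                  int stride) {
  GLMemory mem(policy, 1, n_steps, w, L, K0, soe_w, soe_rho);
  const double gNa = gbar[0], gK = gbar[1], gL = gbar[2];
  const double ENa = erev[0], EK = erev[1], EL = erev[2];
  double v = 0.0, m = m0h0n0[0], h = m0h0n0[1], nn = m0h0n0[2];
  double c1 = w[0], dta = std::pow(dt, alpha);
  long n_rec = n_steps / stride + 1;
  NumericVector rv(n_rec), rm(n_rec), rh(n_rec), rn(n_rec),
                rINa(n_rec), rIK(n_rec), rIL(n_rec), rvmem(n_rec);
  double y0 = 0.0;
  mem.push(0, &y0);
  double vmem = 0.0;
  auto record = [&](long n) {
    long i = n / stride;
    double INa = gNa * m * m * m * h * (v - ENa);
    double IK = gK * nn * nn * nn * nn * (v - EK);
    double ILk = gL * (v - EL);
    rv[i] = v; rm[i] = m; rh[i] = h; rn[i] = nn;
    rINa[i] = INa; rIK[i] = IK; rIL[i] = ILk; rvmem[i] = vmem;
  };
  record(0);
  double S;
  for (long n = 0; n < n_steps; ++n) {
    double INa = gNa * m * m * m * h * (v - ENa);
    double IK = gK * nn * nn * nn * nn * (v - EK);
    double ILk = gL * (v - EL);
    double f = stim[n] - INa - IK - ILk;   // Cm^alpha = 1 in these units
    mem.memsum(n, &S);
    double vprev = v;
    v = S + dta * f;
    vmem = (n >= 1) ? (S - c1 * vprev) : 0.0;
    Rates r = hh_rates(vprev);
    m = clamp01(m + dt * (r.am * (1.0 - m) - r.bm * m));
    h = clamp01(h + dt * (r.ah * (1.0 - h) - r.bh * h));
    nn = clamp01(nn + dt * (r.an * (1.0 - nn) - r.bn * nn));
    check_state(v, n + 1, (n + 1) * dt);
    mem.push(n + 1, &v);
    if ((n + 1) % stride == 0) record(n + 1);
  }
  return List::create(_["v"] = rv, _["m"] = rm, _["h"] = rh, _["n"] = rn,
                      _["I_Na"] = rINa, _["I_K"] = rIK, _["I_L"] = rIL,
                      _["v_mem"] = rvmem);
}

// ---------------------------------------------------------------- cable ----

// [[Rcpp::export]]
List cpp_hh_cable(double alpha, double dt, long n_steps, int n_nodes,
                  NumericVector stim, IntegerVector stim_nodes,
                  NumericMatrix gbar_nodes, NumericVector erev,
                  NumericVector m0h0n0, double D,
                  int policy, NumericVector w, int L, int K0,
                  NumericVector soe_w, NumericVector soe_rho,
                  int stride) {
  GLMemory mem(policy, n_nodes, n_steps, w, L, K0, soe_w, soe_rho);
  const double ENa = erev[0], EK = erev[1], EL = erev[2];
  std::vector<double> v(n_nodes, 0.0), m(n_nodes, m0h0n0[0]),
                      h(n_nodes, m0h0n0[1]), nn(n_nodes, m0h0n0[2]),
                      S(n_nodes), vmem(n_nodes, 0.0), vnew(n_nodes);
  std::vector<char> is_stim(n_nodes, 0);
  for (int i = 0; i < stim_nodes.size(); ++i) is_stim[stim_nodes[i]] = 1;
  double c1 = w[0], dta = std::pow(dt, alpha);
  long n_rec = n_steps / stride + 1;
  NumericMatrix rv(n_rec, n_nodes);
  NumericVector peak_INa(n_nodes), peak_IK(n_nodes), peak_IL_dep(n_nodes),
                peak_vmem(n_nodes);
  mem.push(0, v.data());
  for (int u = 0; u < n_nodes; ++u) rv(0, u) = 0.0;
  for (long n = 0; n < n_steps; ++n) {
    mem.memsum(n, S.data());
    for (int u = 0; u < n_nodes; ++u) {
      double INa = gbar_nodes(u, 0) * m[u] * m[u] * m[u] * h[u] * (v[u] - ENa);
      double IK = gbar_nodes(u, 1) * nn[u] * nn[u] * nn[u] * nn[u] * (v[u] - EK);
      double ILk = gbar_nodes(u, 2) * (v[u] - EL);
      if (std::fabs(INa) > peak_INa[u]) peak_INa[u] = std::fabs(INa);
      if (std::fabs(IK) > peak_IK[u]) peak_IK[u] = std::fabs(IK);
      if (-ILk > peak_IL_dep[u]) peak_IL_dep[u] = -ILk;  // depolarizing = inward
      // sealed (zero-flux) ends: one-sided second difference conserves sum(v)
      double lap;
      if (u == 0) lap = v[1] - v[0];
      else if (u == n_nodes - 1) lap = v[n_nodes - 2] - v[n_nodes - 1];
      else lap = v[u + 1] - 2.0 * v[u] + v[u - 1];
      double I = is_stim[u] ? stim[n] : 0.0;
      double f = D * lap + I - INa - IK - ILk;
      vnew[u] = S[u] + dta * f;
      double vm = (n >= 1) ? (S[u] - c1 * v[u]) : 0.0;
      vmem[u] = vm;
      if (std::fabs(vm) > peak_vmem[u]) peak_vmem[u] = std::fabs(vm);
      Rates r = hh_rates(v[u]);
      m[u] = clamp01(m[u] + dt * (r.am * (1.0 - m[u]) - r.bm * m[u]));
      h[u] = clamp01(h[u] + dt * (r.ah * (1.0 - h[u]) - r.bh * h[u]));
      nn[u] = clamp01(nn[u] + dt * (r.an * (1.0 - nn[u]) - r.bn * nn[u]));
    }
    for (int u = 0; u < n_nodes; ++u) {
      check_state(vnew[u], n + 1, (n + 1) * dt);
      v[u] = vnew[u];
    }
    mem.push(n + 1, v.data());
    if ((n + 1) % stride == 0) {
      long i = (n + 1) / stride;
      for (int u = 0; u < n_nodes; ++u) rv(i, u) = v[u];
    }
  }
  return List::create(_["v"] = rv, _["peak_I_Na"] = peak_INa,
                      _["peak_I_K"] = peak_IK, _["peak_I_L_dep"] = peak_IL_dep,
                      _["peak_v_mem"] = peak_vmem);
}

// -------------------------------------------------------------- network ----

// [[Rcpp::export]]
List cpp_hh_network(double alpha, double dt, long n_steps, int N,
                    IntegerVector exc_ptr, IntegerVector exc_idx,
                    IntegerVector inh_ptr, IntegerVector inh_idx,
                    NumericVector syn,  // gsyn, Eex, Ein, Vsyn, ksyn
                    IntegerVector stim_neurons, double stim_amp, long stim_steps,
                    NumericVector gbar, NumericVector erev,
                    NumericVector m0h0n0,
                    int policy, NumericVector w, int L, int K0,
                    NumericVector soe_w, NumericVector soe_rho,
                    int stride) {
  GLMemory mem(policy, N, n_steps, w, L, K0, soe_w, soe_rho);
  const double gNa = gbar[0], gK = gbar[1], gLk = gbar[2];
  const double ENa = erev[0], EK = erev[1], EL = erev[2];
  const double gsyn = syn[0], Eex = syn[1], Ein = syn[2],
               Vsyn = syn[3], ksyn = syn[4];
  std::vector<double> v(N, 0.0), m(N, m0h0n0[0]), h(N, m0h0n0[1]),
                      nn(N, m0h0n0[2]), S(N), vnew(N), sgate(N);
  std::vector<char> is_stim(N, 0);
  for (int i = 0; i < stim_neurons.size(); ++i) is_stim[stim_neurons[i]] = 1;
  double dta = std::pow(dt, alpha);
  long n_rec = n_steps / stride + 1;
  NumericMatrix rv(n_rec, N);
  NumericVector rIsynE(n_rec), rIsynI(n_rec);  // network-averaged
  mem.push(0, v.data());
  for (long n = 0; n < n_steps; ++n) {
    mem.memsum(n, S.data());
    for (int j = 0; j < N; ++j)
      sgate[j] = 1.0 / (1.0 + std::exp(-(v[j] - Vsyn) / ksyn));
    double sumE = 0.0, sumI = 0.0;
    for (int u = 0; u < N; ++u) {
      double sE = 0.0, sI = 0.0;
      for (int p = exc_ptr[u]; p < exc_ptr[u + 1]; ++p) sE += sgate[exc_idx[p]];
      for (int p = inh_ptr[u]; p < inh_ptr[u + 1]; ++p) sI += sgate[inh_idx[p]];
      double IsynE = gsyn * sE * (v[u] - Eex);
      double IsynI = gsyn * sI * (v[u] - Ein);
      sumE += IsynE; sumI += IsynI;
      double INa = gNa * m[u] * m[u] * m[u] * h[u] * (v[u] - ENa);
      double IK = gK * nn[u] * nn[u] * nn[u] * nn[u] * (v[u] - EK);
      double ILk = gLk * (v[u] - EL);
      double I = (is_stim[u] && n < stim_steps) ? stim_amp : 0.0;
      double f = I - INa - IK - ILk - IsynE - IsynI;
      vnew[u] = S[u] + dta * f;
      Rates r = hh_rates(v[u]);
      m[u] = clamp01(m[u] + dt * (r.am * (1.0 - m[u]) - r.bm * m[u]));
      h[u] = clamp01(h[u] + dt * (r.ah * (1.0 - h[u]) - r.bh * h[u]));
      nn[u] = clamp01(nn[u] + dt * (r.an * (1.0 - nn[u]) - r.bn * nn[u]));
    }
    for (int u = 0; u < N; ++u) {
      check_state(vnew[u], n + 1, (n + 1) * dt);
      v[u] = vnew[u];
    }
    mem.push(n + 1, v.data());
    if ((n + 1) % stride == 0) {
      long i = (n + 1) / stride;
      for (int u = 0; u < N; ++u) rv(i, u) = v[u];
      rIsynE[i] = sumE / N; rIsynI[i] = sumI / N;
    }
  }
  return List::create(_["v"] = rv, _["I_synE"] = rIsynE, _["I_synI"] = rIsynI);
}
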