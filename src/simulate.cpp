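#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Conductance-based network core: N orexin (A) neurons, all-to-all gap
// coupled, reciprocally connected to one glutamate interneuron (B).
// State layout (flat vectors passed from R):
//   V_A[N], aK_A[N], a_glBA[N], a_ox[N], g_avail[N], a_glAB[M], V_B, aK_B
// a_glAB has one entry per A->B synapse; ab_presyn maps each synapse to the
// index of its presynaptic A neuron (all zeros in the effective two-neuron
// reduction, where one A neuron drives a mixture of synaptic thresholds).

struct Params {
  double C_m;
  double g_L, g_Na, g_K, g_gl, g_ox;
  double V_L, V_Na, V_K, V_gl, V_ox;
  double s_Na, s_K, s_gl, s_ox;
  double Vh_Na, Vh_K, theta_ox;
  double tau_K, tau_gl, tau_ox;
  double g_crit, gate_k, theta_dep, theta_rec;
  double g_gap;
};

static inline double sigm(double V, double s, double Vh) {
  return 1.0 / (1.0 + std::exp(-s * (V - Vh)));
}

struct Net {
  int N, M;
  Params p;
  const double *thBA, *thAB;
  const int *presyn;
  double dI, dT, Tper;
  bool stim_on;

  double stim(double t) const {
    if (!stim_on) return 0.0;
    double tm = t - Tper * std::floor(t / Tper);
    return (tm < dT) ? dI : 0.0;
  }

  // y and dy have length 5N + M + 2
  void rhs(const double *y, double t, double *dy) const {
    const double *V_A = y;
    const double *aK_A = y + N;
    const double *a_glBA = y + 2 * N;
    const double *a_ox = y + 3 * N;
    const double *g_av = y + 4 * N;
    const double *a_glAB = y + 5 * N;
    const double V_B = y[5 * N + M];
    const double aK_B = y[5 * N + M + 1];

    double *dV_A = dy;
    double *daK_A = dy + N;
    double *da_glBA = dy + 2 * N;
    double *da_ox = dy + 3 * N;
    double *dg_av = dy + 4 * N;
    double *da_glAB = dy + 5 * N;

    double Iext = stim(t);

    double mean_aox = 0.0;
    for (int i = 0; i < N; ++i) {
      double V = V_A[i];
      double I_L = p.g_L * (V - p.V_L);
      double I_Na = p.g_Na * sigm(V, p.s_Na, p.Vh_Na) * (V - p.V_Na);
      double I_K = p.g_K * aK_A[i] * (V - p.V_K);
      double I_gl = p.g_gl * a_glBA[i] * (V - p.V_gl);
      // pairwise differences cancel exactly for synchronized neurons, so
      // the homogeneous network reduces bitwise to the two-neuron model
      double gap_sum = 0.0;
      for (int j = 0; j < N; ++j) gap_sum += (V - V_A[j]);
      double I_gap = p.g_gap * gap_sum;
      dV_A[i] = (-I_L - I_Na - I_K - I_gl - I_gap + Iext) / p.C_m;
      daK_A[i] = (sigm(V, p.s_K, p.Vh_K) - aK_A[i]) / p.tau_K;
      da_glBA[i] = (sigm(V_B, p.s_gl, thBA[i]) - a_glBA[i]) / p.tau_gl;
      double fire = sigm(V, p.s_ox, p.theta_ox);
      double gate = sigm(g_av[i], p.gate_k, p.g_crit);
      da_ox[i] = (gate * fire - a_ox[i]) / p.tau_ox;
      dg_av[i] = (1.0 - g_av[i]) / p.theta_rec - fire * g_av[i] / p.theta_dep;
      mean_aox += (a_ox[i] - a_ox[0]);
    }
    // offset-form mean is exact when all entries coincide, keeping the
    // population drive identical to the single-neuron case
    mean_aox = a_ox[0] + mean_aox / N;

    double mean_aAB = 0.0;
    for (int j = 0; j < M; ++j) {
      da_glAB[j] = (sigm(V_A[presyn[j]], p.s_gl, thAB[j]) - a_glAB[j]) / p.tau_gl;
      mean_aAB += (a_glAB[j] - a_glAB[0]);
    }
    mean_aAB = a_glAB[0] + mean_aAB / M;

    double I_L = p.g_L * (V_B - p.V_L);
    double I_Na = p.g_Na * sigm(V_B, p.s_Na, p.Vh_Na) * (V_B - p.V_Na);
    double I_K = p.g_K * aK_B * (V_B - p.V_K);
    double I_gl = p.g_gl * mean_aAB * (V_B - p.V_gl);
    double I_ox = p.g_ox * mean_aox * (V_B - p.V_ox);
    dy[5 * N + M] = (-I_L - I_Na - I_K - I_gl - I_ox) / p.C_m;
    dy[5 * N + M + 1] = (sigm(V_B, p.s_K, p.Vh_K) - aK_B) / p.tau_K;
  }
};

static Params params_from_list(const List &par) {
  Params p;
  p.C_m = par["C_m"];
  p.g_L = par["g_L"]; p.g_Na = par["g_Na"]; p.g_K = par["g_K"];
  p.g_gl = par["g_gl"]; p.g_ox = par["g_ox"];
  p.V_L = par["V_L"]; p.V_Na = par["V_Na"]; p.V_K = par["V_K"];
  p.V_gl = par["V_gl"]; p.V_ox = par["V_ox"];
  p.s_Na = par["s_Na"]; p.s_K = par["s_K"]; p.s_gl = par["s_gl"];
  p.s_ox = par["s_ox"];
  p.Vh_Na = par["Vh_Na"]; p.Vh_K = par["Vh_K"]; p.theta_ox = par["theta_ox"];
  p.tau_K = par["tau_K"]; p.tau_gl = par["tau_gl"]; p.tau_ox = par["tau_ox"];
  p.g_crit = par["g_crit"]; p.gate_k = par["gate_k"];
  p.theta_dep = par["theta_dep"]; p.theta_rec = par["theta_rec"];
  p.g_gap = par["g_gap"];
  return p;
}

// Stochastic Heun step on a flat state vector. The same Wiener increment
// enters predictor and corrector (additive noise). Voltage equations only
// receive noise: indices 0..N-1 (A neurons) and 5N+M (neuron B).
// [[Rcpp::export]]
List simulate_network_cpp(NumericVector y0, List par,
                          NumericVector thresholds_BA,
                          NumericVector thresholds_AB,
                          IntegerVector ab_presyn,
                          double stim_height, double stim_length,
                          double stim_period, bool stim_enabled,
                          double D_A, double D_B,
                          double t0, double dt, double n_steps_d,
                          double record_every,
                          double spike_threshold, double refractory,
                          bool record_traces) {
  Net net;
  net.N = thresholds_BA.size();
  net.M = thresholds_AB.size();
  net.p = params_from_list(par);
  net.thBA = thresholds_BA.begin();
  net.thAB = thresholds_AB.begin();
  net.presyn = ab_presyn.begin();
  net.dI = stim_height; net.dT = stim_length; net.Tper = stim_period;
  net.stim_on = stim_enabled;

  const int N = net.N, M = net.M;
  const int dim = 5 * N + M + 2;
  if (y0.size() != dim)
    stop("state vector has length %d, expected %d", (int)y0.size(), dim);
  const long n_steps = (long)n_steps_d;

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> f1(dim), f2(dim), yp(dim), eta(N + 1, 0.0);

  const double sdA = std::sqrt(2.0 * D_A * dt) / net.p.C_m;
  const double sdB = std::sqrt(2.0 * D_B * dt) / net.p.C_m;
  const int iVB = 5 * N + M;

  // online spike detection: per-neuron previous V and last spike time
  std::vector<std::vector<double>> spikes(N + 1);
  std::vector<double> prevV(N + 1), lastSpike(N + 1, -1e18);
  for (int i = 0; i < N; ++i) prevV[i] = y[i];
  prevV[N] = y[iVB];

  long rec_stride = record_every > 0 ? std::max(1L, (long)std::llround(record_every / dt)) : 0;
  std::vector<double> tr_t, tr_VB, tr_VA1, tr_g, tr_aox;
  if (record_traces) {
    long cap = n_steps / std::max(rec_stride, 1L) + 2;
    tr_t.reserve(cap); tr_VB.reserve(cap); tr_VA1.reserve(cap);
    tr_g.reserve(cap); tr_aox.reserve(cap);
  }
  auto record = [&](double t) {
    if (!record_traces) return;
    double gm = 0.0, am = 0.0;
    for (int i = 0; i < N; ++i) { gm += y[4 * N + i]; am += y[3 * N + i]; }
    tr_t.push_back(t); tr_VB.push_back(y[iVB]); tr_VA1.push_back(y[0]);
    tr_g.push_back(gm / N); tr_aox.push_back(am / N);
  };
  record(t0);

  double t = t0;
  for (long step = 0; step < n_steps; ++step) {
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
    // one normal draw per noisy voltage equation, shared by both stages
    if (D_A > 0) for (int i = 0; i < N; ++i) eta[i] = sdA * norm_rand();
    if (D_B > 0) eta[N] = sdB * norm_rand();

    net.rhs(y.data(), t, f1.data());
    for (int k = 0; k < dim; ++k) yp[k] = y[k] + dt * f1[k];
    if (D_A > 0) for (int i = 0; i < N; ++i) yp[i] += eta[i];
    if (D_B > 0) yp[iVB] += eta[N];
    net.rhs(yp.data(), t + dt, f2.data());
    for (int k = 0; k < dim; ++k) y[k] += 0.5 * dt * (f1[k] + f2[k]);
    if (D_A > 0) for (int i = 0; i < N; ++i) y[i] += eta[i];
    if (D_B > 0) y[iVB] += eta[N];

    // clamp orexin availability to [0, 1] (safety net; normally inactive)
    for (int i = 0; i < N; ++i) {
      double &g = y[4 * N + i];
      if (g < 0.0) g = 0.0; else if (g > 1.0) g = 1.0;
    }

    t = t0 + (step + 1) * dt;

    for (int n = 0; n <= N; ++n) {
      double Vnow = (n < N) ? y[n] : y[iVB];
      if (!std::isfinite(Vnow))
        stop("non-finite membrane potential in neuron %s at t = %.3f ms",
             n < N ? ("A" + std::to_string(n)).c_str() : "B", t);
      if (std::fabs(Vnow) > 500.0)
        stop("integration unstable (|V| > 500 mV) in neuron %s at t = %.3f ms",
             n < N ? ("A" + std::to_string(n)).c_str() : "B", t);
      if (prevV[n] < spike_threshold && Vnow >= spike_threshold &&
          t - lastSpike[n] > refractory) {
        double frac = (spike_threshold - prevV[n]) / (Vnow - prevV[n]);
        double ts = t - dt + frac * dt;
        spikes[n].push_back(ts);
        lastSpike[n] = ts;
      }
      prevV[n] = Vnow;
    }

    if (record_traces && rec_stride > 0 && ((step + 1) % rec_stride == 0))
      record(t);
  }

  List spike_list(N + 1);
  CharacterVector ids(N + 1);
  for (int i = 0; i < N; ++i) {
    spike_list[i] = NumericVector(spikes[i].begin(), spikes[i].end());
    ids[i] = "A" + std::to_string(i);
  }
  spike_list[N] = NumericVector(spikes[N].begin(), spikes[N].end());
  ids[N] = "B";
  spike_list.names() = ids;

  List out = List::create(
    _["state"] = NumericVector(y.begin(), y.end()),
    _["t_end"] = t,
    _["spikes"] = spike_list);
  if (record_traces) {
    out["traces"] = DataFrame::create(
      _["t_ms"] = tr_t, _["V_B"] = tr_VB, _["V_A1"] = tr_VA1,
      _["g_avail_mean"] = tr_g, _["a_ox_mean"] = tr_aox);
  }
  return out;
}

// Deterministic right-hand side, exposed for cross-checks against the pure-R
// reference implementation.
// [[Rcpp::export]]
NumericVector network_rhs_cpp(NumericVector y, double t, List par,
                              NumericVector thresholds_BA,
                              NumericVector thresholds_AB,
                              IntegerVector ab_presyn,
                              double stim_height, double stim_length,
                              double stim_period, bool stim_enabled) {
  Net net;
  net.N = thresholds_BA.size();
  net.M = thresholds_AB.size();
  net.p = params_from_list(par);
  net.thBA = thresholds_BA.begin();
  net.thAB = thresholds_AB.begin();
  net.presyn = ab_presyn.begin();
  net.dI = stim_height; net.dT = stim_length; net.Tper = stim_period;
  net.stim_on = stim_enabled;
  const int dim = 5 * net.N + net.M + 2;
  if (y.size() != dim)
    stop("state vector has length %d, expected %d", (int)y.size(), dim);
  NumericVector dy(dim);
  net.rhs(y.begin(), t, dy.begin());
  return dy;
}
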