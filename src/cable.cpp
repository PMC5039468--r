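#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Myelinated axon cable model driven by an extracellular potential profile.
//
// Single-cable discretisation: nodes of Ranvier carry fast Na+, persistent
// Na+, slow K+ and leak channels (mammalian node kinetics, 36-37 C rate
// constants); internodes are passive with myelin-dominated membrane
// parameters. The extracellular field enters through the axial difference
// term g_ax * (Ve_j - Ve_i), gated by a rectangular pulse.
//
// All compartment quantities arrive pre-scaled from R in absolute units:
// capacitance uF, conductances mS, potentials mV, time ms; membrane currents
// are then in uA. Integration: gates advanced by exact exponential update at
// the current voltage, then a backward-Euler tridiagonal solve for V.

static const double V_LO = -250.0, V_HI = 150.0, V_STEP = 0.05;
static const int NTAB = (int)((V_HI - V_LO) / V_STEP) + 2;
static std::vector<double> tab_am, tab_bm, tab_ah, tab_bh, tab_ap, tab_bp,
    tab_as, tab_bs;
static bool tab_ready = false;

static inline double vtrap(double x, double y) {
  // x/(1-exp(-x/y)) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

static void build_tables() {
  tab_am.resize(NTAB); tab_bm.resize(NTAB); tab_ah.resize(NTAB);
  tab_bh.resize(NTAB); tab_ap.resize(NTAB); tab_bp.resize(NTAB);
  tab_as.resize(NTAB); tab_bs.resize(NTAB);
  for (int i = 0; i < NTAB; ++i) {
    const double v = V_LO + i * V_STEP;
    tab_am[i] = 6.57 * vtrap(v + 20.4, 10.3);
    tab_bm[i] = 0.304 * vtrap(-(v + 25.7), 9.16);
    tab_ah[i] = 0.34 * vtrap(-(v + 114.0), 11.0);
    tab_bh[i] = 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4));
    tab_ap[i] = 0.0353 * vtrap(v + 27.0, 10.2);
    tab_bp[i] = 0.000883 * vtrap(-(v + 34.0), 10.0);
    tab_as[i] = 0.3 / (1.0 + std::exp(-(v + 53.0) / 5.0));
    tab_bs[i] = 0.03 / (1.0 + std::exp(-(v + 90.0) / 1.0));
  }
  tab_ready = true;
}

static inline double lut(const std::vector<double> &t, double v) {
  if (v <= V_LO) return t[0];
  if (v >= V_HI) return t[NTAB - 1];
  const double f = (v - V_LO) / V_STEP;
  const int i = (int)f;
  const double w = f - i;
  return t[i] * (1.0 - w) + t[i + 1] * w;
}

// 1 - exp(-x) for x >= 0 with a cheap series fast path (x is dt*(a+b),
// usually well below 0.02 outside an action potential)
static inline double one_m_exp(double x) {
  if (x < 0.02) return x * (1.0 - 0.5 * x * (1.0 - x / 3.0));
  return 1.0 - std::exp(-x);
}

// [[Rcpp::export(name = ".cable_run_cpp")]]
List cable_run_cpp(NumericVector ve_mv, NumericVector cap_uF,
                   NumericVector gpas_mS, NumericVector e_pas,
                   NumericVector gnaf_mS, NumericVector gnap_mS,
                   NumericVector gks_mS, double e_na, double e_k,
                   NumericVector gax_mS, IntegerVector node_of,
                   double v_rest, double rate_factor, double dt_ms,
                   double settle_ms, double pw_ms, double t_end_ms,
                   int min_node_sep, bool record, List init,
                   bool return_state) {
  if (!tab_ready) build_tables();
  const int n = ve_mv.size();
  if (cap_uF.size() != n || gax_mS.size() != n - 1)
    stop("inconsistent compartment arrays");

  std::vector<double> V(n, v_rest), m(n, 0), h(n, 0), p(n, 0), s(n, 0);
  if (init.size() == 5) {
    NumericVector v0 = init[0], m0 = init[1], h0 = init[2], p0 = init[3],
                  s0 = init[4];
    if (v0.size() != n) stop("init state has wrong length");
    for (int i = 0; i < n; ++i) {
      V[i] = v0[i]; m[i] = m0[i]; h[i] = h0[i]; p[i] = p0[i]; s[i] = s0[i];
    }
  } else {
    // resting gate values at v_rest
    const double am = rate_factor * lut(tab_am, v_rest),
                 bm = rate_factor * lut(tab_bm, v_rest),
                 ah = rate_factor * lut(tab_ah, v_rest),
                 bh = rate_factor * lut(tab_bh, v_rest),
                 ap = rate_factor * lut(tab_ap, v_rest),
                 bp = rate_factor * lut(tab_bp, v_rest),
                 as = rate_factor * lut(tab_as, v_rest),
                 bs = rate_factor * lut(tab_bs, v_rest);
    for (int i = 0; i < n; ++i) {
      m[i] = am / (am + bm); h[i] = ah / (ah + bh);
      p[i] = ap / (ap + bp); s[i] = as / (as + bs);
    }
  }

  // peak-drive node (largest |Ve| among node compartments)
  int peak_node = 0;
  double best = -1.0;
  int n_nodes = 0;
  for (int i = 0; i < n; ++i) {
    if (node_of[i] >= 0) {
      ++n_nodes;
      if (std::fabs(ve_mv[i]) > best) {
        best = std::fabs(ve_mv[i]);
        peak_node = node_of[i];
      }
    }
  }

  std::vector<double> lo(n, 0), di(n, 0), up(n, 0), rhs(n, 0), cp(n, 0),
      dp(n, 0);
  const int nsteps = (int)std::ceil((settle_ms + t_end_ms) / dt_ms);
  bool activated = false;
  double t_act = NA_REAL;
  NumericMatrix trace;
  int rec_every = 0;
  if (record) {
    rec_every = std::max(1, nsteps / 600);
    trace = NumericMatrix(nsteps / rec_every + 1, n);
  }
  int rec_row = 0;

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt_ms;
    const double stim_on =
        (t >= settle_ms && t < settle_ms + pw_ms) ? 1.0 : 0.0;
    // gate update (exponential Euler at current V), node compartments only
    for (int i = 0; i < n; ++i) {
      if (node_of[i] < 0) continue;
      const double v = V[i];
      const double am = rate_factor * lut(tab_am, v),
                   bm = rate_factor * lut(tab_bm, v),
                   ah = rate_factor * lut(tab_ah, v),
                   bh = rate_factor * lut(tab_bh, v),
                   ap = rate_factor * lut(tab_ap, v),
                   bp = rate_factor * lut(tab_bp, v),
                   as = rate_factor * lut(tab_as, v),
                   bs = rate_factor * lut(tab_bs, v);
      m[i] += (am / (am + bm) - m[i]) * one_m_exp(dt_ms * (am + bm));
      h[i] += (ah / (ah + bh) - h[i]) * one_m_exp(dt_ms * (ah + bh));
      p[i] += (ap / (ap + bp) - p[i]) * one_m_exp(dt_ms * (ap + bp));
      s[i] += (as / (as + bs) - s[i]) * one_m_exp(dt_ms * (as + bs));
    }
    // assemble backward-Euler tridiagonal system
    for (int i = 0; i < n; ++i) {
      double g = gpas_mS[i];
      double ge = gpas_mS[i] * e_pas[i];
      if (node_of[i] >= 0) {
        const double gnaf = gnaf_mS[i] * m[i] * m[i] * m[i] * h[i];
        const double gnap = gnap_mS[i] * p[i] * p[i] * p[i];
        const double gks = gks_mS[i] * s[i];
        g += gnaf + gnap + gks;
        ge += (gnaf + gnap) * e_na + gks * e_k;
      }
      double d = cap_uF[i] / dt_ms + g;
      double r = cap_uF[i] / dt_ms * V[i] + ge;
      if (i > 0) {
        d += gax_mS[i - 1];
        r += stim_on * gax_mS[i - 1] * (ve_mv[i - 1] - ve_mv[i]);
      }
      if (i < n - 1) {
        d += gax_mS[i];
        r += stim_on * gax_mS[i] * (ve_mv[i + 1] - ve_mv[i]);
      }
      di[i] = d;
      rhs[i] = r;
      lo[i] = (i > 0) ? -gax_mS[i - 1] : 0.0;
      up[i] = (i < n - 1) ? -gax_mS[i] : 0.0;
    }
    // Thomas algorithm
    cp[0] = up[0] / di[0];
    dp[0] = rhs[0] / di[0];
    for (int i = 1; i < n; ++i) {
      const double mlt = 1.0 / (di[i] - lo[i] * cp[i - 1]);
      cp[i] = up[i] * mlt;
      dp[i] = (rhs[i] - lo[i] * dp[i - 1]) * mlt;
    }
    V[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];

    if (!std::isfinite(V[n / 2]))
      stop("membrane integration diverged (non-finite potential)");

    if (record && step % rec_every == 0 && rec_row < trace.nrow()) {
      for (int i = 0; i < n; ++i) trace(rec_row, i) = V[i];
      ++rec_row;
    }
    if (!activated && t >= settle_ms) {
      double vmax_node = -1e30;
      for (int i = 0; i < n; ++i) {
        if (node_of[i] < 0) continue;
        if (V[i] > vmax_node) vmax_node = V[i];
        if (std::abs(node_of[i] - peak_node) < min_node_sep) continue;
        if (V[i] > 0.0) {
          activated = true;
          t_act = t - settle_ms;
          break;
        }
      }
      if (activated && !record && !return_state) break;
      // subthreshold early exit: the pulse is long gone and every node is
      // far below threshold, so no spike can still develop
      if (!activated && !record && !return_state &&
          t > settle_ms + pw_ms + 1.0 && vmax_node < -40.0)
        break;
    }
  }

  List out = List::create(_["activated"] = activated, _["t_spike_ms"] = t_act,
                          _["n_nodes"] = n_nodes, _["peak_node"] = peak_node);
  if (record) out["trace"] = trace;
  if (return_state) {
    out["state"] = List::create(wrap(V), wrap(m), wrap(h), wrap(p), wrap(s));
  }
  return out;
}
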