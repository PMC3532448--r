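// Compartmental cable engine for conductance-based RGC models.
//
// Voltage is advanced by a Crank-Nicolson (theta = 1/2) update on the tree,
// solved in O(N) per step by Hines elimination (compartments are ordered so
// that parent index < child index).  Gating variables relax by their exact
// exponential solution against the voltage at the start of the step
// (staggered update); the intracellular calcium pool is a linear ODE and is
// also advanced exactly over each step.  The extracellular potential enters
// through the axial current terms: currents flow down gradients of
// (Vm + Ve), so a spatially uniform Ve produces no response.
//
// Units: mV, ms, uA, mS, uF, cm2 (conductance densities mS/cm2), mM.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double FARADAY = 96485.33212; // C/mol
static const double GASCONST = 8.31446;    // J/(mol K)

// x / (exp(x) - 1), finite at x = 0 (limit 1 - x/2 + ...)
static inline double exprel_inv(double x) {
  if (std::fabs(x) < 1e-7) return 1.0 - 0.5 * x;
  return x / (std::expm1(x));
}

// Five-channel RGC gating kinetics (Fohlmeister-Miller lineage).
// Rates in 1/ms, V in mV.  Order: m, h, n, a, hA, c.
static inline void hh_rates(double v, double s, double *al, double *be) {
  al[0] = s * 6.0   * exprel_inv(-0.1 * (v + 30.0));  // alpha_m
  be[0] = s * 20.0  * std::exp(-(v + 55.0) / 18.0);   // beta_m
  al[1] = s * 0.4   * std::exp(-(v + 50.0) / 20.0);   // alpha_h
  be[1] = s * 6.0   / (1.0 + std::exp(-0.1 * (v + 20.0))); // beta_h
  al[2] = s * 0.2   * exprel_inv(-0.1 * (v + 40.0));  // alpha_n
  be[2] = s * 0.4   * std::exp(-(v + 50.0) / 80.0);   // beta_n
  al[3] = s * 0.06  * exprel_inv(-0.1 * (v + 90.0));  // alpha_a
  be[3] = s * 0.1   * std::exp(-(v + 30.0) / 10.0);   // beta_a
  al[4] = s * 0.04  * std::exp(-(v + 70.0) / 20.0);   // alpha_hA
  be[4] = s * 0.6   / (1.0 + std::exp(-0.1 * (v + 40.0))); // beta_hA
  al[5] = s * 3.0   * exprel_inv(-0.1 * (v + 13.0));  // alpha_c
  be[5] = s * 10.0  * std::exp(-(v + 38.0) / 18.0);   // beta_c
}

// [[Rcpp::export]]
NumericMatrix hh_rates_cpp(NumericVector v, double rate_scale) {
  int n = v.size();
  NumericMatrix out(n, 12);
  double al[6], be[6];
  for (int i = 0; i < n; i++) {
    hh_rates(v[i], rate_scale, al, be);
    for (int g = 0; g < 6; g++) {
      out(i, 2 * g) = al[g];
      out(i, 2 * g + 1) = be[g];
    }
  }
  colnames(out) = CharacterVector::create(
    "alpha_m", "beta_m", "alpha_h", "beta_h", "alpha_n", "beta_n",
    "alpha_a", "beta_a", "alpha_hA", "beta_hA", "alpha_c", "beta_c");
  return out;
}

// Solve the symmetric tree-structured system A x = b where
// A[i,i] = diag[i], A[i,parent[i]] = A[parent[i],i] = off[i].
// parent is 0-based with -1 at the root and parent[i] < i.
// [[Rcpp::export]]
NumericVector hines_solve_cpp(IntegerVector parent, NumericVector diag,
                              NumericVector off, NumericVector rhs) {
  int n = diag.size();
  std::vector<double> d(diag.begin(), diag.end());
  std::vector<double> b(rhs.begin(), rhs.end());
  for (int i = n - 1; i > 0; i--) {
    int p = parent[i];
    double f = off[i] / d[i];
    d[p] -= f * off[i];
    b[p] -= f * b[i];
  }
  NumericVector x(n);
  x[0] = b[0] / d[0];
  for (int i = 1; i < n; i++) {
    x[i] = (b[i] - off[i] * x[parent[i]]) / d[i];
  }
  return x;
}

// [[Rcpp::export]]
List run_cable_cpp(IntegerVector parent,
                   NumericVector cap_uF,
                   NumericVector g_ax,
                   NumericVector area_cm2,
                   NumericMatrix gdens, // cols: gna gk ga gca gkca gl
                   List ion,
                   double dt,
                   int nsteps,
                   NumericVector stim_mid,  // uA at step midpoints (len nsteps or 0)
                   NumericVector ve_unit,   // mV per uA (len N or 0)
                   NumericMatrix inj,       // site0, amp_uA, onset_ms, dur_ms
                   NumericVector v0,
                   Nullable<List> state0,
                   IntegerVector record,    // 0-based
                   IntegerVector snap_steps,// 0-based, sorted; snapshot after step
                   int spike_site,          // 0-based, -1 off
                   double spike_thr,
                   double cross_min_ms,     // ignore crossings at/before this time
                   bool stop_on_spike,
                   int extra_steps,
                   int stim_substeps) {     // fixed refinement of stimulus-active steps
  const int N = parent.size();
  const double ena = as<double>(ion["ena"]);
  const double ek = as<double>(ion["ek"]);
  const double el = as<double>(ion["el"]);
  const double cao = as<double>(ion["cao_mM"]);
  const double ca_res = as<double>(ion["ca_res_mM"]);
  const double ca_tau = as<double>(ion["ca_tau_ms"]);
  const double ca_depth_um = as<double>(ion["ca_depth_um"]);
  const double kca_kd = as<double>(ion["kca_kd_mM"]);
  const double rate_scale = as<double>(ion["rate_scale"]);
  const double temp_C = as<double>(ion["temp_C"]);
  const double rt2f = 1000.0 * GASCONST * (temp_C + 273.15) / (2.0 * FARADAY); // mV
  // uA/cm2 -> mM/ms in a shell of ca_depth_um
  const double ca_conv = 1e-3 / (2.0 * FARADAY * ca_depth_um * 1e-4);

  const bool has_field = (stim_mid.size() > 0) && (ve_unit.size() == N);

  // absolute conductances (mS) per compartment and channel
  std::vector<double> Gna(N), Gk(N), Ga(N), Gca(N), Gkca(N), Gl(N);
  for (int i = 0; i < N; i++) {
    double A = area_cm2[i];
    Gna[i] = gdens(i, 0) * A;
    Gk[i] = gdens(i, 1) * A;
    Ga[i] = gdens(i, 2) * A;
    Gca[i] = gdens(i, 3) * A;
    Gkca[i] = gdens(i, 4) * A;
    Gl[i] = gdens(i, 5) * A;
  }

  // state
  std::vector<double> V(N), gm(N), gh(N), gn(N), ga_(N), gha(N), gc(N), ca(N);
  if (state0.isNotNull()) {
    List s(state0);
    NumericVector sv = s["V"], sm = s["m"], sh = s["h"], sn = s["n"],
                  sa = s["a"], sha = s["ha"], sc = s["c"], sca = s["ca"];
    for (int i = 0; i < N; i++) {
      V[i] = sv[i]; gm[i] = sm[i]; gh[i] = sh[i]; gn[i] = sn[i];
      ga_[i] = sa[i]; gha[i] = sha[i]; gc[i] = sc[i]; ca[i] = sca[i];
    }
  } else {
    double al[6], be[6];
    for (int i = 0; i < N; i++) {
      V[i] = v0[i];
      hh_rates(V[i], rate_scale, al, be);
      gm[i] = al[0] / (al[0] + be[0]);
      gh[i] = al[1] / (al[1] + be[1]);
      gn[i] = al[2] / (al[2] + be[2]);
      ga_[i] = al[3] / (al[3] + be[3]);
      gha[i] = al[4] / (al[4] + be[4]);
      gc[i] = al[5] / (al[5] + be[5]);
      ca[i] = ca_res;
    }
  }

  const int nrec = record.size();
  NumericMatrix vrec(nsteps + 1, nrec);
  for (int r = 0; r < nrec; r++) vrec(0, r) = V[record[r]];

  const int nsnap = snap_steps.size();
  NumericMatrix snaps(N, nsnap > 0 ? nsnap : 0);
  NumericVector snap_t(nsnap > 0 ? nsnap : 0);
  int snap_ptr = 0;

  IntegerVector first_cross(N, -1);

  std::vector<double> Gi(N), Bi(N), Adiag(N), Aoff(N), rhs(N), axial(N), dstore(N);
  double al[6], be[6];
  int steps_done = 0;
  int countdown = -1;

  int step;
  for (step = 0; step < nsteps; step++) {
    double t_mid = (step + 0.5) * dt;

    // the brief stimulus pulse drives a stiff transient; integrate those
    // steps (and the first step after the pulse) with a fixed number of
    // micro-steps so the transient is resolved at the default dt
    int nsub = 1;
    if (has_field && stim_substeps > 1) {
      bool active = stim_mid[step] != 0.0;
      bool after = step > 0 && stim_mid[step - 1] != 0.0;
      if (active || after) nsub = stim_substeps;
    }
    double dts = dt / nsub;

    for (int sub = 0; sub < nsub; sub++) {

    // 1. gates: exact exponential relaxation using V at start of step
    for (int i = 0; i < N; i++) {
      hh_rates(V[i], rate_scale, al, be);
      for (int g = 0; g < 6; g++) {
        double s = al[g] + be[g];
        double xinf = al[g] / s;
        double e = std::exp(-dts * s);
        double *x = (g == 0 ? &gm[i] : g == 1 ? &gh[i] : g == 2 ? &gn[i]
                     : g == 3 ? &ga_[i] : g == 4 ? &gha[i] : &gc[i]);
        *x = xinf + (*x - xinf) * e;
      }
    }

    // 2. ionic conductance/driving terms with new gates
    for (int i = 0; i < N; i++) {
      double gna = Gna[i] * gm[i] * gm[i] * gm[i] * gh[i];
      double gk4 = Gk[i] * gn[i] * gn[i] * gn[i] * gn[i];
      double gaa = Ga[i] * ga_[i] * ga_[i] * ga_[i] * gha[i];
      double rca = ca[i] / kca_kd;
      double fca = (rca * rca) / (1.0 + rca * rca);
      double gkca = Gkca[i] * fca;
      double gcc = Gca[i] * gc[i] * gc[i] * gc[i];
      double eca = rt2f * std::log(cao / ca[i]);
      Gi[i] = gna + gk4 + gaa + gkca + gcc + Gl[i];
      Bi[i] = gna * ena + (gk4 + gaa + gkca) * ek + gcc * eca + Gl[i] * el;
    }

    // 3. assemble the CN system: 0.5 L (V_n + V_{n+1}) + L Ve_mid, where
    //    (L x)_i = sum_j g_ij (x_j - x_i) over tree neighbours
    std::fill(axial.begin(), axial.end(), 0.0);
    for (int i = 1; i < N; i++) {
      int p = parent[i];
      double c = g_ax[i] * (V[p] - V[i]);
      axial[i] += c;
      axial[p] -= c;
    }
    for (int i = 0; i < N; i++) {
      double cdt = cap_uF[i] / dts;
      Adiag[i] = cdt + 0.5 * Gi[i];
      rhs[i] = cdt * V[i] - 0.5 * Gi[i] * V[i] + Bi[i] + 0.5 * axial[i];
      Aoff[i] = 0.0;
    }
    for (int i = 1; i < N; i++) {
      int p = parent[i];
      Adiag[i] += 0.5 * g_ax[i];
      Adiag[p] += 0.5 * g_ax[i];
      Aoff[i] = -0.5 * g_ax[i];
    }
    if (has_field) {
      double I_mid = stim_mid[step];
      if (I_mid != 0.0) {
        for (int i = 1; i < N; i++) {
          int p = parent[i];
          double c = g_ax[i] * I_mid * (ve_unit[p] - ve_unit[i]);
          rhs[i] += c;
          rhs[p] -= c;
        }
      }
    }
    // injections at midpoint
    for (int k = 0; k < inj.nrow(); k++) {
      double onset = inj(k, 2), dur = inj(k, 3);
      if (t_mid >= onset && t_mid < onset + dur) {
        rhs[(int)inj(k, 0)] += inj(k, 1);
      }
    }

    // Hines elimination
    for (int i = 0; i < N; i++) dstore[i] = Adiag[i];
    for (int i = N - 1; i > 0; i--) {
      int p = parent[i];
      double f = Aoff[i] / dstore[i];
      dstore[p] -= f * Aoff[i];
      rhs[p] -= f * rhs[i];
    }
    std::vector<double> Vn(N);
    Vn[0] = rhs[0] / dstore[0];
    for (int i = 1; i < N; i++)
      Vn[i] = (rhs[i] - Aoff[i] * Vn[parent[i]]) / dstore[i];

    // 5. calcium pool: exact update of linear ODE over the step
    for (int i = 0; i < N; i++) {
      if (Gca[i] > 0.0 || ca[i] > ca_res) {
        double eca = rt2f * std::log(cao / ca[i]);
        double jca = Gca[i] * gc[i] * gc[i] * gc[i] * (Vn[i] - eca) / area_cm2[i];
        double src = jca < 0.0 ? -jca * ca_conv : 0.0; // inward current loads the pool
        double cinf = ca_res + src * ca_tau;
        ca[i] = cinf + (ca[i] - cinf) * std::exp(-dts / ca_tau);
        if (ca[i] < ca_res) ca[i] = ca_res;
      }
    }

    // 6. bookkeeping: crossings and state swap
    double t_next = (step + (sub + 1.0) / nsub) * dt;
    for (int i = 0; i < N; i++) {
      if (first_cross[i] < 0 && t_next > cross_min_ms &&
          V[i] < spike_thr && Vn[i] >= spike_thr)
        first_cross[i] = step;
      V[i] = Vn[i];
    }

    } // micro-steps
    for (int r = 0; r < nrec; r++) vrec(step + 1, r) = V[record[r]];
    while (snap_ptr < nsnap && snap_steps[snap_ptr] == step) {
      for (int i = 0; i < N; i++) snaps(i, snap_ptr) = V[i];
      snap_t[snap_ptr] = (step + 1) * dt;
      snap_ptr++;
    }
    for (int i = 0; i < N; i++) {
      if (!std::isfinite(V[i]))
        stop("cable solver produced non-finite voltage at step %d, compartment %d",
             step + 1, i + 1);
    }

    steps_done = step + 1;
    if (stop_on_spike && spike_site >= 0 && countdown < 0 &&
        first_cross[spike_site] >= 0) {
      countdown = extra_steps;
    }
    if (countdown > 0) countdown--;
    else if (countdown == 0) { step++; break; }
  }

  NumericVector tout(steps_done + 1);
  for (int s = 0; s <= steps_done; s++) tout[s] = s * dt;
  NumericMatrix vrec_out(steps_done + 1, nrec);
  for (int s = 0; s <= steps_done; s++)
    for (int r = 0; r < nrec; r++) vrec_out(s, r) = vrec(s, r);

  List state = List::create(
    _["V"] = NumericVector(V.begin(), V.end()),
    _["m"] = NumericVector(gm.begin(), gm.end()),
    _["h"] = NumericVector(gh.begin(), gh.end()),
    _["n"] = NumericVector(gn.begin(), gn.end()),
    _["a"] = NumericVector(ga_.begin(), ga_.end()),
    _["ha"] = NumericVector(gha.begin(), gha.end()),
    _["c"] = NumericVector(gc.begin(), gc.end()),
    _["ca"] = NumericVector(ca.begin(), ca.end()));

  return List::create(
    _["t"] = tout,
    _["vrec"] = vrec_out,
    _["snaps"] = snaps,
    _["snap_times"] = snap_t,
    _["first_cross"] = first_cross,
    _["state"] = state,
    _["steps_done"] = steps_done);
}
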