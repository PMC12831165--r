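#include <Rcpp.h>
using namespace Rcpp;

// Hybrid deterministic-stochastic single-complex model. Each spot carries two
// ODEs:
//   dI/dt = Pform * Pbound * Kg / (Klimit + I) - Kd * X * I
//   dX/dt = Kxb * I - Kxd * X
// Pform switches 0 -> 1 at the spot's formation time. Pbound is either a
// two-state telegraph process (exact exponential switch times, rates k_bind /
// k_unbind) or a constant mean-field occupancy. Between switch events the
// ODEs are integrated with fixed-step RK4; integration steps never straddle a
// switch or a recording time, so the state is continuous across switches and
// the gate is exact.

struct Pars { double kg, klimit, kd, kxb, kxd; };

static inline void rhs(double I, double X, double gate, const Pars &p,
                       double &dI, double &dX) {
  dI = gate * p.kg / (p.klimit + I) - p.kd * X * I;
  dX = p.kxb * I - p.kxd * X;
}

static void rk4_advance(double &I, double &X, double gate, double from,
                        double to, double dt, const Pars &p) {
  double t = from;
  while (t < to - 1e-12) {
    double h = std::min(dt, to - t);
    double k1I, k1X, k2I, k2X, k3I, k3X, k4I, k4X;
    rhs(I, X, gate, p, k1I, k1X);
    rhs(I + 0.5 * h * k1I, X + 0.5 * h * k1X, gate, p, k2I, k2X);
    rhs(I + 0.5 * h * k2I, X + 0.5 * h * k2X, gate, p, k3I, k3X);
    rhs(I + h * k3I, X + h * k3X, gate, p, k4I, k4X);
    I += h / 6.0 * (k1I + 2 * k2I + 2 * k3I + k4I);
    X += h / 6.0 * (k1X + 2 * k2X + 2 * k3X + k4X);
    if (I < 0 && I > -1e-9) I = 0;
    if (X < 0 && X > -1e-9) X = 0;
    if (!std::isfinite(I) || !std::isfinite(X) || I < 0 || X < 0)
      stop("integration diverged (I or X non-finite/negative); reduce dt");
    t += h;
  }
}

// [[Rcpp::export]]
List hydes_simulate_cpp(NumericVector formation_times,
                        NumericVector record_times,
                        double kgrowth, double klimit, double kdbasal,
                        double kxbasal, double kxdbasal,
                        bool telegraph, double k_bind, double k_unbind,
                        double pbound_const, double dt) {
  const int n_spots = formation_times.size();
  const int n_rec = record_times.size();
  NumericMatrix I_out(n_rec, n_spots), X_out(n_rec, n_spots);
  IntegerMatrix B_out(n_rec, n_spots);
  Pars p = {kgrowth, klimit, kdbasal, kxbasal, kxdbasal};
  const double t_end = record_times[n_rec - 1];

  for (int s = 0; s < n_spots; ++s) {
    double t_form = formation_times[s];
    double I = 0.0, X = 0.0;
    double t = t_form;
    // spots start in the bound state at formation
    bool bound = true;
    double t_switch;
    if (telegraph) {
      t_switch = (k_unbind > 0) ? t + R::exp_rand() / k_unbind : t_end + 1.0;
    } else {
      t_switch = t_end + 1.0;
    }
    int rec = 0;
    while (rec < n_rec && record_times[rec] < t_form - 1e-12) {
      I_out(rec, s) = 0.0; X_out(rec, s) = 0.0; B_out(rec, s) = 0;
      ++rec;
    }
    while (rec < n_rec) {
      double target = record_times[rec];
      while (t_switch < target - 1e-12) {
        double gate = telegraph ? (bound ? 1.0 : 0.0) : pbound_const;
        rk4_advance(I, X, gate, t, t_switch, dt, p);
        t = t_switch;
        bound = !bound;
        double rate = bound ? k_unbind : k_bind;
        t_switch = (rate > 0) ? t + R::exp_rand() / rate : t_end + 1.0;
      }
      double gate = telegraph ? (bound ? 1.0 : 0.0) : pbound_const;
      rk4_advance(I, X, gate, t, target, dt, p);
      t = target;
      I_out(rec, s) = I; X_out(rec, s) = X;
      B_out(rec, s) = telegraph ? (bound ? 1 : 0) : 1;
      ++rec;
    }
  }
  return List::create(_["intensity"] = I_out, _["xbasal"] = X_out,
                      _["bound"] = B_out);
}
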