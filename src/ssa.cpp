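#include <Rcpp.h>
using namespace Rcpp;

// Direct-method Gillespie simulation of the three-step reversible assembly
// cascade with constant ligand concentration:
//   L + R1  <-> LR1          (k1_on_eff * L, k1_off_eff)
//   LR1 + R3 <-> LR1R3       (k2_on, k2_off)
//   LR1R3 + MyD88 <-> C      (k3_on, k3_off)
//   C -> lost                (k_loss; removes receptor, co-receptor, adaptor)
// State recorded on a regular grid. Uses R's RNG so set.seed() governs runs.
// [[Rcpp::export]]
List ssa_assembly_cpp(double k1_on_eff, double k1_off_eff,
                      double k2_on, double k2_off,
                      double k3_on, double k3_off,
                      double k_loss, double ligand,
                      int r1_total, int r3_total, int myd88_total,
                      double t_end, double record_interval) {
  const int n_rec = (int) std::floor(t_end / record_interval + 1e-9) + 1;
  NumericVector times(n_rec);
  IntegerMatrix counts(n_rec, 5); // R1_free, LR1, LR1R3, C_mature, C_lost

  long r1 = r1_total, lr1 = 0, lr1r3 = 0, cm = 0, cl = 0;
  long r3 = r3_total, my = myd88_total;

  double t = 0.0;
  int rec = 0;
  double a[7];

  while (rec < n_rec) {
    a[0] = k1_on_eff * ligand * (double) r1;
    a[1] = k1_off_eff * (double) lr1;
    a[2] = k2_on * (double) lr1 * (double) r3;
    a[3] = k2_off * (double) lr1r3;
    a[4] = k3_on * (double) lr1r3 * (double) my;
    a[5] = k3_off * (double) cm;
    a[6] = k_loss * (double) cm;
    double a0 = 0.0;
    for (int i = 0; i < 7; ++i) a0 += a[i];

    double t_next;
    if (a0 <= 0.0) {
      t_next = t_end + 1.0; // absorbing: flush remaining records
    } else {
      t_next = t + R::exp_rand() / a0;
    }

    while (rec < n_rec && rec * record_interval <= t_next + 1e-12) {
      times[rec] = rec * record_interval;
      counts(rec, 0) = (int) r1;  counts(rec, 1) = (int) lr1;
      counts(rec, 2) = (int) lr1r3; counts(rec, 3) = (int) cm;
      counts(rec, 4) = (int) cl;
      ++rec;
    }
    if (t_next > t_end || a0 <= 0.0) {
      if (rec >= n_rec) break;
      if (a0 <= 0.0) break;
    }
    if (rec >= n_rec) break;

    t = t_next;
    double u = R::unif_rand() * a0;
    double acc = 0.0;
    int mu = 6;
    for (int i = 0; i < 7; ++i) { acc += a[i]; if (u <= acc) { mu = i; break; } }
    switch (mu) {
      case 0: --r1; ++lr1; break;
      case 1: ++r1; --lr1; break;
      case 2: --lr1; --r3; ++lr1r3; break;
      case 3: ++lr1; ++r3; --lr1r3; break;
      case 4: --lr1r3; --my; ++cm; break;
      case 5: ++lr1r3; ++my; --cm; break;
      case 6: --cm; ++cl; break;
    }
  }
  // if the chain went absorbing before the grid was flushed
  for (; rec < n_rec; ++rec) {
    times[rec] = rec * record_interval;
    counts(rec, 0) = (int) r1;  counts(rec, 1) = (int) lr1;
    counts(rec, 2) = (int) lr1r3; counts(rec, 3) = (int) cm;
    counts(rec, 4) = (int) cl;
  }
  colnames(counts) = CharacterVector::create("r1_free", "lr1", "lr1r3",
                                             "c_mature", "c_lost");
  return List::create(_["time"] = times, _["counts"] = counts);
}
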