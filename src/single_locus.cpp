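#include <Rcpp.h>
using namespace Rcpp;

// Structured coalescent for one lineage sampled from each of P1..P4 under the
// instantaneous unidirectional admixture model. Times in units of 2N
// generations; within a population each lineage pair coalesces at rate 1.
//
// Event sequence backwards in time:
//   t1: with probability f the lineage currently in P2 relocates to P3
//   t2: P1 and P2 merge, t3: +P3, t4: +P4 (outgroup)
//
// Lineages are tracked as bitmasks over the samples (1=P1, 2=P2, 4=P3, 8=P4);
// the lifetime of the lineage whose subtended set is exactly {P2,P3} is the
// branch on which a mutation yields an ABBA site, {P1,P3} a BABA site, and the
// terminal branches of P1 and P2 yield BAAA and ABAA sites. Uses R's RNG so
// results are reproducible under set.seed().

// [[Rcpp::export]]
NumericMatrix cpp_single_locus_branches(int n, double f, double t1, double t2,
                                        double t3, double t4) {
  NumericMatrix out(n, 4); // t_abba, t_baba, t_baaa, t_abaa
  const double bound[4] = {t1, t2, t3, t4};
  RNGScope scope;

  for (int rep = 0; rep < n; rep++) {
    int mask[4] = {1, 2, 4, 8};
    int pop[4] = {0, 1, 2, 3};
    double birth[4] = {0.0, 0.0, 0.0, 0.0};
    bool alive[4] = {true, true, true, true};
    int n_alive = 4;
    double t = 0.0;
    int phase = 0; // next demographic event index; 4 = none left
    double t_abba = 0.0, t_baba = 0.0, t_baaa = 0.0, t_abaa = 0.0;

    while (n_alive > 1) {
      // total coalescence rate = sum over populations of k*(k-1)/2
      int cnt[4] = {0, 0, 0, 0};
      for (int i = 0; i < 4; i++)
        if (alive[i]) cnt[pop[i]]++;
      double rate = 0.0;
      for (int p = 0; p < 4; p++) rate += cnt[p] * (cnt[p] - 1) / 2.0;

      double next_bound = (phase < 4) ? bound[phase] : R_PosInf;
      double dt = (rate > 0.0) ? exp_rand() / rate : R_PosInf;

      if (t + dt < next_bound) {
        // coalescence: choose population proportional to its pair count,
        // then a uniform pair within it
        t += dt;
        double u = unif_rand() * rate;
        int cpop = 0;
        for (int p = 0; p < 4; p++) {
          double r = cnt[p] * (cnt[p] - 1) / 2.0;
          if (u < r) { cpop = p; break; }
          u -= r;
        }
        int idx[4], k = 0;
        for (int i = 0; i < 4; i++)
          if (alive[i] && pop[i] == cpop) idx[k++] = i;
        int a = (int)(unif_rand() * k); if (a == k) a = k - 1;
        int b = (int)(unif_rand() * (k - 1)); if (b == k - 1) b = k - 2;
        if (b >= a) b++;
        int ia = idx[a], ib = idx[b];
        // record lifetimes of the dying lineages
        for (int which = 0; which < 2; which++) {
          int i = which == 0 ? ia : ib;
          double life = t - birth[i];
          switch (mask[i]) {
            case 1: t_baaa = life; break;        // {P1}
            case 2: t_abaa = life; break;        // {P2}
            case 6: t_abba = life; break;        // {P2,P3}
            case 5: t_baba = life; break;        // {P1,P3}
            default: break;
          }
        }
        mask[ia] |= mask[ib];
        birth[ia] = t;
        alive[ib] = false;
        n_alive--;
      } else {
        // advance to the demographic event
        t = next_bound;
        if (phase == 0) {
          for (int i = 0; i < 4; i++)
            if (alive[i] && pop[i] == 1 && unif_rand() < f) pop[i] = 2;
        } else if (phase == 1) {
          for (int i = 0; i < 4; i++)
            if (alive[i] && pop[i] == 1) pop[i] = 0; // P2 -> P12
        } else if (phase == 2) {
          for (int i = 0; i < 4; i++)
            if (alive[i] && pop[i] == 2) pop[i] = 0; // P3 -> P123
        } else if (phase == 3) {
          for (int i = 0; i < 4; i++)
            if (alive[i] && pop[i] == 3) pop[i] = 0; // P4 -> ancestral
        }
        phase++;
      }
    }
    out(rep, 0) = t_abba;
    out(rep, 1) = t_baba;
    out(rep, 2) = t_baaa;
    out(rep, 3) = t_abaa;
  }
  return out;
}
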