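#include <Rcpp.h>
using namespace Rcpp;

// Exact SSA for the two-state telegraph model:
//   OFF -> ON   at k_on
//   ON  -> OFF  at k_off
//   0   -> mRNA at T while ON
//   mRNA -> 0   at d_m * m
//   mRNA -> mRNA + protein at L * m   (optional protein stage)
//   protein -> 0 at d_p * p
// Uses R's global RNG (RNGScope via Rcpp attributes) so set.seed() in R
// makes every run reproducible.

struct TeleRates {
  double kon, koff, tr, lr, dm, dp;
};

// Advance one cell from (g, m, p) over [0, t_end]. Counts held as double
// to avoid overflow worries; they remain exact integers.
static inline void advance_cell(const TeleRates &r, double t_end,
                                int &g, double &m, double &p,
                                bool protein) {
  double t = 0.0;
  for (;;) {
    const double a1 = g ? 0.0 : r.kon;
    const double a2 = g ? r.koff : 0.0;
    const double a3 = g ? r.tr : 0.0;
    const double a4 = r.dm * m;
    const double a5 = protein ? r.lr * m : 0.0;
    const double a6 = protein ? r.dp * p : 0.0;
    const double atot = a1 + a2 + a3 + a4 + a5 + a6;
    if (atot <= 0.0) break;            // absorbing: nothing can fire
    t += R::exp_rand() / atot;
    if (t > t_end) break;
    double u = unif_rand() * atot;
    if ((u -= a1) < 0.0)      g = 1;
    else if ((u -= a2) < 0.0) g = 0;
    else if ((u -= a3) < 0.0) m += 1.0;
    else if ((u -= a4) < 0.0) m -= 1.0;
    else if ((u -= a5) < 0.0) p += 1.0;
    else                      p -= 1.0;
  }
}

// [[Rcpp::export(name = ".ssa_trajectory_cpp")]]
List ssa_trajectory_cpp(double kon, double koff, double tr, double lr,
                        double dm, double dp, double t_end,
                        int g0, double m0, double p0, bool protein) {
  TeleRates r = {kon, koff, tr, lr, dm, dp};
  std::vector<double> times;
  std::vector<int> gs;
  std::vector<double> ms, ps;
  times.reserve(1024); gs.reserve(1024); ms.reserve(1024); ps.reserve(1024);

  int g = g0; double m = m0, p = p0, t = 0.0;
  times.push_back(0.0); gs.push_back(g); ms.push_back(m); ps.push_back(p);
  for (;;) {
    const double a1 = g ? 0.0 : r.kon;
    const double a2 = g ? r.koff : 0.0;
    const double a3 = g ? r.tr : 0.0;
    const double a4 = r.dm * m;
    const double a5 = protein ? r.lr * m : 0.0;
    const double a6 = protein ? r.dp * p : 0.0;
    const double atot = a1 + a2 + a3 + a4 + a5 + a6;
    if (atot <= 0.0) break;
    t += R::exp_rand() / atot;
    if (t > t_end) break;
    double u = unif_rand() * atot;
    if ((u -= a1) < 0.0)      g = 1;
    else if ((u -= a2) < 0.0) g = 0;
    else if ((u -= a3) < 0.0) m += 1.0;
    else if ((u -= a4) < 0.0) m -= 1.0;
    else if ((u -= a5) < 0.0) p += 1.0;
    else                      p -= 1.0;
    times.push_back(t); gs.push_back(g); ms.push_back(m); ps.push_back(p);
  }
  return List::create(_["times"] = times,
                      _["promoter_state"] = gs,
                      _["mrna_count"] = ms,
                      _["protein_count"] = ps,
                      _["t_end"] = t_end);
}

// [[Rcpp::export(name = ".ssa_endstate_cpp")]]
NumericMatrix ssa_endstate_cpp(double kon, double koff, double tr, double lr,
                               double dm, double dp, double t_end,
                               int n_cells, bool protein) {
  TeleRates r = {kon, koff, tr, lr, dm, dp};
  NumericMatrix out(n_cells, 2);
  for (int i = 0; i < n_cells; ++i) {
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
    int g = 0; double m = 0.0, p = 0.0;
    advance_cell(r, t_end, g, m, p, protein);
    out(i, 0) = m;
    out(i, 1) = p;
  }
  return out;
}
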