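#include <Rcpp.h>
using namespace Rcpp;

// Moran birth-death core. State is tracked through the per-group strategy
// occupancy (a[g] A-players, b[g] B-players) plus the per-individual arrays;
// the observables I_AA, I_AB are maintained incrementally via
// sum_a2 = sum_g a_g^2 and sum_ab = sum_g a_g b_g, so one event is O(1).

namespace {

struct MoranState {
  IntegerVector strat;   // 0/1 per individual
  IntegerVector group;   // 1..M per individual
  std::vector<double> a, b;  // per-group counts
  double sum_a2, sum_ab;
  int N, M, NA_;

  MoranState(IntegerVector s, IntegerVector g, int M_) :
      strat(clone(s)), group(clone(g)), a(M_, 0.0), b(M_, 0.0),
      sum_a2(0), sum_ab(0), N(s.size()), M(M_), NA_(0) {
    for (int i = 0; i < N; ++i) {
      if (strat[i] == 1) { a[group[i] - 1] += 1; ++NA_; }
      else b[group[i] - 1] += 1;
    }
    for (int g2 = 0; g2 < M; ++g2) {
      sum_a2 += a[g2] * a[g2];
      sum_ab += a[g2] * b[g2];
    }
  }

  void remove(int g, int s) {
    if (s == 1) { sum_a2 -= 2 * a[g] - 1; sum_ab -= b[g]; a[g] -= 1; --NA_; }
    else        { sum_ab -= a[g]; b[g] -= 1; }
  }
  void add(int g, int s) {
    if (s == 1) { sum_a2 += 2 * a[g] + 1; sum_ab += b[g]; a[g] += 1; ++NA_; }
    else        { sum_ab += a[g]; b[g] += 1; }
  }

  // one neutral event using R's RNG; offs = reachable displacements (1..M-1)
  void step_neutral(double u, double v, const IntegerVector& offs) {
    int rep = (int)(unif_rand() * N); if (rep == N) rep = N - 1;
    int die = (int)(unif_rand() * N); if (die == N) die = N - 1;
    int s_off = strat[rep];
    if (u > 0 && unif_rand() < u) s_off = (unif_rand() < 0.5) ? 0 : 1;
    int g_off = group[rep];
    if (v > 0 && unif_rand() < v) {
      int k = (int)(unif_rand() * offs.size());
      if (k == (int)offs.size()) k = offs.size() - 1;
      g_off = 1 + (g_off - 1 + offs[k]) % M;
    }
    remove(group[die] - 1, strat[die]);
    add(g_off - 1, s_off);
    strat[die] = s_off;
    group[die] = g_off;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_moran_neutral(IntegerVector strat, IntegerVector group, int M,
                       double u, double v, IntegerVector offs,
                       double generations, double burn_in, int n_batches,
                       bool include_self) {
  MoranState st(strat, group, M);
  RNGScope scope;
  long long gen_total = (long long)generations;
  long long burn = (long long)burn_in;
  long long kept = gen_total - burn;
  long long batch_len = kept / n_batches;
  if (batch_len < 1) stop("too few generations for the requested batches");
  kept = batch_len * n_batches;  // drop the remainder

  for (long long t = 0; t < burn; ++t) st.step_neutral(u, v, offs);

  NumericVector batch_x(n_batches), batch_y(n_batches);
  double tot_x = 0, tot_y = 0;
  for (int bblock = 0; bblock < n_batches; ++bblock) {
    double bx = 0, by = 0;
    for (long long t = 0; t < batch_len; ++t) {
      st.step_neutral(u, v, offs);
      double NB = st.N - st.NA_;
      double iaa = include_self ? st.sum_a2 : (st.sum_a2 - st.NA_);
      bx += iaa * NB;
      by += st.sum_ab * NB;
    }
    batch_x[bblock] = bx / batch_len;
    batch_y[bblock] = by / batch_len;
    tot_x += bx; tot_y += by;
  }
  return List::create(
      _["mean_iaa_nb"] = tot_x / kept,
      _["mean_iab_nb"] = tot_y / kept,
      _["batch_iaa_nb"] = batch_x,
      _["batch_iab_nb"] = batch_y,
      _["strategies"] = st.strat,
      _["groups"] = st.group);
}

// [[Rcpp::export]]
List cpp_moran_occupancy(IntegerVector strat, IntegerVector group, int M,
                         double u, double v, IntegerVector offs,
                         NumericVector snapshot_times, double w,
                         NumericVector payoff, bool include_self) {
  MoranState st(strat, group, M);
  RNGScope scope;
  int n_snap = snapshot_times.size();
  IntegerVector out_a(n_snap * M), out_b(n_snap * M);
  double pay_a = payoff[0], pay_b = payoff[1], pay_c = payoff[2],
         pay_d = payoff[3];
  long long gen = 0;
  for (int s = 0; s < n_snap; ++s) {
    long long target = (long long)snapshot_times[s];
    for (; gen < target; ++gen) {
      if (w == 0) {
        st.step_neutral(u, v, offs);
        continue;
      }
      // selection: fitness-proportional reproducer via per-group payoffs
      std::vector<double> fit_a(M), fit_b(M);
      double total = 0;
      for (int g = 0; g < M; ++g) {
        double pa = (st.a[g] - 1) * pay_a + st.b[g] * pay_b;
        double pb = st.a[g] * pay_c + (st.b[g] - 1) * pay_d;
        if (include_self) { pa += pay_a; pb += pay_d; }
        fit_a[g] = 1 + w * pa;
        fit_b[g] = 1 + w * pb;
        if ((st.a[g] > 0 && fit_a[g] < 0) || (st.b[g] > 0 && fit_b[g] < 0))
          stop("negative fitness: selection intensity w too strong");
        total += st.a[g] * fit_a[g] + st.b[g] * fit_b[g];
      }
      double zrep = unif_rand() * total;
      int rep_g = -1, rep_s = -1;
      for (int g = 0; g < M && rep_g < 0; ++g) {
        zrep -= st.a[g] * fit_a[g];
        if (zrep < 0) { rep_g = g; rep_s = 1; break; }
        zrep -= st.b[g] * fit_b[g];
        if (zrep < 0) { rep_g = g; rep_s = 0; break; }
      }
      if (rep_g < 0) { rep_g = M - 1; rep_s = st.b[M - 1] > 0 ? 0 : 1; }
      int die = (int)(unif_rand() * st.N); if (die == st.N) die = st.N - 1;
      int s_off = rep_s;
      if (u > 0 && unif_rand() < u) s_off = (unif_rand() < 0.5) ? 0 : 1;
      int g_off = rep_g + 1;
      if (v > 0 && unif_rand() < v) {
        int k = (int)(unif_rand() * offs.size());
        if (k == (int)offs.size()) k = offs.size() - 1;
        g_off = 1 + (g_off - 1 + offs[k]) % M;
      }
      st.remove(st.group[die] - 1, st.strat[die]);
      st.add(g_off - 1, s_off);
      st.strat[die] = s_off;
      st.group[die] = g_off;
    }
    for (int g = 0; g < M; ++g) {
      out_a[s * M + g] = (int)st.a[g];
      out_b[s * M + g] = (int)st.b[g];
    }
  }
  return List::create(_["count_A"] = out_a, _["count_B"] = out_b,
                      _["strategies"] = st.strat, _["groups"] = st.group);
}
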