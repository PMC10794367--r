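// Wright-Fisher forward simulation kernel: discrete generations of N
// diploids, gametes formed with Poisson crossovers on the genetic scale,
// optional additive selection at one site.  Uses R's RNG so the R-level
// seed contract (with_seed) applies unchanged.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".wf_core")]]
List wf_core(IntegerMatrix pop0, NumericVector gpos, double L_cM,
             int generations, int sweep_idx, double s_coef) {
  const int H = pop0.nrow();        // haplotypes = 2N
  const int S = pop0.ncol();
  const int N = H / 2;
  std::vector<int> A(INTEGER(pop0), INTEGER(pop0) + (size_t)H * S);
  std::vector<int> B((size_t)H * S);
  std::vector<double> cumw(N);
  std::vector<double> bk;
  const double *g = REAL(gpos);
  const double lambda = L_cM / 100.0;
  bool lost = false;
  RNGScope scope;
  for (int gen = 0; gen < generations && !lost; ++gen) {
    // cumulative fitness (uniform when neutral)
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = 1.0;
      if (sweep_idx >= 0 && s_coef != 0.0) {
        int cnt = A[(size_t)sweep_idx * H + 2 * i] +
                  A[(size_t)sweep_idx * H + 2 * i + 1];
        w = 1.0 + s_coef * cnt;
      }
      tot += w;
      cumw[i] = tot;
    }
    for (int j = 0; j < H; ++j) {
      // weighted parent draw
      double u = unif_rand() * tot;
      int pr = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) -
                     cumw.begin());
      if (pr >= N) pr = N - 1;
      const size_t h1 = 2 * (size_t)pr, h2 = h1 + 1;
      int k = (int)R::rpois(lambda);
      if (k == 0) {
        const size_t src = (unif_rand() < 0.5) ? h1 : h2;
        for (int c = 0; c < S; ++c) B[(size_t)c * H + j] = A[(size_t)c * H + src];
      } else {
        bk.resize(k);
        for (int x = 0; x < k; ++x) bk[x] = unif_rand() * L_cM;
        std::sort(bk.begin(), bk.end());
        int start = (unif_rand() < 0.5) ? 0 : 1;
        int seg = 0;
        for (int c = 0; c < S; ++c) {
          while (seg < k && g[c] >= bk[seg]) ++seg;
          const size_t src = ((start + seg) % 2 == 0) ? h1 : h2;
          B[(size_t)c * H + j] = A[(size_t)c * H + src];
        }
      }
    }
    A.swap(B);
    if (sweep_idx >= 0) {
      int cnt = 0;
      for (int i = 0; i < H; ++i) cnt += A[(size_t)sweep_idx * H + i];
      if (cnt == 0) lost = true;
    }
  }
  IntegerMatrix out(H, S);
  std::copy(A.begin(), A.end(), INTEGER(out));
  return List::create(_["pop"] = out, _["lost"] = lost);
}
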