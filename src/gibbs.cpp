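#include <Rcpp.h>
using namespace Rcpp;

// Dirichlet-multinomial Gibbs sampler over cluster assignments psi, with
// cluster emission vectors gamma integrated by sampling (conjugate updates).
// Copied lengths are real-valued; the multinomial log-likelihood is
// evaluated with real "counts": sum_k l_k log gamma_k.
//
// Per iteration:
//  (A) gamma_c ~ Dirichlet(delta + within-cluster column sums), each entry
//      clamped to [1e-7, 1 - 1e-7] and the vector renormalised;
//  (B) psi_j ~ categorical with Pr ∝ exp(sum_k l_jk log gamma_ck);
//  (C) any empty cluster receives one randomly chosen distinct individual
//      before the next iteration's step (A).
//
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
List gibbs_dirmult_cpp(const NumericMatrix& lens,  // N x K copied lengths
                       int C, double delta, int M, int burn, int thin,
                       bool keep_gamma) {
  const int N = lens.nrow(), K = lens.ncol();
  if (K < 1) stop("no donor groups");
  if (C < 1) stop("C must be >= 1");
  for (int j = 0; j < N; ++j)
    for (int k = 0; k < K; ++k)
      if (lens(j, k) < 0) stop("negative copied length");

  RNGScope scope;
  const double lo = 1e-7, hi = 1.0 - 1e-7;

  std::vector<int> psi(N);
  for (int j = 0; j < N; ++j) psi[j] = (int)std::floor(unif_rand() * C);

  int n_keep = 0;
  for (int m = 1; m <= M; ++m) if (m > burn && (m - burn) % thin == 0) ++n_keep;
  IntegerMatrix psi_out(n_keep, N);
  NumericMatrix gamma_out(keep_gamma ? n_keep * C : 1, keep_gamma ? K : 1);

  NumericMatrix lgam(C, K);
  std::vector<double> gam(K), ll(C);
  int kept = 0;

  for (int m = 1; m <= M; ++m) {
    // (C) refill empty clusters with distinct random individuals
    std::vector<int> cnt(C, 0);
    for (int j = 0; j < N; ++j) ++cnt[psi[j]];
    std::vector<int> empty;
    for (int c = 0; c < C; ++c) if (cnt[c] == 0) empty.push_back(c);
    if (!empty.empty() && N >= (int)empty.size()) {
      std::vector<int> pool(N);
      for (int j = 0; j < N; ++j) pool[j] = j;
      for (size_t e = 0; e < empty.size(); ++e) {
        int pick = e + (int)std::floor(unif_rand() * (N - e));
        std::swap(pool[e], pool[pick]);
        psi[pool[e]] = empty[e];
      }
    }

    // (A) gamma | psi
    for (int c = 0; c < C; ++c) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = delta;
        for (int j = 0; j < N; ++j) if (psi[j] == c) a += lens(j, k);
        gam[k] = R::rgamma(a, 1.0);
        tot += gam[k];
      }
      double tot2 = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = gam[k] / tot;
        if (g < lo) g = lo;
        if (g > hi) g = hi;
        gam[k] = g;
        tot2 += g;
      }
      for (int k = 0; k < K; ++k) lgam(c, k) = std::log(gam[k] / tot2);
    }

    // (B) psi | gamma
    for (int j = 0; j < N; ++j) {
      double mx = R_NegInf;
      for (int c = 0; c < C; ++c) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += lens(j, k) * lgam(c, k);
        ll[c] = s;
        if (s > mx) mx = s;
      }
      double tot = 0.0;
      for (int c = 0; c < C; ++c) { ll[c] = std::exp(ll[c] - mx); tot += ll[c]; }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = C - 1;
      for (int c = 0; c < C; ++c) { acc += ll[c]; if (u <= acc) { pick = c; break; } }
      psi[j] = pick;
    }

    if (m > burn && (m - burn) % thin == 0) {
      for (int j = 0; j < N; ++j) psi_out(kept, j) = psi[j] + 1;
      if (keep_gamma)
        for (int c = 0; c < C; ++c)
          for (int k = 0; k < K; ++k)
            gamma_out(kept * C + c, k) = std::exp(lgam(c, k));
      ++kept;
    }
  }

  return List::create(_["psi"] = psi_out, _["gamma"] = gamma_out);
}
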