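#include <Rcpp.h>
using namespace Rcpp;

// Li & Stephens copying HMM over donor haploids, one chromosome at a time.
//
// Transition between adjacent sites separated by d Morgans:
//   P(switch) = 1 - exp(-switch_rate * d); after a switch the new donor is
//   drawn from `prior` (uniform by default), independently of the old one.
// Emission: P(mismatch) = theta, P(match) = 1 - theta.
//
// Recursions use per-site rescaling with the log-likelihood accumulated from
// the scaling constants (the standard numerically-stable form of the
// log-space recursion). A zero scaling constant is an error, never a clamp.
//
// Returns, aggregated to donor groups:
//   site_post  L x K posterior copy probabilities
//   f_cm       K   expected copied length in cM (site-weighted posteriors)
//   chunks     K   expected number of contiguous copied segments
//   exp_switch L-1 posterior expected recombination events per interval
//   exp_mismatch   expected number of miscopied sites
//   loglik         observed-data log-likelihood
//   paths      n_samples x L donor indices (1-based), backward-sampled

// [[Rcpp::export]]
List cp_hmm_cpp(const IntegerMatrix& donors,   // H x L alleles in {0,1}
                const IntegerVector& rec,      // L recipient alleles
                const NumericVector& d_morgan, // L-1 inter-site distances
                double switch_rate,
                double theta,
                const NumericVector& prior,    // H landing probabilities
                const IntegerVector& group0,   // H donor-group ids in 0..K-1
                int K,
                const NumericVector& site_w,   // L per-site cM weights
                bool want_sitepost,
                int n_samples) {
  const int H = donors.nrow(), L = donors.ncol();
  if (H < 1) stop("empty donor set");
  if (rec.size() != L) stop("recipient length mismatch");
  const double match = 1.0 - theta, mism = theta;

  NumericMatrix alpha(H, L);       // scaled forward
  NumericVector cvec(L);           // scaling constants
  std::vector<double> em(H);

  // forward
  double c0 = 0.0;
  for (int h = 0; h < H; ++h) {
    double e = (donors(h, 0) == rec[0]) ? match : mism;
    double a = prior[h] * e;
    alpha(h, 0) = a;
    c0 += a;
  }
  if (c0 <= 0.0) stop("likelihood underflow at site 1");
  cvec[0] = c0;
  for (int h = 0; h < H; ++h) alpha(h, 0) /= c0;

  NumericVector p_sw(L - 1 > 0 ? L - 1 : 0);
  for (int l = 0; l < L - 1; ++l)
    p_sw[l] = 1.0 - std::exp(-switch_rate * d_morgan[l]);

  for (int l = 1; l < L; ++l) {
    const double s = p_sw[l - 1], stay = 1.0 - s;
    double cl = 0.0;
    for (int h = 0; h < H; ++h) {
      double e = (donors(h, l) == rec[l]) ? match : mism;
      double a = e * (stay * alpha(h, l - 1) + s * prior[h]);
      alpha(h, l) = a;
      cl += a;
    }
    if (cl <= 0.0) stop("likelihood underflow at site " + std::to_string(l + 1));
    cvec[l] = cl;
    for (int h = 0; h < H; ++h) alpha(h, l) /= cl;
  }

  double loglik = 0.0;
  for (int l = 0; l < L; ++l) loglik += std::log(cvec[l]);

  // backward (scaled by the forward constants), accumulating group summaries
  NumericMatrix site_post(want_sitepost ? L : 1, want_sitepost ? K : 1);
  NumericVector f_cm(K), chunks(K), exp_switch(L - 1 > 0 ? L - 1 : 0);
  double exp_mismatch = 0.0;

  std::vector<double> beta(H, 1.0), beta_next(H);
  std::vector<double> gamma(H);

  // site L-1 (last)
  for (int h = 0; h < H; ++h) {
    gamma[h] = alpha(h, L - 1);  // beta = 1
    int k = group0[h];
    f_cm[k] += gamma[h] * site_w[L - 1];
    if (donors(h, L - 1) != rec[L - 1]) exp_mismatch += gamma[h];
    if (want_sitepost) site_post(L - 1, k) += gamma[h];
  }

  for (int l = L - 2; l >= 0; --l) {
    const double s = p_sw[l], stay = 1.0 - s;
    const double cl1 = cvec[l + 1];
    double sum_peb = 0.0;  // sum_h prior[h] * em(h) * beta(h) at site l+1
    for (int h = 0; h < H; ++h) {
      em[h] = (donors(h, l + 1) == rec[l + 1]) ? match : mism;
      sum_peb += prior[h] * em[h] * beta[h];
    }
    // expected recombination events in interval (l, l+1)
    exp_switch[l] = s * sum_peb / cl1;
    // expected donor-change events, credited to the incoming donor's group
    for (int h = 0; h < H; ++h) {
      double land = s * prior[h] * em[h] * beta[h] / cl1; // P(switch lands on h, data)
      chunks[group0[h]] += land * (1.0 - alpha(h, l));
    }
    // backward recursion
    for (int h = 0; h < H; ++h)
      beta_next[h] = (stay * em[h] * beta[h] + s * sum_peb) / cl1;
    std::swap(beta, beta_next);

    double gsum = 0.0;
    for (int h = 0; h < H; ++h) {
      gamma[h] = alpha(h, l) * beta[h];
      gsum += gamma[h];
    }
    for (int h = 0; h < H; ++h) {
      gamma[h] /= gsum;  // guard against rounding drift
      int k = group0[h];
      f_cm[k] += gamma[h] * site_w[l];
      if (donors(h, l) != rec[l]) exp_mismatch += gamma[h];
      if (want_sitepost) site_post(l, k) += gamma[h];
    }
    if (l == 0)
      for (int h = 0; h < H; ++h) chunks[group0[h]] += gamma[h];
  }
  if (L == 1)
    for (int h = 0; h < H; ++h) chunks[group0[h]] += gamma[h];

  // backward sampling of copy-paths from the posterior
  IntegerMatrix paths(n_samples, n_samples > 0 ? L : 0);
  if (n_samples > 0) {
    RNGScope scope;
    for (int sidx = 0; sidx < n_samples; ++sidx) {
      double u = unif_rand(), acc = 0.0;
      int cur = H - 1;
      for (int h = 0; h < H; ++h) {
        acc += alpha(h, L - 1);
        if (u <= acc) { cur = h; break; }
      }
      paths(sidx, L - 1) = cur + 1;
      for (int l = L - 2; l >= 0; --l) {
        const double s = p_sw[l];
        // P(x_l | x_{l+1}=cur) ∝ alpha_l(h) * [stay*1(h==cur) + s*prior[cur]]
        double w_stay = (1.0 - s) * alpha(cur, l);
        double w_sw = s * prior[cur];  // times sum_h alpha = 1
        double tot = w_stay + w_sw;
        if (unif_rand() * tot >= w_stay) {
          u = unif_rand(); acc = 0.0;
          int nh = H - 1;
          for (int h = 0; h < H; ++h) {
            acc += alpha(h, l);
            if (u <= acc) { nh = h; break; }
          }
          cur = nh;
        }
        paths(sidx, l) = cur + 1;
      }
    }
  }

  return List::create(
    _["site_post"] = site_post, _["f_cm"] = f_cm, _["chunks"] = chunks,
    _["exp_switch"] = exp_switch, _["exp_mismatch"] = exp_mismatch,
    _["loglik"] = loglik, _["paths"] = paths);
}
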