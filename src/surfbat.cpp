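#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward for the haplotype-copying HMM.
// obs: target alleles at T typed sites; A: T x H panel alleles (0/1);
// r: length T-1 per-interval switch probabilities; eps: mismatch probability.
// Transition kernel k -> l is r/H + (1-r)*[k == l]; initial distribution 1/H.
// [[Rcpp::export]]
NumericMatrix fb_posteriors_cpp(IntegerVector obs, IntegerMatrix A,
                                NumericVector r, double eps) {
  const int T = A.nrow(), H = A.ncol();
  if (obs.size() != T) stop("obs length must match site count");
  if (T >= 2 && r.size() != T - 1) stop("need T-1 switch probabilities");
  NumericMatrix alpha(T, H), beta(T, H), post(T, H);

  double s = 0.0;
  for (int k = 0; k < H; ++k) {
    double e = (A(0, k) == obs[0]) ? 1.0 - eps : eps;
    alpha(0, k) = e / H;
    s += alpha(0, k);
  }
  if (s <= 0.0) stop("zero forward likelihood");
  for (int k = 0; k < H; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    const double rt = r[t - 1];
    const double mix = rt / H;  // alpha rows are normalized, sum = 1
    s = 0.0;
    for (int k = 0; k < H; ++k) {
      double e = (A(t, k) == obs[t]) ? 1.0 - eps : eps;
      double v = e * ((1.0 - rt) * alpha(t - 1, k) + mix);
      alpha(t, k) = v;
      s += v;
    }
    if (s <= 0.0) stop("zero forward likelihood");
    for (int k = 0; k < H; ++k) alpha(t, k) /= s;
  }

  for (int k = 0; k < H; ++k) beta(T - 1, k) = 1.0;
  std::vector<double> w(H);
  for (int t = T - 2; t >= 0; --t) {
    const double rt = r[t];
    double wsum = 0.0;
    for (int k = 0; k < H; ++k) {
      double e = (A(t + 1, k) == obs[t + 1]) ? 1.0 - eps : eps;
      w[k] = e * beta(t + 1, k);
      wsum += w[k];
    }
    s = 0.0;
    for (int k = 0; k < H; ++k) {
      double v = (1.0 - rt) * w[k] + rt * wsum / H;
      beta(t, k) = v;
      s += v;
    }
    for (int k = 0; k < H; ++k) beta(t, k) /= s;
  }

  for (int t = 0; t < T; ++t) {
    double ps = 0.0;
    for (int k = 0; k < H; ++k) {
      post(t, k) = alpha(t, k) * beta(t, k);
      ps += post(t, k);
    }
    for (int k = 0; k < H; ++k) post(t, k) /= ps;
  }
  return post;
}

// Transmitted (rho) and pseudo-control (pi) dosages at every panel site for
// one target haplotype, interpolating between the flanking typed sites.
// post_t: H x T posteriors at typed sites (haplotype-major for locality);
// A_t: H x S panel alleles at all sites (haplotype-major); li, ri: 0-based
// typed-column indices of the left/right flank per panel site (equal at
// typed sites and beyond the typed range); w: weight on the right flank.
// pi uses the partner haplotype within each reference individual:
// pi = sum_k post[partner(k)] * a_k with partner(2i) = 2i+1, partner(2i+1) = 2i.
// [[Rcpp::export]]
List dosages_cpp(NumericMatrix post_t, IntegerMatrix A_t,
                 IntegerVector li, IntegerVector ri, NumericVector w) {
  const int H = A_t.nrow(), S = A_t.ncol();
  if (post_t.nrow() != H) stop("posterior/panel haplotype mismatch");
  NumericVector rho(S), pi(S);
  const double* postp = post_t.begin();
  const int* ap = A_t.begin();
  for (int s = 0; s < S; ++s) {
    const int l = li[s], rr = ri[s];
    const double ws = w[s];
    const int* as = ap + (R_xlen_t)s * H;
    const double* pls = postp + (R_xlen_t)l * H;
    double dl = 0.0, dr = 0.0, pl = 0.0, pr = 0.0;
    if (rr == l) {
      for (int k = 0; k < H; ++k) {
        if (as[k]) {
          dl += pls[k];
          pl += pls[k ^ 1];  // partner: flip the low bit of the 0-based index
        }
      }
      rho[s] = dl;
      pi[s] = pl;
    } else {
      const double* prs = postp + (R_xlen_t)rr * H;
      for (int k = 0; k < H; ++k) {
        if (as[k]) {
          dl += pls[k];
          pl += pls[k ^ 1];
          dr += prs[k];
          pr += prs[k ^ 1];
        }
      }
      rho[s] = (1.0 - ws) * dl + ws * dr;
      pi[s] = (1.0 - ws) * pl + ws * pr;
    }
  }
  return List::create(_["rho"] = rho, _["pi"] = pi);
}

// Posterior copying mass per reference group, averaged over typed sites.
// group: 0-based group index per reference haplotype; returns mean mass per group.
// [[Rcpp::export]]
NumericVector group_mass_cpp(NumericMatrix post, IntegerVector group,
                             int n_groups) {
  const int T = post.nrow(), H = post.ncol();
  NumericVector out(n_groups);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < H; ++k)
      out[group[k]] += post(t, k);
  for (int g = 0; g < n_groups; ++g) out[g] /= T;
  return out;
}
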