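#include <Rcpp.h>
using namespace Rcpp;

// Sum of integer-scaled column scores for every window of a sequence.
// seq: base codes 0..3, anything else is treated as ambiguous; windows
// containing an ambiguous base are reported as NA. score: 4 x W integer
// matrix (rows A,C,G,T).
// [[Rcpp::export(name = ".pwm_window_scores_cpp")]]
IntegerVector pwm_window_scores_cpp(IntegerVector seq, IntegerMatrix score) {
  const int W = score.ncol();
  const int L = seq.size();
  if (L < W) return IntegerVector(0);
  IntegerVector out(L - W + 1);
  for (int i = 0; i <= L - W; ++i) {
    long long s = 0;
    bool ok = true;
    for (int j = 0; j < W; ++j) {
      const int b = seq[i + j];
      if (b < 0 || b > 3) { ok = false; break; }
      s += score(b, j);
    }
    out[i] = ok ? static_cast<int>(s) : NA_INTEGER;
  }
  return out;
}

static inline double logsum2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + log(exp(a - m) + exp(b - m));
}

// Log-space forward algorithm for a single-motif profile HMM.
// States: 0 = background B, 1..W = match states M1..MW.
// Transitions: B->B (1-tau), B->M1 (tau), Mi->Mi+1 (1), MW->B (1).
// Initial distribution: pi(B) = 1-tau, pi(M1) = tau.
// log_emis: 4 x (W+1) matrix of log emission probabilities (col 0 = B).
// Ambiguous bases (code outside 0..3) emit with probability 1 in every
// state so they cancel in likelihood ratios.
// Returns log P(seq | HMM), summed over all terminal states.
// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(IntegerVector seq, NumericMatrix log_emis, double tau) {
  const int W = log_emis.ncol() - 1;
  const int L = seq.size();
  if (L == 0) stop("empty sequence");
  const double l1t = log1p(-tau);
  const double lt = log(tau);
  std::vector<double> a(W + 1, R_NegInf), na(W + 1, R_NegInf);

  int b0 = seq[0];
  double e0B = (b0 >= 0 && b0 <= 3) ? log_emis(b0, 0) : 0.0;
  double e0M = (b0 >= 0 && b0 <= 3) ? log_emis(b0, 1) : 0.0;
  a[0] = l1t + e0B;
  a[1] = lt + e0M;

  for (int i = 1; i < L; ++i) {
    const int b = seq[i];
    const bool known = (b >= 0 && b <= 3);
    // into background: from B (1-tau) and from MW (prob 1)
    na[0] = logsum2(a[0] + l1t, a[W]) + (known ? log_emis(b, 0) : 0.0);
    // into M1: from B only
    na[1] = a[0] + lt + (known ? log_emis(b, 1) : 0.0);
    for (int j = 2; j <= W; ++j) {
      na[j] = a[j - 1] + (known ? log_emis(b, j) : 0.0);
    }
    std::swap(a, na);
  }
  double tot = R_NegInf;
  for (int j = 0; j <= W; ++j) tot = logsum2(tot, a[j]);
  return tot;
}
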