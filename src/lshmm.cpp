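#include <Rcpp.h>
using namespace Rcpp;

// Haploid Li-Stephens forward-backward over the full site grid.
//
// alleles:   H x L reference panel, entries 0/1/NA (NA emits 0.5)
// obs:       length-L haploid observation, 0/1/NA (NA = untyped, emits 1)
// no_switch: length L-1 per-interval probability of not switching donor;
//            the switch mass (1 - no_switch) is spread uniformly over all
//            H donors including the current one, so the one-step update
//            collapses to an O(H) rank-one operation.
// lambda:    miscopy probability; emission is 1-lambda on allele match,
//            lambda on mismatch.
//
// Scaled (per-site normalized) linear-space recursion; returns the H x L
// posterior donor distribution, each column summing to 1.

static inline double emit(int a, int o, double lambda) {
  if (o == NA_INTEGER) return 1.0;
  if (a == NA_INTEGER) return 0.5;
  return (a == o) ? (1.0 - lambda) : lambda;
}

// [[Rcpp::export(name = ".ls_forward_backward")]]
NumericMatrix ls_forward_backward_cpp(IntegerMatrix alleles,
                                      IntegerVector obs,
                                      NumericVector no_switch,
                                      double lambda) {
  const int H = alleles.nrow();
  const int L = alleles.ncol();
  if (obs.size() != L) stop("observation length does not match site grid");
  if (no_switch.size() != L - 1 && L > 1)
    stop("no_switch must have length L - 1");

  NumericMatrix alpha(H, L);
  NumericVector beta(H);
  NumericMatrix gamma(H, L);

  // forward
  double tot = 0.0;
  for (int k = 0; k < H; ++k) {
    alpha(k, 0) = emit(alleles(k, 0), obs[0], lambda) / H;
    tot += alpha(k, 0);
  }
  if (tot <= 0.0) stop("zero forward likelihood at site 1");
  for (int k = 0; k < H; ++k) alpha(k, 0) /= tot;

  for (int l = 1; l < L; ++l) {
    const double p = no_switch[l - 1];
    const double mix = (1.0 - p) / H;  // uniform switch mass (incl. self)
    tot = 0.0;
    for (int k = 0; k < H; ++k) {
      double a = p * alpha(k, l - 1) + mix;  // previous column sums to 1
      a *= emit(alleles(k, l), obs[l], lambda);
      alpha(k, l) = a;
      tot += a;
    }
    if (tot <= 0.0) stop("zero forward likelihood during recursion");
    for (int k = 0; k < H; ++k) alpha(k, l) /= tot;
  }

  // backward, combined with forward into gamma on the fly
  for (int k = 0; k < H; ++k) beta[k] = 1.0;
  for (int l = L - 1; l >= 0; --l) {
    double g = 0.0;
    for (int k = 0; k < H; ++k) {
      gamma(k, l) = alpha(k, l) * beta[k];
      g += gamma(k, l);
    }
    if (g <= 0.0) stop("zero posterior mass during backward pass");
    for (int k = 0; k < H; ++k) gamma(k, l) /= g;
    if (l > 0) {
      const double p = no_switch[l - 1];
      double dot = 0.0;
      std::vector<double> eb(H);
      for (int k = 0; k < H; ++k) {
        eb[k] = emit(alleles(k, l), obs[l], lambda) * beta[k];
        dot += eb[k];
      }
      const double mix = dot / H;
      double s = 0.0;
      for (int k = 0; k < H; ++k) {
        beta[k] = p * eb[k] + (1.0 - p) * mix;
        s += beta[k];
      }
      // rescale to keep the recursion in range
      for (int k = 0; k < H; ++k) beta[k] = beta[k] * H / s;
    }
  }
  return gamma;
}
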