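#include <Rcpp.h>
using namespace Rcpp;

// One replicate of the per-locus Wright-Fisher process for an additive trait
// under Gaussian stabilizing selection and symmetric recurrent mutation.
//
// Each generation: the deterministic selection + mutation velocity is applied
// to every locus (directional term coupled through the deviation of the trait
// mean from the current optimum, stabilizing term, mutational flux), the
// result is clipped to [0, 1], and 2N gene copies are then resampled
// binomially and independently per locus.
//
// Arguments
//   p0            initial trait-increasing allele frequencies (length l)
//   gamma         per-locus phenotypic effects (length l)
//   s, mu, nu     selection strength and mutation rates (+ -> -, - -> +)
//   zopt          optimum in effect during each of the T update steps
//   nvec          diploid population size during each of the T update steps
//   record_from   first state index to record (0 = the initial state;
//                 states are indexed 0..T, state g is reached after g steps)
//   freq_stride   if > 0, store the full frequency vector of every
//                 freq_stride-th recorded state
//   delta_c1_fixed if not NA, use this constant mean deviation in the
//                 directional-selection term instead of the replicate's own
//                 c1 - z_opt (used for single-locus diffusion checks where
//                 the mean-field coupling is held external)
//
// Uses R's RNG, so results are reproducible under set.seed() from R.
// [[Rcpp::export(name = ".wf_run_cpp")]]
List wf_run_cpp(NumericVector p0, NumericVector gamma, double s, double mu,
                double nu, NumericVector zopt, NumericVector nvec,
                int record_from, int freq_stride, double delta_c1_fixed) {
  const int l = p0.size();
  const int T = zopt.size();
  if (nvec.size() != T)
    stop("zopt and nvec must have one entry per update step");
  if (record_from < 0 || record_from > T)
    stop("record_from must lie in [0, number of steps]");
  const bool use_fixed = !NumericVector::is_na(delta_c1_fixed);

  std::vector<double> p(p0.begin(), p0.end());
  const int n_rec = T - record_from + 1;
  NumericVector c1_out(n_rec), c2_out(n_rec), c3_out(n_rec);

  int n_frec = 0;
  if (freq_stride > 0) n_frec = (n_rec - 1) / freq_stride + 1;
  NumericMatrix freqs(n_frec > 0 ? n_frec : 1, n_frec > 0 ? l : 1);
  if (n_frec == 0) freqs = NumericMatrix(0, 0);

  RNGScope scope;
  NumericVector init_state(l);

  int frow = 0;
  for (int g = 0; g <= T; ++g) {
    if (g == record_from)
      for (int i = 0; i < l; ++i) init_state[i] = p[i];
    if (g >= record_from) {
      double c1 = 0.0, c2 = 0.0, c3 = 0.0;
      for (int i = 0; i < l; ++i) {
        const double q = 1.0 - p[i];
        const double pq = p[i] * q;
        c1 += gamma[i] * (2.0 * p[i] - 1.0);
        c2 += 2.0 * gamma[i] * gamma[i] * pq;
        c3 += 2.0 * gamma[i] * gamma[i] * gamma[i] * pq * (q - p[i]);
      }
      const int k = g - record_from;
      c1_out[k] = c1;
      c2_out[k] = c2;
      c3_out[k] = c3;
      if (freq_stride > 0 && k % freq_stride == 0) {
        for (int i = 0; i < l; ++i) freqs(frow, i) = p[i];
        ++frow;
      }
    }
    if (g == T) break;

    // selection + mutation, then binomial drift sampling
    double d;
    if (use_fixed) {
      d = delta_c1_fixed;
    } else {
      double c1 = 0.0;
      for (int i = 0; i < l; ++i) c1 += gamma[i] * (2.0 * p[i] - 1.0);
      d = c1 - zopt[g];
    }
    const double twoN = 2.0 * nvec[g];
    for (int i = 0; i < l; ++i) {
      const double q = 1.0 - p[i];
      const double pq = p[i] * q;
      const double v = -s * gamma[i] * pq * d
                       - 0.5 * s * gamma[i] * gamma[i] * pq * (q - p[i])
                       - mu * p[i] + nu * q;
      double ps = p[i] + v;
      if (ps < 0.0) ps = 0.0; else if (ps > 1.0) ps = 1.0;
      p[i] = R::rbinom(twoN, ps) / twoN;
    }
  }

  return List::create(_["c1"] = c1_out, _["c2"] = c2_out, _["c3"] = c3_out,
                      _["freqs"] = freqs, _["init_freqs"] = init_state,
                      _["final_freqs"] = NumericVector(p.begin(), p.end()));
}
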