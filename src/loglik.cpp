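#include <Rcpp.h>
using namespace Rcpp;

// Forward-pass session log-likelihood for the PEIRS / RW models.
// chosen/other are 1-based stimulus indices; other == 0 marks a forced trial
// (state update only, no choice term). stim_set gives each stimulus's set so
// the context signal averages over the four stimuli of the current set.
// [[Rcpp::export]]
double peirs_loglik_cpp(IntegerVector chosen, IntegerVector other,
                        NumericVector reward, IntegerVector stim_set,
                        int n_stim, double q0, double s0,
                        double alpha_q, double alpha_s, double beta,
                        double gamma0, double gamma1) {
  int n = chosen.size();
  std::vector<double> q(n_stim, q0), s(n_stim, s0);
  double ll = 0.0;

  for (int t = 0; t < n; t++) {
    int ch = chosen[t] - 1;
    int ot = other[t] - 1;
    if (ot >= 0) {
      int grp = stim_set[ch];
      double qall = 0.0;
      int nset = 0;
      for (int i = 0; i < n_stim; i++) {
        if (stim_set[i] == grp) { qall += q[i]; nset++; }
      }
      qall /= nset;
      double delta = 0.5 * (q[ch] + q[ot]) - qall;
      double uc = q[ch] + gamma0 * s[ch] + gamma1 * delta * s[ch];
      double uu = q[ot] + gamma0 * s[ot] + gamma1 * delta * s[ot];
      double x = beta * (uc - uu);
      // stable log(logistic(x))
      ll += (x > 0) ? -log1p(std::exp(-x)) : x - log1p(std::exp(x));
    }
    double pe = reward[t] - q[ch];
    s[ch] += alpha_s * (std::fabs(pe) - s[ch]);
    q[ch] += alpha_q * pe;
  }
  return ll;
}
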