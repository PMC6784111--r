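#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Exact permutation p-value for the Spearman rank correlation: enumerates
// every distinct arrangement of the y ranks (feasible for n <= 10) and counts
// arrangements whose correlation is at least as extreme as the observed one.
// With tied ranks std::next_permutation visits each distinct arrangement once
// and all arrangements are equally likely, so count/total is the exact p.

static double rank_cor(const std::vector<double>& x, const std::vector<double>& y) {
  const size_t n = x.size();
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (size_t i = 0; i < n; ++i) {
    sx += x[i]; sy += y[i];
    sxx += x[i] * x[i]; syy += y[i] * y[i];
    sxy += x[i] * y[i];
  }
  double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
  double cv = sxy - sx * sy / n;
  return cv / std::sqrt(vx * vy);
}

// [[Rcpp::export]]
double spearman_exact_perm_p(Rcpp::NumericVector xr, Rcpp::NumericVector yr,
                             std::string alternative) {
  
  std::vector<double> x(xr.begin(), xr.end());
  std::vector<double> y(yr.begin(), yr.end());
  const double rho_obs = rank_cor(x, y);
  const double eps = 1e-12;
  std::sort(y.begin(), y.end());
  long double hits = 0, total = 0;
  do {
    const double rho = rank_cor(x, y);
    bool hit;
    if (alternative == "greater")       hit = rho >= rho_obs - eps;
    else if (alternative == "less")     hit = rho <= rho_obs + eps;
    else                                hit = std::fabs(rho) >= std::fabs(rho_obs) - eps;
    if (hit) ++hits;
    ++total;
  } while (std::next_permutation(y.begin(), y.end()));
  return static_cast<double>(hits / total);
}
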