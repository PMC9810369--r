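#include <Rcpp.h>
using namespace Rcpp;

// Likelihood sweep for S1 angular inference. For each node (in the given
// order) the Bernoulli log-likelihood of its angle against all others is
// evaluated on a coarse global grid and a fine local grid around the coarse
// winner; the move is accepted only if it beats the current angle, so a
// sweep never decreases the total likelihood. Pair terms use
//   ll = (1 - a) * beta * z - softplus(beta * z),   z = log(dt) + lk[j],
// with lk[j] = log(r_circ / (mu * kappa_i * kappa_j)) hoisted per node.

// angles arrive (near-)reduced, so plain subtraction replaces fmod (which
// also sidesteps a glibc >= 2.38 versioned-symbol dependency)
static inline double reduce_2pi(double d) {
  while (d >= 2.0 * M_PI) d -= 2.0 * M_PI;
  while (d < 0.0) d += 2.0 * M_PI;
  return d;
}

static inline double wrap_sep(double a, double b) {
  double d = reduce_2pi(std::fabs(a - b));
  return M_PI - std::fabs(M_PI - d);
}

// [[Rcpp::export]]
NumericVector sweep_angles_cpp(NumericVector theta_, IntegerMatrix adj,
                               NumericVector kappa, double beta, double mu,
                               double r_circ, IntegerVector ord,
                               NumericVector cand_base, double gap,
                               int n_fine) {
  NumericVector theta = clone(theta_);
  const int n = theta.size();
  const int nc = cand_base.size();
  std::vector<double> lk(n);

  for (int oi = 0; oi < ord.size(); ++oi) {
    const int i = ord[oi] - 1;
    for (int j = 0; j < n; ++j)
      lk[j] = std::log(r_circ / (mu * kappa[i] * kappa[j]));

    auto eval1 = [&](double th) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dt = wrap_sep(th, theta[j]);
        if (dt < 1e-12) dt = 1e-12;
        double bz = beta * (std::log(dt) + lk[j]);
        double softplus = (bz > 0.0 ? bz : 0.0) +
          std::log1p(std::exp(-std::fabs(bz)));
        s += (adj(i, j) ? 0.0 : bz) - softplus;
      }
      return s;
    };

    int bi = 0;
    double bll = -std::numeric_limits<double>::infinity();
    for (int c = 0; c < nc; ++c) {
      double v = eval1(cand_base[c]);
      if (v > bll) { bll = v; bi = c; }
    }
    double best_ll = bll, best_th = cand_base[bi];
    for (int t = 0; t < n_fine; ++t) {
      double th = cand_base[bi] - gap + 2.0 * gap * t / (n_fine - 1);
      double v = eval1(th);
      if (v > best_ll) { best_ll = v; best_th = th; }
    }
    if (best_ll > eval1(theta[i]))
      theta[i] = reduce_2pi(best_th);
  }
  return theta;
}

// Total Bernoulli log-likelihood of an angle configuration (same kernel).
// [[Rcpp::export]]
double total_loglik_cpp(NumericVector theta, IntegerMatrix adj,
                        NumericVector kappa, double beta, double mu,
                        double r_circ) {
  const int n = theta.size();
  double s = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dt = wrap_sep(theta[i], theta[j]);
      if (dt < 1e-12) dt = 1e-12;
      double chi = r_circ * dt / (mu * kappa[i] * kappa[j]);
      double bz = beta * std::log(chi);
      double softplus = (bz > 0.0 ? bz : 0.0) +
        std::log1p(std::exp(-std::fabs(bz)));
      s += (adj(i, j) ? 0.0 : bz) - softplus;
    }
  }
  return s;
}
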