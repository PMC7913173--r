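#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// numerically safe log(1 + exp(x))
static inline double log1pexp_(double x) {
  if (x <= -37.0) return std::exp(x);
  if (x <= 18.0)  return std::log1p(std::exp(x));
  if (x <= 33.3)  return x + std::exp(-x);
  return x;
}

static inline double dnorm_log(double x, double m, double v) {
  return -0.5 * std::log(2.0 * M_PI * v) - (x - m) * (x - m) / (2.0 * v);
}

namespace {

struct Problem {
  NumericVector y;
  NumericMatrix X;                       // n x K exposure matrix
  NumericMatrix Z;                       // n x P covariate matrix (P may be 0)
  std::vector< std::vector<int> > gidx;  // 0-based member columns per group
  std::vector< std::vector<double> > alpha;
  int link;                              // 0 = gaussian, 1 = logit
  double theta_m, theta_v;
  double icpt_m, icpt_v;
  double coef_m, coef_v;
  int sigma_prior;                       // 0 = half-cauchy on sigma, 1 = inverse-gamma on sigma^2
  double sigma_scale, ig_shape, ig_rate;
  int n, K, P, G;
};

Problem make_problem(NumericVector y, NumericMatrix X, NumericMatrix Z,
                     List group_idx, List group_alpha, int link,
                     NumericVector prior_pack, int sigma_prior,
                     NumericVector sigma_pack) {
  Problem pb;
  pb.y = y; pb.X = X; pb.Z = Z; pb.link = link;
  pb.n = y.size(); pb.K = X.ncol(); pb.P = Z.ncol();
  pb.G = group_idx.size();
  for (int g = 0; g < pb.G; ++g) {
    IntegerVector ix = group_idx[g];
    NumericVector al = group_alpha[g];
    pb.gidx.push_back(std::vector<int>(ix.begin(), ix.end()));
    pb.alpha.push_back(std::vector<double>(al.begin(), al.end()));
  }
  pb.icpt_m = prior_pack[0]; pb.icpt_v = prior_pack[1];
  pb.theta_m = prior_pack[2]; pb.theta_v = prior_pack[3];
  pb.coef_m = prior_pack[4]; pb.coef_v = prior_pack[5];
  pb.sigma_prior = sigma_prior;
  pb.sigma_scale = sigma_pack[0]; pb.ig_shape = sigma_pack[1]; pb.ig_rate = sigma_pack[2];
  return pb;
}

// linear predictor from parts
void compute_eta(const Problem& pb, const std::vector<double>& beta,
                 const std::vector< std::vector<double> >& Xw,
                 std::vector<double>& eta) {
  const int n = pb.n, G = pb.G, P = pb.P;
  for (int i = 0; i < n; ++i) {
    double e = beta[0];
    for (int g = 0; g < G; ++g) e += beta[1 + g] * Xw[g][i];
    for (int p = 0; p < P; ++p) e += beta[1 + G + p] * pb.Z(i, p);
    eta[i] = e;
  }
}

void compute_Xw(const Problem& pb, int g, const std::vector<double>& w,
                std::vector<double>& out) {
  const std::vector<int>& ix = pb.gidx[g];
  const int n = pb.n, Kg = ix.size();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < Kg; ++k) s += w[k] * pb.X(i, ix[k]);
    out[i] = s;
  }
}

double loglik(const Problem& pb, const std::vector<double>& eta, double sigma) {
  const int n = pb.n;
  double ll = 0.0;
  if (pb.link == 0) {
    double rss = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = pb.y[i] - eta[i];
      rss += r * r;
    }
    ll = -0.5 * n * std::log(2.0 * M_PI * sigma * sigma) - rss / (2.0 * sigma * sigma);
  } else {
    for (int i = 0; i < n; ++i)
      ll += pb.y[i] * eta[i] - log1pexp_(eta[i]);
  }
  return ll;
}

double logprior_beta(const Problem& pb, const std::vector<double>& beta) {
  double lp = dnorm_log(beta[0], pb.icpt_m, pb.icpt_v);
  for (int g = 0; g < pb.G; ++g) lp += dnorm_log(beta[1 + g], pb.theta_m, pb.theta_v);
  for (int p = 0; p < pb.P; ++p) lp += dnorm_log(beta[1 + pb.G + p], pb.coef_m, pb.coef_v);
  return lp;
}

double logdirichlet(const std::vector<double>& w, const std::vector<double>& a) {
  double sa = 0.0, lp = 0.0;
  for (size_t k = 0; k < a.size(); ++k) {
    sa += a[k];
    lp += (a[k] - 1.0) * std::log(w[k]) - R::lgammafn(a[k]);
  }
  return lp + R::lgammafn(sa);
}

// prior log-density on the sigma parameterization itself (no sampling Jacobian)
double logprior_sigma(const Problem& pb, double sigma) {
  if (pb.sigma_prior == 0) {
    // half-Cauchy(scale) on sigma
    double s = pb.sigma_scale;
    return std::log(2.0) - std::log(M_PI * s * (1.0 + (sigma / s) * (sigma / s)));
  }
  // inverse-gamma(shape, rate) on sigma^2
  double s2 = sigma * sigma;
  return pb.ig_shape * std::log(pb.ig_rate) - R::lgammafn(pb.ig_shape) -
         (pb.ig_shape + 1.0) * std::log(s2) - pb.ig_rate / s2;
}

// additive log-ratio transform: v (K-1) -> w (K), overflow-guarded
void alr_inv(const std::vector<double>& v, std::vector<double>& w) {
  const int K = w.size();
  double mx = 0.0;
  for (int k = 0; k < K - 1; ++k) if (v[k] > mx) mx = v[k];
  double denom = std::exp(-mx);
  for (int k = 0; k < K - 1; ++k) denom += std::exp(v[k] - mx);
  for (int k = 0; k < K - 1; ++k) w[k] = std::exp(v[k] - mx) / denom;
  w[K - 1] = std::exp(-mx) / denom;
}

double sum_log(const std::vector<double>& w) {
  double s = 0.0;
  for (size_t k = 0; k < w.size(); ++k) s += std::log(w[k]);
  return s;
}

} // namespace

// Joint log-posterior (likelihood + priors) on the natural parameterization.
// beta = (intercept, theta_1..theta_G, coef_1..coef_P); weights: list of simplex
// vectors, one per group; sigma ignored for the logit link.
// [[Rcpp::export]]
double cpp_log_posterior(NumericVector y, NumericMatrix X, NumericMatrix Z,
                         List group_idx, List group_alpha, int link,
                         NumericVector prior_pack, int sigma_prior,
                         NumericVector sigma_pack,
                         NumericVector beta, List weights, double sigma) {
  Problem pb = make_problem(y, X, Z, group_idx, group_alpha, link,
                            prior_pack, sigma_prior, sigma_pack);
  std::vector<double> b(beta.begin(), beta.end());
  std::vector< std::vector<double> > W, Xw;
  for (int g = 0; g < pb.G; ++g) {
    NumericVector wg = weights[g];
    W.push_back(std::vector<double>(wg.begin(), wg.end()));
    std::vector<double> xw(pb.n);
    compute_Xw(pb, g, W[g], xw);
    Xw.push_back(xw);
  }
  std::vector<double> eta(pb.n);
  compute_eta(pb, b, Xw, eta);
  double lp = loglik(pb, eta, sigma) + logprior_beta(pb, b);
  for (int g = 0; g < pb.G; ++g)
    if ((int)W[g].size() > 1) lp += logdirichlet(W[g], pb.alpha[g]);
  if (pb.link == 0) lp += logprior_sigma(pb, sigma);
  return lp;
}

// One MCMC chain: adaptive random-walk Metropolis within Gibbs on blocks
// {intercept + thetas + coefs}, {per-group unconstrained weight coordinates},
// {log sigma}. Step sizes adapt by Robbins-Monro during burn-in only.
// Uses R's RNG, so set.seed() at the R level makes runs reproducible.
// [[Rcpp::export]]
List run_bws_chain(NumericVector y, NumericMatrix X, NumericMatrix Z,
                   List group_idx, List group_alpha, int link,
                   NumericVector prior_pack, int sigma_prior,
                   NumericVector sigma_pack,
                   int n_iter, int burn_in, int thin,
                   NumericVector init_beta, List init_w, double init_sigma,
                   LogicalVector fix_w, bool fix_sigma) {
  Problem pb = make_problem(y, X, Z, group_idx, group_alpha, link,
                            prior_pack, sigma_prior, sigma_pack);
  const int G = pb.G, P = pb.P, n = pb.n;
  const int d_beta = 1 + G + P;

  std::vector<double> beta(init_beta.begin(), init_beta.end());
  std::vector< std::vector<double> > W(G), V(G), Xw(G);
  std::vector<int> Kg(G);
  for (int g = 0; g < G; ++g) {
    NumericVector wg = init_w[g];
    Kg[g] = wg.size();
    W[g] = std::vector<double>(wg.begin(), wg.end());
    if (Kg[g] > 1) {
      V[g].resize(Kg[g] - 1);
      for (int k = 0; k < Kg[g] - 1; ++k)
        V[g][k] = std::log(W[g][k] / W[g][Kg[g] - 1]);
    }
    Xw[g].resize(n);
    compute_Xw(pb, g, W[g], Xw[g]);
  }
  double sigma = init_sigma;
  std::vector<double> eta(n);
  compute_eta(pb, beta, Xw, eta);

  double cur_ll = loglik(pb, eta, sigma);
  if (!R_finite(cur_ll))
    stop("log-likelihood is not finite at the initial state");

  // adaptation state: one log step per block
  double ls_beta = std::log(0.1 / std::sqrt((double)d_beta));
  std::vector<double> ls_w(G, std::log(0.25));
  double ls_sigma = std::log(0.25);
  const double targ_beta = (d_beta == 1) ? 0.44 : 0.234;
  double acc_beta = 0.0, acc_sigma = 0.0;
  std::vector<double> acc_w(G, 0.0);

  const int n_keep = (n_iter - burn_in) / thin;
  const int n_par = d_beta + pb.K + (link == 0 ? 1 : 0);
  NumericMatrix draws(n_keep, n_par);

  std::vector<double> beta_p(d_beta), eta_p(n), w_p, v_p, xw_p(n);
  int stored = 0;

  for (int t = 1; t <= n_iter; ++t) {
    const bool adapting = (t <= burn_in);
    const double gain = std::pow((double)t, -0.6);

    // --- block 1: intercept + thetas + coefs ---
    {
      double s = std::exp(ls_beta);
      for (int j = 0; j < d_beta; ++j) beta_p[j] = beta[j] + s * norm_rand();
      compute_eta(pb, beta_p, Xw, eta_p);
      double ll_p = loglik(pb, eta_p, sigma);
      double delta = ll_p - cur_ll + logprior_beta(pb, beta_p) - logprior_beta(pb, beta);
      double a = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
      if (unif_rand() < a) {
        beta = beta_p; eta = eta_p; cur_ll = ll_p;
      }
      if (adapting) ls_beta += gain * (a - targ_beta);
      else acc_beta += a;
    }

    // --- block 2: per-group weight coordinates ---
    for (int g = 0; g < G; ++g) {
      if (Kg[g] < 2 || fix_w[g]) continue;
      const int dv = Kg[g] - 1;
      double s = std::exp(ls_w[g]);
      v_p.resize(dv); w_p.resize(Kg[g]);
      for (int k = 0; k < dv; ++k) v_p[k] = V[g][k] + s * norm_rand();
      alr_inv(v_p, w_p);
      compute_Xw(pb, g, w_p, xw_p);
      double th = beta[1 + g];
      for (int i = 0; i < n; ++i) eta_p[i] = eta[i] + th * (xw_p[i] - Xw[g][i]);
      double ll_p = loglik(pb, eta_p, sigma);
      double delta = ll_p - cur_ll +
        logdirichlet(w_p, pb.alpha[g]) - logdirichlet(W[g], pb.alpha[g]) +
        sum_log(w_p) - sum_log(W[g]);  // ALR Jacobian
      double a = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
      if (unif_rand() < a) {
        V[g] = v_p; W[g] = w_p;
        std::copy(xw_p.begin(), xw_p.end(), Xw[g].begin());
        std::copy(eta_p.begin(), eta_p.end(), eta.begin());
        cur_ll = ll_p;
      }
      double targ = (dv == 1) ? 0.44 : 0.234;
      if (adapting) ls_w[g] += gain * (a - targ);
      else acc_w[g] += a;
    }

    // --- block 3: log sigma (gaussian link) ---
    if (link == 0 && !fix_sigma) {
      double u = std::log(sigma);
      double u_p = u + std::exp(ls_sigma) * norm_rand();
      double sig_p = std::exp(u_p);
      double ll_p = loglik(pb, eta, sig_p);
      double delta = ll_p - cur_ll +
        logprior_sigma(pb, sig_p) - logprior_sigma(pb, sigma) +
        (u_p - u);  // Jacobian of the log transform
      double a = R_finite(delta) ? std::min(1.0, std::exp(delta)) : 0.0;
      if (unif_rand() < a) { sigma = sig_p; cur_ll = ll_p; }
      if (adapting) ls_sigma += gain * (a - 0.44);
      else acc_sigma += a;
    }

    // guard against incremental drift in eta
    if (t % 1000 == 0) {
      compute_eta(pb, beta, Xw, eta);
      cur_ll = loglik(pb, eta, sigma);
    }

    if (t > burn_in && (t - burn_in) % thin == 0 && stored < n_keep) {
      int c = 0;
      for (int j = 0; j < d_beta; ++j) draws(stored, c++) = beta[j];
      for (int g = 0; g < G; ++g)
        for (int k = 0; k < Kg[g]; ++k) draws(stored, c++) = W[g][k];
      if (link == 0) draws(stored, c++) = sigma;
      ++stored;
    }
  }

  const double post = std::max(1, n_iter - burn_in);
  NumericVector accw(G);
  for (int g = 0; g < G; ++g) accw[g] = acc_w[g] / post;
  return List::create(
    _["draws"] = draws,
    _["accept_beta"] = acc_beta / post,
    _["accept_weights"] = accw,
    _["accept_sigma"] = acc_sigma / post,
    _["step_beta"] = std::exp(ls_beta),
    _["step_sigma"] = std::exp(ls_sigma));
}
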