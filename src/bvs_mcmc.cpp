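#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for Bayesian variable selection in
// log-link Dirichlet-multinomial regression with a hard-thresholding prior:
//   raw coefficients b_kj ~ N(0, prior_sd^2) i.i.d.,
//   threshold t ~ Uniform(0, t_max) (or fixed),
//   effective coefficients theta_kj = b_kj * 1[|b_kj| >= t] for covariate
//   rows, theta_0j = b_0j (intercepts never thresholded),
//   alpha_i = exp(x_i' theta), y_i ~ DM(alpha_i, N_i).
//
// Element-wise random-walk updates on b; a column-restricted likelihood
// delta makes each update O(n). Uses R's RNG, so results are reproducible
// under set.seed() from the calling R session.

static inline double thresh(double b, double t) {
  return (std::fabs(b) >= t) ? b : 0.0;
}

// full DM log-likelihood core (multinomial coefficient omitted: it is
// constant in theta and cancels from every acceptance ratio)
static double full_core(const NumericMatrix &X, const NumericMatrix &Y,
                        const NumericVector &N, const NumericMatrix &theta,
                        NumericMatrix &alpha, NumericVector &A,
                        NumericVector &lgA, NumericVector &lgNA,
                        NumericMatrix &T) {
  int n = X.nrow(), P = X.ncol(), J = Y.ncol();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double Ai = 0.0;
    for (int j = 0; j < J; ++j) {
      double eta = 0.0;
      for (int k = 0; k < P; ++k) eta += X(i, k) * theta(k, j);
      double a = std::exp(eta);
      alpha(i, j) = a;
      Ai += a;
      T(i, j) = std::lgamma(Y(i, j) + a) - std::lgamma(a);
      ll += T(i, j);
    }
    A[i] = Ai;
    lgA[i] = std::lgamma(Ai);
    lgNA[i] = std::lgamma(N[i] + Ai);
    ll += lgA[i] - lgNA[i];
  }
  return ll;
}

// [[Rcpp::export(name = ".bvs_mcmc_cpp")]]
List bvs_mcmc_cpp(NumericMatrix X, NumericMatrix Y, NumericMatrix b_init,
                  double t_init, int n_iter, int burn_in, int thin,
                  double prior_sd, double proposal_sd, double t_proposal_sd,
                  double t_max, bool t_fixed, double indep_prob) {
  const int n = X.nrow(), P = X.ncol(), J = Y.ncol();
  NumericVector N(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += Y(i, j);
    N[i] = s;
  }

  NumericMatrix b(clone(b_init));
  double t = t_init;
  NumericMatrix theta(P, J);
  for (int j = 0; j < J; ++j) {
    theta(0, j) = b(0, j);
    for (int k = 1; k < P; ++k) theta(k, j) = thresh(b(k, j), t);
  }

  NumericMatrix alpha(n, J), T(n, J);
  NumericVector A(n), lgA(n), lgNA(n);
  double ll = full_core(X, Y, N, theta, alpha, A, lgA, lgNA, T);
  if (!R_finite(ll)) stop("non-finite likelihood at initialization");

  const int n_kept = (n_iter - burn_in + thin - 1) / thin;
  NumericMatrix theta_draws(n_kept, P * J);
  NumericVector t_draws(n_kept);
  int kept = 0;
  long acc_cov = 0, prop_cov = 0, acc_int = 0, prop_int = 0;
  long acc_lik = 0, prop_lik = 0;  // covariate moves that change theta
  long acc_t = 0, prop_t = 0;
  const double inv2v = 1.0 / (2.0 * prior_sd * prior_sd);

  RNGScope scope;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int k = 0; k < P; ++k) {
      for (int j = 0; j < J; ++j) {
        double b_old = b(k, j);
        // mixture kernel: random walk, or (for covariate rows) an
        // independence draw from the prior that jumps the in/out boundary;
        // for the latter the prior and proposal densities cancel, so the
        // acceptance ratio is the likelihood ratio alone
        bool indep = (k > 0) && (unif_rand() < indep_prob);
        double b_new, lp;
        if (indep) {
          b_new = norm_rand() * prior_sd;
          lp = 0.0;
        } else {
          b_new = b_old + norm_rand() * proposal_sd;
          lp = -(b_new * b_new - b_old * b_old) * inv2v;
        }
        double th_old = theta(k, j);
        double th_new = (k == 0) ? b_new : thresh(b_new, t);
        double dll = 0.0;
        bool lik_change = (th_new != th_old);
        // per-sample buffers for a column-j likelihood delta
        std::vector<double> a_new_v, A_new_v;
        if (lik_change) {
          a_new_v.resize(n);
          A_new_v.resize(n);
          double d = th_new - th_old;
          for (int i = 0; i < n; ++i) {
            double a_new = alpha(i, j) * std::exp(d * X(i, k));
            double A_new = A[i] - alpha(i, j) + a_new;
            if (!R_finite(a_new) || !R_finite(A_new) || A_new <= 0.0) {
              dll = R_NegInf;
              break;
            }
            a_new_v[i] = a_new;
            A_new_v[i] = A_new;
            dll += std::lgamma(A_new) - lgA[i] + lgNA[i] -
                   std::lgamma(N[i] + A_new) +
                   std::lgamma(Y(i, j) + a_new) - std::lgamma(a_new) -
                   T(i, j);
          }
          if (!R_finite(dll) && dll > 0) dll = R_NegInf;
        }
        if (k == 0) ++prop_int; else ++prop_cov;
        if (k > 0 && lik_change) ++prop_lik;
        bool accepted = std::log(unif_rand()) < dll + lp;
        if (accepted && k > 0 && lik_change) ++acc_lik;
        if (accepted) {
          b(k, j) = b_new;
          theta(k, j) = th_new;
          if (lik_change && R_finite(dll)) {
            for (int i = 0; i < n; ++i) {
              alpha(i, j) = a_new_v[i];
              A[i] = A_new_v[i];
              lgA[i] = std::lgamma(A[i]);
              lgNA[i] = std::lgamma(N[i] + A[i]);
              T(i, j) = std::lgamma(Y(i, j) + alpha(i, j)) -
                        std::lgamma(alpha(i, j));
            }
            ll += dll;
          }
          if (k == 0) ++acc_int; else ++acc_cov;
        }
      }
    }

    if (!t_fixed) {
      ++prop_t;
      double t_new = t + norm_rand() * t_proposal_sd;
      if (t_new > 0.0 && t_new < t_max) {
        NumericMatrix theta_new(P, J);
        for (int j = 0; j < J; ++j) {
          theta_new(0, j) = b(0, j);
          for (int k = 1; k < P; ++k) theta_new(k, j) = thresh(b(k, j), t_new);
        }
        NumericMatrix alpha2(n, J), T2(n, J);
        NumericVector A2(n), lgA2(n), lgNA2(n);
        double ll_new = full_core(X, Y, N, theta_new, alpha2, A2, lgA2,
                                  lgNA2, T2);
        if (R_finite(ll_new) &&
            std::log(unif_rand()) < ll_new - ll) {
          t = t_new;
          theta = theta_new;
          alpha = alpha2; A = A2; lgA = lgA2; lgNA = lgNA2; T = T2;
          ll = ll_new;
          ++acc_t;
        }
      }
    }

    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      for (int j = 0; j < J; ++j)
        for (int k = 0; k < P; ++k)
          theta_draws(kept, j * P + k) = theta(k, j);
      t_draws[kept] = t;
      ++kept;
    }
  }

  return List::create(
      _["theta_draws"] = theta_draws, _["t_draws"] = t_draws,
      _["acceptance"] = NumericVector::create(
          _["covariate"] = prop_lik ? (double)acc_lik / prop_lik : NA_REAL,
          _["covariate_all"] = prop_cov ? (double)acc_cov / prop_cov : NA_REAL,
          _["intercept"] = prop_int ? (double)acc_int / prop_int : NA_REAL,
          _["threshold"] = prop_t ? (double)acc_t / prop_t : NA_REAL),
      _["final_log_likelihood"] = ll);
}
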