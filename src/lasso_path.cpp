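#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// l1-penalised logistic regression along a descending lambda path, by
// iteratively reweighted least squares with cyclic coordinate descent on the
// weighted working response (warm-started between grid points).  The
// objective is (1/n) * negative log-likelihood + lambda * ||beta||_1 with an
// unpenalised intercept, so lambda_max = max_j |x_j' (y - ybar)| / n zeroes
// every slope.  Convergence: maximum absolute coefficient change below
// `thresh` in the inner (CD) loop and across each outer (IRLS) pass.
//
// 0/1 predictor columns (the package's native case) are visited through
// per-column index lists, and each lambda step iterates the active set to
// convergence before one full sweep confirms no coordinate re-enters.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_logistic_path")]]
List cd_logistic_path(NumericMatrix X, NumericVector y, NumericVector lambda,
                      double thresh = 1e-9, int maxit_outer = 50,
                      int maxit_inner = 5000) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  NumericMatrix beta(p, nlam);
  NumericVector a0(nlam), dev(nlam);

  // With <= 16 binary predictors the likelihood depends on the data only
  // through the 2^p row patterns: collapse observations onto pattern counts
  // (prior weight v_k) and within-pattern response means (fractional y).
  // General numeric designs fall back to one group per row.
  bool binary_design = (p <= 16);
  if (binary_design) {
    for (int j = 0; j < p && binary_design; ++j)
      for (int i = 0; i < n; ++i) {
        double xv = X(i, j);
        if (xv != 0.0 && xv != 1.0) { binary_design = false; break; }
      }
  }

  int K = 0;
  std::vector<double> v, yg;          // group weight (count), group mean of y
  std::vector<std::vector<int> > ones(p);  // groups with bit j set
  std::vector<std::vector<double> > xval;  // dense fallback design
  if (binary_design) {
    std::vector<int> slot(1 << p, -1), key(n);
    for (int i = 0; i < n; ++i) {
      int k = 0;
      for (int j = 0; j < p; ++j) if (X(i, j) == 1.0) k |= (1 << j);
      key[i] = k;
    }
    for (int i = 0; i < n; ++i) {
      if (slot[key[i]] < 0) {
        slot[key[i]] = K++;
        v.push_back(0.0);
        yg.push_back(0.0);
      }
      int g = slot[key[i]];
      v[g] += 1.0;
      yg[g] += y[i];
    }
    for (int g = 0; g < K; ++g) yg[g] /= v[g];
    std::vector<int> inv(K);
    for (int kk = 0; kk < (1 << p); ++kk)
      if (slot[kk] >= 0) inv[slot[kk]] = kk;
    for (int j = 0; j < p; ++j)
      for (int g = 0; g < K; ++g)
        if (inv[g] & (1 << j)) ones[j].push_back(g);
  } else {
    K = n;
    v.assign(n, 1.0);
    yg.resize(n);
    xval.assign(p, std::vector<double>(n));
    for (int i = 0; i < n; ++i) yg[i] = y[i];
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < n; ++i) xval[j][i] = X(i, j);
  }

  std::vector<double> b(p, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double intercept = std::log(ybar / (1.0 - ybar));

  std::vector<double> eta(K, intercept), w(K), e(K), xwx(p, 0.0), mu(K);

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambda[l];
    for (int outer = 0; outer < maxit_outer; ++outer) {
      // quadratic approximation at the current linear predictor
      double wsum = 0.0;
      for (int g = 0; g < K; ++g) {
        double et = eta[g];
        if (et > 30.0) et = 30.0;
        if (et < -30.0) et = -30.0;
        double m = 1.0 / (1.0 + std::exp(-et));
        double q = m * (1.0 - m);
        if (q < 1e-5) q = 1e-5;
        w[g] = v[g] * q;
        wsum += w[g];
        e[g] = (yg[g] - m) / q;  // working residual (z - eta)
      }
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        if (binary_design) {
          for (size_t k = 0; k < ones[j].size(); ++k) s += w[ones[j][k]];
        } else {
          for (int g = 0; g < K; ++g) s += w[g] * xval[j][g] * xval[j][g];
        }
        xwx[j] = s / n;
      }
      std::vector<double> b_old(b);
      const double intercept_old = intercept;

      bool full_pass = true;  // first sweep visits every coordinate
      for (int inner = 0; inner < maxit_inner; ++inner) {
        double delta = 0.0;
        // intercept (unpenalised)
        double num0 = 0.0;
        for (int g = 0; g < K; ++g) num0 += w[g] * e[g];
        double d0 = num0 / wsum;
        if (d0 != 0.0) {
          intercept += d0;
          for (int g = 0; g < K; ++g) e[g] -= d0;
          delta = std::max(delta, std::fabs(d0));
        }
        bool activated = false;
        for (int j = 0; j < p; ++j) {
          if (!full_pass && b[j] == 0.0) continue;
          if (xwx[j] <= 0.0) continue;
          double grad = 0.0;
          if (binary_design) {
            for (size_t k = 0; k < ones[j].size(); ++k)
              grad += w[ones[j][k]] * e[ones[j][k]];
          } else {
            for (int g = 0; g < K; ++g) grad += w[g] * xval[j][g] * e[g];
          }
          grad /= n;
          double bj_new = soft(grad + xwx[j] * b[j], lam) / xwx[j];
          double d = bj_new - b[j];
          if (d != 0.0) {
            if (b[j] == 0.0) activated = true;
            b[j] = bj_new;
            if (binary_design) {
              for (size_t k = 0; k < ones[j].size(); ++k) e[ones[j][k]] -= d;
            } else {
              for (int g = 0; g < K; ++g) e[g] -= d * xval[j][g];
            }
            delta = std::max(delta, std::fabs(d));
          }
        }
        if (delta < thresh) {
          if (full_pass && !activated) break;  // confirmed on a full sweep
          full_pass = true;                    // verify with a full sweep
        } else {
          full_pass = false;                   // iterate the active set
        }
      }
      // refresh the linear predictor from the coefficients
      for (int g = 0; g < K; ++g) eta[g] = intercept;
      for (int j = 0; j < p; ++j) {
        if (b[j] == 0.0) continue;
        if (binary_design) {
          for (size_t k = 0; k < ones[j].size(); ++k) eta[ones[j][k]] += b[j];
        } else {
          for (int g = 0; g < K; ++g) eta[g] += b[j] * xval[j][g];
        }
      }
      double outer_delta = std::fabs(intercept - intercept_old);
      for (int j = 0; j < p; ++j)
        outer_delta = std::max(outer_delta, std::fabs(b[j] - b_old[j]));
      if (outer_delta < thresh) break;
    }
    // binomial deviance at the solution (grouping leaves it unchanged:
    // v * [yg log mu + (1 - yg) log(1 - mu)] sums the member loglik)
    double ll = 0.0;
    for (int g = 0; g < K; ++g) {
      double et = eta[g];
      if (et > 30.0) et = 30.0;
      if (et < -30.0) et = -30.0;
      double m = 1.0 / (1.0 + std::exp(-et));
      ll += v[g] * (yg[g] * std::log(m) + (1.0 - yg[g]) * std::log(1.0 - m));
    }
    dev[l] = -2.0 * ll;
    a0[l] = intercept;
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return List::create(_["beta"] = beta, _["a0"] = a0, _["dev"] = dev);
}

// Full-sweep Gibbs sampling of n independent chains from a {0,1} Ising
// model with conditionals P(x_j = 1 | rest) = logistic(tau_j + W[,j]'x).
// Chains start from fair coin flips and are swept `n_sweeps` times; all
// uniforms come from R's RNG (RNGScope), so draws are reproducible under R
// seeds with a deterministic consumption order.

// [[Rcpp::export(name = ".gibbs_ising")]]
NumericMatrix gibbs_ising(NumericMatrix W, NumericVector tau, int n,
                          int n_sweeps) {
  const int p = tau.size();
  NumericMatrix x(n, p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j)
      x(i, j) = (R::unif_rand() < 0.5) ? 1.0 : 0.0;
  for (int s = 0; s < n_sweeps; ++s) {
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) {
        double et = tau[j];
        for (int jj = 0; jj < p; ++jj) et += W(jj, j) * x(i, jj);
        double pr = 1.0 / (1.0 + std::exp(-et));
        x(i, j) = (R::unif_rand() < pr) ? 1.0 : 0.0;
      }
    }
  }
  return x;
}
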