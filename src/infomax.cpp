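// Extended-infomax ICA inner loop (natural-gradient, block updates, with
// kurtosis-based sub/super-Gaussian sign switching and learning-rate
// annealing). Operates on whitened data; returns the unmixing matrix in
// whitened space. Uses R's RNG for the per-step data permutation, so results
// are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List infomax_core(const arma::mat& X, int max_steps, double lrate,
                        int block, double wchange_tol, bool extended,
                        int kurt_size, double anneal_deg, double anneal_step,
                        double blowup, double blowup_fac) {
  const uword r = X.n_rows, N = X.n_cols;
  mat W = eye<mat>(r, r);
  mat BI = eye<mat>(r, r) * (double)block;
  vec signs = ones<vec>(r);  // +1 super-Gaussian
  mat old_delta;
  double old_change = 0.0;
  int step = 0, nblocks = (int)(N / block);
  double change = datum::inf;
  double degconst = 180.0 / datum::pi;

  // fixed subsample for kurtosis estimation
  uword kn = std::min<uword>(kurt_size, N);
  uvec kidx = conv_to<uvec>::from(round(linspace(0, N - 1, kn)));
  mat Xk = X.cols(kidx);

  while (step < max_steps) {
    mat W_old = W;
    // deterministic-under-seed permutation from R's RNG
    Rcpp::IntegerVector p = Rcpp::sample((int)N, (int)N, false);
    uvec perm(N);
    for (uword i = 0; i < N; ++i) perm(i) = (uword)(p[i] - 1);

    if (extended) {
      mat u = W * Xk;
      vec m2 = mean(square(u), 1);
      vec m4 = mean(square(square(u)), 1);
      for (uword i = 0; i < r; ++i) {
        double k = m4(i) / (m2(i) * m2(i)) - 3.0;
        signs(i) = (k >= 0.0) ? 1.0 : -1.0;
      }
    }

    bool blew = false;
    for (int b = 0; b < nblocks; ++b) {
      uvec cols = perm.subvec((uword)b * block, (uword)(b + 1) * block - 1);
      mat u = W * X.cols(cols);
      mat y = tanh(u);
      mat dW;
      if (extended) {
        dW = (BI - (y.each_col() % signs) * u.t() - u * u.t()) * W;
      } else {
        mat ylog = 1.0 - 2.0 / (1.0 + exp(-u));
        dW = (BI + ylog * u.t()) * W;
      }
      W += lrate * dW;
      if (W.has_nan() || abs(W).max() > blowup) { blew = true; break; }
    }

    if (blew) {
      lrate *= blowup_fac;
      W = eye<mat>(r, r);
      old_delta.reset();
      old_change = 0.0;
      step = 0;
      if (lrate < 1e-10) break;
      continue;
    }

    mat delta = W - W_old;
    change = accu(square(delta));
    if (step > 1 && old_delta.n_elem > 0) {
      double num = accu(delta % old_delta);
      double den = std::sqrt(change * old_change);
      double angle = (den > 0) ? degconst * std::acos(std::max(-1.0, std::min(1.0, num / den))) : 0.0;
      if (angle > anneal_deg) {
        lrate *= anneal_step;
        old_delta = delta;
        old_change = change;
      }
    } else {
      old_delta = delta;
      old_change = change;
    }
    ++step;
    if (step > 2 && change < wchange_tol) break;
  }

  return Rcpp::List::create(Rcpp::Named("weights") = W,
                            Rcpp::Named("steps") = step,
                            Rcpp::Named("wchange") = change,
                            Rcpp::Named("lrate") = lrate,
                            Rcpp::Named("signs") = signs,
                            Rcpp::Named("converged") = change < wchange_tol);
}
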