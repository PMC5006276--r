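#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Penalized maximum-likelihood Newton solver for an exponential-family
// distribution over an enumerated genotype state table.
//
// Phi     : K x p feature matrix (one row per enumerated state; single-site
//           indicator columns followed by pair-product columns)
// t       : length-p vector of data feature sums (sufficient statistics)
// n       : group sample size
// lambda  : l2 penalty on coordinates flagged in penmask
// penmask : length-p 0/1 vector (1 = coupling coordinate, penalized)
// theta   : start values (full parameter vector)
// free_idx: 0-based indices of coordinates being optimized; all other
//           coordinates are held fixed at their theta values (restricted fits)
//
// Objective minimized:
//   nll(theta) = -(t'theta - n*logZ(theta)) + (n*lambda/2) * sum(penmask*theta^2)
// which is the negative of the penalized total log-likelihood. The objective
// is convex, so Newton with step halving converges to the unique optimum.
// [[Rcpp::export]]
List ee_newton_cpp(const arma::mat& Phi, const arma::vec& t, double n,
                   double lambda, const arma::vec& penmask,
                   arma::vec theta, const arma::uvec& free_idx,
                   double tol, int maxit) {
  const arma::uword p = Phi.n_cols;
  if (theta.n_elem != p || t.n_elem != p || penmask.n_elem != p)
    stop("parameter/feature dimension mismatch");
  arma::mat Phif = Phi.cols(free_idx);
  arma::vec pen_f = penmask.elem(free_idx);

  auto eval = [&](const arma::vec& th, double& logZ, arma::vec& prob) {
    arma::vec E = Phi * th;
    double emax = E.max();
    prob = arma::exp(E - emax);
    double s = arma::accu(prob);
    prob /= s;
    logZ = emax + std::log(s);
    double pterm = 0.5 * n * lambda * arma::accu(penmask % arma::square(th));
    return -(arma::dot(t, th) - n * logZ) + pterm;
  };

  double logZ;
  arma::vec prob;
  double nll = eval(theta, logZ, prob);
  bool converged = false;
  int iter = 0;
  double gmax = NA_REAL;

  for (iter = 0; iter < maxit; ++iter) {
    arma::vec mu = Phi.t() * prob;                  // model moments (full)
    arma::vec grad_full = n * mu - t + n * lambda * (penmask % theta);
    arma::vec g = grad_full.elem(free_idx);
    gmax = arma::abs(g).max();
    if (gmax / n < tol) { converged = true; break; }

    arma::vec mu_f = mu.elem(free_idx);
    // Fisher information restricted to free coordinates
    arma::mat H = n * (Phif.t() * (Phif.each_col() % prob) - mu_f * mu_f.t());
    H.diag() += n * lambda * pen_f + 1e-10 * n;
    arma::vec step;
    bool ok = arma::solve(step, H, g, arma::solve_opts::likely_sympd);
    if (!ok) {
      H.diag() += 1e-6 * n;
      step = arma::solve(H, g);
    }
    // cap the step to keep exp() well-behaved far from the optimum
    double smax = arma::abs(step).max();
    if (smax > 5.0) step *= 5.0 / smax;

    double alpha = 1.0;
    arma::vec theta_new = theta;
    double nll_new = nll;
    for (int ls = 0; ls < 40; ++ls) {
      theta_new = theta;
      theta_new.elem(free_idx) = theta.elem(free_idx) - alpha * step;
      nll_new = eval(theta_new, logZ, prob);
      if (nll_new <= nll - 1e-4 * alpha * arma::dot(g, step) || nll_new < nll)
        break;
      alpha *= 0.5;
    }
    if (nll_new >= nll - 1e-14 * std::abs(nll) && alpha < 1e-9) {
      // no further progress possible at machine precision
      theta_new = theta;
      eval(theta, logZ, prob);
      converged = (gmax / n < tol * 10);
      break;
    }
    theta = theta_new;
    nll = nll_new;
  }
  if (!converged && iter == maxit) {
    // re-evaluate gradient at the final point for the report
    arma::vec mu = Phi.t() * prob;
    arma::vec grad_full = n * mu - t + n * lambda * (penmask % theta);
    gmax = arma::abs(grad_full.elem(free_idx)).max();
    converged = (gmax / n < tol);
  }
  return List::create(_["theta"] = theta, _["nll"] = nll, _["logZ"] = logZ,
                      _["converged"] = converged, _["iterations"] = iter,
                      _["grad_max"] = gmax / n);
}
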