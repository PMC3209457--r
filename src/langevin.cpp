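#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Euler-Maruyama integration of overdamped Langevin dynamics on a fixed
// quadratic potential V(x) = 1/2 (x - x0)^T H (x - x0):
//
//   x <- x - (dt/zeta) H (x - x0) + sqrt(2 kT dt / zeta) eta
//
// `rigid` holds an orthonormal basis of the rigid-body (zero-mode)
// subspace at x0; each step increment is projected onto its orthogonal
// complement. This is the Brownian analogue of centre-of-mass motion
// removal in MD: the linearised rigid modes have no restoring force, so
// without removal they diffuse without bound and their tangent-space
// "rotations" corrupt internal geometry at long times. Pass a matrix
// with zero columns to disable.
//
// Noise is drawn from R's RNG (norm_rand) so trajectories are exactly
// reproducible from set.seed() on the R side, coordinate by coordinate in
// a fixed order. Returns saved frames as rows (frame 0 is x0 itself).
// [[Rcpp::export]]
arma::mat langevin_core(const arma::mat& hessian, const arma::vec& x0,
                        const arma::mat& rigid,
                        double dt, double kT, double friction,
                        int n_steps, int save_every) {
  const arma::uword d = x0.n_elem;
  const arma::mat drift = (dt / friction) * hessian;
  const double sigma = std::sqrt(2.0 * kT * dt / friction);
  const int n_saved = n_steps / save_every;
  const bool project = rigid.n_cols > 0;

  arma::mat frames(n_saved + 1, d);
  arma::vec x = x0, dx(d), eta(d);
  frames.row(0) = x0.t();

  int saved = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (arma::uword i = 0; i < d; ++i) eta(i) = norm_rand();
    dx = -drift * (x - x0) + sigma * eta;
    if (project) dx -= rigid * (rigid.t() * dx);
    if (arma::abs(dx).max() > 1e3) {
      Rcpp::stop("divergent displacement at step %d; reduce the timestep",
                 step);
    }
    x += dx;
    if (step % save_every == 0) {
      frames.row(saved) = x.t();
      ++saved;
    }
  }
  return frames;
}
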