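#include <Rcpp.h>
using namespace Rcpp;

// Red-black successive over-relaxation for the 7-point finite-difference
// linear Poisson-Boltzmann stencil on a cubic grid of n nodes per side.
//
// Node (i,j,k) (0-based) lives at flat index i + n*j + n*n*k.
// epsx[i,j,k] is the edge dielectric between nodes (i,j,k) and (i+1,j,k),
// stored with dims (n-1, n, n); epsy/epsz analogous.
// lambda is the ion accessibility (0 inside the solute, 1 in solvent);
// screen = eps_out * kappa^2 * h^2; source = 4*pi*C*q/h per node (kT/e).
// Boundary nodes are Dirichlet: u is updated on interior nodes only.
//
// The update for an interior node is
//   u0 <- (1-w)*u0 + w * (sum_k eps_k u_k + source) / (sum_k eps_k + screen*lambda)
// and the returned residual is the largest absolute node update of the
// final sweep, in kT/e, which is the convergence measure thresholded by
// the caller.

// [[Rcpp::export]]
List sor_solve_cpp(NumericVector epsx, NumericVector epsy, NumericVector epsz,
                   NumericVector lambda, NumericVector source,
                   NumericVector u, int n, double screen, double tol,
                   int max_iter, double omega) {
  const int nn = n * n;
  const int nm1 = n - 1;
  // edge array strides
  const int sx1 = nm1, sx2 = nm1 * n;   // epsx dims (n-1, n, n)
  const int sy1 = n,   sy2 = n * nm1;   // epsy dims (n, n-1, n)
  const int sz1 = n,   sz2 = nn;        // epsz dims (n, n, n-1)

  const double *ex = epsx.begin(), *ey = epsy.begin(), *ez = epsz.begin();
  const double *lam = lambda.begin(), *src = source.begin();
  double *up = u.begin();
  const double om1 = 1.0 - omega;

  double maxdiff = R_PosInf;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    maxdiff = 0.0;
    for (int colour = 0; colour < 2; ++colour) {
      for (int k = 1; k < nm1; ++k) {
        for (int j = 1; j < nm1; ++j) {
          // first interior i of this colour in the current (j,k) column
          const int i0 = 1 + ((1 + j + k + colour) & 1);
          const int bx = sx1 * j + sx2 * k;
          const int by = sy1 * (j - 1) + sy2 * k;
          const int by2 = sy1 * j + sy2 * k;
          const int bz = sz1 * j + sz2 * (k - 1);
          const int bz2 = sz1 * j + sz2 * k;
          const int b0 = n * j + nn * k;
          for (int i = i0; i < nm1; i += 2) {
            const int id = i + b0;
            const double exm = ex[i - 1 + bx];
            const double exp_ = ex[i + bx];
            const double eym = ey[i + by];
            const double eyp = ey[i + by2];
            const double ezm = ez[i + bz];
            const double ezp = ez[i + bz2];
            const double num = exm * up[id - 1] + exp_ * up[id + 1] +
                               eym * up[id - n] + eyp * up[id + n] +
                               ezm * up[id - nn] + ezp * up[id + nn] +
                               src[id];
            const double den = exm + exp_ + eym + eyp + ezm + ezp +
                               screen * lam[id];
            const double unew = om1 * up[id] + omega * num / den;
            const double d = unew - up[id];
            if (d > maxdiff) maxdiff = d;
            else if (-d > maxdiff) maxdiff = -d;
            up[id] = unew;
          }
        }
      }
    }
    if (maxdiff < tol) break;
  }
  return List::create(_["u"] = u, _["residual"] = maxdiff,
                      _["iterations"] = iter > max_iter ? max_iter : iter,
                      _["converged"] = maxdiff < tol);
}
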