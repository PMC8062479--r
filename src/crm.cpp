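// Fixed-step (explicit Euler) integrator for the consumer resource model
// with Monod uptake, leakage and byproduct secretion.
//
// State: N (S species abundances), R (M resource abundances, the first Mp
// columns primary, the rest byproducts).
//
//   dN_i/dt = g_i N_i [ sum_a w_a (1 - l_a) C_ia R_a/(k_a + R_a) - m_i ]
//   dR_a/dt = - sum_i C_ia N_i R_a/(k_a + R_a)
//             + sum_{i,b<=Mp} D_abi (w_b / w_a) l_b C_ib N_i R_b/(k_b + R_b)
//
// The consumption term is negative (resources deplete); byproducts are
// produced from primary resources only and are not converted further.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_integrate_batch(const arma::mat& C, const arma::cube& D,
                         arma::vec N, arma::vec R, int Mp,
                         const arma::vec& g, const arma::vec& m,
                         const arma::vec& w, const arma::vec& l,
                         const arma::vec& k,
                         double dt, double duration, int thin) {
  const int S = C.n_rows;
  const int M = C.n_cols;
  const int Mb = M - Mp;
  const long nsteps = (long) std::llround(duration / dt);

  arma::vec wl = w % (1.0 - l);
  // Production fluxes: for each species i the matrix
  //   E_i(a, b) = D(a, b, i) * w_b * l_b * C(i, b) / w_{Mp+a}
  // is constant over a batch, so prod = sum_i N_i * E_i * monp collapses to
  // one gemv: Ebig (Mb x S*Mp) times v, with v((i,b)) = N_i * monp_b.
  arma::mat Ebig;
  arma::vec v;
  if (Mb > 0) {
    Ebig.set_size(Mb, S * Mp);
    for (int i = 0; i < S; ++i) {
      arma::mat Ei = D.slice(i);
      for (int b = 0; b < Mp; ++b)
        Ei.col(b) *= w(b) * l(b) * C(i, b);
      Ei.each_col() /= w.tail(Mb);
      Ebig.cols(i * Mp, (i + 1) * Mp - 1) = Ei;
    }
    v.set_size(S * Mp);
  }

  const bool record = thin > 0;
  std::vector<double> times;
  std::vector<arma::vec> Ntraj, Rtraj;
  if (record) {
    times.push_back(0.0); Ntraj.push_back(N); Rtraj.push_back(R);
  }

  arma::vec mon(M), dN(S), dR(M);
  for (long s = 1; s <= nsteps; ++s) {
    mon = R / (k + R);
    dN = g % N % (C * (wl % mon) - m);
    dR = -((C.t() * N) % mon);
    if (Mb > 0) {
      for (int i = 0; i < S; ++i)
        v.subvec(i * Mp, (i + 1) * Mp - 1) = N(i) * mon.head(Mp);
      dR.tail(Mb) += Ebig * v;
    }
    N += dt * dN;
    R += dt * dR;
    N.clamp(0.0, arma::datum::inf);
    R.clamp(0.0, arma::datum::inf);
    if (!N.is_finite() || !R.is_finite())
      stop("non-finite state at step %ld (t = %.3f h)", s, s * dt);
    if (record && (s % thin == 0 || s == nsteps)) {
      times.push_back(s * dt); Ntraj.push_back(N); Rtraj.push_back(R);
    }
  }

  List out = List::create(Named("N") = N, Named("R") = R,
                          Named("t") = nsteps * dt);
  if (record) {
    const int nr = times.size();
    arma::mat Nm(nr, S), Rm(nr, M);
    for (int r = 0; r < nr; ++r) {
      Nm.row(r) = Ntraj[r].t();
      Rm.row(r) = Rtraj[r].t();
    }
    out["times"] = NumericVector(times.begin(), times.end());
    out["N_traj"] = Nm;
    out["R_traj"] = Rm;
  }
  return out;
}
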