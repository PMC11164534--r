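// Alternating gradient descent core for the bilinear connectivity model.
//
// Both data regimes share one loop:
//   cell level ("ridge" penalty):
//     L = || W o (Z - XA (YB)^T) ||_F^2 + lA/2 ||A||_F^2 + lB/2 ||B||_F^2
//   type level ("gram" penalty):
//     L = || W o (Zbar - Xh Ah (Yh Bh)^T) ||_F^2
//         + lA/2 ||Ah^T Ah||_F^2 + lB/2 ||Bh^T Bh||_F^2
// where W is a fixed nonnegative weight matrix (all ones when absent; binary
// hold-out masks reuse the same path during cross-validation).
//
// Gradients are the exact derivatives of L, so the weighted residual enters
// as (W o W) o R; for binary W the two coincide. Both gradients of an
// iteration are computed from the same predicted matrix before either factor
// is updated, then A is updated before B.
//
// Step rules:
//   bb (default) - Barzilai-Borwein spectral step on the joint (A, B)
//     gradient with the Grippo-Lampariello-Lucidi nonmonotone safeguard
//     (window 20): a trial step whose loss exceeds the window maximum is
//     halved until accepted. The normalized type-mean matrices are badly
//     scaled (features divided by small pooled sds), and a fixed-rate
//     loop needs millions of iterations there; the spectral step follows
//     the same gradient directions with a data-driven magnitude.
//   fixed - the plain constant-rate loop; loss becoming non-finite is
//     reported as divergence.
// Everything is deterministic given the inputs.

#include <RcppArmadillo.h>
#include <deque>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double penalty_of(const mat& A, const mat& B,
                         const double lA, const double lB,
                         const bool gram) {
  if (gram)
    return 0.5 * lA * accu(square(A.t() * A)) +
           0.5 * lB * accu(square(B.t() * B));
  return 0.5 * lA * accu(square(A)) + 0.5 * lB * accu(square(B));
}

// [[Rcpp::export]]
Rcpp::List agd_fit_cpp(const arma::mat& X, const arma::mat& Y,
                       const arma::mat& Z, const arma::mat& W,
                       arma::mat A, arma::mat B,
                       const double lambda_A, const double lambda_B,
                       double rate, const double tol,
                       const int max_iter, const bool gram_penalty,
                       const bool bb_step) {
  const mat W2 = W % W;
  const int window = 20;
  std::vector<double> trajectory;
  trajectory.reserve(1024);

  bool converged = false, diverged = false;

  auto loss_of = [&](const mat& A_, const mat& B_) {
    const mat R = (X * A_) * (Y * B_).t() - Z;
    return accu(square(W % R)) +
           penalty_of(A_, B_, lambda_A, lambda_B, gram_penalty);
  };

  double loss = loss_of(A, B);
  std::deque<double> hist(window, loss);
  mat A_old, B_old, gA_old, gB_old;
  bool have_prev = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    trajectory.push_back(loss);
    if (!std::isfinite(loss)) { diverged = true; break; }
    if (iter > 0 &&
        std::abs(trajectory[iter - 1] - loss) < tol) {
      converged = true; break;
    }

    const mat P = X * A;
    const mat Q = Y * B;
    const mat M = W2 % (P * Q.t() - Z);
    mat gA = 2.0 * X.t() * M * Q;
    mat gB = 2.0 * Y.t() * M.t() * P;
    if (gram_penalty) {
      gA += 2.0 * lambda_A * A * (A.t() * A);
      gB += 2.0 * lambda_B * B * (B.t() * B);
    } else {
      gA += lambda_A * A;
      gB += lambda_B * B;
    }

    if (bb_step) {
      if (have_prev) {
        const double sy = accu((A - A_old) % (gA - gA_old)) +
                          accu((B - B_old) % (gB - gB_old));
        const double ss = accu(square(A - A_old)) +
                          accu(square(B - B_old));
        if (sy > 0) rate = ss / sy; else rate *= 2.0;
      }
      const double ref = *std::max_element(hist.begin(), hist.end());
      mat A_new, B_new;
      double loss_new;
      for (;;) {
        A_new = A - rate * gA;
        B_new = B - rate * gB;
        loss_new = loss_of(A_new, B_new);
        if (std::isfinite(loss_new) && loss_new <= ref) break;
        rate *= 0.5;
        if (rate < 1e-300) { diverged = true; break; }
      }
      if (diverged) break;
      A_old = A; B_old = B; gA_old = gA; gB_old = gB; have_prev = true;
      A = A_new; B = B_new;
      hist.pop_front(); hist.push_back(loss_new);
      loss = loss_new;
    } else {
      A -= rate * gA;
      B -= rate * gB;
      loss = loss_of(A, B);
    }
  }

  if (!converged && !diverged) {
    trajectory.push_back(loss);
    if (!std::isfinite(loss)) diverged = true;
  }

  return Rcpp::List::create(
    Rcpp::Named("A") = A,
    Rcpp::Named("B") = B,
    Rcpp::Named("loss") = trajectory,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("diverged") = diverged,
    Rcpp::Named("n_iter") = static_cast<int>(trajectory.size()));
}
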