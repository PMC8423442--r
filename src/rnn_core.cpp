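// Compiled core of the two-module recurrent network: the unrolled
// leaky-ReLU rate dynamics with short-term synaptic plasticity, and the
// matching backward pass (backpropagation through time). Gradients are
// with respect to the *effective* weights; the ReLU-of-raw-weight and
// Dale-sign mapping is applied on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List rnn_forward_core(const arma::mat& w_rec, const arma::mat& w_rec_test,
                            const arma::vec& b, const arma::mat& w_out,
                            const arma::vec& b_out, const arma::mat& drive_sample,
                            const arma::mat& drive_test,
                            const Rcpp::IntegerVector& input_code,
                            const arma::cube& noise, const arma::vec& stp_U,
                            const arma::vec& a_x, const arma::vec& a_u, double a,
                            double dt_s, int test_start, bool stp,
                            const arma::vec& unit_mult,
                            bool use_unit_mult) {
  const uword n = w_rec.n_rows;
  const uword nb = noise.n_cols;
  const uword T = noise.n_slices;

  cube r(n, nb, T + 1), x(n, nb, T + 1), u(n, nb, T + 1);
  cube sm(3, nb, T);
  mat Ax = repmat(a_x, 1, nb), Au = repmat(a_u, 1, nb),
      Uu = repmat(stp_U, 1, nb);
  mat rp(n, nb, fill::value(0.1)), xp(n, nb, fill::ones), up = Uu;
  r.slice(0) = rp; x.slice(0) = xp; u.slice(0) = up;

  mat x_raw, u_raw, xt, ut, s, pre, rt, z;
  for (uword t = 0; t < T; ++t) {
    if (stp) {
      x_raw = xp + Ax % (1.0 - xp) - dt_s * (up % xp % rp);
      u_raw = up + Au % (Uu - up) + dt_s * (Uu % (1.0 - up) % rp);
      xt = clamp(x_raw, 0.0, 1.0);
      ut = clamp(u_raw, 0.0, 1.0);
      s = ut % xt % rp;
    } else {
      xt = xp; ut = up; s = rp;
    }
    bool in_test = (static_cast<int>(t) + 1) >= test_start;
    const arma::mat& wr = in_test ? w_rec_test : w_rec;
    pre = wr * s + noise.slice(t);
    if (input_code[t] == 1) pre += drive_sample;
    else if (input_code[t] == 2) pre += drive_test;
    pre.each_col() += b;
    rt = (1.0 - a) * rp + a * clamp(pre, 0.0, datum::inf);
    if (use_unit_mult && in_test) rt.each_col() %= unit_mult;
    r.slice(t + 1) = rt;
    x.slice(t + 1) = xt;
    u.slice(t + 1) = ut;
    z = w_out * rt;
    z.each_col() += b_out;
    z.each_row() -= max(z, 0);
    mat ez = exp(z);
    ez.each_row() /= sum(ez, 0);
    sm.slice(t) = ez;
    rp = rt; xp = xt; up = ut;
  }
  return Rcpp::List::create(
      Rcpp::Named("r") = r, Rcpp::Named("softmax") = sm,
      Rcpp::Named("x") = x, Rcpp::Named("u") = u);
}

// [[Rcpp::export]]
Rcpp::List rnn_backward_core(const arma::cube& r, const arma::cube& x, const arma::cube& u,
                             const arma::cube& sm,
                             const arma::mat& w_rec, const arma::mat& w_out,
                             const Rcpp::IntegerMatrix& target,
                             const arma::mat& loss_mask, const arma::vec& stp_U,
                             const arma::vec& a_x, const arma::vec& a_u, double a,
                             double dt_s, bool stp, double rate_cost) {
  const uword n = w_rec.n_rows;
  const uword nb = r.n_cols;
  const uword T = sm.n_slices;
  const double mask_sum = accu(loss_mask);
  const double n_r = static_cast<double>(n) * nb * T;

  mat g_wrec(n, n, fill::zeros), g_wout(3, n, fill::zeros);
  vec g_b(n, fill::zeros), g_bout(3, fill::zeros);
  mat A_r(n, nb, fill::zeros), A_x(n, nb, fill::zeros),
      A_u(n, nb, fill::zeros);
  mat Ax = repmat(a_x, 1, nb), Au = repmat(a_u, 1, nb),
      Uu = repmat(stp_U, 1, nb);

  mat dz(3, nb), d_pre, s, g_s, A_r_prev, A_x_prev, A_u_prev;
  for (uword t = T; t-- > 0;) {
    const arma::mat& rt = r.slice(t + 1);
    const arma::mat& rp = r.slice(t);
    // cross-entropy at step t (softmax + one-hot target), masked
    dz = sm.slice(t);
    for (uword i = 0; i < nb; ++i) {
      dz(target(t, i) - 1, i) -= 1.0;
      dz.col(i) *= loss_mask(t, i) / mask_sum;
    }
    g_wout += dz * rt.t();
    g_bout += sum(dz, 1);
    A_r += w_out.t() * dz;
    A_r += (2.0 * rate_cost / n_r) * rt;
    // ReLU mask: relu(pre) > 0 iff r_t - (1-a) r_{t-1} > 0
    d_pre = a * (A_r % conv_to<mat>::from((rt - (1.0 - a) * rp) > 0));
    g_b += sum(d_pre, 1);
    if (stp) {
      const arma::mat& xt = x.slice(t + 1);
      const arma::mat& ut = u.slice(t + 1);
      const arma::mat& xp = x.slice(t);
      const arma::mat& up = u.slice(t);
      s = ut % xt % rp;
      g_wrec += d_pre * s.t();
      g_s = w_rec.t() * d_pre;
      A_x += g_s % ut % rp;
      A_u += g_s % xt % rp;
      A_r_prev = (1.0 - a) * A_r + g_s % ut % xt;
      // clip pass-through masks, recovered from the post-clip states
      A_x %= conv_to<mat>::from((xt > 0) % (xt < 1));
      A_u %= conv_to<mat>::from((ut > 0) % (ut < 1));
      A_r_prev += -dt_s * (A_x % up % xp) + dt_s * (A_u % Uu % (1.0 - up));
      A_x_prev = A_x % (1.0 - Ax - dt_s * (up % rp));
      A_u_prev = A_u % (1.0 - Au - dt_s * (Uu % rp)) -
                 dt_s * (A_x % xp % rp);
      A_x = A_x_prev;
      A_u = A_u_prev;
      A_r = A_r_prev;
    } else {
      g_wrec += d_pre * rp.t();
      A_r = (1.0 - a) * A_r + w_rec.t() * d_pre;
    }
  }
  return Rcpp::List::create(Rcpp::Named("w_rec_eff") = g_wrec,
                            Rcpp::Named("b_rec") = g_b,
                            Rcpp::Named("w_out_eff") = g_wout,
                            Rcpp::Named("b_out") = g_bout);
}
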