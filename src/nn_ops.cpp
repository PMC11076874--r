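// Fused hot path of the 1D CNN: one call runs the whole network forward
// (and optionally backward) for a minibatch, keeping every intermediate on
// the C++ side so only parameter-sized objects cross the R boundary.
//
// Layout: a batch of B windows of length L0 is the (1 x L0*B) matrix with
// column index (b-1)*L + l; each conv block maps (cin x L*B) ->
// (cout x L*B) via im2col + GEMM, followed by batch normalization, ReLU,
// and (after blocks 2 and 4) average pooling of size 2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::mat& a, const int k, const int l,
                        const int b) {
  const int cin = a.n_rows;
  const int pad = (k - 1) / 2;
  arma::mat xcol(cin * k, (arma::uword)l * b, arma::fill::zeros);
  for (int bb = 0; bb < b; ++bb) {
    const int off = bb * l;
    for (int j = 0; j < k; ++j) {
      const int shift = j - pad;
      const int lo = std::max(0, -shift);
      const int hi = std::min(l, l - shift);
      for (int pos = lo; pos < hi; ++pos) {
        const double* src = a.colptr(off + pos + shift);
        double* dst = xcol.colptr(off + pos) + (arma::uword)j * cin;
        std::copy(src, src + cin, dst);
      }
    }
  }
  return xcol;
}

static arma::mat col2im_add(const arma::mat& dxcol, const int cin,
                            const int k, const int l, const int b) {
  const int pad = (k - 1) / 2;
  arma::mat dx(cin, (arma::uword)l * b, arma::fill::zeros);
  for (int bb = 0; bb < b; ++bb) {
    const int off = bb * l;
    for (int j = 0; j < k; ++j) {
      const int shift = j - pad;
      const int lo = std::max(0, -shift);
      const int hi = std::min(l, l - shift);
      for (int pos = lo; pos < hi; ++pos) {
        const double* src = dxcol.colptr(off + pos) + (arma::uword)j * cin;
        double* dst = dx.colptr(off + pos + shift);
        for (int c = 0; c < cin; ++c) dst[c] += src[c];
      }
    }
  }
  return dx;
}

static arma::mat avgpool2(const arma::mat& a, const int l, const int b) {
  const int lo = l / 2;
  arma::mat out(a.n_rows, (arma::uword)lo * b);
  for (int bb = 0; bb < b; ++bb) {
    for (int m = 0; m < lo; ++m) {
      out.col(bb * lo + m) =
        0.5 * (a.col(bb * l + 2 * m) + a.col(bb * l + 2 * m + 1));
    }
  }
  return out;
}

static arma::mat avgpool2_bwd(const arma::mat& d, const int l, const int b) {
  const int lo = l / 2;
  arma::mat out(d.n_rows, (arma::uword)l * b);
  for (int bb = 0; bb < b; ++bb) {
    for (int m = 0; m < lo; ++m) {
      arma::vec half = 0.5 * d.col(bb * lo + m);
      out.col(bb * l + 2 * m) = half;
      out.col(bb * l + 2 * m + 1) = half;
    }
  }
  return out;
}

// Forward the full network and, when y is non-empty, backpropagate the
// softmax cross-entropy loss. Returns class probabilities, the loss, the
// gradients of every trainable tensor, and updated BN running statistics.
// `frozen[blk]` keeps that block's BN in inference mode and skips its
// gradients; gradients below the lowest trainable block are not computed.
// [[Rcpp::export(name = ".nn_step_cpp")]]
List nn_step_cpp(const List conv_w, const List bn_gamma, const List bn_beta,
                 const List bn_rmean, const List bn_rvar,
                 const arma::mat& fc1_w, const arma::vec& fc1_b,
                 const arma::mat& fc2_w, const arma::vec& fc2_b,
                 const arma::mat& x,       // B x L0 (windows in rows)
                 const arma::ivec& y,      // 0/1 labels; empty => inference
                 const arma::ivec& kernels,
                 const arma::ivec& pool_after,
                 const bool training,
                 const arma::ivec& frozen,         // per block
                 const bool head_trainable,
                 const double eps, const double momentum) {
  const int nb = conv_w.size();
  const int b = x.n_rows;
  const int l0 = x.n_cols;
  const bool backprop = y.n_elem > 0;

  std::vector<arma::mat> w(nb);
  for (int i = 0; i < nb; ++i) w[i] = as<arma::mat>(conv_w[i]);

  // caches
  std::vector<arma::mat> xcols(nb), xhats(nb), relu_out(nb);
  std::vector<arma::vec> invstds(nb);
  std::vector<int> lens(nb);
  List new_rmean(nb), new_rvar(nb);

  arma::mat a = x.t();
  a.reshape(1, (arma::uword)l0 * b);
  int l = l0;

  for (int blk = 0; blk < nb; ++blk) {
    const int k = kernels[blk];
    lens[blk] = l;
    arma::mat xcol = im2col(a, k, l, b);
    arma::mat out = w[blk] * xcol;
    if (backprop) xcols[blk] = std::move(xcol);

    arma::vec gamma = as<arma::vec>(bn_gamma[blk]);
    arma::vec beta = as<arma::vec>(bn_beta[blk]);
    arma::vec rmean = as<arma::vec>(bn_rmean[blk]);
    arma::vec rvar = as<arma::vec>(bn_rvar[blk]);
    arma::vec mu, invstd;
    if (training && !frozen[blk]) {
      mu = arma::mean(out, 1);
      arma::vec v = arma::mean(out % out, 1) - mu % mu;
      v.transform([](double val) { return val < 0 ? 0 : val; });
      invstd = 1.0 / arma::sqrt(v + eps);
      const double m = (double)out.n_cols;
      const double unbias = m > 1 ? m / (m - 1) : 1.0;
      rmean = (1 - momentum) * rmean + momentum * mu;
      rvar = (1 - momentum) * rvar + momentum * v * unbias;
    } else {
      mu = rmean;
      invstd = 1.0 / arma::sqrt(rvar + eps);
    }
    new_rmean[blk] = rmean;
    new_rvar[blk] = rvar;
    out.each_col() -= mu;
    out.each_col() %= invstd;          // out is now xhat
    if (backprop) {
      xhats[blk] = out;
      invstds[blk] = invstd;
    }
    out.each_col() %= gamma;
    out.each_col() += beta;
    out.transform([](double val) { return val > 0 ? val : 0; });  // ReLU
    const bool pooled = (pool_after[0] == blk + 1) || (pool_after[1] == blk + 1);
    if (backprop) relu_out[blk] = out;
    if (pooled) {
      a = avgpool2(out, l, b);
      l /= 2;
    } else {
      a = std::move(out);
    }
  }

  // head
  arma::mat af = a;
  af.reshape(a.n_rows * l, b);
  arma::mat h = fc1_w * af;
  h.each_col() += fc1_b;
  arma::mat hr = h;
  hr.transform([](double val) { return val > 0 ? val : 0; });
  arma::mat logits = fc2_w * hr;
  logits.each_col() += fc2_b;
  arma::rowvec mx = arma::max(logits, 0);
  logits.each_row() -= mx;
  arma::mat probs = arma::exp(logits);
  arma::rowvec denom = arma::sum(probs, 0);
  probs.each_row() /= denom;

  List out = List::create(
    Named("probs") = probs.t(),
    Named("new_rmean") = new_rmean, Named("new_rvar") = new_rvar);

  if (!backprop) return out;

  double loss = 0;
  for (int i = 0; i < b; ++i) {
    loss -= std::log(std::max(probs(y[i], i), 1e-12));
  }
  loss /= b;
  out["loss"] = loss;

  arma::mat dlogits = probs;
  for (int i = 0; i < b; ++i) dlogits(y[i], i) -= 1.0;
  dlogits /= b;

  List gconv(nb), gbn_gamma(nb), gbn_beta(nb);
  if (head_trainable) {
    out["gfc2_w"] = arma::mat(dlogits * hr.t());
    out["gfc2_b"] = arma::vec(arma::sum(dlogits, 1));
  }
  arma::mat dh = fc2_w.t() * dlogits;
  dh.elem(arma::find(h <= 0)).zeros();
  if (head_trainable) {
    out["gfc1_w"] = arma::mat(dh * af.t());
    out["gfc1_b"] = arma::vec(arma::sum(dh, 1));
  }
  int lowest = nb;  // 0-based index of lowest trainable block; nb if none
  for (int blk = 0; blk < nb; ++blk) {
    if (!frozen[blk]) { lowest = blk; break; }
  }
  if (lowest < nb) {
    arma::mat da = fc1_w.t() * dh;
    da.reshape(a.n_rows, (arma::uword)l * b);
    for (int blk = nb - 1; blk >= lowest; --blk) {
      const int lb = lens[blk];
      const bool pooled = (pool_after[0] == blk + 1) ||
        (pool_after[1] == blk + 1);
      if (pooled) da = avgpool2_bwd(da, lb, b);
      da.elem(arma::find(relu_out[blk] <= 0)).zeros();
      // BN backward
      arma::vec gamma = as<arma::vec>(bn_gamma[blk]);
      gbn_gamma[blk] = arma::vec(arma::sum(da % xhats[blk], 1));
      gbn_beta[blk] = arma::vec(arma::sum(da, 1));
      arma::mat dxhat = da;
      dxhat.each_col() %= gamma;
      if (frozen[blk]) {
        dxhat.each_col() %= invstds[blk];
      } else {
        arma::vec m1 = arma::mean(dxhat, 1);
        arma::vec m2 = arma::mean(dxhat % xhats[blk], 1);
        arma::mat corr = xhats[blk];
        corr.each_col() %= m2;
        dxhat -= corr;
        dxhat.each_col() -= m1;
        dxhat.each_col() %= invstds[blk];
      }
      gconv[blk] = arma::mat(dxhat * xcols[blk].t());
      if (blk > lowest) {
        arma::mat dxcol = w[blk].t() * dxhat;
        da = col2im_add(dxcol, w[blk].n_cols / kernels[blk], kernels[blk],
                        lb, b);
      }
    }
  }
  out["gconv"] = gconv;
  out["gbn_gamma"] = gbn_gamma;
  out["gbn_beta"] = gbn_beta;
  return out;
}
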