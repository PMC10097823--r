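// Encoder-decoder network core: 1-D convolution over time (same padding)
// followed by a fully connected encoder to a low-dimensional bottleneck and
// a fully connected decoder back to the output waveform. Dense training
// loop with Adam and inverted dropout; all randomness comes from one
// std::mt19937 so a fixed seed reproduces training exactly.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct FcLayer {
  mat W;      // in x out
  rowvec b;
  bool relu;
  bool dropout;
};

struct Net {
  mat Wc;     // (K*C) x F
  rowvec bc;
  int K, C, F, T;
  std::vector<FcLayer> fc;
};

Net unpack(const Rcpp::List& weights) {
  Net net;
  net.Wc = Rcpp::as<mat>(weights["Wc"]);
  net.bc = Rcpp::as<rowvec>(weights["bc"]);
  net.K = Rcpp::as<int>(weights["kernel"]);
  net.C = Rcpp::as<int>(weights["n_cells"]);
  net.T = Rcpp::as<int>(weights["n_bins"]);
  net.F = net.Wc.n_cols;
  Rcpp::List fc = weights["fc"];
  for (int l = 0; l < fc.size(); ++l) {
    Rcpp::List lay = fc[l];
    FcLayer f;
    f.W = Rcpp::as<mat>(lay["W"]);
    f.b = Rcpp::as<rowvec>(lay["b"]);
    f.relu = Rcpp::as<bool>(lay["relu"]);
    f.dropout = Rcpp::as<bool>(lay["dropout"]);
    net.fc.push_back(f);
  }
  return net;
}

Rcpp::List pack(const Net& net) {
  Rcpp::List fc(net.fc.size());
  for (size_t l = 0; l < net.fc.size(); ++l) {
    fc[l] = Rcpp::List::create(
        Rcpp::Named("W") = net.fc[l].W, Rcpp::Named("b") = net.fc[l].b,
        Rcpp::Named("relu") = net.fc[l].relu,
        Rcpp::Named("dropout") = net.fc[l].dropout);
  }
  return Rcpp::List::create(
      Rcpp::Named("Wc") = net.Wc, Rcpp::Named("bc") = net.bc,
      Rcpp::Named("kernel") = net.K, Rcpp::Named("n_cells") = net.C,
      Rcpp::Named("n_bins") = net.T, Rcpp::Named("fc") = fc);
}

// im2col for a batch: rows (b-major, t-minor), columns (c*K + k).
mat im2col(const cube& X, const std::vector<int>& ids, int K, int pad) {
  const int B = ids.size();
  const int C = X.n_cols;
  const int T = X.n_slices;
  mat M(B * T, K * C, fill::zeros);
  for (int bi = 0; bi < B; ++bi) {
    const int n = ids[bi];
    for (int c = 0; c < C; ++c) {
      for (int k = 0; k < K; ++k) {
        const int off = k - pad;
        const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
        for (int t = t0; t < t1; ++t)
          M(bi * T + t, c * K + k) = X(n, c, t + off);
      }
    }
  }
  return M;
}

struct ForwardState {
  mat M;                  // im2col input
  mat A0;                 // conv output, post-ReLU
  umat conv_mask;
  mat Z;                  // flattened
  std::vector<mat> H;     // FC activations (post nonlinearity/dropout)
  std::vector<mat> masks; // combined relu/dropout masks (as scaling)
};

// Forward pass for rows `ids` of X. When training, applies inverted
// dropout with the supplied RNG.
mat forward(const Net& net, const cube& X, const std::vector<int>& ids,
            bool training, double p_drop, std::mt19937& rng,
            ForwardState* st) {
  const int B = ids.size();
  const int T = net.T, F = net.F;
  mat M = im2col(X, ids, net.K, net.K / 2);
  mat A0 = M * net.Wc;
  A0.each_row() += net.bc;
  umat cmask = (A0 > 0);
  A0 %= conv_to<mat>::from(cmask);
  mat Z(B, T * F);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      for (int f = 0; f < F; ++f)
        Z(b, t * F + f) = A0(b * T + t, f);
  if (st) {
    st->M = std::move(M);
    st->A0 = A0;
    st->conv_mask = cmask;
    st->Z = Z;
    st->H.clear();
    st->masks.clear();
  }
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  mat H = Z;
  for (size_t l = 0; l < net.fc.size(); ++l) {
    H = H * net.fc[l].W;
    H.each_row() += net.fc[l].b;
    mat scale;
    if (net.fc[l].relu || (training && net.fc[l].dropout && p_drop > 0)) {
      scale.set_size(H.n_rows, H.n_cols);
      scale.ones();
    }
    if (net.fc[l].relu)
      scale %= conv_to<mat>::from(H > 0);
    if (training && net.fc[l].dropout && p_drop > 0) {
      const double keep = 1.0 - p_drop;
      for (uword i = 0; i < scale.n_elem; ++i)
        scale(i) *= (unif(rng) < keep) ? 1.0 / keep : 0.0;
    }
    if (scale.n_elem) H %= scale;
    if (st) {
      st->masks.push_back(scale);  // empty => identity
      st->H.push_back(H);
    }
  }
  return H;
}

struct AdamState {
  std::vector<mat> mW, vW;
  std::vector<rowvec> mb, vb;
};

// Fused single-pass Adam update (the largest layer has 64M parameters, so
// one memory pass per update matters).
template <typename M>
void adam_step(M& W, const M& g, M& m, M& v, double lr, double b1,
               double b2, double eps, long t) {
  const double c1 = 1.0 / (1 - std::pow(b1, (double)t));
  const double c2 = 1.0 / (1 - std::pow(b2, (double)t));
  double* w = W.memptr();
  const double* gp = g.memptr();
  double* mp = m.memptr();
  double* vp = v.memptr();
  const uword n = W.n_elem;
  for (uword i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    w[i] -= lr * (c1 * mp[i]) / (std::sqrt(c2 * vp[i]) + eps);
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_nn_train")]]
Rcpp::List cpp_nn_train(Rcpp::NumericVector x_array, arma::mat y,
                        Rcpp::List weights, double lr, double beta1,
                        double beta2, double eps, double decay,
                        double dropout, int epochs, int batch, int seed,
                        bool verbose) {
  Rcpp::IntegerVector dims = x_array.attr("dim");
  cube X(x_array.begin(), dims[0], dims[1], dims[2]);
  Net net = unpack(weights);
  const int N = X.n_rows;
  if ((int)y.n_rows != N) Rcpp::stop("X and y row counts differ");

  AdamState ad;
  ad.mW.resize(net.fc.size() + 1);
  ad.vW.resize(net.fc.size() + 1);
  ad.mb.resize(net.fc.size() + 1);
  ad.vb.resize(net.fc.size() + 1);
  ad.mW[0] = zeros<mat>(size(net.Wc)); ad.vW[0] = zeros<mat>(size(net.Wc));
  ad.mb[0] = zeros<rowvec>(net.F); ad.vb[0] = zeros<rowvec>(net.F);
  for (size_t l = 0; l < net.fc.size(); ++l) {
    ad.mW[l + 1] = zeros<mat>(size(net.fc[l].W));
    ad.vW[l + 1] = zeros<mat>(size(net.fc[l].W));
    ad.mb[l + 1] = zeros<rowvec>(net.fc[l].b.n_elem);
    ad.vb[l + 1] = zeros<rowvec>(net.fc[l].b.n_elem);
  }

  std::mt19937 rng(seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<double> losses;
  long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; int n_batches = 0;
    for (int start = 0; start < N; start += batch) {
      const int B = std::min(batch, N - start);
      std::vector<int> ids(order.begin() + start,
                           order.begin() + start + B);
      ForwardState st;
      mat O = forward(net, X, ids, true, dropout, rng, &st);
      mat Yb(B, y.n_cols);
      for (int b = 0; b < B; ++b) Yb.row(b) = y.row(ids[b]);
      mat diff = O - Yb;
      const double loss = accu(square(diff)) / diff.n_elem;
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged (non-finite loss)");
      ep_loss += loss; ++n_batches;
      ++step;
      const double lr_t = lr / (1.0 + decay * (double)(step - 1));

      // backward through FC stack
      mat d = (2.0 / diff.n_elem) * diff;
      const int L = net.fc.size();
      std::vector<mat> gW(L);
      std::vector<rowvec> gb(L);
      for (int l = L - 1; l >= 0; --l) {
        if (st.masks[l].n_elem) d %= st.masks[l];
        const mat& input = (l == 0) ? st.Z : st.H[l - 1];
        gW[l] = input.t() * d;
        gb[l] = sum(d, 0);
        if (l > 0) d = d * net.fc[l].W.t();
      }
      mat dZ = d * net.fc[0].W.t();
      // un-flatten to conv output gradient
      const int T = net.T, F = net.F;
      mat dA0(B * T, F);
      for (int b = 0; b < B; ++b)
        for (int t = 0; t < T; ++t)
          for (int f = 0; f < F; ++f)
            dA0(b * T + t, f) = dZ(b, t * F + f);
      dA0 %= conv_to<mat>::from(st.conv_mask);
      mat gWc = st.M.t() * dA0;
      rowvec gbc = sum(dA0, 0);

      adam_step(net.Wc, gWc, ad.mW[0], ad.vW[0], lr_t, beta1, beta2, eps,
                step);
      adam_step(net.bc, gbc, ad.mb[0], ad.vb[0], lr_t, beta1, beta2, eps,
                step);
      for (int l = 0; l < L; ++l) {
        adam_step(net.fc[l].W, gW[l], ad.mW[l + 1], ad.vW[l + 1], lr_t,
                  beta1, beta2, eps, step);
        adam_step(net.fc[l].b, gb[l], ad.mb[l + 1], ad.vb[l + 1], lr_t,
                  beta1, beta2, eps, step);
      }
      Rcpp::checkUserInterrupt();
    }
    losses.push_back(ep_loss / std::max(n_batches, 1));
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << " loss " << losses.back() << std::endl;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = pack(net),
                            Rcpp::Named("loss") = losses);
}

// [[Rcpp::export(name = ".cpp_nn_predict")]]
arma::mat cpp_nn_predict(Rcpp::NumericVector x_array, Rcpp::List weights) {
  Rcpp::IntegerVector dims = x_array.attr("dim");
  cube X(x_array.begin(), dims[0], dims[1], dims[2]);
  Net net = unpack(weights);
  std::mt19937 rng(0);
  const int N = X.n_rows;
  const int chunk = 512;
  mat out;
  for (int start = 0; start < N; start += chunk) {
    const int B = std::min(chunk, N - start);
    std::vector<int> ids(B);
    for (int i = 0; i < B; ++i) ids[i] = start + i;
    mat O = forward(net, X, ids, false, 0.0, rng, nullptr);
    out = out.n_rows ? join_cols(out, O) : O;
  }
  return out;
}
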