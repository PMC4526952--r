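// Inner training loops for the RBM pretraining and back-propagation
// fine-tuning. These mirror the R reference implementations
// (rbm_cd_update, dbn_gradients) batch for batch, but update parameters in
// place so that mini-batch SGD with small batches does not allocate
// parameter-sized temporaries per step. All randomness comes from R's RNG
// stream, so seed determinism is inherited from the caller.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

static inline void bernoulli_sample(arma::mat& out, const arma::mat& p) {
  out.set_size(arma::size(p));
  for (arma::uword i = 0; i < p.n_elem; ++i) {
    out(i) = (unif_rand() < p(i)) ? 1.0 : 0.0;
  }
}

// One epoch of mini-batch CD-k over X in the order given by perm (1-based).
// Returns updated parameters and the mean reconstruction error per batch.
// [[Rcpp::export]]
List cpp_rbm_epoch(arma::mat W, arma::rowvec b, arma::rowvec c,
                   const arma::mat& X, const arma::uvec& perm,
                   double lr, int batch_size, int k) {
  const int n = X.n_rows;
  double err_sum = 0.0;
  int n_batches = 0;
  arma::mat h, pv, ph;
  for (int s = 0; s < n; s += batch_size) {
    const int e = std::min(s + batch_size, n) - 1;
    const arma::uvec idx = perm.subvec(s, e) - 1;
    const arma::mat V = X.rows(idx);
    const double m = static_cast<double>(V.n_rows);
    arma::mat ph0 = sigm((V * W).eval().each_row() + c);
    bernoulli_sample(h, ph0);
    for (int step = 0; step < k; ++step) {
      pv = sigm((h * W.t()).eval().each_row() + b);
      ph = sigm((pv * W).eval().each_row() + c);
      if (step < k - 1) bernoulli_sample(h, ph);
    }
    W += (lr / m) * (V.t() * ph0 - pv.t() * ph);
    b += (lr / m) * arma::sum(V - pv, 0);
    c += (lr / m) * arma::sum(ph0 - ph, 0);
    err_sum += arma::accu(arma::square(V - pv)) / V.n_elem;
    ++n_batches;
  }
  return List::create(_["W"] = W, _["b"] = b, _["c"] = c,
                      _["recon_error"] = err_sum / n_batches);
}

// `epochs` passes of mini-batch SGD on the cross-entropy of the softmax
// output, with inverted dropout on the hidden layers. perms is an n x epochs
// matrix of 1-based permutations (drawn by the caller from R's RNG).
// [[Rcpp::export]]
List cpp_finetune(List W_in, List b_in, const arma::mat& X, const arma::mat& Y,
                  const arma::umat& perms, double lr, int batch_size,
                  double dropout) {
  const int L = W_in.size();
  std::vector<arma::mat> W(L);
  std::vector<arma::rowvec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W_in[l]);
    b[l] = as<arma::rowvec>(b_in[l]);
  }
  const int n = X.n_rows;
  const int epochs = perms.n_cols;
  const double keep = 1.0 - dropout;
  std::vector<arma::mat> A(L + 1), M(L > 1 ? L - 1 : 0);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n; s += batch_size) {
      const int e = std::min(s + batch_size, n) - 1;
      const arma::uvec idx = perms.submat(s, ep, e, ep) - 1;
      const double m = static_cast<double>(idx.n_elem);
      A[0] = X.rows(idx);
      for (int l = 0; l < L - 1; ++l) {
        arma::mat act = sigm((A[l] * W[l]).eval().each_row() + b[l]);
        if (dropout > 0) {
          M[l].set_size(arma::size(act));
          for (arma::uword i = 0; i < act.n_elem; ++i) {
            M[l](i) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
          }
          act %= M[l];
        }
        A[l + 1] = act;
      }
      arma::mat Z = (A[L - 1] * W[L - 1]).eval().each_row() + b[L - 1];
      Z.each_col() -= arma::max(Z, 1);
      arma::mat P = arma::exp(Z);
      P.each_col() /= arma::sum(P, 1);
      arma::mat delta = (P - Y.rows(idx)) / m;
      for (int l = L - 1; l >= 0; --l) {
        const arma::mat gW = A[l].t() * delta;
        const arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          arma::mat dA = delta * W[l].t();
          if (dropout > 0) dA %= M[l - 1];
          delta = dA % A[l] % (1.0 - A[l]);
        }
        W[l] -= lr * gW;
        b[l] -= lr * gb;
      }
    }
  }
  List W_out(L), b_out(L);
  for (int l = 0; l < L; ++l) {
    W_out[l] = W[l];
    b_out[l] = b[l];
  }
  return List::create(_["W"] = W_out, _["b"] = b_out);
}
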