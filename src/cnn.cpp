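// Forward and backward passes, SGD step and prediction for the counting
// network. The plan (a flat list compiled in R from the NetworkSpec) is a
// sequence of layers over activations stored as arma::mat with dimensions
// (channels, pixels * batch): each image occupies a contiguous block of
// `side*side` columns in column-major pixel order, matching R's matrix
// layout. Convolutions are im2col + BLAS gemm; max pooling and the
// cross-channel local response normalization are written out directly.
// Fully connected layers see the flattened activation, which in this
// layout is a plain column-major reshape (no data movement semantics to
// track between R and C++).
//
// Everything is double precision and single threaded: a step is a pure
// function of (plan, params, batch, seed), which is what makes training
// runs reproducible.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct Layer {
  int kind = 0;                 // 1 lrn, 2 max_pool, 3 conv, 4 fc, 5 output
  int k = 0, stride = 1, pad = 0;
  int in_side = 0, in_ch = 0, out_side = 0, out_ch = 0, in_nodes = 0;
  int param = 0;                // 1-based index into the parameter list
  bool dropout = false;
  std::string label;
};

struct Plan {
  std::vector<Layer> layers;
  int lrn_radius = 2;
  double lrn_alpha = 1e-4, lrn_beta = 0.75, lrn_bias = 1.0;
};

Plan parsePlan(const List& plan) {
  Plan P;
  P.lrn_radius = as<int>(plan["lrn_radius"]);
  P.lrn_alpha = as<double>(plan["lrn_alpha"]);
  P.lrn_beta = as<double>(plan["lrn_beta"]);
  P.lrn_bias = as<double>(plan["lrn_bias"]);
  List ls = plan["layers"];
  for (int i = 0; i < ls.size(); ++i) {
    List e = ls[i];
    Layer L;
    L.label = as<std::string>(e["label"]);
    L.kind = as<int>(e["kind"]);
    L.out_ch = as<int>(e["out_ch"]);
    L.out_side = as<int>(e["out_side"]);
    if (e.containsElementNamed("k")) L.k = as<int>(e["k"]);
    if (e.containsElementNamed("stride")) L.stride = as<int>(e["stride"]);
    if (e.containsElementNamed("pad")) L.pad = as<int>(e["pad"]);
    if (e.containsElementNamed("in_side")) L.in_side = as<int>(e["in_side"]);
    if (e.containsElementNamed("in_ch")) L.in_ch = as<int>(e["in_ch"]);
    if (e.containsElementNamed("in_nodes"))
      L.in_nodes = as<int>(e["in_nodes"]);
    if (e.containsElementNamed("param")) L.param = as<int>(e["param"]);
    if (e.containsElementNamed("dropout"))
      L.dropout = as<bool>(e["dropout"]);
    P.layers.push_back(L);
  }
  return P;
}

struct Cache {
  mat out;        // post-activation output
  arma::umat idx; // pool: source column index per (channel, out column)
  mat denom;      // lrn: normalization denominator
  mat mask;       // fc: dropout mask
  mat relu_pre;   // fc: pre-dropout rectified output
};

// gather the k x k receptive fields of one image's output pixels into the
// columns of COL (reused across the batch to keep the working set small)
void im2colImage(const mat& A, int b, const Layer& L, mat& COL) {
  const int ih = L.in_side, ihw = ih * ih, oh = L.out_side;
  const int Cin = L.in_ch, k = L.k, stride = L.stride, pad = L.pad;
  const uword abase = static_cast<uword>(b) * ihw;
  for (int ox = 0; ox < oh; ++ox) {
    for (int oy = 0; oy < oh; ++oy) {
      double* dst = COL.colptr(static_cast<uword>(ox) * oh + oy);
      int r = 0;
      for (int kx = 0; kx < k; ++kx) {
        const int ix = ox * stride - pad + kx;
        for (int ky = 0; ky < k; ++ky) {
          const int iy = oy * stride - pad + ky;
          if (ix >= 0 && ix < ih && iy >= 0 && iy < ih) {
            const double* src =
              A.colptr(abase + static_cast<uword>(ix) * ih + iy);
            std::copy(src, src + Cin, dst + r);
          } else {
            std::fill(dst + r, dst + r + Cin, 0.0);
          }
          r += Cin;
        }
      }
    }
  }
}

// scatter-add one image's column gradients back: the adjoint of im2colImage
void col2imImage(const mat& dCOL, int b, const Layer& L, mat& dA) {
  const int ih = L.in_side, ihw = ih * ih, oh = L.out_side;
  const int Cin = L.in_ch, k = L.k, stride = L.stride, pad = L.pad;
  const uword abase = static_cast<uword>(b) * ihw;
  for (int ox = 0; ox < oh; ++ox) {
    for (int oy = 0; oy < oh; ++oy) {
      const double* src = dCOL.colptr(static_cast<uword>(ox) * oh + oy);
      int r = 0;
      for (int kx = 0; kx < k; ++kx) {
        const int ix = ox * stride - pad + kx;
        for (int ky = 0; ky < k; ++ky) {
          const int iy = oy * stride - pad + ky;
          if (ix >= 0 && ix < ih && iy >= 0 && iy < ih) {
            double* dst =
              dA.colptr(abase + static_cast<uword>(ix) * ih + iy);
            for (int c = 0; c < Cin; ++c) dst[c] += src[r + c];
          }
          r += Cin;
        }
      }
    }
  }
}

// sliding cross-channel window sum over the rows of M (radius r)
mat windowSumRows(const mat& M, int r) {
  const int C = M.n_rows;
  mat CS = arma::cumsum(M, 0);
  mat S(M.n_rows, M.n_cols);
  for (int c = 0; c < C; ++c) {
    const int hi = std::min(c + r, C - 1);
    const int lo = c - r - 1;
    if (lo >= 0) S.row(c) = CS.row(hi) - CS.row(lo);
    else S.row(c) = CS.row(hi);
  }
  return S;
}

class Net {
public:
  Plan P;
  std::vector<mat> W;
  std::vector<vec> b;
  std::vector<Cache> cache;

  Net(const List& plan, const List& params) : P(parsePlan(plan)) {
    for (int i = 0; i < params.size(); ++i) {
      List p = params[i];
      W.push_back(as<mat>(p["W"]));
      b.push_back(as<vec>(p["b"]));
    }
    for (auto& L : P.layers)
      if (L.param > static_cast<int>(W.size()))
        stop("layer '%s' refers to parameter set %d but only %d were given",
             L.label, L.param, static_cast<int>(W.size()));
  }

  // forward pass; returns class probabilities (4 x B)
  mat forward(const mat& A0, int B, bool training, double dropout,
              std::mt19937& gen) {
    cache.assign(P.layers.size(), Cache());
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    const mat* A = &A0;
    mat probs;
    for (size_t i = 0; i < P.layers.size(); ++i) {
      const Layer& L = P.layers[i];
      Cache& C = cache[i];
      if (L.kind == 1) {                       // local response normalization
        mat S = windowSumRows(*A % *A, P.lrn_radius);
        C.denom = P.lrn_bias + P.lrn_alpha * S;
        C.out = *A % arma::pow(C.denom, -P.lrn_beta);
      } else if (L.kind == 2) {                // max pool (2x2, ceil padding)
        const int ih = L.in_side, ihw = ih * ih;
        const int oh = L.out_side, ohw = oh * oh;
        const int Cn = L.out_ch;
        C.out.set_size(Cn, static_cast<uword>(ohw) * B);
        C.idx.set_size(Cn, static_cast<uword>(ohw) * B);
        for (int bb = 0; bb < B; ++bb) {
          const uword abase = static_cast<uword>(bb) * ihw;
          const uword obase = static_cast<uword>(bb) * ohw;
          for (int ox = 0; ox < oh; ++ox) {
            for (int oy = 0; oy < oh; ++oy) {
              const uword ocol = obase + static_cast<uword>(ox) * oh + oy;
              bool first = true;
              for (int kx = 0; kx < L.k; ++kx) {
                const int ix = ox * L.stride - L.pad + kx;
                if (ix < 0 || ix >= ih) continue;
                for (int ky = 0; ky < L.k; ++ky) {
                  const int iy = oy * L.stride - L.pad + ky;
                  if (iy < 0 || iy >= ih) continue;
                  const uword acol = abase + static_cast<uword>(ix) * ih + iy;
                  if (first) {
                    C.out.col(ocol) = A->col(acol);
                    C.idx.col(ocol).fill(acol);
                    first = false;
                  } else {
                    for (int c = 0; c < Cn; ++c) {
                      const double v = (*A)(c, acol);
                      if (v > C.out(c, ocol)) {
                        C.out(c, ocol) = v;
                        C.idx(c, ocol) = acol;
                      }
                    }
                  }
                }
              }
            }
          }
        }
      } else if (L.kind == 3) {                // convolution + ReLU
        const int ohw = L.out_side * L.out_side;
        mat COL(static_cast<uword>(L.k) * L.k * L.in_ch, ohw);
        C.out.set_size(L.out_ch, static_cast<uword>(ohw) * B);
        for (int bb = 0; bb < B; ++bb) {
          im2colImage(*A, bb, L, COL);
          C.out.cols(static_cast<uword>(bb) * ohw,
                     static_cast<uword>(bb + 1) * ohw - 1) =
            W[L.param - 1] * COL;
        }
        C.out.each_col() += b[L.param - 1];
        C.out.transform([](double v) { return v > 0.0 ? v : 0.0; });
      } else {                                 // fully connected / output
        // flatten: (ch, hw*B) -> (ch*hw, B) is a column-major reshape
        mat X = arma::reshape(*A, A->n_elem / B, B);
        mat Z = W[L.param - 1] * X;
        Z.each_col() += b[L.param - 1];
        if (L.kind == 4) {
          Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
          C.relu_pre = Z;
          if (training && L.dropout && dropout > 0.0) {
            C.mask.set_size(Z.n_rows, Z.n_cols);
            const double keep = 1.0 - dropout;
            for (uword j = 0; j < Z.n_elem; ++j)
              C.mask(j) = unif(gen) < keep ? 1.0 / keep : 0.0;
            Z %= C.mask;
          }
          C.out = std::move(Z);
        } else {                               // softmax output
          Z.each_row() -= arma::max(Z, 0);
          Z = arma::exp(Z);
          Z.each_row() /= arma::sum(Z, 0);
          C.out = Z;
          probs = C.out;
        }
      }
      A = &C.out;
    }
    return probs;
  }

  // backward pass from class targets; fills dW/db (averaged over batch)
  void backward(const mat& A0, int B, const arma::ivec& y,
                std::vector<mat>& dW, std::vector<vec>& db) {
    dW.assign(W.size(), mat());
    db.assign(b.size(), vec());
    const int n = P.layers.size();
    mat dA;                                    // gradient wrt layer output
    for (int i = n - 1; i >= 0; --i) {
      const Layer& L = P.layers[i];
      Cache& C = cache[i];
      const mat& Ain = (i == 0) ? A0 : cache[i - 1].out;
      if (L.kind == 5) {
        mat dZ = C.out;                        // probs
        for (int bb = 0; bb < B; ++bb) dZ(y[bb] - 1, bb) -= 1.0;
        dZ /= static_cast<double>(B);
        mat X = arma::reshape(Ain, Ain.n_elem / B, B);
        dW[L.param - 1] = dZ * X.t();
        db[L.param - 1] = arma::sum(dZ, 1);
        dA = arma::reshape(W[L.param - 1].t() * dZ, Ain.n_rows, Ain.n_cols);
      } else if (L.kind == 4) {
        mat dZ = dA;
        if (C.mask.n_elem > 0) dZ %= C.mask;
        dZ %= arma::conv_to<mat>::from(C.relu_pre > 0.0);
        mat X = arma::reshape(Ain, Ain.n_elem / B, B);
        dW[L.param - 1] = dZ * X.t();
        db[L.param - 1] = arma::sum(dZ, 1);
        dA = arma::reshape(W[L.param - 1].t() * dZ, Ain.n_rows, Ain.n_cols);
      } else if (L.kind == 3) {
        mat dZ = dA % arma::conv_to<mat>::from(C.out > 0.0);
        const int ohw = L.out_side * L.out_side;
        mat COL(static_cast<uword>(L.k) * L.k * L.in_ch, ohw);
        mat dAin(Ain.n_rows, Ain.n_cols, arma::fill::zeros);
        mat& dWl = dW[L.param - 1];
        dWl.zeros(W[L.param - 1].n_rows, W[L.param - 1].n_cols);
        db[L.param - 1] = arma::sum(dZ, 1);
        for (int bb = 0; bb < B; ++bb) {
          im2colImage(Ain, bb, L, COL);
          mat dZb = dZ.cols(static_cast<uword>(bb) * ohw,
                            static_cast<uword>(bb + 1) * ohw - 1);
          dWl += dZb * COL.t();
          mat dCOL = W[L.param - 1].t() * dZb;
          col2imImage(dCOL, bb, L, dAin);
        }
        dA = std::move(dAin);
      } else if (L.kind == 2) {
        mat dAin(Ain.n_rows, Ain.n_cols, arma::fill::zeros);
        for (uword j = 0; j < dA.n_cols; ++j)
          for (uword c = 0; c < dA.n_rows; ++c)
            dAin(c, C.idx(c, j)) += dA(c, j);
        dA = std::move(dAin);
      } else {                                 // lrn
        mat t = dA % Ain % arma::pow(C.denom, -P.lrn_beta - 1.0);
        mat T = windowSumRows(t, P.lrn_radius);
        dA = dA % arma::pow(C.denom, -P.lrn_beta) -
          2.0 * P.lrn_alpha * P.lrn_beta * (Ain % T);
      }
    }
  }
};

mat inputActivation(const NumericVector& x, int& B) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3) stop("input must be an (h, w, batch) array");
  const int h = dim[0], w = dim[1];
  if (h != w) stop("input images must be square");
  B = dim[2];
  // one channel: (1, h*w*B) row over pixels in column-major order
  return mat(const_cast<double*>(x.begin()), 1,
             static_cast<uword>(h) * w * B, true);
}

List paramsOut(const Net& net) {
  List out(net.W.size());
  for (size_t i = 0; i < net.W.size(); ++i)
    out[i] = List::create(Named("W") = wrap(net.W[i]),
                          Named("b") = wrap(net.b[i]));
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cnnForward")]]
List cnnForward(List plan, List params, NumericVector x,
                bool training = false, double dropout = 0.0, int seed = 0,
                bool shapes = false) {
  int B = 0;
  mat A0 = inputActivation(x, B);
  Net net(plan, params);
  std::mt19937 gen(static_cast<unsigned>(seed));
  mat probs = net.forward(A0, B, training, dropout, gen);
  List out = List::create(Named("probs") = wrap(mat(probs.t())));
  if (shapes) {
    List sh(net.P.layers.size());
    CharacterVector nm(net.P.layers.size());
    for (size_t i = 0; i < net.P.layers.size(); ++i) {
      const Layer& L = net.P.layers[i];
      nm[i] = L.label;
      sh[i] = IntegerVector::create(
        Named("channels") = static_cast<int>(net.cache[i].out.n_rows),
        Named("pixels") = static_cast<int>(net.cache[i].out.n_cols / B),
        Named("side") = L.out_side);
    }
    sh.attr("names") = nm;
    out["shapes"] = sh;
  }
  return out;
}

// [[Rcpp::export(name = ".cnnTrainStep")]]
List cnnTrainStep(List plan, List params, NumericVector x, IntegerVector y,
                  double lr, double dropout, int seed) {
  int B = 0;
  mat A0 = inputActivation(x, B);
  if (y.size() != B) stop("labels and batch size disagree");
  Net net(plan, params);
  std::mt19937 gen(static_cast<unsigned>(seed));
  mat probs = net.forward(A0, B, true, dropout, gen);
  double loss = 0.0;
  int correct = 0;
  arma::ivec yy(B);
  for (int bb = 0; bb < B; ++bb) {
    yy[bb] = y[bb];
    loss -= std::log(std::max(probs(y[bb] - 1, bb), 1e-12));
    if (probs.col(bb).index_max() == static_cast<uword>(y[bb] - 1))
      ++correct;
  }
  loss /= B;
  if (!std::isfinite(loss))
    stop("non-finite training loss: the learning rate is likely too high");
  std::vector<mat> dW;
  std::vector<vec> db;
  net.backward(A0, B, yy, dW, db);
  for (size_t i = 0; i < net.W.size(); ++i) {
    net.W[i] -= lr * dW[i];
    net.b[i] -= lr * db[i];
  }
  return List::create(Named("params") = paramsOut(net),
                      Named("loss") = loss,
                      Named("accuracy") = static_cast<double>(correct) / B);
}
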