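// Minimal CNN engine: forward/backward for the layer vocabulary
// (conv, relu, cross-channel LRN, maxpool, dropout, fully-connected,
// softmax) and a mini-batch SGD-with-momentum training loop.
// All randomness (shuffling, dropout) is drawn from R's RNG so training is
// reproducible under set.seed() on a single thread.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvSpec { int kernel, stride, pad, filters; };
struct PoolSpec { int size, stride; };
struct LrnSpec  { int window; double alpha, beta, k; };

struct Layer {
  std::string type;
  ConvSpec conv{};
  PoolSpec pool{};
  LrnSpec lrn{};
  double dropout_p = 0.0;
  int fc_units = 0;
  int param_idx = -1;   // index into the weight list for conv/fc layers
};

std::vector<Layer> parse_arch(const List& layers) {
  std::vector<Layer> out;
  int pidx = 0;
  for (int i = 0; i < layers.size(); ++i) {
    List ly = layers[i];
    std::string type = as<std::string>(ly["type"]);
    Layer L; L.type = type;
    if (type == "conv") {
      L.conv = {as<int>(ly["kernel"]), as<int>(ly["stride"]),
                as<int>(ly["pad"]), as<int>(ly["filters"])};
      L.param_idx = pidx++;
    } else if (type == "maxpool") {
      L.pool = {as<int>(ly["size"]), as<int>(ly["stride"])};
    } else if (type == "lrn") {
      L.lrn = {as<int>(ly["window"]), as<double>(ly["alpha"]),
               as<double>(ly["beta"]), as<double>(ly["k"])};
    } else if (type == "dropout") {
      L.dropout_p = as<double>(ly["p"]);
    } else if (type == "fc") {
      L.fc_units = as<int>(ly["units"]);
      L.param_idx = pidx++;
    } else if (type == "input" || type == "relu" || type == "softmax" ||
               type == "output") {
      // no parameters / handled inline
    } else {
      stop("unknown layer type: " + type);
    }
    out.push_back(L);
  }
  return out;
}

// im2col: patches of a (H,W,C) cube as columns, output pixel p = r + Ho*c
arma::mat im2col(const arma::cube& a, const ConvSpec& cs, int Ho, int Wo) {
  const int kh = cs.kernel, kw = cs.kernel, C = a.n_slices;
  arma::mat cols(kh * kw * C, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < Wo; ++c) {
    for (int r = 0; r < Ho; ++r) {
      const int p = r + Ho * c;
      const int r0 = r * cs.stride - cs.pad, c0 = c * cs.stride - cs.pad;
      for (int ch = 0; ch < C; ++ch)
        for (int v = 0; v < kw; ++v) {
          const int cc = c0 + v;
          if (cc < 0 || cc >= (int)a.n_cols) continue;
          for (int u = 0; u < kh; ++u) {
            const int rr = r0 + u;
            if (rr < 0 || rr >= (int)a.n_rows) continue;
            cols(u + kh * (v + kw * ch), p) = a(rr, cc, ch);
          }
        }
    }
  }
  return cols;
}

void col2im_add(arma::cube& grad, const arma::mat& dcols, const ConvSpec& cs,
                int Ho, int Wo) {
  const int kh = cs.kernel, kw = cs.kernel, C = grad.n_slices;
  for (int c = 0; c < Wo; ++c) {
    for (int r = 0; r < Ho; ++r) {
      const int p = r + Ho * c;
      const int r0 = r * cs.stride - cs.pad, c0 = c * cs.stride - cs.pad;
      for (int ch = 0; ch < C; ++ch)
        for (int v = 0; v < kw; ++v) {
          const int cc = c0 + v;
          if (cc < 0 || cc >= (int)grad.n_cols) continue;
          for (int u = 0; u < kh; ++u) {
            const int rr = r0 + u;
            if (rr < 0 || rr >= (int)grad.n_rows) continue;
            grad(rr, cc, ch) += dcols(u + kh * (v + kw * ch), p);
          }
        }
    }
  }
}

inline int out_dim(int in, int kernel, int stride, int pad) {
  return (in + 2 * pad - kernel) / stride + 1;
}

struct Cache {                       // per-layer forward state for backprop
  arma::cube input;                  // input activation
  arma::mat cols;                    // conv: im2col of input
  arma::cube mask;                   // relu/dropout mask
  arma::cube lrn_s;                  // LRN denominator base s
  arma::ucube pool_arg;              // argmax linear index per output pixel
  arma::vec fc_in;                   // flattened fc input
};

class Net {
public:
  std::vector<Layer> layers;
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;

  Net(const List& arch, const List& weights) {
    layers = parse_arch(arch);
    for (int i = 0; i < weights.size(); ++i) {
      List wb = weights[i];
      W.push_back(as<arma::mat>(wb["W"]));
      b.push_back(as<arma::vec>(wb["b"]));
    }
  }

  // forward one image; fills caches when training, returns class probs
  arma::vec forward(const arma::cube& x, std::vector<Cache>& caches,
                    bool training) {
    arma::cube a = x;
    arma::vec logits;
    caches.assign(layers.size(), Cache());
    for (size_t li = 0; li < layers.size(); ++li) {
      const Layer& L = layers[li];
      Cache& K = caches[li];
      if (L.type == "conv") {
        const int Ho = out_dim(a.n_rows, L.conv.kernel, L.conv.stride, L.conv.pad);
        const int Wo = out_dim(a.n_cols, L.conv.kernel, L.conv.stride, L.conv.pad);
        arma::mat cols = im2col(a, L.conv, Ho, Wo);
        arma::mat out = W[L.param_idx].t() * cols;         // F x P
        out.each_col() += b[L.param_idx];
        arma::cube next(Ho, Wo, L.conv.filters);
        for (int f = 0; f < L.conv.filters; ++f)
          next.slice(f) = arma::reshape(out.row(f).t(), Ho, Wo);
        if (training) { K.input = a; K.cols = std::move(cols); }
        a = std::move(next);
      } else if (L.type == "relu") {
        if (training) {
          K.mask = arma::conv_to<arma::cube>::from(a > 0);
          a %= K.mask;
        } else {
          a.transform([](double v) { return v > 0 ? v : 0.0; });
        }
      } else if (L.type == "lrn") {
        const int C = a.n_slices, half = L.lrn.window / 2;
        arma::cube s(a.n_rows, a.n_cols, C);
        arma::cube sq = arma::square(a);
        for (int c = 0; c < C; ++c) {
          arma::mat acc(a.n_rows, a.n_cols, arma::fill::zeros);
          for (int j = std::max(0, c - half); j <= std::min(C - 1, c + half); ++j)
            acc += sq.slice(j);
          s.slice(c) = L.lrn.k + (L.lrn.alpha / L.lrn.window) * acc;
        }
        if (training) { K.input = a; K.lrn_s = s; }
        for (int c = 0; c < C; ++c)
          a.slice(c) %= arma::pow(s.slice(c), -L.lrn.beta);
      } else if (L.type == "maxpool") {
        const int Ho = (a.n_rows - L.pool.size) / L.pool.stride + 1;
        const int Wo = (a.n_cols - L.pool.size) / L.pool.stride + 1;
        arma::cube next(Ho, Wo, a.n_slices);
        arma::ucube argm(Ho, Wo, a.n_slices);
        for (int ch = 0; ch < (int)a.n_slices; ++ch)
          for (int c = 0; c < Wo; ++c)
            for (int r = 0; r < Ho; ++r) {
              double best = -arma::datum::inf; arma::uword bidx = 0;
              for (int v = 0; v < L.pool.size; ++v)
                for (int u = 0; u < L.pool.size; ++u) {
                  const int rr = r * L.pool.stride + u;
                  const int cc = c * L.pool.stride + v;
                  const double val = a(rr, cc, ch);
                  if (val > best) { best = val; bidx = rr + a.n_rows * cc; }
                }
              next(r, c, ch) = best;
              argm(r, c, ch) = bidx;
            }
        if (training) { K.input = a; K.pool_arg = std::move(argm); }
        a = std::move(next);
      } else if (L.type == "dropout") {
        if (training && L.dropout_p > 0) {
          arma::cube m(a.n_rows, a.n_cols, a.n_slices);
          const double keep = 1.0 - L.dropout_p;
          for (arma::uword i = 0; i < m.n_elem; ++i)
            m(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
          K.mask = m;
          a %= m;
        }
      } else if (L.type == "fc") {
        arma::vec in = arma::vectorise(a);
        if (training) { K.input = a; K.fc_in = in; }
        logits = W[L.param_idx].t() * in + b[L.param_idx];
      } else if (L.type == "softmax") {
        logits -= logits.max();
        logits = arma::exp(logits);
        logits /= arma::accu(logits);
      }
      // "input"/"output" carry no computation
    }
    return logits;  // class probabilities after softmax
  }

  // backward one image given probs and true class; accumulates gradients
  void backward(const arma::vec& probs, int y, std::vector<Cache>& caches,
                std::vector<arma::mat>& gW, std::vector<arma::vec>& gb) {
    arma::vec dlogits = probs;
    dlogits(y) -= 1.0;                       // d loss / d logits (CE + softmax)
    arma::cube da;
    bool have_cube = false;
    for (int li = (int)layers.size() - 1; li >= 0; --li) {
      const Layer& L = layers[li];
      Cache& K = caches[li];
      if (L.type == "fc") {
        gW[L.param_idx] += K.fc_in * dlogits.t();
        gb[L.param_idx] += dlogits;
        arma::vec din = W[L.param_idx] * dlogits;
        da = arma::cube(const_cast<double*>(din.memptr()), K.input.n_rows,
                        K.input.n_cols, K.input.n_slices, true);
        have_cube = true;
      } else if (L.type == "dropout") {
        if (have_cube && K.mask.n_elem) da %= K.mask;
      } else if (L.type == "maxpool") {
        arma::cube din(K.input.n_rows, K.input.n_cols, K.input.n_slices,
                       arma::fill::zeros);
        for (int ch = 0; ch < (int)da.n_slices; ++ch)
          for (arma::uword c = 0; c < da.n_cols; ++c)
            for (arma::uword r = 0; r < da.n_rows; ++r) {
              const arma::uword idx = K.pool_arg(r, c, ch);
              din(idx % K.input.n_rows, idx / K.input.n_rows, ch) +=
                da(r, c, ch);
            }
        da = std::move(din);
      } else if (L.type == "lrn") {
        const int C = K.input.n_slices, half = L.lrn.window / 2;
        const double coef = 2.0 * L.lrn.beta * L.lrn.alpha / L.lrn.window;
        arma::cube din(arma::size(K.input), arma::fill::zeros);
        // b_c = a_c s_c^-beta; da_i = sum_c dL/db_c *
        //   [ 1(i==c) s_c^-beta - coef a_c a_i s_c^(-beta-1) 1(i in win(c)) ]
        arma::cube sb(arma::size(K.input));
        arma::cube sb1(arma::size(K.input));
        for (int c = 0; c < C; ++c) {
          sb.slice(c) = arma::pow(K.lrn_s.slice(c), -L.lrn.beta);
          sb1.slice(c) = arma::pow(K.lrn_s.slice(c), -L.lrn.beta - 1.0);
        }
        for (int c = 0; c < C; ++c) {
          din.slice(c) += da.slice(c) % sb.slice(c);
          arma::mat common = da.slice(c) % K.input.slice(c) % sb1.slice(c);
          for (int i = std::max(0, c - half); i <= std::min(C - 1, c + half); ++i)
            din.slice(i) -= coef * common % K.input.slice(i);
        }
        da = std::move(din);
      } else if (L.type == "relu") {
        if (have_cube && K.mask.n_elem) da %= K.mask;
      } else if (L.type == "conv") {
        const int Ho = da.n_rows, Wo = da.n_cols, F = L.conv.filters;
        arma::mat dout(F, Ho * Wo);
        for (int f = 0; f < F; ++f)
          dout.row(f) = arma::vectorise(da.slice(f)).t();
        gW[L.param_idx] += K.cols * dout.t();
        gb[L.param_idx] += arma::sum(dout, 1);
        arma::mat dcols = W[L.param_idx] * dout;
        arma::cube din(arma::size(K.input), arma::fill::zeros);
        col2im_add(din, dcols, L.conv, Ho, Wo);
        da = std::move(din);
      }
    }
  }
};

arma::cube slice_image(const NumericVector& images, int H, int Wd, int C,
                       int n, const arma::cube& mean_img) {
  const double* p = REAL(images) + (size_t)n * H * Wd * C;
  arma::cube x(const_cast<double*>(p), H, Wd, C, /*copy*/ true);
  if (mean_img.n_elem == x.n_elem) x -= mean_img;   // zero-center input
  return x;
}

arma::cube as_mean_cube(const NumericVector& mean_img, int H, int Wd, int C) {
  if (mean_img.size() == 0) return arma::cube();
  if ((int)mean_img.size() != H * Wd * C)
    stop("mean image has the wrong size");
  return arma::cube(const_cast<double*>(REAL(mean_img)), H, Wd, C, true);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(NumericVector images, List arch, List weights,
                              NumericVector mean_img) {
  IntegerVector dims = images.attr("dim");
  if (dims.size() != 4) stop("images must be a 4-d array (H, W, C, N)");
  const int H = dims[0], Wd = dims[1], C = dims[2], N = dims[3];
  Net net(arch, weights);
  arma::cube mu = as_mean_cube(mean_img, H, Wd, C);
  NumericMatrix probs(N, 2);
  std::vector<Cache> caches;
  for (int n = 0; n < N; ++n) {
    arma::cube x = slice_image(images, H, Wd, C, n, mu);
    arma::vec p = net.forward(x, caches, false);
    probs(n, 0) = p(0); probs(n, 1) = p(1);
  }
  return probs;
}

// [[Rcpp::export]]
List cnn_train_cpp(NumericVector images, IntegerVector labels, List arch,
                   List weights, NumericVector mean_img, int epochs,
                   double lr, double momentum, int batch_size) {
  IntegerVector dims = images.attr("dim");
  if (dims.size() != 4) stop("images must be a 4-d array (H, W, C, N)");
  const int H = dims[0], Wd = dims[1], C = dims[2], N = dims[3];
  if (labels.size() != N) stop("one label per image required");
  Net net(arch, weights);
  arma::cube mu = as_mean_cube(mean_img, H, Wd, C);
  const int P = net.W.size();
  std::vector<arma::mat> vW(P), gW(P);
  std::vector<arma::vec> vb(P), gb(P);
  for (int i = 0; i < P; ++i) {
    vW[i].zeros(arma::size(net.W[i]));
    vb[i].zeros(arma::size(net.b[i]));
  }
  NumericVector ep_loss(epochs), ep_acc(epochs);
  std::vector<Cache> caches;
  for (int e = 0; e < epochs; ++e) {
    IntegerVector perm = sample(N, N, false) - 1;
    double loss_sum = 0.0; int correct = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int end = std::min(start + batch_size, N);
      const int bs = end - start;
      for (int i = 0; i < P; ++i) {
        gW[i].zeros(arma::size(net.W[i]));
        gb[i].zeros(arma::size(net.b[i]));
      }
      for (int k = start; k < end; ++k) {
        const int n = perm[k];
        arma::cube x = slice_image(images, H, Wd, C, n, mu);
        arma::vec probs = net.forward(x, caches, true);
        const int y = labels[n];
        loss_sum += -std::log(std::max(probs(y), 1e-12));
        if ((probs(1) > probs(0) ? 1 : 0) == y) ++correct;
        net.backward(probs, y, caches, gW, gb);
      }
      for (int i = 0; i < P; ++i) {
        vW[i] = momentum * vW[i] - lr * gW[i] / bs;
        vb[i] = momentum * vb[i] - lr * gb[i] / bs;
        net.W[i] += vW[i];
        net.b[i] += vb[i];
      }
    }
    ep_loss[e] = loss_sum / N;
    ep_acc[e] = (double)correct / N;
    if (!std::isfinite(ep_loss[e]))
      stop("training diverged: non-finite loss at epoch %d", e + 1);
    Rcpp::checkUserInterrupt();
  }
  List out_w(P);
  for (int i = 0; i < P; ++i)
    out_w[i] = List::create(_["W"] = net.W[i], _["b"] = net.b[i]);
  return List::create(_["weights"] = out_w, _["loss"] = ep_loss,
                      _["accuracy"] = ep_acc);
}
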