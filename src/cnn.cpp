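// Small multi-label CNN: n_conv blocks of (3x3 same-padding conv, ReLU,
// 2x2 max-pool) followed by fully connected layers with ReLU between them,
// dropout after the first FC activation and a sigmoid output, trained with
// ADAM on the multi-label mean-squared-error loss sum_i (ys_i - y_i)^2 / N.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

struct Conf {
  int input, n_conv, filters;
  std::vector<int> widths;  // FC output widths, last = n classes
  double dropout, lr;
  int epochs, batch;
  unsigned seed;
};

static Conf as_conf(const List& c) {
  Conf k;
  k.input = c["input_size"]; k.n_conv = c["n_conv"];
  k.filters = c["filters"];
  k.widths = as<std::vector<int>>(c["linear_widths"]);
  k.dropout = c["dropout"]; k.lr = c["lr"];
  k.epochs = c["epochs"]; k.batch = c["batch_size"];
  k.seed = (unsigned)as<int>(c["seed"]);
  return k;
}

struct Net {
  std::vector<mat> convW;  // F x 9*Cin
  std::vector<vec> convb;
  std::vector<mat> fcW;
  std::vector<vec> fcb;
};

static int flat_dim(const Conf& c) {
  int s = c.input;
  for (int i = 0; i < c.n_conv; ++i) s /= 2;  // conv keeps size, pool halves
  return s * s * c.filters;
}

static Net init_net(const Conf& c, std::mt19937& rng) {
  Net n;
  std::normal_distribution<double> N01(0.0, 1.0);
  int cin = 1;
  for (int l = 0; l < c.n_conv; ++l) {
    double sd = std::sqrt(2.0 / (9.0 * cin));
    mat W(c.filters, 9 * cin);
    for (auto& x : W) x = sd * N01(rng);
    n.convW.push_back(W);
    n.convb.push_back(vec(c.filters, arma::fill::zeros));
    cin = c.filters;
  }
  int in = flat_dim(c);
  for (size_t l = 0; l < c.widths.size(); ++l) {
    int out = c.widths[l];
    double sd = std::sqrt(2.0 / in);
    mat W(out, in);
    for (auto& x : W) x = sd * N01(rng);
    n.fcW.push_back(W);
    n.fcb.push_back(vec(out, arma::fill::zeros));
    in = out;
  }
  return n;
}

// im2col for 3x3 same padding: out (9*C) x (H*W)
static mat im2col3(const cube& in) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  mat col(9 * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& s = in.slice(c);
    int r = 0;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++r) {
        const int row = c * 9 + r;
        for (int j = 0; j < W; ++j) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + di;
            if (si < 0 || si >= H) continue;
            col(row, j * H + i) = s(si, sj);
          }
        }
      }
  }
  return col;
}

// adjoint of im2col3: scatter dcol back to the input cube
static cube col2im3(const mat& dcol, int H, int W, int C) {
  cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& s = out.slice(c);
    int r = 0;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++r) {
        const int row = c * 9 + r;
        for (int j = 0; j < W; ++j) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + di;
            if (si < 0 || si >= H) continue;
            s(si, sj) += dcol(row, j * H + i);
          }
        }
      }
  }
  return out;
}

static cube maxpool2(const cube& in, arma::ucube& argmax) {
  const int H = in.n_rows / 2, W = in.n_cols / 2, C = in.n_slices;
  cube out(H, W, C);
  argmax.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -1e300;
        int bi = 0;
        for (int q = 0; q < 4; ++q) {
          int ii = 2 * i + (q & 1), jj = 2 * j + (q >> 1);
          if (in(ii, jj, c) > best) { best = in(ii, jj, c); bi = q; }
        }
        out(i, j, c) = best;
        argmax(i, j, c) = bi;
      }
  return out;
}

static cube maxpool2_back(const cube& dout, const arma::ucube& argmax,
                          int Hin, int Win) {
  const int H = dout.n_rows, W = dout.n_cols, C = dout.n_slices;
  cube din(Hin, Win, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        int q = argmax(i, j, c);
        din(2 * i + (q & 1), 2 * j + (q >> 1), c) += dout(i, j, c);
      }
  return din;
}

struct FwdCache {
  std::vector<mat> cols;        // im2col inputs per conv layer
  std::vector<cube> conv_post;  // post-ReLU conv activations (pre-pool)
  std::vector<arma::ucube> pool_arg;
  std::vector<int> pool_in_side;
  std::vector<vec> fc_in;       // inputs to each FC layer
  std::vector<vec> fc_z;        // pre-activations
  vec drop_mask;                // inverted-dropout mask after FC1 ReLU
  vec scores;                   // sigmoid outputs
};

// forward one sample; dropout mask empty => inference mode
static void forward(const Net& n, const Conf& c, const mat& x,
                    FwdCache& f, const vec& drop_mask) {
  cube cur(x.n_rows, x.n_cols, 1);
  cur.slice(0) = x;
  f.cols.clear(); f.conv_post.clear(); f.pool_arg.clear();
  f.pool_in_side.clear(); f.fc_in.clear(); f.fc_z.clear();
  for (int l = 0; l < c.n_conv; ++l) {
    mat col = im2col3(cur);
    mat z = n.convW[l] * col;
    z.each_col() += n.convb[l];
    // rows = filters, cols = pixels -> cube H x W x F
    cube a(cur.n_rows, cur.n_cols, c.filters);
    for (int ff = 0; ff < c.filters; ++ff)
      a.slice(ff) = arma::reshape(
          arma::clamp(z.row(ff), 0.0, arma::datum::inf), cur.n_rows,
          cur.n_cols);
    f.cols.push_back(std::move(col));
    f.conv_post.push_back(a);
    arma::ucube am;
    f.pool_in_side.push_back(a.n_rows);
    cur = maxpool2(a, am);
    f.pool_arg.push_back(std::move(am));
  }
  vec h = arma::vectorise(cur);
  for (size_t l = 0; l < n.fcW.size(); ++l) {
    f.fc_in.push_back(h);
    vec z = n.fcW[l] * h + n.fcb[l];
    f.fc_z.push_back(z);
    if (l + 1 < n.fcW.size()) {
      h = arma::clamp(z, 0.0, arma::datum::inf);
      if (l == 0 && drop_mask.n_elem) h %= drop_mask;
    } else {
      h = 1.0 / (1.0 + arma::exp(-z));
    }
  }
  f.drop_mask = drop_mask;
  f.scores = h;
}

// backward one sample from dL/dscores; accumulates into grad net
static void backward(const Net& n, const Conf& c, const FwdCache& f,
                     vec dscore, Net& g) {
  const size_t L = n.fcW.size();
  // through sigmoid
  vec d = dscore % f.scores % (1.0 - f.scores);
  for (int l = (int)L - 1; l >= 0; --l) {
    g.fcW[l] += d * f.fc_in[l].t();
    g.fcb[l] += d;
    vec dh = n.fcW[l].t() * d;
    if (l > 0) {
      vec relu_mask = arma::conv_to<vec>::from(f.fc_z[l - 1] > 0);
      if (l - 1 == 0 && f.drop_mask.n_elem) dh %= f.drop_mask;
      d = dh % relu_mask;
    } else {
      // into the flattened conv stack
      int s = f.conv_post.back().n_rows / 2;
      cube dcur(s, s, c.filters);
      std::copy(dh.begin(), dh.end(), dcur.begin());
      for (int lc = c.n_conv - 1; lc >= 0; --lc) {
        int sin = f.pool_in_side[lc];
        cube da = maxpool2_back(dcur, f.pool_arg[lc], sin, sin);
        // ReLU mask
        da %= arma::conv_to<cube>::from(f.conv_post[lc] > 0);
        // dZ as filters x pixels
        mat dz(c.filters, sin * sin);
        for (int ff = 0; ff < c.filters; ++ff)
          dz.row(ff) = arma::vectorise(da.slice(ff)).t();
        g.convW[lc] += dz * f.cols[lc].t();
        g.convb[lc] += arma::sum(dz, 1);
        if (lc > 0) {
          mat dcol = n.convW[lc].t() * dz;
          dcur = col2im3(dcol, sin, sin, c.filters);
        }
      }
    }
  }
}

static void zero_like(const Net& n, Net& g) {
  g = n;
  for (auto& m : g.convW) m.zeros();
  for (auto& m : g.convb) m.zeros();
  for (auto& m : g.fcW) m.zeros();
  for (auto& m : g.fcb) m.zeros();
}

// ADAM state as a flat vector of matrices in fixed order
struct Adam {
  std::vector<mat> mW, vW;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
};

static std::vector<mat*> net_params(Net& n) {
  std::vector<mat*> p;
  for (auto& m : n.convW) p.push_back(&m);
  for (auto& m : n.fcW) p.push_back(&m);
  return p;
}
static std::vector<vec*> net_biases(Net& n) {
  std::vector<vec*> p;
  for (auto& m : n.convb) p.push_back(&m);
  for (auto& m : n.fcb) p.push_back(&m);
  return p;
}

static List net_to_list(const Net& n) {
  List cw(n.convW.size()), cb(n.convb.size()), fw(n.fcW.size()),
      fb(n.fcb.size());
  for (size_t i = 0; i < n.convW.size(); ++i) cw[i] = n.convW[i];
  for (size_t i = 0; i < n.convb.size(); ++i) cb[i] = n.convb[i];
  for (size_t i = 0; i < n.fcW.size(); ++i) fw[i] = n.fcW[i];
  for (size_t i = 0; i < n.fcb.size(); ++i) fb[i] = n.fcb[i];
  return List::create(_["convW"] = cw, _["convb"] = cb, _["fcW"] = fw,
                      _["fcb"] = fb);
}

static Net net_from_list(const List& l) {
  Net n;
  List cw = l["convW"], cb = l["convb"], fw = l["fcW"], fb = l["fcb"];
  for (int i = 0; i < cw.size(); ++i) n.convW.push_back(as<mat>(cw[i]));
  for (int i = 0; i < cb.size(); ++i) n.convb.push_back(as<vec>(cb[i]));
  for (int i = 0; i < fw.size(); ++i) n.fcW.push_back(as<mat>(fw[i]));
  for (int i = 0; i < fb.size(); ++i) n.fcb.push_back(as<vec>(fb[i]));
  return n;
}

static double sample_loss(const vec& scores, const vec& y) {
  return arma::accu(arma::square(scores - y)) / y.n_elem;
}

// mean loss over an index set (inference mode)
static double set_loss(const Net& n, const Conf& c, const cube& X,
                       const mat& Y, const std::vector<int>& idx) {
  FwdCache f;
  vec nomask;
  double s = 0;
  for (int i : idx) {
    forward(n, c, X.slice(i), f, nomask);
    s += sample_loss(f.scores, Y.row(i).t());
  }
  return s / idx.size();
}

// [[Rcpp::export]]
List cnn_train_cpp(const arma::cube& X, const arma::mat& Y,
                   const IntegerVector& train_idx,
                   const IntegerVector& val_idx, const List& conf) {
  Conf c = as_conf(conf);
  std::mt19937 rng(c.seed);
  Net net = init_net(c, rng);
  Net grad; zero_like(net, grad);
  Adam aW, ab;
  for (auto* p : net_params(net)) {
    aW.mW.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
    aW.vW.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
  }
  for (auto* p : net_biases(net)) {
    ab.mW.push_back(mat(p->n_elem, 1, arma::fill::zeros));
    ab.vW.push_back(mat(p->n_elem, 1, arma::fill::zeros));
  }
  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  for (auto& i : tr) --i;  // to 0-based
  for (auto& i : va) --i;
  const int n_out = c.widths.back();
  const double keep = 1.0 - c.dropout;
  std::uniform_real_distribution<double> U(0.0, 1.0);
  NumericVector train_log(c.epochs), val_log(c.epochs);
  double best_val = 1e300;
  int best_epoch = -1;
  Net best = net;
  FwdCache f;
  for (int ep = 0; ep < c.epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double ep_loss = 0;
    for (size_t b0 = 0; b0 < tr.size(); b0 += c.batch) {
      size_t b1 = std::min(b0 + c.batch, tr.size());
      Net g; zero_like(net, g);
      for (size_t k = b0; k < b1; ++k) {
        int i = tr[k];
        vec dm;
        if (keep < 1.0) {
          dm.set_size(c.widths[0]);
          for (auto& x : dm) x = (U(rng) < keep) ? 1.0 / keep : 0.0;
        }
        forward(net, c, X.slice(i), f, dm);
        vec y = Y.row(i).t();
        ep_loss += sample_loss(f.scores, y);
        vec dscore = 2.0 * (f.scores - y) / n_out;
        backward(net, c, f, dscore / (double)(b1 - b0), g);
      }
      // ADAM update
      ++aW.t;
      double bc1 = 1.0 - std::pow(aW.b1, aW.t),
             bc2 = 1.0 - std::pow(aW.b2, aW.t);
      auto pw = net_params(net);
      auto gw = net_params(g);
      for (size_t k = 0; k < pw.size(); ++k) {
        aW.mW[k] = aW.b1 * aW.mW[k] + (1 - aW.b1) * (*gw[k]);
        aW.vW[k] = aW.b2 * aW.vW[k] + (1 - aW.b2) * arma::square(*gw[k]);
        *pw[k] -= c.lr * (aW.mW[k] / bc1) /
                  (arma::sqrt(aW.vW[k] / bc2) + aW.eps);
      }
      auto pb = net_biases(net);
      auto gb = net_biases(g);
      for (size_t k = 0; k < pb.size(); ++k) {
        mat gm(gb[k]->memptr(), gb[k]->n_elem, 1);
        ab.mW[k] = aW.b1 * ab.mW[k] + (1 - aW.b1) * gm;
        ab.vW[k] = aW.b2 * ab.vW[k] + (1 - aW.b2) * arma::square(gm);
        mat upd = c.lr * (ab.mW[k] / bc1) /
                  (arma::sqrt(ab.vW[k] / bc2) + aW.eps);
        *pb[k] -= vec(upd.colptr(0), pb[k]->n_elem);
      }
    }
    train_log[ep] = ep_loss / tr.size();
    val_log[ep] = set_loss(net, c, X, Y, va);
    if (val_log[ep] < best_val) {
      best_val = val_log[ep];
      best_epoch = ep + 1;
      best = net;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = net_to_list(best),
                      _["final_weights"] = net_to_list(net),
                      _["train_loss"] = train_log, _["val_loss"] = val_log,
                      _["best_epoch"] = best_epoch,
                      _["best_val_loss"] = best_val);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const List& weights, const List& conf,
                          const arma::cube& X) {
  Conf c = as_conf(conf);
  Net net = net_from_list(weights);
  mat out(X.n_slices, c.widths.back());
  FwdCache f;
  vec nomask;
  for (size_t i = 0; i < X.n_slices; ++i) {
    forward(net, c, X.slice(i), f, nomask);
    out.row(i) = f.scores.t();
  }
  return out;
}

// activations of the last conv layer (post-ReLU, pre-pool) and the
// gradient of the pre-sigmoid class score w.r.t. them
// [[Rcpp::export]]
List cnn_lastconv_grad_cpp(const List& weights, const List& conf,
                           const arma::mat& x, int class_index) {
  Conf c = as_conf(conf);
  Net net = net_from_list(weights);
  FwdCache f;
  vec nomask;
  forward(net, c, x, f, nomask);
  const size_t L = net.fcW.size();
  // d(logit_class)/d(fc chain input)
  vec d = net.fcW[L - 1].row(class_index).t();
  for (int l = (int)L - 2; l >= 0; --l) {
    vec relu_mask = arma::conv_to<vec>::from(f.fc_z[l] > 0);
    d = net.fcW[l].t() * (d % relu_mask);
  }
  // through the last pooling layer into the last conv activation
  int lc = c.n_conv - 1;
  int s_out = f.conv_post[lc].n_rows / 2;
  cube dcur(s_out, s_out, c.filters);
  std::copy(d.begin(), d.end(), dcur.begin());
  int sin = f.pool_in_side[lc];
  cube dA = maxpool2_back(dcur, f.pool_arg[lc], sin, sin);
  return List::create(_["A"] = f.conv_post[lc], _["dA"] = dA,
                      _["scores"] = f.scores);
}
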