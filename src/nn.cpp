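// Minimal convolutional-network engine for the dual-path pixel classifier.
//
// The graph is compiled in R to a flat, topologically ordered node list
// (input / conv / bn / relu / pool / up / concat).  Activations are stored
// per node as (H*W x C x batch) single-precision cubes; convolutions run
// as im2col + GEMM.  Buffers persist across minibatches, batch-norm and
// ReLU inner loops are written to vectorize, and no gradient is propagated
// into the input node.  Training uses Adam on softmax cross-entropy with
// per-class weights.  All randomness (weight init, shuffling) comes from a
// std::mt19937 seeded explicitly, so runs are reproducible on one machine.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
using namespace Rcpp;

enum NodeType { N_INPUT = 0, N_CONV = 1, N_BN = 2, N_RELU = 3,
                N_POOL = 4, N_UP = 5, N_CONCAT = 6 };

struct Node {
  int type;
  std::vector<int> in;  // 0-based ids of input nodes
  int k = 0;            // conv kernel size (odd)
  int cout = 0;         // conv output channels
  int cin = 0;
  int C = 0;            // output channels
  int H = 0, W = 0;     // output spatial dims for the current input size
};

static int type_code(const std::string& s) {
  if (s == "input") return N_INPUT;
  if (s == "conv") return N_CONV;
  if (s == "bn") return N_BN;
  if (s == "relu") return N_RELU;
  if (s == "pool") return N_POOL;
  if (s == "up") return N_UP;
  if (s == "concat") return N_CONCAT;
  stop("unknown node type: %s", s.c_str());
  return -1;
}

static std::vector<Node> parse_nodes(const List& nodes_r, int C0) {
  int n = nodes_r.size();
  std::vector<Node> nodes(n);
  for (int i = 0; i < n; ++i) {
    List nd = nodes_r[i];
    Node& v = nodes[i];
    v.type = type_code(as<std::string>(nd["type"]));
    if (nd.containsElementNamed("in") && !Rf_isNull(nd["in"])) {
      IntegerVector iv = nd["in"];
      for (int j = 0; j < iv.size(); ++j) {
        int id = iv[j] - 1;
        if (id < 0 || id >= i) stop("node %d: input id out of order", i + 1);
        v.in.push_back(id);
      }
    }
    if (v.type == N_CONV) {
      v.k = as<int>(nd["k"]);
      v.cout = as<int>(nd["cout"]);
      if (v.k < 1 || v.k % 2 == 0) stop("conv kernel must be odd and >= 1");
    }
  }
  for (int i = 0; i < n; ++i) {  // infer channels
    Node& v = nodes[i];
    switch (v.type) {
    case N_INPUT: v.C = C0; break;
    case N_CONV: v.cin = nodes[v.in[0]].C; v.C = v.cout; break;
    case N_CONCAT: {
      int c = 0;
      for (int id : v.in) c += nodes[id].C;
      v.C = c; break;
    }
    default: v.C = nodes[v.in[0]].C;
    }
  }
  return nodes;
}

static void set_dims(std::vector<Node>& nodes, int H0, int W0) {
  for (size_t i = 0; i < nodes.size(); ++i) {
    Node& v = nodes[i];
    switch (v.type) {
    case N_INPUT: v.H = H0; v.W = W0; break;
    case N_POOL:
      v.H = nodes[v.in[0]].H; v.W = nodes[v.in[0]].W;
      if (v.H % 2 || v.W % 2) stop("pooling needs even spatial dims");
      v.H /= 2; v.W /= 2; break;
    case N_UP:
      v.H = 2 * nodes[v.in[0]].H; v.W = 2 * nodes[v.in[0]].W; break;
    case N_CONCAT: {
      v.H = nodes[v.in[0]].H; v.W = nodes[v.in[0]].W;
      for (int id : v.in)
        if (nodes[id].H != v.H || nodes[id].W != v.W)
          stop("concat inputs have mismatched spatial dims");
      break;
    }
    default: v.H = nodes[v.in[0]].H; v.W = nodes[v.in[0]].W;
    }
  }
}

// ---- weights ---------------------------------------------------------------

struct Weights {
  std::vector<arma::fmat> W;                  // conv: (k*k*cin x cout)
  std::vector<arma::fvec> b, gamma, beta, rmean, rvar;
  void resize(int n) {
    W.resize(n); b.resize(n); gamma.resize(n); beta.resize(n);
    rmean.resize(n); rvar.resize(n);
  }
};

static Weights load_weights(const std::vector<Node>& nodes, const List& wr) {
  Weights w; w.resize(nodes.size());
  auto tofv = [](const NumericVector& v) {
    arma::fvec r(v.size());
    for (int i = 0; i < v.size(); ++i) r[i] = (float)v[i];
    return r;
  };
  for (size_t i = 0; i < nodes.size(); ++i) {
    if (nodes[i].type == N_CONV) {
      List li = wr[i];
      NumericMatrix Wm = li["W"];
      int kk = nodes[i].k * nodes[i].k * nodes[i].cin;
      if (Wm.nrow() != kk || Wm.ncol() != nodes[i].cout)
        stop("conv weight dims mismatch at node %d", (int)i + 1);
      w.W[i].set_size(kk, nodes[i].cout);
      for (int j = 0; j < Wm.length(); ++j) w.W[i][j] = (float)Wm[j];
      w.b[i] = tofv(li["b"]);
    } else if (nodes[i].type == N_BN) {
      List li = wr[i];
      w.gamma[i] = tofv(li["gamma"]); w.beta[i] = tofv(li["beta"]);
      w.rmean[i] = tofv(li["rmean"]); w.rvar[i] = tofv(li["rvar"]);
    }
  }
  return w;
}

static List export_weights(const std::vector<Node>& nodes, const Weights& w) {
  List out(nodes.size());
  auto vec = [](const arma::fvec& v) {
    NumericVector r(v.n_elem);
    std::copy(v.begin(), v.end(), r.begin());
    return r;
  };
  for (size_t i = 0; i < nodes.size(); ++i) {
    if (nodes[i].type == N_CONV) {
      NumericMatrix Wm(w.W[i].n_rows, w.W[i].n_cols);
      std::copy(w.W[i].begin(), w.W[i].end(), Wm.begin());
      out[i] = List::create(_["type"] = "conv", _["W"] = Wm, _["b"] = vec(w.b[i]));
    } else if (nodes[i].type == N_BN) {
      out[i] = List::create(_["type"] = "bn",
                            _["gamma"] = vec(w.gamma[i]), _["beta"] = vec(w.beta[i]),
                            _["rmean"] = vec(w.rmean[i]), _["rvar"] = vec(w.rvar[i]));
    } else {
      out[i] = R_NilValue;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_init_weights(List nodes_r, int in_channels, int seed) {
  std::vector<Node> nodes = parse_nodes(nodes_r, in_channels);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> rnorm(0.0, 1.0);
  List out(nodes.size());
  for (size_t i = 0; i < nodes.size(); ++i) {
    if (nodes[i].type == N_CONV) {
      int fanin = nodes[i].k * nodes[i].k * nodes[i].cin;
      double sd = std::sqrt(2.0 / fanin);  // He initialization
      NumericMatrix Wm(fanin, nodes[i].cout);
      for (int j = 0; j < Wm.length(); ++j) Wm[j] = sd * rnorm(rng);
      out[i] = List::create(_["type"] = "conv", _["W"] = Wm,
                            _["b"] = NumericVector(nodes[i].cout));
    } else if (nodes[i].type == N_BN) {
      int c = nodes[i].C;
      out[i] = List::create(_["type"] = "bn",
                            _["gamma"] = NumericVector(c, 1.0),
                            _["beta"] = NumericVector(c, 0.0),
                            _["rmean"] = NumericVector(c, 0.0),
                            _["rvar"] = NumericVector(c, 1.0));
    } else out[i] = R_NilValue;
  }
  return out;
}

// ---- im2col / col2im -------------------------------------------------------

// X: (H*W x C) one image, pixel p = c*H + r.  col: (H*W x k*k*C), zero-padded
// 'same' convolution; col column d = kr + k*kc + k*k*ci reads X(r+kr-pad, c+kc-pad).
static void im2col(const arma::fmat& X, int H, int W, int k, arma::fmat& col) {
  int pad = (k - 1) / 2, C = X.n_cols;
  col.zeros();
  for (int ci = 0; ci < C; ++ci) {
    const float* src = X.colptr(ci);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        float* dst = col.colptr(kr + k * kc + k * k * ci);
        int dc = kc - pad, dr = kr - pad;
        for (int c = 0; c < W; ++c) {
          int cs = c + dc;
          if (cs < 0 || cs >= W) continue;
          int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          if (r1 <= r0) continue;
          std::memcpy(dst + (size_t)c * H + r0,
                      src + (size_t)cs * H + r0 + dr,
                      (size_t)(r1 - r0) * sizeof(float));
        }
      }
    }
  }
}

static void col2im_acc(const arma::fmat& dcol, int H, int W, int k, arma::fmat& dX) {
  int pad = (k - 1) / 2, C = dX.n_cols;
  for (int ci = 0; ci < C; ++ci) {
    float* dst = dX.colptr(ci);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const float* src = dcol.colptr(kr + k * kc + k * k * ci);
        int dc = kc - pad, dr = kr - pad;
        for (int c = 0; c < W; ++c) {
          int cs = c + dc;
          if (cs < 0 || cs >= W) continue;
          int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          float* d2 = dst + (size_t)cs * H + dr;
          const float* s2 = src + (size_t)c * H;
          for (int r = r0; r < r1; ++r) d2[r] += s2[r];
        }
      }
    }
  }
}

// ---- workspace -------------------------------------------------------------

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.1f;

struct Workspace {
  int B = -1;
  std::vector<arma::fcube> A, dA, xhat;
  std::vector<arma::fvec> istd;
  std::vector<arma::ucube> amax;
  std::vector<arma::fmat> col;     // per conv node im2col buffer
  std::vector<char> touched;       // backward: dA[i] holds data

  void ensure(const std::vector<Node>& nodes, int Bnew, bool training) {
    if (Bnew == B) return;
    B = Bnew;
    int n = nodes.size();
    A.resize(n); dA.resize(n); xhat.resize(n); istd.resize(n);
    amax.resize(n); col.resize(n); touched.assign(n, 0);
    for (int i = 0; i < n; ++i) {
      const Node& v = nodes[i];
      size_t HW = (size_t)v.H * v.W;
      A[i].set_size(HW, v.C, B);
      if (training) {
        dA[i].set_size(HW, v.C, B);
        if (v.type == N_BN) { xhat[i].set_size(HW, v.C, B); istd[i].set_size(v.C); }
      }
      if (v.type == N_POOL) amax[i].set_size(HW, v.C, B);
      if (v.type == N_CONV)
        col[i].set_size(HW, (size_t)v.k * v.k * v.cin);
    }
  }
};

static void relu_fw(const float* in, float* out, size_t n) {
  for (size_t q = 0; q < n; ++q) out[q] = in[q] > 0.0f ? in[q] : 0.0f;
}

static void forward(const std::vector<Node>& nodes, Weights& w, Workspace& ws,
                    bool training) {
  int n = nodes.size(), B = ws.B;
  for (int i = 0; i < n; ++i) {
    const Node& v = nodes[i];
    size_t HW = (size_t)v.H * v.W;
    switch (v.type) {
    case N_INPUT: break;  // ws.A[input] filled by caller
    case N_CONV: {
      const arma::fcube& Ain = ws.A[v.in[0]];
      for (int bi = 0; bi < B; ++bi) {
        im2col(Ain.slice(bi), v.H, v.W, v.k, ws.col[i]);
        ws.A[i].slice(bi) = ws.col[i] * w.W[i];
        ws.A[i].slice(bi).each_row() += w.b[i].t();
      }
      break;
    }
    case N_BN: {
      const arma::fcube& Ain = ws.A[v.in[0]];
      double N = (double)HW * B;
      if (training) {
        for (int c = 0; c < v.C; ++c) {
          double s = 0, s2 = 0;
          for (int bi = 0; bi < B; ++bi) {
            arma::fvec x(const_cast<float*>(Ain.slice_colptr(bi, c)), HW, false, true);
            s += arma::accu(x);
            s2 += arma::dot(x, x);
          }
          float mu = (float)(s / N);
          float var = (float)std::max(0.0, s2 / N - (double)mu * mu);
          float isd = 1.0f / std::sqrt(var + BN_EPS);
          ws.istd[i][c] = isd;
          float g = w.gamma[i][c], be = w.beta[i][c];
          for (int bi = 0; bi < B; ++bi) {
            const float* x = Ain.slice_colptr(bi, c);
            float* xh = ws.xhat[i].slice_colptr(bi, c);
            float* y = ws.A[i].slice_colptr(bi, c);
            for (size_t q = 0; q < HW; ++q) {
              float z = (x[q] - mu) * isd;
              xh[q] = z;
              y[q] = g * z + be;
            }
          }
          w.rmean[i][c] = (1.0f - BN_MOM) * w.rmean[i][c] + BN_MOM * mu;
          w.rvar[i][c] = (1.0f - BN_MOM) * w.rvar[i][c] + BN_MOM * var;
        }
      } else {
        for (int c = 0; c < v.C; ++c) {
          float isd = 1.0f / std::sqrt(w.rvar[i][c] + BN_EPS);
          float g = w.gamma[i][c], be = w.beta[i][c], mu = w.rmean[i][c];
          for (int bi = 0; bi < B; ++bi) {
            const float* x = Ain.slice_colptr(bi, c);
            float* y = ws.A[i].slice_colptr(bi, c);
            for (size_t q = 0; q < HW; ++q) y[q] = g * (x[q] - mu) * isd + be;
          }
        }
      }
      break;
    }
    case N_RELU:
      relu_fw(ws.A[v.in[0]].memptr(), ws.A[i].memptr(), ws.A[i].n_elem);
      break;
    case N_POOL: {
      const Node& u = nodes[v.in[0]];
      for (int bi = 0; bi < B; ++bi)
        for (int c = 0; c < v.C; ++c) {
          const float* src = ws.A[v.in[0]].slice_colptr(bi, c);
          float* dst = ws.A[i].slice_colptr(bi, c);
          arma::uword* am = ws.amax[i].slice_colptr(bi, c);
          for (int co = 0; co < v.W; ++co)
            for (int ro = 0; ro < v.H; ++ro) {
              size_t p00 = (size_t)(2 * co) * u.H + 2 * ro;
              size_t cand[4] = { p00, p00 + 1, p00 + u.H, p00 + u.H + 1 };
              size_t best = cand[0];
              for (int q = 1; q < 4; ++q) if (src[cand[q]] > src[best]) best = cand[q];
              size_t po = (size_t)co * v.H + ro;
              dst[po] = src[best];
              am[po] = best;
            }
        }
      break;
    }
    case N_UP: {
      const Node& u = nodes[v.in[0]];
      for (int bi = 0; bi < B; ++bi)
        for (int c = 0; c < v.C; ++c) {
          const float* src = ws.A[v.in[0]].slice_colptr(bi, c);
          float* dst = ws.A[i].slice_colptr(bi, c);
          for (int co = 0; co < v.W; ++co)
            for (int ro = 0; ro < v.H; ++ro)
              dst[(size_t)co * v.H + ro] = src[(size_t)(co / 2) * u.H + ro / 2];
        }
      break;
    }
    case N_CONCAT: {
      int off = 0;
      for (int id : v.in) {
        int ci = nodes[id].C;
        ws.A[i].cols(off, off + ci - 1) = ws.A[id];
        off += ci;
      }
      break;
    }
    }
  }
}

struct Grads {
  std::vector<arma::fmat> dW;
  std::vector<arma::fvec> db, dgamma, dbeta;
};

static void backward(const std::vector<Node>& nodes, const Weights& w,
                     Workspace& ws, int out_id, Grads& g) {
  int n = nodes.size(), B = ws.B;
  std::fill(ws.touched.begin(), ws.touched.end(), 0);
  ws.touched[out_id] = 1;  // caller wrote dA[out_id]
  auto ensure_zero = [&](int j) {
    if (!ws.touched[j]) { ws.dA[j].zeros(); ws.touched[j] = 1; }
  };
  for (int i = n - 1; i >= 0; --i) {
    const Node& v = nodes[i];
    if (v.type == N_INPUT || !ws.touched[i]) continue;
    switch (v.type) {
    case N_CONV: {
      int src = v.in[0];
      bool to_input = (nodes[src].type == N_INPUT);
      const Node& u = nodes[src];
      if (!to_input) ensure_zero(src);
      for (int bi = 0; bi < B; ++bi) {
        const arma::fmat& dY = ws.dA[i].slice(bi);
        im2col(ws.A[src].slice(bi), v.H, v.W, v.k, ws.col[i]);
        g.dW[i] += ws.col[i].t() * dY;
        g.db[i] += arma::sum(dY, 0).t();
        if (!to_input) {
          arma::fmat dcol = dY * w.W[i].t();
          col2im_acc(dcol, u.H, u.W, v.k, ws.dA[src].slice(bi));
        }
      }
      break;
    }
    case N_BN: {
      int src = v.in[0];
      ensure_zero(src);
      size_t HW = (size_t)v.H * v.W;
      double N = (double)HW * B;
      for (int c = 0; c < v.C; ++c) {
        double sdy = 0, sdyx = 0;
        for (int bi = 0; bi < B; ++bi) {
          arma::fvec dy(ws.dA[i].slice_colptr(bi, c), HW, false, true);
          arma::fvec xh(ws.xhat[i].slice_colptr(bi, c), HW, false, true);
          sdy += arma::accu(dy);
          sdyx += arma::dot(dy, xh);
        }
        g.dgamma[i][c] += (float)sdyx;
        g.dbeta[i][c] += (float)sdy;
        float a = w.gamma[i][c] * ws.istd[i][c];
        float mdy = (float)(sdy / N), mdyx = (float)(sdyx / N);
        for (int bi = 0; bi < B; ++bi) {
          float* dx = ws.dA[src].slice_colptr(bi, c);
          const float* dy = ws.dA[i].slice_colptr(bi, c);
          const float* xh = ws.xhat[i].slice_colptr(bi, c);
          for (size_t q = 0; q < HW; ++q)
            dx[q] += a * (dy[q] - mdy - xh[q] * mdyx);
        }
      }
      break;
    }
    case N_RELU: {
      int src = v.in[0];
      ensure_zero(src);
      const float* act = ws.A[i].memptr();
      const float* dy = ws.dA[i].memptr();
      float* dx = ws.dA[src].memptr();
      size_t m = ws.dA[i].n_elem;
      for (size_t q = 0; q < m; ++q) dx[q] += act[q] > 0.0f ? dy[q] : 0.0f;
      break;
    }
    case N_POOL: {
      int src = v.in[0];
      ensure_zero(src);
      size_t HW = (size_t)v.H * v.W;
      for (int bi = 0; bi < B; ++bi)
        for (int c = 0; c < v.C; ++c) {
          float* dst = ws.dA[src].slice_colptr(bi, c);
          const float* dy = ws.dA[i].slice_colptr(bi, c);
          const arma::uword* am = ws.amax[i].slice_colptr(bi, c);
          for (size_t q = 0; q < HW; ++q) dst[am[q]] += dy[q];
        }
      break;
    }
    case N_UP: {
      int src = v.in[0];
      ensure_zero(src);
      const Node& u = nodes[src];
      for (int bi = 0; bi < B; ++bi)
        for (int c = 0; c < v.C; ++c) {
          float* dst = ws.dA[src].slice_colptr(bi, c);
          const float* dy = ws.dA[i].slice_colptr(bi, c);
          for (int co = 0; co < v.W; ++co)
            for (int ro = 0; ro < v.H; ++ro)
              dst[(size_t)(co / 2) * u.H + ro / 2] += dy[(size_t)co * v.H + ro];
        }
      break;
    }
    case N_CONCAT: {
      int off = 0;
      for (int id : v.in) {
        int ci = nodes[id].C;
        if (nodes[id].type != N_INPUT) {
          ensure_zero(id);
          ws.dA[id] += ws.dA[i].cols(off, off + ci - 1);
        }
        off += ci;
      }
      break;
    }
    }
  }
}

// softmax over channel axis of a logits cube (HW x C x B), in place
static void softmax_cube(arma::fcube& Z) {
  size_t HW = Z.n_rows; int C = Z.n_cols, B = Z.n_slices;
  for (int bi = 0; bi < B; ++bi) {
    arma::fmat& S = Z.slice(bi);
    for (size_t p = 0; p < HW; ++p) {
      float m = S(p, 0);
      for (int c = 1; c < C; ++c) m = std::max(m, S(p, c));
      float s = 0;
      for (int c = 0; c < C; ++c) { float e = std::exp(S(p, c) - m); S(p, c) = e; s += e; }
      for (int c = 0; c < C; ++c) S(p, c) /= s;
    }
  }
}

// copy an R [H,W,C,N] array into an fcube (HW x C x N)
static arma::fcube to_fcube(const NumericVector& x_r, size_t HW, int C, int N) {
  arma::fcube X(HW, C, N);
  const double* px = x_r.begin();
  for (int bi = 0; bi < N; ++bi)
    for (int c = 0; c < C; ++c) {
      float* dst = X.slice_colptr(bi, c);
      const double* src = px + ((size_t)bi * C + c) * HW;
      for (size_t q = 0; q < HW; ++q) dst[q] = (float)src[q];
    }
  return X;
}

// ---- training --------------------------------------------------------------

// [[Rcpp::export]]
List cpp_train(List nodes_r, List weights_r, NumericVector x_r, IntegerVector y_r,
               List opts, Nullable<NumericVector> xval_r = R_NilValue,
               Nullable<IntegerVector> yval_r = R_NilValue) {
  IntegerVector xd = x_r.attr("dim");
  if (xd.size() != 4) stop("x must be a H x W x C x N array");
  int H = xd[0], W = xd[1], C0 = xd[2], Ntr = xd[3];
  size_t HW = (size_t)H * W;
  std::vector<Node> nodes = parse_nodes(nodes_r, C0);
  set_dims(nodes, H, W);
  int out_id = nodes.size() - 1;
  int nclass = nodes[out_id].C;
  Weights w = load_weights(nodes, weights_r);

  int epochs = as<int>(opts["epochs"]);
  double lr = as<double>(opts["lr"]);
  int batch = as<int>(opts["batch_size"]);
  int seed = as<int>(opts["seed"]);
  NumericVector cw_r = opts["class_weights"];
  if (cw_r.size() != nclass) stop("class_weights length must equal n classes");
  std::vector<float> cw(cw_r.begin(), cw_r.end());

  arma::fcube Xall = to_fcube(x_r, HW, C0, Ntr);
  const int* py = y_r.begin();

  arma::fcube Xval; std::vector<int> yval; int Nval = 0;
  if (xval_r.isNotNull()) {
    NumericVector xv(xval_r);
    IntegerVector yv(yval_r);
    IntegerVector vd = xv.attr("dim");
    Nval = vd[3];
    Xval = to_fcube(xv, HW, C0, Nval);
    yval.assign(yv.begin(), yv.end());
  }

  Grads m, v, g;
  auto zero_like = [&](Grads& gg) {
    gg.dW.assign(nodes.size(), arma::fmat());
    gg.db.assign(nodes.size(), arma::fvec());
    gg.dgamma.assign(nodes.size(), arma::fvec());
    gg.dbeta.assign(nodes.size(), arma::fvec());
    for (size_t i = 0; i < nodes.size(); ++i) {
      if (nodes[i].type == N_CONV) {
        gg.dW[i].zeros(arma::size(w.W[i]));
        gg.db[i].zeros(arma::size(w.b[i]));
      } else if (nodes[i].type == N_BN) {
        gg.dgamma[i].zeros(arma::size(w.gamma[i]));
        gg.dbeta[i].zeros(arma::size(w.beta[i]));
      }
    }
  };
  zero_like(m); zero_like(v); zero_like(g);
  const float b1 = 0.9f, b2 = 0.999f, aeps = 1e-8f;
  long tstep = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(Ntr);
  for (int i = 0; i < Ntr; ++i) idx[i] = i;

  NumericVector hist_loss(epochs), hist_vdice(epochs, NA_REAL);
  Workspace ws, wsv;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = Ntr - 1; i > 0; --i) {  // Fisher-Yates shuffle
      std::uniform_int_distribution<int> U(0, i);
      std::swap(idx[i], idx[U(rng)]);
    }
    double ep_loss = 0, ep_wsum = 0;
    for (int start = 0; start < Ntr; start += batch) {
      int B = std::min(batch, Ntr - start);
      ws.ensure(nodes, B, true);
      for (int bi = 0; bi < B; ++bi) ws.A[0].slice(bi) = Xall.slice(idx[start + bi]);
      forward(nodes, w, ws, true);

      // softmax + weighted cross-entropy straight into dA[out_id]
      arma::fcube& dZ = ws.dA[out_id];
      dZ = ws.A[out_id];
      softmax_cube(dZ);
      double wsum = 0, loss = 0;
      for (int bi = 0; bi < B; ++bi) {
        const int* yb = py + (size_t)idx[start + bi] * HW;
        const arma::fmat& S = dZ.slice(bi);
        for (size_t p = 0; p < HW; ++p) {
          int yc = yb[p] - 1;
          loss -= cw[yc] * std::log(std::max(S(p, yc), 1e-12f));
          wsum += cw[yc];
        }
      }
      for (int bi = 0; bi < B; ++bi) {
        const int* yb = py + (size_t)idx[start + bi] * HW;
        arma::fmat& S = dZ.slice(bi);
        for (size_t p = 0; p < HW; ++p) {
          int yc = yb[p] - 1;
          float wt = cw[yc] / (float)wsum;
          for (int c = 0; c < nclass; ++c)
            S(p, c) = wt * (S(p, c) - (c == yc ? 1.0f : 0.0f));
        }
      }
      ep_loss += loss; ep_wsum += wsum;

      for (size_t i = 0; i < nodes.size(); ++i) {
        if (nodes[i].type == N_CONV) { g.dW[i].zeros(); g.db[i].zeros(); }
        else if (nodes[i].type == N_BN) { g.dgamma[i].zeros(); g.dbeta[i].zeros(); }
      }
      backward(nodes, w, ws, out_id, g);

      ++tstep;
      float bc1 = 1.0f - std::pow(b1, (float)tstep);
      float bc2 = 1.0f - std::pow(b2, (float)tstep);
      auto adam = [&](arma::fmat& p, arma::fmat& mm, arma::fmat& vv, const arma::fmat& gr) {
        mm = b1 * mm + (1.0f - b1) * gr;
        vv = b2 * vv + (1.0f - b2) * (gr % gr);
        p -= (float)lr * (mm / bc1) / (arma::sqrt(vv / bc2) + aeps);
      };
      auto adamv = [&](arma::fvec& p, arma::fvec& mm, arma::fvec& vv, const arma::fvec& gr) {
        mm = b1 * mm + (1.0f - b1) * gr;
        vv = b2 * vv + (1.0f - b2) * (gr % gr);
        p -= (float)lr * (mm / bc1) / (arma::sqrt(vv / bc2) + aeps);
      };
      for (size_t i = 0; i < nodes.size(); ++i) {
        if (nodes[i].type == N_CONV) {
          adam(w.W[i], m.dW[i], v.dW[i], g.dW[i]);
          adamv(w.b[i], m.db[i], v.db[i], g.db[i]);
        } else if (nodes[i].type == N_BN) {
          adamv(w.gamma[i], m.dgamma[i], v.dgamma[i], g.dgamma[i]);
          adamv(w.beta[i], m.dbeta[i], v.dbeta[i], g.dbeta[i]);
        }
      }
      Rcpp::checkUserInterrupt();
    }
    hist_loss[ep] = ep_loss / ep_wsum;

    if (Nval > 0) {
      // nuclei-binarized Dice on the validation set (classes 1,2 vs 3)
      long tp2 = 0, fp2 = 0, fn2 = 0;
      int chunk = std::min(25, Nval);
      for (int start = 0; start < Nval; start += chunk) {
        int B = std::min(chunk, Nval - start);
        wsv.ensure(nodes, B, false);
        for (int bi = 0; bi < B; ++bi) wsv.A[0].slice(bi) = Xval.slice(start + bi);
        forward(nodes, w, wsv, false);
        const arma::fcube& Z = wsv.A[out_id];
        for (int bi = 0; bi < B; ++bi) {
          const arma::fmat& S = Z.slice(bi);
          for (size_t p = 0; p < HW; ++p) {
            int am = 0;
            for (int c = 1; c < nclass; ++c) if (S(p, c) > S(p, am)) am = c;
            bool pred_pos = (am + 1) <= 2;
            bool true_pos = yval[(size_t)(start + bi) * HW + p] <= 2;
            if (pred_pos && true_pos) ++tp2;
            else if (pred_pos) ++fp2;
            else if (true_pos) ++fn2;
          }
        }
      }
      hist_vdice[ep] = (2.0 * tp2) / std::max(1.0, 2.0 * tp2 + fp2 + fn2);
    }
  }

  return List::create(
    _["weights"] = export_weights(nodes, w),
    _["loss"] = hist_loss,
    _["val_dice"] = hist_vdice);
}

// ---- inference -------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_forward(List nodes_r, List weights_r, NumericVector x_r,
                          bool softmax = true) {
  IntegerVector xd = x_r.attr("dim");
  if (xd.size() != 4) stop("x must be a H x W x C x N array");
  int H = xd[0], W = xd[1], C0 = xd[2], B = xd[3];
  size_t HW = (size_t)H * W;
  std::vector<Node> nodes = parse_nodes(nodes_r, C0);
  set_dims(nodes, H, W);
  int out_id = nodes.size() - 1;
  int nclass = nodes[out_id].C;
  Weights w = load_weights(nodes, weights_r);

  Workspace ws;
  ws.ensure(nodes, B, false);
  ws.A[0] = to_fcube(x_r, HW, C0, B);
  forward(nodes, w, ws, false);
  arma::fcube Z = ws.A[out_id];
  if (softmax) softmax_cube(Z);

  NumericVector out((R_xlen_t)(HW * nclass * B));
  out.attr("dim") = IntegerVector::create(H, W, nclass, B);
  double* po = out.begin();
  for (int bi = 0; bi < B; ++bi)
    for (int c = 0; c < nclass; ++c) {
      const float* src = Z.slice_colptr(bi, c);
      double* dst = po + ((size_t)bi * nclass + c) * HW;
      for (size_t q = 0; q < HW; ++q) dst[q] = (double)src[q];
    }
  return out;
}

// [[Rcpp::export]]
int cpp_infer_channels(List nodes_r, int in_channels) {
  std::vector<Node> nodes = parse_nodes(nodes_r, in_channels);
  return nodes.back().C;
}
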