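// Single-precision compute core for the spatio-sequential encoding Q-network
// and batched 2.5D patch extraction. Convolutions are im2col + GEMM; the
// gather index tables are built once on the R side (conv_indices) and passed
// in 0-based, with the pad slot mapped to row `in_rows`.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef arma::fmat FM;
typedef arma::fvec FV;

static FM as_fmat(SEXP s) {
  NumericMatrix m(s);
  arma::mat d(m.begin(), m.nrow(), m.ncol(), false);
  return arma::conv_to<FM>::from(d);
}

static FV as_fvec(SEXP s) {
  NumericVector v(s);
  arma::vec d(v.begin(), v.size(), false);
  return arma::conv_to<FV>::from(d);
}

struct ConvGeom {
  arma::uvec idx;   // (kk*c_in*mm), 0-based rows of padded input; pad row = in_rows
  int in_rows;      // n*n*c_in
  int c_out;
  int mm;           // out spatial positions
  int kkcin;        // kk*c_in == W.n_cols
};

struct ConvPar { FM W; FV b; };
struct FcPar   { FM W; FV b; };

struct Encoder {
  std::vector<ConvPar> convs;
  FcPar fc;
};

struct Net {
  Encoder enc[3];
  std::vector<ConvGeom> geom;   // shared across axes
  std::vector<FcPar> omega;     // per-frame local inference
  FcPar global;
  bool dueling;
  FcPar value, adv;             // dueling heads
  FcPar out;                    // plain head
  int frames;
};

static FcPar parse_fc(List l) {
  FcPar p;
  p.W = as_fmat(l["W"]);
  p.b = as_fvec(l["b"]);
  return p;
}

static Net parse_net(List par, List geom) {
  Net net;
  net.geom.resize(geom.size());
  for (int i = 0; i < geom.size(); ++i) {
    List g = geom[i];
    IntegerVector iv = g["idx0"];
    net.geom[i].idx = arma::conv_to<arma::uvec>::from(
      arma::Col<int>(iv.begin(), iv.size(), false));
    net.geom[i].in_rows = as<int>(g["in_rows"]);
    net.geom[i].c_out   = as<int>(g["c_out"]);
    net.geom[i].mm      = as<int>(g["mm"]);
    net.geom[i].kkcin   = as<int>(g["kkcin"]);
  }
  List theta = par["theta"];
  const char* axes[3] = {"x", "y", "z"};
  for (int ax = 0; ax < 3; ++ax) {
    List axl = theta[axes[ax]];
    List convs = axl["conv"];
    if ((int)convs.size() != (int)net.geom.size())
      stop("encoder layer count does not match geometry");
    for (int i = 0; i < convs.size(); ++i) {
      List c = convs[i];
      ConvPar cp;
      cp.W = as_fmat(c["W"]);
      cp.b = as_fvec(c["b"]);
      if ((int)cp.W.n_cols != net.geom[i].kkcin || (int)cp.W.n_rows != net.geom[i].c_out)
        stop("conv layer %d (axis %s): weight shape does not match geometry", i + 1, axes[ax]);
      net.enc[ax].convs.push_back(cp);
    }
    net.enc[ax].fc = parse_fc(axl["fc"]);
  }
  List omega = par["omega"];
  net.frames = omega.size();
  for (int h = 0; h < omega.size(); ++h)
    net.omega.push_back(parse_fc(omega[h]));
  net.global = parse_fc(par["global"]);
  net.dueling = par.containsElementNamed("value");
  if (net.dueling) {
    net.value = parse_fc(par["value"]);
    net.adv   = parse_fc(par["adv"]);
  } else {
    net.out = parse_fc(par["out"]);
  }
  return net;
}

// forward one conv layer; X is (in_rows x P); returns (mm*c_out x P) pre-ReLU
static FM conv_fwd(const FM& X, const ConvPar& cp, const ConvGeom& g, FM* Xcol_out) {
  int P = X.n_cols;
  FM Xp(g.in_rows + 1, P);
  Xp.rows(0, g.in_rows - 1) = X;
  Xp.row(g.in_rows).zeros();
  FM Xcol = Xp.rows(g.idx);            // (kkcin*mm) x P
  Xcol.reshape(g.kkcin, g.mm * P);     // column-major reinterpret, no reorder
  FM Y = cp.W * Xcol;                  // c_out x mm*P
  Y.each_col() += cp.b;
  FM Y2(g.mm * g.c_out, P);
  for (int p = 0; p < P; ++p) {
    FM blk = Y.cols(p * g.mm, (p + 1) * g.mm - 1);  // c_out x mm
    FM t = blk.t();
    std::memcpy(Y2.colptr(p), t.memptr(), sizeof(float) * g.mm * g.c_out);
  }
  if (Xcol_out) *Xcol_out = std::move(Xcol);
  return Y2;
}

// backward one conv layer; dY2 is (mm*c_out x P) grad at post-layer (mask applied)
static FM conv_bwd(const FM& dY2, const FM& Xcol, const ConvPar& cp, const ConvGeom& g,
                   FM& dW, FV& db) {
  int P = dY2.n_cols;
  FM dY(g.c_out, g.mm * P);
  for (int p = 0; p < P; ++p) {
    const FM blk(const_cast<float*>(dY2.colptr(p)), g.mm, g.c_out, false, true);
    dY.cols(p * g.mm, (p + 1) * g.mm - 1) = blk.t();
  }
  dW = dY * Xcol.t();
  db = arma::sum(dY, 1);
  FM dXcol = cp.W.t() * dY;            // kkcin x mm*P
  FM dX(g.in_rows, P, arma::fill::zeros);
  const arma::uword* ip = g.idx.memptr();
  int L = g.idx.n_elem;                // kkcin*mm
  for (int p = 0; p < P; ++p) {
    const float* src = dXcol.colptr(p * g.mm);  // contiguous kkcin*mm values
    float* dst = dX.colptr(p);
    for (int l = 0; l < L; ++l)
      if (ip[l] < (arma::uword)g.in_rows) dst[ip[l]] += src[l];
  }
  return dX;
}

static inline void relu_ip(FM& m) { m.transform([](float v) { return v > 0.f ? v : 0.f; }); }
static inline void relu_mask(FM& grad, const FM& act) {
  grad %= arma::conv_to<FM>::from(act > 0.f);
}

struct Cache {
  // per axis: activations entering each conv (post-ReLU of previous), im2col mats,
  // post-ReLU conv outputs, encoder FC output
  std::vector<FM> conv_in[3], Xcols[3], conv_out[3];
  FM enc[3];                 // enc_dim x P (post-ReLU)
  std::vector<FM> Th, Tl;    // per frame: (3*enc_dim x B), (local_dim x B post-ReLU)
  FM sbar, g;                // (frames*local_dim x B), (global_dim x B post-ReLU)
  FM V, A, Q;                // 1xB, 7xB, 7xB
  int B;
};

static void forward_impl(const std::vector<FM>& planes, const Net& net,
                         bool keep, Cache& C) {
  int P = planes[0].n_cols;
  int B = P / net.frames;
  C.B = B;
  for (int ax = 0; ax < 3; ++ax) {
    FM X = planes[ax];
    for (size_t l = 0; l < net.geom.size(); ++l) {
      FM Xcol;
      if (keep) C.conv_in[ax].push_back(X);
      FM Y = conv_fwd(X, net.enc[ax].convs[l], net.geom[l], keep ? &Xcol : (FM*)0);
      relu_ip(Y);
      if (keep) { C.Xcols[ax].push_back(std::move(Xcol)); C.conv_out[ax].push_back(Y); }
      X = std::move(Y);
    }
    FM f = net.enc[ax].fc.W * X;
    f.each_col() += net.enc[ax].fc.b;
    relu_ip(f);
    if (keep) {
      // also keep FC input (last conv output already stored as conv_out back())
    }
    C.enc[ax] = std::move(f);
  }
  int enc_dim = C.enc[0].n_rows;
  int local_dim = net.omega[0].W.n_rows;
  C.sbar.set_size(net.frames * local_dim, B);
  for (int h = 0; h < net.frames; ++h) {
    FM Th(3 * enc_dim, B);
    for (int ax = 0; ax < 3; ++ax)
      Th.rows(ax * enc_dim, (ax + 1) * enc_dim - 1) = C.enc[ax].cols(h * B, (h + 1) * B - 1);
    FM Tl = net.omega[h].W * Th;
    Tl.each_col() += net.omega[h].b;
    relu_ip(Tl);
    C.sbar.rows(h * local_dim, (h + 1) * local_dim - 1) = Tl;
    if (keep) { C.Th.push_back(std::move(Th)); C.Tl.push_back(std::move(Tl)); }
  }
  C.g = net.global.W * C.sbar;
  C.g.each_col() += net.global.b;
  relu_ip(C.g);
  if (net.dueling) {
    C.V = net.value.W * C.g;  C.V.each_col() += net.value.b;
    C.A = net.adv.W * C.g;    C.A.each_col() += net.adv.b;
    FM mean_a = arma::mean(C.A, 0);   // 1 x B
    C.Q = C.A;
    C.Q.each_row() -= mean_a;
    C.Q.each_row() += C.V.row(0);
  } else {
    C.Q = net.out.W * C.g;
    C.Q.each_col() += net.out.b;
  }
}

static std::vector<FM> parse_planes(List planes) {
  std::vector<FM> out;
  for (int i = 0; i < 3; ++i) out.push_back(as_fmat(planes[i]));
  if (out[1].n_cols != out[0].n_cols || out[2].n_cols != out[0].n_cols)
    stop("plane batches must have equal column counts");
  return out;
}

static NumericVector to_rvec(const FV& v) {
  NumericVector out(v.n_elem);
  for (size_t i = 0; i < v.n_elem; ++i) out[i] = v(i);
  return out;
}

static NumericMatrix to_rmat(const FM& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (size_t j = 0; j < m.n_cols; ++j)
    for (size_t i = 0; i < m.n_rows; ++i)
      out(i, j) = m(i, j);
  return out;
}

// [[Rcpp::export]]
List cpp_esse_forward(List planes, List par, List geom) {
  std::vector<FM> pl = parse_planes(planes);
  Net net = parse_net(par, geom);
  if ((int)(pl[0].n_cols) % net.frames != 0)
    stop("plane column count is not a multiple of the frame count");
  Cache C;
  forward_impl(pl, net, false, C);
  List out = List::create(_["Q"] = to_rmat(C.Q));
  if (net.dueling) {
    out["V"] = to_rmat(C.V);
    out["A"] = to_rmat(C.A);
  }
  return out;
}

// MSE on the Q-values of the taken actions against fixed targets y.
// a_taken is 1-based action index (1..n_actions); returns loss, Q, and
// gradients with the same nesting as the parameter list.
// [[Rcpp::export]]
List cpp_esse_grad(List planes, List par, List geom, IntegerVector a_taken,
                   NumericVector y) {
  std::vector<FM> pl = parse_planes(planes);
  Net net = parse_net(par, geom);
  Cache C;
  forward_impl(pl, net, true, C);
  int B = C.B;
  if (a_taken.size() != B || y.size() != B)
    stop("a_taken and y must have one entry per batch item");
  int nA = C.Q.n_rows;

  FM dQ(nA, B, arma::fill::zeros);
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    int a = a_taken[b] - 1;
    if (a < 0 || a >= nA) stop("action index out of range");
    double diff = (double)C.Q(a, b) - y[b];
    loss += diff * diff;
    dQ(a, b) = (float)(2.0 * diff / B);
  }
  loss /= B;

  int enc_dim = C.enc[0].n_rows;
  int local_dim = net.omega[0].W.n_rows;
  FM dg;
  List grads;
  if (net.dueling) {
    // Q = V + A - mean(A): dA = dQ - colmean(dQ); dV = colsum(dQ)
    FM dA = dQ;
    dA.each_row() -= arma::mean(dQ, 0);
    FM dV = arma::sum(dQ, 0);          // 1 x B
    FM dWv = dV * C.g.t();
    FV dbv = arma::sum(dV, 1);
    FM dWa = dA * C.g.t();
    FV dba = arma::sum(dA, 1);
    dg = net.value.W.t() * dV + net.adv.W.t() * dA;
    grads["value"] = List::create(_["W"] = to_rmat(dWv),
                                  _["b"] = NumericVector::create(dbv(0)));
    grads["adv"] = List::create(_["W"] = to_rmat(dWa),
                                _["b"] = to_rvec(dba));
  } else {
    FM dWo = dQ * C.g.t();
    FV dbo = arma::sum(dQ, 1);
    dg = net.out.W.t() * dQ;
    grads["out"] = List::create(_["W"] = to_rmat(dWo),
                                _["b"] = to_rvec(dbo));
  }
  relu_mask(dg, C.g);
  FM dWg = dg * C.sbar.t();
  FV dbg = arma::sum(dg, 1);
  grads["global"] = List::create(_["W"] = to_rmat(dWg),
                                 _["b"] = to_rvec(dbg));
  FM dsbar = net.global.W.t() * dg;

  std::vector<FM> denc(3);
  for (int ax = 0; ax < 3; ++ax) denc[ax].zeros(enc_dim, B * net.frames);
  List omega_g(net.frames);
  for (int h = 0; h < net.frames; ++h) {
    FM dTl = dsbar.rows(h * local_dim, (h + 1) * local_dim - 1);
    relu_mask(dTl, C.Tl[h]);
    FM dWl = dTl * C.Th[h].t();
    FV dbl = arma::sum(dTl, 1);
    omega_g[h] = List::create(_["W"] = to_rmat(dWl),
                              _["b"] = to_rvec(dbl));
    FM dTh = net.omega[h].W.t() * dTl;
    for (int ax = 0; ax < 3; ++ax)
      denc[ax].cols(h * B, (h + 1) * B - 1) = dTh.rows(ax * enc_dim, (ax + 1) * enc_dim - 1);
  }
  grads["omega"] = omega_g;

  List theta_g;
  const char* axes[3] = {"x", "y", "z"};
  for (int ax = 0; ax < 3; ++ax) {
    FM df = denc[ax];
    relu_mask(df, C.enc[ax]);
    const FM& fc_in = C.conv_out[ax].back();
    FM dWf = df * fc_in.t();
    FV dbf = arma::sum(df, 1);
    FM dX = net.enc[ax].fc.W.t() * df;
    List conv_g(net.geom.size());
    for (int l = (int)net.geom.size() - 1; l >= 0; --l) {
      relu_mask(dX, C.conv_out[ax][l]);
      FM dW; FV db;
      dX = conv_bwd(dX, C.Xcols[ax][l], net.enc[ax].convs[l], net.geom[l], dW, db);
      conv_g[l] = List::create(_["W"] = to_rmat(dW),
                               _["b"] = to_rvec(db));
    }
    theta_g[axes[ax]] = List::create(
      _["conv"] = conv_g,
      _["fc"] = List::create(_["W"] = to_rmat(dWf),
                             _["b"] = to_rvec(dbf)));
  }
  grads["theta"] = theta_g;

  return List::create(_["loss"] = loss, _["Q"] = to_rmat(C.Q), _["grads"] = grads);
}

// Batched extraction of axis-normal N x N patches, linearly windowed to [0,1].
// vol: numeric 3D array (nx, ny, nz); centers: M x 3, 0-based voxel indices
// (may lie outside the grid); axis: 1 = normal x (plane spans y,z),
// 2 = normal y (spans x,z), 3 = normal z (spans x,y). Within a patch the
// first in-plane axis varies fastest. Out-of-grid samples take pad_value
// (raw intensity scale) before windowing.
// [[Rcpp::export]]
NumericMatrix cpp_extract_patches(NumericVector vol, IntegerMatrix centers, int axis,
                                  int N, double lo, double hi, double pad_value) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("volume data must be a 3D array");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int M = centers.nrow();
  int half = N / 2;
  double scale = 1.0 / (hi - lo);
  double padn = (std::min(std::max(pad_value, lo), hi) - lo) * scale;
  NumericMatrix out(N * N, M);
  const double* v = vol.begin();
  int ua, va, na;   // in-plane axes and normal axis (0-based)
  if (axis == 1)      { ua = 1; va = 2; na = 0; }
  else if (axis == 2) { ua = 0; va = 2; na = 1; }
  else if (axis == 3) { ua = 0; va = 1; na = 2; }
  else stop("axis must be 1, 2 or 3");
  int dim3[3] = {nx, ny, nz};
  long strides[3] = {1L, (long)nx, (long)nx * ny};
  for (int m = 0; m < M; ++m) {
    int c[3] = {centers(m, 0), centers(m, 1), centers(m, 2)};
    double* col = &out(0, m);
    int nfix = c[na];
    bool n_in = nfix >= 0 && nfix < dim3[na];
    int k = 0;
    for (int dv = 0; dv < N; ++dv) {
      int vv = c[va] - half + dv;
      bool v_in = vv >= 0 && vv < dim3[va];
      for (int du = 0; du < N; ++du, ++k) {
        int uu = c[ua] - half + du;
        if (n_in && v_in && uu >= 0 && uu < dim3[ua]) {
          double x = v[strides[ua] * uu + strides[va] * vv + strides[na] * nfix];
          x = std::min(std::max(x, lo), hi);
          col[k] = (x - lo) * scale;
        } else {
          col[k] = padn;
        }
      }
    }
  }
  return out;
}

// ---- ADAM ---------------------------------------------------------------
// Walks the (index-parallel) nested parameter / gradient / moment lists.
// m and v are owned by the optimizer state and updated in place; new
// parameter tensors are returned.

static double adam_sumsq(SEXP g) {
  if (TYPEOF(g) == VECSXP) {
    double s = 0;
    List l(g);
    for (int i = 0; i < l.size(); ++i) s += adam_sumsq(l[i]);
    return s;
  }
  if (TYPEOF(g) == REALSXP) {
    NumericVector x(g);
    double s = 0;
    for (int i = 0; i < x.size(); ++i) s += x[i] * x[i];
    return s;
  }
  return 0;
}

static SEXP adam_walk(SEXP p, SEXP g, SEXP m, SEXP v, double scale, double lr,
                      double b1, double b2, double bc1, double bc2, double eps) {
  if (TYPEOF(p) == VECSXP) {
    List pl(p), gl(g), ml(m), vl(v);
    if (gl.size() != pl.size() || ml.size() != pl.size() || vl.size() != pl.size())
      stop("optimizer state does not match the parameter structure");
    List out(pl.size());
    out.names() = pl.names();
    for (int i = 0; i < pl.size(); ++i)
      out[i] = adam_walk(pl[i], gl[i], ml[i], vl[i], scale, lr, b1, b2, bc1,
                         bc2, eps);
    return out;
  }
  if (TYPEOF(p) == REALSXP) {
    NumericVector pv(p), gv(g), mv(m), vv(v);
    int n = pv.size();
    if (gv.size() != n || mv.size() != n || vv.size() != n)
      stop("optimizer state does not match the parameter shape");
    NumericVector out = clone(pv);
    for (int i = 0; i < n; ++i) {
      double gi = gv[i] * scale;
      mv[i] = b1 * mv[i] + (1 - b1) * gi;
      vv[i] = b2 * vv[i] + (1 - b2) * gi * gi;
      out[i] = pv[i] - lr * (mv[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
    }
    out.attr("dim") = pv.attr("dim");
    return out;
  }
  return p;
}

// [[Rcpp::export]]
List cpp_adam_step(List params, List grads, List m, List v, double lr,
                   double clip, double b1, double b2, int t, double eps) {
  double scale = 1.0;
  if (R_finite(clip)) {
    double norm = std::sqrt(adam_sumsq(grads));
    if (norm > clip) scale = clip / norm;
  }
  double bc1 = 1 - std::pow(b1, t);
  double bc2 = 1 - std::pow(b2, t);
  return List(adam_walk(params, grads, m, v, scale, lr, b1, b2, bc1, bc2, eps));
}
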