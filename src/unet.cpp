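// 3D U-Net forward/backward pass on CPU, single sample (batch size 1).
// Tensors are stored as arma::fmat with one column per channel and one row
// per voxel (column-major voxel order matching R arrays).  Convolutions are
// evaluated as 27 shifted GEMMs, which keeps the toy-scale network (base 8
// features, 64^3 input) trainable in minutes on one core.
//
// Layer stack per level: two 3x3x3 convolutions, each followed by batch
// normalization and ReLU.  With batch size 1 the normalization statistics
// are per-channel spatial moments of the sample (used identically at train
// and inference time, so prediction is deterministic).  Levels are joined by
// 2x2x2 max-pooling (encoder) and 2x2x2 stride-2 upconvolution + skip
// concatenation (decoder); a final 1x1x1 convolution + sigmoid yields the
// probability map.  The loss is soft Dice with smoothing eps in numerator
// and denominator.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

struct Dims3 { int nx, ny, nz; R_xlen_t n() const { return (R_xlen_t)nx * ny * nz; } };

// out[v] = X[v + (dx,dy,dz)] with zero padding outside
static void shift_into(const fmat &X, fmat &out, const Dims3 &d, int dx,
                       int dy, int dz) {
  out.zeros(X.n_rows, X.n_cols);
  const int x0 = std::max(0, -dx), x1 = std::min(d.nx, d.nx - dx);
  if (x1 <= x0) return;
  const int run = x1 - x0;
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const float *src = X.colptr(c);
    float *dst = out.colptr(c);
    for (int k = 0; k < d.nz; ++k) {
      const int ks = k + dz;
      if (ks < 0 || ks >= d.nz) continue;
      for (int j = 0; j < d.ny; ++j) {
        const int js = j + dy;
        if (js < 0 || js >= d.ny) continue;
        const R_xlen_t doff = x0 + (R_xlen_t)d.nx * (j + (R_xlen_t)d.ny * k);
        const R_xlen_t soff =
            (x0 + dx) + (R_xlen_t)d.nx * (js + (R_xlen_t)d.ny * ks);
        std::memcpy(dst + doff, src + soff, run * sizeof(float));
      }
    }
  }
}

// weights for one 3x3x3 conv: vector of 27 (cin x cout) matrices, offset
// order o = (dx+1) + 3*(dy+1) + 9*(dz+1)
struct Conv3W {
  std::vector<fmat> W;
  frowvec b;
};

static Conv3W conv3_from_r(const NumericVector &w, const NumericVector &b) {
  IntegerVector dm = w.attr("dim");  // 3,3,3,cin,cout
  const int cin = dm[3], cout = dm[4];
  Conv3W cw;
  cw.W.assign(27, fmat(cin, cout));
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int oz = 0; oz < 3; ++oz)
        for (int oy = 0; oy < 3; ++oy)
          for (int ox = 0; ox < 3; ++ox)
            cw.W[ox + 3 * oy + 9 * oz](ci, co) =
                (float)w[ox + 3 * (oy + 3 * (oz + 3 * (ci + (R_xlen_t)cin * co)))];
  cw.b.set_size(cout);
  for (int co = 0; co < cout; ++co) cw.b(co) = (float)b[co];
  return cw;
}

static void conv3_to_r(const std::vector<fmat> &dW, const frowvec &db,
                       NumericVector &w, NumericVector &b) {
  IntegerVector dm = w.attr("dim");
  const int cin = dm[3], cout = dm[4];
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int oz = 0; oz < 3; ++oz)
        for (int oy = 0; oy < 3; ++oy)
          for (int ox = 0; ox < 3; ++ox)
            w[ox + 3 * (oy + 3 * (oz + 3 * (ci + (R_xlen_t)cin * co)))] =
                dW[ox + 3 * oy + 9 * oz](ci, co);
  for (int co = 0; co < cout; ++co) b[co] = db(co);
}

static fmat conv3_fwd(const fmat &X, const Conv3W &cw, const Dims3 &d,
                      fmat &buf) {
  fmat Y(X.n_rows, cw.b.n_elem);
  Y.each_row() = cw.b;
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
    shift_into(X, buf, d, dx, dy, dz);
    Y += buf * cw.W[o];
  }
  return Y;
}

static fmat conv3_bwd(const fmat &X, const fmat &dY, const Conv3W &cw,
                      const Dims3 &d, std::vector<fmat> &dW, frowvec &db,
                      fmat &buf) {
  dW.assign(27, fmat(X.n_cols, dY.n_cols, arma::fill::zeros));
  db = arma::sum(dY, 0);
  fmat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
    shift_into(X, buf, d, dx, dy, dz);
    dW[o] = buf.t() * dY;
    shift_into(dY, buf, d, -dx, -dy, -dz);
    dX += buf * cw.W[o].t();
  }
  return dX;
}

struct BNState {
  frowvec mu, istd;  // per channel
  fmat xhat;
};

static fmat bn_fwd(const fmat &X, const frowvec &gamma, const frowvec &beta,
                   BNState &st, float eps) {
  st.mu = arma::mean(X, 0);
  frowvec var = arma::mean(arma::square(X.each_row() - st.mu), 0);
  st.istd = 1.0f / arma::sqrt(var + eps);
  st.xhat = (X.each_row() - st.mu);
  st.xhat.each_row() %= st.istd;
  fmat Y = st.xhat;
  Y.each_row() %= gamma;
  Y.each_row() += beta;
  return Y;
}

static fmat bn_bwd(const fmat &dY, const frowvec &gamma, const BNState &st,
                   frowvec &dgamma, frowvec &dbeta) {
  dgamma = arma::sum(dY % st.xhat, 0);
  dbeta = arma::sum(dY, 0);
  const float n = (float)dY.n_rows;
  fmat dX = dY;
  dX.each_row() -= dbeta / n;
  fmat corr = st.xhat;
  corr.each_row() %= (dgamma / n);
  dX -= corr;
  dX.each_row() %= (gamma % st.istd);
  return dX;
}

static fmat pool_fwd(const fmat &X, const Dims3 &d, Dims3 &dd,
                     arma::umat &arg) {
  dd = {d.nx / 2, d.ny / 2, d.nz / 2};
  fmat Y(dd.n(), X.n_cols);
  arg.set_size(dd.n(), X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const float *src = X.colptr(c);
    float *dst = Y.colptr(c);
    arma::uword *am = arg.colptr(c);
    for (int k = 0; k < dd.nz; ++k)
      for (int j = 0; j < dd.ny; ++j)
        for (int i = 0; i < dd.nx; ++i) {
          float best = -1e30f;
          R_xlen_t bidx = 0;
          for (int oz = 0; oz < 2; ++oz)
            for (int oy = 0; oy < 2; ++oy)
              for (int ox = 0; ox < 2; ++ox) {
                const R_xlen_t s =
                    (2 * i + ox) +
                    (R_xlen_t)d.nx * ((2 * j + oy) + (R_xlen_t)d.ny * (2 * k + oz));
                if (src[s] > best) { best = src[s]; bidx = s; }
              }
          const R_xlen_t t = i + (R_xlen_t)dd.nx * (j + (R_xlen_t)dd.ny * k);
          dst[t] = best;
          am[t] = (arma::uword)bidx;
        }
  }
  return Y;
}

static fmat pool_bwd(const fmat &dY, const Dims3 &d, const arma::umat &arg) {
  fmat dX(d.n(), dY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    const float *g = dY.colptr(c);
    const arma::uword *am = arg.colptr(c);
    float *dst = dX.colptr(c);
    for (arma::uword t = 0; t < dY.n_rows; ++t) dst[am[t]] += g[t];
  }
  return dX;
}

// 2x2x2 stride-2 transposed convolution; weights: 8 (cin x cout) matrices
struct UpW {
  std::vector<fmat> W;
  frowvec b;
};

static UpW up_from_r(const NumericVector &w, const NumericVector &b) {
  IntegerVector dm = w.attr("dim");  // 2,2,2,cin,cout
  const int cin = dm[3], cout = dm[4];
  UpW uw;
  uw.W.assign(8, fmat(cin, cout));
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int oz = 0; oz < 2; ++oz)
        for (int oy = 0; oy < 2; ++oy)
          for (int ox = 0; ox < 2; ++ox)
            uw.W[ox + 2 * oy + 4 * oz](ci, co) =
                (float)w[ox + 2 * (oy + 2 * (oz + 2 * (ci + (R_xlen_t)cin * co)))];
  uw.b.set_size(cout);
  for (int co = 0; co < cout; ++co) uw.b(co) = (float)b[co];
  return uw;
}

static void up_to_r(const std::vector<fmat> &dW, const frowvec &db,
                    NumericVector &w, NumericVector &b) {
  IntegerVector dm = w.attr("dim");
  const int cin = dm[3], cout = dm[4];
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int oz = 0; oz < 2; ++oz)
        for (int oy = 0; oy < 2; ++oy)
          for (int ox = 0; ox < 2; ++ox)
            w[ox + 2 * (oy + 2 * (oz + 2 * (ci + (R_xlen_t)cin * co)))] =
                dW[ox + 2 * oy + 4 * oz](ci, co);
  for (int co = 0; co < cout; ++co) b[co] = db(co);
}

static void scatter_fine(const fmat &Yo, fmat &Y, const Dims3 &dc,
                         const Dims3 &df, int ox, int oy, int oz) {
  for (arma::uword c = 0; c < Yo.n_cols; ++c) {
    const float *src = Yo.colptr(c);
    float *dst = Y.colptr(c);
    for (int k = 0; k < dc.nz; ++k)
      for (int j = 0; j < dc.ny; ++j)
        for (int i = 0; i < dc.nx; ++i)
          dst[(2 * i + ox) +
              (R_xlen_t)df.nx * ((2 * j + oy) + (R_xlen_t)df.ny * (2 * k + oz))] +=
              src[i + (R_xlen_t)dc.nx * (j + (R_xlen_t)dc.ny * k)];
  }
}

static fmat gather_fine(const fmat &Y, const Dims3 &dc, const Dims3 &df,
                        int ox, int oy, int oz) {
  fmat G(dc.n(), Y.n_cols);
  for (arma::uword c = 0; c < Y.n_cols; ++c) {
    const float *src = Y.colptr(c);
    float *dst = G.colptr(c);
    for (int k = 0; k < dc.nz; ++k)
      for (int j = 0; j < dc.ny; ++j)
        for (int i = 0; i < dc.nx; ++i)
          dst[i + (R_xlen_t)dc.nx * (j + (R_xlen_t)dc.ny * k)] =
              src[(2 * i + ox) +
                  (R_xlen_t)df.nx * ((2 * j + oy) + (R_xlen_t)df.ny * (2 * k + oz))];
  }
  return G;
}

static fmat up_fwd(const fmat &X, const UpW &uw, const Dims3 &dc, Dims3 &df) {
  df = {2 * dc.nx, 2 * dc.ny, 2 * dc.nz};
  fmat Y(df.n(), uw.b.n_elem);
  Y.each_row() = uw.b;
  for (int o = 0; o < 8; ++o)
    scatter_fine(X * uw.W[o], Y, dc, df, o % 2, (o / 2) % 2, o / 4);
  return Y;
}

static fmat up_bwd(const fmat &X, const fmat &dY, const UpW &uw,
                   const Dims3 &dc, const Dims3 &df, std::vector<fmat> &dW,
                   frowvec &db) {
  dW.assign(8, fmat(X.n_cols, dY.n_cols));
  db = arma::sum(dY, 0);
  fmat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  for (int o = 0; o < 8; ++o) {
    fmat G = gather_fine(dY, dc, df, o % 2, (o / 2) % 2, o / 4);
    dW[o] = X.t() * G;
    dX += G * uw.W[o].t();
  }
  return dX;
}

// per-block saved state for backward
struct BlockState {
  Dims3 d;
  fmat x_in, h1_pre;  // input, pre-BN1 conv output
  BNState bn1, bn2;
  fmat r1;            // post-relu1 (input to conv2)
  fmat h2_pre;
  fmat out;           // post-relu2
};

struct BlockW {
  Conv3W c1, c2;
  frowvec g1, b1, g2, b2;
};

static BlockW block_from_r(List w, const std::string &pre) {
  BlockW bw;
  bw.c1 = conv3_from_r(w[pre + "_conv1_W"], w[pre + "_conv1_b"]);
  bw.c2 = conv3_from_r(w[pre + "_conv2_W"], w[pre + "_conv2_b"]);
  NumericVector g1 = w[pre + "_bn1_gamma"], b1 = w[pre + "_bn1_beta"];
  NumericVector g2 = w[pre + "_bn2_gamma"], b2 = w[pre + "_bn2_beta"];
  bw.g1 = arma::conv_to<frowvec>::from(as<std::vector<double>>(g1));
  bw.b1 = arma::conv_to<frowvec>::from(as<std::vector<double>>(b1));
  bw.g2 = arma::conv_to<frowvec>::from(as<std::vector<double>>(g2));
  bw.b2 = arma::conv_to<frowvec>::from(as<std::vector<double>>(b2));
  return bw;
}

static const float BN_EPS = 1e-5f;

static fmat block_fwd(const fmat &X, const BlockW &bw, const Dims3 &d,
                      BlockState &st, fmat &buf) {
  st.d = d;
  st.x_in = X;
  st.h1_pre = conv3_fwd(X, bw.c1, d, buf);
  fmat h1 = bn_fwd(st.h1_pre, bw.g1, bw.b1, st.bn1, BN_EPS);
  st.r1 = arma::clamp(h1, 0.0f, 1e30f);
  st.h2_pre = conv3_fwd(st.r1, bw.c2, d, buf);
  fmat h2 = bn_fwd(st.h2_pre, bw.g2, bw.b2, st.bn2, BN_EPS);
  st.out = arma::clamp(h2, 0.0f, 1e30f);
  return st.out;
}

struct BlockG {
  std::vector<fmat> dW1, dW2;
  frowvec db1, db2, dg1, dbt1, dg2, dbt2;
};

static fmat block_bwd(const fmat &dOut, const BlockW &bw, BlockState &st,
                      BlockG &g, fmat &buf) {
  fmat d2 = dOut % arma::conv_to<fmat>::from(st.out > 0);
  fmat dh2 = bn_bwd(d2, bw.g2, st.bn2, g.dg2, g.dbt2);
  fmat dr1 = conv3_bwd(st.r1, dh2, bw.c2, st.d, g.dW2, g.db2, buf);
  dr1 %= arma::conv_to<fmat>::from(st.r1 > 0);
  fmat dh1 = bn_bwd(dr1, bw.g1, st.bn1, g.dg1, g.dbt1);
  return conv3_bwd(st.x_in, dh1, bw.c1, st.d, g.dW1, g.db1, buf);
}

struct GradAcc {
  std::vector<std::string> names;
  std::vector<Rcpp::RObject> vals;  // RObject preserves against GC
  void add(const std::string &nm, SEXP v) {
    names.push_back(nm);
    vals.push_back(Rcpp::RObject(v));
  }
  List as_list() const {
    List out(vals.size());
    CharacterVector nm(vals.size());
    for (size_t i = 0; i < vals.size(); ++i) { out[i] = vals[i]; nm[i] = names[i]; }
    out.attr("names") = nm;
    return out;
  }
};

static void block_to_r(const BlockG &g, GradAcc &grads, const std::string &pre,
                       List shapes) {
  NumericVector w1 = clone(as<NumericVector>(shapes[pre + "_conv1_W"]));
  NumericVector b1 = clone(as<NumericVector>(shapes[pre + "_conv1_b"]));
  conv3_to_r(g.dW1, g.db1, w1, b1);
  grads.add(pre + "_conv1_W", w1);
  grads.add(pre + "_conv1_b", b1);
  NumericVector w2 = clone(as<NumericVector>(shapes[pre + "_conv2_W"]));
  NumericVector b2 = clone(as<NumericVector>(shapes[pre + "_conv2_b"]));
  conv3_to_r(g.dW2, g.db2, w2, b2);
  grads.add(pre + "_conv2_W", w2);
  grads.add(pre + "_conv2_b", b2);
  grads.add(pre + "_bn1_gamma", NumericVector(g.dg1.begin(), g.dg1.end()));
  grads.add(pre + "_bn1_beta", NumericVector(g.dbt1.begin(), g.dbt1.end()));
  grads.add(pre + "_bn2_gamma", NumericVector(g.dg2.begin(), g.dg2.end()));
  grads.add(pre + "_bn2_beta", NumericVector(g.dbt2.begin(), g.dbt2.end()));
}

// [[Rcpp::export]]
List cpp_unet_run(List weights, NumericVector x, IntegerVector dims, int depth,
                  NumericVector target, bool want_grads, double dice_eps) {
  Dims3 d0 = {dims[0], dims[1], dims[2]};
  const R_xlen_t nvox = d0.n();
  fmat X(nvox, 1);
  for (R_xlen_t v = 0; v < nvox; ++v) X(v, 0) = (float)x[v];

  std::vector<BlockW> encW(depth), decW(depth - 1);
  std::vector<UpW> upW(depth - 1);
  for (int l = 0; l < depth; ++l)
    encW[l] = block_from_r(weights, "enc" + std::to_string(l + 1));
  for (int l = 0; l < depth - 1; ++l) {
    decW[l] = block_from_r(weights, "dec" + std::to_string(l + 1));
    upW[l] = up_from_r(weights["dec" + std::to_string(l + 1) + "_up_W"],
                       weights["dec" + std::to_string(l + 1) + "_up_b"]);
  }
  Conv3W outW;  // 1x1x1 conv stored as plain matrix
  NumericVector ow = weights["out_W"], ob = weights["out_b"];
  IntegerVector owd = ow.attr("dim");  // cin x 1
  fmat Wout(owd[0], 1);
  for (int ci = 0; ci < owd[0]; ++ci) Wout(ci, 0) = (float)ow[ci];
  const float bout = (float)ob[0];

  fmat buf;
  std::vector<BlockState> encS(depth), decS(depth - 1);
  std::vector<Dims3> lvl(depth);
  std::vector<arma::umat> poolArg(depth - 1);
  std::vector<fmat> poolIn(depth - 1);

  // encoder
  lvl[0] = d0;
  fmat cur = X;
  for (int l = 0; l < depth; ++l) {
    cur = block_fwd(cur, encW[l], lvl[l], encS[l], buf);
    if (l < depth - 1) {
      poolIn[l] = cur;
      Dims3 dd;
      cur = pool_fwd(cur, lvl[l], dd, poolArg[l]);
      lvl[l + 1] = dd;
    }
  }
  // decoder
  std::vector<fmat> upIn(depth - 1), catIn(depth - 1);
  std::vector<Dims3> upDc(depth - 1);
  for (int l = depth - 2; l >= 0; --l) {
    upIn[l] = cur;
    upDc[l] = lvl[l + 1];
    Dims3 df;
    fmat up = up_fwd(cur, upW[l], lvl[l + 1], df);
    fmat cat = arma::join_rows(encS[l].out, up);
    catIn[l] = cat;
    cur = block_fwd(cat, decW[l], lvl[l], decS[l], buf);
  }
  // head
  fmat z = cur * Wout;
  z += bout;
  fmat p = 1.0f / (1.0f + arma::exp(-z));

  NumericVector pred(nvox);
  for (R_xlen_t v = 0; v < nvox; ++v) pred[v] = p(v, 0);

  double loss = NA_REAL;
  GradAcc grads;
  if (target.size() > 0) {
    double spt = 0.0, sp = 0.0, st = 0.0;
    for (R_xlen_t v = 0; v < nvox; ++v) {
      spt += (double)p(v, 0) * target[v];
      sp += p(v, 0);
      st += target[v];
    }
    const double N = 2.0 * spt + dice_eps, D = sp + st + dice_eps;
    loss = 1.0 - N / D;
    if (want_grads) {
      // dL/dp = -(2 t D - N) / D^2 ; chain through sigmoid
      fmat dz(nvox, 1);
      const double iD2 = 1.0 / (D * D);
      for (R_xlen_t v = 0; v < nvox; ++v) {
        const double dldp = -(2.0 * target[v] * D - N) * iD2;
        dz(v, 0) = (float)(dldp * p(v, 0) * (1.0 - p(v, 0)));
      }
      fmat dcur = dz * Wout.t();
      fmat dWout = cur.t() * dz;
      NumericVector gow = clone(ow), gob = clone(ob);
      for (int ci = 0; ci < owd[0]; ++ci) gow[ci] = dWout(ci, 0);
      gob[0] = arma::accu(dz);
      grads.add("out_W", gow);
      grads.add("out_b", gob);
      // decoder backward
      for (int l = 0; l < depth - 1; ++l) {
        BlockG g;
        fmat dcat = block_bwd(dcur, decW[l], decS[l], g, buf);
        block_to_r(g, grads, "dec" + std::to_string(l + 1), weights);
        const int cskip = encS[l].out.n_cols;
        fmat dskip = dcat.cols(0, cskip - 1);
        fmat dup = dcat.cols(cskip, dcat.n_cols - 1);
        std::vector<fmat> dWu;
        frowvec dbu;
        Dims3 df = {2 * upDc[l].nx, 2 * upDc[l].ny, 2 * upDc[l].nz};
        fmat dupin = up_bwd(upIn[l], dup, upW[l], upDc[l], df, dWu, dbu);
        NumericVector uwv =
            clone(as<NumericVector>(weights["dec" + std::to_string(l + 1) + "_up_W"]));
        NumericVector ubv =
            clone(as<NumericVector>(weights["dec" + std::to_string(l + 1) + "_up_b"]));
        up_to_r(dWu, dbu, uwv, ubv);
        grads.add("dec" + std::to_string(l + 1) + "_up_W", uwv);
        grads.add("dec" + std::to_string(l + 1) + "_up_b", ubv);
        decS[l].x_in.reset();
        catIn[l] = dskip;  // skip-connection gradient, consumed below
        dcur = dupin;
      }
      // encoder backward (deepest first)
      fmat denc = dcur;  // gradient into enc block depth-1 output (bottom)
      for (int l = depth - 1; l >= 0; --l) {
        fmat dout;
        if (l == depth - 1) {
          dout = denc;
        } else {
          // gradient from pooling path + skip connection
          fmat dpool = pool_bwd(denc, lvl[l], poolArg[l]);
          dout = dpool + catIn[l];
        }
        BlockG g;
        denc = block_bwd(dout, encW[l], encS[l], g, buf);
        block_to_r(g, grads, "enc" + std::to_string(l + 1), weights);
      }
    }
  }
  return List::create(_["pred"] = pred, _["loss"] = loss,
                      _["grads"] = grads.as_list());
}
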