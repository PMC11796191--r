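// Compact U-Net with reflection-padded 3x3 convolutions, batch
// normalisation, leaky ReLU, 2x2 max-pooling, nearest-neighbour upsampling
// and a softmax head, trained with Adam under a class-weighted soft Dice
// loss. Weights live in an R list (one entry per convolution, in fixed
// topology order); every epoch is run here and the updated state handed
// back, so all randomness (init, shuffling, augmentation) stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static inline int reflect_idx(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

struct ConvParams {
  mat W; vec b; int k; bool bn;
  vec gamma, beta, rmean, rvar;
};

struct ConvGrads {
  mat W; vec b; vec gamma, beta;
  void init(const ConvParams& p) {
    W.zeros(p.W.n_rows, p.W.n_cols); b.zeros(p.b.n_elem);
    if (p.bn) { gamma.zeros(p.gamma.n_elem); beta.zeros(p.beta.n_elem); }
  }
};

struct ConvCache {
  std::vector<cube> x, a, xhat;
  vec invstd;
  int H, W_, Cin;
};

struct AdamMoments { mat mW, vW; vec mb, vb, mg, vg, mbe, vbe; };

// ---- tensor plumbing -------------------------------------------------------

static mat im2col(const cube& x, int k) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (k == 1) {
    mat out(C, H * W);
    for (int ci = 0; ci < C; ++ci)
      out.row(ci) = arma::vectorise(x.slice(ci)).t();
    return out;
  }
  mat out(C * 9, H * W);
  for (int ci = 0; ci < C; ++ci) {
    const mat& s = x.slice(ci);
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        int row = ci * 9 + (dr + 1) * 3 + (dc + 1);
        for (int c = 0; c < W; ++c) {
          int cc = reflect_idx(c + dc, W);
          for (int r = 0; r < H; ++r) {
            out(row, r + c * H) = s(reflect_idx(r + dr, H), cc);
          }
        }
      }
    }
  }
  return out;
}

static cube col2im_back(const mat& dcol, int H, int W, int Cin, int k) {
  cube dx(H, W, Cin, arma::fill::zeros);
  if (k == 1) {
    for (int ci = 0; ci < Cin; ++ci)
      dx.slice(ci) = arma::reshape(dcol.row(ci), H, W);
    return dx;
  }
  for (int ci = 0; ci < Cin; ++ci) {
    mat& s = dx.slice(ci);
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        int row = ci * 9 + (dr + 1) * 3 + (dc + 1);
        for (int c = 0; c < W; ++c) {
          int cc = reflect_idx(c + dc, W);
          for (int r = 0; r < H; ++r) {
            s(reflect_idx(r + dr, H), cc) += dcol(row, r + c * H);
          }
        }
      }
    }
  }
  return dx;
}

static cube mat2cube(const mat& m, int H, int W) {
  cube out(H, W, m.n_rows);
  for (arma::uword ci = 0; ci < m.n_rows; ++ci)
    out.slice(ci) = arma::reshape(m.row(ci), H, W);
  return out;
}

static mat cube2mat(const cube& x) {
  mat out(x.n_slices, x.n_rows * x.n_cols);
  for (arma::uword ci = 0; ci < x.n_slices; ++ci)
    out.row(ci) = arma::vectorise(x.slice(ci)).t();
  return out;
}

// ---- layers ----------------------------------------------------------------

static std::vector<cube> conv_fwd(ConvParams& P, const std::vector<cube>& xin,
                                  ConvCache& C, bool training, bool act,
                                  double slope, double mom, double bneps) {
  int nb = xin.size();
  int H = xin[0].n_rows, W = xin[0].n_cols;
  int Cout = P.W.n_rows;
  C.H = H; C.W_ = W; C.Cin = xin[0].n_slices;
  std::vector<cube> s(nb);
  for (int b = 0; b < nb; ++b) {
    mat S = P.W * im2col(xin[b], P.k);
    S.each_col() += P.b;
    s[b] = mat2cube(S, H, W);
  }
  if (training) C.x = xin;
  std::vector<cube> y = s;
  if (P.bn) {
    double M = (double)nb * H * W;
    vec mu(Cout), var_(Cout);
    if (training) {
      mu.zeros(); var_.zeros();
      for (int b = 0; b < nb; ++b)
        for (int ci = 0; ci < Cout; ++ci) mu(ci) += arma::accu(s[b].slice(ci));
      mu /= M;
      for (int b = 0; b < nb; ++b)
        for (int ci = 0; ci < Cout; ++ci)
          var_(ci) += arma::accu(arma::square(s[b].slice(ci) - mu(ci)));
      var_ /= M;
      P.rmean = mom * P.rmean + (1.0 - mom) * mu;
      P.rvar = mom * P.rvar + (1.0 - mom) * var_;
    } else {
      mu = P.rmean; var_ = P.rvar;
    }
    vec invstd = 1.0 / arma::sqrt(var_ + bneps);
    if (training) { C.invstd = invstd; C.xhat.resize(nb); }
    for (int b = 0; b < nb; ++b) {
      cube xh(H, W, Cout);
      for (int ci = 0; ci < Cout; ++ci)
        xh.slice(ci) = (s[b].slice(ci) - mu(ci)) * invstd(ci);
      if (training) C.xhat[b] = xh;
      for (int ci = 0; ci < Cout; ++ci)
        y[b].slice(ci) = P.gamma(ci) * xh.slice(ci) + P.beta(ci);
    }
  }
  if (act) {
    for (int b = 0; b < nb; ++b)
      y[b] = arma::max(y[b], slope * y[b]);
  }
  if (training) C.a = y;
  return y;
}

static std::vector<cube> conv_bwd(const ConvParams& P, ConvGrads& G,
                                  const ConvCache& C,
                                  const std::vector<cube>& da,
                                  bool act, double slope) {
  int nb = da.size();
  int H = C.H, W = C.W_;
  int Cout = P.W.n_rows;
  std::vector<cube> dy(nb);
  for (int b = 0; b < nb; ++b) {
    if (act) {
      cube d = da[b];
      for (arma::uword i = 0; i < d.n_elem; ++i)
        if (C.a[b](i) <= 0) d(i) *= slope;
      dy[b] = d;
    } else dy[b] = da[b];
  }
  std::vector<cube> ds(nb);
  if (P.bn) {
    double M = (double)nb * H * W;
    vec sum1(Cout, arma::fill::zeros), sum2(Cout, arma::fill::zeros);
    for (int b = 0; b < nb; ++b) {
      for (int ci = 0; ci < Cout; ++ci) {
        const mat dxh = dy[b].slice(ci) * P.gamma(ci);
        sum1(ci) += arma::accu(dxh);
        sum2(ci) += arma::accu(dxh % C.xhat[b].slice(ci));
        G.gamma(ci) += arma::accu(dy[b].slice(ci) % C.xhat[b].slice(ci));
        G.beta(ci) += arma::accu(dy[b].slice(ci));
      }
    }
    for (int b = 0; b < nb; ++b) {
      ds[b].set_size(H, W, Cout);
      for (int ci = 0; ci < Cout; ++ci) {
        mat dxh = dy[b].slice(ci) * P.gamma(ci);
        ds[b].slice(ci) = C.invstd(ci) *
          (dxh - (sum1(ci) + C.xhat[b].slice(ci) * sum2(ci)) / M);
      }
    }
  } else ds = dy;
  std::vector<cube> dx(nb);
  for (int b = 0; b < nb; ++b) {
    mat dsm = cube2mat(ds[b]);
    G.W += dsm * im2col(C.x[b], P.k).t();
    G.b += arma::sum(dsm, 1);
    dx[b] = col2im_back(P.W.t() * dsm, H, W, C.Cin, P.k);
  }
  return dx;
}

struct PoolCache { std::vector<arma::ucube> idx; };

static std::vector<cube> maxpool2(const std::vector<cube>& x, PoolCache& pc) {
  int nb = x.size();
  int H = x[0].n_rows, W = x[0].n_cols, C = x[0].n_slices;
  int h = H / 2, w = W / 2;
  std::vector<cube> out(nb);
  pc.idx.resize(nb);
  for (int b = 0; b < nb; ++b) {
    out[b].set_size(h, w, C);
    pc.idx[b].set_size(h, w, C);
    for (int ci = 0; ci < C; ++ci) {
      const mat& s = x[b].slice(ci);
      for (int c = 0; c < w; ++c) {
        for (int r = 0; r < h; ++r) {
          double best = s(2 * r, 2 * c);
          int br = 2 * r, bc = 2 * c;
          for (int i = 0; i < 2; ++i)
            for (int j = 0; j < 2; ++j)
              if (s(2 * r + i, 2 * c + j) > best) {
                best = s(2 * r + i, 2 * c + j);
                br = 2 * r + i; bc = 2 * c + j;
              }
          out[b](r, c, ci) = best;
          pc.idx[b](r, c, ci) = br + bc * H;
        }
      }
    }
  }
  return out;
}

static std::vector<cube> maxpool2_back(const std::vector<cube>& g,
                                       const PoolCache& pc, int H, int W) {
  int nb = g.size();
  int C = g[0].n_slices;
  std::vector<cube> out(nb);
  for (int b = 0; b < nb; ++b) {
    out[b].zeros(H, W, C);
    for (int ci = 0; ci < C; ++ci) {
      mat& s = out[b].slice(ci);
      for (arma::uword c = 0; c < g[b].n_cols; ++c)
        for (arma::uword r = 0; r < g[b].n_rows; ++r)
          s(pc.idx[b](r, c, ci)) += g[b](r, c, ci);
    }
  }
  return out;
}

static std::vector<cube> upsample2(const std::vector<cube>& x) {
  int nb = x.size();
  int H = x[0].n_rows, W = x[0].n_cols, C = x[0].n_slices;
  std::vector<cube> out(nb);
  for (int b = 0; b < nb; ++b) {
    out[b].set_size(2 * H, 2 * W, C);
    for (int ci = 0; ci < C; ++ci)
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          double v = x[b](r, c, ci);
          out[b](2 * r, 2 * c, ci) = v;
          out[b](2 * r + 1, 2 * c, ci) = v;
          out[b](2 * r, 2 * c + 1, ci) = v;
          out[b](2 * r + 1, 2 * c + 1, ci) = v;
        }
  }
  return out;
}

static std::vector<cube> upsample2_back(const std::vector<cube>& g) {
  int nb = g.size();
  int H = g[0].n_rows / 2, W = g[0].n_cols / 2, C = g[0].n_slices;
  std::vector<cube> out(nb);
  for (int b = 0; b < nb; ++b) {
    out[b].set_size(H, W, C);
    for (int ci = 0; ci < C; ++ci)
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r)
          out[b](r, c, ci) = g[b](2 * r, 2 * c, ci) + g[b](2 * r + 1, 2 * c, ci)
            + g[b](2 * r, 2 * c + 1, ci) + g[b](2 * r + 1, 2 * c + 1, ci);
  }
  return out;
}

static std::vector<cube> concat_ch(const std::vector<cube>& a,
                                   const std::vector<cube>& b) {
  int nb = a.size();
  std::vector<cube> out(nb);
  for (int i = 0; i < nb; ++i) out[i] = arma::join_slices(a[i], b[i]);
  return out;
}

static void softmax_inplace(cube& z) {
  int H = z.n_rows, W = z.n_cols, C = z.n_slices;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double mx = z(r, c, 0);
      for (int ci = 1; ci < C; ++ci) mx = std::max(mx, z(r, c, ci));
      double s = 0;
      for (int ci = 0; ci < C; ++ci) {
        double e = std::exp(z(r, c, ci) - mx);
        z(r, c, ci) = e; s += e;
      }
      for (int ci = 0; ci < C; ++ci) z(r, c, ci) /= s;
    }
}

// ---- state (de)serialisation ----------------------------------------------

static std::vector<ConvParams> load_layers(List layers) {
  std::vector<ConvParams> out(layers.size());
  for (int i = 0; i < layers.size(); ++i) {
    List li = layers[i];
    out[i].W = as<mat>(li["W"]);
    out[i].b = as<vec>(li["b"]);
    out[i].k = as<int>(li["k"]);
    out[i].bn = as<bool>(li["bn"]);
    if (out[i].bn) {
      out[i].gamma = as<vec>(li["gamma"]);
      out[i].beta = as<vec>(li["beta"]);
      out[i].rmean = as<vec>(li["rmean"]);
      out[i].rvar = as<vec>(li["rvar"]);
    }
  }
  return out;
}

static List save_layers(const std::vector<ConvParams>& ps, List proto) {
  List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    List li = clone(as<List>(proto[i]));
    li["W"] = wrap(ps[i].W);
    li["b"] = wrap(ps[i].b);
    if (ps[i].bn) {
      li["gamma"] = wrap(ps[i].gamma);
      li["beta"] = wrap(ps[i].beta);
      li["rmean"] = wrap(ps[i].rmean);
      li["rvar"] = wrap(ps[i].rvar);
    }
    out[i] = li;
  }
  out.attr("names") = proto.attr("names");
  return out;
}

static cube arr2cube(NumericVector a) {
  IntegerVector d = a.attr("dim");
  cube out(d[0], d[1], d.size() == 3 ? d[2] : 1);
  std::copy(a.begin(), a.end(), out.memptr());
  return out;
}

static NumericVector cube2arr(const cube& x) {
  NumericVector out(x.n_elem);
  std::copy(x.memptr(), x.memptr() + x.n_elem, out.begin());
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

// ---- forward over the U topology -------------------------------------------

struct FwdState {
  std::vector<ConvCache> cc;
  std::vector<PoolCache> pc;
  std::vector<std::vector<cube>> skips;
  std::vector<int> preH, preW;   // spatial dims entering each pool
};

static std::vector<cube> unet_forward_batch(std::vector<ConvParams>& P,
                                            int depth, double slope,
                                            double mom, double bneps,
                                            const std::vector<cube>& X,
                                            bool training, FwdState& st) {
  int nconv = P.size();
  st.cc.resize(nconv);
  st.pc.resize(depth);
  st.skips.resize(depth);
  st.preH.resize(depth);
  st.preW.resize(depth);
  int idx = 0;
  std::vector<cube> cur = X;
  for (int d = 0; d < depth; ++d) {
    cur = conv_fwd(P[idx], cur, st.cc[idx], training, true, slope, mom, bneps); ++idx;
    cur = conv_fwd(P[idx], cur, st.cc[idx], training, true, slope, mom, bneps); ++idx;
    st.skips[d] = cur;
    st.preH[d] = cur[0].n_rows; st.preW[d] = cur[0].n_cols;
    cur = maxpool2(cur, st.pc[d]);
  }
  cur = conv_fwd(P[idx], cur, st.cc[idx], training, true, slope, mom, bneps); ++idx;
  cur = conv_fwd(P[idx], cur, st.cc[idx], training, true, slope, mom, bneps); ++idx;
  for (int d = depth - 1; d >= 0; --d) {
    cur = upsample2(cur);
    cur = conv_fwd(P[idx], cur, st.cc[idx], training, true, slope, mom, bneps); ++idx;
    cur = concat_ch(cur, st.skips[d]);
    cur = conv_fwd(P[idx], cur, st.cc[idx], training, true, slope, mom, bneps); ++idx;
    cur = conv_fwd(P[idx], cur, st.cc[idx], training, true, slope, mom, bneps); ++idx;
  }
  cur = conv_fwd(P[idx], cur, st.cc[idx], training, false, slope, mom, bneps); ++idx;
  for (auto& z : cur) softmax_inplace(z);
  return cur;
}

static void unet_backward_batch(std::vector<ConvParams>& P,
                                std::vector<ConvGrads>& G,
                                int depth, double slope, FwdState& st,
                                const std::vector<cube>& dlogits) {
  int idx = P.size() - 1;
  std::vector<cube> g = conv_bwd(P[idx], G[idx], st.cc[idx], dlogits, false, slope); --idx;
  std::vector<std::vector<cube>> skip_g(depth);
  for (int d = 0; d < depth; ++d) {
    g = conv_bwd(P[idx], G[idx], st.cc[idx], g, true, slope); --idx;
    g = conv_bwd(P[idx], G[idx], st.cc[idx], g, true, slope); --idx;
    // split concat: first channels were the upsampled path
    int nb = g.size();
    int Cskip = st.skips[d][0].n_slices;
    int Cup = g[0].n_slices - Cskip;
    std::vector<cube> gup(nb);
    skip_g[d].resize(nb);
    for (int b = 0; b < nb; ++b) {
      gup[b] = g[b].slices(0, Cup - 1);
      skip_g[d][b] = g[b].slices(Cup, Cup + Cskip - 1);
    }
    gup = conv_bwd(P[idx], G[idx], st.cc[idx], gup, true, slope); --idx;
    g = upsample2_back(gup);
  }
  g = conv_bwd(P[idx], G[idx], st.cc[idx], g, true, slope); --idx;
  g = conv_bwd(P[idx], G[idx], st.cc[idx], g, true, slope); --idx;
  for (int d = depth - 1; d >= 0; --d) {
    g = maxpool2_back(g, st.pc[d], st.preH[d], st.preW[d]);
    for (size_t b = 0; b < g.size(); ++b) g[b] += skip_g[d][b];
    g = conv_bwd(P[idx], G[idx], st.cc[idx], g, true, slope); --idx;
    g = conv_bwd(P[idx], G[idx], st.cc[idx], g, true, slope); --idx;
  }
}

// ---- weighted soft Dice loss over a pooled batch ---------------------------

static double dice_loss_grad(const std::vector<cube>& p,
                             const std::vector<cube>& g,
                             const std::vector<mat>& use,
                             const vec& wnorm, double eps,
                             std::vector<cube>& dp) {
  int nb = p.size(), C = p[0].n_slices;
  vec S(C, arma::fill::zeros), Psum(C, arma::fill::zeros), Gsum(C, arma::fill::zeros);
  for (int b = 0; b < nb; ++b)
    for (int ci = 0; ci < C; ++ci) {
      S(ci) += arma::accu(use[b] % p[b].slice(ci) % g[b].slice(ci));
      Psum(ci) += arma::accu(use[b] % p[b].slice(ci));
      Gsum(ci) += arma::accu(use[b] % g[b].slice(ci));
    }
  double loss = 1.0;
  vec D = Psum + Gsum + eps;
  for (int ci = 0; ci < C; ++ci)
    loss -= wnorm(ci) * (2.0 * S(ci) + eps) / D(ci);
  dp.resize(nb);
  for (int b = 0; b < nb; ++b) {
    dp[b].set_size(p[b].n_rows, p[b].n_cols, C);
    for (int ci = 0; ci < C; ++ci) {
      double d = D(ci);
      dp[b].slice(ci) = -wnorm(ci) *
        ((2.0 * g[b].slice(ci) * d - (2.0 * S(ci) + eps)) / (d * d)) % use[b];
    }
  }
  return loss;
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_unet_forward(List layers, List cfg, NumericVector x) {
  std::vector<ConvParams> P = load_layers(layers);
  int depth = as<int>(cfg["depth"]);
  double slope = as<double>(cfg["slope"]);
  double bneps = as<double>(cfg["bn_eps"]);
  FwdState st;
  std::vector<cube> X(1, arr2cube(x));
  std::vector<cube> out = unet_forward_batch(P, depth, slope, 0.9, bneps, X, false, st);
  return cube2arr(out[0]);
}

// [[Rcpp::export]]
List cpp_unet_train_epoch(List layers, List adam, List cfg,
                          List xs, List gs, List igns, List batches,
                          double lr, NumericVector class_w, int t_start) {
  std::vector<ConvParams> P = load_layers(layers);
  int depth = as<int>(cfg["depth"]);
  double slope = as<double>(cfg["slope"]);
  double bneps = as<double>(cfg["bn_eps"]);
  double mom = as<double>(cfg["bn_momentum"]);
  double eps_dice = as<double>(cfg["dice_eps"]);
  vec w = as<vec>(class_w);
  vec wnorm = w / arma::accu(w);

  int nconv = P.size();
  std::vector<AdamMoments> M(nconv);
  bool fresh = (adam.size() == 0);
  for (int i = 0; i < nconv; ++i) {
    if (fresh) {
      M[i].mW.zeros(P[i].W.n_rows, P[i].W.n_cols);
      M[i].vW.zeros(P[i].W.n_rows, P[i].W.n_cols);
      M[i].mb.zeros(P[i].b.n_elem); M[i].vb.zeros(P[i].b.n_elem);
      if (P[i].bn) {
        M[i].mg.zeros(P[i].gamma.n_elem); M[i].vg.zeros(P[i].gamma.n_elem);
        M[i].mbe.zeros(P[i].beta.n_elem); M[i].vbe.zeros(P[i].beta.n_elem);
      }
    } else {
      List ai = adam[i];
      M[i].mW = as<mat>(ai["mW"]); M[i].vW = as<mat>(ai["vW"]);
      M[i].mb = as<vec>(ai["mb"]); M[i].vb = as<vec>(ai["vb"]);
      if (P[i].bn) {
        M[i].mg = as<vec>(ai["mg"]); M[i].vg = as<vec>(ai["vg"]);
        M[i].mbe = as<vec>(ai["mbe"]); M[i].vbe = as<vec>(ai["vbe"]);
      }
    }
  }

  const double b1 = 0.9, b2 = 0.999, aeps = 1e-8;
  int t = t_start;
  NumericVector losses(batches.size());

  for (int bi = 0; bi < batches.size(); ++bi) {
    IntegerVector sel = batches[bi];
    int nb = sel.size();
    std::vector<cube> X(nb), Gt(nb);
    std::vector<mat> use(nb);
    for (int b = 0; b < nb; ++b) {
      X[b] = arr2cube(xs[sel[b] - 1]);
      Gt[b] = arr2cube(gs[sel[b] - 1]);
      RObject ig = igns[sel[b] - 1];
      if (ig.isNULL()) use[b].ones(X[b].n_rows, X[b].n_cols);
      else use[b] = as<mat>(ig);
    }
    FwdState st;
    std::vector<cube> probs = unet_forward_batch(P, depth, slope, mom, bneps, X, true, st);
    std::vector<cube> dp;
    double loss = dice_loss_grad(probs, Gt, use, wnorm, eps_dice, dp);
    if (!std::isfinite(loss)) stop("training loss became non-finite");
    losses[bi] = loss;
    // softmax backward: dz = p * (dp - sum_c dp_c p_c)
    std::vector<cube> dz(nb);
    int C = probs[0].n_slices;
    for (int b = 0; b < nb; ++b) {
      mat inner(probs[b].n_rows, probs[b].n_cols, arma::fill::zeros);
      for (int ci = 0; ci < C; ++ci)
        inner += dp[b].slice(ci) % probs[b].slice(ci);
      dz[b].set_size(probs[b].n_rows, probs[b].n_cols, C);
      for (int ci = 0; ci < C; ++ci)
        dz[b].slice(ci) = probs[b].slice(ci) % (dp[b].slice(ci) - inner);
    }
    std::vector<ConvGrads> G(nconv);
    for (int i = 0; i < nconv; ++i) G[i].init(P[i]);
    unet_backward_batch(P, G, depth, slope, st, dz);

    ++t;
    double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
    for (int i = 0; i < nconv; ++i) {
      M[i].mW = b1 * M[i].mW + (1 - b1) * G[i].W;
      M[i].vW = b2 * M[i].vW + (1 - b2) * arma::square(G[i].W);
      P[i].W -= lr * (M[i].mW / bc1) / (arma::sqrt(M[i].vW / bc2) + aeps);
      M[i].mb = b1 * M[i].mb + (1 - b1) * G[i].b;
      M[i].vb = b2 * M[i].vb + (1 - b2) * arma::square(G[i].b);
      P[i].b -= lr * (M[i].mb / bc1) / (arma::sqrt(M[i].vb / bc2) + aeps);
      if (P[i].bn) {
        M[i].mg = b1 * M[i].mg + (1 - b1) * G[i].gamma;
        M[i].vg = b2 * M[i].vg + (1 - b2) * arma::square(G[i].gamma);
        P[i].gamma -= lr * (M[i].mg / bc1) / (arma::sqrt(M[i].vg / bc2) + aeps);
        M[i].mbe = b1 * M[i].mbe + (1 - b1) * G[i].beta;
        M[i].vbe = b2 * M[i].vbe + (1 - b2) * arma::square(G[i].beta);
        P[i].beta -= lr * (M[i].mbe / bc1) / (arma::sqrt(M[i].vbe / bc2) + aeps);
      }
    }
  }

  List adam_out(nconv);
  for (int i = 0; i < nconv; ++i) {
    if (P[i].bn) {
      adam_out[i] = List::create(_["mW"] = M[i].mW, _["vW"] = M[i].vW,
                                 _["mb"] = M[i].mb, _["vb"] = M[i].vb,
                                 _["mg"] = M[i].mg, _["vg"] = M[i].vg,
                                 _["mbe"] = M[i].mbe, _["vbe"] = M[i].vbe);
    } else {
      adam_out[i] = List::create(_["mW"] = M[i].mW, _["vW"] = M[i].vW,
                                 _["mb"] = M[i].mb, _["vb"] = M[i].vb);
    }
  }
  return List::create(_["layers"] = save_layers(P, layers),
                      _["adam"] = adam_out,
                      _["losses"] = losses,
                      _["t"] = t);
}
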