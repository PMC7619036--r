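#include <Rcpp.h>
#include <random>
#include <algorithm>
#include "tinymat.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Multi-class variational point-cloud autoencoder.
//
// Encoder: two stacked PointNet-style blocks (shared per-point MLP ->
// symmetric max-pool -> global feature concatenated back onto each point)
// with an additive residual connection, followed by an MLP head that emits
// the mean and log-variance of a diagonal Gaussian posterior.
//
// Decoder: an MLP maps the latent vector to a coarse point cloud of
// m_coarse points x 3 coords x (phases * n_classes) channels; a shared
// folding network then places a grid_side^2 patch around every coarse
// anchor and deforms it conditioned on the latent vector, the channel
// identity, and the anchor position, giving the dense output.
//
// Loss: per-channel symmetric squared Chamfer (coarse + alpha * dense),
// summed over channels, plus beta * KL(q(z|x) || N(0, I)) with the KL taken
// as a sum over latent dimensions.  All kernels are scalar C++ so a fixed
// seed reproduces training bit-for-bit on a single CPU.
// ---------------------------------------------------------------------------

struct VaeCfg {
  int L, C, T, K, we, hh, m, gs, wf, hd, fin, p;
  double cs, gext, beta, a0, a1, ramp, beta_warmup, mu_gain, loss_unit;
  double lr, b1, b2, eps;
  int total_steps, batch, train_points, target_points, val_every;
  int fold_cells_train;
  double lr_decay;
  double lv_min = -12.0, lv_max = 8.0;
};

static VaeCfg parse_cfg(const List& cfg) {
  VaeCfg c;
  c.L = as<int>(cfg["latent_dim"]);
  c.C = as<int>(cfg["n_classes"]);
  c.T = as<int>(cfg["phases"]);
  c.K = c.C * c.T;
  c.we = as<int>(cfg["enc_width"]);
  c.hh = as<int>(cfg["enc_hidden"]);
  c.m = as<int>(cfg["m_coarse"]);
  c.gs = as<int>(cfg["grid_side"]);
  c.p = c.gs * c.gs * c.m;
  c.wf = as<int>(cfg["fold_width"]);
  c.hd = as<int>(cfg["dec_hidden"]);
  c.fin = c.L + 3 + 2;
  c.cs = as<double>(cfg["coord_scale"]);
  c.gext = as<double>(cfg["grid_extent"]);
  c.beta = as<double>(cfg["beta"]);
  c.beta_warmup = as<double>(cfg["beta_warmup_frac"]);
  c.mu_gain = as<double>(cfg["mu_gain"]);
  c.loss_unit = as<double>(cfg["loss_unit_mm"]);
  c.a0 = as<double>(cfg["alpha_start"]);
  c.a1 = as<double>(cfg["alpha_end"]);
  c.ramp = as<double>(cfg["alpha_ramp_frac"]);
  c.lr = as<double>(cfg["learning_rate"]);
  c.b1 = 0.9; c.b2 = 0.999; c.eps = 1e-8;
  c.total_steps = as<int>(cfg["total_steps"]);
  c.batch = as<int>(cfg["batch_size"]);
  c.train_points = as<int>(cfg["train_points"]);
  c.target_points = as<int>(cfg["target_points"]);
  c.lr_decay = as<double>(cfg["lr_decay"]);
  c.val_every = as<int>(cfg["val_every"]);
  c.fold_cells_train = as<int>(cfg["fold_cells_train"]);
  return c;
}

static const char* PARAM_NAMES[] = {
    "enc_W1", "enc_b1", "enc_Wc1", "enc_bc1", "enc_W2", "enc_b2",
    "enc_Wc2", "enc_bc2", "enc_Wh", "enc_bh", "enc_Wmu", "enc_bmu",
    "enc_Wlv", "enc_blv", "dec_W1", "dec_b1", "dec_W2", "dec_b2",
    "fold_W1", "fold_b1", "fold_W2", "fold_b2", "fold_W3", "fold_b3"};
static const int N_PARAMS = 24;

static std::vector<std::pair<int, int>> param_shapes(const VaeCfg& c) {
  const int out3mK = 3 * c.m * c.K;
  return {{7, c.we},       {c.we, 1},      {2 * c.we, c.we}, {c.we, 1},
          {c.we, c.we},    {c.we, 1},      {2 * c.we, c.we}, {c.we, 1},
          {2 * c.we, c.hh},{c.hh, 1},      {c.hh, c.L},      {c.L, 1},
          {c.hh, c.L},     {c.L, 1},       {c.L, c.hd},      {c.hd, 1},
          {c.hd, out3mK},  {out3mK, 1},
          {c.fin, c.wf * c.K}, {c.wf * c.K, 1},
          {c.wf, c.wf * c.K},  {c.wf * c.K, 1},
          {c.wf, 3 * c.K},     {3 * c.K, 1}};
}

typedef std::vector<TMat> Params;

static Params weights_from_r(const VaeCfg& c, const List& w) {
  auto shapes = param_shapes(c);
  Params P(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i) {
    NumericVector v = as<NumericVector>(w[PARAM_NAMES[i]]);
    P[i].resize(shapes[i].first, shapes[i].second);
    if ((int)v.size() != shapes[i].first * shapes[i].second)
      stop("weight '%s' has wrong length", PARAM_NAMES[i]);
    std::copy(v.begin(), v.end(), P[i].d.begin());
  }
  return P;
}

static List weights_to_r(const VaeCfg& c, const Params& P) {
  List out(N_PARAMS);
  CharacterVector nm(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i) {
    NumericMatrix m(P[i].nr, P[i].nc);
    std::copy(P[i].d.begin(), P[i].d.end(), m.begin());
    out[i] = m;
    nm[i] = PARAM_NAMES[i];
  }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
List cpp_vae_init(List cfg, int seed) {
  VaeCfg c = parse_cfg(cfg);
  auto shapes = param_shapes(c);
  std::mt19937_64 rng(seed);
  Params P(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i) {
    P[i].resize(shapes[i].first, shapes[i].second);
    if (shapes[i].second == 1) continue;  // biases start at zero
    double lim = std::sqrt(6.0 / (shapes[i].first + shapes[i].second));
    if (i == 10) lim *= 4.0;  // mu head: start with a usable latent scale
    std::uniform_real_distribution<double> U(-lim, lim);
    for (auto& v : P[i].d) v = U(rng);
  }
  // posterior starts narrow (sigma ~ 0.05) so the latent carries signal
  // from the first step; the KL term later widens it toward equilibrium
  std::fill(P[13].d.begin(), P[13].d.end(), -6.0);
  return weights_to_r(c, P);
}

// ----------------------------- encoder -------------------------------------

struct EncCache {
  TMat F, H1, C1, B1, A2, C2, R2, B2;  // B2 = R2 + B1
  std::vector<int> arg_g1, arg_g2, arg_gB1, arg_gB2;
  TMat G, Hh;
  std::vector<double> mu, lv;
};

static void colmax(const TMat& A, std::vector<double>& g, std::vector<int>& arg) {
  g.assign(A.nc, -1e300);
  arg.assign(A.nc, 0);
  for (int j = 0; j < A.nc; ++j) {
    const double* aj = A.col(j);
    double best = aj[0]; int bi = 0;
    for (int i = 1; i < A.nr; ++i)
      if (aj[i] > best) { best = aj[i]; bi = i; }
    g[j] = best; arg[j] = bi;
  }
}

static void concat_global(const TMat& H, const std::vector<double>& g, TMat& C) {
  const int n = H.nr, w = H.nc;
  C.resize(n, 2 * w);
  for (int j = 0; j < w; ++j) {
    std::copy(H.col(j), H.col(j) + n, C.col(j));
    double* cj = C.col(w + j);
    for (int i = 0; i < n; ++i) cj[i] = g[j];
  }
}

static void dense_layer(const TMat& X, const TMat& W, const TMat& b, TMat& Y,
                        bool relu) {
  Y.resize(X.nr, W.nc);
  gemm_nn(X, W, Y);
  add_bias(Y, b.d);
  if (relu) relu_(Y);
}

// X: n x 5 (x,y,z mm, class 1..C, phase 0/1)
static void enc_forward(const VaeCfg& c, const Params& P, const NumericMatrix& X,
                        const std::vector<int>& rows, EncCache& e) {
  const int n = rows.size();
  e.F.resize(n, 7);
  for (int i = 0; i < n; ++i) {
    const int r = rows[i];
    e.F.at(i, 0) = X(r, 0) / c.cs;
    e.F.at(i, 1) = X(r, 1) / c.cs;
    e.F.at(i, 2) = X(r, 2) / c.cs;
    const int cl = (int)X(r, 3);
    e.F.at(i, 3) = cl == 1 ? 1.0 : 0.0;
    e.F.at(i, 4) = cl == 2 ? 1.0 : 0.0;
    e.F.at(i, 5) = cl == 3 ? 1.0 : 0.0;
    e.F.at(i, 6) = X(r, 4) > 0.5 ? 1.0 : -1.0;
  }
  std::vector<double> g;
  dense_layer(e.F, P[0], P[1], e.H1, true);
  colmax(e.H1, g, e.arg_g1);
  concat_global(e.H1, g, e.C1);
  dense_layer(e.C1, P[2], P[3], e.B1, true);
  dense_layer(e.B1, P[4], P[5], e.A2, true);
  colmax(e.A2, g, e.arg_g2);
  concat_global(e.A2, g, e.C2);
  dense_layer(e.C2, P[6], P[7], e.R2, true);
  e.B2 = e.R2;
  for (size_t i = 0; i < e.B2.d.size(); ++i) e.B2.d[i] += e.B1.d[i];
  std::vector<double> gB1, gB2;
  colmax(e.B1, gB1, e.arg_gB1);
  colmax(e.B2, gB2, e.arg_gB2);
  e.G.resize(1, 2 * c.we);
  for (int j = 0; j < c.we; ++j) {
    e.G.at(0, j) = gB1[j];
    e.G.at(0, c.we + j) = gB2[j];
  }
  dense_layer(e.G, P[8], P[9], e.Hh, true);
  TMat mu, lv;
  dense_layer(e.Hh, P[10], P[11], mu, false);
  dense_layer(e.Hh, P[12], P[13], lv, false);
  e.mu.assign(mu.d.begin(), mu.d.end());
  for (auto& v : e.mu) v *= c.mu_gain;
  e.lv.assign(lv.d.begin(), lv.d.end());
  for (auto& v : e.lv) v = std::min(c.lv_max, std::max(c.lv_min, v));
}

// Accumulates parameter gradients into g; dmu/dlv are length-L gradients.
static void enc_backward(const VaeCfg& c, const Params& P, const EncCache& e,
                         const std::vector<double>& dmu,
                         const std::vector<double>& dlv, Params& g) {
  TMat dMu(1, c.L), dLv(1, c.L);
  std::copy(dmu.begin(), dmu.end(), dMu.d.begin());
  for (auto& v : dMu.d) v *= c.mu_gain;
  std::copy(dlv.begin(), dlv.end(), dLv.d.begin());
  // head
  TMat dHh(1, c.hh);
  gemm_nt(dMu, P[10], dHh);
  gemm_nt(dLv, P[12], dHh, true);
  gemm_tn(e.Hh, dMu, g[10], true);
  for (int j = 0; j < c.L; ++j) g[11].d[j] += dMu.d[j];
  gemm_tn(e.Hh, dLv, g[12], true);
  for (int j = 0; j < c.L; ++j) g[13].d[j] += dLv.d[j];
  relu_bwd(e.Hh, dHh);
  TMat dG(1, 2 * c.we);
  gemm_nt(dHh, P[8], dG);
  gemm_tn(e.G, dHh, g[8], true);
  for (int j = 0; j < c.hh; ++j) g[9].d[j] += dHh.d[j];
  // scatter pooled gradients
  const int n = e.B1.nr;
  TMat dB1(n, c.we), dB2(n, c.we);
  for (int j = 0; j < c.we; ++j) {
    dB1.at(e.arg_gB1[j], j) += dG.at(0, j);
    dB2.at(e.arg_gB2[j], j) += dG.at(0, c.we + j);
  }
  // block 2 (residual: dB2 flows into both R2 path and B1)
  TMat dR2 = dB2;
  relu_bwd(e.R2, dR2);
  for (size_t i = 0; i < dB1.d.size(); ++i) dB1.d[i] += dB2.d[i];
  TMat dC2(n, 2 * c.we);
  gemm_nt(dR2, P[6], dC2);
  gemm_tn(e.C2, dR2, g[6], true);
  for (int j = 0; j < c.we; ++j) {
    double s = 0.0;
    const double* cj = dR2.col(j);
    for (int i = 0; i < n; ++i) s += cj[i];
    g[7].d[j] += s;
  }
  TMat dA2(n, c.we);
  for (int j = 0; j < c.we; ++j) {
    std::copy(dC2.col(j), dC2.col(j) + n, dA2.col(j));
    double s = 0.0;
    const double* cj = dC2.col(c.we + j);
    for (int i = 0; i < n; ++i) s += cj[i];
    dA2.at(e.arg_g2[j], j) += s;
  }
  relu_bwd(e.A2, dA2);
  gemm_nt(dA2, P[4], dB1, true);
  gemm_tn(e.B1, dA2, g[4], true);
  for (int j = 0; j < c.we; ++j) {
    double s = 0.0;
    const double* cj = dA2.col(j);
    for (int i = 0; i < n; ++i) s += cj[i];
    g[5].d[j] += s;
  }
  // block 1
  relu_bwd(e.B1, dB1);
  TMat dC1(n, 2 * c.we);
  gemm_nt(dB1, P[2], dC1);
  gemm_tn(e.C1, dB1, g[2], true);
  for (int j = 0; j < c.we; ++j) {
    double s = 0.0;
    const double* cj = dB1.col(j);
    for (int i = 0; i < n; ++i) s += cj[i];
    g[3].d[j] += s;
  }
  TMat dH1(n, c.we);
  for (int j = 0; j < c.we; ++j) {
    std::copy(dC1.col(j), dC1.col(j) + n, dH1.col(j));
    double s = 0.0;
    const double* cj = dC1.col(c.we + j);
    for (int i = 0; i < n; ++i) s += cj[i];
    dH1.at(e.arg_g1[j], j) += s;
  }
  relu_bwd(e.H1, dH1);
  gemm_tn(e.F, dH1, g[0], true);
  for (int j = 0; j < c.we; ++j) {
    double s = 0.0;
    const double* cj = dH1.col(j);
    for (int i = 0; i < n; ++i) s += cj[i];
    g[1].d[j] += s;
  }
}

// ----------------------------- decoder -------------------------------------

struct DecCache {
  TMat z;          // 1 x L
  TMat h;          // 1 x hd
  TMat coarse;     // 1 x 3mK (scaled units), layout i + m*(d + 3*k)
  // per-channel folding network activations, rows = m * ncell
  std::vector<TMat> U, F1, F2, Off;
  std::vector<int> cell_ids;  // which grid cells were folded
};

// contiguous column slice [j0, j0+nc) of a parameter matrix
static TMat col_slice(const TMat& W, int j0, int nc) {
  TMat out(W.nr, nc);
  std::copy(W.col(j0), W.col(j0) + (size_t)W.nr * nc, out.d.begin());
  return out;
}

static void add_col_slice(TMat& W, int j0, const TMat& delta) {
  double* dst = W.col(j0);
  for (size_t i = 0; i < delta.d.size(); ++i) dst[i] += delta.d[i];
}

static std::vector<double> vec_slice(const TMat& b, int j0, int n) {
  return std::vector<double>(b.d.begin() + j0, b.d.begin() + j0 + n);
}

static void grid_offsets(const VaeCfg& c, std::vector<double>& gu,
                         std::vector<double>& gv) {
  gu.resize(c.gs * c.gs);
  gv.resize(c.gs * c.gs);
  for (int a = 0; a < c.gs; ++a)
    for (int b = 0; b < c.gs; ++b) {
      const int id = a * c.gs + b;
      gu[id] = c.gext * (-1.0 + 2.0 * a / (c.gs - 1.0));
      gv[id] = c.gext * (-1.0 + 2.0 * b / (c.gs - 1.0));
    }
}

// Folds the given grid cells around every anchor, with a separate folding
// head per substructure/phase channel.
static void dec_forward(const VaeCfg& c, const Params& P,
                        const std::vector<double>& z,
                        const std::vector<int>& cells, DecCache& d) {
  d.z.resize(1, c.L);
  std::copy(z.begin(), z.end(), d.z.d.begin());
  dense_layer(d.z, P[14], P[15], d.h, true);
  dense_layer(d.h, P[16], P[17], d.coarse, false);
  std::vector<double> gu, gv;
  grid_offsets(c, gu, gv);
  const int ncell = cells.size();
  const int rows = c.m * ncell;
  d.cell_ids = cells;
  d.U.assign(c.K, TMat());
  d.F1.assign(c.K, TMat());
  d.F2.assign(c.K, TMat());
  d.Off.assign(c.K, TMat());
  for (int k = 0; k < c.K; ++k) {
    TMat& U = d.U[k];
    U.resize(rows, c.fin);
    int r = 0;
    for (int i = 0; i < c.m; ++i) {
      const double ax = d.coarse.d[i + c.m * (0 + 3 * k)];
      const double ay = d.coarse.d[i + c.m * (1 + 3 * k)];
      const double az = d.coarse.d[i + c.m * (2 + 3 * k)];
      for (int ci = 0; ci < ncell; ++ci, ++r) {
        for (int l = 0; l < c.L; ++l) U.at(r, l) = z[l];
        U.at(r, c.L + 0) = ax;
        U.at(r, c.L + 1) = ay;
        U.at(r, c.L + 2) = az;
        U.at(r, c.L + 3) = gu[cells[ci]];
        U.at(r, c.L + 4) = gv[cells[ci]];
      }
    }
    TMat W1 = col_slice(P[18], k * c.wf, c.wf);
    TMat W2 = col_slice(P[20], k * c.wf, c.wf);
    TMat W3 = col_slice(P[22], k * 3, 3);
    TMat b1(c.wf, 1), b2(c.wf, 1), b3(3, 1);
    b1.d = vec_slice(P[19], k * c.wf, c.wf);
    b2.d = vec_slice(P[21], k * c.wf, c.wf);
    b3.d = vec_slice(P[23], k * 3, 3);
    dense_layer(U, W1, b1, d.F1[k], true);
    dense_layer(d.F1[k], W2, b2, d.F2[k], true);
    dense_layer(d.F2[k], W3, b3, d.Off[k], false);
  }
}

// dense point (channel k, row r) in mm: cs * (anchor + offset)
static inline void dense_point(const VaeCfg& c, const DecCache& d, int k,
                               int r, double* xyz) {
  for (int dd = 0; dd < 3; ++dd)
    xyz[dd] = c.cs * (d.U[k].at(r, c.L + dd) + d.Off[k].at(r, dd));
}

// Backward through the decoder. dDense[k]: (m*ncell) x 3 per-channel
// gradient on the dense points (mm scale); dCoarseMM: 1 x 3mK gradient on
// the coarse output in mm scale.  Returns dz and accumulates parameter
// gradients.
static void dec_backward(const VaeCfg& c, const Params& P, const DecCache& d,
                         const std::vector<TMat>& dDense,
                         const TMat& dCoarseMM, Params& g,
                         std::vector<double>& dz_out) {
  const int ncell = d.cell_ids.size();
  const int rows = c.m * ncell;
  TMat dCoarse(1, 3 * c.m * c.K);
  for (int j = 0; j < 3 * c.m * c.K; ++j)
    dCoarse.d[j] = c.cs * dCoarseMM.d[j];
  std::vector<double> dz(c.L, 0.0);
  for (int k = 0; k < c.K; ++k) {
    TMat dOff(rows, 3);
    for (int dd = 0; dd < 3; ++dd)
      for (int i = 0; i < rows; ++i)
        dOff.at(i, dd) = c.cs * dDense[k].at(i, dd);
    TMat W1 = col_slice(P[18], k * c.wf, c.wf);
    TMat W2 = col_slice(P[20], k * c.wf, c.wf);
    TMat W3 = col_slice(P[22], k * 3, 3);
    TMat gW1(c.fin, c.wf), gW2(c.wf, c.wf), gW3(c.wf, 3);
    TMat dF2(rows, c.wf);
    gemm_nt(dOff, W3, dF2);
    gemm_tn(d.F2[k], dOff, gW3);
    add_col_slice(g[22], k * 3, gW3);
    for (int j = 0; j < 3; ++j) {
      double sv = 0.0;
      for (int i = 0; i < rows; ++i) sv += dOff.at(i, j);
      g[23].d[k * 3 + j] += sv;
    }
    relu_bwd(d.F2[k], dF2);
    TMat dF1(rows, c.wf);
    gemm_nt(dF2, W2, dF1);
    gemm_tn(d.F1[k], dF2, gW2);
    add_col_slice(g[20], k * c.wf, gW2);
    for (int j = 0; j < c.wf; ++j) {
      double sv = 0.0;
      for (int i = 0; i < rows; ++i) sv += dF2.at(i, j);
      g[21].d[k * c.wf + j] += sv;
    }
    relu_bwd(d.F1[k], dF1);
    TMat dU(rows, c.fin);
    gemm_nt(dF1, W1, dU);
    gemm_tn(d.U[k], dF1, gW1);
    add_col_slice(g[18], k * c.wf, gW1);
    for (int j = 0; j < c.wf; ++j) {
      double sv = 0.0;
      for (int i = 0; i < rows; ++i) sv += dF1.at(i, j);
      g[19].d[k * c.wf + j] += sv;
    }
    int r = 0;
    for (int i = 0; i < c.m; ++i) {
      double sx = 0.0, sy = 0.0, sz = 0.0;
      for (int ci = 0; ci < ncell; ++ci, ++r) {
        sx += c.cs * dDense[k].at(r, 0) + dU.at(r, c.L + 0);
        sy += c.cs * dDense[k].at(r, 1) + dU.at(r, c.L + 1);
        sz += c.cs * dDense[k].at(r, 2) + dU.at(r, c.L + 2);
        for (int l = 0; l < c.L; ++l) dz[l] += dU.at(r, l);
      }
      dCoarse.d[i + c.m * (0 + 3 * k)] += sx;
      dCoarse.d[i + c.m * (1 + 3 * k)] += sy;
      dCoarse.d[i + c.m * (2 + 3 * k)] += sz;
    }
  }
  // through the coarse MLP
  TMat dh(1, c.hd);
  gemm_nt(dCoarse, P[16], dh);
  gemm_tn(d.h, dCoarse, g[16], true);
  for (int j = 0; j < 3 * c.m * c.K; ++j) g[17].d[j] += dCoarse.d[j];
  relu_bwd(d.h, dh);
  TMat dzm(1, c.L);
  gemm_nt(dh, P[14], dzm);
  gemm_tn(d.z, dh, g[14], true);
  for (int j = 0; j < c.hd; ++j) g[15].d[j] += dh.d[j];
  for (int l = 0; l < c.L; ++l) dz[l] += dzm.d[l];
  dz_out = dz;
}

// ------------------------ chamfer loss (squared) ----------------------------

// Symmetric squared Chamfer between prediction rows (mm) and target rows
// (mm); accumulates d loss / d pred into dPred (may be NULL).
static double chamfer_sq_grad(const double* pred, int np, int pred_stride,
                              const double* targ, int nt, int targ_stride,
                              double* dpred, double w) {
  // pred: np x 3 column-major with leading dim pred_stride, same for targ
  std::vector<int> nn_p(np);
  std::vector<double> min_t(nt, 1e300);
  std::vector<int> nn_t(nt, 0);
  double sp = 0.0;
  for (int i = 0; i < np; ++i) {
    const double xi = pred[i], yi = pred[i + pred_stride],
                 zi = pred[i + 2 * pred_stride];
    double best = 1e300; int bj = 0;
    for (int j = 0; j < nt; ++j) {
      const double dx = xi - targ[j], dy = yi - targ[j + targ_stride],
                   dz = zi - targ[j + 2 * targ_stride];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
      if (d2 < min_t[j]) { min_t[j] = d2; nn_t[j] = i; }
    }
    nn_p[i] = bj;
    sp += best;
  }
  double st = 0.0;
  for (int j = 0; j < nt; ++j) st += min_t[j];
  const double loss = 0.5 * (sp / np + st / nt);
  if (dpred) {
    const double cp = w / np, ct = w / nt;
    for (int i = 0; i < np; ++i) {
      const int j = nn_p[i];
      dpred[i] += cp * (pred[i] - targ[j]);
      dpred[i + pred_stride] += cp * (pred[i + pred_stride] - targ[j + targ_stride]);
      dpred[i + 2 * pred_stride] +=
          cp * (pred[i + 2 * pred_stride] - targ[j + 2 * targ_stride]);
    }
    for (int j = 0; j < nt; ++j) {
      const int i = nn_t[j];
      dpred[i] += ct * (pred[i] - targ[j]);
      dpred[i + pred_stride] += ct * (pred[i + pred_stride] - targ[j + targ_stride]);
      dpred[i + 2 * pred_stride] +=
          ct * (pred[i + 2 * pred_stride] - targ[j + 2 * targ_stride]);
    }
  }
  return loss;
}

// --------------------------- sample plumbing --------------------------------

// Per-channel row indices of a sample matrix X (n x 5).
static std::vector<std::vector<int>> channel_rows(const VaeCfg& c,
                                                  const NumericMatrix& X) {
  std::vector<std::vector<int>> idx(c.K);
  for (int r = 0; r < X.nrow(); ++r) {
    const int cl = (int)X(r, 3), ph = X(r, 4) > 0.5 ? 1 : 0;
    const int k = (c.T == 2 ? ph : 0) * c.C + (cl - 1);
    if (k < 0 || k >= c.K) stop("point with invalid class/phase");
    idx[k].push_back(r);
  }
  for (int k = 0; k < c.K; ++k)
    if (idx[k].empty())
      stop("sample is missing points for class %d in phase %d",
           k % c.C + 1, k / c.C + 1);
  return idx;
}

static double alpha_at(const VaeCfg& c, int step) {
  const double ramp_end = c.ramp * c.total_steps;
  if (ramp_end <= 0) return c.a1;
  const double f = std::min(1.0, step / ramp_end);
  return c.a0 + f * (c.a1 - c.a0);
}

// [[Rcpp::export]]
double cpp_alpha_schedule(List cfg, double step) {
  VaeCfg c = parse_cfg(cfg);
  const double ramp_end = c.ramp * c.total_steps;
  if (ramp_end <= 0) return c.a1;
  const double f = std::min(1.0, step / ramp_end);
  return c.a0 + f * (c.a1 - c.a0);
}

// [[Rcpp::export]]
List cpp_vae_encode(List cfg, List weights, NumericMatrix X) {
  VaeCfg c = parse_cfg(cfg);
  Params P = weights_from_r(c, weights);
  channel_rows(c, X);  // validates labels/phases
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  EncCache e;
  enc_forward(c, P, X, rows, e);
  return List::create(_["mu"] = NumericVector(e.mu.begin(), e.mu.end()),
                      _["logvar"] = NumericVector(e.lv.begin(), e.lv.end()));
}

// [[Rcpp::export]]
List cpp_vae_decode(List cfg, List weights, NumericVector z) {
  VaeCfg c = parse_cfg(cfg);
  Params P = weights_from_r(c, weights);
  if ((int)z.size() != c.L) stop("z must have length %d", c.L);
  for (double v : z) if (!std::isfinite(v)) stop("z contains non-finite values");
  std::vector<int> cells(c.gs * c.gs);
  for (int i = 0; i < (int)cells.size(); ++i) cells[i] = i;
  DecCache d;
  dec_forward(c, P, std::vector<double>(z.begin(), z.end()), cells, d);
  NumericVector coarse(3 * c.m * c.K);
  for (int j = 0; j < (int)coarse.size(); ++j) coarse[j] = c.cs * d.coarse.d[j];
  coarse.attr("dim") = IntegerVector::create(c.m, 3, c.K);
  const int per_ch = c.m * (int)cells.size();
  NumericVector dense((size_t)3 * per_ch * c.K);
  double xyz[3];
  for (int k = 0; k < c.K; ++k)
    for (int i = 0; i < per_ch; ++i) {
      dense_point(c, d, k, i, xyz);
      for (int dd = 0; dd < 3; ++dd)
        dense[i + per_ch * (dd + 3 * k)] = xyz[dd];
    }
  dense.attr("dim") = IntegerVector::create(per_ch, 3, c.K);
  return List::create(_["coarse"] = coarse, _["dense"] = dense);
}

// ------------------------------- training ----------------------------------

struct AdamState {
  Params m, v;
  int t = 0;
};

static void adam_step(const VaeCfg& c, Params& P, const Params& g,
                      AdamState& st, double lr) {
  st.t += 1;
  const double bc1 = 1.0 - std::pow(c.b1, st.t);
  const double bc2 = 1.0 - std::pow(c.b2, st.t);
  for (int i = 0; i < N_PARAMS; ++i) {
    double* w = P[i].d.data();
    const double* gr = g[i].d.data();
    double* m = st.m[i].d.data();
    double* v = st.v[i].d.data();
    const size_t n = P[i].d.size();
    for (size_t j = 0; j < n; ++j) {
      m[j] = c.b1 * m[j] + (1 - c.b1) * gr[j];
      v[j] = c.b2 * v[j] + (1 - c.b2) * gr[j] * gr[j];
      w[j] -= lr * (m[j] / bc1) / (std::sqrt(v[j] / bc2) + c.eps);
    }
  }
}

// Loss of one sample given encoder rows + chamfer targets; optionally
// accumulates all gradients. Returns the per-channel breakdown.
struct SampleLoss {
  double kl = 0, recon = 0, total = 0;
  std::vector<double> coarse_k, dense_k;
};

static SampleLoss sample_loss(const VaeCfg& c, const Params& P,
                              const NumericMatrix& X,
                              const std::vector<std::vector<int>>& enc_rows_k,
                              const std::vector<std::vector<int>>& targ_rows_k,
                              const std::vector<int>& cells, double alpha,
                              double beta, const std::vector<double>& eps_z,
                              bool do_grad, Params* g) {
  std::vector<int> enc_rows;
  for (int k = 0; k < c.K; ++k)
    enc_rows.insert(enc_rows.end(), enc_rows_k[k].begin(), enc_rows_k[k].end());
  EncCache e;
  enc_forward(c, P, X, enc_rows, e);
  // reparameterize
  std::vector<double> z(c.L), sig(c.L);
  for (int l = 0; l < c.L; ++l) {
    sig[l] = std::exp(0.5 * e.lv[l]);
    z[l] = e.mu[l] + sig[l] * eps_z[l];
  }
  DecCache d;
  dec_forward(c, P, z, cells, d);
  const int ncell = cells.size(), per_ch = c.m * ncell;
  // assemble predictions in mm, column-major (rows x 3) per channel
  SampleLoss out;
  out.coarse_k.resize(c.K);
  out.dense_k.resize(c.K);
  std::vector<TMat> dDense(c.K);
  for (int k = 0; k < c.K; ++k) dDense[k].resize(per_ch, 3);
  TMat dCoarseMM(1, 3 * c.m * c.K);
  std::vector<double> predc(c.m * 3), predd(per_ch * 3), targ;
  std::vector<double> dpc(c.m * 3), dpd(per_ch * 3);
  for (int k = 0; k < c.K; ++k) {
    for (int i = 0; i < c.m; ++i)
      for (int dd = 0; dd < 3; ++dd)
        predc[i + c.m * dd] = c.cs * d.coarse.d[i + c.m * (dd + 3 * k)];
    for (int i = 0; i < per_ch; ++i) {
      double xyz[3];
      dense_point(c, d, k, i, xyz);
      for (int dd = 0; dd < 3; ++dd) predd[i + per_ch * dd] = xyz[dd];
    }
    const auto& tr = targ_rows_k[k];
    const int nt = tr.size();
    targ.assign(nt * 3, 0.0);
    for (int j = 0; j < nt; ++j)
      for (int dd = 0; dd < 3; ++dd) targ[j + nt * dd] = X(tr[j], dd);
    std::fill(dpc.begin(), dpc.end(), 0.0);
    std::fill(dpd.begin(), dpd.end(), 0.0);
    const double u2 = 1.0 / (c.loss_unit * c.loss_unit);
    out.coarse_k[k] =
        u2 * chamfer_sq_grad(predc.data(), c.m, c.m, targ.data(), nt, nt,
                             do_grad ? dpc.data() : nullptr, u2);
    out.dense_k[k] =
        u2 * chamfer_sq_grad(predd.data(), per_ch, per_ch, targ.data(), nt,
                             nt, do_grad ? dpd.data() : nullptr, alpha * u2);
    if (do_grad) {
      for (int i = 0; i < c.m; ++i)
        for (int dd = 0; dd < 3; ++dd)
          dCoarseMM.d[i + c.m * (dd + 3 * k)] = dpc[i + c.m * dd];
      for (int i = 0; i < per_ch; ++i)
        for (int dd = 0; dd < 3; ++dd)
          dDense[k].at(i, dd) = dpd[i + per_ch * dd];
    }
  }
  for (int k = 0; k < c.K; ++k)
    out.recon += out.coarse_k[k] + alpha * out.dense_k[k];
  for (int l = 0; l < c.L; ++l)
    out.kl += 0.5 * (e.mu[l] * e.mu[l] + std::exp(e.lv[l]) - 1.0 - e.lv[l]);
  out.total = out.recon + beta * out.kl;
  if (do_grad) {
    std::vector<double> dz;
    dec_backward(c, P, d, dDense, dCoarseMM, *g, dz);
    std::vector<double> dmu(c.L), dlv(c.L);
    for (int l = 0; l < c.L; ++l) {
      dmu[l] = dz[l] + beta * e.mu[l];
      dlv[l] = dz[l] * eps_z[l] * 0.5 * sig[l] +
               beta * 0.5 * (std::exp(e.lv[l]) - 1.0);
    }
    enc_backward(c, P, e, dmu, dlv, *g);
  }
  return out;
}

static std::vector<std::vector<int>> subsample_rows(
    const VaeCfg& c, const std::vector<std::vector<int>>& idx, int npts,
    std::mt19937_64& rng) {
  std::vector<std::vector<int>> out(c.K);
  for (int k = 0; k < c.K; ++k) {
    const int n = idx[k].size();
    if (npts >= n) {
      out[k] = idx[k];
      continue;
    }
    // partial Fisher-Yates
    std::vector<int> pool = idx[k];
    for (int i = 0; i < npts; ++i) {
      std::uniform_int_distribution<int> U(i, n - 1);
      std::swap(pool[i], pool[U(rng)]);
    }
    out[k].assign(pool.begin(), pool.begin() + npts);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_vae_train(List cfg, List weights, Nullable<List> adam, List train,
                   List val, int steps, int start_step, int seed) {
  VaeCfg c = parse_cfg(cfg);
  Params P = weights_from_r(c, weights);
  auto shapes = param_shapes(c);
  AdamState st;
  st.m.resize(N_PARAMS); st.v.resize(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i) {
    st.m[i].resize(shapes[i].first, shapes[i].second);
    st.v[i].resize(shapes[i].first, shapes[i].second);
  }
  if (adam.isNotNull()) {
    List a(adam);
    Params m = weights_from_r(c, a["m"]), v = weights_from_r(c, a["v"]);
    st.m = m; st.v = v; st.t = as<int>(a["t"]);
  }
  const int ntrain = train.size(), nval = val.size();
  if (ntrain < 1) stop("empty training set");
  std::vector<NumericMatrix> TR(ntrain), VA(nval);
  std::vector<std::vector<std::vector<int>>> TRidx(ntrain), VAidx(nval);
  for (int i = 0; i < ntrain; ++i) {
    TR[i] = as<NumericMatrix>(train[i]);
    TRidx[i] = channel_rows(c, TR[i]);
  }
  for (int i = 0; i < nval; ++i) {
    VA[i] = as<NumericMatrix>(val[i]);
    VAidx[i] = channel_rows(c, VA[i]);
  }
  std::mt19937_64 rng((uint64_t)seed * 2654435761u + 13u);
  std::vector<int> order(ntrain);
  for (int i = 0; i < ntrain; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  int cursor = 0;
  const int ncell_all = c.gs * c.gs;
  std::vector<int> all_cells(ncell_all);
  for (int i = 0; i < ncell_all; ++i) all_cells[i] = i;
  const int hist_cols = 7 + 2 * c.K;
  NumericMatrix hist(steps, hist_cols);
  std::normal_distribution<double> N01(0.0, 1.0);
  Params g(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i)
    g[i].resize(shapes[i].first, shapes[i].second);
  const std::vector<double> eps0(c.L, 0.0);
  for (int s = 0; s < steps; ++s) {
    const int step = start_step + s;
    const double alpha = alpha_at(c, step);
    const double warm_end = c.beta_warmup * c.total_steps;
    const double beta_t =
        warm_end <= 0 ? c.beta
                      : c.beta * std::min(1.0, step / warm_end);
    for (int i = 0; i < N_PARAMS; ++i) g[i].zero();
    double tot = 0, rec = 0, kl = 0;
    std::vector<double> ck(c.K, 0.0), dk(c.K, 0.0);
    // folded grid cells for this step (shared across the batch)
    std::vector<int> cells;
    if (c.fold_cells_train >= ncell_all) {
      cells = all_cells;
    } else {
      std::vector<int> pool = all_cells;
      for (int i = 0; i < c.fold_cells_train; ++i) {
        std::uniform_int_distribution<int> U(i, ncell_all - 1);
        std::swap(pool[i], pool[U(rng)]);
      }
      cells.assign(pool.begin(), pool.begin() + c.fold_cells_train);
    }
    for (int b = 0; b < c.batch; ++b) {
      if (cursor >= ntrain) {
        std::shuffle(order.begin(), order.end(), rng);
        cursor = 0;
      }
      const int si = order[cursor++];
      auto rows = subsample_rows(c, TRidx[si], c.train_points, rng);
      auto trows = subsample_rows(c, TRidx[si], c.target_points, rng);
      std::vector<double> eps(c.L);
      for (int l = 0; l < c.L; ++l) eps[l] = N01(rng);
      SampleLoss sl = sample_loss(c, P, TR[si], rows, trows, cells, alpha,
                                  beta_t, eps, true, &g);
      tot += sl.total; rec += sl.recon; kl += sl.kl;
      for (int k = 0; k < c.K; ++k) { ck[k] += sl.coarse_k[k]; dk[k] += sl.dense_k[k]; }
    }
    const double inv_b = 1.0 / c.batch;
    for (int i = 0; i < N_PARAMS; ++i)
      for (auto& v : g[i].d) v *= inv_b;
    tot *= inv_b; rec *= inv_b; kl *= inv_b;
    if (!std::isfinite(tot))
      stop("training diverged (non-finite loss) at step %d", step);
    const double lr_t =
        c.lr * (1.0 - c.lr_decay * std::min(1.0, (double)step / c.total_steps));
    adam_step(c, P, g, st, lr_t);
    hist(s, 0) = step + 1;
    hist(s, 1) = alpha;
    hist(s, 2) = beta_t;
    hist(s, 3) = tot;
    hist(s, 4) = rec;
    hist(s, 5) = kl;
    hist(s, 6) = NA_REAL;
    for (int k = 0; k < c.K; ++k) {
      hist(s, 7 + k) = ck[k] * inv_b;
      hist(s, 7 + c.K + k) = dk[k] * inv_b;
    }
    // periodic noiseless validation loss, always at the final objective
    // (alpha_end, full beta) so values are comparable across training
    if (nval > 0 && ((step + 1) % c.val_every == 0 || s == steps - 1)) {
      std::mt19937_64 vrng(9151u + (uint64_t)step);
      double vtot = 0;
      for (int i = 0; i < nval; ++i) {
        auto rows = subsample_rows(c, VAidx[i], c.train_points, vrng);
        auto trows = subsample_rows(c, VAidx[i], c.target_points, vrng);
        SampleLoss sl = sample_loss(c, P, VA[i], rows, trows, all_cells,
                                    c.a1, c.beta, eps0, false, nullptr);
        vtot += sl.total;
      }
      hist(s, 6) = vtot / nval;
    }
    if ((s & 63) == 0) Rcpp::checkUserInterrupt();
  }
  colnames(hist) = [&] {
    CharacterVector nm(hist_cols);
    nm[0] = "step"; nm[1] = "alpha"; nm[2] = "beta"; nm[3] = "total";
    nm[4] = "recon"; nm[5] = "kl"; nm[6] = "val_total";
    for (int k = 0; k < c.K; ++k) {
      nm[7 + k] = std::string("coarse_") + std::to_string(k + 1);
      nm[7 + c.K + k] = std::string("dense_") + std::to_string(k + 1);
    }
    return nm;
  }();
  List adam_out = List::create(_["m"] = weights_to_r(c, st.m),
                               _["v"] = weights_to_r(c, st.v), _["t"] = st.t);
  return List::create(_["weights"] = weights_to_r(c, P), _["adam"] = adam_out,
                      _["history"] = hist);
}
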