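// Compiled kernels for the edge-gated multi-head attention block: the
// per-edge gather/scatter work dominates training time and vectorizes
// poorly in R. Internally everything is laid out transposed (one COLUMN
// per vertex/edge) so per-edge operations touch contiguous memory in
// Armadillo's column-major storage. The backward kernel recomputes the
// forward intermediates from the block inputs instead of shipping ~5 MB of
// cached activations through the R boundary on every training step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;

namespace {

struct FwdState {
  mat Qt, Kt, Vt, Gt;   // d x n / d x E projections
  mat st;               // heads x E raw scores
  mat shatt, clt, wt;   // d x E gated scores, clamped exponents, weights
  mat aggt;             // d x n attention aggregate
};

void forward_pass(const mat& hbar, const mat& ebar,
                  const arma::ivec& src1, const arma::ivec& dst1,
                  const mat& Wq, const mat& Wk, const mat& Wv, const mat& We,
                  const int heads, const bool gate_pre, FwdState& fs) {
  const int n = hbar.n_rows, d = hbar.n_cols;
  const int dk = d / heads;
  const int E = src1.n_elem;
  const double scale = 1.0 / std::sqrt((double) dk);

  const mat ht = hbar.t();
  const mat et = ebar.t();
  fs.Qt = Wq * ht; fs.Kt = Wk * ht; fs.Vt = Wv * ht;
  fs.Gt = We * et;

  fs.st.set_size(heads, E);
  fs.shatt.set_size(d, E);
  fs.clt.set_size(d, E);
  for (int e = 0; e < E; ++e) {
    const double* qc = fs.Qt.colptr(src1[e] - 1);
    const double* kc = fs.Kt.colptr(dst1[e] - 1);
    double* sc = fs.st.colptr(e);
    for (int h = 0; h < heads; ++h) {
      double acc = 0.0;
      for (int c = h * dk; c < (h + 1) * dk; ++c) acc += qc[c] * kc[c];
      sc[h] = acc * scale;
    }
    const double* gc = fs.Gt.colptr(e);
    double* shc = fs.shatt.colptr(e);
    double* clc = fs.clt.colptr(e);
    for (int c = 0; c < d; ++c) {
      shc[c] = sc[c / dk] * gc[c];
      double raw = gate_pre ? shc[c] : sc[c / dk];
      clc[c] = raw > 5.0 ? 5.0 : (raw < -5.0 ? -5.0 : raw);
    }
  }

  mat ut = arma::exp(fs.clt);
  mat dent(d, n, arma::fill::zeros);
  for (int e = 0; e < E; ++e) dent.col(src1[e] - 1) += ut.col(e);
  fs.wt.set_size(d, E);
  for (int e = 0; e < E; ++e)
    fs.wt.col(e) = ut.col(e) / dent.col(src1[e] - 1);
  if (!gate_pre) fs.wt %= fs.Gt;

  fs.aggt.zeros(d, n);
  for (int e = 0; e < E; ++e)
    fs.aggt.col(src1[e] - 1) += fs.wt.col(e) % fs.Vt.col(dst1[e] - 1);
}

}  // namespace

// [[Rcpp::export]]
List gt_block_fwd_cpp(const arma::mat& hbar, const arma::mat& ebar,
                      const arma::ivec& src1, const arma::ivec& dst1,
                      const arma::mat& Wq, const arma::mat& Wk,
                      const arma::mat& Wv, const arma::mat& We,
                      const arma::mat& Oh, const arma::mat& Oe,
                      const int heads, const bool gate_pre,
                      const bool full = false) {
  FwdState fs;
  forward_pass(hbar, ebar, src1, dst1, Wq, Wk, Wv, We, heads, gate_pre, fs);
  mat h_out = hbar + (Oh * fs.aggt).t();
  mat e_out = ebar + (Oe * fs.shatt).t();
  if (!full) return List::create(_["h"] = h_out, _["e"] = e_out);
  return List::create(_["h"] = h_out, _["e"] = e_out, _["wt"] = fs.wt,
                      _["st"] = fs.st, _["Qt"] = fs.Qt, _["Kt"] = fs.Kt,
                      _["Vt"] = fs.Vt, _["Gt"] = fs.Gt, _["aggt"] = fs.aggt);
}

// [[Rcpp::export]]
List gt_block_bwd_cpp(const arma::mat& dh, const arma::mat& de,
                      const arma::mat& hbar, const arma::mat& ebar,
                      const arma::ivec& src1, const arma::ivec& dst1,
                      const arma::mat& Qt, const arma::mat& Kt,
                      const arma::mat& Vt, const arma::mat& Gt,
                      const arma::mat& st, const arma::mat& wt,
                      const arma::mat& aggt,
                      const arma::mat& Wq, const arma::mat& Wk,
                      const arma::mat& Wv, const arma::mat& We,
                      const arma::mat& Oh, const arma::mat& Oe,
                      const int heads) {
  // gradients are only implemented for pre-softmax gating
  const int n = hbar.n_rows, d = hbar.n_cols;
  const int dk = d / heads;
  const int E = src1.n_elem;
  const double scale = 1.0 / std::sqrt((double) dk);

  // cheap re-derivation of the gated scores (for the edge-update gradient
  // and the clamp mask); everything expensive arrives precomputed
  FwdState fs;
  fs.Qt = Qt; fs.Kt = Kt; fs.Vt = Vt; fs.Gt = Gt; fs.wt = wt;
  fs.aggt = aggt; fs.st = st;
  fs.shatt.set_size(d, E);
  fs.clt.set_size(d, E);
  for (int e = 0; e < E; ++e) {
    const double* sc = st.colptr(e);
    const double* gc = Gt.colptr(e);
    double* shc = fs.shatt.colptr(e);
    double* clc = fs.clt.colptr(e);
    for (int c = 0; c < d; ++c) {
      shc[c] = sc[c / dk] * gc[c];
      clc[c] = shc[c] > 5.0 ? 5.0 : (shc[c] < -5.0 ? -5.0 : shc[c]);
    }
  }

  const mat dht = dh.t();
  const mat det = de.t();

  mat dOh = dht * fs.aggt.t();
  mat daggt = Oh.t() * dht;
  mat dOe = det * fs.shatt.t();
  mat dshatt = Oe.t() * det;

  mat dwt(d, E);
  mat dVt(d, n, arma::fill::zeros);
  mat tsumt(d, n, arma::fill::zeros);
  for (int e = 0; e < E; ++e) {
    const int i = src1[e] - 1, j = dst1[e] - 1;
    const double* dac = daggt.colptr(i);
    const double* vc = fs.Vt.colptr(j);
    const double* wc = fs.wt.colptr(e);
    double* dwc = dwt.colptr(e);
    double* dvc = dVt.colptr(j);
    double* tsc = tsumt.colptr(i);
    for (int c = 0; c < d; ++c) {
      dwc[c] = dac[c] * vc[c];
      dvc[c] += wc[c] * dac[c];
      tsc[c] += dwc[c] * wc[c];
    }
  }

  for (int e = 0; e < E; ++e) {
    const int i = src1[e] - 1;
    const double* wc = fs.wt.colptr(e);
    const double* dwc = dwt.colptr(e);
    const double* tsc = tsumt.colptr(i);
    const double* clc = fs.clt.colptr(e);
    double* dsc = dshatt.colptr(e);
    for (int c = 0; c < d; ++c) {
      if (clc[c] > -5.0 && clc[c] < 5.0)
        dsc[c] += wc[c] * (dwc[c] - tsc[c]);
    }
  }

  mat dst(heads, E, arma::fill::zeros);
  mat dGt(d, E);
  for (int e = 0; e < E; ++e) {
    const double* dsh = dshatt.colptr(e);
    const double* gc = fs.Gt.colptr(e);
    const double* sc = fs.st.colptr(e);
    double* dstc = dst.colptr(e);
    double* dgc = dGt.colptr(e);
    for (int c = 0; c < d; ++c) {
      dstc[c / dk] += dsh[c] * gc[c];
      dgc[c] = dsh[c] * sc[c / dk];
    }
  }

  mat dQt(d, n, arma::fill::zeros), dKt(d, n, arma::fill::zeros);
  for (int e = 0; e < E; ++e) {
    const int i = src1[e] - 1, j = dst1[e] - 1;
    const double* dstc = dst.colptr(e);
    const double* kc = fs.Kt.colptr(j);
    const double* qc = fs.Qt.colptr(i);
    double* dqc = dQt.colptr(i);
    double* dkc = dKt.colptr(j);
    for (int c = 0; c < d; ++c) {
      const double g = dstc[c / dk] * scale;
      dqc[c] += g * kc[c];
      dkc[c] += g * qc[c];
    }
  }

  mat dhbar = dh + (Wq.t() * dQt + Wk.t() * dKt + Wv.t() * dVt).t();
  mat debar = de + (We.t() * dGt).t();

  return List::create(_["dh"] = dhbar, _["de"] = debar,
                      _["Wq"] = dQt * hbar, _["Wk"] = dKt * hbar,
                      _["Wv"] = dVt * hbar, _["We"] = dGt * ebar,
                      _["Oh"] = dOh, _["Oe"] = dOe);
}

// One Adam tensor update: m and v are moment buffers owned solely by the
// optimizer state and are updated in place; the returned parameter is a
// fresh allocation so checkpoint snapshots sharing the old memory stay
// valid.
// [[Rcpp::export]]
NumericVector adam_update_cpp(const NumericVector& p, const NumericVector& g,
                              NumericVector m, NumericVector v,
                              const int t, const double lr, const double b1,
                              const double b2, const double eps,
                              const double wd) {
  const R_xlen_t n = p.size();
  NumericVector out(n);
  const double c1 = 1.0 - std::pow(b1, (double) t);
  const double c2 = 1.0 - std::pow(b2, (double) t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i] + wd * p[i];
    const double mi = b1 * m[i] + (1.0 - b1) * gi;
    const double vi = b2 * v[i] + (1.0 - b2) * gi * gi;
    m[i] = mi; v[i] = vi;
    out[i] = p[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  out.attr("dim") = p.attr("dim");
  return out;
}

namespace {

struct GcnState {
  arma::vec z, wsig, wsym;
  mat Ahat, S, HW, pre, M1, M2;
  arma::vec deg, dinv;
};

void gcn_forward(const mat& h, const mat& e, const arma::ivec& src1,
                 const arma::ivec& dst1, const arma::ivec& rev1,
                 const arma::vec& wr, const double br, const mat& Wx,
                 const mat& Wm1, const arma::vec& bm1, const mat& Wm2,
                 const arma::vec& bm2, GcnState& gs) {
  const int n = h.n_rows;
  const int E = src1.n_elem;
  if (E > 0) {
    gs.z = e * wr + br;
    gs.wsig = 1.0 / (1.0 + arma::exp(-gs.z));
    gs.wsym.set_size(E);
    for (int m = 0; m < E; ++m)
      gs.wsym[m] = 0.5 * (gs.wsig[m] + gs.wsig[rev1[m] - 1]);
  }
  gs.Ahat.eye(n, n);
  for (int m = 0; m < E; ++m)
    gs.Ahat(src1[m] - 1, dst1[m] - 1) = gs.wsym[m];
  gs.deg = arma::sum(gs.Ahat, 1);
  gs.dinv = 1.0 / arma::sqrt(gs.deg);
  gs.S = gs.Ahat;
  gs.S.each_col() %= gs.dinv;
  gs.S.each_row() %= gs.dinv.t();
  gs.HW = h * Wx;
  gs.pre = gs.S * gs.HW;
  gs.M1 = h * Wm1.t();
  gs.M1.each_row() += bm1.t();
  gs.M1 = arma::clamp(gs.M1, 0.0, arma::datum::inf);
  gs.M2 = gs.M1 * Wm2.t();
  gs.M2.each_row() += bm2.t();
}

}  // namespace

// [[Rcpp::export]]
arma::mat gcn_fwd_cpp(const arma::mat& h, const arma::mat& e,
                      const arma::ivec& src1, const arma::ivec& dst1,
                      const arma::ivec& rev1, const arma::vec& wr,
                      const double br, const arma::mat& Wx,
                      const arma::mat& Wm1, const arma::vec& bm1,
                      const arma::mat& Wm2, const arma::vec& bm2) {
  GcnState gs;
  gcn_forward(h, e, src1, dst1, rev1, wr, br, Wx, Wm1, bm1, Wm2, bm2, gs);
  return arma::clamp(gs.pre, 0.0, arma::datum::inf) + gs.M2;
}

// [[Rcpp::export]]
List gcn_bwd_cpp(const arma::mat& dout, const arma::mat& h,
                 const arma::mat& e, const arma::ivec& src1,
                 const arma::ivec& dst1, const arma::ivec& rev1,
                 const arma::vec& wr, const double br, const arma::mat& Wx,
                 const arma::mat& Wm1, const arma::vec& bm1,
                 const arma::mat& Wm2, const arma::vec& bm2) {
  const int n = h.n_rows;
  const int E = src1.n_elem;
  GcnState gs;
  gcn_forward(h, e, src1, dst1, rev1, wr, br, Wx, Wm1, bm1, Wm2, bm2, gs);

  mat dpre = dout % (gs.pre > 0);
  mat dWm2 = dout.t() * gs.M1;
  arma::vec dbm2 = arma::sum(dout, 0).t();
  mat dM1 = dout * Wm2;
  mat dZ1 = dM1 % (gs.M1 > 0);
  mat dWm1 = dZ1.t() * h;
  arma::vec dbm1 = arma::sum(dZ1, 0).t();
  mat dh = dZ1 * Wm1;

  mat dS = dpre * gs.HW.t();
  mat dHW = gs.S * dpre;        // S symmetric
  dh += dHW * Wx.t();
  mat dWx = h.t() * dHW;

  mat MS = dS % gs.S;
  arma::vec u = arma::sum(MS, 1) / gs.deg;
  arma::vec v = arma::sum(MS, 0).t() / gs.deg;
  mat dAhat = dS;
  dAhat.each_col() %= gs.dinv;
  dAhat.each_row() %= gs.dinv.t();
  dAhat.each_col() -= 0.5 * u;
  dAhat.each_row() -= 0.5 * v.t();

  arma::vec dwr(wr.n_elem, arma::fill::zeros);
  double dbr = 0.0;
  mat de(E, h.n_cols, arma::fill::zeros);
  if (E > 0) {
    arma::vec dwsym(E);
    for (int m = 0; m < E; ++m)
      dwsym[m] = dAhat(src1[m] - 1, dst1[m] - 1);
    arma::vec dwsig(E);
    for (int m = 0; m < E; ++m)
      dwsig[m] = 0.5 * (dwsym[m] + dwsym[rev1[m] - 1]);
    arma::vec dz = dwsig % gs.wsig % (1.0 - gs.wsig);
    dwr = e.t() * dz;
    dbr = arma::accu(dz);
    de = dz * wr.t();
  }

  return List::create(_["dh"] = dh, _["de"] = de, _["wr"] = dwr,
                      _["br"] = dbr, _["Wx"] = dWx, _["Wm1"] = dWm1,
                      _["bm1"] = dbm1, _["Wm2"] = dWm2, _["bm2"] = dbm2);
}

namespace {

struct FfnState {
  mat xhat, nrm, Z, Rl, Rd;
  arma::vec inv;
};

void ffn_forward(const mat& h, const arma::vec& gamma, const arma::vec& beta,
                 const mat& W1, const arma::vec& b1, const mat& W2,
                 const arma::vec& b2, const mat& mask, FfnState& fs) {
  arma::vec mu = arma::mean(h, 1);
  mat xc = h;
  xc.each_col() -= mu;
  arma::vec va = arma::mean(arma::square(xc), 1);
  fs.inv = 1.0 / arma::sqrt(va + 1e-5);
  fs.xhat = xc;
  fs.xhat.each_col() %= fs.inv;
  fs.nrm = fs.xhat;
  fs.nrm.each_row() %= gamma.t();
  fs.nrm.each_row() += beta.t();
  fs.Z = fs.nrm * W2.t();
  fs.Z.each_row() += b2.t();
  fs.Rl = arma::clamp(fs.Z, 0.0, arma::datum::inf);
  fs.Rd = mask.n_elem > 0 ? mat(fs.Rl % mask) : fs.Rl;
}

}  // namespace

// [[Rcpp::export]]
arma::mat ffn_fwd_cpp(const arma::mat& h, const arma::vec& gamma,
                      const arma::vec& beta, const arma::mat& W1,
                      const arma::vec& b1, const arma::mat& W2,
                      const arma::vec& b2, const arma::mat& mask) {
  FfnState fs;
  ffn_forward(h, gamma, beta, W1, b1, W2, b2, mask, fs);
  mat O = fs.Rd * W1.t();
  O.each_row() += b1.t();
  return h + O;
}

// [[Rcpp::export]]
List ffn_bwd_cpp(const arma::mat& dout, const arma::mat& h,
                 const arma::vec& gamma, const arma::vec& beta,
                 const arma::mat& W1, const arma::vec& b1,
                 const arma::mat& W2, const arma::vec& b2,
                 const arma::mat& mask) {
  FfnState fs;
  ffn_forward(h, gamma, beta, W1, b1, W2, b2, mask, fs);

  mat dW1 = dout.t() * fs.Rd;
  arma::vec db1 = arma::sum(dout, 0).t();
  mat dRd = dout * W1;
  mat dRl = mask.n_elem > 0 ? mat(dRd % mask) : dRd;
  mat dZ = dRl % (fs.Z > 0);
  mat dW2 = dZ.t() * fs.nrm;
  arma::vec db2 = arma::sum(dZ, 0).t();
  mat dnrm = dZ * W2;
  arma::vec dgamma = arma::sum(dnrm % fs.xhat, 0).t();
  arma::vec dbeta = arma::sum(dnrm, 0).t();
  mat dxhat = dnrm;
  dxhat.each_row() %= gamma.t();
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % fs.xhat, 1);
  mat dh = dxhat;
  dh.each_col() -= m1;
  mat xs = fs.xhat;
  xs.each_col() %= m2;
  dh -= xs;
  dh.each_col() %= fs.inv;
  dh += dout;

  return List::create(_["dh"] = dh, _["gamma"] = dgamma, _["beta"] = dbeta,
                      _["W1"] = dW1, _["b1"] = db1, _["W2"] = dW2,
                      _["b2"] = db2);
}

// normalized edge-weighted adjacency alone (inspection / tests)
// [[Rcpp::export]]
arma::mat gcn_norm_adj_cpp(const arma::mat& h, const arma::mat& e,
                           const arma::ivec& src1, const arma::ivec& dst1,
                           const arma::ivec& rev1, const arma::vec& wr,
                           const double br) {
  GcnState gs;
  const int n = h.n_rows;
  const int E = src1.n_elem;
  if (E > 0) {
    gs.z = e * wr + br;
    gs.wsig = 1.0 / (1.0 + arma::exp(-gs.z));
    gs.wsym.set_size(E);
    for (int m = 0; m < E; ++m)
      gs.wsym[m] = 0.5 * (gs.wsig[m] + gs.wsig[rev1[m] - 1]);
  }
  gs.Ahat.eye(n, n);
  for (int m = 0; m < E; ++m)
    gs.Ahat(src1[m] - 1, dst1[m] - 1) = gs.wsym[m];
  arma::vec deg = arma::sum(gs.Ahat, 1);
  arma::vec dinv = 1.0 / arma::sqrt(deg);
  mat S = gs.Ahat;
  S.each_col() %= dinv;
  S.each_row() %= dinv.t();
  return S;
}
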