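// Batched GRU forward/backward kernels. These mirror the reference R
// implementation in R/gru.R exactly (a unit test asserts agreement to
// machine precision); only the time loop lives in C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// plain R numeric vector (arma::vec would wrap as an H x 1 matrix)
static NumericVector vec2r(const arma::rowvec& v) {
  return NumericVector(v.begin(), v.end());
}

struct GruLayer {
  arma::mat Wz, Uz, Wr, Ur, Wc, Uc;
  arma::rowvec bz, br, bc;
  explicit GruLayer(const List& l)
    : Wz(as<arma::mat>(l["Wz"])), Uz(as<arma::mat>(l["Uz"])),
      Wr(as<arma::mat>(l["Wr"])), Ur(as<arma::mat>(l["Ur"])),
      Wc(as<arma::mat>(l["Wc"])), Uc(as<arma::mat>(l["Uc"])),
      bz(arma::conv_to<arma::rowvec>::from(as<arma::vec>(l["bz"]))),
      br(arma::conv_to<arma::rowvec>::from(as<arma::vec>(l["br"]))),
      bc(arma::conv_to<arma::rowvec>::from(as<arma::vec>(l["bc"]))) {}
};

struct GruCache {
  arma::cube z, r, c, hprev, h;  // B x H x T
};

// X: B x D x T cube, mask: T x B. Returns hidden states and gate caches.
static GruCache gru_forward(const GruLayer& L, const arma::cube& X,
                            const arma::mat& mask) {
  const arma::uword Tn = X.n_slices, B = X.n_rows, H = L.Wz.n_cols;
  GruCache C;
  C.z.set_size(B, H, Tn); C.r.set_size(B, H, Tn); C.c.set_size(B, H, Tn);
  C.hprev.set_size(B, H, Tn); C.h.set_size(B, H, Tn);
  arma::mat h(B, H, arma::fill::zeros);
  for (arma::uword t = 0; t < Tn; ++t) {
    const arma::mat x = X.slice(t);
    arma::mat z = x * L.Wz + h * L.Uz; z.each_row() += L.bz; z = sigmoid(z);
    arma::mat r = x * L.Wr + h * L.Ur; r.each_row() += L.br; r = sigmoid(r);
    arma::mat c = x * L.Wc + (r % h) * L.Uc; c.each_row() += L.bc;
    c = arma::tanh(c);
    arma::mat hnew = (1.0 - z) % h + z % c;
    const arma::vec m = mask.row(t).t();
    arma::mat hmask = hnew.each_col() % m + h.each_col() % (1.0 - m);
    C.z.slice(t) = z; C.r.slice(t) = r; C.c.slice(t) = c;
    C.hprev.slice(t) = h;
    h = hmask;
    C.h.slice(t) = h;
  }
  return C;
}

struct GruGrads {
  arma::mat Wz, Uz, Wr, Ur, Wc, Uc;
  arma::rowvec bz, br, bc;
};

// Backward through one layer; dH_seq (B x H x T) may be empty.
static GruGrads gru_backward(const GruLayer& L, const arma::cube& X,
                             const arma::mat& mask, const GruCache& C,
                             const arma::mat& dh_last,
                             const arma::cube& dH_seq, bool has_seq,
                             arma::cube& dX) {
  const arma::uword Tn = X.n_slices, B = X.n_rows, D = X.n_cols,
    H = L.Wz.n_cols;
  GruGrads g;
  g.Wz.zeros(D, H); g.Uz.zeros(H, H); g.Wr.zeros(D, H); g.Ur.zeros(H, H);
  g.Wc.zeros(D, H); g.Uc.zeros(H, H);
  g.bz.zeros(H); g.br.zeros(H); g.bc.zeros(H);
  dX.set_size(B, D, Tn);
  const arma::mat tUz = L.Uz.t(), tUr = L.Ur.t(), tUc = L.Uc.t();
  const arma::mat tWz = L.Wz.t(), tWr = L.Wr.t(), tWc = L.Wc.t();
  arma::mat dh = dh_last;
  for (arma::uword ti = Tn; ti-- > 0;) {
    if (has_seq) dh += dH_seq.slice(ti);
    const arma::vec m = mask.row(ti).t();
    const arma::mat& z = C.z.slice(ti);
    const arma::mat& r = C.r.slice(ti);
    const arma::mat& c = C.c.slice(ti);
    const arma::mat& hprev = C.hprev.slice(ti);
    arma::mat dhn = dh.each_col() % m;
    arma::mat dhp = dh.each_col() % (1.0 - m);
    arma::mat dz = dhn % (c - hprev) % z % (1.0 - z);
    arma::mat dc = dhn % z % (1.0 - c % c);
    arma::mat dcU = dc * tUc;
    arma::mat dr = dcU % hprev % r % (1.0 - r);
    const arma::mat x = X.slice(ti);
    g.Wz += x.t() * dz; g.Uz += hprev.t() * dz; g.bz += arma::sum(dz, 0);
    g.Wr += x.t() * dr; g.Ur += hprev.t() * dr; g.br += arma::sum(dr, 0);
    g.Wc += x.t() * dc; g.Uc += (r % hprev).t() * dc;
    g.bc += arma::sum(dc, 0);
    dX.slice(ti) = dz * tWz + dr * tWr + dc * tWc;
    dh = dhn % (1.0 - z) + dhp + dz * tUz + dr * tUr + dcU % r;
  }
  return g;
}

static List grads_to_list(const GruGrads& g) {
  return List::create(
    _["Wz"] = g.Wz, _["Uz"] = g.Uz, _["bz"] = vec2r(g.bz),
    _["Wr"] = g.Wr, _["Ur"] = g.Ur, _["br"] = vec2r(g.br),
    _["Wc"] = g.Wc, _["Uc"] = g.Uc, _["bc"] = vec2r(g.bc));
}

// Full forward (and optionally backward) pass over one padded batch.
// X: B x D x T cube; mask: T x B; dmask: dropout mask (already scaled by
// 1/(1-p)), 0 x 0 when inactive. Mirrors .batch_pass in R/gru.R.
// [[Rcpp::export(name = ".batch_pass_cpp")]]
List batch_pass_cpp(const List& params, const arma::cube& X,
                    const arma::mat& mask, const arma::vec& y,
                    const arma::vec& w, const arma::mat& dmask,
                    bool train) {
  const List gru = params["gru"];
  const GruLayer L1(gru[0]), L2(gru[1]);
  const List fc = params["fc"];
  const List out = params["out"];
  const arma::uword B = X.n_rows;

  GruCache C1 = gru_forward(L1, X, mask);
  GruCache C2 = gru_forward(L2, C1.h, mask);
  arma::mat h = C2.h.slice(C2.h.n_slices - 1);

  // dense ReLU stack
  std::vector<arma::mat> W(fc.size()), acts(fc.size());
  std::vector<arma::rowvec> b(fc.size());
  arma::mat a = h;
  for (int i = 0; i < fc.size(); ++i) {
    const List li = fc[i];
    W[i] = as<arma::mat>(li["W"]);
    b[i] = arma::conv_to<arma::rowvec>::from(as<arma::vec>(li["b"]));
    a = a * W[i]; a.each_row() += b[i];
    a = arma::clamp(a, 0.0, arma::datum::inf);
    acts[i] = a;
  }
  const bool use_drop = dmask.n_rows == B && dmask.n_cols == a.n_cols;
  arma::mat dropped = use_drop ? arma::mat(a % dmask) : a;
  const arma::mat Wo = as<arma::mat>(out["W"]);
  const double bo = as<arma::vec>(out["b"])(0);
  arma::mat logit = dropped * Wo + bo;
  arma::vec p = 1.0 / (1.0 + arma::exp(-logit.col(0)));

  arma::vec pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  double loss = -arma::mean(w % (y % arma::log(pc) +
                                 (1.0 - y) % arma::log(1.0 - pc)));
  if (!train) {
    return List::create(_["loss"] = loss, _["p"] = p);
  }

  // head backward
  arma::mat dlogit = (w % (pc - y)) / double(B);
  List gout = List::create(_["W"] = arma::mat(dropped.t() * dlogit),
                           _["b"] = NumericVector::create(arma::accu(dlogit)));
  arma::mat da = dlogit * Wo.t();
  if (use_drop) da = da % dmask;
  List gfc(fc.size());
  for (int i = fc.size() - 1; i >= 0; --i) {
    da = da % arma::conv_to<arma::mat>::from(acts[i] > 0);
    const arma::mat inp = (i == 0) ? h : acts[i - 1];
    gfc[i] = List::create(_["W"] = arma::mat(inp.t() * da),
                          _["b"] = vec2r(arma::sum(da, 0)));
    da = da * W[i].t();
  }

  arma::cube dX2, dX1;
  arma::cube empty;
  GruGrads g2 = gru_backward(L2, C1.h, mask, C2, da, empty, false, dX2);
  arma::mat zero(B, L1.Wz.n_cols, arma::fill::zeros);
  GruGrads g1 = gru_backward(L1, X, mask, C1, zero, dX2, true, dX1);

  return List::create(
    _["loss"] = loss, _["p"] = p,
    _["grads"] = List::create(
      _["gru"] = List::create(grads_to_list(g1), grads_to_list(g2)),
      _["fc"] = gfc, _["out"] = gout));
}
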