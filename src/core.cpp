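// Core numerical routines: batched settling, BPTT gradients, twin-network echo.
// The recurrent dynamics are a(t) = a(t-1) + lambda * (sigma(net(t)) - a(t-1)),
// with clamped pools held fixed and unclamped pools starting at sigma(bias).
#include <RcppArmadillo.h>
#include <random>
#include <array>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }
inline rowvec sigm(const rowvec& x) { return 1.0 / (1.0 + exp(-x)); }
inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Deterministic Fisher-Yates (std::shuffle is implementation-defined).
template <class V>
void fy_shuffle(V& v, std::mt19937_64& rng) {
  for (size_t i = v.size(); i > 1; --i) {
    size_t j = static_cast<size_t>(rng() % i);
    std::swap(v[i - 1], v[j]);
  }
}

struct Weights {
  mat w_ah, w_ha, w_bh, w_hb, w_rh, w_hr;
  rowvec b_a, b_b, b_r;
  double b_h;
};

Weights unpack(const List& w) {
  Weights W;
  W.w_ah = as<mat>(w["w_ah"]); W.w_ha = as<mat>(w["w_ha"]);
  W.w_bh = as<mat>(w["w_bh"]); W.w_hb = as<mat>(w["w_hb"]);
  W.w_rh = as<mat>(w["w_rh"]); W.w_hr = as<mat>(w["w_hr"]);
  W.b_a = as<rowvec>(w["b_a"]); W.b_b = as<rowvec>(w["b_b"]);
  W.b_r = as<rowvec>(w["b_r"]); W.b_h = as<double>(w["b_h"]);
  return W;
}

List pack(const Weights& W) {
  return List::create(
    _["w_ah"] = W.w_ah, _["w_ha"] = W.w_ha,
    _["w_bh"] = W.w_bh, _["w_hb"] = W.w_hb,
    _["w_rh"] = W.w_rh, _["w_hr"] = W.w_hr,
    _["b_a"] = NumericVector(W.b_a.begin(), W.b_a.end()),
    _["b_b"] = NumericVector(W.b_b.begin(), W.b_b.end()),
    _["b_r"] = NumericVector(W.b_r.begin(), W.b_r.end()),
    _["b_h"] = W.b_h);
}

struct Grads {
  mat s1h, s2h, ph, hp;    // into-H matrices; H -> target pool
  mat hs1, hs2;            // H -> clamped source pools (readout training)
  rowvec bp, bs1, bs2;     // visible-pool biases
  double loss;
};

// One forward + backward pass over a homogeneous mini-batch.
// S1, S2: clamped source pools (rows = trials); P: target pool; Y: targets.
// The target pool receives cross-entropy on its settling activations over the
// final `target_ticks` ticks. The clamped pools receive cross-entropy on the
// logistic of their hidden-driven net input against their own clamp pattern
// over the same window, so the hidden-to-visible readout of every pool is
// trained in every trial type and the network stores complete propositions
// as attractors.
// Errors are squared deviations with a zero-error margin: a unit within
// `margin` of its target contributes nothing, so training deepens attractors
// only until completions are reliably near their targets and weights stay
// moderate (activations, and hence the test-time echo, remain graded).
inline void margin_sse(const mat& a, const mat& Y, double margin,
                       double& loss, mat& deriv)
{
  mat d = a - Y;
  mat live = conv_to<mat>::from(abs(d) > margin);
  mat dm = (d - margin * sign(d)) % live;
  loss += accu(square(dm));
  deriv = 2.0 * dm;
}

Grads batch_pass(const mat& S1, const mat& S2, const mat& Y,
                 const mat& Ws1h, const mat& Ws2h,
                 const mat& Wph, const mat& Whp,
                 const mat& Whs1, const mat& Whs2,
                 const rowvec& bP, const rowvec& bS1, const rowvec& bS2,
                 double bH, double lambda, int T, int target_ticks,
                 double margin, double readout_margin)
{
  const uword Bt = S1.n_rows, nH = Ws1h.n_cols, nP = Wph.n_rows;

  mat Cin = S1 * Ws1h + S2 * Ws2h;  // clamp drive into H, constant over ticks
  std::vector<mat> Hs(T + 1), Ps(T + 1), sH(T + 1), sP(T + 1);
  std::vector<mat> sS1(T + 1), sS2(T + 1);  // readout predictions of clamps
  Hs[0].set_size(Bt, nH); Hs[0].fill(sigm(bH));
  Ps[0] = repmat(sigm(bP), Bt, 1);
  for (int t = 1; t <= T; ++t) {
    mat netH = Cin + Ps[t - 1] * Wph + bH;
    mat netP = Hs[t - 1] * Whp;
    netP.each_row() += bP;
    sH[t] = sigm(netH);
    sP[t] = sigm(netP);
    if (t > T - target_ticks) {
      mat net1 = Hs[t - 1] * Whs1; net1.each_row() += bS1;
      mat net2 = Hs[t - 1] * Whs2; net2.each_row() += bS2;
      sS1[t] = sigm(net1);
      sS2[t] = sigm(net2);
    }
    Hs[t] = Hs[t - 1] + lambda * (sH[t] - Hs[t - 1]);
    Ps[t] = Ps[t - 1] + lambda * (sP[t] - Ps[t - 1]);
  }

  Grads g;
  g.s1h.zeros(Ws1h.n_rows, nH); g.s2h.zeros(Ws2h.n_rows, nH);
  g.ph.zeros(nP, nH); g.hp.zeros(nH, nP);
  g.hs1.zeros(nH, Whs1.n_cols); g.hs2.zeros(nH, Whs2.n_cols);
  g.bp.zeros(nP); g.bs1.zeros(Whs1.n_cols); g.bs2.zeros(Whs2.n_cols);
  g.loss = 0.0;

  mat gP(Bt, nP, fill::zeros), gH(Bt, nH, fill::zeros);
  mat dPn, dHn, dS1n, dS2n;
  bool have_next = false, have_clamp_next = false;
  for (int t = T; t >= 1; --t) {
    mat direct(Bt, nP, fill::zeros);
    mat dS1, dS2;
    bool clamp_loss = t > T - target_ticks;
    if (clamp_loss) {
      margin_sse(Ps[t], Y, margin, g.loss, direct);
      mat e1, e2;
      margin_sse(sS1[t], S1, readout_margin, g.loss, e1);
      margin_sse(sS2[t], S2, readout_margin, g.loss, e2);
      dS1 = e1 % (sS1[t] % (1.0 - sS1[t]));  // through the readout logistic
      dS2 = e2 % (sS2[t] % (1.0 - sS2[t]));
    }
    if (have_next) {
      gP = direct + (1.0 - lambda) * gP + dHn * Wph.t();
      gH = (1.0 - lambda) * gH + dPn * Whp.t();
      if (have_clamp_next) {
        gH += dS1n * Whs1.t() + dS2n * Whs2.t();
      }
    } else {
      gP = direct;
      gH.zeros();
    }
    mat dP = gP % (lambda * (sP[t] % (1.0 - sP[t])));
    mat dH = gH % (lambda * (sH[t] % (1.0 - sH[t])));
    g.ph  += Ps[t - 1].t() * dH;
    g.s1h += S1.t() * dH;
    g.s2h += S2.t() * dH;
    g.hp  += Hs[t - 1].t() * dP;
    g.bp  += sum(dP, 0);
    if (clamp_loss) {
      g.hs1 += Hs[t - 1].t() * dS1;
      g.hs2 += Hs[t - 1].t() * dS2;
      g.bs1 += sum(dS1, 0);
      g.bs2 += sum(dS2, 0);
      dS1n = dS1; dS2n = dS2;
      have_clamp_next = true;
    } else {
      have_clamp_next = false;
    }
    dPn = dP; dHn = dH;
    have_next = true;
  }
  // Initial-state path: P(0) = sigma(bP), so the target-pool bias also
  // receives gradient through the starting activation.
  mat gP0 = (1.0 - lambda) * gP + dHn * Wph.t();
  rowvec p0 = sigm(bP);
  g.bp += sum(gP0, 0) % (p0 % (1.0 - p0));
  return g;
}

// Build one-hot / pattern matrices for a batch of trials of one combo type.
// combo: 0 = AB->R, 1 = AR->B, 2 = BR->A.  props cols: a, b, rel (0-based), freq.
void make_batch(int combo, const std::vector<int>& perm, int lo, int hi,
                const IntegerMatrix& props, const mat& relpat,
                int nA, int nB, mat& S1, mat& S2, mat& Y)
{
  int Bt = hi - lo;
  int nR = relpat.n_cols;
  switch (combo) {
  case 0: S1.zeros(Bt, nA); S2.zeros(Bt, nB); Y.zeros(Bt, nR); break;
  case 1: S1.zeros(Bt, nA); S2.zeros(Bt, nR); Y.zeros(Bt, nB); break;
  default: S1.zeros(Bt, nB); S2.zeros(Bt, nR); Y.zeros(Bt, nA); break;
  }
  for (int k = 0; k < Bt; ++k) {
    int p = perm[lo + k];
    int a = props(p, 0), b = props(p, 1), r = props(p, 2);
    switch (combo) {
    case 0: S1(k, a) = 1.0; S2(k, b) = 1.0; Y.row(k) = relpat.row(r); break;
    case 1: S1(k, a) = 1.0; S2.row(k) = relpat.row(r); Y(k, b) = 1.0; break;
    default: S1(k, b) = 1.0; S2.row(k) = relpat.row(r); Y(k, a) = 1.0; break;
    }
  }
}

void select_ptrs(int combo, Weights& W,
                 mat*& Ws1h, mat*& Ws2h, mat*& Wph, mat*& Whp,
                 mat*& Whs1, mat*& Whs2,
                 rowvec*& bP, rowvec*& bS1, rowvec*& bS2)
{
  switch (combo) {
  case 0:
    Ws1h = &W.w_ah; Ws2h = &W.w_bh; Wph = &W.w_rh; Whp = &W.w_hr;
    Whs1 = &W.w_ha; Whs2 = &W.w_hb; bP = &W.b_r; bS1 = &W.b_a; bS2 = &W.b_b;
    break;
  case 1:
    Ws1h = &W.w_ah; Ws2h = &W.w_rh; Wph = &W.w_bh; Whp = &W.w_hb;
    Whs1 = &W.w_ha; Whs2 = &W.w_hr; bP = &W.b_b; bS1 = &W.b_a; bS2 = &W.b_r;
    break;
  default:
    Ws1h = &W.w_bh; Ws2h = &W.w_rh; Wph = &W.w_ah; Whp = &W.w_ha;
    Whs1 = &W.w_hb; Whs2 = &W.w_hr; bP = &W.b_a; bS1 = &W.b_b; bS2 = &W.b_r;
    break;
  }
}

}  // namespace

// Train for n_epochs epochs (mini-batch BPTT) and return updated weights plus the
// per-trial mean loss of each epoch.  Epoch shuffles come from an internal
// Mersenne Twister seeded from seed_base and the absolute epoch index, so training
// in chunks is identical to training straight through.
// [[Rcpp::export]]
List cpp_train_epochs(List wlist, IntegerMatrix props, NumericMatrix relpat_,
                      double lr, double lambda, int n_ticks, int target_ticks,
                      double margin, double readout_margin, int batch_size,
                      int epoch_start, int n_epochs, double seed_base,
                      bool tie_weights)
{
  Weights W = unpack(wlist);
  mat relpat = as<mat>(relpat_);
  const int nA = W.w_ah.n_rows, nB = W.w_bh.n_rows;
  const int nProps = props.nrow();

  std::vector<int> E;
  for (int i = 0; i < nProps; ++i)
    for (int k = 0; k < props(i, 3); ++k) E.push_back(i);
  const int F = static_cast<int>(E.size());

  NumericVector mean_loss(n_epochs);
  for (int e = 0; e < n_epochs; ++e) {
    uint64_t s = static_cast<uint64_t>(static_cast<int64_t>(seed_base)) * 2654435761ULL
               + static_cast<uint64_t>(epoch_start + e) * 97531ULL + 17ULL;
    std::mt19937_64 rng(s);
    std::vector<int> perm[3];
    for (int c = 0; c < 3; ++c) { perm[c] = E; fy_shuffle(perm[c], rng); }
    std::vector<std::array<int, 3>> batches;
    for (int c = 0; c < 3; ++c)
      for (int lo = 0; lo < F; lo += batch_size)
        batches.push_back({c, lo, std::min(lo + batch_size, F)});
    fy_shuffle(batches, rng);

    double tot = 0.0;
    mat S1, S2, Y;
    for (const auto& bd : batches) {
      const int combo = bd[0], lo = bd[1], hi = bd[2];
      const int Bt = hi - lo;
      make_batch(combo, perm[combo], lo, hi, props, relpat, nA, nB, S1, S2, Y);
      mat *Ws1h, *Ws2h, *Wph, *Whp, *Whs1, *Whs2;
      rowvec *bP, *bS1, *bS2;
      select_ptrs(combo, W, Ws1h, Ws2h, Wph, Whp, Whs1, Whs2, bP, bS1, bS2);
      Grads g = batch_pass(S1, S2, Y, *Ws1h, *Ws2h, *Wph, *Whp, *Whs1, *Whs2,
                           *bP, *bS1, *bS2, W.b_h,
                           lambda, n_ticks, target_ticks, margin,
                           readout_margin);
      if (!std::isfinite(g.loss))
        stop("non-finite loss at epoch %d (combo %d): diverging weights; lower lr",
             epoch_start + e + 1, combo);
      const double step = lr / Bt;
      *Ws1h -= step * g.s1h; *Ws2h -= step * g.s2h;
      *Wph  -= step * g.ph;  *Whp  -= step * g.hp;
      *Whs1 -= step * g.hs1; *Whs2 -= step * g.hs2;
      *bP -= step * g.bp; *bS1 -= step * g.bs1; *bS2 -= step * g.bs2;
      if (tie_weights) {
        W.w_ah = 0.5 * (W.w_ah + W.w_ha.t()); W.w_ha = W.w_ah.t();
        W.w_bh = 0.5 * (W.w_bh + W.w_hb.t()); W.w_hb = W.w_bh.t();
        W.w_rh = 0.5 * (W.w_rh + W.w_hr.t()); W.w_hr = W.w_rh.t();
      }
      tot += g.loss;
    }
    mean_loss[e] = tot / (3.0 * F);
  }
  return List::create(_["weights"] = pack(W), _["mean_loss"] = mean_loss);
}

// Loss and full gradient for a single triple-completion trial (no update).
// a_idx/b_idx are 0-based localist unit indices; rel is the dense 0/1 pattern.
// [[Rcpp::export]]
List cpp_bptt_grad(List wlist, int a_idx, int b_idx, NumericVector rel, int combo,
                   double lambda, int n_ticks, int target_ticks, double margin,
                   double readout_margin)
{
  Weights W = unpack(wlist);
  const int nA = W.w_ah.n_rows, nB = W.w_bh.n_rows, nR = W.w_rh.n_rows;
  rowvec rpat(rel.begin(), rel.size());
  mat S1, S2, Y;
  switch (combo) {
  case 0:
    S1.zeros(1, nA); S1(0, a_idx) = 1.0;
    S2.zeros(1, nB); S2(0, b_idx) = 1.0;
    Y = rpat; break;
  case 1:
    S1.zeros(1, nA); S1(0, a_idx) = 1.0;
    S2 = rpat;
    Y.zeros(1, nB); Y(0, b_idx) = 1.0; break;
  default:
    S1.zeros(1, nB); S1(0, b_idx) = 1.0;
    S2 = rpat;
    Y.zeros(1, nA); Y(0, a_idx) = 1.0; break;
  }
  mat *Ws1h, *Ws2h, *Wph, *Whp, *Whs1, *Whs2;
  rowvec *bP, *bS1, *bS2;
  select_ptrs(combo, W, Ws1h, Ws2h, Wph, Whp, Whs1, Whs2, bP, bS1, bS2);
  Grads g = batch_pass(S1, S2, Y, *Ws1h, *Ws2h, *Wph, *Whp, *Whs1, *Whs2,
                       *bP, *bS1, *bS2, W.b_h, lambda, n_ticks, target_ticks,
                       margin, readout_margin);

  // Route the live gradients into a full-shape, zero-filled gradient set.
  mat g_ah(nA, W.w_ah.n_cols, fill::zeros), g_bh(nB, W.w_ah.n_cols, fill::zeros),
      g_rh(nR, W.w_ah.n_cols, fill::zeros);
  mat g_ha(W.w_ha.n_rows, nA, fill::zeros), g_hb(W.w_hb.n_rows, nB, fill::zeros),
      g_hr(W.w_hr.n_rows, nR, fill::zeros);
  rowvec g_ba(nA, fill::zeros), g_bb(nB, fill::zeros), g_br(nR, fill::zeros);
  switch (combo) {
  case 0:
    g_ah = g.s1h; g_bh = g.s2h; g_rh = g.ph; g_hr = g.hp; g_br = g.bp;
    g_ha = g.hs1; g_hb = g.hs2; g_ba = g.bs1; g_bb = g.bs2;
    break;
  case 1:
    g_ah = g.s1h; g_rh = g.s2h; g_bh = g.ph; g_hb = g.hp; g_bb = g.bp;
    g_ha = g.hs1; g_hr = g.hs2; g_ba = g.bs1; g_br = g.bs2;
    break;
  default:
    g_bh = g.s1h; g_rh = g.s2h; g_ah = g.ph; g_ha = g.hp; g_ba = g.bp;
    g_hb = g.hs1; g_hr = g.hs2; g_bb = g.bs1; g_br = g.bs2;
    break;
  }
  return List::create(
    _["loss"] = g.loss,
    _["grads"] = List::create(
      _["w_ah"] = g_ah, _["w_ha"] = g_ha,
      _["w_bh"] = g_bh, _["w_hb"] = g_hb,
      _["w_rh"] = g_rh, _["w_hr"] = g_hr,
      _["b_a"] = NumericVector(g_ba.begin(), g_ba.end()),
      _["b_b"] = NumericVector(g_bb.begin(), g_bb.end()),
      _["b_r"] = NumericVector(g_br.begin(), g_br.end())));
}

// Twin-architecture echo trials, batched over questions.  Each row clamps
// a, b, c throughout; d is clamped for phase1 ticks then released with its
// state retained.  Returns the final activation of each row's d unit.
// H->R drive from each half is scaled by `scale` (0.5 restores the trained
// net-input magnitude when both halves agree).
// [[Rcpp::export]]
NumericVector cpp_echo_batch(List wlist,
                             IntegerVector ai, IntegerVector bi,
                             IntegerVector ci, IntegerVector di,
                             int phase1, int phase2, double lambda,
                             double h1_bias, double h2_bias, double scale)
{
  Weights W = unpack(wlist);
  const int nA = W.w_ah.n_rows, nB = W.w_bh.n_rows, nH = W.w_ah.n_cols;
  const int Bt = ai.size();

  mat XA(Bt, nA, fill::zeros), XB(Bt, nB, fill::zeros),
      XC(Bt, nA, fill::zeros), XD(Bt, nB, fill::zeros);
  for (int k = 0; k < Bt; ++k) {
    XA(k, ai[k]) = 1.0; XB(k, bi[k]) = 1.0;
    XC(k, ci[k]) = 1.0; XD(k, di[k]) = 1.0;
  }
  mat H1(Bt, nH), H2(Bt, nH);
  H1.fill(sigm(h1_bias)); H2.fill(sigm(h2_bias));
  mat R = repmat(sigm(W.b_r), Bt, 1);
  mat D = XD;

  const mat C1 = XA * W.w_ah + XB * W.w_bh;  // clamp drive into H1
  const mat C2 = XC * W.w_ah;                // C-item drive into H2

  for (int t = 0; t < phase1 + phase2; ++t) {
    const bool d_free = t >= phase1;
    mat netH1 = C1 + R * W.w_rh + h1_bias;
    mat netH2 = C2 + D * W.w_bh + R * W.w_rh + h2_bias;
    mat netR = scale * ((H1 + H2) * W.w_hr);
    netR.each_row() += W.b_r;
    mat Dn = D;
    if (d_free) {
      mat netD = H2 * W.w_hb;
      netD.each_row() += W.b_b;
      Dn = D + lambda * (sigm(netD) - D);
    }
    H1 += lambda * (sigm(netH1) - H1);
    H2 += lambda * (sigm(netH2) - H2);
    R  += lambda * (sigm(netR) - R);
    D = Dn;
  }
  NumericVector echo(Bt);
  for (int k = 0; k < Bt; ++k) echo[k] = D(k, di[k]);
  return echo;
}
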