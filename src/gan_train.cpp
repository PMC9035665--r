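// Conditional GAN training core.
//
// Dense generator with a linear condition/latent skip path, projection
// discriminator with additive (age row + disease row) label projection,
// least-squares adversarial objective with matching-aware negatives
// (real images paired with permuted labels scored as fakes), Adam updates
// throughout, and a generator-side factorized embedding table trained at
// its own learning rate. All randomness flows through R's RNG so results
// are reproducible from set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;



namespace {

struct Adam {
  fmat m, v;
  int t = 0;
  explicit Adam(const fmat &p) : m(arma::size(p), arma::fill::zeros),
                                v(arma::size(p), arma::fill::zeros) {}
  void step(fmat &p, const fmat &g, float lr) {
    ++t;
    m = 0.9f * m + 0.1f * g;
    v = 0.999f * v + 0.001f * (g % g);
    const float c1 = 1.0f - std::pow(0.9f, t);
    const float c2 = 1.0f - std::pow(0.999f, t);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8f);
  }
  // keep exponentially decaying moments out of the subnormal range,
  // where arithmetic is pathologically slow
  void flush() {
    m.clean(1e-30f);
    v.clean(1e-30f);
  }
};

fmat rnorm_mat(int r, int c) {
  NumericVector draws = rnorm(r * c);
  fmat out(r, c);
  std::copy(draws.begin(), draws.end(), out.begin());
  return out;
}

// sample `k` values from 0..n-1 using R's RNG
arma::uvec sample_idx(int n, int k, bool replace) {
  IntegerVector s = sample(n, k, replace);
  arma::uvec out(k);
  for (int i = 0; i < k; ++i) out[i] = s[i] - 1;
  return out;
}

} // namespace

// [[Rcpp::export(name = ".gan_train_cpp")]]
List gan_train_cpp(const arma::mat &x_all_d,       // npx x N pixel columns
                   const arma::uvec &age_idx,    // 1-based bracket per image
                   const arma::uvec &dis_idx,    // 1-based disease per image
                   const arma::uvec &aff,        // 1-based indices, affected
                   const arma::uvec &unaff,      // 1-based, unaffected
                   List G0, List D0,
                   const arma::mat &age_emb0_d,    // 5 x ea
                   const arma::mat &dis_emb0_d,    // 4 x ed
                   int iters, int batch, int latent,
                   double lr_d, double lr_embed_d,
                   int embed_freeze_after, double mismatch_weight,
                   double recon_weight, double diversity_weight,
                   double diversity_margin) {
  const fmat x_all = arma::conv_to<fmat>::from(x_all_d);
  const float lr = (float)lr_d, lr_embed = (float)lr_embed_d;
  const int npx = x_all.n_rows;
  const fmat age_emb0 = arma::conv_to<fmat>::from(age_emb0_d);
  const fmat dis_emb0 = arma::conv_to<fmat>::from(dis_emb0_d);
  const int ea = age_emb0.n_cols, ed = dis_emb0.n_cols;
  const int cdim = ea + ed;
  const int half = batch / 2;

  fmat Gw1 = arma::conv_to<fmat>::from(as<arma::mat>(G0["W1"]));
  fmat Gw2 = arma::conv_to<fmat>::from(as<arma::mat>(G0["W2"]));
  fmat Gws = arma::conv_to<fmat>::from(as<arma::mat>(G0["Ws"]));
  fvec Gb1 = arma::conv_to<fvec>::from(as<arma::vec>(G0["b1"]));
  fvec Gb2 = arma::conv_to<fvec>::from(as<arma::vec>(G0["b2"]));
  fmat Dw1 = arma::conv_to<fmat>::from(as<arma::mat>(D0["W1"]));
  fmat Dv = arma::conv_to<fmat>::from(as<arma::mat>(D0["V"]));
  fvec Db1 = arma::conv_to<fvec>::from(as<arma::vec>(D0["b1"]));
  frowvec Dw0 = arma::conv_to<frowvec>::from(as<arma::rowvec>(D0["w0"]));
  float Db0 = (float)as<double>(D0["b0"]);
  fmat Aemb = age_emb0, Demb = dis_emb0;

  Adam aGw1(Gw1), aGw2(Gw2), aGws(Gws), aGb1(Gb1), aGb2(Gb2);
  Adam aDw1(Dw1), aDv(Dv), aDb1(Db1), aDw0(Dw0);
  Adam aAemb(Aemb), aDemb(Demb);
  float mDb0 = 0, vDb0 = 0;

  arma::vec trace_real(iters), trace_fake(iters), g_loss(iters), aff_frac(iters);
  arma::mat audit(5, 4, arma::fill::zeros);

  // one-hot label blocks (9 x batch) rebuilt per batch
  fmat L(9, batch), Lm(9, batch), C(cdim, batch);
  arma::uvec idx(batch);

  auto d_forward = [&](const fmat &x, const fmat &lab, fmat &a, frowvec &o) {
    a = arma::tanh(Dw1 * x + arma::repmat(Db1, 1, x.n_cols));
    o = Dw0 * a + Db0 + arma::sum((Dv.t() * lab) % a, 0);
  };

  // backward through D for d(loss)/d(score) = dout; returns dx and
  // accumulates parameter gradients into the g* references
  auto d_backward = [&](const fmat &x, const fmat &lab, const fmat &a,
                        const frowvec &dout, fmat &gW1, fvec &gb1, frowvec &gw0,
                        float &gb0, fmat &gV, fmat &dx, bool want_dx) {
    fmat dA = Dw0.t() * dout + (Dv.t() * lab).eval().each_row() % dout;
    fmat dz = dA % (1.0f - a % a);
    dz.clean(1e-30f);
    gW1 += dz * x.t();
    gb1 += arma::sum(dz, 1);
    gw0 += dout * a.t();
    gb0 += arma::accu(dout);
    gV += lab * (a.each_row() % dout).t();
    if (want_dx) dx = Dw1.t() * dz;
  };

  for (int it = 0; it < iters; ++it) {
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
    arma::uvec ia = sample_idx(aff.n_elem, half, half > (int)aff.n_elem);
    arma::uvec iu = sample_idx(unaff.n_elem, half,
                               half > (int)unaff.n_elem);
    for (int j = 0; j < half; ++j) idx[j] = aff[ia[j]] - 1;
    for (int j = 0; j < half; ++j) idx[half + j] = unaff[iu[j]] - 1;
    float naff = 0;
    L.zeros();
    for (int j = 0; j < batch; ++j) {
      const int i = idx[j];
      L(age_idx[i] - 1, j) = 1.0;
      L(5 + dis_idx[i] - 1, j) = 1.0;
      C.submat(0, j, ea - 1, j) = Aemb.row(age_idx[i] - 1).t();
      C.submat(ea, j, cdim - 1, j) = Demb.row(dis_idx[i] - 1).t();
      if (dis_idx[i] != 4) naff += 1.0; // label 4 is "unaffected"
    }
    aff_frac[it] = naff / batch;
    fmat xr = x_all.cols(idx);

    // ---- discriminator step ----
    fmat z = rnorm_mat(latent, batch);
    fmat ginp = arma::join_cols(z, C);
    fmat ga = arma::tanh(Gw1 * ginp + arma::repmat(Gb1, 1, batch));
    fmat xf = 1.0f / (1.0f + arma::exp(-(Gw2 * ga + Gws * ginp +
                                      arma::repmat(Gb2, 1, batch))));
    xf = arma::clamp(xf, 1e-6f, 1.0f - 1e-6f);

    fmat ar, af, am;
    frowvec orr, off, om;
    d_forward(xr, L, ar, orr);
    d_forward(xf, L, af, off);
    trace_real[it] = arma::mean(orr);
    trace_fake[it] = arma::mean(off);

    // matching-aware negatives: real images, permuted labels
    arma::uvec perm = sample_idx(batch, batch, false);
    Lm = L.cols(perm);
    d_forward(xr, Lm, am, om);

    fmat gDw1(arma::size(Dw1), arma::fill::zeros);
    fvec gDb1(arma::size(Db1), arma::fill::zeros);
    frowvec gDw0(arma::size(Dw0), arma::fill::zeros);
    fmat gDv(arma::size(Dv), arma::fill::zeros);
    float gDb0 = 0;
    fmat dx_unused;
    d_backward(xr, L, ar, 2.0f * (orr - 1.0f) / batch, gDw1, gDb1, gDw0,
               gDb0, gDv, dx_unused, false);
    d_backward(xf, L, af, 2.0f * off / batch, gDw1, gDb1, gDw0, gDb0, gDv,
               dx_unused, false);
    d_backward(xr, Lm, am, (float)mismatch_weight * 2.0f * om / batch,
               gDw1, gDb1, gDw0, gDb0, gDv, dx_unused, false);
    aDw1.step(Dw1, gDw1, lr);
    aDb1.step(Db1, gDb1, lr);
    aDw0.step(Dw0, gDw0, lr);
    aDv.step(Dv, gDv, lr);
    { // scalar Adam for the bias
      mDb0 = 0.9f * mDb0 + 0.1f * gDb0;
      vDb0 = 0.999f * vDb0 + 0.001f * gDb0 * gDb0;
      const int t = aDw0.t;
      Db0 -= lr * (mDb0 / (1 - std::pow(0.9f, t))) /
        (std::sqrt(vDb0 / (1 - std::pow(0.999f, t))) + 1e-8f);
    }

    // ---- generator step ----
    bool have_extra = false;
    fmat gGw2_extra, gGws_extra, gGw1_extra;
    fvec gGb2_extra, gGb1_extra;
    z = rnorm_mat(latent, batch);
    ginp = arma::join_cols(z, C);
    ga = arma::tanh(Gw1 * ginp + arma::repmat(Gb1, 1, batch));
    xf = 1.0f / (1.0f + arma::exp(-(Gw2 * ga + Gws * ginp +
                                  arma::repmat(Gb2, 1, batch))));
    xf = arma::clamp(xf, 1e-6f, 1.0f - 1e-6f);
    fmat afg;
    frowvec ofg;
    d_forward(xf, L, afg, ofg);
    g_loss[it] = arma::mean(arma::square(ofg - 1.0f));

    fmat gW1z(arma::size(Dw1), arma::fill::zeros); // discarded
    fvec gb1z(arma::size(Db1), arma::fill::zeros);
    frowvec gw0z(arma::size(Dw0), arma::fill::zeros);
    fmat gVz(arma::size(Dv), arma::fill::zeros);
    float gb0z = 0;
    fmat dxf;
    d_backward(xf, L, afg, 2.0f * (ofg - 1.0f) / batch, gW1z, gb1z, gw0z,
               gb0z, gVz, dxf, true);

    fmat dpre = dxf % xf % (1.0f - xf);
    if (diversity_weight > 0) {
      // diversity hinge: two fakes sharing each condition are pushed apart
      // until their mean squared difference reaches the margin, so the
      // latent keeps driving within-condition ("identity") variation
      fmat z2 = rnorm_mat(latent, batch);
      fmat ginp2 = arma::join_cols(z2, C);
      fmat ga2 = arma::tanh(Gw1 * ginp2 + arma::repmat(Gb1, 1, batch));
      fmat xf2 = 1.0f / (1.0f + arma::exp(-(Gw2 * ga2 + Gws * ginp2 +
                                            arma::repmat(Gb2, 1, batch))));
      xf2 = arma::clamp(xf2, 1e-6f, 1.0f - 1e-6f);
      fmat dxx = xf - xf2;
      const float msd = arma::accu(dxx % dxx) / (npx * batch);
      if (msd < (float)diversity_margin) {
        const float w = (float)diversity_weight * 2.0f / (npx * batch);
        dpre += (-w * dxx) % xf % (1.0f - xf);
        // backprop the symmetric push through the second fake as well
        fmat dpre2 = (w * dxx) % xf2 % (1.0f - xf2);
        dpre2.clean(1e-30f);
        gGw2_extra = dpre2 * ga2.t();
        gGb2_extra = arma::sum(dpre2, 1);
        gGws_extra = dpre2 * ginp2.t();
        fmat dz2b = (Gw2.t() * dpre2) % (1.0f - ga2 % ga2);
        dz2b.clean(1e-30f);
        gGw1_extra = dz2b * ginp2.t();
        gGb1_extra = arma::sum(dz2b, 1);
        have_extra = true;
      }
    }
    if (recon_weight > 0) {
      // paired conditional reconstruction: the fake generated under image
      // j's labels is anchored to image j itself (conditional-mean anchor)
      const float w = (float)recon_weight * 2.0f / (npx * batch);
      dpre += (w * (xf - xr)) % xf % (1.0f - xf);
    }
    dpre.clean(1e-30f);
    fmat gGw2 = dpre * ga.t();
    fvec gGb2 = arma::sum(dpre, 1);
    fmat gGws = dpre * ginp.t();
    fmat dz2 = (Gw2.t() * dpre) % (1.0f - ga % ga);
    dz2.clean(1e-30f);
    fmat gGw1 = dz2 * ginp.t();
    fvec gGb1 = arma::sum(dz2, 1);
    if (have_extra) {
      gGw2 += gGw2_extra; gGb2 += gGb2_extra; gGws += gGws_extra;
      gGw1 += gGw1_extra; gGb1 += gGb1_extra;
    }
    fmat dinp = Gw1.t() * dz2 + Gws.t() * dpre;

    aGw1.step(Gw1, gGw1, lr);
    aGb1.step(Gb1, gGb1, lr);
    aGw2.step(Gw2, gGw2, lr);
    aGb2.step(Gb2, gGb2, lr);
    aGws.step(Gws, gGws, lr);

    // embedding gradients (generator objective only) + gradient-flow audit
    fmat gA(arma::size(Aemb), arma::fill::zeros);
    fmat gD(arma::size(Demb), arma::fill::zeros);
    for (int j = 0; j < batch; ++j) {
      const int i = idx[j];
      fvec dc = dinp.submat(latent, j, latent + cdim - 1, j);
      gA.row(age_idx[i] - 1) += dc.head(ea).t();
      gD.row(dis_idx[i] - 1) += dc.tail(ed).t();
      audit(age_idx[i] - 1, dis_idx[i] - 1) +=
        arma::accu(arma::abs(dc.head(ea)));
    }
    if (it < embed_freeze_after) {
      aAemb.step(Aemb, gA, lr_embed);
      aDemb.step(Demb, gD, lr_embed);
    }

    if ((it + 1) % 100 == 0) {
      aGw1.flush(); aGw2.flush(); aGws.flush(); aGb1.flush(); aGb2.flush();
      aDw1.flush(); aDv.flush(); aDb1.flush(); aDw0.flush();
      aAemb.flush(); aDemb.flush();
      Gw1.clean(1e-30f); Gw2.clean(1e-30f); Gws.clean(1e-30f);
      Dw1.clean(1e-30f); Dv.clean(1e-30f);
    }
    if (!std::isfinite(trace_real[it]) || !std::isfinite(trace_fake[it]) ||
        !std::isfinite(g_loss[it])) {
      stop("non-finite GAN losses at iteration %d", it + 1);
    }
  }

  auto dbl = [](const fmat &x) { return arma::conv_to<arma::mat>::from(x); };
  return List::create(
    _["G"] = List::create(_["W1"] = dbl(Gw1), _["b1"] = dbl(Gb1),
                          _["W2"] = dbl(Gw2), _["b2"] = dbl(Gb2),
                          _["Ws"] = dbl(Gws)),
    _["D"] = List::create(_["W1"] = dbl(Dw1), _["b1"] = dbl(Db1),
                          _["w0"] = dbl(Dw0), _["b0"] = (double)Db0,
                          _["V"] = dbl(Dv)),
    _["age_emb"] = dbl(Aemb), _["dis_emb"] = dbl(Demb),
    _["trace_real"] = trace_real, _["trace_fake"] = trace_fake,
    _["g_loss"] = g_loss, _["aff_frac"] = aff_frac,
    _["audit"] = audit);
}
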