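#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Event-driven propagation of the accumulator probability density.
//
// The accumulator a follows, away from the sticky bounds +-B,
//   da = sigma_a dW + lambda a dt + click impulses,
// so between consecutive events the transition is a linear SDE with exact
// Gaussian kernel: mean a*exp(lambda*dt), variance
// sigma_a2*(exp(2 lambda dt)-1)/(2 lambda) (limit sigma_a2*dt as lambda->0).
// A click of adapted amplitude Ck on side s contributes a Gaussian impulse
// with mean s*gain*Ck and variance gain^2*Ck^2*sigma_s2 (eta ~ N(1, sigma_s2)
// multiplying gain*Ck).
//
// Each event applies remap (mean mult*x + shift, mean-preserving linear
// interpolation) and diffusion (convolution with the bin-integrated Gaussian
// of the event sd) to the interior density, then transfers mass outside
// (-B, B) to the absorbing bins; absorption is checked once per event, after
// the noise, matching a path simulation that tests |a| >= B at event times.
//
// For event sds spanning many grid bins the convolution runs on a decimated
// grid of pitch h ~ s/2.5: a Gaussian is spectrally negligible beyond its
// bandwidth, so this pitch loses nothing, and the variance added by the
// deposit/kernel/upsample quantization chain (h^2/6 + h^2/12 + h^2/12,
// Sheppard corrections) is subtracted from the kernel width. This keeps the
// per-event cost at O(grid) regardless of the noise scale.

static const double INV_SQRT2 = 0.7071067811865475244;

static inline double norm_cdf(double z) { return 0.5 * erfc(-z * INV_SQRT2); }

struct Scratch {
  std::vector<double> ext, oute, outn, mc, mco, ker;
};

static void build_kernel(std::vector<double> &ker, double pitch, double s,
                         int K) {
  ker.assign(2 * K + 1, 0.0);
  double tot = 0.0;
  double prev = norm_cdf((-K - 0.5) * pitch / s);
  for (int k = -K; k <= K; ++k) {
    double cur = norm_cdf((k + 0.5) * pitch / s);
    double w = cur - prev;
    prev = cur;
    ker[k + K] = w;
    tot += w;
  }
  for (int k = 0; k < 2 * K + 1; ++k) ker[k] /= tot;
}

// Fine-grid path, used when the event sd spans only a few bins.
// mass below this per-bin threshold is dropped during remaps; the total
// leak is < n_bins * 1e-16 per event, orders below the 1e-6 conservation
// tolerance, and it keeps the active support window tight
static const double MASS_EPS = 1e-16;

static bool find_support(const std::vector<double> &m, int n,
                         int &ilo, int &ihi) {
  ilo = 0;
  while (ilo < n && m[ilo] <= MASS_EPS) ++ilo;
  if (ilo == n) return false;
  ihi = n - 1;
  while (m[ihi] <= MASS_EPS) --ihi;
  return true;
}

static void step_fine(std::vector<double> &m, int n, double dx, double B,
                      double mult, double shift, double s, Scratch &sc,
                      double &absL, double &absR) {
  int h = (n - 1) / 2;
  int ilo, ihi;
  if (!find_support(m, n, ilo, ihi)) return;   // everything absorbed
  int K = (s > 0.0) ? (int)std::ceil(5.5 * s / dx) : 0;
  int pad = K + 2;
  int ne = n + 2 * pad;
  sc.ext.assign(ne, 0.0);

  int jmin = ne, jmax = -1;
  double fi = (mult * (ilo - h) * dx + shift) / dx + (h + pad);
  for (int i = ilo; i <= ihi; ++i, fi += mult) {
    double mi = m[i];
    if (mi <= MASS_EPS) continue;
    if (fi < 0.0) { absL += mi; continue; }
    if (fi >= (double)(ne - 1)) { absR += mi; continue; }
    int j = (int)fi;
    double w = fi - j;
    sc.ext[j] += mi * (1.0 - w);
    sc.ext[j + 1] += mi * w;
    if (j < jmin) jmin = j;
    if (j + 1 > jmax) jmax = j + 1;
  }
  if (jmax < 0) { std::fill(m.begin(), m.end(), 0.0); return; }

  if (K > 0) {
    build_kernel(sc.ker, dx, s, K);
    const double *ker = sc.ker.data();
    int neo = ne + 2 * K;
    sc.oute.assign(neo, 0.0);
    double *oute = sc.oute.data();
    const double *ext = sc.ext.data();
    for (int j = jmin; j <= jmax; ++j) {
      double mj = ext[j];
      if (mj <= 0.0) continue;
      double *dst = oute + j;        // target offset j + k + K
      for (int k = 0; k < 2 * K + 1; ++k) dst[k] += mj * ker[k];
    }
    // interior bin t sits at oute index t + pad + K
    int off = pad + K;
    int qhi = std::min(neo, jmax + 2 * K + 1);
    for (int q = std::max(0, jmin); q < off; ++q) absL += oute[q];
    for (int q = std::max(off + n, jmin); q < qhi; ++q) absR += oute[q];
    std::fill(m.begin(), m.end(), 0.0);
    int t0 = std::max(0, jmin - off), t1 = std::min(n, qhi - off);
    for (int i = t0; i < t1; ++i) m[i] = oute[i + off];
  } else {
    for (int q = jmin; q < std::min(jmax + 1, pad); ++q) absL += sc.ext[q];
    for (int q = std::max(jmin, pad + n); q <= jmax; ++q) absR += sc.ext[q];
    std::fill(m.begin(), m.end(), 0.0);
    int t0 = std::max(0, jmin - pad), t1 = std::min(n, jmax + 1 - pad);
    for (int i = t0; i < t1; ++i) m[i] = sc.ext[i + pad];
  }
}

// Decimated path: deposit straight onto a coarse grid of pitch f*dx,
// convolve there, spread each coarse block back over its f fine bins, and
// smooth the blocky upsample with an odd boxcar (box*box = triangle) so
// threshold and bound integrals do not see pitch-scale steps. All variance
// the quantization chain adds (deposit h^2/6, kernel Sheppard h^2/12, box
// upsample h^2/12, boxcar (W^2-1)dx^2/12) is subtracted from the kernel.
static void step_decimated(std::vector<double> &m, int n, double dx, double B,
                           double mult, double shift, double s, int f,
                           Scratch &sc, double &absL, double &absR) {
  int h = (n - 1) / 2;
  double hc = f * dx;
  int W = (f % 2 == 0) ? f + 1 : f + 2;       // odd smoothing window
  double vcomp = (hc * hc) / 3.0 + (double)(W * W - 1) * dx * dx / 12.0;
  double s2 = std::sqrt(std::max(s * s - vcomp, 1e-12));
  int K = (int)std::ceil(5.5 * s2 / hc) + 1;
  build_kernel(sc.ker, hc, s2, K);

  // coarse centers at (j - jmid)*hc + delta; delta aligns block edges with
  // fine-bin edges for even f
  double delta = (f % 2 == 0) ? 0.5 * dx : 0.0;
  double reach = B + (K + 2) * hc;
  int jmid = (int)std::ceil(reach / hc) + K + 2;
  int nc = 2 * jmid + 1;
  sc.mc.assign(nc, 0.0);
  double *mc = sc.mc.data();

  int ilo, ihi;
  if (!find_support(m, n, ilo, ihi)) return;
  double u = (mult * (ilo - h) * dx + shift - delta) / hc + jmid;
  double du = mult * dx / hc;
  for (int i = ilo; i <= ihi; ++i, u += du) {
    double mi = m[i];
    if (mi <= MASS_EPS) continue;
    if (u < (double)(K + 1)) { absL += mi; continue; }
    if (u > (double)(nc - K - 2)) { absR += mi; continue; }
    int j = (int)u;
    double w = u - j;
    mc[j] += mi * (1.0 - w);
    mc[j + 1] += mi * w;
  }

  sc.mco.assign(nc, 0.0);
  double *mco = sc.mco.data();
  const double *ker = sc.ker.data();
  int jlo = nc, jhi = -1;
  for (int j = 0; j < nc; ++j) {
    if (mc[j] > 0.0) { if (j < jlo) jlo = j; jhi = j; }
  }
  for (int j = jlo; j <= jhi; ++j) {
    double mj = mc[j];
    if (mj <= 0.0) continue;
    double *dst = mco + (j - K);
    for (int k = 0; k < 2 * K + 1; ++k) dst[k] += mj * ker[k];
  }

  // upsample onto a padded fine array; mass farther outside the bounds
  // than the boxcar could bring back is absorbed immediately
  int hw = (W - 1) / 2;
  int M = f + W + 2;                   // padding on each side of interior
  int nf = n + 2 * M;
  sc.ext.assign(nf, 0.0);
  double *ext2 = sc.ext.data();
  int half = (f % 2 == 0) ? (f / 2 - 1) : ((f - 1) / 2);
  int qlo = std::max(0, jlo - K), qhi = std::min(nc - 1, jhi + K);
  for (int j = qlo; j <= qhi; ++j) {
    double mj = mco[j];
    if (mj <= 0.0) continue;
    double w = mj / f;
    int tstart = h + (j - jmid) * f - half + M;
    for (int r = 0; r < f; ++r) {
      int t = tstart + r;
      if (t < M - hw) absL += w;
      else if (t >= M + n + hw) absR += w;
      else ext2[t] += w;
    }
  }

  // centered running mean of width W (prefix sums; zero padding)
  sc.oute.assign(nf + 1, 0.0);
  double *cum = sc.oute.data();
  for (int t = 0; t < nf; ++t) cum[t + 1] = cum[t] + ext2[t];
  sc.outn.assign(n, 0.0);
  double *out = sc.outn.data();
  double invW = 1.0 / W;
  for (int t = 0; t < nf; ++t) {
    int lo = t - hw, hi = t + hw + 1;
    if (lo < 0) lo = 0;
    if (hi > nf) hi = nf;
    double v = (cum[hi] - cum[lo]) * invW;
    if (v <= 0.0) continue;
    int ti = t - M;
    if (ti < 0) absL += v;
    else if (ti >= n) absR += v;
    else out[ti] += v;
  }
  m.swap(sc.outn);
}

static void step_event(std::vector<double> &m, int n, double dx, double B,
                       double mult, double shift, double s, Scratch &sc,
                       double &absL, double &absR) {
  int f = (s > 0.0) ? std::max(1, (int)std::floor(s / (2.5 * dx))) : 1;
  if (f > 1) step_decimated(m, n, dx, B, mult, shift, s, f, sc, absL, absR);
  else step_fine(m, n, dx, B, mult, shift, s, sc, absL, absR);
}

static inline double interval_sd(double lambda, double sigma_a2, double dt) {
  if (dt <= 0.0 || sigma_a2 <= 0.0) return 0.0;
  double v;
  if (std::fabs(lambda) < 1e-10) v = sigma_a2 * dt;
  else v = sigma_a2 * std::expm1(2.0 * lambda * dt) / (2.0 * lambda);
  return std::sqrt(v);
}

struct ModelPars {
  double lambda, sigma_a2, sigma_i2, B, dx_req;
  double gain_L, gain_R, sigma_s2_L, sigma_s2_R;
};

// Shared single-trial propagation; events must be time-sorted (left before
// right at ties), amplitudes already adapted.
static void propagate_trial(const double *etime, const int *eside,
                            const double *eamp, int ncl, double duration,
                            const ModelPars &mp, int n, double dx,
                            std::vector<double> &m, Scratch &sc,
                            double &absL, double &absR) {
  int h = (n - 1) / 2;
  double B = mp.B;
  m.assign(n, 0.0);
  absL = absR = 0.0;

  if (mp.sigma_i2 > 0.0) {
    double si = std::sqrt(mp.sigma_i2);
    absL += norm_cdf(-B / si);
    absR += norm_cdf(-B / si);         // symmetric upper tail
    double prev = norm_cdf(-B / si);
    for (int i = 0; i < n; ++i) {
      double edge = (i - h) * dx + 0.5 * dx;
      double cur = norm_cdf(edge / si);
      m[i] = cur - prev;
      prev = cur;
    }
  } else {
    m[h] = 1.0;
  }

  double t = 0.0;
  for (int c = 0; c < ncl; ++c) {
    double tc = etime[c];
    double dt = tc - t;
    if (dt > 0.0) {
      double s = interval_sd(mp.lambda, mp.sigma_a2, dt);
      step_event(m, n, dx, B, std::exp(mp.lambda * dt), 0.0, s, sc,
                 absL, absR);
      t = tc;
    }
    double amp = eamp[c];
    double shift, s2;
    if (eside[c] > 0) { shift = mp.gain_R * amp; s2 = mp.sigma_s2_R; }
    else { shift = -mp.gain_L * amp; s2 = mp.sigma_s2_L; }
    double sd = std::fabs(shift) * std::sqrt(std::max(0.0, s2));
    step_event(m, n, dx, B, 1.0, shift, sd, sc, absL, absR);
  }
  if (duration > t) {
    double dt = duration - t;
    double s = interval_sd(mp.lambda, mp.sigma_a2, dt);
    step_event(m, n, dx, B, std::exp(mp.lambda * dt), 0.0, s, sc, absL, absR);
  }
}

static void grid_dims(double B, double dx_req, int &n, double &dx) {
  int hbins = std::max(1, (int)std::lround(B / dx_req - 0.5));
  n = 2 * hbins + 1;
  dx = 2.0 * B / n;
}

// [[Rcpp::export]]
List cpp_propagate(NumericVector event_time, IntegerVector event_side,
                   NumericVector event_amp, double duration,
                   double lambda, double sigma_a2, double sigma_i2,
                   double B, double dx_req,
                   double gain_L, double gain_R,
                   double sigma_s2_L, double sigma_s2_R) {
  // grid: odd number of interior bins, 0 a bin center, outer edges at +-B
  ModelPars mp{lambda, sigma_a2, sigma_i2, B, dx_req,
               gain_L, gain_R, sigma_s2_L, sigma_s2_R};
  int n; double dx;
  grid_dims(B, dx_req, n, dx);
  std::vector<double> m;
  Scratch sc;
  double absL, absR;
  propagate_trial(event_time.begin(), event_side.begin(), event_amp.begin(),
                  event_time.size(), duration, mp, n, dx, m, sc, absL, absR);

  int h = (n - 1) / 2;
  NumericVector mass(n), centers(n);
  for (int i = 0; i < n; ++i) {
    mass[i] = m[i];
    centers[i] = (i - h) * dx;
  }
  return List::create(_["x"] = centers, _["mass"] = mass,
                      _["absorbed_lo"] = absL, _["absorbed_hi"] = absR,
                      _["dx"] = dx, _["B"] = B);
}

// Adaptation recursion (mirrors adapt_clicks() on the R side; the R version
// is the documented module surface, this one feeds the batched likelihood)
static void adapt_amps(const double *t, int ncl, double phi, double tau_phi,
                       std::vector<double> &amp) {
  amp.resize(ncl);
  double C = 1.0, tp = 0.0;
  for (int k = 0; k < ncl; ++k) {
    C = 1.0 - (1.0 - C) * std::exp(-(t[k] - tp) / tau_phi);
    amp[k] = C;
    C *= phi;
    tp = t[k];
  }
}

// Batched dataset log-likelihood. Trials are concatenated event arrays with
// offsets (0-based, length n_trials + 1). Returns the total log-likelihood,
// per-trial P(choice = R), and optionally each trial's terminal upper
// survival values at every interior bin lower edge (S[j] = absorbed_hi +
// mass in bins >= j), from which P0 at any decision boundary follows by
// linear interpolation without re-propagating.
// [[Rcpp::export]]
List cpp_loglik(NumericVector times, IntegerVector sides,
                IntegerVector offsets, NumericVector durations,
                LogicalVector went_right,
                double lambda, double sigma_a2, double sigma_i2,
                double B, double phi, double tau_phi,
                double sho_eff, double lapse,
                double kappa_L, double kappa_R, double dx_req,
                double gain_L, double gain_R,
                double sigma_s2_L, double sigma_s2_R,
                bool want_surv) {
  ModelPars mp{lambda, sigma_a2, sigma_i2, B, dx_req,
               gain_L, gain_R, sigma_s2_L, sigma_s2_R};
  int n; double dx;
  grid_dims(B, dx_req, n, dx);
  int h = (n - 1) / 2;
  int ntr = durations.size();

  std::vector<double> m, amp;
  Scratch sc;
  NumericVector p_right(ntr);
  NumericMatrix surv = want_surv ? NumericMatrix(n + 1, ntr)
                                 : NumericMatrix(0, 0);
  double ll = 0.0;

  for (int i = 0; i < ntr; ++i) {
    int o0 = offsets[i], o1 = offsets[i + 1];
    int ncl = o1 - o0;
    adapt_amps(&times[o0], ncl, phi, tau_phi, amp);
    double absL, absR;
    propagate_trial(&times[o0], &sides[o0], amp.data(), ncl, durations[i],
                    mp, n, dx, m, sc, absL, absR);

    // survival from above at bin lower edges
    double p0;
    {
      double run = absR;
      if (want_surv) {
        double *sv = &surv(0, i);
        sv[n] = absR;
        for (int j = n - 1; j >= 0; --j) { run += m[j]; sv[j] = run; }
        run = 0.0; // p0 computed below from scratch for clarity
      }
      // mass strictly above sho_eff (fractional bin by interpolation)
      double p = absR;
      for (int j = n - 1; j >= 0; --j) {
        double lo = (j - h) * dx - 0.5 * dx;
        double hi = lo + dx;
        if (lo >= sho_eff) p += m[j];
        else {
          if (hi > sho_eff) p += m[j] * (hi - sho_eff) / dx;
          break;
        }
      }
      p0 = p;
    }
    double p1 = (1.0 - lapse) * p0 + 0.5 * lapse;
    double p = p1 * (1.0 - kappa_R) + (1.0 - p1) * kappa_L;
    p_right[i] = p;
    double q = went_right[i] ? p : 1.0 - p;
    ll += std::log(std::max(q, 1e-300));
  }
  List out = List::create(_["ll"] = ll, _["p_right"] = p_right,
                          _["dx"] = dx, _["n_bins"] = n);
  if (want_surv) out["surv"] = surv;
  return out;
}
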