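// GCAL engine: sheets, connection fields, LGN gain control, V1 settling,
// Hebbian learning with divisive normalization, homeostatic thresholds.
// All state lives in a GcalNet held behind an Rcpp external pointer; the R
// layer owns configuration, stimulus generation and the RNG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>

using namespace Rcpp;

namespace {

// One connection-field projection: per-target index/weight arrays (CSR-like).
struct Proj {
  int n_tgt = 0;
  std::vector<int> off;      // length n_tgt + 1
  std::vector<int> idx;      // flat source indices
  std::vector<double> w;
  double strength = 0.0;     // gamma
  double alpha = 0.0;        // density-independent learning rate (config units)
  int cf(int i) const { return off[i + 1] - off[i]; }
};

struct GcalNet {
  // geometry (square sheets; n units per side over [-r, r], step = 2r/n)
  int n_ret = 0, n_lgn = 0, n_v1 = 0;
  double ret_r = 0, lgn_r = 0, v1_r = 0;
  int ret_lgn_off = 0;       // integer pixel offset retina grid vs LGN grid

  // retina -> LGN DoG kernel (square, half-width dog_hw, circular mask)
  int dog_hw = 0;
  std::vector<double> dog_k;
  double gamma_L = 0;        // retina->LGN strength

  // LGN divisive gain control
  int gc_hw = 0;
  std::vector<double> gc_k;  // unit-sum Gaussian (renormalized at edges)
  double gamma_S = 0, gc_k0 = 0;
  double lgn_scale = 1.0;    // output scaling after divisive normalization

  Proj aff;                  // joint On+Off -> V1 (sources 0..n_lgn^2-1 On,
                             // n_lgn^2..2n_lgn^2-1 Off), jointly normalized
  Proj exc, inh;             // V1 lateral

  // V1 homeostasis
  std::vector<double> theta, trace;
  double mu = 0, lambda = 0, beta = 0;

  int settle_steps = 17;
  double slope = 1.0;        // output-function gain above threshold
  double iteration = 0;      // double to round-trip through R numerics

  // activity buffers (persistent = state of the last learning presentation)
  std::vector<double> lgn_on, lgn_off, v1;
  // scratch used by measurement presentations (side-effect-free)
  std::vector<double> m_on, m_off, m_v1;
  std::vector<double> drive, pool, v1_prev, affdrive;
};

inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// retina->LGN DoG filtering at every LGN unit; LGN unit (r,c) sits over
// retina unit (r + off, c + off). Kernel lobes are unit-volume so a uniform
// image yields zero drive.
void dog_drive(const GcalNet& net, const double* img, double* out) {
  const int n = net.n_lgn, hw = net.dog_hw, nr = net.n_ret, o = net.ret_lgn_off;
  const int kw = 2 * hw + 1;
  for (int r = 0; r < n; ++r) {
    for (int c = 0; c < n; ++c) {
      double s = 0.0;
      for (int dr = -hw; dr <= hw; ++dr) {
        const int rr = r + o + dr;
        const double* krow = &net.dog_k[(dr + hw) * kw];
        const double* irow = &img[rr * nr];
        for (int dc = -hw; dc <= hw; ++dc) {
          const double k = krow[dc + hw];
          if (k != 0.0) s += k * irow[c + o + dc];
        }
      }
      out[r * n + c] = s;
    }
  }
}

// Gaussian pooling with per-unit renormalization at truncated edges.
void gain_pool(const GcalNet& net, const double* act, double* out) {
  const int n = net.n_lgn, hw = net.gc_hw, kw = 2 * hw + 1;
  for (int r = 0; r < n; ++r) {
    for (int c = 0; c < n; ++c) {
      double s = 0.0, ksum = 0.0;
      for (int dr = -hw; dr <= hw; ++dr) {
        const int rr = r + dr;
        if (rr < 0 || rr >= n) continue;
        const double* krow = &net.gc_k[(dr + hw) * kw];
        const double* arow = &act[rr * n];
        for (int dc = -hw; dc <= hw; ++dc) {
          const int cc = c + dc;
          if (cc < 0 || cc >= n) continue;
          const double k = krow[dc + hw];
          if (k != 0.0) { s += k * arow[cc]; ksum += k; }
        }
      }
      out[r * n + c] = (ksum > 0.0) ? s / ksum : 0.0;
    }
  }
}

// LGN step for one channel given signed drive (+ for On, - view for Off).
void lgn_channel(const GcalNet& net, const std::vector<double>& drv,
                 double sign, std::vector<double>& act,
                 std::vector<double>& pool_buf) {
  const int m = net.n_lgn * net.n_lgn;
  // instantaneous rectified feedforward response
  for (int i = 0; i < m; ++i)
    act[i] = std::max(sign * net.gamma_L * drv[i], 0.0);
  if (net.gamma_S > 0.0) {
    gain_pool(net, act.data(), pool_buf.data());
    for (int i = 0; i < m; ++i)
      act[i] = clamp01(net.lgn_scale * act[i] /
                       (net.gc_k0 + net.gamma_S * pool_buf[i]));
  } else {
    for (int i = 0; i < m; ++i)
      act[i] = clamp01(net.lgn_scale * act[i] / net.gc_k0);
  }
}

void projection_sum(const Proj& p, const double* src, double* out) {
  for (int i = 0; i < p.n_tgt; ++i) {
    double s = 0.0;
    const int a = p.off[i], b = p.off[i + 1];
    for (int k = a; k < b; ++k) s += p.w[k] * src[p.idx[k]];
    out[i] = s;
  }
}

// Joint afferent sum: src is the concatenated [On, Off] activity vector.
void afferent_sum(const GcalNet& net, const double* on, const double* offv,
                  double* out) {
  const int m = net.n_lgn * net.n_lgn;
  for (int i = 0; i < net.aff.n_tgt; ++i) {
    double s = 0.0;
    const int a = net.aff.off[i], b = net.aff.off[i + 1];
    for (int k = a; k < b; ++k) {
      const int j = net.aff.idx[k];
      s += net.aff.w[k] * (j < m ? on[j] : offv[j - m]);
    }
    out[i] = s;
  }
}

// 17 recurrent settle steps; initial activity is the afferent-only response.
// Returns max |change| on the final step (convergence diagnostic).
double settle(GcalNet& net, const std::vector<double>& affd,
              std::vector<double>& v1) {
  const int nv = net.n_v1 * net.n_v1;
  std::vector<double>& prev = net.v1_prev;
  std::vector<double> esum(nv), isum(nv);
  for (int i = 0; i < nv; ++i)
    v1[i] = clamp01(net.slope * (net.aff.strength * affd[i] - net.theta[i]));
  double last_change = 0.0;
  for (int s = 0; s < net.settle_steps; ++s) {
    prev = v1;
    projection_sum(net.exc, prev.data(), esum.data());
    projection_sum(net.inh, prev.data(), isum.data());
    last_change = 0.0;
    for (int i = 0; i < nv; ++i) {
      const double x = net.aff.strength * affd[i] +
                       net.exc.strength * esum[i] -
                       net.inh.strength * isum[i] - net.theta[i];
      if (!std::isfinite(x))
        stop("non-finite V1 activity at settle step %d", s + 1);
      const double y = clamp01(net.slope * x);
      const double d = std::fabs(y - prev[i]);
      if (d > last_change) last_change = d;
      v1[i] = y;
    }
  }
  return last_change;
}

// Hebbian update with divisive normalization for one projection; the
// per-connection rate is alpha / (connection-field size).
void hebb(Proj& p, const double* pre, const std::vector<double>& post) {
  if (p.alpha <= 0.0) return;
  for (int i = 0; i < p.n_tgt; ++i) {
    const double y = post[i];
    if (y <= 0.0) continue;
    const int a = p.off[i], b = p.off[i + 1];
    const double rate = p.alpha / (double)(b - a) * y;
    double sum = 0.0;
    for (int k = a; k < b; ++k) {
      p.w[k] += rate * pre[p.idx[k]];
      sum += p.w[k];
    }
    if (sum <= 0.0) continue;  // degenerate unit: keep previous weights
    const double inv = 1.0 / sum;
    for (int k = a; k < b; ++k) p.w[k] *= inv;
  }
}

void hebb_aff(GcalNet& net, const std::vector<double>& post) {
  Proj& p = net.aff;
  if (p.alpha <= 0.0) return;
  const int m = net.n_lgn * net.n_lgn;
  const double* on = net.lgn_on.data();
  const double* offv = net.lgn_off.data();
  for (int i = 0; i < p.n_tgt; ++i) {
    const double y = post[i];
    if (y <= 0.0) continue;
    const int a = p.off[i], b = p.off[i + 1];
    const double rate = p.alpha / (double)(b - a) * y;
    double sum = 0.0;
    for (int k = a; k < b; ++k) {
      const int j = p.idx[k];
      p.w[k] += rate * (j < m ? on[j] : offv[j - m]);
      sum += p.w[k];
    }
    if (sum <= 0.0) continue;
    const double inv = 1.0 / sum;
    for (int k = a; k < b; ++k) p.w[k] *= inv;
  }
}

// ---- construction helpers -------------------------------------------------

double cfg_num(List cfg, const char* name) {
  if (!cfg.containsElementNamed(name)) stop("missing config scalar '%s'", name);
  return as<double>(cfg[name]);
}

// build a circular-mask kernel with two unit-volume Gaussian lobes
std::vector<double> make_dog(int hw, double step, double sc, double ss) {
  const int kw = 2 * hw + 1;
  std::vector<double> c(kw * kw, 0.0), s(kw * kw, 0.0);
  double csum = 0, ssum = 0;
  const double rad2 = (double)hw * hw;
  for (int dr = -hw; dr <= hw; ++dr)
    for (int dc = -hw; dc <= hw; ++dc) {
      const double d2 = (double)(dr * dr + dc * dc);
      if (d2 > rad2) continue;
      const double x2 = d2 * step * step;
      const int k = (dr + hw) * kw + (dc + hw);
      c[k] = std::exp(-x2 / (2 * sc * sc));
      s[k] = std::exp(-x2 / (2 * ss * ss));
      csum += c[k]; ssum += s[k];
    }
  std::vector<double> out(kw * kw, 0.0);
  for (int k = 0; k < kw * kw; ++k) out[k] = c[k] / csum - s[k] / ssum;
  return out;
}

std::vector<double> make_gauss(int hw, double step, double sigma) {
  const int kw = 2 * hw + 1;
  std::vector<double> g(kw * kw, 0.0);
  double sum = 0;
  const double rad2 = (double)hw * hw;
  for (int dr = -hw; dr <= hw; ++dr)
    for (int dc = -hw; dc <= hw; ++dc) {
      const double d2 = (double)(dr * dr + dc * dc);
      if (d2 > rad2) continue;
      const int k = (dr + hw) * kw + (dc + hw);
      g[k] = std::exp(-d2 * step * step / (2 * sigma * sigma));
      sum += g[k];
    }
  for (int k = 0; k < kw * kw; ++k) g[k] /= sum;
  return g;
}

// lateral projection on the V1 grid: circular mask of given radius (sheet
// coords), Gaussian initial profile, truncated at edges and renormalized.
// The unit itself is included for excitatory, excluded never (GCAL keeps it).
Proj make_lateral(int n, double step, double radius, double sigma,
                  double strength, double alpha) {
  Proj p;
  p.n_tgt = n * n;
  p.strength = strength;
  p.alpha = alpha;
  p.off.push_back(0);
  const int hw = (int)std::floor(radius / step + 1e-9);
  const double r2 = radius * radius;
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < n; ++c) {
      double sum = 0.0;
      const size_t start = p.w.size();
      for (int dr = -hw; dr <= hw; ++dr) {
        const int rr = r + dr;
        if (rr < 0 || rr >= n) continue;
        for (int dc = -hw; dc <= hw; ++dc) {
          const int cc = c + dc;
          if (cc < 0 || cc >= n) continue;
          const double d2 = (dr * dr + dc * dc) * step * step;
          if (d2 > r2 + 1e-12) continue;
          const double wv = std::exp(-d2 / (2 * sigma * sigma));
          p.idx.push_back(rr * n + cc);
          p.w.push_back(wv);
          sum += wv;
        }
      }
      for (size_t k = start; k < p.w.size(); ++k) p.w[k] /= sum;
      p.off.push_back((int)p.idx.size());
    }
  return p;
}

GcalNet* get(SEXP xp) {
  XPtr<GcalNet> p(xp);
  if (!p) stop("invalid GCAL engine pointer");
  return p.get();
}

void resize_buffers(GcalNet& net) {
  const int ml = net.n_lgn * net.n_lgn, mv = net.n_v1 * net.n_v1;
  net.lgn_on.assign(ml, 0.0); net.lgn_off.assign(ml, 0.0);
  net.v1.assign(mv, 0.0);
  net.m_on.assign(ml, 0.0); net.m_off.assign(ml, 0.0); net.m_v1.assign(mv, 0.0);
  net.drive.assign(ml, 0.0); net.pool.assign(ml, 0.0);
  net.v1_prev.assign(mv, 0.0); net.affdrive.assign(mv, 0.0);
}

}  // namespace

// [[Rcpp::export]]
SEXP net_build(List geom, List cfg) {
  XPtr<GcalNet> xp(new GcalNet, true);
  GcalNet& net = *xp;
  net.n_ret = as<int>(geom["n_ret"]);
  net.n_lgn = as<int>(geom["n_lgn"]);
  net.n_v1 = as<int>(geom["n_v1"]);
  net.ret_r = as<double>(geom["ret_r"]);
  net.lgn_r = as<double>(geom["lgn_r"]);
  net.v1_r = as<double>(geom["v1_r"]);
  net.ret_lgn_off = as<int>(geom["ret_lgn_off"]);
  const double lgn_step = 2.0 * net.lgn_r / net.n_lgn;
  const double v1_step = 2.0 * net.v1_r / net.n_v1;

  net.gamma_L = cfg_num(cfg, "gamma_L");
  net.gamma_S = cfg_num(cfg, "gamma_S");
  net.gc_k0 = cfg_num(cfg, "gc_k0");
  net.mu = cfg_num(cfg, "mu");
  net.lambda = cfg_num(cfg, "lambda");
  net.beta = cfg_num(cfg, "beta");
  net.settle_steps = (int)cfg_num(cfg, "settle_steps");
  net.slope = cfg_num(cfg, "slope");
  net.lgn_scale = cfg_num(cfg, "lgn_scale");

  const double dog_radius = cfg_num(cfg, "dog_radius");
  net.dog_hw = (int)std::floor(dog_radius / lgn_step + 1e-9);
  if (net.ret_lgn_off < net.dog_hw)
    stop("configuration error: projection retina_to_lgn radius exceeds retina bounds");
  net.dog_k = make_dog(net.dog_hw, lgn_step, cfg_num(cfg, "dog_sigma_c"),
                       cfg_num(cfg, "dog_sigma_s"));

  const double gc_radius = cfg_num(cfg, "gc_radius");
  net.gc_hw = (int)std::floor(gc_radius / lgn_step + 1e-9);
  net.gc_k = make_gauss(net.gc_hw, lgn_step, cfg_num(cfg, "gc_sigma"));

  // afferent CF: circular neighbourhood on the LGN grid around the V1 unit's
  // retinotopic position, duplicated over On and Off, jointly normalized
  {
    Proj& p = net.aff;
    p.n_tgt = net.n_v1 * net.n_v1;
    p.strength = cfg_num(cfg, "gamma_A");
    p.alpha = cfg_num(cfg, "alpha_A");
    const double radius = cfg_num(cfg, "aff_radius");
    const double r2 = radius * radius;
    const int m = net.n_lgn * net.n_lgn;
    p.off.push_back(0);
    for (int r = 0; r < net.n_v1; ++r)
      for (int c = 0; c < net.n_v1; ++c) {
        const double y = -net.v1_r + (r + 0.5) * v1_step;
        const double x = -net.v1_r + (c + 0.5) * v1_step;
        const int cr = (int)std::floor((y + net.lgn_r) / lgn_step);
        const int cc = (int)std::floor((x + net.lgn_r) / lgn_step);
        const int hw = (int)std::ceil(radius / lgn_step) + 1;
        std::vector<int> local;
        for (int dr = -hw; dr <= hw; ++dr) {
          const int rr = cr + dr;
          const double py = -net.lgn_r + (rr + 0.5) * lgn_step;
          for (int dc = -hw; dc <= hw; ++dc) {
            const int ccc = cc + dc;
            const double px = -net.lgn_r + (ccc + 0.5) * lgn_step;
            const double d2 = (px - x) * (px - x) + (py - y) * (py - y);
            if (d2 > r2 + 1e-12) continue;
            if (rr < 0 || rr >= net.n_lgn || ccc < 0 || ccc >= net.n_lgn)
              stop("configuration error: projection lgn_to_v1 radius exceeds LGN bounds");
            local.push_back(rr * net.n_lgn + ccc);
          }
        }
        for (int j : local) p.idx.push_back(j);        // On block
        for (int j : local) p.idx.push_back(j + m);    // Off block
        p.w.resize(p.idx.size(), 0.0);
        p.off.push_back((int)p.idx.size());
      }
  }

  net.exc = make_lateral(net.n_v1, v1_step, cfg_num(cfg, "exc_radius"),
                         cfg_num(cfg, "exc_sigma"), cfg_num(cfg, "gamma_E"),
                         cfg_num(cfg, "alpha_E"));
  net.inh = make_lateral(net.n_v1, v1_step, cfg_num(cfg, "inh_radius"),
                         cfg_num(cfg, "inh_sigma"), cfg_num(cfg, "gamma_I"),
                         cfg_num(cfg, "alpha_I"));

  const int nv = net.n_v1 * net.n_v1;
  net.theta.assign(nv, cfg_num(cfg, "theta_init"));
  net.trace.assign(nv, cfg_num(cfg, "mu"));
  resize_buffers(net);
  return xp;
}

// number of afferent weights (for drawing the random initial values in R)
// [[Rcpp::export]]
int net_aff_size(SEXP xp) { return (int)get(xp)->aff.w.size(); }

// initialize afferent weights: uniform random values shaped by a Gaussian
// envelope of the distance from the CF centre, then jointly normalized.
// [[Rcpp::export]]
void net_init_aff(SEXP xp, NumericVector u, double envelope_sigma) {
  GcalNet& net = *get(xp);
  Proj& p = net.aff;
  if ((int)u.size() != (int)p.w.size()) stop("wrong number of random values");
  const double lgn_step = 2.0 * net.lgn_r / net.n_lgn;
  const double v1_step = 2.0 * net.v1_r / net.n_v1;
  const int m = net.n_lgn * net.n_lgn;
  for (int i = 0; i < p.n_tgt; ++i) {
    const int r = i / net.n_v1, c = i % net.n_v1;
    const double y = -net.v1_r + (r + 0.5) * v1_step;
    const double x = -net.v1_r + (c + 0.5) * v1_step;
    double sum = 0.0;
    for (int k = p.off[i]; k < p.off[i + 1]; ++k) {
      int j = p.idx[k]; if (j >= m) j -= m;
      const double py = -net.lgn_r + (j / net.n_lgn + 0.5) * lgn_step;
      const double px = -net.lgn_r + (j % net.n_lgn + 0.5) * lgn_step;
      const double d2 = (px - x) * (px - x) + (py - y) * (py - y);
      const double env = std::exp(-d2 / (2 * envelope_sigma * envelope_sigma));
      p.w[k] = u[k] * env;
      sum += p.w[k];
    }
    for (int k = p.off[i]; k < p.off[i + 1]; ++k) p.w[k] /= sum;
  }
}

// One full presentation. learn=TRUE runs Hebbian + homeostatic updates and
// advances the iteration counter (training); learn=FALSE uses scratch
// buffers and leaves all state untouched (measurement).
// [[Rcpp::export]]
double net_present(SEXP xp, NumericVector image, bool learn) {
  GcalNet& net = *get(xp);
  if ((int)image.size() != net.n_ret * net.n_ret)
    stop("image must be %d x %d", net.n_ret, net.n_ret);
  std::vector<double>& on = learn ? net.lgn_on : net.m_on;
  std::vector<double>& offv = learn ? net.lgn_off : net.m_off;
  std::vector<double>& v1 = learn ? net.v1 : net.m_v1;
  dog_drive(net, REAL(image), net.drive.data());
  lgn_channel(net, net.drive, +1.0, on, net.pool);
  lgn_channel(net, net.drive, -1.0, offv, net.pool);
  afferent_sum(net, on.data(), offv.data(), net.affdrive.data());
  const double last_change = settle(net, net.affdrive, v1);
  if (learn) {
    hebb_aff(net, net.v1);
    hebb(net.exc, net.v1.data(), net.v1);
    hebb(net.inh, net.v1.data(), net.v1);
    const int nv = net.n_v1 * net.n_v1;
    for (int i = 0; i < nv; ++i) {
      net.trace[i] = (1.0 - net.beta) * net.v1[i] + net.beta * net.trace[i];
      net.theta[i] += net.lambda * (net.trace[i] - net.mu);
    }
    net.iteration += 1;
  }
  return last_change;
}

// [[Rcpp::export]]
List net_activities(SEXP xp, bool measurement) {
  GcalNet& net = *get(xp);
  const int nl = net.n_lgn, nv = net.n_v1;
  NumericMatrix on(nl, nl), offm(nl, nl), v1(nv, nv);
  const std::vector<double>& son = measurement ? net.m_on : net.lgn_on;
  const std::vector<double>& soff = measurement ? net.m_off : net.lgn_off;
  const std::vector<double>& sv1 = measurement ? net.m_v1 : net.v1;
  for (int r = 0; r < nl; ++r)
    for (int c = 0; c < nl; ++c) {
      on(r, c) = son[r * nl + c];
      offm(r, c) = soff[r * nl + c];
    }
  for (int r = 0; r < nv; ++r)
    for (int c = 0; c < nv; ++c) v1(r, c) = sv1[r * nv + c];
  return List::create(_["lgn_on"] = on, _["lgn_off"] = offm, _["v1"] = v1);
}

// LGN drive (pre gain control, pre rectification) for DoG unit tests
// [[Rcpp::export]]
NumericMatrix net_lgn_drive(SEXP xp, NumericVector image) {
  GcalNet& net = *get(xp);
  if ((int)image.size() != net.n_ret * net.n_ret)
    stop("image must be %d x %d", net.n_ret, net.n_ret);
  dog_drive(net, REAL(image), net.drive.data());
  NumericMatrix out(net.n_lgn, net.n_lgn);
  for (int r = 0; r < net.n_lgn; ++r)
    for (int c = 0; c < net.n_lgn; ++c) out(r, c) = net.drive[r * net.n_lgn + c];
  return out;
}

static List proj_struct(const Proj& p) {
  return List::create(_["off"] = IntegerVector(p.off.begin(), p.off.end()),
                      _["idx"] = IntegerVector(p.idx.begin(), p.idx.end()),
                      _["w"] = NumericVector(p.w.begin(), p.w.end()),
                      _["strength"] = p.strength, _["alpha"] = p.alpha);
}

// full structural export (indices + weights) for oracles and snapshots
// [[Rcpp::export]]
List net_struct(SEXP xp) {
  GcalNet& net = *get(xp);
  return List::create(
      _["n_ret"] = net.n_ret, _["n_lgn"] = net.n_lgn, _["n_v1"] = net.n_v1,
      _["ret_lgn_off"] = net.ret_lgn_off,
      _["dog_hw"] = net.dog_hw,
      _["dog_k"] = NumericVector(net.dog_k.begin(), net.dog_k.end()),
      _["gc_hw"] = net.gc_hw,
      _["gc_k"] = NumericVector(net.gc_k.begin(), net.gc_k.end()),
      _["gamma_L"] = net.gamma_L, _["gamma_S"] = net.gamma_S,
      _["gc_k0"] = net.gc_k0, _["lgn_scale"] = net.lgn_scale,
      _["slope"] = net.slope,
      _["aff"] = proj_struct(net.aff), _["exc"] = proj_struct(net.exc),
      _["inh"] = proj_struct(net.inh),
      _["theta"] = NumericVector(net.theta.begin(), net.theta.end()),
      _["trace"] = NumericVector(net.trace.begin(), net.trace.end()),
      _["mu"] = net.mu, _["lambda"] = net.lambda, _["beta"] = net.beta,
      _["settle_steps"] = net.settle_steps, _["iteration"] = net.iteration);
}

// mutable state only (weights, thresholds, traces, activities, iteration)
// [[Rcpp::export]]
List net_get_state(SEXP xp) {
  GcalNet& net = *get(xp);
  return List::create(
      _["aff_w"] = NumericVector(net.aff.w.begin(), net.aff.w.end()),
      _["exc_w"] = NumericVector(net.exc.w.begin(), net.exc.w.end()),
      _["inh_w"] = NumericVector(net.inh.w.begin(), net.inh.w.end()),
      _["theta"] = NumericVector(net.theta.begin(), net.theta.end()),
      _["trace"] = NumericVector(net.trace.begin(), net.trace.end()),
      _["lgn_on"] = NumericVector(net.lgn_on.begin(), net.lgn_on.end()),
      _["lgn_off"] = NumericVector(net.lgn_off.begin(), net.lgn_off.end()),
      _["v1"] = NumericVector(net.v1.begin(), net.v1.end()),
      _["iteration"] = net.iteration);
}

// [[Rcpp::export]]
void net_set_state(SEXP xp, List st) {
  GcalNet& net = *get(xp);
  NumericVector aw = st["aff_w"], ew = st["exc_w"], iw = st["inh_w"],
                th = st["theta"], tr = st["trace"], lo = st["lgn_on"],
                lf = st["lgn_off"], v1 = st["v1"];
  if ((int)aw.size() != (int)net.aff.w.size() ||
      (int)ew.size() != (int)net.exc.w.size() ||
      (int)iw.size() != (int)net.inh.w.size())
    stop("snapshot does not match the built model's connection fields");
  std::copy(aw.begin(), aw.end(), net.aff.w.begin());
  std::copy(ew.begin(), ew.end(), net.exc.w.begin());
  std::copy(iw.begin(), iw.end(), net.inh.w.begin());
  std::copy(th.begin(), th.end(), net.theta.begin());
  std::copy(tr.begin(), tr.end(), net.trace.begin());
  std::copy(lo.begin(), lo.end(), net.lgn_on.begin());
  std::copy(lf.begin(), lf.end(), net.lgn_off.begin());
  std::copy(v1.begin(), v1.end(), net.v1.begin());
  net.iteration = as<double>(st["iteration"]);
}

// [[Rcpp::export]]
double net_get_param(SEXP xp, std::string name) {
  GcalNet& net = *get(xp);
  if (name == "gamma_L") return net.gamma_L;
  if (name == "gamma_S") return net.gamma_S;
  if (name == "gc_k0") return net.gc_k0;
  if (name == "gamma_A") return net.aff.strength;
  if (name == "gamma_E") return net.exc.strength;
  if (name == "gamma_I") return net.inh.strength;
  if (name == "alpha_A") return net.aff.alpha;
  if (name == "alpha_E") return net.exc.alpha;
  if (name == "alpha_I") return net.inh.alpha;
  if (name == "lambda") return net.lambda;
  if (name == "mu") return net.mu;
  if (name == "beta") return net.beta;
  if (name == "settle_steps") return net.settle_steps;
  if (name == "slope") return net.slope;
  if (name == "lgn_scale") return net.lgn_scale;
  if (name == "iteration") return net.iteration;
  stop("unknown engine parameter '%s'", name.c_str());
}

// [[Rcpp::export]]
void net_set_param(SEXP xp, std::string name, double value) {
  GcalNet& net = *get(xp);
  if (name == "gamma_L") net.gamma_L = value;
  else if (name == "gamma_S") net.gamma_S = value;
  else if (name == "gc_k0") net.gc_k0 = value;
  else if (name == "gamma_A") net.aff.strength = value;
  else if (name == "gamma_E") net.exc.strength = value;
  else if (name == "gamma_I") net.inh.strength = value;
  else if (name == "alpha_A") net.aff.alpha = value;
  else if (name == "alpha_E") net.exc.alpha = value;
  else if (name == "alpha_I") net.inh.alpha = value;
  else if (name == "lambda") net.lambda = value;
  else if (name == "mu") net.mu = value;
  else if (name == "beta") net.beta = value;
  else if (name == "settle_steps") net.settle_steps = (int)value;
  else if (name == "slope") net.slope = value;
  else if (name == "lgn_scale") net.lgn_scale = value;
  else stop("unknown engine parameter '%s'", name.c_str());
}
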