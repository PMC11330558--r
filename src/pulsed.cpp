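// Pruning likelihood for the pulsed trait model: Brownian motion plus
// compound-Poisson normal jumps. Conditional on the per-branch jump counts
// the model is Gaussian, so the conditional message passed rootward from any
// subtree is a finite Gaussian mixture in the ancestral value. Along a
// branch of length t each component gains variance sig2*t + delta2*k with
// Poisson(lambda*t) weight on k (truncated at tail mass < tail_tol;
// branches expecting many jumps aggregate jump-count classes, where the
// compound distribution is near its Gaussian limit); at a node, messages
// multiply (pairwise Gaussian products). Components below a relative weight
// of weight_tol are dropped; when a message is denser than max_components it
// is reduced by moment-preserving collapse on a (mean, log-variance) grid,
// which conserves mixture mass exactly.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Mixture {
  std::vector<double> mu, v, lw; // means, variances, log-weights (relative)
  double logscale = 0.0;         // accumulated log normalising constant
};

static inline double log_norm_pdf(double d, double v) {
  return -0.5 * (std::log(2.0 * M_PI * v) + d * d / v);
}

// weight-prune, collapse to <= max_components, and sort by weight (desc)
static void normalise_prune(Mixture &m, double weight_tol, int max_components) {
  size_t n = m.mu.size();
  if (!n) return;
  double mx = *std::max_element(m.lw.begin(), m.lw.end());
  m.logscale += mx;
  std::vector<double> mu2, v2, w2;
  mu2.reserve(n); v2.reserve(n); w2.reserve(n);
  for (size_t i = 0; i < n; ++i) {
    double w = std::exp(m.lw[i] - mx);
    if (w < weight_tol) continue;
    mu2.push_back(m.mu[i]); v2.push_back(m.v[i]); w2.push_back(w);
  }
  if ((int)mu2.size() > max_components) {
    // moment-preserving reduction on a (mean, log-variance) grid
    int n_mu = max_components / 8;
    int n_lv = 8;
    if (n_mu < 8) n_mu = 8;
    double mu_lo = *std::min_element(mu2.begin(), mu2.end());
    double mu_hi = *std::max_element(mu2.begin(), mu2.end());
    double lv_lo = 1e300, lv_hi = -1e300;
    for (double v : v2) {
      double lv = std::log(v + 1e-300);
      if (lv < lv_lo) lv_lo = lv;
      if (lv > lv_hi) lv_hi = lv;
    }
    double dmu = (mu_hi > mu_lo) ? (mu_hi - mu_lo) * (1 + 1e-12) / n_mu : 1.0;
    double dlv = (lv_hi > lv_lo) ? (lv_hi - lv_lo) * (1 + 1e-12) / n_lv : 1.0;
    int nbuck = n_mu * n_lv;
    std::vector<int> slot(nbuck, -1);
    std::vector<double> bw, bmu, bm2;
    bw.reserve(max_components); bmu.reserve(max_components); bm2.reserve(max_components);
    for (size_t i = 0; i < mu2.size(); ++i) {
      int bi = (int)((mu2[i] - mu_lo) / dmu);
      int bj = (int)((std::log(v2[i] + 1e-300) - lv_lo) / dlv);
      int key = bi * n_lv + bj;
      int s = slot[key];
      if (s < 0) {
        s = (int)bw.size();
        slot[key] = s;
        bw.push_back(0.0); bmu.push_back(0.0); bm2.push_back(0.0);
      }
      bw[s] += w2[i];
      bmu[s] += w2[i] * mu2[i];
      bm2[s] += w2[i] * (v2[i] + mu2[i] * mu2[i]);
    }
    mu2.resize(bw.size()); v2.resize(bw.size()); w2.resize(bw.size());
    for (size_t s = 0; s < bw.size(); ++s) {
      double mm = bmu[s] / bw[s];
      double vv = bm2[s] / bw[s] - mm * mm;
      mu2[s] = mm; v2[s] = vv < 0 ? 0 : vv; w2[s] = bw[s];
    }
  }
  // sort by weight so downstream loops can cut off early
  std::vector<size_t> ord(mu2.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return w2[a] > w2[b]; });
  m.mu.resize(ord.size()); m.v.resize(ord.size()); m.lw.resize(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    m.mu[i] = mu2[ord[i]]; m.v[i] = v2[ord[i]];
    m.lw[i] = std::log(w2[ord[i]]);
  }
}

// log of the root mixture density evaluated at z
static double mix_logdens(const Mixture &m, double z) {
  double best = R_NegInf;
  std::vector<double> terms(m.mu.size());
  for (size_t i = 0; i < m.mu.size(); ++i) {
    terms[i] = (m.v[i] < 1e-300) ? R_NegInf
                                 : m.lw[i] + log_norm_pdf(z - m.mu[i], m.v[i]);
    if (terms[i] > best) best = terms[i];
  }
  if (!std::isfinite(best)) return R_NegInf;
  double s = 0.0;
  for (double t : terms) s += std::exp(t - best);
  return best + std::log(s);
}

// [[Rcpp::export(name = "pulsed_prune")]]
NumericVector pulsed_prune(IntegerMatrix edge, NumericVector edge_length,
                           int ntip, int nnode, NumericVector x, double z0,
                           double sig2, double lambda, double delta2,
                           int max_components, double tail_tol,
                           double weight_tol, bool profile_z0 = false) {
  int nn = ntip + nnode;
  std::vector<Mixture> msg(nn + 1);       // 1-based node ids
  std::vector<bool> has(nn + 1, false);

  for (int e = 0; e < edge.nrow(); ++e) { // postorder: children first
    int par = edge(e, 0), ch = edge(e, 1);
    double t = edge_length[e];
    Mixture child;
    if (ch <= ntip) {
      child.mu.push_back(x[ch - 1]);
      child.v.push_back(0.0);
      child.lw.push_back(0.0);
    } else {
      child = std::move(msg[ch]);
    }
    // per-branch jump-count classes
    double lam_t = lambda * t;
    std::vector<double> kvar, klw;
    if (lam_t <= 0.0 || delta2 <= 0.0) {
      kvar.push_back(0.0); klw.push_back(0.0);
    } else {
      std::vector<double> logp_all;
      double logp = -lam_t;
      double cum = std::exp(logp);
      int k = 0;
      logp_all.push_back(logp);
      while (1.0 - cum > tail_tol && k < 100000) {
        ++k;
        logp += std::log(lam_t / k);
        logp_all.push_back(logp);
        cum += std::exp(logp);
      }
      double mx = *std::max_element(logp_all.begin(), logp_all.end());
      int k_lo = 0, k_hi = (int)logp_all.size() - 1;
      while (k_lo < k_hi && logp_all[k_lo] < mx - 30.0) ++k_lo;
      while (k_hi > k_lo && logp_all[k_hi] < mx - 30.0) --k_hi;
      int span = k_hi - k_lo + 1;
      const int max_classes = 32, n_bins = 24;
      if (span <= max_classes) {
        for (int kk = k_lo; kk <= k_hi; ++kk) {
          kvar.push_back(delta2 * kk);
          klw.push_back(logp_all[kk]);
        }
      } else {
        for (int b = 0; b < n_bins; ++b) {
          int b_lo = k_lo + (int)((long long)span * b / n_bins);
          int b_hi = k_lo + (int)((long long)span * (b + 1) / n_bins) - 1;
          if (b_hi < b_lo) continue;
          double w = 0.0, vw = 0.0;
          for (int kk = b_lo; kk <= b_hi; ++kk) {
            double wk = std::exp(logp_all[kk] - mx);
            w += wk;
            vw += wk * delta2 * kk;
          }
          if (w <= 0.0) continue;
          kvar.push_back(vw / w);
          klw.push_back(mx + std::log(w));
        }
      }
    }
    // convolve child message with the branch displacement mixture
    Mixture up;
    up.logscale = child.logscale;
    size_t nc = child.mu.size(), nk = kvar.size();
    double klw_max = *std::max_element(klw.begin(), klw.end());
    double cut_c = child.lw[0] + klw_max + std::log(weight_tol);
    up.mu.reserve(nc * nk); up.v.reserve(nc * nk); up.lw.reserve(nc * nk);
    for (size_t c = 0; c < nc; ++c) {
      if (child.lw[c] + klw_max < cut_c) break; // weight-sorted: done
      double base_v = child.v[c] + sig2 * t;
      for (size_t k = 0; k < nk; ++k) {
        double lw = child.lw[c] + klw[k];
        if (lw < cut_c) continue;
        up.mu.push_back(child.mu[c]);
        up.v.push_back(base_v + kvar[k]);
        up.lw.push_back(lw);
      }
    }
    normalise_prune(up, weight_tol, max_components);

    if (!has[par]) {
      msg[par] = std::move(up);
      has[par] = true;
    } else {
      Mixture &a = msg[par];
      Mixture prod;
      prod.logscale = a.logscale + up.logscale;
      size_t na = a.mu.size(), nb = up.mu.size();
      if (na == 0 || nb == 0) return NumericVector::create(R_NegInf, 0.0, z0);
      double cut_p = a.lw[0] + up.lw[0] + std::log(weight_tol) - 4.6;
      prod.mu.reserve(na * 4); prod.v.reserve(na * 4); prod.lw.reserve(na * 4);
      for (size_t i = 0; i < na; ++i) {
        if (a.lw[i] + up.lw[0] < cut_p) break;
        for (size_t j = 0; j < nb; ++j) {
          if (a.lw[i] + up.lw[j] < cut_p) break;
          double vs = a.v[i] + up.v[j];
          if (vs < 1e-300) continue; // zero-variance clash: measure-zero
          double d = a.mu[i] - up.mu[j];
          prod.mu.push_back((a.mu[i] * up.v[j] + up.mu[j] * a.v[i]) / vs);
          prod.v.push_back(a.v[i] * up.v[j] / vs);
          prod.lw.push_back(a.lw[i] + up.lw[j] + log_norm_pdf(d, vs));
        }
      }
      normalise_prune(prod, weight_tol, max_components);
      msg[par] = std::move(prod);
    }
  }

  int root = ntip + 1;
  Mixture &rm = msg[root];
  if (rm.mu.empty()) return NumericVector::create(R_NegInf, 0.0, z0);
  double z_use = z0;
  if (profile_z0) {
    // profile the root state: candidates at component means and the
    // weighted mean, then refine by short golden-section around the best
    double wsum = 0.0, wm = 0.0;
    for (size_t i = 0; i < rm.mu.size(); ++i) {
      double w = std::exp(rm.lw[i]);
      wsum += w; wm += w * rm.mu[i];
    }
    wm /= wsum;
    double best_z = wm, best_f = mix_logdens(rm, wm);
    for (size_t i = 0; i < rm.mu.size(); ++i) {
      double f = mix_logdens(rm, rm.mu[i]);
      if (f > best_f) { best_f = f; best_z = rm.mu[i]; }
    }
    double step = 0.0;
    for (size_t i = 0; i < rm.mu.size(); ++i)
      step = std::max(step, std::sqrt(rm.v[i] + 1e-12));
    double lo = best_z - step, hi = best_z + step;
    const double gr = 0.61803398875;
    double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
    double fc = mix_logdens(rm, c), fd = mix_logdens(rm, d);
    for (int it = 0; it < 60; ++it) {
      if (fc > fd) { hi = d; d = c; fd = fc; c = hi - gr * (hi - lo); fc = mix_logdens(rm, c); }
      else { lo = c; c = d; fc = fd; d = lo + gr * (hi - lo); fd = mix_logdens(rm, d); }
      if (hi - lo < 1e-10 * (1 + std::fabs(best_z))) break;
    }
    double z_gs = 0.5 * (lo + hi);
    if (mix_logdens(rm, z_gs) > best_f) best_z = z_gs;
    z_use = best_z;
  }
  double ll = rm.logscale + mix_logdens(rm, z_use);
  return NumericVector::create(ll, 0.0, z_use);
}
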