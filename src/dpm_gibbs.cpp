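// Collapsed Gibbs sampler for a Dirichlet-process mixture of bivariate
// normal sources with isotropic dispersal sd sigma and a conjugate
// Normal(m0, tau^2 I) prior on source locations. Cluster means are
// integrated out; sigma is either fixed or sampled over a supplied grid by
// its conditional posterior given the partition (griddy Gibbs). Uses R's RNG
// so reproducibility is governed by set.seed() on the calling side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double log_norm(double x, double m, double v) {
  double d = x - m;
  return -0.5 * std::log(2.0 * M_PI * v) - 0.5 * d * d / v;
}

// log marginal likelihood of one cluster (both dims) given sigma:
// per dim: -n/2 log(2 pi s2) + .5 log(s2/(s2+n tau2)) - SS/(2 s2)
//          - n (xbar-m0)^2 / (2 (s2 + n tau2))
static double cluster_marginal(double n, double sx, double sy, double sxx,
                               double syy, double s2, double tau2,
                               double m0x, double m0y) {
  double xbar = sx / n, ybar = sy / n;
  double ssx = sxx - sx * sx / n, ssy = syy - sy * sy / n;
  double shrink = s2 + n * tau2;
  double out = -n * std::log(2.0 * M_PI * s2) + std::log(s2 / shrink);
  out += -(ssx + ssy) / (2.0 * s2);
  out += -n * ((xbar - m0x) * (xbar - m0x) + (ybar - m0y) * (ybar - m0y)) /
         (2.0 * shrink);
  return out;
}

// [[Rcpp::export]]
List dpm_gibbs_chain(NumericMatrix X, double sigma_init, bool fit_sigma,
                     NumericVector sigma_grid, double alpha, double m0x,
                     double m0y, double tau, int n_samples, int burn_in,
                     int thin) {
  const int n = X.nrow();
  const double tau2 = tau * tau;
  double sigma = sigma_init;

  std::vector<int> z(n, 0);
  std::vector<double> cn, csx, csy, csxx, csyy;
  // start with all points in one cluster
  cn.assign(1, 0.0); csx.assign(1, 0.0); csy.assign(1, 0.0);
  csxx.assign(1, 0.0); csyy.assign(1, 0.0);
  for (int i = 0; i < n; ++i) {
    cn[0] += 1; csx[0] += X(i, 0); csy[0] += X(i, 1);
    csxx[0] += X(i, 0) * X(i, 0); csyy[0] += X(i, 1) * X(i, 1);
  }

  int kept_n = (n_samples - burn_in + thin - 1) / thin;
  IntegerMatrix keep_z(kept_n, n);
  NumericVector keep_sigma(kept_n);
  IntegerVector keep_k(kept_n);
  int kept = 0;

  std::vector<double> logp;
  GetRNGstate();
  for (int sweep = 0; sweep < n_samples; ++sweep) {
    for (int i = 0; i < n; ++i) {
      int zi = z[i];
      double xi = X(i, 0), yi = X(i, 1);
      // remove point i from its cluster
      cn[zi] -= 1; csx[zi] -= xi; csy[zi] -= yi;
      csxx[zi] -= xi * xi; csyy[zi] -= yi * yi;
      if (cn[zi] < 0.5) { // delete empty cluster, swap-with-last relabel
        int last = (int)cn.size() - 1;
        if (zi != last) {
          cn[zi] = cn[last]; csx[zi] = csx[last]; csy[zi] = csy[last];
          csxx[zi] = csxx[last]; csyy[zi] = csyy[last];
          for (int j = 0; j < n; ++j) if (z[j] == last) z[j] = zi;
        }
        cn.pop_back(); csx.pop_back(); csy.pop_back();
        csxx.pop_back(); csyy.pop_back();
      }
      int K = (int)cn.size();
      logp.resize(K + 1);
      double s2 = sigma * sigma;
      for (int k = 0; k < K; ++k) {
        double prec = 1.0 / tau2 + cn[k] / s2;
        double vpost = 1.0 / prec;
        double mx = (m0x / tau2 + csx[k] / s2) * vpost;
        double my = (m0y / tau2 + csy[k] / s2) * vpost;
        double vpred = vpost + s2;
        logp[k] = std::log(cn[k]) + log_norm(xi, mx, vpred) +
                  log_norm(yi, my, vpred);
      }
      logp[K] = std::log(alpha) + log_norm(xi, m0x, tau2 + s2) +
                log_norm(yi, m0y, tau2 + s2);
      double mx = logp[0];
      for (int k = 1; k <= K; ++k) if (logp[k] > mx) mx = logp[k];
      double tot = 0.0;
      for (int k = 0; k <= K; ++k) { logp[k] = std::exp(logp[k] - mx); tot += logp[k]; }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = K;
      for (int k = 0; k <= K; ++k) { acc += logp[k]; if (u <= acc) { pick = k; break; } }
      if (pick == K) {
        cn.push_back(0.0); csx.push_back(0.0); csy.push_back(0.0);
        csxx.push_back(0.0); csyy.push_back(0.0);
      }
      z[i] = pick;
      cn[pick] += 1; csx[pick] += xi; csy[pick] += yi;
      csxx[pick] += xi * xi; csyy[pick] += yi * yi;
    }

    if (fit_sigma && sigma_grid.size() > 0) {
      int G = sigma_grid.size();
      std::vector<double> lg(G);
      double mxg = -1e300;
      for (int g = 0; g < G; ++g) {
        double s2 = sigma_grid[g] * sigma_grid[g];
        double ll = 0.0;
        for (size_t k = 0; k < cn.size(); ++k)
          ll += cluster_marginal(cn[k], csx[k], csy[k], csxx[k], csyy[k], s2,
                                 tau2, m0x, m0y);
        lg[g] = ll;
        if (ll > mxg) mxg = ll;
      }
      double tot = 0.0;
      for (int g = 0; g < G; ++g) { lg[g] = std::exp(lg[g] - mxg); tot += lg[g]; }
      double u = unif_rand() * tot, acc = 0.0;
      for (int g = 0; g < G; ++g) { acc += lg[g]; if (u <= acc) { sigma = sigma_grid[g]; break; } }
    }

    if (sweep >= burn_in && (sweep - burn_in) % thin == 0 && kept < kept_n) {
      // canonical labels by order of first appearance, 1-based
      std::vector<int> remap((int)cn.size(), 0);
      int next = 0;
      for (int j = 0; j < n; ++j) {
        if (remap[z[j]] == 0) remap[z[j]] = ++next;
        keep_z(kept, j) = remap[z[j]];
      }
      keep_sigma[kept] = sigma;
      keep_k[kept] = (int)cn.size();
      ++kept;
    }
  }
  PutRNGstate();
  return List::create(_["assignments"] = keep_z, _["sigma"] = keep_sigma,
                      _["k"] = keep_k);
}
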