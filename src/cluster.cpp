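// Second-level machinery: Wilcoxon rank-sum Z maps across subjects and
// cluster-based permutation correction (max cluster-mass statistic over
// group-label permutations).
//
// Sites live on a channel x frequency x time grid, linearized as
//   site = ch + nch * (fi + nf * ti)      (all 0-based internally).
// Adjacency: 4-connectivity in the frequency x time chart within each
// channel, plus links between the same (f, t) site on neighboring channels
// (disabled when tf_only is set).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// midrank-based Mann-Whitney Z with tie-corrected variance, no continuity
// correction.  Positive Z <=> group A stochastically larger.
static void ranksum_site(const double* vals, const int* grp, int n, int na,
                         double& z, double& p) {
  // insertion sort of indices: n is the subject count (small)
  static thread_local std::vector<int> ord;
  static thread_local std::vector<double> rank;
  ord.resize(n); rank.resize(n);
  for (int i = 0; i < n; ++i) {
    int j = i;
    while (j > 0 && vals[ord[j - 1]] > vals[i]) { ord[j] = ord[j - 1]; --j; }
    ord[j] = i;
  }
  double tie_sum = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && vals[ord[j + 1]] == vals[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;
    int t = j - i + 1;
    for (int k = i; k <= j; ++k) rank[ord[k]] = r;
    if (t > 1) tie_sum += (double)t * t * t - t;
    i = j + 1;
  }
  int nb = n - na;
  double ra = 0.0;
  for (int k = 0; k < n; ++k)
    if (grp[k]) ra += rank[k];
  double u = ra - (double)na * (na + 1) / 2.0;
  double mu = (double)na * nb / 2.0;
  double var = (double)na * nb / 12.0 *
               ((n + 1) - tie_sum / ((double)n * (n - 1)));
  if (var <= 0.0) { z = 0.0; p = 1.0; return; }
  z = (u - mu) / std::sqrt(var);
  p = std::erfc(std::fabs(z) / M_SQRT2);  // two-sided normal
}

// [[Rcpp::export(rng = false)]]
List ranksum_z_sites(NumericMatrix X, LogicalVector in_a) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<int> grp(n);
  int na = 0;
  for (int i = 0; i < n; ++i) { grp[i] = in_a[i] ? 1 : 0; na += grp[i]; }
  NumericVector z(m), p(m);
  std::vector<double> buf(n);
  for (int s = 0; s < m; ++s) {
    for (int i = 0; i < n; ++i) buf[i] = X(i, s);
    ranksum_site(buf.data(), grp.data(), n, na, z[s], p[s]);
  }
  return List::create(_["z"] = z, _["p"] = p);
}

struct Grid {
  int nch, nf, nt;
  const std::vector<std::vector<int>>* chnb;  // channel neighbor lists
  bool tf_only;
  int site(int c, int f, int t) const { return c + nch * (f + nf * t); }
};

// flood fill of same-signed suprathreshold sites; returns cluster labels
// (-1 = none) and per-cluster mass/sign
static void find_clusters_core(const std::vector<int>& sign,
                               const std::vector<double>& z, const Grid& g,
                               std::vector<int>& label,
                               std::vector<double>& mass,
                               std::vector<int>& csign) {
  int n = g.nch * g.nf * g.nt;
  label.assign(n, -1);
  mass.clear(); csign.clear();
  std::vector<int> stack;
  for (int s0 = 0; s0 < n; ++s0) {
    if (sign[s0] == 0 || label[s0] >= 0) continue;
    int id = (int)mass.size();
    int sg = sign[s0];
    double msum = 0.0;
    stack.push_back(s0);
    label[s0] = id;
    while (!stack.empty()) {
      int s = stack.back(); stack.pop_back();
      msum += z[s];
      int c = s % g.nch, rest = s / g.nch;
      int f = rest % g.nf, t = rest / g.nf;
      auto try_add = [&](int cc, int ff, int tt) {
        if (cc < 0 || cc >= g.nch || ff < 0 || ff >= g.nf || tt < 0 ||
            tt >= g.nt)
          return;
        int s2 = g.site(cc, ff, tt);
        if (sign[s2] == sg && label[s2] < 0) {
          label[s2] = id;
          stack.push_back(s2);
        }
      };
      try_add(c, f - 1, t); try_add(c, f + 1, t);
      try_add(c, f, t - 1); try_add(c, f, t + 1);
      if (!g.tf_only)
        for (int cc : (*g.chnb)[c]) try_add(cc, f, t);
    }
    mass.push_back(msum);
    csign.push_back(sg);
  }
}

static void threshold_sites(const std::vector<double>& z,
                            const std::vector<double>& p,
                            const std::vector<bool>& valid, double alpha,
                            std::vector<int>& sign) {
  int n = (int)z.size();
  sign.assign(n, 0);
  for (int s = 0; s < n; ++s)
    if (valid[s] && p[s] < alpha)
      sign[s] = z[s] > 0 ? 1 : (z[s] < 0 ? -1 : 0);
}

static std::vector<std::vector<int>> conv_neighbors(List chnb) {
  std::vector<std::vector<int>> out(chnb.size());
  for (int i = 0; i < chnb.size(); ++i) {
    IntegerVector v = chnb[i];
    for (int j = 0; j < v.size(); ++j) out[i].push_back(v[j] - 1);
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List find_clusters_cpp(IntegerVector sign_map, NumericVector zmap, int nch,
                       int nf, int nt, List chnb, bool tf_only) {
  Grid g{nch, nf, nt, nullptr, tf_only};
  auto nb = conv_neighbors(chnb);
  g.chnb = &nb;
  int n = nch * nf * nt;
  std::vector<int> sign(n);
  std::vector<double> z(n);
  for (int i = 0; i < n; ++i) { sign[i] = sign_map[i]; z[i] = zmap[i]; }
  std::vector<int> label, csign;
  std::vector<double> mass;
  find_clusters_core(sign, z, g, label, mass, csign);
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = label[i] + 1;  // 0 = none
  return List::create(_["label"] = lab, _["mass"] = wrap(mass),
                      _["sign"] = wrap(csign));
}

// Full permutation engine.  X: n_subj x n_site contrast values; valid:
// per-site usability; in_a: observed group-A membership.  Returns observed
// z/p maps, observed clusters, and the permutation distribution of the
// maximum |cluster mass|.  Uses R's RNG for label permutations.
// [[Rcpp::export]]
List perm_cluster_cpp(NumericMatrix X, LogicalVector valid,
                      LogicalVector in_a, double alpha, int n_perm, int nch,
                      int nf, int nt, List chnb, bool tf_only) {
  const int n = X.nrow(), m = X.ncol();
  Grid g{nch, nf, nt, nullptr, tf_only};
  auto nb = conv_neighbors(chnb);
  g.chnb = &nb;
  if (m != nch * nf * nt) stop("site count does not match grid dims");

  std::vector<bool> vmask(m);
  for (int s = 0; s < m; ++s) vmask[s] = valid[s];
  std::vector<int> grp(n);
  int na = 0;
  for (int i = 0; i < n; ++i) { grp[i] = in_a[i] ? 1 : 0; na += grp[i]; }

  std::vector<double> z(m), p(m), buf(n);
  auto compute_maps = [&](const std::vector<int>& gr) {
    for (int s = 0; s < m; ++s) {
      if (!vmask[s]) { z[s] = 0.0; p[s] = 1.0; continue; }
      for (int i = 0; i < n; ++i) buf[i] = X(i, s);
      ranksum_site(buf.data(), gr.data(), n, na, z[s], p[s]);
    }
  };

  compute_maps(grp);
  NumericVector z_obs(m), p_obs(m);
  for (int s = 0; s < m; ++s) { z_obs[s] = z[s]; p_obs[s] = p[s]; }
  std::vector<int> sign, label, csign;
  std::vector<double> mass;
  threshold_sites(z, p, vmask, alpha, sign);
  find_clusters_core(sign, z, g, label, mass, csign);
  IntegerVector lab(m);
  for (int i = 0; i < m; ++i) lab[i] = label[i] + 1;

  NumericVector perm_max(n_perm);
  std::vector<int> pg(n);
  for (int it = 0; it < n_perm; ++it) {
    IntegerVector idx = sample(n, n, false);  // R RNG
    for (int i = 0; i < n; ++i) pg[i] = grp[idx[i] - 1];
    compute_maps(pg);
    std::vector<int> psign, plabel, pcsign;
    std::vector<double> pmass;
    threshold_sites(z, p, vmask, alpha, psign);
    find_clusters_core(psign, z, g, plabel, pmass, pcsign);
    double mx = 0.0;
    for (double mm : pmass) mx = std::max(mx, std::fabs(mm));
    perm_max[it] = mx;
  }

  return List::create(_["z"] = z_obs, _["p"] = p_obs, _["label"] = lab,
                      _["mass"] = wrap(mass), _["sign"] = wrap(csign),
                      _["perm_max"] = perm_max);
}
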