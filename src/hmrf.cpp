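// Hidden Markov random field core for the extended DAWN model.
//
// Latent risk states I follow a (generalized) Ising prior
//   P(I) ~ exp( b * sum I_i + eta * sum_{(i,j) in E} I_i I_j + d * sum H_i I_i )
// and the observed Z-scores are N(0,1) under I=0, N(mu, sigma^2) under I=1.
// Fitting alternates Gibbs imputation of I with moment updates of (mu, sigma)
// and pseudo-likelihood (logistic) updates of (b, eta, d).  All sampling uses
// R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Flat CSR adjacency: neighbours of site i are idx[ptr[i] .. ptr[i+1])
struct NbrList {
  std::vector<int> ptr, idx;
  int n;
};

static NbrList build_nbrs(const List& nbr) {
  NbrList out;
  out.n = nbr.size();
  out.ptr.resize(out.n + 1);
  out.ptr[0] = 0;
  for (int i = 0; i < out.n; ++i) {
    IntegerVector v = nbr[i];
    out.ptr[i + 1] = out.ptr[i] + v.size();
    for (int k = 0; k < v.size(); ++k) out.idx.push_back(v[k]);
  }
  return out;
}

static inline double logistic(double x) {
  if (x > 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

static inline int nbr_sum(const NbrList& nb, const std::vector<int>& I, int i) {
  int s = 0;
  for (int k = nb.ptr[i]; k < nb.ptr[i + 1]; ++k) s += I[nb.idx[k]];
  return s;
}

// Per-site conditional probability tables: the conditional depends on the
// site only through its neighbour sum S in 0..deg(i), so with parameters
// fixed the logistic can be tabulated once and the inner loop needs no exp.
struct PTab {
  std::vector<double> p;   // flattened site x (S = 0..deg) table
  std::vector<int> off;    // off[i]: start of site i's row
};

static void fill_ptab(const NbrList& nb, const IntegerVector& H,
                      const std::vector<double>& llr,
                      double b, double eta, double d, PTab& tab) {
  int n = nb.n;
  if ((int)tab.off.size() != n + 1) {
    tab.off.resize(n + 1);
    tab.off[0] = 0;
    for (int i = 0; i < n; ++i)
      tab.off[i + 1] = tab.off[i] + (nb.ptr[i + 1] - nb.ptr[i]) + 1;
    tab.p.resize(tab.off[n]);
  }
  for (int i = 0; i < n; ++i) {
    double base = b + d * H[i] + (llr.empty() ? 0.0 : llr[i]);
    int deg = nb.ptr[i + 1] - nb.ptr[i];
    for (int s = 0; s <= deg; ++s)
      tab.p[tab.off[i] + s] = logistic(base + eta * s);
  }
}

// One Gibbs sweep over all sites using the precomputed conditional table.
static void gibbs_sweep(const NbrList& nb, const PTab& tab,
                        std::vector<int>& I) {
  int n = I.size();
  for (int i = 0; i < n; ++i)
    I[i] = (unif_rand() < tab.p[tab.off[i] + nbr_sum(nb, I, i)]) ? 1 : 0;
}

// Weighted logistic Newton on aggregated (S, H) cells.
// cols: active design columns among {intercept, S, H}; returns coefficients.
struct PLData {
  std::vector<double> s, h, n, y; // per cell: S value, H value, count, sum(I)
};

static double pl_loglik(const PLData& D, double b, double eta, double d) {
  double ll = 0.0;
  for (size_t c = 0; c < D.n.size(); ++c) {
    double lp = b + eta * D.s[c] + d * D.h[c];
    // log(1+exp(lp)) stable
    double l1p = (lp > 30) ? lp : std::log1p(std::exp(lp));
    ll += D.y[c] * lp - D.n[c] * l1p;
  }
  return ll;
}

// Solve the (at most 3x3) Newton system with active-column masking.
static void pl_newton(const PLData& D, bool use_s, bool use_h,
                      double& b, double& eta, double& d) {
  const int maxit = 30;
  int dim = 1 + (use_s ? 1 : 0) + (use_h ? 1 : 0);
  double theta[3] = { b, use_s ? eta : 0.0, use_h ? d : 0.0 };
  // map active coords: a[0]=b, a[1]=eta (if use_s), next = d
  double cur = pl_loglik(D, theta[0], use_s ? theta[1] : 0.0,
                         use_h ? theta[2] : 0.0);
  for (int it = 0; it < maxit; ++it) {
    double g[3] = {0, 0, 0};
    double Hm[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (size_t c = 0; c < D.n.size(); ++c) {
      double x[3] = {1.0, D.s[c], D.h[c]};
      double lp = theta[0] + (use_s ? theta[1] * x[1] : 0.0) +
                  (use_h ? theta[2] * x[2] : 0.0);
      double p = logistic(lp);
      double r = D.y[c] - D.n[c] * p;
      double w = D.n[c] * p * (1.0 - p);
      int ai = 0;
      int idx[3] = {-1, -1, -1};
      idx[0] = ai++;
      if (use_s) idx[1] = ai++;
      if (use_h) idx[2] = ai++;
      for (int a = 0; a < 3; ++a) {
        if (idx[a] < 0) continue;
        g[idx[a]] += r * x[a];
        for (int bb = 0; bb < 3; ++bb) {
          if (idx[bb] < 0) continue;
          Hm[idx[a] * 3 + idx[bb]] += w * x[a] * x[bb];
        }
      }
    }
    for (int a = 0; a < dim; ++a) Hm[a * 3 + a] += 1e-8; // ridge
    // solve Hm * step = g by Gaussian elimination (dim <= 3)
    double A[3][4];
    for (int a = 0; a < dim; ++a) {
      for (int bb = 0; bb < dim; ++bb) A[a][bb] = Hm[a * 3 + bb];
      A[a][dim] = g[a];
    }
    bool ok = true;
    for (int col = 0; col < dim && ok; ++col) {
      int piv = col;
      for (int r2 = col + 1; r2 < dim; ++r2)
        if (std::fabs(A[r2][col]) > std::fabs(A[piv][col])) piv = r2;
      if (std::fabs(A[piv][col]) < 1e-12) { ok = false; break; }
      if (piv != col)
        for (int cc = 0; cc <= dim; ++cc) std::swap(A[piv][cc], A[col][cc]);
      for (int r2 = 0; r2 < dim; ++r2) {
        if (r2 == col) continue;
        double f = A[r2][col] / A[col][col];
        for (int cc = col; cc <= dim; ++cc) A[r2][cc] -= f * A[col][cc];
      }
    }
    if (!ok) break;
    double step[3] = {0, 0, 0};
    double norm = 0;
    for (int a = 0; a < dim; ++a) {
      step[a] = A[a][dim] / A[a][a];
      norm = std::max(norm, std::fabs(step[a]));
    }
    double scale = (norm > 5.0) ? 5.0 / norm : 1.0; // cap step length
    double halve = 1.0;
    double nt[3];
    double nll = cur;
    for (int tries = 0; tries < 12; ++tries) {
      int ai = 0;
      nt[0] = theta[0] + scale * halve * step[ai++];
      nt[1] = use_s ? theta[1] + scale * halve * step[ai++] : 0.0;
      nt[2] = use_h ? theta[2] + scale * halve * step[ai] : 0.0;
      nll = pl_loglik(D, nt[0], nt[1], nt[2]);
      if (nll >= cur - 1e-12) break;
      halve *= 0.5;
    }
    double delta = std::fabs(nt[0] - theta[0]) + std::fabs(nt[1] - theta[1]) +
                   std::fabs(nt[2] - theta[2]);
    theta[0] = nt[0]; theta[1] = nt[1]; theta[2] = nt[2];
    cur = nll;
    if (delta < 1e-9) break;
  }
  b = theta[0];
  eta = use_s ? theta[1] : 0.0;
  d = use_h ? theta[2] : 0.0;
}

// Aggregate pseudo-likelihood cells from the current configuration.
static void accumulate_cells(const NbrList& nb, const IntegerVector& H,
                             const std::vector<int>& I,
                             std::vector<double>& cnt, std::vector<double>& ysum,
                             int maxdeg) {
  int n = I.size();
  for (int i = 0; i < n; ++i) {
    int s = nbr_sum(nb, I, i);
    int key = s * 2 + H[i];
    cnt[key] += 1.0;
    ysum[key] += I[i];
  }
  (void)maxdeg;
}

static PLData cells_to_data(const std::vector<double>& cnt,
                            const std::vector<double>& ysum) {
  PLData D;
  for (size_t key = 0; key < cnt.size(); ++key) {
    if (cnt[key] <= 0) continue;
    D.s.push_back(static_cast<double>(key / 2));
    D.h.push_back(static_cast<double>(key % 2));
    D.n.push_back(cnt[key]);
    D.y.push_back(ysum[key]);
  }
  return D;
}

// [[Rcpp::export]]
List cpp_fit_hmrf(List nbr, NumericVector z, IntegerVector H, bool use_d,
                  double b0, double eta0, double d0, double mu0, double sigma0,
                  IntegerVector init_state,
                  double tol, int max_iter, int burn, int n_samples,
                  double min_sigma, int final_sweeps) {
  NbrList nb = build_nbrs(nbr);
  int n = z.size();
  int maxdeg = 0;
  for (int i = 0; i < n; ++i)
    maxdeg = std::max(maxdeg, nb.ptr[i + 1] - nb.ptr[i]);
  bool any_edges = maxdeg > 0;

  double b = b0, eta = eta0, d = d0, mu = mu0, sigma = sigma0;
  std::vector<int> I(init_state.begin(), init_state.end());
  std::vector<double> llr(n), post(n, 0.0);
  bool degenerate = false, converged = false;
  int iter = 0;
  double pb = b, peta = eta, pd = d, pmu = mu, psigma = sigma;
  PLData last_cells;
  PTab ptab;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int i = 0; i < n; ++i)
      llr[i] = -std::log(sigma) - 0.5 * std::pow((z[i] - mu) / sigma, 2) +
               0.5 * z[i] * z[i];
    fill_ptab(nb, H, llr, b, eta, d, ptab);
    std::fill(post.begin(), post.end(), 0.0);
    std::vector<double> cnt((maxdeg + 1) * 2, 0.0), ysum((maxdeg + 1) * 2, 0.0);
    for (int s = 0; s < burn; ++s) gibbs_sweep(nb, ptab, I);
    for (int s = 0; s < n_samples; ++s) {
      gibbs_sweep(nb, ptab, I);
      for (int i = 0; i < n; ++i) post[i] += I[i];
      accumulate_cells(nb, H, I, cnt, ysum, maxdeg);
    }
    double tot = 0.0;
    for (int i = 0; i < n; ++i) { post[i] /= n_samples; tot += post[i]; }
    if (tot < 0.5 || tot > n - 0.5) { // posterior mass collapsed
      degenerate = true;
      b = pb; eta = peta; d = pd; mu = pmu; sigma = psigma;
      break;
    }
    pb = b; peta = eta; pd = d; pmu = mu; psigma = sigma;
    // (mu, sigma) from posterior-weighted moments
    double sw = 0, swz = 0;
    for (int i = 0; i < n; ++i) { sw += post[i]; swz += post[i] * z[i]; }
    double nmu = swz / sw;
    double sv = 0;
    for (int i = 0; i < n; ++i) sv += post[i] * (z[i] - nmu) * (z[i] - nmu);
    double nsigma = std::max(min_sigma, std::sqrt(sv / sw));
    // (b, eta, d) by pseudo-likelihood Newton on the sampled states
    PLData D = cells_to_data(cnt, ysum);
    last_cells = D;
    double toty = 0, totn = 0;
    for (size_t c = 0; c < D.n.size(); ++c) { toty += D.y[c]; totn += D.n[c]; }
    double nb_ = b, neta = eta, nd = d;
    if (toty > 1e-9 && toty < totn - 1e-9) {
      // only include covariates whose sampled sufficient statistics vary
      bool s_varies = false, h_varies = false;
      for (size_t c = 1; c < D.n.size(); ++c) {
        if (D.s[c] != D.s[0]) s_varies = true;
        if (D.h[c] != D.h[0]) h_varies = true;
      }
      bool use_s = any_edges && s_varies;
      bool use_h = use_d && h_varies;
      pl_newton(D, use_s, use_h, nb_, neta, nd);
      if (!use_s) neta = eta;
      if (!use_h) nd = d;
      if (use_d && nd < 0) { // clamp d >= 0 under M1
        nd = 0.0;
        pl_newton(D, use_s, false, nb_, neta, nd);
        nd = 0.0;
      }
    }
    double delta = std::max(std::fabs(nb_ - b),
                   std::max(std::fabs(neta - eta),
                   std::max(std::fabs(nd - d),
                   std::max(std::fabs(nmu - mu), std::fabs(nsigma - sigma)))));
    b = nb_; eta = neta; d = nd; mu = nmu; sigma = nsigma;
    if (delta < tol) { converged = true; break; }
  }

  // posterior at the returned parameters
  if (final_sweeps > 0) {
    for (int i = 0; i < n; ++i)
      llr[i] = -std::log(sigma) - 0.5 * std::pow((z[i] - mu) / sigma, 2) +
               0.5 * z[i] * z[i];
    fill_ptab(nb, H, llr, b, eta, d, ptab);
    std::fill(post.begin(), post.end(), 0.0);
    int fburn = std::min(burn, final_sweeps / 4 + 1);
    for (int s = 0; s < fburn; ++s) gibbs_sweep(nb, ptab, I);
    for (int s = 0; s < final_sweeps; ++s) {
      gibbs_sweep(nb, ptab, I);
      for (int i = 0; i < n; ++i) post[i] += I[i];
    }
    for (int i = 0; i < n; ++i) post[i] /= final_sweeps;
  }

  return List::create(_["b"] = b, _["eta"] = eta, _["d"] = d,
                      _["mu"] = mu, _["sigma"] = sigma,
                      _["posterior"] = NumericVector(post.begin(), post.end()),
                      _["n_iter"] = iter, _["converged"] = converged,
                      _["degenerate"] = degenerate,
                      _["pl_cells"] = DataFrame::create(
                        _["s"] = last_cells.s, _["h"] = last_cells.h,
                        _["n"] = last_cells.n, _["y"] = last_cells.y));
}

// Single-site Metropolis-Hastings simulation of the (generalized) Ising
// prior, without data terms.  Convergence is monitored by the running mean of
// sum(I) over consecutive windows.
// [[Rcpp::export]]
List cpp_ising_mh(List nbr, IntegerVector H, double b, double eta, double d,
                  IntegerVector init_state, int max_sweeps, double rel_tol,
                  int window) {
  NbrList nb = build_nbrs(nbr);
  int n = init_state.size();
  std::vector<int> I(init_state.begin(), init_state.end());
  int sweeps = 0;
  bool converged = false;
  double prev_mean = -1.0, acc = 0.0;
  // parameters are fixed for the whole run: tabulate e = exp(b + eta*S + dH)
  // per site and neighbour sum; flipping 0->1 has delta = log(e), 1->0 has
  // delta = -log(e)
  std::vector<int> off(n + 1);
  off[0] = 0;
  for (int i = 0; i < n; ++i)
    off[i + 1] = off[i] + (nb.ptr[i + 1] - nb.ptr[i]) + 1;
  std::vector<double> etab(off[n]);
  for (int i = 0; i < n; ++i) {
    int deg = nb.ptr[i + 1] - nb.ptr[i];
    for (int s = 0; s <= deg; ++s)
      etab[off[i] + s] = std::exp(b + eta * s + d * H[i]);
  }
  for (int s = 1; s <= max_sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      // propose flipping site i
      double e = etab[off[i] + nbr_sum(nb, I, i)];
      if (I[i] == 0) {
        if (e >= 1.0 || unif_rand() < e) I[i] = 1;
      } else {
        if (e <= 1.0 || unif_rand() * e < 1.0) I[i] = 0;
      }
    }
    int tot = 0;
    for (int i = 0; i < n; ++i) tot += I[i];
    acc += tot;
    sweeps = s;
    if (s % window == 0) {
      double m = acc / window;
      acc = 0.0;
      if (prev_mean >= 0) {
        double denom = std::max(1.0, std::fabs(prev_mean));
        if (std::fabs(m - prev_mean) / denom < rel_tol) {
          converged = true;
          break;
        }
      }
      prev_mean = m;
    }
  }
  return List::create(_["state"] = IntegerVector(I.begin(), I.end()),
                      _["sweeps"] = sweeps, _["converged"] = converged);
}
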