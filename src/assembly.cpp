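// Null-model hot paths: abundance-weighted betaMNTD over all sample pairs,
// its tip-shuffle null (shared permutations, shuffle once / evaluate all
// pairs), the abundance-weighted Raup-Crick null on Bray-Curtis, and the
// individual-based Moran neutral simulator. All randomness comes from R's
// RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// min patristic distance from every taxon to each sample's present set,
// under a permutation `perm` of taxon indices (identity = observed).
// D: S x S patristic; presence: list of 0-based present-taxon indices per
// sample. Returns M (S x n): M(k, j) = min_{l in sample j} D(perm[k], perm[l]).
static arma::mat min_dist_matrix(const arma::mat& D,
                                 const std::vector<std::vector<int>>& present,
                                 const arma::uvec& perm) {
  const int S = D.n_rows, n = present.size();
  arma::mat M(S, n);
  for (int j = 0; j < n; ++j) {
    const std::vector<int>& pj = present[j];
    for (int k = 0; k < S; ++k) {
      double mn = R_PosInf;
      const double* drow = D.colptr(perm[k]); // D symmetric: column = row
      for (size_t t = 0; t < pj.size(); ++t) {
        double v = drow[perm[pj[t]]];
        if (v < mn) mn = v;
      }
      M(k, j) = mn;
    }
  }
  return M;
}

static std::vector<std::vector<int>> presence_lists(const arma::mat& F) {
  std::vector<std::vector<int>> present(F.n_cols);
  for (arma::uword j = 0; j < F.n_cols; ++j) {
    for (arma::uword k = 0; k < F.n_rows; ++k) {
      if (F(k, j) > 0) present[j].push_back(k);
    }
  }
  return present;
}

// betaMNTD(i, j) = 0.5 * (sum_k f_ki min_l d + sum_l f_lj min_k d)
static arma::mat bmntd_from_min(const arma::mat& F, const arma::mat& M) {
  arma::mat T = F.t() * M; // T(i, j) = sum_k f_ki * M(k, j)
  return 0.5 * (T + T.t());
}

// [[Rcpp::export]]
arma::mat cpp_bmntd(const arma::mat& D, const arma::mat& F) {
  std::vector<std::vector<int>> present = presence_lists(F);
  arma::uvec id = arma::regspace<arma::uvec>(0, D.n_rows - 1);
  return bmntd_from_min(F, min_dist_matrix(D, present, id));
}

// Observed betaMNTD plus null mean/sd over tip-label shuffles.
// perms: S x n_null matrix of 1-based permutations (columns).
// [[Rcpp::export]]
List cpp_bnti(const arma::mat& D, const arma::mat& F,
              const IntegerMatrix& perms) {
  std::vector<std::vector<int>> present = presence_lists(F);
  const int n = F.n_cols, n_null = perms.ncol();
  arma::uvec id = arma::regspace<arma::uvec>(0, D.n_rows - 1);
  arma::mat obs = bmntd_from_min(F, min_dist_matrix(D, present, id));
  arma::mat mean(n, n, arma::fill::zeros), m2(n, n, arma::fill::zeros);
  for (int b = 0; b < n_null; ++b) {
    arma::uvec perm(D.n_rows);
    for (arma::uword k = 0; k < D.n_rows; ++k) perm[k] = perms(k, b) - 1;
    arma::mat bm = bmntd_from_min(F, min_dist_matrix(D, present, perm));
    arma::mat delta = bm - mean;          // Welford accumulation
    mean += delta / (b + 1);
    m2 += delta % (bm - mean);
  }
  arma::mat sd = arma::sqrt(m2 / (n_null - 1));
  return List::create(_["obs"] = obs, _["null_mean"] = mean,
                      _["null_sd"] = sd);
}

static double bray_curtis_pair(const std::vector<double>& x,
                               const std::vector<double>& y) {
  double num = 0, den = 0;
  for (size_t k = 0; k < x.size(); ++k) {
    num += std::fabs(x[k] - y[k]);
    den += x[k] + y[k];
  }
  return num / den;
}

// Rebuild one community under the Raup-Crick null: draw `richness` taxa
// without replacement with probability ~ occ_w (Efraimidis-Spirakis keys),
// give each one individual, then fill to `total` with multinomial draws
// ~ ab_w restricted to the drawn taxa.
static void null_community(int richness, double total,
                           const std::vector<double>& occ_w,
                           const std::vector<double>& ab_w,
                           std::vector<double>& out,
                           std::vector<int>& chosen,
                           std::vector<double>& prob,
                           std::vector<int>& fill) {
  const int S = occ_w.size();
  std::fill(out.begin(), out.end(), 0.0);
  // weighted sampling without replacement: top-k keys u^(1/w)
  std::vector<std::pair<double, int>> keys(S);
  for (int k = 0; k < S; ++k) {
    double u = unif_rand();
    keys[k] = std::make_pair(std::pow(u, 1.0 / occ_w[k]), k);
  }
  std::partial_sort(keys.begin(), keys.begin() + richness, keys.end(),
                    [](const std::pair<double, int>& a,
                       const std::pair<double, int>& b) {
                      return a.first > b.first;
                    });
  chosen.resize(richness);
  prob.resize(richness);
  double psum = 0;
  for (int t = 0; t < richness; ++t) {
    chosen[t] = keys[t].second;
    prob[t] = ab_w[chosen[t]];
    psum += prob[t];
  }
  for (int t = 0; t < richness; ++t) prob[t] /= psum;
  int extra = (int)std::lround(total) - richness;
  fill.assign(richness, 0);
  if (extra > 0) rmultinom(extra, prob.data(), richness, fill.data());
  for (int t = 0; t < richness; ++t) out[chosen[t]] = 1.0 + fill[t];
}

// Abundance-weighted Raup-Crick on Bray-Curtis for one sample pair.
// counts_i/j: observed counts over the shared taxon registry; occ_w:
// occupancy weights; ab_w: metacommunity relative-abundance weights.
// Returns RC in [-1, 1] with ties at half weight.
// [[Rcpp::export]]
double cpp_rc_bray_pair(const NumericVector& counts_i,
                        const NumericVector& counts_j,
                        const NumericVector& occ_w,
                        const NumericVector& ab_w,
                        int n_null) {
  const int S = counts_i.size();
  std::vector<double> xi(counts_i.begin(), counts_i.end());
  std::vector<double> xj(counts_j.begin(), counts_j.end());
  double obs = bray_curtis_pair(xi, xj);
  int rich_i = 0, rich_j = 0;
  double tot_i = 0, tot_j = 0;
  for (int k = 0; k < S; ++k) {
    if (xi[k] > 0) ++rich_i;
    if (xj[k] > 0) ++rich_j;
    tot_i += xi[k];
    tot_j += xj[k];
  }
  std::vector<double> ow(occ_w.begin(), occ_w.end());
  std::vector<double> aw(ab_w.begin(), ab_w.end());
  std::vector<double> ni(S), nj(S);
  std::vector<int> chosen; std::vector<double> prob; std::vector<int> fill;
  double below = 0, equal = 0;
  for (int b = 0; b < n_null; ++b) {
    null_community(rich_i, tot_i, ow, aw, ni, chosen, prob, fill);
    null_community(rich_j, tot_j, ow, aw, nj, chosen, prob, fill);
    double bc = bray_curtis_pair(ni, nj);
    if (bc < obs - 1e-12) below += 1;
    else if (std::fabs(bc - obs) <= 1e-12) equal += 1;
  }
  return 2.0 * ((below + 0.5 * equal) / n_null) - 1.0;
}

// Individual-based Moran neutral local community: initialize by a
// multinomial draw of N individuals from the source pool, then run
// `generations` x N single-individual replacement steps (death uniform;
// replacement is an immigrant from the pool with probability m_event,
// otherwise a copy of one of the other N-1 local individuals chosen
// uniformly). With m_event = I / (I + N - 1) the stationary distribution
// of counts is Dirichlet-multinomial with concentration I.
// [[Rcpp::export]]
IntegerVector cpp_neutral_moran(int N, double m_event,
                                const NumericVector& pool_p,
                                int generations) {
  const int S = pool_p.size();
  std::vector<double> cum(S);
  double acc = 0;
  for (int k = 0; k < S; ++k) { acc += pool_p[k]; cum[k] = acc; }
  for (int k = 0; k < S; ++k) cum[k] /= acc;
  auto draw_pool = [&]() {
    double u = unif_rand();
    return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  };
  std::vector<int> ind(N);
  for (int i = 0; i < N; ++i) ind[i] = draw_pool();
  const long steps = (long)generations * N;
  for (long s = 0; s < steps; ++s) {
    int death = (int)(unif_rand() * N);
    if (death == N) death = N - 1;
    int repl;
    if (unif_rand() < m_event) {
      repl = draw_pool();
    } else {
      int parent = (int)(unif_rand() * (N - 1));
      if (parent >= death) parent += 1; // parent drawn among the other N-1
      if (parent >= N) parent = N - 1;
      repl = ind[parent];
    }
    ind[death] = repl;
  }
  IntegerVector counts(S);
  for (int i = 0; i < N; ++i) counts[ind[i]] += 1;
  return counts;
}
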