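// Felsenstein pruning over a site-class mixture.
//
// R precomputes, per distinct omega, the symmetric eigendecomposition of
// the (unscaled) GY94 rate matrix; this routine assembles P(t) per edge
// and class, runs the postorder pruning with per-node rescaling, and
// returns per-pattern per-class log-likelihoods.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>

using namespace arma;

// [[Rcpp::export(name = ".cpp_class_loglik")]]
arma::mat cpp_class_loglik(const arma::imat& tips,   // ntip x npat, 0 = missing
                           const arma::imat& edge,   // nedge x 2, postorder, 1-based
                           const arma::ivec& marks,  // per edge, >0 = foreground
                           const arma::vec& bl,      // per edge
                           const arma::cube& U,      // 61 x 61 x ndec
                           const arma::cube& W,      // 61 x 61 x ndec
                           const arma::mat& lambda,  // 61 x ndec
                           const arma::imat& decIdx, // nclass x 2 (bg, fg), 1-based
                           const arma::vec& scaleBgFg, // length 2
                           const arma::vec& pi) {
  const int ntip = tips.n_rows;
  const int npat = tips.n_cols;
  const int nedge = edge.n_rows;
  const int nclass = decIdx.n_rows;
  const int root = edge(nedge - 1, 0) - 1;
  int nnode_tot = root + 1;
  for (int e = 0; e < nedge; ++e) {
    nnode_tot = std::max(nnode_tot, std::max(edge(e, 0), edge(e, 1)));
  }

  mat out(npat, nclass);
  std::vector<mat> part(nnode_tot);
  std::vector<bool> seen(nnode_tot);
  // P matrices cached by (eigendecomposition, scaled time): classes share
  // them wherever their omega coincides on a branch type
  std::map<std::pair<int, long long>, mat> pcache;

  for (int k = 0; k < nclass; ++k) {
    for (int n = 0; n < nnode_tot; ++n) seen[n] = false;
    rowvec logscale(npat, fill::zeros);

    for (int e = 0; e < nedge; ++e) {
      const int parent = edge(e, 0) - 1;
      const int child = edge(e, 1) - 1;
      const bool fg = marks(e) > 0;
      const int d = decIdx(k, fg ? 1 : 0) - 1;
      const double t = bl(e) / scaleBgFg(fg ? 1 : 0);

      const long long tkey = (long long)std::llround(t * 1e12);
      auto key = std::make_pair(d, tkey);
      auto it = pcache.find(key);
      if (it == pcache.end()) {
        vec el = exp(lambda.col(d) * t);
        mat P = U.slice(d) * (W.slice(d).each_col() % el);
        P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
        it = pcache.emplace(key, std::move(P)).first;
      }
      const mat& P = it->second;

      mat contrib(61, npat);
      if (child < ntip) {
        for (int s = 0; s < npat; ++s) {
          const int st = tips(child, s);
          if (st == 0) {
            contrib.col(s).ones();
          } else {
            contrib.col(s) = P.col(st - 1);
          }
        }
      } else {
        mat& cp = part[child];
        rowvec sc = sum(cp, 0) / 61.0;
        for (int s = 0; s < npat; ++s) {
          if (sc(s) <= 0) sc(s) = 1.0;
          cp.col(s) /= sc(s);
          logscale(s) += std::log(sc(s));
        }
        contrib = P * cp;
      }
      if (!seen[parent]) {
        part[parent] = std::move(contrib);
        seen[parent] = true;
      } else {
        part[parent] %= contrib;
      }
    }
    rowvec rootlik = vec(pi).t() * part[root];
    for (int s = 0; s < npat; ++s) {
      out(s, k) = std::log(rootlik(s)) + logscale(s);
    }
  }
  return out;
}
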