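// Core numerics: box-constrained least squares (active-set scheme in the
// style of Stark & Parker's BVLS) and the exchange search for exact designs.
//
// Conventions used throughout:
//   G     : d x p matrix whose row i is the stacked gradient
//           (grad eta0(nom0, x_i), -grad eta1(nom1, x_i)) at design-space
//           point x_i, p = 2m.
//   Delta : d-vector of nominal response differences eta0 - eta1.
//   w     : p-vector of cuboid half-widths r * sigma (entries may be 0 or
//           +Inf); the criterion is
//           delta^2(D) = min_{|u| <= w} || G_D u + Delta_D ||^2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Least-squares solve, falling back to the minimum-norm solution when the
// free-column submatrix is rank deficient (the objective value is unaffected).
static arma::vec ls_min_norm(const arma::mat& A, const arma::vec& z) {
  arma::vec x;
  bool ok = arma::solve(x, A, z, arma::solve_opts::no_approx);
  if (!ok || !x.is_finite()) x = arma::pinv(A) * z;
  return x;
}

struct BvlsFit {
  arma::vec x;
  double rss;
  int status; // 0 converged, 1 iteration limit (degenerate)
};

static double rss_of(const arma::mat& A, const arma::vec& z, const arma::vec& x) {
  arma::vec r = A * x - z;
  return arma::dot(r, r);
}

// Minimize ||A x - z||^2 subject to lb <= x <= ub (entries may be +-Inf;
// lb[j] == ub[j] freezes a coordinate).
static BvlsFit bvls_solve(const arma::mat& A, const arma::vec& z,
                          const arma::vec& lb, const arma::vec& ub) {
  const int p = (int)A.n_cols;
  arma::vec x(p);
  arma::ivec state(p); // -1 at lower, +1 at upper, 0 free, 2 frozen
  for (int j = 0; j < p; ++j) {
    if (lb[j] == ub[j]) { x[j] = lb[j]; state[j] = 2; }
    else if (std::isfinite(lb[j]) && lb[j] >= 0.0) { x[j] = lb[j]; state[j] = -1; }
    else if (std::isfinite(ub[j]) && ub[j] <= 0.0) { x[j] = ub[j]; state[j] = +1; }
    else { x[j] = 0.0; state[j] = 0; }
  }

  const double kkt_tol =
      1e-10 * std::max(1.0, arma::norm(A.t() * z, "inf"));
  arma::ivec banned(p, arma::fill::zeros);
  double rss_prev = std::numeric_limits<double>::infinity();
  const int maxit = 40 * p + 40;

  for (int it = 0; it < maxit; ++it) {
    // Inner loop: least squares over the free set, stepping back to the
    // feasible box and binding variables that hit a face.
    for (int inner = 0; inner <= p; ++inner) {
      arma::uvec F = arma::find(state == 0);
      if (F.n_elem == 0) break;
      arma::vec rhs = z;
      arma::uvec B = arma::find(state != 0);
      if (B.n_elem > 0) rhs -= A.cols(B) * x(B);
      arma::vec xf = ls_min_norm(A.cols(F), rhs);

      double alpha = 1.0;
      int hit = -1, hitdir = 0;
      for (arma::uword t = 0; t < F.n_elem; ++t) {
        int j = (int)F[t];
        double xn = xf[t], xo = x[j];
        if (xn < lb[j]) {
          double a = (xn == xo) ? 0.0 : (lb[j] - xo) / (xn - xo);
          if (a < alpha) { alpha = a; hit = j; hitdir = -1; }
        } else if (xn > ub[j]) {
          double a = (xn == xo) ? 0.0 : (ub[j] - xo) / (xn - xo);
          if (a < alpha) { alpha = a; hit = j; hitdir = +1; }
        }
      }
      if (hit < 0) {
        for (arma::uword t = 0; t < F.n_elem; ++t) x[F[t]] = xf[t];
        break;
      }
      for (arma::uword t = 0; t < F.n_elem; ++t) {
        int j = (int)F[t];
        x[j] += alpha * (xf[t] - x[j]);
        if (x[j] <= lb[j]) { x[j] = lb[j]; state[j] = -1; }
        else if (x[j] >= ub[j]) { x[j] = ub[j]; state[j] = +1; }
      }
      x[hit] = (hitdir < 0) ? lb[hit] : ub[hit];
      state[hit] = hitdir;
    }

    double rss = rss_of(A, z, x);
    if (rss < rss_prev - 1e-15 * (1.0 + rss_prev)) {
      banned.zeros();
      rss_prev = rss;
    }

    // KKT check: free the bound variable with the largest inward descent.
    arma::vec g = A.t() * (z - A * x); // negative half-gradient
    int bestj = -1;
    double best = kkt_tol;
    for (int j = 0; j < p; ++j) {
      if (banned[j]) continue;
      if (state[j] == -1 && g[j] > best) { best = g[j]; bestj = j; }
      else if (state[j] == +1 && -g[j] > best) { best = -g[j]; bestj = j; }
    }
    if (bestj < 0) return BvlsFit{x, rss, 0};
    banned[bestj] = 1; // lifted on the next strict decrease
    state[bestj] = 0;
  }
  return BvlsFit{x, rss_of(A, z, x), 1};
}

// [[Rcpp::export]]
List cpp_bvls(const arma::mat& A, const arma::vec& z,
              const arma::vec& lb, const arma::vec& ub) {
  BvlsFit f = bvls_solve(A, z, lb, ub);
  return List::create(_["x"] = f.x, _["rss"] = f.rss, _["status"] = f.status);
}

static double eval_delta_idx(const arma::mat& G, const arma::vec& Delta,
                             const arma::uvec& idx, const arma::vec& w,
                             bool all_zero_w) {
  if (all_zero_w) {
    double s = 0.0;
    for (arma::uword i = 0; i < idx.n_elem; ++i) {
      double d = Delta[idx[i]];
      s += d * d;
    }
    return s;
  }
  arma::mat A = G.rows(idx);
  arma::vec z = -Delta(idx);
  return bvls_solve(A, z, -w, w).rss;
}

static bool w_all_zero(const arma::vec& w) {
  for (arma::uword j = 0; j < w.n_elem; ++j)
    if (w[j] != 0.0) return false;
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_eval_designs(const arma::mat& G, const arma::vec& Delta,
                               const arma::vec& w, const IntegerMatrix& idx) {
  const int n = idx.nrow(), K = idx.ncol();
  const bool zw = w_all_zero(w);
  NumericVector out(K);
  arma::uvec ix(n);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i) ix[i] = (arma::uword)(idx(i, k) - 1);
    out[k] = eval_delta_idx(G, Delta, ix, w, zw);
  }
  return out;
}

// Best-improvement exchange over n-point designs: from each start, scan all
// (occupied position, candidate point) pairs in a randomized position order,
// apply the single best improving exchange, and repeat to a local maximum.
// Uses R's RNG (for the scan order), so results are reproducible under
// set.seed().
// [[Rcpp::export]]
List cpp_kl_exchange(const arma::mat& G, const arma::vec& Delta,
                     const arma::vec& w, const IntegerMatrix& starts,
                     double tol) {
  const int n = starts.nrow(), S = starts.ncol(), d = (int)G.n_rows;
  const bool zw = w_all_zero(w);
  double bestv = -1.0;
  arma::uvec bestidx;
  NumericVector per_start(S);
  IntegerVector per_iter(S);
  List traces(S);
  double neval = 0.0;
  std::vector<int> perm(n);

  for (int s = 0; s < S; ++s) {
    arma::uvec idx(n);
    for (int i = 0; i < n; ++i) idx[i] = (arma::uword)(starts(i, s) - 1);
    double v = eval_delta_idx(G, Delta, idx, w, zw);
    neval += 1.0;
    std::vector<double> tr;
    tr.push_back(v);
    int iters = 0;

    while (iters < 200) {
      ++iters;
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = n - 1; i > 0; --i) { // Fisher-Yates via R's RNG
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      double bgain = tol;
      int bi = -1, bj = -1;
      double bv = v;
      arma::uvec idx2 = idx;
      for (int t = 0; t < n; ++t) {
        int pos = perm[t];
        arma::uword keep = idx[pos];
        for (int j = 0; j < d; ++j) {
          if ((arma::uword)j == keep) continue;
          idx2[pos] = (arma::uword)j;
          double v2 = eval_delta_idx(G, Delta, idx2, w, zw);
          neval += 1.0;
          if (v2 - v > bgain) { bgain = v2 - v; bi = pos; bj = j; bv = v2; }
        }
        idx2[pos] = keep;
      }
      if (bi < 0) break;
      idx[bi] = (arma::uword)bj;
      v = bv;
      tr.push_back(v);
    }

    per_start[s] = v;
    per_iter[s] = iters;
    traces[s] = NumericVector(tr.begin(), tr.end());
    if (v > bestv) { bestv = v; bestidx = idx; }
  }

  IntegerVector bi(bestidx.n_elem);
  for (arma::uword i = 0; i < bestidx.n_elem; ++i) bi[i] = (int)bestidx[i] + 1;
  return List::create(_["best_value"] = bestv, _["best_idx"] = bi,
                      _["per_start"] = per_start, _["per_start_iters"] = per_iter,
                      _["traces"] = traces, _["n_evaluations"] = neval);
}
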