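// Least absolute deviation (median) regression by basis exchange.
//
// The LAD optimum interpolates p observations (a vertex of the
// piecewise-linear objective). Starting from a warm basis, the solver
// cycles over the p edge directions of the current vertex; whenever a
// direction has a negative directional derivative it moves to the
// weighted-median breakpoint along that edge (Barrodale-Roberts style
// descent) and swaps the corresponding basis row. It stops when all p
// directions certify non-descent, i.e. at a subgradient-optimal vertex,
// so the attained objective equals the linear-programming optimum.
//
// The inner loops are hand-rolled because bootstrap scans refit
// millions of times: the basis inverse is maintained by Sherman-
// Morrison row updates (refactored periodically), edge images X d are
// formed lazily per direction, and residuals are updated in place.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double lad_objective(const mat& X, const vec& y, const vec& beta) {
  return accu(abs(y - X * beta));
}

// Greedy basis from rows with the smallest |residuals| under beta0,
// keeping rows that enlarge the span (incremental Gram-Schmidt over a
// small candidate pool selected in O(n)).
static bool init_basis(const mat& X, const vec& y, const vec& beta0,
                       uvec& basis, std::vector<std::pair<double, uword>>& buf) {
  const uword n = X.n_rows, p = X.n_cols;
  vec r = y - X * beta0;
  buf.clear();
  for (uword k = 0; k < n; ++k) buf.emplace_back(std::abs(r(k)), k);
  uword pool = std::min<uword>(n, 4 * p + 8);
  std::nth_element(buf.begin(), buf.begin() + (pool - 1), buf.end());
  std::sort(buf.begin(), buf.begin() + pool);

  basis.set_size(p);
  mat Q(p, p);
  uword got = 0;
  for (uword k = 0; k < n && got < p; ++k) {
    if (k == pool) std::sort(buf.begin() + pool, buf.end());  // rare
    rowvec v = X.row(buf[k].second);
    double nrm0 = norm(v);
    if (nrm0 <= 1e-12) continue;
    for (uword j = 0; j < got; ++j) v -= dot(v, Q.row(j)) * Q.row(j);
    double nrm = norm(v);
    if (nrm > 1e-9 * nrm0) {
      Q.row(got) = v / nrm;
      basis(got) = buf[k].second;
      ++got;
    }
  }
  return got == p;
}

// Exchange loop; basis updated in place, beta written on success.
static bool lad_descend(const mat& X, const vec& y, uvec& basis, vec& beta,
                        int maxit, int& iters,
                        std::vector<std::pair<double, uword>>& bp) {
  const uword n = X.n_rows, p = X.n_cols;
  const double tol = 1e-11;

  mat XB = X.rows(basis);
  mat XBinv;
  if (!inv(XBinv, XB)) return false;
  vec bcur = XBinv * y.elem(basis);
  vec r = y - X * bcur;
  vec a(n), d(p), u(p);
  rowvec vt(p), dx(p);

  uword fails = 0;  // consecutive certified directions
  uword ii = 0;     // round-robin direction index
  int moves_since_refactor = 0;
  iters = 0;
  double* rp = r.memptr();
  while (fails < p && iters < maxit) {
    ++iters;
    // edge direction ii: d = XBinv.col(ii), a = X d
    d = XBinv.col(ii);
    a = X * d;
    const double* ap = a.memptr();
    double gplus = 0.0, gminus = 0.0;
    for (uword k = 0; k < n; ++k) {
      double ak = ap[k];
      if (std::abs(ak) <= 1e-12) continue;
      if (std::abs(rp[k]) > 1e-11) {
        double s = (rp[k] > 0 ? ak : -ak);
        gplus -= s;
        gminus += s;
      } else {
        double aa = std::abs(ak);
        gplus += aa;
        gminus += aa;
      }
    }
    double dirsign, g;
    if (gplus < -tol) { dirsign = 1.0; g = gplus; }
    else if (gminus < -tol) { dirsign = -1.0; g = gminus; }
    else { ++fails; ii = (ii + 1) % p; continue; }

    // breakpoints t_k = r_k / a_k with sign(t) = dirsign
    bp.clear();
    for (uword k = 0; k < n; ++k) {
      double ak = ap[k];
      if (std::abs(ak) <= 1e-12) continue;
      double t = rp[k] / ak;
      if (dirsign > 0 ? (t > 1e-12) : (t < -1e-12)) {
        bp.emplace_back(std::abs(t), k);
      }
    }
    if (bp.empty()) { ++fails; ii = (ii + 1) % p; continue; }
    std::sort(bp.begin(), bp.end());
    double cum = g;
    uword newrow = bp.back().second;
    double tabs = bp.back().first;
    for (size_t k = 0; k < bp.size(); ++k) {
      uword kr = bp[k].second;
      cum += 2.0 * std::abs(ap[kr]);
      if (cum >= -tol) { newrow = kr; tabs = bp[k].first; break; }
    }
    const double tstar = dirsign * tabs;

    // move along the edge, then swap basis row ii -> newrow
    for (uword k = 0; k < n; ++k) rp[k] -= tstar * ap[k];
    dx = X.row(newrow) - XB.row(ii);
    XB.row(ii) = X.row(newrow);
    basis(ii) = newrow;
    u = XBinv.col(ii);
    vt = dx * XBinv;
    double denom = 1.0 + vt(ii);
    if (std::abs(denom) < 1e-10 || ++moves_since_refactor >= 50) {
      if (!inv(XBinv, XB)) return false;
      moves_since_refactor = 0;
      bcur = XBinv * y.elem(basis);
      r = y - X * bcur;
      rp = r.memptr();
    } else {
      // XBinv -= u vt / denom, without temporaries
      double* Bp = XBinv.memptr();
      const double* up = u.memptr();
      for (uword j = 0; j < p; ++j) {
        double c = vt(j) / denom;
        if (c == 0.0) continue;
        double* col = Bp + j * p;
        for (uword i2 = 0; i2 < p; ++i2) col[i2] -= c * up[i2];
      }
      rp[newrow] = 0.0;  // exact interpolation of the new basis row
    }
    fails = 0;
    ii = (ii + 1) % p;
  }
  // canonical solve at the final vertex (removes incremental drift)
  return solve(beta, XB, y.elem(basis));
}

static bool lad_fit_once(const mat& X, const vec& y, const vec& beta0,
                         vec& beta, uvec& basis, int& iters, int maxit,
                         std::vector<std::pair<double, uword>>& buf) {
  if (!init_basis(X, y, beta0, basis, buf)) return false;
  return lad_descend(X, y, basis, beta, maxit, iters, buf);
}

// Single IRLS pass for a warm start when no coefficient guess exists.
static vec irls_start(const mat& X, const vec& y) {
  vec beta;
  if (!solve(beta, X, y)) beta = zeros<vec>(X.n_cols);
  for (int it = 0; it < 15; ++it) {
    vec r = y - X * beta;
    vec w = 1.0 / clamp(abs(r), 1e-8, datum::inf);
    mat Xw = X.each_col() % sqrt(w);
    vec yw = y % sqrt(w);
    vec bn;
    if (!solve(bn, Xw, yw)) break;
    beta = bn;
  }
  return beta;
}

// [[Rcpp::export]]
Rcpp::List lad_solve_cpp(const arma::mat& X, const arma::vec& y,
                         int maxit = 10000) {
  vec beta0 = irls_start(X, y);
  vec beta;
  uvec basis;
  int iters = 0;
  std::vector<std::pair<double, uword>> buf;
  buf.reserve(X.n_rows);
  if (!lad_fit_once(X, y, beta0, beta, basis, iters, maxit, buf)) {
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  }
  return Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("coefficients") = beta,
    Rcpp::Named("objective") = lad_objective(X, y, beta),
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("basis") = Rcpp::IntegerVector(basis.begin(), basis.end())
  );
}

// Complete a partially filled basis (first `got` entries span their
// rows independently) with small-|residual| rows, Gram-Schmidt style.
static bool complete_basis(const mat& X, const vec& y, const vec& beta0,
                           uvec& basis, uword got,
                           std::vector<std::pair<double, uword>>& buf) {
  const uword n = X.n_rows, p = X.n_cols;
  if (got == p) return true;
  mat Q(p, p);
  uword span = 0;
  for (uword j = 0; j < got; ++j) {
    rowvec v = X.row(basis(j));
    for (uword i2 = 0; i2 < span; ++i2) v -= dot(v, Q.row(i2)) * Q.row(i2);
    double nrm = norm(v);
    if (nrm > 1e-10) { Q.row(span) = v / nrm; ++span; }
  }
  got = span;  // drop dependent transfers
  vec r = y - X * beta0;
  buf.clear();
  for (uword k = 0; k < n; ++k) buf.emplace_back(std::abs(r(k)), k);
  uword pool = std::min<uword>(n, 4 * p + 8);
  std::nth_element(buf.begin(), buf.begin() + (pool - 1), buf.end());
  std::sort(buf.begin(), buf.begin() + pool);
  for (uword k = 0; k < n && got < p; ++k) {
    if (k == pool) std::sort(buf.begin() + pool, buf.end());
    rowvec v = X.row(buf[k].second);
    double nrm0 = norm(v);
    if (nrm0 <= 1e-12) continue;
    for (uword j = 0; j < got; ++j) v -= dot(v, Q.row(j)) * Q.row(j);
    double nrm = norm(v);
    if (nrm > 1e-9 * nrm0) {
      Q.row(got) = v / nrm;
      basis(got) = buf[k].second;
      ++got;
    }
  }
  return got == p;
}

// Case-resampling bootstrap of the LAD fit. Replicates are warm-started
// from the full-data fit: basis rows that survive into the resample
// seed the replicate's starting basis, the remainder is filled from
// smallest residuals under the full-data coefficients. RNG is a
// private mt19937 stream so replicate draws are reproducible per seed
// and independent of R's RNG state (hence invariant to scan order).
// [[Rcpp::export]]
Rcpp::List lad_boot_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::vec& beta_full,
                        const arma::uvec& basis_full, int B,
                        unsigned int seed, int maxit = 10000) {
  const uword n = X.n_rows, p = X.n_cols;
  std::mt19937 rng(seed);
  std::uniform_int_distribution<uword> pick(0, n - 1);
  mat coefs(B, p);
  int dropped = 0;
  uvec idx(n);
  mat Xb(n, p);
  vec yb(n);
  std::vector<std::pair<double, uword>> buf;
  buf.reserve(n);
  std::vector<int> in_basis(n, -1);  // source row -> slot in basis_full
  for (uword j = 0; j < basis_full.n_elem && j < p; ++j) {
    in_basis[basis_full(j)] = (int) j;
  }
  std::vector<char> used(p);
  uvec basis(p);
  for (int b = 0; b < B; ++b) {
    for (uword k = 0; k < n; ++k) idx(k) = pick(rng);
    Xb = X.rows(idx);
    yb = y.elem(idx);
    // transfer surviving full-fit basis rows
    std::fill(used.begin(), used.end(), 0);
    uword got = 0;
    for (uword k = 0; k < n && got < p; ++k) {
      int slot = in_basis[idx(k)];
      if (slot >= 0 && !used[slot]) {
        used[slot] = 1;
        basis(got++) = k;
      }
    }
    vec beta;
    int iters = 0;
    bool ok = complete_basis(Xb, yb, beta_full, basis, got, buf) &&
      lad_descend(Xb, yb, basis, beta, maxit, iters, buf);
    if (!ok) {
      ++dropped;
      coefs.row(b).fill(datum::nan);
    } else {
      coefs.row(b) = beta.t();
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("coefficients") = coefs,
    Rcpp::Named("dropped") = dropped
  );
}
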