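// Minimum-volume enclosing ellipsoid (Lowner-John) solver.
//
// Khachiyan's barycentric coordinate ascent on the lifted determinant
// maximization, accelerated with Wolfe-Atwood away/drop steps (same fixed
// point and approximation guarantee, much faster convergence in practice)
// and an active-set outer loop so that repeated MVEEs of large point sets
// stay cheap: the optimal ellipsoid touches at most d(d+3)/2 points, so the
// solver works on a small core set and only re-solves when outside points
// violate containment.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct KhaResult {
  vec center;   // in the (possibly projected) coordinates
  mat sigma;    // scatter matrix P' diag(u) P - c c'
  vec u;
  int iterations;
  double err;
};

// Core ascent on full-rank point sets (rows of P are points, r columns).
// u0 (optional) warm-starts the barycentric weights.
KhaResult khachiyan_core(const mat& P, double tol, int max_iter,
                         const vec& u0 = vec()) {
  const uword n = P.n_rows, r = P.n_cols;
  const double dp1 = static_cast<double>(r) + 1.0;

  mat Q(n, r + 1);
  Q.cols(0, r - 1) = P;
  Q.col(r).ones();

  vec u;
  if (u0.n_elem == n && u0.min() >= 0.0 && u0.max() > 0.0) {
    u = u0 / accu(u0);
  } else {
    u.set_size(n);
    u.fill(1.0 / static_cast<double>(n));
  }
  mat X = Q.t() * diagmat(u) * Q;
  // ridge keeps the lifted scatter invertible through early iterations
  double ridge = 1e-12 * trace(X) / dp1;
  mat Xinv = inv_sympd(symmatu(X) + ridge * eye(r + 1, r + 1));
  vec M = sum((Q * Xinv) % Q, 1);

  double err = datum::inf;
  int it = 0;
  for (; it < max_iter; ++it) {
    uword jp = M.index_max();
    double up_viol = M(jp) / dp1 - 1.0;

    // worst "away" candidate among support points
    uword jm = jp;
    double down_viol = -datum::inf;
    for (uword i = 0; i < n; ++i) {
      if (u(i) > 1e-14) {
        double v = 1.0 - M(i) / dp1;
        if (v > down_viol) { down_viol = v; jm = i; }
      }
    }
    err = std::max(up_viol, down_viol);
    if (err < tol) break;

    uword j;
    double lam;
    if (up_viol >= down_viol) {
      j = jp;
      lam = (M(j) - dp1) / (dp1 * (M(j) - 1.0));
    } else {
      j = jm;
      double lam_min = -u(j) / (1.0 - u(j));  // drop-step bound
      if (M(j) > 1.0 + 1e-12) {
        lam = (M(j) - dp1) / (dp1 * (M(j) - 1.0));  // negative
        if (lam < lam_min) lam = lam_min;
      } else {
        lam = lam_min;  // interior point: drop its weight entirely
      }
    }
    if (!std::isfinite(lam) || lam == 0.0) break;

    // u' = (1 - lam) u + lam e_j ; rank-one update of Xinv and M
    vec q = Q.row(j).t();
    vec w = Xinv * q;
    double denom = (1.0 - lam) + lam * M(j);
    if (denom <= 0.0) break;
    vec g = Q * w;
    M = M / (1.0 - lam) - (lam / ((1.0 - lam) * denom)) * square(g);
    Xinv = Xinv / (1.0 - lam) - (lam / ((1.0 - lam) * denom)) * (w * w.t());
    u *= (1.0 - lam);
    u(j) += lam;
  }

  KhaResult res;
  res.u = u;
  res.center = P.t() * u;
  mat S = P.t() * diagmat(u) * P - res.center * res.center.t();
  res.sigma = symmatu(S);
  res.iterations = it;
  res.err = err;
  return res;
}

// Shape matrix from scatter with eigenvalue flooring for rank deficiency:
// a floored direction gets semi-axis eps_reg.
mat shape_from_sigma(const mat& sigma, uword d_eff, double eps_reg) {
  vec eval;
  mat evec;
  eig_sym(eval, evec, symmatu(sigma));
  const double d = std::max<double>(d_eff, 1);
  vec inv_ax(eval.n_elem);
  double floor_lam = eps_reg * eps_reg / d;
  for (uword i = 0; i < eval.n_elem; ++i) {
    double lam = std::max(eval(i), floor_lam);
    inv_ax(i) = 1.0 / (d * lam);  // A = Sigma^{-1}/d
  }
  return evec * diagmat(inv_ax) * evec.t();
}

double mean_pairwise_dist(const mat& P) {
  uword n = P.n_rows;
  uword m = std::min<uword>(n, 256);  // subsample for large sets
  double s = 0.0;
  uword cnt = 0;
  uword stride = std::max<uword>(1, n / m);
  for (uword i = 0; i < n; i += stride)
    for (uword j = i + stride; j < n; j += stride) {
      s += norm(P.row(i) - P.row(j), 2);
      ++cnt;
    }
  return cnt ? s / cnt : 0.0;
}

vec memberships(const mat& P, const vec& c, const mat& A) {
  mat D = P.each_row() - c.t();
  return sum((D * A) % D, 1);
}

// Solve MVEE for an arbitrary (possibly affinely degenerate) point set.
Rcpp::List mvee_solve(const mat& P, double tol, int max_iter) {
  const uword n = P.n_rows, d = P.n_cols;
  double mpd = mean_pairwise_dist(P);
  // absolute floor keeps the shape matrix numerically invertible when the
  // point cloud itself is nearly coincident
  double eps_reg = std::max(1e-6 * (mpd > 0 ? mpd : 1.0), 1e-9);

  vec centroid = mean(P, 0).t();
  mat B = P.each_row() - centroid.t();

  // full d x d eigenbasis of the scatter (svd_econ would drop null-space
  // directions when n < d, leaving the regularized shape rank deficient)
  vec ev2;
  mat V;
  eig_sym(ev2, V, symmatu(B.t() * B));
  V = fliplr(V);           // descending variance order
  ev2 = reverse(ev2);
  vec s = sqrt(clamp(ev2, 0.0, datum::inf));
  double smax = s.n_elem ? s.max() : 0.0;
  uword rank = 0;
  for (uword i = 0; i < s.n_elem; ++i)
    if (s(i) > smax * 1e-9 && s(i) > 0) ++rank;

  vec center(d);
  mat A(d, d);
  int iterations = 0;
  double err = 0.0;

  if (rank == 0) {
    // all points coincide: tiny ball of radius eps_reg
    center = centroid;
    A = eye(d, d) / (eps_reg * eps_reg);
  } else if (rank == d) {
    KhaResult k = khachiyan_core(P, tol, max_iter);
    center = k.center;
    A = shape_from_sigma(k.sigma, d, eps_reg);
    iterations = k.iterations;
    err = k.err;
  } else {
    // degenerate: solve in the affine span, floor the null directions
    mat Vr = V.cols(0, rank - 1);
    mat Z = B * Vr;  // n x rank
    KhaResult k = khachiyan_core(Z, tol, max_iter);
    center = centroid + Vr * k.center;
    mat Ar = shape_from_sigma(k.sigma, rank, eps_reg);
    mat Afull = Vr * Ar * Vr.t();
    // null-space directions: semi-axis eps_reg
    mat Vn = V.cols(rank, V.n_cols - 1);
    Afull += Vn * Vn.t() / (eps_reg * eps_reg);
    A = symmatu(Afull);
    iterations = k.iterations;
    err = k.err;
  }

  // guarantee containment: inflate to the worst membership
  vec m = memberships(P, center, A);
  double mx = m.max();
  if (mx > 1.0) A /= mx;

  return Rcpp::List::create(
      Rcpp::Named("center") = center,
      Rcpp::Named("shape") = A,
      Rcpp::Named("iterations") = iterations,
      Rcpp::Named("err") = err);
}

// full-rank fast path used by the warm-started active-set loop
Rcpp::List mvee_fullrank(const mat& P, double tol, int max_iter,
                         const vec& u0, vec& u_out, double eps_reg) {
  KhaResult k = khachiyan_core(P, tol, max_iter, u0);
  u_out = k.u;
  vec center = k.center;
  mat A = shape_from_sigma(k.sigma, P.n_cols, eps_reg);
  vec m = memberships(P, center, A);
  double mx = m.max();
  if (mx > 1.0) A /= mx;
  return Rcpp::List::create(
      Rcpp::Named("center") = center, Rcpp::Named("shape") = A,
      Rcpp::Named("iterations") = k.iterations, Rcpp::Named("err") = k.err);
}

}  // namespace

// [[Rcpp::export(name = ".mvee_cpp")]]
Rcpp::List mvee_cpp(const arma::mat& P, double tol, int max_iter) {
  const uword n = P.n_rows;
  const uword d = P.n_cols;
  if (n < 2) Rcpp::stop("mvee needs at least 2 points");

  const uword n_direct = 600;
  if (n <= n_direct) return mvee_solve(P, tol, max_iter);

  // active-set outer loop: coordinate extremes seed the core set
  std::vector<uword> idx;
  idx.reserve(4 * d + 64);
  for (uword j = 0; j < d; ++j) {
    idx.push_back(P.col(j).index_min());
    idx.push_back(P.col(j).index_max());
  }
  // distance-to-centroid extremes help round shapes
  vec centroid = mean(P, 0).t();
  vec dist = sum(square(P.each_row() - centroid.t()), 1);
  uvec ord = sort_index(dist, "descend");
  for (uword i = 0; i < std::min<uword>(2 * d, n); ++i) idx.push_back(ord(i));
  std::sort(idx.begin(), idx.end());
  idx.erase(std::unique(idx.begin(), idx.end()), idx.end());

  uvec active = conv_to<uvec>::from(idx);
  Rcpp::List fit;
  vec u;  // warm-started weights aligned with `active`
  double eps_reg = std::max(1e-6 * mean_pairwise_dist(P), 1e-9);
  bool warm = false;
  for (int outer = 0; outer < 60; ++outer) {
    mat Psub = P.rows(active);
    if (warm) {
      vec u_out;
      fit = mvee_fullrank(Psub, tol, max_iter, u, u_out, eps_reg);
      u = u_out;
    } else {
      fit = mvee_solve(Psub, tol, max_iter);
      // a subset spanning all d directions lets later rounds warm-start
      mat A0 = Rcpp::as<mat>(fit["shape"]);
      vec ev = eig_sym(symmatu(A0));
      if (ev.min() > 0 && ev.max() / ev.min() < 1e10) {
        warm = true;
        u.set_size(active.n_elem);
        u.fill(1.0 / active.n_elem);
      }
    }
    vec c = Rcpp::as<vec>(fit["center"]);
    mat A = Rcpp::as<mat>(fit["shape"]);
    vec m = memberships(P, c, A);
    uvec viol = find(m > 1.0 + 10.0 * tol);
    if (viol.n_elem == 0) break;
    // add the worst violators to the active set, giving them real weight
    vec mv = m(viol);
    uvec vord = sort_index(mv, "descend");
    uword n_add = std::min<uword>(viol.n_elem, 64);
    uvec add = viol(vord.head(n_add));
    uvec active2 = join_cols(active, add);
    if (warm) {
      double w = 0.25;
      vec u2(active2.n_elem);
      u2.head(active.n_elem) = u * (1.0 - w);
      u2.tail(add.n_elem).fill(w / add.n_elem);
      u = u2;
    }
    active = active2;
  }
  // final safeguard: inflate to contain every point
  vec c = Rcpp::as<vec>(fit["center"]);
  mat A = Rcpp::as<mat>(fit["shape"]);
  vec m = memberships(P, c, A);
  double mx = m.max();
  if (mx > 1.0) {
    A /= mx;
    fit["shape"] = A;
  }
  return fit;
}

// Batch quadratic-form membership (theta - c)' A (theta - c) for rows of P.
// [[Rcpp::export(name = ".ellipsoid_membership_cpp")]]
arma::vec ellipsoid_membership_cpp(const arma::mat& P, const arma::vec& center,
                                   const arma::mat& A) {
  return memberships(P, center, A);
}
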