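#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Scaled forward-backward over a whole dataset of trajectories.
//
// logB    : total_steps x K matrix of log emission densities (one row per
//           observed displacement, trajectories concatenated).
// tstart  : 0-based row index of the first step of each trajectory.
// tlen    : number of steps per trajectory (>= 1).
// span    : per-step frame span m (1 = consecutive frames, m > 1 spans a
//           gap of m-1 missing frames). The transition operator between
//           step i and step i+1 is A^(span[i]).
// Apow    : K x K x M cube; slice m-1 holds A^m.
// pi      : initial/stationary state distribution (length K).
//
// Returns total log-likelihood, per-step posteriors gamma, endpoint pairwise
// posteriors xi summed per span (K x K x M), and the summed first-step
// posteriors g1 (for diagnostics).
// [[Rcpp::export]]
Rcpp::List fb_cpp(const arma::mat& logB,
                  const arma::ivec& tstart,
                  const arma::ivec& tlen,
                  const arma::ivec& span,
                  const arma::cube& Apow,
                  const arma::vec& pi) {
  const int K = logB.n_cols;
  const int M = Apow.n_slices;
  const int ntraj = tstart.n_elem;

  mat gamma(logB.n_rows, K, fill::zeros);
  cube xi(K, K, M, fill::zeros);
  vec g1(K, fill::zeros);
  double loglik = 0.0;

  for (int t = 0; t < ntraj; ++t) {
    const int s0 = tstart[t];
    const int L = tlen[t];

    // shift emissions for numerical stability
    mat B(L, K);
    vec mx(L);
    for (int i = 0; i < L; ++i) {
      rowvec lb = logB.row(s0 + i);
      double m = lb.max();
      mx[i] = m;
      B.row(i) = exp(lb - m);
    }

    mat alpha(L, K), beta(L, K);
    vec c(L);

    rowvec a0 = pi.t() % B.row(0);
    c[0] = accu(a0);
    if (c[0] <= 0.0) Rcpp::stop("zero forward probability (trajectory %d)", t + 1);
    alpha.row(0) = a0 / c[0];

    for (int i = 1; i < L; ++i) {
      const mat& A = Apow.slice(span[s0 + i - 1] - 1);
      rowvec tmp = (alpha.row(i - 1) * A) % B.row(i);
      c[i] = accu(tmp);
      if (c[i] <= 0.0) Rcpp::stop("zero forward probability (trajectory %d)", t + 1);
      alpha.row(i) = tmp / c[i];
    }

    beta.row(L - 1).ones();
    for (int i = L - 2; i >= 0; --i) {
      const mat& A = Apow.slice(span[s0 + i] - 1);
      vec tmp = A * ((B.row(i + 1) % beta.row(i + 1)).t());
      beta.row(i) = tmp.t() / c[i + 1];
    }

    for (int i = 0; i < L; ++i) {
      rowvec g = alpha.row(i) % beta.row(i);
      g /= accu(g);
      gamma.row(s0 + i) = g;
    }
    g1 += gamma.row(s0).t();

    for (int i = 0; i < L - 1; ++i) {
      const int m = span[s0 + i] - 1;
      const mat& A = Apow.slice(m);
      mat x = (alpha.row(i).t() * (B.row(i + 1) % beta.row(i + 1))) % A / c[i + 1];
      xi.slice(m) += x;
    }

    loglik += accu(log(c)) + accu(mx);
  }

  return Rcpp::List::create(Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("xi") = xi,
                            Rcpp::Named("g1") = g1);
}

// Reflect a proposed point into a spherocylinder (axis along x, centered at
// the origin; cylindrical section length 2*halflen, cap/tube radius `radius`).
static inline void reflect_into(double* q, double halflen, double radius) {
  for (int rep = 0; rep < 4; ++rep) {
    double cx = q[0];
    if (cx > halflen) cx = halflen;
    if (cx < -halflen) cx = -halflen;
    double dx = q[0] - cx, dy = q[1], dz = q[2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d <= radius) return;
    double dnew = 2.0 * radius - d;   // mirror across the surface
    if (dnew < 0.0) dnew = 0.5 * radius;  // pathological large step: recenter
    double f = dnew / d;
    q[0] = cx + dx * f;
    q[1] = dy * f;
    q[2] = dz * f;
  }
  // still outside after repeated reflection: clamp just inside
  double cx = q[0];
  if (cx > halflen) cx = halflen;
  if (cx < -halflen) cx = -halflen;
  double dx = q[0] - cx, dy = q[1], dz = q[2];
  double d = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (d > radius) {
    double f = 0.999 * radius / d;
    q[0] = cx + dx * f;
    q[1] = dy * f;
    q[2] = dz * f;
  }
}

// Propagate confined Brownian motion along a sub-step grid.
//
// step_sd : per-sub-step per-dimension displacement standard deviation,
//           sqrt(2 * D(state at sub-step) * dt_sub).
// halflen : half-length of the cylindrical section, (L - w) / 2.
// radius  : cell radius, w / 2.
// start   : 3D start point (inside the spherocylinder, cell frame).
//
// Returns an (n+1) x 3 matrix of positions at sub-step boundaries. Uses R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
arma::mat propagate_cpp(const arma::vec& step_sd,
                        double halflen,
                        double radius,
                        const arma::vec& start) {
  const int n = step_sd.n_elem;
  mat path(n + 1, 3);
  double p[3] = {start[0], start[1], start[2]};
  path(0, 0) = p[0]; path(0, 1) = p[1]; path(0, 2) = p[2];
  for (int i = 0; i < n; ++i) {
    double q[3];
    const double s = step_sd[i];
    q[0] = p[0] + s * norm_rand();
    q[1] = p[1] + s * norm_rand();
    q[2] = p[2] + s * norm_rand();
    reflect_into(q, halflen, radius);
    p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
    path(i + 1, 0) = p[0]; path(i + 1, 1) = p[1]; path(i + 1, 2) = p[2];
  }
  return path;
}
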