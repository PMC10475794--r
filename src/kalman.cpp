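// Exact discretization of continuous-time linear SDEs, Kalman filtering /
// smoothing with missing data, and a specialized fast likelihood for the
// 2-D glucose model (meal impulse responses + circadian baseline).
#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Van Loan matrix-fraction discretization:
//   F = expm(W*dt),  Sigma = int_0^dt expm(W s) Q expm(W' s) ds
// via expm of the 2d x 2d block [[-W, Q], [0, W']] * dt.
// [[Rcpp::export]]
List cpp_discretize(const arma::mat& W, const arma::mat& Q, double dt) {
  const arma::uword d = W.n_rows;
  arma::mat M(2 * d, 2 * d, arma::fill::zeros);
  M.submat(0, 0, d - 1, d - 1) = -W;
  M.submat(0, d, d - 1, 2 * d - 1) = Q;
  M.submat(d, d, 2 * d - 1, 2 * d - 1) = W.t();
  arma::mat E = arma::expmat(M * dt);
  arma::mat F = E.submat(d, d, 2 * d - 1, 2 * d - 1).t();
  arma::mat S = F * E.submat(0, d, d - 1, 2 * d - 1);
  S = 0.5 * (S + S.t());
  if (!F.is_finite() || !S.is_finite())
    stop("discretization produced non-finite entries");
  return List::create(_["F"] = F, _["Sigma"] = S);
}

// Stationary covariance: solve W S + S W' + Q = 0 (requires stable W).
// [[Rcpp::export]]
arma::mat cpp_stationary_cov(const arma::mat& W, const arma::mat& Q) {
  const arma::uword d = W.n_rows;
  arma::mat I = arma::eye(d, d);
  arma::mat A = arma::kron(I, W) + arma::kron(W, I);
  arma::vec q = arma::vectorise(Q);
  arma::vec s;
  if (!arma::solve(s, A, -q, arma::solve_opts::no_approx))
    stop("Lyapunov system singular; W may be (near-)unstable");
  arma::mat S = arma::reshape(s, d, d);
  return 0.5 * (S + S.t());
}

// General missing-data Kalman filter (+ optional RTS smoother).
// F, S: cubes with 1 slice (time-invariant step) or T-1 slices
//       (slice k propagates state from observation k to k+1, 0-based).
// H: c x d; m: T x c offsets; R: c x c; y: T x c with NaN = missing.
// x0m/x0P: state distribution at the first observation time.
// [[Rcpp::export]]
List cpp_kf(const arma::cube& F, const arma::cube& S, const arma::mat& H,
            const arma::mat& m, const arma::mat& R, const arma::mat& y,
            const arma::vec& x0m, const arma::mat& x0P,
            bool keep, bool smooth) {
  const arma::uword T = y.n_rows, d = x0m.n_elem;
  const bool tv = F.n_slices > 1;
  const double LOG2PI = std::log(2.0 * M_PI);

  arma::vec x = x0m;
  arma::mat P = x0P;
  double ll = 0.0;
  arma::vec step_ll(T, arma::fill::zeros);

  arma::mat xp, xf;
  arma::cube Pp, Pf;
  if (keep || smooth) {
    xp.set_size(d, T); xf.set_size(d, T);
    Pp.set_size(d, d, T); Pf.set_size(d, d, T);
  }

  for (arma::uword k = 0; k < T; ++k) {
    if (k > 0) {
      const arma::mat& Fk = F.slice(tv ? k - 1 : 0);
      const arma::mat& Sk = S.slice(tv ? k - 1 : 0);
      x = Fk * x;
      P = Fk * P * Fk.t() + Sk;
      P = 0.5 * (P + P.t());
    }
    if (keep || smooth) { xp.col(k) = x; Pp.slice(k) = P; }

    arma::vec yk = y.row(k).t();
    arma::uvec idx = arma::find_finite(yk);
    if (idx.n_elem > 0) {
      arma::mat Hs = H.rows(idx);
      arma::vec mk = m.row(k).t();
      arma::vec v = yk(idx) - Hs * x - mk(idx);
      arma::mat Sm = Hs * P * Hs.t() + R.submat(idx, idx);
      Sm = 0.5 * (Sm + Sm.t());
      arma::mat L;
      if (!arma::chol(L, Sm, "lower"))
        stop("innovation covariance not positive definite at step %d "
             "(min diag %g); check R/Q conditioning", (int)(k + 1),
             Sm.diag().min());
      arma::vec a;
      if (!arma::solve(a, arma::trimatl(L), v, arma::solve_opts::no_approx))
        stop("innovation system singular at step %d", (int)(k + 1));
      double lk = -0.5 * idx.n_elem * LOG2PI -
                  arma::sum(arma::log(L.diag())) - 0.5 * arma::dot(a, a);
      step_ll(k) = lk;
      ll += lk;
      arma::mat K = P * Hs.t() * arma::inv_sympd(Sm);
      x += K * v;
      arma::mat IKH = arma::eye(d, d) - K * Hs;
      P = IKH * P * IKH.t() + K * R.submat(idx, idx) * K.t();  // Joseph form
      P = 0.5 * (P + P.t());
    }
    if (keep || smooth) { xf.col(k) = x; Pf.slice(k) = P; }
  }

  List out = List::create(_["loglik"] = ll, _["step_loglik"] = step_ll);
  if (keep || smooth) {
    out["pred_mean"] = xp.t();  out["filt_mean"] = xf.t();
    out["pred_cov"] = Pp;       out["filt_cov"] = Pf;
  }
  if (smooth) {
    arma::mat xs = xf;
    arma::cube Ps = Pf;
    for (arma::uword k = T - 1; k-- > 0; ) {
      const arma::mat& Fk = F.slice(tv ? k : 0);
      arma::mat J;
      if (!arma::solve(J, Pp.slice(k + 1), Fk * Pf.slice(k),
                       arma::solve_opts::likely_sympd +
                       arma::solve_opts::no_approx))
        stop("smoother gain system singular at step %d", (int)(k + 1));
      J = J.t();
      xs.col(k) = xf.col(k) + J * (xs.col(k + 1) - xp.col(k + 1));
      Ps.slice(k) = Pf.slice(k) +
        J * (Ps.slice(k + 1) - Pp.slice(k + 1)) * J.t();
      Ps.slice(k) = 0.5 * (Ps.slice(k) + Ps.slice(k).t());
    }
    out["smooth_mean"] = xs.t();
    out["smooth_cov"] = Ps;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Specialized glucose model (Model 1): 2-D drift W = [-A11 -A12; A21 -A22],
// Q = diag(0, B22), observation y = x2 + r(t) + g(t) + N(0, sigma^2).
// The meal response shape is the (2,1) entry of expm(W s):
//   f(s) = A21 * exp(h s) * phi(s),  h = tr(W)/2,  D = tr^2/4 - det
//   phi(s) = sinh(mu s)/mu (D>0), sin(nu s)/nu (D<0), s (D ~ 0)
// normalized to unit peak and scaled by the per-label height.
// ---------------------------------------------------------------------------

struct Glu2 {
  double A11, A12, A21, A22;  // rates
  double h, D;                // tr/2, discriminant/4

  Glu2(double a11, double a12, double a21, double a22)
      : A11(a11), A12(a12), A21(a21), A22(a22) {
    double tr = -(A11 + A22);
    double det = A11 * A22 + A12 * A21;
    h = tr / 2.0;
    D = tr * tr / 4.0 - det;
  }
  // e^{h s} sinh(mu s)/mu and e^{h s} cosh(mu s) computed through
  // e^{(h +/- mu) s} so that stiff systems (mu ~ |h|) cannot overflow;
  // h +/- mu <= 0 for any stable W with positive rates
  inline double ephi(double s) const {
    double z = D * s * s;
    if (std::abs(z) < 1e-8)
      return std::exp(h * s) * s * (1.0 + z / 6.0 + z * z / 120.0);
    if (D > 0) {
      double mu = std::sqrt(D);
      return (std::exp((h + mu) * s) - std::exp((h - mu) * s)) / (2 * mu);
    }
    double nu = std::sqrt(-D);
    return std::exp(h * s) * std::sin(nu * s) / nu;
  }
  inline double ech(double s) const {
    double z = D * s * s;
    if (std::abs(z) < 1e-8)
      return std::exp(h * s) * (1.0 + z / 2.0 + z * z / 24.0);
    if (D > 0) {
      double mu = std::sqrt(D);
      return (std::exp((h + mu) * s) + std::exp((h - mu) * s)) / 2;
    }
    return std::exp(h * s) * std::cos(std::sqrt(-D) * s);
  }
  inline double f(double s) const {  // impulse response, glucose channel
    return A21 * ephi(s);
  }
  // expm(W s) = e^{h s} [cosh(mu s) I + sinh(mu s)/mu (W - h I)]
  void expm(double s, double Fm[2][2]) const {
    double c = ech(s), p = ephi(s);
    Fm[0][0] = c + p * (-A11 - h);
    Fm[0][1] = p * (-A12);
    Fm[1][0] = p * (A21);
    Fm[1][1] = c + p * (-A22 - h);
  }
};

// peak of the impulse response over s > 0 (coarse grid + golden refinement)
static void glu2_peak(const Glu2& g, double& s_peak, double& f_peak) {
  // for complex eigenvalues the response is positive only on the first
  // lobe s in (0, pi/nu); restrict the search there
  double s_hi = 72.0;
  if (g.D < 0) s_hi = std::min(s_hi, M_PI / std::sqrt(-g.D));
  const int n = 720;
  double best_s = s_hi / n, best_f = g.f(best_s);
  for (int i = 2; i <= n; ++i) {
    double s = s_hi * i / n, v = g.f(s);
    if (v > best_f) { best_f = v; best_s = s; }
  }
  double lo = std::max(1e-9, best_s - s_hi / n);
  double hi = std::min(s_hi, best_s + s_hi / n);
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double a = lo, b = hi, c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = g.f(c), fd = g.f(d);
  for (int it = 0; it < 80; ++it) {
    if (fc > fd) { b = d; d = c; fd = fc; c = b - gr * (b - a); fc = g.f(c); }
    else         { a = c; c = d; fc = fd; d = a + gr * (b - a); fd = g.f(d); }
  }
  s_peak = 0.5 * (a + b);
  f_peak = g.f(s_peak);
}

// [[Rcpp::export]]
arma::vec cpp_impulse2(double A11, double A12, double A21, double A22,
                       const arma::vec& s) {
  Glu2 g(A11, A12, A21, A22);
  arma::vec out(s.n_elem);
  for (arma::uword i = 0; i < s.n_elem; ++i)
    out(i) = s(i) <= 0.0 ? 0.0 : g.f(s(i));
  return out;
}

// [[Rcpp::export]]
List cpp_impulse2_peak(double A11, double A12, double A21, double A22) {
  Glu2 g(A11, A12, A21, A22);
  double sp, fp;
  glu2_peak(g, sp, fp);
  return List::create(_["s_peak"] = sp, _["f_peak"] = fp);
}

// r(t) + g(t) observation mean on a time grid. heights: one per label;
// meallab: 1-based label index per event.
static arma::vec model1_mean_core(const Glu2& g, double A0, double A1,
                                  double phi_h, bool circadian,
                                  const arma::vec& heights,
                                  const arma::vec& times,
                                  const arma::vec& mealt,
                                  const arma::ivec& meallab,
                                  double sp, double fp) {
  const double w = 2.0 * M_PI / 24.0;
  double lammax = g.h + (g.D > 0 ? std::sqrt(g.D) : 0.0);
  double s_cut = std::min(336.0, sp + std::log(1e10) / (-lammax));
  const arma::uword T = times.n_elem, M = mealt.n_elem;
  arma::vec m(T);
  arma::uword lo = 0;
  for (arma::uword k = 0; k < T; ++k) {
    double t = times(k);
    double mk = A0;
    if (circadian) mk += A1 * (1.0 + std::cos(w * t - w * phi_h)) / 2.0;
    while (lo < M && t - mealt(lo) > s_cut) ++lo;
    for (arma::uword j = lo; j < M && mealt(j) < t; ++j)
      mk += heights(meallab(j) - 1) * g.f(t - mealt(j)) / fp;
    m(k) = mk;
  }
  return m;
}

// [[Rcpp::export]]
arma::vec cpp_model1_mean(const arma::vec& par, const arma::vec& heights,
                          const arma::vec& times, const arma::vec& mealt,
                          const arma::ivec& meallab, bool circadian) {
  // par = (A11, A12, A21, A22, B22, sigma, A0, A1, phi) natural scale
  Glu2 g(par(0), par(1), par(2), par(3));
  double sp, fp;
  glu2_peak(g, sp, fp);
  if (!(fp > 0.0)) stop("degenerate meal-response shape (non-positive peak)");
  return model1_mean_core(g, par(6), par(7), par(8), circadian, heights,
                          times, mealt, meallab, sp, fp);
}

static double model1_ll_natural(const arma::vec& par, const arma::vec& heights,
                                const arma::vec& times, const arma::vec& y,
                                const arma::ivec& obs, const arma::vec& mealt,
                                const arma::ivec& meallab, bool circadian) {
  const double A11 = par(0), A12 = par(1), A21 = par(2), A22 = par(3);
  const double B22 = par(4), sig2 = par(5) * par(5);
  Glu2 g(A11, A12, A21, A22);
  if (g.h >= 0.0) return -arma::datum::inf;  // unstable
  double sp, fp;
  glu2_peak(g, sp, fp);
  if (!(fp > 0.0) || !std::isfinite(fp)) return -arma::datum::inf;
  arma::vec m = model1_mean_core(g, par(6), par(7), par(8), circadian,
                                 heights, times, mealt, meallab, sp, fp);
  if (!m.is_finite()) return -arma::datum::inf;

  // stationary covariance of (W, diag(0, B22)):
  //  2(w11 s11 + w12 s12) = 0
  //  w21 s11 + (w11 + w22) s12 + w12 s22 = 0
  //  2(w21 s12 + w22 s22) = -B22
  const double w11 = -A11, w12 = -A12, w21 = A21, w22 = -A22;
  arma::mat33 Amat = {{2 * w11, 2 * w12, 0.0},
                      {w21, w11 + w22, w12},
                      {0.0, 2 * w21, 2 * w22}};
  arma::vec3 bvec = {0.0, 0.0, -B22};
  arma::vec3 sv;
  if (!arma::solve(sv, Amat, bvec, arma::solve_opts::no_approx))
    return -arma::datum::inf;
  double S11 = sv(0), S12 = sv(1), S22 = sv(2);

  // discretization cache: Sigma(dt) = S_inf - F S_inf F'
  struct Step { double F[2][2]; double Q11, Q12, Q22; };
  std::map<long long, Step> cache;
  auto get_step = [&](double dt) -> const Step& {
    long long key = llround(dt * 3.6e6);
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    Step st;
    g.expm(dt, st.F);
    double a = st.F[0][0], b = st.F[0][1], c = st.F[1][0], d = st.F[1][1];
    // F S F'
    double t11 = a * (a * S11 + b * S12) + b * (a * S12 + b * S22);
    double t12 = c * (a * S11 + b * S12) + d * (a * S12 + b * S22);
    double t22 = c * (c * S11 + d * S12) + d * (c * S12 + d * S22);
    st.Q11 = S11 - t11; st.Q12 = S12 - t12; st.Q22 = S22 - t22;
    return cache.emplace(key, st).first->second;
  };

  const double LOG2PI = std::log(2.0 * M_PI);
  double x1 = 0.0, x2 = 0.0, P11 = S11, P12 = S12, P22 = S22;
  double ll = 0.0;
  const arma::uword T = times.n_elem;
  for (arma::uword k = 0; k < T; ++k) {
    if (k > 0) {
      const Step& st = get_step(times(k) - times(k - 1));
      const double a = st.F[0][0], b = st.F[0][1], c = st.F[1][0],
                   d = st.F[1][1];
      double nx1 = a * x1 + b * x2, nx2 = c * x1 + d * x2;
      double q11 = a * (a * P11 + b * P12) + b * (a * P12 + b * P22) + st.Q11;
      double q12 = c * (a * P11 + b * P12) + d * (a * P12 + b * P22) + st.Q12;
      double q22 = c * (c * P11 + d * P12) + d * (c * P12 + d * P22) + st.Q22;
      x1 = nx1; x2 = nx2; P11 = q11; P12 = q12; P22 = q22;
    }
    if (obs(k)) {
      double v = y(k) - x2 - m(k);
      double Svar = P22 + sig2;
      if (!(Svar > 0.0) || !std::isfinite(Svar)) return -arma::datum::inf;
      ll += -0.5 * (LOG2PI + std::log(Svar) + v * v / Svar);
      double K1 = P12 / Svar, K2 = P22 / Svar;
      x1 += K1 * v; x2 += K2 * v;
      double n11 = P11 - K1 * P12, n12 = P12 - K1 * P22,
             n22 = P22 - K2 * P22;
      P11 = n11; P12 = n12; P22 = n22;
    }
  }
  return std::isfinite(ll) ? ll : -arma::datum::inf;
}

// Unconstrained packing: with circadian
//   u = (lA11, lA12, lA21, lA22, lB22, lsigma, A0, lA1, phi, lh_1..lh_L)
// without: (lA11..lsigma, A0, lh_1..lh_L)
static double model1_ll_u(const arma::vec& u, arma::uword L,
                          const arma::vec& times, const arma::vec& y,
                          const arma::ivec& obs, const arma::vec& mealt,
                          const arma::ivec& meallab, bool circadian) {
  arma::vec par(9);
  for (int i = 0; i < 5; ++i) par(i) = std::exp(u(i));
  par(5) = std::exp(u(5));
  par(6) = u(6);
  arma::uword off;
  if (circadian) { par(7) = std::exp(u(7)); par(8) = u(8); off = 9; }
  else           { par(7) = 0.0; par(8) = 0.0; off = 7; }
  arma::vec heights(L);
  for (arma::uword j = 0; j < L; ++j) heights(j) = std::exp(u(off + j));
  return model1_ll_natural(par, heights, times, y, obs, mealt, meallab,
                           circadian);
}

// [[Rcpp::export]]
double cpp_model1_loglik_u(const arma::vec& u, int L, const arma::vec& times,
                           const arma::vec& y, const arma::ivec& obs,
                           const arma::vec& mealt, const arma::ivec& meallab,
                           bool circadian) {
  return model1_ll_u(u, (arma::uword)L, times, y, obs, mealt, meallab,
                     circadian);
}

// central finite-difference gradient on the unconstrained scale
// [[Rcpp::export]]
List cpp_model1_grad_u(const arma::vec& u, int L, const arma::vec& times,
                       const arma::vec& y, const arma::ivec& obs,
                       const arma::vec& mealt, const arma::ivec& meallab,
                       bool circadian) {
  double f0 = model1_ll_u(u, (arma::uword)L, times, y, obs, mealt, meallab,
                          circadian);
  arma::vec gr(u.n_elem);
  arma::vec up = u;
  for (arma::uword i = 0; i < u.n_elem; ++i) {
    double h = 1e-6 * std::max(1.0, std::abs(u(i)));
    up(i) = u(i) + h;
    double fp = model1_ll_u(up, (arma::uword)L, times, y, obs, mealt,
                            meallab, circadian);
    up(i) = u(i) - h;
    double fm = model1_ll_u(up, (arma::uword)L, times, y, obs, mealt,
                            meallab, circadian);
    up(i) = u(i);
    gr(i) = (fp - fm) / (2.0 * h);
  }
  return List::create(_["value"] = f0, _["grad"] = gr);
}
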