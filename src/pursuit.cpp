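#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Guidance law codes shared with R/guidance-core.R:
//   1 = PP, 2 = inertial-PN, 3 = background-PN, 4 = inertial-PNP, 5 = background-PNP

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// Forward-Euler, speed-matched pursuit simulation on a uniform dt grid.
//
// Arrays are indexed 0..M over the full window [0, t_end]; the simulation
// runs from index i0 (t_start = i0 * dt), initialised from the measured
// pursuer state at i0.  Delayed feedback terms (deviation angle delta and
// line-of-sight rate lambda-dot) at index j = n - dlag are read from the
// simulated history when j >= i0 and from the precomputed measured-state
// values (del_pre, lam_pre, indexed 0..i0-1) when j < i0.  j < 0 is clamped
// to 0 (only reachable when i0 == 0, i.e. generating truth from onset).
//
// Returns 0 on success, 1 on degenerate geometry (zero-length line-of-sight
// or zero pursuer speed).
static int run_sim(const double* tx, const double* ty,
                   const double* tvx, const double* tvy,
                   const double* sp, int M, int i0, double dt,
                   bool inertial, double N, double K, int dlag,
                   const double* del_pre, const double* lam_pre,
                   double* ox, double* oy, double* ovx, double* ovy,
                   double* del, double* lam, double* oturn,
                   double init_x, double init_y,
                   double init_vx, double init_vy) {
  ox[i0] = init_x;  oy[i0] = init_y;
  ovx[i0] = init_vx; ovy[i0] = init_vy;
  for (int n = i0; n <= M; ++n) {
    const double rx = tx[n] - ox[n], ry = ty[n] - oy[n];
    const double r2 = rx * rx + ry * ry;
    const double vx = ovx[n], vy = ovy[n];
    const double v2 = vx * vx + vy * vy;
    if (r2 <= 0.0 || v2 <= 0.0) return 1;
    del[n] = std::atan2(cross2(rx, ry, vx, vy), rx * vx + ry * vy);
    const double relx = inertial ? tvx[n] - vx : tvx[n];
    const double rely = inertial ? tvy[n] - vy : tvy[n];
    lam[n] = cross2(rx, ry, relx, rely) / r2;

    int j = n - dlag;
    double dj, lj;
    if (j < 0) j = 0;
    if (j >= i0) { dj = del[j]; lj = lam[j]; }
    else         { dj = del_pre[j]; lj = lam_pre[j]; }

    const double turn = N * lj - K * dj;  // commanded inertial turn rate
    oturn[n] = turn;
    if (n == M) break;

    // a = turn * R90(v), R90 = +90 deg (counterclockwise) rotation
    const double ax = -turn * vy, ay = turn * vx;
    ox[n + 1] = ox[n] + dt * vx;
    oy[n + 1] = oy[n] + dt * vy;
    double wx = vx + dt * ax, wy = vy + dt * ay;
    const double wmag = std::sqrt(wx * wx + wy * wy);
    if (wmag <= 0.0) return 1;
    const double s = sp[n];  // measured speed, index n as printed
    ovx[n + 1] = s * wx / wmag;
    ovy[n + 1] = s * wy / wmag;
  }
  return 0;
}

// Precompute delta / lambda-dot on the pre-start window [0, i0) from the
// measured pursuer states.  Throws on degenerate geometry in that window.
static void precompute_measured(const double* tx, const double* ty,
                                const double* tvx, const double* tvy,
                                const double* hx, const double* hy,
                                const double* hvx, const double* hvy,
                                int i0, bool inertial,
                                std::vector<double>& del_pre,
                                std::vector<double>& lam_pre) {
  del_pre.resize(std::max(i0, 1));
  lam_pre.resize(std::max(i0, 1));
  for (int j = 0; j < i0; ++j) {
    const double rx = tx[j] - hx[j], ry = ty[j] - hy[j];
    const double r2 = rx * rx + ry * ry;
    const double vx = hvx[j], vy = hvy[j];
    if (r2 <= 0.0 || vx * vx + vy * vy <= 0.0)
      stop("degenerate geometry in measured pre-start window (frame %d)", j + 1);
    del_pre[j] = std::atan2(cross2(rx, ry, vx, vy), rx * vx + ry * vy);
    const double relx = inertial ? tvx[j] - vx : tvx[j];
    const double rely = inertial ? tvy[j] - vy : tvy[j];
    lam_pre[j] = cross2(rx, ry, relx, rely) / r2;
  }
}

static void law_gains(int law, double N_in, double K_in, double& N, double& K,
                      bool& inertial) {
  inertial = (law == 2 || law == 4);
  N = (law == 1) ? 0.0 : N_in;                       // PP: N forced to 0
  K = (law == 2 || law == 3) ? 0.0 : K_in;           // PN: K forced to 0
}

// [[Rcpp::export]]
List pursuit_sim_cpp(NumericMatrix target, NumericMatrix hawk,
                     NumericVector speed, int i0, double dt, int law,
                     double N, double K, int dlag) {
  const int M = target.nrow() - 1;
  if (i0 < 0 || i0 > M) stop("i0 out of range");
  if (dlag < 0) stop("negative delay");
  if (dlag > i0 && i0 > 0) stop("delay exceeds pre-start window");
  double Nx, Kx; bool inertial;
  law_gains(law, N, K, Nx, Kx, inertial);

  const double* tx = &target(0, 0); const double* ty = &target(0, 1);
  const double* tvx = &target(0, 2); const double* tvy = &target(0, 3);
  const double* hx = &hawk(0, 0); const double* hy = &hawk(0, 1);
  const double* hvx = &hawk(0, 2); const double* hvy = &hawk(0, 3);

  std::vector<double> del_pre, lam_pre;
  precompute_measured(tx, ty, tvx, tvy, hx, hy, hvx, hvy, i0, inertial,
                      del_pre, lam_pre);

  std::vector<double> ox(M + 1), oy(M + 1), ovx(M + 1), ovy(M + 1),
      del(M + 1), lam(M + 1), oturn(M + 1);
  int rc = run_sim(tx, ty, tvx, tvy, REAL(speed), M, i0, dt, inertial, Nx, Kx,
                   dlag, del_pre.data(), lam_pre.data(), ox.data(), oy.data(),
                   ovx.data(), ovy.data(), del.data(), lam.data(),
                   oturn.data(), hx[i0], hy[i0], hvx[i0], hvy[i0]);
  if (rc != 0) stop("degenerate geometry during simulation");

  const int len = M - i0 + 1;
  NumericVector x(len), y(len), vx(len), vy(len), d(len), l(len), tr(len);
  for (int n = i0; n <= M; ++n) {
    const int k = n - i0;
    x[k] = ox[n]; y[k] = oy[n]; vx[k] = ovx[n]; vy[k] = ovy[n];
    d[k] = del[n]; l[k] = lam[n]; tr[k] = oturn[n];
  }
  return List::create(_["x"] = x, _["y"] = y, _["vx"] = vx, _["vy"] = vy,
                      _["delta"] = d, _["los_rate"] = l, _["turn_rate"] = tr);
}

// RMS position error of simulations over a matrix of parameter combinations.
// params columns: N, K, dlag (integration steps).  eval_idx holds 0-based
// indices into the dt grid; ex/ey the measured pursuer positions there.
// Degenerate simulations score +Inf.
// [[Rcpp::export]]
NumericVector pursuit_rms_cpp(NumericMatrix target, NumericMatrix hawk,
                              NumericVector speed, int i0, double dt, int law,
                              NumericMatrix params, IntegerVector eval_idx,
                              NumericVector ex, NumericVector ey) {
  const int M = target.nrow() - 1;
  if (i0 < 0 || i0 > M) stop("i0 out of range");
  const int nev = eval_idx.size();
  if (nev == 0) stop("empty evaluation frame set");
  for (int k = 0; k < nev; ++k)
    if (eval_idx[k] < 0 || eval_idx[k] > M) stop("evaluation index out of range");

  const double* tx = &target(0, 0); const double* ty = &target(0, 1);
  const double* tvx = &target(0, 2); const double* tvy = &target(0, 3);
  const double* hx = &hawk(0, 0); const double* hy = &hawk(0, 1);
  const double* hvx = &hawk(0, 2); const double* hvy = &hawk(0, 3);

  bool inertial_law = (law == 2 || law == 4);
  std::vector<double> del_pre, lam_pre;
  precompute_measured(tx, ty, tvx, tvy, hx, hy, hvx, hvy, i0, inertial_law,
                      del_pre, lam_pre);

  std::vector<double> ox(M + 1), oy(M + 1), ovx(M + 1), ovy(M + 1),
      del(M + 1), lam(M + 1), oturn(M + 1);
  const int ncomb = params.nrow();
  NumericVector eps(ncomb);
  for (int c = 0; c < ncomb; ++c) {
    double Nx, Kx; bool inertial;
    law_gains(law, params(c, 0), params(c, 1), Nx, Kx, inertial);
    const int dlag = static_cast<int>(params(c, 2));
    if (dlag < 0 || (dlag > i0 && i0 > 0)) { eps[c] = R_PosInf; continue; }
    int rc = run_sim(tx, ty, tvx, tvy, REAL(speed), M, i0, dt, inertial, Nx,
                     Kx, dlag, del_pre.data(), lam_pre.data(), ox.data(),
                     oy.data(), ovx.data(), ovy.data(), del.data(), lam.data(),
                     oturn.data(), hx[i0], hy[i0], hvx[i0], hvy[i0]);
    if (rc != 0) { eps[c] = R_PosInf; continue; }
    double ss = 0.0;
    for (int k = 0; k < nev; ++k) {
      const int idx = eval_idx[k];
      const double dx = ox[idx] - ex[k], dy = oy[idx] - ey[k];
      ss += dx * dx + dy * dy;
    }
    eps[c] = std::sqrt(ss / nev);
  }
  return eps;
}

static double median_inplace(std::vector<double>& buf) {
  const size_t n = buf.size();
  std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
  double hi = buf[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(buf.begin(), buf.begin() + n / 2 - 1, buf.begin() + n / 2);
  return 0.5 * (hi + buf[n / 2 - 1]);
}

// Median of x over each row of 1-based resample indices.
// [[Rcpp::export]]
NumericVector resample_medians_cpp(NumericVector x, IntegerMatrix idx) {
  const int B = idx.nrow(), n = idx.ncol();
  NumericVector out(B);
  std::vector<double> buf(n);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < n; ++j) buf[j] = x[idx(b, j) - 1];
    out[b] = median_inplace(buf);
  }
  return out;
}

// Row-wise medians over a subset of columns (1-based, with repetition).
// [[Rcpp::export]]
NumericVector rowmed_subset_cpp(NumericMatrix m, IntegerVector cols) {
  const int nr = m.nrow(), nc = cols.size();
  NumericVector out(nr);
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = m(i, cols[j] - 1);
    out[i] = median_inplace(buf);
  }
  return out;
}
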