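// Forward-Euler integration of the excitatory-inhibitory rate dynamics,
// with optional online Hebbian/BCM plasticity of the E-E weights.
// The R-level stepNetwork()/hebbianUpdate()/bcmUpdate() functions are the
// reference semantics; these loops must match them step for step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static inline vec sq_relu(const vec& z) {
  return square(clamp(z, 0.0, datum::inf));
}

// W %*% x skipping exact-zero entries of x (rates are mostly zero).
// Deterministic column order keeps runs bit-reproducible.
static vec mv_skip(const mat& W, const vec& x) {
  vec out(W.n_rows, fill::zeros);
  for (uword j = 0; j < x.n_elem; ++j) {
    const double xj = x(j);
    if (xj != 0.0) out += xj * W.col(j);
  }
  return out;
}

// Inhibitory-to-excitatory drive: every row of Wei is identical
// (uniform -1/Ni), so one sequential dot product serves all rows.
static vec ei_drive(const mat& Wei, const vec& ri, bool uniform) {
  if (uniform) {
    const double v = Wei(0, 0);
    double s = 0.0;
    for (uword j = 0; j < ri.n_elem; ++j) s += v * ri(j);
    return vec(Wei.n_rows, fill::value(s));
  }
  return mv_skip(Wei, ri);
}

static inline bool is_uniform(const mat& W) {
  return W.n_elem > 0 && W.min() == W.max();
}

// Integrate from the zero state to a fixed point. Convergence requires the
// max-norm step change (over both populations) to stay below tol for
// tol_window consecutive steps; the returned steady state is the average of
// the final avg_window recorded states.
// [[Rcpp::export]]
List cpp_fixed_point(const arma::mat& Wee, const arma::mat& Wei,
                     const arma::mat& Wie, const arma::vec& alpha,
                     double tau_e, double tau_i, double dt,
                     int max_steps, double tol, int tol_window,
                     int avg_window, double div_bound) {
  const uword ne = Wee.n_rows, ni = Wie.n_rows;
  vec re(ne, fill::zeros), ri(ni, fill::zeros);
  // circular buffers of the trailing avg_window states
  mat buf_e(ne, avg_window, fill::zeros), buf_i(ni, avg_window, fill::zeros);
  vec pop_trace(max_steps, fill::zeros);
  vec re_accum(ne, fill::zeros); // per-neuron time average (threshold init)
  int consec = 0, step = 0, diverged = 0;
  double last_change = datum::inf;
  bool converged = false;

  const bool wei_uniform = is_uniform(Wei);
  for (step = 0; step < max_steps; ++step) {
    vec ze = mv_skip(Wee, re) + ei_drive(Wei, ri, wei_uniform) + alpha;
    vec re_new = re + (dt / tau_e) * (-re + sq_relu(ze));
    vec zi = mv_skip(Wie, re);      // pre-update excitatory rates
    vec ri_new = ri + (dt / tau_i) * (-ri + sq_relu(zi));
    last_change = std::max(abs(re_new - re).max(), abs(ri_new - ri).max());
    re = re_new; ri = ri_new;
    if (re.max() > div_bound) { diverged = 1; break; }
    if (ri.max() > div_bound) { diverged = 2; break; }
    buf_e.col(step % avg_window) = re;
    buf_i.col(step % avg_window) = ri;
    pop_trace(step) = mean(re);
    re_accum += re;
    consec = (last_change < tol) ? consec + 1 : 0;
    if (consec >= tol_window && step + 1 >= avg_window) {
      converged = true; ++step; break;
    }
  }
  int used = std::min(step, max_steps);
  vec re_star = mean(buf_e, 1), ri_star = mean(buf_i, 1);
  if (used < avg_window && used > 0) { // short runs: average what exists
    re_star = mean(buf_e.cols(0, used - 1), 1);
    ri_star = mean(buf_i.cols(0, used - 1), 1);
  }
  return List::create(_["re_star"] = re_star, _["ri_star"] = ri_star,
                      _["re_mean"] = re_accum / std::max(used, 1),
                      _["re_final"] = re, _["ri_final"] = ri,
                      _["residual"] = last_change,
                      _["converged"] = converged, _["steps"] = used,
                      _["diverged"] = diverged,
                      _["pop_trace"] = pop_trace.head(std::max(used, 1)));
}

// One stimulus presentation with plasticity on: zero-reset state, n_steps of
// Euler integration; after each rate update the E-E weights (and for BCM the
// sliding thresholds) are updated from the current-step rates.
// rule: 0 = frozen, 1 = general Hebbian, 2 = BCM.
// [[Rcpp::export]]
List cpp_presentation(const arma::mat& Wee0, const arma::mat& Wei,
                      const arma::mat& Wie, const arma::mat& mask,
                      const arma::vec& alpha, const arma::vec& xi0,
                      int rule, int n_steps,
                      double tau_e, double tau_i, double dt,
                      double tau_w, double tau_xi, double div_bound) {
  mat Wee = Wee0;
  vec xi = xi0;
  const uword ne = Wee.n_rows, ni = Wie.n_rows;
  vec re(ne, fill::zeros), ri(ni, fill::zeros);
  int diverged = 0;
  const double cw = dt / tau_w, cxi = dt / tau_xi;

  const bool wei_uniform = is_uniform(Wei);
  for (int step = 0; step < n_steps; ++step) {
    vec ze = mv_skip(Wee, re) + ei_drive(Wei, ri, wei_uniform) + alpha;
    vec re_new = re + (dt / tau_e) * (-re + sq_relu(ze));
    vec zi = mv_skip(Wie, re);
    vec ri_new = ri + (dt / tau_i) * (-ri + sq_relu(zi));
    re = re_new; ri = ri_new;
    if (re.max() > div_bound) { diverged = 1; break; }
    if (ri.max() > div_bound) { diverged = 2; break; }
    // rank-1 weight update restricted to the mask, exploiting the
    // sparsity of the presynaptic rate vector (columns with re[l] = 0
    // contribute nothing)
    if (rule == 1) {
      vec post = square(re);
      for (uword l = 0; l < ne; ++l) {
        if (re(l) == 0.0) continue;
        Wee.col(l) += (cw * re(l)) * (post % mask.col(l));
      }
    } else if (rule == 2) {
      vec post = re % (re - xi);
      for (uword l = 0; l < ne; ++l) {
        if (re(l) == 0.0) continue;
        vec upd = Wee.col(l) + (cw * re(l)) * (post % mask.col(l));
        Wee.col(l) = clamp(upd, 0.0, datum::inf);
      }
      xi += cxi * (-xi + square(re));
    }
  }
  return List::create(_["Wee"] = Wee, _["xi"] = xi,
                      _["re"] = re, _["ri"] = ri,
                      _["diverged"] = diverged);
}
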