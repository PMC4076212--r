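// Exact sampler for the Polya-Gamma distribution PG(1, z), after the
// alternating-series rejection method of Devroye for the Jacobi J*(1, z)
// density.  Uses R's RNG so draws are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;

// n-th coefficient of the alternating series for the J*(1, z) density,
// using the left (x <= t) or right (x > t) expansion.
static double a_coef(int n, double x) {
  double npd = n + 0.5;
  if (x > TRUNC) {
    return M_PI * npd * std::exp(-0.5 * npd * npd * M_PI * M_PI * x);
  }
  return M_PI * npd * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * npd * npd / x);
}

// P(IG(mu, lambda = 1) <= x); log-space for the exp(2/mu) factor.
static double pigauss(double x, double mu) {
  double invmu = (mu == R_PosInf) ? 0.0 : 1.0 / mu;
  double rx = 1.0 / std::sqrt(x);
  double b = rx * (x * invmu - 1.0);
  double a = -rx * (x * invmu + 1.0);
  double term2 = std::exp(2.0 * invmu + R::pnorm(a, 0.0, 1.0, 1, 1));
  return R::pnorm(b, 0.0, 1.0, 1, 0) + term2;
}

// Inverse-Gaussian(1/z, 1) truncated to (0, TRUNC).
static double rtigauss(double z) {
  double t = TRUNC;
  double X = t + 1.0;
  double mu = (z == 0.0) ? R_PosInf : 1.0 / z;
  if (mu > t) {
    // rejection from a truncated inverse-chi-square proposal
    for (;;) {
      double E1, E2;
      do {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      } while (E1 * E1 > 2.0 * E2 / t);
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      double alpha = std::exp(-0.5 * z * z * X);
      if (R::unif_rand() <= alpha) break;
    }
  } else {
    while (X > t) {
      // Michael-Schucany-Haas IG(mu, 1) draw, retried until it lands in (0, t]
      double Y = R::norm_rand();
      Y *= Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * muY -
          0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// One draw from PG(1, z).
static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double fz = M_PI * M_PI * 0.125 + 0.5 * z * z;
  double t = TRUNC;
  double mu = (z == 0.0) ? R_PosInf : 1.0 / z;
  double p = (M_PI / (2.0 * fz)) * std::exp(-fz * t);
  double q = 2.0 * std::exp(-z) * pigauss(t, mu);
  for (;;) {
    double X;
    if (R::unif_rand() * (p + q) <= p) {
      X = t + R::exp_rand() / fz;          // truncated exponential tail
    } else {
      X = rtigauss(z);                     // truncated inverse-Gaussian head
    }
    // squeeze acceptance via the alternating series
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X;       // accept
      } else {
        S += a_coef(n, X);
        if (Y > S) break;                  // reject, redraw X
      }
    }
  }
}

//' Draw Polya-Gamma PG(1, z) variates
//'
//' One exact draw per element of `z`, using R's random number stream.
//'
//' @param z numeric vector of tilting parameters (the linear predictor in
//'   logistic models).
//' @return numeric vector of PG(1, z) draws, same length as `z`.
//' @export
// [[Rcpp::export]]
NumericVector rpolyagamma(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  GetRNGstate();
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  PutRNGstate();
  return out;
}
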