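// Joint likelihood for acclimated tolerance surfaces.
//
// Each observation is one cross-salinity assay well: an initial live-cell
// estimate n0, a final live count nt, and a dead-cell increment, after a
// transfer from acclimation salinity s0 to assay salinity s1 for tdur days.
// Live counts are negative binomial (nbinom2: var = mu + mu^2/size) around
// n0 * (1 - d) * exp(r * t); dead increments are beta-binomial with trials
// round(n0), mean d and precision phi.
//
// Apparent growth r is a bivariate quadratic in (s0, s1) with an acclimation
// cross term; mortality d is logit-linear in s0, s1 and their product.
//
// model_form = 0: one shared surface, breadths parameterized as log(sigma).
// model_form = 1: hierarchical; every surface parameter is a linear function
//   of a population-level regressor row of X (intercept + environmental
//   moments), with breadths on the 1/sigma^2 scale.
//
// beta column order: r_max, mu0, mu1, b0, b1, k, delta, delta0, delta1,
// delta01, where (b0, b1) are log(sigma0), log(sigma1) for model_form 0 and
// 1/sigma0^2, 1/sigma1^2 linear predictors for model_form 1.
#include <TMB.hpp>

template <class Type>
Type dbetabinom_local(Type y, Type n, Type d, Type phi, int give_log) {
  Type a = d * phi;
  Type b = (Type(1.0) - d) * phi;
  Type logres = lgamma(n + Type(1.0)) - lgamma(y + Type(1.0)) -
    lgamma(n - y + Type(1.0)) + lgamma(y + a) + lgamma(n - y + b) -
    lgamma(n + a + b) + lgamma(a + b) - lgamma(a) - lgamma(b);
  if (give_log) return logres;
  return exp(logres);
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_INTEGER(model_form);   // 0 single surface, 1 hierarchical
  DATA_MATRIX(X);             // n_pop x n_reg population-level design
  DATA_IVECTOR(pop);          // 0-based population index per observation
  DATA_VECTOR(s0);
  DATA_VECTOR(s1);
  DATA_VECTOR(n0);
  DATA_VECTOR(nt);
  DATA_VECTOR(dead);          // dead-cell increment, 0 <= dead <= trials
  DATA_VECTOR(trials);
  DATA_VECTOR(tdur);

  PARAMETER_MATRIX(beta);     // n_reg x 10
  PARAMETER(log_nb_size);
  PARAMETER(log_bb_prec);

  Type nb_size = exp(log_nb_size);
  Type bb_prec = exp(log_bb_prec);

  matrix<Type> P = X * beta;  // n_pop x 10 population-level parameters

  Type nll = 0.0;
  int n = s0.size();
  for (int i = 0; i < n; i++) {
    int p = pop(i);
    Type r_max = P(p, 0), mu0 = P(p, 1), mu1 = P(p, 2);
    Type k = P(p, 5);
    Type inv0, inv1;
    if (model_form == 0) {
      inv0 = exp(Type(-2.0) * P(p, 3));
      inv1 = exp(Type(-2.0) * P(p, 4));
    } else {
      inv0 = P(p, 3);
      inv1 = P(p, 4);
    }
    Type z0 = s0(i) - mu0;
    Type z1 = s1(i) - mu1;
    Type r = r_max - z1 * z1 * inv1 - z0 * z0 * inv0 +
      Type(2.0) * k * z1 * z0 * inv1;
    Type eta = P(p, 6) + P(p, 7) * s0(i) + P(p, 8) * s1(i) +
      P(p, 9) * s0(i) * s1(i);
    Type d = invlogit(eta);
    Type mu = n0(i) * (Type(1.0) - d) * exp(r * tdur(i)) + Type(1e-12);
    nll -= dnbinom2(nt(i), mu, mu + mu * mu / nb_size, true);
    if (asDouble(trials(i)) > 0.0) {
      nll -= dbetabinom_local(dead(i), trials(i), d, bb_prec, true);
    }
  }

  if (model_form == 0) {
    Type sigma0 = exp(P(0, 3));
    Type sigma1 = exp(P(0, 4));
    ADREPORT(sigma0);
    ADREPORT(sigma1);
  }
  ADREPORT(nb_size);
  ADREPORT(bb_prec);

  return nll;
}
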