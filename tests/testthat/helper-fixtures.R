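# Shared fixtures, computed once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Intercept-only moment-effect matrix at the reference white-noise surface.
intercept_effects <- function() {
  ref <- reference_surface_params()
  eff <- matrix(0, 5, 10)
  eff[1, ] <- c(ref$growth$r_max, ref$growth$mu0, ref$growth$mu1,
                1 / ref$growth$sigma0^2, 1 / ref$growth$sigma1^2,
                ref$growth$k, ref$mortality$delta, ref$mortality$delta0,
                ref$mortality$delta1, ref$mortality$delta01)
  eff
}

reference_truth_vector <- function() {
  ref <- reference_surface_params()
  c(r_max = ref$growth$r_max, mu0 = ref$growth$mu0, mu1 = ref$growth$mu1,
    sigma0 = ref$growth$sigma0, sigma1 = ref$growth$sigma1,
    k = ref$growth$k, delta = ref$mortality$delta,
    delta0 = ref$mortality$delta0, delta1 = ref$mortality$delta1,
    delta01 = ref$mortality$delta01)
}

# Five populations sharing the reference surface: the standard
# simulate-then-refit dataset.
ref_experiment <- function(seed = 42) {
  cfg <- experiment_config(constant_salinities = numeric(0),
                           constant_replicates = 0,
                           fluct_rhos = 0, fluct_counts = 5, n0_sd = 0,
                           effects = intercept_effects(), seed = seed)
  generate_experiment(cfg)
}

ref_surface_fit <- function() {
  fixture("ref_surface_fit", function() {
    fit_surface(ref_experiment()$counts, seed = 1)
  })
}

# A 25-population experiment with intercept-only effects (null moment
# effects) and its hierarchical fit.
null_hier_experiment <- function(seed = 11) {
  generate_experiment(experiment_config(effects = intercept_effects(),
                                        seed = seed))
}

# Independent single-model Wald F for one lm term block (oracle for the
# m = 1 pooling degenerate case).
car_free_wald <- function(fit, term) {
  asgn <- attr(stats::model.matrix(fit), "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  idx <- which(asgn == match(term, labels))
  Q <- stats::coef(fit)[idx]
  V <- stats::vcov(fit)[idx, idx, drop = FALSE]
  Fstat <- drop(t(Q) %*% solve(V, Q)) / length(idx)
  list(F = Fstat,
       p = stats::pf(Fstat, length(idx), stats::df.residual(fit),
                     lower.tail = FALSE))
}

null_hier_fit <- function() {
  fixture("null_hier_fit", function() {
    exp <- null_hier_experiment()
    list(exp = exp,
         fit = fit_hierarchical(exp$counts, exp$moments, seed = 1))
  })
}
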