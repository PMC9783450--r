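# Bivariate tolerance surface: evaluation, optima, observation model.

ref <- reference_surface_params()

test_that("growth surface evaluates per the quadratic form", {
  g <- ref$growth
  # the surface maximum sits at the optima and equals r_max
  expect_equal(growth_rate(g, g$mu0, g$mu1), g$r_max)
  # independent arithmetic oracle at a stressful corner
  oracle <- function(p, s0, s1) {
    p$r_max - (s1 - p$mu1)^2 / p$sigma1^2 - (s0 - p$mu0)^2 / p$sigma0^2 +
      2 * p$k * (s1 - p$mu1) * (s0 - p$mu0) / p$sigma1^2
  }
  expect_equal(growth_rate(g, 0.1, 4.7), oracle(g, 0.1, 4.7))
  expect_equal(growth_rate(g, 0.1, 4.7), -1.691, tolerance = 1e-3)
  # k = 0: additive surface, acclimation contribution independent of s1
  g0 <- growth_params(1, 2, 1, 3, 4, 0)
  diff1 <- growth_rate(g0, 0.5, 1.3) - growth_rate(g0, g0$mu0, 1.3)
  diff2 <- growth_rate(g0, 0.5, 3.9) - growth_rate(g0, g0$mu0, 3.9)
  expect_equal(diff1, diff2)
})

test_that("growth surface attains r_max at the optima when negative definite", {
  set.seed(71)
  for (i in 1:25) {
    sigma0 <- runif(1, 0.5, 5); sigma1 <- runif(1, 0.5, 5)
    kmax <- sigma1 / sigma0
    g <- growth_params(runif(1, 0.5, 2), runif(1, 0, 4), runif(1, 0, 4),
                       sigma0, sigma1, runif(1, -0.95, 0.95) * kmax)
    grid <- expand.grid(s0 = seq(-10, 10, length.out = 60),
                        s1 = seq(-10, 10, length.out = 60))
    vals <- growth_rate(g, grid$s0, grid$s1)
    expect_lte(max(vals), g$r_max + 1e-9)
  }
  expect_warning(growth_params(1, 2, 1, 4, 1, 2), "no finite maximum")
})

test_that("mortality surface is the logistic of the logit-linear form", {
  m <- ref$mortality
  expect_equal(mortality_ratio(mortality_params(0, 0, 0, 0), 1, 2), 0.5)
  eta <- m$delta + m$delta0 * 0.1 + m$delta1 * 4.7 + m$delta01 * 0.1 * 4.7
  expect_equal(mortality_ratio(m, 0.1, 4.7), 1 / (1 + exp(-eta)))
  expect_equal(mortality_ratio(m, 0.1, 4.7), 0.796, tolerance = 1e-3)
  expect_lt(mortality_ratio(mortality_params(-50, 0, 0, 0), 2, 2), 1e-20)
})

test_that("net growth combines mortality and growth", {
  expect_equal(net_growth(0.7, 0, 3), 0.7)  # identity at zero mortality
  expect_equal(net_growth(-1.69, 0.796, 3), log(1 - 0.796) / 3 - 1.69)
  expect_equal(net_growth(-1.69, 0.796, 3), -2.22, tolerance = 5e-3)
  d <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(net_growth(1, d, 3)) < 0))
  expect_error(net_growth(1, 1, 3), "-Inf")
})

test_that("conditional optimum is linear in acclimation salinity with slope k", {
  g <- ref$growth
  expect_equal(as.numeric(conditional_optimum(g, g$mu0)), g$mu1)
  expect_equal(as.numeric(conditional_optimum(g, 0.5)), -1.410,
               tolerance = 1e-3)
  expect_false(attr(conditional_optimum(g, 0.5), "in_range"))
  s0 <- seq(0, 4.8, by = 0.4)
  slopes <- diff(as.numeric(conditional_optimum(g, s0))) / diff(s0)
  expect_equal(slopes, rep(g$k, length(slopes)))
  g0 <- growth_params(1, 2, 1.2, 3, 4, 0)
  expect_true(all(as.numeric(conditional_optimum(g0, s0)) == 1.2))
})

test_that("joint optimum matches a dense grid oracle", {
  surf <- list(growth = ref$growth, mortality = ref$mortality)
  opt <- joint_optimum(surf, t = 3, bounds = c(0.1, 4.7))
  gr <- seq(0.1, 4.7, length.out = 500)
  grid <- expand.grid(s0 = gr, s1 = gr)
  R <- net_growth(growth_rate(ref$growth, grid$s0, grid$s1),
                  mortality_ratio(ref$mortality, grid$s0, grid$s1), 3)
  i <- which.max(R)
  cell <- diff(gr)[1]
  expect_lt(abs(opt$s0_star - grid$s0[i]), 1.5 * cell)
  expect_lt(abs(opt$s1_star - grid$s1[i]), 1.5 * cell)
  expect_gte(opt$R_star, max(R) - 1e-6)
  # negligible mortality, interior optimum: collapses onto (mu0, mu1)
  g2 <- growth_params(1.153, 2.565, 1.5, 3.101, 4.143, 0.666)
  surf2 <- list(growth = g2, mortality = mortality_params(-100, 0, 0, 0))
  opt2 <- joint_optimum(surf2, t = 3, bounds = c(0.1, 4.7))
  expect_equal(opt2$s0_star, g2$mu0, tolerance = 1e-4)
  expect_equal(opt2$s1_star, g2$mu1, tolerance = 1e-4)
  expect_equal(opt2$R_star, g2$r_max, tolerance = 1e-8)
})

test_that("zero-growth interval matches a fine-grid sign-change oracle", {
  surf <- list(growth = ref$growth, mortality = ref$mortality)
  iv <- zero_growth_interval(surf, s0 = 2.4, t = 3, bounds = c(0.1, 4.7))
  gr <- seq(0.1, 4.7, length.out = 5000)
  R <- net_growth(growth_rate(ref$growth, 2.4, gr),
                  mortality_ratio(ref$mortality, 2.4, gr), 3)
  pos <- gr[R > 0]
  expect_equal(nrow(iv), 1)
  expect_lt(abs(iv$lower - min(pos)), diff(gr)[1] * 2 + 1e-6)
  expect_lt(abs(iv$upper - max(pos)), diff(gr)[1] * 2 + 1e-6)
  # surface everywhere negative: empty result
  low <- list(growth = growth_params(-1, 2.4, 2.4, 3, 4, 0.5),
              mortality = ref$mortality)
  expect_equal(nrow(zero_growth_interval(low, 2.4)), 0)
  # positive across the whole axis: truncation flagged
  high <- list(growth = growth_params(5, 2.4, 2.4, 3, 4, 0.5),
               mortality = mortality_params(-100, 0, 0, 0))
  ivh <- zero_growth_interval(high, 2.4)
  expect_true(ivh$truncated_lower && ivh$truncated_upper)
  expect_equal(c(ivh$lower, ivh$upper), c(0.1, 4.7))
})

test_that("beta-binomial pmf is proper and matches direct summation", {
  for (d in c(0.1, 0.5, 0.9)) {
    for (phi in c(0.5, 2, 10)) {
      expect_equal(sum(dbetabinom(0:5, 5, d, phi)), 1, tolerance = 1e-12)
    }
  }
  # textbook beta-mixing integral, evaluated numerically
  y <- 3; n <- 12; d <- 0.3; phi <- 4
  direct <- integrate(function(p) dbinom(y, n, p) *
                        dbeta(p, d * phi, (1 - d) * phi), 0, 1,
                      rel.tol = 1e-12)$value
  expect_equal(dbetabinom(y, n, d, phi), direct, tolerance = 1e-9)
})

test_that("observation likelihood reduces to Poisson/binomial limits", {
  g <- ref$growth; m <- ref$mortality
  r <- growth_rate(g, 2.4, 1.8)
  d <- mortality_ratio(m, 2.4, 1.8)
  obs <- data.frame(s0_M = 2.4, s1_M = 1.8, n0 = 40, n_t = 0,
                    d0 = 0, d_t = 1, t_days = 3)
  mu <- obs$n0 * (1 - d) * exp(r * obs$t_days)
  obs$n_t <- round(mu)
  # nb_size -> infinity: negative binomial converges to Poisson
  ll <- observation_loglik(obs, g, m, dispersion_params(1e8, 10))
  pois_bb <- dpois(obs$n_t, mu, log = TRUE) +
    dbetabinom(obs$d_t, round(obs$n0), d, 10, log = TRUE)
  expect_lt(abs(ll - pois_bb), 1e-5)
  # bb_precision -> infinity: beta-binomial converges to binomial
  ll2 <- observation_loglik(obs, g, m, dispersion_params(20, 1e9))
  nb_bin <- dnbinom(obs$n_t, mu = mu, size = 20, log = TRUE) +
    dbinom(obs$d_t, round(obs$n0), d, log = TRUE)
  expect_lt(abs(ll2 - nb_bin), 1e-4)
  # zero trials: the dead term contributes nothing
  obs0 <- transform(obs, n0 = 0.4, n_t = 3, d_t = 0)
  ll0 <- observation_loglik(obs0, g, m, dispersion_params(20, 10))
  mu0 <- 0.4 * (1 - d) * exp(r * 3)
  expect_equal(ll0, dnbinom(3, mu = mu0, size = 20, log = TRUE))
})

test_that("observation likelihood agrees with textbook pmfs for small counts", {
  g <- growth_params(0.5, 2, 2, 3, 4, 0.3)
  m <- mortality_params(-1, 0.1, 0.2, -0.05)
  disp <- dispersion_params(5, 3)
  set.seed(8)
  for (i in 1:20) {
    obs <- data.frame(s0_M = runif(1, 0, 4.7), s1_M = runif(1, 0, 4.7),
                      n0 = sample(5:20, 1), n_t = sample(0:20, 1),
                      d0 = 0, d_t = 0, t_days = 3)
    obs$d_t <- sample(0:round(obs$n0), 1)
    r <- g$r_max - (obs$s1_M - g$mu1)^2 / g$sigma1^2 -
      (obs$s0_M - g$mu0)^2 / g$sigma0^2 +
      2 * g$k * (obs$s1_M - g$mu1) * (obs$s0_M - g$mu0) / g$sigma1^2
    d <- plogis(m$delta + m$delta0 * obs$s0_M + m$delta1 * obs$s1_M +
                  m$delta01 * obs$s0_M * obs$s1_M)
    mu <- obs$n0 * (1 - d) * exp(3 * r)
    a <- d * 3; b <- (1 - d) * 3
    n <- round(obs$n0); y <- obs$d_t
    bb <- lgamma(n + 1) - lgamma(y + 1) - lgamma(n - y + 1) +
      lgamma(y + a) + lgamma(n - y + b) - lgamma(n + a + b) +
      lgamma(a + b) - lgamma(a) - lgamma(b)
    nb <- lgamma(obs$n_t + 5) - lgamma(5) - lgamma(obs$n_t + 1) +
      5 * log(5 / (5 + mu)) + obs$n_t * log(mu / (5 + mu))
    expect_equal(observation_loglik(obs, g, m, disp), nb + bb,
                 tolerance = 1e-10)
  }
})

test_that("surface refit recovers the generating parameters", {
  exp <- ref_experiment()
  fit <- ref_surface_fit()
  expect_true(fit$converged)
  truth <- reference_truth_vector()
  z <- abs(fit$estimates[names(truth)] - truth) / fit$se[names(truth)]
  expect_true(all(z < 3))
  expect_equal(fit$estimates[["nb_size"]], 20, tolerance = 0.25)
  expect_equal(fit$estimates[["bb_precision"]], 10, tolerance = 0.25)
  # the pure-R likelihood agrees with the fitted model's log-likelihood
  ll <- sum(observation_loglik(exp$counts, fit$growth, fit$mortality,
                               fit$dispersion))
  expect_equal(ll, fit$loglik, tolerance = 1e-4)
})

test_that("likelihood scaling: duplicated data halves squared SEs", {
  exp <- ref_experiment()
  fit1 <- ref_surface_fit()
  doubled <- rbind(exp$counts, exp$counts)
  fit2 <- fit_surface(doubled, init = list(
    beta = matrix(c(fit1$estimates[1:3], log(fit1$estimates[4:5]),
                    fit1$estimates[6:10]), nrow = 1),
    log_nb_size = log(fit1$estimates[["nb_size"]]),
    log_bb_prec = log(fit1$estimates[["bb_precision"]])),
    seed = 1, n_starts = 1)
  expect_equal(unname(fit2$estimates), unname(fit1$estimates),
               tolerance = 1e-4)
  ratio <- fit2$se / fit1$se
  expect_equal(unname(ratio), rep(1 / sqrt(2), length(ratio)),
               tolerance = 0.02)
})

test_that("degenerate designs raise identifiability errors", {
  exp <- ref_experiment()
  one_s0 <- exp$counts[exp$counts$s0_M == 2.4, ]
  expect_error(fit_surface(one_s0), "identifiability")
  expect_error(fit_surface(exp$counts[0, ]), "schema")
})
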