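# Per-cell glycerol scaling, imputation, pooled regression/ANOVA, and
# plasticity variance.

gly_data <- function(seed = 31, conc_cv = 0.08, density_cv = 0.05, ...) {
  generate_glycerol_data(glycerol_config(seed = seed, conc_cv = conc_cv,
                                         density_cv = density_cv, ...))
}

test_that("per-cell scaling applies the delta method", {
  g <- per_cell(1e-6, 1e-7, 1e6, 0)
  expect_equal(g$est, 1e-12)
  expect_equal(g$se, 1e-13)
  # error only in the density: single-term delta
  g2 <- per_cell(1e-6, 0, 1e6, 1e5)
  expect_equal(g2$se, 1e-6 * 1e5 / 1e12)
  expect_error(per_cell(1e-6, 1e-7, 0, 1), "> 0")
  # Monte-Carlo propagation oracle at moderate CVs
  set.seed(12)
  C <- 2e-6; sC <- 1e-7; N <- 5e5; sN <- 4e4
  draws <- rnorm(1e5, C, sC) / rnorm(1e5, N, sN)
  g3 <- per_cell(C, sC, N, sN)
  expect_equal(g3$se, sd(draws), tolerance = 0.05)
})

test_that("intracellular differencing pairs compartments and adds variances", {
  tab <- gly_data()$measurements
  out <- intracellular(tab)
  intra <- out[out$compartment == "intracellular", ]
  tot <- out[out$compartment == "total", ]
  ext <- out[out$compartment == "extracellular", ]
  key <- function(d) paste(d$population_id, d$s0_M, d$s1_M, d$time_h)
  ext <- ext[match(key(tot), key(ext)), ]
  intra <- intra[match(key(tot), key(intra)), ]
  # exact additivity on the estimate scale
  expect_equal(intra$conc_est + ext$conc_est, tot$conc_est)
  expect_equal(intra$conc_se, sqrt(tot$conc_se^2 + ext$conc_se^2))
  # zero extracellular: intracellular equals total
  tab0 <- tab
  tab0$conc_est[tab0$compartment == "extracellular"] <- 0
  tab0$conc_se[tab0$compartment == "extracellular"] <- 0
  out0 <- intracellular(tab0)
  i0 <- out0[out0$compartment == "intracellular", ]
  t0 <- out0[out0$compartment == "total", ]
  expect_equal(i0$conc_est, t0$conc_est)
  expect_equal(i0$conc_se, t0$conc_se)
  # broken pairing is refused
  expect_error(intracellular(tab[-1, ]), "pairing error")
  # Monte-Carlo differencing oracle
  set.seed(13)
  d <- rnorm(1e5, 5e-7, 3e-8) - rnorm(1e5, 2e-7, 2e-8)
  expect_equal(sqrt(3e-8^2 + 2e-8^2), sd(d), tolerance = 0.02)
})

test_that("imputation is deterministic and unbiased", {
  tab <- gly_data()$measurements
  imp1 <- impute_datasets(tab, m = 50, seed = 99)
  imp2 <- impute_datasets(tab, m = 50, seed = 99)
  expect_identical(imp1, imp2)
  # zero SEs: every imputation equals the input
  tab0 <- tab
  tab0$conc_se <- 0
  imp0 <- impute_datasets(tab0, m = 5, seed = 1)
  expect_identical(imp0[[3]]$conc_est, tab0$conc_est)
  # mean across imputations approaches the point estimate
  imp <- impute_datasets(tab, m = 400, seed = 7)
  est <- vapply(imp, function(d) d$conc_est[1], numeric(1))
  mc_se <- tab$conc_se[1] / sqrt(400)
  expect_lt(abs(mean(est) - tab$conc_est[1]), 3 * mc_se)
  expect_error(impute_datasets(transform(tab, conc_se = -1), 5, 1),
               ">= 0")
})

test_that("Rubin pooling handles the degenerate and generic cases", {
  # identical imputations: no between-variance, SE equals within-SE
  est <- matrix(2, 1, 10)
  se <- matrix(0.5, 1, 10)
  out <- rubin_pool(est, se)
  expect_equal(out$estimate, 2)
  expect_equal(out$se, 0.5)
  expect_equal(out$df, Inf)
  # generic: total variance exceeds within-variance
  set.seed(14)
  est2 <- matrix(rnorm(20, 1, 0.3), 1)
  se2 <- matrix(0.2, 1, 20)
  out2 <- rubin_pool(est2, se2)
  expect_equal(out2$estimate, mean(est2))
  expect_gt(out2$se, 0.2)
  expect_equal(out2$se^2,
               0.04 + (1 + 1 / 20) * var(as.numeric(est2)),
               tolerance = 1e-12)
})

test_that("pooled moment regression recovers a planted predictability slope", {
  gd <- gly_data(seed = 41)
  imps <- impute_datasets(gd$measurements, m = 30, seed = 5)
  cfg_eff <- gd$truth$config$glycerol_effects
  out <- glycerol_moment_regression(imps, gd$moments, "intracellular",
                                    s0 = 3.5, s1 = 3.5, time_h = 8)
  rho2_row <- out[out$moment == "rho2", ]
  truth_slope <- cfg_eff[["rho2"]] + cfg_eff[["rho2_s1"]] * 3.5
  expect_lt(abs(rho2_row$estimate - truth_slope), 3 * rho2_row$se)
  # identical response: all moment slopes vanish
  flat <- gd$measurements
  flat$conc_est <- 1e-6
  flat$conc_se <- 0
  flat$density_est <- 5e5
  flat$density_se <- 0
  out_flat <- suppressWarnings(  # zero residuals: perfect-fit warning
    glycerol_moment_regression(flat, gd$moments, "total",
                               s0 = 0.5, s1 = 2, time_h = 1))
  expect_true(all(abs(out_flat$estimate[out_flat$moment != "intercept"])
                  < 1e-15))
})

test_that("zero-SE pooling collapses onto the point-estimate analysis", {
  gd <- gly_data(seed = 43)
  gd$measurements$conc_se <- 0  # degenerate imputation, noisy response
  tab <- gd$measurements
  imps <- impute_datasets(tab, m = 10, seed = 2)
  pooled <- glycerol_moment_regression(imps, gd$moments, "intracellular",
                                       s0 = 0.5, s1 = 3.5, time_h = 8)
  point <- glycerol_moment_regression(tab, gd$moments, "intracellular",
                                      s0 = 0.5, s1 = 3.5, time_h = 8)
  expect_equal(pooled$estimate, point$estimate, tolerance = 1e-12)
  expect_equal(pooled$se, point$se, tolerance = 1e-10)
})

test_that("pooled ANOVA flags planted structure and respects m = 1", {
  gd <- gly_data(seed = 47)
  # a response that is purely an assay-salinity effect: S1 dominates
  pure <- gd$measurements
  pure$conc_est <- (0.5e-12 + 1e-12 * pure$s1_M) * pure$density_est +
    pure$conc_se * withr::with_seed(8, rnorm(nrow(pure)))
  imps_pure <- impute_datasets(pure, m = 10, seed = 4)
  av_pure <- glycerol_anova(imps_pure, gd$moments, "total")
  expect_true(all(c("S1", "S1:m_rho2") %in% av_pure$term))
  expect_equal(av_pure$term[which.max(av_pure$F)], "S1")
  # a strongly planted rho2 x assay-salinity interaction is detected when
  # measurement noise is at replicate-averaged precision (the fully
  # crossed interaction model dilutes marginal blocks badly with only 8
  # populations, so both signal and precision matter); the raised
  # baseline keeps the strong effect clear of the positivity floor
  gd_hi <- gly_data(seed = 47, conc_cv = 0.02, g_base = 2e-12,
                    glycerol_effects = c(rho2 = -0.3e-12,
                                         rho2_s1 = -0.6e-12))
  imps <- impute_datasets(gd_hi$measurements, m = 20, seed = 3)
  av <- glycerol_anova(imps, gd_hi$moments, "intracellular")
  expect_lt(av$p[av$term == "S1:m_rho2"], 0.05)
  # m = 1 equals the ordinary single-dataset ANOVA
  expect_warning(av1 <- glycerol_anova(imps[[1]], gd$moments,
                                       "intracellular"), "degenerate")
  f1 <- stats::lm(G_est ~ S0 * S1 * Time * m_rho2 + m_rho + m_mean + m_var,
                  data = acclimtol:::glycerol_model_frame(
                    per_cell_table(imps[[1]]), gd$moments, "intracellular"))
  w <- car_free_wald(f1, "S1")
  expect_equal(av1$F[av1$term == "S1"], w$F, tolerance = 1e-10)
  expect_equal(av1$p[av1$term == "S1"], w$p, tolerance = 1e-10)
})

test_that("null glycerol data yields no significant moment terms", {
  gd <- gly_data(seed = 53, glycerol_effects = c(rho2 = 0, rho2_s1 = 0))
  imps <- impute_datasets(gd$measurements, m = 15, seed = 9)
  av <- glycerol_anova(imps, gd$moments, "intracellular")
  moment_terms <- grepl("m_rho|m_mean|m_var", av$term)
  expect_true(all(av$p_bonferroni[moment_terms] > 0.05))
})

test_that("plasticity variance is the among-environment variance", {
  expect_equal(plasticity_variance(c(3, 3, 3)), 0)
  expect_equal(plasticity_variance(c(2, 6)), (2 - 6)^2 / 2)
  set.seed(15)
  x <- rnorm(7)
  expect_equal(plasticity_variance(x), sum((x - mean(x))^2) / 6)
  expect_error(plasticity_variance(1), ">= 2")
  gd <- gly_data(seed = 59)
  pc <- per_cell_table(gd$measurements)
  pv <- plasticity_variance_table(pc)
  # one record per population x acclimation x time x compartment
  expect_equal(nrow(pv), 8 * 2 * 3 * 3)
  expect_true(all(pv$var_G >= 0))
})
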