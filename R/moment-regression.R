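# Regression of tolerance-surface parameters on environmental moments.
#
# Each surface parameter theta of population i is modeled as a linear
# function of the realized moments of its evolutionary salinity regime:
#   theta_i = theta_int + theta_mean * mean_i + theta_var * var_i
#             + theta_rho * rho_i + theta_rho2 * rho2_i
# with tolerance breadths entering on the 1/sigma^2 scale. The full
# hierarchical model is fitted as one joint likelihood over all
# populations' count data.

#' Reference moment-effect estimates
#'
#' Published estimates of the effect of the evolutionary regime's mean,
#' variance, autocorrelation, and predictability (squared autocorrelation)
#' on each tolerance-surface parameter, as a 5 x 10 matrix (moments x
#' parameters; breadths on the 1/sigma^2 scale). The published row for the
#' mortality interaction coefficient `delta01` is a known transcription
#' duplicate of the `delta1` row, so it is represented here by the
#' reference white-noise estimate (-0.444) with no moment dependence.
#'
#' @return Numeric matrix with rownames
#'   `c("intercept", "mean", "var", "rho", "rho2")` and colnames
#'   `c("r_max", "mu0", "mu1", "inv_sigma0_sq", "inv_sigma1_sq", "k",
#'   "delta", "delta0", "delta1", "delta01")`.
#' @export
reference_moment_effects <- function() {
  eff <- rbind(
    r_max         = c(0.949, 0.043, 0.193, -0.198, 0.378),
    mu0           = c(2.865, 0.129, -0.243, 1.393, -2.749),
    mu1           = c(0.993, 0.201, -0.933, 3.747, -6.658),
    inv_sigma0_sq = c(0.086, 0.009, 0.015, -0.004, 0.012),
    inv_sigma1_sq = c(0.080, -0.002, -0.020, 0.056, -0.094),
    k             = c(0.414, 0.040, 0.185, -0.831, 1.573),
    delta         = c(-3.774, 0.003, 0.058, 0.823, -1.349),
    delta0        = c(-0.009, -0.143, 0.002, -0.199, 0.212),
    delta1        = c(0.946, 0.045, 0.110, -0.377, 0.587),
    delta01       = c(-0.444, 0, 0, 0, 0)
  )
  colnames(eff) <- MOMENT_NAMES
  t(eff)[MOMENT_NAMES, HIER_PARAM_NAMES]
}

#' Predict one surface parameter from environmental moments
#'
#' Linear combination `theta_int + theta_mean * mean + theta_var * var +
#' theta_rho * rho + theta_rho2 * rho2`.
#'
#' @param effects Numeric vector of length 5 in the order `(intercept,
#'   mean, var, rho, rho2)` (names, if present, are checked).
#' @param moments A `salinity_moments` object, or a list/data.frame with
#'   `mean`, `variance`, `rho`, `rho2` (vectorized).
#' @return Predicted parameter value(s).
#' @export
predict_parameter <- function(effects, moments) {
  effects <- unlist(effects)
  stopifnot(length(effects) == 5)
  if (!is.null(names(effects)) && all(nzchar(names(effects)))) {
    stopifnot(identical(names(effects), MOMENT_NAMES))
  }
  rho <- moments$rho
  rho2 <- moments$rho2
  rho[is.na(rho)] <- 0
  rho2[is.na(rho2)] <- 0
  unname(effects[1] + effects[2] * moments$mean +
           effects[3] * moments$variance + effects[4] * rho +
           effects[5] * rho2)
}

# Population-level parameter matrix (n_pop x 10) implied by an effects
# matrix and a moments table.
population_params <- function(effects, moments_table) {
  X <- moments_design(moments_table)
  P <- X %*% effects
  colnames(P) <- HIER_PARAM_NAMES
  P
}

# Moments table -> regressor matrix (intercept, mean, var, rho, rho2).
# Constant regimes (undefined autocorrelation) enter with rho = rho2 = 0.
moments_design <- function(moments_table) {
  mt <- as.data.frame(moments_table)
  need <- c("population_id", "mean_M", "var_M2", "rho", "rho2")
  missing_cols <- setdiff(need, names(mt))
  if (length(missing_cols) > 0) {
    stop("data-schema error: moments table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rho <- ifelse(is.na(mt$rho), 0, mt$rho)
  rho2 <- ifelse(is.na(mt$rho2), 0, mt$rho2)
  X <- cbind(intercept = 1, mean = mt$mean_M, var = mt$var_M2,
             rho = rho, rho2 = rho2)
  rownames(X) <- mt$population_id
  X
}

#' Fit the hierarchical moment-regression model
#'
#' One joint maximum-likelihood fit in which every tolerance-surface
#' parameter of every population is a linear function of that population's
#' realized environmental moments (breadths on the 1/sigma^2 scale), and
#' all populations' count observations share the two dispersion
#' parameters. Standard errors come from the observed information at the
#' optimum; Wald p-values are reported per effect.
#'
#' @param observations Count table covering all populations (see
#'   [fit_surface()] for columns).
#' @param moments Moments table: `population_id`, `mean_M`, `var_M2`,
#'   `rho`, `rho2`. Constant regimes may carry `NA` autocorrelation; they
#'   enter with rho = rho2 = 0.
#' @param init Optional named list `beta` (5 x 10), `log_nb_size`,
#'   `log_bb_prec`. By default the intercept row is seeded from a pooled
#'   single-surface fit and all moment effects start at zero.
#' @param seed Integer seed for multi-start jitter.
#' @param n_starts Number of optimizer starts.
#' @param drop Character subset of `c("mean", "var", "rho", "rho2")`:
#'   moment rows fixed at zero (for likelihood-ratio comparisons).
#' @return Object of class `hierarchical_fit`: `effects` and `se`
#'   (5 x 10 matrices), `dispersion`, `loglik`, `n_params`,
#'   `n_populations`, `n_obs`, `converged`, `dropped`.
#' @export
fit_hierarchical <- function(observations, moments, init = NULL, seed = 1,
                             n_starts = 2, drop = NULL) {
  counts <- validate_counts(observations)
  X <- moments_design(moments)
  n_pop <- nrow(X)
  if (n_pop < 6) {
    stop("identifiability error: need >= 6 populations, got ", n_pop)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinearity error: moment design is rank-deficient in column(s): ",
         paste(dropped_cols, collapse = ", "))
  }
  pop_index <- match(counts$population_id, rownames(X))
  if (anyNA(pop_index)) {
    stop("data-schema error: count table has population_id absent from moments table")
  }
  if (!is.null(drop)) {
    bad <- setdiff(drop, MOMENT_NAMES[-1])
    if (length(bad) > 0) stop("unknown moment(s) in drop: ",
                              paste(bad, collapse = ", "))
  }
  data <- tmb_data(counts, X = X, pop_index = pop_index, model_form = 1L)
  if (is.null(init)) {
    pooled <- fit_surface(counts, seed = seed, n_starts = 1)
    e <- pooled$estimates
    beta <- matrix(0, 5, 10, dimnames = list(MOMENT_NAMES, HIER_PARAM_NAMES))
    beta[1, ] <- c(e[["r_max"]], e[["mu0"]], e[["mu1"]],
                   1 / e[["sigma0"]]^2, 1 / e[["sigma1"]]^2, e[["k"]],
                   e[["delta"]], e[["delta0"]], e[["delta1"]],
                   e[["delta01"]])
    init <- list(beta = beta, log_nb_size = log(e[["nb_size"]]),
                 log_bb_prec = log(e[["bb_precision"]]))
  }
  map <- NULL
  if (!is.null(drop) && length(drop) > 0) {
    map_beta <- matrix(seq_len(50), 5, 10)
    map_beta[match(drop, MOMENT_NAMES), ] <- NA
    init$beta[match(drop, MOMENT_NAMES), ] <- 0
    map <- list(beta = factor(map_beta))
  }
  obj <- TMB::MakeADFun(data = data, parameters = init, map = map,
                        DLL = "acclimtol", hessian = TRUE, silent = TRUE)
  start0 <- obj$par
  best <- NULL
  for (j in seq_len(n_starts)) {
    start <- if (j == 1) start0 else {
      jseed <- as.integer((as.numeric(seed) + 1000 + j) %% 2147483646)
      start0 + withr::with_seed(jseed,
                                stats::rnorm(length(start0), 0, 0.02))
    }
    res <- tryCatch(optimize_tmb(obj, start, iter.max = 2000),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective - 1e-8) best <- res
  }
  if (is.null(best)) stop("optimization failed from every start")
  rep <- tryCatch(TMB::sdreport(obj, par.fixed = best$par,
                                getReportCovariance = FALSE),
                  error = function(e) NULL)
  eff <- matrix(0, 5, 10, dimnames = list(MOMENT_NAMES, HIER_PARAM_NAMES))
  se <- matrix(NA_real_, 5, 10,
               dimnames = list(MOMENT_NAMES, HIER_PARAM_NAMES))
  free <- matrix(TRUE, 5, 10)
  if (!is.null(drop) && length(drop) > 0) {
    free[match(drop, MOMENT_NAMES), ] <- FALSE
  }
  par_beta <- best$par[names(best$par) == "beta"]
  eff[free] <- par_beta
  if (!is.null(rep)) {
    se_all <- sqrt(diag(rep$cov.fixed))
    se[free] <- se_all[names(best$par) == "beta"]
  }
  log_disp <- best$par[names(best$par) != "beta"]
  grad_norm <- max(abs(best$gradient))
  tryCatch(TMB::FreeADFun(obj), error = function(e) NULL)
  structure(
    list(
      effects = eff,
      se = se,
      dispersion = dispersion_params(exp(log_disp[[1]]), exp(log_disp[[2]])),
      loglik = -best$objective,
      n_params = length(best$par),
      n_populations = n_pop,
      n_obs = nrow(counts),
      converged = is.finite(grad_norm) && grad_norm < 1e-5,
      gradient_norm = grad_norm,
      dropped = drop
    ),
    class = "hierarchical_fit"
  )
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  cat("Hierarchical tolerance-surface fit\n")
  cat(sprintf("  %d populations, %d obs, loglik %.2f, converged %s\n",
              x$n_populations, x$n_obs, x$loglik, x$converged))
  if (!is.null(x$dropped)) {
    cat("  dropped moment effects:", paste(x$dropped, collapse = ", "), "\n")
  }
  print(round(x$effects, 3))
  invisible(x)
}

#' Effects table with Wald and Bonferroni inference
#'
#' Long-format table of moment effects on each surface parameter, with
#' Wald z-tests per effect and Bonferroni correction over the
#' `m` non-intercept comparisons (default 40 = 4 moments x 10 parameters).
#'
#' @param fit A `hierarchical_fit`.
#' @param m Number of comparisons for the Bonferroni correction.
#' @return Tibble: `parameter`, `moment`, `estimate`, `se`, `p`,
#'   `p_bonferroni` (`NA` for intercept rows).
#' @export
effects_table <- function(fit, m = 40) {
  long <- expand.grid(moment = MOMENT_NAMES, parameter = HIER_PARAM_NAMES,
                      stringsAsFactors = FALSE)
  long$estimate <- as.vector(fit$effects)
  long$se <- as.vector(fit$se)
  w <- wald_test(long$estimate, pmax(long$se, .Machine$double.eps))
  long$p <- w$p
  is_eff <- long$moment != "intercept"
  long$p_bonferroni <- NA_real_
  long$p_bonferroni[is_eff] <- bonferroni(long$p[is_eff], m = m)
  tibble::as_tibble(long[, c("parameter", "moment", "estimate", "se", "p",
                             "p_bonferroni")])
}

#' Likelihood-ratio test between nested fits
#'
#' @param full,reduced Fit objects with `loglik` and `n_params` elements
#'   (e.g. two [fit_hierarchical()] results differing by dropped moment
#'   rows), or plain lists with those elements.
#' @return List with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  df <- full$n_params - reduced$n_params
  if (df <= 0) stop("non-nested models: full must have more parameters")
  if (full$loglik < reduced$loglik - 1e-6) {
    stop("optimization-failure: full model log-likelihood below reduced model's")
  }
  stat <- max(2 * (full$loglik - reduced$loglik), 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Wald z-test
#'
#' @param estimate,se Numeric vectors; `se` must be > 0.
#' @return List with `z` and two-sided normal `p`.
#' @export
wald_test <- function(estimate, se) {
  if (any(!is.na(se) & se <= 0)) stop("standard errors must be > 0")
  z <- estimate / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param m Number of comparisons, at least `length(p_values)`.
#' @return Adjusted p-values `pmin(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) stop("m must be >= number of tests")
  pmin(1, m * p_values)
}

#' Per-transfer regression of growth and mortality on moments
#'
#' For one cross-salinity design cell, regresses final live counts on the
#' four environmental-moment regressors: a negative-binomial (nbinom2,
#' log link) regression with offset `log(n0)` for total growth `R`, the
#' same with an additional offset `log(1 - d_hat)` for apparent growth
#' `r`, and a beta-binomial (logit link) regression for the death ratio
#' `d`. Count-scale coefficients are divided by the assay duration so the
#' growth effects are per day.
#'
#' @param cell_counts Count table restricted to one `(s0_M, s1_M)` cell,
#'   one or more rows per population.
#' @param moments Moments table (see [fit_hierarchical()]).
#' @return Tibble: `response` (`"R"`, `"r"`, `"d"`), `moment`, `estimate`,
#'   `se`, `p`.
#' @export
per_transfer_regression <- function(cell_counts, moments) {
  counts <- validate_counts(cell_counts)
  if (length(unique(paste(counts$s0_M, counts$s1_M))) != 1) {
    stop("cell_counts must cover exactly one (s0, s1) design cell")
  }
  if (length(unique(counts$population_id)) < 6) {
    stop("need >= 6 populations in the design cell")
  }
  mt <- as.data.frame(moments)
  X <- moments_design(mt)
  dat <- merge(counts, data.frame(population_id = rownames(X),
                                  m_mean = X[, "mean"], m_var = X[, "var"],
                                  m_rho = X[, "rho"], m_rho2 = X[, "rho2"]),
               by = "population_id")
  if (all(dat$n_t == 0)) {
    warning("degenerate cell: all final counts zero; effects undefined")
    return(tibble::tibble(response = character(), moment = character(),
                          estimate = numeric(), se = numeric(),
                          p = numeric()))
  }
  t_days <- dat$t_days[1]
  dat$trials <- pmax(round(dat$n0), 1)
  dat$dead <- pmin(pmax(dat$d_t - dat$d0, 0), dat$trials)
  dat$fhat <- pmin(dat$dead / dat$trials, 0.95)
  dat$off_R <- log(dat$n0)
  dat$off_r <- log(dat$n0) + log1p(-dat$fhat)
  moment_terms <- ~ m_mean + m_var + m_rho + m_rho2
  extract <- function(fit, response, scale = 1) {
    cf <- summary(fit)$coefficients$cond
    tibble::tibble(
      response = response,
      moment = MOMENT_NAMES,
      estimate = cf[, "Estimate"] * scale,
      se = cf[, "Std. Error"] * abs(scale),
      p = cf[, "Pr(>|z|)"]
    )
  }
  fit_R <- glmmTMB::glmmTMB(
    stats::update(moment_terms, n_t ~ . + offset(off_R)),
    family = glmmTMB::nbinom2(), data = dat)
  fit_r <- glmmTMB::glmmTMB(
    stats::update(moment_terms, n_t ~ . + offset(off_r)),
    family = glmmTMB::nbinom2(), data = dat)
  fit_d <- glmmTMB::glmmTMB(
    stats::update(moment_terms, cbind(dead, trials - dead) ~ .),
    family = glmmTMB::betabinomial(), data = dat)
  rbind(extract(fit_R, "R", scale = 1 / t_days),
        extract(fit_r, "r", scale = 1 / t_days),
        extract(fit_d, "d"))
}
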