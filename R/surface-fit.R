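# Maximum-likelihood fitting of the acclimated tolerance surface.

# ---- observation model -------------------------------------------------

#' Beta-binomial log-pmf (mean/precision parameterization)
#'
#' Probability of `y` successes in `n` trials when the success probability
#' is Beta-distributed with mean `d` and precision `phi`, i.e.
#' `Beta(d * phi, (1 - d) * phi)` mixing.
#'
#' @param y,n Counts (vectorized).
#' @param d Mean probability in (0, 1).
#' @param phi Precision, > 0.
#' @param log If `TRUE` return the log-pmf.
#' @return Numeric vector.
#' @export
dbetabinom <- function(y, n, d, phi, log = FALSE) {
  stopifnot(all(phi > 0), all(d > 0 & d < 1))
  a <- d * phi
  b <- (1 - d) * phi
  lp <- lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
  lp[y < 0 | y > n] <- -Inf
  if (log) lp else exp(lp)
}

#' Log-likelihood contribution of one or more count observations
#'
#' For each assay well: the negative-binomial log-pmf of the final live
#' count around `n0 * (1 - d) * exp(r * t)` (variance `mu + mu^2/nb_size`),
#' plus the beta-binomial log-pmf of the dead-cell increment
#' `max(d_t - d0, 0)` with `round(n0)` trials, mean `d` and precision
#' `bb_precision`. `r` and `d` are evaluated from the growth and mortality
#' surfaces at the observation's `(s0, s1)`. Wells with zero trials
#' contribute no dead-count term.
#'
#' @param obs Data frame (or one-row list) with columns `s0_M`, `s1_M`,
#'   `n0`, `n_t`, `d0`, `d_t`, `t_days`.
#' @param g A `growth_params` object.
#' @param m A `mortality_params` object.
#' @param disp A `dispersion_params` object.
#' @return Numeric vector of per-observation log-likelihood contributions.
#' @export
observation_loglik <- function(obs, g, m, disp) {
  obs <- as.data.frame(obs)
  if (any(obs$n0 <= 0)) stop("guard error: initial density must be > 0")
  r <- growth_rate(g, obs$s0_M, obs$s1_M)
  d <- mortality_ratio(m, obs$s0_M, obs$s1_M)
  mu <- obs$n0 * (1 - d) * exp(r * obs$t_days)
  if (any(mu <= 0)) stop("guard error: non-positive expected live count")
  ll <- stats::dnbinom(obs$n_t, mu = mu, size = disp$nb_size, log = TRUE)
  trials <- round(obs$n0)
  dead <- pmax(obs$d_t - obs$d0, 0)
  has_trials <- trials > 0
  ll[has_trials] <- ll[has_trials] +
    dbetabinom(dead[has_trials], trials[has_trials], d[has_trials],
               disp$bb_precision, log = TRUE)
  ll
}

# ---- data plumbing -----------------------------------------------------

COUNT_COLUMNS <- c("population_id", "s0_M", "s1_M", "replicate", "n0",
                   "n_t", "d0", "d_t", "t_days")

validate_counts <- function(counts) {
  counts <- as.data.frame(counts)
  missing_cols <- setdiff(COUNT_COLUMNS, names(counts))
  if (length(missing_cols) > 0) {
    stop("data-schema error: count table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(counts) == 0) stop("data-schema error: empty count table")
  num <- c("s0_M", "s1_M", "n0", "n_t", "d0", "d_t", "t_days")
  bad <- num[!vapply(counts[num], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("data-schema error: non-numeric column(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(counts$n_t < 0 | counts$d_t < 0 | counts$d0 < 0)) {
    stop("data-schema error: negative counts")
  }
  if (any(counts$t_days <= 0)) stop("data-schema error: t_days must be > 0")
  counts
}

# Assemble the data list consumed by the compiled likelihood.
tmb_data <- function(counts, X, pop_index, model_form) {
  list(
    model_form = as.integer(model_form),
    X = X,
    pop = as.integer(pop_index) - 1L,
    s0 = counts$s0_M,
    s1 = counts$s1_M,
    n0 = counts$n0,
    nt = counts$n_t,
    dead = pmax(counts$d_t - counts$d0, 0),
    trials = round(counts$n0),
    tdur = counts$t_days
  )
}

# Moment-based starting values: a quadratic regression of raw apparent
# growth maps onto the surface parameters; a quasibinomial logit
# regression of raw dead fractions seeds the mortality coefficients.
moment_init <- function(counts) {
  trials <- pmax(round(counts$n0), 1)
  dead <- pmax(counts$d_t - counts$d0, 0)
  fhat <- pmin(dead / trials, 0.95)
  R_obs <- log(pmax(counts$n_t, 0.5) / counts$n0) / counts$t_days
  r_obs <- R_obs - log1p(-fhat) / counts$t_days
  fallback <- c(r_max = max(r_obs), mu0 = 2.4, mu1 = 1.5,
                log_sigma0 = log(3), log_sigma1 = log(4), k = 0.3)
  quad <- tryCatch({
    fit <- stats::lm(r_obs ~ s1_M + I(s1_M^2) + s0_M + I(s0_M^2) +
                       s0_M:s1_M, data = counts)
    cf <- stats::coef(fit)
    inv1 <- -cf[["I(s1_M^2)"]]
    inv0 <- -cf[["I(s0_M^2)"]]
    if (!is.finite(inv0) || !is.finite(inv1) || inv0 <= 0 || inv1 <= 0) {
      fallback
    } else {
      k <- cf[["s0_M:s1_M"]] / (2 * inv1)
      A <- rbind(c(-2 * k * inv1, 2 * inv1), c(2 * inv0, -2 * k * inv1))
      mu <- solve(A, c(cf[["s1_M"]], cf[["s0_M"]]))
      r_max <- stats::predict(fit, data.frame(s0_M = mu[1], s1_M = mu[2]))
      c(r_max = unname(r_max), mu0 = mu[1], mu1 = mu[2],
        log_sigma0 = -0.5 * log(inv0), log_sigma1 = -0.5 * log(inv1),
        k = k)
    }
  }, error = function(e) fallback)
  if (!all(is.finite(quad))) quad <- fallback
  delta_init <- tryCatch({
    gl <- stats::glm(cbind(dead, trials - dead) ~ s0_M * s1_M,
                     family = stats::quasibinomial(), data = counts)
    cf <- stats::coef(gl)
    ifelse(is.finite(cf), cf, c(-3, 0, 0.5, 0))
  }, error = function(e) c(-3, 0, 0.5, 0))
  beta <- matrix(c(quad[["r_max"]], quad[["mu0"]], quad[["mu1"]],
                   quad[["log_sigma0"]], quad[["log_sigma1"]], quad[["k"]],
                   delta_init[1], delta_init[2], delta_init[3],
                   delta_init[4]),
                 nrow = 1)
  list(beta = beta, log_nb_size = log(10), log_bb_prec = log(5))
}

# nlminb followed by damped-Newton polishing. The Hessian is exact
# (second-order autodiff) when the objective provides it.
optimize_tmb <- function(obj, start, iter.max = 1000) {
  # exact Hessian reserved for the Newton polish: quasi-Newton reaches
  # the neighborhood of the optimum faster without per-iteration Hessians
  hess <- if (!is.null(obj$he)) obj$he else NULL
  o <- stats::nlminb(start, obj$fn, obj$gr,
                     control = list(iter.max = iter.max,
                                    eval.max = 2 * iter.max))
  par <- o$par
  g_prev <- Inf
  for (i in 1:20) {
    gr <- as.numeric(obj$gr(par))
    g_now <- max(abs(gr))
    if (g_now < 1e-8) break
    if (g_now >= g_prev * 0.999) break  # stalled
    g_prev <- g_now
    H <- tryCatch(
      if (!is.null(hess)) hess(par) else
        stats::optimHess(par, obj$fn, obj$gr),
      error = function(e) NULL)
    if (is.null(H)) break
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    f0 <- obj$fn(par)
    improved <- FALSE
    lambda <- 1
    for (h in 1:8) {
      cand <- par - lambda * step
      fc <- obj$fn(cand)
      # near the optimum f changes are at the rounding floor; accept on
      # gradient-norm decrease as long as f does not genuinely rise
      if (is.finite(fc) && fc <= f0 + 1e-6 * max(1, abs(f0)) &&
          max(abs(obj$gr(cand))) < g_now) {
        par <- cand
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      # fall back to a fresh quasi-Newton pass from the current point
      o2 <- stats::nlminb(par, obj$fn, obj$gr,
                          control = list(iter.max = iter.max))
      if (is.finite(o2$objective) && o2$objective <= f0 + 1e-10) {
        par <- o2$par
      } else break
    }
  }
  list(par = par, objective = obj$fn(par),
       gradient = as.numeric(obj$gr(par)), iterations = o$iterations,
       message = o$message)
}

# ---- surface fit -------------------------------------------------------

#' Fit an acclimated tolerance surface by maximum likelihood
#'
#' Jointly maximizes the negative-binomial live-count and beta-binomial
#' dead-count likelihood over the 10 surface parameters and 2 dispersions.
#' Breadths and dispersions are log-transformed for optimization; standard
#' errors come from the inverse observed-information matrix at the optimum
#' (delta method for back-transformed parameters). Gradients are exact
#' (automatic differentiation); optimization restarts from several
#' jittered versions of a moment-based initialization and keeps the best.
#'
#' @param observations Count table with columns `population_id`, `s0_M`,
#'   `s1_M`, `replicate`, `n0`, `n_t`, `d0`, `d_t`, `t_days`. All
#'   observations are pooled onto one shared surface.
#' @param init Optional list with elements `beta` (1 x 10 matrix:
#'   `r_max, mu0, mu1, log(sigma0), log(sigma1), k, delta, delta0, delta1,
#'   delta01`), `log_nb_size`, `log_bb_prec`; replaces the moment-based
#'   start.
#' @param seed Integer seed controlling the multi-start jitter.
#' @param n_starts Number of optimizer starts (first is unjittered).
#' @return Object of class `surface_fit`: `growth`, `mortality`,
#'   `dispersion` parameter objects, named `estimates` and `se`, `loglik`,
#'   `n_obs`, `converged` (max gradient on the transformed scale < 1e-5),
#'   and optimizer diagnostics.
#' @export
fit_surface <- function(observations, init = NULL, seed = 1, n_starts = 5) {
  counts <- validate_counts(observations)
  if (length(unique(counts$s0_M)) < 3 || length(unique(counts$s1_M)) < 3) {
    stop("identifiability error: need >= 3 distinct acclimation and assay salinities")
  }
  data <- tmb_data(counts, X = matrix(1, 1, 1),
                   pop_index = rep(1L, nrow(counts)), model_form = 0L)
  pars <- if (is.null(init)) moment_init(counts) else init
  obj <- TMB::MakeADFun(data = data, parameters = pars, DLL = "acclimtol",
                        hessian = TRUE, silent = TRUE)
  start0 <- obj$par
  jitter_sd <- c(rep(0.25, 3), rep(0.2, 2), 0.25, rep(0.3, 4), 0.5, 0.5)
  best <- NULL
  for (j in seq_len(n_starts)) {
    start <- if (j == 1) start0 else {
      jseed <- as.integer((as.numeric(seed) + j) %% 2147483646)
      start0 + withr::with_seed(jseed,
                                stats::rnorm(length(start0), 0, jitter_sd))
    }
    res <- tryCatch(optimize_tmb(obj, start), error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective - 1e-8) best <- res
  }
  if (is.null(best)) {
    stop("optimization failed from every start")
  }
  fit <- build_surface_fit(obj, best, n_obs = nrow(counts))
  # release the autodiff tapes now rather than at garbage collection;
  # repeated fits otherwise accumulate large C++ allocations
  tryCatch(TMB::FreeADFun(obj), error = function(e) NULL)
  fit
}

build_surface_fit <- function(obj, best, n_obs) {
  rep <- tryCatch(TMB::sdreport(obj, par.fixed = best$par,
                                getReportCovariance = FALSE),
                  error = function(e) NULL)
  par <- best$par
  beta <- par[seq_len(10)]
  est <- c(beta[1:3], exp(beta[4:5]), beta[6:10],
           exp(par[11]), exp(par[12]))
  names(est) <- c("r_max", "mu0", "mu1", "sigma0", "sigma1", "k",
                  "delta", "delta0", "delta1", "delta01",
                  "nb_size", "bb_precision")
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  if (!is.null(rep)) {
    se_t <- sqrt(diag(rep$cov.fixed))
    se[c("r_max", "mu0", "mu1")] <- se_t[1:3]
    se[c("k", "delta", "delta0", "delta1", "delta01")] <- se_t[6:10]
    adr <- summary(rep, select = "report")
    se["sigma0"] <- adr["sigma0", "Std. Error"]
    se["sigma1"] <- adr["sigma1", "Std. Error"]
    se["nb_size"] <- adr["nb_size", "Std. Error"]
    se["bb_precision"] <- adr["bb_prec", "Std. Error"]
  }
  grad_norm <- max(abs(best$gradient))
  structure(
    list(
      growth = growth_params(est[["r_max"]], est[["mu0"]], est[["mu1"]],
                             est[["sigma0"]], est[["sigma1"]], est[["k"]]),
      mortality = mortality_params(est[["delta"]], est[["delta0"]],
                                   est[["delta1"]], est[["delta01"]]),
      dispersion = dispersion_params(est[["nb_size"]],
                                     est[["bb_precision"]]),
      estimates = est,
      se = se,
      loglik = -best$objective,
      n_obs = n_obs,
      converged = is.finite(grad_norm) && grad_norm < 1e-5,
      gradient_norm = grad_norm,
      iterations = best$iterations,
      message = best$message
    ),
    class = "surface_fit"
  )
}

#' @export
print.surface_fit <- function(x, ...) {
  cat("Acclimated tolerance surface fit\n")
  cat(sprintf("  n_obs %d  loglik %.2f  converged %s (max|grad| %.2e)\n",
              x$n_obs, x$loglik, x$converged, x$gradient_norm))
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Tidy a surface fit into a parameter table
#'
#' @param fit A `surface_fit`.
#' @return Tibble with columns `parameter`, `estimate`, `se`.
#' @export
surface_fit_table <- function(fit) {
  tibble::tibble(parameter = names(fit$estimates),
                 estimate = unname(fit$estimates),
                 se = unname(fit$se))
}
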