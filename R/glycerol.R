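# Glycerol plasticity: per-cell scaling, compartment differencing,
# multiple imputation, pooled regression and ANOVA.

GLYCEROL_COLUMNS <- c("population_id", "s0_M", "s1_M", "time_h",
                      "compartment", "conc_est", "conc_se", "density_est",
                      "density_se")
GLYCEROL_KEYS <- c("population_id", "s0_M", "s1_M", "time_h")

validate_glycerol <- function(tab) {
  tab <- as.data.frame(tab)
  missing_cols <- setdiff(GLYCEROL_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    stop("data-schema error: glycerol table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(tab$conc_se < 0 | tab$density_se < 0)) {
    stop("standard errors must be >= 0")
  }
  if (any(tab$density_est <= 0)) stop("density estimates must be > 0")
  tab
}

#' Per-cell scaling of a concentration with delta-method error
#'
#' `G = C / N` with `SE(G) = sqrt(var(C)/N^2 + C^2 var(N)/N^4)`, assuming
#' independent errors in concentration and cell density.
#'
#' @param conc_est,conc_se Concentration estimate and SE (mol/mL),
#'   vectorized.
#' @param density_est,density_se Cell density estimate and SE (cells/mL);
#'   `density_est` must be > 0.
#' @return Tibble with columns `est`, `se` (mol/cell).
#' @export
per_cell <- function(conc_est, conc_se, density_est, density_se) {
  if (any(density_est <= 0)) stop("density must be > 0")
  if (any(conc_se < 0 | density_se < 0)) stop("SEs must be >= 0")
  est <- conc_est / density_est
  se <- sqrt(conc_se^2 / density_est^2 +
               conc_est^2 * density_se^2 / density_est^4)
  tibble::tibble(est = est, se = se)
}

#' Intracellular concentration by compartment differencing
#'
#' Subtracts the extracellular from the total glycerol concentration for
#' every matched (population, transfer, time) key, with
#' `SE = sqrt(se_total^2 + se_extracellular^2)`. Negative estimates
#' (measurement noise) are retained and flagged, not truncated.
#'
#' @param measurements Glycerol table with `compartment` values `"total"`
#'   and `"extracellular"` (columns as in [generate_glycerol_data()]).
#' @return The input table with intracellular rows appended
#'   (`compartment = "intracellular"`, density columns copied from the
#'   total rows) and a logical `negative_intracellular` marker.
#' @export
intracellular <- function(measurements) {
  tab <- validate_glycerol(measurements)
  tot <- tab[tab$compartment == "total", ]
  ext <- tab[tab$compartment == "extracellular", ]
  key <- function(d) do.call(paste, c(d[GLYCEROL_KEYS], sep = "\r"))
  if (nrow(tot) != nrow(ext) || !setequal(key(tot), key(ext))) {
    stop("pairing error: total and extracellular rows do not match one-to-one")
  }
  ext <- ext[match(key(tot), key(ext)), ]
  intra <- tot
  intra$compartment <- "intracellular"
  intra$conc_est <- tot$conc_est - ext$conc_est
  intra$conc_se <- sqrt(tot$conc_se^2 + ext$conc_se^2)
  out <- rbind(tab, intra)
  out$negative_intracellular <- out$compartment == "intracellular" &
    out$conc_est < 0
  tibble::as_tibble(out)
}

#' Scale a glycerol table to per-cell amounts
#'
#' Applies [intracellular()] differencing then [per_cell()] scaling,
#' yielding the per-cell glycerol amount `G` (mol/cell) with delta-method
#' standard errors for all three compartments.
#'
#' @param measurements Glycerol measurement table.
#' @return Tibble keyed by population/transfer/time/compartment with
#'   `G_est`, `G_se`.
#' @export
per_cell_table <- function(measurements) {
  tab <- intracellular(measurements)
  g <- per_cell(tab$conc_est, tab$conc_se, tab$density_est, tab$density_se)
  tibble::tibble(
    population_id = tab$population_id, s0_M = tab$s0_M, s1_M = tab$s1_M,
    time_h = tab$time_h, compartment = tab$compartment,
    G_est = g$est, G_se = g$se
  )
}

#' Multiply-impute a glycerol measurement table
#'
#' Generates `m` perturbed copies of the table in which every
#' concentration estimate is replaced by a draw from
#' `Normal(conc_est, conc_se)`. Imputation is applied on the concentration
#' scale, before per-cell scaling and compartment differencing, so
#' nonlinear error propagation is captured within each imputation.
#' Deterministic given the seed.
#'
#' @param measurements Glycerol measurement table.
#' @param m Number of imputed datasets (>= 2 for pooling; the reference
#'   analysis uses 1000).
#' @param seed Integer seed.
#' @return List of `m` tables.
#' @export
impute_datasets <- function(measurements, m = 1000, seed) {
  tab <- validate_glycerol(measurements)
  if (m < 1) stop("m must be >= 1")
  if (missing(seed)) stop("seed is required")
  n <- nrow(tab)
  draws <- withr::with_seed(as.integer(seed),
                            matrix(stats::rnorm(n * m), n, m))
  lapply(seq_len(m), function(i) {
    out <- tab
    out$conc_est <- tab$conc_est + tab$conc_se * draws[, i]
    out
  })
}

# ---- Rubin / D1 pooling ------------------------------------------------

#' Pool scalar estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the across-imputation mean; total variance is
#' within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance, with Rubin's degrees of freedom.
#'
#' @param est Matrix of estimates, one row per quantity, one column per
#'   imputation (a vector is treated as one quantity).
#' @param se Matching matrix of standard errors.
#' @return Tibble: `estimate`, `se`, `df`, `p` (two-sided t-test of zero).
#' @export
rubin_pool <- function(est, se) {
  est <- rbind(est)
  se <- rbind(se)
  m <- ncol(est)
  qbar <- rowMeans(est)
  ubar <- rowMeans(se^2)
  b <- if (m > 1) apply(est, 1, stats::var) else 0
  total <- ubar + (1 + 1 / m) * b
  df <- ifelse(b > 0, (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2, Inf)
  stat <- qbar / sqrt(total)
  tibble::tibble(estimate = qbar, se = sqrt(total), df = df,
                 p = 2 * stats::pt(-abs(stat), df = df))
}

# D1 multivariate Wald pooling for a block of k coefficients across m
# imputations: est is k x m, vcov_list a list of m k x k matrices.
d1_pool <- function(est, vcov_list) {
  est <- rbind(est)
  k <- nrow(est)
  m <- ncol(est)
  qbar <- rowMeans(est)
  ubar <- Reduce(`+`, vcov_list) / m
  if (m == 1) {
    stat <- drop(t(qbar) %*% solve(ubar, qbar)) / k
    return(list(F = stat, df1 = k, df2 = Inf,
                p = stats::pf(stat, k, 1e6, lower.tail = FALSE)))
  }
  dev <- est - qbar
  B <- tcrossprod(dev) / (m - 1)
  r1 <- (1 + 1 / m) * sum(diag(solve(ubar, B))) / k
  stat <- drop(t(qbar) %*% solve(ubar, qbar)) / (k * (1 + r1))
  t_df <- k * (m - 1)
  df2 <- if (t_df > 4) {
    4 + (t_df - 4) * (1 + (1 - 2 / t_df) / r1)^2
  } else {
    t_df * (1 + 1 / k) * (1 + 1 / r1)^2 / 2
  }
  list(F = stat, df1 = k, df2 = df2,
       p = stats::pf(stat, k, df2, lower.tail = FALSE))
}

# ---- pooled regression and ANOVA --------------------------------------

# Merge per-cell glycerol values for one compartment with population
# moments; factors for the categorical design axes.
glycerol_model_frame <- function(percell, moments, compartment,
                                 assay_continuous = FALSE) {
  sub <- percell[percell$compartment == compartment, ]
  if (nrow(sub) == 0) stop("no rows for compartment ", compartment)
  X <- moments_design(moments)
  dat <- merge(sub, data.frame(population_id = rownames(X),
                               m_mean = X[, "mean"], m_var = X[, "var"],
                               m_rho = X[, "rho"], m_rho2 = X[, "rho2"]),
               by = "population_id")
  dat$S0 <- factor(dat$s0_M)
  dat$S1 <- if (assay_continuous) dat$s1_M else factor(dat$s1_M)
  dat$Time <- factor(dat$time_h)
  dat
}

#' Pooled moment regression of per-cell glycerol for one condition
#'
#' For a single compartment, salinity transfer, and time point, regresses
#' the per-cell glycerol amount on the environmental moments
#' `(mean, var, rho, rho2)` by ordinary least squares in every imputed
#' dataset, then pools estimates by Rubin's rules.
#'
#' @param imputations List of glycerol measurement tables (from
#'   [impute_datasets()]), or a single table for a point-estimate fit.
#' @param moments Moments table (`population_id`, `mean_M`, `var_M2`,
#'   `rho`, `rho2`).
#' @param compartment One of `"intracellular"`, `"extracellular"`,
#'   `"total"`.
#' @param s0,s1 Transfer salinities (M) selecting the condition.
#' @param time_h Time point (hours) selecting the condition.
#' @return Tibble: `moment`, `estimate`, `se`, `df`, `p`.
#' @export
glycerol_moment_regression <- function(imputations, moments,
                                       compartment = "intracellular",
                                       s0, s1, time_h) {
  if (is.data.frame(imputations)) imputations <- list(imputations)
  fits <- lapply(imputations, function(tab) {
    dat <- glycerol_model_frame(per_cell_table(tab), moments, compartment)
    dat <- dat[dat$s0_M == s0 & dat$s1_M == s1 & dat$time_h == time_h, ]
    if (nrow(dat) < 6) stop("need >= 6 populations in the condition")
    fit <- stats::lm(G_est ~ m_mean + m_var + m_rho + m_rho2, data = dat)
    list(est = stats::coef(fit),
         se = sqrt(diag(stats::vcov(fit))))
  })
  est <- vapply(fits, `[[`, numeric(5), "est")
  se <- vapply(fits, `[[`, numeric(5), "se")
  if (any(!is.finite(se))) stop("collinear moments: singular regression")
  pooled <- rubin_pool(est, se)
  pooled$moment <- MOMENT_NAMES
  pooled[, c("moment", "estimate", "se", "df", "p")]
}

#' Pooled ANOVA of glycerol content across imputations
#'
#' Fits, in every imputed dataset, the fixed-effect linear model
#' `G ~ S0 * S1 * Time * rho2 + rho + mean + var` on per-cell glycerol for
#' one compartment (acclimation salinity, assay salinity, and time as
#' categorical axes; assay salinity optionally continuous), then pools
#' each model term's coefficient block across imputations with the D1
#' multivariate Wald statistic.
#'
#' @param imputations List of glycerol measurement tables, or a single
#'   table (ordinary single-fit ANOVA, with a warning if `m = 1` was
#'   meant as pooling).
#' @param moments Moments table.
#' @param compartment Compartment analyzed.
#' @param assay_continuous Treat assay salinity as continuous instead of
#'   categorical.
#' @return Tibble: `term`, `F`, `df1`, `df2`, `p`, `p_bonferroni`.
#' @export
glycerol_anova <- function(imputations, moments,
                           compartment = "intracellular",
                           assay_continuous = FALSE) {
  if (is.data.frame(imputations)) imputations <- list(imputations)
  m <- length(imputations)
  if (m == 1) {
    warning("single dataset: pooling is degenerate; ordinary ANOVA returned")
  }
  fits <- lapply(imputations, function(tab) {
    dat <- glycerol_model_frame(per_cell_table(tab), moments, compartment,
                                assay_continuous)
    stats::lm(G_est ~ S0 * S1 * Time * m_rho2 + m_rho + m_mean + m_var,
              data = dat)
  })
  f1 <- fits[[1]]
  if (any(is.na(stats::coef(f1)))) {
    bad <- names(stats::coef(f1))[is.na(stats::coef(f1))]
    stop("inestimable-term error: empty design cells for coefficient(s): ",
         paste(unique(bad), collapse = ", "))
  }
  asgn <- attr(stats::model.matrix(f1), "assign")
  labels <- attr(stats::terms(f1), "term.labels")
  est_all <- vapply(fits, stats::coef, stats::coef(f1))
  vcov_all <- lapply(fits, stats::vcov)
  res_df <- stats::df.residual(f1)
  rows <- lapply(seq_along(labels), function(j) {
    idx <- which(asgn == j)
    pool <- d1_pool(est_all[idx, , drop = FALSE],
                    lapply(vcov_all, function(v) v[idx, idx, drop = FALSE]))
    if (m == 1) {
      pool$df2 <- res_df
      pool$p <- stats::pf(pool$F, pool$df1, res_df, lower.tail = FALSE)
    }
    tibble::tibble(term = labels[j], F = pool$F, df1 = pool$df1,
                   df2 = pool$df2, p = pool$p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p, m = max(40, nrow(out)))
  out
}

#' Among-assay-environment variance of glycerol content
#'
#' The among-environment component of phenotypic plasticity: the sample
#' variance (denominator n - 1) of per-cell glycerol across assay-salinity
#' levels, for one population, acclimation salinity, compartment, and
#' time point.
#'
#' @param G Numeric vector of per-cell glycerol values, one per assay
#'   salinity level (>= 2 levels).
#' @return Sample variance.
#' @export
plasticity_variance <- function(G) {
  if (length(G) < 2) stop("need >= 2 assay-salinity levels")
  stats::var(G)
}

#' Plasticity variance per population/condition
#'
#' Applies [plasticity_variance()] across assay salinities within every
#' (population, acclimation salinity, time, compartment) group of a
#' per-cell glycerol table; the result can be regressed on environmental
#' moments via [glycerol_moment_regression()]-style pooling.
#'
#' @param percell A table from [per_cell_table()].
#' @return Tibble: `population_id`, `s0_M`, `time_h`, `compartment`,
#'   `var_G`.
#' @export
plasticity_variance_table <- function(percell) {
  sp <- split(percell,
              interaction(percell$population_id, percell$s0_M,
                          percell$time_h, percell$compartment, drop = TRUE))
  rows <- lapply(sp, function(d) {
    tibble::tibble(population_id = d$population_id[1], s0_M = d$s0_M[1],
                   time_h = d$time_h[1], compartment = d$compartment[1],
                   var_G = plasticity_variance(d$G_est))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
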