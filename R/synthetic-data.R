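# Synthetic experiments: treatments, surface parameters, count assays,
# and glycerol measurements with the statistical structure the analysis
# assumes.

#' Random beta-binomial deviates (mean/precision parameterization)
#'
#' @param n Number of draws.
#' @param size Trials per draw.
#' @param d Mean probability.
#' @param phi Precision.
#' @return Integer vector.
#' @export
rbetabinom <- function(n, size, d, phi) {
  p <- stats::rbeta(n, d * phi, (1 - d) * phi)
  stats::rbinom(n, size, p)
}

#' Configuration of a synthetic cross-salinity experiment
#'
#' Defaults reproduce the reference experimental design: 6 constant
#' populations (two each at 0.8, 2.4, and 3.2 M), 19 fluctuating
#' populations across four autocorrelation levels (5 at -0.5, 0, and 0.5;
#' 4 at 0.9) with stationary mean 2.4 M and variance 1 over 80 transfers;
#' the 9 x 9 acclimation-by-assay grid with its 6 unreachable cells (75
#' transfers); 3 replicates per cell; 3-day assays; initial densities
#' Normal(3911, 283) truncated positive and shared within an acclimation
#' flask; negative-binomial live counts (size 20) and beta-binomial dead
#' fractions (precision 10). True surface parameters follow the reference
#' moment-effect matrix unless overridden.
#'
#' @param constant_salinities,constant_replicates Constant-regime levels
#'   (M) and populations per level.
#' @param fluct_rhos,fluct_counts Target autocorrelations and populations
#'   per level.
#' @param fluct_mean,fluct_variance Stationary mean (M) and variance
#'   (M^2) of the fluctuating regimes.
#' @param series_length Transfers per salinity series.
#' @param acclimation_grid,assay_grid,exclusions Cross-transfer design
#'   (see [cross_transfer_design()]).
#' @param replicates Assay replicates per design cell.
#' @param t_days Assay duration (days).
#' @param n0_mean,n0_sd Initial-density distribution (cells).
#' @param nb_size,bb_precision Observation-model dispersions.
#' @param effects True moment-effect matrix (5 x 10, see
#'   [reference_moment_effects()]).
#' @param param_scatter_sd Optional SD of Normal population-level scatter
#'   around the moment predictions (length 1 or 10; default 0: the
#'   reference model has none).
#' @param seed Integer seed (required; the config plus seed reproduces a
#'   dataset bit-exactly).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(constant_salinities = c(0.8, 2.4, 3.2),
                              constant_replicates = 2,
                              fluct_rhos = c(-0.5, 0, 0.5, 0.9),
                              fluct_counts = c(5, 5, 5, 4),
                              fluct_mean = 2.4,
                              fluct_variance = 1,
                              series_length = 80,
                              acclimation_grid = salinity_grid(),
                              assay_grid = salinity_grid(),
                              exclusions = default_exclusions(),
                              replicates = 3,
                              t_days = 3,
                              n0_mean = 3911,
                              n0_sd = 283,
                              nb_size = 20,
                              bb_precision = 10,
                              effects = reference_moment_effects(),
                              param_scatter_sd = 0,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("config error: seed is required")
  # tolerate list-valued inputs (e.g. parsed from YAML)
  constant_salinities <- as.numeric(unlist(constant_salinities))
  fluct_rhos <- as.numeric(unlist(fluct_rhos))
  fluct_counts <- as.numeric(unlist(fluct_counts))
  acclimation_grid <- as.numeric(unlist(acclimation_grid))
  assay_grid <- as.numeric(unlist(assay_grid))
  stopifnot(length(fluct_rhos) == length(fluct_counts),
            all(fluct_counts >= 0), constant_replicates >= 0,
            replicates >= 1, series_length >= 2, t_days > 0,
            n0_mean > 0, n0_sd >= 0, nb_size > 0, bb_precision > 0)
  effects <- as.matrix(effects)
  if (!all(dim(effects) == c(5, 10))) {
    stop("config error: effects must be a 5 x 10 matrix")
  }
  dimnames(effects) <- list(MOMENT_NAMES, HIER_PARAM_NAMES)
  if (length(param_scatter_sd) == 1) {
    param_scatter_sd <- rep(param_scatter_sd, 10)
  }
  structure(
    list(constant_salinities = constant_salinities,
         constant_replicates = constant_replicates,
         fluct_rhos = fluct_rhos, fluct_counts = fluct_counts,
         fluct_mean = fluct_mean, fluct_variance = fluct_variance,
         series_length = series_length,
         acclimation_grid = acclimation_grid, assay_grid = assay_grid,
         exclusions = exclusions, replicates = replicates,
         t_days = t_days, n0_mean = n0_mean, n0_sd = n0_sd,
         nb_size = nb_size, bb_precision = bb_precision,
         effects = effects, param_scatter_sd = param_scatter_sd,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# Hierarchical-scale growth surface (breadths as 1/sigma^2).
growth_rate_hier <- function(p, s0, s1) {
  z0 <- s0 - p[["mu0"]]
  z1 <- s1 - p[["mu1"]]
  p[["r_max"]] - z1^2 * p[["inv_sigma1_sq"]] - z0^2 * p[["inv_sigma0_sq"]] +
    2 * p[["k"]] * z1 * z0 * p[["inv_sigma1_sq"]]
}

mortality_hier <- function(p, s0, s1) {
  stats::plogis(p[["delta"]] + p[["delta0"]] * s0 + p[["delta1"]] * s1 +
                  p[["delta01"]] * s0 * s1)
}

#' Generate a complete synthetic cross-salinity experiment
#'
#' Simulates each fluctuating population's AR(1) salinity series, computes
#' realized moments (constant regimes enter with variance 0 and
#' autocorrelation 0, flagged), derives every population's true surface
#' parameters from the moment-effect matrix (plus optional Normal
#' scatter), draws one initial density per population x acclimation flask,
#' and then draws negative-binomial live counts and beta-binomial dead
#' increments for every design cell and replicate.
#'
#' @param config An [experiment_config()].
#' @return List with `moments` (tibble: `population_id`, `treatment`,
#'   `target_rho`, `mean_M`, `var_M2`, `rho`, `rho2`, `constant`),
#'   `counts` (tibble in the standard count-table schema), and `truth`
#'   (list: `effects`, `params` matrix of per-population true parameters,
#'   `n0` table, `config`).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  withr::with_seed(config$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L,
                        sum(config$fluct_counts))
    pops <- list()
    idx <- 0
    for (s in config$constant_salinities) {
      for (r in seq_len(config$constant_replicates)) {
        idx <- idx + 1
        pops[[idx]] <- list(id = sprintf("pop%02d", idx),
                            treatment = sprintf("constant_%.1fM", s),
                            target_rho = NA_real_, constant = TRUE,
                            mean = s, var = 0, rho = NA_real_,
                            rho2 = NA_real_)
      }
    }
    si <- 0
    for (j in seq_along(config$fluct_rhos)) {
      for (r in seq_len(config$fluct_counts[j])) {
        idx <- idx + 1
        si <- si + 1
        ser <- simulate_ar1(config$fluct_mean, config$fluct_variance,
                            config$fluct_rhos[j], config$series_length,
                            seed = seeds[si])
        mo <- realized_moments(ser)
        pops[[idx]] <- list(id = sprintf("pop%02d", idx),
                            treatment = sprintf("rho_%+.1f",
                                                config$fluct_rhos[j]),
                            target_rho = config$fluct_rhos[j],
                            constant = FALSE, mean = mo$mean,
                            var = mo$variance, rho = mo$rho,
                            rho2 = mo$rho2)
      }
    }
    moments <- tibble::tibble(
      population_id = vapply(pops, `[[`, character(1), "id"),
      treatment = vapply(pops, `[[`, character(1), "treatment"),
      target_rho = vapply(pops, `[[`, numeric(1), "target_rho"),
      mean_M = vapply(pops, `[[`, numeric(1), "mean"),
      var_M2 = vapply(pops, `[[`, numeric(1), "var"),
      rho = vapply(pops, `[[`, numeric(1), "rho"),
      rho2 = vapply(pops, `[[`, numeric(1), "rho2"),
      constant = vapply(pops, `[[`, logical(1), "constant")
    )
    P <- population_params(config$effects, moments)
    if (any(config$param_scatter_sd > 0)) {
      scatter <- matrix(stats::rnorm(length(P), 0,
                                     rep(config$param_scatter_sd,
                                         each = nrow(P))),
                        nrow = nrow(P))
      P <- P + scatter
    }
    rownames(P) <- moments$population_id
    if (any(P[, c("inv_sigma0_sq", "inv_sigma1_sq")] <= 0)) {
      stop("config error: predicted 1/sigma^2 <= 0 for some population ",
           "(moment effects too extreme)")
    }
    design <- cross_transfer_design(config$acclimation_grid,
                                    config$assay_grid, config$exclusions)
    n_pop <- nrow(moments)
    s0_levels <- sort(unique(design$s0_M))
    n0_tab <- expand.grid(population_id = moments$population_id,
                          s0_M = s0_levels, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    repeat {
      n0_draw <- stats::rnorm(nrow(n0_tab), config$n0_mean, config$n0_sd)
      if (all(n0_draw > 0)) break
    }
    n0_tab$n0 <- round(n0_draw)
    rows <- vector("list", n_pop)
    for (i in seq_len(n_pop)) {
      p <- P[i, ]
      r <- growth_rate_hier(p, design$s0_M, design$s1_M)
      d <- mortality_hier(p, design$s0_M, design$s1_M)
      n0 <- n0_tab$n0[match(
        paste(moments$population_id[i], design$s0_M),
        paste(n0_tab$population_id, n0_tab$s0_M))]
      cell <- design[rep(seq_len(nrow(design)), each = config$replicates), ]
      reps <- rep(seq_len(config$replicates), nrow(design))
      mu <- rep(n0 * (1 - d) * exp(r * config$t_days),
                each = config$replicates)
      dd <- rep(d, each = config$replicates)
      trials <- rep(round(n0), each = config$replicates)
      n_t <- stats::rnbinom(length(mu), mu = mu, size = config$nb_size)
      dead <- rbetabinom(length(dd), trials, dd, config$bb_precision)
      rows[[i]] <- tibble::tibble(
        population_id = moments$population_id[i],
        s0_M = cell$s0_M, s1_M = cell$s1_M, replicate = reps,
        n0 = rep(n0, each = config$replicates), n_t = n_t,
        d0 = 0L, d_t = dead, t_days = config$t_days
      )
    }
    counts <- do.call(rbind, rows)
    list(moments = moments, counts = counts,
         truth = list(effects = config$effects, params = P,
                      n0 = tibble::as_tibble(n0_tab), config = config))
  })
}

#' Configuration of a synthetic glycerol experiment
#'
#' Defaults emulate the reference glycerol design: 8 fluctuating
#' populations (2 per target autocorrelation -0.5, 0, 0.5, 0.9),
#' acclimation at 0.5 or 3.5 M, assay at 0.5, 2, or 3.5 M, measured 1 h,
#' 8 h, and 3 days (72 h) after transfer: 8 x 6 x 3 = 144 measurement
#' conditions per compartment. The per-cell intracellular truth relaxes
#' exponentially from the acclimation equilibrium toward the assay
#' equilibrium (faster after downshifts, reflecting excretion), and
#' environmental moments shift the baseline and the response to assay
#' salinity via `glycerol_effects`.
#'
#' @param n_per_rho Populations per autocorrelation level.
#' @param fluct_rhos Target autocorrelations.
#' @param fluct_mean,fluct_variance,series_length AR(1) regime settings.
#' @param acclimation,assay,times_h Measurement design levels.
#' @param g_base,g_slope Equilibrium per-cell glycerol (mol/cell):
#'   `G_eq(s) = g_base + g_slope * s`.
#' @param tau_up_h,tau_down_h Relaxation times (h) for up- and
#'   down-shifts.
#' @param extra_base,extra_excrete Extracellular baseline (mol/cell) and
#'   excretion term per M of downshift.
#' @param glycerol_effects Named vector of planted moment effects on
#'   intracellular per-cell glycerol: `rho2` (baseline, mol/cell per unit
#'   predictability) and `rho2_s1` (interaction with assay salinity,
#'   mol/cell/M); defaults emulate reduced plasticity under high
#'   predictability.
#' @param density,density_cv Assay cell density (cells/mL) and its
#'   measurement CV.
#' @param conc_cv Concentration measurement CV.
#' @param seed Integer seed (required).
#' @return Object of class `glycerol_config`.
#' @export
glycerol_config <- function(n_per_rho = 2,
                            fluct_rhos = c(-0.5, 0, 0.5, 0.9),
                            fluct_mean = 2.4, fluct_variance = 1,
                            series_length = 80,
                            acclimation = c(0.5, 3.5),
                            assay = c(0.5, 2, 3.5),
                            times_h = c(1, 8, 72),
                            g_base = 0.3e-12, g_slope = 1.0e-12,
                            tau_up_h = 16, tau_down_h = 4,
                            extra_base = 0.15e-12, extra_excrete = 0.1e-12,
                            glycerol_effects = c(rho2 = -0.3e-12,
                                                 rho2_s1 = -0.2e-12),
                            density = 5e5, density_cv = 0.05,
                            conc_cv = 0.08,
                            seed) {
  if (missing(seed) || is.null(seed)) stop("config error: seed is required")
  stopifnot(n_per_rho >= 1, density > 0, conc_cv >= 0, density_cv >= 0)
  structure(
    list(n_per_rho = n_per_rho, fluct_rhos = fluct_rhos,
         fluct_mean = fluct_mean, fluct_variance = fluct_variance,
         series_length = series_length, acclimation = acclimation,
         assay = assay, times_h = times_h, g_base = g_base,
         g_slope = g_slope, tau_up_h = tau_up_h, tau_down_h = tau_down_h,
         extra_base = extra_base, extra_excrete = extra_excrete,
         glycerol_effects = glycerol_effects, density = density,
         density_cv = density_cv, conc_cv = conc_cv,
         seed = as.integer(seed)),
    class = "glycerol_config"
  )
}

# True per-cell intracellular glycerol for one condition.
glycerol_truth_fn <- function(config, s0, s1, time_h, rho, rho2) {
  g_eq <- function(s) config$g_base + config$g_slope * s
  tau <- ifelse(s0 > s1, config$tau_down_h, config$tau_up_h)
  g <- g_eq(s1) + (g_eq(s0) - g_eq(s1)) * exp(-time_h / tau)
  eff <- config$glycerol_effects
  g <- g + eff[["rho2"]] * rho2 + eff[["rho2_s1"]] * rho2 * s1
  pmax(g, 0.01e-12)
}

#' Generate a synthetic glycerol experiment
#'
#' Builds the full 144-condition measurement design with total and
#' extracellular concentration rows (288 records), Gaussian measurement
#' error on concentrations and densities, and returns the ground truth
#' alongside.
#'
#' @param config A [glycerol_config()].
#' @return List with `measurements` (glycerol table: `population_id`,
#'   `s0_M`, `s1_M`, `time_h`, `compartment`, `conc_est`, `conc_se`,
#'   `density_est`, `density_se`), `moments` (tibble as in
#'   [generate_experiment()]), and `truth` (per-condition true per-cell
#'   amounts and the config).
#' @export
generate_glycerol_data <- function(config) {
  stopifnot(inherits(config, "glycerol_config"))
  withr::with_seed(config$seed, {
    n_pop <- config$n_per_rho * length(config$fluct_rhos)
    seeds <- sample.int(.Machine$integer.max - 1L, n_pop)
    rows <- list()
    idx <- 0
    for (j in seq_along(config$fluct_rhos)) {
      for (r in seq_len(config$n_per_rho)) {
        idx <- idx + 1
        ser <- simulate_ar1(config$fluct_mean, config$fluct_variance,
                            config$fluct_rhos[j], config$series_length,
                            seed = seeds[idx])
        mo <- realized_moments(ser)
        rows[[idx]] <- tibble::tibble(
          population_id = sprintf("gly%02d", idx),
          treatment = sprintf("rho_%+.1f", config$fluct_rhos[j]),
          target_rho = config$fluct_rhos[j], mean_M = mo$mean,
          var_M2 = mo$variance, rho = mo$rho, rho2 = mo$rho2,
          constant = FALSE)
      }
    }
    moments <- do.call(rbind, rows)
    cond <- expand.grid(population_id = moments$population_id,
                        s0_M = config$acclimation, s1_M = config$assay,
                        time_h = config$times_h, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    cond <- cond[order(cond$population_id, cond$s0_M, cond$s1_M,
                       cond$time_h), ]
    mi <- match(cond$population_id, moments$population_id)
    g_intra <- glycerol_truth_fn(config, cond$s0_M, cond$s1_M, cond$time_h,
                                 moments$rho[mi], moments$rho2[mi])
    g_extra <- config$extra_base +
      config$extra_excrete * pmax(cond$s0_M - cond$s1_M, 0)
    g_total <- g_intra + g_extra
    make_rows <- function(compartment, g_cell) {
      conc_true <- g_cell * config$density
      conc_se <- config$conc_cv * conc_true
      density_se <- config$density_cv * config$density
      tibble::tibble(
        population_id = cond$population_id, s0_M = cond$s0_M,
        s1_M = cond$s1_M, time_h = cond$time_h,
        compartment = compartment,
        conc_est = conc_true + conc_se * stats::rnorm(nrow(cond)),
        conc_se = conc_se,
        density_est = config$density +
          density_se * stats::rnorm(nrow(cond)),
        density_se = density_se
      )
    }
    measurements <- rbind(make_rows("total", g_total),
                          make_rows("extracellular", g_extra))
    truth <- cond
    truth$G_intracellular <- g_intra
    truth$G_extracellular <- g_extra
    truth$G_total <- g_total
    list(measurements = measurements, moments = tibble::as_tibble(moments),
         truth = list(per_cell = tibble::as_tibble(truth), config = config))
  })
}
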