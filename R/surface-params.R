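# Tolerance-surface parameter objects and surface evaluation.

# Canonical parameter order shared with the compiled likelihood. Columns
# 4 and 5 hold log(sigma) in the single-surface fit and 1/sigma^2 linear
# predictors in the hierarchical fit.
SURFACE_PARAM_NAMES <- c("r_max", "mu0", "mu1", "sigma0", "sigma1", "k",
                         "delta", "delta0", "delta1", "delta01")
HIER_PARAM_NAMES <- c("r_max", "mu0", "mu1", "inv_sigma0_sq", "inv_sigma1_sq",
                      "k", "delta", "delta0", "delta1", "delta01")
MOMENT_NAMES <- c("intercept", "mean", "var", "rho", "rho2")

#' Growth-surface parameters
#'
#' The six parameters of the bivariate apparent-growth surface:
#' `r(s0, s1) = r_max - (s1 - mu1)^2 / sigma1^2 - (s0 - mu0)^2 / sigma0^2
#'  + 2 k (s1 - mu1)(s0 - mu0) / sigma1^2`.
#' `r_max` (1/day) is the maximal apparent growth rate, `mu1`/`sigma1` the
#' assay-salinity optimum and breadth (M), `mu0`/`sigma0` the acclimation
#' optimum and breadth, and `k` (dimensionless) the acclimation strength:
#' the slope of the conditional assay optimum in the acclimation salinity.
#' The surface has a finite interior maximum iff `k^2 < sigma1^2/sigma0^2`;
#' a violation is warned about, not rejected.
#'
#' @param r_max,mu0,mu1,sigma0,sigma1,k Numeric scalars; `sigma0`,
#'   `sigma1` must be > 0.
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(r_max, mu0, mu1, sigma0, sigma1, k) {
  stopifnot(sigma0 > 0, sigma1 > 0)
  g <- structure(
    list(r_max = r_max, mu0 = mu0, mu1 = mu1,
         sigma0 = sigma0, sigma1 = sigma1, k = k),
    class = "growth_params"
  )
  if (!has_finite_maximum(g)) {
    warning("k^2 >= sigma1^2/sigma0^2: growth surface has no finite maximum")
  }
  g
}

#' Does the growth surface have a finite interior maximum?
#' @param g A `growth_params` object.
#' @return Logical.
#' @export
has_finite_maximum <- function(g) {
  g$k^2 < g$sigma1^2 / g$sigma0^2
}

#' Mortality-surface parameters
#'
#' Coefficients of the logit-linear instantaneous mortality surface
#' `logit(d) = delta + delta0 * s0 + delta1 * s1 + delta01 * s0 * s1`.
#'
#' @param delta,delta0,delta1,delta01 Numeric scalars (logit scale).
#' @return Object of class `mortality_params`.
#' @export
mortality_params <- function(delta, delta0, delta1, delta01) {
  structure(
    list(delta = delta, delta0 = delta0, delta1 = delta1, delta01 = delta01),
    class = "mortality_params"
  )
}

#' Observation-model dispersion parameters
#'
#' `nb_size` is the negative-binomial dispersion of live counts
#' (variance = mu + mu^2 / nb_size); `bb_precision` the beta-binomial
#' precision of dead-count fractions (the per-well death probability is
#' Beta with mean d and precision phi). Both must be strictly positive.
#'
#' @param nb_size,bb_precision Positive scalars.
#' @return Object of class `dispersion_params`.
#' @export
dispersion_params <- function(nb_size, bb_precision) {
  stopifnot(nb_size > 0, bb_precision > 0)
  structure(list(nb_size = nb_size, bb_precision = bb_precision),
            class = "dispersion_params")
}

#' Reference tolerance-surface estimates
#'
#' Published maximum-likelihood estimates of the acclimated tolerance
#' surface for *Dunaliella salina* populations evolved under white-noise
#' salinity fluctuations (mean 2.4 M, variance 1). Used as defaults in the
#' synthetic-data generator and as ground truth in recovery experiments.
#'
#' @return List with elements `growth` (`growth_params`), `mortality`
#'   (`mortality_params`), and `se` (named numeric vector of reported
#'   standard errors).
#' @export
reference_surface_params <- function() {
  list(
    growth = growth_params(r_max = 1.153, mu0 = 2.565, mu1 = -0.035,
                           sigma0 = 3.101, sigma1 = 4.143, k = 0.666),
    mortality = mortality_params(delta = -3.994, delta0 = -0.033,
                                 delta1 = 1.185, delta01 = -0.444),
    se = c(r_max = 0.038, k = 0.068, mu0 = 0.131, mu1 = 0.332,
           sigma0 = 0.085, sigma1 = 0.202, delta = 0.158, delta0 = 0.072,
           delta1 = 0.054, delta01 = 0.029)
  )
}

#' Apparent growth rate on the tolerance surface
#'
#' Evaluates the bivariate quadratic growth surface at acclimation salinity
#' `s0` and assay salinity `s1` (vectorized).
#'
#' @param g A `growth_params` object.
#' @param s0,s1 Salinities (M).
#' @return Apparent growth rate(s), 1/day.
#' @examples
#' ref <- reference_surface_params()
#' growth_rate(ref$growth, 2.565, -0.035)  # r_max
#' @export
growth_rate <- function(g, s0, s1) {
  z0 <- s0 - g$mu0
  z1 <- s1 - g$mu1
  g$r_max - z1^2 / g$sigma1^2 - z0^2 / g$sigma0^2 +
    2 * g$k * z1 * z0 / g$sigma1^2
}

#' Instantaneous mortality ratio
#'
#' Logistic of the logit-linear mortality surface at `(s0, s1)`
#' (vectorized). Returns the fraction of initial live cells dying upon
#' transfer, in (0, 1).
#'
#' @param m A `mortality_params` object.
#' @param s0,s1 Salinities (M).
#' @return Mortality fraction(s).
#' @export
mortality_ratio <- function(m, s0, s1) {
  stats::plogis(m$delta + m$delta0 * s0 + m$delta1 * s1 +
                  m$delta01 * s0 * s1)
}

#' Net growth rate over an assay
#'
#' Combines instantaneous mortality and subsequent exponential growth into
#' the net per-capita rate over an assay of duration `t`:
#' `R = log(1 - d) / t + r`.
#'
#' @param r Apparent growth rate (1/day).
#' @param d Mortality fraction in `[0, 1)`.
#' @param t Assay duration (days), > 0.
#' @return Net growth rate (1/day).
#' @export
net_growth <- function(r, d, t) {
  stopifnot(all(t > 0))
  if (any(d < 0 | d >= 1)) {
    stop("mortality fraction must lie in [0, 1): d = 1 gives -Inf net growth")
  }
  log1p(-d) / t + r
}

#' Conditional assay-salinity optimum
#'
#' The assay salinity maximizing apparent growth at a fixed acclimation
#' salinity: `s1* = mu1 + k * (s0 - mu0)`. Its slope in `s0` is the
#' acclimation strength `k`. Values outside the mixable range `[0, 4.8]` M
#' are returned as-is but flagged via the `in_range` attribute.
#'
#' @param g A `growth_params` object.
#' @param s0 Acclimation salinity (M), vectorized.
#' @return Numeric vector of conditional optima (M) with attribute
#'   `in_range`.
#' @export
conditional_optimum <- function(g, s0) {
  s1_star <- g$mu1 + g$k * (s0 - g$mu0)
  attr(s1_star, "in_range") <-
    s1_star >= SALINITY_BOUNDS[1] & s1_star <= SALINITY_BOUNDS[2]
  s1_star
}

#' Joint optimum of the net-growth surface
#'
#' Numerically maximizes `net_growth(growth_rate(s0, s1),
#' mortality_ratio(s0, s1), t)` over a bounded salinity square, with
#' multiple deterministic starts (corners, center, and the growth-surface
#' optimum projected into bounds). Ties are broken toward the
#' lexicographically smallest `(s0, s1)`.
#'
#' @param fit A `surface_fit`, or a list with `growth` and `mortality`
#'   components.
#' @param t Assay duration (days).
#' @param bounds Length-2 numeric, the common `[lo, hi]` bounds on both
#'   salinity axes.
#' @return List with `s0_star`, `s1_star`, `R_star`.
#' @export
joint_optimum <- function(fit, t = 3, bounds = c(0.1, 4.7)) {
  g <- fit$growth
  m <- fit$mortality
  f <- function(p) {
    r <- growth_rate(g, p[1], p[2])
    d <- mortality_ratio(m, p[1], p[2])
    net_growth(r, d, t)
  }
  clamp <- function(x) pmin(pmax(x, bounds[1]), bounds[2])
  starts <- rbind(
    c(mean(bounds), mean(bounds)),
    c(bounds[1], bounds[1]), c(bounds[1], bounds[2]),
    c(bounds[2], bounds[1]), c(bounds[2], bounds[2]),
    clamp(c(g$mu0, g$mu1))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], function(p) -f(p), method = "L-BFGS-B",
                      lower = bounds[1], upper = bounds[2])
    if (!is.finite(o$value)) next
    cand <- list(s0_star = o$par[1], s1_star = o$par[2], R_star = -o$value)
    if (is.null(best) || cand$R_star > best$R_star + 1e-10 ||
        (abs(cand$R_star - best$R_star) <= 1e-10 &&
         (cand$s0_star < best$s0_star - 1e-9 ||
          (abs(cand$s0_star - best$s0_star) <= 1e-9 &&
           cand$s1_star < best$s1_star - 1e-9)))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("optimization error: non-finite surface")
  best
}

#' Positive net-growth interval along the assay axis
#'
#' Root-finds `R(s0, s1) = 0` in `s1` at fixed acclimation salinity, on a
#' bounded assay axis, and returns the interval(s) where net growth is
#' positive. Intervals truncated by the bounds are flagged.
#'
#' @param fit A `surface_fit` or list with `growth` and `mortality`.
#' @param s0 Acclimation salinity (M).
#' @param t Assay duration (days).
#' @param bounds Length-2 bounds on the assay axis (M).
#' @param n_grid Sign-scan resolution.
#' @return Tibble with columns `lower`, `upper`, `truncated_lower`,
#'   `truncated_upper`; zero rows if growth is nowhere positive.
#' @export
zero_growth_interval <- function(fit, s0, t = 3, bounds = c(0.1, 4.7),
                                 n_grid = 512) {
  g <- fit$growth
  m <- fit$mortality
  f <- function(s1) {
    net_growth(growth_rate(g, s0, s1), mortality_ratio(m, s0, s1), t)
  }
  grid <- seq(bounds[1], bounds[2], length.out = n_grid)
  v <- f(grid)
  pos <- v > 0
  if (!any(pos)) {
    return(tibble::tibble(lower = numeric(), upper = numeric(),
                          truncated_lower = logical(),
                          truncated_upper = logical()))
  }
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- lapply(which(runs$values), function(j) {
    i0 <- starts[j]
    i1 <- ends[j]
    trunc_lo <- i0 == 1
    trunc_hi <- i1 == n_grid
    lo <- if (trunc_lo) bounds[1] else
      stats::uniroot(f, c(grid[i0 - 1], grid[i0]), tol = 1e-9)$root
    hi <- if (trunc_hi) bounds[2] else
      stats::uniroot(f, c(grid[i1], grid[i1 + 1]), tol = 1e-9)$root
    tibble::tibble(lower = lo, upper = hi, truncated_lower = trunc_lo,
                   truncated_upper = trunc_hi)
  })
  do.call(rbind, out)
}
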