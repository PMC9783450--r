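# Salinity regimes and serial-transfer logistics.

#' Salinity bounds of the mixing chemistry
#'
#' Media are mixed from a hyposaline (0 M NaCl) and a hypersaline (4.8 M
#' NaCl) stock, so no realizable salinity can fall outside `[0, 4.8]` M.
#' @keywords internal
SALINITY_BOUNDS <- c(0, 4.8)

#' Standard acclimation/assay salinity grid
#'
#' The nine NaCl concentrations (M) used both as acclimation (past) and
#' assay (current) salinities in the cross-transfer design.
#'
#' @return Numeric vector of nine salinities in M.
#' @export
salinity_grid <- function() c(0.1, 0.5, 1.1, 1.8, 2.4, 3.0, 3.7, 4.3, 4.7)

#' Cross-transfer pairs excluded by the dilution chemistry
#'
#' Transfers from 0.1 M to 3.7/4.3/4.7 M and from 4.7 M to 0.1/0.5/1.1 M
#' cannot be reached at the dilution level of the standard design.
#'
#' @return Two-column matrix of (s0, s1) pairs in M.
#' @export
default_exclusions <- function() {
  rbind(
    cbind(0.1, c(3.7, 4.3, 4.7)),
    cbind(4.7, c(0.1, 0.5, 1.1))
  )
}

#' Simulate an AR(1) salinity series
#'
#' Draws a stationary first-order autoregressive series
#' `x[t+1] = mean + rho * (x[t] - mean) + eps[t]` with innovation variance
#' `variance * (1 - rho^2)`, so the stationary variance equals `variance`
#' regardless of the autocorrelation `rho`. The first value is drawn from
#' the stationary distribution `Normal(mean, variance)`. Values are then
#' clipped to the physically mixable range `[0, 4.8]` M; the unclipped
#' latent series is retained and the number of clipped steps reported.
#'
#' @param mean Stationary mean (M NaCl).
#' @param variance Stationary variance (M^2); must be > 0.
#' @param rho Lag-1 autocorrelation, `|rho| < 1`.
#' @param n Series length (number of transfers), >= 2.
#' @param seed Integer seed; required, recorded in the result.
#' @return An object of class `salinity_series`: list with `values`
#'   (clipped series), `latent` (unclipped), `n_clipped`, and the target
#'   moments and seed.
#' @examples
#' s <- simulate_ar1(2.4, 1, 0.5, 200, seed = 1)
#' realized_moments(s)
#' @export
simulate_ar1 <- function(mean, variance, rho, n, seed) {
  if (!is.finite(rho) || abs(rho) >= 1) {
    stop("invalid-parameter: |rho| must be < 1, got ", rho)
  }
  if (!is.finite(variance) || variance <= 0) {
    stop("invalid-parameter: variance must be > 0")
  }
  if (n < 2) stop("invalid-parameter: n must be >= 2")
  if (missing(seed) || is.null(seed)) stop("seed is required")
  z <- withr::with_seed(as.integer(seed), stats::rnorm(n))
  x <- numeric(n)
  x[1] <- mean + sqrt(variance) * z[1]
  innov_sd <- sqrt(variance * (1 - rho^2))
  for (t in seq_len(n - 1)) {
    x[t + 1] <- mean + rho * (x[t] - mean) + innov_sd * z[t + 1]
  }
  clipped <- pmin(pmax(x, SALINITY_BOUNDS[1]), SALINITY_BOUNDS[2])
  structure(
    list(
      values = clipped,
      latent = x,
      n_clipped = sum(clipped != x),
      target_mean = mean,
      target_variance = variance,
      target_rho = rho,
      seed = as.integer(seed)
    ),
    class = "salinity_series"
  )
}

#' @export
print.salinity_series <- function(x, ...) {
  cat("<salinity_series> n =", length(x$values),
      " target (mean, var, rho) = (", x$target_mean, ",", x$target_variance,
      ",", x$target_rho, ")  clipped steps:", x$n_clipped,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Realized moments of a salinity series
#'
#' Sample mean, sample variance (denominator n - 1), lag-1 autocorrelation
#' (Pearson correlation of the series against itself shifted by one), and
#' its square ("predictability"). Independent series realizations differ
#' slightly from their target moments; analyses regress on these realized
#' values.
#'
#' @param series A `salinity_series`, or a plain numeric vector.
#' @param use_latent If `TRUE` compute moments of the unclipped latent
#'   series; default uses the realized (clipped) values.
#' @return Object of class `salinity_moments`: list with `mean`, `variance`,
#'   `rho`, `rho2`, and `rho_defined` (FALSE, with `rho = NA`, for a
#'   constant series where the lag correlation is undefined).
#' @export
realized_moments <- function(series, use_latent = FALSE) {
  x <- if (inherits(series, "salinity_series")) {
    if (use_latent) series$latent else series$values
  } else {
    as.numeric(series)
  }
  n <- length(x)
  if (n < 3) stop("need length >= 3 for lag-1 autocorrelation")
  m <- base::mean(x)
  v <- stats::var(x)
  if (v <= 0) {
    warning("zero-variance series: lag-1 autocorrelation undefined")
    rho <- NA_real_
    defined <- FALSE
  } else {
    rho <- stats::cor(x[-n], x[-1])
    defined <- TRUE
  }
  structure(
    list(mean = m, variance = v, rho = rho,
         rho2 = if (defined) rho^2 else NA_real_,
         rho_defined = defined),
    class = "salinity_moments"
  )
}

#' @export
print.salinity_moments <- function(x, ...) {
  cat(sprintf("<salinity_moments> mean %.4f M, var %.4f M^2, rho %s, rho2 %s\n",
              x$mean, x$variance, format(x$rho, digits = 4),
              format(x$rho2, digits = 4)))
  invisible(x)
}

#' Transfer volumes for one cross-salinity inoculation
#'
#' The serial-dilution robot reaches a target assay salinity `s1_target` and
#' initial density `n0_target` by mixing culture (at salinity `s0`, density
#' `n_acclim`) with hyposaline (0 M) and hypersaline (4.8 M) media:
#' `v_culture = n0_target * v_total / n_acclim`,
#' `v_hyper = (s1_target * v_total - s0 * v_culture) / 4.8`, and
#' `v_hypo` the remainder. A target salinity requiring a negative volume is
#' unreachable at this dilution.
#'
#' @param s0 Culture (acclimation) salinity, M.
#' @param s1_target Target assay salinity, M.
#' @param n_acclim Measured acclimation-culture density (cells/mL), > 0.
#' @param n0_target Target initial assay density (cells/mL).
#' @param v_total Total well volume (uL).
#' @return Object of class `transfer_volumes`: list with `v_culture`,
#'   `v_hyper`, `v_hypo`, `total` (uL).
#' @examples
#' transfer_volumes(2.4, 2.4, 1e5, 5e3, 800)
#' @export
transfer_volumes <- function(s0, s1_target, n_acclim, n0_target, v_total) {
  stopifnot(n_acclim > 0, v_total > 0)
  if (s0 < SALINITY_BOUNDS[1] || s0 > SALINITY_BOUNDS[2] ||
      s1_target < SALINITY_BOUNDS[1] || s1_target > SALINITY_BOUNDS[2]) {
    stop("salinities must lie in [0, 4.8] M")
  }
  s_hyper <- SALINITY_BOUNDS[2]
  v_culture <- n0_target * v_total / n_acclim
  v_hyper <- (s1_target * v_total - s0 * v_culture) / s_hyper
  v_hypo <- v_total - v_culture - v_hyper
  eps <- 1e-9
  if (v_culture > v_total + eps) {
    stop("unreachable-salinity: culture volume exceeds total (dilution bound)")
  }
  if (v_hyper < -eps) {
    stop("unreachable-salinity: target ", s1_target,
         " M below what dilution of ", s0, " M culture allows (v_hyper < 0)")
  }
  if (v_hypo < -eps) {
    stop("unreachable-salinity: target ", s1_target,
         " M above what mixing with 4.8 M medium allows (v_hypo < 0)")
  }
  structure(
    list(v_culture = v_culture, v_hyper = max(v_hyper, 0),
         v_hypo = max(v_hypo, 0), total = v_total),
    class = "transfer_volumes"
  )
}

#' @export
print.transfer_volumes <- function(x, ...) {
  cat(sprintf("<transfer_volumes> culture %.2f + hyper %.2f + hypo %.2f = %.2f uL\n",
              x$v_culture, x$v_hyper, x$v_hypo, x$total))
  invisible(x)
}

#' Enumerate the cross-salinity transfer design
#'
#' Full product of acclimation and assay grids minus excluded pairs. The
#' standard 9 x 9 grid with its 6 chemically unreachable exclusions yields
#' 75 transfers.
#'
#' @param acclimation_grid Acclimation salinities (M).
#' @param assay_grid Assay salinities (M).
#' @param exclusions Two-column matrix/data.frame of excluded (s0, s1)
#'   pairs; every exclusion must be in the grid product.
#' @return Tibble with columns `s0_M`, `s1_M`, one row per included pair,
#'   ordered by `s0_M` then `s1_M`.
#' @examples
#' nrow(cross_transfer_design())  # 75
#' @export
cross_transfer_design <- function(acclimation_grid = salinity_grid(),
                                  assay_grid = salinity_grid(),
                                  exclusions = default_exclusions()) {
  if (length(acclimation_grid) == 0 || length(assay_grid) == 0) {
    stop("grids must be non-empty")
  }
  full <- expand.grid(s1_M = assay_grid, s0_M = acclimation_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("s0_M", "s1_M")]
  keep <- rep(TRUE, nrow(full))
  if (!is.null(exclusions) && NROW(exclusions) > 0) {
    ex <- as.matrix(exclusions)
    key_full <- paste(full$s0_M, full$s1_M)
    key_ex <- paste(ex[, 1], ex[, 2])
    if (!all(key_ex %in% key_full)) {
      bad <- key_ex[!(key_ex %in% key_full)]
      stop("invalid-design: exclusion(s) not in grid product: ",
           paste(bad, collapse = "; "))
    }
    keep <- !(key_full %in% key_ex)
  }
  out <- full[keep, , drop = FALSE]
  out <- out[order(out$s0_M, out$s1_M), ]
  tibble::as_tibble(out)
}
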