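# Tabular I/O: CSV schemas (header row, "." decimal, UTF-8, no index
# column), fit JSON, and run manifests.

#' Write / read a count table
#'
#' Columns: `population_id, s0_M, s1_M, replicate, n0, n_t, d0, d_t,
#' t_days`.
#'
#' @param counts Count table.
#' @param path File path.
#' @return `read_counts` returns a validated tibble.
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(validate_counts(counts), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  tibble::as_tibble(validate_counts(
    utils::read.csv(path, fileEncoding = "UTF-8")))
}

#' Write / read a moments table
#'
#' Columns: `population_id, mean_M, var_M2, rho, rho2` (extra columns such
#' as `treatment` are preserved).
#'
#' @param moments Moments table.
#' @param path File path.
#' @return `read_moments` returns a tibble.
#' @export
write_moments <- function(moments, path) {
  moments_design(moments)  # schema check
  utils::write.csv(moments, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_moments
#' @export
read_moments <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
  moments_design(out)
  out
}

#' Write / read a glycerol measurement table
#'
#' @param measurements Glycerol table (see [generate_glycerol_data()]).
#' @param path File path.
#' @return `read_glycerol` returns a validated tibble.
#' @export
write_glycerol <- function(measurements, path) {
  utils::write.csv(validate_glycerol(measurements), path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_glycerol
#' @export
read_glycerol <- function(path) {
  tibble::as_tibble(validate_glycerol(
    utils::read.csv(path, fileEncoding = "UTF-8")))
}

#' Write / read a salinity series
#'
#' CSV with columns `transfer_index, salinity_M, clipped` and `#`-prefixed
#' metadata header lines carrying the target moments and seed.
#'
#' @param series A `salinity_series`.
#' @param path File path.
#' @return `read_series` returns a tibble with the metadata as
#'   attributes.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "salinity_series"))
  meta <- c(
    sprintf("# target_mean: %.17g", series$target_mean),
    sprintf("# target_variance: %.17g", series$target_variance),
    sprintf("# target_rho: %.17g", series$target_rho),
    sprintf("# seed: %d", series$seed)
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(
    data.frame(transfer_index = seq_along(series$values),
               salinity_M = series$values,
               clipped = as.integer(series$values != series$latent)),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  meta <- list()
  for (l in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", l), ":\\s*")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  out <- tibble::as_tibble(tab)
  attributes(out) <- c(attributes(out), meta)
  out
}

#' Write a surface fit as JSON
#'
#' Parameters named exactly `r_max, mu0, mu1, sigma0, sigma1, k, delta,
#' delta0, delta1, delta01, nb_size, bb_precision`, each with `estimate`
#' and `se`, plus `loglik`, `n_obs`, `converged`.
#'
#' @param fit A `surface_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "surface_fit"))
  payload <- stats::setNames(
    lapply(names(fit$estimates), function(nm) {
      list(estimate = unname(fit$estimates[[nm]]),
           se = unname(fit$se[[nm]]))
    }),
    names(fit$estimates))
  payload$loglik <- fit$loglik
  payload$n_obs <- fit$n_obs
  payload$converged <- fit$converged
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline output directory carries one `manifest.json` recording
#' the command, configuration hash, seed, input/output paths, package
#' version, and timestamp; rerunning with the same manifest reproduces
#' deterministic outputs bit-exactly.
#'
#' @param out_dir Output directory.
#' @param command Command name.
#' @param seed Integer seed used.
#' @param inputs,outputs Character vectors of paths.
#' @param config_path Optional config file (hashed with MD5).
#' @export
write_manifest <- function(out_dir, command, seed, inputs = character(),
                           outputs = character(), config_path = NULL) {
  manifest <- list(
    command = command,
    seed = seed,
    config_hash = if (!is.null(config_path)) {
      unname(tools::md5sum(config_path))
    } else NULL,
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("acclimtol")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(out_dir, "manifest.json"))
}
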