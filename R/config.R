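# Configuration and dispatch plumbing shared by the command-line interface.

config_defaults <- function() {
  list(beta = 2, gamma = 0.8, mu = 0.2, N = 1000, kappa = 0, nu = 0,
       schedule = "poisson", rounding = "floor", model = "constrained",
       experiment = "mte", methods = "master_eq", n = 2000, seed = 1,
       t_max = 1e4, out_dir = ".", scale = "ci",
       kappa_grid = NULL, nu_grid = NULL, C = NULL)
}

config_known_keys <- function() names(config_defaults())

#' Parse a run configuration
#'
#' Reads a flat JSON (or YAML, if the `yaml` package is installed)
#' configuration file, applies defaults, and validates the result.  Explicit
#' `overrides` (e.g. from command-line flags) beat file values.  Unknown keys
#' are rejected with a field-level message.
#'
#' @param path Path to a JSON/YAML file, or `NULL` for defaults-plus-overrides.
#' @param overrides Named list of values that take precedence.
#' @return A validated list of class `run_config`.
#' @examples
#' cfg <- parse_config(overrides = list(N = 100, kappa = 0.1, nu = 4))
#' cfg$N
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  vals <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the 'yaml' package")
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (length(file_vals)) {
      unknown <- setdiff(names(file_vals), config_known_keys())
      if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
      vals[names(file_vals)] <- file_vals
    }
  }
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), config_known_keys())
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    vals[names(overrides)] <- overrides
  }
  validate_config(vals)
}

validate_config <- function(vals) {
  # these constructors carry the range checks
  params <- epidemic_params(vals$beta, vals$gamma, vals$mu, vals$N)
  policy <- treatment_policy(vals$kappa, vals$nu, vals$schedule, vals$rounding)
  vals$schedule <- policy$schedule
  vals$rounding <- policy$rounding
  vals$model <- match.arg(vals$model, c("constrained", "full"))
  vals$experiment <- match.arg(vals$experiment,
                               c("mte", "simulate", "path", "action", "qmap",
                                 "sweep", "compare-schedules", "fixed-dose",
                                 "prehistory"))
  vals$methods <- match.arg(vals$methods,
                            c("master_eq", "wkb", "simulation"),
                            several.ok = TRUE)
  vals$scale <- match.arg(vals$scale, c("ci", "full"))
  stopifnot(vals$n >= 1, vals$t_max > 0, is.numeric(vals$seed))
  structure(vals, class = "run_config")
}

#' Serialize a configuration back to its flat list form
#' @param config A `run_config`.
#' @return A plain named list (round-trips through [parse_config()]).
#' @export
config_as_list <- function(config) {
  unclass(config)
}

cfg_model <- function(config) {
  sis_model(epidemic_params(config$beta, config$gamma, config$mu, config$N),
            treatment_policy(config$kappa, config$nu, config$schedule,
                             config$rounding),
            kind = config$model)
}

#' Execute a configured experiment and write its artifacts
#'
#' Dispatches on `config$experiment`, writes the result table as CSV in
#' `config$out_dir` together with a JSON manifest (resolved parameters, seed,
#' wall time, package version), and returns the result invisibly.
#'
#' @param config A [parse_config()] result.
#' @return Invisibly, a list with `result` and the artifact paths.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  params <- epidemic_params(config$beta, config$gamma, config$mu, config$N)
  policy <- treatment_policy(config$kappa, config$nu, config$schedule,
                             config$rounding)
  kgrid <- config$kappa_grid %||% c(0.05, 0.1, 0.2)
  ngrid <- config$nu_grid %||% c(2, 4, 8, 12)

  result <- switch(
    config$experiment,
    "mte" = {
      model <- cfg_model(config)
      rows <- list()
      if ("master_eq" %in% config$methods && config$model == "constrained")
        rows$me <- sweep_record(model, "master_eq", master_eq_mte(model))
      if ("wkb" %in% config$methods && config$model == "constrained")
        rows$wkb <- sweep_record(model, "wkb",
                                 mte_wkb(action_quadrature(params, policy),
                                         prefactor(params, policy, "analytic"),
                                         params$N)$mte)
      if ("simulation" %in% config$methods) {
        e <- extinction_ensemble(model, n = config$n, seed = config$seed,
                                 t_max = config$t_max)
        rows$sim <- sweep_record(model, "simulation", e$mean, e$se, config$n,
                                 config$seed)
      }
      do.call(rbind, rows)
    },
    "simulate" = {
      e <- extinction_ensemble(cfg_model(config), n = config$n,
                               seed = config$seed, t_max = config$t_max)
      data.frame(realization = seq_len(e$n),
                 extinction_time = e$times, censored = !e$extinct,
                 seed = config$seed)
    },
    "path" = ,
    "action" = {
      pa <- optimal_path(cfg_model(config))
      df <- data.frame(t = pa$t)
      st <- as.data.frame(pa$state); names(st) <- if (ncol(st) == 1) "x" else c("s", "x")
      mo <- as.data.frame(pa$momentum); names(mo) <- if (ncol(mo) == 1) "p" else c("ps", "px")
      attr(df, "action") <- pa$action
      cbind(df, st, mo)
    },
    "qmap" = quasistationarity_map(params, policy,
                                   kappa = kgrid,
                                   beta = seq(params$gamma + params$mu + 0.1,
                                              2 * (params$gamma + params$mu), length.out = 8)),
    "sweep" = treatment_sweep(params, kappa = kgrid, nu = ngrid,
                              methods = config$methods, n = config$n,
                              seed = config$seed, t_max = config$t_max,
                              rounding = config$rounding),
    "compare-schedules" = schedule_comparison(params, kappa = kgrid,
                                              nu = ngrid, n = config$n,
                                              seed = config$seed,
                                              t_max = config$t_max,
                                              rounding = config$rounding),
    "fixed-dose" = fixed_dose_sweep(params, C = config$C %||% c(0.1, 0.2, 0.3),
                                    kappa = kgrid, methods = config$methods,
                                    rounding = config$rounding, n = config$n,
                                    seed = config$seed, t_max = config$t_max),
    "prehistory" = {
      pp <- prehistory_vs_path(params, policy, n_extinct = config$n,
                               seed = config$seed, t_max = config$t_max)
      attr(pp$ridge, "mean_dist_bins") <- pp$mean_dist_bins
      pp$ridge
    })

  csv_path <- file.path(config$out_dir,
                        paste0(gsub("-", "_", config$experiment), ".csv"))
  utils::write.csv(result, csv_path, row.names = FALSE)
  manifest <- list(config = config_as_list(config),
                   wall_time_s = proc.time()[["elapsed"]] - t0,
                   package_version = as.character(utils::packageVersion("sispulse")),
                   written = format(Sys.time(), tz = "UTC"))
  manifest_path <- file.path(config$out_dir,
                             paste0(gsub("-", "_", config$experiment),
                                    "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(result = result, csv = csv_path, manifest = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
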