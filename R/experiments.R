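# Scripted computational experiments: parameter sweeps producing tidy
# long-form tables.  Every record carries its full parameter tuple, a method
# tag, and (for simulation) a standard error; results are deterministic given
# the master seed.

sweep_record <- function(model, method, mte, se = NA_real_, n_real = NA_integer_,
                         seed = NA_integer_) {
  p <- model$params; pol <- model$policy
  data.frame(model = model$kind, beta = p$beta, gamma = p$gamma, mu = p$mu,
             N = p$N, kappa = pol$kappa, nu = pol$nu, schedule = pol$schedule,
             rounding = pol$rounding, method = method, mte_mean = mte,
             mte_se = se, log_mte = log(mte), n_realizations = n_real,
             seed = seed)
}

# master-equation MTE from the endemic state; falls back to the QSD decay
# rate when the direct solve leaves its accuracy domain
master_eq_mte <- function(model) {
  gen <- build_generator(model)
  tau <- withCallingHandlers(
    tryCatch(mean_extinction_time_direct(gen, start = endemic_state(model)),
             error = function(e) NA_real_),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.finite(tau) && tau < 1e12) return(tau)
  q <- suppressWarnings(quasi_stationary_distribution(gen))
  q$mte
}

#' Treatment sweep: mean time to extinction over (kappa, nu)
#'
#' Computes the MTE for every combination of treated fraction and pulse
#' frequency by the requested methods: `"master_eq"` (exact for the
#' constrained Poisson-schedule model), `"wkb"` (optimal-path action with
#' the analytic prefactor) and `"simulation"` (Gillespie ensemble of `n`
#' realizations started at the endemic state).  Grid cells with `RT <= 1`
#' are dropped with a note.
#'
#' @param params An [epidemic_params()] object.
#' @param kappa,nu Grid vectors.
#' @param methods Character subset of `c("master_eq", "wkb", "simulation")`.
#' @param n Realizations per simulated cell (default 2000).
#' @param seed Master seed.
#' @param t_max Simulation censoring horizon.
#' @param schedule,rounding Passed to [treatment_policy()].
#' @return Long-form data frame (one row per cell and method).
#' @export
treatment_sweep <- function(params, kappa, nu,
                            methods = c("master_eq", "wkb", "simulation"),
                            n = 2000, seed = 1, t_max = 1e4,
                            schedule = "poisson", rounding = "floor") {
  methods <- match.arg(methods, c("master_eq", "wkb", "simulation"),
                       several.ok = TRUE)
  out <- list()
  for (k in kappa) for (v in nu) {
    pol <- treatment_policy(k, v, schedule, rounding)
    rn <- reproduction_numbers(params, pol)
    if (rn$RT <= 1) {
      message(sprintf("dropping kappa = %g, nu = %g: RT = %.3g <= 1", k, v, rn$RT))
      next
    }
    model <- make_constrained_model(params, pol)
    if ("master_eq" %in% methods)
      out[[length(out) + 1]] <- sweep_record(model, "master_eq", master_eq_mte(model))
    if ("wkb" %in% methods) {
      s <- action_quadrature(params, pol)
      B <- prefactor(params, pol, "analytic")
      out[[length(out) + 1]] <- sweep_record(model, "wkb", mte_wkb(s, B, params$N)$mte)
    }
    if ("simulation" %in% methods) {
      e <- extinction_ensemble(model, n = n, seed = seed, t_max = t_max)
      out[[length(out) + 1]] <- sweep_record(model, "simulation", e$mean, e$se,
                                             n, seed)
    }
  }
  res <- do.call(rbind, out)
  flag_method_disagreement(res)
}

flag_method_disagreement <- function(res) {
  if (is.null(res)) return(res)
  res$flagged <- FALSE
  key <- interaction(res$kappa, res$nu, res$N, res$rounding, drop = TRUE)
  for (k in levels(key)) {
    sub <- res[key == k, ]
    i_sim <- which(key == k & res$method == "simulation")
    me <- sub$mte_mean[sub$method == "master_eq"]
    if (length(i_sim) == 1 && length(me) == 1 && is.finite(res$mte_se[i_sim])) {
      dev <- abs(res$mte_mean[i_sim] - me)
      res$flagged[i_sim] <- dev > 3 * res$mte_se[i_sim]
    }
  }
  res
}

#' Poisson versus periodic schedules, matched realization-by-realization
#'
#' Simulates both schedules at every `(kappa, nu)` cell with the same master
#' seed, so that realization `i` of the Poisson run and realization `i` of
#' the periodic run share a random stream (common random numbers); the paired
#' difference then has a much smaller variance than two independent
#' ensembles.
#'
#' @inheritParams treatment_sweep
#' @param nu Pulse-frequency set (default `c(2, 4, 8, 12)` per year).
#' @return Data frame with one row per cell: cell parameters, mean MTE and SE
#'   under each schedule, the paired mean difference `diff_mean`
#'   (periodic - poisson) and its standard error `diff_se`.
#' @export
schedule_comparison <- function(params, kappa, nu = c(2, 4, 8, 12), n = 2000,
                                seed = 1, t_max = 1e4, rounding = "floor") {
  out <- list()
  for (k in kappa) for (v in nu) {
    # start at the treated endemic state when it exists; when treatment is
    # strong enough to remove it (RT <= 1), the program is taken to begin on
    # an endemic disease, i.e. at the untreated endemic state
    pol0 <- treatment_policy(k, v, "poisson", rounding)
    init <- if (reproduction_numbers(params, pol0)$RT > 1)
      endemic_state(make_constrained_model(params, pol0))
    else endemic_state(make_constrained_model(params, treatment_policy()))
    runs <- lapply(c("poisson", "periodic"), function(sch) {
      pol <- treatment_policy(k, v, sch, rounding)
      extinction_ensemble(make_constrained_model(params, pol), n = n,
                          seed = seed, init = init, t_max = t_max)
    })
    po <- runs[[1]]; pe <- runs[[2]]
    ok <- po$extinct & pe$extinct
    dd <- pe$times[ok] - po$times[ok]
    out[[length(out) + 1]] <- data.frame(
      beta = params$beta, gamma = params$gamma, mu = params$mu, N = params$N,
      kappa = k, nu = v, n_realizations = n, seed = seed,
      mte_poisson = po$mean, se_poisson = po$se,
      mte_periodic = pe$mean, se_periodic = pe$se,
      diff_mean = mean(dd), diff_se = stats::sd(dd) / sqrt(length(dd)),
      n_paired = length(dd))
  }
  do.call(rbind, out)
}

#' Fixed total treatment supply: how to split dose rate into kappa and nu
#'
#' Holds the per-capita dose rate `C = kappa * nu` fixed and sweeps the
#' treated fraction `kappa` (so `nu = C / kappa`), asking whether few large
#' pulses or many small ones eradicate faster.  Methods as in
#' [treatment_sweep()]; with floor rounding, small `kappa` suffers the
#' rounding threshold (pulses stop acting once `I < 1/kappa`), which is what
#' drives the sharp MTE increase as `kappa -> 0`.
#'
#' @inheritParams treatment_sweep
#' @param C Dose-rate constants (1/year), e.g. `c(0.1, 0.2, 0.3)`.
#' @param kappa Treated-fraction grid.
#' @param rounding One or both of `"floor"`, `"ceil"`.
#' @return Long-form data frame with a `C` column.
#' @export
fixed_dose_sweep <- function(params, C = c(0.1, 0.2, 0.3),
                             kappa = c(0.02, 0.05, 0.1, 0.2, 0.3, 0.5),
                             methods = c("master_eq"),
                             rounding = "floor", n = 2000, seed = 1,
                             t_max = 1e4) {
  methods <- match.arg(methods, c("master_eq", "wkb", "simulation"),
                       several.ok = TRUE)
  out <- list()
  for (Ci in C) for (rnd in rounding) for (k in kappa) {
    pol <- treatment_policy(k, Ci / k, rounding = rnd)
    rn <- reproduction_numbers(params, pol)
    if (rn$RT <= 1) next
    model <- make_constrained_model(params, pol)
    rows <- list()
    if ("master_eq" %in% methods)
      rows$me <- sweep_record(model, "master_eq", master_eq_mte(model))
    if ("wkb" %in% methods)
      rows$wkb <- sweep_record(model, "wkb",
                               mte_wkb(action_quadrature(params, pol),
                                       prefactor(params, pol, "analytic"),
                                       params$N)$mte)
    if ("simulation" %in% methods) {
      e <- extinction_ensemble(model, n = n, seed = seed, t_max = t_max)
      rows$sim <- sweep_record(model, "simulation", e$mean, e$se, n, seed)
    }
    sub <- do.call(rbind, rows)
    sub$C <- Ci
    out[[length(out) + 1]] <- sub
  }
  do.call(rbind, out)
}

#' Constrained versus full model: action comparison
#'
#' Numeric optimal-path actions of both models over a `kappa` grid at fixed
#' pulse frequency, with their relative difference.
#'
#' @inheritParams treatment_sweep
#' @param nu Single pulse frequency.
#' @param n_nodes,t_half Passed to [optimal_path()].
#' @return Data frame: `kappa`, `nu`, `action_constrained`, `action_full`,
#'   `rel_diff` (constrained relative to full).
#' @export
model_comparison <- function(params, kappa, nu, n_nodes = 2001, t_half = NULL) {
  out <- lapply(kappa, function(k) {
    pol <- treatment_policy(k, if (k > 0) nu else 0)
    s1 <- tryCatch(optimal_path(make_constrained_model(params, pol),
                                n_nodes = n_nodes, t_half = t_half)$action,
                   error = function(e) NA_real_)
    s2 <- tryCatch(optimal_path(make_full_model(params, pol),
                                n_nodes = n_nodes, t_half = t_half)$action,
                   error = function(e) NA_real_)
    data.frame(kappa = k, nu = pol$nu, action_constrained = s1,
               action_full = s2, rel_diff = (s1 - s2) / s2)
  })
  do.call(rbind, out)
}

#' Extinction prehistory versus the optimal path
#'
#' Simulates full-model extinctions, pools the trailing-window occupancy
#' histogram over (S/N, I/N), extracts its ridge (the argmax susceptible
#' fraction within each infected-fraction column), and measures the mean
#' distance to the WKB optimal path in units of the susceptible-axis bin
#' width.
#'
#' @param params An [epidemic_params()] object.
#' @param policy A [treatment_policy()] object.
#' @param n_extinct Extinct realizations to pool.
#' @param window Trailing window before each extinction (years).
#' @param bins Number of bins per axis.
#' @param seed Master seed.
#' @param t_max Censoring horizon.
#' @param min_weight Ignore histogram columns holding less than this fraction
#'   of the total mass (they carry too few visits to define a ridge).
#' @return A list with the histogram (`density`, bin edges), `ridge` (data
#'   frame of column centers and ridge positions), the interpolated `path`,
#'   and `mean_dist_bins`, the mean ridge-to-path distance in bin widths.
#' @export
prehistory_vs_path <- function(params, policy, n_extinct = 5000, window = 5,
                               bins = 40, seed = 1, t_max = 1e4,
                               min_weight = 1e-4) {
  model <- make_full_model(params, policy)
  pa <- optimal_path(model)
  ep <- mean_field_endemic(params, policy, "full")
  # bin box: cover the path with margins of a few demographic standard deviations
  margin <- 4 / sqrt(params$N)
  s_rng <- range(pa$state[, 1]) + c(-margin, margin)
  x_rng <- c(0, max(pa$state[, 2]) + margin)
  breaks_s <- seq(s_rng[1], s_rng[2], length.out = bins + 1)
  breaks_x <- seq(x_rng[1], x_rng[2], length.out = bins + 1)
  ph <- extinction_prehistory(model, n_extinct = n_extinct, window = window,
                              breaks_s = breaks_s, breaks_x = breaks_x,
                              seed = seed, t_max = t_max)
  dens <- ph$density
  mids_s <- (breaks_s[-1] + breaks_s[-length(breaks_s)]) / 2
  mids_x <- (breaks_x[-1] + breaks_x[-length(breaks_x)]) / 2
  col_mass <- colSums(dens)
  keep <- which(col_mass > min_weight)
  ridge <- data.frame(x = mids_x[keep],
                      s = mids_s[apply(dens[, keep, drop = FALSE], 2, which.max)],
                      mass = col_mass[keep])
  # path s(x): interpolate along the monotone-in-x portion of the path
  ord <- order(pa$state[, 2])
  path_fun <- stats::approxfun(pa$state[ord, 2], pa$state[ord, 1], rule = 2,
                               ties = mean)
  ds <- breaks_s[2] - breaks_s[1]
  dist_bins <- abs(ridge$s - path_fun(ridge$x)) / ds
  list(density = dens, breaks_s = breaks_s, breaks_x = breaks_x,
       ridge = ridge, path = data.frame(s = pa$state[, 1], x = pa$state[, 2]),
       endemic = ep, n_extinct = ph$n_extinct,
       mean_dist_bins = stats::weighted.mean(dist_bins, ridge$mass),
       bin_width_s = ds)
}
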