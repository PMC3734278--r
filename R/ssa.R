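#' @useDynLib sispulse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

schedule_code <- function(policy) if (policy$schedule == "periodic") 1L else 0L
rounding_code <- function(policy) if (policy$rounding == "ceil") 1L else 0L

resolve_init <- function(model, init) {
  if (is.null(init)) init <- endemic_state(model)
  if (model$kind == "constrained") {
    I0 <- as.integer(init[["I"]])
    if (I0 < 0 || I0 > model$params$N) stop("initial I out of range")
    c(S = model$params$N - I0, I = I0)
  } else {
    S0 <- as.integer(init[["S"]]); I0 <- as.integer(init[["I"]])
    if (S0 < 0 || I0 < 0) stop("initial state must be non-negative")
    c(S = S0, I = I0)
  }
}

#' Simulate one realization to disease extinction
#'
#' Statistically exact event-driven simulation of the jump process.  With a
#' Poisson schedule the treatment pulse is an ordinary channel of constant
#' propensity `nu`; with a periodic schedule the demographic channels evolve
#' by the usual exponential clocks between the deterministic pulse times
#' `k/nu` (`k = 1, 2, ...`), the clock being capped at the next pulse, which
#' then fires exactly.  The run stops when the number of infected individuals
#' reaches zero, or is censored at `t_max`.
#'
#' @param model An [sis_model()] object.
#' @param init Named initial state (`c(I = ...)` or `c(S = ..., I = ...)`);
#'   default is the rounded mean-field endemic state.
#' @param t_max Censoring horizon in years (default `1e4`).
#' @param seed Integer master seed; a fixed seed reproduces the trajectory
#'   bit-for-bit.
#' @param record Keep the full event history (set `FALSE` for speed when only
#'   the extinction time is needed).
#' @param max_events Safety cap on the number of events.
#' @return An object of class `sis_trajectory`: list with `time` (extinction
#'   or censoring time, years), `extinct`, `pulse_times`, and, if recorded, a
#'   data frame `states` with columns `t`, `S`, `I`.
#' @examples
#' m <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 50))
#' tr <- simulate_to_extinction(m, seed = 1)
#' tr$extinct
#' @export
simulate_to_extinction <- function(model, init = NULL, t_max = 1e4, seed = 1,
                                   record = TRUE, max_events = 5e7) {
  stopifnot(inherits(model, "sis_model"), is.finite(t_max), t_max > 0)
  st <- resolve_init(model, init)
  p <- model$params; pol <- model$policy
  res <- ssa_run_cpp(if (model$kind == "constrained") 1L else 2L,
                     p$beta, p$gamma, p$mu, p$N, pol$kappa, pol$nu,
                     schedule_code(pol), rounding_code(pol),
                     st[["S"]], st[["I"]], t_max, as.double(seed), record,
                     as.double(max_events))
  out <- list(time = res$time, extinct = res$extinct,
              censored = !res$extinct, n_events = res$n_events,
              pulse_times = res$pulse_times, model = model, seed = seed)
  if (record)
    out$states <- data.frame(t = res$t, S = res$S, I = res$I)
  class(out) <- "sis_trajectory"
  out
}

#' @export
print.sis_trajectory <- function(x, ...) {
  cat(sprintf("SIS trajectory: %s at t = %.4g yr (%g events, %d pulses)\n",
              if (x$extinct) "extinct" else "censored",
              x$time, x$n_events, length(x$pulse_times)))
  invisible(x)
}

#' Ensemble of extinction times
#'
#' Runs `n` independent realizations from a common master seed.  Realization
#' `i` uses its own counter-derived random stream (stream `i` of the master
#' seed), so the ensemble is reproducible and independent of evaluation
#' order, and ensembles that share `seed` and `n` are paired realization-by-
#' realization across policies (useful for matched schedule comparisons).
#'
#' Censored realizations (no extinction by `t_max`) are excluded from the
#' mean and standard deviation; a warning is issued when more than 1% of
#' realizations are censored.
#'
#' @inheritParams simulate_to_extinction
#' @param n Number of realizations.
#' @return An object of class `extinction_ensemble`: list with the vector of
#'   extinction `times` (NA when censored), `n`, `n_censored`, `mean`, `sd`,
#'   `se` (= sd/sqrt(uncensored)), and the generating context.
#' @examples
#' m <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 30))
#' e <- extinction_ensemble(m, n = 200, seed = 42)
#' c(e$mean, e$se)
#' @export
extinction_ensemble <- function(model, n, seed = 1, init = NULL, t_max = 1e4,
                                max_events = 5e7) {
  stopifnot(inherits(model, "sis_model"), n >= 1)
  st <- resolve_init(model, init)
  p <- model$params; pol <- model$policy
  res <- ssa_ensemble_cpp(if (model$kind == "constrained") 1L else 2L,
                          p$beta, p$gamma, p$mu, p$N, pol$kappa, pol$nu,
                          schedule_code(pol), rounding_code(pol),
                          st[["S"]], st[["I"]], t_max, as.double(seed),
                          as.integer(n), as.double(max_events))
  times <- ifelse(res$extinct, res$time, NA_real_)
  n_cens <- sum(!res$extinct)
  if (n_cens > 0.01 * n)
    warning(sprintf("%d of %d realizations censored at t_max = %g yr", n_cens, n, t_max))
  ok <- res$extinct
  m <- if (any(ok)) mean(times[ok]) else NA_real_
  s <- if (sum(ok) > 1) stats::sd(times[ok]) else NA_real_
  structure(list(times = times, extinct = res$extinct, n = n,
                 n_censored = n_cens, mean = m, sd = s,
                 se = s / sqrt(sum(ok)), seed = seed, t_max = t_max,
                 model = model),
            class = "extinction_ensemble")
}

#' @export
print.extinction_ensemble <- function(x, ...) {
  cat(sprintf("Extinction ensemble: n = %d (%d censored)\n", x$n, x$n_censored))
  cat(sprintf("  mean = %.6g yr   sd = %.6g   se = %.3g\n", x$mean, x$sd, x$se))
  invisible(x)
}

#' Extinction prehistory density from recorded trajectories
#'
#' Pools the final `window` years before extinction of each trajectory into a
#' time-weighted occupancy histogram of the normalized state, normalized to
#' total mass 1.  For full-model trajectories the histogram is over
#' (S/N, I/N); for constrained ones, over I/N alone.
#'
#' @param trajectories A list of extinct [simulate_to_extinction()] results
#'   with recorded states.
#' @param window Length of the trailing window (years, default 5).
#' @param breaks_s,breaks_x Bin edges for the susceptible and infected
#'   fractions (the former ignored for constrained trajectories).
#' @return A list with `density` (matrix or vector), the bin edges, and the
#'   pooled occupancy time `total_time`.
#' @export
prehistory_density <- function(trajectories, window = 5,
                               breaks_s = seq(0, 1.5, by = 0.02),
                               breaks_x = seq(0, 1, by = 0.02)) {
  stopifnot(length(trajectories) > 0, window > 0)
  if (!all(vapply(trajectories, function(x) isTRUE(x$extinct), TRUE)))
    stop("all trajectories must be extinct")
  kind <- trajectories[[1]]$model$kind
  N <- trajectories[[1]]$model$params$N
  two_d <- kind == "full"
  dens <- if (two_d)
    matrix(0, length(breaks_s) - 1, length(breaks_x) - 1)
  else numeric(length(breaks_x) - 1)
  total <- 0
  for (tr in trajectories) {
    if (is.null(tr$states)) stop("trajectory has no recorded states")
    st <- tr$states
    t_end <- tr$time
    t0 <- t_end - window
    dur <- pmin(c(st$t[-1], t_end), t_end) - pmax(st$t, t0)
    keep <- dur > 0
    if (!any(keep)) next
    xf <- st$I[keep] / N
    wts <- dur[keep]
    if (two_d) {
      sf <- st$S[keep] / N
      is <- findInterval(sf, breaks_s, rightmost.closed = TRUE)
      ix <- findInterval(xf, breaks_x, rightmost.closed = TRUE)
      ok <- is >= 1 & is <= nrow(dens) & ix >= 1 & ix <= ncol(dens)
      for (j in which(ok)) dens[is[j], ix[j]] <- dens[is[j], ix[j]] + wts[j]
    } else {
      ix <- findInterval(xf, breaks_x, rightmost.closed = TRUE)
      ok <- ix >= 1 & ix <= length(dens)
      for (j in which(ok)) dens[ix[j]] <- dens[ix[j]] + wts[j]
    }
    total <- total + sum(wts)
  }
  if (total <= 0) stop("no occupancy mass collected")
  list(density = dens / total, breaks_s = if (two_d) breaks_s else NULL,
       breaks_x = breaks_x, total_time = total)
}

#' Fast pooled prehistory histogram for the full model
#'
#' Runs full-model realizations until `n_extinct` extinctions have been
#' collected, accumulating the trailing-window occupancy histogram in the
#' simulation core without storing trajectories.
#'
#' @param model A full-kind [sis_model()].
#' @param n_extinct Number of extinct realizations to collect.
#' @param window Trailing window (years).
#' @param breaks_s,breaks_x Uniform bin edges over the susceptible and
#'   infected fractions.
#' @param seed Master seed.
#' @param t_max Censoring horizon per realization.
#' @param max_runs Cap on attempted realizations.
#' @return List with normalized `density` (rows: S/N bins, columns: I/N
#'   bins), bin edges, `n_extinct`, `n_runs`.
#' @export
extinction_prehistory <- function(model, n_extinct, window = 5,
                                  breaks_s = seq(0.7, 1.1, by = 0.01),
                                  breaks_x = seq(0, 0.4, by = 0.01),
                                  seed = 1, t_max = 1e4, max_runs = 10 * n_extinct) {
  stopifnot(inherits(model, "sis_model"))
  if (model$kind != "full")
    stop("extinction_prehistory() requires the full two-compartment model")
  st <- resolve_init(model, NULL)
  p <- model$params; pol <- model$policy
  ds <- diff(breaks_s); dx <- diff(breaks_x)
  if (max(abs(ds - ds[1])) > 1e-12 || max(abs(dx - dx[1])) > 1e-12)
    stop("bin edges must be uniform")
  res <- ssa_prehistory_cpp(p$beta, p$gamma, p$mu, p$N, pol$kappa, pol$nu,
                            schedule_code(pol), rounding_code(pol),
                            st[["S"]], st[["I"]], t_max, as.double(seed),
                            as.integer(n_extinct), as.integer(max_runs), window,
                            breaks_s[1], breaks_s[length(breaks_s)], length(ds),
                            breaks_x[1], breaks_x[length(breaks_x)], length(dx),
                            5e7)
  if (res$n_extinct < n_extinct)
    warning(sprintf("collected %d/%d extinctions in %d runs",
                    res$n_extinct, n_extinct, res$n_runs))
  if (res$n_extinct == 0) stop("no extinct realizations collected")
  h <- res$hist
  list(density = h / sum(h), breaks_s = breaks_s, breaks_x = breaks_x,
       n_extinct = res$n_extinct, n_runs = res$n_runs)
}
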