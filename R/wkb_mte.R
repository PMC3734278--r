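# Mean time to extinction from the WKB side: tau ~ B * exp(N s), with s the
# per-capita action along the optimal path and B a non-exponential prefactor.

#' Small-treatment asymptotic action
#'
#' Truncated expansion `s(kappa) = s0 + kappa * s1 + O(kappa^2)` of the
#' constrained-model action in the treated fraction.  The zeroth term is the
#' untreated closed form `s0 = log(R0) - 1 + 1/R0`.  The linear response
#' `s1` follows from first-order perturbation of the zero-energy action: for
#' a Hamiltonian perturbed by `kappa * H1` the action shift is
#' `-kappa * int H1 dt` along the unperturbed path.  Here the treatment term
#' linearizes to `H1 = -nu * x * p`, so
#' `s1 = nu * int x p dt = nu * int p(x) / ((gamma + mu) - beta (1 - x)) dx`
#' evaluated by quadrature along the untreated branch
#' `p(x) = log((gamma + mu) / (beta (1 - x)))` (the integrand's endpoint
#' limit at the endemic state is `1 / (gamma + mu)`).
#'
#' The expansion is a small-`kappa` approximation; a warning is issued beyond
#' `validity` (default 0.2), where the truncation error grows quickly.
#'
#' @param params An [epidemic_params()] object with `R0 > 1`.
#' @param policy A [treatment_policy()] object.
#' @param validity Warn when `kappa` exceeds this bound.
#' @return The truncated action, with attributes `s0` and `s1`.
#' @examples
#' p <- epidemic_params(2, 0.8, 0.2, 1000)
#' action_asymptotic(p, treatment_policy(0.05, 2))
#' @export
action_asymptotic <- function(params, policy = treatment_policy(),
                              validity = 0.2) {
  beta <- params$beta; gm <- params$gamma + params$mu
  R0 <- beta / gm
  if (R0 <= 1) stop("no endemic state without treatment: R0 <= 1")
  kappa <- policy$kappa; nu <- policy$nu
  if (kappa > validity)
    warning(sprintf("kappa = %g exceeds the expansion's validity bound %g",
                    kappa, validity))
  s0 <- log(R0) - 1 + 1 / R0
  xs <- 1 - 1 / R0
  integrand <- function(x) {
    den <- gm - beta * (1 - x)
    out <- log(gm / (beta * (1 - x))) / den
    out[abs(x - xs) < 1e-10] <- 1 / gm
    out
  }
  s1 <- nu * stats::integrate(integrand, xs, 0, rel.tol = 1e-12)$value
  structure(s0 + kappa * s1, s0 = s0, s1 = s1)
}

#' Prefactor of the mean time to extinction
#'
#' The WKB estimate `tau = B * exp(N s)` needs a non-exponential prefactor
#' `B` (years).  Three modes:
#'
#' * `"analytic"` (constrained model): the matched-asymptotics prefactor of
#'   the one-dimensional chain,
#'   `B = sqrt(2 pi / N) * R / ((R - 1)^2 * delta)`, evaluated with the
#'   treated removal rate `delta = gamma + mu + kappa * nu` and the treated
#'   reproduction number `R = RT`, which carries the policy dependence and
#'   reduces to the classical untreated SIS prefactor at `kappa = 0`.  Like
#'   the action expansion it is a small-treatment approximation.
#' * `"calibrated"`: `B = mte_ref / exp(N_ref * s_ref)` from one reference
#'   mean extinction time (master-equation or simulation), reused across a
#'   parameter sweep; this is the practical route for the full model.
#' * `"unity"`: `B = 1`, for log-scale comparisons where only the exponential
#'   matters.
#'
#' @param params An [epidemic_params()] object.
#' @param policy A [treatment_policy()] object.
#' @param mode `"analytic"`, `"calibrated"` or `"unity"`.
#' @param mte_ref,N_ref,s_ref Calibration data (calibrated mode): a reference
#'   MTE (years), the population and per-capita action at which it was
#'   obtained.
#' @return The prefactor `B` in years.
#' @export
prefactor <- function(params, policy = treatment_policy(),
                      mode = c("analytic", "calibrated", "unity"),
                      mte_ref = NULL, N_ref = NULL, s_ref = NULL) {
  mode <- match.arg(mode)
  if (mode == "unity") return(1)
  if (mode == "calibrated") {
    if (is.null(mte_ref) || is.null(N_ref) || is.null(s_ref))
      stop("calibrated mode needs `mte_ref`, `N_ref` and `s_ref`")
    return(mte_ref / exp(N_ref * s_ref))
  }
  rn <- reproduction_numbers(params, policy)
  if (rn$RT <= 1) stop("analytic prefactor requires RT > 1")
  delta <- params$gamma + params$mu + policy$kappa * policy$nu
  sqrt(2 * pi / params$N) * rn$RT / ((rn$RT - 1)^2 * delta)
}

#' WKB mean time to extinction
#'
#' Combines a per-capita action and a prefactor into
#' `tau = B * exp(N * s)`.  When the exponent overflows double precision the
#' `mte` field is `Inf` with `overflow = TRUE`; `log_mte` is always finite
#' and is the quantity to report for large populations.
#'
#' @param s Per-capita action (dimensionless, `>= 0`).
#' @param B Prefactor (years, `> 0`).
#' @param N Population size.
#' @param method Tag recorded in the result (e.g. `"wkb_numeric"`).
#' @return An object of class `mte_estimate`: list with `s`, `B`, `N`, `mte`,
#'   `log_mte`, `overflow`, `method`.
#' @examples
#' mte_wkb(0.19314718, B = 0.35, N = 100)
#' @export
mte_wkb <- function(s, B, N, method = "wkb_numeric") {
  stopifnot(s >= 0, B > 0, N > 0)
  log_mte <- log(B) + N * s
  structure(list(s = s, B = B, N = N,
                 mte = if (log_mte > 709) Inf else exp(log_mte),
                 log_mte = log_mte, overflow = log_mte > 709,
                 method = method),
            class = "mte_estimate")
}

#' @export
print.mte_estimate <- function(x, ...) {
  cat(sprintf("MTE estimate (%s): ln(tau/yr) = %.4f  (N = %g, s = %.6g, B = %.4g yr)%s\n",
              x$method, x$log_mte, x$N, x$s, x$B,
              if (x$overflow) "  [overflow: tau reported as Inf]" else
                sprintf("  tau = %.6g yr", x$mte)))
  invisible(x)
}

#' Quasi-stationarity map over treatment and contact rate
#'
#' Evaluates the extinction exponent `N * s` of the constrained model on a
#' grid of treated fraction `kappa` and contact rate `beta` at fixed pulse
#' frequency, recovery and turnover rates.  The WKB picture requires
#' quasi-stationarity: extinction must sit far in the tail of the
#' distribution, i.e. `N * s` large (threshold 10 by default).  Cells outside
#' the endemic region (`RT <= 1`) are undefined; the `RT = 1` boundary is the
#' curve `kappa = (beta - gamma - mu) / nu`.  Per-cell actions come from the
#' machine-accurate branch quadrature ([action_quadrature()]), so the map has
#' no path-solver failure modes; `N * s` tends to 0 at the boundary and the
#' fixed-`N*s` contours approach the `RT = 1` curve as `N` grows.
#'
#' @param params An [epidemic_params()] object (its `beta` is ignored).
#' @param policy A [treatment_policy()] object (its `kappa` is ignored).
#' @param kappa,beta Grid vectors.
#' @param threshold Quasi-stationarity threshold on `N * s`.
#' @return A data frame with one row per cell: `kappa`, `beta`, `RT`, `s`,
#'   `Ns`, `quasistationary`; the `RT = 1` boundary is attached as attribute
#'   `rt_boundary` (a data frame of `beta`, `kappa`).
#' @export
quasistationarity_map <- function(params, policy, kappa, beta, threshold = 10) {
  stopifnot(inherits(params, "epidemic_params"),
            inherits(policy, "treatment_policy"))
  grid <- expand.grid(kappa = kappa, beta = beta)
  n <- nrow(grid)
  grid$RT <- grid$beta / (params$gamma + params$mu + grid$kappa * policy$nu)
  grid$s <- NA_real_
  for (i in seq_len(n)) {
    if (grid$RT[i] <= 1) next
    p_i <- epidemic_params(grid$beta[i], params$gamma, params$mu, params$N)
    pol_i <- treatment_policy(grid$kappa[i], policy$nu, policy$schedule,
                              policy$rounding)
    grid$s[i] <- tryCatch(action_quadrature(p_i, pol_i),
                          error = function(e) NA_real_)
  }
  grid$Ns <- params$N * grid$s
  grid$quasistationary <- !is.na(grid$Ns) & grid$Ns >= threshold
  bnd <- data.frame(beta = beta,
                    kappa = pmax((beta - params$gamma - params$mu) / policy$nu, 0))
  attr(grid, "rt_boundary") <- bnd
  attr(grid, "threshold") <- threshold
  grid
}
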