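#' Demographic and epidemic rate parameters
#'
#' Bundles the rates of the SIS model: contact rate `beta`, recovery rate
#' `gamma`, and the common birth-and-death rate `mu` (births balance deaths so
#' that the population is constant over time on average), together with the
#' mean population size `N`.  All rates are per year.
#'
#' @param beta Contact rate (1/year), positive.
#' @param gamma Recovery rate (1/year), non-negative.
#' @param mu Birth-and-death rate (1/year), positive.
#' @param N Mean population size (individuals), integer at least 2.
#'
#' @return An object of class `epidemic_params`.
#' @examples
#' epidemic_params(beta = 2, gamma = 0.8, mu = 0.2, N = 1000)
#' @export
epidemic_params <- function(beta, gamma, mu, N) {
  stopifnot(is.numeric(beta), is.numeric(gamma), is.numeric(mu), is.numeric(N),
            length(beta) == 1, length(gamma) == 1, length(mu) == 1, length(N) == 1)
  if (!is.finite(beta) || beta <= 0) stop("`beta` must be positive and finite")
  if (!is.finite(gamma) || gamma < 0) stop("`gamma` must be non-negative")
  if (!is.finite(mu) || mu <= 0) stop("`mu` must be positive")
  if (!is.finite(N) || N < 2 || N != round(N)) stop("`N` must be an integer >= 2")
  structure(list(beta = beta, gamma = gamma, mu = mu, N = as.integer(N)),
            class = "epidemic_params")
}

#' @export
print.epidemic_params <- function(x, ...) {
  cat("SIS epidemic parameters\n")
  cat(sprintf("  beta  = %g /yr   gamma = %g /yr   mu = %g /yr\n",
              x$beta, x$gamma, x$mu))
  cat(sprintf("  N     = %d individuals   R0 = %.4g\n",
              x$N, x$beta / (x$gamma + x$mu)))
  invisible(x)
}

#' Pulsed-treatment policy
#'
#' Describes a treatment program that, `nu` times per year on average, cures a
#' fraction `kappa` of all currently infected individuals and returns them to
#' the susceptible class (treatment is taken to be fully effective; partial
#' efficacy is equivalent to a smaller `kappa`).  Pulses arrive either at
#' exponentially distributed intervals with mean `1/nu` (`schedule =
#' "poisson"`) or at the fixed times `k/nu`, `k = 1, 2, ...`
#' (`schedule = "periodic"`).  Because the number treated must be an integer,
#' `kappa * I` is rounded: `"floor"` keeps the integer part (so pulses stop
#' having any effect once `I < 1/kappa`), `"ceil"` rounds up to the
#' next-highest integer (so every pulse removes at least one infected).
#'
#' @param kappa Fraction of infecteds treated per pulse, in `[0, 1]`.
#' @param nu Mean number of pulses per year, non-negative.
#' @param schedule `"poisson"` (default) or `"periodic"`.
#' @param rounding `"floor"` (default) or `"ceil"`.
#'
#' @return An object of class `treatment_policy`.
#' @examples
#' treatment_policy(kappa = 0.1, nu = 4)
#' treatment_policy(0.25, 2, schedule = "periodic", rounding = "ceil")
#' @export
treatment_policy <- function(kappa = 0, nu = 0,
                             schedule = c("poisson", "periodic"),
                             rounding = c("floor", "ceil")) {
  schedule <- match.arg(schedule)
  rounding <- match.arg(rounding)
  stopifnot(is.numeric(kappa), length(kappa) == 1,
            is.numeric(nu), length(nu) == 1)
  if (!is.finite(kappa) || kappa < 0 || kappa > 1)
    stop("`kappa` must lie in [0, 1]")
  if (!is.finite(nu) || nu < 0) stop("`nu` must be non-negative and finite")
  structure(list(kappa = kappa, nu = nu, schedule = schedule,
                 rounding = rounding),
            class = "treatment_policy")
}

#' @export
print.treatment_policy <- function(x, ...) {
  if (x$kappa * x$nu == 0) {
    cat("Treatment policy: none (kappa * nu = 0)\n")
  } else {
    cat(sprintf("Treatment policy: %s pulses, %g /yr, fraction %g per pulse (%s rounding)\n",
                x$schedule, x$nu, x$kappa, x$rounding))
  }
  invisible(x)
}

#' Number of infecteds removed by one treatment pulse
#'
#' Applies the policy's rounding rule to `kappa * I`.  With floor rounding the
#' pulse is a no-op whenever `kappa * I < 1`.
#'
#' @param kappa Treated fraction per pulse.
#' @param I Current number of infected individuals (vectorized).
#' @param rounding `"floor"` or `"ceil"`.
#' @return Integer vector of removed counts, each in `[0, I]`.
#' @examples
#' pulse_size(0.3, 3)  # floor(0.9) = 0: no effect
#' pulse_size(0.3, 4)  # floor(1.2) = 1
#' @export
pulse_size <- function(kappa, I, rounding = c("floor", "ceil")) {
  rounding <- match.arg(rounding)
  # tolerance guards against binary representation of kappa * I
  # (e.g. 0.3 * 10 = 2.9999999999999996)
  k <- if (rounding == "floor") floor(kappa * I + 1e-9) else ceiling(kappa * I - 1e-9)
  as.integer(pmax(0, pmin(I, k)))
}

#' Basic and treated reproduction numbers
#'
#' `R0 = beta / (gamma + mu)` is the mean number of secondary cases per
#' infective over one infectious period.  Under pulsed treatment the mean
#' per-capita removal rate gains the term `kappa * nu`, giving the treated
#' reproduction number `RT = beta / (gamma + mu + kappa * nu)`.  The mean-field
#' endemic state exists if and only if `RT > 1`.
#'
#' @param params An [epidemic_params()] object.
#' @param policy A [treatment_policy()] object (default: no treatment).
#' @return A list with components `R0` and `RT`, class `reproduction_numbers`.
#' @examples
#' reproduction_numbers(epidemic_params(2, 0.8, 0.2, 1000),
#'                      treatment_policy(0.1, 4))
#' @export
reproduction_numbers <- function(params, policy = treatment_policy()) {
  stopifnot(inherits(params, "epidemic_params"),
            inherits(policy, "treatment_policy"))
  R0 <- params$beta / (params$gamma + params$mu)
  RT <- params$beta / (params$gamma + params$mu + policy$kappa * policy$nu)
  structure(list(R0 = R0, RT = RT), class = "reproduction_numbers")
}

#' @export
print.reproduction_numbers <- function(x, ...) {
  cat(sprintf("R0 = %.6g,  RT = %.6g%s\n", x$R0, x$RT,
              if (x$RT > 1) "  (endemic state exists)" else "  (no endemic state)"))
  invisible(x)
}

#' Mean-field endemic state
#'
#' The deterministic (zero-momentum) endemic equilibrium of the scaled model.
#' For the constrained model this is the positive root of
#' `beta * x * (1 - x) - (gamma + mu) * x - kappa * nu * x = 0`, i.e.
#' `x* = 1 - 1/RT`.  For the full model the fixed point is
#' `(s*, x*) = ((gamma + mu + kappa*nu) / beta, 1 - (gamma + mu + kappa*nu) / beta)`,
#' which reduces to the constrained result on the `s = 1 - x` slice.
#'
#' @param params An [epidemic_params()] object.
#' @param policy A [treatment_policy()] object.
#' @param model `"constrained"` or `"full"`.
#' @return Named numeric vector: `c(x = ...)` for the constrained model,
#'   `c(s = ..., x = ...)` for the full model (fractions of `N`).
#' @examples
#' mean_field_endemic(epidemic_params(2, 0.8, 0.2, 1000), treatment_policy())
#' @export
mean_field_endemic <- function(params, policy = treatment_policy(),
                               model = c("constrained", "full")) {
  model <- match.arg(model)
  rn <- reproduction_numbers(params, policy)
  if (rn$RT <= 1)
    stop(sprintf("no endemic state: RT = %.4g <= 1", rn$RT))
  delta <- (params$gamma + params$mu + policy$kappa * policy$nu) / params$beta
  if (model == "constrained") c(x = 1 - delta) else c(s = delta, x = 1 - delta)
}
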