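#' SIS jump-process model specification
#'
#' Assembles the transition channels of the stochastic SIS model with pulsed
#' treatment, in one of two forms:
#'
#' * `kind = "constrained"`: the population is held at exactly `N` and only
#'   the infected count `I` is tracked.  Three channels: infection
#'   `I -> I + 1` at rate `beta * I * (N - I) / N`; a combined
#'   recovery-plus-death channel `I -> I - 1` at rate `(gamma + mu) * I`
#'   (a death of an infected is immediately balanced by a susceptible birth,
#'   so both recovery and death act as a unit down-step); and the bulk
#'   treatment channel `I -> I - k(I)` with `k(I) = pulse_size(kappa, I)`,
#'   at constant propensity `nu`.
#' * `kind = "full"`: `S` and `I` are tracked separately and the total
#'   population fluctuates around `N`.  Six channels: birth `S -> S + 1` at
#'   constant rate `mu * N`; deaths of `S` and of `I` at per-capita rate `mu`;
#'   infection `(S, I) -> (S - 1, I + 1)` at `beta * S * I / N`; recovery
#'   `(S, I) -> (S + 1, I - 1)` at `gamma * I`; and treatment
#'   `(S, I) -> (S + k(I), I - k(I))` at propensity `nu`.
#'
#' The infection denominator is the fixed mean population size `N` in both
#' forms, so the full model reduces to the constrained one when population
#' fluctuations are small.  When `kappa * nu = 0` the treatment channel is
#' omitted.  The treatment channel is a realized no-op whenever the rounding
#' rule gives `k(I) = 0` (floor rounding: all `I < 1/kappa`).
#'
#' @param params An [epidemic_params()] object.
#' @param policy A [treatment_policy()] object.
#' @param kind `"constrained"` or `"full"`.
#' @return An object of class `sis_model`: a list with `kind`, `params`,
#'   `policy` and `channels`.  Each channel has a `name`, an `increment`
#'   function of the state (returning the integer jump vector), a `rate`
#'   function of the state, and an `is_bulk` flag.
#' @seealso [make_constrained_model()], [make_full_model()], [propensities()]
#' @examples
#' m <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 100),
#'                             treatment_policy(0.3, 4))
#' propensities(m, c(I = 10))
#' @export
sis_model <- function(params, policy = treatment_policy(),
                      kind = c("constrained", "full")) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "epidemic_params"),
            inherits(policy, "treatment_policy"))
  beta <- params$beta; gamma <- params$gamma; mu <- params$mu
  N <- params$N; kappa <- policy$kappa; nu <- policy$nu
  rounding <- policy$rounding
  treat <- kappa * nu > 0

  if (kind == "constrained") {
    channels <- list(
      list(name = "infection", is_bulk = FALSE,
           increment = function(state) c(I = 1L),
           rate = function(state) beta * state[["I"]] * (N - state[["I"]]) / N),
      list(name = "recovery_death", is_bulk = FALSE,
           increment = function(state) c(I = -1L),
           rate = function(state) (gamma + mu) * state[["I"]])
    )
    if (treat) {
      channels <- c(channels, list(
        list(name = "treatment", is_bulk = TRUE,
             increment = function(state)
               c(I = -pulse_size(kappa, state[["I"]], rounding)),
             rate = function(state) nu)))
    }
  } else {
    channels <- list(
      list(name = "birth", is_bulk = FALSE,
           increment = function(state) c(S = 1L, I = 0L),
           rate = function(state) mu * N),
      list(name = "death_S", is_bulk = FALSE,
           increment = function(state) c(S = -1L, I = 0L),
           rate = function(state) mu * state[["S"]]),
      list(name = "death_I", is_bulk = FALSE,
           increment = function(state) c(S = 0L, I = -1L),
           rate = function(state) mu * state[["I"]]),
      list(name = "infection", is_bulk = FALSE,
           increment = function(state) c(S = -1L, I = 1L),
           rate = function(state) beta * state[["S"]] * state[["I"]] / N),
      list(name = "recovery", is_bulk = FALSE,
           increment = function(state) c(S = 1L, I = -1L),
           rate = function(state) gamma * state[["I"]])
    )
    if (treat) {
      channels <- c(channels, list(
        list(name = "treatment", is_bulk = TRUE,
             increment = function(state) {
               k <- pulse_size(kappa, state[["I"]], rounding)
               c(S = k, I = -k)
             },
             rate = function(state) nu)))
    }
  }
  structure(list(kind = kind, params = params, policy = policy,
                 channels = channels),
            class = "sis_model")
}

#' @rdname sis_model
#' @export
make_constrained_model <- function(params, policy = treatment_policy()) {
  sis_model(params, policy, kind = "constrained")
}

#' @rdname sis_model
#' @export
make_full_model <- function(params, policy = treatment_policy()) {
  sis_model(params, policy, kind = "full")
}

#' @export
print.sis_model <- function(x, ...) {
  cat(sprintf("SIS model (%s), %d channels\n", x$kind, length(x$channels)))
  print(x$params)
  print(x$policy)
  invisible(x)
}

#' Channel propensities at a state
#'
#' Evaluates every channel's rate at the given state of raw counts.  Rates of
#' jumps that would drive a count negative are zero by construction of the
#' rate laws (e.g. the infection rate vanishes at `I = 0` and, in the
#' constrained model, at `I = N`).
#'
#' @param model An [sis_model()] object.
#' @param state Named integer vector: `c(I = ...)` for the constrained model,
#'   `c(S = ..., I = ...)` for the full one.
#' @return Named numeric vector of propensities (1/year).
#' @export
propensities <- function(model, state) {
  stopifnot(inherits(model, "sis_model"))
  if (model$kind == "constrained") {
    stopifnot("I" %in% names(state), state[["I"]] >= 0,
              state[["I"]] <= model$params$N)
  } else {
    stopifnot(all(c("S", "I") %in% names(state)),
              state[["S"]] >= 0, state[["I"]] >= 0)
  }
  vapply(model$channels, function(ch) ch$rate(state), numeric(1)) |>
    stats::setNames(vapply(model$channels, `[[`, "", "name"))
}

#' Default initial state: the mean-field endemic state, rounded to counts
#' @param model An [sis_model()] object.
#' @return Named integer state vector.
#' @export
endemic_state <- function(model) {
  N <- model$params$N
  ep <- mean_field_endemic(model$params, model$policy,
                           if (model$kind == "constrained") "constrained" else "full")
  if (model$kind == "constrained") {
    c(I = as.integer(round(ep[["x"]] * N)))
  } else {
    c(S = as.integer(round(ep[["s"]] * N)), I = as.integer(round(ep[["x"]] * N)))
  }
}
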