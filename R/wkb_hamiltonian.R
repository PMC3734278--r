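# WKB (eikonal) machinery: the probability of a large fluctuation of the
# scaled jump process is written P ~ exp(-N s(x)), which turns the master
# equation into a Hamilton-Jacobi problem with Hamiltonian
#   H(x, p) = sum_r w(x; r) (exp(p . r) - 1),
# w the scaled channel rates and r the (normalized) jumps.  The momentum
# convention is p = ds/dx: the extinction path carries p < 0 and a positive
# action.  The bulk treatment channel keeps its intensive propensity nu and
# enters through its normalized increment -kappa*x (continuous in x: in the
# WKB frame pulses act at arbitrarily small x, with no integer rounding).
#
# Constrained model (state x, momentum p):
#   H = beta x (1-x) (e^p - 1) + (gamma+mu) x (e^-p - 1) + nu (e^{-kappa x p} - 1)
# Full model (state (s, x), momenta (ps, px)):
#   H = mu (e^{ps} - 1) + mu s (e^{-ps} - 1) + mu x (e^{-px} - 1)
#     + beta s x (e^{px - ps} - 1) + gamma x (e^{ps - px} - 1)
#     + nu (e^{kappa x (ps - px)} - 1)

wkb_dim <- function(model) if (model$kind == "constrained") 1L else 2L

# Z: matrix with columns (x, p) or (s, x, ps, px); returns numeric vector H
wkb_H <- function(model, Z) {
  p <- model$params; pol <- model$policy
  beta <- p$beta; gamma <- p$gamma; mu <- p$mu
  kappa <- pol$kappa; nu <- pol$nu
  if (model$kind == "constrained") {
    x <- Z[, 1]; pp <- Z[, 2]
    gm <- gamma + mu
    beta * x * (1 - x) * expm1(pp) + gm * x * expm1(-pp) +
      (if (kappa * nu > 0) nu * expm1(-kappa * x * pp) else 0)
  } else {
    s <- Z[, 1]; x <- Z[, 2]; u <- Z[, 3]; v <- Z[, 4]
    mu * expm1(u) + mu * s * expm1(-u) + mu * x * expm1(-v) +
      beta * s * x * expm1(v - u) + gamma * x * expm1(u - v) +
      (if (kappa * nu > 0) nu * expm1(kappa * x * (u - v)) else 0)
  }
}

# Characteristic field F = (dH/dp, -dH/dx) and its Jacobian, vectorized over
# the rows of Z.  J[n, i, j] = dF_i/dz_j with z the full phase vector.
wkb_field <- function(model, Z) {
  p <- model$params; pol <- model$policy
  beta <- p$beta; gamma <- p$gamma; mu <- p$mu
  kappa <- pol$kappa; nu <- pol$nu
  n <- nrow(Z)
  if (model$kind == "constrained") {
    gm <- gamma + mu
    x <- Z[, 1]; pp <- Z[, 2]
    ep <- exp(pp); em <- exp(-pp)
    a <- beta * x * (1 - x); ap <- beta * (1 - 2 * x)
    if (kappa * nu > 0) {
      et <- exp(-kappa * x * pp)
      Hp <- a * ep - gm * x * em - nu * kappa * x * et
      Hx <- ap * expm1(pp) + gm * expm1(-pp) - nu * kappa * pp * et
      Hpp <- a * ep + gm * x * em + nu * kappa^2 * x^2 * et
      Hxp <- ap * ep - gm * em - nu * kappa * et * (1 - kappa * x * pp)
      Hxx <- -2 * beta * expm1(pp) + nu * kappa^2 * pp^2 * et
    } else {
      Hp <- a * ep - gm * x * em
      Hx <- ap * expm1(pp) + gm * expm1(-pp)
      Hpp <- a * ep + gm * x * em
      Hxp <- ap * ep - gm * em
      Hxx <- -2 * beta * expm1(pp)
    }
    J <- array(c(Hxp, -Hxx, Hpp, -Hxp), dim = c(n, 2, 2))
    list(F = cbind(Hp, -Hx), J = J)
  } else {
    s <- Z[, 1]; x <- Z[, 2]; u <- Z[, 3]; v <- Z[, 4]
    eu <- exp(u); emu <- exp(-u); emv <- exp(-v)
    evu <- exp(v - u); euv <- exp(u - v)
    treat <- kappa * nu > 0
    w <- kappa * x * (u - v); ew <- if (treat) exp(w) else 0
    tk <- if (treat) nu * kappa else 0
    Hu <- mu * eu - mu * s * emu - beta * s * x * evu + gamma * x * euv + tk * x * ew
    Hv <- -mu * x * emv + beta * s * x * evu - gamma * x * euv - tk * x * ew
    Hs <- mu * expm1(-u) + beta * x * expm1(v - u)
    Hx <- mu * expm1(-v) + beta * s * expm1(v - u) + gamma * expm1(u - v) +
      tk * (u - v) * ew
    Huu <- mu * eu + mu * s * emu + beta * s * x * evu + gamma * x * euv +
      tk * kappa * x^2 * ew
    Huv <- -beta * s * x * evu - gamma * x * euv - tk * kappa * x^2 * ew
    Hus <- -mu * emu - beta * x * evu
    Hux <- -beta * s * evu + gamma * euv + tk * ew * (1 + w)
    Hvv <- mu * x * emv + beta * s * x * evu + gamma * x * euv + tk * kappa * x^2 * ew
    Hvs <- beta * x * evu
    Hvx <- -mu * emv + beta * s * evu - gamma * euv - tk * ew * (1 + w)
    Hss <- numeric(n)
    Hsx <- beta * expm1(v - u)
    Hxx2 <- if (treat) nu * kappa^2 * (u - v)^2 * ew else numeric(n)
    F <- cbind(Hu, Hv, -Hs, -Hx)
    J <- array(0, dim = c(n, 4, 4))
    J[, 1, ] <- cbind(Hus, Hux, Huu, Huv)
    J[, 2, ] <- cbind(Hvs, Hvx, Huv, Hvv)
    J[, 3, ] <- -cbind(Hss, Hsx, Hus, Hvs)
    J[, 4, ] <- -cbind(Hsx, Hxx2, Hux, Hvx)
    list(F = F, J = J)
  }
}

as_phase_matrix <- function(model, state, momentum) {
  d <- wkb_dim(model)
  state <- matrix(state, ncol = d)
  momentum <- matrix(momentum, ncol = d)
  stopifnot(nrow(state) == nrow(momentum))
  cbind(state, momentum)
}

#' WKB Hamiltonian of the scaled jump process
#'
#' Evaluates `H(x, p) = sum_r w(x; r) (exp(p . r) - 1)` for the model's
#' channels in normalized variables.  The deterministic (mean-field) dynamics
#' live on the zero-momentum slice, where `H` vanishes identically; the
#' extinction path lies on the nontrivial `H = 0` manifold with negative
#' momentum.  The treatment channel contributes
#' `nu * (exp(-kappa * x * p) - 1)` (constrained model) or
#' `nu * (exp(kappa * x * (p_s - p_x)) - 1)` (full model): continuous in `x`,
#' so in the WKB frame pulses retain an effect at arbitrarily low prevalence,
#' in contrast to the rounded master equation.
#'
#' @param model An [sis_model()] object.
#' @param state Numeric state (fractions): `x`, or `c(s, x)`; may be a matrix
#'   with one row per evaluation point.
#' @param momentum Conjugate momenta, same shape as `state`.
#' @return Numeric vector of energies (1/year).
#' @examples
#' m <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 1000))
#' hamiltonian(m, 0.3, 0)  # zero on the deterministic slice
#' @export
hamiltonian <- function(model, state, momentum) {
  stopifnot(inherits(model, "sis_model"))
  as.numeric(wkb_H(model, as_phase_matrix(model, state, momentum)))
}

#' Characteristic (Hamiltonian) flow field
#'
#' Returns the right-hand side of the characteristic equations
#' `dstate/dt = dH/dp`, `dmomentum/dt = -dH/dstate`, from analytic
#' derivatives of the Hamiltonian.  On the zero-momentum slice the state
#' equation reduces to the mean-field ODE of the model, and the field
#' vanishes at every member of [fixed_points()].
#'
#' @inheritParams hamiltonian
#' @return A list with `state_dot` and `momentum_dot` (matrices with one row
#'   per evaluation point).
#' @export
characteristic_field <- function(model, state, momentum) {
  stopifnot(inherits(model, "sis_model"))
  d <- wkb_dim(model)
  f <- wkb_field(model, as_phase_matrix(model, state, momentum))
  list(state_dot = f$F[, seq_len(d), drop = FALSE],
       momentum_dot = f$F[, d + seq_len(d), drop = FALSE])
}
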