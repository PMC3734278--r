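# Shared fixtures: the canonical slowly-spreading disease (R0 = 2) at various
# population sizes, plus closed-form oracles for the untreated model.

par_canon <- function(N) epidemic_params(beta = 2, gamma = 0.8, mu = 0.2, N = N)

# untreated SIS closed forms (R0 = beta / (gamma + mu))
action_closed_form <- function(R0) log(R0) - 1 + 1 / R0
die_out_closed_form <- function(R0) -log(R0)
branch_closed_form <- function(x, R0) log(1 / (R0 * (1 - x)))

# hand-solved two-state chain (N = 2, beta = 2, gamma + mu = 1, kappa = 0):
# first-step equations tau1 = 1/2 + tau2/2, tau2 = 1/2 + tau1 give 1.5 and 2.
two_state_model <- function() {
  make_constrained_model(epidemic_params(beta = 2, gamma = 0.5, mu = 0.5, N = 2))
}

# independent bisection for the die-out momentum (oracle for fixed_points)
die_out_bisect <- function(beta, gm, kn, lo = -10, hi = -1e-12, tol = 1e-12) {
  g <- function(p) beta * expm1(p) + gm * expm1(-p) - kn * p
  stopifnot(g(lo) > 0, g(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
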