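test_that("parameter and policy constructors validate their domains", {
  expect_s3_class(epidemic_params(2, 0.8, 0.2, 100), "epidemic_params")
  expect_error(epidemic_params(-1, 0.8, 0.2, 100), "beta")
  expect_error(epidemic_params(2, 0.8, 0.2, 1), "N")
  expect_error(treatment_policy(1.5, 2), "kappa")
  expect_error(treatment_policy(0.5, -1), "nu")
  expect_error(treatment_policy(0.5, 2, schedule = "weekly"))
})

test_that("pulse rounding follows the integer-part / next-highest rules", {
  expect_identical(pulse_size(0.3, 3L), 0L)   # floor(0.9)
  expect_identical(pulse_size(0.3, 4L), 1L)   # floor(1.2)
  expect_identical(pulse_size(0.3, 10L), 3L)  # binary-representation guard
  expect_identical(pulse_size(0.3, 3L, "ceil"), 1L)
  expect_identical(pulse_size(1, 7L), 7L)
  expect_identical(pulse_size(0.2, 0L), 0L)
  # never removes more than are present
  expect_true(all(pulse_size(0.99, 1:50, "ceil") <= 1:50))
})

test_that("reproduction numbers match the mean-field threshold", {
  p <- epidemic_params(2, 0.5, 0.5, 100)
  expect_equal(reproduction_numbers(p)$R0, 2)
  rn <- reproduction_numbers(p, treatment_policy(0.125, 4))  # kappa nu = 0.5
  expect_equal(rn$RT, 2 / 1.5)
  # RT = 1 exactly when beta = gamma + mu + kappa nu: the endemic root of
  # beta x (1 - x) - (gamma + mu) x - kappa nu x crosses zero there
  pol_crit <- treatment_policy(0.25, 4)  # kappa nu = 1, beta = 2 = 1 + 1
  expect_equal(reproduction_numbers(p, pol_crit)$RT, 1)
  expect_error(mean_field_endemic(p, pol_crit), "RT")
  # threshold consistency: x* is the root of the mean-field balance
  pol <- treatment_policy(0.1, 4)
  xs <- mean_field_endemic(p, pol)[["x"]]
  expect_equal(p$beta * xs * (1 - xs) - (p$gamma + p$mu) * xs -
                 pol$kappa * pol$nu * xs, 0, tolerance = 1e-12)
  expect_equal(xs, 1 - 1.4 / 2)
  # untreated closed form x* = 1 - 1/R0
  expect_equal(mean_field_endemic(p)[["x"]], 0.5)
})

test_that("constrained model has the stated channels and propensities", {
  p <- epidemic_params(2, 0.5, 0.5, 2)
  m0 <- make_constrained_model(p)                       # no treatment channel
  expect_length(m0$channels, 2)
  m <- make_constrained_model(p, treatment_policy(0.3, 4))
  expect_length(m$channels, 3)
  # N = 2, beta = 2, gamma + mu = 1: up/down rates at I = 1 and I = 2
  pr1 <- propensities(m0, c(I = 1))
  expect_equal(unname(pr1[["infection"]]), 1.0)
  expect_equal(unname(pr1[["recovery_death"]]), 1.0)
  pr2 <- propensities(m0, c(I = 2))
  expect_equal(unname(pr2[["infection"]]), 0.0)
  expect_equal(unname(pr2[["recovery_death"]]), 2.0)
  # bulk channel: constant propensity, state-dependent increment
  p100 <- epidemic_params(2, 0.8, 0.2, 100)
  mt <- make_constrained_model(p100, treatment_policy(0.3, 4))
  ch <- mt$channels[[3]]
  expect_true(ch$is_bulk)
  expect_equal(ch$rate(c(I = 3)), 4)
  expect_identical(ch$increment(c(I = 3)), c(I = 0L))   # floor(0.9) no-op
  expect_identical(ch$increment(c(I = 4)), c(I = -1L))
})

test_that("full model propensities and treatment conservation", {
  p <- epidemic_params(2, 0.8, 0.2, 1000)
  m <- make_full_model(p, treatment_policy(1, 2))
  pr <- propensities(m, c(S = 500, I = 100))
  expect_equal(unname(pr[["infection"]]), 2 * 500 * 100 / 1000)
  expect_equal(unname(pr[["birth"]]), 0.2 * 1000)
  expect_equal(unname(pr[["recovery"]]), 80)
  # extinct state: only S-compartment demography remains active
  pr0 <- propensities(m, c(S = 1000, I = 0))
  expect_equal(unname(pr0[["infection"]]), 0)
  expect_equal(unname(pr0[["death_I"]]), 0)
  # kappa = 1 pulse moves every infected to S: S + I conserved
  inc <- m$channels[[6]]$increment(c(S = 500, I = 100))
  expect_equal(sum(inc), 0)
  expect_equal(unname(inc[["I"]]), -100)
})

test_that("propensities are non-negative across the admissible state space", {
  p <- epidemic_params(3, 0.6, 0.4, 50)
  withr::with_seed(421, {
    mc <- make_constrained_model(p, treatment_policy(0.4, 3))
    for (I in sample(0:50, 20)) {
      expect_true(all(propensities(mc, c(I = I)) >= 0))
    }
    mf <- make_full_model(p, treatment_policy(0.4, 3))
    for (k in 1:20) {
      st <- c(S = sample(0:120, 1), I = sample(0:80, 1))
      expect_true(all(propensities(mf, st) >= 0))
    }
  })
  # boundary: constrained propensities vanish at I = 0, infection at I = N
  mc <- make_constrained_model(p)
  expect_true(all(propensities(mc, c(I = 0)) == 0))
  expect_equal(unname(propensities(mc, c(I = 50))[["infection"]]), 0)
})

test_that("endemic state is a fixed point of the characteristic flow", {
  p <- epidemic_params(2, 0.8, 0.2, 500)
  for (pol in list(treatment_policy(), treatment_policy(0.1, 4))) {
    for (kind in c("constrained", "full")) {
      m <- sis_model(p, pol, kind)
      ep <- mean_field_endemic(p, pol, kind)
      f <- characteristic_field(m, ep, 0 * ep)
      expect_lt(max(abs(unlist(f))), 1e-10)
    }
  }
})
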