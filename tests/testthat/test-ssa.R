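test_that("fixed seeds reproduce trajectories and ensembles bit-for-bit", {
  m <- make_constrained_model(par_canon(40), treatment_policy(0.2, 4))
  a <- simulate_to_extinction(m, seed = 7)
  b <- simulate_to_extinction(m, seed = 7)
  expect_identical(a$states, b$states)
  expect_identical(a$time, b$time)
  e1 <- extinction_ensemble(m, n = 100, seed = 5)
  e2 <- extinction_ensemble(m, n = 100, seed = 5)
  expect_identical(e1$times, e2$times)
  expect_false(identical(a$time, simulate_to_extinction(m, seed = 8)$time))
})

test_that("pure single-death process has unit mean extinction time", {
  # beta ~ 0, gamma + mu = 1, I0 = 1: extinction time ~ Exponential(1)
  m <- make_constrained_model(epidemic_params(1e-12, 0.5, 0.5, 10))
  e <- extinction_ensemble(m, n = 4000, seed = 2, init = c(I = 1))
  expect_equal(e$n_censored, 0)
  expect_lt(abs(e$mean - 1), 3 * e$se)
  expect_lt(abs(e$sd - 1), 0.08)  # exponential: sd = mean = 1
})

test_that("full-kappa pulses end the epidemic by the first pulse", {
  p <- par_canon(50)
  m <- make_constrained_model(p, treatment_policy(1, 2))
  e <- extinction_ensemble(m, n = 1000, seed = 3, init = c(I = 20))
  # first pulse ~ Exponential(nu); demographic extinctions only shorten it
  expect_lte(e$mean, 1 / 2 + 3 * e$se)
  tr <- simulate_to_extinction(m, init = c(I = 20), seed = 1)
  expect_true(tr$extinct)
  expect_lte(tr$time, tr$pulse_times[1] + 1e-12)
})

test_that("periodic pulses fire exactly at k/nu; Poisson gaps are exponential", {
  p <- par_canon(50)
  mper <- make_constrained_model(p, treatment_policy(0.2, 3, "periodic"))
  tr <- simulate_to_extinction(mper, seed = 11, t_max = 200)
  expect_gt(length(tr$pulse_times), 10)
  expect_equal(tr$pulse_times, seq_along(tr$pulse_times) / 3, tolerance = 1e-12)

  # Poisson schedule: inter-pulse gaps ~ Exponential(nu), KS test at alpha 0.01
  mpo <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 400),
                                treatment_policy(0.01, 5))
  tr2 <- simulate_to_extinction(mpo, seed = 13, t_max = 2100, record = FALSE,
                                max_events = 5e7)
  gaps <- diff(c(0, tr2$pulse_times))
  expect_gt(length(gaps), 9000)
  expect_gt(stats::ks.test(gaps, "pexp", 5)$p.value, 0.01)
})

test_that("ensemble mean matches the exact two-state MFPT within 3 SE", {
  m <- two_state_model()
  e <- extinction_ensemble(m, n = 10000, seed = 17, init = c(I = 2))
  expect_lt(abs(e$mean - 2.0), 3 * e$se)
  e1 <- extinction_ensemble(m, n = 10000, seed = 19, init = c(I = 1))
  expect_lt(abs(e1$mean - 1.5), 3 * e1$se)
})

test_that("treatment pulses never drive counts negative and conserve S + I", {
  m <- make_full_model(par_canon(60), treatment_policy(0.7, 6, rounding = "ceil"))
  tr <- simulate_to_extinction(m, init = c(S = 30, I = 30), seed = 23,
                               t_max = 500)
  expect_true(all(tr$states$S >= 0))
  expect_true(all(tr$states$I >= 0))
  # S + I changes only at demographic events: at pulse times it is conserved
  st <- tr$states
  tot <- st$S + st$I
  pulse_rows <- match(round(tr$pulse_times, 10), round(st$t, 10))
  pulse_rows <- pulse_rows[!is.na(pulse_rows)]
  expect_gt(length(pulse_rows), 0)
  expect_identical(tot[pulse_rows], tot[pulse_rows - 1])
  if (tr$extinct) expect_identical(st$I[nrow(st)], 0L)
})

test_that("extinction-time distribution is approximately exponential when rare", {
  # quasi-stationary fixture: N chosen so that N * s ~ 8
  p <- par_canon(50)
  pol <- treatment_policy(0.05, 4)
  m <- make_constrained_model(p, pol)
  e <- extinction_ensemble(m, n = 2000, seed = 29, t_max = 1e5)
  expect_equal(e$n_censored, 0)
  expect_gt(e$sd / e$mean, 0.9)
  expect_lt(e$sd / e$mean, 1.1)
})

test_that("prehistory density is a normalized trailing-window occupancy", {
  p <- epidemic_params(2, 0.8, 0.2, 500)
  pol <- treatment_policy(0.35, 2)
  m <- make_full_model(p, pol)
  trs <- lapply(1:30, function(i) simulate_to_extinction(m, seed = 100 + i))
  trs <- Filter(function(x) x$extinct, trs)
  expect_gt(length(trs), 10)
  ph <- prehistory_density(trs, window = 5)
  expect_equal(sum(ph$density), 1, tolerance = 1e-12)
  expect_true(all(ph$density >= 0))
  # default window is five years
  expect_equal(formals(prehistory_density)$window, 5)
  # fast C++ accumulator agrees on normalization and concentrates mass at
  # low infected fraction (absorbing approach)
  ph2 <- extinction_prehistory(m, n_extinct = 200, seed = 31)
  expect_equal(sum(ph2$density), 1, tolerance = 1e-12)
  x_mass <- colSums(ph2$density)
  expect_gt(sum(x_mass[1:10]), 0.5)
})
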