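test_that("generator has the stated structure and rates", {
  # untreated: tridiagonal birth-death chain with absorbing row 0
  gen <- build_generator(two_state_model())
  Q <- as.matrix(gen$Q)
  expect_equal(Q[1, ], c(0, 0, 0))                  # absorbing
  expect_equal(Q[2, 3], 1)                          # 1 -> 2 at rate 1
  expect_equal(Q[2, 1], 1)                          # 1 -> 0 at rate 1
  expect_equal(Q[3, 2], 2)                          # 2 -> 1 at rate 2
  expect_equal(max(abs(Matrix::rowSums(gen$Q))), 0)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))

  # treatment edge: kappa = 0.5 floor, I = 3 jumps to 3 - floor(1.5) = 2
  m <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 10),
                              treatment_policy(0.5, 7))
  Qt <- as.matrix(build_generator(m)$Q)
  expect_equal(Qt[4, 3], (0.8 + 0.2) * 3 + 7)       # down-step + pulse collide
  expect_equal(Qt[5, 3], 7)                          # I = 4 -> 2
  expect_equal(Qt[2, 1], 1)                          # I = 1: pulse inert, death only

  # periodic schedules have no Markov generator
  mper <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 10),
                                 treatment_policy(0.5, 7, "periodic"))
  expect_error(build_generator(mper), "Poisson")

  # full model refused beyond the state-space cap
  big <- make_full_model(par_canon(1000))
  expect_error(build_generator(big), "states")
})

test_that("MFPT solve reproduces the hand-solved two-state chain", {
  gen <- build_generator(two_state_model())
  tau <- mean_extinction_time_direct(gen)
  expect_equal(tau, c(0, 1.5, 2.0), tolerance = 1e-12)
  expect_equal(mean_extinction_time_direct(gen, start = c(I = 2)), 2,
               tolerance = 1e-12)
  # distribution start: expectation under the start distribution
  expect_equal(mean_extinction_time_direct(gen, start = c(0, 0.5, 0.5)), 1.75,
               tolerance = 1e-12)
})

test_that("any effective treatment strictly shortens the MFPT", {
  p <- par_canon(80)
  tau0 <- mean_extinction_time_direct(build_generator(make_constrained_model(p)),
                                      start = c(I = 40))
  taut <- mean_extinction_time_direct(
    build_generator(make_constrained_model(p, treatment_policy(0.1, 2))),
    start = c(I = 40))
  expect_lt(taut, tau0)
})

test_that("MFPT is monotone non-increasing in kappa and nu (exact solver)", {
  p <- par_canon(100)
  kappas <- seq(0.05, 0.25, by = 0.05)
  nus <- 1:5
  tau <- outer(kappas, nus, Vectorize(function(k, v) {
    m <- make_constrained_model(p, treatment_policy(k, v))
    mean_extinction_time_direct(build_generator(m), start = c(I = 30))
  }))
  expect_true(all(diff(tau) < 0))        # along kappa
  expect_true(all(t(diff(t(tau))) < 0))  # along nu
})

test_that("QSD decay rate agrees with the MFPT from the QSD start", {
  m <- make_constrained_model(par_canon(60))   # N s ~ 11: rare event
  gen <- build_generator(m)
  q <- quasi_stationary_distribution(gen)
  expect_true(all(q$pi >= 0))
  expect_equal(sum(q$pi), 1, tolerance = 1e-10)
  tau_qsd <- mean_extinction_time_direct(gen, start = q$pi)
  expect_lt(abs(q$mte / tau_qsd - 1), 0.01)
  # decay route remains usable where the direct solve has lost accuracy
  m2 <- make_constrained_model(par_canon(300), treatment_policy(0.05, 4))
  q2 <- quasi_stationary_distribution(build_generator(m2))
  expect_equal(q2$log_mte, 35.6147409, tolerance = 1e-4)  # 60-digit direct solve
})

test_that("QSD mode sits at the endemic state for large N", {
  m <- make_constrained_model(par_canon(500), treatment_policy(0.02, 2))
  q <- quasi_stationary_distribution(build_generator(m))
  mode_I <- which.max(q$pi) - 1
  xs <- mean_field_endemic(m$params, m$policy)[["x"]]
  expect_lte(abs(mode_I - 500 * xs), 2)
})

test_that("distribution evolution conserves mass and decays at rate 1/MTE", {
  m <- make_constrained_model(par_canon(60))
  gen <- build_generator(m)
  q <- quasi_stationary_distribution(gen)
  # t = 0 returns the initial distribution
  expect_equal(evolve_distribution(gen, q$pi, 0), q$pi, tolerance = 1e-12)
  # absorbed mass after t = 0.01 MTE matches the exponential-decay law
  t1 <- 0.01 * q$mte
  pt <- evolve_distribution(gen, q$pi, t1)
  expect_equal(sum(pt), 1, tolerance = 1e-8)
  absorbed <- pt[1]
  expect_lt(absorbed / (1 - exp(-t1 / q$mte)), 1.05)
  expect_gt(absorbed / (1 - exp(-t1 / q$mte)), 0.95)
})

test_that("without quasi-stationarity the mass drains visibly within years", {
  # RT barely above 1: extinction is not a rare event
  p <- epidemic_params(1.15, 0.8, 0.2, 60)
  gen <- build_generator(make_constrained_model(p))
  I0 <- endemic_state(make_constrained_model(p))[["I"]]
  p0 <- numeric(61); p0[I0 + 1] <- 1
  out <- evolve_distribution(gen, p0, c(2, 10))
  expect_gt(out[2, 1], out[1, 1])   # absorbed mass grows
  expect_gt(out[2, 1], 0.2)         # and is substantial after a few years
})
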