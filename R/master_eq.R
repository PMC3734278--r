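#' Build the master-equation generator
#'
#' Assembles the (sparse) transition-rate matrix of the Markov jump process,
#' rows indexing source states.  States with `I = 0` are absorbing (their rows
#' are identically zero).  The bulk treatment channel contributes rate `nu`
#' from `I` to `I - pulse_size(kappa, I)` whenever the pulse removes at least
#' one infected; pulses that round to zero contribute nothing, which is where
#' the floor rule's small-`kappa` threshold effect enters.  Only the Poisson
#' schedule is representable (a periodic schedule is not Markovian; it is
#' handled by simulation only).
#'
#' For the full model the state space `(S, I)` with `S + I <= cap_mult * N`
#' grows quadratically; generators beyond `max_states` states are refused.
#' This small-`N` two-dimensional build exists as an exact cross-check for the
#' simulation and WKB routes.
#'
#' @param model An [sis_model()] object with a `"poisson"` schedule.
#' @param cap_mult Full model only: population cap as a multiple of `N`.
#' @param max_states Refuse to build more states than this (default `2e5`).
#' @return An object of class `sis_generator`: list with the sparse matrix
#'   `Q`, a data frame `states`, a logical `absorbing` marker and the model.
#' @examples
#' m <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 10),
#'                             treatment_policy(0.5, 1))
#' gen <- build_generator(m)
#' Matrix::rowSums(gen$Q)  # all zero
#' @export
build_generator <- function(model, cap_mult = 4, max_states = 2e5) {
  stopifnot(inherits(model, "sis_model"))
  if (model$policy$schedule != "poisson" && model$policy$kappa * model$policy$nu > 0)
    stop("only the Poisson schedule has a Markov generator")
  p <- model$params; pol <- model$policy
  beta <- p$beta; gm <- p$gamma + p$mu; mu <- p$mu; gamma <- p$gamma
  N <- p$N; kappa <- pol$kappa; nu <- pol$nu
  treat <- kappa * nu > 0

  if (model$kind == "constrained") {
    states <- data.frame(I = 0:N)
    n <- N + 1L
    I <- 1:N
    row <- I + 1L  # state I sits at index I + 1
    ii <- jj <- vv <- list()
    up <- beta * I * (N - I) / N
    sel <- I < N
    ii$up <- row[sel]; jj$up <- row[sel] + 1L; vv$up <- up[sel]
    dn <- gm * I
    ii$dn <- row; jj$dn <- row - 1L; vv$dn <- dn
    out <- up + dn
    if (treat) {
      k <- pulse_size(kappa, I, pol$rounding)
      selk <- k >= 1L
      ii$tr <- row[selk]; jj$tr <- row[selk] - k[selk]; vv$tr <- rep(nu, sum(selk))
      out <- out + ifelse(selk, nu, 0)
    }
    Q <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                              dims = c(n, n))
    Q <- Q - Matrix::Diagonal(n, c(0, out))
    absorbing <- c(TRUE, rep(FALSE, N))
  } else {
    M <- as.integer(round(cap_mult * N))
    grid <- expand.grid(S = 0:M, I = 0:M)
    grid <- grid[grid$S + grid$I <= M, ]
    if (nrow(grid) > max_states)
      stop(sprintf("full generator would need %d states (max_states = %g)",
                   nrow(grid), max_states))
    states <- grid[order(grid$I, grid$S), ]
    rownames(states) <- NULL
    key <- function(S, I) S + 1L + I * (M + 1L)
    pos <- integer((M + 1L)^2)
    pos[key(states$S, states$I)] <- seq_len(nrow(states))
    S <- states$S; I <- states$I
    live <- I >= 1L
    ii <- jj <- vv <- list(); kk <- 1L
    add <- function(dS, dI, rate) {
      to_S <- S + dS; to_I <- I + dI
      ok <- live & rate > 0 & to_S >= 0L & to_I >= 0L & (to_S + to_I) <= M
      ii[[kk]] <<- pos[key(S, I)][ok]
      jj[[kk]] <<- pos[key(to_S[ok], to_I[ok])]
      vv[[kk]] <<- rate[ok]
      kk <<- kk + 1L
    }
    birth <- ifelse(S + I >= M, 0, mu * N)  # births suspended at the cap
    add(1L, 0L, birth)
    add(-1L, 0L, mu * S)
    add(0L, -1L, mu * I)
    add(rep(-1L, length(S)), rep(1L, length(S)), beta * S * I / N)
    add(1L, -1L, gamma * I)
    out <- ifelse(live, birth + mu * S + mu * I + beta * S * I / N + gamma * I, 0)
    if (treat) {
      k <- pulse_size(kappa, I, pol$rounding)
      add(k, -k, ifelse(k >= 1L, nu, 0))
      out <- out + ifelse(live & k >= 1L, nu, 0)
    }
    n <- nrow(states)
    Q <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                              dims = c(n, n))
    Q <- Q - Matrix::Diagonal(n, out)
    absorbing <- I == 0L
  }
  structure(list(Q = Q, states = states, absorbing = absorbing, model = model),
            class = "sis_generator")
}

#' @export
print.sis_generator <- function(x, ...) {
  cat(sprintf("Master-equation generator (%s model): %d states (%d absorbing), %d transitions\n",
              x$model$kind, nrow(x$states), sum(x$absorbing),
              Matrix::nnzero(x$Q) - sum(Matrix::diag(x$Q) != 0)))
  invisible(x)
}

state_index <- function(gen, state) {
  st <- gen$states
  if (gen$model$kind == "constrained") {
    i <- match(as.integer(state[["I"]]), st$I)
  } else {
    i <- which(st$S == as.integer(state[["S"]]) & st$I == as.integer(state[["I"]]))
  }
  if (length(i) != 1 || is.na(i)) stop("state not in the generator's state space")
  i
}

#' Mean time to extinction by direct linear solve
#'
#' Solves the first-passage system `Q_T tau = -1` over the transient states
#' (`Q_T` the generator restricted to `I >= 1`); absorbing states have
#' `tau = 0`.  This is exact up to floating point, but the solve loses
#' accuracy once the answer exceeds roughly `1e13` years (the transient
#' block's smallest pivot then falls below double-precision resolution); a
#' warning is issued in that regime and [quasi_stationary_distribution()]'s
#' decay-rate route should be used instead.
#'
#' @param gen A [build_generator()] result.
#' @param start Optional: a named state vector, or a probability vector over
#'   all states (length `nrow(gen$states)`), to return the expected absorption
#'   time from that start.  Default returns the full vector.
#' @return Numeric: the MFPT vector over all states (in the order of
#'   `gen$states`), or its value/expectation at `start`.
#' @examples
#' m <- make_constrained_model(epidemic_params(2, 0.5, 0.5, 2))
#' gen <- build_generator(m)
#' mean_extinction_time_direct(gen)  # 0, 1.5, 2 years for I = 0, 1, 2
#' @export
mean_extinction_time_direct <- function(gen, start = NULL) {
  stopifnot(inherits(gen, "sis_generator"))
  tr <- !gen$absorbing
  QT <- gen$Q[tr, tr, drop = FALSE]
  tau_t <- tryCatch(
    as.numeric(Matrix::solve(QT, rep(-1, sum(tr)))),
    error = function(e) stop("singular first-passage system: ", conditionMessage(e)))
  if (any(!is.finite(tau_t)) || any(tau_t <= 0))
    stop("first-passage solve failed (non-finite or non-positive times); ",
         "the extinction time likely exceeds the direct solve's accuracy domain")
  if (max(tau_t) > 1e13)
    warning("MFPT exceeds ~1e13 years; direct solve may be inaccurate, ",
            "use quasi_stationary_distribution()'s decay rate instead")
  tau <- numeric(nrow(gen$states))
  tau[tr] <- tau_t
  if (is.null(start)) return(tau)
  if (!is.null(names(start)) && all(names(start) %in% c("S", "I")))
    return(tau[state_index(gen, start)])
  stopifnot(length(start) == length(tau), all(start >= 0))
  sum(start * tau) / sum(start)
}

#' Quasi-stationary distribution and extinction decay rate
#'
#' Computes the left Perron eigenvector of the transient-restricted generator
#' (the quasi-stationary distribution, QSD) together with its decay rate
#' `lambda1`; when extinction is a rare event, `1/lambda1` is the mean time to
#' extinction from the QSD.
#'
#' The eigenproblem is solved by uniformized power iteration: with
#' `P = I + t(Q_T)/Lambda` (`Lambda` slightly above the largest exit rate) the
#' iteration `v <- P v`, renormalized each step, involves only additions and
#' multiplications of non-negative quantities, so the far tail of the QSD is
#' obtained with full relative accuracy even when it is smaller than
#' `1e-300`.  The decay rate is then read off as the absorption flux
#' `lambda1 = sum(v * r_abs)` with `r_abs` the per-state rate into `I = 0`,
#' again without cancellation.  This is what makes mean extinction times far
#' beyond the reach of the direct linear solve computable.
#'
#' @param gen A [build_generator()] result.
#' @param tol Relative convergence tolerance on `lambda1`.
#' @param max_iter Iteration cap.
#' @return A list of class `sis_qsd`: `pi` (QSD over all states, mass on
#'   transient states summing to 1), `lambda1` (1/year), `mte = 1/lambda1`
#'   (years), `log_mte`, `iterations`, `converged`.
#' @examples
#' m <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 60))
#' q <- quasi_stationary_distribution(build_generator(m))
#' q$log_mte
#' @export
quasi_stationary_distribution <- function(gen, tol = 1e-12, max_iter = 1e6) {
  stopifnot(inherits(gen, "sis_generator"))
  rn <- reproduction_numbers(gen$model$params, gen$model$policy)
  if (rn$RT <= 1)
    warning(sprintf("RT = %.3g <= 1: no quasi-stationary regime, the 'QSD' is transient structure", rn$RT))
  tr <- !gen$absorbing
  QT <- gen$Q[tr, tr, drop = FALSE]
  nT <- nrow(QT)
  # per-state absorption rates (flux to I = 0 states)
  r_abs <- as.numeric(Matrix::rowSums(gen$Q[tr, gen$absorbing, drop = FALSE]))
  Lambda <- max(-Matrix::diag(QT)) * 1.05
  Pt <- Matrix::t(QT) / Lambda
  # start at the endemic state when available, else uniform
  v <- rep(1 / nT, nT)
  ep <- tryCatch(endemic_state(gen$model), error = function(e) NULL)
  if (!is.null(ep)) {
    i0 <- tryCatch(state_index(gen, ep), error = function(e) NULL)
    ti <- if (is.null(i0)) NA_integer_ else match(i0, which(tr))
    if (!is.na(ti)) { v <- numeric(nT); v[ti] <- 1 }
  }
  lam_old <- NA_real_
  converged <- FALSE
  it <- 0L
  check_every <- 100L
  while (it < max_iter) {
    for (k in seq_len(check_every)) v <- v + as.numeric(Pt %*% v)
    v <- v / sum(v)
    it <- it + check_every
    lam <- sum(r_abs * v)
    if (is.finite(lam_old) && abs(lam - lam_old) <= tol * lam) {
      converged <- TRUE
      break
    }
    lam_old <- lam
  }
  if (!converged)
    warning("QSD power iteration did not meet tolerance; result may be biased")
  pi_full <- numeric(nrow(gen$states))
  pi_full[tr] <- v
  structure(list(pi = pi_full, lambda1 = lam, mte = 1 / lam,
                 log_mte = -log(lam), iterations = it, converged = converged),
            class = "sis_qsd")
}

#' @export
print.sis_qsd <- function(x, ...) {
  cat(sprintf("Quasi-stationary distribution: lambda1 = %.6g /yr, MTE = exp(%.4f) yr (%d iterations)\n",
              x$lambda1, x$log_mte, x$iterations))
  invisible(x)
}

#' Evolve a lattice distribution under the master equation
#'
#' Integrates `dp/dt = t(Q) p` with a stiff solver, conserving total mass
#' (including the absorbing states).
#'
#' @param gen A [build_generator()] result.
#' @param p0 Probability vector over all states of `gen` (sums to 1).
#' @param t Time (years), or a vector of output times.
#' @param rtol,atol Solver tolerances.
#' @return If `t` is scalar, the probability vector at `t`; otherwise a matrix
#'   with one row per output time.
#' @export
evolve_distribution <- function(gen, p0, t, rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(gen, "sis_generator"), length(p0) == nrow(gen$states),
            all(p0 >= 0), abs(sum(p0) - 1) < 1e-8, all(t >= 0))
  Qt <- Matrix::t(gen$Q)
  if (all(t == 0)) {
    out <- matrix(p0, nrow = length(t), ncol = length(p0), byrow = TRUE)
    return(if (length(t) == 1) p0 else out)
  }
  times <- sort(unique(c(0, t)))
  sol <- deSolve::lsoda(y = p0, times = times,
                        func = function(tt, y, parms)
                          list(as.numeric(Qt %*% y)),
                        rtol = rtol, atol = atol)
  out <- sol[match(t, sol[, 1]), -1, drop = FALSE]
  drift <- abs(rowSums(out) - 1)
  if (any(drift > 1e-8))
    warning(sprintf("probability mass drift %.2g exceeds 1e-8", max(drift)))
  if (length(t) == 1) as.numeric(out) else unname(as.matrix(out))
}
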