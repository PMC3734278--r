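# Fixed points of the characteristic flow and the optimal path to extinction
# (the heteroclinic H = 0 trajectory from the endemic state to the
# fluctuational die-out point), solved by a generalized Newton iteration on
# the time-discretized characteristic equations.

# Momentum of the fluctuational die-out state: the x -> 0 limit of the
# nontrivial zero-energy branch,
#   beta (e^p - 1) + (gamma+mu) (e^-p - 1) - nu kappa p = 0,  p < 0.
# The function is strictly convex with a root at 0; the negative root exists
# iff RT > 1 and is unique, and reduces to -log(R0) without treatment.
die_out_momentum <- function(params, policy) {
  beta <- params$beta; gm <- params$gamma + params$mu
  kn <- policy$kappa * policy$nu
  if (beta <= gm + kn)
    stop("no die-out momentum: RT <= 1")
  g <- function(p) beta * expm1(p) + gm * expm1(-p) - kn * p
  pf0 <- -log(beta / gm)  # untreated closed form, also the scan anchor
  lo <- pf0 - 1
  while (g(lo) < 0) lo <- lo - 1  # ensure bracket (g -> +Inf as p -> -Inf)
  stats::uniroot(g, c(lo, -1e-14), tol = 1e-15)$root
}

#' Fixed points of the Hamiltonian system
#'
#' Three steady states organize the extinction problem: the disease-free
#' equilibrium (zero state, zero momentum), the endemic state (positive
#' state, zero momentum; absent when `RT <= 1`), and the fluctuational
#' die-out state with zero infected fraction but nonzero momentum `p_f`,
#' defined implicitly by the `x -> 0` limit of the nontrivial zero-energy
#' branch (`die_out_momentum()` in the package source).  Without treatment,
#' `p_f = -log(R0)`.  All members satisfy `H = 0` and are equilibria of
#' [characteristic_field()].
#'
#' @param model An [sis_model()] object.
#' @return A list of class `fixed_point_set` with members `disease_free`,
#'   `endemic` (or `NULL` when `RT <= 1`) and `die_out`, each a list with
#'   `state` and `momentum`.
#' @examples
#' m <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 1000))
#' fixed_points(m)$die_out$momentum  # -log(2)
#' @export
fixed_points <- function(model) {
  stopifnot(inherits(model, "sis_model"))
  p <- model$params; pol <- model$policy
  rn <- reproduction_numbers(p, pol)
  d <- wkb_dim(model)
  zero <- if (d == 1) c(x = 0) else c(s = 1, x = 0)
  zmom <- if (d == 1) c(p = 0) else c(ps = 0, px = 0)
  endemic <- NULL
  if (rn$RT > 1) {
    ep <- mean_field_endemic(p, pol, if (d == 1) "constrained" else "full")
    endemic <- list(state = ep, momentum = zmom)
  }
  die_out <- NULL
  if (rn$RT > 1) {
    pf <- die_out_momentum(p, pol)
    die_out <- list(state = zero,
                    momentum = if (d == 1) c(p = pf) else c(ps = 0, px = pf))
  }
  structure(list(disease_free = list(state = zero, momentum = zmom),
                 endemic = endemic, die_out = die_out),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  show <- function(nm, fp) {
    if (is.null(fp)) cat(sprintf("  %-12s absent\n", nm))
    else cat(sprintf("  %-12s state (%s)  momentum (%s)\n", nm,
                     paste(signif(fp$state, 6), collapse = ", "),
                     paste(signif(fp$momentum, 6), collapse = ", ")))
  }
  cat("Fixed points of the characteristic flow\n")
  show("disease-free", x$disease_free)
  show("endemic", x$endemic)
  show("die-out", x$die_out)
  invisible(x)
}

# slowest contraction/expansion rate of the linearized field at a phase point
slowest_rate <- function(model, z) {
  f <- wkb_field(model, matrix(z, nrow = 1))
  ev <- eigen(f$J[1, , ], only.values = TRUE)$values
  re <- abs(Re(ev))
  re <- re[re > 1e-8]
  if (length(re) == 0) return(NA_real_)
  min(re)
}

# Zero-energy branch momentum of the constrained model at infected fraction x
# (root of H(x, .) in p < 0); vectorized helper for guesses and quadrature.
branch_momentum <- function(params, policy, x) {
  beta <- params$beta; gm <- params$gamma + params$mu
  kappa <- policy$kappa; nu <- policy$nu
  treat <- kappa * nu > 0
  vapply(x, function(xx) {
    if (xx <= 0) return(die_out_momentum(params, policy))
    H <- function(p) beta * xx * (1 - xx) * expm1(p) + gm * xx * expm1(-p) +
      (if (treat) nu * expm1(-kappa * xx * p) else 0)
    lo <- -12
    hi <- -1e-14
    if (H(hi) * H(lo) > 0) return(0)  # at/beyond the endemic point
    stats::uniroot(H, c(lo, hi), tol = 1e-15)$root
  }, numeric(1))
}

simpson_weights <- function(n, h) {
  stopifnot(n >= 3, n %% 2 == 1)
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  w * h / 3
}

#' Optimal path to extinction
#'
#' Solves the heteroclinic boundary-value problem connecting the endemic
#' state (as `t -> -Inf`) to the fluctuational die-out state (as
#' `t -> +Inf`) on the `H = 0` energy surface.  Time is truncated to
#' `[-t_half, t_half]`, the characteristic equations are discretized with
#' second-order central differences on `n_nodes` points with the boundary
#' nodes pinned to the fixed points, and the full stacked nonlinear system is
#' solved by a damped (backtracking) Newton iteration with an analytic sparse
#' Jacobian.
#'
#' The default `t_half` makes the linearized endpoint decay
#' `exp(-lambda * t_half) < 1e-8` for the slowest eigenvalue `lambda` at
#' either endpoint.  The initial guess interpolates the boundary states with
#' a logistic profile; for the constrained model the momentum guess is the
#' same profile, while for the full model the guess embeds the constrained
#' zero-energy branch (`s = 1 - x`, `p_s = 0`, `p_x` from the branch), which
#' is what makes Newton converge from scratch in four dimensions.  If Newton
#' stalls at a treatment strength, the solver falls back to continuation in
#' `kappa` from the untreated problem.
#'
#' @param model An [sis_model()] with `RT > 1`.
#' @param n_nodes Odd number of mesh nodes (default 1601).
#' @param t_half Half-width of the truncated time interval (years); default
#'   chosen from the endpoint eigenvalues as above.
#' @param tol Convergence tolerance on the maximum discretized-equation
#'   residual.
#' @param h_tol Energy tolerance: after convergence the mesh is doubled (up
#'   to `n_max` nodes) until `max |H|` along the path falls below this.
#' @param n_max Node cap for the energy-driven refinement.
#' @param max_iter Newton iteration cap.
#' @param quiet Suppress the continuation notes.
#' @return An object of class `optimal_path`: `t`, `state` (matrix), `momentum`
#'   (matrix), `action` (per-capita, from the Simpson-integrated
#'   `sum_i p_i dx_i/dt`), `max_H`, `residual`, `iterations`, `converged`.
#' @examples
#' \donttest{
#' m <- make_constrained_model(epidemic_params(2, 0.8, 0.2, 1000))
#' pa <- optimal_path(m)
#' pa$action  # log(2) - 1 + 1/2 for R0 = 2
#' }
#' @export
optimal_path <- function(model, n_nodes = 1601, t_half = NULL, tol = 1e-10,
                         h_tol = 1e-6, n_max = 6401, max_iter = 60,
                         quiet = TRUE) {
  stopifnot(inherits(model, "sis_model"))
  fp <- fixed_points(model)
  if (is.null(fp$endemic)) stop("optimal path requires RT > 1")
  if (n_nodes %% 2 == 0) n_nodes <- n_nodes + 1
  d <- wkb_dim(model)
  z_a <- c(fp$endemic$state, fp$endemic$momentum)
  z_b <- c(fp$die_out$state, fp$die_out$momentum)
  t_half_fixed <- !is.null(t_half)
  if (!t_half_fixed) {
    lam <- min(slowest_rate(model, z_a), slowest_rate(model, z_b), na.rm = TRUE)
    t_half <- min(max(log(1e8) / lam, 5), 200)
  }

  sol <- newton_path(model, z_a, z_b, t_half, n_nodes, tol, max_iter)
  if (!sol$converged && !t_half_fixed) {
    # the Newton basin can be sensitive to the truncation length; retry on a
    # ladder of shorter/longer intervals before resorting to continuation
    for (fac in c(0.6, 0.4, 1.5)) {
      if (!quiet) message(sprintf("Newton stalled; retrying with t_half = %.3g", fac * t_half))
      sol <- newton_path(model, z_a, z_b, fac * t_half, n_nodes, tol, max_iter)
      if (sol$converged) { t_half <- fac * t_half; break }
    }
  }
  if (!sol$converged && model$policy$kappa > 0) {
    # continuation in kappa from the untreated problem
    if (!quiet) message("Newton stalled; continuation in kappa")
    kappas <- model$policy$kappa * c(0.25, 0.5, 0.75, 1)
    Zg <- NULL
    for (kk in kappas) {
      pol_k <- treatment_policy(kk, model$policy$nu, model$policy$schedule,
                                model$policy$rounding)
      mk <- sis_model(model$params, pol_k, model$kind)
      fpk <- fixed_points(mk)
      za_k <- c(fpk$endemic$state, fpk$endemic$momentum)
      zb_k <- c(fpk$die_out$state, fpk$die_out$momentum)
      sol <- newton_path(mk, za_k, zb_k, t_half, n_nodes, tol, max_iter,
                         Z_init = Zg)
      if (!sol$converged) break
      Zg <- sol$Z
      # re-pin ends for the next kappa happens inside newton_path
    }
  }
  if (!sol$converged)
    stop(sprintf("optimal path did not converge: residual %.3g after %d iterations",
                 sol$residual, sol$iterations))

  # energy-driven refinement: halve the mesh spacing until |H| is small
  while (max(abs(wkb_H(model, sol$Z))) > h_tol && n_nodes < n_max) {
    n_new <- 2 * (n_nodes - 1) + 1
    tt_old <- seq(-t_half, t_half, length.out = n_nodes)
    tt_new <- seq(-t_half, t_half, length.out = n_new)
    Zg <- apply(sol$Z, 2, function(col) stats::spline(tt_old, col, xout = tt_new)$y)
    sol2 <- newton_path(model, z_a, z_b, t_half, n_new, tol, max_iter, Z_init = Zg)
    if (!sol2$converged) break
    sol <- sol2
    n_nodes <- n_new
  }

  Z <- sol$Z
  f <- wkb_field(model, Z)
  h <- 2 * t_half / (n_nodes - 1)
  w <- simpson_weights(n_nodes, h)
  integrand <- rowSums(Z[, d + seq_len(d), drop = FALSE] *
                         f$F[, seq_len(d), drop = FALSE])
  action <- sum(w * integrand)
  structure(list(t = seq(-t_half, t_half, length.out = n_nodes),
                 state = Z[, seq_len(d), drop = FALSE],
                 momentum = Z[, d + seq_len(d), drop = FALSE],
                 action = action, max_H = max(abs(wkb_H(model, Z))),
                 residual = sol$residual, iterations = sol$iterations,
                 converged = sol$converged, t_half = t_half,
                 n_nodes = n_nodes, model = model),
            class = "optimal_path")
}

#' @export
print.optimal_path <- function(x, ...) {
  cat(sprintf("Optimal path (%s model): action = %.6g, max|H| = %.2g, residual = %.2g (%d Newton iterations)\n",
              x$model$kind, x$action, x$max_H, x$residual, x$iterations))
  invisible(x)
}

# Damped Newton on the central-difference discretization.  Z_init (full node
# matrix) overrides the default guess; boundary rows are always re-pinned.
newton_path <- function(model, z_a, z_b, t_half, n_nodes, tol, max_iter,
                        Z_init = NULL) {
  d <- length(z_a) / 2
  tt <- seq(-t_half, t_half, length.out = n_nodes)
  h <- tt[2] - tt[1]
  if (is.null(Z_init)) {
    sig <- stats::plogis(tt / (t_half / 10))
    Z <- outer(rep(1, n_nodes), z_a) + outer(sig, z_b - z_a)
    if (model$kind == "full") {
      # embed the constrained zero-energy branch as the guess
      xs <- z_a[2]
      xg <- xs * (1 - sig)
      vg <- branch_momentum(model$params, model$policy,
                            pmin(pmax(xg, 0), xs * (1 - 1e-9)))
      Z <- cbind(1 - xg, xg, 0, vg)
    }
  } else {
    Z <- Z_init
    stopifnot(nrow(Z) == n_nodes)
  }
  Z[1, ] <- z_a
  Z[n_nodes, ] <- z_b

  int <- 2:(n_nodes - 1)
  ni <- length(int)
  resid_fun <- function(Z) {
    f <- wkb_field(model, Z)
    (Z[int + 1, , drop = FALSE] - Z[int - 1, , drop = FALSE]) / (2 * h) -
      f$F[int, , drop = FALSE]
  }
  # constant sparsity pattern: diagonal d x d blocks plus +-I/(2h) couplings
  en <- seq_len(ni)
  bi <- rep((en - 1) * (2 * d), each = (2 * d)^2)
  rows_blk <- bi + rep(rep(seq_len(2 * d), times = 2 * d), ni)
  cols_blk <- bi + rep(rep(seq_len(2 * d), each = 2 * d), ni)
  right <- en[en < ni]; left <- en[en > 1]
  rows_r <- rep((right - 1) * (2 * d), each = 2 * d) + rep(seq_len(2 * d), length(right))
  cols_r <- rep(right * (2 * d), each = 2 * d) + rep(seq_len(2 * d), length(right))
  rows_l <- rep((left - 1) * (2 * d), each = 2 * d) + rep(seq_len(2 * d), length(left))
  cols_l <- rep((left - 2) * (2 * d), each = 2 * d) + rep(seq_len(2 * d), length(left))
  vals_off <- c(rep(1 / (2 * h), 2 * d * length(right)),
                rep(-1 / (2 * h), 2 * d * length(left)))

  r <- resid_fun(Z)
  rn <- max(abs(r))
  iter <- 0L
  while (iter < max_iter && rn > tol) {
    iter <- iter + 1L
    f <- wkb_field(model, Z)
    Jf <- f$J[int, , , drop = FALSE]
    # column-major within each block: entry (a, b) of block n at position
    # ((n-1)*(2d)^2 + (b-1)*2d + a)
    vals_blk <- -aperm(Jf, c(2, 3, 1))
    A <- Matrix::sparseMatrix(i = c(rows_blk, rows_r, rows_l),
                              j = c(cols_blk, cols_r, cols_l),
                              x = c(as.numeric(vals_blk), vals_off),
                              dims = c(ni * 2 * d, ni * 2 * d))
    step <- tryCatch(as.numeric(Matrix::solve(A, as.numeric(t(r)))),
                     error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      Z2 <- Z
      Z2[int, ] <- Z[int, ] - alpha * matrix(step, ncol = 2 * d, byrow = TRUE)
      r2 <- resid_fun(Z2)
      if (max(abs(r2)) < rn || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    if (max(abs(r2)) >= rn && alpha < 1e-4) break  # line search failed: stop
    Z <- Z2; r <- r2; rn <- max(abs(r))
  }
  list(Z = Z, residual = rn, iterations = iter, converged = rn <= tol)
}

#' Action along a converged optimal path
#'
#' Integrates `sum_i p_i dx_i` along the path, parametrized by time
#' (`integrand = sum_i p_i * dH/dp_i`) with composite Simpson weights; the
#' time parametrization keeps the integral well-defined when a state
#' coordinate is non-monotone, as full-model paths can be.
#'
#' @param path An [optimal_path()] result.
#' @return The per-capita action (dimensionless, non-negative).
#' @export
action_numeric <- function(path) {
  stopifnot(inherits(path, "optimal_path"))
  d <- ncol(path$state)
  Z <- cbind(path$state, path$momentum)
  f <- wkb_field(path$model, Z)
  h <- path$t[2] - path$t[1]
  w <- simpson_weights(length(path$t), h)
  sum(w * rowSums(path$momentum * f$F[, seq_len(d), drop = FALSE]))
}

#' Constrained-model action by zero-energy branch quadrature
#'
#' For the constrained model the `H = 0` manifold gives the momentum as an
#' implicit function `p(x)`, so the action is a one-dimensional integral
#' `s = -int_0^{x*} p(x) dx` requiring no path solve.  Each `p(x)` is found
#' by bracketed root-finding to machine precision and the integral by
#' adaptive quadrature; the result serves as an independent cross-check for
#' [optimal_path()] and as the fast per-cell route in
#' [quasistationarity_map()].
#'
#' @param params An [epidemic_params()] object.
#' @param policy A [treatment_policy()] object.
#' @return The per-capita action (dimensionless).
#' @examples
#' action_quadrature(epidemic_params(2, 0.8, 0.2, 1000), treatment_policy())
#' # log(2) - 1 + 1/2
#' @export
action_quadrature <- function(params, policy = treatment_policy()) {
  rn <- reproduction_numbers(params, policy)
  if (rn$RT <= 1) stop("action undefined: RT <= 1")
  xs <- 1 - 1 / rn$RT
  f <- function(x) branch_momentum(params, policy, x)
  -stats::integrate(f, 0, xs * (1 - 1e-9), rel.tol = 1e-12,
                    subdivisions = 400L)$value
}
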