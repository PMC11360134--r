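# Matrix-free charge equilibration.
#
# The Qeq energy is E_Qeq(Q) = E_elec(Q) + sum_i (E_i + chi_i q_i +
# 0.5 J_i q_i^2) with E_elec = 0.5 Q^T A Q, and the equilibrated charges
# minimize it under sum(q) = Q_tot. The Coulomb matrix A is never formed:
# A %*% Q is evaluated as spread -> FFT Poisson solve -> probe, and the
# constrained stationarity conditions M Q = -chi + lambda 1 (M = A + diag(J))
# are solved by conjugate gradients with every residual and search direction
# projected onto the zero-sum hyperplane.

#' Solver settings for the projected conjugate gradient
#'
#' @param tol convergence tolerance: max-norm of the projected residual
#'   (hartree/e). Default 1e-8.
#' @param max_iter maximum CG iterations. Default 300.
#' @param initial initial-guess policy: "uniform" (q_i = Q_tot/N, satisfies
#'   the constraint exactly) or "supplied" (use `q0`, shifted onto the
#'   constraint if needed).
#' @param q0 initial charge vector when `initial = "supplied"` (also used as
#'   a warm start).
#' @param preconditioner "none" (plain CG, default) or "diagonal" (Jacobi
#'   preconditioner from the analytic diagonal A_ii + J_i = 1/(sigma_i
#'   sqrt(pi)) + J_i, applied inside the projected subspace).
#' @return object of class `qeq_solver_settings`.
#' @export
qeq_solver_settings <- function(tol = 1e-8, max_iter = 300L,
                                initial = c("uniform", "supplied"), q0 = NULL,
                                preconditioner = c("none", "diagonal")) {
  initial <- match.arg(initial)
  preconditioner <- match.arg(preconditioner)
  if (!is.finite(tol) || tol <= 0) stop("qeq_solver_settings: tol must be > 0")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("qeq_solver_settings: max_iter must be >= 1")
  if (initial == "supplied" && is.null(q0))
    stop("qeq_solver_settings: initial = 'supplied' needs q0")
  structure(list(tol = tol, max_iter = max_iter, initial = initial, q0 = q0,
                 preconditioner = preconditioner),
            class = "qeq_solver_settings")
}

#' Precomputed solver context
#'
#' Bundles a system with its resolved per-atom parameters and the FFT grid so
#' that repeated matrix-free products reuse the reciprocal-space bookkeeping.
#' All lower-level operations ([apply_A()], [qeq_gradient()],
#' [electrostatic_forces()], ...) take a context.
#'
#' @param system an [atomic_system()].
#' @param params a [qeq_parameters()] set.
#' @param grid optional [qeq_grid()]; default: spacing `min(sigma)/3`.
#' @param spacing grid spacing used when `grid` is NULL (bohr); default
#'   `min(sigma)/3`.
#' @param eps_trunc Gaussian truncation threshold for spreading/probing.
#' @param multi_image allow atom supports wider than the cell.
#' @return object of class `qeq_context`.
#' @export
qeq_context <- function(system, params, grid = NULL, spacing = NULL,
                        eps_trunc = 1e-10, multi_image = TRUE) {
  stopifnot(inherits(system, "atomic_system"))
  pp <- resolve_parameters(system, params)
  if (is.null(grid)) {
    if (is.null(spacing)) spacing <- min(pp$sigma) / 3
    grid <- qeq_grid(system$lattice, spacing = spacing)
  }
  check_system_grid(system, grid)
  structure(list(system = system, params = params, atom = pp, grid = grid,
                 eps_trunc = eps_trunc, multi_image = multi_image),
            class = "qeq_context")
}

#' @export
print.qeq_context <- function(x, ...) {
  cat(sprintf("qeq_context: %d atoms, grid %d x %d x %d, eps_trunc %.1e\n",
              x$system$n_atoms, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$eps_trunc))
  invisible(x)
}

as_qeq_context <- function(x, params = NULL, ...) {
  if (inherits(x, "qeq_context")) x else qeq_context(x, params, ...)
}

#' Matrix-free Coulomb product A %*% Q
#'
#' Component i is `int V[rho(Q)](r) rho_i(r) dr`: the density of Q is spread
#' on the mesh, Poisson's equation is solved in reciprocal space, and the
#' potential is probed on each atom's local support. Linear and symmetric in
#' Q without ever forming A.
#'
#' @param ctx a [qeq_context()].
#' @param q charge vector (e), length N.
#' @param with_field when TRUE, also return the density and potential fields.
#' @return numeric vector (hartree/e), or a list(Aq, rho, V) when
#'   `with_field` is TRUE.
#' @export
apply_A <- function(ctx, q, with_field = FALSE) {
  stopifnot(inherits(ctx, "qeq_context"))
  rho <- build_density(ctx$system, ctx$atom$sigma, q, grid = ctx$grid,
                       eps_trunc = ctx$eps_trunc, multi_image = ctx$multi_image)
  V <- solve_poisson(rho)
  Aq <- probe_potential_on_support(V, ctx$system, ctx$atom$sigma,
                                   eps_trunc = ctx$eps_trunc,
                                   multi_image = ctx$multi_image)
  if (with_field) list(Aq = Aq, rho = rho, V = V) else Aq
}

#' Matrix-free product M %*% Q with M = A + diag(J)
#'
#' @inheritParams apply_A
#' @return numeric vector (hartree/e).
#' @export
apply_M <- function(ctx, q) {
  apply_A(ctx, q) + ctx$atom$hardness * q
}

#' Project a gradient onto the total-charge constraint
#'
#' Orthogonal projection onto the hyperplane sum(dq) = 0: returns
#' `g - mean(g)`. Idempotent; the output sums to zero exactly (the mean is
#' subtracted in a numerically compensated way).
#'
#' @param g numeric vector.
#' @return numeric vector with zero sum.
#' @export
project_constrained <- function(g) {
  g - mean(g)
}

#' Gradient of the Qeq energy with respect to the charges
#'
#' `dE_Qeq/dq_i = chi_i + J_i q_i + (A Q)_i`. At the constrained minimum the
#' projected gradient vanishes and the unprojected gradient is the constant
#' lambda (equal effective electronegativity on every atom).
#'
#' @inheritParams apply_A
#' @return numeric vector (hartree/e).
#' @export
qeq_gradient <- function(ctx, q) {
  stopifnot(inherits(ctx, "qeq_context"))
  ctx$atom$chi + ctx$atom$hardness * q + apply_A(ctx, q)
}

#' Charge equilibration by projected conjugate gradients
#'
#' Minimizes the Qeq energy under the total-charge constraint with standard
#' CG on the projected stationarity system: every residual and search
#' direction is projected onto the zero-sum hyperplane, so each iterate
#' satisfies sum(q) = Q_tot to machine precision and arbitrarily large steps
#' stay on the constraint. Convergence is measured by the max-norm of the
#' projected residual.
#'
#' @param system an [atomic_system()] or a prebuilt [qeq_context()].
#' @param params a [qeq_parameters()] set (ignored when `system` is a
#'   context).
#' @param settings a [qeq_solver_settings()].
#' @param grid,spacing,eps_trunc,multi_image forwarded to [qeq_context()]
#'   when a raw system is given.
#' @return object of class `qeq_result`: `charges`, `e_elec`, `e_qeq`,
#'   `lambda` (scalar Lagrange multiplier, hartree/e), `iterations`,
#'   `residual_maxnorm`, `residual_history`, `energy_history` (E_Qeq at each
#'   iterate), `converged`.
#' @export
solve_qeq <- function(system, params = NULL, settings = qeq_solver_settings(),
                      grid = NULL, spacing = NULL, eps_trunc = 1e-10,
                      multi_image = TRUE) {
  ctx <- as_qeq_context(system, params, grid = grid, spacing = spacing,
                        eps_trunc = eps_trunc, multi_image = multi_image)
  n <- ctx$system$n_atoms
  qtot <- ctx$system$total_charge
  chi <- ctx$atom$chi

  q <- if (settings$initial == "supplied") {
    q0 <- rep_len(as.numeric(settings$q0), n)
    q0 + (qtot - sum(q0)) / n          # shift onto the constraint
  } else rep(qtot / n, n)

  prec <- switch(settings$preconditioner,
                 none = NULL,
                 diagonal = 1 / (1 / (ctx$atom$sigma * sqrt(pi)) + ctx$atom$hardness))

  cg <- projected_cg(function(x) apply_M(ctx, x), b = -chi, x0 = q,
                     tol = settings$tol, max_iter = settings$max_iter,
                     prec = prec)
  q <- cg$x
  if (!cg$converged)
    stop(structure(class = c("qeq_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "solve_qeq: projected residual %.3e after %d iterations (tol %.1e)",
                     cg$residual, cg$iterations, settings$tol),
                     call = sys.call(-1), best = q,
                     residual_history = cg$residual_history)))

  af <- apply_A(ctx, q, with_field = TRUE)
  e_elec <- electrostatic_energy(af$rho)
  e_qeq <- e_elec + sum(ctx$atom$e_offset + chi * q + 0.5 * ctx$atom$hardness * q^2)
  grad <- chi + ctx$atom$hardness * q + af$Aq
  lambda <- mean(grad)                  # -mean of the unprojected residual b - Mq
  # energy history from the CG quadratic model, anchored at the final energy
  e_hist <- e_qeq + cg$de_history - cg$de_history[length(cg$de_history)]
  structure(list(charges = q, e_elec = e_elec, e_qeq = e_qeq, lambda = lambda,
                 iterations = cg$iterations, residual_maxnorm = cg$residual,
                 residual_history = cg$residual_history,
                 energy_history = e_hist, converged = cg$converged,
                 constraint_dev = cg$constraint_dev,
                 grid_dims = ctx$grid$dims),
            class = "qeq_result")
}

#' @export
print.qeq_result <- function(x, ...) {
  cat(sprintf(paste0("qeq_result: %d charges, E_elec = %.8f Ha, E_Qeq = %.8f Ha,\n",
                     "  lambda = %.6e Ha/e, %d iterations, max|residual| = %.3e\n"),
              length(x$charges), x$e_elec, x$e_qeq, x$lambda, x$iterations,
              x$residual_maxnorm))
  invisible(x)
}

# Projected CG for M x = b on the affine constraint sum(x) = sum(x0).
# apply_fn must be symmetric positive definite on the zero-sum hyperplane.
# Tracks the energy change of the quadratic model 0.5 x^T M x - b^T x
# (exact for exact arithmetic) for the monotonicity diagnostics.
projected_cg <- function(apply_fn, b, x0, tol, max_iter, prec = NULL) {
  x <- x0
  r <- project_constrained(b - apply_fn(x))
  z <- if (is.null(prec)) r else project_constrained(r * prec)
  p <- z
  rz <- sum(r * z)
  res <- max(abs(r))
  res_hist <- res
  de_hist <- 0
  de <- 0
  it <- 0L
  target_sum <- sum(x0)
  csum_dev <- abs(sum(x) - target_sum)
  while (res > tol && it < max_iter) {
    Mp <- apply_fn(p)
    pMp <- sum(p * Mp)
    if (!is.finite(pMp) || pMp <= 0)
      stop("projected_cg: non-positive curvature p^T M p = ", format(pMp),
           "; the operator is not positive definite (check hardness/width parameters)")
    alpha <- rz / pMp
    x <- x + alpha * p
    r <- r - alpha * project_constrained(Mp)
    de <- de - 0.5 * alpha * rz    # exact model decrease of the CG step
    z <- if (is.null(prec)) r else project_constrained(r * prec)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
    it <- it + 1L
    res <- max(abs(r))
    res_hist <- c(res_hist, res)
    de_hist <- c(de_hist, de)
    csum_dev <- max(csum_dev, abs(sum(x) - target_sum))
  }
  list(x = x, iterations = it, residual = res, converged = res <= tol,
       residual_history = res_hist, de_history = de_hist,
       constraint_dev = csum_dev)
}
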