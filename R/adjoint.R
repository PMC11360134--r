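# Forces, macroscopic stress, and the adjoint (lambda) machinery.
#
# For E = E_Qeq the charges are variational, so the total force needs no
# extra solve (Hellmann-Feynman shortcut). For a downstream energy E that
# consumes the equilibrated charges, one extra projected-CG solve for the
# adjoint charges lambda converts the implicit dQ/dR dependence into two
# quasi-linear terms:
#   dE/dR = dE/dR|explicit + lambda^T dchi/dR + lambda^T (dA/dR) Q
#   dE/deps = dE/deps|explicit + lambda^T dchi/deps + lambda^T (dA/deps) Q
# The lambda-Q Coulomb term is evaluated by probing the potential of the
# lambda-density against each q_i rho_i and vice versa (real space), and its
# strain counterpart with six extra FFTs (reciprocal space) -- O(1) Poisson
# solves per derivative evaluation, independent of N.

#' Electrostatic forces at fixed charges
#'
#' `F_i = -q_i int V(r) d rho_i / d r_i dr`, the derivative of the mesh
#' electrostatic energy with the charges held fixed, evaluated with the
#' analytic Gaussian gradient on each atom's local support. Because probe is
#' the exact adjoint of spread, this is the exact gradient of the discrete
#' energy up to the Gaussian truncation threshold.
#'
#' @param ctx a [qeq_context()].
#' @param q charge vector (e).
#' @param fields optional precomputed `list(rho, V)` from [apply_A()].
#' @return N x 3 matrix of forces (hartree/bohr).
#' @export
electrostatic_forces <- function(ctx, q, fields = NULL) {
  stopifnot(inherits(ctx, "qeq_context"))
  q <- rep_len(as.numeric(q), ctx$system$n_atoms)
  if (is.null(fields)) {
    rho <- build_density(ctx$system, ctx$atom$sigma, q, grid = ctx$grid,
                         eps_trunc = ctx$eps_trunc, multi_image = ctx$multi_image)
    V <- solve_poisson(rho)
  } else V <- fields$V
  G <- probe_potential_gradient(V, ctx$system, ctx$atom$sigma,
                                eps_trunc = ctx$eps_trunc,
                                multi_image = ctx$multi_image)
  -q * G
}

#' Total forces for E = E_Qeq (variational shortcut)
#'
#' Because the equilibrated charges minimize E_Qeq, its total position
#' derivative needs no adjoint solve: the force is the fixed-charge
#' electrostatic force plus the explicit position dependence of the
#' electronegativities contracted with the charges (zero for constant
#' per-element chi).
#'
#' @param ctx a [qeq_context()].
#' @param result a converged `qeq_result` from [solve_qeq()].
#' @param dchi_dR optional contraction hook: `function(v)` returning the
#'   N x 3 matrix with rows `sum_j v_j d chi_j / d r_i` (see
#'   [toy_chi_model()]); the hook is called with the charges.
#' @return N x 3 matrix of forces (hartree/bohr).
#' @export
qeq_forces <- function(ctx, result, dchi_dR = NULL) {
  stopifnot(inherits(ctx, "qeq_context"), inherits(result, "qeq_result"))
  if (!isTRUE(result$converged))
    stop("qeq_forces: the Qeq result is not converged")
  f <- electrostatic_forces(ctx, result$charges)
  if (!is.null(dchi_dR)) f <- f - dchi_dR(result$charges)
  f
}

#' Macroscopic stress for E = E_Qeq
#'
#' `sigma = (1/Omega) dE_elec/deps` evaluated in reciprocal space with the
#' six strain-derivative densities (the charges are variational, so no
#' adjoint term is needed; constant chi has no strain dependence).
#'
#' @param ctx a [qeq_context()].
#' @param q equilibrated charges (e).
#' @return 3x3 symmetric stress tensor (hartree/bohr^3), sign convention
#'   `+ (1/Omega) dE/deps`.
#' @export
qeq_stress <- function(ctx, q) {
  stopifnot(inherits(ctx, "qeq_context"))
  q <- rep_len(as.numeric(q), ctx$system$n_atoms)
  rho <- build_density(ctx$system, ctx$atom$sigma, q, grid = ctx$grid,
                       eps_trunc = ctx$eps_trunc, multi_image = ctx$multi_image)
  ds <- build_strain_derivative_densities(ctx$system, ctx$atom$sigma, q,
                                          grid = ctx$grid,
                                          eps_trunc = ctx$eps_trunc,
                                          multi_image = ctx$multi_image)
  reciprocal_stress(rho, ds) / ctx$system$volume
}

#' Adjoint (lambda) charges by projected conjugate gradients
#'
#' Solves `M lambda = -dE_dQ` under `sum(lambda) = 0` with the same
#' matrix-free operator and projected CG as [solve_qeq()]. A constant
#' `dE_dQ` has zero projected right-hand side and returns lambda = 0.
#'
#' @param ctx a [qeq_context()].
#' @param dE_dQ derivative of the downstream energy w.r.t. the charges
#'   (length N, hartree/e).
#' @param settings a [qeq_solver_settings()] (the initial-guess policy is
#'   ignored; lambda starts from 0).
#' @return list: `lambda` (length N, sums to zero), `iterations`,
#'   `residual_maxnorm`, `residual_history`, `converged`.
#' @export
solve_lambda <- function(ctx, dE_dQ, settings = qeq_solver_settings()) {
  stopifnot(inherits(ctx, "qeq_context"))
  n <- ctx$system$n_atoms
  if (length(dE_dQ) != n) stop("solve_lambda: dE_dQ must have length N")
  prec <- switch(settings$preconditioner,
                 none = NULL,
                 diagonal = 1 / (1 / (ctx$atom$sigma * sqrt(pi)) + ctx$atom$hardness))
  cg <- projected_cg(function(x) apply_M(ctx, x), b = -as.numeric(dE_dQ),
                     x0 = rep(0, n), tol = settings$tol,
                     max_iter = settings$max_iter, prec = prec)
  if (!cg$converged)
    stop(sprintf("solve_lambda: projected residual %.3e after %d iterations (tol %.1e)",
                 cg$residual, cg$iterations, settings$tol))
  list(lambda = cg$x, iterations = cg$iterations,
       residual_maxnorm = cg$residual, residual_history = cg$residual_history,
       constraint_dev = cg$constraint_dev, converged = cg$converged)
}

#' Total forces for a downstream energy of the equilibrated charges
#'
#' Assembles
#' `F = F_elec(Q) [optional] + explicit_forces - dchi_dR(lambda) - lambda-Q term`,
#' where the lambda-Q Coulomb double sum is evaluated in quasi-linear time by
#' probing the potential of the lambda-density against each q_i rho_i and the
#' potential of the Q-density against each lambda_i rho_i (O(1) Poisson
#' solves). `explicit_forces` is `-dE/dR` of the non-electrostatic explicit
#' part, owned by the caller; `include_elec` states whether the downstream
#' energy contains E_elec(Q) itself (as in fourth-generation MLPs).
#'
#' With `lambda = 0` (the E = E_Qeq limit) and `explicit_forces` the chi
#' term contracted with Q, this reduces to [qeq_forces()].
#'
#' @param ctx a [qeq_context()].
#' @param q equilibrated charges (e).
#' @param lambda adjoint charges from [solve_lambda()] (length N, zero sum).
#' @param explicit_forces N x 3 matrix `-dE/dR|explicit` of the downstream
#'   energy's own position dependence (default zero).
#' @param dchi_dR optional contraction hook called with lambda (see
#'   [qeq_forces()]).
#' @param include_elec does the downstream energy include E_elec(Q)?
#' @return N x 3 matrix of forces (hartree/bohr).
#' @export
total_forces <- function(ctx, q, lambda, explicit_forces = NULL,
                         dchi_dR = NULL, include_elec = TRUE) {
  stopifnot(inherits(ctx, "qeq_context"))
  n <- ctx$system$n_atoms
  q <- rep_len(as.numeric(q), n)
  if (length(lambda) != n) stop("total_forces: lambda must have length N")
  sig <- ctx$atom$sigma
  rho_q <- build_density(ctx$system, sig, q, grid = ctx$grid,
                         eps_trunc = ctx$eps_trunc, multi_image = ctx$multi_image)
  V_q <- solve_poisson(rho_q)
  rho_l <- build_density(ctx$system, sig, lambda, grid = ctx$grid,
                         eps_trunc = ctx$eps_trunc, multi_image = ctx$multi_image)
  V_l <- solve_poisson(rho_l)
  Gq <- probe_potential_gradient(V_q, ctx$system, sig, eps_trunc = ctx$eps_trunc,
                                 multi_image = ctx$multi_image)
  Gl <- probe_potential_gradient(V_l, ctx$system, sig, eps_trunc = ctx$eps_trunc,
                                 multi_image = ctx$multi_image)
  # d(lambda^T A Q)/dr_i = lambda_i G_i(V_q) + q_i G_i(V_lambda)
  f <- -(lambda * Gq + q * Gl)
  if (include_elec) f <- f - q * Gq
  if (!is.null(explicit_forces)) f <- f + explicit_forces
  if (!is.null(dchi_dR)) f <- f - dchi_dR(lambda)
  f
}

#' Total macroscopic stress for a downstream energy
#'
#' `sigma = (1/Omega) [dE/deps|explicit + dE_elec/deps(Q) [optional]
#' + d(lambda^T A Q)/deps]`, with the electrostatic strain terms evaluated in
#' reciprocal space (six extra FFTs for each set of strain-derivative
#' densities).
#'
#' @param ctx a [qeq_context()].
#' @param q equilibrated charges (e).
#' @param lambda adjoint charges (length N, zero sum).
#' @param explicit_stress 3x3 matrix `dE/deps|explicit` of the downstream
#'   energy (default zero; note: energy-gradient convention, not divided by
#'   volume).
#' @param include_elec does the downstream energy include E_elec(Q)?
#' @return 3x3 symmetric stress tensor (hartree/bohr^3).
#' @export
total_stress <- function(ctx, q, lambda, explicit_stress = NULL,
                         include_elec = TRUE) {
  stopifnot(inherits(ctx, "qeq_context"))
  n <- ctx$system$n_atoms
  q <- rep_len(as.numeric(q), n)
  if (length(lambda) != n) stop("total_stress: lambda must have length N")
  sig <- ctx$atom$sigma
  rho_q <- build_density(ctx$system, sig, q, grid = ctx$grid,
                         eps_trunc = ctx$eps_trunc, multi_image = ctx$multi_image)
  ds_q <- build_strain_derivative_densities(ctx$system, sig, q, grid = ctx$grid,
                                            eps_trunc = ctx$eps_trunc,
                                            multi_image = ctx$multi_image)
  de <- matrix(0, 3, 3)
  if (any(lambda != 0)) {
    rho_l <- build_density(ctx$system, sig, lambda, grid = ctx$grid,
                           eps_trunc = ctx$eps_trunc, multi_image = ctx$multi_image)
    ds_l <- build_strain_derivative_densities(ctx$system, sig, lambda,
                                              grid = ctx$grid,
                                              eps_trunc = ctx$eps_trunc,
                                              multi_image = ctx$multi_image)
    de <- de + cross_strain_derivative(rho_l, ds_l, rho_q, ds_q)
  }
  if (include_elec) de <- de + reciprocal_stress(rho_q, ds_q)
  if (!is.null(explicit_stress)) de <- de + explicit_stress
  de / ctx$system$volume
}
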