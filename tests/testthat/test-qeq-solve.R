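# Matrix-free operators and the projected conjugate-gradient solver.

test_that("constraint projection is idempotent and kills constants", {
  expect_equal(project_constrained(rep(3.2, 7)), rep(0, 7))
  g <- c(1, 0, -1)
  expect_equal(project_constrained(g), g)          # already mean-zero
  set.seed(1)
  x <- rnorm(11)
  p <- project_constrained(x)
  expect_equal(project_constrained(p), p)
  expect_lt(abs(sum(p)), 1e-14)
})

test_that("matrix-free A is linear, symmetric and matches the dense oracle", {
  fx <- small_fixture(n = 12, seed = 21, cell = 9)
  ctx <- qeq_context(fx$system, fx$params)
  set.seed(2)
  q <- rnorm(12); p <- rnorm(12)
  expect_true(all(apply_A(ctx, rep(0, 12)) == 0))
  # symmetry p^T A q = q^T A p
  expect_lt(abs(sum(p * apply_A(ctx, q)) - sum(q * apply_A(ctx, p))), 1e-10)
  # dense Ewald product
  pp <- resolve_parameters(fx$system, fx$params)
  A <- ewald_matrix(fx$system, pp$sigma)
  expect_lt(max(abs(apply_A(ctx, q) - A %*% q)), 1e-7)
  # M = A + diag(J), positive definite
  expect_lt(max(abs(apply_M(ctx, q) - (A %*% q + pp$hardness * q))), 1e-7)
  expect_gt(sum(q * apply_M(ctx, q)), 0)
})

test_that("qeq gradient reduces to chi at Q = 0 and matches finite differences", {
  fx <- small_fixture(n = 5, seed = 23)
  ctx <- qeq_context(fx$system, fx$params)
  pp <- resolve_parameters(fx$system, fx$params)
  expect_equal(qeq_gradient(ctx, rep(0, 5)), pp$chi, tolerance = 1e-12)
  # constrained FD: move charge between atoms 1 and 2
  q <- c(0.3, -0.1, -0.1, 0, -0.1)
  e_qeq <- function(qq) {
    rho <- build_density(fx$system, pp$sigma, qq, grid = ctx$grid)
    electrostatic_energy(rho) + sum(pp$chi * qq + 0.5 * pp$hardness * qq^2)
  }
  h <- 1e-6
  d12 <- c(1, -1, 0, 0, 0)
  fd <- (e_qeq(q + h * d12) - e_qeq(q - h * d12)) / (2 * h)
  gr <- qeq_gradient(ctx, q)
  expect_lt(abs(fd - (gr[1] - gr[2])), 1e-6)
})

test_that("two identical atoms split the charge symmetrically", {
  sys0 <- atomic_system(diag(3) * 10, c("a", "a"),
                        rbind(c(2, 5, 5), c(6, 5, 5)), 0)
  par <- qeq_parameters("a", chi = 0.3, hardness = 0.8, sigma = 1)
  r0 <- solve_qeq(sys0, par)
  expect_equal(r0$charges, c(0, 0), tolerance = 1e-10)
  sys1 <- atomic_system(sys0$lattice, sys0$species, sys0$positions, 1)
  r1 <- solve_qeq(sys1, par)
  expect_equal(r1$charges, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("two-atom solve matches the hand-solved bordered KKT system", {
  sys <- atomic_system(diag(3) * 12, c("a", "a"),
                       rbind(c(0, 0, 0), c(3.5, 0, 0)), 0)
  par <- qeq_parameters("a", chi = 0, hardness = 0.9, sigma = 1,
                        chi_atoms = c(0.1, 0.5))
  A <- ewald_matrix(sys, c(1, 1))
  # q1 = -q2 = (chi2 - chi1)/(J1 + J2 + 2 (A11 - A12))
  q_exact <- (0.5 - 0.1) / (0.9 + 0.9 + 2 * (A[1, 1] - A[1, 2]))
  res <- solve_qeq(sys, par, settings = qeq_solver_settings(tol = 1e-10))
  expect_equal(res$charges, c(q_exact, -q_exact), tolerance = 1e-9)
  # lambda equals the common effective electronegativity
  ctx <- qeq_context(sys, par)
  gr <- qeq_gradient(ctx, res$charges)
  expect_lt(max(abs(gr - res$lambda)), 1e-9)
})

test_that("iterates conserve the total charge and decrease the energy", {
  fx <- small_fixture(n = 8, seed = 25, cell = 9)
  sys <- atomic_system(fx$system$lattice, fx$system$species,
                       fx$system$positions, total_charge = 0.5)
  res <- solve_qeq(sys, fx$params, settings = qeq_solver_settings(tol = 1e-9))
  expect_lt(abs(sum(res$charges) - 0.5), 1e-12)
  expect_lt(res$constraint_dev, 1e-12)             # every CG iterate
  expect_true(all(diff(res$energy_history) <= 1e-13))  # monotone decrease
  expect_lte(res$residual_maxnorm, 1e-9)
  # equal effective electronegativity at convergence
  ctx <- qeq_context(sys, fx$params)
  gr <- qeq_gradient(ctx, res$charges)
  expect_lt(max(abs(gr - mean(gr))), 1e-8)
})

test_that("iterative charges match the dense direct solve", {
  for (seed in c(31, 32)) {
    fx <- small_fixture(n = 15, seed = seed, cell = 10)
    it <- solve_qeq(fx$system, fx$params,
                    settings = qeq_solver_settings(tol = 1e-9))
    dr <- direct_solve(fx$system, fx$params)
    expect_lt(max(abs(it$charges - dr$charges)), 1e-6)
    expect_lt(abs(it$e_elec - dr$e_elec), 1e-6)
    expect_lt(abs(it$lambda - dr$lambda), 1e-6)
  }
})

test_that("warm start from a perturbed solution converges in fewer iterations", {
  fx <- small_fixture(n = 12, seed = 33, cell = 9)
  res <- solve_qeq(fx$system, fx$params,
                   settings = qeq_solver_settings(tol = 1e-9))
  set.seed(4)
  sys2 <- atomic_system(fx$system$lattice, fx$system$species,
                        fx$system$positions + matrix(rnorm(36, 0, 0.02), 12, 3),
                        fx$system$total_charge)
  cold <- solve_qeq(sys2, fx$params, settings = qeq_solver_settings(tol = 1e-9))
  warm <- solve_qeq(sys2, fx$params,
                    settings = qeq_solver_settings(tol = 1e-9,
                                                   initial = "supplied",
                                                   q0 = res$charges))
  expect_lt(warm$iterations, cold$iterations)
  expect_lt(max(abs(warm$charges - cold$charges)), 1e-7)
})

test_that("diagonal preconditioner reaches the same solution", {
  fx <- small_fixture(n = 10, seed = 35, cell = 9)
  a <- solve_qeq(fx$system, fx$params, settings = qeq_solver_settings(tol = 1e-10))
  b <- solve_qeq(fx$system, fx$params,
                 settings = qeq_solver_settings(tol = 1e-10,
                                                preconditioner = "diagonal"))
  expect_lt(max(abs(a$charges - b$charges)), 1e-8)
})

test_that("non-convergence raises a diagnostic error", {
  fx <- small_fixture(n = 8, seed = 37, cell = 9)
  expect_error(solve_qeq(fx$system, fx$params,
                         settings = qeq_solver_settings(tol = 1e-13,
                                                        max_iter = 2L)),
               "residual")
})
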