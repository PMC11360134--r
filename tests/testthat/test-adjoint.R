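# Forces, stress and the adjoint (lambda) machinery.

test_that("single atom in a cubic cell feels no force", {
  sys <- atomic_system(diag(3) * 12, "A", matrix(c(3, 7, 5), 1, 3), 1)
  par <- qeq_parameters("A", 0, 1, 1)
  ctx <- qeq_context(sys, par)
  f <- electrostatic_forces(ctx, 1)
  expect_lt(max(abs(f)), 1e-10)
})

test_that("oppositely charged dimer forces are equal, opposite, along the bond", {
  sys <- atomic_system(diag(3) * 14, c("a", "a"),
                       rbind(c(4, 7, 7), c(9, 7, 7)), 0)
  par <- qeq_parameters("a", 0, 1, 1)
  ctx <- qeq_context(sys, par)
  f <- electrostatic_forces(ctx, c(1, -1))
  expect_lt(max(abs(f[1, ] + f[2, ])), 1e-10)       # Newton's third law
  expect_lt(max(abs(f[, 2:3])), 1e-10)              # along x only
  expect_gt(f[1, 1], 0)                              # attraction
})

test_that("electrostatic forces match finite differences at fixed charges", {
  fx <- small_fixture(n = 6, seed = 51)
  ctx <- qeq_context(fx$system, fx$params)
  pp <- resolve_parameters(fx$system, fx$params)
  set.seed(6)
  q <- project_constrained(rnorm(6))
  f <- electrostatic_forces(ctx, q)
  fd <- fd_forces(fx$system, mesh_energy_fn(pp$sigma, q, ctx$grid$dims))
  expect_lt(max(abs(f - fd)), 1e-6)
  expect_lt(max(abs(colSums(f))), 1e-8)
})

test_that("lambda solve matches the dense bordered oracle and is linear", {
  fx <- small_fixture(n = 10, seed = 53, cell = 9)
  ctx <- qeq_context(fx$system, fx$params)
  set.seed(7)
  dE <- rnorm(10)
  la <- solve_lambda(ctx, dE, qeq_solver_settings(tol = 1e-10))
  ld <- dense_lambda_solve(fx$system, fx$params, dE)
  expect_lt(max(abs(la$lambda - ld)), 1e-8)
  expect_lt(abs(sum(la$lambda)), 1e-12)
  expect_lt(la$constraint_dev, 1e-12)
  # constant right-hand side -> lambda = 0
  l0 <- solve_lambda(ctx, rep(4.2, 10), qeq_solver_settings(tol = 1e-10))
  expect_lt(max(abs(l0$lambda)), 1e-12)
  # linearity
  l2 <- solve_lambda(ctx, 2 * dE, qeq_solver_settings(tol = 1e-10))
  expect_lt(max(abs(l2$lambda - 2 * la$lambda)), 1e-8)
})

test_that("lambda-Q force term matches the dense double-sum oracle", {
  # d(lambda^T A Q)/dr_i computed quasi-linearly vs dense FD of lambda^T A Q
  fx <- small_fixture(n = 8, seed = 55, cell = 9)
  ctx <- qeq_context(fx$system, fx$params)
  pp <- resolve_parameters(fx$system, fx$params)
  set.seed(8)
  q <- rnorm(8); lam <- project_constrained(rnorm(8))
  # quasi-linear term alone: total_forces with no elec, no explicit parts
  f_term <- total_forces(ctx, q, lam, include_elec = FALSE)
  cross_fn <- function(s) {
    A <- ewald_matrix(s, pp$sigma)
    sum(lam * (A %*% q))
  }
  fd <- fd_forces(fx$system, cross_fn, h = 2e-5)
  expect_lt(max(abs(f_term - fd)), 1e-6)
})

test_that("qeq forces equal electrostatic forces for constant chi", {
  fx <- small_fixture(n = 5, seed = 57)
  ctx <- qeq_context(fx$system, fx$params)
  res <- solve_qeq(ctx, settings = qeq_solver_settings(tol = 1e-10))
  expect_identical(qeq_forces(ctx, res), electrostatic_forces(ctx, res$charges))
  # with lambda = 0 the total-force assembly reduces to the same thing
  ft <- total_forces(ctx, res$charges, rep(0, 5))
  expect_lt(max(abs(ft - qeq_forces(ctx, res))), 1e-12)
})

test_that("qeq forces match finite differences of E_Qeq with re-equilibration", {
  fx <- small_fixture(n = 6, seed = 59)
  base_chi <- fx$params$chi[match(fx$system$species, fx$params$elements)]
  mk <- function(sys) {
    toy <- toy_chi_model(sys, base = base_chi, amp = 0.08, w = 3, rc = 3.4)
    par <- fx$params; par$chi_atoms <- toy$chi
    list(toy = toy, par = par)
  }
  dims <- qeq_context(fx$system, fx$params)$grid$dims
  m <- mk(fx$system)
  ctx <- qeq_context(fx$system, m$par, grid = qeq_grid(fx$system$lattice, dims = dims))
  res <- solve_qeq(ctx, settings = qeq_solver_settings(tol = 1e-11))
  f <- qeq_forces(ctx, res, dchi_dR = m$toy$dchi_dR)
  e_fn <- function(s) {
    mm <- mk(s)
    solve_qeq(s, mm$par, grid = qeq_grid(s$lattice, dims = dims),
              settings = qeq_solver_settings(tol = 1e-10))$e_qeq
  }
  fd <- fd_forces(fx$system, e_fn)
  expect_lt(max(abs(f - fd)), 1e-6)
})

test_that("doubling the hardness changes forces smoothly", {
  fx <- small_fixture(n = 5, seed = 61)
  res1 <- solve_qeq(fx$system, fx$params)
  par2 <- fx$params; par2$hardness <- 2 * par2$hardness
  res2 <- solve_qeq(fx$system, par2)
  ctx1 <- qeq_context(fx$system, fx$params)
  ctx2 <- qeq_context(fx$system, par2)
  f1 <- qeq_forces(ctx1, res1); f2 <- qeq_forces(ctx2, res2)
  expect_true(all(is.finite(f1)) && all(is.finite(f2)))
  expect_gt(max(abs(f1)), max(abs(f2)))   # stiffer atoms, smaller charges
})

test_that("qeq stress matches finite differences with re-equilibration", {
  fx <- rocksalt_fixture(a = 7.5)
  ctx <- qeq_context(fx$system, fx$params, spacing = 0.3)
  res <- solve_qeq(ctx, settings = qeq_solver_settings(tol = 1e-11))
  st <- qeq_stress(ctx, res$charges)
  e_fn <- function(s) solve_qeq(s, fx$params,
                                grid = qeq_grid(s$lattice, dims = ctx$grid$dims),
                                settings = qeq_solver_settings(tol = 1e-10))$e_qeq
  fd <- fd_strain_gradient(fx$system, e_fn) / fx$system$volume
  expect_lt(max(abs(st - fd)), 1e-7)
})

test_that("rigid translation leaves forces unchanged within grid tolerance", {
  fx <- small_fixture(n = 5, seed = 63)
  ctx <- qeq_context(fx$system, fx$params)
  res <- solve_qeq(ctx, settings = qeq_solver_settings(tol = 1e-10))
  f0 <- qeq_forces(ctx, res)
  sys2 <- atomic_system(fx$system$lattice, fx$system$species,
                        sweep(fx$system$positions, 2, c(0.31, -0.17, 0.23), "+"),
                        fx$system$total_charge)
  ctx2 <- qeq_context(sys2, fx$params, grid = ctx$grid)
  res2 <- solve_qeq(ctx2, settings = qeq_solver_settings(tol = 1e-10))
  f2 <- qeq_forces(ctx2, res2)
  expect_lt(max(abs(f0 - f2)), 1e-8)
})
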