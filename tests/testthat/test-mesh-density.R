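# Gaussian rasterization on the periodic mesh: normalization, linearity,
# periodic-image correctness, translation invariance, probing.

test_that("single normalized Gaussian integrates to its charge on the mesh", {
  sys <- atomic_system(diag(3) * 20, "X", matrix(c(3, 4, 5), 1, 3), 1)
  g <- qeq_grid(sys$lattice, dims = c(64, 64, 64))
  rho <- build_density(sys, sigma = 1, q = 1, grid = g)
  integral <- sum(rho$values) * g$volume / g$n_points
  expect_lt(abs(integral - 1), 1e-8)
})

test_that("density is linear in the charges and vanishes for Q = 0", {
  fx <- small_fixture(n = 5, seed = 4)
  sig <- resolve_parameters(fx$system, fx$params)$sigma
  g <- qeq_grid(fx$system$lattice, dims = c(24, 24, 24))
  expect_true(all(build_density(fx$system, sig, 0, grid = g)$values == 0))
  q1 <- c(1, -1, 2, 0, -2) / 3
  q2 <- c(0.3, 0.1, -0.5, 0.4, -0.3)
  lhs <- build_density(fx$system, sig, 2 * q1 - 0.5 * q2, grid = g)$values
  rhs <- 2 * build_density(fx$system, sig, q1, grid = g)$values -
    0.5 * build_density(fx$system, sig, q2, grid = g)$values
  expect_lt(max(abs(lhs - rhs)), 1e-14)
})

test_that("mesh density matches a brute-force periodic image sum (triclinic)", {
  # non-orthogonal cell exercises the general (non-separable) kernel path
  h <- matrix(c(7, 0, 0, 1.1, 6.5, 0, 0.7, -0.6, 7.2), 3, 3)
  set.seed(9)
  pos <- t(h %*% matrix(runif(15), 3))
  sys <- atomic_system(h, letters[1:5], pos, 0)
  sig <- runif(5, 0.5, 0.7)
  q <- rnorm(5)
  dims <- c(18, 16, 18)
  rho <- build_density(sys, sig, q, grid = qeq_grid(h, dims = dims),
                       eps_trunc = 1e-12)
  # brute force: loop every grid point over atoms and a 5^3 block of images
  frac <- sapply(0:2, function(a) (0:(dims[a + 1] - 1)) / dims[a + 1])
  ref <- array(0, dims)
  imgs <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  for (i in 1:5) {
    for (im in seq_len(nrow(imgs))) {
      center <- pos[i, ] + as.numeric(h %*% imgs[im, ])
      for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) {
        r <- t(h %*% rbind(frac[[1]], frac[[2]][j], frac[[3]][k]))
        d2 <- (r[, 1] - center[1])^2 + (r[, 2] - center[2])^2 + (r[, 3] - center[3])^2
        ref[, j, k] <- ref[, j, k] +
          q[i] * (2 * pi * sig[i]^2)^(-1.5) * exp(-d2 / (2 * sig[i]^2))
      }
    }
  }
  expect_lt(max(abs(rho$values - ref)), 5e-12)
})

test_that("integer grid-vector translation permutes field values exactly", {
  fx <- small_fixture(n = 4, seed = 5)
  sig <- resolve_parameters(fx$system, fx$params)$sigma
  dims <- c(24, 24, 24)
  g <- qeq_grid(fx$system$lattice, dims = dims)
  q <- c(0.5, -0.2, -0.4, 0.1)
  rho <- build_density(fx$system, sig, q, grid = g)
  shift <- as.numeric(fx$system$lattice %*% (c(3, 0, 0) / dims))
  sys2 <- atomic_system(fx$system$lattice, fx$system$species,
                        sweep(fx$system$positions, 2, shift, "+"), 0)
  rho2 <- build_density(sys2, sig, q, grid = g)
  perm <- rho$values[c(22:24, 1:21), , ]   # values shifted by 3 along axis 1
  expect_identical(rho2$values[4, 5, 6], perm[4, 5, 6])
  expect_lt(max(abs(rho2$values - perm)), 1e-16)
})

test_that("strain-derivative densities match central differences in strain", {
  fx <- small_fixture(n = 3, seed = 11)
  pp <- resolve_parameters(fx$system, fx$params)
  dims <- c(27, 27, 27)
  g <- qeq_grid(fx$system$lattice, dims = dims)
  q <- c(0.4, -0.7, 0.3)
  ds <- build_strain_derivative_densities(fx$system, pp$sigma, q, grid = g)
  e <- 1e-5
  comp <- list(xx = c(1, 1), yy = c(2, 2), zz = c(3, 3),
               xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  for (nm in names(comp)) {
    eps <- matrix(0, 3, 3); eps[comp[[nm]][1], comp[[nm]][2]] <- e
    sp <- strain_system(fx$system, eps); sm <- strain_system(fx$system, -eps)
    num <- (build_density(sp, pp$sigma, q, grid = qeq_grid(sp$lattice, dims = dims))$values -
            build_density(sm, pp$sigma, q, grid = qeq_grid(sm$lattice, dims = dims))$values) / (2 * e)
    expect_lt(max(abs(num - ds[[nm]]$values)), 1e-6 * max(1, max(abs(ds[[nm]]$values))))
  }
  # zero charges give six zero fields
  ds0 <- build_strain_derivative_densities(fx$system, pp$sigma, 0, grid = g)
  expect_true(all(vapply(ds0, function(f) all(f$values == 0), logical(1))))
})

test_that("off-diagonal strain fields vanish at a cubic-symmetric atom", {
  sys <- atomic_system(diag(3) * 12, "A", matrix(c(6, 6, 6), 1, 3), 0)
  g <- qeq_grid(sys$lattice, dims = c(24, 24, 24))
  ds <- build_strain_derivative_densities(sys, 1, 1, grid = g)
  # at the atom position (grid point 13,13,13) d = 0, so every field is 0
  expect_lt(abs(ds$xy$values[13, 13, 13]), 1e-14)
  # summed over the cell the off-diagonal fields cancel by symmetry
  expect_lt(abs(sum(ds$xy$values)), 1e-10)
  expect_lt(abs(sum(ds$xz$values)), 1e-10)
  expect_lt(abs(sum(ds$yz$values)), 1e-10)
})

test_that("probing a constant potential returns the constant", {
  sys <- atomic_system(diag(3) * 15, "A", matrix(c(2, 3, 4), 1, 3), 0)
  g <- qeq_grid(sys$lattice, dims = c(30, 30, 30))
  V <- mesh_field(g, array(3.7, c(30, 30, 30)))
  # exact up to the relative Gaussian truncation threshold
  expect_lt(abs(probe_potential_on_support(V, sys, 1) - 3.7), 1e-8)
})

test_that("probed pair potential matches the closed-form Gaussian integral", {
  # two Gaussians: probe of V[rho_j] on atom i equals the Ewald pair value,
  # which tends to erf(d/sqrt(2(si^2+sj^2)))/d in a large cell
  L <- 26
  sys <- atomic_system(diag(3) * L, c("a", "b"),
                       rbind(c(8, 13, 13), c(13, 13, 13)), 0)
  si <- 1.0; sj <- 0.8
  g <- qeq_grid(sys$lattice, spacing = sj / 3)
  rho_j <- build_density(sys, c(si, sj), c(0, 1), grid = g)
  V <- solve_poisson(rho_j)
  got <- probe_potential_on_support(V, sys, c(si, sj), atoms = 1L)
  ref <- ewald_pair_interaction(c(5, 0, 0), si, sj, sys$lattice)
  expect_lt(abs(got - ref), 1e-7)
  # and the periodic value is near the isolated-pair closed form
  iso <- erf_(5 / sqrt(2 * (si^2 + sj^2))) / 5
  expect_lt(abs(ref - iso), 3 / L)     # background (Madelung) offset ~ 2.84/L
})

test_that("probe result is invariant under full grid-vector translation", {
  sys <- atomic_system(diag(3) * 15, "A", matrix(c(2, 3, 4), 1, 3), 0)
  g <- qeq_grid(sys$lattice, dims = c(30, 30, 30))
  set.seed(2)
  V <- mesh_field(g, array(rnorm(27000), c(30, 30, 30)))
  a <- probe_potential_on_support(V, sys, 1)
  shift <- as.numeric(sys$lattice %*% c(1, 0, 0))  # one full lattice vector
  sys2 <- atomic_system(sys$lattice, "A", matrix(c(2, 3, 4) + shift, 1, 3), 0)
  b <- probe_potential_on_support(V, sys2, 1)
  expect_lt(abs(a - b), 1e-14 * max(1, abs(a)))
})

test_that("halving the grid spacing reduces the probe error", {
  L <- 22
  sys <- atomic_system(diag(3) * L, c("a", "b"),
                       rbind(c(7, 11, 11), c(11, 11, 11)), 0)
  si <- 1.0; sj <- 0.9
  ref <- ewald_pair_interaction(c(4, 0, 0), si, sj, sys$lattice)
  err <- sapply(c(1.0, 0.5), function(sp) {
    g <- qeq_grid(sys$lattice, spacing = sp)
    V <- solve_poisson(build_density(sys, c(si, sj), c(0, 1), grid = g))
    abs(probe_potential_on_support(V, sys, c(si, sj), atoms = 1L) - ref)
  })
  expect_lt(err[2], err[1])
})

test_that("oversized truncation radius errors unless multi-image is enabled", {
  sys <- atomic_system(diag(3) * 6, "A", matrix(3, 1, 3), 0)
  g <- qeq_grid(sys$lattice, dims = c(24, 24, 24))
  # sigma 2 -> r_cut ~ 13.6 bohr > half height 3
  expect_error(build_density(sys, 2, 1, grid = g, multi_image = FALSE),
               "multi-image")
  rho <- build_density(sys, 2, 1, grid = g, multi_image = TRUE)
  integral <- sum(rho$values) * g$volume / g$n_points
  expect_lt(abs(integral - 1), 1e-8)
})
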