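erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Shared fixtures and finite-difference utilities. Everything is generated
# in code with fixed seeds; no data files.

# small random neutral system with comfortable separations (fast grids)
small_fixture <- function(n = 6, seed = 11, cell = 8, min_distance = 1.5,
                          sigma_range = c(0.8, 1.2)) {
  random_test_system(n_atoms = n, n_elements = max(2L, n %/% 2L),
                     min_distance = min_distance, cell = cell,
                     sigma_range = sigma_range, seed = seed)
}

# apply a (not necessarily symmetric) strain eps to lattice and positions
strain_system <- function(sys, eps) {
  f <- diag(3) + eps
  atomic_system(f %*% sys$lattice, sys$species, t(f %*% t(sys$positions)),
                sys$total_charge)
}

# displace one atom along one Cartesian direction
displace_atom <- function(sys, i, m, h) {
  sys$positions[i, m] <- sys$positions[i, m] + h
  atomic_system(sys$lattice, sys$species, sys$positions, sys$total_charge)
}

# central finite-difference force matrix -(dE/dR) for an energy functional
# energy_fn(system) -> scalar
fd_forces <- function(sys, energy_fn, h = 1e-5) {
  n <- sys$n_atoms
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) for (m in 1:3) {
    ep <- energy_fn(displace_atom(sys, i, m, h))
    em <- energy_fn(displace_atom(sys, i, m, -h))
    out[i, m] <- -(ep - em) / (2 * h)
  }
  out
}

# central finite-difference dE/deps (9-component convention) for an energy
# functional of the strained system
fd_strain_gradient <- function(sys, energy_fn, e = 1e-5) {
  out <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    eps <- matrix(0, 3, 3); eps[a, b] <- e
    out[a, b] <- (energy_fn(strain_system(sys, eps)) -
                  energy_fn(strain_system(sys, -eps))) / (2 * e)
  }
  out
}

# mesh electrostatic energy of a system at fixed charges on a fixed-dims grid
mesh_energy_fn <- function(sigma, q, dims) {
  function(s) electrostatic_energy(
    build_density(s, sigma, q, grid = qeq_grid(s$lattice, dims = dims)))
}
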