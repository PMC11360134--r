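# Reciprocal-space electrostatics on the mesh.
#
# Normalization bookkeeping (used consistently below): with F = fft(values)
# the continuous Fourier coefficient of a cell-periodic field is
# rho~(G_k) = (Omega/N) F_k, and the inverse is
# values = Re(fft(X, inverse = TRUE)) / N for coefficients X on the FFT scale.
# Poisson's equation gives V~(G) = 4 pi rho~(G) / |G|^2 for G != 0; the G = 0
# coefficient is set to zero, which is the uniform neutralizing-background
# (jellium) convention for cells with net charge.

#' Solve Poisson's equation on the mesh
#'
#' Returns the periodic electrostatic potential V of a mesh charge density:
#' V~(G) = 4 pi rho~(G)/|G|^2 for G != 0 and V~(0) = 0, transformed back to
#' real space. For a charged cell the dropped G = 0 term amounts to adding a
#' uniform neutralizing background; the potential is then defined up to that
#' convention.
#'
#' @param rho a [mesh_field()] charge density (e/bohr^3).
#' @return a [mesh_field()] with the potential (hartree/e).
#' @export
solve_poisson <- function(rho) {
  stopifnot(inherits(rho, "mesh_field"))
  g <- rho$grid
  Fk <- field_fk(rho)
  # 1/n_points of the unnormalized inverse transform folded into the kernel
  V <- Re(stats::fft(Fk * (g$kernel / g$n_points), inverse = TRUE))
  mesh_field(g, V)
}

#' Electrostatic energy of a mesh density
#'
#' The reciprocal-space series
#' \deqn{E = \frac{2\pi}{\Omega} \sum_{G \ne 0} |\tilde\rho(G)|^2 / |G|^2,}
#' equal (by the discrete Plancherel identity) to the midpoint quadrature of
#' `0.5 * rho * V` in real space. Non-negative for every density with the
#' G = 0 term dropped.
#'
#' @param rho a [mesh_field()] charge density.
#' @return energy in hartree (scalar, >= 0).
#' @export
electrostatic_energy <- function(rho) {
  stopifnot(inherits(rho, "mesh_field"))
  g <- rho$grid
  Fk <- field_fk(rho)
  # (2 pi/Omega) sum |(Omega/N) F|^2 kernel/(4 pi) -> (Omega/(2 N^2)) sum |F|^2 kernel
  g$volume / (2 * g$n_points^2) * sum(Mod(Fk)^2 * g$kernel)
}

#' Cross (interaction) energy of two densities
#'
#' The reciprocal-space coupling integral `int rho_a V[rho_b] dr` =
#' (4 pi / Omega) sum_{G != 0} Re(conj(rho_a~) rho_b~)/|G|^2. Symmetric in
#' its arguments; `cross_energy(rho, rho) == 2 * electrostatic_energy(rho)`.
#'
#' @param rho_a,rho_b [mesh_field()]s on the same grid.
#' @return scalar (hartree).
#' @export
cross_energy <- function(rho_a, rho_b) {
  stopifnot(inherits(rho_a, "mesh_field"), inherits(rho_b, "mesh_field"))
  g <- rho_a$grid
  if (!identical(g$dims, rho_b$grid$dims) ||
      max(abs(g$h - rho_b$grid$h)) > 1e-12 * max(abs(g$h)))
    stop("cross_energy: fields live on different grids")
  Fa <- field_fk(rho_a); Fb <- field_fk(rho_b)
  g$volume / g$n_points^2 * sum(Re(Conj(Fa) * Fb) * g$kernel)
}

# strain derivative (9-component convention, symmetric 3x3 returned) of the
# cross energy int rho_a V[rho_b] dr, given both densities and both sets of
# six strain-derivative fields. Shared backend of reciprocal_stress and the
# adjoint lambda-Q strain term:
#   d/d eps_mn int rho_a V_b = (4 pi/Omega) sum_{G!=0} [
#     Re(a* b) (delta_mn + 2 G_m G_n/|G|^2)/|G|^2
#     + Re(Da_mn* b + a* Db_mn)/|G|^2 ]
cross_strain_derivative <- function(rho_a, strain_a, rho_b = NULL, strain_b = NULL) {
  g <- rho_a$grid
  same <- is.null(rho_b)
  if (same) { rho_b <- rho_a; strain_b <- strain_a }
  Fa <- field_fk(rho_a); Fb <- field_fk(rho_b)
  kern <- g$kernel                       # 4 pi/G^2, zero at G = 0
  base <- Re(Conj(Fa) * Fb) * kern
  Gcomp <- list(xx = g$Gx * g$Gx, yy = g$Gy * g$Gy, zz = g$Gz * g$Gz,
                xy = g$Gx * g$Gy, xz = g$Gx * g$Gz, yz = g$Gy * g$Gz)
  invG2 <- array(0, g$dims); invG2[-1] <- 1 / g$G2[-1]
  pref <- g$volume / g$n_points^2        # converts FFT-scale sums to physical
  out <- matrix(0, 3, 3)
  comp <- c("xx", "yy", "zz", "xy", "xz", "yz")
  ij <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (m in seq_along(comp)) {
    nm <- comp[m]
    kernel_term <- sum(base * (2 * Gcomp[[nm]] * invG2))
    if (m <= 3) kernel_term <- kernel_term + sum(base)
    Da <- field_fk(strain_a[[nm]])
    dens_term <- if (same) 2 * sum(Re(Conj(Da) * Fb) * kern)
                 else sum(Re(Conj(Da) * Fb + Conj(Fa) * field_fk(strain_b[[nm]])) * kern)
    v <- pref * (kernel_term + dens_term)
    out[ij[[m]][1], ij[[m]][2]] <- v
    out[ij[[m]][2], ij[[m]][1]] <- v
  }
  out
}

#' Reciprocal-space strain derivative of the electrostatic energy
#'
#' Returns the 3x3 symmetric tensor dE_elec/d eps_mn (hartree, *not* divided
#' by the volume), combining the kernel's own strain dependence (variation of
#' |G|^2 and Omega) with the density's strain derivative via the six
#' transformed fields of [build_strain_derivative_densities()].
#'
#' @param rho a [mesh_field()] charge density.
#' @param strain_rho named list of six strain-derivative fields (xx..yz).
#' @return 3x3 symmetric matrix, dE/d eps (9-component convention).
#' @export
reciprocal_stress <- function(rho, strain_rho) {
  stopifnot(inherits(rho, "mesh_field"), is.list(strain_rho))
  0.5 * cross_strain_derivative(rho, strain_rho)
}
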