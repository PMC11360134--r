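# Periodic mesh: grid construction, Gaussian density rasterization and
# potential probing. The mesh lives on the fractional-coordinate grid of the
# cell: point (i1,i2,i3) (0-based) is at h %*% c(i1/n1, i2/n2, i3/n3).

#' FFT-friendly grid size
#'
#' Smallest integer >= `n` whose prime factors are all 2, 3 or 5 (mixed-radix
#' FFT sizes), and at least 4.
#' @param n lower bound.
#' @return integer.
#' @export
good_fft_size <- function(n) {
  n <- max(4L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Periodic FFT grid for a cell
#'
#' Builds the reciprocal-space bookkeeping for a cell: grid dimensions, the
#' reciprocal vectors G = 2 pi t(solve(h)) %*% k for every FFT index, |G|^2
#' and the Coulomb kernel 4 pi / |G|^2 with the G = 0 entry set to zero
#' (uniform neutralizing-background convention for charged cells).
#'
#' The default spacing is min(sigma)/3 per axis, rounded up to FFT-friendly
#' dimensions; it is the single accuracy knob of the mesh electrostatics.
#'
#' @param lattice 3x3 lattice matrix (columns = lattice vectors, bohr).
#' @param spacing target grid spacing (bohr); used when `dims` is NULL.
#' @param dims optional explicit grid dimensions (length 3, each >= 4).
#' @return object of class `qeq_grid`.
#' @export
qeq_grid <- function(lattice, spacing = NULL, dims = NULL) {
  h <- matrix(as.numeric(lattice), 3, 3)
  vol <- det(h)
  if (vol <= 0) stop("qeq_grid: det(lattice) must be positive")
  hinv <- solve(h)
  # cell heights = distance between opposite cell faces along each axis
  heights <- 1 / sqrt(rowSums(hinv^2))
  if (is.null(dims)) {
    if (is.null(spacing) || spacing <= 0)
      stop("qeq_grid: give a positive spacing or explicit dims")
    dims <- vapply(heights / spacing, good_fft_size, integer(1))
  } else {
    dims <- as.integer(dims)
    if (length(dims) != 3L || any(dims < 4L))
      stop("qeq_grid: dims must be three integers >= 4")
  }
  kidx <- function(n) { k <- 0:(n - 1L); ifelse(k <= n %/% 2, k, k - n) }
  b <- 2 * pi * t(hinv)                       # reciprocal vectors: columns of b %*% k
  k1 <- kidx(dims[1]); k2 <- kidx(dims[2]); k3 <- kidx(dims[3])
  # G component arrays via outer sums (dims-shaped)
  G1 <- outer(outer(b[1, 1] * k1, b[1, 2] * k2, "+"), b[1, 3] * k3, "+")
  G2c <- outer(outer(b[2, 1] * k1, b[2, 2] * k2, "+"), b[2, 3] * k3, "+")
  G3 <- outer(outer(b[3, 1] * k1, b[3, 2] * k2, "+"), b[3, 3] * k3, "+")
  G2 <- G1^2 + G2c^2 + G3^2
  kernel <- array(0, dims)
  kernel[-1] <- 4 * pi / G2[-1]
  kernel[1] <- 0                               # G = 0 dropped (jellium background)
  structure(list(h = h, hinv = hinv, dims = dims, n_points = prod(dims),
                 volume = vol, heights = heights,
                 Gx = G1, Gy = G2c, Gz = G3, G2 = G2, kernel = kernel),
            class = "qeq_grid")
}

#' @export
print.qeq_grid <- function(x, ...) {
  cat(sprintf("qeq_grid: %d x %d x %d (%d points), cell volume %.4f bohr^3\n",
              x$dims[1], x$dims[2], x$dims[3], x$n_points, x$volume))
  invisible(x)
}

#' Real-space scalar field on a periodic grid
#'
#' Thin container pairing a [qeq_grid()] with real values on the grid.
#' Reciprocal coefficients (the FFT of the values) are computed lazily by
#' [field_fk()] and cached.
#'
#' @param grid a [qeq_grid()].
#' @param values numeric array with dimensions `grid$dims`.
#' @return object of class `mesh_field`.
#' @export
mesh_field <- function(grid, values) {
  stopifnot(inherits(grid, "qeq_grid"))
  if (!identical(dim(values), as.integer(grid$dims)))
    stop("mesh_field: values dimensions do not match the grid")
  e <- new.env(parent = emptyenv())
  e$grid <- grid; e$values <- values; e$fk <- NULL
  class(e) <- "mesh_field"
  e
}

#' Reciprocal coefficients of a mesh field
#'
#' Returns the raw FFT `fft(values)` of the field (unnormalized; the
#' continuous Fourier coefficient rho~(G_k) is `volume / n_points` times
#' entry k), cached on first use.
#' @param field a [mesh_field()].
#' @return complex array.
#' @export
field_fk <- function(field) {
  stopifnot(inherits(field, "mesh_field"))
  if (is.null(field$fk)) field$fk <- stats::fft(field$values)
  field$fk
}

#' @export
print.mesh_field <- function(x, ...) {
  cat(sprintf("mesh_field on %d x %d x %d grid, range [%.3e, %.3e]\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# truncation radius of a Gaussian of width sigma at relative threshold eps
trunc_radius <- function(sigma, eps_trunc) sigma * sqrt(-2 * log(eps_trunc))

# fractional halfwidths (3 x N) of the support boxes: rcut converted to a
# fractional offset along each axis via the cell heights
support_widths <- function(grid, rcut) {
  outer(1 / grid$heights, rcut)
}

check_system_grid <- function(system, grid) {
  if (max(abs(system$lattice - grid$h)) > 1e-10 * max(abs(grid$h)))
    stop("grid was built for a different lattice than this system")
}

#' Rasterize the Gaussian charge density onto the mesh
#'
#' Builds rho(r) = sum_i q_i sum_images (2 pi sigma_i^2)^(-3/2)
#' exp(-|r - r_i - image|^2 / (2 sigma_i^2)) on the grid, truncating each
#' Gaussian at `eps_trunc` (relative); all periodic images whose truncated
#' support intersects the cell are summed.
#'
#' @param system an [atomic_system()].
#' @param sigma per-atom Gaussian widths (bohr).
#' @param q per-atom charges (e).
#' @param grid a [qeq_grid()] built for the system's lattice; when NULL a
#'   default grid with spacing min(sigma)/3 is built.
#' @param eps_trunc relative truncation threshold of the Gaussian tails.
#' @param multi_image allow supports wider than the cell (images summed).
#'   When FALSE, a truncation radius exceeding half the smallest cell height
#'   is an error.
#' @return a [mesh_field()] with the charge density (e/bohr^3).
#' @export
build_density <- function(system, sigma, q, grid = NULL, eps_trunc = 1e-10,
                          multi_image = TRUE) {
  stopifnot(inherits(system, "atomic_system"))
  n <- system$n_atoms
  sigma <- rep_len(as.numeric(sigma), n)
  q <- rep_len(as.numeric(q), n)
  if (any(sigma <= 0)) stop("build_density: sigma must be positive")
  if (is.null(grid)) grid <- qeq_grid(system$lattice, spacing = min(sigma) / 3)
  check_system_grid(system, grid)
  frac <- frac_coords(system)
  pref <- q * (2 * pi * sigma^2)^(-1.5)
  rcut <- trunc_radius(sigma, eps_trunc)
  w <- support_widths(grid, rcut)
  vals <- cpp_spread(grid$dims, grid$h, frac, sigma, pref, w, rcut, multi_image)
  mesh_field(grid, vals)
}

#' Strain derivatives of the mesh charge density
#'
#' The six independent derivative fields d rho / d eps_mn at fixed fractional
#' grid coordinates, where the symmetric strain eps deforms both the lattice
#' and the atomic positions (r' = (1 + eps) r). For Gaussian densities the
#' derivative is
#' \deqn{\partial\rho/\partial\varepsilon_{\mu\nu}
#'       = -\sum_i q_i \sum_{img} \rho_i(d)\, d_\mu d_\nu / \sigma_i^2,}
#' with d the displacement from the (image of the) atom. Components are in
#' the 9-component convention (each eps_mn treated as independent); a
#' symmetric finite strain with off-diagonal e therefore changes the density
#' by 2 e times the xy field, etc.
#'
#' @inheritParams build_density
#' @return named list of six [mesh_field()]s: xx, yy, zz, xy, xz, yz.
#' @export
build_strain_derivative_densities <- function(system, sigma, q, grid = NULL,
                                              eps_trunc = 1e-10,
                                              multi_image = TRUE) {
  stopifnot(inherits(system, "atomic_system"))
  n <- system$n_atoms
  sigma <- rep_len(as.numeric(sigma), n)
  q <- rep_len(as.numeric(q), n)
  if (any(sigma <= 0)) stop("build_strain_derivative_densities: sigma must be positive")
  if (is.null(grid)) grid <- qeq_grid(system$lattice, spacing = min(sigma) / 3)
  check_system_grid(system, grid)
  frac <- frac_coords(system)
  pref <- q * (2 * pi * sigma^2)^(-1.5)
  rcut <- trunc_radius(sigma, eps_trunc)
  w <- support_widths(grid, rcut)
  vals <- cpp_spread_strain(grid$dims, grid$h, frac, sigma, pref, w, rcut, multi_image)
  comp <- c("xx", "yy", "zz", "xy", "xz", "yz")
  out <- lapply(seq_along(comp), function(m)
    mesh_field(grid, array(vals[, , , m], grid$dims)))
  names(out) <- comp
  out
}

#' Probe a potential field on atomic supports
#'
#' Midpoint-quadrature integrals `int V(r) rho_i(r) dr` over the truncated
#' local support of each requested atom (all periodic images included). With
#' V the potential of a charge density this is one component of the
#' matrix-free Coulomb product.
#'
#' @param V a [mesh_field()] holding the potential (hartree/e).
#' @param system an [atomic_system()] on the same lattice.
#' @param sigma per-atom Gaussian widths (bohr).
#' @param atoms integer indices of atoms to probe (default: all).
#' @inheritParams build_density
#' @return numeric vector, one value (hartree/e) per probed atom.
#' @export
probe_potential_on_support <- function(V, system, sigma, atoms = NULL,
                                       eps_trunc = 1e-10, multi_image = TRUE) {
  stopifnot(inherits(V, "mesh_field"), inherits(system, "atomic_system"))
  grid <- V$grid
  check_system_grid(system, grid)
  n <- system$n_atoms
  sigma <- rep_len(as.numeric(sigma), n)
  if (is.null(atoms)) atoms <- seq_len(n)
  frac <- frac_coords(system)[, atoms, drop = FALSE]
  sig <- sigma[atoms]
  rcut <- trunc_radius(sig, eps_trunc)
  w <- support_widths(grid, rcut)
  raw <- cpp_probe(V$values, grid$dims, grid$h, frac, sig, w, rcut, multi_image)
  wq <- grid$volume / grid$n_points
  raw * (2 * pi * sig^2)^(-1.5) * wq
}

#' Gradient probe: derivative of the support integral w.r.t. atom positions
#'
#' Returns `G_i = int V(r) d rho_i(r - r_i) / d r_i dr` for each atom (N x 3,
#' hartree/e/bohr), evaluated with the analytic Gaussian gradient on the same
#' truncated support as [probe_potential_on_support()], so it is the exact
#' derivative of that quadrature. The electrostatic force on atom i with
#' charge q_i in potential V is `-q_i * G_i`.
#'
#' @inheritParams probe_potential_on_support
#' @return numeric matrix N x 3.
#' @export
probe_potential_gradient <- function(V, system, sigma, atoms = NULL,
                                     eps_trunc = 1e-10, multi_image = TRUE) {
  stopifnot(inherits(V, "mesh_field"), inherits(system, "atomic_system"))
  grid <- V$grid
  check_system_grid(system, grid)
  n <- system$n_atoms
  sigma <- rep_len(as.numeric(sigma), n)
  if (is.null(atoms)) atoms <- seq_len(n)
  frac <- frac_coords(system)[, atoms, drop = FALSE]
  sig <- sigma[atoms]
  rcut <- trunc_radius(sig, eps_trunc)
  w <- support_widths(grid, rcut)
  raw <- cpp_probe_grad(V$values, grid$dims, grid$h, frac, sig, w, rcut, multi_image)
  wq <- grid$volume / grid$n_points
  raw * ((2 * pi * sig^2)^(-1.5) * wq)
}
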