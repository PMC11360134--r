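#' pmqeq: particle-mesh charge equilibration
#'
#' Charge equilibration (Qeq) assigns atomic partial charges by minimizing a
#' quadratic charge-dependent energy under a total-charge constraint. This
#' package evaluates the electrostatics of atom-centered Gaussian charge
#' densities on a periodic mesh (FFT Poisson solver) so that the Coulomb
#' matrix is never formed, solves the constrained minimization with a
#' projected conjugate-gradient method, and computes forces, macroscopic
#' stress and adjoint (lambda) total derivatives in quasi-linear time.
#'
#' All quantities are in Hartree atomic units: lengths in bohr, energies in
#' hartree, charges in units of the elementary charge e. No function performs
#' an implicit unit conversion; the only conversion in the package is the
#' optional Angstrom-to-bohr factor applied by [read_xyz()].
#'
#' @useDynLib pmqeq, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
#' @keywords internal
"_PACKAGE"

#' Conversion factor: one Angstrom in bohr
#'
#' Used only by the file readers/writers; all internal computation is in bohr.
#' @export
ANGSTROM_IN_BOHR <- 1.8897261254578281

#' Periodic atomic system
#'
#' Container for a periodic structure: lattice matrix, element labels,
#' Cartesian positions and total charge. Positions are stored as given
#' (possibly outside the cell); algorithms wrap them into fractional
#' coordinates only where needed, so user input and finite-difference
#' continuity are preserved.
#'
#' @param lattice 3x3 matrix whose *columns* are the lattice vectors
#'   h1, h2, h3 (bohr). `det(lattice)` must be positive.
#' @param species character vector of element labels, one per atom.
#' @param positions N x 3 matrix of Cartesian positions (bohr).
#' @param total_charge total charge Q_tot of the cell (e). Default 0.
#' @return object of class `atomic_system` with fields `lattice`, `species`,
#'   `positions`, `total_charge`, `n_atoms`, `volume`.
#' @export
atomic_system <- function(lattice, species, positions, total_charge = 0) {
  lattice <- matrix(as.numeric(lattice), 3, 3)
  positions <- matrix(as.numeric(positions), ncol = 3)
  species <- as.character(species)
  n <- length(species)
  if (n < 1L) stop("atomic_system: at least one atom is required")
  if (nrow(positions) != n)
    stop("atomic_system: positions must have one row per species entry")
  vol <- det(lattice)
  if (!is.finite(vol) || vol <= 0)
    stop("atomic_system: cell volume det(lattice) must be positive ",
         "(got ", format(vol), "); check lattice vector handedness")
  if (!is.finite(total_charge)) stop("atomic_system: total_charge must be finite")
  structure(list(lattice = lattice, species = species, positions = positions,
                 total_charge = as.numeric(total_charge), n_atoms = n,
                 volume = vol),
            class = "atomic_system")
}

#' @export
print.atomic_system <- function(x, ...) {
  cat(sprintf("atomic_system: %d atoms, %d species, volume %.4f bohr^3, Q_tot = %g e\n",
              x$n_atoms, length(unique(x$species)), x$volume, x$total_charge))
  invisible(x)
}

#' Per-element Qeq parameters
#'
#' Element table of electronegativity chi (hartree/e), hardness J
#' (hartree/e^2), Gaussian density width sigma (bohr, the standard deviation
#' of the normalized Gaussian) and energy offset E (hartree), with an
#' optional per-atom electronegativity override that takes precedence over
#' the element values when resolved against a system.
#'
#' The atomic charge density convention is
#' \deqn{\rho_i(r) = (2\pi\sigma_i^2)^{-3/2} \exp(-|r - r_i|^2 / (2\sigma_i^2)),}
#' normalized to 1. Note that parts of the Qeq literature use
#' \eqn{\exp(-r^2/\sigma^2)} widths; convert before building the table.
#'
#' @param elements character vector of element labels (unique).
#' @param chi electronegativities (hartree/e), recycled to length of elements.
#' @param hardness hardnesses J (hartree/e^2), all > 0.
#' @param sigma Gaussian widths (bohr), all > 0.
#' @param e_offset atomic reference energy offsets (hartree). Default 0.
#' @param chi_atoms optional per-atom electronegativity override vector; when
#'   present it replaces the element chi for every atom (length must match
#'   the system it is resolved against).
#' @return object of class `qeq_parameters`.
#' @export
qeq_parameters <- function(elements, chi, hardness, sigma, e_offset = 0,
                           chi_atoms = NULL) {
  elements <- as.character(elements)
  if (anyDuplicated(elements)) stop("qeq_parameters: duplicate element labels")
  k <- length(elements)
  chi <- rep_len(as.numeric(chi), k)
  hardness <- rep_len(as.numeric(hardness), k)
  sigma <- rep_len(as.numeric(sigma), k)
  e_offset <- rep_len(as.numeric(e_offset), k)
  if (any(!is.finite(hardness)) || any(hardness <= 0))
    stop("qeq_parameters: hardness J must be positive for every element")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("qeq_parameters: Gaussian width sigma must be positive for every element")
  structure(list(elements = elements, chi = chi, hardness = hardness,
                 sigma = sigma, e_offset = e_offset,
                 chi_atoms = if (is.null(chi_atoms)) NULL else as.numeric(chi_atoms)),
            class = "qeq_parameters")
}

#' @export
print.qeq_parameters <- function(x, ...) {
  cat(sprintf("qeq_parameters: %d elements%s\n", length(x$elements),
              if (is.null(x$chi_atoms)) "" else
                sprintf(", per-atom chi override (%d atoms)", length(x$chi_atoms))))
  df <- data.frame(element = x$elements, chi = x$chi, J = x$hardness,
                   sigma = x$sigma, E = x$e_offset)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Resolve per-atom Qeq parameters
#'
#' Expands the element table to per-atom vectors in atom order. A per-atom
#' chi override stored in the parameter set takes precedence over the element
#' electronegativities.
#'
#' @param system an [atomic_system()].
#' @param params a [qeq_parameters()] set covering every species present.
#' @return list with numeric vectors `chi`, `hardness`, `sigma`, `e_offset`
#'   of length `system$n_atoms`.
#' @export
resolve_parameters <- function(system, params) {
  stopifnot(inherits(system, "atomic_system"), inherits(params, "qeq_parameters"))
  idx <- match(system$species, params$elements)
  if (anyNA(idx)) {
    missing <- unique(system$species[is.na(idx)])
    stop("resolve_parameters: no Qeq parameters for species: ",
         paste(missing, collapse = ", "))
  }
  chi <- params$chi[idx]
  if (!is.null(params$chi_atoms)) {
    if (length(params$chi_atoms) != system$n_atoms)
      stop("resolve_parameters: per-atom chi override has length ",
           length(params$chi_atoms), " but system has ", system$n_atoms, " atoms")
    chi <- params$chi_atoms
  }
  list(chi = chi, hardness = params$hardness[idx], sigma = params$sigma[idx],
       e_offset = params$e_offset[idx])
}

# fractional coordinates of positions (unwrapped), columns = atoms
frac_coords <- function(system) {
  solve(system$lattice, t(system$positions))
}
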