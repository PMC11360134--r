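Package: pmqeq
Title: Particle-Mesh Charge Equilibration for Periodic Atomic Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quasi-linear-scaling charge equilibration (Qeq) for periodic
    atomic structures. Atomic Gaussian charge densities are spread onto a
    periodic mesh, Poisson's equation is solved in reciprocal space with fast
    Fourier transforms, and the constrained Qeq energy is minimized with a
    matrix-free, constraint-projected conjugate gradient method that never
    forms the Coulomb matrix. Provides electrostatic energies, forces, the
    macroscopic stress tensor, and adjoint (lambda) total derivatives for
    downstream energies that consume the equilibrated charges, together with
    a dense Ewald-summation reference solver used as an exactness oracle,
    deterministic synthetic test-system generators, extended-XYZ input and
    output, and a command-line interface. All quantities are in Hartree
    atomic units (bohr, hartree, elementary charge).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
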