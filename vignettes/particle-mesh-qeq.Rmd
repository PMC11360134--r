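---
title: "Particle-mesh charge equilibration: model, algorithms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-mesh charge equilibration: model, algorithms, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmqeq)
```

## The model

Charge equilibration (Qeq) assigns partial charges to atoms by minimizing a
quadratic charge-dependent energy under a total-charge constraint. The energy
is the electrostatic energy of a superposition of atom-centered charge
densities plus a per-atom Taylor expansion in the charge:

$$
E_\mathrm{Qeq}(\mathbf{Q}) \;=\; E_\mathrm{elec}(\mathbf{Q})
\;+\; \sum_i \Big( E_i + \chi_i q_i + \tfrac{1}{2} J_i q_i^2 \Big),
\qquad
E_\mathrm{elec} = \tfrac{1}{2}\!\int\!\rho(\mathbf r)\,V(\mathbf r)\,d\mathbf r ,
$$

where $\chi_i$ is the electronegativity (hartree/e), $J_i > 0$ the hardness
(hartree/e²), and $E_i$ an energy offset that shifts $E_\mathrm{Qeq}$ without
affecting the charges. The charge density is
$\rho(\mathbf r) = \sum_i q_i \rho_i(\mathbf r)$ with normalized Gaussians

$$
\rho_i(\mathbf r) = (2\pi\sigma_i^2)^{-3/2}
  \exp\!\big(-|\mathbf r-\mathbf r_i|^2/(2\sigma_i^2)\big),
$$

summed over all periodic images of the cell. **Unit and convention
discipline:** everything is in Hartree atomic units (bohr, hartree, charges in
e; $4\pi\varepsilon_0 = 1$), the Coulomb kernel in reciprocal space is
$4\pi/|\mathbf G|^2$, and $\sigma_i$ is the *standard deviation* of the
Gaussian. Parts of the Qeq literature write $\exp(-r^2/\sigma^2)$; convert
widths before building a parameter table.

Minimizing $E_\mathrm{Qeq}$ under $\sum_i q_i = Q_\mathrm{tot}$ gives the
stationarity conditions $\chi_i + J_i q_i + (\mathbf{AQ})_i = \lambda$ for all
$i$ — equalized effective electronegativities — where
$A_{ij} = \int \rho_i V[\rho_j]$ is the Coulomb matrix of the normalized
densities, symmetric positive definite. In matrix form,
$\mathbf M \mathbf Q = -\boldsymbol\chi + \lambda \mathbf 1$ with
$\mathbf M = \mathbf A + \operatorname{diag}(\mathbf J)$.

## The matrix-free solver

The conventional approach forms $\mathbf A$ explicitly (Ewald summation,
$N^2$ elements) and solves the bordered KKT system by dense factorization —
implemented here in `ewald_matrix()` / `direct_solve()` as the exactness
oracle. The package's main solver never forms $\mathbf A$: the product
$\mathbf A\mathbf Q$ is evaluated as

1. **spread** — rasterize $\rho(\mathbf Q)$ onto a periodic mesh over each
   atom's truncated local support (`build_density()`);
2. **Poisson solve** — $\tilde V(\mathbf G) = 4\pi\tilde\rho(\mathbf G)/|\mathbf G|^2$
   with FFTs, $\tilde V(0)=0$ (`solve_poisson()`);
3. **probe** — $(\mathbf{AQ})_i = \int V \rho_i$ by midpoint quadrature over
   each atom's support (`probe_potential_on_support()`).

Because the constraint manifold $\sum_i q_i = Q_\mathrm{tot}$ is a
hyperplane, a step of any length along a projected direction stays feasible,
so plain conjugate gradients applies: every residual and search direction is
projected by $g \mapsto g - \operatorname{mean}(g)$ and each iterate
satisfies the constraint to machine precision (`solve_qeq()`). Convergence is
measured by the max-norm of the *projected* residual — the raw residual
cannot vanish when $\lambda \neq 0$; $\lambda$ is recovered at the end as the
mean of the unprojected gradient. The iteration is deterministic, the
residual and energy histories are logged, and the default initial guess is
the uniform $q_i = Q_\mathrm{tot}/N$ (it satisfies the constraint exactly); a
user-supplied warm start (e.g. the previous MD step's charges) is supported
and measurably cuts iterations. An optional Jacobi preconditioner built from
the analytic diagonal $A_{ii} + J_i = 1/(\sigma_i\sqrt\pi) + J_i$ is
available but off by default — the plain CG is the reference behavior.

## Derivatives

For $E = E_\mathrm{Qeq}$ the charges are variational, so the total force
needs no adjoint machinery: `qeq_forces()` evaluates the fixed-charge
electrostatic force
$F_i = -q_i \int V \,\partial\rho_i/\partial\mathbf r_i\,d\mathbf r$ on the
same truncated support with the analytic Gaussian gradient, plus the explicit
position dependence of $\chi(\mathbf R)$ contracted with $\mathbf Q$ when a
$\chi$ model supplies it.

When a *downstream* energy consumes the equilibrated charges (as in
fourth-generation machine-learning potentials), the implicit dependence
$\mathbf Q(\mathbf R)$ enters. Instead of the $3N^2$ derivatives
$\partial q_j/\partial \mathbf r_i$, one extra projected-CG solve with the
same operator gives adjoint charges:
$\mathbf M \boldsymbol\lambda = -\partial E/\partial\mathbf Q$ with
$\sum_i\lambda_i = 0$ (`solve_lambda()`), after which

$$
\frac{dE}{d\mathbf r_i} = \frac{\partial E}{\partial \mathbf r_i}
 + \boldsymbol\lambda^T\frac{\partial\boldsymbol\chi}{\partial\mathbf r_i}
 + \lambda_i\!\int\! V^{\mathbf Q}\frac{\partial\rho_i}{\partial\mathbf r_i}
 + q_i\!\int\! V^{\boldsymbol\lambda}\frac{\partial\rho_i}{\partial\mathbf r_i},
$$

where $V^{\mathbf Q}$ and $V^{\boldsymbol\lambda}$ are the potentials of the
charge and adjoint densities. The $\lambda$–$Q$ Coulomb double sum thus
becomes two local-support probes — `total_forces()` performs $O(1)$ Poisson
solves per evaluation regardless of $N$. The $\chi$ Jacobian itself is *not*
computed here: electronegativity models (atomic neural networks, the bundled
`toy_chi_model()`) live outside and enter through a contraction hook
returning $\sum_j v_j \partial\chi_j/\partial\mathbf r_i$. Hardness is
treated as element-specific and position-independent throughout.

The macroscopic stress is the strain derivative of the energy per volume,
$\sigma_{\mu\nu} = \Omega^{-1} \partial E/\partial\varepsilon_{\mu\nu}$,
evaluated in reciprocal space (`reciprocal_stress()`, `total_stress()`): the
kernel contributes
$(\delta_{\mu\nu} + 2G_\mu G_\nu/|\mathbf G|^2)/|\mathbf G|^2$ terms from the
strain dependence of $|\mathbf G|^2$ and $\Omega$, and the density
contributes through its six strain-derivative fields
$\partial\rho/\partial\varepsilon_{\mu\nu} = -\sum_i q_i \rho_i(\mathbf d)\,
d_\mu d_\nu/\sigma_i^2$ (six extra FFTs; the tensor is symmetric). Strain
components use the 9-component convention (each $\varepsilon_{\mu\nu}$
independent); a symmetric finite strain with off-diagonal $e$ perturbs the
energy by $2e$ times the off-diagonal derivative, which the tests account
for. Only the macroscopic stress is provided; the microscopic (Maxwell-field)
stress tensor is rarely used for periodic bulk systems and is out of scope.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| grid spacing | $\min_i(\sigma_i)/3$ bohr per axis | sole accuracy knob of the mesh; dims rounded up to 2ᵃ3ᵇ5ᶜ FFT sizes |
| `eps_trunc` | $10^{-10}$ (relative) | Gaussian tail truncation; support radius $r_\mathrm{cut} = \sigma\sqrt{-2\ln\varepsilon}$ |
| `tol` | $10^{-8}$ hartree/e | max-norm of the projected CG residual |
| `max_iter` | 300 | CG iteration cap; exceeding it is a diagnostic error |
| Ewald `eta` | $\max(\max\sigma,\ h_\mathrm{min}/10)$ | splitting width of the dense oracle; results are `eta`-independent to ~1e-10 |

At the default spacing the mesh Coulomb matrix agrees with the Ewald oracle
to ~1e-11 per element on small systems, far below the 1e-6 equivalence
targets; halving the spacing reduces the residual mesh error further (tested
as a convergence property). Support truncation is the only other error
source; both are orders below the solver tolerance.

## Numerical choices

* **G = 0 and charged cells.** The $\mathbf G = 0$ Fourier term is dropped,
  which for $Q_\mathrm{tot} \neq 0$ is the uniform neutralizing-background
  (jellium) convention; energies of charged cells are defined only up to this
  convention. A practical consequence worth knowing: every pairwise
  interaction in a cubic cell of side $L$ carries a background offset
  $-2.837\ldots/L$ relative to the open-boundary value, which decays only as
  $1/L$ — the test suite therefore checks background-free combinations
  against closed forms, and absolute values against a direct Ewald-type
  lattice sum with the same convention.
* **Exact adjointness of spread and probe.** Both use the identical truncated
  support (a fractional-coordinate box clipped to the $r_\mathrm{cut}$
  sphere, identical arithmetic), so the mesh operator is symmetric to
  machine precision and the analytic force is the exact gradient of the
  discrete energy up to the truncation threshold — finite-difference force
  checks pass at 1e-10, far inside the 1e-6 target.
* **Direct Gaussian evaluation, no B-splines.** Charges are spread by
  evaluating the Gaussian at mesh points rather than smooth-PME cardinal
  B-spline interpolation: it is the simplest scheme consistent with the
  model density, and it keeps energies, forces and stress consistent at the
  quadrature level with one accuracy knob.
* **Positions are stored unwrapped**; wrapping happens in index arithmetic
  only. Supports wider than the cell sum all periodic images automatically
  (`multi_image = TRUE`); with `multi_image = FALSE` a truncation radius
  beyond half the smallest cell height is refused.
* **Triclinic cells** are supported through fractional coordinates; the
  orthogonal-cell fast path (separable Gaussian factors, sphere row windows)
  falls back to a general path for non-orthogonal lattices.
* **Degenerate inputs.** Non-positive hardness or width is rejected at
  construction; a non-positive-definite curvature $p^T M p \le 0$ inside CG
  aborts with a parameter diagnostic; non-convergence raises an error
  carrying the best iterate and residual history.

## The synthetic generators and what the tests show

`random_test_system()` reproduces the deliberately difficult stress test
used to validate the solver: 800 atoms of 60 elements placed uniformly at
random in a periodic cell with pairwise minimum-image distances ≥ 0.4 bohr,
hardnesses from $U(0.4, 1.4)$, electronegativities and initial charges from a
standard normal. The cell (cubic, 20 bohr) and the Gaussian widths
($U(0.5, 1.0)$ bohr) are this package's conventions — the original experiment
does not state them — so iteration counts are reproducible only in order of
magnitude (tens of iterations; the projected residual reaches $10^{-9}$
regardless). `rocksalt_fixture()` provides a cubic-symmetry fixture for
symmetry and stress checks, and `toy_chi_model()` is a smooth, cutoff,
pairwise stand-in for a learned $\chi(\mathbf R)$ that closes the loop for
end-to-end total-derivative tests.

These generators emulate the *electrostatic* difficulty of real systems
(close contacts, many species, random parameters) but not their chemistry:
there are no bonded interactions, no realistic parameter correlations, and
the toy $\chi$ model is not a trained network. Passing tests therefore
demonstrate the correctness of the electrostatics, the solver and the
derivative machinery — not the physical accuracy of any particular force
field built on top.

## Problem sizes and the scaling experiment

The test suite exercises 2–100-atom systems against the dense oracle
(agreement to ~1e-9 e on charges, bound 1e-6), finite-difference checks on
6-atom fixtures, and one 800-atom stress-test solve. The scaling experiment
compares a charge solve on a 100-atom random system at realistic
condensed-matter conditions (0.015 atoms/bohr³, minimum distance 1.8 bohr,
$\sigma \sim U(1.0, 1.5)$ bohr) with its 2×2×2 supercell (800 atoms, grid
dimensions exactly doubled) — the supercell protocol mirrors how such
benchmarks are usually constructed and keeps the CG iteration count nearly
size-independent, isolating the cost growth of the mesh machinery.

Measured on one CPU, the Gaussian spread and probe kernels grow by the ideal
factor ~8.2 for 8× atoms. The FFTs grow by ~13–20× at these sizes because
the transforms leave processor cache, so the full solve-time factor lands at
~12–13 — quasi-linear (a quadratic method would give 64), but the FFT
library's cache behavior, not the method, sets the constant. With
independently drawn systems instead of supercells the factor rises to
~14–18: the largest eigenvalue of the Coulomb operator grows with the
longest-wavelength $\mathbf G$ mode of the cell, so CG needs ~1.5–2× more
iterations at the larger size. That growth is a property of the physics of
charge equilibration, consistent with the expectation that iteration counts
increase slightly with system size.

## Known limitations

* Energies of charged cells depend on the neutralizing-background
  convention; compare only like with like.
* No smooth-PME interpolation means the grid must resolve the narrowest
  Gaussian (spacing $\le \sigma_\mathrm{min}/3$); point charges are not
  representable on the mesh (the dense Ewald oracle handles them in the
  $\sigma \to 0$ limit analytically, but the mesh solver requires
  $\sigma > 0$).
* The dense oracle is guarded to $N \le 5000$ by design.
* Subsystem (per-molecule) charge constraints, multilevel CG, MPI/GPU
  parallelism and trained electronegativity models are out of scope; the
  hooks (`dchi_dR`, `dchi_deps`) define the boundary where such models plug
  in.
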