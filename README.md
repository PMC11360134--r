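# pmqeq — particle-mesh charge equilibration for periodic systems

Charge equilibration (Qeq) assigns atomic partial charges in a periodic
structure by minimizing

```
E_Qeq(Q) = E_elec(Q) + Σᵢ ( Eᵢ + χᵢ qᵢ + ½ Jᵢ qᵢ² )    s.t.  Σᵢ qᵢ = Q_tot
```

where `E_elec = ½∫ρV` is the electrostatic energy of atom-centered Gaussian
charge densities, `χᵢ` is the electronegativity and `Jᵢ > 0` the hardness.
It is the charge model behind polarizable/reactive force fields and
fourth-generation machine-learning potentials, where long-range charge
transfer matters. Solved conventionally, Qeq needs the dense N×N Coulomb
matrix **A** (Ewald summation) and a cubic-scaling bordered solve — the
bottleneck for large systems.

`pmqeq` is for people who need those charges — and the forces and stresses
that come with them — at quasi-linear cost. It never forms **A**: the
product `A·Q` is evaluated by spreading the Gaussian density on a periodic
mesh, solving Poisson's equation in reciprocal space with FFTs
(`Ṽ(G) = 4π ρ̃(G)/|G|²`, `Ṽ(0) = 0`), and probing the potential back on each
atom's local support. The constrained minimization runs standard conjugate
gradients with every residual projected onto the zero-sum hyperplane, so
each iterate conserves the total charge to machine precision. One extra
projected-CG solve yields adjoint charges **λ** that turn the implicit
`∂Q/∂R` dependence of any downstream energy into quasi-linear force and
stress terms — no `3N²` charge derivatives. A dense Ewald reference solver
(`ewald_matrix()`, `direct_solve()`) is included as the exactness oracle.

All quantities are in Hartree atomic units: bohr, hartree, charges in e.
The Gaussian width σ is a standard deviation
(`ρᵢ ∝ exp(−r²/2σᵢ²)`, normalized to 1).

## Worked example

An 8-atom rocksalt cell (8 bohr) with two species of opposite
electronegativity:

```r
library(pmqeq)
fx  <- rocksalt_fixture(a = 8)
ctx <- qeq_context(fx$system, fx$params)
res <- solve_qeq(ctx, settings = qeq_solver_settings(tol = 1e-9))
print(res)
#> qeq_result: 8 charges, E_elec = 0.02535418 Ha, E_Qeq = -0.17020800 Ha,
#>   lambda = 8.007847e-03 Ha/e, 1 iterations, max|residual| = 1.061e-12

round(res$charges, 5)
#> [1]  0.21276  0.21276  0.21276  0.21276 -0.21276 -0.21276 -0.21276 -0.21276
```

The four low-χ atoms donate 0.213 e each to the four high-χ atoms (cubic
symmetry makes all magnitudes equal, and the high symmetry lets CG converge
in a single iteration); `lambda` is the equalized effective
electronegativity — at the solution `χᵢ + Jᵢqᵢ + (AQ)ᵢ` is the same
8.008e-3 hartree/e on every atom. Forces vanish by symmetry and the stress
is isotropic:

```r
max(abs(qeq_forces(ctx, res)))        # hartree/bohr
#> [1] 1.70821e-18
diag(qeq_stress(ctx, res$charges))    # hartree/bohr^3
#> [1] 4.361e-05 4.361e-05 4.361e-05
```

The iterative charges agree with the dense Ewald reference to 1e-12 e here:

```r
max(abs(res$charges - direct_solve(fx$system, fx$params)$charges))
#> [1] 1.092793e-12
```

For a downstream energy `E(Q, R)` that consumes the charges (e.g. a 4G-MLP
short-range term), compute `λ` and total derivatives:

```r
lam <- solve_lambda(ctx, dE_dQ)$lambda
F   <- total_forces(ctx, res$charges, lam, explicit_forces = ..., dchi_dR = ...)
S   <- total_stress(ctx, res$charges, lam, explicit_stress = ...)
```

`toy_chi_model()` provides a smooth position-dependent electronegativity
with the contraction hooks these functions expect.

## Command line

A thin wrapper over the same functions is installed at `exec/pmqeq`
(subcommands `charges`, `forces`, `stress`, `validate`, `fixture`), reading
extended-XYZ structures (mandatory `Lattice="..."` record; Ångström by
default, `--units bohr` or a `units=bohr` field for atomic units) and a
plain-text per-element parameter table:

```sh
Rscript inst/exec/pmqeq fixture  --n-atoms 20 --seed 1 --out demo
Rscript inst/exec/pmqeq charges  --structure demo.xyz --params demo.params --out run1
Rscript inst/exec/pmqeq validate --n-atoms 20 --seed 1
```

Every run logs grid dimensions, truncation threshold, tolerance, iteration
count and the residual history; results go to extended-XYZ (charge/force
columns) plus a JSON sidecar.

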