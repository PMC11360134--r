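# Deterministic generators for test systems: the 800-atom/60-element random
# stress test, simple rocksalt cells, and a smooth toy position-dependent
# electronegativity model that stands in for a learned chi(R) when testing
# total derivatives.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Random stress-test system
#'
#' Generates a deliberately difficult random periodic system: positions
#' uniform in the cell subject to a pairwise minimum-image distance floor,
#' elements assigned round-robin, element hardnesses from U(0.4, 1.4)
#' hartree/e^2, electronegativities and the initial charge guess from a
#' standard normal. Defaults reproduce the 800-atom, 60-element,
#' 0.4-bohr-minimum-distance setup used for solver stress testing; cell side
#' (20 bohr) and Gaussian widths (U(0.5, 1.0) bohr) are this package's
#' conventions and are configurable.
#'
#' @param n_atoms number of atoms. Default 800.
#' @param n_elements number of distinct elements. Default 60.
#' @param min_distance pairwise minimum-image distance floor (bohr).
#'   Default 0.4.
#' @param cell lattice matrix (3x3) or a single cubic cell side (bohr).
#'   Default 20.
#' @param hardness_range range of the uniform hardness draw. Default
#'   c(0.4, 1.4).
#' @param sigma_range range of the uniform Gaussian-width draw (bohr).
#'   Default c(0.5, 1.0).
#' @param total_charge cell charge Q_tot (e). Default 0.
#' @param seed RNG seed; the same seed reproduces the fixture bit for bit.
#' @param max_tries placement attempts per atom before giving up.
#' @return list: `system` ([atomic_system()]), `params`
#'   ([qeq_parameters()]), `q0` (initial charge guess summing to
#'   `total_charge`).
#' @export
random_test_system <- function(n_atoms = 800L, n_elements = 60L,
                               min_distance = 0.4, cell = 20,
                               hardness_range = c(0.4, 1.4),
                               sigma_range = c(0.5, 1.0),
                               total_charge = 0, seed = 1L,
                               max_tries = 1000L) {
  stopifnot(min_distance > 0, n_atoms >= 1, n_elements >= 1,
            n_elements <= n_atoms)
  h <- if (length(cell) == 1L) diag(3) * cell else matrix(cell, 3, 3)
  with_seed(seed, {
    pos <- matrix(NA_real_, n_atoms, 3)
    placed <- 0L
    md2 <- min_distance^2
    hinv <- solve(h)
    while (placed < n_atoms) {
      tries <- 0L
      repeat {
        cand <- as.numeric(h %*% runif(3))
        ok <- TRUE
        if (placed > 0L) {
          dfrac <- hinv %*% (t(pos[seq_len(placed), , drop = FALSE]) - cand)
          dfrac <- dfrac - round(dfrac)
          dc <- h %*% dfrac
          ok <- min(colSums(dc^2)) >= md2
        }
        if (ok) break
        tries <- tries + 1L
        if (tries >= max_tries)
          stop("random_test_system: could not place atom ", placed + 1L,
               " at min_distance ", min_distance, "; use a larger cell")
      }
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
    elements <- sprintf("El%02d", seq_len(n_elements))
    species <- elements[(seq_len(n_atoms) - 1L) %% n_elements + 1L]
    hardness <- runif(n_elements, hardness_range[1], hardness_range[2])
    sigma <- runif(n_elements, sigma_range[1], sigma_range[2])
    chi <- rnorm(n_elements)
    q0 <- rnorm(n_atoms)
    q0 <- q0 + (total_charge - sum(q0)) / n_atoms
    list(system = atomic_system(h, species, pos, total_charge),
         params = qeq_parameters(elements, chi, hardness, sigma),
         q0 = q0)
  })
}

#' Eight-atom rocksalt fixture
#'
#' Conventional cubic rocksalt cell with two species of opposite
#' electronegativity, used for symmetry and stress tests.
#'
#' @param a cubic lattice constant (bohr). Default 8.
#' @param sigma_cation,sigma_anion Gaussian widths (bohr).
#' @param chi_split electronegativity difference: the cation gets
#'   `-chi_split/2`, the anion `+chi_split/2`. Default 0.4.
#' @param hardness common hardness (hartree/e^2). Default 0.8.
#' @return list: `system`, `params`.
#' @export
rocksalt_fixture <- function(a = 8, sigma_cation = 0.9, sigma_anion = 1.1,
                             chi_split = 0.4, hardness = 0.8) {
  stopifnot(a > 0)
  frac <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5),
                c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5), c(0.5, 0.5, 0.5))
  species <- c(rep("Ct", 4), rep("An", 4))
  pos <- frac * a
  list(system = atomic_system(diag(3) * a, species, pos, 0),
       params = qeq_parameters(c("Ct", "An"), chi = c(-chi_split / 2, chi_split / 2),
                               hardness = hardness,
                               sigma = c(sigma_cation, sigma_anion)))
}

# smooth radial weight of the toy chi model and its derivative:
# g(r) = amp * exp(-r^2/w) * (1 - (r/rc)^2)^2 for r < rc, else 0
toy_chi_radial <- function(r, amp, w, rc) {
  inside <- r < rc
  g <- numeric(length(r)); dg <- numeric(length(r))
  ri <- r[inside]
  e <- exp(-ri^2 / w); c2 <- (1 - (ri / rc)^2)
  g[inside] <- amp * e * c2^2
  dg[inside] <- amp * e * (-2 * ri / w * c2^2 - 4 * ri / rc^2 * c2)
  list(g = g, dg = dg)
}

#' Toy position-dependent electronegativity model
#'
#' A smooth stand-in for a learned chi(R):
#' `chi_i = base_i + sum_{j != i} amp * exp(-r_ij^2/w) * (1 - (r_ij/rc)^2)^2`
#' over minimum-image neighbor distances, with a smooth cutoff at `rc`.
#' Returns the per-atom chi values plus contraction hooks for the position
#' and strain derivatives, the shapes consumed by [qeq_forces()],
#' [total_forces()] and [total_stress()].
#'
#' @param system an [atomic_system()].
#' @param base per-atom (or recycled) baseline electronegativities.
#' @param amp interaction amplitude (hartree/e). `amp = 0` gives constant
#'   chi and zero hooks.
#' @param w squared-distance decay scale (bohr^2).
#' @param rc cutoff radius (bohr); must be below half the smallest cell
#'   height.
#' @return list: `chi` (length N), `dchi_dR(v)` returning the N x 3 matrix
#'   with rows `sum_j v_j dchi_j/dr_i`, and `dchi_deps(v)` returning the
#'   3x3 matrix `sum_j v_j dchi_j/deps` (strain derivative, 9-component
#'   convention).
#' @export
toy_chi_model <- function(system, base = 0, amp = 0.05, w = 4, rc = NULL) {
  stopifnot(inherits(system, "atomic_system"))
  n <- system$n_atoms
  base <- rep_len(as.numeric(base), n)
  hinv <- solve(system$lattice)
  half_height <- min(1 / sqrt(rowSums(hinv^2))) / 2
  if (is.null(rc)) rc <- 0.95 * half_height
  if (rc >= half_height + 1e-12)
    stop("toy_chi_model: cutoff rc must be below half the smallest cell height")

  # minimum-image pair geometry (kept dense: toy model is for small fixtures)
  pair_geometry <- function() {
    pos <- system$positions
    dxf <- hinv %*% t(pos)
    d1 <- outer(dxf[1, ], dxf[1, ], "-"); d1 <- d1 - round(d1)
    d2 <- outer(dxf[2, ], dxf[2, ], "-"); d2 <- d2 - round(d2)
    d3 <- outer(dxf[3, ], dxf[3, ], "-"); d3 <- d3 - round(d3)
    h <- system$lattice
    dx <- h[1, 1] * d1 + h[1, 2] * d2 + h[1, 3] * d3
    dy <- h[2, 1] * d1 + h[2, 2] * d2 + h[2, 3] * d3
    dz <- h[3, 1] * d1 + h[3, 2] * d2 + h[3, 3] * d3
    r <- sqrt(dx^2 + dy^2 + dz^2)
    list(dx = dx, dy = dy, dz = dz, r = r)
  }
  geo <- pair_geometry()
  rad <- toy_chi_radial(geo$r, amp, w, rc)
  gmat <- matrix(rad$g, n, n); diag(gmat) <- 0
  dgmat <- matrix(rad$dg, n, n); diag(dgmat) <- 0
  chi <- base + rowSums(gmat)
  # unit vectors (zero on the diagonal)
  rsafe <- geo$r; diag(rsafe) <- 1
  ux <- geo$dx / rsafe; uy <- geo$dy / rsafe; uz <- geo$dz / rsafe

  # d chi_j / d r_i: for i != j the pair term g(r_ij) appears in both chi_i
  # and chi_j; d r_ij / d r_i = -u_ij with u = (r_j - r_i)/r ... displacement
  # here is d_ij = r_i - r_j (row i minus column j), so d r_ij/d r_i = +u_ij.
  dchi_dR <- function(v) {
    v <- rep_len(as.numeric(v), n)
    # sum_j v_j dchi_j/dr_i = v_i * sum_k dg(r_ik) u_ik + sum_j v_j dg(r_ij) (-u_ji->i)
    cx <- rowSums(dgmat * ux) * v + rowSums(sweep(dgmat * ux, 2, v, "*"))
    cy <- rowSums(dgmat * uy) * v + rowSums(sweep(dgmat * uy, 2, v, "*"))
    cz <- rowSums(dgmat * uz) * v + rowSums(sweep(dgmat * uz, 2, v, "*"))
    cbind(cx, cy, cz, deparse.level = 0)
  }
  # strain: r_ij -> |(1+eps) d_ij|, d r_ij/d eps_mn = d_m d_n / r
  dchi_deps <- function(v) {
    v <- rep_len(as.numeric(v), n)
    wmat <- (outer(v, rep(1, n)) + outer(rep(1, n), v)) * dgmat / rsafe
    diag(wmat) <- 0
    m <- matrix(0, 3, 3)
    d <- list(geo$dx, geo$dy, geo$dz)
    for (a in 1:3) for (b in a:3) {
      m[a, b] <- 0.5 * sum(wmat * d[[a]] * d[[b]])
      m[b, a] <- m[a, b]
    }
    m
  }
  list(chi = chi, dchi_dR = dchi_dR, dchi_deps = dchi_deps, rc = rc)
}
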