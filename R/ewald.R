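# Dense reference electrostatics: Gaussian-Gaussian Coulomb matrix by Ewald
# summation and direct solution of the bordered KKT system. This is the
# conventional direct method -- cubic-scaling, exact -- used as the oracle
# for every iterative particle-mesh result.
#
# The pair interaction of two normalized Gaussians of widths si, sj at
# separation r is erf(r / sqrt(2 (si^2 + sj^2))) / r in open boundaries. In
# a periodic cell with the G = 0 term dropped (same neutralizing-background
# convention as the mesh solver) the lattice sum is split with a screening
# width eta:
#   A_ij = (4 pi/Omega) sum_{0<|G|<Gcut} exp(-Gamma^2 G^2/2) cos(G.r)/G^2
#        + sum_{|r+L|<rcut} [erf(|r+L|/(sqrt2 gamma)) - erf(|r+L|/(sqrt2 Gamma))]/|r+L|
#        - 4 pi eta^2 / Omega,
# gamma^2 = si^2 + sj^2, Gamma^2 = gamma^2 + 2 eta^2. The reciprocal factor
# is separable per atom, exp(-(si^2+eta^2)G^2/2) exp(-(sj^2+eta^2)G^2/2), so
# the whole reciprocal block is one rank-nG matrix product.

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# screened pair kernel values with the r -> 0 limit handled
erf_over_r <- function(r, width) {
  out <- numeric(length(r))
  z <- r == 0
  out[z] <- sqrt(2 / pi) / width[z]
  out[!z] <- erf_(r[!z] / (sqrt(2) * width[!z])) / r[!z]
  out
}

ewald_cutoffs <- function(lattice, sigma, eta, eps) {
  hinv <- solve(lattice)
  heights <- 1 / sqrt(rowSums(hinv^2))
  c0 <- sqrt(2 * log(1 / eps))
  gamma_max <- sqrt(2 * max(sigma)^2 + 2 * eta^2)
  gamma_min <- sqrt(2 * min(sigma)^2 + 2 * eta^2)
  rcut <- c0 * gamma_max
  gcut <- c0 / gamma_min
  nimg <- pmax(0L, as.integer(ceiling(rcut / heights)))
  klim <- as.integer(ceiling(gcut * sqrt(colSums(lattice^2)) / (2 * pi)))
  list(rcut = rcut, gcut = gcut, nimg = nimg, klim = klim, heights = heights)
}

#' Dense Coulomb matrix by Ewald summation
#'
#' Builds the full N x N matrix A of pairwise interactions of the normalized
#' periodic Gaussian charge densities, including the diagonal self terms
#' `1/(sigma_i sqrt(pi))` plus image contributions, under the dropped-G=0
#' (neutralizing background) convention that matches the mesh solver. The
#' result is independent of the splitting parameter `eta` to within `eps`.
#'
#' Intended as the exactness oracle for small systems; refuses N > 5000.
#'
#' @param system an [atomic_system()].
#' @param sigma per-atom Gaussian widths (bohr).
#' @param eta Ewald splitting width (bohr); default
#'   `max(max(sigma), min cell height / 10)`.
#' @param eps target accuracy of the lattice sums. Default 1e-12.
#' @return N x N symmetric matrix (hartree/e^2).
#' @export
ewald_matrix <- function(system, sigma, eta = NULL, eps = 1e-12) {
  stopifnot(inherits(system, "atomic_system"))
  n <- system$n_atoms
  if (n > 5000) stop("ewald_matrix: dense oracle limited to N <= 5000 atoms")
  sigma <- rep_len(as.numeric(sigma), n)
  h <- system$lattice
  vol <- system$volume
  if (is.null(eta)) {
    hinv <- solve(h)
    eta <- max(max(sigma), min(1 / sqrt(rowSums(hinv^2))) / 10)
  }
  ct <- ewald_cutoffs(h, sigma, eta, eps)

  pos <- system$positions
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dz <- outer(pos[, 3], pos[, 3], "-")
  gam <- sqrt(outer(sigma^2, sigma^2, "+"))
  Gam <- sqrt(gam^2 + 2 * eta^2)

  # real-space part: sum over lattice images of the difference kernel
  A <- matrix(0, n, n)
  for (i1 in -ct$nimg[1]:ct$nimg[1])
    for (i2 in -ct$nimg[2]:ct$nimg[2])
      for (i3 in -ct$nimg[3]:ct$nimg[3]) {
        L <- h %*% c(i1, i2, i3)
        r <- sqrt((dx + L[1])^2 + (dy + L[2])^2 + (dz + L[3])^2)
        A <- A + erf_over_r(r, gam) - erf_over_r(r, Gam)
      }

  # reciprocal part, separable over atoms: t_i(G) = exp(i G.r_i - (s_i^2+eta^2) G^2/2)
  b <- 2 * pi * t(solve(h))
  kl <- ct$klim
  ks <- as.matrix(expand.grid(k1 = -kl[1]:kl[1], k2 = -kl[2]:kl[2], k3 = -kl[3]:kl[3]))
  G <- ks %*% t(b)                                  # nK x 3
  G2 <- rowSums(G^2)
  keep <- G2 > 1e-14 & G2 <= ct$gcut^2
  G <- G[keep, , drop = FALSE]; G2 <- G2[keep]
  wts <- 4 * pi / (vol * G2)
  sig2e <- sigma^2 + eta^2
  chunk <- max(1L, as.integer(2e6 / n))
  for (s in split(seq_along(G2), ceiling(seq_along(G2) / chunk))) {
    ph <- pos %*% t(G[s, , drop = FALSE])           # n x nk phases
    damp <- exp(-0.5 * outer(sig2e, G2[s]))
    Tm <- complex(modulus = 1, argument = ph) * damp
    Tm <- Tm * rep(sqrt(wts[s]), each = n)
    A <- A + Re(Tm %*% Conj(t(Tm)))
  }

  A - 4 * pi * eta^2 / vol
}

#' Single Ewald pair interaction
#'
#' The periodic Coulomb interaction A_ij of two normalized Gaussians of
#' widths `sigma_i`, `sigma_j` whose centers differ by the displacement
#' vector `d` (bohr), with all periodic images summed. `d = c(0,0,0)` with
#' `sigma_i == sigma_j` gives the diagonal self term.
#'
#' @param d Cartesian displacement r_j - r_i (length-3, bohr).
#' @param sigma_i,sigma_j Gaussian widths (bohr).
#' @param lattice 3x3 lattice matrix (columns = lattice vectors).
#' @param eta,eps see [ewald_matrix()].
#' @return scalar (hartree/e^2).
#' @export
ewald_pair_interaction <- function(d, sigma_i, sigma_j, lattice, eta = NULL,
                                   eps = 1e-12) {
  sys2 <- atomic_system(lattice, c("a", "b"),
                        rbind(c(0, 0, 0), as.numeric(d)), 0)
  A <- ewald_matrix(sys2, c(sigma_i, sigma_j), eta = eta, eps = eps)
  A[1, 2]
}

#' Direct (dense) charge equilibration
#'
#' The conventional cubic-scaling reference: builds the Ewald Coulomb matrix,
#' forms the bordered KKT system
#' `rbind(cbind(M, 1), c(1, 0)) %*% c(Q, nu) = c(-chi, Q_tot)` with
#' `M = A + diag(J)`, and solves it by dense factorization.
#'
#' @param system an [atomic_system()].
#' @param params a [qeq_parameters()] set.
#' @param eta,eps Ewald controls, see [ewald_matrix()].
#' @return object of class `qeq_result` (iterations = 0; residual is that of
#'   the bordered linear system).
#' @export
direct_solve <- function(system, params, eta = NULL, eps = 1e-12) {
  pp <- resolve_parameters(system, params)
  n <- system$n_atoms
  A <- ewald_matrix(system, pp$sigma, eta = eta, eps = eps)
  M <- A + diag(pp$hardness, n)
  B <- rbind(cbind(M, 1), c(rep(1, n), 0))
  rhs <- c(-pp$chi, system$total_charge)
  sol <- tryCatch(solve(B, rhs),
                  error = function(e) stop("direct_solve: bordered KKT system is singular ",
                                           "(degenerate parameters): ", conditionMessage(e)))
  q <- sol[1:n]
  e_elec <- 0.5 * sum(q * (A %*% q))
  e_qeq <- e_elec + sum(pp$e_offset + pp$chi * q + 0.5 * pp$hardness * q^2)
  res <- max(abs(B %*% sol - rhs))
  structure(list(charges = q, e_elec = e_elec, e_qeq = e_qeq,
                 lambda = -sol[n + 1], iterations = 0L,
                 residual_maxnorm = res, residual_history = res,
                 energy_history = e_qeq, converged = TRUE,
                 coulomb_matrix = A),
            class = "qeq_result")
}

#' Dense adjoint (lambda) solve
#'
#' Reference bordered solve of the adjoint system
#' `M lambda = -dE_dQ + nu 1` with `sum(lambda) = 0`, the dense counterpart
#' of [solve_lambda()].
#'
#' @param system an [atomic_system()].
#' @param params a [qeq_parameters()] set.
#' @param dE_dQ derivative of the downstream energy w.r.t. the charges
#'   (length N, hartree/e).
#' @param eta,eps Ewald controls.
#' @return numeric vector lambda (e), summing to zero.
#' @export
dense_lambda_solve <- function(system, params, dE_dQ, eta = NULL, eps = 1e-12) {
  pp <- resolve_parameters(system, params)
  n <- system$n_atoms
  if (length(dE_dQ) != n) stop("dense_lambda_solve: dE_dQ must have length N")
  A <- ewald_matrix(system, pp$sigma, eta = eta, eps = eps)
  M <- A + diag(pp$hardness, n)
  B <- rbind(cbind(M, 1), c(rep(1, n), 0))
  sol <- solve(B, c(-as.numeric(dE_dQ), 0))
  sol[1:n]
}
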