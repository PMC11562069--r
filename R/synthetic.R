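#' Harmonic spring topology
#'
#' Describes a network of pairwise harmonic springs,
#' E = sum over pairs of k/2 (|r_a - r_b| - r0)^2, used by the synthetic
#' fixture generators. Optionally a set of frozen atoms whose Hessian rows
#' and columns are zeroed, emulating genuinely immobile sites.
#'
#' @param pairs m x 2 integer matrix of bonded atom indices (1-based).
#' @param force_constants length-m vector, Hartree/Bohr^2, all > 0.
#' @param equilibrium_lengths length-m vector, Bohr.
#' @param frozen_atoms optional integer vector of immobilized atoms.
#' @return An object of class `phva_springs`.
#' @export
spring_topology <- function(pairs, force_constants, equilibrium_lengths,
                            frozen_atoms = integer(0)) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  m <- nrow(pairs)
  if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs are not allowed", call. = FALSE)
  force_constants <- rep_len(force_constants, m)
  equilibrium_lengths <- rep_len(equilibrium_lengths, m)
  if (any(force_constants <= 0)) stop("force constants must be > 0", call. = FALSE)
  structure(
    list(pairs = pairs, force_constants = force_constants,
         equilibrium_lengths = equilibrium_lengths,
         frozen_atoms = as.integer(frozen_atoms)),
    class = "phva_springs"
  )
}

#' Harmonic spring energy of a geometry
#'
#' The potential energy of the spring network at the system's current
#' coordinates, in Hartree. Exposed so finite-difference checks of the
#' analytic Hessian can be written against the same energy function.
#'
#' @param system a `phva_system`.
#' @param topology a `phva_springs`.
#' @param coords optional override coordinates in Bohr (N x 3).
#' @return Energy in Hartree.
#' @export
spring_energy <- function(system, topology, coords = NULL) {
  r <- coords %||% system$coords
  e <- 0
  for (p in seq_len(nrow(topology$pairs))) {
    a <- topology$pairs[p, 1]; b <- topology$pairs[p, 2]
    d <- sqrt(sum((r[a, ] - r[b, ])^2))
    e <- e + 0.5 * topology$force_constants[p] * (d - topology$equilibrium_lengths[p])^2
  }
  e
}

#' Analytic Hessian of a harmonic spring network
#'
#' Exact second derivatives of the spring energy at the system's
#' geometry. For a pair with unit bond vector u at separation r the 3 x 3
#' pair block is k (u u^T) + k (1 - r0/r) (I - u u^T); at equilibrium the
#' transverse part vanishes. With no frozen atoms the result is
#' translation-invariant (atom-block row sums vanish) by construction.
#'
#' @param system a `phva_system`.
#' @param topology a `phva_springs`.
#' @return A `phva_hessian` with scope "full" over the system's atoms.
#' @export
spring_hessian <- function(system, topology) {
  n <- n_atoms(system)
  H <- matrix(0, 3 * n, 3 * n)
  r <- system$coords
  for (p in seq_len(nrow(topology$pairs))) {
    a <- topology$pairs[p, 1]; b <- topology$pairs[p, 2]
    k <- topology$force_constants[p]
    r0 <- topology$equilibrium_lengths[p]
    d <- r[a, ] - r[b, ]
    rr <- sqrt(sum(d^2))
    if (rr < 1e-12) stop("bonded atoms ", a, " and ", b, " coincide", call. = FALSE)
    u <- d / rr
    B <- k * tcrossprod(u) + k * (1 - r0 / rr) * (diag(3) - tcrossprod(u))
    ia <- (3 * (a - 1) + 1):(3 * a)
    ib <- (3 * (b - 1) + 1):(3 * b)
    H[ia, ia] <- H[ia, ia] + B
    H[ib, ib] <- H[ib, ib] + B
    H[ia, ib] <- H[ia, ib] - B
    H[ib, ia] <- H[ib, ia] - B
  }
  for (fa in topology$frozen_atoms) {
    idx <- (3 * (fa - 1) + 1):(3 * fa)
    H[idx, ] <- 0
    H[, idx] <- 0
  }
  hessian_matrix(H, scope = "full")
}

#' Build a caged-solute fixture
#'
#' Emulates the situation partial Hessian vibrational analysis is designed
#' for: a mobile core (solute) surrounded by environment sites (solvent
#' cage). Cage atoms are explicit atoms joined to the core by springs, and
#' their "immobility" is realized exactly the way the approximation under
#' study realizes it -- by keeping only the core-core block of the full
#' Hessian. Each core atom is tethered to its nearest cage point with
#' force constant `coupling_k`; at `coupling_k = 0` no tethers exist and
#' the core block equals the isolated-core Hessian.
#'
#' @param core_system `phva_system` of the core (all atoms tagged core).
#' @param core_topology `phva_springs` over the core atoms.
#' @param cage_points ncage x 3 matrix of cage coordinates, Angstrom.
#' @param coupling_k tether force constant, Hartree/Bohr^2, >= 0.
#' @param cage_element element symbol for the cage atoms (default "Ar").
#' @return A list: `system` (core + cage, partitioned), `full`
#'   (`phva_hessian`, full scope), `partial` (core block), and `topology`
#'   (combined spring network).
#' @export
build_caged_solute <- function(core_system, core_topology, cage_points,
                               coupling_k, cage_element = "Ar") {
  stopifnot(coupling_k >= 0)
  cage_points <- as.matrix(cage_points)
  ncage <- nrow(cage_points)
  if (coupling_k > 0 && ncage == 0) {
    stop("coupling_k > 0 requires at least one cage point", call. = FALSE)
  }
  nc <- n_atoms(core_system)
  combined <- molecular_system(
    atoms = c(core_system$atoms, rep(cage_element, ncage)),
    coords = rbind(coordinates(core_system), cage_points),
    partition = c(rep("core", nc), rep("environment", ncage)),
    masses = c(core_system$masses, atomic_mass(rep(cage_element, ncage)))
  )
  pairs <- core_topology$pairs
  ks <- core_topology$force_constants
  r0s <- core_topology$equilibrium_lengths
  if (coupling_k > 0) {
    cage_bohr <- angstrom_to_bohr(cage_points)
    for (a in seq_len(nc)) {
      d2 <- rowSums(sweep(cage_bohr, 2, core_system$coords[a, ])^2)
      j <- which.min(d2)
      pairs <- rbind(pairs, c(a, nc + j))
      ks <- c(ks, coupling_k)
      r0s <- c(r0s, sqrt(d2[j]))      # tether at its current length
    }
  }
  topo <- spring_topology(pairs, ks, r0s)
  full <- spring_hessian(combined, topo)
  partial <- extract_partial(full, combined)
  list(system = combined, full = full, partial = partial, topology = topo)
}

#' Dipole gradient of a rigid point-charge model
#'
#' For mu = sum over atoms of q_a r_a, the derivative of dipole component
#' a with respect to coordinate b of atom alpha is q_alpha if a == b and
#' zero otherwise: each atom contributes a q * identity 3 x 3 block.
#'
#' @param system a `phva_system`.
#' @param charges per-atom charges, e.
#' @return A `phva_gradient` of kind "dipole", full scope.
#' @export
point_charge_dipole_gradient <- function(system, charges) {
  n <- n_atoms(system)
  stopifnot(length(charges) == n, all(is.finite(charges)))
  G <- matrix(0, 3 * n, 3)
  for (a in seq_len(n)) {
    G[(3 * (a - 1) + 1):(3 * a), ] <- diag(3) * charges[a]
  }
  property_gradient(G, kind = "dipole", scope = "full")
}

# run expr with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

#' Random reproducible test fixture
#'
#' Generates a complete synthetic fixture: a random nonlinear core of
#' light atoms inside a shell of environment atoms, a full Cartesian
#' Hessian that is positive semidefinite with an exact translation/rotation
#' null space (built as S P A A^T P S in mass-weighted coordinates, with P
#' the TR projector of the whole system and S the mass-weighting
#' un-scaling), its core block, a point-charge dipole gradient, and a
#' random polarizability gradient. Identical seeds give bit-identical
#' fixtures; the caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param n_core number of core atoms (>= 2).
#' @param n_env number of environment atoms (>= 1).
#' @param scale amplitude of the random stiffness factor A (controls the
#'   wavenumber range of the fixture).
#' @return A list with `system`, `full`, `partial` (hessians), `dipole`,
#'   `polarizability` (gradients), `charges`, `seed`.
#' @export
random_system <- function(seed, n_core = 4, n_env = 6, scale = 0.05) {
  stopifnot(n_core >= 1, n_env >= 1)
  with_private_seed(seed, {
    n <- n_core + n_env
    core_xyz <- matrix(stats::rnorm(3 * n_core, sd = 0.9), ncol = 3)
    u <- matrix(stats::rnorm(3 * n_env), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    env_xyz <- u * (3.5 + stats::runif(n_env, 0, 1.5))
    elements <- c(sample(c("C", "N", "O", "H"), n_core, replace = TRUE),
                  rep("Ar", n_env))
    system <- molecular_system(
      atoms = elements,
      coords = rbind(core_xyz, env_xyz),
      partition = c(rep("core", n_core), rep("environment", n_env))
    )

    basis <- build_tr_basis(system, seq_len(n))
    P <- diag(3 * n) - tcrossprod(basis$vectors)
    A <- matrix(stats::rnorm((3 * n)^2, sd = scale), 3 * n, 3 * n)
    h_mw <- P %*% tcrossprod(A) %*% P
    h_mw <- (h_mw + t(h_mw)) / 2
    s <- sqrt(rep(system$masses, each = 3))
    H <- h_mw * outer(s, s)                 # undo mass-weighting exactly
    full <- hessian_matrix(H, scope = "full")

    charges <- stats::runif(n, -0.5, 0.5)
    charges <- charges - mean(charges)      # neutral system
    dipole <- point_charge_dipole_gradient(system, charges)
    alpha <- property_gradient(
      matrix(stats::rnorm(3 * n * 6, sd = 0.1), ncol = 6),
      kind = "polarizability", scope = "full"
    )

    list(
      system = system,
      full = full,
      partial = extract_partial(full, system),
      dipole = dipole,
      polarizability = alpha,
      charges = charges,
      seed = seed
    )
  })
}
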