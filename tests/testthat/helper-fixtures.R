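# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

# bent water-like triatomic (angles/lengths in Angstrom), all core
water_system <- function() {
  molecular_system(
    c("O", "H", "H"),
    rbind(c(0, 0, 0.1173),
          c(0, 0.7572, -0.4692),
          c(0, -0.7572, -0.4692))
  )
}

water_topology <- function(sys) {
  r12 <- sqrt(sum((sys$coords[1, ] - sys$coords[2, ])^2))
  r13 <- sqrt(sum((sys$coords[1, ] - sys$coords[3, ])^2))
  r23 <- sqrt(sum((sys$coords[2, ] - sys$coords[3, ])^2))
  spring_topology(rbind(c(1, 2), c(1, 3), c(2, 3)),
                  c(0.35, 0.35, 0.08), c(r12, r13, r23))
}

# homonuclear diatomic on the z axis
diatomic_system <- function(sep = 0.74, element = "H") {
  molecular_system(c(element, element),
                   rbind(c(0, 0, 0), c(0, 0, sep)))
}

diatomic_topology <- function(sys, k = 0.37) {
  r0 <- sqrt(sum((sys$coords[1, ] - sys$coords[2, ])^2))
  spring_topology(rbind(c(1, 2)), k, r0)
}

# collinear triatomic chain along x
linear_chain_system <- function() {
  molecular_system(c("O", "C", "O"),
                   rbind(c(-1.16, 0, 0), c(0, 0, 0), c(1.16, 0, 0)))
}

linear_chain_topology <- function(sys, k = 0.6) {
  r0 <- sqrt(sum((sys$coords[1, ] - sys$coords[2, ])^2))
  spring_topology(rbind(c(1, 2), c(2, 3)), k, r0)
}

# caged water: bent core + cage shell, tunable tether stiffness
caged_water <- function(coupling_k = 0.02, n_cage = 8, seed = 42) {
  sys <- water_system()
  topo <- water_topology(sys)
  set.seed(seed)
  u <- matrix(rnorm(3 * n_cage), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  cage <- u * 3.0
  build_caged_solute(sys, topo, cage, coupling_k)
}

# decoupled core/environment fixture with strictly distinct eigenvalues in
# each block: eigenvectors unique up to sign, so the comparison pipeline
# has an exact expected answer. Dipole gradient is nonzero on core rows
# only.
decoupled_fixture <- function(seed = 1, n_core = 3, n_env = 4) {
  set.seed(seed)
  n <- n_core + n_env
  sys <- molecular_system(
    atoms = c(rep("C", n_core), rep("Ar", n_env)),
    coords = matrix(rnorm(3 * n, sd = 2), ncol = 3),
    partition = c(rep("core", n_core), rep("environment", n_env))
  )
  rand_block <- function(dim, lo, hi) {
    Q <- qr.Q(qr(matrix(rnorm(dim^2), dim, dim)))
    lam <- seq(lo, hi, length.out = dim)
    h_mw <- Q %*% diag(lam) %*% t(Q)
    (h_mw + t(h_mw)) / 2
  }
  dc <- 3 * n_core
  de <- 3 * n_env
  h_mw <- matrix(0, 3 * n, 3 * n)
  h_mw[1:dc, 1:dc] <- rand_block(dc, 0.01, 0.2)
  h_mw[(dc + 1):(3 * n), (dc + 1):(3 * n)] <- rand_block(de, 0.27, 0.9)
  s <- sqrt(rep(sys$masses, each = 3))
  H <- hessian_matrix(h_mw * outer(s, s), scope = "full")
  G <- matrix(0, 3 * n, 3)
  G[1:dc, ] <- rnorm(dc * 3, sd = 0.3)
  A <- matrix(0, 3 * n, 6)
  A[1:dc, ] <- rnorm(dc * 6, sd = 0.1)
  list(system = sys,
       full = H,
       dipole = property_gradient(G, "dipole", "full"),
       polarizability = property_gradient(A, "polarizability", "full"))
}

# central-finite-difference Hessian of the spring energy (independent of
# the analytic derivatives in spring_hessian)
fd_spring_hessian <- function(sys, topo, step = 1e-4) {
  n <- n_atoms(sys)
  d <- 3 * n
  H <- matrix(0, d, d)
  x0 <- as.vector(t(sys$coords))
  energy_at <- function(x) {
    spring_energy(sys, topo, coords = matrix(x, ncol = 3, byrow = TRUE))
  }
  for (i in seq_len(d)) {
    for (j in i:d) {
      xpp <- x0; xpm <- x0; xmp <- x0; xmm <- x0
      xpp[i] <- xpp[i] + step; xpp[j] <- xpp[j] + step
      xpm[i] <- xpm[i] + step; xpm[j] <- xpm[j] - step
      xmp[i] <- xmp[i] - step; xmp[j] <- xmp[j] + step
      xmm[i] <- xmm[i] - step; xmm[j] <- xmm[j] - step
      H[i, j] <- (energy_at(xpp) - energy_at(xpm) -
                    energy_at(xmp) + energy_at(xmm)) / (4 * step^2)
      H[j, i] <- H[i, j]
    }
  }
  H
}

# linear molecule with a synthetic stiffness in every non-TR direction
# (pair springs on a collinear chain leave the bends floppy, so the exact
# five-vector null space needs a constructed Hessian)
linear_synthetic_fixture <- function(seed = 3) {
  chain <- linear_chain_system()
  basis <- build_tr_basis(chain, 1:3)
  set.seed(seed)
  P <- diag(9) - tcrossprod(basis$vectors)
  A <- matrix(rnorm(81, sd = 0.1), 9, 9)
  hmw <- P %*% tcrossprod(A) %*% P
  hmw <- (hmw + t(hmw)) / 2
  s <- sqrt(rep(chain$masses, each = 3))
  list(system = chain,
       hessian = hessian_matrix(hmw * outer(s, s), scope = "full"))
}

# random proper rotation matrix
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# apply a global rotation R (and optional translation t, Angstrom) to a
# system, Hessian, and gradients
rotate_fixture <- function(sys, R, t = c(0, 0, 0), hessian = NULL,
                           dipole = NULL, alpha = NULL) {
  n <- n_atoms(sys)
  xyz <- coordinates(sys) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  sys2 <- molecular_system(sys$atoms, xyz, sys$partition, sys$masses)
  bigR <- kronecker(diag(n), R)
  out <- list(system = sys2)
  if (!is.null(hessian)) {
    out$hessian <- hessian_matrix(bigR %*% hessian$matrix %*% t(bigR),
                                  scope = hessian$scope)
  }
  if (!is.null(dipole)) {
    out$dipole <- property_gradient(bigR %*% dipole$values %*% t(R),
                                    "dipole", dipole$scope)
  }
  if (!is.null(alpha)) {
    V <- alpha$values
    V2 <- matrix(0, nrow(V), 6)
    # expand 6 symmetric components -> 3x3, rotate both tensor indices
    # and the displacement index, repack
    for (a in seq_len(n)) {
      rows <- (3 * (a - 1) + 1):(3 * a)
      Ta <- array(0, c(3, 3, 3))          # [coord, tensor_i, tensor_j]
      for (c3 in 1:3) {
        v <- V[rows[c3], ]
        Ta[c3, , ] <- matrix(c(v[1], v[2], v[3],
                               v[2], v[4], v[5],
                               v[3], v[5], v[6]), 3, 3)
      }
      Tr <- array(0, c(3, 3, 3))
      for (c3 in 1:3) {
        for (cc in 1:3) {
          Tr[c3, , ] <- Tr[c3, , ] + R[c3, cc] * R %*% Ta[cc, , ] %*% t(R)
        }
      }
      for (c3 in 1:3) {
        M <- Tr[c3, , ]
        V2[rows[c3], ] <- c(M[1, 1], M[1, 2], M[1, 3], M[2, 2], M[2, 3], M[3, 3])
      }
    }
    out$alpha <- property_gradient(V2, "polarizability", alpha$scope)
  }
  out
}

# orthonormal mode-set stand-in built from an arbitrary orthogonal matrix
orthonormal_modes <- function(dim, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(dim^2), dim, dim)))
}
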