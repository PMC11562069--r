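test_that("mass weighting matches the element-wise definition", {
  expect_equal(mass_weight(diag(6), c(1, 1)), diag(6))
  expect_equal(mass_weight(diag(6), c(4, 4)), diag(6) / 4)

  set.seed(11)
  H <- matrix(rnorm(36), 6, 6); H <- H + t(H)
  masses <- c(1, 2)
  got <- mass_weight(H, masses)
  expected <- matrix(0, 6, 6)          # independent double loop
  m3 <- rep(masses, each = 3)
  for (i in 1:6) for (j in 1:6) expected[i, j] <- H[i, j] / sqrt(m3[i] * m3[j])
  expect_equal(got, expected, tolerance = 1e-14)

  expect_error(mass_weight(diag(6), c(1, 2, 3)), "expected 2 masses")
  expect_error(mass_weight(diag(6), c(1, 0)), "positive")
})

test_that("diagonalization yields sorted orthonormal modes that reconstruct the input", {
  z <- diagonalize(matrix(0, 6, 6))
  expect_equal(z$values, rep(0, 6))
  expect_equal(z$wavenumbers, rep(0, 6))

  # two-body closed form: single nonzero eigenvalue k(1/m1 + 1/m2)
  sys <- molecular_system(c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 0.92)),
                          masses = c(1.008, 18.998))
  topo <- diatomic_topology(sys, k = 0.44)
  hmw <- mass_weight(spring_hessian(sys, topo), sys$masses)
  md <- diagonalize(hmw, sys$masses)
  nz <- md$values[abs(md$values) > 1e-12]
  expect_length(nz, 1)
  expect_equal(nz, 0.44 * (1 / 1.008 + 1 / 18.998), tolerance = 1e-12)

  expect_true(all(diff(md$values) >= 0))
  expect_equal(crossprod(md$vectors), diag(6), tolerance = 1e-12)
  recon <- md$vectors %*% diag(md$values) %*% t(md$vectors)
  expect_lt(max(abs(hmw - recon)), 1e-9 * max(abs(hmw)))

  expect_error(diagonalize(matrix(rnorm(36), 6, 6)), "asymmetry")
})

test_that("wavenumbers are invariant under rotation of the geometry", {
  sys <- water_system()
  topo <- water_topology(sys)
  wn0 <- sort(diagonalize(mass_weight(spring_hessian(sys, topo),
                                      sys$masses))$wavenumbers)
  for (s in 1:3) {
    R <- random_rotation(s)
    sys2 <- molecular_system(sys$atoms, coordinates(sys) %*% t(R),
                             masses = sys$masses)
    wn <- sort(diagonalize(mass_weight(spring_hessian(sys2, topo),
                                       sys2$masses))$wavenumbers)
    expect_equal(wn, wn0, tolerance = 1e-6)
  }
})

test_that("partial extraction keeps exactly the core rows and columns", {
  set.seed(5)
  M <- matrix(rnorm(81), 9, 9); M <- M + t(M)
  H <- hessian_matrix(M, scope = "full")

  # all-core partition: identical copy
  sys_all <- molecular_system(c("C", "C", "C"), matrix(rnorm(9), 3, 3))
  expect_equal(extract_partial(H, sys_all)$matrix, M)

  # atom 2 core: rows/cols 4:6 (1-based bookkeeping)
  sys2 <- molecular_system(c("C", "C", "C"), matrix(rnorm(9), 3, 3),
                           partition = c("environment", "core", "environment"))
  p <- extract_partial(H, sys2)
  expect_equal(p$matrix, M[4:6, 4:6])
  expect_identical(p$scope, "partial")
  expect_error(extract_partial(p, sys2), "already 'partial'")
})

test_that("block-diagonal Hessians give partial eigenvalues that are a subset of the full", {
  fx <- decoupled_fixture(seed = 8)
  full_vals <- eigen(mass_weight(fx$full, fx$system$masses),
                     symmetric = TRUE, only.values = TRUE)$values
  csys <- core_system(fx$system)
  part_vals <- eigen(mass_weight(extract_partial(fx$full, fx$system),
                                 csys$masses),
                     symmetric = TRUE, only.values = TRUE)$values
  for (v in part_vals) expect_lt(min(abs(full_vals - v)), 1e-10)
})

test_that("nested partial extraction composes", {
  set.seed(6)
  M <- matrix(rnorm(144), 12, 12); M <- M + t(M)
  H <- hessian_matrix(M, scope = "full")
  xyz <- matrix(rnorm(12), 4, 3)
  sysA <- molecular_system(rep("C", 4), xyz,
                           partition = c("core", "core", "core", "environment"))
  HA <- extract_partial(H, sysA)
  sysB <- molecular_system(rep("C", 3), xyz[1:3, ],
                           partition = c("core", "environment", "core"))
  HB <- extract_partial(hessian_matrix(HA$matrix, scope = "full"), sysB)
  sysAB <- molecular_system(rep("C", 4), xyz,
                            partition = c("core", "environment", "core",
                                          "environment"))
  expect_equal(HB$matrix, extract_partial(H, sysAB)$matrix)
})

test_that("TR basis has the right vector count for point, linear, and bent geometries", {
  atom <- molecular_system("Ar", matrix(c(1, 2, 3), 1, 3))
  b1 <- build_tr_basis(atom, 1)
  expect_equal(ncol(b1$vectors), 3)
  expect_equal(b1$labels, c("Tx", "Ty", "Tz"))

  dia <- diatomic_system()
  b2 <- build_tr_basis(dia, 1:2)
  expect_equal(ncol(b2$vectors), 5)           # rotation about the axis absent
  expect_equal(n_rotations(b2), 2)

  chain <- linear_chain_system()
  expect_equal(ncol(build_tr_basis(chain, 1:3)$vectors), 5)

  wat <- water_system()
  b3 <- build_tr_basis(wat, 1:3)
  expect_equal(ncol(b3$vectors), 6)
  expect_lt(max(abs(crossprod(b3$vectors) - diag(6))), 1e-10)
  expect_equal(colSums(b3$vectors^2), rep(1, 6), tolerance = 1e-12)

  expect_error(build_tr_basis(wat, integer(0)), "at least one atom")
})

test_that("TR projection annihilates the basis and is idempotent on TR-free input", {
  cw <- caged_water(0.02)
  csys <- core_system(cw$system)
  hmw <- mass_weight(cw$partial, csys$masses)
  basis <- build_tr_basis(cw$system)

  proj <- project_tr(hmw, basis)
  expect_lt(max(abs(proj %*% basis$vectors)), 1e-12)

  # already TR-free: projecting again changes nothing
  expect_lt(max(abs(project_tr(proj, basis) - proj)), 1e-12)

  # isolated spring molecule: exactly 6 near-null eigenvalues, before and
  # after projection; 5 for a linear one
  wat <- water_system()
  topo <- water_topology(wat)
  hw <- mass_weight(spring_hessian(wat, topo), wat$masses)
  expect_equal(sum(abs(eigen(hw, symmetric = TRUE)$values) < 1e-10), 6)
  bw <- build_tr_basis(wat, 1:3)
  expect_equal(sum(abs(eigen(project_tr(hw, bw),
                             symmetric = TRUE)$values) < 1e-10), 6)

  lin <- linear_synthetic_fixture()
  hc <- mass_weight(lin$hessian, lin$system$masses)
  expect_equal(sum(abs(eigen(hc, symmetric = TRUE)$values) < 1e-10), 5)

  # retained modes of a projected caged partial Hessian carry no TR character
  pj <- diagonalize(proj, csys$masses, scope = "projected")
  keep <- abs(pj$values) > 1e-8
  tr_char <- ptc(pj$vectors[, keep, drop = FALSE], basis) +
    prc(pj$vectors[, keep, drop = FALSE], basis)
  expect_lt(max(tr_char), 1e-10)

  expect_error(project_tr(diag(5), basis), "dimension")
})

test_that("projection before diagonalization differs from filtering after it on a coupled cage", {
  cw <- caged_water(0.03)
  csys <- core_system(cw$system)
  hmw <- mass_weight(cw$partial, csys$masses)
  basis <- build_tr_basis(cw$system)
  pm <- diagonalize(hmw, csys$masses, scope = "partial")
  diag_tab <- diagnose_modes(pm, basis)
  kept <- filter_modes(pm, diag_tab)
  pj <- diagonalize(project_tr(hmw, basis), csys$masses, scope = "projected")
  surv_proj <- sort(pj$wavenumbers[abs(pj$wavenumbers) > 1e-3])
  surv_filt <- sort(kept$modes$wavenumbers)
  nk <- length(surv_filt)
  expect_gt(max(abs(rev(surv_proj)[seq_len(nk)] - rev(surv_filt))), 1e-3)
})
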