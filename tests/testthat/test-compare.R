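test_that("eigenvector splitting and environmental contribution partition the norm", {
  sys <- molecular_system(c("C", "Ar"), rbind(c(0, 0, 0), c(3, 0, 0)),
                          partition = c("core", "environment"))
  core_mode <- c(1, 0, 0, 0, 0, 0)
  p <- split_eigenvector(core_mode, sys)
  expect_equal(environmental_contribution(p$core, p$env), 0)

  env_mode <- c(0, 0, 0, 0, 1, 0)
  p <- split_eigenvector(env_mode, sys)
  expect_equal(environmental_contribution(p$core, p$env), 1)

  half <- c(1, 0, 0, 1, 0, 0) / sqrt(2)
  p <- split_eigenvector(half, sys)
  expect_equal(environmental_contribution(p$core, p$env), 0.5)
  expect_equal(sum(p$core^2) + sum(p$env^2), 1, tolerance = 1e-10)

  expect_error(split_eigenvector(c(1, 0, 0), sys), "length")

  # decoupled block system: every full mode is exactly pure core or pure
  # environment
  fx <- decoupled_fixture(seed = 30)
  fm <- vibrational_analysis(fx$system, fx$full)
  ecs <- vapply(seq_len(n_modes(fm)), function(i) {
    q <- split_eigenvector(fm$vectors[, i], fx$system)
    environmental_contribution(q$core, q$env)
  }, numeric(1))
  expect_true(all(pmin(ecs, 1 - ecs) < 1e-20))
})

test_that("mode matching recovers permutations and sign flips with unit overlap", {
  fx <- decoupled_fixture(seed = 2)
  fm <- vibrational_analysis(fx$system, fx$full)
  pm <- vibrational_analysis(fx$system, fx$full, partial = TRUE)

  base <- match_modes(fm, pm, fx$system)
  expect_equal(base$overlap, rep(1, n_modes(pm)), tolerance = 1e-10)
  # matched full modes are exactly the pure-core ones, in spectral order
  expect_equal(pm$values, fm$values[base$full], tolerance = 1e-10)

  set.seed(99)
  perm <- sample(n_modes(pm))
  signs <- sample(c(-1, 1), n_modes(pm), replace = TRUE)
  pm2 <- pm
  pm2$vectors <- sweep(pm$vectors[, perm], 2, signs, "*")
  pm2$values <- pm$values[perm]
  pm2$wavenumbers <- pm$wavenumbers[perm]
  got <- match_modes(fm, pm2, fx$system)
  expect_equal(got$overlap, rep(1, n_modes(pm)), tolerance = 1e-10)
  expect_equal(got$full, base$full[perm])
})

test_that("exactly tied overlaps break toward lower index pairs", {
  sys <- molecular_system(c("C", "Ar"), rbind(c(0, 0, 0), c(3, 0, 0)),
                          partition = c("core", "environment"))
  s2 <- sqrt(0.5)
  # full modes 1 and 2 share the same core part (e1+e2)/2 and differ only
  # in the environment block: both overlap partial mode 1 equally
  L1 <- c(0.5, 0.5, 0, s2, 0, 0)
  L2 <- c(0.5, 0.5, 0, -s2, 0, 0)
  L3 <- c(s2, -s2, 0, 0, 0, 0)
  L4 <- c(0, 0, 1, 0, 0, 0)
  L5 <- c(0, 0, 0, 0, 1, 0)
  L6 <- c(0, 0, 0, 0, 0, 1)
  full <- structure(list(values = 1:6, vectors = cbind(L1, L2, L3, L4, L5, L6),
                         wavenumbers = 1:6, displacements = NULL,
                         masses = sys$masses, scope = "full"),
                    class = "phva_modes")
  pvec <- cbind(c(s2, s2, 0), c(s2, -s2, 0), c(0, 0, 1))
  partial <- structure(list(values = 1:3, vectors = pvec,
                            wavenumbers = 1:3, displacements = NULL,
                            masses = sys$masses[1], scope = "partial"),
                       class = "phva_modes")
  got <- match_modes(full, partial, sys)
  # partial 1 ties between full 1 and 2 at overlap 1/sqrt(2): lower wins
  expect_equal(got$full, c(1, 3, 4))
  expect_equal(got$overlap, c(s2, 1, 1), tolerance = 1e-12)
})

test_that("angular deviation obeys its sign and range conventions", {
  c1 <- c(2, 0, 0)            # un-normalized core part: renormalized inside
  expect_equal(angular_deviation(c1, c(1, 0, 0)), 0)
  expect_equal(angular_deviation(c1, c(-1, 0, 0)), 0)
  expect_equal(angular_deviation(c1, c(0, 1, 0)), 90)
  expect_equal(angular_deviation(c(1, 1, 0), c(1, 0, 0)), 45,
               tolerance = 1e-10)
  expect_error(angular_deviation(c(0, 0, 0), c(1, 0, 0)), "core support")
})

test_that("difference metrics follow the normalizer and relative conventions", {
  mk_modes <- function(wn) {
    structure(list(values = wn, vectors = diag(length(wn)),
                   wavenumbers = wn, displacements = NULL,
                   masses = NULL, scope = "partial"),
              class = "phva_modes")
  }
  ref <- mk_modes(c(100, 200, 300))
  cmp <- mk_modes(c(110, 195, 300))
  pairs <- tibble::tibble(full = 1:3, partial = 1:3, overlap = rep(1, 3))
  r_int <- list(ir = c(10, 4, 8))
  c_int <- list(ir = c(8, 3, 4))              # |dI| = (2, 1, 4)
  out <- difference_metrics(pairs, ref, cmp,
                            reference_intensities = r_int,
                            comparison_intensities = c_int,
                            exclude_lowest = 0)
  expect_equal(out$table$delta_freq, c(10, 5, 0))
  expect_equal(out$table$ir_norm, c(0.5, 0.25, 1.0))
  expect_equal(out$table$ir_rel, c(0.2, 0.25, 0.5))
  expect_false(any(out$table$excluded))

  # zero reference with nonzero difference: NA sentinel, not infinity
  out2 <- difference_metrics(pairs, ref, cmp,
                             reference_intensities = list(ir = c(0, 4, 8)),
                             comparison_intensities = list(ir = c(2, 4, 8)),
                             exclude_lowest = 0)
  expect_true(is.na(out2$table$ir_rel[1]))
  expect_equal(out2$table$ir_rel[2:3], c(0, 0))

  # excluded lowest-frequency pairs do not define the normalizer but are
  # still reported
  out3 <- difference_metrics(pairs, ref, cmp,
                             reference_intensities = list(ir = c(10, 4, 8)),
                             comparison_intensities = list(ir = c(2, 3, 7)),
                             exclude_lowest = 1)
  # |dI| = (8, 1, 1); pair 1 (lowest comparison frequency) excluded
  expect_true(out3$table$excluded[1])
  expect_equal(out3$table$ir_norm, c(8, 1, 1))
  # exactly one non-excluded pair attains 1.0
  expect_equal(sum(out3$table$ir_norm[!out3$table$excluded] == 1), 2)

  # identical inputs: everything zero
  out4 <- difference_metrics(pairs, ref, ref,
                             reference_intensities = r_int,
                             comparison_intensities = r_int,
                             exclude_lowest = 0)
  expect_equal(out4$table$delta_freq, rep(0, 3))
  expect_equal(out4$table$ir_norm, rep(0, 3))
})

test_that("the decoupled limit zeroes the whole comparison pipeline", {
  for (s in c(1, 6)) {
    fx <- decoupled_fixture(seed = s)
    cmp <- phva_compare(fx$system, fx$full, fx$dipole, fx$polarizability)
    tb <- cmp$table
    expect_lt(max(tb$delta_freq), 1e-6)
    expect_lt(max(tb$ad), 1e-6)
    expect_lt(max(tb$ec), 1e-12)
    expect_lt(max(tb$ir_rel, na.rm = TRUE), 1e-10)
    expect_lt(max(tb$raman_rel, na.rm = TRUE), 1e-10)
    expect_equal(tb$overlap, rep(1, nrow(tb)), tolerance = 1e-10)
  }
})

test_that("rmsd matches direct arithmetic and superposition removes rigid motion", {
  A <- matrix(rnorm(15), 5, 3)
  expect_equal(rmsd(A, A), 0)
  expect_equal(rmsd(A, sweep(A, 2, c(3, 0, 4), "+")), 5, tolerance = 1e-12)

  B <- rbind(c(0, 0, 0), c(1, 0, 0))
  B2 <- rbind(c(0, 0, 3), c(1, 4, 0))          # displacements 3 and 4
  expect_equal(rmsd(B, B2), sqrt(12.5), tolerance = 1e-12)

  R <- random_rotation(55)
  A2 <- sweep(A %*% t(R), 2, c(1, 2, 3), "+")
  expect_gt(rmsd(A, A2), 0.1)
  expect_lt(rmsd(A, A2, superpose = TRUE), 1e-10)

  # subset selection
  expect_equal(rmsd(B, B2, subset = 1), 3, tolerance = 1e-12)
  expect_error(rmsd(A, B), "sizes differ")
})
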