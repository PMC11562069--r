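#' Split a full-system eigenvector into core and environment parts
#'
#' A normalized eigenvector of the full mass-weighted Hessian is divided
#' into the components on core atoms (C) and on environment atoms (E);
#' by normalization, the squared norms of the two parts sum to one.
#'
#' @param mode unit 3N-vector over the full system.
#' @param system the partitioned `phva_system`.
#' @return A list with `core` (3Ncore-vector) and `env` (3Nenv-vector).
#' @export
split_eigenvector <- function(mode, system) {
  mode <- as.numeric(mode)
  if (length(mode) != 3 * n_atoms(system)) {
    stop("mode has length ", length(mode), " but system needs ",
         3 * n_atoms(system), call. = FALSE)
  }
  ci <- cart_indices(core_atoms(system))
  list(core = mode[ci], env = mode[-ci])
}

#' Environmental contribution of a full-system normal mode
#'
#' The fraction of a normalized full-Hessian mode's weight that resides on
#' environment atoms: the squared norm of the environment part. Modes with
#' high environmental contribution cannot be represented by a partial
#' (core-only) Hessian.
#'
#' @param core,env the two parts from [split_eigenvector()].
#' @return A value in [0, 1]; core weight + environmental contribution = 1.
#' @export
environmental_contribution <- function(core, env) {
  tot <- sum(core^2) + sum(env^2)
  sum(env^2) / tot
}

# Hungarian algorithm (O(n^3), potentials formulation) for the rectangular
# min-cost assignment of n rows to n of m >= n columns.
.hungarian <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)          # p[j+1]: row matched to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

#' Match partial-Hessian modes to full-Hessian modes by overlap
#'
#' Computes the absolute overlap (dot product) between the core parts of
#' the full-Hessian eigenvectors and the partial-Hessian eigenvectors,
#' then finds the one-to-one assignment maximizing the total absolute
#' overlap (globally optimal bipartite matching, not greedy -- greedy
#' matching is order-dependent and can swap near-degenerate pairs).
#' Absolute values make the match insensitive to eigenvector phase.
#' Exactly equal alternatives are tie-broken toward pairing lower full
#' indices with lower partial indices.
#'
#' @param full `phva_modes` of the full system (3N modes).
#' @param partial `phva_modes` of the core subsystem (3Ncore modes).
#' @param system the partitioned `phva_system`.
#' @return A tibble with one row per partial mode: `full` and `partial`
#'   mode indices and the absolute `overlap` of the pair.
#' @export
match_modes <- function(full, partial, system) {
  nc <- length(core_atoms(system))
  if (nc == 0) stop("system has no core atoms", call. = FALSE)
  if (nrow(partial$vectors) != 3 * nc) {
    stop("partial mode dimension ", nrow(partial$vectors),
         " does not match 3 x ", nc, " core coordinates", call. = FALSE)
  }
  if (nrow(full$vectors) != 3 * n_atoms(system)) {
    stop("full mode dimension does not match the system", call. = FALSE)
  }
  ci <- cart_indices(core_atoms(system))
  C <- full$vectors[ci, , drop = FALSE]          # core parts, 3Nc x Nfull
  ov <- abs(crossprod(partial$vectors, C))       # Npartial x Nfull
  assign_full <- .hungarian(-ov)

  # degenerate 2-cycles: prefer (low partial, low full) when the swap is
  # overlap-neutral
  np <- n_modes(partial)
  repeat {
    swapped <- FALSE
    for (a in seq_len(np - 1)) {
      for (b in (a + 1):np) {
        ja <- assign_full[a]; jb <- assign_full[b]
        if (ja > jb) {
          gain <- (ov[a, jb] + ov[b, ja]) - (ov[a, ja] + ov[b, jb])
          if (gain > -1e-12) {
            assign_full[a] <- jb; assign_full[b] <- ja
            swapped <- TRUE
          }
        }
      }
    }
    if (!swapped) break
  }

  tibble::tibble(
    full = assign_full,
    partial = seq_len(np),
    overlap = ov[cbind(seq_len(np), assign_full)]
  )
}

#' Angular deviation between a core-projected full mode and a partial mode
#'
#' The angle (in degrees, in [0, 90]) between the renormalized core part
#' of a full-Hessian eigenvector and the matched partial-Hessian
#' eigenvector. Absolute dot products are used, so a sign flip of either
#' vector leaves the angle unchanged. Direction (angular deviation) and
#' magnitude (environmental contribution) are thereby kept as separate
#' diagnostics.
#'
#' @param core the core part C of the full mode (need not be normalized).
#' @param l_partial normalized partial-Hessian eigenvector.
#' @return Angle in degrees.
#' @export
angular_deviation <- function(core, l_partial) {
  nc <- sqrt(sum(core^2))
  if (nc < 1e-10) {
    stop("mode has no core support; angular deviation undefined", call. = FALSE)
  }
  cosang <- abs(sum(core * l_partial)) / (nc * sqrt(sum(l_partial^2)))
  acos(min(1, max(0, cosang))) * 180 / pi
}

#' Frequency and intensity difference metrics over matched mode pairs
#'
#' For each matched (reference, comparison) mode pair, computes the
#' absolute frequency difference, and for each supplied intensity type the
#' relative difference (absolute difference over the reference intensity)
#' and the normalized absolute difference (absolute difference divided by
#' the maximum absolute difference over all pairs except the excluded
#' lowest-frequency ones). The excluded pairs -- by default the six whose
#' comparison-set modes have the lowest wavenumbers, i.e. the pseudo-TR
#' set -- are still reported, but do not enter the normalizer.
#'
#' @param pairs tibble from [match_modes()] (columns full, partial,
#'   overlap); "full" indexes the reference set, "partial" the comparison
#'   set.
#' @param reference,comparison the two `phva_modes` sets.
#' @param system the partitioned `phva_system` (for environmental
#'   contribution and core splitting); may be NULL when both sets share a
#'   scope (then EC and AD on core parts use the modes as-is).
#' @param reference_intensities,comparison_intensities optional named
#'   lists with elements `ir` and/or `raman`: per-mode intensity vectors
#'   aligned with each mode set.
#' @param exclude_lowest number of lowest-frequency comparison modes to
#'   exclude from the normalizer; default 6 (use 5 for a linear core).
#' @return An object of class `phva_comparison` whose `table` has one row
#'   per pair: indices, overlap, ec, ad, delta_freq (cm^-1), excluded
#'   flag, and for each intensity type ir_rel/ir_norm and
#'   raman_rel/raman_norm. Relative differences with a zero reference and
#'   nonzero difference are NA.
#' @export
difference_metrics <- function(pairs, reference, comparison, system = NULL,
                               reference_intensities = NULL,
                               comparison_intensities = NULL,
                               exclude_lowest = 6) {
  stopifnot(exclude_lowest >= 0)
  iref <- pairs$full
  icmp <- pairs$partial
  np <- nrow(pairs)

  ec <- ad <- rep(NA_real_, np)
  if (!is.null(system)) {
    same_dim <- nrow(reference$vectors) == nrow(comparison$vectors)
    for (r in seq_len(np)) {
      parts <- split_eigenvector(reference$vectors[, iref[r]], system)
      ec[r] <- environmental_contribution(parts$core, parts$env)
      cvec <- if (same_dim) reference$vectors[, iref[r]] else parts$core
      ad[r] <- angular_deviation(cvec, comparison$vectors[, icmp[r]])
    }
  }

  dfreq <- abs(reference$wavenumbers[iref] - comparison$wavenumbers[icmp])

  # excluded set: pairs whose comparison mode is among the lowest-frequency
  excl <- rep(FALSE, np)
  if (exclude_lowest > 0) {
    low <- order(comparison$wavenumbers[icmp])[seq_len(min(exclude_lowest, np))]
    excl[low] <- TRUE
  }

  out <- tibble::tibble(
    full = iref, partial = icmp, overlap = pairs$overlap,
    ec = ec, ad = ad, delta_freq = dfreq, excluded = excl
  )

  for (kind in c("ir", "raman")) {
    r_int <- reference_intensities[[kind]]
    c_int <- comparison_intensities[[kind]]
    if (is.null(r_int) || is.null(c_int)) next
    dI <- abs(r_int[iref] - c_int[icmp])
    rel <- ifelse(dI == 0, 0,
                  ifelse(abs(r_int[iref]) > 0, dI / abs(r_int[iref]), NA_real_))
    normalizer <- if (any(!excl)) max(dI[!excl]) else 0
    nrm <- if (normalizer > 0) dI / normalizer else rep(0, np)
    out[[paste0(kind, "_rel")]] <- rel
    out[[paste0(kind, "_norm")]] <- nrm
  }

  structure(
    list(table = out, exclude_lowest = exclude_lowest),
    class = "phva_comparison"
  )
}

#' @export
print.phva_comparison <- function(x, ...) {
  cat("<phva_comparison> ", nrow(x$table), " matched pairs (",
      sum(x$table$excluded), " excluded from normalizer)\n", sep = "")
  cat("  max |delta freq| = ",
      sprintf("%.4f", max(x$table$delta_freq)), " cm^-1",
      if (!all(is.na(x$table$ad)))
        paste0(", max AD = ", sprintf("%.3f", max(x$table$ad, na.rm = TRUE)),
               " deg"),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.phva_comparison <- function(x, ...) x$table

#' @export
glance.phva_comparison <- function(x, ...) {
  tb <- x$table
  kept <- tb[!tb$excluded, ]
  tibble::tibble(
    n_pairs = nrow(tb),
    n_excluded = sum(tb$excluded),
    mean_overlap = mean(tb$overlap),
    max_delta_freq = max(kept$delta_freq),
    max_ad = if (all(is.na(tb$ad))) NA_real_ else max(kept$ad, na.rm = TRUE),
    mean_ec = if (all(is.na(tb$ec))) NA_real_ else mean(kept$ec, na.rm = TRUE)
  )
}

#' Plot matched-pair difference metrics
#'
#' @param object a `phva_comparison`.
#' @param ... unused.
#' @return A ggplot object: per-pair frequency differences, excluded pairs
#'   greyed out.
#' @export
autoplot.phva_comparison <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$partial, y = .data$delta_freq,
                               fill = .data$excluded)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey25",
                                          `TRUE` = "grey80")) +
    ggplot2::labs(x = "matched mode", y = expression(abs(Delta * tilde(nu)) ~ (cm^-1)),
                  fill = "excluded") +
    ggplot2::theme_minimal()
}

#' Full-vs-partial comparison pipeline
#'
#' Runs the whole comparison in one call: diagonalizes the full Hessian
#' and its core block, matches modes by overlap, and computes
#' environmental contributions, angular deviations, and frequency and
#' intensity difference metrics. Property gradients, when given with full
#' scope, are truncated to the core for the partial-side intensities.
#'
#' @param system partitioned `phva_system`.
#' @param full_hessian `phva_hessian`, full scope.
#' @param dipole,polarizability optional full-scope `phva_gradient`s.
#' @param exclude_lowest passed to [difference_metrics()].
#' @return A `phva_comparison`.
#' @export
phva_compare <- function(system, full_hessian, dipole = NULL,
                         polarizability = NULL, exclude_lowest = 6) {
  full_modes <- vibrational_analysis(system, full_hessian)
  partial_modes <- vibrational_analysis(system, full_hessian, partial = TRUE)
  pairs <- match_modes(full_modes, partial_modes, system)

  intens <- function(modes, dip, alpha) {
    out <- list()
    if (!is.null(dip)) out$ir <- ir_intensities(transform_gradient(dip, modes))
    if (!is.null(alpha)) out$raman <- raman_activities(transform_gradient(alpha, modes))
    if (length(out)) out else NULL
  }
  ref_int <- intens(full_modes, dipole, polarizability)
  cmp_int <- intens(
    partial_modes,
    if (!is.null(dipole)) truncate_gradient(dipole, system),
    if (!is.null(polarizability)) truncate_gradient(polarizability, system)
  )

  difference_metrics(pairs, full_modes, partial_modes, system,
                     reference_intensities = ref_int,
                     comparison_intensities = cmp_int,
                     exclude_lowest = exclude_lowest)
}

#' Root-mean-square deviation of nuclear positions
#'
#' RMSD over a subset of atoms between two conformations with matched atom
#' order. By default no superposition is applied (frames sharing a frozen
#' environment are directly comparable); with `superpose = TRUE` the
#' deviation is minimized over rigid rotation and translation (Kabsch
#' alignment on the subset) first.
#'
#' @param geom_a,geom_b N x 3 coordinate matrices, Angstrom (or two
#'   `phva_system`s).
#' @param subset atom indices entering the RMSD; default all atoms.
#' @param superpose logical; minimize over rigid-body motion first.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(geom_a, geom_b, subset = NULL, superpose = FALSE) {
  if (inherits(geom_a, "phva_system")) geom_a <- coordinates(geom_a)
  if (inherits(geom_b, "phva_system")) geom_b <- coordinates(geom_b)
  geom_a <- as.matrix(geom_a)
  geom_b <- as.matrix(geom_b)
  subset <- subset %||% seq_len(nrow(geom_a))
  if (max(subset) > nrow(geom_a) || max(subset) > nrow(geom_b)) {
    stop("subset sizes differ: geometries have ", nrow(geom_a), " and ",
         nrow(geom_b), " atoms", call. = FALSE)
  }
  A <- geom_a[subset, , drop = FALSE]
  B <- geom_b[subset, , drop = FALSE]
  if (superpose) {
    ca <- colMeans(A); cb <- colMeans(B)
    A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
    s <- svd(crossprod(B0, A0))
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    B <- sweep(B0 %*% t(R), 2, ca, "+")
    A <- A0
    B <- sweep(B, 2, ca)
  }
  sqrt(mean(rowSums((A - B)^2)))
}
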