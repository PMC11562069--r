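#' Diagonalize a mass-weighted Hessian into a normal mode set
#'
#' Eigenanalysis of the (symmetric) mass-weighted Hessian. Eigenvalues are
#' returned in ascending order with orthonormal eigenvectors; signed
#' harmonic wavenumbers are attached via [wavenumber_from_eigenvalue()].
#' If masses are supplied, Cartesian displacement vectors are produced by
#' un-mass-weighting the eigenvectors (columns of M^(-1/2) L).
#'
#' Determinism conventions: degenerate eigenvalues are ordered by the atom
#' index carrying the dominant coefficient, and each eigenvector's sign is
#' fixed so its largest-magnitude component is positive. This makes mode
#' matching and regression comparisons reproducible across platforms.
#'
#' @param h_mw symmetric mass-weighted Hessian (3n x 3n),
#'   Hartree Bohr^-2 amu^-1.
#' @param masses optional numeric vector of the n atomic masses, amu, used
#'   to build Cartesian displacements.
#' @param scope "full", "partial", or "projected" -- recorded metadata.
#' @return An object of class `phva_modes`: `values` (ascending
#'   eigenvalues), `vectors` (orthonormal columns), `wavenumbers` (signed,
#'   cm^-1), `displacements` (Cartesian, or NULL), `masses`, `scope`.
#' @export
diagonalize <- function(h_mw, masses = NULL,
                        scope = c("full", "partial", "projected")) {
  scope <- match.arg(scope)
  h_mw <- as.matrix(h_mw)
  asym <- max(abs(h_mw - t(h_mw)))
  if (asym > 1e-8) {
    stop("mass-weighted Hessian asymmetry ", format(asym), " exceeds 1e-8",
         call. = FALSE)
  }
  e <- eigen((h_mw + t(h_mw)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]

  # tie-break degenerate eigenvalues by the atom index of the dominant
  # coefficient; fix sign so the largest-magnitude component is positive
  dom <- apply(vecs, 2, function(v) which.max(abs(v)))
  grp <- cumsum(c(TRUE, diff(vals) > 1e-10 * max(1, abs(vals[-1]))))
  ord2 <- order(grp, dom)
  vals <- vals[ord2]
  vecs <- vecs[, ord2, drop = FALSE]
  for (i in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, i]))
    if (vecs[j, i] < 0) vecs[, i] <- -vecs[, i]
  }

  disp <- NULL
  if (!is.null(masses)) {
    if (length(masses) * 3 != nrow(h_mw)) {
      stop("expected ", nrow(h_mw) / 3, " masses", call. = FALSE)
    }
    disp <- vecs / sqrt(rep(masses, each = 3))
  }

  structure(
    list(
      values = vals,
      vectors = vecs,
      wavenumbers = wavenumber_from_eigenvalue(vals),
      displacements = disp,
      masses = masses,
      scope = scope
    ),
    class = "phva_modes"
  )
}

#' @export
print.phva_modes <- function(x, ...) {
  nneg <- sum(x$wavenumbers < -1e-6)
  cat("<phva_modes> ", length(x$values), " modes (", x$scope, " scope)",
      if (nneg) paste0(", ", nneg, " imaginary"), "\n", sep = "")
  if (length(x$wavenumbers)) {
    rng <- range(x$wavenumbers)
    cat("  wavenumbers: ", sprintf("%.2f", rng[1]), " .. ",
        sprintf("%.2f", rng[2]), " cm^-1\n", sep = "")
  }
  invisible(x)
}

#' Number of modes in a normal mode set
#' @param modes a `phva_modes`.
#' @return Integer mode count.
#' @export
n_modes <- function(modes) length(modes$values)

#' Full vibrational analysis of a Hessian
#'
#' Convenience pipeline: mass-weight, optionally extract the core block
#' (partial Hessian vibrational analysis), optionally project out
#' translation/rotation, then diagonalize.
#'
#' @param system a `phva_system`.
#' @param hessian a `phva_hessian` (full scope, spanning the system).
#' @param partial if TRUE, analyze only the core-core Hessian block.
#' @param project if TRUE, apply the Wilson translation/rotation projector
#'   (built over the analyzed atoms) before diagonalizing.
#' @return A `phva_modes` object over the analyzed atoms.
#' @export
vibrational_analysis <- function(system, hessian, partial = FALSE,
                                 project = FALSE) {
  if (partial && hessian$scope == "full") {
    hessian <- extract_partial(hessian, system)
    sys_used <- core_system(system)
  } else if (hessian$scope == "partial") {
    sys_used <- core_system(system)
  } else {
    sys_used <- system
  }
  h_mw <- mass_weight(hessian, sys_used$masses)
  scope <- if (hessian$scope == "partial") "partial" else "full"
  if (project) {
    basis <- build_tr_basis(sys_used, seq_len(n_atoms(sys_used)))
    h_mw <- project_tr(h_mw, basis)
    scope <- "projected"
  }
  diagonalize(h_mw, sys_used$masses, scope = scope)
}

#' Tidy table of a normal mode set
#'
#' @param x a `phva_modes`.
#' @param ... unused.
#' @return A tibble with one row per mode: mode index, eigenvalue
#'   (Hartree Bohr^-2 amu^-1), signed wavenumber (cm^-1), and whether the
#'   mode is imaginary.
#' @export
tidy.phva_modes <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$values),
    eigenvalue = x$values,
    wavenumber = x$wavenumbers,
    imaginary = x$wavenumbers < -1e-6
  )
}

#' One-row summary of a normal mode set
#'
#' @param x a `phva_modes`.
#' @param ... unused.
#' @return A one-row tibble: mode count, scope, number of near-zero modes
#'   (|wavenumber| < 1 cm^-1), number of imaginary modes, and the extreme
#'   wavenumbers.
#' @export
glance.phva_modes <- function(x, ...) {
  tibble::tibble(
    n_modes = length(x$values),
    scope = x$scope,
    n_zero = sum(abs(x$wavenumbers) < 1),
    n_imaginary = sum(x$wavenumbers < -1),
    min_wavenumber = min(x$wavenumbers),
    max_wavenumber = max(x$wavenumbers)
  )
}

#' Stick-spectrum plot of a normal mode set
#'
#' @param object a `phva_modes`.
#' @param intensities optional per-mode heights (e.g. IR intensities);
#'   defaults to unit sticks.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.phva_modes <- function(object, intensities = NULL, ...) {
  df <- tidy(object)
  df$intensity <- intensities %||% rep(1, nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber,
                                   xend = .data$wavenumber,
                                   y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)),
                  y = if (is.null(intensities)) "mode" else "intensity") +
    ggplot2::theme_minimal()
}
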