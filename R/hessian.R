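#' Construct a Cartesian Hessian matrix object
#'
#' Wraps a 3N x 3N matrix of second derivatives of the energy with respect
#' to Cartesian nuclear displacements, in Hartree/Bohr^2. The scope records
#' whether the matrix spans the full system or only the core block retained
#' by partial Hessian vibrational analysis.
#'
#' Symmetry policy: parsed or finite-difference Hessians are never exactly
#' symmetric. Asymmetries with max |H - t(H)| <= 1e-8 are accepted silently;
#' up to 1e-6 the matrix is symmetrized as (H + t(H))/2 with a warning;
#' beyond that the input is rejected.
#'
#' @param matrix square numeric matrix, 3N x 3N, Hartree/Bohr^2.
#' @param scope "full" or "partial".
#' @return An object of class `phva_hessian` with fields `matrix`,
#'   `n_atoms`, `scope`.
#' @export
hessian_matrix <- function(matrix, scope = c("full", "partial")) {
  scope <- match.arg(scope)
  matrix <- as.matrix(matrix)
  d <- dim(matrix)
  if (d[1] != d[2] || d[1] %% 3 != 0 || d[1] == 0) {
    stop("Hessian must be square with dimension a multiple of 3, got ",
         d[1], " x ", d[2], call. = FALSE)
  }
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-6) {
    stop("Hessian asymmetry ", format(asym), " exceeds 1e-6 Hartree/Bohr^2",
         call. = FALSE)
  }
  if (asym > 1e-8) {
    warning("Hessian asymmetry ", format(asym),
            " > 1e-8; symmetrizing as (H + t(H))/2", call. = FALSE)
    matrix <- (matrix + t(matrix)) / 2
  }
  structure(
    list(matrix = unname(matrix), n_atoms = d[1] %/% 3L, scope = scope),
    class = "phva_hessian"
  )
}

#' @export
print.phva_hessian <- function(x, ...) {
  cat("<phva_hessian> ", x$scope, " scope, ", x$n_atoms, " atoms (",
      3 * x$n_atoms, " x ", 3 * x$n_atoms, ")\n", sep = "")
  invisible(x)
}

#' Mass-weight a Cartesian Hessian
#'
#' Computes M^(-1/2) H M^(-1/2), where M is the diagonal matrix repeating
#' each atomic mass three times. Eigenvectors of the result are the normal
#' modes; eigenvalues carry units Hartree Bohr^-2 amu^-1.
#'
#' @param hessian a `phva_hessian` or a bare 3N x 3N matrix.
#' @param masses numeric vector of N atomic masses, amu.
#' @return A 3N x 3N mass-weighted matrix (plain numeric matrix).
#' @export
mass_weight <- function(hessian, masses) {
  H <- if (inherits(hessian, "phva_hessian")) hessian$matrix else as.matrix(hessian)
  n <- nrow(H) / 3
  if (length(masses) != n) {
    stop("expected ", n, " masses for a ", nrow(H), "-dimensional Hessian, got ",
         length(masses), call. = FALSE)
  }
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  w <- 1 / sqrt(rep(masses, each = 3))
  H * outer(w, w)
}

#' Extract the core block of a full Hessian
#'
#' Partial Hessian vibrational analysis retains only the core-core block of
#' the full Cartesian Hessian, discarding all rows and columns that involve
#' environment atoms. Atom order within the core is preserved.
#'
#' @param hessian a `phva_hessian` with scope "full".
#' @param system the `phva_system` whose partition defines the core.
#' @return A `phva_hessian` with scope "partial" over the core atoms.
#' @export
extract_partial <- function(hessian, system) {
  stopifnot(inherits(hessian, "phva_hessian"))
  if (hessian$scope != "full") {
    stop("Hessian scope is already 'partial'", call. = FALSE)
  }
  if (hessian$n_atoms != n_atoms(system)) {
    stop("Hessian spans ", hessian$n_atoms, " atoms but system has ",
         n_atoms(system), call. = FALSE)
  }
  core <- core_atoms(system)
  idx <- cart_indices(core)
  hessian_matrix(hessian$matrix[idx, idx, drop = FALSE], scope = "partial")
}
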