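#' Construct a Cartesian property gradient
#'
#' Holds the derivatives of the molecular dipole moment (3N x 3, a.u.) or
#' of the polarizability tensor (3N x 6 symmetric components ordered
#' xx, xy, xz, yy, yz, zz, a.u.) with respect to Cartesian nuclear
#' displacements. Rows follow atom-major order (x, y, z of atom 1, then
#' atom 2, ...).
#'
#' @param values 3N x 3 (dipole) or 3N x 6 (polarizability) numeric matrix.
#' @param kind "dipole" or "polarizability".
#' @param scope "full" or "partial".
#' @return An object of class `phva_gradient`.
#' @export
property_gradient <- function(values, kind = c("dipole", "polarizability"),
                              scope = c("full", "partial")) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  values <- as.matrix(values)
  want <- if (kind == "dipole") 3L else 6L
  if (ncol(values) != want) {
    stop(kind, " gradient must have ", want, " columns, got ", ncol(values),
         call. = FALSE)
  }
  if (nrow(values) %% 3 != 0 || nrow(values) == 0) {
    stop("gradient must have 3N rows, got ", nrow(values), call. = FALSE)
  }
  if (any(!is.finite(values))) stop("gradient has non-finite entries", call. = FALSE)
  structure(
    list(values = unname(values), kind = kind, scope = scope,
         n_atoms = nrow(values) %/% 3L),
    class = "phva_gradient"
  )
}

#' @export
print.phva_gradient <- function(x, ...) {
  cat("<phva_gradient> ", x$kind, ", ", x$scope, " scope, ",
      x$n_atoms, " atoms\n", sep = "")
  invisible(x)
}

#' Transform a Cartesian property gradient to normal coordinates
#'
#' Contracts the mass-weighted gradient with the normal-mode eigenvectors:
#' the derivative of the property along normal coordinate Q_i is
#' t(L_i) M^(-1/2) (d prop / d x). The Hessian reduction affects
#' frequencies directly; intensities are affected only through this
#' transformation, which is why truncating gradients and truncating the
#' Hessian are separate, separately-assessable approximations.
#'
#' @param gradient a `phva_gradient` whose rows span the same atoms as the
#'   mode set.
#' @param modes a `phva_modes`.
#' @param masses numeric vector of the atomic masses (amu) of those atoms;
#'   defaults to `modes$masses`.
#' @return A (number of modes) x 3 or x 6 matrix of per-mode property
#'   derivatives (units: input units per sqrt(amu) per Bohr).
#' @export
transform_gradient <- function(gradient, modes, masses = NULL) {
  stopifnot(inherits(gradient, "phva_gradient"), inherits(modes, "phva_modes"))
  masses <- masses %||% modes$masses
  if (is.null(masses)) stop("masses required (not stored in mode set)", call. = FALSE)
  if (nrow(gradient$values) != nrow(modes$vectors)) {
    stop("gradient spans ", gradient$n_atoms, " atoms but modes span ",
         nrow(modes$vectors) / 3, " (scope mismatch?)", call. = FALSE)
  }
  w <- 1 / sqrt(rep(masses, each = 3))
  crossprod(modes$vectors, gradient$values * w)
}

#' IR intensities from per-mode dipole derivatives
#'
#' Double-harmonic IR intensity of mode i: the squared norm of the dipole
#' derivative along Q_i times a prefactor assembled from CODATA constants
#' to give km/mol (inputs in atomic units, e per sqrt(amu)).
#'
#' @param dipole_derivs modes x 3 matrix from [transform_gradient()].
#' @return Nonnegative per-mode intensities, km/mol.
#' @export
ir_intensities <- function(dipole_derivs) {
  dipole_derivs <- as.matrix(dipole_derivs)
  stopifnot(ncol(dipole_derivs) == 3, all(is.finite(dipole_derivs)))
  .const$ir_factor * rowSums(dipole_derivs^2)
}

#' Raman scattering activities from per-mode polarizability derivatives
#'
#' Computes the rotational-invariant activity 45*a'^2 + 7*gamma'^2 per
#' mode, where a' is the isotropic mean of the diagonal derivatives and
#' gamma'^2 the anisotropy invariant
#' 1/2 ((axx-ayy)^2 + (ayy-azz)^2 + (azz-axx)^2 + 6(axy^2 + ayz^2 + axz^2)).
#' Inputs in atomic units give activities reported in Angstrom^4/amu, the
#' conventional unit. Any frequency dependence of the polarizability lives
#' in the input gradients and is not re-modeled here.
#'
#' @param alpha_derivs modes x 6 matrix from [transform_gradient()],
#'   columns ordered xx, xy, xz, yy, yz, zz.
#' @return Nonnegative per-mode activities, Angstrom^4/amu.
#' @export
raman_activities <- function(alpha_derivs) {
  alpha_derivs <- as.matrix(alpha_derivs)
  stopifnot(ncol(alpha_derivs) == 6, all(is.finite(alpha_derivs)))
  axx <- alpha_derivs[, 1]; axy <- alpha_derivs[, 2]; axz <- alpha_derivs[, 3]
  ayy <- alpha_derivs[, 4]; ayz <- alpha_derivs[, 5]; azz <- alpha_derivs[, 6]
  a_iso <- (axx + ayy + azz) / 3
  gamma2 <- 0.5 * ((axx - ayy)^2 + (ayy - azz)^2 + (azz - axx)^2 +
                     6 * (axy^2 + ayz^2 + axz^2))
  .const$raman_factor * (45 * a_iso^2 + 7 * gamma2)
}

#' Truncate a property gradient to the core subsystem
#'
#' Removes the derivative rows belonging to environment atoms, keeping
#' only the core rows in their original order -- the gradient-side
#' counterpart of extracting the core block of the Hessian.
#'
#' @param gradient a `phva_gradient` with scope "full".
#' @param system the partitioned `phva_system` it spans.
#' @return A `phva_gradient` with scope "partial".
#' @export
truncate_gradient <- function(gradient, system) {
  stopifnot(inherits(gradient, "phva_gradient"))
  if (gradient$scope != "full") stop("gradient scope is already 'partial'", call. = FALSE)
  if (gradient$n_atoms != n_atoms(system)) {
    stop("gradient spans ", gradient$n_atoms, " atoms but system has ",
         n_atoms(system), call. = FALSE)
  }
  idx <- cart_indices(core_atoms(system))
  property_gradient(gradient$values[idx, , drop = FALSE],
                    kind = gradient$kind, scope = "partial")
}
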