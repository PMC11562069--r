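#' Mass-weighted translation/rotation basis vectors
#'
#' Builds the up-to-six orthonormal mass-weighted vectors spanning rigid
#' translation (D1-D3) and rigid rotation about the principal axes of
#' inertia (D4-D6) of a set of atoms. The atoms are first centered at their
#' center of mass; the inertia tensor is diagonalized to obtain the
#' principal axes. The translation vector along axis j carries sqrt(m) on
#' the j component of every atom; the rotation vector about principal axis
#' k carries sqrt(m) times the cross product of the axis with the atom's
#' center-of-mass-relative position. Each vector is normalized to unit
#' length.
#'
#' For a linear arrangement the rotation about the molecular axis has zero
#' norm and is not generated (two rotation vectors remain); for a single
#' atom no rotation vectors are generated. A rotation vector counts as
#' absent when its pre-normalization squared norm is below 1e-10 times the
#' largest rotational squared norm.
#'
#' In a partial Hessian analysis the basis is built from the core atoms
#' only, matching the dimension of the core block.
#'
#' @param system a `phva_system`.
#' @param subset integer atom indices over which to build the basis;
#'   defaults to the core atoms.
#' @return An object of class `phva_trbasis`: fields `vectors`
#'   (3n x k orthonormal matrix over the subset's Cartesian coordinates),
#'   `labels` (among "Tx","Ty","Tz","R1","R2","R3"), `generated` (named
#'   logical over all six labels), `axes` (principal axes as columns),
#'   `com` (center of mass used, Bohr), `atoms` (the subset indices).
#' @export
build_tr_basis <- function(system, subset = NULL) {
  subset <- subset %||% core_atoms(system)
  if (length(subset) < 1) stop("subset must contain at least one atom", call. = FALSE)
  m <- system$masses[subset]
  r <- system$coords[subset, , drop = FALSE]           # Bohr
  com <- colSums(r * m) / sum(m)
  rc <- sweep(r, 2, com)

  n <- length(subset)
  sm <- sqrt(m)

  # inertia tensor and principal axes
  inertia <- matrix(0, 3, 3)
  for (a in seq_len(n)) {
    ra <- rc[a, ]
    inertia <- inertia + m[a] * (sum(ra^2) * diag(3) - tcrossprod(ra))
  }
  axes <- eigen(inertia, symmetric = TRUE)$vectors

  labels6 <- c("Tx", "Ty", "Tz", "R1", "R2", "R3")
  raw <- matrix(0, 3 * n, 6)
  for (j in 1:3) {                                      # translations
    raw[seq(j, 3 * n, by = 3), j] <- sm
  }
  for (k in 1:3) {                                      # rotations
    ax <- axes[, k]
    cr <- t(apply(rc, 1, function(ra) c(
      ax[2] * ra[3] - ax[3] * ra[2],
      ax[3] * ra[1] - ax[1] * ra[3],
      ax[1] * ra[2] - ax[2] * ra[1]
    )))
    if (n == 1) cr <- matrix(cr, 1, 3)
    raw[, 3 + k] <- as.vector(t(cr * sm))
  }

  norms2 <- colSums(raw^2)
  rot_norm2 <- norms2[4:6]
  keep_rot <- if (max(rot_norm2) == 0) rep(FALSE, 3) else
    rot_norm2 >= 1e-10 * max(rot_norm2)
  keep <- c(rep(TRUE, 3), keep_rot)

  V <- raw[, keep, drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")

  # rotation vectors about degenerate inertia axes can lose orthogonality;
  # apply symmetric (Loewdin) re-orthonormalization only when needed
  gram <- crossprod(V)
  if (max(abs(gram - diag(ncol(V)))) > 1e-8) {
    e <- eigen(gram, symmetric = TRUE)
    V <- V %*% e$vectors %*% diag(1 / sqrt(e$values), ncol(V)) %*% t(e$vectors)
  }

  structure(
    list(
      vectors = V,
      labels = labels6[keep],
      generated = setNames(keep, labels6),
      axes = axes,
      com = com,
      atoms = subset
    ),
    class = "phva_trbasis"
  )
}

#' @export
print.phva_trbasis <- function(x, ...) {
  cat("<phva_trbasis> ", ncol(x$vectors), " vectors (",
      paste(x$labels, collapse = ", "), ") over ",
      length(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Number of translation / rotation vectors in a TR basis
#' @param basis a `phva_trbasis`.
#' @return Integer count.
#' @export
n_translations <- function(basis) sum(startsWith(basis$labels, "T"))

#' @rdname n_translations
#' @export
n_rotations <- function(basis) sum(startsWith(basis$labels, "R"))

#' Project translation and rotation out of a mass-weighted Hessian
#'
#' Applies the Wilson projector P = 1 - sum_j D_j t(D_j) on both sides of
#' the mass-weighted Hessian, forcing every TR basis vector into the null
#' space of the result. For an isolated system this removes the six (five
#' if linear) rigid-body modes exactly; applied to a partial Hessian it
#' instead redistributes the internal motion mixed into pseudo-TR modes --
#' the operation whose side effects the diagnostics in this package
#' quantify.
#'
#' @param h_mw mass-weighted Hessian matrix (3n x 3n over the basis atoms).
#' @param basis a `phva_trbasis` of matching dimension.
#' @return The projected, symmetric mass-weighted matrix.
#' @export
project_tr <- function(h_mw, basis) {
  h_mw <- as.matrix(h_mw)
  if (nrow(h_mw) != nrow(basis$vectors)) {
    stop("Hessian dimension ", nrow(h_mw), " does not match basis dimension ",
         nrow(basis$vectors), call. = FALSE)
  }
  P <- diag(nrow(h_mw)) - tcrossprod(basis$vectors)
  out <- P %*% h_mw %*% P
  (out + t(out)) / 2
}
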