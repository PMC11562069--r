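#' Build a molecular system with a core/environment partition
#'
#' The molecular system is the geometric substrate for all vibrational
#' analysis in the package: element labels, per-atom masses, Cartesian
#' coordinates, and a per-atom tag assigning each atom to the core region
#' (the subsystem whose Hessian block is retained in partial Hessian
#' vibrational analysis) or the environment (frozen surroundings).
#'
#' Coordinates are supplied in Angstrom and stored internally in Bohr; all
#' exported accessors and writers convert back at the boundary.
#'
#' @param atoms character vector of element symbols.
#' @param coords N x 3 numeric matrix of Cartesian coordinates in Angstrom.
#' @param partition character vector, each element "core" or "environment".
#'   Defaults to all-core.
#' @param masses optional numeric vector of per-atom masses in amu;
#'   defaults to the bundled most-abundant-isotope table.
#' @return An object of class `phva_system`.
#' @export
#' @examples
#' water <- molecular_system(
#'   c("O", "H", "H"),
#'   rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692), c(0, -0.7572, -0.4692))
#' )
#' n_atoms(water)
molecular_system <- function(atoms, coords, partition = NULL, masses = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3) {
    stop("coords must be an N x 3 matrix", call. = FALSE)
  }
  n <- length(atoms)
  if (nrow(coords) != n) {
    stop("atoms (", n, ") and coords (", nrow(coords), " rows) disagree",
         call. = FALSE)
  }
  if (is.null(partition)) partition <- rep("core", n)
  if (length(partition) != n || !all(partition %in% c("core", "environment"))) {
    stop("partition must tag each atom 'core' or 'environment'", call. = FALSE)
  }
  if (!any(partition == "core")) {
    stop("at least one atom must be in the core", call. = FALSE)
  }
  if (is.null(masses)) masses <- atomic_mass(atoms)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0)) {
    stop("masses must be ", n, " finite positive values", call. = FALSE)
  }
  structure(
    list(
      atoms = as.character(atoms),
      masses = as.numeric(masses),
      coords = unname(angstrom_to_bohr(coords)),   # Bohr internally
      partition = partition
    ),
    class = "phva_system"
  )
}

#' @export
print.phva_system <- function(x, ...) {
  cat("<phva_system> ", n_atoms(x), " atoms (",
      sum(x$partition == "core"), " core, ",
      sum(x$partition == "environment"), " environment)\n", sep = "")
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `phva_system`.
#' @return Integer atom count.
#' @export
n_atoms <- function(system) length(system$atoms)

#' Indices of core / environment atoms
#' @param system a `phva_system`.
#' @return Integer vector of atom indices (1-based).
#' @export
core_atoms <- function(system) which(system$partition == "core")

#' @rdname core_atoms
#' @export
environment_atoms <- function(system) which(system$partition == "environment")

#' Cartesian coordinates of a system
#' @param system a `phva_system`.
#' @param unit "angstrom" (default) or "bohr".
#' @return N x 3 numeric matrix.
#' @export
coordinates <- function(system, unit = c("angstrom", "bohr")) {
  unit <- match.arg(unit)
  if (unit == "bohr") system$coords else bohr_to_angstrom(system$coords)
}

#' Restrict a system to a subset of its atoms
#'
#' Used to carve the core subsystem out of a full system; the resulting
#' system is all-core unless a partition is re-imposed.
#'
#' @param system a `phva_system`.
#' @param idx integer vector of atom indices to keep.
#' @param partition optional partition tags for the kept atoms.
#' @return A `phva_system` over the selected atoms, order preserved.
#' @export
subset_system <- function(system, idx, partition = NULL) {
  stopifnot(length(idx) >= 1, all(idx >= 1), all(idx <= n_atoms(system)))
  molecular_system(
    atoms = system$atoms[idx],
    coords = bohr_to_angstrom(system$coords[idx, , drop = FALSE]),
    partition = partition %||% rep("core", length(idx)),
    masses = system$masses[idx]
  )
}

#' The core subsystem of a partitioned system
#' @param system a `phva_system`.
#' @return A `phva_system` containing only the core atoms (all tagged core).
#' @export
core_system <- function(system) subset_system(system, core_atoms(system))

# row indices into a 3N-dimensional Cartesian vector for a set of atoms
cart_indices <- function(atom_idx) {
  as.vector(t(outer(atom_idx - 1L, 1:3, function(a, k) 3L * a + k)))
}

#' Tidy per-atom table of a molecular system
#'
#' @param x a `phva_system`.
#' @param ... unused.
#' @return A tibble with one row per atom: index, element, mass, x/y/z in
#'   Angstrom, and partition tag.
#' @export
tidy.phva_system <- function(x, ...) {
  xyz <- coordinates(x)
  tibble::tibble(
    atom = seq_len(n_atoms(x)),
    element = x$atoms,
    mass = x$masses,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    region = x$partition
  )
}
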