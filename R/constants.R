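#' Physical constants and unit conversions
#'
#' CODATA 2018 values used throughout the package. Internal working units are
#' Bohr for coordinates, Hartree/Bohr^2 for Hessians and amu for masses; all
#' user-facing coordinate I/O is in Angstrom. Derived conversion factors (the
#' wavenumber constant, the IR intensity prefactor, the Raman activity unit
#' conversion) are assembled from these values at load time rather than being
#' hard-coded as rounded literals, so they carry full precision.
#'
#' @return A named list with the base constants (SI) and the derived factors:
#'   \describe{
#'     \item{hartree_J}{Hartree energy in joule.}
#'     \item{bohr_m}{Bohr radius in metre.}
#'     \item{amu_kg}{Unified atomic mass unit in kilogram.}
#'     \item{c_ms}{Speed of light in vacuum, m/s.}
#'     \item{e_C}{Elementary charge in coulomb.}
#'     \item{eps0}{Vacuum electric permittivity, F/m.}
#'     \item{avogadro}{Avogadro constant, 1/mol.}
#'     \item{bohr_angstrom}{Bohr radius in Angstrom.}
#'     \item{wavenumber_factor}{cm^-1 per sqrt(Hartree/(Bohr^2 amu)).}
#'     \item{ir_factor}{km/mol per (e/sqrt(amu))^2 of squared dipole derivative.}
#'     \item{raman_factor}{Angstrom^4 per Bohr^4 (fourth power of the length
#'       conversion), turning a.u. polarizability-derivative invariants into
#'       the conventional Angstrom^4/amu activity unit.}
#'   }
#' @export
#' @examples
#' phva_constants()$wavenumber_factor  # ~5140.49
phva_constants <- function() {
  hartree_J <- 4.3597447222071e-18
  bohr_m    <- 0.529177210903e-10
  amu_kg    <- 1.66053906660e-27
  c_ms      <- 299792458
  e_C       <- 1.602176634e-19
  eps0      <- 8.8541878128e-12
  avogadro  <- 6.02214076e23

  # eigenvalue lambda [Hartree Bohr^-2 amu^-1] -> angular frequency^2 [s^-2]
  omega2_SI <- hartree_J / (bohr_m^2 * amu_kg)
  wavenumber_factor <- sqrt(omega2_SI) / (2 * pi * c_ms) / 100

  # |dmu/dQ|^2 in e^2/amu -> km/mol: N_A / (12 eps0 c^2) * (e^2/amu in SI) / 1000
  ir_factor <- avogadro / (12 * eps0 * c_ms^2) * (e_C^2 / amu_kg) / 1000

  bohr_angstrom <- bohr_m * 1e10

  list(
    hartree_J = hartree_J,
    bohr_m = bohr_m,
    amu_kg = amu_kg,
    c_ms = c_ms,
    e_C = e_C,
    eps0 = eps0,
    avogadro = avogadro,
    bohr_angstrom = bohr_angstrom,
    wavenumber_factor = wavenumber_factor,
    ir_factor = ir_factor,
    raman_factor = bohr_angstrom^4
  )
}

.const <- phva_constants()

#' Convert between Angstrom and Bohr
#'
#' @param x numeric vector or matrix of lengths.
#' @return The converted values.
#' @export
angstrom_to_bohr <- function(x) x / .const$bohr_angstrom

#' @rdname angstrom_to_bohr
#' @export
bohr_to_angstrom <- function(x) x * .const$bohr_angstrom

#' Signed harmonic wavenumber from a mass-weighted Hessian eigenvalue
#'
#' Maps an eigenvalue of the mass-weighted Hessian (Hartree Bohr^-2 amu^-1)
#' to a harmonic wavenumber in cm^-1. Negative eigenvalues (imaginary
#' frequencies) are reported as negative wavenumbers of the magnitude that
#' the absolute eigenvalue would give, the usual quantum-chemistry output
#' convention.
#'
#' @param eigenvalue numeric vector of eigenvalues, Hartree Bohr^-2 amu^-1.
#' @return Signed wavenumbers in cm^-1, same length as the input.
#' @export
#' @examples
#' wavenumber_from_eigenvalue(0)
#' wavenumber_from_eigenvalue(c(-0.25, 0.25))
wavenumber_from_eigenvalue <- function(eigenvalue) {
  stopifnot(is.numeric(eigenvalue), all(is.finite(eigenvalue)))
  sign(eigenvalue) * .const$wavenumber_factor * sqrt(abs(eigenvalue))
}

# Atomic masses of the most abundant isotope, amu (AME2020 rounded to the
# precision typical of quantum-chemistry mass tables). Overridable per atom
# through the `masses` argument of molecular_system() or a config file.
.atomic_masses <- c(
  H  = 1.00782503, He = 4.00260325,
  Li = 7.01600344, Be = 9.01218307, B  = 11.00930536, C  = 12.0,
  N  = 14.00307401, O  = 15.99491462, F  = 18.99840316, Ne = 19.99244018,
  Na = 22.98976928, Mg = 23.98504170, Al = 26.98153853, Si = 27.97692653,
  P  = 30.97376200, S  = 31.97207117, Cl = 34.96885268, Ar = 39.96238312,
  K  = 38.96370649, Ca = 39.96259086, Ti = 47.94794198, Cr = 51.94050623,
  Mn = 54.93804391, Fe = 55.93493633, Co = 58.93319429, Ni = 57.93534241,
  Cu = 62.92959772, Zn = 63.92914201, Br = 78.91833760, Kr = 83.91149773,
  I  = 126.9044719
)

#' Look up atomic masses by element symbol
#'
#' Masses are those of the most abundant isotope. Unknown symbols are an
#' error unless an override is supplied.
#'
#' @param symbols character vector of element symbols (case sensitive, e.g.
#'   "H", "He").
#' @param overrides optional named numeric vector of per-symbol masses that
#'   take precedence over the bundled table.
#' @return Numeric vector of masses in amu.
#' @export
atomic_mass <- function(symbols, overrides = NULL) {
  tab <- .atomic_masses
  if (!is.null(overrides)) tab[names(overrides)] <- overrides
  m <- unname(tab[symbols])
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(m)]), collapse = ", "),
         " (supply a mass override)", call. = FALSE)
  }
  m
}
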