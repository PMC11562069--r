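#' Read a molecular system from an XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' "element x y z" line per atom with coordinates in Angstrom. The
#' partition defaults to all-core; supply `core` (1-based atom indices,
#' the chemistry convention used in all user-facing files) to tag the
#' remaining atoms as environment.
#'
#' @param path file path.
#' @param core optional integer vector of 1-based core atom indices.
#' @param mass_overrides optional named vector of per-element masses.
#' @return A `phva_system`.
#' @export
read_xyz <- function(path, core = NULL, mass_overrides = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("XYZ file too short: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("line 1 of ", path, " is not an atom count", call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop("XYZ file declares ", n, " atoms but has ", length(body),
         " atom lines (first missing: line ", length(body) + 3, ")",
         call. = FALSE)
  }
  toks <- strsplit(trimws(body[seq_len(n)]), "\\s+")
  atoms <- vapply(toks, `[`, "", 1)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (n == 1) xyz <- matrix(xyz, 1, 3)
  partition <- rep("core", n)
  if (!is.null(core)) {
    partition <- rep("environment", n)
    partition[core] <- "core"
  }
  molecular_system(atoms, xyz, partition,
                   masses = atomic_mass(atoms, mass_overrides))
}

#' Write a molecular system as an XYZ file
#'
#' @param system a `phva_system`.
#' @param path output file.
#' @param comment comment line content.
#' @return Invisibly, the path.
#' @export
write_xyz <- function(system, path, comment = "written by phva") {
  xyz <- coordinates(system)
  lines <- c(
    as.character(n_atoms(system)),
    comment,
    sprintf("%-3s % .10e % .10e % .10e",
            system$atoms, xyz[, 1], xyz[, 2], xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a Cartesian Hessian from plain text
#'
#' Two dialects are auto-detected from the number of whitespace-separated
#' values: the full 3N x 3N matrix in row-major order ((3N)^2 values), or
#' the lower triangle in row-major order (3N(3N+1)/2 values), both in
#' Hartree/Bohr^2. The result passes through the package's symmetry
#' policy (see [hessian_matrix()]).
#'
#' @param path file path.
#' @param n_atoms atom count N of the Hessian's scope.
#' @param scope "full" or "partial".
#' @return A `phva_hessian`.
#' @export
read_hessian <- function(path, n_atoms, scope = "full") {
  vals <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  d <- 3L * n_atoms
  if (length(vals) == d^2) {
    H <- matrix(vals, d, d, byrow = TRUE)
  } else if (length(vals) == d * (d + 1) / 2) {
    H <- matrix(0, d, d)
    H[upper.tri(H, diag = TRUE)] <- vals     # column-major upper == row-major lower
    H <- H + t(H) - diag(diag(H))
  } else {
    stop("Hessian file has ", length(vals), " values; expected ", d^2,
         " (full) or ", d * (d + 1) / 2, " (lower triangle) for ",
         n_atoms, " atoms", call. = FALSE)
  }
  hessian_matrix(H, scope = scope)
}

#' Write a Hessian as plain text (full square dialect)
#'
#' @param hessian a `phva_hessian`.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_hessian <- function(hessian, path) {
  utils::write.table(format(hessian$matrix, digits = 10, scientific = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Cartesian property gradient table
#'
#' Plain text, 3N rows of 3 (dipole) or 6 (polarizability, ordered
#' xx xy xz yy yz zz) whitespace-separated values in atomic units.
#'
#' @param path file path.
#' @param kind "dipole" or "polarizability".
#' @param scope "full" or "partial".
#' @return A `phva_gradient`.
#' @export
read_gradient <- function(path, kind = c("dipole", "polarizability"),
                          scope = "full") {
  kind <- match.arg(kind)
  tab <- as.matrix(utils::read.table(path, comment.char = "#"))
  property_gradient(tab, kind = kind, scope = scope)
}

#' @rdname read_gradient
#' @param gradient a `phva_gradient` (for writing).
#' @export
write_gradient <- function(gradient, path) {
  utils::write.table(format(gradient$values, digits = 10, scientific = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write normal modes in Molden format
#'
#' Emits [Molden Format] with [FREQ] (wavenumbers in cm^-1), [FR-COORD]
#' (coordinates in Bohr), [FR-NORM-COORD] (one Cartesian displacement
#' block per mode), and, when intensities are given, [INT]. An empty mode
#' set produces a valid file with zero mode blocks.
#'
#' @param path output file.
#' @param system a `phva_system` over the modes' atoms.
#' @param modes a `phva_modes` with displacements.
#' @param intensities optional per-mode intensities for the [INT] section.
#' @return Invisibly, the path.
#' @export
write_molden_modes <- function(path, system, modes, intensities = NULL) {
  if (is.null(modes$displacements)) {
    stop("modes carry no Cartesian displacements; diagonalize with masses",
         call. = FALSE)
  }
  nm <- n_modes(modes)
  out <- c("[Molden Format]", "[FREQ]",
           sprintf("%14.6f", modes$wavenumbers),
           "[FR-COORD]",
           sprintf("%-3s % .10f % .10f % .10f", system$atoms,
                   system$coords[, 1], system$coords[, 2], system$coords[, 3]),
           "[FR-NORM-COORD]")
  for (i in seq_len(nm)) {
    d <- matrix(modes$displacements[, i], ncol = 3, byrow = TRUE)
    out <- c(out, sprintf("vibration %d", i),
             sprintf(" % .10f % .10f % .10f", d[, 1], d[, 2], d[, 3]))
  }
  if (!is.null(intensities)) {
    out <- c(out, "[INT]", sprintf("%14.6f", intensities))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a key-value configuration file
#'
#' Simple "key = value" lines; '#' starts a comment. Recognized keys:
#' `core` (comma/space separated 1-based atom indices), `threshold`
#' (pseudo-TR flagging threshold), `exclude_lowest`, `linearity_tolerance`,
#' and `mass.<El>` entries overriding the mass of element El.
#'
#' @param path file path.
#' @return A named list with parsed values; `mass_overrides` is a named
#'   numeric vector (possibly empty).
#' @export
read_phva_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  cfg <- list(mass_overrides = numeric(0))
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (key == "core") {
      cfg$core <- as.integer(strsplit(val, "[,[:space:]]+")[[1]])
    } else if (key %in% c("threshold", "linearity_tolerance")) {
      cfg[[key]] <- as.numeric(val)
    } else if (key == "exclude_lowest") {
      cfg$exclude_lowest <- as.integer(val)
    } else if (startsWith(key, "mass.")) {
      el <- sub("^mass\\.", "", key)
      cfg$mass_overrides[el] <- as.numeric(val)
    }
  }
  cfg
}
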