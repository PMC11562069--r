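#' Pseudotranslational and pseudorotational contributions of a mode
#'
#' For a normalized mode vector L and the mass-weighted TR basis vectors
#' D_j, the pseudotranslational contribution is the sum over the generated
#' translation vectors of (t(D_j) L)^2, and the pseudorotational
#' contribution is the same sum over the generated rotation vectors. Both
#' lie in [0, 1] and, over a complete orthonormal mode set, sum to the
#' number of generated translation (resp. rotation) vectors.
#'
#' In a partial Hessian these quantify how much of the mode is a rigid
#' displacement of the core against the frozen environment -- motion the
#' partial Hessian describes poorly.
#'
#' @param mode a unit 3n-vector, or a 3n x m matrix of orthonormal mode
#'   columns (then a vector of m values is returned).
#' @param basis a `phva_trbasis` over the same atoms.
#' @return Numeric contribution(s) in [0, 1].
#' @export
ptc <- function(mode, basis) .tr_contribution(mode, basis, "T")

#' @rdname ptc
#' @export
prc <- function(mode, basis) .tr_contribution(mode, basis, "R")

.tr_contribution <- function(mode, basis, which_kind) {
  M <- if (is.matrix(mode)) mode else matrix(mode, ncol = 1)
  if (nrow(M) != nrow(basis$vectors)) {
    stop("mode dimension ", nrow(M), " does not match basis dimension ",
         nrow(basis$vectors), call. = FALSE)
  }
  norms <- sqrt(colSums(M^2))
  if (any(abs(norms - 1) > 1e-8)) {
    stop("mode vectors must be normalized (norm deviation ",
         format(max(abs(norms - 1))), ")", call. = FALSE)
  }
  sel <- startsWith(basis$labels, which_kind)
  if (!any(sel)) return(rep(0, ncol(M)))
  D <- basis$vectors[, sel, drop = FALSE]
  colSums(crossprod(D, M)^2)
}

#' Diagnose pseudotranslation/pseudorotation across a mode set
#'
#' Computes per-mode pseudotranslational (PTC) and pseudorotational (PRC)
#' contributions, verifies the completeness sum rules (the PTC total must
#' equal the number of translation vectors and the PRC total the number of
#' rotation vectors, since the modes form an orthonormal basis and the TR
#' vectors are normalized), and flags modes whose combined PTC + PRC
#' exceeds a threshold. Flagged modes are candidates for removal: they are
#' collective core-against-environment motions that the partial Hessian
#' does not describe reliably.
#'
#' @param modes a `phva_modes` over the basis atoms (complete orthonormal
#'   set).
#' @param basis a `phva_trbasis` over the same atoms.
#' @param threshold flagging threshold on PTC + PRC; default 0.01,
#'   i.e. modes carrying more than 1 percent combined TR character.
#' @param separate_thresholds optional numeric length-2 vector
#'   c(ptc, prc); when supplied a mode is flagged if either contribution
#'   exceeds its own threshold, instead of the combined rule.
#' @return An object of class `phva_diagnostics`: a per-mode tibble
#'   (`table` with mode, wavenumber, ptc, prc, flagged), the threshold(s),
#'   and the sum-rule residuals.
#' @export
diagnose_modes <- function(modes, basis, threshold = 0.01,
                           separate_thresholds = NULL) {
  stopifnot(inherits(modes, "phva_modes"), inherits(basis, "phva_trbasis"))
  p_t <- ptc(modes$vectors, basis)
  p_r <- prc(modes$vectors, basis)

  res_t <- sum(p_t) - n_translations(basis)
  res_r <- sum(p_r) - n_rotations(basis)
  if (n_modes(modes) == nrow(basis$vectors)) {
    if (abs(res_t) > 1e-6 || abs(res_r) > 1e-6) {
      stop("sum-rule residual (", format(res_t), ", ", format(res_r),
           ") exceeds 1e-6: modes and TR basis are inconsistent",
           call. = FALSE)
    }
  }

  flagged <- if (is.null(separate_thresholds)) {
    p_t + p_r > threshold
  } else {
    p_t > separate_thresholds[1] | p_r > separate_thresholds[2]
  }

  structure(
    list(
      table = tibble::tibble(
        mode = seq_along(p_t),
        wavenumber = modes$wavenumbers,
        ptc = p_t,
        prc = p_r,
        flagged = flagged
      ),
      threshold = threshold,
      separate_thresholds = separate_thresholds,
      sum_residuals = c(ptc = res_t, prc = res_r),
      n_translations = n_translations(basis),
      n_rotations = n_rotations(basis)
    ),
    class = "phva_diagnostics"
  )
}

#' @export
print.phva_diagnostics <- function(x, ...) {
  cat("<phva_diagnostics> ", nrow(x$table), " modes, ",
      sum(x$table$flagged), " flagged (threshold ",
      format(x$threshold), ")\n", sep = "")
  cat("  sum rules: total PTC = ",
      format(x$n_translations + x$sum_residuals["ptc"]),
      " (expected ", x$n_translations, "), total PRC = ",
      format(x$n_rotations + x$sum_residuals["prc"]),
      " (expected ", x$n_rotations, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.phva_diagnostics <- function(x, ...) x$table

#' @export
glance.phva_diagnostics <- function(x, ...) {
  tibble::tibble(
    n_modes = nrow(x$table),
    n_flagged = sum(x$table$flagged),
    threshold = x$threshold,
    ptc_total = sum(x$table$ptc),
    prc_total = sum(x$table$prc),
    ptc_residual = unname(x$sum_residuals["ptc"]),
    prc_residual = unname(x$sum_residuals["prc"])
  )
}

#' Bar chart of per-mode TR character
#'
#' @param object a `phva_diagnostics`.
#' @param ... unused.
#' @return A ggplot object: stacked PTC/PRC bars per mode, flagged modes
#'   marked.
#' @export
autoplot.phva_diagnostics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$table, c("ptc", "prc"),
                            names_to = "kind", values_to = "contribution")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$contribution,
                                   fill = toupper(.data$kind))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "mode", y = "contribution", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Remove flagged pseudo-TR modes from a mode set
#'
#' Drops the modes flagged by [diagnose_modes()] and keeps the survivors
#' untouched: no re-diagonalization, no projection -- surviving
#' eigenvalues and eigenvectors are bitwise identical to the input. This
#' is the filtering alternative to Wilson TR projection: projection
#' redistributes the internal motion of mixed modes onto the survivors,
#' whereas removal leaves them alone.
#'
#' @param modes a `phva_modes`.
#' @param diagnostics a `phva_diagnostics` computed from `modes`.
#' @return A list with `modes` (the retained `phva_modes`, possibly empty)
#'   and `removed` (integer indices of the dropped modes).
#' @export
filter_modes <- function(modes, diagnostics) {
  stopifnot(inherits(modes, "phva_modes"),
            inherits(diagnostics, "phva_diagnostics"))
  if (nrow(diagnostics$table) != n_modes(modes)) {
    stop("diagnostics cover ", nrow(diagnostics$table),
         " modes but the set has ", n_modes(modes), call. = FALSE)
  }
  removed <- which(diagnostics$table$flagged)
  keep <- setdiff(seq_len(n_modes(modes)), removed)
  retained <- structure(
    list(
      values = modes$values[keep],
      vectors = modes$vectors[, keep, drop = FALSE],
      wavenumbers = modes$wavenumbers[keep],
      displacements = if (!is.null(modes$displacements))
        modes$displacements[, keep, drop = FALSE],
      masses = modes$masses,
      scope = modes$scope
    ),
    class = "phva_modes"
  )
  list(modes = retained, removed = removed)
}
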