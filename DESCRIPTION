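Package: phva
Title: Partial Hessian Vibrational Analysis with Pseudotranslation and
    Pseudorotation Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonic vibrational analysis for core/environment-partitioned
    molecular systems. Implements partial Hessian vibrational analysis (PHVA),
    construction of mass-weighted translation/rotation basis vectors from the
    principal axes of inertia, quantification of pseudotranslational and
    pseudorotational contributions in normal modes, mode filtering as an
    alternative to Wilson-style translation-rotation projection, IR intensities
    and Raman activities from Cartesian dipole and polarizability gradients,
    and metrics (environmental contribution, angular deviation, frequency and
    intensity differences) for comparing normal modes obtained from full,
    partial, and embedded Hessians. Includes a generator of analytic harmonic
    spring fixtures, including caged-solute models, so every stage of the
    pipeline can be exercised without electronic-structure software.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
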