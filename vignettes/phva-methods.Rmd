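---
title: "Partial Hessian vibrational analysis: model, diagnostics, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial Hessian vibrational analysis: model, diagnostics, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phva)
```

## The problem this package addresses

In hybrid calculations on a solute embedded in a (frozen) solvent
environment, only the core–core block of the nuclear Hessian is computed
and diagonalized: partial Hessian vibrational analysis (PHVA). The
approximation is cheap and usually good for localized, high-frequency
vibrations, but it manufactures a class of artifact modes. Because the
environment atoms are absent from the partial Hessian, the core can move
*as a whole* against the frozen surroundings; the resulting low-frequency
eigenvectors resemble rigid translations and rotations of the core —
*pseudotranslation* and *pseudorotation* — mixed to varying degree with
genuine internal motion. Two treatments exist:

1. **Projection** (Wilson): apply `P = 1 − Σ_j D_j D_jᵀ` to the
   mass-weighted Hessian before diagonalizing, forcing six zero modes.
   This is rigorous for an isolated molecule, where the potential truly is
   invariant under rigid motion. For a partial Hessian it is unfounded:
   the pseudo-TR modes are real, finite-frequency vibrations of the
   core-in-cage system, and projecting them away redistributes whatever
   internal motion they contained onto all remaining modes, shifting
   frequencies and reshuffling intensities of modes that were unaffected
   by the approximation.
2. **Diagnosis and removal** (the approach implemented here as the
   default): quantify the TR character of each mode and drop the
   contaminated ones, leaving every surviving eigenpair untouched.

Both operations are provided (`project_tr()`, `diagnose_modes()` +
`filter_modes()`), precisely so their consequences can be compared; the
package's tests assert the contrast quantitatively (removal is bitwise
inert on survivors; projection moves surviving frequencies and per-mode
intensities while conserving the total IR intensity, which is a trace
invariant of the complete orthonormal mode basis).

## The diagnostics

With core masses $m_\alpha$, center-of-mass-relative positions
$\mathbf R_\alpha$, and principal inertia axes $\mathbf I_k$ (eigenvectors
of the inertia tensor), the mass-weighted rigid-motion vectors are

$$\mathbf D_{k} \propto \sqrt{m_\alpha}\,\hat{\mathbf e}_k
  \quad (k = 1,2,3), \qquad
  \mathbf D_{3+k} \propto \sqrt{m_\alpha}\,
  (\mathbf I_k \times \mathbf R_\alpha),$$

each normalized to unit length. For normalized eigenvectors
$\mathbf L_i$ of the mass-weighted partial Hessian,

$$\mathrm{PTC}_i = \sum_{j=1}^{3} (\mathbf D_j \cdot \mathbf L_i)^2,
  \qquad
  \mathrm{PRC}_i = \sum_{j=4}^{6} (\mathbf D_j \cdot \mathbf L_i)^2 .$$

Because the $\mathbf D_j$ are normalized and the $\mathbf L_i$ form an
orthonormal basis, the totals obey exact sum rules: $\sum_i
\mathrm{PTC}_i$ equals the number of translation vectors (always 3) and
$\sum_i \mathrm{PRC}_i$ the number of rotation vectors (3, or 2 for a
linear core). `diagnose_modes()` recomputes these sums on every call,
records the residuals, and errors if they exceed $10^{-6}$ — an
inconsistent mode set or basis cannot pass silently. The squared-overlap
form is forced by these sum rules; the orientation of the cross product in
the rotation vectors only flips signs and leaves PTC/PRC unchanged.

For full-vs-partial comparisons, each normalized full-Hessian eigenvector
is split into its core part $\mathbf C_i$ and environment part
$\mathbf E_i$; the environmental contribution is
$\mathrm{EC}_i = \lVert\mathbf E_i\rVert^2$ (so core weight plus EC is
exactly 1, and direction information is kept separate). Partial modes are
matched to full modes by a globally optimal one-to-one assignment on the
absolute overlaps $|\mathbf C_i \cdot \mathbf L_j^{\mathrm{PH}}|$ —
optimal rather than greedy, because greedy matching is order dependent and
swaps near-degenerate pairs. Matched pairs are scored by the angular
deviation $\mathrm{AD} = \arccos|\hat{\mathbf C}_i \cdot \mathbf
L_j^{\mathrm{PH}}|$ in degrees (absolute values make it immune to the
arbitrary eigenvector phase), the absolute frequency difference, and two
intensity-difference conventions: relative (absolute difference over the
reference value; a zero reference with a nonzero difference yields `NA`,
never infinity) and normalized absolute (absolute difference divided by
the largest absolute difference among all pairs except the excluded
lowest-frequency ones).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.01 | flag a mode when PTC + PRC exceeds this fraction; 1 % TR character is already enough to visibly perturb intensities, and the genuine vibrations of weakly caged cores sit orders of magnitude below it. Separate PTC/PRC thresholds are available via `separate_thresholds`. |
| `exclude_lowest` | 6 | matched pairs whose comparison-set modes have the lowest wavenumbers are excluded from the normalized-difference denominator (they are the pseudo-TR set); use 5 for a linear core. |
| linearity tolerance | 1e-10 (relative, squared norm) | a rotation vector is "not generated" when its pre-normalization squared norm falls below this fraction of the largest rotational squared norm. |
| Hessian symmetry | accept ≤ 1e-8; symmetrize with warning ≤ 1e-6; error beyond | parsed and finite-difference Hessians are never exactly symmetric. |
| mode normalization | 1e-8 | PTC/PRC inputs must be unit vectors to this tolerance. |

Internal units are Bohr, Hartree/Bohr², and amu; coordinates cross the I/O
boundary in Å, and atom indices in user-facing files are 1-based. The
wavenumber conversion constant (≈ 5140.49 cm⁻¹ per
$\sqrt{E_h\,a_0^{-2}\,\mathrm{amu}^{-1}}$), the IR prefactor
(≈ 974.9 km/mol per (e²/amu)), and the Raman unit conversion are assembled
from CODATA 2018 constants at load time, never hard-coded as rounded
literals. Atomic masses are those of the most abundant isotope and can be
overridden per element; whether isotopic or abundance-averaged masses are
appropriate for a given comparison is a user decision, which is why the
override exists.

## What the synthetic generator emulates — and what it does not

The fixture module builds analytic harmonic systems whose Hessians are
exact:

- `spring_hessian()` gives the closed-form second derivatives of a
  pairwise spring network (verified against central finite differences to
  1e-6);
- `build_caged_solute()` surrounds a mobile core with explicit cage atoms
  tethered by springs and realizes "immobility" exactly the way PHVA does
  — by keeping only the core–core block — rather than by infinite masses,
  so it reproduces the approximation under study, not a proxy for it;
- `random_system()` produces seeded random fixtures whose full
  mass-weighted Hessian is built as $P A A^{\mathsf T} P$ with $P$ the TR
  projector, guaranteeing positive semidefiniteness and an *exact*
  six-dimensional rigid-motion null space by construction.

Default study conditions, chosen once: cores of 3–4 light atoms with bond
springs around 0.35 Hartree/Bohr² (stretch frequencies in the
3000 cm⁻¹ range), cages of 6–8 sites at ~3 Å with tether constants
0.005–0.03 Hartree/Bohr² — the weak-cage regime in which pseudo-TR modes
appear at tens to hundreds of cm⁻¹ below the internal vibrations, which is
where the diagnostic question is interesting. Tethers are created at their
current length, so the assembled geometry is a true equilibrium and no
spurious imaginary modes appear; the price is that tethers have no
transverse stiffness, leaving some pseudo modes at numerically zero
frequency (see below).

What the generator does **not** emulate: real electrostatic embedding
(polarizable or otherwise), anharmonicity, many-body force fields,
realistic solvent structure, or property gradients of correlated charge
distributions (dipole gradients come from a rigid point-charge model,
polarizability gradients are random smooth tables). Passing tests
therefore demonstrate that the *algebra* of the pipeline — eigenanalysis,
TR construction, sum rules, matching, metric conventions, unit
conversions — is correct and stable; they say nothing about how large
pseudo-TR contamination is in any real solute–solvent system.

## Numerical choices

- **Determinism.** Eigenvalues are sorted ascending; exact ties are broken
  by the atom index carrying the dominant eigenvector coefficient, and
  each eigenvector's sign is fixed so its largest-magnitude component is
  positive. Matching ties (equal absolute overlaps) resolve toward pairing
  lower full indices with lower partial indices via a swap-neutral
  post-pass over the optimal assignment.
- **Degenerate inertia moments.** Principal axes from the inertia-tensor
  eigendecomposition are accepted as-is; orthonormality of the resulting
  basis is verified post hoc and symmetric (Löwdin) re-orthonormalization
  applied only if the Gram residual exceeds 1e-8. The freedom in choosing
  degenerate axes never matters for the diagnostics: PTC/PRC depend only
  on the projectors onto the translation and rotation spans, which the
  tests assert by re-mixing rotation vectors in place.
- **Numerically degenerate clusters.** Eigenvectors within a degenerate
  eigenvalue cluster are individually arbitrary — any orthogonal mixture
  is equally valid, and different arithmetic (a rotated frame, a different
  LAPACK path) yields different members. Per-mode quantities are therefore
  only meaningful for spectrally isolated modes; for clusters, the
  invariant content is the cluster total (of PTC + PRC, of intensity).
  The test suite is written accordingly.
- **Zero-frequency noise.** A numerically zero eigenvalue of magnitude
  ~1e-15 maps through the square root to a wavenumber of ~1e-4 cm⁻¹, so
  "zero" modes fluctuate at that scale between equivalent computations;
  assertions on them use windows well above it.
- **Angle conditioning.** Near 0° the arccosine amplifies dot-product
  rounding: a 1e-12 error in the cosine is ~1e-7 degrees at θ ≈ 0.04°.
  Angular-deviation comparisons between equivalent computations therefore
  use an absolute band of 1e-6 degrees rather than a relative one.
- **Why the linear-molecule fixtures are synthetic.** A collinear chain
  bound by pair springs has *seven* zero modes, not five: bending carries
  no restoring force at equilibrium. The five-zero linear case is
  exercised with a constructed Hessian (TR-projected PSD form) that is
  stiff in every non-TR direction; sum-rule checks, which require only a
  complete orthonormal eigenbasis, use the spring chain unchanged.
- **Exact decoupled limit.** The end-to-end zero test of the comparison
  pipeline uses a block-diagonal fixture whose core and environment blocks
  have strictly distinct spectra, making every eigenvector unique up to
  sign. A spring cage at zero coupling would instead have a large
  degenerate zero eigenspace mixing core-TR and cage directions, for
  which per-pair metrics are undefined rather than zero.

## Problem sizes

The shipped tests and the acceptance script run on systems of 2–11 atoms
(6–33 Cartesian coordinates), 20–50 random seeds per property, chosen as
the smallest sizes at which every phenomenon of interest — pseudo-TR
mixing, projection redistribution, degenerate clusters, linear cores — is
present; the whole suite completes in seconds.

## Known limitations

- Raman output is the frequency-independent activity invariant; any
  incident-frequency dependence must already live in the supplied
  polarizability gradients. Cross-sections with Boltzmann/temperature
  factors are out of scope.
- Removed modes' intensity is not re-assigned to survivors; filtering
  reports what remains, by design.
- The Hungarian matcher is O(n³) in plain R; fine for the hundreds of
  modes typical of PHVA cores, not tuned for thousands.
- No parsers for native quantum-chemistry output formats are included;
  Hessians and gradients enter as plain-text tables (two dialects
  auto-detected), geometries as XYZ.
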