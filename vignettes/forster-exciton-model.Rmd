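---
title: "A semiempirical Förster/exciton model for pigment-protein networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semiempirical Förster/exciton model for pigment-protein networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigmentnet)
```

## The problem and the model

Photosynthetic antenna complexes concentrate chlorophylls (Chl a, b, c1)
and carotenoids at nanometre spacings. After photon absorption, the
excitation can hop between pigments (excitation energy transfer, EET) or
relax within one pigment (internal conversion, IC). For the low-energy Q
band, IC to the ground state is slow (nanoseconds) and EET wins easily.
For the Soret (B) band, IC down to Q is ultrafast (on the order of 100 fs),
so the interesting question is quantitative: are Soret-band couplings and
rates large enough for EET to compete at all — the anti-Kasha scenario —
and how do the accessory pigments change that picture?

`pigmentnet` answers this with a deliberately transparent, semiempirical
chain:

1. **Geometry.** Pigments come from a PDB/mmCIF file (or a seeded
   generator). A chlorophyll's interaction centre is its Mg atom; a
   carotenoid's is the unweighted centroid of its conjugated carbons
   (all carbons are equal mass, so centroid and centre of mass
   coincide). Transition-dipole directions run along named atom pairs —
   the macrocycle nitrogen trans-axes NB→ND (Q) and NA→NC (B) by
   default, overridable per class or per site through the axis table.
   The shipped pairs are a documented convention; curated per-pigment
   tables should be loaded when available. Coordinates stay in the
   file's frame; multimers are taken as deposited.
2. **Couplings.** Screened point dipoles,
   `V = C_dip * kappa * mu_i * mu_j / (n^2 R^3)`, with `C_dip`
   derived from first principles (5.034 cm⁻¹ nm³ D⁻² to four
   significant figures, unit-tested against an SI-unit evaluation) and
   `n = 1.4` for the protein medium. The point-dipole form is the
   conservative choice: it underestimates close-range couplings relative
   to transition-density methods, which biases against, not toward, the
   effect under study.
3. **Overlap densities.** The density of interacting states between a
   donor and an acceptor is the integral of the two area-normalized line
   shapes on a common wavenumber grid — units cm, computed
   trapezoidally on the intersection of supports at the finer grid
   spacing. This convention is dimensionally consistent with the rate
   kernel below; the older wavelength-domain λ⁴-weighted ratio is kept
   only as a diagnostic (`rho_lambda4_ratio()`), because its literal
   units cannot feed a rate. Wavelength-domain inputs are treated as
   densities per nm and converted with the λ²/10⁷ Jacobian before
   normalization, so the line shape does not depend on the grid
   convention of the source file.
4. **Rates and efficiencies.** `k = 4 pi^2 c V^2 rho` (the
   wavenumber-domain realization of the golden rule), reported in ns⁻¹.
   Efficiencies are branching ratios of summed EET rates against summed
   EET plus IC rates; every EET channel of a donor competes with that
   donor's single IC process. Overlap densities are computed once per
   ordered (donor class, acceptor class, band) and shared across site
   pairs — class-level granularity; per-site spectra are out of scope.
5. **Excitons.** Per band, a real symmetric Hamiltonian with site
   energies on the diagonal (experimental band maximum plus a per-site
   shift) and couplings off it. Eigenvector weights are squared
   coefficients; delocalization per exciton is the inverse participation
   ratio `1 / sum(w^2)`, between 1 and N.
6. **Absorption.** A Lambert–Beer ensemble absorbance and an
   absorbed-photon score `P = int I (1 - 10^-A) dlambda` against a solar
   photon-flux spectrum, with per-class contributions expressed as
   fractions of the wild-type `P`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| refractive index `n` | 1.4 | — | protein interior screening |
| `tau_Q` (Chl) | 6.3 | ns | Q→S0 lifetime of Chl a |
| `tau_B` (Chl) | 1e-4 (100 fs) | ns | B→Q; the low end of reported values, biasing against Soret EET |
| `tau` (Crt S2) | 1.5e-4 | ns | sub-picosecond bright-state decay |
| Crt relaxation | 0.8 | eV | lowers the Crt bright-band energy to its relaxed emitting state for the Q-band Hamiltonian |
| weight threshold | 0.1 | — | minimum squared coefficient for "exciton on pigment" assignments |
| multimer order `q` | 1 | — | class-pair averages over a trimer/tetramer are multiplied by 3/4 so the many near-zero inter-subunit pairs do not mask the intra-subunit scale |
| windows | 350–800, 350–500 | nm | full spectrum and Soret-band absorption scoring |
| `cl_factor` | 1e-6 | — | dimensionless concentration × path length; set so the shipped fixture peaks near A ≈ 1, the regime where contribution analysis is informative |

All of these surface as arguments or named config keys; none is hard-coded
in the computational kernels. Energies are carried in cm⁻¹ internally;
eV inputs convert at 8065.544 cm⁻¹/eV.

## The synthetic fixtures

The generators make every stage testable offline. They emulate the
*structure* of real inputs, not their numbers:

* `make_toy_complex()` — rejection-sampled centres in a 40 Å box with a
  10 Å minimum separation (typical nearest-neighbour Mg–Mg distances),
  random orientations realized as synthetic atoms so the same axis-table
  machinery applies. Default census is CP24-like: 11 chlorophylls
  (6 a + 5 b) and 3 carotenoids.
* `make_toy_spectral_library()` — Gaussian bands in the wavenumber
  domain. Chl Q bands sit at 662/645/630 nm (a/b/c1) with σ = 320 cm⁻¹
  and 250 cm⁻¹ Stokes shifts; Soret bands at 430/460/460 nm with
  σ = 900 cm⁻¹, peak extinctions above the Q-band ones, and dipoles
  twice the Q dipoles (6.45 D for Chl a Q, matching the
  reverse-engineered experimental scale). Accessory-Chl Soret bands are
  red-shifted relative to Chl a's so they act as Soret-band energy
  sinks, and the carotenoid is one broad bright band at 490 nm
  (σ = 1500 cm⁻¹, 13 D) overlapping the Chl Soret window, with its
  relaxed state 0.8 eV lower. These choices were made once so that the
  qualitative orderings a real antenna shows (Soret/Q coupling ratio of
  several, Stokes-shift asymmetry of the overlap densities, downhill
  donation favoured, accessory-pigment sink) all manifest; they are
  documented conventions, not fits, and no generator parameter encodes
  a numerical claim about any deposited structure or measured spectrum.
* `make_toy_irradiance()` — a 5800 K blackbody-shaped photon flux for
  the surface scene and a 100 m depth scene attenuated by a toy
  K(λ) that rises with wavelength, leaving blue-dominated light.

Every generator is a pure function of its spec including the seed
(`with_seed` restores global random state), and golden-file tests pin the
seed-42 fixture.

What passing tests on these fixtures shows: the kernels, conventions and
orderings are implemented correctly and deterministically. What it does
not show: agreement with measured couplings, overlap matrices or
absorption gains of real LHCII/CP24/CP26/CP29/FCP — those require the
deposited structures, curated axis/shift tables and experimental spectra,
which the package accepts through the same interfaces but does not ship.

## Numerical choices and degenerate inputs

* Integration is trapezoidal everywhere; overlap grids are the
  intersection of supports at the finer median spacing. Halving the grid
  changes the Gaussian self-overlap by well under 0.5%.
* `eigen(symmetric = TRUE)` does the diagonalization; eigenvalues are
  re-sorted ascending. Sign convention: the largest-magnitude
  coefficient of each eigenvector is made positive. Within numerically
  degenerate blocks (relative gap < 1e-9) excitons are ordered by their
  leading-weight site index, so reports are reproducible.
* Disjoint spectral supports give a zero overlap with a warning, not an
  error; a zero coupling or zero overlap gives exactly zero rate.
* Degenerate dipole axes (atom pair closer than 1e-6 Å), missing Mg
  atoms, empty conjugated-carbon sets, coincident centres, band
  mismatches and unnormalized weight vectors are all hard errors naming
  the offending site.
* Site shifts above 0.1 eV in magnitude warn (they are outside the usual
  protein-pocket range) but proceed; a missing B-band shift falls back to
  the site's Q-band shift.
* Artifact files embed the package version, a config hash and the seed,
  with pinned number formatting, so identical configs rewrite
  byte-identical outputs.

## Open design points, decided

* **Substitution direction.** The all-Chl-a experiment can be read as
  "replace Chl b/c by Chl a" or the reverse; both directions are
  supported (`standard_configurations()` ships ALL_CHL_A; a custom
  directive expresses the reverse). Substituted sites keep their
  geometry and axis atoms and swap only spectral identity.
* **Carotenoids in the Q-band Hamiltonian.** Included by default via
  their relaxed (bright band − 0.8 eV) energy, reflecting that such
  states can mix into the Q-energy range; `crt_q_participation = FALSE`
  removes them, and reports flag the choice. The default likely
  overstates Crt participation — constant intermixing of relaxed Crt
  states is not expected physically.
* **Class-pair averages** are over |V| (bar-height style); a signed mode
  is kept for diagnostics. Standard errors use the number of
  contributing pairs.
* **Contribution conventions.** Carotenoid contributions use the
  remove variant (Crts are additions on top of the Chl complement);
  accessory-chlorophyll contributions use the substitute-by-Chl-a
  variant (they occupy sites a Chl a could). Both the per-class
  differences and the full decomposition are reported, because
  `1 - 10^-A` is concave and per-class differences are **not**
  additive — a point the tests assert explicitly.
* **Dipole strengths from extinction bands** use the standard
  integrated-absorption relation with a single calibration constant
  (`c_cal`), documented rather than fitted; only its scaling laws are
  load-bearing in this package.

## Limitations

Point dipoles only (no transition-density or extended-dipole couplings,
no Dexter term); no excited-state dynamics or master-equation
propagation; single-state treatment of each band; class-level overlap
densities; no vibronic line-shape theory; IPR⁻¹ measures weight
concentration, not spatial extent — two distant pigments sharing one
exciton score the same as two adjacent ones.

## Problem sizes

The shipped analyses run on the 14-site fixture (91 pairs per band,
14×14 Hamiltonians); the property suite uses up to a few thousand
randomized orientation draws and 12-site constructed assemblies. A full
model fit takes well under a second, and the complete test suite runs in
seconds on one CPU.
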