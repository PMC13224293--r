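---
title: "Linear unmixing of infrared spectra: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear unmixing of infrared spectra: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irmixid)
```

# The problem and the model

An infrared spectrum of a liquid mixture is *almost* the weighted sum of
its components' pure spectra — almost, because intermolecular
interactions in the condensed phase shift and broaden bands relative to
both the gas phase and the neat liquids. `irmixid` takes the pragmatic
position that a linear model fit against the right reference data (pure
*liquid*-phase spectra) identifies components reliably despite these
nonlinearities, and provides the machinery to quantify exactly when and
why it fails.

The data model is deliberately minimal. A spectrum is a vector of
non-negative intensities on a uniform wavenumber grid, preprocessed in a
fixed order — Gaussian smoothing, clipping of negative intensities,
unit-area normalization — so that all spectra are comparable
probability-density-like vectors. The default grid places 1250 points at
$\nu_i = 4i$ cm$^{-1}$, $i = 0 \dots 1249$, i.e. 0–4996 cm$^{-1}$. (A
1250-point grid "spanning 0 to 5000" is off by one point no matter how
you cut it; we fix $\nu_i = 4i$ and make the grid fully configurable.)
All area bookkeeping uses the rectangle rule, $\sum_i y_i \,\Delta\nu$:
it is the simplest reading of "total integrated intensity" and makes the
cumulative-distribution identities below exact rather than approximate.

Unmixing solves, per mixture spectrum $y$ and basis matrix $X$ of pure
spectra,

$$\min_c \; \lVert y - Xc \rVert^2 + \lambda \lVert c \rVert^2
\quad \text{(LS)}, \qquad
\min_{c \ge 0} \; \lVert y - Xc \rVert^2 + \lambda \lVert c \rVert^2
\quad \text{(NNLS)},$$

each mixture independently (the matrix formulation decouples row by
row). The non-negativity constraint is what makes coefficients
physically meaningful — a component cannot contribute negative
absorbance — and empirically it is also what produces sparse,
well-separated coefficient distributions. With unit-area basis spectra,
coefficients on an exactly linear mixture equal the mole fractions;
normalizing a coefficient vector to unit sum is therefore a reporting
convention, not a model assumption.

# Numerical choices

**NNLS solver.** Lawson–Hanson active set on the normal equations, with
the ridge term folded into the diagonal (equivalently: augmenting the
design with $\sqrt{\lambda} I$ rows). The optimality tolerance on the
dual vector is $10^{-10}\max(1, \max|X^\top y|)$. The iteration cap
defaults to $3p$ for a $p$-column basis, the conventional bound for
active-set methods; hitting it is *not* an error — the result is flagged
`converged = FALSE` and every benchmark counts such mixtures as
incorrect, because a production identification pipeline has to make a
call either way. At $\lambda = 0$ the ridge path reduces exactly to
plain NNLS.

**Tie-breaking.** Candidate ranking sorts by descending $|c_i|$ with
ties resolved by basis order (stable sort); the pairwise baseline
enumerates pairs in library order and keeps the first minimum; a pair of
bit-identical spectra gets $\alpha = 0.5$ by convention. Every such rule
exists to make reports bit-reproducible from `(seed, config)`.

**Degenerate inputs.** Normalizing an all-zero (post-clip) spectrum,
unmixing across mismatched grids, an all-zero dipole trajectory, and a
grid extending past the trajectory's Nyquist limit are all hard errors;
a mixture whose fit merely fails to converge is a flagged result.

**Smoothing.** Gaussian kernel expressed in cm$^{-1}$ (default 8
cm$^{-1}$ = two grid steps when smoothing is requested; 0 disables),
truncated at $4\sigma$, with half-sample symmetric (edge-repeated)
reflection — chosen because that padding conserves the total intensity
sum exactly, so smoothing commutes with area normalization.

**Spectral comparison.** Three metrics serve different purposes. MSE
(mean squared intensity difference) is the solver-aligned distance and
defines nearest spectral neighbours. The CDF difference — the mean gap
between two spectra's running integrals — is shift-sensitive: for a
rigid shift by $\delta$ the signed mean gap is exactly $\delta / (n
\,\Delta\nu)$ for on-grid shifts, so its sign reads off red/blue shift
direction. We define "grid span" as $n\,\Delta\nu$ (5000 cm$^{-1}$ on
the default grid) precisely so this identity is exact. Both the signed
and the absolute variants are exposed, since either reading of an
"average distance between CDFs" is defensible; the signed one carries
the direction information. The convention: positive
`avg_cdf_difference(a, b)` means `a` sits at lower wavenumbers
(red-shifted) relative to `b`.

# Spectra from dipole trajectories

Simulated reference spectra come from the Fourier transform of the
total-dipole autocorrelation function
$C(\tau) = \langle M(t)\!\cdot\!M(t+\tau)\rangle$, computed with the
unbiased estimator (each lag divided by its number of valid origins) and
accumulated by FFT. The classical line shape $\tilde C(\nu)$ is turned
into an absorbance spectrum by the combined field-coupling/quantum
correction in its reduced form

$$S_{qm}(\nu) = \tilde C(\nu)\, \nu^2,$$

which is the only form implemented: the separate field and thermal
correction factors require the explicit correction-function bodies,
and the $\nu^2$ product is what they reduce to. The optional trajectory
temperature is carried as metadata only. A Hann window (configurable,
`"none"` available) is applied to the autocorrelation before the
transform to suppress truncation ringing; the default lag cut is half
the trajectory, which sets the frequency resolution $1/(2 L \Delta t
c)$. Residual negative transform values are clipped, consistent with
the global preprocessing convention. Gas-phase mixture spectra are
composed as mole-fraction-weighted sums of pure spectra — in a dilute
gas the dipoles of distinct molecules are uncorrelated, so the spectrum
is exactly additive.

# Identification benchmarks

Two protocols. The **distractor protocol** builds, per repeat, a basis
of all true components plus an equal number of distractor spectra
sampled without replacement with a repeat-specific generator derived
from the master seed, and scores the exact top-$k$ criterion at $k$ =
the known mixture size. The **basis sweep** grows the basis in nested
fashion — the smallest basis is exactly the union of all mixtures'
components; each larger size appends further spectra in one seeded
shuffle, so every basis contains all smaller ones — and records accuracy
per (size, criterion, $k$). The growth order is a seeded shuffle because
no canonical ordering of "additional" spectra exists.

The **atom filter** re-ranks size-$k$ candidate combinations (from the
top-10 pool by default) in descending joint-coefficient order and
promotes the first combination whose pooled *element set* equals the
mixture's known element set. Set semantics, not counts, is the default
because the experimentally available side information — "there is
chlorine in this sample, no sulfur" — is presence/absence information;
exact atom counts would additionally require known mole ratios. A strict
count mode is provided behind `mode = "count"` for when they are known.
If nothing in the pool qualifies, the unfiltered prediction stands,
flagged.

# Component-count inference

The reconstruction trace adds components to an empty spectrum in
descending coefficient order, each scaled by its coefficient, and
records after each step the explained variance
$R^2 = 1 - \sum(y-\hat y)^2 / \sum(y - \bar y)^2$ (with $\bar y$ the
mean intensity of the target), the MSE, and the signed mean gap between
running cumulative curves (partial reconstructions are not unit-area, so
the raw running integrals are compared). The inferred component count is
where the $R^2$ increment first drops below 1% — a first-class
configurable threshold, since any plateau rule trades false splits
against false merges; 1% is a conservative signal-to-noise floor for
unit-area spectra. Leave-one-out importance refits the basis without one
component and reports the $R^2$ drop and MSE/CDF increases; spectrally
degenerate duplicates produce near-zero importance for either copy,
which is the designed signature of degeneracy rather than a defect.

# Robustness and misidentification profiling

The peak-shift study rebuilds each mixture from its components' pure
spectra after each is independently, rigidly translated by a
fixed-magnitude, random-sign offset (realized on-grid; vacated bins
zeroed; renormalized), while the identification basis keeps unshifted
spectra. A rigid whole-spectrum translation is the chosen perturbation
model because the data model does not individuate peaks; per-peak
independent shifting would require a peak-picking layer that the
pipeline otherwise never needs.

Failed identifications are profiled by pairing each missed true
component with a false-positive candidate by minimal spectral MSE
(closest pair first) — the natural pairing for an algorithm that
minimizes squared error — and classifying each pair by formula: isomer
(identical formulas), single-atom substitution (one element count $+1$,
another $-1$, rest equal), carbon difference (only carbon differs, by
exactly one; a `h_tolerance` option admits CH$_2$-style homologues but
is off by default because it is an interpretive extension), otherwise
"other". A mixture whose pairs span two or more named categories is
labelled "mixed" at the mixture level.

# The synthetic fixture generator

`generate_library()` emulates just enough structure for every test to
run without external data: gas-like spectra are 3–8 Gaussian peaks of
width 4–10 cm$^{-1}$ (sharp, nearly orthogonal between molecules —
the regime where linear identification should be perfect); the
liquid-like transform broadens all of a molecule's peaks by a common
factor of 2–6 and shifts them rigidly by a uniform −30…+30 cm$^{-1}$
draw, mimicking interaction-driven condensed-phase effects. Formulas are
drawn over C/H/N/O/S/Cl/Br, with planted isomer and single-substitution
traps at 5% rates each so misidentification profiling has ground truth.
Mixtures default to equimolar; the nonlinearity knobs (per-component
rigid shift SD, per-peak intensity jitter SD) break exact additivity in
a controlled way. Benchmark suites draw mixture components from the
first half of the library so the second half is a distractor reservoir.

What the generator does *not* emulate — and what passing synthetic tests
therefore cannot show — includes realistic band shapes and functional
group positions, baseline drift and instrument noise, concentration
nonlinearities beyond rigid shift/jitter, and the long tail of real
spectral degeneracy among thousands of structurally related molecules.
Synthetic results establish correctness of the machinery (exact recovery
in the linear regime, correct counting, monotone degradation under
perturbation), not field accuracy; quantitative accuracy claims require
real pure-component libraries, which `adapt_external_dataset()` can map
in from a manually downloaded deposit.

Default suite sizes in the test and acceptance runs — 200 molecules, 100
binary mixtures, 8 distractor repeats; smaller suites (25–80 molecules)
for property checks — keep a full test cycle within seconds while
leaving every conclusion unchanged at larger sizes; all sizes are
configurable.

# Known limitations

- Linear models cannot distinguish components whose spectra are
  (near-)identical; the profiling tools quantify this ceiling rather
  than remove it.
- The CLI and library operate on single-beam-style intensity spectra;
  JCAMP-DX parsing, baseline correction and ATR penetration-depth
  correction are out of scope.
- The ridge variants expose $\lambda$ but the package takes no position
  on its value; 0 is the default everywhere.
- Formula-level misidentification categories are structure-blind:
  "isomer" means equal formulas, with no connectivity check.
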