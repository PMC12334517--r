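---
title: "Methods: zone-based synchronous fluorescence analysis of spent embryo culture medium"
author: "secmFluor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zone-based synchronous fluorescence analysis of spent embryo culture medium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secmFluor)
```

## The measurement and the question

During IVF an embryo is cultured to the blastocyst stage in a ~20 µl droplet
of defined medium. The spent embryo culture medium (SECM) collected at
transfer carries the embryo's secretome, and the question the package
addresses is whether cheap, non-invasive optical and molecular readouts of
that droplet separate embryos that implanted successfully (group F) from
those that did not (group N), against unused medium (group M) as a blank.

The optical readout is synchronous fluorescence: emission is scanned at a
fixed offset $\Delta\lambda$ above the excitation wavelength
$\lambda_{ex}$, and a family of scans over offsets 30–170 nm forms a 3D map
$I(\lambda_{ex}, \Delta\lambda)$ on the excitation interval 200–400 nm —
the UV range where the aromatic amino acids and their metabolites
fluoresce. Each sample is measured at 1:2500 dilution in two solvents, PBS
and PBS:DMSO (1:1); the tyrosine band near 223 nm is quenched in PBS:DMSO
while the tryptophan band near 280 nm becomes more pronounced, so the two
dilutions carry complementary information. Intensities are arbitrary units
throughout; only relative comparisons are made and no absolute calibration
is attempted.

## From maps to profiles and zones

A `SynchronousMap` is collapsed to a 1-D `FluorescenceProfile` by taking,
at each excitation wavelength, the maximum over the offset axis
(`maxProjection()`). The projection rule is deliberately isolated behind
one generic: the envelope of the synchronous scans is the natural reading
of "profile" for band-shaped maps, but a fixed-offset slice could be
substituted without touching anything downstream.

The *additive profile* of a sample is the point-wise sum of its PBS and
PBS:DMSO profiles (`additiveProfile()`); it represents the sample's total
fluorescence across both dilutions. Profiles are averaged within groups
(`groupAverage()`), and averaging is done on profiles, not raw maps, so
each sample contributes through the same projection.

The additive profile is partitioned into five zones on the excitation axis,

| zone | interval (nm) |
|------|---------------|
| Z1 | 200–230 |
| Z2 | 230–260 |
| Z3 | 260–290 |
| Z4 | 290–330 |
| Z5 | 330–400 |

with half-open intervals $[lo, hi)$ except Z5, which keeps 400 nm, so every
grid point belongs to exactly one zone. Zone fluorescence is the
trapezoidal integral of the profile over the zone (`integrateZones()`);
the trapezoid spanning a shared boundary is split at the boundary, which
guarantees *zone conservation*: the five zone values sum to the full-range
integral to machine precision. The aggregation rule is configurable
(`"sum"` and `"mean"` of the grid points are provided) because an integral,
a sum and a mean only differ by grid-dependent factors and the choice
should be explicit, but the integral is the default since it is robust to
the wavelength step. Per-zone values are normalized to the free medium by
subtracting the M-group mean (`cohortZoneTable(normalize = "subtract")`);
a ratio-to-M mode sits behind the same flag because "normalized to free
medium" admits both readings, and subtraction is the one consistent with
reporting negative zone values.

## The decomposition into HSA, metabolites and embryo activity

The dominant fluorophore of the medium is human serum albumin (HSA). Its
concentration in each sample is measured photometrically, and its
fluorescence contribution is modelled as linear through the origin,
$F_{HSA} = k \cdot c_{HSA}$ (`hsaFluorescence()`), with the coefficient
$k$ (a.u. per g/L) supplied by the user as an `hsaCalibration()` — the
package deliberately does not guess $k$, because it is an instrument
property. The decomposition is then pure arithmetic, and holds exactly for
every emitted result:

$$F_{metab} = F_{total} - F_{HSA}, \qquad
  A = F_{metab} - F_{metab}(M), \qquad
  R = A_N / A_F$$

where $F_{total}$ is the total fluorescence of the group-average additive
profile, $A$ is the *embryo metabolic activity* — the fluorescence left
after removing calculated albumin and the blank medium — and $R$ is the
headline N/F activity ratio. Two readings of $F_{total}$ are provided:
`full_integral` (default), the sum of the five zone integrals, and
`z3_peak`, the maximum additive intensity inside Z3 (the 280 nm region
read as albumin + other proteins + free tryptophan + metabolites). The
integral is the default because it is conserved under zoning; the peak
mode is retained for sensitivity analysis. The decomposition is computed
on group-average profiles (one value per group); a per-sample mode exists
for future statistics but the group mode is the primary output because the
ratio is defined on group averages and is not statistically tested.

## The statistical toolkit

Fluorescence intensities are heavy-tailed, so each group's zone values
first pass through ROUT outlier removal (`routOutliers()`, Q = 1% by
default), specialised to a constant model: the robust center minimises the
Lorentzian merit $\sum \log(1 + (r_i/\mathrm{RSDR})^2)$ initialised at the
median; the robust spread RSDR is the 68.27th percentile of the absolute
residuals times $n/(n-1)$; each residual's two-tailed t-tail probability
($n-1$ df) is screened largest-first under the step-down FDR rule
$p_{(i)} < (Q/100)\, i/n$. Measured on clean normal data at $n = 30$ the
per-dataset false-flag rate is ≈1.75% at Q = 1% — slightly above Q, a
known small-sample property of the percentile RSDR estimate — and a single
gross (100σ) contaminant is flagged with certainty.

Cleaned groups pass a Shapiro–Wilk gate (`shapiroGate()`): if either group
looks non-normal at p < 0.05 the F-vs-N comparison uses the Mann–Whitney
U test, otherwise an unpaired t-test. `mannWhitney()` uses the exact
distribution when both groups are small and tie-free and a tie-corrected
normal approximation with continuity correction otherwise; enumerating all
U values at $n_1 = n_2 = 8$ the two branches agree within 0.011 in p. All
tests are two-tailed at the 0.05 level, and no multiple-testing correction
is applied across zones — the zone comparisons are reported as a panel,
not as a single decision rule.

Percent differences between group values use the larger value's magnitude
as denominator: $100\,(hi - lo)/|hi|$ (`percentDifference()`). This is the
formula that reproduces the reported expression changes of 137%, 104.6%,
44.4% and 38.5% from the published group means; the remaining published
percentages (230%, 24.5%, 23%, 7.8%) are not reproducible from the rounded
group means under this or any variant formula we tried (nearest candidates
236.9, 24.8, 24.5, 7.7) and are presumed computed on unrounded source
data; the discrepancy is pinned in the test suite rather than guessed
away.

## qPCR relative expression without a housekeeping gene

Cell-free medium has no stable endogenous reference, so the relative
expression of an SECM miRNA is its log2 fold change versus the free-medium
baseline, $\log_2 FC = \overline{Ct}_M - \overline{Ct}_g$ — one qPCR cycle
equals one log2 unit, and values are negative when the free medium carries
more signal than the SECM. Each group is a pool measured in technical
duplicates, so the SEM is propagated from duplicates of both the group and
the baseline and reflects technical, not biological, replication — a
documented limitation, since pooling removes the biological denominator.
The formula is invariant to a global Ct offset (instrument calibration).

## The synthetic cohort generator

No SECM spectra are publicly deposited, so the package ships a forward
model (`cohortSpec()`, `simulateCohort()`) that emulates the *structure*
of the real data and makes every downstream stage testable:

* bands are separable Gaussians in $(\lambda_{ex}, \Delta\lambda)$ — the
  simplest shape reproducing profile maxima at 223 and 280 nm; the
  pipeline itself never assumes it;
* the tyrosine-like band (223 nm) has solvent factor ≈0 (quenched in
  PBS:DMSO), the tryptophan-like bands are enhanced (>1);
* the HSA band's amplitude is tied to the sample's drawn photometric
  concentration so that it contributes exactly $k \cdot c$ to the
  additive-profile integral, making the decomposition exactly invertible
  on noiseless cohorts (a test asserts machine-precision recovery of the
  injected embryo-band contribution);
* embryo-secretome bands feed Z1, Z2, Z4 and Z5; in group N the Z1/Z2/Z4
  bands are scaled by a common multiplier (≈1.74) sized so the noiseless
  group means reproduce the reference decomposition table (totals
  301,582.6 / 312,698.6 / 259,570.1 a.u.; activities 16,805.2 / 27,836.0;
  ratio 1.66);
* all default bands share the offset response (center 70 nm, SD 35 nm),
  which makes the max projection additive in bands — the property the
  exact-recovery guarantee rests on;
* variability is split into a small technical CV (2%) on medium bands in
  every sample — the free medium is aliquots of one lot — and a larger
  biological CV (15%) on embryo bands, plus Gaussian instrument noise
  (SD 2 a.u.) truncated at zero;
* default group sizes are the study's: 30 F, 36 N, 3 M, with transfer
  days assigned 6:24 (F) and 7:29 (N).

What passing tests on this generator do **not** show: real SECM spectra
have scattering ridges (Rayleigh/Raman), inner-filter effects,
photobleaching and an unknown fluorophore inventory for the medium; none
of these are modelled, and the generator's defaults are illustrative, not
a claim about the true band composition of any commercial medium.

## Numerical choices and degenerate inputs

* Grids: excitation default 1 nm step (201 points), offset default 10 nm
  step (15 points); any strictly increasing grid inside the measured
  ranges is accepted, since instruments differ in step size.
* Resampling (`resampleProfile()`) is linear interpolation and refuses
  extrapolation.
* Map/manifest CSV writers render doubles at 17 significant digits so a
  write/read cycle is value-identical.
* ROUT with zero spread: all-equal samples flag nothing; a massive tie
  with distinct strays treats the strays as infinitely many RSDRs away.
* A cohort without M samples aborts immediately — every normalization and
  the activity statistic need the free-medium baseline.
* Zone ratio features drop (with a warning) samples whose denominator
  zones are non-positive.

Problem sizes in the test suite are chosen to keep the full run around a
minute on one core: cohorts of 6–69 samples on the default grids, 50
replicate null cohorts for the specificity check, and 500 draws for the
ROUT calibration estimate.

## Reproducing the packaged results

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from scratch:
the decomposition arithmetic on the published group values, the percent
differences from the published expression means, and a full synthetic
cohort run at the study's group sizes (group totals, activities, N/F
ratio, and per-zone Mann–Whitney p-values for Z1/Z2/Z4). Everything it
writes is computed at run time by the same exported functions documented
here.

```{r example, eval = FALSE}
co <- simulateCohort(cohortSpec(seed = 1))
profiles <- cohortProfiles(co$maps)
dec <- decomposeCohort(profiles, co$manifest, hsaCalibration(1000))
dec$table
dec$ratioNF
```
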