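---
title: "Screening sponge extracts for 3-alkyl pyridine alkaloids"
author: "apascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening sponge extracts for 3-alkyl pyridine alkaloids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apascreen)
```

## The problem

Marine sponges of the order Haplosclerida accumulate 3-alkyl pyridine
alkaloids (3-APAs): pyridinium (Pyr) or tetrahydropyridine (THP) rings
joined head-to-tail by alkyl chains into cyclic dimers
(cyclostellettamines, haliclamines), cyclic trimers (viscosamines) and
linear oligomers carrying a beta-alanine unit (viscosalines). Many 3-APAs
are cytotoxic, which makes them both interesting leads and frequent
re-isolation traps. `apascreen` implements a desk-scale version of a
metabolomics dereplication screen for this compound family: identify
3-APA-bearing specimens in an untargeted LC-MS cohort, annotate the
individual alkaloids from two-function data-independent (MSE)
acquisitions, resolve coeluting isobars by ion-mobility drift time, and
prioritize specimens by aligning the chemistry with cell-viability data.

## Exact-mass arithmetic

All m/z values derive from four atomic monoisotopic masses (C = 12
exactly, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221). The m/z
of an ion is the monoisotopic mass of the complete charged-species formula
(added protons counted as H atoms) divided by the charge, with **no
electron-mass correction**. This convention reproduces the reference value
of the THP diagnostic fragment C6H12N+ at m/z 98.0970 (the
electron-corrected value would be 98.0964) and every self-consistent
literature value for the thirteen curated compounds. Masses are kept at
full precision internally and rounded to four decimals only for display.

Natively charged macrocycles need one bookkeeping rule: a
cyclostellettamine is an intact dication, so its "doubly charged molecular
ion" is the formula mass divided by two with no added protons, while its
singly charged species is formula + 1 H. Neutral haliclamines instead form
`[M+H]+` and `[M+2H]2+` by protonation. Viscosamines are intact
trications; viscosalines intact monocations.

## The compound library

Two generative rules produce the dimer formulas from the chain lengths
`n`, `m` (carbons): Pyr--Pyr cyclic dimers are `C(10+n+m) H(2(n+m)+8) N2`
with onium fragments `C(5+k) H(2k+4) N` for `k = n, m`; THP--THP dimers
are `C(10+n+m) H(2(n+m)+14) N2` with fragments `C(5+k) H(2k+8) N`.
Trimeric viscosamines are `C(15+S) H(2S+12) N3` over the chain sum `S`;
viscosalines `C(13+n+m) H(2(n+m)+14) N3 O2`.

The curated library holds the thirteen compounds reported in *Haliclona
rosea* extracts. Each entry stores the literature-printed ion and fragment
m/z **alongside** the recomputed values, because several printed values are
internally inconsistent with their printed formulas (doubly charged ions
of haliclamines A/D/E and cyclostellettamines Q/N/G/A, the viscosamine
trication, one cyclostellettamine G fragment, and the viscosaline C
formula, which disagrees with its printed mass by one H). Matching uses
recomputed values by default (`use_printed = TRUE` switches). Haliclamine
A violates the THP--THP hydrogen rule and its main fragments follow the
pyridinium rule; it is stored as a curated-only entry with both moiety
diagnostics and is never produced by `expand_homologs()`. The default
homolog expansion range, 8--14 chain carbons, covers all curated species.

## The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` generates the validation conditions the package is
tested under, mimicking the study design it models:

* 28 specimens, 3 of which (`S1`, `S5`, `S8`) carry the thirteen curated
  compounds; per-specimen abundance profiles are an ordinal mimic of the
  reported distribution (S1 and S5 similar with S1 richer in
  cyclostellettamine Q and the haliclamines; S8 divergent).
* ~2100 background features shared across specimens, log-normal
  (meanlog 10, sdlog 1) base intensities with 20% per-specimen
  multiplicative noise, uniform m/z on the acquired 50--1200 range and
  uniform retention time on the 21-minute gradient.
* Gaussian m/z jitter of 3 ppm (the curated compounds' reported deviations
  span 1--10 ppm), isotope envelopes from a carbon-only binomial model
  (per-carbon heavy-isotope probability 0.0107; N/O heavy isotopes
  contribute below matching tolerance), shot noise at 2 random peaks per
  spectrum, and a per-compound main-ion intensity of 1e6 at abundance 1 --
  large enough that the alkaloids form a substantial share of an
  APA-bearing specimen's total signal, as the dominant metabolome
  difference they represent.
* Retention times by a deterministic hash of the compound name onto the
  2--16 min window: reproducible placement without modeling
  chromatography. The retention-time grid step is 0.1 min with Gaussian
  peak shapes (SD 0.12 min).
* Viability values seeded from the reported assay table for S1--S8
  (APA-bearing specimens are always active) and near control level for the
  rest.

Not emulated: profile-mode peak shapes, ion suppression, adducts,
chromatographic drift between runs, and real instrument noise. Passing the
simulation-based tests therefore demonstrates the *logic* of the screen --
matching, gating, multivariate separation -- not robustness to every
artefact of real acquisitions.

Every simulator is a pure function of its spec and seed; two calls with
identical arguments produce byte-identical serialized output.

## Screening logic

Annotation follows the published gate: extract the two diagnostic-fragment
ion chromatograms (m/z 98.0970 for THP, 106.0657 for Pyr) from the
high-energy function, detect their retention-time peaks, search the
low-energy function within each peak's bounds for library precursor ions
at 10 ppm, verify charge states by the 1.003355/z isotope spacing, confirm
diagnostic and onium (F1/F2) fragments, and accept a compound only with a
precursor hit plus at least one diagnostic and one F fragment (both
requirements configurable). The composition of the Pyr diagnostic at m/z
106.0657 is nowhere stated in the source literature; C7H8N
(methylenepyridinium) matches to four decimals under the package's
convention and is adopted, flagged as inferred.

Numerical choices worth knowing:

* EIC peak prominence threshold 0.05 of the apex: homolog pairs eluting
  ~0.3 min apart produce twin peaks with shallow (~8%) valleys that a
  stricter threshold would merge.
* Charge verification additionally rejects a claimed charge when a peak
  sits at the tighter spacing of a higher charge state -- otherwise the
  second isotope of a 2+ envelope (spacing 2 x 0.5017 = 1.0034) would
  "confirm" charge 1.
* When several library entries match one peak, all are kept and ranked by
  score then |ppm|, mirroring tentative identification; the score is
  `w1 (1 - |ppm|/tol) + w2 #diagnostics + w3 #F-matched/#F-predicted +
  w4 [isotopes confirmed]` with unit weights.

## Pseudo-MS3 isobar resolution

In time-aligned parallel (TAP) mode, precursor fragments are separated by
ion mobility and fragmented again, so secondary spectra can be keyed to the
drift time of their primary fragment. `resolve_isobars()` builds the
driftogram of a target m/z, detects drift peaks (minimum separation 0.5
ms), assembles each peak's pseudo-MS3 spectrum (0.01 Da merge width,
matching two-decimal fragment reporting), and classifies each isobar:
"ring-opened" when the macrocycle-opening signature is present -- a
fragment at `2 mz + m(H) - m(C2H6N)`, the loss of a C2H5NH iminium from
the singly charged macrocycle -- and "compact/onium" when both onium
fragments of the best library match are present. Signature peaks must
reach 5% of the spectrum's base peak, because edge bins of a drift window
pick up sub-percent tails of the neighbouring drift population. The drift
dimension is modeled in milliseconds with Gaussian peaks and no
collision-cross-section calibration; the simulated drift times (4.0 and
5.5 ms) are arbitrary since none are reported.

The doubly charged macrocycle producing two mobility-separated gas-phase
forms is encoded in the generator by fiat -- two populations at the same
m/z -- with no structural modeling.

## Prioritization

Feature tables are built by greedy m/z (15 ppm) and retention-time (0.4
min) binning of low-energy centroids with isotope-position deisotoping
(peaks at `mz - k 1.003355/z`, z in 1..3, of a stronger co-eluting peak are
removed). Features must occur in at least two samples (one for single-run
input): without this reproducible-occurrence rule every one-sample noise
spike becomes a feature and the table inflates far beyond the ~2100-feature
scale the emulated study reports.

Normalization follows the sum / log / unit-variance recipe: sample-wise
total-intensity normalization, zeros replaced by half the smallest positive
normalized value, log10 (the upstream tool states neither base nor zero
rule; both are package decisions), then per-feature centering and unit
variance. PCA is computed by SVD of the centered matrix with a fixed sign
convention (largest-magnitude loading entry positive) for reproducibility,
and is cross-checked in the tests against an independent covariance
eigendecomposition.

Specimen prioritization runs k-means (k = 2, 20 restarts, seeded) on the
first two component scores. The smaller cluster becomes the candidate set
only if its active fraction (viability < 50% of control, strict) exceeds
the other cluster's **and** reaches 0.8. The gate matters: on a
signal-free cohort with scattered actives, a random k-means split gives
the smaller cluster the higher active fraction about half the time, so the
comparison alone would fabricate candidates; requiring a nearly all-active
cluster suppresses that failure mode while the genuine
alkaloid-driven cluster (3/3 active) passes. The reported assay table also
contains one extract at exactly 51% viability counted as cytotoxic in the
original report; under the strict rule it is inactive, and the threshold
is left configurable rather than bent.

Driver features are ranked by loading magnitude on the separating
components (those carrying at least half the between-cluster variance) and
matched against the library at 10 ppm.

## Problem sizes and validation

The test-suite and acceptance-script runs use the full emulated conditions:
28-specimen cohorts with 2100 background features, ten independent seeds
for each stochastic claim (thirteen-compound recovery from single runs;
exact recovery of {S1, S5, S8} by the cohort pipeline), plus exhaustive
brute-force cross-checks on small runs (every peak against every library
ion) and eigendecomposition cross-checks for PCA. A worked example with
concrete numbers is in the README.

## Known limitations

* The element table covers C, H, N, O only -- sufficient for 3-APAs,
  extendable through the shipped atomic-mass table.
* The viscosaline "first" doubly charged species and the viscosamine
  fragment compositions are not derivable from the stated formulas; they
  are carried as printed reference values and never matched against.
* Real-data observables that depend on the original raw files (total
  feature counts, exact PCA variance fractions) are out of scope; the
  synthetic cohort reproduces the structure, not those numbers.
* mzML import maps MS levels 1/2 to the low/high-energy functions, which
  fits common exports of two-function acquisitions but not every vendor
  convention.
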