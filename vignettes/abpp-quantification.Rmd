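---
title: "Quantifying competitive ABPP and targeted FAHFA lipidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying competitive ABPP and targeted FAHFA lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abppquant)
```

# The measurement problem

Covalent serine/threonine hydrolase inhibitors are profiled by competition:
a fluorophosphonate (FP) activity probe labels every active hydrolase in a
proteome, and pre-treatment with an inhibitor blocks labeling of its
targets in proportion to occupancy. Quantifying the probe-labeled signal
per protein, per treatment condition, against vehicle controls yields a
selectivity map across the enzyme family. Two quantification chemistries
are supported here — isobaric TMTpro multiplexing (one channel per
condition, read out as MS3 reporter ions) and reductive dimethylation
(ReDiMe; paired light/heavy channels read out as peptide ratio pairs) —
together with the gel-densitometry dose–response fit used for single-target
potency, and the internal-standard quantification of FAHFA lipids, the
substrates whose levels these hydrolases control.

All of it rests on mass bookkeeping, so the package carries a
molecular-formula calculator whose outputs are pinned, test-by-test, to
printed reference masses.

# Formula masses and the no-electron convention

`monoisotopicMass()` sums isotope monoisotopic masses from a committed
constants table (`isotopeMasses()`, CODATA/NIST values at 6+ decimals,
never fetched at runtime). `adductMz()` computes ion m/z as

$$ m/z = \frac{M(\text{neutral} + \text{added} - \text{removed})}{|z|} $$

with **no electron-mass correction**. Synthesis chemistry sections print
"calcd" ion values under exactly this convention: the [M+H]+ of
C21H22N4O4S prints as 427.1440, which is the plain proton-added formula
mass; subtracting the electron mass would give 427.1435 and fail the
comparison at 4 decimals. The convention is therefore the package default
and is documented on `adductMz()`. Rounding for comparison against printed
values is round-half-even at the printed precision (4 dp for HRMS, 1 or 0
dp for low-resolution MS), applied only at the reporting boundary.

The `[M-tBu+H]+` adduct used for Boc-protected intermediates is modeled as
loss of isobutylene (C4H8) followed by protonation — the net composition
change that reproduces printed tBu-loss fragments.

## FAHFA transitions

A FAHFA is the ester of an acyl fatty acid and a hydroxy fatty acid:
intact formula = acyl + hydroxy − H2O. Negative-mode MRM transitions are
generated from a fixed three-fragment catalog: the acyl carboxylate, the
hydroxy-FA carboxylate, and its water loss. Isotope labels (the 13C16 and
13C18 acyl chains of commercial internal standards) propagate to the
precursor and to the acyl fragment. This reproduces the full endogenous
PAHSA/OAHSA/POHSA panel and the labeled-standard transitions, including
the labeled palmitate fragment at m/z 271.3.

One known catalog gap: targeted panels also monitor an *endogenous* POHSA
fragment at m/z 271.3, which none of the three catalog fragments produces
(palmitoleate plus water computes to 271.2). Its identity is not
documented in the sources the catalog is built from, so it is deliberately
not forced into the catalog; users needing it can append a custom row.

# Reporter extraction

`extractReporters()` implements the standard MS3 reporter readout: for
each channel, the most intense centroid within a window of the expected
reporter mass supplies intensity and its instrument-reported noise;
SNR = intensity / noise.

Two deliberate choices:

* **Window semantics.** A "0.002 Th window" is read as a *total* width
  (± 0.001 Th). This is the stricter of the two readings; the
  `halfWindow` argument makes the other available explicitly.
* **Missing channels.** A channel with no in-window peak gets intensity 0
  and SNR 0 (noise recorded as NA). Encoding absence as SNR 0 lets the
  downstream mean-SNR filter see weak PSMs instead of silently dropping
  channels.

Ties in intensity are broken by smaller |Δm/z|, then lower m/z, so
extraction is deterministic under any peak ordering.

# The isobaric competition pipeline

Stages, in order (`proteinCompetition()` runs them all):

1. **Normalization** (`normalizeChannels()`): each channel is scaled so
   its summed SNR equals the grand mean of per-channel summed SNRs. This
   removes loading bias. It is idempotent, and it is *optional*: in a
   simulated experiment where every protein is inhibited in a channel,
   the channel sum deficit is inhibition signal, not loading bias, and
   normalizing would rescale it away. The exact noise-free round-trip
   identity (percent competition = 100φ) therefore holds with
   `normalize = FALSE`; with realistic proteomes — where unaffected
   background proteins dominate the channel sums — normalization is benign
   and stays on by default.
2. **PSM filters** (`filterPsms()`): remove a PSM when the CV of its
   control-channel SNRs exceeds 0.5 or its all-channel mean SNR is below
   2. CV uses the sample (n−1) standard deviation over the mean — with
   only 2–3 control replicates this is the stricter reading. A zero
   control mean makes the CV undefined; it is treated as infinite (PSM
   removed), a documented package choice. Every removal is logged with
   the rule that fired.
3. **Rollup** (`proteinRatios()`): per protein, SNR is summed per channel
   over its PSMs; the control figure is the mean of the control-channel
   sums; the raw ratio in each treatment channel is control figure /
   channel sum. "Summed SNR for every other channel" is read at the
   protein level, symmetric with the control figure. Proteins are grouped
   by accession as given — no parsimony or inference.
4. **Capping and percent** (`capAndPercent()`): ratios cap at ±32; the
   negative bound cannot bind for ratios of non-negative SNR sums and is
   retained only for fidelity to the capping rule. Percent competition is
   100 × (1 − 1/r), clipped to [0, 100] — the standard competitive-ABPP
   convention mapping ratio 1 → 0% and the 32 cap → 96.875%. The
   conversion formula is a package decision; the convention is stated
   here because the underlying rule is usually left implicit.
5. **Reporting** (`reportingFilter()`): ≥ 3 quantified peptides (distinct
   post-filter sequences — counting post-filter is a package decision)
   and ≥ 1 unique peptide, with an exception list for always-reported
   proteins. The canonical exception is AIG1-type targets detected with
   very few peptides.

# The ReDiMe pipeline

`redimeCompetition()`: protein ratio = median of **all** peptide-level
ratio entries (duplicate quantification events of one sequence retained,
since every measured ratio is evidence; `collapsePeptides = TRUE` gives
the collapse-first variant). Each sample is then normalized so its median
protein ratio is exactly 1. Capping at ±32 is applied **after**
normalization — ratios enter percent space only once, post-normalization;
applying the cap earlier would let the normalization factor depend on the
cap. Light = vehicle, heavy = treated by default; `heavyIsControl = TRUE`
inverts the ratios when label assignment was swapped between replicates.

The median makes the rollup robust: corrupting fewer than half of a
protein's peptide ratios cannot flip the direction of its competition
call, a property the test suite checks directly.

# Dose–response fitting

`fit4PL()` fits the variable-slope four-parameter logistic on
semi-log-transformed concentrations by Levenberg–Marquardt least squares
(via minpack.lm), unweighted by default as is usual for densitometry.
Initialization is deterministic: bottom = min response, top = max
response, |hill| = 1 with sign from the response trend, log10 IC50 at the
half-range response; hill is bounded to [−10, 10] and log10 IC50 to the
data range ± 3 decades. Neither asymptote is constrained to 0/100 — the
data are percent-of-control, but real gel series over- and under-shoot,
and an unconstrained fit reports that rather than hiding it. Degenerate
input (constant responses) and optimizer failure return a flagged
non-converged result, never a silent number. At least 4 distinct
concentrations are required — with 4 parameters, anything less is
unidentifiable.

# FAHFA quantification

`quantifyLipids()` is single-point isotope-dilution arithmetic:
amount = (area / IS area) × IS pmol / normalizer, with units carried as
pmol per mg protein (cells), per g tissue, or per mL serum. Response
factors between an analyte and its family's isotopologue standard are
assumed 1:1; no external calibration curves. The default standard map
sends PAHSAs to the 13C16-9-PAHSA spike and OAHSAs to 13C18-12-OAHSA.
Although a 13C16-5-PAHSA standard is typically co-spiked, normalization
uses the 9-isomer alone by default, matching stated practice; the map is
an argument for panels that average the two. POHSAs have no labeled
standard of their own; routing them to the PAHSA standard is an inference
(flagged here and in the docs), defensible because the chains differ by
one double bond. Samples with a missing or zero-area standard are
excluded with a reason, not quantified.

# What the synthetic data emulate — and what they do not

The generators produce data with the statistical structure the pipelines
assume, under the conditions a competition screen actually uses:

* `defaultTmtDesign()`: TMTpro 16-plex, 3 vehicle-control replicates (a
  typical choice; published designs do not always state the count), 13
  treatment channels log-spaced over 1 nM–10 µM — the concentration
  window of covalent hydrolase inhibitor screens.
* `simulateIsobaricPsms()`: per-PSM log-normal base abundance
  (σ = 1, an order-of-magnitude spread), per-measurement log-normal noise
  (σ = 0.3, typical MS3 reporter scatter), log-normal reporter noise
  floor, optional per-channel loading bias, and per-protein inhibition
  given directly or via a logistic occupancy curve.
  `selectivityTruth()` ships a qualitative archetype — one potent
  low-coverage target, carbamate-typical off-targets, unaffected
  background — for demonstrations; it asserts no measured values.
* `simulateSpectra()` re-expresses a PSM table as centroided peak lists
  with m/z jitter and decoy peaks, to exercise extraction adversarially.
* `simulateDimethylRatios()`, `simulateDoseResponse()`,
  `simulateMrmBatch()` provide the corresponding ground-truth inputs for
  the other pipelines; densitometry noise is additive Gaussian (gels can
  go slightly negative), intensities and areas are log-normal (strictly
  positive, scale-free).

Every generator saves and restores the global RNG state, so it is a pure
function of parameters and seed, and noise-free settings invert exactly
through their pipeline stage — the round-trip identities the test suite
leans on.

What they do **not** emulate: chromatography, MS1/MS2 spectra, search
engines and FDR, isotope-impurity cross-talk between reporter channels,
co-isolation interference, retention-time drift, or missing-value
structure from data-dependent acquisition. Passing tests demonstrate that
the arithmetic of each stage is right and stable under calibrated noise —
not that real instrument data are free of the artifacts above.

# Recovery tolerances

The stochastic recovery checks use tolerances frozen from pre-build
Monte-Carlo calibration of the generators, not tuned afterwards:

* isobaric, σ = 0.3, 10 peptides × 3 PSMs: median absolute
  percent-competition error ≤ 5 points over 100 seeds;
* 4PL, Gaussian σ = 5 on an 8-point curve: IC50 within 2-fold in ≥ 95%
  of 200 seeds;
* MRM, σ = 0.2 on analyte and standard areas (so the area-ratio spreads
  with σ√2 ≈ 0.28): median batch-mean relative error ≤ 25% over 100
  seeds.

These problem sizes (hundreds of PSMs, tens of proteins, hundreds of
seeds) keep the full suite under a minute while giving the Monte-Carlo
summaries stable medians.

# Known limitations

* Single plex: no multi-plex batch bridging or reference-channel
  alignment.
* No reporter isotope-impurity correction matrices.
* Protein groups are taken as given; shared peptides count toward each
  accession they are assigned to.
* The ±32 cap's negative branch is dead range for SNR-sum ratios (kept
  for fidelity); how a negative ratio could arise upstream is out of
  scope.
* The POHSA 271.3 fragment and the POHSA standard assignment are
  documented inferences, not measurements.
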