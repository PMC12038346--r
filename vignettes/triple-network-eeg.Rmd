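---
title: "Triple-network EEG analysis: models, estimators and design choices"
author: "TripleNetEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple-network EEG analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TripleNetEEG)
```

# The problem

Early sensory deprivation — congenital visual or hearing impairment —
reshapes not only the deprived sensory cortex but the large-scale networks
that coordinate attention and cognitive control: the default mode (DMN),
salience (SN) and central executive (CEN) networks of the triple-network
model, alongside the visual (VN) and auditory (AN) networks. Resting-state
EEG gives a noninvasive window on this reorganization through three
complementary measurements: band-limited functional connectivity between
cortical regions, cross-frequency (theta–gamma) coupling within regions,
and machine-learning classification that ranks which connections carry the
group difference.

This package implements that full analysis chain on ROI time series, plus a
synthetic-data generator with planted, recoverable effects. Patient EEG of
this kind is rarely deposited; the generator therefore serves as the
package's verifiable stand-in for real cohorts: every estimator is tested
by whether it recovers what was planted.

# The atlas and feature geometry

The packaged atlas (`loadAtlas()`) lists 24 ROIs: bilateral V1/V2 (VN,
BA17/18), A1/A2 (AN, BA41/42), PHC/PCC/AG/MPFC (DMN), INS/dACC (SN) and
DLPFC/PPC (CEN), each with its Brodmann label. The resource reproduces its
source table verbatim, including assignments a reader might query (MPFC
listed under BA46, PHC under BA27); correcting them silently would detach
the atlas from the published ROI definitions. ROI order is fixed — table
order, left before right — and the connectivity feature order is the
row-major upper triangle over that order (`roiPairs()`), giving
24·23/2 = 276 named pair features. The fixed order is what makes ranked SVM
weights comparable across runs.

# Frequency bands

Two band tables coexist deliberately. Spectral analysis and connectivity
use delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–44 Hz
(`analysisBands()`, tiling 1–44 Hz contiguously); cross-frequency coupling
uses theta 4–7 and gamma 30–45 Hz (`cfcBands()`). The source methodology
specifies both tables with exactly these inconsistent edges; we keep both
rather than guess a reconciliation, and each stage selects its own.
Adjacent analysis bands share their edge frequency bin (both intervals are
closed), so a strong effect at exactly 8 or 13 Hz can register in two
bands; the demo run in the README shows this.

# Preprocessing

`resampleRecording()` (polyphase, via the `signal` package),
`notchFilter()` (50 Hz band-stop), `filterBand()` and `segment()` implement
the standard chain: decimate to 500 Hz, remove mains interference,
band-pass, cut into non-overlapping 2-s epochs (about 7 minutes of
recording yields 210). Filters are zero-phase by construction
(forward–backward Hamming-window FIR): phase linearity is not cosmetic
here, since both lagged coherence and phase–amplitude coupling are phase
metrics. The FIR order targets a transition width of 25 % of the lower band
edge and is capped at one third of the series length so that
forward–backward filtering remains applicable to 2-s epochs; for the lowest
bands on short epochs the effective transition is therefore wider than the
25 % target. Epochs are non-overlapping because the cross-spectral
averaging below treats them as independent.

Independent-component artifact removal is deliberately absent: the
synthetic recordings contain no ocular or muscular artifacts, so an ICA
stage would be untestable dead code here. `zscoreKeep()` implements the
±5 SD z-score outlier exclusion applied to per-subject feature vectors
ahead of classification — that placement (features, not raw samples)
matches the stated role of the step in the machine-learning workflow.

# The synthetic generator

`generateSubject()` builds each subject as a sum of controlled components
on a silent background:

* **Oscillators** (`oscillatorSpec`): narrowband Gaussian noise
  (frequency-domain brick-wall of white noise) at a given centre/bandwidth
  and RMS amplitude. Narrowband noise rather than sinusoids mimics the
  stochastic character of EEG rhythms and avoids degenerate phase
  estimates.
* **Lagged couplings** (`couplingSpec`): a shared narrowband component
  injected into both ROIs of a pair, the second copy rotated by a constant
  phase lag through its analytic signal. Mixing the shared component
  (amplitude √m) with an independent same-band component (amplitude
  √(1−m)) makes the in-band coherence magnitude equal m; at quadrature lag
  the lagged coherence is then m², so the estimate is strictly increasing
  in the planted strength — the property the recovery tests assert.
* **Phase–amplitude coupling** (`pacSpec`): a theta-band oscillation plus a
  gamma-band carrier whose envelope is (1 + d·cos θ(t))/(1 + d), θ(t) the
  instantaneous theta phase. d = 0 gives a flat envelope (MI ≈ 0); d = 1
  silences the carrier at the antiphase.
* **White noise** at `noiseSd`.

Group differences are planted by giving a coupling strength or PAC depth
per group (named vectors). Defaults follow the retained-data scale of the
study setting: 500 Hz sampling, 2-s epochs, 150 epochs (~5 min retained
from a ~7-min session; the retained epoch count after artifact rejection is
not published, so 150 is this package's choice of a realistic value). Test
fixtures scale the geometry down (typically 128 Hz, 1–2 s epochs, 15–40
epochs, 2–8 ROIs) to keep the suite fast; the estimator code paths are
identical at either scale.

Per-subject seeds derive from the design seed by a Lehmer-style modular
hash over (seed, group index, subject index) — reproducible, collision-free
in practice, and exact in double arithmetic. The generator's brick-wall
spectral shaping is intentionally a *different* filtering mechanism from
the FIR estimating chain, so generator and estimator never share an
implementation that could mask a bug.

What the generator does **not** emulate: 1/f background spectra, volume
conduction and field spread (beyond the instantaneous-mixing robustness
test), artifacts, nonstationarity, and inter-subject variability beyond
seed-driven noise. Passing recovery tests therefore demonstrates estimator
correctness, not clinical performance on real EEG.

# Lagged coherence

From the epoch-averaged cross-spectrum (`crossSpectrum()`: demeaned,
Hanning-tapered FFT outer products averaged over epochs) the per-bin lagged
coherence is Im[S_xy]² / (S_xx S_yy − Re[S_xy]²). The formulation removes
the instantaneous (zero-lag) component of the dependence, which on real
scalp/source data is dominated by volume conduction; identical signals give
exactly 0, a π/2-lagged noiseless pair gives 1.

Numerical decisions:

* **Band pooling** averages numerator and denominator separately over
  in-band bins before dividing. This pooled form is stabler than averaging
  per-bin ratios (whose denominators can be tiny at weakly powered bins); a
  per-bin mean would also be bounded but noisier.
* **Degenerate bins.** At a bin with perfect instantaneous coherence the
  denominator vanishes. Such bins are skipped with a warning. If *every*
  in-band bin is degenerate, the pair is purely instantaneous and the value
  is 0 by the measure's own logic (its numerator is 0 there); the `NA`
  marker is reserved for the contradictory case of vanishing denominator
  with nonzero pooled numerator, which Cauchy–Schwarz rules out for valid
  averaged spectra.
* **Clipping** to [0, 1] guards against rounding at the boundary only.

The estimator is validated three ways: equality (to 1e-10) with a
brute-force recomputation from raw epoch FFTs; bounds on hundreds of random
inputs; and invariance of the estimate under real instantaneous mixing of
independent channels (the volume-conduction rationale).

# Modulation index

`modulationIndex()` bins phase into n = 18 bins of 20° — the established
convention for this entropy-based index; the source text leaves n open —
and uses base-2 entropy (consistent with the lb(n) normalization). Edge
cases are defined, not accidental: constant amplitude gives exactly 0
(equal bin means regardless of phase-sample counts), a single occupied bin
gives 1, an empty phase bin contributes a zero mean with a warning, and an
all-zero amplitude series returns 0 with a warning. The index is invariant
under amplitude scaling (exactly) and under circular phase shifts by a bin
width (to floating-point error). Per epoch, phase and amplitude are
extracted with one filter length trimmed from each end (edge transients),
then pooled across epochs into a single distribution per ROI
(`pacMap()`) — pooling after trimming avoids filter artifacts at epoch
joints.

The estimator has a positive small-sample bias (entropy deficit of a noisy
uniform distribution); at the study's pooled series length the null median
is below 0.01, which the suite asserts. Recovery tests plant depths
0–0.9 and require strictly increasing estimates.

# Standardized inverse (optional stage)

`sloretaWeights()` computes W = G′(GG′ + αI)⁻¹ and standardizes each row by
the square root of the corresponding diagonal of the resolution matrix WG.
The default α = 10⁻² · mean eigenvalue of GG′ is scale-free. The
standardized operator localizes a noiseless single source exactly (tested
exhaustively on a toy leadfield); α = 0 on a rank-deficient gain raises an
informative error. ROI aggregation (`roiTimeseries()`) takes the first
principal direction of the member sources, sign-aligned to the ROI mean
series — standard practice, and deterministic. The pipeline's default ROI
mode skips this stage entirely; it exists so sensor-space data with a user
leadfield can enter the same chain.

# Group inference

`permutationThreshold()` implements max-statistic family-wise correction:
the null distribution of the maximum |t| over features under label
shuffling, with the critical value at the empirical (1−α) quantile. The
max-statistic scheme is the standard nonparametric-mapping correction for
this kind of feature family; pooled-variance t statistics are used
throughout so that df = n₁+n₂−2 (80 for 40 vs 42 subjects, matching the
published comparisons). When the number of distinct group assignments is
small (n = 4 vs 4 has only 70), the scheme enumerates all of them instead
of sampling; the suite proves equality with an independent enumeration
oracle. Calibration is asserted empirically: family-wise error on 200 null
cohorts falls within [0.02, 0.09] at α = 0.05. FDR-corrected per-feature t
tests (`ttestFDR`, used for the per-ROI MI comparisons) and the
summary-statistic ANOVA/chi-square (`anovaFromSummary`,
`chisqFromCounts`) complete the inferential toolbox; the latter two
reproduce published participant-table statistics from their printed
summaries to printed precision (the ANOVA within the rounding of the
printed means/SDs).

# Classification

`crossvalSvm()` fixes the classifier completely: linear kernel, C = 1,
features standardized to zero mean/unit variance *within each training
fold*, stratified folds from a recorded seed, metrics pooled over held-out
predictions with the impaired group as the positive class. A linear kernel
is required for meaningful weight ranking; C = 1 with standardization is
the documented equivalent of common SMO default settings.
`rankWeights()` ranks features by absolute hyperplane coefficient from a
single fit on the fully standardized table — a per-fold mean-|weight|
variant would also be defensible, but the single full fit is deterministic
given the data and is the documented choice; ties break by fixed feature
order. The top set keeps ⌊0.05·276⌋ = 13 features, annotated to network
pairs by `networkAnnotate()`.

Note one asymmetry in the published metric set this package does not try to
reverse-engineer: a 40-vs-42 comparison reporting sensitivity = specificity
= 77.5 % is only consistent with one group's denominator. The package
computes sensitivity and specificity by their standard confusion-matrix
definitions, verified against an independent oracle in the suite.

# Pipeline and provenance

`runPipeline()` executes simulate → connectivity + CFC → stats → classify,
writing TSV/JSON outputs and a manifest with every parameter, stage seed
(derived from the master seed) and an md5 per output file; identical
configurations give byte-identical outputs. `pipelineReport()` renders the
textual analogue of the study's figures: per-band metrics, significant
connections with network annotation, top MI ROIs. Stage failures abort with
the stage name and leave an incomplete-marked manifest.

Problem sizes in the shipped tests and acceptance script are chosen as the
smallest cohorts at which each statistical property is stable: 200 null
cohorts of 20 subjects × 10 features for permutation calibration, 50
label-shuffled cohorts for chance-level classification, 20 seeds per level
for monotone recovery, and a 20-subject, 6-ROI cohort for the band-specific
classification contrast.

# Known limitations

* ROI mode assumes the input series already are source-level ROI signals;
  the inverse stage ships with toy leadfields only.
* The generator's white-noise background makes absolute connectivity/MI
  values cleaner than on real EEG; thresholds tuned on synthetic cohorts do
  not transfer to patients.
* Lagged coherence is undefined (reported 0) for mathematically identical
  channels — real pipelines should not feed duplicated ROIs.
* No comodulograms, no surrogate-based MI normalization, no alternative
  connectivity estimators (PLV, wPLI): group permutation inference covers
  significance for the implemented measures.
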