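# TripleNetEEG

Resting-state EEG analysis of large-scale brain-network reorganization, for
researchers studying how congenital sensory impairment (e.g. early visual or
hearing loss) reshapes functional connectivity among the sensory networks
and the triple network (default mode, salience and central executive). The
package provides the complete analysis chain as tested, reusable R
functions, together with a seeded synthetic-EEG generator that plants known
effects so that every stage can be validated against recoverable ground
truth.

## What it computes

**Lagged-coherence functional connectivity.** For ROI series x and y with
epoch-averaged cross-spectrum S<sub>xy</sub>(ω) and auto-spectra
S<sub>xx</sub>, S<sub>yy</sub>, the band-pooled lagged coherence is

```
LagCoh = Σ_ω Im[S_xy(ω)]² / Σ_ω ( S_xx(ω) S_yy(ω) − Re[S_xy(ω)]² )
```

over in-band frequency bins. It is bounded in [0, 1], is exactly 0 for
purely instantaneous (zero-lag, e.g. volume-conducted) coupling and reaches
1 for a noiseless quadrature pair. Over the packaged 24-ROI triple-network
atlas this yields 276 pairwise features per subject per band
(delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–44 Hz).

**Theta–gamma phase–amplitude coupling.** Per ROI, the instantaneous theta
(4–7 Hz) phase and gamma (30–45 Hz) amplitude are extracted by zero-phase
filtering plus the analytic signal; the phase axis is cut into n = 18 bins
and the modulation index is the normalized entropy deficit of the
phase-binned amplitude distribution P:

```
MI = ( lb(n) − H(P) ) / lb(n),   H(P) = −Σ_j P(j) lb P(j),   MI ∈ [0, 1]
```

**Group inference.** Pooled-variance two-sample t statistics per feature
with (a) max-statistic permutation correction (family-wise threshold from
the null distribution of max |t| under label shuffling, exhaustive
enumeration at tiny n) and (b) Benjamini–Hochberg FDR; plus summary-statistic
one-way ANOVA and Pearson chi-square for participant characteristics tables.

**Classification.** Linear SVM (C = 1) on the 276 connectivity features with
stratified 10-fold cross-validation (per-fold standardization), pooled
accuracy/sensitivity/specificity, and ranked absolute hyperplane weights
with extraction of the top 5 % (13/276) connections, annotated by network
pair.

**Optional source stage.** A standardized minimum-norm (sLORETA-style)
inverse with the zero-localization-error property on toy leadfields, and
first-principal-direction ROI aggregation, for running the pipeline from
sensor space; by default the pipeline operates directly on ROI series.

## Worked example

```r
library(TripleNetEEG)

# A small two-group cohort with an alpha-band connectivity reduction
# planted in the impaired group (pairs roi1–roi2 and roi3–roi4 drop from
# coherence 0.8 to 0.2), then the full chain:
cfg <- pipelineConfig(masterSeed = 11L, outDir = "demo_run")
run <- runPipeline(cfg)
pipelineReport(run)
```

prints

```
Pipeline run (master seed 11)
band      accuracy  sensitivity  specificity
delta        0.625        0.625        0.625
theta        0.938        0.875        1.000
alpha        1.000        1.000        1.000
beta         1.000        1.000        1.000
gamma        0.625        0.750        0.500
delta: no significant connections (crit |t| = 3.679)
theta: 2 significant connection(s): roi1--roi2, roi3--roi4
alpha: 2 significant connection(s): roi1--roi2, roi3--roi4
beta: 2 significant connection(s): roi1--roi2, roi3--roi4
gamma: no significant connections (crit |t| = 3.771)
MI group differences: largest |t| at roi5 (none FDR-significant)
```

The planted alpha effect is recovered exactly where it was planted: the two
manipulated connections are the only ones crossing the permutation
threshold, classification is perfect in the alpha band and at chance in
delta/gamma, and no spurious phase–amplitude coupling difference survives
FDR. (Theta and beta also respond because adjacent analysis bands share
their edge frequency bin with alpha.) Every output file, parameter and seed
is recorded in `demo_run/manifest.json`; re-running the same configuration
reproduces byte-identical outputs.

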