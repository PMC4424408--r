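---
title: "The HRM-DIA workflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The HRM-DIA workflow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmdia)
```

This vignette is the package's own account of the science it implements:
the models behind each workflow stage, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the design choices made where the design was
genuinely open. It states no empirical result that the package's tests and
scripts do not themselves compute.

## 1. The workflow in one paragraph

Data-independent acquisition records MS2 spectra over a fixed cycle of
precursor isolation windows, so every detectable peptide leaves a
fragment-level chromatographic trace in every run. Identification is
targeted and post hoc: a spectral library supplies, for each peptide
precursor, its fragment m/z values, their relative intensities and a
normalized retention time (iRT). For each run the iRT scale is mapped onto
the gradient by locating a handful of reference peptides, fragment
chromatograms are extracted in a narrow dynamic retention-time window,
candidate peak groups are scored by how well they behave like the library
says they should, and an mProphet-style target–decoy discriminant converts
those scores into peptide-level q-values. Quantities are fragment-area
sums on the MS2 level, normalized across runs, and differential protein
abundance is tested with a linear mixed-effects model per protein.

## 2. Acquisition scheme

`build_variable_windows()` splits the survey range into contiguous
half-open windows `[l, u)` carrying equal shares of a user-supplied
precursor density histogram (piecewise-linear quantiles, so per-window
mass is exact up to one bin). Variable widths mean densely populated m/z
regions get narrow windows — less co-isolation where it matters. The
half-open convention removes double assignment at boundaries, and no
overlap margin is added by default. `default_hrm_scheme()` fixes 19
windows over 400–1220 m/z at a 3.5 s cycle; rather than hard-coding any
particular instrument method's boundary list, the default density is a
smooth two-component normal mixture emulating tryptic 2+/3+ precursors, so
the shipped scheme is reproducible and structurally faithful (narrow
windows near 500–700 m/z, wide at the sparse high end). `cycle_period` is
pure configuration; no instrument duty-cycle model is attempted.

## 3. The synthetic-data generator

The generator is the package's stand-in for the spike-in benchmark: it
defines the study conditions and every downstream validation measures
against its ground truth.

**Design** (`make_profiling_design()`): 8 samples; a constant background
proteome (default level 20 concentration units); 12 spike-in proteins in
three master mixes. Mixes 1 and 2 introduce +10% and +60% changes at base
levels 1, 10 and 50 (the lowest spike level defines concentration unit 1);
mix 3 is a fourfold dilution series 1, 4, …, 4⁷. How the changed levels
are laid out across the 8 samples is a free design axis, so the multiplier
patterns are config-driven defaults (mix 1: `1, 1.1, 1.6` recycled; mix 2
the same rotated by one sample to avoid collinearity) and the ground truth
is, by definition, whatever the config produced.

**Catalog** (`simulate_catalog()`): random tryptic-like sequences (C-term
K/R), charge 2–3, precursor m/z constrained to the survey range, true iRT
uniform on [0, 100], per-peptide fragment templates (b/y ions, y-biased)
with relative intensities normalized to max 1. Masses use real residue
monoisotopic masses so precursor and fragment m/z are physically
consistent; sequence realism beyond that is immaterial because
identification is by extraction, not by sequence search. Eleven reference
peptides with evenly spaced iRTs emulate a calibration kit and are always
present at a constant level. *Absent* proteins get catalog entries — so
extraction assays exist — but never receive signal: they play the role of
the foreign-organism null set.

**DIA runs** (`simulate_dia_run()`): each present fragment contributes a
Gaussian elution peak (σ = 0.1 min by default, giving ~7 points per peak
at the 3.5 s cycle — the sampling density the acquisition method targets;
the peak shape itself is an assumption, the density is not). The apex sits
at the iRT-mapped retention time plus Gaussian jitter (default SD 0.2% of
the gradient), heights are concentration × template intensity ×
multiplicative lognormal error (default CV 10%, mean-corrected), every
trace carries a Poisson baseline (default mean 100 counts), and with
probability 0.05 a fragment receives an off-apex co-isolated interferent
(offset 1.5–3 peak SDs, comparable height). Traces are keyed by fragment
m/z rounded to 4 decimals. Because the trace map is sparse, baseline-only
traces are materialized for every m/z key that will be queried (absent
assays, plus `extra_mz` for decoys) — real spectra contain noise at any
m/z, and a null assay must extract *something*. The default gradient is
120 min, matching the 2 h separation the benchmark emulates.

**Height scale**: the benchmark design places the lowest spike level at
the limit of detection, a notion that is instrument-relative; here one
concentration unit maps to an apex of ~3× the baseline RMS
(`height_unit = 30` against Poisson(100) noise). This is a documented free
parameter, and the package's own fold-change validation shows its
consequence: contrasts involving the level-1 cells carry a quantification
bias comparable to (and exceeding 3×) the replicate standard error, while
every contrast above that level is recovered within ±3 SE. Small
concentration changes sitting at the detection limit are simply not
measurable with three replicates — an expected property of the regime,
reproduced rather than hidden by the simulation.

**DDA runs** (`simulate_dda_psms()`): shotgun undersampling as a logistic
detection probability in log2 abundance (monotone by construction),
retention-time error, multiplicative fragment noise, and a small chimeric
duplication rate. This is the input for library building only.

What the generator does **not** emulate: isotope envelopes, charge-state
cross-talk between windows, chromatographic tailing, ionization
competition, mass-calibration drift, and real proteome sequence
redundancy. Tests passing on this generator therefore validate the
*computational* workflow — extraction geometry, scoring calibration,
statistical machinery — not instrument physics.

## 4. Spectral libraries

`fit_irt_map()` fits `iRT = a·RT + b` by least squares with an iterated
3-SD outlier rejection (`robust = TRUE`), reporting the residual SD in iRT
units. `build_library()` builds consensus assays per (peptide, charge):
within-run duplicate identifications keep the most intense; observations
whose iRT deviates from the per-peptide median by more than 5 robust SDs
are discarded (the scale is the MAD-consistent SD — a plain SD would let a
single gross outlier widen its own acceptance band until nothing is ever
removed); consensus iRT and fragment intensities are medians over the
survivors; assays with fewer than 6 fragments are dropped. The 5-SD filter
is interpreted per-peptide rather than globally — a global band on the iRT
axis would remove almost nothing. `library_growth()` rebuilds the library
on run prefixes to show the saturation behaviour that motivates acquiring
redundant shotgun runs.

**Decoys** (`generate_decoys()`): one scrambled decoy per target ("no
decoy limit" read as 1:1) — non-terminal residues permuted with the
C-terminal residue fixed, fragment m/z recomputed for the same ion series,
iRT and intensities inherited (the mProphet convention; composition and
hence precursor mass are preserved). One subtlety surfaced by the
generator: a decoy lives in its target's isolation window at its target's
retention time, so any scramble that happens to leave a fragment mass
within the extraction tolerance of the target's ladder co-extracts *real*
signal and is no longer null. Scrambles are therefore re-drawn (best of
10) to avoid fragment-mass collisions within 25 ppm; the package's null
validation (decoy vs truly-absent Cscore distributions) quantifies the
residual difference.

`modification_mass()` computes monoisotopic deltas from elemental
compositions (e.g. `C8H7NO2`, the reactive-metabolite cysteine adduct);
`modified_assays()` emits position-annotated variable-modification assays
with correctly shifted precursor and fragment masses.

## 5. Targeted extraction and scoring

`calibrate_run()` locates the reference assays by unconstrained
whole-gradient extraction (best co-elution apex among the top candidates),
fits the robust iRT map, and sets the dynamic half-width to
`max(k · SD_resid, floor)` with `k = 3` and floor 1% of the library iRT
span. The instrument software's cryptic "correction factor" is implemented
as this configurable multiplier. At the default jitter the floor binds and
the window is ~2% of the gradient wide; as calibration degrades the window
widens automatically — that is the "dynamic" behaviour, validated by
`coverage_experiment()`.

`detect_peak_groups()` smooths the summed fragment XIC with a 1-cycle
Gaussian kernel, takes local maxima as candidate apexes, and walks
boundaries outward to flanking minima. Two numerical choices matter on
noisy pedestals: the boundary walk tolerates upward wiggles below 20% of
the peak prominence (otherwise counting noise truncates weak peaks at the
first dip), and integration never spans fewer than 3 cycles on each side
of the apex (the acquisition design guarantees 6–8 points per peak).
Fragment areas are trapezoidal integrals of the baseline-subtracted trace;
the per-fragment baseline is the *median of the out-of-peak portion* of
the extraction window, subtracted without clamping (only the final area is
clamped at zero). An earlier clamped-quartile variant was measurably
biased upward at low signal: the median-subtraction form is unbiased for
counting noise, which the fold-change validation at the detection limit
made visible.

Subscores per candidate: mean pairwise in-peak Pearson correlation
(co-elution), mean correlation with the summed consensus (shape),
correlation of areas with library intensities, absolute iRT deviation,
a mass-accuracy proxy (mean ppm offset of matched trace keys), and log
total area. `detect_interference()` flags a fragment when its in-peak
correlation against the consensus of the others falls below 0.75 or its
area share exceeds 5× its library share; the 3 best-correlating fragments
are always retained, and the retained area sum is renormalized by the
retained library-intensity share so exclusion does not shift the quantity
scale. Interference correction means *exclusion*, not subtraction — the
simpler, directly testable reading; down-weighting would be a config
extension.

`train_discriminant()` is the mProphet loop: iteration 0 ranks by the seed
score (z-standardized co-elution minus z-standardized iRT deviation); each
iteration takes targets at q ≤ 0.01 as positives and all decoys as
negatives, fits an LDA on standardized subscores (zero-variance subscores
dropped), and rescores; after 5 iterations the projection is z-normalized
against the decoy distribution — the "normalized discriminant score". LDA
(not boosting or SVMs) matches the original mProphet and is deterministic.
With fewer than 50 scored targets or decoys the seed score is used
directly. `assign_qvalues()` estimates FDR at threshold c as
`#{decoys ≥ c}/#{targets ≥ c}` with π₀ = 1 (conservative, appropriate for
1:1 decoys), running-minimum monotonized, ties resolved decoy-first.
Peptide-level control collapses charge states by maximum Cscore.

## 6. Quantification and normalization

`quantify()` fills a precursor × run matrix with interference-corrected
fragment-area sums where the run-level q-value passes (default 0.01); no
alignment, no imputation — missingness is the phenomenon under study, not
something to paper over. Modified forms and charge states stay separate
rows. `local_normalize()` removes loading and spray bias: per run, the
log2 deviations from row-wise cross-run medians are summarized by a
running median over retention time (window 10% of the RT span, a
configurable width) and subtracted — a running median is the natural
robust estimator for a smooth retention-time-dependent bias.
It assumes most peptides are invariant — true in the emulated experiment,
where the constant background dwarfs 12 spike-ins, and the benchmark
configurations keep that proportion. `completeness_and_cv()` reports the
missing fraction, full-profile counts over run prefixes, and
technical-replicate CVs on linear-scale intensities (the field's
convention for reported CVs); the pipeline computes them both before and
after normalization.

## 7. Differential abundance

Per protein, log2 intensities enter the MSstats-style mixed model

&nbsp;&nbsp;&nbsp;&nbsp;`y = μ + Sample_i + Precursor_j + Run_k + ε`,
`Run_k ~ N(0, σ²_run)`, `ε ~ N(0, σ²)`,

fit by REML via lmerTest (runs are nested in samples: one injection per
technical replicate). This is the published MSstats group-comparison
formulation for a design with fixed sample and precursor effects and a
random run, and the balanced special case is covered by an invariant: on complete
balanced data the mixed-model contrast t equals the closed-form two-stage
statistic (precursor-averaged run means, pooled within-sample variance,
df = Σ(r−1)), and the REML variance components match a brute-force
profiled-likelihood grid to 10⁻⁶ (both are frozen tests). Satterthwaite
degrees of freedom cover the unbalanced case. Single-precursor proteins
drop the precursor term; when the random effect is inestimable the fit
falls back to a fixed-effects model and is tagged. All 28 pairwise sample
contrasts are computed per protein; contrasts touching a sample with no
data are *infeasible*: p = 1, estimate missing — encoding inability to
test rather than evidence of no change. BH adjustment is applied across
proteins within each contrast (the MSstats convention; global pooling is a
config switch), and candidates require adjusted p ≤ 0.05 *and* a
fold change beyond 50% in either direction (`|log2FC| > log2 1.5`);
infeasible results never pass. ROC curves treat each (protein, contrast)
pair as one case (the pair-level reading; protein-level is available by
aggregating upstream), with AUCs compared by paired DeLong tests via pROC
— identical score vectors short-circuit to p = 1, where the variance
estimator degenerates.

## 8. Orchestration and reproducibility

`run_benchmark()` chains design → catalog → run order → DDA → library →
decoys → per-run simulate/calibrate/score → quantify → normalize →
metrics → mixed-model comparisons → candidates/ROC, with one global seed
expanded to per-stage seeds (`seed × 100 + stage`) so a config fully
determines the outputs. Absent-protein assays enter the library from the
catalog truth (they cannot be observed in DDA) and their realized false
discovery proportion is reported per run. The optional DDA arm degrades
the same quantity matrix with abundance-dependent missingness and re-runs
the differential analysis, giving the matched completeness/AUC contrast.
Intermediate artifacts are plain text (TSV/JSON/YAML).

## 9. Problem sizes

The package's studies run at desk scale, chosen once: the standard
benchmark uses a 60-min gradient, ~40 background + 12 spike proteins at ~5
peptides each, 24 runs; the window-coverage experiment uses the full
120-min gradient with ~2,000 present peptides over 5 runs; the FDR
calibration uses ~5,000 target assays (20% truly absent, 6 fragments each)
on a 20-min gradient over 20 seeds — a short gradient *raises* co-elution
density, making the null calibration conservative rather than easier.

## 10. Known limitations

* Elution peaks are Gaussian with a single width; no tailing, no
  saturation, no isotope structure — conclusions about instrument physics
  cannot be drawn from these simulations.
* The six subscores are a declared, extensible set; no claim of
  feature-for-feature parity with any proprietary implementation is made.
* Quantification at the detection limit (~3× baseline RMS) is biased
  relative to its replicate SE; the package reports it honestly rather
  than modelling heteroscedastic variances.
* Protein-level FDR of the library-building search is delegated to the
  generator's truth labels; with real DDA search results an external
  protein-FDR step would be required.
* No cross-run feature alignment is implemented, by design — the central
  claim under study is that targeted extraction makes alignment
  unnecessary.
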