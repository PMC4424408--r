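# hrmdia

End-to-end hyper reaction monitoring (HRM) workflow for SWATH-type
data-independent acquisition (DIA) proteomics, exercised on a bundled
synthetic-data generator.

## The problem

Shotgun (DDA) proteomics samples precursors semistochastically: typical
technical replicates share only 35–60% of their peptide identifications, so
multi-sample quantitative profiling suffers from pervasive missing values.
DIA instead fragments everything inside a fixed cycle of precursor
isolation windows, and peptides are identified *post hoc* by extracting
fragment-ion chromatograms with a spectral library. The HRM flavour of this
workflow adds variable-width isolation windows adapted to precursor
density, retention-time-normalized (iRT) libraries with in-run dynamic
calibration, fragment-level interference detection, and mProphet-style
semi-supervised scoring with target–decoy false discovery rate control at
the peptide level.

`hrmdia` implements that workflow for R users — method developers and
computational proteomics researchers who want a transparent, fully
inspectable reference implementation whose every stage can be validated
against simulated ground truth. Real instrument data is deliberately out of
scope: the package ships a generator that emulates a spike-in "profiling
standard" benchmark (a constant background proteome, 12 spike-in proteins
in three master mixes across 8 samples, technical triplicates in
block-randomized run order, DDA undersampling for library building, and
truly-absent peptides for null validation), so every claim the workflow
makes can be checked against known truth.

## The core machinery

* **Acquisition scheme** — `n` contiguous half-open windows
  `[l_i, u_i)` tiling the survey range such that each window carries an
  equal share of the precursor density mass (equal-mass quantile split);
  default: 19 windows over 400–1220 m/z at a 3.5 s cycle.
* **iRT calibration** — robust least squares `iRT = a·RT + b` through the
  reference-peptide apexes of each run; dynamic extraction half-width
  `max(3·SD_resid, 1% iRT span)`.
* **Scoring** — per assay, candidate peak groups from the smoothed summed
  fragment XIC; subscores (co-elution, shape correlation, library
  intensity correlation, iRT deviation, mass accuracy, log area) combined
  by an iteratively retrained linear discriminant (positives: targets at
  q ≤ 0.01; negatives: scrambled decoys); Cscore = decoy-normalized
  projection; `q(c) = min_{c' ≤ c} #{decoys ≥ c'} / #{targets ≥ c'}`.
* **Quantification** — MS2-level: interference-corrected fragment area
  sums, local (RT-windowed running median) normalization, no imputation.
* **Differential abundance** — per protein, the MSstats-style mixed model
  `log2 y = μ + Sample_i + Precursor_j + Run_k + ε`, `Run_k` random, fit by
  REML (lmerTest); all `n(n−1)/2 = 28` pairwise sample contrasts with
  Satterthwaite degrees of freedom; Benjamini–Hochberg adjustment across
  proteins within each contrast; candidates at adjusted p ≤ 0.05 and a
  more-than-50% fold change; ROC/AUC and DeLong AUC comparison via pROC.

## Worked example

```r
library(hrmdia)
bench <- run_benchmark(benchmark_config(seed = 9))
print(bench)
```

```
HRM benchmark report
  library: 188 targets, 188 decoys
  quant: 170 precursors x 24 runs, 6.15% missing, median CV 4.24%
  comparisons: 1120 (1113 feasible), candidates: 147
  AUC: 0.964
  DDA-degraded arm: 55.7% missing, AUC 0.710, DeLong p 3.08e-17
```

Reading this: the DDA simulations produced a consensus library of 188
target assays plus 1:1 scrambled decoys; targeted extraction of the 24 DIA
runs gave a quantification matrix with 6.15% missing cells and a median
technical-replicate CV of 4.24%; the mixed model ran all 28 pairwise
comparisons for each of 40 proteins (1120 tests) and flagged 147
candidates. When the very same quantities are degraded with DDA-like
semistochastic missingness, 55.7% of cells disappear and the ability to
rank truly differential spike-ins drops from AUC 0.964 to 0.710 (paired
DeLong p ≈ 3·10⁻¹⁷) — the completeness advantage the HRM design is built
around.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/diaprofiler.R all --seed 9 --out results/
```

## Package tour

| Stage | Functions |
| --- | --- |
| Scheme design | `build_variable_windows`, `assign_window`, `default_hrm_scheme` |
| Synthetic data | `make_profiling_design`, `simulate_catalog`, `simulate_dia_run`, `simulate_dda_psms`, `block_randomize` |
| Spectral library | `fit_irt_map`, `build_library`, `library_growth`, `generate_decoys`, `modification_mass`, `modified_assays` |
| Targeted extraction | `calibrate_run`, `extract_xic`, `detect_peak_groups`, `detect_interference`, `score_run` |
| Scoring & FDR | `train_discriminant`, `assign_qvalues`, `peptide_qvalues`, `validate_null` |
| Quantification | `quantify`, `local_normalize`, `completeness_and_cv` |
| Differential | `fit_protein`, `pairwise_compare`, `adjust_bh`, `candidate_list`, `roc_and_auc`, `delong_compare` |
| Orchestration | `benchmark_config`, `run_benchmark`, `coverage_experiment`, `fdr_experiment` |

The methods vignette (`vignettes/hrm-workflow.Rmd`) documents the models,
noise assumptions, parameter choices and known limitations.
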