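# erpica

Discriminating clinical groups from multi-channel event-related potentials
(ERPs) via independent components: Infomax ICA decomposition of group-level
ERP matrices, projector-based spatial filtering, sliding-window extremum
feature extraction, and a forward-selected SVM classifier under 10-fold
cross-validation. The package is aimed at EEG/ERP researchers who want a
tested, fully reproducible implementation of this pipeline, exercised
end-to-end on synthetic ERP data with known ground truth.

## The method

A subject's averaged ERP is a matrix *P* of 19 channels (rows, International
10-20 montage, average reference) by *T* time samples (250 Hz, 0–600 ms after
the second stimulus of a GO/NOGO pair). ICA models the collection of ERPs as
a linear mixture of temporally independent sources:

```
S = U P,          P = U⁻¹ S = Σᵢ Pᵢ,          Pᵢ = Fᵢ P,   Fᵢ = U⁻¹ U_zi
```

where *U* is the square unmixing matrix found by natural-gradient Infomax
(Bell–Sejnowski, logistic nonlinearity), columns of *U⁻¹* are component
topographies, and *U_zi* is *U* with all rows but *i* zeroed. Each spatial
filter *Fᵢ* is an oblique projector (*FᵢFᵢ = Fᵢ*, *FᵢFⱼ = 0*, *ΣFᵢ = I*)
that extracts component *i*'s scalp contribution from any subject's ERP.

From each component's time course at its most prominent channel, sliding
windows (template: start, end, window size, step) yield extremum features —
the minimum/maximum amplitude (μV) or its latency (ms). A greedy wrapper then
forward-selects *M* features by 10-fold cross-validated SVM accuracy (RBF
kernel, features standardized per training fold), and the selected panel is
scored by pooled out-of-fold accuracy, sensitivity and specificity. Group
comparisons use pooled-variance Student t-tests (from raw values, from
printed summary statistics, or pointwise along component time courses).

Because no ERP cohort is bundled, the `sim_config()` / `make_ground_truth()`
/ `simulate_dataset()` generator produces two-group datasets with known
topographies, Gaussian-bump source waveforms, per-subject latency and
amplitude variability, and a planted group latency shift — so every stage of
the pipeline can be validated against ground truth. A companion generator
plants amplitude, fast (20–35 Hz) and slow (0–1 Hz) artifacts in raw epochs
to exercise the automatic rejection rules (thresholds 100, 35 and 50 μV).

## Worked example

The numbered drivers under `analysis/` run the whole study in order
(`01_simulate` → `06_stats`), writing tables under `results/` and bulky
intermediates under `scratch/`. The classification stage prints:

```
Selected features (in order):
  1. IC6_Fz_min_latency_380_480  (CV accuracy 0.986)
  2. IC1_Pz_max_amplitude_80_180  (CV accuracy 1.000)
  ...
RBF:    accuracy 100.0%, sensitivity 100.0%, specificity 100.0%
Linear: accuracy 96.6%
```

The first selected feature is the latency of the minimum in the 380–480 ms
window of component IC6 at Fz — exactly the trough of the synthetic source
whose latency was shifted by 24 ms in the case group, recovered from 728
candidate features with no knowledge of the ground truth. The decomposition
stage reports the projector-algebra residuals (≈1e-16), the power explained
by the top seven components (97%), and split-half stability (mean absolute
topography correlation 0.9998); the statistics stage reproduces the pooled
t(146) statistics of the shipped cohort summary table
(`inst/extdata/cohort_summary_stats.csv`), e.g. t = 16.66 for
hyperactive/impulsive symptom counts.

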