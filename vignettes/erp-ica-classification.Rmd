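---
title: "Classifying groups from independent ERP components: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying groups from independent ERP components: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, assumptions, parameter choices and known
limitations behind `erpica`. It is the companion to the numbered drivers
under `analysis/`, which run the full study on synthetic data.

## The decomposition model

An averaged ERP is a channels-by-time matrix `P` (19 rows, 10-20 montage,
average reference; 250 Hz; time 0 at the second stimulus of a GO/NOGO pair).
ICA assumes that scalp potentials are an instantaneous linear mixture of a
fixed set of cortical generators with fixed scalp projections and temporally
independent activations, and that generator geometry is similar enough
across individuals that one unmixing matrix can serve a whole group. Under
those assumptions `S = U P` recovers source activations, the columns of
`U^-1` are component topographies, and `F_i = U^-1 U_zi` is an oblique
projector that extracts component i's scalp contribution from any ERP of any
subject. The projector identities (`F_i F_i = F_i`, `F_i F_j = 0`,
`sum F_i = I`, `sum F_i P = P`) hold algebraically for any invertible `U`,
so the test suite checks them to 1e-8 for every fitted model — they are the
contract that component removal (`remove_components`) and per-subject
projection (`project_component`) rely on.

ICA is fitted to *averaged* ERPs, concatenated across subjects
(`C x sum(T)`), not to concatenated raw EEG: averaging suppresses ongoing
background activity, so the decomposition concentrates on stimulus-locked
components rather than spontaneous rhythms. Fitting is per condition by
default (a NOGO-set decomposition and, where needed, a NOVEL one), since
different task sets engage partly different generators.

## Infomax: numerical choices

`fit_infomax` implements Bell–Sejnowski Infomax with the logistic
nonlinearity and the natural gradient, after row-centering and PCA
whitening. Concrete choices:

* **Learning rate 0.05, annealed by 0.9** whenever the gradient direction
  turns by more than 60 degrees between full-batch iterations. On whitened
  data the natural-gradient update is well scaled, and this rate converges
  in a few hundred iterations on all the package's benchmarks; much smaller
  rates (1e-3 and below) cannot reach the stopping tolerance within any
  reasonable iteration budget, which we verified on a two-source Laplacian
  mixture before fixing the default.
* **Stopping rule**: relative weight change `||dW||/||W|| < 1e-7`, or 1024
  iterations with a warning. Non-convergence warnings on noisy data are
  expected and benign: the rotation *within* the isotropic noise subspace
  has no unique optimum, so the full square model may keep drifting there
  after the signal components have long converged.
* **Rank handling**: average-referenced data have zero channel means, hence
  rank at most C-1 — the pipeline's own input is always rank deficient. The
  rotation is therefore estimated in the subspace of eigenvalues above
  `rank_tol` (1e-9 relative) and the square model is completed with the
  orthonormal null basis. Null components carry numerically zero power, sort
  last, and never affect filters of the retained components. An error is
  raised only when fewer than two informative dimensions survive.
* **Indeterminacies**: component order is fixed by descending explained
  power of `F_i P`, and signs by making each topography's largest-magnitude
  entry positive. With these conventions, independent restarts from
  different seeds reproduce the signal topographies to about 1e-3 on
  well-separated data (tested), which is what makes the decomposition
  citable as *the* decomposition of a dataset.

The independent check on correctness is deliberately crude: on two-channel
mixtures, a brute-force search over whitening-space rotation angles
maximizing total absolute excess kurtosis (tests/helper code, sharing
nothing with `fit_infomax`) must agree with Infomax at |correlation| >= 0.95
per source.

## What the generator emulates — and what it does not

`make_ground_truth()` builds seven sources mirroring the component families
this analysis targets: occipital and bilateral temporo-parietal sensory
sources, parietal/premotor/anterior-midline executive sources (NOGO
condition), and a central novelty source (NOVEL condition). Each source is a
focal, zero-mean, unit-norm scalp pattern and a waveform of one or two
Gaussian bumps with analytically known extremum latencies. Design
constraints, chosen once:

* **Bump latencies are spread** (main deflections at 105, 175, 250, 320/510,
  385, 440, 140/212 ms) so that source time courses are close to
  uncorrelated. ICA *assumes* independent sources; a generator with heavily
  overlapping bumps would violate the model it is meant to exercise.
* **Scalp magnitudes are a few microvolt** at each source's best channel
  (source amplitudes 6–15 in generator units, unit-norm topographies).
  Against the default residual sensor noise (0.5 μV per sample, the scale
  left after averaging on the order of a hundred raw trials), trough
  latencies are then measurable to a few milliseconds — the regime real ERP
  latency analyses operate in.
* **Per-subject variability**: Gaussian latency jitter (sd 4 ms per source)
  and log-normal amplitude scaling (sdlog 0.3 per source). The amplitude
  variability matters: adult ERP amplitudes vary strongly across
  individuals, and it is precisely this variability that makes fixed-window
  *amplitude* features unreliable group markers while *latency* features
  stay informative. Without it, an amplitude feature reads a planted latency
  shift off the moving flank of a deflection just as cleanly as a latency
  feature does, and the benchmark would not reproduce the latency-dominance
  phenomenon it is built around.
* **The group effect** is a 24 ms latency shift (six times the jitter sd) of
  the anterior-midline source in the case group — a trough-only source, so
  the planted difference is specifically a trough-latency shift. Shifts move
  the analytic Gaussian centers; nothing is circularly rotated, so there are
  no wrap-around artifacts. The shift magnitude is a free parameter of the
  benchmark: no effect sizes for component latency differences were
  available to calibrate against, only their statistical significance.

What the generator does *not* emulate: volume-conducted realistic head
geometry (topographies are schematic Gaussians on a 2-D layout), ongoing
oscillatory EEG and its 1/f spectrum (sensor noise is white), eyeblinks,
trial-to-trial latency variability within the average, and behavioral
responses. Consequently, passing tests show the pipeline is *correct and
recovers what was planted under its own assumptions*; they cannot show that
real recordings satisfy those assumptions.

For artifact-rejection tests, `simulate_artifact_epochs()` plants epochs
violating exactly one rule each — a 150 μV spike, a 60 μV oscillation at
27.5 Hz, a 75 μV wave at 0.5 Hz — against clean epochs of 5 μV noise. All
margins exceed 10% of the corresponding threshold on both sides, so a
correct classifier must agree with the planted labels exactly, and the tests
demand 100% agreement.

## Preprocessing rules

Epoch rejection follows three rules, applied per channel: absolute amplitude
strictly above 100 μV; 20–35 Hz band content above 35 μV; 0–1 Hz content
above 50 μV. The band criteria are implemented as the maximum absolute value
of the zero-phase (forward–backward) Butterworth-filtered trace — a 4th-order
band-pass for the fast rule and a 4th-order low-pass for the slow rule. Peak
amplitude, peak-to-peak and RMS readings of "μV in band" were all defensible;
maximum absolute in-band amplitude is the simplest and is what the tests
pin down. Values exactly at a threshold are kept (the rules are strict
inequalities). Rejection is epoch-wise, with reason codes recorded per epoch.

## Feature machinery

A feature template (start, end, window, step, min/max, amplitude/latency)
expands into concrete windows advancing while `t0 + window <= end`; the
count per window size obeys `floor((end - window - start)/step) + 1` (126
windows for 0–600 ms, 100 ms window, 4 ms step; the full reference grid with
window sizes 50/75/100/125/150 ms, both extrema and both return types over
seven components enumerates 17,584 features). The alternative reading of
"until the window reaches the end" (`t0 <= end`) was rejected because it
produces truncated windows of varying length. Window membership is a closed
interval on the millisecond axis; extremum ties break to the earliest
sample; latency is reported relative to stimulus onset, not window start.
The benchmark grid used by the drivers and the acceptance script is coarser
(100 ms windows, 20 ms steps, 728 features over seven components) purely to
keep the wrapper search inside a desktop run; the enumeration logic is
identical and tested at both granularities.

## Classification protocol

The wrapper forward selection scores each candidate feature set by the same
stratified 10-fold cross-validated accuracy later reported — a single-loop
protocol that is knowingly optimistic, because the selection has seen every
fold's test labels through the criterion. This reproduces the protocol the
pipeline is modeled on; `selection_generalization()` provides the honest
alternative (selection repeated inside each outer fold) for anyone who wants
an unbiased estimate, and is clearly separated from the default path. Folds
are stratified by group and fixed once per selection run, which makes the
greedy search deterministic and cuts its cost to at most `N x M`
evaluations; ties break to the lowest feature index.

SVM details (unstated in the protocol being reproduced, so fixed here):
`e1071::svm` with C = 1; features standardized inside each training fold
(amplitudes are μV, latencies ms — unstandardized they are incommensurable);
RBF gamma = 1/(p × mean feature variance) computed on the standardized
training block. Sensitivity is the true-positive rate on the case group.

## Statistics

All group comparisons are pooled-variance Student t-tests (two-sided); for
74 + 74 subjects the degrees of freedom are 146, which is the signature of
pooling (Welch would give fractional df). `ttest_from_summary` works from
printed (mean, sd, n) triples and equals the raw-data `t.test(var.equal =
TRUE)` exactly when the summaries come from the raw samples; recomputing t
from a published table's rounded cells reproduces printed t values only to
within rounding of those cells, which is why the acceptance checks use a 1%
relative band. Pointwise component comparisons apply the same t at every
time sample with an uncorrected p < 0.05 mask — deliberately, as the
reference analyses apply no multiple-comparison correction; under the null
the mask fires at the alpha rate (tested by simulation).

## Split-half stability

`split_half_stability` randomly halves the subjects (on the sorted ID list,
so subject order is irrelevant), fits ICA on each half's grand-average ERP
(conditions concatenated), and greedily matches components across halves by
absolute topography correlation. The report is restricted to the top
`n_components` by explained power (7 in the benchmark): a square model on
rank-deficient, near-noiseless grand averages necessarily contains
null-space components whose "topographies" are arbitrary, and averaging
their chance-level matches into a stability figure would say nothing about
the components anyone retains.

## Problem sizes

The shipped analyses use: 74 subjects per group, 19 channels, 151 samples
per ERP (0–600 ms at 250 Hz), two conditions; ICA on the 19 × 22,348 NOGO
concatenation; 728-feature wrapper selection of M = 5 under 10-fold CV;
ICA-recovery checks on a 17-per-group noiseless set (10,268 concatenated
samples); artifact tests on 19–32 epochs of 1.2 s. The unit-test fixtures
use 4–6 subjects per group. These sizes were chosen so the full suite and
the acceptance script each complete in minutes on a single CPU while keeping
every check at, or above, the scale at which its property is meaningful.

## Known limitations

* Spatial filters fitted on a study's own sample are *not* generic: applying
  this pipeline to new cohorts requires either refitting or importing an
  external decomposition via `read_mixing_model`.
* The square-model completion assigns null-space directions arbitrary (if
  harmless) topographies; only components within the signal rank are
  interpretable.
* The single-loop selection accuracy is an optimistic estimate by
  construction; treat it as a selection criterion, not a generalization
  claim.
* The generator's schematic topographies make scalp-pattern realism claims
  impossible; it validates algebra and recovery, not physiology.
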