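---
title: "Connectivity increment rate features from motor-imagery brain networks"
author: "bfncir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity increment rate features from motor-imagery brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

bfncir implements a graph-theoretic feature-extraction route for
multiclass motor-imagery (MI) EEG. The premise is neurophysiological:
imagining a limb movement engages the corresponding motor cortex — the
left-hand area under electrode C4, the right-hand area under C3, the foot
area under Cz — and this engagement shows up in the mu rhythm (8–13 Hz)
not only as a local power change (ERD) but as a change in the
*coordination* between channels. The pipeline therefore works on
inter-channel dependence rather than band power:

1. **Mu rhythm.** Each channel of a 60-electrode, 250 Hz trial is
   band-pass filtered to 8–13 Hz with a 4th-order Butterworth filter
   applied forward–backward (zero phase, so the filter cannot shift
   correlations between channels). The imagery window (4–8 s of the 10 s
   trial) is then sliced out; the order is fixed as filter-then-slice so
   that filter transients never sit at stage boundaries.
2. **Weighted network.** The Pearson correlation coefficient
   \(r_{ij}\) between every pair of channel signals gives a 60 × 60
   symmetric connection matrix — a weighted brain functional network
   (BFN) whose nodes are electrodes.
3. **Thresholding.** A binary adjacency keeps an edge exactly when
   \(r_{ij} \ge \delta\) (boundary inclusive, signed correlation;
   an absolute-value mode exists behind a flag but is off by default
   because with thresholds \(\ge 0.5\) negative correlations never
   survive anyway). Self-loops are excluded.
4. **Threshold selection.** \(\delta\) is chosen per subject–task
   condition on the trial-averaged correlation matrix by two principles:
   the network must retain significant connectivity — mean node degree
   \(K = 2E/N \ge \ln N\) (\(\ln 60 \approx 4.09\)) — and, among feasible
   candidates on the grid 0.50–0.95 (step 0.05), it should have maximal
   small-world character, measured by the comprehensive index
   \(\sigma = \gamma / \lambda\) with
   \(\gamma = C_\mathrm{real}/C_\mathrm{rand}\) and
   \(\lambda = L_\mathrm{real}/L_\mathrm{rand}\). Ties go to the larger
   threshold, matching the observation that \(\sigma\) grows with
   \(\delta\) on these networks.
5. **Regional connectivity value.** For each of three fixed 15-electrode
   regions centred on C3, C4 and Cz, the connectivity value
   \(C = \sum_{i<j \in V} r_{ij} a_{ij}\) sums the surviving edge weights
   inside the region — a scalar measure of how strongly and densely the
   region is internally coupled.
6. **CIR.** Each region's imagery-window \(C\) is normalised by the
   pooled resting baseline \(\bar{C}_\mathrm{rest}\) of that region, and
   the absolute ratio \(\mathrm{CIR} = |C_\mathrm{image} /
   \bar{C}_\mathrm{rest}|\) forms the per-trial feature vector
   \([\mathrm{CIR}_{C3}, \mathrm{CIR}_{C4}, \mathrm{CIR}_{Cz}]\).
7. **Classification.** A one-versus-rest RBF SVM over the seven mental
   tasks (silence, three simple MI tasks, three compound MI tasks),
   evaluated with stratified 5-fold cross-validation repeated 10 times;
   pairwise task differences are assessed with a two-sample multivariate
   (Hotelling-type) test per task pair.

## Design choices where the design was open

Several points are under-determined by the method description and were
fixed as package design decisions:

* **Random reference.** The small-world reference is the uniform ensemble
  of graphs with the *same node and edge count* (100 realizations by
  default). Matching only the node count would make \(\gamma\) and
  \(\lambda\) incomparable across thresholds, since both clustering and
  path length depend strongly on density.
* **Disconnected networks.** Near the \(K \ge \ln N\) boundary the
  thresholded network can be disconnected. The characteristic path length
  averages over connected ordered pairs only and the disconnection is
  flagged, rather than returning infinity, because the feasibility bound
  (not the path length) is the guard against fragmentation.
* **Threshold granularity.** One \(\delta\) per subject–task condition,
  selected on the trial-averaged correlation matrix. A per-trial mode and
  a global fixed \(\delta\) are available
  (`runExperiment(globalDelta =)`); per-condition selection is the
  default because a single threshold per condition is what a per-subject,
  per-task audit table naturally reports.
* **Baseline.** The default baseline pools the imagery-window
  connectivity of the *silence* task over all subjects
  (`baselineMode = "silence"`). An alternative pools the 0–3 s
  preparation stage of every trial (`"preparation"`); both readings of
  "resting" are defensible, so both are implemented and the choice is a
  flag. Baselines are per-region scalars, which calibrates each silent
  CIR coordinate to ≈ 1 separately.
* **Region restriction order.** Regional networks are built by
  restricting the correlation matrix to the 15 region nodes *before*
  thresholding. Because the edge rule is pairwise, restricting before or
  after thresholding is provably equivalent, and a test asserts this
  equivalence.
* **Multivariate test.** "Multifactor ANOVA" over a 3-D feature with one
  p-value per task pair is operationalised as a two-group MANOVA (Pillai
  statistic, equivalent to Hotelling's \(T^2\) for two groups), with a
  univariate per-coordinate breakdown reported alongside. Raw p-values
  are reported; a Holm correction can be applied by the user
  (`p.adjust`).
* **SVM.** RBF kernel, cost 1, features standardised with training-fold
  statistics only. Splitting is stratified by task and pools subjects; a
  subject-aware split is deliberately out of scope for the default
  because the evaluation design pools subjects.

## The synthetic generator

Real recordings of this experiment design are not redistributable, so the
package ships a seeded generator whose *defaults are the study
conditions*: 12 subjects × 7 tasks × 10 trials (840 trials), 10 s trials
at 250 Hz, stages 0/3/4/8/10 s.

Each region centre (C3, C4, Cz) drives one latent source: band-limited
8–13 Hz Gaussian noise, scaled to unit variance. (Band-limited noise, not
a sinusoid: equal-frequency sinusoids would correlate perfectly across
channels regardless of gain, leaving nothing to tune.) Channel \(c\)
records

\[ x_c(t) = \sum_r g_r(t)\, e^{-d(c,r)/\lambda_s}\, s_r(t) + \varepsilon_c(t), \]

where \(d\) is the electrode distance on a schematic 2-D 10-20 grid,
\(\lambda_s\) the spatial decay (1.5 grid units), \(g_r(t)\) the coupling
gain — elevated (5) for task-active regions during the 4–8 s imagery
window, baseline (2) otherwise — and \(\varepsilon\) white noise of sd 3.
ERD itself (an amplitude *decrease*) is modelled only through its network
consequence, increased inter-channel mu-band correlation during imagery,
because the pipeline consumes correlations, not power.

The gains, decay and noise level are free parameters: nothing in the
method description quantifies within-region correlation levels. They were
chosen once so that a scientist would recognise the qualitative regional
pattern — the silent state keeps a connected mu network (so threshold
selection is feasible and baselines are nonzero), left-hand imagery
elevates the C4 region most, right-hand C3, foot Cz, and compound tasks
elevate both their regions — and were not revisited. With these defaults
the selected thresholds fall in the 0.55–0.85 range across conditions and
per-trial seeds are derived by stable integer hashing of
(master seed, subject, task, trial), so the full experiment is
reproducible bit for bit from one integer.

What the generator does *not* emulate: volume conduction and a realistic
forward head model, ocular/muscular artifacts, 1/f background spectra,
subject-level variability beyond seed differences, and non-stationarity
within stages. Passing tests on this generator therefore demonstrate that
the pipeline recovers planted correlation structure of the expected
regional kind — not that the feature separates real EEG, whose
between-subject variability is far richer.

## Numerical choices and degenerate inputs

* Correlations are computed by `stats::cor` and clamped to \([-1, 1]\);
  zero-variance channels are an error naming the channel.
* Matrix symmetry is enforced to within 1e-12 by averaging with the
  transpose; class validity checks symmetry, unit diagonal and range.
* Sample indexing is 0-based half-open in time: the window
  \([a, b)\) seconds maps to samples \(\lfloor a f_s \rfloor + 1\) through
  \(\lfloor b f_s \rfloor\) (1-based), so a 4 s window at 250 Hz is
  exactly 1000 samples.
* An empty graph has no defined path length (error); a graph whose random
  reference has zero clustering leaves \(\sigma\) undefined (`NA` in the
  audit table, error in `smallWorld`).
* If no grid threshold satisfies \(K \ge \ln N\), selection fails with a
  condition of class `noFeasibleThreshold` carrying the full audit table.
* Random-reference values inside threshold selection are cached by edge
  count, with the reference seed a pure function of (seed, E), so cached
  and uncached runs agree exactly.

## Problem sizes used in the shipped checks

The test suite runs the full default experiment (840 trials) once for the
end-to-end checks: task-wise regional dominance by majority vote over the
120 trials per task, silent-state calibration on a 60/60 split of the
silence trials (baseline vs held-out), and classification with 5-fold CV
repeated 10 times. Unit tests use 1–4 subjects and 2–6 trials per
condition; oracle comparisons (triangle counting, all-pairs BFS, the
double-loop correlation sum, pair enumeration of the connectivity value)
run on random graphs of up to 12 nodes, where exhaustive enumeration is
exact and fast. Monte-Carlo checks (mixing closed form, small-world
calibration of \(\sigma\) on uniform graphs) use pooled samples of 10^4
and ensembles of 50 graphs respectively.

## Known limitations

* The CIR scale depends on the selected threshold; conditions with
  different \(\delta\) have connectivity values summed over different
  edge sets. The per-condition selection mirrors the audit-table design,
  but a global-\(\delta\) sensitivity check (`globalDelta = 0.85`) is one
  line.
* The silent-state calibration (CIR ≈ 1) is exact by construction when
  the baseline pool and the evaluated trials coincide; the shipped checks
  use disjoint sets, which is the honest version of the same property.
* Classification accuracy on synthetic data reflects the generator's
  separation and should not be read as a claim about real-data accuracy.
* EDF support is a minimal profile (one data record, 16-bit samples,
  per-channel physical scaling) sufficient for round-tripping trials, not
  a general EDF(+) implementation.
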