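# bfncir

Brain functional network connectivity features for motor-imagery EEG.

## What it does, and for whom

Brain–computer interfaces that decode *motor imagery* (MI) — imagined
hand or foot movements — usually work from band-power features of single
channels. For multiclass problems, and especially for *compound* imagery
engaging two limbs at once, single-region power misses the point: several
motor areas coordinate. This package implements a network route for
researchers working on MI decoding: it treats the 60 scalp electrodes as
nodes of a **brain functional network (BFN)**, quantifies coupling on the
mu rhythm, and extracts a three-dimensional regional feature that
classifies seven mental tasks (silence, left hand, right hand, left foot,
and the compounds LH&RH, LH&LF, RH&LF).

The core quantities, in the field's notation:

* Edge weights: Pearson correlation
  *r<sub>ij</sub>* between the 8–13 Hz (mu) filtered signals of channels
  *i* and *j* during the 4–8 s imagery window.
* Binary network: *a<sub>ij</sub>* = 1 iff *r<sub>ij</sub>* ≥ δ
  (boundary inclusive, no self-loops).
* Threshold selection: δ swept over 0.50–0.95 (step 0.05); feasible
  when the mean node degree satisfies **K ≥ ln N** (ln 60 ≈ 4.09); among
  feasible candidates, maximise the small-world index
  **σ = γ/λ**, where γ = C<sub>real</sub>/C<sub>rand</sub> and
  λ = L<sub>real</sub>/L<sub>rand</sub> against random graphs with the
  same nodes and edges.
* Connectivity value of a region (15 electrodes centred on C3, C4 or
  Cz): **C = Σ<sub>i&lt;j∈V</sub> r<sub>ij</sub> a<sub>ij</sub>**.
* Feature: the **connectivity increment rate**
  **CIR = |C<sub>image</sub> / C̄<sub>rest</sub>|**, one per region,
  giving the per-trial vector [CIR<sub>C3</sub>, CIR<sub>C4</sub>,
  CIR<sub>Cz</sub>]. Silent-state trials calibrate to ≈ 1 in every
  coordinate; imagining the left hand inflates CIR<sub>C4</sub>, the
  right hand CIR<sub>C3</sub>, the foot CIR<sub>Cz</sub>, and compound
  tasks both of their regions.
* Classification: one-versus-rest RBF SVM, stratified 5-fold
  cross-validation repeated 10 times; pairwise task differences by a
  two-sample multivariate (Hotelling-type) test for each of the 21 task
  pairs.

Because recordings of this experiment design are not redistributable, the
package ships a seeded synthetic EEG generator (12 subjects × 7 tasks ×
10 trials of 10 s at 250 Hz) whose latent mu-band sources sit at C3, C4
and Cz and couple into the channels with task-dependent gains — enough
structure to exercise and test every stage of the pipeline.

## Worked example

```r
library(bfncir)

## one left-hand trial end to end
rec <- simulateTrial(simulationConfig(), task = "LH", subject = 1, trial = 1)
mu  <- bandpassMu(rec)                               # 8-13 Hz, zero phase
R   <- correlationMatrix(extractStage(mu, "imagery"))
sel <- selectThreshold(R, nReps = 100, seed = 1)
sel
#> ThresholdSelection: chosen delta = 0.85 (K >= ln N = 4.09)
#>   10 candidates, 8 feasible
head(auditTable(sel)[, c("delta", "K", "sigma", "feasible")], 4)
#>   delta        K    sigma feasible
#> 1  0.50 25.70000 1.766466     TRUE
#> 2  0.55 22.20000 1.826065     TRUE
#> 3  0.60 18.16667 1.981266     TRUE
#> 4  0.65 15.00000 2.388535     TRUE

## a small experiment: 2 subjects x 7 tasks x 5 trials
res <- runExperiment(simulationConfig(nSubjects = 2, nTrialsPerTask = 5),
                     nReps = 50)
aggregate(cbind(CIR_C3, CIR_C4, CIR_Cz) ~ task, featureTable(res),
          function(x) round(mean(x), 2))
#>    task CIR_C3 CIR_C4 CIR_Cz
#> 1    LF   0.87   0.78   1.82
#> 2    LH   0.29   1.93   0.66
#> 3 LH&LF   0.63   1.78   1.53
#> 4 LH&RH   1.78   1.54   0.56
#> 5    RH   2.19   0.19   0.59
#> 6 RH&LF   1.84   0.34   1.24
#> 7     S   1.00   1.00   1.00

cv <- ovrSvmCv(featureTable(res), folds = 5, repeats = 10, seed = 1)
cv
#> ClassificationResult: 5-fold CV x 10 repeats, overall accuracy 89.43%
```

Reading the numbers: the chosen δ = 0.85 keeps the network both connected
(K ≥ 4.09) and maximally small-world. In the feature table each row is a
task's mean CIR vector — silence sits at 1 in all three coordinates (its
connectivity matches the pooled resting baseline), left-hand imagery
peaks in the C4 column, right-hand in C3, left-foot in Cz, and each
compound task elevates its two regions. Those separations are what the
one-versus-rest SVM exploits.

A thin command-line wrapper over the same functions is installed at
`inst/cli/bfncir.R` (`simulate`, `features`, `classify`, `run-all`).

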