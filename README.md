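# reflexquant

Quantification and NINDS-scale classification of the patellar (knee-jerk)
reflex from three-channel inertial recordings.

## The problem

The patellar reflex test is usually elicited and graded by eye on the NINDS
scale (`0+` absent, `1+` diminished, `2+` lower-normal, `3+` upper-normal).
Instrumenting the test — a tapping sensor on the tendon marking the hammer
impact with a 5 V pulse, and an inertial measurement unit on the ankle
recording the knee angular position (degrees) and angular velocity
(degrees/s) at 5 kHz — turns the grading into a signal-analysis problem.
`reflexquant` is aimed at researchers in clinical biomechanics who want a
tested, reproducible implementation of that analysis chain:

1. **Preprocessing** — impact-pulse synchronisation (2.5 V threshold), a
   4-s post-impact analysis window, and a zero-phase 3rd-order Chebyshev
   type-I low-pass at 100 Hz.
2. **Feature extraction** — six biomechanical features of the response
   θ(t): the peak-to-peak excursion Δa = max θ − min θ; the max-to-min
   interval Δt₁ (ms); the first-to-third positive-peak decay ratio
   Δ₁/₃ = P₃/P₁ and interval Δt₂ (s); the settling time T_s, the earliest
   time at which the cumulative energy Σθᵢ² reaches 97% of the window
   total; and the peak angular velocity V_max.
3. **Statistics** — per-grade summaries and tie-corrected Kruskal–Wallis
   H tests of group separation for every feature.
4. **Classification** — leave-one-out cross-validated Gaussian naive
   Bayes, KNN, linear SVM and bagged trees over the published feature-set
   combinations, with optional fold-wise PCA.
5. **A calibrated synthetic cohort** — the clinical recordings behind the
   published group statistics are not public, so the package includes a
   seeded generator based on an exponentially damped sinusoid
   A·e^(−t/τ)·sin(2πft) plus a slow return-to-baseline component, inverted
   per grade against the published feature means through the full pipeline
   (see the methods vignette for the model and its justification).

Recordings are read and written in a LabVIEW-measurement-style (LVM)
tab-delimited text dialect; feature tables are plain CSV.

## Worked example

```r
library(reflexquant)

config <- pipeline_config(seed = 42)

# calibrate the generator to the published per-grade feature statistics
# and simulate the default cohort (8 x 0+, 20 x 1+, 48 x 2+, 30 x 3+)
recs <- simulate_dataset(seed = 42, config = config)
features <- extract_dataset_features(recs, config)

subset(group_summary(features), feature %in% c("delta_a", "vmax"))
#>    label feature  n   mean     sd
#> 1     0+ delta_a  8  3.234  1.560
#> 6     0+    vmax  8  2.497  1.342
#> 7     1+ delta_a 20 22.891 11.153
#> 12    1+    vmax 20  9.904  5.066
#> 13    2+ delta_a 48 56.454 13.432
#> 18    2+    vmax 48 23.183  7.380
#> 19    3+ delta_a 30 93.218 24.191
#> 24    3+    vmax 30 38.718  8.765

kruskal_wallis(split(features$delta_a, features$label))$p
#> [1] 6.282098e-17

spec <- classifier_spec("naive_bayes", feature_subset = c("delta_a", "vmax"))
loo_cv(features, spec, seed = 42)
#> <cv_report> LOO accuracy 83.02% (18/106 misclassified)
#>      predicted
#> truth 0+ 1+ 2+ 3+
#>    0+  8  0  0  0
#>    1+  1 16  3  0
#>    2+  0  2 41  5
#>    3+  0  0  7 23
```

The excursion and peak-velocity means rise strictly with the clinical
grade (3.2 / 22.9 / 56.5 / 93.2 degrees for the excursion), every feature
separates the grades at p < 0.05 under the Kruskal-Wallis test, and the
headline classifier configuration (naive Bayes on the excursion and peak
velocity) reaches ~83% leave-one-out accuracy on this cohort, with the
errors concentrated on the 2+/3+ boundary - the same qualitative picture
as the clinical study the synthetic cohort is calibrated to.

The complete analysis is scripted under `analysis/`
(`01_calibrate_and_simulate.R` ... `04_classification.R`), writing its
tables under `results/`.

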