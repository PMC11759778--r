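# tremorclust

Unsupervised classification of parkinsonian resting tremor from wearable
triaxial accelerometry.

Clinicians grade resting tremor with item 3.17 of the MDS-UPDRS — the maximal
displacement amplitude of the tremor at rest, scored 0–4 per limb — a quick
but subjective assessment. `tremorclust` implements a deliberately simple,
fully unsupervised pipeline that recovers this grading from body-worn
accelerometer recordings without any training labels, for researchers in
digital health and movement disorders who want an objective, reproducible
baseline for tremor quantification.

## Method

For each subject-limb, the rest-period samples identified by the clinical
task annotations are concatenated into a *recording instance*
$a_i = \{(x_j, y_j, z_j): j = 1..n_i\}$, mean-centered per axis (removing the
constant gravity/orientation component), and reduced to the movement-intensity
modulus $\lVert a^*_{ji} \rVert = \sqrt{x_j^{*2} + y_j^{*2} + z_j^{*2}}$ — a
scalar, orientation-invariant intensity series. The pooled moduli of all
instances are clustered with one-dimensional k-means, minimising the
within-cluster SSE $\sum_u \sum_{s \in C_u} (s - \mu_u)^2$ (greedy k-means++
initialisation, ten restarts, batch Lloyd plus online single-point
refinement). Each instance is then summarised by its **dominant cluster**:
the modal cluster label among the samples above the instance's own 95th
percentile of intensity. Because cluster labels are arbitrary, they are
aligned to the clinical scores by exhaustive **permutation mapping** — the
accuracy-maximising one-to-one assignment — and evaluated with confusion
matrices, accuracy, precision, recall and F1.

Three evaluation tasks are supported: tremor vs non-tremor detection over
patients and controls (k = 2), multiclass severity grading among PD
instances (k = number of observed scores), and moderate-vs-milder severity
(k = 2). A dynamic-programming oracle (`kmeans1d_dp()`) provides the exact
globally optimal 1-D clustering for verification, and a synthetic cohort
generator (`simulate_cohort()`) produces severity-graded accelerometer
cohorts with annotations so the whole pipeline runs offline.

## Worked example

Simulate a 25-instance cohort with cleanly separated severity bands,
preprocess it, and run the detection task:

```r
library(tremorclust)

cfg <- recovery_config(seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic tremor cohort: 25 recording instances (14 PD, 11 HC)
#> score
#>  0  1  2  3
#> 11  6  5  3

instances <- preprocess_cohort(cohort)
run_task(instances, task = 1, seed = 42)
#> Unsupervised tremor classification - task 1
#> 25 instances, k = 2, SSE = 11691
#> Task 1 evaluation (25 instances)
#> Accuracy: 1.00 (25/25)
#> Confusion matrix (rows = true, cols = predicted):
#>     predicted
#> true  0  1
#>    0 11  0
#>    1  0 14
#>  class precision recall f1 support
#>      0         1      1  1      11
#>      1         1      1  1      14
#> Macro: precision 1.00, recall 1.00, F1 1.00
#> Positive class 1: precision 1.00, recall 1.00, F1 1.00
```

All 11 controls land in the low-intensity cluster and all 14 tremor
instances in the high-intensity cluster: with gapped amplitude bands and low
noise the detection task is fully recoverable. On real cohorts the bands
overlap in acceleration terms and accuracy is substantially lower (see the
next section and the methods vignette).

The package also ships the published per-instance clustering tables for the
25-instance clinic cohort it re-implements, and re-derives every reported
metric from them:

```r
reference_evaluation()
#> Performance across tasks (from the packaged reference tables)
#>  Task Accuracy Precision Recall   F1
#>     1     0.76      1.00   0.57 0.73
#>     2     0.57      0.56   0.53 0.54
#>     3     0.71      0.40   0.67 0.50
#> (Task 1: tremor vs non-tremor, 25 instances; Task 2: multiclass severity,
#>  14 PD instances, macro-averaged; Task 3: moderate vs milder tremor.)
```

Row 1 reads: 19 of 25 instances correctly detected (accuracy 0.76), no
control ever placed in the tremor cluster (precision 1.00), but only 8 of 14
tremor instances recovered (recall 0.57) — mild tremor is the failure mode.

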