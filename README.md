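# kneegrade

Automated Kellgren–Lawrence (KL) grading of knee osteoarthritis from
bilateral knee radiographs — built as a fully testable R package that needs
no patient data.

## The problem

KL grading scores radiographic knee osteoarthritis on an ordinal 0–4 scale
using two cardinal signs: narrowing of the joint space between femur and
tibia, and marginal osteophytes. Clinical films are *bilateral* (both knees
in one image, each with its own grade), and in symptomatic cohorts grades 0
and 1 share identical radiographic appearance — the label difference is
patient-reported pain. A computer-aided grading pipeline therefore has to
(1) isolate each knee from the raw film, (2) split data by *patient* so the
two knees of one person never straddle the train/test boundary, (3) learn
the severity signal, and (4) be evaluated in a way that is honest about the
0-vs-1 ambiguity.

`kneegrade` implements that pipeline end to end for researchers and
students of medical image analysis who want to study, test or extend it
without access to a clinical dataset:

* **`phantom`** — synthetic bilateral radiographs with known per-knee
  grades, grade-dependent joint-space gap `g(k)` (default 12/12/8/4/1 px
  for k = 0…4), 0/0/1/2/4 marginal osteophytes, an annotation-text block,
  size jitter and Gaussian noise; grades 0 and 1 are image-identical by
  construction with a latent pain flag carrying the label.
* **`isolation`** — standardize → unsharp-mask sharpen → Otsu threshold
  (maximizing between-class variance σ²_b(t) over the 256-bin histogram) →
  5×5 morphological opening → column-projection knee detection → crop →
  zero-pad to square → resize to 224×224 → divide by 255.
* **`datapipe`** — patient-level 80/20 split (`ceil`, so 301 patients give
  61 test patients), then augmentation (rotation ±30°, zoom 0.8–1.2, shift
  ≤10%, shear ±20°, horizontal flips) and a slice-level 90/10
  train/validation split of the augmented pool.
* **`model`** — the classifier architecture with exact parameter
  accounting: a 3×3 conv adapter (1→3 channels, 30 parameters), a
  DenseNet-121 backbone (7,037,504 parameters, 83,648 non-trainable
  batch-norm statistics, 7×7×1024 output), flatten (50,176), and an FC head
  128/64/16/5 with ReLU, L2 (λ=1e-4), dropout 0.3 and softmax — 13,469,571
  parameters in total. A compact trainable profile (`backbone = "tiny"`)
  with hand-verified gradients runs on a laptop CPU.
* **`metrics`** — categorical accuracy, macro one-vs-rest ROC AUC
  (Mann–Whitney rank statistic), macro precision and recall from
  one-vs-rest confusion counts `TP/(TP+FN)`, `TP/(TP+FP)`, and categorical
  cross-entropy `−Σ yᵢ log ŷᵢ`, each checked against brute-force oracles.
* **`trainer`** — Adam with reduce-on-plateau and early stopping, classical
  baselines (entropy decision tree, SVM with one-vs-one decisions, random
  forest) on standardized flattened slices, and the grade-0/1
  confusability analysis.

## A worked example

```r
library(kneegrade)

# five phantom patients, two knees each
cohort <- generate_cohort(5, seed = 1)
cohort[, c("patient_id", "grade_left", "grade_right")]
#> # A tibble: 5 x 3
#>   patient_id grade_left grade_right
#>   <chr>           <int>       <int>
#> 1 P0001               3           1
#> 2 P0002               2           1
#> 3 P0003               2           4
#> 4 P0004               1           4
#> 5 P0005               3           3

slices <- cohort |> patient_split(0.2, seed = 1) |> isolate_cohort()
nrow(slices)          # 10 knees from 5 bilateral films
dim(slices$pixels[[1]]) # 224 224, values in [0, 1]

# the architecture of the full model, with Table-style accounting
m <- build_model(head_config(), backbone = "densenet121")
glance(m)
#> # A tibble: 1 x 5
#>   backbone    total_params trainable_params non_trainable_params executable
#>   <chr>              <dbl>            <dbl>                <dbl> <lgl>
#> 1 densenet121     13469571         13385923                83648 FALSE
```

The model prints the layer table (`print(m)`): the adapter conv contributes
30 parameters, FC_1 6,422,656 (= 50,176·128 + 128), FC_2 8,256, FC_3 1,040,
FC_4 85.

The desk-scale system experiment — train the compact profile on phantoms,
then test that severity grades are recovered while the 0-vs-1 distinction
stays at chance:

```r
ex <- grade_recovery_experiment(seed = 1)   # ~12 min on one CPU
ex$recall_234           # macro recall over grades 2-4: 1.0 at seed 1
ex$confusability$auc_01 # 0-vs-1 AUC: 0.499 at seed 1 (chance -- no pixel signal)
```

## Command line

A thin CLI over the package functions ships in `inst/cli/`:

```sh
Rscript inst/cli/kneegrade.R simulate --n 301 --seed 1 --out phantoms/
Rscript inst/cli/kneegrade.R isolate --in phantoms --cohort phantoms/cohort.csv --out slices/
Rscript inst/cli/kneegrade.R summarize --backbone densenet121
Rscript inst/cli/kneegrade.R run --n 60 --seed 1 --out run_dir/
```

## What this package is not

The phantoms are geometric stand-ins, not photorealistic radiographs;
phantom results demonstrate pipeline correctness, not clinical accuracy.
The large ImageNet backbones are exact accounting objects — only the
compact profile trains. See `vignettes/kneegrade-methods.Rmd` for the full
methods discussion.
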