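# afablate

Simulation of atrial-fibrillation (AF) ablation strategies on synthetic
2D left-atrial (LA) tissue, deep-learning prediction of each strategy's
success from the tissue image alone, and quantitative evaluation of
whether the network's saliency maps point at the (unseen) ablation
lesions.

## The problem

Radiofrequency catheter ablation treats AF by destroying or isolating
arrhythmogenic tissue, but choosing the right lesion set for a given
atrium is hard, and a black-box classifier that predicts strategy success
from imaging is clinically useless unless its decision process can be
inspected. `afablate` builds the full in-silico chain needed to study
that question:

1. **Tissue** — circular LA disks (0.3 mm/px) with pulmonary-vein (PV)
   openings (6 anatomical variants) and spatially correlated fibrosis;
   a weighted-average + affine augmentation scheme grows a virtual
   cohort from a set of base disks.
2. **Electrophysiology** — the three-variable Fenton–Karma model in the
   monodomain equation,

   `du/dt = div(D grad u) − (I_fi + I_so + I_si)`,

   solved by forward Euler with a 5-point heterogeneous-diffusion
   Laplacian (zero-flux boundaries; D = 0.1 mm²/ms healthy, 0.015
   fibrotic, 0 ablated). AF is induced with the cross-field S1–S2
   protocol, with the S2 coupling interval scanned as in programmed
   stimulation.
3. **Ablation** — three strategies: **PVI** (rings around the PV
   openings), **FIBRO** (perimeter of fibrotic patches) and **ROTOR**
   (discs at phase-singularity cluster cores, with phase from the
   analytic signal and singularities as ±2π wrapped loop sums). A
   strategy *succeeds* iff AF terminates within 2000 ms and < 40% of the
   tissue is ablated — the 3-bit multi-label ground truth.
4. **Model** — a CNN (4 conv blocks, linear layers, per-class sigmoid)
   trained on the tissue image only, with a multi-label MSE loss, under a
   fixed hold-out + 5-fold protocol.
5. **Interpretability** — GradCAM, occlusions and LIME maps per strategy,
   thresholded above the tissue-mean attribution into *informative
   regions* and scored against the hidden lesion masks by IoU (Jaccard),
   lesion percentage `|R∩L|/|L|` and non-arrhythmogenic-tissue (NAT)
   percentage `|R∩H|/|R|`, plus Wilcoxon signed-rank / Bonferroni and
   one-sided t statistics.

See `vignettes/methods.Rmd` for the model, calibration and all design
decisions.

## Worked example

Label one disk end to end (a few simulated seconds of tissue time; about
half a minute of CPU):

```r
library(afablate)
geo   <- make_disk_geometry(100, pv_variant = 2)
field <- sample_base_fibrosis(geo, correlation_length = 4, seed = 7)
disk  <- threshold_fibrosis(field, geo, threshold = 0.6)
disk$fibrotic_fraction
#> [1] 0.061

out <- label_disk(disk)   # S2 scan + baseline + 3 strategy simulations
out$inducible; out$s2_time
#> [1] TRUE
#> [1] 80
out$labels
#>   PVI FIBRO ROTOR
#>  TRUE FALSE FALSE
```

This disk was inducible at an 80 ms S2 coupling interval; PVI terminated
the episode at 1910 ms having ablated 3.6% of tissue (success), while
FIBRO (1.4% ablated — little fibrosis to encircle) and ROTOR (2.1%)
left AF running (failure). With a labelled cohort (`generate_cohort()` +
`label_cohort()`, or the packaged study via `study_dataset()`) the rest
of the chain is:

```r
dat   <- study_dataset(input_size = 64)      # fixed 250-disk cohort + cached labels
split <- study_split(dat$ids)
model <- train_fold(dat$images, dat$labels,
                    train_idx, val_idx, study_model_spec(),
                    study_train_config(seed = 1))
fa    <- gradcam(model, disk_to_image(dat$disks[[1]], 64), class_index = 2)
reg   <- threshold_fa(fa, dat$disks[[1]], factor = 1.0)
compute_metrics(reg, plan_fibro(dat$disks[[1]]), dat$disks[[1]])
```

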