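# rhdtype

Classification of the four Rhesus D blood-group phenotypes — **D+**
(high antigen expression), **weak D** (reduced), **DEL** (very low) and
**D−** (absent) — from single-molecule fluorescence microscopy of
erythrocytes labelled with fluorophore-conjugated anti-D antibodies
(H41, BRAD3, BIRMA-D6). The DEL phenotype is the clinically critical
case: routine serology types DEL donors as D−, yet their red cells can
immunise a D− recipient.

The package implements the full computational workflow for laboratory
scientists and methods developers in transfusion medicine:

1. **Simulation** (`simulate_image`, `simulate_sample`,
   `build_default_manifest`): synthetic bright-field + fluorescence
   stacks with ground truth, calibrated to the published cohort
   (12/14/12/13 samples per class), per-population peak-intensity laws
   (3×3-sum ~ N(μ, σ) per class and antibody), labelled-cell fractions
   (100/100/10/1%), field geometry (512 × 512 px, 0.16 µm/px) and peak
   SNR (31 ± 9).
2. **Segmentation** (`detect_cells`, `refine_contour`,
   `flag_edge_cells`): ring-kernel matched filtering of the
   bright-field gradient plus a pressure-driven greedy active contour;
   border-clipped cells are flagged and excluded.
3. **Spot detection** (`detect_peaks`, `peak_intensity`,
   `assign_peaks`, `estimate_snr`): conservative smoothing, white
   top-hat, robust thresholding and seeded region growing; every peak
   is quantified as the exact 3×3-pixel sum around its maximum and
   assigned to the cell whose mask contains it.
4. **Features** (`image_features`, `sample_features`): the seven
   per-image classification features (peak count per cell, per-cell
   intensity mean and SD, peak density, pairwise and nearest peak
   distances, intra/extra-cellular intensity ratio) and their
   per-sample averages.
5. **Overlap statistics** (`intensity_histogram`,
   `distribution_overlap`, `pairwise_overlap_matrix`): binned
   (width 50 counts) histogram-overlap coefficients between the class
   intensity distributions.
6. **Ensemble classification** (`train_vote`, `classify_method1`,
   `classify_method2`): random forest, RBF-SVM, kNN and genetic
   programming with offspring selection, each under 5-fold
   cross-validation repeated 40 times, voting per image (Method 1,
   tallies pooled per sample) and per sample (Method 2); 160 votes per
   item at the defaults.
7. **Rule fusion** (`combine_methods`, `classify_cohort`,
   `run_pipeline`): Method 3 resolves disagreements — concordance wins;
   D− vs DEL trusts the image level when a sample has ≥ 11 images,
   else the sample level; weak D vs DEL always takes the image level;
   anything else takes the sample level.

The methods vignette (`vignettes/rhd-classification.Rmd`) documents the
model assumptions, parameter defaults with provenance, numerical
choices, and what the synthetic world does and does not establish.

## Worked example

```r
library(rhdtype)

# one weak D field of view: 1 bright-field + 1 fluorescence frame
sim   <- simulate_image("WEAK_D", channel = "H41", n_bf = 1, n_fluo = 1, seed = 7)
cells <- detect_cells(sim$stack$frames[[1]])
peaks <- assign_peaks(detect_peaks(sim$stack$frames[[2]]), cells)
length(cells)                       # 15 cells, none border-clipped
#> [1] 15
sum(!is.na(peaks$cell_id))          # 123 of 131 peaks assigned to a cell
#> [1] 123
image_features(cells, peaks, sim$stack$frames[[2]], 0.16)[, 1:4]
#>   number_of_peaks cell_intensity sd_cell_intensity peak_density
#> 1             8.2       7472.207           693.838        0.191
```

The detected mean per-peak intensity (7472 counts) reproduces the weak
D/H41 population calibration (7400 ± 1400 counts/peak); ~8 peaks per
cell reflect the weak D per-cell rate.

```r
# pairwise histogram overlap (bin width 50) of the four H41 populations
set.seed(1)
pops <- lapply(default_intensity_models()$H41, function(m)
  pmax(rnorm(2e4, m$mean_peak_intensity, m$sd_peak_intensity), 0))
round(100 * pairwise_overlap_matrix(pops), 1)
#>        D_POS WEAK_D   DEL D_NEG
#> D_POS  100.0   34.0  19.7  37.2
#> WEAK_D  34.0  100.0  59.1  77.6
#> DEL     19.7   59.1 100.0  65.7
#> D_NEG   37.2   77.6  65.7 100.0
```

The 66% D−/DEL overlap is why no single intensity threshold can type a
sample and an ensemble over seven features is used instead.

```r
# method 3 rule fusion for one sample with 13 images
combine_methods("DEL", "D_NEG", n_images = 13)
#>   label m1_label m2_label n_images            rule_fired
#> 1   DEL      DEL    D_NEG       13 DNEG_DEL_IMAGES_GE_11
```

A full synthetic cohort (simulate → segment → detect → features →
Methods 1–3) runs in one call:

```r
cfg <- pipeline_config(
  simulate = list(n_bf = 1, n_fluo = 1, images_range = c(5L, 5L)),
  cv = list(n_repeats = 5, gp = list(population_size = 50,
                                     max_generations = 15)),
  seed = 7)
out <- run_pipeline(cfg)          # ~2 min on one CPU
out$result$accuracy               # 0.92 overall; DEL 11/12 correct
```

A command-line interface with subcommands `simulate`, `segment`,
`spots`, `features`, `overlap`, `classify` and `pipeline` is installed
at `system.file("scripts", "rhdtype", package = "rhdtype")`.

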