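# spatpdr

Single-cell spatial analysis for imaging mass cytometry (IMC) cohorts.

IMC ablates antibody-stained tissue in 1 µm steps and reads metal-isotope
tags by mass, producing ~30-plex images of intact tissue. After
segmentation, every cell carries a marker-expression vector and a centroid
in micrometres. `spatpdr` answers the two questions that follow for
researchers studying tissue microenvironments (here motivated by
immune-mediated liver injury, where the spatial company kept by apoptotic
hepatocytes is the finding of interest):

1. **Which phenotypes are present?** PhenoGraph-style phenotyping:
   `arcsinh(x/5)` transform, per-marker standardisation, exact k-nearest
   neighbours in expression space (k = 30), Jaccard edge weighting, and
   Louvain modularity maximisation (with seeded restarts and a refinement
   stage), giving data-driven clusters with scaled mean-expression
   signatures, per-ROI abundances, and condition comparisons by unpaired
   t-tests with Holm adjustment.

2. **Which phenotypes sit near each other?** The symmetric **pairwise
   distance rank (PDR)**: for each cell, its K = 50 nearest neighbours
   within the ROI; per-cell mean distance to each phenotype; pooled over
   the analysis ROIs into the mean-distance matrix D[A,B] (µm); all
   defined ordered off-diagonal entries ranked jointly and rescaled to
   [0, 1]; symmetrised by the geometric mean

   PDR(A,B) = sqrt( r(A,B) · r(B,A) ),

   so 0 marks the closest interacting pair and 1 the furthest. Companion
   outputs: a 2-D feature map of the PDR rows, per-phenotype
   neighbour-distance summaries with Welch's ANOVA, and RGB
   interaction-zone renderings (each colour channel `exp(-d/τ)` for the
   distance to one of three reference phenotypes; white = three-way zone).

Because public IMC cohorts with ground-truth interactions do not exist,
the package ships a first-class synthetic-tissue simulator: multi-ROI
cohorts with planted phenotype signatures, condition-dependent abundance
shifts, and planted spatial attraction (Matérn-style parent–offspring
placement), so every stage is validated against known truth. A label-mask
renderer and featurizer close the loop from images (16-bit label TIFF +
float32 channel-stack TIFF) to the cell table.

## Worked example

```r
library(spatpdr)

# a small two-arm cohort: 17 ROIs, ~300 cells per control ROI
cfg <- default_sim_config(cells_per_roi = 300, seed = 7)
sim <- simulate_cohort(cfg)

# graph-based phenotyping (arcsinh -> kNN Jaccard graph -> Louvain)
pa <- cluster_phenotypes(sim$cells, cfg$panel, k = 30, seed = 1)

# spatial interaction: 50-NN profiles -> mean distances -> PDR (treated arm)
labs <- sim$cells$true_phenotype
prof <- phenotype_profiles(spatial_knn(sim$cells, K = 50), labs)
ici  <- unique(sim$cells$roi_id[sim$cells$condition == "ICI"])
dd   <- mean_distance_matrix(prof, labs, rois = ici, roi_id = sim$cells$roi_id)
pm   <- pdr(dd$D)
round(pm[c("Hep_cC3", "Kupffer", "Macrophage", "CD8_T"),
         c("Hep_cC3", "Kupffer", "Macrophage", "CD8_T")], 3)
```

This prints:

```
simulated 5465 cells in 17 ROIs
found 8 clusters, modularity 0.827, ARI vs truth 1.000
           Hep_cC3 Kupffer Macrophage CD8_T
Hep_cC3         NA   0.026      0.000 0.485
Kupffer      0.026      NA      0.081 0.404
Macrophage   0.000   0.081         NA 0.551
CD8_T        0.485   0.404    0.551      NA
```

The clustering recovers all 8 planted phenotypes exactly (adjusted Rand
index 1.0 against the generator's labels), and the PDR identifies the
planted attractions: apoptotic (cC3+) hepatocytes are closest to
macrophages (PDR 0.000, the global minimum) and Kupffer cells (0.026),
while CD8 T cells — placed at random in this cohort — rank far from
everything (≈ 0.4–0.55, the middle of the scale).

## The analysis workflow

Numbered drivers under `analysis/` run the full study-shaped workflow
(17 ROIs of 700 × 700 µm, 5 control vs 12 treated, ~78,000 cells, 32
markers) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1    # cohort + config        -> results/cohort/
Rscript analysis/02_phenotype.R 1   # clusters, signatures,
                                    # abundances, t-tests    -> results/phenotype/
Rscript analysis/03_spatial.R 1     # D, PDR, feature map,
                                    # Welch summaries        -> results/spatial/
Rscript analysis/04_zones.R         # RGB interaction zones  -> results/zones/
Rscript analysis/05_report.R 1      # JSON run report        -> results/report.json
```

Every figure has a CSV twin, and identically seeded reruns reproduce all
numeric artifacts byte for byte.

## Documentation

The methods vignette (`vignettes/spatpdr-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate,
numerical edge cases, and known limitations.
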