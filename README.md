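# mucquant

Quantitative analysis of regulated exocytosis phenotypes in the ciliate
*Tetrahymena thermophila*, built around two questions that arise when a
secretory mutant is dissected by microscopy and by forward genetics:

1. **Where does a protein sit on a secretory organelle?** Mucocysts are
   ~1 µm elongated lysosome-related organelles that dock at the plasma
   membrane along cortical "meridians" and discharge on stimulation.
   Whether a membrane protein concentrates at the docking tip of the
   organelle is decided here from two-channel fluorescence micrographs:
   the organelle channel (Grl core stain) and the punctum channel (Mdl
   tip protein) are segmented by adaptive thresholding with
   morphological cleanup, overlapping features are paired, and each pair
   is summarized by two statistics —

   - the **angle** θ ∈ [0°, 90°] between the organelle's fitted long
     axis and the segment joining the two centroids (0° = punctum on the
     long axis, 90° = on the short axis), and
   - the **normalized offset** = centroid distance / (L/2), where L is
     the fitted major-axis length (0 = organelle center, 1 = tip).

   Significance comes from a randomization null: punctum centroids are
   resampled uniformly inside each paired organelle ellipse, and the
   observed and null distributions are compared with the two-sample
   Kolmogorov–Smirnov test, D = sup |F̂₁ − F̂₂|. A coarser object-based
   colocalization measure (fraction of puncta sharing ≥ 1 pixel with an
   organelle, against a random-translocation null within the cell mask)
   and a docking measure (fraction of organelle signal in a peripheral
   band of a cross-sectional image, compared between strains by one-way
   ANOVA) complete the imaging arm.

2. **Which mutation causes the phenotype?** Two pools of 32 F2
   whole-genome-homozygous segregant clones — one phenotypically mutant,
   one wildtype — are sequenced to ~90×. For every variant site with
   ≥ 100× coverage in both pools the pipeline scores the allelic
   contrast Δ = (alt/depth)ₘᵤₜ − (alt/depth)wₜ ∈ [−1, 1], smooths it in
   200-kb windows, normalizes the genome maximum to 1, locates the peak
   region by a fraction-of-maximum run rule, then refilters sites in the
   region (≥ 5× both pools, mutant pool apparently homozygous, wildtype
   pool not) and ranks candidates by predicted functional impact
   (HIGH > MODERATE > LOW > MODIFIER), ties by descending contrast.
   Linked markers follow the Haldane map function
   r = (1 − e^(−2dc/100))/2.

Both arms ship with synthetic-data generators carrying full ground
truth — micrographs with elliptical organelles, tip-biased puncta,
Gaussian PSF and Poisson/Gaussian noise; and pooled variant tables from
a simulated cross with one planted causal variant — so every stage is
testable without external data.

## Worked example

```r
library(mucquant)

# simulate one docked cell: 12 organelles, puncta at tip bias 0.9
sim <- generate_cell_image(image_sim_params(seed = 101))

# segment both channels, pair features, test tip polarity
an <- tip_localization_analysis(sim$micrograph, R = 1000, seed = 42)
median(an$pairs$offset_norm)   # 0.91  (ground truth bias: 0.90)
an$ks_offset$p.value           # ~1e-22: offsets are not the uniform null

# map a causal mutation from simulated pools
cross <- generate_pool_counts(cross_sim_params(seed = 7))
track <- build_linkage_track(cross$sites)      # 100x filter, 200 kb smoothing
peak  <- find_peak_region(track)               # chr3:700000-10000000
cands <- candidate_variants(cross$sites, peak)
cands[1, c("chrom", "pos", "impact")]          # chr3 5000000 HIGH  <- planted
```

Running the numbered drivers reproduces the full workflow and writes
tables under `results/`:

```sh
Rscript analysis/01_simulate_images.R      # example micrographs + truth
Rscript analysis/02_colocalization_sweep.R # overlap vs sensitivity, null
Rscript analysis/03_tip_localization.R     # angles/offsets, KS tests
Rscript analysis/04_docking_anova.R        # peripheral fractions, ANOVA
Rscript analysis/05_bsa_mapping.R          # VCF -> track -> peak -> candidates
Rscript analysis/06_coexpression.R         # max-normalized profile similarity
```

From `03_tip_localization.R`, for example:

```
36 pairs pooled from 6 cells
median offset 0.913 (null mean 0.518); median angle 1.9 deg (null mean 33.1)
KS offsets: D = 0.848, p = 6.9e-23; KS angles: D = 0.856, p = 2.44e-23
```

i.e. measured puncta sit near the organelle tips (offset ≈ 0.9, angle
≈ 0°), far from the uniform within-organelle expectation.

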