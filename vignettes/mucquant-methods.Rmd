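---
title: "mucquant: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mucquant: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mucquant)
```

This vignette is the package's account of what it computes and why the
defaults are what they are. It states no empirical numbers beyond those
the test suite and the analysis drivers themselves compute.

# The imaging arm

## Segmentation model

A channel is binarized by an adaptive threshold: pixel `x` is foreground
iff

    I(x) > mean_w(x) + s * (max I - min I)

where `mean_w` is the mean over a `window`-sized square centred on `x`
(edge pixels use the in-bounds part of the window) and the range is the
global image range. This makes the sensitivity `s` dimensionless and
invariant to affine intensity rescaling, and it gives a provable
monotonicity: raising `s` never adds foreground, so feature counts are
non-increasing in `s`. The windowed mean is computed with a summed-area
table after subtracting the global mean, so a constant image yields an
exactly constant local mean and an all-background mask (no cancellation
artifacts).

* `window` (default 51 px): larger than any organelle at the simulated
  magnification (organelle major axis ~12 px), so the local mean tracks
  background, not objects.
* `s`: the operating point. The package's prescribed way to choose it is
  a ground-truth calibration: segment simulated cells over a grid of `s`
  and pick the value at which the fitted major-axis length matches the
  known organelle length. At the default simulation settings this gives
  `s = 0.25` for both channels; at `s = 0.5` the threshold sits above
  the blurred amplitude of the narrow organelles and the fit shrinks by
  roughly 20%, inflating normalized offsets correspondingly. The same
  trade-off is visible in the colocalization sensitivity sweep
  (`analysis/02`), which is how an operating point would be chosen on
  real images, where no ground truth exists.

Masks are cleaned by binary opening then closing with disc structuring
elements (radii 1 px by default; radius 0 skips a step). Note that
opening with any disc of radius >= 2 rounds the corners of rectangular
objects — that is correct morphology, not an artifact. Components are
labelled with 8-connectivity, restricted to the cell mask, and
components below `min_area` (default 4 px²) are dropped to suppress
shot noise.

## Ellipse fits

Each component is summarized by its intensity-unweighted centroid and a
moment-matched ellipse: orientation `atan2(2*mu11, mu20 - mu02)/2`
mapped to [0°, 180°) (counterclockwise from the +column axis, with
y = -row), and axis lengths `4*sqrt(eigenvalues)` of the
area-normalized central second-moment matrix, so a solid rendered
ellipse recovers its full axis lengths. Pixel coordinates are 1-based
(row, column), the native convention of R matrices and EBImage.

Validity regime, characterized by rendering ellipses at known
parameters: axis lengths are recovered within 3% down to semi-axes of
~5 px; orientation is recovered within 2° for semi-major axes >= 12 px,
degrading to ~3° around 8–9 px purely from pixelation, and becoming
ill-conditioned as the shape approaches a circle. The simulated
organelles (12.5 × 5 px) sit inside the reliable regime; fits of
features much smaller than that should not be over-interpreted.

## Tip statistics and their null

For every punctum sharing >= 1 pixel with an organelle (assigned to the
organelle with the largest shared-pixel count; ties to the smaller
label), two statistics are computed from the *fitted* organelle ellipse:

* angle: the acute angle between the undirected major axis and the
  centroid-connecting segment, folded into [0°, 90°]; undefined when the
  centroids coincide (such pairs are excluded from angle statistics but
  retained at offset 0 in offset statistics);
* normalized offset: centroid distance divided by half the fitted
  major-axis length, so 1 marks the vertex of the fitted ellipse.

The randomization null translates each paired punctum centroid to a
uniform point inside the fitted ellipse (rejection sampling from the
bounding box in the ellipse frame). Sampling within the *fitted* ellipse
rather than the raw pixel set is deliberate: it models the organelle the
same way the statistics do and admits exact oracles — for a circular
feature the null offset density is 2r on [0, 1] (mean 2/3) and the null
angle is Uniform(0°, 90°) (mean 45°), both used as 3-standard-error
checks at R = 1e5 in the tests.

Observed statistics are pooled across all pairs of all cells before
testing, with R null points per pair (R = 1000 by default), mirroring
an analysis that pools a few dozen organelle/punctum pairs from a
handful of cells. The two-sample KS test is two-sided with the
asymptotic Kolmogorov p-value evaluated at `sqrt(n1*n2/(n1+n2))*D`;
ties are handled by evaluating both ECDFs on the pooled support. Both
the offset and the angle tests are reported, since either alone could
be argued; with samples below ~4 the asymptotic p is crude, and the
package does not attempt an exact computation.

## Colocalization and docking

Object overlap is binary (>= 1 shared pixel) — parameter-free, at the
cost of ignoring overlap extent. Its null rigidly translates each
punctum pixel set (no rotation) to a uniform position wholly inside the
cell mask; translocated features may overlap each other. For point-like
features this null converges to the organelle coverage fraction of the
cell, the binomial oracle used in the tests.

Docking is the fraction of channel intensity inside a peripheral band:
the cell mask minus its erosion by a disc of radius `band_width`. A
fixed-width band replaces a hand-drawn peripheral region so the measure
is reproducible; the default width, 10% of the cell's equivalent radius
(`sqrt(area/pi)`), is a deliberate convention — the measure is monotone
in the width and strain *comparisons* are insensitive to it as long as
one width is used throughout. The fraction is invariant under global
intensity rescaling. Degenerate case: a band so wide that the erosion is
empty returns fraction 1 with a warning. Strains are compared by
classical one-way ANOVA (`stats::oneway.test`, equal variances).

## What the image simulator emulates — and what it does not

`generate_cell_image()` draws an elliptical cell (default semi-axes
7.5 × 6 µm at 0.08 µm/px, a mid-section of a Tetrahymena cell at high
magnification); `n_mucocysts` (12) non-overlapping elliptical organelles
of 0.5 × 0.2 µm, either docked — centroids in the outer radial band
(scaled radius 0.76–0.92, within the outer 25%), major axes along the
local outward normal, tips pointing at the membrane — or cytoplasmic
(uniform interior positions and orientations); one punctum disk of
radius 0.15 µm per organelle at normalized tip distance `tip_bias`
(default 0.9, a strongly tip-polarized protein), or, with
`punctum_placement = "uniform"`, at a uniform point inside the organelle
ellipse. The uniform mode exists because it *is* the randomization
null: simulating unbiased puncta by setting `tip_bias = 0` would place
every punctum exactly at the organelle centroid, which a calibrated
test must (and does) reject. Type-I calibration therefore uses uniform
placement; `tip_bias = 0` is kept as the degenerate centroid case.
Both channels are blurred with a Gaussian PSF (sigma 0.1 µm), shot
noise is applied as Poisson at `poisson_scale` photons per intensity
unit (200), then Gaussian read noise (sd 0.02), and intensities are
clamped to [0, 1] — the package's normalized-detector convention, which
also matches 16-bit TIFF storage. A few broad dim blobs (amplitude
0.25, sigma 0.5 µm) are added to the punctum channel to mimic
mitochondrial autofluorescence.

Not emulated: 3-D structure and defocus, chromatic misregistration,
uneven illumination, organelle shape variability, clustered or touching
organelles, and structured background beyond the smooth blobs. Passing
tests on these images show that the estimators are correct and
calibrated under the stated noise model; they do not show robustness to
artifacts the simulator omits.

Placement is by bounded rejection sampling (500 attempts per organelle,
centre separation >= one major-axis length); an over-packed
configuration raises an error naming the constraint rather than
degrading silently.

# The mapping arm

## Pool model

Each F2 clone is whole-genome homozygous, so a pool of clones behaves
as a set of haploid-derived genotypes. A clone destined for the mutant
pool carries the causal allele (the phenotype is recessive and fully
penetrant except for `phenotyping_error`, the probability of assignment
to the wrong pool, default 0); at a marker `d` Mb away on the causal
chromosome it carries the causal-coupled allele with probability
`1 - r`, `r = (1 - exp(-2*d*c/100))/2` (Haldane, no interference,
`c` = recomb rate in cM/Mb, default 1); unlinked chromosomes segregate
at 1/2. Marker genotypes are drawn independently per clone given the
causal genotype — the correct marginal model; it omits the
within-clone haplotype correlation of real crossovers, which matters
for multi-marker haplotype statistics but not for the per-site
frequencies and windowed means computed here. Pool allele frequency is
the clone mean; per-pool depth is Poisson(`mean_depth` = 90) and alt
reads Binomial(depth, frequency). Read mapping artifacts, base-calling
error, and depth overdispersion are not modelled.

The simulated genome is 5 × 10 Mb with markers every 10 kb
(`background_variant_rate` is the retention probability of each
non-causal grid site; default 1). Impact annotations are drawn as
HIGH 5e-4, MODERATE 4e-3, LOW 1.55e-2, MODIFIER 0.98; the causal site
is always HIGH. The grounding: a mutagenized strain whose load has been
reduced by outcross and backcross carries on the order of a hundred
point variants genome-wide, of which nonsense-class changes are a
handful — scaled to this 50 Mb genome, roughly 2–3 HIGH sites in 5,000
markers.

## Scoring, smoothing, peak, candidates

The contrast score is the plain pool allele-frequency difference —
interpretable, antisymmetric under pool swap, and bounded in [-1, 1].
No depth weighting or likelihood is applied; at the default coverage
the clone-sampling variance dominates the read-sampling variance
anyway. Sites with zero depth in either pool carry no frequency
information and are set NA with a message; the track builder excludes
them. The track filter (>= 100x in both pools) and the candidate
refilter (>= 5x plus mutant-homozygous, wildtype-not, at alt-frequency
threshold 0.9) follow the published workflow's cutoffs; under the
Poisson(90) depth model the 100x filter is severe (it retains a few
percent of sites), which the peak rule must tolerate.

Smoothing is a centred sliding-window mean over `window_bp` (200 kb)
per chromosome, and the smoothed track is normalized so the genome
maximum is 1 (an all-non-positive track stays at 0 rather than being
divided). The peak region is the *longest* contiguous run of sites, on
the chromosome carrying the global maximum, whose normalized score is
>= `frac_of_max` (0.9), expanded to its bounding positions; among
equally long runs the one containing the maximum wins. The longest-run
reading was chosen over "the run containing the argmax" because single
noisy sites break runs on sparse tracks, and the argmax itself is only
weakly localized (see Limitations). Candidates within the region are
ranked by impact class, ties by descending contrast, then by position.

## Limitations of the cross design

With 10 cM chromosomes and 2 × 32 clones, the expected number of
recombinants within 500 kb of the causal site is below one, so the
linkage signal is flat at the sub-megabase scale: the smoothed-track
argmax localizes the causal site only to within roughly half a
chromosome, and sites in complete pool-linkage with the causal variant
are statistically indistinguishable from it (their sampled contrast is
exactly 1). Identification therefore leans on the homozygosity
refilter and the impact ranking, exactly as the original workflow
leaned on functional annotation. When another HIGH-impact site lies in
complete linkage earlier on the chromosome, the position tie-break
ranks it first; at the default impact frequencies this costs a few
replicates per hundred.

# Problem sizes in the test suite

The suite's simulation sizes are chosen to make binomial tolerances
meaningful while keeping the default run desk-scale: type-I calibration
uses 200 independent cells (per-cell KS at alpha = 0.05, acceptance
band 1–10%), power uses 100 pooled analyses of 32 pairs each at tip
bias 0.9 (threshold p < 1e-4), analytic null oracles use R = 1e5 draws
with 3-standard-error bands, and causal recovery uses 100 replicate
crosses. Determinism is asserted bit-for-bit for every stochastic
operation under fixed seeds; seeded calls restore the caller's RNG
state.
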