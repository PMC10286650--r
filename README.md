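# pancparts

Automated subsegmentation of whole-pancreas MRI segmentations into the
three anatomical parts — head, body and tail — by groupwise registration
to a shape template, with a k-means baseline, a segmentation-agreement
metric suite, and regional quantification of 2D proton density fat
fraction (PDFF) maps.

## Who this is for

Quantitative-imaging studies of the pancreas (fat infiltration, diabetes,
chronic pancreatitis) increasingly need *regional* readouts: disease is
spatially heterogeneous, and whole-organ averages can hide it. Manual
region-of-interest placement adds observer variance; manual part
annotation does not scale to biobank-sized cohorts. `pancparts` takes a
whole-organ binary segmentation (however it was produced) and splits it
into head/body/tail automatically, then quantifies biomarkers per part.

## Method

**Offline (template construction).** Whole-pancreas masks are resampled
to 2 mm isotropic resolution and centroid-aligned. Groupwise
diffeomorphic registration iteratively co-registers all masks into a
probabilistic template $T : \Omega \to [0,1]$: at each of four
iterations, every mask is registered to the current average with a
stationary-velocity diffeomorphic demons scheme (warp $\exp(v)$ by
scaling-and-squaring, inverse $\exp(-v)$), the velocities are centered so
the mean deformation is the identity (unbiased averaging), and the
average is recomputed from the warped masks. The template is binarized at
0.5 and annotated once with two boundary planes orthogonal to its
centerline: head–body at 40% of the arc length, body–tail at the midpoint
between the head–body boundary and the tail tip,
$s_{bt} = s_{hb} + (L - s_{hb})/2$.

**Inference (subsegmentation).** A new mask is registered to the
template; the annotated parts travel back through the *inverse* warp with
nearest-label interpolation; every foreground voxel of the subject
receives the warped label at its location, or the label of the nearest
labeled voxel — so the three parts always partition the input mask
exactly.

**Validation machinery.** Dice coefficient, 95th-percentile Hausdorff
distance (pooled symmetric, exact anisotropic distances), per-part volume
deltas and Bland–Altman limits of agreement ($\mathrm{bias} \pm 1.96\,
\mathrm{SD}$); a spatial k-means (k = 3, k-means++) baseline; and a
synthetic pancreas-phantom generator with exact ground-truth part labels,
so the whole pipeline is testable without access-controlled imaging data.

**PDFF quantification.** A 3D parts segmentation is intersected with a 2D
PDFF map via scanner-coordinate geometry; per part, masks of ≤ 30 pixels
are excluded, pixels exceeding 50% PDFF are removed, the remainder is
opened with a 3-pixel-diameter disk, and the median PDFF of the surviving
pixels is reported (with explicit exclusion reasons otherwise).

## Worked example

Build a template from 7 synthetic pancreas phantoms, annotate it, and
subsegment a held-out phantom:

```r
library(pancparts)
cohort <- generate_cohort(phantom_spec(), n = 8, seed = 42)
masks  <- lapply(cohort, `[[`, "mask")

tb  <- build_template(masks[1:7], n_iterations = 4)
pt  <- annotate_by_arclength(binarize(tb$template), head_fraction = 0.40)
res <- subsegment_template(masks[[8]], pt)
res
#> <subseg_result> method=template, coverage=0.9481
#>   <parts_labels> 64x64x64 voxels; head/body/tail = 1891/736/533

compare_parts(res$parts, cohort[[8]]$labels)
#>   part present       dsc hd95_mm dvol_ml
#> 1 head    TRUE 0.9848958       2  -0.464
#> 2 body    TRUE 0.9325997       2   0.144
#> 3 tail    TRUE 0.9610136       2   0.320
```

`coverage` is the fraction of the subject's foreground directly covered
by the warped template labels (the rest is filled by the nearest-label
rule). The comparison table scores the prediction against the phantom's
exact ground truth: Dice overlap per part, 95% Hausdorff distance in mm,
and the volume difference in mL. The k-means baseline on the same subject
is markedly worse at the anatomical boundaries:

```r
km <- subsegment_kmeans(masks[[8]], seed = 0)
compare_parts(km$parts, cohort[[8]]$labels)
#>   part present       dsc   hd95_mm dvol_ml
#> 1 head    TRUE 0.8262572 13.311472  -4.616
#> 2 body    TRUE 0.5635053 14.282857   2.936
#> 3 tail    TRUE 0.8244147  8.246211   1.680
```

A command-line interface wrapping the same functions (subcommands
`make-phantoms`, `preprocess`, `build-template`, `annotate`,
`subsegment`, `subsegment-kmeans`, `evaluate`, `pdff-quant`) is installed
at `inst/cli/pancparts`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/pancparts", package="pancparts"))') \
    make-phantoms --n 10 --seed 1 --out-dir phantoms
```

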