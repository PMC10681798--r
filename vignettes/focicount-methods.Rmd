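---
title: "Counting mitochondrial foci in single cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting mitochondrial foci in single cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focicount)
```

## The problem

Mitochondrial DNA is packaged into diffraction-limited nucleoprotein foci
(nucleoids, roughly 100 nm) distributed over the mitochondrial network.
Bulk assays (qPCR, sequencing) only give a population-averaged copy number
per cell and hide cell-to-cell heterogeneity, which is large: per-cell
nucleoid counts in cultured fibroblasts span more than an order of
magnitude. Counting foci directly in fluorescence images preserves the
single-cell context — in particular the mitochondrial network area, which
lets a count be normalised into a density (foci per square micrometre),
a markedly less variable quantity than the raw count.

`focicount` implements that workflow as scriptable, fully traceable code:
per cell it detects foci on the projected foci channel, filters them with
a mitochondrial inclusion mask and a nuclear exclusion mask, measures the
inclusion-mask area, and reports count, area and density, together with
the artifacts (masks, foci lists, manifests) needed to reproduce every
number from the raw image.

## Detection: topographic prominence

Foci are local intensity maxima, but raw local maxima include every noise
ripple. The detector keeps a maximum only if it is *prominent*: the
intensity drop separating it from any higher ground must exceed a single
parameter, the prominence (in intensity units, au). Precisely, on an
integer-valued image:

* candidates are connected plateaus of equal intensity with no strictly
  higher neighbour (8-connectivity by default);
* a candidate at value $v$ is rejected iff some connected path leads from
  it to a strictly higher pixel with every pixel on the path at intensity
  $\ge v - \mathrm{prominence}$ — equivalently, its drop to the highest
  saddle towards higher ground is $\le$ the prominence;
* equal-valued survivors connected within the same tolerance region are
  merged, keeping the plateau whose top-left pixel comes first in
  row-major order;
* each plateau reports its pixel centroid, rounded to the nearest pixel
  with half-ties towards the image origin;
* a perfectly flat image has no maxima.

Every boundary rule is fixed deliberately. Published descriptions of
prominence-style spot detection leave the saddle rule, plateau handling
and tie-breaking unspecified, which makes counts irreproducible at the
few-foci level; here the same contract is implemented twice — once in
C++ for speed, once as a brute-force flood oracle in the test suite — and
the two are required to agree exactly on randomized images. Note one
consequence of the contract: the global maximum of a non-flat image always
survives, at any prominence, because no higher ground exists to flood to.
Detection runs on raw projected intensities; no pre-smoothing is applied,
and the integer intensity domain means there are no floating-point ties.

```{r detect}
img <- matrix(c(0L, 80L, 70L, 100L, 0L), nrow = 1)
find_maxima(img, prominence = 9)   # both peaks survive
find_maxima(img, prominence = 10)  # the 80-peak's drop is exactly 10: rejected
```

## The parameter sweep

The right prominence depends on staining, exposure and camera gain, so it
must be established per experimental workflow, not copied between them. The
package encourages a sweep of six evenly spaced values over a user range
(default 5–200 au): counts fall sharply while the sweep crosses the noise
floor and then plateau over the range where real foci dominate.

```{r sweep}
make_sweep(5, 200, 6)
```

Counts are provably non-increasing in prominence, so a sweep is cheap to
interpret: the working value is chosen on the plateau past the initial
drop (83 au for the synthetic defaults below), and the per-prominence
binary foci images are persisted for visual verification.

## Masks, area and density

Detected maxima are filtered by the single pixel at their coordinate:
kept iff inside the mitochondrial mask (inclusion) and outside the nuclear
mask (exclusion). Nuclear exclusion matters because z-projection overlays
nuclear DNA signal onto mitochondria crossing the nucleus, producing false
positives there. Filtering by one pixel rather than a neighbourhood makes
the effect of mask erosion or dilation predictable.

Masks are built per cell with deliberately simple, fully parameterised
recipes (`seg_params()`):

* mitochondria: median filter (radius 1 px) → Otsu threshold → drop
  objects < 4 px → closing (radius 1 px);
* nucleus: Gaussian blur (sigma 2 px) → Otsu → fill holes → keep the
  largest component.

The threshold is always computed from intensities *inside the cell ROI
only*, because marker expression differs between cells and a global
threshold would under-segment dim cells. Externally produced masks
(ilastik, Weka, CellProfiler, manual polygons) are accepted verbatim
through the same interface, and every mask used is archived as an 8-bit
TIFF so the analysis can be replayed.

The mitochondrial area is the inclusion-mask pixel count times the squared
pixel size (um^2), and the density is the filtered count divided by that
area. Density is only reported when the mitochondrial filter is actually
applied: it pairs the filtered count with the inclusion-mask area, and
reporting it for unfiltered counts would mix incommensurate quantities.

## Conventions and numerical choices

* Pixel coordinates are 0-based, `x` = column, `y` = row; a pixel's centre
  is at `(x + 0.5, y + 0.5)`. ROI rasterization includes a pixel iff its
  centre is inside the polygon (even-odd rule), with centres exactly on an
  edge counted as foreground. This one documented convention replaces
  ImageJ's mixture of conventions and makes rasterized areas converge to
  the polygon's shoelace area as resolution grows.
* Channel indices are 1-based (the natural R convention) and are always
  supplied explicitly via a role map (`foci`, `mito`, `nucleus`) — channel
  order is never guessed, since acquisition order differs between
  microscopes.
* Pixel size resolution order: explicit override > ImageJ TIFF metadata
  (`unit=micron` with the x-resolution tag) > plain TIFF resolution tags
  (cm/inch) > unknown. An unknown pixel size is only an error once an area
  is actually requested. TIFFs written by this package carry no resolution
  tags (the underlying writer does not support them), so synthetic
  datasets carry the pixel size in their truth files and run configs.
* Mean z-projection rounds half up to stay in the integer intensity
  domain; maximum projection is the default.
* Intensities outside the cell ROI are set to zero before detection so a
  neighbouring cell's foci cannot contribute maxima; the trade-off is a
  possible artificial plateau if the ROI interior is perfectly constant,
  which does not occur on real (noisy) data.
* All result CSV numerics are written with 17 significant digits so a
  written table reads back bit-identically; runs with identical inputs and
  config produce byte-identical outputs (manifests contain no timestamps).

## The synthetic ground-truth generator

Real acceptance data for this kind of tool (raw microscope images with
manual ROIs) is far too large to ship, so the package carries a generator
whose output exercises every pipeline stage with exactly known truth.
A synthetic cell is: a star-shaped cell polygon; a mitochondrial network
rendered as momentum random walks (24 branches of 340 steps by default)
dilated to 3 px width; an elliptical nucleus overlapping the network (a
third of the walks start at its centre to guarantee overlap); Gaussian
foci of sigma 1.3 px planted at integer pixel positions on the network
with a minimum separation of 6 px; and a constant background plus Gaussian
noise, quantised to 16 bit. Defaults are 320 x 320 px at 0.1 um/px,
amplitudes 120–160 au over background 100 au with noise sigma 5 au.

Those defaults pin a regime where detection should be essentially perfect
— amplitude at least prominence + 6 noise sigmas, prominence at least
6 noise sigmas, separation at least 4 spot sigmas — and the test suite
holds the pipeline to recall and precision of at least 0.99 there. Foci
meant to be *removed* are planted as real image structure (not just truth
entries): outside the mitochondrial mask with a 4 px margin, and on
network inside the nucleus with a 2 px margin, so mask filtering is tested
end-to-end through segmentation, not against idealised masks.

Spot placement is sequential adsorption over a random permutation of
eligible pixels: deterministic for a seed, and it either fills the request
or fails honestly when the network is jammed at the requested separation.
Per-cell counts for whole datasets are drawn lognormal (median 299,
log-sigma 0.49, chosen so the quartile spread matches what is observed in
cultured fibroblast populations), truncated at 500 because the rendered
network jams near 600 spots at 6 px separation; the truncation touches
only the top few percent of draws.

What the generator does *not* model, and what passing tests therefore do
not show: point-spread convolution of the extended structures, SIM
reconstruction artifacts, uneven illumination, autofluorescent debris,
overlapping neighbour cells, or foci in 3-D (detection is 2-D on
projections). Results on real data still depend on staining quality and a
sweep-validated prominence.

```{r cell, eval = FALSE}
cell <- generate_cell(synthetic_spec(n_foci = 300), seed = 42)
cfg <- run_config(channel_roles = list(mito = 1, nucleus = 2, foci = 3),
                  prominences = 83L)
quantify_cell(cell$stack, cell$cell_roi, cfg)
```

## Statistics

Downstream analysis of per-cell tables uses standard machinery, wrapped so
that every method and seed is recorded in the result objects:

* `summary_stats()`: mean, sample (n−1) standard deviation, median, IQR by
  linear interpolation, and the coefficient of variation
  `100 * sd / mean` — the heterogeneity measure of choice for per-cell
  counts.
* `ks_two_sample()`: two-sided Kolmogorov–Smirnov test for replicate
  comparison; exact p-values for small samples, asymptotic otherwise, with
  the method recorded.
* `ks_normality_vs_sim()`: a pragmatic normality screen that compares the
  data against one simulated Normal sample with the observed moments, ten
  times the data size by default; the simulation seed is stored in the
  result, making the screen exactly reproducible. Its printed p-values
  depend on that simulation and are therefore reproducible only given the
  seed, which is why the seed is part of the result object.
* `kruskal_wallis()`: tie-corrected rank test across independent
  experiments, with the degenerate all-identical case defined as H = 0,
  p = 1.
* `correlation()`: Pearson by default ("correlation" unqualified means
  Pearson here), Spearman as an option, for count-versus-area analysis.

Test sizes used in the shipped suite are chosen to keep the whole run in
minutes on one core: oracle equivalence on 200 random 12 x 12 images,
sweep monotonicity on 50 small cells, end-to-end recovery on 50 full-size
cells, and 100-seed size/power checks for the normality screen.

## Known limitations

* Detection is 2-D; overlapping foci separated only in z are merged, so
  absolute counts from projections systematically underestimate truth.
  Relative comparisons between identically imaged samples remain valid.
* The built-in segmentation recipes are deliberately simple; convoluted
  or dim networks deserve an external segmentation fed through the mask
  gateway.
* Prominence values are not transferable between imaging set-ups; rerun
  the sweep whenever optics, exposure or processing change.
* The ImageJ ROI reader handles polygon-family ROIs (polygon, freehand,
  traced) only; line and point ROIs are rejected by name.
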