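# focicount

Reproducible single-cell quantification of mitochondrial foci —
nucleoids, mitochondrial RNA granules and similar diffraction-limited
puncta — from multi-channel fluorescence microscopy images.

Mitochondrial DNA is packaged into ~100 nm foci (nucleoids) spread over
the mitochondrial network. Bulk qPCR/sequencing assays report only a
population average per cell; imaging preserves the single-cell context,
but manual counting and undisclosed analysis parameters make published
counts hard to reproduce. `focicount` makes the whole analysis scriptable
and traceable, from TIFF stack to statistics table, for anyone counting
fluorescent puncta per cell: cell biologists quantifying mtDNA copy-number
phenotypes, and image analysts who need a spot counter whose every rule is
written down.

## What it computes

Per cell, from a multi-channel TIFF (foci / mitochondria / nucleus) and a
polygon cell outline:

1. **Detection** — local maxima of the projected foci channel that are
   *topographically prominent*: a maximum at intensity $v$ survives only
   if every path to higher ground passes through a pixel below
   $v - \mathrm{prominence}$. A single parameter (prominence, in intensity
   units) thus separates foci from noise. All boundary rules — plateau
   handling, the saddle rule (a drop of exactly the prominence rejects),
   merging of equal peaks, tie-breaking — are fixed and verified against a
   brute-force oracle, so counts are exactly reproducible.
2. **Parameter sweep** — detection at six evenly spaced prominences over a
   user range (`make_sweep(5, 200, 6)` → 5, 44, 83, 122, 161, 200) to
   expose the transition from noise to true foci; counts are non-increasing
   in prominence.
3. **Filtering** — keep foci inside the automatically segmented
   mitochondrial mask, discard foci inside the nuclear mask (nuclear DNA
   bleeds into projected mitochondria crossing the nucleus). Pre-segmented
   masks from other tools are accepted verbatim.
4. **Area and density** — mitochondrial mask area $A$ (µm², pixel count ×
   pixel size²) and foci density $N_\mathrm{filtered}/A$ (µm⁻²), the
   quantity that turns out far less variable cell-to-cell than the raw
   count.
5. **Batch + statistics** — directory-level processing with per-cell
   artifact folders and manifests, then distribution summaries (mean, sd,
   median, IQR, CoV), two-sample Kolmogorov–Smirnov replicate comparisons,
   a simulation-based normality screen, Kruskal–Wallis tests across
   experiments, and count–area correlation.

A synthetic-cell generator (`generate_cell()`, `generate_dataset()`)
renders curvilinear mitochondrial networks carrying Gaussian foci with
known ground truth, so the full pipeline is testable without microscope
data.

## Worked example

```r
library(focicount)

# a synthetic cell with 300 known foci, 5% planted outside mitochondria
# and 5% inside the nucleus
spec <- synthetic_spec(n_foci = 300,
                       fraction_spurious_outside_mito = 0.05,
                       fraction_in_nucleus = 0.05)
cell <- generate_cell(spec, seed = 42)

cfg <- run_config(channel_roles = list(mito = 1, nucleus = 2, foci = 3),
                  prominences = c(44L, 83L))
quantify_cell(cell$stack, cell$cell_roi, cfg, cell_id = "demo")
#>   cell_id source_image experiment_id prominence n_foci_raw n_foci_filtered
#> 1    demo         <NA>          <NA>         44        330             300
#> 2    demo         <NA>          <NA>         83        330             300
#>   mito_area_um2 density_per_um2 pixel_size_um
#> 1        231.81        1.294163           0.1
#> 2        231.81        1.294163           0.1
```

At the working prominence (83 au) the pipeline recovers exactly the 300
planted mitochondrial foci: the 30 foci planted outside the mitochondrial
mask or inside the nucleus appear in `n_foci_raw` but are removed by
filtering. The measured mask area (231.8 µm² vs 213.2 µm² true) reflects
the segmentation recipe, and the density is the filtered count divided by
that area.

Batch processing and statistics:

```r
generate_dataset("dataset", n_cells = 20, spec, n_experiments = 2, seed = 1)
cfg <- run_config(channel_roles = list(mito = 1, nucleus = 2, foci = 3),
                  prominences = 83L, pixel_size_override = 0.1,
                  output_dir = "out")
batch <- run_batch("dataset", cfg)
batch_stats(batch$records)
```

A thin command-line interface is installed under `exec/focicount`
(subcommands `count`, `sweep`, `segment`, `simulate`, `stats`):

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/focicount", package="focicount"))')" \
    sweep --min 5 --max 200 --n 6
#> 5 44 83 122 161 200
```

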