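# gliamorph

Quantification of glial cell number, morphology and activation state from
immunohistochemically stained brain sections, plus magnetization transfer
ratio (MTR) mapping from paired MR acquisitions.

## The problem

Microglia and astrocytes change shape when they activate: resting
("ramified") microglia carry long, thin, branched processes, while
activated ("ameboid") microglia enlarge their soma and retract their
arbor. In brightfield sections stained with a DAB chromogen against
Iba1 (microglia) or GFAP (astrocytes) on a hematoxylin counterstain,
these changes can be quantified — but only with a pipeline that separates
the chromogen from the counterstain, finds each soma, traces the thin
processes, and splits each cell's arbor into a proximal and a distal
compartment. `gliamorph` implements that pipeline for calibrated RGB
sections, along with the bulk-stain readouts (stained area fraction,
integrated density) used for myelin stains (MBP/MOG/GST-π), MTR maps for
paired MR images, and the 2^−ΔΔCt transform for qPCR tables.

## The method

For an RGB section with calibration in µm/pixel:

1. **Colour deconvolution.** Per channel, optical density
   `OD_c = −log10((I_c + 1)/256)`; per pixel, solve `OD = M·c` for stain
   concentrations `c` with unit-norm absorption vectors (Ruifrok–Johnston
   DAB and hematoxylin by default), clipping negative concentrations.
   The chromogen channel is rendered back to a gray image
   `g = 255·10^(−c)` in which stained structures are dark.
2. **Tissue mask.** Threshold on overall brightness, closing, hole
   filling, opening, small-object removal.
3. **Soma segmentation.** Adaptive threshold: mean gray of the darkest
   fraction of in-tissue pixels times a factor; binarize, 8-connected
   labeling, size window in µm².
4. **Process segmentation.** Black top-hat with a disc sized to thin
   processes, binarized at a fraction of the soma contrast, size
   filtered, soma subtracted.
5. **Skeletonization.** Homotopic thinning to one-pixel-wide skeletons
   (connectivity preserving, endpoint keeping).
6. **Arbor decomposition.** Per soma: a dilated-soma marker reconstructs
   the thinned processes inside a circular influence zone (proximal);
   reconstructing the full process mask from those and splitting at the
   circle yields final proximal and distal compartments; contested
   pixels go to the nearer soma centroid.
7. **Morphometry.** Per cell: soma area, corner-corrected boundary-walk
   perimeter, form factor `4πA/P²`, compartment areas, skeleton lengths
   (1 px orthogonal, √2 diagonal steps), optical densities against the
   non-cell background. Per ROI: soma count and density,
   **activation index** `(Σ soma + Σ proximal area)/Σ distal area` and
   **size index** `(Σ soma + Σ proximal area)/cell count`.

MTR is computed as `MTR = (S0 − S_MT)/S0` on pixels above a noise floor,
with per-ROI means of signal and MTR, optionally normalized to a control
group.

A seeded synthetic generator (`generate_histology`, `generate_mr_pair`)
renders ground-truthed fields of ramified/ameboid cells via the same
Beer–Lambert model, so every stage is testable without slide data.

## Worked example

```r
library(gliamorph)

# a 500x500 um field of 30 ramified microglia at 0.5 um/px, seed 1
g <- generate_histology(n_cells = 30, field_size_um = 500, seed = 1)

cfg <- default_config()
cfg$calibration <- 0.5
res <- run_pipeline(g$section, cfg, out_dir = "run1")

res$seg
#> glia_segmentation: 30 soma objects, 62423 process px, 36573 skeleton px (threshold 43.1)
res$rois[, c("soma_count", "activation_index", "size_index")]
#>   soma_count activation_index size_index
#> 1         30        0.2837354   122.2167
```

Thirty somata are recovered (the planted count), the activation index is
low (≈ 0.28: a large distal arbor relative to soma + proximal area, i.e.
a resting phenotype — the same field rendered with ameboid cells scores
≈ 8), and the size index says each cell covers ≈ 122 µm² of soma plus
proximal processes. `run1/` contains all intermediate masks,
`cells.csv`, `rois.csv`, a run manifest and a log; re-running the same
config reproduces the CSVs byte for byte.

A command-line wrapper ships in `inst/cli/gliamorph.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","gliamorph.R",package="gliamorph"))')" \
  run --image slide.png --calibration 0.25 --roi rois.json --out-dir out/
```

with subcommands `run`, `segment`, `arborize`, `quantify`, `mtr`,
`qpcr`, `synth` (exit codes: 0 ok, 2 validation, 3 I/O, 4 computation).

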