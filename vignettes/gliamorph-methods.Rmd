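---
title: "Glial morphometry and MTR mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glial morphometry and MTR mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliamorph)
```

This vignette documents the models behind `gliamorph`, the parameters
that matter, the numerical conventions, and the design decisions that
were genuinely open — in enough detail that a user can judge when the
defaults apply to their data and when they do not.

## The optical model

Brightfield chromogens obey Beer–Lambert absorption to a good
approximation: the optical density of channel $c$,
$OD_c = -\log_{10}((I_c + 1)/256)$, is linear in the amounts of the
stains present, $OD = M\,c$, where the columns of $M$ are unit-norm
absorption vectors. The $+1$ offset keeps the transform finite at
$I = 0$ and exactly invertible for 8-bit data. We default to the
Ruifrok–Johnston vectors for hematoxylin $(0.650, 0.704, 0.286)$ and DAB
$(0.269, 0.568, 0.778)$; batches of chromogen differ, so both are
config-exposed (`stain.dab_vector`, `stain.hematoxylin_vector`). A
two-stain matrix is completed with its normalized cross product so the
per-pixel solve is exact; the residual channel is discarded and negative
concentrations (pixels slightly outside the stain simplex, usually
noise) are clipped to zero. Segmentation operates on the chromogen
rendering $g = 255 \cdot 10^{-c_{DAB}}$, in which stained structures are
dark; this is an interpretation choice — "the blue channel of the
deconvolved brown image" could also be read as the literal RGB blue
channel, but the deconvolved rendering is the variant that is invariant
to counterstain intensity.

## Segmentation parameters and why

Tissue is masked on overall brightness (mean of R, G, B), not on the
chromogen channel: a counterstain-only region has near-zero chromogen
but is clearly tissue. The sequence — threshold (default 235), closing
(5 µm disc), border-connected hole filling, opening (5 µm), removal of
fragments under 10 000 µm² — is fixed, because each step repairs a
specific artifact (tears, folds, dust) and their order changes the
result.

The soma threshold is adaptive: the mean gray of the darkest
`dark_seed_fraction` of in-tissue pixels ("sufficiently dark regions",
i.e. the soma cores) times `soma_threshold_factor`. The two defaults
were tuned jointly on synthetic fixtures and are deliberately a
*small* fraction with a *large* factor: at realistic densities
(10–60 cells per 500 µm field) somata occupy roughly 0.3–1 % of the
tissue, so a seed fraction of 0.002 stays inside the darkest soma cores
at any density, making the seed mean a stable estimate of peak soma
darkness (gray ≈ 10–20). The factor 3.0 then places the threshold
(gray ≈ 30–48) in the gap between the soma mode and the process mode
(gray ≈ 75–105). A larger fraction lets process pixels leak into the
seed, which *raises* the threshold on dense fields and *clips faint
somata* on sparse ones — a failure mode we observed and designed out.
For chromogens or counterstains with a different contrast gap the pair
must be re-tuned; both are config keys. The soma size window
([20, 400] µm² for Iba1 microglia; widen to ~800 µm² for GFAP
astrocytes) removes debris below and vessels/merged clumps above.

Processes are extracted by a black top-hat (closing minus image) with a
1.5 µm-radius disc: structures thinner than the disc — processes are
0.5–2 µm wide — produce a strong response, while soma-scale objects are
suppressed. The binarization cutoff reuses the seed mean as
`process_threshold_factor × (255 − seed mean)`, i.e. a fixed fraction
(default 0.15) of the soma darkness contrast; this is the concrete rule
behind "reusing the gray average of brown objects", documented as our
choice. Fragments under 5 px are removed, then all soma pixels are
subtracted (no dilated halo — exactly the soma), leaving the "true
processes".

## Thinning and length measurement

Skeletons come from homotopic thinning: simple border pixels (Yokoi
8-connectivity number 1) that are not endpoints are deleted, cycling
over the four cardinal directions until stability; candidates are
collected per direction before deletion so each pass peels one layer.
This guarantees the skeleton has exactly the components of the process
mask and keeps line endpoints, so process length survives thinning.
Length is a chain measure: each 4-adjacent skeleton pair is one pixel
step, each diagonal pair √2 — except diagonals whose two pixels share an
orthogonal skeleton neighbour, which would double-count a corner. A
straight 100-px run measures 99 steps; a 45° run 99√2.

Perimeters use the corner-corrected boundary walk
(Vossepoel–Smeulders weights 0.980 per axial step, 1.406 per diagonal,
−0.091 per corner). The naive √2 walk systematically overestimates
smooth perimeters by ~5 % (a staircase artifact), deflating the form
factor of a large disk to ≈ 0.91; the corrected walk converges
(measured: 1.027 at r = 20 px, 1.006 at r = 80 px). For very small
objects quantization can still push $4\pi A/P^2$ above 1, so the form
factor is capped at 1.0, the ImageJ circularity convention.

## Arbor decomposition

Per soma: the soma dilated `soma_dilations` (default 2) times is the
marker; skeleton pixels inside the circular influence zone
(`influence_radius_um`, default 12 µm, Euclidean distance to the
unweighted soma centroid) that are reachable from the marker are the
proximal thinned processes; morphological reconstruction (union of
8-connected components intersecting the markers) of the full process
mask from those, clipped to the circle, gives the final proximal
processes; soma plus proximal is the "visible" cell; the reconstructed
components outside the circle are distal. Components touching no marker
(arbors from cells in another focus plane, debris) belong to no cell.
The 12 µm default reflects the proximal-arbor scale of murine cortical
microglia at 20× scanning; neither it nor the dilation count is a
published value, and both are config keys. Where two cells could claim
the same process pixel, the pixel goes to the nearer soma centroid with
ties to the lower label — an arbitrary but deterministic rule; cell
masks therefore partition the claimed pixels.

The activation index, $(\sum \text{soma} + \sum \text{proximal
area})/\sum \text{distal area}$, rises when cells retract their distal
arbor (activation); the size index divides the same numerator by the
cell count. Both are aggregated over the cells whose soma *centroid*
falls in the ROI (edge cells are counted by where their soma sits), and
both are reported as `NA` — flagged undefined, never infinity — when the
denominator is empty. Optical density uses
$\log_{10}(\bar g_{\text{background}}/\bar g_{\text{object}})$ with the
background being in-tissue pixels outside every visible cell. The
stained-area readouts for bulk myelin stains divide by the in-ROI
*tissue* area (not the full ROI area) so that tears do not dilute the
fraction.

## MTR

$MTR = (S_0 - S_{MT})/S_0$ per pixel, computed only where $S_0$ exceeds
a noise floor (default: 5× the MAD of a user-named background region;
the masking is our addition — ratios of near-zero signals are
meaningless). MTR is reported as a fraction; multiply by 100 for
percentage points. ROI means are taken over valid pixels and can be
normalized by supplied control-group means.

## What the synthetic generator emulates — and what it does not

`generate_histology` renders elliptical somata (ramified: radii
2.8–3.8 µm, 4–6 processes of ~40 ± 10 µm, 1–2 px thick; ameboid: radii
4.0–5.5 µm, 2–3 processes of ~10 ± 3 µm, 2–3 px thick) as random walks
with wrapped-normal turning and occasional branching, placed ≥ 15 µm
apart edge-to-edge, and renders them through the same Beer–Lambert
model with peak chromogen ODs of ~1.0–1.4 (soma) and ~0.4–0.55
(process) on a hematoxylin background (OD 0.12 with smooth texture),
plus Gaussian pixel noise (σ = 4 by default). Each call uses a private
RNG stream derived from its seed, so identical seeds give identical
images and ground truth and the global RNG is untouched.

The generator captures the features the pipeline depends on — a bimodal
soma/process darkness distribution, thin curvilinear processes, partial
overlap of arbors — but *not* out-of-focus arbors, uneven illumination,
stain batch variation, touching somata, or vessels. Passing the
recovery tests therefore shows the algorithms are correct under the
stated optical model, not that the default thresholds transfer to any
particular scanner; on real slides the calibration is mandatory user
input (scan magnification alone does not determine µm/pixel) and the
threshold pair may need adjustment.

`generate_mr_pair` draws $S_0 = S + \varepsilon_1$ and
$S_{MT} = S(1 - MTR_{\text{region}}) + \varepsilon_2$ with independent
Gaussian noise. The delta method gives
$\mathrm{Var}(\widehat{MTR}) \approx \sigma^2 (1 + (1-m)^2)/(S^2 n)$ for
an $n$-pixel ROI mean and a small negative bias
$-(1-m)\sigma^2/S^2$ from the noisy denominator; the tests compare
recovered means against this bias-corrected expectation within three
standard errors.

## Problem sizes and numerical conventions

Tests and the acceptance script use 500 µm fields (1000×1000 px at
0.5 µm/px) with 30 cells for recovery checks and 150–300 µm fields for
unit tests — sizes chosen so the full suite exercises every stage on
realistic densities while remaining quick to run. Coordinates are
(row, col), 0-based, origin top-left; polygon ROIs use half-open
pixel-center containment (a (0,0)–(k,k) square covers exactly k²
pixels, and clockwise/counter-clockwise orientations rasterize
identically); all object labeling is 8-connected; hole filling is
border-connected background flood fill; CSV output uses a fixed 10
significant-digit format so identical runs are byte-identical.

## Known limitations

- Stain vectors are fixed per run; no automatic (Macenko-style)
  estimation.
- Overlapping arbors are split by a centroid-distance heuristic, not by
  tracing continuity across crossings.
- No Sholl analysis or branch-order statistics; lengths are totals per
  compartment.
- 2-D only; no z-stacks, no registration between sections or
  timepoints; whole-slide pyramidal formats must be tiled and exported
  to PNG/TIFF first.
- Hematoxylin nuclei are used only as background context, never
  counted.
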