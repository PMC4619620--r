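---
title: "Modeling the calcein cytotoxicity assay and its image-cytometry readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the calcein cytotoxicity assay and its image-cytometry readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcytox)
```

## The assay and why two readouts disagree

In a calcein-release cytotoxicity assay, target tumor cells are loaded with
calcein-AM, mixed with natural-killer (NK) effector cells at several
effector-to-target (E:T) ratios, and incubated for four hours. The classical
readout measures the calcein released into the supernatant:

$$\%\,\text{lysis}_{\text{release}} =
  100 \cdot \frac{T - S}{M - S},$$

where $T$, $S$ and $M$ are the supernatant fluorescences of the test well,
the spontaneous control (targets in plain media) and the maximum control
(targets fully solubilized with Triton X-100).

The image-cytometry readout instead counts the brightly fluorescent live
target cells remaining in the well:

$$\%\,\text{lysis}_{\text{imaging}} =
  100 \cdot \frac{C_S - C_T}{C_S},$$

with $C_S$ and $C_T$ the live-cell counts in the spontaneous control and the
test well, after gating out every object whose integrated fluorescence falls
below the spontaneous-control target cells.

The two formulas measure the same biology through different physics, and
they disagree whenever a killed cell does not surrender its dye. NK killing
proceeds by two morphologically distinct routes: a necrosis-like lysis that
empties most of the cell's calcein into the supernatant (a small remnant
fraction stays entrapped in debris), and an apoptotic death in which the
cell fragments into membrane-bound apoptotic bodies that retain the dye for
the duration of the assay. Retained calcein never reaches the supernatant,
so the release readout systematically underestimates lysis; the count-based
readout does not, because a killed cell is missing from the live count
regardless of where its dye went. calcytox exists to make that mechanism
explicit, simulatable and testable.

## The well model

`simulate_well()` produces the four-hour endpoint state of one well.

* **Loading.** Per-cell calcein loads are lognormal with mean `load_mean`
  (arbitrary units, AU) and coefficient of variation `load_cv` (default
  0.3). A lognormal is the simplest strictly positive, right-skewed
  two-parameter family, consistent with the well-known heterogeneity of
  calcein loading between cells and cell lines.
* **Spontaneous leak.** Every live cell loses a fixed fraction `leak_frac`
  (default 0.1) of its load to the supernatant. The leak is deterministic
  per cell; a stochastic leak would only add variance that neither readout
  resolves at plate scale.
* **Killing.** Each target in a test well is killed independently with the
  E:T-specific probability `kill_frac_by_et` (defaults 0.9, 0.6 and 0.35 at
  E:T 2:1, 1:1 and 0.5:1). Killing is a single end-of-assay Bernoulli event:
  both readouts are endpoint measurements, so the four-hour kinetics can be
  collapsed without affecting anything either readout can see. E:T ratios
  absent from the map are rejected rather than interpolated — silent
  interpolation hides configuration mistakes.
* **Lysis modes.** A killed cell dies apoptotically with probability
  `apoptotic_frac` (default 0.7), otherwise necrosis-like. Necrosis leaves
  one cell-sized remnant retaining `necrotic_retention` (default 0.1) of the
  cell's calcein. Apoptosis produces `bodies_per_cell` apoptotic bodies
  (default 6, diameter 4 µm against 10 µm live cells) jointly retaining
  `apoptotic_retention` (default 0.5); the retained total is split across
  bodies by a symmetric Dirichlet draw.
* **Conservation.** Supernatant plus particle calcein equals total loaded
  calcein exactly, by construction; the suite checks it to 10⁻⁹ relative.

Under this model, with leak 0, all-apoptotic killing at kill fraction $k$
and retention $\rho$, the expected readouts have a closed form:
release % $= 100\,k\,(1-\rho)$ and imaging % $= 100\,k$. The gap
$100\,k\,\rho$ is the retention-driven underestimation of the release assay,
and the acceptance suite verifies both limits to within two percentage
points at $n = 10{,}000$ targets per well.

### Why the body split is not uniform

A maximally uninformative (flat Dirichlet) split of retained calcein across
four bodies makes individual bodies brighter than the dimmest spontaneous
live cells alarmingly often: with loading CV 0.3, about 8 % of bodies at
full retention would out-shine the 5th-percentile live cell, and the
intensity gate could no longer separate bodies from live cells — contrary
to what the assay's images show, where bodies are uniformly small and dim
and the spontaneous-referenced gate excludes them cleanly. We therefore
fragment cells into six moderately even bodies (`body_split_conc = 8`,
giving fragment shares of 17 % ± 6 %). With these defaults the probability
that a single body at full retention exceeds the 5th-percentile spontaneous
intensity is about $4 \times 10^{-4}$, dominated by the irreducible
loading-tail case of a cell that loaded four times the typical amount.
These values were fixed by this generator-level analysis, not fitted to
anything downstream.

## The imaging model

`sample_field()` and `render_field()` form the camera model. Resuspending
the pellet and transferring an aliquot to the counting slide randomizes
particle positions, so each particle of the well appears in the imaged
field independently with probability `sampled_fraction` (default 0.03; the
chamber geometry of a real instrument fixes this, and about 3,000 counted
objects from 50,000 cells suggests values near 0.06) and receives a fresh
uniform position. Placement keeps centres at least `min_spacing_um`
(default 15 µm) apart and `edge_margin_um` (13 µm) from the borders: the
counting chamber is a dilute monolayer, and the defaults keep neighbouring
spots resolvable at the default point-spread width and unclipped at the
image edge. The default field is 1024 × 1024 px at 1 µm/px, which holds the
densest default test wells (roughly 1,200 rendered particles) comfortably
below the packing limit of that spacing.

A particle of calcein $c$ renders as an isotropic Gaussian spot of total
signal $\text{gain} \cdot c$ counts and width
$\sigma = \max(\text{psf\_sigma\_um}, d/4)$, pixel-integrated (pixel $i$
spans $[i-0.5, i+0.5)$). Exposure time and optics are deliberately absorbed
into the one `gain` constant (default 100 counts/AU), since only relative
intensities matter to gating. Noise follows the standard camera forward
model — Poisson shot noise on signal plus `background_offset` (100 counts),
additive Gaussian read noise (SD 2), quantization, clipping to the bit
depth (16 by default). At these defaults a typical live cell peaks about
250 counts above background, roughly 25 background-noise SDs. Every
rendered image carries a ground-truth table of per-particle noiseless
totals, which is what makes oracle tests of the detection stage possible.

## Detection and gating

`detect_objects()` estimates background as the image median (robust to
bright objects), thresholds at background + `k_sigma` robust SDs (MAD-based,
default k = 5; Otsu is available but unstable on sparse fields whose
foreground occupies a tiny fraction of pixels), labels connected components
(8-connectivity by default; touching cells are not split — acceptable at
the dilute densities simulated, and noted as a limitation), and reports
per-object background-subtracted integrated intensities, clamped at zero.
Components below `min_diameter_um` equivalent diameter are dropped. The
default cutoff is 1.5 µm: at 1 µm/px a single pixel has equivalent diameter
1.13 µm, so a cutoff of 1.5 removes the one-pixel shot-noise specks that
otherwise appear in spot halos, while leaving the 4 µm apoptotic bodies
untouched — their exclusion from live counts belongs to the intensity gate,
as in the assay itself. A constant image yields an empty table with a
warning rather than an error, so a saturated well does not abort a plate.

`derive_gate()` formalizes the histogram gate drawn against the spontaneous
control: the live-cell intensity bound is the `q`-th percentile (linear
interpolation, default q = 5) of the pooled spontaneous-control
intensities. The percentile form is a reproducible, data-driven analogue of
the manual gate; q = 5 tolerates a small dim tail in the controls while
excluding partially released cells and bodies. `count_live()` applies the
intensity and diameter bounds inclusively.

Because the same gate bias applies to spontaneous and test wells, the count
*ratio* in the imaging formula is unbiased even though each count is about
5 % low; the end-to-end acceptance check verifies recovered live counts
against rendered ground truth within 99 % binomial intervals.

## Readouts and statistics

Out-of-range lysis values (below 0 % or above 100 %) are reported unmodified
and flagged — clamping would hide assay failures such as an inverted
dynamic range. Controls are averaged before the formulas (plate-reader
practice); per-test-well values are retained for statistics. The release
formula is invariant to rescaling all three releases by a common constant,
so the supernatant sampling fraction cancels; the analogous property holds
for the imaging formula and the field-sampling fraction in expectation.

The paired comparison between readouts uses the Wilcoxon matched-pairs
signed-rank test, two-tailed. Zero differences are dropped (Wilcoxon's
original convention) and ties receive mid-ranks. For up to 25 informative
pairs the null distribution of $W$ is computed exactly by convolution over
the observed rank multiset — this remains exact under ties, where the
textbook tables do not apply — and beyond 25 pairs a normal approximation
with continuity and tie corrections takes over. The 15-pair design
(5 donors × 3 replicates) that a typical study yields falls squarely in the
exact regime. `stats::wilcox.test` deliberately serves only as an
independent cross-check in the tie-free case, and full enumeration of sign
assignments as the brute-force oracle.

## Orchestration, seeds and the two counting routes

`run_plate()` executes a full plate. Per-well seeds derive from the master
seed by a fixed linear-congruential mix (`derive_seed()`), so wells are
independent yet the entire plate is bitwise reproducible. Two counting
routes exist:

* `counting_mode = "render"` — the full pipeline: sample a field, render
  it, detect, gate, count. This is the honest instrument emulation and the
  default.
* `counting_mode = "table"` — per-object measurement tables built directly
  from particle states (every particle measured, no field sampling). This
  is the route for externally supplied measurement tables, and for
  large-sample statistical checks where field-sampling noise (binomial with
  roughly 300 spontaneous objects per field at the defaults) would swamp
  the quantity under test.

`analyze_images()` is the analysis-only entry point: a plate map pointing
at TIFF images or object-table CSVs reproduces `run_plate()`'s downstream
behaviour exactly; an unreadable well is reported and skipped, a map
without spontaneous wells is a gating error. A thin command-line front end
(`inst/cli/calcytox`) exposes `simulate`, `analyze`, `quantify` and
`compare` with exit codes 0/2/3 for success, configuration and gating
errors.

## Problem sizes, tolerances and what the tests do not show

The test and acceptance suites run at desk scale: 10,000 targets per well
(the wet protocol's 100,000 is a pipetting quantity, not a statistical
requirement), 1024² px default fields, three replicates, and Monte-Carlo
loops of 100 runs for directional claims (the release-underestimation gap
growing with retention; the paired test detecting imaging > release at
15 pairs). Closed-form limits are checked to 2 percentage points, method
agreement at zero retention to 3, conservation to 10⁻⁹ relative.

The generator emulates loading heterogeneity, spontaneous leak, the two
lysis modes, dye conservation, field subsampling and camera noise. It does
not emulate: effector-cell biology (conjugation, serial killing,
degranulation kinetics), time courses, cell clumping or overlap beyond the
spacing floor, photobleaching, bright-field context, focus or illumination
artifacts, or the biological density dependence of killing seen when assay
volume is reduced — reducing `n_targets_per_well` at fixed kill fractions
leaves expected lysis unchanged by design. Passing tests therefore
demonstrate that the pipeline measures what the model generates; they do
not certify performance on real images with artifacts the renderer does not
produce.

## Known limitations

* No declumping: two cells closer than the spacing floor would merge into
  one object; real dense fields need a watershed step the package does not
  provide.
* The apoptotic-retention fraction and the apoptotic/necrotic mix are free
  parameters; the source observations are qualitative, so defaults encode
  plausibility, not measurement.
* The exact-test implementation enumerates rank convolutions up to 25
  pairs; far larger paired designs fall back to the corrected normal
  approximation.
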