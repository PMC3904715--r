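---
title: "Counting particles per cell without bias: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting particles per cell without bias: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disectr)
```

## The problem

A common way to report chloroplast number per mesophyll cell is to count
chloroplast profiles in 2D micrographs of sectioned cells. A section,
however, is a measure-zero slice of a 3D tissue: a plane hits a particle
with probability proportional to the particle's extent along the sectioning
axis (its *caliper height*). For a stationary particle field the areal
density of profiles is

$$N_A = N_V \cdot \bar h,$$

where $N_V$ is the numerical density (particles per volume) and $\bar h$ the
mean caliper height. Taking the ratio of chloroplast profiles to cell
profiles therefore yields

$$\frac{N_A^{chl}}{N_A^{cell}} = \frac{N_V^{chl}\,\bar h_{chl}}
{N_V^{cell}\,\bar h_{cell}},$$

which differs from the desired per-cell count
$N_V^{chl}/N_V^{cell}$ by the factor $\bar h_{chl}/\bar h_{cell}$
(`bias_ratio()`). Chloroplasts are about 4 µm tall while conifer mesophyll
cells are 40–60 µm tall along the optical axis, so 2D profile counting
underestimates the per-cell count roughly 10- to 15-fold. This package
implements both the biased 2D procedure and the design-based 3D remedy, and
quantifies the gap on synthetic tissue where the truth is known.

## The probes

**Optical disector (unbiased brick).** `disector_brick()` is a 3D block with
a *reference* (inclusion) plane on top and exclusion surfaces elsewhere:
the bottom *look-up* face, and forbidden side walls. A particle is counted
when it intersects the closed block and touches no exclusion surface
(`brick_count()`). The normative property is *mosaic exactness*: when
translated copies of the brick tile space, every particle is counted by
exactly one copy, which is what makes $E[Q] = N_V \, a \, h$ exact without
any assumption on particle shape or size.

The side-wall geometry deserves a note. Per horizontal slice, the wall
cross-section is the full Gundersen forbidden line of the frame footprint:
the left edge *with its upward in-plane extension*, the bottom edge, and the
downward extension through the bottom-right corner. A reading with plain
rectangular side faces (no in-plane extensions) fails the tiling property:
an axis-aligned ellipsoid centred laterally beyond a wall, dipping into the
brick while crossing the wall's plane only outside the brick footprint, is
counted twice by adjacent probes. The walls sweep from the look-up level
upward past the reference plane to infinity; no downward extension is
needed, because any particle that intersects the block and crosses the
look-up level either cuts the look-up face itself or crosses a neighbour's
wall. The test suite asserts exact single counting on 3D tilings with
hundreds of random spheroids, which validates the convention.

**Double disector.** `double_disector_count()` applies the brick in both
z-directions on the same slab; an interior particle may be counted twice by
design, and the reported probe height is twice the slab height (a 10 µm
slab yields a 20 µm probe), which keeps $Q/(a\,h)$ unbiased while doubling
the sample.

**Unbiased counting frame.** `frame_count()` counts 2D profiles that meet
the closed frame rectangle without touching the forbidden line (left edge +
upward extension, bottom edge, downward extension through the bottom-right
corner). The same tiling property holds in 2D and is tested the same way.

**Point grid and Cavalieri.** `point_grid_hits()` estimates reference areas
as $P \cdot a/p$; `cavalieri_volume()` turns SUR section areas into a volume
either as $T \sum A_i$ (textbook) or as $\bar A \cdot L$ (the variant used
when a needle's length is measured directly). The two agree exactly when
$L = nT$; the mean-times-length form is the default and reports are explicit
about the mode.

**Tangency convention.** All contact tests are closed-set: touching an
exclusion surface excludes, touching an inclusion face includes. These are
measure-zero events for random data, but fixing them deterministically is
what allows the tiling tests to assert *exact* equality. All geometry is
exact for axis-aligned spheroids (per-axis scaling maps a spheroid to the
unit sphere while keeping boxes axis-aligned, so closest-point clamping
decides contact); no rotation support is offered, because every caliper
height of interest is stated along the optical axis.

## The estimators

`nv_estimate()` implements the pooled disector estimator
$(\Sigma Q \cdot p)/(\Sigma P \cdot a \cdot h)$ and `na_estimate()` its areal
analogue $(\Sigma Q \cdot p)/(\Sigma P \cdot a)$. Densities are ratios of
sums across probes, not means of per-probe ratios — that is how the pooled
formulas are defined, and it avoids division by ill-conditioned per-probe
reference tallies. $\Sigma P = 0$ is a guarded error (one cannot divide by
an empty reference space); no further tolerance on $\Sigma P$ is imposed,
raw tallies are always reported. `per_cell_ratio()` forms the final
particles-per-cell quotient.

## The synthetic tissue generator

The generator is the ground-truth side of every experiment, so its defaults
*are* the study conditions:

| parameter | default | meaning |
|---|---|---|
| chloroplast semi-axes | (2.5, 2.5, 2.0) µm | z-caliper 4 µm |
| per-axis scatter | CV 0.1 | keeps the mean caliper at 4 µm |
| model-cell z semi-axis | 24.5 µm | z-caliper 49 µm, inside 40–60 µm |
| chloroplasts per model cell | 210 | the demonstration count |
| tissue cell caliper | 40 ± 2 µm | low end of the 40–60 µm range |
| tissue cell lateral semi-axis | 12.5 ± 0.6 µm | ~25 µm wide cells |
| chloroplasts per tissue cell | 210 ± 21 | Gaussian, rounded, ≥ 0 |
| mesophyll fraction | 0.72 | mesophyll region / needle volume |
| cell packing | 0.60 | cell volume / mesophyll region |
| tissue domain | 200 × 200 × 400 µm | ~350 cells, ~73k chloroplasts |

Design choices that were genuinely open:

* **Mesophyll fraction vs cell packing.** The 72% figure is the fraction of
  the needle occupied by the mesophyll *region* (what point counting on
  cross-sections measures, intercellular space included). It cannot be a
  packing fraction of disjoint spheroids — random sequential placement
  saturates near 0.38 and even lattice packings of spheroids cap at 0.74 —
  so the generator realises it as a centred inner box holding exactly that
  share of the domain volume, and packs cells inside it at a separate
  `cell_packing` target (default 0.60, tightly connected but not maximal).
* **Lattice placement.** Mesophyll cells form tightly connected layers, so
  the default placement is an affinely scaled face-centred-cubic lattice
  with a uniform random phase, jittered within the packing slack. The
  random phase is what makes fixed-frame probe counts unbiased across
  replicate tissues. Size scatter is truncated by the packing slack, so at
  high packing targets cells become nearly uniform in size — the per-cell
  chloroplast counts still scatter. A `dart` mode (uniform rejection
  sampling) exists for sparse tissues.
* **Containment.** Chloroplasts are kept wholly inside their parent cell by
  a conservative sufficient test (scaled centre norm plus largest scaled
  semi-axis ≤ 1). Placements are therefore slightly interior; this leaves
  the per-section expectation $n \bar h / H$ untouched (it depends only on
  calipers being inside the cell extent) and buys an exact guarantee that
  the dense-surface-sampling oracle in the tests confirms.
* **Uniform placement by default.** Frozen-then-sectioned tissue loses the
  in vivo peripheral arrangement of chloroplasts, so centers are
  volume-uniform by default; a `peripheral_shell` mode is available for
  arrangement studies. Chloroplast overlap is allowed by default (counting
  is id-based, not morphological); a bounded-rejection non-overlap mode
  exists and errors informatively when packing is impossible.
* **Lobed cells.** Real mesophyll cells are lobed; here they are single
  spheroids. The per-cell bias depends on caliper heights, not lobing, so
  this simplification does not touch the quantity under study — but it does
  mean the generator says nothing about, e.g., profile shape statistics.

`render_label_stack()` voxelizes a model into 16-bit label images (page 0 =
topmost plane, matching disector browsing order; ties to the highest id,
documented in its help page) with TIFF + JSON-sidecar I/O. It emulates
perfectly segmented confocal stacks: no point-spread function, no noise, no
bleed-through. Passing stack-based tests therefore shows correctness of the
counting rules on labelled data, not robustness to real fluorescence
imaging.

## The two experiments

**Model cell** (`model_cell_experiment()`): 111 systematic sections through
the 49 µm cell; the mean profile count per section sits at the analytic
expectation $210 \times 4 / 49 = 17.1$, about 12-fold below the true 210.
The sections are SUR through the cell extent — whether the original
demonstration's 111 sections were systematic or exhaustive is not decisive,
and systematic matches the sampling philosophy used everywhere else; the
choice is recorded in each report's `assumptions` field.

**Tissue comparison** (`tissue_comparison()`): SUR positions along the
needle axis; at each position a cell double disector (10 µm slab), a
chloroplast double disector (5.5 µm slab), point-grid reference counts and
middle-section frame counts; pooling per the formulas; then the 3D and 2D
per-cell estimates and their ratio, plus a paired t test across positions
(`paired_t()`, reported but never used as an acceptance gate — p-values on
synthetic replicates are not the quantity of interest). Positions with a
zero cell tally are flagged, excluded from the paired values and logged in
`notes`. The default probe count is 10 positions per tissue, the order of
cross-sections obtained per needle under 3 mm SUR sampling.

```{r experiments}
ex <- model_cell_experiment(seed = 1)
ex

tc <- tissue_comparison(seed = 1)
tc
```

## Numerical choices and problem sizes

* The frame for the tissue comparison is inset from the mesophyll region by
  one cell diameter, and probe z-positions keep one cell caliper plus half a
  slab of clearance, so every counted particle comes from a homogeneous
  region of the generated field — otherwise edge deficits would leak into
  the density estimates.
* The point grid spacing is the frame side divided by `grid_points`, so the
  number of test points per frame is constant (almost surely) across random
  offsets, as the pooled formulas assume.
* Degenerate inputs are first-class: zero-particle models, single sections
  (SE reported as `NA`), zero tallies (guarded errors), tangent planes
  (point profiles, closed convention).
* Test-time problem sizes are chosen to keep the whole suite in tens of
  seconds while leaving Monte-Carlo checks well-powered: tiling exactness on
  ~400 spheroids × 80–100 probes, unbiasedness on 20 independent fields ×
  25 probes (500 probes, with field-level noise in the SE), the DeHoff
  identity on 10^4 particles, Cavalieri on 100 random offsets, and 25
  stack-versus-geometry trials at the resolution contract (`dz ≤ rz/4`,
  `pixel ≤ rx/4`). Stack trials additionally require the probe to be in
  general position — the geometric count must be invariant to one-pixel
  probe shifts — because a particle boundary lying within a fraction of a
  pixel of a probe surface is a discretisation tie that pixel sampling
  cannot resolve; such ties are measure-zero in continuous geometry.

## Limitations

The generator produces axis-aligned spheroids on a jittered lattice, not
lobed cells in real anatomy (epidermis, hypodermis, vascular tissue are all
absent); the stacks are noise-free label images; and the acceptance-level
agreement of the 3D:2D ratio with the caliper prediction is a property of
the generated conditions (4 µm particles in 40 µm cells), not a measurement
of any real specimen. Real-needle quantities — total needle volume via
`cavalieri_volume()` on measured cross-section areas, per-needle pooled
tallies — are supported by the same functions but require real
measurements. Coefficient-of-error formulas for stereological estimators
and section-thickness corrections are out of scope: optical sections are
treated as true planes throughout.
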