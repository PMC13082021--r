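---
title: "Quantifying the ciliary base: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the ciliary base: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliabase)
```

# Scope

`ciliabase` implements the quantitative layer of an in situ structural
study of the ciliary base in mammalian multiciliated cells: the stretch
from the proximal centriole through the transition zone into the early
axoneme, together with the ciliary necklace on the surrounding membrane,
a cross-linking mass-spectrometry (XL/MS) interactome, and
expansion-microscopy (U-ExM) scaling. It deliberately stops short of
image processing: tilt-series alignment, reconstruction, denoising,
subtomogram alignment and membrane segmentation are the province of the
established cryo-ET stacks, and spectral searching belongs to the MS
engines. What this package owns is everything those tools leave as
"custom scripts": particle geometry on traced filaments, spatially
constrained label cleanup, membrane-lattice statistics, consensus
interactome construction with distance-restraint mapping, and the U-ExM
arithmetic. Every stage is paired with a synthetic generator that emits
ground truth, so the whole pipeline is testable on a laptop with no
deposited data.

# The zone model of the ciliary base

The barrel of nine microtubule filaments is modelled as a sequence of
ordered subzones, proximal to distal: proximal centriole (**P**), core
centriole (**C**), a short boundary region around the distal ring
(**B**), transition zone (**TZ**) and early axoneme (**AX**). The
default lengths are 205, 230, 30, 253 and 300 nm and the default barrel
diameters 215, 197, 190, 169 and 178 nm. P/C/TZ lengths and all four
measured diameters are tomogram means; the boundary-region length
(order of a few 8 nm tubulin repeats) and the simulated axoneme length
are free choices, because the boundary region's extent is not a measured
quantity and the real axoneme continues far beyond the field of view.
Both are plain entries of the `zones` data frame and can be changed
freely.

`gen_cilium()` realizes this model as straight generatrices on a barrel
whose radius follows the zone profile. Real barrels taper smoothly, so
the stepwise radius profile is smoothed with a 20 nm moving average by
default (`radius_smoothing`); with smoothing on, bins inside a zone
still read the zone diameter and only bins within half a window of a
boundary interpolate. Because generatrices are straight and radius
changes are gentle, the axial coordinate doubles as the arc-length
coordinate `s`; particle counts per filament are exactly
`floor(total_length / step) + 1`.

Diameters throughout are **axis-to-particle-centre distances times
two**, not tubule-wall diameters: the profile reports twice the mean
perpendicular distance of particle centres from the fitted barrel axis.

# Filament geometry

`resample_spline()` interpolates traced control points with a natural
cubic spline (chord-length parameterized), reparameterizes by arc
length using dense numeric integration (several hundred evaluations per
control segment, spacing error well under 1%), and emits particles
every 4 nm — the conventional oversampling for filament subtomogram
averaging — with the particle Z axis along the local tangent and the
in-plane angle drawn uniformly. Orientations are stored as ZYZ Euler
angles in degrees (`rot`, `tilt`, `psi`), the STAR-file convention, and
the rotation matrix contract is that its third column equals the unit
tangent.

`clean_by_distance()` is a greedy first-come-kept pass in stored order
with an 8 nm default: deterministic, order-stable and idempotent, which
is the behaviour one wants from a cleaning step that may be re-run.
Note the pass is global, not per filament, so two filaments traced
closer than the cleaning distance will shadow each other — intentional,
since duplicate traces are exactly what cleaning should remove.

`split_halfsets()` tags half-sets at the **arc-length midpoint of each
filament** (median rank; ties give the extra particle to half A).
Splitting at the midpoint rather than randomly keeps heavily
overlapping neighbours inside one half-set, avoiding inflated
correlation between half-maps in resolution estimation.

`fit_barrel_axis()` takes the principal direction of all positions as
the axial coordinate and builds the axis as a running centroid over
overlapping 40 nm windows, which follows gently bent barrels. At least
three filaments are required; with fewer, the centroid does not track
the barrel centre.

# Zone classification

Upstream 3D classification assigns one of five classes per particle,
imperfectly. Sharpening happens in two separable passes:

1. **`vote_reassign()`** — iterated synchronous majority vote. Each
   particle adopts the modal label of its neighbourhood (itself
   included); ties keep the current label, which guarantees fixed
   points exist; iteration stops at a fixed point or `max_iter`. The
   default neighbourhood is a one-dimensional arc window of ±8 nm on
   the particle's own filament (about 5 particles at 4 nm spacing); an
   alternative 3D k-nearest-neighbour mode (`k = 15`, across
   filaments) is available. The window half-width must stay below half
   the shortest expected zone: the boundary region is only ~30 nm long,
   and a wider window (e.g. ±24 nm, spanning 48 nm) makes the majority
   vote erode it entirely on a few percent of filaments and drag its
   boundaries by tens of nm. At ±8 nm and 20% label noise the vote
   recovers ~99% of ground-truth labels in simulation while preserving
   all five zones.
2. **`enforce_ordering()`** — exact dynamic-programming segmentation of
   each filament into at most one contiguous segment per zone in the
   prescribed proximal-to-distal order, minimizing the number of
   relabelled particles. Zones listed in `optional_zones` (the boundary
   region by default) may be empty; all others must keep at least one
   particle. Keeping the spatial-constraint logic in its own exact pass,
   rather than baking it into the vote, makes both steps independently
   testable — the DP is verified against exhaustive enumeration of
   boundary placements on small instances.

Boundaries are reported midway (in arc length) between the two
particles flanking a label change, with across-filament mean and SD per
transition. On the default synthetic barrel at 20% label noise, the
across-filament mean boundary lands within ~5 nm of truth and the
per-transition SD is a few nm (one step is 4 nm).

# Membrane lattice (ciliary necklace)

The necklace is modelled as `n_rows` rings of `particles_per_row`
equally spaced particles on a cylinder, with isotropic positional noise
and independent dropout. Defaults — 7 rows, 17.5 nm pitch, 54 particles
per row on a 945 nm circumference — put the generator at the measured
lattice: 17.5 nm in-row spacing and six particles per doublet
microtubule.

Quantification proceeds by: least-squares cylinder fit (`fit_cylinder`,
Nelder-Mead over axis orientation and in-plane offset from two
principal-direction initializations — largest and smallest variance, so
both tall cylinders and flat rings start near the optimum; the radius
is the mean radial distance, optimal given an axis); isometric
unrolling into `(u, v)` flattened coordinates (`unroll_membrane`, the
coordinate system of a membranogram); row detection as local maxima of
a 1D Gaussian kernel density over `u` (`detect_rows`, bandwidth 4 nm ≈
a quarter of the pitch; rows closer than about twice the bandwidth
merge — a documented resolution limit, verified at 6 nm pitch); and
within-row nearest-neighbour spacing (`row_spacing`) pooling gaps
**including the wrap-around gap**, since rows are closed rings — a row
of n particles contributes exactly n gaps. Line-profile protocols do not usually say whether they include the
wrap-around gap; including it is the choice that makes the gap count
equal the particle count.

Two caveats are inherent. First, the package measures spacing on picked
particle coordinates, not on line profiles over rendered membranogram
images; coordinates are the quantitative content of those images.
Second, for a *single* flat ring the cylinder axis tilt is nearly
unidentifiable (the objective is quartic in the tilt angle around the
optimum), so axial scatter from a slightly tilted fit can split one
ring into two apparent rows; with two or more rows the axis is
well-conditioned. Lattice statistics are rigid-motion invariant up to
the ~0.1 nm quantization of the density grid.

`fit_cylinder` doubles as the diameter estimator for traced
cytoskeletal filaments (actin ~7 nm, intermediate filaments ~10 nm),
which it recovers exactly on noise-free surface points.

# XL/MS consensus interactome

Engine tables (schema
`protein_a,residue_a,protein_b,residue_b,score,csm_fdr`) are filtered
at CSM-level FDR — 1% for the primary engine and 5% for the secondary
by default — canonicalized so the lexicographically smaller
(protein, residue) endpoint comes first, and de-duplicated at
residue-pair level keeping the best score. **Consensus** keeps links
reported by both engines at exact residue-pair identity; a coarser
protein-pair mode exists for engines with divergent residue-level
localization. Residue-pair granularity is the right default because
"unique cross-links" are counted at amino-acid level. No additional
link-level FDR is computed beyond the per-engine thresholds.

`network_stats()` counts unique residue-level links, distinct proteins,
and protein-protein interactions as unordered pairs of *distinct*
proteins (homotypic pairs excluded by default, with an inclusive option, since
reported interactome sizes rarely state the convention).

`map_links()` resolves both endpoints in a structure map — (protein,
residue) → Cα coordinate in Å, built by `read_structure()` from
PDB/mmCIF with highest-occupancy altloc resolution — and reports the
Euclidean Cα–Cα distance, taking the minimum over chain combinations
for proteins present on several chains (homodimeric ambiguity). The
"mapped" denominator is links with both residues present in the model,
which is why mapped counts are smaller than table totals.
`restraint_satisfaction()` reports the fraction of mapped links within
35 Å, the span compatible with a DSSO cross-link measured between Cα
atoms; with zero mapped links the fraction is `NA`, never 0. Cα–Cα is
the standard DSSO practice; side-chain distances would require full
side-chain coordinates, which the structure map intentionally does not
carry.

The simulator `gen_crosslinks()` plants true links among residue pairs
within the restraint on an idealized structure and decoys beyond it,
then emits per-engine tables under independent detection
probabilities. By construction, truth links satisfy the restraint and
decoys violate it, so the satisfied fraction of emitted records equals
the planted true fraction exactly — the property the restraint oracle
tests lean on — and two engines at detection probabilities 0.9 and 0.8
give an expected consensus recall of 0.72.

# U-ExM metrics

The expansion factor is the mean of per-measurement ratios
`width / reference`, with 250 nm as the reference axoneme width; for a
fixed reference this equals mean-width over reference, but per-ratio
bookkeeping keeps the SD meaningful. Lengths measured on the expanded
scale divide by EF.

The transition-zone length is read from a two-channel intensity
profile as the gap in the polyglutamylated-tubulin channel: signal
support is where intensity reaches half the channel maximum
(configurable; half-maximum is the standard edge criterion where a protocol states
none), and the
gap is the distance from the end of the first support interval to the
start of the next, divided by EF. The result is invariant to overall
intensity scaling. The synthetic profile generator defines its sampling
grid in corrected units (0.5 nm default) so pulse edges fall on grid
points; noise-free gaps are then recovered exactly, noisy ones within
one sampling step. Profile extraction from images is the caller's
concern — the package consumes position/intensity tables.

# Randomness and reproducibility

Every generator takes one integer seed. Per-filament and per-row
substreams are derived by drawing substream seeds from a master RNG
seeded once (`sample.int` under the model seed) — a linear formula over
(seed, stream index) was measurably correlated across nearby seeds and
was replaced. All generator calls restore the session RNG state on
exit. Identical model + seed gives bit-identical output, which the CLI
exploits: `simulate --seed 7` twice produces byte-identical files, and
every CLI run writes its fully resolved configuration (YAML) next to
its outputs.

# Problem sizes

The test-suite and acceptance simulations run at the biological
geometry itself: nine filaments × 255 particles (2295 particles) for the
barrel, 7 × 54 lattice points for the necklace, a few hundred planted
cross-links on toy structures of 100–200 residues, and 30-width U-ExM
samples. These sizes keep every simulation deterministic-feeling and
fast while leaving enough particles per zone (hundreds) for the
recovery tolerances quoted above to be meaningful.

# What the synthetic data does and does not show

The generators emulate the *statistical* structure of the study's
data: zone-dependent geometry with uniform label flips, a periodic
lattice with isotropic noise and dropout, engine tables with
independent detection and decoy rates, rectangular fluorescence
pulses. They do not emulate missing-wedge anisotropy, structured
(confusable-neighbour) misclassification, membrane curvature beyond a
cylinder, engine score correlation, or point-spread blurring. Passing
recovery tests therefore demonstrates that the estimators are unbiased
and correctly implemented under the stated noise models — not that the
original imaging pipeline was artifact-free. The printed-value
benchmarks that need deposited data (the full consensus table, the
doublet-microtubule coordinate model) are exposed as ordinary function
calls (`network_stats`, `map_links`, `tubulin_partners`) for users who
download them.

# Known limitations

- Filaments in the generator are straight generatrices; the spline
  resampler handles curved traces, but end-to-end zone recovery is only
  simulated on straight barrels.
- The DP ordering pass assumes each zone occurs at most once per
  filament; genuinely interleaved classes (e.g. a pathology) would be
  forced into the canonical order.
- `detect_rows` is a 1D method on the axial coordinate; strongly tilted
  lattices (rows not perpendicular to the axis) would need a 2D lattice
  model.
- Protein identifier normalization across engines is left to a
  configurable upstream step; the consensus assumes both tables use the
  same accession style.
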