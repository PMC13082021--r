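# ciliabase

Quantitative analysis of the multiciliated-cell ciliary base for in situ
structural biology: oriented particle generation along traced filaments,
spatially constrained class-label cleanup defining ciliary subzones,
ciliary-necklace membrane-lattice statistics, two-engine consensus
cross-linking MS (XL/MS) interactomes with distance-restraint mapping,
and expansion-microscopy (U-ExM) metrics — all backed by ground-truthed
synthetic generators so every stage is testable without deposited data.

It is aimed at cryo-ET practitioners who trace filaments in IMOD and
average subtomograms in STOPGAP/RELION, and at XL/MS users combining two
search engines. The package owns the "custom script" layer between those
tools; it does not align tilt series, segment membranes, or search
spectra.

## The quantities it computes

- **Filament geometry.** Traces are resampled every 4 nm along a natural
  cubic spline, arc-length parameterized, each particle oriented with
  its Z axis along the local tangent and a randomized in-plane angle
  (ZYZ Euler angles, STAR convention). Particle lists are cleaned with a
  greedy 8 nm minimum-distance pass and half-sets are split at the
  midpoint of each filament to avoid overlap-induced half-map
  correlation. The nine-filament barrel axis is a running centroid along
  the principal direction; the diameter profile is twice the mean
  perpendicular distance of particles from that axis, binned axially
  (axis-to-particle-centre, not wall-to-wall).
- **Subzones.** Noisy per-particle class labels are sharpened by an
  iterated synchronous majority vote among arc-window neighbours
  (ties keep the current label), then made contiguous and ordered
  (P → C → B → TZ → AX) by an exact dynamic program minimizing label
  changes. Boundaries are reported midway between flanking particles,
  with across-filament mean ± SD per transition.
- **Ciliary necklace.** A least-squares cylinder fit, isometric
  unrolling into flattened membrane coordinates (u = axial,
  v = circumferential arc), row detection by 1D kernel-density maxima,
  within-row neighbour spacing including the wrap-around gap, inter-row
  pitch, and particles-per-doublet stoichiometry (mean row count / 9).
- **XL/MS interactome.** Engine tables filtered at CSM FDR (1% / 5%
  defaults), canonicalized and de-duplicated; the consensus keeps
  residue pairs reported by both engines; network statistics count
  unique links, proteins and heterotypic PPIs; links map onto PDB/mmCIF
  models as Cα–Cα distances (minimum over chain copies) against the
  35 Å DSSO restraint; tubulin partners and lumen/exterior topology
  calls come from the same link table.
- **U-ExM.** Expansion factor EF = mean(width / 250 nm); length
  correction by 1/EF; transition-zone length as the half-maximum gap in
  the polyglutamylation (GT335) channel, EF-corrected.

## Worked example

A synthetic nine-filament barrel with 20% label noise and 1 nm jitter,
sharpened and measured:

```r
library(ciliabase)
ps <- gen_cilium(cilium_model(label_noise = 0.2, jitter_sigma = 1, seed = 1))
sharp <- enforce_ordering(vote_reassign(ps), zone_ordering())
count_segments(sharp)
#> 1 2 3 4 5 6 7 8 9
#> 5 5 5 5 5 5 5 5 5
zone_boundaries(sharp)$summary
#>   transition  mean    sd n
#> 1       P->C 204.7 3.464 9
#> 2       C->B 433.6 3.127 9
#> 3      B->TZ 464.7 4.472 9
#> 4     TZ->AX 718.4 2.404 9
zone_means(diameter_profile(ps, fit_barrel_axis(ps), bin = 10,
                            label_col = "true_label"))
#>   zone diameter n_bins n_particles
#> 1    P    214.6     21         471
#> 2    C    197.0     23         519
#> 3    B    186.8      3          69
#> 4   TZ    169.2     25         561
#> 5   AX    177.9     30         675
```

Every filament recovers the five subzones; the recovered boundaries sit
within ~2 nm of the generating zone model (205, 435, 465, 718 nm) and
the zone diameters read back the generator values (215/197/190/169/178
nm, with the short boundary zone pulled slightly by its taper).

The necklace lattice on a noisy synthetic membrane:

```r
nk   <- gen_necklace(necklace_model(noise_sigma = 0.5, seed = 1))
pts  <- nk$points[, c("x", "y", "z")]
fm   <- unroll_membrane(pts, fit_cylinder(pts))
rows <- detect_rows(fm)
rows
#> row_assignment: 7 rows at u = -52.6, -35.0, -17.5, 0.0, 17.6, 34.9, 52.6 nm
sp <- row_spacing(fm, rows)
round(c(mean = sp$mean, sd = sp$sd, n = sp$n, pitch = sp$pitch), 3)
#>    mean      sd       n   pitch
#>  17.504   0.654 378.000  17.530
per_doublet_stoichiometry(sp$per_row$n)$ratio
#> [1] 6
```

Seven rows at 17.5 nm pitch, 17.5 nm mean in-row spacing over 378
periodic gaps, and six necklace particles per doublet microtubule.

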