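---
title: "Building complex asymmetric CG membranes and analysing their lipid organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building complex asymmetric CG membranes and analysing their lipid organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lipidorg)
```

## The problem

Mammalian plasma membranes are strongly asymmetric multicomponent mixtures:
the extracellular leaflet is rich in phosphatidylcholine, sphingomyelin and
glycolipids such as GM3, the cytosolic leaflet in phosphatidylethanolamine,
phosphatidylserine and PIP2, with cholesterol distributed across both. In
coarse-grained (CG) simulations of such mixtures the interesting biology is
statistical: transient GM3 nano-domains in the outer leaflet, PIP2 networks
in the inner leaflet, cholesterol hopping between leaflets, slowed diffusion
of clustered species, and coupling between local composition and bilayer
undulations. `lipidorg` provides two things: a *builder* that constructs
such asymmetric CG bilayers with exact compositional control, and an
*analysis stack* for quantifying lipid organization in bead-coordinate
trajectories. Because converged multi-microsecond CG trajectories cannot be
regenerated at desk scale, every analysis is validated against a
*synthetic-membrane generator* that plants known statistical structure and
reports it in a ground-truth manifest; correctness is then a
parameter-recovery statement, not an eyeball comparison.

## Membrane construction

The builder starts from an idealized all-POPC bilayer
(`generate_template_bilayer()`): lipids on a jittered square lattice at a
chosen area per lipid (default 53.3 Å², giving the canonical ~20 x 20 nm
patch for 750 lipids per leaflet), heads out, tails toward the midplane,
with the lower-leaflet lattice staggered by half a cell so that beads
approaching the midplane from opposite sides are laterally offset.
`exchange_lipids()` then edits this template into any per-leaflet
composition:

* Integer species counts per leaflet come from **largest-remainder
  rounding** of the requested fractions (ties broken by alphabetical
  species name), so every count is within one lipid of `fraction x
  leaflet size` and leaflet totals are preserved exactly. The exchange is
  one-for-one, which keeps the non-cholesterol percentage of the two
  leaflets equal by construction — the property that protects an
  asymmetric build from an area-per-lipid mismatch between leaflets.
* Molecules to convert are drawn uniformly without replacement under a
  recorded seed; rebuilding with the same seed is bit-identical.
* Species with POPC-length or shorter chains (POPE, POPS, sphingomyelin)
  are relabeled bead-for-bead in place. Larger species (GM3, PIP2, and the
  di-unsaturated lipids) are rigid-superimposed from an idealized
  straight-chain template onto the first two tail beads of the selected
  POPC. Two anchor points leave the azimuthal orientation free, so the
  adjacent linker bead — geometrically congruent between templates — is
  used as a third Kabsch anchor; the two tail beads still map exactly, and
  the new molecule inherits the replaced lipid's orientation instead of a
  random one (which otherwise produces steric overlap with neighbours).
  Cholesterol is superimposed on the head group plus the first three tail
  beads, and is split exactly equally between leaflets.
* Tail beads beyond the four-bead reference tail (PIP2's fifth bead) are
  packed at reduced spacing so long tails stay on their own side of the
  midplane.

The templates are idealized conformers, not simulation snapshots: the
analyses in this package operate on configurations and never evaluate
energies, so the idealization costs nothing downstream, and a built frame
satisfies a hard steric invariant (no inter-molecular bead pair closer than
1 Å). `place_protein_grid()` adds idealized transmembrane helices (one
backbone bead per residue, 1.5 Å rise, 100°/residue) on a regular grid —
spacing exactly the requested value, 60 Å by default, so initial
protein-protein contacts are unbiased — and deletes lipids with any bead
within an exclusion radius (default 3 Å) of a protein bead.
`replicate_frame()` tiles a membrane laterally (the genconf-style route
from 1500 to 6000 lipids).

```{r}
pm <- build_membrane(pm_composition(), n_lipids = 1500, seed = 1)
composition_counts(pm, "outer")   # GM3 = 75 of 750, exactly
pm6000 <- replicate_frame(pm, 2, 2)
```

## Leaflet assignment

All per-leaflet statistics need leaflet tags. `assign_leaflets()` is
three-state: a lipid whose reference bead (head-bead centroid; the ROH bead
for cholesterol) sits more than `core_half_width` (default 10 Å — the
sources of such data rarely state a threshold, and 10 Å is roughly half a
leaflet thickness) above the local midplane is `outer`, below is `inner`,
otherwise `core`. The midplane is estimated locally on a 4x4 lateral grid
from the linker beads (glycerol esters / amino alcohols), so assignment
remains correct in strongly undulating patches where a global plane would
misclassify; how to assign leaflets in curved regions is genuinely open,
and the local-midplane rule is this package's choice. Compact trajectories
that store only reference points (the diffusion and flip-flop generators)
use the per-frame global midplane instead, which is exact for the flat
synthetic systems they describe.

## Fractional lipid-lipid interactions

Two lipids are in contact when any pair of their linker beads is closer
than 11 Å (lateral minimum image, strict `<`); however many bead pairs
qualify, the pair counts once. Cholesterol, which cannot be assigned to one
leaflet over time, is excluded. The *fractional interaction matrix*
normalizes the pooled ordered contact counts by the number of ordered pairs
available:

r(A→B) = C(A→B) / (N_A · Ñ_B),  Ñ_B = N_B (B ≠ A), N_A − 1 (B = A),

then row-normalizes. The literature describing this statistic states the
abundance correction only in words; this per-ordered-pair rate is adopted
here because it is the unique simple choice whose expectation under random
labeling is the same for every entry — hence 1/k for k species *regardless
of composition*, reproducing both printed baselines (0.5 for two species,
0.25 for four) — while preserving the asymmetry of the raw counts (A's
neighborhood of B differs from B's of A when one species clusters). Counts
are summed over frames before normalization (sum-then-normalize) rather
than averaging per-frame fractions; with stationary frame weights the two
differ only at third order, and pooling is robust to frames where a rare
species has few contacts.

## Nano-cluster statistics

`dbscan_periodic()` implements DBSCAN over lateral minimum-image distances.
Conventions, each of which the original description leaves open: the
eps-neighborhood *includes the point itself* when compared with
`min_elements` (the common convention for "minimum number of elements = 3");
neighbors are counted at distance ≤ eps; clustering is strictly lateral
(nano-domains are in-leaflet structures and the analysis is per leaflet);
border points reachable from two clusters go to the first cluster
discovered in deterministic point order, so runs are reproducible; noise
points get singleton labels so every run partitions the input. The
implementation is tested for exact partition equality against an
independent brute-force reference that enumerates periodic images,
including clusters straddling the boundary. `cluster_timeseries()` bins
per-lipid cluster sizes into the standard classes (1-3 non-clustered, 4-20
small, 21-40 medium, >40 large). `protein_clusters()` is single-linkage
connectivity: proteins are linked when any inter-protein bead pair is
within 8 Å, transitively.

## Cholesterol flip-flop

`detect_flipflops()` tracks the three-state leaflet label per cholesterol
and records an event only for a completed crossing — the confirmed leaflet
changes outer↔inner, core passages allowed in between — after the new
leaflet has persisted `min_dwell` consecutive frames (default 5). The
debounce is this package's addition: without it, boundary noise at the
core threshold inflates rates, and excursions into the core that return to
the same leaflet must not count. Rates are reported per system
(events/ns summed over molecules). Event counts are invariant to which
exact frame a crossing is stamped on, so recovery is scored against the
generator's manifest event list and Poisson counting error.

## Lateral diffusion

`lateral_msd()` computes the lateral MSD averaged over molecules and all
time origins (FFT accumulation, tested to 1e-9 against the direct O(n²)
sum), after removing the per-leaflet center of motion frame-by-frame —
leaflets can drift antisymmetrically, so drift is removed per leaflet, not
globally. `fit_diffusion()` fits a straight line over lags in a fractional
window of the maximum lag, default 10-50%: short lags carry crossover
effects in real data, long lags have few independent origins. D = slope/4
with 1 Å²/ns = 1e-7 cm²/s. `windowed_diffusion()` repeats the fit in
consecutive windows (default 1 µs) to expose time trends. Fits require
unwrapped coordinates and refuse wrapped input with guidance.

## Curvature-composition correlation

`grid_decompose()` bins a leaflet into an 8x8 lateral grid (half-open
boxes, periodic wrap, edge points to the higher-index box). The surface
height z_n of a box is the mean z of the head/tail interface beads of the
lipids in it, excluding the species being correlated — a species must not
define the surface it is correlated against. The normalized
cross-correlation R_L,z between per-box counts and z_n uses Pearson
normalization (the natural reading of "normalized cross correlation",
bounded in [−1, 1] and consistent with error-barred per-species values);
it is computed per frame against the per-frame box mean (the average
position is per-snapshot, another open reading resolved here), empty boxes
are excluded, zero-variance frames contribute R = 0 with a flag, and the
implementation is tested to 1e-12 against `cor()`. Sign convention:
negative R for an outer-leaflet species means enrichment where the surface
deflects toward the cell interior — concave viewed from outside.
`interleaflet_correlation()` correlates outer-species counts with
inner-species counts across laterally corresponding boxes, and
`local_thickness()` reports per-box interface separation and its
correlation with height, so "bending without thinning" is a testable
property rather than a remark.

## The synthetic generators, and what passing tests do not show

Each generator plants exactly the structure one analysis estimates:

* `make_random_leaflet()` — hard-core (7 Å) random sequential adsorption
  with randomly permuted species labels: the random-mixing null. The
  default density is 90 Å² per lipid: a hard-core sequential process jams
  at ~70 Å²/lipid (disk jamming coverage ≈ 0.547), so the physical ~60 Å²
  cannot be realized by RSA at all; 90 Å² keeps the point pattern
  homogeneous and placement fast while the label permutation — not the
  point pattern — carries the random-mixing property being calibrated.
* `make_clustered_leaflet()` — hexagonally packed discs of chosen sizes
  (8 Å spacing, well inside eps), inter-disc gaps > 45 Å, singletons
  kept ≥ 18-20 Å from everything: DBSCAN must recover the planted
  partition exactly, and the size-class fractions are scored against the
  manifest.
* `make_curved_frame()` — a sum of sinusoidal surface modes displacing
  both leaflets congruently; species are placed by thinning a Poisson
  process with intensity ∝ 1 + c·ẑ. ẑ is the surface normalized by its
  *amplitude* (not its standard deviation): with amplitude normalization,
  |c| ≤ 1 is exactly the condition for a nonnegative intensity, whereas a
  z-scored sinusoid exceeds one in magnitude and would make strong
  couplings ill-defined.
* `make_diffusion_trajectory()` — independent Gaussian walks, per-axis
  step variance 2·D·dt so the lateral MSD is 4·D·t, unwrapped, z fixed per
  leaflet. Defaults are the CG plasma-membrane scale: 2.6/2.0/1.5 x 1e-7
  cm²/s for bulk lipid / PIP2 / GM3, 500 lipids, 5000 frames at 1 ns.
* `make_flipflop_trajectory()` — a three-state Markov jump process.
  Given target occupancy π and system crossing rate R over N molecules,
  leaflet exit rates a_X = R/(N·π_X) and core exit rate b = R/(N·π_core)
  (split equally toward both leaflets) satisfy detailed balance with
  stationary distribution π and completed-crossing flux exactly R.
  Defaults: N = 1500 cholesterol (the 6000-lipid membrane's pool),
  1000 ns at 1 ns, R = 0.14/ns, π = (0.49, 0.02, 0.49), initial states
  stratified exactly to π — mirroring a builder's exactly equal initial
  cholesterol split. The pool size matters statistically: the deviation of
  time-averaged occupancy scales like sqrt(R·T)/N, so a ±0.02 occupancy
  recovery at this rate and duration requires a membrane-scale pool, not a
  token handful of molecules.

What these generators deliberately do not emulate: energetics and force
fields, correlated many-body dynamics (real lipids develop RSA-unlike pair
correlations, hydrodynamic and sub-diffusive behavior at short times),
coupling between processes (clustering is static per frame; diffusing
lipids do not cluster; flip-flopping cholesterol does not diffuse
laterally), and solvent or ions. Passing recovery tests therefore
demonstrates that the *estimators* are correct and calibrated — unbiased
under the null, able to recover planted effect sizes at realistic problem
sizes — not that any particular membrane exhibits those effects. Applied
to real trajectories the same code paths run unchanged via the GRO
readers.

## Problem sizes and numerical choices

The test-suite and acceptance runs use: 50-frame, 1000-lipid leaflets for
the mixing calibration (three seeds, plus two-species and skewed
variants); 200 random instances of ≤ 100 points for DBSCAN oracle
equivalence; the full 500-lipid, 5000-frame diffusion recovery; the
1500-cholesterol, 1000 ns flip-flop recovery; and 20-50 curvature frames
with 3000-lipid leaflets. These sizes were chosen so each statistic's
sampling error is several times smaller than the tolerance it is tested
at. Degenerate inputs are defined rather than accidental: empty grid boxes
are excluded, zero-variance frames give R = 0 with a flag, negative MSD
slopes are reported with a warning and their sign, wrapped trajectories
are rejected by the MSD path, triclinic boxes are rejected at I/O, and
exact-boundary distances follow the stated strict/inclusive conventions
(contacts strictly `< 11 Å`; DBSCAN and protein connectivity at `≤`).

## Known limitations

The builder produces starting structures, not equilibrated ensembles; no
minimization or solvation is performed. GM3 and PIP2 bead topologies are
idealized stand-ins at the topology level (bead counts, head/linker/tail
roles, charges), not validated force-field parameter sets. The
fractional-interaction normalization is one defensible reading of a
verbally specified correction; alternatives (per-frame averaging,
unordered-pair normalization) would shift clustered-system values, though
not the random-mixing calibration. Leaflet assignment near strong
curvature depends on the midplane grid resolution. The RDF assumes an
orthorhombic box and lateral geometry.
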