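---
title: "Analysing noble-gas binding to membrane proteins with gasbind"
author: "gasbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing noble-gas binding to membrane proteins with gasbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasbind)
```

## The problem

Noble gases (argon, krypton, xenon) bind to proteins through weak London
dispersion forces, preferring apolar pockets. For membrane proteins the
picture is richer than for soluble ones: besides internal cavities, gas
atoms accumulate on the lipid-facing hydrophobic surface -- the same belt
that annular lipids occupy -- and, in a crystal, in the membrane-plane
contacts between lattice neighbours. Quantifying where gas binds, how
strongly, and what it does to protein dynamics connects directly to the
question of how chemically inert anaesthetics act on membrane proteins.

`gasbind` implements the complete computational side of such a study for
seven-transmembrane-helix (7-TM) systems:

1. **Site classification** -- sort crystallographic gas sites into
   *internal*, *surface* and *crystal_contact* groups with per-group
   occupancy/B-factor summaries.
2. **Occupancy density maps** -- accumulate time-averaged 3-D gas
   occupancy grids from aligned trajectory frames, and read/write
   CCP4/MRC and OpenDX maps.
3. **Peak analysis** -- detect density peaks above a `mean + k sigma`
   threshold, match them to crystallographic sites, cluster them, count
   clusters absent from the crystallographic model, and convert peak
   densities to binding free energies via the Boltzmann relation.
4. **Elastic-network dynamics** -- anisotropic network model (ANM) normal
   modes with gas atoms included as network beads, and the per-residue
   fluctuation change that bound gas induces.
5. **Synthetic ground truth** -- generators for helical bundles, planted
   gas sites, Gaussian-blob grids and dwell/hop trajectories, so every
   stage can be validated end to end against known answers.

## Site classification

A gas site is classified with precedence *internal* → *crystal_contact* →
*surface*:

* **Internal.** The site is buried if its position cannot be connected to
  the exterior of the model's bounding box by a flood fill over grid
  voxels (default spacing 1.0 Å) whose distance to every occluding atom
  exceeds that atom's van der Waals radius plus a probe radius of 1.2 Å
  (roughly a noble-gas-accessible channel). Built-in vdW radii: C 1.70,
  N 1.55, O 1.52, S 1.80 Å; 1.70 Å otherwise. Occluders are the protein
  plus non-water, non-gas heteroatoms (lipid fragments and, in synthetic
  fixtures, cavity walls). A site pressed so close to the wall that its
  own voxel is blocked inherits the exterior status of the nearest free
  voxel within 2 Å -- without this, genuinely exposed sites hugging the
  surface would be misread as buried.
* **Crystal contact.** Any atom of any non-identity symmetry image
  (operators × lattice translations −1..+1 per axis) within 4.0 Å of the
  site. The source data never states its numeric contact criterion, so
  4.0 Å -- a typical gas-to-heavy-atom van der Waals contact distance --
  is the default and is exposed in the configuration. Contacts are
  evaluated against images of the protein/lipid occluder set, not against
  images of other gas atoms: the "crystal contact" group describes gas
  wedged between *molecules*. The −1..+1 translation range assumes the
  model fits one unit cell (a documented limitation).
* **Surface.** Everything else. A membrane slab, when supplied, is
  recorded as evidence only; it never changes a label.

Sites farther than 15 Å from all protein atoms are labelled surface with
a "detached site" warning. Increasing the contact cutoff can only move
sites *into* the contact group, never out of it -- a monotonicity the test
suite asserts.

```{r classify-demo}
bundle <- make_bundle(bundle_spec())          # 7 x 25-residue CA bundle
planted <- plant_sites(bundle, plant_site_spec(1, 3, 2), seed = 2)
classified <- classify_sites(planted$model, planted$sites)
summarize_groups(classified)
```

## Occupancy maps and their statistics

`accumulate_density()` aligns every frame to the reference bead set with
a Kabsch superposition (proper rotation only), applies the same transform
to the gas positions, and adds one count to the voxel containing each gas
atom -- the centre/nearest-voxel convention
`floor((r - origin)/spacing + 0.5)` -- before dividing by the frame
count. Values are therefore time-averaged atoms per voxel. Gas centres
are counted as points; no atomic-radius smearing is applied, because the
point-count reading is the one with an exact occupancy-histogram
interpretation and known threshold behaviour under the synthetic blob
generator. Periodic-boundary re-imaging is the frame provider's
responsibility: box geometry is engine-specific, so the module requires
pre-imaged gas coordinates.

`grid_stats()` reports the mean and the *population* standard deviation
over the sampling box, matching the r.m.s.-from-mean convention used for
thresholding; both are computed over the supplied box only, since the
systems of interest use a sub-box around the protein rather than the full
simulation cell.

## Peak detection, matching, clustering, free energies

* **Detection.** A voxel is a peak iff its value exceeds
  `mean + k * sigma` (default `k = 5`) *and* it is maximal over the cube
  of half-width `window` (default 2 Å, i.e. ±4 voxels at 0.5 Å spacing;
  a full-width reading would halve this, so the choice is exposed).
  Plateau ties resolve to the lexicographically smallest voxel index
  among all equal-valued voxels of the candidate's window -- a local,
  order-independent rule. Display conventions for such maps often use a
  lower contour (3.5 sigma); the 5-sigma value is the *detection*
  threshold and the two roles are kept distinct.
* **Matching.** Site-centric and non-exclusive: a crystallographic site
  is an "atom match" iff at least one peak lies within 4 Å. This mirrors
  how match counts are tabulated per site group; a one-to-one assignment
  variant was considered and deliberately not implemented (see
  *Limitations*).
* **Clustering.** Greedy agglomeration with centroid linkage: repeatedly
  merge the closest pair of cluster centroids (ties to the smallest id
  pair) until all inter-centroid distances reach the 5 Å cutoff,
  recomputing centroids as member means. The cutoff is phrased "between
  cluster centres", which is why centroid linkage is used; the stopping
  rule is robust to centroid-linkage inversions, which is why a generic
  dendrogram cut is not. Clusters whose members match no site are
  counted "not present" in the crystallographic model.
* **Free energy.** `dG = -R T ln(rho_peak / rho_ref)` in kJ/mol, with
  T = 323.15 K by default. When the map was accumulated by the package,
  the map mean over the sampling box *equals* the bulk (composition)
  density of in-box gas over that box, so it is the natural default
  reference; `bulk_reference_density()` converts a known box composition
  into a reference for externally produced maps. For scale: a peak 400x
  the reference at 323.15 K gives −16.1 kJ/mol.

## Elastic-network dynamics with gas beads

The ANM places one bead per residue at its CA and connects every bead
pair closer than 15 Å (strict inequality) with a uniform spring
`gamma = 1`; resolved gas atoms enter the network as additional beads
with the same spring constant and cutoff. Fluctuations are in arbitrary
units (the spring constant sets the scale, and halving `gamma` doubles
every MSF), with `kT = 1`. The Hessian's 3x3 off-diagonal blocks are
`-gamma * d d^T` with `d` the unit inter-bead vector; diagonal blocks
are minus the row sums, so uniform translations lie in the null space
exactly. A connected 3-D network has exactly six zero modes (a collinear
geometry such as the two-bead dimer has five); any other count aborts
with the count reported, which catches disconnected networks. Modes
below `1e-8` of the largest eigenvalue count as zero (configurable).
Mean-square fluctuations sum `kT / lambda` over all non-zero modes --
no truncation, since the choice of a mode subset is otherwise arbitrary.

Gas occupancy does not affect the network by default (all resolved sites
enter at weight 1); `occupancy_weighted = TRUE` scales each gas bead's
springs by its occupancy for sensitivity analysis.

### Why the difference profile marginalizes the gas beads

`fluctuation_difference()` compares residue fluctuations without gas
against the with-gas network *after integrating out the gas
coordinates*: the effective residue Hessian is the Schur complement
`H_rr - H_rg pinv(H_gg) H_gr`. This is the exact Gaussian marginal of
the with-gas Boltzmann distribution over residue coordinates, it shares
the six rigid-body zero modes of the gas-free network, and it dominates
the gas-free Hessian in the positive-semidefinite order because the
added springs contribute a positive-semidefinite term. Consequently the
per-residue difference is *provably* non-positive: bound gas can damp,
never amplify, the harmonic dynamics -- the package's desk-scale
counterpart of the uniformly negative difference profiles seen in the
full study.

The naive alternative -- taking the residue diagonal of the full
with-gas pseudo-inverse -- is *not* exactly monotone: the gas beads
shift the rigid-body null space of the combined network, and small
positive per-residue differences (of order 0.1-1% of the MSF) appear.
Both quantities agree to that same order; the marginalized form is used
because the inequality it satisfies is the scientific statement being
made. `fluctuations()` on a full with-gas network remains available when
the gas beads' own fluctuations are of interest.

```{r enm-demo}
fd <- fluctuation_difference(planted$model, planted$sites)
summary(fd$delta)   # all non-positive
```

## The synthetic generators: what they emulate, and what not

The generators produce every input with known ground truth:

* `make_bundle()` -- an idealized 7-TM fold: seven ideal alpha-helix CA
  traces (rise 1.5 Å/residue, 100°/residue, helix radius 2.3 Å, hence
  consecutive CA distances of 3.83 Å) on a 10 Å circle, axes along +z.
  The membrane normal is fixed to +z throughout the synthetic fixtures;
  some convention has to be chosen and this matches how membrane slabs
  are usually drawn.
* `plant_sites()` -- surface sites in inter-helix clefts placed so the
  nearest protein atom is 3.5 Å away; internal sites at the centre of
  sealed 4 Å cages of pseudo-atoms (Fibonacci sphere, 60 atoms, gaps well
  below twice the probe-inflated vdW radius) appended to the model;
  contact sites 3.0 Å off a lattice image inside a P1 cell with a 9 Å
  packing gap -- far enough inside the 4 Å cutoff that the 0.2-0.3 Å
  positional jitter cannot flip the label. Occupancies and B-factors are
  drawn from ranges typical of refined gas sites (0.15-0.5 and
  20-50 Å²).
* `make_blob_grid()` -- sums of isotropic Gaussians plus independent
  per-voxel half-normal noise. Half-normal (mean
  `sd * sqrt(2/pi)`) keeps grids non-negative, as occupancy counts are;
  blob amplitudes are naturally expressed in units of the noise sigma so
  threshold behaviour is known by construction.
* `make_hop_trajectory()` -- a gas atom dwells at a site and hops with
  probability `1/mean_dwell` per frame to a site drawn from the
  stationary weights, emulating the long-lived (tens of ns) site
  residences seen in simulation; hop targets are drawn independently of
  the current site, so the stationary occupancy equals the weights in
  expectation. Frames are given a random rigid wobble by default so the
  accumulation step genuinely exercises its alignment.

What they do **not** emulate: real lipids or any force-field energetics,
side chains (CA traces only), finite map resolution, anisotropic
B-factors, or correlated experimental noise. Passing the closed-loop
tests therefore demonstrates the *computational chain* is correct --
planted sites recovered, planted blobs detected and matched, decoys
counted as novel clusters -- not that any particular biological system
behaves this way.

## Numerical choices

* Kabsch superposition uses SVD with the determinant correction (proper
  rotations only) and rejects collinear point sets, for which the
  rotation is underdetermined.
* Alternate locations resolve to the highest-occupancy conformer, ties
  by altloc letter -- the deterministic choice parsing requires.
* RMSD between two models pairs atoms by chain + residue number + atom
  name over the common set; unpaired atoms are dropped with a message
  reporting the count.
* Voxel assignment is nearest-voxel with the origin at the centre of
  voxel `[1,1,1]`; grid values are finite and non-negative by contract.
* Map I/O: MRC mode 2 (32-bit float), axis order normalized to x-fastest
  on read; OpenDX text grids transpose their z-fastest layout. Round
  trips are exact to float32 precision.
* The clustering and peak tie-breaks are fully deterministic, so two
  runs on identical inputs produce byte-identical reports (timestamps
  are deliberately excluded from all outputs).

## Problem sizes in the shipped validation

The test-suite and acceptance fixtures use 7x25-residue bundles
(175 CA beads, 525 ANM coordinates), grids up to 30^3 voxels against the
brute-force peak oracle, up to 40 peaks against the exhaustive-merge
clustering oracle, 50 randomized classification fixtures and 20
randomized damping fixtures, and dwell/hop trajectories of 600-10000
frames. These sizes were chosen so each oracle comparison is exhaustive
and exact; all scale linearly (grids, trajectories) or cubically (ANM
eigendecompositions) for real systems of a few hundred residues.

## Limitations

* Cavity detection is a probe flood fill on a 1 Å grid, not a
  solvent-excluded-surface computation; channels narrower than the probe
  (1.2 Å) read as sealed, and the grid can quantize marginal cases
  (halving the spacing is a supported robustness check).
* One-to-one (assignment-style) peak-site matching is not implemented;
  matching is site-centric, so one peak may match several nearby sites.
* Lattice expansion searches translations −1..+1 only, sufficient when
  the model occupies a single cell.
* The deposited-structure checks require the user to supply the
  coordinate files (see `tests/testthat/test-acceptance.R`); they are
  not shipped.
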