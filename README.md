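# gasbind

Analysis of noble-gas binding to membrane proteins: site classification
in a crystal lattice, gas occupancy density maps from trajectory frames,
density-peak statistics with Boltzmann binding free energies, and
elastic-network (ANM) estimates of how bound gas damps protein dynamics.

## Who this is for

Structural biologists and simulators studying how small hydrophobic
ligands -- argon, krypton, xenon -- interact with membrane proteins.
Crystals pressurized with noble gas reveal binding sites by anomalous
scattering; molecular-dynamics simulations of the same proteins in a
bilayer produce 3-D gas probability maps. `gasbind` provides the
computations that connect the two and quantify the consequences:

* **Where does the gas bind?** Each crystallographic site is assigned to
  one of three groups with `classify_sites()`:
  * *internal* -- inside a cavity, detected by an exterior flood fill
    over probe-accessible voxels (probe 1.2 Å, vdW radii C 1.70 /
    N 1.55 / O 1.52 / S 1.80 Å);
  * *crystal_contact* -- within 4 Å of a symmetry-related molecule,
    found by expanding the crystal symmetry
    (fractionalize → operate → orthogonalize, lattice translations
    −1..+1);
  * *surface* -- on the lipid-facing hydrophobic belt (everything else).
* **How does simulation compare with crystallography?**
  `accumulate_density()` builds volmap-style time-averaged occupancy
  grids from Kabsch-aligned frames; `detect_peaks()` finds local maxima
  above mean + 5σ in a 2 Å moving window; `match_peaks()` counts sites
  with a peak within 4 Å ("atom matches"); `cluster_peaks()` groups
  peaks by centroid-linkage agglomeration with a 5 Å cutoff; clusters
  with no matched member are "not present" in the crystal model.
* **How strong is the binding?** The Boltzmann relation
  ΔG = −RT·ln(ρ_peak / ρ_ref) at 323.15 K converts density ratios into
  kJ/mol (`binding_free_energy()`).
* **What does gas do to dynamics?** An anisotropic network model (one
  bead per residue at Cα, uniform springs below 15 Å) with gas atoms
  included as beads; `fluctuation_difference()` returns per-residue
  mean-square-fluctuation changes, provably non-positive (the gas
  coordinates are marginalized out via the Schur complement, so added
  springs can only stiffen the effective residue Hessian).

Synthetic generators (`make_bundle()`, `plant_sites()`,
`make_blob_grid()`, `make_hop_trajectory()`) produce 7-TM-like fixtures
with known ground truth, so the whole chain is testable end to end.

## Worked example

Plant one internal, three surface and two crystal-contact krypton sites
on a synthetic 7-helix bundle, let a gas trajectory dwell at the surface
sites, and run the full pipeline:

```r
library(gasbind)

bundle    <- make_bundle(bundle_spec())                  # 7 x 25 residues
planted   <- plant_sites(bundle, plant_site_spec(1, 3, 2), seed = 2)
summarize_groups(classify_sites(planted$model, planted$sites))
#>             label n mean_occupancy   mean_b
#> 1        internal 1      0.2822897 32.50173
#> 2         surface 3      0.3034841 41.49545
#> 3 crystal_contact 2      0.2884260 26.52741
#> 4           total 6      0.2949323 35.00715

surf <- as.matrix(planted$sites[planted$sites$label == "surface",
                                c("x", "y", "z")])
traj <- make_hop_trajectory(planted$model,
          hop_trajectory_spec(surf, n_frames = 600, mean_dwell = 8,
                              jitter = 0.25, n_gas = 2), seed = 5)$traj
report <- run_pipeline(run_config(model = planted$model,
                                  sites = planted$sites, frames = traj))
#> [gasbind] classify: 6 sites (1/3/2)
#> [gasbind] peaks: 3 above mean + 5 sigma
#> [gasbind] match: 3/6 sites matched, 3 clusters, 0 not present
#> [gasbind] enm: 175 residues, mean delta -0.01301
```

The classification recovers the planted 1/3/2 split. The trajectory
dwelt only at the three surface sites, so exactly those three sites gain
density peaks ("3/6 sites matched"); internal and contact sites have no
counterpart, just as single-molecule simulations cannot reproduce
lattice-contact sites. Peak free energies
(`report$free_energy$dg_kj_mol`: −28.7 to −30.4 kJ/mol here) measure how
concentrated the occupancy is relative to the box average, and the ANM
block shows the damping bound gas imposes on every residue
(`report$enm$mean_delta = -0.013` arbitrary units, always ≤ 0).

A thin command-line wrapper ships at `inst/cli/gasbind`
(`gasbind run --config run.yaml`, `gasbind rmsd`, `gasbind classify`,
`gasbind peaks`, `gasbind enm`).

## Package layout

* `R/structures.R` -- PDB/mmCIF models, selection, Kabsch superposition,
  crystal-symmetry expansion
* `R/site_classification.R` -- burial flood fill, site groups, summaries
* `R/density_maps.R` -- occupancy grids, statistics, MRC/DX I/O,
  trajectory accumulation
* `R/peak_analysis.R` -- peak detection, matching, clustering, free
  energies
* `R/enm.R` -- elastic networks, normal modes, fluctuation differences
* `R/synthetic.R` -- ground-truth generators
* `R/pipeline.R` -- end-to-end orchestration with JSON/TSV reports
* `vignettes/gas-binding-analysis.Rmd` -- the model, conventions and
  design choices in detail
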