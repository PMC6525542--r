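# capsidlattice

Analysis of fullerene capsid lattices — the closed pentamer/hexamer shells
formed by retroelement and retrovirus capsid (CA) proteins — as they are
recovered by cryo-electron tomography and subtomogram averaging.

Capsid geometry follows the Caspar–Klug quasi-equivalence rules: a shell in
which the shortest lattice route between two pentamers is *h* steps, a 60°
turn, and *k* further steps has triangulation number

    T = h² + hk + k²

and, when closed and icosahedral, consists of 60 T subunits arranged as 12
pentamers and 10(T−1) hexamers on 10 T + 2 capsomers.  Real particles are
often damaged, and some are closed but non-icosahedral ("mixed" local
T-numbers, unevenly distributed pentamers).  This package provides the full
desk-scale toolchain for studying such lattices:

- **Synthetic generators** — ideal icosahedral (h,k) lattices (Goldberg-dual
  construction), skew-elongated prolate shells with mixed local T, positional
  noise and capsomer loss (`generate_icosahedral`, `generate_prolate`,
  `perturb`), and density-map rendering with immature-like (thick inner
  layer) or mature-like (condensed core) interiors (`render_density`).
- **Lattice graphs** — noise-robust capsomer adjacency (local distance
  cutoff plus a Delaunay-flip pruning step), symmetry-environment
  classification (fivefold / pseudothreefold / true threefold / boundary),
  and fullerene closure detection via the discrete Gauss–Bonnet sum
  (`build_graph`, `classify_capsomers`, `closure_report`).
- **T-number determination** — local (h,k,T) between pentamer pairs by
  breadth-first lattice walks that transport a hexagonal coordinate frame
  through hexamer-only corridors (`local_t`), per-particle verdicts
  icosahedral / mixed / incomplete (`particle_t`), closed-form censuses
  (`lattice_census`), and asymmetric-unit decompositions
  (`asu_decomposition`).
- **Density-map analysis** — radial profiles and shell radii, particle
  centre estimation, two-type morphology classification, cyclic-symmetry
  spectra of capsomer subvolumes, translational align-and-average, Fourier
  shell correlation with 0.5 / 0.143 resolution reporting, and shrinkage
  correction for resin-embedded material (`radial_profile`,
  `estimate_center`, `classify_morphology`, `cyclic_symmetry_spectrum`,
  `align_average`, `fsc`, `shrinkage_correct`).
- **Packaging arithmetic** — genomic bases per Gag molecule and interior
  volume per base (`packaging_stats`).
- **I/O** — capsomer tables (CSV), MRC2014 maps, Chimera-style lattice-map
  marker files with the blue/green/yellow class colours, YAML run
  configurations and deterministic JSON reports; a command-line front end
  lives at `inst/cli/capsid.R` (verbs `generate`, `analyze`, `profile`,
  `fsc`, `packaging`, `pipeline`).

## Worked example

Generate an ideal T = 9 particle at the ~24 nm CA-layer radius typical of a
retroelement capsid, classify its lattice, and read off its architecture:

```r
library(capsidlattice)

s <- generate_icosahedral(3, 0, radius_nm = 24)
g <- classify_capsomers(build_graph(s))
g
#> <lattice_graph> 'ico_h3_k0': 92 capsomers, 270 edges
#>   coordination: 12 x deg 5, 80 x deg 6
#>   classes: 12 fivefold, 60 pseudothreefold, 20 threefold

particle_t(g)
#> <t_report> 'ico_h3_k0': verdict icosahedral (T = 9)
#>   30 pentamer pairs, 0 unresolved
#>   capsomer-count T = 9

asu_decomposition(g)
#>        fivefold pseudothreefold       threefold
#>               1               6               2

lattice_census(9)
#> <lattice_census> T=9: 540 subunits on 92 capsomers (12 pentamers + 80 hexamers)
```

The 30 pentamer-pair vectors are all (3,0): every nearest pentamer pair is
separated by two hexamers along one lattice vector, the signature of a T = 9
icosahedron.  The asymmetric unit holds nine quasi-equivalent subunits: one
in the fivefold, six in pseudothreefold and two in true threefold positions.

Packaging density for such a shell holding two copies of a 5.2-kb genome in
a ~5 × 10⁴ nm³ interior:

```r
packaging_stats(5.2, 2, lattice_census(9)$n_subunits, 5e4)
#> <packaging_report> 5.2 kb x 2 copies = 10400 bases in 540 Gag, 5e+04 nm^3
#>   19.26 bases/Gag (~20), 4.81 nm^3/base (~5)
```

Rendering and profiling the same particle recovers its radius:

```r
m <- render_density(s, voxel_nm = 1, blob_sigma_nm = 2)
radial_profile(m, estimate_center(m))
#> <radial_profile> 53 bins, peak at 23.50 nm (density 0.3118)
```

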