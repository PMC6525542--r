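---
title: "Methods: fullerene capsid lattice analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fullerene capsid lattice analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidlattice)
```

# The model

Retroelement and retrovirus capsids are fullerene shells: closed surfaces
tiled by hexamers of CA with exactly 12 pentamers supplying the total
curvature that Euler's formula demands.  In Caspar–Klug terms a shell is
indexed by two non-negative integers \((h, k)\): the shortest lattice route
between two pentamers runs \(h\) steps along one hexagonal lattice
direction, turns 60°, and runs \(k\) further steps, giving the
triangulation number

\[ T = h^2 + hk + k^2. \]

An icosahedral \(T\)-shell has \(60T\) subunits in \(10T + 2\) capsomers
(12 pentamers, \(10(T-1)\) hexamers), and its asymmetric unit holds \(T\)
quasi-equivalent subunits.  Not every particle is icosahedral: pentamers
may be unevenly distributed, in which case different pentamer pairs return
different local \(T\) values ("mixed") and the shell deviates from
sphericity; and many imaged particles are damaged or incomplete.  The
package's job is to start from capsomer centre coordinates — the quantity
that subtomogram averaging actually delivers — and recover coordination
environments, closure, and local/global T-numbers, plus the density-map
and packaging arithmetic that surrounds such an analysis.

# Synthetic data: what it emulates, and what it does not

The generators produce the *geometry* of lattice maps and particle
averages, under the package's control so every analysis step has exact
ground truth:

- `generate_icosahedral(h, k, radius_nm)` builds the \((h,k)\) geodesic
  triangulation of the icosahedron; its vertices are the capsomer centres
  of the dual Goldberg shell, projected onto the sphere (default) or left
  on the planar facets (`projection = "facetted"`).  The two conventions
  differ by roughly 10% in inter-capsomer distances; spherical is the
  default because imaged particles are quasi-spherical.  Faces are
  consistently oriented before tiling — for chiral lattices
  (\(h \neq k\), \(k > 0\)) a mirrored face parametrization would tile
  mirror-image patches that do not mesh across edges.  \((h,k)\) and
  \((k,h)\) are enantiomers; both generate, and the analysis
  canonicalises to \(h \ge k \ge 0\) since \(T\) is chirality-blind.
- `generate_prolate(h_cap, q_rings, radius_nm)` builds a closed tubular
  shell from two \((h_{cap}, 0)\) icosahedral caps about a fivefold axis
  separated by `q_rings` rings of \(5\,h_{cap}\) hexamers.  The equatorial
  band is one \(5h \times (h+q)\) patch of hexagonal lattice wrapped on a
  cylinder — the skew (chiral) elongation, which is the one that keeps
  every capsomer on an exact lattice point.  Two geometric details matter:
  each inserted ring advances the lattice by half a spacing
  circumferentially, so the band carries a progressive twist of
  \(\pi/(5h)\) per ring and the far cap is rotated by the accumulated
  twist; and the shell is only partially inflated toward the bounding
  spherocylinder (`inflate = 0.5`), because full inflation stretches the
  equatorial lattice anisotropically enough to distort neighbour
  distances.  How real irregular particles deviate from sphericity is not
  known in geometric detail; the prolate family is a representative,
  well-defined generator of closed mixed-T shells, not a claim about any
  particular specimen.
- `perturb(set, sigma_nm, drop_fraction, seed)` models subtomogram
  localisation error (isotropic Gaussian displacement) and particle damage
  (uniform random capsomer loss), with a single integer seed recorded in
  provenance.  Removal happens first, then displacement of the survivors.
- `render_density(set, voxel_nm, blob_sigma_nm, interior)` renders unit
  Gaussian blobs at capsomer centres.  `interior = "thick_shell"` adds a
  wide layer directly beneath the capsomer shell with an empty centre
  (immature-like morphology: thick rings, empty inside);
  `"condensed_core"` adds a compact central ball (mature-like: thin ring
  with condensed material in the middle).  Interior amplitudes are scaled
  to the map's own rotationally averaged shell density (50% and 80% of it,
  respectively) so the capsomer layer remains the radial-profile peak for
  any capsomer count, radius or blob width.

The generators deliberately do **not** simulate tomographic imaging: no
missing wedge, no contrast transfer function, no projection artefacts, no
membrane or Gag-polyprotein internal structure, and no atomic coordinates.
Passing tests on synthetic data therefore demonstrate the correctness of
the lattice and map analysis given capsomer positions and densities of the
stated form — they do not certify performance on raw tomograms, where
localisation error is anisotropic and correlated.

# Capsomer adjacency

The neighbour rule is the one genuinely open design in the pipeline, since
lattice maps are published as pictures, not as adjacency criteria.  The
package uses a two-stage rule in `build_graph`:

1. **Local distance cutoff.** Two capsomers are candidate neighbours if
   their distance is at most `cutoff_factor` (default 1.4) times the local
   lattice spacing, estimated per capsomer as the median of its six
   smallest distances.  The reference is local, not global: projection
   onto a sphere or spherocylinder makes the spacing vary systematically
   by ~10% across the shell, and a global median wastes margin on that
   variation.  The median-of-six statistic centres on the first neighbour
   shell and is robust to single outliers; 1.4 sits between the first and
   second shells (1.0 and \(\sqrt{3} \approx 1.73\) spacings).
2. **Flip pruning.** Under positional noise the two distance shells
   overlap, so a pure cutoff occasionally admits a second-shell pair.
   Such a spurious edge always crosses a shorter true edge whose endpoints
   are common neighbours of the spurious pair.  Every edge is therefore
   tested against the local Delaunay flip criterion — drop \((i,j)\) if a
   shorter edge between two of its common neighbours geometrically crosses
   it in the tangent plane.  The crossing test is essential: without it, a
   single admitted false edge can make a *true* edge appear flippable and
   fracture the lattice.  On noise-free lattices the criterion never
   fires, because there the flanking pair of any true edge is 1.73
   spacings apart — farther than the edge itself.

With this rule, T-recovery and class labels on ideal lattices
(\(h \le 4\)) under 5% positional noise were exact in all 140 trial
perturbations measured during development, comfortably above the 95%/99%
targets the test suite enforces over 50 seeds per lattice.  A
convex-hull/spherical-Delaunay adjacency mode was considered as a
heavy-noise fallback and dropped: no installed qhull-style dependency is
available, the flip-pruned cutoff already saturates the targeted noise
regime, and a hull triangulates across lattice gaps, which would require
its own pruning to avoid closing damaged particles.

Classification then follows the lattice-map colour rule: degree-5
capsomers are fivefold (blue); degree-6 capsomers with a fivefold
neighbour are pseudothreefold (green); degree-6 capsomers surrounded by
sixfold positions are true threefold (yellow).  Anything else — boundary
capsomers of damaged particles, or degree-7+ noise artefacts — is labelled
`edge` (grey) and excluded from class counts, so lattice gaps never
masquerade as symmetry environments.  Whether partially bounded capsomers
should enter class statistics is unstated in the source imagery
convention; exclusion plus an explicit excluded-count is the conservative
choice.  Closure requires all coordinations in {5, 6}, a connected graph,
and the discrete Gauss–Bonnet sum \(\sum_v (6 - \deg v) = 12\).

# The lattice walk

`local_t` assigns integer axial coordinates on the hexagonal lattice by
breadth-first frame transport.  Starting at pentamer \(i\), one neighbour
is anchored at \((1,0)\); each visited hexamer orders its six neighbours
counterclockwise about the outward normal and assigns them the six unit
hex steps, rotated to agree with the already-known step to a reference
neighbour.  Frames are path-dependent around pentagonal disclinations, so
walks propagate through hexamers only: corridors containing other
pentamers are never used, which implements the "shortest route between two
pentamers" reading.  All five start directions are tried, every coordinate
under which the target pentamer is reached is collected, and the
minimal-\(T\) canonical result is returned; pairs with no hexamer-only
corridor are reported unresolvable rather than failing.

`particle_t` selects the pentamer pairs: for closed shells, the edges of
the convex-hull triangulation of the 12 pentamer direction vectors (the
natural geodesic "neighbouring fivefold positions", exactly 30 pairs for
icosahedral particles; the hull is brute-force over face triples, which is
trivial at \(n = 12\)); for incomplete shells, mutually nearest pentamer
pairs.  The verdict is `icosahedral(T)` iff all local T agree and match
the closed-shell count \(T = (N-2)/10\); `mixed` for closed shells with
disagreeing local T; `incomplete` otherwise — damaged particles never
receive a global T, only their resolvable local values.  One caveat is
inherent to coordination-based classification: in a damaged lattice a
hexamer that has lost one neighbour has degree 5 and is indistinguishable
from a pentamer by coordination alone, so local T values listed for
incomplete particles can include spurious small entries from such
boundary pairs.

# Density-map analysis

Radial profiles bin voxels by distance to the centre at one-voxel width
with no smoothing (the rawest choice; smoothing is an explicit option via
`bin_nm`).  The shell radius is the bin-centre of maximal mean density.
`estimate_center` initialises at the density centre of mass and refines by
Nelder–Mead, maximising profile sharpness (peak height over width at half
maximum); flat maps raise a no-particle error, and boxes whose bright mask
splits into two or more comparable connected components raise an ambiguity
error rather than silently returning a midpoint.

Morphology typing operationalises "empty inside" versus "condensed
material in the middle": the statistic is the ratio of mean density inside
\(0.6 \times\) the peak radius to the peak shell density, and the
two-group threshold is data-driven (largest gap in the sorted ratios, with
a degenerate-split warning when no meaningful gap exists).  Peak
statistics ignore radial bins holding fewer than eight voxels: the
innermost bins contain a handful of voxels whose means are far too noisy
to anchor the shell radius.  Group-mean profiles are returned, mirroring
the practice of averaging morphology groups separately.

Cyclic-symmetry spectra score each candidate order \(n\) by the
correlation of a subvolume with itself rotated by \(360°/n\) about a given
axis (trilinear resampling); a pentamer peaks at \(n = 5\), and a hexamer
built from three dimers peaks at \(n = 3\) despite its six blobs —
the trimeric appearance of sixfold positions.  Rotationally uniform
objects score ≈ 1 at every order and are flagged ambiguous rather than
assigned the arbitrary argmax.

`align_average` is translational only (integer-voxel shifts by FFT
cross-correlation, zero-filled), mirroring in-cell particle averaging;
rotational refinement is out of scope.  `fsc` uses shells one frequency
voxel wide and reports threshold crossings at 0.5 and 0.143 by linear
interpolation; no masking or phase-randomisation corrections are applied,
since the mask parameters used in any particular study are unstated and
guessing them would manufacture resolution figures.  `shrinkage_correct`
is plain rescaling by a calibration factor (default 25/21 in
`run_config`, the embedding-shrinkage correction that takes a 21 nm
measured radius to its ~25 nm unshrunken value).

# Packaging arithmetic

`packaging_stats` computes bases per Gag, \(1000 \cdot kb \cdot
copies / N_{Gag}\), and interior volume per base.  The interior volume is
an *input*: which radius bounds the interior (centre of the CA layer
versus its inner surface) is a modelling choice the package does not make;
`sphere_volume_nm3` does the \(\tfrac{4}{3}\pi r^3\) arithmetic for a
user-chosen inner radius.  One-significant-figure roundings are emitted
alongside the raw values because such capacity numbers are conventionally
quoted to one figure.

# Numerical choices and degenerate inputs

- Units are nm throughout; MRC headers are converted (Å ↔ nm, factor 10)
  at the I/O boundary, ORIGIN is honoured and the start-index records are
  ignored with a note, and only axis order MAPC/MAPR/MAPS = 1/2/3 is
  accepted.
- Coordinates in written capsomer tables are particle-centred by default
  and carry 17 significant digits, so tables round-trip doubles exactly.
- All randomness flows through single integer seeds recorded in
  provenance; `perturb` restores the caller's RNG state.
- Generator degeneracies are rejected with explicit errors: \(h = k = 0\),
  non-positive radii, drop fractions that leave no capsomers, collinear or
  coincident point sets, voxels coarser than 8 per particle diameter,
  unsupported MRC modes (named by number), unclassified graphs passed to
  the marker writer.
- Reports contain no timestamps, so a fixed configuration yields
  byte-identical JSON across runs.

# Problem sizes used by the test and acceptance suites

The suites run entirely on generated data: the \((h,k)\) grid up to
\(h = 4\) (shells of 12–482 capsomers), prolate shells up to
\((h, q) = (4, 3)\), 50-seed perturbation sweeps at \(\sigma = 5\%\) of
the lattice spacing, 50-seed morphology mixtures of eight maps each at
power SNR 1 on a 32-capsomer shell at 18 nm radius, and FSC/alignment
checks on 24–61 voxel cubes.  These sizes were chosen as the smallest at
which every property being asserted is well-resolved statistically.

# Known limitations

- Coordination-based pentamer identification cannot distinguish a true
  pentamer from a hexamer at a lattice boundary (see above); only closed
  shells receive global verdicts for this reason.
- The adjacency rule targets localisation noise up to ~5% of the lattice
  spacing and uniform random capsomer loss; heavily anisotropic or
  spatially correlated distortions (e.g. flattening against a support
  film) are untested regimes.
- `align_average` has no rotational degree of freedom and integer-voxel
  precision only.
- FSC resolutions are unmasked and will underestimate what a masked
  protocol would report on the same maps.
- The experimental composition of any real dataset (fractions of complete,
  mixed and damaged particles, attained map resolutions) depends on raw
  data this package does not model; the package reproduces the geometry
  and arithmetic of the analysis, and its dataset-level aggregates reflect
  whatever synthetic composition the user generates.
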