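Package: capsidlattice
Title: Fullerene Capsid Lattice Analysis and Triangulation-Number Determination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generation and analysis of fullerene (pentamer/hexamer) capsid
    lattices of the kind recovered by cryo-electron tomography and
    subtomogram averaging of retroelement and retrovirus particles.
    Provides synthetic generators for ideal icosahedral (h,k) Caspar-Klug
    lattices, skew-elongated (prolate) shells with mixed local
    triangulation numbers, positional noise and capsomer loss; capsomer
    neighbour-graph construction and symmetry-environment classification
    (fivefold, pseudothreefold, true threefold); local and global
    T-number determination by disclination-aware lattice walks; closure
    (fullerene) detection via the discrete Gauss-Bonnet sum; radial
    density profiling and morphology typing of particle density maps;
    cyclic-symmetry spectra; translational align-and-average; Fourier
    shell correlation; and genome-packaging density arithmetic.
    Includes MRC2014 and tabular I/O plus Chimera-style lattice-map
    marker output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
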