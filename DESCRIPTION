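Package: cmcnano
Title: Modelling Amphiphilic Carboxymethyl Cellulose Nanovehicles
Version: 0.1.0
Authors@R:
    person("Dev", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for statistical modelling of substituted-cellulose
    polyelectrolytes and their zinc-carrying self-assemblies. Generates
    carboxymethyl cellulose (CMC) and N-octyl-amidated CMC (CMC-8) chains
    under reconciled positional and class substitution statistics, embeds
    them as coarse-grained bead conformers with tunable persistence length,
    computes Debye-Hueckel screened electrostatic potential grids with
    negative-potential hotspot detection and greedy Zn2+ placement, packs
    chains into periodic boxes at a target bulk density with hydrophobic
    (alkyl) and acidic (carboxylate) cluster detection, and implements two
    bench assay computations: critical aggregation concentration from pyrene
    I3/I1 titration curves (two-segment intersection) and octyl-amide degree
    of substitution inverted from elemental C/N analysis. Every input can be
    produced by seed-deterministic synthetic generators with ground-truth
    sidecars, and chains, coordinates and grids round-trip through JSON/CSV,
    XYZ/PDB and OpenDX files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
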