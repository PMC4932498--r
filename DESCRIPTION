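Package: dendrimicelle
Title: Coarse-Grained Modelling and Self-Assembly Analysis of Amphiphilic
    Dendrimer / siRNA Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds MARTINI-style coarse-grained topologies for amphiphilic
    PAMAM dendrimers (generations 0-2, alkyl tails of 13/15/18 carbons) and
    for an elastic-network 20 base-pair siRNA duplex; generates seeded
    synthetic micelle, dendriplex and micelle-fusion configurations; and
    implements the micelle and interaction analysis layer: aggregate
    detection under periodic boundaries, radius-of-gyration geometry, the
    Israelachvili packing parameter with sphere/cylinder/bilayer
    classification, interdigitation and surface-charge indices,
    Shrake-Rupley solvent-accessible surface area, contact and
    solvation-shell counters, per-base-pair radial distribution functions,
    and amine-phosphate (N/P) binding statistics.
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
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
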