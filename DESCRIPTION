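Package: scafdock
Title: Simultaneous Docking and Mutation of Fixed-Backbone Binding Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Rigid-body docking of small fixed-backbone binding scaffolds
    (affibody/DARPin-style) onto a target epitope by geometric matching of
    hydrogen-bond half-sites. Scaffold paratope residues, both in their
    native form and as rotamers of polar mutations, contribute donor and
    acceptor half-sites whose pairwise distances and quadrilateral angles
    are matched against exposed epitope polar atoms. Mutually compatible
    interaction sets of three or more designed hydrogen bonds define
    candidate poses, which are realized by least-squares superposition and
    screened with steric-clash, coarse-grained interface and hydrogen-bond
    validation filters. Remaining clashes of mutable side chains are
    rescued by an ordered feature-based mutation cascade (repack, salt
    bridge, polar, nonpolar). Includes a synthetic fixture generator that
    plants hydrogen-bond geometries with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
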