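Package: airtree
Title: Deterministic Volume-Filling Generation of the Human Conducting Airway Tree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates anatomically consistent three-dimensional models of the
    conducting bronchial tree by deterministic, fractal space subdivision inside
    confining lobar volumes. A voxel lobe mask is discretized into a seed grid;
    starting from segmented (or synthetic stub) central airways, each unflagged
    leaf recursively splits its sub-space by a plane through the centre of
    volume, growing child branches toward the sub-space centroids under
    physiological length, diameter and branching-angle constraints until
    terminal-bronchiole stopping criteria are met. Includes the full
    morphometric analysis suite used for validation: generation, Horsfield and
    Strahler ordering, branching/diameter/length ratios from log-linear fits,
    homothety ratios, branching and planar rotation angles, acinar-volume
    statistics, and order-range normalization, plus readers and writers for a
    plain-text airway morphology/connectivity exchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    RNifti,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
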