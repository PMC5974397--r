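Package: oligoscope
Title: Oligomeric-State Classification of Membrane Proteins from Simulated AFM Topographs and Exciton-Coupled CD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for determining the oligomeric state of ring-forming membrane
    proteins such as microbial rhodopsins. Simulates atomic force microscopy
    (AFM) topographs from atomic structures with a hard-sphere tip model
    (blended sphere/cone probe, grayscale dilation), measures ring geometry
    from height maps (subunit peaks, rotational symmetry order, peak-circle
    and outer diameters, central protrusion or pore), and predicts the sign
    and shape of exciton-coupled circular dichroism (CD) couplets from retinal
    chromophore geometry with a point-dipole matrix method. Includes a
    synthetic ring-oligomer generator with exact ground truth so the whole
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
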