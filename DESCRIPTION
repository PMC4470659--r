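Package: swarmtrack
Title: Multi-Camera 3D Tracking of Fruit Fly Swarms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A multi-camera three-dimensional tracking system for swarms of
    flying fruit flies (Drosophila melanogaster) in a confined cubic arena.
    Converts synchronized back-lit grayscale image sequences from three or
    more calibrated cameras into per-fly trajectories of position and body
    orientation, using background-subtraction blob detection with wing-pixel
    removal and intensity-weighted sub-pixel ellipse fitting, a particle
    filter with first-order linear extrapolation dynamics, cross-view
    pixels-occupancy association, orientation reconstruction by intersecting
    back-projected ellipse major-axis planes, and generative-shape validation
    and correction. Also provides swarm-statistics analyses (kinematics and
    z-scores, polarisation, nearest-neighbour distances with wall-margin
    filtering, power-law density scaling, acceleration-direction maps) and a
    ground-truthed synthetic multi-view swarm simulator and renderer for
    end-to-end testing without original video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
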