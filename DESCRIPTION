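Package: ventbloom
Title: Hydrothermal Iron Supply and Phytoplankton Bloom Diagnostics for the
    Southern Ocean
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An observational pipeline linking mid-ocean-ridge hydrothermal
    activity to open-ocean phytoplankton blooms. Processes biogeochemical
    Argo float profiles (fluorescence calibration, non-photochemical
    quenching correction, mixed-layer and euphotic depths, depth-integrated
    chlorophyll), characterizes annual bloom cycles and compares bloom
    types, estimates surface and deep eddy kinetic energy from gridded
    velocities and float displacements, builds optimally interpolated
    potential-density climatologies with alongstream isopycnal differencing
    in dynamic-height coordinates, models horizontal iron delivery by
    backward Lagrangian advection with exponential scavenging, and grids
    helium-isotope tracer sections. A seeded synthetic-data generator
    emulates every input with prescribed ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
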