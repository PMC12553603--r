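Package: gustfall
Title: Accelerating-Frame Simulation of Transverse Gust Response for
    Free-Falling Bodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the response of untethered free-falling bodies, such as
    plant diaspores, to uniform irrotational transverse gusts using the
    accelerating (wind-tunnel) frame method: rigid-body dynamics with
    quasi-steady aerodynamic closures, reduced gust forces and buoyancy
    torques in a non-inertial frame, the equivalent inertial-frame
    formulation, and the effective-gravity construction. Includes the
    dimensionless scaling (Galilei number, density ratio), facility
    characterisation statistics for gridded velocity fields (flow uniformity,
    turbulence intensity, frame shifting), marker-track kinematics extraction
    (de-noising, differentiation, stem-angle convention), seeded synthetic
    fixtures emulating a translating vertical wind tunnel, and a command-line
    interface for batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
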