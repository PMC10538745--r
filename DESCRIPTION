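Package: osseogait
Title: Musculoskeletal Simulation of Osseointegrated Transfemoral Amputee Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sagittal-plane musculoskeletal modelling and simulation toolkit
    for level-ground walking of people with a unilateral osseointegrated
    transfemoral amputation wearing a generic prosthesis. Builds a generic
    23-DOF/92-muscle lower-extremity model and a 19-DOF/76-muscle amputee
    variant with ideal torque actuators at the prosthetic knee and ankle;
    reads and writes TRC marker and MOT/STO force and motion files; performs
    model scaling, inverse kinematics, inverse dynamics with ground reaction
    forces, residual reduction, modified static optimization of the muscle
    redundancy, and a modified computed-muscle-control forward simulation
    that co-ordinates Hill-type muscles with the prosthesis actuators.
    Includes a dynamically consistent synthetic gait-trial generator and
    post-processing of joint powers, energies, and muscle-group forces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    xml2,
    optparse
Suggests: testthat (>= 3.0.0), pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
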