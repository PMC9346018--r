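Package: patellofem
Title: Patellofemoral Finite-Element Contact Analysis of Virtual Trochleoplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static finite-element analysis of patellofemoral cartilage
    contact in healthy and trochleodysplastic knees, before and after virtual
    sulcus-deepening trochleoplasty. Provides parametric synthetic knee
    geometries (healthy and Dejour type-D dysplastic presets) with cartilage
    thickness maps and anatomical landmarks, a sulcus lateralization/deepening
    surgery operator with configurable correction factors, linear-elastic
    tetrahedral cartilage meshes bonded to rigid bone, spring-and-muscle
    loading of the patella, a penalty / augmented-Lagrange contact solver,
    thresholded contact-stress and Von Mises stress metrics, alignment indices
    (TT-TG, patellar tilt, bisect offset), and the summary statistics used to
    compare the resulting pressure distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
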