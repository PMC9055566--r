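Package: goniostack
Title: Focal-Plane Merging of Gonioscopic Image Stacks by Tiled Fourier
    Burst Accumulation
Version: 0.1.0
Authors@R: person("goniostack", "developers", role = c("aut", "cre"),
    email = "goniostack@example.org")
Description: Merges an ordered focal stack of anterior-segment (gonioscopic)
    photographs into a single deep-focus image by applying Fourier Burst
    Accumulation independently to overlapping local tiles and blending the
    tiles with a raised-cosine overlap-add window. Includes the Laplacian
    focus measure (mean absolute discrete second derivative) used for
    best-frame selection and objective sharpness comparison, a seeded
    synthetic focal-stack generator with known all-in-focus ground truth,
    exact sign-test statistics for paired forced-choice comparisons, and a
    command-line workflow (simulate, merge, measure, evaluate).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    jpeg,
    optparse,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
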