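Package: aortamech
Title: Evaluation of In Vivo Arterial Parameter Identification Against
    Thick-Walled Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates residually stressed, thick-walled abdominal aortas as
    incompressible Holzapfel-Gasser-Ogden cylinders under extension and
    inflation, identifies constitutive membrane-model parameters from the
    resulting pressure-radius response by bounded multi-start least squares,
    and quantifies how well the membrane model reproduces the wall stress
    state and the collagen-attributed load-bearing fraction. Ships the 21
    published in silico parameter sets and the identified membrane parameter
    sets as fixtures, and regenerates the published comparison tables,
    transmural stress gradients, and group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    magrittr,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
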