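Package: rflpdiet
Title: RFLP-Based Diet Inference for Small Known Plant Communities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring herbivore diet from restriction fragment
    length polymorphism (RFLP) of amplified plant barcode regions. Performs
    in-silico PCR against reference ITS2 sequences, virtual restriction
    digestion, selection of minimal enzyme panels that discriminate all
    members of a small plant community, mixture-aware identification of host
    plants from observed gel band sizes, and the diet summary statistics used
    in mesocosm feeding studies (success proportions with Wilson intervals,
    paired-sample agreement, species-per-sample means, detection-bias
    deviance tables, contingency chi-squared tests and trait regressions).
    Includes a synthetic-data generator that emulates a grassland mesocosm
    experiment so every stage of the pipeline can be tested end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
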