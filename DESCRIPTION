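Package: boafhir
Title: FHIR R4 Profiles and Tooling for AI-Derived CT Body Composition
    and Organ Volume Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Represents the output of automated CT body-and-organ analysis
    (tissue volumes and densities per body region, organ volumes, model
    provenance) as profile-conformant HL7 FHIR R4 resources. Ships the
    value sets binding body sites, tissues, regions and 104 anatomical
    landmarks to SNOMED CT or a project-local code system; builders for
    the BCA Observation, Body Structure Volume Observation, Diagnostic
    Report and Imaging Study profiles with AIAST provenance tagging; a
    conformance validator with machine-readable issues; a seeded synthetic
    result generator; and a round-trip extractor back to tidy measurement
    tables, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
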