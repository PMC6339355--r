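Package: operonDesign
Title: Design-of-Experiments Automation for Combinatorial Operon Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An automated design-build-test workflow for combinatorial
    metabolic-pathway engineering. Characterised biological parts (promoters,
    ribosome binding sites, coding sequences) are ranked by relative strength,
    the full factorial space of operon configurations is enumerated, and a
    D-optimal subset of constructs is selected by coordinate exchange for a
    stated linear model. Selected constructs are translated into acoustic
    liquid-handler picklists for modular (linker-based) DNA assembly.
    Screening measurements (OD600 and LC peak areas) are converted to product
    titres in mg per g dry cell weight via a fitted standard curve, factor
    effects are screened by least squares with partial-F LogWorth statistics,
    and the configuration predicted to maximise titre is reported. A seeded
    titre simulator with promoter-strength-dependent assembly failure stands
    in for the wet lab so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'partLibrary.R'
    'designSpace.R'
    'modelMatrix.R'
    'doptimal.R'
    'assembly.R'
    'quantify.R'
    'effects.R'
    'simulate.R'
    'demoData.R'
    'pipeline.R'
    'operonDesign-package.R'
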