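Package: radvar
Title: Rare-Variant Gene Discovery and Ancestry Concentration Analysis
Version: 0.1.0
Authors@R: person("ADSP", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-based rare-variant association testing and carrier profiling
    for multi-ancestry case-control sequencing studies. Builds Sequence
    Ontology consequence masks (loss-of-function, protein-altering,
    splice-region), runs covariate-adjusted burden, SKAT, SKAT-O, ACAT-V and
    ACAT-O score tests per gene and mask, computes ancestry-stratified carrier
    odds ratios with Haldane-Anscombe correction, carrier trait shifts
    (Wilcoxon / Hodges-Lehmann, Fisher), ancestry-concentration metrics
    (dominant-ancestry proportion, Gini-Simpson diversity) and allele-age
    summaries, and ships a seeded synthetic multi-ancestry cohort generator so
    the whole pipeline is testable without controlled-access genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    yaml,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
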