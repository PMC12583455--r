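Package: fpftiers
Title: Tiered Virtual Gene Panels for Familial Pulmonary Fibrosis Variant Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a tiered virtual-gene-panel strategy for identifying
    relevant germline variants in familial pulmonary fibrosis (FPF) from
    annotated multi-sample exome VCFs. Provides tier-0 rarity/consequence
    filtering, an ACMG/AMP combining-rules classification engine with
    VUS-LP/VUS-LB subclasses and a telomere-length supporting criterion,
    age-normalised telomere-length Z-scores and percentiles, sequential
    application of three gene panels gated by ACMG class and severe telomere
    shortening, family-level diagnostic-yield estimation with Wilson
    confidence intervals, exact and asymptotic association statistics,
    concordance metrics against external variant prioritizers, and a
    pedigree-aware cohort simulator with planted pathogenic variants for
    end-to-end validation. A bundled fixture transcribing the published
    cohort tables allows the whole pipeline to run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
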