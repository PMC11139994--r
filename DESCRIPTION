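Package: abppquant
Title: Competitive ABPP Quantification and Targeted FAHFA Lipidomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipelines for competitive activity-based protein
    profiling (ABPP) of serine/threonine hydrolases and for targeted FAHFA
    lipidomics. Implements isobaric (TMTpro) reporter-ion extraction from
    centroided peak lists, per-channel signal-to-noise normalization, PSM
    quality filters, protein-level competition-ratio rollup with capping and
    percent-competition conversion, reductive-dimethylation (light/heavy)
    median-ratio rollup, four-parameter logistic IC50 fitting of
    gel-densitometry dose series, internal-standard quantification of FAHFA
    MRM peak areas, a molecular-formula mass calculator with adduct and
    isotope-label support that generates FAHFA MRM transition tables, and
    seeded synthetic-data generators so that every stage can be exercised
    against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
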