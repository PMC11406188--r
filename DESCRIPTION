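Package: ncburden
Title: Recessive Burden Analysis of Conserved Non-Coding Elements and
    Reporter Assay Activity Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control burden analysis of rare, recessive variants
    (homozygous, transmission-phased compound-heterozygous, and male
    X-hemizygous genotypes) in classes of conserved non-coding elements
    such as human accelerated regions, VISTA enhancers, and conserved
    neural enhancers. Provides element-set construction from
    conservation and chromatin-state annotations, per-cohort genotype
    quality control, an ensemble damaging/neutral variant classifier,
    Woolf odds-ratio statistics with a consanguinity correction and
    contribution estimates, massively parallel reporter assay (MPRA)
    barcode-count analysis with directional barcode error correction,
    and synthetic cohort and MPRA library generators with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
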