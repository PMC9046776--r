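Package: matepairsv
Title: CNV, Structural Variant and Absence-of-Heterozygosity Detection
    from Mate-Pair Low-Pass Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection of copy-number variants, structural rearrangements
    and regions with absence of heterozygosity (AOH) from large-insert
    (mate-pair) low-pass genome sequencing. Implements read-depth CNV
    calling on adjustable sliding windows (50 kb with 5 kb increments) and
    non-overlapping 5 kb windows with GC and reference-panel normalization,
    step-statistic boundary refinement, and a dedicated homozygous /
    hemizygous deletion rule; chimeric read-pair selection (inter-chromosomal
    or >= 10 kb span), single-linkage junction clustering, and a joint
    depth-plus-junction event grammar that resolves duplication orientation
    (forward tandem, insertional, complex, or unresolved within low-copy
    repeats); windowed heterozygous/homozygous SNV rate analysis for AOH,
    uniparental-disomy and consanguinity flagging; ISCN-like rearrangement
    nomenclature emission and parsing; and a seeded simulator that generates
    aligned mate-pair tables, pileups and truth sets over a toy genome so
    every engine is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
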